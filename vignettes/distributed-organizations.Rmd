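---
title: "Distributed organizations and organizational reaction sets: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed organizations and organizational reaction sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosor)
```

## The structural question

A reaction network is a set of $n$ species and $m$ reactions
$\sum_i a_{ij}\,s_i \rightarrow \sum_i b_{ij}\,s_i$ with non-negative
integer coefficients, summarised by the stoichiometric matrix
$N \in \mathbb{Z}^{n\times m}$, $N_{ij} = b_{ij}-a_{ij}$. Chemical
organization theory asks which sub-systems of such a network can sustain
themselves: a species set $S$ is *closed* when the products of every
reaction whose support (reactant set) lies inside $S$ also lie inside
$S$, and *self-maintaining* when some flux $v \ge 0$, strictly positive
exactly on the reactions supported by $S$, achieves $Nv \ge 0$. A closed
and self-maintaining set is an *organization* — the classic structural
candidate for a long-term state of the corresponding dynamical system.

Spatially or temporally extended systems can do more: different
*compartments* can run different reaction subsets, none of them
self-maintaining alone, while the summed flux is. A *distributed
organization* (DO) is a species set $D$ that is a union of closed
compartments $S_1,\dots,S_k$ with per-compartment feasible fluxes
$\hat v^i$ whose sum $\hat v$ satisfies $N\hat v \ge 0$. A DO with no
single-compartment realisation is a *genuine* DO; persistent subspaces
of reaction–diffusion dynamics are always DOs, which makes the complete
DO inventory of a network a structural map of everything that can
persist. This package computes that inventory exactly, from the network
alone, with no kinetic information.

## From species to reactions

Working on reaction sets rather than species sets makes the search
tractable. The *elementary reaction closure* of a reaction $\hat r$,

$$\mathrm{ERC}(\hat r) = \{\,r : \mathrm{supp}(r) \subseteq
\mathrm{clos}(\mathrm{supp}(\hat r))\,\},$$

collects the reactions that are unavoidably activated once $\hat r$
runs (`create_ercs()`). A *set of organizational reactions* (SOR) is a
reaction set $R$ that (i) is ERC-closed, $R = \bigcup_{r\in R}
\mathrm{ERC}(r)$, and (ii) admits a flux with support exactly $R$ and
$Nv \ge 0$. Every SOR runs on a minimal DO — the union of the closures
of its reaction supports — and every DO realises at least one SOR, so
enumerating SORs and DOs together yields the full picture. Both the set
of SORs and the set of DOs of a network form lattices under inclusion:
the supremum of two SORs is their union (compartmentalizations can be
placed side by side), the infimum is the union of all SORs inside the
intersection.

## The mixed-integer programs

`all_sors()` maximises $\sum_j b_j$ over $(v, b) \in \mathbb{R}_+^m
\times \{0,1\}^m$ subject to

* $Nv \ge 0$ (self-maintenance),
* $b_j \ge b_k$ whenever $r_j \in \mathrm{ERC}(r_k)$ (reaction closure,
  emitted on the transitively reduced ERC containment graph: one
  equality per mutual-containment class member and one inequality per
  reduced edge),
* $b_j = 1$ for inflow reactions (reactions with empty support are
  active in every feasible flux),
* $c\,b_j \ge v_j \ge b_j$ with $c = 10000$, the big-M coupling that
  makes $b_j = 1$ equivalent to $v_j > 0$. Encoding strict positivity
  as $v_j \ge 1$ is harmless because $Nv \ge 0$ is scale-invariant; the
  upper bound $c$ caps the dynamic range of a witness flux, which is far
  above anything the bundled and generated networks require.

The optimum is the largest SOR. All remaining SORs are obtained by
adding, per solution found, one *no-good integer cut*
$\sum_{j: b_j = 1}(1-b_j) + \sum_{j: b_j = 0} b_j \ge 1$ and re-solving,
so solutions arrive in non-increasing size until the program is
infeasible (`integer_cut()`, exposed for transparency). The full
no-good cut over the complete binary vector is the only cut that
excludes exactly one solution, which is what complete enumeration — not
just enumeration of maximal solutions — requires.

`all_dos()` adds one binary $e_i$ per species and maximises
$\sum_i e_i$ under two additional families: $e_i \ge b_j$ for every
species taking part in reaction $j$ (active reactions pull their
species into $D$), and $b_j \ge e_i$ whenever
$\mathrm{supp}(r_j) \subseteq \mathrm{clos}(\{s_i\})$ (a present species
activates everything its own closure supports). Cuts run over the
concatenated $(b, e)$ vector, so the program enumerates DO–SOR *pairs*;
projection onto distinct $e$-patterns gives the DOs and the retained
pair map gives each DO its realisable SORs. Every feasible $(b,e)$
point is certifiably a DO: the closures $\mathrm{clos}(\{s_i\})$ and
$\mathrm{clos}(\mathrm{supp}(r_j))$ of the active rows are closed
subsets of $D$ that cover $D$ and jointly support exactly the SOR. The
package still validates this invariant in its test suite via the
compartment machinery rather than assuming it.

## Compartments

For a DO–SOR pair, `create_mcs()` computes all *maximal compartments*:
inclusion-maximal subsets of the DO that are closed and support only
SOR reactions. The algorithm starts from the full DO species set and
repeatedly splits any candidate that supports a violating reaction — a
reaction outside the SOR, or one whose products escape the candidate —
into one child per support species, each child missing exactly that
species; subset candidates are pruned throughout, and a candidate
supporting a violating inflow reaction is discarded outright since an
empty support cannot be broken. Termination follows because children
are strictly smaller; correctness because any valid compartment must
omit at least one support species of every violating reaction, so some
branch preserves every maximal valid set.

`get_min_compartments()` then solves the exact set-cover integer
program: choose the fewest MCs such that every species of
$\mathrm{species}(\mathrm{SOR})$ is covered and every SOR reaction's
support lies inside a chosen MC. The optimal *size* is unique; the
chosen MCs need not be, and ties are left to the solver. The cover is
taken over $\mathrm{species}(\mathrm{SOR})$, not the whole DO: the
worked micro-RNA example drops a non-reacting species from a compartment
"without impacting the active reactions", which identifies the species
of the SOR as the operative requirement. A strict mode
(`cover_do = TRUE`) additionally covers all DO species for users who
want the literal union-equals-DO reading. A SOR whose minimal DO admits
a one-compartment cover is an organization; a DO is an organization
precisely when it is closed and its full supported reaction set is
self-maintainable, and `is_organization()` tests exactly that — the two
views coincide because a single compartment must equal the whole DO.

## The built-in solver

No MILP library is attached: the programs are solved by an exact
branch-and-bound over a dense two-phase simplex written for this
package (`solver_backend("simplex_bb")`). The LP core equilibrates
rows, recomputes reduced costs from the tableau every iteration,
refactorises the tableau from the original data at fixed intervals and
before accepting optimality or feasibility verdicts, prefers large
pivot elements among ratio-test ties, and falls back to Bland's rule
under stalling. Every LP answer is verified against the original
constraints; a solve that fails verification is retried once under
Bland's rule and otherwise surfaces as an error, which the
branch-and-bound treats by branching (keeping the search complete)
rather than pruning. Incumbents are accepted only after passing the
same verification. These measures are what the degenerate,
big-M-coupled enumeration programs demand; the unit tests cross-check
the LP core against an independent simplex implementation and the whole
enumeration path against brute-force oracles. The backend interface is
a two-function contract (`solve`, `enumerate`), so an external MILP
solver can be registered under a name and selected through
`enumeration_config()` without touching the enumeration code;
solution-pool style backends fit the same contract as iterative-cut
ones, and results must be set-identical either way.

Numerical parameters: positivity/feasibility tolerance $10^{-7}$ (one
order above typical LP tolerances), big-M $c = 10000$, integrality
tolerance $10^{-6}$, enumeration cap 50000 solutions, optional wall
time limit. Overproduction (`max_overproduced()`) probes one species at
a time with the extra constraint $(Nv)_i \ge 1$ — $n$ trivial LPs whose
union over species is, by the scale-invariance argument above, the
unique largest overproducible set; the choice of $\ge 1$ rather than a
strict inequality is a deliberate, scale-invariant encoding.

## What the random-network generator emulates

`random_network()` draws seeded networks with controlled size, maximal
reaction order, inflow/outflow and catalysis probabilities. Roughly a
fifth of non-inflow reactions get order two or higher, mirroring the
prevalence of higher-order reactions in curated biochemical model
repositories — the feature that makes genuine DOs possible, since a
reaction can only be disabled by separating its support. The generator
targets structural coverage, not kinetic realism: coefficients are
small integers, species participation is uniform, and no thermodynamic
or mass conservation constraints are imposed. Passing the
oracle-equivalence suite on this corpus therefore demonstrates
correctness of the enumeration logic on arbitrary small networks, not
statistical fidelity to any model database.

The test corpus sizes — around a hundred seeded networks with up to 8
species and 12 reactions for the SOR oracle ($2^m$ subsets), up to 8
species for the DO oracle, plus the two bundled models — keep the
brute-force oracles exact while the whole suite runs in minutes on one
CPU.

## Degenerate inputs and edge cases

An empty network has exactly one SOR (the empty set) and one DO (the
empty species set). A network without inflow reactions always contains
the empty SOR and the empty DO as lattice bottoms; with inflow
reactions the bottom is $R_{\min}$, the union of the ERCs of all
inflows, which every SOR contains. Non-reacting species (those whose
single-species closure supports nothing within the SOR) multiply DOs
without changing SORs — the bundled micro-RNA model shows this
prominently. Reversible SBML reactions are split into forward/reverse
pairs whose ERCs coincide, which the ERC graph collapses into one
equality class before constraints are emitted. Duplicate reactions are
kept as distinct columns sharing one ERC. Fractional SBML
stoichiometries are rejected (tolerance $10^{-9}$) rather than scaled,
keeping coefficients integral as the theory assumes.

## The bundled models

`example_network("mirna")` is a micro-RNA transcription-factor
interaction model (9 species, 11 reactions, no inflow): 8 SORs, 17 DOs
of which 6 are genuine, and a worked compartment example — the SOR with
all reactions except the gene–TF1 binding pair and the miR-mediated
mRNA degradation has exactly 3 maximal compartments on the full species
set and a minimal compartmentalization of size 2.

`example_network("three_generator")` is an artificial model of three
catalytic generators whose products interact destructively, with an
intermediate species D1 (7 species, 9 reactions). On this network as
specified, conservation analysis pins down the enumeration: nothing
produces A1 or A3, while R7 and R8 consume them, and D1 production caps
R9 below the A2 demand of R4, R5 and R7 — so no self-maintaining flux
can use R4, R5, R7, R8 or R9, and both the MILP path and the exhaustive
oracle find exactly 10 SORs (the unions of the closures of R1, R2, R3
and R6 that balance B1 and B3), five of them organizations. Narrative
descriptions of this model elsewhere suggest a variant with additional
generator regeneration in which destruction reactions participate in
SORs; the package ships the reaction list exactly as printed and reports
what that list implies.

## Known limitations

Enumeration cost grows with the number of solutions and binaries
(worst case exponential); the 50000-solution cap and the time limit
turn runaway cases into flagged partial results instead of hangs. The
big-M coupling bounds witness fluxes at $10^4$, so a SOR whose only
witnesses need a larger dynamic range would be missed — irrelevant at
the bundled and generated scales, and shared by the brute-force oracle,
but worth raising `big_m` for networks with long amplification chains.
The dense simplex is not meant for networks with thousands of
reactions; the design target is exact, verifiable enumeration on the
small-to-medium networks where complete DO inventories are meaningful.
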