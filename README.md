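# dosor

Exact structural analysis of reaction networks in the sense of chemical
organization theory: **dosor** enumerates every *set of organizational
reactions* (SOR) and every *distributed organization* (DO) of a network,
computes the *maximal compartments* and a *minimal compartmentalization*
for each DO–SOR pair, and renders the annotated inclusion lattices of
both. The audience is systems and theoretical biologists who want to
know, from stoichiometry alone — no rate constants, no kinetic laws —
which sub-systems of a model can persist, and how many spatial (or
temporal) compartments that persistence requires.

## The objects being computed

For a network of species $\mathcal S$ and reactions $\mathcal R$ with
stoichiometric matrix $N$ ($N_{ij} = b_{ij} - a_{ij}$):

- a species set $S$ is **closed** if products of reactions supported by
  $S$ (support = reactant set) stay in $S$, and **self-maintaining** if
  some flux $v \ge 0$, positive exactly on the reactions $S$ supports,
  has $Nv \ge 0$; a closed self-maintaining set is an **organization**;
- a **DO** is a species set $D = S_1 \cup \dots \cup S_k$ with closed
  compartments $S_i$ and per-compartment feasible fluxes summing to a
  $\hat v$ with $N \hat v \ge 0$; a DO with no $k=1$ realisation is a
  **genuine DO** — self-maintenance achieved only by separation;
- the **ERC** of a reaction $\hat r$ is
  $\{r : \mathrm{supp}(r) \subseteq \mathrm{clos}(\mathrm{supp}(\hat r))\}$,
  everything unavoidably activated with $\hat r$;
- a **SOR** is a reaction set $R$ that is ERC-closed
  ($R = \bigcup_{r \in R} \mathrm{ERC}(r)$) and admits a witness flux
  with support exactly $R$ and $Nv \ge 0$ — equivalently, the active
  reaction set of some DO;
- a **maximal compartment (MC)** of a DO–SOR pair is an
  inclusion-maximal closed subset of the DO supporting only SOR
  reactions; a **minimal compartmentalization** is a smallest MC
  selection covering the SOR's species and supporting all its reactions
  (an exact set-cover integer program).

Enumeration runs as a mixed-integer linear program — binaries $b_j$ for
reaction activity (and $e_i$ for species membership in the DO variant),
big-M coupling $c\,b_j \ge v_j \ge b_j$ with $c = 10000$, ERC-closure
constraints on the transitively reduced ERC graph — solved to the
largest solution first, then exhaustively via no-good integer cuts. The
solver is an exact branch-and-bound over a verified two-phase simplex
built into the package; backends are pluggable by name.

## Worked example

The bundled `"mirna"` fixture is a micro-RNA transcription-factor
interaction model (9 species, 11 reactions, no inflow):

```r
library(dosor)
net <- example_network("mirna")
sors <- all_sors(net)
sors
#> sor_set: 8 SORs ( complete )
#>   {r1, r2, r3, r4, r5, r6, r7, r8, r9, r10, r11} [organization]
#>   {r1, r2, r3, r4, r5, r6, r7, r8, r10, r11}
#>   {r3, r4, r5, r6, r7, r8, r9, r10, r11}
#>   {r3, r4, r5, r6, r7, r8, r10, r11}
#>   {r1, r2, r7, r8, r10, r11} [organization]
#>   {r7, r8, r10, r11} [organization]
#>   {r3, r4, r5, r6} [organization]
#>   {} [organization]

dos <- all_dos(net)
dos
#> do_set: 17 DOs, 6 genuine ( complete ), 19 DO-SOR pairs
```

Eight reaction sets can persist; the largest runs the whole model in a
single compartment (an organization), while e.g.
`{r3,r4,r5,r6,r7,r8,r10,r11}` — the model with the gene–TF1 binding
pair and the miR-mediated mRNA degradation switched off — is not
realisable in one compartment. Its compartment structure:

```r
sor <- c("r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11")
mcs <- create_mcs(net, sor, net$species)
length(mcs)                                 # 3 maximal compartments
length(get_min_compartments(net, sor, mcs)) # minimal compartmentalization: 2
```

Three maximal compartments exist and two of them suffice: the model
needs at least two separated volumes to hold this reaction set
persistent, which is why 6 of the 17 DOs are genuine. The annotated
Hasse diagram (boxes = organizations, ellipses = genuine-only, green =
new elements, red links = SORs sharing a species set):

```r
export_dot(sor_lattice(net, sors), "mirna_sors.dot")  # render with Graphviz
```

A shell entry point wraps the same pipeline
(`inst/scripts/dosor --network model.xml --hasse out.dot --report out.csv`),
including a batch mode over a directory of SBML/text models.

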