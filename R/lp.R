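## ---------------------------------------------------------------------------
## Dense two-phase simplex and exact branch-and-bound MILP
##
## The enumeration problems solved in this package are small (tens of
## variables, at most a few hundred constraints), so a dense tableau
## simplex is adequate.  Reliability measures: rows are equilibrated, the
## reduced costs are recomputed from the tableau every iteration, the
## tableau is refactorised from the original data at regular intervals and
## before declaring optimality, and every LP answer is verified against
## the original constraints.  All variables are non-negative; bounds are
## expressed as rows.
## ---------------------------------------------------------------------------

## Solve  min/max obj'x  s.t.  A x (dir) rhs, x >= 0.
## dir is a character vector of "<=", ">=", "==" per row.
## Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
.lp_solve <- function(obj, A, dir, rhs, maximize = TRUE,
                      tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  if (is.null(A)) A <- matrix(0, 0, n)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(dir) == m, length(rhs) == m)
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)  # internal: minimize

  if (n == 0L) {  # degenerate: no variables
    ok <- all((dir == "<=" & rhs >= -tol) | (dir == ">=" & rhs <= tol) |
                (dir == "==" & abs(rhs) <= tol))
    return(list(status = if (ok) "optimal" else "infeasible",
                x = numeric(0), value = 0))
  }
  A0 <- A; dir0 <- dir; rhs0 <- rhs  # for the final verification

  ## row equilibration: large coefficients (e.g. the big-M coupling rows)
  ## otherwise dominate pivoting and degrade the tableau
  if (m > 0L) {
    rowmax <- pmax(apply(abs(A), 1, max), abs(rhs))
    rowmax[rowmax < 1e-12] <- 1
    A <- A / rowmax
    rhs <- rhs / rowmax
  }

  ## orient rows so rhs >= 0
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  le <- dir == "<="; ge <- dir == ">="; eq <- dir == "=="
  n_slack <- sum(le) + sum(ge)
  ## system with slack/surplus columns only (artificials are added per
  ## phase-1 run inside .two_phase)
  M <- matrix(0, m, n + n_slack)
  M[, seq_len(n)] <- A
  basis_kind <- character(m)  # "slack" rows start basic without artificial
  scol <- n
  slack_col <- integer(m)
  for (i in seq_len(m)) {
    if (le[i]) {
      scol <- scol + 1L
      M[i, scol] <- 1
      slack_col[i] <- scol
      basis_kind[i] <- "slack"
    } else if (ge[i]) {
      scol <- scol + 1L
      M[i, scol] <- -1
      slack_col[i] <- scol
      basis_kind[i] <- "art"
    } else {
      basis_kind[i] <- "art"
    }
  }
  c2 <- numeric(n + n_slack)
  c2[seq_len(n)] <- cvec
  start <- ifelse(basis_kind == "slack", slack_col, NA_integer_)
  residual <- function(xout) {
    if (m == 0L) return(0)
    lhs <- as.numeric(A0 %*% xout)
    scale <- pmax(1, abs(rhs0))
    max(pmax(
      ifelse(dir0 == "<=", lhs - rhs0, 0),
      ifelse(dir0 == ">=", rhs0 - lhs, 0),
      ifelse(dir0 == "==", abs(lhs - rhs0), 0)
    ) / scale)
  }
  last <- "unknown"
  xout <- NULL
  for (attempt in 1:2) {
    ## second attempt: Bland's rule throughout (slower, numerically tamer);
    ## an infeasibility or factorisation verdict is only final once the
    ## Bland pass agrees
    res <- .two_phase(M, rhs, start, c2, tol, max_iter,
                      bland = (attempt == 2L))
    last <- res$status
    if (res$status == "unbounded") return(list(status = "unbounded"))
    if (res$status == "infeasible") {
      ## a refactorisation-confirmed positive phase-1 optimum doubles as a
      ## Farkas certificate: the verdict needs no second pass
      return(list(status = "infeasible"))
    }
    if (res$status == "optimal") {
      x <- numeric(n + n_slack)
      x[res$basis] <- res$rhs
      xout <- x[seq_len(n)]
      if (residual(xout) <= 1e-6 && min(xout) >= -1e-6) {
        val <- sum(cvec * xout)
        return(list(status = "optimal", x = pmax(xout, 0),
                    value = if (maximize) -val else val))
      }
    }
  }
  if (last == "infeasible") return(list(status = "infeasible"))
  stop("simplex: unreliable solve (final status ", last,
       if (!is.null(xout)) paste0(", residual ", format(residual(xout))), ")")
}

## Two-phase driver on the standard-form system M x = b, x >= 0 (b >= 0).
## `start_basis` holds a starting basic column per row, NA where none is
## available (those rows get a phase-1 artificial).  If the phase-1 basis
## cannot be carried into phase 2 (numerically singular after dropping
## redundant rows), the reduced system is re-solved from fresh artificials.
.two_phase <- function(M, b, start_basis, cost, tol, max_iter, depth = 0L,
                       bland = FALSE) {
  m <- nrow(M)
  ntot <- ncol(M)
  if (m == 0L) return(.simplex_run(M, b, integer(0), cost, tol, max_iter))
  retry <- function(M2, b2) {
    if (depth >= 3L) return(list(status = "factorisation_failed"))
    .two_phase(M2, b2, rep(NA_integer_, nrow(M2)), cost, tol, max_iter,
               depth + 1L, bland = TRUE)
  }
  need_art <- is.na(start_basis)
  if (any(need_art)) {
    n_art <- sum(need_art)
    Maug <- cbind(M, matrix(0, m, n_art))
    art_cols <- ntot + seq_len(n_art)
    Maug[cbind(which(need_art), art_cols)] <- 1
    basis <- start_basis
    basis[need_art] <- art_cols
    c1 <- numeric(ntot + n_art)
    c1[art_cols] <- 1
    res <- .simplex_run(Maug, b, basis, c1, tol, max_iter, bland_start = bland)
    if (res$status %in% c("factorisation_failed", "needs_restart")) {
      return(retry(M, b))
    }
    if (res$status != "optimal") {
      return(list(status = "infeasible", phase1 = Inf))
    }
    if (res$value > 1e-7) {
      ## report the residual: a clearly positive optimum is a confident
      ## verdict, a near-threshold one deserves re-examination upstream
      return(list(status = "infeasible", phase1 = res$value))
    }
    basis <- res$basis
    ## recompute the tableau rows of the basic artificials from a fresh
    ## factorisation; pivot them out where a solid pivot exists, and only
    ## then treat left-over artificial rows as redundant
    art_rows <- which(basis %in% art_cols)
    if (length(art_rows)) {
      Binv <- tryCatch(solve(Maug[, basis, drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(Binv)) return(retry(M, b))
      Tm <- cbind(Binv %*% Maug, pmax(as.numeric(Binv %*% b), 0))
      for (i in art_rows) {
        coefs <- abs(Tm[i, seq_len(ntot)])
        j <- which.max(coefs)
        if (coefs[j] > 1e-6) {
          Tm <- .pivot(Tm, i, j)
          basis[i] <- j
        }
      }
    }
    keep <- !(basis %in% art_cols)
    M2 <- M[keep, , drop = FALSE]
    b2 <- b[keep]
    basis2 <- basis[keep]
  } else {
    M2 <- M; b2 <- b; basis2 <- start_basis
  }
  res <- .simplex_run(M2, b2, basis2, cost, tol, max_iter, bland_start = bland)
  if (res$status %in% c("factorisation_failed", "needs_restart")) {
    return(retry(M2, b2))
  }
  res
}

## tableau pivot on (row, col); Tm carries the rhs as its last column
.pivot <- function(Tm, row, col) {
  Tm[row, ] <- Tm[row, ] / Tm[row, col]
  other <- setdiff(seq_len(nrow(Tm)), row)
  if (length(other)) {
    f <- Tm[other, col]
    nz <- f != 0
    if (any(nz)) {
      Tm[other[nz], ] <- Tm[other[nz], , drop = FALSE] -
        outer(f[nz], Tm[row, ])
    }
  }
  Tm
}

## Primal simplex minimizing cost'x from a basic feasible start.
## M (m x ntot) and b are the immutable augmented system; the working
## tableau is refactorised from them every `refactor_every` iterations and
## before optimality is declared, so round-off cannot accumulate without
## bound.  Columns in `forbid` (retired artificials) never enter.
.simplex_run <- function(M, b, basis, cost, tol, max_iter,
                         forbid = integer(0), refactor_every = 60L,
                         bland_start = FALSE) {
  m <- nrow(M)
  ntot <- ncol(M)
  if (m == 0L) {
    if (any(cost < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", T = M, rhs = numeric(0),
                basis = basis, value = 0))
  }
  lost_feasibility <- FALSE
  refact <- function(basis) {
    B <- M[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) return(NULL)
    rhs <- as.numeric(Binv %*% b)
    if (min(rhs) < -1e-4) {  # basis drifted far from feasibility
      lost_feasibility <<- TRUE
      return(NULL)
    }
    lost_feasibility <<- FALSE
    list(T = Binv %*% M, rhs = pmax(rhs, 0))
  }
  f <- refact(basis)
  if (is.null(f)) {
    return(list(status = if (lost_feasibility) "needs_restart"
                         else "factorisation_failed"))
  }
  ## working tableau carries the rhs as its last column
  rhs_col <- ntot + 1L
  Tb <- cbind(f$T, f$rhs)
  cols <- seq_len(ntot)
  reduced_costs <- function() {
    r <- cost - as.numeric(cost[basis] %*% Tb[, cols, drop = FALSE])
    r[basis] <- 0
    r
  }
  red <- reduced_costs()
  allowed <- setdiff(cols, forbid)
  iter <- 0L
  bland <- bland_start
  stall <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex: iteration limit reached")
    if (iter %% refactor_every == 0L) {
      f <- refact(basis)
      if (!is.null(f)) {
        Tb <- cbind(f$T, f$rhs)
        red <- reduced_costs()
      }
    }
    cand <- allowed[red[allowed] < -tol]
    if (!length(cand)) {
      ## candidate optimum: refactorise and confirm before accepting
      f <- refact(basis)
      if (is.null(f)) {
        return(list(status = if (lost_feasibility) "needs_restart"
                             else "factorisation_failed"))
      }
      Tb <- cbind(f$T, f$rhs)
      red <- reduced_costs()
      cand <- allowed[red[allowed] < -tol]
      if (!length(cand)) {
        rhs <- Tb[, rhs_col]
        return(list(status = "optimal", T = Tb[, cols, drop = FALSE],
                    rhs = rhs, basis = basis,
                    value = sum(cost[basis] * rhs)))
      }
    }
    enter <- if (bland) cand[1] else cand[which.min(red[cand])]
    colv <- Tb[, enter]
    ## pivot acceptability well above round-off level: the rows are
    ## equilibrated, so structural entries are O(1e-4) or larger
    pos <- which(colv > 1e-7)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- pmax(Tb[pos, rhs_col], 0) / colv[pos]
    rmin <- min(ratios)
    tie <- pos[ratios <= rmin + 1e-9 * (1 + abs(rmin))]
    if (bland) {
      leave_row <- tie[which.min(basis[tie])]
    } else {
      ## among (near-)minimal ratios prefer the largest pivot element,
      ## which keeps the tableau well conditioned
      leave_row <- tie[which.max(colv[tie])]
    }
    if (rmin < tol) {
      stall <- stall + 1L
    } else {
      stall <- 0L
      if (!bland_start) bland <- FALSE
    }
    if (stall > m + 20L) bland <- TRUE   # anti-cycling fallback
    Tb <- .pivot(Tb, leave_row, enter)
    basis[leave_row] <- enter
    ## incremental reduced-cost update; exact values are restored at every
    ## refactorisation and re-checked before optimality is declared
    rc <- red[enter]
    if (rc != 0) red <- red - rc * Tb[leave_row, cols]
    red[enter] <- 0
    red[basis] <- 0
  }
}

## ---------------------------------------------------------------------------
## Branch and bound for mixed binary-continuous programs
## ---------------------------------------------------------------------------

## Solve max/min obj'x s.t. A x (dir) rhs, x >= 0, x[binary_idx] in {0,1}.
## Rows x_j <= 1 for the binaries must be part of (A, dir, rhs).  When
## `integer_objective` is TRUE the objective restricted to feasible points
## is integral, which sharpens bound-based pruning.  Every incumbent is
## verified against the original constraints before being accepted.
.milp_solve <- function(obj, A, dir, rhs, binary_idx, maximize = TRUE,
                        integer_objective = TRUE, int_tol = 1e-6) {
  n <- length(obj)
  best <- NULL
  best_val <- if (maximize) -Inf else Inf
  improves <- function(bound) {
    if (maximize) {
      b <- if (integer_objective) floor(bound + 1e-7) else bound
      b > best_val + 1e-9
    } else {
      b <- if (integer_objective) ceiling(bound - 1e-7) else bound
      b < best_val - 1e-9
    }
  }
  feasible_at <- function(x) {
    if (nrow(A) == 0L) return(TRUE)
    lhs <- as.numeric(A %*% x)
    scale <- pmax(1, abs(rhs))
    all(ifelse(dir == "<=", lhs - rhs, ifelse(dir == ">=", rhs - lhs,
                                              abs(lhs - rhs))) <= 1e-6 * scale)
  }
  ## depth-first stack of partial assignments over the binaries
  stack <- list(integer())  # named int vector: index -> fixed value
  while (length(stack)) {
    fix <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    fixed_idx <- as.integer(names(fix))
    free <- setdiff(seq_len(n), fixed_idx)
    rhs_adj <- rhs
    const <- 0
    if (length(fixed_idx)) {
      vals <- as.numeric(fix)
      if (any(vals > 0)) {
        on <- fixed_idx[vals > 0]
        rhs_adj <- rhs - A[, on, drop = FALSE] %*% rep(1, length(on))
        const <- sum(obj[on])
      }
    }
    sol <- tryCatch(
      .lp_solve(obj[free], A[, free, drop = FALSE], dir, as.numeric(rhs_adj),
                maximize = maximize),
      error = function(e) list(status = "error")
    )
    if (sol$status == "error") {
      ## the node LP could not be solved reliably: keep the search complete
      ## by branching on an unfixed binary instead of pruning
      bfree <- intersect(binary_idx, free)
      if (length(bfree)) {
        for (v in c(0L, 1L)) {
          child <- fix
          child[as.character(bfree[1])] <- v
          stack[[length(stack) + 1L]] <- child
        }
      }
      next
    }
    if (!(sol$status %in% "optimal")) next
    bound <- sol$value + const
    if (!improves(bound)) next
    x <- numeric(n)
    x[free] <- sol$x
    if (length(fixed_idx)) x[fixed_idx] <- as.numeric(fix)
    bfree <- intersect(binary_idx, free)
    fracs <- abs(x[bfree] - round(x[bfree]))
    if (!length(bfree) || all(fracs <= int_tol)) {
      xi <- x
      xi[binary_idx] <- round(xi[binary_idx])
      if (feasible_at(xi)) {
        best <- xi
        best_val <- bound
        next
      }
      ## LP claims integrality but the rounded point fails verification:
      ## branch explicitly on an unfixed binary instead of accepting
      if (!length(bfree)) next
      j <- bfree[1]
    } else {
      j <- bfree[which.max(fracs)]
    }
    for (v in c(0L, 1L)) {   # pushed 0 first => the 1-branch is explored first
      child <- fix
      child[as.character(j)] <- v
      stack[[length(stack) + 1L]] <- child
    }
  }
  if (is.null(best)) return(list(status = "infeasible"))
  list(status = "optimal", x = best, value = best_val)
}

#' Integer (no-good) cut for a 0/1 assignment
#'
#' Given a full 0/1 assignment of a set of cut variables, returns the
#' linear constraint `sum_(j: x_j = 1) (1 - x_j) + sum_(j: x_j = 0) x_j >= 1`,
#' which is violated by exactly that assignment and by no other 0/1
#' assignment. Successively adding such cuts is how the enumeration walks
#' through all solutions of the SOR and DO programs, starting from the
#' largest.
#'
#' @param assignment numeric/integer vector of 0s and 1s
#' @return a list with `coef` (the constraint row: -1 where the assignment
#'   is 1, +1 where it is 0), `dir` (`">="`) and `rhs` (`1 - sum(assignment)`)
#' @export
#' @examples
#' integer_cut(c(1, 1, 0))  # (1-x1) + (1-x2) + x3 >= 1
integer_cut <- function(assignment) {
  a <- round(as.numeric(assignment))
  if (any(a != 0 & a != 1)) stop("assignment must be 0/1")
  list(coef = ifelse(a == 1, -1, 1), dir = ">=", rhs = 1 - sum(a))
}

## Enumerate all 0/1 patterns of x[cut_idx] admitting a feasible completion,
## in non-increasing objective order, by repeated MILP solves with no-good
## cuts.  Enumeration stops after max_solutions or when the program becomes
## infeasible.
.milp_enumerate <- function(obj, A, dir, rhs, binary_idx, cut_idx,
                            maximize = TRUE, max_solutions = 50000L,
                            time_limit = Inf) {
  solutions <- list()
  status <- "complete"
  t0 <- Sys.time()
  repeat {
    sol <- .milp_solve(obj, A, dir, rhs, binary_idx, maximize = maximize)
    if (sol$status != "optimal") break
    solutions[[length(solutions) + 1L]] <- sol
    if (length(solutions) >= max_solutions) {
      status <- "truncated"
      break
    }
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      status <- "timeout"
      break
    }
    cut <- integer_cut(sol$x[cut_idx])
    row <- numeric(length(obj))
    row[cut_idx] <- cut$coef
    A <- rbind(A, row)
    dir <- c(dir, cut$dir)
    rhs <- c(rhs, cut$rhs)
  }
  list(solutions = solutions, status = status)
}

## ---------------------------------------------------------------------------
## Solver backend registry
## ---------------------------------------------------------------------------

## Backend contract: a list of two functions,
##   solve(obj, A, dir, rhs, binary_idx, maximize)      -> status/x/value
##   enumerate(obj, A, dir, rhs, binary_idx, cut_idx,
##             maximize, max_solutions, time_limit)     -> solutions/status
## Any backend honouring the contract can be registered by name.
.solver_backends <- new.env(parent = emptyenv())

#' Register or look up a MILP solver backend
#'
#' The package ships one backend, `"simplex_bb"` (exact branch and bound
#' over a built-in two-phase simplex). Additional backends satisfying the
#' same contract (linear objective, linear constraints, non-negative
#' continuous variables, binaries; returns status and assignment) can be
#' registered and selected by name through [enumeration_config()].
#'
#' @param name backend name
#' @param backend for `register_solver_backend`: a list with functions
#'   `solve` and `enumerate`
#' @return `solver_backend` returns the backend list; registering returns
#'   the name invisibly
#' @export
solver_backend <- function(name = "simplex_bb") {
  b <- get0(name, envir = .solver_backends, inherits = FALSE)
  if (is.null(b)) {
    stop("unknown solver backend '", name, "'; available: ",
         paste(ls(.solver_backends), collapse = ", "))
  }
  b
}

#' @rdname solver_backend
#' @export
register_solver_backend <- function(name, backend) {
  stopifnot(is.list(backend), is.function(backend$solve),
            is.function(backend$enumerate))
  assign(name, backend, envir = .solver_backends)
  invisible(name)
}

## default backend
local({
  assign("simplex_bb",
         list(solve = .milp_solve, enumerate = .milp_enumerate),
         envir = .solver_backends)
})
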