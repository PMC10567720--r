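test_that("the built-in LP solver agrees with an independent simplex", {
  skip_if_not_installed("boot")
  ## boot::simplex requires non-negative rhs, which these problems satisfy
  set.seed(71)
  checked <- 0
  for (i in 1:150) {
    n <- sample(2:6, 1)
    m <- sample(2:8, 1)
    A <- matrix(round(runif(m * n, -3, 3)), m, n)
    b <- round(runif(m, 0, 6))
    obj <- round(runif(n, -3, 3))
    ## bound the box so neither solver can report unbounded
    A <- rbind(A, diag(n))
    b <- c(b, rep(10, n))
    mine <- dosor:::.lp_solve(obj, A, rep("<=", m + n), b, maximize = TRUE)
    ref <- tryCatch(boot::simplex(a = obj, A1 = A, b1 = b, maxi = TRUE),
                    error = function(e) NULL)
    if (!is.null(ref) && ref$solved == 1) {
      expect_equal(mine$status, "optimal")
      expect_equal(mine$value, unname(ref$value), tolerance = 1e-7)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("LP solver detects infeasible and unbounded problems", {
  ## x >= 2 and x <= 1
  r <- dosor:::.lp_solve(1, matrix(c(1, 1), 2, 1), c(">=", "<="), c(2, 1))
  expect_equal(r$status, "infeasible")
  ## max x with x >= 0 unconstrained above
  r <- dosor:::.lp_solve(1, matrix(1, 1, 1), ">=", 0, maximize = TRUE)
  expect_equal(r$status, "unbounded")
  ## no variables: consistency of the constant system decides
  expect_equal(dosor:::.lp_solve(numeric(0), matrix(0, 1, 0), "<=", 1)$status,
               "optimal")
  expect_equal(dosor:::.lp_solve(numeric(0), matrix(0, 1, 0), ">=", 1)$status,
               "infeasible")
})

test_that("branch and bound solves small knapsacks exactly", {
  ## brute-force oracle over all 0/1 patterns
  set.seed(72)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    w <- sample(1:6, k, replace = TRUE)
    p <- sample(1:9, k, replace = TRUE)
    cap <- sum(w) %/% 2
    A <- rbind(w, diag(k))
    sol <- dosor:::.milp_solve(p, A, rep("<=", k + 1), c(cap, rep(1, k)),
                               binary_idx = seq_len(k))
    patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
    feas <- patterns[patterns %*% w <= cap, , drop = FALSE]
    best <- max(feas %*% p)
    expect_equal(sol$status, "optimal")
    expect_equal(sol$value, best)
  }
})

test_that("integer cuts exclude exactly the cut assignment", {
  cut <- integer_cut(c(1, 1, 0))
  expect_equal(cut$coef, c(-1, -1, 1))
  expect_equal(cut$rhs, -1)
  ## over all 2^3 assignments the cut removes only (1,1,0)
  patterns <- as.matrix(expand.grid(rep(list(0:1), 3)))
  lhs <- patterns %*% cut$coef
  excluded <- lhs < cut$rhs
  expect_equal(sum(excluded), 1)
  expect_equal(patterns[excluded, ], c(1, 1, 0), ignore_attr = TRUE)
  expect_error(integer_cut(c(1, 2)), "0/1")
})

test_that("cut-based enumeration visits every feasible pattern once", {
  ## free 3-binary problem: enumeration must find all 8 patterns,
  ## in non-increasing objective order
  A <- diag(3)
  res <- dosor:::.milp_enumerate(rep(1, 3), A, rep("<=", 3), rep(1, 3),
                                 binary_idx = 1:3, cut_idx = 1:3)
  expect_equal(res$status, "complete")
  expect_equal(length(res$solutions), 8)
  sizes <- vapply(res$solutions, function(s) sum(round(s$x)), 0)
  expect_true(all(diff(sizes) <= 0))
  pats <- vapply(res$solutions, function(s) paste(round(s$x), collapse = ""), "")
  expect_equal(anyDuplicated(pats), 0)
  ## cap truncates with the matching status
  res <- dosor:::.milp_enumerate(rep(1, 3), A, rep("<=", 3), rep(1, 3),
                                 binary_idx = 1:3, cut_idx = 1:3,
                                 max_solutions = 3)
  expect_equal(res$status, "truncated")
  expect_length(res$solutions, 3)
})

test_that("solver backends are pluggable by name", {
  expect_error(solver_backend("no_such"), "unknown solver backend")
  b <- solver_backend("simplex_bb")
  expect_true(is.function(b$solve))
  register_solver_backend("mirror", b)
  cfg <- enumeration_config(solver = "mirror")
  s <- all_sors(toy_net(), cfg)
  expect_equal(length(s$sors), 2)  # {} and {p,d}
})
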