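test_that("perfectly correlated pair reduces to a rank-1 solution", {
  set.seed(8)
  x <- rnorm(50)
  X <- cbind(a = x, b = 2 * x + 3)
  sol <- fit_factor_solution(X)
  expect_equal(sol$eigenvalues, c(2, 0), tolerance = 1e-8)
  expect_equal(sol$n_retained, 1L)
  expect_equal(unname(sol$loadings[, 1]), c(1, 1), tolerance = 1e-8)
  expect_equal(sol$proportion_per_factor, 100, tolerance = 1e-8)
  expect_equal(sol$total_eigenvalue, 2, tolerance = 1e-8)
})

test_that("eigenvalue sum equals the variable count; Kaiser rule applies", {
  set.seed(13)
  X <- matrix(rpois(12 * 400, 3), ncol = 12,
              dimnames = list(NULL, category_names()))
  sol <- fit_factor_solution(X)
  expect_equal(sum(sol$eigenvalues), 12, tolerance = 1e-8)
  # retention matches an independent application of the Kaiser criterion
  ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sol$n_retained, sum(ev > 1))
  # independent noise: retained factors explain modest structure
  expect_lt(sol$n_retained, 12)
  expect_true(all(abs(sol$loadings) <= 1 + 1e-8))
})

test_that("degenerate inputs raise informative errors", {
  X <- matrix(rpois(12 * 10, 3), ncol = 12,
              dimnames = list(NULL, category_names()))
  X[, "Calls"] <- 2
  expect_error(fit_factor_solution(X), "Calls")
  expect_error(fit_factor_solution(matrix(rnorm(24), nrow = 2)),
               "3 observations")
})

test_that("varimax preserves communalities and improves the criterion", {
  set.seed(99)
  for (k in 1:5) {
    L <- matrix(rnorm(12 * 4), nrow = 12)
    rot <- varimax_rotate(L, tol = 1e-9, max_iter = 500)
    expect_equal(rowSums(rot$loadings^2), rowSums(L^2), tolerance = 1e-8)
    expect_gte(varimax_criterion(rot$loadings),
               varimax_criterion(L) - 1e-10)
    # rotation matrix is orthogonal
    expect_equal(t(rot$rotmat) %*% rot$rotmat, diag(4), tolerance = 1e-8)
    expect_equal(rot$loadings, L %*% rot$rotmat, tolerance = 1e-8)
    # cross-check criterion against the reference rotation in stats
    ref <- stats::varimax(L, normalize = TRUE, eps = 1e-9)
    expect_equal(varimax_criterion(rot$loadings),
                 varimax_criterion(ref$loadings %*% diag(4)),
                 tolerance = 1e-4)
  }
  # single column: nothing to rotate
  L1 <- matrix(rnorm(12), ncol = 1)
  expect_identical(varimax_rotate(L1)$loadings, L1)
  # perfect simple structure is a fixed point (up to sign/permutation)
  Ls <- matrix(0, 12, 3)
  Ls[1:4, 1] <- 0.9; Ls[5:8, 2] <- 0.8; Ls[9:12, 3] <- 0.7
  rot <- varimax_rotate(Ls)
  expect_equal(abs(rot$loadings), Ls, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(rot$converged)
})

test_that("a planted 2-factor structure is recovered up to sign/permutation", {
  set.seed(2024)
  n <- 1000
  Lam <- matrix(0, 12, 2)
  Lam[1:6, 1] <- 0.8
  Lam[7:12, 2] <- 0.8
  F <- matrix(rnorm(n * 2), n, 2)
  X <- F %*% t(Lam) + 0.6 * matrix(rnorm(n * 12), n, 12)
  colnames(X) <- category_names()
  sol <- fit_factor_solution(X)
  expect_equal(sol$n_retained, 2L)
  # population loadings under this model: sqrt(0.64/(0.64+0.36)) scaled by
  # the correlation metric -> sqrt(0.7) ~= 0.837 within block, 0 across
  target <- matrix(0, 12, 2)
  target[1:6, 1] <- sqrt(0.7)
  target[7:12, 2] <- sqrt(0.7)
  L <- sol$loadings
  perms <- list(1:2, 2:1)
  devs <- vapply(perms, function(p) {
    Lp <- L[, p, drop = FALSE]
    for (j in 1:2) if (sum(Lp[, j] * target[, j]) < 0) Lp[, j] <- -Lp[, j]
    max(abs(Lp - target))
  }, numeric(1))
  expect_lt(min(devs), 0.1)
})

test_that("the solution is invariant to positive column rescaling", {
  set.seed(7)
  X <- matrix(rpois(12 * 200, 4), ncol = 12,
              dimnames = list(NULL, category_names()))
  X2 <- X
  X2[, 3] <- X2[, 3] * 10
  X2[, 8] <- X2[, 8] * 0.5
  a <- fit_factor_solution(X)
  b <- fit_factor_solution(X2)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-8)
  expect_equal(a$loadings, b$loadings, tolerance = 1e-6)
})

test_that("compare_solutions detects structure differences and self-matches", {
  set.seed(31)
  X <- matrix(rpois(12 * 300, 3), ncol = 12,
              dimnames = list(NULL, category_names()))
  A <- fit_factor_solution(X)
  cmp <- compare_solutions(A, A)
  expect_false(cmp$structure_differs)
  expect_equal(cmp$matching$congruence, rep(1, A$n_retained),
               tolerance = 1e-8)

  # permuted and sign-flipped copy still matches with |congruence| 1
  B <- A
  k <- A$n_retained
  perm <- rev(seq_len(k))
  B$loadings <- A$loadings[, perm, drop = FALSE] %*%
    diag(rep(c(-1, 1), length.out = k), k)
  cmp2 <- compare_solutions(A, B)
  expect_false(cmp2$structure_differs)
  expect_equal(abs(cmp2$matching$congruence), rep(1, k), tolerance = 1e-8)
  expect_equal(cmp2$matching$factor_b[order(cmp2$matching$factor_a)], perm)

  # 4 vs 5 retained factors: structures differ by one dimension
  A4 <- A; A4$n_retained <- 4L; A4$loadings <- matrix(rnorm(48), 12, 4)
  A5 <- A; A5$n_retained <- 5L; A5$loadings <- matrix(rnorm(60), 12, 5)
  cmp3 <- compare_solutions(A4, A5)
  expect_true(cmp3$structure_differs)
  expect_equal(cmp3$delta_n_factors, 1L)
})

test_that("episode counts matrix feeds the factor analysis", {
  sim <- generate_synthetic_log(synth_config(n_participants = 5,
                                             n_weeks = 8, seed = 4))
  eps <- do.call(rbind, lapply(sim$logs, segment_episodes))
  X <- episode_counts_matrix(eps)
  expect_equal(colnames(X), category_names())
  expect_equal(sum(X), nrow(eps))
  expect_equal(nrow(episode_counts_matrix(eps, per_participant = TRUE)), 5)
  sol <- fit_factor_solution(X)
  expect_equal(sum(sol$eigenvalues), 12, tolerance = 1e-8)
})
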