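test_that("initialization is uniform on [0,1) and seed-reproducible", {
  a <- nmf_init(100, 10, 100, seed = 5)
  b <- nmf_init(100, 10, 100, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$W0 >= 0 & a$W0 < 1) && all(a$H0 >= 0 & a$H0 < 1))
  big <- nmf_init(1000, 10, 10, seed = 6)
  expect_lt(abs(mean(big$W0) - 0.5), 0.005)
})

test_that("the objective has its closed forms and scaling identity", {
  W <- matrix(1, 2, 1); H <- matrix(1, 1, 2)  # WH all ones
  X <- W %*% H
  expect_equal(nmf_objective(X, W, H), -4, tolerance = 1e-9)  # -G*T
  X0 <- matrix(0, 2, 2)
  expect_equal(nmf_objective(X0, W, H, epsilon = 0), -sum(W %*% H))
  # scaling H by c changes O by sum(X) log c - (c - 1) sum(WH)
  set.seed(4)
  X <- matrix(runif(12, 0.5, 2), 3, 4)
  W <- matrix(runif(6, 0.5, 2), 3, 2); H <- matrix(runif(8, 0.5, 2), 2, 4)
  cc <- 1.7
  expect_equal(nmf_objective(X, W, cc * H, epsilon = 0) -
                 nmf_objective(X, W, H, epsilon = 0),
               sum(X) * log(cc) - (cc - 1) * sum(W %*% H),
               tolerance = 1e-9)
})

test_that("one update step matches the scalar-arithmetic oracle", {
  # hand-checkable instance
  X <- matrix(c(1, 3, 2, 4), 2, 2)
  W0 <- matrix(1, 2, 1); H0 <- matrix(1, 1, 2)
  up <- nmf_update_step(X, W0, H0)
  expect_equal(up$W, matrix(c(1.5, 3.5), 2, 1), tolerance = 1e-12)
  # H uses the already-updated W: W'^T X = (12, 17), W'^T W' = 14.5
  expect_equal(up$H, matrix(c(12, 17) / 14.5, 1, 2), tolerance = 1e-12)
  orc <- update_step_oracle(X, W0, H0)
  expect_equal(up$W, orc$W, tolerance = 1e-12)
  expect_equal(up$H, orc$H, tolerance = 1e-12)
  # random instances against the oracle; exact zeros stay zero
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(runif(20), 4, 5)
    W <- matrix(runif(8), 4, 2); H <- matrix(runif(10), 2, 5)
    W[1, 1] <- 0; H[2, 3] <- 0
    up <- nmf_update_step(X, W, H)
    orc <- update_step_oracle(X, W, H)
    expect_equal(up$W, orc$W, tolerance = 1e-12)
    expect_equal(up$H, orc$H, tolerance = 1e-12)
    expect_identical(up$W[1, 1], 0)
    expect_identical(up$H[2, 3], 0)
    expect_true(all(up$W >= 0) && all(up$H >= 0))
  }
})

test_that("a rank-1 exact factorization is a fixed point of the update", {
  w <- matrix(c(1, 2, 0.5), 3, 1); h <- matrix(c(3, 1, 2, 4), 1, 4)
  X <- w %*% h
  up <- nmf_update_step(X, w, h)
  expect_equal(up$W, w, tolerance = 1e-9)
  expect_equal(up$H, h, tolerance = 1e-9)
})

test_that("the Frobenius gap never increases across updates", {
  set.seed(31)
  for (i in 1:100) {
    G <- sample(3:8, 1); T_ <- sample(3:8, 1); M <- sample(1:3, 1)
    X <- matrix(runif(G * T_), G, T_)
    W <- matrix(runif(G * M), G, M); H <- matrix(runif(M * T_), M, T_)
    f0 <- frobenius_gap(X, W, H)
    up <- nmf_update_step(X, W, H)
    expect_lte(frobenius_gap(X, up$W, up$H), f0 + 1e-9)
  }
})

test_that("frobenius_gap and rmse agree with elementwise oracles", {
  set.seed(41)
  X <- matrix(runif(20), 5, 4)
  W <- matrix(runif(10), 5, 2); H <- matrix(runif(8), 2, 4)
  R <- X - W %*% H
  expect_equal(frobenius_gap(X, W, H), sqrt(sum(R * R)), tolerance = 1e-12)
  expect_equal(frobenius_gap(W %*% H, W, H), 0)
  D <- matrix(0, 3, 3); D[2, 2] <- 3
  expect_equal(frobenius_gap(D, matrix(0, 3, 1), matrix(0, 1, 3)), 3)
  A <- matrix(runif(12), 3, 4); B <- matrix(runif(12), 3, 4)
  expect_equal(rmse(A, B), sqrt(sum((A - B)^2) / 12), tolerance = 1e-12)
  expect_equal(rmse(A, A), 0)
  expect_equal(rmse(A, B), rmse(B, A))
  C <- matrix(runif(12), 3, 4)
  expect_lte(rmse(A, C), rmse(A, B) + rmse(B, C) + 1e-12)
  expect_equal(rmse(matrix(1, 2, 2), matrix(2, 2, 2)), 1)
  expect_error(rmse(A, matrix(0, 2, 2)), "shape mismatch")
})

test_that("fit stops on the Frobenius change rule and flags convergence", {
  # started at an exact factorization: immediate convergence
  set.seed(51)
  W <- matrix(runif(30), 10, 3); H <- matrix(runif(15), 3, 5)
  X <- W %*% H
  fit <- nmf_fit(X, M = 3, W0 = W, H0 = H, theta = 0.05)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2)
  # trace is non-increasing and convergence satisfies the theta rule
  fit2 <- nmf_fit(X, M = 3, seed = 1, theta = 0.01)
  expect_true(all(diff(fit2$frobenius_trace) <= 1e-6))
  n <- length(fit2$frobenius_trace)
  expect_lt(abs(fit2$frobenius_trace[n] - fit2$frobenius_trace[n - 1]), 0.01)
  expect_true(all(fit2$W >= 0) && all(fit2$H >= 0))
  # a consecutive F change of 0.04 stops at theta = 0.05 (10.00 -> 9.96)
  expect_true(abs(9.96 - 10.00) < 0.05)
  # unscaled timepoint matrices are refused without the explicit flag
  fx <- fixture_default()
  expect_error(nmf_fit(fx$tm, M = 2), "not max-scaled")
  expect_s3_class(nmf_fit(fx$tm, M = 2, allow_unscaled = TRUE, seed = 1,
                          max_iter = 50),
                  "nmf_model")
})

test_that("the factorization carries the permutation/scale gauge freedom", {
  set.seed(61)
  X <- matrix(runif(40), 8, 5)
  fit <- nmf_fit(X, M = 3, seed = 2, theta = 1e-3)
  P <- diag(3)[, c(2, 3, 1)]
  D <- diag(c(2, 0.5, 3))
  W2 <- fit$W %*% P %*% D
  H2 <- solve(D) %*% t(P) %*% fit$H
  expect_equal(frobenius_gap(X, fit$W, fit$H), frobenius_gap(X, W2, H2),
               tolerance = 1e-9)
})

test_that("rank sweep pinpoints exact low-rank structure", {
  set.seed(71)
  W <- matrix(runif(60), 20, 3); H <- matrix(runif(18), 3, 6)
  X <- W %*% H
  sel <- sweep_rank(X, M_range = 2:8, seed = 5, theta = 1e-4,
                    max_iter = 5000)
  expect_length(sel$rmse_successive, 6)  # |M_range| - 1 entries
  expect_identical(as.integer(names(sel$rmse_successive)), 2:7)
  # at and beyond the true rank the fit error is near zero
  expect_lt(min(sel$rmse_fit[as.character(3:8)]), 0.01)
  expect_gt(sel$rmse_fit["2"], 0.05)
  expect_true(all(sel$rmse_successive >= 0))
})

test_that("restart robustness: pairwise spread below distance to data", {
  fx <- fixture_default()
  rb <- nmf_robustness(fx$tm_scaled, M = 5, n_runs = 5, seed = 3,
                       theta = 0.01)
  expect_length(rb$rmse_pairwise, choose(5, 2))
  expect_length(rb$rmse_to_data, 5)
  expect_lt(max(rb$rmse_pairwise), min(rb$rmse_to_data))
  # forced identical seeds give identical reconstructions
  f1 <- nmf_fit(fx$tm_scaled, M = 3, seed = 9, theta = 0.01)
  f2 <- nmf_fit(fx$tm_scaled, M = 3, seed = 9, theta = 0.01)
  expect_equal(rmse(nmf_approximation(f1), nmf_approximation(f2)), 0)
})

test_that("cumulative gene reconstruction accumulates to the full model", {
  set.seed(81)
  X <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("t", 1:5)))
  fit <- nmf_fit(X, M = 3, seed = 4, theta = 1e-3)
  curves <- reconstruct_gene(fit, "g3")
  expect_equal(unname(curves[3, ]), unname((fit$W %*% fit$H)["g3", ]),
               tolerance = 1e-12)
  # partial sums are pointwise nondecreasing (non-negativity)
  expect_true(all(diff(curves) >= -1e-12))
  expect_error(reconstruct_gene(fit, "nope"), "unknown gene")
  # a single-weight gene: curves constant from that behavior's rank on
  fit$W["g1", ] <- c(0, 2, 0)
  cv <- reconstruct_gene(fit, "g1", behavior_order = c(2, 1, 3))
  expect_equal(cv[1, ], cv[3, ], tolerance = 1e-12)
})

test_that("behavior matching is exact over permutations", {
  set.seed(91)
  H <- matrix(runif(24), 4, 6)
  perm <- c(3, 1, 4, 2)
  m <- match_behaviors(H[perm, ], H)
  expect_identical(m$perm, order(perm))  # inverse permutation
  expect_identical(H[perm, ][m$perm, ], H)
  expect_true(all(m$cor > 0.999))
})
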