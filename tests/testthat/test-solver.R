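# Augmented nonnegative least squares and the adaptive lambda rule.

test_that("nnls_normal solves unconstrained-feasible systems exactly", {
  set.seed(1)
  M <- matrix(rnorm(40), 10, 4)
  x_true <- c(0.5, 1.2, 0.3, 2.0)  # strictly positive: NNLS == OLS
  b <- as.numeric(M %*% x_true)
  fit <- nnls_normal(crossprod(M), as.numeric(crossprod(M, b)))
  expect_equal(fit$x, x_true, tolerance = 1e-8)
})

test_that("solve_fixed_lambda recovers exactly representable samples", {
  sc1 <- kmer_scheme(1)
  tm <- build_training_matrix(c(a = "AAAA", c = "CCCC", g = "GGGG",
                                t = "TTTT"), sc1)
  s <- c(0.5, 0.5, 0, 0)
  fit <- solve_fixed_lambda(tm, s, lam = 1e4)
  expect_equal(unname(fit$x), c(0.5, 0.5, 0, 0), tolerance = 1e-6)
  expect_true(all(fit$x >= 0))
  expect_lt(abs(sum(fit$x) - 1), 1e-9)
})

test_that("a column equal to the sample takes all the mass", {
  # orthogonal columns: each a unit vector at k = 1
  tm <- build_training_matrix(c(a = "AAAA", c = "CCCC", g = "GGGG"),
                              kmer_scheme(1))
  for (lam in c(1, 1e2, 1e4)) {
    fit <- solve_fixed_lambda(tm, c(0, 1, 0, 0), lam)
    expect_equal(unname(fit$x["c"]), 1, tolerance = 1e-9)
  }
})

test_that("sparse mixtures are recovered on random dictionaries", {
  set.seed(12)
  for (rep in 1:5) {
    A <- random_stochastic(16, 6)
    tm <- as_training_matrix(A)
    x_true <- c(0.7, 0.3, 0, 0, 0, 0)
    s <- as.numeric(A %*% x_true)
    fit <- solve_fixed_lambda(tm, s, lam = 1e4)
    expect_lt(sum(abs(fit$x - x_true)), 1e-4)
  }
})

test_that("objective matches the projected-gradient oracle on small instances", {
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(2:3, 1)
    n <- sample(3:6, 1)
    A <- random_stochastic(4^k, n)
    x_true <- numeric(n)
    x_true[sample(n, 2)] <- c(0.6, 0.4)
    s <- as.numeric(A %*% x_true) + runif(4^k, 0, 0.005)
    s <- s / sum(s)
    lam <- sample(c(1, 10), 1)
    tm <- as_training_matrix(A)
    fit <- solve_fixed_lambda(tm, s, lam)
    sys <- augmented_system(A, s, lam)
    obj_pkg <- sum((as.numeric(sys$M %*% fit$x_raw) - sys$b)^2)
    obj_oracle <- pg_nnls_objective(sys$M, sys$b)
    expect_lt(abs(obj_pkg - obj_oracle), 1e-6)
  }
})

test_that("select_lambda picks the smallest lambda on a plateau", {
  tm <- build_training_matrix(c(a = "AAAA", c = "CCCC", g = "GGGG",
                                t = "TTTT"), kmer_scheme(1))
  sel <- select_lambda(tm, c(0.5, 0.5, 0, 0))
  expect_equal(sel$lambda, 1)
  expect_identical(nrow(sel$diagnostics), 9L)
  expect_true(all(sel$diagnostics$residual < 1e-8))
})

test_that("select_lambda agrees with a 10x finer grid within one coarse step", {
  set.seed(91)
  for (rep in 1:5) {
    A <- random_stochastic(16, 6)
    x_true <- c(0.6, 0.4, 0, 0, 0, 0)
    s <- as.numeric(A %*% x_true)
    s <- abs(s + runif(16, -1, 1) * 0.01 / 16)  # L1 perturbation ~ 0.01
    s <- s / sum(s)
    tm <- as_training_matrix(A)
    coarse <- select_lambda(tm, s, lambda_schedule(10^(0:8)))
    fine <- select_lambda(tm, s, lambda_schedule(10^seq(0, 8, by = 0.1)))
    expect_lte(abs(log10(coarse$lambda) - log10(fine$lambda)), 1)
  }
})

test_that("the data-fit residual is non-increasing along the grid", {
  # increasing lambda puts more weight on the data-fit block, so the raw
  # L2 residual of the fit cannot grow; the normalized L1 residual used
  # for selection is only plateau-flat (it can wiggle by ~1e-4, well
  # inside the tau = 0.01 plateau tolerance)
  set.seed(55)
  for (rep in 1:8) {
    A <- random_stochastic(16, 6)
    x_true <- numeric(6)
    x_true[sample(6, 2)] <- c(0.7, 0.3)
    s <- as.numeric(A %*% x_true) + runif(16, 0, 0.01)
    s <- s / sum(s)
    diag <- select_lambda(as_training_matrix(A), s)$diagnostics
    expect_true(all(diff(diag$residual_l2_raw) <= 1e-8))
    rmin <- min(diag$residual)
    expect_true(all(diag$residual[diag$lambda >= 1e2] <= (1 + 0.01) * rmin))
  }
})

test_that("reconstruct returns normalized output with diagnostics", {
  set.seed(2)
  A <- random_stochastic(64, 8)
  tm <- as_training_matrix(A)
  x_true <- c(0.5, 0.3, 0.2, 0, 0, 0, 0, 0)
  est <- reconstruct(tm, as.numeric(A %*% x_true))
  expect_lt(sum(abs(est$x - x_true)), 1e-3)
  expect_s3_class(est, "concentration")
  expect_identical(names(est$x), tm$seq_ids)
  expect_false(is.null(attr(est, "diagnostics")))

  # a sample unrelated to the dictionary still yields a valid probability
  # vector, with the (large) residual reported
  s_rand <- runif(64); s_rand <- s_rand / sum(s_rand)
  est <- reconstruct(tm, s_rand)
  expect_true(all(est$x >= 0))
  expect_lt(abs(sum(est$x) - 1), 1e-9)
  expect_gt(est$residual_l1, 0)

  # single-column edge case
  tm1 <- as_training_matrix(random_stochastic(16, 1))
  est <- reconstruct(tm1, as.numeric(tm1$A[, 1]))
  expect_equal(unname(est$x), 1)

  # fixed-lambda shortcut
  est <- reconstruct(tm, as.numeric(A %*% x_true), schedule = 1e4)
  expect_equal(est$lambda_used, 1e4)
})

test_that("small lambda promotes sparsity on average", {
  set.seed(66)
  supp_small <- supp_big <- numeric(20)
  for (rep in 1:20) {
    A <- random_stochastic(64, 10)
    x_true <- numeric(10)
    x_true[sample(10, 3)] <- c(0.6, 0.3, 0.1)
    s <- as.numeric(A %*% x_true) + runif(64, 0, 0.02)
    s <- s / sum(s)
    tm <- as_training_matrix(A)
    supp_small[rep] <- length(solve_fixed_lambda(tm, s, 1)$support)
    supp_big[rep] <- length(solve_fixed_lambda(tm, s, 1e6)$support)
  }
  expect_lte(mean(supp_small), mean(supp_big) + 1)
})

test_that("solver rejects invalid input", {
  tm <- as_training_matrix(random_stochastic(16, 3))
  expect_error(solve_fixed_lambda(tm, runif(16), lam = -1), "positive")
  expect_error(solve_fixed_lambda(tm, runif(8), 1), "length")
  sv <- sample_vector("ACGT", kmer_scheme(1))
  expect_error(solve_fixed_lambda(tm, sv, 1), "k mismatch")
  expect_error(lambda_schedule(c(10, 1)), "increasing")
  expect_error(lambda_schedule(tau = -1), "tau")
})
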