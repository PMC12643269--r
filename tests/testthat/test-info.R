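test_that("Kozachenko-Leonenko entropy matches closed forms", {
  set.seed(1)
  h <- kl_entropy(matrix(rnorm(50000), ncol = 1))
  expect_equal(h, 0.5 * log(2 * pi * exp(1)), tolerance = 0.02)

  set.seed(2)
  expect_equal(kl_entropy(matrix(runif(50000), ncol = 1)), 0, tolerance = 0.02)

  set.seed(3)
  h2 <- kl_entropy(matrix(rnorm(40000), ncol = 2))
  expect_equal(h2, log(2 * pi * exp(1)), tolerance = 0.05)

  # euclidean metric agrees in 1D and on 2D gaussians
  set.seed(4)
  he <- kl_entropy(matrix(rnorm(40000), ncol = 2), metric = "euclidean")
  expect_equal(he, log(2 * pi * exp(1)), tolerance = 0.05)
})

test_that("O = TC - DTC and S = TC + DTC hold exactly", {
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(600 * 3), ncol = 3)
    e <- estimate_all(x)
    expect_equal(e$o, e$tc - e$dtc, tolerance = 1e-12)
    expect_equal(e$s, e$tc + e$dtc, tolerance = 1e-12)
    if (!is.na(e$o_norm)) expect_equal(e$o_norm, e$o / e$s, tolerance = 1e-12)
  }
})

test_that("independent columns carry no higher-order information", {
  set.seed(6)
  u <- matrix(runif(30000, -1, 1), ncol = 3)
  e <- estimate_all(u)
  expect_lt(abs(e$tc), 0.05)
  expect_lt(abs(e$dtc), 0.05)
  expect_lt(abs(e$o), 0.05)
})

test_that("estimates agree with the Gaussian log-determinant oracle", {
  for (i in 1:3) {
    cv <- random_pd_cov(3, seed = 100 + i)
    x <- sample_gaussian(10000, cv, seed = 200 + i)
    set.seed(300 + i)
    e <- estimate_all(x)
    orc <- gaussian_o_information(cv)
    expect_lt(abs(e$tc - orc$tc), 0.07)
    expect_lt(abs(e$dtc - orc$dtc), 0.07)
    expect_lt(abs(e$o - orc$o), 0.07)
  }
})

test_that("three-variable O equals pairwise MI sum minus TC", {
  cv <- matrix(0.6, 3, 3); diag(cv) <- 1
  x <- sample_gaussian(10000, cv, seed = 7)
  set.seed(8)
  e <- estimate_all(x)
  mi <- pairwise_mi(x[, 1], x[, 2]) + pairwise_mi(x[, 1], x[, 3]) +
    pairwise_mi(x[, 2], x[, 3])
  expect_equal(e$o, mi - e$tc, tolerance = 0.1)
})

test_that("KSG mutual information matches Gaussian closed form", {
  set.seed(9)
  z <- matrix(rnorm(40000), ncol = 2)
  expect_lt(abs(pairwise_mi(z[, 1], z[, 2])), 0.02)
  z[, 2] <- 0.8 * z[, 1] + sqrt(1 - 0.64) * z[, 2]
  expect_equal(pairwise_mi(z[, 1], z[, 2]), -0.5 * log(1 - 0.64),
               tolerance = 0.03)
})

test_that("functionally dependent columns give large MI that grows with n", {
  set.seed(10)
  x_small <- runif(300)
  x_large <- runif(3000)
  mi_small <- pairwise_mi(x_small, x_small)
  mi_large <- pairwise_mi(x_large, x_large)
  expect_gt(mi_small, 2)
  expect_gt(mi_large, mi_small)
})

test_that("Gaussian oracle reproduces canonical structures", {
  z <- gaussian_o_information(diag(3))
  expect_equal(unlist(z), c(tc = 0, dtc = 0, o = 0, s = 0), tolerance = 1e-12)

  eq <- matrix(0.9, 3, 3); diag(eq) <- 1
  expect_gt(gaussian_o_information(eq)$o, 0)

  # collider: X3 = X1 + X2 + noise, sd^2 = 0.01
  coll <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 2.01))
  expect_lt(gaussian_o_information(coll)$o, 0)

  expect_error(gaussian_o_information(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("estimates are invariant under column permutation", {
  set.seed(11)
  x <- matrix(rnorm(1500), ncol = 3)
  a <- estimate_all(x, tie_noise = 0)
  b <- estimate_all(x[, c(3, 1, 2)], tie_noise = 0)
  expect_equal(a$tc, b$tc, tolerance = 1e-12)
  expect_equal(a$dtc, b$dtc, tolerance = 1e-12)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(estimate_all(matrix(rnorm(20), ncol = 2)), "3 variables")
  expect_error(estimate_all(matrix(rnorm(9), ncol = 3)), "more samples")
  dup <- matrix(1, 50, 3)
  expect_error(estimate_all(dup, tie_noise = 0), "degenerate")
  expect_error(pairwise_mi(matrix(rnorm(30), ncol = 3)), "two columns")
})
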