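test_that("surface shapes satisfy their defining equations exactly", {
  s <- generate_shape("sphere", 1000, radius = 1, seed = 1)
  expect_lt(max(abs(sqrt(rowSums(s^2)) - 1)), 1e-12)
  expect_lt(max(abs(colMeans(s))), 3 / sqrt(1000))

  th <- generate_shape("torus_hollow", 1000, R = 1, r = 0.5, seed = 2)
  resid <- (sqrt(th[, 1]^2 + th[, 2]^2) - 1)^2 + th[, 3]^2
  expect_lt(max(abs(resid - 0.25)), 1e-12)

  kn <- generate_shape("torus_knot", 1000, p = 5, q = 3, seed = 3)
  resid <- (sqrt(kn[, 1]^2 + kn[, 2]^2) - 1)^2 + kn[, 3]^2
  expect_lt(max(abs(resid - 0.25)), 1e-12)
})

test_that("interior shapes stay inside their solid", {
  b <- generate_shape("ball", 1000, radius = 1, seed = 4)
  expect_lte(max(sqrt(rowSums(b^2))), 1)
  tf <- generate_shape("torus_filled", 1000, R = 1, r = 0.5, seed = 5)
  resid <- (sqrt(tf[, 1]^2 + tf[, 2]^2) - 1)^2 + tf[, 3]^2
  expect_lte(max(resid), 0.25)
})

test_that("the line copies one coordinate into all three columns", {
  l <- generate_shape("line", 1000, seed = 6)
  expect_identical(l[, 1], unname(l[, 2]))
  expect_identical(l[, 1], unname(l[, 3]))
  expect_true(all(abs(l[, 1]) <= 1))
})

test_that("shape generation is deterministic given a seed", {
  a <- generate_shape("torus_hollow", 200, rotation = c(0.1, 0.2, 0.3), seed = 7)
  b <- generate_shape("torus_hollow", 200, rotation = c(0.1, 0.2, 0.3), seed = 7)
  expect_identical(a, b)
  c <- generate_shape("torus_hollow", 200, rotation = c(0.1, 0.2, 0.3), seed = 8)
  expect_false(identical(a, c))
})

test_that("rotation is an isometry with the expected conventions", {
  # zero angles: identity
  cl <- generate_shape("ball", 100, seed = 9)
  expect_equal(rotate_cloud(cl, c(0, 0, 0)), cl)
  # quarter turn about z maps e1 to e2
  e1 <- matrix(c(1, 0, 0), 1)
  expect_equal(as.numeric(rotate_cloud(e1, c(0, 0, pi / 2))),
               c(0, 1, 0), tolerance = 1e-12)
  # Euclidean pairwise distances preserved, Chebyshev generally not
  set.seed(10)
  x <- matrix(rnorm(90), ncol = 3)
  rx <- rotate_cloud(x, c(0.4, 1.1, -0.7))
  expect_lt(max(abs(dist(x) - dist(rx))), 1e-10)
  expect_gt(max(abs(chebyshev_distances(x) - chebyshev_distances(rx))), 1e-3)
})

test_that("invalid shape specifications are rejected", {
  expect_error(generate_shape("cube", 10), "arg")
  expect_error(generate_shape("torus_knot", 10, p = 4, q = 2), "coprime")
  expect_error(generate_shape("torus_hollow", 10, R = 0.5, r = 0.5), "minor")
  expect_error(generate_shape("sphere", 10, radius = -1), "positive")
  expect_error(rotate_cloud(matrix(0, 2, 2), c(0, 0, 0)), "3-column")
})

test_that("cloud TSV round-trips", {
  cl <- generate_shape("sphere", 50, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_cloud_tsv(cl, path)
  back <- read_cloud_tsv(path)
  expect_equal(unname(back), unname(cl), tolerance = 1e-12)
  expect_identical(colnames(back), c("x1", "x2", "x3"))
})
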