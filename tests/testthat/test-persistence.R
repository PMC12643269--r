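test_that("chebyshev distances match the definition and a brute-force loop", {
  pts <- rbind(c(0, 0, 0), c(1, 2, 0.5))
  expect_equal(chebyshev_distances(pts)[1, 2], 2)
  expect_equal(chebyshev_distances(rbind(c(1, 1), c(1, 1)))[1, 2], 0)
  set.seed(1)
  x <- matrix(rnorm(150), ncol = 3)
  expect_equal(chebyshev_distances(x), brute_chebyshev(x), tolerance = 1e-14)
})

test_that("two points give one finite and one infinite component", {
  d <- vr_diagram(matrix(c(0, 3, 3, 0), 2), maxdim = 2)
  expect_equal(nrow(d), 2)
  expect_equal(d$dim, c(0L, 0L))
  expect_equal(sort(d$death), c(3, Inf))
})

test_that("the square carries one 1-cycle born sqrt(2), filled at 2", {
  sq <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  d <- vr_diagram(as.matrix(dist(sq)), maxdim = 1)
  pos <- d[d$dim == 1 & d$death > d$birth, ]
  expect_equal(nrow(pos), 1)
  expect_equal(pos$birth, sqrt(2), tolerance = 1e-12)
  expect_equal(pos$death, 2, tolerance = 1e-12)
})

test_that("the octahedron carries one 2-sphere born sqrt(2), filled at 2", {
  oc <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  d <- vr_diagram(as.matrix(dist(oc)), maxdim = 2)
  pos <- d[d$dim == 2 & d$death > d$birth, ]
  expect_equal(nrow(pos), 1)
  expect_equal(pos$birth, sqrt(2), tolerance = 1e-12)
  expect_equal(pos$death, 2, tolerance = 1e-12)
  sm <- tda_summary(d)
  expect_equal(sm$n_voids, 1L)
  expect_equal(sm$avg_persistence, 2 - sqrt(2), tolerance = 1e-12)
  expect_equal(sm$max_persistence, 2 - sqrt(2), tolerance = 1e-12)
})

test_that("the reducer matches a naive full-matrix reduction bar for bar", {
  set.seed(2)
  for (rep in 1:8) {
    n <- sample(5:16, 1)
    cloud <- matrix(rnorm(3 * n), ncol = 3)
    D <- chebyshev_distances(cloud)
    fast <- vr_diagram(D, maxdim = 2)
    slow <- naive_vr_diagram(D, maxdim = 2)
    expect_equal(diagram_key(fast), diagram_key(slow), tolerance = 1e-12)
  }
})

test_that("every point births a component and exactly one survives", {
  set.seed(3)
  x <- matrix(runif(60), ncol = 3)
  d <- vr_diagram(chebyshev_distances(x), maxdim = 0)
  expect_equal(sum(d$dim == 0), 20)
  expect_equal(sum(is.infinite(d$death)), 1)
})

test_that("tda_summary aggregates finite positive bars only", {
  dg <- data.frame(dim = c(2, 2, 2, 1, 2),
                   birth = c(1, 1, 2, 0.5, 3),
                   death = c(1.2, 1.4, 2, 9, Inf))
  sm <- tda_summary(dg)
  expect_equal(sm$n_voids, 2L)
  expect_equal(sm$avg_persistence, 0.3)
  expect_equal(sm$max_persistence, 0.4)
  none <- tda_summary(data.frame(dim = 1L, birth = 0, death = 1), dim = 2)
  expect_equal(none, list(n_voids = 0L, avg_persistence = 0,
                          max_persistence = 0))
})

test_that("subsampling is uniform, seed-deterministic and bounded", {
  set.seed(4)
  x <- matrix(rnorm(60), ncol = 3)
  s1 <- subsample_rows(x, 20, seed = 1)  # m = n: a permutation of the rows
  expect_equal(dim(s1), dim(x))
  expect_equal(apply(s1, 2, sort), apply(x, 2, sort))
  expect_identical(subsample_rows(x, 5, seed = 2), subsample_rows(x, 5, seed = 2))
  one <- subsample_rows(x, 1, seed = 3)
  expect_true(any(apply(x, 1, function(r) all(r == one[1, ]))))
  expect_error(subsample_rows(x, 21, seed = 1), "more rows")
})

test_that("oversized inputs and malformed matrices are refused", {
  big <- matrix(0, 401, 401)
  expect_error(vr_diagram(big, maxdim = 2), "400")
  expect_error(vr_diagram(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(vr_diagram(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  expect_error(vr_diagram(matrix(c(1, 0, 0, 1), 2)), "diagonal")
})

test_that("diagrams round-trip through TSV including infinite bars", {
  oc <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  d <- vr_diagram(as.matrix(dist(oc)), maxdim = 2)
  path <- tempfile(fileext = ".tsv")
  write_diagram_tsv(d, path)
  back <- read_diagram_tsv(path)
  expect_equal(diagram_key(back), diagram_key(d), tolerance = 1e-9)
})
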