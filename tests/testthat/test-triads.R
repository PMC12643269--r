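test_that("triad enumeration is complete, sorted and lexicographic", {
  t3 <- enumerate_triads(3)
  expect_equal(unname(t3), matrix(c(1L, 2L, 3L), 1))
  t10 <- enumerate_triads(10)
  expect_equal(nrow(t10), 120)
  expect_true(all(t10[, 1] < t10[, 2] & t10[, 2] < t10[, 3]))
  expect_false(is.unsorted(t10[, 1]))
  expect_error(enumerate_triads(2), "at least 3")
})

test_that("circular shift is a per-channel permutation anchored at channel 1", {
  sim <- generate_bold(n_parcels = 5, scan_length = 100, n_scans = 4, seed = 1)
  tri <- c(2, 4, 5)
  sh <- circular_shift_triad(sim, tri)
  expect_equal(sh[, 1], unname(sim$data[, 2]))
  for (c in 1:3) {
    expect_equal(sort(sh[, c]), sort(unname(sim$data[, tri[c]])))
  }
  # shifting by scan_length n_scans times wraps to the identity
  roll <- function(v, s) if (s %% length(v) == 0) v else
    c(v[(s + 1):length(v)], v[1:s])
  v <- sim$data[, 4]
  for (i in 1:4) v <- roll(v, 100)
  expect_equal(v, sim$data[, 4])
  expect_error(
    circular_shift_triad(multiscan_series(sim$data, 200), tri),
    "at least 3 scans"
  )
})

test_that("the shift destroys cross-channel dependence but not the marginals", {
  sim <- generate_bold(n_parcels = 3, scan_length = 400, n_scans = 4,
                       redundant = 1, coupling = 0.95, seed = 2)
  set.seed(3)
  o_raw <- estimate_o_information(sim$data)
  sh <- circular_shift_triad(sim, c(1, 2, 3))
  set.seed(4)
  o_null <- estimate_o_information(sh)
  expect_gt(o_raw, 0.5)
  expect_lt(abs(o_null), 0.2)
})

test_that("null O distribution is centered at zero on independent data", {
  sim <- generate_bold(n_parcels = 10, scan_length = 300, n_scans = 4, seed = 5)
  triads <- enumerate_triads(10)[1:100, ]
  set.seed(6)
  null <- build_null(sim, triads)
  expect_equal(null$count, 100)
  expect_lt(abs(null$mean), 3 * null$sd / sqrt(100))

  set.seed(7)
  single <- build_null(sim, enumerate_triads(10)[1, , drop = FALSE])
  expect_equal(single$count, 1)
  expect_equal(single$sd, 0)
})

test_that("shifted and raw O distributions match on null data", {
  sim <- generate_bold(n_parcels = 12, scan_length = 300, n_scans = 4, seed = 8)
  triads <- enumerate_triads(12)[seq_len(200), ]
  set.seed(9)
  o_raw <- vapply(seq_len(200), function(r) {
    estimate_o_information(sim$data[, triads[r, ]])
  }, numeric(1))
  set.seed(10)
  null <- build_null(sim, triads)
  expect_gt(ks_compare(abs(o_raw), abs(null$values))$p, 0.01)
})

test_that("classification uses strict three-sigma boundaries", {
  null <- list(mean = 0, sd = 0.1)
  expect_equal(classify_o(-0.5, null), "synergistic")
  expect_equal(classify_o(0.2, null), "neither")
  expect_equal(classify_o(0.31, null), "redundant")
  expect_equal(classify_o(c(-1, 0, 1), null),
               c("synergistic", "neither", "redundant"))
  # exactly on the boundary is not significant
  expect_equal(classify_o(0.3, null), "neither")
})

test_that("raising the threshold multiplier can only shrink significant sets", {
  sim <- generate_bold(n_parcels = 9, scan_length = 300, n_scans = 4,
                       redundant = 1, synergistic = 1, seed = 11)
  set.seed(12)
  scr <- screen_triads(sim)
  lab3 <- scr$table$label
  lab4 <- classify_o(scr$table$o, scr$null, sd_mult = 4)
  expect_lte(sum(lab4 == "redundant"), sum(lab3 == "redundant"))
  expect_lte(sum(lab4 == "synergistic"), sum(lab3 == "synergistic"))
  expect_true(all(lab3[lab4 == "redundant"] == "redundant"))
  expect_true(all(lab3[lab4 == "synergistic"] == "synergistic"))
})
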