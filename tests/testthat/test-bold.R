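test_that("null channels are AR(1) with the requested autocorrelation", {
  sim <- generate_bold(n_parcels = 6, scan_length = 1100, n_scans = 2,
                       ar_coefficient = 0.4, seed = 1)
  idx <- seq_len(1099)
  ac <- vapply(seq_len(6), function(c) {
    cor(sim$data[idx, c], sim$data[idx + 1, c])
  }, numeric(1))
  expect_lt(max(abs(ac - 0.4)), 0.05 + 2 / sqrt(1100))
  expect_equal(mean(ac), 0.4, tolerance = 0.05)
})

test_that("columns are z-scored within each scan", {
  sim <- generate_bold(n_parcels = 4, scan_length = 250, n_scans = 3, seed = 2)
  for (s in 1:3) {
    idx <- (s - 1) * 250 + seq_len(250)
    expect_lt(max(abs(colMeans(sim$data[idx, ]))), 1e-10)
    expect_lt(max(abs(apply(sim$data[idx, ], 2, sd) - 1)), 1e-10)
  }
})

test_that("planted triads carry higher-order information of the right sign", {
  sim <- generate_bold(n_parcels = 6, scan_length = 1000, n_scans = 4,
                       redundant = 1, synergistic = 1,
                       coupling = 0.9, noise_level = 0.1, seed = 3)
  set.seed(4)
  o_red <- estimate_o_information(sim$data[, 1:3])
  o_syn <- estimate_o_information(sim$data[, 4:6])
  expect_gt(o_red, 0.1)
  expect_lt(o_syn, -0.1)
  expect_equal(sim$ground_truth$label, c("redundant", "synergistic"))
})

test_that("gaussian oracle predicts the sign of both planted constructions", {
  # shared source: x_j = sqrt(c) L + sqrt(1-c) E_j
  cpl <- 0.9
  red_cov <- matrix(cpl, 3, 3); diag(red_cov) <- 1
  expect_gt(gaussian_o_information(red_cov)$o, 0)
  # collider: x3 = (x1 + x2)/sqrt(2) + eps, sd 0.1
  a <- 1 / sqrt(2)
  syn_cov <- rbind(c(1, 0, a), c(0, 1, a), c(a, a, 1 + 0.01))
  expect_lt(gaussian_o_information(syn_cov)$o, 0)
})

test_that("unplanted data yields no significant triads", {
  sim <- generate_bold(n_parcels = 6, scan_length = 400, n_scans = 4, seed = 5)
  set.seed(6)
  scr <- screen_triads(sim)
  expect_gte(mean(scr$table$label == "neither"), 0.95)
})

test_that("BOLD csv round-trips and carries the scan structure", {
  sim <- generate_bold(n_parcels = 5, scan_length = 10, n_scans = 4, seed = 7)
  path <- tempfile(fileext = ".csv")
  write_bold_csv(sim, path)
  back <- read_bold_csv(path, scan_length = 10)
  expect_equal(back$data, sim$data, tolerance = 1e-9)
  expect_equal(back$n_scans, 4L)
  expect_identical(colnames(back$data), paste0("p", 1:5))

  writeLines(c("a,b", "1,x", "2,3"), path)
  expect_error(read_bold_csv(path, scan_length = 1), "numeric")
})

test_that("overlapping planted triads are rejected", {
  expect_error(
    generate_bold(n_parcels = 5, scan_length = 50, n_scans = 4,
                  redundant = list(c(1, 2, 3)), synergistic = list(c(3, 4, 5)),
                  seed = 1),
    "share parcels"
  )
  expect_error(
    generate_bold(n_parcels = 5, scan_length = 50, n_scans = 4,
                  redundant = list(c(1, 2, 9)), seed = 1),
    "exceeds"
  )
})
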