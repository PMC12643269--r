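#' Enumerate all triads of channels
#'
#' All `choose(C, 3)` unordered triples of channel indices, 1-based, each row
#' sorted ascending, in lexicographic order. For 200 parcels this is the
#' 1,313,400-triad census used for whole-cortex screens.
#'
#' @param C number of channels (at least 3).
#' @return integer matrix with columns `i`, `j`, `k`.
#' @export
enumerate_triads <- function(C) {
  if (C < 3) stop("need at least 3 channels")
  out <- t(combn(C, 3L))
  colnames(out) <- c("i", "j", "k")
  out
}

#' Circular-shift surrogate for a triad
#'
#' Extracts the three channels of a triad and circularly shifts channel
#' position `c` (0, 1, 2) by `c * scan_length` frames with wraparound, so
#' each channel effectively comes from a different scan. The shift is a
#' circular permutation of frames: each channel's marginal distribution and
#' within-channel autocorrelation are untouched, but any cross-channel
#' dependence is destroyed — any O-information that survives is attributable
#' to autocorrelation alone, which makes the shifted triads a null ensemble
#' for significance testing.
#'
#' @param series a `multiscan_series` with at least 3 scans.
#' @param triad integer vector of three distinct channel indices.
#' @return `T x 3` matrix of the shifted channels.
#' @export
circular_shift_triad <- function(series, triad) {
  stopifnot(inherits(series, "multiscan_series"))
  if (series$n_scans < 3) {
    stop("circular-shift null needs at least 3 scans so every channel comes from a different one")
  }
  triad <- as.integer(triad)
  stopifnot(length(triad) == 3, !anyDuplicated(triad))
  T_total <- nrow(series$data)
  out <- matrix(0, T_total, 3)
  for (c in 0:2) {
    shift <- (c * series$scan_length) %% T_total
    col <- series$data[, triad[c + 1]]
    out[, c + 1] <- if (shift == 0) col else
      c(col[(shift + 1):T_total], col[1:shift])
  }
  colnames(out) <- paste0("p", triad)
  out
}

#' Null distribution of O-information under circular shifting
#'
#' One surrogate O-information per triad (the estimator applied to the
#' circularly shifted channels), pooled into a single null distribution whose
#' mean and standard deviation calibrate the significance threshold.
#'
#' @param series a `multiscan_series`.
#' @param triads integer matrix of triads (rows), e.g. from
#'   [enumerate_triads()].
#' @param k neighbor order for the O-information estimator.
#' @param tie_noise tie-breaking jitter passed to the estimator.
#' @return list of class `null_distribution` with `mean`, `sd` (0 when only
#'   one triad), `count` and the vector of null `values`.
#' @export
build_null <- function(series, triads, k = 4, tie_noise = 1e-8) {
  triads <- rbind(triads)
  if (nrow(triads) < 1) stop("need at least one triad")
  values <- vapply(seq_len(nrow(triads)), function(r) {
    shifted <- circular_shift_triad(series, triads[r, ])
    estimate_o_information(shifted, k = k, tie_noise = tie_noise)
  }, numeric(1))
  structure(
    list(mean = mean(values),
         sd = if (length(values) > 1) sd(values) else 0,
         count = length(values), values = values),
    class = "null_distribution"
  )
}

#' Classify a triad's O-information against the null
#'
#' A triad is significantly `"synergistic"` when its O-information lies more
#' than `sd_mult` standard deviations below the null mean, significantly
#' `"redundant"` when more than `sd_mult` above, and `"neither"` otherwise.
#'
#' @param o O-information value(s) in nats.
#' @param null a [build_null()] result (or any list with `mean` and `sd`).
#' @param sd_mult threshold multiplier (default 3).
#' @return character vector of labels.
#' @export
classify_o <- function(o, null, sd_mult = 3) {
  stopifnot(null$sd >= 0)
  lo <- null$mean - sd_mult * null$sd
  hi <- null$mean + sd_mult * null$sd
  ifelse(o < lo, "synergistic", ifelse(o > hi, "redundant", "neither"))
}

#' Screen every triad of a multi-scan series
#'
#' The full significance screen: estimates the O-information (and TC, DTC, S,
#' normalized O) of every requested triad, builds the pooled circular-shift
#' null (one surrogate per triad), and labels each triad as redundant,
#' synergistic or neither at `sd_mult` standard deviations.
#'
#' @inheritParams build_null
#' @param sd_mult significance threshold multiplier (default 3).
#' @param triads optional triad matrix; defaults to all triads.
#' @return list of class `triad_screen` with `table` (data frame: `i`, `j`,
#'   `k`, `tc`, `dtc`, `o`, `s`, `o_norm`, `label`) and `null` (the pooled
#'   null distribution).
#' @export
screen_triads <- function(series, triads = NULL, k = 4, sd_mult = 3,
                          tie_noise = 1e-8) {
  stopifnot(inherits(series, "multiscan_series"))
  if (is.null(triads)) triads <- enumerate_triads(ncol(series$data))
  triads <- rbind(triads)
  est <- lapply(seq_len(nrow(triads)), function(r) {
    cloud <- series$data[, triads[r, ], drop = FALSE]
    estimate_all(cloud, k = k, tie_noise = tie_noise)
  })
  null <- build_null(series, triads, k = k, tie_noise = tie_noise)
  tab <- data.frame(
    i = triads[, 1], j = triads[, 2], k = triads[, 3],
    tc = vapply(est, `[[`, numeric(1), "tc"),
    dtc = vapply(est, `[[`, numeric(1), "dtc"),
    o = vapply(est, `[[`, numeric(1), "o"),
    s = vapply(est, `[[`, numeric(1), "s"),
    o_norm = vapply(est, `[[`, numeric(1), "o_norm"),
    stringsAsFactors = FALSE
  )
  tab$label <- classify_o(tab$o, null, sd_mult)
  structure(list(table = tab, null = null, k = k, sd_mult = sd_mult),
            class = "triad_screen")
}

#' @export
print.triad_screen <- function(x, ...) {
  cat(sprintf(
    "triad_screen: %d triads, null mean %.4f sd %.4f (threshold %.1f sd)\n",
    nrow(x$table), x$null$mean, x$null$sd, x$sd_mult))
  print(table(x$table$label))
  invisible(x)
}
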