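#' Synthetic multi-scan BOLD-like time series with planted triads
#'
#' Emulates the statistical skeleton of parcellated resting-state fMRI as the
#' triad screen sees it: several scans of equal length concatenated along
#' time, each channel temporally autocorrelated, with a handful of channel
#' triples carrying genuine higher-order structure and everything else
#' independent. Three channel classes are generated, all built from unit-
#' variance AR(1) innovations re-initialized at every scan boundary:
#'
#' * null channels: independent AR(1) series;
#' * redundant triads: three channels sharing a common latent AR(1) source,
#'   `x_j = sqrt(coupling) * L + sqrt(1 - coupling) * E_j` — redundancy as a
#'   synchronized component, giving O-information > 0;
#' * synergistic triads: two independent AR(1) parents and a third channel
#'   equal to their standardized sum plus a little observation noise — a
#'   causal collider, where the joint state of the parents pins down the
#'   child (like a tilted plane), giving O-information < 0. The sum (rather
#'   than a product) keeps the construction jointly Gaussian so closed-form
#'   covariance oracles apply.
#'
#' Every column is z-scored within each scan, mirroring the scale of
#' preprocessed BOLD output.
#'
#' @param n_parcels number of channels (columns).
#' @param scan_length frames per scan.
#' @param n_scans number of concatenated scans.
#' @param ar_coefficient lag-1 autocorrelation of every AR(1) process, in
#'   `[0, 1)`.
#' @param redundant list of integer triples (1-based parcel indices) to plant
#'   as redundant triads, or an integer count (triads are then assigned to
#'   the lowest free parcel indices).
#' @param synergistic same, for collider triads.
#' @param coupling shared-source variance fraction for redundant triads.
#' @param noise_level collider observation-noise standard deviation, relative
#'   to the unit-variance standardized sum.
#' @param seed integer seed (private RNG state).
#' @return list of class `multiscan_series` with `data` (`T x C` matrix,
#'   `T = scan_length * n_scans`), `scan_length`, `n_scans`, and
#'   `ground_truth` (data frame of planted triads: `i`, `j`, `k`, `label`).
#' @examples
#' sim <- generate_bold(n_parcels = 9, scan_length = 200, n_scans = 4,
#'                      redundant = 1, synergistic = 1, seed = 1)
#' sim$ground_truth
#' @export
generate_bold <- function(n_parcels, scan_length, n_scans,
                          ar_coefficient = 0.4, redundant = 0,
                          synergistic = 0, coupling = 0.9,
                          noise_level = 0.1, seed = 1) {
  stopifnot(n_parcels >= 1, scan_length >= 2, n_scans >= 1,
            ar_coefficient >= 0, ar_coefficient < 1)
  as_triads <- function(x, offset) {
    if (is.numeric(x) && length(x) == 1 && x == floor(x) && is.null(dim(x))) {
      if (x == 0) return(matrix(integer(0), 0, 3))
      t(vapply(seq_len(x), function(m) as.integer(offset + 3 * (m - 1) + 1:3),
               integer(3)))
    } else {
      m <- do.call(rbind, lapply(x, function(tr) sort(as.integer(tr))))
      matrix(as.integer(m), ncol = 3)
    }
  }
  red <- as_triads(redundant, 0)
  syn <- as_triads(synergistic, 3 * nrow(red))
  planted <- rbind(red, syn)
  if (nrow(planted) > 0) {
    if (max(planted) > n_parcels) stop("planted triad index exceeds n_parcels")
    if (anyDuplicated(as.vector(planted))) {
      stop("planted triads must not share parcels")
    }
  }

  T_total <- scan_length * n_scans
  data <- with_private_seed(seed, {
    # stationary unit-variance AR(1), re-initialized per scan
    ar1 <- function() {
      out <- numeric(T_total)
      for (s in seq_len(n_scans)) {
        idx <- (s - 1) * scan_length + seq_len(scan_length)
        e <- rnorm(scan_length, sd = sqrt(1 - ar_coefficient^2))
        x <- numeric(scan_length)
        x[1] <- rnorm(1)
        for (t in 2:scan_length) x[t] <- ar_coefficient * x[t - 1] + e[t]
        out[idx] <- x
      }
      out
    }
    M <- matrix(0, T_total, n_parcels)
    for (c in seq_len(n_parcels)) M[, c] <- ar1()
    if (nrow(red) > 0) {
      for (m in seq_len(nrow(red))) {
        L <- ar1()
        for (c in red[m, ]) {
          M[, c] <- sqrt(coupling) * L + sqrt(1 - coupling) * M[, c]
        }
      }
    }
    if (nrow(syn) > 0) {
      for (m in seq_len(nrow(syn))) {
        tr <- syn[m, ]
        M[, tr[3]] <- (M[, tr[1]] + M[, tr[2]]) / sqrt(2) +
          noise_level * rnorm(T_total)
      }
    }
    # z-score each column within each scan
    for (s in seq_len(n_scans)) {
      idx <- (s - 1) * scan_length + seq_len(scan_length)
      M[idx, ] <- scale(M[idx, , drop = FALSE])
    }
    colnames(M) <- paste0("p", seq_len(n_parcels))
    M
  })

  truth <- data.frame(
    i = planted[, 1], j = planted[, 2], k = planted[, 3],
    label = rep(c("redundant", "synergistic"), c(nrow(red), nrow(syn))),
    stringsAsFactors = FALSE
  )
  structure(
    list(data = data, scan_length = as.integer(scan_length),
         n_scans = as.integer(n_scans), ground_truth = truth),
    class = "multiscan_series"
  )
}

#' Multi-scan series from an existing matrix
#'
#' Wraps a `T x C` numeric matrix (rows = frames, columns = parcels) with the
#' scan structure needed by the circular-shift null.
#'
#' @param data numeric matrix.
#' @param scan_length frames per scan; must divide `nrow(data)`.
#' @return a `multiscan_series` (without ground truth).
#' @export
multiscan_series <- function(data, scan_length) {
  data <- as_cloud(data)
  if (nrow(data) %% scan_length != 0) {
    stop("scan_length must divide the number of frames")
  }
  structure(
    list(data = data, scan_length = as.integer(scan_length),
         n_scans = as.integer(nrow(data) / scan_length),
         ground_truth = NULL),
    class = "multiscan_series"
  )
}

#' @export
print.multiscan_series <- function(x, ...) {
  cat(sprintf("multiscan_series: %d frames (%d scans x %d) x %d parcels\n",
              nrow(x$data), x$n_scans, x$scan_length, ncol(x$data)))
  if (!is.null(x$ground_truth) && nrow(x$ground_truth) > 0) {
    cat(sprintf("  planted: %d redundant, %d synergistic\n",
                sum(x$ground_truth$label == "redundant"),
                sum(x$ground_truth$label == "synergistic")))
  }
  invisible(x)
}

#' Read and write BOLD-style CSV matrices
#'
#' Plain numeric CSV, rows = time frames, columns = parcels, with a header
#' row of column names. The scan structure is not stored in the file; supply
#' `scan_length` when reading.
#'
#' @param series a `multiscan_series` or plain matrix.
#' @param path file path.
#' @param scan_length frames per scan for the returned series.
#' @return `read_bold_csv()` returns a `multiscan_series`; `write_bold_csv()`
#'   returns `path` invisibly.
#' @export
write_bold_csv <- function(series, path) {
  m <- if (inherits(series, "multiscan_series")) series$data else
    as_cloud(series)
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bold_csv
#' @export
read_bold_csv <- function(path, scan_length) {
  df <- read.csv(path, header = TRUE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("BOLD csv must be entirely numeric")
  }
  m <- as.matrix(df)
  multiscan_series(m, scan_length)
}
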