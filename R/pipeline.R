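#' O-information of the benchmark shape suite
#'
#' Runs the eight benchmark configurations — line, embedded plane, sphere,
#' ball, hollow torus, filled torus, trefoil knot and 5,3-knot — at the study
#' scale (10,000 points, k = 4, Chebyshev metric) and reports the estimated
#' O-information of each raw (rotated) cloud and of the same cloud after PCA
#' rotation. The plane, both tori and both knots are rotated by pi/4 about
#' each axis; the line, sphere and ball are orientation-trivial and generated
#' unrotated.
#'
#' The 5,3-knot row uses the torus-knot embedding with five windings around
#' the tube and three around the symmetry axis (`generate_shape(p = 3,
#' q = 5)`), the embedding whose higher-order structure matches the published
#' benchmark values; the trefoil is the (2, 3) knot.
#'
#' @param n points per shape.
#' @param k neighbor order.
#' @param seed integer seed controlling both sampling and tie noise.
#' @return data frame with columns `shape`, `o_raw`, `o_pca`, `pc1_variance`.
#' @export
run_shape_suite <- function(n = 10000, k = 4, seed = 1) {
  rot <- rep(pi / 4, 3)
  none <- c(0, 0, 0)
  configs <- list(
    line = list(kind = "line", rotation = none),
    plane = list(kind = "plane", rotation = rot),
    sphere = list(kind = "sphere", rotation = none),
    ball = list(kind = "ball", rotation = none),
    torus_hollow = list(kind = "torus_hollow", rotation = rot),
    torus_filled = list(kind = "torus_filled", rotation = rot),
    trefoil = list(kind = "torus_knot", rotation = rot, p = 2, q = 3),
    knot_53 = list(kind = "torus_knot", rotation = rot, p = 3, q = 5)
  )
  rows <- lapply(seq_along(configs), function(idx) {
    cfg <- configs[[idx]]
    cloud <- do.call(generate_shape,
                     c(cfg, list(n = n, seed = seed + idx)))
    with_private_seed(seed + 1000 + idx, {
      o_raw <- estimate_o_information(cloud, k = k)
      pca <- pca_rotate(cloud)
      o_pca <- estimate_o_information(pca$rotated, k = k)
      data.frame(shape = names(configs)[idx], o_raw = o_raw, o_pca = o_pca,
                 pc1_variance = pca$explained_fractions[1],
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Information, topology and compressibility features per triad
#'
#' For each triad: the information measures of the raw 3-column point cloud
#' and of its PCA rotation; the dimension-2 persistence summaries (void
#' count, average and maximum persistence) of the Vietoris-Rips filtration on
#' the Chebyshev distances of a subsampled raw cloud; and the fraction of
#' variance on the first principal component. Topology is computed on the
#' raw (un-rotated) cloud: the Chebyshev metric is not rotation-invariant, so
#' the filtration must see the data in its recorded orientation (set
#' `tda_on_pca = TRUE` to add post-PCA summaries).
#'
#' One frame subsample (of size `subsample`, seed-controlled) is shared by
#' all triads so their topological summaries are comparable.
#'
#' @param series a `multiscan_series`.
#' @param triads integer matrix of triads (rows); typically the significant
#'   rows of a [screen_triads()] table.
#' @param k neighbor order.
#' @param subsample frames used for persistence (default 120; the reducer
#'   enumerates all 4-point subsets, so keep this a few hundred at most).
#' @param seed seed for the shared frame subsample and tie noise.
#' @param tda_on_pca also compute persistence summaries of the PCA-rotated
#'   subsampled cloud.
#' @param labels optional character vector of significance labels, recycled
#'   onto the output.
#' @return data frame, one row per triad: `i`, `j`, `k`, `label` (if given),
#'   `tc`, `dtc`, `o`, `s`, `o_norm`, the same with suffix `_pca`,
#'   `n_voids`, `avg_persistence`, `max_persistence` (plus `_pca` variants if
#'   requested) and `pc1_variance`.
#' @export
compute_triad_features <- function(series, triads, k = 4, subsample = 120,
                                   seed = 1, tda_on_pca = FALSE,
                                   labels = NULL) {
  stopifnot(inherits(series, "multiscan_series"))
  triads <- rbind(triads)
  T_total <- nrow(series$data)
  m <- min(subsample, T_total)
  frame_idx <- with_private_seed(seed, sample.int(T_total, m))
  rows <- lapply(seq_len(nrow(triads)), function(r) {
    cloud <- series$data[, triads[r, ], drop = FALSE]
    with_private_seed(seed + r, {
      raw <- estimate_all(cloud, k = k)
      pca <- pca_rotate(cloud)
      rot <- estimate_all(pca$rotated, k = k)
      sub <- cloud[frame_idx, , drop = FALSE]
      tda <- tda_summary(vr_diagram(chebyshev_distances(sub), maxdim = 2))
      out <- data.frame(
        i = triads[r, 1], j = triads[r, 2], k = triads[r, 3],
        tc = raw$tc, dtc = raw$dtc, o = raw$o, s = raw$s, o_norm = raw$o_norm,
        tc_pca = rot$tc, dtc_pca = rot$dtc, o_pca = rot$o, s_pca = rot$s,
        o_norm_pca = rot$o_norm,
        n_voids = tda$n_voids, avg_persistence = tda$avg_persistence,
        max_persistence = tda$max_persistence,
        pc1_variance = pca$explained_fractions[1],
        stringsAsFactors = FALSE
      )
      if (tda_on_pca) {
        sub_pca <- pca$rotated[frame_idx, , drop = FALSE]
        tp <- tda_summary(vr_diagram(chebyshev_distances(sub_pca), maxdim = 2))
        out$n_voids_pca <- tp$n_voids
        out$avg_persistence_pca <- tp$avg_persistence
        out$max_persistence_pca <- tp$max_persistence
      }
      out
    })
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out <- cbind(out[, 1:3], label = labels,
                                     out[, -(1:3), drop = FALSE])
  out
}

#' Spearman correlations between triad features, by significance class
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value for
#' each requested feature pair, computed separately within each significance
#' class. Classes (or feature pairs) with fewer than 3 complete rows are
#' skipped with a warning; rows where either feature is missing (e.g. an
#' undefined normalized O-information) are dropped pairwise. No multiplicity
#' correction is applied.
#'
#' @param rows a [compute_triad_features()] data frame with a `label` column.
#' @param pairs list of length-2 character vectors naming feature columns.
#' @param classes classes to analyze (default redundant and synergistic).
#' @return data frame: `feature_x`, `feature_y`, `class`, `rho`, `p`, `n`.
#' @export
correlate_features <- function(rows, pairs,
                               classes = c("redundant", "synergistic")) {
  stopifnot("label" %in% names(rows))
  out <- list()
  for (cl in classes) {
    sub <- rows[rows$label == cl, , drop = FALSE]
    if (nrow(sub) < 3) {
      warning(sprintf("class '%s' has fewer than 3 triads; skipped", cl))
      next
    }
    for (pr in pairs) {
      ok <- stats::complete.cases(sub[[pr[1]]], sub[[pr[2]]])
      if (sum(ok) < 3) {
        warning(sprintf("pair (%s, %s) in class '%s' has fewer than 3 complete rows; skipped",
                        pr[1], pr[2], cl))
        next
      }
      ct <- suppressWarnings(
        cor.test(sub[[pr[1]]][ok], sub[[pr[2]]][ok], method = "spearman",
                 exact = FALSE)
      )
      out[[length(out) + 1]] <- data.frame(
        feature_x = pr[1], feature_y = pr[2], class = cl,
        rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Maximum gap between the two empirical CDFs, with the asymptotic two-sided
#' p-value; used to compare the compressibility (PC1 variance share) of
#' redundant versus synergistic triads.
#'
#' @param values_a,values_b numeric samples.
#' @return list with `statistic` and `p`.
#' @export
ks_compare <- function(values_a, values_b) {
  if (length(values_a) < 1 || length(values_b) < 1) {
    stop("both samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(values_a, values_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}
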