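#' Chebyshev distance matrix of a point cloud
#'
#' `D[a, b] = max_j |cloud[a, j] - cloud[b, j]|`. The max-norm is used
#' throughout so that the topological and information-theoretic analyses see
#' the same geometry.
#'
#' @param cloud numeric matrix, one row per point.
#' @return an `n x n` symmetric matrix with zero diagonal.
#' @export
chebyshev_distances <- function(cloud) {
  cloud <- as_cloud(cloud)
  n <- nrow(cloud)
  D <- matrix(0, n, n)
  for (j in seq_len(ncol(cloud))) {
    D <- pmax(D, abs(outer(cloud[, j], cloud[, j], "-")))
  }
  D
}

#' Vietoris-Rips persistence diagram
#'
#' Persistent homology of the Rips clique-complex filtration over Z/2,
#' computed by boundary-matrix reduction (with the clearing optimization and
#' union-find for connected components). Simplices up to dimension
#' `maxdim + 1` are enumerated so that deaths in dimension `maxdim` are
#' resolved. The filtration is ordered by simplex diameter, with ties broken
#' by dimension and then lexicographic vertex tuple, and truncated at the
#' enclosing radius (the smallest distance at which some point is within
#' reach of every other): past that value the complex is a cone, so homology
#' in dimensions 1 and above is already dead and the bars are identical to
#' the untruncated filtration's.
#'
#' Zero-persistence bars are retained in the diagram (summaries drop them,
#' see [tda_summary()]). A connected cloud yields exactly one infinite
#' dimension-0 bar.
#'
#' The reducer enumerates all `choose(n, maxdim + 2)` top simplices, so for
#' `maxdim = 2` it refuses clouds with more than 400 points (use
#' [subsample_rows()] first); for `maxdim = 1` the cap is 2000 points.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal (see
#'   [chebyshev_distances()]), or a point cloud matrix to be converted.
#' @param maxdim highest homology dimension to resolve (0, 1 or 2).
#' @param threshold filtration truncation value; default the enclosing
#'   radius.
#' @return a data frame of class `persistence_diagram` with columns `dim`,
#'   `birth`, `death` (`Inf` for essential classes).
#' @examples
#' sq <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
#' D <- as.matrix(dist(sq))           # Euclidean square: one 1-cycle
#' vr_diagram(D, maxdim = 1)
#' @export
vr_diagram <- function(D, maxdim = 2, threshold = NULL) {
  D <- as.matrix(D)
  if (!maxdim %in% 0:2) stop("maxdim must be 0, 1 or 2")
  n <- nrow(D)
  if (ncol(D) != n) stop("distance matrix must be square")
  if (any(D < 0)) stop("distance matrix entries must be nonnegative")
  if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (maxdim == 2 && n > 400) {
    stop("maxdim = 2 supports at most 400 points; subsample the cloud first")
  }
  if (maxdim == 1 && n > 2000) {
    stop("maxdim = 1 supports at most 2000 points; subsample the cloud first")
  }
  if (is.null(threshold)) threshold <- enclosing_radius(D)
  bars <- cpp_vr_diagram(D, as.integer(maxdim), threshold)
  out <- data.frame(dim = as.integer(bars[, "dim"]), birth = bars[, "birth"],
                    death = bars[, "death"])
  out <- out[order(out$dim, out$birth, out$death), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("persistence_diagram", "data.frame")
  out
}

#' Enclosing radius of a distance matrix
#'
#' The smallest filtration value at which some point is joined to every other
#' point: `min_a max_b D[a, b]`. At and beyond it the Rips complex is a cone
#' and therefore contractible in dimensions 1 and above.
#'
#' @param D symmetric distance matrix.
#' @return a scalar radius.
#' @export
enclosing_radius <- function(D) {
  D <- as.matrix(D)
  min(apply(D, 1, max))
}

#' Summaries of the voids in a persistence diagram
#'
#' Counts and sizes the finite, positive-persistence features of the
#' requested dimension. For `dim = 2` these are enclosed three-dimensional
#' cavities ("voids") such as the interior of a sphere or hollow torus:
#' `n_voids` is their count, `avg_persistence` the mean lifetime
#' (death - birth) and `max_persistence` the longest lifetime, both 0 when no
#' such feature exists. Zero-persistence pairs and essential (infinite)
#' classes are excluded.
#'
#' @param diag a [vr_diagram()] result (or any data frame with `dim`,
#'   `birth`, `death`).
#' @param dim homology dimension to summarize (default 2).
#' @return list with `n_voids`, `avg_persistence`, `max_persistence`.
#' @export
tda_summary <- function(diag, dim = 2) {
  stopifnot(all(c("dim", "birth", "death") %in% names(diag)))
  pers <- diag$death - diag$birth
  keep <- diag$dim == dim & is.finite(diag$death) & pers > 0
  if (!any(keep)) {
    return(list(n_voids = 0L, avg_persistence = 0, max_persistence = 0))
  }
  list(n_voids = sum(keep),
       avg_persistence = mean(pers[keep]),
       max_persistence = max(pers[keep]))
}

#' Subsample rows of a point cloud without replacement
#'
#' Persistence computation scales steeply with the number of points, so large
#' clouds (e.g. concatenated multi-scan time series) are thinned to `m`
#' uniformly chosen frames before the Rips filtration. Seed-deterministic and
#' isolated from the session RNG.
#'
#' @param cloud numeric matrix.
#' @param m number of rows to keep (`m <= nrow(cloud)`).
#' @param seed integer seed.
#' @return an `m x d` matrix.
#' @export
subsample_rows <- function(cloud, m, seed) {
  cloud <- as_cloud(cloud)
  n <- nrow(cloud)
  if (m > n) stop("cannot subsample more rows than the cloud has")
  idx <- with_private_seed(seed, sample.int(n, m))
  cloud[idx, , drop = FALSE]
}

#' Read and write persistence diagrams as TSV
#'
#' Columns `dim`, `birth`, `death`, with `inf` marking essential classes.
#'
#' @param diag persistence diagram data frame.
#' @param path file path.
#' @return `read_diagram_tsv()` returns the diagram; `write_diagram_tsv()`
#'   returns `path` invisibly.
#' @export
write_diagram_tsv <- function(diag, path) {
  out <- data.frame(dim = diag$dim, birth = diag$birth,
                    death = ifelse(is.finite(diag$death), diag$death, "inf"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram_tsv
#' @export
read_diagram_tsv <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "numeric", "character"))
  out <- data.frame(dim = raw$dim, birth = raw$birth,
                    death = ifelse(raw$death == "inf", Inf,
                                   suppressWarnings(as.numeric(raw$death))))
  class(out) <- c("persistence_diagram", "data.frame")
  out
}
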