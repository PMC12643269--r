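#' PCA rotation of a point cloud
#'
#' Mean-centers the cloud and rotates it onto the eigenvectors of its sample
#' covariance — a pure rotation/reflection, with no scaling or whitening, so
#' Euclidean pairwise distances are preserved and the information content is
#' only re-embedded, never rescaled. Columns are ordered by decreasing
#' eigenvalue. Separating information that survives this rotation
#' ("intrinsic") from information that does not ("contextual") is the point:
#' a straight line loses all of its redundancy after PCA, a sphere keeps all
#' of its synergy.
#'
#' Determinism: each principal axis is oriented so that its largest-magnitude
#' loading is positive; eigenvalue ties keep input-axis order (R's `eigen`
#' returns them in stable order).
#'
#' @param cloud numeric matrix, rows are observations (needs `n > d`).
#' @return a list of class `pca_result` with `rotated` (the centered, rotated
#'   cloud) and `explained_fractions` (nonnegative, non-increasing, summing
#'   to 1).
#' @examples
#' set.seed(1)
#' x <- runif(1000, -1, 1)
#' pca_rotate(cbind(x, x, x))$explained_fractions  # (1, 0, 0): rank-1 data
#' @export
pca_rotate <- function(cloud) {
  cloud <- as_cloud(cloud)
  n <- nrow(cloud)
  d <- ncol(cloud)
  if (n <= d) stop("need more observations than dimensions")
  centered <- sweep(cloud, 2, colMeans(cloud))
  cv <- crossprod(centered) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vec <- eg$vectors
  # orient each axis so its largest-magnitude loading is positive
  for (j in seq_len(d)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  val <- pmax(eg$values, 0)
  rotated <- centered %*% vec
  colnames(rotated) <- paste0("pc", seq_len(d))
  structure(
    list(rotated = rotated,
         explained_fractions = if (sum(val) > 0) val / sum(val) else
           rep(1 / d, d)),
    class = "pca_result"
  )
}

#' Fraction of variance on the first principal component
#'
#' For a completely unstructured (independent, equal-variance) d-dimensional
#' cloud this is about `1/d` (roughly 33% for triads); redundancy-dominated
#' clouds push it toward 1.
#'
#' @inheritParams pca_rotate
#' @return a fraction in `[0, 1]`.
#' @export
pc1_variance <- function(cloud) {
  pca_rotate(cloud)$explained_fractions[1]
}
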