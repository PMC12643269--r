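# Independent oracles used to validate the package implementations.
# These deliberately use the plainest possible algorithms (full boundary
# matrix, double loops, textbook formulas) and share no code with the
# package.

# Plain persistent-homology reduction: enumerate every simplex up to
# dimension maxdim + 1 under the threshold, order the full boundary matrix by
# (diameter, dimension, lexicographic vertex tuple) and reduce left to right.
naive_vr_diagram <- function(D, maxdim = 2, threshold = NULL) {
  n <- nrow(D)
  if (is.null(threshold)) threshold <- min(apply(D, 1, max))
  simps <- as.list(seq_len(n))
  diams <- rep(0, n)
  dims <- rep(0L, n)
  for (p in seq_len(maxdim + 1)) {
    if (n < p + 1) break
    cmb <- utils::combn(n, p + 1)
    for (cidx in seq_len(ncol(cmb))) {
      v <- cmb[, cidx]
      dm <- max(D[v, v])
      if (dm <= threshold) {
        simps[[length(simps) + 1]] <- v
        diams[length(simps)] <- dm
        dims[length(simps)] <- p
      }
    }
  }
  skey <- vapply(simps, function(v) paste(sprintf("%03d", v), collapse = ""),
                 character(1))
  ord <- order(diams, dims, skey)
  simps <- simps[ord]; diams <- diams[ord]; dims <- dims[ord]
  pos <- seq_along(simps)
  names(pos) <- skey[ord]

  N <- length(simps)
  owner <- integer(N)
  reduced <- vector("list", N)
  creator <- logical(N)
  for (j in seq_len(N)) {
    if (dims[j] == 0) { creator[j] <- TRUE; next }
    v <- simps[[j]]
    faces <- utils::combn(v, length(v) - 1)
    fk <- apply(faces, 2, function(f) paste(sprintf("%03d", f), collapse = ""))
    col <- sort(unname(pos[fk]))
    repeat {
      if (length(col) == 0) { creator[j] <- TRUE; break }
      l <- col[length(col)]
      if (owner[l] == 0L) { owner[l] <- j; reduced[[j]] <- col; break }
      o <- reduced[[owner[l]]]
      col <- sort(c(setdiff(col, o), setdiff(o, col)))
    }
  }
  rows <- vector("list", N)
  for (l in seq_len(N)) {
    if (owner[l] > 0L) {
      rows[[l]] <- c(dims[l], diams[l], diams[owner[l]])
    } else if (creator[l] && dims[l] <= maxdim) {
      rows[[l]] <- c(dims[l], diams[l], Inf)
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(dim = as.integer(m[, 1]), birth = m[, 2], death = m[, 3])
  out[order(out$dim, out$birth, out$death), , drop = FALSE]
}

# sorted (dim, birth, death) triples for multiset comparison of diagrams
diagram_key <- function(diag) {
  ord <- order(diag$dim, diag$birth, diag$death)
  data.frame(dim = as.integer(diag$dim[ord]), birth = diag$birth[ord],
             death = diag$death[ord])
}

brute_chebyshev <- function(cloud) {
  n <- nrow(cloud)
  D <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) D[a, b] <- max(abs(cloud[a, ] - cloud[b, ]))
  }
  D
}

brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

brute_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# random symmetric positive-definite covariance with unit-scale variances
random_pd_cov <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) + diag(d) * 0.5
  Dg <- diag(1 / sqrt(diag(S)))
  Dg %*% S %*% Dg
}

sample_gaussian <- function(n, covariance, seed) {
  set.seed(seed)
  matrix(rnorm(n * ncol(covariance)), n) %*% chol(covariance)
}
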