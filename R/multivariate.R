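# PCA over 59-dimensional RSCU vectors.  Covariance (not correlation) PCA
# on the raw values: RSCU is already family-normalized, so no further
# per-codon scaling is applied.  Axis signs are fixed by making each
# axis's largest-magnitude loading positive, so outputs are reproducible.

#' Principal component analysis of RSCU profiles
#'
#' @param profiles list of complete `cub_rscu` profiles (one per
#'   sequence/group), or a numeric matrix with 59 columns.
#' @param n_axes number of axes to retain in `coordinates`.
#' @return Object of class `cub_pca`: `coordinates` (n x n_axes),
#'   `loadings` (59 x n_axes), `explained_variance_pct` (all axes,
#'   non-increasing, summing to 100), `n_axes`.  Zero-variance input
#'   returns all-zero coordinates with a warning instead of erroring.
#' @export
pca_rscu <- function(profiles, n_axes = 2L) {
  X <- if (is.matrix(profiles)) profiles else
    do.call(rbind, lapply(profiles, function(p) {
      v <- unclass(p)
      if (anyNA(v)) stop("PCA requires profiles complete over the 59 codons")
      v
    }))
  if (nrow(X) < 2L) stop("PCA requires at least 2 profiles")
  if (is.null(rownames(X)))
    rownames(X) <- names(profiles) %||% as.character(seq_len(nrow(X)))
  n_axes <- min(n_axes, nrow(X) - 1L, ncol(X))
  cx <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(cx) < 1e-12)) {
    warning("PCA degenerate: zero total variance; returning zero coordinates")
    coords <- matrix(0, nrow(X), n_axes,
                     dimnames = list(rownames(X),
                                     paste0("axis", seq_len(n_axes))))
    return(structure(list(coordinates = coords,
                          loadings = matrix(0, ncol(X), n_axes),
                          explained_variance_pct = rep(NA_real_, n_axes),
                          n_axes = n_axes), class = "cub_pca"))
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention: largest |loading| per axis is positive
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  ev <- pr$sdev^2
  pct <- 100 * ev / sum(ev)
  keep <- seq_len(n_axes)
  coords <- pr$x[, keep, drop = FALSE]
  colnames(coords) <- paste0("axis", keep)
  structure(list(coordinates = coords,
                 loadings = pr$rotation[, keep, drop = FALSE],
                 explained_variance_pct = pct,
                 n_axes = n_axes), class = "cub_pca")
}

#' @export
print.cub_pca <- function(x, ...) {
  cat(sprintf("<cub_pca> %d profiles, %d axes retained\n",
              nrow(x$coordinates), x$n_axes))
  pct <- x$explained_variance_pct[seq_len(x$n_axes)]
  cat("Explained variance:",
      paste(sprintf("axis%d %.2f%%", seq_along(pct), pct), collapse = ", "),
      sprintf("(first %d axes: %.2f%%)\n", x$n_axes, sum(pct)))
  invisible(x)
}
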