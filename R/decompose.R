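#' Principal component analysis of a spectrum set
#'
#' SVD of the column-centered intensity matrix (numerically preferable to an
#' eigendecomposition of the p x p covariance when the axis is much longer
#' than the spectrum count). Sign convention: each loading's
#' largest-magnitude element is positive. Explained variances are the squared
#' singular values divided by n - 1, in non-increasing order.
#'
#' @param set a `raman_set` (standardize upstream)
#' @param k number of components, 1 <= k <= min(n, axis length)
#' @return list of class `raman_pca`: loadings (p x k), scores (n x k),
#'   explained_variance (k), center (p), labels
#' @export
pca_spectra <- function(set, k = 3L) {
  X <- set$intensities
  n <- nrow(X); p <- ncol(X)
  if (k < 1L || k > min(n, p))
    stop("k must lie in [1, min(n spectra, axis length)]", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = k, nv = k)
  V <- sv$v
  # sign convention: largest-|.| element of each loading is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- set$meta$spectrum_id
  structure(list(loadings = V, scores = scores,
                 explained_variance = sv$d[seq_len(k)]^2 / (n - 1L),
                 total_variance = sum(Xc^2) / (n - 1L),
                 center = ctr, axis = set$axis, labels = set$meta$label),
            class = "raman_pca")
}

#' Per-cluster covariance ellipsoids in the first three PC coordinates
#'
#' For each label: the mean and covariance of the first three score columns.
#' `scale = "1sd"` leaves semi-axes at the covariance eigenvalue square
#' roots; `"95pct"` multiplies them by sqrt of the 0.95 chi-square(3)
#' quantile (a 95% coverage region under normality).
#'
#' @param pca a `raman_pca` with k >= 3
#' @param labels label per score row (defaults to those stored in the pca);
#'   each used label needs >= 4 members
#' @param scale `"1sd"` or `"95pct"`
#' @param which_labels labels to draw (default tumor and normal)
#' @return list of `cluster_ellipsoid` objects: label, center (3), covariance
#'   (3 x 3), scale, semi_axes, axes (rotation matrix)
#' @export
cluster_ellipsoids <- function(pca, labels = pca$labels,
                               scale = c("1sd", "95pct"),
                               which_labels = c("tumor", "normal")) {
  scale <- match.arg(scale)
  if (ncol(pca$scores) < 3L)
    stop("ellipsoids need at least 3 components", call. = FALSE)
  mult <- if (scale == "95pct") sqrt(qchisq(0.95, df = 3L)) else 1
  out <- list()
  for (lb in which_labels) {
    idx <- which(labels == lb)
    if (length(idx) < 4L)
      stop("label ", lb, " has fewer than 4 members", call. = FALSE)
    S <- pca$scores[idx, 1:3, drop = FALSE]
    cv <- stats::cov(S)
    cv <- (cv + t(cv)) / 2          # enforce exact symmetry
    eg <- eigen(cv, symmetric = TRUE)
    out[[lb]] <- structure(list(label = lb, center = colMeans(S),
                                covariance = cv, scale = scale,
                                semi_axes = mult * sqrt(pmax(eg$values, 0)),
                                axes = eg$vectors),
                           class = "cluster_ellipsoid")
  }
  out
}
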