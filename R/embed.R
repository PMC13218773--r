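#' Learn a shared low-dimensional pose space from aligned crops
#'
#' Pools the flattened aligned crops of all sessions and fits a principal
#' component analysis; each recording is later projected onto the top
#' `n_components` components to give a compact pose time series for the
#' AR-HMM. Component signs are fixed (largest-magnitude loading positive)
#' so the fit is deterministic. If the pooled set exceeds `max_frames`,
#' a uniformly strided subsample is used to bound memory.
#'
#' @param crop_sets a list of `aligned_crops` objects (or of T x D
#'   matrices of already-flattened frames).
#' @param n_components number of components kept (default 10).
#' @param max_frames cap on frames used for the fit (default 2e5).
#' @param fill how missing pixels were treated upstream; crops from
#'   [crop_align_frames()] are already zero-filled, `"mean"` re-fills any
#'   NAs with the pixel mean instead.
#' @return a `pose_pca`: `mean` (length D), `components`
#'   (`n_components x D`, orthonormal rows), `explained_variance_ratio`
#'   (non-increasing), `total_variance`.
#' @export
fit_pose_pca <- function(crop_sets, n_components = 10L, max_frames = 2e5,
                         fill = c("zero", "mean")) {
  fill <- match.arg(fill)
  mats <- lapply(crop_sets, flatten_crops)
  X <- do.call(rbind, mats)
  if (anyNA(X)) {
    if (fill == "zero") X[is.na(X)] <- 0
    else for (j in which(colSums(is.na(X)) > 0)) {
      m <- mean(X[, j], na.rm = TRUE)
      X[is.na(X), j] <- if (is.finite(m)) m else 0
    }
  }
  if (nrow(X) < n_components)
    stopf("need at least %d frames to fit %d components", n_components, n_components)
  if (nrow(X) > max_frames) {
    keep <- unique(round(seq(1, nrow(X), length.out = max_frames)))
    X <- X[keep, , drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  comp <- t(pc$rotation)                       # n_components x D
  # fix signs: largest-|loading| entry of each component positive
  for (k in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[k, ]))
    if (comp[k, j] < 0) comp[k, ] <- -comp[k, ]
  }
  total_var <- sum(apply(X, 2, var))
  ratio <- pc$sdev[seq_len(nrow(comp))]^2 / max(total_var, .Machine$double.eps)
  structure(list(mean = pc$center, components = comp,
                 explained_variance_ratio = ratio, total_variance = total_var,
                 n_components = nrow(comp)),
            class = "pose_pca")
}

flatten_crops <- function(x) {
  if (inherits(x, "aligned_crops")) {
    d <- dim(x$crops)
    matrix(x$crops, d[1], d[2] * d[3])
  } else if (is.matrix(x)) x
  else stopf("crop sets must be aligned_crops objects or matrices")
}

#' @export
print.pose_pca <- function(x, ...) {
  cat(sprintf("<pose_pca> %d components over %d pixels; top-%d variance explained: %.1f%%\n",
              x$n_components, length(x$mean), x$n_components,
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project a session's crops into the learned pose space
#'
#' Scores are `(flattened crops - mean) %*% t(components)`.
#'
#' @param crops an `aligned_crops` object or a T x D matrix.
#' @param pca a fitted `pose_pca`.
#' @return a `pose_series`: `scores` (T x n_components), `frame_rate_hz`.
#' @export
project_poses <- function(crops, pca) {
  stopifnot(inherits(pca, "pose_pca"))
  X <- flatten_crops(crops)
  X[is.na(X)] <- 0
  if (ncol(X) != length(pca$mean))
    stopf("crop dimension %d does not match PCA dimension %d", ncol(X), length(pca$mean))
  scores <- sweep(X, 2, pca$mean) %*% t(pca$components)
  fr <- if (inherits(crops, "aligned_crops")) crops$frame_rate_hz else NA_real_
  structure(list(scores = unname(scores), frame_rate_hz = fr, pca = pca),
            class = "pose_series")
}

#' Reconstruct crops from pose scores (diagnostic)
#' @param scores T x k score matrix (k <= n_components); @param pca fitted
#'   `pose_pca`.
#' @return T x D matrix in pixel space.
#' @export
reconstruct_from_scores <- function(scores, pca) {
  k <- ncol(scores)
  sweep(scores %*% pca$components[seq_len(k), , drop = FALSE], 2, pca$mean, `+`)
}
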