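#' Clean a raw depth recording
#'
#' Crops frames to the recording's region of interest and replaces
#' out-of-range sentinel pixels with `NA`, which every downstream statistic
#' ignores. Values stay in mm distance-from-sensor.
#'
#' @param rec a `depth_recording`.
#' @return the recording with `frames` a numeric array (NAs for dropouts),
#'   cropped to the ROI, and `cleaned = TRUE`.
#' @export
prepare_frames <- function(rec) {
  stopifnot(inherits(rec, "depth_recording"))
  roi <- rec$roi
  if (is.null(roi) || roi["rmax"] < roi["rmin"] || roi["cmax"] < roi["cmin"])
    stopf("recording has an empty or missing ROI")
  fr <- rec$frames[, roi["rmin"]:roi["rmax"], roi["cmin"]:roi["cmax"], drop = FALSE]
  fr <- fr * 1.0
  fr[fr == rec$sentinel] <- NA_real_
  rec$frames <- fr
  rec$cleaned <- TRUE
  rec
}

# 3x3 spatial median filter ignoring NAs (edges use the in-bounds window)
median_filter_3x3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  stack <- array(NA_real_, c(H, W, 9L))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    rs <- pmin(pmax(seq_len(H) + dr, 1L), H)  # replicate borders
    cs <- pmin(pmax(seq_len(W) + dc, 1L), W)
    stack[, , k] <- img[rs, cs]
  }
  apply(stack, c(1, 2), median, na.rm = TRUE)
}

#' Estimate the static background of a recording
#'
#' Per-pixel median over frames sampled at a fixed interval through the
#' recording (frames 1, 1+interval, 1+2*interval, ...), each sampled frame
#' first passed through a 3x3 spatial median filter. Missing pixels are
#' ignored; a pixel missing in every sampled frame stays `NA` and is
#' flagged.
#'
#' @param rec a cleaned `depth_recording` (see [prepare_frames()]).
#' @param interval sampling stride in frames (default 500).
#' @return list of class `depth_background`: `depth_mm` (H x W),
#'   `n_samples_used`, `all_missing` (logical mask).
#' @export
compute_background <- function(rec, interval = 500L) {
  stopifnot(inherits(rec, "depth_recording"))
  Tn <- dim(rec$frames)[1]
  idx <- seq(1L, Tn, by = as.integer(interval))
  filt <- lapply(idx, function(t) median_filter_3x3(rec$frames[t, , ]))
  stack <- simplify2array(filt)                   # H x W x n
  if (length(idx) == 1L) {
    bg <- stack[, , 1L]
  } else {
    bg <- apply(stack, c(1, 2), median, na.rm = TRUE)
  }
  bg[is.nan(bg)] <- NA_real_
  all_missing <- is.na(bg)
  structure(list(depth_mm = bg, n_samples_used = length(idx),
                 all_missing = all_missing),
            class = "depth_background")
}

#' Track the mouse through a session by per-frame EM Gaussian fitting
#'
#' For each frame the height image (background minus frame, clipped at 0)
#' is modelled as a mixture of one 3D Gaussian over (row, col, height) —
#' the mouse — and a uniform clutter component over the arena volume (dust
#' and sensor speckle). EM alternates per-pixel responsibilities (E-step)
#' with weighted mean/covariance updates (M-step), warm-started from the
#' previous frame's fit; the first frame is initialized from the largest
#' connected component of pixels above `init_height_mm`. The body ellipse
#' is read off the spatial 2x2 covariance: semi-axes are
#' `scale_factor * sqrt(eigenvalues)` and the axis angle is the major
#' eigenvector's angle, reported in [-pi/2, pi/2). Mean height averages the
#' height image over pixels with spatial Mahalanobis distance at most
#' `mask_threshold`.
#'
#' @param rec cleaned `depth_recording`.
#' @param bg `depth_background` from [compute_background()].
#' @param params list overriding defaults: `mask_threshold` (2.0),
#'   `scale_factor` (2.0), `max_iter` (25), `tol` (1e-4 on the
#'   log-likelihood change), `init_height_mm` (10), `min_height_mm` (5,
#'   pixels below this are treated as floor and excluded from EM),
#'   `height_range_mm` (150, clutter support).
#' @return a `tracked_series`: per-frame data.frame (`center_r`, `center_c`
#'   subpixel 0-based px; `axis_angle`; `heading` — equal to the axis angle
#'   until flips are resolved; `major_mm`, `minor_mm`; `mean_height_mm`;
#'   `converged`), plus `speed_mm_s` (frame 0 speed defined 0) and
#'   `total_distance_mm`.
#' @export
em_track_session <- function(rec, bg, params = list()) {
  stopifnot(inherits(rec, "depth_recording"), inherits(bg, "depth_background"))
  p <- modifyList(list(mask_threshold = 2.0, scale_factor = 2.0,
                       max_iter = 25L, tol = 1e-4, init_height_mm = 10,
                       min_height_mm = 5, height_range_mm = 150), params)
  Tn <- dim(rec$frames)[1]
  H <- dim(rec$frames)[2]; W <- dim(rec$frames)[3]
  area <- H * W
  u_dens <- 1 / (area * p$height_range_mm)     # clutter density, px^2 mm units
  rows0 <- matrix(rep(0:(H - 1), W), H, W)     # 0-based pixel coordinates
  cols0 <- matrix(rep(0:(W - 1), each = H), H, W)
  fit <- NULL
  out <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    h <- bg$depth_mm - rec$frames[t, , ]
    h[h < 0] <- 0
    sel <- which(!is.na(h) & h > p$min_height_mm)
    if (length(sel) >= 6L) {
      X <- cbind(r = rows0[sel], c = cols0[sel], h = h[sel])
      if (is.null(fit)) {
        mask <- !is.na(h) & h > p$init_height_mm
        if (!any(mask))
          stopf("tracking failed at frame %d: no pixels above %g mm", t, p$init_height_mm)
        lab <- cpp_label_components(mask)
        big <- which.max(tabulate(lab[lab > 0]))
        cc <- which(lab == big)
        Xi <- cbind(rows0[cc], cols0[cc], h[cc])
        fit <- list(mu = colMeans(Xi),
                    Sigma = ensure_spd(stats::cov(Xi) + diag(1e-2, 3), 1e-2),
                    w = max(length(cc) / length(sel), 0.2))
      }
      new_fit <- em_fit_frame(X, fit, u_dens, p$max_iter, p$tol)
      if (!is.null(new_fit)) fit <- new_fit
      conv <- !is.null(new_fit) && new_fit$converged
    } else {
      conv <- FALSE   # near-total dropout: carry previous fit forward
      if (is.null(fit))
        stopf("tracking failed at frame %d: no pixels above %g mm", t, p$min_height_mm)
    }
    S2 <- fit$Sigma[1:2, 1:2]
    e <- eigen(S2, symmetric = TRUE)
    ang <- wrap_axis(atan2(e$vectors[1, 1], e$vectors[2, 1])) # (row, col) -> image angle
    axes_px <- p$scale_factor * sqrt(pmax(e$values, 1e-8))
    # mean height over pixels inside the ellipse (spatial Mahalanobis <= threshold)
    d2 <- mahalanobis(cbind(as.vector(rows0), as.vector(cols0)), fit$mu[1:2], S2)
    inside <- d2 <= p$mask_threshold^2 & !is.na(as.vector(h))
    mh <- if (any(inside)) mean(h[inside]) else NA_real_
    out[[t]] <- data.frame(center_r = fit$mu[1], center_c = fit$mu[2],
                           axis_angle = ang, heading = ang,
                           major_mm = axes_px[1] / rec$px_per_mm,
                           minor_mm = axes_px[2] / rec$px_per_mm,
                           mean_height_mm = mh, converged = conv)
  }
  frames <- do.call(rbind, out)
  new_tracked_series(frames, rec$frame_rate_hz, rec$px_per_mm)
}

# one frame's EM fit; returns NULL if the fit degenerates
em_fit_frame <- function(X, fit, u_dens, max_iter, tol) {
  n <- nrow(X)
  mu <- fit$mu; Sigma <- fit$Sigma; w <- min(max(fit$w, 1e-3), 1 - 1e-3)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    R <- chol(Sigma)
    z <- forwardsolve(t(R), t(X) - mu)
    logf <- -0.5 * colSums(z^2) - sum(log(diag(R))) - 1.5 * log(2 * pi)
    a <- w * exp(logf); b <- (1 - w) * u_dens
    resp <- a / (a + b)
    ll <- sum(log(a + b))
    sw <- sum(resp)
    if (!is.finite(ll) || sw < 3) return(NULL)
    mu_new <- colSums(X * resp) / sw
    Xc <- sweep(X, 2, mu_new)
    Sigma_new <- crossprod(Xc * sqrt(resp)) / sw
    Sigma <- ensure_spd(Sigma_new + diag(1e-3, 3), 1e-3)
    mu <- mu_new
    w <- min(max(sw / n, 1e-3), 1 - 1e-3)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, w = w, converged = converged)
}

new_tracked_series <- function(frames, frame_rate_hz, px_per_mm) {
  dr <- diff(frames$center_r); dc <- diff(frames$center_c)
  step_mm <- sqrt(dr^2 + dc^2) / px_per_mm
  speed <- c(0, step_mm * frame_rate_hz)
  structure(list(frames = frames, speed_mm_s = speed,
                 total_distance_mm = sum(step_mm),
                 frame_rate_hz = frame_rate_hz, px_per_mm = px_per_mm),
            class = "tracked_series")
}

#' Build a tracked series directly from center coordinates
#'
#' Convenience constructor used when positions are known without video
#' (e.g. planted trajectories): fills the speed/total-distance fields with
#' the same definitions as [em_track_session()].
#'
#' @param center_r,center_c per-frame subpixel centers (px).
#' @param frame_rate_hz,px_per_mm scales.
#' @param mean_height_mm optional per-frame height.
#' @export
tracked_series_from_centers <- function(center_r, center_c, frame_rate_hz = 30,
                                        px_per_mm = 1, mean_height_mm = NA_real_) {
  frames <- data.frame(center_r = center_r, center_c = center_c,
                       axis_angle = 0, heading = 0, major_mm = NA_real_,
                       minor_mm = NA_real_, mean_height_mm = mean_height_mm,
                       converged = TRUE)
  new_tracked_series(frames, frame_rate_hz, px_per_mm)
}

#' @export
print.tracked_series <- function(x, ...) {
  cat(sprintf("<tracked_series> %d frames, %.1f%% converged, total distance %.2f m\n",
              nrow(x$frames), 100 * mean(x$frames$converged),
              x$total_distance_mm / 1000))
  invisible(x)
}

#' Extract mouse-centered, axis-aligned crops
#'
#' Rotates each frame's height image by minus the tracked axis angle about
#' the body center and samples an `size x size` window (bilinear
#' interpolation) so the spinal axis lies horizontally. Missing pixels and
#' out-of-frame samples contribute height 0; frames whose window leaves the
#' frame are flagged.
#'
#' @param rec cleaned `depth_recording`; @param bg background;
#' @param tracked `tracked_series`; @param size crop side (80).
#' @param min_converged minimum fraction of converged frames required
#'   (default 0.9).
#' @return `aligned_crops`: list with `crops` (T x size x size, mm height,
#'   `>= 0`), `flip_decisions` (logical, NA until flips resolved),
#'   `edge_flagged`, plus the tracked series reference.
#' @export
crop_align_frames <- function(rec, bg, tracked, size = 80L,
                              min_converged = 0.9) {
  stopifnot(inherits(rec, "depth_recording"), inherits(tracked, "tracked_series"))
  fr_ok <- mean(tracked$frames$converged)
  if (fr_ok < min_converged)
    stopf("only %.1f%% of frames converged (< %.0f%%)", 100 * fr_ok, 100 * min_converged)
  Tn <- dim(rec$frames)[1]
  H <- dim(rec$frames)[2]; W <- dim(rec$frames)[3]
  offs <- seq_len(size) - (size + 1) / 2        # symmetric around the center
  a <- rep(offs, each = size)                   # along-axis (crop columns)
  b <- rep(offs, times = size)                  # across-axis (crop rows)
  crops <- array(0, c(Tn, size, size))
  edge <- logical(Tn)
  for (t in seq_len(Tn)) {
    h <- bg$depth_mm - rec$frames[t, , ]
    h[h < 0 | is.na(h)] <- 0
    th <- tracked$frames$axis_angle[t]
    sc <- tracked$frames$center_c[t] + a * cos(th) - b * sin(th)
    sr <- tracked$frames$center_r[t] + a * sin(th) + b * cos(th)
    edge[t] <- any(sr < 0 | sr > H - 1 | sc < 0 | sc > W - 1)
    crops[t, , ] <- bilinear_sample(h, sr, sc, size)
  }
  structure(list(crops = crops, flip_decisions = rep(NA, Tn),
                 edge_flagged = edge, tracked = tracked,
                 frame_rate_hz = rec$frame_rate_hz),
            class = "aligned_crops")
}

# bilinear gather from img (0-based coords); out-of-range -> 0
bilinear_sample <- function(img, sr, sc, size) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- numeric(length(sr))
  for (k in 1:4) {
    rr <- r0 + (k - 1) %% 2
    cc <- c0 + (k - 1) %/% 2
    wt <- (if ((k - 1) %% 2 == 0) 1 - fr else fr) *
      (if ((k - 1) %/% 2 == 0) 1 - fc else fc)
    ok <- rr >= 0 & rr < H & cc >= 0 & cc < W
    v <- numeric(length(sr))
    v[ok] <- img[cbind(rr[ok] + 1L, cc[ok] + 1L)]
    val <- val + wt * v
  }
  matrix(val, size, size)   # rows = across-axis, cols = along-axis
}

#' Resolve head/tail orientation of aligned crops
#'
#' The ellipse axis angle is only defined up to 180 degrees; this step
#' decides, per frame, whether the nose faces left or right and mirrors
#' left-facing crops so the mouse always faces right. A small classifier is
#' trained on the session's own crops plus their mirror images (features:
#' block-mean downsampled pixels; initial orientation labels from the sign
#' of the along-axis third moment, i.e. the nose-ward mass asymmetry).
#' Per-frame discriminant scores are median-filtered over a 7-frame window
#' before thresholding. If the two orientations are statistically
#' indistinguishable (symmetric animal), a temporal-consistency heuristic
#' is used instead: each frame keeps the orientation closer to the previous
#' resolved frame.
#'
#' @param crops `aligned_crops`.
#' @param method `"lda"` (regularized Fisher discriminant, default),
#'   `"rf"` (random forest, needs the randomForest package), or
#'   `"heuristic"` (temporal consistency only).
#' @param downsample feature grid side (8: 64 features).
#' @param median_window temporal median window on scores (7 frames).
#' @param seed RNG seed (classifier training subsampling).
#' @return the crops with left-facing frames mirrored, `flip_decisions`
#'   filled, and headings in the embedded tracked series updated to
#'   (-pi, pi].
#' @export
detect_and_fix_flips <- function(crops, method = c("lda", "rf", "heuristic"),
                                 downsample = 8L, median_window = 7L,
                                 seed = 1L) {
  stopifnot(inherits(crops, "aligned_crops"))
  method <- match.arg(method)
  Tn <- dim(crops$crops)[1]
  size <- dim(crops$crops)[2]
  # light spatial smoothing for the features only (decisions apply to the
  # raw crops)
  Ksm <- gauss_band_matrix(size, 2.5)
  smcr <- array(0, dim(crops$crops))
  for (t in seq_len(Tn)) smcr[t, , ] <- Ksm %*% crops$crops[t, , ] %*% t(Ksm)
  feat <- t(apply(smcr, 1, block_mean_features, grid = downsample))
  mfeat <- t(apply(smcr, 1, function(m) block_mean_features(m[, rev(seq_len(size))], downsample)))
  # along-axis third central moment: the head/shoulder bulk sits nose-ward
  # while the rear tapers into a longer tail, so a right-facing animal has
  # NEGATIVE skewness along +x
  skew <- apply(smcr, 1, function(m) {
    w <- pmax(m, 0); tot <- sum(w)
    if (tot == 0) return(0)
    cx <- sum(colSums(w) * seq_len(size)) / tot
    sum(colSums(w) * (seq_len(size) - cx)^3) / tot
  })
  flip <- rep(FALSE, Tn)
  degenerate <- FALSE
  if (method != "heuristic") {
    # unsupervised seeding: the mirror-difference features d = f - mirror(f)
    # are antisymmetric in orientation (+mu for right-facing, -mu for left),
    # so the leading principal component of d recovers the discriminating
    # axis without labels; the global sign follows the skewness convention
    d <- feat - mfeat
    sv <- svd(d, nu = 0, nv = 1)
    sc <- as.vector(d %*% sv$v[, 1])
    # true orientation persists across frames, so real scores have strong
    # uncentered lag-1 autocorrelation (also when one orientation dominates);
    # scores driven by sensor noise do not
    lag1 <- if (Tn >= 20) sum(sc[-1] * sc[-Tn]) / sum(sc^2) else 1
    degenerate <- !is.finite(lag1) || lag1 < 0.15
    sgn <- sign(sum(sign(-skew) * sign(sc)))
    if (sgn == 0) sgn <- 1
    sc <- sc * sgn
    wide <- min(2L * median_window + 1L, Tn - (1L - Tn %% 2L))
    labels <- if (wide >= 3) runmed(sc, wide, endrule = "median") > 0 else sc > 0
    # supervised refinement on the seeded labels (mirror-augmented so the
    # classes stay balanced and the classifier antisymmetric)
    for (round in if (degenerate) integer(0) else 1:2) {
      Xtr <- rbind(feat, mfeat)
      ytr <- c(labels, !labels)
      if (length(unique(ytr)) < 2) break
      if (method == "lda" || !requireNamespace("randomForest", quietly = TRUE)) {
        mR <- colMeans(Xtr[ytr, , drop = FALSE])
        mL <- colMeans(Xtr[!ytr, , drop = FALSE])
        Sw <- stats::cov(Xtr[ytr, , drop = FALSE]) + stats::cov(Xtr[!ytr, , drop = FALSE])
        wv <- solve(Sw + diag(1e-6 * (sum(diag(Sw)) / ncol(Sw) + 1), ncol(Sw)), mR - mL)
        scores <- as.vector(feat %*% wv) - as.numeric((mR + mL) %*% wv / 2)
        sep <- abs(sum((mR - mL) * wv)) /
          sqrt(as.numeric(t(wv) %*% Sw %*% wv) / 2 + 1e-12)
        degenerate <- !is.finite(sep) || sep < 0.5
      } else {
        idx <- with_seed(seed + round, sample.int(2 * Tn, min(2 * Tn, 2000L)))
        rf <- with_seed(seed + round, randomForest::randomForest(
          Xtr[idx, , drop = FALSE], factor(ytr[idx], levels = c(FALSE, TRUE)),
          ntree = 50))
        scores <- predict(rf, feat, type = "prob")[, "TRUE"] - 0.5
        degenerate <- sd(scores) < 0.05
      }
      if (degenerate) break
      if (median_window > 1 && Tn > median_window)
        scores <- runmed(scores, median_window, endrule = "median")
      labels <- scores > 0
    }
    if (!degenerate) flip <- !labels
  }
  if (method == "heuristic" || degenerate) {
    # orientation ambiguous: keep whichever orientation best matches the
    # previous resolved frame (temporally consistent, globally arbitrary);
    # a small hysteresis margin prevents chatter when both match equally
    flip <- rep(FALSE, Tn)
    prev <- crops$crops[1, , ]
    for (t in 2:Tn) {
      cur <- crops$crops[t, , ]
      mir <- cur[, rev(seq_len(size))]
      d_keep <- sum(abs(cur - prev)); d_mir <- sum(abs(mir - prev))
      margin <- (d_keep - d_mir) / (d_keep + d_mir + 1e-12)
      flip[t] <- if (abs(margin) > 0.05) margin > 0 else flip[t - 1]
      prev <- if (flip[t]) mir else cur
    }
  }
  for (t in which(flip)) crops$crops[t, , ] <- crops$crops[t, , rev(seq_len(size))]
  crops$flip_decisions <- flip
  if (!is.null(crops$tracked)) {
    ax <- crops$tracked$frames$axis_angle
    crops$tracked$frames$heading <- wrap_angle(ifelse(flip, ax + pi, ax))
  }
  crops
}

block_mean_features <- function(m, grid = 8L) {
  size <- nrow(m)
  cut <- as.integer(floor((seq_len(size) - 1) * grid / size))
  rowsum_m <- rowsum(m, cut)               # sum rows into grid bands
  out <- t(rowsum(t(rowsum_m), cut))
  as.vector(out) * (grid / size)^2
}

#' Denoise aligned crops
#'
#' Spatial 2D Gaussian smoothing (default SDs 3.25 px along the body axis,
#' 2.0 px across it) followed by a per-pixel temporal median filter
#' (default 5 frames, i.e. 167 ms at 30 Hz; edge frames use shrunken
#' windows).
#'
#' @param crops `aligned_crops` (flip-resolved).
#' @param sigma_col,sigma_row spatial Gaussian SDs in px (columns = along
#'   the body axis).
#' @param t_window temporal median window (odd).
#' @export
smooth_crops <- function(crops, sigma_col = 3.25, sigma_row = 2.0,
                         t_window = 5L) {
  stopifnot(inherits(crops, "aligned_crops"))
  Tn <- dim(crops$crops)[1]; size <- dim(crops$crops)[2]
  Kr <- gauss_band_matrix(size, sigma_row)
  Kc <- gauss_band_matrix(size, sigma_col)
  for (t in seq_len(Tn))
    crops$crops[t, , ] <- Kr %*% crops$crops[t, , ] %*% t(Kc)
  if (t_window > 1 && Tn >= t_window) {
    flat <- matrix(crops$crops, Tn, size * size)
    flat <- apply(flat, 2, runmed, k = t_window, endrule = "median")
    crops$crops <- array(flat, c(Tn, size, size))
  }
  crops
}

# row-normalized truncated-Gaussian convolution matrix (edges renormalized)
gauss_band_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-0.5 * (d / sigma)^2)
  K[abs(d) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

#' Per-session kinematics summary
#'
#' Per-frame speed (mm/s) and mean height (mm) plus session totals —
#' distance travelled (m) and session-averaged speed (mm/s) — restricted to
#' the first `session_minutes` of recording. Sessions shorter than the
#' requested window are summarized over the frames available and flagged.
#'
#' @param tracked `tracked_series`.
#' @param session_minutes analysis window (default 30).
#' @return list of class `kinematics`: `per_frame` data.frame,
#'   `total_distance_m`, `avg_speed_mm_s`, `n_frames_used`, `truncated`.
#' @export
compute_kinematics <- function(tracked, session_minutes = 30) {
  stopifnot(inherits(tracked, "tracked_series"))
  Tn <- nrow(tracked$frames)
  want <- as.integer(round(session_minutes * 60 * tracked$frame_rate_hz))
  n <- min(Tn, want)
  truncated <- n < want
  if (truncated) warnf("session has %d frames; window of %d requested", Tn, want)
  sp <- tracked$speed_mm_s[seq_len(n)]
  per_frame <- data.frame(frame = seq_len(n), speed_mm_s = sp,
                          height_mm = tracked$frames$mean_height_mm[seq_len(n)])
  dist_mm <- sum(sp[-1]) / tracked$frame_rate_hz
  structure(list(per_frame = per_frame,
                 total_distance_m = dist_mm / 1000,
                 avg_speed_mm_s = mean(sp),
                 n_frames_used = n, truncated = truncated),
            class = "kinematics")
}
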