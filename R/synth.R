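#' Ground-truth generative model for synthetic behavior
#'
#' Defines the switching autoregressive (AR) process that generates
#' synthetic syllable sequences and pose dynamics: a Markov chain over
#' `n_states` discrete syllables, each with its own vector-AR dynamics in
#' pose space. This is the generative counterpart of the AR-HMM that the
#' segmentation stage fits, so every downstream operation can be tested
#' against known truth.
#'
#' @param n_states number of true syllables (>= 1).
#' @param transition `n_states x n_states` row-stochastic matrix of
#'   between-syllable transition probabilities. Default: uniform over the
#'   other states (no self mass; persistence comes from `duration_bias`).
#' @param ar_params per-state AR parameters: a list of length `n_states`,
#'   each element a list with `A` (a `dim x dim x L` array of lag
#'   coefficient matrices), `b` (length-`dim` bias) and `Sigma`
#'   (`dim x dim` positive-definite noise covariance). Default: stable
#'   random dynamics from [default_ar_params()].
#' @param duration_bias extra self-transition weight `>= 0` folded into the
#'   chain, controlling mean syllable duration. The effective transition
#'   matrix is `(transition + duration_bias * I)` row-renormalized.
#' @param dim pose-space dimension (default 10, matching the number of
#'   principal components used downstream).
#' @param kinematics per-state locomotion parameters used when rendering
#'   depth video: a data.frame with columns `speed_mm_s`, `turn_sd_rad` and
#'   `height_mm` (one row per state). Default: a spread of slow-to-fast
#'   states in the regime of real open-field mice.
#' @param seed integer seed stored with the spec; all generators derive
#'   their randomness from it.
#'
#' @return an object of class `ground_truth_spec`.
#' @seealso [gen_markov_labels()], [gen_ar_pose_series()], [make_cohort()]
#' @export
ground_truth_spec <- function(n_states, transition = NULL, ar_params = NULL,
                              duration_bias = 10, dim = 10,
                              kinematics = NULL, seed = 1L) {
  if (!is_count(n_states)) stopf("n_states must be a positive integer")
  if (is.null(transition)) {
    if (n_states == 1L) {
      transition <- matrix(1, 1, 1)
    } else {
      transition <- matrix(1 / (n_states - 1), n_states, n_states)
      diag(transition) <- 0
    }
  }
  assert_row_stochastic(transition)
  if (nrow(transition) != n_states) stopf("transition must be %d x %d", n_states, n_states)
  if (duration_bias < 0) stopf("duration_bias must be >= 0")
  if (is.null(ar_params)) ar_params <- default_ar_params(n_states, dim, seed = seed)
  for (p in ar_params) {
    if (!all(dim(p$A)[1:2] == dim)) stopf("ar_params A must be %d x %d x L", dim, dim)
    p$Sigma <- ensure_spd(p$Sigma)
  }
  if (is.null(kinematics)) {
    sp <- seq(10, 120, length.out = n_states)
    kinematics <- data.frame(speed_mm_s = sp,
                             turn_sd_rad = seq(0.25, 0.05, length.out = n_states),
                             height_mm = seq(55, 30, length.out = n_states))
  }
  structure(list(n_states = as.integer(n_states), transition = transition,
                 ar_params = ar_params, duration_bias = duration_bias,
                 dim = as.integer(dim), kinematics = kinematics,
                 seed = as.integer(seed)),
            class = "ground_truth_spec")
}

#' Stable random per-state AR parameters
#'
#' Each state gets a contraction `A = rho * R` (R a random rotation-like
#' orthogonal matrix, `rho < 1` so the dynamics are stable), a distinct bias
#' vector (states sit at separated fixed points in pose space) and
#' isotropic noise.
#'
#' @param n_states,dim sizes; `L` AR lag order; `rho` spectral radius;
#'   `bias_scale` separation of the per-state fixed points;
#'   `noise_sd` innovation standard deviation; `seed` RNG seed.
#' @return list of per-state `list(A, b, Sigma)`.
#' @export
default_ar_params <- function(n_states, dim = 10, L = 1, rho = 0.7,
                              bias_scale = 4, noise_sd = 0.5, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_states), function(k) {
      A <- array(0, c(dim, dim, L))
      Q <- qr.Q(qr(matrix(rnorm(dim * dim), dim)))
      A[, , 1] <- rho * Q
      if (L > 1) for (l in 2:L) A[, , l] <- matrix(0, dim, dim)
      b <- rnorm(dim, sd = bias_scale)
      list(A = A, b = b, Sigma = diag(noise_sd^2, dim))
    })
  })
}

# effective chain after folding duration_bias into self-transitions
effective_transition <- function(spec) {
  P <- spec$transition + diag(spec$duration_bias, spec$n_states)
  P / rowSums(P)
}

#' Sample a syllable label sequence from the ground-truth chain
#'
#' Draws a Markov chain of length `T` from the spec's transition matrix with
#' `duration_bias` folded into the self-transitions. Labels are 1-based
#' state ids.
#'
#' @param spec a [ground_truth_spec()].
#' @param T number of frames (>= 1).
#' @param seed RNG seed (default: the spec's seed).
#' @param init initial distribution (default: stationary of the effective
#'   chain, computed from its leading left eigenvector).
#' @return integer vector of length `T` with values in `1..n_states`.
#' @export
gen_markov_labels <- function(spec, T, seed = spec$seed, init = NULL) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (!is_count(T)) stopf("T must be a positive integer")
  P <- effective_transition(spec)
  assert_row_stochastic(P)
  if (is.null(init)) init <- stationary_distribution(P)
  z <- with_seed(seed, cpp_sample_markov(as.integer(T), P, init))
  as.integer(z) + 1L
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v <- abs(v)
  v / sum(v)
}

#' Generate pose dynamics from a syllable sequence
#'
#' Simulates `x_t = sum_l A[z_t, l] x_{t-l} + b[z_t] + eps_t` with per-state
#' Gaussian innovations. The first `L` frames are seeded from the current
#' state's bias plus innovation noise. AR coefficient sets whose companion
#' matrix has spectral radius >= 1 produce a warning (trajectories may
#' diverge) but are simulated as requested.
#'
#' @param labels integer state sequence from [gen_markov_labels()].
#' @param spec the [ground_truth_spec()] holding the AR parameters.
#' @param dim observation dimension; must match the spec's `dim`.
#' @param seed RNG seed (default: the spec's seed).
#' @return numeric `T x dim` matrix of pose observations.
#' @export
gen_ar_pose_series <- function(labels, spec, dim = spec$dim, seed = spec$seed) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > spec$n_states))
    stopf("labels out of range for spec with %d states", spec$n_states)
  if (dim != spec$dim) stopf("dim (%d) does not match spec dim (%d)", dim, spec$dim)
  L <- dim(spec$ar_params[[1]]$A)[3]
  for (k in seq_len(spec$n_states)) {
    if (ar_spectral_radius(spec$ar_params[[k]]$A) >= 1)
      warnf("state %d has unstable AR coefficients (spectral radius >= 1)", k)
  }
  Tn <- length(labels)
  chol_list <- lapply(spec$ar_params, function(p) {
    if (all(p$Sigma == 0)) matrix(0, dim, dim) else chol(ensure_spd(p$Sigma))
  })
  with_seed(seed, {
    X <- matrix(0, Tn, dim)
    eps <- matrix(rnorm(Tn * dim), Tn, dim)
    for (t in seq_len(Tn)) {
      k <- labels[t]
      p <- spec$ar_params[[k]]
      e <- as.numeric(eps[t, ] %*% chol_list[[k]])
      if (t <= L) {
        X[t, ] <- p$b + e
      } else {
        m <- p$b
        for (l in seq_len(L)) m <- m + as.numeric(p$A[, , l] %*% X[t - l, ])
        X[t, ] <- m + e
      }
    }
    X
  })
}

# spectral radius of the AR companion matrix
ar_spectral_radius <- function(A) {
  d <- dim(A)[1]; L <- dim(A)[3]
  C <- matrix(0, d * L, d * L)
  for (l in seq_len(L)) C[1:d, ((l - 1) * d + 1):(l * d)] <- A[, , l]
  if (L > 1) C[(d + 1):(d * L), 1:(d * (L - 1))] <- diag(d * (L - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Depth-camera and arena geometry for the synthetic renderer
#'
#' Defaults follow a square open-field arena, 30 x 30 cm, viewed from a
#' depth sensor mounted 52 cm above the floor, recording 640 x 480 px
#' frames at 30 Hz with pixel values in mm distance-from-sensor.
#'
#' @param arena_side_mm arena side length (mm).
#' @param camera_height_mm sensor height above the arena floor (mm); this is
#'   the floor's depth value.
#' @param frame_shape `c(rows, cols)` of a frame.
#' @param frame_rate_hz acquisition rate.
#' @param px_per_mm spatial scale; the arena must fit inside the frame.
#' @param noise_sd_mm per-pixel Gaussian sensor noise SD (mm).
#' @param invalid_pixel_rate fraction of pixels replaced by the out-of-range
#'   sentinel in each frame.
#' @param sentinel out-of-range pixel value (sensor dropout convention: 0).
#' @param reflection_on if TRUE the renderer adds a mirrored ghost blob
#'   along one wall when the mouse is near it, emulating wall reflections.
#' @return an object of class `arena_spec`.
#' @export
arena_spec <- function(arena_side_mm = 300, camera_height_mm = 520,
                       frame_shape = c(480L, 640L), frame_rate_hz = 30,
                       px_per_mm = 1.4, noise_sd_mm = 2,
                       invalid_pixel_rate = 0.01, sentinel = 0L,
                       reflection_on = FALSE) {
  stopifnot(all(frame_shape > 0), frame_rate_hz > 0, px_per_mm > 0,
            noise_sd_mm >= 0, invalid_pixel_rate >= 0, invalid_pixel_rate <= 1)
  if (arena_side_mm * px_per_mm > min(frame_shape))
    stopf("arena (%.0f mm at %.2f px/mm) does not fit in a %d x %d frame",
          arena_side_mm, px_per_mm, frame_shape[1], frame_shape[2])
  structure(list(arena_side_mm = arena_side_mm,
                 camera_height_mm = camera_height_mm,
                 frame_shape = as.integer(frame_shape),
                 frame_rate_hz = frame_rate_hz, px_per_mm = px_per_mm,
                 noise_sd_mm = noise_sd_mm,
                 invalid_pixel_rate = invalid_pixel_rate,
                 sentinel = as.integer(sentinel),
                 reflection_on = isTRUE(reflection_on)),
            class = "arena_spec")
}

#' Turn a syllable sequence into a mouse trajectory
#'
#' Maps each syllable to locomotion statistics (per-state speed, turning
#' variability, rearing height from the spec's `kinematics` table) and
#' integrates a heading/position trajectory inside the arena, reflecting
#' off the walls. Body shape (length, width) is constant within a session.
#'
#' @param labels syllable sequence (1-based).
#' @param spec [ground_truth_spec()] providing per-state kinematics.
#' @param arena [arena_spec()].
#' @param body_length_mm,body_width_mm body ellipse axes (mm).
#' @param seed RNG seed.
#' @return data.frame of per-frame poses: `x_mm`, `y_mm` (arena coordinates,
#'   origin at the arena's top-left corner), `heading_rad` in (-pi, pi],
#'   `body_length_mm`, `body_width_mm`, `peak_height_mm`, `state`.
#' @export
gen_pose_trajectory <- function(labels, spec, arena = arena_spec(),
                                body_length_mm = 70, body_width_mm = 28,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "ground_truth_spec"), inherits(arena, "arena_spec"))
  Tn <- length(labels)
  kin <- spec$kinematics
  margin <- body_length_mm / 2 + 5
  lo <- margin; hi <- arena$arena_side_mm - margin
  dt <- 1 / arena$frame_rate_hz
  with_seed(seed, {
    x <- numeric(Tn); y <- numeric(Tn); h <- numeric(Tn)
    x[1] <- runif(1, lo, hi); y[1] <- runif(1, lo, hi)
    h[1] <- runif(1, -pi, pi)
    turn <- rnorm(Tn)
    for (t in 2:Tn) {
      k <- labels[t]
      h[t] <- wrap_angle(h[t - 1] + turn[t] * kin$turn_sd_rad[k])
      step <- kin$speed_mm_s[k] * dt
      nx <- x[t - 1] + step * cos(h[t])
      ny <- y[t - 1] + step * sin(h[t])
      if (nx < lo || nx > hi) { h[t] <- wrap_angle(pi - h[t]); nx <- min(max(nx, lo), hi) }
      if (ny < lo || ny > hi) { h[t] <- wrap_angle(-h[t]); ny <- min(max(ny, lo), hi) }
      x[t] <- nx; y[t] <- ny
    }
    data.frame(x_mm = x, y_mm = y, heading_rad = h,
               body_length_mm = body_length_mm, body_width_mm = body_width_mm,
               peak_height_mm = kin$height_mm[labels], state = labels)
  })
}

#' Render a depth-video session from a pose trajectory
#'
#' Each frame is the arena floor at `camera_height_mm` minus an anisotropic
#' Gaussian height bump centered and oriented by the pose (length along the
#' heading, width across it), with a small nose-ward height asymmetry so
#' that head/tail orientation is recoverable, plus Gaussian sensor noise.
#' A random fraction `invalid_pixel_rate` of pixels per frame is set to the
#' out-of-range sentinel. Values are rounded to integer mm and stored as
#' 16-bit-range integers.
#'
#' Poses outside the arena are clipped to the walls with a warning.
#'
#' @param poses pose data.frame from [gen_pose_trajectory()].
#' @param arena [arena_spec()].
#' @param nose_asym relative strength of the nose-ward height asymmetry
#'   (0 = perfectly symmetric blob).
#' @param seed RNG seed for sensor noise and dropout.
#' @return a `depth_recording`: list with `frames` (T x H x W integer
#'   array, mm distance-from-sensor), `frame_rate_hz`, `px_per_mm`, `roi`,
#'   `sentinel`, `arena` and `truth` (the input poses).
#' @export
render_depth_session <- function(poses, arena = arena_spec(),
                                 nose_asym = 0.15, seed = 1L) {
  stopifnot(inherits(arena, "arena_spec"))
  Tn <- nrow(poses)
  H <- arena$frame_shape[1]; W <- arena$frame_shape[2]
  s <- arena$px_per_mm
  side_px <- arena$arena_side_mm * s
  # arena centered in the frame; (row, col) origin top-left, 0-based pixels
  r0 <- (H - side_px) / 2; c0 <- (W - side_px) / 2
  out_of <- poses$x_mm < 0 | poses$x_mm > arena$arena_side_mm |
    poses$y_mm < 0 | poses$y_mm > arena$arena_side_mm
  if (any(out_of)) {
    warnf("%d poses outside the arena were clipped to the walls", sum(out_of))
    poses$x_mm <- pmin(pmax(poses$x_mm, 0), arena$arena_side_mm)
    poses$y_mm <- pmin(pmax(poses$y_mm, 0), arena$arena_side_mm)
  }
  frames <- array(as.integer(round(arena$camera_height_mm)), c(Tn, H, W))
  with_seed(seed, {
    for (t in seq_len(Tn)) {
      # pose center in pixel coordinates (col along x, row along y)
      pc <- c0 + poses$x_mm[t] * s
      pr <- r0 + poses$y_mm[t] * s
      len_px <- poses$body_length_mm[t] * s
      wid_px <- poses$body_width_mm[t] * s
      ext <- ceiling(2.5 * len_px / 2)
      rr <- max(0, floor(pr - ext)):min(H - 1, ceiling(pr + ext))
      cc <- max(0, floor(pc - ext)):min(W - 1, ceiling(pc + ext))
      dr <- rep(rr - pr, times = length(cc))
      dc <- rep(cc - pc, each = length(rr))
      th <- poses$heading_rad[t]
      u <- dc * cos(th) + dr * sin(th)      # along-heading (nose = +u)
      v <- -dc * sin(th) + dr * cos(th)     # across
      sig_u <- len_px / 4; sig_v <- wid_px / 4
      q <- (u / sig_u)^2 + (v / sig_v)^2
      bump <- poses$peak_height_mm[t] * exp(-q / 2) *
        (1 + nose_asym * tanh(u / sig_u))
      blk <- frames[t, rr + 1L, cc + 1L] - matrix(bump, length(rr), length(cc))
      frames[t, rr + 1L, cc + 1L] <- blk
      if (arena$reflection_on && poses$x_mm[t] > arena$arena_side_mm - 60) {
        # faint isotropic ghost mirrored across the near wall
        mc <- c0 + (2 * arena$arena_side_mm - poses$x_mm[t]) * s
        gc <- max(0, floor(mc - ext)):min(W - 1, ceiling(mc + ext))
        if (length(gc) > 1) {
          ghost <- 0.2 * poses$peak_height_mm[t] *
            exp(-outer(((rr - pr) / sig_u)^2, ((gc - mc) / sig_u)^2, `+`) / 2)
          frames[t, rr + 1L, gc + 1L] <- frames[t, rr + 1L, gc + 1L] - ghost
        }
      }
      fr <- frames[t, , ]
      if (arena$noise_sd_mm > 0)
        fr <- fr + rnorm(H * W, sd = arena$noise_sd_mm)
      fr <- round(pmin(pmax(fr, 1), 65535))
      if (arena$invalid_pixel_rate > 0) {
        drop <- runif(H * W) < arena$invalid_pixel_rate
        fr[drop] <- arena$sentinel
      }
      frames[t, , ] <- as.integer(fr)
    }
  })
  structure(list(frames = frames, frame_rate_hz = arena$frame_rate_hz,
                 px_per_mm = arena$px_per_mm,
                 roi = c(rmin = 1L, rmax = H, cmin = 1L, cmax = W),
                 sentinel = arena$sentinel, arena = arena, truth = poses),
            class = "depth_recording")
}

#' Render an empty-arena recording (no mouse)
#'
#' Floor depth plus sensor noise and dropout only; useful for background
#' estimation and for validating the preprocessing chain.
#'
#' @param arena [arena_spec()]; @param n_frames frames to render;
#' @param seed RNG seed.
#' @return a `depth_recording` with `truth = NULL`.
#' @export
render_empty_session <- function(arena = arena_spec(), n_frames = 10L, seed = 1L) {
  H <- arena$frame_shape[1]; W <- arena$frame_shape[2]
  frames <- array(0L, c(n_frames, H, W))
  with_seed(seed, {
    for (t in seq_len(n_frames)) {
      fr <- matrix(arena$camera_height_mm, H, W)
      if (arena$noise_sd_mm > 0) fr <- fr + rnorm(H * W, sd = arena$noise_sd_mm)
      fr <- round(pmin(pmax(fr, 1), 65535))
      if (arena$invalid_pixel_rate > 0)
        fr[runif(H * W) < arena$invalid_pixel_rate] <- arena$sentinel
      frames[t, , ] <- as.integer(fr)
    }
  })
  structure(list(frames = frames, frame_rate_hz = arena$frame_rate_hz,
                 px_per_mm = arena$px_per_mm,
                 roi = c(rmin = 1L, rmax = H, cmin = 1L, cmax = W),
                 sentinel = arena$sentinel, arena = arena, truth = NULL),
            class = "depth_recording")
}

#' @export
print.depth_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<depth_recording> %d frames, %d x %d px, %.0f Hz, %.2f px/mm\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$px_per_mm))
  invisible(x)
}

#' Cohort design for synthetic experiments
#'
#' Describes a set of experimental cells (genotype x sex x treatment) with
#' per-cell session counts and optional per-cell ground-truth overrides
#' (planted usage / transition / kinematic effects). The default design
#' mirrors a crossover drug-challenge study: 17 subjects (10 mutant: 5 M,
#' 5 F; 7 control: 3 M, 4 F), each recorded once under saline and once
#' under the drug, order counterbalanced.
#'
#' @param base_spec [ground_truth_spec()] used for every cell unless
#'   overridden.
#' @param subjects data.frame with columns `subject`, `genotype`
#'   (`"control"`/`"mutant"`) and `sex` (`"M"`/`"F"`); one crossover pair of
#'   sessions (saline, THP) is generated per subject. Default: the 17-mouse
#'   design above.
#' @param session_length_frames frames per session (default 30 min at
#'   30 Hz).
#' @param overrides list of `list(genotype=, sex=, treatment=, spec=)`
#'   entries; a session matching all non-NULL selectors uses that spec.
#' @param seed master seed; per-session seeds are derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(base_spec = ground_truth_spec(5),
                        subjects = NULL,
                        session_length_frames = 54000L,
                        overrides = list(), seed = 1L) {
  if (is.null(subjects)) {
    subjects <- data.frame(
      subject = sprintf("m%02d", 1:17),
      genotype = rep(c("mutant", "control"), c(10, 7)),
      sex = c(rep(c("M", "F"), c(5, 5)), rep(c("M", "F"), c(3, 4))))
  }
  stopifnot(nrow(subjects) >= 1, is_count(session_length_frames))
  structure(list(base_spec = base_spec, subjects = subjects,
                 session_length_frames = as.integer(session_length_frames),
                 overrides = overrides, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Shift transition mass between two target syllables
#'
#' Returns a copy of the spec whose between-syllable transition matrix has
#' `mass` probability moved from entry `(row, from)` to `(row, to)` —
#' a planted sequencing effect that leaves usage of the source syllable
#' row-marginally unchanged.
#'
#' @param spec [ground_truth_spec()].
#' @param row,from,to state indices (1-based).
#' @param mass probability mass to move.
#' @export
shift_transition_mass <- function(spec, row, from, to, mass = 0.2) {
  P <- spec$transition
  if (P[row, from] < mass)
    stopf("entry (%d,%d) = %.3f has less than %.3f mass", row, from, P[row, from], mass)
  P[row, from] <- P[row, from] - mass
  P[row, to] <- P[row, to] + mass
  spec$transition <- P
  spec
}

#' Generate a labeled synthetic cohort
#'
#' Produces one session per subject x treatment cell of the design, with
#' the crossover treatment order counterbalanced across subjects, keeping
#' the ground-truth syllable labels for every session. Sessions can be
#' generated at three levels: `"labels"` (syllable sequences only — enough
#' for all usage/transition statistics), `"poses"` (plus the switching-AR
#' pose series used by the segmentation stage), or `"video"` (plus rendered
#' depth recordings for the tracking stage).
#'
#' @param cohort a [cohort_spec()].
#' @param level what to generate (see above). Video rendering at full
#'   session length is expensive; prefer short sessions at `"video"` level.
#' @param arena [arena_spec()] used at `"video"` level.
#' @return list of sessions; each has `meta` (one-row data.frame: subject,
#'   genotype, sex, treatment, session_index, treatment_order), `labels`
#'   (ground-truth syllable sequence), and depending on `level` `poses`
#'   (T x dim matrix) and `recording` (a `depth_recording`).
#' @export
make_cohort <- function(cohort, level = c("labels", "poses", "video"),
                        arena = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  level <- match.arg(level)
  subj <- cohort$subjects
  if (nrow(subj) == 0) stopf("cohort has no subjects")
  n_sessions <- 2L * nrow(subj)
  seeds <- derive_seeds(cohort$seed, n_sessions + 1L)
  # counterbalanced crossover order: alternate within the subject list
  first_thp <- rep(c(FALSE, TRUE), length.out = nrow(subj))
  sessions <- vector("list", n_sessions)
  idx <- 0L
  for (i in seq_len(nrow(subj))) {
    order_i <- if (first_thp[i]) c("THP", "saline") else c("saline", "THP")
    for (s in 1:2) {
      idx <- idx + 1L
      treatment <- order_i[s]
      spec_i <- cohort$base_spec
      for (ov in cohort$overrides) {
        ok <- (is.null(ov$genotype) || ov$genotype == subj$genotype[i]) &&
          (is.null(ov$sex) || ov$sex == subj$sex[i]) &&
          (is.null(ov$treatment) || ov$treatment == treatment)
        if (ok) spec_i <- ov$spec
      }
      meta <- data.frame(subject = subj$subject[i],
                         genotype = subj$genotype[i], sex = subj$sex[i],
                         treatment = treatment, session_index = s,
                         treatment_order = paste(order_i, collapse = "-"))
      labels <- gen_markov_labels(spec_i, cohort$session_length_frames,
                                  seed = seeds[idx])
      sess <- list(meta = meta, labels = labels, spec = spec_i)
      if (level %in% c("poses", "video")) {
        sess$poses <- gen_ar_pose_series(labels, spec_i, seed = seeds[idx])
      }
      if (level == "video") {
        if (is.null(arena)) arena <- arena_spec()
        traj <- gen_pose_trajectory(labels, spec_i, arena, seed = seeds[idx])
        sess$recording <- render_depth_session(traj, arena, seed = seeds[idx])
      }
      sessions[[idx]] <- sess
    }
  }
  attr(sessions, "cohort") <- cohort
  sessions
}

#' Session metadata of a cohort as one data.frame
#' @param sessions result of [make_cohort()].
#' @export
cohort_metadata <- function(sessions) {
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    cbind(session = i, sessions[[i]]$meta)
  }))
}

#' Write ground-truth labels of a cohort session to CSV
#' @param labels integer label vector; @param path output file.
#' @export
write_labels_csv <- function(labels, path) {
  write.csv(data.frame(frame_index = seq_along(labels) - 1L,
                       state = as.integer(labels)),
            path, row.names = FALSE)
  invisible(path)
}
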