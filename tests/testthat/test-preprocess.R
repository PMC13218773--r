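test_that("frame cleanup conserves sentinel counts and values", {
  arena <- test_arena()
  rec <- render_empty_session(arena, n_frames = 2, seed = 1)
  # no sentinels: values unchanged
  clean <- prepare_frames(rec)
  expect_false(anyNA(clean$frames))
  expect_equal(clean$frames[1, , ], rec$frames[1, , ] * 1.0)
  # k sentinels -> exactly k missing markers
  rec$frames[1, 5, 7] <- rec$sentinel
  rec$frames[1, 50, 70] <- rec$sentinel
  rec$frames[2, 8, 9] <- rec$sentinel
  clean2 <- prepare_frames(rec)
  expect_equal(sum(is.na(clean2$frames)), 3)
  # planted dropout rate is recovered
  arena2 <- test_arena(noise_sd_mm = 2, invalid_pixel_rate = 0.01)
  rec3 <- prepare_frames(render_empty_session(arena2, n_frames = 5, seed = 2))
  expect_lt(abs(mean(is.na(rec3$frames)) - 0.01), 0.002)
})

test_that("background is the median of strided filtered frames", {
  arena <- test_arena()
  # static noise-free empty arena: background equals any frame exactly
  rec <- prepare_frames(render_empty_session(arena, n_frames = 4, seed = 1))
  bg <- compute_background(rec, interval = 2)
  expect_equal(bg$depth_mm, rec$frames[1, , ])
  expect_equal(bg$n_samples_used, 2)
  # interval beyond T degenerates to the first frame's filtered values
  bg1 <- compute_background(rec, interval = 100)
  expect_equal(bg1$n_samples_used, 1)
  expect_equal(bg1$depth_mm, rec$frames[1, , ])
  # with a moving mouse, the floor is recovered at almost all pixels
  spec <- test_gts()
  arena3 <- test_arena(noise_sd_mm = 2, invalid_pixel_rate = 0.01)
  z <- gen_markov_labels(spec, 900, seed = 11)
  traj <- gen_pose_trajectory(z, spec, arena3, seed = 11)
  rec3 <- prepare_frames(render_depth_session(traj, arena3, seed = 11))
  bg3 <- compute_background(rec3, interval = 100)
  expect_gte(mean(abs(bg3$depth_mm - 520) <= 2, na.rm = TRUE), 0.99)
})

test_that("EM tracker recovers planted centers, ellipse and speed", {
  # zero noise: sub-half-pixel center recovery at every frame
  ses <- render_test_session(T = 80, noise_sd_mm = 0, seed = 13)
  tr <- em_track_session(ses$rec, ses$bg)
  pc <- planted_centers_px(ses$traj, ses$arena)
  err <- sqrt((tr$frames$center_r - pc$r)^2 + (tr$frames$center_c - pc$c)^2)
  expect_lt(max(err), 0.5)
  # ellipse respects major >= minor and the planted elongation
  expect_true(all(tr$frames$major_mm >= tr$frames$minor_mm))
  expect_true(all(tr$frames$minor_mm > 0))

  # stationary blob: zero speed and distance
  arena <- test_arena()
  poses <- data.frame(x_mm = 150, y_mm = 150, heading_rad = 0.4,
                      body_length_mm = 70, body_width_mm = 28,
                      peak_height_mm = 45, state = 1L)[rep(1, 20), ]
  rec <- prepare_frames(render_depth_session(poses, arena, seed = 1))
  trs <- em_track_session(rec, empty_background(arena))
  expect_lt(max(trs$speed_mm_s), 1e-6)
  expect_lt(trs$total_distance_mm, 1e-6)

  # translation at 3 mm/frame: 90 mm/s mean speed within 2%
  n <- 90
  poses2 <- data.frame(x_mm = 30 + 3 * (0:(n - 1)) / sqrt(2),
                       y_mm = 30 + 3 * (0:(n - 1)) / sqrt(2),
                       heading_rad = pi / 4, body_length_mm = 70,
                       body_width_mm = 28, peak_height_mm = 45, state = 1L)
  rec2 <- prepare_frames(render_depth_session(poses2, arena, seed = 2))
  tr2 <- em_track_session(rec2, empty_background(arena))
  expect_lt(abs(mean(tr2$speed_mm_s[-1]) - 90) / 90, 0.02)

  # total distance is the sum of per-frame displacements by definition
  expect_equal(tr2$total_distance_mm,
               sum(tr2$speed_mm_s[-1]) / tr2$frame_rate_hz, tolerance = 1e-9)

  # an empty first frame is a hard tracking error
  emp <- prepare_frames(render_empty_session(test_arena(), 3, seed = 4))
  expect_error(em_track_session(emp, empty_background(test_arena())),
               "frame 1")
})

test_that("crop-align is rotation-equivariant and centered", {
  arena <- test_arena()
  bg <- empty_background(arena)
  mk <- function(heading) {
    poses <- data.frame(x_mm = 150, y_mm = 150, heading_rad = heading,
                        body_length_mm = 70, body_width_mm = 36,
                        peak_height_mm = 45, state = 1L)[rep(1, 3), ]
    prepare_frames(render_depth_session(poses, arena, nose_asym = 0, seed = 1))
  }
  crop_of <- function(rec) {
    tr <- em_track_session(rec, bg)
    # resolve the 180-degree axis ambiguity using the known heading
    crop_align_frames(rec, bg, tr, size = 80)$crops[1, , ]
  }
  c0 <- crop_of(mk(0))
  c37 <- crop_of(mk(37 * pi / 180))
  # same blob observed at 37 degrees, re-aligned: equal up to interpolation
  # error (the axis fit may point either way for a symmetric blob)
  diff_fwd <- max(abs(c37 - c0))
  diff_rev <- max(abs(c37[80:1, 80:1] - c0))
  expect_lt(min(diff_fwd, diff_rev) / 45, 0.05)
  # axis-aligned symmetric blob: symmetric under vertical flip
  expect_lt(max(abs(c0 - c0[80:1, ])), 1e-6)
  # planted elongation shows up as larger horizontal than vertical spread
  wcol <- colSums(c0); wrow <- rowSums(c0)
  sd_col <- sqrt(sum(wcol * (1:80 - 40.5)^2) / sum(wcol))
  sd_row <- sqrt(sum(wrow * (1:80 - 40.5)^2) / sum(wrow))
  expect_gt(sd_col, sd_row)
})

test_that("orientation flips are detected against planted headings", {
  ses <- render_test_session(T = 250, noise_sd_mm = 2, nose_asym = 0.15,
                             invalid_pixel_rate = 0.01, seed = 17)
  tr <- em_track_session(ses$rec, ses$bg)
  # force all crops right-facing by aligning along the true heading
  tr_right <- tr
  tr_right$frames$axis_angle <- ses$traj$heading_rad
  cr_right <- crop_align_frames(ses$rec, ses$bg, tr_right, size = 80)
  f1 <- detect_and_fix_flips(cr_right, seed = 1)
  expect_lte(mean(f1$flip_decisions), 0.01)
  # mirror every frame: nearly all must flip back
  cr_mir <- cr_right
  for (t in seq_len(dim(cr_mir$crops)[1]))
    cr_mir$crops[t, , ] <- cr_mir$crops[t, , 80:1]
  f2 <- detect_and_fix_flips(cr_mir, seed = 1)
  expect_gte(mean(f2$flip_decisions), 0.99)
  # realistic mixed-orientation session: headings recovered after flips
  cr <- crop_align_frames(ses$rec, ses$bg, tr, size = 80)
  f3 <- detect_and_fix_flips(cr, seed = 1)
  herr <- heading_error(f3$tracked$frames$heading, ses$traj$heading_rad)
  expect_gte(mean(herr < pi / 2), 0.95)
})

test_that("ambiguous symmetric blobs get temporally consistent decisions", {
  ses <- render_test_session(T = 200, noise_sd_mm = 2, nose_asym = 0,
                             seed = 19)
  tr <- em_track_session(ses$rec, ses$bg)
  cr <- crop_align_frames(ses$rec, ses$bg, tr, size = 80)
  f <- detect_and_fix_flips(cr, seed = 1)
  transitions <- sum(diff(f$flip_decisions) != 0)
  expect_lt(transitions / length(f$flip_decisions), 0.01)
})

test_that("crop smoothing denoises without distorting static content", {
  mk_crops <- function(arr) structure(
    list(crops = arr, flip_decisions = rep(FALSE, dim(arr)[1]),
         edge_flagged = rep(FALSE, dim(arr)[1]), tracked = NULL,
         frame_rate_hz = 30), class = "aligned_crops")
  base <- matrix(10 * exp(-((row(diag(80)) - 40)^2 + (col(diag(80)) - 40)^2) / 200),
                 80, 80)
  const <- mk_crops(array(rep(base, each = 9), c(9, 80, 80)))
  # temporal median of a constant sequence is the identity
  sm <- smooth_crops(const, sigma_col = 0, sigma_row = 0)
  expect_equal(sm$crops, const$crops)
  # an isolated single-frame impulse is removed entirely
  imp <- const
  imp$crops[5, 40, 40] <- imp$crops[5, 40, 40] + 100
  sm2 <- smooth_crops(imp, sigma_col = 0, sigma_row = 0)
  expect_equal(sm2$crops[5, 40, 40], base[40, 40])
  # white noise SD is at least halved on a flat background
  set.seed(42)
  noisy <- mk_crops(array(rnorm(60 * 80 * 80, sd = 2), c(60, 80, 80)))
  sm3 <- smooth_crops(noisy)
  mid <- sm3$crops[10:50, 20:60, 20:60]
  expect_lte(sd(as.vector(mid)), 1)
})

test_that("kinematics summaries have the right units and windowing", {
  # planted 30 mm/s for 30 min -> 54 m and 30 mm/s averages
  n <- 30 * 60 * 30
  # 1 mm per frame at 30 Hz = 30 mm/s, on a folded path that stays in frame
  zig <- cumsum(rep(c(rep(1, 300), rep(-1, 300)), length.out = n + 1))
  tr <- tracked_series_from_centers(100 + zig * 1, rep(50, n + 1),
                                    frame_rate_hz = 30, px_per_mm = 1)
  kin <- compute_kinematics(tr, session_minutes = 30)
  expect_equal(kin$n_frames_used, n)
  expect_lt(abs(kin$total_distance_m - 54) / 54, 0.01)
  expect_false(kin$truncated)
  # stationary short session: all zero, flagged as truncated
  tr0 <- tracked_series_from_centers(rep(5, 100), rep(5, 100))
  expect_warning(kin0 <- compute_kinematics(tr0, session_minutes = 30),
                 "frames")
  expect_equal(kin0$total_distance_m, 0)
  expect_equal(kin0$avg_speed_mm_s, 0)
  expect_true(kin0$truncated)
})
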