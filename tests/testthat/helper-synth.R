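# shared fixtures: everything is generated in code at test time

# small test arena: same 30 cm x 52 cm geometry, reduced pixel resolution
test_arena <- function(noise_sd_mm = 0, invalid_pixel_rate = 0,
                       px_per_mm = 0.5) {
  arena_spec(frame_shape = c(168L, 168L), px_per_mm = px_per_mm,
             noise_sd_mm = noise_sd_mm, invalid_pixel_rate = invalid_pixel_rate)
}

# background estimated from a mouse-free recording under the same noise
empty_background <- function(arena, n_frames = 9L, seed = 99L) {
  emp <- prepare_frames(render_empty_session(arena, n_frames, seed = seed))
  compute_background(emp, interval = 1L)
}

# a small well-separated switching-AR generator
test_gts <- function(n_states = 3, dim = 4, duration_bias = 10, seed = 5,
                     rho = 0.7, noise_sd = 0.5, bias_scale = 4) {
  ground_truth_spec(n_states, duration_bias = duration_bias, dim = dim,
                    ar_params = default_ar_params(n_states, dim, rho = rho,
                                                  noise_sd = noise_sd,
                                                  bias_scale = bias_scale,
                                                  seed = seed + 1),
                    seed = seed)
}

# rendered + cleaned session with tracking-ready background
render_test_session <- function(T = 120, noise_sd_mm = 0, nose_asym = 0,
                                invalid_pixel_rate = 0, seed = 3) {
  arena <- test_arena(noise_sd_mm, invalid_pixel_rate)
  spec <- test_gts()
  z <- gen_markov_labels(spec, T, seed = seed)
  traj <- gen_pose_trajectory(z, spec, arena, seed = seed)
  rec <- prepare_frames(render_depth_session(traj, arena,
                                             nose_asym = nose_asym,
                                             seed = seed))
  list(rec = rec, traj = traj, arena = arena,
       bg = empty_background(arena, seed = seed + 50))
}

# planted pixel coordinates of a trajectory in the test arena
planted_centers_px <- function(traj, arena) {
  s <- arena$px_per_mm
  off_r <- (arena$frame_shape[1] - arena$arena_side_mm * s) / 2
  off_c <- (arena$frame_shape[2] - arena$arena_side_mm * s) / 2
  list(r = off_r + traj$y_mm * s, c = off_c + traj$x_mm * s)
}

# angular distance between two headings (radians)
heading_error <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi)
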