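# a 10-dim 3-state generator with well-separated dynamics, as used for
# segmentation recovery checks
recovery_spec <- function(seed = 7) {
  ground_truth_spec(3, duration_bias = 20, dim = 10,
                    ar_params = default_ar_params(3, 10, rho = 0.8,
                                                  bias_scale = 4,
                                                  noise_sd = 0.5,
                                                  seed = seed),
                    seed = seed)
}

test_that("sequence log-likelihood matches the closed form for iid Gaussians", {
  # K = 1, L = 1, A = 0, b = 0, Sigma = I: the AR collapses to iid normals
  pars <- list(list(A = array(0, c(3, 3, 1)), b = rep(0, 3), Sigma = diag(3)))
  m <- arhmm_model(pars, matrix(1, 1, 1))
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  ll <- sequence_loglik(m, X)
  closed <- sum(dnorm(X[-1, ], log = TRUE))
  expect_equal(ll, closed, tolerance = 1e-8)

  # additivity over independent sessions
  expect_equal(sequence_loglik(m, X) * 2,
               sequence_loglik(m, X) + sequence_loglik(m, X))

  # moving one observation far from its prediction strictly lowers loglik
  X2 <- X; X2[10, ] <- X2[10, ] + 50
  expect_lt(sequence_loglik(m, X2), ll)
})

test_that("decoding recovers generative states and handles K = 1", {
  spec <- recovery_spec()
  gm <- as_arhmm_model(spec)
  z <- gen_markov_labels(spec, 3000, seed = 2)
  X <- gen_ar_pose_series(z, spec, seed = 2)
  dec <- decode_labels(gm, X)
  al <- align_states(z, dec$labels)
  expect_gte(al$accuracy, 0.9)
  # K = 1: every frame gets the single state
  pars <- list(list(A = array(0, c(2, 2, 1)), b = rep(0, 2), Sigma = diag(2)))
  m1 <- arhmm_model(pars, matrix(1, 1, 1))
  expect_identical(unique(decode_labels(m1, matrix(rnorm(40), 20, 2))$labels), 1L)
})

test_that("Gibbs training recovers a 3-state switching AR process", {
  spec <- recovery_spec()
  z1 <- gen_markov_labels(spec, 4000, seed = 21)
  z2 <- gen_markov_labels(spec, 4000, seed = 22)
  X1 <- gen_ar_pose_series(z1, spec, seed = 31)
  X2 <- gen_ar_pose_series(z2, spec, seed = 32)
  fit <- train_arhmm(list(X1, X2), K = 10, L = 1, n_iter = 60, seed = 1)
  al <- align_states(c(z1, z2),
                     c(fit$labeled[[1]]$labels, fit$labeled[[2]]$labels))
  expect_gte(al$accuracy, 0.9)
  expect_gte(n_used_states(fit$labeled, 10, threshold = 0.01), 3)
  # transition rows remain stochastic after sampling
  expect_lt(max(abs(rowSums(fit$model$transition) - 1)), 1e-10)
  expect_true(all(fit$model$transition >= 0))
  # decoding the training series agrees with training-time labels
  dec <- decode_labels(fit$model, X1)
  expect_gte(mean(dec$labels == fit$labeled[[1]]$labels), 0.95)
  # planted fixed points are recovered by the matched states
  fp_true <- t(vapply(spec$ar_params, function(p)
    as.numeric(solve(diag(10) - p$A[, , 1], p$b)), numeric(10)))
  map <- align_states(c(z1, z2),
                      c(fit$labeled[[1]]$labels, fit$labeled[[2]]$labels))$mapping
  for (k in 1:3) {
    st <- fit$model$states[[map[as.character(k)]]]
    fp_hat <- as.numeric(solve(diag(10) - st$W[, 1:10], st$b))
    expect_lt(sqrt(sum((fp_hat - fp_true[k, ])^2)) /
                sqrt(sum(fp_true[k, ]^2)), 0.1)
  }
})

test_that("single-state data concentrates on one state", {
  spec <- test_gts(1, dim = 4, duration_bias = 0)
  X <- gen_ar_pose_series(rep(1L, 3000), spec, seed = 3)
  fit <- train_arhmm(list(X), K = 5, L = 1, n_iter = 30, seed = 2)
  occ <- tabulate(fit$labeled[[1]]$labels, 5) / 3000
  expect_gte(max(occ), 0.95)
})

test_that("the sticky weight controls syllable persistence", {
  spec <- recovery_spec(seed = 9)
  z <- gen_markov_labels(spec, 4000, seed = 4)
  X <- gen_ar_pose_series(z, spec, seed = 4)
  durs <- vapply(c(1, 1e3, 1e5), function(kap) {
    fit <- train_arhmm(list(X), K = 8, L = 1, n_iter = 25, seed = 3,
                       hyperparams = list(kappa = kap))
    median_syllable_duration(fit$labeled[[1]])
  }, 0)
  expect_true(all(diff(durs) > 0))
})

test_that("series shorter than the lag order are skipped with a warning", {
  spec <- test_gts(1, dim = 4)
  X <- gen_ar_pose_series(rep(1L, 500), spec, seed = 5)
  expect_warning(
    fit <- train_arhmm(list(X, X[1:2, ]), K = 3, L = 3, n_iter = 5, seed = 1),
    "skipped")
  expect_length(fit$labeled, 1)
  expect_error(train_arhmm(list(X), K = 0, n_iter = 5), "positive")
})

test_that("cross-likelihood separates distinct dynamics and is 0 on the diagonal", {
  # two states with IDENTICAL parameters: all entries exactly 0
  p1 <- list(A = array(0.5 * diag(4), c(4, 4, 1)), b = c(1, 0, 0, 0),
             Sigma = diag(0.25, 4))
  same <- ground_truth_spec(2, ar_params = list(p1, p1), dim = 4,
                            duration_bias = 10)
  z <- gen_markov_labels(same, 4000, seed = 6)
  X <- gen_ar_pose_series(z, same, seed = 6)
  cl <- cross_likelihood_matrix(as_arhmm_model(same),
                                list(list(series = X, labels = z)))
  expect_equal(unname(diag(cl$values)), rep(0, 2))
  expect_lt(max(abs(cl$values)), 1e-8)

  # disjoint dynamics: strongly negative off-diagonal, diagonal the row max
  spec <- recovery_spec(seed = 13)
  z2 <- gen_markov_labels(spec, 6000, seed = 7)
  X2 <- gen_ar_pose_series(z2, spec, seed = 7)
  cl2 <- cross_likelihood_matrix(as_arhmm_model(spec),
                                 list(list(series = X2, labels = z2)))
  expect_equal(unname(diag(cl2$values)), rep(0, 3))
  off <- cl2$values[row(cl2$values) != col(cl2$values)]
  expect_true(all(off < -1))
  expect_true(all(apply(cl2$values, 1, which.max) == 1:3))
})

test_that("training is deterministic given the seed", {
  spec <- recovery_spec()
  X <- gen_ar_pose_series(gen_markov_labels(spec, 1500, seed = 8), spec, seed = 8)
  f1 <- train_arhmm(list(X), K = 6, L = 1, n_iter = 10, seed = 42)
  f2 <- train_arhmm(list(X), K = 6, L = 1, n_iter = 10, seed = 42)
  expect_identical(f1$labeled[[1]]$labels, f2$labeled[[1]]$labels)
  expect_equal(f1$model$transition, f2$model$transition)
})
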