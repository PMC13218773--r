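#' Sticky autoregressive hidden Markov model for behavioral syllables
#'
#' The segmentation engine: each hidden state (syllable) emits pose
#' observations through its own vector-autoregressive process
#' `x_t = sum_l A_l x_{t-l} + b + eps`, and states follow a Markov chain
#' whose self-transitions carry an extra sticky weight so syllables persist
#' over sub-second time scales. The finite weak-limit approximation with a
#' generous state cap `K` stands in for the nonparametric hierarchical
#' model; unused states simply receive negligible usage.
#'
#' Inference is blocked Gibbs sampling: the state sequence is drawn jointly
#' by forward-filter backward-sampling given the AR parameters, AR
#' parameters are drawn from their matrix-normal-inverse-Wishart (MNIW)
#' conditionals given the assigned frames, and transition rows from sticky
#' Dirichlet conditionals.
#'
#' @name arhmm
NULL

default_arhmm_hyperparams <- function(d, L) {
  p <- d * L + 1L
  M0 <- matrix(0, d, p)
  M0[, 1:d] <- diag(d)           # prior mean: persist the previous frame
  list(alpha = 5, kappa = 100, M0 = M0, K0 = diag(0.1, p),
       nu0 = d + 2, S0 = diag(1, d))
}

# lagged design: Y (T-L x d) and regressors [x_{t-1},...,x_{t-L},1]
make_regressors <- function(X, L) {
  Tn <- nrow(X); d <- ncol(X)
  if (Tn <= L) return(NULL)
  idx <- (L + 1):Tn
  Xr <- matrix(0, length(idx), d * L + 1L)
  for (l in seq_len(L))
    Xr[, ((l - 1) * d + 1):(l * d)] <- X[idx - l, , drop = FALSE]
  Xr[, d * L + 1L] <- 1
  list(Y = X[idx, , drop = FALSE], Xr = Xr)
}

# per-state emission log-densities: (T-L) x K matrix
emission_logliks <- function(reg, states) {
  n <- nrow(reg$Y); d <- ncol(reg$Y)
  out <- matrix(0, n, length(states))
  for (k in seq_along(states)) {
    st <- states[[k]]
    R <- chol(st$Sigma)
    resid <- reg$Y - reg$Xr %*% t(st$W)
    z <- resid %*% backsolve(R, diag(d))
    out[, k] <- -0.5 * rowSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
  }
  out
}

# one MNIW posterior draw for a state given its assigned rows
sample_mniw_state <- function(Y, Xr, hp) {
  d <- nrow(hp$M0); p <- ncol(hp$K0)
  if (is.null(Y) || nrow(Y) == 0) {
    Sxx <- hp$K0; Syx <- hp$M0 %*% hp$K0
    Syy <- hp$M0 %*% hp$K0 %*% t(hp$M0)
    n <- 0
  } else {
    Sxx <- crossprod(Xr) + hp$K0
    Syx <- crossprod(Y, Xr) + hp$M0 %*% hp$K0
    Syy <- crossprod(Y) + hp$M0 %*% hp$K0 %*% t(hp$M0)
    n <- nrow(Y)
  }
  Sxx <- ensure_spd(Sxx, 1e-8)
  Vinv_chol <- chol(Sxx)
  V <- chol2inv(Vinv_chol)                  # posterior column covariance
  Wn <- Syx %*% V
  Sn <- ensure_spd(hp$S0 + Syy - Wn %*% t(Syx), 1e-8)
  nun <- hp$nu0 + n
  Prec <- rWishart(1, nun, chol2inv(chol(Sn)))[, , 1]
  Sigma <- ensure_spd(chol2inv(chol(Prec)), 1e-6)
  Z <- matrix(rnorm(d * p), d, p)
  W <- Wn + t(chol(Sigma)) %*% Z %*% chol(ensure_spd(V, 1e-10))
  list(W = W, b = W[, p], Sigma = Sigma)
}

sample_dirichlet <- function(a) {
  g <- rgamma(length(a), shape = pmax(a, 1e-8))
  if (sum(g) <= 0) g <- rep(1, length(a))
  g / sum(g)
}

#' Train the AR-HMM on pooled pose series
#'
#' Blocked Gibbs sampling over the concatenated sessions. Labels are
#' reported from the final sample by default (deterministic given `seed`),
#' or as the per-frame mode over the last `modal_over` samples.
#'
#' @param series_list list of `pose_series` (or plain T x d score
#'   matrices) sharing a common dimension.
#' @param K state cap (weak-limit truncation; default 100).
#' @param L AR lag order (default 3).
#' @param n_iter number of Gibbs sweeps.
#' @param hyperparams overrides for the defaults: `alpha` (transition
#'   Dirichlet concentration), `kappa` (sticky self-transition weight),
#'   `M0`, `K0`, `nu0`, `S0` (MNIW prior).
#' @param seed RNG seed; the whole run is deterministic given it.
#' @param heldout optional `pose_series` scored by [sequence_loglik()]
#'   every `heldout_every` sweeps (training diagnostic).
#' @param heldout_every sweeps between held-out evaluations (default 5).
#' @param modal_over if > 1, report per-frame modal labels over the last
#'   `modal_over` samples instead of the final sample.
#' @return list with `model` (an `arhmm_model`), `labeled` (per-session
#'   `labeled_session`s: 1-based `labels` of length T — the first `L`
#'   frames inherit the first sampled state — and run `onsets`), and
#'   `diagnostics` (`train_loglik` trace, `heldout_loglik` data.frame).
#' @export
train_arhmm <- function(series_list, K = 100L, L = 3L, n_iter = 100L,
                        hyperparams = list(), seed = 1L,
                        heldout = NULL, heldout_every = 5L, modal_over = 1L) {
  if (!is_count(K)) stopf("K must be a positive integer")
  if (!is_count(n_iter)) stopf("n_iter must be >= 1")
  mats <- lapply(series_list, as_score_matrix)
  d <- unique(vapply(mats, ncol, 1L))
  if (length(d) != 1L) stopf("all series must share one dimension")
  regs <- lapply(mats, make_regressors, L = L)
  short <- vapply(regs, is.null, TRUE)
  if (any(short)) {
    warnf("%d series shorter than L+1 frames skipped", sum(short))
    regs <- regs[!short]; mats <- mats[!short]
  }
  if (length(regs) == 0) stopf("no usable series")
  hp <- modifyList(default_arhmm_hyperparams(d, L), hyperparams)
  ns <- length(regs)
  diag_train <- numeric(n_iter)
  heldout_reg <- if (!is.null(heldout)) make_regressors(as_score_matrix(heldout), L)
  heldout_trace <- list()
  label_hist <- list()
  with_seed(seed, {
    z <- lapply(regs, function(r) sample.int(K, nrow(r$Y), replace = TRUE))
    trans <- matrix(1 / K, K, K)
    init <- rep(1 / K, K)
    states <- NULL
    for (it in seq_len(n_iter)) {
      # --- conjugate parameter updates given labels
      allz <- unlist(z)
      states <- vector("list", K)
      for (k in seq_len(K)) {
        rows <- lapply(seq_len(ns), function(s) which(z[[s]] == k))
        Yk <- do.call(rbind, lapply(seq_len(ns), function(s) regs[[s]]$Y[rows[[s]], , drop = FALSE]))
        Xk <- do.call(rbind, lapply(seq_len(ns), function(s) regs[[s]]$Xr[rows[[s]], , drop = FALSE]))
        states[[k]] <- sample_mniw_state(Yk, Xk, hp)
      }
      # --- sticky Dirichlet transition updates
      cnt <- matrix(0, K, K)
      for (s in seq_len(ns)) {
        zs <- z[[s]]
        if (length(zs) > 1) {
          tab <- table(factor(zs[-length(zs)], levels = 1:K),
                       factor(zs[-1], levels = 1:K))
          cnt <- cnt + as.matrix(tab)
        }
      }
      for (k in seq_len(K)) {
        a <- rep(hp$alpha / K, K)
        a[k] <- a[k] + hp$kappa
        trans[k, ] <- sample_dirichlet(a + cnt[k, ])
      }
      ini_cnt <- tabulate(vapply(z, `[`, 1L, 1L), K)
      init <- sample_dirichlet(1 + ini_cnt)
      # --- blocked state resampling (FFBS)
      ll <- 0
      for (s in seq_len(ns)) {
        lo <- emission_logliks(regs[[s]], states)
        ll <- ll + cpp_forward_loglik(lo, trans, init)
        z[[s]] <- as.integer(cpp_ffbs(lo, trans, init)) + 1L
      }
      diag_train[it] <- ll
      if (!is.null(heldout_reg) && (it %% heldout_every == 0 || it == n_iter)) {
        lo <- emission_logliks(heldout_reg, states)
        heldout_trace[[length(heldout_trace) + 1]] <-
          data.frame(iter = it, loglik = cpp_forward_loglik(lo, trans, init))
      }
      if (modal_over > 1 && it > n_iter - modal_over)
        label_hist[[length(label_hist) + 1]] <- z
    }
    if (modal_over > 1 && length(label_hist) > 1) {
      z <- lapply(seq_len(ns), function(s) {
        zm <- vapply(label_hist, function(h) h[[s]], integer(length(z[[s]])))
        apply(zm, 1, function(v) as.integer(names(which.max(table(v)))))
      })
    }
    model <- new_arhmm_model(K, L, d, states, trans, init, hp, seed)
    labeled <- lapply(seq_len(ns), function(s)
      new_labeled_session(c(rep(z[[s]][1], L), z[[s]]), K))
    ho <- if (length(heldout_trace)) do.call(rbind, heldout_trace) else NULL
    list(model = model,
         labeled = labeled,
         diagnostics = list(train_loglik = diag_train, heldout_loglik = ho))
  })
}

#' Construct an AR-HMM from explicit parameters
#'
#' Builds a model object from per-state AR parameters (as in
#' [ground_truth_spec()]: `A` a `d x d x L` array, `b`, `Sigma`), a
#' row-stochastic transition matrix and an initial distribution — useful
#' for scoring and decoding with known dynamics.
#'
#' @param ar_params list of per-state `list(A, b, Sigma)`.
#' @param transition K x K row-stochastic matrix.
#' @param initial length-K simplex (default uniform).
#' @export
arhmm_model <- function(ar_params, transition, initial = NULL) {
  K <- length(ar_params)
  d <- dim(ar_params[[1]]$A)[1]; L <- dim(ar_params[[1]]$A)[3]
  assert_row_stochastic(transition)
  if (nrow(transition) != K) stopf("transition must be %d x %d", K, K)
  if (is.null(initial)) initial <- rep(1 / K, K)
  states <- lapply(ar_params, function(p) {
    W <- matrix(0, d, d * L + 1L)
    for (l in seq_len(L)) W[, ((l - 1) * d + 1):(l * d)] <- p$A[, , l]
    W[, d * L + 1L] <- p$b
    list(W = W, b = p$b, Sigma = ensure_spd(p$Sigma))
  })
  new_arhmm_model(K, L, d, states, transition, initial,
                  default_arhmm_hyperparams(d, L), NA_integer_)
}

#' Ground-truth generator as an AR-HMM
#' @param spec a [ground_truth_spec()].
#' @return the equivalent `arhmm_model` (effective transition matrix with
#'   the duration bias folded in).
#' @export
as_arhmm_model <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  P <- effective_transition(spec)
  arhmm_model(spec$ar_params, P, stationary_distribution(P))
}

as_score_matrix <- function(x) {
  if (inherits(x, "pose_series")) x$scores
  else if (is.matrix(x)) x
  else stopf("series must be pose_series objects or matrices")
}

new_arhmm_model <- function(K, L, d, states, trans, init, hp, seed) {
  structure(list(K = as.integer(K), L = as.integer(L), dim = as.integer(d),
                 states = states, transition = trans, initial = init,
                 hyperparams = hp, seed = seed),
            class = "arhmm_model")
}

new_labeled_session <- function(labels, K) {
  runs <- label_runs(labels)
  structure(list(labels = as.integer(labels), onsets = runs$onset, K = K),
            class = "labeled_session")
}

#' @export
print.arhmm_model <- function(x, ...) {
  cat(sprintf("<arhmm_model> K = %d states (cap), %d-dim AR(%d) emissions\n",
              x$K, x$dim, x$L))
  invisible(x)
}

#' Decode a pose series with a trained model
#'
#' Most-probable state per frame from the forward-backward posterior
#' marginals under the AR emission likelihood. The first `L` frames (which
#' have no complete lag window) inherit the first decoded state.
#'
#' @param model `arhmm_model`; @param series `pose_series` or matrix.
#' @return a `labeled_session`.
#' @export
decode_labels <- function(model, series) {
  stopifnot(inherits(model, "arhmm_model"))
  X <- as_score_matrix(series)
  if (ncol(X) != model$dim)
    stopf("series dimension %d does not match model dimension %d", ncol(X), model$dim)
  reg <- make_regressors(X, model$L)
  if (is.null(reg)) stopf("series shorter than L + 1 frames")
  lo <- emission_logliks(reg, model$states)
  post <- cpp_fb_posterior(lo, model$transition, model$initial)
  z <- max.col(post, ties.method = "first")
  new_labeled_session(c(rep(z[1], model$L), z), model$K)
}

#' Log-likelihood of a pose series under the model
#'
#' `log p(x_{L+1:T} | x_{1:L}, model)` by the forward algorithm in log
#' space (nats).
#'
#' @inheritParams decode_labels
#' @export
sequence_loglik <- function(model, series) {
  stopifnot(inherits(model, "arhmm_model"))
  X <- as_score_matrix(series)
  reg <- make_regressors(X, model$L)
  if (is.null(reg)) stopf("series shorter than L + 1 frames")
  lo <- emission_logliks(reg, model$states)
  cpp_forward_loglik(lo, model$transition, model$initial)
}

#' Cross-likelihood validation of syllable distinctness
#'
#' For every ordered state pair (i, j): take the frames assigned to state i
#' whose full lag window also lies in state i (interior of the runs), and
#' compare the mean per-frame AR log-likelihood of those frames under
#' state j's parameters with the same quantity under state i's own
#' parameters. Entry (i, j) is that difference in nats per frame, so the
#' diagonal is exactly 0 and strongly negative off-diagonal entries mean
#' state j's dynamics fail to describe state i's frames — i.e. the states
#' are distinct. States without a qualifying segment get NA rows/columns.
#'
#' @param model `arhmm_model`.
#' @param labeled_data list of `list(series = , labels = )` pairs (labels
#'   as `labeled_session` or integer vectors of length T).
#' @return list of class `cross_likelihood`: `values` (K_used x K_used),
#'   `states` (ids with data), `n_frames` per state.
#' @export
cross_likelihood_matrix <- function(model, labeled_data) {
  stopifnot(inherits(model, "arhmm_model"))
  L <- model$L
  per_state_ll <- vector("list", model$K)   # frames' logliks under all states
  n_frames <- integer(model$K)
  sums <- matrix(0, model$K, model$K)       # sums[i, j]: state-i frames under model j
  for (item in labeled_data) {
    X <- as_score_matrix(item$series)
    lab <- if (inherits(item$labels, "labeled_session")) item$labels$labels else as.integer(item$labels)
    if (length(lab) != nrow(X)) stopf("labels and series lengths differ")
    reg <- make_regressors(X, L)
    if (is.null(reg)) next
    lo <- emission_logliks(reg, model$states)       # (T-L) x K
    labY <- lab[(L + 1):length(lab)]
    # interior frames: the whole lag window shares the frame's state
    interior <- rep(TRUE, length(labY))
    for (l in seq_len(L))
      interior <- interior & lab[(L + 1 - l):(length(lab) - l)] == labY
    for (i in unique(labY[interior])) {
      rows <- which(labY == i & interior)
      sums[i, ] <- sums[i, ] + colSums(lo[rows, , drop = FALSE])
      n_frames[i] <- n_frames[i] + length(rows)
    }
  }
  used <- which(n_frames > 0)
  vals <- matrix(NA_real_, length(used), length(used),
                 dimnames = list(used, used))
  for (a in seq_along(used)) {
    i <- used[a]
    mean_ll <- sums[i, used] / n_frames[i]
    vals[a, ] <- mean_ll - mean_ll[a]
  }
  structure(list(values = vals, states = used, n_frames = n_frames[used]),
            class = "cross_likelihood")
}

#' Align predicted states to ground-truth states
#'
#' Finds the injective map from true states to predicted states maximizing
#' matched frames (exhaustive search over assignments; intended for small
#' numbers of true states) and returns the mapping and frame accuracy.
#'
#' @param true,pred integer label vectors of equal length.
#' @return list: `mapping` (named vector true -> pred), `accuracy`.
#' @export
align_states <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  tu <- sort(unique(true)); pu <- sort(unique(pred))
  C <- table(factor(true, levels = tu), factor(pred, levels = pu))
  nt <- length(tu)
  if (nt > 6) stopf("exhaustive alignment supports at most 6 true states")
  best <- list(score = -1, map = NULL)
  combs <- utils::combn(length(pu), min(nt, length(pu)), simplify = FALSE)
  for (cmb in combs) {
    perms <- all_perms(cmb)
    for (pm in perms) {
      sc <- sum(C[cbind(seq_len(min(nt, length(pm))), pm[seq_len(min(nt, length(pm)))])])
      if (sc > best$score) best <- list(score = sc, map = pm)
    }
  }
  mapping <- setNames(pu[best$map], tu[seq_along(best$map)])
  list(mapping = mapping, accuracy = best$score / length(true))
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Median syllable duration of a labeled session (frames)
#' @param labeled a `labeled_session` or integer labels.
#' @export
median_syllable_duration <- function(labeled) {
  lab <- if (inherits(labeled, "labeled_session")) labeled$labels else labeled
  median(label_runs(lab)$length)
}

#' Number of used states above a usage threshold
#' @param labeled_list list of `labeled_session`s; @param K state cap;
#' @param threshold minimum frame-occupancy fraction (0 counts any use).
#' @export
n_used_states <- function(labeled_list, K, threshold = 0) {
  occ <- rep(0, K)
  tot <- 0
  for (ls in labeled_list) {
    lab <- if (inherits(ls, "labeled_session")) ls$labels else ls
    occ <- occ + tabulate(lab, K)
    tot <- tot + length(lab)
  }
  sum(occ / tot > threshold)
}
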