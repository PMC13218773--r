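# shared validation / small numeric helpers

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

#' @keywords internal
assert_row_stochastic <- function(P, tol = 1e-12, what = "transition matrix") {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stopf("%s must be a square matrix", what)
  if (any(P < -tol)) stopf("%s has negative entries", what)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > max(tol, 1e-8)))
    stopf("%s rows must sum to 1 (max |row sum - 1| = %.3g)", what,
          max(abs(rs - 1)))
  invisible(P)
}

# symmetric PD check with a small eigenvalue floor applied when needed
ensure_spd <- function(S, floor = 1e-10) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < floor) {
    S <- ev$vectors %*% diag(pmax(ev$values, floor), nrow(S)) %*% t(ev$vectors)
    S <- (S + t(S)) / 2
  }
  S
}

# wrap angle into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# wrap an undirected axis angle into [-pi/2, pi/2)
wrap_axis <- function(a) {
  a <- (a + pi / 2) %% pi - pi / 2
  a[a >= pi / 2] <- a[a >= pi / 2] - pi
  a
}

# run-length encode an integer label vector: data.frame(state, length, onset)
label_runs <- function(labels) {
  r <- rle(as.integer(labels))
  onsets <- cumsum(c(1L, head(r$lengths, -1L)))
  data.frame(state = r$values, length = r$lengths, onset = onsets)
}

# draw independent sub-seeds from a master seed (keeps them < 2^31)
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
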