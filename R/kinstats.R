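#' Histogram / CDF summary of a kinematic variable
#'
#' Normalized histogram over fixed bins, its log10 (empty bins reported as
#' NA rather than -Inf), and the empirical CDF evaluated at the bin edges.
#' Defaults: speed 0-400 mm/s in 100 bins, height 0-100 mm in 50 bins.
#'
#' @param x numeric series (per-frame speeds or heights); NAs dropped.
#' @param variable `"speed"` or `"height"` (sets default bins).
#' @param breaks bin edges overriding the defaults; values outside the
#'   range are clamped to the end bins.
#' @return a `kinematic_summary`: `breaks`, `prob` (sums to 1),
#'   `log10_prob`, `cdf` (at `breaks`, ends at 1).
#' @export
distribution_summaries <- function(x, variable = c("speed", "height"),
                                   breaks = NULL) {
  variable <- match.arg(variable)
  x <- x[!is.na(x)]
  if (length(x) == 0) stopf("all values missing")
  if (is.null(breaks))
    breaks <- if (variable == "speed") seq(0, 400, length.out = 101)
              else seq(0, 100, length.out = 51)
  if (length(breaks) < 2 || is.unsorted(breaks)) stopf("invalid bins")
  xc <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  h <- hist(xc, breaks = breaks, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  lp <- ifelse(prob > 0, log10(prob), NA_real_)
  cdf <- c(0, cumsum(prob))
  structure(list(variable = variable, breaks = breaks, prob = prob,
                 log10_prob = lp, cdf = cdf, n = length(x)),
            class = "kinematic_summary")
}

#' Per-group totals: distance and session-averaged speed
#'
#' Mean and SEM (SD / sqrt(n)) per group of each session's total distance
#' (m) and session-averaged speed (mm/s). Groups with a single session
#' report `NA` SEMs.
#'
#' @param kin_list list of `kinematics` objects (see
#'   [compute_kinematics()]).
#' @param groups character/factor of group labels, one per session.
#' @return data.frame with one row per group: `group`, `n`,
#'   `distance_mean_m`, `distance_sem_m`, `speed_mean_mm_s`,
#'   `speed_sem_mm_s`.
#' @export
group_totals <- function(kin_list, groups) {
  stopifnot(length(kin_list) == length(groups))
  dist <- vapply(kin_list, function(k) k$total_distance_m, 0)
  sp <- vapply(kin_list, function(k) k$avg_speed_mm_s, 0)
  g <- factor(groups)
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  do.call(rbind, lapply(levels(g), function(lv) {
    i <- g == lv
    data.frame(group = lv, n = sum(i),
               distance_mean_m = mean(dist[i]), distance_sem_m = sem(dist[i]),
               speed_mean_mm_s = mean(sp[i]), speed_sem_mm_s = sem(sp[i]))
  }))
}

#' Pooled-variance two-sample t test
#'
#' Student's pooled two-sample t statistic, computable either from raw
#' samples or from published summary statistics (mean, SEM, n per group):
#' `SD_i = sem_i * sqrt(n_i)`, pooled variance
#' `((n1-1) SD1^2 + (n2-1) SD2^2) / (n1+n2-2)`,
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))`, `df = n1 + n2 - 2`,
#' two-sided p from the t distribution. The pooled (not Welch) form is
#' used so that `df` equals `n1 + n2 - 2`.
#'
#' @param x,y raw samples (ignored when summaries are given).
#' @param m1,sem1,n1,m2,sem2,n2 summary form.
#' @return list: `t`, `df`, `p_value`, `mean_diff`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, m1 = NULL, sem1 = NULL, n1 = NULL,
                         m2 = NULL, sem2 = NULL, n2 = NULL) {
  if (!is.null(x) && !is.null(y)) {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stopf("need at least 2 observations per group")
    m1 <- mean(x); m2 <- mean(y)
    sd1 <- sd(x); sd2 <- sd(y)
  } else {
    if (any(vapply(list(m1, sem1, n1, m2, sem2, n2), is.null, TRUE)))
      stopf("provide either raw samples or the full summary sextet")
    if (n1 < 2 || n2 < 2) stopf("need n >= 2 per group")
    sd1 <- sem1 * sqrt(n1); sd2 <- sem2 * sqrt(n2)
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) {
    if (isTRUE(all.equal(m1, m2))) return(list(t = 0, df = df, p_value = 1,
                                               mean_diff = 0))
    stopf("zero pooled variance with unequal means")
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df), mean_diff = m1 - m2)
}
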