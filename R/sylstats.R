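#' Per-session syllable usage profile
#'
#' Frequency vector over the `K` syllables, either by run onsets (each
#' maximal run of one syllable counts once — the default, emphasizing
#' sequencing) or by frame occupancy.
#'
#' @param labels a `labeled_session` or integer label vector (1-based).
#' @param K number of syllables.
#' @param mode `"onsets"` or `"frames"`.
#' @return a `usage_profile`: `freq` (length K, sums to 1), `mode`.
#' @export
usage_profile <- function(labels, K, mode = c("onsets", "frames")) {
  mode <- match.arg(mode)
  lab <- if (inherits(labels, "labeled_session")) labels$labels else as.integer(labels)
  if (length(lab) == 0) stopf("empty label sequence")
  if (any(lab < 1L | lab > K)) stopf("labels outside 1..%d", K)
  cnt <- if (mode == "onsets") tabulate(label_runs(lab)$state, K) else tabulate(lab, K)
  structure(list(freq = cnt / sum(cnt), mode = mode, K = K),
            class = "usage_profile")
}

#' Bigram-normalized transition matrix of a session
#'
#' Transitions are counted between consecutive distinct-syllable runs
#' (self-transitions are excluded by run-length encoding first; set
#' `exclude_self = FALSE` for the frame-level variant). Each row of `P` is
#' the conditional probability of the next syllable given the current one:
#' pair count divided by the total outgoing occurrences of the first
#' syllable. Syllables with no outgoing transition get an all-zero row and
#' are flagged.
#'
#' @param labels `labeled_session` or integer labels.
#' @param K number of syllables.
#' @param exclude_self drop self-transitions via run-length encoding
#'   (default TRUE).
#' @return a `bigram_matrix`: `P` (K x K), `counts` (K x K integer),
#'   `zero_rows` (logical length K).
#' @export
bigram_matrix <- function(labels, K, exclude_self = TRUE) {
  lab <- if (inherits(labels, "labeled_session")) labels$labels else as.integer(labels)
  seqs <- if (exclude_self) label_runs(lab)$state else lab
  counts <- matrix(0L, K, K)
  if (length(seqs) >= 2) {
    from <- seqs[-length(seqs)]; to <- seqs[-1]
    tab <- table(factor(from, levels = 1:K), factor(to, levels = 1:K))
    counts <- matrix(as.integer(tab), K, K)
  } else {
    warnf("fewer than 2 runs: all-zero bigram matrix")
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  structure(list(P = P, counts = counts, zero_rows = rs == 0, K = K,
                 exclude_self = exclude_self),
            class = "bigram_matrix")
}

#' Group-average transition matrices and their difference
#'
#' Element-wise mean of session transition matrices within each group;
#' rows flagged all-zero in a session are excluded from that row's mean
#' (or count-weight the sessions with `weight = "counts"`). For a pair of
#' groups the difference of group means is returned, exportable as a
#' signed weighted graph.
#'
#' @param matrices_by_group named list: group -> list of `bigram_matrix`.
#' @param pair character vector of two group names to difference (default:
#'   the first two).
#' @param weight `"equal"` (mean over sessions with a valid row) or
#'   `"counts"` (pool counts before normalizing).
#' @return list: `group_means` (named list of K x K matrices),
#'   `difference` (K x K, `pair[1] - pair[2]`), `pair`.
#' @export
group_transition_graphs <- function(matrices_by_group, pair = NULL,
                                    weight = c("equal", "counts")) {
  weight <- match.arg(weight)
  stopifnot(length(matrices_by_group) >= 1)
  means <- lapply(matrices_by_group, function(ms) {
    stopifnot(length(ms) >= 1)
    K <- ms[[1]]$K
    if (weight == "counts") {
      tot <- Reduce(`+`, lapply(ms, `[[`, "counts"))
      rs <- rowSums(tot)
      P <- tot / ifelse(rs > 0, rs, 1); P[rs == 0, ] <- 0
      P
    } else {
      num <- matrix(0, K, K); den <- matrix(0, K, K)
      for (m in ms) {
        ok <- !m$zero_rows
        num[ok, ] <- num[ok, ] + m$P[ok, , drop = FALSE]
        den[ok, ] <- den[ok, ] + 1
      }
      out <- num / ifelse(den > 0, den, 1)
      out[den == 0] <- 0
      out
    }
  })
  if (is.null(pair)) pair <- names(means)[seq_len(min(2, length(means)))]
  diff <- if (length(pair) == 2) means[[pair[1]]] - means[[pair[2]]] else NULL
  list(group_means = means, difference = diff, pair = pair)
}

#' Export a (difference) transition matrix as a GraphML file
#'
#' Nodes are syllables; edges carry the (signed) transition weight.
#' Edges with |weight| below `min_weight` are dropped.
#'
#' @param M K x K matrix; @param path output file; @param min_weight edge
#'   threshold.
#' @export
write_transition_graphml <- function(M, path, min_weight = 0) {
  g <- igraph::graph_from_adjacency_matrix(M, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  if (min_weight > 0)
    g <- igraph::delete_edges(g, which(abs(igraph::E(g)$weight) < min_weight))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2` with `M = (P + Q)/2` and the
#' convention `0 log 0 = 0`. In base 2 the value lies in [0, 1]. Inputs off
#' the simplex by less than 1e-6 are renormalized with a warning; larger
#' deviations are errors.
#'
#' @param P,Q non-negative vectors (matrices are flattened).
#' @param base logarithm base (2 default).
#' @export
jensen_shannon_divergence <- function(P, Q, base = 2) {
  P <- as.vector(P); Q <- as.vector(Q)
  if (length(P) != length(Q)) stopf("P and Q must have equal length")
  for (nm in c("P", "Q")) {
    v <- get(nm)
    if (any(v < 0)) stopf("%s has negative entries", nm)
    s <- sum(v)
    if (abs(s - 1) > 1e-6) stopf("%s is not normalized (sum = %.8f)", nm, s)
    if (abs(s - 1) > 1e-12)
      warnf("%s off the simplex by %.2g; renormalizing", nm, abs(s - 1))
    if (s != 1) assign(nm, v / s)
  }
  M <- (P + Q) / 2
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v, base = base)) }
  ent(M) - (ent(P) + ent(Q)) / 2
}

#' Flatten a session's transitions into a distribution for JSD
#'
#' The default representation is the joint bigram distribution
#' `counts / sum(counts)` — the conditional matrix weighted by how often
#' each source syllable actually occurs. `"conditional"` instead averages
#' the per-row JSD of the conditional matrices over rows valid in both
#' sessions (see [session_jsd()]).
#'
#' @param bm a `bigram_matrix`.
#' @export
bigram_joint_distribution <- function(bm) {
  tot <- sum(bm$counts)
  if (tot == 0) return(matrix(0, bm$K, bm$K))
  bm$counts / tot
}

#' JSD between two sessions' transition structure
#' @param bm1,bm2 `bigram_matrix` objects; @param representation
#'   `"joint"` (default) or `"conditional"`; @param base log base.
#' @export
session_jsd <- function(bm1, bm2, representation = c("joint", "conditional"),
                        base = 2) {
  representation <- match.arg(representation)
  if (representation == "joint") {
    jensen_shannon_divergence(bigram_joint_distribution(bm1),
                              bigram_joint_distribution(bm2), base = base)
  } else {
    ok <- !bm1$zero_rows & !bm2$zero_rows
    if (!any(ok)) return(0)
    mean(vapply(which(ok), function(i)
      jensen_shannon_divergence(bm1$P[i, ], bm2$P[i, ], base = base), 0))
  }
}

#' Permutation test on cross-group transition-structure divergence
#'
#' The observed statistic is the mean JSD over all cross-group session
#' pairs (within-group pairs excluded). Under the null, session group
#' labels are reshuffled `n_perm` times preserving group sizes and the
#' mean cross-group JSD recomputed; the p-value is the fraction of
#' permutations with a statistic greater than or equal to the observed one
#' (no add-one correction by default).
#'
#' @param groupA,groupB lists of `bigram_matrix` objects (or of
#'   `labeled_session`s / label vectors, converted with `K`).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param K needed only when raw labels are passed.
#' @param representation,base see [session_jsd()].
#' @param add_one if TRUE use the (b + 1) / (n + 1) estimator.
#' @return a `jsd_test`: `observed_mean_jsd`, `null` (length n_perm),
#'   `p_value`, `n_perm`, `seed`.
#' @export
jsd_permutation_test <- function(groupA, groupB, n_perm = 10000L, seed = 1L,
                                 K = NULL,
                                 representation = c("joint", "conditional"),
                                 base = 2, add_one = FALSE) {
  representation <- match.arg(representation)
  if (!is_count(n_perm)) stopf("n_perm must be >= 1")
  to_bm <- function(x) {
    if (inherits(x, "bigram_matrix")) return(x)
    if (is.null(K)) stopf("K is required when passing raw labels")
    bigram_matrix(x, K)
  }
  A <- lapply(groupA, to_bm); B <- lapply(groupB, to_bm)
  nA <- length(A); nB <- length(B)
  if (nA < 1 || nB < 1) stopf("both groups need at least one session")
  if (nA < 2 && nB < 2) warnf("degenerate design: both groups have a single session")
  all_bm <- c(A, B)
  n <- nA + nB
  # pairwise JSD between all sessions, computed once
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- session_jsd(all_bm[[i]], all_bm[[j]],
                                      representation, base)
  }
  cross_mean <- function(ia) mean(D[ia, setdiff(seq_len(n), ia), drop = FALSE])
  observed <- cross_mean(seq_len(nA))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) cross_mean(sample.int(n, nA)), 0)
  })
  hits <- sum(null >= observed)
  p <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  structure(list(observed_mean_jsd = observed, null = null, p_value = p,
                 n_perm = as.integer(n_perm), seed = seed,
                 representation = representation, base = base),
            class = "jsd_test")
}

#' @export
print.jsd_test <- function(x, ...) {
  cat(sprintf("<jsd_test> observed mean cross-group JSD = %.4f (base %g), p = %.4g (%d permutations)\n",
              x$observed_mean_jsd, x$base, x$p_value, x$n_perm))
  invisible(x)
}

#' Low-dimensional embedding of session usage vectors
#'
#' `"pca2"`: centered PCA of the usage vectors, top-2 scores per session.
#' `"lda1"`: one ridge-regularized Fisher discriminant axis per declared
#' subset of sessions, discriminating a two-level class label; per-class
#' score densities are smoothed with a Gaussian KDE (Scott bandwidth).
#'
#' @param usage matrix (sessions x K) of usage frequencies, or list of
#'   `usage_profile`s.
#' @param meta data.frame of session metadata (one row per session);
#'   required for `"lda1"`.
#' @param method `"pca2"` or `"lda1"`.
#' @param class_col metadata column holding the two-level class for lda1.
#' @param subset_cols metadata columns defining the subsets (one
#'   discriminant per unique combination); NULL = one global axis.
#' @param ridge within-class scatter regularization (default 1e-6 of the
#'   mean diagonal).
#' @return for `"pca2"` a list with `scores` (n x 2) and
#'   `explained_variance_ratio`; for `"lda1"` a list of per-subset results:
#'   `scores`, `class`, `densities` (per class KDE), `axis`.
#' @export
usage_embedding <- function(usage, meta = NULL, method = c("pca2", "lda1"),
                            class_col = "genotype", subset_cols = NULL,
                            ridge = 1e-6) {
  method <- match.arg(method)
  U <- if (is.list(usage) && !is.matrix(usage))
    do.call(rbind, lapply(usage, function(u) u$freq)) else as.matrix(usage)
  if (method == "pca2") {
    if (nrow(U) < 3) stopf("pca2 needs at least 3 sessions")
    Uc <- sweep(U, 2, colMeans(U))
    sv <- svd(Uc, nu = 2, nv = 2)
    scores <- Uc %*% sv$v
    if (all(Uc == 0)) return(list(scores = matrix(0, nrow(U), 2),
                                  explained_variance_ratio = c(0, 0)))
    evr <- sv$d[1:2]^2 / sum(sv$d^2)
    return(list(scores = scores, explained_variance_ratio = evr))
  }
  stopifnot(!is.null(meta), nrow(meta) == nrow(U))
  subsets <- if (is.null(subset_cols)) list(all = seq_len(nrow(U)))
  else split(seq_len(nrow(U)), interaction(meta[subset_cols], drop = TRUE))
  lapply(subsets, function(idx) {
    cls <- factor(meta[[class_col]][idx])
    if (nlevels(cls) != 2) stopf("lda1 needs exactly 2 classes; got %d", nlevels(cls))
    X <- U[idx, , drop = FALSE]
    m1 <- colMeans(X[cls == levels(cls)[1], , drop = FALSE])
    m2 <- colMeans(X[cls == levels(cls)[2], , drop = FALSE])
    Sw <- matrix(0, ncol(X), ncol(X))
    for (lv in levels(cls)) {
      Xi <- X[cls == lv, , drop = FALSE]
      if (nrow(Xi) > 1) Sw <- Sw + stats::cov(Xi) * (nrow(Xi) - 1)
    }
    lam <- ridge * (sum(diag(Sw)) / ncol(Sw) + 1)
    w <- solve(Sw + diag(lam, ncol(Sw)), m2 - m1)
    sc <- as.vector(X %*% w)
    dens <- lapply(levels(cls), function(lv) {
      v <- sc[cls == lv]
      if (length(v) >= 2 && sd(v) > 0)
        density(v, bw = bw.nrd(v)) else NULL
    })
    names(dens) <- levels(cls)
    list(scores = sc, class = cls, densities = dens, axis = w)
  })
}
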