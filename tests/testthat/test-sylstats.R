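test_that("usage profiles match hand counts", {
  lab <- c(1L, 1L, 2L, 2L, 1L)        # runs: 1, 2, 1
  expect_equal(usage_profile(lab, K = 2, mode = "onsets")$freq, c(2/3, 1/3))
  expect_equal(usage_profile(lab, K = 2, mode = "frames")$freq, c(3/5, 2/5))
  expect_equal(usage_profile(rep(2L, 10), K = 3)$freq, c(0, 1, 0))
  expect_error(usage_profile(integer(0), K = 2), "empty")
  expect_lt(abs(sum(usage_profile(lab, 2)$freq) - 1), 1e-12)
})

test_that("bigram matrices match hand counts and flag dead rows", {
  # run sequence 1 -> 2 -> 1 -> 2
  bm <- bigram_matrix(c(1L, 2L, 2L, 1L, 2L), K = 2)
  expect_equal(bm$P, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sum(bm$counts), 3)
  # a state only appearing at the end has a zero, flagged row
  bm2 <- bigram_matrix(c(1L, 2L, 1L, 3L), K = 3)
  expect_true(bm2$zero_rows[3])
  expect_equal(bm2$P[3, ], rep(0, 3))
  expect_lt(max(abs(rowSums(bm2$P)[!bm2$zero_rows] - 1)), 1e-12)
  # single-run sequence: all-zero with a warning
  expect_warning(bm3 <- bigram_matrix(rep(1L, 5), K = 2), "fewer than 2 runs")
  expect_equal(sum(bm3$counts), 0)
})

test_that("empirical bigrams converge to the planted conditional matrix", {
  spec <- test_gts(3, duration_bias = 10)
  z <- gen_markov_labels(spec, 1e5, seed = 10)
  bm <- bigram_matrix(z, K = 3)
  # removing self-transitions leaves the base between-state conditional
  expect_lt(max(abs(bm$P - spec$transition)), 0.03)
  # error shrinks with T at roughly root-T rate
  z_small <- gen_markov_labels(spec, 2e4, seed = 11)
  e_small <- max(abs(bigram_matrix(z_small, K = 3)$P - spec$transition))
  z_big <- gen_markov_labels(spec, 8e4, seed = 12)
  e_big <- max(abs(bigram_matrix(z_big, K = 3)$P - spec$transition))
  expect_lt(e_big, e_small)
  expect_lt(e_small / e_big, 6)
})

test_that("group transition means and differences behave like convex averages", {
  spec <- test_gts(3, duration_bias = 5)
  mk <- function(seed, sp = spec) bigram_matrix(gen_markov_labels(sp, 1e5, seed = seed), K = 3)
  A <- lapply(1:5, function(i) mk(i))
  # identical groups: difference is 0
  g <- group_transition_graphs(list(a = A, b = A))
  expect_equal(g$difference, matrix(0, 3, 3))
  # rows of the group mean stay stochastic
  expect_lt(max(abs(rowSums(g$group_means$a) - 1)), 1e-9)
  # planted 0.2 shift shows up in the difference entry
  sh <- shift_transition_mass(spec, 1, 2, 3, 0.2)
  B <- lapply(6:10, function(i) mk(i, sh))
  g2 <- group_transition_graphs(list(a = A, b = B))
  expect_lt(abs(g2$difference[1, 2] - 0.2), 0.05)
  expect_lt(abs(g2$difference[1, 3] + 0.2), 0.05)
  # graph export writes parseable GraphML
  f <- tempfile(fileext = ".graphml")
  write_transition_graphml(g2$difference, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})

test_that("JSD matches an independent KL-form oracle and its axioms", {
  # closed forms
  expect_equal(jensen_shannon_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1)), 1)
  # oracle: JSD = (KL(P||M) + KL(Q||M)) / 2, a different decomposition
  kl <- function(p, q) { i <- p > 0; sum(p[i] * log2(p[i] / q[i])) }
  jsd_oracle <- function(p, q) { m <- (p + q) / 2; (kl(p, m) + kl(q, m)) / 2 }
  set.seed(3)
  for (i in 1:25) {
    p <- rgamma(12, 1); p <- p / sum(p)
    q <- rgamma(12, 1); q <- q / sum(q)
    v <- jensen_shannon_divergence(p, q)
    expect_lt(abs(v - jsd_oracle(p, q)), 1e-12)
    expect_equal(v, jensen_shannon_divergence(q, p))     # symmetry
    expect_gte(v, 0); expect_lte(v, 1)                    # bounds (base 2)
  }
  expect_error(jensen_shannon_divergence(c(0.5, 0.6), c(0.5, 0.5)),
               "not normalized")
})

test_that("the JSD permutation test is symmetric, deterministic and honest", {
  spec <- test_gts(5, dim = 2, duration_bias = 8)
  A <- lapply(1:4, function(i) gen_markov_labels(spec, 2e4, seed = 100 + i))
  B <- lapply(1:4, function(i) gen_markov_labels(spec, 2e4, seed = 200 + i))
  r1 <- jsd_permutation_test(A, B, n_perm = 200, seed = 5, K = 5)
  # swapping the groups changes nothing (equal sizes, same seed)
  r2 <- jsd_permutation_test(B, A, n_perm = 200, seed = 5, K = 5)
  expect_equal(r1$observed_mean_jsd, r2$observed_mean_jsd)
  expect_equal(r1$p_value, r2$p_value)
  # determinism
  r3 <- jsd_permutation_test(A, B, n_perm = 200, seed = 5, K = 5)
  expect_identical(r1$null, r3$null)
  # p-value definition: fraction of null >= observed
  expect_equal(r1$p_value, mean(r1$null >= r1$observed_mean_jsd))
  # identical sessions in both groups: observed 0, p = 1
  same <- lapply(1:3, function(i) gen_markov_labels(spec, 5000, seed = 42))
  r4 <- jsd_permutation_test(same, same, n_perm = 50, seed = 1, K = 5)
  expect_equal(r4$observed_mean_jsd, 0)
  expect_equal(r4$p_value, 1)
  expect_error(jsd_permutation_test(A, B, n_perm = 0, seed = 1, K = 5), "n_perm")
})

test_that("a planted transition shift is detected while the null is calibrated", {
  spec <- test_gts(5, dim = 2, duration_bias = 8)
  shifted <- shift_transition_mass(spec, 1, 2, 3, 0.2)
  ps_null <- ps_alt <- numeric(12)
  for (r in 1:12) {
    A <- lapply(1:5, function(i) gen_markov_labels(spec, 2e4, seed = 7000 + 10 * r + i))
    B0 <- lapply(1:5, function(i) gen_markov_labels(spec, 2e4, seed = 8000 + 10 * r + i))
    B1 <- lapply(1:5, function(i) gen_markov_labels(shifted, 2e4, seed = 8000 + 10 * r + i))
    ps_null[r] <- jsd_permutation_test(A, B0, n_perm = 200, seed = r, K = 5)$p_value
    ps_alt[r] <- jsd_permutation_test(A, B1, n_perm = 200, seed = r, K = 5)$p_value
  }
  # planted effect: overwhelmingly significant
  expect_gte(mean(ps_alt < 0.05), 0.8)
  # null p-values spread over [0, 1] rather than piling near 0
  expect_lte(mean(ps_null < 0.05), 0.25)
  expect_gt(mean(ps_null), 0.2)
})

test_that("usage embeddings separate planted clusters", {
  set.seed(9)
  # two usage clusters separated along one direction, 5x the noise SD
  base1 <- c(0.4, 0.3, 0.2, 0.1); base2 <- c(0.1, 0.2, 0.3, 0.4)
  mk <- function(b) { u <- pmax(b + rnorm(4, sd = 0.012), 1e-4); u / sum(u) }
  U <- rbind(t(replicate(6, mk(base1))), t(replicate(6, mk(base2))))
  emb <- usage_embedding(U, method = "pca2")
  pc1 <- emb$scores[, 1]
  expect_true(max(pc1[1:6]) < min(pc1[7:12]) || min(pc1[1:6]) > max(pc1[7:12]))
  # identical usage vectors: all scores 0
  U0 <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), 5), 5, 4, byrow = TRUE)
  expect_lt(max(abs(usage_embedding(U0, method = "pca2")$scores)), 1e-12)
  # LDA on linearly separable classes gives disjoint projected ranges
  meta <- data.frame(genotype = rep(c("control", "mutant"), each = 6))
  lda <- usage_embedding(U, meta, method = "lda1")$all
  s1 <- lda$scores[lda$class == "control"]; s2 <- lda$scores[lda$class == "mutant"]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))
})
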