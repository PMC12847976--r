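test_that("vehicle normalization follows its defining arithmetic", {
  layout <- data.frame(plate = "P1", chip = c("a", "b", "c"),
                       treatment = c("DMSO", "DMSO", "drug"))
  vals <- data.frame(chip = c("a", "b", "c"), viability = c(90, 110, 80))
  out <- normalize_to_vehicle(vals, layout)
  expect_equal(out$viability[out$chip == "c"], 80)
  expect_equal(mean(out$viability[out$chip %in% c("a", "b")]), 100)
  # all equal in -> all 100
  vals2 <- data.frame(chip = c("a", "b", "c"), viability = c(5, 5, 5))
  expect_true(all(normalize_to_vehicle(vals2, layout)$viability == 100))
})

test_that("normalization is invariant to per-plate rescaling", {
  scr <- generate_screen(null_design(8))
  nv1 <- normalize_to_vehicle(scr$viability, scr$layout)
  v2 <- scr$viability
  v2$viability <- v2$viability * 7.3
  nv2 <- normalize_to_vehicle(v2, scr$layout)
  expect_equal(nv1$viability, nv2$viability, tolerance = 1e-12)
})

test_that("a plate without vehicle chips raises a named error", {
  layout <- data.frame(plate = c("P1", "P2"), chip = c("a", "b"),
                       treatment = c("DMSO", "drug"))
  vals <- data.frame(chip = c("a", "b"), viability = c(1, 2))
  expect_error(normalize_to_vehicle(vals, layout), "P2")
})

test_that("replicate correlation behaves at its limits and matches covariance", {
  x <- c(1, 3, 7, 2, 9)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, -x), -1)
  expect_true(is.na(replicate_correlation(x, rep(2, 5))))
  expect_error(replicate_correlation(1:2, 2:3), "3")
  # independent covariance-based computation
  y <- c(2, 1, 8, 3, 7)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(replicate_correlation(x, y), r_oracle, tolerance = 1e-12)
})

test_that("replicate pairs from a noisy screen correlate strongly", {
  trts <- c(list(DMSO = list()),
            stats::setNames(lapply(seq(0.4, 1, length.out = 6),
                                   function(m) list(viability = m)),
                            paste0("T", 1:6)))
  des <- screen_design(donors = "D1", treatments = trts, replicates = 2,
                       control_replicates = 2, plates_per_donor = 1,
                       replicate_cv = 0.10, seed = 12)
  scr <- generate_screen(des)
  m <- merge(scr$viability, scr$layout, by = "chip")
  r1 <- m$viability[m$replicate == 1][order(m$treatment[m$replicate == 1])]
  r2 <- m$viability[m$replicate == 2][order(m$treatment[m$replicate == 2])]
  expect_gt(replicate_correlation(r1, r2), 0.8)
})

test_that("PCA embedding is deterministic with orthonormal loadings", {
  scr <- generate_screen(null_design(4))
  emb <- embed_descriptors(scr$descriptors, "pca", seed = 1)
  L <- attr(emb, "loadings")
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  emb2 <- embed_descriptors(scr$descriptors, "pca", seed = 99)
  expect_identical(emb, emb2)  # PCA ignores the seed entirely
  ev <- attr(emb, "explained_variance")
  expect_equal(sum(ev), 1, tolerance = 1e-12)
})

test_that("collinear descriptors give PC1 explained variance of one", {
  n <- 20
  t <- seq_len(n)
  X <- data.frame(chip = paste0("c", t))
  for (k in 1:15) X[[paste0("d", k)]] <- t * k - 3 * k
  emb <- embed_descriptors(X, "pca", seed = 1)
  expect_equal(attr(emb, "explained_variance")[1], 1, tolerance = 1e-10)
})

test_that("t-SNE is deterministic given a seed and validates perplexity", {
  scr <- generate_screen(null_design(6))
  a <- embed_descriptors(scr$descriptors, "tsne", seed = 3)
  b <- embed_descriptors(scr$descriptors, "tsne", seed = 3)
  expect_identical(a, b)
  expect_error(embed_descriptors(scr$descriptors, "tsne", seed = 1,
                                 perplexity = nrow(scr$descriptors)),
               "perplexity")
})

test_that("identical groups compare as non-significant", {
  vals <- rep(c(1, 2, 3, 4), 2)
  groups <- rep(c("a", "b"), each = 4)
  res <- compare_groups(vals, groups, design = "nonparametric")
  expect_gte(res$p_adj, 0.99)
  expect_equal(res$stars, "")
})

test_that("Dunn z-statistics match a hand rank computation", {
  res <- dunn_test(1:9, rep(c("a", "b", "c"), each = 3))
  # pooled ranks 1..9; mean ranks 2, 5, 8; se = sqrt((9*10/12)*(2/3))
  se <- sqrt((9 * 10 / 12) * (2 / 3))
  expect_equal(res$z[res$group1 == "a" & res$group2 == "b"], -3 / se,
               tolerance = 1e-12)
  expect_equal(res$z[res$group1 == "a" & res$group2 == "c"], -6 / se,
               tolerance = 1e-12)
  # tie correction: duplicate values shrink the variance term
  res_tie <- dunn_test(c(1, 1, 2, 3, 3, 4, 5, 6, 7),
                       rep(c("a", "b", "c"), each = 3))
  ties <- table(c(1, 1, 2, 3, 3, 4, 5, 6, 7))
  Tc <- sum(ties^3 - ties) / (12 * 8)
  se_tie <- sqrt((9 * 10 / 12 - Tc) * (2 / 3))
  rk <- rank(c(1, 1, 2, 3, 3, 4, 5, 6, 7))
  zab <- (mean(rk[1:3]) - mean(rk[4:6])) / se_tie
  expect_equal(res_tie$z[res_tie$group1 == "a" & res_tie$group2 == "b"], zab,
               tolerance = 1e-12)
})

test_that("the auto gate routes gaussian data parametric and skewed data not", {
  set.seed(5)
  g <- rep(c("a", "b", "c"), each = 12)
  gauss <- stats::rnorm(36)
  res_g <- compare_groups(gauss, g)
  expect_equal(attr(res_g, "gate")$path, "parametric")
  expect_true(all(res_g$test == "anova_tukey"))
  skew <- stats::rlnorm(36, sdlog = 2.5)
  res_s <- compare_groups(skew, g)
  expect_equal(attr(res_s, "gate")$path, "nonparametric")
  expect_true(all(res_s$test == "kw_dunn"))
})

test_that("zero-variance groups fall back to the nonparametric path", {
  vals <- c(rep(5, 4), stats::rnorm(4))
  g <- rep(c("a", "b"), each = 4)
  expect_warning(res <- compare_groups(vals, g, design = "parametric"),
                 "zero variance")
  expect_true(all(res$test == "kw_dunn"))
})

test_that("Wilcoxon analyte tests give p = 1 for identical groups and use BH", {
  layout <- data.frame(chip = paste0("c", 1:12), plate = "P1",
                       treatment = rep(c("DMSO", "same", "diff"), each = 4))
  an <- data.frame(chip = paste0("c", 1:12),
                   A = c(1, 2, 3, 4, 1, 2, 3, 4, 11, 12, 13, 14))
  res <- analyte_tests(an, layout)
  expect_equal(res$p_adj[res$treatment == "same"], 1)
  expect_lt(res$p[res$treatment == "diff"], 0.05)
})

test_that("BH adjustment reproduces the step-up formula on a printed example", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  # monotonicity property on random p-vectors
  set.seed(9)
  for (i in 1:5) {
    praw <- stats::runif(20)
    adj <- stats::p.adjust(praw, "BH")
    o <- order(praw)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(adj >= praw))
  }
})

test_that("Welch test matches its closed form and symmetry", {
  w <- welch_compare(c(1, 2, 3), c(2, 3, 4))
  # hand formulas: means 2 and 3, variances 1 and 1, n = 3
  t_hand <- (2 - 3) / sqrt(1 / 3 + 1 / 3)
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(w$statistic, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  sw <- welch_compare(c(2, 3, 4), c(1, 2, 3))
  expect_equal(sw$statistic, -w$statistic)
  expect_equal(sw$p, w$p)
  id <- welch_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$statistic, 0)
  expect_equal(id$p, 1)
  # degenerate equal constants
  expect_equal(welch_compare(c(2, 2), c(2, 2))$p, 1)
})

test_that("significance stars follow the published thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("", "*", "**", "***", "****"))
})

test_that("the heatmap matrix is signed by effect direction", {
  layout <- data.frame(chip = paste0("c", 1:12), plate = "P1",
                       treatment = rep(c("DMSO", "up", "down"), each = 4))
  an <- data.frame(chip = paste0("c", 1:12),
                   A = c(5, 6, 7, 8, 50, 60, 70, 80, 0.5, 0.6, 0.7, 0.8))
  res <- analyte_tests(an, layout)
  hm <- heatmap_matrix(res, an, layout)
  expect_gt(hm["up", "A"], 0)
  expect_lt(hm["down", "A"], 0)
})
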