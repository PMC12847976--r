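#' Normalize per-chip viability to the plate vehicle-control mean
#'
#' Each chip's value becomes `100 * raw / mean(vehicle raws on its plate)`,
#' the standard percent-of-control normalization that makes plates and
#' batches comparable.
#'
#' @param values Data frame with columns `chip` and a value column (second
#'   column, e.g. `viability`).
#' @param layout Data frame with columns `plate`, `chip`, `treatment`.
#' @param control Vehicle-control treatment label (default "DMSO").
#' @return The input data frame with the value column replaced by percent
#'   of plate control.
#' @export
normalize_to_vehicle <- function(values, layout, control = "DMSO") {
  stopifnot("chip" %in% names(values), ncol(values) >= 2)
  m <- merge(values, layout[, c("plate", "chip", "treatment")], by = "chip",
             sort = FALSE)
  vcol <- names(values)[2]
  for (pl in unique(m$plate)) {
    sel <- m$plate == pl
    veh <- m[[vcol]][sel & m$treatment == control]
    if (!length(veh))
      stop("plate '", pl, "' has no vehicle-control ('", control, "') chips")
    m[[vcol]][sel] <- 100 * m[[vcol]][sel] / mean(veh)
  }
  out <- m[, c("chip", vcol)]
  out[match(values$chip, out$chip), , drop = FALSE]
}

#' Replicate reproducibility (Pearson r)
#'
#' Pearson product-moment correlation between paired replicate readouts.
#'
#' @param x,y Numeric vectors of paired replicate values (>= 3 pairs).
#' @return Pearson r, or `NA` if either vector has zero variance.
#' @export
replicate_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 replicate pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Low-dimensional embedding of chip descriptor profiles
#'
#' Standardizes the descriptor columns (zero mean, unit variance; columns
#' with missing values or zero variance are dropped) and embeds chips in
#' 2-D by PCA or t-SNE.  PCA uses a fixed sign convention (the loading
#' with largest magnitude on each component is positive) so results are
#' fully deterministic; t-SNE is deterministic given the seed.
#'
#' @param descriptors Data frame with a `chip` column and numeric
#'   descriptor columns.
#' @param method `"pca"` or `"tsne"`.
#' @param seed Integer seed (required for t-SNE).
#' @param perplexity t-SNE perplexity; default `min(30, n/4)`, must be
#'   below `n/3`.
#' @return Data frame `chip`, `dim1`, `dim2`; for PCA the attribute
#'   `explained_variance` holds per-component variance fractions and
#'   `loadings` the rotation matrix.
#' @export
embed_descriptors <- function(descriptors, method = c("pca", "tsne"),
                              seed = 1L, perplexity = NULL) {
  method <- match.arg(method)
  num <- descriptors[, setdiff(names(descriptors), "chip"), drop = FALSE]
  keep <- vapply(num, function(v) !anyNA(v) && stats::sd(v) > 0, logical(1))
  X <- scale(as.matrix(num[, keep, drop = FALSE]))
  n <- nrow(X)
  if (n < 3) stop("fewer chips than embedding dimensions")
  if (method == "pca") {
    pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
    rot <- pc$rotation
    for (j in seq_len(ncol(rot))) {
      if (rot[which.max(abs(rot[, j])), j] < 0) {
        rot[, j] <- -rot[, j]; pc$x[, j] <- -pc$x[, j]
      }
    }
    out <- data.frame(chip = descriptors$chip,
                      dim1 = pc$x[, 1], dim2 = pc$x[, 2])
    attr(out, "explained_variance") <- pc$sdev^2 / sum(pc$sdev^2)
    attr(out, "loadings") <- rot
    out
  } else {
    if (is.null(perplexity)) perplexity <- min(30, floor(n / 4))
    if (perplexity >= n / 3) stop("perplexity must be < n/3")
    with_seed(seed, {
      ts <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                         check_duplicates = FALSE, pca = TRUE)
      data.frame(chip = descriptors$chip,
                 dim1 = ts$Y[, 1], dim2 = ts$Y[, 2])
    })
  }
}

#' Significance stars for adjusted p-values
#' @param p Numeric vector of (adjusted) p-values.
#' @return Character vector: `****` p < 0.0001, `***` < 0.001, `**` < 0.01,
#'   `*` < 0.05, empty otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 1e-4, "****",
      ifelse(p < 1e-3, "***",
        ifelse(p < 1e-2, "**",
          ifelse(p < 0.05, "*", "")))))
}

#' Dunn's post-hoc test (pairwise rank-sum z after Kruskal-Wallis)
#'
#' Pairwise z statistics on pooled mid-ranks with the tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tied groups; two-sided normal
#' p-values, unadjusted.
#'
#' @param values Numeric vector.
#' @param groups Factor/character of group labels.
#' @return Data frame: group1, group2, z, p.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- unique(groups)
  rbar <- vapply(lev, function(g) mean(rk[groups == g]), numeric(1))
  ns <- vapply(lev, function(g) sum(groups == g), numeric(1))
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / ns[i] + 1 / ns[j]))
    z <- unname((rbar[i] - rbar[j]) / se)
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p = res["p", ], row.names = NULL)
}

#' Pairwise group comparison with a normality-gated test choice
#'
#' In `"auto"` mode a Shapiro-Wilk test on each group at alpha = 0.05
#' gates the path: if every group is compatible with normality (and has
#' positive variance), one-way ANOVA with Tukey HSD post-hoc comparisons
#' is used; otherwise Kruskal-Wallis with Dunn's post-hoc test.  Post-hoc
#' p-values are then adjusted across all pairwise comparisons
#' (Bonferroni by default).
#'
#' @param values Numeric vector of readouts.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @param design `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param adjust `"bonferroni"` or `"bh"`.
#' @return Data frame, one row per group pair: group1, group2, test,
#'   statistic, p, p_adj, stars; attribute `gate` records the path taken
#'   and the per-group Shapiro p-values.
#' @export
compare_groups <- function(values, groups,
                           design = c("auto", "parametric", "nonparametric"),
                           adjust = c("bonferroni", "bh")) {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  ns <- vapply(lev, function(g) sum(groups == g), numeric(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  sds <- vapply(lev, function(g) stats::sd(values[groups == g]), numeric(1))
  shapiro_p <- rep(NA_real_, length(lev))
  path <- design
  if (design == "auto") {
    shapiro_p <- vapply(lev, function(g) {
      v <- values[groups == g]
      if (length(v) < 3 || stats::sd(v) == 0) return(0)
      stats::shapiro.test(v)$p.value
    }, numeric(1))
    path <- if (all(shapiro_p > 0.05)) "parametric" else "nonparametric"
  }
  if (path == "parametric" && any(sds == 0)) {
    warning("a group has zero variance; falling back to the nonparametric path")
    path <- "nonparametric"
  }
  if (path == "parametric") {
    df <- data.frame(y = values, g = factor(groups))
    fit <- stats::aov(y ~ g, data = df)
    tk <- stats::TukeyHSD(fit)$g
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    res <- data.frame(group1 = vapply(prs, `[`, "", 2),
                      group2 = vapply(prs, `[`, "", 1),
                      test = "anova_tukey",
                      statistic = tk[, "diff"],
                      p = tk[, "p adj"], row.names = NULL)
  } else {
    dn <- dunn_test(values, groups)
    res <- data.frame(group1 = dn$group1, group2 = dn$group2,
                      test = "kw_dunn", statistic = dn$z, p = dn$p,
                      row.names = NULL)
  }
  res$p_adj <- stats::p.adjust(res$p,
                               method = if (adjust == "bh") "BH" else "bonferroni")
  res$stars <- significance_stars(res$p_adj)
  attr(res, "gate") <- list(path = path, shapiro_p = shapiro_p)
  res
}

#' Wilcoxon rank-sum tests of every treatment against control, per analyte
#'
#' For each analyte and each non-control treatment, a two-sided unpaired
#' Wilcoxon rank-sum test of treated chips versus control chips, with
#' Benjamini-Hochberg adjustment across the full analyte x treatment
#' family (or per analyte).
#'
#' @param analytes Data frame: `chip` column plus one numeric column per
#'   analyte.
#' @param layout Data frame with `chip`, `treatment`.
#' @param control Control treatment label.
#' @param adjust `"bh"` (default) or `"bonferroni"`.
#' @param family `"global"` (adjust across all analyte x treatment pairs)
#'   or `"per_analyte"`.
#' @return Data frame: analyte, treatment, statistic (W), p, p_adj, stars.
#' @export
analyte_tests <- function(analytes, layout, control = "DMSO",
                          adjust = c("bh", "bonferroni"),
                          family = c("global", "per_analyte")) {
  adjust <- match.arg(adjust)
  family <- match.arg(family)
  m <- merge(analytes, layout[, c("chip", "treatment")], by = "chip",
             sort = FALSE)
  if (!any(m$treatment == control))
    stop("control group '", control, "' not present")
  acols <- setdiff(names(analytes), "chip")
  trts <- setdiff(unique(m$treatment), control)
  res <- do.call(rbind, lapply(acols, function(a) {
    ctl <- m[[a]][m$treatment == control]
    do.call(rbind, lapply(trts, function(tr) {
      x <- m[[a]][m$treatment == tr]
      if (length(unique(c(x, ctl))) == 1L) {
        w <- length(x) * length(ctl) / 2; p <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x, ctl, exact = NULL))
        w <- unname(wt$statistic); p <- wt$p.value
      }
      data.frame(analyte = a, treatment = tr, statistic = w, p = p)
    }))
  }))
  meth <- if (adjust == "bh") "BH" else "bonferroni"
  if (family == "global") {
    res$p_adj <- stats::p.adjust(res$p, method = meth)
  } else {
    res$p_adj <- stats::ave(res$p, res$analyte,
                            FUN = function(p) stats::p.adjust(p, method = meth))
  }
  res$stars <- significance_stars(res$p_adj)
  res
}

#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with the Welch-Satterthwaite degrees of
#' freedom, as used to compare biomarker levels between patient-derived
#' and cell-line cultures.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return List: statistic (t), df, p.
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, df = NA_real_, p = 1))
    return(list(statistic = Inf * sign(mean(a) - mean(b)), df = NA_real_,
                p = 0))
  }
  t <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(t$statistic), df = unname(t$parameter),
       p = t$p.value)
}

#' Signed -log10 adjusted-p matrix for heatmaps
#'
#' Builds the treatment x readout matrix of `sign(effect) *
#' -log10(p_adj)` used for screen-overview heatmaps, where the sign is the
#' direction of the treatment median relative to control.
#'
#' @param results Data frame from [analyte_tests()].
#' @param analytes,layout,control As in [analyte_tests()].
#' @return Numeric matrix, treatments in rows, readouts in columns.
#' @export
heatmap_matrix <- function(results, analytes, layout, control = "DMSO") {
  m <- merge(analytes, layout[, c("chip", "treatment")], by = "chip",
             sort = FALSE)
  trts <- unique(results$treatment)
  acols <- unique(results$analyte)
  out <- matrix(0, length(trts), length(acols),
                dimnames = list(trts, acols))
  for (i in seq_len(nrow(results))) {
    a <- results$analyte[i]; tr <- results$treatment[i]
    dir <- sign(stats::median(m[[a]][m$treatment == tr]) -
                  stats::median(m[[a]][m$treatment == control]))
    out[tr, a] <- dir * -log10(max(results$p_adj[i], 1e-300))
  }
  out
}

#' Mean silhouette of one group against another in an embedding
#'
#' @param coords Data frame with `dim1`, `dim2`.
#' @param labels Group label per row.
#' @param group Group whose mean silhouette width is returned.
#' @return Mean silhouette width of `group` members.
#' @export
group_silhouette <- function(coords, labels, group) {
  lab <- as.integer(factor(labels))
  d <- stats::dist(as.matrix(coords[, c("dim1", "dim2")]))
  sil <- cluster::silhouette(lab, d)
  mean(sil[labels == group, "sil_width"])
}
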