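#' pOverA low-coverage gene filter
#'
#' Genes with zero counts across all samples are removed first; a remaining
#' gene is retained when it has a count of at least `count_threshold` in at
#' least `min_samples` samples (defaults 10 and 3).
#'
#' @param counts genes x samples integer count matrix.
#' @param count_threshold minimum count (default 10).
#' @param min_samples minimum number of samples reaching it (default 3).
#' @return the filtered count matrix.
#' @export
pover_a_filter <- function(counts, count_threshold = 10, min_samples = 3) {
  stopifnot(count_threshold > 0, min_samples > 0)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  keep <- rowSums(counts >= count_threshold) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is
#' the median ratio of its counts to the gene-wise geometric means; factors
#' are rescaled to have geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return positive numeric vector of per-sample size factors.
#' @export
median_of_ratios_size_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in all samples; ",
         "a pseudo-reference fallback would be required")
  }
  sub <- counts[all_pos, , drop = FALSE]
  log_geo <- rowMeans(log(sub))
  sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - log_geo)))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion pooled across design cells
#'
#' Per gene, a moment dispersion estimate `(var - mean) / mean^2` is formed
#' on the depth-normalized scale within every design cell (e.g. every
#' condition x timepoint combination), then pooled across cells weighted by
#' their degrees of freedom and floored at 1e-8. Estimating the dispersion
#' from the whole design rather than only the two contrasted groups is
#' standard practice for replicated designs: it gives the per-contrast
#' Wald statistic far more dispersion degrees of freedom.
#'
#' @param counts genes x samples count matrix.
#' @param size_factors per-sample size factors.
#' @param groups per-sample design-cell labels.
#' @return numeric vector of per-gene dispersions with attribute `"df"`,
#'   the total pooled degrees of freedom.
#' @export
mom_dispersion <- function(counts, size_factors, groups) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts),
            length(size_factors) == ncol(counts))
  X <- sweep(as.matrix(counts), 2, size_factors, "/")
  num <- 0
  df <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    n_g <- length(idx)
    if (n_g < 2) next
    m <- rowMeans(X[, idx, drop = FALSE])
    v <- apply(X[, idx, drop = FALSE], 1, stats::var)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + (n_g - 1) * a
    df <- df + (n_g - 1)
  }
  if (df == 0) stop("no design cell with at least 2 replicates")
  out <- pmax(1e-8, num / df)
  attr(out, "df") <- df
  out
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Counts are depth-normalized by the size factors. Per gene, the NB
#' dispersion is estimated on the normalized scale by the method of moments
#' in each group, pooled by degrees of freedom across the two groups, and
#' floored at 1e-8; size factors enter only through normalization, making
#' the test exactly invariant to jointly rescaling any sample's counts and
#' size factor. When the experiment has more design cells than the two
#' contrasted groups, a dispersion estimated from the whole design (see
#' [mom_dispersion()]) should be supplied instead.
#' The log fold-change is the log2 ratio of normalized group means with a
#' pseudocount of 0.5, and the Wald statistic divides the log-scale mean
#' difference by its delta-method standard error. Because the dispersion is
#' estimated from limited residual degrees of freedom, the statistic is
#' referred to a t distribution with the dispersion's degrees of freedom
#' rather than a normal. P values are Benjamini-Hochberg adjusted and a
#' gene is called significant when `q < alpha` and
#' `|log2fc| > lfc_threshold` (strict).
#'
#' @param counts genes x samples count matrix (already filtered).
#' @param size_factors per-sample size factors.
#' @param group two-level factor (or character) over samples; the contrast
#'   is second level versus first.
#' @param alpha BH threshold (default 0.05).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param dispersion optional per-gene dispersion vector with a `"df"`
#'   attribute (see [mom_dispersion()]); defaults to pooling over the two
#'   contrasted groups with `n1 + n2 - 2` degrees of freedom.
#' @return `data.frame` with `gene`, `base_mean`, `log2fc`, `dispersion`,
#'   `stat`, `p`, `q`, `significant`, `zero_group`.
#' @export
nb_wald_test <- function(counts, size_factors, group, alpha = 0.05,
                         lfc_threshold = 1, dispersion = NULL) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, length(group) == ncol(counts),
            length(size_factors) == ncol(counts))
  g1 <- which(group == levels(group)[1])
  g2 <- which(group == levels(group)[2])
  n1 <- length(g1)
  n2 <- length(g2)
  stopifnot(n1 >= 2, n2 >= 2)
  X <- sweep(as.matrix(counts), 2, size_factors, "/")
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, g2, drop = FALSE])
  if (is.null(dispersion)) {
    v1 <- apply(X[, g1, drop = FALSE], 1, stats::var)
    v2 <- apply(X[, g2, drop = FALSE], 1, stats::var)
    # moments are taken on the normalized scale (Var = mu + disp * mu^2),
    # so jointly rescaling a sample's counts and size factor changes
    # nothing
    a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, 0)
    a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, 0)
    disp <- pmax(1e-8, ((n1 - 1) * a1 + (n2 - 1) * a2) / (n1 + n2 - 2))
    disp_df <- n1 + n2 - 2
  } else {
    stopifnot(length(dispersion) == nrow(counts))
    disp <- pmax(1e-8, as.numeric(dispersion))
    disp_df <- attr(dispersion, "df")
    if (is.null(disp_df)) disp_df <- n1 + n2 - 2
  }
  var_m1 <- (m1 + disp * m1^2) / n1
  var_m2 <- (m2 + disp * m2^2) / n2
  delta <- log(m2 + 0.5) - log(m1 + 0.5)
  se <- sqrt(var_m1 / (m1 + 0.5)^2 + var_m2 / (m2 + 0.5)^2)
  stat <- ifelse(se > 0, delta / se, 0)
  p <- 2 * stats::pt(-abs(stat), df = disp_df)
  q <- benjamini_hochberg(p)
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  data.frame(gene = rownames(counts), base_mean = (m1 + m2) / 2,
             log2fc = log2fc, dispersion = disp, stat = stat, p = p, q = q,
             significant = q < alpha & abs(log2fc) > lfc_threshold,
             zero_group = m1 == 0 | m2 == 0, row.names = NULL)
}

#' Variance-stabilizing transform used for clustering and heatmaps
#'
#' `log2(normalized count + 1)`: robust for the downstream uses here
#' (k-means on row-centered profiles, centroid correlations).
#'
#' @param counts genes x samples count matrix.
#' @param size_factors per-sample size factors.
#' @return transformed matrix.
#' @export
vst_transform <- function(counts, size_factors) {
  log2(sweep(as.matrix(counts), 2, size_factors, "/") + 1)
}

#' Two k-means clusters of differentially expressed genes
#'
#' Rows (genes) of the transformed matrix are centered by subtracting their
#' means, then clustered with Lloyd's k-means (25 restarts). Cluster 1 is
#' the cluster whose centroid has the higher mean treated-minus-control
#' difference ("upregulated first"). Each gene's correlation to its
#' cluster centroid is reported, and the `n_top` genes with centroid
#' correlation above `cor_threshold` are selected per cluster.
#'
#' @param mat genes x samples transformed expression (e.g.
#'   [vst_transform()] output restricted to DE genes).
#' @param treatment per-sample condition labels (two levels; the second
#'   sorted level is treated as "treated").
#' @param k number of clusters (default 2).
#' @param seed RNG seed for the restarts.
#' @param n_top number of top centroid-correlated genes (default 100).
#' @param cor_threshold Pearson threshold for top genes (default 0.85).
#' @return list with `cluster` (named integer), `centroids`,
#'   `centroid_cor` (named per gene), `top` (list per cluster), `tot_withinss`.
#' @export
kmeans_gene_clusters <- function(mat, treatment, k = 2, seed = 1,
                                 n_top = 100, cor_threshold = 0.85) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= k, length(treatment) == ncol(mat))
  centered <- mat - rowMeans(mat)
  if (max(abs(sweep(centered, 2, centered[1, ], "-"))) < 1e-12) {
    stop("all row profiles identical after centering; a single cluster")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  km <- stats::kmeans(centered, centers = k, nstart = 25, iter.max = 100,
                      algorithm = "Lloyd")
  treatment <- as.factor(treatment)
  trt <- treatment == levels(treatment)[2]
  diff_by_cluster <- apply(km$centers, 1, function(ctr) {
    mean(ctr[trt]) - mean(ctr[!trt])
  })
  ord <- order(diff_by_cluster, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cluster <- stats::setNames(relabel[km$cluster], rownames(mat))
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  centroid_cor <- vapply(seq_len(nrow(centered)), function(i) {
    ctr <- centroids[cluster[i], ]
    if (stats::sd(centered[i, ]) == 0 || stats::sd(ctr) == 0) return(NA_real_)
    stats::cor(centered[i, ], ctr)
  }, numeric(1))
  names(centroid_cor) <- rownames(mat)
  top <- lapply(seq_len(k), function(cl) {
    g <- names(cluster)[cluster == cl]
    rho <- centroid_cor[g]
    g <- g[!is.na(rho) & rho > cor_threshold]
    g[order(centroid_cor[g], decreasing = TRUE)][seq_len(min(n_top,
                                                             length(g)))]
  })
  list(cluster = cluster, centroids = centroids,
       centroid_cor = centroid_cor, top = top,
       tot_withinss = km$tot.withinss)
}

#' Two-way ANOVA on per-replicate cluster means
#'
#' Tests main effects of treatment and timepoint and their interaction on
#' replicate-level mean expression, with Type-II sums of squares (robust to
#' the mild imbalance of a dropped replicate). Degenerate all-equal input
#' is reported as F = 0, p = 1 for every term.
#'
#' @param df `data.frame` with columns `value`, `treatment`, `timepoint`.
#' @return `data.frame` with `term`, `sum_sq`, `df`, `statistic`, `p`.
#' @export
cluster_mean_anova <- function(df) {
  stopifnot(all(c("value", "treatment", "timepoint") %in% names(df)))
  df$treatment <- as.factor(df$treatment)
  df$timepoint <- as.factor(df$timepoint)
  stopifnot(nlevels(df$treatment) >= 2, nlevels(df$timepoint) >= 2)
  cells <- table(df$treatment, df$timepoint)
  if (any(cells == 0)) stop("empty treatment x timepoint cell")
  terms <- c("treatment", "timepoint", "treatment:timepoint")
  a <- nlevels(df$treatment)
  b <- nlevels(df$timepoint)
  dfs <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_res <- nrow(df) - a * b
  if (stats::var(df$value) == 0) {
    return(data.frame(term = terms, sum_sq = 0, df = dfs, statistic = 0,
                      p = 1, row.names = NULL))
  }
  # Type-II sums of squares from nested residual sums of squares
  rss <- function(formula) {
    sum(stats::resid(stats::lm(formula, data = df))^2)
  }
  r_add <- rss(value ~ treatment + timepoint)
  r_full <- rss(value ~ treatment * timepoint)
  ss <- c(rss(value ~ timepoint) - r_add,
          rss(value ~ treatment) - r_add,
          r_add - r_full)
  ss <- pmax(ss, 0)
  if (df_res > 0 && r_full > 1e-12 * sum((df$value - mean(df$value))^2)) {
    ms_res <- r_full / df_res
    f <- (ss / dfs) / ms_res
    p <- stats::pf(f, dfs, df_res, lower.tail = FALSE)
  } else {
    # saturated or noise-free fit: mean squares are undefined
    f <- rep(NA_real_, 3)
    p <- rep(NA_real_, 3)
  }
  data.frame(term = terms, sum_sq = ss, df = dfs, statistic = f, p = p,
             row.names = NULL)
}

#' Per-cell-type condition differential expression (single cell)
#'
#' Within each cell type having at least `min_cells` cells in both
#' conditions, each gene is tested with a rank-sum test of treated versus
#' control cells on log-normalized values; p values are BH adjusted within
#' the type and the log2 fold-change is of normalized group means
#' (pseudocount 1). Calls are `up` when `q < alpha` and
#' `log2fc > lfc_threshold`, `down` when `q < alpha` and
#' `log2fc < -lfc_threshold` (strict), otherwise `ns`. Undersized types are
#' skipped with a warning.
#'
#' @param normalized cells x genes log-normalized matrix.
#' @param cells per-cell metadata with `condition` and `cell_type`.
#' @param min_cells minimum cells per condition within a type (default 20).
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @return `data.frame` with `cell_type`, `gene`, `p`, `q`, `log2fc`,
#'   `call`.
#' @export
sc_condition_de <- function(normalized, cells, min_cells = 20, alpha = 0.05,
                            lfc_threshold = 1) {
  stopifnot(nrow(normalized) == nrow(cells),
            all(c("condition", "cell_type") %in% names(cells)))
  conds <- sort(unique(cells$condition))
  stopifnot(length(conds) == 2)
  out <- list()
  for (ty in unique(cells$cell_type)) {
    idx <- which(cells$cell_type == ty)
    in_trt <- cells$condition[idx] == conds[2]
    if (sum(in_trt) < min_cells || sum(!in_trt) < min_cells) {
      warning("cell type skipped (fewer than ", min_cells,
              " cells per condition): ", ty)
      next
    }
    X <- normalized[idx, , drop = FALSE]
    rs <- .rank_sum_p(X, in_trt)
    q <- benjamini_hochberg(rs$p)
    l2 <- .log2fc_normalized(X, in_trt)
    call <- ifelse(q < alpha & l2 > lfc_threshold, "up",
                   ifelse(q < alpha & l2 < -lfc_threshold, "down", "ns"))
    out[[ty]] <- data.frame(cell_type = ty, gene = colnames(normalized),
                            p = rs$p, q = q, log2fc = l2, call = call,
                            row.names = NULL)
  }
  if (!length(out)) {
    return(data.frame(cell_type = character(), gene = character(),
                      p = numeric(), q = numeric(), log2fc = numeric(),
                      call = character()))
  }
  do.call(rbind, out)
}
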