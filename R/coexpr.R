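#' Depth-aware gene-gene co-expression estimation from UMI counts
#'
#' Estimates latent (expression-scale) co-expression for the requested gene
#' pairs under the Poisson measurement model
#' `X_ij | z_ij ~ Poisson(s_i z_ij)` with `E z_ij = mu_j`,
#' `Cov(z_ij, z_ik) = sigma_jk`. Per-gene means and variances are fit by
#' iteratively reweighted least squares on the moment conditions (weights
#' are inverse estimated variances of each condition, at most `max_iter`
#' iterations, relative tolerance `tol`); pair covariances are then solved
#' in a single weighted step and tested against `sigma_jk = 0` with a
#' standard-normal reference on the WLS slope over its standard error.
#' The co-expression estimate is
#' `rho_jk = sigma_jk / sqrt(sigma_jj sigma_kk)`, clipped to `[-1, 1]`.
#'
#' @param counts cells x genes UMI count matrix (dense or sparse).
#' @param pairs two-column `data.frame` or matrix of gene names (or column
#'   indices); a self-pair `(j, j)` returns `rho = 1` whenever
#'   `sigma_jj > 0`.
#' @param depths per-cell sequencing depths; defaults to the per-cell total
#'   count over all genes of `counts`.
#' @param max_iter,tol IRLS controls.
#' @return `data.frame` with one row per pair: `gene1`, `gene2`, `mu1`,
#'   `mu2`, `sigma1`, `sigma2`, `sigma12`, `rho`, `p`, `q`, `valid`,
#'   `flags`. Negative variances are clipped to zero and flagged; genes with
#'   all-zero counts give flagged-invalid records with undefined `rho`;
#'   non-convergence returns the last iterate, flagged. `q` is BH across
#'   the supplied (valid) pairs.
#' @export
estimate_coexpression <- function(counts, pairs, depths = NULL,
                                  max_iter = 10, tol = 1e-5) {
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) >= 2)
  names(pairs)[1:2] <- c("gene1", "gene2")
  if (is.null(depths)) depths <- Matrix::rowSums(counts)
  stopifnot(all(depths > 0), length(depths) == nrow(counts))
  gene_names <- colnames(counts)
  resolve <- function(g) {
    if (is.numeric(g)) {
      if (any(g < 1 | g > ncol(counts))) stop("pair index out of range")
      if (is.null(gene_names)) as.character(g) else gene_names[g]
    } else {
      miss <- setdiff(unique(g), gene_names)
      if (length(miss)) {
        stop("pair genes absent from matrix: ", paste(miss, collapse = ", "))
      }
      as.character(g)
    }
  }
  pairs$gene1 <- resolve(pairs$gene1)
  pairs$gene2 <- resolve(pairs$gene2)
  used <- unique(c(pairs$gene1, pairs$gene2))
  X <- as.matrix(counts[, used, drop = FALSE])
  colnames(X) <- used
  fit <- .coexpr_moments(X, depths, max_iter, tol)
  .coexpr_records(X, depths, fit, pairs)
}

# converged per-gene moments plus bookkeeping flags
.coexpr_moments <- function(X, depths, max_iter, tol) {
  mom <- cscore_moments_cpp(X, depths, as.integer(max_iter), tol)
  names(mom$mu) <- names(mom$sigma) <- colnames(X)
  mom$all_zero <- colSums(X) == 0
  mom
}

.coexpr_records <- function(X, depths, fit, pairs) {
  i1 <- match(pairs$gene1, colnames(X))
  i2 <- match(pairs$gene2, colnames(X))
  pr <- cscore_pairs_cpp(X, depths, fit$mu, fit$sigma,
                         as.integer(i1 - 1L), as.integer(i2 - 1L))
  sigma1 <- fit$sigma[i1]
  sigma2 <- fit$sigma[i2]
  theta <- pr$theta
  self <- i1 == i2
  flags <- character(nrow(pairs))
  add_flag <- function(flags, cond, label) {
    ifelse(cond, ifelse(nzchar(flags), paste(flags, label, sep = ";"),
                        label), flags)
  }
  var_bad <- sigma1 <= 0 | sigma2 <= 0
  all_zero <- fit$all_zero[i1] | fit$all_zero[i2]
  not_conv <- !fit$converged[i1] | !fit$converged[i2]
  rho <- rep(NA_real_, nrow(pairs))
  ok <- !var_bad
  rho[ok] <- theta[ok] / sqrt(sigma1[ok] * sigma2[ok])
  rho[self & ok] <- 1
  theta[self] <- sigma1[self]
  clipped <- !is.na(rho) & abs(rho) > 1
  rho <- pmin(1, pmax(-1, rho))
  p <- 2 * stats::pnorm(-abs(pr$z))
  p[self] <- NA_real_
  flags <- add_flag(flags, all_zero, "all_zero")
  flags <- add_flag(flags, var_bad & !all_zero, "var_nonpositive")
  flags <- add_flag(flags, clipped, "clipped")
  flags <- add_flag(flags, not_conv, "not_converged")
  valid <- !all_zero & !var_bad
  p[!valid] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[valid & !self] <- benjamini_hochberg(p[valid & !self])
  data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
             mu1 = fit$mu[i1], mu2 = fit$mu[i2],
             sigma1 = pmax(sigma1, 0), sigma2 = pmax(sigma2, 0),
             sigma12 = theta, rho = rho, p = p, q = q,
             valid = valid, flags = flags, row.names = NULL)
}

#' Retain significant strongly co-expressed pairs
#'
#' Keeps pairs with BH-adjusted `q < q_threshold` and signed co-expression
#' estimate `rho > rho_threshold` (strict inequalities); flagged-invalid
#' records are excluded.
#'
#' @param records output of [estimate_coexpression()].
#' @param q_threshold corrected-p threshold (default 0.05).
#' @param rho_threshold signed estimate threshold (default 0.5).
#' @return the retained subset of `records`.
#' @export
filter_significant_pairs <- function(records, q_threshold = 0.05,
                                     rho_threshold = 0.5) {
  keep <- records$valid & !is.na(records$q) & records$q < q_threshold &
    records$rho > rho_threshold
  records[keep, , drop = FALSE]
}

#' Permutation test for differential co-expression
#'
#' Subsamples up to `n_per_group` cells per condition (without replacement,
#' once), computes each pair's co-expression difference
#' `delta = rho_treated - rho_control` on the subsample, then permutes the
#' group labels of the pooled subsample `B` times, re-estimating the
#' difference each time, to form the null distribution. Two-sided p values
#' use the add-one convention `p = (1 + #{|delta_b| >= |delta|}) / (B + 1)`
#' and are BH-adjusted across pairs. A permutation in which a pair's
#' estimate is flagged invalid is dropped for that pair and its effective
#' `B` reduced (recorded in `b_used`).
#'
#' @param counts_ctrl,counts_trt cells x genes UMI matrices for the two
#'   conditions (same gene set).
#' @param pairs two-column `data.frame`/matrix of gene pairs.
#' @param n_per_group cells subsampled per group (default 10000).
#' @param B number of label permutations (default 1000).
#' @param seed RNG seed for subsampling and permutation.
#' @param q_threshold significance threshold on BH-adjusted permutation p.
#' @return `data.frame` with `gene1`, `gene2`, `rho_ctrl`, `rho_trt`,
#'   `delta`, `p`, `q`, `significant`, `b_used`; the subsample sizes, `B`,
#'   and `seed` are stored in the `"params"` attribute.
#' @export
differential_coexpression <- function(counts_ctrl, counts_trt, pairs,
                                      n_per_group = 10000, B = 1000,
                                      seed = 1, q_threshold = 0.05) {
  stopifnot(nrow(counts_ctrl) >= 50, nrow(counts_trt) >= 50)
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("gene1", "gene2")
  set.seed(seed)
  d_ctrl <- Matrix::rowSums(counts_ctrl)
  d_trt <- Matrix::rowSums(counts_trt)
  n_c <- min(n_per_group, nrow(counts_ctrl))
  n_t <- min(n_per_group, nrow(counts_trt))
  idx_c <- sample.int(nrow(counts_ctrl), n_c)
  idx_t <- sample.int(nrow(counts_trt), n_t)
  used <- unique(c(pairs$gene1, pairs$gene2))
  Xc <- as.matrix(counts_ctrl[idx_c, used, drop = FALSE])
  Xt <- as.matrix(counts_trt[idx_t, used, drop = FALSE])
  sc <- d_ctrl[idx_c]
  st <- d_trt[idx_t]
  i1 <- match(pairs$gene1, used)
  i2 <- match(pairs$gene2, used)

  pair_rho <- function(X, s) {
    mom <- cscore_moments_cpp(X, s, 10L, 1e-5)
    pr <- cscore_pairs_cpp(X, s, mom$mu, mom$sigma,
                           as.integer(i1 - 1L), as.integer(i2 - 1L))
    s1 <- mom$sigma[i1]
    s2 <- mom$sigma[i2]
    rho <- ifelse(s1 > 0 & s2 > 0, pr$theta / sqrt(s1 * s2), NA_real_)
    pmin(1, pmax(-1, rho))
  }
  rho_c <- pair_rho(Xc, sc)
  rho_t <- pair_rho(Xt, st)
  delta <- rho_t - rho_c

  Xp <- rbind(Xc, Xt)
  sp <- c(sc, st)
  n_pool <- n_c + n_t
  exceed <- integer(length(delta))
  b_used <- integer(length(delta))
  for (b in seq_len(B)) {
    perm <- sample.int(n_pool)
    pc <- perm[seq_len(n_c)]
    pt_ <- perm[(n_c + 1):n_pool]
    db <- pair_rho(Xp[pt_, , drop = FALSE], sp[pt_]) -
      pair_rho(Xp[pc, , drop = FALSE], sp[pc])
    usable <- !is.na(db) & !is.na(delta)
    b_used <- b_used + usable
    exceed <- exceed + (usable & abs(db) >= abs(delta))
  }
  p <- ifelse(is.na(delta), NA_real_, (1 + exceed) / (b_used + 1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- benjamini_hochberg(p[!is.na(p)])
  out <- data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
                    rho_ctrl = rho_c, rho_trt = rho_t, delta = delta,
                    p = p, q = q,
                    significant = !is.na(q) & q < q_threshold,
                    b_used = b_used, row.names = NULL)
  attr(out, "params") <- list(n_ctrl = n_c, n_trt = n_t, B = B, seed = seed,
                              q_threshold = q_threshold)
  out
}
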