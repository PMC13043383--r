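#' Latent expression model for single-cell count simulation
#'
#' Describes the latent (pre-measurement) expression of each gene: gamma
#' marginals with mean `mu` and variance `diag(sigma)`, coupled through a
#' Gaussian copula whose correlation is taken from `sigma`. Observed UMI
#' counts arise by Poisson thinning of the latent vector with a per-cell
#' sequencing depth, so `mu` is relative expression. Condition-specific
#' structure is planted through `de_lfc` (log2 mean shifts in the treated
#' condition) and `dc_pairs` (condition-specific latent correlations).
#'
#' @param mu named positive numeric vector of relative gene means.
#' @param sigma gene-gene latent covariance matrix (symmetric, `diag >= 0`),
#'   or `NULL` to use independent genes with coefficient of variation `cv`.
#' @param cv latent coefficient of variation used when `sigma` is `NULL`.
#' @param de_lfc named numeric of planted log2 mean shifts applied in the
#'   treated condition (genes absent from the vector are unshifted).
#' @param dc_pairs `data.frame` with columns `gene1`, `gene2`, `rho_ctrl`,
#'   `rho_trt`: planted condition-specific latent correlations.
#' @return object of class `latent_model`.
#' @details Correlation matrices are repaired once by eigenvalue clipping at
#'   zero if not positive semi-definite; if the repair fails the constructor
#'   errors naming the offending pairs. Gamma shapes are `mu^2 / sigma_jj`,
#'   so a planted mean shift preserves the latent coefficient of variation.
#' @export
latent_model <- function(mu, sigma = NULL, cv = 0.5, de_lfc = NULL,
                         dc_pairs = NULL) {
  stopifnot(is.numeric(mu), all(mu > 0))
  if (is.null(names(mu))) {
    names(mu) <- sprintf("G%04d", seq_along(mu))
  }
  G <- length(mu)
  genes <- names(mu)
  if (is.null(sigma)) {
    sigma <- diag((cv * mu)^2, G)
    dimnames(sigma) <- list(genes, genes)
  }
  stopifnot(is.matrix(sigma), nrow(sigma) == G, ncol(sigma) == G)
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  sig_jj <- diag(sigma)
  if (any(sig_jj < 0)) stop("negative latent variances")

  # implied correlation; zero-variance genes carry zero correlation
  sd_j <- sqrt(sig_jj)
  denom <- outer(sd_j, sd_j)
  R <- ifelse(denom > 0, sigma / denom, 0)
  diag(R) <- 1
  .check_corr_range(R, genes)

  if (!is.null(de_lfc)) {
    stopifnot(is.numeric(de_lfc), !is.null(names(de_lfc)))
    missing <- setdiff(names(de_lfc), genes)
    if (length(missing)) {
      stop("de_lfc genes absent from model: ", paste(missing, collapse = ", "))
    }
  }
  R_ctrl <- R
  R_trt <- R
  if (!is.null(dc_pairs)) {
    stopifnot(is.data.frame(dc_pairs),
              all(c("gene1", "gene2", "rho_ctrl", "rho_trt") %in%
                    names(dc_pairs)))
    missing <- setdiff(c(dc_pairs$gene1, dc_pairs$gene2), genes)
    if (length(missing)) {
      stop("dc_pairs genes absent from model: ",
           paste(unique(missing), collapse = ", "))
    }
    if (any(abs(c(dc_pairs$rho_ctrl, dc_pairs$rho_trt)) > 1)) {
      stop("planted correlations must lie in [-1, 1]")
    }
    for (r in seq_len(nrow(dc_pairs))) {
      i <- match(dc_pairs$gene1[r], genes)
      j <- match(dc_pairs$gene2[r], genes)
      R_ctrl[i, j] <- R_ctrl[j, i] <- dc_pairs$rho_ctrl[r]
      R_trt[i, j] <- R_trt[j, i] <- dc_pairs$rho_trt[r]
    }
  }
  R_ctrl <- .repair_psd(R_ctrl, genes)
  R_trt <- .repair_psd(R_trt, genes)

  structure(list(mu = mu, sigma_jj = sig_jj, R_control = R_ctrl,
                 R_treated = R_trt, de_lfc = de_lfc, dc_pairs = dc_pairs,
                 genes = genes),
            class = "latent_model")
}

.check_corr_range <- function(R, genes) {
  bad <- which(abs(R) > 1 + 1e-8, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad)) {
    stop("implied correlations outside [-1, 1] for pairs: ",
         paste(genes[bad[, 1]], genes[bad[, 2]], sep = "~", collapse = ", "))
  }
}

# one round of eigenvalue clipping at zero, then rescale to unit diagonal;
# a second failure is an error naming the most entangled pairs
.repair_psd <- function(R, genes) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= -1e-10) return(R)
  vals <- pmax(ev$values, 0)
  R2 <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  diag(R2) <- 1
  if (min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    off <- abs(R2)
    diag(off) <- 0
    idx <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("latent correlation matrix not repairable to PSD; worst pair: ",
         genes[idx[1]], "~", genes[idx[2]])
  }
  dimnames(R2) <- dimnames(R)
  R2
}

#' Cohort design for single-cell cohort simulation
#'
#' Encodes the two-condition, replicated cohort layout: three control and
#' three treated samples of coelomocytes with the four canonical cell types
#' at the control proportions (phagocytes 0.79, vibratile cells 0.07, red
#' spherule cells 0.06, colorless spherule cells 0.08). Marker genes for
#' each type are elevated `marker_fold`-fold in cells of their own type.
#'
#' @param n_cells_per_sample cells per sample.
#' @param samples_per_condition biological replicates per condition.
#' @param type_props named cell-type proportions summing to 1.
#' @param markers named list mapping cell types to their marker gene names;
#'   defaults to the genes of [default_marker_dictionary()].
#' @param marker_fold fold-elevation of a type's markers within that type.
#' @param depth_mean,depth_cv mean and coefficient of variation of the
#'   log-normal per-cell sequencing depth.
#' @param clusters_per_type number of (true-label) clusters each type is
#'   split into.
#' @param seed RNG seed recorded in the output metadata.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_cells_per_sample = 2500,
                          samples_per_condition = 3,
                          type_props = c(phagocyte = 0.79, vibratile = 0.07,
                                         RSC = 0.06, CSC = 0.08),
                          markers = NULL,
                          marker_fold = 8,
                          depth_mean = 2000,
                          depth_cv = 0.5,
                          clusters_per_type = 1,
                          seed = 1) {
  stopifnot(n_cells_per_sample > 0, samples_per_condition >= 1,
            marker_fold > 0, depth_mean > 0, depth_cv >= 0,
            clusters_per_type >= 1)
  if (abs(sum(type_props) - 1) > 1e-8) {
    stop("type proportions must sum to 1")
  }
  if (is.null(names(type_props))) stop("type_props must be named")
  if (is.null(markers)) {
    markers <- markers_from_dictionary(default_marker_dictionary())
    markers <- markers[names(type_props)]
  }
  stopifnot(all(names(markers) %in% names(type_props)))
  structure(list(n_cells_per_sample = as.integer(n_cells_per_sample),
                 samples_per_condition = as.integer(samples_per_condition),
                 type_props = type_props, markers = markers,
                 marker_fold = marker_fold, depth_mean = depth_mean,
                 depth_cv = depth_cv,
                 clusters_per_type = as.integer(clusters_per_type),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default latent model matching a cohort design
#'
#' Builds a gene panel holding every marker gene of the design plus
#' `n_background` background genes with a deterministic log-spaced spread of
#' relative means and `n_rare` weakly expressed genes (these exercise the
#' minimum-cells gene filter). Relative means are normalised to sum to 1.
#'
#' @param design a [cohort_design()].
#' @param n_background number of background genes.
#' @param n_rare number of near-zero background genes.
#' @param cv latent coefficient of variation for all genes.
#' @inheritParams latent_model
#' @return a [latent_model()].
#' @export
default_cohort_model <- function(design, n_background = 60, n_rare = 5,
                                 cv = 0.5, de_lfc = NULL, dc_pairs = NULL) {
  marker_genes <- unique(unlist(design$markers))
  bg <- sprintf("BG%03d", seq_len(n_background))
  rare <- if (n_rare > 0) sprintf("RARE%02d", seq_len(n_rare)) else character()
  mu_bg <- exp(seq(log(0.2), log(5), length.out = n_background))
  mu <- c(stats::setNames(rep(stats::median(mu_bg), length(marker_genes)),
                          marker_genes),
          stats::setNames(mu_bg, bg),
          stats::setNames(rep(1e-3, length(rare)), rare))
  mu <- mu / sum(mu)
  latent_model(mu, cv = cv, de_lfc = de_lfc, dc_pairs = dc_pairs)
}

#' Marker gene names grouped by cell type, from a marker dictionary
#'
#' @param dictionary a marker dictionary, see [default_marker_dictionary()].
#' @return named list of character vectors (significance requirements plus
#'   supporting genes; exclusion-only genes are not included).
#' @export
markers_from_dictionary <- function(dictionary) {
  lapply(dictionary, function(d) {
    unique(unlist(c(d$significant, d$supporting)))
  })
}

#' Simulate a replicated two-condition single-cell UMI cohort
#'
#' For each cell, a cell type is drawn from the design proportions, a latent
#' expression vector `z` is drawn from the model's gamma-marginal Gaussian
#' copula (with the type's markers fold-elevated and, in the treated
#' condition, planted log2 shifts and planted pair correlations applied),
#' a sequencing depth `s` is drawn log-normal, and counts are emitted as
#' `X_j ~ Poisson(s * z_j)`. Regeneration with the same seed is
#' bit-identical.
#'
#' @param design a [cohort_design()].
#' @param model a [latent_model()]; defaults to
#'   [default_cohort_model()] of the design.
#' @param return_latent keep the latent matrix `z` in the truth table
#'   (memory-hungry; intended for estimator validation).
#' @return list with `counts` (sparse cells x genes), `cells` (per-cell
#'   metadata: `cell`, `sample`, `condition`, `cluster`, `cell_type_true`),
#'   and `truth` (planted markers, DE genes, DC pairs, depths, seed, and
#'   optionally the latent draws).
#' @export
simulate_single_cell_cohort <- function(design, model = NULL,
                                        return_latent = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(model)) model <- default_cohort_model(design)
  stopifnot(inherits(model, "latent_model"))
  missing <- setdiff(unlist(design$markers), model$genes)
  if (length(missing)) {
    stop("design markers absent from model: ", paste(missing, collapse = ", "))
  }
  set.seed(design$seed)
  G <- length(model$mu)
  genes <- model$genes
  types <- names(design$type_props)
  chol_ctrl <- chol(model$R_control + diag(1e-10, G))
  chol_trt <- chol(model$R_treated + diag(1e-10, G))
  shape <- ifelse(model$sigma_jj > 0, model$mu^2 / model$sigma_jj, Inf)

  counts_blocks <- list()
  meta_blocks <- list()
  latent_blocks <- if (return_latent) list() else NULL
  depth_all <- numeric()
  sdlog <- sqrt(log(1 + design$depth_cv^2))

  for (cond in c("control", "treated")) {
    ch <- if (cond == "control") chol_ctrl else chol_trt
    lfc <- stats::setNames(rep(0, G), genes)
    if (cond == "treated" && !is.null(model$de_lfc)) {
      lfc[names(model$de_lfc)] <- model$de_lfc
    }
    for (smp in seq_len(design$samples_per_condition)) {
      sample_id <- sprintf("%s_S%d", cond, smp)
      n <- design$n_cells_per_sample
      cell_type <- sample(types, n, replace = TRUE, prob = design$type_props)
      s <- stats::rlnorm(n, meanlog = log(design$depth_mean) - sdlog^2 / 2,
                         sdlog = sdlog)
      s <- s * design$depth_mean / mean(s)
      sub <- if (design$clusters_per_type > 1) {
        sample.int(design$clusters_per_type, n, replace = TRUE)
      } else {
        rep(1L, n)
      }
      X <- matrix(0, n, G, dimnames = list(NULL, genes))
      Z <- if (return_latent) X else NULL
      for (ty in types) {
        idx <- which(cell_type == ty)
        if (!length(idx)) next
        mu_t <- model$mu * 2^lfc
        mk <- design$markers[[ty]]
        if (length(mk)) mu_t[mk] <- mu_t[mk] * design$marker_fold
        U <- matrix(stats::rnorm(length(idx) * G), length(idx), G) %*% ch
        z <- matrix(mu_t, length(idx), G, byrow = TRUE)
        pos <- which(is.finite(shape))
        if (length(pos)) {
          p <- stats::pnorm(U[, pos, drop = FALSE])
          z[, pos] <- stats::qgamma(
            p, shape = rep(shape[pos], each = length(idx)),
            rate = rep(shape[pos] / mu_t[pos], each = length(idx)))
        }
        X[idx, ] <- matrix(stats::rpois(length(idx) * G, s[idx] * z),
                           length(idx), G)
        if (return_latent) Z[idx, ] <- z
      }
      cell_ids <- sprintf("%s_C%05d", sample_id, seq_len(n))
      rownames(X) <- cell_ids
      counts_blocks[[sample_id]] <- X
      meta_blocks[[sample_id]] <- data.frame(
        cell = cell_ids, sample = sample_id, condition = cond,
        cluster = sprintf("c%d", (match(cell_type, types) - 1L) *
                            design$clusters_per_type + sub - 1L),
        cell_type_true = cell_type, stringsAsFactors = FALSE)
      depth_all <- c(depth_all, stats::setNames(s, cell_ids))
      if (return_latent) {
        rownames(Z) <- cell_ids
        latent_blocks[[sample_id]] <- Z
      }
    }
  }
  counts <- methods::as(Matrix::Matrix(do.call(rbind, counts_blocks),
                                       sparse = TRUE), "CsparseMatrix")
  cells <- do.call(rbind, meta_blocks)
  rownames(cells) <- NULL
  truth <- list(markers = design$markers,
                de_lfc = model$de_lfc,
                dc_pairs = model$dc_pairs,
                depths = depth_all,
                type_props = design$type_props,
                cluster_type = .cluster_type_map(design, types),
                seed = design$seed)
  if (return_latent) truth$latent <- do.call(rbind, latent_blocks)
  list(counts = counts, cells = cells, truth = truth)
}

.cluster_type_map <- function(design, types) {
  k <- design$clusters_per_type
  stats::setNames(rep(types, each = k),
                  sprintf("c%d", seq_len(length(types) * k) - 1L))
}

#' Bulk RNA-seq experiment design
#'
#' Two conditions, five recovery timepoints, three replicates by default,
#' mirroring a whole-coelomic-fluid bulk time course. Counts are negative
#' binomial around log-normal baseline means with sample-specific depth
#' multipliers; a planted fraction of genes carries a log2 fold-change in
#' the treated condition.
#'
#' @param n_genes number of genes.
#' @param timepoints numeric recovery times (hours).
#' @param replicates biological replicates per condition x timepoint.
#' @param mean_log_mean,mean_log_sd log-normal parameters for baseline means.
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param de_fraction fraction of genes with planted differential expression.
#' @param de_lfc magnitude of the planted log2 fold-change.
#' @param de_balance fraction of planted genes shifted upward (the rest are
#'   shifted down).
#' @param sample_depth_sd log-sd of sample-specific depth multipliers.
#' @param time_effect_sd log-sd of shared per-gene time effects (0 = none).
#' @param seed RNG seed.
#' @return object of class `bulk_design`.
#' @export
bulk_design <- function(n_genes = 2000, timepoints = c(0, 1, 3, 6, 24),
                        replicates = 3, mean_log_mean = log(100),
                        mean_log_sd = 1, dispersion = 0.05,
                        de_fraction = 0.1, de_lfc = 2, de_balance = 0.5,
                        sample_depth_sd = 0.2, time_effect_sd = 0,
                        seed = 1) {
  stopifnot(n_genes >= 1, replicates >= 1, dispersion >= 0,
            de_fraction >= 0, de_fraction <= 1, de_balance >= 0,
            de_balance <= 1, sample_depth_sd >= 0, time_effect_sd >= 0)
  structure(list(n_genes = as.integer(n_genes), timepoints = timepoints,
                 replicates = as.integer(replicates),
                 mean_log_mean = mean_log_mean, mean_log_sd = mean_log_sd,
                 dispersion = dispersion, de_fraction = de_fraction,
                 de_lfc = de_lfc, de_balance = de_balance,
                 sample_depth_sd = sample_depth_sd,
                 time_effect_sd = time_effect_sd, seed = as.integer(seed)),
            class = "bulk_design")
}

#' Simulate a bulk count table with planted differential expression
#'
#' @param design a [bulk_design()].
#' @return list with `counts` (genes x samples integer matrix), `samples`
#'   (sample, condition, timepoint, replicate), and `truth` (planted log2
#'   fold-changes, baseline means, sample depth multipliers, seed).
#' @export
simulate_bulk_experiment <- function(design) {
  stopifnot(inherits(design, "bulk_design"))
  set.seed(design$seed)
  G <- design$n_genes
  genes <- sprintf("gene%05d", seq_len(G))
  base <- stats::rlnorm(G, design$mean_log_mean, design$mean_log_sd)
  lfc <- stats::setNames(rep(0, G), genes)
  n_de <- round(design$de_fraction * G)
  de_genes <- character()
  if (n_de > 0) {
    de_idx <- sample.int(G, n_de)
    n_up <- round(design$de_balance * n_de)
    sign_vec <- c(rep(1, n_up), rep(-1, n_de - n_up))
    lfc[de_idx] <- sign_vec * design$de_lfc
    de_genes <- genes[de_idx]
  }
  time_mult <- if (design$time_effect_sd > 0) {
    matrix(stats::rlnorm(G * length(design$timepoints),
                         -design$time_effect_sd^2 / 2, design$time_effect_sd),
           G, length(design$timepoints))
  } else {
    matrix(1, G, length(design$timepoints))
  }
  samples <- expand.grid(replicate = seq_len(design$replicates),
                         timepoint = design$timepoints,
                         condition = c("control", "treated"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_t%g_r%d", samples$condition,
                            samples$timepoint, samples$replicate)
  samples <- samples[, c("sample", "condition", "timepoint", "replicate")]
  depth <- stats::rlnorm(nrow(samples), -design$sample_depth_sd^2 / 2,
                         design$sample_depth_sd)
  counts <- matrix(0L, G, nrow(samples), dimnames = list(genes,
                                                         samples$sample))
  for (k in seq_len(nrow(samples))) {
    mu_k <- base * time_mult[, match(samples$timepoint[k],
                                     design$timepoints)] * depth[k]
    if (samples$condition[k] == "treated") mu_k <- mu_k * 2^lfc
    counts[, k] <- if (design$dispersion > 0) {
      stats::rnbinom(G, mu = mu_k, size = 1 / design$dispersion)
    } else {
      stats::rpois(G, mu_k)
    }
  }
  list(counts = counts, samples = samples,
       truth = list(lfc = lfc, de_genes = de_genes, base_mean = base,
                    depth_multipliers = stats::setNames(depth,
                                                        samples$sample),
                    dispersion = design$dispersion, seed = design$seed))
}

#' Generate small assay fixtures with known ground truth
#'
#' Three fixture kinds support the functional-assay quantification modules:
#' `"dose_response"` draws a dose-viability table from the three-parameter
#' logistic `V(d) = top / (1 + (d / ld50)^hill)` with optional multiplicative
#' Gaussian noise; `"comet_masks"` builds an intensity image plus disjoint
#' head/tail label masks with a known intensity split; `"puncta_image"`
#' builds a two-channel field (puncta signal, nuclei) with known object
#' counts. Defaults mirror the UVB challenge: doses 0-9999 mJ/cm2 and a
#' coelomocyte-like LD50.
#'
#' @param kind one of `"dose_response"`, `"comet_masks"`, `"puncta_image"`.
#' @param params named list overriding the kind's defaults.
#' @param seed RNG seed.
#' @param dir optional directory; when given, CSV/PNG fixtures and a YAML
#'   parameter sidecar are written there.
#' @return list with the fixture data and a `truth` element.
#' @export
simulate_assay_fixtures <- function(kind, params = list(), seed = 1,
                                    dir = NULL) {
  set.seed(seed)
  out <- switch(kind,
    dose_response = .fixture_dose_response(params),
    comet_masks = .fixture_comet_masks(params),
    puncta_image = .fixture_puncta_image(params),
    stop("unknown fixture kind: ", kind)
  )
  out$kind <- kind
  out$seed <- seed
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    .write_params_yaml(c(list(kind = kind, seed = seed), out$params),
                       file.path(dir, paste0(kind, "_params.yaml")))
    if (kind == "dose_response") {
      utils::write.table(out$data, file.path(dir, "dose_response.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
    } else if (kind == "comet_masks") {
      png::writePNG(.to_unit(out$image), file.path(dir, "comet_image.png"))
      png::writePNG(out$head_mask * 1, file.path(dir, "comet_head_mask.png"))
      png::writePNG(out$tail_mask * 1, file.path(dir, "comet_tail_mask.png"))
    } else {
      png::writePNG(.to_unit(out$signal), file.path(dir, "puncta_signal.png"))
      png::writePNG(.to_unit(out$nuclei), file.path(dir, "puncta_nuclei.png"))
    }
  }
  out
}

.to_unit <- function(m) pmin(pmax(m / max(max(m), 1e-12), 0), 1)

.fixture_dose_response <- function(params) {
  p <- utils::modifyList(list(doses = c(0, 1000, 2000, 4000, 6000, 9999),
                              ld50 = 7232, hill = 2, top = 100,
                              noise_cv = 0, replicates = 3), params)
  stopifnot(p$ld50 > 0, p$hill > 0, p$top > 0, p$noise_cv >= 0)
  df <- expand.grid(replicate = seq_len(p$replicates), dose = p$doses,
                    KEEP.OUT.ATTRS = FALSE)
  v <- p$top / (1 + (df$dose / p$ld50)^p$hill)
  if (p$noise_cv > 0) {
    v <- pmax(0, v * (1 + stats::rnorm(length(v), 0, p$noise_cv)))
  }
  df$viability <- v
  list(data = df[, c("dose", "replicate", "viability")],
       params = p, truth = list(ld50 = p$ld50, hill = p$hill, top = p$top))
}

.fixture_comet_masks <- function(params) {
  p <- utils::modifyList(list(head_sum = 900, tail_sum = 100,
                              nrow = 64, ncol = 96, head_radius = 10),
                         params)
  img <- matrix(0, p$nrow, p$ncol)
  cy <- round(p$nrow / 2)
  cx <- round(p$ncol / 4)
  rr <- outer(seq_len(p$nrow) - cy, seq_len(p$ncol) - cx,
              function(a, b) sqrt(a^2 + b^2))
  head_mask <- rr <= p$head_radius
  tail_mask <- matrix(FALSE, p$nrow, p$ncol)
  tail_rows <- (cy - round(p$head_radius / 2)):(cy + round(p$head_radius / 2))
  tail_cols <- (cx + p$head_radius + 2):(p$ncol - 4)
  tail_mask[tail_rows, tail_cols] <- TRUE
  img[head_mask] <- p$head_sum / sum(head_mask)
  img[tail_mask] <- p$tail_sum / sum(tail_mask)
  list(image = img, head_mask = head_mask, tail_mask = tail_mask, params = p,
       truth = list(head_sum = p$head_sum, tail_sum = p$tail_sum,
                    tail_pct = 100 * p$tail_sum / (p$head_sum + p$tail_sum)))
}

.fixture_puncta_image <- function(params) {
  p <- utils::modifyList(list(n_nuclei = 12, n_puncta = 40, dim = c(192, 192),
                              nucleus_radius = 6, punctum_size = 2,
                              punctum_intensity = 1, nucleus_intensity = 0.8,
                              background_sd = 0.01), params)
  h <- p$dim[1]
  w <- p$dim[2]
  nuclei <- matrix(0, h, w)
  signal <- matrix(0, h, w)
  # nuclei on a jittered grid, separation enforced by construction
  ngrid <- ceiling(sqrt(p$n_nuclei))
  step_y <- floor(h / ngrid)
  step_x <- floor(w / ceiling(p$n_nuclei / ngrid))
  centers <- expand.grid(gy = seq_len(ngrid),
                         gx = seq_len(ceiling(p$n_nuclei / ngrid)))
  centers <- centers[seq_len(p$n_nuclei), ]
  jit <- p$nucleus_radius
  for (k in seq_len(p$n_nuclei)) {
    cy <- (centers$gy[k] - 0.5) * step_y + sample(-jit:jit, 1) / 2
    cx <- (centers$gx[k] - 0.5) * step_x + sample(-jit:jit, 1) / 2
    rr <- outer(seq_len(h) - cy, seq_len(w) - cx,
                function(a, b) sqrt(a^2 + b^2))
    nuclei[rr <= p$nucleus_radius] <- p$nucleus_intensity
  }
  # puncta as small squares of unit intensity; additive so the integrated
  # intensity equals n_puncta * area * intensity even under overlap
  sz <- p$punctum_size
  py <- sample(seq_len(h - sz), p$n_puncta, replace = TRUE)
  px <- sample(seq_len(w - sz), p$n_puncta, replace = TRUE)
  for (k in seq_len(p$n_puncta)) {
    ys <- py[k]:(py[k] + sz - 1)
    xs <- px[k]:(px[k] + sz - 1)
    signal[ys, xs] <- signal[ys, xs] + p$punctum_intensity
  }
  if (p$background_sd > 0) {
    signal <- signal + pmax(matrix(stats::rnorm(h * w, 0, p$background_sd),
                                   h, w), 0)
  }
  list(signal = signal, nuclei = nuclei, params = p,
       truth = list(n_nuclei = p$n_nuclei, n_puncta = p$n_puncta,
                    integrated = p$n_puncta * sz^2 * p$punctum_intensity))
}
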