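#' Default pipeline configuration
#'
#' All analysis thresholds default to the study's stated values: 5-MAD cell
#' QC, 50-cell gene filter, pOverA 10-in-3, marker calls at adjusted
#' p < 0.05 and log2FC > 0.5, DE calls at FDR < 0.05 and |log2FC| > 1,
#' co-expression retention at q < 0.05 and rho > 0.5, differential
#' co-expression with 10,000 cells per group and 1,000 permutations.
#' Simulation sizes default to a small preset (about 2,000 cells) so the
#' full pipeline runs interactively.
#'
#' @return nested named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    simdata = list(n_cells_per_sample = 334, samples_per_condition = 3,
                   depth_mean = 2000, marker_fold = 8, n_de_genes = 6,
                   de_lfc = 2, plant_dc = TRUE, dc_rho_ctrl = 0,
                   dc_rho_trt = 0.6),
    bulk = list(n_genes = 1000, de_fraction = 0.1, de_lfc = 2,
                dispersion = 0.05, replicates = 3),
    qc = list(n_mads = 5, min_cells = 50),
    markers = list(adj_p = 0.05, lfc = 0.5),
    sc_de = list(alpha = 0.05, lfc = 1, min_cells = 20),
    bulk_de = list(count_threshold = 10, min_samples = 3, alpha = 0.05,
                   lfc = 1),
    gene_clusters = list(n_top = 100, cor_threshold = 0.85),
    coexpr = list(n_per_group = 10000, permutations = 1000,
                  q_threshold = 0.05, rho_threshold = 0.5),
    assays = list(enabled = TRUE)
  )
}

# field -> validation rule; each rule returns NULL or an error string
.config_rules <- function() {
  pos <- function(x) if (!is.numeric(x) || length(x) != 1 || x <= 0) {
    "must be a positive number"
  }
  nonneg_int <- function(x) if (!is.numeric(x) || length(x) != 1 || x < 0 ||
                                  x != round(x)) {
    "must be a non-negative integer"
  }
  pos_int <- function(x) if (!is.numeric(x) || length(x) != 1 || x < 1 ||
                               x != round(x)) {
    "must be a positive integer"
  }
  prob <- function(x) if (!is.numeric(x) || length(x) != 1 || x < 0 ||
                            x > 1) {
    "must lie in [0, 1]"
  }
  corr <- function(x) if (!is.numeric(x) || length(x) != 1 || x < -1 ||
                            x > 1) {
    "must lie in [-1, 1]"
  }
  flag <- function(x) if (!is.logical(x) || length(x) != 1) {
    "must be TRUE or FALSE"
  }
  list(seed = nonneg_int,
       simdata = list(n_cells_per_sample = pos_int,
                      samples_per_condition = pos_int, depth_mean = pos,
                      marker_fold = pos, n_de_genes = nonneg_int,
                      de_lfc = pos, plant_dc = flag, dc_rho_ctrl = corr,
                      dc_rho_trt = corr),
       bulk = list(n_genes = pos_int, de_fraction = prob, de_lfc = pos,
                   dispersion = function(x) {
                     if (!is.numeric(x) || length(x) != 1 || x < 0) {
                       "must be a non-negative number"
                     }
                   }, replicates = pos_int),
       qc = list(n_mads = pos, min_cells = nonneg_int),
       markers = list(adj_p = pos, lfc = pos),
       sc_de = list(alpha = pos, lfc = pos, min_cells = pos_int),
       bulk_de = list(count_threshold = pos, min_samples = pos_int,
                      alpha = pos, lfc = pos),
       gene_clusters = list(n_top = pos_int, cor_threshold = corr),
       coexpr = list(n_per_group = pos_int, permutations = pos_int,
                     q_threshold = pos, rho_threshold = corr),
       assays = list(enabled = flag))
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or nothing (all defaults).
#' Unknown keys are rejected and every schema violation is reported in one
#' error message naming the offending fields.
#'
#' @param config path to a YAML file, a nested list, or `NULL`.
#' @return the normalized configuration (defaults filled in).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  rules <- .config_rules()
  errors <- character()
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top)) {
    errors <- c(errors, paste0("unknown key: ", unknown_top))
  }
  for (section in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[section]])) {
      if (!is.list(config[[section]])) {
        errors <- c(errors, paste0(section, " must be a section"))
        next
      }
      unknown <- setdiff(names(config[[section]]),
                         names(defaults[[section]]))
      if (length(unknown)) {
        errors <- c(errors, paste0("unknown key: ", section, ".", unknown))
      }
      for (key in intersect(names(config[[section]]),
                            names(defaults[[section]]))) {
        msg <- rules[[section]][[key]](config[[section]][[key]])
        if (!is.null(msg)) {
          errors <- c(errors, paste0(section, ".", key, " ", msg))
        }
      }
    } else {
      msg <- rules[[section]](config[[section]])
      if (!is.null(msg)) errors <- c(errors, paste0(section, " ", msg))
    }
  }
  if (length(errors)) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  }
  out <- utils::modifyList(defaults, config)
  out$seed <- as.integer(out$seed)
  out
}

#' Write a configuration to YAML
#'
#' @param config configuration list (validated first).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

.stage_seed <- function(base, k) {
  as.integer((as.numeric(base) * 1009 + k * 9973) %% 2147483647)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes, in order: cohort simulation, single-cell QC and normalization,
#' marker ranking and cell-type assignment with fraction comparison,
#' per-cell-type condition DE, phagocyte co-expression and permutation
#' differential co-expression, bulk simulation with pOverA filtering,
#' size factors, per-timepoint NB Wald DE, gene clustering and two-way
#' ANOVA, gene-set over-representation against the planted truth, and
#' (optionally) the assay quantifications on generated fixtures. The
#' global seed is expanded deterministically into per-stage seeds, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config configuration (path, list, or `NULL` for defaults); see
#'   [validate_config()].
#' @param output_dir optional directory to write TSV/MTX/YAML outputs into.
#' @return list of per-stage results plus a `manifest` recording package
#'   version, seeds, stages, and the configuration hash.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL) {
  config <- validate_config(config)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("stage '", name, "' failed: ",
                                conditionMessage(e)))
      err$partial <- results
      stop(err)
    })
  }
  seeds <- vapply(1:6, function(k) .stage_seed(config$seed, k), integer(1))
  names(seeds) <- c("simdata", "bulk", "coexpr", "kmeans", "assays",
                    "reserved")

  results$cohort <- stage("simdata", {
    sim_cfg <- config$simdata
    design <- cohort_design(n_cells_per_sample = sim_cfg$n_cells_per_sample,
                            samples_per_condition =
                              sim_cfg$samples_per_condition,
                            depth_mean = sim_cfg$depth_mean,
                            marker_fold = sim_cfg$marker_fold,
                            seed = seeds["simdata"])
    de_lfc <- NULL
    if (sim_cfg$n_de_genes > 0) {
      g <- sprintf("BG%03d", seq_len(sim_cfg$n_de_genes))
      de_lfc <- stats::setNames(rep_len(c(1, -1), sim_cfg$n_de_genes) *
                                  sim_cfg$de_lfc, g)
    }
    dc_pairs <- NULL
    if (isTRUE(sim_cfg$plant_dc)) {
      dc_pairs <- data.frame(
        gene1 = sprintf("BG%03d", c(21, 23, 25)),
        gene2 = sprintf("BG%03d", c(22, 24, 26)),
        rho_ctrl = sim_cfg$dc_rho_ctrl, rho_trt = sim_cfg$dc_rho_trt)
    }
    model <- default_cohort_model(design, de_lfc = de_lfc,
                                  dc_pairs = dc_pairs)
    simulate_single_cell_cohort(design, model)
  })

  results$qc <- stage("qc", {
    cell_f <- filter_cells_mad(results$cohort$counts, config$qc$n_mads)
    counts <- filter_genes_min_cells(cell_f$counts, config$qc$min_cells)
    norm <- normalize_log(counts)
    cells <- results$cohort$cells[
      match(rownames(counts), results$cohort$cells$cell), ]
    rownames(cells) <- NULL
    list(counts = counts, normalized = norm$normalized, cells = cells,
         removal_report = cell_f$report, target = norm$target)
  })

  results$celltyping <- stage("celltyping", {
    markers <- rank_cluster_markers(results$qc$normalized,
                                    results$qc$cells$cluster,
                                    adj_p = config$markers$adj_p,
                                    lfc = config$markers$lfc)
    assignments <- assign_cell_types(markers)
    cells <- results$qc$cells
    cells$cell_type <- assignments$cell_type[
      match(cells$cluster, assignments$cluster)]
    fractions <- cell_type_fractions(cells)
    pairing <- stats::setNames(
      sub("^(control|treated)_", "p", unique(cells$sample)),
      unique(cells$sample))
    tests <- compare_fractions(fractions, pairing)
    list(markers = markers, assignments = assignments, cells = cells,
         fractions = fractions, fraction_tests = tests)
  })

  results$sc_de <- stage("sc_de", {
    sc_condition_de(results$qc$normalized, results$celltyping$cells,
                    min_cells = config$sc_de$min_cells,
                    alpha = config$sc_de$alpha,
                    lfc_threshold = config$sc_de$lfc)
  })

  results$coexpr <- stage("coexpr", {
    cells <- results$celltyping$cells
    phag <- cells$cell_type == "phagocyte"
    counts <- results$qc$counts
    genes <- colnames(counts)
    planted <- results$cohort$truth$dc_pairs
    null_pairs <- data.frame(gene1 = sprintf("BG%03d", c(31, 33)),
                             gene2 = sprintf("BG%03d", c(32, 34)))
    pairs <- if (is.null(planted)) null_pairs else {
      rbind(planted[, c("gene1", "gene2")], null_pairs)
    }
    pairs <- pairs[pairs$gene1 %in% genes & pairs$gene2 %in% genes, ]
    ctrl <- counts[phag & cells$condition == "control", , drop = FALSE]
    trt <- counts[phag & cells$condition == "treated", , drop = FALSE]
    est_ctrl <- estimate_coexpression(ctrl, pairs)
    est_trt <- estimate_coexpression(trt, pairs)
    diff <- differential_coexpression(
      ctrl, trt, pairs, n_per_group = config$coexpr$n_per_group,
      B = config$coexpr$permutations, seed = seeds["coexpr"],
      q_threshold = config$coexpr$q_threshold)
    list(estimates_control = est_ctrl, estimates_treated = est_trt,
         retained_control = filter_significant_pairs(
           est_ctrl, config$coexpr$q_threshold,
           config$coexpr$rho_threshold),
         retained_treated = filter_significant_pairs(
           est_trt, config$coexpr$q_threshold,
           config$coexpr$rho_threshold),
         differential = diff)
  })

  results$bulk <- stage("bulk", {
    bd <- bulk_design(n_genes = config$bulk$n_genes,
                      replicates = config$bulk$replicates,
                      dispersion = config$bulk$dispersion,
                      de_fraction = config$bulk$de_fraction,
                      de_lfc = config$bulk$de_lfc, seed = seeds["bulk"])
    sim <- simulate_bulk_experiment(bd)
    filtered <- pover_a_filter(sim$counts, config$bulk_de$count_threshold,
                               config$bulk_de$min_samples)
    sf <- median_of_ratios_size_factors(filtered)
    disp <- mom_dispersion(filtered, sf,
                           paste(sim$samples$condition,
                                 sim$samples$timepoint))
    de_by_tp <- lapply(unique(sim$samples$timepoint), function(tp) {
      idx <- sim$samples$timepoint == tp
      res <- nb_wald_test(filtered[, idx, drop = FALSE], sf[idx],
                          sim$samples$condition[idx],
                          alpha = config$bulk_de$alpha,
                          lfc_threshold = config$bulk_de$lfc,
                          dispersion = disp)
      res$timepoint <- tp
      res
    })
    de_all <- do.call(rbind, de_by_tp)
    de_genes <- unique(de_all$gene[de_all$significant])
    vst <- vst_transform(filtered, sf)
    clusters <- NULL
    anova_tables <- NULL
    if (length(de_genes) >= 2) {
      clusters <- kmeans_gene_clusters(
        vst[de_genes, , drop = FALSE], sim$samples$condition,
        seed = seeds["kmeans"], n_top = config$gene_clusters$n_top,
        cor_threshold = config$gene_clusters$cor_threshold)
      anova_tables <- lapply(seq_len(nrow(clusters$centroids)),
                             function(cl) {
        g <- names(clusters$cluster)[clusters$cluster == cl]
        df <- data.frame(
          value = colMeans(vst[g, , drop = FALSE]),
          treatment = sim$samples$condition,
          timepoint = sim$samples$timepoint)
        cluster_mean_anova(df)
      })
    }
    list(sim = sim, filtered = filtered, size_factors = sf, de = de_all,
         de_genes = de_genes, gene_clusters = clusters,
         anova = anova_tables)
  })

  results$enrichment <- stage("enrichment", {
    truth <- results$bulk$sim$truth
    universe <- rownames(results$bulk$sim$counts)
    up <- names(truth$lfc)[truth$lfc > 0]
    down <- names(truth$lfc)[truth$lfc < 0]
    sets <- list(planted_up = up, planted_down = down,
                 first_hundred = universe[seq_len(min(100,
                                                      length(universe)))])
    sets <- sets[lengths(sets) > 0]
    collection <- gene_set_collection(sets, universe)
    query <- intersect(results$bulk$de_genes, universe)
    hypergeometric_ora(query, collection)
  })

  if (isTRUE(config$assays$enabled)) {
    results$assays <- stage("assays", {
      dr <- simulate_assay_fixtures("dose_response",
                                    list(noise_cv = 0.05),
                                    seed = seeds["assays"])
      fit <- fit_ld50_3param(dr$data)
      comet <- simulate_assay_fixtures("comet_masks",
                                       seed = seeds["assays"])
      tail_rec <- comet_tail_percent(comet$image, comet$head_mask,
                                     comet$tail_mask)
      pim <- simulate_assay_fixtures("puncta_image",
                                     seed = seeds["assays"])
      dens <- puncta_density_normalized(pim$signal, pim$nuclei)
      blot <- densitometry_normalize(
        lane = c(1000, 1400, 900, 1600, 1100, 1500),
        background = 100,
        control = c(450, 430, 460, 420, 440, 455),
        control_background = 50)
      list(dose_response = fit, comet = tail_rec, puncta = dens,
           densitometry = blot)
    })
  }

  results$manifest <- list(
    package = "coelomyx",
    version = as.character(utils::packageVersion("coelomyx")),
    seed = config$seed, stage_seeds = as.list(seeds),
    config_hash = .config_hash(config),
    stages = setdiff(names(results), "manifest"),
    config = config)

  if (!is.null(output_dir)) .write_pipeline_outputs(results, output_dir)
  results
}

.write_pipeline_outputs <- function(results, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_count_matrix(results$qc$counts, file.path(output_dir, "counts"))
  .write_tsv(results$celltyping$cells, file.path(output_dir, "cells.tsv"))
  .write_tsv(results$celltyping$markers,
             file.path(output_dir, "markers.tsv"))
  .write_tsv(results$celltyping$fractions,
             file.path(output_dir, "fractions.tsv"))
  .write_tsv(results$celltyping$fraction_tests,
             file.path(output_dir, "fraction_tests.tsv"))
  .write_tsv(results$sc_de, file.path(output_dir, "sc_de.tsv"))
  .write_tsv(results$coexpr$differential,
             file.path(output_dir, "differential_coexpression.tsv"))
  .write_tsv(results$bulk$de, file.path(output_dir, "bulk_de.tsv"))
  .write_tsv(results$enrichment, file.path(output_dir, "enrichment.tsv"))
  writeLines(yaml::as.yaml(results$manifest[
    c("package", "version", "seed", "stage_seeds", "config_hash",
      "stages")]), file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}
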