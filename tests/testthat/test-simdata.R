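test_that("independent zero-variance latents give Poisson counts", {
  mu <- setNames(rep(0.02, 10), sprintf("g%02d", 1:10))
  model <- latent_model(mu, sigma = matrix(0, 10, 10,
                                           dimnames = list(names(mu),
                                                           names(mu))))
  design <- cohort_design(n_cells_per_sample = 3000,
                          samples_per_condition = 1,
                          markers = list(), marker_fold = 1,
                          depth_mean = 1000, depth_cv = 0, seed = 11)
  sim <- simulate_single_cell_cohort(design, model)
  X <- as.matrix(sim$counts)
  ratio <- apply(X, 2, var) / colMeans(X)
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("realized type counts stay inside the multinomial 99% envelope", {
  design <- cohort_design(n_cells_per_sample = 10000,
                          samples_per_condition = 1, seed = 7)
  sim <- simulate_single_cell_cohort(design)
  frac <- table(sim$cells$cell_type_true) / nrow(sim$cells)
  for (ty in names(design$type_props)) {
    p <- design$type_props[[ty]]
    half <- qnorm(0.995) * sqrt(p * (1 - p) / 10000)
    expect_lt(abs(frac[[ty]] - p), half)
  }
})

test_that("latent draws reproduce the planted copula correlation", {
  d <- sim_pair_counts(5000, rho = 0.5, depth_cv = 0, seed = 21)
  expect_lt(abs(cor(d$latent[, 1], d$latent[, 2]) - 0.5), 0.03)
})

test_that("Poisson thinning attenuates the count-level correlation", {
  for (seed in 1:3) {
    d <- sim_pair_counts(5000, rho = 0.5, seed = seed)
    expect_lt(abs(cor(d$counts[, 1], d$counts[, 2])), 0.5)
  }
})

test_that("counts regress on depths to the latent means", {
  mu <- setNames(c(0.05, 0.02, 0.01), c("a", "b", "c"))
  model <- latent_model(mu, cv = 0.5)
  design <- cohort_design(n_cells_per_sample = 4000,
                          samples_per_condition = 1, markers = list(),
                          marker_fold = 1, depth_mean = 2000, seed = 3)
  sim <- simulate_single_cell_cohort(design, model)
  s <- sim$truth$depths[rownames(sim$counts)]
  for (g in names(mu)) {
    fit <- lm(as.numeric(sim$counts[, g]) ~ 0 + s)
    est <- coef(fit)[["s"]]
    se <- summary(fit)$coefficients["s", "Std. Error"]
    expect_lt(abs(est - mu[[g]]), 3 * se)
  }
})

test_that("cohort regeneration under the same seed is bit-identical", {
  design <- cohort_design(n_cells_per_sample = 200, seed = 5)
  a <- simulate_single_cell_cohort(design)
  b <- simulate_single_cell_cohort(design)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$depths, b$truth$depths)
})

test_that("impossible planted correlations fail naming the pair", {
  mu <- setNames(rep(1, 3), c("x", "y", "z"))
  sigma <- diag(0.25, 3)
  dimnames(sigma) <- list(names(mu), names(mu))
  sigma[1, 2] <- sigma[2, 1] <- 0.3  # implied correlation 1.2
  expect_error(latent_model(mu, sigma), "x~y")
})

test_that("near-singular planted correlation matrices are repaired to PSD", {
  mu <- setNames(rep(1, 3), c("x", "y", "z"))
  dc <- data.frame(gene1 = c("x", "x", "y"), gene2 = c("y", "z", "z"),
                   rho_ctrl = c(0.9, 0.9, -0.9), rho_trt = 0)
  model <- latent_model(mu, cv = 0.5, dc_pairs = dc)
  ev <- eigen(model$R_control, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("zero-dispersion bulk counts are Poisson and planted folds recover", {
  sim <- simulate_bulk_experiment(bulk_design(n_genes = 400, dispersion = 0,
                                              de_fraction = 0,
                                              sample_depth_sd = 0,
                                              seed = 2))
  ratio <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  expect_lt(abs(median(ratio) - 1), 0.15)

  sim2 <- simulate_bulk_experiment(bulk_design(n_genes = 1000,
                                               de_fraction = 0.1,
                                               de_lfc = 2, de_balance = 1,
                                               sample_depth_sd = 0,
                                               seed = 4))
  de <- sim2$truth$de_genes
  trt <- sim2$samples$condition == "treated"
  obs_ratio <- rowMeans(sim2$counts[de, trt]) /
    rowMeans(sim2$counts[de, !trt])
  expect_lt(abs(mean(obs_ratio) - 4), 0.3)
})

test_that("bulk regeneration under the same seed is identical", {
  d <- bulk_design(n_genes = 100, seed = 9)
  expect_identical(simulate_bulk_experiment(d),
                   simulate_bulk_experiment(d))
})

test_that("assay fixture ground truth is internally consistent", {
  dr <- simulate_assay_fixtures("dose_response",
                                list(ld50 = 1000, hill = 2, top = 100,
                                     noise_cv = 0))
  at_ld50 <- dr$data$viability[dr$data$dose == 1000]
  expect_equal(unique(at_ld50), 50)

  cm <- simulate_assay_fixtures("comet_masks",
                                list(head_sum = 900, tail_sum = 100))
  expect_equal(cm$truth$tail_pct, 10)
  expect_equal(sum(cm$image[cm$head_mask]), 900, tolerance = 1e-9)

  pim <- simulate_assay_fixtures("puncta_image",
                                 list(n_nuclei = 12, n_puncta = 40),
                                 seed = 3)
  expect_identical(pim$truth$n_nuclei, 12)
  expect_identical(pim$truth$n_puncta, 40)

  expect_error(simulate_assay_fixtures("unknown_kind"), "unknown")
})

test_that("fixtures round-trip to plain-text files with a YAML sidecar", {
  dir <- tempfile()
  simulate_assay_fixtures("dose_response", seed = 2, dir = dir)
  expect_true(file.exists(file.path(dir, "dose_response.csv")))
  side <- yaml::read_yaml(file.path(dir, "dose_response_params.yaml"))
  expect_equal(side$seed, 2)
  expect_equal(side$ld50, 7232)
})

test_that("count matrices round-trip through MTX sidecar files", {
  X <- random_counts(30, 12, seed = 8)
  dir <- tempfile()
  write_count_matrix(X, dir)
  back <- read_count_matrix(dir)
  expect_equal(as.matrix(back), X)
})
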