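test_that("pOverA keeps genes at the count/sample boundary", {
  counts <- rbind(
    ten_in_three = c(10, 10, 10, 0, 0, 0),
    nine_fifty = c(9, 50, 50, 0, 0, 0),
    all_zero = c(0, 0, 0, 0, 0, 0),
    strong = c(100, 100, 100, 100, 100, 100))
  out <- pover_a_filter(counts)
  expect_setequal(rownames(out), c("ten_in_three", "strong"))
})

test_that("pOverA equals a brute-force double loop", {
  set.seed(3)
  counts <- matrix(rpois(500 * 8, 8), 500, 8,
                   dimnames = list(sprintf("g%03d", 1:500), NULL))
  out <- pover_a_filter(counts, 10, 3)
  expect_gt(nrow(out), 0)
  expect_lt(nrow(out), nrow(counts))
  brute <- rownames(counts)[vapply(seq_len(nrow(counts)), function(i) {
    n_ok <- 0
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] >= 10) n_ok <- n_ok + 1
    }
    n_ok >= 3 && sum(counts[i, ]) > 0
  }, logical(1))]
  expect_identical(rownames(out), brute)
})

test_that("size factors honor scale and identity cases", {
  X <- matrix(rpois(100 * 2, 50), 100, 2)
  X <- cbind(X[, 1], X[, 1])
  expect_equal(unname(median_of_ratios_size_factors(X)), c(1, 1))

  Y <- cbind(a = rpois(100, 60) + 1, b = 0)
  Y[, "b"] <- Y[, "a"] * 2
  sf <- median_of_ratios_size_factors(Y)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  Z <- matrix(0, 5, 3)
  expect_error(median_of_ratios_size_factors(Z), "pseudo-reference")
})

test_that("size factors recover simulated depth multipliers within 5%", {
  sim <- simulate_bulk_experiment(bulk_design(n_genes = 2000,
                                              de_fraction = 0,
                                              sample_depth_sd = 0.25,
                                              seed = 6))
  sf <- median_of_ratios_size_factors(pover_a_filter(sim$counts))
  truth <- sim$truth$depth_multipliers
  truth <- truth / exp(mean(log(truth)))
  expect_lt(max(abs(sf / truth - 1)), 0.05)
})

test_that("identical groups give zero fold-change and p of 1", {
  X <- matrix(rpois(200 * 3, 40), 200, 3)
  counts <- cbind(X, X)
  rownames(counts) <- sprintf("g%d", 1:200)
  res <- nb_wald_test(counts, rep(1, 6), rep(c("a", "b"), each = 3))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p == 1))
})

test_that("the Wald test is invariant to joint count/size-factor scaling", {
  sim <- simulate_bulk_experiment(bulk_design(n_genes = 300, seed = 8))
  idx <- sim$samples$timepoint == 6
  counts <- pover_a_filter(sim$counts[, idx])
  sf <- median_of_ratios_size_factors(counts)
  res1 <- nb_wald_test(counts, sf, sim$samples$condition[idx])
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 7
  sf2 <- sf
  sf2[2] <- sf2[2] * 7
  res2 <- nb_wald_test(counts2, sf2, sim$samples$condition[idx])
  expect_equal(res1$stat, res2$stat, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("BH adjusted p values are monotone in raw-p rank", {
  set.seed(11)
  p <- runif(200)^2
  q <- benjamini_hochberg(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

test_that("k-means recovers planted antiphase profile groups", {
  for (seed in 1:10) {
    set.seed(seed)
    profile <- c(-2, -1, 0, 1, 2, 2, 1, 0, -1, -2)
    up <- matrix(rep(profile, 15), 15, 10, byrow = TRUE)
    down <- -up
    mat <- rbind(up, down) + matrix(rnorm(300, 0, 0.1), 30, 10)
    rownames(mat) <- sprintf("g%02d", 1:30)
    treatment <- rep(c("control", "treated"), 5)
    km <- kmeans_gene_clusters(mat, treatment, seed = seed)
    grp <- km$cluster[sprintf("g%02d", 1:30)]
    expect_equal(length(unique(grp[1:15])), 1)
    expect_equal(length(unique(grp[16:30])), 1)
    expect_false(grp[1] == grp[16])
  }
})

test_that("a row equal to its centroid has centroid correlation 1", {
  base <- c(1, 2, 3, 4, 3, 2)
  mat <- rbind(r1 = base, r2 = base, r3 = -base, r4 = -base)
  km <- kmeans_gene_clusters(mat, treatment = rep(c("a", "b"), 3),
                             seed = 1)
  expect_equal(unname(km$centroid_cor["r1"]), 1, tolerance = 1e-12)
  expect_error(kmeans_gene_clusters(rbind(base, base, base),
                                    rep(c("a", "b"), 3)),
               "single cluster")
})

test_that("cluster ordering puts the treated-elevated cluster first", {
  mat <- rbind(up1 = c(0, 5, 0, 5), up2 = c(0, 4, 0, 6),
               dn1 = c(5, 0, 5, 0), dn2 = c(6, 0, 4, 0))
  km <- kmeans_gene_clusters(mat,
                             treatment = c("control", "treated",
                                           "control", "treated"),
                             seed = 2)
  expect_equal(unname(km$cluster[c("up1", "up2")]), c(1, 1))
  expect_equal(unname(km$cluster[c("dn1", "dn2")]), c(2, 2))
})

test_that("two-way ANOVA matches additive structure and textbook fixture", {
  grid <- expand.grid(treatment = c("ctl", "uvb"),
                      timepoint = c(0, 1, 3, 6, 24), rep = 1:3)
  # exact additivity, no noise: interaction SS is zero
  grid$value <- ifelse(grid$treatment == "uvb", 2, 0) +
    as.numeric(factor(grid$timepoint)) * 0.5
  tab <- cluster_mean_anova(grid)
  expect_lt(tab$sum_sq[tab$term == "treatment:timepoint"], 1e-20)

  # pure treatment shift with small noise
  set.seed(4)
  grid$value <- ifelse(grid$treatment == "uvb", 1, 0) + rnorm(30, 0, 0.2)
  tab2 <- cluster_mean_anova(grid)
  expect_lt(tab2$p[tab2$term == "treatment"], 0.01)
  expect_gt(tab2$p[tab2$term == "treatment:timepoint"], 0.05)

  # all values equal: F = 0, p = 1
  grid$value <- 3
  tab3 <- cluster_mean_anova(grid)
  expect_true(all(tab3$statistic == 0) && all(tab3$p == 1))

  # empty cell errors
  bad <- grid[!(grid$treatment == "uvb" & grid$timepoint == 3), ]
  expect_error(cluster_mean_anova(bad), "empty")
})

test_that("Type-II sums of squares match an independent implementation", {
  set.seed(21)
  grid <- expand.grid(treatment = c("ctl", "uvb"),
                      timepoint = c(0, 1, 3, 6, 24), rep = 1:3)
  grid$value <- rnorm(30) + ifelse(grid$treatment == "uvb", 0.8, 0)
  # drop one replicate to make the design unbalanced
  grid <- grid[-7, ]
  tab <- cluster_mean_anova(grid)
  fit <- lm(value ~ factor(treatment) * factor(timepoint), data = grid)
  ref <- car::Anova(fit, type = 2)
  expect_equal(tab$sum_sq, ref[1:3, "Sum Sq"], tolerance = 1e-10)
  expect_equal(tab$p, ref[1:3, "Pr(>F)"], tolerance = 1e-10)
})

test_that("single-cell condition DE calls planted genes and not the boundary", {
  set.seed(5)
  n <- 400
  cells <- data.frame(condition = rep(c("control", "treated"), each = n),
                      cell_type = "phagocyte")
  X <- matrix(rpois(2 * n * 6, 3), 2 * n, 6,
              dimnames = list(NULL, sprintf("g%d", 1:6)))
  X[cells$condition == "treated", "g1"] <-
    rpois(n, 12)  # planted 4-fold up
  norm <- log1p(X)
  res <- sc_condition_de(norm, cells)
  expect_equal(res$call[res$gene == "g1"], "up")
  expect_true(all(res$call[res$gene != "g1"] == "ns"))

  # exact log2fc of 1 is not called (strict inequality)
  Xb <- matrix(0, 2 * n, 2, dimnames = list(NULL, c("gx", "gy")))
  Xb[cells$condition == "treated", "gx"] <- 3
  Xb[cells$condition == "control", "gx"] <- 1
  Xb[, "gy"] <- rep(c(1, 2), n)
  normb <- log1p(Xb)
  resb <- sc_condition_de(normb, cells)
  expect_equal(resb$log2fc[resb$gene == "gx"], 1)
  expect_lt(resb$q[resb$gene == "gx"], 0.05)
  expect_equal(resb$call[resb$gene == "gx"], "ns")

  # undersized groups are skipped with a warning
  small <- cells
  small$cell_type[1:(2 * n - 10)] <- "phagocyte"
  small$cell_type[seq_len(5)] <- "RSC"
  expect_warning(sc_condition_de(norm, small), "RSC")
})

test_that("label-permuted single-cell DE is calibrated", {
  set.seed(17)
  n <- 300
  X <- matrix(rpois(2 * n * 40, 3), 2 * n, 40,
              dimnames = list(NULL, sprintf("g%d", 1:40)))
  cells <- data.frame(condition = sample(rep(c("control", "treated"),
                                             each = n)),
                      cell_type = "phagocyte")
  res <- sc_condition_de(log1p(X), cells)
  rate <- mean(res$p < 0.05)
  expect_gt(rate, 0.0)
  expect_lt(rate, 0.15)
})
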