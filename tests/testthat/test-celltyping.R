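norm_fixture <- function(n_per_cluster = 60, n_genes = 8, seed = 1) {
  set.seed(seed)
  clusters <- rep(c("c0", "c1"), each = n_per_cluster)
  X <- matrix(rpois(2 * n_per_cluster * n_genes, 2), 2 * n_per_cluster,
              n_genes, dimnames = list(NULL, sprintf("g%d",
                                                     seq_len(n_genes))))
  list(norm = log1p(X), clusters = clusters)
}

test_that("a gene expressed only in one cluster is its significant marker", {
  fx <- norm_fixture(seed = 2)
  fx$norm[, "g1"] <- ifelse(fx$clusters == "c0", log1p(20), 0)
  mk <- rank_cluster_markers(fx$norm, fx$clusters)
  row <- mk[mk$cluster == "c0" & mk$gene == "g1", ]
  expect_true(row$significant)
  expect_gt(row$log2fc, 0.5)
  expect_false(mk[mk$cluster == "c1" & mk$gene == "g1", "significant"])
})

test_that("null genes are not called markers across seeded fixtures", {
  hits <- vapply(1:10, function(seed) {
    fx <- norm_fixture(seed = seed)
    mk <- rank_cluster_markers(fx$norm, fx$clusters)
    sum(mk$significant)
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.05)
})

test_that("undersized clusters are excluded with a warning", {
  fx <- norm_fixture(seed = 3)
  clusters <- fx$clusters
  clusters[1:2] <- "tiny"
  expect_warning(mk <- rank_cluster_markers(fx$norm, clusters), "tiny")
  expect_false("tiny" %in% mk$cluster)
})

marker_table <- function(sig_by_cluster) {
  dict_genes <- unique(unlist(lapply(default_marker_dictionary(),
                                     function(d) {
    unlist(c(d$significant, d$not_significant))
  })))
  do.call(rbind, lapply(names(sig_by_cluster), function(cl) {
    data.frame(cluster = cl, gene = dict_genes,
               statistic = 0, p = 1, q = 1, log2fc = 0,
               significant = dict_genes %in% sig_by_cluster[[cl]])
  }))
}

test_that("dictionary rules assign the four coelomocyte types", {
  mk <- marker_table(list(
    c0 = "Pks1",
    c1 = c("SpTrf-A", "TLR-1"),
    c2 = c("DYH-2", "Sp-P2rx4"),
    c3 = c("BPI", "Lyz", "Strongylocin"),
    c4 = character(0),
    c5 = c("BPI", "Lyz")  # incomplete CSC signature
  ))
  out <- assign_cell_types(mk)
  got <- setNames(out$cell_type, out$cluster)
  expect_equal(got[["c0"]], "RSC")
  expect_equal(got[["c1"]], "phagocyte")
  expect_equal(got[["c2"]], "vibratile")
  expect_equal(got[["c3"]], "CSC")
  expect_equal(got[["c4"]], "unassigned")
  expect_equal(got[["c5"]], "unassigned")
})

test_that("CSC requires its exclusion conditions and precedence holds", {
  # full CSC signature but significant Pks1: precedence gives RSC
  mk <- marker_table(list(c0 = c("BPI", "Lyz", "Strongylocin", "Pks1")))
  expect_equal(assign_cell_types(mk)$cell_type, "RSC")
  # CSC signature plus a significant phagocyte marker: phagocyte wins and
  # the CSC exclusion would anyway veto
  mk2 <- marker_table(list(c0 = c("BPI", "Lyz", "Strongylocin", "SpC3")))
  expect_equal(assign_cell_types(mk2)$cell_type, "phagocyte")
})

test_that("assignment is invariant to cluster relabeling", {
  sig <- list(c0 = "Pks1", c1 = c("SpTrf-A"),
              c2 = c("DYH-1"), c3 = c("BPI", "Lyz", "Strongylocin"))
  out1 <- assign_cell_types(marker_table(sig))
  relabeled <- setNames(sig, c("z9", "a1", "m5", "b2"))
  out2 <- assign_cell_types(marker_table(relabeled))
  map1 <- setNames(out1$cell_type, out1$cluster)
  map2 <- setNames(out2$cell_type, out2$cluster)
  expect_equal(unname(map1[c("c0", "c1", "c2", "c3")]),
               unname(map2[c("z9", "a1", "m5", "b2")]))
})

test_that("missing dictionary genes raise an informative error", {
  mk <- marker_table(list(c0 = "Pks1"))
  mk <- mk[mk$gene != "Lyz", ]
  expect_error(assign_cell_types(mk), "Lyz")
})

test_that("fractions cover all types, include zeros, and sum to one", {
  cells <- data.frame(
    sample = rep(c("s1", "s2"), c(100, 50)),
    condition = rep(c("control", "treated"), c(100, 50)),
    cell_type = c(rep(c("phagocyte", "vibratile", "RSC", "CSC"),
                      c(79, 7, 6, 8)),
                  rep(c("phagocyte", "unassigned"), c(45, 5))))
  fr <- cell_type_fractions(cells)
  s1 <- fr[fr$sample == "s1", ]
  expect_equal(s1$fraction[match(c("phagocyte", "vibratile", "RSC", "CSC"),
                                 s1$cell_type)],
               c(0.79, 0.07, 0.06, 0.08))
  # absent type present with fraction zero
  expect_equal(s1$fraction[s1$cell_type == "unassigned"], 0)
  sums <- tapply(fr$fraction, fr$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("paired fraction comparison matches the closed-form t", {
  fr <- data.frame(
    sample = rep(c("c1", "c2", "c3", "t1", "t2", "t3"), each = 1),
    condition = rep(c("control", "treated"), each = 3),
    cell_type = "phagocyte",
    n = 1,
    fraction = c(0.70, 0.75, 0.80, 0.78, 0.85, 0.86))
  pairing <- setNames(rep(c("p1", "p2", "p3"), 2), fr$sample)
  out <- compare_fractions(fr, pairing)
  d <- c(0.08, 0.10, 0.06)
  t_ref <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(out$t, t_ref, tolerance = 1e-12)
  expect_false(out$degenerate)

  # identical fractions in both conditions: degenerate, p = 1
  fr$fraction <- rep(c(0.7, 0.75, 0.8), 2)
  out2 <- compare_fractions(fr, pairing)
  expect_true(out2$degenerate)
  expect_equal(out2$p, 1)

  # constant nonzero differences: degenerate flag
  fr$fraction <- c(0.7, 0.75, 0.8, 0.8, 0.85, 0.9)
  out3 <- compare_fractions(fr, pairing)
  expect_true(out3$degenerate)
})

test_that("planted cohorts are typed perfectly through the full path", {
  for (seed in c(101, 202)) {
    design <- cohort_design(n_cells_per_sample = 350, seed = seed)
    sim <- simulate_single_cell_cohort(design)
    qcf <- filter_cells_mad(sim$counts)
    counts <- filter_genes_min_cells(qcf$counts, 50)
    norm <- normalize_log(counts)
    cl <- sim$cells$cluster[match(rownames(counts), sim$cells$cell)]
    mk <- rank_cluster_markers(norm$normalized, cl)
    out <- assign_cell_types(mk)
    truth <- sim$truth$cluster_type[out$cluster]
    expect_identical(setNames(out$cell_type, NULL), unname(truth))
  }
})
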