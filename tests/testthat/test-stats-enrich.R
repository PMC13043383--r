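test_that("BH matches the hand-computed step-up example", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.3), 0.3)
})

test_that("BH equals the brute-force definition on random vectors", {
  set.seed(2)
  for (m in c(1, 3, 7, 12)) {
    p <- runif(m)
    expect_equal(benjamini_hochberg(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("BH propagates NaN, excludes it from m, and is idempotent", {
  p <- c(0.01, NaN, 0.04)
  q <- benjamini_hochberg(p)
  expect_true(is.nan(q[2]))
  expect_equal(q[c(1, 3)], benjamini_hochberg(c(0.01, 0.04))[1:2])
  expect_true(all(q[c(1, 3)] >= p[c(1, 3)]))
  # flat adjusted vectors are fixed points of the step-up
  flat <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(benjamini_hochberg(flat), flat)
  expect_equal(benjamini_hochberg(rep(0.3, 5)), rep(0.3, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ORA reproduces the exact combinatorial case", {
  universe <- letters[1:10]
  coll <- gene_set_collection(list(s = letters[1:5]), universe)
  out <- hypergeometric_ora(letters[1:5], coll)
  expect_equal(out$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(out$overlap, 5)

  # zero overlap: upper tail is 1
  out0 <- hypergeometric_ora(letters[6:8], coll)
  expect_equal(out0$p, 1)
  expect_true(is.na(out0$strength))
})

test_that("ORA equals exhaustive enumeration on tiny universes", {
  set.seed(5)
  universe <- letters[1:9]
  sets <- list(u = letters[1:4], v = letters[3:8])
  coll <- gene_set_collection(sets, universe)
  query <- c("a", "c", "d", "g")
  out <- hypergeometric_ora(query, coll)
  for (nm in names(sets)) {
    ov <- length(intersect(sets[[nm]], query))
    expect_equal(out$p[out$set == nm],
                 ora_enum(universe, sets[[nm]], length(query), ov),
                 tolerance = 1e-12)
  }
})

test_that("ORA p is monotone decreasing in overlap at fixed sizes", {
  p_at <- vapply(0:4, function(ov) {
    phyper(ov - 1, 5, 7, 4, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("collections harmonize sets against the universe", {
  expect_warning(
    coll <- gene_set_collection(list(a = c("x", "nope"), b = "gone"),
                                c("x", "y")),
    "empty gene sets")
  expect_identical(names(coll$sets), "a")
  expect_identical(coll$sets$a, "x")
  expect_error(hypergeometric_ora("zz", coll), "outside the universe")
  expect_equal(nrow(hypergeometric_ora(character(0), coll)), 0)
})

test_that("GMT files round-trip", {
  path <- tempfile(fileext = ".gmt")
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  write_gmt(sets, path, description = c("first", "second"))
  back <- read_gmt(path)
  expect_equal(back$alpha, sets$alpha)
  expect_equal(back$beta, sets$beta)
  expect_equal(unname(attr(back, "description")["alpha"]), "first")
})

test_that("rank-sum test gives the exact enumerated p for small samples", {
  out <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_true(out$exact)
  expect_equal(out$p, 0.1, tolerance = 1e-12)
  expect_equal(out$statistic, 6)  # ranks 1+2+3

  same <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)
})

test_that("rank-sum test is calibrated in large samples and order-invariant", {
  set.seed(9)
  hits <- replicate(300, {
    x <- rnorm(30)
    y <- rnorm(30)
    wilcoxon_rank_sum(x, y)$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.035)
  x <- rnorm(15)
  y <- rnorm(12)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
})

test_that("paired t matches the closed form and flags degeneracy", {
  d <- c(0.4, 0.7, 0.1, 0.9, 0.5)
  out <- paired_t(d, alternative = "two.sided")
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$statistic, t_ref, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_ref), df = 4), tolerance = 1e-12)

  up <- paired_t(rep(1, 4) + c(1e-3, -1e-3, 2e-3, -2e-3), alternative = "greater")
  expect_lt(up$p, 1e-6)
  sym <- paired_t(c(-2, -1, 1, 2), alternative = "greater")
  expect_equal(sym$p, 0.5)
  deg <- paired_t(rep(0.1, 3))
  expect_true(deg$degenerate)
})

test_that("one-way ANOVA with Tukey matches oracles and edge cases", {
  # textbook 3-group sum-of-squares decomposition
  g <- rep(c("a", "b", "c"), each = 4)
  v <- c(1, 2, 3, 4, 3, 4, 5, 6, 6, 7, 8, 9)
  out <- oneway_anova_tukey(v, g)
  grand <- mean(v)
  ss_between <- 4 * sum((tapply(v, g, mean) - grand)^2)
  ss_within <- sum((v - ave(v, g))^2)
  f_ref <- (ss_between / 2) / (ss_within / 9)
  expect_equal(out$F, f_ref, tolerance = 1e-12)

  # two-group Tukey equals the pooled two-sided t-test p
  g2 <- rep(c("a", "b"), each = 5)
  v2 <- c(rnorm(5, 0), rnorm(5, 1))
  out2 <- oneway_anova_tukey(v2, g2)
  t_p <- t.test(v2 ~ g2, var.equal = TRUE)$p.value
  expect_equal(out2$tukey$p_adj, t_p, tolerance = 1e-6)

  # degenerate and invalid inputs
  same <- oneway_anova_tukey(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(oneway_anova_tukey(1:4, c("a", "a", "a", "b")),
               "at least 2")
})
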