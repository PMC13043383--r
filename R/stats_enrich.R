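#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving step-up FDR adjustment, capped at 1. `NA`/`NaN` entries
#' propagate unchanged and are excluded from the number of tests.
#'
#' @param p numeric vector of p values in `[0, 1]` (plus `NA`/`NaN`).
#' @return adjusted values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  out <- as.numeric(p)
  idx <- !is.na(out)
  if (any(out[idx] < 0 | out[idx] > 1)) stop("p values must lie in [0, 1]")
  out[idx] <- stats::p.adjust(out[idx], method = "BH")
  out
}

#' Gene-set collection for over-representation analysis
#'
#' Harmonizes named gene sets against a background universe: members
#' outside the universe are dropped, and sets left empty are removed with a
#' warning.
#'
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background gene identifiers.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(universe) >= 1)
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("empty gene sets dropped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set of the collection, BH-adjusted across sets. The enrichment
#' strength is `log10((overlap/query) / (set/universe))` (`NA` at zero
#' overlap).
#'
#' @param query character vector of query genes (must lie in the universe).
#' @param collection a [gene_set_collection()].
#' @return `data.frame` with `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `strength`, `p`, `q`.
#' @export
hypergeometric_ora <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    stop("query genes outside the universe: ",
         paste(outside, collapse = ", "))
  }
  if (!length(query)) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), strength = numeric(),
                      p = numeric(), q = numeric()))
  }
  N <- length(collection$universe)
  nq <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    K <- length(s)
    ov <- length(intersect(s, query))
    p <- stats::phyper(ov - 1, K, N - K, nq, lower.tail = FALSE)
    strength <- if (ov > 0) log10((ov / nq) / (K / N)) else NA_real_
    data.frame(set = nm, overlap = ov, set_size = K, query_size = nq,
               universe_size = N, strength = strength, p = p,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p for combined `n <= 20` without ties, normal
#' approximation with tie correction otherwise. If every value in both
#' groups is identical the test is degenerate and p is 1.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (rank-sum `W` of `x`), `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    return(list(statistic = sum(rank(c(x, y))[seq_along(x)]), p = 1,
                exact = FALSE))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !has_ties
  wt <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  # wilcox.test reports the Mann-Whitney U; convert to the rank-sum W of x
  list(statistic = unname(wt$statistic) +
         length(x) * (length(x) + 1) / 2,
       p = wt$p.value, exact = use_exact)
}

#' Paired t-test on differences
#'
#' One-sided by default direction argument; the two-sided variant serves
#' fraction comparisons. Zero-variance differences are flagged degenerate:
#' p is 1 when all differences are zero, `NA` otherwise.
#'
#' @param x paired differences, or first member when `y` is given.
#' @param y optional second member (differences are `x - y`).
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return list with `statistic`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(x, y = NULL,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 2)
  # constant differences up to floating-point noise are degenerate
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    zeroish <- all(abs(d) <= 1e-12 * max(1, max(abs(d))))
    return(list(statistic = if (zeroish) 0 else NA_real_,
                df = length(d) - 1,
                p = if (zeroish) 1 else NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(d, alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric response.
#' @param groups group labels (at least two groups, each with at least two
#'   observations).
#' @return list with `F`, `p`, and `tukey` (`data.frame` of pairwise
#'   comparisons with adjusted p). All-identical input gives `F = 0`,
#'   `p = 1` and Tukey adjusted p of 1.
#' @export
oneway_anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  combos <- utils::combn(levels(groups), 2)
  comparison <- paste(combos[2, ], combos[1, ], sep = "-")
  if (stats::var(values) == 0) {
    return(list(F = 0, p = 1,
                tukey = data.frame(comparison = comparison, diff = 0,
                                   p_adj = 1, row.names = NULL)))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit)$groups
  list(F = tab["groups", "F value"], p = tab["groups", "Pr(>F)"],
       tukey = data.frame(comparison = rownames(hsd),
                          diff = hsd[, "diff"], p_adj = hsd[, "p adj"],
                          row.names = NULL))
}
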