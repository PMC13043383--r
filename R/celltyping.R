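#' Default coelomocyte marker dictionary
#'
#' Maps each of the four canonical coelomocyte cell types to its marker
#' signature. Red spherule cells (RSC) are called by polyketide synthase 1
#' (*Pks1*), the echinochrome pigment synthase. Phagocytes are called by any
#' of the SpTransformer family, Toll-like receptors, complement *SpC3*, or
#' *Sp-B7L3*. Vibratile cells are called by axonemal dynein heavy chain
#' genes, with *Sp-P2rx4* and *FoxJ1* as supporting (non-required) markers.
#' Colorless spherule cells (CSC) need the combined signature of
#' bactericidal permeability-increasing protein, lysozyme, and strongylocin
#' all significant, together with *non*-significant *Pks1* and phagocyte
#' markers (they are partly defined by exclusion).
#'
#' Each entry has `mode` (`"any"`: any group fires; `"all"`: every group
#' must fire, a group firing when any of its genes is significant),
#' `significant` (list of required gene groups), and optionally
#' `not_significant` (groups that must contain no significant gene) and
#' `supporting` (informative but not required).
#'
#' @return named list usable by [assign_cell_types()].
#' @export
default_marker_dictionary <- function() {
  phagocyte_groups <- list(c("SpTrf-A", "SpTrf-B"), "TLR-1", "SpC3",
                           "Sp-B7L3")
  list(
    RSC = list(mode = "any", significant = list("Pks1")),
    phagocyte = list(mode = "any", significant = phagocyte_groups),
    vibratile = list(mode = "any", significant = list(c("DYH-1", "DYH-2")),
                     supporting = list("Sp-P2rx4", "FoxJ1")),
    CSC = list(mode = "all",
               significant = list("BPI", "Lyz", "Strongylocin"),
               not_significant = c(list("Pks1"), phagocyte_groups))
  )
}

#' Rank one-vs-rest cluster markers
#'
#' For every cluster with at least three cells, each gene is tested with a
#' two-sided rank-sum test of the cluster's cells against all other cells on
#' log-normalized values. Log2 fold-changes are of group means on the
#' normalized scale (pseudocount 1). P values are Benjamini-Hochberg
#' adjusted within each cluster, and a gene is flagged significant when
#' `q < adj_p` and `log2fc > lfc` (strict inequalities).
#'
#' @param normalized cells x genes log-normalized matrix
#'   (see [normalize_log()]).
#' @param clusters per-cell cluster labels.
#' @param adj_p adjusted-p threshold (default 0.05).
#' @param lfc log2 fold-change threshold (default 0.5).
#' @return `data.frame` with columns `cluster`, `gene`, `statistic`, `p`,
#'   `q`, `log2fc`, `significant`.
#' @export
rank_cluster_markers <- function(normalized, clusters, adj_p = 0.05,
                                 lfc = 0.5) {
  stopifnot(adj_p > 0, lfc > 0, nrow(normalized) == length(clusters))
  clusters <- as.character(clusters)
  tab <- table(clusters)
  if (length(tab) < 2) stop("at least two clusters required")
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("clusters with fewer than 3 cells excluded: ",
            paste(small, collapse = ", "))
  }
  use <- setdiff(names(tab), small)
  X <- as.matrix(normalized)
  genes <- colnames(X)
  out <- lapply(use, function(cl) {
    in_group <- clusters == cl
    rs <- .rank_sum_p(X, in_group)
    l2 <- .log2fc_normalized(X, in_group)
    q <- benjamini_hochberg(rs$p)
    data.frame(cluster = cl, gene = genes, statistic = rs$statistic,
               p = rs$p, q = q, log2fc = l2,
               significant = q < adj_p & l2 > lfc,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Assign cell types to clusters from marker significance
#'
#' Applies the marker dictionary's rules to a marker table from
#' [rank_cluster_markers()]. Rules are evaluated in the fixed precedence
#' RSC, phagocyte, vibratile, CSC; the first signature that fires wins, and
#' clusters matching no signature are `"unassigned"`. The CSC signature also
#' requires its exclusion conditions (no significant *Pks1* or phagocyte
#' marker).
#'
#' @param markers marker table covering every cluster to assign.
#' @param dictionary marker dictionary
#'   (default [default_marker_dictionary()]).
#' @return `data.frame` with columns `cluster` and `cell_type`.
#' @export
assign_cell_types <- function(markers, dictionary = default_marker_dictionary()) {
  dict_genes <- unique(unlist(lapply(dictionary, function(d) {
    unlist(c(d$significant, d$not_significant))
  })))
  missing <- setdiff(dict_genes, unique(markers$gene))
  if (length(missing)) {
    stop("dictionary genes absent from marker table: ",
         paste(missing, collapse = ", "))
  }
  clusters <- sort(unique(markers$cluster))
  assign_one <- function(cl) {
    sig_genes <- markers$gene[markers$cluster == cl & markers$significant]
    for (ty in names(dictionary)) {
      d <- dictionary[[ty]]
      fired <- vapply(d$significant, function(g) any(g %in% sig_genes),
                      logical(1))
      ok <- if (identical(d$mode, "all")) all(fired) else any(fired)
      if (ok && !is.null(d$not_significant)) {
        excluded <- vapply(d$not_significant,
                           function(g) any(g %in% sig_genes), logical(1))
        ok <- !any(excluded)
      }
      if (ok) return(ty)
    }
    "unassigned"
  }
  data.frame(cluster = clusters,
             cell_type = vapply(clusters, assign_one, character(1)),
             row.names = NULL)
}

#' Per-sample cell-type fractions
#'
#' Divides cell-type-specific counts by the total number of cells per
#' sample. Every combination of sample and cell type appears in the output
#' (absent types with fraction 0, `"unassigned"` included as its own
#' category), so fractions sum to exactly 1 within each sample.
#'
#' @param cells per-cell `data.frame` with columns `sample`, `cell_type`,
#'   and optionally `condition`.
#' @return `data.frame` with `sample`, (`condition`,) `cell_type`, `n`,
#'   `fraction`.
#' @export
cell_type_fractions <- function(cells) {
  stopifnot(all(c("sample", "cell_type") %in% names(cells)))
  samples <- unique(cells$sample)
  types <- unique(cells$cell_type)
  grid <- expand.grid(sample = samples, cell_type = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- as.data.frame(table(sample = cells$sample,
                             cell_type = cells$cell_type),
                       stringsAsFactors = FALSE)
  out <- merge(grid, tab, by = c("sample", "cell_type"), all.x = TRUE)
  out$Freq[is.na(out$Freq)] <- 0L
  totals <- table(cells$sample)
  out$n <- out$Freq
  out$Freq <- NULL
  out$fraction <- out$n / as.numeric(totals[out$sample])
  if ("condition" %in% names(cells)) {
    cond <- unique(cells[, c("sample", "condition")])
    out <- merge(out, cond, by = "sample")
    out <- out[, c("sample", "condition", "cell_type", "n", "fraction")]
  }
  out[order(out$sample, out$cell_type), , drop = FALSE]
}

#' Compare cell-type fractions between conditions with paired t-tests
#'
#' For each cell type, paired differences (treated minus control within each
#' pair) are tested with a two-sided paired t-test. Zero-variance
#' differences are flagged degenerate: p is 1 when all differences are zero
#' and `NA` otherwise.
#'
#' @param fractions output of [cell_type_fractions()] including `condition`.
#' @param pairing named character: sample name to pair identifier; each pair
#'   must hold one sample per condition.
#' @return `data.frame` with `cell_type`, `mean_diff`, `t`, `p`,
#'   `degenerate`.
#' @export
compare_fractions <- function(fractions, pairing) {
  stopifnot("condition" %in% names(fractions))
  conds <- sort(unique(fractions$condition))
  if (length(conds) != 2) stop("exactly two conditions required")
  fractions$pair <- pairing[fractions$sample]
  if (any(is.na(fractions$pair))) stop("pairing misses some samples")
  types <- unique(fractions$cell_type)
  out <- lapply(types, function(ty) {
    f <- fractions[fractions$cell_type == ty, ]
    wide <- merge(f[f$condition == conds[1], c("pair", "fraction")],
                  f[f$condition == conds[2], c("pair", "fraction")],
                  by = "pair", suffixes = c("_a", "_b"))
    if (nrow(wide) < 2) stop("need at least two pairs per cell type")
    d <- wide$fraction_b - wide$fraction_a
    tt <- paired_t(d, alternative = "two.sided")
    data.frame(cell_type = ty, mean_diff = mean(d), t = tt$statistic,
               p = tt$p, degenerate = tt$degenerate, row.names = NULL)
  })
  do.call(rbind, out)
}
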