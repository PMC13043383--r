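#' Fit a three-parameter logistic dose-response curve
#'
#' Model: `V(d) = top / (1 + (d / ld50)^hill)` with floor 0, so the fitted
#' viability at `ld50` is `top / 2` by construction. The fit is nonlinear
#' least squares with multi-starts over log-spaced `ld50` initials and hill
#' slopes in \{0.5, 1, 2, 4\}; the best converged start (lowest residual
#' sum of squares) is returned. If mean viability does not decline from the
#' lowest to the highest dose the data show no kill and the sentinel
#' `ld50 = Inf` is returned with `no_kill = TRUE`.
#'
#' @param dose numeric doses (must include 0 and at least 4 levels), or a
#'   `data.frame` with columns `dose` and `viability`.
#' @param viability numeric responses, when `dose` is a vector.
#' @return list of class `dose_response_fit` with `ld50`, `hill`, `top`,
#'   `rss`, `converged`, `no_kill`.
#' @export
fit_ld50_3param <- function(dose, viability = NULL) {
  if (is.data.frame(dose)) {
    df <- dose[, c("dose", "viability")]
  } else {
    df <- data.frame(dose = dose, viability = viability)
  }
  stopifnot(nrow(df) >= 4, any(df$dose == 0))
  if (length(unique(df$dose)) < 4) stop("at least 4 dose levels required")
  agg <- tapply(df$viability, df$dose, mean)
  doses_sorted <- sort(unique(df$dose))
  if (agg[as.character(max(doses_sorted))] >=
        agg[as.character(min(doses_sorted))]) {
    return(structure(list(ld50 = Inf, hill = NA_real_,
                          top = unname(agg[as.character(min(doses_sorted))]),
                          rss = NA_real_, converged = FALSE, no_kill = TRUE),
                     class = "dose_response_fit"))
  }
  dmax <- max(df$dose)
  dpos <- min(df$dose[df$dose > 0])
  starts <- expand.grid(
    ld50 = exp(seq(log(dpos / 2), log(2 * dmax), length.out = 6)),
    hill = c(0.5, 1, 2, 4))
  top0 <- max(agg)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nlsLM(
      viability ~ top / (1 + (dose / ld50)^hill), data = df,
      start = list(top = top0, ld50 = starts$ld50[k], hill = starts$hill[k]),
      lower = c(top = 0, ld50 = 1e-9, hill = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(ld50 = unname(cf["ld50"]), hill = unname(cf["hill"]),
                   top = unname(cf["top"]), rss = rss, converged = TRUE,
                   no_kill = FALSE)
    }
  }
  if (is.null(best)) {
    best <- list(ld50 = NA_real_, hill = NA_real_, top = NA_real_,
                 rss = NA_real_, converged = FALSE, no_kill = FALSE)
  }
  structure(best, class = "dose_response_fit")
}

#' Comet tail-DNA percent from an intensity image and head/tail masks
#'
#' Integrates intensity over the (disjoint) head and tail masks and reports
#' `100 * tail / (head + tail)`. A comet with zero total intensity is
#' flagged invalid.
#'
#' @param image numeric intensity matrix.
#' @param head_mask,tail_mask logical matrices, disjoint, same dimension as
#'   `image`.
#' @return list with `head`, `tail`, `tail_pct`, `valid`.
#' @export
comet_tail_percent <- function(image, head_mask, tail_mask) {
  stopifnot(identical(dim(image), dim(head_mask)),
            identical(dim(image), dim(tail_mask)))
  if (any(head_mask & tail_mask)) stop("head and tail masks overlap")
  head <- sum(image[head_mask])
  tail <- sum(image[tail_mask])
  total <- head + tail
  list(head = head, tail = tail,
       tail_pct = if (total > 0) 100 * tail / total else NA_real_,
       valid = total > 0)
}

#' Mean tail-DNA percent over scored comets
#'
#' @param tail_pcts per-comet tail percentages.
#' @param min_cells minimum number of scored comets expected per slide
#'   (default 50); fewer triggers a warning.
#' @return the mean tail percent.
#' @export
comet_slide_mean <- function(tail_pcts, min_cells = 50) {
  tail_pcts <- tail_pcts[!is.na(tail_pcts)]
  if (length(tail_pcts) < min_cells) {
    warning("fewer than ", min_cells, " scored comets (",
            length(tail_pcts), ")")
  }
  mean(tail_pcts)
}

#' Histogram thresholding (Otsu or triangle)
#'
#' Intensities are quantized to `levels` equally spaced gray levels between
#' the image minimum and maximum. Otsu returns the level maximizing the
#' between-class variance (lowest level on ties); triangle returns the
#' level whose histogram point lies furthest (perpendicular distance) from
#' the line joining the histogram peak to the far end of the occupied
#' range on the longer-tail side. The returned threshold is on the original
#' intensity scale; foreground is `image > threshold`.
#'
#' @param image numeric matrix (non-constant).
#' @param method `"otsu"` or `"triangle"`.
#' @param levels number of gray levels (default 256).
#' @return scalar threshold.
#' @export
image_threshold <- function(image, method = c("otsu", "triangle"),
                            levels = 256) {
  method <- match.arg(method)
  v <- as.numeric(image)
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) stop("constant image has no threshold")
  lev <- round((v - lo) / (hi - lo) * (levels - 1))
  h <- tabulate(lev + 1L, nbins = levels)
  t_lev <- if (method == "otsu") .otsu_level(h) else .triangle_level(h)
  centers <- lo + (0:(levels - 1)) * (hi - lo) / (levels - 1)
  (centers[t_lev + 1L] + centers[t_lev + 2L]) / 2
}

# between-class variance maximization via cumulative moments;
# ties resolved toward the lowest level
.otsu_level <- function(h) {
  h <- as.numeric(h)
  L <- length(h)
  n <- sum(h)
  lv <- 0:(L - 1)
  w0 <- cumsum(h)[-L]
  w1 <- n - w0
  m0 <- cumsum(h * lv)[-L]
  mt <- sum(h * lv)
  bcv <- rep(-Inf, L - 1)
  ok <- w0 > 0 & w1 > 0
  bcv[ok] <- (mt * w0[ok] / n - m0[ok])^2 / (w0[ok] / n * w1[ok] / n) / n^2
  which.max(bcv) - 1L
}

# maximum perpendicular distance from the peak-to-tail-end line
.triangle_level <- function(h) {
  L <- length(h)
  peak <- which.max(h) - 1L
  occ <- which(h > 0) - 1L
  lmin <- min(occ)
  lmax <- max(occ)
  if ((lmax - peak) >= (peak - lmin)) {
    x0 <- peak; y0 <- h[peak + 1L]; x1 <- lmax; y1 <- h[lmax + 1L]
    cand <- if (x1 > x0 + 1L) (x0 + 1L):(x1 - 1L) else x0
  } else {
    x0 <- peak; y0 <- h[peak + 1L]; x1 <- lmin; y1 <- h[lmin + 1L]
    cand <- if (x0 > x1 + 1L) (x1 + 1L):(x0 - 1L) else x0
  }
  num <- abs((y1 - y0) * cand - (x1 - x0) * h[cand + 1L] +
               x1 * y0 - y1 * x0)
  cand[which.max(num)]
}

# neighborhood maximum over a (2r+1)^2 window via shifted copies
.nb_max <- function(m, r = 2) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (di in -r:r) {
    for (dj in -r:r) {
      shifted <- matrix(-Inf, nrow(m), ncol(m))
      src_r <- max(1, 1 - di):min(nrow(m), nrow(m) - di)
      src_c <- max(1, 1 - dj):min(ncol(m), ncol(m) - dj)
      shifted[src_r + di, src_c + dj] <- m[src_r, src_c]
      out <- pmax(out, shifted)
    }
  }
  out
}

#' Count nuclei by Otsu thresholding and distance-peak splitting
#'
#' The nuclei channel is thresholded (Otsu), connected components are
#' labeled, and merged blobs are split by counting distance-transform peak
#' plateaus within each component (each component counts at least one
#' nucleus).
#'
#' @param nuclei numeric nuclei-channel matrix.
#' @return integer nucleus count.
#' @export
count_nuclei <- function(nuclei) {
  if (max(nuclei) == min(nuclei)) return(0L)
  thr <- image_threshold(nuclei, "otsu")
  mask <- nuclei > thr
  if (!any(mask)) return(0L)
  comp <- EBImage::bwlabel(mask * 1)
  dm <- EBImage::distmap(mask * 1)
  peaks <- (dm >= .nb_max(dm, 2) & mask) * 1
  plateau <- EBImage::bwlabel(peaks)
  n_total <- 0L
  for (cl in seq_len(max(comp))) {
    n_peaks <- length(unique(plateau[comp == cl & plateau > 0]))
    n_total <- n_total + max(1L, n_peaks)
  }
  n_total
}

#' Nuclei-normalized integrated puncta density
#'
#' The signal channel is thresholded with the triangle method and its
#' intensity integrated over the foreground; the result is divided by the
#' nucleus count of the companion nuclei channel. Zero detected nuclei
#' flags the value invalid.
#'
#' @param signal puncta-channel matrix (e.g. autophagy probe fluorescence).
#' @param nuclei nuclei-channel matrix of the same field.
#' @return list with `integrated_density`, `n_nuclei`, `density`,
#'   `threshold`, `valid`.
#' @export
puncta_density_normalized <- function(signal, nuclei) {
  stopifnot(identical(dim(signal), dim(nuclei)))
  if (max(signal) == min(signal)) {
    # blank channel: nothing above background
    intdens <- 0
    thr <- NA_real_
  } else {
    thr <- image_threshold(signal, "triangle")
    intdens <- sum(signal[signal > thr])
  }
  n <- count_nuclei(nuclei)
  list(integrated_density = intdens, n_nuclei = n,
       density = if (n > 0) intdens / n else NA_real_,
       threshold = thr, valid = n > 0)
}

#' Background-corrected, loading-control-normalized densitometry
#'
#' Each lane's raw integrated density is background corrected, then divided
#' by the background-corrected loading-control (beta-actin) density of the
#' same sample: `(lane - background) / (control - control_background)`.
#'
#' @param lane raw integrated densities per lane.
#' @param background matched background ROI densities.
#' @param control loading-control band densities.
#' @param control_background background for the control bands (defaults to
#'   `background`).
#' @return `data.frame` with the inputs and the `normalized` values.
#' @export
densitometry_normalize <- function(lane, background, control,
                                   control_background = background) {
  n <- length(lane)
  background <- rep_len(background, n)
  control <- rep_len(control, n)
  control_background <- rep_len(control_background, n)
  if (any(control - control_background <= 0)) {
    stop("loading control does not exceed background; invalid blot")
  }
  data.frame(lane = lane, background = background, control = control,
             control_background = control_background,
             normalized = (lane - background) /
               (control - control_background))
}
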