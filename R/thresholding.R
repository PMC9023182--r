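#' Reference-slice index of a CT sequence
#'
#' In an abdominal CT sequence the liver cross-section is largest about one
#' third of the way through the stack (a 90-slice sequence peaks near slice
#' 30), so that slice is used to estimate the sequence-wide approximate
#' liver gray value.
#'
#' @param sequence_length Number of slices (>= 1).
#' @return 1-based slice index, `round(sequence_length / 3)` clamped to the
#'   valid range.
#' @export
select_reference_slice <- function(sequence_length) {
  stopifnot(sequence_length >= 1)
  min(max(round(sequence_length / 3), 1), sequence_length)
}

#' Approximate liver gray value (LV_A) from a sampling band
#'
#' Gray-level statistics are taken over a horizontal band 10 pixels tall
#' placed one quarter of the way down the body's bounding box — a height at
#' which the liver dominates the cross-section. The modal gray value of the
#' band is returned after discarding the black zone (background/air, levels
#' below `black_cutoff`) and the white zone (bone, levels above
#' `white_cutoff`).
#'
#' @param image Integer matrix of gray values (rows are the vertical axis).
#' @param band_height Band thickness in pixels.
#' @param black_cutoff,white_cutoff Gray levels excluded as black / white
#'   zones.
#' @return The modal gray value of the band (scalar).
#' @export
estimate_lva <- function(image, band_height = 10, black_cutoff = 10,
                         white_cutoff = 245) {
  body_rows <- which(apply(image > black_cutoff, 1, any))
  if (length(body_rows) == 0) stop("estimate_lva: no body (non-black) region found")
  top <- min(body_rows); bottom <- max(body_rows)
  start <- top + floor((bottom - top + 1) / 4)
  rows <- start:min(start + band_height - 1, bottom)
  v <- as.vector(image[rows, , drop = FALSE])
  v <- v[v >= black_cutoff & v <= white_cutoff]
  if (length(v) == 0)
    stop("estimate_lva: sampling band empty after removing black/white zones")
  counts <- tabulate(v + 1L, nbins = 256)
  which.max(counts) - 1L
}

# Moving-average smoothing of counts (centered window, edges shrink).
smooth_counts <- function(counts, window = 5) {
  half <- window %/% 2
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    mean(counts[idx])
  }, numeric(1))
}

# Peak prominence on a 1-D profile: height above the higher of the two
# valley minima separating the peak from taller terrain (or the profile
# ends).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1) {
      seg <- y[1:(p - 1)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[(max(higher) + 1):(p - 1)]) else min(seg)
    } else h
    right <- if (p < length(y)) {
      seg <- y[(p + 1):length(y)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[1:(min(higher) - 1)]) else min(seg)
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Liver peak gray value (LV_M) on a slice histogram
#'
#' Smooths the histogram with a 5-level moving average, finds strict local
#' maxima with prominence at least 1% of the largest smoothed count, and
#' returns the peak gray level closest to the sequence's approximate liver
#' value `lva`. Equidistant peaks are broken toward the larger count, then
#' toward the lower gray value. If no peak qualifies the function falls back
#' to `lva` itself with a warning.
#'
#' @param hist A [gray_histogram].
#' @param lva Approximate liver gray value from [estimate_lva()].
#' @param window Moving-average window (levels).
#' @param prominence_frac Minimum prominence as a fraction of the maximum
#'   smoothed count.
#' @return The LV_M gray level (scalar).
#' @export
find_lvm <- function(hist, lva, window = 5, prominence_frac = 0.01) {
  y <- smooth_counts(hist$counts, window)
  n <- length(y)
  interior <- 2:(n - 1)
  peaks <- interior[y[interior] > y[interior - 1] & y[interior] > y[interior + 1]]
  if (length(peaks)) {
    prom <- peak_prominence(y, peaks)
    peaks <- peaks[prom >= prominence_frac * max(y)]
  }
  if (!length(peaks)) {
    warning("find_lvm: no qualifying histogram peak; falling back to LV_A = ", lva)
    return(structure(lva, fallback = TRUE))
  }
  lv <- hist$levels[peaks]
  d <- abs(lv - lva)
  cand <- which(d == min(d))
  if (length(cand) > 1) {
    cts <- hist$counts[peaks][cand]
    cand <- cand[cts == max(cts)]
    cand <- cand[which.min(lv[cand])]
  }
  lv[cand]
}

# Crossings of the weighted density curves of components j and k inside
# (a, b): sign changes of w_j p_j - w_k p_k on a 0.1-gray-level grid,
# refined by bisection to 1e-3.
pair_crossings <- function(model, j, k, a, b, grid_step = 0.1, refine_tol = 1e-3) {
  if (model$family == "jsb") {
    eps <- 1e-9 * model$lam
    a <- max(a, model$xi + eps)
    b <- min(b, model$xi + model$lam - eps)
  }
  if (a >= b) return(numeric(0))
  g <- function(x) {
    lp <- comp_log_density(x, model)
    model$weights[j] * exp(lp[, j]) - model$weights[k] * exp(lp[, k])
  }
  xs <- seq(a, b, by = grid_step)
  if (length(xs) < 2) return(numeric(0))
  ys <- g(xs)
  sgn <- sign(ys)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  # a zero exactly on the grid counts only when flanked by opposite signs
  # (identical curves give ys == 0 everywhere: no isolated crossing)
  n <- length(ys)
  iso <- which(ys == 0)
  iso <- iso[iso > 1 & iso < n]
  iso <- iso[sgn[iso - 1] * sgn[iso + 1] < 0]
  roots <- xs[iso]
  for (i in flip) {
    lo <- xs[i]; hi <- xs[i + 1]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(unique(roots))
}

#' Crossing points of adjacent weighted component curves
#'
#' Orders components by median, then for each pair adjacent in that order
#' finds all gray values in `(a, b)` where the two weighted component
#' densities `w_j p_j` and `w_k p_k` cross. These crossings are the raw
#' material of threshold extraction.
#'
#' @param model A [mixture_model].
#' @param a,b Search interval (gray values, `a < b`).
#' @return Sorted numeric vector of crossing points (possibly empty).
#' @export
component_intersections <- function(model, a, b) {
  stopifnot(a < b)
  ord <- order(component_medians(model))
  out <- numeric(0)
  for (i in seq_len(model$K - 1)) {
    out <- c(out, pair_crossings(model, ord[i], ord[i + 1], a, b))
  }
  sort(out)
}

#' Segmentation threshold from one histogram part
#'
#' Implements the intersection rule for a fitted part-model: on the left
#' part the candidate low threshold is the crossing of the two component
#' curves with the *largest* medians; on the right part the candidate high
#' threshold is the crossing of the two with the *smallest* medians. When the
#' chosen pair crosses more than once, the crossing nearest `lvm` is used.
#' Peak-override rule: if any other component's density peaks strictly
#' between that crossing and `lvm`, the peak gray value (the one nearest the
#' crossing, when several interpose) replaces the crossing as the threshold.
#' Components with weight below `weight_floor` are ignored throughout.
#'
#' Because the split deliberately places the liver peak at the part's edge,
#' EM frequently dedicates one or more components to the shared boundary bin
#' itself. Such edge fragments describe the liver peak, not a neighboring
#' structure, so they can neither carry a separating intersection nor count
#' as an interposed peak: components whose density mode lies within
#' `edge_margin` gray levels of `lvm` are excluded (unless fewer than two
#' components would remain, in which case the exclusion is waived).
#'
#' @param part_model A [mixture_model] fitted to one histogram part.
#' @param side `"left"` (low threshold) or `"right"` (high threshold).
#' @param lvm The liver peak gray value at which the histogram was split.
#' @param weight_floor Components at or below this weight are ignored.
#' @param edge_margin Components peaking within this many gray levels of
#'   `lvm` are treated as liver-peak fragments and skipped.
#' @return List with `value` (gray value) and `rule` (`"intersection"` or
#'   `"peak_override"`).
#' @export
threshold_from_part <- function(part_model, side = c("left", "right"), lvm,
                                weight_floor = 1e-4, edge_margin = 1.5) {
  side <- match.arg(side)
  usable <- which(part_model$weights > weight_floor)
  if (length(usable) < 2)
    stop(sprintf("threshold_from_part (%s): only %d usable component(s) above the weight floor",
                 side, length(usable)))
  all_modes <- component_modes(part_model)
  interior <- usable[abs(all_modes[usable] - lvm) > edge_margin]
  if (length(interior) >= 2) usable <- interior
  med <- component_medians(part_model)
  ord <- usable[order(med[usable])]
  pair <- if (side == "left") utils::tail(ord, 2) else utils::head(ord, 2)
  if (part_model$family == "jsb") {
    a <- part_model$xi; b <- part_model$xi + part_model$lam
  } else {
    sd2 <- sqrt(max(part_model$var))
    a <- min(part_model$mean) - 4 * sd2; b <- max(part_model$mean) + 4 * sd2
  }
  crossings <- pair_crossings(part_model, pair[1], pair[2], a, b)
  # the separating point of two unimodal curves lies between their peaks;
  # crossings outside that interval are boundary artifacts where both
  # densities vanish
  sep <- crossings[crossings > min(all_modes[pair]) & crossings < max(all_modes[pair])]
  if (length(sep)) crossings <- sep
  crossing <- if (length(crossings)) {
    crossings[which.min(abs(crossings - lvm))]
  } else {
    # no isolated crossing (e.g. near-identical curves): fall back to the
    # midpoint of the pair medians
    mean(med[pair])
  }
  others <- setdiff(ord, pair)
  if (length(others)) {
    modes <- component_modes(part_model)[others]
    lo <- min(crossing, lvm); hi <- max(crossing, lvm)
    interposed <- modes[modes > lo & modes < hi]
    if (length(interposed)) {
      value <- interposed[which.min(abs(interposed - crossing))]
      return(list(value = value, rule = "peak_override"))
    }
  }
  list(value = crossing, rule = "intersection")
}

# Zero out the pure-black background level before fitting: air outside the
# body piles up at gray 0 as a delta spike that a continuous bounded density
# cannot represent (EM components collapse onto it), and it carries no liver
# information — the same reason the black zone is omitted from LV_A
# statistics. The level axis (and hence the support) is unchanged.
drop_black_level <- function(hist, black_level = 0) {
  hist$counts[hist$levels == black_level] <- 0
  gray_histogram(hist$levels, hist$counts)
}

#' Divided-histogram (TDH) segmentation threshold range
#'
#' The centerpiece of the method: split the slice histogram at the liver
#' peak `lvm` (the peak bin is shared by both parts), fit a K-component
#' mixture to each part by EM, and extract the low threshold from the left
#' part and the high threshold from the right part with
#' [threshold_from_part()]. If a part has fewer populated levels than K, K
#' is reduced for that part (flagged in the result).
#'
#' The pure-black background level (gray 0) is excluded from the fitted
#' counts, as in LV_A estimation: it is a delta spike of air pixels that a
#' continuous density cannot represent.
#'
#' @param hist A [gray_histogram] of the whole slice.
#' @param lvm Liver peak gray value from [find_lvm()].
#' @param config An [em_config]; `config$K` components per part.
#' @param exclude_black Drop the gray-0 background spike before fitting.
#' @return An object of class `threshold_range`: `low`, `high`, `low_rule`,
#'   `high_rule`, `lvm`, `k_left`, `k_right` and the two part fits.
#' @export
tdh_threshold <- function(hist, lvm, config = em_config(), exclude_black = TRUE) {
  if (exclude_black) hist <- drop_black_level(hist)
  parts <- split_histogram(hist, lvm)
  fit_part <- function(part) {
    k <- min(config$K, length(populated_levels(part)) - 1)
    if (k < 2) stop("tdh_threshold: histogram part too small to fit a mixture")
    cfg <- config; cfg$K <- as.integer(k)
    if (cfg$family == "jsb") fit_em(part, cfg) else fit_gmm(part, cfg)
  }
  fl <- fit_part(parts$left)
  fr <- fit_part(parts$right)
  lo <- threshold_from_part(fl$model, "left", lvm)
  hi <- threshold_from_part(fr$model, "right", lvm)
  low <- min(lo$value, lvm)
  high <- max(hi$value, lvm)
  structure(list(low = low, high = high,
                 low_rule = lo$rule, high_rule = hi$rule,
                 lvm = lvm, k_left = fl$model$K, k_right = fr$model$K,
                 fit_left = fl, fit_right = fr),
            class = "threshold_range")
}

#' Whole-histogram (TWH) threshold range
#'
#' Comparison mode that fits one mixture to the undivided histogram and
#' takes as thresholds the adjacent-component crossings nearest the liver
#' peak on either side. Used as the baseline convention for the Gaussian
#' mixture and as a fallback; divided-histogram fitting is the headline
#' method.
#'
#' @inheritParams tdh_threshold
#' @return A `threshold_range` (rules are `"intersection"`).
#' @export
twh_threshold <- function(hist, lvm, config = em_config(), exclude_black = TRUE) {
  if (exclude_black) hist <- drop_black_level(hist)
  fit <- if (config$family == "jsb") fit_em(hist, config) else fit_gmm(hist, config)
  model <- fit$model
  pop <- populated_levels(hist)
  cross <- component_intersections(model, min(pop) - 0.5, max(pop) + 0.5)
  below <- cross[cross < lvm]
  above <- cross[cross > lvm]
  if (!length(below) || !length(above))
    stop("twh_threshold: no component crossing on one side of the liver peak")
  structure(list(low = max(below), high = min(above),
                 low_rule = "intersection", high_rule = "intersection",
                 lvm = lvm, k_left = model$K, k_right = model$K,
                 fit_left = fit, fit_right = fit),
            class = "threshold_range")
}

#' @export
print.threshold_range <- function(x, ...) {
  cat(sprintf("threshold range [%.1f, %.1f] around LV_M = %g (low: %s, high: %s)\n",
              x$low, x$high, x$lvm, x$low_rule, x$high_rule))
  invisible(x)
}
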