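#' Binarize an image by a threshold range
#'
#' Pixels with gray value in the closed interval `[low, high]` become 1,
#' everything else 0.
#'
#' @param image Integer matrix of gray values.
#' @param range A `threshold_range` (or any list with `low` and `high`).
#' @return Logical matrix.
#' @export
binarize <- function(image, range) {
  stopifnot(range$low < range$high)
  image >= range$low & image <= range$high
}

#' Morphological cleanup of a binary mask
#'
#' Fills holes, opens (erosion then dilation) with a disc structuring
#' element, and keeps only the largest 8-connected component — the standard
#' fill / erode / dilate post-processing that turns a thresholded speckle
#' mask into a single solid organ region. An empty input mask is returned
#' unchanged with attribute `empty = TRUE` and a warning.
#'
#' @param mask Logical or 0/1 matrix.
#' @param radius Disc radius in pixels for the opening.
#' @return Logical matrix containing at most one connected component.
#' @export
morphology_clean <- function(mask, radius = 3) {
  m <- (as.logical(mask)) * 1
  dim(m) <- dim(mask)
  if (sum(m) == 0) {
    warning("morphology_clean: empty input mask")
    return(structure(as.logical(mask), dim = dim(mask), empty = TRUE))
  }
  m <- EBImage::fillHull(m)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  m <- EBImage::opening(m, brush)
  lab <- EBImage::bwlabel(m)
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) {
    warning("morphology_clean: mask vanished under opening")
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    return(structure(out, empty = TRUE))
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- lab == keep
  dim(out) <- dim(mask)
  out
}

# Ordered boundary of the largest component, via EBImage's contour tracer.
trace_contour <- function(mask) {
  if (sum(mask) == 0) return(matrix(numeric(0), ncol = 2))
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0) return(matrix(numeric(0), ncol = 2))
  oc[[which.max(vapply(oc, nrow, integer(1)))]]
}

#' Segment the liver in one CT slice
#'
#' Full per-slice pipeline: locate the liver histogram peak LV_M nearest the
#' (sequence-level) approximate liver value LV_A, derive the threshold
#' range — divided-histogram fitting by default — binarize, clean up
#' morphologically and trace the boundary contour. All intermediate values
#' are kept on the result for audit.
#'
#' @param image Integer matrix of gray values in `[0, 255]`.
#' @param lva Approximate liver gray value; estimated from this slice when
#'   `NULL`.
#' @param config An [em_config].
#' @param mode `"tdh"` (divided histogram, default) or `"twh"` (whole
#'   histogram).
#' @return An object of class `segmentation_result`: `mask`, `mask_raw`
#'   (pre-morphology), `contour`, `thresholds`, `lva`, `lvm`, `histogram`.
#' @export
segment_slice <- function(image, lva = NULL, config = em_config(),
                          mode = c("tdh", "twh")) {
  mode <- match.arg(mode)
  if (is.null(lva)) lva <- estimate_lva(image)
  hist <- build_histogram(image)
  lvm <- find_lvm(hist, lva)
  thr <- if (mode == "tdh") tdh_threshold(hist, lvm, config)
         else twh_threshold(hist, lvm, config)
  mask_raw <- binarize(image, thr)
  mask <- morphology_clean(mask_raw)
  structure(list(mask = mask, mask_raw = mask_raw,
                 contour = trace_contour(mask),
                 thresholds = thr, lva = lva, lvm = as.numeric(lvm),
                 histogram = hist, mode = mode, config = config),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation (%s): LV_A %g, LV_M %g, thresholds [%.1f, %.1f], mask %d px\n",
              x$mode, x$lva, x$lvm, x$thresholds$low, x$thresholds$high,
              sum(x$mask)))
  invisible(x)
}

#' Segment an ordered CT slice sequence
#'
#' The approximate liver value LV_A is estimated once on the reference
#' slice (about one third into the sequence, where the liver section is
#' largest) and shared by all slices; the liver peak LV_M is still located
#' per slice, since liver gray levels drift slightly along the stack.
#'
#' @param slices List of gray-image matrices, in stack order.
#' @param config An [em_config].
#' @param mode `"tdh"` or `"twh"`.
#' @return List of `segmentation_result`, one per slice, with attribute
#'   `reference_slice`.
#' @export
segment_sequence <- function(slices, config = em_config(), mode = c("tdh", "twh")) {
  mode <- match.arg(mode)
  stopifnot(length(slices) >= 1)
  ref <- select_reference_slice(length(slices))
  lva <- tryCatch(estimate_lva(slices[[ref]]),
                  error = function(e) stop("segment_sequence: LV_A estimation failed on reference slice ",
                                           ref, ": ", conditionMessage(e)))
  res <- lapply(slices, segment_slice, lva = lva, config = config, mode = mode)
  attr(res, "reference_slice") <- ref
  res
}

#' Tabulate threshold results for a slice sequence
#'
#' @param results List of `segmentation_result` objects.
#' @param ids Optional slice identifiers.
#' @return Data frame with one row per slice: LV_A, LV_M, thresholds, the
#'   rule that produced each, and the component counts used per part —
#'   ready for `write.csv`.
#' @export
thresholds_table <- function(results, ids = seq_along(results)) {
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(slice_id = ids[i], lva = r$lva, lvm = r$lvm,
               low = r$thresholds$low, high = r$thresholds$high,
               low_rule = r$thresholds$low_rule,
               high_rule = r$thresholds$high_rule,
               k_left = r$thresholds$k_left, k_right = r$thresholds$k_right)
  }))
}
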