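#' Gray-level histogram
#'
#' Counts over integer gray levels. All mixture fitting and thresholding in
#' this package operates on these histograms rather than on raw pixels: the
#' discrete log-likelihood treats the count at each level as a multiplicity,
#' which is identical to per-pixel fitting but far cheaper.
#'
#' @param levels Integer vector of gray levels (strictly increasing).
#' @param counts Non-negative integer vector, same length as `levels`.
#' @return An object of class `gray_histogram` with fields `levels`,
#'   `counts` and `total`.
#' @export
gray_histogram <- function(levels, counts) {
  stopifnot(length(levels) == length(counts))
  if (is.unsorted(levels, strictly = TRUE)) stop("gray_histogram: levels must be strictly increasing")
  if (any(counts < 0)) stop("gray_histogram: counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("gray_histogram: histogram is empty (total count 0)")
  structure(list(levels = as.numeric(levels), counts = as.numeric(counts),
                 total = total),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  pop <- x$levels[x$counts > 0]
  cat(sprintf("gray_histogram: %d levels (%g..%g populated), %g pixels\n",
              length(x$levels), min(pop), max(pop), x$total))
  invisible(x)
}

#' Build a gray-level histogram from an image
#'
#' @param image Integer matrix of gray values in `[0, n_levels - 1]`.
#' @param roi Optional logical matrix of the same shape; only `TRUE` pixels
#'   are counted.
#' @param n_levels Number of gray levels (256 for 8-bit input).
#' @return A [gray_histogram] over `0 .. n_levels - 1` (zero-count levels
#'   retained so the level axis is always complete).
#' @export
build_histogram <- function(image, roi = NULL, n_levels = 256) {
  v <- as.vector(image)
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(image)))
    v <- v[as.vector(roi)]
    if (length(v) == 0) stop("build_histogram: empty roi")
  }
  if (any(v < 0 | v > n_levels - 1 | v != floor(v)))
    stop("build_histogram: image values must be integers in [0, ", n_levels - 1, "]")
  counts <- tabulate(v + 1L, nbins = n_levels)
  gray_histogram(0:(n_levels - 1), counts)
}

#' Populated levels of a histogram
#'
#' @param hist A [gray_histogram].
#' @return Numeric vector of levels with nonzero counts.
#' @export
populated_levels <- function(hist) {
  hist$levels[hist$counts > 0]
}

#' Split a histogram at the liver peak
#'
#' Divides a gray-level histogram into a left part (levels `<= lvm`) and a
#' right part (levels `>= lvm`). The `lvm` bin is shared by both parts so
#' that the liver peak sits at the boundary of each — the premise of the
#' divided-histogram thresholding strategy.
#'
#' @param hist A [gray_histogram].
#' @param lvm The liver peak gray value; must lie strictly inside the
#'   populated range.
#' @return List with [gray_histogram] elements `left` and `right`.
#' @export
split_histogram <- function(hist, lvm) {
  pop <- populated_levels(hist)
  if (!(lvm > min(pop) && lvm < max(pop)))
    stop(sprintf("split_histogram: lvm = %g is not strictly inside the populated range [%g, %g]",
                 lvm, min(pop), max(pop)))
  li <- hist$levels <= lvm
  ri <- hist$levels >= lvm
  list(left = gray_histogram(hist$levels[li], hist$counts[li]),
       right = gray_histogram(hist$levels[ri], hist$counts[ri]))
}
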