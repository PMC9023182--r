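#' Jaccard index of two binary masks
#'
#' `|A intersect B| / |A union B|`. When both masks are empty the index is
#' undefined: `NA` is returned with attribute `undefined = TRUE` so sequence
#' averages can skip such slices rather than silently scoring them 1.
#'
#' @param a,b Logical (or 0/1) matrices of equal shape.
#' @return Scalar in `[0, 1]`, or flagged `NA` for two empty masks.
#' @export
jaccard <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("jaccard: masks must have equal shape")
  u <- sum(a | b)
  if (u == 0) return(structure(NA_real_, undefined = TRUE))
  sum(a & b) / u
}

#' Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; algebraically `2J / (1 + J)` in terms
#' of the Jaccard index `J`. Two empty masks give flagged `NA` as in
#' [jaccard()].
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`, or flagged `NA` for two empty masks.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("dice: masks must have equal shape")
  s <- sum(a) + sum(b)
  if (s == 0) return(structure(NA_real_, undefined = TRUE))
  2 * sum(a & b) / s
}

#' Evaluate predicted against ground-truth masks
#'
#' @param pred,truth Lists of binary masks (same length and shapes).
#' @param ids Optional slice identifiers.
#' @return Data frame with columns `slice_id`, `jaccard`, `dice` (NA for
#'   slices where both masks are empty).
#' @export
evaluate_masks <- function(pred, truth, ids = seq_along(pred)) {
  stopifnot(length(pred) == length(truth), length(ids) == length(pred))
  data.frame(
    slice_id = ids,
    jaccard = vapply(seq_along(pred), function(i) as.numeric(jaccard(pred[[i]], truth[[i]])), numeric(1)),
    dice = vapply(seq_along(pred), function(i) as.numeric(dice(pred[[i]], truth[[i]])), numeric(1))
  )
}

#' Window CT attenuation values to 8-bit gray levels
#'
#' Standard radiology windowing: HU values inside
#' `[center - width/2, center + width/2]` are mapped affinely onto
#' `[0, 255]`; values outside are clipped to 0 or 255. The default is an
#' abdominal soft-tissue window (center 60 HU, width 400 HU).
#'
#' @param hu Numeric vector or matrix of Hounsfield units.
#' @param center,width Window center and width in HU.
#' @return Integer gray values with the shape of `hu`.
#' @export
window_hu <- function(hu, center = 60, width = 400) {
  lo <- center - width / 2
  g <- round((hu - lo) / width * 255)
  out <- pmin(pmax(g, 0), 255)
  storage.mode(out) <- "integer"
  if (!is.null(dim(hu))) dim(out) <- dim(hu)
  out
}

#' Read a grayscale slice as an 8-bit integer matrix
#'
#' PNG input is read with the `png` package and rescaled to integer levels
#' 0..255; color PNGs whose channels disagree are rejected. DICOM input is
#' not supported by this build (no DICOM reader is bundled); convert CT
#' slices to PNG externally after applying [window_hu()] to the rescaled
#' Hounsfield values.
#'
#' @param path File path.
#' @param format `"png"` (the only supported format).
#' @return Integer matrix of gray values in `[0, 255]`.
#' @export
read_slice <- function(path, format = c("png", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom")
    stop("read_slice: DICOM input is not supported by this build; ",
         "window to 8-bit PNG first (see window_hu())")
  if (!file.exists(path)) stop("read_slice: no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    ch <- dim(a)[3]
    rgb <- a[, , seq_len(min(ch, 3)), drop = FALSE]
    if (max(abs(sweep(rgb, c(1, 2), rgb[, , 1]))) > 1e-9)
      stop("read_slice: PNG is not grayscale: ", path)
    a <- a[, , 1]
  }
  out <- round(a * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit gray image to PNG
#'
#' @param image Integer matrix of gray values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(all(image >= 0), all(image <= 255))
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a binary mask to PNG (0 = background, 255 = mask)
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((as.logical(mask) * 1) + matrix(0, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG path; any pixel above half intensity counts as mask.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}
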