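#' Histogram sampled from a mixture model
#'
#' Draws `n` gray values from the mixture (component picked by weight, then
#' a draw from that component), quantizes them to integer gray levels by
#' rounding, clamps to `[0, n_levels - 1]` and bins them.
#'
#' @param model A [mixture_model].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param n_levels Number of gray levels.
#' @return A [gray_histogram] with `total == n`.
#' @export
make_mixture_histogram <- function(model, n, seed = 1L, n_levels = 256) {
  stopifnot(n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  comp <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  x <- numeric(n)
  if (model$family == "jsb") {
    z <- stats::rnorm(n)
    x <- jsb_logit_inv((z - model$gamma[comp]) / model$delta[comp],
                       list(xi = model$xi, lam = model$lam))
  } else {
    x <- stats::rnorm(n, model$mean[comp], sqrt(model$var[comp]))
  }
  g <- pmin(pmax(round(x), 0), n_levels - 1)
  gray_histogram(0:(n_levels - 1), tabulate(g + 1L, nbins = n_levels))
}

#' Default phantom layout
#'
#' Describes a synthetic abdominal CT slice: a black background, an
#' elliptical body with a bright bone-like rim, a broad soft-tissue
#' ("flesh") interior, one large liver region and three smaller confounding
#' organ blobs whose gray distributions sit 15-25 levels on either side of
#' the liver's. Every region's gray values are drawn from a known
#' Johnson-SB distribution, so the generating mixture is exact ground
#' truth.
#'
#' The liver distribution is deliberately skewed (`gamma = -0.8`, long
#' right tail) to exercise the asymmetry the Johnson-SB family models and a
#' Gaussian cannot; the confounders reuse the liver's shape at offset
#' medians so the thresholds are nontrivial. The liver ellipse is placed so
#' it dominates the quarter-height sampling band used by [estimate_lva()],
#' mimicking a mid-liver slice.
#'
#' @param liver_median Target median gray value of the liver region.
#' @param size Image side length in pixels.
#' @return A `phantom_spec` list: `size`, `body` (center, radii, rim width,
#'   rim distribution), `regions` (name, center, radii, [jsb_params]).
#' @export
phantom_spec <- function(liver_median = 150, size = 512) {
  s <- size / 512  # all geometry scales with the image side
  jsb_with_median <- function(med, gamma, delta, lam) {
    xi <- med - lam * stats::plogis(-gamma / delta)
    jsb_params(gamma, delta, xi, lam)
  }
  list(
    size = size,
    body = list(center = c(256, 256) * s, radii = c(190, 230) * s, # (row, col)
                rim_width = 10 * s,
                bone = jsb_params(gamma = 0, delta = 1.5, xi = 235, lam = 22)),
    regions = list(
      list(name = "flesh", role = "fill",
           params = jsb_with_median(95, gamma = 0.3, delta = 1.5, lam = 70)),
      list(name = "liver", role = "liver",
           center = c(205, 185) * s, radii = c(95, 100) * s,
           params = jsb_with_median(liver_median, gamma = -0.8, delta = 2.5, lam = 64)),
      list(name = "organ_low", role = "confounder",
           center = c(360, 200) * s, radii = c(45, 60) * s,
           params = jsb_with_median(liver_median - 15, gamma = -0.8, delta = 2.5, lam = 64)),
      list(name = "organ_high", role = "confounder",
           center = c(330, 370) * s, radii = c(40, 50) * s,
           params = jsb_with_median(liver_median + 15, gamma = -0.8, delta = 2.5, lam = 64)),
      list(name = "organ_higher", role = "confounder",
           center = c(250, 380) * s, radii = c(35, 40) * s,
           params = jsb_with_median(liver_median + 25, gamma = -0.8, delta = 2.5, lam = 64))
    )
  )
}

# Logical mask of an axis-aligned ellipse; center/radii as (row, col).
ellipse_mask <- function(size, center, radii) {
  r <- matrix(seq_len(size), nrow = size, ncol = size)
  c_ <- matrix(seq_len(size), nrow = size, ncol = size, byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c_ - center[2]) / radii[2])^2 <= 1
}

#' Generate a synthetic abdominal-CT phantom slice
#'
#' Renders the layout from [phantom_spec()] into an 8-bit gray image plus a
#' ground-truth liver mask. Region gray values are independent Johnson-SB
#' draws (rounded, clamped to 0..255); the background is exactly 0. All
#' randomness flows through one generator seeded with `seed`, so the same
#' `(spec, seed)` pair reproduces the image bit for bit.
#'
#' @param spec A `phantom_spec` layout.
#' @param seed Integer seed.
#' @return An object of class `phantom`: `image` (integer matrix),
#'   `liver_mask` (logical matrix), `masks` (per-region logical matrices),
#'   `spec`, `seed`.
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  size <- spec$size
  body <- ellipse_mask(size, spec$body$center, spec$body$radii)
  inner <- ellipse_mask(size, spec$body$center,
                        spec$body$radii - spec$body$rim_width)
  rim <- body & !inner
  blob_masks <- list()
  for (rg in spec$regions) {
    if (rg$role == "fill") next
    m <- ellipse_mask(size, rg$center, rg$radii)
    if (any(m & !inner))
      stop("make_phantom: region '", rg$name, "' extends outside the body interior")
    for (nm in names(blob_masks)) {
      if (any(m & blob_masks[[nm]]))
        stop("make_phantom: regions '", rg$name, "' and '", nm, "' overlap")
    }
    blob_masks[[rg$name]] <- m
  }
  occupied <- Reduce(`|`, blob_masks, init = matrix(FALSE, size, size))
  flesh <- inner & !occupied
  img <- matrix(0L, size, size)
  sample_into <- function(mask, params) {
    n <- sum(mask)
    if (n == 0) return()
    v <- as.integer(pmin(pmax(round(rjsb(n, params)), 0), 255))
    img[mask] <<- v
  }
  sample_into(rim, spec$body$bone)
  for (rg in spec$regions) {
    m <- if (rg$role == "fill") flesh else blob_masks[[rg$name]]
    sample_into(m, rg$params)
  }
  liver_name <- vapply(spec$regions, function(r) r$role, character(1)) == "liver"
  liver_mask <- blob_masks[[spec$regions[[which(liver_name)]]$name]]
  masks <- c(list(background = !body, rim = rim, flesh = flesh), blob_masks)
  structure(list(image = img, liver_mask = liver_mask, masks = masks,
                 spec = spec, seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom %dx%d (seed %d): liver %d px, background %.1f%%\n",
              nrow(x$image), ncol(x$image), x$seed, sum(x$liver_mask),
              100 * mean(x$masks$background)))
  invisible(x)
}

#' Write a phantom to disk as paired PNGs plus a JSON spec
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the three paths written.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  mask_path <- file.path(dir, paste0(stem, "_liver_mask.png"))
  spec_path <- file.path(dir, paste0(stem, "_spec.json"))
  write_gray_png(phantom$image, img_path)
  write_mask_png(phantom$liver_mask, mask_path)
  spec <- phantom$spec
  spec$seed <- phantom$seed
  spec$body$bone <- unclass(spec$body$bone)
  spec$regions <- lapply(spec$regions, function(r) { r$params <- unclass(r$params); r })
  jsonlite::write_json(spec, spec_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, mask_path, spec_path))
}
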