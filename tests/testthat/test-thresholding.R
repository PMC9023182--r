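test_that("reference slice sits one third into the sequence", {
  expect_equal(select_reference_slice(90), 30)
  expect_equal(select_reference_slice(3), 1)
  expect_equal(select_reference_slice(1), 1)
  expect_equal(select_reference_slice(100), 33)
})

test_that("LV_A is the band mode after black/white removal", {
  img <- matrix(0L, 200, 200)
  img[41:160, 41:160] <- 60L                 # body block, rows 41..160
  # quarter-height band starts at row 41 + 30 = 71
  img[71:80, 41:160] <- 131L
  img[71:80, 41:60] <- 0L                    # black zone inside the band
  img[71:80, 61:65] <- 250L                  # white zone inside the band
  expect_equal(estimate_lva(img), 131)
  img[71:80, ] <- 0L
  img[71:80, 41:160] <- 178L                 # constant band
  expect_equal(estimate_lva(img), 178)
  img[71:80, ] <- 0L                         # band all black
  expect_error(estimate_lva(img), "band empty")
  expect_error(estimate_lva(matrix(0L, 10, 10)), "no body")
})

triangle_bump <- function(center, height, halfwidth = 6) {
  lv <- (center - halfwidth):(center + halfwidth)
  ct <- height * (1 - abs(lv - center) / (halfwidth + 1))
  list(levels = lv, counts = round(ct))
}

hist_with_peaks <- function(centers, heights) {
  counts <- rep(0, 256)
  for (i in seq_along(centers)) {
    b <- triangle_bump(centers[i], heights[i])
    counts[b$levels + 1] <- counts[b$levels + 1] + b$counts
  }
  gray_histogram(0:255, counts)
}

test_that("LV_M is the histogram peak nearest LV_A with stated tie-breaks", {
  h <- hist_with_peaks(c(120, 179, 230), c(800, 1000, 600))
  expect_equal(find_lvm(h, 178), 179)
  # single peak anywhere wins
  h1 <- hist_with_peaks(60, 500)
  expect_equal(find_lvm(h1, 178), 60)
  # equidistant peaks: larger count wins
  h2 <- hist_with_peaks(c(170, 186), c(500, 400))
  expect_equal(find_lvm(h2, 178), 170)
  # no peaks at all: falls back to LV_A with a warning
  flat <- gray_histogram(0:255, rep(4, 256))
  expect_warning(lvm <- find_lvm(flat, 100), "falling back")
  expect_equal(as.numeric(lvm), 100)
})

test_that("histogram split shares the LV_M bin between both parts", {
  h <- hist_with_peaks(c(100, 176, 220), c(700, 900, 500))
  parts <- split_histogram(h, 176)
  expect_equal(max(parts$left$levels), 176)
  expect_equal(min(parts$right$levels), 176)
  expect_equal(parts$left$total + parts$right$total,
               h$total + h$counts[h$levels == 176])
  # split then merge (dropping one copy of the shared bin) restores the original
  merged <- c(parts$left$counts, parts$right$counts[-1])
  expect_equal(merged, h$counts)
  expect_error(split_histogram(h, min(populated_levels(h))), "strictly inside")
})

test_that("mirror-image components cross exactly at the support midpoint", {
  m <- mixture_model("jsb", c(0.5, 0.5), gamma = c(0.8, -0.8),
                     delta = c(2, 2), xi = 0, lam = 200)
  cr <- component_intersections(m, 1, 199)
  expect_equal(length(cr), 1)
  expect_equal(cr, 100, tolerance = 1e-3)
  # identical components: no isolated crossing
  m2 <- mixture_model("jsb", c(0.5, 0.5), gamma = c(0.3, 0.3),
                      delta = c(2, 2), xi = 0, lam = 200)
  expect_length(component_intersections(m2, 1, 199), 0)
})

test_that("crossings match a dense-grid brute-force scan on random models", {
  for (seed in c(4, 8, 15)) {
    m <- random_jsb_mixture(seed, K = 2)
    got <- component_intersections(m, 0, 255)
    # brute force on a 0.05-level grid
    xs <- seq(0.5, 254.5, by = 0.05)
    d1 <- m$weights[1] * djsb(xs, jsb_params(m$gamma[1], m$delta[1], m$xi, m$lam))
    d2 <- m$weights[2] * djsb(xs, jsb_params(m$gamma[2], m$delta[2], m$xi, m$lam))
    sgn <- sign(d1 - d2)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    brute <- (xs[flips] + xs[flips + 1]) / 2
    expect_equal(length(got), length(brute))
    if (length(got)) expect_true(all(abs(got - brute) < 0.5))
  }
})

test_that("part thresholds follow the intersection rule and the peak override", {
  # left part: mirror pair with equal weights crosses at the midpoint 157
  left <- mixture_model("jsb", c(0.5, 0.5), gamma = c(0.4, -0.4),
                        delta = c(2, 2), xi = 107, lam = 100)
  lo <- threshold_from_part(left, "left", lvm = 176)
  expect_equal(lo$value, 157, tolerance = 0.01)
  expect_identical(lo$rule, "intersection")

  # right part: the two lowest-median curves cross at 190 (weights solved so
  # the weighted densities are equal there); a third unimodal curve whose
  # density peaks at 188 (gamma solved from the mode equation) interposes
  fx <- override_fixture()
  hi <- threshold_from_part(fx$with_peak, "right", lvm = 176)
  expect_identical(hi$rule, "peak_override")
  expect_equal(hi$value, 188, tolerance = 0.5)
  # without the interposed component the crossing itself is returned
  hi2 <- threshold_from_part(fx$pair_only, "right", lvm = 176)
  expect_identical(hi2$rule, "intersection")
  expect_equal(hi2$value, 190, tolerance = 0.01)
  # the resulting range brackets the liver peak
  expect_lte(lo$value, 176)
  expect_gte(hi$value, 176)

  expect_error(threshold_from_part(
    mixture_model("jsb", c(1 - 1e-5, 1e-5), gamma = c(0, 0), delta = c(1, 1),
                  xi = 0, lam = 255), "left", 100), "usable component")
})

test_that("divided-histogram thresholds bracket LV_M on a symmetric histogram", {
  # exactly mirror-symmetric histogram about 128 on the level axis 1..255,
  # so the two parts are mirror images bin for bin
  xs <- 1:255
  counts <- round(3000 * exp(-(xs - 128)^2 / 50) +
                  1500 * exp(-(xs - 88)^2 / 120) +
                  1500 * exp(-(xs - 168)^2 / 120)) + 2
  stopifnot(identical(counts, rev(counts)))
  h <- gray_histogram(xs, counts)
  thr <- tdh_threshold(h, 128, em_config(K = 6))
  expect_lte(thr$low, 128)
  expect_gte(thr$high, 128)
  expect_equal(abs(128 - thr$low), abs(thr$high - 128), tolerance = 1)
  expect_s3_class(thr, "threshold_range")
})

test_that("divided-histogram thresholds are deterministic on a phantom", {
  ph <- make_phantom(phantom_spec(size = 512), seed = 3)
  h <- build_histogram(ph$image)
  lvm <- find_lvm(h, estimate_lva(ph$image))
  t1 <- tdh_threshold(h, lvm, em_config(K = 13))
  t2 <- tdh_threshold(h, lvm, em_config(K = 13))
  expect_identical(t1$low, t2$low)
  expect_identical(t1$high, t2$high)
  expect_lte(t1$low, lvm)
  expect_gte(t1$high, lvm)
})
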