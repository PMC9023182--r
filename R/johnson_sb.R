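#' Johnson-SB parameter set
#'
#' Bundles the four parameters of a Johnson-SB distribution: the shape pair
#' (`gamma`, `delta`) and the support interval, expressed as lower bound `xi`
#' and width `lam`. The distribution lives on the open interval
#' `(xi, xi + lam)`; a logit-type transform of the variable,
#' `z = gamma + delta * log((x - xi) / (xi + lam - x))`, is standard normal.
#'
#' `gamma` controls skewness: `gamma = 0` gives a symmetric density,
#' `gamma > 0` a negatively skewed one and `gamma < 0` a positively skewed
#' one. `delta > 0` controls peakedness (large `delta` concentrates mass).
#'
#' @param gamma Real shape parameter (any sign).
#' @param delta Positive shape parameter.
#' @param xi Support lower bound, in gray-level units.
#' @param lam Support width (must be positive).
#' @return An object of class `jsb_params`.
#' @examples
#' p <- jsb_params(gamma = 0, delta = 1, xi = 0, lam = 1)
#' djsb(0.5, p)  # 4 / sqrt(2 * pi)
#' @export
jsb_params <- function(gamma, delta, xi, lam) {
  stopifnot(is.numeric(gamma), is.numeric(delta), is.numeric(xi), is.numeric(lam))
  if (!(delta > 0)) stop("jsb_params: 'delta' must be > 0, got ", delta)
  if (!(lam > 0)) stop("jsb_params: 'lam' must be > 0, got ", lam)
  structure(list(gamma = as.numeric(gamma), delta = as.numeric(delta),
                 xi = as.numeric(xi), lam = as.numeric(lam)),
            class = "jsb_params")
}

#' @export
print.jsb_params <- function(x, ...) {
  cat(sprintf("Johnson-SB(gamma = %.4g, delta = %.4g, support = (%.4g, %.4g))\n",
              x$gamma, x$delta, x$xi, x$xi + x$lam))
  invisible(x)
}

#' Logit transform underlying the Johnson-SB distribution
#'
#' Computes `f(x) = log((x - xi) / (xi + lam - x))`, the monotone map from
#' the open support onto the real line. `gamma + delta * f(x)` is standard
#' normal when `x` follows the corresponding Johnson-SB distribution.
#'
#' @param x Numeric vector, strictly inside the open support.
#' @param params A [jsb_params] object (only `xi` and `lam` are used).
#' @return Numeric vector of transformed values.
#' @seealso [jsb_logit_inv()] for the inverse map.
#' @export
jsb_logit <- function(x, params) {
  xi <- params$xi; lam <- params$lam
  bad <- !(x > xi & x < xi + lam)
  if (any(bad)) {
    stop(sprintf("jsb_logit: value(s) outside open support (%.6g, %.6g): %s",
                 xi, xi + lam, paste(utils::head(x[bad], 5), collapse = ", ")))
  }
  log((x - xi) / (lam + xi - x))
}

#' Inverse of the Johnson-SB logit transform
#'
#' Maps a real value `f` back to the support: `x = xi + lam * plogis(f)`.
#'
#' @param f Numeric vector.
#' @param params A [jsb_params] object.
#' @return Numeric vector inside the open support.
#' @export
jsb_logit_inv <- function(f, params) {
  params$xi + params$lam * stats::plogis(f)
}

#' Johnson-SB probability density
#'
#' Density
#' `p(x) = delta / sqrt(2 pi) * lam / ((x - xi) * (lam + xi - x)) *
#'   exp(-0.5 * (gamma + delta * f(x))^2)`
#' with `f` the logit transform of the support. Values outside the open
#' support get density 0 (not an error), so mixtures can be evaluated over a
#' full 0..255 gray grid.
#'
#' @param x Numeric vector of evaluation points.
#' @param params A [jsb_params] object.
#' @param log Return the log density? Points outside the support give `-Inf`.
#' @return Numeric vector of densities.
#' @export
djsb <- function(x, params, log = FALSE) {
  g <- params$gamma; d <- params$delta; xi <- params$xi; lam <- params$lam
  out <- rep(if (log) -Inf else 0, length(x))
  inside <- x > xi & x < xi + lam
  if (any(inside)) {
    xs <- x[inside]
    f <- base::log((xs - xi) / (lam + xi - xs))
    lp <- base::log(d) - 0.5 * base::log(2 * pi) + base::log(lam) -
      base::log(xs - xi) - base::log(lam + xi - xs) - 0.5 * (g + d * f)^2
    out[inside] <- if (log) lp else exp(lp)
  }
  out
}

#' Johnson-SB cumulative distribution function
#'
#' `P(X <= x) = pnorm(gamma + delta * f(x))`; 0 below the support, 1 above.
#'
#' @inheritParams djsb
#' @return Numeric vector of probabilities.
#' @export
pjsb <- function(x, params) {
  g <- params$gamma; d <- params$delta; xi <- params$xi; lam <- params$lam
  out <- numeric(length(x))
  out[x >= xi + lam] <- 1
  inside <- x > xi & x < xi + lam
  if (any(inside)) {
    f <- base::log((x[inside] - xi) / (lam + xi - x[inside]))
    out[inside] <- stats::pnorm(g + d * f)
  }
  out
}

#' Johnson-SB quantile function
#'
#' @param p Numeric vector of probabilities.
#' @param params A [jsb_params] object.
#' @return Numeric vector of quantiles inside the open support.
#' @export
qjsb <- function(p, params) {
  stopifnot(all(p >= 0 & p <= 1))
  z <- stats::qnorm(p)
  jsb_logit_inv((z - params$gamma) / params$delta, params)
}

#' Sample from a Johnson-SB distribution
#'
#' Draws standard normal deviates `z` and maps them through the inverse
#' transform `x = xi + lam * plogis((z - gamma) / delta)`; all draws fall
#' strictly inside the open support.
#'
#' @param n Number of samples (>= 1).
#' @param params A [jsb_params] object.
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of length `n`.
#' @export
rjsb <- function(n, params, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("rjsb: 'n' must be >= 1")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  z <- stats::rnorm(n)
  jsb_logit_inv((z - params$gamma) / params$delta, params)
}

#' Median of a Johnson-SB distribution
#'
#' Closed form: the median solves `gamma + delta * f(x) = 0`, i.e.
#' `x = xi + lam * plogis(-gamma / delta)`.
#'
#' @param params A [jsb_params] object.
#' @return The median gray value.
#' @export
jsb_median <- function(params) {
  jsb_logit_inv(-params$gamma / params$delta, params)
}

#' Mode of a Johnson-SB density
#'
#' Located numerically: coarse grid over the support followed by a local
#' golden-section refinement of the log density. For `delta` well below 1 the
#' density can be bimodal; the global maximum is returned.
#'
#' @param params A [jsb_params] object.
#' @return Gray value at which the density is largest.
#' @export
jsb_mode <- function(params) {
  xi <- params$xi; lam <- params$lam
  eps <- lam * 1e-6
  grid <- seq(xi + eps, xi + lam - eps, length.out = 1024)
  lp <- djsb(grid, params, log = TRUE)
  i <- which.max(lp)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(x) djsb(x, params, log = TRUE),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6 * lam)
  opt$maximum
}

#' Skew direction implied by the gamma shape parameter
#'
#' `gamma = 0` gives a symmetric density, `gamma > 0` a negatively skewed one
#' (long left tail) and `gamma < 0` a positively skewed one (long right
#' tail).
#'
#' @param params A [jsb_params] object.
#' @return One of `"symmetric"`, `"negative"`, `"positive"`.
#' @export
jsb_skew_direction <- function(params) {
  if (params$gamma == 0) "symmetric" else if (params$gamma > 0) "negative" else "positive"
}

#' Support parameters from observed data
#'
#' The support is anchored to the data range, `xi = min(x)` and
#' `lam = max(x) - min(x)`, padded by half a gray level on each side
#' (`xi - 0.5`, width `+ 1`) so that every observed value — including pixels
#' sitting exactly at the range limits — lies strictly inside the open
#' support where the logit transform is finite.
#'
#' @param x Numeric vector of observed gray values (or histogram levels).
#' @param pad Padding added below the minimum and above the maximum; default
#'   half a gray level.
#' @return List with elements `xi` and `lam`.
#' @export
jsb_support <- function(x, pad = 0.5) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  r <- range(x)
  list(xi = r[1] - pad, lam = (r[2] - r[1]) + 2 * pad)
}

# Save / restore the caller's RNG state so seeded helpers are side-effect free.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
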