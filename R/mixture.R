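#' Finite mixture model over gray levels
#'
#' Container for a K-component mixture of either Johnson-SB components
#' (all sharing one support `(xi, xi + lam)`; per-component shape pair
#' `gamma_k`, `delta_k`) or Gaussian components (per-component `mean_k`,
#' `var_k`). Mixing weights are held to `sum(weights) == 1` within 1e-10.
#'
#' @param family `"jsb"` or `"gaussian"`.
#' @param weights Numeric vector of K mixing proportions.
#' @param gamma,delta Johnson-SB shape vectors (family `"jsb"`).
#' @param xi,lam Shared Johnson-SB support (family `"jsb"`).
#' @param mean,var Gaussian parameter vectors (family `"gaussian"`).
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(family = c("jsb", "gaussian"), weights,
                          gamma = NULL, delta = NULL, xi = NULL, lam = NULL,
                          mean = NULL, var = NULL) {
  family <- match.arg(family)
  weights <- as.numeric(weights)
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-10)
    stop("mixture_model: weights must be in [0,1] and sum to 1 (got sum ",
         format(sum(weights), digits = 15), ")")
  K <- length(weights)
  if (family == "jsb") {
    stopifnot(length(gamma) == K, length(delta) == K,
              length(xi) == 1, length(lam) == 1)
    if (any(delta <= 0)) stop("mixture_model: all delta must be > 0")
    if (lam <= 0) stop("mixture_model: lam must be > 0")
    m <- list(family = family, K = K, weights = weights,
              gamma = as.numeric(gamma), delta = as.numeric(delta),
              xi = as.numeric(xi), lam = as.numeric(lam))
  } else {
    stopifnot(length(mean) == K, length(var) == K)
    if (any(var <= 0)) stop("mixture_model: all var must be > 0")
    m <- list(family = family, K = K, weights = weights,
              mean = as.numeric(mean), var = as.numeric(var))
  }
  structure(m, class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("%s mixture, K = %d\n", x$family, x$K))
  if (x$family == "jsb") {
    cat(sprintf("  support (%.4g, %.4g)\n", x$xi, x$xi + x$lam))
    df <- data.frame(weight = x$weights, gamma = x$gamma, delta = x$delta,
                     median = component_medians(x))
  } else {
    df <- data.frame(weight = x$weights, mean = x$mean, sd = sqrt(x$var))
  }
  print(df, digits = 4)
  invisible(x)
}

# Per-component log densities: matrix length(x) x K.
comp_log_density <- function(x, model) {
  K <- model$K
  out <- matrix(-Inf, nrow = length(x), ncol = K)
  if (model$family == "jsb") {
    for (k in seq_len(K)) {
      out[, k] <- djsb(x, jsb_params(model$gamma[k], model$delta[k],
                                     model$xi, model$lam), log = TRUE)
    }
  } else {
    for (k in seq_len(K)) {
      out[, k] <- stats::dnorm(x, model$mean[k], sqrt(model$var[k]), log = TRUE)
    }
  }
  out
}

# Row-wise log(sum(exp(lp + lw))) guarded against underflow.
log_mix_density <- function(x, model) {
  lp <- comp_log_density(x, model)
  lw <- log(pmax(model$weights, .Machine$double.xmin))
  lpw <- sweep(lp, 2, lw, "+")
  m <- apply(lpw, 1, max)
  res <- m + log(rowSums(exp(lpw - m)))
  res[!is.finite(m)] <- -Inf
  res
}

#' Mixture probability density
#'
#' `p(x) = sum_k weights_k * p_k(x)`; for the Johnson-SB family the density
#' is 0 outside the shared support.
#'
#' @param x Numeric vector of gray values.
#' @param model A [mixture_model].
#' @return Numeric vector of densities.
#' @export
mixture_pdf <- function(x, model) {
  exp(log_mix_density(x, model))
}

#' Component medians of a mixture
#'
#' Johnson-SB components have the closed-form median
#' `xi + lam * plogis(-gamma/delta)`; Gaussian components' medians are their
#' means. Medians give the total order used to name the "leftmost" and
#' "rightmost" component curves during thresholding.
#'
#' @param model A [mixture_model].
#' @return Numeric vector of K medians.
#' @export
component_medians <- function(model) {
  if (model$family == "jsb") {
    model$xi + model$lam * stats::plogis(-model$gamma / model$delta)
  } else {
    model$mean
  }
}

#' Component density modes of a mixture
#'
#' The gray value at which each component's density peaks (mixing weights
#' scale a curve but do not move its peak). Johnson-SB modes are located
#' numerically; Gaussian modes are the means.
#'
#' @param model A [mixture_model].
#' @return Numeric vector of K modes.
#' @export
component_modes <- function(model) {
  if (model$family == "jsb") {
    vapply(seq_len(model$K), function(k)
      jsb_mode(jsb_params(model$gamma[k], model$delta[k], model$xi, model$lam)),
      numeric(1))
  } else {
    model$mean
  }
}

#' Discrete log-likelihood of a histogram under a mixture
#'
#' `L = sum_i counts_i * log(sum_k weights_k p_k(level_i))` over populated
#' levels; zero-count levels contribute nothing.
#'
#' @param hist A [gray_histogram].
#' @param model A [mixture_model].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(hist, model) {
  keep <- hist$counts > 0
  x <- hist$levels[keep]; cts <- hist$counts[keep]
  lm <- log_mix_density(x, model)
  if (any(!is.finite(lm))) {
    bad <- x[!is.finite(lm)]
    stop("log_likelihood: populated level(s) with zero mixture density (outside support?): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  sum(cts * lm)
}

#' E-step: posterior component responsibilities
#'
#' For each populated gray level `x_i`, the posterior probability that a
#' pixel at that level came from component k:
#' `w_ik = weights_k p_k(x_i) / sum_j weights_j p_j(x_i)`.
#'
#' @param hist A [gray_histogram].
#' @param model A [mixture_model].
#' @return Matrix (populated levels x K); attribute `"levels"` carries the
#'   gray levels of the rows. Every row sums to 1.
#' @export
e_step <- function(hist, model) {
  keep <- hist$counts > 0
  x <- hist$levels[keep]
  lp <- comp_log_density(x, model)
  lw <- log(pmax(model$weights, .Machine$double.xmin))
  lpw <- sweep(lp, 2, lw, "+")
  m <- apply(lpw, 1, max)
  if (any(!is.finite(m)))
    stop("e_step: all component densities are zero at populated level(s) ",
         paste(utils::head(x[!is.finite(m)], 5), collapse = ", "))
  w <- exp(lpw - m)
  resp <- w / rowSums(w)
  attr(resp, "levels") <- x
  resp
}

# Condition signalled when a component's responsibility-weighted variance
# collapses onto a single gray level.
collapse_condition <- function(k, v) {
  structure(class = c("jsbseg_collapse", "error", "condition"),
            list(message = sprintf("component %d collapsed (weighted variance %.3g)", k, v),
                 call = sys.call(-1), component = k))
}

#' M-step: closed-form weighted maximum-likelihood updates
#'
#' With `f_i` the logit transform of populated level `i`,
#' `N_k = sum_i c_i w_ik`, `m_k` and `v_k` the responsibility-weighted mean
#' and variance of `f`, the updates are `weights_k = N_k / sum(c)`,
#' `delta_k = 1/sqrt(v_k)` and `gamma_k = -delta_k * m_k` — the unique
#' stationary point of the weighted log-likelihood in `(gamma_k, delta_k)`
#' (the test suite checks this against a direct numerical maximizer). The
#' Gaussian family uses the standard weighted mean/variance updates.
#'
#' Because gray values are integer-quantized, a component narrower than one
#' gray level is unidentifiable and the unconstrained MLE can diverge onto a
#' single bin (the classic degenerate mixture likelihood). With
#' `var_floor = "quantization"` (the default, used by the EM driver) each
#' component's variance is floored at the in-bin quantization variance — for
#' the Johnson-SB family the responsibility-weighted mean of `f'(x)^2 / 12`
#' (the image of a unit gray bin in transform space), for Gaussians `1/12`.
#' The floor only binds for near-degenerate components; away from the floor
#' the update equals the exact closed form. With `var_floor = "none"` a
#' collapsing component (`v_k < 1e-8`) raises a collapse error naming it.
#'
#' When the previous model is supplied (as the EM driver does), the floor is
#' additionally capped at each component's current variance, so the update
#' never forces a component wider than it already is. This keeps the
#' constrained M-step a true ascent step and preserves the EM monotonicity
#' guarantee even while the floor binds.
#'
#' @param hist A [gray_histogram].
#' @param resp Responsibility matrix from [e_step()].
#' @param support List with `xi`, `lam` (Johnson-SB family only).
#' @param family `"jsb"` or `"gaussian"`.
#' @param var_floor `"quantization"` or `"none"` (see Details).
#' @param prev Optional previous [mixture_model] (ratchets the floor; see
#'   Details).
#' @return An updated [mixture_model].
#' @export
m_step <- function(hist, resp, support = NULL, family = c("jsb", "gaussian"),
                   var_floor = c("quantization", "none"), prev = NULL) {
  family <- match.arg(family)
  var_floor <- match.arg(var_floor)
  keep <- hist$counts > 0
  x <- hist$levels[keep]; cts <- hist$counts[keep]
  stopifnot(nrow(resp) == length(x))
  K <- ncol(resp)
  cw <- resp * cts              # c_i * w_ik
  Nk <- colSums(cw)
  if (any(Nk <= 0)) {
    k <- which(Nk <= 0)[1]
    stop(collapse_condition(k, 0))
  }
  weights <- Nk / sum(cts)
  if (family == "jsb") {
    stopifnot(!is.null(support))
    f <- jsb_logit(x, list(xi = support$xi, lam = support$lam))
    mk <- colSums(cw * f) / Nk
    vk <- colSums(cw * f^2) / Nk - mk^2
    if (var_floor == "quantization") {
      fp2 <- (support$lam / ((x - support$xi) * (support$lam + support$xi - x)))^2
      qk <- colSums(cw * fp2) / (12 * Nk)
      if (!is.null(prev)) qk <- pmin(qk, 1 / prev$delta^2)
      vk <- pmax(vk, qk)
    } else if (any(vk < 1e-8)) {
      k <- which(vk < 1e-8)[1]
      stop(collapse_condition(k, vk[k]))
    }
    delta <- 1 / sqrt(vk)
    gamma <- -delta * mk
    mixture_model("jsb", weights, gamma = gamma, delta = delta,
                  xi = support$xi, lam = support$lam)
  } else {
    mu <- colSums(cw * x) / Nk
    vk <- vapply(seq_len(K), function(k) sum(cw[, k] * (x - mu[k])^2) / Nk[k],
                 numeric(1))
    if (var_floor == "quantization") {
      qk <- rep(1 / 12, K)
      if (!is.null(prev)) qk <- pmin(qk, prev$var)
      vk <- pmax(vk, qk)
    } else if (any(vk < 1e-8)) {
      k <- which(vk < 1e-8)[1]
      stop(collapse_condition(k, vk[k]))
    }
    mixture_model("gaussian", weights, mean = mu, var = vk)
  }
}

#' EM configuration
#'
#' @param K Number of mixture components (the cluster number; default 13,
#'   the fixed value used for divided-histogram thresholding).
#' @param max_iter Iteration cap.
#' @param tol Relative log-likelihood convergence tolerance
#'   (`|dL| / max(1, |L|) < tol` stops the fit).
#' @param init_delta Initial `delta` for every Johnson-SB component.
#' @param family `"jsb"` or `"gaussian"`.
#' @param seed Integer seed recorded with fits (EM itself is deterministic;
#'   the seed governs any sampling done around it).
#' @return An object of class `em_config`.
#' @export
em_config <- function(K = 13, max_iter = 500, tol = 1e-6, init_delta = 2,
                      family = c("jsb", "gaussian"), seed = 1L) {
  family <- match.arg(family)
  stopifnot(K >= 1, tol > 0, max_iter >= 1, init_delta > 0)
  structure(list(K = as.integer(K), max_iter = as.integer(max_iter),
                 tol = tol, init_delta = init_delta, family = family,
                 seed = as.integer(seed)),
            class = "em_config")
}

#' Initial mixture with evenly spaced component locations
#'
#' Component locations are arranged evenly over the populated gray range
#' `[lo, hi]`: `c_k = lo + k/(K+1) * (hi - lo)`, k = 1..K, so all locations
#' are interior. Johnson-SB components are built so that `c_k` is exactly
#' the component median (`gamma_k = -init_delta * f(c_k)`, all
#' `delta_k = init_delta`); Gaussian components get `mean = c_k` and a common
#' variance `((hi - lo)/K)^2`. All weights start at `1/K`.
#'
#' @param hist A [gray_histogram] with at least K populated levels.
#' @param config An [em_config].
#' @return A [mixture_model].
#' @export
init_model <- function(hist, config) {
  pop <- populated_levels(hist)
  if (length(pop) < config$K)
    stop(sprintf("init_model: %d populated levels < K = %d", length(pop), config$K))
  lo <- min(pop); hi <- max(pop)
  ck <- lo + seq_len(config$K) / (config$K + 1) * (hi - lo)
  if (config$family == "jsb") {
    # support anchored to the histogram's full level axis (a CT slice always
    # spans black background to bright bone), padded so boundary levels stay
    # strictly interior
    sup <- jsb_support(hist$levels)
    f <- jsb_logit(ck, list(xi = sup$xi, lam = sup$lam))
    mixture_model("jsb", rep(1 / config$K, config$K),
                  gamma = -config$init_delta * f,
                  delta = rep(config$init_delta, config$K),
                  xi = sup$xi, lam = sup$lam)
  } else {
    v <- max(((hi - lo) / config$K)^2, 1)
    mixture_model("gaussian", rep(1 / config$K, config$K),
                  mean = ck, var = rep(v, config$K))
  }
}

# Re-seat a collapsed component at the populated level with the largest
# positive residual count (observed minus model-expected), with the initial
# delta; weights are re-normalized.
reinit_component <- function(model, k, hist, init_delta) {
  keep <- hist$counts > 0
  x <- hist$levels[keep]; cts <- hist$counts[keep]
  expected <- hist$total * mixture_pdf(x, model)
  target <- x[which.max(cts - expected)]
  w <- model$weights
  w[k] <- 1 / model$K
  w <- w / sum(w)
  if (model$family == "jsb") {
    f <- jsb_logit(target, list(xi = model$xi, lam = model$lam))
    model$gamma[k] <- -init_delta * f
    model$delta[k] <- init_delta
  } else {
    model$mean[k] <- target
    model$var[k] <- max(stats::var(rep(x, times = cts)) / model$K, 1)
  }
  model$weights <- w
  model
}

# Shared EM driver for both families.
run_em <- function(hist, config) {
  model <- init_model(hist, config)
  support <- if (config$family == "jsb") list(xi = model$xi, lam = model$lam) else NULL
  ll <- log_likelihood(hist, model)
  trace <- ll
  rescued <- rep(FALSE, config$K)
  converged <- FALSE
  iter <- 0
  while (iter < config$max_iter) {
    iter <- iter + 1
    resp <- e_step(hist, model)
    new_model <- tryCatch(
      m_step(hist, resp, support = support, family = config$family,
             prev = model),
      jsbseg_collapse = function(e) e)
    if (inherits(new_model, "jsbseg_collapse")) {
      k <- new_model$component
      if (rescued[k])
        stop(sprintf("fit_em: component %d collapsed twice; aborting (%s)",
                     k, conditionMessage(new_model)))
      rescued[k] <- TRUE
      model <- reinit_component(model, k, hist, config$init_delta)
      ll <- log_likelihood(hist, model)
      trace <- c(trace, ll)
      next
    }
    model <- new_model
    ll_new <- log_likelihood(hist, model)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) / max(1, abs(ll_new)) < config$tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  structure(list(model = model, loglik_trace = trace, n_iter = iter,
                 converged = converged, config = config),
            class = "jsb_fit")
}

#' Fit a Johnson-SB mixture to a histogram by EM
#'
#' Alternates posterior responsibilities ([e_step()]) with the closed-form
#' weighted maximum-likelihood updates ([m_step()]) until the relative
#' log-likelihood change drops below `config$tol` or `config$max_iter` is
#' reached. The shared support is fixed from the populated gray range (with
#' half-level padding) and never re-estimated; only the weights and the
#' shape pairs move. If a component collapses onto a single gray level it is
#' re-seated once at the most under-fitted level; a second collapse of the
#' same component is an error.
#'
#' @param hist A [gray_histogram].
#' @param config An [em_config] (family `"jsb"`).
#' @return A `jsb_fit` object: `model`, non-decreasing `loglik_trace`,
#'   `n_iter`, `converged`, `config`.
#' @export
fit_em <- function(hist, config = em_config()) {
  if (config$family != "jsb") config$family <- "jsb"
  run_em(hist, config)
}

#' Fit a Gaussian mixture baseline to a histogram by EM
#'
#' Identical driver and even initialization as [fit_em()], with Gaussian
#' components (mean, variance) in place of Johnson-SB shape pairs.
#'
#' @param hist A [gray_histogram].
#' @param config An [em_config]; its family is forced to `"gaussian"`.
#' @return A `jsb_fit` object.
#' @export
fit_gmm <- function(hist, config = em_config()) {
  config$family <- "gaussian"
  run_em(hist, config)
}

#' @export
print.jsb_fit <- function(x, ...) {
  cat(sprintf("EM fit (%s): K = %d, %d iterations, %sconverged, logLik %.2f\n",
              x$model$family, x$model$K, x$n_iter,
              if (x$converged) "" else "NOT ", utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

#' Serialize a fitted mixture to JSON
#'
#' Writes family, K, weights and per-component parameters to a plain-text
#' JSON file so fits are reproducible and inspectable.
#'
#' @param model A [mixture_model] (or a `jsb_fit`, whose model is taken).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mixture <- function(model, path) {
  if (inherits(model, "jsb_fit")) model <- model$model
  stopifnot(inherits(model, "mixture_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted mixture from JSON
#'
#' @param path File written by [write_mixture()].
#' @return A [mixture_model].
#' @export
read_mixture <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (m$family == "jsb") {
    mixture_model("jsb", m$weights, gamma = m$gamma, delta = m$delta,
                  xi = m$xi, lam = m$lam)
  } else {
    mixture_model("gaussian", m$weights, mean = m$mean, var = m$var)
  }
}
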