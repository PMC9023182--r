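# Shared fixtures: all randomness goes through explicit seeds so the suite
# is reproducible run to run.

random_jsb_params <- function(seed, xi = -0.5, lam = 256) {
  set.seed(seed)
  jsb_params(gamma = runif(1, -2, 2), delta = runif(1, 0.8, 4),
             xi = xi, lam = lam)
}

# A valid random mixture over the 0..255 gray axis.
random_jsb_mixture <- function(seed, K = 3) {
  set.seed(seed)
  w <- runif(K, 0.5, 2); w <- w / sum(w)
  mixture_model("jsb", w,
                gamma = runif(K, -2, 2), delta = runif(K, 0.8, 4),
                xi = -0.5, lam = 256)
}

# Small random histogram drawn from a random mixture.
random_histogram <- function(seed, K = 3, n = 5000) {
  make_mixture_histogram(random_jsb_mixture(seed, K), n, seed = seed + 1000)
}

# Johnson-SB mixture with well-separated medians used for recovery tests;
# gammas are solved in closed form so the medians are exact.
separated_mixture <- function(medians = c(60, 130, 200),
                              deltas = c(2.5, 3, 2.5),
                              weights = c(0.3, 0.45, 0.25)) {
  gammas <- -deltas * stats::qlogis((medians + 0.5) / 256)
  mixture_model("jsb", weights, gamma = gammas, delta = deltas,
                xi = -0.5, lam = 256)
}

# Worked right-part configuration: two curves with the smallest medians
# crossing at exactly gray 190 (the weight ratio is solved from the density
# ratio there), plus a third unimodal curve whose density peaks at exactly
# 188 — between the liver peak at 176 and the crossing — with a median above
# both. Constructed entirely in closed form.
override_fixture <- function() {
  xi <- 130; lam <- 120
  u <- (188 - xi) / lam
  dC <- 0.72
  gC <- (2 * u - 1) / dC - dC * log(u / (1 - u)) # mode equation at 188
  dA <- 2.4; dB <- 2.2
  gA <- -dA * stats::qlogis((184 - xi) / lam)    # median 184
  gB <- -dB * stats::qlogis((188.5 - xi) / lam)  # median 188.5
  r <- djsb(190, jsb_params(gA, dA, xi, lam)) /
       djsb(190, jsb_params(gB, dB, xi, lam))    # wB/wA for a crossing at 190
  wA <- 0.75 / (1 + r); wB <- 0.75 * r / (1 + r)
  list(
    with_peak = mixture_model("jsb", c(wA, wB, 0.25),
                              gamma = c(gA, gB, gC), delta = c(dA, dB, dC),
                              xi = xi, lam = lam),
    pair_only = mixture_model("jsb", c(wA, wB) / (wA + wB),
                              gamma = c(gA, gB), delta = c(dA, dB),
                              xi = xi, lam = lam))
}

sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / (mean(z^2)^1.5)
}

# Brute-force maximizer of one component's responsibility-weighted
# log-likelihood over (gamma, delta); the independent oracle for the
# closed-form M-step.
oracle_component_mle <- function(x, cw_k, support) {
  f <- log((x - support$xi) / (support$lam + support$xi - x))
  const <- log(support$lam) - log(x - support$xi) - log(support$lam + support$xi - x)
  nll <- function(par) {
    g <- par[1]; d <- exp(par[2])
    -sum(cw_k * (log(d) - 0.5 * log(2 * pi) + const - 0.5 * (g + d * f)^2))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  c(gamma = fit$par[1], delta = exp(fit$par[2]))
}
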