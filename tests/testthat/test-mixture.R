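test_that("histogram constructor validates and counts pixels", {
  img <- matrix(c(0L, 0L, 5L, 255L), 2, 2)
  h <- build_histogram(img)
  expect_s3_class(h, "gray_histogram")
  expect_equal(h$total, 4)
  expect_equal(h$counts[h$levels %in% c(0, 5, 255)], c(2, 1, 1))
  expect_equal(sum(h$counts), 4)
  # constant image is a single spike
  hc <- build_histogram(matrix(7L, 3, 3))
  expect_equal(populated_levels(hc), 7)
  # roi partition preserves the total
  roi <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  ha <- build_histogram(img, roi)
  hb <- build_histogram(img, !roi)
  expect_equal(ha$total + hb$total, h$total)
  expect_error(build_histogram(img, matrix(FALSE, 2, 2)), "empty roi")
  expect_error(gray_histogram(0:3, rep(0, 4)), "empty")
})

test_that("mixture density reduces to its component and is convex in weights", {
  p <- jsb_params(0.5, 1.5, xi = -0.5, lam = 256)
  m1 <- mixture_model("jsb", 1, gamma = p$gamma, delta = p$delta,
                      xi = p$xi, lam = p$lam)
  x <- seq(10, 240, by = 5)
  expect_equal(mixture_pdf(x, m1), djsb(x, p), tolerance = 1e-12)
  # two identical components behave as one
  m2 <- mixture_model("jsb", c(0.3, 0.7), gamma = rep(p$gamma, 2),
                      delta = rep(p$delta, 2), xi = p$xi, lam = p$lam)
  expect_equal(mixture_pdf(x, m2), djsb(x, p), tolerance = 1e-12)
  # random mixture integrates to 1
  m <- random_jsb_mixture(5, K = 4)
  I <- stats::integrate(function(x) mixture_pdf(x, m), m$xi, m$xi + m$lam,
                        rel.tol = 1e-10, subdivisions = 400L)$value
  expect_equal(I, 1, tolerance = 1e-8)
})

test_that("mixture constructor enforces the weight simplex", {
  expect_error(mixture_model("jsb", c(0.5, 0.6), gamma = c(0, 0),
                             delta = c(1, 1), xi = 0, lam = 1), "sum to 1")
})

test_that("log-likelihood is count-weighted and matches a per-pixel computation", {
  m <- random_jsb_mixture(9, K = 2)
  # single populated level, K = 1
  m1 <- mixture_model("jsb", 1, gamma = 0.3, delta = 2, xi = -0.5, lam = 256)
  h1 <- gray_histogram(c(100, 101), c(1, 0))
  expect_equal(log_likelihood(h1, m1), djsb(100, jsb_params(0.3, 2, -0.5, 256), log = TRUE))
  # linearity in counts
  h <- random_histogram(3, K = 2, n = 2000)
  h2 <- gray_histogram(h$levels, 2 * h$counts)
  expect_equal(log_likelihood(h2, m), 2 * log_likelihood(h, m), tolerance = 1e-12)
  # 4-pixel image: flat per-pixel oracle
  pix <- c(40L, 40L, 90L, 200L)
  hp <- build_histogram(matrix(pix, 2, 2))
  expect_equal(log_likelihood(hp, m), sum(log(mixture_pdf(pix, m))), tolerance = 1e-12)
})

test_that("log-likelihood rejects populated levels outside the support", {
  m <- mixture_model("jsb", 1, gamma = 0, delta = 1, xi = 50, lam = 100)
  h <- gray_histogram(c(10, 60), c(5, 5))
  expect_error(log_likelihood(h, m), "outside support")
})

test_that("responsibilities are a proper posterior", {
  h <- random_histogram(21, K = 3)
  # K = 1: all ones
  m1 <- mixture_model("jsb", 1, gamma = 0, delta = 1, xi = -0.5, lam = 256)
  r1 <- e_step(h, m1)
  expect_true(all(r1 == 1))
  # identical components with equal weights: all entries 1/2
  m2 <- mixture_model("jsb", c(0.5, 0.5), gamma = c(0, 0), delta = c(1, 1),
                      xi = -0.5, lam = 256)
  r2 <- e_step(h, m2)
  expect_true(all(abs(r2 - 0.5) < 1e-14))
  # random model: rows sum to one
  m <- random_jsb_mixture(22, K = 4)
  r <- e_step(h, m)
  expect_equal(rowSums(r), rep(1, nrow(r)), tolerance = 1e-12)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("closed-form M-step reproduces hand-computed shape updates", {
  sup <- list(xi = -0.5, lam = 256)
  # two levels placed at f = -1 and f = +1: weighted mean 0, variance 1
  lv <- sort(jsb_logit_inv(c(-1, 1), sup))
  h <- gray_histogram(lv, c(10, 10))
  resp <- matrix(1, nrow = 2, ncol = 1)
  m <- m_step(h, resp, support = sup, family = "jsb")
  expect_equal(m$delta, 1, tolerance = 1e-12)
  expect_equal(m$gamma, 0, tolerance = 1e-12)
  # general weighted mean/sd of f
  lv2 <- jsb_logit_inv(c(-0.4, 0.1, 1.3), sup)
  cts <- c(5, 2, 3)
  h2 <- gray_histogram(lv2, cts)
  m2 <- m_step(h2, matrix(1, 3, 1), support = sup, family = "jsb")
  f <- jsb_logit(lv2, sup)
  mu <- sum(cts * f) / sum(cts)
  sdf <- sqrt(sum(cts * f^2) / sum(cts) - mu^2)
  expect_equal(m2$delta, 1 / sdf, tolerance = 1e-12)
  expect_equal(m2$gamma, -mu / sdf, tolerance = 1e-12)
})

test_that("M-step signals a named collapse when a component owns one level", {
  sup <- list(xi = -0.5, lam = 256)
  h <- gray_histogram(c(50, 150), c(5, 5))
  resp <- matrix(c(0, 1, 1, 0), nrow = 2) # each component owns a single level
  expect_error(m_step(h, resp, support = sup, family = "jsb", var_floor = "none"),
               "component 1 collapsed")
})

test_that("closed-form M-step agrees with a numerical maximizer on random cases", {
  sup <- list(xi = -0.5, lam = 256)
  n_cases <- 20
  for (case in seq_len(n_cases)) {
    h <- random_histogram(100 + case, K = 2, n = 3000)
    m0 <- random_jsb_mixture(200 + case, K = 2)
    resp <- e_step(h, m0)
    fit <- m_step(h, resp, support = sup, family = "jsb")
    keep <- h$counts > 0
    x <- h$levels[keep]; cts <- h$counts[keep]
    for (k in 1:2) {
      ora <- oracle_component_mle(x, cts * resp[, k], sup)
      expect_equal(fit$delta[k], unname(ora["delta"]), tolerance = 1e-4)
      expect_equal(fit$gamma[k], unname(ora["gamma"]), tolerance = 1e-4)
    }
    # weight update: responsibility mass fractions
    expect_equal(fit$weights, colSums(resp * cts) / sum(cts), tolerance = 1e-12)
  }
})

test_that("even initialization places component medians at interior locations", {
  h <- gray_histogram(0:255, c(0, rep(10, 255))) # populated 1..255
  cfg <- em_config(K = 2, init_delta = 2)
  m <- init_model(h, cfg)
  pop <- populated_levels(h)
  lo <- min(pop); hi <- max(pop)
  expected <- lo + (1:2) / 3 * (hi - lo)
  expect_equal(component_medians(m), expected, tolerance = 1e-9)
  expect_equal(m$weights, c(0.5, 0.5))
  # each component's CDF at its location is exactly one half
  for (k in 1:2) {
    pk <- jsb_params(m$gamma[k], m$delta[k], m$xi, m$lam)
    expect_equal(pjsb(expected[k], pk), 0.5, tolerance = 1e-9)
  }
  expect_error(init_model(gray_histogram(0:2, c(4, 0, 0)), em_config(K = 2)),
               "populated levels")
})

test_that("EM recovers a single Johnson-SB component within 5%", {
  tru <- mixture_model("jsb", 1, gamma = 1, delta = 2, xi = -0.5, lam = 256)
  h <- make_mixture_histogram(tru, 50000, seed = 7)
  fit <- fit_em(h, em_config(K = 1))
  expect_lt(abs(fit$model$gamma - 1) / 1, 0.05)
  expect_lt(abs(fit$model$delta - 2) / 2, 0.05)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("EM fits are deterministic and traces never decrease", {
  h <- random_histogram(55, K = 3, n = 20000)
  f1 <- fit_em(h, em_config(K = 4))
  f2 <- fit_em(h, em_config(K = 4))
  expect_identical(f1$model, f2$model)
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
  expect_gte(utils::tail(f1$loglik_trace, 1), f1$loglik_trace[1])
  expect_equal(sum(f1$model$weights), 1, tolerance = 1e-10)
})

test_that("Gaussian EM recovers single and symmetric two-component truths", {
  g1 <- mixture_model("gaussian", 1, mean = 120, var = 300)
  h1 <- make_mixture_histogram(g1, 50000, seed = 3)
  f1 <- fit_gmm(h1, em_config(K = 1))
  expect_equal(f1$model$mean, 120, tolerance = 1)
  expect_equal(f1$model$var, 300, tolerance = 300 * 0.05)
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
  # symmetric two-component truth: fitted means symmetric about the center
  g2 <- mixture_model("gaussian", c(0.5, 0.5), mean = c(100, 156), var = c(144, 144))
  h2 <- make_mixture_histogram(g2, 80000, seed = 13)
  f2 <- fit_gmm(h2, em_config(K = 2, tol = 1e-8))
  mu <- sort(f2$model$mean)
  expect_equal(mu[1] + mu[2], 256, tolerance = 1)
  expect_equal(mu, c(100, 156), tolerance = 1)
})

test_that("fitted mixtures serialize to JSON and back", {
  m <- random_jsb_mixture(77, K = 3)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_mixture(m, path)
  m2 <- read_mixture(path)
  expect_equal(m2, m, tolerance = 1e-12)
  g <- mixture_model("gaussian", c(0.4, 0.6), mean = c(50, 200), var = c(100, 400))
  write_mixture(g, path)
  expect_equal(read_mixture(path), g, tolerance = 1e-12)
})
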