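test_that("inverse_logit matches its closed form and stays stable far out", {
  expect_equal(inverse_logit(0), 0.5)
  expect_equal(inverse_logit(log(3)), 0.75)
  low <- inverse_logit(-50)
  expect_gt(low, 0)
  expect_lt(low, 1e-20)
  expect_equal(inverse_logit(700), 1)       # saturates, never overflows
  expect_gt(inverse_logit(-700), -1e-300)
  expect_error(inverse_logit(NaN), "finite")
  expect_error(inverse_logit(Inf), "finite")
})

test_that("linear predictor reproduces the per-row arithmetic", {
  data <- make_small_data(N = 20, K = 3, J = 3, seed = 2)
  zero <- param_vector(alpha0 = 0, mu_raw = rep(0, 3), log_sigma_mu = 0,
                       beta = rep(0, 3))
  expect_equal(linear_predictor(zero, data), rep(0, 20))

  one <- hl_dataset(y = 1, X = matrix(3), group = 1,
                    covariate_names = "x")
  p1 <- param_vector(alpha0 = 1, mu_raw = 0, log_sigma_mu = 0, beta = 2)
  expect_equal(linear_predictor(p1, one), 7)

  # brute-force per-row loop oracle on random instances
  for (seed in 1:5) {
    data <- make_small_data(N = 25, K = 4, J = 3, seed = seed)
    set.seed(seed + 100)
    p <- random_params(J = 3, K = 4)
    eta <- linear_predictor(p, data)
    oracle <- vapply(seq_len(data$N), function(i) {
      p$alpha0 + exp(p$log_sigma_mu) * p$mu_raw[data$group[i]] +
        sum(p$beta * data$X[i, ])
    }, numeric(1))
    expect_equal(eta, oracle, tolerance = 1e-12)
  }

  bad <- param_vector(alpha0 = 0, mu_raw = rep(0, 3), beta = rep(0, 5))
  expect_error(linear_predictor(bad, data), "mismatch")
})

test_that("log likelihood matches direct Bernoulli evaluation and is stable", {
  one <- hl_dataset(y = 1, X = matrix(0), group = 1)
  p0 <- param_vector(alpha0 = 0, mu_raw = 0, log_sigma_mu = 0, beta = 0)
  expect_equal(log_likelihood(p0, one), log(0.5))

  two <- hl_dataset(y = c(1, 0), X = matrix(c(0, 0)), group = c(1, 1))
  pl3 <- param_vector(alpha0 = log(3), mu_raw = 0, log_sigma_mu = -9,
                      beta = 0)
  expect_equal(log_likelihood(pl3, two),
               log(0.75) + log(0.25), tolerance = 1e-6)

  # product-then-log oracle on a random small instance
  data <- make_small_data(N = 15, K = 2, J = 3, seed = 7)
  set.seed(7)
  p <- random_params(J = 3, K = 2)
  pi_i <- plogis(linear_predictor(p, data))
  direct <- sum(log(pi_i^data$y * (1 - pi_i)^(1 - data$y)))
  expect_equal(log_likelihood(p, data), direct, tolerance = 1e-10)

  # extreme logits must not produce -Inf/NaN via 0*log(0)
  pbig <- param_vector(alpha0 = 400, mu_raw = rep(0, 3), log_sigma_mu = 0,
                       beta = rep(0, 2))
  expect_true(is.finite(log_likelihood(pbig, data)))
})

test_that("log likelihood is invariant to row permutation", {
  data <- make_small_data(N = 40, K = 3, J = 3, seed = 3)
  set.seed(3)
  p <- random_params()
  perm <- sample(data$N)
  shuffled <- hl_dataset(y = data$y[perm], X = data$X[perm, ],
                         group = data$group[perm],
                         covariate_names = data$covariate_names)
  expect_equal(log_likelihood(p, data), log_likelihood(p, shuffled))
})

test_that("log prior equals the sum of its closed-form components", {
  priors <- prior_spec()
  J <- 3; K <- 2
  zero <- param_vector(alpha0 = 0, mu_raw = rep(0, J), log_sigma_mu = 0,
                       beta = rep(0, K))
  # written out by hand: normals at 0, half-Cauchy at sigma = 1, zero Jacobian
  expected <- -log(sqrt(2 * pi) * 10) +            # alpha0
    K * -log(sqrt(2 * pi) * 10) +                  # slopes
    J * -log(sqrt(2 * pi)) +                       # standardized deviations
    log(2 / (pi * 2.5 * (1 + (1 / 2.5)^2))) +      # half-Cauchy(2.5) at 1
    0                                              # log-Jacobian at log sigma = 0
  expect_equal(log_prior(zero, priors), expected, tolerance = 1e-12)

  # strictly decreasing as a slope moves away from the mode
  lp_at <- function(b) log_prior(
    param_vector(0, rep(0, J), 0, c(b, 0)), priors)
  vals <- vapply(c(0, 1, 2, 5), lp_at, numeric(1))
  expect_true(all(diff(vals) < 0))

  # doubling sigma_scale touches only the scale-prior component
  p <- param_vector(0.4, c(0.2, -1, 0.5), 0.3, c(1, -2))
  pri2 <- prior_spec(sigma_scale = 5)
  sigma <- exp(0.3)
  hc <- function(x, s) log(2) - log(pi * s) - log1p((x / s)^2)
  expect_equal(log_prior(p, pri2) - log_prior(p, priors),
               hc(sigma, 5) - hc(sigma, 2.5), tolerance = 1e-12)
})

test_that("log posterior is the sum of likelihood and prior, and is symmetric
           under consistent group relabeling", {
  data <- make_small_data(N = 30, K = 3, J = 3, seed = 5)
  priors <- prior_spec()
  set.seed(5)
  p <- random_params()
  expect_equal(log_posterior(p, data, priors),
               log_likelihood(p, data) + log_prior(p, priors))

  # relabel groups 1<->3 in both data and mu_raw
  relab <- c(3L, 2L, 1L)
  data2 <- hl_dataset(y = data$y, X = data$X, group = relab[data$group],
                      covariate_names = data$covariate_names)
  p2 <- param_vector(p$alpha0, p$mu_raw[relab], p$log_sigma_mu, p$beta)
  expect_equal(log_posterior(p2, data2, priors),
               log_posterior(p, data, priors))

  # all-ones outcome: a finite maximizer over alpha0 exists
  flat <- hl_dataset(y = rep(1, 20), X = matrix(0, 20, 1),
                     group = rep(1:2, 10))
  lp_a <- vapply(seq(-5, 40, by = 0.5), function(a) {
    log_posterior(param_vector(a, c(0, 0), 0, 0), flat, priors)
  }, numeric(1))
  expect_lt(which.max(lp_a), length(lp_a))   # interior maximum
})

test_that("analytic gradient matches central finite differences", {
  priors <- prior_spec()
  for (seed in 1:25) {
    set.seed(seed)
    N <- sample(10:50, 1); K <- sample(1:5, 1)
    data <- make_small_data(N = N, K = K, J = 3, seed = seed)
    p <- random_params(J = 3, K = K)
    theta <- c(p$alpha0, p$mu_raw, p$log_sigma_mu, p$beta)
    g <- grad_log_posterior(p, data, priors)
    fd <- fd_grad(function(th) {
      q <- param_vector(th[1], th[2:4], th[5], th[5 + seq_len(K)])
      log_posterior(q, data, priors)
    }, theta)
    expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-5)
  }
})

test_that("gradient closed forms at special points hold", {
  data <- make_small_data(N = 24, K = 2, J = 3, seed = 9)
  priors <- prior_spec()
  # prior mode, sigma = 1: beta-gradient is X'(y - 1/2)
  p0 <- param_vector(0, rep(0, 3), 0, rep(0, 2))
  g <- grad_log_posterior(p0, data, priors)
  expect_equal(unname(g[6:7]),
               unname(drop(crossprod(data$X, data$y - 0.5))),
               tolerance = 1e-12)
  # prior score at beta = scale is -1/scale
  prior_score <- fd_grad(function(b) {
    log_prior(param_vector(0, rep(0, 3), 0, c(b, 0)), priors)
  }, 10)
  expect_equal(prior_score, -1 / 10, tolerance = 1e-6)
})

test_that("dataset constructor enforces its invariants", {
  expect_error(hl_dataset(y = c(0, 2), X = matrix(0, 2, 1), group = c(1, 1)),
               "0/1")
  expect_error(hl_dataset(y = c(0, NA), X = matrix(0, 2, 1), group = c(1, 1)),
               "missing")
  expect_error(hl_dataset(y = c(0, 1), X = matrix(0, 2, 1), group = c(1, 3)),
               "contiguous")
  expect_error(hl_dataset(y = c(0, 1), X = matrix(0, 2, 2), group = c(1, 2),
                          covariate_names = c("a", "a")), "unique")
})

test_that("survey CSV round-trips through the package readers", {
  sim <- generate_dataset(generator_config(N = 60, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(sim$data, path)
  back <- read_survey_csv(path, outcome = "outcome", group = "group")
  expect_equal(back$y, sim$data$y)
  expect_equal(back$X, sim$data$X, ignore_attr = TRUE)
  expect_equal(back$group, sim$data$group)
  expect_equal(back$covariate_names, sim$data$covariate_names)
})
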