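# Shared fixtures and independent oracles for the test suite.

# random small dataset for gradient / likelihood property tests
make_small_data <- function(N = 30, K = 3, J = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(N * K), N, K)
  group <- sort(c(seq_len(J), sample.int(J, N - J, replace = TRUE)))
  y <- rbinom(N, 1, 0.5)
  hl_dataset(y = y, X = X, group = group)
}

random_params <- function(J = 3, K = 3) {
  param_vector(alpha0 = rnorm(1, 0, 0.5),
               mu_raw = rnorm(J),
               log_sigma_mu = rnorm(1, 0, 0.5),
               beta = rnorm(K, 0, 0.5))
}

# central finite differences of a scalar function
fd_grad <- function(fn, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, numeric(1))
}

# multivariate Gaussian target in the sampler's model interface
gaussian_target <- function(mean, precision) {
  D <- length(mean)
  nm <- paste0("t", seq_len(D))
  list(dim = D, param_names = nm, constrained_names = nm,
       lp_grad = function(theta) {
         d <- theta - mean
         list(lp = -0.5 * sum(d * (precision %*% d)),
              grad = -drop(precision %*% d))
       },
       constrain = function(m) { colnames(m) <- nm; m })
}

# dense 2-d trapezoid-integration oracle for a non-hierarchical
# Bayesian logit with one covariate: posterior mean and SD of
# (alpha0, beta) under N(0, scale) priors
grid_posterior_2param <- function(y, x, alpha_scale = 10, beta_scale = 10,
                                  n_nodes = 400, lim = 10) {
  a <- seq(-lim, lim, length.out = n_nodes)
  b <- seq(-lim, lim, length.out = n_nodes)
  l1pe <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
  sy <- sum(y); syx <- sum(y * x)
  lp <- matrix(0, n_nodes, n_nodes)
  for (j in seq_len(n_nodes)) {
    S <- colSums(l1pe(outer(b[j] * x, a, "+")))   # over data rows
    lp[, j] <- a * sy + b[j] * syx - S +
      dnorm(a, 0, alpha_scale, log = TRUE) +
      dnorm(b[j], 0, beta_scale, log = TRUE)
  }
  w <- rep(1, n_nodes); w[c(1, n_nodes)] <- 0.5
  W <- outer(w, w)
  p <- exp(lp - max(lp)) * W
  p <- p / sum(p)
  pa <- rowSums(p); pb <- colSums(p)
  mean_a <- sum(pa * a); mean_b <- sum(pb * b)
  list(mean = c(alpha0 = mean_a, beta = mean_b),
       sd = c(alpha0 = sqrt(sum(pa * (a - mean_a)^2)),
              beta = sqrt(sum(pb * (b - mean_b)^2))))
}

# Monte Carlo standard error from pooled chains
mcse <- function(chains) {
  sd(as.vector(chains)) / sqrt(effective_sample_size(chains))
}

# the expensive default-protocol fit is shared across acceptance tests
.fit_cache <- new.env(parent = emptyenv())

default_protocol_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    sim <- generate_dataset(generator_config(seed = 20))
    draws <- run_chains(hl_model(sim$data), sampler_config(seed = 20))
    .fit_cache$fit <- list(sim = sim, draws = draws)
  }
  .fit_cache$fit
}
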