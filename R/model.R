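#' Prior specification
#'
#' Weakly informative priors matching the study protocol: independent
#' Normal(0, `alpha_scale`) on the global intercept, Normal(0,
#' `beta_scale`) on each slope, and a half-Cauchy(0, `sigma_scale`) on
#' the between-group standard deviation. Scales are standard deviations
#' (the Stan convention), not variances.
#'
#' @param beta_scale prior SD of each slope (default 10).
#' @param alpha_scale prior SD of the global intercept (default 10).
#' @param sigma_scale half-Cauchy scale of the group SD (default 2.5).
#' @return An object of class `hl_priors`.
#' @export
prior_spec <- function(beta_scale = 10, alpha_scale = 10, sigma_scale = 2.5) {
  for (s in c(beta_scale, alpha_scale, sigma_scale))
    if (!is.finite(s) || s <= 0)
      stop("prior_spec: all scales must be strictly positive", call. = FALSE)
  structure(list(beta_scale = beta_scale, alpha_scale = alpha_scale,
                 sigma_scale = sigma_scale),
            class = "hl_priors")
}

#' Unconstrained parameter state
#'
#' The model is parameterized non-centrally: group intercepts are
#' `alpha0 + sigma_mu * mu_raw[j]` with `mu_raw[j] ~ N(0,1)` a priori,
#' and the group scale is carried as `log_sigma_mu` so that all
#' components live on an unconstrained scale suitable for Hamiltonian
#' Monte Carlo.
#'
#' @param alpha0 global intercept (logit scale).
#' @param mu_raw numeric vector of `J` standardized group deviations.
#' @param log_sigma_mu log of the between-group SD.
#' @param beta numeric vector of `K` slopes (logit scale).
#' @return An object of class `hl_params`.
#' @export
param_vector <- function(alpha0 = 0, mu_raw = numeric(0), log_sigma_mu = 0,
                         beta = numeric(0)) {
  p <- list(alpha0 = as.numeric(alpha0), mu_raw = as.numeric(mu_raw),
            log_sigma_mu = as.numeric(log_sigma_mu), beta = as.numeric(beta))
  if (!all(vapply(p, function(v) all(is.finite(v)), logical(1))))
    stop("param_vector: all entries must be finite", call. = FALSE)
  structure(p, class = "hl_params")
}

# flat layout: alpha0 | mu_raw (J) | log_sigma_mu | beta (K)
pack_params <- function(params) {
  c(params$alpha0, params$mu_raw, params$log_sigma_mu, params$beta)
}

unpack_params <- function(theta, J, K) {
  stopifnot(length(theta) == 1L + J + 1L + K)
  param_vector(alpha0 = theta[1L],
               mu_raw = theta[seq_len(J) + 1L],
               log_sigma_mu = theta[J + 2L],
               beta = theta[J + 2L + seq_len(K)])
}

#' Numerically stable inverse logit
#'
#' `1 / (1 + exp(-eta))`, evaluated so that arguments of magnitude
#' several hundred neither overflow nor collapse beyond floating-point
#' limits.
#'
#' @param eta numeric vector of logits; must be finite.
#' @return probabilities in (0, 1).
#' @export
inverse_logit <- function(eta) {
  if (!all(is.finite(eta)))
    stop("inverse_logit: input must be finite", call. = FALSE)
  stats::plogis(eta)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

check_dims <- function(params, data) {
  if (length(params$beta) != data$K)
    stop("parameter/data mismatch: ", length(params$beta),
         " slopes vs ", data$K, " covariates", call. = FALSE)
  if (length(params$mu_raw) != data$J)
    stop("parameter/data mismatch: ", length(params$mu_raw),
         " group deviations vs ", data$J, " groups", call. = FALSE)
  invisible(TRUE)
}

#' Linear predictor of the varying-intercept logit model
#'
#' Row `i` receives `alpha0 + sigma_mu * mu_raw[group(i)] + X[i, ] %*% beta`
#' with `sigma_mu = exp(log_sigma_mu)`.
#'
#' @param params an `hl_params`.
#' @param data an `hl_dataset`.
#' @return numeric vector of `N` logits.
#' @export
linear_predictor <- function(params, data) {
  check_dims(params, data)
  sigma_mu <- exp(params$log_sigma_mu)
  eta <- params$alpha0 + sigma_mu * params$mu_raw[data$group]
  drop(eta + data$X %*% params$beta)
}

#' Bernoulli log-likelihood on the logit scale
#'
#' `sum(y * eta - log(1 + exp(eta)))`, algebraically equal to
#' `sum(y log pi + (1 - y) log(1 - pi))` but evaluated without ever
#' forming `pi`, so it stays finite for any finite parameters.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  eta <- linear_predictor(params, data)
  sum(data$y * eta - log1pexp(eta))
}

# half-Cauchy(0, s) log density at x > 0
log_half_cauchy <- function(x, s) {
  log(2) - log(pi * s) - log1p((x / s)^2)
}

#' Log prior density on the unconstrained scale
#'
#' Sum of the Normal log-densities for `alpha0` and each slope,
#' standard-Normal log-densities for the standardized group deviations,
#' the half-Cauchy log-density for `sigma_mu`, and the log-Jacobian
#' `log_sigma_mu` of the log transform, so that the density is proper on
#' the unconstrained scale. Normalizing constants are included.
#'
#' @param params an `hl_params`.
#' @param priors an `hl_priors`.
#' @return scalar log prior density.
#' @export
log_prior <- function(params, priors) {
  sigma_mu <- exp(params$log_sigma_mu)
  stats::dnorm(params$alpha0, 0, priors$alpha_scale, log = TRUE) +
    sum(stats::dnorm(params$beta, 0, priors$beta_scale, log = TRUE)) +
    sum(stats::dnorm(params$mu_raw, log = TRUE)) +
    log_half_cauchy(sigma_mu, priors$sigma_scale) +
    params$log_sigma_mu
}

#' Unnormalized log posterior
#'
#' @inheritParams linear_predictor
#' @param priors an `hl_priors`.
#' @return `log_likelihood(params, data) + log_prior(params, priors)`.
#' @export
log_posterior <- function(params, data, priors) {
  log_likelihood(params, data) + log_prior(params, priors)
}

#' Analytic gradient of the log posterior
#'
#' Exact gradient with respect to the unconstrained coordinates
#' `(alpha0, mu_raw, log_sigma_mu, beta)`. The likelihood contribution
#' to each coordinate is `sum_i (y_i - pi_i) * d eta_i / d theta`.
#'
#' @inheritParams log_posterior
#' @return numeric vector of length `1 + J + 1 + K`, named.
#' @export
grad_log_posterior <- function(params, data, priors) {
  check_dims(params, data)
  sigma_mu <- exp(params$log_sigma_mu)
  eta <- linear_predictor(params, data)
  r <- data$y - stats::plogis(eta)           # y - pi
  gsum <- rowsum(r, data$group)              # per-group residual sums

  g_alpha0 <- sum(r) - params$alpha0 / priors$alpha_scale^2
  g_mu <- sigma_mu * drop(gsum) - params$mu_raw
  g_beta <- drop(crossprod(data$X, r)) - params$beta / priors$beta_scale^2
  # d/d log_sigma: likelihood + half-Cauchy score * sigma + Jacobian
  g_ls <- sigma_mu * sum(params$mu_raw * drop(gsum)) -
    2 * sigma_mu^2 / (priors$sigma_scale^2 + sigma_mu^2) + 1

  g <- c(g_alpha0, g_mu, g_ls, g_beta)
  if (!all(is.finite(g))) {
    bad <- which(!is.finite(g))
    stop("grad_log_posterior: non-finite gradient at coordinate(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  names(g) <- c("alpha0", paste0("mu_raw[", seq_len(data$J), "]"),
                "log_sigma_mu", paste0("beta[", seq_len(data$K), "]"))
  g
}

#' Build a sampler-ready model object
#'
#' Packages the data and priors into the interface the sampler consumes:
#' the unconstrained dimension, parameter names, a fused log-posterior /
#' gradient evaluator, and the map from unconstrained draws to the
#' constrained reporting scale. With `hierarchical = FALSE` the group
#' structure is ignored and the model reduces to a plain Bayesian logit
#' with parameters `(alpha0, beta)` — used mainly for oracle checks
#' against low-dimensional quadrature.
#'
#' @param data an `hl_dataset`.
#' @param priors an `hl_priors`.
#' @param hierarchical include grade-varying intercepts? Default `TRUE`.
#' @return An object of class `hl_model` with elements `dim`,
#'   `param_names`, `constrained_names`, `lp_grad(theta)`, `lp(theta)`,
#'   `constrain(mat)`, plus `data`, `priors`, `hierarchical`.
#' @export
hl_model <- function(data, priors = prior_spec(), hierarchical = TRUE) {
  stopifnot(inherits(data, "hl_dataset"), inherits(priors, "hl_priors"))
  K <- data$K; J <- data$J
  X <- data$X; y <- data$y
  # W = [1 | group indicators | X]: one GEMV yields eta, one its adjoint
  Z <- matrix(0, data$N, J)
  Z[cbind(seq_len(data$N), data$group)] <- 1
  W <- cbind(1, Z, X)
  a2 <- priors$alpha_scale^2
  b2 <- priors$beta_scale^2
  s2 <- priors$sigma_scale^2

  if (hierarchical) {
    dim <- 1L + J + 1L + K
    param_names <- c("alpha0", paste0("mu_raw[", data$group_labels, "]"),
                     "log_sigma_mu", data$covariate_names)
    constrained_names <- c("alpha0", paste0("mu_raw[", data$group_labels, "]"),
                           "sigma_mu", data$covariate_names)
    i_mu <- seq_len(J) + 1L
    i_ls <- J + 2L
    i_beta <- J + 2L + seq_len(K)
    gn_beta <- J + 1L + seq_len(K)   # beta block inside W's adjoint
    # normalizing constants so lp() agrees with log_posterior() exactly
    lp_const <- -0.5 * log(2 * pi) * (1 + J + K) -
      log(priors$alpha_scale) - K * log(priors$beta_scale) +
      log(2) - log(pi * priors$sigma_scale)
    lp_grad <- function(theta) {
      alpha0 <- theta[1L]; mu_raw <- theta[i_mu]
      ls <- theta[i_ls]; beta <- theta[i_beta]
      sigma <- exp(ls)
      eta <- drop(W %*% c(alpha0, sigma * mu_raw, beta))
      p <- stats::plogis(eta)
      lp <- sum(y * eta - log1pexp(eta)) -
        0.5 * alpha0^2 / a2 - 0.5 * sum(mu_raw^2) -
        0.5 * sum(beta^2) / b2 - log1p(sigma^2 / s2) + ls + lp_const
      g_nat <- drop(crossprod(W, y - p))
      g <- numeric(dim)
      g[1L] <- g_nat[1L] - alpha0 / a2
      g[i_mu] <- sigma * g_nat[i_mu] - mu_raw
      g[i_ls] <- sigma * sum(mu_raw * g_nat[i_mu]) -
        2 * sigma^2 / (s2 + sigma^2) + 1
      g[i_beta] <- g_nat[gn_beta] - beta / b2
      list(lp = lp, grad = g)
    }
    constrain <- function(mat) {
      mat[, i_ls] <- exp(mat[, i_ls])
      colnames(mat) <- constrained_names
      mat
    }
    unpack <- function(theta) unpack_params(theta, J, K)
  } else {
    dim <- 1L + K
    param_names <- c("alpha0", data$covariate_names)
    constrained_names <- param_names
    i_beta <- 1L + seq_len(K)
    W0 <- cbind(1, X)
    lp_const <- -0.5 * log(2 * pi) * (1 + K) -
      log(priors$alpha_scale) - K * log(priors$beta_scale)
    lp_grad <- function(theta) {
      eta <- drop(W0 %*% theta)
      p <- stats::plogis(eta)
      lp <- sum(y * eta - log1pexp(eta)) + lp_const -
        0.5 * theta[1L]^2 / a2 - 0.5 * sum(theta[i_beta]^2) / b2
      g <- drop(crossprod(W0, y - p))
      g[1L] <- g[1L] - theta[1L] / a2
      g[i_beta] <- g[i_beta] - theta[i_beta] / b2
      list(lp = lp, grad = g)
    }
    constrain <- function(mat) { colnames(mat) <- constrained_names; mat }
    unpack <- function(theta)
      param_vector(alpha0 = theta[1L], beta = theta[i_beta])
  }

  structure(
    list(dim = dim, param_names = param_names,
         constrained_names = constrained_names,
         lp_grad = lp_grad, lp = function(theta) lp_grad(theta)$lp,
         constrain = constrain, unpack = unpack,
         data = data, priors = priors, hierarchical = hierarchical),
    class = "hl_model")
}
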