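#' Gelman-Rubin potential scale reduction factor
#'
#' Compares within-chain and between-chain variation for one parameter.
#' With `split = TRUE` (the default) each chain is halved first, which
#' also exposes within-chain trends; `split = FALSE` gives the original
#' two-chain formulation. Writing `W` for the mean within-chain
#' variance and `B` for `n` times the variance of the chain means, the
#' statistic is `sqrt(((n - 1) / n * W + B / n) / W)`.
#'
#' @param chains matrix with one row per chain, one column per draw, or
#'   a list of equal-length draw vectors.
#' @param split halve each chain first? Default `TRUE`.
#' @return the scale-reduction statistic (>= `sqrt((n - 1) / n)`).
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  m <- as_chain_matrix(chains)
  if (nrow(m) < 2L)
    stop("gelman_rubin: need at least 2 chains", call. = FALSE)
  if (ncol(m) < 4L)
    stop("gelman_rubin: need at least 4 draws per chain", call. = FALSE)
  if (split) {
    n2 <- ncol(m) %/% 2L
    m <- rbind(m[, seq_len(n2), drop = FALSE],
               m[, ncol(m) - n2 + seq_len(n2), drop = FALSE])
  }
  n <- ncol(m)
  within <- apply(m, 1, stats::var)
  W <- mean(within)
  if (W == 0)
    stop("gelman_rubin: zero within-chain variance (constant chains); ",
         "statistic undefined", call. = FALSE)
  B_over_n <- stats::var(rowMeans(m))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

as_chain_matrix <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L)
      stop("chains must have equal length", call. = FALSE)
    chains <- do.call(rbind, lapply(chains, as.numeric))
  }
  as.matrix(chains)
}

# spectral density at frequency zero via an AR fit (the classical
# estimator used for Geweke's diagnostic)
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE, order.max = min(length(x) - 1L,
                                                  floor(10 * log10(length(x)))))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of an early window of a single chain with
#' the mean of a late window, using spectral-density-at-zero variance
#' estimates so that autocorrelation is accounted for. Large |z|
#' indicates the chain had not reached its stationary distribution.
#'
#' @param x a single chain (numeric vector, >= 100 draws).
#' @param first_frac fraction of the chain in the early window
#'   (default 0.1).
#' @param last_frac fraction in the late window (default 0.5).
#' @return the z-score.
#' @export
geweke <- function(x, first_frac = 0.1, last_frac = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100L)
    stop("geweke: need at least 100 draws", call. = FALSE)
  if (first_frac + last_frac >= 1)
    stop("geweke: windows overlap (first_frac + last_frac must be < 1)",
         call. = FALSE)
  n1 <- max(2L, floor(first_frac * n))
  n2 <- max(2L, floor(last_frac * n))
  x1 <- x[seq_len(n1)]
  x2 <- x[(n - n2 + 1L):n]
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  denom <- sqrt(s1 / n1 + s2 / n2)
  if (denom == 0) {
    if (mean(x1) == mean(x2)) return(0)
    stop("geweke: zero spectral variance with unequal window means",
         call. = FALSE)
  }
  (mean(x1) - mean(x2)) / denom
}

#' Effective sample size
#'
#' Autocorrelation-sum estimator pooled across chains, truncated at the
#' first negative pair of successive autocorrelations (Geyer's initial
#' positive sequence rule). Between-chain variance enters through the
#' pooled variance estimate, so unmixed chains are penalized.
#'
#' @param chains matrix with one row per chain (or list of chains, or a
#'   single numeric vector).
#' @return estimated number of effectively independent draws.
#' @export
effective_sample_size <- function(chains) {
  if (is.numeric(chains) && is.null(dim(chains)))
    chains <- matrix(chains, nrow = 1)
  m <- as_chain_matrix(chains)
  n_chain <- nrow(m); n <- ncol(m)
  if (n < 4L)
    stop("effective_sample_size: need at least 4 draws", call. = FALSE)
  within <- apply(m, 1, stats::var)
  W <- mean(within)
  if (W == 0)
    stop("effective_sample_size: constant chain; undefined", call. = FALSE)
  var_plus <- (n - 1) / n * W
  if (n_chain > 1L) var_plus <- var_plus + stats::var(rowMeans(m))

  # mean autocovariance across chains at each lag
  max_lag <- n - 1L
  acov <- rowMeans(vapply(seq_len(n_chain), function(c) {
    a <- stats::acf(m[c, ], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)
    drop(a$acf)
  }, numeric(max_lag + 1L)))
  rho <- 1 - (W - acov[-1L]) / var_plus

  # pairwise-positive truncation
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  ess <- n_chain * n / tau
  min(ess, 1.5 * n_chain * n)   # cap super-efficiency claims
}

#' Convergence report for a posterior sample
#'
#' Evaluates the split Gelman-Rubin statistic for every parameter and
#' gates the fit on all of them falling below `threshold` (1.10 is the
#' conventional cut-off used here). Geweke z-scores (first chain) and
#' effective sample sizes are attached for reference but do not affect
#' the gate.
#'
#' @param draws an `hl_draws`.
#' @param threshold Gelman-Rubin gate (default 1.10).
#' @param split use split chains (default `TRUE`).
#' @return An object of class `hl_convergence`: a data frame
#'   (`parameter`, `rhat`, `geweke_z`, `ess`) plus attributes `pass`,
#'   `threshold`, `max_rhat`.
#' @export
check_convergence <- function(draws, threshold = 1.10, split = TRUE) {
  stopifnot(inherits(draws, "hl_draws"))
  pars <- draws$parameter_names
  rows <- lapply(seq_along(pars), function(j) {
    ch <- t(vapply(draws$constrained, function(m) m[, j],
                   numeric(draws$n_kept)))
    gz <- tryCatch(geweke(ch[1L, ]), error = function(e) NA_real_)
    data.frame(parameter = pars[j],
               rhat = gelman_rubin(ch, split = split),
               geweke_z = gz,
               ess = effective_sample_size(ch))
  })
  report <- do.call(rbind, rows)
  structure(report,
            class = c("hl_convergence", "data.frame"),
            pass = all(report$rhat < threshold),
            threshold = threshold,
            max_rhat = max(report$rhat))
}

#' @export
print.hl_convergence <- function(x, ...) {
  pass <- attr(x, "pass")
  cat(sprintf("Convergence gate (split R-hat < %.3g): %s (max R-hat %.4f)\n",
              attr(x, "threshold"), if (pass) "PASS" else "FAIL",
              attr(x, "max_rhat")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a convergence report to CSV
#'
#' @param report an `hl_convergence`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_convergence_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Prior-informativeness check
#'
#' For the global intercept and every slope, the ratio of the posterior
#' standard deviation to the prior standard deviation. The weak-prior
#' rule adopted from the study protocol requires every ratio to be
#' below 10%: priors should contribute little information relative to
#' the data.
#'
#' @param draws an `hl_draws` from a model fit.
#' @param priors the `hl_priors` used in the fit.
#' @param cutoff pass cut-off on the ratio scale (default 0.10).
#' @return data frame (`parameter`, `posterior_sd`, `prior_sd`,
#'   `ratio`) with attribute `pass`.
#' @export
prior_informativeness_check <- function(draws, priors, cutoff = 0.10) {
  stopifnot(inherits(draws, "hl_draws"), inherits(priors, "hl_priors"))
  pooled <- as.matrix(draws)
  pars <- draws$parameter_names
  coef_idx <- which(!grepl("^mu_raw\\[", pars) & pars != "sigma_mu")
  prior_sd <- ifelse(pars[coef_idx] == "alpha0",
                     priors$alpha_scale, priors$beta_scale)
  post_sd <- apply(pooled[, coef_idx, drop = FALSE], 2, stats::sd)
  out <- data.frame(parameter = pars[coef_idx],
                    posterior_sd = post_sd,
                    prior_sd = prior_sd,
                    ratio = post_sd / prior_sd,
                    row.names = NULL)
  attr(out, "pass") <- all(out$ratio < cutoff)
  attr(out, "cutoff") <- cutoff
  out
}
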