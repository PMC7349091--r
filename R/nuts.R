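#' Sampler configuration
#'
#' Defaults follow the study protocol: two chains of 4000 transitions
#' each, the first 2500 discarded as warmup (which doubles as the
#' adaptation phase for the step size and the diagonal mass matrix).
#'
#' @param n_chains number of chains (at least 2; the Gelman-Rubin
#'   diagnostic needs them).
#' @param n_iterations total transitions per chain, warmup included.
#' @param n_warmup warmup transitions discarded and used for adaptation.
#' @param target_accept dual-averaging acceptance target in (0, 1).
#'   The 0.9 default keeps divergent transitions rare on hierarchical
#'   posteriors with few groups; lower values buy speed on easy targets.
#' @param max_tree_depth cap on trajectory doublings.
#' @param seed integer seed; per-chain seeds are derived from it
#'   deterministically.
#' @param init_jitter chains start at independent
#'   uniform(-init_jitter, init_jitter) unconstrained values.
#' @return An object of class `hl_sampler_config`.
#' @export
sampler_config <- function(n_chains = 2L, n_iterations = 4000L,
                           n_warmup = 2500L, target_accept = 0.9,
                           max_tree_depth = 10L, seed = 1L,
                           init_jitter = 1) {
  n_chains <- as.integer(n_chains)
  n_iterations <- as.integer(n_iterations)
  n_warmup <- as.integer(n_warmup)
  if (n_chains < 2L)
    stop("sampler_config: need at least 2 chains", call. = FALSE)
  if (!(n_warmup > 0L && n_warmup < n_iterations))
    stop("sampler_config: need 0 < n_warmup < n_iterations", call. = FALSE)
  if (!(target_accept > 0 && target_accept < 1))
    stop("sampler_config: target_accept must lie in (0, 1)", call. = FALSE)
  if (max_tree_depth < 1L)
    stop("sampler_config: max_tree_depth must be positive", call. = FALSE)
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 n_warmup = n_warmup, target_accept = target_accept,
                 max_tree_depth = as.integer(max_tree_depth),
                 seed = as.integer(seed), init_jitter = init_jitter),
            class = "hl_sampler_config")
}

#' One leapfrog step
#'
#' Standard half-kick / drift / half-kick update of Hamiltonian
#' dynamics for the potential `-lp(theta)` with diagonal mass matrix
#' `1 / inv_mass`. Reversible and volume-preserving; a non-finite
#' position, momentum or gradient after the step marks the transition
#' divergent rather than raising an error.
#'
#' @param position current unconstrained position.
#' @param momentum current momentum.
#' @param step_size leapfrog step size (non-zero; negative integrates
#'   the trajectory backward in time).
#' @param lp_grad_fn function `theta -> list(lp, grad)`.
#' @param inv_mass diagonal of the inverse mass matrix (defaults to 1).
#' @param grad optional gradient at `position`, to avoid recomputation.
#' @return list with `position`, `momentum`, `lp`, `grad`, `divergent`.
#' @export
leapfrog <- function(position, momentum, step_size, lp_grad_fn,
                     inv_mass = rep(1, length(position)), grad = NULL) {
  if (!is.finite(step_size) || step_size == 0)
    stop("leapfrog: step_size must be non-zero and finite", call. = FALSE)
  if (is.null(grad)) grad <- lp_grad_fn(position)$grad
  momentum <- momentum + 0.5 * step_size * grad
  position <- position + step_size * inv_mass * momentum
  if (all(is.finite(position))) {
    lg <- lp_grad_fn(position)
    if (all(is.finite(lg$grad)) && is.finite(lg$lp)) {
      momentum <- momentum + 0.5 * step_size * lg$grad
      return(list(position = position, momentum = momentum,
                  lp = lg$lp, grad = lg$grad, divergent = FALSE))
    }
  }
  list(position = position, momentum = momentum,
       lp = -Inf, grad = grad, divergent = TRUE)
}

# log joint density of (theta, p): lp - kinetic energy
joint_lp <- function(lp, momentum, inv_mass) {
  lp - 0.5 * sum(momentum^2 * inv_mass)
}

# energy error beyond this is a divergence (standard choice)
DIVERGENCE_ENERGY <- 1000

# U-turn criterion on velocities (mass-adjusted momenta)
no_uturn <- function(theta_minus, theta_plus, p_minus, p_plus, inv_mass) {
  d <- theta_plus - theta_minus
  sum(d * (inv_mass * p_minus)) >= 0 && sum(d * (inv_mass * p_plus)) >= 0
}

# Recursive tree doubling of the slice-sampling NUTS formulation.
# Returns the subtree's endpoints, a candidate drawn uniformly among
# valid leaves, the leaf count, the stop flag and acceptance statistics.
build_tree <- function(st, log_u, dir, depth, step_size, inv_mass,
                       lp_grad_fn, joint0) {
  if (depth == 0L) {
    lf <- leapfrog(st$theta, st$p, dir * step_size, lp_grad_fn,
                   inv_mass, grad = st$grad)
    j <- joint_lp(lf$lp, lf$momentum, inv_mass)
    divergent <- lf$divergent || (log_u - j > DIVERGENCE_ENERGY)
    n_valid <- if (!divergent && log_u <= j) 1L else 0L
    leaf <- list(theta = lf$position, p = lf$momentum,
                 lp = lf$lp, grad = lf$grad)
    return(list(minus = leaf, plus = leaf, proposal = leaf,
                n_valid = n_valid, stop = divergent,
                divergent = divergent,
                alpha = min(1, exp(j - joint0)), n_alpha = 1L))
  }
  t1 <- build_tree(st, log_u, dir, depth - 1L, step_size, inv_mass,
                   lp_grad_fn, joint0)
  if (t1$stop) return(t1)
  inner <- if (dir == -1) t1$minus else t1$plus
  t2 <- build_tree(inner, log_u, dir, depth - 1L, step_size, inv_mass,
                   lp_grad_fn, joint0)
  minus <- if (dir == -1) t2$minus else t1$minus
  plus  <- if (dir == -1) t1$plus else t2$plus
  n_tot <- t1$n_valid + t2$n_valid
  proposal <- t1$proposal
  if (n_tot > 0L && stats::runif(1) < t2$n_valid / n_tot)
    proposal <- t2$proposal
  stop_flag <- t2$stop ||
    !no_uturn(minus$theta, plus$theta, minus$p, plus$p, inv_mass)
  list(minus = minus, plus = plus, proposal = proposal,
       n_valid = n_tot, stop = stop_flag,
       divergent = t1$divergent || t2$divergent,
       alpha = t1$alpha + t2$alpha, n_alpha = t1$n_alpha + t2$n_alpha)
}

#' One No-U-Turn transition
#'
#' Grows a leapfrog trajectory by repeated doubling until either end
#' starts to turn back (momentum/position-difference dot products at
#' both trajectory ends), a divergence occurs, or `max_tree_depth` is
#' reached; the next state is drawn from the slice-valid leaves.
#'
#' @param state list with `theta`, `lp`, `grad` (current position).
#' @param step_size leapfrog step size.
#' @param inv_mass diagonal inverse mass.
#' @param lp_grad_fn function `theta -> list(lp, grad)`.
#' @param max_tree_depth doubling cap.
#' @return list with the next `state` and transition statistics
#'   (`accept_stat`, `divergent`, `depth`, `saturated`).
#' @export
nuts_step <- function(state, step_size, inv_mass, lp_grad_fn,
                      max_tree_depth = 10L) {
  D <- length(state$theta)
  p0 <- stats::rnorm(D) / sqrt(inv_mass)
  joint0 <- joint_lp(state$lp, p0, inv_mass)
  log_u <- joint0 + log(stats::runif(1))   # slice variable

  node <- list(theta = state$theta, p = p0, lp = state$lp, grad = state$grad)
  minus <- node; plus <- node
  sample <- node
  n_valid <- 1L
  depth <- 0L
  divergent <- FALSE
  alpha_sum <- 0; n_alpha <- 0L

  repeat {
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    st <- if (dir == -1) minus else plus
    tree <- build_tree(st, log_u, dir, depth, step_size, inv_mass,
                       lp_grad_fn, joint0)
    if (dir == -1) minus <- tree$minus else plus <- tree$plus
    divergent <- divergent || tree$divergent
    alpha_sum <- alpha_sum + tree$alpha
    n_alpha <- n_alpha + tree$n_alpha
    if (!tree$stop && tree$n_valid > 0L &&
        stats::runif(1) < tree$n_valid / n_valid)
      sample <- tree$proposal
    n_valid <- n_valid + tree$n_valid
    depth <- depth + 1L
    if (tree$stop ||
        !no_uturn(minus$theta, plus$theta, minus$p, plus$p, inv_mass) ||
        depth >= max_tree_depth)
      break
  }

  list(state = list(theta = sample$theta, lp = sample$lp, grad = sample$grad),
       accept_stat = alpha_sum / max(1L, n_alpha),
       divergent = divergent, depth = depth,
       saturated = depth >= max_tree_depth)
}

# Coarse initial step size: double/halve until the one-step acceptance
# probability crosses 1/2 (Hoffman & Gelman's heuristic).
find_initial_step <- function(state, inv_mass, lp_grad_fn) {
  eps <- 0.1
  D <- length(state$theta)
  p0 <- stats::rnorm(D) / sqrt(inv_mass)
  j0 <- joint_lp(state$lp, p0, inv_mass)
  one_step <- function(eps) {
    lf <- leapfrog(state$theta, p0, eps, lp_grad_fn, inv_mass,
                   grad = state$grad)
    if (lf$divergent) return(-Inf)
    joint_lp(lf$lp, lf$momentum, inv_mass) - j0
  }
  delta <- one_step(eps)
  dir <- if (is.finite(delta) && delta > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^dir
    delta <- one_step(eps)
    if (dir == 1 && !(is.finite(delta) && delta > log(0.5))) break
    if (dir == -1 && (is.finite(delta) && delta > log(0.5))) break
  }
  eps
}

# Dual-averaging step-size adaptation state (Nesterov-style averaging).
da_init <- function(eps0, target) {
  list(mu = log(10 * eps0), log_eps = log(eps0), log_eps_bar = 0,
       h_bar = 0, counter = 0L, target = target,
       gamma = 0.05, t0 = 10, kappa = 0.75)
}

da_update <- function(da, accept_stat) {
  da$counter <- da$counter + 1L
  m <- da$counter
  eta <- 1 / (m + da$t0)
  da$h_bar <- (1 - eta) * da$h_bar + eta * (da$target - accept_stat)
  da$log_eps <- da$mu - sqrt(m) / da$gamma * da$h_bar
  w <- m^(-da$kappa)
  da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
  da
}

run_one_chain <- function(model, config, chain_seed) {
  set.seed(chain_seed)
  D <- model$dim
  lp_grad_fn <- model$lp_grad
  theta <- stats::runif(D, -config$init_jitter, config$init_jitter)
  lg <- lp_grad_fn(theta)
  if (!is.finite(lg$lp))
    stop("run_chains: non-finite log posterior at the initial point",
         call. = FALSE)
  state <- list(theta = theta, lp = lg$lp, grad = lg$grad)

  inv_mass <- rep(1, D)
  eps <- find_initial_step(state, inv_mass, lp_grad_fn)
  da <- da_init(eps, config$target_accept)

  n_warm <- config$n_warmup
  n_keep <- config$n_iterations - n_warm
  # mass window: draws in (50%, 75%] of warmup feed the variance
  # estimate; the step size then re-adapts to the new metric
  w_lo <- floor(0.5 * n_warm); w_hi <- floor(0.75 * n_warm)
  collect_mass <- n_warm >= 80L   # skip mass adaptation on tiny runs
  mass_buf <- if (collect_mass) matrix(0, w_hi - w_lo, D) else NULL

  draws <- matrix(0, n_keep, D)
  divergences <- 0L
  saturations <- 0L
  accept_sum <- 0

  for (it in seq_len(config$n_iterations)) {
    step <- nuts_step(state, exp(da$log_eps), inv_mass, lp_grad_fn,
                      config$max_tree_depth)
    state <- step$state
    if (it <= n_warm) {
      da <- da_update(da, step$accept_stat)
      if (exp(da$log_eps) < 1e-10)
        stop("run_chains: step size collapsed below 1e-10; ",
             "parameter scales are likely degenerate", call. = FALSE)
      if (collect_mass && it > w_lo && it <= w_hi)
        mass_buf[it - w_lo, ] <- state$theta
      if (collect_mass && it == w_hi) {
        v <- apply(mass_buf, 2, stats::var)
        # guard against zero-variance coordinates, regularize slightly
        v <- pmax(v, 1e-8)
        n_est <- nrow(mass_buf)
        inv_mass <- v * n_est / (n_est + 5) + 1e-3 * 5 / (n_est + 5)
        # re-open dual averaging around the current step size
        da <- da_init(exp(da$log_eps), config$target_accept)
      }
      if (it == n_warm) {
        eps_final <- exp(da$log_eps_bar)
        if (eps_final < 1e-10)
          stop("run_chains: adapted step size collapsed below 1e-10",
               call. = FALSE)
        da$log_eps <- log(eps_final)   # freeze
      }
    } else {
      draws[it - n_warm, ] <- state$theta
      divergences <- divergences + step$divergent
      saturations <- saturations + step$saturated
      accept_sum <- accept_sum + step$accept_stat
    }
  }

  list(draws = draws, divergences = divergences,
       saturations = saturations, step_size = exp(da$log_eps),
       inv_mass = inv_mass, mean_accept = accept_sum / n_keep)
}

#' Run NUTS chains on a model
#'
#' Runs `config$n_chains` independent chains, each seeded
#' deterministically from `config$seed`, with step-size and diagonal
#' mass adaptation during warmup. The same configuration and seed
#' reproduce the draws bit for bit. A run in which any chain records
#' more than 10% divergent transitions after warmup is marked failed
#' (`failed = TRUE`) with the per-chain counts attached.
#'
#' @param model an `hl_model` (or any list exposing `dim`,
#'   `param_names`, `constrained_names`, `lp_grad`, `constrain`).
#' @param config an `hl_sampler_config`.
#' @return An object of class `hl_draws`: per-chain matrices of kept
#'   unconstrained draws, the constrained view (`sigma_mu`
#'   exponentiated), parameter names, divergence / tree-depth
#'   saturation counts, adapted step sizes and mass diagonals.
#' @export
run_chains <- function(model, config = sampler_config()) {
  stopifnot(inherits(config, "hl_sampler_config"))
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- lapply(seq_len(config$n_chains), function(c)
    run_one_chain(model, config, chain_seeds[c]))

  n_keep <- config$n_iterations - config$n_warmup
  divergences <- vapply(chains, `[[`, integer(1), "divergences")
  failed <- any(divergences > 0.1 * n_keep)

  draws <- lapply(chains, function(ch) {
    m <- ch$draws
    colnames(m) <- model$param_names
    m
  })
  constrained <- lapply(chains, function(ch) model$constrain(ch$draws))

  structure(
    list(draws = draws, constrained = constrained,
         parameter_names = model$constrained_names,
         unconstrained_names = model$param_names,
         n_chains = config$n_chains, n_kept = n_keep,
         divergence_count = divergences,
         tree_depth_saturation = vapply(chains, `[[`, integer(1),
                                        "saturations"),
         step_size = vapply(chains, `[[`, numeric(1), "step_size"),
         inv_mass = lapply(chains, `[[`, "inv_mass"),
         mean_accept = vapply(chains, `[[`, numeric(1), "mean_accept"),
         chain_seeds = chain_seeds, config = config, failed = failed),
    class = "hl_draws")
}

#' @export
print.hl_draws <- function(x, ...) {
  cat("<hl_draws> ", x$n_chains, " chains x ", x$n_kept, " kept draws, ",
      length(x$parameter_names), " parameters\n",
      "divergences per chain: ", paste(x$divergence_count, collapse = ", "),
      "; mean acceptance: ",
      paste(signif(x$mean_accept, 3), collapse = ", "), "\n", sep = "")
  if (x$failed)
    cat("RUN MARKED FAILED: > 10% divergent transitions in some chain\n")
  invisible(x)
}

#' Pooled constrained draws as one matrix
#'
#' @param x an `hl_draws`.
#' @param ... unused.
#' @return matrix of `n_chains * n_kept` rows, one column per parameter
#'   on the constrained (reporting) scale.
#' @export
as.matrix.hl_draws <- function(x, ...) {
  do.call(rbind, x$constrained)
}

#' Per-chain draws of a single parameter
#'
#' @param draws an `hl_draws`.
#' @param parameter parameter name (constrained naming).
#' @return matrix with one row per chain, one column per kept draw.
#' @export
extract_parameter <- function(draws, parameter) {
  idx <- match(parameter, draws$parameter_names)
  if (is.na(idx))
    stop("extract_parameter: unknown parameter '", parameter, "'",
         call. = FALSE)
  t(vapply(draws$constrained, function(m) m[, idx], numeric(draws$n_kept)))
}

#' Export draws in long format
#'
#' Writes `(chain, iteration, parameter, value)` rows (constrained
#' scale) for external trace plotting and diagnostics.
#'
#' @param draws an `hl_draws`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_draws_csv <- function(draws, path) {
  P <- length(draws$parameter_names)
  out <- do.call(rbind, lapply(seq_len(draws$n_chains), function(c) {
    m <- draws$constrained[[c]]
    data.frame(chain = c,
               iteration = rep(seq_len(draws$n_kept), times = P),
               parameter = rep(draws$parameter_names, each = draws$n_kept),
               value = as.vector(m))
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
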