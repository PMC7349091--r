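#' Covariate specification for the survey generator
#'
#' @param name column name.
#' @param kind `"binary"`, `"ordinal"` (integer codes `0..support_max`,
#'   drawn binomially to match the target mean) or
#'   `"categorical-level"` (a one-hot level of a mutually exclusive
#'   set named in `set`; the reference level is never generated as a
#'   column).
#' @param target_mean marginal mean to match (binary/level: a
#'   proportion; ordinal: mean of the integer codes).
#' @param support_max largest code for ordinal covariates (default 6).
#' @param set set name for `"categorical-level"` covariates.
#' @param true_or generating odds ratio attached to this covariate
#'   (used for default effect sizes in simulations).
#' @return one-row data frame.
#' @export
covariate_spec <- function(name, kind = c("binary", "ordinal",
                                          "categorical-level"),
                           target_mean, support_max = 6L, set = NA_character_,
                           true_or = 1) {
  kind <- match.arg(kind)
  if (kind %in% c("binary", "categorical-level")) {
    if (!(target_mean > 1e-6 && target_mean < 1 - 1e-6))
      stop("covariate_spec: proportion target_mean for '", name,
           "' must lie strictly inside (0, 1)", call. = FALSE)
  } else {
    if (!(target_mean > 1e-6 && target_mean < support_max - 1e-6))
      stop("covariate_spec: ordinal target_mean for '", name,
           "' must lie inside (0, support_max)", call. = FALSE)
  }
  data.frame(name = name, kind = kind, target_mean = target_mean,
             support_max = as.integer(support_max), set = set,
             true_or = true_or, stringsAsFactors = FALSE)
}

#' Default covariate catalogue of the youth tobacco survey
#'
#' The explanatory variables of the school-based youth tobacco survey
#' analysis, with their published marginal means and the published
#' odds ratios as default generating effect sizes. Mutually exclusive
#' sets (age groups, parental smoking, usual cigarette brand) are
#' marked so the generator draws them as single categoricals; the
#' reference levels (age group one, neither parent smokes, no usual
#' brand) are absorbed into the intercept and carry no column.
#'
#' @return data frame of covariate specifications (one row each).
#' @export
gyts_covariates <- function() {
  s <- function(...) covariate_spec(...)
  rbind(
    s("gender",                   "binary", 0.492, true_or = 1.428),
    s("age_group_two",    "categorical-level", 0.577, set = "age",
      true_or = 1.347),
    s("age_group_three",  "categorical-level", 0.375, set = "age",
      true_or = 1.333),
    s("cigarettes_per_day",       "ordinal", 1.792, true_or = 1.050),
    s("smokeless_tobacco_30d",    "binary", 0.245, true_or = 2.035),
    s("smoking_past_5yr",         "binary", 0.230, true_or = 1.387),
    s("difficult_to_quit",        "binary", 0.528, true_or = 2.262),
    s("smoking_harmful",          "binary", 0.441, true_or = 1.211),
    s("gained_weight",            "binary", 0.209, true_or = 1.890),
    s("lost_weight",              "binary", 0.444, true_or = 2.371),
    s("ask_permission_to_smoke",  "binary", 0.358, true_or = 0.779),
    s("safe_for_1_2_years",       "binary", 0.291, true_or = 1.294),
    s("times_smoked_inhouse",     "ordinal", 2.261, true_or = 1.125),
    s("times_smoked_enclosed",    "ordinal", 2.319, true_or = 1.163),
    s("times_smoked_outdoor",     "ordinal", 2.248, true_or = 0.994),
    s("favors_public_ban",        "binary", 0.359, true_or = 2.633),
    s("advised_to_stop",          "binary", 0.809, true_or = 2.884),
    s("owns_brand_logo",          "binary", 0.313, true_or = 1.471),
    s("attends_ad_events",        "binary", 0.530, true_or = 1.889),
    s("offered_free_cigarettes",  "binary", 0.267, true_or = 1.031),
    s("taught_dangers",           "binary", 0.436, true_or = 1.444),
    s("cigarettes_in_life",       "ordinal", 2.289, true_or = 0.901),
    s("sold_near_home",           "binary", 0.405, true_or = 0.679),
    s("youth_groups_discourage",  "binary", 0.356, true_or = 1.209),
    s("health_workers_explained", "binary", 0.452, true_or = 1.591),
    s("religious_discourage",     "binary", 0.413, true_or = 0.906),
    s("not_tried_to_stop",        "binary", 0.111, true_or = 0.733),
    s("tried_stop_health",        "binary", 0.227, true_or = 2.661),
    s("tried_stop_money",         "binary", 0.059, true_or = 1.812),
    s("tried_stop_family",        "binary", 0.209, true_or = 2.013),
    s("friends_smoke",            "binary", 0.603, true_or = 0.839),
    s("both_parents_smoke", "categorical-level", 0.069, set = "parents",
      true_or = 0.984),
    s("father_smokes",      "categorical-level", 0.213, set = "parents",
      true_or = 1.324),
    s("mother_smokes",      "categorical-level", 0.047, set = "parents",
      true_or = 0.348),
    s("brand_peter_stuyvesant", "categorical-level", 0.077, set = "brand",
      true_or = 0.429),
    s("brand_rothman",          "categorical-level", 0.045, set = "brand",
      true_or = 1.407),
    s("brand_consulate",        "categorical-level", 0.059, set = "brand",
      true_or = 1.001),
    s("brand_safari",           "categorical-level", 0.006, set = "brand",
      true_or = 1.381),
    s("brand_own_burns",        "categorical-level", 0.034, set = "brand",
      true_or = 3.486)
  )
}

#' Generator configuration
#'
#' Defaults emulate the published survey sample: 640 respondents,
#' grade shares (0.398, 0.325, 0.277), the full covariate catalogue
#' at its published marginal means, the published odds ratios (logged)
#' as generating slopes, a between-grade intercept scale of 0.3, and
#' an intercept auto-calibrated so the simulated outcome prevalence
#' matches the published 63.3%.
#'
#' @param N number of rows (default 640).
#' @param grade_probs multinomial grade shares, must sum to 1.
#' @param covariates covariate specification data frame
#'   (see [gyts_covariates()]).
#' @param true_beta generating slopes; default `log(covariates$true_or)`.
#' @param sigma_mu between-grade intercept SD (default 0.3).
#' @param alpha0 generating intercept, or `"auto"` to calibrate
#'   against `target_prevalence`.
#' @param target_prevalence outcome prevalence used when
#'   `alpha0 = "auto"` (default 0.633).
#' @param seed integer seed.
#' @return An object of class `hl_generator_config`.
#' @export
generator_config <- function(N = 640L,
                             grade_probs = c(0.398, 0.325, 0.277),
                             covariates = gyts_covariates(),
                             true_beta = log(covariates$true_or),
                             sigma_mu = 0.3,
                             alpha0 = "auto",
                             target_prevalence = 0.633,
                             seed = 1L) {
  N <- as.integer(N)
  if (N < 10L) stop("generator_config: N must be at least 10", call. = FALSE)
  if (abs(sum(grade_probs) - 1) > 1e-12)
    stop("generator_config: grade_probs must sum to 1", call. = FALSE)
  if (any(grade_probs <= 0))
    stop("generator_config: grade_probs must be positive", call. = FALSE)
  if (length(true_beta) != nrow(covariates))
    stop("generator_config: true_beta length must match the covariate list",
         call. = FALSE)
  if (sigma_mu < 0)
    stop("generator_config: sigma_mu must be non-negative", call. = FALSE)
  if (!identical(alpha0, "auto") && !is.finite(alpha0))
    stop("generator_config: alpha0 must be finite or \"auto\"", call. = FALSE)
  if (!(target_prevalence > 0 && target_prevalence < 1))
    stop("generator_config: target_prevalence must lie in (0, 1)",
         call. = FALSE)
  structure(list(N = N, grade_probs = grade_probs, covariates = covariates,
                 true_beta = true_beta, sigma_mu = sigma_mu, alpha0 = alpha0,
                 target_prevalence = target_prevalence,
                 seed = as.integer(seed)),
            class = "hl_generator_config")
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Draw the covariate matrix and grade vector
#'
#' Binary columns are independent Bernoulli draws at their target
#' means; ordinal columns are binomial on `0..support_max` scaled to
#' the target mean; each mutually exclusive set is drawn as a single
#' categorical (any unassigned probability mass goes to the reference
#' level) and one-hot encoded with the reference level dropped; grades
#' are multinomial at `grade_probs`.
#'
#' @param config an `hl_generator_config`.
#' @param n number of rows (default `config$N`).
#' @return list with `X` (matrix, columns in catalogue order) and
#'   `grade` (integer vector in `1..length(grade_probs)`).
#' @export
generate_covariates <- function(config, n = config$N) {
  spec <- config$covariates
  X <- matrix(0, n, nrow(spec), dimnames = list(NULL, spec$name))
  singles <- which(spec$kind != "categorical-level")
  for (j in singles) {
    if (spec$kind[j] == "binary") {
      X[, j] <- stats::rbinom(n, 1L, spec$target_mean[j])
    } else {
      X[, j] <- stats::rbinom(n, spec$support_max[j],
                              spec$target_mean[j] / spec$support_max[j])
    }
  }
  for (set_name in unique(stats::na.omit(spec$set))) {
    idx <- which(!is.na(spec$set) & spec$set == set_name)
    p <- spec$target_mean[idx]
    if (sum(p) > 1 + 1e-9)
      stop("generate_covariates: set '", set_name,
           "' has level probabilities summing above 1", call. = FALSE)
    # level 0 = reference (absorbs any unassigned mass)
    lev <- sample.int(length(idx) + 1L, n, replace = TRUE,
                      prob = c(max(0, 1 - sum(p)), p)) - 1L
    for (k in seq_along(idx)) X[, idx[k]] <- as.numeric(lev == k)
  }
  grade <- sample.int(length(config$grade_probs), n, replace = TRUE,
                      prob = config$grade_probs)
  list(X = X, grade = grade)
}

#' Calibrate the generating intercept to a target prevalence
#'
#' Bisection over `alpha0` in [-30, 30] on a fixed Monte Carlo draw of
#' `M` covariate rows (seed-derived, so the result is deterministic
#' given the config seed). The objective is the mean outcome
#' probability, so no outcome noise enters the calibration. Group
#' intercept deviations are either supplied (`mu_dev`, the realized
#' deviations of a dataset being generated, giving a calibration
#' conditional on them) or integrated out by drawing a fresh
#' `N(0, sigma_mu)` deviation per Monte Carlo row.
#'
#' @param config an `hl_generator_config`.
#' @param mu_dev optional vector of realized group intercept
#'   deviations (length = number of grades).
#' @param M Monte Carlo rows (default 1e5).
#' @param tol tolerance on the achieved prevalence (default 0.002).
#' @return the calibrated `alpha0`.
#' @export
calibrate_intercept <- function(config, mu_dev = NULL, M = 1e5, tol = 0.002) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(derive_seed(config$seed, 500009))
  cov <- generate_covariates(config, n = as.integer(M))
  xb <- drop(cov$X %*% config$true_beta)
  base <- if (is.null(mu_dev)) {
    xb + stats::rnorm(as.integer(M), 0, config$sigma_mu)
  } else {
    xb + mu_dev[cov$grade]
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  prev <- function(a) mean(stats::plogis(a + base))
  lo <- -30; hi <- 30
  target <- config$target_prevalence
  if (prev(lo) > target || prev(hi) < target)
    stop("calibrate_intercept: target prevalence ", target,
         " unreachable for alpha0 in [-30, 30]; the generating effect ",
         "sizes push the outcome too far", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    p <- prev(mid)
    if (abs(p - target) < tol / 4) break
    if (p < target) lo <- mid else hi <- mid
  }
  mid
}

#' Generate a survey dataset from the varying-intercept logit model
#'
#' Draws grade intercept deviations `Normal(0, sigma_mu^2)`, covariates
#' per the catalogue, calibrates the intercept if requested
#' (conditioning on the realized grade deviations, so the simulated
#' prevalence tracks the target tightly), and draws Bernoulli outcomes
#' at the inverse-logit of the linear predictor. Fully deterministic
#' given `config$seed`.
#'
#' @param config an `hl_generator_config`.
#' @return list with `data` (an `hl_dataset`), `truth` (generating
#'   parameters: `alpha0`, `mu_raw`, `mu_dev`, `sigma_mu`, `beta`) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "hl_generator_config"))
  J <- length(config$grade_probs)

  set.seed(derive_seed(config$seed, 0))
  cov <- generate_covariates(config)
  mu_raw <- stats::rnorm(J)
  mu_dev <- config$sigma_mu * mu_raw

  alpha0 <- if (identical(config$alpha0, "auto")) {
    calibrate_intercept(config, mu_dev = mu_dev)
  } else config$alpha0

  set.seed(derive_seed(config$seed, 900007))
  eta <- alpha0 + mu_dev[cov$grade] + drop(cov$X %*% config$true_beta)
  y <- stats::rbinom(config$N, 1L, stats::plogis(eta))

  data <- hl_dataset(y = y, X = cov$X, group = cov$grade,
                     covariate_names = config$covariates$name,
                     group_labels = paste0("grade", 6L + seq_len(J)))
  truth <- list(alpha0 = alpha0, mu_raw = mu_raw, mu_dev = mu_dev,
                sigma_mu = config$sigma_mu, beta = config$true_beta)
  list(data = data, truth = truth, config = config)
}

#' Write the generating parameters next to a dataset
#'
#' Sidecar CSV with columns `parameter`, `true_value`.
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param covariate_names slope labels.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, covariate_names, path) {
  df <- data.frame(
    parameter = c("alpha0", paste0("mu_dev[", seq_along(truth$mu_dev), "]"),
                  "sigma_mu", covariate_names),
    true_value = c(truth$alpha0, truth$mu_dev, truth$sigma_mu, truth$beta))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
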