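#' Coefficient-scale posterior summaries
#'
#' Pools the kept draws of all chains and reports, per parameter on the
#' constrained scale, the posterior mean, standard deviation and the
#' equal-tailed interval bounds. Quantiles use linear interpolation
#' between order statistics (R's default type 7 convention).
#'
#' @param draws an `hl_draws`.
#' @param level credible level (default 0.95).
#' @return data frame (`parameter`, `mean`, `sd`, `ci_low`, `ci_high`).
#' @export
summarize_coefficients <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "hl_draws"))
  pooled <- as.matrix(draws)
  if (nrow(pooled) == 0L)
    stop("summarize_coefficients: no draws", call. = FALSE)
  if (!(level > 0 && level < 1))
    stop("summarize_coefficients: level must lie in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  q <- apply(pooled, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(parameter = draws$parameter_names,
             mean = colMeans(pooled),
             sd = apply(pooled, 2, stats::sd),
             ci_low = q[1L, ],
             ci_high = q[2L, ],
             row.names = NULL)
}

#' Odds-ratio summary table
#'
#' One row per slope coefficient, on the reporting surface used for the
#' survey analysis: the odds ratio as the exponentiated posterior mean
#' (`exp(E[beta])`; set `point = "mean_exp"` for `E[exp(beta)]`
#' instead), the SD of the exponentiated draws, equal-tailed credible
#' bounds obtained by exponentiating the coefficient-scale quantiles
#' (identical to quantiles of the exponentiated draws, by
#' monotonicity), the percentage effect `(OR - 1) * 100`, and a
#' significance flag set when the interval excludes 1.
#'
#' @param draws an `hl_draws` from a fitted model.
#' @param level credible level (default 0.95).
#' @param point `"exp_mean"` (default) or `"mean_exp"`.
#' @return data frame of class `hl_or_table` with columns `parameter`,
#'   `odds_ratio`, `or_sd`, `ci_low`, `ci_high`, `pct_effect`,
#'   `significant`.
#' @export
odds_ratio_table <- function(draws, level = 0.95,
                             point = c("exp_mean", "mean_exp")) {
  stopifnot(inherits(draws, "hl_draws"))
  point <- match.arg(point)
  pooled <- as.matrix(draws)
  pars <- draws$parameter_names
  slope_idx <- which(!grepl("^mu_raw\\[", pars) &
                       !pars %in% c("alpha0", "sigma_mu"))
  if (!length(slope_idx))
    stop("odds_ratio_table: no slope draws present", call. = FALSE)
  a <- (1 - level) / 2
  rows <- lapply(slope_idx, function(j) {
    b <- pooled[, j]
    or <- if (point == "exp_mean") exp(mean(b)) else mean(exp(b))
    ci <- exp(stats::quantile(b, probs = c(a, 1 - a), names = FALSE))
    data.frame(parameter = pars[j],
               odds_ratio = or,
               or_sd = stats::sd(exp(b)),
               ci_low = ci[1L],
               ci_high = ci[2L],
               pct_effect = (or - 1) * 100,
               significant = ci[1L] > 1 || ci[2L] < 1)
  })
  structure(do.call(rbind, rows),
            class = c("hl_or_table", "data.frame"),
            level = level, point = point)
}

#' Render the analysis report
#'
#' Prints the convergence-gate status followed by the odds-ratio table
#' in the reporting column order (`parameter`, `odds_ratio`, `or_sd`,
#' `ci_low`, `ci_high`, `pct_effect`, `significant`). When the gate
#' failed, estimates are withheld and only the diagnostics are shown,
#' unless `force = TRUE`. Optionally writes the table to CSV (full
#' precision; re-reading reproduces the values bit for bit).
#'
#' @param or_table an `hl_or_table` (may have zero rows).
#' @param convergence an `hl_convergence` report, or `NULL` to skip the
#'   gate.
#' @param file optional CSV path for the machine-readable table.
#' @param force print estimates even when the gate failed.
#' @return the character vector of report lines, invisibly.
#' @export
render_report <- function(or_table, convergence = NULL, file = NULL,
                          force = FALSE) {
  lines <- character(0)
  gate_ok <- TRUE
  if (!is.null(convergence)) {
    gate_ok <- isTRUE(attr(convergence, "pass"))
    lines <- c(lines, sprintf(
      "Convergence gate (split R-hat < %.3g): %s (max R-hat %.4f)",
      attr(convergence, "threshold"),
      if (gate_ok) "PASS" else "FAIL",
      attr(convergence, "max_rhat")))
  }
  if (!gate_ok && !force) {
    lines <- c(lines,
               "Estimates withheld: convergence gate failed ",
               "(rerun with force = TRUE to override).")
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  df <- as.data.frame(or_table)
  header <- paste(c("parameter", "odds_ratio", "or_sd", "ci_low",
                    "ci_high", "pct_effect", "significant"),
                  collapse = ",")
  lines <- c(lines, header)
  if (nrow(df) > 0L)
    lines <- c(lines, vapply(seq_len(nrow(df)), function(i) {
      paste(c(df$parameter[i],
              formatC(c(df$odds_ratio[i], df$or_sd[i], df$ci_low[i],
                        df$ci_high[i], df$pct_effect[i]),
                      digits = 4, format = "f"),
              df$significant[i]),
            collapse = ",")
    }, character(1)))
  if (!is.null(file)) {
    out <- df
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "significant"
    out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
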