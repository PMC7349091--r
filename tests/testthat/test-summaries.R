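fake_fit <- function(chain_list, names) {
  chains <- lapply(chain_list, function(m) {
    colnames(m) <- names
    m
  })
  structure(list(draws = chains, constrained = chains,
                 parameter_names = names,
                 n_chains = length(chains), n_kept = nrow(chains[[1]]),
                 divergence_count = rep(0L, length(chains)),
                 failed = FALSE),
            class = "hl_draws")
}

test_that("coefficient summaries match direct order-statistic computation", {
  # constant draws: degenerate summary
  d <- fake_fit(list(matrix(2.5, 100, 1), matrix(2.5, 100, 1)), "x1")
  s <- summarize_coefficients(d)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 0)
  expect_equal(s$ci_low, 2.5)
  expect_equal(s$ci_high, 2.5)

  # sorted grid: type-7 quantiles pinned against the explicit formula
  g <- matrix(as.numeric(1:1000), 1000, 1)
  d <- fake_fit(list(g[1:500, , drop = FALSE], g[501:1000, , drop = FALSE]),
                "x1")
  s <- summarize_coefficients(d)
  # type 7 on 1..n: q(p) = 1 + (n - 1) p
  expect_equal(s$ci_low, 1 + 999 * 0.025)
  expect_equal(s$ci_high, 1 + 999 * 0.975)
  expect_equal(s$mean, 500.5)

  # pooled two-chain summary equals summary of the concatenation
  set.seed(1)
  a <- matrix(rnorm(300), 300, 1); b <- matrix(rnorm(300, 1), 300, 1)
  s2 <- summarize_coefficients(fake_fit(list(a, b), "x1"))
  pooled <- c(a, b)
  expect_equal(s2$mean, mean(pooled))
  expect_equal(s2$sd, sd(pooled))
  expect_equal(s2$ci_low, unname(quantile(pooled, 0.025)))
})

test_that("odds-ratio rows obey their defining identities", {
  d <- fake_fit(list(matrix(log(2), 50, 1), matrix(log(2), 50, 1)), "x1")
  tab <- odds_ratio_table(d)
  expect_equal(tab$odds_ratio, 2)
  expect_equal(tab$pct_effect, 100)
  expect_equal(tab$ci_low, 2)
  expect_equal(tab$ci_high, 2)
  expect_true(tab$significant)    # the degenerate interval [2, 2] excludes 1

  # an odds ratio of 1.428 corresponds to a +42.8% effect on the odds
  d2 <- fake_fit(list(matrix(log(1.428), 80, 1),
                      matrix(log(1.428), 80, 1)), "gender")
  expect_equal(odds_ratio_table(d2)$pct_effect, 42.8, tolerance = 1e-9)

  # interval straddling 1 (e.g. bounds 0.943 and 1.028) is not significant
  set.seed(2)
  b <- log(seq(0.943, 1.028, length.out = 200))
  d3 <- fake_fit(list(matrix(b, 200, 1), matrix(rev(b), 200, 1)),
                 "both_parents_smoke")
  t3 <- odds_ratio_table(d3)
  expect_false(t3$significant)
  expect_lt(t3$ci_low, 1)
  expect_gt(t3$ci_high, 1)
})

test_that("odds-ratio intervals are the exp of coefficient-scale intervals", {
  set.seed(3)
  nm <- c("alpha0", "x1", "x2")
  mk <- function() cbind(rnorm(400, 0.5, 1), rnorm(400, 0.3, 0.2),
                         rnorm(400, -0.4, 0.3))
  d <- fake_fit(list(mk(), mk()), nm)
  tab <- odds_ratio_table(d)
  cs <- summarize_coefficients(d)
  for (p in c("x1", "x2")) {
    i <- match(p, tab$parameter); j <- match(p, cs$parameter)
    expect_equal(tab$ci_low[i], exp(cs$ci_low[j]), tolerance = 1e-12)
    expect_equal(tab$ci_high[i], exp(cs$ci_high[j]), tolerance = 1e-12)
    expect_equal(tab$odds_ratio[i], exp(cs$mean[j]), tolerance = 1e-12)
  }
  # monotone transform: exp of quantile equals quantile of exp draws,
  # exactly when 0.025 (n - 1) is an order-statistic index
  x <- rnorm(801)
  expect_equal(exp(quantile(x, c(0.025, 0.975))),
               quantile(exp(x), c(0.025, 0.975)), ignore_attr = TRUE)
  expect_true(all(tab$odds_ratio > 0))
  expect_equal(sign(tab$pct_effect), sign(tab$odds_ratio - 1))
  # alpha0 and hierarchy parameters never appear as odds-ratio rows
  expect_false(any(tab$parameter %in% c("alpha0", "sigma_mu")))

  # symmetric draws around zero: OR near 1, not significant
  sym <- cbind(rnorm(2000, 0, 0.01))
  d4 <- fake_fit(list(sym, -sym), "x1")
  t4 <- odds_ratio_table(d4)
  expect_equal(t4$odds_ratio, 1, tolerance = 1e-3)
  expect_false(t4$significant)

  # the alternative point estimate E[exp(beta)] is available and larger
  # for spread-out draws (Jensen)
  t5 <- odds_ratio_table(d, point = "mean_exp")
  expect_true(all(t5$odds_ratio >= tab$odds_ratio))
})

test_that("render_report gates on convergence and round-trips its CSV", {
  set.seed(4)
  nm <- c("alpha0", "x1")
  d <- fake_fit(list(cbind(rnorm(300), rnorm(300, 0.4)),
                     cbind(rnorm(300), rnorm(300, 0.4))), nm)
  tab <- odds_ratio_table(d)
  conv <- check_convergence(d)

  # empty table: header-only body
  empty <- tab[0, ]
  out <- render_report(empty, NULL)
  expect_match(out[length(out)], "^parameter,odds_ratio")

  # failed gate without override: no estimates printed
  bad <- fake_fit(list(cbind(rnorm(300, -5, 0.1), rnorm(300, -5, 0.1)),
                       cbind(rnorm(300, 5, 0.1), rnorm(300, 5, 0.1))), nm)
  conv_bad <- check_convergence(bad)
  out_bad <- render_report(tab, conv_bad)
  expect_false(any(grepl("^x1,", out_bad)))
  expect_true(any(grepl("FAIL", out_bad)))
  out_forced <- render_report(tab, conv_bad, force = TRUE)
  expect_true(any(grepl("^x1,", out_forced)))

  # CSV round trip is exact
  path <- withr::local_tempfile(fileext = ".csv")
  render_report(tab, conv, file = path)
  back <- utils::read.csv(path)
  expect_identical(back$odds_ratio, tab$odds_ratio)
  expect_identical(back$ci_low, tab$ci_low)
  expect_identical(back$ci_high, tab$ci_high)
  expect_identical(back$pct_effect, tab$pct_effect)
  expect_identical(back$significant, tab$significant)
})
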