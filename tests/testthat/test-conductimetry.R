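test_that("a noiseless piecewise-linear curve is inverted exactly", {
  # kappa = 50*C below 25 mM, slope halves above: cmc 25, alpha 0.5
  p <- noiseless_params(cmc = 25, alpha = 0.5, s1 = 50, kappa0 = 0)
  s <- gen_conductivity(p, seq(2, 50, by = 2), seed = NULL)
  fit <- fit_two_segments(s)
  expect_equal(fit$cmc, 25)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-10)
  expect_equal(fit$s1, 50, tolerance = 1e-10)
  expect_equal(fit$s2, 25, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-16)
  expect_length(fit$flags, 0)
  expect_gte(min(fit$n_below, fit$n_above), 3)
})

test_that("the golden-section polish recovers off-grid breaks on clean data", {
  p <- noiseless_params(cmc = 26.5, alpha = 0.47)
  s <- gen_conductivity(p, seed = NULL)  # 2 mM grid: 26.5 not a candidate
  fit <- fit_two_segments(s, refine = TRUE)
  expect_equal(fit$cmc, 26.5, tolerance = 1e-5)
  expect_equal(fit$alpha, 0.47, tolerance = 1e-6)
})

test_that("cmc and alpha are invariant to response scaling and offsets", {
  withr::local_seed(21)
  s <- gen_conductivity(truth_params(seed = 21))
  base <- fit_two_segments(s)
  for (c0 in c(0.25, 7)) {
    sc <- titration_series(s$concentration, s$response * c0, "conductivity")
    fit <- fit_two_segments(sc)
    expect_equal(fit$cmc, base$cmc)
    expect_equal(fit$alpha, base$alpha, tolerance = 1e-12)
    expect_equal(fit$s1, base$s1 * c0, tolerance = 1e-12)
    expect_equal(fit$rss, base$rss * c0^2, tolerance = 1e-9)
  }
  off <- titration_series(s$concentration, s$response + 500, "conductivity")
  fit <- fit_two_segments(off)
  expect_equal(fit$cmc, base$cmc)
  expect_equal(fit$s1, base$s1, tolerance = 1e-10)
  expect_equal(fit$s2, base$s2, tolerance = 1e-10)
})

test_that("alpha is invariant to a change of concentration unit", {
  s <- gen_conductivity(truth_params(seed = 8))
  base <- fit_two_segments(s)
  molar <- titration_series(mm_to_molar(s$concentration), s$response,
                            "conductivity")
  fit <- fit_two_segments(molar)
  expect_equal(fit$alpha, base$alpha, tolerance = 1e-12)
  expect_equal(fit$cmc * 1000, base$cmc, tolerance = 1e-9)
})

test_that("the fit equals the exhaustive break-candidate oracle", {
  withr::local_seed(99)
  for (i in 1:60) {
    inst <- random_break_instance()
    s <- titration_series(inst$x, inst$y, "conductivity")
    fit <- fit_two_segments(s)
    orc <- oracle_two_segments(inst$x, inst$y)
    expect_equal(fit$cmc, orc$cmc)
    expect_equal(fit$rss, orc$rss, tolerance = 1e-9)
    expect_equal(fit$s1, orc$s1, tolerance = 1e-8)
    expect_equal(fit$s2, orc$s2, tolerance = 1e-8)
  }
})

test_that("degenerate inputs raise the advertised errors and flags", {
  expect_error(
    fit_two_segments(titration_series(1:5, (1:5) * 10, "conductivity")),
    "insufficient|at least")
  expect_error(
    fit_two_segments(titration_series(1:6, c(-1, 2, 3, 4, 5, 6), "conductivity")),
    "positive")
  expect_error(fit_two_segments(gen_tension(truth_params())), "response_kind")

  # upward break: slope increases above the "cmc" -> flagged, alpha > 1
  x <- seq(2, 40, 2)
  y <- 10 + 20 * pmin(x, 20) + 40 * pmax(x - 20, 0)
  fit <- fit_two_segments(titration_series(x, y, "conductivity"))
  expect_true("no micellization signature" %in% fit$flags)
  expect_gt(fit$alpha, 1)
})

test_that("a smoothed break is localized within half its width and flagged", {
  p <- noiseless_params(transition_width = 4)
  s <- gen_conductivity(p, seed = NULL)
  fit <- fit_two_segments(s, refine = TRUE)
  expect_lt(abs(fit$cmc - 26.5), 2)
  expect_true("broad transition" %in% fit$flags)
})

test_that("the residual bootstrap reports a finite cmc dispersion", {
  s <- gen_conductivity(truth_params(seed = 13))
  fit <- fit_two_segments(s, n_boot = 50, seed = 13)
  expect_true(is.finite(fit$cmc_sd))
  expect_lt(fit$cmc_sd, 3)
})
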