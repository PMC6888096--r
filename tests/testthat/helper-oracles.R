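# Independent brute-force oracle for the two-segment break fit: tries every
# interior sample abscissa and every midpoint between adjacent samples as a
# break candidate, fitting the joined model via lm() with a different
# parameterization (pmin/pmax segment slopes) than the package uses.
oracle_two_segments <- function(x, y, min_seg = 3) {
  n <- length(x)
  idx <- seq(min_seg, n - min_seg)
  cand <- sort(unique(c(x[idx], (x[idx] + x[idx + 1]) / 2)))
  best <- list(rss = Inf)
  for (b in cand) {
    lo <- pmin(x, b)
    hi <- pmax(x - b, 0)
    fit <- lm(y ~ lo + hi)
    rss <- sum(resid(fit)^2)
    if (rss < best$rss * (1 - 1e-12)) {
      best <- list(cmc = b, rss = rss,
                   s1 = unname(coef(fit)[2]), s2 = unname(coef(fit)[3]))
    }
  }
  best
}

# random piecewise-linear conductivity-like instance on <= 40 points
random_break_instance <- function() {
  n <- sample(8:40, 1)
  x <- sort(runif(n, 1, 50))
  while (anyDuplicated(x)) x <- sort(runif(n, 1, 50))
  b <- runif(1, x[4], x[n - 3])
  s1 <- runif(1, 20, 80)
  alpha <- runif(1, 0.3, 0.9)
  k0 <- runif(1, 0, 50)
  y <- k0 + s1 * pmin(x, b) + alpha * s1 * pmax(x - b, 0)
  y <- y + rnorm(n, 0, runif(1, 0, 0.01) * y)
  y <- pmax(y, 1e-3)
  list(x = x, y = y)
}

noiseless_params <- function(...) {
  truth_params(noise_sd = list(conductivity = 0, tension = 0,
                               ratio = 0, eta_r = 0), ...)
}

# two-band Gaussian pyrene-like spectrum with prescribed peak heights
two_band_spectrum <- function(h1, h3, grid = seq(360, 400, 0.25), sigma = 1.5) {
  emission_spectrum(grid, h1 * exp(-(grid - 373)^2 / (2 * sigma^2)) +
                      h3 * exp(-(grid - 383)^2 / (2 * sigma^2)))
}
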