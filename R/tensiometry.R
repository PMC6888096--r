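#' Pre-CMC slope of a surface-tension curve
#'
#' Ordinary least-squares slope of surface tension versus log10 of the
#' concentration (in mM) over a stated concentration window. This is the
#' d(gamma)/d(logC) that feeds the Gibbs adsorption equation.
#'
#' @param series A surface-tension [titration_series()].
#' @param window Numeric length-2 concentration interval (mM), inclusive,
#'   selecting the points to fit.
#' @return List with `slope` (mN/m per decade), `intercept` (gamma at 1 mM),
#'   `slope_se`, `n` and `flags` (contains `"non-surface-active"` when the
#'   slope is >= 0).
#' @export
pre_cmc_slope <- function(series, window = range(series$concentration)) {
  .assert_kind(series, "surface_tension")
  sel <- series$concentration >= window[1] & series$concentration <= window[2]
  x <- log10(series$concentration[sel])
  y <- series$response[sel]
  if (length(x) < 3) stop("insufficient data: need >= 3 points in the window",
                          call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  # slope SE computed directly (avoids summary.lm noise on perfect fits)
  s2 <- sum(stats::resid(fit)^2) / max(length(x) - 2, 1)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  flags <- if (slope >= 0) "non-surface-active" else character(0)
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       slope_se = se, n = length(x), flags = flags)
}

#' Maximum surface excess from the Gibbs adsorption equation
#'
#' `Gamma_max = -(dgamma/dlogC) / (2.303 * n * R * T)` with the slope in
#' mN/m per log10 decade and T in Kelvin, returned in mol cm^-2. The
#' prefactor `n` is 2 for an ionic surfactant whose ion and counterion are
#' both monovalent and fully dissociated (no swamping electrolyte); 1 for
#' nonionics or swamped systems; 3 for 2:1 systems. The printed constant
#' 2.303 is used verbatim (log base 10 convention).
#'
#' @param slope d(gamma)/d(logC) in mN/m per decade (negative for a
#'   surface-active solute).
#' @param temperature Absolute temperature in K.
#' @param n_prefactor Gibbs prefactor, one of 1, 2, 3.
#' @return Surface excess in mol cm^-2.
#' @examples
#' surface_excess(-29.6, celsius_to_kelvin(24), 2) # 2.60e-10 mol cm^-2
#' @export
surface_excess <- function(slope, temperature, n_prefactor = 2) {
  if (!n_prefactor %in% c(1, 2, 3)) {
    stop("n_prefactor must be 1, 2 or 3", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be > 0 K", call. = FALSE)
  }
  # slope mN/m -> N/m (1e-3); result mol m^-2 -> mol cm^-2 (1e-4)
  gamma_m2 <- -slope * 1e-3 / (2.303 * n_prefactor * micelle_constants$R * temperature)
  gamma_m2 * 1e-4
}

#' Minimum area per surfactant molecule
#'
#' `Amin = 1 / (N_A * Gamma_max)`, converted to Angstrom^2:
#' `1e16 / (N_A * Gamma_max[mol cm^-2])`. Always feed the unrounded
#' `Gamma_max`; rounding intermediates shifts Amin by around half an
#' Angstrom^2.
#'
#' @param gamma_max Surface excess in mol cm^-2 (> 0).
#' @return Area per molecule in A^2.
#' @examples
#' min_area(surface_excess(-29.6, 297.15, 2)) # 63.8 A^2
#' @export
min_area <- function(gamma_max) {
  if (!is.finite(gamma_max) || gamma_max <= 0) {
    stop("gamma_max must be > 0", call. = FALSE)
  }
  1e16 / (micelle_constants$N_A * gamma_max)
}

#' Gibbs adsorption analysis of a surface-tension titration
#'
#' End-to-end tensiometry stage: detects the post-CMC plateau, selects the
#' descending (pre-CMC) fit window, fits gamma versus log10(C), and chains
#' the unrounded slope through the Gibbs equation to `Gamma_max` and `Amin`.
#' If a fluorocarbon surfactant (or explicit tail geometry) is supplied,
#' the critical packing parameter and shape class are appended.
#'
#' Window selection is deterministic: a continuous two-segment model is
#' fitted to gamma versus log10(C) by the same exhaustive break-candidate
#' search used for conductivity curves; the points at or below the break
#' form the descending window and the points above it the plateau. This
#' partition is exact on clean data (the break lands at the CMC) and
#' degrades gracefully under noise, unlike terminal-run rules keyed to a
#' fixed tension spread. The CMC from tension is the abscissa where the
#' descending line meets the horizontal plateau level. Both windows are
#' reported so every number is auditable; `window` overrides the automatic
#' choice. A curve whose total tension spread is within `flat_tol` is
#' declared non-surface-active up front.
#'
#' @inheritParams pre_cmc_slope
#' @param temperature Temperature in degrees C; defaults to the series
#'   temperature.
#' @param n_prefactor Gibbs prefactor (see [surface_excess()]).
#' @param surfactant Optional [surfactant_spec()] with tail geometry for
#'   packing analysis.
#' @param window Optional explicit concentration window (mM) for the
#'   descending fit.
#' @param flat_tol Total tension spread (mN/m) below which the curve is
#'   treated as flat (non-surface-active).
#' @return An object of class `adsorption_result`: `slope`, `slope_se`,
#'   `gamma_max` (mol cm^-2), `a_min`, `a_min_sd` (A^2), `cmc_tension`
#'   (mM), `plateau_gamma` (mN/m), `n_prefactor`, `window`, `flags`, and
#'   `packing` (a [packing_parameter()] result or `NULL`).
#' @export
analyze_tension <- function(series, temperature = series_temperature(series),
                            n_prefactor = 2, surfactant = NULL,
                            window = NULL, flat_tol = 0.5) {
  .assert_kind(series, "surface_tension")
  x <- series$concentration
  y <- series$response
  n <- length(x)
  if (n < 6) stop("insufficient data: need >= 6 points", call. = FALSE)

  if (diff(range(y)) <= flat_tol) {
    return(structure(
      list(slope = 0, slope_se = NA_real_, gamma_max = 0, a_min = NA_real_,
           a_min_sd = NA_real_, cmc_tension = NA_real_,
           plateau_gamma = mean(y), n_prefactor = n_prefactor,
           window = NULL, flags = "non-surface-active", packing = NULL),
      class = "adsorption_result"
    ))
  }

  if (is.null(window)) {
    # partition descending branch / plateau by a two-segment fit in log C
    u <- log10(x)
    cand <- .break_candidates(u, 3)
    prof <- vapply(cand, function(b) .hinge_rss(u, y, b)$rss, numeric(1))
    ub <- cand[which(prof <= min(prof) * (1 + 1e-12))[1]]
    window <- c(x[1], max(x[u <= ub]))
  }
  plateau_idx <- which(x > window[2])
  if (length(plateau_idx) < 2) {
    stop("no plateau beyond the descending window; cannot locate the CMC",
         call. = FALSE)
  }
  plateau_gamma <- mean(y[plateau_idx])
  sl <- pre_cmc_slope(series, window)
  flags <- sl$flags

  if (sl$slope < 0) {
    gamma_max <- surface_excess(sl$slope, celsius_to_kelvin(temperature),
                                n_prefactor)
    a_min <- min_area(gamma_max)
    a_min_sd <- a_min * sl$slope_se / abs(sl$slope) # Amin ~ 1/|slope|
    cmc_tension <- 10^((plateau_gamma - sl$intercept) / sl$slope)
  } else {
    gamma_max <- 0
    a_min <- a_min_sd <- cmc_tension <- NA_real_
  }

  packing <- NULL
  if (!is.null(surfactant) && is.finite(a_min)) {
    if (is.null(surfactant$tail_volume) || is.null(surfactant$tail_length)) {
      flags <- c(flags, "no tail geometry: packing skipped")
    } else {
      packing <- packing_parameter(surfactant$tail_volume, a_min,
                                   surfactant$tail_length)
    }
  }

  structure(
    list(slope = sl$slope, slope_se = sl$slope_se, gamma_max = gamma_max,
         a_min = a_min, a_min_sd = a_min_sd, cmc_tension = cmc_tension,
         plateau_gamma = plateau_gamma, n_prefactor = n_prefactor,
         window = window, flags = flags, packing = packing),
    class = "adsorption_result"
  )
}

#' @export
print.adsorption_result <- function(x, ...) {
  cat(sprintf("<adsorption_result: slope %.3g mN/m/decade, Gamma_max %.3g mol/cm^2, Amin %.3g A^2, CMC %.4g mM>\n",
              x$slope, x$gamma_max, x$a_min, x$cmc_tension))
  if (!is.null(x$packing)) print(x$packing)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
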