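# seeded evaluation that leaves the caller's RNG stream untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Ground-truth parameters for the synthetic titration generators
#'
#' Bundles every parameter of the four forward models with defaults
#' matching the APFO-in-water study conditions: CMC 26.5 mM and counterion
#' dissociation 0.47 (conductivity), surface-tension slope -29.6 mN/m per
#' decade descending to an ~18 mN/m plateau, pyrene I1/I3 falling from the
#' aqueous 1.8 baseline to 1.2 in the micelle-bound limit, and a
#' relative-viscosity curve with shape factor 2.97 (short cylindrical
#' micelles) and hydrated molecular volume 0.710 nm^3. Noise defaults are
#' per-channel: conductivity 0.5% relative, tension 0.3 mN/m, I1/I3 0.01
#' and eta_r 0.002 absolute; the last reflects the 0.2% efflux-time
#' reproducibility typical of capillary viscometers, the others are
#' conventions matched to typical instrument scatter.
#'
#' @param cmc CMC, mM.
#' @param alpha Degree of counterion dissociation (0-1).
#' @param kappa0 Conductivity intercept at zero surfactant, uS/cm.
#' @param s1 Pre-CMC conductivity slope, uS cm^-1 mM^-1.
#' @param gamma0 Surface tension at 1 mM, mN/m; `NULL` pins the descending
#'   branch so that it meets the plateau exactly at `cmc`.
#' @param tension_slope d(gamma)/d(log10 C), mN/m per decade.
#' @param plateau_gamma Post-CMC surface tension, mN/m.
#' @param ratio_water,ratio_micelle I1/I3 in water and in the bound limit.
#' @param partition_k Pyrene binding constant, per mM of micellized
#'   surfactant.
#' @param nu Viscosity shape factor.
#' @param v_shyd Hydrated volume per molecule, nm^3.
#' @param k1 Pairwise hydrodynamic coefficient.
#' @param noise_sd Named list of per-channel noise SDs: `conductivity`
#'   (relative), `tension`, `ratio`, `eta_r` (absolute).
#' @param transition_width Width (mM) of the smoothed conductivity break;
#'   0 gives a sharp hinge.
#' @param seed Default seed carried by the parameter set.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(cmc = 26.5, alpha = 0.47, kappa0 = 10, s1 = 50,
                         gamma0 = NULL, tension_slope = -29.6,
                         plateau_gamma = 18, ratio_water = 1.8,
                         ratio_micelle = 1.2, partition_k = 0.1,
                         nu = 2.97, v_shyd = 0.710, k1 = 1.0,
                         noise_sd = list(conductivity = 0.005, tension = 0.3,
                                         ratio = 0.01, eta_r = 0.002),
                         transition_width = 0, seed = NULL) {
  if (cmc <= 0) stop("cmc must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (ratio_water <= ratio_micelle) {
    stop("ratio_water must exceed ratio_micelle", call. = FALSE)
  }
  if (transition_width < 0) stop("transition_width must be >= 0", call. = FALSE)
  if (any(unlist(noise_sd) < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  if (is.null(gamma0)) gamma0 <- plateau_gamma - tension_slope * log10(cmc)
  structure(
    list(cmc = cmc, alpha = alpha, kappa0 = kappa0, s1 = s1, gamma0 = gamma0,
         tension_slope = tension_slope, plateau_gamma = plateau_gamma,
         ratio_water = ratio_water, ratio_micelle = ratio_micelle,
         partition_k = partition_k, nu = nu, v_shyd = v_shyd, k1 = k1,
         noise_sd = noise_sd, transition_width = transition_width,
         seed = seed),
    class = "truth_params"
  )
}

.check_conc <- function(concentrations) {
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be positive and strictly ascending", call. = FALSE)
  }
  concentrations
}

#' Simulate a conductivity titration
#'
#' Forward model: conductivity rises linearly with slope `s1` below the
#' CMC and with slope `alpha * s1` above, the two branches joined
#' continuously at the break. A positive `transition_width` replaces the
#' sharp hinge by a softplus blend whose visible curvature spans roughly
#' that width, emulating the gradual breaks seen at high cosolvent
#' content. Seeded Gaussian noise is relative to the signal.
#'
#' @param params A [truth_params()].
#' @param concentrations Ascending positive concentrations, mM; default
#'   2-50 mM in 2 mM steps (the usual conductimetric range).
#' @param seed Seed for the noise stream (default `params$seed`; `NULL`
#'   means no seeding).
#' @return A conductivity [titration_series()] (24 C) with attribute
#'   `truth = params`.
#' @export
gen_conductivity <- function(params, concentrations = seq(2, 50, by = 2),
                             seed = params$seed) {
  stopifnot(inherits(params, "truth_params"))
  x <- .check_conc(concentrations)
  w <- params$transition_width
  excess <- x - params$cmc
  hinge <- if (w == 0) pmax(excess, 0) else {
    s <- w / 4
    z <- excess / s
    s * ifelse(z > 30, z, log1p(exp(pmin(z, 30)))) # softplus, overflow-safe
  }
  kappa <- params$kappa0 + params$s1 * x -
    (1 - params$alpha) * params$s1 * hinge
  kappa <- .with_seed(seed, {
    kappa * (1 + stats::rnorm(length(x), 0, params$noise_sd$conductivity))
  })
  out <- titration_series(x, kappa, "conductivity", temperature = 24)
  attr(out, "truth") <- params
  out
}

#' Simulate a surface-tension titration
#'
#' Forward model: tension falls linearly in log10 concentration with slope
#' `tension_slope` from `gamma0` (value at 1 mM) and is clipped below at
#' the plateau level, so the break sits where the two branches intersect
#' (at the CMC when `gamma0` is left at its pinned default). Errors if the
#' plateau lies above the descending branch at the CMC (inconsistent
#' parameters). Seeded Gaussian noise is absolute (mN/m).
#'
#' @inheritParams gen_conductivity
#' @param concentrations Default 11 points from 5 to 150 mM spanning both
#'   branches.
#' @return A surface-tension [titration_series()] (24 C).
#' @export
gen_tension <- function(params,
                        concentrations = c(5, 8, 12, 16, 20, 25, 35, 50, 75,
                                           100, 150),
                        seed = params$seed) {
  stopifnot(inherits(params, "truth_params"))
  x <- .check_conc(concentrations)
  desc <- params$gamma0 + params$tension_slope * log10(x)
  desc_at_cmc <- params$gamma0 + params$tension_slope * log10(params$cmc)
  if (params$plateau_gamma > desc_at_cmc + 1e-9) {
    stop("inconsistent params: plateau lies above the descending branch at the CMC",
         call. = FALSE)
  }
  gamma <- pmax(desc, params$plateau_gamma)
  gamma <- .with_seed(seed, {
    gamma + stats::rnorm(length(x), 0, params$noise_sd$tension)
  })
  out <- titration_series(x, gamma, "surface_tension", temperature = 24)
  attr(out, "truth") <- params
  out
}

#' Simulate pyrene I1/I3 data (ratio curve or full spectra)
#'
#' Forward model: the micelle-bound pyrene fraction is 0 below the CMC and
#' `f = K*(C - cmc) / (1 + K*(C - cmc))` above; the observed ratio is the
#' bound-fraction mixture of the aqueous and micellar limits,
#' `(1 - f)*ratio_water + f*ratio_micelle`. With `full_spectra = TRUE`,
#' each sample is emitted as a two-band Gaussian spectrum (373 and 383 nm
#' centres, 3 nm widths) whose band amplitudes are solved so the peak
#' maxima realize the target ratio exactly despite band overlap. Noise:
#' absolute on the ratio, relative on spectral intensities.
#'
#' @inheritParams gen_conductivity
#' @param concentrations Default 1-200 mM, the usual fluorimetric range.
#' @param full_spectra If `TRUE`, return a list of [emission_spectrum()]
#'   objects (one per concentration) instead of a ratio series.
#' @param wavelengths Spectrum grid, nm (default 360-400 by 0.5).
#' @return An i1i3 [titration_series()] (22 C), or a list of spectra.
#' @export
gen_pyrene <- function(params, concentrations = c(1, seq(5, 200, by = 5)),
                       full_spectra = FALSE,
                       wavelengths = seq(360, 400, by = 0.5),
                       seed = params$seed) {
  stopifnot(inherits(params, "truth_params"))
  x <- .check_conc(concentrations)
  K <- params$partition_k
  if (K <= 0) stop("partition_k must be > 0", call. = FALSE)
  f <- ifelse(x <= params$cmc, 0,
              K * (x - params$cmc) / (1 + K * (x - params$cmc)))
  ratio <- (1 - f) * params$ratio_water + f * params$ratio_micelle

  if (!full_spectra) {
    ratio <- .with_seed(seed, {
      ratio + stats::rnorm(length(x), 0, params$noise_sd$ratio)
    })
    out <- titration_series(x, ratio, "i1i3", temperature = 22)
    attr(out, "truth") <- params
    return(out)
  }

  sigma <- 3
  g <- exp(-(383 - 373)^2 / (2 * sigma^2)) # cross-talk between the bands
  .with_seed(seed, {
    lapply(seq_along(x), function(i) {
      r <- ratio[i]
      # solve peak amplitudes so maxima at the centres equal (r, 1)
      amp <- solve(matrix(c(1, g, g, 1), 2), c(r, 1))
      base <- amp[1] * exp(-(wavelengths - 373)^2 / (2 * sigma^2)) +
        amp[2] * exp(-(wavelengths - 383)^2 / (2 * sigma^2))
      noisy <- base * (1 + stats::rnorm(length(wavelengths), 0,
                                        params$noise_sd$ratio))
      emission_spectrum(wavelengths, pmax(noisy, 0), label = x[i])
    })
  })
}

#' Simulate a relative-viscosity titration
#'
#' Forward model: `eta_r = 1 + nu*phi + k1*(nu*phi)^2` with micelle volume
#' fraction `phi = v_shyd * N_A * (C - cmc)` (concentration in mol/L) above
#' the CMC, and `eta_r = 1` below. Seeded Gaussian noise is absolute on
#' `eta_r`.
#'
#' @inheritParams gen_conductivity
#' @param concentrations Default 30-150 mM in 10 mM steps, a typical
#'   capillary-viscometry series above the CMC.
#' @return A relative-viscosity [titration_series()] (20 C).
#' @export
gen_viscosity <- function(params, concentrations = seq(30, 150, by = 10),
                          seed = params$seed) {
  stopifnot(inherits(params, "truth_params"))
  x <- .check_conc(concentrations)
  if (max(x) <= params$cmc) {
    stop("concentrations must span above the CMC", call. = FALSE)
  }
  phi <- params$v_shyd * 1e-24 * micelle_constants$N_A *
    mm_to_molar(pmax(x - params$cmc, 0))
  eta_r <- 1 + params$nu * phi + params$k1 * (params$nu * phi)^2
  eta_r <- .with_seed(seed, {
    eta_r + stats::rnorm(length(x), 0, params$noise_sd$eta_r)
  })
  out <- titration_series(x, eta_r, "relative_viscosity", temperature = 20)
  attr(out, "truth") <- params
  out
}

#' Simulate a full experiment bundle
#'
#' Runs all four generators with sub-seeds derived deterministically from
#' `seed`, optionally writing the CSVs the analysis stages read plus a
#' `truth.json` sidecar.
#'
#' @inheritParams gen_conductivity
#' @param dir Output directory; `NULL` skips writing.
#' @return Named list with the four series and `params`.
#' @export
gen_bundle <- function(params = truth_params(), seed = params$seed,
                       dir = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), 4) else as.list(seed * 4 + 0:3)
  out <- list(
    conductivity = gen_conductivity(params, seed = seeds[[1]]),
    tension = gen_tension(params, seed = seeds[[2]]),
    pyrene = gen_pyrene(params, seed = seeds[[3]]),
    viscosity = gen_viscosity(params, seed = seeds[[4]]),
    params = params
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hdr <- if (is.null(seed)) "unseeded" else paste("seed", seed)
    write_titration(out$conductivity, file.path(dir, "conductivity.csv"), hdr)
    write_titration(out$tension, file.path(dir, "tension.csv"), hdr)
    write_titration(out$pyrene, file.path(dir, "pyrene_ratios.csv"), hdr)
    write_titration(out$viscosity, file.path(dir, "viscosity.csv"), hdr)
    truth <- params
    truth$seed <- seed
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
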