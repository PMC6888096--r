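#' Relative viscosity from capillary efflux times
#'
#' A capillary viscometer gives the kinematic viscosity as efflux time
#' times the viscometer calibration constant. The relative viscosity is
#' the ratio of sample to pure-solvent kinematic viscosities; when both
#' runs use the same viscometer it reduces to the time ratio.
#'
#' @param efflux_sample Sample efflux time(s), s.
#' @param efflux_solvent Pure-solvent efflux time, s.
#' @param calib_sample,calib_solvent Viscometer calibration constants for
#'   the sample and solvent runs (cancel when equal).
#' @return Relative viscosity (dimensionless), vectorized over
#'   `efflux_sample`.
#' @export
relative_viscosity <- function(efflux_sample, efflux_solvent,
                               calib_sample = 1, calib_solvent = 1) {
  vals <- c(efflux_sample, efflux_solvent, calib_sample, calib_solvent)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("efflux times and calibration constants must be positive", call. = FALSE)
  }
  (efflux_sample * calib_sample) / (efflux_solvent * calib_solvent)
}

#' Convert an efflux-time titration to relative viscosity
#'
#' @param series An efflux-time [titration_series()].
#' @inheritParams relative_viscosity
#' @return A relative-viscosity [titration_series()].
#' @export
efflux_to_relative <- function(series, efflux_solvent,
                               calib_sample = 1, calib_solvent = 1) {
  .assert_kind(series, "efflux_time")
  titration_series(series$concentration,
                   relative_viscosity(series$response, efflux_solvent,
                                      calib_sample, calib_solvent),
                   "relative_viscosity", series_temperature(series))
}

#' Virial fit of relative viscosity above the CMC
#'
#' Fits `eta_r - 1 = p1 * x + p2 * x^2` by least squares with the intercept
#' fixed by the model at `eta_r = 1`, where `x = (c_s - c1)` is the
#' micellized surfactant concentration in mol/L and `c1` (the free-monomer
#' concentration) is taken equal to the CMC. In terms of the micelle volume
#' fraction `phi = Vshyd * N_A * x`, the expansion reads
#' `eta_r = 1 + nu*phi + k1*(nu*phi)^2` with shape factor `nu`, so the
#' hydrated volume per surfactant molecule is `Vshyd = p1 / (nu * N_A)`
#' (reported in nm^3) and the pairwise hydrodynamic coefficient is
#' `k1 = p2 / p1^2`. Third-order (direct micelle-micelle) terms are
#' neglected, which restricts the fit to dilute solutions.
#'
#' @param series A relative-viscosity [titration_series()].
#' @param cmc CMC in mM (free-monomer concentration `c1`). Priority when
#'   assembling a report: user-supplied, then conductivity, then tension.
#' @param nu Shape factor (2.5 for spheres; see [shape_factor()]).
#' @param free_intercept Diagnostic only: if `TRUE` the intercept is
#'   estimated rather than fixed at 1.
#' @return An object of class `viscosity_fit`: `p1`, `p2` (per mol/L and
#'   per (mol/L)^2), `k1`, `nu`, `v_shyd` (nm^3), `c1` (mM), `rss`,
#'   `n_used`, `intercept`, `flags`.
#' @export
fit_virial <- function(series, cmc, nu = 2.5, free_intercept = FALSE) {
  .assert_kind(series, "relative_viscosity")
  if (!is.finite(cmc) || cmc <= 0) stop("cmc must be positive (mM)", call. = FALSE)
  if (!is.finite(nu) || nu < 2.5) stop("nu must be >= 2.5", call. = FALSE)
  sel <- series$concentration > cmc
  x <- mm_to_molar(series$concentration[sel] - cmc) # mol/L micellized
  y <- series$response[sel] - 1
  if (length(x) < 4) stop("need >= 4 points above the CMC", call. = FALSE)

  if (free_intercept) {
    fit <- stats::lm(y ~ x + I(x^2))
    intercept <- unname(stats::coef(fit)[1]) + 1
    p1 <- unname(stats::coef(fit)[2]); p2 <- unname(stats::coef(fit)[3])
  } else {
    fit <- stats::lm(y ~ 0 + x + I(x^2))
    intercept <- 1
    p1 <- unname(stats::coef(fit)[1]); p2 <- unname(stats::coef(fit)[2])
  }
  rss <- sum(stats::resid(fit)^2)

  flags <- character(0)
  if (max(abs(y)) < 1e-10) {
    flags <- c(flags, "no micellar contribution")
    p1 <- p2 <- 0
  } else if (p1 <= 0) {
    flags <- c(flags, "nonphysical: p1 <= 0")
  }
  # phi = Vshyd[nm^3] * 1e-24 L * N_A * x[mol/L]
  v_shyd <- if (p1 > 0) p1 / (nu * micelle_constants$N_A * 1e-24) else NA_real_
  k1 <- if (p1 > 0) p2 / p1^2 else NA_real_

  structure(
    list(p1 = p1, p2 = p2, k1 = k1, nu = nu, v_shyd = v_shyd,
         c1 = cmc, rss = rss, n_used = length(x), intercept = intercept,
         flags = flags),
    class = "viscosity_fit"
  )
}

#' @export
print.viscosity_fit <- function(x, ...) {
  cat(sprintf("<viscosity_fit: p1 %.4g L/mol, k1 %.3g, nu %.3g -> Vshyd %.4g nm^3 (c1 %.4g mM)>\n",
              x$p1, x$k1, x$nu, x$v_shyd, x$c1))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Einstein-type shape factor of a cylindrical micelle
#'
#' For hydrodynamic purposes a cylindrical rod of axial ratio `L/d`
#' (length over diameter, hemispherical caps included) is equated to a
#' prolate ellipsoid of equal length and volume, whose axial ratio is
#' `J = (L/d) * sqrt(2 / (3 - d/L))`. The intrinsic (shape) factor is then
#' `nu = 2.5` at the sphere limit `J = 1`,
#' `nu = 2.5 + 0.407 * (J - 1)^1.508` for `1 < J <= 15` (short rods), and
#' `nu = 1.6 + (J^2/15) * (1/(ln(2J) - 1.5) + 3/(ln(2J) - 0.5))` for
#' `J > 15` (long rods). The two branches disagree slightly at `J = 15`;
#' the short-rod branch is used there and the long-rod value reported as
#' `nu_alt` for the record.
#'
#' @param axial_ratio Rod axial ratio `L/d` (>= 1).
#' @return An object of class `shape_model`: `axial_ratio`, `j`, `nu`,
#'   `regime` (`"sphere"`, `"short_rod"`, `"long_rod"`), `nu_alt`.
#' @examples
#' shape_factor(1)$nu # 2.5
#' @export
shape_factor <- function(axial_ratio) {
  if (!is.finite(axial_ratio) || axial_ratio < 1) {
    stop("axial ratio L/d must be >= 1", call. = FALSE)
  }
  j <- axial_ratio * sqrt(2 / (3 - 1 / axial_ratio))
  nu <- shape_factor_from_j(j)
  regime <- if (j <= 1) "sphere" else if (j <= 15) "short_rod" else "long_rod"
  nu_alt <- if (j == 15) .nu_long_rod(15) else NA_real_
  structure(
    list(axial_ratio = axial_ratio, j = j, nu = nu, regime = regime,
         nu_alt = nu_alt),
    class = "shape_model"
  )
}

#' @rdname shape_factor
#' @param j Equivalent prolate axial ratio (>= 1).
#' @export
shape_factor_from_j <- function(j) {
  if (!is.finite(j) || j < 1) stop("J must be >= 1", call. = FALSE)
  if (j == 1) 2.5
  else if (j <= 15) 2.5 + 0.407 * (j - 1)^1.508
  else .nu_long_rod(j)
}

.nu_long_rod <- function(j) {
  1.6 + (j^2 / 15) * (1 / (log(2 * j) - 1.5) + 3 / (log(2 * j) - 0.5))
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model: L/d %.3g -> J %.4g, nu %.4g (%s)>\n",
              x$axial_ratio, x$j, x$nu, x$regime))
  invisible(x)
}

#' Invert the shape-factor relation
#'
#' Root-finds the equivalent prolate axial ratio `J` (and the rod axial
#' ratio `L/d`) that yields a given shape factor `nu`. Useful when `nu` is
#' obtained from scattering or assumed, and the corresponding geometry is
#' wanted.
#'
#' @param nu Shape factor (>= 2.5).
#' @param j_max Upper search bound for `J`.
#' @return List with `j`, `axial_ratio`, `nu`.
#' @examples
#' invert_shape_factor(2.97)$j # 2.10
#' @export
invert_shape_factor <- function(nu, j_max = 1e3) {
  if (!is.finite(nu) || nu < 2.5) stop("nu must be >= 2.5", call. = FALSE)
  if (nu == 2.5) {
    j <- 1
  } else {
    f <- function(j) shape_factor_from_j(j) - nu
    upper <- if (f(15) >= 0) 15 else j_max
    j <- stats::uniroot(f, c(1, upper), tol = 1e-10)$root
  }
  # invert J = r*sqrt(2/(3 - 1/r)) for the rod axial ratio r
  r <- if (j == 1) 1 else {
    stats::uniroot(function(r) r * sqrt(2 / (3 - 1 / r)) - j,
                   c(1, j * 2 + 1), tol = 1e-10)$root
  }
  list(j = j, axial_ratio = r, nu = nu)
}

#' Solvation bookkeeping from the hydrated molecular volume
#'
#' Decomposes the hydrated volume per surfactant molecule `Vshyd` into the
#' dry molecular volume, bound water, and (optionally) bound cosolvent:
#'
#' * Plain water: `V_water_total = Vshyd - V_molecule`; the water count is
#'   `V_water_total` over the single-water volume, rounded to the nearest
#'   integer.
#' * With cosolvent: given the plain-water reference `V_water_total` (the
#'   bound-water volume is assumed unchanged by the cosolvent), the excess
#'   `Vshyd - V_molecule - V_water_reference` is attributed to cosolvent;
#'   the cosolvent count is reported to one decimal. A negative excess is
#'   flagged `"dehydration relative to reference"` and the count floored
#'   at 0.
#'
#' The identity `V_molecule + V_water_total + V_cosolvent_total = Vshyd`
#' holds exactly before rounding.
#'
#' @param v_shyd Hydrated volume per molecule, nm^3 (>= the dry molecular
#'   volume).
#' @param spec A [surfactant_spec()] (supplies the dry molecular volume).
#' @param solvent A [solvent_spec()] (supplies single-molecule volumes).
#' @param v_water_total_reference Bound-water volume (nm^3) from the
#'   plain-water condition; `NULL` for the no-cosolvent scenario.
#' @param scenario Label recorded in the result, e.g.
#'   `"case_I_cylindrical"`, `"case_II_spherical"`, `"direct"`.
#' @return An object of class `hydration_budget`: `v_shyd`, `v_molecule`,
#'   `v_water_total`, `n_water`, `v_cosolvent_total`, `n_cosolvent`,
#'   `scenario`, `flags`.
#' @examples
#' hydration_budget(0.710, apfo_spec(), solvent_spec()) # 11 bound waters
#' @export
hydration_budget <- function(v_shyd, spec, solvent = solvent_spec(),
                             v_water_total_reference = NULL,
                             scenario = "direct") {
  stopifnot(inherits(spec, "surfactant_spec"), inherits(solvent, "solvent_spec"))
  v_mol <- spec$molecular_volume
  if (!is.finite(v_shyd) || v_shyd < v_mol) {
    stop("v_shyd must be >= the dry molecular volume (", v_mol, " nm^3)",
         call. = FALSE)
  }
  flags <- character(0)
  if (is.null(v_water_total_reference)) {
    v_water_total <- v_shyd - v_mol
    v_cos_total <- 0
  } else {
    v_water_total <- v_water_total_reference
    v_cos_total <- v_shyd - v_mol - v_water_total_reference
    if (v_cos_total < 0) {
      flags <- c(flags, "dehydration relative to reference")
      warning("negative cosolvent volume; count floored at 0", call. = FALSE)
      v_cos_total <- max(v_cos_total, 0)
    }
  }
  n_water <- round(v_water_total / solvent$water_molecular_volume)
  n_cos <- round(v_cos_total / solvent$cosolvent_molecular_volume, 1)
  structure(
    list(v_shyd = v_shyd, v_molecule = v_mol,
         v_water_total = v_water_total, n_water = n_water,
         v_cosolvent_total = v_cos_total, n_cosolvent = n_cos,
         scenario = scenario, flags = flags),
    class = "hydration_budget"
  )
}

#' @export
print.hydration_budget <- function(x, ...) {
  cat(sprintf("<hydration_budget [%s]: Vshyd %.3f = mol %.3f + water %.3f (n=%d) + cosolvent %.3f (n=%.1f) nm^3>\n",
              x$scenario, x$v_shyd, x$v_molecule, x$v_water_total,
              x$n_water, x$v_cosolvent_total, x$n_cosolvent))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
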