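#' Physical constants used throughout the package
#'
#' A fixed list with the universal gas constant `R` (8.314 J mol^-1 K^-1)
#' and the Avogadro number `N_A` (6.022e23 mol^-1), the two constants the
#' Gibbs adsorption and hydration calculations depend on. They are stored
#' at the precision conventionally used in surfactant work so that derived
#' quantities match the precision of published tables.
#'
#' @format A named list with elements `R` and `N_A`.
#' @export
micelle_constants <- list(R = 8.314, N_A = 6.022e23)

#' Temperature conversions
#'
#' Convert between Celsius and Kelvin. `celsius_to_kelvin()` refuses
#' temperatures below absolute zero.
#'
#' @param t Temperature in degrees Celsius.
#' @param t_k Temperature in Kelvin.
#' @return Temperature in the other unit (numeric, vectorized).
#' @examples
#' celsius_to_kelvin(24) # 297.15
#' @export
celsius_to_kelvin <- function(t) {
  if (any(!is.finite(t)) || any(t < -273.15)) {
    stop("temperature below absolute zero (-273.15 C) or non-finite", call. = FALSE)
  }
  t + 273.15
}

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(t_k) {
  if (any(!is.finite(t_k)) || any(t_k < 0)) {
    stop("absolute temperature must be >= 0 K", call. = FALSE)
  }
  t_k - 273.15
}

#' Concentration unit conversions
#'
#' Interfaces in this package carry concentrations in mM (matching the axes
#' of conventional titration plots); SI conversions happen inside the
#' operations that need them.
#'
#' @param c_mm Concentration in mmol/L (mM).
#' @param c_molar Concentration in mol/L.
#' @return Concentration in the other unit.
#' @export
mm_to_molar <- function(c_mm) c_mm / 1000

#' @rdname mm_to_molar
#' @export
molar_to_mm <- function(c_molar) c_molar * 1000

.response_kinds <- c("conductivity", "surface_tension", "i1i3",
                     "efflux_time", "relative_viscosity")

#' Construct a titration series
#'
#' The backbone container of the package: an ordered set of
#' (concentration, response) pairs with a response-kind tag and the
#' measurement temperature. Rows are sorted by concentration; duplicate
#' concentrations are averaged with a warning.
#'
#' @param concentration Concentrations in mM.
#' @param response Measured response (uS/cm, mN/m, I1/I3 ratio, s, or
#'   dimensionless relative viscosity depending on `response_kind`).
#' @param response_kind One of `"conductivity"`, `"surface_tension"`,
#'   `"i1i3"`, `"efflux_time"`, `"relative_viscosity"`.
#' @param temperature Measurement temperature in degrees C, in `[0, 100)`.
#' @return A data frame of class `titration_series` with columns
#'   `concentration` and `response` and attributes `response_kind` and
#'   `temperature`.
#' @export
titration_series <- function(concentration, response,
                             response_kind = .response_kinds,
                             temperature = 24) {
  response_kind <- match.arg(response_kind)
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response)) {
    stop("concentration and response must have equal length", call. = FALSE)
  }
  if (length(concentration) < 2) {
    stop("a titration series needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(!is.finite(response))) {
    stop("all concentrations and responses must be finite", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature < 0 || temperature >= 100) {
    stop("temperature must lie in [0, 100) C", call. = FALSE)
  }
  ord <- order(concentration)
  concentration <- concentration[ord]
  response <- response[ord]
  if (anyDuplicated(concentration)) {
    warning("duplicate concentrations averaged", call. = FALSE)
    response <- as.numeric(tapply(response, concentration, mean))
    concentration <- sort(unique(concentration))
  }
  structure(
    data.frame(concentration = concentration, response = response),
    response_kind = response_kind,
    temperature = temperature,
    class = c("titration_series", "data.frame")
  )
}

#' @rdname titration_series
#' @param x A `titration_series`.
#' @export
response_kind <- function(x) attr(x, "response_kind")

#' @rdname titration_series
#' @export
series_temperature <- function(x) attr(x, "temperature")

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series: %s, %d points, %.4g-%.4g mM, %g C>\n",
              response_kind(x), nrow(x), min(x$concentration),
              max(x$concentration), series_temperature(x)))
  print.data.frame(x, ...)
  invisible(x)
}

.assert_kind <- function(series, kind) {
  if (!inherits(series, "titration_series")) {
    stop("expected a titration_series", call. = FALSE)
  }
  if (!identical(response_kind(series), kind)) {
    stop(sprintf("expected response_kind '%s', got '%s'", kind,
                 response_kind(series)), call. = FALSE)
  }
  invisible(series)
}

#' Read a titration series from CSV
#'
#' Expects a comma-separated file with one header row, `.` decimal marks and
#' two numeric columns (concentration in mM, then the response); lines
#' starting with `#` are ignored. Rows are sorted and duplicate
#' concentrations averaged.
#'
#' @param path Path to the CSV file.
#' @inheritParams titration_series
#' @return A [titration_series()].
#' @export
read_titration <- function(path, response_kind = .response_kinds,
                           temperature = 24) {
  response_kind <- match.arg(response_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected two columns in ", path, call. = FALSE)
  for (j in 1:2) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & !is.na(raw[[j]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column %d, data row %d of %s",
                   raw[bad[1], j], j, bad[1], path), call. = FALSE)
    }
    raw[[j]] <- num
  }
  titration_series(raw[[1]], raw[[2]], response_kind, temperature)
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration()]: two columns, one header row, `#` comment
#' lines allowed. Used by the simulator to emit files the analysis stages
#' can read back.
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @param header_comment Optional character vector written as leading
#'   `#`-prefixed lines (e.g. simulation seed and truth parameters).
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path, header_comment = NULL) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  writeLines(sprintf("concentration_mM,%s", response_kind(series)), con)
  writeLines(sprintf("%.12g,%.12g", series$concentration, series$response), con)
  invisible(path)
}

#' Surfactant descriptor
#'
#' Static molecular information about the surfactant under study: tail
#' carbon count, tail chemistry, molecular volume and ion valences. The
#' Gibbs prefactor n (2 for a fully dissociating 1:1 ionic surfactant with
#' no swamping electrolyte) is derived from the valences.
#'
#' @param name Surfactant name.
#' @param tail_carbons Number of carbon atoms in the hydrophobic tail.
#' @param tail_chemistry `"fluorocarbon"` or `"hydrocarbon"`.
#' @param molecular_volume Dry molecular volume in nm^3.
#' @param ion_valences Integer vector of length 2: (surfactant ion,
#'   counterion) valences; both nonzero.
#' @param tail_volume,tail_length Optional explicit tail volume (A^3) and
#'   extended length (A). For fluorocarbon tails these default to the linear
#'   group-additivity formulas ([fluorotail_volume()], [fluorotail_length()]);
#'   hydrocarbon tails must supply them explicitly.
#' @return An object of class `surfactant_spec`.
#' @export
surfactant_spec <- function(name, tail_carbons,
                            tail_chemistry = c("fluorocarbon", "hydrocarbon"),
                            molecular_volume, ion_valences = c(-1L, 1L),
                            tail_volume = NULL, tail_length = NULL) {
  tail_chemistry <- match.arg(tail_chemistry)
  if (tail_carbons < 1 || tail_carbons != round(tail_carbons)) {
    stop("tail_carbons must be a positive integer", call. = FALSE)
  }
  if (!is.finite(molecular_volume) || molecular_volume <= 0) {
    stop("molecular_volume must be > 0 (nm^3)", call. = FALSE)
  }
  if (length(ion_valences) != 2 || any(ion_valences == 0)) {
    stop("ion_valences must be two nonzero integers", call. = FALSE)
  }
  if (tail_chemistry == "fluorocarbon") {
    if (is.null(tail_volume)) tail_volume <- fluorotail_volume(tail_carbons)
    if (is.null(tail_length)) tail_length <- fluorotail_length(tail_carbons)
  } else if (is.null(tail_volume) || is.null(tail_length)) {
    stop("hydrocarbon tails need explicit tail_volume and tail_length",
         call. = FALSE)
  }
  n_prefactor <- if (all(abs(ion_valences) == 1)) 2L else NA_integer_
  structure(
    list(name = name, tail_carbons = as.integer(tail_carbons),
         tail_chemistry = tail_chemistry,
         molecular_volume = molecular_volume,
         ion_valences = as.integer(ion_valences),
         tail_volume = tail_volume, tail_length = tail_length,
         n_prefactor = n_prefactor),
    class = "surfactant_spec"
  )
}

#' @export
print.surfactant_spec <- function(x, ...) {
  cat(sprintf("<surfactant_spec %s: n_c=%d (%s), V_mol=%.3f nm^3, tail %.1f A^3 / %.2f A>\n",
              x$name, x$tail_carbons, x$tail_chemistry, x$molecular_volume,
              x$tail_volume, x$tail_length))
  invisible(x)
}

#' Bundled surfactant descriptors
#'
#' `apfo_spec()`: ammonium perfluorooctanoate, C7F15-COO- NH4+, a 7-carbon
#' fluorocarbon tail and a dry molecular volume of 0.376 nm^3.
#' `sds_spec()`: sodium dodecyl sulfate, a 12-carbon hydrocarbon tail and a
#' molecular volume of 0.410 nm^3 (tail geometry must be supplied by the
#' user if packing analysis is wanted; no hydrocarbon tail formula is built
#' in).
#'
#' @return A [surfactant_spec()].
#' @export
apfo_spec <- function() {
  surfactant_spec("APFO", 7L, "fluorocarbon", 0.376, c(-1L, 1L))
}

#' @rdname apfo_spec
#' @export
sds_spec <- function() {
  # tail geometry left NULL on purpose: no hydrocarbon formula is bundled,
  # so packing analysis for SDS requires user-supplied volume/length
  structure(
    list(name = "SDS", tail_carbons = 12L, tail_chemistry = "hydrocarbon",
         molecular_volume = 0.410, ion_valences = c(-1L, 1L),
         tail_volume = NULL, tail_length = NULL, n_prefactor = 2L),
    class = "surfactant_spec"
  )
}

#' Solvent descriptor
#'
#' Describes the aqueous medium: cosolvent identity and molarity plus the
#' single-molecule volumes used in the hydration bookkeeping (water
#' 0.030 nm^3; urea 0.075 nm^3).
#'
#' @param cosolvent_name Cosolvent name (e.g. `"urea"`); `"none"` for plain
#'   water.
#' @param cosolvent_molarity Cosolvent concentration in mol/L (>= 0).
#' @param cosolvent_molecular_volume Volume of one cosolvent molecule, nm^3.
#' @param water_molecular_volume Volume of one water molecule, nm^3.
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(cosolvent_name = "none", cosolvent_molarity = 0,
                         cosolvent_molecular_volume = 0.075,
                         water_molecular_volume = 0.030) {
  if (cosolvent_molarity < 0) stop("cosolvent molarity must be >= 0", call. = FALSE)
  if (cosolvent_molecular_volume <= 0 || water_molecular_volume <= 0) {
    stop("molecular volumes must be > 0", call. = FALSE)
  }
  structure(
    list(cosolvent_name = cosolvent_name,
         cosolvent_molarity = cosolvent_molarity,
         cosolvent_molecular_volume = cosolvent_molecular_volume,
         water_molecular_volume = water_molecular_volume),
    class = "solvent_spec"
  )
}

#' @rdname solvent_spec
#' @param molarity Urea molarity in mol/L.
#' @export
urea_solvent <- function(molarity = 4) {
  solvent_spec("urea", molarity, 0.075, 0.030)
}
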