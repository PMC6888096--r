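#' Run the full analysis pipeline from a configuration
#'
#' Chains whichever stages have inputs: conductimetry (CMC, alpha),
#' tensiometry (slope, Gamma_max, Amin, CPP), fluorimetry (CMC from the
#' I1/I3 curve) and viscometry (virial fit, Vshyd, hydration budget).
#' Stages with no input are marked `"absent"`; stages that fail are marked
#' `"failed"` with the error message, and the run continues. The CMC fed
#' to the viscometry stage is, in priority order: `config$cmc`, the
#' conductivity result, the tension result.
#'
#' @param config A named list, or path to a JSON file, with elements:
#'   * `surfactant`: `"apfo"`, `"sds"`, or a list of [surfactant_spec()]
#'     arguments (required);
#'   * `inputs`: named list of CSV paths among `conductivity`, `tension`,
#'     `fluorescence` (I1/I3 ratios), `viscosity` (relative viscosity)
#'     (at least one required);
#'   * optional: `solvent` (list of [solvent_spec()] arguments),
#'     `temperature` (named list per stage, degrees C), `n_prefactor`,
#'     `nu`, `cmc`, `reference_water_volume` (nm^3).
#' @return A nested list of class `micellar_report` with one section per
#'   stage plus derived `packing` and `hydration` sections; every value
#'   carries explicit units in its key name where ambiguous.
#' @export
run_report <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || length(config) == 0 ||
      is.null(config$surfactant) || is.null(config$inputs) ||
      length(config$inputs) == 0) {
    stop("config must provide at least: surfactant, inputs ",
         "(one or more of conductivity, tension, fluorescence, viscosity); ",
         "optional: solvent, temperature, n_prefactor, nu, cmc, ",
         "reference_water_volume", call. = FALSE)
  }
  spec <- .resolve_surfactant(config$surfactant)
  solvent <- if (is.null(config$solvent)) solvent_spec()
  else do.call(solvent_spec, config$solvent)
  temp <- function(stage, default) {
    t <- config$temperature
    if (is.list(t) && !is.null(t[[stage]])) t[[stage]] else
      if (is.numeric(t) && length(t) == 1) t else default
  }

  stage <- function(name, f) {
    path <- config$inputs[[name]]
    if (is.null(path)) return(list(status = "absent"))
    tryCatch(c(list(status = "ok"), f(path)),
             error = function(e) list(status = "failed",
                                      message = conditionMessage(e)))
  }

  conduct <- stage("conductivity", function(p) {
    s <- read_titration(p, "conductivity", temp("conductivity", 24))
    fit <- fit_two_segments(s)
    list(cmc_mM = fit$cmc, alpha = fit$alpha, s1 = fit$s1, s2 = fit$s2,
         rss = fit$rss, cmc_sd_mM = fit$cmc_sd,
         flags = as.list(fit$flags))
  })

  tension <- stage("tension", function(p) {
    s <- read_titration(p, "surface_tension", temp("tension", 24))
    n_pref <- if (!is.null(config$n_prefactor)) config$n_prefactor
    else if (is.na(spec$n_prefactor)) stop("n_prefactor needed for non 1:1 valences")
    else spec$n_prefactor
    res <- analyze_tension(s, n_prefactor = n_pref, surfactant = spec)
    list(slope_mN_m_decade = res$slope, gamma_max_mol_cm2 = res$gamma_max,
         a_min_A2 = res$a_min, a_min_sd_A2 = res$a_min_sd,
         cmc_mM = res$cmc_tension, plateau_gamma_mN_m = res$plateau_gamma,
         n_prefactor = n_pref, window_mM = as.list(res$window),
         flags = as.list(res$flags),
         packing = if (is.null(res$packing)) NULL else
           list(cpp = res$packing$cpp, cpp_display = res$packing$cpp_display,
                shape_class = res$packing$shape_class,
                boundary = res$packing$boundary))
  })

  fluor <- stage("fluorescence", function(p) {
    s <- read_titration(p, "i1i3", temp("fluorescence", 22))
    res <- cmc_from_ratio_curve(s)
    list(cmc_mM = res$cmc, variant = res$variant, flags = as.list(res$flags))
  })

  cmc_used <- config$cmc
  if (is.null(cmc_used) && identical(conduct$status, "ok")) cmc_used <- conduct$cmc_mM
  if (is.null(cmc_used) && identical(tension$status, "ok") &&
      is.finite(tension$cmc_mM %||% NA)) cmc_used <- tension$cmc_mM

  visc <- stage("viscosity", function(p) {
    if (is.null(cmc_used)) stop("no CMC available for the viscometry stage")
    s <- read_titration(p, "relative_viscosity", temp("viscosity", 20))
    nu <- config$nu %||% 2.5
    fit <- fit_virial(s, cmc = cmc_used, nu = nu)
    out <- list(p1_L_mol = fit$p1, p2 = fit$p2, k1 = fit$k1, nu = nu,
                v_shyd_nm3 = fit$v_shyd, c1_mM = fit$c1, rss = fit$rss,
                flags = as.list(fit$flags))
    if (is.finite(fit$v_shyd %||% NA) && fit$v_shyd >= spec$molecular_volume) {
      budget <- hydration_budget(fit$v_shyd, spec, solvent,
                                 v_water_total_reference =
                                   config$reference_water_volume)
      out$hydration <- list(
        v_molecule_nm3 = budget$v_molecule,
        v_water_total_nm3 = budget$v_water_total, n_water = budget$n_water,
        v_cosolvent_total_nm3 = budget$v_cosolvent_total,
        n_cosolvent = budget$n_cosolvent, flags = as.list(budget$flags))
    }
    out
  })

  structure(
    list(surfactant = list(name = spec$name, tail_carbons = spec$tail_carbons,
                           molecular_volume_nm3 = spec$molecular_volume),
         solvent = list(cosolvent = solvent$cosolvent_name,
                        cosolvent_molarity = solvent$cosolvent_molarity),
         conductivity = conduct, tension = tension, fluorescence = fluor,
         viscosity = visc,
         cmc_used_mM = if (is.null(cmc_used)) NA else cmc_used),
    class = "micellar_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_surfactant <- function(x) {
  if (inherits(x, "surfactant_spec")) return(x)
  if (is.character(x)) {
    return(switch(tolower(x),
                  apfo = apfo_spec(),
                  sds = sds_spec(),
                  stop("unknown surfactant '", x,
                       "'; bundled specs: apfo, sds", call. = FALSE)))
  }
  do.call(surfactant_spec, x)
}

#' @export
print.micellar_report <- function(x, ...) {
  cat("<micellar_report>\n")
  fmt <- function(v) if (is.numeric(v)) sprintf("%.4g", v) else as.character(v)
  for (sec in c("conductivity", "tension", "fluorescence", "viscosity")) {
    s <- x[[sec]]
    cat(sprintf("  %-12s %s", sec, s$status))
    if (identical(s$status, "ok") && !is.null(s$cmc_mM)) {
      cat(sprintf("  (CMC %.4g mM)", s$cmc_mM))
    }
    cat("\n")
  }
  cat("  CMC in use:", fmt(x$cmc_used_mM), "mM\n")
  invisible(x)
}

#' Write / read a report as canonical JSON
#'
#' Serialization is canonical: keys sorted recursively, 12-significant-digit
#' float formatting, two-space pretty printing. Reading a written report and
#' re-serializing it is byte-identical, so reports can be diffed and
#' version-controlled.
#'
#' @param report A report list (e.g. from [run_report()]).
#' @param path Output / input JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed list.
#' @export
write_report <- function(report, path) {
  canon <- .canonicalize(report)
  json <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = I(12),
                           pretty = 2, null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.canonicalize <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, .canonicalize)
  } else x
}
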