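#' Fluorocarbon tail volume
#'
#' Group-additivity volume of a linear perfluorinated tail with `n_c`
#' carbons: one CF3 group (84.0 A^3) and `n_c - 1` CF2 groups (41.6 A^3
#' each), i.e. `41.6 * n_c + 42.4` A^3.
#'
#' @param n_c Integer tail carbon count (>= 1).
#' @return Tail volume in A^3.
#' @examples
#' fluorotail_volume(7) # 333.6, the C7F15 tail of APFO
#' @export
fluorotail_volume <- function(n_c) {
  .check_nc(n_c)
  41.6 * n_c + 42.4
}

#' Extended fluorocarbon tail length
#'
#' Extended (all-trans) length of a linear fluorocarbon chain with `n_c`
#' carbons: `1.3 * n_c + 2.04` Angstrom.
#'
#' @inheritParams fluorotail_volume
#' @return Extended tail length in Angstrom.
#' @examples
#' fluorotail_length(7) # 11.14
#' @export
fluorotail_length <- function(n_c) {
  .check_nc(n_c)
  1.3 * n_c + 2.04
}

.check_nc <- function(n_c) {
  if (any(!is.finite(n_c)) || any(n_c < 1) || any(n_c != round(n_c))) {
    stop("n_c must be an integer >= 1", call. = FALSE)
  }
  invisible(n_c)
}

#' Critical packing parameter and micelle shape class
#'
#' CPP = V0 / (Amin * lc), where V0 is the tail volume (A^3), Amin the
#' interfacial area per headgroup (A^2) and lc the extended tail length (A).
#' The shape class follows the standard curvature bands, with the exact
#' fractions 1/3 and 1/2 as boundaries:
#' sphere (CPP <= 1/3), cylinder (1/3 < CPP <= 1/2), bilayer
#' (1/2 < CPP <= 1), inverted (CPP > 1). A value within 0.01 of a band
#' boundary carries a `"boundary"` annotation, since experimental CPPs near
#' 1/3 are routinely read as "close to spherical".
#'
#' @param volume Tail volume V0 in A^3.
#' @param amin Area per headgroup Amin in A^2.
#' @param length Extended tail length lc in Angstrom.
#' @return An object of class `packing_result`: list with `cpp` (full
#'   precision), `cpp_display` (2-decimal convention), `shape_class`,
#'   `boundary` flag, and `amin_used`.
#' @examples
#' packing_parameter(fluorotail_volume(7), 63.84, fluorotail_length(7))
#' @export
packing_parameter <- function(volume, amin, length) {
  if (any(!is.finite(c(volume, amin, length))) ||
      volume <= 0 || amin <= 0 || length <= 0) {
    stop("volume, amin and length must all be positive", call. = FALSE)
  }
  cpp <- volume / (amin * length)
  shape_class <- if (cpp <= 1 / 3) "sphere"
  else if (cpp <= 1 / 2) "cylinder"
  else if (cpp <= 1) "bilayer"
  else "inverted"
  boundary <- min(abs(cpp - c(1 / 3, 1 / 2, 1))) <= 0.01
  structure(
    list(cpp = cpp, cpp_display = round(cpp, 2), shape_class = shape_class,
         boundary = boundary, amin_used = amin),
    class = "packing_result"
  )
}

#' @export
print.packing_result <- function(x, ...) {
  cat(sprintf("<packing_result: CPP = %.3f (displays %.2f), shape %s%s, Amin %.2f A^2>\n",
              x$cpp, x$cpp_display, x$shape_class,
              if (x$boundary) " [boundary]" else "", x$amin_used))
  invisible(x)
}
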