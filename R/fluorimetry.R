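#' Construct a pyrene emission spectrum
#'
#' Wavelength/intensity pairs on an ascending nm grid. The grid must cover
#' at least 365-395 nm so that both vibronic peak windows are sampled.
#'
#' @param wavelength Ascending wavelength grid, nm.
#' @param intensity Nonnegative intensities (arbitrary units), not all zero.
#' @param label Sample concentration in mM (optional).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, intensity, label = NA_real_) {
  if (length(wavelength) != length(intensity)) {
    stop("wavelength and intensity must have equal length", call. = FALSE)
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelength grid must be strictly ascending", call. = FALSE)
  }
  if (min(wavelength) > 365 || max(wavelength) < 395) {
    stop("spectrum must cover at least 365-395 nm", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0) || all(intensity == 0)) {
    stop("intensities must be finite, >= 0 and not all zero", call. = FALSE)
  }
  structure(
    data.frame(wavelength = wavelength, intensity = intensity),
    label = label,
    class = c("emission_spectrum", "data.frame")
  )
}

#' Read an emission spectrum from CSV
#'
#' Two numeric columns (wavelength_nm, intensity), one header row, `#`
#' comments ignored.
#'
#' @param path CSV path.
#' @param label Sample concentration in mM (optional).
#' @return An [emission_spectrum()].
#' @export
read_spectrum <- function(path, label = NA_real_) {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected two columns in ", path, call. = FALSE)
  emission_spectrum(as.numeric(raw[[1]]), as.numeric(raw[[2]]), label)
}

#' First/third vibronic peak intensities and their ratio
#'
#' Extracts I1 as the maximum intensity in the first-peak window (default
#' 370-376 nm, centred on pyrene's canonical 373 nm band) and I3 in the
#' third-peak window (default 380-386 nm, centred on the 383 nm band), and
#' returns the micropolarity ratio I1/I3. If a window's maximum sits on the
#' window edge (no interior local maximum) the edge value is used and the
#' result flagged.
#'
#' @param spectrum An [emission_spectrum()] covering both windows.
#' @param window1,window3 Length-2 nm intervals searched for I1 and I3.
#' @return An object of class `vibronic_ratios`: `i1`, `i3`, `ratio`,
#'   `lambda1`, `lambda3`, `windows`, `flags`.
#' @export
vibronic_ratio <- function(spectrum, window1 = c(370, 376),
                           window3 = c(380, 386)) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  pk <- function(win, name) {
    sel <- which(spectrum$wavelength >= win[1] & spectrum$wavelength <= win[2])
    if (!length(sel)) stop("spectrum does not cover the ", name, " window",
                           call. = FALSE)
    j <- sel[which.max(spectrum$intensity[sel])]
    flag <- if (j == sel[1] || j == sel[length(sel)]) {
      paste0(name, " peak at window edge")
    } else character(0)
    list(i = spectrum$intensity[j], lambda = spectrum$wavelength[j], flag = flag)
  }
  p1 <- pk(window1, "I1")
  p3 <- pk(window3, "I3")
  if (p1$i <= 0 || p3$i <= 0) stop("peak intensities must be positive", call. = FALSE)
  structure(
    list(i1 = p1$i, i3 = p3$i, ratio = p1$i / p3$i,
         lambda1 = p1$lambda, lambda3 = p3$lambda,
         windows = list(i1 = window1, i3 = window3),
         flags = c(p1$flag, p3$flag)),
    class = "vibronic_ratios"
  )
}

#' @export
print.vibronic_ratios <- function(x, ...) {
  cat(sprintf("<vibronic_ratios: I1 %.4g @ %.1f nm, I3 %.4g @ %.1f nm, I1/I3 = %.3f>\n",
              x$i1, x$lambda1, x$i3, x$lambda3, x$ratio))
  invisible(x)
}

#' Normalize a spectrum by its first vibronic peak
#'
#' Divides every intensity by I1 so that the value at the first-peak
#' wavelength equals 1; the conventional presentation of pyrene monomer
#' spectra. Idempotent and invariant to overall scaling.
#'
#' @inheritParams vibronic_ratio
#' @return The normalized [emission_spectrum()].
#' @export
normalize_by_i1 <- function(spectrum, window1 = c(370, 376)) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  sel <- which(spectrum$wavelength >= window1[1] &
                 spectrum$wavelength <= window1[2])
  i1 <- max(spectrum$intensity[sel])
  if (i1 <= 0) stop("I1 is zero; cannot normalize", call. = FALSE)
  emission_spectrum(spectrum$wavelength, spectrum$intensity / i1,
                    attr(spectrum, "label"))
}

#' CMC from the I1/I3 ratio curve
#'
#' Intersection estimator: a line is fitted to the low-concentration
#' plateau of the I1/I3 curve and another to the steepest part of the
#' decrease (near the inflection); the CMC is the abscissa where the two
#' lines cross. This is the variant that tracks conductivity-derived CMCs;
#' the alternative pairing of the descent line with the upper (high
#' concentration) plateau is available via `variant = "upper"`.
#'
#' The descent run is the point of steepest negative finite difference plus
#' `k` neighbours on each side (ties on the steepest difference resolved to
#' the middle tied interval, which centres the window on long uniform
#' descents). The plateau comprises the points before the first interval
#' whose slope reaches `plateau_frac` times the steepest slope — a
#' shift-invariant rule that excludes the onset of the decrease; the fitted
#' plateau line may be shallow rather than exactly horizontal.
#'
#' @param series An i1i3 [titration_series()] (>= 6 points) showing a
#'   plateau followed by a decrease.
#' @param k Descent half-width in points (default 2).
#' @param plateau_frac Fraction of the steepest descent slope at which a
#'   point is considered to have left the plateau (default 0.25).
#' @param variant `"lower"` (default) intersects descent with the lower
#'   plateau; `"upper"` with the terminal plateau.
#' @return List of class `fluor_cmc`: `cmc` (mM), `plateau_line`,
#'   `descent_line` (intercept/slope pairs), `plateau_idx`, `descent_idx`,
#'   `flags`.
#' @export
cmc_from_ratio_curve <- function(series, k = 2, plateau_frac = 0.25,
                                 variant = c("lower", "upper")) {
  .assert_kind(series, "i1i3")
  variant <- match.arg(variant)
  x <- series$concentration
  y <- series$response
  n <- length(x)
  if (n < 6) stop("insufficient data: need >= 6 points", call. = FALSE)
  third <- max(2, floor(n / 3))
  if (mean(y[1:third]) <= mean(y[(n - third + 1):n])) {
    stop("no CMC signature: ratio curve does not decrease", call. = FALSE)
  }

  slopes <- diff(y) / diff(x)
  steep <- min(slopes)
  tied <- which(slopes <= steep + 1e-12 * abs(steep))
  m <- tied[ceiling(length(tied) / 2)] # middle of tied steepest intervals
  descent_idx <- max(1, m - k + 1):min(n, m + k)
  if (length(descent_idx) < 2) stop("descent run too short", call. = FALSE)
  dfit <- stats::lm(y[descent_idx] ~ x[descent_idx])
  a2 <- unname(stats::coef(dfit)[1]); b2 <- unname(stats::coef(dfit)[2])

  flags <- character(0)
  thresh <- plateau_frac * steep # both negative
  if (variant == "lower") {
    first_drop <- which(slopes <= thresh)[1]
    plateau_idx <- seq_len(max(1, first_drop - 1))
  } else {
    last_drop <- max(which(slopes <= thresh))
    plateau_idx <- seq(min(n, last_drop + 2), n)
  }
  if (length(plateau_idx) >= 2) {
    pfit <- stats::lm(y[plateau_idx] ~ x[plateau_idx])
    a1 <- unname(stats::coef(pfit)[1]); b1 <- unname(stats::coef(pfit)[2])
  } else {
    a1 <- y[plateau_idx]; b1 <- 0
    flags <- c(flags, "single-point plateau: horizontal line assumed")
  }

  if (abs(b2 - b1) < .Machine$double.eps^0.5) {
    stop("plateau and descent lines are parallel; no intersection", call. = FALSE)
  }
  cmc <- (a1 - a2) / (b2 - b1)
  if (cmc < min(x) || cmc > max(x)) flags <- c(flags, "extrapolated intersection")

  structure(
    list(cmc = cmc, plateau_line = c(intercept = a1, slope = b1),
         descent_line = c(intercept = a2, slope = b2),
         plateau_idx = plateau_idx, descent_idx = descent_idx,
         variant = variant, flags = flags),
    class = "fluor_cmc"
  )
}

#' @export
print.fluor_cmc <- function(x, ...) {
  cat(sprintf("<fluor_cmc: CMC = %.4g mM (%s-plateau intersection)>\n",
              x$cmc, x$variant))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
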