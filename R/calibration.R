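#' Photoreceptor calibration
#'
#' Converts photon flux at the preparation into photoisomerization rates.
#' The conversion multiplies the flux by the photoreceptor collecting area
#' (1.0 um^2 for rods, 0.37 um^2 for cones) and by the spectral overlap
#' between the light source emission spectrum and the photoreceptor
#' absorption spectrum, computed on their shared wavelength grid as the
#' emission-weighted mean absorption.
#'
#' @param collecting_area Effective collecting area in um^2 (> 0).
#' @param emission Named list or data.frame with `wavelength` (nm) and
#'   `power` (relative emission, >= 0).
#' @param absorption Named list or data.frame with `wavelength` (nm) and
#'   `sensitivity` (relative absorption, >= 0).
#' @return An object of class `"photoreceptor_calibration"`.
#' @examples
#' wl <- 400:700
#' cal <- photoreceptor_calibration(
#'   1.0,
#'   emission = list(wavelength = wl, power = dnorm(wl, 460, 15)),
#'   absorption = list(wavelength = wl, sensitivity = dnorm(wl, 500, 40))
#' )
#' photoisomerization_rate(100, cal)
#' @export
photoreceptor_calibration <- function(collecting_area, emission, absorption) {
  stopifnot_scalar(collecting_area, "collecting_area", positive = TRUE)
  emission <- as.data.frame(emission)
  absorption <- as.data.frame(absorption)
  if (!all(c("wavelength", "power") %in% names(emission))) {
    stop("`emission` needs fields wavelength and power", call. = FALSE)
  }
  if (!all(c("wavelength", "sensitivity") %in% names(absorption))) {
    stop("`absorption` needs fields wavelength and sensitivity", call. = FALSE)
  }
  if (any(emission$power < 0) || any(absorption$sensitivity < 0)) {
    stop("spectra must be non-negative", call. = FALSE)
  }
  shared <- intersect(emission$wavelength, absorption$wavelength)
  if (length(shared) == 0L) {
    stop("emission and absorption spectra share no wavelengths", call. = FALSE)
  }
  structure(list(collecting_area = collecting_area, emission = emission,
                 absorption = absorption, shared_wavelengths = shared),
            class = "photoreceptor_calibration")
}

#' @rdname photoreceptor_calibration
#' @param flux Photon flux in photons/um^2/s (>= 0; may be a vector).
#' @param cal A `"photoreceptor_calibration"`.
#' @return For `photoisomerization_rate()`: rate(s) in
#'   R*/photoreceptor/s.
#' @export
photoisomerization_rate <- function(flux, cal) {
  stopifnot(inherits(cal, "photoreceptor_calibration"))
  if (any(flux < 0)) stop("`flux` must be >= 0", call. = FALSE)
  flux * cal$collecting_area * spectral_overlap(cal)
}

# Emission-weighted mean absorption over the shared wavelength grid.
spectral_overlap <- function(cal) {
  wl <- cal$shared_wavelengths
  em <- cal$emission$power[match(wl, cal$emission$wavelength)]
  ab <- cal$absorption$sensitivity[match(wl, cal$absorption$wavelength)]
  if (sum(em) == 0) return(0)
  sum(em * ab) / sum(em)
}

#' @export
print.photoreceptor_calibration <- function(x, ...) {
  cat(sprintf(
    "<photoreceptor_calibration> area %.3g um^2, overlap %.4g (%d shared wavelengths)\n",
    x$collecting_area, spectral_overlap(x), length(x$shared_wavelengths)))
  invisible(x)
}

#' Standard rod and cone collecting areas
#'
#' Convenience constructors with the standard primate collecting areas
#' (rod 1.0 um^2, cone 0.37 um^2) and user-supplied spectra.
#'
#' @param emission,absorption Spectra as in [photoreceptor_calibration()].
#' @return A `"photoreceptor_calibration"`.
#' @export
rod_calibration <- function(emission, absorption) {
  photoreceptor_calibration(1.0, emission, absorption)
}

#' @rdname rod_calibration
#' @export
cone_calibration <- function(emission, absorption) {
  photoreceptor_calibration(0.37, emission, absorption)
}
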