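#' Construct a Gaussian spectral reflectance peak
#'
#' A minimal description of a structural-color reflectance spectrum: a
#' Gaussian peak of given center wavelength and full-width-half-maximum
#' riding on a flat baseline. Reflectance is dimensionless in `[0, 1]`.
#'
#' @param center_nm Peak center wavelength in nanometres; clamped to the
#'   visible range `[380, 780]` (the clamp is recorded in the `clamped`
#'   field).
#' @param width_nm Full width at half maximum in nanometres; must be > 0.
#' @param amplitude Peak reflectance in `[0, 1]`.
#' @param baseline Off-peak reflectance in `[0, baseline <= amplitude]`.
#' @return An object of class `"spectral_peak"`.
#' @examples
#' spectral_peak(550, 30)
#' @export
spectral_peak <- function(center_nm, width_nm = 30, amplitude = 0.9,
                          baseline = 0.05) {
  if (!is.finite(center_nm))
    stop_csa("center_nm must be finite", class = "invalid_parameter")
  if (!is.finite(width_nm) || width_nm <= 0)
    stop_csa("width_nm must be > 0", class = "invalid_parameter")
  if (baseline < 0 || amplitude > 1 || baseline > amplitude)
    stop_csa("need 0 <= baseline <= amplitude <= 1",
             class = "invalid_parameter")
  clamped <- center_nm < 380 || center_nm > 780
  structure(
    list(center_nm = min(max(center_nm, 380), 780), width_nm = width_nm,
         amplitude = amplitude, baseline = baseline, clamped = clamped),
    class = "spectral_peak")
}

#' Bragg reflection peak of a swollen periodic nanostructure
#'
#' First-order normal-incidence Bragg reflection from a film with structure
#' period `d`: the reflected wavelength is `lambda = 2 * n_eff * d * (1 + s)`
#' where `s` is the fractional swelling of the period. Analyte uptake swells
#' the self-assembled film, increasing `d` and red-shifting the reflected
#' color; this is the optical mechanism behind the sensor's response.
#'
#' @param period_nm Unswollen structure period `d` in nanometres (> 0).
#' @param n_eff Effective refractive index of the film (>= 1).
#' @param swelling_fraction Fractional period increase `s` (>= 0).
#' @param ... Passed to [spectral_peak()] (`width_nm`, `amplitude`,
#'   `baseline`).
#' @return A `"spectral_peak"` whose center is the Bragg wavelength, clamped
#'   to the visible range.
#' @examples
#' bragg_peak(150, 1.5, 0)    # 450 nm, blue film
#' bragg_peak(150, 1.5, 0.1)  # swollen: 495 nm
#' @export
bragg_peak <- function(period_nm, n_eff, swelling_fraction = 0, ...) {
  if (!is.finite(period_nm) || period_nm <= 0)
    stop_csa("period_nm must be > 0", class = "invalid_parameter")
  if (!is.finite(n_eff) || n_eff < 1)
    stop_csa("n_eff must be >= 1", class = "invalid_parameter")
  if (!is.finite(swelling_fraction) || swelling_fraction < 0)
    stop_csa("swelling_fraction must be >= 0", class = "invalid_parameter")
  spectral_peak(2 * n_eff * period_nm * (1 + swelling_fraction), ...)
}

#' CIE 1931 2-degree colour-matching functions
#'
#' Analytic piecewise-Gaussian fit of the CIE 1931 standard observer
#' (Wyman, Sloan & Shirley 2013), accurate to about 1% of peak — ample for
#' rendering smooth reflectance spectra.
#'
#' @param lambda_nm Wavelengths in nanometres.
#' @return A matrix with columns `x`, `y`, `z`.
#' @keywords internal
cie_cmf <- function(lambda_nm) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  x <- 1.056 * g(lambda_nm, 599.8, 37.9, 31.0) +
       0.362 * g(lambda_nm, 442.0, 16.0, 26.7) -
       0.065 * g(lambda_nm, 501.1, 20.4, 26.2)
  y <- 0.821 * g(lambda_nm, 568.8, 46.9, 40.5) +
       0.286 * g(lambda_nm, 530.9, 16.3, 31.1)
  z <- 1.217 * g(lambda_nm, 437.0, 11.8, 36.0) +
       0.681 * g(lambda_nm, 459.0, 26.0, 13.8)
  cbind(x = x, y = y, z = z)
}

# Reflectance of a spectral_peak on a wavelength grid.
peak_reflectance <- function(peak, lambda_nm) {
  peak$baseline + (peak$amplitude - peak$baseline) *
    exp(-4 * log(2) * ((lambda_nm - peak$center_nm) / peak$width_nm)^2)
}

#' Render a spectral peak to an 8-bit sRGB triple
#'
#' Integrates the Gaussian reflectance spectrum against the CIE 1931
#' 2-degree colour-matching functions on a wavelength grid (default 10 nm
#' over 380-780 nm), normalised so a flat unit spectrum has luminance
#' `Y = 1`, then converts XYZ to linear sRGB (D65 primaries), applies the
#' sRGB transfer curve, and quantises to 8-bit integers. Out-of-gamut
#' channels are clipped and flagged.
#'
#' @param peak A `"spectral_peak"`.
#' @param step_nm Sampling step of the wavelength grid in nanometres.
#' @return Integer vector `c(R, G, B)` in `[0, 255]`, with attribute
#'   `gamut_clipped` (logical).
#' @examples
#' spectrum_to_rgb8(spectral_peak(550, 30))  # green-dominant
#' @export
spectrum_to_rgb8 <- function(peak, step_nm = 10) {
  stopifnot(inherits(peak, "spectral_peak"))
  lam <- seq(380, 780, by = step_nm)
  cmf <- cie_cmf(lam)
  refl <- peak_reflectance(peak, lam)
  xyz <- colSums(refl * cmf) / sum(cmf[, "y"])
  # linear sRGB, D65 primaries (IEC 61966-2-1 matrix)
  m <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  lin <- drop(m %*% xyz)
  clipped <- any(lin < 0) || any(lin > 1)
  lin <- pmin(pmax(lin, 0), 1)
  srgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                 1.055 * lin^(1 / 2.4) - 0.055)
  out <- as.integer(round(255 * srgb))
  names(out) <- c("R", "G", "B")
  attr(out, "gamut_clipped") <- clipped
  out
}
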