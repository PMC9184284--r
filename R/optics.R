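#' Optical model for nanochannel scattering contrast
#'
#' Bundles the optical constants that relate a molecule's integrated optical
#' contrast (iOC) to its molecular weight, together with the imaging
#' parameters of the kymograph (line-spread width, pixel pitch, noise level,
#' frame rate).
#'
#' The mass-polarizability constant `a` converts molecular weight to optical
#' polarizability (alpha_m = a * MW) and defaults to 0.46 A^3/Da
#' (4.6e-4 nm^3/Da), an average over a large set of proteins. The contrast
#' factor `nbar` is derived from the refractive indices of the medium and the
#' channel wall; it is negative for a water-filled channel in silica, which
#' is why molecules appear as dark dips in the differential image.
#'
#' @param n_medium Refractive index of the liquid in the channel (water: 1.33).
#' @param n_wall Refractive index of the channel wall material (fused silica:
#'   1.46).
#' @param a Mass polarizability constant in nm^3 per Da.
#' @param psf_sigma Standard deviation of the 1-D Gaussian line-spread
#'   function, in nm.
#' @param pixel_pitch Kymograph pixel size along the channel axis, in nm.
#' @param noise_rel Per-pixel relative contrast noise (standard deviation of
#'   the processed kymograph background), dimensionless. Default 5e-5
#'   (0.005\%).
#' @param frame_rate Acquisition rate of the processed kymograph in frames
#'   per second.
#' @return An object of class `optical_model` (a list with the fields above
#'   plus the derived `nbar`).
#' @seealso [contrast_factor()], [mw_from_ioc()], [ioc_from_mw()]
#' @examples
#' om <- optical_model()
#' om$nbar  # about -10.25 for water in silica
#' @export
optical_model <- function(n_medium = 1.33, n_wall = 1.46, a = 4.6e-4,
                          psf_sigma = 100, pixel_pitch = 30,
                          noise_rel = 5e-5, frame_rate = 200) {
  stopifnot(n_medium > 0, n_wall > 0, a > 0, psf_sigma > 0,
            pixel_pitch > 0, noise_rel >= 0, frame_rate > 0)
  obj <- list(
    n_medium = n_medium, n_wall = n_wall, a = a,
    nbar = contrast_factor(n_medium, n_wall),
    psf_sigma = psf_sigma, pixel_pitch = pixel_pitch,
    noise_rel = noise_rel, frame_rate = frame_rate
  )
  class(obj) <- "optical_model"
  obj
}

#' @export
print.optical_model <- function(x, ...) {
  cat("<optical_model>\n")
  cat(sprintf("  n_medium = %.3f, n_wall = %.3f, nbar = %.4f\n",
              x$n_medium, x$n_wall, x$nbar))
  cat(sprintf("  a = %.3g nm^3/Da, psf_sigma = %g nm, pixel_pitch = %g nm\n",
              x$a, x$psf_sigma, x$pixel_pitch))
  cat(sprintf("  noise_rel = %.3g, frame_rate = %g fps\n",
              x$noise_rel, x$frame_rate))
  invisible(x)
}

#' Interference contrast factor of a filled nanochannel
#'
#' Computes the dimensionless factor
#' \deqn{\bar n = (1.5 n_m^2 + 0.5 n_w^2) / (n_m^2 - n_w^2)}
#' that scales the relative differential contrast of a molecule inside a
#' channel of medium index `n_medium` embedded in wall material of index
#' `n_wall`. Negative when the wall is optically denser than the medium.
#'
#' @inheritParams optical_model
#' @return The signed contrast factor (scalar).
#' @examples
#' contrast_factor(1.33, 1.46)  # -10.254
#' @export
contrast_factor <- function(n_medium, n_wall) {
  stopifnot(n_medium > 0, n_wall > 0)
  den <- n_medium^2 - n_wall^2
  if (abs(den) < .Machine$double.eps * (n_medium^2 + n_wall^2)) {
    stop("degenerate contrast: n_medium and n_wall are equal, ",
         "the contrast factor is undefined")
  }
  (1.5 * n_medium^2 + 0.5 * n_wall^2) / den
}

#' Molecular polarizability from molecular weight
#'
#' Linear mass-polarizability relation alpha_m = a * MW. The
#' proportionality holds across proteins because the number of electrons,
#' and hence the optical extinction, scales with mass.
#'
#' @param mw Molecular weight in Da.
#' @param model An [optical_model()] supplying the constant `a`.
#' @return Polarizability volume in nm^3.
#' @export
polarizability_from_mw <- function(mw, model = optical_model()) {
  if (any(mw < 0)) stop("molecular weight must be non-negative")
  model$a * mw
}

#' Convert integrated optical contrast to molecular weight
#'
#' Implements the mass calibration
#' \deqn{MW = iOC \cdot A / (\bar n a)}
#' where `ioc` is the integrated optical contrast of a molecule (relative
#' contrast integrated along the channel, units of nm), `area` the channel
#' cross-sectional area in nm^2, and `nbar`, `a` come from the optical
#' model. Both `ioc` and `nbar` are negative in the default water-in-silica
#' configuration, so a positive mass emerges from signed inputs; magnitudes
#' are used so that either sign convention gives the same (non-negative)
#' mass.
#'
#' @param ioc Integrated optical contrast in nm (signed; dips are negative).
#' @param area Channel cross-sectional area in nm^2.
#' @param model An [optical_model()].
#' @return Molecular weight in Da (non-negative).
#' @examples
#' mw_from_ioc(-1.1687, 2700)  # about 669 kDa (thyroglobulin, Channel I)
#' @export
mw_from_ioc <- function(ioc, area, model = optical_model()) {
  if (any(area <= 0)) stop("channel area must be positive")
  abs(ioc) * area / (abs(model$nbar) * model$a)
}

#' Convert molecular weight to integrated optical contrast
#'
#' Exact inverse of [mw_from_ioc()]: iOC = MW * nbar * a / A. Returns a
#' signed contrast, negative in the default configuration (dark dips).
#'
#' @param mw Molecular weight in Da.
#' @param area Channel cross-sectional area in nm^2.
#' @param model An [optical_model()].
#' @return Integrated optical contrast in nm (signed).
#' @examples
#' ioc_from_mw(669000, 2700)  # -1.1687 nm
#' @export
ioc_from_mw <- function(mw, area, model = optical_model()) {
  if (any(mw < 0)) stop("molecular weight must be non-negative")
  if (any(area <= 0)) stop("channel area must be positive")
  mw * model$nbar * model$a / area
}

#' Intensity model for channel-molecule interference
#'
#' Describes the absolute dark-field intensities in the interference picture:
#' the channel scatters with per-length polarizability `alpha_channel`
#' (negative for a water-filled groove in silica), a molecule inside it with
#' polarizability `alpha_molecule`, and the collected field is their coherent
#' sum over an effective segment length `L`. Only relative contrasts matter
#' for the analysis pipeline; this model exists for consistency checks and
#' for exploring the interference amplification of the molecular signal.
#'
#' The default `alpha_channel` magnitude is a slab-contrast surrogate,
#' A |n_wall^2 - n_medium^2| / (n_wall^2 + n_medium^2), for a channel of
#' cross-section `area`.
#'
#' @param I0 Incident intensity (arbitrary units).
#' @param collection Collection efficiency (dimensionless, arbitrary scale).
#' @param wavelength Central illumination wavelength in nm (default 600, the
#'   mid-band of a 450-750 nm source).
#' @param L Effective diffraction-limited segment length in nm; defaults to
#'   3 pi / (2 k) for wavenumber k = 2 pi n_medium / wavelength.
#' @param alpha_channel Per-length channel polarizability in nm^2 (signed,
#'   negative for water in silica).
#' @param alpha_molecule Molecular polarizability in nm^3 (signed, positive).
#' @param area Channel cross-section in nm^2 used for the default
#'   `alpha_channel`.
#' @param model An [optical_model()] supplying refractive indices.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(I0 = 1, collection = 1, wavelength = 600,
                            L = NULL, alpha_channel = NULL,
                            alpha_molecule = polarizability_from_mw(66000),
                            area = 2700, model = optical_model()) {
  stopifnot(I0 > 0, collection > 0, wavelength > 0)
  k <- 2 * pi * model$n_medium / wavelength
  if (is.null(L)) L <- 3 * pi / (2 * k)
  stopifnot(L > 0)
  if (is.null(alpha_channel)) {
    alpha_channel <- -area * abs(model$n_wall^2 - model$n_medium^2) /
      (model$n_wall^2 + model$n_medium^2)
  }
  obj <- list(I0 = I0, collection = collection, k = k, L = L,
              alpha_channel = alpha_channel,
              alpha_molecule = alpha_molecule)
  class(obj) <- "intensity_model"
  obj
}

#' Interference intensities of channel, molecule and their cross term
#'
#' Evaluates the dark-field intensity decomposition
#' I_c = c I0 L |alpha_c|^2 k^3 / 4 (channel),
#' I_m = c I0 |alpha_m|^2 k^4 / (6 pi) (molecule), and the interference
#' term Delta I_t = -2 sqrt(I_c I_m) by which the channel amplifies the
#' molecular signal. For any realistic molecule |Delta I_t| greatly exceeds
#' the bare molecular scattering I_m, which is the working principle of the
#' technique.
#'
#' @param im An [intensity_model()].
#' @return A list with `I_c`, `I_m`, `dI_t` (= -2 sqrt(I_c I_m), <= 0) and
#'   the amplification ratio `amplification` = |dI_t| / I_m.
#' @export
interference_intensities <- function(im) {
  stopifnot(inherits(im, "intensity_model"))
  cI0 <- im$collection * im$I0
  I_c <- cI0 * im$L * abs(im$alpha_channel)^2 * im$k^3 / 4
  I_m <- cI0 * abs(im$alpha_molecule)^2 * im$k^4 / (6 * pi)
  dI_t <- -2 * sqrt(I_c * I_m)
  list(I_c = I_c, I_m = I_m, dI_t = dI_t,
       amplification = if (I_m > 0) abs(dI_t) / I_m else Inf)
}
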