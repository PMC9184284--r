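#' Reference nanochannel geometries
#'
#' Cross-sections of the six nanochannels used throughout the package
#' examples, as width x height in nm. The equivalent radius is
#' r = sqrt(A/pi).
#'
#' @return A data.frame with columns `channel`, `width_nm`, `height_nm`,
#'   `area_nm2`, `r_nm`.
#' @examples
#' nsm_channels()
#' @export
nsm_channels <- function() {
  d <- data.frame(
    channel  = c("I", "II", "III", "IV", "V", "VI"),
    width_nm  = c(100, 110, 100, 145, 225, 82),
    height_nm = c(27, 72, 15, 27, 200, 40),
    stringsAsFactors = FALSE
  )
  d$area_nm2 <- d$width_nm * d$height_nm
  d$r_nm <- sqrt(d$area_nm2 / pi)
  d
}

#' Look up a nanochannel geometry by name
#'
#' @param channel Channel label, one of "I".."VI", or a numeric
#'   cross-sectional area in nm^2.
#' @param fov_length Field-of-view length along the channel in nm.
#' @param domain_length Length of the simulated channel segment in nm;
#'   defaults to twice the field of view, centered on it.
#' @return An object of class `channel_geometry` with fields `area` (nm^2),
#'   `r` (nm), `fov_length` (nm) and `domain_length` (nm).
#' @examples
#' channel_geometry("I")
#' channel_geometry(2700)
#' @export
channel_geometry <- function(channel = "I", fov_length = 15000,
                             domain_length = NULL) {
  if (is.character(channel)) {
    tab <- nsm_channels()
    i <- match(channel, tab$channel)
    if (is.na(i)) stop("unknown channel label: ", channel)
    area <- tab$area_nm2[i]
    name <- channel
  } else {
    stopifnot(is.numeric(channel), channel > 0)
    area <- channel
    name <- sprintf("custom(%g nm^2)", area)
  }
  if (is.null(domain_length)) domain_length <- 2 * fov_length
  stopifnot(fov_length > 0, domain_length >= fov_length)
  obj <- list(name = name, area = area, r = sqrt(area / pi),
              fov_length = fov_length, domain_length = domain_length)
  class(obj) <- "channel_geometry"
  obj
}

#' Reference biomolecule species
#'
#' Nominal molecular weights and literature hydrodynamic radii of the
#' protein and DNA species used in examples and simulations. DNA mass
#' follows the 650 Da per base pair rule.
#'
#' @return A data.frame with columns `species`, `mw_kDa`, `rs_nm`
#'   (NA where no literature radius is quoted).
#' @examples
#' nsm_species()
#' @export
nsm_species <- function() {
  data.frame(
    species = c("thyroglobulin", "ferritin", "ADH", "BSA", "aldolase",
                "dna_1kb", "dna_400bp", "dna_200bp"),
    mw_kDa = c(669, 440, 150, 66, 158,
               650 * 1000 / 1000, 650 * 400 / 1000, 650 * 200 / 1000),
    rs_nm = c(8.6, 6.1, 4.6, 3.5, 4.6, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' DNA molecular weight from length in base pairs
#'
#' @param n_bp Number of base pairs.
#' @param da_per_bp Average mass per base pair in Da (default 650).
#' @return Molecular weight in kDa.
#' @examples
#' dna_mw_kda(1000)  # 650 kDa
#' @export
dna_mw_kda <- function(n_bp, da_per_bp = 650) {
  if (any(n_bp < 0)) stop("base-pair count must be non-negative")
  n_bp * da_per_bp / 1000
}
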