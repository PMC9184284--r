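#' Kymograph container
#'
#' A kymograph is a 2-D array of relative differential contrast with one
#' row per frame and one column per position pixel along the channel axis.
#' It is the exchange format between the simulator and the analysis
#' pipeline. Molecule signatures are negative dips; the background is zero
#' after normalization.
#'
#' @param contrast Numeric matrix, frames x pixels, dimensionless relative
#'   contrast (signed).
#' @param dt Frame interval in s.
#' @param pixel_pitch Pixel size along the channel in nm.
#' @param origin Position (nm) of the center of pixel 1.
#' @param metadata Optional named list of provenance (channel area, noise
#'   level, seed, ...).
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(contrast, dt, pixel_pitch, origin = 0,
                      metadata = list()) {
  contrast <- as.matrix(contrast)
  if (!all(is.finite(contrast))) stop("kymograph contains non-finite values")
  stopifnot(dt > 0, pixel_pitch > 0)
  obj <- list(contrast = contrast, dt = dt, pixel_pitch = pixel_pitch,
              origin = origin, metadata = metadata)
  class(obj) <- "kymograph"
  obj
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d pixels, dt = %g s, pitch = %g nm\n",
              nrow(x$contrast), ncol(x$contrast), x$dt, x$pixel_pitch))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$contrast)

#' Pixel-center coordinates of a kymograph
#'
#' @param kymo A [kymograph()].
#' @return Numeric vector of positions in nm, one per pixel column.
#' @export
kymo_positions <- function(kymo) {
  kymo$origin + (seq_len(ncol(kymo$contrast)) - 1) * kymo$pixel_pitch
}

#' Write a kymograph as a 32-bit float TIFF with a JSON sidecar
#'
#' The image rows are frames and columns are position pixels. Calibration
#' metadata (frame interval, pixel pitch, origin, plus any extra metadata)
#' goes to `<path>.json`.
#'
#' @param kymo A [kymograph()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  # TIFF stores [0, 1]; map the signed contrast affinely and record the
  # range in the sidecar (32-bit floats keep ~1e-7 relative precision)
  lo <- min(kymo$contrast)
  hi <- max(kymo$contrast)
  if (hi <= lo) hi <- lo + 1
  tiff::writeTIFF((kymo$contrast - lo) / (hi - lo), path,
                  bits.per.sample = 32, reduce = TRUE)
  side <- c(list(dt_s = kymo$dt, pixel_pitch_nm = kymo$pixel_pitch,
                 origin_nm = kymo$origin, contrast_min = lo,
                 contrast_max = hi), kymo$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path TIFF path; `<path>.json` must hold the calibration sidecar.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("missing JSON sidecar: ", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!is.null(side$contrast_min)) {
    img <- side$contrast_min +
      img * (side$contrast_max - side$contrast_min)
  }
  meta <- side[setdiff(names(side),
                       c("dt_s", "pixel_pitch_nm", "origin_nm",
                         "contrast_min", "contrast_max"))]
  kymograph(img, dt = side$dt_s, pixel_pitch = side$pixel_pitch_nm,
            origin = if (is.null(side$origin_nm)) 0 else side$origin_nm,
            metadata = meta)
}
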