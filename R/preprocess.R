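#' Collapse a 3-D movie stack onto the channel axis
#'
#' Averages the intensity across the channel's short (transverse) axis for
#' every frame, producing the 2-D intensity kymograph on which the rest of
#' the pipeline operates.
#'
#' @param frames 3-D numeric array, time x transverse (y) x axial (x).
#' @param rows Indices of the transverse rows covering the channel
#'   (default: all rows).
#' @return Numeric matrix, frames x axial pixels.
#' @export
collapse_transverse <- function(frames, rows = NULL) {
  stopifnot(length(dim(frames)) == 3)
  if (is.null(rows)) rows <- seq_len(dim(frames)[2])
  if (length(rows) == 0) stop("empty transverse row selection")
  sub <- frames[, rows, , drop = FALSE]
  apply(sub, c(1, 3), mean)
}

#' Estimate the empty-channel background of a raw kymograph
#'
#' Pixel-wise temporal median over the movie (optionally over a rolling
#' window). At realistic occupancies (a couple of molecules per field of
#' view) each pixel is molecule-free in well over half of the frames, so
#' the median equals the empty-channel intensity; a molecule stuck at one
#' position for most of the movie will leak into the background estimate,
#' which is the documented failure mode of any temporal estimator.
#'
#' @param raw Numeric matrix of raw intensities, frames x pixels.
#' @param window Optional rolling-window length in frames; `NULL` (default)
#'   uses the whole movie, giving one background line.
#' @param occupancy_warn Fraction of frames above which a pixel's dip
#'   occupancy triggers a warning (default 0.5).
#' @param mask Optional logical matrix of the same shape as `raw`, TRUE
#'   where a molecule is believed to sit (e.g. from a first detection
#'   pass); masked entries are excluded from the per-pixel median, which
#'   removes the small negative bias the molecule's own dip exerts on the
#'   background where it lingers. Pixels with fewer than 20% unmasked
#'   frames fall back to the unmasked median.
#' @return If `window` is `NULL`, a numeric vector (one value per pixel);
#'   otherwise a matrix of the same shape as `raw` with the per-frame
#'   rolling background.
#' @export
estimate_background <- function(raw, window = NULL, occupancy_warn = 0.5,
                                mask = NULL) {
  raw <- as.matrix(raw)
  bg <- apply(raw, 2, stats::median)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(raw)))
    n_t <- nrow(raw)
    for (p in which(colSums(mask) > 0)) {
      free <- !mask[, p]
      if (sum(free) >= 0.2 * n_t) {
        bg[p] <- stats::median(raw[free, p])
      }
    }
  }
  # occupancy check: where a dark dip sits in most frames, the median is
  # dragged into the dip and the gap to the upper quantile opens far beyond
  # the noise; pixels occupied in literally every frame are indistinguishable
  # from background structure and cannot be caught here
  sd_est <- stats::mad(raw - rep(bg, each = nrow(raw)))
  if (sd_est > 0 && occupancy_warn < 1) {
    hi <- apply(raw, 2, stats::quantile, probs = 0.9, names = FALSE)
    suspect <- (hi - bg) > 5 * sd_est
    if (any(suspect)) {
      warning(sprintf(
        "%d pixel(s) appear occupied in a large fraction of frames; %s",
        sum(suspect), "background estimate may be biased there"))
    }
  }
  if (is.null(window)) return(bg)
  window <- min(window, nrow(raw))
  out <- matrix(NA_real_, nrow(raw), ncol(raw))
  half <- floor(window / 2)
  for (t in seq_len(nrow(raw))) {
    lo <- max(1, t - half)
    hi <- min(nrow(raw), lo + window - 1)
    lo <- max(1, hi - window + 1)
    out[t, ] <- apply(raw[lo:hi, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Normalize a raw kymograph to relative differential contrast
#'
#' Removes per-frame global intensity fluctuations (source drift), then
#' subtracts and divides by the empty-channel background:
#' contrast[t, x] = raw[t, x] / (gain_t * background[x]) - 1. The global
#' per-frame gain is the median of raw/background over the pixels of the
#' frame, which is robust to the few pixels occupied by a molecule.
#'
#' @param raw Numeric matrix of raw intensities, frames x pixels.
#' @param background Per-pixel background vector, or per-frame background
#'   matrix, as from [estimate_background()]. Default: estimated from
#'   `raw`.
#' @param dt Frame interval in s.
#' @param pixel_pitch Pixel size in nm.
#' @param origin Position of pixel 1 center in nm.
#' @param metadata Metadata list passed to the result.
#' @return A [kymograph()] of relative differential contrast.
#' @export
normalize_kymograph <- function(raw, background = NULL, dt, pixel_pitch,
                                origin = 0, metadata = list()) {
  raw <- as.matrix(raw)
  if (is.null(background)) background <- estimate_background(raw)
  if (is.matrix(background)) {
    if (!all(dim(background) == dim(raw))) {
      stop("background matrix must match raw dimensions")
    }
    bg <- background
  } else {
    if (length(background) != ncol(raw)) {
      stop("background length must equal the pixel count")
    }
    bg <- matrix(background, nrow(raw), ncol(raw), byrow = TRUE)
  }
  if (any(bg <= 0)) stop("background must be positive everywhere")
  ratio <- raw / bg
  gain <- apply(ratio, 1, stats::median)
  contrast <- ratio / gain - 1
  kymograph(contrast, dt = dt, pixel_pitch = pixel_pitch, origin = origin,
            metadata = metadata)
}

#' Run background estimation and normalization on a raw movie
#'
#' Convenience wrapper: collapse (if 3-D), estimate the background, and
#' normalize, returning a contrast [kymograph()].
#'
#' @param raw Raw intensity matrix (frames x pixels) or 3-D stack.
#' @param dt Frame interval in s.
#' @param pixel_pitch Pixel size in nm.
#' @param origin Position of pixel 1 center in nm.
#' @param window Optional rolling background window (frames).
#' @param metadata Metadata list for the result.
#' @return A [kymograph()].
#' @export
preprocess_movie <- function(raw, dt, pixel_pitch, origin = 0,
                             window = NULL, metadata = list()) {
  if (length(dim(raw)) == 3) raw <- collapse_transverse(raw)
  bg <- estimate_background(raw, window = window)
  normalize_kymograph(raw, bg, dt = dt, pixel_pitch = pixel_pitch,
                      origin = origin, metadata = metadata)
}
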