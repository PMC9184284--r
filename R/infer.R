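#' Mean integrated optical contrast of a trajectory
#'
#' The iOC of a molecule is the arithmetic mean of its per-frame
#' integrated contrasts over the free (non-bound) frames of the
#' trajectory. Frames whose summation window was clipped by the
#' field-of-view edge are excluded, because their integrated contrast is
#' truncated; if every frame is edge-clipped the plain mean is returned
#' and the caller sees the `edge_truncated` situation through the
#' trajectory flags.
#'
#' @param traj A `trajectory` from [link_detections()], or a numeric vector
#'   of per-frame iOC values in nm.
#' @return Mean iOC in nm (signed).
#' @export
trajectory_ioc <- function(traj) {
  ioc <- if (inherits(traj, "trajectory")) traj$ioc else traj
  if (length(ioc) == 0) stop("empty trajectory")
  if (inherits(traj, "trajectory") && !is.null(traj$edge) &&
      any(!traj$edge)) {
    ioc <- ioc[!traj$edge]
  }
  mean(ioc)
}

#' Covariance-based diffusivity estimator
#'
#' Estimates the diffusion coefficient of a tracked molecule from its
#' frame-to-frame displacements:
#' \deqn{D = \overline{(\Delta x_n)^2} / (2\Delta t)
#'        + \overline{\Delta x_n \Delta x_{n+1}} / \Delta t.}
#' The covariance term cancels the bias from both static localization
#' noise and motion blur, so the estimator is unbiased for confined-free
#' Brownian motion recorded with a camera; it can return negative values
#' for noise-dominated trajectories, which are passed through unchanged
#' and flagged downstream rather than truncated (truncation would bias
#' population means).
#'
#' Only displacements between consecutive frames enter; gaps in `frames`
#' break the displacement sequence. In flow mode the mean displacement
#' (drift) is subtracted before forming the moments.
#'
#' @param x Positions in nm.
#' @param dt Frame interval in s.
#' @param frames Optional integer frame indices matching `x`; used to
#'   exclude displacement pairs across gaps.
#' @param flow Subtract the mean displacement first (drift removal).
#' @return Diffusivity in m^2/s (possibly negative).
#' @examples
#' cve_diffusivity(cumsum(c(0, rep(1, 4))), dt = 0.005) * 1e18  # 300 nm^2/s
#' @export
cve_diffusivity <- function(x, dt, frames = NULL, flow = FALSE) {
  n <- length(x)
  if (n < 3) stop("need at least 3 positions (two displacements)")
  stopifnot(dt > 0)
  if (is.null(frames)) frames <- seq_len(n)
  dx <- diff(x)
  consec <- diff(frames) == 1L
  dx_ok <- dx[consec]
  if (length(dx_ok) < 2) stop("need at least two consecutive displacements")
  if (flow) dx_ok <- dx_ok - mean(dx_ok)
  # adjacent displacement pairs: both displacements must be gap-free and
  # contiguous with each other
  pair_ok <- consec[-length(consec)] & consec[-1]
  dxl <- dx[-length(dx)]; dxr <- dx[-1]
  if (flow) {
    m <- mean(dx[consec])
    dxl <- dxl - m; dxr <- dxr - m
  }
  cov_term <- if (any(pair_ok)) mean(dxl[pair_ok] * dxr[pair_ok]) else 0
  D_nm2 <- mean(dx_ok^2) / (2 * dt) + cov_term / dt
  D_nm2 * 1e-18
}

#' Characterize a single trajectory
#'
#' Converts a tracked trajectory into physical molecule properties: the
#' mean iOC is converted to molecular weight through the channel
#' cross-section and the optical calibration, and the covariance-based
#' diffusivity is inverted through the hindrance-corrected Stokes-Einstein
#' relation to a hydrodynamic radius. Conversion failures (negative
#' diffusivity, unresolvable confinement) are flagged, never dropped
#' silently.
#'
#' @param traj A `trajectory`.
#' @param channel A [channel_geometry()] (or area in nm^2).
#' @param optics An [optical_model()].
#' @param ctx A [hydro_context()]; defaults to the channel's.
#' @param flow Passed to [cve_diffusivity()] (drift removal).
#' @return A one-row data.frame: `traj_id`, `N`, `ioc_nm`, `D_um2_s`,
#'   `mw_kDa`, `rs_nm`, `flags`.
#' @export
characterize_trajectory <- function(traj, channel, optics = optical_model(),
                                    ctx = NULL, flow = FALSE) {
  if (is.numeric(channel)) channel <- channel_geometry(channel)
  if (is.null(ctx)) ctx <- hydro_context(area = channel$area)
  flags <- traj$flags
  ioc <- trajectory_ioc(traj)
  mw <- mw_from_ioc(ioc, channel$area, optics) / 1000
  D <- tryCatch(cve_diffusivity(traj$x, traj$dt, frames = traj$frame,
                                flow = flow),
                error = function(e) NA_real_)
  rs <- NA_real_
  if (is.na(D)) {
    flags <- c(flags, "short_for_cve")
  } else if (D <= 0) {
    flags <- c(flags, "invalid_negative_D")
  } else {
    rs <- tryCatch(stokes_radius_from_diffusivity(D, ctx),
                   error = function(e) NA_real_)
    if (is.na(rs)) flags <- c(flags, "unresolvable_confinement")
  }
  data.frame(traj_id = traj$id, N = traj$N, ioc_nm = ioc,
             D_um2_s = if (is.na(D)) NA_real_ else D * 1e12,
             mw_kDa = mw, rs_nm = rs,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Characterize all trajectories of a recording
#'
#' Applies [characterize_trajectory()] to each trajectory and attaches the
#' statistical weight N_i / sum(N) used by the population histograms, so
#' that long trajectories count proportionally to the evidence they carry.
#'
#' @param trajs List of trajectories.
#' @inheritParams characterize_trajectory
#' @return A data.frame of per-trajectory estimates with a `weight` column
#'   summing to 1.
#' @export
characterize_trajectories <- function(trajs, channel,
                                      optics = optical_model(),
                                      ctx = NULL, flow = FALSE) {
  if (length(trajs) == 0) stop("no trajectories to characterize")
  est <- do.call(rbind, lapply(trajs, characterize_trajectory,
                               channel = channel, optics = optics,
                               ctx = ctx, flow = flow))
  est$weight <- est$N / sum(est$N)
  est
}

#' N-weighted population histogram
#'
#' Histogram of a per-trajectory quantity in which every trajectory
#' contributes its weight N_i / sum(N) to the bin of its estimate, so the
#' bin masses sum to one and peak areas reflect relative population
#' concentrations.
#'
#' @param estimates Data.frame from [characterize_trajectories()] (needs
#'   the target column and `N`).
#' @param field Column to histogram (e.g. "mw_kDa", "rs_nm", "ioc_nm",
#'   "D_um2_s").
#' @param bin_width Bin width in the field's units; default
#'   Freedman-Diaconis on the valid values.
#' @return A list of class `population_histogram` with `breaks`, `mids`,
#'   `counts` (weighted, summing to 1), `field`, `n_traj`.
#' @export
population_histogram <- function(estimates, field = "mw_kDa",
                                 bin_width = NULL) {
  v <- estimates[[field]]
  ok <- is.finite(v)
  if (!any(ok)) stop("no valid estimates for field ", field)
  v <- v[ok]
  w <- estimates$N[ok]
  w <- w / sum(w)
  if (is.null(bin_width)) {
    # Freedman-Diaconis, capped so that small samples still spread over
    # enough bins for a Gaussian fit
    iqr <- stats::IQR(v)
    spread <- diff(range(v))
    bin_width <- if (iqr > 0) 2 * iqr / length(v)^(1 / 3) else
      max(spread, abs(stats::median(v)) * 1e-3, 1e-12) / 10
    if (spread > 0) bin_width <- min(bin_width, spread / 10)
  }
  lo <- floor(min(v) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 6) breaks <- seq(lo, hi, length.out = 6)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  counts <- vapply(seq_len(length(breaks) - 1),
                   function(b) sum(w[bin == b]), numeric(1))
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, field = field, n_traj = length(v)),
            class = "population_histogram")
}

#' Fit Gaussian components to a population histogram
#'
#' Least-squares fit of a sum of `n_components` Gaussians to the weighted
#' histogram (Levenberg-Marquardt). The population mean is the fitted
#' center and the resolution is the full width at half maximum,
#' FWHM = 2 sqrt(2 ln 2) sigma = 2.3548 sigma. Initialization defaults to
#' the histogram mode and the weighted standard deviation; for multiple
#' components supply `init`.
#'
#' @param hist A [population_histogram()].
#' @param n_components Number of Gaussian components (default 1).
#' @param init Optional list with numeric vectors `center`, `sigma`,
#'   `amplitude` of length `n_components`.
#' @return An object of class `population_fit`: a data.frame with one row
#'   per component (`center`, `sigma`, `fwhm`, `area`) plus attributes
#'   `field` and `fitted` (fitted curve at bin mids).
#' @export
fit_population <- function(hist, n_components = 1, init = NULL) {
  stopifnot(inherits(hist, "population_histogram"), n_components >= 1)
  x <- hist$mids
  y <- hist$counts
  if (sum(y > 0) < 5 * n_components) {
    stop("degenerate histogram: need at least ", 5 * n_components,
         " populated bins for ", n_components, " component(s)")
  }
  bw <- mean(diff(hist$breaks))
  if (is.null(init)) {
    if (n_components > 1) {
      stop("supply `init` (center, sigma, amplitude) for multi-component fits")
    }
    mu0 <- x[which.max(y)]
    w <- y / sum(y)
    sd0 <- sqrt(max(sum(w * (x - sum(w * x))^2), (bw / 2)^2))
    init <- list(center = mu0, sigma = sd0, amplitude = max(y))
  }
  par0 <- c(init$center, log(init$sigma), init$amplitude)
  nc <- n_components
  model <- function(p) {
    mu <- p[1:nc]; sg <- exp(p[nc + 1:nc]); am <- p[2 * nc + 1:nc]
    rowSums(vapply(seq_len(nc), function(i) {
      am[i] * exp(-(x - mu[i])^2 / (2 * sg[i]^2))
    }, numeric(length(x))))
  }
  fit <- minpack.lm::nls.lm(par = par0,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  if (fit$info %in% c(0, 9)) {
    stop("population fit did not converge: ", fit$message)
  }
  p <- fit$par
  centers <- p[1:nc]; sigmas <- exp(p[nc + 1:nc]); amps <- p[2 * nc + 1:nc]
  res <- data.frame(center = centers, sigma = sigmas,
                    fwhm = 2 * sqrt(2 * log(2)) * sigmas,
                    area = amps * sigmas * sqrt(2 * pi) / bw)
  res <- res[order(res$center), ]
  rownames(res) <- NULL
  attr(res, "field") <- hist$field
  attr(res, "fitted") <- model(p)
  class(res) <- c("population_fit", "data.frame")
  res
}
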