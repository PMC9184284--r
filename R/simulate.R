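#' Species specification for simulation
#'
#' Ground-truth properties of a simulated molecular species. The
#' hydrodynamic radius may be given explicitly (literature value) or
#' derived from the globular scaling [globular_radius_from_mw()].
#'
#' @param name Species label.
#' @param mw Molecular weight in kDa.
#' @param r_s Hydrodynamic radius in nm; if `NULL`, derived from `mw` via
#'   the globular scaling.
#' @param concentration Molar concentration in mol/L (optional; used by
#'   [simulate_experiment()] for occupancy sampling).
#' @param drift_velocity Drift velocity along the channel in nm/s
#'   (default 0; nonzero in flow mode).
#' @return An object of class `species_spec`.
#' @examples
#' species_spec("BSA", mw = 66, r_s = 3.5)
#' @export
species_spec <- function(name, mw, r_s = NULL, concentration = NULL,
                         drift_velocity = 0) {
  stopifnot(mw >= 0)
  if (is.null(r_s)) r_s <- globular_radius_from_mw(mw)
  stopifnot(r_s > 0)
  obj <- list(name = name, mw = mw, r_s = r_s,
              concentration = concentration,
              drift_velocity = drift_velocity)
  class(obj) <- "species_spec"
  obj
}

#' Simulation plan
#'
#' Describes one simulated recording: the channel segment, frame timing and
#' the numerical discretization. The simulation domain extends beyond the
#' field of view (default twice its length, centered) with reflecting
#' boundaries at the domain ends, so molecules wander in and out of view as
#' in a real channel whose length exceeds the field of view.
#'
#' @param channel A [channel_geometry()].
#' @param frame_rate Frames per second of the rendered kymograph.
#' @param n_frames Number of frames to simulate.
#' @param substeps_per_frame Brownian substeps per frame; the rendered
#'   image averages the substep profiles, which produces motion blur.
#' @param rng_seed Integer seed; fixes all randomness of the run.
#' @param binding_events Optional data.frame with columns `start_frame`,
#'   `duration_frames` describing transient wall-binding intervals during
#'   which the molecule is immobilized.
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(channel = channel_geometry("I"),
                            frame_rate = 200, n_frames = 500,
                            substeps_per_frame = 20, rng_seed = 1L,
                            binding_events = NULL) {
  stopifnot(inherits(channel, "channel_geometry"),
            frame_rate > 0, n_frames >= 1, substeps_per_frame >= 1)
  obj <- list(channel = channel, frame_rate = frame_rate,
              dt = 1 / frame_rate, n_frames = as.integer(n_frames),
              substeps_per_frame = as.integer(substeps_per_frame),
              rng_seed = as.integer(rng_seed),
              binding_events = binding_events)
  class(obj) <- "simulation_plan"
  obj
}

#' Simulate one confined Brownian trajectory
#'
#' Overdamped 1-D Brownian dynamics with optional drift:
#' x_{i+1} = x_i + v dt_sub + sqrt(2 D dt_sub) xi, with xi standard normal
#' and dt_sub the substep interval. The diffusivity is the
#' hindrance-corrected value for the species radius in the plan's channel.
#' Boundaries at the domain ends are reflecting. During a binding event the
#' position is frozen.
#'
#' Does not seed the RNG itself; callers ([simulate_experiment()]) fix the
#' seed once per run.
#'
#' @param species A [species_spec()].
#' @param plan A [simulation_plan()].
#' @param ctx A [hydro_context()]; its channel radius should match the
#'   plan's channel.
#' @param x0 Starting position in nm (default: uniform over the domain).
#' @param D Diffusivity override in m^2/s (default: from
#'   [hindered_diffusivity()]).
#' @return A list with `x_sub` (positions at every substep, nm),
#'   `x_frame` (substep-averaged position per frame, nm, the blurred
#'   centroid a camera would see), `D` (m^2/s) and `dt_sub` (s).
#' @export
simulate_trajectory <- function(species, plan,
                                ctx = hydro_context(area = plan$channel$area),
                                x0 = NULL, D = NULL) {
  stopifnot(inherits(species, "species_spec"),
            inherits(plan, "simulation_plan"))
  if (is.null(D)) D <- hindered_diffusivity(species$r_s, ctx)
  D_nm2 <- D * 1e18
  S <- plan$substeps_per_frame
  n_sub <- plan$n_frames * S
  dt_sub <- plan$dt / S
  dom <- plan$channel$domain_length
  if (is.null(x0)) x0 <- stats::runif(1, 0, dom)
  steps <- species$drift_velocity * dt_sub +
    sqrt(2 * D_nm2 * dt_sub) * stats::rnorm(n_sub)
  # freeze steps inside binding events (frames are 1-based)
  if (!is.null(plan$binding_events) && nrow(plan$binding_events) > 0) {
    frame_of_sub <- rep(seq_len(plan$n_frames), each = S)
    for (i in seq_len(nrow(plan$binding_events))) {
      ev <- plan$binding_events[i, ]
      bound <- frame_of_sub >= ev$start_frame &
        frame_of_sub < ev$start_frame + ev$duration_frames
      steps[bound] <- 0
    }
  }
  x <- x0 + cumsum(steps)
  x <- reflect_positions(x, 0, dom)
  x_frame <- colMeans(matrix(x, nrow = S))
  list(x_sub = x, x_frame = x_frame, D = D, dt_sub = dt_sub, x0 = x0)
}

# Fold positions back into [lo, hi] by reflection (handles multiple wraps).
reflect_positions <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

#' Render ground-truth trajectories into a kymograph
#'
#' Camera model: each molecule contributes, at every substep, a Gaussian
#' line profile of standard deviation `psf_sigma` whose spatial integral
#' equals the molecule's integrated optical contrast (iOC, negative);
#' substep profiles are averaged within a frame (motion blur), sampled at
#' the pixel pitch (the per-pixel value is the profile divided by the
#' pitch, so that summing pixels times the pitch recovers the iOC), and
#' zero-mean Gaussian noise of standard deviation `noise_rel` is added per
#' pixel. The pixel grid covers the field of view, centered in the
#' simulation domain; molecules outside the field of view contribute only
#' the tail of their profile that falls on the grid.
#'
#' @param truth A list of per-molecule ground truths, each a list with
#'   `x_sub` (substep positions, nm) and `ioc` (nm, signed); typically
#'   built by [simulate_experiment()].
#' @param optics An [optical_model()].
#' @param plan A [simulation_plan()].
#' @param noise Logical; add camera noise (default TRUE).
#' @return A [kymograph()] of relative contrast.
#' @export
render_kymograph <- function(truth, optics, plan, noise = TRUE) {
  stopifnot(inherits(optics, "optical_model"),
            inherits(plan, "simulation_plan"))
  if (optics$psf_sigma / optics$pixel_pitch < 2) {
    stop("pixel grid too coarse: need pixel_pitch <= psf_sigma / 2 ",
         "to sample the line-spread function")
  }
  n_px <- floor(plan$channel$fov_length / optics$pixel_pitch)
  origin <- (plan$channel$domain_length - plan$channel$fov_length) / 2
  K <- matrix(0, nrow = plan$n_frames, ncol = n_px)
  S <- plan$substeps_per_frame
  sigma <- optics$psf_sigma
  pitch <- optics$pixel_pitch
  half_w <- ceiling(5 * sigma / pitch)
  offsets <- -half_w:half_w
  frames <- seq_len(plan$n_frames)
  for (mol in truth) {
    amp <- mol$ioc / (sigma * sqrt(2 * pi)) / S
    xs <- matrix(mol$x_sub, nrow = plan$n_frames, ncol = S, byrow = TRUE)
    for (s in seq_len(S)) {
      pos <- xs[, s] - origin
      ci <- round(pos / pitch) + 1L
      d <- pos - (ci - 1L) * pitch
      for (o in offsets) {
        px <- ci + o
        ok <- px >= 1L & px <= n_px
        if (!any(ok)) next
        v <- amp * exp(-((o * pitch - d[ok])^2) / (2 * sigma^2))
        idx <- cbind(frames[ok], px[ok])
        K[idx] <- K[idx] + v
      }
    }
  }
  if (noise && optics$noise_rel > 0) {
    K <- K + matrix(stats::rnorm(length(K), sd = optics$noise_rel),
                    nrow = nrow(K))
  }
  kymograph(K, dt = plan$dt, pixel_pitch = pitch, origin = origin,
            metadata = list(channel_area_nm2 = plan$channel$area,
                            fov_length_nm = plan$channel$fov_length,
                            noise_rel = optics$noise_rel,
                            seed = plan$rng_seed))
}

#' Simulate a complete recording
#'
#' Draws molecules, propagates their Brownian trajectories and renders the
#' kymograph. With `n_molecules` given, exactly that many molecules are
#' placed (uniformly over the domain); with species concentrations given
#' instead, the number of molecules in the domain is Poisson with mean
#' [expected_count()] scaled to the domain length. The RNG is seeded once
#' from `plan$rng_seed`, making the whole run reproducible bit-for-bit.
#'
#' @param species A [species_spec()] or list of them.
#' @param plan A [simulation_plan()].
#' @param optics An [optical_model()].
#' @param ctx A [hydro_context()].
#' @param n_molecules Number of molecules per species (scalar or vector
#'   matching `species`); overrides concentration-based sampling.
#' @param noise Logical; add camera noise.
#' @param x0_range Length-2 range (nm) for the initial positions; default
#'   the whole simulation domain.
#' @return A list with `kymo` (a [kymograph()]) and `truth` (a data.frame
#'   with one row per molecule: `molecule_id`, `species`, `mw_kDa`,
#'   `rs_nm`, `D_um2_s`, `ioc_nm`, `x0_nm`) plus `positions`, a list of
#'   per-frame blurred-centroid positions per molecule.
#' @export
simulate_experiment <- function(species, plan,
                                optics = optical_model(),
                                ctx = hydro_context(area = plan$channel$area),
                                n_molecules = NULL, noise = TRUE,
                                x0_range = NULL) {
  if (inherits(species, "species_spec")) species <- list(species)
  if (is.null(x0_range)) x0_range <- c(0, plan$channel$domain_length)
  set.seed(plan$rng_seed)
  counts <- if (!is.null(n_molecules)) {
    rep_len(n_molecules, length(species))
  } else {
    vapply(species, function(sp) {
      if (is.null(sp$concentration)) {
        stop("species ", sp$name,
             " has no concentration; pass n_molecules instead")
      }
      stats::rpois(1, expected_count(sp$concentration, plan$channel$area,
                                     plan$channel$domain_length))
    }, numeric(1))
  }
  truth_rows <- list()
  mols <- list()
  positions <- list()
  id <- 0L
  for (k in seq_along(species)) {
    sp <- species[[k]]
    if (counts[k] == 0) next
    ioc <- ioc_from_mw(sp$mw * 1000, plan$channel$area, optics)
    D <- hindered_diffusivity(sp$r_s, ctx)
    for (j in seq_len(counts[k])) {
      id <- id + 1L
      tr <- simulate_trajectory(sp, plan, ctx, D = D,
                                x0 = stats::runif(1, x0_range[1],
                                                  x0_range[2]))
      mols[[id]] <- list(x_sub = tr$x_sub, ioc = ioc)
      positions[[id]] <- tr$x_frame
      truth_rows[[id]] <- data.frame(
        molecule_id = id, species = sp$name, mw_kDa = sp$mw,
        rs_nm = sp$r_s, D_um2_s = D * 1e12, ioc_nm = ioc,
        x0_nm = tr$x0, stringsAsFactors = FALSE)
    }
  }
  kymo <- render_kymograph(mols, optics, plan, noise = noise)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(molecule_id = integer(), species = character(),
               mw_kDa = numeric(), rs_nm = numeric(), D_um2_s = numeric(),
               ioc_nm = numeric(), x0_nm = numeric())
  list(kymo = kymo, truth = truth, positions = positions)
}

#' Embed a contrast kymograph in a raw intensity movie
#'
#' Inverse of the preprocessing step, used to exercise the background
#' estimation and normalization on simulated data: produces
#' raw[t, x] = gain_t * profile_x * (1 + contrast[t, x]), with a static
#' illumination profile and per-frame global gain factors.
#'
#' @param kymo A [kymograph()] of relative contrast.
#' @param profile Illumination profile per pixel (positive), recycled to
#'   the pixel count. Default: a smooth bump between 0.8 and 1.
#' @param frame_gain Per-frame global intensity factor (positive), recycled
#'   to the frame count. Default 1.
#' @return A numeric matrix of raw intensities, frames x pixels.
#' @export
as_raw_intensity <- function(kymo, profile = NULL, frame_gain = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  n_px <- ncol(kymo$contrast)
  n_t <- nrow(kymo$contrast)
  if (is.null(profile)) {
    u <- seq(0, 1, length.out = n_px)
    profile <- 0.8 + 0.2 * sin(pi * u)
  }
  profile <- rep_len(profile, n_px)
  frame_gain <- rep_len(frame_gain, n_t)
  if (any(profile <= 0) || any(frame_gain <= 0)) {
    stop("illumination profile and frame gains must be positive")
  }
  (frame_gain %o% profile) * (1 + kymo$contrast)
}
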