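#' Simulate and analyze a single-species (or mixture) study
#'
#' Runs the complete closed loop used throughout the package's validation:
#' for each of `n_traj` recordings, one molecule per species is simulated
#' in the channel, rendered to a contrast kymograph, embedded in a raw
#' intensity movie (static illumination profile), pushed through
#' background estimation, normalization, detection, linking and filtering,
#' and the resulting trajectories are characterized. The RNG seed is fixed
#' once per recording from `seed`, so the study is reproducible.
#'
#' @param species A [species_spec()] or list of them (one molecule each per
#'   recording).
#' @param channel A [channel_geometry()].
#' @param n_traj Number of independent recordings.
#' @param n_frames Frames per recording; a scalar, or a length-2 range from
#'   which lengths are drawn uniformly.
#' @param optics An [optical_model()].
#' @param ctx A [hydro_context()]; defaults to the channel's geometry.
#' @param seed Integer seed for the whole study.
#' @param kappa Detection threshold (see [detect_kymograph()]).
#' @param min_N Minimum trajectory length kept (see
#'   [filter_trajectories()]).
#' @param gate_nm Linking gate; default [linking_gate()] sized for 1.5x
#'   the fastest declared species (the headroom covers displacement-tail
#'   fluctuations).
#' @param raw_roundtrip If TRUE (default) exercise the preprocessing stage
#'   by rendering to raw intensity and re-normalizing; if FALSE analyze the
#'   simulator's contrast kymograph directly.
#' @param flow If TRUE, link with automatic drift estimation and remove
#'   drift before the diffusivity estimate.
#' @param substeps_per_frame Brownian substeps per frame.
#' @return A list with `estimates` (data.frame from
#'   [characterize_trajectories()]), `trajectories` (list), `truth`
#'   (data.frame of simulated ground truths) and `log` (per-stage counts).
#' @export
nsm_study <- function(species, channel = channel_geometry("I"),
                      n_traj = 50, n_frames = 500,
                      optics = optical_model(),
                      ctx = hydro_context(area = channel$area),
                      seed = 1L, kappa = 5, min_N = 50, gate_nm = NULL,
                      raw_roundtrip = TRUE, flow = FALSE,
                      substeps_per_frame = 20) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(n_traj >= 1)
  if (is.null(gate_nm)) {
    d_max <- max(vapply(species, function(sp) {
      hindered_diffusivity(sp$r_s, ctx) * 1e12
    }, numeric(1)))
    v_max <- max(abs(vapply(species, `[[`, numeric(1), "drift_velocity")))
    gate_nm <- linking_gate(1 / optics$frame_rate, d_max = 1.5 * d_max,
                            drift = v_max)
  }
  set.seed(seed)
  lengths <- if (length(n_frames) == 2) {
    sample(seq(n_frames[1], n_frames[2]), n_traj, replace = TRUE)
  } else rep(n_frames, n_traj)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_traj)
  has_drift <- any(vapply(species, function(s) s$drift_velocity != 0,
                          logical(1)))
  flow <- flow || has_drift
  all_trajs <- list()
  truths <- list()
  n_det <- 0L; n_linked <- 0L
  for (i in seq_len(n_traj)) {
    plan <- simulation_plan(channel = channel,
                            frame_rate = optics$frame_rate,
                            n_frames = lengths[i],
                            substeps_per_frame = substeps_per_frame,
                            rng_seed = scene_seeds[i])
    sim <- simulate_experiment(species, plan, optics, ctx,
                               n_molecules = 1,
                               x0_range = fov_range(channel))
    kymo <- sim$kymo
    if (raw_roundtrip) {
      raw <- as_raw_intensity(kymo)
      kymo1 <- preprocess_movie(raw, dt = kymo$dt,
                                pixel_pitch = kymo$pixel_pitch,
                                origin = kymo$origin,
                                metadata = kymo$metadata)
      # second pass: re-estimate the background with the detected molecule
      # masked out, so its dip does not leak into the temporal median
      dets1 <- detect_kymograph(kymo1, optics, kappa = kappa)
      mask <- detection_mask(dets1, dim(raw), kymo$pixel_pitch,
                             kymo$origin,
                             halfwidth = 10 * optics$psf_sigma + 1000)
      bg <- estimate_background(raw, mask = mask)
      kymo <- normalize_kymograph(raw, bg, dt = kymo$dt,
                                  pixel_pitch = kymo$pixel_pitch,
                                  origin = kymo$origin,
                                  metadata = kymo$metadata)
    }
    dets <- detect_kymograph(kymo, optics, kappa = kappa)
    n_det <- n_det + nrow(dets)
    trajs <- link_detections(dets, dt = kymo$dt, gate_nm = gate_nm,
                             drift = if (flow) "auto" else 0)
    n_linked <- n_linked + length(trajs)
    trajs <- filter_trajectories(trajs, min_N = min_N)
    sim$truth$scene <- i
    truths[[i]] <- sim$truth
    for (tr in trajs) {
      tr$id <- length(all_trajs) + 1L
      tr$scene <- i
      all_trajs[[tr$id]] <- tr
    }
  }
  if (length(all_trajs) == 0) stop("study produced no usable trajectories")
  estimates <- characterize_trajectories(all_trajs, channel, optics, ctx,
                                         flow = flow)
  list(estimates = estimates, trajectories = all_trajs,
       truth = do.call(rbind, truths),
       log = list(n_scenes = n_traj, n_detections = n_det,
                  n_linked = n_linked, n_kept = length(all_trajs),
                  seed = seed))
}

fov_range <- function(channel) {
  origin <- (channel$domain_length - channel$fov_length) / 2
  c(origin, origin + channel$fov_length)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> preprocess -> track -> estimate -> report as
#' described by a configuration (see [read_run_config()]) and writes the
#' artifacts: the last scene's kymograph as TIFF + JSON sidecar, the
#' trajectories and estimates as CSV, and a population report as JSON. The
#' seed is recorded in every artifact.
#'
#' @param config A configuration list from [read_run_config()] or
#'   constructed in code.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing files.
#' @return Invisibly, a list with `study` (the [nsm_study()] result),
#'   `fits` (population fits per reported field) and `paths` of written
#'   artifacts.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir %||% NULL) {
  cfg <- normalize_config(config)
  study <- nsm_study(species = cfg$species, channel = cfg$channel,
                     n_traj = cfg$simulate$n_traj,
                     n_frames = cfg$simulate$n_frames,
                     optics = cfg$optics, ctx = cfg$hydro,
                     seed = cfg$seed, kappa = cfg$track$kappa,
                     min_N = cfg$track$min_n,
                     flow = isTRUE(cfg$simulate$flow),
                     substeps_per_frame = cfg$simulate$substeps_per_frame)
  fits <- list()
  for (field in cfg$report$fields) {
    h <- population_histogram(study$estimates, field)
    fits[[field]] <- tryCatch(
      fit_population(h, n_components = cfg$report$n_components),
      error = function(e) e$message)
  }
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$trajectories <- file.path(out_dir, "trajectories.csv")
    utils::write.csv(trajectories_to_df(study$trajectories),
                     paths$trajectories, row.names = FALSE)
    paths$estimates <- file.path(out_dir, "estimates.csv")
    utils::write.csv(study$estimates, paths$estimates, row.names = FALSE)
    paths$report <- file.path(out_dir, "report.json")
    report <- list(
      seed = cfg$seed,
      log = study$log,
      populations = lapply(fits, function(f) {
        if (is.character(f)) list(error = f) else
          list(field = attr(f, "field"),
               components = as.data.frame(f))
      }))
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(study = study, fits = fits, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scatter report of molecular weight versus hydrodynamic radius
#'
#' Draws the characteristic population scatter: each trajectory as one
#' point at (MW, R_s), shaded by trajectory length, the fitted population
#' ellipses (center at the population means, diameters equal to the FWHM
#' resolutions) and the globular scaling line R_s = b MW^(1/3).
#'
#' @param estimates Data.frame from [characterize_trajectories()].
#' @param fits Optional list with elements `mw_kDa` and `rs_nm`, each a
#'   [fit_population()] result, for the ellipse overlays.
#' @param b Globular-scaling prefactor (nm/kDa^(1/3)).
#' @param file Optional PDF path; `NULL` draws on the active device.
#' @return Invisibly, a summary list with the ellipse parameters and the
#'   globular line.
#' @export
scatter_report <- function(estimates, fits = NULL, b = 0.88, file = NULL) {
  ok <- is.finite(estimates$mw_kDa) & is.finite(estimates$rs_nm)
  if (!any(ok)) stop("no valid (MW, R_s) estimates to plot")
  est <- estimates[ok, ]
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  shade <- grDevices::gray(1 - 0.2 - 0.8 * est$N / max(est$N))
  graphics::plot(est$mw_kDa, est$rs_nm, pch = 16, col = shade,
                 xlab = "molecular weight (kDa)",
                 ylab = "hydrodynamic radius (nm)",
                 main = "single-molecule population")
  mwg <- seq(max(min(est$mw_kDa) * 0.5, 1), max(est$mw_kDa) * 1.5,
             length.out = 200)
  graphics::lines(mwg, globular_radius_from_mw(mwg, b), col = "gray40")
  ellipses <- NULL
  if (!is.null(fits) && !is.null(fits$mw_kDa) && !is.null(fits$rs_nm) &&
      inherits(fits$mw_kDa, "population_fit") &&
      inherits(fits$rs_nm, "population_fit")) {
    ncomp <- min(nrow(fits$mw_kDa), nrow(fits$rs_nm))
    ellipses <- data.frame(mw = fits$mw_kDa$center[seq_len(ncomp)],
                           rs = fits$rs_nm$center[seq_len(ncomp)],
                           mw_fwhm = fits$mw_kDa$fwhm[seq_len(ncomp)],
                           rs_fwhm = fits$rs_nm$fwhm[seq_len(ncomp)])
    th <- seq(0, 2 * pi, length.out = 100)
    for (i in seq_len(ncomp)) {
      graphics::lines(ellipses$mw[i] + ellipses$mw_fwhm[i] / 2 * cos(th),
                      ellipses$rs[i] + ellipses$rs_fwhm[i] / 2 * sin(th),
                      col = "red3")
    }
  }
  invisible(list(ellipses = ellipses, b = b, n_points = nrow(est)))
}

# Logical frames x pixels mask covering `halfwidth` nm around every
# detection.
detection_mask <- function(detections, dims, pixel_pitch, origin,
                           halfwidth) {
  mask <- matrix(FALSE, dims[1], dims[2])
  if (nrow(detections) == 0) return(mask)
  hw <- ceiling(halfwidth / pixel_pitch)
  ci <- round((detections$x_nm - origin) / pixel_pitch) + 1
  for (k in seq_len(nrow(detections))) {
    cols <- max(1, ci[k] - hw):min(dims[2], ci[k] + hw)
    mask[detections$frame[k], cols] <- TRUE
  }
  mask
}
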