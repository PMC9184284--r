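#' Read and validate a run configuration from YAML
#'
#' A run configuration describes a complete simulated study. Top-level
#' keys (all optional except `species`): `optics`, `hydro`, `channel`,
#' `simulate`, `track`, `report`, `species`, `seed`, `out_dir`. Unknown
#' keys are rejected so that typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list (still declarative; objects
#'   are built by [normalize_config()] inside [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.config_keys <- list(
  top = c("optics", "hydro", "channel", "simulate", "track", "report",
          "species", "seed", "out_dir"),
  optics = c("n_medium", "n_wall", "a", "psf_sigma", "pixel_pitch",
             "noise_rel", "frame_rate"),
  hydro = c("temperature", "viscosity"),
  channel = c("name", "area", "fov_length", "domain_length"),
  simulate = c("n_traj", "n_frames", "substeps_per_frame", "flow"),
  track = c("kappa", "min_n", "gate_nm", "gap_frames"),
  report = c("fields", "n_components"),
  species_item = c("name", "mw", "r_s", "concentration", "drift_velocity")
)

validate_config <- function(cfg) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
  }
  check_keys(cfg, .config_keys$top, "top level")
  for (sec in c("optics", "hydro", "channel", "simulate", "track",
                "report")) {
    if (!is.null(cfg[[sec]])) {
      check_keys(cfg[[sec]], .config_keys[[sec]], sec)
    }
  }
  if (!is.null(cfg$species)) {
    for (sp in cfg$species) {
      check_keys(sp, .config_keys$species_item, "species entry")
      if (is.null(sp$mw)) stop("species entry missing `mw` (kDa)")
    }
  }
  invisible(cfg)
}

# Turn a declarative configuration into the package's objects, filling in
# defaults.
normalize_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_config(cfg)
  optics <- do.call(optical_model, cfg$optics %||% list())
  ch <- cfg$channel %||% list()
  channel <- channel_geometry(
    channel = ch$name %||% ch$area %||% "I",
    fov_length = ch$fov_length %||% 15000,
    domain_length = ch$domain_length %||% NULL)
  hydro <- do.call(hydro_context,
                   c(list(area = channel$area), cfg$hydro %||% list()))
  if (is.null(cfg$species)) stop("configuration must declare `species`")
  species <- lapply(cfg$species, function(sp) {
    species_spec(name = sp$name %||% "species", mw = sp$mw,
                 r_s = sp$r_s %||% NULL,
                 concentration = sp$concentration %||% NULL,
                 drift_velocity = sp$drift_velocity %||% 0)
  })
  sim <- cfg$simulate %||% list()
  track <- cfg$track %||% list()
  report <- cfg$report %||% list()
  list(
    optics = optics, channel = channel, hydro = hydro, species = species,
    simulate = list(n_traj = sim$n_traj %||% 50,
                    n_frames = unlist(sim$n_frames %||% 500),
                    substeps_per_frame = sim$substeps_per_frame %||% 20,
                    flow = sim$flow %||% FALSE),
    track = list(kappa = track$kappa %||% 5,
                 min_n = track$min_n %||% 50,
                 gap_frames = track$gap_frames %||% 3),
    report = list(fields = unlist(report$fields %||% c("mw_kDa", "rs_nm")),
                  n_components = report$n_components %||% 1),
    seed = cfg$seed %||% 1L,
    out_dir = cfg$out_dir %||% NULL
  )
}
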