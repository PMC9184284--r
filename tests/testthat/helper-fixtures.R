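# Shared fixtures for the test suite. Everything is generated in code at
# load time; nothing is read from disk.

default_optics <- function(...) optical_model(...)

channel_I <- channel_geometry("I")
ctx_I <- hydro_context(area = channel_I$area)

# Render one noise-free kymograph with molecules held static at given
# positions -- handy for detector and conservation tests.
static_scene <- function(x_nm, ioc_nm, n_frames = 5,
                         optics = optical_model(),
                         channel = channel_geometry("I"),
                         noise = FALSE, seed = 1) {
  plan <- simulation_plan(channel, n_frames = n_frames,
                          substeps_per_frame = 1, rng_seed = seed)
  set.seed(seed)
  truth <- mapply(function(x, i) {
    list(x_sub = rep(x, n_frames), ioc = i)
  }, x_nm, ioc_nm, SIMPLIFY = FALSE)
  render_kymograph(truth, optics, plan, noise = noise)
}

# A small cached BSA study shared by pipeline-level tests (built once per
# test run).
shared_bsa_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- nsm_study(species_spec("BSA", 66, r_s = 3.5),
                          channel_geometry("I"), n_traj = 8,
                          n_frames = 400, seed = 101)
    }
    cache
  }
})
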