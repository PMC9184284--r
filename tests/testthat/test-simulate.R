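test_that("degenerate dynamics behave exactly", {
  plan <- simulation_plan(channel_I, n_frames = 50, rng_seed = 1)
  sp <- species_spec("still", mw = 66, r_s = 3.5)
  set.seed(1)
  tr <- simulate_trajectory(sp, plan, ctx_I, x0 = 12000, D = 0)
  expect_true(all(tr$x_sub == 12000))
  drifting <- species_spec("drift", mw = 66, r_s = 3.5,
                           drift_velocity = 1e5)  # 100 um/s
  set.seed(1)
  tr2 <- simulate_trajectory(drifting, plan, ctx_I, x0 = 1000, D = 0)
  expect_equal(tr2$x_sub,
               1000 + 1e5 * tr2$dt_sub * seq_along(tr2$x_sub),
               tolerance = 1e-10)
})

test_that("sampled MSD slope recovers the input diffusivity", {
  plan <- simulation_plan(channel_geometry(2700, fov_length = 1e7),
                          n_frames = 5000, substeps_per_frame = 1,
                          rng_seed = 5)
  sp <- species_spec("probe", mw = 100, r_s = 5)
  set.seed(5)
  tr <- simulate_trajectory(sp, plan, ctx_I, x0 = 1e7, D = 10e-12)
  dx <- diff(tr$x_sub)
  D_hat <- mean(dx^2) / (2 * plan$dt) * 1e-18
  expect_equal(D_hat, 10e-12, tolerance = 0.05)
  # with drift, the mean displacement per step is v * dt
  spd <- species_spec("probe", mw = 100, r_s = 5, drift_velocity = 2e5)
  set.seed(6)
  trd <- simulate_trajectory(spd, plan, ctx_I, x0 = 1e7, D = 10e-12)
  expect_equal(mean(diff(trd$x_sub)), 2e5 * plan$dt, tolerance = 0.1)
})

test_that("positions stay inside the reflecting domain", {
  plan <- simulation_plan(channel_geometry(2700, fov_length = 2000),
                          n_frames = 500, rng_seed = 2)
  sp <- species_spec("fast", mw = 66, r_s = 3.5)
  set.seed(2)
  tr <- simulate_trajectory(sp, plan, ctx_I, x0 = 2000)
  expect_true(all(tr$x_sub >= 0 & tr$x_sub <= plan$channel$domain_length))
})

test_that("binding events freeze the position", {
  plan <- simulation_plan(
    channel_I, n_frames = 100, rng_seed = 3,
    binding_events = data.frame(start_frame = 30, duration_frames = 40))
  sp <- species_spec("sticky", mw = 669, r_s = 8.6)
  set.seed(3)
  tr <- simulate_trajectory(sp, plan, ctx_I, x0 = 15000)
  S <- plan$substeps_per_frame
  bound <- tr$x_sub[((30 - 1) * S + 1):((30 + 40 - 1) * S)]
  expect_equal(length(unique(bound)), 1)
  expect_gt(length(unique(tr$x_sub[1:((30 - 1) * S)])), 1)
})

test_that("rendering conserves the integrated contrast", {
  om <- optical_model()
  ioc <- ioc_from_mw(669000, 2700, om)
  k <- static_scene(15000, ioc, n_frames = 3, optics = om)
  sums <- rowSums(k$contrast) * om$pixel_pitch
  expect_equal(sums, rep(ioc, 3), tolerance = 1e-3)
})

test_that("motion blur redistributes but conserves contrast", {
  om <- optical_model()
  plan <- simulation_plan(channel_I, n_frames = 20, rng_seed = 4)
  sp <- species_spec("fast", mw = 669, r_s = 3.5)  # heavy and fast
  sim <- simulate_experiment(sp, plan, om, ctx_I, n_molecules = 1,
                             noise = FALSE, x0_range = c(14000, 16000))
  ioc <- sim$truth$ioc_nm
  sums <- rowSums(sim$kymo$contrast) * om$pixel_pitch
  # frames where the whole blurred profile fits inside the field of view
  pos <- sim$positions[[1]]
  inside <- pos > sim$kymo$origin + 2500 &
    pos < sim$kymo$origin + 15000 - 2500
  expect_true(any(inside))
  expect_equal(sums[inside], rep(ioc, sum(inside)), tolerance = 1e-3)
})

test_that("noise-only kymographs sit at the configured noise floor", {
  om <- optical_model()
  plan <- simulation_plan(channel_I, n_frames = 200, rng_seed = 9)
  set.seed(9)
  k <- render_kymograph(list(), om, plan, noise = TRUE)
  expect_equal(sd(k$contrast), om$noise_rel, tolerance = 0.02)
  k0 <- render_kymograph(list(), om, plan, noise = FALSE)
  expect_true(all(k0$contrast == 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  plan <- simulation_plan(channel_I, n_frames = 50, rng_seed = 77)
  sp <- species_spec("BSA", 66, r_s = 3.5)
  a <- simulate_experiment(sp, plan, optical_model(), ctx_I, n_molecules = 1)
  b <- simulate_experiment(sp, plan, optical_model(), ctx_I, n_molecules = 1)
  expect_identical(a$kymo$contrast, b$kymo$contrast)
  expect_identical(a$truth, b$truth)
})

test_that("occupancy sampling follows the expected count", {
  sp <- species_spec("BSA", 66, r_s = 3.5, concentration = 28e-9)
  plan <- simulation_plan(channel_I, n_frames = 2, rng_seed = 1)
  lambda <- expected_count(28e-9, channel_I$area, channel_I$domain_length)
  counts <- vapply(1:60, function(i) {
    plan$rng_seed <- i
    nrow(simulate_experiment(sp, plan, optical_model(), ctx_I)$truth)
  }, numeric(1))
  # Poisson mean over 60 draws: sd of the mean is sqrt(lambda/60)
  expect_equal(mean(counts), lambda,
               tolerance = 3 * sqrt(lambda / 60) / lambda)
})

test_that("mixtures keep per-molecule species labels", {
  plan <- simulation_plan(channel_I, n_frames = 5, rng_seed = 12)
  sps <- list(species_spec("A", 66, r_s = 3.5),
              species_spec("B", 669, r_s = 8.6))
  sim <- simulate_experiment(sps, plan, optical_model(), ctx_I,
                             n_molecules = c(2, 3))
  expect_equal(sum(sim$truth$species == "A"), 2)
  expect_equal(sum(sim$truth$species == "B"), 3)
  expect_equal(sort(unique(sim$truth$mw_kDa)), c(66, 669))
})

test_that("raw embedding inverts the normalization model", {
  k <- static_scene(15000, -0.5, n_frames = 4)
  raw <- as_raw_intensity(k, frame_gain = c(1, 1.01, 0.99, 1))
  expect_true(all(raw > 0))
  expect_equal(dim(raw), dim(k$contrast))
  expect_error(as_raw_intensity(k, profile = -1), "positive")
})
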