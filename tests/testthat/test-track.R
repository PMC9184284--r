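test_that("pure noise yields almost no detections at kappa = 5", {
  om <- optical_model()
  plan <- simulation_plan(channel_I, n_frames = 2000, rng_seed = 41)
  set.seed(41)
  k <- render_kymograph(list(), om, plan, noise = TRUE)
  d <- detect_kymograph(k, om)
  # false-positive rate per line below 1e-2
  expect_lt(nrow(d) / plan$n_frames, 1e-2)
})

test_that("a static dip is located and quantified accurately", {
  om <- optical_model()
  x_true <- 7432.1 + 7500  # inside the FOV (origin at 7500)
  ioc <- -0.12  # SNR ~ 10 per pixel at the default noise
  k <- static_scene(x_true, ioc, n_frames = 40, noise = TRUE, seed = 42)
  d <- detect_kymograph(k, om)
  expect_gte(nrow(d), 35)
  expect_lt(abs(median(d$x_nm) - x_true), 15)
  expect_lt(abs(mean(d$ioc_nm) - ioc) / abs(ioc), 0.05)
  # fixed-width fit and windowed sum agree for an unblurred dip
  expect_lt(abs(mean(d$ioc_fit_nm) - mean(d$ioc_nm)) / abs(ioc), 0.05)
})

test_that("well-separated dips are detected individually", {
  om <- optical_model()
  x1 <- 12000; x2 <- x1 + 5 * om$psf_sigma * 4  # 2000 nm apart
  k <- static_scene(c(x1, x2), c(-0.5, -0.5), n_frames = 10,
                    noise = TRUE, seed = 43)
  d <- detect_kymograph(k, om)
  per_frame <- table(d$frame)
  expect_true(all(per_frame == 2))
})

test_that("localization error decreases with SNR", {
  om <- optical_model()
  errs <- vapply(c(-0.06, -0.12, -0.5, -1.2), function(ioc) {
    k <- static_scene(15000, ioc, n_frames = 60, noise = TRUE,
                      seed = round(abs(ioc * 1000)))
    d <- detect_kymograph(k, om)
    sqrt(mean((d$x_nm - 15000)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("linking keeps one molecule in one trajectory", {
  dets <- data.frame(frame = rep(1:100, each = 1),
                     x_nm = 10000 + cumsum(rnorm(100, sd = 50)),
                     ioc_nm = -0.5, ioc_fit_nm = -0.5, loc_sigma_nm = 10,
                     snr = 20, scale_nm = 100, edge = FALSE)
  trs <- link_detections(dets, dt = 0.005, gate_nm = 500)
  expect_length(trs, 1)
  expect_equal(trs[[1]]$N, 100)
  expect_true(all(diff(trs[[1]]$frame) == 1))
})

test_that("linking is invariant to detection order within frames", {
  set.seed(44)
  f <- rep(1:50, each = 2)
  x <- c(rbind(5000 + cumsum(rnorm(50, sd = 40)),
               12000 + cumsum(rnorm(50, sd = 40))))
  dets <- data.frame(frame = f, x_nm = x, ioc_nm = -0.5, ioc_fit_nm = -0.5,
                     loc_sigma_nm = 10, snr = 20, scale_nm = 100,
                     edge = FALSE)
  trs1 <- link_detections(dets, dt = 0.005, gate_nm = 500)
  perm <- dets[sample(nrow(dets)), ]
  trs2 <- link_detections(perm, dt = 0.005, gate_nm = 500)
  expect_equal(length(trs1), length(trs2))
  sig <- function(trs) {
    s <- lapply(trs, function(t) round(sort(t$x), 6))
    s[order(vapply(s, function(v) v[1], numeric(1)))]
  }
  expect_equal(sig(trs1), sig(trs2))
})

test_that("two distant molecules never swap identities", {
  om <- optical_model()
  # seed chosen so the two molecules stay more than 2.5 um apart throughout
  plan <- simulation_plan(channel_I, n_frames = 150, rng_seed = 59)
  sp <- species_spec("thyroglobulin", 669, r_s = 8.6)
  sim <- simulate_experiment(list(sp, sp), plan, om, ctx_I,
                             n_molecules = c(1, 1),
                             x0_range = c(11000, 19000))
  d <- detect_kymograph(sim$kymo, om)
  trs <- link_detections(d, dt = plan$dt, gate_nm = 1500)
  trs <- filter_trajectories(trs, min_N = 30)
  pos <- do.call(cbind, sim$positions)
  for (tr in trs) {
    # every position matches one and the same truth molecule
    e1 <- abs(tr$x - pos[tr$frame, 1])
    e2 <- abs(tr$x - pos[tr$frame, 2])
    who <- ifelse(e1 < e2, 1, 2)
    expect_equal(length(unique(who)), 1)
  }
})

test_that("gaps longer than the tolerance split trajectories", {
  f <- c(1:30, 40:70)  # 9 missing frames
  dets <- data.frame(frame = f, x_nm = 10000, ioc_nm = -0.5,
                     ioc_fit_nm = -0.5, loc_sigma_nm = 10, snr = 20,
                     scale_nm = 100, edge = FALSE)
  trs <- link_detections(dets, dt = 0.005, gate_nm = 500, gap_frames = 3)
  expect_length(trs, 2)
  expect_equal(sort(vapply(trs, `[[`, numeric(1), "N")), c(30, 31))
})

test_that("short trajectories are dropped and binding segments excised", {
  mk <- function(n, x) {
    structure(list(id = 1, frame = seq_len(n), t_s = seq_len(n) * 5e-3,
                   x = x, ioc = rep(-0.5, n), loc_sigma = rep(10, n),
                   edge = rep(FALSE, n), N = n, flags = character(0),
                   dt = 5e-3),
              class = "trajectory")
  }
  expect_length(filter_trajectories(list(mk(10, rnorm(10, sd = 300))),
                                    min_N = 50), 0)
  # free - bound - free trajectory: 200 bound frames in the middle
  set.seed(46)
  x <- c(cumsum(rnorm(150, sd = 300)), rep(0, 200),
         cumsum(rnorm(150, sd = 300)))
  x[351:500] <- x[351:500] + x[150]
  out <- filter_trajectories(list(mk(500, x)), min_N = 50,
                             immobile_window = 50)
  expect_gte(length(out), 2)
  expect_true(all(vapply(out, function(t)
    "bound_segment_excised" %in% t$flags, logical(1))))
  # the frozen stretch is gone
  kept_frames <- sort(unlist(lapply(out, `[[`, "frame")))
  expect_lt(length(intersect(kept_frames, 170:330)), 30)
  # a freely diffusing trajectory passes through untouched
  set.seed(47)
  free <- mk(300, cumsum(rnorm(300, sd = 300)))
  out2 <- filter_trajectories(list(free), min_N = 50)
  expect_length(out2, 1)
  expect_equal(out2[[1]]$N, 300)
})

test_that("tracked recall is high at realistic SNR", {
  om <- optical_model()
  plan <- simulation_plan(channel_I, n_frames = 300, rng_seed = 48)
  sp <- species_spec("thyroglobulin", 669, r_s = 8.6)
  sim <- simulate_experiment(sp, plan, om, ctx_I, n_molecules = 1,
                             x0_range = c(12000, 18000))
  d <- detect_kymograph(sim$kymo, om)
  pos <- sim$positions[[1]]
  infov <- which(pos > sim$kymo$origin + 1500 &
                   pos < sim$kymo$origin + 15000 - 1500)
  expect_gte(length(intersect(d$frame, infov)) / length(infov), 0.95)
})
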