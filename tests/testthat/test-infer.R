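test_that("trajectory iOC is the mean over usable frames", {
  expect_equal(trajectory_ioc(rep(-0.5, 10)), -0.5)
  expect_equal(trajectory_ioc(c(-1, -2, -3)), -2)
  expect_error(trajectory_ioc(numeric(0)), "empty")
  tr <- structure(list(ioc = c(-1, -2, -9), edge = c(FALSE, FALSE, TRUE)),
                  class = "trajectory")
  expect_equal(trajectory_ioc(tr), -1.5)  # edge-truncated frame excluded
  tr2 <- structure(list(ioc = c(-1, -3), edge = c(TRUE, TRUE)),
                   class = "trajectory")
  expect_equal(trajectory_ioc(tr2), -2)   # all-edge fallback: plain mean
})

test_that("CVE matches hand arithmetic of the two-term formula", {
  # constant displacements of 1 nm at 5 ms: 100 + 200 = 300 nm^2/s
  x <- cumsum(c(0, rep(1, 4)))
  expect_equal(cve_diffusivity(x, 0.005) * 1e18, 300)
  # alternating +-delta: pure-noise signature, -delta^2 / (2 dt)
  d <- 2
  x2 <- cumsum(c(0, d, -d, d, -d))
  expect_equal(cve_diffusivity(x2, 0.005) * 1e18, -d^2 / (2 * 0.005))
  expect_error(cve_diffusivity(c(0, 1), 0.005), "at least 3")
})

test_that("CVE skips displacements across frame gaps", {
  # same positions, but a gap between indices 3 and 4 removes that
  # displacement and both products touching it
  x <- c(0, 1, 2, 10, 11, 12)
  f_gap <- c(1, 2, 3, 7, 8, 9)
  with_gap <- cve_diffusivity(x, 0.005, frames = f_gap) * 1e18
  expect_equal(with_gap, 300)  # as if only the 1-nm steps existed
})

test_that("CVE is unbiased under localization noise", {
  set.seed(51)
  D <- 10e-12; dt <- 0.005; N <- 1e4
  est <- replicate(100, {
    x <- cumsum(c(0, rnorm(N - 1, sd = sqrt(2 * D * 1e18 * dt))))
    xo <- x + rnorm(N, sd = 30)
    cve_diffusivity(xo, dt)
  })
  expect_lt(abs(mean(est) / D - 1), 0.02)
  # variance shrinks roughly like 1/N
  set.seed(52)
  v_short <- var(replicate(200, {
    x <- cumsum(c(0, rnorm(499, sd = sqrt(2 * D * 1e18 * dt)))) +
      rnorm(500, sd = 30)
    cve_diffusivity(x, dt)
  }))
  set.seed(53)
  v_long <- var(replicate(200, {
    x <- cumsum(c(0, rnorm(1999, sd = sqrt(2 * D * 1e18 * dt)))) +
      rnorm(2000, sd = 30)
    cve_diffusivity(x, dt)
  }))
  expect_lt(v_long, v_short / 2)
})

test_that("flow mode removes drift before estimating D", {
  set.seed(54)
  D <- 10e-12; dt <- 0.005; N <- 5e3
  x <- cumsum(c(0, rnorm(N - 1, sd = sqrt(2 * D * 1e18 * dt)))) +
    seq_len(N) * 500  # 100 um/s drift
  biased <- cve_diffusivity(x, dt)
  unbiased <- cve_diffusivity(x, dt, flow = TRUE)
  expect_gt(biased / D, 2)
  expect_lt(abs(unbiased / D - 1), 0.1)
})

test_that("characterization converts and flags correctly", {
  n <- 200
  set.seed(55)
  D <- hindered_diffusivity(8.6, ctx_I)
  x <- cumsum(c(0, rnorm(n - 1, sd = sqrt(2 * D * 1e18 * 0.005))))
  ioc <- ioc_from_mw(669000, 2700, optical_model())
  tr <- structure(list(id = 1, frame = seq_len(n), t_s = seq_len(n) * 5e-3,
                       x = x, ioc = rep(ioc, n), loc_sigma = rep(10, n),
                       edge = rep(FALSE, n), N = n, flags = character(0),
                       dt = 5e-3),
                  class = "trajectory")
  est <- characterize_trajectory(tr, channel_I)
  expect_equal(est$mw_kDa, 669, tolerance = 1e-6)
  expect_equal(est$rs_nm, 8.6, tolerance = 0.35)
  expect_equal(est$flags, "")
  # a noise-dominated trajectory: negative D is preserved and flagged
  tr$x <- rep(c(0, 5), length.out = n)
  est2 <- characterize_trajectory(tr, channel_I)
  expect_lt(est2$D_um2_s, 0)
  expect_true(grepl("invalid_negative_D", est2$flags))
  expect_true(is.na(est2$rs_nm))
  expect_equal(est2$mw_kDa, 669, tolerance = 1e-6)  # mass still reported
})

test_that("population histogram weights trajectories by N", {
  est <- data.frame(mw_kDa = c(60, 90), N = c(100, 300))
  h <- population_histogram(est, "mw_kDa", bin_width = 10)
  expect_equal(sum(h$counts), 1)
  expect_equal(sort(h$counts[h$counts > 0]), c(0.25, 0.75))
  one <- population_histogram(data.frame(mw_kDa = 66, N = 10), "mw_kDa",
                              bin_width = 5)
  expect_equal(sum(one$counts), 1)
  expect_error(population_histogram(data.frame(mw_kDa = NA_real_, N = 1),
                                    "mw_kDa"), "no valid")
})

test_that("histogram mass is conserved for any weighting", {
  set.seed(56)
  for (i in 1:5) {
    est <- data.frame(mw_kDa = rnorm(50, 100, 20),
                      N = sample(50:1000, 50, replace = TRUE))
    h <- population_histogram(est, "mw_kDa")
    expect_equal(sum(h$counts), 1, tolerance = 1e-12)
  }
})

test_that("Gaussian fit recovers a known population", {
  set.seed(57)
  est <- data.frame(mw_kDa = rnorm(1e4, 66, 5), N = 500)
  f <- fit_population(population_histogram(est, "mw_kDa"))
  expect_equal(f$center, 66, tolerance = 0.5 / 66)
  expect_equal(f$fwhm, 2 * sqrt(2 * log(2)) * 5, tolerance = 1 / 11.77)
  expect_equal(f$fwhm, 2.3548 * f$sigma, tolerance = 1e-4)
  # mixture with user-supplied initialization
  est2 <- data.frame(mw_kDa = c(rnorm(5e3, 66, 4), rnorm(5e3, 132, 6)),
                     N = 500)
  f2 <- fit_population(population_histogram(est2, "mw_kDa"),
                       n_components = 2,
                       init = list(center = c(60, 140), sigma = c(5, 5),
                                   amplitude = c(0.05, 0.05)))
  expect_equal(f2$center, c(66, 132), tolerance = 0.02)
  expect_error(
    fit_population(population_histogram(est, "mw_kDa"), n_components = 2),
    "init")
  expect_error(
    fit_population(population_histogram(data.frame(mw_kDa = rep(66, 3),
                                                   N = 1),
                                        "mw_kDa", bin_width = 1)),
    "degenerate")
})

test_that("a rare heavy population appears with its concentration", {
  set.seed(58)
  n <- 2000
  is_dimer <- runif(n) < 0.05
  est <- data.frame(mw_kDa = ifelse(is_dimer, rnorm(n, 132, 3),
                                    rnorm(n, 66, 3)),
                    N = 500)
  h <- population_histogram(est, "mw_kDa", bin_width = 5)
  heavy <- sum(h$counts[h$mids > 100])
  expect_equal(heavy, 0.05, tolerance = 0.4)
})

test_that("MW resolution improves with trajectory length", {
  fwhms <- vapply(c(50, 200, 1000), function(nf) {
    st <- nsm_study(species_spec("BSA", 66, r_s = 3.5), channel_I,
                    n_traj = 14, n_frames = nf, seed = 59,
                    min_N = min(50, nf - 10), raw_roundtrip = FALSE)
    f <- fit_population(population_histogram(st$estimates, "mw_kDa"))
    f$fwhm
  }, numeric(1))
  expect_lt(fwhms[3], fwhms[1])
})
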