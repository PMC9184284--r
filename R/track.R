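#' Detect molecule dips in every frame of a kymograph
#'
#' Multi-scale matched-filter detector. Each frame (row) is correlated
#' with Gaussian templates at a small set of widths (the optical
#' line-spread width times `scales`), because fast molecules are widened
#' by motion blur well beyond the static line-spread function. Templates
#' have unit L2 norm, so the filtered noise keeps the per-pixel noise
#' standard deviation, estimated robustly from the filtered kymograph by
#' the median absolute deviation. Local minima of a filtered line below
#' `-kappa` times the noise level are candidates; candidates from
#' different scales that fall on the same dip are merged, keeping the
#' scale with the strongest normalized response. Each surviving candidate
#' is refined by a least-squares Gaussian fit with fixed width (the
#' winning scale; Gauss-Newton on the subpixel position, amplitude in
#' closed form).
#'
#' The per-frame integrated contrast `ioc_nm` is the windowed sum of
#' contrast within `ioc_halfwidth` of the fitted position times the pixel
#' pitch, which is insensitive to motion blur redistributing the profile.
#' The amplitude-based estimate `ioc_fit_nm` (amplitude x sigma x
#' sqrt(2 pi)) is also reported; the two agree for slow molecules and the
#' windowed sum is the default used downstream. Candidates closer to the
#' field-of-view edges than their fit window are rejected.
#'
#' @param kymo A [kymograph()] of relative contrast.
#' @param optics An [optical_model()] (supplies the line-spread width).
#' @param kappa Detection threshold in units of filtered noise (default 5).
#' @param scales Template widths as multiples of `psf_sigma` (default
#'   c(1, 2, 4), covering static to strongly blurred profiles).
#' @param template_sigma Single template width in nm, overriding `scales`.
#' @param ioc_halfwidth Half-width in nm of the summation window for the
#'   integrated contrast (default 10 x psf_sigma).
#' @return A data.frame with one row per detection: `frame`, `x_nm`,
#'   `ioc_nm`, `ioc_fit_nm`, `loc_sigma_nm`, `snr`, `scale_nm`, and
#'   `edge` (TRUE when the summation window was clipped by the
#'   field-of-view boundary, so `ioc_nm` underestimates the molecule's
#'   contrast; such frames are excluded from the trajectory-mean iOC but
#'   still used for linking and diffusivity).
#' @export
detect_kymograph <- function(kymo, optics = optical_model(),
                             kappa = 5, scales = c(1, 2, 4),
                             template_sigma = NULL,
                             ioc_halfwidth = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  K <- kymo$contrast
  pitch <- kymo$pixel_pitch
  sigmas <- if (is.null(template_sigma)) optics$psf_sigma * scales else
    template_sigma
  if (is.null(ioc_halfwidth)) ioc_halfwidth <- 10 * optics$psf_sigma
  n_px <- ncol(K)
  empty <- data.frame(frame = integer(), x_nm = numeric(),
                      ioc_nm = numeric(), ioc_fit_nm = numeric(),
                      loc_sigma_nm = numeric(), snr = numeric(),
                      scale_nm = numeric(), edge = logical())

  # candidate minima at every scale; all templates share one forward FFT
  hws <- ceiling(4 * sigmas / pitch)
  usable <- 2 * hws + 1 < n_px
  sigmas <- sigmas[usable]
  hws <- hws[usable]
  if (length(sigmas) == 0) return(empty)
  FMs <- filter_rows_fft(K, lapply(seq_along(sigmas), function(i) {
    kt <- exp(-((-hws[i]:hws[i]) * pitch)^2 / (2 * sigmas[i]^2))
    kt / sqrt(sum(kt^2))
  }))
  cands <- list()
  for (si in seq_along(sigmas)) {
    sigma <- sigmas[si]
    hw <- hws[si]
    FM <- FMs[[si]]
    # unit-norm template: filtered white noise keeps the pixel noise sd;
    # estimate it robustly on a strided subsample
    sub <- FM[seq(1, length(FM), by = max(1L, length(FM) %/% 50000L))]
    sig_f <- stats::mad(sub)
    if (!is.finite(sig_f) || sig_f == 0) sig_f <- stats::sd(sub)
    left <- cbind(Inf, FM[, -n_px, drop = FALSE])
    right <- cbind(FM[, -1, drop = FALSE], Inf)
    cand <- which(FM < -kappa * sig_f & FM <= left & FM < right,
                  arr.ind = TRUE)
    if (nrow(cand) == 0) next
    margin <- max(hw, ceiling(3 * optics$psf_sigma / pitch))
    keep <- cand[, 2] > margin & cand[, 2] <= n_px - margin
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    fr <- cand[, 1]; ci <- cand[, 2]
    fm <- FM[cand]
    fl <- FM[cbind(fr, ci - 1L)]
    frr <- FM[cbind(fr, ci + 1L)]
    den <- fl - 2 * fm + frr
    u0 <- ifelse(abs(den) > 0, 0.5 * (fl - frr) / den * pitch, 0)
    cands[[length(cands) + 1]] <- data.frame(
      frame = fr, ci = ci, u0 = pmax(pmin(u0, pitch), -pitch),
      snr = abs(fm) / sig_f, sigma = sigma, noise = sig_f)
  }
  if (length(cands) == 0) return(empty)
  cand <- do.call(rbind, cands)

  # merge across scales: within a frame, candidates closer than 2.5x the
  # wider of the two templates belong to the same dip; keep the strongest
  # normalized response
  cand <- cand[order(cand$frame, -cand$snr), ]
  keep <- logical(nrow(cand))
  for (idx in split(seq_len(nrow(cand)), cand$frame)) {
    taken_x <- numeric(0)
    taken_s <- numeric(0)
    for (i in idx) {
      x <- cand$ci[i] * pitch
      sep <- 2.5 * pmax(cand$sigma[i], taken_s)
      if (all(abs(x - taken_x) > sep)) {
        keep[i] <- TRUE
        taken_x <- c(taken_x, x)
        taken_s <- c(taken_s, cand$sigma[i])
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  # subpixel Gauss-Newton refinement at the winning scale (fixed width,
  # amplitude in closed form), vectorized per scale
  cand$u <- cand$u0
  cand$A <- NA_real_
  for (sigma in unique(cand$sigma)) {
    rows <- which(cand$sigma == sigma)
    cc <- cand[rows, , drop = FALSE]
    nc <- nrow(cc)
    fit_hw <- ceiling(4 * sigma / pitch)
    offs <- (-fit_hw:fit_hw) * pitch
    L <- length(offs)
    colidx <- outer(cc$ci, -fit_hw:fit_hw, "+")
    Y <- matrix(K[cbind(rep(cc$frame, L), as.vector(colidx))], nc, L)
    O <- matrix(offs, nc, L, byrow = TRUE)
    u <- cc$u0
    A <- numeric(nc)
    for (it in 1:6) {
      G <- exp(-(O - u)^2 / (2 * sigma^2))
      A <- rowSums(Y * G) / rowSums(G * G)
      R <- Y - A * G
      dG <- A * G * (O - u) / sigma^2
      step <- rowSums(R * dG) / pmax(rowSums(dG * dG), 1e-300)
      step <- pmax(pmin(step, pitch), -pitch)
      u <- u + step
    }
    cand$u[rows] <- u
    cand$A[rows] <- A
  }

  # iterative windowed centroid: the center of mass of the dip over a wide
  # window estimates the frame-averaged (motion-blurred) position, which is
  # what the covariance-based diffusivity estimator expects; iterating
  # recenters the window on the centroid
  sum_hw <- ceiling(max(ioc_halfwidth, 4 * max(cand$sigma)) / pitch)
  soffs <- (-sum_hw:sum_hw) * pitch
  nc <- nrow(cand)
  pos <- (cand$ci - 1) * pitch + cand$u
  # per-frame residual offset, estimated from pixels far from any detection
  # in that frame: the robust per-frame gain of the normalization is biased
  # by the dip itself (it pulls the frame median down), and even an offset
  # of a fraction of the noise level integrates to a sizeable error over
  # the wide summation window
  excl_hw <- sum_hw + ceiling(1000 / pitch)
  frame_offset <- numeric(nrow(K))
  for (f in unique(cand$frame)) {
    ci_f <- cand$ci[cand$frame == f]
    far <- rep(TRUE, n_px)
    for (c0 in ci_f) {
      far[max(1, c0 - excl_hw):min(n_px, c0 + excl_hw)] <- FALSE
    }
    if (sum(far) >= 20) frame_offset[f] <- stats::median(K[f, far])
  }
  gather <- function(center_px) {
    scol <- outer(center_px, -sum_hw:sum_hw, "+")
    okm <- scol >= 1L & scol <= n_px
    scol_c <- pmin(pmax(scol, 1L), n_px)
    YS <- matrix(K[cbind(rep(cand$frame, ncol(scol)), as.vector(scol_c))],
                 nc, ncol(scol))
    YS <- YS - frame_offset[cand$frame]
    YS[!okm] <- 0
    list(Y = YS, clipped = rowSums(!okm) > 0)
  }
  for (it in 1:3) {
    cpx <- pmin(pmax(as.integer(round(pos / pitch)) + 1L, 1L), n_px)
    g <- gather(cpx)
    wsum <- rowSums(g$Y)
    num <- rowSums(g$Y * matrix(soffs, nc, length(soffs), byrow = TRUE))
    shift <- ifelse(abs(wsum) > 0, num / wsum, 0)
    shift <- pmax(pmin(shift, 500), -500)
    pos <- (cpx - 1) * pitch + shift
  }
  cpx <- pmin(pmax(as.integer(round(pos / pitch)) + 1L, 1L), n_px)
  g <- gather(cpx)
  ioc_sum <- rowSums(g$Y) * pitch
  x_nm <- kymo$origin + pos
  # centroid localization uncertainty from the pixel noise
  Xc <- matrix(soffs, nc, length(soffs), byrow = TRUE) -
    (pos - (cpx - 1) * pitch)
  loc_sigma <- cand$noise * pitch * sqrt(rowSums(Xc^2) / pitch^2) /
    pmax(abs(ioc_sum / pitch), 1e-300)

  out <- data.frame(frame = cand$frame, x_nm = x_nm, ioc_nm = ioc_sum,
                    ioc_fit_nm = cand$A * cand$sigma * sqrt(2 * pi),
                    loc_sigma_nm = loc_sigma, snr = cand$snr,
                    scale_nm = cand$sigma, edge = g$clipped)

  # centroids of duplicate lobe detections converge to the same position;
  # keep the strongest per cluster
  out <- out[order(out$frame, -out$snr), ]
  keep <- logical(nrow(out))
  for (idx in split(seq_len(nrow(out)), out$frame)) {
    taken_x <- numeric(0)
    taken_s <- numeric(0)
    for (i in idx) {
      sep <- 2.5 * pmax(out$scale_nm[i], taken_s)
      if (all(abs(out$x_nm[i] - taken_x) > sep)) {
        keep[i] <- TRUE
        taken_x <- c(taken_x, out$x_nm[i])
        taken_s <- c(taken_s, out$scale_nm[i])
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$frame, out$x_nm), ]
  rownames(out) <- NULL
  out
}

#' Default linking gate from a worst-case diffusivity
#'
#' gate = 4 sqrt(2 D_max dt) + |v| dt: four standard deviations of the
#' per-frame Brownian displacement of the fastest species expected, plus
#' the deterministic drift.
#'
#' @param dt Frame interval in s.
#' @param d_max Largest expected diffusivity in um^2/s (default 30).
#' @param drift Drift velocity in nm/s (default 0).
#' @return Gate in nm.
#' @export
linking_gate <- function(dt, d_max = 30, drift = 0) {
  4 * sqrt(2 * d_max * 1e6 * dt) + abs(drift) * dt
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbor linking: frame by frame, candidate links between
#' open trajectories and new detections are sorted by displacement
#' magnitude (after subtracting the expected drift) and accepted in order,
#' each detection and each trajectory used at most once; links beyond the
#' gate (scaled by sqrt of the frame gap for skipped frames) are forbidden.
#' Trajectories tolerate up to `gap_frames` consecutive missed frames, then
#' close. In flow mode (`drift = "auto"`) the per-frame drift is estimated
#' as the median nearest-neighbor displacement between consecutive frames
#' before linking.
#'
#' @param detections Data.frame from [detect_kymograph()].
#' @param dt Frame interval in s.
#' @param gate_nm Maximum linking displacement per frame in nm (default
#'   [linking_gate()] at 30 um^2/s).
#' @param gap_frames Tolerated missed frames (default 3).
#' @param drift Expected displacement per frame in nm, or "auto" to
#'   estimate it from the data (flow mode). Default 0.
#' @return A list of `trajectory` objects: each a list with `id`, `frame`,
#'   `t_s`, `x`, `ioc`, `loc_sigma`, `N` and `flags`.
#' @export
link_detections <- function(detections, dt, gate_nm = linking_gate(dt),
                            gap_frames = 3, drift = 0) {
  stopifnot(gate_nm > 0, gap_frames >= 0)
  if (nrow(detections) == 0) return(list())
  if (identical(drift, "auto")) {
    drift <- estimate_frame_drift(detections)
  }
  dets <- split(detections, detections$frame)
  frames <- as.integer(names(dets))
  open <- list()   # each: list(rows = data.frame rows, last_x, last_frame)
  done <- list()
  for (f in frames) {
    d <- dets[[as.character(f)]]
    # close stale trajectories
    if (length(open)) {
      stale <- vapply(open, function(tr) f - tr$last_frame > gap_frames + 1,
                      logical(1))
      done <- c(done, open[stale])
      open <- open[!stale]
    }
    n_open <- length(open)
    n_det <- nrow(d)
    used_det <- rep(FALSE, n_det)
    if (n_open > 0) {
      last_x <- vapply(open, `[[`, numeric(1), "last_x")
      last_f <- vapply(open, `[[`, numeric(1), "last_frame")
      gap <- f - last_f
      disp <- outer(last_x + drift * gap, d$x_nm,
                    function(a, b) abs(b - a))
      lim <- gate_nm * sqrt(gap)
      allowed <- sweep(disp, 1, lim, "<=")
      cand <- which(allowed, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cost <- disp[cand]
        ord <- order(cost, -abs(d$ioc_nm[cand[, 2]]))
        used_tr <- rep(FALSE, n_open)
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_tr[i] || used_det[j]) next
          used_tr[i] <- TRUE
          used_det[j] <- TRUE
          open[[i]]$rows <- rbind(open[[i]]$rows, d[j, ])
          open[[i]]$last_x <- d$x_nm[j]
          open[[i]]$last_frame <- f
        }
      }
    }
    for (j in which(!used_det)) {
      open[[length(open) + 1]] <- list(rows = d[j, ], last_x = d$x_nm[j],
                                       last_frame = f)
    }
  }
  done <- c(done, open)
  trajs <- lapply(seq_along(done), function(i) {
    r <- done[[i]]$rows
    edge <- if (is.null(r$edge)) rep(FALSE, nrow(r)) else r$edge
    structure(list(id = i, frame = r$frame, t_s = (r$frame - 1) * dt,
                   x = r$x_nm, ioc = r$ioc_nm,
                   loc_sigma = r$loc_sigma_nm, edge = edge, N = nrow(r),
                   flags = character(0), dt = dt),
              class = "trajectory")
  })
  trajs
}

# Median nearest-neighbor displacement between consecutive frames.
estimate_frame_drift <- function(detections) {
  dets <- split(detections$x_nm, detections$frame)
  frames <- as.integer(names(dets))
  disp <- numeric(0)
  for (i in seq_len(length(frames) - 1)) {
    if (frames[i + 1] != frames[i] + 1) next
    a <- dets[[i]]; b <- dets[[i + 1]]
    for (x in a) disp <- c(disp, b[which.min(abs(b - x))] - x)
  }
  if (length(disp) == 0) 0 else stats::median(disp)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory %d> N = %d frames [%d..%d], mean iOC = %.4g nm%s\n",
    x$id, x$N, min(x$frame), max(x$frame), mean(x$ioc),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Filter trajectories and excise transient binding segments
#'
#' Drops trajectories shorter than `min_N` frames and removes segments
#' where the molecule is transiently bound to the wall. Binding is
#' recognized as anomalously low positional variability: the rolling
#' standard deviation of position over `immobile_window` frames falling
#' below `immobile_sigma_factor` times the median localization uncertainty
#' (a freely diffusing molecule moves much farther between frames than the
#' localization noise). Flagged segments are excised and the remaining
#' free segments are re-emitted as separate trajectories when still at
#' least `min_N` frames long.
#'
#' @param trajs List of trajectories from [link_detections()].
#' @param min_N Minimum trajectory length in frames (default 50).
#' @param immobile_window Rolling window in frames for the immobility test
#'   (default 50).
#' @param immobile_sigma_factor Multiple of the median localization sigma
#'   below which a segment counts as bound (default 3).
#' @return A list of trajectories with binding segments removed; excised
#'   trajectories carry the flag `"bound_segment_excised"`.
#' @export
filter_trajectories <- function(trajs, min_N = 50, immobile_window = 50,
                                immobile_sigma_factor = 3) {
  stopifnot(min_N >= 2)
  out <- list()
  for (tr in trajs) {
    if (tr$N < min_N) next
    bound <- immobile_mask(tr$x, immobile_window,
                           immobile_sigma_factor *
                             stats::median(tr$loc_sigma))
    if (!any(bound)) {
      out[[length(out) + 1]] <- tr
      next
    }
    runs <- rle(!bound)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      sel <- idx_start[k]:idx_end[k]
      if (length(sel) < min_N) next
      seg <- tr
      seg$frame <- tr$frame[sel]; seg$t_s <- tr$t_s[sel]
      seg$x <- tr$x[sel]; seg$ioc <- tr$ioc[sel]
      seg$loc_sigma <- tr$loc_sigma[sel]
      seg$edge <- tr$edge[sel]
      seg$N <- length(sel)
      seg$flags <- union(tr$flags, "bound_segment_excised")
      out[[length(out) + 1]] <- seg
    }
  }
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

# TRUE where the centered rolling sd of x falls below `threshold`.
immobile_mask <- function(x, window, threshold) {
  n <- length(x)
  if (n < window || threshold <= 0) return(rep(FALSE, n))
  half <- floor(window / 2)
  rsd <- rep(NA_real_, n)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  m <- hi - lo + 1
  sx <- cs[hi + 1] - cs[lo]
  sx2 <- cs2[hi + 1] - cs2[lo]
  v <- (sx2 - sx^2 / m) / (m - 1)
  rsd <- sqrt(pmax(v, 0))
  rsd < threshold
}

#' Flatten trajectories to a tidy data.frame
#'
#' @param trajs List of trajectories.
#' @return Data.frame with columns `traj_id`, `frame`, `t_s`, `x_nm`,
#'   `ioc_nm`, `loc_sigma_nm`, `flag`.
#' @export
trajectories_to_df <- function(trajs) {
  if (length(trajs) == 0) {
    return(data.frame(traj_id = integer(), frame = integer(),
                      t_s = numeric(), x_nm = numeric(), ioc_nm = numeric(),
                      loc_sigma_nm = numeric(), flag = character()))
  }
  do.call(rbind, lapply(trajs, function(tr) {
    data.frame(traj_id = tr$id, frame = tr$frame, t_s = tr$t_s,
               x_nm = tr$x, ioc_nm = tr$ioc, loc_sigma_nm = tr$loc_sigma,
               flag = paste(tr$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

# Correlate every row of K with each kernel (odd length, centered), sharing
# one forward FFT across kernels. Circular wrap only affects pixels within
# a kernel half-width of the edges, which the detector's edge margin
# discards anyway.
filter_rows_fft <- function(K, kernels) {
  n_px <- ncol(K)
  maxlen <- max(vapply(kernels, length, integer(1)))
  P <- stats::nextn(n_px + maxlen, c(2, 3, 5))
  Kp <- matrix(0, P, nrow(K))
  Kp[seq_len(n_px), ] <- t(K)
  Ff <- stats::mvfft(Kp)
  lapply(kernels, function(kt) {
    hw <- (length(kt) - 1L) %/% 2L
    kv <- numeric(P)
    kv[c(seq_len(hw + 1L), P - seq_len(hw) + 1L)] <-
      c(kt[(hw + 1L):(2L * hw + 1L)], kt[hw:1L])
    kf <- stats::fft(kv)
    out <- Re(stats::mvfft(Ff * kf, inverse = TRUE)) / P
    t(out[seq_len(n_px), , drop = FALSE])
  })
}
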