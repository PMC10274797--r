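test_that("model MSDs: closed forms and parameter validation", {
  tt <- 10^seq(-4, 0, by = 0.1)
  # Stokes-Einstein
  eta <- 2e-3
  m <- msd_from_model(rheo_newtonian(eta, 300, 1e-6), tt)
  expect_equal(m$msd, KB * 300 / (pi * 1e-6 * eta) * tt, tolerance = 1e-14)
  # power law pushed through the pipeline GSER returns |G*| = A w^alpha0
  A <- 0.05; al0 <- 0.6
  mp <- msd_from_model(rheo_powerlaw(A, al0), 10^seq(-5, 0, by = 0.02))
  sp <- gser(compute_alpha(mp), gser_context())
  expect_lt(max(abs(sp$G_mag[sp$valid] - A * sp$omega[sp$valid]^al0) /
                  (A * sp$omega[sp$valid]^al0)), 1e-8)
  # Maxwell from the creep compliance: alpha crosses 0.5 at t = tau_r
  tau <- 7e-3
  mm <- msd_from_model(rheo_maxwell(50, tau), 10^seq(-5, 0.5, by = 0.02))
  am <- compute_alpha(mm)
  cross <- which(diff(sign(am$alpha - 0.5)) != 0)[1L]
  t_cross <- 1 / am$omega[cross]
  expect_rel(t_cross, tau, 0.1)
  expect_error(rheo_powerlaw(0.1, 1.2), "alpha0")
  expect_error(rheo_piecewise_msd(c(1e-3, 1e-2), c(1e-13, 1e-11)), "slopes")
})

test_that("synthesize_g2: static limit and beta handling", {
  cal <- cal_mid
  tt <- 10^seq(-4, -1, by = 0.1)
  m0 <- msd_curve(tt, rep(0, length(tt)))
  g2 <- synthesize_g2(m0, cal, beta = 0.7)
  expect_equal(g2$g2, rep(1.7, length(tt) + 1L), tolerance = 1e-14)
  expect_equal(normalize_g2(g2)$g2, rep(2, length(tt) + 1L), tolerance = 1e-14)
})

test_that("default instrument: measured speckle size 3.5 px within 10%", {
  inst <- instrument_model(shape = c(64L, 64L), n_frames = 10L, seed = 2L)
  m <- msd_curve(10^seq(-5, -2, length.out = 9), rep(0, 9))
  mv <- synthesize_speckle_movie(m, cal_dls, inst)
  expect_rel(measure_speckle_size(mv, 10L), 3.5, 0.10)
  # a different requested size is honoured too
  inst6 <- instrument_model(shape = c(64L, 64L), n_frames = 10L, seed = 2L,
                            speckle_size = 6)
  mv6 <- synthesize_speckle_movie(m, cal_dls, inst6)
  expect_rel(measure_speckle_size(mv6, 10L), 6, 0.10)
  expect_error(instrument_model(speckle_size = 1.5), "undersampled")
})

test_that("zero-dynamics schedule freezes the movie: pipeline g2 = 2", {
  inst <- instrument_model(shape = c(48L, 48L), n_frames = 12L, seed = 5L,
                           drp_radius_px = 18)
  m0 <- msd_curve(10^seq(-5, -2, length.out = 9), rep(0, 9))
  mv <- synthesize_speckle_movie(m0, cal_dls, inst)
  g2 <- compute_g2(mv, lags = 0:10)
  expect_equal(g2$g2, rep(2, 11L), tolerance = 1e-9)
})

test_that("movies are bit-identical under the same seed and config", {
  inst <- instrument_model(shape = c(32L, 32L), n_frames = 40L, seed = 123L,
                           shot_noise = TRUE)
  model <- rheo_newtonian(3e-3)
  a <- synthesize_speckle_movie(model, cal_dls, inst)
  b <- synthesize_speckle_movie(model, cal_dls, inst)
  expect_identical(a$frames, b$frames)
  inst2 <- instrument_model(shape = c(32L, 32L), n_frames = 40L, seed = 124L,
                            shot_noise = TRUE)
  c2 <- synthesize_speckle_movie(model, cal_dls, inst2)
  expect_false(identical(a$frames, c2$frames))
})

test_that("fully developed speckle: contrast ~ 1 inside the 1/e disc", {
  chain <- newtonian_movie_chain()
  mv <- chain$movie
  roi <- chain$res$roi
  cons <- vapply(c(1L, 1000L, 3000L), function(i) {
    I <- mv$frames[, , i][roi]
    sd(I) / mean(I)
  }, 0)
  # raw contrast carries a small envelope inflation (~8% for a Gaussian DRP)
  expect_true(all(abs(cons - 1) < 0.12))
  # envelope-corrected contrast is within 10% of 1
  A <- rowMeans(mv$frames, dims = 2L)
  Iflat <- mv$frames[, , 1L][roi] / A[roi]
  expect_lt(abs(sd(Iflat) / mean(Iflat) - 1), 0.1)
})

test_that("two-decade power-law movie matches its target g2 within 5% RMS", {
  model <- rheo_powerlaw(0.03, 0.5)
  inst <- instrument_model(shape = c(64L, 64L), n_frames = 4000L,
                           frame_rate = 1e4, seed = 31L)
  mv <- synthesize_speckle_movie(model, cal_dls, inst)
  g2 <- compute_g2(mv)
  tt <- g2$lags[g2$lags > 0]
  target <- 1 + exp(-2 * cal_dls$gamma *
                      (cal_dls$k^2 * msd_from_model(model, tt)$msd)^cal_dls$zeta)
  sel <- target - 1 > 0.05
  rms <- sqrt(mean(((g2$g2[g2$lags > 0][sel] - target[sel]) /
                      (target[sel] - 1))^2))
  expect_lt(rms, 0.05)
  tspan <- range(tt[sel])
  expect_gt(log10(tspan[2] / tspan[1]), 2)   # at least two decades probed
})

test_that("full-chain Newtonian viscosity recovery within 5% from a movie", {
  chain <- newtonian_movie_chain()
  sp <- chain$res$spectrum
  sel <- sp$valid & !chain$res$alpha$edge
  f <- stats::lm(log10(sp$G_loss[sel]) ~ log10(sp$omega[sel]))
  expect_lt(abs(coef(f)[2L] - 1), 0.02)
  expect_rel(10^coef(f)[1L], chain$eta, 0.05)
})

test_that("full-chain Maxwell: (G0, tau_r) recovered within 10% from a movie", {
  # soft enough that the plateau sits at k^2 MSD ~ 0.3, where the log
  # inversion is well conditioned (stiffer samples pin g2 - 1 near its
  # ceiling, where tiny estimator noise blows up in -log(g2 - 1))
  G0 <- 0.5; tau <- 4e-3
  model <- rheo_maxwell(G0, tau)
  inst <- instrument_model(shape = c(64L, 64L), n_frames = 8000L,
                           frame_rate = 2e4, seed = 13L)
  mv <- synthesize_speckle_movie(model, cal_dls, inst)
  res <- process_speckle(mv, calibration = cal_dls)
  tr <- res$params$transitions
  expect_gte(nrow(tr), 1L)
  expect_rel(tr$omega_T[1L], 1 / tau, 0.10)
  pl <- res$params$plateaus
  if (nrow(pl)) expect_rel(pl$G0[1L], G0, 0.15)
  # plateau modulus via G' at the top of the band as fallback diagnostic
  sp <- res$spectrum
  hi <- sp$valid & sp$omega > 3 / tau & sp$omega < 30 / tau
  expect_rel(stats::median(sp$G_storage[hi]), G0, 0.10)
})

test_that("planted two-exponent MSD recovered within 15% from a movie", {
  # piecewise MSD with log-log slopes 0.25 (t < 5 ms) then 0.85 (t > 5 ms):
  # alpha(omega) should read 0.85 at low omega and 0.25 at high omega
  tb <- 5e-3
  msd_b <- 2.9e-15
  knots_t <- c(1e-6, tb, 1)
  knots_m <- c(msd_b * (1e-6 / tb)^0.25, msd_b, msd_b * (1 / tb)^0.85)
  model <- rheo_piecewise_msd(knots_t, knots_m)
  inst <- instrument_model(shape = c(64L, 64L), n_frames = 8000L,
                           frame_rate = 2e4, seed = 19L)
  mv <- synthesize_speckle_movie(model, cal_dls, inst)
  res <- process_speckle(mv, calibration = cal_dls)
  a <- res$alpha
  lo_ok <- a$omega > 40 & a$omega < 120 & !a$edge     # t >> tb
  hi_ok <- a$omega > 600 & a$omega < 5e3 & !a$edge    # t << tb
  expect_gt(sum(lo_ok), 5); expect_gt(sum(hi_ok), 5)
  expect_lt(abs(stats::median(a$alpha[lo_ok]) - 0.85), 0.15 * 0.85)
  expect_lt(abs(stats::median(a$alpha[hi_ok]) - 0.25), 0.15 * 0.85)
})
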