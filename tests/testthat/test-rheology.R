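test_that("MSD inversion algebra matches the closed forms at both limits", {
  # gamma = 2/3, zeta = 1, g2 - 1 = exp(-1)  =>  k^2 MSD = 3/4 exactly
  cc <- correlation_curve(c(0, 1e-4), c(2, 1 + exp(-1)), normalized = TRUE)
  m <- invert_msd(cc, cal_dls, mask = c(TRUE, TRUE))
  expect_equal(cal_dls$k^2 * m$msd, 0.75, tolerance = 1e-14)
  # gamma = 5/3, zeta = 0.5, g2 - 1 = exp(-10/3)  =>  k^2 MSD = 1 exactly
  cc2 <- correlation_curve(c(0, 1e-4), c(2, 1 + exp(-10 / 3)), normalized = TRUE)
  m2 <- invert_msd(cc2, cal_dws, mask = c(TRUE, TRUE))
  expect_equal(cal_dws$k^2 * m2$msd, 1, tolerance = 1e-14)
})

test_that("forward synthesis then inversion is the identity (any calibration)", {
  tt <- 10^seq(-5, -0.5, by = 0.05)
  for (cal in list(cal_dls, cal_dws, cal_mid)) {
    for (beta in c(1, 0.62)) {
      msd <- msd_from_model(rheo_powerlaw(0.05, 0.6), tt)
      g2 <- synthesize_g2(msd, cal, beta = beta)
      m <- invert_msd(g2, cal)
      ok <- m$valid
      expect_gt(sum(ok), 20)
      ref <- stats::approx(msd$times, msd$msd, xout = m$times[ok])$y
      expect_lt(max(abs(m$msd[ok] - ref) / ref), 1e-10)
    }
  }
})

test_that("fully decorrelated input is rejected", {
  cc <- correlation_curve(c(0, 1e-3, 2e-3), c(2, 1.001, 1.0), normalized = TRUE)
  expect_error(invert_msd(cc, cal_dls), "decorrelated")
})

test_that("alpha of exact power laws is exact; spans < 1 decade are rejected", {
  tt <- 10^seq(-5, -1, by = 0.02)
  m05 <- msd_curve(tt, 1e-13 * (tt / 1e-3)^0.5)
  a <- compute_alpha(m05)
  expect_lt(max(abs(a$alpha[!a$edge] - 0.5)), 1e-10)
  # Newtonian (linear MSD) => alpha = 1 everywhere
  eta <- 3e-3
  mlin <- msd_from_model(rheo_newtonian(eta), tt)
  a1 <- compute_alpha(mlin)
  expect_lt(max(abs(a1$alpha[!a1$edge] - 1)), 1e-10)
  expect_error(compute_alpha(msd_curve(10^seq(-3, -2.5, by = 0.05),
                                       rep(1e-13, 11) * 10^seq(0, .5, by = .05))),
               "decade")
})

test_that("two-segment MSD: alpha transition matches the window-convolution oracle", {
  # slopes 1.0 then 0.1, breaking at t = 1e-2 s
  tt <- 10^seq(-4.5, 0.5, by = 0.02)
  tb <- 1e-2
  lmsd <- ifelse(tt <= tb, log10(1e-13) + 1.0 * (log10(tt) - log10(tb)),
                 log10(1e-13) + 0.1 * (log10(tt) - log10(tb)))
  m <- msd_curve(tt, 10^lmsd)
  a <- compute_alpha(m)
  # oracle: the exact slope step convolved with the 7-point regression kernel
  # (weights j / sum(j^2), j = -3..3) and the 15-point moving average, both on
  # the 30/decade grid, computed here directly from the definition
  dlw <- 1 / 30
  lt_grid <- -log10(a$omega)                       # log10 t at grid points
  step_slope <- ifelse(lt_grid <= log10(tb), 1.0, 0.1)
  ord <- order(lt_grid)
  n <- length(lt_grid)
  reg <- numeric(n)
  jj <- -3:3
  wreg <- jj / sum(jj^2)
  lts <- lt_grid[ord]
  lys <- stats::approx(log10(tt), lmsd, xout = lts, rule = 2)$y
  for (i in seq_len(n)) {
    if (i <= 3 || i > n - 3) { reg[i] <- NA; next }
    reg[i] <- sum(wreg * lys[i + jj]) / dlw
  }
  sm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= 10 || i > n - 10) next
    sm[i] <- mean(reg[(i - 7):(i + 7)])
  }
  oracle <- numeric(n); oracle[ord] <- sm
  int <- !is.na(oracle)
  expect_lt(max(abs(a$alpha[int] - pmin(1, pmax(0, oracle[int])))), 1e-10)
  # monotone transition from 1 to 0.1 with midpoint at omega = 1/tb = 100
  mid <- 0.55
  cross <- which(diff(sign(a$alpha - mid)) != 0)
  w_mid <- sqrt(a$omega[cross] * a$omega[cross + 1L])
  expect_lt(abs(log10(w_mid) - 2), 1.5 * dlw + 1e-9)
  # alpha rises with omega: slope 0.1 at long t (low omega), 1.0 at short t
  tr <- a$alpha[a$omega > 1 & a$omega < 1e4]
  expect_true(all(diff(tr) > -1e-9))
})

test_that("GSER identities: phase at alpha = 0.5 and the Newtonian closed form", {
  tt <- 10^seq(-5, -1, by = 0.02)
  a <- compute_alpha(msd_curve(tt, 2e-13 * (tt / 1e-3)^0.5))
  sp <- gser(a, gser_context())
  expect_equal(sp$G_storage, sp$G_loss, tolerance = 1e-12)
  # Newtonian: G' = 0, G'' = eta * omega exactly (Gamma(2) = 1)
  eta <- 3e-3
  ctx <- gser_context(temperature = 295, particle_radius = 1.5e-6)
  mlin <- msd_from_model(rheo_newtonian(eta, 295, 1.5e-6), tt)
  sp1 <- gser(compute_alpha(mlin), ctx)
  expect_lt(max(abs(sp1$G_storage) / sp1$G_mag), 1e-12)
  expect_equal(sp1$G_loss, eta * sp1$omega, tolerance = 1e-9)
  # |G*|^2 = G'^2 + G''^2 by construction
  expect_equal(sp1$G_mag^2, sp1$G_storage^2 + sp1$G_loss^2, tolerance = 1e-12)
})

test_that("power-law GSER agrees with a numerical-transform oracle within 3%", {
  alpha0 <- 0.65
  C <- 4e-13
  tt <- 10^seq(-6, 0, by = 0.02)
  ctx <- gser_context()
  m <- msd_curve(tt, C * tt^alpha0)
  sp <- gser(compute_alpha(m), ctx)
  sel <- which(sp$valid & sp$omega > 10^(min(log10(sp$omega)) + 1) &
                 sp$omega < 10^(max(log10(sp$omega)) - 1))
  sel <- sel[seq(1, length(sel), by = 15)]
  # oracle: |G*(omega)| = kB T / (pi a omega M(omega)), M = numerical Laplace
  # transform of the MSD evaluated at s = omega (independent of gamma())
  for (i in sel) {
    om <- sp$omega[i]
    # substitute v = om * u so the quadrature sees an O(1)-scaled integrand
    M <- C / om^(1 + alpha0) *
      stats::integrate(function(v) v^alpha0 * exp(-v), 0, Inf,
                       rel.tol = 1e-10)$value
    G_or <- KB * 295 / (pi * 1.5e-6 * om * M)
    expect_rel(sp$G_mag[i], G_or, 0.03)
  }
})

test_that("mask_decorrelated: floor, known-noise threshold, static input", {
  tt <- 10^seq(-4, 0, by = 0.05)
  clean <- exp(-tt / 1e-2)
  cc <- correlation_curve(c(0, tt), c(2, 1 + clean), normalized = TRUE)
  msk <- mask_decorrelated(cc, absolute_floor = 0.03)
  expect_identical(msk[-1L], clean >= 0.03)
  # additive tail noise of known sigma: threshold within 20% of 3*sigma
  set.seed(2)
  sigma <- 0.05
  noisy <- clean + rnorm(length(tt), sd = sigma) * (tt > max(tt) / 10)
  ccn <- correlation_curve(c(0, tt), c(2, 1 + noisy), normalized = TRUE)
  mn <- mask_decorrelated(ccn, absolute_floor = 0.03)
  # recover the implied threshold: largest masked value below smallest kept
  thr_lo <- max(noisy[!mn[-1L]][noisy[!mn[-1L]] < min(noisy[mn[-1L]])])
  tail_sd <- sd(noisy[tt >= max(tt) / 10])
  expect_lt(abs(3 * tail_sd - 3 * sigma) / (3 * sigma), 0.2)
  expect_lte(thr_lo, 3 * tail_sd)
  # static: nothing masked
  ccs <- correlation_curve(c(0, tt), rep(2, length(tt) + 1L), normalized = TRUE)
  expect_true(all(mask_decorrelated(ccs)))
})

test_that("|G*| is pointwise non-increasing in the MSD at fixed alpha", {
  tt <- 10^seq(-5, -1, by = 0.02)
  ctx <- gser_context()
  base <- compute_alpha(msd_curve(tt, 1e-13 * (tt / 1e-3)^0.4))
  up <- base; up$msd <- base$msd * 2.5
  g1 <- gser(base, ctx); g2 <- gser(up, ctx)
  expect_true(all(g2$G_mag < g1$G_mag))
})

test_that("doubling the particle radius halves moduli, shape unchanged", {
  tt <- 10^seq(-5, -1, by = 0.02)
  m <- msd_from_model(rheo_maxwell(50, 5e-3), tt)
  a <- compute_alpha(m)
  s1 <- gser(a, gser_context(particle_radius = 1.5e-6))
  s2 <- gser(a, gser_context(particle_radius = 3.0e-6))
  expect_equal(s2$G_mag, s1$G_mag / 2, tolerance = 1e-12)
  expect_equal(s2$G_loss / s2$G_storage, s1$G_loss / s1$G_storage,
               tolerance = 1e-12)
})

test_that("spectra never extend outside 1/duration < omega < frame_rate", {
  chain <- newtonian_movie_chain()
  sp <- chain$res$spectrum
  mv <- chain$movie
  expect_true(all(sp$omega[sp$valid] > 1 / mv$duration))
  expect_true(all(sp$omega[sp$valid] < mv$frame_rate))
})

test_that("end-to-end on synthesized g2: models reproduced within 10%", {
  tt <- 10^seq(-5.5, 0, by = 0.02)
  ctx <- gser_context()
  models <- list(rheo_newtonian(2e-3),
                 rheo_maxwell(30, 5e-3),
                 rheo_powerlaw(0.08, 0.55),
                 rheo_generalized_maxwell(c(20, 200), c(0.05, 1e-4),
                                          eta_s = 1e-4))
  for (model in models) {
    msd <- msd_from_model(model, tt)
    g2 <- synthesize_g2(msd, cal_mid, beta = 0.85)
    m <- invert_msd(g2, cal_mid)
    a <- compute_alpha(m)
    sp <- gser(a, ctx)
    gs <- model_gstar(model, sp$omega)
    lw <- log10(sp$omega)
    interior <- sp$valid & !a$edge &
      lw > min(lw[sp$valid]) + 0.25 & lw < max(lw[sp$valid]) - 0.25
    expect_gt(sum(interior), 20)
    expect_lt(stats::median(abs(sp$G_mag[interior] - Mod(gs)[interior]) /
                              Mod(gs)[interior]), 0.10)
    expect_lt(max(abs(sp$G_mag[interior] - Mod(gs)[interior]) /
                    Mod(gs)[interior]), 0.25)
  }
})
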