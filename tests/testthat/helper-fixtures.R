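# Shared fixtures, built in code at test time.

options(specklerheo.verbose = FALSE)

KB <- 1.380649e-23

# default calibrations used throughout
cal_dls <- optical_calibration(2 / 3, 1)
cal_dws <- optical_calibration(5 / 3, 0.5)
cal_mid <- optical_calibration(1.1, 0.7)

# A movie of iid pixels with exponential field decorrelation time tau_c,
# deliberately independent of synthesize_speckle_movie: complex AR(1) phasors
# E(t+dt) = rho E(t) + sqrt(1-rho^2) xi give exactly g1(t) = exp(-t/tau_c).
make_ar1_movie <- function(h = 12L, w = 12L, n_frames = 3000L,
                           frame_rate = 1e4, tau_c = 2e-3, seed = 99L,
                           mean_counts = 5000) {
  set.seed(seed)
  npx <- h * w
  rho <- exp(-1 / (frame_rate * tau_c))
  E <- complex(real = rnorm(npx), imaginary = rnorm(npx)) / sqrt(2)
  frames <- array(0L, dim = c(h, w, n_frames))
  for (t0 in seq_len(n_frames)) {
    if (t0 > 1L)
      E <- rho * E + sqrt(1 - rho^2) *
        complex(real = rnorm(npx), imaginary = rnorm(npx)) / sqrt(2)
    frames[, , t0] <- pmin(as.integer(round(Mod(E)^2 * mean_counts)), 65535L)
  }
  speckle_series(frames, frame_rate = frame_rate, bit_depth = 16L)
}

# Static frames whose time average is an isotropic Gaussian intensity
# envelope; tiny temporal jitter keeps the series non-constant.
make_gaussian_movie <- function(h = 32L, w = 128L, center = c(16, 64),
                                sigma = 8, n_frames = 3L, peak = 10000,
                                seed = 1L) {
  set.seed(seed)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  base <- peak * exp(-((rows - center[1L])^2 + (cols - center[2L])^2) /
                       (2 * sigma^2))
  frames <- array(0L, dim = c(h, w, n_frames))
  for (i in seq_len(n_frames))
    frames[, , i] <- as.integer(round(base + runif(h * w)))
  speckle_series(frames, frame_rate = 100, bit_depth = 16L)
}

# lazily built, cached heavyweight fixtures (one build per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

newtonian_movie_chain <- function() {
  cached("newtonian_chain", function() {
    eta <- 2.5e-3
    model <- rheo_newtonian(eta)
    inst <- instrument_model(n_frames = 6000L, frame_rate = 1e4, seed = 11L)
    movie <- synthesize_speckle_movie(model, cal_dls, inst)
    res <- process_speckle(movie, calibration = cal_dls)
    list(eta = eta, movie = movie, res = res)
  })
}

# a fibrin-like planted spectrum: Maxwell base (omega_T = 20 rad/s, plateau
# 700 Pa with G'' minimum near 300 rad/s) plus a two-exponent loss branch
# (0.4 -> 1.2) breaking at 1.7e4 rad/s. alpha is the GSER phase of the
# composite. Returns spectrum + aligned alpha curve + planted truth.
planted_fibrin_spectrum <- function(points_per_decade = 30L) {
  omega <- 10^seq(log10(0.5), log10(3e5), by = 1 / points_per_decade)
  G0 <- 700; wT <- 20; w0 <- 300; wg <- 1.7e4
  gma <- 0.4; gmb <- 1.2
  x <- omega / wT
  Gp_mx <- G0 * x^2 / (1 + x^2)
  Gpp_mx <- G0 * x / (1 + x^2)
  # branch amplitude: d/domega of (Gpp_mx + branch) = 0 at w0
  g_a <- (G0 * wT / w0) / gma          # Gpp_mx ~ G0*wT/omega for omega >> wT
  la <- g_a * (omega / w0)^gma
  lb <- g_a * (wg / w0)^gma * (omega / wg)^gmb
  branch <- pmax(la, lb)               # clean two-exponent loss branch
  Gpp <- Gpp_mx + branch
  # storage companion of the steep branch keeps alpha below 0.5 at high omega
  Gp <- Gp_mx + 1.1 * lb
  Gmag <- sqrt(Gp^2 + Gpp^2)
  alpha <- (2 / pi) * atan2(Gpp, Gp)
  ac <- structure(list(omega = omega, alpha = alpha, alpha_raw = alpha,
                       msd = KB * 295 / (pi * 1.5e-6 * Gmag * gamma(1 + alpha)),
                       edge = rep(FALSE, length(omega)),
                       points_per_decade = points_per_decade),
                  class = "alpha_curve")
  sp <- structure(list(omega = omega, G_storage = Gp, G_loss = Gpp,
                       G_mag = Gmag, alpha = alpha,
                       valid = rep(TRUE, length(omega))),
                  class = "visco_spectrum")
  list(spectrum = sp, alpha = ac,
       truth = list(omega_T = wT, omega0 = w0, G0 = G0, gamma_a = gma,
                    gamma_b = gmb, omega_gamma = wg))
}

# Spectrum with two planted plateaus (alpha minima at 1e2 and 1e4 rad/s) and
# two scaling stretches, piecewise-linear alpha in log-omega.
planted_two_plateau_spectrum <- function(points_per_decade = 30L) {
  lw <- seq(-0.5, 5, by = 1 / points_per_decade)
  omega <- 10^lw
  ctrl_w <- c(-0.5, 1.0, log10(20), 2, 3, 4, 5)
  ctrl_a <- c(0.90, 0.70, 0.50, 0.10, 0.45, 0.15, 0.45)
  alpha <- approx(ctrl_w, ctrl_a, xout = lw)$y
  Gmag <- 500 * (omega / 100)^0.2
  sp <- structure(list(omega = omega, G_storage = Gmag * cospi(alpha / 2),
                       G_loss = Gmag * sinpi(alpha / 2), G_mag = Gmag,
                       alpha = alpha, valid = rep(TRUE, length(omega))),
                  class = "visco_spectrum")
  ac <- structure(list(omega = omega, alpha = alpha, alpha_raw = alpha,
                       msd = KB * 295 / (pi * 1.5e-6 * Gmag * gamma(1 + alpha)),
                       edge = rep(FALSE, length(omega)),
                       points_per_decade = points_per_decade),
                  class = "alpha_curve")
  list(spectrum = sp, alpha = ac)
}

planted_two_plateau_params <- function() {
  cached("two_plateau", function() {
    px <- planted_two_plateau_spectrum()
    px$params <- extract_spectro_params(px$spectrum, px$alpha)
    px
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
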