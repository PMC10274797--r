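# Forward simulator: GSER-consistent MSDs from viscoelastic models, synthetic
# g2 curves via the empirical inversion run forwards, and full synthetic
# speckle movies whose ensemble statistics realize a prescribed g2(t).
#
# Movie field model: fully developed speckle (circular complex Gaussian),
# spatial grain size set by Gaussian low-pass filtering of a white complex
# field, temporal decorrelation by per-pixel Gaussian phase processes whose
# structure function equals D(t) = 2*gamma*(k^2*MSD(t))^zeta, so that
# g1(t) = exp(-D(t)/2) and (after the Siegert relation) g2 - 1 = beta*g1^2.

#' Viscoelastic model constructors
#'
#' `rheo_newtonian`: purely viscous fluid, MSD = kB*T/(pi*a*eta) * t.
#' `rheo_powerlaw`: |G*| = A*omega^alpha0, MSD = kB*T/(pi*a*A*Gamma(1+alpha0)) * t^alpha0.
#' `rheo_maxwell`: single Maxwell element, MSD from the creep compliance
#'   J(t) = (1 + t/tau_r)/G0; its log-log slope crosses 0.5 at t = tau_r.
#' `rheo_generalized_maxwell`: arms (G_i, tau_i) plus optional solvent
#'   viscosity; MSD from the exact G*(omega) through the inverse algebraic
#'   GSER (phase -> alpha, magnitude -> MSD).
#' `rheo_piecewise_msd`: direct log-log MSD knot list with segment slopes in
#'   `[0, 1]` (piecewise power-law interpolation, end slopes extrapolated).
#'
#' @param eta viscosity, Pa s.
#' @param A power-law modulus prefactor, Pa s^alpha0.
#' @param alpha0 power-law exponent in (0, 1).
#' @param G0 Maxwell modulus, Pa.
#' @param tau_r Maxwell relaxation time, s.
#' @param G,tau generalized-Maxwell arm moduli (Pa) and times (s).
#' @param eta_s solvent viscosity, Pa s (0 for none).
#' @param knot_t,knot_msd piecewise MSD knots (s, m^2), log-log interpolated.
#' @param temperature kelvin.
#' @param particle_radius probe radius, metres.
#' @return a `rheo_model`.
#' @name rheo_models
NULL

new_rheo_model <- function(kind, pars, temperature, particle_radius) {
  if (temperature <= 0 || particle_radius <= 0)
    stop_sr("temperature and particle_radius must be positive")
  structure(list(kind = kind, pars = pars, temperature = temperature,
                 particle_radius = particle_radius), class = "rheo_model")
}

#' @rdname rheo_models
#' @export
rheo_newtonian <- function(eta, temperature = 295, particle_radius = 1.5e-6) {
  if (eta <= 0) stop_sr("viscosity must be positive")
  new_rheo_model("newtonian", list(eta = eta), temperature, particle_radius)
}

#' @rdname rheo_models
#' @export
rheo_powerlaw <- function(A, alpha0, temperature = 295,
                          particle_radius = 1.5e-6) {
  if (A <= 0) stop_sr("prefactor A must be positive")
  if (alpha0 <= 0 || alpha0 >= 1) stop_sr("alpha0 must lie in (0, 1)")
  new_rheo_model("powerlaw", list(A = A, alpha0 = alpha0), temperature,
                 particle_radius)
}

#' @rdname rheo_models
#' @export
rheo_maxwell <- function(G0, tau_r, temperature = 295,
                         particle_radius = 1.5e-6) {
  if (G0 <= 0 || tau_r <= 0) stop_sr("G0 and tau_r must be positive")
  new_rheo_model("maxwell", list(G0 = G0, tau_r = tau_r), temperature,
                 particle_radius)
}

#' @rdname rheo_models
#' @export
rheo_generalized_maxwell <- function(G, tau, eta_s = 0, temperature = 295,
                                     particle_radius = 1.5e-6) {
  if (length(G) != length(tau)) stop_sr("G and tau lengths differ")
  if (any(G <= 0) || any(tau <= 0) || eta_s < 0)
    stop_sr("arm moduli and times must be positive, eta_s >= 0")
  new_rheo_model("generalized_maxwell", list(G = G, tau = tau, eta_s = eta_s),
                 temperature, particle_radius)
}

#' @rdname rheo_models
#' @export
rheo_piecewise_msd <- function(knot_t, knot_msd, temperature = 295,
                               particle_radius = 1.5e-6) {
  if (length(knot_t) != length(knot_msd) || length(knot_t) < 2L)
    stop_sr("need >= 2 knots")
  if (any(knot_t <= 0) || any(knot_msd <= 0)) stop_sr("knots must be positive")
  if (is.unsorted(knot_t, strictly = TRUE)) stop_sr("knot_t must increase")
  sl <- diff(log(knot_msd)) / diff(log(knot_t))
  if (any(sl < -1e-9 | sl > 1 + 1e-9))
    stop_sr("piecewise knot slopes must lie in [0, 1]")
  new_rheo_model("piecewise_msd", list(knot_t = knot_t, knot_msd = knot_msd),
                 temperature, particle_radius)
}

#' @export
print.rheo_model <- function(x, ...) {
  cat("rheo_model:", x$kind, "(T =", x$temperature, "K, a =",
      x$particle_radius, "m)\n")
  invisible(x)
}

#' Exact complex modulus of a rheo_model (where defined)
#' @param model a `rheo_model`.
#' @param omega angular frequencies, rad/s.
#' @return complex vector G*(omega).
#' @export
model_gstar <- function(model, omega) {
  p <- model$pars
  switch(model$kind,
    newtonian = 1i * omega * p$eta,
    powerlaw = p$A * omega^p$alpha0 *
      exp(1i * pi * p$alpha0 / 2),
    maxwell = p$G0 * (1i * omega * p$tau_r) / (1 + 1i * omega * p$tau_r),
    generalized_maxwell = {
      gs <- rep(0 + 0i, length(omega))
      for (j in seq_along(p$G))
        gs <- gs + p$G[j] * (1i * omega * p$tau[j]) / (1 + 1i * omega * p$tau[j])
      gs + 1i * omega * p$eta_s
    },
    stop_sr("no closed-form G* for model kind ", model$kind))
}

#' Ground-truth MSD from a viscoelastic model
#'
#' Closed forms where available (Newtonian, power law, Maxwell via the creep
#' compliance); generalized Maxwell through the inverse algebraic GSER on its
#' exact G*(omega); piecewise models by log-log interpolation of their knots.
#'
#' @param model a `rheo_model`.
#' @param times lag times, seconds (positive, sorted).
#' @return an [msd_curve()].
#' @export
msd_from_model <- function(model, times) {
  if (any(times <= 0)) stop_sr("times must be positive")
  if (is.unsorted(times)) stop_sr("times must be sorted")
  kT <- .kB * model$temperature
  pref <- kT / (pi * model$particle_radius)
  p <- model$pars
  msd <- switch(model$kind,
    newtonian = pref / p$eta * times,
    powerlaw = pref / (p$A * gamma(1 + p$alpha0)) * times^p$alpha0,
    maxwell = pref / p$G0 * (1 + times / p$tau_r),
    generalized_maxwell = {
      om <- 1 / times
      gs <- model_gstar(model, om)
      alpha <- (2 / pi) * atan2(Im(gs), Re(gs))
      alpha <- pmin(1, pmax(0, alpha))
      pref / (Mod(gs) * gamma(1 + alpha))
    },
    piecewise_msd = {
      lk <- stats::approx(log(p$knot_t), log(p$knot_msd), xout = log(times),
                          rule = 2)$y
      # extrapolate with the end-segment slopes instead of flat
      nk <- length(p$knot_t)
      sl1 <- (log(p$knot_msd[2L]) - log(p$knot_msd[1L])) /
        (log(p$knot_t[2L]) - log(p$knot_t[1L]))
      sl2 <- (log(p$knot_msd[nk]) - log(p$knot_msd[nk - 1L])) /
        (log(p$knot_t[nk]) - log(p$knot_t[nk - 1L]))
      lo <- times < p$knot_t[1L]; hi <- times > p$knot_t[nk]
      lk[lo] <- log(p$knot_msd[1L]) + sl1 * (log(times[lo]) - log(p$knot_t[1L]))
      lk[hi] <- log(p$knot_msd[nk]) + sl2 * (log(times[hi]) - log(p$knot_t[nk]))
      exp(lk)
    },
    stop_sr("unsupported model kind: ", model$kind))
  msd_curve(times, msd)
}

#' Forward-synthesize a correlation curve from an MSD
#'
#' Runs the empirical inversion forwards:
#' `g2(t) - 1 = beta * exp(-2*gamma*(k^2*MSD(t))^zeta)`, on the MSD's own lag
#' grid plus a lag-0 point (`g2(0) - 1 = beta`). The result is a *raw* curve;
#' [normalize_g2()] (or [invert_msd()], which normalizes internally) removes
#' beta again.
#'
#' @param msd an [msd_curve()].
#' @param calibration an [optical_calibration()].
#' @param beta coherence factor in (0, 1].
#' @return a `correlation_curve` (not contrast-normalized).
#' @export
synthesize_g2 <- function(msd, calibration, beta = 1) {
  stopifnot(inherits(msd, "msd_curve"), inherits(calibration, "optical_calibration"))
  if (beta <= 0 || beta > 1) stop_sr("beta must lie in (0, 1]")
  k2msd <- calibration$k^2 * msd$msd
  g2m1 <- beta * exp(-2 * calibration$gamma * k2msd^calibration$zeta)
  correlation_curve(c(0, msd$times), c(1 + beta, 1 + g2m1),
                    n_pairs = rep(1, length(msd$times) + 1L),
                    normalized = FALSE)
}

#' Instrument model for the synthetic speckle generator
#'
#' @param shape frame `c(height, width)` in pixels.
#' @param frame_rate frames per second.
#' @param n_frames movie length.
#' @param speckle_size pixels per speckle, measured as the FWHM of the spatial
#'   intensity autocovariance (default 3.5; must be >= 2 for adequate
#'   sampling).
#' @param beta coherence factor in (0, 1].
#' @param drp_radius_px 1/e radius of the Gaussian diffuse-reflectance
#'   intensity envelope, pixels.
#' @param shot_noise Poisson photon noise on/off.
#' @param bit_depth quantization depth.
#' @param mean_counts target mean intensity at the beam centre, counts.
#' @param seed RNG seed (identical seed + config -> bit-identical movie).
#' @return an `instrument_model`.
#' @export
instrument_model <- function(shape = c(64L, 64L), frame_rate = 1e4,
                             n_frames = 200L, speckle_size = 3.5, beta = 1,
                             drp_radius_px = 24, shot_noise = FALSE,
                             bit_depth = 16L,
                             mean_counts = 0.2 * (2^bit_depth - 1),
                             seed = 1L) {
  if (speckle_size < 2) stop_sr("speckle size < 2 px: undersampled speckle")
  if (beta <= 0 || beta > 1) stop_sr("beta must lie in (0, 1]")
  structure(list(shape = as.integer(shape), frame_rate = frame_rate,
                 n_frames = as.integer(n_frames), speckle_size = speckle_size,
                 beta = beta, drp_radius_px = drp_radius_px,
                 shot_noise = shot_noise, bit_depth = as.integer(bit_depth),
                 mean_counts = mean_counts, seed = seed),
            class = "instrument_model")
}

# --- Gaussian field machinery ------------------------------------------------

# Stationary circular complex Gaussian processes with prescribed temporal
# autocovariance rho(j) = exp(-D(j)/2), one column per pixel, via circulant
# embedding. rho is extended beyond the record length with the structure
# function's local log-log slope before embedding; any (tiny) negative
# circulant eigenvalues are clipped. Returns a T x ncol complex matrix of
# unit-variance CCG series. Because the field is exactly jointly Gaussian, the
# Siegert relation g2 - 1 = |g1|^2 holds exactly — a phase-only modulation of
# a fixed amplitude field would leave a static self-term floor of order one
# over the phasor count per speckle.
ccg_process_matrix <- function(D, n_frames, ncol) {
  M <- 2^ceiling(log2(2 * n_frames))
  half <- M %/% 2L
  # extend D to half lags: continue the last local log-log slope
  j <- seq_len(half)
  Dx <- numeric(half)
  Dx[seq_along(D)] <- D
  if (half > length(D)) {
    n0 <- length(D)
    i0 <- max(2L, n0 - 20L)
    slope <- (log(D[n0] + 1e-300) - log(D[i0] + 1e-300)) /
      (log(n0) - log(i0))
    slope <- min(max(slope, 0), 2)
    Dx[(n0 + 1L):half] <- D[n0] * (j[(n0 + 1L):half] / n0)^slope
  }
  rho <- c(1, exp(-Dx / 2))                      # lags 0..half
  circ <- c(rho, rev(rho[2:half]))               # length M
  lam <- Re(stats::fft(circ))
  lam[lam < 0] <- 0
  sq <- sqrt(lam / M)
  out <- matrix(0 + 0i, n_frames, ncol)
  blk <- max(1L, min(ncol, as.integer(2^24 / M)))
  for (b0 in seq(1L, ncol, by = blk)) {
    b1 <- min(b0 + blk - 1L, ncol)
    Z <- matrix(complex(real = stats::rnorm(M * (b1 - b0 + 1L)),
                        imaginary = stats::rnorm(M * (b1 - b0 + 1L))),
                M, b1 - b0 + 1L)
    X <- stats::mvfft(Z * sq)
    out[, b0:b1] <- X[seq_len(n_frames), , drop = FALSE] / sqrt(2)
  }
  out
}

#' Synthesize a speckle movie realizing a prescribed MSD schedule
#'
#' Generates fully developed speckle whose field autocorrelation is
#' `g1(t) = exp(-gamma*(k^2*MSD(t))^zeta)`: per-pixel stationary circular
#' complex Gaussian processes with autocovariance `exp(-D(t)/2)` where
#' `D(t) = 2*gamma*(k^2*MSD(t))^zeta` is the Gaussian phase structure function
#' (generated exactly by circulant embedding, so the Siegert relation holds
#' exactly), a Gaussian spatial low-pass that sets the pixels-per-speckle
#' ratio, a Gaussian diffuse-reflectance intensity envelope, an optional
#' static background realizing the coherence factor beta, optional shot noise,
#' and quantization to the sensor bit depth. Deterministic under the
#' instrument seed.
#'
#' @param msd an [msd_curve()] defined on (at least) the frame-lag grid, or a
#'   `rheo_model` (evaluated on the frame-lag grid).
#' @param calibration an [optical_calibration()].
#' @param instrument an [instrument_model()].
#' @return a [speckle_series()].
#' @export
synthesize_speckle_movie <- function(msd, calibration, instrument) {
  stopifnot(inherits(calibration, "optical_calibration"),
            inherits(instrument, "instrument_model"))
  h <- instrument$shape[1L]; w <- instrument$shape[2L]
  Tn <- instrument$n_frames
  dt <- 1 / instrument$frame_rate
  lag_t <- dt * seq_len(Tn - 1L)
  if (inherits(msd, "rheo_model")) msd <- msd_from_model(msd, lag_t)
  stopifnot(inherits(msd, "msd_curve"))
  msd_lag <- stats::approx(log(msd$times), log(pmax(msd$msd, 1e-300)),
                           xout = log(lag_t), rule = 2)$y
  msd_lag <- exp(msd_lag)
  if (max(msd$msd) == 0) msd_lag[] <- 0
  D <- 2 * calibration$gamma * (calibration$k^2 * msd_lag)^calibration$zeta
  npx <- h * w
  frozen <- max(D) == 0
  with_seed(instrument$seed, {
    # per-pixel unit-variance CCG time series with ACF exp(-D/2)
    W <- if (frozen) {
      matrix(complex(real = stats::rnorm(npx), imaginary = stats::rnorm(npx)),
             1L, npx) / sqrt(2)
    } else ccg_process_matrix(D, Tn, npx)
    sigma_E <- instrument$speckle_size / (2 * sqrt(log(2)))
    fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
    fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
    k2 <- outer((2 * pi * fy)^2, rep(1, w)) + outer(rep(1, h), (2 * pi * fx)^2)
    H_k <- exp(-k2 * sigma_E^2 / 4)
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    r2 <- (rows - ctr[1L])^2 + (cols - ctr[2L])^2
    env <- exp(-r2 / instrument$drp_radius_px^2)   # intensity envelope, 1/e radius
    frames <- array(0L, dim = c(h, w, Tn))
    # normalization: mean |E|^2 of the filtered unit-variance field
    mean_I <- mean(H_k^2)
    scale_I <- instrument$mean_counts / mean_I
    bg_c <- (1 / sqrt(instrument$beta) - 1)        # static offset for beta < 1
    maxc <- 2^instrument$bit_depth - 1
    for (t0 in seq_len(Tn)) {
      f <- matrix(W[if (frozen) 1L else t0, ], h, w)
      E <- stats::fft(stats::fft(f) * H_k, inverse = TRUE) / npx
      I <- Mod(E)^2 * scale_I * env
      I <- I + bg_c * instrument$mean_counts * env
      if (instrument$shot_noise) I <- stats::rpois(npx, I)
      frames[, , t0] <- pmin(maxc, pmax(0L, as.integer(round(I))))
    }
    speckle_series(frames, frame_rate = instrument$frame_rate,
                   exposure = 0.5 * dt, bit_depth = instrument$bit_depth)
  })
}

#' Measure pixels-per-speckle of a movie
#'
#' Computes, per frame, the spatial autocovariance of the envelope-normalized
#' intensity (the envelope estimate is a heavily blurred time-averaged frame),
#' averages the autocovariance over frames, radially averages it, and returns
#' the full width at half maximum in pixels.
#'
#' @param series a [speckle_series()].
#' @param n_frames number of frames to average (default 10).
#' @return FWHM of the spatial intensity autocovariance, pixels.
#' @export
measure_speckle_size <- function(series, n_frames = 10L) {
  fr <- series$frames
  d <- dim(fr)
  h <- d[1L]; w <- d[2L]
  n_frames <- min(n_frames, d[3L])
  use <- round(seq(1L, d[3L], length.out = n_frames))
  # envelope estimate: blurred time average
  A <- rowMeans(fr[, , use, drop = FALSE], dims = 2L)
  fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
  fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
  k2 <- outer((2 * pi * fy)^2, rep(1, w)) + outer(rep(1, h), (2 * pi * fx)^2)
  blur <- exp(-k2 * 8^2 / 2)
  env <- Re(stats::fft(stats::fft(A) * blur, inverse = TRUE)) / (h * w)
  env <- pmax(env, max(env) * 0.02)
  acc <- matrix(0, h, w)
  for (t0 in use) {
    x <- fr[, , t0] / env
    x <- x - mean(x)
    Fx <- stats::fft(x)
    acc <- acc + Re(stats::fft(Fx * Conj(Fx), inverse = TRUE)) / (h * w)
  }
  acc <- acc / length(use)
  # radial profile of the autocovariance
  sh <- function(i, n) ifelse(i - 1L <= n / 2, i - 1L, i - 1L - n)
  rows <- matrix(sh(seq_len(h), h), h, w)
  cols <- matrix(sh(seq_len(w), w), h, w, byrow = TRUE)
  r <- sqrt(rows^2 + cols^2)
  bins <- round(r * 2) / 2                        # half-pixel bins
  prof <- tapply(acc, bins, mean)
  rad <- as.numeric(names(prof))
  ord <- order(rad)
  rad <- rad[ord]; prof <- as.numeric(prof)[ord]
  half <- prof[1L] / 2
  below <- which(prof < half)
  if (!length(below)) stop_sr("speckle autocovariance does not reach half maximum")
  j <- below[1L]
  r_half <- rad[j - 1L] + (prof[j - 1L] - half) / (prof[j - 1L] - prof[j]) *
    (rad[j] - rad[j - 1L])
  2 * r_half
}
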