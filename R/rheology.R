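# Core inversion chain: g2(t) -> MSD -> alpha(omega) -> G*(omega).
#
# MSD inversion:   k^2 <dr^2> = (-ln(g2 - 1) / (2*gamma))^(1/zeta)
# Algebraic GSER:  |G*(omega)| = kB*T / (pi*a*Gamma(1+alpha(omega))*<dr^2(1/omega)>)
#                  G' = |G*| cos(pi*alpha/2),  G'' = |G*| sin(pi*alpha/2)
# alpha(omega) is the local log-log slope of the MSD at t = 1/omega, computed
# with the fixed numerics: 30 points/decade log-omega resampling, 7-point
# rolling log-log regression, 15-point moving-average smoothing.

#' MSD curve container
#' @param times lag times, seconds (positive, strictly increasing).
#' @param msd mean square displacements, m^2 (>= 0 at valid points).
#' @param valid logical validity mask; valid points must form one contiguous
#'   block (enforced by keeping the longest run).
#' @return an `msd_curve`.
#' @export
msd_curve <- function(times, msd, valid = rep(TRUE, length(times))) {
  if (length(times) != length(msd)) stop_sr("times and msd lengths differ")
  if (any(times <= 0)) stop_sr("MSD times must be positive")
  if (is.unsorted(times, strictly = TRUE)) stop_sr("times must be strictly increasing")
  valid <- valid & is.finite(msd) & msd >= 0
  valid <- longest_true_run(valid)
  structure(list(times = times, msd = msd, valid = valid), class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("msd_curve: %d points (%d valid), t = %.3g..%.3g s\n",
              length(x$times), sum(x$valid), min(x$times), max(x$times)))
  invisible(x)
}

#' Mask fully decorrelated lags
#'
#' Marks invalid every lag at which `g2 - 1` has sunk into the noise floor:
#' below `max(absolute_floor, 3 * sd(g2 - 1 over the last decade of lags))`.
#' Beyond that point the speckle pattern has completely decorrelated and the
#' inversion is undefined. The tail-noise rule only makes sense when the tail
#' *is* decorrelated (so its spread measures noise, not the decay itself);
#' when the tail mean of `g2 - 1` still sits above twice the absolute floor —
#' slowly relaxing, elastic-plateau-type samples — only the absolute floor is
#' applied.
#'
#' @param corr a normalized `correlation_curve`.
#' @param absolute_floor minimum usable `g2 - 1` (default 0.03, below typical
#'   speckle-contrast noise for the ensemble sizes involved).
#' @return logical validity mask over the lags.
#' @export
mask_decorrelated <- function(corr, absolute_floor = 0.03) {
  y <- corr$g2 - 1
  t <- corr$lags
  tail_idx <- t >= max(t) / 10 & t > 0
  tail_decorrelated <- sum(tail_idx) >= 3L &&
    mean(y[tail_idx]) < 2 * absolute_floor
  tail_sd <- if (tail_decorrelated) stats::sd(y[tail_idx]) else 0
  thr <- max(absolute_floor, 3 * tail_sd)
  y >= thr
}

#' Invert g2(t) to the mean square displacement
#'
#' Applies the empirical DWS-style inversion
#' `k^2 <dr^2(t)> = (-ln(g2 - 1) / (2*gamma))^(1/zeta)` at every lag with
#' `g2 - 1` inside `(noise floor, 1]`; all other lags are masked invalid.
#'
#' @param corr a `correlation_curve`; if not yet contrast-normalized it is
#'   normalized first (requires the lag-0 point).
#' @param calibration an [optical_calibration()] supplying gamma, zeta, k.
#' @param mask optional validity mask; defaults to [mask_decorrelated()].
#' @param absolute_floor forwarded to [mask_decorrelated()].
#' @return an [msd_curve()] in m^2 (lag 0 excluded).
#' @export
invert_msd <- function(corr, calibration, mask = NULL, absolute_floor = 0.03) {
  stopifnot(inherits(calibration, "optical_calibration"))
  corr <- normalize_g2(corr)
  if (is.null(mask)) mask <- mask_decorrelated(corr, absolute_floor)
  keep <- corr$lags > 0
  t <- corr$lags[keep]
  y <- corr$g2[keep] - 1
  ok <- mask[keep] & y > 0 & y <= 1
  if (!any(ok)) stop_sr("fully decorrelated or static signal: no invertible lags")
  k2msd <- rep(NA_real_, length(t))
  k2msd[ok] <- (-log(y[ok]) / (2 * calibration$gamma))^(1 / calibration$zeta)
  msd_curve(t, k2msd / calibration$k^2, valid = ok)
}

#' Alpha curve: local power-law exponent of the MSD on a log-omega grid
#'
#' Implements the fixed estimation numerics: (i) resample log-MSD onto a
#' log-spaced omega grid at `points_per_decade` (omega = 1/t); (ii) alpha at
#' each omega is the least-squares slope of log-MSD vs log-t over a
#' `reg_window`-point window centred at t = 1/omega; (iii) alpha is smoothed
#' by a `smooth_window`-point centred moving average (windows shrink
#' symmetrically at the edges); (iv) alpha is clamped to `[0, 1]` (the
#' algebraic GSER's domain), with clamp events logged.
#'
#' @param msd an [msd_curve()] with >= 7 valid points spanning >= 1 decade.
#' @param points_per_decade log-omega resampling density (default 30).
#' @param reg_window rolling regression width, points (default 7).
#' @param smooth_window moving-average width, points (default 15).
#' @return an `alpha_curve`: `omega` (rad/s, increasing), `alpha` (smoothed,
#'   clamped), `alpha_raw` (pre-smoothing, pre-clamp), `msd` (resampled, m^2),
#'   `edge` (lower-confidence edge flag).
#' @export
compute_alpha <- function(msd, points_per_decade = 30L, reg_window = 7L,
                          smooth_window = 15L) {
  stopifnot(inherits(msd, "msd_curve"))
  t <- msd$times[msd$valid]
  m <- msd$msd[msd$valid]
  pos <- m > 0
  t <- t[pos]; m <- m[pos]
  if (length(t) < reg_window)
    stop_sr("need at least ", reg_window, " valid MSD points")
  span <- log10(max(t) / min(t))
  if (span < 1) stop_sr("valid MSD must span at least one decade (has ",
                        signif(span, 3), ")")
  lo <- log10(1 / max(t)); hi <- log10(1 / min(t))
  lw <- seq(lo, hi, by = 1 / points_per_decade)
  omega <- 10^lw
  lt <- -lw                                   # log10 t on the resampled grid
  lmsd <- stats::approx(log10(t), log10(m), xout = lt, rule = 2)$y
  # regression runs over increasing t; grid is increasing omega = decreasing t
  ord <- order(lt)
  rs <- rolling_slope(lt[ord], lmsd[ord], reg_window)
  alpha_raw <- numeric(length(lt)); edge <- logical(length(lt))
  alpha_raw[ord] <- rs$slope; edge[ord] <- rs$edge
  alpha_s <- moving_average(alpha_raw, smooth_window)
  n_clamp <- sum(alpha_s < 0 | alpha_s > 1)
  if (n_clamp > 0)
    sr_log("INFO", "alpha clamped to [0, 1] at ", n_clamp, " of ",
           length(alpha_s), " points")
  alpha <- pmin(1, pmax(0, alpha_s))
  half <- (smooth_window - 1L) %/% 2L
  edge[seq_len(min(half, length(edge)))] <- TRUE
  edge[seq.int(max(1L, length(edge) - half + 1L), length(edge))] <- TRUE
  structure(list(omega = omega, alpha = alpha, alpha_raw = alpha_raw,
                 msd = 10^lmsd, edge = edge,
                 points_per_decade = points_per_decade),
            class = "alpha_curve")
}

#' @export
print.alpha_curve <- function(x, ...) {
  cat(sprintf("alpha_curve: %d points, omega = %.3g..%.3g rad/s, alpha in [%.3f, %.3f]\n",
              length(x$omega), min(x$omega), max(x$omega),
              min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' GSER context (thermal prefactor)
#' @param temperature kelvin (default 295, room temperature).
#' @param particle_radius scattering particle radius, metres.
#' @return a `gser_context`.
#' @export
gser_context <- function(temperature = 295, particle_radius = 1.5e-6) {
  if (temperature <= 0) stop_sr("temperature must be positive")
  if (particle_radius <= 0) stop_sr("particle_radius must be positive")
  structure(list(kB = .kB, temperature = temperature,
                 particle_radius = particle_radius), class = "gser_context")
}

new_visco_spectrum <- function(omega, G_storage, G_loss, G_mag, alpha, valid) {
  structure(list(omega = omega, G_storage = G_storage, G_loss = G_loss,
                 G_mag = G_mag, alpha = alpha, valid = valid),
            class = "visco_spectrum")
}

#' Algebraic GSER: viscoelastic spectrum from MSD and alpha
#'
#' `|G*(omega)| = kB*T / (pi * a * Gamma(1 + alpha(omega)) * <dr^2(1/omega)>)`
#' with phase set by alpha: `G' = |G*| cos(pi*alpha/2)`,
#' `G'' = |G*| sin(pi*alpha/2)`. The validity mask is cropped to the
#' instrument band `1/duration < omega < frame_rate` when given.
#'
#' @param alpha_curve an `alpha_curve` from [compute_alpha()] (carries the
#'   resampled MSD on the same omega grid).
#' @param context a [gser_context()].
#' @param frame_rate,duration optional acquisition bounds used to crop the
#'   valid band to `1/duration < omega < frame_rate`.
#' @return a `visco_spectrum`: omega (rad/s), G_storage, G_loss, G_mag (Pa),
#'   alpha, valid.
#' @export
gser <- function(alpha_curve, context = gser_context(), frame_rate = NULL,
                 duration = NULL) {
  stopifnot(inherits(alpha_curve, "alpha_curve"), inherits(context, "gser_context"))
  a <- alpha_curve$alpha
  if (any(a < 0 | a > 1)) {  # defensive: constructor clamps already
    sr_log("WARN", "alpha outside [0, 1] reached the GSER; clamping")
    a <- pmin(1, pmax(0, a))
  }
  Gmag <- context$kB * context$temperature /
    (pi * context$particle_radius * gamma(1 + a) * alpha_curve$msd)
  Gp <- Gmag * cospi(a / 2)
  Gpp <- Gmag * sinpi(a / 2)
  valid <- is.finite(Gmag) & Gmag > 0
  if (!is.null(duration)) valid <- valid & alpha_curve$omega > 1 / duration
  if (!is.null(frame_rate)) valid <- valid & alpha_curve$omega < frame_rate
  new_visco_spectrum(alpha_curve$omega, Gp, Gpp, Gmag, a, valid)
}

#' @export
print.visco_spectrum <- function(x, ...) {
  v <- x$valid
  cat(sprintf("visco_spectrum: %d points (%d valid), omega = %.3g..%.3g rad/s, |G*| = %.3g..%.3g Pa\n",
              length(x$omega), sum(v),
              min(x$omega[v]), max(x$omega[v]),
              min(x$G_mag[v]), max(x$G_mag[v])))
  invisible(x)
}

#' As data frame
#' @param x a `visco_spectrum`.
#' @param ... unused.
#' @return data.frame with omega_rad_s, G_storage_Pa, G_loss_Pa, G_mag_Pa,
#'   alpha, valid.
#' @export
as.data.frame.visco_spectrum <- function(x, ...) {
  data.frame(omega_rad_s = x$omega, G_storage_Pa = x$G_storage,
             G_loss_Pa = x$G_loss, G_mag_Pa = x$G_mag, alpha = x$alpha,
             valid = x$valid)
}

#' End-to-end pipeline: speckle series to spectrum and fingerprints
#'
#' Convenience wrapper running DRP/ROI selection, correlation, masking,
#' MSD inversion, alpha estimation, GSER and parameter extraction.
#'
#' @param series a [speckle_series()].
#' @param calibration an [optical_calibration()]; if NULL and `config`
#'   carries optical properties plus a `lookup`, the calibration is looked up.
#' @param config a [sample_config()].
#' @param lookup optional `gz_lookup` table for (gamma, zeta).
#' @param lags optional lag set (frames); defaults to [multitau_lags()].
#' @param absolute_floor noise floor on `g2 - 1`.
#' @return list with `drp`, `roi`, `g2`, `msd`, `alpha`, `spectrum`, `params`.
#' @export
process_speckle <- function(series, calibration = NULL,
                            config = sample_config(), lookup = NULL,
                            lags = NULL, absolute_floor = 0.03) {
  k <- 2 * pi * config$refractive_index / series$wavelength
  if (is.null(calibration)) {
    if (!is.null(config$gamma) && !is.null(config$zeta)) {
      calibration <- optical_calibration(config$gamma, config$zeta, k = k)
    } else if (!is.null(lookup) && !is.null(config$mu_s_prime)) {
      calibration <- lookup_gamma_zeta(lookup, config$mu_s_prime,
                                       config$mu_a %||% 0, config$g %||% 0,
                                       k = k)
    } else stop_sr("no calibration: give (gamma, zeta), or optical properties + lookup")
  }
  drp <- compute_drp(series)
  roi <- select_roi(drp)
  g2 <- compute_g2(series, roi, lags = lags)
  msd <- invert_msd(g2, calibration, absolute_floor = absolute_floor)
  alpha <- compute_alpha(msd)
  ctx <- gser_context(config$temperature, config$particle_radius)
  spec <- gser(alpha, ctx, frame_rate = series$frame_rate,
               duration = series$duration)
  params <- extract_spectro_params(spec, alpha)
  list(drp = drp, roi = roi, g2 = g2, msd = msd, alpha = alpha,
       spectrum = spec, params = params, calibration = calibration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
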