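# Beam localisation, diffused reflectance profile, ROI selection and the
# contrast-normalized intensity autocorrelation g2(t).

#' Diffused reflectance profile (DRP)
#'
#' Locates the beam as the intensity-weighted centroid of the time-averaged
#' frame and builds the azimuthally averaged radial intensity profile about
#' that centre. The background (mean of the outermost 5% radial annulus) is
#' subtracted before locating the first radius at which the profile falls
#' below 1/e of its peak; that radius defines the speckle ensemble ROI.
#'
#' @param series a [speckle_series()].
#' @return an object of class `dr_profile` with fields `radial_bins_px`,
#'   `radial_bins_m`, `mean_intensity` (background-subtracted counts),
#'   `background`, `beam_center` (row, col; sub-pixel), `one_over_e_radius`
#'   (pixels) and `pixel_pitch`.
#' @export
compute_drp <- function(series) {
  stopifnot(inherits(series, "speckle_series"))
  A <- rowMeans(series$frames, dims = 2L)      # time-averaged frame
  h <- nrow(A); w <- ncol(A)
  tot <- sum(A)
  if (tot <= 0) stop_sr("no DRP decay detected: empty image")
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  ctr <- c(sum(rows * A), sum(cols * A)) / tot
  r <- sqrt((rows - ctr[1L])^2 + (cols - ctr[2L])^2)
  bin <- as.vector(floor(r)) + 1L               # 1-px annuli from the centre
  prof <- as.numeric(tapply(as.vector(A), bin, mean))
  radii <- sort(unique(bin)) - 0.5              # bin centres in px
  # background: outermost 5% of the radial range
  n_bins <- length(prof)
  bg_idx <- radii >= max(radii) * 0.95
  if (!any(bg_idx)) bg_idx <- n_bins
  bg <- mean(prof[bg_idx])
  prof_bs <- prof - bg
  pk_i <- which.max(prof_bs)
  pk <- prof_bs[pk_i]
  if (!is.finite(pk) || pk <= 0 ||
      pk < 0.05 * max(prof) || stats::sd(prof) < 1e-12 * max(prof))
    stop_sr("no DRP decay detected")
  thr <- pk / exp(1)
  below <- which(prof_bs < thr & seq_along(prof_bs) > pk_i)
  if (!length(below)) stop_sr("no DRP decay detected")
  j <- below[1L]
  # linear interpolation between annuli for a sub-pixel 1/e radius
  r1e <- radii[j - 1L] + (prof_bs[j - 1L] - thr) /
    (prof_bs[j - 1L] - prof_bs[j]) * (radii[j] - radii[j - 1L])
  r1e <- min(r1e, min(h, w) / 2)
  structure(list(radial_bins_px = radii,
                 radial_bins_m = radii * series$pixel_pitch,
                 mean_intensity = prof_bs, background = bg,
                 beam_center = ctr, one_over_e_radius = r1e,
                 pixel_pitch = series$pixel_pitch, frame_dim = c(h, w)),
            class = "dr_profile")
}

#' Circular ensemble ROI from a DRP
#'
#' Boolean mask of pixels whose centre lies within the 1/e radius of the beam
#' centre. A radius reaching past the frame is clipped to the frame with a
#' warning.
#'
#' @param drp a `dr_profile` from [compute_drp()].
#' @param frame_dim optional `c(height, width)`; defaults to the DRP's own.
#' @param radius optional override of the radius in pixels.
#' @return logical matrix mask.
#' @export
select_roi <- function(drp, frame_dim = drp$frame_dim,
                       radius = drp$one_over_e_radius) {
  h <- frame_dim[1L]; w <- frame_dim[2L]
  ctr <- drp$beam_center
  if (ctr[1L] - radius < 0.5 || ctr[1L] + radius > h + 0.5 ||
      ctr[2L] - radius < 0.5 || ctr[2L] + radius > w + 0.5)
    warning("ROI radius extends beyond the frame; clipping to the frame",
            call. = FALSE)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - ctr[1L])^2 + (cols - ctr[2L])^2 <= radius^2
}

#' Pseudo-logarithmic (multi-tau style) lag set
#'
#' Every integer lag is kept up to `dense_until`, then lags are placed
#' log-uniformly at `points_per_octave` per octave up to `max_lag`
#' (default n_frames/10). All-pairs correlation at every integer lag of a
#' multi-million-frame series is infeasible; this scheme preserves ~16
#' lags/octave resolution on a log axis.
#'
#' @param n_frames number of frames available.
#' @param points_per_octave lag density beyond the dense region.
#' @param max_lag largest lag in frames.
#' @param dense_until keep all integer lags up to this value.
#' @return sorted unique integer lags, starting at 0.
#' @export
multitau_lags <- function(n_frames, points_per_octave = 16L,
                          max_lag = max(1L, n_frames %/% 10L),
                          dense_until = 16L) {
  max_lag <- min(max_lag, n_frames - 1L)
  dense <- 0:min(dense_until, max_lag)
  if (max_lag <= dense_until) return(as.integer(dense))
  lg <- 2^seq(log2(dense_until), log2(max_lag), by = 1 / points_per_octave)
  sort(unique(c(dense, as.integer(round(lg)))))
}

#' Contrast-normalized intensity autocorrelation g2(t)
#'
#' Computes the ensemble-averaged intensity autocorrelation
#' `g2_raw(t) = <I(t0) I(t0+t)> / (<I(t0)> <I(t0+t)>)` where `< >` averages
#' over all ROI pixels and all admissible frame pairs at each lag, then
#' contrast-normalizes: `g2 = (g2_raw(t) - 1) / (g2_raw(0) - 1) + 1`. The
#' lag-0 reference uses the same-frame second moment, which forces `g2(0) = 2`
#' exactly and cancels any global coherence factor beta.
#'
#' The space-time ensemble estimator assumes spatially homogeneous mean
#' intensity, but the diffuse-reflectance envelope makes pixel means vary
#' across the ROI, which would leave a spurious baseline in `g2 - 1`
#' (proportional to the spatial variance of the envelope over the ROI).
#' `flatten = "radial"` (default) divides every pixel by the azimuthally
#' averaged time-mean intensity at its radius — a static, speckle-free
#' envelope estimate that leaves the dynamics untouched. `flatten = "pixel"`
#' divides by per-pixel temporal means instead; note that over a finite record
#' this high-passes the signal and suppresses long-lag correlations, so it is
#' kept only for comparison. `flatten = "none"` correlates raw intensities.
#'
#' @param series a [speckle_series()].
#' @param roi_mask logical matrix; defaults to the full frame.
#' @param lags integer frame offsets (must include representable lags only);
#'   defaults to [multitau_lags()]. Lags >= n_frames are dropped with a
#'   warning.
#' @param chunk frames per accumulation block (memory control).
#' @param flatten envelope handling: "radial" (default), "pixel" or "none".
#' @return a `correlation_curve`: `lags` (seconds), `g2`, `n_pairs`,
#'   plus attributes `normalized = TRUE`.
#' @export
compute_g2 <- function(series, roi_mask = NULL, lags = NULL, chunk = 4096L,
                       flatten = c("radial", "pixel", "none")) {
  flatten <- match.arg(flatten)
  stopifnot(inherits(series, "speckle_series"))
  d <- dim(series$frames)
  Tn <- d[3L]
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1L], d[2L])
  if (!any(roi_mask)) stop_sr("ROI mask is empty")
  if (is.null(lags)) lags <- multitau_lags(Tn)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags >= Tn)) {
    warning("dropping lags >= n_frames", call. = FALSE)
    lags <- lags[lags < Tn]
  }
  if (!0L %in% lags) lags <- c(0L, lags)
  # ROI pixels x frames matrix
  X <- matrix(series$frames[rep(roi_mask, Tn)], nrow = sum(roi_mask), ncol = Tn)
  storage.mode(X) <- "double"
  X <- flatten_envelope(X, series, roi_mask, flatten)
  npx <- nrow(X)
  col_sum <- colSums(X)
  col_sq <- colSums(X * X)
  cum_sum <- cumsum(col_sum)
  g2_raw <- numeric(length(lags))
  n_pairs <- numeric(length(lags))
  for (i in seq_along(lags)) {
    L <- lags[i]
    nf <- Tn - L
    if (L == 0L) {
      num <- sum(col_sq) / (npx * Tn)
      m1 <- m2 <- sum(col_sum) / (npx * Tn)
    } else {
      # streaming accumulation over frame blocks
      s <- 0
      for (b0 in seq(1L, nf, by = chunk)) {
        b1 <- min(b0 + chunk - 1L, nf)
        s <- s + sum(X[, b0:b1, drop = FALSE] *
                       X[, (b0 + L):(b1 + L), drop = FALSE])
      }
      num <- s / (npx * nf)
      m1 <- cum_sum[nf] / (npx * nf)
      m2 <- (cum_sum[Tn] - cum_sum[L]) / (npx * nf)
    }
    g2_raw[i] <- num / (m1 * m2)
    n_pairs[i] <- npx * nf
  }
  denom <- g2_raw[lags == 0L] - 1
  if (!is.finite(denom) || denom <= 0)
    stop_sr("zero speckle contrast: g2_raw(0) - 1 = 0")
  new_correlation_curve(lags / series$frame_rate,
                        (g2_raw - 1) / denom + 1, n_pairs, normalized = TRUE)
}

#' Direct all-pairs reference correlator
#'
#' Brute-force O(T^2) implementation of the same estimator as [compute_g2()],
#' looping explicitly over every admissible frame pair. Kept as an independent
#' reference for validating the optimized accumulation on short series; do not
#' use on long movies.
#'
#' @inheritParams compute_g2
#' @return a `correlation_curve`.
#' @export
compute_g2_direct <- function(series, roi_mask = NULL, lags = NULL,
                              flatten = c("radial", "pixel", "none")) {
  flatten <- match.arg(flatten)
  stopifnot(inherits(series, "speckle_series"))
  d <- dim(series$frames)
  Tn <- d[3L]
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1L], d[2L])
  if (is.null(lags)) lags <- multitau_lags(Tn)
  lags <- sort(unique(as.integer(lags)))
  lags <- lags[lags < Tn]
  if (!0L %in% lags) lags <- c(0L, lags)
  X <- matrix(series$frames[rep(roi_mask, Tn)], nrow = sum(roi_mask), ncol = Tn)
  storage.mode(X) <- "double"
  X <- flatten_envelope(X, series, roi_mask, flatten)
  npx <- nrow(X)
  g2_raw <- numeric(length(lags))
  n_pairs <- numeric(length(lags))
  for (i in seq_along(lags)) {
    L <- lags[i]
    num <- 0; s1 <- 0; s2 <- 0
    for (t0 in seq_len(Tn - L)) {
      num <- num + sum(X[, t0] * X[, t0 + L])
      s1 <- s1 + sum(X[, t0])
      s2 <- s2 + sum(X[, t0 + L])
    }
    nf <- Tn - L
    g2_raw[i] <- (num / (npx * nf)) / ((s1 / (npx * nf)) * (s2 / (npx * nf)))
    n_pairs[i] <- npx * nf
  }
  denom <- g2_raw[lags == 0L] - 1
  if (!is.finite(denom) || denom <= 0)
    stop_sr("zero speckle contrast: g2_raw(0) - 1 = 0")
  new_correlation_curve(lags / series$frame_rate,
                        (g2_raw - 1) / denom + 1, n_pairs, normalized = TRUE)
}

# Divide ROI pixel traces by a static envelope estimate (see compute_g2).
flatten_envelope <- function(X, series, roi_mask, flatten) {
  if (flatten == "none") return(X)
  if (flatten == "pixel") {
    pm <- rowMeans(X)
    if (any(pm <= 0)) stop_sr("zero-mean pixels in the ROI; cannot flatten")
    return(X / pm)
  }
  # radial: azimuthal average of the time-averaged frame at each pixel radius
  A <- rowMeans(series$frames, dims = 2L)
  h <- nrow(A); w <- ncol(A)
  tot <- sum(A)
  if (tot <= 0) stop_sr("empty series; cannot flatten")
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  ctr <- c(sum(rows * A), sum(cols * A)) / tot
  r <- sqrt((rows - ctr[1L])^2 + (cols - ctr[2L])^2)
  bin <- as.vector(floor(r)) + 1L
  prof <- as.numeric(tapply(as.vector(A), bin, mean))
  radii <- sort(unique(bin)) - 0.5
  env_px <- stats::approx(radii, prof, xout = r[roi_mask], rule = 2)$y
  if (any(env_px <= 0)) stop_sr("non-positive envelope estimate in the ROI")
  X / env_px
}

new_correlation_curve <- function(lags, g2, n_pairs, normalized) {
  structure(list(lags = lags, g2 = g2, n_pairs = n_pairs,
                 normalized = normalized),
            class = "correlation_curve")
}

#' Construct a correlation curve by hand
#' @param lags lag times, seconds, strictly increasing, first lag 0.
#' @param g2 intensity autocorrelation values.
#' @param n_pairs ensemble pair counts per lag (default 1).
#' @param normalized has the contrast normalization already been applied?
#' @return a `correlation_curve`.
#' @export
correlation_curve <- function(lags, g2, n_pairs = rep(1, length(lags)),
                              normalized = FALSE) {
  if (length(lags) != length(g2)) stop_sr("lags and g2 lengths differ")
  if (is.unsorted(lags, strictly = TRUE)) stop_sr("lags must be strictly increasing")
  if (any(n_pairs < 1)) stop_sr("n_pairs must be >= 1 for every retained lag")
  new_correlation_curve(lags, g2, n_pairs, normalized)
}

#' Apply the contrast normalization to a raw correlation curve
#' @param corr a `correlation_curve` whose first lag is 0.
#' @return a normalized `correlation_curve` with `g2(0) = 2`.
#' @export
normalize_g2 <- function(corr) {
  if (isTRUE(corr$normalized)) return(corr)
  if (corr$lags[1L] != 0) stop_sr("normalization needs the lag-0 point")
  denom <- corr$g2[1L] - 1
  if (!is.finite(denom) || denom <= 0) stop_sr("zero speckle contrast")
  new_correlation_curve(corr$lags, (corr$g2 - 1) / denom + 1, corr$n_pairs,
                        normalized = TRUE)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation_curve: %d lags, %.3g..%.3g s, g2(0) = %.4f%s\n",
              length(x$lags), min(x$lags[x$lags > 0], na.rm = TRUE),
              max(x$lags), x$g2[1L],
              if (isTRUE(x$normalized)) " (contrast-normalized)" else ""))
  invisible(x)
}

#' Export a correlogram as CSV (lag_s, g2, n_pairs)
#' @param corr a `correlation_curve`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_correlogram <- function(corr, path) {
  utils::write.csv(data.frame(lag_s = corr$lags, g2 = corr$g2,
                              n_pairs = corr$n_pairs),
                   path, row.names = FALSE)
  invisible(path)
}
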