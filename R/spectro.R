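# Regime segmentation and spectroscopic fingerprint parameters:
#   omega_T  fluid-solid transition, alpha(omega_T) = 0.5 (G' = G'')
#   omega0   plateau frequency, local minimum of alpha (and of G'')
#   G0       elastic plateau modulus, G'(omega0)
#   gamma_k  log-log slope of G''(omega) within each scaling regime
#   omega_gamma  inflection of the G'' log-log derivative (scaling transition)
#   alpha_k  log-log slope of |G*(omega)| within each scaling regime

#' Fluid-solid transition frequencies
#'
#' All crossings of alpha through 0.5, located by linear interpolation in
#' log-omega; each is tagged by its direction: decreasing alpha is a
#' fluid-to-solid transition (G' overtakes G''), increasing the reverse. Ties
#' (alpha exactly 0.5 on the grid) break toward lower omega.
#'
#' @param alpha_curve an `alpha_curve`.
#' @return data.frame with `omega_T` and `direction`
#'   ("fluid_to_solid"/"solid_to_fluid"); zero rows when no crossing.
#' @export
find_transitions <- function(alpha_curve, level = 0.5) {
  a <- alpha_curve$alpha
  lw <- log10(alpha_curve$omega)
  d <- a - level
  out <- list()
  i <- 1L
  n <- length(a)
  while (i < n) {
    if (d[i] == 0) {
      dir <- if (i > 1L && d[i - 1L] > 0 || d[i + 1L] < 0) "fluid_to_solid"
             else "solid_to_fluid"
      out[[length(out) + 1L]] <- data.frame(omega_T = alpha_curve$omega[i],
                                            direction = dir)
      while (i < n && d[i] == 0) i <- i + 1L
    } else if (d[i] * d[i + 1L] < 0) {
      f <- d[i] / (d[i] - d[i + 1L])
      w <- 10^(lw[i] + f * (lw[i + 1L] - lw[i]))
      dir <- if (d[i] > 0) "fluid_to_solid" else "solid_to_fluid"
      out[[length(out) + 1L]] <- data.frame(omega_T = w, direction = dir)
      i <- i + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(data.frame(omega_T = numeric(), direction = character()))
  do.call(rbind, out)
}

#' Elastic plateaus
#'
#' Interior local minima of the (already smoothed) alpha curve with relative
#' prominence at least `prominence`: the minimum must sit at least that far
#' below the lower of its neighbouring maxima. Plateau frequency omega0 is the
#' minimum's grid point (these minima coincide with local minima of G'');
#' plateau modulus G0 is G'(omega0). Boundary points are excluded.
#'
#' @param spectrum a `visco_spectrum`.
#' @param alpha_curve the aligned `alpha_curve`.
#' @param prominence minimum alpha drop relative to neighbouring maxima.
#' @return data.frame with `omega0`, `G0`, `index`; zero rows if none.
#' @export
find_plateaus <- function(spectrum, alpha_curve, prominence = 0.05) {
  a <- alpha_curve$alpha
  n <- length(a)
  if (n < 3L) return(data.frame(omega0 = numeric(), G0 = numeric(),
                                index = integer()))
  mins <- integer()
  for (i in 2:(n - 1L)) {
    if (a[i] < a[i - 1L] && a[i] <= a[i + 1L]) mins <- c(mins, i)
  }
  # topographic prominence: walk outward until the terrain drops below the
  # candidate; the lower of the two enclosing maxima sets the prominence.
  # Only the deepest minimum of each basin survives a meaningful threshold.
  keep <- logical(length(mins))
  for (j in seq_along(mins)) {
    i <- mins[j]
    v <- a[i]
    left_max <- -Inf
    for (p in seq.int(i - 1L, 1L)) {
      if (a[p] < v) break
      left_max <- max(left_max, a[p])
    }
    right_max <- -Inf
    for (p in seq.int(i + 1L, n)) {
      if (a[p] < v) break
      right_max <- max(right_max, a[p])
    }
    keep[j] <- is.finite(left_max) && is.finite(right_max) &&
      min(left_max, right_max) - v >= prominence
  }
  mins <- mins[keep]
  data.frame(omega0 = alpha_curve$omega[mins],
             G0 = spectrum$G_storage[mins], index = mins)
}

#' Power-law fits within regime intervals
#'
#' Per interval, least-squares log-log slope of G'' (the loss exponent
#' gamma_k) and of |G*| (the magnitude exponent alpha_k), with standard
#' errors.
#'
#' @param spectrum a `visco_spectrum`.
#' @param regime_intervals list of `c(omega_lo, omega_hi)` pairs.
#' @return data.frame: interval bounds, `gamma`, `gamma_se`, `alpha_mag`,
#'   `alpha_mag_se`, `n`.
#' @export
fit_power_laws <- function(spectrum, regime_intervals) {
  if (!length(regime_intervals)) stop_sr("no regime intervals given")
  rows <- lapply(regime_intervals, function(iv) {
    sel <- spectrum$omega >= iv[1L] & spectrum$omega <= iv[2L] & spectrum$valid
    if (sum(sel) < 5L)
      stop_sr("interval [", signif(iv[1L], 3), ", ", signif(iv[2L], 3),
              "] contains fewer than 5 grid points")
    if (any(spectrum$G_loss[sel] <= 0) || any(spectrum$G_mag[sel] <= 0))
      stop_sr("non-positive moduli inside fit interval")
    lw <- log10(spectrum$omega[sel])
    f1 <- stats::lm(log10(spectrum$G_loss[sel]) ~ lw)
    f2 <- stats::lm(log10(spectrum$G_mag[sel]) ~ lw)
    s1 <- summary(f1)$coefficients; s2 <- summary(f2)$coefficients
    data.frame(omega_lo = iv[1L], omega_hi = iv[2L],
               gamma = s1[2L, 1L], gamma_se = s1[2L, 2L],
               alpha_mag = s2[2L, 1L], alpha_mag_se = s2[2L, 2L],
               n = sum(sel))
  })
  do.call(rbind, rows)
}

#' Scaling transition frequency within a regime
#'
#' Finds the inflection of the smoothed log-log derivative of G'' inside the
#' interval: omega_gamma sits at the sign change of the second difference of
#' that derivative. A single material inflection is returned; zero or multiple
#' inflections yield `omega_gamma = NA` with the multiplicity reported.
#'
#' @param spectrum a `visco_spectrum`.
#' @param regime_interval `c(omega_lo, omega_hi)` spanning >= 1 decade.
#' @param smooth_window moving-average width for the derivative.
#' @param min_slope_change total derivative change below which the interval is
#'   declared a single power law (no transition).
#' @return list with `omega_gamma` (or NA) and `multiplicity`.
#' @export
find_scaling_transition <- function(spectrum, regime_interval,
                                    smooth_window = 7L,
                                    min_slope_change = 0.1) {
  sel <- spectrum$omega >= regime_interval[1L] &
    spectrum$omega <= regime_interval[2L] & spectrum$valid
  w <- spectrum$omega[sel]
  if (length(w) < 8L || log10(max(w) / min(w)) < 1)
    stop_sr("regime interval must span at least one decade")
  lw <- log10(w)
  ly <- log10(spectrum$G_loss[sel])
  d <- rolling_slope(lw, ly, 5L)$slope
  ds <- moving_average(d, smooth_window)
  # drop the shrunk-window edges, where the derivative estimate wiggles
  trim <- max(2L, (smooth_window - 1L) %/% 2L)
  keep <- (trim + 1L):(length(ds) - trim)
  ds <- ds[keep]; w_in <- w[keep]
  if (max(ds) - min(ds) < min_slope_change)
    return(list(omega_gamma = NA_real_, multiplicity = 0L))
  d2 <- diff(ds, differences = 2L)
  # material sign changes of the second difference only
  tol <- 0.1 * max(abs(d2))
  sgn <- sign(d2)
  sgn[abs(d2) < tol] <- 0
  nz <- which(sgn != 0)
  flips <- integer()
  if (length(nz) > 1L)
    for (j in seq_len(length(nz) - 1L))
      if (sgn[nz[j]] != sgn[nz[j + 1L]]) flips <- c(flips, nz[j + 1L])
  if (length(flips) != 1L)
    return(list(omega_gamma = NA_real_, multiplicity = length(flips)))
  list(omega_gamma = w_in[flips + 1L], multiplicity = 1L)
}

#' Segment the valid band into viscoelastic regimes
#'
#' The valid band is partitioned at the ordered feature frequencies:
#' transitions (alpha = 0.5 crossings) break regimes exactly at omega_T, and
#' boundaries between a plateau and the adjacent scaling anchor (the alpha
#' local maximum following it) sit at the log-midpoint between the two.
#' Intervals are labelled with ascending Roman numerals starting at I; an
#' interval split by a scaling transition omega_gamma gets sub-labels a/b.
#'
#' @param alpha_curve an `alpha_curve`.
#' @param transitions data.frame from [find_transitions()].
#' @param plateaus data.frame from [find_plateaus()].
#' @param scaling_transitions optional numeric vector of omega_gamma values.
#' @param band optional `c(lo, hi)` frequency band; defaults to the grid range.
#' @return data.frame with `label`, `omega_lo`, `omega_hi`, `kind`
#'   ("pre_transition", "plateau", "scaling").
#' @export
segment_regimes <- function(alpha_curve, transitions, plateaus,
                            scaling_transitions = numeric(), band = NULL) {
  w <- alpha_curve$omega
  a <- alpha_curve$alpha
  if (is.null(band)) band <- range(w)
  feats <- data.frame(omega = numeric(), kind = character())
  if (nrow(transitions))
    feats <- rbind(feats, data.frame(omega = transitions$omega_T,
                                     kind = "transition"))
  if (nrow(plateaus))
    feats <- rbind(feats, data.frame(omega = plateaus$omega0, kind = "plateau"))
  # scaling anchors: alpha local maxima after each plateau (band edge allowed)
  if (nrow(plateaus)) {
    for (j in seq_len(nrow(plateaus))) {
      i0 <- plateaus$index[j]
      i1 <- if (j < nrow(plateaus)) plateaus$index[j + 1L] else length(w)
      if (i1 > i0) {
        im <- i0 + which.max(a[i0:i1]) - 1L
        feats <- rbind(feats, data.frame(omega = w[im], kind = "scaling"))
      }
    }
  }
  feats <- feats[order(feats$omega), , drop = FALSE]
  # transitions/plateaus must lie strictly inside the band; scaling anchors may
  # sit at the band edge (the alpha maximum after the last plateau often does)
  inside <- feats$omega > band[1L] &
    (feats$omega < band[2L] |
       (feats$kind == "scaling" & feats$omega <= band[2L]))
  feats <- feats[inside, , drop = FALSE]
  # breakpoints: transitions break at omega_T; plateau/scaling pairs break at
  # their log-midpoint
  bps <- numeric()
  if (nrow(feats)) {
    for (j in seq_len(nrow(feats))) {
      if (feats$kind[j] == "transition") bps <- c(bps, feats$omega[j])
      else if (j < nrow(feats) && feats$kind[j + 1L] != "transition")
        bps <- c(bps, sqrt(feats$omega[j] * feats$omega[j + 1L]))
    }
  }
  bps <- sort(unique(bps))
  bps <- bps[bps > band[1L] & bps < band[2L]]
  edges <- c(band[1L], bps, band[2L])
  n_int <- length(edges) - 1L
  lab <- character(0); lo <- numeric(0); hi <- numeric(0); kind <- character(0)
  for (i in seq_len(n_int)) {
    l <- edges[i]; h <- edges[i + 1L]
    inside <- feats$omega > l & feats$omega < h
    k <- if (any(inside & feats$kind == "plateau")) "plateau"
         else if (i == 1L && nrow(feats) && feats$kind[1L] == "transition" &&
                  feats$omega[1L] >= h) "pre_transition"
         else "scaling"
    og <- scaling_transitions[scaling_transitions > l & scaling_transitions < h]
    if (k == "scaling" && length(og) == 1L) {
      lab <- c(lab, paste0(roman(i), "a"), paste0(roman(i), "b"))
      lo <- c(lo, l, og); hi <- c(hi, og, h); kind <- c(kind, k, k)
    } else {
      lab <- c(lab, roman(i)); lo <- c(lo, l); hi <- c(hi, h); kind <- c(kind, k)
    }
  }
  data.frame(label = lab, omega_lo = lo, omega_hi = hi, kind = kind)
}

#' Extract the full spectroscopic fingerprint
#'
#' Orchestrates [find_transitions()], [find_plateaus()], regime segmentation,
#' per-regime power-law fits (fit intervals shrink by one grid step at each
#' end to avoid curvature contamination) and the scaling-transition search
#' within scaling regimes.
#'
#' @param spectrum a `visco_spectrum`.
#' @param alpha_curve the aligned `alpha_curve`.
#' @param prominence plateau prominence threshold on alpha.
#' @return a `spectro_params` object: `transitions`, `plateaus`, `regimes`,
#'   `power_laws` (per scaling regime), `scaling_transitions`.
#' @export
extract_spectro_params <- function(spectrum, alpha_curve, prominence = 0.05) {
  v <- spectrum$valid
  band <- range(spectrum$omega[v])
  sub_alpha <- alpha_curve
  trans <- find_transitions(alpha_curve)
  trans <- trans[trans$omega_T > band[1L] & trans$omega_T < band[2L], ,
                 drop = FALSE]
  plat <- find_plateaus(spectrum, alpha_curve, prominence)
  plat <- plat[plat$omega0 > band[1L] & plat$omega0 < band[2L], , drop = FALSE]
  # first pass without omega_gamma to get scaling intervals
  reg0 <- segment_regimes(sub_alpha, trans, plat, numeric(), band = band)
  step <- 10^(1 / alpha_curve$points_per_decade)
  og <- numeric(); og_mult <- integer()
  for (i in which(reg0$kind == "scaling")) {
    iv <- c(reg0$omega_lo[i] * step, reg0$omega_hi[i] / step)
    if (iv[2L] / iv[1L] < 10) next
    st <- tryCatch(find_scaling_transition(spectrum, iv),
                   error = function(e) list(omega_gamma = NA_real_,
                                            multiplicity = 0L))
    if (!is.na(st$omega_gamma)) og <- c(og, st$omega_gamma)
    og_mult <- c(og_mult, st$multiplicity)
  }
  regimes <- segment_regimes(sub_alpha, trans, plat, og, band = band)
  sc <- regimes[regimes$kind == "scaling", , drop = FALSE]
  pl_fits <- NULL
  if (nrow(sc)) {
    ivs <- lapply(seq_len(nrow(sc)), function(i)
      c(sc$omega_lo[i] * step, sc$omega_hi[i] / step))
    enough <- vapply(ivs, function(iv) {
      sum(spectrum$omega >= iv[1L] & spectrum$omega <= iv[2L] &
            spectrum$valid) >= 5L
    }, TRUE)
    if (any(enough)) {
      pl_fits <- fit_power_laws(spectrum, ivs[enough])
      pl_fits$label <- sc$label[enough]
    }
  }
  structure(list(transitions = trans, plateaus = plat, regimes = regimes,
                 power_laws = pl_fits,
                 scaling_transitions = og, scaling_multiplicity = og_mult,
                 band = band),
            class = "spectro_params")
}

#' @export
print.spectro_params <- function(x, ...) {
  cat("spectro_params over omega =", signif(x$band[1L], 3), "..",
      signif(x$band[2L], 3), "rad/s\n")
  if (nrow(x$transitions))
    cat("  omega_T:", paste(signif(x$transitions$omega_T, 3), collapse = ", "),
        "rad/s\n")
  if (nrow(x$plateaus))
    for (j in seq_len(nrow(x$plateaus)))
      cat(sprintf("  plateau: omega0 = %.3g rad/s, G0 = %.3g Pa\n",
                  x$plateaus$omega0[j], x$plateaus$G0[j]))
  if (!is.null(x$power_laws))
    for (j in seq_len(nrow(x$power_laws)))
      cat(sprintf("  regime %s: gamma = %.3f +/- %.3f, alpha_mag = %.3f +/- %.3f\n",
                  x$power_laws$label[j], x$power_laws$gamma[j],
                  x$power_laws$gamma_se[j], x$power_laws$alpha_mag[j],
                  x$power_laws$alpha_mag_se[j]))
  cat("  regimes:", paste(x$regimes$label, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a spectro_params object into the tabular export layout
#' @param params a `spectro_params`.
#' @return data.frame: parameter, regime, value, units, fit_lo, fit_hi.
#' @export
spectro_params_table <- function(params) {
  rows <- list()
  add <- function(parameter, regime, value, units, lo = NA, hi = NA)
    rows[[length(rows) + 1L]] <<- data.frame(parameter = parameter,
                                             regime = regime, value = value,
                                             units = units, fit_lo = lo,
                                             fit_hi = hi)
  if (nrow(params$transitions))
    for (j in seq_len(nrow(params$transitions)))
      add("omega_T", params$transitions$direction[j],
          params$transitions$omega_T[j], "rad/s")
  if (nrow(params$plateaus)) {
    plats <- params$plateaus
    plab <- params$regimes$label[params$regimes$kind == "plateau"]
    for (j in seq_len(nrow(plats))) {
      rg <- if (j <= length(plab)) plab[j] else NA_character_
      add("omega0", rg, plats$omega0[j], "rad/s")
      add("G0", rg, plats$G0[j], "Pa")
    }
  }
  if (!is.null(params$power_laws))
    for (j in seq_len(nrow(params$power_laws))) {
      pw <- params$power_laws[j, ]
      add("gamma", pw$label, pw$gamma, "dimensionless", pw$omega_lo, pw$omega_hi)
      add("alpha", pw$label, pw$alpha_mag, "dimensionless", pw$omega_lo,
          pw$omega_hi)
    }
  for (ogv in params$scaling_transitions)
    add("omega_gamma", NA_character_, ogv, "rad/s")
  if (!length(rows))
    return(data.frame(parameter = character(), regime = character(),
                      value = numeric(), units = character(),
                      fit_lo = numeric(), fit_hi = numeric()))
  do.call(rbind, rows)
}
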