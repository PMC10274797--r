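# Monte Carlo photon transport and the sample-specific (gamma, zeta)
# calibration of the empirical g2 <-> MSD inversion
#   g2(t) - 1 = exp(-2*gamma*(k^2*<dr^2(t)>)^zeta).
# gamma = 2/3, zeta = 1 recovers the single-scattering (DLS, 180 degrees)
# limit; gamma = 5/3, zeta = 0.5 the diffusive (DWS backscattering) limit.
# Intermediate optical properties land between the two.

.GAMMA_BOUNDS <- c(2 / 3, 5 / 3)
.ZETA_BOUNDS <- c(0.5, 1)

#' Optical calibration constants
#'
#' @param gamma,zeta empirical inversion constants; gamma in `[2/3, 5/3]`,
#'   zeta in `[0.5, 1]` (DLS and DWS limits).
#' @param k in-medium wavenumber, rad/m; alternatively give `wavelength` and
#'   `refractive_index`.
#' @param wavelength illumination wavelength, metres.
#' @param refractive_index sample refractive index.
#' @param source optional provenance (optical properties used).
#' @return an `optical_calibration` object.
#' @export
optical_calibration <- function(gamma, zeta, k = NULL, wavelength = 637e-9,
                                refractive_index = 1.33, source = NULL) {
  if (is.null(k)) k <- 2 * pi * refractive_index / wavelength
  if (k <= 0) stop_sr("wavenumber k must be positive")
  if (gamma < .GAMMA_BOUNDS[1L] - 1e-9 || gamma > .GAMMA_BOUNDS[2L] + 1e-9)
    stop_sr("gamma must lie in [2/3, 5/3]")
  if (zeta < .ZETA_BOUNDS[1L] - 1e-9 || zeta > .ZETA_BOUNDS[2L] + 1e-9)
    stop_sr("zeta must lie in [0.5, 1]")
  structure(list(gamma = gamma, zeta = zeta, k = k, source = source),
            class = "optical_calibration")
}

#' @export
print.optical_calibration <- function(x, ...) {
  cat(sprintf("optical_calibration: gamma = %.4f, zeta = %.4f, k = %.4g rad/m\n",
              x$gamma, x$zeta, x$k))
  invisible(x)
}

#' Path-length distribution container
#' @param s path lengths in units of the transport mean free path l* = 1/mu_s'.
#' @param weights detected photon weights; renormalized to sum to 1.
#' @param n_photons number of photons launched.
#' @param exit_r exit radii (units of l*), optional.
#' @param detector_radius detector radius (units of l*), optional.
#' @param mu_s_prime,mu_a,g source optical properties (SI), optional.
#' @return a `path_length_distribution`.
#' @export
path_length_distribution <- function(s, weights = rep(1, length(s)),
                                     n_photons = length(s), exit_r = NULL,
                                     detector_radius = NA_real_,
                                     mu_s_prime = NA_real_, mu_a = NA_real_,
                                     g = NA_real_) {
  if (length(s) == 0L) stop_sr("no backscattered photons detected")
  if (any(s <= 0)) stop_sr("all path lengths must be positive")
  if (any(weights < 0)) stop_sr("weights must be non-negative")
  w <- weights / sum(weights)
  structure(list(s = s, weights = w, n_photons = n_photons, exit_r = exit_r,
                 detector_radius = detector_radius, mu_s_prime = mu_s_prime,
                 mu_a = mu_a, g = g,
                 total_weight = sum(weights) / n_photons),
            class = "path_length_distribution")
}

#' Monte Carlo photon transport in a semi-infinite turbid medium
#'
#' Random-walk photon transport with exponential free paths at rate
#' `mu_s = mu_s' / (1 - g)`, Henyey-Greenstein scattering with anisotropy `g`,
#' and absorption handled by weight attenuation `exp(-mu_a * s)`. Photons are
#' launched at the origin into the medium (+z), the surface is
#' refractive-index matched (photons crossing z = 0 exit), and a photon is
#' detected if it exits within `detector_radius` of the injection point
#' (180-degree backscattered configuration, detector co-located with the
#' source).
#'
#' @param mu_s_prime reduced scattering coefficient, 1/m (> 0).
#' @param mu_a absorption coefficient, 1/m (>= 0).
#' @param g Henyey-Greenstein anisotropy, `0 <= g < 1`.
#' @param detector_radius collection radius, metres (use
#'   `n_lstar / mu_s_prime` for a radius of `n_lstar` transport mean free
#'   paths). Default `Inf` collects every backscattered photon.
#' @param n_photons photons to launch (>= 1000 recommended).
#' @param seed RNG seed; identical seed and arguments give a bit-identical
#'   distribution.
#' @param max_steps scattering-event cap per photon; walks exceeding it are
#'   discarded (counted in `truncated`). In 3D half-space the first-passage
#'   tail decays like n^-1/2, so the default loses well under 1% of photons.
#' @return a [path_length_distribution()] with path lengths in units of
#'   l* = 1/mu_s'.
#' @export
simulate_photon_paths <- function(mu_s_prime, mu_a = 0, g = 0,
                                  detector_radius = Inf, n_photons = 1e4,
                                  seed = NULL, max_steps = 30000L) {
  if (mu_s_prime <= 0) stop_sr("mu_s_prime must be positive")
  if (mu_a < 0) stop_sr("mu_a must be non-negative")
  if (g < 0 || g >= 1) stop_sr("anisotropy g must be in [0, 1)")
  if (n_photons < 1) stop_sr("n_photons must be positive")
  mu_s <- mu_s_prime / (1 - g)
  with_seed(seed, {
    n <- as.integer(n_photons)
    x <- numeric(n); y <- numeric(n); z <- numeric(n)
    ux <- numeric(n); uy <- numeric(n); uz <- rep(1, n)
    s_tot <- numeric(n)
    out_s <- vector("list", 64L); out_r <- vector("list", 64L); n_out <- 0L
    active <- rep(TRUE, n)
    step_i <- 0L
    while (any(active) && step_i < max_steps) {
      step_i <- step_i + 1L
      idx <- which(active)
      st <- stats::rexp(length(idx), rate = mu_s)
      xn <- x[idx] + st * ux[idx]
      yn <- y[idx] + st * uy[idx]
      zn <- z[idx] + st * uz[idx]
      exiting <- zn < 0
      if (any(exiting)) {
        ei <- idx[exiting]
        f <- z[ei] / (z[ei] - zn[exiting])       # fraction of step to z = 0
        sx <- x[ei] + f * st[exiting] * ux[ei]
        sy <- y[ei] + f * st[exiting] * uy[ei]
        n_out <- n_out + 1L
        if (n_out > length(out_s)) {
          out_s <- c(out_s, vector("list", length(out_s)))
          out_r <- c(out_r, vector("list", length(out_r)))
        }
        out_s[[n_out]] <- s_tot[ei] + f * st[exiting]
        out_r[[n_out]] <- sqrt(sx^2 + sy^2)
        active[ei] <- FALSE
      }
      keep <- idx[!exiting]
      if (length(keep)) {
        ki <- !exiting
        x[keep] <- xn[ki]; y[keep] <- yn[ki]; z[keep] <- zn[ki]
        s_tot[keep] <- s_tot[keep] + st[ki]
        # Henyey-Greenstein polar angle, uniform azimuth
        m <- length(keep)
        xi <- stats::runif(m)
        ct <- if (g > 0) {
          tmp <- (1 - g^2) / (1 - g + 2 * g * xi)
          (1 + g^2 - tmp^2) / (2 * g)
        } else 2 * xi - 1
        ct <- pmin(1, pmax(-1, ct))
        stheta <- sqrt(1 - ct^2)
        phi <- stats::runif(m, 0, 2 * pi)
        cphi <- cos(phi); sphi <- sin(phi)
        uzo <- uz[keep]; uxo <- ux[keep]; uyo <- uy[keep]
        near_pole <- abs(uzo) > 0.99999
        denom <- sqrt(pmax(1e-30, 1 - uzo^2))
        nux <- stheta * (uxo * uzo * cphi - uyo * sphi) / denom + uxo * ct
        nuy <- stheta * (uyo * uzo * cphi + uxo * sphi) / denom + uyo * ct
        nuz <- -stheta * cphi * denom + uzo * ct
        if (any(near_pole)) {
          sg <- sign(uzo[near_pole])
          nux[near_pole] <- stheta[near_pole] * cphi[near_pole]
          nuy[near_pole] <- stheta[near_pole] * sphi[near_pole]
          nuz[near_pole] <- sg * ct[near_pole]
        }
        nrm <- sqrt(nux^2 + nuy^2 + nuz^2)
        ux[keep] <- nux / nrm; uy[keep] <- nuy / nrm; uz[keep] <- nuz / nrm
      }
    }
    truncated <- sum(active)
    s_exit <- unlist(out_s[seq_len(n_out)], use.names = FALSE)
    r_exit <- unlist(out_r[seq_len(n_out)], use.names = FALSE)
    det <- r_exit <= detector_radius
    if (!any(det)) stop_sr("no backscattered photons detected")
    w <- exp(-mu_a * s_exit[det])
    lstar <- 1 / mu_s_prime
    pd <- path_length_distribution(
      s = s_exit[det] / lstar, weights = w, n_photons = n,
      exit_r = r_exit[det] / lstar,
      detector_radius = detector_radius / lstar,
      mu_s_prime = mu_s_prime, mu_a = mu_a, g = g)
    pd$truncated <- truncated
    # reflectance bookkeeping over ALL exit radii (absorption-weighted)
    pd$total_reflectance <- sum(exp(-mu_a * s_exit)) / n
    pd
  })
}

#' DWS path-integral field autocorrelation
#'
#' Synthesizes `g1` over a path-length distribution with the standard
#' diffusing-wave kernel: each path of length `s` contributes
#' `exp(-(k^2 * msd / 3) * (s / l*))`.
#'
#' @param path_dist a [path_length_distribution()] (s in units of l*).
#' @param k2msd dimensionless `k^2 * msd` values.
#' @return numeric `g1` of the same length as `k2msd`.
#' @export
dws_g1 <- function(path_dist, k2msd) {
  E <- exp(-outer(path_dist$s / 3, k2msd))
  as.vector(crossprod(path_dist$weights, E))
}

#' Fit the empirical inversion constants (gamma, zeta)
#'
#' Synthesizes `g2 - 1 = g1^2` over the path distribution and fits
#' `ln(-ln(g2 - 1))` linearly in `ln(k^2 * msd)`: the slope is `zeta`, the
#' intercept `ln(2*gamma)`. Values are clipped to the DLS/DWS bounds
#' `[2/3, 5/3] x [0.5, 1]` with a warning if clipping occurred.
#'
#' @param path_dist a [path_length_distribution()].
#' @param k in-medium wavenumber, rad/m.
#' @param msd_grid MSD grid (m^2) spanning at least ~3 decades around `1/k^2`.
#' @param fit_range the `g2 - 1` window actually entered into the regression
#'   (default `(0.01, 0.95)`): the experimentally measurable part of the
#'   decay. Outside it the double-log transform amplifies the tails, which are
#'   dominated by the shortest/longest paths rather than by the decay the
#'   inversion must describe.
#' @return an [optical_calibration()].
#' @export
fit_gamma_zeta <- function(path_dist, k,
                           msd_grid = 10^seq(-2.5, 1.5, by = 0.05) / k^2,
                           fit_range = c(0.01, 0.95)) {
  x <- k^2 * msd_grid
  if (diff(range(log10(x))) < 3) stop_sr("msd_grid must span >= 3 decades")
  g1 <- dws_g1(path_dist, x)
  if (any(diff(g1) > 1e-12)) stop_sr("synthesized g1 is not monotone decreasing")
  g2m1 <- g1^2
  raw <- fit_gz_loglog(x, g2m1, fit_range)
  gamma <- gamma_raw <- raw$gamma
  zeta <- zeta_raw <- raw$zeta
  clipped <- FALSE
  if (gamma < .GAMMA_BOUNDS[1L] || gamma > .GAMMA_BOUNDS[2L]) {
    gamma <- min(max(gamma, .GAMMA_BOUNDS[1L]), .GAMMA_BOUNDS[2L]); clipped <- TRUE
  }
  if (zeta < .ZETA_BOUNDS[1L] || zeta > .ZETA_BOUNDS[2L]) {
    zeta <- min(max(zeta, .ZETA_BOUNDS[1L]), .ZETA_BOUNDS[2L]); clipped <- TRUE
  }
  if (clipped)
    warning("fitted (gamma, zeta) clipped to the DLS/DWS bounds", call. = FALSE)
  optical_calibration(gamma, zeta, k = k,
                      source = list(mu_s_prime = path_dist$mu_s_prime,
                                    mu_a = path_dist$mu_a, g = path_dist$g,
                                    clipped = clipped, gamma_raw = gamma_raw,
                                    zeta_raw = zeta_raw))
}

# double-log regression behind fit_gamma_zeta:
# ln(-ln(g2 - 1)) = ln(2*gamma) + zeta * ln(k^2 MSD)
fit_gz_loglog <- function(x, g2m1, fit_range) {
  ok <- g2m1 > fit_range[1L] & g2m1 < fit_range[2L]
  if (sum(ok) < 5L) stop_sr("too few usable points to fit (gamma, zeta)")
  fit <- stats::lm(log(-log(g2m1[ok])) ~ log(x[ok]))
  list(gamma = exp(unname(stats::coef(fit)[1L])) / 2,
       zeta = unname(stats::coef(fit)[2L]))
}

#' Limiting path-length distributions
#'
#' `single_scattering_paths()` is the single-scattering (DLS, 180-degree
#' backscatter) limit: all detected light scattered once at a depth of about
#' one transport mean free path, path length s = 2 l*. Under the DWS kernel it
#' reproduces `g2 - 1 = exp(-(4/3) k^2 MSD)`, i.e. gamma = 2/3, zeta = 1.
#'
#' `diffusive_path_distribution()` samples the diffusion-approximation
#' backscattering limit: path lengths follow the first-passage (Levy) law of a
#' photon random walk released at the extrapolated source depth
#' `z_e = z0 + zb = (5/3) l*` in a semi-infinite medium,
#' `s = z_e^2 / (2 D_s Z^2)` with `D_s = l*/3` and `Z ~ N(0, 1)`. Its exact
#' DWS transform is `g1 = exp(-(z_e/l*) sqrt(k^2 MSD))`, i.e. gamma = 5/3,
#' zeta = 0.5. Raw photon-transport distributions from
#' [simulate_photon_paths()] contain genuine low-order scattering and
#' therefore land *between* the two limits.
#'
#' @param mu_s_prime reduced scattering coefficient, 1/m (provenance only).
#' @param n_paths number of sampled paths.
#' @param seed RNG seed.
#' @param z_e extrapolated source depth in units of l* (default 5/3, matched
#'   boundary).
#' @return a [path_length_distribution()].
#' @export
single_scattering_paths <- function(mu_s_prime = 1000) {
  path_length_distribution(s = 2, weights = 1, n_photons = 1L,
                           mu_s_prime = mu_s_prime)
}

#' @rdname single_scattering_paths
#' @export
diffusive_path_distribution <- function(mu_s_prime = 1000, n_paths = 1e5,
                                        seed = NULL, z_e = 5 / 3) {
  with_seed(seed, {
    z <- stats::rnorm(n_paths)
    s <- z_e^2 / (2 * (1 / 3) * z^2)
    path_length_distribution(s, n_photons = n_paths, mu_s_prime = mu_s_prime)
  })
}

#' Build a (gamma, zeta) lookup table over optical properties
#'
#' Runs the Monte Carlo + fit at every grid node. Queries interpolate
#' bilinearly in `(log mu_s', log(mu_a + 1))` within the nearest-`g` slice.
#' Defaults span soft-tissue optics.
#'
#' @param mu_s_grid reduced scattering grid, 1/m.
#' @param mu_a_grid absorption grid, 1/m.
#' @param g_grid anisotropy grid.
#' @param n_photons photons per node.
#' @param seed base seed; node seeds are derived deterministically.
#' @param k wavenumber used for the fit grid.
#' @param detector_radius_lstar collection radius in units of l*.
#' @return a `gz_lookup` data frame (mu_s_prime, mu_a, g, gamma, zeta) with
#'   provenance attributes.
#' @export
build_lookup_table <- function(mu_s_grid = 10^seq(2, 4, length.out = 5),
                               mu_a_grid = 10^seq(0, 3, length.out = 4),
                               g_grid = c(0, 0.8, 0.9),
                               n_photons = 1e5, seed = 1L,
                               k = 2 * pi * 1.33 / 637e-9,
                               detector_radius_lstar = 30) {
  grid <- expand.grid(mu_s_prime = mu_s_grid, mu_a = mu_a_grid, g = g_grid)
  gamma <- zeta <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pd <- simulate_photon_paths(grid$mu_s_prime[i], grid$mu_a[i], grid$g[i],
                                detector_radius =
                                  detector_radius_lstar / grid$mu_s_prime[i],
                                n_photons = n_photons,
                                seed = (seed + i - 1L) %% .Machine$integer.max)
    cal <- suppressWarnings(fit_gamma_zeta(pd, k))
    gamma[i] <- cal$gamma; zeta[i] <- cal$zeta
  }
  tab <- cbind(grid, gamma = gamma, zeta = zeta)
  attr(tab, "seed") <- seed
  attr(tab, "n_photons") <- n_photons
  class(tab) <- c("gz_lookup", class(tab))
  tab
}

#' Query a (gamma, zeta) lookup table
#'
#' @param table a `gz_lookup` from [build_lookup_table()] / [read_lookup_table()].
#' @param mu_s_prime,mu_a,g query point (SI; nearest `g` slice is used).
#' @param k wavenumber for the returned calibration.
#' @return an [optical_calibration()]. Queries outside the grid hull are
#'   answered by the nearest node with a warning.
#' @export
lookup_gamma_zeta <- function(table, mu_s_prime, mu_a, g = 0,
                              k = 2 * pi * 1.33 / 637e-9) {
  gs <- sort(unique(table$g))
  g_use <- gs[which.min(abs(gs - g))]
  sl <- table[table$g == g_use, ]
  xs <- sort(unique(sl$mu_s_prime)); ys <- sort(unique(sl$mu_a))
  lx <- log(mu_s_prime); ly <- log(mu_a + 1)
  lxs <- log(xs); lys <- log(ys + 1)
  if (lx < min(lxs) || lx > max(lxs) || ly < min(lys) || ly > max(lys)) {
    warning("query outside lookup grid hull; using nearest node", call. = FALSE)
    lx <- min(max(lx, min(lxs)), max(lxs))
    ly <- min(max(ly, min(lys)), max(lys))
  }
  i <- max(1L, findInterval(lx, lxs, rightmost.closed = TRUE))
  j <- max(1L, findInterval(ly, lys, rightmost.closed = TRUE))
  i2 <- min(i + 1L, length(xs)); j2 <- min(j + 1L, length(ys))
  tx <- if (i2 > i) (lx - lxs[i]) / (lxs[i2] - lxs[i]) else 0
  ty <- if (j2 > j) (ly - lys[j]) / (lys[j2] - lys[j]) else 0
  pick <- function(mi, mj, col)
    sl[sl$mu_s_prime == xs[mi] & sl$mu_a == ys[mj], col]
  bil <- function(col) {
    (1 - tx) * (1 - ty) * pick(i, j, col) + tx * (1 - ty) * pick(i2, j, col) +
      (1 - tx) * ty * pick(i, j2, col) + tx * ty * pick(i2, j2, col)
  }
  optical_calibration(min(max(bil("gamma"), .GAMMA_BOUNDS[1L]), .GAMMA_BOUNDS[2L]),
                      min(max(bil("zeta"), .ZETA_BOUNDS[1L]), .ZETA_BOUNDS[2L]),
                      k = k,
                      source = list(mu_s_prime = mu_s_prime, mu_a = mu_a,
                                    g = g_use, lookup = TRUE))
}

#' Persist / load a lookup table as CSV with a provenance header
#' @param table a `gz_lookup`.
#' @param path CSV path.
#' @return invisibly `path`; `read_lookup_table` returns the `gz_lookup`.
#' @export
write_lookup_table <- function(table, path) {
  con <- file(path, "w")
  writeLines(c(paste0("# specklerheo gz_lookup seed=", attr(table, "seed"),
                      " n_photons=", attr(table, "n_photons"))), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  tab <- utils::read.csv(path, comment.char = "#")
  seed <- sub(".*seed=([0-9]+).*", "\\1", hdr)
  np <- sub(".*n_photons=([0-9eE+.]+).*", "\\1", hdr)
  attr(tab, "seed") <- as.integer(seed)
  attr(tab, "n_photons") <- as.numeric(np)
  class(tab) <- c("gz_lookup", class(tab))
  tab
}

#' Radial diffuse-reflectance profile from Monte Carlo exits
#'
#' Bins the exit radii of a photon-transport run into annuli and returns the
#' detected weight per unit area, in SI units, directly comparable with a
#' measured DRP.
#'
#' @param path_dist a [path_length_distribution()] carrying `exit_r`.
#' @param n_bins number of radial bins.
#' @param r_max outer radius in units of l* (default: 30 l*).
#' @return list with `radial_bins_m` and `mean_intensity`.
#' @export
drp_from_paths <- function(path_dist, n_bins = 40L, r_max = 30) {
  if (is.null(path_dist$exit_r)) stop_sr("path distribution has no exit radii")
  lstar <- 1 / path_dist$mu_s_prime
  r <- path_dist$exit_r * lstar
  w <- path_dist$weights
  edges <- seq(0, r_max * lstar, length.out = n_bins + 1L)
  idx <- findInterval(r, edges, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx <= n_bins
  wsum <- tapply(w[keep], factor(idx[keep], levels = seq_len(n_bins)), sum,
                 default = 0)
  area <- pi * diff(edges^2)
  mid <- (edges[-1L] + edges[-length(edges)]) / 2
  list(radial_bins_m = mid, mean_intensity = as.numeric(wsum) / area)
}

#' Steady-state diffusion-approximation reflectance (semi-infinite medium)
#'
#' Two-source (dipole) diffusion model for the radially resolved diffuse
#' reflectance of a semi-infinite turbid medium with a matched boundary.
#'
#' @param rho source-detector separation, metres.
#' @param mu_s_prime,mu_a optical properties, 1/m.
#' @param A internal-reflection parameter (1 for a matched boundary).
#' @return reflectance per unit area at each `rho`.
#' @export
diffusion_reflectance <- function(rho, mu_s_prime, mu_a, A = 1) {
  mu_t <- mu_s_prime + mu_a
  D <- 1 / (3 * mu_t)
  mu_eff <- sqrt(3 * mu_a * mu_t)
  z0 <- 1 / mu_t
  zb <- 2 * A * D
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
     (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2) / (4 * pi)
}

#' Estimate optical properties from a measured radial DRP
#'
#' Nonlinear least squares of the radial profile against the semi-infinite
#' diffusion-approximation reflectance model, fitted on a log scale with a
#' free amplitude.
#'
#' @param drp a `dr_profile` from [compute_drp()], or any list with
#'   `radial_bins_m` and `mean_intensity`.
#' @param min_bins minimum usable radial bins required beyond the first.
#' @return list with `mu_s_prime`, `mu_a` (1/m), `amplitude`, `residual`
#'   (RMS log residual) and `convergence`.
#' @export
estimate_optical_properties <- function(drp, min_bins = 10L) {
  rho <- drp$radial_bins_m
  y <- drp$mean_intensity
  ok <- is.finite(y) & y > 0 & rho > 0
  if (sum(ok) < min_bins)
    stop_sr("DRP has fewer than ", min_bins, " usable radial bins")
  rho <- rho[ok]; y <- y[ok]
  if (stats::sd(log(y)) < 1e-6) stop_sr("flat DRP: no decay to fit")
  obj <- function(p) {
    m <- diffusion_reflectance(rho, exp(p[1L]), exp(p[2L]))
    r <- log(y) - (p[3L] + log(m))
    sum(r^2)
  }
  init <- c(log(1 / stats::median(rho)), log(10),
            log(y[1L] / diffusion_reflectance(rho[1L], 1 / stats::median(rho), 10)))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop_sr("optical-property fit did not converge (code ", fit$convergence, ")")
  mu_s_prime <- exp(fit$par[1L]); mu_a <- exp(fit$par[2L])
  if (mu_s_prime > 1e7 || mu_s_prime < 1e-2 || mu_a > 1e6)
    stop_sr("optical-property fit ran to a parameter bound: mu_s' = ",
            signif(mu_s_prime, 3), ", mu_a = ", signif(mu_a, 3))
  list(mu_s_prime = mu_s_prime, mu_a = mu_a,
       amplitude = exp(fit$par[3L]),
       residual = sqrt(fit$value / length(y)), convergence = fit$convergence)
}
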