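#' Speckle time series container
#'
#' Holds raw speckle intensity frames together with the acquisition metadata
#' needed downstream: frame rate (sets the upper frequency bound
#' `omega < F_s`), duration (lower bound `omega > 1/tau`), exposure,
#' wavelength, pixel pitch and bit depth.
#'
#' @param frames integer (or integer-valued) array, height x width x n_frames;
#'   photon-count-proportional intensities.
#' @param frame_rate frames per second (F_s > 0).
#' @param exposure exposure time per frame, seconds; must be <= 1/frame_rate.
#' @param wavelength illumination wavelength, metres.
#' @param pixel_pitch physical pixel size at the sample plane, metres.
#' @param bit_depth sensor bit depth; all intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @return an object of class `speckle_series`.
#' @export
speckle_series <- function(frames, frame_rate, exposure = 0.5 / frame_rate,
                           wavelength = 637e-9, pixel_pitch = 20e-6,
                           bit_depth = 16L) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L)
    stop_sr("frames must be a height x width x n_frames array")
  if (d[3L] < 2L) stop_sr("a speckle series needs at least 2 frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop_sr("frame_rate must be a positive scalar")
  if (exposure > 1 / frame_rate + 1e-12)
    stop_sr("exposure must not exceed the frame period 1/frame_rate")
  rng <- range(frames)
  if (rng[1L] < 0) stop_sr("negative intensities are not allowed")
  if (rng[2L] > 2^bit_depth - 1)
    stop_sr("intensities exceed the stated bit depth (", bit_depth, " bits)")
  structure(list(frames = frames, frame_rate = frame_rate,
                 n_frames = d[3L], duration = d[3L] / frame_rate,
                 exposure = exposure, wavelength = wavelength,
                 pixel_pitch = pixel_pitch, bit_depth = as.integer(bit_depth)),
            class = "speckle_series")
}

#' @export
print.speckle_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "speckle_series: %d x %d px, %d frames @ %.6g fps (%.4g s), %d-bit\n",
    d[1L], d[2L], d[3L], x$frame_rate, x$duration, x$bit_depth))
  invisible(x)
}

#' Sample configuration
#'
#' Optical/thermodynamic description of the sample used for the inversion:
#' refractive index (sets the in-medium wavenumber `k = 2*pi*n/lambda`),
#' temperature and scattering particle radius (GSER prefactor), and either
#' measured optical properties (for the Monte Carlo lookup of gamma/zeta) or a
#' direct `(gamma, zeta)` override.
#'
#' @param refractive_index sample refractive index, >= 1.
#' @param temperature kelvin.
#' @param particle_radius scattering particle radius, metres. The radius only
#'   scales the absolute moduli; it does not change their frequency dependence.
#' @param mu_s_prime reduced scattering coefficient, 1/m (optional).
#' @param mu_a absorption coefficient, 1/m (optional).
#' @param g scattering anisotropy in `[0, 1)` (optional).
#' @param gamma,zeta optional direct override of the inversion constants.
#' @return an object of class `sample_config`.
#' @export
sample_config <- function(refractive_index = 1.33, temperature = 295,
                          particle_radius = 1.5e-6, mu_s_prime = NULL,
                          mu_a = NULL, g = NULL, gamma = NULL, zeta = NULL) {
  if (refractive_index < 1) stop_sr("refractive_index must be >= 1")
  if (temperature <= 0) stop_sr("temperature must be positive (kelvin)")
  if (particle_radius <= 0) stop_sr("particle_radius must be positive")
  if (!is.null(mu_s_prime) && mu_s_prime <= 0) stop_sr("mu_s_prime must be > 0")
  if (!is.null(g) && (g < 0 || g >= 1)) stop_sr("anisotropy g must be in [0, 1)")
  structure(list(refractive_index = refractive_index,
                 temperature = temperature, particle_radius = particle_radius,
                 mu_s_prime = mu_s_prime, mu_a = mu_a, g = g,
                 gamma = gamma, zeta = zeta),
            class = "sample_config")
}

.meta_fields <- c("frame_rate", "exposure", "wavelength", "pixel_pitch",
                  "bit_depth")

#' Read a speckle time series from disk
#'
#' Reads a multi-page grayscale TIFF stack or a raw binary dump, with
#' acquisition metadata supplied by a YAML sidecar file (deterministic parsing;
#' camera TIFF tag conventions vary too much to be trusted). Raw binary is
#' unsigned little-endian (1 byte for bit depths <= 8, otherwise 2 bytes),
#' frame-major, and the sidecar must carry `height`, `width` and `n_frames`.
#'
#' @param path path to the `.tif`/`.tiff` stack or `.raw`/`.bin` file.
#' @param metadata_path path to the YAML sidecar. Required keys: `frame_rate`,
#'   `exposure`, `wavelength`, `pixel_pitch`, `bit_depth` (+ geometry for raw).
#' @return a [speckle_series()].
#' @export
read_speckle_series <- function(path, metadata_path) {
  if (!file.exists(path)) stop_sr("no such file: ", path)
  if (!file.exists(metadata_path)) stop_sr("no such metadata file: ", metadata_path)
  meta <- yaml::read_yaml(metadata_path)
  missing <- setdiff(.meta_fields, names(meta))
  if (length(missing))
    stop_sr("metadata is missing required field(s): ",
            paste(missing, collapse = ", "))
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) {
    frames <- read_tiff_stack(path)
  } else {
    for (f in c("height", "width", "n_frames"))
      if (is.null(meta[[f]]))
        stop_sr("metadata is missing required field(s): ", f)
    bpp <- if (meta$bit_depth <= 8L) 1L else 2L
    expect_bytes <- meta$height * meta$width * meta$n_frames * bpp
    have <- file.info(path)$size
    if (have != expect_bytes)
      stop_sr("frame-count mismatch: metadata declares ", meta$n_frames,
              " frames (", expect_bytes, " bytes) but file holds ", have,
              " bytes")
    vals <- readBin(path, "integer", n = meta$height * meta$width * meta$n_frames,
                    size = bpp, signed = FALSE, endian = "little")
    frames <- array(vals, dim = c(meta$height, meta$width, meta$n_frames))
  }
  if (!is.null(meta$n_frames) && dim(frames)[3L] != meta$n_frames)
    stop_sr("frame-count mismatch: metadata declares ", meta$n_frames,
            " frames but ", dim(frames)[3L], " frames are on disk")
  speckle_series(frames, frame_rate = meta$frame_rate, exposure = meta$exposure,
                 wavelength = meta$wavelength, pixel_pitch = meta$pixel_pitch,
                 bit_depth = meta$bit_depth)
}

#' Write a speckle series (TIFF or raw binary) plus YAML sidecar
#'
#' @param series a [speckle_series()].
#' @param path output movie path (`.tif`/`.tiff` or `.raw`/`.bin`).
#' @param metadata_path output sidecar path; defaults to `<path>.yaml`.
#' @return invisibly, `path`.
#' @export
write_speckle_series <- function(series, path,
                                 metadata_path = paste0(path, ".yaml")) {
  stopifnot(inherits(series, "speckle_series"))
  d <- dim(series$frames)
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  fr <- series$frames
  storage.mode(fr) <- "integer"
  if (is_tiff) {
    write_tiff_stack(fr, path,
                     storage_bits = if (series$bit_depth <= 8L) 8L else 16L)
  } else {
    bpp <- if (series$bit_depth <= 8L) 1L else 2L
    con <- file(path, "wb")
    writeBin(as.vector(fr), con, size = bpp, endian = "little")
    close(con)
  }
  meta <- list(frame_rate = series$frame_rate, exposure = series$exposure,
               wavelength = series$wavelength, pixel_pitch = series$pixel_pitch,
               bit_depth = series$bit_depth, height = d[1L], width = d[2L],
               n_frames = d[3L])
  yaml::write_yaml(meta, metadata_path)
  invisible(path)
}

#' Persist a reconstructed spectrum and its fingerprint parameter table
#'
#' Writes `spectrum.csv` (omega_rad_s, G_storage_Pa, G_loss_Pa, G_mag_Pa,
#' alpha, valid) and `params.csv` (parameter, regime, value, spread, units,
#' fit_lo, fit_hi, spread_method) into `path`. All values are SI; nothing is
#' rescaled on output.
#'
#' @param spectrum a `visco_spectrum` (see [gser()]).
#' @param params a `spectro_params` object (see [extract_spectro_params()]),
#'   or NULL to write the spectrum only.
#' @param path output directory (created if needed).
#' @param spread optional named numeric vector of spreads (same names as the
#'   parameter table rows) when aggregating repeat measurements.
#' @param spread_method character note recording how `spread` was computed
#'   (e.g. "sd over N=9 repeats"); stored verbatim in the table because the
#'   aggregation convention must be explicit, never guessed.
#' @return invisibly, the directory path.
#' @export
write_results <- function(spectrum, params, path, spread = NULL,
                          spread_method = "none (single measurement)") {
  if (is.null(spectrum) || length(spectrum$omega) == 0L)
    stop_sr("refusing to write an empty spectrum")
  if (!all(is.finite(spectrum$omega)))
    stop_sr("spectrum contains non-finite frequencies")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sp <- data.frame(omega_rad_s = spectrum$omega,
                   G_storage_Pa = spectrum$G_storage,
                   G_loss_Pa = spectrum$G_loss,
                   G_mag_Pa = spectrum$G_mag,
                   alpha = spectrum$alpha,
                   valid = spectrum$valid)
  utils::write.csv(sp, file.path(path, "spectrum.csv"), row.names = FALSE)
  if (!is.null(params)) {
    tab <- spectro_params_table(params)
    tab$spread <- if (!is.null(spread)) {
      unname(spread[make.unique(paste0(tab$parameter, "_", tab$regime))])
    } else NA_real_
    tab$spread_method <- spread_method
    utils::write.csv(tab, file.path(path, "params.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read back a spectrum written by [write_results()]
#' @param path run directory.
#' @return a `visco_spectrum`.
#' @export
read_spectrum <- function(path) {
  sp <- utils::read.csv(file.path(path, "spectrum.csv"))
  new_visco_spectrum(sp$omega_rad_s, sp$G_storage_Pa, sp$G_loss_Pa,
                     sp$G_mag_Pa, sp$alpha, sp$valid)
}

#' Resumable run bundle
#'
#' Persists every intermediate product of a pipeline run (g2, MSD, alpha,
#' spectrum, parameter table, configuration) into one directory with a JSON
#' manifest, so a failed stage can be resumed without re-correlating a long
#' movie. Plain-text substitute for a hierarchical container file.
#'
#' @param results named list as returned by [process_speckle()].
#' @param path bundle directory.
#' @return invisibly, `path`.
#' @export
save_run_bundle <- function(results, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  if (!is.null(results$g2)) {
    utils::write.csv(data.frame(lag_s = results$g2$lags, g2 = results$g2$g2,
                                n_pairs = results$g2$n_pairs),
                     file.path(path, "g2.csv"), row.names = FALSE)
    stages <- c(stages, "g2")
  }
  if (!is.null(results$msd)) {
    utils::write.csv(data.frame(t_s = results$msd$times, msd_m2 = results$msd$msd,
                                valid = results$msd$valid),
                     file.path(path, "msd.csv"), row.names = FALSE)
    stages <- c(stages, "msd")
  }
  if (!is.null(results$alpha)) {
    utils::write.csv(data.frame(omega_rad_s = results$alpha$omega,
                                alpha = results$alpha$alpha,
                                alpha_raw = results$alpha$alpha_raw,
                                msd_m2 = results$alpha$msd),
                     file.path(path, "alpha.csv"), row.names = FALSE)
    stages <- c(stages, "alpha")
  }
  if (!is.null(results$spectrum)) {
    write_results(results$spectrum, results$params, path)
    stages <- c(stages, "spectrum",
                if (!is.null(results$params)) "params")
  }
  manifest <- list(package = "specklerheo",
                   version = as.character(utils::packageVersion("specklerheo")),
                   stages = as.list(stages),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(.to_json(manifest), file.path(path, "manifest.json"))
  invisible(path)
}

# minimal JSON writer for the manifest (avoids a hard jsonlite dependency)
.to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.list(x) && !is.null(names(x)))
    return(paste0("{", paste0('"', names(x), '": ',
                              vapply(x, .to_json, ""), collapse = ", "), "}"))
  if (is.list(x))
    return(paste0("[", paste0(vapply(x, .to_json, ""), collapse = ", "), "]"))
  if (is.character(x)) return(paste0('"', esc(x), '"'))
  as.character(x)
}
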