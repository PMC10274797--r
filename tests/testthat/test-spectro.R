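test_that("alpha = 0.5 crossings interpolate in log-omega with direction tags", {
  omega <- 10^seq(0, 3.9, by = 0.1)       # even count: no exact-0.5 grid value
  a <- seq(0.6, 0.4, length.out = length(omega))
  ac <- structure(list(omega = omega, alpha = a, points_per_decade = 10L),
                  class = "alpha_curve")
  tr <- find_transitions(ac)
  expect_equal(nrow(tr), 1L)
  expect_identical(tr$direction, "fluid_to_solid")
  # adjacent grid values 0.6 / 0.4 -> crossing at the log-midpoint
  i <- max(which(a > 0.5)); expect_equal(a[i], min(a[a > 0.5]))
  expect_equal(log10(tr$omega_T),
               (log10(omega[i]) + log10(omega[i + 1L])) / 2, tolerance = 1e-9)
  # all above 0.5 -> empty
  ac2 <- ac; ac2$alpha <- a + 0.3
  expect_equal(nrow(find_transitions(ac2)), 0L)
})

test_that("Maxwell crossover: single fluid->solid omega_T at 1/tau_r", {
  tau <- 0.05
  tt <- 10^seq(-4, 1.5, by = 0.02)
  m <- msd_from_model(rheo_maxwell(40, tau), tt)
  a <- compute_alpha(m)
  tr <- find_transitions(a)
  expect_equal(nrow(tr), 1L)
  expect_identical(tr$direction, "fluid_to_solid")
  expect_rel(tr$omega_T, 1 / tau, 0.10)
})

test_that("plateau detection: planted minimum found, monotone alpha empty", {
  px <- planted_fibrin_spectrum()
  pl <- find_plateaus(px$spectrum, px$alpha)
  expect_equal(nrow(pl), 1L)
  expect_rel(pl$omega0, px$truth$omega0, 0.15)
  expect_rel(pl$G0, px$truth$G0, 0.15)
  mono <- px$alpha
  mono$alpha <- seq(0.2, 0.9, length.out = length(mono$omega))
  expect_equal(nrow(find_plateaus(px$spectrum, mono)), 0L)
})

test_that("power-law fits: exact segments and the 0.4 -> 1.2 pair", {
  omega <- 10^seq(1, 5, by = 1 / 30)
  mk <- function(gl) structure(list(
    omega = omega, G_loss = gl, G_mag = gl, G_storage = gl * 0.3,
    alpha = rep(0.5, length(omega)), valid = rep(TRUE, length(omega))),
    class = "visco_spectrum")
  # exact power law: slope recovered with zero standard error
  f <- fit_power_laws(mk(2 * omega^0.4), list(c(1e2, 1e4)))
  expect_equal(f$gamma, 0.4, tolerance = 1e-10)
  expect_lt(f$gamma_se, 1e-10)
  # Newtonian: gamma = 1 within 1e-6
  f1 <- fit_power_laws(mk(1e-3 * omega), list(c(1e2, 1e4)))
  expect_equal(f1$gamma, 1, tolerance = 1e-6)
  # two segments breaking at 1.7e4 mirrored by per-segment fits
  br <- 1.7e4
  gl <- ifelse(omega <= br, 2 * (omega / br)^0.4, 2 * (omega / br)^1.2)
  f2 <- fit_power_laws(mk(gl), list(c(1e2, br * 0.9), c(br * 1.1, 1e5)))
  expect_lt(abs(f2$gamma[1L] - 0.4), 0.05)
  expect_lt(abs(f2$gamma[2L] - 1.2), 0.05)
  # non-positive moduli rejected
  bad <- mk(2 * omega^0.4); bad$G_loss[5] <- 0
  expect_error(fit_power_laws(bad, list(c(1e1, 1e3))), "non-positive")
})

test_that("scaling transition: planted break found, pure law absent,
           three-exponent interval reports multiplicity 2", {
  omega <- 10^seq(2, 6, by = 1 / 30)
  mk <- function(gl) structure(list(
    omega = omega, G_loss = gl, G_mag = gl, G_storage = gl,
    alpha = rep(0.5, length(omega)), valid = rep(TRUE, length(omega))),
    class = "visco_spectrum")
  lse <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))
  # two-exponent break at 1.7e4 rad/s
  br <- 1.7e4
  gl <- exp(lse(0.4 * log(omega / br), 1.2 * log(omega / br)))
  st <- find_scaling_transition(mk(gl), c(1e3, 1e6))
  expect_equal(st$multiplicity, 1L)
  expect_lt(abs(log(st$omega_gamma / br)), log(1.3))
  # exact single power law: absent
  st1 <- find_scaling_transition(mk(3 * omega^0.7), c(1e3, 1e6))
  expect_identical(st1$multiplicity, 0L)
  expect_true(is.na(st1$omega_gamma))
  # three exponents (0.2 -> 0.9 -> 0.3): two inflections, absent
  # (soft-max joins a slope increase, soft-min a slope decrease)
  g3 <- exp(-lse(-lse(0.2 * log(omega / 1e4), 0.9 * log(omega / 1e4)),
                 -(0.3 * log(omega / 1e5) + 0.9 * log(1e5 / 1e4))))
  st3 <- find_scaling_transition(mk(g3), c(1e3, 1e6))
  expect_true(is.na(st3$omega_gamma))
  expect_gte(st3$multiplicity, 2L)
})

test_that("fibrin-like planted spectrum: parameters and labels I, II, IIIa, IIIb", {
  px <- planted_fibrin_spectrum()
  params <- extract_spectro_params(px$spectrum, px$alpha)
  tr <- params$transitions
  expect_equal(nrow(tr), 1L)
  expect_rel(tr$omega_T, px$truth$omega_T, 0.15)
  expect_equal(nrow(params$plateaus), 1L)
  expect_rel(params$plateaus$G0, px$truth$G0, 0.15)
  expect_rel(params$plateaus$omega0, px$truth$omega0, 0.15)
  expect_identical(params$regimes$label, c("I", "II", "IIIa", "IIIb"))
  expect_equal(length(params$scaling_transitions), 1L)
  expect_lt(abs(log(params$scaling_transitions / px$truth$omega_gamma)),
            log(1.3))
  pw <- params$power_laws
  expect_lt(abs(pw$gamma[pw$label == "IIIa"] - px$truth$gamma_a), 0.15 * 1)
  expect_lt(abs(pw$gamma[pw$label == "IIIb"] - px$truth$gamma_b),
            0.15 * px$truth$gamma_b)
})

test_that("featureless and two-plateau spectra are labelled deterministically", {
  omega <- 10^seq(1, 4, by = 1 / 30)
  gl <- 2 * omega^0.6
  sp <- structure(list(omega = omega, G_loss = gl, G_mag = gl,
                       G_storage = gl * 0.4, alpha = rep(0.7, length(omega)),
                       valid = rep(TRUE, length(omega))),
                  class = "visco_spectrum")
  ac <- structure(list(omega = omega, alpha = rep(0.7, length(omega)),
                       alpha_raw = rep(0.7, length(omega)),
                       msd = rep(1e-13, length(omega)),
                       edge = rep(FALSE, length(omega)),
                       points_per_decade = 30L), class = "alpha_curve")
  p <- extract_spectro_params(sp, ac)
  expect_identical(p$regimes$label, "I")
  # two plateaus + two scaling intervals -> I..V
  p2 <- planted_two_plateau_params()$params
  expect_identical(p2$regimes$label, c("I", "II", "III", "IV", "V"))
  expect_identical(p2$regimes$kind[c(2, 4)], c("plateau", "plateau"))
})

test_that("extraction is invariant to rescaling moduli except G0", {
  px <- planted_fibrin_spectrum()
  p1 <- extract_spectro_params(px$spectrum, px$alpha)
  sp2 <- px$spectrum
  for (f in c("G_storage", "G_loss", "G_mag")) sp2[[f]] <- sp2[[f]] * 37
  p2 <- extract_spectro_params(sp2, px$alpha)
  expect_equal(p2$transitions$omega_T, p1$transitions$omega_T)
  expect_equal(p2$plateaus$omega0, p1$plateaus$omega0)
  expect_equal(p2$plateaus$G0, 37 * p1$plateaus$G0)
  expect_equal(p2$power_laws$gamma, p1$power_laws$gamma, tolerance = 1e-10)
})

test_that("omega-type parameters are stable under grid refinement", {
  px30 <- planted_fibrin_spectrum(30L)
  px60 <- planted_fibrin_spectrum(60L)
  p30 <- extract_spectro_params(px30$spectrum, px30$alpha)
  p60 <- extract_spectro_params(px60$spectrum, px60$alpha)
  step30 <- 10^(1 / 30)
  expect_lt(abs(log(p60$transitions$omega_T / p30$transitions$omega_T)),
            log(step30))
  expect_lt(abs(log(p60$plateaus$omega0 / p30$plateaus$omega0)), log(step30))
})

test_that("100 random planted spectra: median parameter error <= 15%", {
  set.seed(31)
  errs <- list(omega_T = c(), omega0 = c(), G0 = c(), gam = c())
  n_ok <- 0L
  for (rep in seq_len(100L)) {
    wT <- 10^runif(1, 0.5, 1.5)
    w0 <- wT * 10^runif(1, 0.8, 1.4)
    G0 <- 10^runif(1, 1.5, 3.5)
    gma <- runif(1, 0.2, 0.6)
    omega <- 10^seq(log10(wT) - 2, log10(w0) + 3, by = 1 / 30)
    x <- omega / wT
    Gp <- G0 * x^2 / (1 + x^2)
    g_a <- (G0 * wT / w0) / gma
    Gpp <- G0 * x / (1 + x^2) + g_a * (omega / w0)^gma
    # ground truth from the noise-free composite (the loss branch shifts the
    # crossing and minimum away from the bare-Maxwell values)
    al0 <- (2 / pi) * atan2(Gpp, Gp)
    cr <- which(diff(sign(al0 - 0.5)) < 0)[1L]
    f <- (al0[cr] - 0.5) / (al0[cr] - al0[cr + 1L])
    wT_true <- 10^(log10(omega[cr]) + f * (log10(omega[cr + 1L]) -
                                             log10(omega[cr])))
    i_min <- which.min(al0)
    w0_true <- omega[i_min]
    G0_true <- Gp[i_min]
    Gpp_n <- Gpp * exp(rnorm(length(omega), sd = 0.05))
    Gp_n <- Gp * exp(rnorm(length(omega), sd = 0.05))
    al <- pmin(1, pmax(0, (2 / pi) * atan2(Gpp_n, Gp_n)))
    # smooth alpha like the pipeline does before extraction
    al <- specklerheo:::moving_average(al, 15L)
    Gm <- sqrt(Gp_n^2 + Gpp_n^2)
    sp <- structure(list(omega = omega, G_storage = Gp_n, G_loss = Gpp_n,
                         G_mag = Gm, alpha = al,
                         valid = rep(TRUE, length(omega))),
                    class = "visco_spectrum")
    ac <- structure(list(omega = omega, alpha = al, alpha_raw = al,
                         msd = rep(1e-13, length(omega)),
                         edge = rep(FALSE, length(omega)),
                         points_per_decade = 30L), class = "alpha_curve")
    p <- extract_spectro_params(sp, ac)
    if (nrow(p$transitions) < 1L || nrow(p$plateaus) < 1L) next
    n_ok <- n_ok + 1L
    errs$omega_T <- c(errs$omega_T,
                      abs(p$transitions$omega_T[1L] - wT_true) / wT_true)
    i0 <- which.min(abs(log(p$plateaus$omega0 / w0_true)))
    errs$omega0 <- c(errs$omega0,
                     abs(p$plateaus$omega0[i0] - w0_true) / w0_true)
    errs$G0 <- c(errs$G0, abs(p$plateaus$G0[i0] - G0_true) / G0_true)
    if (!is.null(p$power_laws)) {
      sc <- p$power_laws[which.max(p$power_laws$omega_hi), ]
      errs$gam <- c(errs$gam, abs(sc$gamma - gma) / gma)
    }
  }
  expect_gt(n_ok, 85L)
  for (nm in names(errs))
    expect_lt(stats::median(errs[[nm]]), 0.15)
})
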