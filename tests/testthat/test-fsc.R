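# FSC reduction: sample mass, peak detection, zero-rate extrapolation,
# molar fusion enthalpy, entropy.

cp_flat <- function(T) rep(1, length(T))

test_that("sample mass is the heat-capacity ratio, with a mass-loss guard", {
  TT <- seq(303, 473, by = 1)
  hc <- data.frame(T_K = TT, Cp_J_per_K = rep(100e-9, length(TT)))
  out <- determine_sample_mass(hc, hc, cp_flat)
  expect_equal(out$mass_g, 100e-9, tolerance = 1e-12)
  expect_equal(out$u_mass_g, 0.11 * 100e-9, tolerance = 1e-12)

  # planted 80 ng with 2% noise recovers within 5%
  cp_ref <- function(T) 1.3 + 0.002 * (T - 300)
  cur <- simulate_cp_curves(80e-9, cp_ref, noise = 0.02, seed = 12)
  out <- determine_sample_mass(cur$heating, cur$cooling, cp_ref)
  expect_lt(abs(out$mass_g / 80e-9 - 1), 0.05)

  # 20% heating/cooling disagreement triggers the mass-loss error
  bad <- simulate_cp_curves(80e-9, cp_ref, noise = 0, mass_loss = 0.2,
                            seed = 12)
  expect_error(determine_sample_mass(bad$heating, bad$cooling, cp_ref),
               "mass loss")
})

make_triangle_scan <- function(T_on = 590, T_pk = 595, T_end = 600,
                               height = 1e-3, beta = 2000,
                               baseline = 0, slope = 0, scale = 1,
                               second_peak_at = NULL) {
  TT <- seq(520, 660, by = 0.2)
  y <- ifelse(TT >= T_on & TT <= T_pk, height * (TT - T_on) / (T_pk - T_on),
              ifelse(TT > T_pk & TT <= T_end,
                     height * (T_end - TT) / (T_end - T_pk), 0))
  if (!is.null(second_peak_at)) {
    y <- y + ifelse(abs(TT - second_peak_at) < 4,
                    0.8 * height * (1 - abs(TT - second_peak_at) / 4), 0)
  }
  y <- scale * (y + baseline + slope * (TT - TT[1]))
  thermogram("tri", beta, time_s = (TT - TT[1]) / beta, T_K = TT, hf_W = y)
}

test_that("a triangular peak yields the exact onset and area", {
  tg <- make_triangle_scan()
  pk <- detect_melting_peak(tg)
  expect_lt(abs(pk$T_onset - 590), 0.02)
  area_true <- 0.5 * (600 - 590) * 1e-3 / 2000   # J, time-domain integral
  expect_lt(abs(pk$dH_J / area_true - 1), 0.005)

  # invariant to a constant baseline offset
  pk_off <- detect_melting_peak(make_triangle_scan(baseline = 5e-4))
  expect_equal(pk_off$T_onset, pk$T_onset, tolerance = 1e-6)
  expect_equal(pk_off$dH_J, pk$dH_J, tolerance = 1e-9)

  # invariant to a sloped baseline
  pk_slope <- detect_melting_peak(make_triangle_scan(slope = 2e-6))
  expect_lt(abs(pk_slope$T_onset - 590), 0.05)
  expect_lt(abs(pk_slope$dH_J / area_true - 1), 0.01)

  # uniform unit rescaling rescales the area and keeps the onset
  pk_scale <- detect_melting_peak(make_triangle_scan(scale = 1000))
  expect_equal(pk_scale$T_onset, pk$T_onset, tolerance = 1e-9)
  expect_equal(pk_scale$dH_J, 1000 * pk$dH_J, tolerance = 1e-9)
})

test_that("flat baselines and double peaks are rejected", {
  TT <- seq(520, 660, by = 0.2)
  flat <- thermogram("flat", 2000, (TT - 520) / 2000, TT,
                     rep(1e-4, length(TT)))
  expect_error(detect_melting_peak(flat), "no melting peak")

  expect_error(detect_melting_peak(make_triangle_scan(second_peak_at = 630)),
               "ambiguous")
})

test_that("synthetic scans of either peak shape reduce to the planted truth", {
  for (sh in c("linexp", "gaussexp")) {
    pr <- scan_protocol(rates = 3000, scans_per_rate = 1, noise = 0,
                        lag_slope = 0, onset_jitter = 0,
                        mass_uncertainty = 0, T_fus = 600,
                        dh_specific = 250, shape = sh, seed = 7)
    scans <- simulate_thermogram_set(pr)
    truth <- attr(scans, "truth")
    pk <- detect_melting_peak(scans[[1]])
    expect_lt(abs(pk$T_onset - truth$T_onset_true), 0.1)
    expect_lt(abs(pk$dH_J / truth$dH_true_J - 1), 0.005)
    expect_lt(pk$T_onset, pk$T_peak)
  }
})

test_that("zero-rate extrapolation recovers intercepts with honest coverage", {
  # degenerate fit: identical onsets at every rate
  df <- data.frame(beta = rep(c(1000, 4000, 10000), each = 3), T_onset = 608)
  zr <- extrapolate_zero_rate(df)
  expect_equal(zr$T_fus, 608, tolerance = 1e-10)
  expect_equal(zr$slope, 0, tolerance = 1e-12)

  expect_error(extrapolate_zero_rate(data.frame(beta = c(1000, 1000, 2000),
                                                T_onset = c(1, 2, 3))),
               "3 distinct")

  # Monte-Carlo coverage of the intercept's confidence statement
  set.seed(31)
  rates <- rep(seq(1000, 10000, length.out = 8), each = 5)
  hits <- vapply(1:100, function(rep) {
    T_on <- 600 + 5e-4 * rates + rnorm(length(rates), 0, 3)
    zr <- extrapolate_zero_rate(data.frame(beta = rates, T_onset = T_on),
                                u_calibration = 0)
    abs(zr$T_fus - 600) <= zr$u_T_fus
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("molar fusion enthalpy comes from the through-origin mass fit", {
  masses <- c(40e-9, 70e-9, 100e-9)
  df <- data.frame(mass_g = masses, dH_J = 250 * masses)
  en <- molar_fusion_enthalpy(df, molar_mass = 89.1)
  expect_equal(en$dH_fus, 22.275e3, tolerance = 1e-12)
  expect_equal(en$dh_specific, 250, tolerance = 1e-12)
  # residual-free fit: uncertainty is the 11% mass term alone (k = 2)
  expect_equal(en$u_dH_fus, 2 * 0.11 * 22.275e3, tolerance = 1e-9)

  # scattered synthetic data: slope recovered within 2 standard errors
  set.seed(8)
  m50 <- runif(50, 30e-9, 110e-9)
  dh50 <- 280 * m50 * (1 + rnorm(50, 0, 0.10))
  en50 <- molar_fusion_enthalpy(data.frame(mass_g = m50, dH_J = dh50),
                                molar_mass = 75.1)
  expect_lt(abs(en50$dh_specific - 280), 2 * en50$se_slope)
  expect_lt(abs(en50$dh_specific - 280) / 280, 0.1)

  expect_error(molar_fusion_enthalpy(
    data.frame(mass_g = rep(5e-8, 4), dH_J = rep(1e-5, 4)), 89.1),
    "ill-conditioned")
})

test_that("entropy of fusion reproduces the published rounding", {
  s_ala <- fusion_entropy(22e3, 608, 5e3, 9)
  expect_identical(round(s_ala$dS_fus / 1000, 3), 0.036)
  s_gly <- fusion_entropy(21e3, 569, 4e3, 7)
  expect_identical(round(s_gly$dS_fus / 1000, 3), 0.037)
  expect_identical(fusion_entropy(0, 600)$dS_fus, 0)
  expect_error(fusion_entropy(1, -1), "T_fus > 0")
  # propagated uncertainty matches the first-order formula
  expect_equal(s_ala$u_dS_fus,
               (22e3 / 608) * sqrt((5 / 22)^2 + (9 / 608)^2),
               tolerance = 1e-12)
})

test_that("the full reduction pipeline recovers a planted scan set", {
  pr <- scan_protocol(T_fus = 569, dh_specific = 280, seed = 99)
  scans <- simulate_thermogram_set(pr)
  red <- reduce_fsc(scans, molar_mass = 75.1, substance = "glycine")
  expect_lt(abs(red$melting$T_fus - 569), red$melting$u_T_fus)
  expect_lt(abs(red$melting$dH_fus - 280 * 75.1), red$melting$u_dH_fus)
  expect_equal(red$melting$dS_fus,
               red$melting$dH_fus / red$melting$T_fus, tolerance = 1e-12)
})
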