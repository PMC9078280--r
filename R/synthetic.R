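# Seeded generators for every input the pipeline consumes: FSC thermogram
# sets with planted melting properties, osmotic-coefficient tables with a
# planted binary interaction parameter, and solubility tables. All output is
# a pure function of the seed and the settings.

#' Scan protocol for a synthetic FSC measurement campaign
#'
#' The defaults emulate the measurement design of the study conditions: 45
#' heating scans at rates spread over 1000-10000 K/s, sub-100-ng samples,
#' a thermal-lag onset shift of a few kelvin across the rate range, onset
#' scatter of a few kelvin, and an 11% sample-mass uncertainty.
#'
#' @param rates heating rates in K/s.
#' @param scans_per_rate scans per rate.
#' @param mass_range sample-mass range in g (drawn uniformly).
#' @param T_fus planted melting temperature (zero-rate onset) in K.
#' @param dh_specific planted specific fusion enthalpy in J/g.
#' @param lag_slope apparent-onset shift per unit heating rate, K/(K/s).
#' @param noise relative additive noise (fraction of peak height).
#' @param onset_jitter per-scan onset scatter (K, 1 sd).
#' @param mass_uncertainty relative error of the reported (estimated) sample
#'   mass; the true mass sets the peak area.
#' @param shape leading-edge shape: `"linexp"` (linear edge, exponential
#'   tail) or `"gaussexp"` (Gaussian edge calibrated so the tangent onset is
#'   the planted onset, exponential tail).
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return a `scan_protocol` object.
#' @export
scan_protocol <- function(rates = seq(1000, 10000, length.out = 9),
                          scans_per_rate = 5,
                          mass_range = c(4e-8, 1e-7),
                          T_fus = 608, dh_specific = 250,
                          lag_slope = 5e-4, noise = 0.02,
                          onset_jitter = 3, mass_uncertainty = 0.11,
                          shape = c("linexp", "gaussexp"), seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(all(rates > 0), scans_per_rate >= 1, all(mass_range > 0),
            T_fus > 0, dh_specific > 0, lag_slope >= 0, noise >= 0,
            onset_jitter >= 0, mass_uncertainty >= 0)
  out <- list(rates = rates, scans_per_rate = scans_per_rate,
              mass_range = mass_range, T_fus = T_fus,
              dh_specific = dh_specific, lag_slope = lag_slope,
              noise = noise, onset_jitter = onset_jitter,
              mass_uncertainty = mass_uncertainty, shape = shape,
              seed = as.integer(seed))
  class(out) <- "scan_protocol"
  out
}

# One synthetic melting peak in temperature units (J/K), area normalised to
# 1. Both shapes are built so that the baseline/tangent onset construction
# recovers `T_on` exactly in the noise-free limit.
.peak_shape <- function(T, T_on, shape, rise = 4, tail = 2, sigma = 1.5) {
  if (shape == "linexp") {
    T_pk <- T_on + rise
    up <- (T - T_on) / rise
    y <- ifelse(T >= T_on & T <= T_pk, up,
                ifelse(T > T_pk, exp(-(T - T_pk) / tail), 0))
    area <- rise / 2 + tail
  } else {
    # Gaussian leading edge: tangent at the inflection point (Tc - sigma)
    # crosses zero at Tc - 2 sigma, so centre the peak at T_on + 2 sigma.
    Tc <- T_on + 2 * sigma
    y <- ifelse(T <= Tc, exp(-(T - Tc)^2 / (2 * sigma^2)),
                exp(-(T - Tc) / tail))
    area <- sigma * sqrt(2 * pi) / 2 + tail
  }
  y / area
}

#' Simulate a set of FSC heating scans
#'
#' Each scan has an apparent onset `T_fus + lag_slope * beta` (plus scatter),
#' a melting peak whose baseline-subtracted area equals `mass x dh_specific`,
#' a mildly sloped sensor baseline proportional to the heating rate, and
#' additive Gaussian noise. The reported `mass_ng` metadata carries the
#' estimated sample mass (true mass perturbed by `mass_uncertainty`), as a
#' mass determined from a heat-capacity calibration would be; the true
#' values are attached as attribute `"truth"`.
#'
#' @param protocol a [scan_protocol()].
#' @return list of [thermogram()]s with attribute `"truth"` (data frame of
#'   the planted per-scan values) and `"protocol"`.
#' @export
simulate_thermogram_set <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  pr <- protocol
  withr::with_seed(pr$seed, {
    design <- expand.grid(rep = seq_len(pr$scans_per_rate), beta = pr$rates)
    n <- nrow(design)
    truth <- data.frame(
      scan_id = sprintf("scan%03d", seq_len(n)),
      beta = design$beta,
      mass_g = stats::runif(n, pr$mass_range[1], pr$mass_range[2]),
      T_onset_true = pr$T_fus + pr$lag_slope * design$beta +
        stats::rnorm(n, 0, pr$onset_jitter)
    )
    truth$dH_true_J <- truth$mass_g * pr$dh_specific
    truth$mass_est_g <- truth$mass_g *
      (1 + stats::rnorm(n, 0, pr$mass_uncertainty))
    scans <- lapply(seq_len(n), function(i) {
      beta <- truth$beta[i]
      T_on <- truth$T_onset_true[i]
      # peak widens mildly with rate, as superheating smears the transition
      rise <- 3 + beta / 4000
      T0 <- 423
      T1 <- T_on + 45
      TT <- seq(T0, T1, by = 0.25)
      shape <- .peak_shape(TT, T_on, pr$shape, rise = rise)
      peak_W <- truth$dH_true_J[i] * shape * beta
      # sensor + sample baseline: C(T) in J/K times beta, with mild drift
      C0 <- truth$mass_g[i] * 1.35 + 2e-8
      C1 <- truth$mass_g[i] * 0.002
      base_W <- (C0 + C1 * (TT - T0)) * beta
      h <- max(peak_W)
      y <- base_W + peak_W + stats::rnorm(length(TT), 0, pr$noise * h)
      thermogram(truth$scan_id[i], beta, time_s = (TT - T0) / beta,
                 T_K = TT, hf_W = y,
                 meta = list(mass_ng = truth$mass_est_g[i] * 1e9,
                             stage = "melting", T_max = T1,
                             oil_coated = TRUE))
    })
    attr(scans, "truth") <- truth
    attr(scans, "protocol") <- pr
    scans
  })
}

#' Simulate heat-capacity curves for sample-mass determination
#'
#' Heating and cooling sample heat-capacity curves `C_p(T) = m0 c_p(T)` with
#' multiplicative noise, as produced by the mass-determination stage of an
#' FSC protocol.
#'
#' @param mass_g planted sample mass in g.
#' @param cp_reference specific heat capacity (function of T, J/g/K, or data
#'   frame with `T_K`, `cp_J_per_gK`).
#' @param T_range temperature range (K).
#' @param noise relative noise level.
#' @param mass_loss fractional mass lost between heating and cooling (0 for
#'   a reproducible sample).
#' @param seed integer seed.
#' @return list with `heating` and `cooling` data frames
#'   (`T_K`, `Cp_J_per_K`).
#' @export
simulate_cp_curves <- function(mass_g, cp_reference, T_range = c(303, 473),
                               noise = 0.02, mass_loss = 0, seed = 1L) {
  cp_fun <- if (is.function(cp_reference)) {
    cp_reference
  } else {
    stats::approxfun(cp_reference$T_K, cp_reference$cp_J_per_gK, rule = 2)
  }
  withr::with_seed(seed, {
    TT <- seq(T_range[1], T_range[2], by = 0.5)
    mk <- function(m) data.frame(
      T_K = TT,
      Cp_J_per_K = m * cp_fun(TT) * (1 + stats::rnorm(length(TT), 0, noise)))
    list(heating = mk(mass_g), cooling = mk(mass_g * (1 - mass_loss)))
  })
}

#' Simulate an osmotic-coefficient table with a planted k_ij
#'
#' Computes osmotic coefficients with the forward PC-SAFT model after
#' setting the solute-water `kij_ref` to the planted value, then applies
#' multiplicative Gaussian noise.
#'
#' @inheritParams activity_coefficient
#' @param kij_planted planted 298.15 K binary interaction parameter.
#' @param molalities molalities in mol/kg.
#' @param T temperature in K.
#' @param noise relative (multiplicative) noise level.
#' @param seed integer seed.
#' @return a data frame (`T_K`, `molality`, `value`, `sigma`) with attribute
#'   `"kij_planted"`.
#' @export
simulate_osmotic_table <- function(params, solute, kij_planted,
                                   molalities = seq(0.25, 3, by = 0.25),
                                   T = 298.15, noise = 0, seed = 1L,
                                   P = P_DEFAULT) {
  key <- .normalise_pair(c(solute, "water"))
  found <- FALSE
  for (k in seq_along(params$binary_interactions)) {
    if (identical(params$binary_interactions[[k]]$pair, key)) {
      params$binary_interactions[[k]]$kij_ref <- kij_planted
      found <- TRUE
    }
  }
  if (!found) {
    params$binary_interactions <- c(
      params$binary_interactions,
      list(list(pair = key, kij_ref = kij_planted, kij_slope = 0)))
  }
  phi <- osmotic_coefficient(params, solute, molalities, T, P)
  withr::with_seed(seed, {
    obs <- phi * (1 + stats::rnorm(length(phi), 0, noise))
    out <- data.frame(T_K = T, molality = molalities, value = obs,
                      sigma = noise * phi)
    attr(out, "kij_planted") <- kij_planted
    out
  })
}

#' Simulate a solubility table from melting properties
#'
#' Saturation molalities from [predict_solubility()] over a temperature
#' grid, with multiplicative noise at the level of typical experimental
#' solubility scatter.
#'
#' @inheritParams predict_solubility
#' @param temperatures temperatures in K (all below `melting$T_fus`).
#' @param noise relative noise level (default 0; experimental scatter is
#'   typically below 0.03).
#' @param seed integer seed.
#' @return a data frame (`T_K`, `molality`, `value`, `sigma`) where `value`
#'   is the noisy molality and `molality` the noise-free model value.
#' @export
simulate_solubility_table <- function(params, solute, melting, temperatures,
                                      noise = 0, seed = 1L, P = P_DEFAULT) {
  if (any(temperatures >= melting$T_fus)) {
    stop("all temperatures must be below T_fus")
  }
  m_model <- vapply(temperatures, function(T) {
    predict_solubility(params, solute, T, melting, P)$molality
  }, numeric(1))
  withr::with_seed(seed, {
    obs <- m_model * (1 + stats::rnorm(length(m_model), 0, noise))
    data.frame(T_K = temperatures, molality = m_model, value = obs,
               sigma = noise * m_model)
  })
}
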