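# Reduction of fast-scanning-calorimetry heating scans to melting
# temperature, molar enthalpy of fusion and entropy of fusion.
#
# Conventions: heat flow rate is in W, endothermic positive; a thermogram is
# a heating segment with strictly increasing temperature. The melting onset
# is the intersection of the extrapolated pre-peak baseline with the tangent
# at the leading-edge inflection point; the peak enthalpy is the integral of
# the baseline-subtracted heat flow rate over time.

#' Construct a thermogram
#'
#' @param scan_id identifier string.
#' @param beta heating rate in K/s (positive).
#' @param time_s,T_K,hf_W equal-length series: time (s), temperature (K,
#'   strictly increasing), heat flow rate (W, endothermic positive).
#' @param meta named list of free-form metadata (e.g. `mass_ng`, `stage`,
#'   `T_max`, `oil_coated`).
#' @return a `thermogram` object.
#' @export
thermogram <- function(scan_id, beta, time_s, T_K, hf_W, meta = list()) {
  if (beta <= 0) stop("heating rate beta must be positive")
  n <- length(time_s)
  if (length(T_K) != n || length(hf_W) != n) {
    stop("time_s, T_K, hf_W must have equal length")
  }
  if (any(diff(T_K) <= 0)) {
    stop("temperature must be strictly increasing on a heating segment")
  }
  out <- list(scan_id = as.character(scan_id), beta = beta,
              time_s = time_s, T_K = T_K, hf_W = hf_W, meta = meta)
  class(out) <- "thermogram"
  out
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("thermogram %s: beta = %g K/s, %d points, T %.1f..%.1f K\n",
              x$scan_id, x$beta, length(x$T_K), min(x$T_K), max(x$T_K)))
  invisible(x)
}

.runmean <- function(y, k) {
  if (k <= 1L) return(y)
  as.numeric(stats::filter(y, rep(1 / k, k), sides = 2)) -> ys
  # fill the filter's NA edges with the nearest smoothed value
  idx <- which(!is.na(ys))
  ys[seq_len(idx[1] - 1)] <- ys[idx[1]]
  ys[seq((idx[length(idx)] + 1), length.out = length(ys) - idx[length(idx)])] <-
    ys[idx[length(idx)]]
  ys
}

#' Determine sample mass from heat-capacity curves
#'
#' `m0 = mean(C_p(T) / c_p(T))` over an evaluation window, where `C_p` is the
#' measured sample heat capacity (J/K) and `c_p` the literature specific heat
#' capacity (J/g/K). The heating and cooling curves must agree within
#' `tolerance` (checks the absence of mass loss).
#'
#' @param heating,cooling data frames with columns `T_K` and `Cp_J_per_K`.
#' @param cp_reference specific heat capacity: a function of T (J/g/K) or a
#'   data frame with columns `T_K`, `cp_J_per_gK` (interpolated linearly).
#' @param window numeric(2) temperature window (K); default the central 60%
#'   of the overlap of the two curves.
#' @param tolerance maximal mean relative heating/cooling disagreement.
#' @param rel_uncertainty relative uncertainty assigned to the mass
#'   (default 0.11).
#' @return list with `mass_g`, `u_mass_g`, `window`, and the mean relative
#'   heating/cooling disagreement `discrepancy`.
#' @export
determine_sample_mass <- function(heating, cooling, cp_reference,
                                  window = NULL, tolerance = 0.1,
                                  rel_uncertainty = 0.11) {
  cp_fun <- if (is.function(cp_reference)) {
    cp_reference
  } else {
    stats::approxfun(cp_reference$T_K, cp_reference$cp_J_per_gK, rule = 2)
  }
  lo <- max(min(heating$T_K), min(cooling$T_K))
  hi <- min(max(heating$T_K), max(cooling$T_K))
  if (is.null(window)) {
    span <- hi - lo
    window <- c(lo + 0.2 * span, hi - 0.2 * span)
  }
  if (window[1] >= window[2]) stop("empty evaluation window")
  grid <- seq(window[1], window[2], length.out = 200L)
  Ch <- stats::approx(heating$T_K, heating$Cp_J_per_K, grid)$y
  Cc <- stats::approx(cooling$T_K, cooling$Cp_J_per_K, grid)$y
  disc <- mean(abs(Ch - Cc)) / mean(abs(Ch))
  if (disc > tolerance) {
    stop(sprintf(
      "heating/cooling heat capacities disagree by %.1f%% (> %.1f%%): mass loss suspected",
      100 * disc, 100 * tolerance))
  }
  m <- mean((Ch + Cc) / 2 / cp_fun(grid))
  list(mass_g = m, u_mass_g = rel_uncertainty * m, window = window,
       discrepancy = disc)
}

#' Detect the melting peak of a thermogram
#'
#' Fits a linear baseline over pre- and post-peak windows, locates the
#' dominant endothermic peak, and reports the onset temperature (baseline /
#' leading-edge-tangent intersection) and the peak enthalpy (time integral
#' of the baseline-subtracted heat flow rate).
#'
#' @param tg a [thermogram()].
#' @param baseline_window width (K) of the pre/post baseline fit windows.
#' @param baseline_gap gap (K) between the peak extent and the baseline
#'   windows.
#' @param noise_threshold peak detection threshold as a multiple of the
#'   baseline noise level.
#' @return a `peak_measurement`: `scan_id`, `beta`, `T_onset` (K), `dH_J`
#'   (J), `mass_g` (copied from metadata `mass_ng` if present), `T_peak`,
#'   `T_endset`, `height_W`, `noise_W`.
#' @export
detect_melting_peak <- function(tg, baseline_window = 20, baseline_gap = 5,
                                noise_threshold = 5) {
  stopifnot(inherits(tg, "thermogram"))
  T <- tg$T_K; y <- tg$hf_W; t <- tg$time_s
  n <- length(y)
  if (n < 50L) stop("thermogram too short for peak analysis")
  dT <- stats::median(diff(T))
  k <- max(3L, min(round(0.5 / dT), 25L)) # ~0.5 K smoothing
  ys <- .runmean(y, k)
  noise <- stats::mad(diff(y)) / sqrt(2)

  # initial linear detrend from the outer quarters of the scan
  outer_idx <- c(seq_len(n %/% 4), seq(n - n %/% 4 + 1L, n))
  fit0 <- stats::lm.fit(cbind(1, T[outer_idx]), ys[outer_idx])
  base0 <- fit0$coefficients[1] + fit0$coefficients[2] * T
  r <- ys - base0
  ip <- which.max(r)
  height0 <- r[ip]
  floor_h <- max(noise_threshold * noise, 1e-6 * max(abs(y)), 1e-300)
  if (!is.finite(height0) || height0 < floor_h) {
    stop("no melting peak above the noise threshold")
  }

  # peak extent: walk out from the maximum to the 2% level of the detrended
  # signal
  lvl <- 0.02 * height0
  il <- ip; while (il > 1L && r[il] > lvl) il <- il - 1L
  ir <- ip; while (ir < n && r[ir] > lvl) ir <- ir + 1L
  T_lo <- T[il]; T_hi <- T[ir]

  # final baseline from windows clear of the peak
  pre <- which(T >= T_lo - baseline_gap - baseline_window &
                 T <= T_lo - baseline_gap)
  post <- which(T >= T_hi + baseline_gap &
                  T <= T_hi + baseline_gap + baseline_window)
  if (length(pre) < 5L) pre <- which(T <= T_lo - baseline_gap)
  if (length(post) < 5L) post <- which(T >= T_hi + baseline_gap)
  if (length(pre) < 5L || length(post) < 5L) {
    stop("not enough baseline on both sides of the peak")
  }
  bidx <- c(pre, post)
  bfit <- stats::lm.fit(cbind(1, T[bidx]), y[bidx])
  bl <- function(TT) bfit$coefficients[1] + bfit$coefficients[2] * TT
  yc <- y - bl(T)
  ysc <- ys - bl(T)
  height <- max(ysc[il:ir])
  ipk <- il - 1L + which.max(ysc[il:ir])

  # ambiguity check: other peaks comparable to the main one
  others <- .find_other_peaks(T, ysc, il, ir, height, noise)
  if (length(others) > 0L) {
    stop(sprintf("ambiguous melting signal: comparable peaks near T = %s K",
                 paste(sprintf("%.1f", others), collapse = ", ")))
  }

  # leading edge: 10%..85% of peak height before the maximum
  lead <- which(T >= T_lo & T <= T[ipk])
  lead <- lead[ysc[lead] >= 0.10 * height & ysc[lead] <= 0.85 * height]
  if (length(lead) < 4L) stop("leading edge too short to locate the onset")
  dy <- .runmean(diff(ysc) / diff(T), k)
  im <- lead[which.max(dy[pmin(lead, n - 1L)])]
  # tangent at the inflection point from a local cubic fit: the cubic's own
  # inflection refines the grid estimate, and its derivative there is the
  # tangent slope (exact for a straight leading edge, unbiased to O(dT^4)
  # for a curved one)
  w <- max(4L, round(1.2 / dT))
  seg <- max(il, im - w):min(ipk, im + w)
  Tc0 <- T[im]
  Ts <- T[seg] - Tc0
  cf <- stats::lm.fit(cbind(1, Ts, Ts^2, Ts^3), yc[seg])$coefficients
  Ti <- -cf[3] / (3 * cf[4])   # inflection of the cubic, relative to Tc0
  if (!is.finite(Ti) || abs(Ti) > max(abs(Ts))) Ti <- 0
  slope <- cf[2] + 2 * cf[3] * Ti + 3 * cf[4] * Ti^2
  y_i <- cf[1] + cf[2] * Ti + cf[3] * Ti^2 + cf[4] * Ti^3
  if (!is.finite(slope) || slope <= 0) stop("degenerate leading-edge tangent")
  T_onset <- Tc0 + Ti - y_i / slope   # tangent crosses the baseline (0)

  # enthalpy: integrate the baseline-subtracted signal over time between the
  # points where the smoothed signal falls to 0.5% of the peak height
  lvl2 <- 0.005 * height
  il2 <- ipk; while (il2 > 1L && ysc[il2] > lvl2) il2 <- il2 - 1L
  ir2 <- ipk; while (ir2 < n && ysc[ir2] > lvl2) ir2 <- ir2 + 1L
  seg2 <- il2:ir2
  dH <- sum(diff(t[seg2]) * (yc[seg2][-1] + yc[seg2][-length(seg2)]) / 2)
  if (dH <= 0) stop("nonpositive peak area: not a melting peak")

  mass_g <- if (!is.null(tg$meta$mass_ng)) tg$meta$mass_ng * 1e-9 else NA_real_
  out <- list(scan_id = tg$scan_id, beta = tg$beta, T_onset = T_onset,
              dH_J = dH, mass_g = mass_g, T_peak = T[ipk], T_endset = T_hi,
              height_W = height, noise_W = noise)
  class(out) <- "peak_measurement"
  out
}

# Secondary-peak scan outside the main extent [il, ir].
.find_other_peaks <- function(T, ysc, il, ir, height, noise) {
  n <- length(ysc)
  cand <- numeric(0)
  mask <- rep(TRUE, n)
  mask[max(1, il - 5):min(n, ir + 5)] <- FALSE
  idx <- which(mask)
  if (length(idx) < 10L) return(cand)
  for (blk in split(idx, cumsum(c(1, diff(idx) != 1)))) {
    if (length(blk) < 5L) next
    pk <- blk[which.max(ysc[blk])]
    if (ysc[pk] > 0.5 * height && ysc[pk] > 5 * noise) {
      cand <- c(cand, T[pk])
    }
  }
  cand
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat(sprintf(
    "peak %s: beta = %g K/s, onset %.2f K, dH = %.4g uJ, mass = %s ng\n",
    x$scan_id, x$beta, x$T_onset, x$dH_J * 1e6,
    if (is.na(x$mass_g)) "?" else sprintf("%.1f", x$mass_g * 1e9)))
  invisible(x)
}

#' Extrapolate apparent melting temperatures to zero heating rate
#'
#' Ordinary least squares of the onset temperature against the heating rate;
#' the intercept is the thermodynamic melting temperature. Its uncertainty
#' combines the intercept's standard error (scaled by the two-sided 95%
#' Student-t factor) with the temperature-calibration uncertainty in
#' quadrature.
#'
#' @param measurements list of `peak_measurement`s, or a data frame with
#'   columns `beta` and `T_onset` (at least 3 distinct rates).
#' @param u_calibration temperature-calibration uncertainty in K.
#' @param conf confidence level of the Student-t factor.
#' @return list with `T_fus` (K), `u_T_fus` (K), `slope` (K per (K/s)),
#'   `se_intercept`, `n`, and the `lm` fit.
#' @export
extrapolate_zero_rate <- function(measurements, u_calibration = 5,
                                  conf = 0.95) {
  df <- .as_peak_df(measurements)
  if (length(unique(df$beta)) < 3L) {
    stop("need onsets at >= 3 distinct heating rates")
  }
  fit <- stats::lm(T_onset ~ beta, data = df)
  # a degenerate, residual-free fit is legitimate input (all onsets equal)
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- sm["(Intercept)", "Std. Error"]
  tfac <- stats::qt(1 - (1 - conf) / 2, df = nrow(df) - 2L)
  list(T_fus = unname(stats::coef(fit)[1]),
       u_T_fus = sqrt((tfac * se)^2 + u_calibration^2),
       slope = unname(stats::coef(fit)[2]),
       se_intercept = se, n = nrow(df), fit = fit)
}

.as_peak_df <- function(measurements) {
  if (is.data.frame(measurements)) return(measurements)
  do.call(rbind, lapply(measurements, function(pm) {
    data.frame(scan_id = pm$scan_id, beta = pm$beta, T_onset = pm$T_onset,
               dH_J = pm$dH_J, mass_g = pm$mass_g)
  }))
}

#' Molar enthalpy of fusion from peak areas and sample masses
#'
#' The peak enthalpy grows linearly with sample mass regardless of heating
#' rate; the through-origin least-squares slope of `dH` (J) against mass (g)
#' is the specific fusion enthalpy (J/g), multiplied by the molar mass. The
#' relative uncertainty combines the slope's standard error with the sample
#' mass uncertainty in quadrature, expanded with coverage factor `k`.
#'
#' @param measurements list of `peak_measurement`s or a data frame with
#'   columns `dH_J` and `mass_g` (at least 3 points spanning a mass range).
#' @param molar_mass molar mass in g/mol.
#' @param mass_rel_uncertainty relative sample-mass uncertainty
#'   (default 0.11).
#' @param k coverage factor for the expanded uncertainty.
#' @return list with `dH_fus` (J/mol), `u_dH_fus` (J/mol), `dh_specific`
#'   (J/g), `se_slope`, `n`.
#' @export
molar_fusion_enthalpy <- function(measurements, molar_mass,
                                  mass_rel_uncertainty = 0.11, k = 2) {
  df <- .as_peak_df(measurements)
  df <- df[is.finite(df$mass_g) & is.finite(df$dH_J), , drop = FALSE]
  if (nrow(df) < 3L) stop("need >= 3 (mass, area) measurements")
  if (stats::sd(df$mass_g) / mean(df$mass_g) < 1e-12) {
    stop("all sample masses equal: through-origin fit is ill-conditioned")
  }
  sxx <- sum(df$mass_g^2)
  slope <- sum(df$mass_g * df$dH_J) / sxx
  res <- df$dH_J - slope * df$mass_g
  se <- sqrt(sum(res^2) / (nrow(df) - 1L) / sxx)
  rel <- sqrt((se / slope)^2 + mass_rel_uncertainty^2)
  dH <- slope * molar_mass
  list(dH_fus = dH, u_dH_fus = k * rel * dH, dh_specific = slope,
       se_slope = se, n = nrow(df))
}

#' Entropy of fusion with propagated uncertainty
#'
#' `dS_fus = dH_fus / T_fus`, first-order uncertainty propagation.
#'
#' @param dH_fus molar enthalpy of fusion, J/mol (>= 0).
#' @param T_fus melting temperature, K (> 0).
#' @param u_dH_fus,u_T_fus uncertainties of the inputs.
#' @return list with `dS_fus` (J/K/mol) and `u_dS_fus`.
#' @export
fusion_entropy <- function(dH_fus, T_fus, u_dH_fus = 0, u_T_fus = 0) {
  if (T_fus <= 0 || dH_fus < 0) stop("require T_fus > 0 and dH_fus >= 0")
  dS <- dH_fus / T_fus
  u <- if (dH_fus == 0) u_dH_fus / T_fus else {
    dS * sqrt((u_dH_fus / dH_fus)^2 + (u_T_fus / T_fus)^2)
  }
  list(dS_fus = dS, u_dS_fus = u)
}

#' Reduce a full FSC scan set to melting properties
#'
#' Convenience pipeline: peak detection on every scan, zero-rate
#' extrapolation of the onsets, mass regression of the peak areas, and
#' entropy of fusion.
#'
#' @param scans list of [thermogram()]s (with `mass_ng` metadata).
#' @param molar_mass molar mass of the substance in g/mol.
#' @param substance substance id for the result record.
#' @param ... passed to [detect_melting_peak()].
#' @inheritParams extrapolate_zero_rate
#' @inheritParams molar_fusion_enthalpy
#' @return list with `peaks` (data frame), `zero_rate`, `enthalpy`, and
#'   `melting` (a [melting_properties()] object).
#' @export
reduce_fsc <- function(scans, molar_mass, substance = "sample",
                       u_calibration = 5, mass_rel_uncertainty = 0.11, ...) {
  peaks <- lapply(scans, detect_melting_peak, ...)
  df <- .as_peak_df(peaks)
  zr <- extrapolate_zero_rate(df, u_calibration = u_calibration)
  en <- molar_fusion_enthalpy(df, molar_mass,
                              mass_rel_uncertainty = mass_rel_uncertainty)
  mel <- melting_properties(substance, zr$T_fus, en$dH_fus,
                            u_T_fus = zr$u_T_fus, u_dH_fus = en$u_dH_fus)
  list(peaks = df, zero_rate = zr, enthalpy = en, melting = mel)
}
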