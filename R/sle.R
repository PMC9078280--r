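# Solid-liquid equilibrium: the melting-property route to activity
# coefficients and solubility, and the two fitting procedures (binary
# interaction parameter to osmotic data, fusion enthalpy to one solubility
# point). Heat-capacity differences between solid and subcooled liquid are
# neglected throughout, so the saturation condition is
#   x_sat * gamma(x_sat, T) = exp[-(dHfus/R) (1/T - 1/Tfus)].

#' Melting properties of a substance
#'
#' @param substance substance id.
#' @param T_fus melting temperature in K.
#' @param dH_fus molar enthalpy of fusion in J/mol.
#' @param u_T_fus,u_dH_fus standard (expanded) uncertainties of the two, same
#'   units; default 0.
#' @return a `melting_properties` object; the entropy of fusion
#'   `dS_fus = dH_fus / T_fus` (J/K/mol) and its propagated uncertainty are
#'   filled in.
#' @export
melting_properties <- function(substance, T_fus, dH_fus, u_T_fus = 0,
                               u_dH_fus = 0) {
  if (T_fus <= 0 || dH_fus <= 0) stop("T_fus and dH_fus must be positive")
  dS <- fusion_entropy(dH_fus, T_fus, u_dH_fus, u_T_fus)
  out <- list(substance = substance, T_fus = T_fus, dH_fus = dH_fus,
              dS_fus = dS$dS_fus, u_T_fus = u_T_fus, u_dH_fus = u_dH_fus,
              u_dS_fus = dS$u_dS_fus)
  class(out) <- "melting_properties"
  out
}

#' @export
print.melting_properties <- function(x, ...) {
  cat(sprintf("melting properties of %s:\n", x$substance))
  cat(sprintf("  T_fus  = %.4g +/- %.2g K\n", x$T_fus, x$u_T_fus))
  cat(sprintf("  dH_fus = %.4g +/- %.2g kJ/mol\n", x$dH_fus / 1000,
              x$u_dH_fus / 1000))
  cat(sprintf("  dS_fus = %.2g +/- %.1g kJ/K/mol\n", x$dS_fus / 1000,
              x$u_dS_fus / 1000))
  invisible(x)
}

#' Activity coefficient implied by melting properties at saturation
#'
#' Rearranges the solid-liquid equilibrium condition (heat-capacity terms
#' neglected) for the activity coefficient at a known saturation mole
#' fraction: `gamma = exp[-(dHfus/R)(1/T - 1/Tfus)] / x`.
#'
#' @param x saturation mole fraction of the solute, in (0, 1).
#' @param T temperature in K, `0 < T <= T_fus`.
#' @param melting a [melting_properties()] object.
#' @return the activity coefficient.
#' @export
#' @examples
#' gly <- melting_properties("glycine", 569, 21000)
#' gamma_from_melting(0.05724, 298.15, gly)  # 0.31
gamma_from_melting <- function(x, T, melting) {
  if (any(x <= 0 | x >= 1)) stop("x must be in (0, 1)")
  if (any(T <= 0 | T > melting$T_fus)) stop("require 0 < T <= T_fus")
  exp(-(melting$dH_fus / R_GAS) * (1 / T - 1 / melting$T_fus)) / x
}

#' Ideal solubility from melting properties
#'
#' The saturation mole fraction when the activity coefficient is taken as 1:
#' `x_ideal = exp[-(dHfus/R)(1/T - 1/Tfus)]`.
#'
#' @inheritParams gamma_from_melting
#' @return ideal saturation mole fraction; 1 at `T = T_fus`.
#' @export
ideal_solubility <- function(T, melting) {
  if (any(T <= 0)) stop("T must be positive")
  if (any(T > melting$T_fus)) {
    stop("T > T_fus: no solid phase, ideal solubility undefined")
  }
  exp(-(melting$dH_fus / R_GAS) * (1 / T - 1 / melting$T_fus))
}

#' Predict solubility from melting properties and the equation of state
#'
#' Solves the saturation condition
#' `x gamma(x, T) = exp[-(dHfus/R)(1/T - 1/Tfus)]`
#' with the activity coefficient from PC-SAFT (pure-liquid reference), by a
#' damped fixed-point iteration `x <- x_ideal / gamma(x)` started at the
#' ideal solubility, followed by a bracketed root polish.
#'
#' @inheritParams activity_coefficient
#' @param T temperature in K, below `melting$T_fus`.
#' @param melting a [melting_properties()] object for the solute.
#' @param ideal_gamma if `TRUE`, forces `gamma = 1` and returns the ideal
#'   solubility (degenerate closure, useful for comparison columns).
#' @param tol relative tolerance on the saturation condition.
#' @param max_iter fixed-point iteration cap.
#' @param .ctx internal: a prebuilt solution context (reuses cached
#'   reference states across repeated calls at one T, P).
#' @return a list with `molality` (mol/kg), `x` (mole fraction), `gamma`
#'   (solute activity coefficient at saturation), `iterations` and
#'   `residual` (relative saturation-condition residual).
#' @export
predict_solubility <- function(params, solute, T, melting, P = P_DEFAULT,
                               ideal_gamma = FALSE, tol = 1e-10,
                               max_iter = 200L, .ctx = NULL) {
  if (T >= melting$T_fus) stop("T must be below T_fus for a solid phase")
  K <- ideal_solubility(T, melting)
  if (ideal_gamma) {
    return(list(molality = mole_fraction_to_molality(K), x = K, gamma = 1,
                iterations = 0L, residual = 0))
  }
  ctx <- if (is.null(.ctx)) .solution_context(params, solute, T, P) else .ctx
  lnK <- log(K)
  lgam <- function(xs) .ln_gammas(ctx, xs)[["solute"]]
  # damped fixed point in log space: ln x <- ln K - ln gamma(x)
  lx <- lnK
  it <- 0L
  repeat {
    it <- it + 1L
    xs <- min(exp(lx), 0.95)
    lg <- lgam(xs)
    lx_new <- lnK - lg
    step <- lx_new - lx
    lx <- lx + 0.5 * step
    if (abs(step) < 1e-9 || it >= max_iter) break
  }
  if (abs(step) >= 1e-9) {
    stop(sprintf(
      "saturation iteration did not converge at T = %g K (last step %.3e)",
      T, step))
  }
  # root polish on f(lx) = lx + ln gamma - lnK around the fixed point
  f <- function(l) l + lgam(exp(l)) - lnK
  lo <- lx - 5e-4; hi <- lx + 5e-4
  sol <- tryCatch(
    uniroot(f, lower = lo, upper = hi, extendInt = "yes", tol = tol),
    error = function(e) NULL)
  if (!is.null(sol)) lx <- sol$root
  xs <- exp(lx)
  lg <- lgam(xs)
  resid <- abs(lx + lg - lnK)
  list(molality = mole_fraction_to_molality(xs), x = xs, gamma = exp(lg),
       iterations = it, residual = resid)
}

#' Fit the fusion enthalpy to one experimental solubility point
#'
#' One-dimensional root solve for `dH_fus` such that [predict_solubility()]
#' reproduces a target solubility at one temperature, with the melting
#' temperature held fixed. The search is restricted to the physically
#' plausible band (default 5-50 kJ/mol).
#'
#' @inheritParams predict_solubility
#' @param target_molality experimental solubility in mol/kg water.
#' @param T_fus fixed melting temperature in K.
#' @param band numeric(2), search band for `dH_fus` in J/mol.
#' @param rel_tol relative tolerance on the reproduced solubility.
#' @return a `fit_result` with `value` (fitted dH_fus, J/mol), the achieved
#'   solubility, residual and convergence metadata.
#' @export
fit_hfus <- function(params, solute, target_molality, T, T_fus,
                     P = P_DEFAULT, band = c(5e3, 5e4), rel_tol = 1e-6) {
  if (target_molality <= 0) stop("target molality must be positive")
  if (T >= T_fus) stop("T must be below T_fus")
  ctx <- .solution_context(params, solute, T, P)
  pred_m <- function(dh) {
    mel <- melting_properties(solute, T_fus, dh)
    predict_solubility(params, solute, T, mel, P, .ctx = ctx)$molality
  }
  g <- function(dh) log(pred_m(dh) / target_molality)
  glo <- g(band[1]); ghi <- g(band[2])
  if (glo * ghi > 0) {
    stop(sprintf(
      "no dH_fus root in band [%.3g, %.3g] J/mol: log-residuals %.3g, %.3g",
      band[1], band[2], glo, ghi))
  }
  sol <- uniroot(g, lower = band[1], upper = band[2], tol = 1e-4)
  dh <- sol$root
  m_fit <- pred_m(dh)
  # polish: Newton step on the log residual if still above tolerance
  reps <- 0L
  while (abs(log(m_fit / target_molality)) > rel_tol && reps < 10L) {
    h <- max(1e-3 * dh, 1)
    slope <- (g(dh + h) - g(dh - h)) / (2 * h)
    dh <- dh - log(m_fit / target_molality) / slope
    m_fit <- pred_m(dh)
    reps <- reps + 1L
  }
  out <- list(parameter = "dH_fus", value = dh, units = "J/mol",
              objective = abs(log(m_fit / target_molality)),
              residuals = m_fit - target_molality,
              fitted_molality = m_fit, target_molality = target_molality,
              converged = abs(log(m_fit / target_molality)) <= rel_tol,
              iterations = sol$iter + reps)
  class(out) <- "fit_result"
  out
}

#' Fit the binary interaction parameter to osmotic-coefficient data
#'
#' Least-squares minimisation of `sum((Phi_model - Phi_exp)^2)` over the
#' 298.15 K intercept `kij_ref` of the solute-water pair; any declared
#' temperature slope is held fixed.
#'
#' @inheritParams activity_coefficient
#' @param data a data frame with columns `molality`, `value` (osmotic
#'   coefficient) and optionally `T_K` (single temperature, default 298.15).
#' @param interval numeric(2), search interval for `kij_ref`.
#' @return a `fit_result` with `value` (fitted kij_ref), per-point
#'   `residuals`, the objective at the fitted value and at the declared
#'   starting value.
#' @export
fit_kij <- function(params, solute, data, P = P_DEFAULT,
                    interval = c(-0.25, 0.15)) {
  if (nrow(data) < 3L) stop("need at least 3 osmotic-coefficient points")
  T <- if ("T_K" %in% names(data)) unique(data$T_K) else 298.15
  if (length(T) != 1L) stop("fit_kij expects a single-temperature data set")
  set_kij <- function(p, val) {
    key <- .normalise_pair(c(solute, "water"))
    found <- FALSE
    for (k in seq_along(p$binary_interactions)) {
      if (identical(p$binary_interactions[[k]]$pair, key)) {
        p$binary_interactions[[k]]$kij_ref <- val
        found <- TRUE
      }
    }
    if (!found) {
      p$binary_interactions <- c(p$binary_interactions,
                                 list(list(pair = key, kij_ref = val,
                                           kij_slope = 0)))
    }
    p
  }
  obj <- function(kref) {
    phi <- osmotic_coefficient(set_kij(params, kref), solute,
                               data$molality, T, P)
    sum((phi - data$value)^2)
  }
  start <- tryCatch(kij_at(params, solute, "water", 298.15),
                    error = function(e) 0)
  opt <- optimize(obj, interval = interval, tol = 1e-6)
  kfit <- opt$minimum
  phi_fit <- osmotic_coefficient(set_kij(params, kfit), solute,
                                 data$molality, T, P)
  out <- list(parameter = "kij_ref", value = kfit, units = "",
              objective = opt$objective,
              objective_at_start = obj(start), start = start,
              residuals = phi_fit - data$value,
              converged = TRUE, iterations = NA_integer_)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit of %s: %.6g %s (objective %.3e%s)\n", x$parameter,
              x$value, x$units, x$objective,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Average absolute relative deviation in percent
#'
#' `ARD = 100/NP * sum(|1 - model/exp|)` over paired series.
#'
#' @param model,exp equal-length numeric vectors; `exp` must be nonzero.
#' @return ARD in percent.
#' @export
ard <- function(model, exp) {
  if (length(model) != length(exp)) stop("series lengths differ")
  if (any(exp == 0)) stop("experimental values must be nonzero")
  100 * mean(abs(1 - model / exp))
}
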