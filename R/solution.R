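# Concentration conversions and solution non-ideality measures for aqueous
# amino-acid solutions.

M_WATER <- 18.015     # g/mol
P_DEFAULT <- 101325   # Pa

#' Convert molality to solute mole fraction
#'
#' `x = m / (m + 1000 / M_water)` for a binary solute + water solution,
#' with `M_water = 18.015` g/mol.
#'
#' @param m molality in mol solute per kg water (nonnegative).
#' @return solute mole fraction.
#' @export
#' @examples
#' molality_to_mole_fraction(1.828)  # 0.03188
molality_to_mole_fraction <- function(m) {
  if (any(m < 0)) stop("molality must be nonnegative")
  m / (m + 1000 / M_WATER)
}

#' @rdname molality_to_mole_fraction
#' @param x solute mole fraction in `[0, 1)`.
#' @export
mole_fraction_to_molality <- function(x) {
  if (any(x < 0 | x >= 1)) stop("mole fraction must be in [0, 1)")
  (1000 / M_WATER) * x / (1 - x)
}

# Internal context for repeated activity-coefficient evaluations at one
# (solute, T, P): fluids built once, pure-component reference states cached.
.solution_context <- function(params, solute, T, P = P_DEFAULT,
                              kij_missing_zero = FALSE) {
  mix <- pcsaft_fluid(params, c(solute, "water"),
                      kij_missing_zero = kij_missing_zero)
  pure_s <- pcsaft_fluid(params, solute)
  pure_w <- pcsaft_fluid(params, "water")
  lnphi0 <- local({
    val_s <- NULL; val_w <- NULL
    function(which) {
      if (which == "solute") {
        if (is.null(val_s)) {
          lp <- tryCatch(
            ln_fugacity_coefficients(pure_s, T, P, 1, "liquid"),
            error = function(e) stop(
              "no liquid root for the pure (hypothetical liquid) solute at ",
              sprintf("T = %g K, P = %g Pa: %s", T, P, conditionMessage(e))))
          val_s <<- lp[[1L]]
        }
        val_s
      } else {
        if (is.null(val_w)) {
          val_w <<- ln_fugacity_coefficients(pure_w, T, P, 1, "liquid")[[1L]]
        }
        val_w
      }
    }
  })
  list(mix = mix, T = T, P = P, lnphi0 = lnphi0, solute = solute)
}

# ln gamma of both components at solute mole fraction xs (pure-liquid
# reference for each component).
.ln_gammas <- function(ctx, xs) {
  x <- c(xs, 1 - xs)
  lph <- ln_fugacity_coefficients(ctx$mix, ctx$T, ctx$P, x, "liquid")
  c(solute = lph[[1L]] - ctx$lnphi0("solute"),
    water = lph[[2L]] - ctx$lnphi0("water"))
}

#' Activity coefficient of a solute in water from the equation of state
#'
#' Mole-fraction-scale activity coefficient on the pure-liquid reference:
#' `gamma_i = phi_i(T, P, x) / phi_0i(T, P, pure liquid i)`, where the pure
#' reference is the (possibly hypothetical, subcooled) liquid solute at the
#' same temperature and pressure. `gamma_i -> 1` as `x_i -> 1`.
#'
#' @param params a `pcsaft_params` parameter set.
#' @param solute component id of the solute.
#' @param x solute mole fraction (give either `x` or `molality`).
#' @param molality solute molality in mol/kg water.
#' @param T temperature in K.
#' @param P pressure in Pa (default atmospheric).
#' @return activity coefficient of the solute; the water activity
#'   coefficient is attached as attribute `"gamma_water"`.
#' @export
activity_coefficient <- function(params, solute, x = NULL, molality = NULL,
                                 T = 298.15, P = P_DEFAULT) {
  if (is.null(x) == is.null(molality)) {
    stop("give exactly one of 'x' or 'molality'")
  }
  if (is.null(x)) x <- molality_to_mole_fraction(molality)
  if (x < 0 || x > 1) stop("solute mole fraction must be in [0, 1]")
  if (x == 1) return(structure(1, gamma_water = NA_real_))
  ctx <- .solution_context(params, solute, T, P)
  lg <- .ln_gammas(ctx, x)
  structure(exp(lg[["solute"]]), gamma_water = exp(lg[["water"]]))
}

#' Osmotic coefficient of an aqueous solution
#'
#' `Phi = -ln(a_w) / (M_water m)` with the water activity
#' `a_w = x_w gamma_w`, `gamma_w` on the pure-liquid reference scale and
#' `M_water` in kg/mol. `Phi -> 1` at infinite dilution.
#'
#' @inheritParams activity_coefficient
#' @param molality solute molality in mol/kg water; must be positive.
#' @return osmotic coefficient (dimensionless), vectorised over `molality`.
#' @export
osmotic_coefficient <- function(params, solute, molality, T = 298.15,
                                P = P_DEFAULT) {
  if (any(molality <= 0)) {
    stop("molality must be positive (the m -> 0 limit is 1 by definition)")
  }
  ctx <- .solution_context(params, solute, T, P)
  vapply(molality, function(m) {
    xs <- molality_to_mole_fraction(m)
    lg <- .ln_gammas(ctx, xs)
    aw <- log(1 - xs) + lg[["water"]]
    -aw / (M_WATER / 1000 * m)
  }, numeric(1))
}
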