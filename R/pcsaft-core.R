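# PC-SAFT residual Helmholtz energy and derived properties for associating
# mixtures. Internal length unit is the angstrom: number densities are in
# molecules per A^3 and are converted to SI only where a pressure is formed.

KB_SI <- 1.380649e-23   # J K^-1
N_AVOGADRO <- 6.02214076e23
R_GAS <- 8.314          # J mol^-1 K^-1, used in all SLE relations

# Universal model constants of the dispersion power series (two 7-term series
# in packing fraction; rows are the polynomial order 0..6).
.PC_A <- matrix(c(
  0.91056314451539, -0.30840169182720, -0.09061483509767,
  0.63612814494991,  0.18605311591713,  0.45278428063920,
  2.68613478913903, -2.50300472586548,  0.59627007280101,
 -26.5473624914884,  21.4197936296668, -1.72418291311787,
  97.7592087835073, -65.2558853303492, -4.13021125311661,
 -159.591540865600,  83.3186804808856,  13.7766318697211,
  91.2977740839123, -33.7469229297323, -8.67284703679646), ncol = 3, byrow = TRUE)

.PC_B <- matrix(c(
  0.72409469413165, -0.57554980753450,  0.09768831158356,
  2.23827918609380,  0.69950955214436, -0.25757749407912,
 -4.00258494846342,  3.89256733895307, -9.15585615297321,
 -21.0035768148465, -17.2154716477721,  20.6420759743972,
  26.8556413626615,  192.672264465249, -38.8044300520628,
  206.551338406619, -161.826461648765,  93.6267740770146,
 -355.602356122079, -165.207693455561, -29.6669055851473), ncol = 3, byrow = TRUE)

#' Assemble a working fluid from a parameter set
#'
#' Selects components from a loaded parameter set and freezes the data the
#' equation of state needs: segment numbers, temperature-dependent segment
#' diameters, dispersion energies, association parameters and the binary
#' interaction matrix.
#'
#' @param params a `pcsaft_params` object from [load_parameter_set()].
#' @param ids character vector of component ids, in the order mole fractions
#'   will be supplied.
#' @param kij_missing_zero if `TRUE`, undeclared binary pairs fall back to
#'   `k_ij = 0`; otherwise they are an error when the fluid is evaluated.
#' @return an object of class `pcsaft_fluid`.
#' @export
pcsaft_fluid <- function(params, ids, kij_missing_zero = FALSE) {
  stopifnot(inherits(params, "pcsaft_params"))
  missing <- setdiff(ids, names(params$components))
  if (length(missing) > 0L) {
    stop("unknown component id(s): ", paste(missing, collapse = ", "))
  }
  comps <- params$components[ids]
  n <- length(ids)
  kij_pairs <- params$binary_interactions
  fl <- list(
    ids = ids,
    n = n,
    m = vapply(comps, function(cp) cp$m_seg, numeric(1)),
    Mw = vapply(comps, function(cp) cp$molar_mass, numeric(1)),
    u = vapply(comps, function(cp) cp$u_k, numeric(1)),
    eps_ab = vapply(comps, function(cp) cp$eps_assoc_k, numeric(1)),
    kappa_ab = vapply(comps, function(cp) cp$kappa_assoc, numeric(1)),
    comps = comps,
    pairs = kij_pairs,
    kij_missing_zero = isTRUE(kij_missing_zero)
  )
  class(fl) <- "pcsaft_fluid"
  fl
}

#' @export
print.pcsaft_fluid <- function(x, ...) {
  cat("PC-SAFT fluid:", paste(x$ids, collapse = " + "), "\n")
  cat("  m_seg:", paste(format(x$m), collapse = ", "), "\n")
  cat("  associating:", paste(x$ids[x$kappa_ab > 0], collapse = ", "), "\n")
  invisible(x)
}

# k_ij matrix at temperature T for the fluid's components.
.fluid_kij <- function(fl, T) {
  K <- matrix(0, fl$n, fl$n)
  if (fl$n < 2L) return(K)
  for (i in seq_len(fl$n - 1L)) {
    for (j in (i + 1L):fl$n) {
      val <- kij_lookup(fl$pairs, fl$ids[i], fl$ids[j], T,
                        missing_zero = fl$kij_missing_zero)
      K[i, j] <- K[j, i] <- val
    }
  }
  K
}

# Temperature-frozen quantities: hard-sphere diameters, cross parameters and
# association strength prefactors. Everything downstream depends on (rho, x).
.fluid_tx <- function(fl, T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("temperature must be a positive finite scalar (K)")
  }
  sig <- vapply(fl$comps, function(cp) sigma_at(cp, T), numeric(1))
  d <- sig * (1 - 0.12 * exp(-3 * fl$u / T))
  kij <- .fluid_kij(fl, T)
  sig_ij <- outer(sig, sig, "+") / 2
  u_ij <- sqrt(outer(fl$u, fl$u)) * (1 - kij)
  # 2B cross association: energy arithmetic mean, volume geometric mean scaled
  # by the ratio of geometric to arithmetic mean segment diameters.
  eps_ij <- outer(fl$eps_ab, fl$eps_ab, "+") / 2
  kap_ij <- sqrt(outer(fl$kappa_ab, fl$kappa_ab)) *
    (sqrt(outer(sig, sig)) / sig_ij)^3
  assoc <- which(fl$kappa_ab > 0)
  list(
    T = T, m = fl$m, d = d, sigma = sig,
    sig_ij = sig_ij, u_ij = u_ij,
    eps_ij = eps_ij, kap_ij = kap_ij,
    f_ij = expm1(eps_ij / T),
    dstar = outer(d, d) / outer(d, d, "+"),
    assoc = assoc, n = fl$n, kij = kij
  )
}

# Solve the 2B association site balances X_i = 1/(1 + rho sum_j x_j X_j D_ij)
# over the associating components. Damped successive substitution followed by
# a Newton polish; supports complex x for derivative propagation.
.solve_site_fractions <- function(D, xs, tol = 1e-13, max_iter = 500L) {
  na <- length(xs)
  # D: na x na matrix rho * Delta_ij restricted to associating components,
  # xs: their mole fractions. Returns X (site fraction per component).
  C <- D * rep(xs, each = na)      # C[i, j] = D[i, j] * x_j
  X <- rep(if (is.complex(C)) 0.2 + 0i else 0.2, na)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Xn <- 1 / (1 + drop(C %*% X))
    step <- Xn - X
    X <- X + 0.5 * step
    if (max(Mod(step)) < 1e-9) { converged <- TRUE; break }
  }
  # Newton polish on R_i = X_i (1 + sum_j C_ij X_j) - 1 = 0
  for (it in 1:50) {
    s <- drop(C %*% X)
    Rres <- X * (1 + s) - 1
    if (max(Mod(Rres)) < tol && it > 2L) { converged <- TRUE; break }
    J <- diag(1 + s, na) + X * C
    X <- X - drop(solve(J, Rres))
  }
  s <- drop(C %*% X)
  resid <- max(Mod(X * (1 + s) - 1))
  if (resid > 1e-10) {
    stop(sprintf("association site balance did not converge (residual %.3e)",
                 resid))
  }
  X
}

# Full evaluation of the residual Helmholtz energy (per mole of molecules,
# divided by RT) together with the analytic packing-fraction derivative that
# yields the compressibility factor. `x` may be complex (used for
# composition-derivative propagation); `rho` is a real number density in A^-3.
.eos_eval <- function(pre, rho, x) {
  n <- pre$n
  m <- pre$m; d <- pre$d
  zeta <- (pi / 6) * rho * c(
    sum(x * m), sum(x * m * d), sum(x * m * d^2), sum(x * m * d^3))
  eta <- zeta[4]
  if (Re(eta) >= 0.7405) {
    stop(sprintf("packing fraction %.4f >= 0.7405: density out of range",
                 Re(eta)))
  }
  mbar <- sum(x * m)
  z0 <- zeta[1]; z1 <- zeta[2]; z2 <- zeta[3]; z3 <- eta
  om <- 1 - z3

  # --- hard-sphere / hard-chain ---
  a_hs <- (3 * z1 * z2 / om + z2^3 / (z3 * om^2) +
             (z2^3 / z3^2 - z0) * log(om)) / z0
  g_ij <- 1 / om + pre$dstar * 3 * z2 / om^2 + pre$dstar^2 * 2 * z2^2 / om^3
  g_ii <- diag(g_ij)
  a_hc <- mbar * a_hs - sum(x * (m - 1) * log(g_ii))

  Z_hs <- z3 / om + 3 * z1 * z2 / (z0 * om^2) + (3 - z3) * z2^3 / (z0 * om^3)
  rho_dg <- z3 / om^2 +
    pre$dstar * (3 * z2 / om^2 + 6 * z2 * z3 / om^3) +
    pre$dstar^2 * (4 * z2^2 / om^3 + 6 * z2^2 * z3 / om^4)
  Z_hc <- mbar * Z_hs - sum(x * (m - 1) / g_ii * diag(rho_dg))

  # --- dispersion ---
  mm <- outer(x * m, x * m)
  uT <- pre$u_ij / pre$T
  s3 <- pre$sig_ij^3
  m2es3 <- sum(mm * uT * s3)
  m2e2s3 <- sum(mm * uT^2 * s3)
  w1 <- (mbar - 1) / mbar
  w2 <- w1 * (mbar - 2) / mbar
  ai <- .PC_A[, 1] + w1 * .PC_A[, 2] + w2 * .PC_A[, 3]
  bi <- .PC_B[, 1] + w1 * .PC_B[, 2] + w2 * .PC_B[, 3]
  etap <- eta^(0:6)
  I1 <- sum(ai * etap)
  I2 <- sum(bi * etap)
  dI1 <- sum(ai * (1:7) * etap)   # d(eta*I1)/d(eta)
  dI2 <- sum(bi * (1:7) * etap)
  C1 <- 1 / (1 + mbar * (8 * eta - 2 * eta^2) / om^4 +
               (1 - mbar) * (20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4) /
               (om * (2 - eta))^2)
  C2 <- -C1^2 * (mbar * (-4 * eta^2 + 20 * eta + 8) / om^5 +
                   (1 - mbar) * (2 * eta^3 + 12 * eta^2 - 48 * eta + 40) /
                   (om * (2 - eta))^3)
  a_disp <- -2 * pi * rho * I1 * m2es3 - pi * rho * mbar * C1 * I2 * m2e2s3
  Z_disp <- -2 * pi * rho * dI1 * m2es3 -
    pi * rho * mbar * (C1 * dI2 + C2 * eta * I2) * m2e2s3

  # --- association (2B) ---
  assoc <- pre$assoc
  X_full <- rep(if (is.complex(x)) 1 + 0i else 1, n)
  a_assoc <- 0 * mbar
  Z_assoc <- 0 * mbar
  delta_full <- NULL
  if (length(assoc) > 0L) {
    ia <- assoc
    delta <- (pre$sig_ij^3 * pre$kap_ij * pre$f_ij * g_ij)[ia, ia, drop = FALSE]
    X <- .solve_site_fractions(rho * delta, x[ia])
    X_full[ia] <- X
    a_assoc <- sum(x[ia] * (2 * log(X) - X + 1))
    # d(a_assoc)/d(rho) at fixed X (site balances are stationary):
    rho_ddelta <- (pre$sig_ij^3 * pre$kap_ij * pre$f_ij *
                     rho_dg)[ia, ia, drop = FALSE]
    XX <- outer(x[ia] * X, x[ia] * X)
    Z_assoc <- -rho * sum(XX * (delta + rho_ddelta))
    delta_full <- matrix(0, n, n)
    if (!is.complex(x)) delta_full[ia, ia] <- delta
  }

  list(
    hc = a_hc, disp = a_disp, assoc = a_assoc,
    total = a_hc + a_disp + a_assoc,
    Z = 1 + Z_hc + Z_disp + Z_assoc,
    eta = eta, X = X_full, delta = delta_full, g_ij = g_ij
  )
}

.check_composition <- function(x, n) {
  if (length(x) != n) stop("composition length does not match fluid")
  if (any(x < -1e-15)) stop("mole fractions must be nonnegative")
  if (abs(sum(x) - 1) > 1e-12) stop("mole fractions must sum to 1 (1e-12)")
  pmax(x, 0)
}

#' Residual Helmholtz energy of a PC-SAFT mixture
#'
#' Evaluates the reduced residual Helmholtz energy a^res/RT per mole of
#' molecules at a given temperature, number density and composition, split
#' into its hard-chain, dispersion and association contributions.
#'
#' @param fluid a [pcsaft_fluid()] object.
#' @param T temperature in K.
#' @param rho total number density in molecules per m^3.
#' @param x mole fractions in the fluid's component order.
#' @return a list with elements `hc`, `disp`, `assoc`, `total` (all
#'   dimensionless), the packing fraction `eta`, and the compressibility
#'   factor `Z` implied by the analytic packing-fraction derivative.
#' @export
residual_helmholtz <- function(fluid, T, rho, x) {
  stopifnot(inherits(fluid, "pcsaft_fluid"))
  x <- .check_composition(x, fluid$n)
  if (!is.numeric(rho) || rho <= 0) stop("rho must be positive (m^-3)")
  pre <- .fluid_tx(fluid, T)
  ev <- .eos_eval(pre, rho * 1e-30, x)
  list(hc = Re(ev$hc), disp = Re(ev$disp), assoc = Re(ev$assoc),
       total = Re(ev$total), eta = Re(ev$eta), Z = Re(ev$Z))
}

#' Solve the Wertheim 2B association site balances
#'
#' Returns the fraction of association sites not bonded for every component
#' (1 for non-associating components) and the association-strength matrix.
#' Each 2B molecule carries one donor and one acceptor site; by symmetry the
#' two site fractions are equal and a single value per component is reported.
#'
#' @inheritParams residual_helmholtz
#' @return a list with `X` (named site fractions) and `delta` (association
#'   strength matrix in m^3).
#' @export
solve_association <- function(fluid, T, rho, x) {
  stopifnot(inherits(fluid, "pcsaft_fluid"))
  x <- .check_composition(x, fluid$n)
  pre <- .fluid_tx(fluid, T)
  ev <- .eos_eval(pre, rho * 1e-30, x)
  X <- Re(ev$X); names(X) <- fluid$ids
  delta <- if (is.null(ev$delta)) matrix(0, fluid$n, fluid$n) else Re(ev$delta)
  delta <- delta * 1e-30   # A^3 -> m^3
  dimnames(delta) <- list(fluid$ids, fluid$ids)
  list(X = X, delta = delta)
}

#' Pressure and compressibility factor at given density
#'
#' @inheritParams residual_helmholtz
#' @return list with `P` (Pa) and `Z` (dimensionless),
#'   via Z = 1 + eta d(a^res/RT)/d(eta) and P = Z rho k_B T.
#' @export
pressure_and_Z <- function(fluid, T, rho, x) {
  stopifnot(inherits(fluid, "pcsaft_fluid"))
  x <- .check_composition(x, fluid$n)
  pre <- .fluid_tx(fluid, T)
  ev <- .eos_eval(pre, rho * 1e-30, x)
  Z <- Re(ev$Z)
  list(P = Z * rho * KB_SI * T, Z = Z)
}

# Pressure (Pa) as a function of packing fraction for fixed T, x. Returns the
# densities too so the caller can convert roots back.
.pressure_of_eta <- function(pre, eta, x) {
  smd3 <- sum(x * pre$m * pre$d^3)
  rho <- 6 * eta / (pi * smd3)           # A^-3
  ev <- .eos_eval(pre, rho, x)
  list(P = Re(ev$Z) * rho * 1e30 * KB_SI * pre$T, Z = Re(ev$Z), rho = rho)
}

#' Solve the equation of state for density
#'
#' Finds the number density at which the model pressure equals the specified
#' pressure. The packing-fraction axis (1e-10, 0.7404) is scanned for sign
#' changes of P(eta) - P and each bracket is refined; the highest-density
#' root is returned for `phase = "liquid"`, the lowest for `phase = "vapor"`.
#' When several roots exist the one with the lower residual Gibbs energy is
#' flagged as `stable`.
#'
#' @inheritParams residual_helmholtz
#' @param P pressure in Pa.
#' @param phase `"liquid"` or `"vapor"`.
#' @return a `mixture_state` list: `T`, `P`, `x`, `rho` (m^-3), `eta`, `Z`,
#'   `phase`, `stable`, and `rho_molar` (mol m^-3).
#' @export
solve_density <- function(fluid, T, P, x, phase = c("liquid", "vapor")) {
  phase <- match.arg(phase)
  stopifnot(inherits(fluid, "pcsaft_fluid"))
  if (!is.numeric(P) || P <= 0) stop("P must be positive (Pa)")
  x <- .check_composition(x, fluid$n)
  pre <- .fluid_tx(fluid, T)

  etas <- c(10^seq(-10, -5, by = 1), seq(1e-4, 0.7404, length.out = 120))
  f <- vapply(etas, function(e) .pressure_of_eta(pre, e, x)$P - P, numeric(1))
  sc <- which(f[-1] * f[-length(f)] <= 0 & is.finite(f[-1]) &
                is.finite(f[-length(f)]))
  if (length(sc) == 0L) {
    stop(sprintf(
      "no density root for T = %g K, P = %g Pa (eta scanned 1e-10..0.7404)",
      T, P))
  }
  roots <- vapply(sc, function(k) {
    uniroot(function(e) .pressure_of_eta(pre, e, x)$P - P,
            lower = etas[k], upper = etas[k + 1L],
            tol = .Machine$double.eps, maxiter = 2000L)$root
  }, numeric(1))
  roots <- sort(unique(roots))

  g_res <- function(e) {
    smd3 <- sum(x * pre$m * pre$d^3)
    rho <- 6 * e / (pi * smd3)
    ev <- .eos_eval(pre, rho, x)
    Re(ev$total) + (Re(ev$Z) - 1) - log(Re(ev$Z))
  }
  pick <- if (phase == "liquid") which.max(roots) else which.min(roots)
  eta <- roots[pick]
  stable <- TRUE
  if (length(roots) > 1L) {
    gs <- vapply(roots, g_res, numeric(1))
    stable <- pick == which.min(gs)
  }
  # Newton polish: drives the pressure residual to machine level, so that
  # differences of fugacity coefficients between nearby states (activity and
  # osmotic coefficients at high dilution) stay meaningful.
  for (it in 1:5) {
    pe <- .pressure_of_eta(pre, eta, x)
    r <- pe$P - P
    if (abs(r) <= 1e-12 * P) break
    h <- 1e-7 * eta
    dP <- (.pressure_of_eta(pre, eta + h, x)$P -
             .pressure_of_eta(pre, eta - h, x)$P) / (2 * h)
    step <- r / dP
    if (!is.finite(step) || abs(step) > 0.05 * eta) break
    eta <- eta - step
  }
  pe <- .pressure_of_eta(pre, eta, x)
  if (abs(pe$P - P) / P > 1e-9) {
    stop(sprintf("density root refinement failed (residual %.3e relative)",
                 abs(pe$P - P) / P))
  }
  state <- list(T = T, P = P, x = stats::setNames(x, fluid$ids),
                rho = pe$rho * 1e30, eta = eta, Z = pe$Z,
                phase = phase, stable = stable,
                rho_molar = pe$rho * 1e30 / N_AVOGADRO,
                n_roots = length(roots))
  class(state) <- "mixture_state"
  state
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf("mixture state (%s%s): T = %.2f K, P = %.6g Pa\n", x$phase,
              if (x$stable) "" else ", metastable", x$T, x$P))
  cat("  x:", paste(sprintf("%s = %.6g", names(x$x), x$x), collapse = ", "),
      "\n")
  cat(sprintf("  rho = %.6e m^-3 (%.4f mol L^-1), eta = %.6f, Z = %.6e\n",
              x$rho, x$rho_molar / 1000, x$eta, x$Z))
  invisible(x)
}

# Total reduced residual Helmholtz energy A^res/(N kT) as a function of the
# (unnormalised) composition at fixed T and total number density. Used with a
# complex perturbation of one mole fraction to obtain composition partials.
.ares_of_x <- function(pre, rho, x) {
  .eos_eval(pre, rho, x)$total
}

#' Log fugacity coefficients of a mixture
#'
#' Solves the density at (T, P, x) for the requested phase, then forms
#' ln phi_i = mu_i^res/RT - ln Z. Residual chemical potentials are obtained
#' from composition partial derivatives of the reduced residual Helmholtz
#' energy at constant temperature and total density (complex-step
#' differentiation, accurate to machine precision).
#'
#' @inheritParams solve_density
#' @param state optionally, a pre-solved `mixture_state` (skips the density
#'   solve; `P` and `phase` are then ignored).
#' @return named numeric vector of ln phi_i; the solved state is attached as
#'   attribute `"state"`.
#' @export
ln_fugacity_coefficients <- function(fluid, T, P, x,
                                     phase = c("liquid", "vapor"),
                                     state = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(fluid, "pcsaft_fluid"))
  if (is.null(state)) state <- solve_density(fluid, T, P, x, phase)
  x <- .check_composition(unname(state$x), fluid$n)
  pre <- .fluid_tx(fluid, T)
  rho <- state$rho * 1e-30
  ev <- .eos_eval(pre, rho, x)
  a <- Re(ev$total); Z <- Re(ev$Z)
  h <- 1e-200
  dadx <- vapply(seq_len(fluid$n), function(i) {
    xp <- as.complex(x)
    xp[i] <- xp[i] + h * 1i
    Im(.ares_of_x(pre, rho, xp)) / h
  }, numeric(1))
  mu_res <- a + (Z - 1) + dadx - sum(x * dadx)
  lnphi <- mu_res - log(Z)
  names(lnphi) <- fluid$ids
  attr(lnphi, "state") <- state
  attr(lnphi, "mu_res") <- stats::setNames(mu_res, fluid$ids)
  lnphi
}
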