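# Pure-component and binary PC-SAFT parameters: validation, temperature
# rules, and YAML serialization.

.SIGMA_T_RANGE <- c(273, 700)

.validate_component <- function(cp) {
  req <- c("id", "molar_mass", "m_seg", "sigma", "u_k", "eps_assoc_k",
           "kappa_assoc")
  for (f in req) {
    if (is.null(cp[[f]])) {
      stop(sprintf("component '%s': missing required field '%s'",
                   if (is.null(cp$id)) "<unnamed>" else cp$id, f))
    }
  }
  if (cp$m_seg <= 0) stop(sprintf("component '%s': m_seg must be > 0", cp$id))
  if (cp$u_k <= 0) stop(sprintf("component '%s': u_k must be > 0", cp$id))
  if (cp$molar_mass <= 0) {
    stop(sprintf("component '%s': molar_mass must be > 0", cp$id))
  }
  if (cp$kappa_assoc < 0 || cp$eps_assoc_k < 0) {
    stop(sprintf("component '%s': association parameters must be >= 0", cp$id))
  }
  # A component is associating exactly when kappa > 0; a 2B scheme then
  # requires a positive association energy.
  if (cp$kappa_assoc > 0 && is.null(cp$n_sites)) cp$n_sites <- "2B"
  if (cp$kappa_assoc == 0) cp$n_sites <- "none"
  Tchk <- seq(.SIGMA_T_RANGE[1], .SIGMA_T_RANGE[2], by = 10)
  sg <- vapply(Tchk, function(T) sigma_at(cp, T), numeric(1))
  if (any(sg <= 0)) {
    stop(sprintf("component '%s': sigma(T) must be positive on [273, 700] K",
                 cp$id))
  }
  class(cp) <- "component_parameters"
  cp
}

#' Segment diameter at temperature
#'
#' Constant-diameter components return their constant regardless of
#' temperature. Components with a three-term exponential diameter rule
#' (water here) return
#' `base + a1 exp(b1 T) + a2 exp(b2 T)` in angstroms.
#'
#' @param component a `component_parameters` record.
#' @param T temperature in K (positive).
#' @return segment diameter in angstroms.
#' @export
sigma_at <- function(component, T) {
  if (!is.numeric(T) || any(T <= 0)) stop("temperature must be positive (K)")
  s <- component$sigma
  if (is.numeric(s) && length(s) == 1L) return(rep(s, length(T))[seq_along(T)])
  if (is.list(s) && identical(s$type, "temperature_exponential")) {
    return(s$base + s$a1 * exp(s$b1 * T) + s$a2 * exp(s$b2 * T))
  }
  stop(sprintf("component '%s': unrecognised sigma specification",
               component$id))
}

.normalise_pair <- function(pair) sort(as.character(pair))

.validate_binary <- function(bi, comp_ids) {
  if (is.null(bi$pair) || length(bi$pair) != 2L) {
    stop("binary interaction: field 'pair' must name two components")
  }
  unknown <- setdiff(as.character(bi$pair), comp_ids)
  if (length(unknown) > 0L) {
    stop("binary interaction references unknown component(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(bi$kij_ref)) stop("binary interaction: missing field 'kij_ref'")
  if (is.null(bi$kij_slope)) bi$kij_slope <- 0
  Tchk <- seq(.SIGMA_T_RANGE[1], .SIGMA_T_RANGE[2], by = 25)
  if (any(abs(bi$kij_ref + bi$kij_slope * (Tchk - 298.15)) >= 1)) {
    stop("binary interaction: |kij(T)| must stay below 1 on [273, 700] K")
  }
  bi$pair <- .normalise_pair(bi$pair)
  bi
}

#' Load a PC-SAFT parameter set from a YAML file
#'
#' The file holds a `components` block (one record per component with fields
#' `id`, `molar_mass` (g/mol), `m_seg`, `sigma` (angstrom constant or a
#' `temperature_exponential` rule), `u_k` (K), `eps_assoc_k` (K),
#' `kappa_assoc`, `n_sites`) and a `binary_interactions` block (records with
#' `pair`, `kij_ref` at 298.15 K, and an optional per-kelvin `kij_slope`).
#' The packaged fixture `table1.yaml` carries the glycine / l-alanine / water
#' parameter set used throughout.
#'
#' @param source path to a YAML parameter file.
#' @return a `pcsaft_params` object: list with `components` (named list of
#'   `component_parameters`) and `binary_interactions`.
#' @export
#' @examples
#' p <- load_parameter_set(meltsol_example("table1.yaml"))
#' p$components$glycine$m_seg
load_parameter_set <- function(source) {
  if (!file.exists(source)) stop("parameter file not found: ", source)
  raw <- yaml::read_yaml(source)
  comps <- raw$components
  if (is.null(comps)) comps <- list()
  comps <- lapply(comps, .validate_component)
  names(comps) <- vapply(comps, function(cp) cp$id, character(1))
  if (anyDuplicated(names(comps))) stop("duplicate component ids")
  bis <- raw$binary_interactions
  if (is.null(bis)) bis <- list()
  bis <- lapply(bis, .validate_binary, comp_ids = names(comps))
  out <- list(components = comps, binary_interactions = bis)
  class(out) <- "pcsaft_params"
  out
}

#' Write a parameter set back to YAML
#'
#' Inverse of [load_parameter_set()]; a round trip reproduces every numeric
#' value exactly (values are emitted with full precision).
#'
#' @param params a `pcsaft_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "pcsaft_params"))
  strip <- function(cp) {
    cp <- unclass(cp)
    cp[c("id", "molar_mass", "m_seg", "sigma", "u_k", "eps_assoc_k",
         "kappa_assoc", "n_sites")]
  }
  obj <- list(
    components = lapply(unname(params$components), strip),
    binary_interactions = lapply(params$binary_interactions, function(bi) {
      list(pair = as.list(bi$pair), kij_ref = bi$kij_ref,
           kij_slope = bi$kij_slope)
    })
  )
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @export
print.pcsaft_params <- function(x, ...) {
  cat("PC-SAFT parameter set:", length(x$components), "component(s),",
      length(x$binary_interactions), "binary pair(s)\n")
  for (cp in x$components) {
    sg <- if (is.list(cp$sigma)) "sigma(T)" else sprintf("%.4f A", cp$sigma)
    cat(sprintf("  %-12s m = %.4f, %s, u/k = %.2f K, assoc %s\n",
                cp$id, cp$m_seg, sg, cp$u_k,
                if (cp$kappa_assoc > 0) cp$n_sites else "none"))
  }
  invisible(x)
}

# Find the declared interaction record for an unordered pair, or NULL.
.find_pair <- function(pairs, i, j) {
  key <- .normalise_pair(c(i, j))
  for (bi in pairs) if (identical(bi$pair, key)) return(bi)
  NULL
}

#' Binary interaction parameter at temperature
#'
#' `kij(T) = kij_ref + kij_slope (T - 298.15)`; symmetric in the component
#' order.
#'
#' @param params a `pcsaft_params` object (or a list of binary records).
#' @param i,j component ids.
#' @param T temperature in K.
#' @param missing_zero if `TRUE`, an undeclared pair returns 0 instead of an
#'   error.
#' @return dimensionless k_ij.
#' @export
kij_at <- function(params, i, j, T, missing_zero = FALSE) {
  pairs <- if (inherits(params, "pcsaft_params")) {
    params$binary_interactions
  } else {
    params
  }
  kij_lookup(pairs, i, j, T, missing_zero)
}

#' @rdname kij_at
#' @param pairs list of binary interaction records.
#' @export
kij_lookup <- function(pairs, i, j, T, missing_zero = FALSE) {
  bi <- .find_pair(pairs, i, j)
  if (is.null(bi)) {
    if (missing_zero) return(rep(0, length(T))[seq_along(T)])
    stop(sprintf("no binary interaction declared for pair (%s, %s)", i, j))
  }
  bi$kij_ref + bi$kij_slope * (T - 298.15)
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return full path (or a character vector of file names).
#' @export
meltsol_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "meltsol")))
  }
  path <- system.file("extdata", file, package = "meltsol")
  if (!nzchar(path)) stop("no packaged file named ", file)
  path
}
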