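# Shared fixtures: the packaged parameter set and small in-code parameter
# builders for oracle tests.

table1 <- load_parameter_set(meltsol_example("table1.yaml"))

# A minimal parameter set built in code: `comps` is a list of lists with
# fields (id, M, m, sigma, u, eps, kappa); pairs is a list of
# list(pair=, kij_ref=, kij_slope=).
make_params <- function(comps, pairs = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  obj <- list(
    components = lapply(comps, function(cp) list(
      id = cp$id, molar_mass = cp$M, m_seg = cp$m, sigma = cp$sigma,
      u_k = cp$u, eps_assoc_k = if (is.null(cp$eps)) 0 else cp$eps,
      kappa_assoc = if (is.null(cp$kappa)) 0 else cp$kappa,
      n_sites = if (is.null(cp$kappa) || cp$kappa == 0) "none" else "2B")),
    binary_interactions = pairs)
  yaml::write_yaml(obj, tmp, precision = 17L)
  load_parameter_set(tmp)
}

# single non-associating chain/sphere component
sphere_params <- make_params(list(
  list(id = "sphere", M = 40, m = 1.0, sigma = 3.5, u = 200)))

chain_params <- make_params(list(
  list(id = "chain", M = 86, m = 3.0, sigma = 3.8, u = 240)))

# two associating 2B components (water-like and solute-like)
assoc2_params <- make_params(list(
  list(id = "aw", M = 18, m = 1.2047, sigma = 3.0, u = 353.94,
       eps = 2425.67, kappa = 0.0451),
  list(id = "as", M = 75, m = 4.8, sigma = 2.4, u = 220,
       eps = 2600, kappa = 0.04)),
  pairs = list(list(pair = c("aw", "as"), kij_ref = -0.05, kij_slope = 0)))

glycine_melting <- melting_properties("glycine", 569, 21000,
                                      u_T_fus = 7, u_dH_fus = 4000)
alanine_melting <- melting_properties("l-alanine", 608, 22000,
                                      u_T_fus = 9, u_dH_fus = 5000)
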