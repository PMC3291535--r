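#' Model parameters for the minimal distance constraint model
#'
#' The mDCM free-energy functional is parameterized by the solvent
#' compensation enthalpy `u_sol` (gained when a hydrogen bond breaks), the
#' native-torsion enthalpy/entropy pair (`v_nat`, `delta_nat`), the
#' disordered-torsion pair (`v_dis`, `delta_dis`, fixed by convention), and a
#' linear map from hydrogen-bond enthalpy to its entropy weight,
#' `gamma_hb(u) = gamma_intercept + gamma_slope * u`, clamped at zero.
#'
#' `u_sol`, `v_nat` and `delta_nat` are the quantities adjusted when fitting
#' an experimental heat-capacity curve; the remaining values are treated as
#' fixed model conventions.  Enthalpies are kcal/mol; entropy weights are pure
#' numbers (multiplied by the gas constant internally).  The default
#' `delta_nat = 1.24` is the value used across the lysozyme dataset this model
#' was developed on; `u_sol` and `v_nat` defaults are the wild-type dataset
#' means.  The gamma map and the disordered-torsion values are documented
#' reconstructions (the defaults keep every gamma below `delta_nat`, so the
#' entropy-ascending pebble-game insertion order is covalent bonds, hydrogen
#' bonds, native torsions, then disordered torsions).
#'
#' @param u_sol Solvent compensation enthalpy per broken H-bond, kcal/mol.
#' @param v_nat,delta_nat Native torsion enthalpy (kcal/mol) and entropy
#'   weight (pure number).
#' @param v_dis,delta_dis Disordered torsion enthalpy and entropy weight;
#'   must satisfy `v_nat < v_dis` and `delta_nat < delta_dis`.
#' @param gamma_slope,gamma_intercept Coefficients of the linear
#'   `gamma_hb(u_hb)` map.
#' @return An object of class `dcm_params` (a named list).
#' @examples
#' p <- dcm_params(u_sol = -2.0, v_nat = -0.3)
#' hbond_entropy(-4, p)
#' @export
dcm_params <- function(u_sol = -1.98, v_nat = -0.23, delta_nat = 1.24,
                       v_dis = 0, delta_dis = 2.0,
                       gamma_slope = 0.125, gamma_intercept = 1.0) {
  stopifnot(is.finite(u_sol), is.finite(v_nat), is.finite(delta_nat))
  if (!(v_nat < v_dis)) {
    stop("invalid parameters: v_nat (", v_nat, ") must be < v_dis (", v_dis, ")")
  }
  if (!(delta_nat < delta_dis)) {
    stop("invalid parameters: delta_nat (", delta_nat,
         ") must be < delta_dis (", delta_dis, ")")
  }
  structure(
    list(u_sol = u_sol, v_nat = v_nat, delta_nat = delta_nat,
         v_dis = v_dis, delta_dis = delta_dis,
         gamma_slope = gamma_slope, gamma_intercept = gamma_intercept),
    class = "dcm_params")
}

#' @export
print.dcm_params <- function(x, ...) {
  cat("mDCM parameters\n")
  cat(sprintf("  u_sol     %8.3f kcal/mol\n", x$u_sol))
  cat(sprintf("  v_nat     %8.3f kcal/mol   delta_nat %6.3f\n",
              x$v_nat, x$delta_nat))
  cat(sprintf("  v_dis     %8.3f kcal/mol   delta_dis %6.3f\n",
              x$v_dis, x$delta_dis))
  cat(sprintf("  gamma_hb(u) = max(0, %.3f %+.3f u)\n",
              x$gamma_intercept, x$gamma_slope))
  invisible(x)
}

#' Entropy weight of a hydrogen bond from its enthalpy
#'
#' The entropy weight of each fluctuating hydrogen bond is a linear function
#' of its enthalpy: stronger (more negative) bonds confine more phase space
#' and carry less entropy.  The result is clamped at zero.
#'
#' @param u_hb Hydrogen-bond enthalpy, kcal/mol (scalar or vector).
#' @param params A [dcm_params()] object.
#' @return Pure-number entropy weight(s), `>= 0`.
#' @export
hbond_entropy <- function(u_hb, params = dcm_params()) {
  stopifnot(all(is.finite(u_hb)))
  pmax(0, params$gamma_intercept + params$gamma_slope * u_hb)
}

#' Network-building configuration
#'
#' Geometry cutoffs, bar multiplicities and empirical hydrogen-bond potential
#' constants used when turning a structure into a body-bar constraint
#' network.  The hydrogen-bond energy function is a reconstruction of the
#' Mayo-type 12-10 potential with an angular factor (the exact modified form
#' used in prior mDCM work is unpublished); all constants live here so
#' alternatives can be explored.
#'
#' @param ... Named overrides of the defaults, at the top level (e.g.
#'   `energy_ceiling = -0.5`) or as nested lists (`hbond`, `bars`).
#' @return A nested list of class `dcm_network_config`.
#' @export
dcm_network_config <- function(...) {
  cfg <- list(
    hbond = list(
      v0 = 8.0,             # well depth, kcal/mol
      d0 = 2.8,             # donor-acceptor equilibrium distance, Angstrom
      cutoff_da = 3.6,      # donor-acceptor distance cutoff
      cutoff_ha = 2.5,      # hydrogen-acceptor distance cutoff
      min_angle_dha = 100,  # minimum donor-H-acceptor angle, degrees
      energy_ceiling = -0.1,# discard weaker (less favourable) candidates
      salt_d0 = 3.2,        # equilibrium distance for salt bridges
      salt_cutoff = 4.6     # distance cutoff for salt bridges
    ),
    bars = list(
      covalent_generic = 5, # single bond: locks lengths/angles, keeps dihedral
      covalent_locked = 6,  # peptide/ring/terminal/double bonds
      hbond_main = 5,       # bars between donor hydrogen and acceptor
      hbond_antecedent = 1, # extra bar to the acceptor antecedent
      torsion = 1           # native torsion force
    ),
    covalent = list(
      heavy_cut = 1.8,      # heavy-heavy bond detection cutoff, Angstrom
      heavy_cut_s = 2.1,    # cutoff when sulfur is involved
      h_cut = 1.25,         # X-H bond cutoff
      double_co = 1.30,     # C-O below this is a double bond
      double_cn = 1.38      # C-N below this is conjugated (e.g. guanidinium)
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      hit <- FALSE
      for (blk in names(cfg)) {
        if (nm %in% names(cfg[[blk]])) {
          cfg[[blk]][[nm]] <- dots[[nm]]
          hit <- TRUE
        }
      }
      if (!hit) stop("unknown network config entry: ", nm)
    }
  }
  structure(cfg, class = "dcm_network_config")
}

#' Ensemble and landscape configuration
#'
#' @param n_samples Monte-Carlo frameworks per macrostate.
#' @param exhaustive_limit Macrostates with at most this many distinct
#'   frameworks are enumerated exactly instead of sampled.
#' @param q_tol Convergence tolerance on the self-consistent independence
#'   probabilities.
#' @param max_iter Maximum self-consistency iterations.
#' @param grid_stride Landscape grid stride (1 = full grid; coarse grids are
#'   refined locally around the detected minima).
#' @param rho_floor Gibbs weights below this fraction of the basin maximum are
#'   dropped when no saddle confines the basin.
#' @return A list of class `dcm_ensemble_config`.
#' @export
dcm_ensemble_config <- function(n_samples = 200, exhaustive_limit = 1024,
                                q_tol = 1e-4, max_iter = 50,
                                grid_stride = 1, rho_floor = 1e-9) {
  stopifnot(n_samples >= 1, grid_stride >= 1)
  structure(list(n_samples = n_samples, exhaustive_limit = exhaustive_limit,
                 q_tol = q_tol, max_iter = max_iter,
                 grid_stride = grid_stride, rho_floor = rho_floor),
            class = "dcm_ensemble_config")
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) file with optional `network:`, `ensemble:` and
#' `fit:` blocks and returns the corresponding config objects with defaults
#' filled in.
#'
#' @param path Path to a YAML/JSON file.
#' @return A list with elements `network`, `ensemble`, `fit`, `params`.
#' @export
read_dcm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    network = do.call(dcm_network_config, raw$network %||% list()),
    ensemble = do.call(dcm_ensemble_config, raw$ensemble %||% list()),
    fit = raw$fit %||% list(),
    params = do.call(dcm_params, raw$params %||% list())
  )
}
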