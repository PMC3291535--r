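# Quantified stability/flexibility relationships: the flexibility index and
# the cooperativity-correlation matrix, per framework and basin-averaged.

#' Flexibility index of each rotatable bond in one framework
#'
#' Bonds in a flexible cluster receive `+A/H` (density of independent
#' degrees of freedom); bonds in an over-constrained cluster receive `-B/D`
#' (density of redundant constraints, multiplied by -1); isostatic bonds
#' receive 0.  With `clamp = TRUE` (default) over-constrained densities are
#' capped at 1 so the index stays within `[-1, 1]` (on dense toy networks
#' `B` can exceed `D`).
#'
#' @param decomp A `dcm_rigidity` from [run_pebble_game()].
#' @param clamp Cap magnitudes at 1.
#' @return Tibble with columns `bond_id`, `cluster`, `label`, `f`.
#' @export
flexibility_index <- function(decomp, clamp = TRUE) {
  stopifnot(inherits(decomp, "dcm_rigidity"))
  cl <- decomp$clusters
  fcl <- cluster_f_values(cl, clamp)
  tibble::tibble(
    bond_id = decomp$bonds$bond_id,
    cluster = decomp$bonds$cluster,
    label = cl$label[decomp$bonds$cluster],
    f = fcl[decomp$bonds$cluster])
}

cluster_f_values <- function(cl, clamp = TRUE) {
  dens_over <- cl$b / pmax(cl$n_bonds, 1L)
  if (clamp) dens_over <- pmin(1, dens_over)
  f <- ifelse(cl$label == "flexible", cl$a / pmax(cl$n_bonds, 1L),
              ifelse(cl$label == "overconstrained", -dens_over, 0))
  f[cl$n_bonds == 0] <- 0
  f
}

#' Cooperativity-correlation entry for a bond pair in one framework
#'
#' Equal to the shared cluster's flexibility value when bonds `m` and `n`
#' are in the same flexible, isostatic or over-constrained cluster, and 0
#' when they belong to distinct clusters (of any type — two different rigid
#' clusters are uncorrelated).
#'
#' @inheritParams flexibility_index
#' @param m,n Rotatable-bond ids.
#' @export
cc_entry <- function(decomp, m, n, clamp = TRUE) {
  stopifnot(inherits(decomp, "dcm_rigidity"))
  bm <- match(m, decomp$bonds$bond_id)
  bn <- match(n, decomp$bonds$bond_id)
  stopifnot(!is.na(bm), !is.na(bn))
  cm <- decomp$bonds$cluster[bm]
  if (cm != decomp$bonds$cluster[bn]) return(0)
  cluster_f_values(decomp$clusters, clamp)[cm]
}

#' Full cooperativity-correlation matrix of one framework
#'
#' @inheritParams flexibility_index
#' @return Symmetric matrix over rotatable bonds; the diagonal equals the
#'   flexibility index.
#' @export
cc_matrix <- function(decomp, clamp = TRUE) {
  stopifnot(inherits(decomp, "dcm_rigidity"))
  n <- nrow(decomp$bonds)
  fcl <- cluster_f_values(decomp$clusters, clamp)
  cc <- matrix(0, n, n)
  for (cl in seq_len(nrow(decomp$clusters))) {
    idx <- which(decomp$bonds$cluster == cl)
    if (length(idx) > 0) cc[idx, idx] <- fcl[cl]
  }
  dimnames(cc) <- list(decomp$bonds$bond_id, decomp$bonds$bond_id)
  cc
}

#' Ensemble-averaged QSFR profile (FI and CC over the native basin)
#'
#' Runs the full pipeline: heat-capacity scan to locate the melting
#' temperature, landscape at `Tm`, native-basin identification, and
#' Gibbs-weighted averaging of the per-macrostate mechanical means of the
#' flexibility index and cooperativity correlation.  Per-residue values
#' aggregate each residue's phi/psi bond values (mean by default; proline
#' has only psi).
#'
#' @param net A `dcm_network`.
#' @param params A [dcm_params()].
#' @param T_grid Temperature grid for the heat-capacity scan.
#' @param config A [dcm_ensemble_config()].
#' @param seed Integer seed.
#' @param landscape Optional pre-built `dcm_landscape` with mechanical
#'   averages (skips the Cp scan).
#' @param residue_reduce How residue-level FI summarizes the phi/psi bond
#'   values: `"mean"`, `"min"` or `"max"`.
#' @return A `dcm_qsfr` object: `fi_bond` tibble, `fi_residue` tibble (when
#'   residue labels exist), `cc` (bond-level matrix), `cc_residue`,
#'   `tm`, `provenance`.
#' @export
ensemble_qsfr <- function(net, params = dcm_params(),
                          T_grid = seq(250, 420, by = 5),
                          config = dcm_ensemble_config(), seed = 1,
                          landscape = NULL,
                          residue_reduce = c("mean", "min", "max")) {
  residue_reduce <- match.arg(residue_reduce)
  cache <- new_dcm_cache()
  if (is.null(landscape)) {
    hc <- heat_capacity(net, params, T_grid, config, seed, cache = cache)
    tm <- hc$tm
    landscape <- build_landscape(net, params, tm, config, seed,
                                 mech = FALSE, cache = cache)
  } else {
    tm <- landscape$temperature
  }

  basin <- find_native_basin(landscape, config)

  # mechanical averages only where the basin needs them, with the seeds the
  # landscape used, so the thermal and mechanical statistics agree
  plan <- bar_plan(net, params)
  fi <- rep(0, net$n_tor)
  cc <- matrix(0, net$n_tor, net$n_tor)
  for (i in seq_along(basin$members)) {
    row <- basin$members[i]
    j <- landscape$grid$n_nat[row]; k <- landscape$grid$n_hb[row]
    total <- choose(net$n_tor, j) * choose(net$n_hb_max, k)
    mode <- if (total <= max(config$exhaustive_limit,
                             landscape$meta$n_samples)) "exhaustive" else "mc"
    mac <- macro_eval(net, plan, params, j, k, tm, config, mode,
                      landscape$meta$n_samples,
                      seed = landscape$meta$seed + 1009L * j + k,
                      mech = TRUE, cache = cache)
    fi <- fi + basin$rho[i] * mac$mech$f
    cc <- cc + basin$rho[i] * mac$mech$cc
  }

  fi_bond <- tibble::tibble(bond_id = net$rotatable$bond_id,
                            residue_index = net$rotatable$residue_index,
                            angle = net$rotatable$angle, fi = fi)
  fi_residue <- NULL
  cc_residue <- NULL
  bb <- which(net$rotatable$angle %in% c("phi", "psi"))
  if (length(bb) > 0 && !all(is.na(net$rotatable$residue_index))) {
    red <- switch(residue_reduce, mean = mean, min = min, max = max)
    fi_residue <- fi_bond[bb, ] |>
      dplyr::group_by(.data$residue_index) |>
      dplyr::summarise(fi = red(.data$fi), .groups = "drop")
    res <- sort(unique(net$rotatable$residue_index[bb]))
    cc_residue <- matrix(0, length(res), length(res),
                         dimnames = list(res, res))
    for (a in seq_along(res)) {
      for (b in seq_along(res)) {
        ia <- bb[net$rotatable$residue_index[bb] == res[a]]
        ib <- bb[net$rotatable$residue_index[bb] == res[b]]
        cc_residue[a, b] <- mean(cc[ia, ib])
      }
    }
  }

  structure(
    list(fi_bond = fi_bond, fi_residue = fi_residue,
         cc = cc, cc_residue = cc_residue, tm = tm,
         basin = basin,
         provenance = list(seed = seed, n_samples = landscape$meta$n_samples,
                           params = params, residue_reduce = residue_reduce)),
    class = "dcm_qsfr")
}

#' @export
print.dcm_qsfr <- function(x, ...) {
  cat(sprintf("QSFR profile at Tm = %.2f K\n", x$tm))
  cat(sprintf("  bond FI range [%.3f, %.3f] over %d rotatable bonds\n",
              min(x$fi_bond$fi), max(x$fi_bond$fi), nrow(x$fi_bond)))
  if (!is.null(x$fi_residue)) {
    cat(sprintf("  residue FI over %d residues\n", nrow(x$fi_residue)))
  }
  invisible(x)
}
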