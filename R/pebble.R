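#' Run the (6,6) body-bar pebble game on an engaged framework
#'
#' Every body starts with 6 pebbles (its 6 trivial degrees of freedom; 6 are
#' withheld per connected component).  Bars are inserted in ascending order
#' of their entropy weight — quenched covalent bars first, ties broken by
#' kind (covalent < torsion < hbond) then constraint id — which yields the
#' lowest upper bound on the total conformational entropy.  Each bar is
#' either covered by a pebble (independent) or, after an exhaustive pebble
#' search fails, marked redundant.  Afterwards the a-priori rotatable bonds
#' are partitioned into clusters:
#'
#' * **flexible** — under-constrained regions, reported with the number of
#'   member rotatable bonds `H` and independent degrees of freedom `A`
#'   (independent disordered torsion test bars);
#' * **isostatic** — rigid with exactly the needed constraints;
#' * **over-constrained** — rigid with `B` redundant constraints among the
#'   `D` member rotatable bonds.
#'
#' @param net A `dcm_network`.
#' @param engaged_hb Logical vector over candidate hydrogen bonds (which are
#'   present in this framework).  Default: all present.
#' @param engaged_nat Logical vector over rotatable bonds (which torsions are
#'   natively engaged).  Default: none (all dihedrals disordered), which
#'   exposes the mechanical flexibility of the hydrogen-bond network.
#' @param params A [dcm_params()] (entropy weights set the insertion order).
#' @return An object of class `dcm_rigidity`: list with `bars` (per-bar
#'   tibble with independence labels), `bonds` (per rotatable bond: locked
#'   flag and cluster id), `clusters` (per cluster: label and counts),
#'   `free_pebbles`, `n_bodies`.
#' @export
run_pebble_game <- function(net, engaged_hb = rep(TRUE, net$n_hb_max),
                            engaged_nat = rep(FALSE, net$n_tor),
                            params = dcm_params()) {
  stopifnot(inherits(net, "dcm_network"),
            length(engaged_hb) == net$n_hb_max,
            length(engaged_nat) == net$n_tor)
  bars <- framework_bars(net, engaged_hb, engaged_nat, params)
  test_bond <- which(!engaged_nat)
  res <- .pg_analyze(net$n_bodies, bars$i, bars$j,
                     net$rotatable$i, net$rotatable$j, test_bond)
  bars$independent <- res$independent

  bonds <- tibble::tibble(
    bond_id = net$rotatable$bond_id,
    native = engaged_nat,
    locked = res$locked,
    cluster = res$bond_cluster)
  test_indep <- rep(NA, net$n_tor)
  test_indep[test_bond] <- res$test_independent
  bonds$dihedral_free <- ifelse(bonds$native, FALSE, test_indep)

  clusters <- tibble::tibble(
    cluster = seq_along(res$cluster_label),
    label = res$cluster_label,
    n_bonds = res$cluster_n_bonds,
    a = res$cluster_A,
    b = res$cluster_B)

  structure(
    list(bars = bars, bonds = bonds, clusters = clusters,
         free_pebbles = res$free_pebbles, n_bodies = net$n_bodies),
    class = "dcm_rigidity")
}

#' @export
print.dcm_rigidity <- function(x, ...) {
  cat("pebble-game rigidity decomposition\n")
  cat(sprintf("  bodies %d, engaged bars %d (%d independent, %d redundant)\n",
              x$n_bodies, nrow(x$bars), sum(x$bars$independent),
              sum(!x$bars$independent)))
  cat(sprintf("  free pebbles %d\n", x$free_pebbles))
  tab <- table(factor(x$clusters$label,
                      c("flexible", "isostatic", "overconstrained")))
  cat(sprintf("  clusters: %d flexible / %d isostatic / %d over-constrained\n",
              tab[["flexible"]], tab[["isostatic"]], tab[["overconstrained"]]))
  invisible(x)
}

#' Per-cluster counts of a rigidity decomposition
#'
#' Returns the cluster table: flexible clusters with `(H, A)` (rotatable
#' bonds, independent DOF), over-constrained clusters with `(D, B)`
#' (rotatable bonds, redundant constraints), isostatic clusters with neither.
#'
#' @param decomp A `dcm_rigidity` object from [run_pebble_game()].
#' @return Tibble with columns `cluster`, `label`, `n_bonds`, `a`, `b`.
#' @export
cluster_counts <- function(decomp) {
  stopifnot(inherits(decomp, "dcm_rigidity"))
  decomp$clusters
}

# Bare-bones rank interface (used by order-invariance tests and the DOF
# bookkeeping): run the game on explicit bar lists.
pebble_rank <- function(n_bodies, i, j) {
  res <- .pg_rank(n_bodies, as.integer(i), as.integer(j))
  list(independent = res$independent, free_pebbles = res$free_pebbles,
       rank = sum(res$independent))
}

#' Write a rigidity decomposition debug dump
#'
#' @param decomp A `dcm_rigidity`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rigidity_tsv <- function(decomp, path) {
  tab <- dplyr::left_join(decomp$bonds, decomp$clusters, by = "cluster")
  readr::write_tsv(tab, path)
  invisible(path)
}
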