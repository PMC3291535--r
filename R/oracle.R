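#' Rigidity-matrix oracle for body-bar frameworks
#'
#' Numerical cross-check of the pebble game, used by the synthetic-framework
#' generators to attach ground truth and by the test suite.  Bodies at
#' generic positions are connected by bars with generic attachment points;
#' the rank of the body-bar rigidity matrix counts independent bars, its
#' null space yields rigid clusters (bodies sharing one rigid motion), and
#' SVD rank queries on dihedral test rows reproduce the flexible-cluster
#' matroid decomposition.
#'
#' @name rigidity_oracle
NULL

# One rigidity-matrix row per bar.  coords: n x 3 body positions; bars:
# tibble/df with columns i, j.  Attachment points are jittered per bar for
# genericity (uses the current RNG stream).
rigidity_rows <- function(coords, i, j) {
  m <- length(i)
  rows <- matrix(0, m, 6 * nrow(coords))
  for (r in seq_len(m)) {
    pi_ <- coords[i[r], ] + stats::rnorm(3, sd = 0.37)
    pj_ <- coords[j[r], ] + stats::rnorm(3, sd = 0.37)
    d <- pi_ - pj_
    rows[r, (6 * (i[r] - 1) + 1):(6 * (i[r] - 1) + 3)] <- d
    rows[r, (6 * (i[r] - 1) + 4):(6 * (i[r] - 1) + 6)] <- crossprod3(pi_, d)
    rows[r, (6 * (j[r] - 1) + 1):(6 * (j[r] - 1) + 3)] <- -d
    rows[r, (6 * (j[r] - 1) + 4):(6 * (j[r] - 1) + 6)] <- -crossprod3(pj_, d)
  }
  rows
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

svd_rank <- function(m, tol = 1e-8) {
  if (nrow(m) == 0 || ncol(m) == 0) return(0L)
  sv <- svd(m, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv[1], 1))
}

null_basis <- function(m, tol = 1e-8) {
  s <- svd(m, nu = 0, nv = ncol(m))
  keep <- c(rep(FALSE, svd_rank(m, tol)), rep(TRUE, ncol(m) - svd_rank(m, tol)))
  s$v[, keep, drop = FALSE]
}

#' Decompose a framework with the rigidity-matrix oracle
#'
#' @param coords Matrix (n x 3) of generic body positions.
#' @param bar_i,bar_j Engaged bars, one entry per bar (atom indices).
#' @param rot_i,rot_j A-priori rotatable bonds.
#' @param test_bond Indices (into the rotatable bonds) of the disordered
#'   bonds probed with test bars.
#' @param tol Relative SVD tolerance.
#' @return List mirroring the pebble-game output: `rank`, `locked`,
#'   `bond_cluster`, `test_independent`, `clusters` tibble.
#' @export
oracle_decompose <- function(coords, bar_i, bar_j, rot_i, rot_j,
                             test_bond = seq_along(rot_i), tol = 1e-8) {
  n <- nrow(coords)
  nrot <- length(rot_i)
  M <- rigidity_rows(coords, bar_i, bar_j)
  r0 <- svd_rank(M, tol)
  N <- null_basis(M, tol)

  test_rows <- if (nrot > 0) rigidity_rows(coords, rot_i, rot_j) else
    matrix(0, 0, 6 * n)
  psi <- test_rows %*% N                         # motions seen by each bond

  locked <- rep(TRUE, nrot)
  if (nrot > 0) {
    locked <- sqrt(rowSums(psi^2)) <
      tol * 10 * pmax(sqrt(rowSums(test_rows^2)), 1)
  }

  # rigid clusters over bodies: identical (t, w) null-space blocks
  body_block <- matrix(0, n, ncol(N) * 6)
  for (b in seq_len(n)) {
    body_block[b, ] <- as.vector(N[(6 * (b - 1) + 1):(6 * b), , drop = FALSE])
  }
  cluster_of_bond <- rep(NA_integer_, nrot)
  rigid_rep <- integer(0)
  same_motion <- function(a, b) {
    sqrt(sum((body_block[a, ] - body_block[b, ])^2)) < tol * 100
  }
  for (bnd in which(locked)) {
    hit <- NA_integer_
    for (cid in seq_along(rigid_rep)) {
      if (same_motion(rot_i[bnd], rigid_rep[cid])) { hit <- cid; break }
    }
    if (is.na(hit)) { rigid_rep <- c(rigid_rep, rot_i[bnd]); hit <- length(rigid_rep) }
    cluster_of_bond[bnd] <- hit
  }
  # redundant-bar counts per rigid cluster: internal bars minus their rank
  rigid_B <- integer(length(rigid_rep))
  rigid_D <- tabulate(cluster_of_bond[locked], nbins = length(rigid_rep))
  bar_cluster <- rep(NA_integer_, length(bar_i))
  for (cid in seq_along(rigid_rep)) {
    internal <- which(vapply(seq_along(bar_i), function(r) {
      same_motion(bar_i[r], rigid_rep[cid]) &&
        same_motion(bar_j[r], rigid_rep[cid])
    }, logical(1)))
    if (length(internal) > 0) {
      rigid_B[cid] <- length(internal) -
        svd_rank(M[internal, , drop = FALSE], tol)
    }
    bar_cluster[internal] <- cid
  }
  # over-constrained regions holding no rotatable bond: remaining redundancy
  orphan_B <- (length(bar_i) - r0) - sum(rigid_B)

  # flexible components: matroid of test-bar rows in the quotient over M,
  # via fundamental circuits w.r.t. a greedy basis
  free <- intersect(test_bond, which(!locked))
  comp <- rep(NA_integer_, nrot)
  test_indep <- rep(NA, nrot)
  n_flex <- 0L
  flex_H <- integer(0); flex_A <- integer(0)
  if (length(free) > 0) {
    uf <- seq_along(free)
    findr <- function(x) { while (uf[x] != x) x <- uf[x]; x }
    basis <- integer(0)
    qrank <- function(rows_idx) {
      if (length(rows_idx) == 0) return(0L)
      svd_rank(rbind(M, test_rows[rows_idx, , drop = FALSE]), tol) - r0
    }
    for (k in seq_along(free)) {
      cand <- c(basis, free[k])
      if (qrank(cand) == length(cand)) {
        basis <- cand
        test_indep[free[k]] <- TRUE
      } else {
        test_indep[free[k]] <- FALSE
        for (bpos in seq_along(basis)) {
          without <- c(basis[-bpos], free[k])
          if (qrank(without) == length(without)) {
            # basis element is in the fundamental circuit -> same component
            ub <- which(free == basis[bpos])
            uf[findr(ub)] <- findr(k)
          }
        }
      }
    }
    roots <- vapply(seq_along(free), function(k) findr(k), integer(1))
    labs <- match(roots, unique(roots))
    comp[free] <- labs
    n_flex <- length(unique(roots))
    flex_H <- tabulate(labs, nbins = n_flex)
    flex_A <- vapply(seq_len(n_flex), function(cid) {
      sum(free[labs == cid] %in% basis)
    }, integer(1))
  }

  n_rigid <- length(rigid_rep)
  clusters <- tibble::tibble(
    cluster = seq_len(n_rigid + n_flex),
    label = c(ifelse(rigid_B > 0, "overconstrained", "isostatic"),
              rep("flexible", n_flex)),
    n_bonds = c(rigid_D, flex_H),
    a = c(rep(NA_integer_, n_rigid), flex_A),
    b = c(rigid_B, rep(NA_integer_, n_flex)))
  bond_cluster <- ifelse(locked, cluster_of_bond, comp + n_rigid)

  list(rank = r0, nullity = 6 * n - r0, locked = locked,
       bond_cluster = bond_cluster, test_independent = test_indep,
       clusters = clusters, orphan_redundant = orphan_B)
}
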