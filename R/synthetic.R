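#' Generate a toy body-bar framework with known rigidity
#'
#' Seed-deterministic generators for small frameworks whose rigidity
#' decomposition is known in closed form or attached from the
#' rigidity-matrix oracle ([oracle_decompose()]):
#'
#' * `rotor_chain` — open chain of 5-bar rotatable bonds; every bond is its
#'   own flexible cluster with `A = H = 1`.
#' * `ring` — cycle of 5-bar rotatable bonds; flexible for `n >= 7`
#'   (one cluster, `A = n - 6`), isostatic at `n = 6`, over-constrained with
#'   `B = 6 - n` redundant bars for `n < 6`.
#' * `locked_triangle` — two 6-bar bonds lock three bodies; `extra_bars`
#'   additional bars across the closing pair are all redundant.
#' * `over_braced_pair` — two bodies, `6 + extra_bars` bars; `extra_bars`
#'   redundant.
#' * `random` — random spanning tree of rotatable bonds plus random braces
#'   and locked bonds; ground truth from the rank oracle.
#'
#' `n_hbonds > 0` adds fluctuating hydrogen-bond braces (random non-bonded
#' pairs with enthalpies drawn in `u_range`), turning the toy into a thermal
#' network usable with the ensemble machinery; ground truth then refers to
#' the fully engaged framework and is always oracle-derived.
#'
#' @param topology One of `"rotor_chain"`, `"ring"`, `"locked_triangle"`,
#'   `"over_braced_pair"`, `"random"`.
#' @param n_bodies Number of bodies.
#' @param extra_bars Extra redundant bars for the braced topologies; for
#'   `random`, the number of random brace bars.
#' @param n_hbonds Number of fluctuating hydrogen-bond braces to add.
#' @param u_range Range the brace enthalpies are drawn from (kcal/mol).
#' @param seed Integer seed; every draw is derived from it.
#' @param params A [dcm_params()] (entropy weights for added H-bonds).
#' @return List with elements `net` (a `dcm_network`) and `truth` (list:
#'   `clusters` tibble, `rank`, `dof`, plus `source` = "closed_form" or
#'   "oracle"; truth describes the fully engaged framework).
#' @export
make_toy_framework <- function(topology = c("rotor_chain", "ring",
                                            "locked_triangle",
                                            "over_braced_pair", "random"),
                               n_bodies = 6, extra_bars = 1, n_hbonds = 0,
                               u_range = c(-4, -1), seed = 1,
                               params = dcm_params()) {
  topology <- match.arg(topology)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- switch(topology, locked_triangle = 3L, over_braced_pair = 2L,
              as.integer(n_bodies))
  coords <- generic_coords(n)

  cov <- switch(topology,
    rotor_chain = tibble::tibble(i = 1:(n - 1), j = 2:n, bars = 5L,
                                 rotatable = TRUE),
    ring = tibble::tibble(i = 1:n, j = c(2:n, 1L), bars = 5L,
                          rotatable = TRUE),
    locked_triangle = tibble::tibble(
      i = c(1L, 2L, rep(1L, extra_bars)),
      j = c(2L, 3L, rep(3L, extra_bars)),
      bars = c(6L, 6L, rep(1L, extra_bars)),
      rotatable = FALSE),
    over_braced_pair = tibble::tibble(i = 1L, j = 2L,
                                      bars = 6L + as.integer(extra_bars),
                                      rotatable = FALSE),
    random = {
      tree <- tibble::tibble(
        i = vapply(2:n, function(k) sample.int(k - 1, 1), integer(1)),
        j = 2:n,
        bars = sample(c(5L, 6L), n - 1, replace = TRUE, prob = c(0.7, 0.3)))
      tree$rotatable <- tree$bars == 5L
      nb <- max(0L, as.integer(extra_bars))
      if (nb > 0 && n >= 3) {
        pairs <- t(replicate(nb, sort(sample.int(n, 2))))
        braces <- tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                                 bars = sample(1:3, nb, replace = TRUE),
                                 rotatable = FALSE)
        dplyr::bind_rows(tree, braces)
      } else tree
    })
  cov$id <- seq_len(nrow(cov))

  rot <- cov[cov$rotatable, c("i", "j")]
  rotatable <- tibble::tibble(bond_id = seq_len(nrow(rot)),
                              i = rot$i, j = rot$j,
                              residue_index = NA_integer_,
                              angle = "other")

  hbonds <- NULL
  if (n_hbonds > 0) {
    stopifnot(n >= 3)
    taken <- paste(pmin(cov$i, cov$j), pmax(cov$i, cov$j))
    hb_i <- integer(0); hb_j <- integer(0)
    guard <- 0
    while (length(hb_i) < n_hbonds && guard < 1000) {
      guard <- guard + 1
      p <- sort(sample.int(n, 2))
      k <- paste(p[1], p[2])
      if (k %in% taken) next
      taken <- c(taken, k)
      hb_i <- c(hb_i, p[1]); hb_j <- c(hb_j, p[2])
    }
    if (length(hb_i) < n_hbonds) {
      stop("could not place ", n_hbonds, " distinct hydrogen-bond braces")
    }
    u <- runif(n_hbonds, u_range[1], u_range[2])
    hbonds <- tibble::tibble(
      hb_id = seq_len(n_hbonds), donor = hb_i, h = hb_i, acceptor = hb_j,
      antecedent = NA_integer_, u_hb = u,
      gamma = hbond_entropy(u, params), salt_bridge = FALSE)
  }

  atoms <- tibble::tibble(atom_id = seq_len(n),
                          x = coords[, 1], y = coords[, 2], z = coords[, 3])
  net <- dcm_network(atoms, cov[, c("id", "i", "j", "bars")], rotatable,
                     hbonds)

  truth <- toy_truth(topology, n, extra_bars, net, coords, params)
  list(net = net, truth = truth)
}

toy_truth <- function(topology, n, extra_bars, net, coords, params) {
  closed <- topology != "random" && net$n_hb_max == 0
  if (closed) {
    cl <- switch(topology,
      rotor_chain = tibble::tibble(
        label = rep("flexible", n - 1), n_bonds = 1L, a = 1L, b = NA_integer_),
      ring = if (n >= 7) {
        tibble::tibble(label = "flexible", n_bonds = n, a = n - 6L,
                       b = NA_integer_)
      } else if (n == 6) {
        tibble::tibble(label = "isostatic", n_bonds = 6L, a = NA_integer_,
                       b = NA_integer_)
      } else {
        tibble::tibble(label = "overconstrained", n_bonds = n,
                       a = NA_integer_, b = 6L - n)
      },
      locked_triangle = tibble::tibble(
        label = "overconstrained", n_bonds = 0L, a = NA_integer_,
        b = as.integer(extra_bars)),
      over_braced_pair = tibble::tibble(
        label = "overconstrained", n_bonds = 0L, a = NA_integer_,
        b = as.integer(extra_bars)))
    cl$cluster <- seq_len(nrow(cl))
    rank <- switch(topology,
      rotor_chain = 5L * (n - 1L),
      ring = min(6L * n - 6L, 5L * n),
      locked_triangle = 12L,
      over_braced_pair = 6L)
    return(list(clusters = cl[, c("cluster", "label", "n_bonds", "a", "b")],
                rank = rank, dof = 6L * n - rank - 6L,
                source = "closed_form"))
  }
  # truth for the framework with every H-bond engaged and every torsion
  # disordered (all dihedrals probed)
  bars <- framework_bars(net, rep(TRUE, net$n_hb_max) > 0,
                         rep(FALSE, net$n_tor), params)
  orc <- oracle_decompose(coords, bars$i, bars$j,
                          net$rotatable$i, net$rotatable$j)
  list(clusters = orc$clusters, rank = orc$rank, dof = orc$nullity - 6L,
       locked = orc$locked, bond_cluster = orc$bond_cluster,
       orphan_redundant = orc$orphan_redundant, source = "oracle")
}

# generic positions: unit-ish box with a minimum-separation rejection step,
# avoiding non-generic degeneracies in the rank oracle
generic_coords <- function(n, min_sep = 0.35) {
  for (attempt in 1:200) {
    xy <- matrix(runif(3 * n, 0, max(1.5, n^(1 / 3))), n, 3)
    if (n < 2 || min(stats::dist(xy)) > min_sep) return(xy)
  }
  stop("failed to draw well-separated generic coordinates")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- polymer pseudo-proteins ------------------------------------------------

# internal-coordinate atom placement: d bonded to c, |cd| = L, angle
# b-c-d = theta (degrees), dihedral a-b-c-d = chi (degrees)
place_atom <- function(a, b, c, L, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- crossprod3(ab, bc); nrm <- nrm / sqrt(sum(nrm^2))
  m <- crossprod3(nrm, bc)
  c + L * (-cos(th) * bc + sin(th) * (cos(ch) * m + sin(ch) * nrm))
}

.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            b_n_h = 1.01, b_c_h = 1.09,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.8, omega = 180)

#' Generate a polymer pseudo-protein with a designed hydrogen-bond network
#'
#' Builds a geometrically valid all-atom poly-peptide (internal-coordinate
#' chain construction with ideal bond lengths/angles) whose backbone
#' torsions realize a helix (phi,psi = -57,-47; the i,i+4 carbonyl-amide
#' hydrogen bonds form by construction), an extended strand, or random
#' coil-like torsions.  The helix design target is `n_res - 4` hydrogen
#' bonds, recovered exactly by [detect_hbonds()] at default cutoffs.
#' Supported residues: ALA, GLY, SER, PRO (proline's phi sits inside the
#' pyrrolidine ring, so it contributes only a psi torsion).
#'
#' @param n_res Number of residues (>= 3).
#' @param hbond_pattern `"helix_like"`, `"sheet_like"` or `"random"`.
#' @param seed Integer seed (used by `"random"` torsion draws and B-factors).
#' @param sequence Optional character vector of 3-letter residue codes
#'   recycled to length `n_res`; defaults to poly-ALA for the regular
#'   patterns and an ALA/GLY/SER mix for `"random"`.
#' @return List with `atoms` (atom tibble as from [read_structure()]),
#'   `annotations` (residue_index, ss_class, subdomain),
#'   `designed_hbonds` (helix target count, else `NA`).
#' @export
make_polymer_protein <- function(n_res,
                                 hbond_pattern = c("helix_like", "sheet_like",
                                                   "random"),
                                 seed = 1, sequence = NULL) {
  hbond_pattern <- match.arg(hbond_pattern)
  stopifnot(n_res >= 3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (is.null(sequence)) {
    sequence <- if (hbond_pattern == "random") {
      sample(c("ALA", "GLY", "SER"), n_res, replace = TRUE)
    } else rep("ALA", n_res)
  }
  sequence <- rep(sequence, length.out = n_res)

  tors <- switch(hbond_pattern,
    helix_like = matrix(rep(c(-57, -47), n_res), ncol = 2, byrow = TRUE),
    sheet_like = matrix(rep(c(-119, 113), n_res), ncol = 2, byrow = TRUE),
    random = {
      pool <- rbind(c(-65, -40), c(-120, 125), c(-80, 80), c(-150, 150),
                    c(-70, 150))
      pool[sample.int(nrow(pool), n_res, replace = TRUE), , drop = FALSE]
    })
  phi <- tors[, 1]; psi <- tors[, 2]
  phi[sequence == "PRO"] <- -65   # constrained by the ring

  atoms <- list()
  put <- function(name, element, res, resname, xyz) {
    atoms[[length(atoms) + 1]] <<- tibble::tibble(
      name = name, element = element, residue_index = res,
      residue_name = resname, x = xyz[1], y = xyz[2], z = xyz[3])
  }

  N <- CA <- CC <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    rn <- sequence[i]
    if (i == 1) {
      N[[1]] <- c(0, 0, 0)
      CA[[1]] <- c(.BB$b_n_ca, 0, 0)
      th <- .BB$a_n_ca_c * pi / 180
      CC[[1]] <- CA[[1]] + .BB$b_ca_c * c(-cos(th), sin(th), 0)
    } else {
      N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], CC[[i - 1]],
                           .BB$b_c_n, .BB$a_ca_c_n, psi[i - 1])
      CA[[i]] <- place_atom(CA[[i - 1]], CC[[i - 1]], N[[i]],
                            .BB$b_n_ca, .BB$a_c_n_ca, .BB$omega)
      CC[[i]] <- place_atom(CC[[i - 1]], N[[i]], CA[[i]],
                            .BB$b_ca_c, .BB$a_n_ca_c, phi[i])
    }
    O <- place_atom(N[[i]], CA[[i]], CC[[i]], .BB$b_c_o, .BB$a_ca_c_o,
                    psi[i] + 180)
    put("N", "N", i, rn, N[[i]])
    put("CA", "C", i, rn, CA[[i]])
    put("C", "C", i, rn, CC[[i]])
    put("O", "O", i, rn, O)
    if (rn != "PRO") {
      H <- if (i == 1) {
        place_atom(CC[[1]], CA[[1]], N[[1]], .BB$b_n_h, 118, 180)
      } else {
        # amide H anti to the preceding carbonyl oxygen
        Oprev <- place_atom(N[[i - 1]], CA[[i - 1]], CC[[i - 1]], .BB$b_c_o,
                            .BB$a_ca_c_o, psi[i - 1] + 180)
        place_atom(Oprev, CC[[i - 1]], N[[i]], .BB$b_n_h, 119, 180)
      }
      put("H", "H", i, rn, H)
    }
    HA <- place_atom(CC[[i]], N[[i]], CA[[i]], .BB$b_c_h, 109.5, -121)
    put("HA", "H", i, rn, HA)
    sidechain_atoms(rn, N[[i]], CA[[i]], CC[[i]], i, put)
  }

  atoms <- dplyr::bind_rows(atoms)
  atoms$chain <- "A"
  atoms$occupancy <- 1
  atoms$bfactor <- round(runif(nrow(atoms), 8, 30), 2)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$atom_id <- atoms$serial
  atoms <- atoms[, c("atom_id", "serial", "name", "element", "residue_index",
                     "residue_name", "chain", "x", "y", "z", "bfactor",
                     "occupancy")]

  ss <- switch(hbond_pattern, helix_like = "helix", sheet_like = "strand",
               random = "coil")
  annotations <- tibble::tibble(
    residue_index = seq_len(n_res),
    ss_class = ss,
    subdomain = if (ss == "strand") "beta" else "alpha")

  list(atoms = atoms, annotations = annotations,
       designed_hbonds = if (hbond_pattern == "helix_like") n_res - 4L
                         else NA_integer_)
}

sidechain_atoms <- function(rn, N, CA, C, res, put) {
  if (rn == "GLY") {
    put("HA2", "H", res, rn, place_atom(C, N, CA, .BB$b_c_h, 109.5, 121))
    return(invisible())
  }
  CB <- place_atom(C, N, CA, 1.53, 110.5, 122)
  put("CB", "C", res, rn, CB)
  if (rn == "ALA") {
    for (k in 0:2) {
      put(paste0("HB", k + 1), "H", res, rn,
          place_atom(N, CA, CB, .BB$b_c_h, 109.5, 60 + 120 * k))
    }
  } else if (rn == "SER") {
    OG <- place_atom(N, CA, CB, 1.42, 110.5, 180)
    put("OG", "O", res, rn, OG)
    put("HG", "H", res, rn, place_atom(CA, CB, OG, 0.96, 108, 180))
    put("HB1", "H", res, rn, place_atom(N, CA, CB, .BB$b_c_h, 109.5, 60))
    put("HB2", "H", res, rn, place_atom(N, CA, CB, .BB$b_c_h, 109.5, -60))
  } else if (rn == "PRO") {
    # planar pyrrolidine approximation in the plane through CA, N
    # perpendicular-ish to the backbone
    u <- N - CA; u <- u / sqrt(sum(u^2))
    w <- C - CA; w <- w - sum(w * u) * u
    v <- crossprod3(u, w / sqrt(sum(w^2)))
    to3d <- function(x, y) CA + x * u + y * v
    nb <- sqrt(sum((N - CA)^2))
    CB2 <- c(1.53 * cos(103.2 * pi / 180), 1.53 * sin(103.2 * pi / 180))
    # CG: 1.53 from CB, interior-ish angle
    dir1 <- -CB2 / sqrt(sum(CB2^2))
    rot <- function(p, ang) {
      a <- ang * pi / 180
      c(p[1] * cos(a) - p[2] * sin(a), p[1] * sin(a) + p[2] * cos(a))
    }
    CG2 <- CB2 + 1.53 * rot(dir1, 104.5)
    # CD: closes the ring (1.53 from CG, 1.47 from N at (nb, 0))
    N2 <- c(nb, 0)
    dvec <- N2 - CG2; dd <- sqrt(sum(dvec^2))
    x <- (dd^2 + 1.53^2 - 1.47^2) / (2 * dd)
    h <- sqrt(max(1e-6, 1.53^2 - x^2))
    perp <- c(-dvec[2], dvec[1]) / dd
    cand1 <- CG2 + x * dvec / dd + h * perp
    cand2 <- CG2 + x * dvec / dd - h * perp
    CD2 <- if (sum(cand1^2) > sum(cand2^2)) cand1 else cand2
    put("CB", "C", res, rn, to3d(CB2[1], CB2[2]))
    put("CG", "C", res, rn, to3d(CG2[1], CG2[2]))
    put("CD", "C", res, rn, to3d(CD2[1], CD2[2]))
  }
  invisible()
}

#' Two-stage benchmark network for parameter fitting
#'
#' A 12-body network with two melting stages: a free rotor chain (5 torsions,
#' no hydrogen bonds) whose disordered-torsion hump pins down the native
#' torsion parameters, and a second rotor chain cross-braced by four
#' hydrogen bonds of graded strength whose cooperative melting pins down
#' `u_sol`.  The two stages break the near-collinearity of `u_sol` and
#' `v_nat` that a single cooperative transition leaves behind, which is what
#' makes simulated-annealing recovery of the parameters from a synthetic
#' heat-capacity curve well-posed.
#'
#' @param params A [dcm_params()] (entropy weights for the braces).
#' @return A `dcm_network` (12 bodies, 10 rotatable bonds, 4 H-bonds).
#' @export
make_two_stage_network <- function(params = dcm_params()) {
  n1 <- 6; n2 <- 6; n <- n1 + n2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(42)
  coords <- matrix(runif(3 * n, 0, 3), n, 3)
  cov <- tibble::tibble(
    i = c(1:(n1 - 1), (n1 + 1):(n - 1)),
    j = c(2:n1, (n1 + 2):n),
    bars = 5L)
  cov$id <- seq_len(nrow(cov))
  rot <- tibble::tibble(bond_id = seq_len(nrow(cov)), i = cov$i, j = cov$j,
                        residue_index = NA_integer_, angle = "other")
  u <- c(-4.2, -3.6, -3.0, -2.6)
  hb <- tibble::tibble(
    hb_id = 1:4, donor = c(7L, 8L, 9L, 7L), h = c(7L, 8L, 9L, 7L),
    acceptor = c(10L, 11L, 12L, 12L), antecedent = NA_integer_,
    u_hb = u, gamma = hbond_entropy(u, params), salt_bridge = FALSE)
  dcm_network(tibble::tibble(atom_id = seq_len(n), x = coords[, 1],
                             y = coords[, 2], z = coords[, 3]),
              cov, rot, hb)
}

# --- synthetic thermodynamic and null-model data ----------------------------

#' Synthetic heat-capacity curve from a toy network
#'
#' Runs the exact (exhaustively enumerated) ensemble path at known
#' parameters and adds Gaussian noise — the recovery target for
#' [fit_cp()].
#'
#' @param net A small `dcm_network` with fluctuating constraints.
#' @param params True [dcm_params()].
#' @param T_grid Temperatures (K).
#' @param noise_sd Gaussian noise standard deviation, in the units of Cp
#'   (kcal/(mol K)); 0 reproduces [heat_capacity()] output exactly.
#' @param seed Integer seed for the noise draws.
#' @return Tibble with columns `T_K`, `cp_kcal_per_mol_K` and attribute
#'   `truth` (the noise-free curve and parameters).
#' @export
make_synthetic_cp <- function(net, params, T_grid, noise_sd = 0, seed = 1) {
  hc <- heat_capacity(net, params, T_grid,
                      config = dcm_ensemble_config(exhaustive_limit = Inf))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- tibble::tibble(
    T_K = hc$cp$T_K,
    cp_kcal_per_mol_K = hc$cp$cp + rnorm(nrow(hc$cp), sd = noise_sd))
  attr(out, "truth") <- list(cp = hc$cp, tm = hc$tm, params = params)
  out
}

#' Gaussian null profiles around a baseline
#'
#' Draws mutant-like profiles position-wise from the wild-type baseline
#' distribution; used to calibrate the five-bin response histogram against
#' its analytic expectation.
#'
#' @param baseline_mean,baseline_sigma Numeric vectors (equal length).
#' @param n_mutants Number of profiles to draw.
#' @param seed Integer seed.
#' @return A matrix (`n_mutants` rows) of profiles.
#' @export
make_null_profiles <- function(baseline_mean, baseline_sigma, n_mutants,
                               seed = 1) {
  stopifnot(length(baseline_mean) == length(baseline_sigma),
            all(baseline_sigma >= 0), n_mutants >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  npos <- length(baseline_mean)
  mat <- matrix(rnorm(n_mutants * npos, mean = rep(baseline_mean,
                                                   each = n_mutants),
                      sd = rep(baseline_sigma, each = n_mutants)),
                nrow = n_mutants)
  mat
}
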