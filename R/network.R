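#' Construct a body-bar constraint network
#'
#' Low-level constructor.  Atoms are rigid bodies with 6 degrees of freedom;
#' covalent bonds are quenched bars (5 bars for a generic single bond, which
#' locks lengths and angles but leaves the dihedral rotation; 6 bars when the
#' rotation is chemically forbidden); hydrogen bonds and torsion forces are
#' fluctuating constraints engaged or not per sampled framework.
#'
#' Most users build networks with [build_covalent_framework()] +
#' [add_hbonds()] or with the synthetic generators ([make_toy_framework()],
#' [make_polymer_protein()]).
#'
#' @param atoms Tibble with at least `atom_id`, `x`, `y`, `z`; protein
#'   networks also carry `name`, `element`, `residue_index`, `residue_name`.
#' @param covalent Tibble with columns `i`, `j` (atom ids) and `bars` (5 or 6).
#' @param rotatable Tibble with columns `bond_id`, `i`, `j` and optionally
#'   `residue_index`, `angle` (`"phi"`, `"psi"`, `"chi"`, `"other"`).  These
#'   are the a-priori rotatable bonds that carry torsion constraints.
#' @param hbonds Tibble with columns `hb_id`, `donor`, `h`, `acceptor`,
#'   `antecedent` (atom ids; `antecedent` may be `NA`), `u_hb` (kcal/mol),
#'   `gamma` (entropy weight) and `salt_bridge` (logical).
#' @param config A [dcm_network_config()].
#' @return An object of class `dcm_network`.
#' @export
dcm_network <- function(atoms, covalent, rotatable, hbonds = NULL,
                        config = dcm_network_config()) {
  atoms <- tibble::as_tibble(atoms)
  if (!"atom_id" %in% names(atoms)) atoms$atom_id <- seq_len(nrow(atoms))
  covalent <- tibble::as_tibble(covalent)
  if (!"id" %in% names(covalent)) covalent$id <- seq_len(nrow(covalent))
  rotatable <- tibble::as_tibble(rotatable)
  if (nrow(rotatable) > 0 && !"bond_id" %in% names(rotatable)) {
    rotatable$bond_id <- seq_len(nrow(rotatable))
  }
  if (is.null(hbonds)) {
    hbonds <- tibble::tibble(hb_id = integer(), donor = integer(),
                             h = integer(), acceptor = integer(),
                             antecedent = integer(), u_hb = double(),
                             gamma = double(), salt_bridge = logical())
  }
  hbonds <- tibble::as_tibble(hbonds)
  if (nrow(hbonds) > 0 && !"hb_id" %in% names(hbonds)) {
    hbonds$hb_id <- seq_len(nrow(hbonds))
  }
  stopifnot(all(covalent$bars >= 1))
  n <- nrow(atoms)
  stopifnot(all(c(covalent$i, covalent$j, rotatable$i, rotatable$j) %in%
                  seq_len(n)))
  structure(
    list(atoms = atoms, covalent = covalent, rotatable = rotatable,
         hbonds = hbonds, n_bodies = n, n_tor = nrow(rotatable),
         n_hb_max = nrow(hbonds), config = config),
    class = "dcm_network")
}

#' @export
print.dcm_network <- function(x, ...) {
  cat("mDCM constraint network\n")
  cat(sprintf("  bodies:            %d\n", x$n_bodies))
  cat(sprintf("  covalent bonds:    %d (%d bars)\n",
              nrow(x$covalent), sum(x$covalent$bars)))
  cat(sprintf("  rotatable bonds:   %d\n", x$n_tor))
  cat(sprintf("  candidate H-bonds: %d\n", x$n_hb_max))
  invisible(x)
}

# Expand a framework (engaged pattern) into per-bar vectors in the
# entropy-ascending insertion order required for the lowest-upper-bound
# entropy estimate: ties broken by kind (covalent < torsion < hbond), then
# constraint id.  Disordered torsions carry no engaged bar; they are probed
# by test bars inserted after everything else.
framework_bars <- function(net, hb_on, nat_on, params) {
  cov <- net$covalent
  bars_u <- rep(cov$i, cov$bars)
  bars_v <- rep(cov$j, cov$bars)
  bars_s <- rep(0, sum(cov$bars))
  bars_k <- rep(0L, sum(cov$bars))        # kind priority
  bars_id <- rep(cov$id, cov$bars)
  bars_con <- rep(NA_integer_, sum(cov$bars))
  bars_kind <- rep("covalent", sum(cov$bars))

  if (any(nat_on)) {
    rb <- net$rotatable[nat_on, , drop = FALSE]
    bars_u <- c(bars_u, rb$i); bars_v <- c(bars_v, rb$j)
    bars_s <- c(bars_s, rep(params$delta_nat, nrow(rb)))
    bars_k <- c(bars_k, rep(1L, nrow(rb)))
    bars_id <- c(bars_id, rb$bond_id)
    bars_con <- c(bars_con, rb$bond_id)
    bars_kind <- c(bars_kind, rep("torsion", nrow(rb)))
  }

  if (any(hb_on)) {
    hb <- net$hbonds[hb_on, , drop = FALSE]
    nb_main <- net$config$bars$hbond_main
    nb_ante <- net$config$bars$hbond_antecedent
    for (r in seq_len(nrow(hb))) {
      ante <- hb$antecedent[r]
      if (is.na(ante)) {          # no antecedent (toy braces): all bars on pair
        uu <- rep(hb$h[r], nb_main + nb_ante)
        vv <- rep(hb$acceptor[r], nb_main + nb_ante)
      } else {
        uu <- c(rep(hb$h[r], nb_main), hb$h[r])
        vv <- c(rep(hb$acceptor[r], nb_main), ante)
      }
      nb <- length(uu)
      bars_u <- c(bars_u, uu); bars_v <- c(bars_v, vv)
      bars_s <- c(bars_s, rep(hb$gamma[r], nb))
      bars_k <- c(bars_k, rep(2L, nb))
      bars_id <- c(bars_id, rep(hb$hb_id[r], nb))
      bars_con <- c(bars_con, rep(hb$hb_id[r], nb))
      bars_kind <- c(bars_kind, rep("hbond", nb))
    }
  }

  ord <- order(bars_s, bars_k, bars_id)
  tibble::tibble(i = bars_u[ord], j = bars_v[ord],
                 entropy = bars_s[ord], kind = bars_kind[ord],
                 constraint = bars_con[ord])
}

#' Build the quenched covalent part of a constraint network
#'
#' Covalent bonds are detected geometrically (element-aware distance
#' cutoffs), then classified: a generic single bond contributes a quenched
#' 5-bar constraint (one dihedral of rotational freedom left); bonds whose
#' rotation is chemically forbidden get a sixth bar.  Non-rotatable bonds are
#' peptide bonds, bonds inside rings (found as non-bridge edges of the bond
#' graph), bonds to terminal single atoms (hydrogens, carbonyl oxygens, ...)
#' and short double/conjugated bonds.  The remaining 5-bar bonds form the
#' a-priori rotatable set; backbone bonds are labelled `phi` / `psi`
#' (proline, whose N-CA bond sits in the pyrrolidine ring, contributes a psi
#' angle only).
#'
#' @param atoms Atom tibble as returned by [read_structure()].
#' @param config A [dcm_network_config()].
#' @return A `dcm_network` with covalent constraints and the rotatable-bond
#'   table filled in (no hydrogen bonds yet; see [add_hbonds()]).
#' @export
build_covalent_framework <- function(atoms, config = dcm_network_config()) {
  atoms <- tibble::as_tibble(atoms)
  if (!"atom_id" %in% names(atoms)) atoms$atom_id <- seq_len(nrow(atoms))
  n <- nrow(atoms)
  stopifnot(n >= 2)
  cc <- config$covalent
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  elem <- toupper(atoms$element)

  # candidate bonds by distance (grid-free O(n^2); fine at protein scale here)
  d <- as.matrix(stats::dist(xyz))
  is_h <- elem == "H"
  cut <- matrix(cc$heavy_cut, n, n)
  cut[is_h, ] <- cc$h_cut
  cut[, is_h] <- cc$h_cut
  cut[is_h, is_h] <- 0            # no H-H bonds
  sul <- elem == "S"
  cut[sul, !is_h] <- cc$heavy_cut_s
  cut[!is_h, sul] <- cc$heavy_cut_s
  sel <- which(d > 0 & d < cut & upper.tri(d), arr.ind = TRUE)
  if (nrow(sel) == 0) stop("no covalent bonds detected")
  bonds <- tibble::tibble(i = sel[, 1], j = sel[, 2],
                          length = d[sel])

  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  lonely <- which(deg == 0)
  if (length(lonely) > 0) {
    stop("atom(s) with no covalent partner: ",
         paste(atoms$name[lonely], atoms$residue_index[lonely],
               collapse = ", "))
  }

  # bonds on cycles are locked: a bond is in a cycle iff it is not a bridge
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(bonds))
  in_ring[as.integer(br)] <- FALSE

  name_i <- atoms$name[bonds$i]; name_j <- atoms$name[bonds$j]
  res_i <- atoms$residue_index[bonds$i]; res_j <- atoms$residue_index[bonds$j]
  el_i <- elem[bonds$i]; el_j <- elem[bonds$j]

  peptide <- (name_i == "C" & name_j == "N" & res_j == res_i + 1) |
             (name_j == "C" & name_i == "N" & res_i == res_j + 1)
  terminal <- deg[bonds$i] == 1 | deg[bonds$j] == 1
  dbl <- (((el_i == "C" & el_j == "O") | (el_i == "O" & el_j == "C")) &
            bonds$length < cc$double_co) |
         (((el_i == "C" & el_j == "N") | (el_i == "N" & el_j == "C")) &
            bonds$length < cc$double_cn & !peptide)

  locked <- in_ring | peptide | terminal | dbl
  bonds$bars <- ifelse(locked, config$bars$covalent_locked,
                       config$bars$covalent_generic)
  bonds$id <- seq_len(nrow(bonds))

  rot <- bonds[!locked, , drop = FALSE]
  angle <- rep("chi", nrow(rot))
  # phi: N-CA with N bonded to the previous residue's C; psi: CA-C with C
  # bonded to the next residue's N
  nm_i <- atoms$name[rot$i]; nm_j <- atoms$name[rot$j]
  has_prev <- function(k) {
    any((bonds$i == k & atoms$name[bonds$j] == "C" &
           atoms$residue_index[bonds$j] == atoms$residue_index[k] - 1) |
        (bonds$j == k & atoms$name[bonds$i] == "C" &
           atoms$residue_index[bonds$i] == atoms$residue_index[k] - 1))
  }
  has_next <- function(k) {
    any((bonds$i == k & atoms$name[bonds$j] == "N" &
           atoms$residue_index[bonds$j] == atoms$residue_index[k] + 1) |
        (bonds$j == k & atoms$name[bonds$i] == "N" &
           atoms$residue_index[bonds$i] == atoms$residue_index[k] + 1))
  }
  for (r in seq_len(nrow(rot))) {
    a <- rot$i[r]; b <- rot$j[r]
    na <- atoms$name[a]; nb <- atoms$name[b]
    if ((na == "N" && nb == "CA") || (na == "CA" && nb == "N")) {
      nn <- if (na == "N") a else b
      if (has_prev(nn)) angle[r] <- "phi"
    } else if ((na == "CA" && nb == "C") || (na == "C" && nb == "CA")) {
      ccat <- if (na == "C") a else b
      if (has_next(ccat)) angle[r] <- "psi"
    }
  }
  rot_res <- pmin(atoms$residue_index[rot$i], atoms$residue_index[rot$j])
  rotatable <- tibble::tibble(
    bond_id = seq_len(nrow(rot)), i = rot$i, j = rot$j,
    residue_index = rot_res, angle = angle)

  dcm_network(atoms,
              covalent = bonds[, c("id", "i", "j", "bars")],
              rotatable = rotatable, config = config)
}

# 12-10 distance well with angular attenuation; reconstruction of the
# Mayo-type empirical potential.  d = donor-acceptor distance, theta =
# donor-H-acceptor angle.  Salt bridges use a longer equilibrium distance and
# no angular factor.
hbond_energy <- function(d, cos_theta, cfg, salt = FALSE) {
  d0 <- if (salt) cfg$salt_d0 else cfg$d0
  well <- cfg$v0 * (5 * (d0 / d)^12 - 6 * (d0 / d)^10)
  if (salt) well else well * cos_theta^2
}

.SALT_DONORS <- c("LYS.NZ", "ARG.NH1", "ARG.NH2", "ARG.NE",
                  "HIS.ND1", "HIS.NE2")
.SALT_ACCEPTORS <- c("ASP.OD1", "ASP.OD2", "GLU.OE1", "GLU.OE2")

#' Detect candidate hydrogen bonds
#'
#' Candidate donors are N/O/S atoms carrying a covalently bound hydrogen;
#' acceptors are oxygens and nitrogens with free valence.  Candidates within
#' the geometry cutoffs are scored with an empirical 12-10 potential
#' (angular-attenuated; salt bridges between charged side-chain pairs are a
#' special case with a longer equilibrium distance and no angular factor),
#' and those with energy above `energy_ceiling` are discarded.  Detection is
#' deterministic: the same structure and configuration always yield the same
#' candidate list.
#'
#' @param atoms Atom tibble (hydrogens required).
#' @param config A [dcm_network_config()].
#' @param params A [dcm_params()], used for the entropy weight `gamma`.
#' @return Tibble of hydrogen-bond constraints (columns `hb_id`, `donor`,
#'   `h`, `acceptor`, `antecedent`, `d_da`, `u_hb`, `gamma`, `salt_bridge`).
#' @export
detect_hbonds <- function(atoms, config = dcm_network_config(),
                          params = dcm_params()) {
  atoms <- tibble::as_tibble(atoms)
  if (!"atom_id" %in% names(atoms)) atoms$atom_id <- seq_len(nrow(atoms))
  cfg <- config$hbond
  cc <- config$covalent
  n <- nrow(atoms)
  elem <- toupper(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))

  # covalent adjacency (same rule as build_covalent_framework)
  is_h <- elem == "H"
  cut <- matrix(cc$heavy_cut, n, n)
  cut[is_h, ] <- cc$h_cut; cut[, is_h] <- cc$h_cut
  cut[is_h, is_h] <- 0
  bonded <- d > 0 & d < cut

  key <- paste(atoms$residue_name, atoms$name, sep = ".")
  donors <- which(elem %in% c("N", "O", "S") &
                    vapply(seq_len(n), function(k) any(bonded[k, ] & is_h),
                           logical(1)))
  acceptors <- which(elem %in% c("O", "N"))
  # nitrogen acceptors only with free valence (degree < 3), excluding donors
  degh <- rowSums(bonded)
  acceptors <- acceptors[!(elem[acceptors] == "N" &
                             (degh[acceptors] >= 3 |
                                acceptors %in% donors))]

  out <- list()
  for (dn in donors) {
    hs <- which(bonded[dn, ] & is_h)
    for (ac in acceptors) {
      if (ac == dn || bonded[dn, ac]) next
      salt <- key[dn] %in% .SALT_DONORS && key[ac] %in% .SALT_ACCEPTORS
      dda <- d[dn, ac]
      if (dda > (if (salt) cfg$salt_cutoff else cfg$cutoff_da)) next
      # pick the donor hydrogen with the best (largest) D-H-A angle
      best <- NULL
      for (h in hs) {
        v1 <- xyz[dn, ] - xyz[h, ]; v2 <- xyz[ac, ] - xyz[h, ]
        ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
        if (is.null(best) || ang > best$ang) best <- list(h = h, ang = ang)
      }
      if (is.null(best)) next
      if (!salt && best$ang < cfg$min_angle_dha) next
      if (!salt && sqrt(sum((xyz[best$h, ] - xyz[ac, ])^2)) > cfg$cutoff_ha)
        next
      u <- hbond_energy(dda, cos(best$ang * pi / 180), cfg, salt = salt)
      if (u > cfg$energy_ceiling) next
      # antecedent: heavy atom bonded to the acceptor (lowest atom id)
      ante <- which(bonded[ac, ] & !is_h)
      ante <- if (length(ante) > 0) min(ante) else NA_integer_
      out[[length(out) + 1]] <- tibble::tibble(
        donor = dn, h = best$h, acceptor = ac, antecedent = ante,
        d_da = dda, u_hb = u, salt_bridge = salt)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(hb_id = integer(), donor = integer(), h = integer(),
                          acceptor = integer(), antecedent = integer(),
                          d_da = double(), u_hb = double(), gamma = double(),
                          salt_bridge = logical()))
  }
  hb <- dplyr::arrange(dplyr::bind_rows(out), .data$donor, .data$acceptor)
  hb$gamma <- hbond_entropy(hb$u_hb, params)
  hb$hb_id <- seq_len(nrow(hb))
  hb[, c("hb_id", "donor", "h", "acceptor", "antecedent", "d_da", "u_hb",
         "gamma", "salt_bridge")]
}

#' Attach fluctuating hydrogen bonds to a network
#'
#' @param net A `dcm_network`.
#' @param hbonds Result of [detect_hbonds()]; defaults to running detection
#'   on the network's atoms.
#' @param params A [dcm_params()] used for entropy weights.
#' @return The network with `hbonds` and `n_hb_max` filled in.
#' @export
add_hbonds <- function(net, hbonds = NULL, params = dcm_params()) {
  stopifnot(inherits(net, "dcm_network"))
  if (is.null(hbonds)) hbonds <- detect_hbonds(net$atoms, net$config, params)
  net$hbonds <- tibble::as_tibble(hbonds)
  if (nrow(net$hbonds) > 0 && !"hb_id" %in% names(net$hbonds)) {
    net$hbonds$hb_id <- seq_len(nrow(net$hbonds))
  }
  net$n_hb_max <- nrow(net$hbonds)
  net
}

#' Summarise torsion constraint assignment
#'
#' Every a-priori rotatable bond carries a fluctuating torsion constraint
#' with native parameters (`v_nat`, `delta_nat`; engaged as a single bar) and
#' disordered parameters (`v_dis`, `delta_dis`; no bar).  This helper
#' tabulates the assignment and the total torsion enthalpy for an engagement
#' pattern.
#'
#' @param net A `dcm_network`.
#' @param params A [dcm_params()].
#' @param native Logical vector over rotatable bonds (which are natively
#'   engaged); default all native.
#' @return Tibble with one row per rotatable bond and an attribute
#'   `total_enthalpy`.
#' @export
assign_torsion_constraints <- function(net, params = dcm_params(),
                                       native = rep(TRUE, net$n_tor)) {
  stopifnot(length(native) == net$n_tor)
  tab <- dplyr::mutate(
    net$rotatable,
    state = ifelse(native, "native", "disordered"),
    enthalpy = ifelse(native, params$v_nat, params$v_dis),
    entropy_weight = ifelse(native, params$delta_nat, params$delta_dis),
    bars = ifelse(native, net$config$bars$torsion, 0L))
  attr(tab, "total_enthalpy") <- sum(tab$enthalpy)
  tab
}
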