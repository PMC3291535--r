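# Shared fixtures and the independent brute-force ensemble oracle.

R_GAS <- 1.987e-3

# Minimal thermal toy: one rotatable bond between two bodies plus a 1-bar
# hydrogen bond across the same pair.  Four macrostates, closed-form
# thermodynamics.
four_state_net <- function(params = four_state_params()) {
  cfg <- dcm_network_config(bars = list(hbond_main = 1, hbond_antecedent = 0))
  atoms <- tibble::tibble(atom_id = 1:2, x = c(0, 1), y = c(0, 0.5),
                          z = c(0, 0.2))
  cov <- tibble::tibble(id = 1L, i = 1L, j = 2L, bars = 5L)
  rot <- tibble::tibble(bond_id = 1L, i = 1L, j = 2L,
                        residue_index = NA_integer_, angle = "other")
  hb <- tibble::tibble(hb_id = 1L, donor = 1L, h = 1L, acceptor = 2L,
                       antecedent = NA_integer_, u_hb = -3,
                       gamma = hbond_entropy(-3, params),
                       salt_bridge = FALSE)
  dcm_network(atoms, cov, rot, hb, config = cfg)
}

four_state_params <- function() dcm_params(u_sol = -2.3, v_nat = -0.3)

# closed-form macrostate table of the four-state toy: (n_nat, n_hb) in rows
# (0,0), (0,1), (1,0), (1,1)
four_state_table <- function(params = four_state_params()) {
  gam <- hbond_entropy(-3, params)
  tibble::tibble(
    n_nat = c(0, 0, 1, 1), n_hb = c(0, 1, 0, 1),
    u = c(params$u_sol + params$v_dis, -3 + params$v_dis,
          params$u_sol + params$v_nat, -3 + params$v_nat),
    s = R_GAS * c(params$delta_dis, gam, params$delta_nat, gam))
}

# Cooperative melting toy used throughout the ensemble tests.
thermal_toy <- function(params = thermal_params(), n_bodies = 6,
                        n_hbonds = 4, seed = 11) {
  make_toy_framework("rotor_chain", n_bodies = n_bodies,
                     n_hbonds = n_hbonds, seed = seed,
                     u_range = c(-4.5, -2.5), params = params)$net
}

thermal_params <- function() dcm_params(u_sol = -2.2, v_nat = -0.35)

# Brute-force macrostate evaluation through the public pebble-game surface
# only (no ensemble internals): enumerate every placement, iterate the
# entropy-attenuated weights to self-consistency, apply the free-energy
# functional directly.
oracle_macrostate <- function(net, params, n_nat, n_hb, T, mech = FALSE,
                              tol = 1e-4) {
  beta <- 1 / (R_GAS * T)
  hsubs <- if (n_hb == 0) list(integer(0)) else
    if (n_hb == net$n_hb_max) list(seq_len(net$n_hb_max)) else
      asplit(combn(net$n_hb_max, n_hb), 2)
  nsubs <- if (n_nat == 0) list(integer(0)) else
    if (n_nat == net$n_tor) list(seq_len(net$n_tor)) else
      asplit(combn(net$n_tor, n_nat), 2)
  combos <- expand.grid(a = seq_along(hsubs), b = seq_along(nsubs))
  P <- nrow(combos)
  qhb <- matrix(NA_real_, P, net$n_hb_max)
  present <- matrix(FALSE, P, net$n_hb_max)
  qnat <- numeric(P); qdis <- numeric(P); usum <- numeric(P)
  fmat <- if (mech) matrix(0, P, net$n_tor)
  ccarr <- if (mech) array(0, c(P, net$n_tor, net$n_tor))
  for (r in seq_len(P)) {
    hb_on <- seq_len(net$n_hb_max) %in% hsubs[[combos$a[r]]]
    nat_on <- seq_len(net$n_tor) %in% nsubs[[combos$b[r]]]
    d <- run_pebble_game(net, hb_on, nat_on, params)
    hsel <- d$bars$kind == "hbond"
    if (any(hsel)) {
      for (i in which(hb_on)) {
        qhb[r, i] <- mean(d$bars$independent[hsel & d$bars$constraint == i])
      }
    }
    present[r, ] <- hb_on
    tsel <- d$bars$kind == "torsion"
    qnat[r] <- if (any(tsel)) mean(d$bars$independent[tsel]) else 0
    free <- d$bonds$dihedral_free[!nat_on]
    qdis[r] <- if (length(free) > 0) mean(free) else 0
    usum[r] <- sum(net$hbonds$u_hb[hb_on])
    if (mech) {
      fi <- flexibility_index(d)
      fmat[r, ] <- fi$f
      ccarr[r, , ] <- cc_matrix(d)
    }
  }
  gam <- net$hbonds$gamma
  q <- rep(0, net$n_hb_max)
  for (it in 1:100) {
    lw <- as.vector(present %*% (-beta * net$hbonds$u_hb + gam * q))
    w <- exp(lw - max(lw, 0)); w <- w / sum(w)
    pi_i <- as.vector(w %*% present)
    qn <- vapply(seq_len(net$n_hb_max), function(i) {
      rows <- present[, i]
      if (!any(rows)) return(0)
      sum(w[rows] * qhb[rows, i]) / sum(w[rows])
    }, numeric(1))
    if (max(abs(qn - q), 0) < tol) { q <- qn; break }
    q <- qn
  }
  s_mix <- R_GAS * (lchoose(net$n_hb_max, n_hb) + lchoose(net$n_tor, n_nat))
  s_conf <- R_GAS * (sum(pi_i * q * gam) +
                       sum(w * qnat) * n_nat * params$delta_nat +
                       sum(w * qdis) * (net$n_tor - n_nat) * params$delta_dis)
  u_tot <- sum(w * usum) + (net$n_hb_max - n_hb) * params$u_sol +
    n_nat * params$v_nat + (net$n_tor - n_nat) * params$v_dis
  out <- list(u = u_tot, s_mix = s_mix, s_conf = s_conf,
              g = u_tot - T * (s_mix + s_conf))
  if (mech) {
    out$f <- as.vector(w %*% fmat)
    cc <- matrix(0, net$n_tor, net$n_tor)
    for (r in seq_len(P)) cc <- cc + w[r] * ccarr[r, , ]
    out$cc <- cc
  }
  out
}

# Full-grid brute-force landscape
oracle_landscape <- function(net, params, T) {
  grid <- expand.grid(n_nat = 0:net$n_tor, n_hb = 0:net$n_hb_max)
  grid$g <- vapply(seq_len(nrow(grid)), function(r) {
    oracle_macrostate(net, params, grid$n_nat[r], grid$n_hb[r], T)$g
  }, numeric(1))
  grid$u <- vapply(seq_len(nrow(grid)), function(r) {
    oracle_macrostate(net, params, grid$n_nat[r], grid$n_hb[r], T)$u
  }, numeric(1))
  grid
}

# raw PDB line helpers for dialect fixtures
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, elem = substr(name, 1, 1),
                     altloc = " ") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, resname, chain, resno, x, y, z, occ, b, elem)
}
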