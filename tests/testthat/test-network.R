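test_that("a single generic bond leaves one internal rotation", {
  # ethane-like two-body framework: one 5-bar constraint, one dihedral DOF
  tf <- make_toy_framework("rotor_chain", n_bodies = 2, seed = 1)
  expect_equal(nrow(tf$net$covalent), 1L)
  expect_equal(tf$net$covalent$bars, 5L)
  d <- run_pebble_game(tf$net)
  expect_equal(d$free_pebbles, 7L)             # 6 trivial + 1 dihedral
  expect_equal(sum(d$bars$independent), 5L)

  # in an atom chain, interior bonds rotate while terminal bonds are locked
  at <- tibble::tibble(atom_id = 1:4, name = paste0("C", 1:4),
                       element = "C", residue_index = 1L,
                       residue_name = "ALA",
                       x = c(0, 1.5, 2.2, 3.7),
                       y = c(0, 0, 1.3, 1.3), z = 0)
  net <- build_covalent_framework(at)
  expect_equal(sort(net$covalent$bars), c(5L, 6L, 6L))
  expect_equal(net$n_tor, 1L)                  # only the central bond
})

test_that("a benzene-like ring is locked with zero internal DOF", {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  at <- tibble::tibble(atom_id = 1:6,
                       name = paste0("C", 1:6), element = "C",
                       residue_index = 1L, residue_name = "PHE",
                       x = 1.39 / (2 * sin(pi / 6)) * cos(ang),
                       y = 1.39 / (2 * sin(pi / 6)) * sin(ang),
                       z = 0)
  net <- build_covalent_framework(at)
  expect_true(all(net$covalent$bars == 6L))    # ring bonds non-rotatable
  expect_equal(net$n_tor, 0L)
  d <- run_pebble_game(net)
  expect_equal(d$free_pebbles, 6L)             # rigid: trivial DOF only
  # rank oracle agrees
  set.seed(1)
  bars <- mdcm:::framework_bars(net, logical(0), logical(0), dcm_params())
  orc <- oracle_decompose(as.matrix(at[, c("x", "y", "z")]),
                          bars$i, bars$j, integer(0), integer(0))
  expect_equal(sum(d$bars$independent), orc$rank)
})

test_that("tripeptide rotatable set covers phi/psi/chi; proline psi only", {
  pp <- make_polymer_protein(3, "random", seed = 2,
                             sequence = c("ALA", "PRO", "SER"))
  net <- build_covalent_framework(pp$atoms)
  rot2 <- net$rotatable[net$rotatable$residue_index == 2, ]
  expect_equal(rot2$angle, "psi")              # proline: ring owns phi
  rot3 <- net$rotatable[net$rotatable$residue_index == 3, ]
  expect_true(all(c("phi", "chi") %in% rot3$angle))
  expect_true("psi" %in% net$rotatable$angle[net$rotatable$residue_index == 1])
})

test_that("atoms without any covalent partner are rejected", {
  at <- tibble::tibble(atom_id = 1:3, name = c("C1", "C2", "C3"),
                       element = "C", residue_index = 1L,
                       residue_name = "ALA",
                       x = c(0, 1.5, 40), y = 0, z = 0)
  expect_error(build_covalent_framework(at), "no covalent partner")
})

test_that("the ideal linear geometry maximizes hydrogen-bond strength", {
  mk <- function(d_da, tilt = 0) {
    # N-H ... O=C with donor-acceptor distance d_da and H tilted off-axis
    tibble::tibble(
      atom_id = 1:4,
      name = c("N", "H", "O", "C"), element = c("N", "H", "O", "C"),
      residue_index = c(1L, 1L, 2L, 2L), residue_name = "ALA",
      x = c(0, 1.01 * cos(tilt), d_da, d_da + 1.23),
      y = c(0, 1.01 * sin(tilt), 0, 0), z = 0)
  }
  cfg <- dcm_network_config()
  ideal <- detect_hbonds(mk(2.8))
  expect_equal(nrow(ideal), 1L)
  expect_lt(ideal$u_hb, 0)
  # perturbation scan: no displaced/tilted geometry is stronger
  for (dd in c(-0.3, -0.15, 0.15, 0.3)) {
    hb <- detect_hbonds(mk(2.8 + dd))
    if (nrow(hb) > 0) expect_gte(hb$u_hb, ideal$u_hb)
  }
  for (tl in c(0.3, 0.6)) {
    hb <- detect_hbonds(mk(2.8, tilt = tl))
    if (nrow(hb) > 0) expect_gte(hb$u_hb, ideal$u_hb)
  }
  # beyond the cutoff: not listed
  expect_equal(nrow(detect_hbonds(mk(3.8))), 0L)
})

test_that("helix fixture sets n_hb_max to the designed count", {
  pp <- make_polymer_protein(10, "helix_like", seed = 1)
  net <- build_covalent_framework(pp$atoms) |> add_hbonds()
  expect_equal(net$n_hb_max, pp$designed_hbonds)
  # detection is deterministic
  hb1 <- detect_hbonds(pp$atoms)
  hb2 <- detect_hbonds(pp$atoms)
  expect_identical(hb1, hb2)
})

test_that("salt bridges are detected as the special case", {
  # LYS NZ (with H) against ASP OD1 at 3.5 A, bent geometry
  at <- tibble::tibble(
    atom_id = 1:4,
    name = c("NZ", "HZ1", "OD1", "CG"),
    element = c("N", "H", "O", "C"),
    residue_index = c(1L, 1L, 2L, 2L), residue_name = c("LYS", "LYS",
                                                        "ASP", "ASP"),
    x = c(0, 0.6, 3.5, 4.2), y = c(0, 0.82, 1.2, 1.6), z = 0)
  hb <- detect_hbonds(at)
  expect_equal(nrow(hb), 1L)
  expect_true(hb$salt_bridge)
  expect_lt(hb$u_hb, 0)
})

test_that("hbond entropy is the clamped linear map", {
  p <- dcm_params()
  expect_equal(hbond_entropy(0, p), p$gamma_intercept)
  expect_equal(hbond_entropy(-2, p),
               p$gamma_intercept + p$gamma_slope * -2)
  # stronger bond (more negative u), lower entropy; clamped at zero
  us <- seq(-12, 0, by = 0.5)
  g <- hbond_entropy(us, p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0))
})

test_that("torsion assignment carries both states and sums enthalpies", {
  net <- thermal_toy()
  p <- thermal_params()
  all_nat <- assign_torsion_constraints(net, p)
  expect_equal(attr(all_nat, "total_enthalpy"), net$n_tor * p$v_nat)
  expect_true(all(all_nat$entropy_weight == p$delta_nat))

  mix <- rep(c(TRUE, FALSE), length.out = net$n_tor)
  tab <- assign_torsion_constraints(net, p, native = mix)
  expect_equal(attr(tab, "total_enthalpy"),
               sum(mix) * p$v_nat + sum(!mix) * p$v_dis)
  expect_equal(tab$bars[!mix], rep(0L, sum(!mix)))   # disordered: no bar
  expect_equal(net$n_hb_max, nrow(net$hbonds))
})

test_that("the quenched covalent set is identical across frameworks", {
  net <- thermal_toy()
  p <- thermal_params()
  b1 <- mdcm:::framework_bars(net, rep(TRUE, net$n_hb_max),
                              rep(FALSE, net$n_tor), p)
  b2 <- mdcm:::framework_bars(net, rep(FALSE, net$n_hb_max),
                              rep(TRUE, net$n_tor), p)
  cov1 <- b1[b1$kind == "covalent", c("i", "j")]
  cov2 <- b2[b2$kind == "covalent", c("i", "j")]
  expect_identical(cov1, cov2)
})

test_that("parameter validation enforces the state ordering", {
  expect_error(dcm_params(v_nat = 0.5), "v_nat")
  expect_error(dcm_params(delta_nat = 2.5), "delta_nat")
})

test_that("YAML configuration files round into the config objects", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "network:",
    "  energy_ceiling: -0.5",
    "  bars:",
    "    hbond_main: 3",
    "ensemble:",
    "  n_samples: 64",
    "params:",
    "  u_sol: -2.5",
    "  v_nat: -0.4"), f)
  cfg <- read_dcm_config(f)
  expect_equal(cfg$network$hbond$energy_ceiling, -0.5)
  expect_equal(cfg$network$bars$hbond_main, 3)
  expect_equal(cfg$network$bars$hbond_antecedent, 1)   # default kept
  expect_equal(cfg$ensemble$n_samples, 64)
  expect_equal(cfg$params$u_sol, -2.5)
  expect_equal(cfg$params$delta_nat, 1.24)
})

test_that("the on/off pattern count over hydrogen bonds is 2^N", {
  net <- make_toy_framework("rotor_chain", n_bodies = 6, n_hbonds = 5,
                            seed = 3)$net
  total <- sum(vapply(0:net$n_hb_max, function(k) {
    length(mdcm:::subsets_of(net$n_hb_max, k))
  }, numeric(1)))
  expect_equal(total, 2^net$n_hb_max)
  # every subset distinct
  subs <- unlist(lapply(0:net$n_hb_max, function(k) {
    vapply(mdcm:::subsets_of(net$n_hb_max, k),
           function(s) paste(s, collapse = ","), character(1))
  }))
  expect_equal(anyDuplicated(subs), 0L)
})
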