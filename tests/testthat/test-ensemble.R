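test_that("mixing entropy is the combinatorial log-count", {
  net <- make_toy_framework("rotor_chain", n_bodies = 5, n_hbonds = 3,
                            seed = 2)$net
  expect_equal(net$n_tor, 4L)
  # single-combination edges contribute nothing
  expect_equal(mixing_entropy(0, 0, net), 0)
  expect_equal(mixing_entropy(net$n_tor, net$n_hb_max, net), 0)
  # direct binomial count: C(4,2) = 6
  expect_equal(mixing_entropy(2, 0, net), R_GAS * log(6))
  # binomial symmetry of the torsion term
  for (j in 0:net$n_tor) {
    expect_equal(mixing_entropy(j, 1, net),
                 mixing_entropy(net$n_tor - j, 1, net))
  }
})

test_that("conformational entropy reverts to the additive sum at q = 1", {
  net <- thermal_toy()
  p <- thermal_params()
  mac <- sample_macrostate(net, 2, 2, T = 350, params = p, seed = 1)
  mac_all1 <- mac
  mac_all1$q_hb <- rep(1, net$n_hb_max)
  mac_all1$pi_hb <- rep(2 / net$n_hb_max, net$n_hb_max)
  mac_all1$q_nat <- 1
  mac_all1$q_dis <- 1
  s <- conformational_entropy(mac_all1, p, net)
  additive <- R_GAS * (sum(mac_all1$pi_hb * net$hbonds$gamma) +
                         2 * p$delta_nat + (net$n_tor - 2) * p$delta_dis)
  expect_equal(s, additive)

  mac_all0 <- mac
  mac_all0$q_hb <- rep(0, net$n_hb_max)
  mac_all0$q_nat <- 0
  mac_all0$q_dis <- 0
  expect_equal(conformational_entropy(mac_all0, p, net), 0)
})

test_that("free energy is the enthalpy bracket at T = 0 and linear in T", {
  net <- thermal_toy()
  p <- thermal_params()
  mac <- sample_macrostate(net, 1, 2, T = 350, params = p, seed = 1)
  g0 <- free_energy(mac, 0, p, net)
  expect_equal(g0, mac$enthalpy)
  # linearity
  g300 <- free_energy(mac, 300, p, net)
  g400 <- free_energy(mac, 400, p, net)
  g350 <- free_energy(mac, 350, p, net)
  expect_equal(g350, (g300 + g400) / 2, tolerance = 1e-12)
})

test_that("raising u_sol penalizes broken hydrogen bonds", {
  net <- thermal_toy()
  p_lo <- dcm_params(u_sol = -2.5, v_nat = -0.35)
  p_hi <- dcm_params(u_sol = -1.5, v_nat = -0.35)
  mac_lo <- sample_macrostate(net, 0, 0, T = 350, params = p_lo, seed = 1)
  mac_hi <- sample_macrostate(net, 0, 0, T = 350, params = p_hi, seed = 1)
  full_lo <- sample_macrostate(net, 0, net$n_hb_max, T = 350, params = p_lo,
                               seed = 1)
  full_hi <- sample_macrostate(net, 0, net$n_hb_max, T = 350, params = p_hi,
                               seed = 1)
  rel_lo <- mac_lo$free_energy - full_lo$free_energy
  rel_hi <- mac_hi$free_energy - full_hi$free_energy
  expect_gt(rel_hi, rel_lo)    # less negative u_sol disfavours broken bonds
})

test_that("the landscape matches the brute-force functional everywhere", {
  net <- thermal_toy()
  p <- thermal_params()
  cfg <- dcm_ensemble_config(exhaustive_limit = Inf)
  L <- build_landscape(net, p, T = 380, config = cfg)
  for (r in seq_len(nrow(L$grid))) {
    om <- oracle_macrostate(net, p, L$grid$n_nat[r], L$grid$n_hb[r], 380)
    expect_equal(L$grid$free_energy[r], om$g, tolerance = 1e-9)
    expect_equal(L$grid$enthalpy[r], om$u, tolerance = 1e-9)
    expect_equal(L$grid$s_conf[r], om$s_conf, tolerance = 1e-9)
  }
})

test_that("macrostates are deterministic and flag exhaustive enumeration", {
  net <- thermal_toy()
  p <- thermal_params()
  m1 <- sample_macrostate(net, 2, 2, n_samples = 50, seed = 7, params = p,
                          T = 350)
  m2 <- sample_macrostate(net, 2, 2, n_samples = 50, seed = 7, params = p,
                          T = 350)
  expect_identical(m1, m2)
  expect_true(m1$exhaustive)                   # tiny network: enumerated

  # degenerate macrostate runs and is deterministic
  m0 <- sample_macrostate(net, 0, 0, seed = 3, params = p, T = 350)
  expect_equal(m0$n_frameworks, 1)
  expect_true(is.finite(m0$free_energy))

  # exhaustive q equals the exact few-case average: 3 H-bonds, one engaged
  net3 <- make_toy_framework("rotor_chain", n_bodies = 5, n_hbonds = 3,
                             seed = 2, params = p)$net
  m <- sample_macrostate(net3, 0, 1, seed = 1, params = p, T = 350)
  om <- oracle_macrostate(net3, p, 0, 1, 350)
  expect_equal(m$free_energy, om$g, tolerance = 1e-9)
})

test_that("the four-state toy reproduces its closed-form thermodynamics", {
  p <- four_state_params()
  net <- four_state_net(p)
  tab <- four_state_table(p)
  L <- build_landscape(net, p, T = 330,
                       config = dcm_ensemble_config(exhaustive_limit = Inf))
  grid <- dplyr::arrange(L$grid, n_nat, n_hb)
  tab <- dplyr::arrange(tab, n_nat, n_hb)
  expect_equal(grid$enthalpy, tab$u, tolerance = 1e-12)
  expect_equal(grid$free_energy, tab$u - 330 * tab$s, tolerance = 1e-12)

  # Cp from the package path matches the analytic four-state form within 1%
  Tg <- seq(200, 560, by = 4)
  cache <- mdcm:::new_dcm_cache()
  h_pkg <- vapply(Tg, function(Tk) {
    mdcm:::landscape_mean_enthalpy(build_landscape(
      net, p, Tk, dcm_ensemble_config(exhaustive_limit = Inf),
      cache = cache))
  }, numeric(1))
  hmean_an <- function(T) {
    w <- exp(-(tab$u - T * tab$s) / (R_GAS * T))
    sum(w * tab$u) / sum(w)
  }
  n <- length(Tg)
  cp_pkg <- (h_pkg[3:n] - h_pkg[1:(n - 2)]) / (Tg[3:n] - Tg[1:(n - 2)])
  # analytic derivative by fine differentiation of the closed form
  cp_an <- vapply(Tg[2:(n - 1)], function(T) {
    (hmean_an(T + 0.005) - hmean_an(T - 0.005)) / 0.01
  }, numeric(1))
  expect_lt(max(abs(cp_pkg - cp_an)) / max(cp_an), 0.01)
})

test_that("heat capacity is nonnegative with an interior melting peak", {
  net <- thermal_toy()
  p <- thermal_params()
  cfg <- dcm_ensemble_config(exhaustive_limit = Inf)
  hc <- heat_capacity(net, p, T_grid = seq(250, 600, by = 10), config = cfg)
  expect_true(all(hc$cp$cp >= 0, na.rm = TRUE))
  expect_gt(hc$tm, 300); expect_lt(hc$tm, 550)
  expect_gt(hc$cp_max, 0)

  # a window that misses the transition is rejected
  expect_error(
    heat_capacity(net, p, T_grid = seq(200, 240, by = 5), config = cfg),
    "widen")
})

test_that("a strongly bonded toy folds into the maximal corner", {
  # deep H-bond wells and native torsions overwhelm the mixing entropy
  p <- dcm_params(u_sol = -2.2, v_nat = -2)
  net <- thermal_toy(params = p)
  net$hbonds$u_hb <- rep(-12, net$n_hb_max)
  net$hbonds$gamma <- hbond_entropy(net$hbonds$u_hb, p)
  L <- build_landscape(net, p, T = 200,
                       config = dcm_ensemble_config(exhaustive_limit = Inf))
  i <- which.min(L$grid$free_energy)
  expect_equal(L$grid$n_hb[i], net$n_hb_max)
  expect_equal(L$grid$n_nat[i], net$n_tor)
  # single basin: no saddle to be found
  expect_error(mdcm:::find_native_basin(L), "single")
})

test_that("native-basin averages are hand-normalized Gibbs sums", {
  net <- thermal_toy()
  p <- thermal_params()
  cfg <- dcm_ensemble_config(exhaustive_limit = Inf)
  hc <- heat_capacity(net, p, T_grid = seq(250, 600, by = 10), config = cfg)
  L <- build_landscape(net, p, T = hc$tm, config = cfg)
  basin <- mdcm:::find_native_basin(L, cfg)
  expect_equal(sum(basin$rho), 1, tolerance = 1e-12)

  qty <- L$grid$q_dis
  avg <- native_basin_average(L, qty, cfg)
  hand <- sum(exp(-(L$grid$free_energy[basin$members] -
                      min(L$grid$free_energy[basin$members])) /
                    (R_GAS * hc$tm)) * qty[basin$members]) /
    sum(exp(-(L$grid$free_energy[basin$members] -
                min(L$grid$free_energy[basin$members])) / (R_GAS * hc$tm)))
  expect_equal(avg, hand, tolerance = 1e-10)
  # bounded by the field's range
  expect_gte(avg, min(qty[basin$members]) - 1e-12)
  expect_lte(avg, max(qty[basin$members]) + 1e-12)

  # uniform field: plain arithmetic mean of a constant is the constant
  expect_equal(native_basin_average(L, rep(0.7, nrow(L$grid)), cfg), 0.7)
})

test_that("landscapes are seed-deterministic in Monte-Carlo mode", {
  net <- make_toy_framework("rotor_chain", n_bodies = 8, n_hbonds = 5,
                            seed = 11, u_range = c(-4.5, -2.5),
                            params = thermal_params())$net
  p <- thermal_params()
  cfg <- dcm_ensemble_config(exhaustive_limit = 0, n_samples = 60)
  L1 <- build_landscape(net, p, T = 380, config = cfg, seed = 42)
  L2 <- build_landscape(net, p, T = 380, config = cfg, seed = 42)
  expect_identical(L1$grid, L2$grid)
  expect_false(all(L1$grid$exhaustive))
})

test_that("grid striding keeps the basin minimum in place", {
  net <- thermal_toy()
  p <- thermal_params()
  L1 <- build_landscape(net, p, T = 380,
                        config = dcm_ensemble_config(exhaustive_limit = Inf,
                                                     grid_stride = 1))
  L2 <- build_landscape(net, p, T = 380,
                        config = dcm_ensemble_config(exhaustive_limit = Inf,
                                                     grid_stride = 2))
  i1 <- which.min(L1$grid$free_energy)
  i2 <- which.min(L2$grid$free_energy)
  expect_equal(L1$grid[i1, c("n_nat", "n_hb")],
               L2$grid[i2, c("n_nat", "n_hb")])
})
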