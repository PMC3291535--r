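# Free-energy landscape over macrostates (N_nat, N_hb).
#
# A macrostate fixes the number of engaged native torsions and hydrogen
# bonds.  Frameworks satisfying it are either enumerated exactly (small
# networks) or sampled by a Metropolis subset sampler whose stationary
# distribution is the product of single-bond Gibbs factors
#   w_i = exp(-beta * (u_i - T R gamma_i q_i)),
# with the independence probabilities q_i supplied by the previous
# self-consistency iteration (first iteration: uniform).  Because
# beta * T * R = 1, the log subset weight is sum(-beta u_i + gamma_i q_i).
# Native-torsion placements are uniform.  Every sampled framework is pebble-
# gamed; conditional independence probabilities and mechanical averages are
# weight-averaged over frameworks.

# --- per-framework statistics (cached) --------------------------------------

new_dcm_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$frameworks <- new.env(parent = emptyenv())
  e$macro <- new.env(parent = emptyenv())
  e
}

bar_plan <- function(net, params) {
  plan <- framework_bars(net, rep(TRUE, net$n_hb_max) > 0,
                         rep(TRUE, net$n_tor) > 0, params)
  attr(plan, "signature") <- paste(plan$kind, plan$constraint, collapse = ";")
  plan
}

framework_stats <- function(net, plan, hb_on, nat_on, mech, cache) {
  key <- paste0("h", paste(which(hb_on), collapse = ","),
                "|n", paste(which(nat_on), collapse = ","),
                "|m", as.integer(mech))
  hit <- cache$frameworks[[key]]
  if (!is.null(hit)) return(hit)

  keep <- plan$kind == "covalent" |
    (plan$kind == "torsion" & nat_on[pmax(plan$constraint, 1L)]) |
    (plan$kind == "hbond" & hb_on[pmax(plan$constraint, 1L)])
  bars <- plan[keep, , drop = FALSE]
  test_bond <- which(!nat_on)
  res <- .pg_analyze(net$n_bodies, bars$i, bars$j,
                     net$rotatable$i, net$rotatable$j, test_bond)

  qhb <- rep(NA_real_, net$n_hb_max)
  hsel <- bars$kind == "hbond"
  if (any(hsel)) {
    byc <- rowsum(cbind(as.numeric(res$independent[hsel]), 1),
                  bars$constraint[hsel])
    qhb[as.integer(rownames(byc))] <- byc[, 1] / byc[, 2]
  }
  tsel <- bars$kind == "torsion"
  qnat <- if (any(tsel)) mean(res$independent[tsel]) else NA_real_
  qdis <- if (length(test_bond) > 0) mean(res$test_independent) else NA_real_

  out <- list(qhb = qhb, qnat = qnat, qdis = qdis)
  if (mech && net$n_tor > 0) {
    nb <- res$cluster_n_bonds
    fcl <- ifelse(res$cluster_label == "flexible",
                  res$cluster_A / pmax(nb, 1L),
                  ifelse(res$cluster_label == "overconstrained",
                         -pmin(1, res$cluster_B / pmax(nb, 1L)), 0))
    fcl[nb == 0] <- 0
    out$f <- fcl[res$bond_cluster]
    cc <- matrix(0, net$n_tor, net$n_tor)
    for (cl in seq_along(fcl)) {
      idx <- which(res$bond_cluster == cl)
      if (length(idx) > 0) cc[idx, idx] <- fcl[cl]
    }
    out$cc <- as.vector(cc)
  }
  cache$frameworks[[key]] <- out
  out
}

# --- macrostate framework tables --------------------------------------------

subsets_of <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  if (k == n) return(list(seq_len(n)))
  asplit(combn(n, k), 2)
}

# Exhaustive table of frameworks for a macrostate: stat matrices plus the
# hydrogen-bond subset index of each row.
macro_table <- function(net, plan, n_nat, n_hb, mech, cache,
                        mode, n_samples, seed) {
  key <- paste0(n_nat, "_", n_hb, "_", as.integer(mech), "_", mode, "_",
                n_samples, "_", seed)
  hit <- cache$macro[[key]]
  if (!is.null(hit)) return(hit)

  nhb_sub <- choose(net$n_hb_max, n_hb)
  nnat_sub <- choose(net$n_tor, n_nat)

  if (mode == "exhaustive") {
    hsubs <- subsets_of(net$n_hb_max, n_hb)
    nsubs <- subsets_of(net$n_tor, n_nat)
    grid <- expand.grid(a = seq_along(hsubs), b = seq_along(nsubs))
    rows <- lapply(seq_len(nrow(grid)), function(r) {
      hb_on <- seq_len(net$n_hb_max) %in% hsubs[[grid$a[r]]]
      nat_on <- seq_len(net$n_tor) %in% nsubs[[grid$b[r]]]
      framework_stats(net, plan, hb_on, nat_on, mech, cache)
    })
    present <- do.call(rbind, lapply(grid$a, function(a)
      seq_len(net$n_hb_max) %in% hsubs[[a]]))
    if (net$n_hb_max == 0) present <- matrix(FALSE, nrow(grid), 0)
    tab <- list(exhaustive = TRUE, n_frameworks = nhb_sub * nnat_sub,
                present = present,
                u_sum = vapply(grid$a, function(a)
                  sum(net$hbonds$u_hb[hsubs[[a]]]), numeric(1)))
  } else {
    # frameworks are drawn when weights are known; here only the seeds and
    # placeholders are fixed (see macro_eval)
    tab <- list(exhaustive = FALSE, n_frameworks = nhb_sub * nnat_sub,
                n_samples = n_samples, seed = seed)
    rows <- NULL
  }
  tab$mech <- mech
  if (!is.null(rows)) tab <- c(tab, stack_stats(rows, net, mech))
  cache$macro[[key]] <- tab
  tab
}

stack_stats <- function(rows, net, mech) {
  out <- list(
    qhb = do.call(rbind, lapply(rows, `[[`, "qhb")),
    qnat = vapply(rows, `[[`, numeric(1), "qnat"),
    qdis = vapply(rows, `[[`, numeric(1), "qdis"))
  if (net$n_hb_max == 0) out$qhb <- matrix(NA_real_, length(rows), 0)
  if (mech && net$n_tor > 0) {
    out$f <- do.call(rbind, lapply(rows, `[[`, "f"))
    out$cc <- do.call(rbind, lapply(rows, `[[`, "cc"))
  }
  out
}

# Metropolis sampler over hydrogen-bond subsets with log bond weights lw;
# uniform native placements.  Deterministic given the RNG state.
sample_frameworks <- function(net, plan, n_nat, n_hb, n_samples, lw,
                              mech, cache) {
  nhb <- net$n_hb_max
  state <- if (n_hb > 0) {
    sort(sample.int(nhb, n_hb, prob = exp(lw - max(lw))))
  } else integer(0)
  thin <- max(1L, nhb)
  step <- function(st) {
    if (n_hb == 0 || n_hb == nhb) return(st)
    out <- st[sample.int(length(st), 1)]
    absent <- setdiff(seq_len(nhb), st)
    inn <- absent[sample.int(length(absent), 1)]
    if (log(runif(1)) < lw[inn] - lw[out]) st <- sort(c(setdiff(st, out), inn))
    st
  }
  for (b in seq_len(10L * thin)) state <- step(state)   # burn-in
  rows <- vector("list", n_samples)
  present <- matrix(FALSE, n_samples, nhb)
  u_sum <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    for (b in seq_len(thin)) state <- step(state)
    nat <- if (n_nat > 0) sort(sample.int(net$n_tor, n_nat)) else integer(0)
    hb_on <- seq_len(nhb) %in% state
    nat_on <- seq_len(net$n_tor) %in% nat
    rows[[s]] <- framework_stats(net, plan, hb_on, nat_on, mech, cache)
    present[s, ] <- hb_on
    u_sum[s] <- sum(net$hbonds$u_hb[state])
  }
  c(list(present = present, u_sum = u_sum), stack_stats(rows, net, mech))
}

# Weight-average a framework table into macrostate statistics.
macro_aggregate <- function(tab, w) {
  pi_hb <- as.vector(w %*% tab$present)
  qw <- tab$qhb
  qw[is.na(qw)] <- 0
  q_hb <- as.vector(w %*% (qw * tab$present)) / ifelse(pi_hb > 0, pi_hb, 1)
  q_hb[pi_hb == 0] <- NA_real_
  agg <- list(
    pi_hb = pi_hb, q_hb = q_hb,
    q_nat = sum(w * ifelse(is.na(tab$qnat), 0, tab$qnat)),
    q_dis = sum(w * ifelse(is.na(tab$qdis), 0, tab$qdis)),
    mean_u_hb = sum(w * tab$u_sum))
  if (!is.null(tab$f)) {
    agg$f <- as.vector(w %*% tab$f)
    agg$cc <- as.vector(w %*% tab$cc)
  }
  agg
}

# Self-consistent evaluation of one macrostate at temperature T.
macro_eval <- function(net, plan, params, n_nat, n_hb, T, config, mode,
                       n_samples, seed, mech, cache) {
  beta <- 1 / (.R_GAS * T)
  gam <- net$hbonds$gamma
  lw_base <- -beta * net$hbonds$u_hb    # single-bond Gibbs factors
  q <- rep(0, net$n_hb_max)
  delta_q <- Inf
  agg <- NULL
  tab <- macro_table(net, plan, n_nat, n_hb, mech, cache, mode,
                     n_samples, seed)
  if (!tab$exhaustive) {
    # Monte-Carlo frameworks are drawn once from the enthalpy Gibbs base;
    # the entropy-attenuation factor exp(sum gamma_i q_i) enters through
    # importance reweighting so the self-consistency loop converges
    # deterministically
    old <- .Random.seed_save()
    set.seed(seed)
    smp <- sample_frameworks(net, plan, n_nat, n_hb, n_samples, lw_base,
                             mech, cache)
    .Random.seed_restore(old)
    tab[names(smp)] <- smp
  }
  for (it in seq_len(config$max_iter)) {
    lsub <- as.vector(tab$present %*%
                        (if (tab$exhaustive) lw_base + gam * q else gam * q))
    w <- exp(lsub - max(lsub, 0))
    w <- w / sum(w)
    agg <- macro_aggregate(tab, w)
    qn <- ifelse(is.na(agg$q_hb), 0, agg$q_hb)
    delta_q <- if (net$n_hb_max > 0) max(abs(qn - q)) else 0
    q <- qn
    if (delta_q < config$q_tol) break
  }
  if (delta_q >= config$q_tol && config$max_iter > 1) {
    stop(sprintf(paste0("mean-field self-consistency did not converge in %d ",
                        "iterations (last max |dq| = %.3g)"),
                 config$max_iter, delta_q))
  }

  s_mix <- mixing_entropy(n_nat, n_hb, net)
  s_conf <- .R_GAS *
    (sum(agg$pi_hb * ifelse(is.na(agg$q_hb), 0, agg$q_hb) * gam) +
       agg$q_nat * n_nat * params$delta_nat +
       agg$q_dis * (net$n_tor - n_nat) * params$delta_dis)
  u_total <- agg$mean_u_hb + (net$n_hb_max - n_hb) * params$u_sol +
    n_nat * params$v_nat + (net$n_tor - n_nat) * params$v_dis

  structure(
    list(n_nat = n_nat, n_hb = n_hb, temperature = T,
         q_hb = agg$q_hb, pi_hb = agg$pi_hb, gamma = gam,
         q_nat = agg$q_nat, q_dis = agg$q_dis,
         mean_u_hb = agg$mean_u_hb, enthalpy = u_total,
         s_mix = s_mix, s_conf = s_conf,
         free_energy = u_total - T * (s_mix + s_conf),
         mech = if (!is.null(agg$f)) {
           list(f = agg$f,
                cc = matrix(agg$cc, net$n_tor, net$n_tor))
         },
         exhaustive = tab$exhaustive, n_frameworks = tab$n_frameworks,
         iterations = NA_integer_, delta_q = delta_q),
    class = "dcm_macrostate")
}

#' Sample (or enumerate) one macrostate of the ensemble
#'
#' Draws frameworks with exactly `n_hb` hydrogen bonds and `n_nat` native
#' torsions engaged, pebble-games each one, and returns the conditional
#' independence probabilities, entropy terms, free energy and (optionally)
#' mechanically averaged flexibility quantities.  Macrostates whose exact
#' framework count does not exceed `config$exhaustive_limit` (or
#' `n_samples`) are enumerated exactly; this is flagged in the result.
#'
#' @param net A `dcm_network`.
#' @param n_nat,n_hb Macrostate order parameters.
#' @param n_samples Monte-Carlo sample count (ignored in exhaustive mode).
#' @param seed Integer seed; identical inputs and seed give an identical
#'   result.
#' @param params A [dcm_params()].
#' @param T Temperature, K.
#' @param mech Also compute per-bond flexibility and pair-correlation
#'   averages?
#' @param config A [dcm_ensemble_config()].
#' @return A `dcm_macrostate` object.
#' @export
sample_macrostate <- function(net, n_nat, n_hb, n_samples = 200, seed = 1,
                              params = dcm_params(), T = 300, mech = FALSE,
                              config = dcm_ensemble_config()) {
  stopifnot(n_nat >= 0, n_nat <= net$n_tor, n_hb >= 0, n_hb <= net$n_hb_max,
            n_samples >= 1)
  plan <- bar_plan(net, params)
  cache <- new_dcm_cache()
  total <- choose(net$n_tor, n_nat) * choose(net$n_hb_max, n_hb)
  mode <- if (total <= max(config$exhaustive_limit, n_samples))
    "exhaustive" else "mc"
  macro_eval(net, plan, params, n_nat, n_hb, T, config, mode, n_samples,
             seed, mech, cache)
}

#' @export
print.dcm_macrostate <- function(x, ...) {
  cat(sprintf("macrostate (N_nat = %d, N_hb = %d) at T = %.1f K [%s]\n",
              x$n_nat, x$n_hb, x$temperature,
              if (x$exhaustive) "exhaustive" else "sampled"))
  cat(sprintf("  G = %.4f kcal/mol (U = %.4f, S_mix = %.3e, S_conf = %.3e)\n",
              x$free_energy, x$enthalpy, x$s_mix, x$s_conf))
  invisible(x)
}

#' Mixing entropy of a macrostate
#'
#' Combinatorial log-count of the placements compatible with the order
#' parameters: `R * [ln C(N_hb_max, n_hb) + ln C(N_tor, n_nat)]`, computed
#' with log-gamma for stability.  Units: kcal/(mol K).
#'
#' @inheritParams sample_macrostate
#' @export
mixing_entropy <- function(n_nat, n_hb, net) {
  stopifnot(n_nat >= 0, n_nat <= net$n_tor, n_hb >= 0, n_hb <= net$n_hb_max)
  .R_GAS * (lchoose(net$n_hb_max, n_hb) + lchoose(net$n_tor, n_nat))
}

#' Conformational entropy of a macrostate
#'
#' Entropy components summed over constraints and attenuated by the
#' conditional probability of each constraint to be independent:
#' `R * [sum_i pi_i q_i gamma_i + q_nat N_nat delta_nat +
#' q_dis (N_tor - N_nat) delta_dis]`.  With every `q = 1` this reverts to
#' the plain additive free-energy-decomposition sum.
#'
#' @param mac A `dcm_macrostate`.
#' @param params A [dcm_params()].
#' @param net The network the macrostate belongs to.
#' @return Entropy in kcal/(mol K).
#' @export
conformational_entropy <- function(mac, params, net) {
  .R_GAS * (sum(mac$pi_hb * ifelse(is.na(mac$q_hb), 0, mac$q_hb) *
                  mac$gamma) +
              mac$q_nat * mac$n_nat * params$delta_nat +
              mac$q_dis * (net$n_tor - mac$n_nat) * params$delta_dis)
}

#' Free energy of a macrostate at a temperature
#'
#' `G = [sum of engaged H-bond enthalpies + (N_hb_max - n_hb) u_sol +
#' n_nat v_nat + (N_tor - n_nat) v_dis] - T (S_mix + S_conf)`; linear in
#' `T` for fixed entropies.
#'
#' @inheritParams conformational_entropy
#' @param T Temperature, K.
#' @export
free_energy <- function(mac, T, params, net) {
  u <- mac$mean_u_hb + (net$n_hb_max - mac$n_hb) * params$u_sol +
    mac$n_nat * params$v_nat + (net$n_tor - mac$n_nat) * params$v_dis
  u - T * (mac$s_mix + conformational_entropy(mac, params, net))
}

# --- landscape --------------------------------------------------------------

strided_levels <- function(nmax, stride) {
  lev <- unique(c(seq(0L, nmax, by = stride), nmax))
  sort(lev)
}

#' Build the 2D free-energy landscape over (N_nat, N_hb)
#'
#' Evaluates every macrostate on the (possibly strided) grid at temperature
#' `T`.  With `grid_stride > 1` the coarse grid is evaluated first and the
#' neighbourhoods of the detected minima are refined to the full grid.
#'
#' @inheritParams sample_macrostate
#' @param T Temperature, K.
#' @param mech Compute mechanical averages at every grid point (expensive;
#'   [ensemble_qsfr()] restricts this to the native basin).
#' @param cache Internal framework cache (reused across temperatures by
#'   [heat_capacity()] and [fit_cp()]).
#' @return A `dcm_landscape`: list with `grid` tibble (`n_nat`, `n_hb`,
#'   `enthalpy`, `s_mix`, `s_conf`, `free_energy`, `q_nat`, `q_dis`),
#'   `macrostates` (list), `temperature`, `meta`.
#' @export
build_landscape <- function(net, params = dcm_params(), T = 300,
                            config = dcm_ensemble_config(), seed = 1,
                            n_samples = config$n_samples, mech = FALSE,
                            cache = NULL) {
  plan <- bar_plan(net, params)
  if (is.null(cache)) cache <- new_dcm_cache()
  jj <- strided_levels(net$n_tor, config$grid_stride)
  kk <- strided_levels(net$n_hb_max, config$grid_stride)
  pts <- expand.grid(n_nat = jj, n_hb = kk)

  eval_pts <- function(pts) {
    lapply(seq_len(nrow(pts)), function(r) {
      j <- pts$n_nat[r]; k <- pts$n_hb[r]
      total <- choose(net$n_tor, j) * choose(net$n_hb_max, k)
      mode <- if (total <= max(config$exhaustive_limit, n_samples))
        "exhaustive" else "mc"
      macro_eval(net, plan, params, j, k, T, config, mode, n_samples,
                 seed = seed + 1009L * j + k, mech, cache)
    })
  }
  macs <- eval_pts(pts)

  if (config$grid_stride > 1) {
    g <- vapply(macs, `[[`, numeric(1), "free_energy")
    mins <- pts[order(g)[seq_len(min(2, nrow(pts)))], , drop = FALSE]
    box <- unique(do.call(rbind, lapply(seq_len(nrow(mins)), function(r) {
      expand.grid(
        n_nat = max(0, mins$n_nat[r] - config$grid_stride):
          min(net$n_tor, mins$n_nat[r] + config$grid_stride),
        n_hb = max(0, mins$n_hb[r] - config$grid_stride):
          min(net$n_hb_max, mins$n_hb[r] + config$grid_stride))
    })))
    new_pts <- dplyr::anti_join(box, pts, by = c("n_nat", "n_hb"))
    if (nrow(new_pts) > 0) {
      macs <- c(macs, eval_pts(new_pts))
      pts <- rbind(pts, new_pts)
    }
  }

  grid <- tibble::tibble(
    n_nat = pts$n_nat, n_hb = pts$n_hb,
    enthalpy = vapply(macs, `[[`, numeric(1), "enthalpy"),
    s_mix = vapply(macs, `[[`, numeric(1), "s_mix"),
    s_conf = vapply(macs, `[[`, numeric(1), "s_conf"),
    free_energy = vapply(macs, `[[`, numeric(1), "free_energy"),
    q_nat = vapply(macs, `[[`, numeric(1), "q_nat"),
    q_dis = vapply(macs, `[[`, numeric(1), "q_dis"),
    exhaustive = vapply(macs, `[[`, logical(1), "exhaustive"))
  ord <- order(grid$n_nat, grid$n_hb)
  structure(
    list(grid = grid[ord, ], macrostates = macs[ord], temperature = T,
         net = net, params = params,
         meta = list(seed = seed, n_samples = n_samples,
                     stride = config$grid_stride, mech = mech,
                     config = config)),
    class = "dcm_landscape")
}

#' @export
print.dcm_landscape <- function(x, ...) {
  cat(sprintf("mDCM free-energy landscape at T = %.1f K: %d macrostates\n",
              x$temperature, nrow(x$grid)))
  i <- which.min(x$grid$free_energy)
  cat(sprintf("  G min %.3f kcal/mol at (N_nat = %d, N_hb = %d)\n",
              x$grid$free_energy[i], x$grid$n_nat[i], x$grid$n_hb[i]))
  invisible(x)
}

# mean enthalpy over the whole landscape (Gibbs-weighted across macrostates)
landscape_mean_enthalpy <- function(ls) {
  beta <- 1 / (.R_GAS * ls$temperature)
  lw <- -beta * ls$grid$free_energy
  w <- exp(lw - max(lw)); w <- w / sum(w)
  sum(w * ls$grid$enthalpy)
}

#' Heat-capacity curve and melting temperature
#'
#' `Cp(T) = d<H>/dT` by centred finite differences of the landscape-averaged
#' enthalpy; the melting temperature is the `Cp` maximum located by
#' quadratic interpolation around the grid maximum.  An error is raised if
#' the maximum sits on an endpoint of the temperature grid.
#'
#' @inheritParams build_landscape
#' @param T_grid Sorted temperatures (K), at least 5, spanning the
#'   transition.
#' @return List of class `dcm_cp`: `cp` tibble (`T_K`, `h_mean`, `cp`),
#'   `tm` (K), `cp_max`.
#' @export
heat_capacity <- function(net, params = dcm_params(),
                          T_grid = seq(250, 420, by = 5),
                          config = dcm_ensemble_config(), seed = 1,
                          cache = NULL) {
  stopifnot(length(T_grid) >= 5, !is.unsorted(T_grid))
  if (is.null(cache)) cache <- new_dcm_cache()
  h <- vapply(T_grid, function(Tk) {
    landscape_mean_enthalpy(
      build_landscape(net, params, Tk, config, seed, cache = cache))
  }, numeric(1))
  n <- length(T_grid)
  cp <- rep(NA_real_, n)
  cp[2:(n - 1)] <- (h[3:n] - h[1:(n - 2)]) / (T_grid[3:n] - T_grid[1:(n - 2)])
  imax <- which.max(cp[2:(n - 1)]) + 1L
  if (imax <= 2 || imax >= n - 1) {
    stop(sprintf(paste0("heat-capacity maximum at the edge of the grid ",
                        "(T = %.1f K); widen T_grid"), T_grid[imax]))
  }
  # quadratic interpolation of the apex
  t3 <- T_grid[(imax - 1):(imax + 1)]; c3 <- cp[(imax - 1):(imax + 1)]
  denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
  aa <- (t3[3] * (c3[2] - c3[1]) + t3[2] * (c3[1] - c3[3]) +
           t3[1] * (c3[3] - c3[2])) / denom
  bb <- (t3[3]^2 * (c3[1] - c3[2]) + t3[2]^2 * (c3[3] - c3[1]) +
           t3[1]^2 * (c3[2] - c3[3])) / denom
  tm <- if (abs(aa) > 1e-12) -bb / (2 * aa) else t3[2]
  cc0 <- c3[2] - aa * t3[2]^2 - bb * t3[2]
  cp_max <- if (abs(aa) > 1e-12) aa * tm^2 + bb * tm + cc0 else cp[imax]
  structure(list(cp = tibble::tibble(T_K = T_grid, h_mean = h, cp = cp),
                 tm = tm, cp_max = cp_max,
                 net = net, params = params),
            class = "dcm_cp")
}

#' @export
print.dcm_cp <- function(x, ...) {
  cat(sprintf("heat capacity: Tm = %.2f K, max Cp = %.3f kcal/(mol K)\n",
              x$tm, x$cp_max))
  invisible(x)
}

# --- native basin -----------------------------------------------------------

# neighbour structure over evaluated grid points: nearest evaluated point
# up/down/left/right on the (n_nat, n_hb) lattice
grid_neighbours <- function(grid) {
  n <- nrow(grid)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    same_j <- which(grid$n_nat == grid$n_nat[i] & grid$n_hb != grid$n_hb[i])
    same_k <- which(grid$n_hb == grid$n_hb[i] & grid$n_nat != grid$n_nat[i])
    pick <- function(cand, coord, val) {
      up <- cand[coord[cand] > val]
      dn <- cand[coord[cand] < val]
      c(if (length(up)) up[which.min(coord[up])],
        if (length(dn)) dn[which.max(coord[dn])])
    }
    nbr[[i]] <- c(pick(same_j, grid$n_hb, grid$n_hb[i]),
                  pick(same_k, grid$n_nat, grid$n_nat[i]))
  }
  nbr
}

find_native_basin <- function(ls, config = dcm_ensemble_config()) {
  grid <- ls$grid
  g <- grid$free_energy
  nbr <- grid_neighbours(grid)
  is_min <- vapply(seq_along(g), function(i) all(g[i] <= g[nbr[[i]]]),
                   logical(1))
  mins <- which(is_min)
  # collapse plateau minima that are mutual neighbours
  if (length(mins) > 1) {
    drop <- rep(FALSE, length(mins))
    for (a in seq_along(mins)) {
      for (b in seq_along(mins)) {
        if (a < b && mins[b] %in% nbr[[mins[a]]] &&
            g[mins[a]] <= g[mins[b]]) drop[b] <- TRUE
      }
    }
    mins <- mins[!drop]
  }
  if (length(mins) < 2) {
    stop(sprintf(paste0("no saddle found: the landscape at T = %.2f K has a ",
                        "single free-energy basin"), ls$temperature))
  }
  score <- grid$n_nat[mins] + grid$n_hb[mins]
  native <- mins[which.max(score)]
  unfolded <- mins[which.min(score)]
  if (native == unfolded) {
    stop(sprintf("cannot separate native and unfolded basins at T = %.2f K",
                 ls$temperature))
  }

  # watershed: steepest-descent assignment of every point to a minimum
  assign_to <- rep(NA_integer_, length(g))
  desc <- function(i) {
    seen <- integer(0)
    while (is.na(assign_to[i])) {
      seen <- c(seen, i)
      lower <- nbr[[i]][g[nbr[[i]]] < g[i]]
      if (length(lower) == 0) { assign_to[seen] <<- i; return(i) }
      i <- lower[which.min(g[lower])]
    }
    assign_to[seen] <<- assign_to[i]
    assign_to[i]
  }
  for (i in order(g)) desc(i)

  # saddle: flood points by ascending G until the two minima connect
  ord <- order(g)
  uf <- seq_along(g)
  findr <- function(x) { while (uf[x] != x) x <- uf[x]; x }
  added <- rep(FALSE, length(g))
  saddle_g <- NA_real_
  for (i in ord) {
    added[i] <- TRUE
    for (j in nbr[[i]]) {
      if (added[j]) uf[findr(i)] <- findr(j)
    }
    if (findr(native) == findr(unfolded)) { saddle_g <- g[i]; break }
  }

  members <- which(assign_to == native & g < saddle_g)
  members <- union(members, native)
  beta_m <- 1 / (.R_GAS * ls$temperature)
  lw <- -beta_m * (g[members] - g[native])
  rho <- exp(lw)
  keep <- rho / max(rho) >= config$rho_floor
  members <- members[keep]; rho <- rho[keep]
  rho <- rho / sum(rho)
  list(members = members, rho = rho, basin_min = native,
       unfolded_min = unfolded, saddle_g = saddle_g)
}

#' Write a landscape grid (with basin weights where defined) as TSV
#'
#' @param landscape A `dcm_landscape`.
#' @param path Output path.
#' @param config A [dcm_ensemble_config()] for the basin detection; basin
#'   weights are written as 0 outside the native basin and omitted entirely
#'   when the landscape has no two-basin structure.
#' @export
write_landscape_tsv <- function(landscape, path,
                                config = dcm_ensemble_config()) {
  tab <- landscape$grid[, c("n_nat", "n_hb", "free_energy", "enthalpy",
                            "s_mix", "s_conf")]
  rho <- rep(0, nrow(tab))
  basin <- tryCatch(find_native_basin(landscape, config),
                    error = function(e) NULL)
  if (!is.null(basin)) {
    rho[basin$members] <- basin$rho
    tab$rho <- rho
  }
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Gibbs average of a quantity over the native basin
#'
#' Weights `rho(j,k) ~ exp(-beta_m G(j,k))` are normalized over the
#' neighbourhood of the native free-energy minimum (steepest-descent
#' watershed truncated at the saddle separating it from the unfolded
#' basin).
#'
#' @param landscape A `dcm_landscape` built at the temperature of interest
#'   (typically the melting temperature).
#' @param quantity Numeric vector aligned with `landscape$grid` rows, or a
#'   function applied to each `dcm_macrostate`.
#' @param config A [dcm_ensemble_config()].
#' @return The basin-averaged value (vectors are averaged element-wise).
#' @export
native_basin_average <- function(landscape, quantity,
                                 config = dcm_ensemble_config()) {
  basin <- find_native_basin(landscape, config)
  vals <- if (is.function(quantity)) {
    lapply(landscape$macrostates[basin$members], quantity)
  } else {
    as.list(quantity[basin$members])
  }
  out <- 0
  for (i in seq_along(vals)) out <- out + basin$rho[i] * vals[[i]]
  out
}
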