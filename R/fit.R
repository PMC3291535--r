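# Simulated-annealing parameterization of the mDCM against an experimental
# heat-capacity curve.
#
# The per-macrostate conditional statistics (independence probabilities and
# mean engaged H-bond enthalpy) do not depend on the fitting parameters
# {u_sol, v_nat, delta_nat} except through the bar insertion order, so they
# are precomputed once per temperature and insertion-order signature; each
# annealing proposal then only re-evaluates the free-energy algebra.

precompute_thermo <- function(net, params, T_eval, config, cache) {
  plan <- bar_plan(net, params)
  jj <- 0:net$n_tor; kk <- 0:net$n_hb_max
  pts <- expand.grid(n_nat = jj, n_hb = kk)
  M <- nrow(pts)
  out <- list(T_eval = T_eval, n_nat = pts$n_nat, n_hb = pts$n_hb,
              sc_hb = matrix(0, length(T_eval), M),
              q_nat = matrix(0, length(T_eval), M),
              q_dis = matrix(0, length(T_eval), M),
              mean_u = matrix(0, length(T_eval), M))
  s_mix <- vapply(seq_len(M), function(r)
    mixing_entropy(pts$n_nat[r], pts$n_hb[r], net), numeric(1))
  out$s_mix <- s_mix
  for (ti in seq_along(T_eval)) {
    for (r in seq_len(M)) {
      total <- choose(net$n_tor, pts$n_nat[r]) *
        choose(net$n_hb_max, pts$n_hb[r])
      mode <- if (total <= max(config$exhaustive_limit, config$n_samples))
        "exhaustive" else "mc"
      mac <- macro_eval(net, plan, params, pts$n_nat[r], pts$n_hb[r],
                        T_eval[ti], config, mode, config$n_samples,
                        seed = 1L + 1009L * pts$n_nat[r] + pts$n_hb[r],
                        mech = FALSE, cache = cache)
      out$sc_hb[ti, r] <- sum(mac$pi_hb *
                                ifelse(is.na(mac$q_hb), 0, mac$q_hb) *
                                mac$gamma)
      out$q_nat[ti, r] <- mac$q_nat
      out$q_dis[ti, r] <- mac$q_dis
      out$mean_u[ti, r] <- mac$mean_u_hb
    }
  }
  out
}

# Heat capacity on the data grid from the precomputed thermo tables:
# <H>(T) by Gibbs weights over macrostates, Cp by centred differences.
thermo_cp <- function(th, net, u_sol, v_nat, delta_nat, delta_dis, v_dis) {
  nT <- length(th$T_eval)
  h <- numeric(nT)
  for (ti in seq_len(nT)) {
    Tk <- th$T_eval[ti]
    s_conf <- .R_GAS * (th$sc_hb[ti, ] +
                          th$q_nat[ti, ] * th$n_nat * delta_nat +
                          th$q_dis[ti, ] * (net$n_tor - th$n_nat) * delta_dis)
    u <- th$mean_u[ti, ] + (net$n_hb_max - th$n_hb) * u_sol +
      th$n_nat * v_nat + (net$n_tor - th$n_nat) * v_dis
    g <- u - Tk * (th$s_mix + s_conf)
    lw <- -g / (.R_GAS * Tk)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    h[ti] <- sum(w * u)
  }
  cp <- rep(NA_real_, nT)
  cp[2:(nT - 1)] <- (h[3:nT] - h[1:(nT - 2)]) /
    (th$T_eval[3:nT] - th$T_eval[1:(nT - 2)])
  cp
}

#' Fit mDCM parameters to a heat-capacity curve by simulated annealing
#'
#' Minimizes the mean squared difference between the model and experimental
#' heat-capacity curves (after a constant baseline offset) over
#' `{u_sol, v_nat}` (`mode = "two_param"`, `delta_nat` held fixed) or
#' `{u_sol, v_nat, delta_nat}` (`mode = "three_param"`).  Annealing uses
#' Gaussian proposals reflected at the bounds, Metropolis acceptance, and
#' geometric cooling.
#'
#' @param net A `dcm_network` small enough for the ensemble machinery.
#' @param cp_data Data frame whose first two columns are temperature (K) and
#'   Cp (kcal/(mol K)), spanning a single Cp peak.
#' @param mode `"two_param"` or `"three_param"`.
#' @param start A [dcm_params()] giving the starting point (also supplies
#'   the fixed `delta_nat` in two-parameter mode).
#' @param bounds Named list of `c(lo, hi)` for `u_sol`, `v_nat`,
#'   `delta_nat`.
#' @param schedule List: `t0_scale` (initial annealing temperature as a
#'   multiple of the starting residual), `cooling` (geometric factor per
#'   step), `steps`, `proposals` (per step), `prop_frac` (proposal s.d. as a
#'   fraction of each bound range; proposals shrink with the square root of
#'   the annealing temperature down to `prop_floor` of the initial width).
#' @param seed Integer seed.
#' @param polish Finish with a bounded quasi-Newton descent from the best
#'   annealed point (removes residual optimizer noise along shallow
#'   directions of the objective).
#' @param config A [dcm_ensemble_config()].
#' @param cache Optional framework cache shared across fits of the same
#'   network (the per-framework pebble-game statistics do not depend on the
#'   data or the fitted parameters).
#' @return A `dcm_fit` object: fitted `params`, `objective` (MSE after
#'   offset), `tm_model`, `n_evaluations`, `seed`, `mode`, `offset`.
#' @export
fit_cp <- function(net, cp_data, mode = c("two_param", "three_param"),
                   start = dcm_params(u_sol = -2, v_nat = -0.3),
                   bounds = list(u_sol = c(-4, -0.5),
                                 v_nat = c(-1, -0.02),
                                 delta_nat = c(1.05, 1.9)),
                   schedule = list(t0_scale = 10, cooling = 0.95,
                                   steps = 200, proposals = 20,
                                   prop_frac = 0.04, prop_floor = 0.02),
                   seed = 1, polish = TRUE,
                   config = dcm_ensemble_config(), cache = NULL) {
  mode <- match.arg(mode)
  cp_data <- as.data.frame(cp_data)
  T_dat <- cp_data[[1]]; cp_dat <- cp_data[[2]]
  stopifnot(length(T_dat) >= 7, !is.unsorted(T_dat))
  if (!(start$v_nat < start$v_dis)) stop("start must satisfy v_nat < v_dis")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (is.null(cache)) cache <- new_dcm_cache()
  if (is.null(cache$thermo)) cache$thermo <- new.env(parent = emptyenv())
  th_env <- cache$thermo
  get_thermo <- function(delta_nat) {
    p <- start; p$delta_nat <- delta_nat
    sig <- paste(attr(bar_plan(net, p), "signature"),
                 paste(round(T_dat, 6), collapse = ","))
    hit <- th_env[[sig]]
    if (is.null(hit)) {
      hit <- precompute_thermo(net, p, T_dat, config, cache)
      th_env[[sig]] <- hit
    }
    hit
  }

  interior <- 2:(length(T_dat) - 1)
  n_eval <- 0L
  any_interior_peak <- FALSE
  objective <- function(x) {
    n_eval <<- n_eval + 1L
    th <- get_thermo(x[["delta_nat"]])
    cp_mod <- thermo_cp(th, net, x[["u_sol"]], x[["v_nat"]],
                        x[["delta_nat"]], start$delta_dis, start$v_dis)
    pk <- which.max(cp_mod[interior])
    if (pk > 1 && pk < length(interior)) any_interior_peak <<- TRUE
    resid <- cp_dat[interior] - cp_mod[interior]
    off <- mean(resid)
    list(mse = mean((resid - off)^2), offset = off, cp_mod = cp_mod)
  }

  free <- if (mode == "two_param") c("u_sol", "v_nat") else
    c("u_sol", "v_nat", "delta_nat")
  x <- c(u_sol = start$u_sol, v_nat = start$v_nat,
         delta_nat = start$delta_nat)
  clampx <- function(x) {
    for (nm in free) {
      lo <- bounds[[nm]][1]; hi <- bounds[[nm]][2]
      v <- x[[nm]]
      while (v < lo || v > hi) {         # reflect into bounds
        if (v < lo) v <- 2 * lo - v
        if (v > hi) v <- 2 * hi - v
      }
      x[[nm]] <- v
    }
    x
  }
  x <- clampx(x)

  cur <- objective(x)
  best <- list(x = x, mse = cur$mse, offset = cur$offset)
  t0 <- schedule$t0_scale * max(cur$mse, 1e-12)
  t_anneal <- t0
  prop_floor <- schedule$prop_floor %||% 0.02
  for (stp in seq_len(schedule$steps)) {
    shrink <- if (t0 > 0) max(sqrt(t_anneal / t0), prop_floor) else prop_floor
    for (pr in seq_len(schedule$proposals)) {
      cand <- x
      for (nm in free) {
        rng <- diff(bounds[[nm]])
        cand[[nm]] <- cand[[nm]] +
          rnorm(1, sd = schedule$prop_frac * rng * shrink)
      }
      cand <- clampx(cand)
      if (cand[["v_nat"]] >= start$v_dis) next
      res <- objective(cand)
      if (res$mse < cur$mse ||
          (t_anneal > 0 && runif(1) < exp((cur$mse - res$mse) / t_anneal))) {
        x <- cand; cur <- res
        if (res$mse < best$mse) {
          best <- list(x = x, mse = res$mse, offset = res$offset)
        }
      }
    }
    t_anneal <- t_anneal * schedule$cooling
  }

  if (!any_interior_peak) {
    stop(paste0("model Cp peak fell outside the data range for every ",
                "sampled parameter set; widen the bounds or the data window"))
  }

  if (isTRUE(polish)) {
    fn <- function(v) {
      x2 <- best$x
      for (k in seq_along(free)) x2[[free[k]]] <- v[k]
      if (x2[["v_nat"]] >= start$v_dis) return(1e6)
      objective(x2)$mse
    }
    opt <- stats::optim(vapply(free, function(nm) best$x[[nm]], numeric(1)),
                        fn, method = "L-BFGS-B",
                        lower = vapply(free, function(nm) bounds[[nm]][1],
                                       numeric(1)),
                        upper = vapply(free, function(nm) bounds[[nm]][2],
                                       numeric(1)),
                        control = list(factr = 1e4))
    if (opt$value <= best$mse) {
      for (k in seq_along(free)) best$x[[free[k]]] <- opt$par[k]
      best$mse <- opt$value
    }
  }

  fin <- objective(best$x)
  cp_mod <- fin$cp_mod
  pk <- which.max(cp_mod[interior]) + 1L
  tm_model <- T_dat[pk]
  if (pk > 2 && pk < length(T_dat) - 1) {
    t3 <- T_dat[(pk - 1):(pk + 1)]; c3 <- cp_mod[(pk - 1):(pk + 1)]
    denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
    aa <- (t3[3] * (c3[2] - c3[1]) + t3[2] * (c3[1] - c3[3]) +
             t3[1] * (c3[3] - c3[2])) / denom
    bb <- (t3[3]^2 * (c3[1] - c3[2]) + t3[2]^2 * (c3[3] - c3[1]) +
             t3[1]^2 * (c3[2] - c3[3])) / denom
    if (abs(aa) > 1e-12) tm_model <- -bb / (2 * aa)
  }

  pars <- start
  pars$u_sol <- unname(best$x[["u_sol"]])
  pars$v_nat <- unname(best$x[["v_nat"]])
  pars$delta_nat <- unname(best$x[["delta_nat"]])
  structure(
    list(params = pars, objective = best$mse, offset = best$offset,
         tm_model = tm_model, n_evaluations = n_eval, seed = seed,
         mode = mode,
         model_cp = tibble::tibble(T_K = T_dat, cp_model = cp_mod,
                                   cp_data = cp_dat)),
    class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("mDCM heat-capacity fit (%s, seed %d)\n", x$mode, x$seed))
  cat(sprintf("  u_sol %.4f  v_nat %.4f  delta_nat %.4f\n",
              x$params$u_sol, x$params$v_nat, x$params$delta_nat))
  cat(sprintf("  objective (MSE) %.4g after %d evaluations; Tm %.2f K\n",
              x$objective, x$n_evaluations, x$tm_model))
  invisible(x)
}

#' Write a fit result as JSON with full provenance
#'
#' @param fit A `dcm_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dcm_fit"))
  jsonlite::write_json(
    list(mode = fit$mode, seed = fit$seed,
         params = unclass(fit$params)[c("u_sol", "v_nat", "delta_nat",
                                        "v_dis", "delta_dis")],
         objective = fit$objective, offset = fit$offset,
         tm_model = fit$tm_model, n_evaluations = fit$n_evaluations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.dcm_fit <- function(x, ...) {
  fixed2 <- x$mode == "two_param"
  tibble::tibble(
    term = c("u_sol", "v_nat", "delta_nat"),
    estimate = c(x$params$u_sol, x$params$v_nat, x$params$delta_nat),
    fixed = c(FALSE, FALSE, fixed2))
}

#' @export
glance.dcm_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, tm_model = x$tm_model,
                 n_evaluations = x$n_evaluations, mode = x$mode,
                 seed = x$seed)
}

#' @export
tidy.dcm_qsfr <- function(x, ...) {
  if (!is.null(x$fi_residue)) {
    dplyr::mutate(x$fi_residue, level = "residue")
  } else {
    dplyr::mutate(x$fi_bond[, c("bond_id", "fi")], level = "bond")
  }
}

#' @export
glance.dcm_qsfr <- function(x, ...) {
  tibble::tibble(tm = x$tm, n_bonds = nrow(x$fi_bond),
                 fi_min = min(x$fi_bond$fi), fi_max = max(x$fi_bond$fi),
                 n_basin = length(x$basin$members))
}
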