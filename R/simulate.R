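#' Run one exact stochastic epidemic
#'
#' Event-driven (Gillespie) continuous-time realization of the four reactions
#' on a fixed network: per S-I edge, infection at rate `beta` and alerting at
#' rate `beta_f`; per S^F-I edge, infection at rate `gamma * beta`; per
#' infectious node, recovery at rate `mu`. The run ends when no infectious node
#' remains; protected nodes never revert and recovery is absorbing.
#'
#' @param net an [epinet].
#' @param params an [epidemic_params].
#' @param initial_infected number of initially infectious nodes, chosen
#'   uniformly at random (ignored when `seed_nodes` is given).
#' @param seed_nodes optional explicit 0-based node ids to start infectious.
#' @param seed integer seed; the same seed reproduces the run bit-for-bit.
#' @return Object of class `sim_outcome`: `final_recovered_fraction` (the
#'   realization prevalence rho), `final_sf_fraction`,
#'   `peak_infected_fraction`, `extinction_time`, the four event counts, and
#'   the initially infected nodes.
#' @export
run_epidemic <- function(net, params, initial_infected = 1L, seed_nodes = NULL, seed) {
  stopifnot(inherits(net, "epinet"), inherits(params, "epidemic_params"))
  if (is.null(seed_nodes)) {
    initial_infected <- as.integer(initial_infected)
    if (is.na(initial_infected) || initial_infected < 1L || initial_infected > net$n) {
      stop("'initial_infected' must be between 1 and n")
    }
    seed_nodes <- with_seed(derive_seed(seed, 0L),
                            sample.int(net$n, initial_infected) - 1L)
  } else {
    seed_nodes <- as.integer(seed_nodes)
    if (length(seed_nodes) == 0L) stop("'seed_nodes' must be nonempty")
    if (any(seed_nodes < 0L | seed_nodes >= net$n) || anyDuplicated(seed_nodes)) {
      stop("'seed_nodes' must be distinct 0-based node ids")
    }
  }
  raw <- .cpp_run_epidemic(net$n, net$adj_ptr, net$adj_idx,
                           params$beta, params$beta_f, params$gamma, params$mu,
                           seed_nodes, as.integer(seed))
  if (raw[["consistent"]] != 1) stop("internal error: state conservation violated")
  structure(
    list(
      final_recovered_fraction = raw[["n_r"]] / net$n,
      final_sf_fraction = raw[["n_sf"]] / net$n,
      peak_infected_fraction = raw[["peak_i"]] / net$n,
      extinction_time = raw[["t_end"]],
      events = c(infect_s = raw[["ev_inf_s"]], alert = raw[["ev_alert"]],
                 infect_sf = raw[["ev_inf_sf"]], recover = raw[["ev_rec"]]),
      seed_nodes = seed_nodes,
      params = params
    ),
    class = "sim_outcome"
  )
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("epidemic run: rho = %.4g, S^F = %.4g, peak I = %.4g, t_end = %.4g\n",
              x$final_recovered_fraction, x$final_sf_fraction,
              x$peak_infected_fraction, x$extinction_time))
  invisible(x)
}

#' Ensemble of independent epidemic realizations
#'
#' Runs `n_realizations` independent realizations, each (by default) seeded
#' with one fresh uniformly random infectious node, and collects the final
#' sizes. The variability measure `Delta` is computed over all realizations,
#' including early die-outs; the outbreak-conditioned mean discards
#' realizations with final size at or below `outbreak_cutoff` (with a single
#' seed on a large graph the unconditional mean is depressed by the die-out
#' probability and is not comparable to the theoretical prevalence).
#'
#' @inheritParams run_epidemic
#' @param n_realizations number of independent realizations.
#' @param n_seeds infectious seeds per realization (fresh random nodes each
#'   realization).
#' @param seed_nodes optional fixed 0-based seed set used in every realization.
#' @param outbreak_cutoff fraction above which a realization counts as a
#'   genuine outbreak.
#' @return Object of class `ensemble_result` with `rho_values`, `mean_rho`,
#'   `mean_rho_outbreak`, `delta` (see [variability_delta()]),
#'   `outbreak_fraction`, per-realization columns, and bookkeeping.
#' @export
run_ensemble <- function(net, params, n_realizations, seed, n_seeds = 1L,
                         seed_nodes = NULL, outbreak_cutoff = 0.01) {
  stopifnot(inherits(net, "epinet"), inherits(params, "epidemic_params"))
  n_realizations <- as.integer(n_realizations)
  if (is.na(n_realizations) || n_realizations < 1L) {
    stop("'n_realizations' must be a positive integer")
  }
  fixed <- if (is.null(seed_nodes)) integer(0) else as.integer(seed_nodes)
  runs <- .cpp_run_ensemble(net$n, net$adj_ptr, net$adj_idx,
                            params$beta, params$beta_f, params$gamma, params$mu,
                            n_realizations, as.integer(n_seeds), fixed,
                            as.integer(seed))
  rho <- runs[, "rho"]
  outbreak <- rho > outbreak_cutoff
  structure(
    list(
      rho_values = rho,
      mean_rho = mean(rho),
      mean_rho_outbreak = if (any(outbreak)) mean(rho[outbreak]) else NA_real_,
      outbreak_fraction = mean(outbreak),
      delta = variability_delta(rho),
      realization_count = n_realizations,
      runs = as.data.frame(runs),
      params = params,
      seed = seed,
      outbreak_cutoff = outbreak_cutoff
    ),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "ensemble: %d realizations, mean rho = %.4g (outbreak-conditioned %.4g), Delta = %.4g\n",
    x$realization_count, x$mean_rho, x$mean_rho_outbreak, x$delta))
  invisible(x)
}

#' Variability measure of an ensemble of final sizes
#'
#' `Delta = sqrt(<rho^2> - <rho>^2) / <rho>` with population moments over the
#' realizations — the relative standard deviation of the final epidemic size.
#' Its peak across a sweep in `beta` locates the epidemic threshold.
#'
#' @param rho_values nonempty numeric vector of per-realization final sizes.
#' @return A non-negative number; 0 when all values are equal; `NaN` with a
#'   warning when the mean is 0 (the measure is undefined).
#' @export
variability_delta <- function(rho_values) {
  if (length(rho_values) == 0L || any(!is.finite(rho_values))) {
    stop("'rho_values' must be a nonempty finite numeric vector")
  }
  m <- mean(rho_values)
  if (m == 0) {
    warning("mean final size is 0: Delta is undefined")
    return(NaN)
  }
  v <- mean(rho_values^2) - m^2
  sqrt(max(v, 0)) / m
}

#' Threshold estimate from the Delta peak
#'
#' Runs an ensemble at every value of a `beta` grid and returns the grid point
#' maximising the variability measure — the standard stochastic protocol for
#' locating the SIR-type epidemic threshold. Ties break toward smaller `beta`.
#'
#' @param net an [epinet].
#' @param beta_grid sorted grid of transmission rates.
#' @param beta_f,gamma,mu remaining rates.
#' @param n_realizations realizations per grid point.
#' @param seed master seed; each grid point uses a derived sub-seed.
#' @param n_seeds,outbreak_cutoff passed to [run_ensemble()].
#' @return List with `beta_c` (the argmax grid point), `curve` (a data frame
#'   of `beta`, `mean_rho`, `mean_rho_outbreak`, `delta`, `n_realizations`),
#'   and `interior_peak` (`FALSE`, with a warning, when the maximum sits on the
#'   grid boundary so the grid should be widened).
#' @export
threshold_by_delta_peak <- function(net, beta_grid, beta_f = 0, gamma = 0, mu = 1,
                                    n_realizations = 1000L, seed = 1L,
                                    n_seeds = 1L, outbreak_cutoff = 0.01) {
  if (length(beta_grid) < 1L || is.unsorted(beta_grid, strictly = TRUE)) {
    stop("'beta_grid' must be strictly increasing")
  }
  if (length(beta_grid) == 1L) {
    warning("single-point beta grid: returning it as the threshold estimate")
  }
  rows <- lapply(seq_along(beta_grid), function(i) {
    params <- epidemic_params(beta_grid[i], beta_f, gamma, mu)
    ens <- run_ensemble(net, params, n_realizations, derive_seed(seed, i),
                        n_seeds = n_seeds, outbreak_cutoff = outbreak_cutoff)
    data.frame(beta = beta_grid[i], mean_rho = ens$mean_rho,
               mean_rho_outbreak = ens$mean_rho_outbreak,
               delta = ens$delta, n_realizations = n_realizations)
  })
  curve <- do.call(rbind, rows)
  i_max <- which.max(curve$delta)
  interior <- length(beta_grid) >= 3L && i_max > 1L && i_max < length(beta_grid)
  if (!interior && length(beta_grid) > 1L) {
    warning("Delta has no interior peak on this grid; widen the beta grid")
  }
  list(beta_c = beta_grid[i_max], curve = curve, interior_peak = interior)
}
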