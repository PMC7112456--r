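# Dormand-Prince 5(4) adaptive integrator. The degree-class system is small
# (4 x support size) and non-stiff, so a self-contained explicit pair with
# step control is sufficient.
rk45 <- function(f, y0, t0, t_max, rtol = 1e-8, atol = 1e-10,
                 stop_fn = NULL, record_every = 0.5) {
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  )
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200, 187 / 2100, 1 / 40)

  t <- t0
  y <- y0
  h <- min(0.1, t_max - t0)
  ks <- vector("list", 7)
  ks[[1]] <- f(t, y)
  times <- t0
  states <- list(y0)
  next_rec <- t0 + record_every
  repeat {
    if (t >= t_max) break
    h <- min(h, t_max - t)
    for (i in 1:6) {
      yi <- y
      for (j in seq_along(a[[i]])) yi <- yi + h * a[[i]][j] * ks[[j]]
      ks[[i + 1]] <- f(t + h * sum(a[[i]]), yi)
    }
    y5 <- y
    for (j in 1:7) y5 <- y5 + h * b5[j] * ks[[j]]
    y4 <- y
    for (j in 1:7) y4 <- y4 + h * b4[j] * ks[[j]]
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {
      t <- t + h
      y <- y5
      ks[[1]] <- ks[[7]]  # FSAL
      if (t >= next_rec || t >= t_max) {
        times <- c(times, t)
        states[[length(states) + 1L]] <- y
        next_rec <- t + record_every
      }
      if (!is.null(stop_fn) && stop_fn(t, y)) break
    } else {
      ks[[1]] <- f(t, y)
    }
    h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    if (h < 1e-12) stop("integration step underflow at t = ", t)
  }
  list(t = times, y = do.call(rbind, states), t_end = t, y_end = y)
}

mf_unpack <- function(y, nk) {
  list(s = y[seq_len(nk)], f = y[nk + seq_len(nk)],
       i = y[2L * nk + seq_len(nk)], r = y[3L * nk + seq_len(nk)])
}

#' Degree-based mean-field right-hand side
#'
#' Time derivatives of the degree-class fractions under the first-order
#' (heterogeneous mean-field) closure. With `Theta = sum_k k P(k) I_k / <k>`
#' the probability that a random link points at an infectious node,
#' `dS_k = -(beta + beta_f) k S_k Theta`,
#' `dSF_k = beta_f k S_k Theta - gamma beta k SF_k Theta`,
#' `dI_k = k Theta beta (S_k + gamma SF_k) - mu I_k`,
#' `dR_k = mu I_k`. The recovery terms carry an explicit `mu` factor (the
#' closure is usually written with `mu = 1` absorbed).
#'
#' This closure predicts a threshold `<k>/<k^2>` independent of `beta_f` and
#' `gamma`: near the threshold the flux S -> S^F -> I is second order in the
#' infectious density once dynamic correlations are discarded, so the
#' protective class drops out of the linearisation. The stochastic simulator
#' and the percolation theory both contradict that prediction.
#'
#' @param state list with per-degree-class fractions `s`, `f`, `i`, `r`, each
#'   aligned with `dist$k`.
#' @param dist a [degree_distribution].
#' @param params an [epidemic_params].
#' @return List of the four derivative vectors, same shapes as the input.
#' @export
mf_rhs <- function(state, dist, params) {
  stopifnot(inherits(dist, "degree_distribution"), inherits(params, "epidemic_params"))
  k <- dist$k
  theta_link <- sum(k * dist$p * state$i) / dist$kmean
  drive <- k * theta_link
  ds <- -(params$beta + params$beta_f) * drive * state$s
  df <- params$beta_f * drive * state$s - params$gamma * params$beta * drive * state$f
  di <- params$beta * drive * (state$s + params$gamma * state$f) - params$mu * state$i
  dr <- params$mu * state$i
  list(s = ds, f = df, i = di, r = dr)
}

#' Integrate the mean-field system to its final state
#'
#' Starts from a uniform small infectious fraction in every degree class and
#' integrates until the aggregate infectious fraction falls below `i_floor` (or
#' `t_max`). The reported final size folds any residual infectious mass into
#' `R`.
#'
#' @param dist a [degree_distribution].
#' @param params an [epidemic_params].
#' @param i0 initial infectious fraction per degree class (default `1e-4`).
#' @param t_max integration horizon.
#' @param tol relative tolerance of the integrator.
#' @param i_floor termination level for the aggregate infectious fraction.
#' @return List with the recorded trajectory (`t` and aggregate `S`, `SF`,
#'   `I`, `R`), the final size `r_inf`, and `converged` (`TRUE` when the
#'   epidemic died out before `t_max`).
#' @export
integrate_mf <- function(dist, params, i0 = 1e-4, t_max = 10000, tol = 1e-8,
                         i_floor = 1e-9) {
  stopifnot(inherits(dist, "degree_distribution"), inherits(params, "epidemic_params"))
  if (i0 <= 0 || i0 >= 1) stop("'i0' must lie in (0, 1)")
  nk <- length(dist$k)
  p <- dist$p
  y0 <- c(rep(1 - i0, nk), rep(0, nk), rep(i0, nk), rep(0, nk))
  f <- function(t, y) {
    st <- mf_unpack(y, nk)
    d <- mf_rhs(st, dist, params)
    c(d$s, d$f, d$i, d$r)
  }
  agg_i <- function(y) sum(p * y[2L * nk + seq_len(nk)])
  sol <- rk45(f, y0, 0, t_max, rtol = tol, atol = tol * 1e-2,
              stop_fn = function(t, y) agg_i(y) < i_floor)
  traj <- t(apply(sol$y, 1L, function(y) {
    st <- mf_unpack(y, nk)
    c(S = sum(p * st$s), SF = sum(p * st$f), I = sum(p * st$i), R = sum(p * st$r))
  }))
  st_end <- mf_unpack(sol$y_end, nk)
  list(
    t = sol$t,
    trajectory = as.data.frame(traj),
    r_inf = sum(p * (st_end$r + st_end$i)),
    converged = agg_i(sol$y_end) < i_floor,
    t_end = sol$t_end
  )
}

#' Mean-field epidemic threshold
#'
#' The first-order closure gives `beta_c = <k> / <k^2>`, with no dependence on
#' the response rate or the discount factor.
#'
#' @param dist a [degree_distribution].
#' @return The mean-field critical transmission rate.
#' @export
mf_threshold <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (dist$k2mean <= 0) stop("second moment must be positive")
  dist$kmean / dist$k2mean
}

#' Mean-field final-size curve and liftoff point
#'
#' `mf_final_size_curve` integrates the system across a `beta` grid;
#' `mf_liftoff` additionally reports the smallest grid `beta` whose final size
#' exceeds `10 * i0` — the operational definition of the threshold used when
#' demonstrating that the mean-field liftoff ignores `beta_f` and `gamma`.
#'
#' @param dist a [degree_distribution].
#' @param beta_grid increasing transmission-rate grid.
#' @param beta_f,gamma,mu remaining rates.
#' @param i0 initial infectious fraction.
#' @param ... passed to [integrate_mf()].
#' @return `mf_final_size_curve`: a data frame of `beta` and `r_inf`.
#'   `mf_liftoff`: a list with `beta` (the liftoff point, `NA` if the curve
#'   never lifts off), `found`, and the `curve`.
#' @export
mf_final_size_curve <- function(dist, beta_grid, beta_f = 0, gamma = 0, mu = 1,
                                i0 = 1e-4, ...) {
  r <- vapply(beta_grid, function(b) {
    integrate_mf(dist, epidemic_params(b, beta_f, gamma, mu), i0 = i0, ...)$r_inf
  }, numeric(1))
  data.frame(beta = beta_grid, r_inf = r)
}

#' @rdname mf_final_size_curve
#' @export
mf_liftoff <- function(dist, beta_grid, beta_f = 0, gamma = 0, mu = 1,
                       i0 = 1e-4, ...) {
  curve <- mf_final_size_curve(dist, beta_grid, beta_f, gamma, mu, i0 = i0, ...)
  idx <- which(curve$r_inf > 10 * i0)
  list(
    beta = if (length(idx) > 0L) curve$beta[min(idx)] else NA_real_,
    found = length(idx) > 0L,
    curve = curve
  )
}
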