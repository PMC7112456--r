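#' Epidemic rate parameters
#'
#' The process on a network is defined by four reactions: an infectious node
#' transmits along each S-I edge at rate `beta`; it triggers the protective
#' response of the susceptible endpoint (S to S^F) at rate `beta_f`; protected
#' nodes are infected along S^F-I edges at the discounted rate `gamma * beta`;
#' infectious nodes recover at rate `mu`. `beta_f` is a rate, not a
#' probability, and may exceed 1. `gamma = 0` makes protection equivalent to
#' vaccination; `gamma = 1` (admitted as a validation limit) makes it
#' ineffective and the model collapses to classical SIR.
#'
#' @param beta transmission rate per S-I edge, non-negative.
#' @param beta_f response (alerting) rate per S-I edge, non-negative.
#' @param gamma discount factor in `[0, 1]`.
#' @param mu recovery rate, positive.
#' @return An object of class `epidemic_params`.
#' @export
epidemic_params <- function(beta, beta_f = 0, gamma = 0, mu = 1) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("'beta' must be a non-negative number")
  }
  if (!is.numeric(beta_f) || length(beta_f) != 1L || is.na(beta_f) || beta_f < 0) {
    stop("'beta_f' must be a non-negative number")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0 || gamma > 1) {
    stop("'gamma' must lie in [0, 1]")
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0) {
    stop("'mu' must be positive")
  }
  structure(list(beta = beta, beta_f = beta_f, gamma = gamma, mu = mu),
            class = "epidemic_params")
}

#' @export
print.epidemic_params <- function(x, ...) {
  cat(sprintf("epidemic params: beta = %g, beta_f = %g, gamma = %g, mu = %g\n",
              x$beta, x$beta_f, x$gamma, x$mu))
  invisible(x)
}

#' Per-edge competition probabilities
#'
#' Along an S-I edge, transmission (rate `beta`), alerting (rate `beta_f`) and
#' recovery of the infectious endpoint (rate `mu`) compete; the probabilities
#' that the edge ends up transmitting or alerting are `T1 = beta / (beta +
#' beta_f + mu)` and `T2 = beta_f / (beta + beta_f + mu)`. Along an S^F-I edge
#' only the discounted transmission competes with recovery, giving
#' `T3 = gamma*beta / (gamma*beta + mu)`.
#'
#' @param params an [epidemic_params].
#' @return Object of class `edge_probabilities` with fields `t1`, `t2`, `t3`.
#' @export
edge_probabilities <- function(params) {
  stopifnot(inherits(params, "epidemic_params"))
  denom <- params$beta + params$beta_f + params$mu
  gb <- params$gamma * params$beta
  structure(
    list(t1 = params$beta / denom,
         t2 = params$beta_f / denom,
         t3 = if (gb == 0) 0 else gb / (gb + params$mu)),
    class = "edge_probabilities"
  )
}

# Coefficients of the closed forms: for D = T1 + T2 - T3 away from 0,
#   p(R|m) = 1 - A (1-T1-T2)^m - B (1-T3)^m
# with A = (T1 - T3 + T2 T3)/D, B = (1-T3) T2 / D, A + B = 1.
# D -> 0 is a removable singularity (then 1-T3 -> 1-T1-T2), handled by the
# analytic limit wherever these coefficients are used.
DEGENERATE_EPS <- 1e-9

pr_coefs <- function(ep) {
  d <- ep$t1 + ep$t2 - ep$t3
  list(
    d = d,
    degenerate = abs(d) < DEGENERATE_EPS,
    a = if (abs(d) < DEGENERATE_EPS) NA_real_ else (ep$t1 - ep$t3 + ep$t2 * ep$t3) / d,
    b = if (abs(d) < DEGENERATE_EPS) NA_real_ else (1 - ep$t3) * ep$t2 / d
  )
}

#' Probability of infection given m externally infected neighbours
#'
#' Cavity-method conditional probability that a focal node ends up infected
#' when `m` of its neighbours are externally infected (infected even with the
#' focal node removed), under the non-overlapping ordering approximation: the
#' infectious neighbours act on the focal node one at a time, each resolving
#' to transmit / alert / recover with probabilities `(T1, T2, 1-T1-T2)`; after
#' an alert the remaining actors (including the alerting one) transmit with
#' probability `T3` each.
#'
#' @param m number of externally infected neighbours (vectorised).
#' @param ep an [edge_probabilities].
#' @return Probabilities in `[0, 1]`, exactly 0 at `m = 0`, nondecreasing in
#'   `m`.
#' @export
p_infected_given_m <- function(m, ep) {
  stopifnot(inherits(ep, "edge_probabilities"))
  m <- as.integer(m)
  if (any(is.na(m)) || any(m < 0L)) stop("'m' must be non-negative integers")
  co <- pr_coefs(ep)
  x <- 1 - ep$t1 - ep$t2
  y <- 1 - ep$t3
  out <- if (co$degenerate) {
    1 - x^m - (1 - ep$t3) * ep$t2 * m * x^pmax(m - 1L, 0L) * (m > 0L)
  } else {
    1 - co$a * x^m - co$b * y^m
  }
  pmin(pmax(out, 0), 1)
}

#' Probability of infection for a node of degree k
#'
#' Mixes [p_infected_given_m()] over a binomial number of externally infected
#' neighbours: each of the `k` neighbours is externally infected independently
#' with probability `theta`. Evaluated in closed form.
#'
#' @param k node degree (vectorised).
#' @param theta probability that a random neighbour is externally infected.
#' @param ep an [edge_probabilities].
#' @return Probabilities in `[0, 1]`.
#' @export
p_infected_given_k <- function(k, theta, ep) {
  stopifnot(inherits(ep, "edge_probabilities"))
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 0L)) stop("'k' must be non-negative integers")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1) {
    stop("'theta' must be a probability")
  }
  co <- pr_coefs(ep)
  xa <- 1 - theta * (ep$t1 + ep$t2)
  xb <- 1 - theta * ep$t3
  out <- if (co$degenerate) {
    1 - xa^k - (1 - ep$t3) * ep$t2 * theta * k * xa^pmax(k - 1L, 0L) * (k > 0L)
  } else {
    1 - co$a * xa^k - co$b * xb^k
  }
  pmin(pmax(out, 0), 1)
}

# Self-consistency map f(theta): the probability that a node reached along a
# random edge is externally infected, given neighbour EIN probability theta.
theta_map <- function(theta, dist, ep) {
  co <- pr_coefs(ep)
  xa <- 1 - theta * (ep$t1 + ep$t2)
  xb <- 1 - theta * ep$t3
  if (co$degenerate) {
    1 - g1(dist, xa) - (1 - ep$t3) * ep$t2 * theta * g1_prime(dist, xa)
  } else {
    1 - co$a * g1(dist, xa) - co$b * g1(dist, xb)
  }
}

#' Solve the self-consistent equation for the EIN probability
#'
#' Finds the largest fixed point in `[0, 1]` of the cavity map
#' `theta = f(theta)` by fixed-point iteration started at `theta = 1` (the map
#' is nondecreasing, so the iteration converges monotonically to the largest,
#' physical, fixed point), with 0.5 damping if the iterates oscillate. When the
#' outbreak condition fails the only fixed point is 0 and it is returned
#' exactly.
#'
#' @param dist a [degree_distribution].
#' @param params an [epidemic_params].
#' @param tol residual tolerance on `|theta - f(theta)|`.
#' @param max_iter iteration cap; hitting it flags `converged = FALSE` rather
#'   than erroring.
#' @return List with `theta`, `converged`, `iterations`, `residual`.
#' @export
solve_theta <- function(dist, params, tol = 1e-12, max_iter = 100000L) {
  stopifnot(inherits(dist, "degree_distribution"), inherits(params, "epidemic_params"))
  oc <- outbreak_condition(dist, params)
  if (!oc$outbreak) {
    return(list(theta = 0, converged = TRUE, iterations = 0L, residual = 0))
  }
  ep <- edge_probabilities(params)
  theta <- 1
  prev_step <- 0
  for (it in seq_len(max_iter)) {
    fnew <- theta_map(theta, dist, ep)
    step <- fnew - theta
    theta_new <- if (step * prev_step < 0) theta + 0.5 * step else fnew
    prev_step <- step
    if (abs(step) <= tol) {
      return(list(theta = theta_new, converged = TRUE, iterations = it,
                  residual = abs(theta_new - theta_map(theta_new, dist, ep))))
    }
    theta <- theta_new
  }
  list(theta = theta, converged = FALSE, iterations = max_iter,
       residual = abs(theta - theta_map(theta, dist, ep)))
}

#' Final epidemic prevalence from the percolation theory
#'
#' Solves for the EIN probability `theta` and evaluates the final size
#' `R(infinity) = 1 - A G0(1 - theta(T1+T2)) - B G0(1 - theta T3)`, the
#' degree-distribution average of [p_infected_given_k()].
#'
#' @inheritParams solve_theta
#' @return List with `theta`, `prevalence`, `converged`, `iterations`.
#' @export
final_prevalence <- function(dist, params, tol = 1e-12, max_iter = 100000L) {
  sol <- solve_theta(dist, params, tol = tol, max_iter = max_iter)
  ep <- edge_probabilities(params)
  co <- pr_coefs(ep)
  theta <- sol$theta
  xa <- 1 - theta * (ep$t1 + ep$t2)
  xb <- 1 - theta * ep$t3
  r_inf <- if (co$degenerate) {
    1 - g0(dist, xa) - (1 - ep$t3) * ep$t2 * theta * g0_prime(dist, xa)
  } else {
    1 - co$a * g0(dist, xa) - co$b * g0(dist, xb)
  }
  list(theta = theta, prevalence = min(max(r_inf, 0), 1),
       converged = sol$converged, iterations = sol$iterations)
}

#' Outbreak condition and threshold margin
#'
#' A giant outbreak is possible when the linearisation of the cavity map at the
#' origin exceeds 1: `(T1 + T2*T3) * G1'(1) >= 1`. In terms of rates this reads
#' `beta (mu + gamma beta + gamma beta_f) / [(mu + gamma beta)(mu + beta +
#' beta_f)] >= <k> / (<k^2> - <k>)`.
#'
#' @inheritParams solve_theta
#' @return List with logical `outbreak` and the signed `margin`
#'   `(T1 + T2*T3) G1'(1) - 1` (`-Inf` when the network has no giant
#'   component potential, i.e. `<k^2> <= <k>`).
#' @export
outbreak_condition <- function(dist, params) {
  stopifnot(inherits(dist, "degree_distribution"), inherits(params, "epidemic_params"))
  g1p <- g1_prime_at_1(dist)
  if (g1p <= 0) return(list(outbreak = FALSE, margin = -Inf))
  ep <- edge_probabilities(params)
  margin <- (ep$t1 + ep$t2 * ep$t3) * g1p - 1
  list(outbreak = margin >= 0, margin = margin)
}

#' Epidemic threshold in beta
#'
#' Bisection root of the outbreak margin as a function of `beta` at fixed
#' `beta_f`, `gamma`, `mu`. For a Poisson degree distribution this solves
#' `beta (mu + gamma beta + gamma beta_f) / [(mu + gamma beta)(mu + beta +
#' beta_f)] = 1 / <k>` (up to the `G1'(1) = <k>` identity).
#'
#' @param dist a [degree_distribution].
#' @param beta_f,gamma,mu fixed rates.
#' @param bracket search interval for `beta`; the margin must change sign
#'   across it.
#' @param tol relative tolerance on the root.
#' @return The critical transmission rate `beta_c`.
#' @export
solve_threshold_beta <- function(dist, beta_f = 0, gamma = 0, mu = 1,
                                 bracket = c(1e-6, 50 * mu), tol = 1e-10) {
  margin_fn <- function(beta) {
    outbreak_condition(dist, epidemic_params(beta, beta_f, gamma, mu))$margin
  }
  lo <- margin_fn(bracket[1L])
  hi <- margin_fn(bracket[2L])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) {
    stop(sprintf(
      "no sign change in bracket [%g, %g]: margin(%g) = %g, margin(%g) = %g",
      bracket[1L], bracket[2L], bracket[1L], lo, bracket[2L], hi))
  }
  uniroot(margin_fn, interval = bracket, tol = tol * max(1, bracket[2L]))$root
}
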