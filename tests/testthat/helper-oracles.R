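# Independent oracles used to cross-check the package implementation. These
# deliberately avoid the package's own generating-function and fixed-point
# code paths.

# Classical SIR bond percolation on a degree distribution given as (k, p):
# transmissibility T = beta/(beta+mu), theta solves theta = 1 - G1(1 - T theta),
# final size 1 - G0(1 - T theta), threshold T G1'(1) = 1.
sir_percolation_oracle <- function(k, p, beta, mu) {
  p <- p / sum(p)
  TT <- beta / (beta + mu)
  kmean <- sum(k * p)
  kk <- k[k >= 1]
  qq <- kk * p[k >= 1] / kmean
  G0 <- function(x) sum(p * x^k)
  G1 <- function(x) sum(qq * x^(kk - 1))
  g <- function(th) th - (1 - G1(1 - TT * th))
  g1p <- sum(qq * (kk - 1))
  theta <- if (g(1e-9) > 0 || TT * g1p <= 1) 0 else {
    uniroot(g, c(1e-9, 1), tol = 1e-15)$root
  }
  list(theta = theta,
       r_inf = if (theta == 0) 0 else 1 - G0(1 - TT * theta),
       beta_c = if (g1p > 1) mu / (g1p - 1) else Inf)
}

# Monte-Carlo oracle for the conditional infection probability p(R|m): the m
# externally infected neighbours act on the focal node one at a time; while
# the node is susceptible each actor transmits w.p. T1, alerts w.p. T2 or
# does nothing (recovers first) w.p. 1-T1-T2; from the alerting actor onward
# (inclusive) each remaining actor transmits w.p. T3.
mc_p_infected_given_m <- function(m, ep, n_rep) {
  infected <- logical(n_rep)
  alerted <- logical(n_rep)
  for (j in seq_len(m)) {
    u <- runif(n_rep)
    v <- runif(n_rep)
    still_s <- !infected & !alerted
    in_f <- !infected & alerted
    infected[in_f & v < ep$t3] <- TRUE
    new_inf <- still_s & u < ep$t1
    new_alert <- still_s & u >= ep$t1 & u < ep$t1 + ep$t2
    infected[new_inf] <- TRUE
    alerted[new_alert] <- TRUE
    infected[new_alert & v < ep$t3] <- TRUE  # alerting actor retries at T3
  }
  mean(infected)
}

# Independent degree-based SIR mean-field (no protective class), fixed-step
# RK4; used to check the beta_f = 0 reduction of the full system.
sir_meanfield_oracle <- function(k, p, beta, mu, i0, dt = 0.02, t_max = 3000) {
  kmean <- sum(k * p)
  s <- rep(1 - i0, length(k)); i <- rep(i0, length(k)); r <- rep(0, length(k))
  rhs <- function(s, i) {
    th <- sum(k * p * i) / kmean
    list(ds = -beta * k * th * s, di = beta * k * th * s - mu * i, dr = mu * i)
  }
  t <- 0
  while (t < t_max && sum(p * i) > 1e-9) {
    k1 <- rhs(s, i)
    k2 <- rhs(s + dt / 2 * k1$ds, i + dt / 2 * k1$di)
    k3 <- rhs(s + dt / 2 * k2$ds, i + dt / 2 * k2$di)
    k4 <- rhs(s + dt * k3$ds, i + dt * k3$di)
    s <- s + dt / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
    inew <- i + dt / 6 * (k1$di + 2 * k2$di + 2 * k3$di + k4$di)
    r <- r + dt / 6 * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr)
    i <- inew
    t <- t + dt
  }
  sum(p * (r + i))
}

# small deterministic fixtures
path_graph3 <- function() epinet(3, rbind(c(0, 1), c(1, 2)))
ring_graph <- function(n) epinet(n, cbind(0:(n - 1), c(1:(n - 1), 0)))
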