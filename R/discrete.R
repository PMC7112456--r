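# Synchronous small-timestep reference engine. Not exported: it exists only to
# cross-validate the event-driven simulator (the two must agree statistically
# as dt -> 0). Per step each I->S contact infects w.p. beta*dt or alerts w.p.
# beta_f*dt, each I->S^F contact infects w.p. gamma*beta*dt, and each I node
# recovers w.p. mu*dt; simultaneous infection and alerting of one node
# resolves in favour of infection (an O(dt^2) event).
sim_discrete <- function(net, params, dt, seed_nodes, seed, t_max = Inf) {
  stopifnot(inherits(net, "epinet"), inherits(params, "epidemic_params"), dt > 0)
  n <- net$n
  e <- net$edges + 1L
  src <- c(e[, 1L], e[, 2L])
  dst <- c(e[, 2L], e[, 1L])
  p_inf <- params$beta * dt
  p_alert <- params$beta_f * dt
  p_inf_f <- params$gamma * params$beta * dt
  p_rec <- params$mu * dt
  if (p_inf + p_alert > 1 || p_inf_f > 1 || p_rec > 1) {
    stop("dt too large for the given rates")
  }
  # states: 0 = S, 1 = S^F, 2 = I, 3 = R
  state <- integer(n)
  state[seed_nodes + 1L] <- 2L
  t <- 0
  with_seed(seed, {
    while (any(state == 2L) && t < t_max) {
      active <- state[src] == 2L
      tgt <- dst[active]
      ts <- state[tgt]
      u <- runif(length(tgt))
      new_i <- unique(c(tgt[ts == 0L & u < p_inf], tgt[ts == 1L & u < p_inf_f]))
      new_f <- setdiff(unique(tgt[ts == 0L & u >= p_inf & u < p_inf + p_alert]), new_i)
      inf_nodes <- which(state == 2L)
      rec <- inf_nodes[runif(length(inf_nodes)) < p_rec]
      state[new_i] <- 2L
      state[new_f] <- 1L
      state[rec] <- 3L
      t <- t + dt
    }
  })
  list(final_recovered_fraction = sum(state == 3L) / n,
       final_sf_fraction = sum(state == 1L) / n,
       t_end = t)
}
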