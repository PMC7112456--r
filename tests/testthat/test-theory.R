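test_that("edge probabilities are the rate-competition ratios", {
  ep <- edge_probabilities(epidemic_params(1, 1, 0.5, 1))
  expect_equal(ep$t1, 1 / 3)
  expect_equal(ep$t2, 1 / 3)
  expect_equal(ep$t3, 1 / 3)

  ep2 <- edge_probabilities(epidemic_params(0.4, 0, 0.7, 1))  # beta_f = 0
  expect_equal(ep2$t2, 0)
  expect_equal(ep2$t1, 0.4 / 1.4)

  expect_equal(edge_probabilities(epidemic_params(0.4, 1, 0, 1))$t3, 0)  # gamma = 0
  expect_error(epidemic_params(-1, 0, 0, 1), "beta")
  expect_error(epidemic_params(1, 0, 1.5, 1), "gamma")
  expect_error(epidemic_params(1, 0, 0, 0), "mu")
})

test_that("p(R|m) has the right limits and is monotone in m", {
  set.seed(71)
  for (rep in 1:20) {
    ep <- edge_probabilities(
      epidemic_params(runif(1, 0.01, 2), runif(1, 0, 3), runif(1, 0, 1), 1))
    pm <- p_infected_given_m(0:12, ep)
    expect_equal(pm[1], 0)
    expect_true(all(pm >= 0 & pm <= 1))
    expect_true(all(diff(pm) >= -1e-12))
  }

  # beta_f = 0 collapses to classical per-contact escape
  ep <- edge_probabilities(epidemic_params(0.5, 0, 0.4, 1))
  expect_equal(p_infected_given_m(1:8, ep), 1 - (1 - ep$t1)^(1:8), tolerance = 1e-12)

  # degenerate denominator T1+T2 = T3 (gamma = 1, beta_f = 0): same SIR limit
  epd <- edge_probabilities(epidemic_params(0.5, 0, 1, 1))
  expect_equal(ep$t1 + ep$t2 - ep$t3 > 1e-9, TRUE)
  expect_equal(epd$t1 + epd$t2 - epd$t3, 0)
  expect_equal(p_infected_given_m(1:8, epd), 1 - (1 - epd$t1)^(1:8), tolerance = 1e-12)
})

test_that("p(R|k) equals the binomial mixture of p(R|m)", {
  expect_equal(p_infected_given_k(0:7, 0,
                                  edge_probabilities(epidemic_params(1, 1, 0.5))),
               rep(0, 8))

  # one-neighbour enumeration: infect directly or alert-then-infect
  ep <- edge_probabilities(epidemic_params(0.7, 1.3, 0.45, 1))
  expect_equal(p_infected_given_k(1, 1, ep), ep$t1 + ep$t2 * ep$t3, tolerance = 1e-14)

  set.seed(12)
  for (rep in 1:10) {
    ep <- edge_probabilities(
      epidemic_params(runif(1, 0.05, 1.5), runif(1, 0, 2), runif(1, 0, 1), 1))
    theta <- runif(1)
    for (k in c(1L, 6L, 17L, 50L)) {
      m <- 0:k
      brute <- sum(dbinom(m, k, theta) * p_infected_given_m(m, ep))
      expect_equal(p_infected_given_k(k, theta, ep), brute, tolerance = 1e-12)
    }
  }
})

test_that("the cavity map fixes the origin and is nondecreasing", {
  pois <- poisson_degree_distribution(10)
  set.seed(31)
  for (rep in 1:15) {
    ep <- edge_probabilities(
      epidemic_params(runif(1, 0.01, 1), runif(1, 0, 3), runif(1, 0, 1), 1))
    th <- seq(0, 1, length.out = 41)
    fv <- vapply(th, function(t) ssfir:::theta_map(t, pois, ep), numeric(1))
    expect_equal(fv[1], 0, tolerance = 1e-14)
    expect_true(all(diff(fv) >= -1e-12))
    expect_true(all(fv >= -1e-12 & fv <= 1 + 1e-12))
  }
})

test_that("solve_theta finds the physical fixed point", {
  pois <- poisson_degree_distribution(10)

  sub <- solve_theta(pois, epidemic_params(0.05, 0, 0, 1))
  expect_identical(sub$theta, 0)

  sol <- solve_theta(pois, epidemic_params(0.2, 0, 0.5, 1), tol = 1e-13)
  ep <- edge_probabilities(epidemic_params(0.2, 0, 0.5, 1))
  expect_lt(abs(sol$theta - ssfir:::theta_map(sol$theta, pois, ep)), 1e-10)
  expect_true(sol$converged)

  # beta_f = 0 reduces to the classical bond-percolation fixed point
  oracle <- sir_percolation_oracle(pois$k, pois$p, 0.2, 1)
  expect_equal(sol$theta, oracle$theta, tolerance = 1e-9)
})

test_that("prevalence matches its degree-average definition and responds to gamma", {
  pois <- poisson_degree_distribution(10)

  expect_lt(final_prevalence(pois, epidemic_params(0.05, 0, 0, 1))$prevalence, 1e-10)

  params <- epidemic_params(0.25, 1.2, 0.4, 1)
  sol <- final_prevalence(pois, params, tol = 1e-14)
  ep <- edge_probabilities(params)
  direct <- sum(pois$p * p_infected_given_k(pois$k, sol$theta, ep))
  expect_equal(sol$prevalence, direct, tolerance = 1e-10)

  # lowering the discount factor never increases the final size
  r <- vapply(c(0.8, 0.5, 0.3, 0.1), function(g) {
    final_prevalence(pois, epidemic_params(0.25, 1.2, g, 1))$prevalence
  }, numeric(1))
  expect_true(all(diff(r) <= 1e-10))
})

test_that("outbreak condition: both algebraic forms agree and limits hold", {
  pois <- poisson_degree_distribution(10)
  expect_false(outbreak_condition(pois, epidemic_params(0, 5, 0.5, 1))$outbreak)

  leaf <- degree_distribution(0:1, c(0.5, 0.5))  # no giant component possible
  oc <- outbreak_condition(leaf, epidemic_params(2, 0, 0, 1))
  expect_false(oc$outbreak)
  expect_identical(oc$margin, -Inf)

  set.seed(99)
  for (rep in 1:25) {
    beta <- runif(1, 0.01, 2); bf <- runif(1, 0, 3); g <- runif(1, 0, 1); mu <- runif(1, 0.5, 2)
    params <- epidemic_params(beta, bf, g, mu)
    m1 <- outbreak_condition(pois, params)$margin
    # rate form of the same condition
    lhs <- beta * (mu + g * beta + g * bf) / ((mu + g * beta) * (mu + beta + bf))
    m2 <- lhs * g1_prime_at_1(pois) - 1
    expect_equal(m1, m2, tolerance = 1e-12)
    # gamma = 1: condition reduces to classical SIR regardless of beta_f
    m3 <- outbreak_condition(pois, epidemic_params(beta, bf, 1, mu))$margin
    m4 <- beta / (beta + mu) * g1_prime_at_1(pois) - 1
    expect_equal(m3, m4, tolerance = 1e-12)
  }
})

test_that("threshold solver reproduces closed forms and reports bad brackets", {
  pois <- poisson_degree_distribution(10)
  expect_equal(solve_threshold_beta(pois, 0, 0, 1), 1 / 9, tolerance = 1e-10)
  expect_equal(solve_threshold_beta(pois, 0.5, 0, 1), 1.5 / 9, tolerance = 1e-10)
  for (bf in c(0, 1, 4)) {
    expect_equal(solve_threshold_beta(pois, bf, 1, 1), 1 / 9, tolerance = 1e-10)
  }
  expect_error(solve_threshold_beta(pois, 0, 0, 1, bracket = c(0.5, 1)),
               "no sign change")

  # threshold > 0 exactly when the margin crosses: theta agrees either side
  bc <- solve_threshold_beta(pois, 1, 0.2, 1)
  below <- solve_theta(pois, epidemic_params(bc * 0.97, 1, 0.2, 1))
  above <- solve_theta(pois, epidemic_params(bc * 1.03, 1, 0.2, 1))
  expect_identical(below$theta, 0)
  expect_gt(above$theta, 0)
})
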