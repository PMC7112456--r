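test_that("epinet enforces simple-graph invariants", {
  expect_error(epinet(3, rbind(c(0, 0))), "self-loop")
  expect_error(epinet(3, rbind(c(0, 1), c(1, 0))), "duplicate")
  expect_error(epinet(3, rbind(c(0, 3))), "endpoints")
  net <- epinet(4, rbind(c(2, 1), c(0, 1)))
  expect_equal(net$edges, rbind(c(0L, 1L), c(1L, 2L)))  # canonical order
  expect_equal(net$degree, c(1L, 2L, 1L, 0L))
  expect_equal(net$adj_ptr, c(0L, 1L, 3L, 4L, 4L))
})

test_that("ER generator hits forced and statistical targets", {
  expect_error(er_network(1, 0.5, seed = 1), ">= 2")
  expect_error(er_network(100, 0, seed = 1), "mean_degree")

  tiny <- er_network(2, 1, seed = 1)  # p = 1: the single edge is forced
  expect_equal(tiny$edges, rbind(c(0L, 1L)))

  # realized mean degree within 3 standard errors of the target:
  # Var(mean degree) ~ 2 p (1-p) (n-1) / n ~ 2 <k> / n
  for (n in c(1000L, 10000L)) {
    net <- er_network(n, 10, seed = 42)
    se <- sqrt(2 * 10 / n)
    expect_lt(abs(mean(net$degree) - 10), 3 * se)
  }
})

test_that("ER degrees are Poisson-like: variance tracks the mean", {
  # pooled over 20 seeds at n = 1000, <k> = 10; sd of the pooled sample
  # variance of Poisson(10) over 20000 draws is about 0.1
  degs <- unlist(lapply(1:20, function(s) er_network(1000, 10, seed = s)$degree))
  expect_lt(abs(var(degs) - mean(degs)), 0.5)
})

test_that("UCM generator respects degree bounds and the power law", {
  expect_error(ucm_network(100, exponent = 1.5, seed = 1), "exponent")
  expect_error(ucm_network(100, k_min = 1, seed = 1), "k_min")

  small <- ucm_network(100, 3, 3, seed = 7)  # k_max = floor(sqrt(100)) = 10
  expect_true(all(small$degree >= 3 & small$degree <= 10))

  big <- ucm_network(10000, 3, 3, seed = 11)
  expect_equal(min(big$degree), 3L)
  expect_lte(max(big$degree), 100L)
  key <- as.double(big$edges[, 1]) * big$n + big$edges[, 2]
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(big$edges[, 1] < big$edges[, 2]))

  # pooled log-log degree histogram over 10 seeds has slope ~ -3
  degs <- unlist(lapply(1:10, function(s) ucm_network(5000, 3, 3, seed = s)$degree))
  tab <- table(degs)
  k <- as.integer(names(tab))
  keep <- k <= 25 & tab >= 50
  fit <- lm(log(as.numeric(tab[keep])) ~ log(k[keep]))
  expect_lt(abs(unname(coef(fit)[2]) + 3), 0.15)
})

test_that("empirical degree distribution matches hand counts", {
  d <- empirical_degree_distribution(path_graph3())
  expect_equal(d$p[d$k == 1], 2 / 3)
  expect_equal(d$p[d$k == 2], 1 / 3)
  expect_equal(d$kmean, 4 / 3)

  reg <- empirical_degree_distribution(ring_graph(10))
  expect_equal(reg$p[reg$k == 2], 1)

  # Poisson identity <k^2> - <k> = <k>^2 up to sampling error
  d2 <- empirical_degree_distribution(er_network(10000, 10, seed = 3))
  expect_lt(abs((d2$k2mean - d2$kmean) - d2$kmean^2) / d2$kmean^2, 0.05)
})

test_that("generating functions obey their defining identities", {
  d <- degree_distribution(2L, 1)
  expect_equal(g0(d, 0.5), 0.25)
  expect_equal(g0(d, 1), 1)
  expect_error(g0(d, 1.2), "\\[0, 1\\]")

  d3 <- degree_distribution(3L, 1)  # 3-regular: Q concentrated at 2
  expect_equal(g1(d3, 0.7), 0.49)
  expect_equal(g1_prime_at_1(d3), 2)

  pois <- poisson_degree_distribution(10)
  expect_equal(g0(pois, 0.9), exp(-1), tolerance = 1e-10)
  xs <- c(0, 0.3, 0.8, 1)
  expect_equal(g1(pois, xs), g0(pois, xs), tolerance = 1e-10)  # G0 = G1 for Poisson
  expect_equal(g1_prime_at_1(pois), 10, tolerance = 1e-9)

  # arbitrary distribution: Q sums to 1, G1'(1) equals the direct sum and a
  # one-sided finite difference
  set.seed(5)
  for (rep in 1:5) {
    k <- sort(sample(0:30, 8))
    p <- runif(8); p <- p / sum(p)
    d <- degree_distribution(k, p)
    ex <- ssfir:::excess_distribution(d)
    expect_equal(sum(ex$q), 1, tolerance = 1e-12)
    expect_equal(g1_prime_at_1(d), sum(ex$k * ex$q), tolerance = 1e-12)
    h <- 1e-7
    expect_equal(g1_prime_at_1(d), (g1(d, 1) - g1(d, 1 - h)) / h, tolerance = 1e-5)
  }
})

test_that("edge-list io round-trips and reports bad lines", {
  f <- tempfile()
  writeLines(c("# a comment", "0 1", "1 2"), f)
  net <- read_edge_list(f)
  expect_equal(net$n, 3L)
  expect_equal(net$edges, rbind(c(0L, 1L), c(1L, 2L)))

  g <- ucm_network(300, 3, 3, seed = 9)
  write_edge_list(g, f)
  expect_equal(read_edge_list(f)$edges, g$edges)

  writeLines(c("0 1", "2 2"), f)
  expect_error(read_edge_list(f), "line 2: self-loop")
  writeLines(c("0 1", "1 0"), f)
  expect_error(read_edge_list(f), "line 2: duplicate")
  writeLines(c("0 1", "1 2 3"), f)
  expect_error(read_edge_list(f), "line 2")

  d <- empirical_degree_distribution(g)
  f2 <- tempfile()
  write_degree_distribution(d, f2)
  d2 <- read_degree_distribution(f2)
  expect_equal(d2$p, d$p, tolerance = 1e-12)
  expect_equal(d2$k, d$k)
})
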