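#' Network container for epidemic simulation
#'
#' An `epinet` is an undirected simple graph on nodes `0, ..., n-1` stored as a
#' canonical edge matrix plus a compressed adjacency structure used by the
#' event-driven simulator. Node ids are 0-based to match the on-disk edge-list
#' format.
#'
#' @param n number of nodes (positive integer).
#' @param edges two-column integer matrix of 0-based endpoints, one edge per
#'   row. Self-loops and duplicate edges are rejected.
#' @return An object of class `epinet` with elements `n`, `edges` (canonical:
#'   smaller endpoint first, rows sorted), `degree` (length `n`), and the
#'   adjacency arrays `adj_ptr` / `adj_idx` (0-based CSR layout).
#' @export
epinet <- function(n, edges) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("'n' must be a positive integer")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)) || any(edges < 0L) || any(edges >= n)) {
      stop("edge endpoints must be integers in [0, n-1]")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L)]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    key <- as.double(edges[, 1L]) * n + edges[, 2L]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  both <- rbind(edges, edges[, c(2L, 1L), drop = FALSE])
  o <- order(both[, 1L], both[, 2L])
  deg <- tabulate(both[, 1L] + 1L, nbins = n)
  structure(
    list(
      n = n,
      edges = edges,
      degree = deg,
      adj_ptr = c(0L, cumsum(deg)),
      adj_idx = both[o, 2L]
    ),
    class = "epinet"
  )
}

#' @export
print.epinet <- function(x, ...) {
  cat(sprintf("epinet: %d nodes, %d edges, mean degree %.4g\n",
              x$n, nrow(x$edges), mean(x$degree)))
  invisible(x)
}

#' Erdos-Renyi random graph
#'
#' Samples a G(n, p) graph with `p = mean_degree / (n - 1)`, so the expected
#' mean degree equals `mean_degree`.
#'
#' @param n number of nodes, at least 2.
#' @param mean_degree target mean degree, in `(0, n-1)`.
#' @param seed integer seed; the generator is self-contained and does not touch
#'   R's RNG state.
#' @return An [epinet].
#' @export
er_network <- function(n, mean_degree, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (!is.numeric(mean_degree) || mean_degree <= 0 || mean_degree >= n - 1 + 1e-12) {
    stop("'mean_degree' must lie in (0, n-1)")
  }
  p <- min(1, mean_degree / (n - 1))
  epinet(n, .cpp_er_edges(n, p, as.integer(seed)))
}

#' Uncorrelated configuration-model graph with power-law degrees
#'
#' Draws a degree sequence from `P(k)` proportional to `k^-exponent` on
#' `[k_min, floor(sqrt(n))]` and matches stubs into a simple graph. The
#' `sqrt(n)` degree cutoff suppresses degree-degree correlations. Stub pairs
#' that would create a self-loop or multi-edge are redrawn; if the matching
#' deadlocks it is restarted from scratch (bounded by `max_restarts`), which
#' preserves the degree sequence exactly.
#'
#' @param n number of nodes.
#' @param exponent power-law exponent, must exceed 2.
#' @param k_min minimum degree, `2 <= k_min < sqrt(n)`.
#' @param seed integer seed.
#' @param max_restarts bound on full re-matchings before giving up.
#' @return An [epinet] whose degrees all lie in `[k_min, floor(sqrt(n))]`.
#' @export
ucm_network <- function(n, exponent = 3, k_min = 3, seed, max_restarts = 100L) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop("'n' must be an integer >= 4")
  if (exponent <= 2) stop("'exponent' must be > 2")
  k_max <- as.integer(floor(sqrt(n)))
  if (k_min < 2 || k_min >= sqrt(n)) stop("'k_min' must satisfy 2 <= k_min < sqrt(n)")
  support <- k_min:k_max
  prob <- support^(-exponent)
  degrees <- with_seed(seed, {
    d <- sample(support, n, replace = TRUE, prob = prob)
    while (sum(d) %% 2L == 1L) d[1L] <- sample(support, 1L, prob = prob)
    d
  })
  epinet(n, .cpp_stub_match(degrees, as.integer(seed), as.integer(max_restarts)))
}

#' Degree distribution with generating-function calculus
#'
#' Represents `P(k)` on a finite support together with its first two moments.
#' The excess degree distribution `Q(k) = (k+1) P(k+1) / <k>` (degree of a node
#' reached along a random edge, excluding that edge) and the generating
#' functions [g0()] and [g1()] are derived from it.
#'
#' @param k integer support (non-negative degrees, strictly increasing).
#' @param p probabilities `P(k)`, non-negative, summing to 1 (tolerance 1e-8;
#'   renormalised exactly on construction).
#' @return An object of class `degree_distribution` with elements `k`, `p`,
#'   `kmean`, `k2mean`.
#' @export
degree_distribution <- function(k, p) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 0L) || is.unsorted(k, strictly = TRUE)) {
    stop("'k' must be strictly increasing non-negative integers")
  }
  if (length(p) != length(k) || any(!is.finite(p)) || any(p < 0)) {
    stop("'p' must be non-negative and match 'k' in length")
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-8) stop("'p' must sum to 1 (got ", format(s), ")")
  p <- p / s
  kmean <- sum(k * p)
  if (kmean <= 0) stop("degree distribution has zero mean degree")
  structure(
    list(k = k, p = p, kmean = kmean, k2mean = sum(as.double(k)^2 * p)),
    class = "degree_distribution"
  )
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("degree distribution on k in [%d, %d]: <k> = %.6g, <k^2> = %.6g\n",
              min(x$k), max(x$k), x$kmean, x$k2mean))
  invisible(x)
}

#' @describeIn degree_distribution realized degree histogram of a network.
#' @param net an [epinet].
#' @export
empirical_degree_distribution <- function(net) {
  stopifnot(inherits(net, "epinet"))
  counts <- tabulate(net$degree + 1L, nbins = max(net$degree) + 1L)
  degree_distribution(0:max(net$degree), counts / net$n)
}

#' @describeIn degree_distribution Poisson degrees with the stated mean,
#'   truncated where the upper tail mass drops below `tail_tol`.
#' @param mean_degree,tail_tol Poisson mean and truncation tolerance.
#' @export
poisson_degree_distribution <- function(mean_degree, tail_tol = 1e-12) {
  stopifnot(mean_degree > 0)
  kmax <- ceiling(mean_degree + 10 * sqrt(mean_degree))
  while (ppois(kmax, mean_degree, lower.tail = FALSE) > tail_tol) kmax <- kmax + 5
  p <- dpois(0:kmax, mean_degree)
  degree_distribution(0:kmax, p / sum(p))
}

#' @describeIn degree_distribution pure power law `P(k) ~ k^-exponent` on
#'   `[k_min, k_max]`.
#' @param exponent,k_min,k_max power-law parameters.
#' @export
powerlaw_degree_distribution <- function(exponent, k_min, k_max) {
  stopifnot(k_min >= 1, k_max >= k_min)
  k <- k_min:k_max
  p <- k^(-exponent)
  degree_distribution(k, p / sum(p))
}

# Excess degree distribution Q(k) = (k+1) P(k+1) / <k> on support k - 1.
excess_distribution <- function(dist) {
  keep <- dist$k >= 1L
  k <- dist$k[keep]
  list(k = k - 1L, q = k * dist$p[keep] / dist$kmean)
}

#' Degree generating functions
#'
#' `g0(dist, x)` evaluates the probability generating function of `P(k)`;
#' `g1(dist, x)` that of the excess degree distribution `Q(k)`;
#' `g1_prime_at_1(dist)` returns the mean excess degree
#' `G1'(1) = (<k^2> - <k>) / <k>`, the branching factor that controls the
#' epidemic threshold.
#'
#' @param dist a [degree_distribution].
#' @param x evaluation point(s) in `[0, 1]`.
#' @return Numeric vector of the same length as `x`.
#' @export
g0 <- function(dist, x) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  vapply(x, function(xx) sum(dist$p * xx^dist$k), numeric(1))
}

#' @rdname g0
#' @export
g1 <- function(dist, x) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  ex <- excess_distribution(dist)
  vapply(x, function(xx) sum(ex$q * xx^ex$k), numeric(1))
}

#' @rdname g0
#' @export
g1_prime_at_1 <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  (dist$k2mean - dist$kmean) / dist$kmean
}

# derivative of G1 at interior points, needed for the removable singularity
# of the cavity equations when T1 + T2 = T3
g1_prime <- function(dist, x) {
  ex <- excess_distribution(dist)
  keep <- ex$k >= 1L
  vapply(x, function(xx) sum(ex$q[keep] * ex$k[keep] * xx^(ex$k[keep] - 1L)), numeric(1))
}

g0_prime <- function(dist, x) {
  keep <- dist$k >= 1L
  vapply(x, function(xx) {
    sum(dist$p[keep] * dist$k[keep] * xx^(dist$k[keep] - 1L))
  }, numeric(1))
}

#' Read or write a plain-text edge list
#'
#' The format is one edge per line as two whitespace-separated 0-based integer
#' node ids; `#` starts a comment. Writing emits the canonical form (smaller id
#' first, rows sorted), so write-then-read is an identity on the edge set.
#'
#' @param path file path.
#' @param n optional node count; defaults to `max(id) + 1`.
#' @return `read_edge_list` returns an [epinet]; `write_edge_list` returns
#'   `path` invisibly.
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  parts <- strsplit(trimws(stripped[keep]), "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected two node ids, got '%s'", keep[bad[1L]], lines[keep[bad[1L]]]))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2L, byrow = TRUE)
  if (any(is.na(m))) {
    i <- which(is.na(m[, 1L]) | is.na(m[, 2L]))[1L]
    stop(sprintf("line %d: non-integer node id in '%s'", keep[i], lines[keep[i]]))
  }
  loops <- which(m[, 1L] == m[, 2L])
  if (length(loops) > 0L) {
    stop(sprintf("line %d: self-loop '%s'", keep[loops[1L]], lines[keep[loops[1L]]]))
  }
  key <- paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("line %d: duplicate edge '%s'", keep[dup[1L]], lines[keep[dup[1L]]]))
  }
  if (is.null(n)) n <- max(m) + 1L
  epinet(n, m)
}

#' @rdname read_edge_list
#' @param net an [epinet] to serialize.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "epinet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d nodes, %d edges", net$n, nrow(net$edges)), con)
  writeLines(paste(net$edges[, 1L], net$edges[, 2L]), con)
  invisible(path)
}

#' Serialize a degree distribution as two-column TSV
#'
#' Columns are `k` and `p_k`.
#'
#' @param dist a [degree_distribution].
#' @param path file path.
#' @export
write_degree_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "degree_distribution"))
  df <- data.frame(k = dist$k, p_k = formatC(dist$p, digits = 15, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_degree_distribution
#' @export
read_degree_distribution <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  degree_distribution(df$k, df$p_k)
}
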