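# Figure-level experiment driver: config parsing, the five subcommands, and a
# tiny CLI front end. Outputs are CSV/JSON with canonical float formatting so
# reruns under the same seed are byte-stable.

fmt10 <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 10, format = "g") else as.character(x)
}

write_canonical_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt10), stringsAsFactors = FALSE)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# FNV-1a over the raw config text; logged so a run can be matched to its file.
config_hash <- function(text) {
  h <- 2166136261
  for (b in utf8ToInt(paste(text, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

exp_log <- function(quiet, ...) {
  if (!isTRUE(quiet)) message(sprintf(...))
  invisible(NULL)
}

#' Read an experiment configuration file
#'
#' The format is one `key: value` pair per line; `#` starts a comment. Values
#' are parsed as numbers where possible, and comma-separated values become
#' vectors. Recognised keys: `network` (`er`, `ucm`, or a path to an edge
#' list), `n`, `mean_degree`, `exponent`, `k_min`, `mu`, `beta_grid`,
#' `beta_f_values`, `gamma_values`, `n_realizations`, `i0`, `outbreak_cutoff`.
#' Defaults mirror the reference experimental setup (`n = 10000`,
#' `mean_degree = 10`, `mu = 1`, `n_realizations = 1000`).
#'
#' @param path config file path.
#' @return A named list of class `ssfir_config` (attribute `hash` carries a
#'   hash of the raw text).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  stripped <- trimws(sub("#.*$", "", lines))
  stripped <- stripped[stripped != ""]
  cfg <- list()
  for (ln in stripped) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)[[:space:]]*:[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: '", ln, "'")
    vals <- trimws(strsplit(m[3L], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    cfg[[m[2L]]] <- if (any(is.na(num))) {
      if (length(vals) == 1L) vals else as.list(vals)
    } else num
  }
  validate_config(cfg)
  structure(cfg, class = "ssfir_config", hash = config_hash(lines))
}

config_defaults <- list(
  network = "er", n = 10000, mean_degree = 10, exponent = 3, k_min = 3,
  mu = 1, beta_f_values = 0, gamma_values = 0.1, n_realizations = 1000,
  i0 = 1e-4, outbreak_cutoff = 0.01
)

validate_config <- function(cfg) {
  known <- c(names(config_defaults), "beta_grid")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  scalars <- c("n", "mean_degree", "exponent", "k_min", "mu", "n_realizations",
               "i0", "outbreak_cutoff")
  bad <- Filter(function(k) !is.null(cfg[[k]]) &&
                  (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L), scalars)
  if (length(bad) > 0L) {
    stop("config keys must be numeric scalars: ", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

fill_config <- function(cfg) {
  for (k in names(config_defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- config_defaults[[k]]
  }
  if (is.null(cfg$beta_grid)) stop("config is missing required key: beta_grid")
  cfg
}

config_network <- function(cfg, seed) {
  switch(cfg$network,
    er = er_network(cfg$n, cfg$mean_degree, seed),
    ucm = ucm_network(cfg$n, cfg$exponent, cfg$k_min, seed),
    read_edge_list(cfg$network)
  )
}

config_ideal_dist <- function(cfg) {
  switch(cfg$network,
    er = poisson_degree_distribution(cfg$mean_degree),
    ucm = powerlaw_degree_distribution(cfg$exponent, cfg$k_min, floor(sqrt(cfg$n))),
    empirical_degree_distribution(read_edge_list(cfg$network))
  )
}

as_config <- function(config) {
  if (inherits(config, "ssfir_config")) return(fill_config(config))
  if (is.character(config)) return(fill_config(read_config(config)))
  if (is.list(config)) {
    validate_config(config)
    return(fill_config(config))
  }
  stop("'config' must be a path, an ssfir_config, or a named list")
}

#' Experiment subcommands
#'
#' Each subcommand evaluates one engine across the configured parameter grid
#' and writes tables under `out_dir`:
#'
#' * `cmd_theory()` — percolation theta, prevalence and outbreak margin per
#'   `(beta, beta_f, gamma)` (`theory_sweep.csv`) plus the bisection thresholds
#'   per `(beta_f, gamma)` (`thresholds.json`). Uses the ideal degree
#'   distribution implied by the config.
#' * `cmd_simulate()` — stochastic ensembles per grid point
#'   (`sim_sweep.csv`, one row per `beta` with mean sizes and Delta;
#'   `realizations.csv`, one row per run) plus `summary.json` with the Delta
#'   peaks.
#' * `cmd_meanfield()` — mean-field final sizes (`mf_sweep.csv`) and liftoff
#'   points (`mf_liftoff.json`).
#' * `cmd_compare()` — joins all three engines on the shared `beta` grid
#'   (`compare.csv`) and reports the three threshold estimates per parameter
#'   set (`compare_thresholds.json`). The simulation and percolation columns
#'   use the empirical degree distribution of the generated graph; the
#'   mean-field column shows the closure's insensitivity to `beta_f` and
#'   `gamma`.
#' * `cmd_net()` — generates the configured network and writes `edges.tsv` and
#'   `degree_dist.tsv`.
#'
#' @param config path to a config file, or a parsed config list
#'   (see [read_config()]).
#' @param seed master integer seed for everything stochastic.
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress logging.
#' @param n_realizations optional override of the configured ensemble size.
#' @return Invisibly, a list of the produced file paths and headline results.
#' @export
cmd_theory <- function(config, out_dir, quiet = FALSE) {
  cfg <- as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  dist <- config_ideal_dist(cfg)
  grid <- expand.grid(beta = cfg$beta_grid, beta_f = cfg$beta_f_values,
                      gamma = cfg$gamma_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    params <- epidemic_params(grid$beta[i], grid$beta_f[i], grid$gamma[i], cfg$mu)
    sol <- final_prevalence(dist, params)
    data.frame(beta = grid$beta[i], beta_f = grid$beta_f[i],
               gamma = grid$gamma[i], mu = cfg$mu, theta = sol$theta,
               prevalence = sol$prevalence,
               margin = outbreak_condition(dist, params)$margin)
  })
  sweep_path <- file.path(out_dir, "theory_sweep.csv")
  write_canonical_csv(do.call(rbind, rows), sweep_path)

  combos <- expand.grid(beta_f = cfg$beta_f_values, gamma = cfg$gamma_values)
  thresholds <- lapply(seq_len(nrow(combos)), function(i) {
    list(beta_f = combos$beta_f[i], gamma = combos$gamma[i], mu = cfg$mu,
         beta_c = solve_threshold_beta(dist, combos$beta_f[i], combos$gamma[i], cfg$mu))
  })
  thr_path <- file.path(out_dir, "thresholds.json")
  jsonlite::write_json(thresholds, thr_path, auto_unbox = TRUE, digits = 10)
  exp_log(quiet, "[theory] %d sweep rows, %d thresholds in %.2fs",
          nrow(grid), nrow(combos), proc.time()[["elapsed"]] - t0)
  invisible(list(sweep = sweep_path, thresholds = thr_path,
                 threshold_values = thresholds))
}

#' @rdname cmd_theory
#' @export
cmd_simulate <- function(config, seed, out_dir, quiet = FALSE,
                         n_realizations = NULL) {
  cfg <- as_config(config)
  if (!is.null(n_realizations)) cfg$n_realizations <- n_realizations
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  exp_log(quiet, "[simulate] config hash %s, seed %d", attr(cfg, "hash") %||% "-", seed)
  net <- config_network(cfg, seed)
  combos <- expand.grid(beta_f = cfg$beta_f_values, gamma = cfg$gamma_values)
  sweep <- list(); reals <- list(); peaks <- list()
  for (i in seq_len(nrow(combos))) {
    bf <- combos$beta_f[i]; gm <- combos$gamma[i]
    est <- threshold_by_delta_peak(
      net, cfg$beta_grid, beta_f = bf, gamma = gm, mu = cfg$mu,
      n_realizations = cfg$n_realizations, seed = derive_seed(seed, i),
      outbreak_cutoff = cfg$outbreak_cutoff)
    sweep[[i]] <- cbind(beta_f = bf, gamma = gm, est$curve)
    peaks[[i]] <- list(beta_f = bf, gamma = gm, beta_c_delta_peak = est$beta_c,
                       interior_peak = est$interior_peak)
    if (!est$interior_peak && length(cfg$beta_grid) > 1L) {
      exp_log(quiet, "[simulate] warning: no interior Delta peak for beta_f=%g gamma=%g", bf, gm)
    }
    per_run <- lapply(seq_along(cfg$beta_grid), function(j) {
      params <- epidemic_params(cfg$beta_grid[j], bf, gm, cfg$mu)
      ens <- run_ensemble(net, params, cfg$n_realizations,
                          derive_seed(derive_seed(seed, i), j),
                          outbreak_cutoff = cfg$outbreak_cutoff)
      cbind(beta = cfg$beta_grid[j], beta_f = bf, gamma = gm, ens$runs)
    })
    reals[[i]] <- do.call(rbind, per_run)
  }
  sweep_path <- file.path(out_dir, "sim_sweep.csv")
  write_canonical_csv(do.call(rbind, sweep), sweep_path)
  real_path <- file.path(out_dir, "realizations.csv")
  write_canonical_csv(do.call(rbind, reals), real_path)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(seed = seed, config_hash = attr(cfg, "hash") %||% NA,
         network = list(type = cfg$network, n = net$n,
                        mean_degree = mean(net$degree)),
         n_realizations = cfg$n_realizations, delta_peaks = peaks),
    summary_path, auto_unbox = TRUE, digits = 10)
  exp_log(quiet, "[simulate] done in %.2fs", proc.time()[["elapsed"]] - t0)
  invisible(list(sweep = sweep_path, realizations = real_path,
                 summary = summary_path, delta_peaks = peaks))
}

#' @rdname cmd_theory
#' @export
cmd_meanfield <- function(config, out_dir, quiet = FALSE) {
  cfg <- as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  dist <- config_ideal_dist(cfg)
  combos <- expand.grid(beta_f = cfg$beta_f_values, gamma = cfg$gamma_values)
  sweep <- list(); lifts <- list()
  for (i in seq_len(nrow(combos))) {
    lift <- mf_liftoff(dist, cfg$beta_grid, combos$beta_f[i], combos$gamma[i],
                       cfg$mu, i0 = cfg$i0)
    sweep[[i]] <- cbind(beta_f = combos$beta_f[i], gamma = combos$gamma[i],
                        lift$curve)
    lifts[[i]] <- list(beta_f = combos$beta_f[i], gamma = combos$gamma[i],
                       beta_liftoff = lift$beta,
                       beta_c_closed_form = mf_threshold(dist))
  }
  sweep_path <- file.path(out_dir, "mf_sweep.csv")
  write_canonical_csv(do.call(rbind, sweep), sweep_path)
  lift_path <- file.path(out_dir, "mf_liftoff.json")
  jsonlite::write_json(lifts, lift_path, auto_unbox = TRUE, digits = 10)
  exp_log(quiet, "[meanfield] %d settings in %.2fs", nrow(combos),
          proc.time()[["elapsed"]] - t0)
  invisible(list(sweep = sweep_path, liftoff = lift_path, liftoffs = lifts))
}

#' @rdname cmd_theory
#' @export
cmd_compare <- function(config, seed, out_dir, quiet = FALSE,
                        n_realizations = NULL) {
  cfg <- as_config(config)
  if (!is.null(n_realizations)) cfg$n_realizations <- n_realizations
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  net <- config_network(cfg, seed)
  dist <- empirical_degree_distribution(net)
  combos <- expand.grid(beta_f = cfg$beta_f_values, gamma = cfg$gamma_values)
  rows <- list(); thr <- list()
  for (i in seq_len(nrow(combos))) {
    bf <- combos$beta_f[i]; gm <- combos$gamma[i]
    est <- threshold_by_delta_peak(
      net, cfg$beta_grid, beta_f = bf, gamma = gm, mu = cfg$mu,
      n_realizations = cfg$n_realizations, seed = derive_seed(seed, i),
      outbreak_cutoff = cfg$outbreak_cutoff)
    theory_r <- vapply(cfg$beta_grid, function(b) {
      final_prevalence(dist, epidemic_params(b, bf, gm, cfg$mu))$prevalence
    }, numeric(1))
    mf_r <- mf_final_size_curve(dist, cfg$beta_grid, bf, gm, cfg$mu,
                                i0 = cfg$i0)$r_inf
    rows[[i]] <- data.frame(
      beta = cfg$beta_grid, beta_f = bf, gamma = gm,
      sim_mean_rho = est$curve$mean_rho,
      sim_mean_rho_outbreak = est$curve$mean_rho_outbreak,
      sim_delta = est$curve$delta,
      theory_prevalence = theory_r, mf_prevalence = mf_r)
    thr[[i]] <- list(
      beta_f = bf, gamma = gm,
      beta_c_delta_peak = est$beta_c,
      beta_c_percolation = tryCatch(
        solve_threshold_beta(dist, bf, gm, cfg$mu), error = function(e) NA),
      beta_c_meanfield = mf_threshold(dist))
  }
  cmp_path <- file.path(out_dir, "compare.csv")
  write_canonical_csv(do.call(rbind, rows), cmp_path)
  thr_path <- file.path(out_dir, "compare_thresholds.json")
  jsonlite::write_json(thr, thr_path, auto_unbox = TRUE, digits = 10)
  exp_log(quiet, "[compare] %d settings in %.2fs", nrow(combos),
          proc.time()[["elapsed"]] - t0)
  invisible(list(compare = cmp_path, thresholds = thr_path,
                 threshold_values = thr))
}

#' @rdname cmd_theory
#' @export
cmd_net <- function(config, seed, out_dir, quiet = FALSE) {
  cfg <- as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- config_network(cfg, seed)
  edge_path <- file.path(out_dir, "edges.tsv")
  write_edge_list(net, edge_path)
  dist_path <- file.path(out_dir, "degree_dist.tsv")
  write_degree_distribution(empirical_degree_distribution(net), dist_path)
  exp_log(quiet, "[net] wrote %s (%d nodes, %d edges)", edge_path, net$n,
          nrow(net$edges))
  invisible(list(edges = edge_path, degree_dist = dist_path, network = net))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Dispatches `theory`, `simulate`, `meanfield`, `compare` and `net`
#' subcommands with flags `--config <path>`, `--seed <int>`, `--out <dir>`,
#' `--n-realizations <int>` and `--quiet`. Installed as the `ssfir` script
#' (under `exec/`).
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success).
#' @export
ssfir_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ssfir <theory|simulate|meanfield|compare|net>",
    "--config <file> --out <dir> [--seed <int>] [--n-realizations <int>] [--quiet]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- list(seed = 1L, quiet = FALSE, n_realizations = NULL)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; if (i > length(args)) stop("missing value for ", a); args[i] }
    switch(a,
      "--config" = opts$config <- take(),
      "--seed" = opts$seed <- as.integer(take()),
      "--out" = opts$out <- take(),
      "--n-realizations" = opts$n_realizations <- as.integer(take()),
      "--quiet" = opts$quiet <- TRUE,
      stop("unknown flag: ", a)
    )
    i <- i + 1L
  }
  if (is.null(opts$config) || is.null(opts$out)) { message(usage); return(invisible(1L)) }
  status <- tryCatch({
    switch(cmd,
      theory = cmd_theory(opts$config, opts$out, quiet = opts$quiet),
      simulate = cmd_simulate(opts$config, opts$seed, opts$out,
                              quiet = opts$quiet,
                              n_realizations = opts$n_realizations),
      meanfield = cmd_meanfield(opts$config, opts$out, quiet = opts$quiet),
      compare = cmd_compare(opts$config, opts$seed, opts$out,
                            quiet = opts$quiet,
                            n_realizations = opts$n_realizations),
      net = cmd_net(opts$config, opts$seed, opts$out, quiet = opts$quiet),
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
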