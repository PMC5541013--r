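#' Run a configured figure-class experiment
#'
#' Config-driven wrapper around the simulation pipeline. A configuration
#' (R list, or path to a JSON/YAML file) selects one experiment family,
#' its network, dynamics and ensemble parameters; the runner executes the
#' ensemble and writes plain-text outputs plus a manifest sufficient to
#' reproduce the run exactly.
#'
#' Experiment families and their main outputs:
#' \describe{
#'   \item{monoplex}{uncoupled complete graphs (`q = 0`), ageing rule;
#'     ensemble active-link decay and its fitted tail exponent.}
#'   \item{duplex_aging}{complete graphs at a given `q`, ageing in both
#'     layers; ensemble decay and outcome counts.}
#'   \item{duplex_rau_lattice}{ring or square lattice, RAU in both
#'     layers, one ensemble per `q` in `q_grid`.}
#'   \item{mixed_update}{complete graphs, ageing layer plus RAU layer;
#'     ensemble decay and the crossing time of `rho = 0.1`.}
#'   \item{qstar_scan}{trapped-fraction curve over `q_grid` and the
#'     largest-`q`-with-trapping bracket.}
#'   \item{qstar_asymptotic}{trapped fractions on a grid of sizes
#'     `N_grid` x `q_grid` under layer-polarized initial conditions.}
#' }
#'
#' Configuration fields (defaults in parentheses): `experiment`;
#' `N` (1000) or `L` for lattices; `q` or `q_grid`; `N_grid`;
#' `b1`, `b2` (1); `rule1`, `rule2` (per experiment); `network`
#' (`"complete"`, `"ring1d"`, `"lattice2d"`, or a list
#' `list(family=, mean_degree=, gamma=, k_min=)` for configuration-model
#' layers); `procedure` (`"random"`); `n_common`; `init_mode`;
#' `polarized_common_value` (1); `t_max` (10000); `n_realizations`
#' (1000); `m_threshold` (0.8); `seed`; `out_dir`.
#'
#' @param config list or path to a JSON/YAML configuration file.
#' @param out_dir output directory (overrides the config field).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the computed results and the paths of
#'   the written files.
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- .load_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg <- .validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("experiment '%s' (seed %d) -> %s", cfg$experiment, cfg$seed,
      cfg$out_dir)
  result <- switch(cfg$experiment,
    monoplex = .exp_decay(cfg, q_default = 0),
    duplex_aging = .exp_decay(cfg, q_default = cfg$q %||% 0.5),
    duplex_rau_lattice = .exp_rau_lattice(cfg),
    mixed_update = .exp_mixed(cfg),
    qstar_scan = .exp_qstar_scan(cfg),
    qstar_asymptotic = .exp_qstar_asymptotic(cfg))

  manifest <- list(config = cfg,
                   package_version =
                     as.character(utils::packageVersion("agevoter")),
                   written = result$files)
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  result$files <- c(result$files, manifest = mpath)
  say("done: %s", paste(basename(unlist(result$files)), collapse = ", "))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package", call. = FALSE)
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  config
}

.validate_config <- function(cfg) {
  experiments <- c("monoplex", "duplex_aging", "duplex_rau_lattice",
                   "mixed_update", "qstar_scan", "qstar_asymptotic")
  problems <- character(0)
  if (is.null(cfg$experiment) || !cfg$experiment %in% experiments)
    problems <- c(problems, sprintf("experiment: must be one of %s",
                                    paste(experiments, collapse = ", ")))
  cfg$N <- as.integer(cfg$N %||% 1000L)
  cfg$b1 <- cfg$b1 %||% 1
  cfg$b2 <- cfg$b2 %||% 1
  cfg$t_max <- as.integer(cfg$t_max %||% 10000L)
  cfg$n_realizations <- as.integer(cfg$n_realizations %||% 1000L)
  cfg$m_threshold <- cfg$m_threshold %||% 0.8
  # lattice duplexes share node identities site-by-site; elsewhere the
  # common set is paired uniformly at random
  cfg$procedure <- cfg$procedure %||%
    (if (identical(cfg$experiment, "duplex_rau_lattice")) "aligned"
     else "random")
  cfg$network <- cfg$network %||% "complete"
  cfg$polarized_common_value <- cfg$polarized_common_value %||% 1L
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "agevoter-run"
  if (cfg$N < 2) problems <- c(problems, "N: must be >= 2")
  if (cfg$t_max < 1) problems <- c(problems, "t_max: must be >= 1")
  if (cfg$n_realizations < 1)
    problems <- c(problems, "n_realizations: must be >= 1")
  if (cfg$b1 < 1 || cfg$b2 < 1)
    problems <- c(problems, "b1/b2: must be >= 1")
  for (qf in c("q", "q_grid")) {
    if (!is.null(cfg[[qf]]) && any(cfg[[qf]] < 0 | cfg[[qf]] > 1))
      problems <- c(problems, sprintf("%s: values must lie in [0, 1]", qf))
  }
  if (length(problems))
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  cfg
}

.config_net_factory <- function(cfg, q) {
  N <- cfg$N
  procedure <- cfg$procedure
  n_common <- if (!is.null(cfg$n_common)) as.integer(cfg$n_common) else NULL
  if (is.list(cfg$network)) {
    spec <- degree_spec(family = cfg$network$family,
                        mean_degree = cfg$network$mean_degree,
                        gamma = cfg$network$gamma,
                        k_min = cfg$network$k_min %||% 2L)
    # fresh configuration-model layers for every realization
    return(function(i) {
      g1 <- configuration_model(sample_degree_sequence(spec, N))
      g2 <- configuration_model(sample_degree_sequence(spec, N))
      couple_layers(g1, g2, q, procedure = procedure, n_common = n_common)
    })
  }
  make_layer <- switch(cfg$network,
    complete = function() complete_graph(N),
    ring1d = function() ring_lattice(N),
    lattice2d = function() square_lattice(cfg$L %||%
                                            as.integer(round(sqrt(N)))),
    stop(sprintf("unknown network kind '%s'", cfg$network), call. = FALSE))
  g1 <- make_layer(); g2 <- make_layer()
  function(i) couple_layers(g1, g2, q, procedure = procedure,
                            n_common = n_common)
}

.write_rho_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}

.exp_decay <- function(cfg, q_default) {
  q <- cfg$q %||% q_default
  rules <- rule_spec(cfg$rule1 %||% "endogenous",
                     cfg$rule2 %||% "endogenous", cfg$b1, cfg$b2)
  ens <- run_ensemble(.config_net_factory(cfg, q), rules,
                      cfg$n_realizations, cfg$t_max, seed = cfg$seed,
                      init_mode = cfg$init_mode %||% "random",
                      polarized_common_value = cfg$polarized_common_value,
                      m_threshold = cfg$m_threshold)
  rho <- ensemble_rho(ens)
  fit <- tryCatch(fit_tail_exponent(rho$t, rho$rho), error = function(e) NULL)
  f1 <- .write_rho_tsv(rho, file.path(cfg$out_dir, "ensemble_rho.tsv"))
  summary <- list(q = q, outcome_counts = as.list(ens$outcome_counts),
                  tail_exponent = if (is.null(fit)) NULL else
                    fit[c("exponent", "se", "window")])
  f2 <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, f2, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(ensemble = ens, rho = rho, fit = fit, files = c(f1, f2))
}

.exp_rau_lattice <- function(cfg) {
  q_grid <- cfg$q_grid %||% c(0, 0.5, 1)
  rules <- rule_spec("rau", "rau", cfg$b1, cfg$b2)
  out <- lapply(q_grid, function(q) {
    ens <- run_ensemble(.config_net_factory(cfg, q), rules,
                        cfg$n_realizations, cfg$t_max,
                        seed = cfg$seed + round(1000 * q),
                        init_mode = cfg$init_mode %||% "random")
    cbind(q = q, ensemble_rho(ens))
  })
  rho <- do.call(rbind, out)
  f1 <- .write_rho_tsv(rho, file.path(cfg$out_dir, "ensemble_rho.tsv"))
  list(rho = rho, files = f1)
}

.exp_mixed <- function(cfg) {
  q <- cfg$q %||% 1
  rules <- rule_spec(cfg$rule1 %||% "endogenous", cfg$rule2 %||% "rau",
                     cfg$b1, cfg$b2)
  ens <- run_ensemble(.config_net_factory(cfg, q), rules,
                      cfg$n_realizations, cfg$t_max, seed = cfg$seed,
                      init_mode = cfg$init_mode %||% "random")
  rho <- ensemble_rho(ens)
  f1 <- .write_rho_tsv(rho, file.path(cfg$out_dir, "ensemble_rho.tsv"))
  crossing <- crossing_time(rho$t, rho$rho, 0.1)
  summary <- list(q = q, tau_star = crossing,
                  outcome_counts = as.list(ens$outcome_counts))
  f2 <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, f2, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(ensemble = ens, rho = rho, tau_star = crossing, files = c(f1, f2))
}

.exp_qstar_scan <- function(cfg) {
  q_grid <- cfg$q_grid %||% c(0.15, 0.2, 0.25, 0.3, 0.35, 0.4)
  rules <- rule_spec(cfg$rule1 %||% "endogenous",
                     cfg$rule2 %||% "endogenous", cfg$b1, cfg$b2)
  curve <- trapped_fraction_curve(
    function(q) .config_net_factory(cfg, q), rules, q_grid,
    cfg$n_realizations, cfg$t_max, seed = cfg$seed,
    init_mode = cfg$init_mode %||% "random",
    polarized_common_value = cfg$polarized_common_value,
    m_threshold = cfg$m_threshold)
  qs <- tryCatch(estimate_q_star(curve), error = function(e)
    list(q_star = NA_real_, bracket = c(NA_real_, NA_real_),
         note = conditionMessage(e)))
  f1 <- .write_rho_tsv(curve, file.path(cfg$out_dir,
                                        "trapped_fraction.tsv"))
  doc <- list(q_grid = q_grid, trapped_fraction = curve$fraction,
              stderr = curve$se, q_star = qs$q_star,
              q_star_bracket = qs$bracket, seed = cfg$seed)
  f2 <- file.path(cfg$out_dir, "qstar.json")
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(curve = curve, q_star = qs, files = c(f1, f2))
}

.exp_qstar_asymptotic <- function(cfg) {
  N_grid <- as.integer(cfg$N_grid %||% c(1000L, 2000L, 4000L, 8000L))
  q_grid <- cfg$q_grid %||% c(0.27, 0.275)
  rules <- rule_spec(cfg$rule1 %||% "endogenous",
                     cfg$rule2 %||% "endogenous", cfg$b1, cfg$b2)
  rows <- list()
  for (N in N_grid) {
    cfgN <- cfg
    cfgN$N <- N
    curve <- trapped_fraction_curve(
      function(q) .config_net_factory(cfgN, q), rules, q_grid,
      cfg$n_realizations, cfg$t_max, seed = cfg$seed + N,
      init_mode = cfg$init_mode %||% "layer_polarized",
      polarized_common_value = cfg$polarized_common_value,
      m_threshold = cfg$m_threshold)
    rows[[length(rows) + 1L]] <- cbind(N = N, curve)
  }
  tab <- do.call(rbind, rows)
  f1 <- .write_rho_tsv(tab, file.path(cfg$out_dir,
                                      "trapped_fraction_by_N.tsv"))
  list(table = tab, files = f1)
}

#' First crossing time of a decaying series
#'
#' Log-linear interpolation of the first time at which `y` drops below
#' `level`; used for the `rho = 0.1` crossing of the mixed-update decay.
#'
#' @param t,y the series.
#' @param level threshold.
#' @return The interpolated crossing time, or `NA` if never crossed.
#' @export
crossing_time <- function(t, y, level = 0.1) {
  below <- which(y < level & t > 0)
  if (!length(below)) return(NA_real_)
  k <- below[1L]
  if (k == 1L || y[k - 1L] <= 0) return(as.numeric(t[k]))
  # interpolate in log y between the straddling samples
  f <- (log(level) - log(y[k - 1L])) / (log(y[k]) - log(y[k - 1L]))
  t[k - 1L] + f * (t[k] - t[k - 1L])
}

#' Deterministic miniature instances for tests and examples
#'
#' @param kind `"tiny_complete"` (N = 6, two common nodes),
#'   `"tiny_ring"` (N = 8, two common nodes) or `"tiny_config"` (N = 30,
#'   Poisson degrees).
#' @param seed integer seed.
#' @param dir if non-NULL, serialize the network (edge lists + JSON) and
#'   the initial state (JSON) under this directory.
#' @return List with `net`, `state`, `rules` and, if written, `files`.
#' @export
make_fixture <- function(kind = c("tiny_complete", "tiny_ring",
                                  "tiny_config"),
                         seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  rules <- rule_spec("endogenous", "endogenous", 1, 1)
  built <- withr::with_seed(as.integer(seed), {
    net <- switch(kind,
      tiny_complete = duplex_complete(6L, 1 / 3),
      tiny_ring = couple_layers(ring_lattice(8L), ring_lattice(8L), 0.25),
      tiny_config = {
        spec <- degree_spec("poisson", mean_degree = 4)
        couple_layers(configuration_model(sample_degree_sequence(spec, 30L)),
                      configuration_model(sample_degree_sequence(spec, 30L)),
                      0.2)
      })
    list(net = net, state = init_state(net, rules, mode = "random"))
  })
  out <- list(net = built$net, state = built$state, rules = rules)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    prefix <- file.path(dir, kind)
    jnet <- write_multilayer(built$net, prefix, seed = as.integer(seed))
    spath <- paste0(prefix, "_state.json")
    jsonlite::write_json(
      list(t = built$state$t, spins1 = built$state$spins1,
           spins2 = built$state$spins2, tau1 = built$state$tau1,
           tau2 = built$state$tau2),
      spath, auto_unbox = TRUE, digits = NA)
    out$files <- c(jnet, paste0(prefix, "_layer1.txt"),
                   paste0(prefix, "_layer2.txt"), spath)
  }
  out
}
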