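#' Per-layer update rules and activation coefficients
#'
#' The endogenous (ageing) rule activates node `i` with probability
#' `b_l / tau_i`, where `tau_i` is the persistence time: the time elapsed
#' since the node's last change of state, reset to `1 + b_l` on a flip.
#' The RAU rule (random asynchronous update) is the memoryless standard
#' voter update: one Monte Carlo step performs `N` random node picks with
#' forced adoption of a random neighbour's state.
#'
#' @param rule1,rule2 `"endogenous"` or `"rau"`, per layer.
#' @param b1,b2 activation coefficients, `>= 1`. For a RAU layer the
#'   coefficient only sets the clock reset value `1 + b_l` (the clocks are
#'   maintained so that a mixed-rule partner layer stays well defined);
#'   RAU activation itself ignores the clock.
#' @return An object of class `rule_spec`.
#' @export
rule_spec <- function(rule1 = c("endogenous", "rau"),
                      rule2 = c("endogenous", "rau"),
                      b1 = 1, b2 = 1) {
  rule1 <- match.arg(rule1)
  rule2 <- match.arg(rule2)
  if (!is.numeric(b1) || !is.numeric(b2) || b1 < 1 || b2 < 1)
    stop("activation coefficients b1, b2 must be >= 1", call. = FALSE)
  structure(list(rule1 = rule1, rule2 = rule2,
                 b1 = as.numeric(b1), b2 = as.numeric(b2)),
            class = "rule_spec")
}

#' Initial state of a two-layer simulation
#'
#' All persistence times start at `1 + b_l` of the node's layer; common
#' nodes, which share one clock, start at `1 + min(b1, b2)`.
#'
#' Initial spins:
#' \describe{
#'   \item{random}{each logical node `+1` or `-1` with probability 1/2;
#'     each common pair is drawn once and copied to both layers.}
#'   \item{layer_polarized}{layer 1 all `+1`, layer 2 all `-1`, common
#'     pairs set to `polarized_common_value` in both layers. This seeds the
#'     opposite-majority configuration and strongly enhances the trapped
#'     outcome, which is how finite-size scans of the trapping threshold
#'     stay affordable.}
#' }
#'
#' Uses R's global RNG; call [set.seed()] (or let [run_realization()]
#' seed it) for reproducibility.
#'
#' @param net a `multilayer_net`.
#' @param rules a [rule_spec()].
#' @param mode `"random"` or `"layer_polarized"`.
#' @param polarized_common_value `+1` or `-1`, spin given to common nodes
#'   under the polarized mode.
#' @return An object of class `sim_state`: `spins1`, `spins2` (integer,
#'   values in -1/+1), `tau1`, `tau2` (numeric), `t` (MCS counter).
#' @export
init_state <- function(net, rules, mode = c("random", "layer_polarized"),
                       polarized_common_value = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "multilayer_net"), inherits(rules, "rule_spec"))
  N <- net$layer1$n_nodes
  if (mode == "random") {
    spins1 <- sample(c(-1L, 1L), N, replace = TRUE)
    spins2 <- sample(c(-1L, 1L), N, replace = TRUE)
    if (nrow(net$pairs))
      spins2[net$pairs[, 2L]] <- spins1[net$pairs[, 1L]]
  } else {
    v <- as.integer(sign(polarized_common_value))
    if (!v %in% c(-1L, 1L))
      stop("polarized_common_value must be +1 or -1", call. = FALSE)
    spins1 <- rep.int(1L, N)
    spins2 <- rep.int(-1L, N)
    if (nrow(net$pairs)) {
      spins1[net$pairs[, 1L]] <- v
      spins2[net$pairs[, 2L]] <- v
    }
  }
  tau1 <- rep(1 + rules$b1, N)
  tau2 <- rep(1 + rules$b2, N)
  if (nrow(net$pairs)) {
    tau_common <- 1 + min(rules$b1, rules$b2)
    tau1[net$pairs[, 1L]] <- tau_common
    tau2[net$pairs[, 2L]] <- tau_common
  }
  structure(list(spins1 = spins1, spins2 = spins2,
                 tau1 = tau1, tau2 = tau2, t = 0L,
                 flipped1 = logical(N), flipped2 = logical(N)),
            class = "sim_state")
}

# flip node i of `layer` to new_spin with clock reset; propagate to the
# paired node so the shared-state invariant holds within the MCS
.apply_flip <- function(state, partners, layer, i, new_spin, reset) {
  if (layer == 1L) {
    state$spins1[i] <- new_spin
    state$tau1[i] <- reset
    state$flipped1[i] <- TRUE
    j <- partners$p1[i]
    if (!is.na(j)) {
      state$spins2[j] <- new_spin
      state$tau2[j] <- reset
      state$flipped2[j] <- TRUE
    }
  } else {
    state$spins2[i] <- new_spin
    state$tau2[i] <- reset
    state$flipped2[i] <- TRUE
    j <- partners$p2[i]
    if (!is.na(j)) {
      state$spins1[j] <- new_spin
      state$tau1[j] <- reset
      state$flipped1[j] <- TRUE
    }
  }
  state
}

#' One endogenous (ageing) sweep of a layer — reference implementation
#'
#' Iterates the layer's nodes in a fresh random permutation; each node
#' activates with probability `b_l / tau_i` using its current clock (which
#' may already have been reset earlier in the same MCS by the other
#' layer), and on activation copies the spin of a uniformly random
#' neighbour. A spin change resets the clock to `1 + b_l` and propagates
#' to the paired node. Clocks are not incremented here; ageing happens
#' once per MCS in [mcs_step()].
#'
#' This pure-R stepper is the readable reference used on small systems and
#' as a statistical cross-check of the compiled engine behind
#' [run_realization()].
#'
#' @param state a `sim_state`.
#' @param net a `multilayer_net`.
#' @param layer 1 or 2.
#' @param b activation coefficient of this layer.
#' @return The updated `sim_state` (flip flags accumulate in
#'   `flipped1`/`flipped2`).
#' @export
endogenous_sweep <- function(state, net, layer, b) {
  stopifnot(layer %in% c(1L, 2L))
  N <- net$layer1$n_nodes
  partners <- partner_vectors(net)
  g <- if (layer == 1L) net$layer1 else net$layer2
  for (i in sample.int(N, N)) {
    tau_i <- if (layer == 1L) state$tau1[i] else state$tau2[i]
    p <- min(1, b / tau_i)
    if (stats::runif(1) < p) {
      nb <- neighbors_of(g, i)
      j <- nb[sample.int(length(nb), 1L)]
      s_i <- if (layer == 1L) state$spins1[i] else state$spins2[i]
      s_j <- if (layer == 1L) state$spins1[j] else state$spins2[j]
      if (s_j != s_i)
        state <- .apply_flip(state, partners, layer, i, s_j, 1 + b)
    }
  }
  state
}

#' One RAU sweep of a layer — reference implementation
#'
#' Performs `N` basic steps; each picks a uniformly random node of the
#' layer and forces it to adopt the state of a uniformly random
#' neighbour. Flips propagate to the paired node and reset the shared
#' clock to `1 + b_l`, so mixed-rule runs keep valid clocks for the
#' endogenous partner layer; RAU activation itself ignores the clock.
#'
#' @inheritParams endogenous_sweep
#' @param b clock reset coefficient of this layer.
#' @return The updated `sim_state`.
#' @export
rau_sweep <- function(state, net, layer, b) {
  stopifnot(layer %in% c(1L, 2L))
  N <- net$layer1$n_nodes
  partners <- partner_vectors(net)
  g <- if (layer == 1L) net$layer1 else net$layer2
  for (step in seq_len(N)) {
    i <- sample.int(N, 1L)
    nb <- neighbors_of(g, i)
    j <- nb[sample.int(length(nb), 1L)]
    s_i <- if (layer == 1L) state$spins1[i] else state$spins2[i]
    s_j <- if (layer == 1L) state$spins1[j] else state$spins2[j]
    if (s_j != s_i)
      state <- .apply_flip(state, partners, layer, i, s_j, 1 + b)
  }
  state
}

#' One Monte Carlo step — reference implementation
#'
#' Chooses the layer order uniformly at random, sweeps each layer with its
#' rule, then ages every logical node that did not flip during this MCS by
#' one unit (flipped nodes keep their reset value) and increments the MCS
#' counter. Uses R's global RNG.
#'
#' @param state a `sim_state`.
#' @param net a `multilayer_net`.
#' @param rules a [rule_spec()].
#' @return The updated `sim_state`.
#' @export
mcs_step <- function(state, net, rules) {
  N <- net$layer1$n_nodes
  state$flipped1 <- logical(N)
  state$flipped2 <- logical(N)
  order_12 <- stats::runif(1) < 0.5
  layers <- if (order_12) c(1L, 2L) else c(2L, 1L)
  for (L in layers) {
    rule <- if (L == 1L) rules$rule1 else rules$rule2
    b <- if (L == 1L) rules$b1 else rules$b2
    spins <- if (L == 1L) state$spins1 else state$spins2
    if (all(spins == spins[1L])) next  # uniform layer: sweep is a no-op
    state <- if (rule == "endogenous") endogenous_sweep(state, net, L, b)
             else rau_sweep(state, net, L, b)
  }
  state$tau1[!state$flipped1] <- state$tau1[!state$flipped1] + 1
  state$tau2[!state$flipped2] <- state$tau2[!state$flipped2] + 1
  state$t <- state$t + 1L
  state
}

#' Logarithmically spaced sample times
#'
#' @param t_max last time.
#' @param points_per_decade sampling density.
#' @param include_zero prepend `t = 0`.
#' @return Sorted unique integer times in `[0, t_max]`.
#' @export
log_times <- function(t_max, points_per_decade = 50, include_zero = TRUE) {
  stopifnot(t_max >= 1)
  ts <- unique(round(10^seq(0, log10(t_max), by = 1 / points_per_decade)))
  ts <- ts[ts <= t_max]
  if (!t_max %in% ts) ts <- c(ts, as.integer(t_max))
  if (include_zero) ts <- c(0L, ts)
  as.integer(sort(unique(ts)))
}

# CSR (0-based) for the engine; complete layers stay implicit
.layer_csr <- function(g) {
  if (is.null(g$adj))
    return(list(complete = TRUE, off = integer(0), adj = integer(0)))
  off <- c(0L, cumsum(g$degrees))
  list(complete = FALSE, off = as.integer(off),
       adj = as.integer(unlist(g$adj, use.names = FALSE) - 1L))
}

.stop_reasons <- c("t_max", "consensus", "frozen")

#' Run one realization of the dynamics
#'
#' Repeats Monte Carlo steps (via the compiled engine) until global
#' consensus — both layers uniform with the same sign — or `t_max`. With
#' `q = 0` a run may also freeze with the two disconnected layers ordered
#' in opposite states. Observables are recorded on a logarithmic schedule
#' by default; after an early stop the recorded series are continued
#' analytically (active-link densities are zero, magnetizations constant,
#' all clocks age by one per MCS).
#'
#' @param net a `multilayer_net`.
#' @param rules a [rule_spec()].
#' @param t_max maximum number of MCS, `>= 1`.
#' @param seed integer seed; drives both the R-side initialization draws
#'   and the engine's counter-based stream. Identical seeds reproduce the
#'   realization exactly.
#' @param init optional `sim_state` to start from (overrides `init_mode`).
#' @param init_mode,polarized_common_value passed to [init_state()].
#' @param sample_times integer times at which to record observables;
#'   default [log_times()] of `t_max`.
#' @param record_flips keep the per-node state-change times (needed for
#'   inter-event statistics).
#' @param stream sub-stream index, used by [run_ensemble()] to give every
#'   realization an independent stream under one master seed.
#' @return An object of class `realization`: `trajectory` (data.frame with
#'   columns `t`, `rho1`, `rho2`, `rho_mean`, `m1`, `m2`, `taubar1`,
#'   `taubar2`), `events` (data.frame `node`, `time`; logical node ids,
#'   see Details), `state` (final `sim_state`), `stop_reason`, `t_final`.
#'
#' @details Logical node ids in `events` are the layer-1 index for layer-1
#' and common nodes, and `N +` the layer-2 index for nodes private to
#' layer 2. At most one state change per node per MCS is logged (the MCS
#' time resolution cannot separate a flip and an immediate flip-back).
#' @export
run_realization <- function(net, rules, t_max, seed,
                            init = NULL,
                            init_mode = c("random", "layer_polarized"),
                            polarized_common_value = 1L,
                            sample_times = NULL,
                            record_flips = FALSE,
                            stream = 0) {
  stopifnot(inherits(net, "multilayer_net"), inherits(rules, "rule_spec"))
  t_max <- as.integer(t_max)
  if (is.na(t_max) || t_max < 1) stop("t_max must be >= 1", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  init_mode <- match.arg(init_mode)
  if (is.null(init)) {
    rseed <- (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
    init <- withr::with_seed(as.integer(rseed) + 1L,
      init_state(net, rules, mode = init_mode,
                 polarized_common_value = polarized_common_value))
  }
  if (is.null(sample_times)) sample_times <- log_times(t_max)
  sample_times <- as.integer(sort(unique(sample_times)))
  if (any(sample_times < 0 | sample_times > t_max))
    stop("sample_times must lie in [0, t_max]", call. = FALSE)

  N <- net$layer1$n_nodes
  csr1 <- .layer_csr(net$layer1)
  csr2 <- .layer_csr(net$layer2)
  partners <- partner_vectors(net)
  p1 <- ifelse(is.na(partners$p1), -1L, partners$p1 - 1L)
  p2 <- ifelse(is.na(partners$p2), -1L, partners$p2 - 1L)

  res <- .run_engine_cpp(
    N, csr1$complete, csr1$off, csr1$adj,
    csr2$complete, csr2$off, csr2$adj,
    as.integer(p1), as.integer(p2),
    if (rules$rule1 == "endogenous") 0L else 1L,
    if (rules$rule2 == "endogenous") 0L else 1L,
    rules$b1, rules$b2,
    as.integer(init$spins1), as.integer(init$spins2),
    as.numeric(init$tau1), as.numeric(init$tau2),
    as.integer(init$t), t_max, sample_times,
    record_flips, as.numeric(seed), as.numeric(stream))

  if (res$n_clamped > 0)
    warning(sprintf("activation probability clamped to 1 in %g draws",
                    res$n_clamped))
  traj <- data.frame(t = res$times, rho1 = res$rho1, rho2 = res$rho2,
                     rho_mean = (res$rho1 + res$rho2) / 2,
                     m1 = res$m1, m2 = res$m2,
                     taubar1 = res$taubar1, taubar2 = res$taubar2)
  # logical ids come back 0-based; shift the whole range to 1-based
  events <- data.frame(node = res$flip_node + 1L, time = res$flip_time)
  final <- structure(list(spins1 = res$spins1, spins2 = res$spins2,
                          tau1 = res$tau1, tau2 = res$tau2,
                          t = res$t_final,
                          flipped1 = logical(N), flipped2 = logical(N)),
                     class = "sim_state")
  structure(list(trajectory = traj, events = events, state = final,
                 stop_reason = .stop_reasons[res$stop_reason + 1L],
                 t_final = res$t_final, seed = seed, stream = stream,
                 t_max = t_max, init_mode = init_mode),
            class = "realization")
}

#' Run an ensemble of realizations
#'
#' Runs `n_realizations` independent realizations on a common sampling
#' grid and aggregates them. Realization `i` uses sub-stream `i` of the
#' master seed, so results are independent of execution order and
#' reproducible.
#'
#' @param net a `multilayer_net`, or a factory `function(i)` returning a
#'   fresh network for realization `i` (used when every realization draws
#'   its own configuration-model layers). Factories are invoked under a
#'   seed derived from the master seed, so they are reproducible; a
#'   directly supplied network whose construction was stochastic should
#'   itself be built under [withr::with_seed()].
#' @param rules a [rule_spec()].
#' @param n_realizations number of realizations, `>= 1`.
#' @param t_max maximum MCS per realization.
#' @param seed master integer seed.
#' @param init_mode,polarized_common_value passed to [init_state()].
#' @param sample_times common sampling grid; default [log_times()].
#' @param record_flips pool per-node state-change times across
#'   realizations.
#' @param m_threshold `|m|` threshold used to classify trapped outcomes,
#'   see [classify_outcome()].
#' @return An object of class `ensemble_result`: `times`; matrices `rho1`,
#'   `rho2`, `gap` (`taubar1 - taubar2`), one column per realization;
#'   `final` (data.frame `realization`, `m1`, `m2`, `t_final`,
#'   `stop_reason`, `outcome`); pooled `events` (with a `realization`
#'   column) if requested; `outcome_counts`; call metadata.
#' @export
run_ensemble <- function(net, rules, n_realizations, t_max, seed,
                         init_mode = c("random", "layer_polarized"),
                         polarized_common_value = 1L,
                         sample_times = NULL,
                         record_flips = FALSE,
                         m_threshold = 0.8) {
  init_mode <- match.arg(init_mode)
  n_realizations <- as.integer(n_realizations)
  if (is.na(n_realizations) || n_realizations < 1)
    stop("n_realizations must be >= 1", call. = FALSE)
  if (is.null(sample_times)) sample_times <- log_times(t_max)
  sample_times <- as.integer(sort(unique(sample_times)))

  factory <- if (is.function(net)) net else function(i) net
  nt <- length(sample_times)
  rho1 <- matrix(NA_real_, nt, n_realizations)
  rho2 <- matrix(NA_real_, nt, n_realizations)
  gap <- matrix(NA_real_, nt, n_realizations)
  final <- vector("list", n_realizations)
  events <- if (record_flips) vector("list", n_realizations) else NULL

  q_eff <- 0
  for (i in seq_len(n_realizations)) {
    rseed <- (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
    net_i <- withr::with_seed(as.integer(rseed) + 1L, factory(i))
    q_eff <- net_i$n_common / net_i$layer1$n_nodes
    r <- run_realization(net_i, rules, t_max, seed = seed,
                         init_mode = init_mode,
                         polarized_common_value = polarized_common_value,
                         sample_times = sample_times,
                         record_flips = record_flips, stream = i)
    rho1[, i] <- r$trajectory$rho1
    rho2[, i] <- r$trajectory$rho2
    gap[, i] <- r$trajectory$taubar1 - r$trajectory$taubar2
    nr <- nrow(r$trajectory)
    final[[i]] <- data.frame(
      realization = i,
      m1 = r$trajectory$m1[nr], m2 = r$trajectory$m2[nr],
      t_final = r$t_final, stop_reason = r$stop_reason)
    if (record_flips && nrow(r$events))
      events[[i]] <- cbind(realization = i, r$events)
  }
  final <- do.call(rbind, final)
  final$outcome <- classify_outcome(final$stop_reason, final$m1, final$m2,
                                    m_threshold = m_threshold,
                                    q = q_eff)
  out_events <- if (record_flips) {
    keep <- !vapply(events, is.null, logical(1))
    if (any(keep)) do.call(rbind, events[keep])
    else data.frame(realization = integer(0), node = integer(0),
                    time = integer(0))
  } else NULL

  structure(list(times = sample_times, rho1 = rho1, rho2 = rho2,
                 gap = gap, final = final, events = out_events,
                 outcome_counts = table(factor(final$outcome,
                   levels = c("consensus", "trapped", "undecided"))),
                 n_realizations = n_realizations, rules = rules,
                 t_max = as.integer(t_max), seed = seed,
                 init_mode = init_mode, m_threshold = m_threshold),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  oc <- x$outcome_counts
  cat(sprintf(
    "<ensemble_result: %d realizations, t_max = %d; consensus %d, trapped %d, undecided %d>\n",
    x$n_realizations, x$t_max, oc[["consensus"]], oc[["trapped"]],
    oc[["undecided"]]))
  invisible(x)
}

#' Ensemble-averaged active-link density
#'
#' The order parameter of the dynamics: the fraction of intra-layer edges
#' joining nodes in different states, averaged first over the two layers
#' within a realization and then across realizations.
#'
#' @param ens an `ensemble_result`.
#' @param survivors_only if `TRUE`, average at each time only over
#'   realizations that have not yet been absorbed; the default averages
#'   over all realizations, absorbed runs contributing zero.
#' @return data.frame with columns `t`, `rho`, `se`, `n` (realizations
#'   entering the average at that time).
#' @export
ensemble_rho <- function(ens, survivors_only = FALSE) {
  stopifnot(inherits(ens, "ensemble_result"))
  rho <- (ens$rho1 + ens$rho2) / 2
  if (survivors_only) {
    absorbed_at <- ifelse(ens$final$stop_reason %in% c("consensus", "frozen"),
                          ens$final$t_final, Inf)
    out <- t(vapply(seq_along(ens$times), function(k) {
      alive <- ens$times[k] < absorbed_at
      v <- rho[k, alive]
      n <- sum(alive)
      c(mean = if (n) mean(v) else NA_real_,
        se = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
        n = n)
    }, numeric(3)))
    return(data.frame(t = ens$times, rho = out[, "mean"],
                      se = out[, "se"], n = as.integer(out[, "n"])))
  }
  n <- ncol(rho)
  data.frame(t = ens$times,
             rho = rowMeans(rho),
             se = apply(rho, 1L, stats::sd) / sqrt(n),
             n = n)
}
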