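#' Fraction of active links in one layer
#'
#' An active link joins two nodes in different states; their fraction
#' `rho` is the order parameter of the dynamics (`rho = 0` at internal
#' consensus). For complete graphs the closed form
#' `2 n_plus n_minus / (N (N - 1))` is used; otherwise the layer's edges
#' are enumerated.
#'
#' @param state a `sim_state`.
#' @param net a `multilayer_net`.
#' @param layer 1 or 2.
#' @return Fraction in `[0, 1]`.
#' @export
active_link_fraction <- function(state, net, layer) {
  stopifnot(layer %in% c(1L, 2L))
  g <- if (layer == 1L) net$layer1 else net$layer2
  spins <- if (layer == 1L) state$spins1 else state$spins2
  N <- g$n_nodes
  if (edge_count(g) == 0)
    stop("active-link fraction undefined on an edgeless layer",
         call. = FALSE)
  if (is.null(g$adj)) {
    n_plus <- sum(spins > 0)
    return(2 * n_plus * (N - n_plus) / (N * (N - 1)))
  }
  e <- as_edge_list(g)
  mean(spins[e[, 1L]] != spins[e[, 2L]])
}

#' Layer magnetization
#'
#' Mean spin `m = N^-1 sum_i x_i` of one layer; `|m| = 1` at internal
#' consensus, and `|m| ~ 1 - 2q` for the dominated layer of a trapped
#' state.
#'
#' @param state a `sim_state`.
#' @param layer 1 or 2.
#' @return Value in `[-1, 1]`.
#' @export
magnetization <- function(state, layer) {
  stopifnot(layer %in% c(1L, 2L))
  spins <- if (layer == 1L) state$spins1 else state$spins2
  mean(spins)
}

#' Classify the outcome of a realization
#'
#' A realization is `consensus` if it was absorbed (both layers uniform
#' with the same sign); `trapped` if at the evaluation time the two layer
#' magnetizations have opposite signs and both layers are saturated near
#' their trapped-state ceiling; otherwise `undecided`.
#'
#' Saturation is judged against what the trapped configuration allows:
#' the dominant layer (larger `|m|`) can reach `|m| = 1`, but the
#' dominated layer holds `qN` common nodes of the contrary opinion and
#' saturates at `|m| = 1 - 2q`. The rule therefore requires
#' `|m| >= m_threshold` of the dominant layer and
#' `|m| >= m_threshold * (1 - 2q)` of the dominated one.
#'
#' @param stop_reason character vector (`"consensus"`, `"t_max"`,
#'   `"frozen"`), or a `realization` object (then `m1`, `m2` are taken
#'   from it).
#' @param m1,m2 final layer magnetizations.
#' @param m_threshold saturation threshold, default 0.8 of the ceiling.
#' @param q multiplexity (fraction of common nodes), used for the
#'   dominated-layer ceiling; `q = 0` recovers the plain symmetric rule.
#' @return Character vector in `{"consensus", "trapped", "undecided"}`.
#' @export
classify_outcome <- function(stop_reason, m1 = NULL, m2 = NULL,
                             m_threshold = 0.8, q = 0) {
  if (inherits(stop_reason, "realization")) {
    r <- stop_reason
    nr <- nrow(r$trajectory)
    m1 <- r$trajectory$m1[nr]
    m2 <- r$trajectory$m2[nr]
    stop_reason <- r$stop_reason
  }
  out <- rep("undecided", length(stop_reason))
  out[stop_reason == "consensus"] <- "consensus"
  m_dom <- pmax(abs(m1), abs(m2))
  m_sub <- pmin(abs(m1), abs(m2))
  tr <- stop_reason != "consensus" &
    sign(m1) * sign(m2) < 0 &
    m_dom >= m_threshold &
    m_sub >= m_threshold * max(0, 1 - 2 * q)
  out[tr] <- "trapped"
  out
}

#' Persistence-time gap between the layers
#'
#' The ensemble mean of `taubar1 - taubar2`, the difference of the layers'
#' mean persistence times. In trapped realizations one layer freezes in
#' its majority while the other keeps churning, so the gap grows without
#' bound; in realizations that order by coarsening it saturates. The gap
#' is therefore a diagnostic separating the two outcome classes.
#'
#' @param ens an `ensemble_result`.
#' @param by_outcome stratify by outcome class.
#' @param dominant_minus_dominated if `TRUE`, orient each realization's
#'   gap so that the layer with the larger final `|m|` (the dominant one)
#'   comes first; default keeps the signed layer-1-minus-layer-2 value.
#' @return data.frame with columns `t`, `gap`, `se`, `n` and, if
#'   stratified, `outcome`.
#' @export
persistence_gap <- function(ens, by_outcome = FALSE,
                            dominant_minus_dominated = FALSE) {
  stopifnot(inherits(ens, "ensemble_result"))
  if (ens$n_realizations < 1) stop("empty ensemble", call. = FALSE)
  g <- ens$gap
  if (dominant_minus_dominated) {
    flip <- abs(ens$final$m2) > abs(ens$final$m1)
    g[, flip] <- -g[, flip]
  }
  summarize <- function(cols) {
    gm <- g[, cols, drop = FALSE]
    n <- ncol(gm)
    data.frame(t = ens$times, gap = rowMeans(gm),
               se = if (n > 1) apply(gm, 1L, stats::sd) / sqrt(n)
                    else NA_real_,
               n = n)
  }
  if (!by_outcome) return(summarize(seq_len(ncol(g))))
  out <- lapply(split(seq_len(ncol(g)), ens$final$outcome), summarize)
  do.call(rbind, Map(function(d, cls) cbind(d, outcome = cls),
                     out, names(out)))
}

#' Complementary cumulative distribution of inter-event times
#'
#' Pools, per logical node and realization, the waiting times between
#' consecutive state changes, and returns their CCDF `C(dt)`. The final
#' right-censored interval of every node (last flip to end of run) is
#' excluded, which biases heavy tails slightly downward.
#'
#' @param events data.frame with columns `node`, `time` and optionally
#'   `realization` (as produced by [run_realization()] or pooled by
#'   [run_ensemble()]).
#' @return data.frame with columns `dt` (increasing) and `C`
#'   (nonincreasing, `C(min dt) = 1`).
#' @export
interevent_ccdf <- function(events) {
  stopifnot(is.data.frame(events), all(c("node", "time") %in% names(events)))
  key <- if ("realization" %in% names(events))
    paste(events$realization, events$node) else as.character(events$node)
  dts <- unlist(lapply(split(events$time, key), function(ts) {
    if (length(ts) < 2) return(numeric(0))
    diff(sort(ts))
  }), use.names = FALSE)
  if (length(dts) == 0)
    stop("no complete inter-event intervals in the event log",
         call. = FALSE)
  tab <- table(dts)
  dt <- as.numeric(names(tab))
  n <- sum(tab)
  cc <- rev(cumsum(rev(as.numeric(tab)))) / n
  data.frame(dt = dt, C = cc)
}

#' Fit a power-law tail exponent
#'
#' Least-squares slope of `log y` versus `log t` inside a window; the
#' standard estimator for the decay exponents of the active-link density
#' and of the inter-event CCDF.
#'
#' @param t,y the series (positive `t`; points with `y <= 0` are
#'   dropped).
#' @param window `c(t_lo, t_hi)`; default covers the last 1.5 decades of
#'   `t` where `y > 0`.
#' @param min_points minimum number of usable points, default 10.
#' @return List with `exponent` (magnitude of the slope), `se`,
#'   `n_points`, `window`.
#' @export
fit_tail_exponent <- function(t, y, window = NULL, min_points = 10) {
  keep <- is.finite(t) & is.finite(y) & t > 0 & y > 0
  t <- t[keep]; y <- y[keep]
  if (is.null(window)) {
    if (!length(t)) stop("no positive points to fit", call. = FALSE)
    t_hi <- max(t)
    window <- c(t_hi / 10^1.5, t_hi)
  }
  inw <- t >= window[1] & t <= window[2]
  if (sum(inw) < min_points)
    stop(sprintf("need >= %d positive points in the fit window, have %d",
                 min_points, sum(inw)), call. = FALSE)
  fit <- stats::lm(log(y[inw]) ~ log(t[inw]))
  # summary.lm warns on an exactly power-law input; the fit is still valid
  sl <- suppressWarnings(summary(fit))$coefficients[2L, ]
  list(exponent = abs(unname(sl["Estimate"])),
       se = unname(sl["Std. Error"]),
       n_points = sum(inw), window = window)
}

#' Time-averaged plateau level of a layer's active-link density
#'
#' @param traj a trajectory data.frame (from a `realization`) with
#'   columns `t`, `rho1`, `rho2`.
#' @param layer 1 or 2.
#' @param t_window `c(t_lo, t_hi)` inside the recorded times.
#' @return List with `mean`, `sd`, `n_points`.
#' @export
plateau_level <- function(traj, layer, t_window) {
  stopifnot(layer %in% c(1L, 2L))
  rho <- if (layer == 1L) traj$rho1 else traj$rho2
  inw <- traj$t >= t_window[1] & traj$t <= t_window[2]
  if (!any(inw)) stop("empty plateau window", call. = FALSE)
  list(mean = mean(rho[inw]), sd = stats::sd(rho[inw]),
       n_points = sum(inw))
}

#' Trapped fraction as a function of multiplexity
#'
#' Runs an ensemble for every `q` on the grid, classifies outcomes and
#' returns the trapped fractions with binomial standard errors. `q = 0`
#' is rejected: with disconnected layers each layer coarsens to its own
#' consensus and no trapping between layers is possible, so the point is
#' singular.
#'
#' @param net_factory `function(q)` returning a `multilayer_net` (or a
#'   per-realization factory `function(i)`, see [run_ensemble()]) for
#'   that multiplexity.
#' @param rules a [rule_spec()].
#' @param q_grid multiplexity values in `(0, 1]`.
#' @param n_realizations realizations per grid point.
#' @param t_max maximum MCS per realization.
#' @param seed master seed; grid point `k` uses `seed + k` so points are
#'   independent.
#' @param init_mode,polarized_common_value passed to [run_ensemble()].
#' @param m_threshold trapped-classification threshold.
#' @param ci `"wald"` (default) or `"clopper-pearson"` for the interval
#'   half-widths reported in `se`/`lo`/`hi`.
#' @return data.frame with columns `q`, `n_trapped`, `n_total`,
#'   `fraction`, `se`, `lo`, `hi`.
#' @export
trapped_fraction_curve <- function(net_factory, rules, q_grid,
                                   n_realizations, t_max, seed,
                                   init_mode = "random",
                                   polarized_common_value = 1L,
                                   m_threshold = 0.8,
                                   ci = c("wald", "clopper-pearson")) {
  ci <- match.arg(ci)
  if (any(q_grid <= 0))
    stop(paste("q = 0 is excluded: disconnected layers always coarsen",
               "to their own consensus, so trapping is undefined there"),
         call. = FALSE)
  if (any(q_grid > 1)) stop("q must be in (0, 1]", call. = FALSE)
  n_realizations <- as.integer(n_realizations)
  if (is.na(n_realizations) || n_realizations < 1)
    stop("n_realizations must be >= 1", call. = FALSE)
  rows <- lapply(seq_along(q_grid), function(k) {
    q <- q_grid[k]
    # build (or capture) the network under a derived seed so the whole
    # scan is reproducible from `seed` alone
    net <- withr::with_seed(as.integer((seed + k) %% 2147483646L) + 1L,
                            net_factory(q))
    ens <- run_ensemble(net, rules, n_realizations, t_max,
                        seed = seed + k, init_mode = init_mode,
                        polarized_common_value = polarized_common_value,
                        m_threshold = m_threshold)
    n_tr <- sum(ens$final$outcome == "trapped")
    p <- n_tr / n_realizations
    if (ci == "wald") {
      se <- sqrt(p * (1 - p) / n_realizations)
      lo <- max(0, p - 1.96 * se); hi <- min(1, p + 1.96 * se)
    } else {
      bt <- stats::binom.test(n_tr, n_realizations)
      lo <- bt$conf.int[1]; hi <- bt$conf.int[2]
      se <- (hi - lo) / (2 * 1.96)
    }
    data.frame(q = q, n_trapped = n_tr, n_total = n_realizations,
               fraction = p, se = se, lo = lo, hi = hi)
  })
  do.call(rbind, rows)
}

#' Estimate the trapping threshold q*
#'
#' `q*` is defined as the largest multiplexity at which trapped
#' realizations are observed. Given a trapped-fraction curve over a grid
#' that brackets the transition, returns the largest grid `q` with a
#' positive trapped fraction and the bracketing interval up to the next
#' grid point (where the fraction is zero).
#'
#' @param curve data.frame as returned by [trapped_fraction_curve()].
#' @return List with `q_star` and `bracket = c(q_star, next_grid_q)`.
#' @export
estimate_q_star <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("q", "fraction") %in% names(curve)))
  curve <- curve[order(curve$q), ]
  pos <- curve$fraction > 0
  if (!any(pos))
    stop("no trapped realizations anywhere on the grid: q* unbracketed",
         call. = FALSE)
  if (all(pos))
    stop("trapped realizations at every grid q: q* unbracketed from above",
         call. = FALSE)
  k <- max(which(pos))
  if (k == nrow(curve))
    stop("largest grid q still shows trapping: q* unbracketed from above",
         call. = FALSE)
  list(q_star = curve$q[k], bracket = c(curve$q[k], curve$q[k + 1L]))
}
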