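# Helpers shared across the test files. Fixtures are built in code; the
# enumeration oracle below is independent of the simulation engine.

# duplex with an explicitly chosen pairing
duplex_with_pairs <- function(g1, g2, pairs) {
  net <- couple_layers(g1, g2, 0, n_common = 0L)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  net$pairs <- pairs
  net$n_common <- nrow(pairs)
  net$q <- nrow(pairs) / g1$n_nodes
  net
}

# hand-built simulation state
manual_state <- function(spins1, spins2, tau1, tau2, t = 0L) {
  structure(list(spins1 = as.integer(spins1), spins2 = as.integer(spins2),
                 tau1 = as.numeric(tau1), tau2 = as.numeric(tau2),
                 t = as.integer(t),
                 flipped1 = logical(length(spins1)),
                 flipped2 = logical(length(spins2))),
            class = "sim_state")
}

# Exact one-MCS outcome distribution for the focal node of a 3-node
# complete duplex (q = 1, same-index pairing) whose two neighbours are
# inert (effectively infinite persistence time). Enumerates the layer
# order, the activation attempt in each layer (the second attempt uses
# the possibly-reset clock), the uniform neighbour choice, the
# flip/reset bookkeeping and the end-of-MCS ageing. Returns the
# probability of every (spin, tau) pair of the focal node after the MCS.
enumerate_one_mcs <- function(tau0, b1, b2, nb_spins) {
  stopifnot(length(nb_spins) == 2)
  acc <- new.env(parent = emptyenv())
  add <- function(spin, tau, prob) {
    key <- sprintf("%d|%.10g", spin, tau)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
  }
  attempt <- function(s, tau, flipped, b, prob, cont) {
    p <- b / tau
    cont(s, tau, flipped, prob * (1 - p))          # not selected
    for (nb in nb_spins) {                         # selected, pick nb
      if (nb != s) cont(nb, 1 + b, TRUE, prob * p / 2)
      else cont(s, tau, flipped, prob * p / 2)
    }
  }
  for (order in list(c(b1, b2), c(b2, b1))) {
    attempt(1L, tau0, FALSE, order[1], 0.5, function(s1, t1, f1, pr1) {
      attempt(s1, t1, f1, order[2], pr1, function(s2, t2, f2, pr2) {
        add(s2, if (f2) t2 else t2 + 1, pr2)       # end-of-MCS ageing
      })
    })
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(spin = as.integer(parts[, 1]),
                    tau = as.numeric(parts[, 2]),
                    prob = vapply(keys, function(k) acc[[k]], numeric(1)))
  out[order(out$spin, out$tau), ]
}

# engine-side counterpart: empirical (spin, tau) frequencies of node 1
# after one MCS, from n_trials independent single-step realizations
engine_one_mcs_trials <- function(tau0, b1, b2, nb_spins, n_trials,
                                  seed0 = 1000) {
  net <- duplex_with_pairs(complete_graph(3), complete_graph(3),
                           cbind(1:3, 1:3))
  rules <- rule_spec("endogenous", "endogenous", b1, b2)
  big <- 1e12
  init <- manual_state(spins1 = c(1L, nb_spins),
                       spins2 = c(1L, nb_spins),
                       tau1 = c(tau0, big, big),
                       tau2 = c(tau0, big, big))
  spin <- integer(n_trials)
  tau <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    r <- run_realization(net, rules, t_max = 1, seed = seed0,
                         init = init, sample_times = 1L, stream = k)
    spin[k] <- r$state$spins1[1]
    tau[k] <- r$state$tau1[1]
  }
  data.frame(spin = spin, tau = tau)
}

# brute-force active-link fraction by explicit pair enumeration
rho_by_enumeration <- function(spins) {
  n <- length(spins)
  active <- 0L
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (spins[i] != spins[j]) active <- active + 1L
  active / (n * (n - 1) / 2)
}

# small random duplex for invariant sweeps
random_small_duplex <- function(seed) {
  withr::with_seed(seed, {
    pick <- sample(c("complete", "ring", "config"), 2, replace = TRUE)
    mk <- function(kind, n) switch(kind,
      complete = complete_graph(n),
      ring = ring_lattice(n),
      config = configuration_model(sample_degree_sequence(
        degree_spec("poisson", mean_degree = 4), n)))
    n <- sample(25:40, 1)
    couple_layers(mk(pick[1], n), mk(pick[2], n), q = stats::runif(1))
  })
}
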