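test_that("initial states set spins and persistence clocks as specified", {
  net <- withr::with_seed(1, duplex_complete(200, 0.3))
  rules <- rule_spec("endogenous", "endogenous", b1 = 1, b2 = 2)

  pol <- init_state(net, rules, mode = "layer_polarized",
                    polarized_common_value = 1L)
  expect_equal(mean(pol$spins1), 1)
  expect_equal(mean(pol$spins2), -1 + 2 * 0.3)  # m2 = -1 + 2q
  # clocks start at 1 + b of the layer; shared clocks at 1 + min(b1, b2)
  expect_true(all(pol$tau1[net$pairs[, 1]] == 2))
  expect_true(all(pol$tau2[net$pairs[, 2]] == 2))
  expect_true(all(pol$tau1[-net$pairs[, 1]] == 2))
  expect_true(all(pol$tau2[-net$pairs[, 2]] == 3))

  r1 <- withr::with_seed(2, init_state(net, rules))
  r2 <- withr::with_seed(2, init_state(net, rules))
  expect_identical(r1, r2)
  expect_equal(r1$spins1[net$pairs[, 1]], r1$spins2[net$pairs[, 2]])
  expect_true(all(r1$spins1 %in% c(-1L, 1L)))

  # b = 1 with q = 0: every clock starts at 2
  q0 <- init_state(duplex_complete(50, 0), rule_spec(b1 = 1, b2 = 1),
                   mode = "layer_polarized")
  expect_true(all(c(q0$tau1, q0$tau2) == 2))
})

test_that("one-MCS outcome distribution matches the exact enumeration", {
  # focal node with both neighbours opposed: any activation flips it, so
  # the flip probability is the closed-form effective activation; the
  # final clock identifies the layer that flipped it
  n_trials <- 8000
  for (case in list(list(tau0 = 2, b1 = 1, b2 = 1, nb = c(-1L, -1L)),
                    list(tau0 = 4, b1 = 1, b2 = 2, nb = c(-1L, -1L)),
                    list(tau0 = 3, b1 = 1.5, b2 = 1, nb = c(1L, -1L)))) {
    exact <- enumerate_one_mcs(case$tau0, case$b1, case$b2, case$nb)
    expect_equal(sum(exact$prob), 1, tolerance = 1e-12)
    if (all(case$nb == -1L)) {
      p_flip <- sum(exact$prob[exact$spin == -1L])
      expect_equal(p_flip,
                   effective_activation(case$tau0, case$b1, case$b2),
                   tolerance = 1e-12)
    }
    emp <- engine_one_mcs_trials(case$tau0, case$b1, case$b2, case$nb,
                                 n_trials, seed0 = 77)
    for (k in seq_len(nrow(exact))) {
      p <- exact$prob[k]
      if (p < 1e-6) next
      obs <- mean(emp$spin == exact$spin[k] &
                    abs(emp$tau - exact$tau[k]) < 1e-9)
      se <- sqrt(p * (1 - p) / n_trials)
      expect_lt(abs(obs - p), 3 * se + 1e-12)
    }
  }
})

test_that("reference sweeps agree with the enumeration too", {
  # same three-node setup, driven through the pure-R mcs_step
  case <- list(tau0 = 2, b1 = 1, b2 = 2, nb = c(1L, -1L))
  exact <- enumerate_one_mcs(case$tau0, case$b1, case$b2, case$nb)
  net <- duplex_with_pairs(complete_graph(3), complete_graph(3),
                           cbind(1:3, 1:3))
  rules <- rule_spec("endogenous", "endogenous", case$b1, case$b2)
  big <- 1e12
  n_trials <- 4000
  res <- withr::with_seed(31, vapply(seq_len(n_trials), function(k) {
    st <- manual_state(c(1L, case$nb), c(1L, case$nb),
                       c(case$tau0, big, big), c(case$tau0, big, big))
    st <- mcs_step(st, net, rules)
    c(st$spins1[1], st$tau1[1])
  }, numeric(2)))
  for (k in seq_len(nrow(exact))) {
    p <- exact$prob[k]
    if (p < 1e-6) next
    obs <- mean(res[1, ] == exact$spin[k] &
                  abs(res[2, ] - exact$tau[k]) < 1e-9)
    expect_lt(abs(obs - p), 3.5 * sqrt(p * (1 - p) / n_trials) + 1e-12)
  }
})

test_that("shared state and clocks stay synchronized through the dynamics", {
  for (s in 1:6) {
    net <- random_small_duplex(s)
    rules <- rule_spec(sample(c("endogenous", "rau"), 1),
                       sample(c("endogenous", "rau"), 1),
                       b1 = 1 + s / 10, b2 = 1.5)
    r <- run_realization(net, rules, t_max = 60, seed = s)
    if (nrow(net$pairs)) {
      expect_equal(r$state$spins1[net$pairs[, 1]],
                   r$state$spins2[net$pairs[, 2]])
      expect_equal(r$state$tau1[net$pairs[, 1]],
                   r$state$tau2[net$pairs[, 2]])
    }
    expect_true(all(r$state$tau1 >= 1))
    expect_true(all(abs(r$state$spins1) == 1L))
  }
})

test_that("clocks equal last reset value plus time since the last flip", {
  net <- withr::with_seed(7, duplex_complete(40, 0.25))
  rules <- rule_spec(b1 = 1, b2 = 1)
  r <- run_realization(net, rules, t_max = 80, seed = 3,
                       record_flips = TRUE)
  N <- 40
  last_flip <- rep(NA_integer_, N)
  for (k in seq_len(nrow(r$events))) {
    id <- r$events$node[k]
    if (id <= N) last_flip[id] <- r$events$time[k]
  }
  t_end <- r$t_final
  never <- is.na(last_flip)
  # never-flipped nodes: initial clock + elapsed MCS
  expect_equal(r$state$tau1[never], rep(2 + t_end, sum(never)))
  # flipped nodes: reset value (2) + time since last recorded flip,
  # unless a same-MCS flip-back hid an extra reset (clock then younger)
  flipped <- which(!never)
  expect_true(all(r$state$tau1[flipped] <=
                    2 + (t_end - last_flip[flipped]) + 1e-9))
})

test_that("RAU basic steps force adoption and conserve magnetization on average", {
  # two mutually connected nodes with opposite spins reach consensus
  # within one sweep: the first basic step already copies the other spin
  net <- duplex_with_pairs(complete_graph(2), complete_graph(2),
                           matrix(integer(0), ncol = 2))
  rules <- rule_spec("rau", "rau")
  for (s in 1:10) {
    st <- manual_state(c(1L, -1L), c(1L, 1L), c(2, 2), c(2, 2))
    out <- withr::with_seed(s, rau_sweep(st, net, 1, b = 1))
    expect_equal(out$spins1[1], out$spins1[2])
  }

  # uniform layer is untouched
  st <- manual_state(c(1L, 1L), c(1L, -1L), c(2, 2), c(2, 2))
  out <- withr::with_seed(1, rau_sweep(st, net, 1, b = 1))
  expect_equal(out$spins1, c(1L, 1L))

  # ensemble-mean magnetization of a degree-regular RAU monolayer is
  # conserved (neutral drift)
  ring <- couple_layers(ring_lattice(60), ring_lattice(60), 0)
  m_final <- vapply(1:80, function(s) {
    r <- run_realization(ring, rules, t_max = 150, seed = s)
    tail(r$trajectory$m1, 1)
  }, numeric(1))
  expect_lt(abs(mean(m_final)), 3 * sd(m_final) / sqrt(length(m_final)))
})

test_that("consensus is absorbing and ends the run", {
  net <- withr::with_seed(2, duplex_complete(30, 0.5))
  st <- manual_state(rep(1L, 30), rep(1L, 30), rep(2, 30), rep(2, 30))
  r <- run_realization(net, rule_spec(), t_max = 50, seed = 1, init = st)
  expect_equal(r$stop_reason, "consensus")
  expect_equal(r$t_final, 1L)
  expect_true(all(r$trajectory$rho1 == 0))
  # clocks still age while nothing flips
  expect_true(all(r$state$tau1 == 3))
})

test_that("fixed seeds reproduce realizations exactly", {
  net <- withr::with_seed(3, duplex_complete(80, 0.2))
  rules <- rule_spec(b1 = 1, b2 = 1.5)
  a <- run_realization(net, rules, t_max = 200, seed = 99,
                       record_flips = TRUE)
  b <- run_realization(net, rules, t_max = 200, seed = 99,
                       record_flips = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$events, b$events)
  expect_identical(a$state, b$state)
  c <- run_realization(net, rules, t_max = 200, seed = 100)
  expect_false(identical(a$trajectory, c$trajectory))

  expect_error(run_realization(net, rules, t_max = 0, seed = 1), "t_max")
  expect_error(run_realization(net, rules, t_max = 10), "seed")
})

test_that("uncoupled uniform-opposite layers freeze instead of absorbing", {
  net <- duplex_complete(20, 0)
  st <- manual_state(rep(1L, 20), rep(-1L, 20), rep(2, 20), rep(2, 20))
  r <- run_realization(net, rule_spec(), t_max = 30, seed = 4, init = st)
  expect_equal(r$stop_reason, "frozen")
  expect_equal(tail(r$trajectory$m1, 1), 1)
  expect_equal(tail(r$trajectory$m2, 1), -1)
})

test_that("ensembles aggregate deterministically and classify outcomes", {
  net <- withr::with_seed(5, duplex_complete(60, 0.2))
  a <- run_ensemble(net, rule_spec(), 6, 120, seed = 17)
  b <- run_ensemble(net, rule_spec(), 6, 120, seed = 17)
  expect_identical(a$rho1, b$rho1)
  expect_identical(a$final, b$final)
  expect_equal(sum(a$outcome_counts), 6)
  expect_equal(dim(a$rho1), c(length(a$times), 6L))

  rho <- ensemble_rho(a)
  expect_equal(rho$rho, rowMeans((a$rho1 + a$rho2) / 2))
  surv <- ensemble_rho(a, survivors_only = TRUE)
  expect_true(all(surv$n <= rho$n))
})
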