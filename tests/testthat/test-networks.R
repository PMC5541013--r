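test_that("complete graphs have all pairs adjacent and reject N < 2", {
  g <- complete_graph(3)
  expect_equal(edge_count(g), 3L)
  expect_equal(g$degrees, rep(2L, 3))
  expect_setequal(neighbors_of(g, 2), c(1L, 3L))

  expect_equal(edge_count(complete_graph(1000)), 499500L)
  expect_error(complete_graph(1), "N >= 2")
})

test_that("ring lattice is a periodic chain of degree 2", {
  g <- ring_lattice(1000)
  expect_equal(edge_count(g), 1000L)
  expect_true(all(g$degrees == 2L))

  expect_equal(edge_count(ring_lattice(3)), 3L)  # triangle
  g4 <- ring_lattice(4)
  expect_setequal(neighbors_of(g4, 1), c(2L, 4L))  # periodic wrap
  expect_error(ring_lattice(2), "N >= 3")
})

test_that("square lattice is a 4-neighbour torus", {
  g <- square_lattice(100)
  expect_equal(g$n_nodes, 10000L)
  expect_equal(edge_count(g), 20000L)

  g3 <- square_lattice(3)
  expect_true(all(g3$degrees == 4L))
  g4 <- square_lattice(4)
  # node (1,1) wraps to (1,2), (1,4), (2,1), (4,1): indices 2, 4, 5, 13
  expect_setequal(neighbors_of(g4, 1), c(2L, 4L, 5L, 13L))
  expect_error(square_lattice(2), "L >= 3")
})

test_that("generated layers satisfy the undirected-simple invariants", {
  graphs <- list(ring_lattice(17), square_lattice(5),
                 withr::with_seed(4, configuration_model(
                   sample_degree_sequence(
                     degree_spec("poisson", mean_degree = 5), 60))))
  for (g in graphs) {
    for (i in seq_len(g$n_nodes)) {
      nb <- neighbors_of(g, i)
      expect_false(i %in% nb)                 # no self-loops
      expect_equal(anyDuplicated(nb), 0L)     # no multi-edges
      expect_true(length(nb) >= 1)
      for (j in nb) expect_true(i %in% neighbors_of(g, j))  # symmetry
    }
  }
})

test_that("degree sequences respect the truncated support and parity", {
  spec <- degree_spec("poisson", mean_degree = 14)
  deg <- withr::with_seed(1, sample_degree_sequence(spec, 1000))
  expect_length(deg, 1000)
  expect_true(all(deg >= 2 & deg <= 31))  # k_max = floor(sqrt(1000))
  expect_equal(sum(deg) %% 2, 0)

  pl <- degree_spec("powerlaw", gamma = 2.5)
  deg2 <- withr::with_seed(2, sample_degree_sequence(pl, 2000))
  expect_true(all(deg2 >= 2 & deg2 <= 44))
  expect_equal(sum(deg2) %% 2, 0)

  # forced support: N = 4 gives k_max = 2 = k_min
  expect_equal(sample_degree_sequence(spec, 4), rep(2L, 4))
  expect_error(sample_degree_sequence(spec, 3), "infeasible")
})

test_that("poisson degree histogram matches the truncated law", {
  spec <- degree_spec("poisson", mean_degree = 14)
  draws <- withr::with_seed(8, unlist(
    lapply(1:100, function(i) sample_degree_sequence(spec, 1000))))
  support <- 2:31
  prob <- dpois(support, 14) / sum(dpois(support, 14))
  obs <- tabulate(factor(draws, levels = support), nbins = length(support))
  keep <- prob * length(draws) >= 5
  chi <- suppressWarnings(
    chisq.test(obs[keep], p = prob[keep] / sum(prob[keep])))
  expect_gt(chi$p.value, 1e-4)
})

test_that("configuration model realizes the degree sequence exactly", {
  expect_equal(edge_count(configuration_model(c(2, 2, 2))), 3L)  # triangle
  expect_equal(edge_count(configuration_model(c(1, 1))), 1L)
  expect_error(configuration_model(c(2, 2, 1)), "even")

  for (s in 1:5) {
    g <- withr::with_seed(s, {
      spec <- degree_spec("powerlaw", gamma = 2.5)
      configuration_model(sample_degree_sequence(spec, 150))
    })
    expect_equal(sum(g$degrees) %% 2, 0)
    # cross-check degrees and simplicity with igraph
    skip_if_not_installed("igraph")
    ig <- igraph::graph_from_edgelist(as_edge_list(g), directed = FALSE)
    expect_true(igraph::is_simple(ig))
    expect_equal(as.integer(igraph::degree(ig)), g$degrees)
  }
})

test_that("coupling selects round(qN) pairs with the requested procedure", {
  g <- complete_graph(100)
  expect_equal(nrow(couple_layers(g, g, 0)$pairs), 0L)

  net1 <- withr::with_seed(3, couple_layers(g, g, 1))
  expect_equal(nrow(net1$pairs), 100L)
  expect_equal(sort(net1$pairs[, 1]), 1:100)  # a permutation
  expect_equal(sort(net1$pairs[, 2]), 1:100)

  # exact-count override for q = 10/N
  net2 <- withr::with_seed(3, couple_layers(g, g, 10 / 1000,
                                            n_common = 10L))
  expect_equal(nrow(net2$pairs), 10L)
  expect_equal(nrow(duplex_complete(1000, 10 / 1000)$pairs), 10L)

  expect_error(couple_layers(g, complete_graph(50), 0.5), "same number")
  expect_error(couple_layers(g, g, 1.2), "\\[0, 1\\]")
})

test_that("degree-ranked procedures pair by rank with index tie-breaks", {
  # two hand-built layers with distinct degree profiles
  adj1 <- list(c(2L, 3L, 4L), c(1L, 3L), c(1L, 2L), 1L)        # degrees 3,2,2,1
  adj2 <- list(2L, c(1L, 3L, 4L), c(2L, 4L), c(2L, 3L))        # degrees 1,3,2,2
  g1 <- agevoter:::new_layer_graph(4L, adj1, "custom")
  g2 <- agevoter:::new_layer_graph(4L, adj2, "custom")

  hh <- couple_layers(g1, g2, 0.25, procedure = "high_high")
  expect_equal(hh$pairs, cbind(1L, 2L))  # both maximum-degree nodes

  hl <- couple_layers(g1, g2, 0.5, procedure = "high_low")
  # layer-1 by degree desc: 1, then 2 (tie 2/3 broken by index);
  # layer-2 by degree asc: 1, then 3 (tie 3/4 broken by index)
  expect_equal(hl$pairs, cbind(c(1L, 2L), c(1L, 3L)))

  al <- withr::with_seed(9, couple_layers(g1, g2, 0.5,
                                          procedure = "aligned"))
  expect_equal(al$pairs[, 1], al$pairs[, 2])
})

test_that("coupling is reproducible under a fixed seed", {
  g1 <- ring_lattice(50)
  g2 <- ring_lattice(50)
  a <- withr::with_seed(11, couple_layers(g1, g2, 0.3))
  b <- withr::with_seed(11, couple_layers(g1, g2, 0.3))
  expect_identical(a$pairs, b$pairs)
})

test_that("edge lists and multilayer documents round-trip", {
  g <- withr::with_seed(5, configuration_model(
    sample_degree_sequence(degree_spec("poisson", mean_degree = 4), 30)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_equal(g2$n_nodes, g$n_nodes)
  expect_equal(g2$adj, g$adj)

  net <- withr::with_seed(6, couple_layers(g, ring_lattice(30), 0.2))
  prefix <- file.path(withr::local_tempdir(), "net")
  jpath <- write_multilayer(net, prefix, seed = 6L)
  back <- read_multilayer(jpath)
  expect_equal(back$pairs, net$pairs)
  # neighbour order is not part of the format; compare as sets
  expect_equal(lapply(back$layer1$adj, sort), lapply(net$layer1$adj, sort))
  expect_equal(lapply(back$layer2$adj, sort), lapply(net$layer2$adj, sort))
  expect_equal(back$q, net$q)
})
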