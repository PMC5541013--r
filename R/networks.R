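#' Single-layer graph objects
#'
#' A `layer_graph` stores one layer's undirected topology as a 0-based-free,
#' 1-based adjacency list together with its degree sequence. Complete graphs
#' are stored implicitly (no adjacency list is materialized), so layers with
#' many thousands of nodes stay cheap; [neighbors_of()] and [as_edge_list()]
#' present a uniform interface regardless of storage.
#'
#' @param n_nodes number of nodes.
#' @param adj list of integer vectors, `adj[[i]]` the neighbours of node `i`
#'   (1-based), or `NULL` for an implicit complete graph.
#' @param kind one of `"complete"`, `"ring1d"`, `"lattice2d"`,
#'   `"config_model"`, `"custom"`.
#' @return An object of class `layer_graph` with fields `n_nodes`, `adj`,
#'   `kind`, `degrees`.
#' @keywords internal
new_layer_graph <- function(n_nodes, adj, kind) {
  if (is.null(adj)) {
    degrees <- rep.int(n_nodes - 1L, n_nodes)
  } else {
    stopifnot(length(adj) == n_nodes)
    degrees <- vapply(adj, length, integer(1))
  }
  structure(list(n_nodes = as.integer(n_nodes), adj = adj, kind = kind,
                 degrees = degrees),
            class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph: %s, N = %d, edges = %d>\n",
              x$kind, x$n_nodes, edge_count(x)))
  invisible(x)
}

#' Neighbours of a node
#'
#' @param g a `layer_graph`.
#' @param i node index (1-based).
#' @return Integer vector of neighbour indices.
#' @export
neighbors_of <- function(g, i) {
  stopifnot(inherits(g, "layer_graph"), i >= 1, i <= g$n_nodes)
  if (is.null(g$adj)) return(setdiff(seq_len(g$n_nodes), as.integer(i)))
  g$adj[[i]]
}

#' Number of undirected edges in a layer
#' @param g a `layer_graph`.
#' @return Integer edge count.
#' @export
edge_count <- function(g) {
  stopifnot(inherits(g, "layer_graph"))
  as.integer(sum(g$degrees) / 2)
}

#' Complete graph layer
#'
#' Fully connected layer: every pair of the `N` nodes is adjacent. Used for
#' the mean-field setting in which the trapped-state plateau levels have
#' closed forms.
#'
#' @param N number of nodes, at least 2.
#' @return A `layer_graph` of kind `"complete"`.
#' @export
#' @examples
#' g <- complete_graph(10)
#' edge_count(g)  # 45
complete_graph <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1 || is.na(N) || N < 2)
    stop("complete_graph() needs N >= 2", call. = FALSE)
  new_layer_graph(N, NULL, "complete")
}

#' One-dimensional periodic lattice (ring)
#'
#' @param N number of nodes, at least 3.
#' @return A `layer_graph` of kind `"ring1d"`; every node has degree 2.
#' @export
ring_lattice <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1 || is.na(N) || N < 3)
    stop("ring_lattice() needs N >= 3", call. = FALSE)
  adj <- lapply(seq_len(N), function(i) {
    c((i - 2L) %% N + 1L, i %% N + 1L)
  })
  new_layer_graph(N, adj, "ring1d")
}

#' Two-dimensional periodic square lattice
#'
#' `L x L` torus with 4-neighbour (von Neumann) adjacency, the standard
#' choice for lattice voter models.
#'
#' @param L linear size, at least 3; the layer has `N = L^2` nodes.
#' @return A `layer_graph` of kind `"lattice2d"`; every node has degree 4.
#' @export
square_lattice <- function(L) {
  L <- as.integer(L)
  if (length(L) != 1 || is.na(L) || L < 3)
    stop("square_lattice() needs L >= 3", call. = FALSE)
  N <- L * L
  idx <- function(r, c) ((r - 1L) %% L) * L + ((c - 1L) %% L) + 1L
  adj <- vector("list", N)
  for (r in seq_len(L)) {
    for (c in seq_len(L)) {
      adj[[idx(r, c)]] <- c(idx(r - 1L, c), idx(r + 1L, c),
                            idx(r, c - 1L), idx(r, c + 1L))
    }
  }
  new_layer_graph(N, adj, "lattice2d")
}

#' Degree-distribution specification for the configuration model
#'
#' Degrees are drawn from a distribution truncated to
#' `[k_min, floor(sqrt(N))]`; the square-root cutoff avoids structural
#' degree-degree correlations in the resulting graphs and `k_min >= 2`
#' keeps the layers from fragmenting.
#'
#' @param family `"poisson"` (parameter `mean_degree`) or `"powerlaw"`
#'   (tail exponent `gamma`, i.e. P(k) proportional to `k^-gamma`).
#' @param mean_degree mean degree for the Poisson family.
#' @param gamma positive tail-exponent magnitude for the power-law family.
#' @param k_min minimum degree, at least 2.
#' @return An object of class `degree_spec`.
#' @export
degree_spec <- function(family = c("poisson", "powerlaw"),
                        mean_degree = NULL, gamma = NULL, k_min = 2L) {
  family <- match.arg(family)
  k_min <- as.integer(k_min)
  if (k_min < 2) stop("k_min must be >= 2", call. = FALSE)
  if (family == "poisson") {
    if (is.null(mean_degree) || mean_degree <= 0)
      stop("poisson family needs a positive mean_degree", call. = FALSE)
  } else {
    if (is.null(gamma) || gamma <= 0)
      stop("powerlaw family needs a positive gamma", call. = FALSE)
  }
  structure(list(family = family, mean_degree = mean_degree, gamma = gamma,
                 k_min = k_min, k_max_rule = "sqrt(N)"),
            class = "degree_spec")
}

#' Sample a degree sequence
#'
#' Draws `N` degrees from the truncated distribution of `spec` with
#' `k_max = floor(sqrt(N))`. If the sum is odd, single entries are redrawn
#' until the total stub count is even (a simple-graph requirement).
#'
#' Uses R's global RNG; call [set.seed()] for reproducibility.
#'
#' @param spec a [degree_spec()].
#' @param N number of nodes.
#' @return Integer vector of length `N` with even sum, entries in
#'   `[k_min, floor(sqrt(N))]`.
#' @export
sample_degree_sequence <- function(spec, N) {
  stopifnot(inherits(spec, "degree_spec"))
  N <- as.integer(N)
  k_max <- as.integer(floor(sqrt(N)))
  if (k_max < spec$k_min)
    stop(sprintf("infeasible degree support: k_max = %d < k_min = %d",
                 k_max, spec$k_min), call. = FALSE)
  support <- spec$k_min:k_max
  prob <- if (spec$family == "poisson") {
    stats::dpois(support, spec$mean_degree)
  } else {
    support^(-spec$gamma)
  }
  if (sum(prob) <= 0)
    stop("degree distribution has no mass on the truncated support",
         call. = FALSE)
  draw <- function(n) {
    if (length(support) == 1L) rep.int(support, n)
    else sample(support, n, replace = TRUE, prob = prob)
  }
  deg <- draw(N)
  guard <- 0L
  while (sum(deg) %% 2L != 0L) {
    deg[sample.int(N, 1L)] <- draw(1L)
    guard <- guard + 1L
    if (guard > 10000L)
      stop("could not reach an even degree sum", call. = FALSE)
  }
  deg
}

#' Configuration-model graph from a degree sequence
#'
#' Random stub matching followed by degree-preserving rewiring to repair
#' self-loops and multi-edges. The returned graph realizes the input
#' degree sequence exactly; if the repair does not converge within
#' `max_attempts` rewiring proposals, an error is raised rather than
#' silently accepting a defective graph.
#'
#' Uses R's global RNG; call [set.seed()] for reproducibility.
#'
#' @param degrees integer degree sequence with even sum; max degree < N.
#' @param max_attempts bound on rewiring proposals during repair.
#' @return A `layer_graph` of kind `"config_model"`.
#' @export
configuration_model <- function(degrees, max_attempts = 100000L) {
  degrees <- as.integer(degrees)
  N <- length(degrees)
  if (N < 2) stop("need at least two nodes", call. = FALSE)
  if (any(degrees < 1)) stop("all degrees must be >= 1", call. = FALSE)
  if (max(degrees) >= N)
    stop("max degree must be < N for a simple graph", call. = FALSE)
  if (sum(degrees) %% 2L != 0L)
    stop("degree sum must be even", call. = FALSE)

  stubs <- rep.int(seq_len(N), degrees)
  stubs <- sample(stubs)
  edges <- matrix(stubs, ncol = 2L, byrow = TRUE)
  edges <- t(apply(edges, 1L, sort))  # i <= j per row

  ekey <- function(e) (e[, 1L] - 1) * N + (e[, 2L] - 1)
  # a row is bad if it is a self-loop, or a duplicate beyond the first copy
  bad_rows <- function(e) {
    keys <- ekey(e)
    self <- e[, 1L] == e[, 2L]
    dup <- duplicated(keys)
    which(self | dup)
  }

  attempts <- 0L
  m <- nrow(edges)
  repeat {
    bad <- bad_rows(edges)
    if (length(bad) == 0L) break
    r1 <- bad[[1L]]
    r2 <- sample.int(m, 1L)
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("configuration model repair failed: rewiring bound exceeded",
           call. = FALSE)
    if (r2 == r1) next
    a <- edges[r1, ]; b <- edges[r2, ]
    cand1 <- sort(c(a[1L], b[1L])); cand2 <- sort(c(a[2L], b[2L]))
    if (cand1[1L] == cand1[2L] || cand2[1L] == cand2[2L]) {
      cand1 <- sort(c(a[1L], b[2L])); cand2 <- sort(c(a[2L], b[1L]))
      if (cand1[1L] == cand1[2L] || cand2[1L] == cand2[2L]) next
    }
    keys <- ekey(edges[-c(r1, r2), , drop = FALSE])
    k1 <- (cand1[1L] - 1) * N + (cand1[2L] - 1)
    k2 <- (cand2[1L] - 1) * N + (cand2[2L] - 1)
    if (k1 == k2 || k1 %in% keys || k2 %in% keys) next
    edges[r1, ] <- cand1
    edges[r2, ] <- cand2
  }

  adj <- edge_matrix_to_adj(edges, N)
  g <- new_layer_graph(N, adj, "config_model")
  stopifnot(identical(g$degrees, degrees))
  g
}

# 1-based m x 2 edge matrix -> adjacency list with sorted neighbours
edge_matrix_to_adj <- function(edges, N) {
  adj <- vector("list", N)
  both <- rbind(edges, edges[, 2:1, drop = FALSE])
  sp <- split(both[, 2L], factor(both[, 1L], levels = seq_len(N)))
  for (i in seq_len(N)) adj[[i]] <- as.integer(sort(sp[[i]]))
  adj
}

#' Couple two layers into a two-layer network
#'
#' Selects `round(q * N)` common nodes (or an exact count via `n_common`,
#' useful for values such as `q = 10/N`) and pairs a node of layer 1 with a
#' node of layer 2. Paired (common) nodes share their state and persistence
#' clock during the dynamics.
#'
#' Pairing procedures:
#' \describe{
#'   \item{random}{uniform pairing without replacement (global RNG).}
#'   \item{aligned}{a uniformly random subset of `qN` node indices is
#'     shared, each node paired with the node of the same index in the
#'     other layer. This is the natural choice when the two layers carry
#'     the same node identities — on lattice duplexes in particular, a
#'     shared node occupies the same site in both layers, which preserves
#'     the monolayer coarsening law for every `q` (random cross-index
#'     pairing would instead overlay an effective long-range graph).}
#'   \item{high_low}{the `qN` highest-degree nodes of layer 1, paired
#'     rank-by-rank with the `qN` lowest-degree nodes of layer 2.}
#'   \item{high_high}{highest-degree nodes of both layers, paired
#'     rank-by-rank.}
#' }
#' Degree ties are broken by node index.
#'
#' @param g1,g2 `layer_graph` objects with equal `n_nodes`.
#' @param q multiplexity, fraction of shared nodes in `[0, 1]`.
#' @param procedure `"random"`, `"aligned"`, `"high_low"` or
#'   `"high_high"`.
#' @param n_common optional exact number of common nodes, overriding
#'   `round(q * N)`.
#' @return An object of class `multilayer_net` with fields `layer1`,
#'   `layer2`, `pairs` (two-column integer matrix, 1-based), `q`,
#'   `n_common`, `procedure`.
#' @export
couple_layers <- function(g1, g2, q,
                          procedure = c("random", "aligned", "high_low",
                                        "high_high"),
                          n_common = NULL) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(g1, "layer_graph"), inherits(g2, "layer_graph"))
  if (g1$n_nodes != g2$n_nodes)
    stop("layers must have the same number of nodes", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0 || q > 1)
    stop("q must be a single value in [0, 1]", call. = FALSE)
  N <- g1$n_nodes
  n_common <- if (is.null(n_common)) as.integer(round(q * N))
              else as.integer(n_common)
  if (n_common < 0 || n_common > N)
    stop("n_common out of range", call. = FALSE)

  if (n_common == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else if (procedure == "random") {
    pairs <- cbind(sample.int(N, n_common), sample.int(N, n_common))
  } else if (procedure == "aligned") {
    S <- sort(sample.int(N, n_common))
    pairs <- cbind(S, S)
  } else {
    # order(): ties broken by node index (stable ascending index)
    desc1 <- order(-g1$degrees, seq_len(N))[seq_len(n_common)]
    if (procedure == "high_low") {
      sel2 <- order(g2$degrees, seq_len(N))[seq_len(n_common)]
    } else {
      sel2 <- order(-g2$degrees, seq_len(N))[seq_len(n_common)]
    }
    pairs <- cbind(desc1, sel2)
  }
  dimnames(pairs) <- NULL
  storage.mode(pairs) <- "integer"
  structure(list(layer1 = g1, layer2 = g2, pairs = pairs,
                 q = q, n_common = n_common, procedure = procedure),
            class = "multilayer_net")
}

#' @export
print.multilayer_net <- function(x, ...) {
  cat(sprintf(
    "<multilayer_net: %s + %s, N = %d, q = %.4g (%d common, %s pairing)>\n",
    x$layer1$kind, x$layer2$kind, x$layer1$n_nodes, x$q, x$n_common,
    x$procedure))
  invisible(x)
}

# partner vectors (1-based, NA if not common) for the engine and invariants
partner_vectors <- function(net) {
  N <- net$layer1$n_nodes
  p1 <- rep(NA_integer_, N)
  p2 <- rep(NA_integer_, N)
  if (nrow(net$pairs) > 0) {
    p1[net$pairs[, 1L]] <- net$pairs[, 2L]
    p2[net$pairs[, 2L]] <- net$pairs[, 1L]
  }
  list(p1 = p1, p2 = p2)
}

#' Convenience constructor: duplex of two complete graphs
#'
#' @param N nodes per layer.
#' @param q multiplexity.
#' @param n_common optional exact common-node count (see [couple_layers()]).
#' @return A `multilayer_net`.
#' @export
duplex_complete <- function(N, q, n_common = NULL) {
  couple_layers(complete_graph(N), complete_graph(N), q,
                procedure = "random", n_common = n_common)
}

#' Edge-list representation of a layer
#' @param g a `layer_graph`.
#' @return Two-column integer matrix of edges with `i < j`, 1-based.
#' @export
as_edge_list <- function(g) {
  stopifnot(inherits(g, "layer_graph"))
  N <- g$n_nodes
  if (is.null(g$adj)) {
    idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    e <- cbind(idx[, "row"], idx[, "col"])
    return(matrix(as.integer(e[order(e[, 1L], e[, 2L]), ]), ncol = 2L))
  }
  rows <- lapply(seq_len(N), function(i) {
    js <- g$adj[[i]][g$adj[[i]] > i]
    if (length(js)) cbind(i, js) else NULL
  })
  e <- do.call(rbind, rows)
  if (is.null(e)) e <- matrix(integer(0), ncol = 2L)
  dimnames(e) <- NULL
  storage.mode(e) <- "integer"
  e
}

#' Write / read a layer as a whitespace-separated edge list
#'
#' Format: one undirected edge per line, two 0-based integer columns with
#' `i < j`; lines starting with `#` are comments.
#'
#' @param g a `layer_graph`.
#' @param path file path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   returns a `layer_graph`.
#' @export
write_edge_list <- function(g, path) {
  e <- as_edge_list(g) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d kind=%s", g$n_nodes, g$kind), con)
  utils::write.table(e, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_nodes node count; if `NULL`, taken from the `#` header or from
#'   the largest index seen.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  kind <- "custom"
  if (is.null(n_nodes) && length(header)) {
    m <- regmatches(header[1], regexec("n_nodes=(\\d+)", header[1]))[[1]]
    if (length(m) == 2) n_nodes <- as.integer(m[2])
    k <- regmatches(header[1], regexec("kind=(\\S+)", header[1]))[[1]]
    if (length(k) == 2) kind <- k[2]
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body)) {
    e <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                               function(x) as.integer(x[1:2]))) + 1L
  } else {
    e <- matrix(integer(0), ncol = 2L)
  }
  if (is.null(n_nodes)) n_nodes <- if (nrow(e)) max(e) else 0L
  if (kind == "complete") return(complete_graph(n_nodes))
  adj <- edge_matrix_to_adj(e, n_nodes)
  for (i in seq_len(n_nodes)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  new_layer_graph(n_nodes, adj, kind)
}

#' Serialize / restore a two-layer network
#'
#' Writes `<prefix>.json` (N, q, procedure, 0-based pairs, layer file
#' names) plus `<prefix>_layer1.txt` and `<prefix>_layer2.txt` edge lists.
#'
#' @param net a `multilayer_net`.
#' @param prefix path prefix for the three files.
#' @param seed optional integer recorded in the JSON for provenance.
#' @return `write_multilayer()` returns the JSON path invisibly;
#'   `read_multilayer()` returns a `multilayer_net`.
#' @export
write_multilayer <- function(net, prefix, seed = NULL) {
  f1 <- paste0(prefix, "_layer1.txt")
  f2 <- paste0(prefix, "_layer2.txt")
  write_edge_list(net$layer1, f1)
  write_edge_list(net$layer2, f2)
  doc <- list(N = net$layer1$n_nodes, q = net$q,
              n_common = net$n_common, procedure = net$procedure,
              seed = seed,
              pairs = if (nrow(net$pairs)) unname(net$pairs - 1L)
                      else matrix(integer(0), ncol = 2L),
              layer1 = basename(f1), layer2 = basename(f2))
  jpath <- paste0(prefix, ".json")
  jsonlite::write_json(doc, jpath, auto_unbox = TRUE, digits = NA)
  invisible(jpath)
}

#' @rdname write_multilayer
#' @param json_path path to the JSON document written by
#'   `write_multilayer()`.
#' @export
read_multilayer <- function(json_path) {
  doc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dir <- dirname(json_path)
  g1 <- read_edge_list(file.path(dir, doc$layer1))
  g2 <- read_edge_list(file.path(dir, doc$layer2))
  pairs <- if (length(doc$pairs)) matrix(as.integer(doc$pairs), ncol = 2L) + 1L
           else matrix(integer(0), ncol = 2L)
  net <- couple_layers(g1, g2, doc$q, procedure = doc$procedure,
                       n_common = 0L)
  net$pairs <- pairs
  net$n_common <- nrow(pairs)
  net
}
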