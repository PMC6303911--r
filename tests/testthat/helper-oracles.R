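# Independent oracles used across the suite. Everything here is a
# deliberately different computational route from the package internals:
# dense matrices built from first principles, explicit boundary node,
# full-kernel solves, and brute-force enumeration.

# The hand-solved worked example: compounds c1, c2 feeding reaction r
# under pathway p. With input {c1} the grounded system gives
# T = (c1 = 3, c2 = 2, r = 2, p = 1).
toy_graph4 <- function() {
  knowledge_graph(
    nodes = data.frame(
      id = c("p", "r", "c1", "c2"),
      level = c("pathway", "reaction", "compound", "compound")),
    edges = data.frame(from = c("c1", "c2", "r"),
                       to = c("r", "r", "p"))
  )
}

# Small random graphs for property tests.
random_kg <- function(seed, pathways = 2, modules = 3, enzymes = 6,
                      reactions = 12, compounds = 20, mean_degree = 2.5) {
  generate_graph(pathways = pathways, modules = modules,
                 enzymes = enzymes, reactions = reactions,
                 compounds = compounds, mean_degree = mean_degree,
                 seed = seed)
}

# Dense diffusion oracle: literally build the boundary-augmented graph's
# Laplacian, delete the boundary row/column, invert densely.
dense_diffusion <- function(g, input_ids) {
  ids <- igraph::V(g)$name
  n <- length(ids)
  A <- matrix(0, n + 1, n + 1,
              dimnames = list(c(ids, ".b"), c(ids, ".b")))
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    A[el[i, 1], el[i, 2]] <- 1
    A[el[i, 2], el[i, 1]] <- 1
  }
  for (p in ids[igraph::V(g)$level == "pathway"]) {
    A[p, ".b"] <- 1
    A[".b", p] <- 1
  }
  L <- diag(rowSums(A)) - A
  Lgg <- L[ids, ids]
  G <- as.numeric(ids %in% input_ids)
  drop(solve(Lgg) %*% G)
}

# Dense PageRank oracle: build the full stochastic kernel on the upward
# view (dangling rows uniform over all nodes) and solve the stationary
# equations directly.
dense_pagerank <- function(g, input_ids, damping = 0.85) {
  up <- upward_view(g)
  ids <- igraph::V(up)$name
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  el <- igraph::as_edgelist(up)
  for (i in seq_len(nrow(el))) P[el[i, 1], el[i, 2]] <- 1
  outdeg <- rowSums(P)
  for (i in seq_len(n)) {
    if (outdeg[i] == 0) P[i, ] <- 1 / n else P[i, ] <- P[i, ] / outdeg[i]
  }
  v <- as.numeric(ids %in% input_ids)
  v <- v / sum(v)
  p <- solve(diag(n) - damping * t(P)) %*% ((1 - damping) * v)
  setNames(drop(p), ids)
}

# Exhaustive permutation-null moments: score every one of the C(m, n)
# possible inputs with the dense oracles and take exact moments
# (denominator N, since the enumeration is the whole population).
enumerate_moments <- function(g, method, n, damping = 0.85) {
  compounds <- kg_nodes(g, "compound")
  sets <- utils::combn(compounds, n, simplify = FALSE)
  scorer <- if (method == "diffusion") dense_diffusion else
    function(g, ids) dense_pagerank(g, ids, damping)
  S <- vapply(sets, function(s) scorer(g, s),
              numeric(igraph::vcount(g)))
  mu <- rowMeans(S)
  sigma <- sqrt(rowMeans((S - mu)^2))
  list(ids = igraph::V(g)$name, mu = mu, sigma = sigma,
       scores = S, sets = sets)
}

# Brute-force upper-tail hypergeometric: enumerate every n-subset of m
# compounds, of which m_a are annotated, and count draws with >= x hits.
enumerate_hypergeom <- function(m, m_a, n, x) {
  sets <- utils::combn(m, n, simplify = FALSE)
  hits <- vapply(sets, function(s) sum(s <= m_a), numeric(1))
  mean(hits >= x)
}

# Exact max-component tail on a tiny graph: enumerate all k-subsets.
enumerate_cc_tail <- function(graph, k, r) {
  n <- igraph::vcount(graph)
  sets <- utils::combn(n, k, simplify = FALSE)
  maxcc <- vapply(sets, function(s) {
    max(igraph::components(igraph::induced_subgraph(graph, s))$csize)
  }, numeric(1))
  mean(maxcc >= r)
}

with_seed <- netmet:::with_seed
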