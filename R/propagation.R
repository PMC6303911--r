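#' Map submitted compound identifiers onto a graph
#'
#' Matches a list of KEGG-style compound identifiers against the compound
#' nodes of the knowledge graph. Duplicates are collapsed; identifiers
#' not found in the graph (or found at a non-compound level) are kept as
#' mismatches in submission order.
#'
#' @param ids Character vector of submitted identifiers.
#' @param g A valid `knowledge_graph`.
#' @return An object of class `nm_input`: list with `mapped` (compound
#'   node ids present in the graph) and `mismatches`.
#' @export
#' @examples
#' g <- generate_graph(pathways = 2, modules = 2, enzymes = 4,
#'                     reactions = 8, compounds = 12, seed = 1)
#' inp <- define_compounds(kg_nodes(g, "compound")[1:3], g)
#' inp$mapped
define_compounds <- function(ids, g) {
  stopifnot(length(ids) > 0)
  ids <- as.character(ids)
  ids <- ids[!duplicated(ids)]
  compounds <- kg_nodes(g, "compound")
  mapped <- ids[ids %in% compounds]
  mismatches <- ids[!(ids %in% compounds)]
  if (length(mapped) == 0) {
    stop("no input compounds mapped to the graph")
  }
  structure(list(mapped = mapped, mismatches = mismatches),
            class = "nm_input")
}

#' @exportS3Method base::print
print.nm_input <- function(x, ...) {
  cat("<nm_input> ", length(x$mapped), " mapped, ",
      length(x$mismatches), " mismatching identifier(s)\n", sep = "")
  invisible(x)
}

as_input <- function(inp, g) {
  if (inherits(inp, "nm_input")) {
    missing <- setdiff(inp$mapped, kg_nodes(g, "compound"))
    if (length(missing)) {
      stop("input compounds not in graph: ", paste(missing, collapse = ", "))
    }
    inp
  } else {
    define_compounds(inp, g)
  }
}

#' Read a compound list from a plain-text file
#'
#' One KEGG compound identifier per line; blank lines and `#` comments
#' are ignored.
#'
#' @param path Path to the text file.
#' @return Character vector of identifiers.
#' @export
read_compound_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

# Grounded Laplacian of the boundary-augmented graph. Attaching a single
# temperature-0 boundary node to every pathway and deleting its row and
# column leaves L(g) + diag(1 on pathways): each pathway's degree grows
# by one and no other entry changes.
grounded_laplacian <- function(g) {
  if (!any(igraph::V(g)$level == "pathway")) {
    stop("graph has no pathway node; the boundary is unreachable")
  }
  L <- igraph::laplacian_matrix(g, sparse = TRUE,
                                normalization = "unnormalized")
  d <- as.numeric(igraph::V(g)$level == "pathway")
  L <- L + Matrix::Diagonal(n = igraph::vcount(g), x = d)
  rownames(L) <- colnames(L) <- igraph::V(g)$name
  L
}

#' Heat-diffusion scores
#'
#' Scores every node by the equilibrium temperature of a heat-diffusion
#' model on the undirected graph: each input compound generates unit
#' flow, and a boundary node held at temperature zero, attached to every
#' pathway, absorbs it. The returned temperatures solve the grounded
#' Laplacian system \eqn{L_g T = G}, where \eqn{L_g} is the Laplacian of
#' the boundary-augmented graph with the boundary row/column removed and
#' \eqn{G} is the 0/1 indicator of the input compounds. All scores are
#' non-negative and the total flow into the boundary equals the input
#' size.
#'
#' @param g A valid, connected `knowledge_graph`.
#' @param input An `nm_input` from [define_compounds()], or a character
#'   vector of compound ids.
#' @return Named numeric vector of temperatures over all nodes, with
#'   attributes `method = "diffusion"` and `n_input`.
#' @export
diffusion_raw <- function(g, input) {
  input <- as_input(input, g)
  Lg <- grounded_laplacian(g)
  G <- as.numeric(igraph::V(g)$name %in% input$mapped)
  temp <- as.numeric(Matrix::solve(Lg, G))
  structure(setNames(temp, igraph::V(g)$name),
            method = "diffusion", n_input = length(input$mapped))
}

# Sparse machinery for personalized PageRank on the upward view.
# Transition: a node moves uniformly over its upward neighbours; a
# dangling node (no upward arcs -- pathways, by construction) moves
# uniformly over all nodes. Returns the pieces needed to solve
#   p = d W' p + d (a' p) u + (1 - d) v
# for any restart vector v, where u is uniform and a flags danglers.
pagerank_operator <- function(g, damping) {
  if (damping <= 0 || damping >= 1) {
    stop("damping must lie strictly inside (0, 1)")
  }
  up <- upward_view(g)
  n <- igraph::vcount(up)
  A <- igraph::as_adjacency_matrix(up, sparse = TRUE)  # i -> j
  outdeg <- Matrix::rowSums(A)
  dangling <- outdeg == 0
  Wt <- Matrix::t(A / pmax(outdeg, 1))                 # column-stochastic W'
  M <- Matrix::Diagonal(n) - damping * Wt
  qu <- as.numeric(Matrix::solve(M, rep(1 / n, n)))
  list(M = M, dangling = dangling, qu = qu, n = n,
       names = igraph::V(up)$name, damping = damping)
}

# Solve the personalized PageRank fixed point for restart columns V
# (a dense or sparse matrix, columns summing to 1). Exactly linear in V.
pagerank_solve <- function(op, V) {
  d <- op$damping
  QV <- Matrix::solve(op$M, V)
  denom <- 1 - d * sum(op$qu[op$dangling])
  s <- (1 - d) * Matrix::colSums(QV[op$dangling, , drop = FALSE]) / denom
  P <- (1 - d) * QV + outer(op$qu, d * as.numeric(s))
  as.matrix(P)
}

#' Personalized-PageRank scores
#'
#' Scores every node by the stationary distribution of a random walk on
#' the upward-directed view of the graph that restarts, with probability
#' `1 - damping`, uniformly into the input compounds. Dangling nodes
#' (nodes without upward arcs, i.e. pathways) redistribute their walk
#' mass uniformly over all nodes, the classical PageRank convention; this
#' keeps the transition kernel independent of the input, so the score is
#' exactly linear in the restart distribution. Scores are non-negative
#' and sum to one.
#'
#' @inheritParams diffusion_raw
#' @param damping Probability of following an arc rather than
#'   restarting; strictly inside (0, 1). Default 0.85.
#' @return Named numeric vector of stationary probabilities with
#'   attributes `method = "pagerank"`, `n_input` and `damping`.
#' @export
pagerank_raw <- function(g, input, damping = 0.85) {
  input <- as_input(input, g)
  op <- pagerank_operator(g, damping)
  v <- as.numeric(op$names %in% input$mapped)
  v <- v / sum(v)
  p <- pagerank_solve(op, matrix(v, ncol = 1))[, 1]
  structure(setNames(p, op$names),
            method = "pagerank", n_input = length(input$mapped),
            damping = damping)
}

# Reference power iteration for the same fixed point; used as an
# independent route in tests, never in the main path.
pagerank_power <- function(g, input, damping = 0.85, tol = 1e-12,
                           maxiter = 10000) {
  input <- as_input(input, g)
  up <- upward_view(g)
  n <- igraph::vcount(up)
  A <- igraph::as_adjacency_matrix(up, sparse = TRUE)
  outdeg <- Matrix::rowSums(A)
  dangling <- outdeg == 0
  Wt <- Matrix::t(A / pmax(outdeg, 1))
  v <- as.numeric(igraph::V(up)$name %in% input$mapped)
  v <- v / sum(v)
  p <- v
  for (i in seq_len(maxiter)) {
    pn <- damping * as.numeric(Wt %*% p) +
      damping * sum(p[dangling]) / n + (1 - damping) * v
    if (max(abs(pn - p)) < tol) {
      p <- pn
      break
    }
    p <- pn
  }
  setNames(p, igraph::V(up)$name)
}

# For every pathway, the set of compounds from which it can be reached
# by an upward walk; defines the compound--pathway annotation used by
# the hypergeometric reference test.
pathway_reach <- function(g) {
  up <- upward_view(g)
  pathways <- kg_nodes(g, "pathway")
  compounds <- kg_nodes(g, "compound")
  if (!length(pathways) || !length(compounds)) {
    stop("graph must contain pathway and compound nodes")
  }
  D <- igraph::distances(up, v = pathways, to = compounds, mode = "in")
  reach <- is.finite(D)
  rownames(reach) <- pathways
  colnames(reach) <- compounds
  reach
}

#' Hypergeometric over-representation scores
#'
#' The classical over-representation reference: for each pathway, tests
#' whether the input compounds are enriched among the compounds annotated
#' to that pathway (those with an upward path to it), via the upper-tail
#' hypergeometric probability \eqn{\Pr(X \ge x)} — Fisher's exact test.
#' Only pathway nodes carry scores; the score is already a p-value, so no
#' permutation normalization applies.
#'
#' @inheritParams diffusion_raw
#' @return Named numeric vector over pathway nodes with attributes
#'   `method = "hypergeom"` and `n_input`.
#' @export
hypergeom_scores <- function(g, input) {
  input <- as_input(input, g)
  reach <- pathway_reach(g)
  m <- ncol(reach)                      # total compounds
  n <- length(input$mapped)             # input size
  in_input <- colnames(reach) %in% input$mapped
  m_p <- rowSums(reach)                 # annotated compounds per pathway
  x <- rowSums(reach[, in_input, drop = FALSE])
  # upper tail Pr(X >= x), X ~ Hypergeom(white = m_p, black = m - m_p, n)
  p <- phyper(x - 1, m_p, m - m_p, n, lower.tail = FALSE)
  structure(setNames(pmin(p, 1), rownames(reach)),
            method = "hypergeom", n_input = n)
}

score_method <- function(scores) {
  m <- attr(scores, "method")
  if (is.null(m)) stop("score vector carries no method tag")
  m
}
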