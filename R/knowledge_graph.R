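#' @import Matrix
#' @importFrom stats pnorm phyper setNames
#' @importFrom utils read.delim write.table
NULL

#' The five node levels of the knowledge graph
#'
#' The hierarchical knowledge graph links metabolites to pathways through
#' intermediate biochemical entities. Levels are returned from top to
#' bottom of the hierarchy: pathways sit on top, compounds at the bottom.
#'
#' @return Character vector of the five level names, highest first.
#' @export
#' @examples
#' kg_levels()
kg_levels <- function() {
  c("pathway", "module", "enzyme", "reaction", "compound")
}

# Vertical position: compound = 1 (bottom) ... pathway = 5 (top).
level_height <- function(level) {
  match(level, rev(kg_levels()))
}

#' Construct a knowledge graph
#'
#' Builds the undirected, unweighted heterogeneous graph used by all
#' scoring methods. Nodes belong to one of five levels (see
#' [kg_levels()]); edges must join nodes of two different levels. The
#' object is an `igraph` graph with class `knowledge_graph` prepended;
#' vertex attributes are `name` (the KEGG-style identifier), `level`,
#' `label` and `genes` (semicolon-joined gene identifiers, enzyme nodes
#' only).
#'
#' The constructor checks structural well-formedness (unique ids, known
#' levels, edges referencing declared nodes) and fails on violation.
#' Higher-level invariants (connectedness, cross-level edges, presence of
#' pathway and compound nodes) are reported by [validate_graph()]; use
#' [largest_connected_component()] to reduce a raw build to its largest
#' component.
#'
#' @param nodes data.frame with columns `id`, `level`, and optionally
#'   `label` and `genes` (semicolon-joined string).
#' @param edges data.frame with columns `from`, `to` holding node ids.
#' @param provenance named character vector of free-text metadata
#'   (organism code, source release, build date, ...).
#' @return A `knowledge_graph` object.
#' @export
#' @examples
#' g <- knowledge_graph(
#'   nodes = data.frame(id = c("p1", "r1", "c1"),
#'                      level = c("pathway", "reaction", "compound")),
#'   edges = data.frame(from = c("c1", "r1"), to = c("r1", "p1"))
#' )
#' validate_graph(g)
knowledge_graph <- function(nodes, edges, provenance = character()) {
  stopifnot(is.data.frame(nodes), all(c("id", "level") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$level <- as.character(nodes$level)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad_level <- setdiff(unique(nodes$level), kg_levels())
  if (length(bad_level)) {
    stop("unknown level token(s): ", paste(bad_level, collapse = ", "))
  }
  if (is.null(nodes$label)) nodes$label <- ""
  if (is.null(nodes$genes)) nodes$genes <- ""
  nodes$label[is.na(nodes$label)] <- ""
  nodes$genes[is.na(nodes$genes)] <- ""
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character())
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  undeclared <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(undeclared)) {
    stop("edge references undeclared node(s): ",
         paste(undeclared, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    d = edges,
    vertices = nodes[, c("id", "level", "label", "genes")],
    directed = FALSE
  )
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  class(g) <- c("knowledge_graph", class(g))
  g
}

as_knowledge_graph <- function(g) {
  if (!inherits(g, "knowledge_graph")) {
    class(g) <- c("knowledge_graph", class(g))
  }
  g
}

#' @exportS3Method base::print
print.knowledge_graph <- function(x, ...) {
  lv <- igraph::V(x)$level
  counts <- table(factor(lv, levels = kg_levels()))
  cat("<knowledge_graph> ", igraph::vcount(x), " nodes, ",
      igraph::ecount(x), " edges\n", sep = "")
  cat("  ", paste(sprintf("%s: %d", names(counts), as.integer(counts)),
                  collapse = ", "), "\n", sep = "")
  prov <- kg_provenance(x)
  if (length(prov)) {
    cat("  provenance: ",
        paste(names(prov), prov, sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Graph provenance metadata
#'
#' @param g A `knowledge_graph`.
#' @return Named character vector recorded at build time.
#' @export
kg_provenance <- function(g) {
  prov <- igraph::graph_attr(g, "provenance")
  if (is.null(prov)) character() else prov
}

#' Node ids at a given level
#'
#' @param g A `knowledge_graph`.
#' @param level One of [kg_levels()].
#' @return Character vector of node ids.
#' @export
kg_nodes <- function(g, level = NULL) {
  ids <- igraph::V(g)$name
  if (is.null(level)) return(ids)
  level <- match.arg(level, kg_levels())
  ids[igraph::V(g)$level == level]
}

#' Validate knowledge-graph invariants
#'
#' Checks the structural contract that the scoring methods rely on: the
#' graph is simple (no self-loops or parallel edges), every edge joins
#' two different levels, the graph is connected, and at least one pathway
#' and one compound node exist. Violations are reported, not thrown, so a
#' raw build can be inspected before reduction.
#'
#' @param g A `knowledge_graph`.
#' @return Character vector of human-readable violations; empty if the
#'   graph satisfies all invariants.
#' @export
validate_graph <- function(g) {
  violations <- character()
  lv <- igraph::V(g)$name
  bad_level <- setdiff(unique(igraph::V(g)$level), kg_levels())
  if (length(bad_level)) {
    violations <- c(violations,
                    paste0("unknown level token: ",
                           paste(bad_level, collapse = ", ")))
  }
  loops <- which(igraph::which_loop(g))
  if (length(loops)) {
    el <- igraph::as_edgelist(g)
    violations <- c(violations,
                    paste0("self-loop at node ", el[loops, 1]))
  }
  multi <- which(igraph::which_multiple(g))
  if (length(multi)) {
    el <- igraph::as_edgelist(g)
    violations <- c(violations,
                    paste0("parallel edge {", el[multi, 1], ", ",
                           el[multi, 2], "}"))
  }
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    lev <- setNames(igraph::V(g)$level, igraph::V(g)$name)
    same <- lev[el[, 1]] == lev[el[, 2]]
    same <- same & !igraph::which_loop(g)  # loops already reported
    if (any(same)) {
      violations <- c(violations,
                      paste0("within-level edge {", el[same, 1], ", ",
                             el[same, 2], "}"))
    }
  }
  if (igraph::vcount(g) > 0 && !igraph::is_connected(g)) {
    violations <- c(violations, "graph not connected")
  }
  if (!any(igraph::V(g)$level == "pathway")) {
    violations <- c(violations, "no pathway node")
  }
  if (!any(igraph::V(g)$level == "compound")) {
    violations <- c(violations, "no compound node")
  }
  violations
}

#' Reduce a graph to its largest connected component
#'
#' The grounded heat-diffusion system is only invertible on a connected
#' graph, so builders reduce their raw output with this function. Ties in
#' component size are broken towards the component containing the
#' lexicographically smallest node id, making the reduction deterministic.
#'
#' @param g A `knowledge_graph` (possibly disconnected).
#' @return The induced subgraph on the largest component, as a
#'   `knowledge_graph`.
#' @export
largest_connected_component <- function(g) {
  stopifnot(igraph::vcount(g) >= 1)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest lexicographic node id among tied components wins
    firsts <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(firsts)[1]]
  }
  keep <- which(comp$membership == best)
  sub <- igraph::induced_subgraph(g, keep)
  as_knowledge_graph(sub)
}

#' Upward-directed view of the knowledge graph
#'
#' Orients every undirected edge from the lower level to the higher one
#' (compound is lowest, pathway highest), the direction in which random
#' walks travel for the PageRank scoring. The arc count equals the
#' undirected edge count.
#'
#' @param g A valid `knowledge_graph`.
#' @return A directed `igraph` graph on the same node set.
#' @export
upward_view <- function(g) {
  lev <- setNames(igraph::V(g)$level, igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    h1 <- level_height(lev[el[, 1]])
    h2 <- level_height(lev[el[, 2]])
    if (any(h1 == h2)) {
      stop("within-level edge encountered; graph is invalid")
    }
    swap <- h1 > h2
    el[swap, ] <- el[swap, c(2, 1)]
  }
  nodes <- data.frame(id = igraph::V(g)$name,
                      level = igraph::V(g)$level,
                      label = igraph::V(g)$label,
                      genes = igraph::V(g)$genes,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    d = data.frame(from = el[, 1], to = el[, 2]),
    vertices = nodes, directed = TRUE
  )
}

#' Save and load a knowledge graph
#'
#' On-disk dialect: a directory containing three UTF-8 files —
#' `nodes.tsv` (columns `id`, `level`, `label`, `genes`), `edges.tsv`
#' (columns `from`, `to`) and `provenance.tsv` (columns `key`, `value`).
#' Loading the saved directory reproduces the graph exactly (node set,
#' edge set, levels, labels, genes, provenance).
#'
#' @param g A `knowledge_graph`.
#' @param path Directory to write to / read from (created if missing).
#' @return `save_graph` returns `path` invisibly; `load_graph` returns
#'   the `knowledge_graph`.
#' @export
save_graph <- function(g, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(id = igraph::V(g)$name,
                      level = igraph::V(g)$level,
                      label = igraph::V(g)$label,
                      genes = igraph::V(g)$genes,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      stringsAsFactors = FALSE)
  prov <- kg_provenance(g)
  provdf <- data.frame(key = names(prov), value = as.character(prov),
                       stringsAsFactors = FALSE)
  write_tsv <- function(df, file) {
    write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv(nodes, "nodes.tsv")
  write_tsv(edges, "edges.tsv")
  write_tsv(provdf, "provenance.tsv")
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  read_tsv <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop("missing file: ", f)
    read.delim(f, sep = "\t", header = TRUE, colClasses = "character",
               quote = "", fileEncoding = "UTF-8")
  }
  nodes <- read_tsv("nodes.tsv")
  if (!all(c("id", "level") %in% names(nodes))) {
    stop("nodes.tsv: header must contain 'id' and 'level' (line 1)")
  }
  dup <- which(duplicated(nodes$id))
  if (length(dup)) {
    stop("nodes.tsv: duplicate node id '", nodes$id[dup[1]],
         "' (line ", dup[1] + 1L, ")")
  }
  bad <- which(!(nodes$level %in% kg_levels()))
  if (length(bad)) {
    stop("nodes.tsv: unknown level token '", nodes$level[bad[1]],
         "' (line ", bad[1] + 1L, ")")
  }
  edges <- read_tsv("edges.tsv")
  if (nrow(edges)) {
    miss <- which(!(edges$from %in% nodes$id) | !(edges$to %in% nodes$id))
    if (length(miss)) {
      stop("edges.tsv: edge references undeclared node (line ",
           miss[1] + 1L, ")")
    }
  }
  provdf <- read_tsv("provenance.tsv")
  prov <- setNames(as.character(provdf$value), provdf$key)
  knowledge_graph(nodes, edges, provenance = prov)
}

#' Export a graph to GraphML
#'
#' Writes the graph with `level`, `label` and `genes` vertex attributes
#' for interoperability with Cytoscape and other standard readers.
#'
#' @param g A `knowledge_graph` or plain `igraph` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  gg <- g
  class(gg) <- "igraph"
  # GraphML attributes must be scalars; fold the provenance vector into one
  for (a in igraph::graph_attr_names(gg)) {
    val <- igraph::graph_attr(gg, a)
    if (length(val) != 1L || !is.atomic(val)) {
      gg <- igraph::delete_graph_attr(gg, a)
      if (is.atomic(val) && length(val)) {
        gg <- igraph::set_graph_attr(
          gg, a, paste(names(val), val, sep = "=", collapse = "; "))
      }
    }
  }
  igraph::write_graph(gg, path, format = "graphml")
  invisible(path)
}
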