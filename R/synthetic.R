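#' Generate a random hierarchical knowledge graph
#'
#' Builds a synthetic five-level graph with the same five link families
#' the KEGG builder assembles: pathway--module, pathway--enzyme,
#' module--enzyme, enzyme--reaction and reaction--compound, each drawn
#' as random bipartite edges at a given density. A family touching an
#' empty level is simply skipped (with no modules, pathways still reach
#' enzymes through the direct annotation family). The raw draw is
#' reduced to its largest connected component, so the output always
#' passes [validate_graph()]. Node ids follow the KEGG-like patterns
#' `pw001`, `md001`, `ec001`, `rn001`, `cp001`.
#'
#' Default level sizes follow the proportions of published organism
#' builds (roughly 10 compounds and 14 reactions per pathway, with few
#' modules and a few enzymes per pathway), scaled to a graph of about
#' 450--500 nodes. Default densities keep the upper hierarchy sparse —
#' modules belong to about one pathway, enzymes to at most a few
#' modules/pathways — so that each pathway is reachable from only a
#' minority of compounds, as in the real database. This partial
#' coverage is what makes a planted input set informative.
#'
#' Densities can be given either as per-family probabilities (`p_edge`)
#' or as the mean number of upward links per lower-level node
#' (`mean_degree`), both length 1 or 5 in the family order above.
#'
#' @param pathways,modules,enzymes,reactions,compounds Level sizes.
#' @param p_edge Optional numeric vector (length 1 or 5) of bipartite
#'   edge probabilities per link family.
#' @param mean_degree Mean upward links per lower-level node, per
#'   family; used when `p_edge` is `NULL`.
#' @param seed Integer seed; the build is deterministic given the seed.
#' @return A `knowledge_graph` (largest connected component).
#' @export
#' @examples
#' g <- generate_graph(seed = 1)
#' g
generate_graph <- function(pathways = 16, modules = 10, enzymes = 55,
                           reactions = 240, compounds = 175,
                           p_edge = NULL,
                           mean_degree = c(1.2, 0.6, 0.8, 1.0, 2.2),
                           seed = 1) {
  counts <- c(pathway = pathways, module = modules, enzyme = enzymes,
              reaction = reactions, compound = compounds)
  stopifnot(all(counts >= 0), counts["pathway"] >= 1,
            counts["compound"] >= 1)
  prefix <- c(pathway = "pw", module = "md", enzyme = "ec",
              reaction = "rn", compound = "cp")
  nodes <- do.call(rbind, lapply(kg_levels(), function(lv) {
    n <- counts[[lv]]
    if (n == 0) return(NULL)
    data.frame(id = sprintf("%s%03d", prefix[[lv]], seq_len(n)),
               level = lv,
               label = sprintf("synthetic %s %d", lv, seq_len(n)),
               genes = "",
               stringsAsFactors = FALSE)
  }))
  families <- list(c("pathway", "module"), c("pathway", "enzyme"),
                   c("module", "enzyme"), c("enzyme", "reaction"),
                   c("reaction", "compound"))
  nfam <- length(families)
  if (!is.null(p_edge)) {
    p_fam <- rep_len(p_edge, nfam)
    stopifnot(all(p_fam >= 0), all(p_fam <= 1))
  } else {
    md_fam <- rep_len(mean_degree, nfam)
    stopifnot(all(md_fam >= 0))
  }
  edges <- with_seed(seed, {
    out <- vector("list", nfam)
    for (i in seq_len(nfam)) {
      upper <- nodes$id[nodes$level == families[[i]][1]]
      lower <- nodes$id[nodes$level == families[[i]][2]]
      if (!length(upper) || !length(lower)) next
      p <- if (!is.null(p_edge)) p_fam[i] else
        min(1, md_fam[i] / length(upper))
      pick <- which(stats::runif(length(upper) * length(lower)) < p)
      if (!length(pick)) next
      out[[i]] <- data.frame(
        from = upper[(pick - 1L) %% length(upper) + 1L],
        to = lower[(pick - 1L) %/% length(upper) + 1L],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  raw <- knowledge_graph(nodes, edges,
                         provenance = c(source = "synthetic",
                                        seed = as.character(seed)))
  g <- largest_connected_component(raw)
  lv <- igraph::V(g)$level
  if (!any(lv == "pathway") || !any(lv == "compound")) {
    stop("spec too sparse: largest component lacks a pathway or compound")
  }
  g
}

#' Compounds with an upward path to a pathway
#'
#' @param g A `knowledge_graph`.
#' @param pathway_id A pathway node id.
#' @return Character vector of compound ids that reach the pathway in
#'   the upward-directed view.
#' @export
compounds_under_pathway <- function(g, pathway_id) {
  stopifnot(pathway_id %in% kg_nodes(g, "pathway"))
  reach <- pathway_reach(g)
  colnames(reach)[reach[pathway_id, ]]
}

#' Generate a planted-signal input set
#'
#' Samples an input concentrated under one pathway: a fraction
#' `1 - noise_fraction` of the `n` compounds is drawn from those with an
#' upward path to the planted pathway, and the remainder uniformly from
#' the other compounds. This emulates a coherent biological perturbation
#' (metabolites close to each other in the graph) plus unrelated noise,
#' and is the input model used to check that the enrichment recovers a
#' known signal.
#'
#' @param g A `knowledge_graph`.
#' @param pathway_id Planted pathway id; by default the most specific
#'   pathway that can supply the signal draw (the one reachable from
#'   the fewest compounds among those with at least the required signal
#'   size; ties by id).
#' @param n Input size.
#' @param noise_fraction Fraction of the input drawn off-signal, in
#'   \[0, 1\]. Default 0.
#' @param seed Integer seed.
#' @return Character vector of compound ids with attribute
#'   `planted_pathway`.
#' @export
generate_planted_input <- function(g, pathway_id = NULL, n,
                                   noise_fraction = 0, seed = 1) {
  stopifnot(n >= 1, noise_fraction >= 0, noise_fraction <= 1)
  reach <- pathway_reach(g)
  n_signal <- ceiling((1 - noise_fraction) * n)
  if (is.null(pathway_id)) {
    sizes <- rowSums(reach)
    big_enough <- sizes[sizes >= n_signal]
    if (!length(big_enough)) {
      stop("no pathway is reachable from ", n_signal, " compounds")
    }
    pathway_id <-
      names(big_enough)[order(big_enough, names(big_enough))][1]
  }
  stopifnot(pathway_id %in% rownames(reach))
  under <- colnames(reach)[reach[pathway_id, ]]
  if (length(under) < n_signal) {
    stop("only ", length(under), " compounds reach ", pathway_id,
         " upward; cannot draw ", n_signal, " signal compounds")
  }
  ids <- with_seed(seed, {
    signal <- sample(under, n_signal)
    rest <- setdiff(colnames(reach), signal)
    n_noise <- n - n_signal
    if (n_noise > length(rest)) {
      stop("not enough compounds left for the noise draw")
    }
    noise <- if (n_noise > 0) sample(rest, n_noise) else character()
    c(signal, noise)
  })
  structure(ids, planted_pathway = pathway_id)
}
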