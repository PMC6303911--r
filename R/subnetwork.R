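#' Select the top-ranked nodes
#'
#' Keeps nodes whose p-score does not exceed `threshold`; if more than
#' `nlimit` remain, keeps the `nlimit` best. The full ordering is
#' p-score ascending, then raw score descending, then node id ascending,
#' which makes the cut deterministic under ties.
#'
#' @param pscores Named p-score vector.
#' @param raw Named raw score vector used for tie-breaking (optional;
#'   missing nodes break ties by id alone).
#' @param threshold p-score cutoff in (0, 1]. Default 0.05.
#' @param nlimit Maximum number of reported nodes. Default 250.
#' @return Character vector of selected node ids, in ranking order.
#' @export
select_nodes <- function(pscores, raw = NULL, threshold = 0.05,
                         nlimit = 250) {
  stopifnot(threshold > 0, threshold <= 1, nlimit >= 1)
  ids <- names(pscores)
  r <- if (is.null(raw)) rep(0, length(ids)) else {
    out <- as.numeric(raw[ids])
    out[is.na(out)] <- 0
    out
  }
  keep <- pscores <= threshold
  ord <- order(pscores[keep], -r[keep], ids[keep])
  utils::head(ids[keep][ord], nlimit)
}

#' Null distribution of connected-component sizes
#'
#' For each subgraph size `k` in a grid, samples `reps` uniform `k`-node
#' induced subgraphs and records the order of the largest connected
#' component. The resulting table characterizes how infrequent a
#' component of order at least `r` is when `k` nodes are drawn at
#' random, which the component filter compares against: a meaningful
#' input concentrates near-by nodes and produces larger components than
#' chance.
#'
#' @param g A `knowledge_graph`.
#' @param k_grid Integer grid of subgraph sizes; clipped to the graph
#'   order. Default `c(10, 20, 50, 100, 250, 500)`.
#' @param reps Random subgraphs per grid point. Default 1000.
#' @param seed Integer seed.
#' @return Object of class `nm_cc_null`: list with `k_grid`, `samples`
#'   (one integer vector of max-component orders per `k`), `reps`,
#'   `seed`.
#' @export
build_cc_null_table <- function(g, k_grid = c(10, 20, 50, 100, 250, 500),
                                reps = 1000, seed = 1) {
  stopifnot(reps >= 1)
  nv <- igraph::vcount(g)
  k_grid <- sort(unique(pmin(pmax(as.integer(k_grid), 1L), nv)))
  samples <- with_seed(seed, lapply(k_grid, function(k) {
    vapply(seq_len(reps), function(i) {
      vs <- sample.int(nv, k)
      max(igraph::components(igraph::induced_subgraph(g, vs))$csize)
    }, numeric(1))
  }))
  names(samples) <- as.character(k_grid)
  structure(list(k_grid = k_grid, samples = samples, reps = reps,
                 seed = seed),
            class = "nm_cc_null")
}

#' Empirical tail probability of the largest component
#'
#' `Pr(largest component order >= r)` when `k` nodes are sampled
#' uniformly, read from a [build_cc_null_table()] table. `k` is matched
#' to the nearest grid point (ties towards the smaller); with
#' `interpolate = TRUE` the log-probability is interpolated linearly
#' between the bracketing grid points instead.
#'
#' @param table An `nm_cc_null` table.
#' @param k Subgraph size of interest.
#' @param r Component order.
#' @param interpolate Interpolate between grid points (default FALSE).
#' @return Probability in \[0, 1\].
#' @export
cc_null_prob <- function(table, k, r, interpolate = FALSE) {
  stopifnot(inherits(table, "nm_cc_null"))
  grid <- table$k_grid
  emp <- function(kk) mean(table$samples[[as.character(kk)]] >= r)
  if (k %in% grid) return(emp(k))
  if (!interpolate) {
    nearest <- grid[which.min(abs(grid - k))]
    return(emp(nearest))
  }
  lo <- max(grid[grid <= k], -Inf)
  hi <- min(grid[grid >= k], Inf)
  if (!is.finite(lo) || !is.finite(hi)) {
    stop("grid does not cover k = ", k, " for interpolation")
  }
  plo <- emp(lo)
  phi <- emp(hi)
  if (plo == 0 || phi == 0) {
    w <- (k - lo) / (hi - lo)
    return((1 - w) * plo + w * phi)
  }
  exp(log(plo) + (k - lo) / (hi - lo) * (log(phi) - log(plo)))
}

#' Drop small connected components from a reported sub-network
#'
#' Removes components of the selection whose order is unsurprising under
#' uniform random sampling of the same number of nodes: a component of
#' order `r` is kept only if `Pr(max component >= r | k)` from the null
#' table is at most `alpha_cc`. With `alpha_cc = 1` the filter is the
#' identity.
#'
#' @param g The `knowledge_graph` the selection comes from.
#' @param selected Character vector of selected node ids.
#' @param table An `nm_cc_null` table built on the same graph.
#' @param alpha_cc Tail-probability cutoff, default 0.05.
#' @param interpolate Passed to [cc_null_prob()].
#' @return The filtered character vector of node ids (ranking order
#'   preserved).
#' @export
filter_small_components <- function(g, selected, table, alpha_cc = 0.05,
                                    interpolate = FALSE) {
  if (length(selected) == 0) return(selected)
  sub <- igraph::induced_subgraph(g, selected)
  comp <- igraph::components(sub)
  k <- length(selected)
  keep_comp <- vapply(seq_along(comp$csize), function(ci) {
    cc_null_prob(table, k, comp$csize[ci], interpolate) <= alpha_cc
  }, logical(1))
  keep_ids <- igraph::V(sub)$name[keep_comp[comp$membership]]
  selected[selected %in% keep_ids]
}

#' Tabulate an enrichment result
#'
#' One row per selected node, sorted by p-score ascending (ties: raw
#' score descending, then id).
#'
#' @param res An `nm_enrichment` from [enrich()].
#' @param g The `knowledge_graph` used for the analysis.
#' @return data.frame with columns `id`, `label`, `level`, `raw_score`,
#'   `p_score`.
#' @export
results_table <- function(res, g) {
  ids <- res$selected
  lv <- setNames(igraph::V(g)$level, igraph::V(g)$name)
  lab <- setNames(igraph::V(g)$label, igraph::V(g)$name)
  data.frame(id = ids,
             label = unname(lab[ids]),
             level = unname(lv[ids]),
             raw_score = unname(as.numeric(res$raw[ids])),
             p_score = unname(as.numeric(res$pscores[ids])),
             stringsAsFactors = FALSE)
}

#' Reported enzymes with their gene annotations
#'
#' Restricts the selection to enzyme-level nodes and joins the gene
#' identifiers recorded on the graph. Enzymes without gene annotation
#' keep their row with an empty `genes` field.
#'
#' @inheritParams results_table
#' @return data.frame with columns `ec_number`, `label`, `genes`,
#'   `p_score`.
#' @export
enzymes_table <- function(res, g) {
  tab <- results_table(res, g)
  tab <- tab[tab$level == "enzyme", , drop = FALSE]
  genes <- setNames(igraph::V(g)$genes, igraph::V(g)$name)
  data.frame(ec_number = tab$id,
             label = tab$label,
             genes = unname(genes[tab$id]),
             p_score = tab$p_score,
             stringsAsFactors = FALSE)
}

#' Write an enrichment result to files
#'
#' Writes `results.tsv`, `enzymes.tsv` and `subnetwork.graphml` (the
#' induced subgraph on the selection, with `level`, `label` and
#' `pscore` node attributes) into a directory. Output is deterministic:
#' the same result object always produces byte-identical files.
#'
#' @inheritParams results_table
#' @param path Output directory (created if missing).
#' @param format Either `"tsv"` (tables only), `"graphml"` (sub-network
#'   only) or `"all"` (default).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(res, g, path, format = c("all", "tsv",
                                                    "graphml")) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  fmt_num <- function(x) sprintf("%.10g", x)
  if (format %in% c("all", "tsv")) {
    rt <- results_table(res, g)
    rt$raw_score <- fmt_num(rt$raw_score)
    rt$p_score <- fmt_num(rt$p_score)
    f1 <- file.path(path, "results.tsv")
    write.table(rt, f1, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    et <- enzymes_table(res, g)
    et$p_score <- fmt_num(et$p_score)
    f2 <- file.path(path, "enzymes.tsv")
    write.table(et, f2, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    written <- c(written, f1, f2)
  }
  if (format %in% c("all", "graphml")) {
    sub <- igraph::induced_subgraph(g, res$selected)
    sub <- igraph::set_vertex_attr(
      sub, "pscore", value = as.numeric(res$pscores[igraph::V(sub)$name]))
    sub <- igraph::set_vertex_attr(
      sub, "raw_score", value = as.numeric(res$raw[igraph::V(sub)$name]))
    f3 <- file.path(path, "subnetwork.graphml")
    export_graphml(sub, f3)
    written <- c(written, f3)
  }
  invisible(written)
}

#' Network-based enrichment of a compound list
#'
#' The main entry point: maps the submitted compounds onto the graph,
#' scores every node by the chosen propagation method, normalizes the
#' scores against the permutation null, selects the top-ranked nodes and
#' (optionally) removes connected components no larger than expected by
#' chance.
#'
#' For `method = "hypergeom"` the score is already a p-value, so the
#' `approx` normalization does not apply and only pathway nodes are
#' ranked.
#'
#' @param g A valid `knowledge_graph`.
#' @param compounds Character vector of compound identifiers, or an
#'   `nm_input`.
#' @param method `"diffusion"` (default), `"pagerank"` or
#'   `"hypergeom"`.
#' @param approx Null approximation: `"normality"` (parametric
#'   z-scores, default) or `"simulation"` (Monte Carlo permutations).
#' @param threshold p-score cutoff, default 0.05.
#' @param nlimit Maximum reported nodes, default 250.
#' @param niter Monte Carlo permutations when `approx = "simulation"`,
#'   default 1000.
#' @param damping PageRank damping, default 0.85.
#' @param seed Integer seed for all randomized steps (simulation null,
#'   component-null table), default 1.
#' @param cc_filter Apply the connected-component filter, default FALSE.
#' @param alpha_cc Filter cutoff when `cc_filter = TRUE`, default 0.05.
#' @param cc_table Optional pre-built [build_cc_null_table()] table;
#'   built on the fly (with `seed`) when the filter is on and no table
#'   is supplied.
#' @return Object of class `nm_enrichment`: list with `input`, `raw`,
#'   `pscores`, `selected` (ids in ranking order), `subnetwork`
#'   (induced `igraph`), and `params`.
#' @export
#' @examples
#' g <- generate_graph(seed = 7)
#' inp <- generate_planted_input(g, n = 8, seed = 7)
#' res <- enrich(g, inp)
#' head(results_table(res, g))
enrich <- function(g, compounds,
                   method = c("diffusion", "pagerank", "hypergeom"),
                   approx = c("normality", "simulation"),
                   threshold = 0.05, nlimit = 250, niter = 1000,
                   damping = 0.85, seed = 1, cc_filter = FALSE,
                   alpha_cc = 0.05, cc_table = NULL) {
  method <- match.arg(method)
  approx <- match.arg(approx)
  input <- as_input(compounds, g)
  if (method == "hypergeom") {
    raw <- hypergeom_scores(g, input)
    pscores <- structure(as.numeric(raw), names = names(raw),
                         method = "hypergeom", approx = "exact")
    # the hypergeometric score IS the p-value; rank small-first on both
    tie_raw <- structure(1 - as.numeric(raw), names = names(raw))
  } else {
    raw <- if (method == "diffusion") diffusion_raw(g, input)
           else pagerank_raw(g, input, damping)
    if (approx == "normality") {
      mom <- parametric_moments(g, method, n = length(input$mapped),
                                damping = damping)
      pscores <- zscore_pscores(raw, mom)
    } else {
      pscores <- simulation_pscores(g, raw, niter = niter, seed = seed,
                                    damping = damping)
    }
    tie_raw <- raw
  }
  selected <- select_nodes(pscores, tie_raw, threshold, nlimit)
  if (cc_filter && length(selected)) {
    if (is.null(cc_table)) {
      cc_table <- build_cc_null_table(g, seed = seed)
    }
    selected <- filter_small_components(g, selected, cc_table, alpha_cc)
  }
  raw_full <- setNames(rep(NA_real_, length(pscores)), names(pscores))
  raw_full[names(raw)] <- as.numeric(raw)
  structure(list(
    input = input,
    method = method,
    approx = if (method == "hypergeom") "exact" else approx,
    raw = raw_full,
    pscores = setNames(as.numeric(pscores), names(pscores)),
    selected = selected,
    subnetwork = igraph::induced_subgraph(g, selected),
    params = list(threshold = threshold, nlimit = nlimit, niter = niter,
                  damping = damping, seed = seed, cc_filter = cc_filter,
                  alpha_cc = alpha_cc)
  ), class = "nm_enrichment")
}

#' @exportS3Method base::print
print.nm_enrichment <- function(x, ...) {
  cat("<nm_enrichment> method=", x$method, " approx=", x$approx, "\n",
      sep = "")
  cat("  input: ", length(x$input$mapped), " mapped / ",
      length(x$input$mismatches), " mismatching\n", sep = "")
  cat("  selected: ", length(x$selected), " node(s), threshold ",
      x$params$threshold, ", nlimit ", x$params$nlimit, "\n", sep = "")
  invisible(x)
}
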