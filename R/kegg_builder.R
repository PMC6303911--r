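# --- KEGG REST access with a file cache -------------------------------
#
# Every query is a relative path like "list/pathway/hsa" or
# "link/compound/reaction". With a cache directory the response is read
# from (or written to) a file named after the query with "/" replaced by
# "_", so a complete build can run from pre-fetched tables with zero
# network access.

kegg_fetch <- function(query, cache_dir = NULL,
                       base_url = "https://rest.kegg.jp") {
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, gsub("/", "_", query))
    if (file.exists(f)) {
      return(readLines(f, encoding = "UTF-8", warn = FALSE))
    }
  }
  url <- paste(base_url, query, sep = "/")
  lines <- tryCatch(suppressWarnings(readLines(url, warn = FALSE)),
                    error = function(e) {
                      stop("KEGG query failed (retryable): ", query,
                           " [", conditionMessage(e), "]")
                    })
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(cache_dir, gsub("/", "_", query)))
  }
  lines
}

# KEGG "list"/"link" responses are two-column tab-separated text.
kegg_table <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(V1 = character(), V2 = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(V1 = vapply(parts, `[`, character(1), 1),
             V2 = vapply(parts, function(x) {
               if (length(x) >= 2) x[2] else ""
             }, character(1)),
             stringsAsFactors = FALSE)
}

strip_kegg_prefix <- function(x) {
  sub("^[a-z]+:", "", x)
}

# Global/overview KEGG maps (pathway numbers 011xx and 012xx) describe
# the whole metabolism and would connect everything to everything; they
# are removed before the largest-component reduction.
is_overview_pathway <- function(ids) {
  grepl("(011|012)[0-9]{2}$", ids)
}

#' Build a knowledge graph from KEGG REST data
#'
#' Assembles the five-level knowledge graph for an organism from the
#' KEGG "list" and "link" tabular endpoints: pathway--module,
#' pathway--enzyme, module--enzyme, enzyme--reaction and
#' reaction--compound annotations, restricted to the pathways of the
#' organism. Generalist and overview pathways (map numbers 011xx/012xx)
#' are removed, gene annotations are attached to enzyme nodes from the
#' organism's gene--enzyme link table, and the result is reduced to its
#' largest connected component. The build is a pure function of the
#' fetched tables: rebuilding from the same cache is bit-identical.
#'
#' @param organism 3--4 letter KEGG organism code (e.g. `"hsa"`).
#' @param cache_dir Directory of cached KEGG responses; queries found
#'   there are never fetched from the network (see Details in the
#'   package vignette). With `NULL`, all queries hit the network.
#' @param base_url KEGG REST base URL.
#' @return A `knowledge_graph` with provenance recording the organism
#'   and the KEGG release string.
#' @export
build_graph_from_kegg <- function(organism, cache_dir = NULL,
                                  base_url = "https://rest.kegg.jp") {
  stopifnot(grepl("^[a-z]{3,4}$", organism))
  fetch <- function(q) kegg_table(kegg_fetch(q, cache_dir, base_url))

  info <- kegg_fetch("info/kegg", cache_dir, base_url)
  release <- if (length(info)) {
    sub("^.*Release ", "", grep("Release", info, value = TRUE)[1])
  } else "unknown"

  pw <- fetch(paste0("list/pathway/", organism))
  if (!nrow(pw)) {
    stop("unknown organism or empty pathway list: query 'list/pathway/",
         organism, "'")
  }
  pw$V1 <- strip_kegg_prefix(pw$V1)
  pw <- pw[!is_overview_pathway(pw$V1), , drop = FALSE]
  # organism pathways (hsa00010) correspond to reference maps (map00010)
  pw_num <- sub(paste0("^", organism), "", pw$V1)
  map_of <- setNames(pw$V1, paste0("map", pw_num))

  md <- fetch("list/module")
  ec <- fetch("list/enzyme")
  rn <- fetch("list/reaction")
  cp <- fetch("list/compound")
  for (nm in c("md", "ec", "rn", "cp")) {
    tab <- get(nm)
    tab$V1 <- strip_kegg_prefix(tab$V1)
    assign(nm, tab)
  }

  link <- function(q) {
    tab <- fetch(q)
    tab$V1 <- strip_kegg_prefix(tab$V1)
    tab$V2 <- strip_kegg_prefix(tab$V2)
    tab
  }
  pw_md <- link("link/module/pathway")    # map*/M*
  pw_ec <- link("link/enzyme/pathway")    # map*/EC
  md_ec <- link("link/enzyme/module")     # M*/EC
  ec_rn <- link("link/reaction/enzyme")   # EC/R*
  rn_cp <- link("link/compound/reaction") # R*/C*
  ec_gene <- link(paste0("link/enzyme/", organism))  # gene/EC

  # keep map-level links whose pathway exists for this organism
  pw_md <- pw_md[pw_md$V1 %in% names(map_of), , drop = FALSE]
  pw_ec <- pw_ec[pw_ec$V1 %in% names(map_of), , drop = FALSE]
  pw_md$V1 <- unname(map_of[pw_md$V1])
  pw_ec$V1 <- unname(map_of[pw_ec$V1])

  edges <- rbind(
    data.frame(from = pw_md$V1, to = pw_md$V2),
    data.frame(from = pw_ec$V1, to = pw_ec$V2),
    data.frame(from = md_ec$V1, to = md_ec$V2),
    data.frame(from = ec_rn$V1, to = ec_rn$V2),
    data.frame(from = rn_cp$V1, to = rn_cp$V2)
  )
  edges <- unique(edges)

  label_of <- function(tab) setNames(tab$V2, tab$V1)
  genes_by_ec <- vapply(split(ec_gene$V1, ec_gene$V2),
                        function(x) paste(sort(unique(x)),
                                          collapse = ";"),
                        character(1))
  node_df <- function(ids, level, labels) {
    ids <- sort(unique(ids))
    if (!length(ids)) return(NULL)
    data.frame(id = ids, level = level,
               label = unname(labels[ids]),
               genes = if (level == "enzyme")
                 unname(genes_by_ec[ids]) else "",
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_df(pw$V1, "pathway", label_of(pw)),
    node_df(c(pw_md$V2, md_ec$V1), "module", label_of(md)),
    node_df(c(pw_ec$V2, md_ec$V2, ec_rn$V1), "enzyme", label_of(ec)),
    node_df(c(ec_rn$V2, rn_cp$V1), "reaction", label_of(rn)),
    node_df(rn_cp$V2, "compound", label_of(cp))
  )
  nodes$label[is.na(nodes$label)] <- ""
  nodes$genes[is.na(nodes$genes)] <- ""
  # drop edges whose endpoints did not survive node assembly (e.g. a
  # link naming an entity absent from the list tables)
  edges <- edges[edges$from %in% nodes$id & edges$to %in% nodes$id, ,
                 drop = FALSE]

  raw <- knowledge_graph(
    nodes, edges,
    provenance = c(organism = organism,
                   source = "KEGG REST",
                   release = release)
  )
  largest_connected_component(raw)
}
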