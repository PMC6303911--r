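test_that("select_nodes applies threshold, nlimit and the tie-break", {
  p <- c(a = 0.01, b = 0.20, c = 0.04, d = 1.0)
  raw <- c(a = 5, b = 1, c = 9, d = 0)
  expect_equal(select_nodes(p, raw, threshold = 0.05, nlimit = 10),
               c("a", "c"))
  # all p-scores 1 under a strict threshold: empty selection
  expect_equal(select_nodes(rep(1, 4) |> setNames(letters[1:4]),
                            threshold = 0.05, nlimit = 10),
               character(0))
  # nlimit cuts after sorting
  expect_equal(select_nodes(p, raw, threshold = 1, nlimit = 2),
               c("a", "c"))
  # ties on p-score: larger raw first, then smaller id
  p2 <- c(x = 0.02, y = 0.02, z = 0.02)
  r2 <- c(x = 1, y = 2, z = 2)
  expect_equal(select_nodes(p2, r2, threshold = 0.05, nlimit = 2),
               c("y", "z"))
  expect_equal(select_nodes(p2, r2, threshold = 0.05, nlimit = 3),
               c("y", "z", "x"))
  # monotone: raising the threshold never shrinks the pre-nlimit set
  s1 <- select_nodes(p, raw, threshold = 0.05, nlimit = 100)
  s2 <- select_nodes(p, raw, threshold = 0.5, nlimit = 100)
  expect_true(all(s1 %in% s2))
})

test_that("cc null table matches exhaustive enumeration on tiny graphs", {
  # 4-node path, k = 2: 3 of the 6 pairs are adjacent, Pr(max >= 2) = 0.5
  path4 <- igraph::make_graph(~ a - b - c - d)
  expect_equal(enumerate_cc_tail(path4, 2, 2), 0.5)
  tab <- build_cc_null_table(path4, k_grid = 2, reps = 2000, seed = 5)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(cc_null_prob(tab, 2, 2) - 0.5), 3 * se)
  # Pr(max >= 1) is always 1
  expect_equal(cc_null_prob(tab, 2, 1), 1)

  # complete graph: every sample is one component
  k5 <- igraph::make_full_graph(5)
  tabk <- build_cc_null_table(k5, k_grid = c(2, 3, 4), reps = 500,
                              seed = 1)
  for (k in 2:4) expect_equal(cc_null_prob(tabk, k, k), 1)

  # exhaustive check on a 7-node tree at k = 3 for several orders r
  tree7 <- igraph::make_tree(7, children = 2, mode = "undirected")
  tab7 <- build_cc_null_table(tree7, k_grid = 3, reps = 4000, seed = 2)
  for (r in 1:3) {
    exact <- enumerate_cc_tail(tree7, 3, r)
    se <- sqrt(max(exact * (1 - exact), 1e-6) / 4000)
    expect_lt(abs(cc_null_prob(tab7, 3, r) - exact), 3 * se + 1e-9)
  }
})

test_that("cc table is reproducible given the seed and supports lookup", {
  g <- random_kg(3)
  t1 <- build_cc_null_table(g, k_grid = c(5, 10), reps = 50, seed = 9)
  t2 <- build_cc_null_table(g, k_grid = c(5, 10), reps = 50, seed = 9)
  expect_identical(t1$samples, t2$samples)
  # nearest-k lookup and interpolation both work off-grid
  expect_no_error(cc_null_prob(t1, 7, 2))
  expect_no_error(cc_null_prob(t1, 7, 2, interpolate = TRUE))
  expect_error(cc_null_prob(t1, 12, 2, interpolate = TRUE), "cover")
})

test_that("component filter drops only unsurprising components", {
  # planted line pathway--...--compounds plus isolated extras
  g <- random_kg(21, pathways = 3, modules = 4, enzymes = 10,
                 reactions = 25, compounds = 50)
  tab <- build_cc_null_table(g, k_grid = c(5, 10, 20, 40), reps = 400,
                             seed = 11)
  # take one big connected chunk: a pathway and its neighbourhood
  pw <- kg_nodes(g, "pathway")[1]
  ball <- igraph::ego(g, order = 3, nodes = pw)[[1]]$name
  ball <- utils::head(ball, 12)
  # plus three nodes far from it, ideally isolated in the selection
  rest <- setdiff(kg_nodes(g), ball)
  sel <- c(ball, utils::tail(rest, 3))
  filt <- filter_small_components(g, sel, tab, alpha_cc = 0.05)
  sub <- igraph::induced_subgraph(g, sel)
  comp <- igraph::components(sub)
  big <- igraph::V(sub)$name[comp$membership == which.max(comp$csize)]
  # the dominant component survives whenever it is null-infrequent
  if (cc_null_prob(tab, length(sel), max(comp$csize)) <= 0.05) {
    expect_true(all(big %in% filt))
  }
  # singletons can never be infrequent (Pr(max >= 1) = 1)
  singles <- igraph::V(sub)$name[comp$csize[comp$membership] == 1]
  expect_false(any(singles %in% filt))
  # alpha_cc = 1 keeps everything
  expect_equal(filter_small_components(g, sel, tab, alpha_cc = 1), sel)
  # output components are a subset of input components
  expect_true(all(filt %in% sel))
})

test_that("results and enzymes tables reflect the selection", {
  g <- random_kg(2)
  ecs <- kg_nodes(g, "enzyme")
  g <- as_knowledge_graph(
    igraph::set_vertex_attr(g, "genes", index = ecs[1], value = "gA;gB"))
  inp <- generate_planted_input(g, n = 6, seed = 2)
  res <- enrich(g, inp, threshold = 0.5, nlimit = 40)
  tab <- results_table(res, g)
  expect_equal(nrow(tab), length(res$selected))
  expect_true(!is.unsorted(tab$p_score))
  expect_equal(tab$id[1],
               res$selected[1])
  et <- enzymes_table(res, g)
  expect_setequal(et$ec_number, intersect(res$selected, ecs))
  expect_true(all(et$ec_number %in% ecs))

  # empty selection gives empty tables with the header intact
  res0 <- res
  res0$selected <- character(0)
  expect_equal(nrow(results_table(res0, g)), 0)
  expect_named(results_table(res0, g),
               c("id", "label", "level", "raw_score", "p_score"))
  expect_equal(nrow(enzymes_table(res0, g)), 0)
})

test_that("export_results writes reloadable tsv and graphml", {
  g <- random_kg(6)
  inp <- generate_planted_input(g, n = 6, seed = 6)
  res <- enrich(g, inp, threshold = 0.3)
  dir <- withr::local_tempdir()
  export_results(res, g, dir)
  tab <- read.delim(file.path(dir, "results.tsv"))
  expect_equal(tab$id, results_table(res, g)$id)
  sub <- igraph::read_graph(file.path(dir, "subnetwork.graphml"),
                            format = "graphml")
  expect_setequal(igraph::V(sub)$name, res$selected)
  expect_true(all(c("level", "pscore") %in%
                    igraph::vertex_attr_names(sub)))

  # empty result still writes valid files
  res0 <- res
  res0$selected <- character(0)
  dir0 <- withr::local_tempdir()
  export_results(res0, g, dir0)
  expect_equal(nrow(read.delim(file.path(dir0, "results.tsv"))), 0)
  sub0 <- igraph::read_graph(file.path(dir0, "subnetwork.graphml"),
                             format = "graphml")
  expect_equal(igraph::vcount(sub0), 0)
})

test_that("hypergeom enrichment reports pathway nodes only", {
  g <- random_kg(14)
  inp <- generate_planted_input(g, n = 6, seed = 14)
  res <- enrich(g, inp, method = "hypergeom", threshold = 1, nlimit = 10)
  expect_true(all(res$selected %in% kg_nodes(g, "pathway")))
  tab <- results_table(res, g)
  expect_true(all(tab$level == "pathway"))
  expect_true(all(tab$p_score >= 0 & tab$p_score <= 1))
})
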