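small_cfg <- function(...) {
  base <- list(n_genes = 400, attachment_edges = 3, panel_sizes = c(40, 25, 35),
               n_planted_common = 6, n_pathways = 30,
               pathway_size_range = c(10, 30), n_enriched_pathways = 4,
               module_size = 5, n_samples_per_group = 5, n_de_genes = 60,
               seed = 123)
  do.call(synth_config, utils::modifyList(base, list(...)))
}

test_that("generation is deterministic under the config seed", {
  cfg <- small_cfg()
  s1 <- generate_synthetic_study(cfg)
  s2 <- generate_synthetic_study(cfg)
  expect_identical(igraph::as_edgelist(s1$network), igraph::as_edgelist(s2$network))
  expect_identical(s1$panels, s2$panels)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$truth, s2$truth)
})

test_that("the planted module is a clique anchored inside the network", {
  cfg <- small_cfg()
  net <- generate_network(cfg)
  module <- igraph::graph_attr(net, "module_genes")
  expect_length(module, cfg$module_size)
  for (pair in utils::combn(module, 2, simplify = FALSE)) {
    expect_true(igraph::are_adjacent(net, pair[1], pair[2]))
  }
  anchor <- igraph::graph_attr(net, "anchor_gene")
  expect_true(all(vapply(module, igraph::are_adjacent, logical(1),
                         graph = net, v2 = anchor)))
  expect_true(igraph::is_connected(net))
})

test_that("preferential attachment yields heavy-tailed degrees", {
  for (seed in 1:20) {
    cfg <- synth_config(n_genes = 2000, attachment_edges = 5, seed = seed)
    net <- generate_network(cfg)
    deg <- igraph::degree(net)
    expect_gt(max(deg), 5 * stats::median(deg))
  }
})

test_that("panels intersect in exactly the planted common set", {
  cfg <- small_cfg()
  net <- generate_network(cfg)
  pan <- generate_panels(net, cfg)
  expect_equal(lengths(pan$panels), cfg$panel_sizes, ignore_attr = TRUE)
  expect_setequal(Reduce(intersect, pan$panels), pan$planted_common)
  expect_length(pan$planted_common, cfg$n_planted_common)
  expect_true(igraph::graph_attr(net, "anchor_gene") %in% pan$planted_common)

  cfg0 <- small_cfg(n_planted_common = 0)
  pan0 <- generate_panels(generate_network(cfg0), cfg0)
  expect_length(Reduce(intersect, pan0$panels), 0)
})

test_that("enriched pathways contain the module; components partition pathways", {
  s <- generate_synthetic_study(small_cfg())
  for (id in s$truth$planted_enriched_pathway_ids) {
    expect_true(all(s$truth$planted_module_genes %in% s$pathways[[id]]))
  }
  for (id in names(s$pathways)) {
    members <- unlist(s$components$members[s$components$pathway_id == id])
    expect_setequal(members, s$pathways[[id]])   # covering
    expect_false(anyDuplicated(members) > 0)     # disjoint
  }
  multi <- lengths(s$components$members) > 1
  expect_gt(mean(multi), 0.1)
})

test_that("null pathway overlap with the CFNN is hypergeometric-consistent", {
  cfg <- synth_config(n_genes = 1500, n_pathways = 110,
                      n_enriched_pathways = 10, seed = 5)
  s <- generate_synthetic_study(cfg)
  cfnn <- build_cfnn(s$network, s$truth$planted_common_genes)
  K <- igraph::vcount(cfnn); N <- cfg$n_genes
  nulls <- setdiff(names(s$pathways), s$truth$planted_enriched_pathway_ids)
  k_obs <- vapply(s$pathways[nulls],
                  function(g) length(intersect(g, igraph::V(cfnn)$name)),
                  integer(1))
  m <- lengths(s$pathways[nulls])
  expected <- m * K / N
  v <- m * (K / N) * (1 - K / N) * (N - m) / (N - 1)
  se_mean <- sqrt(sum(v)) / length(nulls)
  expect_lt(abs(mean(k_obs) - mean(expected)), 3 * se_mean)
})

test_that("planted expression shifts match the configured effect", {
  cfg <- small_cfg(n_samples_per_group = 20)
  s <- generate_synthetic_study(cfg)
  ex <- s$expression
  de <- s$truth$planted_de_genes
  diffs <- rowMeans(ex$values[de, ex$groups == "case"]) -
    rowMeans(ex$values[de, ex$groups == "control"])
  bound <- 3 * cfg$noise_sd * sqrt(2 / cfg$n_samples_per_group)
  expect_true(all(abs(diffs - cfg$de_effect) < bound))

  cfg0 <- small_cfg(n_de_genes = 0)
  s0 <- generate_synthetic_study(cfg0)
  expect_length(s0$truth$planted_de_genes, 0)
  grand_diff <- mean(s0$expression$values[, s0$expression$groups == "case"]) -
    mean(s0$expression$values[, s0$expression$groups == "control"])
  expect_lt(abs(grand_diff), 0.05)
})

test_that("ground truth is consistent with the generated objects", {
  s <- generate_synthetic_study(small_cfg())
  nodes <- igraph::V(s$network)$name
  expect_true(all(s$truth$planted_common_genes %in% nodes))
  expect_true(all(s$truth$planted_module_genes %in% nodes))
  expect_true(all(s$truth$planted_de_genes %in% rownames(s$expression$values)))
  expect_true(all(s$truth$planted_enriched_pathway_ids %in% names(s$pathways)))
  expect_true(all(vapply(s$panels, function(p) all(s$truth$planted_common_genes %in% p),
                         logical(1))))
})

test_that("a study round-trips through its plain-text files", {
  s <- generate_synthetic_study(small_cfg())
  dir <- withr::local_tempdir()
  suppressWarnings(write_synthetic_study(s, dir))
  net <- read_edge_list(file.path(dir, "network.tsv"))
  expect_equal(igraph::ecount(net), igraph::ecount(s$network))
  panels <- read_gmt(file.path(dir, "panels.gmt"))
  expect_equal(lapply(panels, sort), lapply(s$panels, sort), ignore_attr = TRUE)
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "design.tsv"))
  expect_equal(expr$values, s$expression$values, tolerance = 1e-10)
})
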