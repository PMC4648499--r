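# Small fixture: a CFNN, a pathway database and an enrichment table marking
# some pathways significant, built by hand so expected matrices are obvious.
make_clust_fixture <- function() {
  cfnn <- gene_network(cbind(c("A", "B", "C"), c("B", "C", "A")))
  pathways <- list(P = c("B", "C", "D"), Q = c("B", "C", "D"), R = c("A", "X"))
  enr <- data.frame(pathway_id = c("P", "Q", "R"),
                    significant = c(TRUE, TRUE, TRUE))
  list(cfnn = cfnn, pathways = pathways, enr = enr)
}

test_that("association matrix marks CFNN genes inside significant pathways", {
  fx <- make_clust_fixture()
  M <- build_association_matrix(fx$cfnn, fx$enr, fx$pathways)
  expect_setequal(rownames(M), c("A", "B", "C"))  # D and X are not in the CFNN
  expect_equal(unname(M[c("B", "C"), "P"]), c(1L, 1L))
  expect_equal(unname(M["A", "P"]), 0L)
  # identical pathways give identical columns
  expect_equal(M[, "P"], M[, "Q"])

  none <- data.frame(pathway_id = "P", significant = FALSE)
  expect_error(build_association_matrix(fx$cfnn, none, fx$pathways),
               "no significant")
})

test_that("cosine distances follow the binary-profile geometry", {
  M <- cbind(P = c(1L, 1L, 0L), Q = c(1L, 0L, 0L), R = c(0L, 0L, 1L),
             S = c(1L, 1L, 0L))
  rownames(M) <- c("a", "b", "c")
  D <- as.matrix(pathway_cosine_distance(M))
  expect_equal(D["P", "S"], 0)            # identical profiles
  expect_equal(D["P", "R"], 1)            # disjoint profiles
  expect_equal(D["P", "Q"], 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D, t(D))

  bad <- cbind(P = c(1L, 0L), Q = c(0L, 0L))
  expect_error(pathway_cosine_distance(bad), "no associated genes")
  expect_error(pathway_cosine_distance(M[, 1, drop = FALSE]), "at least two")
})

test_that("tree cutting groups identical pathways and splits distant ones", {
  M <- cbind(P = c(1L, 1L, 0L), Q = c(1L, 1L, 0L))
  rownames(M) <- letters[1:3]
  cl <- cluster_pathways(pathway_cosine_distance(M), cut_distance = 0.3)
  expect_length(cl, 1)
  expect_setequal(cl[["1"]], c("P", "Q"))

  # orthogonal profiles at distance 1 fall apart at a 0.5 cut
  M2 <- diag(3L); dimnames(M2) <- list(letters[1:3], c("P", "Q", "R"))
  cl2 <- cluster_pathways(pathway_cosine_distance(M2), cut_distance = 0.5)
  expect_length(cl2, 3)
  expect_true(all(lengths(cl2) == 1))
})

test_that("planted two-block structure is recovered exactly", {
  set.seed(12)
  genes <- sprintf("g%02d", 1:40)
  # two groups of 5 pathways sharing genes within-group only
  cols <- c(lapply(1:5, function(i) c(genes[1:12], sample(genes[13:20], 3))),
            lapply(1:5, function(i) c(genes[21:32], sample(genes[33:40], 3))))
  names(cols) <- sprintf("pw%02d", 1:10)
  M <- matrix(0L, 40, 10, dimnames = list(genes, names(cols)))
  for (p in names(cols)) M[cols[[p]], p] <- 1L
  cl <- cluster_pathways(pathway_cosine_distance(M), cut_distance = 0.9)
  expect_length(cl, 2)
  truth <- rep(1:2, each = 5)
  got <- rep(seq_along(cl), lengths(cl))[match(names(cols), unlist(cl))]
  expect_equal(rand_index(truth, got), 1)
})

test_that("clustering is invariant to pathway input order", {
  set.seed(8)
  M <- matrix(rbinom(60, 1, 0.4), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("pw%d", 1:6)))
  M[1, colSums(M) == 0] <- 1L  # no empty profiles
  cl <- cluster_pathways(pathway_cosine_distance(M), cut_distance = 0.7)
  perm <- sample(ncol(M))
  cl2 <- cluster_pathways(pathway_cosine_distance(M[, perm]), cut_distance = 0.7)
  expect_identical(cl, cl2)
})

test_that("common modules intersect member profiles inside the CFNN", {
  fx <- make_clust_fixture()
  M <- build_association_matrix(fx$cfnn, fx$enr, fx$pathways)

  # singleton cluster: common genes are just that pathway's associated genes
  m1 <- extract_common_module("P", M, fx$cfnn)
  expect_setequal(m1$common_genes, c("B", "C"))
  expect_equal(igraph::ecount(m1$subnetwork), 1)

  # disjoint associated genes: an empty module, reported as None
  m2 <- extract_common_module(c("P", "R"), M, fx$cfnn)
  expect_length(m2$common_genes, 0)
  expect_true(is.na(m2$avg_cc))

  expect_error(extract_common_module("ZZ", M, fx$cfnn), "absent")
})

test_that("a planted clique shared by several pathways is recovered intact", {
  clique_genes <- sprintf("m%d", 1:6)
  extra <- sprintf("x%d", 1:6)
  edges <- rbind(t(utils::combn(clique_genes, 2)),
                 cbind(extra, sample(clique_genes, 6, replace = TRUE)))
  cfnn <- gene_network(edges)
  pathways <- lapply(1:4, function(i) c(clique_genes, extra[i]))
  names(pathways) <- sprintf("pw%d", 1:4)
  enr <- data.frame(pathway_id = names(pathways), significant = TRUE)
  M <- build_association_matrix(cfnn, enr, pathways)
  mod <- extract_common_module(names(pathways), M, cfnn)
  expect_setequal(mod$common_genes, clique_genes)
  expect_equal(mod$avg_cc, 1)
  # the module is a subgraph of the CFNN
  el <- igraph::as_edgelist(mod$subnetwork)
  for (i in seq_len(nrow(el))) {
    expect_true(igraph::are_adjacent(cfnn, el[i, 1], el[i, 2]))
  }
})
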