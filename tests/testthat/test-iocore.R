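test_that("edge-list reader drops self-loops and duplicate pairs", {
  f <- withr::local_tempfile(lines = c("A B", "B A", "A A"))
  net <- suppressMessages(read_edge_list(f))
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(igraph::ecount(net), 1)
  expect_message(read_edge_list(f), "1 self-loop.*1 duplicate")
})

test_that("edge-list reader handles TSV, SIF and malformed input", {
  tri <- withr::local_tempfile(lines = c("A\tB", "B\tC", "C\tA"))
  net <- read_edge_list(tri)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 3)

  sif <- withr::local_tempfile(lines = c("A pp B", "B pp C"))
  net2 <- read_edge_list(sif, dialect = "sif")
  expect_equal(igraph::ecount(net2), 2)
  # a 2-column line in a SIF file is malformed, and vice versa
  expect_error(read_edge_list(sif, dialect = "tsv"), "line 1")
  expect_error(read_edge_list(tri, dialect = "sif"), "line 1.*expected 3")

  empty <- withr::local_tempfile(lines = character())
  expect_warning(net3 <- read_edge_list(empty), "no edges")
  expect_equal(igraph::vcount(net3), 0)
})

test_that("edge-list write/read round-trips a network", {
  net <- random_gene_graph(20, 0.2, seed = 4)
  f <- withr::local_tempfile()
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name[igraph::degree(net) > 0])
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(back), key(net))
})

test_that("GMT reader deduplicates genes and rejects structural problems", {
  f <- withr::local_tempfile(lines = "P1\tdesc\tA\tB\tA")
  sets <- read_gmt(f)
  expect_named(sets, "P1")
  expect_setequal(sets$P1, c("A", "B"))

  dup <- withr::local_tempfile(lines = c("P1\td\tA", "P1\td\tB"))
  expect_error(read_gmt(dup), "duplicate.*P1")
  short <- withr::local_tempfile(lines = "P1\tdesc")
  expect_error(read_gmt(short), "3 tab-separated fields")
})

test_that("GMT write/read round-trips sets and descriptions", {
  sets <- list(P1 = c("A", "B"), P2 = c("C", "D", "E"))
  attr(sets, "description") <- c(P1 = "disease", P2 = "functional")
  f <- withr::local_tempfile()
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(lapply(back, sort), lapply(sets[names(back)], sort),
               ignore_attr = TRUE)
  expect_equal(attr(back, "description"), attr(sets, "description"))
})

test_that("expression reader averages duplicate gene rows", {
  ef <- withr::local_tempfile(lines = c(
    "gene\ts1\ts2\ts3\ts4",
    "G\t1\t3\t1\t3",
    "G\t3\t5\t3\t5",
    "H\t0\t0\t0\t0"
  ))
  df <- withr::local_tempfile(lines = c(
    "sample\tgroup", "s1\tcase", "s2\tcase", "s3\tcontrol", "s4\tcontrol"
  ))
  expr <- read_expression(ef, df)
  expect_equal(unname(expr$values["G", ]), c(2, 4, 2, 4))
  expect_equal(nrow(expr$values), 2)
})

test_that("expression reader joins samples and enforces group sizes", {
  ef <- withr::local_tempfile(lines = c(
    "gene\ts1\ts2\ts3\ts4\ts5",
    "G\t1\t2\t3\t4\t5"
  ))
  df <- withr::local_tempfile(lines = c(
    "sample\tgroup", "s1\tcase", "s2\tcase", "s3\tcontrol", "s4\tcontrol", "s6\tcontrol"
  ))
  expect_warning(expr <- read_expression(ef, df), "s5.*s6|s6.*s5")
  expect_setequal(colnames(expr$values), c("s1", "s2", "s3", "s4"))

  one_case <- withr::local_tempfile(lines = c(
    "sample\tgroup", "s1\tcase", "s3\tcontrol", "s4\tcontrol"
  ))
  expect_error(suppressWarnings(read_expression(ef, one_case)), "at least 2")
})

test_that("component table round-trips and validates members", {
  comp <- data.frame(
    component_id = c("c1", "c2"), pathway_id = c("pw1", "pw1"),
    members = I(list(c("CTNNA1", "CTNNA2", "CTNNA3"), "TP53")),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile()
  write_components(comp, f)
  back <- read_components(f)
  expect_equal(back$component_id, comp$component_id)
  expect_equal(unclass(back$members), unclass(comp$members), ignore_attr = TRUE)

  bad <- withr::local_tempfile(lines = c("component_id\tpathway_id\tmembers", "c1\tpw1\t"))
  expect_error(read_components(bad), "at least one member")
})
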