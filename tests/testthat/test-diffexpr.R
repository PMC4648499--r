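test_that("degenerate genes are handled without corrupting the adjustment", {
  mat <- rbind(
    flat = c(2, 2, 2, 2),          # constant everywhere: not testable
    sym  = c(1, 2, 2, 1),          # equal group means: t = 0, p = 1
    real = c(5, 6, 1, 2)
  )
  colnames(mat) <- c("a", "b", "c", "d")
  expr <- expression_set(mat, c("case", "case", "control", "control"))
  res <- de_test(expr)
  expect_false(res$testable[res$gene == "flat"])
  expect_false(res$significant[res$gene == "flat"])
  expect_equal(res$statistic[res$gene == "sym"], 0)
  expect_equal(res$p_raw[res$gene == "sym"], 1)
  # BH runs over the two testable genes only
  expect_equal(sum(!is.na(res$p_adj)), 2)
})

test_that("planted effects are recovered at the closed-form power", {
  n <- 10; effect <- 2; sd <- 1
  fx <- sim_expression(1000, 250, n, effect, sd, seed = 61)
  res <- de_test(fx$expr, alpha = 0.05)
  recovered <- mean(fx$de %in% res$gene[res$significant])

  # oracle: Welch power at the self-consistent BH threshold
  ncp <- effect / (sd * sqrt(2 / n)); df <- 2 * n - 2
  pow <- 0.9
  for (i in 1:50) {
    a <- 0.05 * (250 * pow) / 1000
    crit <- stats::qt(1 - a / 2, df)
    pow <- 1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
  expect_gt(recovered, 0.9)
  expect_lt(abs(recovered - pow), 0.05)

  # false positives among the 750 null genes stay within the FDR budget
  fp <- mean(res$significant[!res$gene %in% fx$de])
  expect_lt(fp, 0.05)
})

test_that("DEG union combines datasets and warns when empty", {
  r1 <- data.frame(gene = c("a", "b", "c"), significant = c(TRUE, TRUE, FALSE))
  r2 <- data.frame(gene = c("b", "c", "d"), significant = c(TRUE, FALSE, TRUE))
  expect_setequal(union_deg(list(r1, r2)), c("a", "b", "d"))
  expect_setequal(union_deg(list(r1)), c("a", "b"))
  none <- data.frame(gene = "a", significant = FALSE)
  expect_warning(u <- union_deg(list(none)), "no significant")
  expect_length(u, 0)
})

test_that("a multi-protein component is hit by any of its members", {
  comp <- data.frame(
    component_id = c("alpha_catenin", "p53", "gsk"),
    pathway_id = c("adherens", "adherens", "wnt"),
    members = I(list(c("CTNNA1", "CTNNA2", "CTNNA3"), "TP53", "GSK3B")),
    stringsAsFactors = FALSE
  )
  expect_equal(count_de_components(c("CTNNA2", "XYZ"), comp, "adherens"), 1)
  expect_equal(count_de_components(c("CTNNA2", "TP53"), comp, "adherens"), 2)
  expect_equal(count_de_components("NOPE", comp, "adherens"), 0)
  expect_error(count_de_components("TP53", comp, "unknown_pw"), "unknown_pw")

  singles <- data.frame(component_id = c("c1", "c2"), pathway_id = "pw",
                        members = I(list("A", "B")), stringsAsFactors = FALSE)
  expect_equal(count_de_components(c("A", "B"), singles, "pw"), 2)
})

test_that("component permutation p-values hit their boundary cases", {
  universe <- sprintf("u%03d", 1:60)
  comp <- data.frame(
    component_id = sprintf("c%d", 1:5), pathway_id = "pw",
    members = I(split(universe[1:10], rep(1:5, each = 2))),
    stringsAsFactors = FALSE
  )
  # nothing observed: every replicate count is >= 0
  r0 <- component_permutation_test(character(0), universe, comp, "pw",
                                   n_replicates = 50, seed = 3)
  expect_equal(r0$observed_hits, 0)
  expect_equal(r0$permutation$p_empirical, 1)

  # saturated draw: every replicate hits every hittable component
  rs <- component_permutation_test(universe, universe, comp, "pw",
                                   n_replicates = 50, seed = 3)
  expect_equal(rs$observed_hits, 5)
  expect_equal(rs$permutation$p_empirical, 1)
})

test_that("a DEG set concentrated in one pathway's components is significant", {
  set.seed(77)
  universe <- sprintf("u%04d", 1:2000)
  members <- split(universe[1:90], rep(1:30, each = 3))
  comp <- data.frame(component_id = sprintf("c%02d", 1:30), pathway_id = "pw",
                     members = I(members), stringsAsFactors = FALSE)
  deg <- c(universe[seq(1, 90, by = 3)], sample(universe[500:2000], 30))
  res <- component_permutation_test(deg, universe, comp, "pw",
                                    n_replicates = 500, seed = 19)
  expect_equal(res$observed_hits, 30)
  expect_lt(res$permutation$p_empirical, 0.05)
  rerun <- component_permutation_test(deg, universe, comp, "pw",
                                      n_replicates = 500, seed = 19)
  expect_identical(res, rerun)
})
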