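# Two-group differential expression and the multi-protein-component
# permutation test used to evaluate enriched pathways against expression
# data.

#' Per-gene two-group differential expression test
#'
#' Welch two-sample t-test on log-scale expression values, gene by gene,
#' followed by Benjamini-Hochberg adjustment. Genes with zero variance in
#' both groups carry no usable signal; they are marked non-testable and
#' excluded from the BH denominator rather than assigned p = 1, keeping the
#' adjustment honest. Inputs are assumed already normalized (the package
#' does no array preprocessing).
#'
#' @param expr an [expression_set()].
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return Data frame with one row per gene: `gene`, `effect`
#'   (mean case - mean control, log units), `statistic` (Welch t), `p_raw`,
#'   `p_adj`, `significant`, `testable`.
#' @export
de_test <- function(expr, alpha = 0.05) {
  stopifnot(inherits(expr, "expr_set"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  X1 <- expr$values[, expr$groups == "case", drop = FALSE]
  X2 <- expr$values[, expr$groups == "control", drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples", call. = FALSE)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  testable <- se2 > 0
  tstat <- ifelse(testable, (m1 - m2) / sqrt(se2), NA_real_)
  df <- ifelse(testable,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  p_raw <- ifelse(testable, 2 * stats::pt(abs(tstat), df, lower.tail = FALSE), NA_real_)
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[testable] <- bh_adjust(p_raw[testable])
  data.frame(
    gene = rownames(expr$values),
    effect = m1 - m2,
    statistic = tstat,
    p_raw = p_raw,
    p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha,
    testable = testable,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Union of significant genes across datasets
#'
#' Combines differentially expressed genes from several expression datasets
#' of the same contrast (e.g. four case/control cohorts of one disease) into
#' a single panel.
#'
#' @param results list of [de_test()] result data frames.
#' @return Character vector of genes significant in at least one dataset;
#'   warns when empty.
#' @export
union_deg <- function(results) {
  if (!is.list(results) || length(results) == 0) {
    stop("`results` must be a non-empty list of de_test() results", call. = FALSE)
  }
  deg <- sort(unique(unlist(lapply(results, function(r) r$gene[r$significant]))))
  if (length(deg) == 0) warning("no significant genes in any dataset", call. = FALSE)
  deg
}

#' Count differentially expressed components of a pathway
#'
#' A pathway component counts as differentially expressed as soon as any of
#' its member proteins is in the differentially expressed gene set (so a
#' multi-protein component such as an alpha-Catenin node is hit by any of
#' CTNNA1/2/3).
#'
#' @param deg character vector of differentially expressed genes.
#' @param components component table from [read_components()].
#' @param pathway_id pathway whose components to count.
#' @return Integer: the number of hit components.
#' @export
count_de_components <- function(deg, components, pathway_id) {
  comp <- components[components$pathway_id == pathway_id, , drop = FALSE]
  if (nrow(comp) == 0) {
    stop(sprintf("no components defined for pathway '%s'", pathway_id), call. = FALSE)
  }
  sum(vapply(comp$members, function(m) any(m %in% deg), logical(1)))
}

#' Permutation test for the number of differentially expressed components
#'
#' Each replicate draws a gene set of the same size as the observed
#' differentially expressed set, uniformly without replacement from the
#' universe (by default the genes measured on the array), and counts the
#' pathway components hit. The upper-tail empirical p-value uses the add-one
#' rule `(n_at_least + 1) / (n_replicates + 1)`.
#'
#' @param deg character vector of observed differentially expressed genes.
#' @param universe character vector of genes to draw null sets from.
#' @param components component table from [read_components()].
#' @param pathway_id pathway whose components to test.
#' @param n_replicates number of null replicates (conventionally 1e4).
#' @param seed RNG seed.
#' @return List of class `"component_test"` with elements `pathway_id`,
#'   `n_components`, `observed_hits` and `permutation` (a `"perm_test"`).
#' @export
component_permutation_test <- function(deg, universe, components, pathway_id,
                                       n_replicates = 10000, seed = 1) {
  universe <- unique(as.character(universe))
  deg <- unique(as.character(deg))
  if (length(deg) > length(universe)) {
    stop("the differentially expressed set cannot exceed the universe", call. = FALSE)
  }
  comp <- components[components$pathway_id == pathway_id, , drop = FALSE]
  if (nrow(comp) == 0) {
    stop(sprintf("no components defined for pathway '%s'", pathway_id), call. = FALSE)
  }
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1)
  observed <- count_de_components(deg, comp, pathway_id)
  # gene -> component index lookup (components partition the pathway)
  comp_of <- stats::setNames(rep(seq_len(nrow(comp)), lengths(comp$members)),
                             unlist(comp$members))
  deg_size <- length(deg)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      d <- universe[sample.int(length(universe), deg_size)]
      idx <- comp_of[d]
      length(unique(idx[!is.na(idx)]))
    }, integer(1))
  })
  n_at_least <- sum(null_counts >= observed)
  perm <- structure(list(
    observed = observed,
    n_replicates = n_replicates,
    n_at_least = n_at_least,
    p_empirical = (n_at_least + 1) / (n_replicates + 1),
    p_parametric = NULL,
    parametric_family = NULL,
    null_mean = mean(null_counts),
    seed = as.integer(seed)
  ), class = "perm_test")
  structure(list(
    pathway_id = pathway_id,
    n_components = nrow(comp),
    observed_hits = observed,
    permutation = perm
  ), class = "component_test")
}

#' @export
print.component_test <- function(x, ...) {
  cat(sprintf("Component test for pathway '%s': %d/%d components hit, p = %.4g (%d replicates)\n",
              x$pathway_id, x$observed_hits, x$n_components,
              x$permutation$p_empirical, x$permutation$n_replicates))
  invisible(x)
}
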