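# Pathway enrichment: two-sided hypergeometric tests with
# Benjamini-Hochberg correction across a pathway database.

#' Two-sided hypergeometric test
#'
#' Tests whether the overlap `k` between a query gene list of size `n` and a
#' pathway of size `m`, inside a universe of `N` genes, is larger (enrichment)
#' or smaller (depletion) than expected under Hypergeometric(N, m, n). The
#' two-sided p-value doubles the smaller of the upper tail `P(X >= k)` and
#' the lower tail `P(X <= k)`, capped at 1 -- a transparent convention that
#' can be checked against exhaustive enumeration. Direction is `"enriched"`
#' when `k >= n*m/N` (ties count as enriched), `"depleted"` otherwise.
#'
#' All four arguments are vectorized.
#'
#' @param k overlap count(s).
#' @param m pathway size(s) within the universe.
#' @param n query size(s) within the universe.
#' @param N universe size(s).
#' @return Data frame with columns `p_raw` and `direction`.
#' @export
hypergeom_two_sided <- function(k, m, n, N) {
  if (any(k < 0 | m < 0 | n < 0 | N < 0) ||
      any(k != floor(k) | m != floor(m) | n != floor(n) | N != floor(N))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(m > N) || any(n > N) || any(k > pmin(m, n)) || any(k < pmax(0, m + n - N))) {
    stop("inconsistent counts: need max(0, m+n-N) <= k <= min(m, n) and m, n <= N",
         call. = FALSE)
  }
  upper <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  lower <- stats::phyper(k, m, N - m, n)
  data.frame(
    p_raw = pmin(1, 2 * pmin(upper, lower)),
    direction = ifelse(k >= m * n / N, "enriched", "depleted"),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement, preserving
#' input order. Raw p-values outside (0, 1] are rejected rather than
#' silently clamped.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pathway enrichment of a gene list
#'
#' Tests every pathway with at least one gene in the universe for enrichment
#' or depletion of the query list, using [hypergeom_two_sided()], then
#' applies [bh_adjust()] across all tested pathways. Zero-overlap pathways
#' are still tested (they can be significantly depleted). The default
#' universe is the set of genes annotated to at least one pathway in the
#' database; pass the network's gene set (or any custom list) to change the
#' reference population.
#'
#' @param query character vector of gene identifiers (e.g. CFNN nodes).
#' @param pathways named list of pathway gene vectors, as from [read_gmt()];
#'   a `"description"` attribute, when present, is carried through as the
#'   `category` column.
#' @param universe optional character vector of gene identifiers; defaults to
#'   all genes annotated in `pathways`.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return Data frame with one row per tested pathway -- columns
#'   `pathway_id`, `category`, `k`, `m`, `n`, `N`, `p_raw`, `direction`,
#'   `p_adj`, `significant` -- sorted by `p_adj` then `pathway_id`.
#' @export
enrich_pathways <- function(query, pathways, universe = NULL, alpha = 0.05) {
  if (length(query) == 0) stop("`query` must be non-empty", call. = FALSE)
  if (length(pathways) == 0 || is.null(names(pathways))) {
    stop("`pathways` must be a non-empty named list", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  universe <- unique(as.character(universe %||% unlist(pathways, use.names = FALSE)))
  query_u <- intersect(unique(as.character(query)), universe)
  if (length(query_u) == 0) {
    stop("no query gene lies in the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query_u)
  genes_u <- lapply(pathways, intersect, universe)
  tested <- which(lengths(genes_u) > 0)
  if (length(tested) == 0) stop("no pathway has genes in the universe", call. = FALSE)
  m <- lengths(genes_u)[tested]
  k <- vapply(genes_u[tested], function(g) length(intersect(g, query_u)), integer(1))
  ht <- hypergeom_two_sided(k, m, n, N)
  desc <- attr(pathways, "description")
  out <- data.frame(
    pathway_id = names(pathways)[tested],
    category = if (is.null(desc)) NA_character_ else unname(desc[names(pathways)[tested]]),
    k = k, m = unname(m), n = n, N = N,
    p_raw = ht$p_raw, direction = ht$direction,
    p_adj = bh_adjust(ht$p_raw),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
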