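# Common susceptibility genes, their permutation significance, and
# construction of the common-gene first-neighbor network (CFNN).

#' Intersect disease gene panels
#'
#' @param panels list (length >= 2) of character gene vectors.
#' @return Character vector of genes present in every panel; a warning is
#'   raised when the intersection is empty (downstream stages cannot run).
#' @export
intersect_panels <- function(panels) {
  if (!is.list(panels) || length(panels) < 2) {
    stop("`panels` must be a list of at least two gene panels", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(panels, unique))
  if (length(common) == 0) {
    warning("panels share no common genes", call. = FALSE)
  }
  sort(common)
}

#' Permutation test for the size of a multi-panel intersection
#'
#' Each replicate draws panels of the given sizes uniformly without
#' replacement (independently of one another) from the gene universe --
#' normally the interaction network's gene set -- and records the size of
#' their intersection. The empirical p-value uses the add-one rule
#' `(n_at_least + 1) / (n_replicates + 1)`, which cannot reach zero. Because
#' the resolution of the empirical estimate is bounded by the replicate
#' count, a parametric companion p-value is also reported: a Poisson
#' distribution (a natural model for rare-overlap counts) is fitted to the
#' null intersection sizes and its upper tail evaluated at the observed
#' value. The family choice is flagged in the result.
#'
#' @param universe character vector of gene identifiers to draw from.
#' @param sizes integer vector of panel sizes, each at most `length(universe)`.
#' @param observed observed intersection size.
#' @param n_replicates number of null replicates (conventionally 1e4).
#' @param seed RNG seed; the same seed reproduces the result bit for bit.
#' @return List of class `"perm_test"` with elements `observed`,
#'   `n_replicates`, `n_at_least`, `p_empirical`, `p_parametric`,
#'   `parametric_family`, `null_mean` and `seed`.
#' @export
overlap_permutation_test <- function(universe, sizes, observed,
                                     n_replicates = 10000, seed = 1) {
  universe <- unique(as.character(universe))
  n_univ <- length(universe)
  sizes <- vapply(sizes, check_count, integer(1), arg = "sizes", min = 1)
  if (any(sizes > n_univ)) {
    stop("panel sizes cannot exceed the universe size", call. = FALSE)
  }
  observed <- check_count(observed, "observed")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1)
  k <- length(sizes)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      draws <- unlist(lapply(sizes, function(s) sample.int(n_univ, s)))
      sum(tabulate(draws, nbins = n_univ) == k)
    }, integer(1))
  })
  n_at_least <- sum(null_counts >= observed)
  lambda <- mean(null_counts)
  p_par <- if (observed == 0) 1 else stats::ppois(observed - 1, lambda, lower.tail = FALSE)
  structure(list(
    observed = observed,
    n_replicates = n_replicates,
    n_at_least = n_at_least,
    p_empirical = (n_at_least + 1) / (n_replicates + 1),
    p_parametric = p_par,
    parametric_family = "poisson",
    null_mean = lambda,
    seed = as.integer(seed)
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed = %d, %d/%d null replicates >= observed\n",
              x$observed, x$n_at_least, x$n_replicates))
  cat(sprintf("  p (empirical, add-one)  = %.4g\n", x$p_empirical))
  if (!is.null(x$p_parametric)) {
    cat(sprintf("  p (parametric, %s; null mean %.3g) = %.4g\n",
                x$parametric_family, x$null_mean, x$p_parametric))
  }
  invisible(x)
}

#' Build the common-gene first-neighbor network (CFNN)
#'
#' The CFNN contains the common susceptibility genes present in the network
#' together with all of their direct interaction partners, and every network
#' edge between the kept genes (induced-subgraph semantics, so
#' neighbor-neighbor edges are included). Isolated common genes have no
#' neighborhood and are excluded with a warning.
#'
#' @param net gene network.
#' @param common character vector of common susceptibility genes.
#' @return A gene network in which every node is a common gene or adjacent to
#'   at least one common gene; the common genes are recorded in the graph
#'   attribute `"common_genes"`.
#' @export
build_cfnn <- function(net, common) {
  check_gene_network(net)
  present <- intersect(unique(as.character(common)), igraph::V(net)$name)
  if (length(present) == 0) {
    stop("no common gene is present in the network", call. = FALSE)
  }
  iso <- present[igraph::degree(net, present) == 0]
  if (length(iso) > 0) {
    warning(sprintf("excluding %d isolated common gene(s): %s",
                    length(iso), paste(iso, collapse = ", ")), call. = FALSE)
    present <- setdiff(present, iso)
    if (length(present) == 0) {
      stop("every common gene is isolated in the network", call. = FALSE)
    }
  }
  nb_idx <- unique(unlist(igraph::adjacent_vertices(net, present)))
  nb <- igraph::V(net)$name[nb_idx]
  cfnn <- induced_network(net, union(present, nb))
  cfnn <- igraph::set_graph_attr(cfnn, "common_genes", present)
  cfnn
}
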