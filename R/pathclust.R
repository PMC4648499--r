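# Clustering of enriched pathways by shared associated genes, and
# extraction of common modules from the CFNN.

#' Binary associated gene-pathway matrix
#'
#' "Associated genes" are the genes present in both the CFNN and at least
#' one significantly enriched pathway. The matrix has one row per associated
#' gene and one column per significant pathway, with entry 1 when the gene
#' belongs to that pathway. Significant pathways without any associated gene
#' (possible for significantly depleted pathways) carry no clustering signal
#' and are dropped with a message.
#'
#' @param cfnn the common-gene first-neighbor network.
#' @param enrichment enrichment table from [enrich_pathways()].
#' @param pathways the pathway database the enrichment was computed on.
#' @return Binary integer matrix with gene identifiers as rownames and
#'   pathway identifiers as colnames.
#' @export
build_association_matrix <- function(cfnn, enrichment, pathways) {
  check_gene_network(cfnn, "cfnn")
  sig <- enrichment$pathway_id[enrichment$significant]
  if (length(sig) == 0) stop("no significant pathway to build the matrix from",
                             call. = FALSE)
  nodes <- igraph::V(cfnn)$name
  assoc <- lapply(pathways[sig], intersect, nodes)
  empty <- lengths(assoc) == 0
  if (any(empty)) {
    message(sprintf("build_association_matrix: dropping %d significant pathway(s) with no associated genes",
                    sum(empty)))
    assoc <- assoc[!empty]
  }
  genes <- sort(unique(unlist(assoc)))
  if (length(genes) == 0) stop("no associated genes: CFNN and significant pathways are disjoint",
                               call. = FALSE)
  M <- matrix(0L, nrow = length(genes), ncol = length(assoc),
              dimnames = list(genes, names(assoc)))
  for (p in names(assoc)) M[assoc[[p]], p] <- 1L
  M
}

#' Cosine distances between pathways' associated-gene profiles
#'
#' Distance between two pathways is `1 - cosine similarity` of their binary
#' associated-gene columns (raw 0/1 values, no weighting). Identical profiles
#' are at distance 0, disjoint ones at distance 1.
#'
#' @param matrix binary matrix from [build_association_matrix()].
#' @return A [stats::dist] object over the pathways.
#' @export
pathway_cosine_distance <- function(matrix) {
  if (ncol(matrix) < 2) stop("need at least two pathways to compute distances",
                             call. = FALSE)
  nrm <- sqrt(colSums(matrix^2))
  if (any(nrm == 0)) {
    stop(sprintf("pathway column(s) with no associated genes: %s",
                 paste(colnames(matrix)[nrm == 0], collapse = ", ")), call. = FALSE)
  }
  S <- crossprod(matrix) / outer(nrm, nrm)
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  stats::as.dist(D)
}

#' Agglomerative clustering of pathways
#'
#' Hierarchical clustering of the pathway distance matrix, cut at a fixed
#' height. With average (or complete) linkage on cosine distances all merge
#' heights lie in `[0, 1]`, so the default cut is 0.9; Ward linkage produces
#' heights above 1 and accommodates the conventional cut of 1.1. Cluster
#' identifiers are assigned by the lexicographically smallest member pathway,
#' so numbering is deterministic and independent of input order.
#'
#' @param distances a [stats::dist] over pathways, e.g. from
#'   [pathway_cosine_distance()].
#' @param cut_distance tree cut height (> 0).
#' @param linkage `"average"`, `"complete"` or `"ward"` (ward.D2).
#' @return List of character vectors of pathway identifiers, one per cluster
#'   (singletons allowed), names `"1"`, `"2"`, ...
#' @export
cluster_pathways <- function(distances, cut_distance = 0.9,
                             linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (!is.numeric(cut_distance) || cut_distance <= 0) {
    stop("`cut_distance` must be > 0", call. = FALSE)
  }
  labels <- attr(distances, "Labels")
  n <- attr(distances, "Size")
  if (n < 2) {
    return(stats::setNames(list(sort(labels)), "1"))
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(distances, method = method)
  member <- stats::cutree(hc, h = cut_distance)
  groups <- split(names(member), member)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, character(1), 1L))]
  stats::setNames(groups, as.character(seq_along(groups)))
}

#' Extract the common module of a pathway cluster
#'
#' The cluster's common associated genes are the intersection of its member
#' pathways' associated-gene sets; their induced subnetwork within the CFNN
#' is the cluster's common module. When the intersection is empty the module
#' is empty and its average clustering coefficient is `NA` (reported as
#' "None").
#'
#' @param members character vector of pathway identifiers (a cluster).
#' @param matrix association matrix from [build_association_matrix()].
#' @param cfnn the CFNN the matrix was built against.
#' @param cluster_id optional identifier stored in the result.
#' @return Object of class `"common_module"`: list with `cluster_id`,
#'   `pathways`, `common_genes`, `subnetwork` and `avg_cc`.
#' @export
extract_common_module <- function(members, matrix, cfnn, cluster_id = NA_integer_) {
  if (length(members) == 0) stop("`members` must be non-empty", call. = FALSE)
  missing <- setdiff(members, colnames(matrix))
  if (length(missing) > 0) {
    stop(sprintf("pathway(s) absent from association matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sub <- matrix[, members, drop = FALSE]
  common <- rownames(matrix)[rowSums(sub) == length(members)]
  subnet <- induced_network(cfnn, common)
  avg_cc <- if (length(common) > 0) avg_clustering_coefficient(subnet) else NA_real_
  structure(list(
    cluster_id = cluster_id,
    pathways = sort(members),
    common_genes = sort(common),
    subnetwork = subnet,
    avg_cc = avg_cc
  ), class = "common_module")
}

#' @export
print.common_module <- function(x, ...) {
  cat(sprintf("Common module (cluster %s): %d pathway(s), %d common gene(s)\n",
              as.character(x$cluster_id), length(x$pathways), length(x$common_genes)))
  if (length(x$common_genes) > 0) {
    cat(sprintf("  subnetwork: %d nodes, %d edges; avg clustering coefficient %.3f\n",
                igraph::vcount(x$subnetwork), igraph::ecount(x$subnetwork), x$avg_cc))
  } else {
    cat("  no common associated genes (module: None)\n")
  }
  invisible(x)
}

#' Extract common modules for every cluster
#'
#' @param clusters list of pathway-id vectors from [cluster_pathways()].
#' @param matrix association matrix.
#' @param cfnn the CFNN.
#' @return List of [extract_common_module()] results, one per cluster.
#' @export
extract_common_modules <- function(clusters, matrix, cfnn) {
  out <- lapply(seq_along(clusters), function(i) {
    extract_common_module(clusters[[i]], matrix, cfnn, cluster_id = i)
  })
  stats::setNames(out, names(clusters))
}
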