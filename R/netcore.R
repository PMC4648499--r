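# Graph primitives shared by the propagation, overlap and module stages.

#' Column-normalized adjacency matrix
#'
#' Builds the column-stochastic transition matrix W of the random walk:
#' entry (i, j) is 1/degree(j) when genes i and j interact and 0 otherwise,
#' so each column over a non-isolated gene is a probability distribution over
#' its neighbors. Columns of isolated genes are left all-zero and their
#' identifiers reported via a message; the walk itself refuses isolated
#' seeds (see [make_restart_vector()]).
#'
#' @param net gene network.
#' @return Sparse [Matrix][Matrix::Matrix-class] with gene identifiers as
#'   dimnames.
#' @export
column_normalize <- function(net) {
  check_gene_network(net)
  if (igraph::vcount(net) == 0) stop("network is empty", call. = FALSE)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- Matrix::colSums(A)
  isolated <- colnames(A)[deg == 0]
  if (length(isolated) > 0) {
    message(sprintf("column_normalize: %d isolated node(s) have all-zero columns: %s",
                    length(isolated),
                    paste(utils::head(isolated, 5), collapse = ", ")))
  }
  W <- A %*% Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0))
  dimnames(W) <- dimnames(A)
  W
}

#' Induced subnetwork on a set of genes
#'
#' Keeps the genes in `keep` that are present in the network together with
#' every edge whose two endpoints are both kept.
#'
#' @param net gene network.
#' @param keep character vector of gene identifiers.
#' @return The induced gene network (possibly empty).
#' @export
induced_network <- function(net, keep) {
  check_gene_network(net)
  igraph::induced_subgraph(net, intersect(igraph::V(net)$name, keep))
}

#' Average clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient (the fraction of a
#' node's neighbor pairs that are themselves connected). Nodes of degree < 2
#' have no neighbor pairs and contribute 0 to the mean rather than being
#' excluded, so the statistic is defined on every non-empty graph.
#'
#' @param net non-empty gene network.
#' @return A number in `[0, 1]`.
#' @export
avg_clustering_coefficient <- function(net) {
  check_gene_network(net)
  if (igraph::vcount(net) == 0) stop("average clustering coefficient of an empty graph is undefined",
                                     call. = FALSE)
  cc <- igraph::transitivity(net, type = "local", vids = igraph::V(net))
  cc[is.nan(cc)] <- 0
  mean(cc)
}
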