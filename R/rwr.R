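# Random walk with restart: network propagation used to expand an
# under-annotated susceptibility gene panel through the interaction network.

#' Random-walk-with-restart configuration
#'
#' The walker moves to a uniformly chosen interaction partner with
#' probability `1 - gamma` and restarts at the seed genes with probability
#' `gamma` at every step. The fixed point of
#' `p[t+1] = (1 - gamma) * W %*% p[t] + gamma * p0`
#' ranks every gene by proximity to the seeds. `gamma = 0.75` is the
#' standard choice for disease-gene prioritization; `top_k = 400` is the
#' conventional expanded-panel size.
#'
#' @param gamma restart probability in (0, 1].
#' @param tolerance L1 convergence threshold of the power iteration. The
#'   iteration is a contraction with factor `1 - gamma`, so convergence to
#'   `1e-10` takes only a few dozen iterations at `gamma = 0.75`.
#' @param max_iter iteration cap.
#' @param top_k number of genes (seeds included) kept by [rank_and_select()].
#' @return A list of class `"rwr_config"`.
#' @export
rwr_config <- function(gamma = 0.75, tolerance = 1e-10, max_iter = 1e5, top_k = 400) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0 || gamma > 1) {
    stop("`gamma` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(tolerance) || tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  max_iter <- check_count(max_iter, "max_iter", min = 1)
  top_k <- check_count(top_k, "top_k", min = 1)
  structure(list(gamma = gamma, tolerance = tolerance,
                 max_iter = max_iter, top_k = top_k),
            class = "rwr_config")
}

#' Restart probability vector over the network's genes
#'
#' Distributes unit restart mass equally over the seed genes; every other
#' gene gets 0. Seeds must be present in the network and non-isolated
#' (an isolated seed cannot take part in the walk).
#'
#' @param net gene network.
#' @param seeds character vector of seed gene identifiers.
#' @return Named numeric vector over all network genes, summing to 1.
#' @export
make_restart_vector <- function(net, seeds) {
  check_gene_network(net)
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("`seeds` must be non-empty", call. = FALSE)
  nodes <- igraph::V(net)$name
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0) {
    stop(sprintf("seed gene(s) absent from network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  iso <- seeds[igraph::degree(net, seeds) == 0]
  if (length(iso) > 0) {
    stop(sprintf("seed gene(s) isolated in network: %s",
                 paste(iso, collapse = ", ")), call. = FALSE)
  }
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  p0
}

#' Propagate a restart vector to its steady state
#'
#' Power iteration of `p[t+1] = (1 - gamma) * W %*% p[t] + gamma * p0` on the
#' non-isolated part of the network, stopping when the L1 change falls below
#' `cfg$tolerance`. Isolated nodes cannot carry walk mass and are removed
#' first (with a message when any are dropped); the restart vector must have
#' all of its support on the remaining part. Every iterate, and hence the
#' result, sums to 1.
#'
#' @param net gene network.
#' @param p0 restart vector from [make_restart_vector()] (a named numeric
#'   probability vector over the network's genes).
#' @param cfg an [rwr_config()].
#' @return Named numeric steady-state probability vector over the
#'   non-isolated genes, with attributes `iterations` (number of updates),
#'   `residual` (final L1 change), `iter_sums` (total mass after each
#'   update, for conservation diagnostics) and `iter_residuals` (the L1
#'   change at each update; a contraction, so non-increasing after the
#'   first step).
#' @export
rwr_propagate <- function(net, p0, cfg = rwr_config()) {
  check_gene_network(net)
  stopifnot(inherits(cfg, "rwr_config"))
  nodes <- igraph::V(net)$name
  if (!all(names(p0) %in% nodes)) {
    stop("`p0` names must be network genes", call. = FALSE)
  }
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-10) {
    stop("`p0` must be a probability vector (non-negative, summing to 1)",
         call. = FALSE)
  }
  keep <- nodes[igraph::degree(net) > 0]
  dropped <- setdiff(nodes, keep)
  if (length(dropped) > 0) {
    message(sprintf("rwr_propagate: excluding %d isolated node(s) from the walk",
                    length(dropped)))
  }
  if (any(p0[setdiff(names(p0), keep)] > 0)) {
    stop("restart vector places mass on isolated nodes", call. = FALSE)
  }
  sub <- induced_network(net, keep)
  W <- column_normalize(sub)
  ord <- colnames(W)
  p0k <- stats::setNames(numeric(length(ord)), ord)
  p0k[intersect(names(p0), ord)] <- p0[intersect(names(p0), ord)]
  p <- p0k
  sums <- numeric(0)
  residuals <- numeric(0)
  res <- Inf
  for (it in seq_len(cfg$max_iter)) {
    p_new <- (1 - cfg$gamma) * as.numeric(W %*% p) + cfg$gamma * p0k
    res <- sum(abs(p_new - p))
    p <- stats::setNames(p_new, ord)
    sums <- c(sums, sum(p))
    residuals <- c(residuals, res)
    if (res < cfg$tolerance) {
      attr(p, "iterations") <- it
      attr(p, "residual") <- res
      attr(p, "iter_sums") <- sums
      attr(p, "iter_residuals") <- residuals
      return(p)
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (last L1 residual %.3g)",
               cfg$max_iter, res), call. = FALSE)
}

#' Rank genes by steady-state probability and keep the top k
#'
#' Genes are sorted by descending probability with ties broken by
#' lexicographic gene identifier, so the selection is deterministic. Seeds
#' retain restart mass and are expected -- but not forced -- to rank inside
#' the top `top_k`; a warning names any seed that falls outside.
#'
#' @param p named probability vector (e.g. from [rwr_propagate()]).
#' @param seeds seed gene identifiers used for the walk.
#' @param cfg an [rwr_config()]; only `top_k` is used.
#' @return Character vector of the `top_k` gene identifiers, best first.
#' @export
rank_and_select <- function(p, seeds, cfg = rwr_config()) {
  stopifnot(inherits(cfg, "rwr_config"))
  if (cfg$top_k > length(p)) {
    stop(sprintf("top_k (%d) exceeds the number of ranked genes (%d)",
                 cfg$top_k, length(p)), call. = FALSE)
  }
  ord <- order(-p, names(p))
  top <- names(p)[ord][seq_len(cfg$top_k)]
  left_out <- setdiff(intersect(seeds, names(p)), top)
  if (length(left_out) > 0) {
    warning(sprintf("seed gene(s) outside the top %d: %s", cfg$top_k,
                    paste(left_out, collapse = ", ")), call. = FALSE)
  }
  top
}

#' Expand a susceptibility panel by random walk with restart
#'
#' Convenience wrapper: builds the restart vector, propagates it to the
#' steady state and keeps the top-ranked genes (seeds included).
#'
#' @param net gene network.
#' @param seeds seed gene identifiers.
#' @param cfg an [rwr_config()].
#' @return List with `panel` (the selected gene identifiers) and `scores`
#'   (the full steady-state vector).
#' @export
rwr_expand <- function(net, seeds, cfg = rwr_config()) {
  p0 <- make_restart_vector(net, seeds)
  p <- rwr_propagate(net, p0, cfg)
  list(panel = rank_and_select(p, seeds, cfg), scores = p)
}
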