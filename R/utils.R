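# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. All stochastic operations in the package route
# through this so that a seed in a config reproduces a run bit for bit.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Validate that `net` is an undirected igraph with unique vertex names.
check_gene_network <- function(net, arg = "net") {
  if (!igraph::is_igraph(net)) {
    stop(sprintf("`%s` must be an igraph object (see gene_network())", arg),
         call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop(sprintf("`%s` must be undirected", arg), call. = FALSE)
  }
  nm <- igraph::V(net)$name
  if (igraph::vcount(net) > 0 && (is.null(nm) || anyDuplicated(nm))) {
    stop(sprintf("`%s` must have unique vertex names (gene identifiers)", arg),
         call. = FALSE)
  }
  invisible(net)
}

check_count <- function(x, arg, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", arg, min), call. = FALSE)
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
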