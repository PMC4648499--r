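# Independent oracles and small fixture builders used across the suite.
# Every oracle is deliberately naive (enumeration, dense linear algebra,
# textbook definitions) and shares no code with the implementation paths
# it checks.

# Evaluate code under a fixed seed, restoring the caller's RNG stream.
with_seed_test <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Erdos-Renyi gene graph with named vertices; optionally resampled until
# connected (for walk oracles).
random_gene_graph <- function(n, p, seed, connected = FALSE) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
    if (!connected || igraph::is_connected(g)) return(g)
  }
}

# Average clustering coefficient by brute-force triangle enumeration.
brute_avg_cc <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::adjacent_vertices(net, nodes), names)
  names(adj) <- nodes
  cc <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    tri <- sum(apply(pairs, 2, function(pr) pr[2] %in% adj[[pr[1]]]))
    tri / ncol(pairs)
  }, numeric(1))
  mean(cc)
}

# Steady state of the restart walk by dense linear solve:
# p = gamma * (I - (1 - gamma) W)^{-1} p0.
dense_rwr_solve <- function(net, p0, gamma) {
  W <- as.matrix(crosspath::column_normalize(net))
  ord <- colnames(W)
  b <- stats::setNames(numeric(length(ord)), ord)
  b[names(p0)] <- p0
  x <- solve(diag(length(ord)) - (1 - gamma) * W, gamma * b)
  stats::setNames(as.numeric(x), ord)
}

# Two-sided hypergeometric p by exhaustive summation of the pmf computed
# from binomial coefficients.
enum_hyper_two_sided <- function(k, m, n, N) {
  support <- max(0, m + n - N):min(m, n)
  pmf <- choose(m, support) * choose(N - m, n - support) / choose(N, n)
  upper <- sum(pmf[support >= k])
  lower <- sum(pmf[support <= k])
  min(1, 2 * min(upper, lower))
}

# Benjamini-Hochberg by the step-up definition: adjusted p at rank i is
# min over j >= i of p_(j) * m / j, capped at 1, mapped back to input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Rand index between two flat clusterings given as membership vectors.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

# Small deterministic expression fixture: n_genes x (2 * n) matrix with the
# first n_de genes shifted by `effect` in the case group.
sim_expression <- function(n_genes, n_de, n, effect, sd = 1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  mat <- matrix(stats::rnorm(n_genes * 2 * n, 0, sd), nrow = n_genes,
                dimnames = list(genes, c(sprintf("ca%02d", 1:n), sprintf("co%02d", 1:n))))
  groups <- c(rep("case", n), rep("control", n))
  if (n_de > 0) mat[seq_len(n_de), groups == "case"] <-
    mat[seq_len(n_de), groups == "case"] + effect
  list(expr = crosspath::expression_set(mat, groups), de = genes[seq_len(n_de)])
}
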