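# Domain types and file readers/writers.
#
# Gene identifiers are opaque, case-sensitive strings throughout: mapping
# between protein and gene namespaces (or between databases) is the caller's
# job and must happen before files reach this package.

#' Construct a gene interaction network
#'
#' A gene network is an undirected simple [igraph][igraph::igraph-package]
#' graph whose vertex names are gene identifiers. The same representation is
#' used for the full interaction network, for the common-gene first-neighbor
#' network (CFNN) and for extracted modules. Self-loops and duplicate
#' (unordered) edges are dropped.
#'
#' @param edges two-column character matrix or data frame of edge endpoints,
#'   or `NULL` for an edgeless graph.
#' @param nodes character vector of gene identifiers to include even when
#'   isolated; the final node set is the union of `nodes` and edge endpoints.
#' @return An undirected simple igraph object with named vertices.
#' @examples
#' net <- gene_network(cbind(c("A", "B"), c("B", "C")))
#' igraph::vcount(net)
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("`edges` must have exactly two columns", call. = FALSE)
    storage.mode(edges) <- "character"
    keep <- edges[, 1L] != edges[, 2L]
    edges <- edges[keep, , drop = FALSE]
  }
  all_nodes <- unique(c(as.character(nodes %||% character()), as.vector(edges)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read an interaction network from an edge-list or SIF file
#'
#' Lines are whitespace-separated. The TSV dialect expects two columns
#' (gene, gene); the SIF dialect expects three, with the middle interaction-
#' type column ignored. Self-loops and duplicate unordered pairs are dropped
#' silently with a message reporting the count.
#'
#' @param path file to read.
#' @param dialect `"tsv"` (two columns) or `"sif"` (three columns).
#' @return A gene network (see [gene_network()]).
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    warning(sprintf("'%s' contains no edges; returning an empty network", path),
            call. = FALSE)
    return(gene_network())
  }
  fields <- strsplit(trimws(lines[nonblank]), "[ \t]+")
  want <- if (dialect == "tsv") 2L else 3L
  bad <- which(lengths(fields) != want)
  if (length(bad) > 0) {
    stop(sprintf("line %d of '%s': expected %d fields, found %d",
                 nonblank[bad[1L]], path, want, lengths(fields)[bad[1L]]),
         call. = FALSE)
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), want)
  n_loops <- sum(from == to)
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  n_dup <- sum(duplicated(key[from != to]))
  if (n_loops + n_dup > 0) {
    message(sprintf("read_edge_list: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dup))
  }
  gene_network(cbind(from, to))
}

#' Write a network as a two-column edge list
#'
#' @param net gene network.
#' @param path output file.
#' @return `path`, invisibly. Isolated nodes are not representable in an
#'   edge list and are omitted with a warning.
#' @export
write_edge_list <- function(net, path) {
  check_gene_network(net)
  n_iso <- sum(igraph::degree(net) == 0)
  if (n_iso > 0) {
    warning(sprintf("%d isolated node(s) cannot be written to an edge list", n_iso),
            call. = FALSE)
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a line are deduplicated. The same reader serves disease
#' susceptibility panels and pathway databases; for pathways the description
#' field conventionally carries the category (e.g. disease vs functional).
#'
#' @param path GMT file.
#' @return Named list of character gene vectors, with a `"description"`
#'   attribute (named character vector) preserving the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    stop(sprintf("line %d of '%s': a GMT line needs at least 3 tab-separated fields",
                 bad[1L], path), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene-set name in '%s': %s",
                 path, ids[duplicated(ids)][1L]), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character gene vectors.
#' @param path output file.
#' @param description optional named character vector of per-set descriptions;
#'   defaults to the `"description"` attribute of `sets`, or the set names.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must be a uniquely named list", call. = FALSE)
  }
  description <- description %||% attr(sets, "description") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, unname(description[[id]]) %||% id, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read pathway component definitions
#'
#' A pathway diagram node ("component") stands for one protein or for a small
#' family of interchangeable proteins (a multi-protein component, e.g. an
#' alpha-Catenin node covering CTNNA1/2/3). The file is a header-bearing TSV
#' with columns `component_id`, `pathway_id`, `members` (comma-separated gene
#' identifiers).
#'
#' @param path component TSV.
#' @return Data frame with columns `component_id`, `pathway_id` and list
#'   column `members`.
#' @export
read_components <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("component_id", "pathway_id", "members")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' must have columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  ms <- as.character(df$members)
  ms[is.na(df$members)] <- ""
  members <- lapply(strsplit(ms, ",", fixed = TRUE),
                    function(m) unique(trimws(m[nzchar(trimws(m))])))
  if (any(lengths(members) == 0)) {
    stop(sprintf("'%s': every component needs at least one member gene", path),
         call. = FALSE)
  }
  if (anyDuplicated(df$component_id)) {
    stop(sprintf("duplicate component_id in '%s': %s", path,
                 df$component_id[duplicated(df$component_id)][1L]), call. = FALSE)
  }
  data.frame(component_id = df$component_id, pathway_id = df$pathway_id,
             members = I(members), stringsAsFactors = FALSE)
}

#' Write pathway component definitions
#'
#' @param components data frame as returned by [read_components()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_components <- function(components, path) {
  out <- data.frame(
    component_id = components$component_id,
    pathway_id = components$pathway_id,
    members = vapply(components$members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a two-group expression set
#'
#' @param values numeric matrix of log-scale expression values, genes in rows
#'   (rownames are gene identifiers), samples in columns.
#' @param groups character or factor of per-sample labels, each `"case"` or
#'   `"control"`, aligned with the columns of `values`.
#' @return An object of class `"expr_set"`: a list with elements `values` and
#'   `groups`.
#' @export
expression_set <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` needs gene identifiers as rownames",
                                      call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("`groups` must have one label per sample column", call. = FALSE)
  }
  if (!all(groups %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  if (min(table(factor(groups, levels = c("case", "control")))) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  structure(list(values = values, groups = groups), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Read an expression matrix and its two-group design
#'
#' The expression TSV has a header row of sample identifiers and a first
#' column of gene identifiers; the design TSV has columns `sample` and
#' `group` (`case`/`control`). Samples are restricted to those present in
#' both files (dropped samples produce a warning). Duplicate gene rows --
#' e.g. several probe sets mapping to one gene -- are mean-averaged.
#'
#' @param path expression TSV.
#' @param design_path design TSV.
#' @return An [expression_set()].
#' @export
read_expression <- function(path, design_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop(sprintf("'%s' has no sample columns", path), call. = FALSE)
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(design))) {
    stop(sprintf("'%s' must have columns sample, group", design_path), call. = FALSE)
  }
  shared <- intersect(colnames(mat), design$sample)
  lost <- setdiff(union(colnames(mat), design$sample), shared)
  if (length(lost) > 0) {
    warning(sprintf("dropping %d sample(s) absent from matrix or design: %s",
                    length(lost), paste(lost, collapse = ", ")), call. = FALSE)
  }
  mat <- mat[, shared, drop = FALSE]
  groups <- design$group[match(shared, design$sample)]
  if (anyDuplicated(genes)) {
    mat <- rowsum(mat, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(mat) <- unique(genes)
  } else {
    rownames(mat) <- genes
  }
  expression_set(mat, groups)
}

#' Write an expression set as TSV plus design file
#'
#' @param expr an [expression_set()].
#' @param path expression TSV to write.
#' @param design_path design TSV to write.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, design_path) {
  stopifnot(inherits(expr, "expr_set"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(expr$values), group = expr$groups),
    design_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a one-gene-per-line list
#'
#' @param path text file with one gene identifier per line.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
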