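# Orchestration of the full workflow: panel expansion, common genes and
# their significance, CFNN, enrichment, pathway clustering with module
# extraction, and optional expression-based evaluation. Every stage writes
# its artifacts as plain files so any stage can be inspected or re-run
# independently.

#' Pipeline configuration
#'
#' Inputs may be given as in-memory objects (a gene network, named lists of
#' gene vectors, an [expression_set()], a component data frame) or as file
#' paths, which are read with the package's readers ([read_edge_list()],
#' [read_gmt()], [read_components()], [read_expression()]).
#'
#' @param network interaction network (igraph) or edge-list path.
#' @param panels named list of gene panels or GMT path (>= 2 panels).
#' @param pathways named list of pathway gene sets or GMT path.
#' @param components optional component table or TSV path.
#' @param expression optional [expression_set()] or expression TSV path.
#' @param design design TSV path (required when `expression` is a path).
#' @param expand_panel optional name of one panel to expand by random walk
#'   with restart before intersection (for a panel too small to intersect
#'   directly, as with an under-annotated disease).
#' @param rwr an [rwr_config()] for the expansion.
#' @param n_replicates permutation replicates for the overlap and component
#'   tests.
#' @param seed master seed; stage-level seeds are derived from it.
#' @param alpha adjusted-p threshold for pathway enrichment.
#' @param universe optional enrichment universe (default: annotated genes).
#' @param cut_distance tree cut height for pathway clustering.
#' @param linkage clustering linkage (`"average"`, `"complete"`, `"ward"`).
#' @param de_alpha adjusted-p threshold for differential expression.
#' @param component_pathways pathway identifiers to run the component
#'   permutation test on (requires `components` and `expression`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(network, panels, pathways,
                            components = NULL, expression = NULL, design = NULL,
                            expand_panel = NULL, rwr = rwr_config(),
                            n_replicates = 10000, seed = 1,
                            alpha = 0.05, universe = NULL,
                            cut_distance = 0.9,
                            linkage = c("average", "complete", "ward"),
                            de_alpha = 0.05, component_pathways = NULL) {
  structure(list(
    network = network, panels = panels, pathways = pathways,
    components = components, expression = expression, design = design,
    expand_panel = expand_panel, rwr = rwr,
    n_replicates = check_count(n_replicates, "n_replicates", min = 1),
    seed = check_count(seed, "seed"),
    alpha = alpha, universe = universe,
    cut_distance = cut_distance, linkage = match.arg(linkage),
    de_alpha = de_alpha, component_pathways = component_pathways
  ), class = "pipeline_config")
}

#' Pipeline configuration from a YAML file
#'
#' Reads a YAML mapping whose keys mirror the arguments of
#' [pipeline_config()], with inputs given as file paths (relative paths are
#' resolved against the YAML file's directory). Nested `rwr:` keys
#' (`gamma`, `tolerance`, `max_iter`, `top_k`) configure the expansion.
#'
#' @param path YAML file.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  rwr <- do.call(rwr_config, y$rwr %||% list())
  pipeline_config(
    network = resolve(y$network), panels = resolve(y$panels),
    pathways = resolve(y$pathways), components = resolve(y$components),
    expression = resolve(y$expression), design = resolve(y$design),
    expand_panel = y$expand_panel, rwr = rwr,
    n_replicates = y$n_replicates %||% 10000, seed = y$seed %||% 1,
    alpha = y$alpha %||% 0.05, universe = y$universe,
    cut_distance = y$cut_distance %||% 0.9, linkage = y$linkage %||% "average",
    de_alpha = y$de_alpha %||% 0.05, component_pathways = y$component_pathways
  )
}

resolve_inputs <- function(cfg) {
  net <- if (is.character(cfg$network)) read_edge_list(cfg$network) else cfg$network
  check_gene_network(net, "network")
  panels <- if (is.character(cfg$panels)) read_gmt(cfg$panels) else cfg$panels
  pathways <- if (is.character(cfg$pathways)) read_gmt(cfg$pathways) else cfg$pathways
  components <- if (is.character(cfg$components)) read_components(cfg$components) else cfg$components
  expr <- cfg$expression
  if (is.character(expr)) {
    if (is.null(cfg$design)) stop("`design` path is required with an expression path",
                                  call. = FALSE)
    expr <- read_expression(expr, cfg$design)
  }
  list(network = net, panels = panels, pathways = pathways,
       components = components, expression = expr)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full shared-pathway pipeline
#'
#' Executes, in order: optional random-walk expansion of one panel, panel
#' intersection with its overlap permutation test, CFNN construction,
#' pathway enrichment, pathway clustering with common-module extraction,
#' and (when expression data are provided) differential expression with
#' component permutation tests. Every stage's artifacts are written to
#' `out_dir` as plain TSV/JSON files, together with a `manifest.json`
#' recording parameters, seeds and stage tallies. The run aborts with a
#' clear message if the panels share no common genes.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of class `"crosspath_run"` with the in-memory
#'   stage results (`common`, `overlap_test`, `cfnn`, `enrichment`,
#'   `clusters`, `modules`, `de`, `component_tests`, `out_dir`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    parameters = list(
      seed = cfg$seed, n_replicates = cfg$n_replicates,
      alpha = cfg$alpha, cut_distance = cfg$cut_distance,
      linkage = cfg$linkage, de_alpha = cfg$de_alpha,
      rwr_gamma = cfg$rwr$gamma, rwr_top_k = cfg$rwr$top_k,
      expand_panel = cfg$expand_panel %||% NA
    ),
    stages = list()
  )
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = ", ")))
  }

  inp <- resolve_inputs(cfg)
  net <- inp$network
  panels <- inp$panels
  note("load", n_genes = igraph::vcount(net), n_interactions = igraph::ecount(net),
       n_panels = length(panels), n_pathways = length(inp$pathways))

  if (!is.null(cfg$expand_panel)) {
    if (!cfg$expand_panel %in% names(panels)) {
      stop(sprintf("expand_panel '%s' is not a panel", cfg$expand_panel), call. = FALSE)
    }
    seeds <- panels[[cfg$expand_panel]]
    usable <- intersect(seeds, igraph::V(net)$name[igraph::degree(net) > 0])
    if (length(usable) < length(seeds)) {
      warning(sprintf("expansion: dropping %d seed(s) absent or isolated in the network",
                      length(seeds) - length(usable)), call. = FALSE)
    }
    exp <- rwr_expand(net, usable, cfg$rwr)
    ranking <- data.frame(gene = names(sort(exp$scores, decreasing = TRUE)),
                          score = as.numeric(sort(exp$scores, decreasing = TRUE)))
    write_tsv(ranking, file.path(out_dir, "rwr_ranking.tsv"))
    panels[[cfg$expand_panel]] <- exp$panel
    write_gmt(panels[cfg$expand_panel], file.path(out_dir, "expanded_panel.gmt"))
    note("expand", panel = cfg$expand_panel, n_seeds = length(usable),
         top_k = cfg$rwr$top_k)
  }

  common <- intersect_panels(panels)
  writeLines(common, file.path(out_dir, "common_genes.txt"))
  perm <- overlap_permutation_test(
    universe = igraph::V(net)$name, sizes = lengths(panels),
    observed = length(common), n_replicates = cfg$n_replicates,
    seed = cfg$seed
  )
  jsonlite::write_json(unclass(perm), file.path(out_dir, "overlap_test.json"),
                       auto_unbox = TRUE, digits = NA)
  note("overlap", n_common = length(common),
       p_empirical = perm$p_empirical, p_parametric = perm$p_parametric)
  if (length(common) == 0) {
    stop("pipeline aborted: the panels share no common genes, so the CFNN cannot be built",
         call. = FALSE)
  }

  cfnn <- build_cfnn(net, common)
  write_edge_list(cfnn, file.path(out_dir, "cfnn_edges.tsv"))
  cfnn_cc <- avg_clustering_coefficient(cfnn)
  note("cfnn", n_nodes = igraph::vcount(cfnn), n_edges = igraph::ecount(cfnn),
       avg_cc = cfnn_cc)

  enr <- enrich_pathways(igraph::V(cfnn)$name, inp$pathways,
                         universe = cfg$universe, alpha = cfg$alpha)
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  note("enrich", n_tested = nrow(enr), n_significant = sum(enr$significant))

  clusters <- NULL
  modules <- NULL
  if (sum(enr$significant) > 0) {
    M <- tryCatch(build_association_matrix(cfnn, enr, inp$pathways),
                  error = function(e) NULL)
    if (!is.null(M)) {
      clusters <- if (ncol(M) >= 2) {
        cluster_pathways(pathway_cosine_distance(M),
                         cut_distance = cfg$cut_distance, linkage = cfg$linkage)
      } else {
        stats::setNames(list(colnames(M)), "1")
      }
      modules <- extract_common_modules(clusters, M, cfnn)
      membership <- data.frame(
        pathway_id = unlist(clusters, use.names = FALSE),
        cluster_id = rep(names(clusters), lengths(clusters))
      )
      write_tsv(membership, file.path(out_dir, "clusters.tsv"))
      summary_df <- data.frame(
        cluster_id = names(clusters),
        n_pathways = lengths(clusters),
        n_common_genes = vapply(modules, function(m) length(m$common_genes), integer(1)),
        avg_cc = vapply(modules, function(m) m$avg_cc, numeric(1))
      )
      write_tsv(summary_df, file.path(out_dir, "modules.tsv"))
      for (m in modules) {
        if (length(m$common_genes) > 0 && igraph::ecount(m$subnetwork) > 0) {
          write_edge_list(m$subnetwork,
                          file.path(out_dir, sprintf("module_%s_edges.tsv", m$cluster_id)))
        }
      }
      note("cluster", n_associated_genes = nrow(M), n_clusters = length(clusters))
    } else {
      note("cluster", n_associated_genes = 0, n_clusters = 0)
    }
  } else {
    note("cluster", n_associated_genes = 0, n_clusters = 0)
  }

  de <- NULL
  comp_tests <- NULL
  if (!is.null(inp$expression)) {
    de <- de_test(inp$expression, alpha = cfg$de_alpha)
    write_tsv(de, file.path(out_dir, "de_results.tsv"))
    deg <- de$gene[de$significant]
    note("diffexpr", n_tested = sum(de$testable), n_significant = length(deg))
    if (!is.null(inp$components) && length(cfg$component_pathways) > 0) {
      comp_tests <- lapply(seq_along(cfg$component_pathways), function(i) {
        component_permutation_test(
          deg, universe = rownames(inp$expression$values),
          components = inp$components, pathway_id = cfg$component_pathways[i],
          n_replicates = cfg$n_replicates, seed = cfg$seed + i
        )
      })
      names(comp_tests) <- cfg$component_pathways
      jsonlite::write_json(
        lapply(comp_tests, function(x) {
          list(pathway_id = x$pathway_id, n_components = x$n_components,
               observed_hits = x$observed_hits,
               p_empirical = x$permutation$p_empirical,
               n_replicates = x$permutation$n_replicates,
               seed = x$permutation$seed)
        }),
        file.path(out_dir, "component_tests.json"), auto_unbox = TRUE, digits = NA
      )
      note("components", n_pathways_tested = length(comp_tests))
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(list(
    common = common, overlap_test = perm, cfnn = cfnn, enrichment = enr,
    clusters = clusters, modules = modules, de = de,
    component_tests = comp_tests, out_dir = out_dir
  ), class = "crosspath_run"))
}

#' Summarize a pipeline run directory
#'
#' Builds a one-page key/value report from the stored artifacts, flagging
#' stages that did not run, and writes it as `summary.tsv` alongside them.
#' Network statistics are recomputed from the stored edge lists, so the
#' report is self-consistent with the artifacts rather than with transient
#' in-memory state.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Data frame with columns `field` and `value`.
#' @export
summarize_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no manifest.json in '%s'", run_dir), call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  rows <- list()
  add <- function(field, value) rows[[length(rows) + 1L]] <<- data.frame(
    field = field, value = as.character(value), stringsAsFactors = FALSE)

  add("seed", manifest$parameters$seed)
  common_path <- file.path(run_dir, "common_genes.txt")
  if (file.exists(common_path)) {
    add("n_common_genes", length(read_gene_list(common_path)))
  } else add("n_common_genes", "not run")
  ov_path <- file.path(run_dir, "overlap_test.json")
  if (file.exists(ov_path)) {
    ov <- jsonlite::read_json(ov_path)
    add("overlap_p_empirical", ov$p_empirical)
    add("overlap_p_parametric", ov$p_parametric)
  } else add("overlap_p_empirical", "not run")
  cfnn_path <- file.path(run_dir, "cfnn_edges.tsv")
  if (file.exists(cfnn_path)) {
    cfnn <- read_edge_list(cfnn_path)
    add("cfnn_n_nodes", igraph::vcount(cfnn))
    add("cfnn_n_edges", igraph::ecount(cfnn))
    add("cfnn_avg_cc", sprintf("%.4f", avg_clustering_coefficient(cfnn)))
  } else add("cfnn", "not run")
  enr_path <- file.path(run_dir, "enrichment.tsv")
  if (file.exists(enr_path)) {
    enr <- utils::read.delim(enr_path, stringsAsFactors = FALSE)
    add("n_pathways_tested", nrow(enr))
    add("n_significant_pathways", sum(enr$significant))
    if (!all(is.na(enr$category))) {
      for (cat in sort(unique(enr$category[enr$significant]))) {
        add(paste0("n_significant_", cat), sum(enr$significant & enr$category == cat))
      }
    }
  } else add("enrichment", "not run")
  mod_path <- file.path(run_dir, "modules.tsv")
  if (file.exists(mod_path)) {
    mods <- utils::read.delim(mod_path, stringsAsFactors = FALSE)
    add("n_clusters", nrow(mods))
    for (i in seq_len(nrow(mods))) {
      add(sprintf("module_%s", mods$cluster_id[i]),
          sprintf("%d pathways, %d common genes, avg_cc %s",
                  mods$n_pathways[i], mods$n_common_genes[i],
                  ifelse(is.na(mods$avg_cc[i]), "None",
                         sprintf("%.3f", mods$avg_cc[i]))))
    }
  } else add("clustering", "not run")
  de_path <- file.path(run_dir, "de_results.tsv")
  if (file.exists(de_path)) {
    de <- utils::read.delim(de_path, stringsAsFactors = FALSE)
    add("n_de_significant", sum(de$significant))
  } else add("differential_expression", "not run")
  ct_path <- file.path(run_dir, "component_tests.json")
  if (file.exists(ct_path)) {
    ct <- jsonlite::read_json(ct_path)
    for (nm in names(ct)) {
      add(sprintf("component_test_%s", nm),
          sprintf("%d/%d components, p %.4g", ct[[nm]]$observed_hits,
                  ct[[nm]]$n_components, ct[[nm]]$p_empirical))
    }
  }
  out <- do.call(rbind, rows)
  write_tsv(out, file.path(run_dir, "summary.tsv"))
  out
}
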