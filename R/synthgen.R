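# Synthetic-data generator. Emulates the statistical structure the pipeline
# assumes -- a scale-free interaction network, three disease panels with a
# small planted common-gene set, pathways of mixed sizes some of which are
# enriched around the planted genes' neighborhood, multi-protein pathway
# components, and two-group expression with planted differential genes --
# with full ground truth, so every stage is testable without external
# databases.

#' Synthetic study configuration
#'
#' Defaults mirror the magnitudes of a real three-disease interaction-network
#' study scaled down roughly tenfold: 1500 genes, panels of 100/60/90 genes
#' sharing 10 planted common genes, 120 pathways of 15-80 genes of which 8
#' are enriched around the planted neighborhood, and a 6-gene fully connected
#' module shared by the enriched pathways. The planted differential-expression
#' fraction (25% of genes at effect 2 log-units, noise sd 1, 10 samples per
#' group) is sized by a closed-form power calculation so that the planted
#' genes are recoverable at BH-adjusted 0.05 with power about 0.94.
#'
#' @param n_genes number of genes in the interaction network.
#' @param attachment_edges edges added per node by the preferential-attachment
#'   generator (mean degree is about twice this).
#' @param panel_sizes sizes of the three disease panels.
#' @param n_planted_common number of genes planted into all three panels.
#' @param n_pathways number of pathways in the synthetic database.
#' @param pathway_size_range inclusive range of pathway sizes.
#' @param n_enriched_pathways number of pathways planted to be enriched.
#' @param enriched_fraction fraction of an enriched pathway's members drawn
#'   from the planted module plus the planted common genes' neighborhood.
#' @param multi_protein_fraction fraction of pathway components that are
#'   multi-protein (2-3 members).
#' @param module_size size of the planted fully connected module (>= 3).
#' @param n_samples_per_group expression samples per group.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param de_effect log-units shift added to cases for planted genes.
#' @param noise_sd expression noise standard deviation.
#' @param seed master RNG seed; every generator derives its stream from it.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 1500, attachment_edges = 5,
                         panel_sizes = c(100, 60, 90), n_planted_common = 10,
                         n_pathways = 120, pathway_size_range = c(15, 80),
                         n_enriched_pathways = 8, enriched_fraction = 0.7,
                         multi_protein_fraction = 0.3, module_size = 6,
                         n_samples_per_group = 10, n_de_genes = 375,
                         de_effect = 2, noise_sd = 1, seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 10),
    attachment_edges = check_count(attachment_edges, "attachment_edges", min = 1),
    panel_sizes = vapply(panel_sizes, check_count, integer(1), arg = "panel_sizes", min = 1),
    n_planted_common = check_count(n_planted_common, "n_planted_common"),
    n_pathways = check_count(n_pathways, "n_pathways", min = 1),
    pathway_size_range = vapply(pathway_size_range, check_count, integer(1),
                                arg = "pathway_size_range", min = 1),
    n_enriched_pathways = check_count(n_enriched_pathways, "n_enriched_pathways"),
    enriched_fraction = enriched_fraction,
    multi_protein_fraction = multi_protein_fraction,
    module_size = check_count(module_size, "module_size", min = 3),
    n_samples_per_group = check_count(n_samples_per_group, "n_samples_per_group", min = 2),
    n_de_genes = check_count(n_de_genes, "n_de_genes"),
    de_effect = de_effect,
    noise_sd = noise_sd,
    seed = check_count(seed, "seed")
  )
  if (length(cfg$panel_sizes) != 3) stop("`panel_sizes` must have length 3", call. = FALSE)
  if (cfg$n_planted_common > min(cfg$panel_sizes)) {
    stop("`n_planted_common` cannot exceed the smallest panel", call. = FALSE)
  }
  if (cfg$n_genes <= cfg$attachment_edges) {
    stop("`n_genes` must exceed `attachment_edges`", call. = FALSE)
  }
  if (cfg$enriched_fraction < 0.6 || cfg$enriched_fraction > 1) {
    stop("`enriched_fraction` must be in [0.6, 1]", call. = FALSE)
  }
  if (cfg$n_de_genes > cfg$n_genes) stop("`n_de_genes` cannot exceed `n_genes`",
                                         call. = FALSE)
  structure(cfg, class = "synth_config")
}

synth_gene_names <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a scale-free interaction network with a planted module
#'
#' Builds a connected preferential-attachment graph (heavy-tailed degrees,
#' as in protein-protein interaction networks), wires the planted module
#' genes -- the last `module_size` vertices -- into a clique, and connects
#' every module gene to a designated anchor hub (the first vertex, which
#' preferential attachment makes high-degree). The anchor is later forced
#' into the planted common-gene set, which guarantees the module lies inside
#' the common genes' first-neighbor network.
#'
#' @param cfg a [synth_config()].
#' @return Gene network with graph attributes `"module_genes"` and
#'   `"anchor_gene"`.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  g <- with_seed(cfg$seed + 1L, {
    igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$attachment_edges,
                      directed = FALSE)
  })
  nm <- synth_gene_names(cfg$n_genes)
  igraph::V(g)$name <- nm
  module <- nm[(cfg$n_genes - cfg$module_size + 1):cfg$n_genes]
  anchor <- nm[1L]
  clique_edges <- t(utils::combn(module, 2))
  anchor_edges <- cbind(rep(anchor, length(module)), module)
  g <- igraph::add_edges(g, t(rbind(clique_edges, anchor_edges)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "module_genes", module)
  g <- igraph::set_graph_attr(g, "anchor_gene", anchor)
  g
}

#' Generate three disease panels with a planted common-gene set
#'
#' Each panel is the planted common genes plus a uniform draw from the
#' remaining network genes. With `enforce_exact = TRUE` (the default) the
#' draw is repeated until the three-way intersection equals the planted set
#' exactly, so intersection recovery is a sharp test; set it to `FALSE` for
#' fully uniform null panels (used for permutation-calibration checks).
#' The planted set always contains the network's anchor gene (see
#' [generate_network()]) and excludes the module genes, mirroring a module
#' that sits in the common genes' neighborhood rather than among them.
#'
#' @param net network from [generate_network()].
#' @param cfg a [synth_config()].
#' @param enforce_exact redraw until the intersection is exactly the planted
#'   set.
#' @return List with `panels` (named list of three gene vectors) and
#'   `planted_common` (character vector).
#' @export
generate_panels <- function(net, cfg, enforce_exact = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  check_gene_network(net)
  nodes <- igraph::V(net)$name
  module <- igraph::graph_attr(net, "module_genes") %||% character()
  anchor <- igraph::graph_attr(net, "anchor_gene") %||% character()
  with_seed(cfg$seed + 2L, {
    planted <- character(0)
    if (cfg$n_planted_common > 0) {
      pool <- setdiff(nodes, c(module, anchor))
      planted <- sort(c(anchor, sample(pool, cfg$n_planted_common - 1L)))
    }
    rest <- setdiff(nodes, planted)
    draw_panels <- function() {
      lapply(cfg$panel_sizes, function(s) {
        c(planted, sample(rest, s - length(planted)))
      })
    }
    panels <- draw_panels()
    if (enforce_exact) {
      for (attempt in seq_len(1000)) {
        if (setequal(Reduce(intersect, panels), planted)) break
        panels <- draw_panels()
        if (attempt == 1000) stop("could not enforce the planted intersection",
                                  call. = FALSE)
      }
    }
    names(panels) <- c("disease_A", "disease_B", "disease_C")
    list(panels = panels, planted_common = planted)
  })
}

#' Generate a pathway database with planted enrichment, plus components
#'
#' Enriched pathways draw `enriched_fraction` of their members from the
#' planted module together with the planted common genes' network
#' neighborhood (and always contain all module genes); null pathways draw
#' uniformly from the gene universe. Every pathway is partitioned into
#' components, a configurable fraction of which are multi-protein (2-3
#' members).
#'
#' @param net network from [generate_network()].
#' @param truth list with at least `planted_common_genes` and
#'   `planted_module_genes` (as assembled by [generate_synthetic_study()]).
#' @param cfg a [synth_config()].
#' @return List with `pathways` (named list with a `"description"` category
#'   attribute), `components` (data frame) and `planted_enriched`
#'   (character vector of enriched pathway identifiers).
#' @export
generate_pathways <- function(net, truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  check_gene_network(net)
  nodes <- igraph::V(net)$name
  module <- truth$planted_module_genes %||% character()
  commons <- truth$planted_common_genes %||% character()
  nb <- character()
  if (length(commons) > 0) {
    nb <- nodes[unique(unlist(igraph::adjacent_vertices(net, commons)))]
  }
  pool <- union(module, union(commons, nb))
  with_seed(cfg$seed + 3L, {
    ids <- sprintf("pw%03d", seq_len(cfg$n_pathways))
    sizes <- sample(cfg$pathway_size_range[1]:cfg$pathway_size_range[2],
                    cfg$n_pathways, replace = TRUE)
    enriched_ids <- if (cfg$n_enriched_pathways > 0) {
      sort(sample(ids, cfg$n_enriched_pathways))
    } else character()
    pathways <- vector("list", cfg$n_pathways)
    names(pathways) <- ids
    for (i in seq_len(cfg$n_pathways)) {
      s <- sizes[i]
      if (ids[i] %in% enriched_ids) {
        s <- max(s, cfg$module_size + 2L)
        n_pool <- max(cfg$module_size, round(cfg$enriched_fraction * s))
        n_pool <- min(n_pool, length(pool))
        extra_pool <- sample(setdiff(pool, module),
                             min(n_pool - cfg$module_size,
                                 length(setdiff(pool, module))))
        members <- c(module, extra_pool)
        outside <- setdiff(nodes, members)
        members <- c(members, sample(outside, max(0L, s - length(members))))
      } else {
        members <- sample(nodes, s)
      }
      pathways[[i]] <- members
    }
    categories <- stats::setNames(sample(c("disease", "functional"),
                                         cfg$n_pathways, replace = TRUE), ids)
    attr(pathways, "description") <- categories
    # partition each pathway into components
    comp_rows <- lapply(ids, function(id) {
      genes <- sample(pathways[[id]])
      members <- list(); j <- 0L
      while (length(genes) > 0) {
        size <- if (stats::runif(1) < cfg$multi_protein_fraction) sample(2:3, 1) else 1L
        size <- min(size, length(genes))
        j <- j + 1L
        members[[j]] <- genes[seq_len(size)]
        genes <- genes[-seq_len(size)]
      }
      data.frame(component_id = sprintf("%s_c%03d", id, seq_len(j)),
                 pathway_id = id, members = I(members),
                 stringsAsFactors = FALSE)
    })
    components <- do.call(rbind, comp_rows)
    list(pathways = pathways, components = components,
         planted_enriched = enriched_ids)
  })
}

#' Generate a two-group expression matrix with planted differential genes
#'
#' Baseline values are Normal(0, `noise_sd`) over all network genes; planted
#' differentially expressed genes -- half drawn (where available) from the
#' planted enriched pathways' members, the rest uniformly -- receive a
#' `de_effect` shift in the case group.
#'
#' @param net network from [generate_network()].
#' @param truth list with `planted_enriched_genes` (possibly empty).
#' @param cfg a [synth_config()].
#' @return List with `expression` (an [expression_set()]) and `planted_de`
#'   (character vector).
#' @export
generate_expression <- function(net, truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  check_gene_network(net)
  genes <- igraph::V(net)$name
  n_s <- cfg$n_samples_per_group
  with_seed(cfg$seed + 4L, {
    pool <- intersect(truth$planted_enriched_genes %||% character(), genes)
    n_biased <- min(round(cfg$n_de_genes / 2), length(pool))
    de <- character(0)
    if (cfg$n_de_genes > 0) {
      de <- c(if (n_biased > 0) sample(pool, n_biased) else character(0),
              sample(setdiff(genes, pool), cfg$n_de_genes - n_biased))
      de <- sort(de)
    }
    mat <- matrix(stats::rnorm(length(genes) * 2 * n_s, 0, cfg$noise_sd),
                  nrow = length(genes),
                  dimnames = list(genes,
                                  c(sprintf("case_%02d", seq_len(n_s)),
                                    sprintf("ctrl_%02d", seq_len(n_s)))))
    groups <- c(rep("case", n_s), rep("control", n_s))
    mat[de, groups == "case"] <- mat[de, groups == "case"] + cfg$de_effect
    list(expression = expression_set(mat, groups), planted_de = de)
  })
}

#' Generate a full synthetic study with ground truth
#'
#' Runs the four generators in order and assembles the planted truth. All
#' randomness derives from `cfg$seed`, so the same configuration reproduces
#' the same study bit for bit.
#'
#' @param cfg a [synth_config()].
#' @return List of class `"synthetic_study"`: `network`, `panels`,
#'   `pathways`, `components`, `expression`, `truth` (with elements
#'   `planted_common_genes`, `planted_enriched_pathway_ids`,
#'   `planted_enriched_genes`, `planted_module_genes`, `planted_de_genes`,
#'   `anchor_gene`) and `config`.
#' @export
generate_synthetic_study <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  net <- generate_network(cfg)
  truth <- list(
    planted_module_genes = igraph::graph_attr(net, "module_genes"),
    anchor_gene = igraph::graph_attr(net, "anchor_gene")
  )
  pan <- generate_panels(net, cfg)
  truth$planted_common_genes <- pan$planted_common
  pw <- generate_pathways(net, truth, cfg)
  truth$planted_enriched_pathway_ids <- pw$planted_enriched
  truth$planted_enriched_genes <-
    sort(unique(unlist(pw$pathways[pw$planted_enriched])))
  ex <- generate_expression(net, truth, cfg)
  truth$planted_de_genes <- ex$planted_de
  structure(list(
    network = net,
    panels = pan$panels,
    pathways = pw$pathways,
    components = pw$components,
    expression = ex$expression,
    truth = truth,
    config = cfg
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d genes, %d interactions; panels %s; %d pathways (%d enriched); module of %d\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              paste(lengths(x$panels), collapse = "/"),
              length(x$pathways), length(x$truth$planted_enriched_pathway_ids),
              length(x$truth$planted_module_genes)))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes the network edge list, panel and pathway GMTs, component TSV,
#' expression TSV plus design, and the ground truth as JSON into a
#' directory.
#'
#' @param study a [generate_synthetic_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(study$network, file.path(dir, "network.tsv"))
  write_gmt(study$panels, file.path(dir, "panels.gmt"))
  write_gmt(study$pathways, file.path(dir, "pathways.gmt"))
  write_components(study$components, file.path(dir, "components.tsv"))
  write_expression(study$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "design.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
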