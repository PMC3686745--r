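#' Read a pipeline run configuration
#'
#' YAML file with fields: \code{expression} (path), \code{labels} (path to
#' a 2-column sample/condition TSV, or an inline mapping),
#' \code{probe_map} (optional path), \code{annotation} (optional path),
#' \code{condition_a} / \code{condition_b} (which condition is the
#' reference, e.g. normal, and which the contrast, e.g. disease),
#' \code{tau} (default 0.8), \code{min_cardinality} (default 100),
#' \code{top_k} (gene pairs per report, default 5), \code{seed} and
#' \code{out_dir}. The defaults match the analysis the pipeline mirrors: a
#' hard absolute-correlation cut-off of 0.8 and a community cardinality
#' floor of 100.
#'
#' @param path path to the YAML config.
#' @param ... named overrides applied on top of the file.
#' @return A list of validated configuration values.
#' @export
readRunConfig <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  defaults <- list(tau = 0.8, min_cardinality = 100L, top_k = 5L,
                   seed = 1L, probe_map = NULL, annotation = NULL)
  for (f in names(defaults))
    if (is.null(cfg[[f]])) cfg[f] <- defaults[f]
  needed <- c("expression", "labels", "condition_a", "condition_b",
              "out_dir")
  missing <- needed[!needed %in% names(cfg)]
  if (length(missing))
    stop("run config is missing field(s): ", paste(missing, collapse = ", "))
  cfg$tau <- as.numeric(cfg$tau)
  cfg$min_cardinality <- as.integer(cfg$min_cardinality)
  cfg$seed <- as.integer(cfg$seed)
  cfg$top_k <- as.integer(cfg$top_k)
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full co-expression community / pathway-projection pipeline
#'
#' End to end: load (and optionally probe-collapse) the expression matrix,
#' split it by condition, derive the thresholded interaction network and
#' its topology panel for both conditions, detect communities on the
#' largest component of the reference-condition network by divisive edge
#' betweenness, extract per-community sub-networks specific to the
#' reference condition, keep those above the cardinality floor, reduce
#' their pathway annotation to one-to-one, and emit Pathway Projection
#' Networks plus top cross-pathway gene-pair reports. Every stage logs its
#' counts; a failing stage aborts with the stage name while earlier
#' outputs remain on disk.
#'
#' @param config a list from [readRunConfig()], or a path to a YAML config.
#' @return Invisibly, a list with the per-condition \code{networks} and
#'   \code{stats}, the \code{communities} [CommunitySet-class], the kept
#'   \code{subnetworks}, the \code{ppns} and per-PPN \code{pairReports},
#'   and the \code{summary} list written to \code{summary.json}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  expr <- .stage("load_expression", {
    labels <- config$labels
    if (is.list(labels)) labels <- unlist(labels)
    loadExpression(config$expression, labels)
  })
  if (!is.null(config$probe_map))
    expr <- .stage("collapse_probes",
                   collapseProbes(expr, loadProbeGeneMap(config$probe_map)))

  byCond <- .stage("split_by_condition", splitByCondition(expr))
  condA <- config$condition_a
  condB <- config$condition_b
  for (cond in c(condA, condB))
    if (!cond %in% names(byCond))
      stop("pipeline stage 'split_by_condition' failed: condition '", cond,
           "' absent from the labels", call. = FALSE)

  nets <- list()
  stats <- list()
  for (cond in c(condA, condB)) {
    nets[[cond]] <- .stage(paste0("network_", cond), {
      net <- buildNetwork(correlationMatrix(byCond[[cond]]),
                          tau = config$tau)
      if (igraph::vcount(net@graph) == 0)
        stop("no edges survive |r| > ", config$tau)
      writeEdgeList(net, file.path(config$out_dir,
                                   paste0("network_", cond, ".tsv")))
      writeGraphML(net, file.path(config$out_dir,
                                  paste0("network_", cond, ".graphml")))
      net
    })
    stats[[cond]] <- .stage(paste0("stats_", cond),
                            networkStats(nets[[cond]]))
  }
  statsPanel <- do.call(rbind, stats)
  statsPanel <- cbind(condition = rownames(statsPanel), statsPanel)
  utils::write.table(statsPanel,
                     file.path(config$out_dir, "network_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  communities <- .stage("community_detection", {
    base <- nets[[condA]]
    # restricting to the dominant component mirrors published single-core
    # analyses; by default every component takes part (the divisive loop
    # starts from the component partition of a disconnected graph)
    if (isTRUE(config$largest_component)) base <- largestComponent(base)
    bestPartition(ngDendrogram(base, seed = config$seed))
  })
  commDf <- data.frame(gene = names(communities@membership),
                       community_id = unname(communities@membership))
  utils::write.table(commDf, file.path(config$out_dir, "communities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  subnets <- list()
  ppns <- list()
  pairReports <- list()
  if (!is.null(config$annotation)) {
    ann <- .stage("load_annotation",
                  if (methods::is(config$annotation, "PathwayAnnotation"))
                    config$annotation
                  else loadPathwayAnnotation(config$annotation))
    subnets <- .stage("condition_specific_subnetworks", {
      all <- lapply(communityList(communities), conditionSpecificSubnetwork,
                    netA = nets[[condA]], netB = nets[[condB]])
      filterByCardinality(all, minN = config$min_cardinality)
    })
    message("runPipeline: ", length(subnets), " sub-network(s) pass the ",
            "cardinality floor of ", config$min_cardinality)
    for (idx in seq_along(subnets)) {
      tag <- sprintf("ppn%02d", idx)
      ppns[[tag]] <- .stage(paste0("ppn_", idx), {
        assign <- reducePathways(subnets[[idx]], ann)
        ppn <- buildPPN(subnets[[idx]], assign)
        writeGraphML(ppn, file.path(config$out_dir,
                                    paste0(tag, ".graphml")))
        writeSIF(ppn, file.path(config$out_dir, paste0(tag, ".sif")))
        writePPNEdges(ppn, file.path(config$out_dir,
                                     paste0(tag, "_edges.tsv")))
        g <- ppn@graph
        if (igraph::ecount(g)) {
          ends <- igraph::ends(g, igraph::E(g))
          heavy <- which.max(igraph::E(g)$weight)
          pairReports[[tag]] <- topPairs(subnets[[idx]], assign,
                                          ends[heavy, 1], ends[heavy, 2],
                                          k = config$top_k)
          utils::write.table(pairReports[[tag]],
                             file.path(config$out_dir,
                                       paste0(tag, "_top_pairs.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        ppn
      })
    }
  }

  summary <- list(
    seed = config$seed, tau = config$tau,
    min_cardinality = config$min_cardinality,
    conditions = c(condA, condB),
    n_genes = nrow(expr),
    n_vertices = vapply(nets, function(x)
      as.integer(igraph::vcount(x@graph)), integer(1)),
    n_edges = vapply(nets, function(x)
      as.integer(igraph::ecount(x@graph)), integer(1)),
    n_communities = length(communityList(communities)),
    q_max = qMax(communities),
    n_subnetworks_kept = length(subnets),
    n_ppns = length(ppns))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(networks = nets, stats = statsPanel,
                 communities = communities, subnetworks = subnets,
                 ppns = ppns, pairReports = pairReports,
                 summary = summary))
}
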