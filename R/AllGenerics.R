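#' Accessors for ppnet classes
#'
#' Small accessor generics so that user code never touches slots:
#' \code{interactionGraph} returns the underlying \code{igraph},
#' \code{networkTau} the threshold used, \code{isolatedGenes} the genes
#' dropped for lack of an above-threshold partner, \code{conditions} the
#' per-sample condition labels, \code{membership} the gene -> community map,
#' \code{qMax} the peak modularity, \code{communityList} the per-community
#' gene lists, \code{pathwayAssignment} the reduced gene -> pathway map and
#' \code{unannotatedGenes} the genes it had to leave out.
#'
#' @param x a ppnet object.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("interactionGraph", function(x) standardGeneric("interactionGraph"))

#' @rdname accessors
#' @export
setGeneric("networkTau", function(x) standardGeneric("networkTau"))

#' @rdname accessors
#' @export
setGeneric("isolatedGenes", function(x) standardGeneric("isolatedGenes"))

#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("qMax", function(x) standardGeneric("qMax"))

#' @rdname accessors
#' @export
setGeneric("communityList", function(x) standardGeneric("communityList"))

#' @rdname accessors
#' @export
setGeneric("pathwayAssignment", function(x) standardGeneric("pathwayAssignment"))

#' @rdname accessors
#' @export
setGeneric("unannotatedGenes", function(x) standardGeneric("unannotatedGenes"))

#' @rdname accessors
#' @export
setGeneric("correlationValues", function(x) standardGeneric("correlationValues"))

#' @rdname accessors
#' @export
setGeneric("undefinedGenes", function(x) standardGeneric("undefinedGenes"))

#' @rdname accessors
#' @export
setMethod("interactionGraph", "InteractionNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("interactionGraph", "PPNGraph", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("networkTau", "InteractionNetwork", function(x) x@tau)

#' @rdname accessors
#' @export
setMethod("isolatedGenes", "InteractionNetwork", function(x) x@isolated)

#' @rdname accessors
#' @export
setMethod("conditions", "ExpressionMatrix",
          function(x) {
            stats::setNames(SummarizedExperiment::colData(x)$condition,
                            colnames(x))
          })

#' @rdname accessors
#' @export
setMethod("membership", "CommunitySet", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("qMax", "CommunitySet", function(x) x@qMax)

#' @rdname accessors
#' @export
setMethod("communityList", "CommunitySet", function(x) x@communities)

#' @rdname accessors
#' @export
setMethod("pathwayAssignment", "PathwayAssignment", function(x) x@assignment)

#' @rdname accessors
#' @export
setMethod("unannotatedGenes", "PathwayAssignment", function(x) x@unannotated)

#' @rdname accessors
#' @export
setMethod("correlationValues", "CorrelationMatrix", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("undefinedGenes", "CorrelationMatrix", function(x) x@undefined)

setMethod("show", "ExpressionMatrix", function(object) {
  cond <- table(SummarizedExperiment::colData(object)$condition)
  cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  conditions:",
      paste(sprintf("%s (%d)", names(cond), as.integer(cond)),
            collapse = ", "), "\n")
})

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat("InteractionNetwork: ", igraph::vcount(g), " genes, ",
      igraph::ecount(g), " edges (|r| > ", object@tau, ")\n", sep = "")
  if (length(object@isolated))
    cat("  isolated genes dropped:", length(object@isolated), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix:", nrow(object@r), "genes\n")
  if (length(object@undefined))
    cat("  zero-variance (undefined) genes:", length(object@undefined), "\n")
})

setMethod("show", "NetworkDendrogram", function(object) {
  cat("NetworkDendrogram:", nrow(object@removalOrder), "edge removals,",
      length(object@splits), "recorded splits (seed", object@seed, ")\n")
})

setMethod("show", "CommunitySet", function(object) {
  cat("CommunitySet:", length(object@communities), "communities over",
      length(object@membership), "genes; Q_max =",
      format(object@qMax, digits = 6), "\n")
})

setMethod("show", "PathwayAnnotation", function(object) {
  npw <- length(unique(unlist(object@gene2pathway)))
  cat("PathwayAnnotation:", length(object@gene2pathway), "genes,",
      npw, "pathways\n")
})

setMethod("show", "PathwayAssignment", function(object) {
  cat("PathwayAssignment:", length(object@assignment), "genes ->",
      length(unique(object@assignment)), "pathways;",
      length(object@unannotated), "unannotated\n")
})

setMethod("show", "PPNGraph", function(object) {
  g <- object@graph
  cat("PPNGraph:", igraph::vcount(g), "pathway nodes,",
      igraph::ecount(g), "inter-pathway edges;",
      object@nUnannotated, "unannotated genes excluded\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", length(object@blockSizes), "blocks (",
      paste(object@blockSizes, collapse = ", "), "genes );",
      "rhoIn =", object@rhoIn, "rhoOut =", object@rhoOut, "\n")
  cat("  samples:", object@nSamplesA, "/", object@nSamplesB,
      paste0("(", paste(object@conditions, collapse = " / "), ");"),
      "seed", object@seed, "\n")
})
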