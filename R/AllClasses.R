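#' @import methods
#' @importFrom igraph V E ecount vcount is_simple any_loop edge_attr
#'   vertex_attr is_directed
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

setOldClass("igraph")

#' ExpressionMatrix: genes-by-samples expression values with condition labels
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}, log-scale expression, genes in rows) and a mandatory
#' \code{condition} column in \code{colData}. Row names are gene (or probe)
#' identifiers and must be unique; the assay must be free of missing values
#' (rows failing that are dropped, and counted, at load time).
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure.
#' @seealso [loadExpression()], [collapseProbes()], [splitByCondition()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'condition' column")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "row (gene) names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "column (sample) names must be present and unique")
  if ("exprs" %in% SummarizedExperiment::assayNames(object) &&
      anyNA(SummarizedExperiment::assay(object, "exprs")))
    msg <- c(msg, "assay 'exprs' must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param condition character vector of per-sample condition labels, either
#'   unnamed (in column order) or named by sample id.
#' @param metadata optional list stored in the object metadata (e.g.
#'   preprocessing counters).
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' ExpressionMatrix(m, c(s1 = "normal", s2 = "dmd"))
#' @export
ExpressionMatrix <- function(values, condition, metadata = list()) {
  values <- as.matrix(values)
  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(values), names(condition))
    if (length(missing))
      stop("no condition label for sample(s): ",
           paste(missing, collapse = ", "))
    condition <- condition[colnames(values)]
  }
  if (length(condition) != ncol(values))
    stop("need exactly one condition label per sample")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = colnames(values)),
    metadata = metadata)
  methods::new("ExpressionMatrix", se)
}

#' InteractionNetwork: thresholded gene co-expression graph
#'
#' Undirected simple graph over gene identifiers. Edges carry the signed
#' Pearson correlation that created them in the \code{weight} attribute;
#' every edge satisfies \code{abs(weight) > tau}. Genes left without any
#' above-threshold partner are not vertices; they are recorded in
#' \code{isolated}. Downstream algorithms treat the graph as unweighted.
#'
#' @slot graph an \code{igraph} object (undirected, simple, named vertices).
#' @slot tau numeric(1), the absolute-correlation threshold used.
#' @slot isolated character, genes dropped for having no incident edge.
#' @export
setClass("InteractionNetwork",
         representation(graph = "igraph", tau = "numeric",
                        isolated = "character"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::any_loop(g)) msg <- c(msg, "graph must not contain self-loops")
  if (!igraph::is_simple(g)) msg <- c(msg, "graph must not have parallel edges")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named by gene id")
  if (length(object@tau) != 1 || is.na(object@tau))
    msg <- c(msg, "tau must be a single non-missing number")
  w <- igraph::edge_attr(g, "weight")
  if (!is.null(w) && length(w) && any(abs(w) <= object@tau))
    msg <- c(msg, "every edge weight must satisfy |weight| > tau")
  if (length(msg)) msg else TRUE
})

# internal constructor; fixtures and subgraph inductions go through here
.InteractionNetwork <- function(graph, tau = 0, isolated = character()) {
  methods::new("InteractionNetwork", graph = graph, tau = tau,
               isolated = isolated)
}

#' CorrelationMatrix: all-pairs Pearson coefficients between genes
#'
#' Symmetric matrix of Pearson correlations between gene expression profiles
#' (genes as variables, samples as observations). Genes with zero variance
#' across samples cannot be correlated; their rows/columns are \code{NA} and
#' their ids are listed in \code{undefined}.
#'
#' @slot r symmetric numeric matrix with unit diagonal for defined genes.
#' @slot undefined character, zero-variance gene ids.
#' @export
setClass("CorrelationMatrix",
         representation(r = "matrix", undefined = "character"))

setValidity("CorrelationMatrix", function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    msg <- c(msg, "r must have identical row and column gene names")
  ok <- !rownames(r) %in% object@undefined
  if (any(ok)) {
    sub <- r[ok, ok, drop = FALSE]
    if (anyNA(sub)) msg <- c(msg, "defined entries must not be NA")
    else {
      if (max(abs(sub - t(sub))) > 1e-8) msg <- c(msg, "r must be symmetric")
      if (max(abs(diag(sub) - 1)) > 1e-8)
        msg <- c(msg, "diagonal must be 1 for defined genes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' NetworkDendrogram: divisive edge-removal history and recorded splits
#'
#' Output of the divisive edge-betweenness loop: the full edge removal
#' order, plus a partition and its modularity Q recorded each time the
#' component count of the depleted graph increased (and, for a disconnected
#' input, the initial component partition). Q is always evaluated against
#' the original edge set.
#'
#' @slot graph the original \code{igraph} the loop started from.
#' @slot removalOrder character matrix, one row per removed edge (endpoints).
#' @slot splits list of named integer membership vectors, one per recorded
#'   partition, community ids dense starting at 1.
#' @slot q numeric, modularity of each recorded partition.
#' @slot seed integer seed that fixed tie-breaking.
#' @export
setClass("NetworkDendrogram",
         representation(graph = "igraph", removalOrder = "matrix",
                        splits = "list", q = "numeric", seed = "integer"))

setValidity("NetworkDendrogram", function(object) {
  msg <- character()
  if (length(object@splits) != length(object@q))
    msg <- c(msg, "one Q value per recorded split is required")
  k <- vapply(object@splits, function(m) length(unique(m)), integer(1))
  if (length(k) > 1 && any(diff(k) <= 0))
    msg <- c(msg, "community counts along splits must strictly increase")
  if (length(msg)) msg else TRUE
})

#' CommunitySet: the modularity-optimal partition of a network
#'
#' @slot membership named integer vector, gene -> community id (dense, 1..k).
#' @slot qMax numeric(1), the peak modularity over all recorded splits.
#' @slot communities list of character vectors (per-community gene lists),
#'   ordered by decreasing size.
#' @export
setClass("CommunitySet",
         representation(membership = "integer", qMax = "numeric",
                        communities = "list"))

setValidity("CommunitySet", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by gene id")
  ids <- sort(unique(object@membership))
  if (length(ids) && !identical(ids, seq_along(ids)))
    msg <- c(msg, "community ids must be dense integers starting at 1")
  if (length(object@qMax) != 1 ||
      (!is.na(object@qMax) && (object@qMax < -1 || object@qMax > 1)))
    msg <- c(msg, "qMax must be a single value in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' PathwayAnnotation: many-to-many gene-to-pathway map
#'
#' @slot gene2pathway named list; each element the character set of candidate
#'   pathway ids for one gene (possibly empty).
#' @slot pathwayNames named character, pathway id -> display name.
#' @export
setClass("PathwayAnnotation",
         representation(gene2pathway = "list", pathwayNames = "character"))

setValidity("PathwayAnnotation", function(object) {
  msg <- character()
  if (length(object@gene2pathway) && is.null(names(object@gene2pathway)))
    msg <- c(msg, "gene2pathway must be named by gene id")
  if (anyDuplicated(names(object@gene2pathway)))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayAnnotation
#'
#' @param gene2pathway named list of character vectors (gene -> candidate
#'   pathway ids).
#' @param pathwayNames optional named character vector of display names.
#' @return A [PathwayAnnotation-class] object.
#' @export
PathwayAnnotation <- function(gene2pathway, pathwayNames = character()) {
  gene2pathway <- lapply(gene2pathway, function(p) unique(as.character(p)))
  methods::new("PathwayAnnotation", gene2pathway = gene2pathway,
               pathwayNames = pathwayNames)
}

#' PathwayAssignment: the reduced one-to-one gene-to-pathway map
#'
#' Result of the maximum-spanning-pathway-reduction heuristic on one
#' sub-network: every annotated gene of the sub-network is assigned exactly
#' one pathway drawn from its candidate set. Unannotated genes are excluded
#' and tracked.
#'
#' @slot assignment named character, gene -> single pathway id.
#' @slot unannotated character, sub-network genes without any candidate
#'   pathway.
#' @export
setClass("PathwayAssignment",
         representation(assignment = "character", unannotated = "character"))

setValidity("PathwayAssignment", function(object) {
  if (length(object@assignment) && is.null(names(object@assignment)))
    "assignment must be named by gene id" else TRUE
})

#' PPNGraph: a community projected onto pathway space
#'
#' Nodes are pathways; node \code{cardinality} counts the genes assigned to
#' the pathway, \code{selfWeight} counts intra-pathway gene edges, and
#' \code{degree} counts distinct neighbouring pathways (self-weights do not
#' contribute). Edge \code{weight} counts the underlying gene-gene edges
#' between the two pathways' gene sets.
#'
#' @slot graph \code{igraph} with vertex attributes \code{cardinality},
#'   \code{selfWeight}, and edge attribute \code{weight}.
#' @slot nUnannotated integer, genes of the sub-network left out of the
#'   projection for lack of annotation.
#' @export
setClass("PPNGraph",
         representation(graph = "igraph", nUnannotated = "integer"))

setValidity("PPNGraph", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "PPN must be undirected")
  if (igraph::vcount(g) > 0) {
    if (is.null(igraph::vertex_attr(g, "cardinality")) ||
        is.null(igraph::vertex_attr(g, "selfWeight")))
      msg <- c(msg, "nodes need 'cardinality' and 'selfWeight' attributes")
  }
  if (igraph::ecount(g) > 0 && is.null(igraph::edge_attr(g, "weight")))
    msg <- c(msg, "edges need a 'weight' attribute")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the planted-partition expression generator
#'
#' Describes a two-condition expression dataset whose gene-gene correlation
#' has planted block structure: \code{rhoIn} within blocks, \code{rhoOut}
#' between blocks, in condition A; in condition B the blocks listed in
#' \code{decorrelatedBlocks} have their within-block correlation lowered to
#' \code{rhoInB}, emulating a sparser disease network.
#'
#' @slot blockSizes integer vector, genes per planted block.
#' @slot rhoIn,rhoOut within-/between-block target correlations (rhoIn > rhoOut).
#' @slot rhoInB within-block correlation of the decorrelated blocks in
#'   condition B.
#' @slot decorrelatedBlocks integer indices of blocks decorrelated in B.
#' @slot nSamplesA,nSamplesB samples per condition.
#' @slot noiseSd standard deviation of independent jitter added on top of
#'   the block-correlated signal (attenuates realised correlations by
#'   1/(1 + noiseSd^2)).
#' @slot conditions character(2), the labels of conditions A and B.
#' @slot pathwayScheme list, one element per block: the candidate pathway
#'   id set(s) planted on that block's genes (see [SyntheticSpec()]).
#' @slot seed integer, master seed; the same spec and seed reproduce the
#'   matrices bit for bit.
#' @export
setClass("SyntheticSpec",
         representation(blockSizes = "integer", rhoIn = "numeric",
                        rhoOut = "numeric", rhoInB = "numeric",
                        decorrelatedBlocks = "integer",
                        nSamplesA = "integer", nSamplesB = "integer",
                        noiseSd = "numeric", conditions = "character",
                        pathwayScheme = "list", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (any(object@blockSizes < 1)) msg <- c(msg, "block sizes must be >= 1")
  if (object@rhoIn <= object@rhoOut)
    msg <- c(msg, "rhoIn must exceed rhoOut")
  for (rho in c(object@rhoIn, object@rhoOut, object@rhoInB))
    if (rho <= -1 || rho > 1)
      msg <- c(msg, "correlations must lie in (-1, 1]")
  if (any(object@decorrelatedBlocks < 1) ||
      any(object@decorrelatedBlocks > length(object@blockSizes)))
    msg <- c(msg, "decorrelatedBlocks out of range")
  if (object@nSamplesA < 2 || object@nSamplesB < 2)
    msg <- c(msg, "need >= 2 samples per condition")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@conditions) != 2 ||
      anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be two distinct labels")
  if (length(object@pathwayScheme) != length(object@blockSizes))
    msg <- c(msg, "pathwayScheme needs one element per block")
  # planted structure must be a valid correlation matrix for both
  # conditions; positive semi-definite accepted so that degenerate
  # rho = 1 blocks (perfectly correlated genes) remain expressible
  if (!length(msg)) {
    for (target in list(.blockCorrelation(object, "A"),
                        .blockCorrelation(object, "B"))) {
      ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) {
        msg <- c(msg, "planted block correlation matrix is not positive definite")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})
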