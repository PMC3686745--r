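# target gene-gene correlation matrix for one condition ("A" or "B"):
# rhoIn within blocks, rhoOut between; in condition B the decorrelated
# blocks use rhoInB instead of rhoIn
.blockCorrelation <- function(spec, condition = c("A", "B")) {
  condition <- match.arg(condition)
  sizes <- spec@blockSizes
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  sigma <- matrix(spec@rhoOut, n, n)
  for (b in seq_along(sizes)) {
    rho <- if (condition == "B" && b %in% spec@decorrelatedBlocks)
      spec@rhoInB else spec@rhoIn
    idx <- which(block == b)
    sigma[idx, idx] <- rho
  }
  diag(sigma) <- 1
  sigma
}

#' Specify a planted-partition synthetic expression dataset
#'
#' The defaults emulate a two-condition muscle-biopsy style study: four
#' co-functional gene blocks of 10 genes with strong within-block
#' correlation (0.95) and none between blocks, 13 samples in condition A
#' ("normal") and 23 in condition B ("dmd"), and, in condition B, half of
#' the blocks decorrelated (within-block correlation lowered to 0.3) so
#' that thresholding produces a sparser disease network. Each block is
#' planted a block-specific candidate pathway; every second gene
#' additionally carries a shared pathway (\code{"pw_shared"}) so the
#' annotation is genuinely one-to-many.
#'
#' @param blockSizes integer vector of genes per block; default
#'   \code{rep(10, 4)}.
#' @param rhoIn,rhoOut within-/between-block target correlations; defaults
#'   0.95 and 0.
#' @param rhoInB within-block correlation of the decorrelated blocks in
#'   condition B; default 0.3.
#' @param decorrelatedBlocks indices of the blocks decorrelated in B;
#'   default the second half of the blocks.
#' @param nSamplesA,nSamplesB samples per condition; defaults 13 and 23.
#' @param noiseSd sd of independent jitter added to the block-correlated
#'   signal; default 0 (sampling noise at these sample sizes already
#'   provides realistic estimation error).
#' @param conditions labels for the two conditions; default
#'   \code{c("normal", "dmd")}.
#' @param pathwayScheme list with one element per block, each a list of
#'   candidate pathway-id sets cycled over the block's genes; default as
#'   described above.
#' @param seed master seed; with the spec it determines the matrices bit
#'   for bit.
#' @return A [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(blockSizes = rep(10L, 4), rhoIn = 0.95,
                          rhoOut = 0, rhoInB = 0.3,
                          decorrelatedBlocks = NULL,
                          nSamplesA = 13L, nSamplesB = 23L, noiseSd = 0,
                          conditions = c("normal", "dmd"),
                          pathwayScheme = NULL, seed = 1L) {
  blockSizes <- as.integer(blockSizes)
  if (is.null(decorrelatedBlocks)) {
    nb <- length(blockSizes)
    decorrelatedBlocks <- if (nb > 1) seq.int(nb %/% 2 + 1, nb) else integer(0)
  }
  if (is.null(pathwayScheme)) {
    pathwayScheme <- lapply(seq_along(blockSizes), function(b) {
      own <- sprintf("pw%02d", b)
      list(own, c(own, "pw_shared"))   # cycled: every 2nd gene many-to-many
    })
  }
  methods::new("SyntheticSpec", blockSizes = blockSizes, rhoIn = rhoIn,
               rhoOut = rhoOut, rhoInB = rhoInB,
               decorrelatedBlocks = as.integer(decorrelatedBlocks),
               nSamplesA = as.integer(nSamplesA),
               nSamplesB = as.integer(nSamplesB),
               noiseSd = noiseSd, conditions = conditions,
               pathwayScheme = pathwayScheme, seed = as.integer(seed))
}

#' Generate a planted-partition expression dataset
#'
#' Samples each condition from a zero-mean multivariate normal whose
#' correlation matrix is block structured (\code{rhoIn} within planted
#' blocks, \code{rhoOut} between; condition B decorrelates the blocks
#' named in the spec), via the symmetric (eigen) square root of the target
#' matrix, then adds independent \code{noiseSd} jitter. Positive
#' definiteness of the target is verified before sampling (it is also part
#' of the spec's validity). Returns the per-condition expression matrices,
#' the planted block membership, and the planted many-to-many pathway
#' annotation.
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with elements \code{expression} (named list of
#'   [ExpressionMatrix-class], one per condition), \code{truth} (named
#'   integer vector, gene -> planted block) and \code{annotation}
#'   (a [PathwayAnnotation-class]).
#' @export
generateSynthetic <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  sizes <- spec@blockSizes
  nGenes <- sum(sizes)
  genes <- sprintf("g%03d", seq_len(nGenes))
  block <- stats::setNames(rep(seq_along(sizes), sizes), genes)

  sqrtm <- function(sigma) {
    es <- eigen(sigma, symmetric = TRUE)
    if (min(es$values) < -1e-8)
      stop("target correlation matrix is not positive definite")
    es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  }
  rootA <- sqrtm(.blockCorrelation(spec, "A"))
  rootB <- sqrtm(.blockCorrelation(spec, "B"))

  sample_condition <- function(root, nSamples, label) {
    z <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples)
    x <- root %*% z
    if (spec@noiseSd > 0)
      x <- x + spec@noiseSd * matrix(stats::rnorm(nGenes * nSamples),
                                     nGenes, nSamples)
    dimnames(x) <- list(genes, sprintf("%s_s%02d", label, seq_len(nSamples)))
    ExpressionMatrix(x, stats::setNames(rep(label, nSamples), colnames(x)))
  }

  exprs <- withr::with_seed(spec@seed, {
    list(sample_condition(rootA, spec@nSamplesA, spec@conditions[1]),
         sample_condition(rootB, spec@nSamplesB, spec@conditions[2]))
  })
  names(exprs) <- spec@conditions

  g2p <- lapply(genes, function(g) {
    b <- block[[g]]
    scheme <- spec@pathwayScheme[[b]]
    posInBlock <- g == names(block)[block == b]
    unlist(scheme[[(which(posInBlock) - 1) %% length(scheme) + 1]])
  })
  names(g2p) <- genes

  list(expression = exprs, truth = block,
       annotation = PathwayAnnotation(g2p))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a recovered partition and the
#' planted truth over the same vertex set: 1 iff the partitions are
#' identical up to relabelling, about 0 for independent partitions,
#' possibly negative for worse-than-chance agreement.
#'
#' @param found,truth named vectors (vertex -> community label) over the
#'   same vertex names.
#' @return The adjusted Rand index, a number in \code{[-1, 1]}.
#' @export
evaluateRecovery <- function(found, truth) {
  if (is.null(names(found)) || is.null(names(truth)))
    stop("both partitions must be named by vertex id")
  if (!setequal(names(found), names(truth)))
    stop("vertex sets of the two partitions differ")
  found <- found[names(truth)]
  mclust::adjustedRandIndex(as.vector(found), as.vector(truth))
}
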