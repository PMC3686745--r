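#' Read a gene-expression matrix with per-sample condition labels
#'
#' Reads a rectangular tab-separated matrix (header row of sample ids,
#' first column of probe/gene ids) or a GEO series-matrix-style file, in
#' which lines starting with \code{"!"} are metadata and the expression
#' table is delimited by \code{!series_matrix_table_begin} /
#' \code{!series_matrix_table_end}. Values are used as-is (assumed already
#' normalised and log-scaled by the source); rows containing any missing or
#' non-numeric cell are dropped and counted.
#'
#' @param path path to the expression file.
#' @param sampleConditions per-sample condition labels: either a named
#'   character vector (sample id -> condition) or a path to a two-column
#'   TSV (sample id, condition). Every sample in the file must be covered.
#' @return An [ExpressionMatrix-class]; \code{metadata()} records
#'   \code{nRowsRead}, \code{nSamplesRead} and \code{nRowsDropped}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tsv)
#' loadExpression(tsv, c(s1 = "normal", s2 = "dmd"))
#' @export
loadExpression <- function(path, sampleConditions) {
  lines <- readLines(path)
  if (any(startsWith(lines, "!"))) {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
      stop("malformed series-matrix file: table delimiters not found in '",
           path, "'")
    lineNo <- seq(beg + 1, end - 1)
    lines <- lines[lineNo]
  } else {
    lineNo <- seq_along(lines)
  }
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (length(lines) < 2)
    stop("expression file '", path, "' has no data rows")

  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(cells)
  if (any(width != width[1]))
    stop("ragged row in '", path, "': line ",
         lineNo[which(width != width[1])[1]], " has ",
         width[which(width != width[1])[1]], " fields, expected ", width[1])

  header <- gsub("\"", "", cells[[1]])
  sampleIds <- header[-1]
  if (anyDuplicated(sampleIds))
    stop("duplicated sample column header: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))

  body <- cells[-1]
  geneIds <- gsub("\"", "", vapply(body, `[`, character(1), 1))
  if (anyDuplicated(geneIds))
    stop("duplicated row (probe/gene) id: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  values <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(body, `[`, -1)))),
    nrow = length(body), ncol = length(sampleIds), byrow = TRUE,
    dimnames = list(geneIds, sampleIds))

  complete <- !apply(is.na(values), 1, any)
  nDropped <- sum(!complete)
  values <- values[complete, , drop = FALSE]
  if (nrow(values) == 0)
    stop("no complete rows left after dropping rows with missing values")

  if (is.character(sampleConditions) && is.null(names(sampleConditions)) &&
      length(sampleConditions) == 1 && file.exists(sampleConditions)) {
    lab <- utils::read.delim(sampleConditions, header = FALSE,
                             colClasses = "character")
    sampleConditions <- stats::setNames(lab[[2]], lab[[1]])
  }
  unknown <- setdiff(sampleIds, names(sampleConditions))
  if (length(unknown))
    stop("sample id(s) without a condition label: ",
         paste(unknown, collapse = ", "))

  message("loadExpression: read ", length(body), " rows x ",
          length(sampleIds), " samples; dropped ", nDropped,
          " incomplete row(s)")
  ExpressionMatrix(values, sampleConditions[sampleIds],
                   metadata = list(nRowsRead = length(body),
                                   nSamplesRead = length(sampleIds),
                                   nRowsDropped = nDropped))
}

#' Read a probe-to-gene mapping table
#'
#' @param path two-column TSV (probe id, gene id); many-to-many rows allowed.
#' @param header logical, whether the first line is a header.
#' @return data.frame with columns \code{probe} and \code{gene}.
#' @export
loadProbeGeneMap <- function(path, header = FALSE) {
  map <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(map) < 2)
    stop("probe map must have two columns (probe id, gene id)")
  data.frame(probe = map[[1]], gene = map[[2]], stringsAsFactors = FALSE)
}

#' Collapse probes to one row per gene
#'
#' Resolves the many-to-many probe/gene relationship to a bijection:
#' probes mapping to more than one gene are dropped; among the remaining
#' probes of a gene, the probe with the largest expression variance across
#' all samples is kept (ties broken by lexicographically smallest probe id).
#' Retained rows keep their original values bit for bit.
#'
#' @param expr an [ExpressionMatrix-class] whose rows are probe ids.
#' @param map data.frame with columns \code{probe}, \code{gene} (e.g. from
#'   [loadProbeGeneMap()]); every row id of \code{expr} must appear.
#' @return An [ExpressionMatrix-class] with one row per gene, rows renamed
#'   to gene ids; \code{metadata()} records \code{nMultiGeneProbesDropped}
#'   and \code{nProbesCollapsed}.
#' @export
collapseProbes <- function(expr, map) {
  stopifnot(methods::is(expr, "ExpressionMatrix"))
  probes <- rownames(expr)
  missing <- setdiff(probes, map$probe)
  if (length(missing))
    stop("probe(s) absent from the mapping table: ",
         paste(utils::head(missing, 5), collapse = ", "))

  map <- unique(map[map$probe %in% probes, c("probe", "gene")])
  genesPerProbe <- table(map$probe)
  multi <- names(genesPerProbe)[genesPerProbe > 1]
  map <- map[!map$probe %in% multi, , drop = FALSE]
  if (nrow(map) == 0)
    stop("no probes left after dropping multi-gene probes")

  values <- SummarizedExperiment::assay(expr, "exprs")
  rowVar <- apply(values[map$probe, , drop = FALSE], 1, stats::var)
  # per gene: keep max-variance probe, ties -> smallest probe id
  ord <- order(map$gene, -rowVar[map$probe], map$probe)
  map <- map[ord, , drop = FALSE]
  keepIdx <- !duplicated(map$gene)
  keep <- map[keepIdx, , drop = FALSE]
  nCollapsed <- nrow(map) - nrow(keep)

  out <- values[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  # restore the input's row order for probes that survived unchanged
  ord2 <- order(match(keep$probe, probes))
  out <- out[ord2, , drop = FALSE]

  message("collapseProbes: dropped ", length(multi),
          " multi-gene probe(s); collapsed ", nCollapsed,
          " probe(s) by max variance; ", nrow(out), " genes retained")
  ExpressionMatrix(out, conditions(expr),
                   metadata = c(S4Vectors::metadata(expr),
                                list(nMultiGeneProbesDropped = length(multi),
                                     nProbesCollapsed = nCollapsed)))
}

#' Split an expression matrix by condition
#'
#' @param expr an [ExpressionMatrix-class].
#' @return Named list of [ExpressionMatrix-class] objects, one per
#'   condition, all sharing the full gene set; the sample columns partition
#'   the input columns.
#' @export
splitByCondition <- function(expr) {
  stopifnot(methods::is(expr, "ExpressionMatrix"))
  cond <- conditions(expr)
  counts <- table(cond)
  if (any(counts < 2))
    stop("condition(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "),
         " (correlation needs >= 2 samples)")
  lapply(split(names(cond), cond), function(samples) {
    methods::new("ExpressionMatrix", expr[, samples])
  })
}
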