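#' Construct an AbundanceTable
#'
#' @param counts taxon x sample matrix of non-negative integers with taxon
#'   ids as rownames and sample ids as colnames.
#' @param sampleData optional data.frame/DataFrame of per-sample metadata
#'   (rownames or `sample_id` column matching colnames of `counts`).
#' @return An [AbundanceTable-class].
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, dimnames = list(c("g__A", "g__B"),
#'                                                   c("s1", "s2")))
#' AbundanceTable(m)
#' @export
AbundanceTable <- function(counts, sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "numeric"
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(counts))
  } else {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData))
      rownames(sampleData) <- sampleData$sample_id
    if (!all(colnames(counts) %in% rownames(sampleData)))
      stop("sampleData is missing rows for some samples")
    DataFrame(sampleData[colnames(counts), , drop = FALSE])
  }
  new("AbundanceTable",
      SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

#' Construct a RelativeAbundanceTable
#'
#' @param relabund taxon x sample matrix of proportions; columns must sum
#'   to 1 within 1e-9.
#' @param sampleData optional per-sample metadata (as in [AbundanceTable()]).
#' @return A [RelativeAbundanceTable-class].
#' @export
RelativeAbundanceTable <- function(relabund, sampleData = NULL) {
  relabund <- as.matrix(relabund)
  storage.mode(relabund) <- "numeric"
  cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(relabund))
        else DataFrame(as.data.frame(sampleData)[colnames(relabund), ,
                                                 drop = FALSE])
  new("RelativeAbundanceTable",
      SummarizedExperiment(assays = list(relabund = relabund), colData = cd))
}

#' Count assay accessor
#'
#' @param object an [AbundanceTable-class].
#' @param ... ignored.
#' @return Numeric taxon x sample matrix.
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
counts <- BiocGenerics::counts
setMethod("counts", "AbundanceTable",
          function(object, ...) assay(object, "counts"))

#' @rdname relabund
setMethod("relabund", "RelativeAbundanceTable",
          function(x) assay(x, "relabund"))

#' @rdname taxonIds
setMethod("taxonIds", "SummarizedExperiment", function(x) rownames(x))
#' @rdname taxonIds
setMethod("taxonIds", "TaxonNetwork", function(x) x@nodes$taxon_id)

#' @rdname sampleIds
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d taxa x %d samples, total count %s\n",
              nrow(object), ncol(object),
              format(sum(assay(object, "counts")), big.mark = ",")))
  cat("  taxa: ", paste(head(rownames(object), 4), collapse = ", "),
      if (nrow(object) > 4) ", ..." else "", "\n", sep = "")
})

setMethod("show", "RelativeAbundanceTable", function(object) {
  cat(sprintf("RelativeAbundanceTable: %d taxa x %d samples\n",
              nrow(object), ncol(object)))
})

#' Read a taxon x sample count table from TSV
#'
#' Expected layout: header row of sample ids with first cell `taxon_id`,
#' one row per taxon, integer counts.
#'
#' @param path file path.
#' @param format only `"tsv"`.
#' @return An [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, format = c("tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance TSV needs a taxon_id column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated taxon id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric count cell(s) in ", path)
  if (any(m < 0)) stop("negative count cell(s) in ", path)
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer count cell(s) in ", path)
  rownames(m) <- ids
  AbundanceTable(m)
}

#' Write a count table as TSV
#'
#' @param x an [AbundanceTable-class].
#' @param path output path.
#' @export
writeAbundanceTable <- function(x, path) {
  stopifnot(is(x, "AbundanceTable"))
  m <- assay(x, "counts")
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname toRelative
setMethod("toRelative", "AbundanceTable", function(x) {
  m <- assay(x, "counts")
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[tot <= 0], collapse = ", "))
  RelativeAbundanceTable(sweep(m, 2L, tot, "/"),
                         sampleData = as.data.frame(colData(x)))
})

#' @rdname selectTopTaxa
#' @details Retains the `n` taxa with the largest mean relative abundance
#'   across the table's samples; ties broken by lexicographic taxon id. If
#'   the table holds fewer than `n` taxa it is returned unchanged with a
#'   message. Retained proportions are renormalized per sample so the
#'   result is again a valid relative-abundance table (a monotone
#'   per-sample rescaling, so rank-based statistics are unaffected).
setMethod("selectTopTaxa", "RelativeAbundanceTable", function(x, n) {
  stopifnot(length(n) == 1L, n >= 1)
  m <- relabund(x)
  if (nrow(m) <= n) {
    if (nrow(m) < n)
      message("table has only ", nrow(m), " taxa (< n = ", n, "); keeping all")
    return(x)
  }
  mu <- rowMeans(m)
  ord <- order(-mu, rownames(m))
  keep <- sort(ord[seq_len(n)])  # preserve original row order
  kept <- m[keep, , drop = FALSE]
  tot <- colSums(kept)
  if (any(tot <= 0))
    stop("sample(s) with zero abundance over the retained taxa: ",
         paste(colnames(kept)[tot <= 0], collapse = ", "))
  RelativeAbundanceTable(sweep(kept, 2L, tot, "/"),
                         sampleData = as.data.frame(colData(x)))
})

#' Subset a table to a sample stratum
#'
#' @param x an [AbundanceTable-class] or [RelativeAbundanceTable-class].
#' @param samples character vector of sample ids to keep.
#' @return Table restricted to `samples` (original order preserved).
#' @export
subsetSamples <- function(x, samples) {
  miss <- setdiff(samples, colnames(x))
  if (length(miss))
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  x[, colnames(x) %in% samples]
}
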