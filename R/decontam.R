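#' Construct a ControlProfile
#'
#' @param counts named non-negative integer vector (taxon id -> count in the
#'   negative control). Taxa not listed are implicitly zero.
#' @return A [ControlProfile-class].
#' @export
ControlProfile <- function(counts = numeric(0)) {
  new("ControlProfile", counts = counts)
}

#' Control counts accessor
#' @param x a [ControlProfile-class].
#' @export
controlCounts <- function(x) x@counts

setMethod("show", "ControlProfile", function(object) {
  cat(sprintf("ControlProfile: %d taxa, %d total contaminant reads\n",
              length(object@counts), sum(object@counts)))
})

#' Read a control profile from TSV (columns taxon_id, count)
#'
#' @param path file path.
#' @return A [ControlProfile-class].
#' @export
readControlProfile <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "count") %in% names(df)))
    stop("control TSV needs columns taxon_id, count")
  ControlProfile(setNames(as.numeric(df$count), df$taxon_id))
}

#' Merge several negative controls into one subtraction profile
#'
#' The sequenced controls (e.g. three pure-water runs) are aggregated
#' per taxon: `mean_rounded` takes the mean rounded half-up to an integer
#' (default); `max` takes the per-taxon maximum (stricter).
#'
#' @param controls list of [ControlProfile-class] objects (>= 1).
#' @param mode `"mean_rounded"` or `"max"`.
#' @return A merged [ControlProfile-class].
#' @examples
#' a <- ControlProfile(c(g__X = 5)); b <- ControlProfile(c(g__X = 7))
#' d <- ControlProfile(c(g__X = 9))
#' controlCounts(mergeControls(list(a, b, d)))  # g__X = 7
#' @export
mergeControls <- function(controls, mode = c("mean_rounded", "max")) {
  mode <- match.arg(mode)
  if (!length(controls)) stop("need at least one control")
  stopifnot(all(vapply(controls, is, logical(1), "ControlProfile")))
  ids <- unique(unlist(lapply(controls, function(cp) names(cp@counts))))
  if (!length(ids)) return(ControlProfile())
  m <- vapply(controls,
              function(cp) ifelse(ids %in% names(cp@counts),
                                  cp@counts[ids], 0), numeric(length(ids)))
  m <- matrix(m, nrow = length(ids))
  agg <- switch(mode,
                mean_rounded = floor(rowMeans(m) + 0.5),  # round half up
                max = apply(m, 1L, max))
  ControlProfile(setNames(agg, ids))
}

#' @rdname subtractControl
#' @details Implements subtraction decontamination: the same control count
#'   is removed from every sample, cell-wise as `max(0, count - control)`.
#'   Clipping at zero is unavoidable (counts cannot go negative) and is
#'   accounted for in the report. The report (attached as
#'   `metadata(result)$decontam`) lists, per taxon, the control count, the
#'   total reads removed across samples, and whether the taxon was zeroed in
#'   every sample.
#' @return An [AbundanceTable-class]; the removal report is in
#'   `S4Vectors::metadata(x)$decontam`.
setMethod("subtractControl", c("AbundanceTable", "ControlProfile"),
          function(x, control) {
  m <- assay(x, "counts")
  ctl <- setNames(numeric(nrow(m)), rownames(m))
  known <- intersect(names(control@counts), rownames(m))
  ctl[known] <- control@counts[known]
  out <- pmax(m - ctl, 0)
  removed <- m - out
  report <- data.frame(
    taxon_id = rownames(m),
    control_count = unname(ctl),
    total_removed = rowSums(removed),
    zeroed_all_samples = apply(out, 1L, function(r) all(r == 0)) &
      rowSums(m) > 0,
    stringsAsFactors = FALSE)
  res <- AbundanceTable(out, sampleData = as.data.frame(colData(x)))
  metadata(res)$decontam <- list(
    report = report,
    total_removed = sum(removed),
    unmatched_control_taxa = setdiff(names(control@counts), rownames(m)))
  res
})
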