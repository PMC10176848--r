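#' Read per-sample metadata from TSV
#'
#' Expected columns: `sample_id`, `cohort` (healthy/NSCLC), `subtype`
#' (SCC/AC/none), `metastasis` (yes/no/unknown) and optionally
#' `survival_months`. `subtype` must be `none` exactly for healthy samples.
#'
#' @param path file path.
#' @return data.frame keyed by `sample_id`.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateSampleMetadata(df)
}

#' Validate a sample-metadata data.frame
#'
#' @param df data.frame with the columns described in [readSampleMetadata()].
#' @return The validated data.frame (invisibly unchanged).
#' @export
validateSampleMetadata <- function(df) {
  need <- c("sample_id", "cohort", "subtype", "metastasis")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  if (!all(df$cohort %in% c("healthy", "NSCLC")))
    stop("cohort must be 'healthy' or 'NSCLC'")
  if (!all(df$subtype %in% c("SCC", "AC", "none")))
    stop("subtype must be 'SCC', 'AC' or 'none'")
  if (!all(df$metastasis %in% c("yes", "no", "unknown")))
    stop("metastasis must be 'yes', 'no' or 'unknown'")
  bad <- xor(df$cohort == "healthy", df$subtype == "none")
  if (any(bad))
    stop("subtype must be 'none' iff cohort is 'healthy'; offending: ",
         paste(df$sample_id[bad], collapse = ", "))
  if ("survival_months" %in% names(df) &&
      any(df$survival_months < 0, na.rm = TRUE))
    stop("survival_months must be non-negative")
  rownames(df) <- df$sample_id
  df
}

#' Read a sample x clinical-factor table from TSV
#'
#' One row per sample (`sample_id` column), one numeric column per factor
#' (immune-cell densities in 1e9 cells/L, cancer-marker concentrations in
#' ng/mL or units/mL). Missing values allowed.
#'
#' @param path file path.
#' @return data.frame keyed by `sample_id`.
#' @export
readClinicalFactors <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  validateClinicalFactors(df)
}

#' Validate a clinical-factor data.frame
#'
#' @param df data.frame with `sample_id` plus numeric factor columns.
#' @return The validated data.frame.
#' @export
validateClinicalFactors <- function(df) {
  if (!"sample_id" %in% names(df)) stop("factor table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in factor table")
  fcols <- setdiff(names(df), "sample_id")
  if (anyDuplicated(fcols)) stop("duplicated factor name(s)")
  for (fc in fcols) {
    v <- df[[fc]]
    if (!is.numeric(v)) stop("factor column '", fc, "' is not numeric")
    if (any(!is.finite(v) & !is.na(v)))
      stop("factor column '", fc, "' has non-finite values")
  }
  rownames(df) <- df$sample_id
  df
}

#' Select sample ids belonging to a stratum
#'
#' @param metadata validated metadata data.frame.
#' @param ... named stratum filters over metadata columns, e.g.
#'   `cohort = "NSCLC"`, `metastasis = "yes"`. Several values per column are
#'   allowed; filters combine with AND.
#' @return Character vector of matching sample ids.
#' @examples
#' md <- data.frame(sample_id = c("a", "b"), cohort = c("healthy", "NSCLC"),
#'                  subtype = c("none", "AC"), metastasis = c("no", "yes"))
#' selectStratum(validateSampleMetadata(md), cohort = "NSCLC")
#' @export
selectStratum <- function(metadata, ...) {
  filt <- list(...)
  keep <- rep(TRUE, nrow(metadata))
  for (col in names(filt)) {
    if (!col %in% names(metadata)) stop("unknown metadata column: ", col)
    keep <- keep & metadata[[col]] %in% filt[[col]]
  }
  metadata$sample_id[keep]
}
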