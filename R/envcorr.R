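#' Drop taxa detected in too few samples
#'
#' Retains taxa with nonzero abundance in at least `minSamples` samples of
#' the (already stratified) table — the detection filter applied before
#' taxon-factor correlation.
#'
#' @param table a [RelativeAbundanceTable-class] or [AbundanceTable-class].
#' @param minSamples minimum number of samples with nonzero abundance
#'   (default 2).
#' @return The filtered table (same class); relative-abundance tables are
#'   renormalized per sample over the retained taxa.
#' @export
detectionFilter <- function(table, minSamples = 2L) {
  if (is(table, "RelativeAbundanceTable")) {
    m <- relabund(table)
    kept <- m[rowSums(m > 0) >= minSamples, , drop = FALSE]
    tot <- colSums(kept)
    if (any(tot <= 0))
      stop("sample(s) with zero abundance over the retained taxa: ",
           paste(colnames(kept)[tot <= 0], collapse = ", "))
    RelativeAbundanceTable(sweep(kept, 2L, tot, "/"),
                           sampleData = as.data.frame(colData(table)))
  } else {
    m <- assay(table, "counts")
    table[rowSums(m > 0) >= minSamples, ]
  }
}

#' Correlate taxon abundances with clinical factors
#'
#' Pearson correlation (two-sided analytic t-transform p-value) between each
#' taxon's relative abundance and each clinical factor over the stratum's
#' samples, with pairwise-complete handling of missing factor values; pairs
#' with fewer than `minN` complete observations are excluded, constant
#' factors are flagged and excluded. An association is `significant` iff
#' |r| > 0.5 AND p < 0.05 (the joint filter used for the bacteria-vs-factor
#' heatmaps and networks).
#'
#' @param table a [RelativeAbundanceTable-class].
#' @param factors validated clinical-factor data.frame (see
#'   [readClinicalFactors()]).
#' @param samples stratum sample ids (default: all table samples).
#' @param rThreshold,alpha joint significance filter (defaults 0.5, 0.05).
#' @param minN minimum pairwise-complete n (default 4).
#' @param stratum description string.
#' @return data.frame with taxon_id, factor, n, r, p, significant, stratum;
#'   excluded (constant/short) pairs carry NA r and a `flag`.
#' @export
correlateFactors <- function(table, factors, samples = NULL,
                             rThreshold = 0.5, alpha = 0.05, minN = 4L,
                             stratum = "all") {
  if (!is.null(samples)) table <- subsetSamples(table, samples)
  m <- relabund(table)
  sm <- colnames(m)
  miss <- setdiff(sm, rownames(factors))
  if (length(miss))
    stop("factor table missing sample(s): ", paste(miss, collapse = ", "))
  fcols <- setdiff(names(factors), "sample_id")
  fm <- as.matrix(factors[sm, fcols, drop = FALSE])
  rows <- list()
  for (tx in rownames(m)) {
    for (fc in fcols) {
      ok <- !is.na(fm[, fc])
      n <- sum(ok)
      x <- m[tx, ok]; y <- fm[ok, fc]
      if (n < minN) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = tx, factor = fc, n = n, r = NA_real_, p = NA_real_,
          significant = FALSE, flag = "insufficient_n",
          stringsAsFactors = FALSE)
        next
      }
      if (sd(y) == 0 || sd(x) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = tx, factor = fc, n = n, r = NA_real_, p = NA_real_,
          significant = FALSE, flag = "constant",
          stringsAsFactors = FALSE)
        next
      }
      r <- cor(x, y)
      p <- .pearsonP(r, n)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = tx, factor = fc, n = n, r = r, p = p,
        significant = abs(r) > rThreshold && p < alpha,
        flag = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$stratum <- stratum
  out
}

# two-sided p from the t-transform of a Pearson r at n observations
.pearsonP <- function(r, n) {
  if (abs(r) >= 1) return(.Machine$double.xmin)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Bipartite taxon-factor network from correlation results
#'
#' Nodes of two classes (`taxon`, `factor`); edges are exactly the
#' significant associations, signed by the correlation's sign. The object is
#' a [TaxonNetwork-class] whose node table gains a `class` column, so
#' [writeNetwork()] export (GraphML/TSV) applies unchanged.
#'
#' @param results data.frame from [correlateFactors()].
#' @return A [TaxonNetwork-class] with bipartite node classes.
#' @export
bipartiteNetwork <- function(results) {
  taxa <- unique(results$taxon_id)
  facs <- unique(results$factor)
  if (length(bad <- intersect(taxa, facs)))
    stop("taxon and factor ids collide: ", paste(bad, collapse = ", "))
  nodes <- data.frame(
    taxon_id = c(taxa, facs),
    abundance = NA_real_,
    class = rep(c("taxon", "factor"), c(length(taxa), length(facs))),
    stringsAsFactors = FALSE)
  sig <- results[results$significant, , drop = FALSE]
  edges <- if (nrow(sig)) {
    data.frame(taxon_a = sig$taxon_id, taxon_b = sig$factor,
               method = "pearson", rho = sig$r, p = sig$p,
               sign = ifelse(sig$r > 0, 1L, -1L), stringsAsFactors = FALSE)
  } else NULL
  TaxonNetwork(nodes, edges, stratum = unique(results$stratum)[1L])
}

#' Write the taxon x factor correlation matrix with significance stars
#'
#' Emits two parallel TSV matrices: the Pearson r values and a star matrix
#' (`*`, `**`, `***` at p 0.05/0.01/0.001; empty otherwise) mirroring the
#' usual heatmap annotation.
#'
#' @param results data.frame from [correlateFactors()].
#' @param rPath,starsPath output file paths.
#' @export
writeCorrelationMatrix <- function(results, rPath, starsPath) {
  taxa <- unique(results$taxon_id)
  facs <- unique(results$factor)
  rm_ <- matrix(NA_real_, length(taxa), length(facs),
                dimnames = list(taxa, facs))
  st <- matrix("", length(taxa), length(facs), dimnames = list(taxa, facs))
  for (k in seq_len(nrow(results))) {
    i <- results$taxon_id[k]; j <- results$factor[k]
    rm_[i, j] <- results$r[k]
    p <- results$p[k]
    st[i, j] <- if (is.na(p)) "" else if (p <= 0.001) "***"
                else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  }
  write.table(data.frame(taxon_id = taxa, rm_, check.names = FALSE),
              rPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(taxon_id = taxa, st, check.names = FALSE),
              starsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(rPath, starsPath))
}
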