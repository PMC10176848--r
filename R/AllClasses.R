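#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

.checkAxes <- function(object) {
  m <- assay(object, 1L)
  msg <- character(0)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "taxon and sample ids (dimnames) are required")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, sprintf("duplicated taxon id(s): %s",
                            paste(unique(rownames(m)[duplicated(rownames(m))]),
                                  collapse = ", ")))
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, sprintf("duplicated sample id(s): %s",
                            paste(unique(colnames(m)[duplicated(colnames(m))]),
                                  collapse = ", ")))
  }
  msg
}

#' Taxon x sample count table
#'
#' A `SummarizedExperiment` whose single `counts` assay holds non-negative
#' integer read counts with rank-prefixed taxon ids (e.g. `"g__Prevotella_7"`,
#' `"o__Saccharimonadales"`) as rownames and sample ids as colnames. Sample
#' metadata, when available, lives in `colData`.
#'
#' @seealso [AbundanceTable()], [toRelative()], [subtractControl()]
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  m <- assay(object, "counts")
  msg <- .checkAxes(object)
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    msg <- c(msg, "counts must be finite numbers")
  else {
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(m - round(m)) > 1e-8)) msg <- c(msg, "counts must be integers")
  }
  if (length(msg)) msg else TRUE
})

#' Taxon x sample relative-abundance table
#'
#' Same axes as [AbundanceTable-class], values are proportions; every sample
#' column sums to 1 within 1e-9 (zero-total samples are rejected upstream by
#' [toRelative()]).
#'
#' @export
setClass("RelativeAbundanceTable", contains = "SummarizedExperiment")

setValidity("RelativeAbundanceTable", function(object) {
  if (!"relabund" %in% SummarizedExperiment::assayNames(object))
    return("assay 'relabund' is missing")
  m <- assay(object, "relabund")
  msg <- .checkAxes(object)
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m > 1))
    msg <- c(msg, "relative abundances must lie in [0, 1]")
  else if (any(abs(colSums(m) - 1) > 1e-9))
    msg <- c(msg, "sample columns must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Negative-control contamination profile
#'
#' Per-taxon counts observed in a sequenced negative control (pure water run
#' through extraction, amplification and sequencing). Taxa absent from the
#' profile are implicitly zero.
#'
#' @slot counts named non-negative integer vector.
#' @seealso [ControlProfile()], [subtractControl()], [mergeControls()]
#' @export
setClass("ControlProfile", representation(counts = "numeric"))

setValidity("ControlProfile", function(object) {
  ct <- object@counts
  msg <- character(0)
  if (length(ct)) {
    if (is.null(names(ct)) || anyDuplicated(names(ct)))
      msg <- c(msg, "control counts need unique taxon-id names")
    if (anyNA(ct) || any(ct < 0))
      msg <- c(msg, "control counts must be non-negative")
    else if (any(abs(ct - round(ct)) > 1e-8))
      msg <- c(msg, "control counts must be integers")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the correlation/network stage
#'
#' @slot method `"spearman"` (rank) or `"pearson"`.
#' @slot rThreshold minimum absolute correlation for an edge (default 0.5).
#' @slot alpha significance level for the resampled p-value (default 0.05).
#' @slot nResamples number of resamples (default 999, minimum 99).
#' @slot nullScheme `"permutation"` (default; exchangeable null by permuting
#'   one vector, exact enumeration when n! <= nResamples) or
#'   `"bootstrap_sign"` (paired bootstrap, two-sided sign test on rho).
#' @slot useCounts correlate raw counts instead of relative abundances.
#' @slot seed integer root seed; per-pair substreams are derived from it so
#'   results do not depend on pair evaluation order.
#' @seealso [correlationConfig()], [buildNetwork()]
#' @export
setClass("CorrelationConfig",
         representation(method = "character", rThreshold = "numeric",
                        alpha = "numeric", nResamples = "integer",
                        nullScheme = "character", useCounts = "logical",
                        seed = "integer"))

setValidity("CorrelationConfig", function(object) {
  msg <- character(0)
  if (!object@method %in% c("spearman", "pearson"))
    msg <- c(msg, "method must be 'spearman' or 'pearson'")
  if (!object@nullScheme %in% c("permutation", "bootstrap_sign"))
    msg <- c(msg, "nullScheme must be 'permutation' or 'bootstrap_sign'")
  if (object@rThreshold <= 0 || object@rThreshold >= 1)
    msg <- c(msg, "rThreshold must lie in (0, 1)")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@nResamples < 99L) msg <- c(msg, "nResamples must be >= 99")
  if (length(msg)) msg else TRUE
})

#' Filtered signed correlation network over taxa
#'
#' Nodes are all taxa of the input stratum (isolated nodes allowed) and carry
#' their mean relative abundance; edges survive the joint filter
#' |rho| >= rThreshold and p < alpha, are canonically oriented
#' (`taxon_a < taxon_b`) and carry rho, the resampled p and the sign.
#'
#' @slot nodes data.frame with columns `taxon_id`, `abundance`.
#' @slot edges data.frame with columns `taxon_a`, `taxon_b`, `method`,
#'   `rho`, `p`, `sign`.
#' @slot stratum description of the sample subset used.
#' @seealso [buildNetwork()], [writeNetwork()], [partitionCommunities()]
#' @export
setClass("TaxonNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        stratum = "character"))

setValidity("TaxonNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  msg <- character(0)
  if (!all(c("taxon_id", "abundance") %in% names(nd)))
    msg <- c(msg, "nodes need columns taxon_id, abundance")
  if (!all(c("taxon_a", "taxon_b", "method", "rho", "p", "sign") %in% names(ed)))
    msg <- c(msg, "edges need columns taxon_a, taxon_b, method, rho, p, sign")
  if (!length(msg) && nrow(ed)) {
    if (any(ed$taxon_a == ed$taxon_b)) msg <- c(msg, "self-edges are not allowed")
    if (any(ed$taxon_a > ed$taxon_b))
      msg <- c(msg, "edges must be oriented taxon_a < taxon_b")
    if (anyDuplicated(paste(ed$taxon_a, ed$taxon_b)))
      msg <- c(msg, "duplicate edges are not allowed")
    if (!all(c(ed$taxon_a, ed$taxon_b) %in% nd$taxon_id))
      msg <- c(msg, "every edge endpoint must be a node")
    if (any(abs(ed$rho) > 1 + 1e-12)) msg <- c(msg, "rho must lie in [-1, 1]")
    if (any(ed$sign != ifelse(ed$rho > 0, 1, -1)))
      msg <- c(msg, "edge sign must match sign(rho)")
  }
  if (!length(msg) && anyDuplicated(nd$taxon_id))
    msg <- c(msg, "duplicate node ids")
  if (length(msg)) msg else TRUE
})

#' Community partition of a taxon network
#'
#' Communities are the connected components (>= minSize nodes) of the
#' positive-edge subgraph, so every member positively correlates with at
#' least one co-member (principle 2) and no positive edge joins two distinct
#' communities (principle 3). Negative inter-community edges are recorded in
#' `interCommunityNegative`, not violations.
#'
#' @slot membership named integer vector over all network nodes; `NA` =
#'   unassigned (isolated or in a component smaller than minSize).
#' @slot violations data.frame of positive edges breaching principle 3
#'   (empty by construction under the component rule; kept for audits).
#' @slot interCommunityNegative data.frame of negative edges between
#'   distinct communities.
#' @slot coreMatch data.frame mapping community labels to reference
#'   communities (filled by [matchToReference()]).
#' @export
setClass("CommunityAssignment",
         representation(membership = "integer", violations = "data.frame",
                        interCommunityNegative = "data.frame",
                        coreMatch = "data.frame"))

setValidity("CommunityAssignment", function(object) {
  mb <- object@membership
  msg <- character(0)
  if (length(mb) && (is.null(names(mb)) || anyDuplicated(names(mb))))
    msg <- c(msg, "membership needs unique taxon-id names")
  if (any(!is.na(mb) & mb < 1L))
    msg <- c(msg, "community labels must be integers >= 1")
  if (length(msg)) msg else TRUE
})

#' Per-community degree statistics
#'
#' @slot degrees named list: community label -> integer vector of member
#'   degrees in the full filtered network (edges of either sign).
#' @slot table data.frame with columns `community`, `n`, `mean_degree`.
#' @export
setClass("DegreeSummary",
         representation(degrees = "list", table = "data.frame"))

#' Parameterization of the planted-structure cohort generator
#'
#' Defaults mirror the modelled study: four positively-correlated taxon
#' blocks of sizes 12/14/6/8 plus 10 background taxa among the top-50
#' genera; 50 healthy, 26 non-metastatic and 29 metastatic NSCLC samples;
#' community-2 block up-shifted (x2) and blocks 1/3/4 down-shifted (x0.6) in
#' NSCLC; block 1 and part of block 2 further up-shifted (x1.8) with
#' metastasis; immune-cell factors coupled (0.8) to the block-2 latent in
#' metastatic samples only; multinomial sequencing depth 20,000; a fixed
#' 5-taxon contaminant profile added to every sample and reported as the
#' negative control.
#'
#' @seealso [syntheticSpec()], [generateDataset()], [truthTable()]
#' @export
setClass("SyntheticSpec",
         representation(blockSizes = "integer", nBackground = "integer",
                        withinBlockRho = "numeric", crossBlockRho = "numeric",
                        nHealthy = "integer", nNoMet = "integer",
                        nMet = "integer",
                        diseaseEffectUp = "numeric",
                        diseaseEffectDown = "numeric",
                        metastasisEffect = "numeric",
                        factorCoupling = "numeric",
                        factorNoiseSd = "numeric",
                        markerCoupling = "numeric",
                        sigmaLog = "numeric",
                        depth = "integer",
                        contaminantCounts = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (length(object@blockSizes) != 4L || any(object@blockSizes < 2L))
    msg <- c(msg, "blockSizes must be four integers >= 2")
  if (object@withinBlockRho < 0 || object@withinBlockRho >= 1)
    msg <- c(msg, "withinBlockRho must lie in [0, 1)")
  if (abs(object@crossBlockRho) >= 1)
    msg <- c(msg, "crossBlockRho must lie in (-1, 1)")
  if (any(c(object@diseaseEffectUp, object@diseaseEffectDown,
            object@metastasisEffect) <= 0))
    msg <- c(msg, "effect multipliers must be > 0")
  if (min(object@nHealthy, object@nNoMet, object@nMet) < 4L)
    msg <- c(msg, "each cohort needs >= 4 samples")
  if (object@sigmaLog <= 0) msg <- c(msg, "sigmaLog must be > 0")
  if (object@depth < 100L) msg <- c(msg, "depth must be >= 100")
  if (any(object@contaminantCounts < 0))
    msg <- c(msg, "contaminant counts must be non-negative")
  # the implied latent correlation matrix must be positive semi-definite
  rhoP <- 2 * sin(pi * object@withinBlockRho / 6)
  k <- max(object@blockSizes)
  if (rhoP < -1 / (k - 1))
    msg <- c(msg, "within-block correlation matrix is not positive semi-definite")
  if (length(msg)) msg else TRUE
})
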