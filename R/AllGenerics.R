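#' @import methods
#' @importFrom stats cor pt qt sd p.adjust wilcox.test rnorm rmultinom rexp
#'   setNames
#' @importFrom utils read.delim write.table head
NULL

#' Taxon identifiers of a table or network
#'
#' @param x an object with a taxon axis.
#' @return Character vector of taxon ids (rank-prefixed, e.g.
#'   `"g__Prevotella_7"`).
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))

#' Sample identifiers
#'
#' @param x an object with a sample axis.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Relative-abundance matrix
#'
#' @param x a [RelativeAbundanceTable-class].
#' @return Numeric taxon x sample matrix of proportions.
#' @export
setGeneric("relabund", function(x) standardGeneric("relabund"))

#' Convert counts to relative abundances
#'
#' @param x an [AbundanceTable-class].
#' @return A [RelativeAbundanceTable-class]; every sample column sums to 1.
#' @export
setGeneric("toRelative", function(x) standardGeneric("toRelative"))

#' Keep the most abundant taxa
#'
#' @param x a [RelativeAbundanceTable-class].
#' @param n number of taxa to retain.
#' @export
setGeneric("selectTopTaxa", function(x, n) standardGeneric("selectTopTaxa"))

#' Subtract a negative-control profile from every sample
#'
#' @param x an [AbundanceTable-class].
#' @param control a [ControlProfile-class].
#' @export
setGeneric("subtractControl",
           function(x, control) standardGeneric("subtractControl"))

#' Serialize a network to disk
#'
#' @param net a [TaxonNetwork-class].
#' @param path output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
setGeneric("writeNetwork",
           function(net, path, format = c("graphml", "edge_tsv"))
             standardGeneric("writeNetwork"))

#' Partition a network into communities
#'
#' @param net a [TaxonNetwork-class].
#' @param minSize smallest admissible community (default 2).
#' @export
setGeneric("partitionCommunities",
           function(net, minSize = 2L) standardGeneric("partitionCommunities"))

#' Match detected communities to reference core-member lists
#'
#' @param assignment a [CommunityAssignment-class].
#' @param cores named list of core taxon-id vectors (see [referenceCores()]).
#' @export
setGeneric("matchToReference",
           function(assignment, cores) standardGeneric("matchToReference"))

#' Per-community degree statistics
#'
#' @param net a [TaxonNetwork-class].
#' @param assignment a [CommunityAssignment-class] derived from `net`.
#' @param withinCommunityOnly count only within-community edges?
#' @export
setGeneric("degreeSummary",
           function(net, assignment, withinCommunityOnly = FALSE)
             standardGeneric("degreeSummary"))

#' Community membership vector
#'
#' @param x a [CommunityAssignment-class].
#' @return Named integer vector; `NA` marks unassigned taxa.
#' @export
setGeneric("communityMembership",
           function(x) standardGeneric("communityMembership"))

#' Generate a synthetic cohort dataset
#'
#' @param spec a [SyntheticSpec-class].
#' @export
setGeneric("generateDataset",
           function(spec) standardGeneric("generateDataset"))

#' Planted structure of a synthetic specification
#'
#' @param spec a [SyntheticSpec-class].
#' @export
setGeneric("truthTable", function(spec) standardGeneric("truthTable"))
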