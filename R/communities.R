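#' Reference community core members
#'
#' The four lung-mucosa bacterial communities' core member lists, shipped as
#' a packaged TSV (columns `community`, `taxon_id`). Community 1:
#' Saccharimonadales (order), Sphingomonas, Bradyrhizobium. Community 2:
#' Neisseria, Alloprevotella, Prevotella, Peptostreptococcus, Haemophilus,
#' Granulicatella. Community 3: Burkholderia-Caballeronia-Paraburkholderia,
#' Acinetobacter, Rhodococcus. Community 4: Prevotella_9, Lactobacillus,
#' Megamonas (the Prevotella core of community 4 is disambiguated by its
#' numeric suffix to keep the lists disjoint).
#'
#' @param path optional path to an alternative cores TSV.
#' @return Named list `community 1..4` -> character vector of taxon ids.
#' @export
referenceCores <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_cores.tsv",
                        package = "MucosaNet", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("community", "taxon_id") %in% names(df)))
  split(df$taxon_id, df$community)
}

#' @rdname partitionCommunities
#' @details Operationalizes the three community principles: (1) a community
#'   is a closely, densely connected net -- here a connected component of the
#'   positive-edge subgraph; (2) every member positively correlates with at
#'   least one co-member -- guaranteed for components of size >= `minSize`
#'   (default 2; singletons cannot satisfy this and stay unassigned); (3) a
#'   community has no positive correlation with other communities --
#'   vacuously true across components, asserted into the (empty) `violations`
#'   slot. Negative inter-community edges are permitted and recorded.
#'   Community labels are deterministic: decreasing component size, ties
#'   broken by the lexicographically smallest member.
setMethod("partitionCommunities", "TaxonNetwork",
          function(net, minSize = 2L) {
  g <- asIgraph(net, positiveOnly = TRUE)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  memb <- comp$membership

  sizes <- comp$csize
  keep <- which(sizes >= minSize)
  # deterministic relabelling: size desc, then smallest member asc
  firstMember <- vapply(seq_along(sizes),
                        function(k) min(ids[memb == k]), character(1))
  ord <- keep[order(-sizes[keep], firstMember[keep])]
  relabel <- rep(NA_integer_, length(sizes))
  relabel[ord] <- seq_along(ord)

  assignment <- setNames(relabel[memb], ids)
  ed <- net@edges
  lab <- function(t) assignment[t]
  negInter <- ed[ed$sign < 0 & !is.na(lab(ed$taxon_a)) &
                   !is.na(lab(ed$taxon_b)) &
                   lab(ed$taxon_a) != lab(ed$taxon_b), , drop = FALSE]
  posInter <- ed[ed$sign > 0 & !is.na(lab(ed$taxon_a)) &
                   !is.na(lab(ed$taxon_b)) &
                   lab(ed$taxon_a) != lab(ed$taxon_b), , drop = FALSE]
  stopifnot(nrow(posInter) == 0L)  # principle 3, by construction
  rownames(negInter) <- NULL
  new("CommunityAssignment", membership = assignment,
      violations = posInter, interCommunityNegative = negInter,
      coreMatch = data.frame())
})

#' @rdname communityMembership
setMethod("communityMembership", "CommunityAssignment",
          function(x) x@membership)

setMethod("show", "CommunityAssignment", function(object) {
  mb <- object@membership
  tab <- table(mb, useNA = "no")
  cat(sprintf("CommunityAssignment: %d communities, %d/%d taxa assigned\n",
              length(tab), sum(!is.na(mb)), length(mb)))
  if (length(tab))
    cat("  sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  if (nrow(object@coreMatch)) {
    m <- object@coreMatch
    cat("  core matches:",
        paste(sprintf("%d->%s(%d)", m$community, m$reference, m$overlap),
              collapse = ", "), "\n")
  }
})

#' @rdname matchToReference
#' @details Each detected community is mapped to the reference community
#'   whose core-member list it overlaps most (ties to the smaller reference
#'   index); zero-overlap communities stay unmatched (`NA`). The mapping need
#'   not be injective; duplicated reference assignments are flagged in the
#'   `duplicated` column.
#' @return The assignment with a filled `coreMatch` slot (columns
#'   `community`, `reference`, `overlap`, `duplicated`).
setMethod("matchToReference", c("CommunityAssignment", "list"),
          function(assignment, cores) {
  mb <- assignment@membership
  labs <- sort(unique(mb[!is.na(mb)]))
  refNames <- names(cores)
  rows <- lapply(labs, function(l) {
    members <- names(mb)[!is.na(mb) & mb == l]
    ov <- vapply(cores, function(cl) length(intersect(members, cl)),
                 integer(1))
    best <- if (max(ov) == 0L) NA_character_ else refNames[which.max(ov)]
    data.frame(community = l, reference = best, overlap = max(ov),
               stringsAsFactors = FALSE)
  })
  cm <- do.call(rbind, rows)
  cm$duplicated <- !is.na(cm$reference) & cm$reference %in%
    cm$reference[duplicated(cm$reference) & !is.na(cm$reference)]
  assignment@coreMatch <- cm
  assignment
})

#' @rdname degreeSummary
#' @details A member's degree is its number of incident edges of either sign
#'   in the full filtered network (set `withinCommunityOnly = TRUE` to count
#'   only edges joining two members of the same community).
setMethod("degreeSummary", c("TaxonNetwork", "CommunityAssignment"),
          function(net, assignment, withinCommunityOnly = FALSE) {
  mb <- assignment@membership
  if (!all(names(mb) %in% net@nodes$taxon_id))
    stop("assignment refers to taxa absent from the network")
  ed <- net@edges
  if (withinCommunityOnly && nrow(ed)) {
    la <- mb[ed$taxon_a]; lb <- mb[ed$taxon_b]
    ed <- ed[!is.na(la) & !is.na(lb) & la == lb, , drop = FALSE]
  }
  deg <- setNames(integer(nrow(net@nodes)), net@nodes$taxon_id)
  if (nrow(ed)) {
    t1 <- table(ed$taxon_a); t2 <- table(ed$taxon_b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  labs <- sort(unique(mb[!is.na(mb)]))
  degrees <- lapply(labs, function(l) deg[names(mb)[!is.na(mb) & mb == l]])
  names(degrees) <- as.character(labs)
  tab <- data.frame(community = labs,
                    n = vapply(degrees, length, integer(1)),
                    mean_degree = vapply(degrees, function(d) mean(d),
                                         numeric(1)))
  rownames(tab) <- NULL
  new("DegreeSummary", degrees = degrees, table = tab)
})

setMethod("show", "DegreeSummary", function(object) {
  cat("DegreeSummary:\n")
  print(object@table, row.names = FALSE)
})

#' Degree table accessor
#' @param x a [DegreeSummary-class].
#' @export
degreeTable <- function(x) x@table

#' Per-member degrees of one community
#' @param x a [DegreeSummary-class].
#' @param community community label.
#' @export
communityDegrees <- function(x, community) {
  key <- as.character(community)
  if (!key %in% names(x@degrees)) stop("unknown community label: ", community)
  x@degrees[[key]]
}

#' Compare a community's degree counts between two networks
#'
#' Two-sided pooled-variance two-sample t-test on the per-node degree lists
#' of the reference community named `community`, matched in both networks
#' via their core-match tables (so "community 2" means the detected
#' community matched to reference community 2 in each network).
#'
#' @param netA,netB [TaxonNetwork-class] objects (e.g. healthy vs NSCLC).
#' @param assignmentA,assignmentB matched [CommunityAssignment-class]
#'   objects (after [matchToReference()]).
#' @param community reference community name to compare.
#' @param withinCommunityOnly passed to [degreeSummary()].
#' @return List with `t`, `df`, `p`, `meanA`, `meanB`.
#' @export
compareDegree <- function(netA, netB, assignmentA, assignmentB, community,
                          withinCommunityOnly = FALSE) {
  pick <- function(net, asg) {
    cm <- asg@coreMatch
    if (!nrow(cm)) stop("assignment has no core match; run matchToReference()")
    hit <- cm$community[!is.na(cm$reference) & cm$reference == community]
    if (!length(hit))
      stop("community '", community, "' not matched in network [",
           net@stratum, "]")
    ds <- degreeSummary(net, asg, withinCommunityOnly = withinCommunityOnly)
    communityDegrees(ds, hit[1L])
  }
  dA <- pick(netA, assignmentA)
  dB <- pick(netB, assignmentB)
  if (length(dA) < 2L || length(dB) < 2L)
    stop("need >= 2 members per network for the t-test")
  res <- pooledT(dA, dB)
  c(res, list(meanA = mean(dA), meanB = mean(dB)))
}

#' Mean clustering coefficient of a community (optional statistic)
#'
#' Average local transitivity (treating the signed network as unsigned) over
#' the members of one community; isolated or degree-1 members contribute 0.
#'
#' @param net a [TaxonNetwork-class].
#' @param assignment a [CommunityAssignment-class].
#' @param community community label.
#' @export
clusteringCoefficient <- function(net, assignment, community) {
  g <- asIgraph(net)
  members <- names(assignment@membership)[
    !is.na(assignment@membership) & assignment@membership == community]
  if (!length(members)) stop("unknown or empty community: ", community)
  tr <- igraph::transitivity(g, type = "local", vids = members,
                             isolates = "zero")
  mean(tr)
}
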