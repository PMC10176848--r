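#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors over the same
#' items; 1 for identical partitions, ~0 for independent ones. `NA` labels
#' are treated as one extra category.
#'
#' @param a,b label vectors of equal length.
#' @return Number <= 1.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- addNA(as.factor(a), ifany = TRUE)
  b <- addNA(as.factor(b), ifany = TRUE)
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(ch2(tab))
  sumI <- sum(ch2(rowSums(tab)))
  sumJ <- sum(ch2(colSums(tab)))
  expIdx <- sumI * sumJ / ch2(n)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expIdx) return(1)
  (sumIj - expIdx) / (maxIdx - expIdx)
}

#' Score a community assignment against a planted block structure
#'
#' Adjusted Rand index between detected community labels and the planted
#' blocks, computed over the planted (non-background) taxa; unassigned taxa
#' count as their own category.
#'
#' @param assignment a [CommunityAssignment-class].
#' @param truth data.frame from [truthTable()]`$taxa` (columns `taxon_id`,
#'   `block`).
#' @return ARI in \[-1, 1\].
#' @export
scoreRecovery <- function(assignment, truth) {
  planted <- truth[truth$block != "none", ]
  mb <- communityMembership(assignment)
  miss <- setdiff(planted$taxon_id, names(mb))
  if (length(miss))
    stop("assignment missing planted taxa: ", paste(miss, collapse = ", "))
  adjustedRandIndex(planted$block, mb[planted$taxon_id])
}
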