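#' Shannon diversity index
#'
#' H = -sum(p_i * ln p_i) over p_i > 0 (natural log).
#'
#' @param p vector of proportions summing to 1.
#' @return Non-negative number.
#' @examples
#' shannonIndex(rep(1/8, 8))  # ln 8
#' @export
shannonIndex <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Chao1 richness estimate (optional alpha-diversity statistic)
#'
#' S_obs + F1^2/(2*F2) with singleton/doubleton counts F1/F2; the
#' bias-corrected form S_obs + F1*(F1-1)/2 is used when F2 = 0.
#'
#' @param counts integer count vector for one sample.
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0))
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  if (f2 == 0) sObs + f1 * (f1 - 1) / 2 else sObs + f1^2 / (2 * f2)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' 1 - 2*sum(min(a_i, b_i)) / sum(a_i + b_i) over a shared taxon axis.
#'
#' @param a,b non-negative abundance vectors of equal length.
#' @return Number in \[0, 1\].
#' @export
brayCurtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a + b)
  if (tot == 0) stop("both samples are all-zero")
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Bray-Curtis distance matrix over a table's samples
#'
#' @param table a [RelativeAbundanceTable-class] (or
#'   [AbundanceTable-class]).
#' @return Symmetric sample x sample matrix.
#' @export
brayCurtisMatrix <- function(table) {
  m <- if (is(table, "RelativeAbundanceTable")) relabund(table)
       else assay(table, "counts")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers -d^2/2 and eigendecomposes the Gram matrix; axes are
#' sorted by decreasing eigenvalue and negative eigenvalues (possible for
#' non-Euclidean distances such as Bray-Curtis) are reported, not silently
#' dropped. Coordinates are returned for positive-eigenvalue axes only.
#'
#' @param d symmetric zero-diagonal distance matrix.
#' @return List with `coordinates` (samples x axes) and `eigenvalues`
#'   (all of them, descending).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with a zero diagonal")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-10)
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords, eigenvalues = eg$values)
}

#' PERMANOVA on a distance matrix
#'
#' Permutation test of group separation (via `vegan::adonis2`);
#' p = (1 + #\{F_perm >= F_obs\}) / (nPerm + 1).
#'
#' @param d symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups).
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return List with `F`, `p`.
#' @export
permanova <- function(d, labels, nPerm = 999L, seed = 1L) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 groups")
  stopifnot(length(labels) == nrow(d))
  fit <- withr::with_seed(as.integer(seed),
    vegan::adonis2(stats::as.dist(d) ~ labels, permutations = nPerm))
  list(F = fit$F[1L], p = fit$`Pr(>F)`[1L])
}

#' Wilcoxon rank-sum differential abundance with BH correction
#'
#' Per-taxon two-sided rank-sum test between two sample groups: exact when
#' the combined n is <= 20 and there are no ties, tie-corrected normal
#' approximation (with continuity correction) otherwise. Raw p-values are
#' Benjamini-Hochberg adjusted.
#'
#' @param table a [RelativeAbundanceTable-class] (or
#'   [AbundanceTable-class]).
#' @param groups two-level label vector named by (or aligned with) the
#'   table's samples; >= 3 samples per level.
#' @return data.frame with taxon_id, the two group means, statistic, p, q,
#'   test.
#' @export
wilcoxonFdr <- function(table, groups) {
  m <- if (is(table, "RelativeAbundanceTable")) relabund(table)
       else assay(table, "counts")
  groups <- .alignGroups(groups, colnames(m), nMin = 3L)
  lv <- levels(groups)
  i1 <- which(groups == lv[1L]); i2 <- which(groups == lv[2L])
  res <- lapply(rownames(m), function(tx) {
    x <- m[tx, i1]; y <- m[tx, i2]
    useExact <- (length(x) + length(y)) <= 20L &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = useExact,
                                       correct = !useExact))
    data.frame(taxon_id = tx, mean_a = mean(x), mean_b = mean(y),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", lv)
  out$q <- p.adjust(out$p, method = "BH")
  out$test <- "wilcoxon"
  rownames(out) <- NULL
  out
}

#' Two-stage step-up (adaptive) FDR adjustment
#'
#' Stage 1 runs Benjamini-Hochberg at level q' = q/(1+q) to estimate the
#' number of true nulls m0 = m - r1; stage 2 re-runs BH at level q*m/m0.
#' Returned q-values are the BH-adjusted p scaled by m0/m, so a feature is
#' discovered iff its q-value is <= q (no discoveries at all when r1 = 0).
#'
#' @param p vector of raw p-values.
#' @param q nominal FDR level (default 0.05).
#' @return List with `qvalues`, `discoveries` (logical), `m0`.
#' @export
bkyAdjust <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  m <- length(p)
  bh <- p.adjust(p, method = "BH")
  r1 <- sum(bh <= q / (1 + q))
  if (r1 == 0L)
    return(list(qvalues = rep(1, m), discoveries = rep(FALSE, m), m0 = m))
  if (r1 == m)  # all nulls rejected at stage 1: m0 = 0, everything discovered
    return(list(qvalues = numeric(m), discoveries = rep(TRUE, m), m0 = 0L))
  m0 <- m - r1
  qv <- pmin(1, bh * m0 / m)
  list(qvalues = qv, discoveries = qv <= q, m0 = m0)
}

#' Per-feature t-tests with two-stage step-up FDR
#'
#' Pooled-variance two-sample t-test per feature (row), adjusted by
#' [bkyAdjust()]. Features with zero variance in both groups get p = 1 and
#' a flag.
#'
#' @param table feature x sample matrix, [RelativeAbundanceTable-class] or
#'   [AbundanceTable-class].
#' @param groups two-level label vector (>= 2 samples per level).
#' @param q nominal FDR level.
#' @return data.frame with taxon_id, group means, t, p, q, discovery, flag.
#' @export
multiTBky <- function(table, groups, q = 0.05) {
  m <- if (is(table, "RelativeAbundanceTable")) relabund(table)
       else if (is(table, "AbundanceTable")) assay(table, "counts")
       else as.matrix(table)
  groups <- .alignGroups(groups, colnames(m), nMin = 2L)
  lv <- levels(groups)
  i1 <- which(groups == lv[1L]); i2 <- which(groups == lv[2L])
  res <- lapply(seq_len(nrow(m)), function(k) {
    x <- m[k, i1]; y <- m[k, i2]
    if (sd(x) == 0 && sd(y) == 0)
      data.frame(t = 0, p = 1, flag = "zero_variance",
                 stringsAsFactors = FALSE)
    else {
      tt <- pooledT(x, y)
      data.frame(t = tt$t, p = tt$p, flag = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out <- data.frame(taxon_id = rownames(m), mean_a = rowMeans(m[, i1, drop = FALSE]),
                    mean_b = rowMeans(m[, i2, drop = FALSE]), out,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", lv)
  adj <- bkyAdjust(out$p, q = q)
  out$q <- adj$qvalues
  out$discovery <- adj$discoveries
  out$test <- "t_multi"
  rownames(out) <- NULL
  out
}

#' Group summary with Student-t confidence interval
#'
#' mean, sample SD (n-1 denominator) and the two-sided t interval
#' mean +/- t(1-(1-level)/2, n-1) * SD/sqrt(n).
#'
#' @param values numeric vector (n >= 2).
#' @param level confidence level (default 0.95).
#' @param variable,group optional labels carried into the output.
#' @return One-row data.frame: variable, group, n, mean, sd, ci_low,
#'   ci_high, level.
#' @export
summarizeGroup <- function(values, level = 0.95, variable = NA_character_,
                           group = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need n >= 2")
  groupSummaryFromStats(mean(values), sd(values), length(values),
                        level = level, variable = variable, group = group)
}

#' Group summary from printed (mean, SD, n) statistics
#'
#' Rebuilds the Student-t confidence interval from already-summarized
#' statistics, as printed in cohort tables.
#'
#' @param mean,sd,n summary statistics (sample SD, n >= 2).
#' @param level confidence level.
#' @param variable,group optional labels.
#' @return One-row data.frame as in [summarizeGroup()].
#' @examples
#' # lymphocyte density, non-metastatic NSCLC stratum
#' groupSummaryFromStats(1.30, 0.52, 26)  # CI (1.09, 1.51)
#' @export
groupSummaryFromStats <- function(mean, sd, n, level = 0.95,
                                  variable = NA_character_,
                                  group = NA_character_) {
  stopifnot(n >= 2, sd >= 0, level > 0, level < 1)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  data.frame(variable = variable, group = group, n = as.integer(n),
             mean = mean, sd = sd, ci_low = mean - half,
             ci_high = mean + half, level = level,
             stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample t-test (raw vectors)
#'
#' @param x,y numeric vectors (n >= 2 each).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pooledT <- function(x, y) {
  twoSampleTFromStats(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries (sample SDs).
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' twoSampleTFromStats(1.30, 0.52, 26, 1.61, 0.55, 29)$p  # ~0.037
#' @export
twoSampleTFromStats <- function(meanA, sdA, nA, meanB, sdB, nB) {
  stopifnot(nA >= 2, nB >= 2)
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB) return(list(t = 0, df = nA + nB - 2, p = 1))
    stop("degenerate (zero) variance in both groups with unequal means")
  }
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
  tstat <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
  df <- nA + nB - 2
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# align a group label vector with sample ids, check two levels and sizes
.alignGroups <- function(groups, samples, nMin) {
  if (!is.null(names(groups))) {
    miss <- setdiff(samples, names(groups))
    if (length(miss))
      stop("groups missing for sample(s): ", paste(miss, collapse = ", "))
    groups <- groups[samples]
  } else stopifnot(length(groups) == length(samples))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly two group levels")
  if (any(table(groups) < nMin))
    stop("each group needs >= ", nMin, " samples")
  groups
}
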