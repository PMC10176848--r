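#' Build a CorrelationConfig
#'
#' Defaults follow the modelled study's filter: |rho| >= 0.5 and p < 0.05
#' supported by 999 resamples. The resampling null defaults to a permutation
#' scheme (one vector independently permuted), which gives a valid
#' exchangeable null; `bootstrap_sign` mirrors a paired-bootstrap reading of
#' the procedure (two-sided sign test on the resampled rho distribution).
#'
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param rThreshold minimum |rho| for an edge, in (0,1).
#' @param alpha significance level, strict (`p < alpha`).
#' @param nResamples resamples for the p-value (>= 99).
#' @param nullScheme `"permutation"` or `"bootstrap_sign"`.
#' @param useCounts correlate raw counts instead of relative abundances
#'   (irrelevant for Spearman, which is rank-invariant to per-sample
#'   rescaling).
#' @param seed integer root seed.
#' @return A [CorrelationConfig-class].
#' @export
correlationConfig <- function(method = c("spearman", "pearson"),
                              rThreshold = 0.5, alpha = 0.05,
                              nResamples = 999L,
                              nullScheme = c("permutation", "bootstrap_sign"),
                              useCounts = FALSE, seed = 1L) {
  new("CorrelationConfig", method = match.arg(method),
      rThreshold = rThreshold, alpha = alpha,
      nResamples = as.integer(nResamples),
      nullScheme = match.arg(nullScheme),
      useCounts = useCounts, seed = as.integer(seed))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank-transformed vectors (ties get
#' average ranks), identical to the classical 1 - 6*sum(d^2)/(n(n^2-1))
#' formula when there are no ties.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\]; `NA` (with a message attribute `"constant"`)
#'   when either vector is constant.
#' @examples
#' spearmanRho(1:3, c(10, 20, 30))  # 1
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(NA_real_, flag = "constant"))
  cor(rank(x), rank(y))
}

# all n! permutations of 1..n as an n! x n matrix (n small)
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

# standardized version for fast correlation via crossprod
.std <- function(v) {
  s <- sd(v)
  if (s == 0) return(NULL)
  (v - mean(v)) / s
}

.obsRho <- function(x, y, method) {
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# permutation p; exact enumeration when n! <= B, Monte Carlo otherwise.
# assumes RNG state already set by the caller.
.permP <- function(x, y, method, B) {
  n <- length(x)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  xs <- .std(x); ys <- .std(y)
  if (is.null(xs) || is.null(ys)) return(list(p = 1, flag = "constant"))
  rObs <- sum(xs * ys) / (n - 1)
  eps <- 1e-12
  nf <- factorial(n)
  if (nf <= B) {
    pm <- .allPerms(n)
    rb <- as.vector(matrix(ys[pm], nrow(pm), n) %*% xs) / (n - 1)
    p <- sum(abs(rb) >= abs(rObs) - eps) / nf   # identity included => p >= 1/n!
  } else {
    idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
    # for spearman, permuting the (standardized) ranks equals ranking the
    # permuted vector, so no re-ranking is needed
    Yp <- matrix(ys[idx], n, B)
    rb <- as.vector(crossprod(xs, Yp)) / (n - 1)
    p <- (1 + sum(abs(rb) >= abs(rObs) - eps)) / (B + 1)
  }
  list(p = min(p, 1), flag = NA_character_)
}

# paired bootstrap; two-sided sign test on the resampled rho distribution,
# floored at 1/(B+1)
.bootSignP <- function(x, y, method, B) {
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) return(list(p = 1, flag = "constant"))
  rb <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    xb <- x[i]; yb <- y[i]
    if (method == "spearman") { xb <- rank(xb); yb <- rank(yb) }
    rb[b] <- if (sd(xb) == 0 || sd(yb) == 0) 0 else cor(xb, yb)
  }
  p <- 2 * min(mean(rb <= 0), mean(rb >= 0))
  list(p = min(max(p, 1 / (B + 1)), 1), flag = NA_character_)
}

#' Resampling-based correlation p-value
#'
#' Two-sided p-value for the correlation between `x` and `y` under the
#' configured null scheme. The permutation scheme enumerates all n!
#' permutations exactly when n! <= `nResamples` (then p =
#' #\{|rho_perm| >= |rho_obs|\}/n!), and otherwise uses the Monte-Carlo
#' estimator p = (1 + #\{b : |rho_b| >= |rho_obs|\}) / (B + 1), so p is
#' bounded below by 1/(B+1). Constant input yields p = 1 with a flag.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param config a [CorrelationConfig-class]; its seed drives the RNG.
#' @return List with `rho`, `p`, `flag`.
#' @export
resampledP <- function(x, y, config = correlationConfig()) {
  stopifnot(is(config, "CorrelationConfig"),
            length(x) == length(y), length(x) >= 3L)
  rho <- .obsRho(x, y, config@method)
  if (is.na(rho)) return(list(rho = NA_real_, p = 1, flag = "constant"))
  res <- withr::with_seed(config@seed, {
    if (config@nullScheme == "permutation")
      .permP(x, y, config@method, config@nResamples)
    else
      .bootSignP(x, y, config@method, config@nResamples)
  })
  list(rho = rho, p = res$p, flag = res$flag)
}

#' Build the filtered signed co-occurrence network for a stratum
#'
#' Computes all pairwise taxon correlations within the selected samples and
#' keeps an edge iff |rho| >= `rThreshold` AND resampled p < `alpha`. All
#' input taxa become nodes (isolated nodes allowed) carrying their mean
#' relative abundance in the stratum. The resampled p is only evaluated for
#' pairs passing the |rho| filter (the other pairs cannot become edges);
#' each pair draws from its own RNG substream keyed by the canonical pair
#' index, so results are independent of evaluation order and bit-reproducible
#' under a fixed seed.
#'
#' @param table a [RelativeAbundanceTable-class] (or [AbundanceTable-class]
#'   when `config@useCounts`); taxa should already be top-N selected.
#' @param samples sample ids of the stratum (default: all; >= 4 required).
#' @param config a [CorrelationConfig-class].
#' @param stratum description string stored on the network.
#' @return A [TaxonNetwork-class].
#' @export
buildNetwork <- function(table, samples = NULL,
                         config = correlationConfig(), stratum = "all") {
  stopifnot(is(config, "CorrelationConfig"))
  if (!is.null(samples)) table <- subsetSamples(table, samples)
  if (is(table, "AbundanceTable")) {
    m <- if (config@useCounts) assay(table, "counts")
         else relabund(toRelative(table))
    ab <- rowMeans(relabund(toRelative(table)))
  } else if (is(table, "RelativeAbundanceTable")) {
    m <- relabund(table)
    ab <- rowMeans(m)
  } else stop("table must be an AbundanceTable or RelativeAbundanceTable")
  if (ncol(m) < 4L)
    stop("stratum has only ", ncol(m), " samples; >= 4 required")

  n <- ncol(m)
  taxa <- rownames(m)
  X <- t(m)
  R <- suppressWarnings(cor(X, method = config@method))
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  pairIdx <- (pairs[, 2] - 1L) * (pairs[, 2] - 2L) / 2 + pairs[, 1]  # canonical
  cand <- which(!is.na(R[pairs]) & abs(R[pairs]) >= config@rThreshold)

  pairSeeds <- withr::with_seed(config@seed,
                                sample.int(.Machine$integer.max, nrow(pairs)))
  rows <- vector("list", length(cand))
  for (k in seq_along(cand)) {
    i <- pairs[cand[k], 1L]; j <- pairs[cand[k], 2L]
    res <- withr::with_seed(pairSeeds[pairIdx[cand[k]]], {
      if (config@nullScheme == "permutation")
        .permP(X[, i], X[, j], config@method, config@nResamples)
      else
        .bootSignP(X[, i], X[, j], config@method, config@nResamples)
    })
    if (!is.na(res$p) && res$p < config@alpha)
      rows[[k]] <- data.frame(taxon_a = taxa[i], taxon_b = taxa[j],
                              method = config@method, rho = R[i, j],
                              p = res$p, sign = ifelse(R[i, j] > 0, 1L, -1L),
                              stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  TaxonNetwork(data.frame(taxon_id = taxa, abundance = unname(ab),
                          stringsAsFactors = FALSE),
               edges, stratum = stratum)
}
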