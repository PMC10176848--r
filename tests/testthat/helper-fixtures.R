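# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately avoid the package's own code paths.

randomCountTable <- function(nTaxa = 8, nSamples = 6, seed = 1,
                             lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(nTaxa * nSamples, lambda), nTaxa, nSamples,
              dimnames = list(sprintf("g__Taxon%02d", seq_len(nTaxa)),
                              sprintf("S%02d", seq_len(nSamples))))
  AbundanceTable(m)
}

# --- connected components of the positive subgraph, by union-find ---------
unionFindComponents <- function(nodes, posEdges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(posEdges)) for (k in seq_len(nrow(posEdges))) {
    ra <- find(posEdges$taxon_a[k]); rb <- find(posEdges$taxon_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}

# --- BH step-up, coded from the definition --------------------------------
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- two-stage step-up discovery set, straight from the procedure ---------
bkyOracle <- function(p, q = 0.05) {
  m <- length(p)
  bhReject <- function(pv, level) {
    o <- order(pv)
    ok <- pv[o] <= seq_len(m) * level / m
    r <- if (any(ok)) max(which(ok)) else 0L
    rej <- rep(FALSE, m)
    if (r > 0) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  r1 <- sum(bhReject(p, q / (1 + q)))
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bhReject(p, q * m / (m - r1))
}

# --- exact rank-sum p by enumeration over group assignments ---------------
wilcoxEnumOracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n, n1)
  w <- apply(combos, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  mean(abs(w - mu) >= abs(wObs - mu) - 1e-9)
}

# small signed network from an edge list; nodes get unit abundance
makeNet <- function(edgeList, nodes = NULL, stratum = "test") {
  ed <- if (length(edgeList)) {
    do.call(rbind, lapply(edgeList, function(e)
      data.frame(taxon_a = e[[1]], taxon_b = e[[2]], method = "spearman",
                 rho = as.numeric(e[[3]]), p = 0.001,
                 sign = ifelse(as.numeric(e[[3]]) > 0, 1L, -1L),
                 stringsAsFactors = FALSE)))
  } else NULL
  if (is.null(nodes))
    nodes <- sort(unique(unlist(lapply(edgeList, function(e) c(e[[1]], e[[2]])))))
  TaxonNetwork(data.frame(taxon_id = nodes, abundance = 1,
                          stringsAsFactors = FALSE), ed, stratum = stratum)
}
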