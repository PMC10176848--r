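test_that("spearmanRho matches the classical rank formula", {
  expect_equal(spearmanRho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearmanRho(1:3, c(3, 2, 1)), -1)
  # hand-computable no-ties case: 1 - 6*sum(d^2)/(n(n^2-1))
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  d <- rank(x) - rank(y)
  expect_equal(spearmanRho(x, y), 1 - 6 * sum(d^2) / (5 * 24))
  # constant vector flagged
  expect_true(is.na(spearmanRho(c(1, 1, 1), 1:3)))
})

test_that("permutation p equals exhaustive enumeration for tiny n", {
  for (s in 1:4) {
    set.seed(400 + s)
    x <- rnorm(4); y <- rnorm(4)
    rx <- rank(x); ry <- rank(y)
    rObs <- cor(rx, ry)
    perms <- list()
    grid <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    grid <- grid[apply(grid, 1, function(r) length(unique(r)) == 4), ]
    rPerm <- apply(grid, 1, function(ix) cor(rx, ry[ix]))
    pOracle <- mean(abs(rPerm) >= abs(rObs) - 1e-12)
    res <- resampledP(x, y, correlationConfig(seed = s))
    expect_equal(res$p, pOracle)
    expect_equal(res$rho, rObs)
  }
})

test_that("permutation p attains its floor for perfect monotone data", {
  x <- 1:30; y <- x^3
  res <- resampledP(x, y, correlationConfig(nResamples = 999L, seed = 5))
  expect_equal(res$p, 1 / 1000)
  expect_equal(res$rho, 1)
  # constant input: p = 1 with flag
  res0 <- resampledP(rep(2, 10), rnorm(10), correlationConfig(seed = 1))
  expect_equal(res0$p, 1)
  expect_identical(res0$flag, "constant")
})

test_that("resampled p is reproducible and bounded below by 1/(B+1)", {
  set.seed(77); x <- rnorm(20); y <- rnorm(20)
  cfg <- correlationConfig(nResamples = 199L, seed = 123)
  expect_identical(resampledP(x, y, cfg), resampledP(x, y, cfg))
  ps <- replicate(20, {
    xy <- matrix(rnorm(16), 8)
    resampledP(xy[, 1], xy[, 2], cfg)$p
  })
  expect_true(all(ps >= 1 / 200))
  # bootstrap_sign scheme shares the floor and determinism
  cfgB <- correlationConfig(nResamples = 199L, seed = 9,
                            nullScheme = "bootstrap_sign")
  expect_identical(resampledP(x, y, cfgB), resampledP(x, y, cfgB))
  expect_gte(resampledP(1:20, (1:20)^2, cfgB)$p, 1 / 200)
})

test_that("filtered edge set equals brute force on small tables", {
  for (s in 1:3) {
    tab <- toRelative(randomCountTable(6, 12, seed = 500 + s, lambda = 15))
    cfg <- correlationConfig(nResamples = 199L, seed = s)
    net <- buildNetwork(tab, config = cfg)
    m <- relabund(tab)
    ids <- rownames(m)
    oracle <- list()
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      rho <- suppressWarnings(cor(m[i, ], m[j, ], method = "spearman"))
      if (is.na(rho) || abs(rho) < cfg@rThreshold) next
      # reproduce the per-pair substream the builder uses
      pairIdx <- (j - 1) * (j - 2) / 2 + i
      seeds <- withr::with_seed(cfg@seed,
                                sample.int(.Machine$integer.max, 15))
      p <- withr::with_seed(seeds[pairIdx],
        MucosaNet:::.permP(m[i, ], m[j, ], "spearman", 199L))$p
      if (p < cfg@alpha)
        oracle[[length(oracle) + 1]] <- paste(ids[i], ids[j])
    }
    got <- with(networkEdges(net), paste(taxon_a, taxon_b))
    expect_setequal(got, unlist(oracle))
  }
})

test_that("spearman edge set is invariant to per-sample count rescaling", {
  spec <- syntheticSpec(nHealthy = 20L, nNoMet = 4L, nMet = 4L, seed = 8L)
  tabA <- generateDataset(spec)$table
  cfg <- correlationConfig(nResamples = 199L, seed = 8)
  netA <- buildNetwork(toRelative(tabA), config = cfg)
  # rescale every sample's counts (sequencing depth) by a power of two:
  # relative abundances are bit-identical, so the spearman network is too
  set.seed(9)
  scaled <- sweep(counts(tabA), 2,
                  sample(c(2, 4, 8), ncol(tabA), replace = TRUE), "*")
  netB <- buildNetwork(toRelative(AbundanceTable(scaled)), config = cfg)
  expect_identical(networkEdges(netA), networkEdges(netB))
})

test_that("networks are deterministic under a fixed seed and need >= 4 samples", {
  tab <- toRelative(randomCountTable(5, 10, seed = 600))
  cfg <- correlationConfig(nResamples = 99L, seed = 42)
  expect_identical(networkEdges(buildNetwork(tab, config = cfg)),
                   networkEdges(buildNetwork(tab, config = cfg)))
  expect_error(buildNetwork(tab[, 1:3], config = cfg), ">= 4")
})

test_that("planted within-block pairs are recovered at cohort scale", {
  # scaled-down version of the detection property (acceptance covers the
  # full 20-seed community-recovery run): one seed, NSCLC stratum (~57
  # samples), full-depth resampling
  spec <- syntheticSpec(seed = 31L)
  ds <- generateDataset(spec)
  rel <- selectTopTaxa(toRelative(subtractControl(ds$table, ds$control)), 50)
  ids <- selectStratum(ds$metadata, cohort = "NSCLC")
  net <- buildNetwork(rel, samples = ids,
                      config = correlationConfig(seed = 31L),
                      stratum = "NSCLC")
  tt <- truthTable(spec)$taxa
  ed <- networkEdges(net)
  key <- paste(ed$taxon_a, ed$taxon_b)
  detected <- 0; total <- 0
  for (b in c("1", "2", "3", "4")) {
    tx <- sort(tt$taxon_id[tt$block == b])
    prs <- t(combn(tx, 2))
    total <- total + nrow(prs)
    detected <- detected + sum(paste(prs[, 1], prs[, 2]) %in% key)
  }
  expect_gt(detected / total, 0.8)
  # and essentially no edges among background taxa
  bg <- tt$taxon_id[tt$block == "none"]
  expect_lte(sum(ed$taxon_a %in% bg & ed$taxon_b %in% bg), 1)
})
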