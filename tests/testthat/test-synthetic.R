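test_that("generation is bit-identical under a fixed seed", {
  spec <- syntheticSpec(seed = 99L)
  a <- generateDataset(spec)
  b <- generateDataset(spec)
  expect_identical(counts(a$table), counts(b$table))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$factors, b$factors)
  expect_identical(controlCounts(a$control), controlCounts(b$control))
  # and different under another seed
  c <- generateDataset(syntheticSpec(seed = 100L))
  expect_false(identical(counts(a$table), counts(c$table)))
})

test_that("truth table lists planted blocks, effects and couplings", {
  spec <- syntheticSpec()
  tt <- truthTable(spec)
  sizes <- table(tt$taxa$block)
  expect_equal(unname(sizes[c("1", "2", "3", "4")]),
               as.integer(c(12, 14, 6, 8)), ignore_attr = TRUE)
  expect_equal(sum(tt$taxa$block == "none"), 10)
  expect_true(all(tt$taxa$fold_change_nsclc[tt$taxa$block == "2"] == 2))
  expect_true(all(tt$taxa$fold_change_nsclc[tt$taxa$block %in%
                                              c("1", "3", "4")] == 0.6))
  # immune couplings vanish outside the metastatic stratum
  cp <- tt$couplings
  expect_true(all(cp$coupling[cp$stratum == "non_metastatic"] == 0))
  expect_true(all(cp$coupling[cp$stratum == "metastatic" &
                                cp$factor %in% c("eosinophils",
                                                 "neutrophils",
                                                 "monocytes")] == 0.8))
})

test_that("generated structure matches the declared cohort design", {
  spec <- syntheticSpec(seed = 7L)
  ds <- generateDataset(spec)
  expect_equal(dim(counts(ds$table)), c(50, 105))
  md <- ds$metadata
  expect_equal(sum(md$cohort == "healthy"), 50)
  expect_equal(sum(md$cohort == "NSCLC" & md$metastasis == "no"), 26)
  expect_equal(sum(md$metastasis == "yes"), 29)
  expect_silent(validateSampleMetadata(md))
  # healthy samples have no blood measurements
  healthy <- selectStratum(md, cohort = "healthy")
  expect_true(all(is.na(ds$factors[healthy, "neutrophils"])))
  expect_true(all(!is.na(ds$factors[selectStratum(md, cohort = "NSCLC"),
                                    "neutrophils"])))
  # all sample totals near the configured depth (contaminants add a bit)
  expect_true(all(colSums(counts(ds$table)) ==
                    20000 + sum(controlCounts(ds$control))))
})

test_that("decontaminating with the emitted control removes the injection", {
  spec <- syntheticSpec(seed = 13L)
  ds <- generateDataset(spec)
  out <- subtractControl(ds$table, ds$control)
  ctl <- controlCounts(ds$control)
  # contaminated cells were count + ctl with count >= 0, so subtraction
  # removes exactly the injected reads wherever no clipping occurs; with
  # positive underlying counts clipping is impossible here
  removed <- counts(ds$table) - counts(out)
  for (tx in names(ctl)) {
    expect_true(all(removed[tx, ] == ctl[tx]))
  }
  other <- setdiff(rownames(removed), names(ctl))
  expect_true(all(removed[other, ] == 0))
})

test_that("disease effect shifts community-2 relative abundance upward", {
  spec <- syntheticSpec(seed = 17L)
  ds <- generateDataset(spec)
  rel <- relabund(toRelative(ds$table))
  tt <- truthTable(spec)$taxa
  b2 <- tt$taxon_id[tt$block == "2"]
  b1 <- tt$taxon_id[tt$block == "1"]
  h <- selectStratum(ds$metadata, cohort = "healthy")
  n <- selectStratum(ds$metadata, cohort = "NSCLC")
  # block 2 rises in NSCLC, block 1 falls (x2 vs x0.6 planted effects)
  expect_gt(mean(rel[b2, n]) / mean(rel[b2, h]), 1.3)
  expect_lt(mean(rel[b1, n]) / mean(rel[b1, h]), 0.9)
})

test_that("a null spec yields no sizeable communities", {
  # no planted correlation, no effects: the filtered network over the
  # NSCLC stratum should not contain components of >= 4 taxa
  hits <- vapply(1:6, function(s) {
    spec <- syntheticSpec(withinBlockRho = 0, diseaseEffectUp = 1,
                          diseaseEffectDown = 1, metastasisEffect = 1,
                          factorCoupling = 0, markerCoupling = 0, seed = s)
    ds <- generateDataset(spec)
    rel <- toRelative(ds$table)
    ids <- selectStratum(ds$metadata, cohort = "NSCLC")
    net <- buildNetwork(rel, samples = ids,
                        config = correlationConfig(nResamples = 99L,
                                                   seed = s))
    mb <- communityMembership(partitionCommunities(net))
    any(table(mb[!is.na(mb)]) >= 4)
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("dataset TSV export round-trips through the readers", {
  spec <- syntheticSpec(seed = 3L)
  ds <- generateDataset(spec)
  dir <- withr::local_tempdir()
  writeDataset(ds, spec, dir)
  tab <- readAbundanceTable(file.path(dir, "abundance.tsv"))
  expect_identical(counts(tab), counts(ds$table))
  md <- readSampleMetadata(file.path(dir, "metadata.tsv"))
  expect_identical(md$cohort, ds$metadata$cohort)
  fac <- readClinicalFactors(file.path(dir, "factors.tsv"))
  expect_equal(fac$neutrophils, ds$factors$neutrophils)
  ctl <- readControlProfile(file.path(dir, "control.tsv"))
  expect_equal(controlCounts(ctl), controlCounts(ds$control))
})
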