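# Curated taxon panel for the default spec: four planted blocks mirroring
# the four lung-mucosa communities (core members first), plus typical
# environmental/kit-contaminant background genera.
.defaultBlockTaxa <- list(
  `1` = c("o__Saccharimonadales", "g__Sphingomonas", "g__Bradyrhizobium",
          "g__Haliangium", "g__Streptomyces", "g__Gaiella", "g__Arthrobacter",
          "g__Candidatus_Solibacter", "g__Gemmatimonas", "f__Micropepsaceae",
          "f__Chitinophagaceae", "o__IMCC26256"),
  `2` = c("g__Neisseria", "g__Alloprevotella", "g__Prevotella",
          "g__Peptostreptococcus", "g__Haemophilus", "g__Granulicatella",
          "g__Rothia", "g__Gemella", "g__Porphyromonas", "g__Prevotella_7",
          "g__Streptococcus", "g__Veillonella", "g__Fusobacterium",
          "g__Actinomyces"),
  `3` = c("g__Burkholderia-Caballeronia-Paraburkholderia", "g__Acinetobacter",
          "g__Rhodococcus", "g__Acidovorax", "g__Cutibacterium",
          "g__Corynebacterium_1"),
  `4` = c("g__Prevotella_9", "g__Lactobacillus", "g__Megamonas",
          "g__Faecalibacterium", "g__Bacteroides", "g__Phascolarctobacterium",
          "g__Marinobacter", "f__Flavobacteriaceae"))

.defaultBackground <- c("g__Pseudomonas", "g__Ralstonia", "g__Staphylococcus",
                        "g__Escherichia-Shigella", "g__Delftia",
                        "g__Stenotrophomonas", "g__Enterococcus",
                        "g__Brevundimonas", "g__Methylobacterium",
                        "g__Ochrobactrum")

# community-2 members further up-shifted with metastasis (the subset reported
# to increase in the metastatic stratum)
.defaultMetSubset <- c("g__Prevotella_7", "g__Alloprevotella",
                       "g__Porphyromonas", "g__Prevotella",
                       "g__Granulicatella", "g__Rothia", "g__Gemella",
                       "g__Peptostreptococcus")

.immuneFactors <- c("neutrophils", "monocytes", "lymphocytes", "eosinophils",
                    "basophils")
.coupledImmune <- c("eosinophils", "neutrophils", "monocytes")
.cancerMarkers <- c("CEA", "NSE", "CYFRA21_1", "CA125", "SCCA")

# marginal (mean, sd) per factor and stratum, on the published cohort scale
# (immune cells 1e9 cells/L; markers ng/mL, CA125 units/mL)
.factorMarginals <- list(
  no_met = c(neutrophils = 5.51, monocytes = 0.56, lymphocytes = 1.30,
             eosinophils = 0.14, basophils = 0.04,
             CEA = 3.95, NSE = 23.10, CYFRA21_1 = 10.15, CA125 = 57.62,
             SCCA = 1.87),
  no_met_sd = c(neutrophils = 2.23, monocytes = 0.23, lymphocytes = 0.52,
                eosinophils = 0.12, basophils = 0.08,
                CEA = 3.92, NSE = 22.12, CYFRA21_1 = 10.31, CA125 = 74.03,
                SCCA = 1.68),
  met = c(neutrophils = 7.52, monocytes = 0.60, lymphocytes = 1.61,
          eosinophils = 0.23, basophils = 0.02,
          CEA = 353.20, NSE = 30.51, CYFRA21_1 = 19.85, CA125 = 733.40,
          SCCA = 1.48),
  met_sd = c(neutrophils = 2.48, monocytes = 0.25, lymphocytes = 0.55,
             eosinophils = 0.26, basophils = 0.02,
             CEA = 914.80, NSE = 32.56, CYFRA21_1 = 27.13, CA125 = 2209.0,
             SCCA = 1.47))

#' Build a SyntheticSpec
#'
#' Defaults state the emulated study design: four positively-correlated
#' genus blocks (12/14/6/8 taxa) plus 10 background taxa among the top 50;
#' target within-block Spearman correlation 0.7; 50 healthy, 26
#' non-metastatic and 29 metastatic NSCLC samples; disease effect x2 on the
#' community-2 block and x0.6 on blocks 1/3/4; metastasis effect x1.8 on
#' block 1 and on the reported community-2 subset; immune-cell coupling 0.8
#' to the block-2 latent in metastatic samples only; multinomial depth
#' 20,000; five fixed-count contaminant taxa reported identically as the
#' negative control.
#'
#' @param blockSizes four block sizes.
#' @param nBackground number of uncorrelated background taxa.
#' @param withinBlockRho target within-block Spearman correlation; the
#'   latent Gaussian correlation is set to 2*sin(pi*rho/6).
#' @param crossBlockRho taxon-level correlation between block 2 and the
#'   other blocks (default 0; e.g. -0.3 for antagonistic communities).
#' @param nHealthy,nNoMet,nMet cohort sizes.
#' @param diseaseEffectUp,diseaseEffectDown,metastasisEffect multiplicative
#'   abundance shifts (applied on the log scale).
#' @param factorCoupling loading of coupled immune-cell factors on the
#'   block-2 latent mean in metastatic samples.
#' @param factorNoiseSd measurement-noise sd of the factor signal on the
#'   latent scale.
#' @param markerCoupling weak loading of cancer markers on the block-1/3
#'   latent mean in NSCLC samples.
#' @param sigmaLog biological log-scale dispersion of taxon abundances
#'   (sd of the latent Gaussian on the natural-log scale).
#' @param depth multinomial sequencing depth per sample.
#' @param contaminantCounts named vector of fixed per-sample contaminant
#'   counts (the negative-control profile).
#' @param seed integer seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(blockSizes = c(12L, 14L, 6L, 8L),
                          nBackground = 10L,
                          withinBlockRho = 0.7, crossBlockRho = 0,
                          nHealthy = 50L, nNoMet = 26L, nMet = 29L,
                          diseaseEffectUp = 2, diseaseEffectDown = 0.6,
                          metastasisEffect = 1.8,
                          factorCoupling = 0.8, factorNoiseSd = 0.3,
                          markerCoupling = 0.3,
                          sigmaLog = 0.6,
                          depth = 20000L,
                          contaminantCounts = c(g__Ralstonia = 120,
                                                g__Delftia = 80,
                                                g__Stenotrophomonas = 60,
                                                g__Brevundimonas = 40,
                                                g__Methylobacterium = 20),
                          seed = 1L) {
  new("SyntheticSpec", blockSizes = as.integer(blockSizes),
      nBackground = as.integer(nBackground),
      withinBlockRho = withinBlockRho, crossBlockRho = crossBlockRho,
      nHealthy = as.integer(nHealthy), nNoMet = as.integer(nNoMet),
      nMet = as.integer(nMet),
      diseaseEffectUp = diseaseEffectUp,
      diseaseEffectDown = diseaseEffectDown,
      metastasisEffect = metastasisEffect,
      factorCoupling = factorCoupling, factorNoiseSd = factorNoiseSd,
      markerCoupling = markerCoupling, sigmaLog = sigmaLog,
      depth = as.integer(depth), contaminantCounts = contaminantCounts,
      seed = as.integer(seed))
}

# taxon panel for a spec: curated names at the default geometry, generated
# ids otherwise
.specTaxa <- function(spec) {
  blocks <- spec@blockSizes
  if (identical(blocks, c(12L, 14L, 6L, 8L)) && spec@nBackground <= 10L) {
    taxa <- .defaultBlockTaxa
    bg <- .defaultBackground[seq_len(spec@nBackground)]
  } else {
    taxa <- lapply(1:4, function(b)
      sprintf("g__Block%d_taxon%02d", b, seq_len(blocks[b])))
    names(taxa) <- as.character(1:4)
    if (identical(blocks[2], 14L)) taxa[["2"]] <- .defaultBlockTaxa[["2"]]
    bg <- sprintf("g__Background%02d", seq_len(spec@nBackground))
  }
  taxa <- lapply(1:4, function(b) taxa[[as.character(b)]][seq_len(blocks[b])])
  names(taxa) <- as.character(1:4)
  list(blocks = taxa, background = bg)
}

#' @rdname truthTable
#' @details Returns the planted structure used for scoring recovery: per
#'   taxon its block ("1".."4" or "none"), expected NSCLC and metastasis
#'   fold-changes and contaminant status, plus the factor-coupling table
#'   (couplings are zero in the non-metastatic stratum for immune cells).
#' @return List with `taxa` (data.frame) and `couplings` (data.frame).
setMethod("truthTable", "SyntheticSpec", function(spec) {
  pan <- .specTaxa(spec)
  ids <- c(unlist(pan$blocks, use.names = FALSE), pan$background)
  block <- c(rep(names(pan$blocks), lengths(pan$blocks)),
             rep("none", length(pan$background)))
  fcN <- ifelse(block == "2", spec@diseaseEffectUp,
                ifelse(block %in% c("1", "3", "4"), spec@diseaseEffectDown, 1))
  metSub <- intersect(.defaultMetSubset, pan$blocks[["2"]])
  fcM <- ifelse(block == "1" | ids %in% metSub, spec@metastasisEffect, 1)
  taxa <- data.frame(taxon_id = ids, block = block,
                     fold_change_nsclc = fcN, fold_change_metastasis = fcM,
                     contaminant = ids %in% names(spec@contaminantCounts),
                     stringsAsFactors = FALSE)
  couplings <- rbind(
    data.frame(factor = .coupledImmune, block = "2",
               coupling = spec@factorCoupling, stratum = "metastatic",
               stringsAsFactors = FALSE),
    data.frame(factor = .coupledImmune, block = "2", coupling = 0,
               stratum = "non_metastatic", stringsAsFactors = FALSE),
    data.frame(factor = .cancerMarkers, block = "1/3",
               coupling = spec@markerCoupling, stratum = "NSCLC",
               stringsAsFactors = FALSE))
  list(taxa = taxa, couplings = couplings)
})

#' @rdname generateDataset
#' @details Log-normal-multinomial generative model: per sample a latent
#'   Gaussian vector with exchangeable within-block correlation (one latent
#'   factor per block; cross-block factor correlation derived from
#'   `crossBlockRho`) is shifted on the log scale by the cohort effects,
#'   exponentiated and normalized into proportions, then counted by a
#'   multinomial draw at the configured depth. Fixed contaminant counts are
#'   added to every sample and reported identically as the negative-control
#'   profile. Coupled immune-cell factors are linear in the block-2 latent
#'   mean (plus Gaussian noise) in metastatic samples and independent noise
#'   otherwise; cancer markers load weakly on the block-1/3 latent mean in
#'   all NSCLC samples; healthy samples have no blood measurements (NA).
#'   Factor marginals are located/scaled to the published per-stratum
#'   means/SDs. Fully reproducible under the spec seed.
#' @return List with `table` ([AbundanceTable-class], metadata in colData),
#'   `metadata`, `factors` (data.frames) and `control`
#'   ([ControlProfile-class]).
setMethod("generateDataset", "SyntheticSpec", function(spec) {
  withr::with_seed(spec@seed, .generate(spec))
})

.generate <- function(spec) {
  pan <- .specTaxa(spec)
  ids <- c(unlist(pan$blocks, use.names = FALSE), pan$background)
  nT <- length(ids)
  blockOf <- setNames(c(rep(1:4, lengths(pan$blocks)),
                        rep(0L, length(pan$background))), ids)

  # latent Gaussian correlation implied by the target Spearman (Gaussian
  # copula inverse: rho_P = 2 sin(pi rho_S / 6))
  rhoP <- 2 * sin(pi * spec@withinBlockRho / 6)
  cFac <- if (spec@crossBlockRho == 0) 0 else spec@crossBlockRho / rhoP
  facCor <- diag(4)
  facCor[1, 2] <- facCor[2, 1] <- cFac
  facCor[2, 3] <- facCor[3, 2] <- cFac
  facCor[2, 4] <- facCor[4, 2] <- cFac
  eg <- eigen(facCor, symmetric = TRUE)
  if (min(eg$values) < -1e-8) stop("infeasible cross-block correlation")
  facRoot <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)

  # deterministic log-scale baselines: an abundance gradient in which the
  # uncorrelated background carries most of the mass, so compositional
  # closure does not cancel the planted block factors (a dominant block's
  # shared factor would otherwise be absorbed by the normalizing total)
  mu0 <- setNames(numeric(nT), ids)
  for (b in 1:4) {
    bt <- pan$blocks[[b]]
    mu0[bt] <- seq(1.0, -1.0, length.out = length(bt))
  }
  mu0[pan$background] <- seq(3.5, 1.5,
                             length.out = length(pan$background))

  nH <- spec@nHealthy; nN <- spec@nNoMet; nM <- spec@nMet
  n <- nH + nN + nM
  sampleIds <- c(sprintf("H%03d", seq_len(nH)), sprintf("N%03d", seq_len(nN)),
                 sprintf("M%03d", seq_len(nM)))
  cohort <- rep(c("healthy", "NSCLC", "NSCLC"), c(nH, nN, nM))
  metast <- rep(c("no", "no", "yes"), c(nH, nN, nM))
  # subtype mix mirrors the modelled strata (20 SCC : 6 AC no-met,
  # 11 SCC : 18 AC met), scaled to the requested sizes
  nSccNo <- round(nN * 20 / 26); nSccMet <- round(nM * 11 / 29)
  subtype <- c(rep("none", nH),
               rep(c("SCC", "AC"), c(nSccNo, nN - nSccNo)),
               rep(c("SCC", "AC"), c(nSccMet, nM - nSccMet)))

  # cohort effects on the log scale
  eff <- matrix(0, nT, n, dimnames = list(ids, sampleIds))
  isN <- cohort == "NSCLC"; isM <- metast == "yes"
  eff[blockOf == 2, isN] <- log(spec@diseaseEffectUp)
  eff[blockOf %in% c(1, 3, 4), isN] <- log(spec@diseaseEffectDown)
  metSub <- intersect(.defaultMetSubset, pan$blocks[["2"]])
  eff[blockOf == 1, isM] <- eff[blockOf == 1, isM] +
    log(spec@metastasisEffect)
  eff[metSub, isM] <- eff[metSub, isM] + log(spec@metastasisEffect)

  # latent field: z_i = sqrt(rhoP) F_block + sqrt(1 - rhoP) eps_i
  Fraw <- matrix(rnorm(4 * n), 4, n)
  Ffac <- facRoot %*% Fraw
  eps <- matrix(rnorm(nT * n), nT, n)
  z <- eps
  inBlock <- blockOf > 0
  z[inBlock, ] <- sqrt(rhoP) * Ffac[blockOf[inBlock], , drop = FALSE] +
    sqrt(1 - rhoP) * eps[inBlock, , drop = FALSE]

  sigmaLog <- spec@sigmaLog
  logAb <- mu0 + eff + sigmaLog * z
  props <- apply(logAb, 2L, function(v) { e <- exp(v); e / sum(e) })
  counts <- apply(props, 2L, function(p) rmultinom(1L, spec@depth, p))
  dimnames(counts) <- list(ids, sampleIds)

  # contamination: identical fixed counts in every sample, reported as the
  # negative-control profile
  ctl <- spec@contaminantCounts
  known <- intersect(names(ctl), ids)
  counts[known, ] <- counts[known, ] + ctl[known]

  metadata <- data.frame(
    sample_id = sampleIds, cohort = cohort, subtype = subtype,
    metastasis = metast,
    survival_months = ifelse(cohort == "NSCLC",
                             round(pmin(rexp(n, 1 / 12), 60), 1), NA),
    stringsAsFactors = FALSE)
  metadata <- validateSampleMetadata(metadata)

  factors <- .generateFactors(spec, z, blockOf, pan, cohort, metast,
                              sampleIds)
  tab <- AbundanceTable(counts, sampleData = metadata)
  list(table = tab, metadata = metadata, factors = factors,
       control = ControlProfile(ctl[known]))
}

.generateFactors <- function(spec, z, blockOf, pan, cohort, metast,
                             sampleIds) {
  n <- length(sampleIds)
  rhoP <- 2 * sin(pi * spec@withinBlockRho / 6)
  zBar2 <- colMeans(z[blockOf == 2, , drop = FALSE])
  zBar13 <- colMeans(z[blockOf %in% c(1, 3), , drop = FALSE])
  k2 <- sum(blockOf == 2)
  k13 <- sum(blockOf %in% c(1, 3))
  varBar2 <- rhoP + (1 - rhoP) / k2   # exchangeable-block latent mean
  # blocks 1 and 3 share no factor, so their latents average independently
  k1 <- sum(blockOf == 1); k3 <- sum(blockOf == 3)
  varBar13 <- (k1^2 * (rhoP + (1 - rhoP) / k1) +
                 k3^2 * (rhoP + (1 - rhoP) / k3)) / k13^2

  isN <- cohort == "NSCLC"; isM <- metast == "yes"
  mg <- .factorMarginals
  out <- data.frame(sample_id = sampleIds, stringsAsFactors = FALSE)
  for (fc in c(.immuneFactors, .cancerMarkers)) {
    v <- rep(NA_real_, n)
    mu <- ifelse(isM, mg$met[fc], mg$no_met[fc])
    sdv <- ifelse(isM, mg$met_sd[fc], mg$no_met_sd[fc])
    if (fc %in% .coupledImmune) {
      sig <- rep(NA_real_, n)
      sig[isN & !isM] <- rnorm(sum(isN & !isM))
      sdSig <- sqrt(spec@factorCoupling^2 * varBar2 + spec@factorNoiseSd^2)
      sig[isM] <- (spec@factorCoupling * zBar2[isM] +
                     rnorm(sum(isM), 0, spec@factorNoiseSd)) / sdSig
      v[isN] <- mu[isN] + sdv[isN] * sig[isN]
    } else if (fc %in% .cancerMarkers) {
      sdSig <- sqrt(spec@markerCoupling^2 * varBar13 + spec@factorNoiseSd^2)
      sig <- (spec@markerCoupling * zBar13 +
                rnorm(n, 0, spec@factorNoiseSd)) / sdSig
      v[isN] <- mu[isN] + sdv[isN] * sig[isN]
    } else {
      v[isN] <- mu[isN] + sdv[isN] * rnorm(sum(isN))
    }
    out[[fc]] <- v
  }
  validateClinicalFactors(out)
}

#' Write a generated dataset to TSV files
#'
#' Writes the abundance table, metadata, clinical factors and control
#' profile of a [generateDataset()] result into a directory, plus the truth
#' table as JSON.
#'
#' @param dataset list from [generateDataset()].
#' @param spec the [SyntheticSpec-class] used (for the truth table).
#' @param dir output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
writeDataset <- function(dataset, spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pAb <- file.path(dir, "abundance.tsv")
  writeAbundanceTable(dataset$table, pAb)
  pMd <- file.path(dir, "metadata.tsv")
  write.table(dataset$metadata, pMd, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pFc <- file.path(dir, "factors.tsv")
  write.table(dataset$factors, pFc, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pCt <- file.path(dir, "control.tsv")
  cc <- controlCounts(dataset$control)
  write.table(data.frame(taxon_id = names(cc), count = unname(cc)),
              pCt, sep = "\t", quote = FALSE, row.names = FALSE)
  pTr <- file.path(dir, "truth.json")
  jsonlite::write_json(truthTable(spec), pTr, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(pAb, pMd, pFc, pCt, pTr))
}
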