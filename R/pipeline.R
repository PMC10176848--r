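#' Default end-to-end run configuration
#'
#' Returns the full configuration the pipeline understands, populated with
#' the defaults of the modelled study (top-50 genera, |rho| >= 0.5 &
#' p < 0.05 with 999 permutations, healthy/NSCLC and metastatic strata,
#' BH-corrected rank-sum differential abundance between cohorts, immune-cell
#' and cancer-marker correlation in the metastatic contrast). With
#' `synthetic = TRUE` (default) inputs are generated by [generateDataset()]
#' under the run seed; otherwise set `input$abundance`, `input$metadata`,
#' `input$factors` and optionally `input$control` to TSV paths.
#'
#' @param outdir output directory.
#' @param seed root seed; every stage draws from a named substream of it.
#' @param synthetic generate inputs instead of reading them?
#' @return Nested list; see the fields it documents.
#' @export
defaultRunConfig <- function(outdir = tempfile("mucosanet_run_"), seed = 1L,
                             synthetic = TRUE) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = synthetic,
    input = list(abundance = NULL, metadata = NULL, factors = NULL,
                 control = NULL),
    stages = list(decontam = TRUE, topn = TRUE, networks = TRUE,
                  communities = TRUE, diffabund = TRUE, diversity = TRUE,
                  envcorr = TRUE),
    topN = 50L,
    correlation = list(method = "spearman", rThreshold = 0.5, alpha = 0.05,
                       nResamples = 999L, nullScheme = "permutation"),
    strata = list(healthy = list(cohort = "healthy"),
                  NSCLC = list(cohort = "NSCLC"),
                  metastatic = list(cohort = "NSCLC", metastasis = "yes"),
                  non_metastatic = list(cohort = "NSCLC", metastasis = "no")),
    networkStrata = c("healthy", "NSCLC"),
    degreeCompare = list(strata = c("healthy", "NSCLC"),
                         communities = c("community 1", "community 2",
                                         "community 3", "community 4")),
    diffabund = list(column = "cohort"),
    envcorrStrata = c("metastatic", "non_metastatic"))
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with (a subset of) the fields of
#'   [defaultRunConfig()]; missing fields take their defaults.
#' @return Config list.
#' @export
readRunConfig <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- defaultRunConfig()
  mergeIn <- function(base, upd) {
    for (k in names(upd))
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        mergeIn(base[[k]], upd[[k]]) else upd[[k]]
    base
  }
  mergeIn(cfg, user)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes decontamination, top-N selection, per-stratum network inference,
#' community partition and reference matching, cross-stratum degree
#' comparison, differential abundance, alpha/beta diversity and
#' taxon-factor correlation, writing all tables/networks under
#' `config$outdir` and returning (and writing) a machine-readable run
#' report. Re-running with the same config reproduces byte-identical
#' outputs.
#'
#' @param config list from [defaultRunConfig()]/[readRunConfig()], or a path
#'   to a JSON config.
#' @return Run report (list), invisibly also written as `report.json`.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  report <- list(
    package = as.character(utils::packageVersion("MucosaNet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, outputs = list(), counts = list())
  on <- function(s) isTRUE(config$stages[[s]])
  if (on("communities") && !on("networks"))
    stop("pipeline stage 'communities' consumes the outputs of stage ",
         "'networks', which is disabled; enable 'networks' or disable ",
         "'communities'", call. = FALSE)

  # --- inputs ---------------------------------------------------------
  if (isTRUE(config$synthetic)) {
    ds <- .stage("input", {
      spec <- syntheticSpec(seed = config$seed)
      generateDataset(spec)
    })
    table <- ds$table; metadata <- ds$metadata
    factors <- ds$factors; control <- ds$control
  } else {
    ds <- .stage("input", {
      inp <- config$input
      stopifnot(!is.null(inp$abundance), !is.null(inp$metadata))
      list(table = readAbundanceTable(inp$abundance),
           metadata = readSampleMetadata(inp$metadata),
           factors = if (!is.null(inp$factors))
             readClinicalFactors(inp$factors) else NULL,
           control = if (!is.null(inp$control))
             readControlProfile(inp$control) else NULL)
    })
    table <- ds$table; metadata <- ds$metadata
    factors <- ds$factors; control <- ds$control
  }
  report$counts$input <- c(taxa = nrow(table), samples = ncol(table))

  # --- decontamination ------------------------------------------------
  if (on("decontam") && !is.null(control)) {
    table <- .stage("decontam", subtractControl(table, control))
    rep0 <- metadata(table)$decontam
    report$counts$decontam <- c(total_removed = rep0$total_removed)
    p <- file.path(outdir, "decontam_report.json")
    jsonlite::write_json(rep0, p, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    report$outputs$decontam_report <- p
  }

  # --- relative abundance + top-N -------------------------------------
  rel <- .stage("to_relative", toRelative(table))
  if (on("topn"))
    rel <- .stage("topn", selectTopTaxa(rel, config$topN))
  report$counts$taxa_analyzed <- nrow(rel)

  # --- per-stratum networks + communities -----------------------------
  nets <- list(); assignments <- list()
  if (on("networks")) {
    cores <- referenceCores()
    for (sname in config$networkStrata) {
      ids <- do.call(selectStratum,
                     c(list(metadata), config$strata[[sname]]))
      cc <- correlationConfig(
        method = config$correlation$method,
        rThreshold = config$correlation$rThreshold,
        alpha = config$correlation$alpha,
        nResamples = config$correlation$nResamples,
        nullScheme = config$correlation$nullScheme,
        seed = config$seed)
      net <- .stage(paste0("network[", sname, "]"),
                    buildNetwork(rel, samples = ids, config = cc,
                                 stratum = sname))
      p <- file.path(outdir, paste0("network_", sname, ".graphml"))
      writeNetwork(net, p, "graphml")
      report$outputs[[paste0("network_", sname)]] <- p
      nets[[sname]] <- net
      if (on("communities")) {
        asg <- .stage(paste0("communities[", sname, "]"), {
          a <- partitionCommunities(net)
          matchToReference(a, cores)
        })
        assignments[[sname]] <- asg
        p2 <- file.path(outdir, paste0("communities_", sname, ".tsv"))
        mb <- communityMembership(asg)
        write.table(data.frame(taxon_id = names(mb), community = unname(mb)),
                    p2, sep = "\t", quote = FALSE, row.names = FALSE)
        report$outputs[[paste0("communities_", sname)]] <- p2
        report$counts[[paste0("communities_", sname)]] <-
          c(n_communities = sum(!is.na(unique(mb))),
            n_matched = sum(!is.na(asg@coreMatch$reference)))
      }
    }
  }

  # --- degree comparison ---------------------------------------------
  if (on("communities") && length(config$degreeCompare$strata) == 2L &&
      all(config$degreeCompare$strata %in% names(nets))) {
    sA <- config$degreeCompare$strata[1L]
    sB <- config$degreeCompare$strata[2L]
    rows <- list()
    for (cm in config$degreeCompare$communities) {
      res <- tryCatch(
        compareDegree(nets[[sA]], nets[[sB]], assignments[[sA]],
                      assignments[[sB]], cm),
        error = function(e) NULL)
      if (!is.null(res))
        rows[[cm]] <- data.frame(community = cm, mean_a = res$meanA,
                                 mean_b = res$meanB, t = res$t, df = res$df,
                                 p = res$p, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      deg <- do.call(rbind, rows)
      p <- file.path(outdir, "degree_comparison.tsv")
      write.table(deg, p, sep = "\t", quote = FALSE, row.names = FALSE)
      report$outputs$degree_comparison <- p
    }
  }

  # --- differential abundance ----------------------------------------
  if (on("diffabund")) {
    da <- .stage("diffabund", {
      groups <- setNames(metadata[[config$diffabund$column]],
                         metadata$sample_id)
      wilcoxonFdr(rel, groups[colnames(rel)])
    })
    p <- file.path(outdir, "diffabund.tsv")
    write.table(da, p, sep = "\t", quote = FALSE, row.names = FALSE)
    report$outputs$diffabund <- p
    report$counts$diffabund_q05 <- sum(da$q < 0.05)
  }

  # --- diversity ------------------------------------------------------
  if (on("diversity")) {
    div <- .stage("diversity", {
      m <- relabund(rel)
      data.frame(sample_id = colnames(m),
                 shannon = apply(m, 2L, shannonIndex),
                 stringsAsFactors = FALSE)
    })
    p <- file.path(outdir, "alpha_diversity.tsv")
    write.table(div, p, sep = "\t", quote = FALSE, row.names = FALSE)
    report$outputs$alpha_diversity <- p
    bd <- .stage("beta_diversity", {
      d <- brayCurtisMatrix(rel)
      grp <- metadata[colnames(rel), "cohort"]
      pv <- permanova(d, grp, nPerm = 999L, seed = config$seed)
      list(F = pv$F, p = pv$p)
    })
    report$counts$permanova <- bd
  }

  # --- environmental (clinical factor) correlation --------------------
  if (on("envcorr") && !is.null(factors)) {
    for (sname in config$envcorrStrata) {
      ids <- do.call(selectStratum,
                     c(list(metadata), config$strata[[sname]]))
      res <- .stage(paste0("envcorr[", sname, "]"), {
        tab <- detectionFilter(subsetSamples(rel, ids), 2L)
        correlateFactors(tab, factors, stratum = sname)
      })
      p <- file.path(outdir, paste0("envcorr_", sname, ".tsv"))
      write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
      report$outputs[[paste0("envcorr_", sname)]] <- p
      bp <- bipartiteNetwork(res)
      p2 <- file.path(outdir, paste0("envcorr_", sname, ".graphml"))
      writeNetwork(bp, p2, "graphml")
      report$outputs[[paste0("envcorr_net_", sname)]] <- p2
      report$counts[[paste0("envcorr_", sname)]] <-
        c(significant = sum(res$significant, na.rm = TRUE))
    }
  }

  rp <- file.path(outdir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA)
  report$report_path <- rp
  invisible(report)
}
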