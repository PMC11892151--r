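#' Assemble a pipeline configuration
#'
#' Bundles per-stage parameter objects, the synthetic-data sizes and the
#' single global seed that every stage's randomness flows from. The
#' configuration is a plain list (JSON-serializable for the run report).
#'
#' @param seed Global integer seed (default 1).
#' @param outDir Output directory for stage files.
#' @param kinetics A [KineticsParams] (default: 1 cm path).
#' @param screen A [ScreenParams].
#' @param qpcr A [QpcrParams].
#' @param proteomics A [ProteomicsParams].
#' @param enrichAlpha Significance level of the ORF enrichment stage
#'   (default 0.05).
#' @param minIdentity Minimum homolog identity for compensation calls
#'   (default 0.73).
#' @param treeOutgroup Taxon to root the tree at (default: first taxon in
#'   the distance matrix).
#' @param simulate Named list of synthetic-data sizes; see Details.
#' @details The `simulate` block accepts `nStrains`, `nHits`, `effectSize`,
#'   `noiseSd`, `nOrfs`, `nTaxa`, `nProteins`, `nBioReps`, `nTechReps`,
#'   `nSecondaryReps`, `secondaryCv`, `qpcrNoiseSd`; unset entries take the
#'   generator defaults.
#' @return A `PipelineConfig` list.
#' @examples
#' cfg <- pipelineConfig(seed = 1, outDir = tempfile(),
#'                       simulate = list(nStrains = 60, nHits = 6))
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(seed = 1, outDir = "panscreen_run",
                           kinetics = KineticsParams(pathLength = 1),
                           screen = ScreenParams(), qpcr = QpcrParams(),
                           proteomics = ProteomicsParams(),
                           enrichAlpha = 0.05, minIdentity = 0.73,
                           treeOutgroup = NULL, simulate = list()) {
  defaults <- list(nStrains = 600L, nHits = 30L, effectSize = 2,
                   noiseSd = 0.002, nOrfs = 500L, nTaxa = 24L,
                   nProteins = 4000L, nBioReps = 4L, nTechReps = 14L,
                   nSecondaryReps = 4L, secondaryCv = 0.22,
                   qpcrNoiseSd = 0.1)
  unknown <- setdiff(names(simulate), names(defaults))
  if (length(unknown))
    stop("unknown simulate settings: ", paste(unknown, collapse = ", "))
  defaults[names(simulate)] <- simulate
  cfg <- list(seed = as.integer(seed), outDir = outDir, kinetics = kinetics,
              screen = screen, qpcr = qpcr, proteomics = proteomics,
              enrichAlpha = enrichAlpha, minIdentity = minIdentity,
              treeOutgroup = treeOutgroup, simulate = defaults)
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

paramsToList <- function(p) {
  sn <- slotNames(class(p))
  setNames(lapply(sn, function(s) slot(p, s)), sn)
}

#' Validate a pipeline configuration
#'
#' Checks every parameter object and simulate setting, aggregating all
#' violations into a single error.
#'
#' @param config A `PipelineConfig`.
#' @return `TRUE` invisibly, or an error listing every violation.
#' @export
validatePipelineConfig <- function(config) {
  msg <- character()
  for (nm in c("kinetics", "screen", "qpcr", "proteomics")) {
    v <- try(validObject(config[[nm]]), silent = TRUE)
    if (inherits(v, "try-error"))
      msg <- c(msg, paste0(nm, ": ", conditionMessage(attr(v, "condition"))))
  }
  if (is.na(config$kinetics@pathLength))
    msg <- c(msg, "kinetics: pathLength must be set for a pipeline run")
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed))
    msg <- c(msg, "seed must be a single integer")
  sim <- config$simulate
  if (sim$nHits >= sim$nStrains)
    msg <- c(msg, "simulate: nHits must be smaller than nStrains")
  if (sim$nTaxa < 4) msg <- c(msg, "simulate: nTaxa must be >= 4")
  if (!(config$enrichAlpha > 0 && config$enrichAlpha < 1))
    msg <- c(msg, "enrichAlpha must lie in (0, 1)")
  if (!(config$minIdentity >= 0 && config$minIdentity <= 1))
    msg <- c(msg, "minIdentity must lie in [0, 1]")
  if (length(msg))
    stop("invalid pipeline configuration:\n  - ",
         paste(msg, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

configHash <- function(config) {
  ser <- list(seed = config$seed,
              kinetics = paramsToList(config$kinetics),
              screen = paramsToList(config$screen),
              qpcr = paramsToList(config$qpcr),
              proteomics = paramsToList(config$proteomics),
              enrichAlpha = config$enrichAlpha,
              minIdentity = config$minIdentity,
              treeOutgroup = config$treeOutgroup,
              simulate = config$simulate)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stageInputs <- list(
  quantify = c(kinetics.csv = "simulate", layout.csv = "simulate"),
  screen = c(activity.tsv = "quantify"),
  enrich = c(presence.tsv = "simulate", homology.tsv = "simulate",
             primary_hits.tsv = "screen"),
  tree = c(distances.tsv = "simulate"),
  qpcr = c(ct.csv = "simulate", activity.tsv = "quantify"),
  proteomics = c(intensity.tsv = "simulate", samples.tsv = "simulate"))

#' Run the screening pipeline
#'
#' Executes the requested stages in the fixed order simulate, quantify,
#' screen, enrich, tree, qpcr, proteomics. Each stage reads its inputs from
#' `outDir` (written by an earlier stage of this or a previous run) and
#' writes its outputs there; every output file carries a header comment
#' with package version, configuration hash and seed. Rerunning with an
#' identical configuration and inputs reproduces identical outputs. A
#' machine-readable run report (JSON) with parameters, seed, per-stage
#' counts and collected warnings is written to `report.json` and returned.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @param stages Subset of stages to run (default: all).
#' @param quiet Suppress per-stage progress messages (default FALSE;
#'   messages go to stderr).
#' @return The run report, invisibly.
#' @examples
#' cfg <- pipelineConfig(seed = 1, outDir = tempfile(),
#'                       simulate = list(nStrains = 40, nHits = 4,
#'                                       nOrfs = 60, nProteins = 120,
#'                                       nTaxa = 8, nTechReps = 3,
#'                                       nBioReps = 3))
#' rep <- runPipeline(cfg, quiet = TRUE)
#' rep$counts$n_primary_hits
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "quantify", "screen",
                                   "enrich", "tree", "qpcr", "proteomics"),
                        quiet = FALSE) {
  validatePipelineConfig(config)
  allStages <- c("simulate", "quantify", "screen", "enrich", "tree",
                 "qpcr", "proteomics")
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- allStages[allStages %in% stages]
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(configHash = configHash(config), seed = config$seed)
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] ", stage), ...)
  pth <- function(f) file.path(outDir, f)

  warningsSeen <- character()
  counts <- list()
  withWarnings <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      warningsSeen <<- c(warningsSeen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  for (stage in stages) {
    need <- stageInputs[[stage]]
    for (f in names(need)) if (!file.exists(pth(f)))
      stop("stage '", stage, "' needs ", f, ", which is produced by stage '",
           need[[f]], "'; run that stage first")
    meta$stage <- stage
    sim <- config$simulate
    withWarnings(switch(stage,
      simulate = {
        say(stage, "generating synthetic inputs (seed ", config$seed, ")")
        scr <- simulateScreen(
          nStrains = sim$nStrains, nHits = sim$nHits,
          effectSize = sim$effectSize, noiseSd = sim$noiseSd,
          seed = config$seed,
          pathLength = config$kinetics@pathLength)
        writeKineticTable(scr$kinetics, pth("kinetics.csv"), meta)
        writePlateLayout(scr$layout, pth("layout.csv"), meta)
        hits <- scr$truth$planted_hits
        mtHits <- hits[seq_len(floor(length(hits) / 2))]
        sec <- simulateSecondaryScreen(
          candidates = hits,
          producers = list(ttLcc1 = hits, mtLcc1 = mtHits),
          nReps = sim$nSecondaryReps, cv = sim$secondaryCv,
          effectSize = sim$effectSize, seed = config$seed)
        writeDelimited(sec$replicates, pth("secondary_replicates.csv"), ",",
                       meta)
        # planted class sizes scale with the simulated ORF universe
        sc <- min(1, sim$nOrfs / 500)
        nComp <- max(1L, round(10 * sc))
        panTruth <- pangenomeTruth(
          nEnriched = max(nComp + 1L, round(23 * sc)),
          nDepleted = max(nComp + 1L, round(48 * sc)),
          nCompensated = nComp)
        pan <- simulatePangenome(
          nStrains = sim$nStrains, nOrfs = sim$nOrfs, truth = panTruth,
          hitSet = hits, strainIds = scr$truth$strain_ids,
          seed = config$seed)
        writePresenceMatrix(pan$presence, pth("presence.tsv"), meta)
        writeHomologyMap(pan$homology, pth("homology.tsv"), meta)
        dst <- simulateDistances(sim$nTaxa, seed = config$seed)
        writeDistanceMatrix(dst$d, pth("distances.tsv"), meta)
        qpStrains <- c(config$qpcr@calibratorStrain,
                       head(hits, min(9L, length(hits))))
        lv <- setNames(c(1, 2^seq(-2, 2,
                                  length.out = length(qpStrains) - 1L)),
                       qpStrains)
        qp <- simulateQpcr(qpStrains, trueRelExpression = lv,
                           ctNoiseSd = sim$qpcrNoiseSd,
                           params = config$qpcr, seed = config$seed)
        writeCtTable(qp$ct, pth("ct.csv"), meta)
        protStrains <- head(hits, min(20L, length(hits)))
        nUp <- max(1L, min(60L, floor(sim$nProteins / 10)))
        pf <- rbind(
          expand.grid(protein_id = sprintf("P%05d", seq_len(nUp)),
                      strain_id = protStrains, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE),
          expand.grid(protein_id = sprintf("P%05d", nUp + seq_len(nUp)),
                      strain_id = protStrains, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE))
        pf$log2fc <- rep(c(2, -2), each = nUp * length(protStrains))
        prot <- simulateProteomes(
          nProteins = sim$nProteins, strains = protStrains,
          truth = proteomeTruth(plantedFoldChanges = pf),
          nBioReps = sim$nBioReps, nTechReps = sim$nTechReps,
          referenceId = config$qpcr@calibratorStrain, seed = config$seed)
        writeIntensityMatrix(prot$pe, pth("intensity.tsv"),
                             pth("samples.tsv"), meta)
        panTruthOut <- pan$truth
        # named vectors serialize nameless; keep the pair mapping as an
        # object
        panTruthOut$plantedCompensatedPairs <-
          as.list(panTruthOut$plantedCompensatedPairs)
        truth <- list(screen = scr$truth, secondary = sec$truth,
                      pangenome = panTruthOut, qpcr = as.list(qp$truth),
                      proteome = list(cvTechnical = prot$truth$cvTechnical,
                                      cvBiological = prot$truth$cvBiological))
        jsonlite::write_json(truth, pth("truth.json"), auto_unbox = TRUE,
                             digits = NA, null = "null")
        counts$n_strains_simulated <- sim$nStrains
        counts$n_planted_hits <- length(hits)
      },
      quantify = {
        say(stage, "fitting linear windows and converting to Units")
        kin <- readKineticTable(pth("kinetics.csv"))
        lay <- readPlateLayout(pth("layout.csv"))
        act <- quantifyPlate(kin, lay, config$kinetics)
        writeActivityTable(act, pth("activity.tsv"), meta)
        counts$n_wells_quantified <- nrow(act)
        counts$n_qc_flagged <- sum(act$qc != "ok")
      },
      screen = {
        say(stage, "calling primary hits and confirming with replicates")
        act <- readActivityTable(pth("activity.tsv"))
        nBad <- sum(is.na(act$activity_U))
        if (nBad > 0)
          warning(nBad, " well(s) without a linear window dropped from ",
                  "hit calling")
        act <- act[!is.na(act$activity_U), , drop = FALSE]
        perStrain <- tapply(act$activity_U, act$strain_id, mean)
        hits <- callPrimaryHits(setNames(as.numeric(perStrain),
                                         names(perStrain)), config$screen)
        writeDelimited(hits, pth("primary_hits.tsv"), "\t", meta)
        counts$n_strains_screened <- nrow(hits)
        counts$n_primary_hits <- sum(hits$is_hit)
        if (file.exists(pth("secondary_replicates.csv"))) {
          reps <- readDelimited(pth("secondary_replicates.csv"), ",")
          refId <- config$qpcr@calibratorStrain
          res <- lapply(split(reps, reps$enzyme), function(r)
            secondaryScreen(r, refId, config$screen,
                            enzyme = r$enzyme[1]))
          sec <- do.call(rbind, c(unname(res),
                                  list(make.row.names = FALSE)))
          writeDelimited(sec, pth("secondary.tsv"), "\t", meta)
          counts$n_secondary_significant <-
            lapply(res, function(r) sum(r$significant))
          if (length(res) == 2L) {
            dual <- combineDualScreen(res[[1]], res[[2]])
            writeDelimited(dual$table, pth("dual_screen.tsv"), "\t", meta)
            counts$n_dual_union <- unname(dual$counts[["union"]])
            counts$pearson_r_dual <- dual$pearson_r
          }
        }
      },
      enrich = {
        say(stage, "ORF presence/absence enrichment")
        opm <- readPresenceMatrix(pth("presence.tsv"), "REF")
        hom <- readHomologyMap(pth("homology.tsv"))
        ph <- readDelimited(pth("primary_hits.tsv"), "\t")
        hitSet <- intersect(ph$strain_id[ph$is_hit], strainNames(opm))
        if (!length(hitSet)) stop("no called hits present in the matrix")
        rec <- fisherEnrichment(opm, hitSet, alpha = config$enrichAlpha)
        # pairs touching ORFs outside the tested (retained) set carry no
        # information for compensation
        hom <- hom[hom$orf_id %in% rec$orf_id &
                     hom$homolog_id %in% rec$orf_id, , drop = FALSE]
        cls <- classifyCompensation(rec, hom,
                                    minIdentity = config$minIdentity)
        writeDelimited(cls$records, pth("enrichment.tsv"), "\t", meta)
        counts$n_orfs_tested <- nrow(cls$records)
        counts$enrichment_classes <- as.list(cls$summary)
      },
      tree = {
        say(stage, "neighbour-joining tree")
        d <- readDistanceMatrix(pth("distances.tsv"))
        tr <- njTree(d)
        og <- config$treeOutgroup %||% sort(rownames(d))[1]
        writeNewick(rootAtOutgroup(tr, og), pth("tree.nwk"))
        counts$n_taxa <- nrow(d)
        counts$tree_outgroup <- og
      },
      qpcr = {
        say(stage, "comparative-Ct relative expression")
        ct <- readCtTable(pth("ct.csv"))
        lev <- relativeExpression(ct, config$qpcr)
        act <- readActivityTable(pth("activity.tsv"))
        perStrain <- tapply(act$activity_U, act$strain_id, mean)
        shared <- intersect(lev$strain_id, names(perStrain))
        ratio <- activityPerMrna(
          setNames(as.numeric(perStrain[shared]), shared),
          lev[lev$strain_id %in% shared, ],
          config$qpcr@calibratorStrain)
        out <- merge(lev, ratio[, c("strain_id", "activity_U",
                                    "activity_per_mrna")],
                     by = "strain_id", all.x = TRUE, sort = TRUE)
        writeDelimited(out, pth("qpcr.tsv"), "\t", meta)
        counts$n_qpcr_strains <- nrow(lev)
      },
      proteomics = {
        say(stage, "proteome QC, normalization, imputation, testing")
        pe <- readIntensityMatrix(pth("intensity.tsv"), pth("samples.tsv"))
        qc <- replicateQC(pe, config$proteomics)
        writeDelimited(qc$report, pth("qc_report.tsv"), "\t", meta)
        pe2 <- imputeMinProb(medianNormalize(qc$pe), config$proteomics,
                             seed = streamSeed(config$seed, "impute"))
        refId <- config$qpcr@calibratorStrain
        strains <- setdiff(unique(sampleInfo(pe2)$strain_id), refId)
        diffs <- do.call(rbind, c(lapply(strains, function(s)
          differentialAbundance(pe2, s, refId, config$proteomics)),
          list(make.row.names = FALSE)))
        writeDelimited(diffs, pth("differential.tsv"), "\t", meta)
        recur <- recurrenceFilter(diffs, config$proteomics)
        writeDelimited(
          data.frame(protein_id = c(recur$up, recur$down),
                     direction = rep(c("up", "down"),
                                     c(length(recur$up),
                                       length(recur$down))),
                     stringsAsFactors = FALSE),
          pth("recurrent.tsv"), "\t", meta)
        cvT <- try(cvProfile(pe2, "technical"), silent = TRUE)
        counts$n_samples_excluded <- length(qc$excluded)
        counts$n_differential_up <- sum(diffs$direction == "up")
        counts$n_differential_down <- sum(diffs$direction == "down")
        counts$n_recurrent_up <- length(recur$up)
        counts$n_recurrent_down <- length(recur$down)
        if (!inherits(cvT, "try-error"))
          counts$median_cv_technical <- unname(cvT$medianCV[refId])
      }))
  }

  report <- list(package = "PanScreen",
                 version = as.character(packageVersion("PanScreen")),
                 configHash = meta$configHash, seed = config$seed,
                 stages = stages, counts = counts,
                 warnings = warningsSeen)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
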