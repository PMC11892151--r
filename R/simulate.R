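## Seeded synthetic-data generators with planted ground truth. Each
## generator consumes one substream of the global seed (see streamSeed) so
## any stage can be regenerated independently, and returns the truth object
## needed for downstream recovery checks.

#' Simulate a primary production screen
#'
#' Generates plate-reader kinetic tables and a plate layout for a library
#' screen with planted high-producer strains. Each well's progress curve is
#' a lag followed by exponential saturation,
#' \deqn{A(t) = A_{base} + A_{max}\,(1 - e^{-r\,(t - t_{lag})_+}) + \epsilon,}
#' with rate r scaled so that the initial slope corresponds to the strain's
#' true activity through the Beer-Lambert relation, and Gaussian reading
#' noise of sd `noiseSd`. The lag and the saturation create the non-linear
#' ends that linear-range trimming removes. Strains share a common baseline
#' activity (per-strain biological spread can be added via `strainSdLog`);
#' planted hits are multiplied by `effectSize`. Strains are arrayed onto
#' 96-well plates, each carrying one reference-strain control well.
#'
#' @param nStrains Number of library strains (default 600).
#' @param nHits Number of planted high producers (default 30).
#' @param effectSize Fold activity increase of planted hits (default 2).
#' @param noiseSd Absorbance reading noise sd in AU (default 0.002).
#' @param nTimepoints Readings per trace, one per minute from minute 0
#'   (default 61).
#' @param seed Integer seed.
#' @param baselineActivity Baseline strain activity in Units
#'   (default 2e-4).
#' @param strainSdLog Log-scale sd of per-strain baseline variation
#'   (default 0: all non-hit strains share the baseline).
#' @param aMax Absorbance ceiling at full substrate conversion in AU
#'   (default 36, i.e. 1 mM oxidized product at epsilon 36000 and 1 cm).
#' @param lagTime Lag before the reaction starts, minutes (default 3).
#' @param baseAbs Background absorbance in AU (default 0.05).
#' @param pathLength Optical path length (cm) the traces correspond to
#'   (default 1).
#' @param referenceId Reference strain identifier (default "BY4741").
#' @return A list with `kinetics` (`data.frame`: `time_min` plus one column
#'   per well), `layout` (`data.frame`: `well`, `strain_id`,
#'   `replicate_id`, `role`, `plate`), and `truth` (list with `strain_ids`,
#'   `true_activity` named Units vector including the reference,
#'   `planted_hits`, `reference_id`).
#' @examples
#' sim <- simulateScreen(nStrains = 8, nHits = 2, seed = 1)
#' str(sim$truth)
#' @export
simulateScreen <- function(nStrains = 600, nHits = 30, effectSize = 2,
                           noiseSd = 0.002, nTimepoints = 61, seed = 1,
                           baselineActivity = 2e-4, strainSdLog = 0,
                           aMax = 36, lagTime = 3, baseAbs = 0.05,
                           pathLength = 1, referenceId = "BY4741") {
  nStrains <- assertCount(nStrains, "nStrains")
  nHits <- assertCount(nHits, "nHits", min = 0L)
  stopIfNot(nHits < nStrains, "nHits must be smaller than nStrains")
  assertNumber(effectSize, "effectSize", min = 1)
  assertNumber(noiseSd, "noiseSd", min = 0)
  nTimepoints <- assertCount(nTimepoints, "nTimepoints", min = 10L)
  assertNumber(baselineActivity, "baselineActivity", min = 0, strict = TRUE)
  assertNumber(strainSdLog, "strainSdLog", min = 0)
  set.seed(streamSeed(seed, "screen"))

  strainIds <- sprintf("strain%04d", seq_len(nStrains))
  baseline <- baselineActivity *
    exp(rnorm(nStrains, -strainSdLog^2 / 2, strainSdLog))
  hits <- sort(sample(strainIds, nHits))
  activity <- setNames(baseline, strainIds)
  activity[hits] <- activity[hits] * effectSize
  activity[referenceId] <- baselineActivity

  # one reference control well per 96-well plate, samples in the rest
  perPlate <- 95L
  nPlates <- ceiling(nStrains / perPlate)
  wellNames <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0))
  layout <- do.call(rbind, lapply(seq_len(nPlates), function(p) {
    idx <- ((p - 1L) * perPlate + 1L):min(p * perPlate, nStrains)
    ids <- c(referenceId, strainIds[idx])
    data.frame(
      well = paste0("P", sprintf("%02d", p), "_", wellNames[seq_along(ids)]),
      strain_id = ids, replicate_id = "r1",
      role = c("reference", rep("sample", length(idx))),
      plate = p, stringsAsFactors = FALSE)
  }))

  times <- seq(0, nTimepoints - 1L)
  eps <- 36000; vol <- 200  # assay constants matched by KineticsParams
  trace <- function(act) {
    slope0 <- act * eps * pathLength / vol
    r <- slope0 / aMax
    a <- baseAbs + aMax * (1 - exp(-r * pmax(times - lagTime, 0)))
    a + if (noiseSd > 0) rnorm(length(times), 0, noiseSd) else 0
  }
  mat <- vapply(layout$strain_id, function(s) trace(activity[[s]]),
                numeric(length(times)))
  kinetics <- data.frame(time_min = times, mat, check.names = FALSE)
  names(kinetics) <- c("time_min", layout$well)

  list(kinetics = kinetics, layout = layout,
       truth = list(strain_ids = strainIds, true_activity = activity,
                    planted_hits = hits, reference_id = referenceId))
}

#' Simulate a replicated secondary screen for one or two enzymes
#'
#' Generates per-replicate activities for a set of candidate strains plus
#' the reference strain, for each enzyme: log-normal noise of coefficient
#' of variation `cv` around the strain's true activity (baseline times
#' `effectSize` for planted producers of that enzyme).
#'
#' @param candidates Character vector of candidate strain ids.
#' @param producers Named list mapping enzyme name to the character vector
#'   of candidate strains that truly overproduce it.
#' @param nReps Biological replicates per strain (default 4).
#' @param cv Between-replicate coefficient of variation (default 0.22).
#' @param effectSize Fold effect of true producers (default 2).
#' @param baselineActivity Baseline activity in Units (default 2e-4).
#' @param referenceId Reference strain id (default "BY4741").
#' @param seed Integer seed.
#' @return A list with `replicates` (`data.frame`: `strain_id`, `enzyme`,
#'   `replicate_id`, `activity_U`) and `truth` (the `producers` list).
#' @export
simulateSecondaryScreen <- function(candidates,
                                    producers = list(ttLcc1 = candidates),
                                    nReps = 4, cv = 0.22, effectSize = 2,
                                    baselineActivity = 2e-4,
                                    referenceId = "BY4741", seed = 1) {
  nReps <- assertCount(nReps, "nReps", min = 2L)
  assertNumber(cv, "cv", min = 0)
  assertNumber(effectSize, "effectSize", min = 1)
  set.seed(streamSeed(seed, "screen") + 1L)
  sdlog <- sqrt(log(1 + cv^2))
  strains <- c(referenceId, setdiff(candidates, referenceId))
  rows <- list()
  for (enz in names(producers)) {
    for (s in strains) {
      act <- baselineActivity *
        (if (s %in% producers[[enz]]) effectSize else 1)
      vals <- act * exp(rnorm(nReps, -sdlog^2 / 2, sdlog))
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = s, enzyme = enz,
        replicate_id = paste0("r", seq_len(nReps)), activity_U = vals,
        stringsAsFactors = FALSE)
    }
  }
  list(replicates = do.call(rbind, rows), truth = producers)
}

#' Default planted truth for a simulated pan-genome
#'
#' Study-scale defaults: 23 enriched ORFs of which 10 are close homologs
#' compensating 10 of 48 depleted ORFs, on a background presence rate of
#' 0.35.
#'
#' @param nEnriched,nDepleted,nCompensated Planted class sizes (the
#'   compensating homologs are counted inside `nEnriched`, the compensated
#'   ORFs inside `nDepleted`).
#' @param backgroundRate Presence rate of unplanted ORFs (default 0.35).
#' @param enrichedRateHits,enrichedRateRest Presence rates of enriched ORFs
#'   in hit and non-hit strains (defaults 0.9 / 0.1).
#' @param depletedRateHits,depletedRateRest Presence rates of depleted ORFs
#'   in hit and non-hit strains (defaults 0.05 / 0.8).
#' @return A list usable as the `truth` argument of
#'   [simulatePangenome()].
#' @export
pangenomeTruth <- function(nEnriched = 23, nDepleted = 48, nCompensated = 10,
                           backgroundRate = 0.35, enrichedRateHits = 0.9,
                           enrichedRateRest = 0.1, depletedRateHits = 0.05,
                           depletedRateRest = 0.8) {
  nEnriched <- assertCount(nEnriched, "nEnriched", min = 0L)
  nDepleted <- assertCount(nDepleted, "nDepleted", min = 0L)
  nCompensated <- assertCount(nCompensated, "nCompensated", min = 0L)
  stopIfNot(nCompensated <= min(nEnriched, nDepleted),
            "nCompensated cannot exceed nEnriched or nDepleted")
  for (r in c(backgroundRate, enrichedRateHits, enrichedRateRest,
              depletedRateHits, depletedRateRest))
    stopIfNot(r >= 0 && r <= 1, "rates must lie in [0, 1]")
  stopIfNot(backgroundRate > 0 && backgroundRate < 1,
            "backgroundRate must lie in (0, 1)")
  comp <- sprintf("GENE_C%02d", seq_len(nCompensated))
  list(
    plantedEnriched = c(paste0(comp, "-like"),
                        sprintf("ORF_E%02d",
                                seq_len(nEnriched - nCompensated))),
    plantedDepleted = c(comp,
                        sprintf("GENE_D%02d",
                                seq_len(nDepleted - nCompensated))),
    plantedCompensatedPairs = setNames(paste0(comp, "-like"), comp),
    backgroundRate = backgroundRate,
    enrichedRateHits = enrichedRateHits,
    enrichedRateRest = enrichedRateRest,
    depletedRateHits = depletedRateHits,
    depletedRateRest = depletedRateRest)
}

#' Simulate a pan-genome presence/absence matrix with planted enrichment
#'
#' Builds a strains-by-ORFs presence matrix in which planted enriched ORFs
#' appear at an elevated rate among hit strains, planted depleted ORFs at a
#' reduced rate, and background ORFs i.i.d. at the background rate. The
#' reference strain carries the laboratory genome: it has every planted
#' depleted ORF and lacks every planted enriched ORF (which model
#' pan-genome ORFs absent from the reference assembly). Compensated pairs
#' are emitted in the homology map with amino-acid identities drawn
#' uniformly from [0.73, 0.99], alongside a few decoy pairs between
#' background ORFs.
#'
#' @param nStrains Number of strains including the reference (default 600).
#' @param nOrfs Number of ORFs (default 500).
#' @param truth Planted truth from [pangenomeTruth()] (default).
#' @param hitSet Character vector of hit strain ids (non-empty, proper
#'   subset of the strains).
#' @param seed Integer seed.
#' @param strainIds Optional strain identifiers (default
#'   `strain0001...`); the reference id is appended if absent.
#' @param referenceId Reference strain id (default "REF").
#' @param nDecoyPairs Homology decoy pairs among background ORFs
#'   (default 5).
#' @return A list with `presence` (an [ORFPresenceMatrix]), `homology`
#'   (`data.frame`: `orf_id`, `homolog_id`, `identity`) and `truth`.
#' @examples
#' sim <- simulatePangenome(nStrains = 60, nOrfs = 120,
#'                          hitSet = sprintf("strain%04d", 1:10), seed = 1)
#' sim$presence
#' @export
simulatePangenome <- function(nStrains = 600, nOrfs = 500,
                              truth = pangenomeTruth(), hitSet, seed = 1,
                              strainIds = NULL, referenceId = "REF",
                              nDecoyPairs = 5) {
  nStrains <- assertCount(nStrains, "nStrains", min = 2L)
  nOrfs <- assertCount(nOrfs, "nOrfs")
  if (is.null(strainIds)) strainIds <- sprintf("strain%04d", seq_len(nStrains))
  # the reference strain joins the matrix as an extra strain when absent
  if (!referenceId %in% strainIds) strainIds <- c(referenceId, strainIds)
  stopIfNot(length(hitSet) >= 1L, "hitSet must be non-empty")
  stopIfNot(all(hitSet %in% strainIds), "hitSet must be a subset of strains")
  stopIfNot(length(hitSet) < length(strainIds),
            "hitSet must be smaller than the strain set")
  stopIfNot(!referenceId %in% hitSet, "the reference strain cannot be a hit")
  planted <- c(truth$plantedEnriched, truth$plantedDepleted)
  if (length(planted) > nOrfs)
    stop("planted ORF count (", length(planted), ") exceeds nOrfs (",
         nOrfs, ")")
  set.seed(streamSeed(seed, "pangenome"))

  nBackground <- nOrfs - length(planted)
  orfIds <- c(planted, sprintf("ORF_B%04d", seq_len(nBackground)))
  isHit <- strainIds %in% hitSet
  isRef <- strainIds == referenceId

  rateFor <- function(orf) {
    if (orf %in% truth$plantedEnriched)
      ifelse(isRef, 0, ifelse(isHit, truth$enrichedRateHits,
                              truth$enrichedRateRest))
    else if (orf %in% truth$plantedDepleted)
      ifelse(isRef, 1, ifelse(isHit, truth$depletedRateHits,
                              truth$depletedRateRest))
    else rep(truth$backgroundRate, length(strainIds))
  }
  presence <- vapply(orfIds, function(o)
    runif(length(strainIds)) < rateFor(o), logical(length(strainIds)))
  dimnames(presence) <- list(strainIds, orfIds)

  pairs <- data.frame(
    orf_id = names(truth$plantedCompensatedPairs),
    homolog_id = unname(truth$plantedCompensatedPairs),
    identity = runif(length(truth$plantedCompensatedPairs), 0.73, 0.99),
    stringsAsFactors = FALSE)
  nDecoy <- min(nDecoyPairs, floor(nBackground / 2))
  if (nDecoy > 0) {
    bg <- sprintf("ORF_B%04d", seq_len(2 * nDecoy))
    pairs <- rbind(pairs, data.frame(
      orf_id = bg[seq_len(nDecoy)],
      homolog_id = bg[nDecoy + seq_len(nDecoy)],
      identity = runif(nDecoy, 0.73, 0.99), stringsAsFactors = FALSE))
  }
  list(presence = ORFPresenceMatrix(presence, referenceId),
       homology = pairs, truth = truth)
}

#' Simulate an additive distance matrix from a random tree
#'
#' Draws a random unrooted binary tree with branch lengths uniform in
#' `branchLengthRange` and returns the matrix of exact path-length (patristic)
#' distances between leaves, which is additive by construction, together
#' with the generating tree.
#'
#' @param nTaxa Number of taxa (>= 3; at least 4 for a non-trivial
#'   topology).
#' @param branchLengthRange Length-2 numeric range for branch lengths
#'   (default c(0.05, 1)).
#' @param seed Integer seed.
#' @return A list with `d` (symmetric numeric matrix, zero diagonal) and
#'   `tree` (the generating [ape::phylo]).
#' @examples
#' sim <- simulateDistances(8, seed = 1)
#' all.equal(sort(sim$d[1, ]), sort(cophenetic(sim$tree)[1, ]))
#' @export
simulateDistances <- function(nTaxa, branchLengthRange = c(0.05, 1),
                              seed = 1) {
  nTaxa <- assertCount(nTaxa, "nTaxa", min = 3L)
  stopIfNot(length(branchLengthRange) == 2L &&
              all(branchLengthRange > 0) && !is.unsorted(branchLengthRange),
            "branchLengthRange must be an increasing positive range")
  set.seed(streamSeed(seed, "distances"))
  tr <- ape::rtree(nTaxa, rooted = FALSE,
                   tip.label = sprintf("taxon%02d", seq_len(nTaxa)))
  tr$edge.length <- runif(nrow(tr$edge), branchLengthRange[1],
                          branchLengthRange[2])
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(d = d, tree = tr)
}

#' Default planted truth for simulated proteomes
#'
#' @param plantedFoldChanges `data.frame` with columns `protein_id`,
#'   `strain_id`, `log2fc` (default: none).
#' @param cvTechnical Technical replicate coefficient of variation
#'   (default 0.08).
#' @param cvBiological Total between-biological-replicate coefficient of
#'   variation, technical noise included (default 0.22; must exceed
#'   `cvTechnical` unless both are 0).
#' @param missMax Maximum censoring probability (default 1; 0 disables
#'   missingness).
#' @param missMidpoint Log2 intensity at which censoring probability is
#'   half of `missMax` (default 16).
#' @param missScale Logistic width of the censoring curve in log2 units
#'   (default 1).
#' @return A list usable as the `truth` argument of
#'   [simulateProteomes()].
#' @export
proteomeTruth <- function(plantedFoldChanges = NULL, cvTechnical = 0.08,
                          cvBiological = 0.22, missMax = 1,
                          missMidpoint = 16, missScale = 1) {
  assertNumber(cvTechnical, "cvTechnical", min = 0)
  assertNumber(cvBiological, "cvBiological", min = 0)
  if (!(cvTechnical < cvBiological || (cvTechnical == 0 && cvBiological == 0)))
    stop("cvTechnical must be smaller than cvBiological")
  assertNumber(missMax, "missMax", min = 0)
  stopIfNot(missMax <= 1, "missMax must lie in [0, 1]")
  assertNumber(missScale, "missScale", min = 0)
  if (is.null(plantedFoldChanges))
    plantedFoldChanges <- data.frame(protein_id = character(),
                                     strain_id = character(),
                                     log2fc = numeric())
  list(plantedFoldChanges = plantedFoldChanges, cvTechnical = cvTechnical,
       cvBiological = cvBiological, missMax = missMax,
       missMidpoint = missMidpoint, missScale = missScale)
}

#' Simulate proteome intensity matrices with planted effects
#'
#' Protein base abundances are log-normal (log2 intensities normal with
#' mean `baseMean`, sd `baseSd`). Each biological replicate adds log-scale
#' noise sized so the realized between-replicate CV matches
#' `truth$cvBiological`; technical replicates of the reference strain share
#' one biological draw and add technical noise at `truth$cvTechnical`.
#' Planted log2 fold changes shift specific proteins in specific strains.
#' Cells are then censored with probability
#' `missMax * plogis((missMidpoint - log2(I)) / missScale)`, i.e.
#' left-censoring that increases as intensity drops (missScale 0 with
#' missMax 0 disables censoring entirely).
#'
#' @param nProteins Number of proteins (default 4000).
#' @param strains Character vector of non-reference strains (default 20
#'   strains).
#' @param truth Planted truth from [proteomeTruth()].
#' @param nBioReps Biological replicates per strain (default 4; >= 2).
#' @param nTechReps Technical replicates of the reference sample
#'   (default 14).
#' @param referenceId Reference strain id (default "BY4741").
#' @param baseMean,baseSd Log2 base-intensity distribution parameters
#'   (defaults 20 and 2).
#' @param seed Integer seed.
#' @return A list with `pe` (a [ProteomeExperiment]) and `truth`.
#' @examples
#' sim <- simulateProteomes(nProteins = 50, strains = c("s1", "s2"),
#'                          nBioReps = 3, nTechReps = 3, seed = 1)
#' sim$pe
#' @export
simulateProteomes <- function(nProteins = 4000,
                              strains = sprintf("hit%02d", 1:20),
                              truth = proteomeTruth(), nBioReps = 4,
                              nTechReps = 14, referenceId = "BY4741",
                              baseMean = 20, baseSd = 2, seed = 1) {
  nProteins <- assertCount(nProteins, "nProteins")
  nBioReps <- assertCount(nBioReps, "nBioReps", min = 2L)
  nTechReps <- assertCount(nTechReps, "nTechReps", min = 0L)
  set.seed(streamSeed(seed, "proteomes"))

  # the plain sd/mean estimator over n replicates is biased low (its median
  # is that of a scaled chi distribution); inflate the injected spread so
  # the realized median CV matches the target at the design's replicate
  # counts
  chiMedian <- function(n) if (n >= 2) sqrt(qchisq(0.5, n - 1) / (n - 1))
    else 1
  cvTech <- truth$cvTechnical / chiMedian(nTechReps)
  cvBio <- truth$cvBiological / chiMedian(nBioReps)
  log2e <- log(2)
  sTechL2 <- sqrt(log(1 + cvTech^2)) / log2e
  sBioTotalL2 <- sqrt(log(1 + cvBio^2)) / log2e
  # biological component on top of technical measurement noise
  sBioL2 <- sqrt(max(sBioTotalL2^2 - sTechL2^2, 0))

  proteinIds <- sprintf("P%05d", seq_len(nProteins))
  base <- rnorm(nProteins, baseMean, baseSd)
  names(base) <- proteinIds

  fc <- matrix(0, nProteins, length(strains) + 1L,
               dimnames = list(proteinIds, c(referenceId, strains)))
  pf <- truth$plantedFoldChanges
  if (nrow(pf)) {
    stopIfNot(all(pf$protein_id %in% proteinIds) &&
                all(pf$strain_id %in% colnames(fc)),
              "plantedFoldChanges reference unknown proteins or strains")
    fc[cbind(match(pf$protein_id, proteinIds),
             match(pf$strain_id, colnames(fc)))] <- pf$log2fc
  }

  cols <- list(); meta <- list()
  addSample <- function(id, strain, repId, type, values) {
    cols[[id]] <<- values
    meta[[id]] <<- data.frame(sample_id = id, strain_id = strain,
                              replicate_id = repId, replicate_type = type,
                              stringsAsFactors = FALSE)
  }
  for (s in c(referenceId, strains)) {
    mu <- base + fc[, s]
    for (b in seq_len(nBioReps)) {
      x <- mu +
        (if (sBioL2 > 0) rnorm(nProteins, 0, sBioL2) else 0) +
        (if (sTechL2 > 0) rnorm(nProteins, 0, sTechL2) else 0)
      addSample(paste0(s, ".b", b), s, paste0("b", b), "biological", x)
    }
  }
  if (nTechReps > 0) {
    # technical replicates re-measure one biological preparation
    prep <- base + fc[, referenceId] +
      (if (sBioL2 > 0) rnorm(nProteins, 0, sBioL2) else 0)
    for (tch in seq_len(nTechReps))
      addSample(paste0(referenceId, ".t", tch), referenceId,
                paste0("t", tch), "technical",
                prep + (if (sTechL2 > 0) rnorm(nProteins, 0, sTechL2) else 0))
  }

  logI <- do.call(cbind, cols)
  rownames(logI) <- proteinIds
  intensity <- 2^logI
  if (truth$missMax > 0 && truth$missScale > 0) {
    pMiss <- truth$missMax *
      plogis((truth$missMidpoint - logI) / truth$missScale)
    intensity[matrix(runif(length(pMiss)), nrow(pMiss)) < pMiss] <- NA
  }
  info <- do.call(rbind, meta)
  rownames(info) <- info$sample_id
  list(pe = ProteomeExperiment(intensity, info), truth = truth)
}

#' Simulate a comparative-Ct qPCR table
#'
#' Target-gene Ct values encode the planted relative expression level:
#' `ct = ctBase - log(level) / log(efficiency) + noise`, with the reference
#' gene flat across strains, three technical replicates per strain and gene
#' by default. The calibrator strain must be included; planted levels are
#' normalized to it.
#'
#' @param strains Character vector of strain ids (must include the
#'   calibrator).
#' @param trueRelExpression Named positive numeric vector of relative
#'   levels per strain (default 1 for every strain).
#' @param ctNoiseSd Ct noise sd in cycles (default 0.1).
#' @param nTechReps Technical replicates (default 3).
#' @param params A [QpcrParams].
#' @param ctBaseTarget,ctBaseReference Baseline Ct values (defaults 22
#'   and 18).
#' @param seed Integer seed.
#' @return A list with `ct` (`data.frame`: `strain_id`, `gene`,
#'   `technical_replicate`, `ct`) and `truth` (normalized level vector).
#' @examples
#' sim <- simulateQpcr(c("BY4741", "s1"),
#'                     trueRelExpression = c(BY4741 = 1, s1 = 4),
#'                     ctNoiseSd = 0, seed = 1)
#' relativeExpression(sim$ct)
#' @export
simulateQpcr <- function(strains, trueRelExpression = NULL, ctNoiseSd = 0.1,
                         nTechReps = 3, params = QpcrParams(),
                         ctBaseTarget = 22, ctBaseReference = 18, seed = 1) {
  validObject(params)
  assertNumber(ctNoiseSd, "ctNoiseSd", min = 0)
  nTechReps <- assertCount(nTechReps, "nTechReps")
  cal <- params@calibratorStrain
  stopIfNot(cal %in% strains,
            "calibrator strain '", cal, "' must be among strains")
  if (is.null(trueRelExpression))
    trueRelExpression <- setNames(rep(1, length(strains)), strains)
  stopIfNot(all(strains %in% names(trueRelExpression)),
            "trueRelExpression must cover every strain")
  if (any(trueRelExpression <= 0))
    stop("relative expression levels must be positive")
  lv <- trueRelExpression[strains] / trueRelExpression[[cal]]
  set.seed(streamSeed(seed, "qpcr"))

  rows <- list()
  for (s in strains) for (g in c(params@targetGene, params@referenceGene)) {
    ctMean <- if (g == params@targetGene)
      ctBaseTarget - log(lv[[s]]) / log(params@efficiency)
    else ctBaseReference
    rows[[paste(s, g)]] <- data.frame(
      strain_id = s, gene = g, technical_replicate = seq_len(nTechReps),
      ct = ctMean + (if (ctNoiseSd > 0) rnorm(nTechReps, 0, ctNoiseSd)
                     else 0),
      stringsAsFactors = FALSE)
  }
  list(ct = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = lv)
}
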