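test_that("every generator is byte-identical under the same seed", {
  s1 <- simulateScreen(nStrains = 20, nHits = 3, seed = 7)
  s2 <- simulateScreen(nStrains = 20, nHits = 3, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(
    s1$kinetics, simulateScreen(nStrains = 20, nHits = 3, seed = 8)$kinetics))

  p1 <- simulatePangenome(nStrains = 30, nOrfs = 90, hitSet = "strain0001",
                          seed = 5)
  p2 <- simulatePangenome(nStrains = 30, nOrfs = 90, hitSet = "strain0001",
                          seed = 5)
  expect_identical(p1, p2)

  d1 <- simulateDistances(6, seed = 3)
  expect_identical(d1, simulateDistances(6, seed = 3))

  pr1 <- simulateProteomes(nProteins = 40, strains = "x", nBioReps = 2,
                           nTechReps = 2, seed = 4)
  expect_identical(pr1, simulateProteomes(nProteins = 40, strains = "x",
                                          nBioReps = 2, nTechReps = 2,
                                          seed = 4))

  q1 <- simulateQpcr(c("BY4741", "a"), seed = 2)
  expect_identical(q1, simulateQpcr(c("BY4741", "a"), seed = 2))
})

test_that("zero noise and no effect give identical traces across wells", {
  sim <- simulateScreen(nStrains = 2, nHits = 0, noiseSd = 0,
                        effectSize = 1, seed = 1)
  k <- sim$kinetics
  wells <- setdiff(names(k), "time_min")
  for (w in wells[-1]) expect_identical(k[[w]], k[[wells[1]]])
})

test_that("simulateScreen validates its parameters", {
  expect_error(simulateScreen(nStrains = 10, nHits = 10, seed = 1),
               "smaller")
  expect_error(simulateScreen(nStrains = 0, seed = 1), "nStrains")
  expect_error(simulateScreen(nStrains = 5, nHits = 1, noiseSd = -1,
                              seed = 1), "noiseSd")
  expect_error(simulateScreen(nStrains = 5, nHits = 1, effectSize = 0.5,
                              seed = 1), "effectSize")
  expect_error(simulateScreen(nStrains = 5, nHits = 1, nTimepoints = 5,
                              seed = 1), "nTimepoints")
})

test_that("simulated screen truth is internally consistent", {
  sim <- simulateScreen(nStrains = 50, nHits = 5, seed = 2)
  tr <- sim$truth
  expect_true(all(tr$planted_hits %in% tr$strain_ids))
  expect_true(all(tr$true_activity >= 0))
  expect_true(tr$reference_id %in% names(tr$true_activity))
  expect_equal(length(tr$planted_hits), 5L)
  # one reference well per plate
  expect_equal(sum(sim$layout$role == "reference"),
               length(unique(sim$layout$plate)))
})

test_that("pangenome identities lie in the reported homolog range", {
  sim <- simulatePangenome(nStrains = 60, nOrfs = 120,
                           hitSet = sprintf("strain%04d", 1:10), seed = 6)
  expect_true(all(sim$homology$identity >= 0.73 &
                    sim$homology$identity <= 0.99))
  expect_true(validObject(sim$presence))
  # reference carries depleted ORFs and lacks enriched ones
  p <- presenceMatrix(sim$presence)
  expect_true(all(p["REF", sim$truth$plantedDepleted]))
  expect_false(any(p["REF", sim$truth$plantedEnriched]))
  expect_error(
    simulatePangenome(nStrains = 10, nOrfs = 20,
                      hitSet = sprintf("strain%04d", 1:2), seed = 1),
    "planted ORF count")
  expect_error(simulatePangenome(nStrains = 10, nOrfs = 200,
                                 hitSet = character(), seed = 1),
               "non-empty")
})

test_that("an all-or-nothing depleted ORF reaches p below 1e-6", {
  truth <- pangenomeTruth(depletedRateHits = 0, depletedRateRest = 1)
  hits <- sprintf("strain%04d", 1:20)
  sim <- simulatePangenome(nStrains = 600, nOrfs = 500, truth = truth,
                           hitSet = hits, seed = 3)
  rec <- fisherEnrichment(sim$presence, hits,
                          orfs = truth$plantedDepleted[1])
  expect_lt(rec$p_value, 1e-6)
  expect_equal(rec$p_value,
               oracleFisherP(rec$present_in_hits, rec$absent_in_hits,
                             rec$present_in_rest, rec$absent_in_rest),
               tolerance = 1e-10)
})

test_that("empty planted sets give near-null discovery behaviour", {
  truth <- pangenomeTruth(nEnriched = 0, nDepleted = 0, nCompensated = 0)
  hits <- sprintf("strain%04d", 1:20)
  sim <- simulatePangenome(nStrains = 400, nOrfs = 400, truth = truth,
                           hitSet = hits, seed = 8)
  rec <- fisherEnrichment(sim$presence, hits, orfs = orfNames(sim$presence))
  disc <- sum(rec$class != "ns")
  expect_lt(disc, 0.05 * 400 * 1.6)  # conservative exact test
})

test_that("distance simulation yields a metric additive by construction", {
  sim <- simulateDistances(8, seed = 10)
  d <- sim$d
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
  # four-point condition on every quartet: the two largest of the three
  # pairings coincide
  taxa <- rownames(d)
  for (q in combn(taxa, 4, simplify = FALSE)) {
    s <- c(d[q[1], q[2]] + d[q[3], q[4]],
           d[q[1], q[3]] + d[q[2], q[4]],
           d[q[1], q[4]] + d[q[2], q[3]])
    s <- sort(s, decreasing = TRUE)
    expect_equal(s[1], s[2], tolerance = 1e-9)
  }
  expect_error(simulateDistances(2, seed = 1), "nTaxa")
})

test_that("proteome generator hits the planted CV scales", {
  sim <- simulateProteomes(nProteins = 2000, strains = c("s1", "s2"),
                           nBioReps = 4, nTechReps = 8, seed = 11)
  pe <- sim$pe
  cvT <- cvProfile(pe, "technical")$medianCV[["BY4741"]]
  cvB <- cvProfile(pe, "biological")$medianCV
  expect_lt(abs(cvT - 0.08), 0.02)
  expect_true(all(abs(cvB - 0.22) < 0.05))
  # left-censoring: missing cells concentrate at low planted intensity
  m <- intensities(pe)
  expect_gt(mean(is.na(m)), 0.01)

  noMiss <- simulateProteomes(nProteins = 100, strains = "s1",
                              truth = proteomeTruth(missMax = 0),
                              nBioReps = 2, nTechReps = 0, seed = 1)
  expect_false(anyNA(intensities(noMiss$pe)))
  # with no censoring, imputation is the identity
  expect_identical(intensities(imputeMinProb(noMiss$pe, seed = 3)),
                   intensities(noMiss$pe))
})

test_that("zero biological CV collapses replicates and differential calls", {
  sim <- simulateProteomes(nProteins = 150, strains = c("s1", "s2"),
                           truth = proteomeTruth(cvTechnical = 0,
                                                 cvBiological = 0,
                                                 missMax = 0),
                           nBioReps = 3, nTechReps = 0, seed = 2)
  m <- intensities(sim$pe)
  expect_identical(m[, "s1.b1"], m[, "s1.b2"])
  res <- differentialAbundance(sim$pe, "s1", "BY4741")
  expect_true(all(res$direction == "ns"))
  expect_true(all(res$log2_fc == 0))

  expect_error(proteomeTruth(cvTechnical = -1), "cvTechnical")
  expect_error(proteomeTruth(cvTechnical = 0.3, cvBiological = 0.2),
               "smaller")
})

test_that("planted proteome fold changes are recovered by the tests", {
  pf <- data.frame(protein_id = sprintf("P%05d", 1:20),
                   strain_id = "s1", log2fc = 2)
  sim <- simulateProteomes(nProteins = 400, strains = "s1",
                           truth = proteomeTruth(plantedFoldChanges = pf),
                           nBioReps = 4, nTechReps = 0, seed = 5)
  pe <- imputeMinProb(medianNormalize(sim$pe), seed = 9)
  res <- differentialAbundance(pe, "s1", "BY4741")
  planted <- res$protein_id %in% pf$protein_id
  expect_gt(mean(res$direction[planted] == "up"), 0.8)
  expect_lt(mean(res$direction[!planted] != "ns"), 0.05)
})

test_that("secondary-screen generator plants per-enzyme producers", {
  sim <- simulateSecondaryScreen(paste0("s", 1:6),
                                 producers = list(ttLcc1 = paste0("s", 1:3),
                                                  mtLcc1 = "s4"),
                                 cv = 0, seed = 1)
  reps <- sim$replicates
  tt <- reps[reps$enzyme == "ttLcc1", ]
  expect_equal(unique(tt$activity_U[tt$strain_id == "s1"]), 4e-4)
  expect_equal(unique(tt$activity_U[tt$strain_id == "s5"]), 2e-4)
  mt <- reps[reps$enzyme == "mtLcc1", ]
  expect_equal(unique(mt$activity_U[mt$strain_id == "s4"]), 4e-4)
})
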