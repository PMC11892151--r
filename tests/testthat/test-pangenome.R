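mkOpm <- function(p, ref = rownames(p)[1]) ORFPresenceMatrix(p, ref)

test_that("retainVariableOrfs keeps ORFs differing from the reference", {
  p <- matrix(c(TRUE, TRUE, TRUE,    # orfA: ref present, hits present
                TRUE, FALSE, TRUE,   # orfB: one hit lacks it
                FALSE, FALSE, FALSE, # orfC: absent everywhere
                FALSE, TRUE, TRUE),  # orfD: hits gained it
              nrow = 3,
              dimnames = list(c("ref", "h1", "h2"),
                              c("orfA", "orfB", "orfC", "orfD")))
  opm <- mkOpm(p)
  expect_equal(retainVariableOrfs(opm, c("h1", "h2")), c("orfB", "orfD"))
  expect_error(retainVariableOrfs(opm, character()), "non-empty")
  expect_error(retainVariableOrfs(opm, "nope"), "nope")
})

test_that("retainVariableOrfs equals an independent double loop", {
  set.seed(14)
  p <- matrix(runif(20 * 200) < 0.5, nrow = 20,
              dimnames = list(paste0("s", 1:20), paste0("o", 1:200)))
  opm <- mkOpm(p, "s1")
  hits <- paste0("s", 2:8)
  got <- retainVariableOrfs(opm, hits)
  want <- character()
  for (o in colnames(p)) {
    keep <- FALSE
    for (h in hits) if (p[h, o] != p["s1", o]) keep <- TRUE
    if (keep) want <- c(want, o)
  }
  expect_equal(got, want)
})

test_that("fisherExactP matches hypergeometric enumeration", {
  expect_equal(fisherExactP(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:50, 1), runif(4, 0.05, 1)))
    expect_equal(fisherExactP(cells[1], cells[2], cells[3], cells[4]),
                 oracleFisherP(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("fisherEnrichment classifies by direction and significance", {
  n <- 30; hits <- paste0("s", 1:6)
  p <- matrix(TRUE, n, 3,
              dimnames = list(paste0("s", 1:n), c("all", "enr", "dep")))
  p[, "enr"] <- c(rep(TRUE, 6), rep(FALSE, 24))
  p[, "dep"] <- c(rep(FALSE, 6), rep(TRUE, 24))
  opm <- mkOpm(p, "s30")
  rec <- fisherEnrichment(opm, hits, orfs = c("all", "enr", "dep"))
  expect_equal(rec$p_value[rec$orf_id == "all"], 1)
  expect_equal(rec$class, c("ns", "enriched", "depleted"))
  expect_equal(rec$present_in_hits + rec$absent_in_hits +
                 rec$present_in_rest + rec$absent_in_rest, rep(n, 3))

  expect_error(fisherEnrichment(opm, rownames(p)), "remainder")
  expect_error(fisherEnrichment(opm, hits, orfs = "nope"), "nope")
})

test_that("p-values and labels are invariant to strain and ORF order", {
  set.seed(31)
  p <- matrix(runif(40 * 30) < 0.4, 40,
              dimnames = list(paste0("s", 1:40), paste0("o", 1:30)))
  hits <- paste0("s", 1:8)
  a <- fisherEnrichment(mkOpm(p, "s40"), hits)
  perm <- p[sample(40), sample(30)]
  b <- fisherEnrichment(mkOpm(perm, "s40"), hits)
  b <- b[match(a$orf_id, b$orf_id), ]
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$class, b$class)
})

test_that("null presence matrices give roughly alpha*nOrfs discoveries", {
  set.seed(77)
  nOrfs <- 500
  p <- matrix(runif(120 * nOrfs) < 0.5, 120,
              dimnames = list(paste0("s", 1:120), paste0("o", 1:nOrfs)))
  rec <- fisherEnrichment(mkOpm(p, "s120"), paste0("s", 1:20),
                          orfs = colnames(p))
  disc <- sum(rec$class != "ns")
  # Fisher is conservative for discrete tables: at most ~alpha*n, not far
  # below on margins this size
  expect_lt(disc, 0.05 * nOrfs * 1.6)
  expect_gt(disc, 0)
  ks <- suppressWarnings(ks.test(rec$p_value, "punif"))
  expect_gt(mean(rec$p_value), 0.4)  # no systematic enrichment signal
  expect_true(is.finite(ks$statistic))
})

test_that("compensation relabels depleted ORFs with enriched homologs", {
  rec <- data.frame(
    orf_id = c("GAL1", "GAL1-like", "other"),
    present_in_hits = c(0, 10, 5), absent_in_hits = c(10, 0, 5),
    present_in_rest = c(40, 5, 20), absent_in_rest = c(10, 45, 30),
    odds_ratio = 1, p_value = c(1e-6, 1e-6, 0.8),
    q_value = NA_real_,
    class = c("depleted", "enriched", "ns"), stringsAsFactors = FALSE)

  none <- classifyCompensation(rec, data.frame(orf_id = character(),
                                               homolog_id = character(),
                                               identity = numeric()))
  expect_equal(none$records$class, rec$class)
  expect_equal(unname(none$summary),
               c(1L, 0L, 1L))

  hom <- data.frame(orf_id = "GAL1", homolog_id = "GAL1-like",
                    identity = 0.9)
  res <- classifyCompensation(rec, hom)
  expect_equal(res$records$class[res$records$orf_id == "GAL1"],
               "compensated")
  expect_equal(res$records$compensating_orf[1], "GAL1-like")
  expect_equal(unname(res$summary), c(1L, 1L, 0L))

  # below the identity floor the link does not count
  low <- classifyCompensation(rec, transform(hom, identity = 0.5))
  expect_equal(low$summary[["n_compensated"]], 0L)

  expect_error(classifyCompensation(rec,
                                    data.frame(orf_id = "zzz",
                                               homolog_id = "GAL1",
                                               identity = 0.9)),
               "zzz")
})

test_that("the highest-identity enriched homolog is recorded", {
  rec <- data.frame(
    orf_id = c("dep", "enrA", "enrB"),
    present_in_hits = 1, absent_in_hits = 1, present_in_rest = 1,
    absent_in_rest = 1, odds_ratio = 1, p_value = 0.01, q_value = NA_real_,
    class = c("depleted", "enriched", "enriched"), stringsAsFactors = FALSE)
  hom <- data.frame(orf_id = c("dep", "enrB"),
                    homolog_id = c("enrA", "dep"),
                    identity = c(0.8, 0.95))
  res <- classifyCompensation(rec, hom)
  expect_equal(res$records$compensating_orf[1], "enrB")  # symmetric link
  expect_equal(res$records$compensating_identity[1], 0.95)
})

test_that("class labels partition tested ORFs after compensation", {
  set.seed(4)
  sim <- simulatePangenome(nStrains = 200, nOrfs = 150,
                           hitSet = sprintf("strain%04d", 1:20), seed = 9)
  rec <- fisherEnrichment(sim$presence, sprintf("strain%04d", 1:20))
  res <- classifyCompensation(rec, sim$homology)
  expect_true(all(res$records$class %in%
                    c("enriched", "depleted", "compensated", "ns")))
  expect_equal(sum(res$summary[c("n_compensated",
                                 "n_depleted_remaining")]),
               sum(rec$class == "depleted"))
})

test_that("planted pan-genome classes are recovered at generous effects", {
  sim <- simulatePangenome(nStrains = 600, nOrfs = 500,
                           hitSet = sprintf("strain%04d", 1:20), seed = 2)
  rec <- fisherEnrichment(sim$presence, sprintf("strain%04d", 1:20),
                          correct = "BH")
  res <- classifyCompensation(rec, sim$homology)
  truth <- sim$truth
  cls <- setNames(res$records$class, res$records$orf_id)
  plantedComp <- names(truth$plantedCompensatedPairs)
  plainDepleted <- setdiff(truth$plantedDepleted, plantedComp)
  # perfect recall of every planted class at these effect sizes
  expect_true(all(cls[truth$plantedEnriched] == "enriched"))
  expect_true(all(cls[plantedComp] == "compensated"))
  expect_true(all(cls[plainDepleted] == "depleted"))
  # chance discoveries among the null background stay within the FDR the
  # BH procedure targets (with Monte-Carlo slack)
  planted <- c(truth$plantedEnriched, truth$plantedDepleted)
  fp <- sum(cls[setdiff(names(cls), planted)] != "ns")
  expect_lte(fp / sum(cls != "ns"), 0.2)
})
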