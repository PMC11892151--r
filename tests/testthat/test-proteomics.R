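mkPe <- function(m, strains, types = "biological") {
  info <- data.frame(strain_id = strains,
                     replicate_id = paste0("r", seq_along(strains)),
                     replicate_type = types, stringsAsFactors = FALSE)
  rownames(info) <- colnames(m)
  ProteomeExperiment(m, info)
}

test_that("ProteomeExperiment enforces positivity and metadata", {
  m <- matrix(c(1, 2, 3, 4), 2,
              dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_s4_class(mkPe(m, c("x", "x")), "ProteomeExperiment")
  m2 <- m; m2[1, 1] <- -1
  expect_error(mkPe(m2, c("x", "x")), "positive")
  info <- data.frame(strain_id = c("x", "x"))
  expect_error(ProteomeExperiment(m, info), "replicate_id")
})

test_that("replicateQC keeps concordant and drops discordant replicates", {
  set.seed(1)
  base <- 2^rnorm(400, 20, 2)
  m <- cbind(a1 = base * 2^rnorm(400, 0, 0.1),
             a2 = base * 2^rnorm(400, 0, 0.1),
             a3 = 2^rnorm(400, 20, 2),    # unrelated noise
             b1 = base * 2^rnorm(400, 0, 0.1),
             b2 = base * 2^rnorm(400, 0, 0.1))
  rownames(m) <- paste0("p", 1:400)
  pe <- mkPe(m, c("A", "A", "A", "B", "B"))
  res <- replicateQC(pe)
  expect_equal(res$excluded, "a3")
  expect_equal(ncol(intensities(res$pe)), 4L)
  expect_true(all(res$report$max_r2[res$report$sample_id %in%
                                      c("a1", "a2")] > 0.85))
})

test_that("two mutually discordant replicates lose only the worse one", {
  set.seed(2)
  base <- 2^rnorm(500, 20, 2)
  m <- cbind(c1 = base * 2^rnorm(500, 0, 0.05),  # consistent with B strain
             c2 = 2^rnorm(500, 20, 2),           # unrelated to everything
             b1 = base * 2^rnorm(500, 0, 0.05),
             b2 = base * 2^rnorm(500, 0, 0.05))
  rownames(m) <- paste0("p", 1:500)
  pe <- mkPe(m, c("C", "C", "B", "B"))
  res <- replicateQC(pe)
  expect_equal(res$excluded, "c2")  # c1 correlates with B samples globally
})

test_that("a single-replicate strain is retained with a warning", {
  set.seed(4)
  base <- 2^rnorm(50, 20, 2)
  m <- cbind(a1 = base, a2 = base * 2^rnorm(50, 0, 0.05),
             b1 = 2^rnorm(50, 20, 2))
  rownames(m) <- paste0("p", 1:50)
  pe <- mkPe(m, c("A", "A", "B"))
  expect_warning(res <- replicateQC(pe), "single biological replicate")
  expect_equal(length(res$excluded), 0L)
})

test_that("median normalization equalizes observed sample medians", {
  m <- matrix(c(5, 10, 15, 10, 20, 30), 3,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  pe <- mkPe(m, c("A", "B"))
  out <- intensities(medianNormalize(pe))
  expect_equal(unname(apply(out, 2, median)), c(15, 15))

  # idempotent; pre-scaling one sample only changes the global scale, so
  # within- and between-sample ratios are exactly invariant
  pe1 <- medianNormalize(pe)
  expect_equal(intensities(medianNormalize(pe1)), intensities(pe1))
  for (c_ in c(0.1, 1, 10)) {
    m2 <- m; m2[, 1] <- m[, 1] * c_
    out2 <- intensities(medianNormalize(mkPe(m2, c("A", "B"))))
    ratio <- out2 / intensities(pe1)
    expect_equal(max(ratio), min(ratio), tolerance = 1e-12)
    expect_equal(out2[, 1] / out2[, 2],
                 intensities(pe1)[, 1] / intensities(pe1)[, 2])
  }

  # a single sample is unchanged
  one <- mkPe(m[, 1, drop = FALSE], "A")
  expect_equal(intensities(medianNormalize(one)), m[, 1, drop = FALSE])

  mNA <- m; mNA[, 2] <- NA
  expect_error(medianNormalize(mkPe(mNA, c("A", "B"))), "no observed")
})

test_that("missing cells survive normalization untouched as NA", {
  m <- matrix(c(5, 10, 15, 10, NA, 30), 3,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  out <- intensities(medianNormalize(mkPe(m, c("A", "B"))))
  expect_true(is.na(out[2, 2]))
  expect_equal(sum(is.na(out)), 1L)
})

test_that("imputation fills all gaps positively, reproducibly, low", {
  set.seed(33)
  m <- matrix(2^rnorm(3000, 20, 2), 300,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:10)))
  m[runif(length(m)) < 0.1] <- NA
  pe <- mkPe(m, rep(c("A", "B"), each = 5))
  imp1 <- imputeMinProb(pe, seed = 7)
  imp2 <- imputeMinProb(pe, seed = 7)
  out <- intensities(imp1)
  expect_false(anyNA(out))
  expect_true(all(out > 0))
  expect_identical(out, intensities(imp2))
  obs <- !is.na(m)
  expect_identical(out[obs], m[obs])  # observed cells never altered
  # imputed values sit near each sample's low quantile
  expect_lt(median(out[!obs]), quantile(m[obs], 0.2))
  # a different seed gives different draws
  expect_false(identical(out, intensities(imputeMinProb(pe, seed = 8))))

  # complete input is returned unchanged
  full <- mkPe(matrix(2^rnorm(40, 20, 1), 20,
                      dimnames = list(paste0("p", 1:20), c("a", "b"))),
               c("A", "B"))
  expect_identical(intensities(imputeMinProb(full, seed = 1)),
                   intensities(full))
})

test_that("sparse samples fall back to the global quantile with warning", {
  set.seed(5)
  m <- matrix(2^rnorm(60, 20, 2), 30,
              dimnames = list(paste0("p", 1:30), c("a", "b")))
  m[1:20, 2] <- NA  # only 10 observed values in sample b
  pe <- mkPe(m, c("A", "A"))
  expect_warning(imp <- imputeMinProb(pe, seed = 1), "< 20 observed")
  expect_false(anyNA(intensities(imp)))
})

test_that("differential abundance is antisymmetric with exact nulls", {
  set.seed(12)
  m <- 2^matrix(rnorm(200 * 8, 20, 0.3), 200)
  dimnames(m) <- list(paste0("p", 1:200), paste0("s", 1:8))
  m[1:5, 1:4] <- m[1:5, 1:4] * 8  # planted 3-log2 up in strain A
  pe <- mkPe(m, rep(c("A", "B"), each = 4))
  ab <- differentialAbundance(pe, "A", "B")
  ba <- differentialAbundance(pe, "B", "A")
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(all(ab$direction[1:5] == "up"))
  expect_true(all(ba$direction[1:5] == "down"))
  expect_true(all(ab$q_value >= ab$p_value))
  expect_equal(ab$q_value, p.adjust(ab$p_value, "BH"))

  # identical groups: no fold change, no calls
  m2 <- cbind(m[, 1:4], m[, 1:4])
  colnames(m2) <- paste0("s", 1:8)
  peSame <- mkPe(m2, rep(c("A", "B"), each = 4))
  same <- differentialAbundance(peSame, "A", "B")
  expect_true(all(same$log2_fc == 0))
  expect_true(all(same$direction == "ns"))
  expect_true(all(same$p_value == 1))

  mNA <- m; mNA[1, 1] <- NA
  expect_error(differentialAbundance(mkPe(mNA, rep(c("A", "B"), each = 4)),
                                     "A", "B"), "missing cells")
  expect_error(differentialAbundance(pe, "A", "Z"), "replicates")
})

test_that("direction calls respect the fold-change and alpha gates", {
  set.seed(3)
  base <- 2^rnorm(100, 20, 0.01)
  m <- cbind(a1 = base, a2 = base * 2^0.02, a3 = base * 2^-0.02,
             b1 = base, b2 = base * 2^0.02, b3 = base * 2^-0.02)
  m[1, 1:3] <- m[1, 1:3] * 1.8   # significant but below 2-fold
  rownames(m) <- paste0("p", 1:100)
  pe <- mkPe(m, rep(c("A", "B"), each = 3))
  res <- differentialAbundance(pe, "A", "B")
  expect_lt(res$p_value[1], 0.05)
  expect_equal(res$direction[1], "ns")  # fails the fold-change gate
})

test_that("recurrence filter applies the at-least-half rule exactly", {
  mk <- function(protein, nUp, nDown, nStrains = 20) {
    dirs <- c(rep("up", nUp), rep("down", nDown),
              rep("ns", nStrains - nUp - nDown))
    data.frame(protein_id = protein, strain_id = paste0("st", 1:nStrains),
               log2_fc = 0, p_value = 1, q_value = 1, direction = dirs,
               stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("boundary", 10, 0), mk("below", 9, 0),
               mk("downer", 0, 12), mk("mixed", 10, 10))
  expect_warning(res <- recurrenceFilter(rec), "both directions")
  expect_equal(res$up, "boundary")
  expect_equal(res$down, "downer")
  expect_equal(res$conflicted, "mixed")
  expect_equal(res$n_required, 10)

  # brute-force recount on random assignments
  set.seed(9)
  rnd <- do.call(rbind, lapply(paste0("p", 1:50), function(p)
    data.frame(protein_id = p, strain_id = paste0("st", 1:8), log2_fc = 0,
               p_value = 1, q_value = 1,
               direction = sample(c("up", "down", "ns"), 8, replace = TRUE),
               stringsAsFactors = FALSE)))
  res2 <- suppressWarnings(recurrenceFilter(rnd))
  need <- ceiling(0.5 * 8)
  for (p in paste0("p", 1:50)) {
    ups <- sum(rnd$direction[rnd$protein_id == p] == "up")
    dns <- sum(rnd$direction[rnd$protein_id == p] == "down")
    expect_equal(p %in% res2$up, ups >= need && dns < need)
    expect_equal(p %in% res2$down, dns >= need && ups < need)
  }
})

test_that("CV profile matches hand-computed values", {
  m <- matrix(c(8, 12, 10, 10), 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("t1", "t2")))
  pe <- mkPe(m, c("X", "X"), types = "technical")
  prof <- cvProfile(pe, "technical")
  expect_equal(prof$cv$cv[prof$cv$protein_id == "p1"],
               sd(c(8, 12)) / 10)
  expect_equal(prof$cv$cv[prof$cv$protein_id == "p2"], 0)
  expect_equal(unname(prof$medianCV["X"]),
               median(c(sd(c(8, 12)) / 10, 0)))

  expect_error(cvProfile(mkPe(m[, 1, drop = FALSE], "X",
                              types = "technical"), "technical"),
               "single")
  expect_error(cvProfile(pe, "biological"), "no biological")
})

test_that("PCA separates strains with distinct proteomes", {
  set.seed(20)
  base <- rnorm(300, 20, 2)
  shift <- c(rep(3, 150), rep(0, 150))
  m <- 2^cbind(a1 = base + rnorm(300, 0, 0.1),
               a2 = base + rnorm(300, 0, 0.1),
               b1 = base + shift + rnorm(300, 0, 0.1),
               b2 = base + shift + rnorm(300, 0, 0.1))
  rownames(m) <- paste0("p", 1:300)
  res <- pcaSamples(mkPe(m, c("A", "A", "B", "B")))
  expect_equal(nrow(res$scores), 4L)
  pc1 <- res$scores$PC1
  expect_gt(min(abs(outer(pc1[1:2], pc1[3:4], `-`))),
            max(abs(pc1[1] - pc1[2]), abs(pc1[3] - pc1[4])))
  expect_gt(res$varianceExplained[1], 0.5)
})
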