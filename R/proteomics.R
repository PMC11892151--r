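#' Exclude discordant biological replicates
#'
#' For every biological-replicate sample, computes the pairwise R^2 of
#' log2 intensities (over mutually observed proteins) against each other
#' biological replicate of the same strain. A sample is excluded only when
#' it falls below `params@r2Exclude` against *every* sibling replicate.
#' When exactly two replicates are mutually discordant, only the one with
#' the lower median R^2 against all other samples in the dataset is
#' excluded (ties keep the earlier column), so a strain is never emptied.
#' Strains with a single biological replicate are retained with a warning.
#' Technical replicates are not subject to exclusion.
#'
#' @param pe A [ProteomeExperiment].
#' @param params A [ProteomicsParams].
#' @return A list with `pe` (filtered [ProteomeExperiment]), `excluded`
#'   (character vector of sample ids) and `report` (`data.frame` with
#'   per-sample minimum and maximum sibling R^2).
#' @export
replicateQC <- function(pe, params = ProteomicsParams()) {
  validObject(pe); validObject(params)
  m <- log2(intensities(pe))
  info <- sampleInfo(pe)
  bio <- which(info$replicate_type == "biological")

  pairR2 <- function(i, j) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (sum(ok) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(m[ok, i], m[ok, j]))^2
  }

  excluded <- character()
  report <- data.frame(sample_id = colnames(m)[bio],
                       strain_id = info$strain_id[bio],
                       min_r2 = NA_real_, max_r2 = NA_real_,
                       excluded = FALSE, stringsAsFactors = FALSE)
  for (s in unique(info$strain_id[bio])) {
    idx <- bio[info$strain_id[bio] == s]
    if (length(idx) < 2L) {
      warning("strain '", s, "' has a single biological replicate; retained")
      next
    }
    r2 <- matrix(NA_real_, length(idx), length(idx))
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a != b)
      r2[a, b] <- pairR2(idx[a], idx[b])
    rows <- match(colnames(m)[idx], report$sample_id)
    report$min_r2[rows] <- apply(r2, 1, min, na.rm = TRUE)
    report$max_r2[rows] <- apply(r2, 1, max, na.rm = TRUE)
    bad <- which(report$max_r2[rows] < params@r2Exclude)
    if (length(bad) == length(idx) && length(idx) == 2L) {
      # mutual two-replicate discord: drop only the globally less
      # consistent sample
      med <- vapply(idx, function(i) {
        others <- setdiff(seq_len(ncol(m)), i)
        median(vapply(others, function(j) pairR2(i, j), numeric(1)),
               na.rm = TRUE)
      }, numeric(1))
      bad <- which.min(med)
    }
    if (length(bad)) {
      excluded <- c(excluded, colnames(m)[idx[bad]])
      report$excluded[rows[bad]] <- TRUE
    }
  }
  keep <- setdiff(colnames(m), excluded)
  list(pe = pe[, keep], excluded = excluded, report = report)
}

#' Median-scaling normalization across samples
#'
#' Divides each sample's observed intensities by that sample's median, then
#' multiplies by the mean of the per-sample medians, so that every sample's
#' observed-value median equals the grand mean of the original medians.
#' Missing cells are untouched. The operation is idempotent.
#'
#' @param pe A [ProteomeExperiment].
#' @return The normalized [ProteomeExperiment].
#' @export
medianNormalize <- function(pe) {
  validObject(pe)
  m <- intensities(pe)
  med <- apply(m, 2, median, na.rm = TRUE)
  if (any(!is.finite(med))) {
    bad <- colnames(m)[!is.finite(med)]
    stop("sample(s) with no observed intensities: ",
         paste(bad, collapse = ", "))
  }
  target <- mean(med)
  m <- sweep(m, 2, target / med, `*`)
  intensities(pe) <- m
  pe
}

#' Left-censored imputation from the bottom of each sample's distribution
#'
#' Missing proteome intensities are predominantly low-abundance censoring,
#' so missing cells in each sample are drawn from a normal distribution
#' centred at that sample's `imputeQuantile` quantile (bottom 5% by
#' default). The spread starts at the standard deviation of the sample's
#' bottom-decile intensities and is halved until all draws for the sample
#' are positive, guaranteeing valid intensities. Observed cells are never
#' altered; given a seed the result is reproducible. Samples with fewer
#' than 20 observed values fall back to the global quantile and spread,
#' with a warning.
#'
#' @param pe A [ProteomeExperiment] (normalize first; see
#'   [medianNormalize()]).
#' @param params A [ProteomicsParams].
#' @param seed Integer seed for the imputation draws (optional).
#' @return A complete [ProteomeExperiment] with metadata fields
#'   `imputeSeed` and `imputeSigma` (final per-sample spreads) recorded in
#'   `metadata(pe)`.
#' @export
imputeMinProb <- function(pe, params = ProteomicsParams(), seed = NULL) {
  validObject(pe); validObject(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- intensities(pe)
  allObs <- m[!is.na(m)]
  gMu <- quantile(allObs, params@imputeQuantile, names = FALSE)
  gSig <- sd(allObs[allObs <= quantile(allObs, 0.1)])
  sigmas <- setNames(rep(NA_real_, ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    miss <- which(is.na(m[, j]))
    if (!length(miss)) next
    obs <- m[!is.na(m[, j]), j]
    if (length(obs) < 20L) {
      warning("sample '", colnames(m)[j],
              "' has < 20 observed values; using global quantile")
      mu <- gMu; sig <- gSig
    } else {
      mu <- quantile(obs, params@imputeQuantile, names = FALSE)
      sig <- sd(obs[obs <= quantile(obs, 0.1)])
    }
    if (!is.finite(sig) || sig <= 0) sig <- 0.1 * mu
    repeat {
      draws <- rnorm(length(miss), mean = mu, sd = sig)
      if (all(draws > 0)) break
      sig <- sig / 2
    }
    m[miss, j] <- draws
    sigmas[j] <- sig
  }
  intensities(pe) <- m
  S4Vectors::metadata(pe)$imputeSeed <- seed
  S4Vectors::metadata(pe)$imputeSigma <- sigmas
  pe
}

#' Differential protein abundance versus the reference strain
#'
#' Per protein, a Welch unequal-variance t-test (two-sided) on log2
#' intensities of the strain's biological replicates against the
#' reference strain's biological replicates. The log2 fold change is the
#' difference of group means. Benjamini-Hochberg adjusted values are always
#' reported; the `direction` call (`up`/`down`/`ns`) requires
#' |log2FC| >= log2(`fcMin`) and raw p <= `alpha` by default
#' (`params@correction` "BH" switches the filter to the adjusted value).
#' Swapping strain and reference negates every fold change and leaves
#' p-values unchanged.
#'
#' @param pe A complete (imputed) [ProteomeExperiment]; missing cells are
#'   an error, enforcing the QC-normalize-impute-test order.
#' @param strain,reference Strain identifiers to compare.
#' @param params A [ProteomicsParams].
#' @return `data.frame` with columns `protein_id`, `strain_id`, `log2_fc`,
#'   `p_value`, `q_value`, `direction`.
#' @export
differentialAbundance <- function(pe, strain, reference,
                                  params = ProteomicsParams()) {
  validObject(pe); validObject(params)
  m <- intensities(pe)
  if (anyNA(m))
    stop("intensity matrix has missing cells; run imputeMinProb() first")
  info <- sampleInfo(pe)
  gi <- which(info$strain_id == strain & info$replicate_type == "biological")
  gr <- which(info$strain_id == reference &
                info$replicate_type == "biological")
  if (length(gi) < 2L || length(gr) < 2L)
    stop("both groups need >= 2 biological replicates (",
         strain, ": ", length(gi), ", ", reference, ": ", length(gr), ")")
  x <- log2(m[, gi, drop = FALSE])
  y <- log2(m[, gr, drop = FALSE])
  lfc <- rowMeans(x) - rowMeans(y)
  sdx <- apply(x, 1, sd); sdy <- apply(y, 1, sd)
  pv <- vapply(seq_len(nrow(m)), function(i) {
    if (sdx[i] == 0 && sdy[i] == 0)
      return(if (lfc[i] == 0) 1 else 0)
    t.test(x[i, ], y[i, ], var.equal = FALSE)$p.value
  }, numeric(1))
  qv <- p.adjust(pv, "BH")
  crit <- if (params@correction == "BH") qv else pv
  lfcMin <- log2(params@fcMin)
  dir_ <- ifelse(crit <= params@alpha & lfc >= lfcMin, "up",
          ifelse(crit <= params@alpha & lfc <= -lfcMin, "down", "ns"))
  data.frame(protein_id = rownames(m), strain_id = strain, log2_fc = lfc,
             p_value = pv, q_value = qv, direction = dir_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter differential calls recurring across hit strains
#'
#' A protein passes the recurrence filter when it is called in the same
#' direction in at least `ceil(recurrenceFraction * nStrains)` of the
#' compared strains. A protein reaching the cut-off in both directions
#' (possible only at fractions <= 0.5) is excluded from both sets and
#' reported as conflicted.
#'
#' @param records Row-bound [differentialAbundance()] outputs across
#'   strains.
#' @param params A [ProteomicsParams].
#' @return A list with `up` and `down` (character vectors of protein ids),
#'   `conflicted`, and `n_required` (the strain count cut-off used).
#' @export
recurrenceFilter <- function(records, params = ProteomicsParams()) {
  validObject(params)
  stopIfNot(all(c("protein_id", "strain_id", "direction") %in%
                  names(records)),
            "records must come from differentialAbundance()")
  nStrains <- length(unique(records$strain_id))
  stopIfNot(nStrains >= 1L, "records must span at least one strain")
  need <- ceiling(params@recurrenceFraction * nStrains)
  cnt <- function(dir_) {
    r <- records[records$direction == dir_, ]
    tab <- table(r$protein_id)
    names(tab)[tab >= need]
  }
  up <- cnt("up"); down <- cnt("down")
  conflicted <- intersect(up, down)
  if (length(conflicted))
    warning(length(conflicted),
            " protein(s) recurrent in both directions; excluded from both")
  list(up = sort(setdiff(up, conflicted)),
       down = sort(setdiff(down, conflicted)),
       conflicted = sort(conflicted), n_required = need)
}

#' Per-protein coefficients of variation within replicate groups
#'
#' CV = sd/mean on linear-scale intensities, per protein, within each
#' strain's technical or biological replicates; proteins observed in fewer
#' than 2 samples of a group get `NA`. The summary is the median CV across
#' proteins per strain.
#'
#' @param pe A [ProteomeExperiment].
#' @param groupBy "technical" or "biological" replicate groups.
#' @return A list with `cv` (`data.frame`: `strain_id`, `protein_id`, `cv`)
#'   and `medianCV` (named numeric, per strain).
#' @export
cvProfile <- function(pe, groupBy = c("technical", "biological")) {
  validObject(pe)
  groupBy <- match.arg(groupBy)
  m <- intensities(pe)
  info <- sampleInfo(pe)
  sel <- which(info$replicate_type == groupBy)
  if (!length(sel)) stop("no ", groupBy, " replicates in the experiment")
  out <- list(); med <- c()
  for (s in unique(info$strain_id[sel])) {
    idx <- sel[info$strain_id[sel] == s]
    if (length(idx) < 2L)
      stop("strain '", s, "' has a single ", groupBy,
           " replicate; CV undefined")
    sub <- m[, idx, drop = FALSE]
    nObs <- rowSums(!is.na(sub))
    cv <- ifelse(nObs >= 2L,
                 apply(sub, 1, sd, na.rm = TRUE) /
                   rowMeans(sub, na.rm = TRUE), NA_real_)
    out[[s]] <- data.frame(strain_id = s, protein_id = rownames(m),
                           cv = unname(cv), stringsAsFactors = FALSE)
    med[s] <- median(cv, na.rm = TRUE)
  }
  list(cv = do.call(rbind, c(out, list(make.row.names = FALSE))),
       medianCV = med)
}

#' Principal component analysis of sample proteomes
#'
#' Reporting aid: log2-transforms the intensity matrix, keeps complete-case
#' proteins only, centres each protein, and runs [stats::prcomp] on the
#' samples.
#'
#' @param pe A [ProteomeExperiment].
#' @param nComponents Number of components to return (default 2).
#' @return A list with `scores` (`data.frame` of sample coordinates with
#'   strain metadata) and `varianceExplained` (fractions per component).
#' @export
pcaSamples <- function(pe, nComponents = 2L) {
  validObject(pe)
  m <- log2(intensities(pe))
  m <- m[complete.cases(m), , drop = FALSE]
  stopIfNot(nrow(m) >= 2L, "need >= 2 complete-case proteins for PCA")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(sample_id = colnames(m),
                       sampleInfo(pe)[colnames(m),
                                      c("strain_id", "replicate_type")],
                       pc$x[, seq_len(k), drop = FALSE], row.names = NULL)
  list(scores = scores, varianceExplained = ve[seq_len(k)])
}
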