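#' Relative expression by the comparative Ct method
#'
#' Averages technical replicates on the Ct scale, then computes per strain
#' \eqn{\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{reference}}, the
#' calibrator-referenced \eqn{\Delta\Delta Ct}, and the relative level
#' \eqn{E^{-\Delta\Delta Ct}} (with amplification efficiency E, 2 by
#' default, giving the classic \eqn{2^{-\Delta\Delta Ct}}). The calibrator
#' strain's level is exactly 1 by construction, and levels are invariant to
#' any constant added to both genes' Ct values of a strain.
#'
#' @param ct `data.frame` with columns `strain_id`, `gene`,
#'   `technical_replicate`, `ct` (cycles, finite).
#' @param params A [QpcrParams].
#' @return `data.frame` with columns `strain_id`, `dct`, `ddct`,
#'   `rel_level`, with the calibrator first.
#' @examples
#' ct <- data.frame(
#'   strain_id = rep(c("BY4741", "s1"), each = 2),
#'   gene = rep(c("ttLCC1", "UBC6"), 2),
#'   technical_replicate = 1L,
#'   ct = c(22, 18, 20, 18))
#' relativeExpression(ct)  # s1 at level 4
#' @export
relativeExpression <- function(ct, params = QpcrParams()) {
  validObject(params)
  need <- c("strain_id", "gene", "technical_replicate", "ct")
  miss <- setdiff(need, names(ct))
  stopIfNot(length(miss) == 0L,
            "Ct table is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct))) stop("Ct values must be finite")
  cal <- params@calibratorStrain
  if (!cal %in% ct$strain_id)
    stop("calibrator strain '", cal, "' has no Ct rows")

  strains <- unique(ct$strain_id)
  meanCt <- function(s, g) {
    v <- ct$ct[ct$strain_id == s & ct$gene == g]
    if (length(v) == 0L)
      stop("strain '", s, "' has no Ct rows for gene '", g, "'")
    mean(v)
  }
  dct <- vapply(strains, function(s)
    meanCt(s, params@targetGene) - meanCt(s, params@referenceGene),
    numeric(1))
  ddct <- dct - dct[[cal]]
  out <- data.frame(strain_id = strains, dct = unname(dct),
                    ddct = unname(ddct),
                    rel_level = params@efficiency^(-unname(ddct)),
                    stringsAsFactors = FALSE)
  out[order(out$strain_id != cal), , drop = FALSE]
}

#' Enzyme activity per unit mRNA
#'
#' Ratio of enzyme activity to relative transcript level per strain,
#' rescaled so that the calibrator strain's ratio is 1. A strain with a
#' ratio above 1 produces more active enzyme per transcript than the
#' calibrator, pointing at post-transcriptional (folding, modification,
#' secretion) rather than transcriptional differences.
#'
#' @param activity Named numeric vector of activity Units per strain, or
#'   `data.frame` with `strain_id` and `activity_U`.
#' @param levels Output of [relativeExpression()], or a named numeric
#'   vector of relative levels.
#' @param calibrator Calibrator strain identifier.
#' @return `data.frame` with columns `strain_id`, `activity_U`,
#'   `rel_level`, `activity_per_mrna`.
#' @examples
#' act <- c(BY4741 = 2, s1 = 2)
#' lev <- c(BY4741 = 1, s1 = 0.5)
#' activityPerMrna(act, lev, "BY4741")  # s1 ratio 2
#' @export
activityPerMrna <- function(activity, levels, calibrator) {
  if (is.data.frame(activity))
    activity <- setNames(activity$activity_U, activity$strain_id)
  if (is.data.frame(levels))
    levels <- setNames(levels$rel_level, levels$strain_id)
  shared <- intersect(names(activity), names(levels))
  onlyA <- setdiff(names(activity), names(levels))
  onlyL <- setdiff(names(levels), names(activity))
  if (length(onlyA) || length(onlyL))
    stop("strain universes differ; only in activity: [",
         paste(onlyA, collapse = ", "), "], only in levels: [",
         paste(onlyL, collapse = ", "), "]")
  if (!calibrator %in% shared)
    stop("calibrator '", calibrator, "' absent from inputs")
  if (any(levels <= 0)) stop("relative levels must be positive")
  ratio <- activity[shared] / levels[shared]
  ratio <- ratio / ratio[[calibrator]]
  data.frame(strain_id = shared, activity_U = unname(activity[shared]),
             rel_level = unname(levels[shared]),
             activity_per_mrna = unname(ratio), stringsAsFactors = FALSE)
}
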