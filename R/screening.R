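#' Scaled median absolute deviation
#'
#' Robust spread estimator `constant * median(|x_i - median(x)|)`. The
#' default constant 1.4826 makes the MAD a consistent estimator of the
#' standard deviation for normal data. Medians of even-length vectors use
#' the midpoint convention.
#'
#' @param values Numeric vector with at least one finite value.
#' @param constant Consistency constant (default 1.4826).
#' @return The scaled MAD (numeric scalar).
#' @examples
#' madValue(c(1, 2, 3))  # 1.4826
#' madValue(rep(2, 4))   # 0
#' @export
madValue <- function(values, constant = 1.4826) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (any(!is.finite(values))) stop("values must be finite")
  stats::mad(values, constant = constant)
}

#' Call primary producer hits with a MAD threshold
#'
#' Flags strains whose activity strictly exceeds
#' `median + madK * MAD` computed over all screened strains (the reference
#' strain included, since the threshold is defined over the whole screen).
#' The threshold is translation- and positive-scale-equivariant, so the hit
#' set does not depend on the unit of activity.
#'
#' @param activities Named numeric vector of activity Units (one per
#'   strain), or a `data.frame` with columns `strain_id` and `activity_U`.
#' @param params A [ScreenParams] supplying `madK` and `madConstant`.
#' @return `data.frame` with columns `strain_id`, `activity_U`,
#'   `threshold_U`, `is_hit`, in the input strain order.
#' @examples
#' a <- c(s1 = 1, s2 = 1, s3 = 1, s4 = 5)
#' callPrimaryHits(a)
#' @export
callPrimaryHits <- function(activities, params = ScreenParams()) {
  validObject(params)
  if (is.data.frame(activities)) {
    stopIfNot(all(c("strain_id", "activity_U") %in% names(activities)),
              "activities data.frame needs columns strain_id, activity_U")
    x <- setNames(activities$activity_U, activities$strain_id)
  } else {
    x <- activities
    stopIfNot(!is.null(names(x)), "activities must be named by strain")
  }
  if (anyDuplicated(names(x)))
    stop("one activity per strain required; duplicated: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  bad <- names(x)[!is.finite(x)]
  if (length(bad))
    stop("non-finite activity for strain(s): ", paste(bad, collapse = ", "))
  thr <- median(x) + params@madK * madValue(x, params@madConstant)
  data.frame(strain_id = names(x), activity_U = unname(x),
             threshold_U = thr, is_hit = unname(x > thr),
             stringsAsFactors = FALSE)
}

#' Confirm hits against the reference strain with replicate tests
#'
#' For every strain with replicated activity measurements, performs a Welch
#' unequal-variance t-test against the reference strain's replicates
#' (one-sided "greater" by default, matching the question "does this strain
#' produce significantly more than the reference?"). Benjamini-Hochberg
#' adjusted values are computed across strains when `params@correct` is
#' "BH"; the `significant` flag additionally requires the strain mean to
#' exceed the reference mean.
#'
#' @param replicates `data.frame` with columns `strain_id`, `replicate_id`,
#'   `activity_U`; at least 2 replicates per tested strain and for the
#'   reference.
#' @param referenceId Reference strain identifier.
#' @param params A [ScreenParams].
#' @param enzyme Optional enzyme label carried into the output
#'   (default `NA`).
#' @return `data.frame` with columns `strain_id`, `enzyme`, `mean_U`, `n`,
#'   `p`, `q`, `significant` (reference strain excluded from the rows).
#' @examples
#' reps <- data.frame(
#'   strain_id = rep(c("ref", "s1"), each = 4),
#'   replicate_id = rep(1:4, 2),
#'   activity_U = c(1, 1.1, 0.9, 1, 4, 4.2, 3.9, 4.1))
#' secondaryScreen(reps, "ref")
#' @export
secondaryScreen <- function(replicates, referenceId,
                            params = ScreenParams(), enzyme = NA_character_) {
  validObject(params)
  stopIfNot(all(c("strain_id", "replicate_id", "activity_U") %in%
                  names(replicates)),
            "replicates needs columns strain_id, replicate_id, activity_U")
  if (!referenceId %in% replicates$strain_id)
    stop("reference strain '", referenceId, "' has no replicates")
  ref <- replicates$activity_U[replicates$strain_id == referenceId]
  if (length(ref) < 2L)
    stop("reference strain needs >= 2 replicates")
  strains <- setdiff(unique(replicates$strain_id), referenceId)
  rows <- lapply(strains, function(s) {
    x <- replicates$activity_U[replicates$strain_id == s]
    if (length(x) < 2L)
      stop("strain '", s, "' needs >= 2 replicates")
    p <- if (sd(x) == 0 && sd(ref) == 0) {
      # degenerate zero-variance groups: separated groups are certain,
      # identical groups are null
      if (mean(x) == mean(ref)) 1
      else if (params@alternative == "two.sided" || mean(x) > mean(ref)) 0
      else 1
    } else t.test(x, ref, alternative = params@alternative,
                  var.equal = FALSE)$p.value
    data.frame(strain_id = s, enzyme = enzyme, mean_U = mean(x),
               n = length(x), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- if (params@correct == "BH") p.adjust(out$p, "BH") else NA_real_
  crit <- if (params@correct == "BH") out$q else out$p
  out$significant <- out$mean_U > mean(ref) & crit < params@alpha
  out
}

#' Combine two secondary screens of different enzymes
#'
#' Cross-tabulates confirmed hits from two enzyme screens over the same
#' strain universe and reports the Pearson correlation of the mean
#' activities across all assessed strains (with the exact p-value of the
#' standard t transform, via [stats::cor.test]).
#'
#' @param resA,resB Outputs of [secondaryScreen()] for the two enzymes,
#'   covering the same strains.
#' @return A list with `table` (`data.frame`: `strain_id`, `mean_U_a`,
#'   `mean_U_b`, `significant_a`, `significant_b`, `category` in
#'   \{a_only, b_only, both, neither\}), `counts` (named vector including
#'   `union`), `pearson_r` and `pearson_p`.
#' @examples
#' reps <- data.frame(
#'   strain_id = rep(c("ref", "s1", "s2"), each = 3),
#'   replicate_id = rep(1:3, 3),
#'   activity_U = c(1, 1.1, 0.9, 4, 4.1, 3.9, 1, 0.95, 1.05))
#' a <- secondaryScreen(reps, "ref", enzyme = "ttLcc1")
#' b <- secondaryScreen(reps, "ref", enzyme = "mtLcc1")
#' combineDualScreen(a, b)$counts
#' @export
combineDualScreen <- function(resA, resB) {
  sa <- sort(resA$strain_id); sb <- sort(resB$strain_id)
  if (!identical(sa, sb)) {
    d <- union(setdiff(sa, sb), setdiff(sb, sa))
    stop("strain sets differ between screens: ", paste(d, collapse = ", "))
  }
  resB <- resB[match(resA$strain_id, resB$strain_id), ]
  cat_ <- ifelse(resA$significant & resB$significant, "both",
          ifelse(resA$significant, "a_only",
          ifelse(resB$significant, "b_only", "neither")))
  tab <- data.frame(
    strain_id = resA$strain_id, mean_U_a = resA$mean_U,
    mean_U_b = resB$mean_U, significant_a = resA$significant,
    significant_b = resB$significant, category = cat_,
    stringsAsFactors = FALSE)
  ct <- cor.test(tab$mean_U_a, tab$mean_U_b, method = "pearson")
  counts <- c(a_only = sum(cat_ == "a_only"), b_only = sum(cat_ == "b_only"),
              both = sum(cat_ == "both"), neither = sum(cat_ == "neither"),
              union = sum(cat_ != "neither"))
  list(table = tab, counts = counts,
       pearson_r = unname(ct$estimate), pearson_p = ct$p.value)
}
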