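#' Retain ORFs whose presence varies between hits and the reference
#'
#' Pre-filter for the enrichment analysis: only ORFs whose presence state in
#' at least one hit strain differs from the reference strain's state are
#' informative. ORFs shared (or jointly absent) by the reference and every
#' hit are dropped.
#'
#' @param opm An [ORFPresenceMatrix].
#' @param hitSet Character vector of hit strain identifiers (non-empty,
#'   subset of the matrix strains).
#' @return Character vector of retained ORF identifiers, in matrix column
#'   order.
#' @examples
#' m <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 3,
#'             dimnames = list(c("ref", "h1", "r1"), c("orfA", "orfB")))
#' opm <- ORFPresenceMatrix(m, "ref")
#' retainVariableOrfs(opm, "h1")
#' @export
retainVariableOrfs <- function(opm, hitSet) {
  validObject(opm)
  if (length(hitSet) == 0L) stop("hitSet must be non-empty")
  unknown <- setdiff(hitSet, strainNames(opm))
  if (length(unknown))
    stop("hit strains not in matrix: ", paste(unknown, collapse = ", "))
  p <- presenceMatrix(opm)
  refState <- p[referenceStrain(opm), ]
  hitBlock <- p[hitSet, , drop = FALSE]
  differs <- colSums(hitBlock != matrix(refState, nrow = length(hitSet),
                                        ncol = ncol(p), byrow = TRUE)) > 0
  colnames(p)[differs]
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test] on the table
#' `matrix(c(a, b, c, d), 2)`; used by [fisherEnrichment()] for every ORF.
#'
#' @param a,b,c,d Non-negative integer cell counts (column-wise:
#'   `a` = present in hits, `b` = absent in hits, `c` = present in rest,
#'   `d` = absent in rest).
#' @return The two-sided exact p-value.
#' @examples
#' fisherExactP(3, 0, 0, 3)  # 0.1
#' @export
fisherExactP <- function(a, b, c, d) {
  fisher.test(matrix(c(a, b, c, d), nrow = 2), conf.int = FALSE)$p.value
}

#' Exact-test enrichment of ORF presence among hit strains
#'
#' For each ORF, builds the 2x2 table of presence/absence in the hit strains
#' versus the remainder of the library and computes the two-sided Fisher
#' exact p-value. An ORF is classed `enriched` when its presence proportion
#' is higher among hits than in the rest and p < alpha, `depleted` when
#' lower and p < alpha, otherwise `ns`. Odds ratios are the
#' Haldane-Anscombe-corrected sample odds ratios
#' `((a+0.5)(d+0.5)) / ((b+0.5)(c+0.5))`.
#'
#' @param opm An [ORFPresenceMatrix].
#' @param hitSet Character vector of hit strains (proper non-empty subset of
#'   the matrix strains).
#' @param orfs ORFs to test; defaults to [retainVariableOrfs()] output.
#' @param alpha Significance level (default 0.05).
#' @param correct "none" (default, raw p classification) or "BH"
#'   (classification on adjusted values; q-values are reported either way
#'   when "BH").
#' @return `data.frame` with columns `orf_id`, `present_in_hits`,
#'   `absent_in_hits`, `present_in_rest`, `absent_in_rest`, `odds_ratio`,
#'   `p_value`, `q_value`, `class`.
#' @examples
#' sim <- simulatePangenome(nStrains = 60, nOrfs = 40,
#'                          hitSet = paste0("strain", 1:10), seed = 1)
#' head(fisherEnrichment(sim$presence, paste0("strain", 1:10)))
#' @export
fisherEnrichment <- function(opm, hitSet, orfs = NULL, alpha = 0.05,
                             correct = c("none", "BH")) {
  validObject(opm)
  correct <- match.arg(correct)
  assertNumber(alpha, "alpha", min = 0, strict = TRUE)
  stopIfNot(alpha < 1, "alpha must lie in (0, 1)")
  strains <- strainNames(opm)
  unknown <- setdiff(hitSet, strains)
  if (length(unknown))
    stop("hit strains not in matrix: ", paste(unknown, collapse = ", "))
  if (length(hitSet) == 0L) stop("hitSet must be non-empty")
  if (setequal(hitSet, strains))
    stop("hitSet equals the full strain set; no remainder to compare against")
  if (is.null(orfs)) orfs <- retainVariableOrfs(opm, hitSet)
  unknownOrf <- setdiff(orfs, orfNames(opm))
  if (length(unknownOrf))
    stop("ORFs not in matrix: ", paste(unknownOrf, collapse = ", "))

  p <- presenceMatrix(opm)
  rest <- setdiff(strains, hitSet)
  nHit <- length(hitSet); nRest <- length(rest)
  a <- colSums(p[hitSet, orfs, drop = FALSE])        # present in hits
  c_ <- colSums(p[rest, orfs, drop = FALSE])         # present in rest
  b <- nHit - a; d <- nRest - c_
  pv <- mapply(fisherExactP, a, b, c_, d)
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  qv <- if (correct == "BH") p.adjust(pv, "BH") else rep(NA_real_, length(pv))
  crit <- if (correct == "BH") qv else pv
  propHit <- a / nHit; propRest <- c_ / nRest
  cls <- ifelse(crit < alpha & propHit > propRest, "enriched",
         ifelse(crit < alpha & propHit < propRest, "depleted", "ns"))
  data.frame(orf_id = orfs, present_in_hits = unname(a),
             absent_in_hits = unname(b), present_in_rest = unname(c_),
             absent_in_rest = unname(d), odds_ratio = unname(or),
             p_value = unname(pv), q_value = unname(qv), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Relabel depleted ORFs with an enriched homolog as compensated
#'
#' A depleted ORF whose close homolog (amino-acid identity at least
#' `minIdentity`) is itself enriched among the hit strains is relabeled
#' `compensated`: the enriched gene plausibly substitutes for the missing
#' one. When several enriched homologs link to one depleted ORF, the
#' highest-identity link is recorded. Homology pairs are treated as
#' symmetric.
#'
#' @param records Output of [fisherEnrichment()].
#' @param homology `data.frame` with columns `orf_id`, `homolog_id`,
#'   `identity` (fraction in 0..1). May be empty.
#' @param minIdentity Minimum identity for a link to count (default 0.73).
#' @return A list with `records` (input with updated `class` and new
#'   columns `compensating_orf`, `compensating_identity`) and `summary`
#'   (named vector `n_enriched`, `n_compensated`, `n_depleted_remaining`).
#' @examples
#' rec <- data.frame(orf_id = c("GAL1", "GAL1-like"),
#'                   present_in_hits = c(0, 10), absent_in_hits = c(10, 0),
#'                   present_in_rest = c(40, 5), absent_in_rest = c(10, 45),
#'                   odds_ratio = c(0.01, 100), p_value = c(1e-6, 1e-6),
#'                   q_value = NA_real_, class = c("depleted", "enriched"))
#' hom <- data.frame(orf_id = "GAL1", homolog_id = "GAL1-like",
#'                   identity = 0.9)
#' classifyCompensation(rec, hom)$summary
#' @export
classifyCompensation <- function(records, homology, minIdentity = 0.73) {
  stopIfNot(all(c("orf_id", "class") %in% names(records)),
            "records must come from fisherEnrichment()")
  records$compensating_orf <- NA_character_
  records$compensating_identity <- NA_real_
  if (nrow(homology) > 0) {
    stopIfNot(all(c("orf_id", "homolog_id", "identity") %in% names(homology)),
              "homology needs columns orf_id, homolog_id, identity")
    if (any(homology$identity < 0 | homology$identity > 1))
      stop("homology identities must lie in [0, 1]")
    if (any(homology$orf_id == homology$homolog_id))
      stop("homology pairs must link two distinct ORFs")
    known <- records$orf_id
    bad <- setdiff(c(homology$orf_id, homology$homolog_id), known)
    if (length(bad))
      stop("homology pairs reference unknown ORFs: ",
           paste(unique(bad), collapse = ", "))
    # symmetric closure, then keep links from a depleted ORF to an enriched one
    pairs <- rbind(
      homology[, c("orf_id", "homolog_id", "identity")],
      setNames(homology[, c("homolog_id", "orf_id", "identity")],
               c("orf_id", "homolog_id", "identity")))
    pairs <- pairs[pairs$identity >= minIdentity, , drop = FALSE]
    cls <- setNames(records$class, records$orf_id)
    pairs <- pairs[cls[pairs$orf_id] == "depleted" &
                     cls[pairs$homolog_id] == "enriched", , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- pairs[order(pairs$orf_id, -pairs$identity), ]
      pairs <- pairs[!duplicated(pairs$orf_id), ]
      i <- match(pairs$orf_id, records$orf_id)
      records$class[i] <- "compensated"
      records$compensating_orf[i] <- pairs$homolog_id
      records$compensating_identity[i] <- pairs$identity
    }
  }
  summary <- c(n_enriched = sum(records$class == "enriched"),
               n_compensated = sum(records$class == "compensated"),
               n_depleted_remaining = sum(records$class == "depleted"))
  list(records = records, summary = summary)
}
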