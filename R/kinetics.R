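#' Find the longest linear window of a kinetic trace
#'
#' Microplate enzyme progress curves are linear only in an interior range:
#' early readings can show a lag and late readings saturate as substrate is
#' consumed. Following the usual practice of removing points from both ends
#' of the curve until the fit reaches an acceptance R^2, this function
#' performs a deterministic exhaustive search over all contiguous windows
#' and returns the longest window (ties broken by earliest start) of at
#' least `minPoints` readings whose least-squares fit has
#' R^2 >= `r2Min`.
#'
#' R^2 is defined as 1 - SSres/SStot. A window with zero response variance
#' (SStot = 0) is assigned R^2 = 1, slope 0 and the `flat` flag: a well with
#' no signal change is a valid zero-activity measurement, not a fit failure.
#' If no window qualifies, the best-R^2 window of length `minPoints`
#' (earliest on ties) is reported with flag `no_linear_window`.
#'
#' @param times Numeric vector of reading times in minutes, strictly
#'   increasing.
#' @param absorbance Numeric vector of absorbance readings (AU), same
#'   length as `times`.
#' @param params A [KineticsParams] object supplying `r2Min` and
#'   `minPoints`.
#' @return A [LinearFit] object.
#' @examples
#' trimToLinear(0:60, 0.01 * (0:60), KineticsParams(pathLength = 1))
#' @seealso [activityFromFit()], [quantifyPlate()]
#' @export
trimToLinear <- function(times, absorbance, params = KineticsParams()) {
  validObject(params)
  n <- length(times)
  if (length(absorbance) != n)
    stop("times and absorbance must have equal length")
  if (n < 2L) stop("a kinetic trace needs at least 2 points")
  if (any(!is.finite(times)) || any(!is.finite(absorbance)))
    stop("times and absorbance must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  minPts <- params@minPoints
  if (minPts > n)
    stop(sprintf("trace has %d points but minPoints is %d", n, minPts))

  # Prefix sums on centred data keep the O(n^2) sweep cheap; each accepted
  # candidate is re-verified with a direct stable fit before being returned.
  xc <- times - mean(times)
  yc <- absorbance - mean(absorbance)
  cx <- c(0, cumsum(xc));  cy <- c(0, cumsum(yc))
  cxx <- c(0, cumsum(xc * xc)); cyy <- c(0, cumsum(yc * yc))
  cxy <- c(0, cumsum(xc * yc))

  windowStats <- function(starts, L) {
    ends <- starts + L - 1L
    sx <- cx[ends + 1L] - cx[starts];   sy <- cy[ends + 1L] - cy[starts]
    sxx <- cxx[ends + 1L] - cxx[starts]; syy <- cyy[ends + 1L] - cyy[starts]
    sxy <- cxy[ends + 1L] - cxy[starts]
    vxx <- sxx - sx * sx / L
    vyy <- syy - sy * sy / L
    vxy <- sxy - sx * sy / L
    # zero response variance up to rounding noise from the prefix sums
    flat <- vyy <= 1e-9 * (syy / L + .Machine$double.xmin)
    r2 <- ifelse(flat, 1, (vxy * vxy) / (vxx * pmax(vyy, .Machine$double.xmin)))
    list(r2 = r2, flat = flat)
  }

  finalize <- function(start, L, qcIfOk) {
    idx <- start:(start + L - 1L)
    f <- olsFit(times[idx], absorbance[idx])
    qc <- if (qcIfOk != "ok") qcIfOk else if (f$flat) "flat" else "ok"
    LinearFit(startIndex = start, endIndex = start + L - 1L,
              slope = f$slope, intercept = f$intercept, rSquared = f$r2,
              qcFlag = qc)
  }

  for (L in seq(n, minPts)) {
    starts <- seq_len(n - L + 1L)
    st <- windowStats(starts, L)
    cand <- starts[st$flat | st$r2 >= params@r2Min - 1e-9]
    for (s in cand) {
      idx <- s:(s + L - 1L)
      f <- olsFit(times[idx], absorbance[idx])
      if (f$flat || f$r2 >= params@r2Min)
        return(finalize(s, L, "ok"))
    }
  }

  # no qualifying window: report the best minPoints-length window
  starts <- seq_len(n - minPts + 1L)
  r2s <- vapply(starts, function(s) {
    f <- olsFit(times[s:(s + minPts - 1L)], absorbance[s:(s + minPts - 1L)])
    if (f$flat) 1 else f$r2
  }, numeric(1))
  finalize(starts[which.max(r2s)], minPts, "no_linear_window")
}

#' Convert a linear-window slope to enzyme activity Units
#'
#' Applies the Beer-Lambert law to the fitted absorbance slope to obtain the
#' rate of product formation, in enzyme Units (1 U = 1 umol substrate
#' oxidized per minute):
#'
#' \deqn{U = \frac{\mathrm{slope}}{\varepsilon \, l} \times V_{rxn}(L)
#'   \times 10^6 \times \mathrm{dilution}}
#'
#' With the defaults (epsilon = 36000 M^-1 cm^-1, 200 uL reaction) and a
#' 1 cm path, a slope of 0.036 AU/min corresponds to 2.0e-4 U. Negative
#' slopes are clamped to 0 (activity is physically non-negative; such wells
#' are non-producers) and flagged via the `"clamped"` attribute.
#'
#' @param fit A [LinearFit] with `qcFlag` "ok" or "flat".
#' @param params A [KineticsParams]; `pathLength` (cm) must be set.
#' @return Activity in Units (numeric scalar); attribute `clamped` is TRUE
#'   when a negative slope was clamped.
#' @examples
#' fit <- LinearFit(startIndex = 1L, endIndex = 10L, slope = 0.036,
#'                  intercept = 0, rSquared = 1, qcFlag = "ok")
#' activityFromFit(fit, KineticsParams(pathLength = 1))  # 2e-4
#' @export
activityFromFit <- function(fit, params) {
  validObject(params)
  if (is.na(params@pathLength))
    stop("pathLength is not set; supply KineticsParams(pathLength = ...)")
  if (!fit@qcFlag %in% c("ok", "flat"))
    stop("activity is undefined for qcFlag '", fit@qcFlag, "'")
  slope <- fit@slope
  clamped <- slope < 0
  slope <- max(slope, 0)
  act <- slope / (params@epsilon * params@pathLength) *
    (params@reactionVolume * 1e-6) * 1e6 * params@dilutionFactor
  attr(act, "clamped") <- clamped
  act
}

#' Quantify every well of a plate read
#'
#' Runs [trimToLinear()] and [activityFromFit()] on each non-blank well of a
#' plate-reader kinetic table, joining the plate layout to produce one
#' activity record per well. When the layout contains blank wells and
#' `params@blankSubtract` is TRUE, the mean blank slope is subtracted from
#' every sample/reference slope before conversion to Units.
#'
#' @param kinetics `data.frame` with a `time_min` column and one absorbance
#'   column per well (as read by [readKineticTable()]).
#' @param layout `data.frame` with columns `well`, `strain_id`,
#'   `replicate_id`, `role` (one of "sample", "reference", "blank") and
#'   optionally `od600`.
#' @param params A [KineticsParams].
#' @return `data.frame` with columns `strain_id`, `replicate_id`, `well`,
#'   `slope`, `r2`, `window_start`, `window_end`, `qc`, `activity_U`,
#'   `od600`. `activity_U` is `NA` for wells flagged `no_linear_window`.
#' @examples
#' sim <- simulateScreen(nStrains = 4, nHits = 0, seed = 1)
#' res <- quantifyPlate(sim$kinetics, sim$layout,
#'                      KineticsParams(pathLength = 1))
#' head(res)
#' @export
quantifyPlate <- function(kinetics, layout, params) {
  validObject(params)
  stopIfNot(is.data.frame(kinetics) && "time_min" %in% names(kinetics),
            "kinetics must be a data.frame with a 'time_min' column")
  need <- c("well", "strain_id", "replicate_id", "role")
  miss <- setdiff(need, names(layout))
  stopIfNot(length(miss) == 0L,
            "layout is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(layout$well))
    stop("duplicate wells in layout: ",
         paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "))
  bad <- setdiff(layout$role, c("sample", "reference", "blank"))
  stopIfNot(length(bad) == 0L,
            "unknown layout roles: ", paste(bad, collapse = ", "))
  absent <- setdiff(layout$well, names(kinetics))
  if (length(absent))
    stop("layout wells missing from kinetic table: ",
         paste(absent, collapse = ", "))

  fits <- lapply(layout$well, function(w)
    trimToLinear(kinetics$time_min, kinetics[[w]], params))
  slopes <- vapply(fits, slot, numeric(1), "slope")

  blankSlope <- 0
  isBlank <- layout$role == "blank"
  if (params@blankSubtract && any(isBlank))
    blankSlope <- mean(slopes[isBlank])

  keep <- which(!isBlank)
  rows <- lapply(keep, function(i) {
    f <- fits[[i]]
    act <- NA_real_
    if (f@qcFlag != "no_linear_window") {
      fAdj <- f
      fAdj@slope <- f@slope - blankSlope
      act <- as.numeric(activityFromFit(fAdj, params))
    }
    data.frame(
      strain_id = layout$strain_id[i], replicate_id = layout$replicate_id[i],
      well = layout$well[i], slope = f@slope, r2 = f@rSquared,
      window_start = f@startIndex, window_end = f@endIndex, qc = f@qcFlag,
      activity_U = act,
      od600 = if ("od600" %in% names(layout)) layout$od600[i] else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
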