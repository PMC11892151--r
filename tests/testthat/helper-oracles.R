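# Independent oracles used to cross-check the implementation. Each is coded
# from the definition, deliberately not sharing code with the package.

# Scaled MAD straight from the formula.
oracleMad <- function(x, constant = 1.4826) {
  constant * median(abs(x - median(x)))
}

# Two-sided Fisher exact p by full hypergeometric enumeration: the sum of
# the probabilities of all tables (same margins) no more likely than the
# observed one. The 1e-7 relative tolerance is the standard guard for
# floating-point ties among outcome probabilities.
oracleFisherP <- function(a, b, c, d) {
  m <- a + b          # row 1 total (hits)
  n <- c + d          # row 2 total (rest)
  k <- a + c          # first column total (present)
  support <- max(0L, k - n):min(m, k)
  probs <- dhyper(support, k, m + n - k, m)
  pObs <- probs[match(a, support)]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exhaustive longest-linear-window search, coded as a plain double loop
# with running sums (no shared code with trimToLinear). Returns the chosen
# window, its qc flag and slope.
oracleLinearWindow <- function(times, y, r2Min = 0.999, minPoints = 10L) {
  n <- length(times)
  best <- NULL          # longest qualifying, earliest start
  bestFallback <- NULL  # best-r2 window of length minPoints
  for (s in 1:(n - minPoints + 1L)) {
    sx <- sy <- sxx <- syy <- sxy <- 0
    lo <- Inf; hi <- -Inf
    for (e in s:n) {
      x1 <- times[e]; y1 <- y[e]
      sx <- sx + x1; sy <- sy + y1
      sxx <- sxx + x1 * x1; syy <- syy + y1 * y1; sxy <- sxy + x1 * y1
      lo <- min(lo, y1); hi <- max(hi, y1)
      L <- e - s + 1L
      if (L < minPoints) next
      vxx <- sxx - sx * sx / L
      vyy <- syy - sy * sy / L
      vxy <- sxy - sx * sy / L
      flat <- (lo == hi)
      r2 <- if (flat) 1 else (vxy * vxy) / (vxx * vyy)
      slope <- if (flat) 0 else vxy / vxx
      if (is.null(bestFallback) && L == minPoints ||
          (!is.null(bestFallback) && L == minPoints &&
             r2 > bestFallback$r2))
        bestFallback <- list(start = s, end = e, r2 = r2, slope = slope,
                             flat = flat)
      if (flat || r2 >= r2Min) {
        if (is.null(best) || L > best$len ||
            (L == best$len && s < best$start))
          best <- list(start = s, end = e, len = L, slope = slope,
                       flat = flat, r2 = r2)
      }
    }
  }
  if (!is.null(best))
    list(start = best$start, end = best$end,
         qc = if (best$flat) "flat" else "ok", slope = best$slope)
  else
    list(start = bestFallback$start, end = bestFallback$end,
         qc = "no_linear_window", slope = bestFallback$slope)
}

# Pearson r from the raw textbook sums formula.
oraclePearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Hit threshold recomputed spreadsheet-style (sort-based median, manual
# abs-deviation median).
oracleHitSet <- function(activities, k = 3, constant = 1.4826) {
  v <- sort(unname(activities))
  n <- length(v)
  med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  dev <- sort(abs(unname(activities) - med))
  madv <- if (n %% 2 == 1) dev[(n + 1) / 2] else
    (dev[n / 2] + dev[n / 2 + 1]) / 2
  thr <- med + k * constant * madv
  names(activities)[activities > thr]
}

# Tiny deterministic KineticsParams used across kinetics tests.
kp <- function(...) KineticsParams(pathLength = 1, ...)
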