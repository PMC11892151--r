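# Internal helpers shared across modules.

# Deterministic fan-out of one global seed into named per-module substreams,
# so any generator can be re-run independently of the others. Kept within
# 32-bit integer range.
streamSeed <- function(seed, stream) {
  streams <- c(screen = 1L, pangenome = 2L, distances = 3L, proteomes = 4L,
               qpcr = 5L, impute = 6L, pilot = 7L)
  if (!stream %in% names(streams))
    stop("unknown random stream: ", stream)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer")
  as.integer((as.numeric(seed) * 7919 + streams[[stream]] * 104729) %%
               2147483647)
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

assertNumber <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- length(x) == 1L && is.finite(x) && (if (strict) x > min else x >= min)
  if (!ok)
    stop(sprintf("%s must be a single finite number %s %g", name,
                 if (strict) ">" else ">=", min), call. = FALSE)
  as.numeric(x)
}

# Ordinary least squares of y on x via closed-form sums; returns slope,
# intercept and R^2 with the flat (zero response variance) convention.
olsFit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (max(y) == min(y))
    return(list(slope = 0, intercept = my, r2 = 1, flat = TRUE))
  slope <- sxy / sxx
  r2 <- (sxy * sxy) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2, flat = FALSE)
}
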