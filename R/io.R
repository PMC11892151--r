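## Plain-text readers and writers for every pipeline format. Writers can
## prepend a '#'-prefixed header comment (version, config hash, seed);
## readers skip such comments and validate the format, naming the file and
## the rule violated in error messages.

headerComment <- function(meta = NULL) {
  if (is.null(meta)) return(character())
  sprintf("# PanScreen %s | config=%s | seed=%s | %s",
          as.character(packageVersion("PanScreen")),
          meta$configHash %||% "NA", meta$seed %||% "NA",
          meta$stage %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeDelimited <- function(df, path, sep, meta = NULL, na = "NA") {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- headerComment(meta)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = na)
  invisible(path)
}

readDelimited <- function(path, sep, na = "NA", colClasses = NA) {
  stopIfNot(file.exists(path), "no such file: ", path)
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    na.strings = na, check.names = FALSE,
                    colClasses = colClasses, stringsAsFactors = FALSE)
}

requireColumns <- function(df, path, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read a plate-reader kinetic table
#'
#' CSV with first column `time_min` and one absorbance column (AU) per
#' well. Times must be strictly increasing and all values finite.
#'
#' @param path CSV file path.
#' @return `data.frame` with `time_min` and one column per well.
#' @export
readKineticTable <- function(path) {
  df <- readDelimited(path, ",")
  requireColumns(df, path, "time_min")
  if (ncol(df) < 2L)
    stop(path, ": kinetic table has no well columns")
  if (anyDuplicated(names(df)))
    stop(path, ": duplicated well column names")
  if (any(!is.finite(as.matrix(df))))
    stop(path, ": kinetic table contains non-finite values")
  if (any(diff(df$time_min) <= 0))
    stop(path, ": time_min must be strictly increasing")
  df
}

#' @rdname readKineticTable
#' @param kinetics Kinetic `data.frame` to write.
#' @param meta Optional header metadata list (`configHash`, `seed`,
#'   `stage`).
#' @export
writeKineticTable <- function(kinetics, path, meta = NULL)
  writeDelimited(kinetics, path, ",", meta)

#' Read a plate layout
#'
#' CSV with columns `well`, `strain_id`, `replicate_id`, `role`
#' (sample/reference/blank) and optional `od600` and `plate`.
#'
#' @param path CSV file path.
#' @return Layout `data.frame`.
#' @export
readPlateLayout <- function(path) {
  df <- readDelimited(path, ",", colClasses = "character")
  requireColumns(df, path, c("well", "strain_id", "replicate_id", "role"))
  if (anyDuplicated(df$well))
    stop(path, ": duplicated wells: ",
         paste(unique(df$well[duplicated(df$well)]), collapse = ", "))
  bad <- setdiff(unique(df$role), c("sample", "reference", "blank"))
  if (length(bad))
    stop(path, ": unknown roles: ", paste(bad, collapse = ", "))
  if ("od600" %in% names(df)) df$od600 <- as.numeric(df$od600)
  df
}

#' @rdname readPlateLayout
#' @param layout Layout `data.frame` to write.
#' @param meta Optional header metadata list.
#' @export
writePlateLayout <- function(layout, path, meta = NULL)
  writeDelimited(layout, path, ",", meta)

#' Read or write a per-well activity table
#'
#' TSV with columns `strain_id`, `replicate_id`, `well`, `slope`, `r2`,
#' `window_start`, `window_end`, `qc`, `activity_U`, `od600` (the output of
#' [quantifyPlate()]).
#'
#' @param path TSV file path.
#' @return Activity `data.frame`.
#' @export
readActivityTable <- function(path) {
  df <- readDelimited(path, "\t")
  requireColumns(df, path, c("strain_id", "activity_U"))
  df
}

#' @rdname readActivityTable
#' @param activity Activity `data.frame` to write.
#' @param meta Optional header metadata list.
#' @export
writeActivityTable <- function(activity, path, meta = NULL)
  writeDelimited(activity, path, "\t", meta)

#' Read a strain-by-ORF presence/absence matrix
#'
#' TSV with first column `strain_id` and one 0/1 column per ORF.
#'
#' @param path TSV file path.
#' @param referenceStrain Reference strain identifier (must be a row).
#' @return An [ORFPresenceMatrix].
#' @export
readPresenceMatrix <- function(path, referenceStrain) {
  df <- readDelimited(path, "\t")
  requireColumns(df, path, "strain_id")
  m <- as.matrix(df[, setdiff(names(df), "strain_id"), drop = FALSE])
  if (!all(m %in% c(0, 1)))
    stop(path, ": presence cells must be 0 or 1")
  rownames(m) <- df$strain_id
  if (anyDuplicated(df$strain_id))
    stop(path, ": duplicated strain ids")
  ORFPresenceMatrix(m, referenceStrain)
}

#' @rdname readPresenceMatrix
#' @param opm [ORFPresenceMatrix] to write.
#' @param meta Optional header metadata list.
#' @export
writePresenceMatrix <- function(opm, path, meta = NULL) {
  p <- presenceMatrix(opm)
  df <- data.frame(strain_id = rownames(p), p * 1L, check.names = FALSE)
  writeDelimited(df, path, "\t", meta)
}

#' Read or write an ORF homology map
#'
#' TSV with columns `orf_id`, `homolog_id`, `identity` (fraction in 0..1).
#'
#' @param path TSV file path.
#' @return Homology `data.frame`.
#' @export
readHomologyMap <- function(path) {
  df <- readDelimited(path, "\t")
  requireColumns(df, path, c("orf_id", "homolog_id", "identity"))
  if (any(!is.finite(df$identity)) ||
      any(df$identity < 0 | df$identity > 1))
    stop(path, ": identity must be a fraction in [0, 1]")
  df
}

#' @rdname readHomologyMap
#' @param homology Homology `data.frame` to write.
#' @param meta Optional header metadata list.
#' @export
writeHomologyMap <- function(homology, path, meta = NULL)
  writeDelimited(homology, path, "\t", meta)

#' Read or write a strain distance matrix
#'
#' Tab-separated square matrix with taxon identifiers as header row and
#' first column (the layout of published SNP distance tables).
#'
#' @param path TSV file path.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
readDistanceMatrix <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          comment.char = "#", check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(path, ": distance matrix must be square")
  if (!identical(rownames(m), colnames(m)))
    stop(path, ": row and column taxon labels must match")
  if (any(!is.finite(m)) || any(m < 0))
    stop(path, ": distances must be finite and non-negative")
  m
}

#' @rdname readDistanceMatrix
#' @param d Distance matrix to write.
#' @param meta Optional header metadata list.
#' @export
writeDistanceMatrix <- function(d, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- headerComment(meta)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(data.frame(taxon = rownames(d), d, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a qPCR Ct table
#'
#' CSV with columns `strain_id`, `gene`, `technical_replicate`, `ct`.
#'
#' @param path CSV file path.
#' @return Ct `data.frame`.
#' @export
readCtTable <- function(path) {
  df <- readDelimited(path, ",")
  requireColumns(df, path,
                 c("strain_id", "gene", "technical_replicate", "ct"))
  if (any(!is.finite(df$ct)))
    stop(path, ": Ct values must be finite")
  df
}

#' @rdname readCtTable
#' @param ct Ct `data.frame` to write.
#' @param meta Optional header metadata list.
#' @export
writeCtTable <- function(ct, path, meta = NULL)
  writeDelimited(ct, path, ",", meta)

#' Read or write a proteome intensity matrix with sample metadata
#'
#' Intensity TSV: first column `protein_id`, one column per sample, blank
#' cells for missing values. Metadata TSV: columns `sample_id`,
#' `strain_id`, `replicate_id`, `replicate_type`.
#'
#' @param path Intensity TSV path.
#' @param metadataPath Sample metadata TSV path.
#' @return A [ProteomeExperiment].
#' @export
readIntensityMatrix <- function(path, metadataPath) {
  df <- readDelimited(path, "\t", na = "")
  requireColumns(df, path, "protein_id")
  m <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  rownames(m) <- df$protein_id
  info <- readDelimited(metadataPath, "\t")
  requireColumns(info, metadataPath,
                 c("sample_id", "strain_id", "replicate_id",
                   "replicate_type"))
  miss <- setdiff(colnames(m), info$sample_id)
  if (length(miss))
    stop(metadataPath, ": no metadata for sample(s): ",
         paste(miss, collapse = ", "))
  rownames(info) <- info$sample_id
  ProteomeExperiment(m, info[colnames(m), , drop = FALSE])
}

#' @rdname readIntensityMatrix
#' @param pe [ProteomeExperiment] to write.
#' @param meta Optional header metadata list.
#' @export
writeIntensityMatrix <- function(pe, path, metadataPath, meta = NULL) {
  m <- intensities(pe)
  writeDelimited(data.frame(protein_id = rownames(m), m,
                            check.names = FALSE),
                 path, "\t", meta, na = "")
  info <- sampleInfo(pe)
  if (!"sample_id" %in% names(info))
    info <- data.frame(sample_id = rownames(info), info,
                       stringsAsFactors = FALSE)
  writeDelimited(info, metadataPath, "\t", meta)
  invisible(path)
}
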