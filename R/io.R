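# Readers/writers for the tab-separated exchange formats: ion library,
# run design, fragment/MRM intensity tables, expression tables, quant tables.
# Dialect: TSV, UTF-8, header row, "." decimal point, empty string = missing.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  invisible(df)
}

.check_numeric <- function(raw, col, what) {
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(x))
  if (length(bad) > 0)
    stop(sprintf("%s: malformed numeric value in column '%s' at row %d",
                 what, col, bad[1]))
  x
}

#' Read (and filter) an ion library
#'
#' Reads a tab-separated transition list and applies the identification-level
#' filters used to build a quantifiable library: minimum peptide confidence,
#' exclusion of peptides shared between proteins, exclusion of modified
#' peptides. The three filters commute, so the retained set does not depend
#' on their order.
#'
#' @param path TSV with columns \code{protein_id}, \code{peptide},
#'   \code{charge}, \code{fragment_id}, \code{precursor_mz},
#'   \code{fragment_mz}, \code{shared}, \code{modified}, \code{confidence}.
#' @param minConfidence minimum peptide confidence (percent) to retain;
#'   default 99, compared with \code{>=} (\code{strict = TRUE} uses \code{>}).
#' @param excludeShared,excludeModified drop shared / modified peptides
#'   (default TRUE).
#' @param strict logical; use a strict \code{>} confidence threshold.
#' @return An \linkS4class{IonLibrary}. The number of retained entries is
#'   reported with \code{message()}.
#' @export
readIonLibrary <- function(path, minConfidence = 99, excludeShared = TRUE,
                           excludeModified = TRUE, strict = FALSE) {
  df <- .read_tsv(path)
  .require_cols(df, .IONLIB_COLS, "ion library")
  for (col in c("charge", "precursor_mz", "fragment_mz", "confidence"))
    df[[col]] <- .check_numeric(df[[col]], col, "ion library")
  df$shared <- as.logical(df$shared)
  df$modified <- as.logical(df$modified)
  keep <- if (strict) df$confidence > minConfidence else
    df$confidence >= minConfidence
  if (excludeShared) keep <- keep & !df$shared
  if (excludeModified) keep <- keep & !df$modified
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0)
    stop("empty library after confidence/shared/modified filtering")
  message(sprintf("ion library: %d entries retained", nrow(df)))
  IonLibrary(df)
}

#' Write an ion library to TSV
#' @param lib An \linkS4class{IonLibrary}.
#' @param path output path.
#' @export
writeIonLibrary <- function(lib, path) {
  .write_tsv(as.data.frame(ionEntries(lib)), path)
}

#' Read a run design table
#'
#' @param path TSV with columns \code{run_id}, \code{sample_type},
#'   \code{bio_rep}, \code{dig_rep}, \code{inj_rep}.
#' @return data.frame of the design.
#' @export
readRunDesign <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("run_id", "sample_type", "bio_rep", "dig_rep",
                      "inj_rep"), "run design")
  if (anyDuplicated(df$run_id))
    stop("run design: duplicated run_id")
  df
}

#' @rdname readRunDesign
#' @param design data.frame run design.
#' @export
writeRunDesign <- function(design, path) .write_tsv(design, path)

#' Read a fragment x run intensity table
#'
#' The table has the four fragment key columns followed by one column per run;
#' empty cells are missing values. Runs must match the design exactly.
#'
#' @param path intensity TSV.
#' @param designPath run design TSV (see \code{\link{readRunDesign}}), or a
#'   data.frame passed directly.
#' @return A \linkS4class{FragmentExperiment}.
#' @export
readFragmentTable <- function(path, designPath) {
  df <- .read_tsv(path)
  .require_cols(df, .KEY_COLS, "fragment table")
  design <- if (is.character(designPath)) readRunDesign(designPath) else
    designPath
  runcols <- setdiff(colnames(df), .KEY_COLS)
  unknown <- setdiff(runcols, design$run_id)
  if (length(unknown) > 0)
    stop(sprintf("design mismatch: run(s) %s absent from design",
                 paste(unknown, collapse = ", ")))
  absent <- setdiff(design$run_id, runcols)
  if (length(absent) > 0)
    stop(sprintf("design mismatch: design run(s) %s absent from table",
                 paste(absent, collapse = ", ")))
  m <- as.matrix(df[, design$run_id, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE))
    stop("fragment table: negative intensity value")
  FragmentExperiment(m, df[, .KEY_COLS, drop = FALSE], design)
}

#' @rdname readFragmentTable
#' @param fe A FragmentExperiment to write.
#' @export
writeFragmentTable <- function(fe, path) {
  .write_tsv(cbind(fragmentKeys(fe), as.data.frame(intensities(fe))), path)
}

#' Read a transcript expression table
#'
#' @param path TSV with columns \code{gene_id}, one or more \code{fpkm_*}
#'   columns, \code{log2_fc}, \code{fdr}.
#' @return data.frame; FPKM columns validated non-negative, FDR in [0,1].
#' @export
readExpressionTable <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0) stop("expression table: no records")
  .require_cols(df, c("gene_id", "log2_fc", "fdr"), "expression table")
  numcols <- setdiff(colnames(df), "gene_id")
  for (col in numcols)
    df[[col]] <- .check_numeric(df[[col]], col, "expression table")
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    stop("expression table: fdr outside [0, 1]")
  fpkm <- grep("^fpkm", colnames(df), value = TRUE)
  if (any(unlist(df[fpkm]) < 0, na.rm = TRUE))
    stop("expression table: negative FPKM")
  df
}

#' @rdname readExpressionTable
#' @param expr expression data.frame to write.
#' @export
writeExpressionTable <- function(expr, path) .write_tsv(expr, path)

#' Read/write a protein quantification table
#'
#' Plain TSV round-trip of the \code{\link{callDaps}} output; writing then
#' reading reproduces all numeric values to full precision.
#'
#' @param path file path.
#' @export
readQuantTable <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0) stop("quant table: no records")
  .require_cols(df, c("protein_id", "log_B_fc", "linear_fc"), "quant table")
  for (col in setdiff(colnames(df), c("protein_id", "dap_flag", "note")))
    df[[col]] <- .check_numeric(df[[col]], col, "quant table")
  df
}

#' @rdname readQuantTable
#' @param quant data.frame as returned by \code{\link{callDaps}}.
#' @export
writeQuantTable <- function(quant, path) {
  num <- vapply(quant, is.numeric, logical(1))
  out <- quant
  # full-precision round trip
  out[num] <- lapply(quant[num], function(x) format(x, digits = 17))
  .write_tsv(out, path)
}

#' Read an MRM peak-area export
#'
#' Long-format export from a transition-analysis tool with columns
#' \code{protein_id}, \code{peptide}, \code{charge}, \code{fragment_id},
#' \code{run_id}, \code{area}; reshaped into a \linkS4class{FragmentExperiment}.
#'
#' @param path peak-area table (TSV).
#' @param designPath run design TSV or data.frame.
#' @return A \linkS4class{FragmentExperiment} of peak areas.
#' @export
readMrmAreas <- function(path, designPath) {
  df <- .read_tsv(path)
  .require_cols(df, c(.KEY_COLS, "run_id", "area"), "MRM areas")
  df$area <- .check_numeric(df$area, "area", "MRM areas")
  if (any(df$area < 0, na.rm = TRUE)) stop("MRM areas: negative area")
  design <- if (is.character(designPath)) readRunDesign(designPath) else
    designPath
  unknown <- setdiff(unique(df$run_id), design$run_id)
  if (length(unknown) > 0)
    stop(sprintf("design mismatch: run(s) %s absent from design",
                 paste(unknown, collapse = ", ")))
  key <- fragmentKeyString(df)
  ukey <- unique(key)
  m <- matrix(NA_real_, nrow = length(ukey), ncol = nrow(design),
              dimnames = list(ukey, design$run_id))
  m[cbind(match(key, ukey), match(df$run_id, design$run_id))] <- df$area
  frag <- df[match(ukey, key), .KEY_COLS, drop = FALSE]
  FragmentExperiment(m, frag, design)
}
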