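# Proteome-transcriptome integration: pair protein quantifications with
# transcript fold changes, correlate, and classify each gene into one of the
# nine (protein call x transcript call) concordance classes.

#' Pair proteins with transcripts
#'
#' Defaults to exact identifier equality; an optional two-column map
#' (\code{protein_id}, \code{gene_id}) handles namespace exceptions.
#' Unmatched proteins and proteins matching more than one transcript row are
#' reported separately and excluded from the paired table.
#'
#' @param quant protein quantification (\code{\link{callDaps}} output).
#' @param expr expression table (\code{\link{readExpressionTable}} or
#'   \code{\link{simulateTranscripts}} output).
#' @param idMap optional data.frame with columns \code{protein_id},
#'   \code{gene_id}.
#' @return list with \code{paired} (data.frame), \code{unmatched} and
#'   \code{ambiguous} (character vectors of protein ids).
#' @export
matchGenes <- function(quant, expr, idMap = NULL) {
  gene_of <- quant$protein_id
  if (!is.null(idMap)) {
    hit <- match(quant$protein_id, idMap$protein_id)
    gene_of <- ifelse(is.na(hit), gene_of, idMap$gene_id[hit])
  }
  counts <- table(expr$gene_id)
  ambiguous <- quant$protein_id[gene_of %in%
                                  names(counts)[counts > 1]]
  unmatched <- quant$protein_id[!(gene_of %in% expr$gene_id)]
  ok <- !(quant$protein_id %in% c(ambiguous, unmatched))
  i <- match(gene_of[ok], expr$gene_id)
  paired <- data.frame(
    protein_id = quant$protein_id[ok],
    gene_id = gene_of[ok],
    protein_log_B_fc = quant$log_B_fc[ok],
    protein_p = quant$p_value[ok],
    protein_call = quant$dap_flag[ok],
    transcript_log2_fc = expr$log2_fc[i],
    transcript_fdr = expr$fdr[i])
  cfg <- attr(quant, "config")
  attr(paired, "B") <- if (is.null(cfg)) 1.4 else cfg$B
  list(paired = paired, unmatched = unmatched, ambiguous = ambiguous)
}

#' Protein-transcript fold-change correlation
#'
#' Pearson correlation between protein log2 fold change (converted from the
#' log_B scale) and transcript log2 fold change over complete pairs.
#'
#' @param paired paired table from \code{\link{matchGenes}}.
#' @param B log base of the protein fold changes (taken from the paired
#'   table's attribute when present).
#' @return Pearson r.
#' @export
proteomeTranscriptomeCorrelation <- function(paired, B = NULL) {
  if (is.null(B)) B <- attr(paired, "B")
  if (is.null(B)) B <- 1.4
  p <- paired$protein_log_B_fc * log(B) / log(2)
  t <- paired$transcript_log2_fc
  ok <- !is.na(p) & !is.na(t)
  if (sum(ok) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(p[ok]) == 0 || stats::sd(t[ok]) == 0)
    stop("correlation undefined: zero variance in fold changes")
  stats::cor(p[ok], t[ok])
}

#' Classify genes into concordance classes
#'
#' Protein call: the DAP rule (linear fold change above threshold and
#' p < alpha, from \code{\link{callDaps}}). Transcript call: FDR below
#' \code{transcriptFdr} and |log2 FC| above \code{transcriptLfc} (the
#' stringent two-part rule; set \code{transcriptLfc = 0} for an FDR-only
#' mode). Each paired gene lands in exactly one of the nine
#' protein x transcript classes.
#'
#' @param paired paired table from \code{\link{matchGenes}}.
#' @param transcriptFdr transcript FDR threshold (default 0.05).
#' @param transcriptLfc transcript |log2 FC| threshold (default 2).
#' @return list with \code{records} (the paired table plus
#'   \code{transcript_call} and \code{class}), \code{counts} (9-class
#'   contingency table) and \code{heatmap} (gene, protein log_B FC,
#'   transcript log2 FC, class).
#' @export
classifyConcordance <- function(paired, transcriptFdr = 0.05,
                                transcriptLfc = 2) {
  tcall <- ifelse(!is.na(paired$transcript_fdr) &
                    paired$transcript_fdr < transcriptFdr &
                    abs(paired$transcript_log2_fc) > transcriptLfc,
                  ifelse(paired$transcript_log2_fc > 0, "up", "down"),
                  "unchanged")
  rec <- paired
  rec$transcript_call <- tcall
  rec$class <- paste(rec$protein_call, tcall, sep = ":")
  lv <- c("up", "down", "unchanged")
  counts <- table(protein = factor(rec$protein_call, lv),
                  transcript = factor(tcall, lv))
  heat <- data.frame(gene_id = rec$gene_id,
                     protein_log_B_fc = rec$protein_log_B_fc,
                     transcript_log2_fc = rec$transcript_log2_fc,
                     class = rec$class)
  list(records = rec, counts = counts, heatmap = heat)
}
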