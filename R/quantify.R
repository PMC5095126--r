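# Log-base-B protein quantification: fragment logs -> peptide means ->
# median of the top-3 most intense peptides -> fold change, CV, Student's
# t-test and differential-accumulation calling.

#' Quantification configuration
#'
#' @param B logarithm base used for abundances and fold changes (> 1,
#'   default 1.4, so fold-change columns follow the log_1.4 convention).
#' @param fcThreshold linear fold-change threshold for differential
#'   accumulation (default 1.4).
#' @param alpha significance level (default 0.05).
#' @param topN peptides entering the protein median (default 3).
#' @return list of class \code{QuantConfig}.
#' @export
quantConfig <- function(B = 1.4, fcThreshold = 1.4, alpha = 0.05, topN = 3) {
  stopifnot(B > 1, fcThreshold >= 1, alpha > 0, alpha < 1, topN >= 1)
  structure(list(B = B, fcThreshold = fcThreshold, alpha = alpha,
                 topN = topN), class = "QuantConfig")
}

.logB <- function(x, B) log(x) / log(B)

#' Peptide abundance from fragment log values
#'
#' Mean of the fragment log_B values of one peptide in one sample; missing
#' fragments are ignored.
#'
#' @param fragLogValues numeric vector of fragment log_B intensities.
#' @return log_B peptide abundance.
#' @export
peptideValue <- function(fragLogValues) mean(fragLogValues, na.rm = TRUE)

#' Protein abundance from peptide values
#'
#' Median of the \code{topN} peptides ranked by total intensity (summed
#' fragment intensity over all runs); ranking ties are broken
#' lexicographically by peptide sequence so the roll-up is deterministic.
#'
#' @param values named (by peptide sequence) log_B peptide abundances.
#' @param totalIntensity named total intensities used for ranking.
#' @param topN number of peptides to use (default 3).
#' @return log_B protein abundance.
#' @export
proteinValue <- function(values, totalIntensity, topN = 3) {
  stopifnot(length(values) >= 1)
  peps <- names(values)
  ord <- order(-totalIntensity[peps], peps)
  sel <- ord[seq_len(min(topN, length(values)))]
  stats::median(values[sel], na.rm = TRUE)
}

#' Fold change on the log-B scale
#'
#' \code{log_B_fc = value_A - value_B}; \code{linear_fc = B^log_B_fc}.
#'
#' @param valueA,valueB log_B protein abundances of the two samples.
#' @param config a \code{\link{quantConfig}}.
#' @return list with \code{log_B_fc} and \code{linear_fc}.
#' @export
foldChange <- function(valueA, valueB, config = quantConfig()) {
  lfc <- valueA - valueB
  list(log_B_fc = lfc, linear_fc = config$B^lfc)
}

#' Coefficient of variation across biological replicates
#'
#' Sample standard deviation divided by the mean, on the linear scale.
#'
#' @param linearValues positive per-replicate abundances (>= 2 values).
#' @return CV as a fraction.
#' @export
proteinCV <- function(linearValues) {
  linearValues <- linearValues[!is.na(linearValues)]
  if (length(linearValues) < 2)
    stop("CV needs >= 2 replicates")
  stopifnot(all(linearValues > 0))
  stats::sd(linearValues) / mean(linearValues)
}

.ttest_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  out <- tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
  out
}

#' Quantify proteins and call differential accumulation
#'
#' Rolls fragments up to proteins per biological sample: fragment log_B
#' values (already averaged over the technical levels by the cascade) are
#' averaged per peptide, each protein is the median of its top-3 most
#' intense peptides, the per-sample-type abundance is the mean of the
#' biological-replicate protein values, and the fold change is the
#' between-type difference of those medians-of-top-3 raised to the power B
#' -- the same quantity the t-test compares, so the call and the reported
#' fold change are coherent. Differential accumulation requires both the
#' linear fold-change threshold and a two-sided Student's t-test on the
#' per-biological-replicate log_B values below alpha; BH-adjusted q-values
#' are reported informationally.
#'
#' @param bioRep replicate-resolved \linkS4class{FragmentExperiment}
#'   (runs = sample_type x bio_rep).
#' @param sampleType sample-type-averaged \linkS4class{FragmentExperiment};
#'   optional, retained for reporting symmetry (values are computed from
#'   \code{bioRep}).
#' @param config a \code{\link{quantConfig}}.
#' @param contrast character of length 2: the sample types compared, fold
#'   change is \code{contrast[1]} relative to \code{contrast[2]}. Default:
#'   second vs first type of the design.
#' @return data.frame (one row per protein): per-type abundances, per-bio-rep
#'   abundances, \code{log_B_fc}, \code{linear_fc}, \code{p_value}, \code{q_value},
#'   per-type \code{cv_*}, \code{dap_flag} in \{up, down, unchanged\}, and a
#'   \code{note} column (e.g. "untestable" when a group has n < 2).
#' @export
callDaps <- function(bioRep, sampleType = NULL, config = quantConfig(),
                     contrast = NULL) {
  types <- unique(colData(bioRep)$sample_type)
  if (is.null(contrast)) contrast <- c(types[2], types[1])
  stopifnot(all(contrast %in% types))
  fk <- fragmentKeys(bioRep)
  B <- config$B

  total <- tapply(rowSums(intensities(bioRep), na.rm = TRUE), fk$peptide, sum)

  lx <- .logB(intensities(bioRep), B)
  pepBio <- do.call(rbind, lapply(split(seq_len(nrow(lx)), fk$peptide),
                                  function(i)
    colMeans(lx[i, , drop = FALSE], na.rm = TRUE)))
  pepBio[is.nan(pepBio)] <- NA
  pepProt <- fk$protein_id[match(rownames(pepBio), fk$peptide)]

  cdB <- runDesign(bioRep)
  rows <- lapply(split(seq_len(nrow(pepBio)), pepProt), function(i) {
    peps <- rownames(pepBio)[i]
    ord <- order(-total[peps], peps)
    sel <- peps[ord[seq_len(min(config$topN, length(peps)))]]
    vBio <- apply(pepBio[sel, , drop = FALSE], 2, stats::median,
                  na.rm = TRUE)
    vType <- vapply(types, function(s)
      mean(vBio[cdB$sample_type == s], na.rm = TRUE), numeric(1))
    a <- vBio[cdB$sample_type == contrast[1]]
    b <- vBio[cdB$sample_type == contrast[2]]
    lfc <- vType[contrast[1]] - vType[contrast[2]]
    p <- .ttest_p(a, b)
    cvs <- vapply(types, function(s) {
      v <- B^vBio[cdB$sample_type == s]
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v) / mean(v)
    }, numeric(1))
    out <- data.frame(n_peptides = length(peps),
                      log_B_fc = unname(lfc),
                      linear_fc = unname(B^lfc),
                      p_value = p)
    for (s in types) out[[paste0("abundance_", s)]] <- unname(vType[s])
    for (s in types) out[[paste0("cv_", s)]] <- unname(cvs[s])
    for (r in seq_along(vBio))
      out[[paste0("abundance_", names(vBio)[r])]] <- unname(vBio[r])
    out
  })
  quant <- do.call(rbind, rows)
  quant <- cbind(protein_id = names(rows), quant)
  rownames(quant) <- NULL
  quant$q_value <- stats::p.adjust(quant$p_value, method = "BH")
  thr <- .logB(config$fcThreshold, B)
  flag <- ifelse(is.na(quant$p_value), "unchanged",
          ifelse(quant$p_value < config$alpha & quant$log_B_fc >= thr, "up",
          ifelse(quant$p_value < config$alpha & quant$log_B_fc <= -thr,
                 "down", "unchanged")))
  quant$dap_flag <- flag
  quant$note <- ifelse(is.na(quant$p_value), "untestable", "")
  attr(quant, "contrast") <- contrast
  attr(quant, "config") <- config
  quant
}
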