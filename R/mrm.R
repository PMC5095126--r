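# Targeted MRM branch: transition-list constraint validation, peptide-level
# injection normalization, protein-level sample-set normalization based on
# the 2 most intense peptides, Student's t-test with BH FDR control, and
# cross-platform comparison against the SWATH quantification.

#' Validate an MRM transition list
#'
#' Applies the targeted-assay design constraints: peptide length 5--30
#' residues, fully tryptic peptides without missed cleavage sites (no
#' internal K/R unless followed by P), precursor charge 2--4, at most 4
#' transitions per peptide (most intense kept when \code{area} is present)
#' and no more than 3 best-flyer peptides per protein (ranked by total
#' area when available).
#'
#' @param transitions data.frame with columns \code{protein_id},
#'   \code{peptide}, \code{charge}, \code{fragment_id}, optionally
#'   \code{area}.
#' @param lengthRange allowed peptide length (default \code{c(5, 30)}).
#' @param maxPeptides best-flyer peptides retained per protein (default 3).
#' @param maxFragments transitions retained per peptide (default 4).
#' @return list with \code{valid} (filtered data.frame) and
#'   \code{violations} (data.frame entity/reason).
#' @export
validateTransitionList <- function(transitions, lengthRange = c(5, 30),
                                   maxPeptides = 3, maxFragments = 4) {
  .require_cols(transitions, c("protein_id", "peptide", "charge",
                               "fragment_id"), "transition list")
  v <- list()
  flag <- function(entity, reason)
    v[[length(v) + 1]] <<- data.frame(entity = entity, reason = reason)

  len <- nchar(transitions$peptide)
  badLen <- unique(transitions$peptide[len < lengthRange[1] |
                                         len > lengthRange[2]])
  if (length(badLen)) flag(badLen, "peptide length outside 5-30")

  missed <- vapply(unique(transitions$peptide), function(p) {
    aa <- strsplit(p, "")[[1]]
    n <- length(aa)
    internal <- which(aa[-n] %in% c("K", "R"))
    any(aa[internal + 1] != "P")
  }, logical(1))
  badMC <- names(missed)[missed]
  if (length(badMC)) flag(badMC, "missed cleavage site")

  badZ <- unique(transitions$peptide[!transitions$charge %in% 2:4])
  if (length(badZ)) flag(badZ, "precursor charge outside 2-4")

  keep <- !(transitions$peptide %in% c(badLen, badMC, badZ))
  out <- transitions[keep, , drop = FALSE]

  if (nrow(out) > 0) {
    hasArea <- "area" %in% colnames(out)
    rank_metric <- if (hasArea) out$area else rep(1, nrow(out))
    # cap transitions per peptide
    fkeep <- unlist(lapply(split(seq_len(nrow(out)), out$peptide),
                           function(i) {
      if (length(i) <= maxFragments) return(i)
      flag(out$peptide[i[1]],
           sprintf("more than %d transitions; keeping most intense",
                   maxFragments))
      i[order(-rank_metric[i])][seq_len(maxFragments)]
    }), use.names = FALSE)
    out <- out[sort(fkeep), , drop = FALSE]
    # cap peptides per protein
    peps <- unique(out[, c("protein_id", "peptide")])
    tot <- tapply(if (hasArea) out$area else rep(1, nrow(out)),
                  out$peptide, sum)
    pkeep <- unlist(lapply(split(peps$peptide, peps$protein_id),
                           function(pp) {
      if (length(pp) <= maxPeptides) return(pp)
      flag(setdiff(pp, pp[order(-tot[pp])][seq_len(maxPeptides)]),
           "beyond 3 best-flyer peptides per protein")
      pp[order(-tot[pp])][seq_len(maxPeptides)]
    }), use.names = FALSE)
    out <- out[out$peptide %in% pkeep, , drop = FALSE]
  }
  list(valid = out,
       violations = if (length(v)) do.call(rbind, v) else
         data.frame(entity = character(0), reason = character(0)))
}

# Collapse fragment-level areas to peptide areas (sum over transitions).
.peptide_areas <- function(fe) {
  fk <- fragmentKeys(fe)
  x <- intensities(fe)
  m <- do.call(rbind, lapply(split(seq_len(nrow(x)), fk$peptide),
                             function(i) {
    cs <- colSums(x[i, , drop = FALSE], na.rm = TRUE)
    all_na <- colSums(!is.na(x[i, , drop = FALSE])) == 0
    cs[all_na] <- NA
    cs
  }))
  prot <- fk$protein_id[match(rownames(m), fk$peptide)]
  list(areas = m, protein = prot)
}

#' Normalize an MRM peak-area table
#'
#' Stage 1: injection replicates of each sample are median-equalized at the
#' peptide level and averaged (log scale). Stage 2: samples are scale-
#' normalized at the protein level, each protein contributing the mean log
#' area of its 2 most intense peptides; the per-sample factor is the median
#' correction over proteins (robust to differential proteins in the target
#' panel), re-centered to geometric mean 1. Proteins with
#' fewer than 2 peptides do not contribute to factor estimation but are
#' still normalized.
#'
#' @param fe MRM \linkS4class{FragmentExperiment} (transition x run areas).
#' @return list with \code{peptides} (peptide x sample matrix, normalized),
#'   \code{protein} (peptide-to-protein map), \code{design} (collapsed run
#'   design) and \code{factors} (per-stage list).
#' @export
normalizeMrm <- function(fe) {
  pa <- .peptide_areas(fe)
  design <- runDesign(fe)
  pfe <- FragmentExperiment(
    pa$areas,
    data.frame(protein_id = pa$protein, peptide = rownames(pa$areas),
               charge = 0, fragment_id = "pep"),
    design)
  injFactors <- list()
  if ("inj_rep" %in% colnames(design)) {
    g <- paste(design$sample_type, design$bio_rep, design$dig_rep)
    for (gr in unique(g)) {
      runs <- design$run_id[g == gr]
      if (length(runs) < 2) next
      res <- scaleNormalize(pfe, runs, minSharedRows = 2)
      pfe <- res$fe
      injFactors[[gr]] <- res$factors
    }
    pfe <- averageLevel(pfe, "injection")
    if ("dig_rep" %in% colnames(runDesign(pfe)) &&
        length(unique(runDesign(pfe)$dig_rep)) == 1) {
      cd <- runDesign(pfe)
      cd$dig_rep <- NULL
      pfe <- FragmentExperiment(intensities(pfe), fragmentKeys(pfe), cd)
    }
  }
  m <- intensities(pfe)
  prot <- fragmentKeys(pfe)$protein_id

  # protein-level sample-set normalization from the 2 most intense peptides
  tot <- rowSums(m, na.rm = TRUE)
  top2 <- unlist(lapply(split(seq_len(nrow(m)), prot), function(i) {
    if (length(i) < 2) return(integer(0))
    i[order(-tot[i])][1:2]
  }), use.names = FALSE)
  protFactors <- rep(1, ncol(m))
  names(protFactors) <- colnames(m)
  if (length(top2) >= 2) {
    lm2 <- log(m[top2, , drop = FALSE])
    pr2 <- prot[top2]
    pm <- do.call(rbind, lapply(split(seq_len(nrow(lm2)), pr2), function(i)
      colMeans(lm2[i, , drop = FALSE], na.rm = TRUE)))
    dev <- sweep(pm, 1, rowMeans(pm, na.rm = TRUE))
    # median across proteins: robust to differential proteins in the panel
    shift <- -apply(dev, 2, stats::median, na.rm = TRUE)
    shift <- shift - mean(shift)
    protFactors <- exp(shift)
    m <- sweep(m, 2, protFactors, `*`)
  }
  list(peptides = m, protein = prot, design = runDesign(pfe),
       factors = list(injection = injFactors, protein = protFactors))
}

#' Differential testing of normalized MRM data
#'
#' Protein abundance per biological replicate is the mean log area of its 2
#' most intense peptides; differences are tested with a two-sided Student's
#' t-test across biological replicates and controlled with Benjamini-
#' Hochberg FDR; significant iff FDR < 0.05.
#'
#' @param norm output of \code{\link{normalizeMrm}}.
#' @param contrast sample types compared (default second vs first).
#' @param fdrThreshold significance threshold on the BH FDR (default 0.05).
#' @return data.frame: \code{protein_id}, \code{log2_fc}, \code{p_value},
#'   \code{fdr}, \code{significant}.
#' @export
testMrm <- function(norm, contrast = NULL, fdrThreshold = 0.05) {
  design <- norm$design
  types <- unique(design$sample_type)
  if (is.null(contrast)) contrast <- c(types[2], types[1])
  nbio <- vapply(contrast, function(s)
    length(unique(design$bio_rep[design$sample_type == s])), integer(1))
  if (any(nbio < 3))
    warning("fewer than 3 biological replicates in a group")
  lm <- log(norm$peptides)
  tot <- rowSums(norm$peptides, na.rm = TRUE)
  rows <- lapply(split(seq_len(nrow(lm)), norm$protein), function(i) {
    sel <- i[order(-tot[i])][seq_len(min(2, length(i)))]
    v <- colMeans(lm[sel, , drop = FALSE], na.rm = TRUE)
    a <- v[design$sample_type == contrast[1]]
    b <- v[design$sample_type == contrast[2]]
    data.frame(log2_fc = (mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)) /
                 log(2),
               p_value = .ttest_p(a, b))
  })
  out <- do.call(rbind, rows)
  out <- cbind(protein_id = names(rows), out)
  rownames(out) <- NULL
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdrThreshold
  attr(out, "contrast") <- contrast
  out
}

#' Cross-platform agreement of fold changes
#'
#' Pearson correlation between the SWATH and MRM log2 fold changes over
#' shared proteins (SWATH log_B values are converted to log2).
#'
#' @param swathQuant output of \code{\link{callDaps}}.
#' @param mrmQuant output of \code{\link{testMrm}}.
#' @return list with \code{r} and the paired scatter table \code{pairs}.
#' @export
comparePlatforms <- function(swathQuant, mrmQuant) {
  cfg <- attr(swathQuant, "config")
  B <- if (is.null(cfg)) 1.4 else cfg$B
  shared <- intersect(swathQuant$protein_id, mrmQuant$protein_id)
  if (length(shared) < 3)
    stop("need >= 3 shared proteins for a correlation")
  sw <- swathQuant$log_B_fc[match(shared, swathQuant$protein_id)] *
    log(B) / log(2)
  mr <- mrmQuant$log2_fc[match(shared, mrmQuant$protein_id)]
  ok <- !is.na(sw) & !is.na(mr)
  pairs <- data.frame(protein_id = shared[ok], swath_log2_fc = sw[ok],
                      mrm_log2_fc = mr[ok])
  list(r = stats::cor(pairs$swath_log2_fc, pairs$mrm_log2_fc),
       pairs = pairs)
}
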