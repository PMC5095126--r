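# End-to-end orchestration: the SWATH pipeline in the published stage order
# (stage-1 injection normalization -> fragment filtering -> cascade stages
# 2-4 -> log-base-B quantification), and the full study surface with the
# MRM, emPAI and transcript-integration branches.

#' Default study configuration
#'
#' One declarative list controlling every module parameter; all thresholds
#' (tau, minimum counts, B, fold-change threshold, alpha) are surfaced here
#' with the published analysis values as defaults.
#'
#' @param seed master RNG seed; all branch seeds are derived from it.
#' @return nested configuration list.
#' @export
studyConfig <- function(seed = 1) {
  list(
    seed = seed,
    synthetic = list(nProteins = 300, fracDa = 0.1,
                     fcSet = c(0.25, 0.5, 2, 4),
                     peptidesPerProtein = c(4, 8),
                     fragmentsPerPeptide = c(5, 8),
                     fracInterference = 0.3,
                     rho = 0, nExtraGenes = 50),
    noise = noiseModel(),
    filter = list(tau = 0.95, minTrend = 3, minFragments = 3,
                  minPeptides = 3),
    normalization = list(center = "median", minSharedRows = 10),
    quant = quantConfig(),
    mrm = list(panelSize = 60),
    empai = list(mzRange = c(300, 1250), charges = c(2, 3),
                 lengthRange = c(5, 30))
  )
}

.check_config <- function(config) {
  tau <- config$filter$tau
  if (is.null(tau) || tau <= 0 || tau >= 1)
    stop("config validation error: filter$tau must lie in (0, 1)")
  if (!inherits(config$quant, "QuantConfig"))
    config$quant <- do.call(quantConfig, as.list(config$quant))
  if (!inherits(config$noise, "NoiseModel"))
    config$noise <- do.call(noiseModel, as.list(config$noise))
  config
}

# Stage 1: scale-normalize and average the injection replicates of each
# digestion sample.
.stage1 <- function(fe, center = "median", minSharedRows = 10) {
  cd <- runDesign(fe)
  if (!"inj_rep" %in% colnames(cd))
    return(list(fe = fe, report = NULL))
  gcols <- intersect(c("sample_type", "bio_rep", "dig_rep"), colnames(cd))
  g <- do.call(paste, c(cd[gcols], sep = "\r"))
  rep <- list()
  for (gr in unique(g)) {
    runs <- cd$run_id[g == gr]
    if (length(runs) < 2) next
    res <- scaleNormalize(fe, runs, center = center,
                          minSharedRows = minSharedRows)
    fe <- res$fe
    rep[[gr]] <- data.frame(stage = "injection", run_id = names(res$factors),
                            factor = unname(res$factors))
  }
  list(fe = averageLevel(fe, "injection"), report = do.call(rbind, rep))
}

.funnel <- function(fe) {
  fk <- fragmentKeys(fe)
  c(fragments = nrow(fe), peptides = length(unique(fk$peptide)),
    proteins = length(unique(fk$protein_id)))
}

#' Run the SWATH quantification pipeline
#'
#' Stages, in the published order: (1) scaling normalization and averaging of
#' the injection replicates of each digestion sample; (2) reliable-fragment
#' filtering (minimum-count pre-exclusion + spectral contrast angle
#' clustering); (3) normalization/averaging over digestion replicates and
#' within sample type, with cross-sample scale normalization between sample
#' types; (4) log-base-B top-3-median protein quantification with
#' differential-accumulation calling.
#'
#' @param fragments a \linkS4class{FragmentExperiment} or the path to a
#'   fragment intensity TSV.
#' @param design run design (data.frame or path); required when
#'   \code{fragments} is a path.
#' @param library optional \linkS4class{IonLibrary} or path; fragment keys
#'   are checked against it.
#' @param config configuration list (see \code{\link{studyConfig}}).
#' @return list: \code{quant} (protein table), \code{report} (normalization
#'   factors), \code{rejections} (filter log), \code{counts} (entity funnel
#'   per stage), plus the intermediate \code{bioRep}/\code{sampleType}
#'   tables.
#' @export
runSwathPipeline <- function(fragments, design = NULL, library = NULL,
                             config = studyConfig()) {
  config <- .check_config(config)
  if (is.character(fragments)) {
    if (is.null(design))
      stop("config error: a run design is required to read a fragment table")
    fragments <- readFragmentTable(fragments, design)
  }
  if (is.character(library)) library <- readIonLibrary(library)
  counts <- list(input = .funnel(fragments))

  s1 <- .stage1(fragments, center = config$normalization$center,
                minSharedRows = config$normalization$minSharedRows)
  filtered <- filterReliable(s1$fe, library = library,
                             tau = config$filter$tau,
                             minTrend = config$filter$minTrend,
                             minFragments = config$filter$minFragments,
                             minPeptides = config$filter$minPeptides)
  counts$filtered <- .funnel(filtered)
  message(sprintf(
    "filtering: %d/%d fragments, %d/%d peptides, %d/%d proteins retained",
    counts$filtered[1], counts$input[1], counts$filtered[2],
    counts$input[2], counts$filtered[3], counts$input[3]))

  casc <- runCascade(filtered, center = config$normalization$center,
                     minSharedRows = config$normalization$minSharedRows,
                     levels = intersect(
                       c("digestion", "biological"),
                       names(.LEVELS)[.LEVELS %in%
                                        colnames(colData(filtered))]))
  quant <- callDaps(casc$bioRep, casc$sampleType, config = config$quant)
  counts$quantified <- c(fragments = nrow(filtered),
                         peptides = counts$filtered[["peptides"]],
                         proteins = nrow(quant))
  report <- rbind(s1$report, casc$report)
  list(quant = quant, report = report,
       rejections = metadata(filtered)$rejections,
       counts = do.call(rbind, counts),
       stage1 = s1$fe, filtered = filtered,
       bioRep = casc$bioRep, sampleType = casc$sampleType)
}

#' Score fold-change recovery against a known truth
#'
#' @param quant \code{\link{callDaps}} output.
#' @param truth the generating \linkS4class{GroundTruth}.
#' @param fcSensitivity minimum |linear fold change| counted in the
#'   sensitivity estimate (default 2).
#' @return list: \code{medae_log2} (median absolute error of recovered log2
#'   fold change), \code{sensitivity} (fraction of truly differential
#'   proteins with |FC| >= \code{fcSensitivity} called), \code{fdr}
#'   (false discoveries among calls), \code{n_quantified}, \code{n_called}.
#' @export
scoreRecovery <- function(quant, truth, fcSensitivity = 2) {
  cfg <- attr(quant, "config")
  B <- if (is.null(cfg)) 1.4 else cfg$B
  tp <- truthProteins(truth)
  i <- match(quant$protein_id, tp$protein_id)
  est <- quant$log_B_fc * log(B) / log(2)
  err <- est - tp$true_log2_fc[i]
  called <- quant$dap_flag != "unchanged"
  isDa <- tp$true_log2_fc[i] != 0
  bigDa <- tp$protein_id[abs(tp$true_log2_fc) >= log2(fcSensitivity)]
  sens <- sum(called & quant$protein_id %in% bigDa) /
    sum(tp$protein_id %in% bigDa)
  list(medae_log2 = stats::median(abs(err), na.rm = TRUE),
       sensitivity = sens,
       fdr = if (any(called)) mean(!isDa[called]) else 0,
       n_quantified = nrow(quant), n_called = sum(called))
}

#' Score interference rejection against a known truth
#'
#' Compares the fragments retained by \code{\link{filterReliable}} with the
#' generator's interference labels.
#'
#' @param filtered filtered \linkS4class{FragmentExperiment}.
#' @param input the pre-filter table the filter ran on.
#' @param truth the generating \linkS4class{GroundTruth}.
#' @return list: \code{interference_rejected} and \code{clean_retained}
#'   fractions, with the underlying counts.
#' @export
scoreInterference <- function(filtered, input, truth) {
  tf <- truthFragments(truth)
  tkey <- fragmentKeyString(tf)
  inKeys <- rownames(intensities(input))
  outKeys <- rownames(intensities(filtered))
  isIntf <- inKeys %in% tkey[tf$interference]
  kept <- inKeys %in% outKeys
  list(interference_rejected = mean(!kept[isIntf]),
       clean_retained = mean(kept[!isIntf]),
       n_interference = sum(isIntf), n_clean = sum(!isIntf))
}

#' Run the full synthetic study
#'
#' Generates ground truth, runs the SWATH pipeline, quantifies a data-driven
#' MRM validation panel (the SWATH differential calls plus random fill, up
#' to \code{mrm$panelSize} proteins), computes emPAI from simulated peptide
#' identifications, simulates a coupled transcriptome and classifies
#' concordance. All randomness derives from \code{config$seed}.
#'
#' @param config configuration list (see \code{\link{studyConfig}}).
#' @return list with elements \code{truth}, \code{swath}, \code{mrm},
#'   \code{empai}, \code{transcripts}, and \code{summary} (named numeric of
#'   the study's headline quantities).
#' @export
runFullStudy <- function(config = studyConfig()) {
  config <- .check_config(config)
  seed <- config$seed
  syn <- config$synthetic
  truth <- generateTruth(nProteins = syn$nProteins, fracDa = syn$fracDa,
                         fcSet = syn$fcSet,
                         peptidesPerProtein = syn$peptidesPerProtein,
                         fragmentsPerPeptide = syn$fragmentsPerPeptide,
                         fracInterference = syn$fracInterference,
                         seed = seed)
  design <- defaultRunDesign()
  frag <- simulateFragmentTable(truth, design, config$noise, seed = seed + 1)
  swath <- runSwathPipeline(frag, config = config)
  recovery <- scoreRecovery(swath$quant, truth)
  interference <- scoreInterference(swath$filtered, swath$stage1, truth)

  # MRM validation panel: SWATH differential calls + random fill
  called <- swath$quant$protein_id[swath$quant$dap_flag != "unchanged"]
  panelSize <- config$mrm$panelSize
  fill <- setdiff(swath$quant$protein_id, called)
  panel <- .with_seed(seed + 2, {
    if (length(called) >= panelSize) sample(called, panelSize) else
      c(called, sample(fill, min(length(fill),
                                 panelSize - length(called))))
  })
  mrmTab <- simulateMrmTable(truth, noise = config$noise, proteins = panel,
                             seed = seed + 3)
  mrmNorm <- normalizeMrm(mrmTab)
  mrmQuant <- testMrm(mrmNorm)
  platforms <- comparePlatforms(swath$quant, mrmQuant)

  # emPAI branch
  sequences <- generateProteinSequences(truth, seed = seed + 4)
  obs <- simulatePeptideObservations(
    truth, sequences, mzRange = config$empai$mzRange,
    charges = config$empai$charges,
    lengthRange = config$empai$lengthRange, seed = seed + 5)
  empaiRecs <- lapply(obs, function(o)
    empaiTable(sequences, o, mzLo = config$empai$mzRange[1],
               mzHi = config$empai$mzRange[2],
               charges = config$empai$charges,
               lengthRange = config$empai$lengthRange))
  names(empaiRecs) <- names(obs)
  empaiFc <- empaiFoldChange(empaiRecs[[2]], empaiRecs[[1]])
  shared <- intersect(empaiFc$protein_id[empaiFc$defined],
                      swath$quant$protein_id)
  B <- config$quant$B
  swLfc <- swath$quant$log_B_fc[match(shared, swath$quant$protein_id)] *
    log(B) / log(2)
  emLfc <- empaiFc$log2_fc[match(shared, empaiFc$protein_id)]
  empaiR <- if (length(shared) >= 3) stats::cor(swLfc, emLfc) else NA_real_

  # transcript branch
  expr <- simulateTranscripts(truth, rho = syn$rho,
                              nExtraGenes = syn$nExtraGenes,
                              seed = seed + 6)
  matched <- matchGenes(swath$quant, expr)
  ptr <- proteomeTranscriptomeCorrelation(matched$paired)
  conc <- classifyConcordance(matched$paired)

  medianCV <- vapply(unique(design$sample_type), function(s)
    stats::median(swath$quant[[paste0("cv_", s)]], na.rm = TRUE),
    numeric(1))

  summary <- c(n_quantified = nrow(swath$quant),
               n_daps = sum(swath$quant$dap_flag != "unchanged"),
               medae_log2fc = recovery$medae_log2,
               sensitivity_2fold = recovery$sensitivity,
               empirical_fdr = recovery$fdr,
               interference_rejected = interference$interference_rejected,
               clean_retained = interference$clean_retained,
               swath_mrm_r = platforms$r,
               swath_empai_r = empaiR,
               transcript_protein_r = ptr,
               median_cv = unname(stats::median(medianCV)))

  list(truth = truth, swath = swath, recovery = recovery,
       interference = interference,
       mrm = list(table = mrmTab, norm = mrmNorm, quant = mrmQuant,
                  panel = panel, platforms = platforms),
       empai = list(records = empaiRecs, fc = empaiFc, r = empaiR),
       transcripts = list(expr = expr, matched = matched, r = ptr,
                          concordance = conc),
       medianCV = medianCV, summary = summary)
}
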