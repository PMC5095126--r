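# Synthetic SWATH/MRM/transcript data with known ground truth. The generator
# emulates the structure of fragment-level XIC exports: multiplicative
# log-normal noise at each replicate level, per-run scale factors, additive
# interference transitions with their own cross-sample trend, and
# limit-of-detection censoring.

#' Ground truth of a synthetic quantification study
#'
#' @slot proteins DataFrame: \code{protein_id}, \code{base_abundance},
#'   \code{true_log2_fc}.
#' @slot peptides DataFrame: \code{protein_id}, \code{peptide}, \code{charge},
#'   \code{ionization_factor}.
#' @slot fragments DataFrame: fragment keys, \code{share} (fraction of the
#'   peptide signal carried by the fragment; shares of a peptide sum to 1),
#'   \code{interference} flag and one \code{intf_<sample_type>} column per
#'   sample type holding the additive interference trend.
#' @slot sampleTypes character; first element is the reference condition, the
#'   true fold change applies to the remaining type(s).
#' @export
setClass("GroundTruth",
         slots = c(proteins = "DataFrame", peptides = "DataFrame",
                   fragments = "DataFrame", sampleTypes = "character"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d proteins (%d differential), %d peptides, %d fragments\n",
    nrow(object@proteins), sum(object@proteins$true_log2_fc != 0),
    nrow(object@peptides), nrow(object@fragments)))
})

#' @describeIn GroundTruth-class protein-level truth as data.frame.
#' @param x A GroundTruth.
#' @export
truthProteins <- function(x) as.data.frame(x@proteins)

#' @describeIn GroundTruth-class peptide-level truth as data.frame.
#' @export
truthPeptides <- function(x) as.data.frame(x@peptides)

#' @describeIn GroundTruth-class fragment-level truth as data.frame.
#' @export
truthFragments <- function(x) as.data.frame(x@fragments)

# Evaluate expr under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Hierarchical noise model for synthetic intensities
#'
#' Coefficients of variation are fractions and act multiplicatively as
#' log-normal factors with sd \code{sqrt(log(1 + cv^2))} (so the linear-scale
#' CV of each factor equals the configured value). Biological noise is drawn
#' per (peptide, biological replicate), digestion noise per (peptide, bio,
#' digestion replicate), injection noise per (fragment, run) -- fragments of
#' one peptide therefore share the bio/dig factors, which is the
#' proportionality the spectral-angle filter relies on.
#'
#' @param cvInjection,cvDigestion,cvBiological per-level CVs (defaults
#'   0.10 / 0.15 / 0.20).
#' @param runScaleRange multiplicative per-run scale factor interval,
#'   sampled uniformly on the log scale (default \code{c(0.5, 2)}).
#' @param lod limit of detection: simulated intensities below it are censored
#'   to NA (default 100; base protein abundance has median 5e4).
#' @return list of class \code{NoiseModel}.
#' @export
noiseModel <- function(cvInjection = 0.10, cvDigestion = 0.15,
                       cvBiological = 0.20, runScaleRange = c(0.5, 2),
                       lod = 100) {
  stopifnot(cvInjection >= 0, cvDigestion >= 0, cvBiological >= 0,
            all(runScaleRange > 0), length(runScaleRange) == 2)
  structure(list(cvInjection = cvInjection, cvDigestion = cvDigestion,
                 cvBiological = cvBiological,
                 runScaleRange = sort(runScaleRange), lod = lod),
            class = "NoiseModel")
}

#' Replicate design of the default synthetic study
#'
#' Two sample types, three biological replicates each, three digestion
#' replicates for the first type and two for the second, three injections per
#' digestion sample.
#'
#' @param sampleTypes character vector of condition labels (first = reference).
#' @param nBio biological replicates per sample type.
#' @param digReps digestion (trypsinolysis) replicates per sample type,
#'   recycled over \code{sampleTypes}.
#' @param nInj injection replicates per digestion sample.
#' @return data.frame with columns \code{run_id}, \code{sample_type},
#'   \code{bio_rep}, \code{dig_rep}, \code{inj_rep}.
#' @export
defaultRunDesign <- function(sampleTypes = c("protonema", "protoplast"),
                             nBio = 3, digReps = c(3, 2), nInj = 3) {
  digReps <- rep(digReps, length.out = length(sampleTypes))
  rows <- do.call(rbind, lapply(seq_along(sampleTypes), function(i) {
    expand.grid(inj_rep = seq_len(nInj), dig_rep = seq_len(digReps[i]),
                bio_rep = seq_len(nBio), sample_type = sampleTypes[i],
                stringsAsFactors = FALSE)
  }))
  rows$run_id <- sprintf("%s_b%d_d%d_i%d", rows$sample_type, rows$bio_rep,
                         rows$dig_rep, rows$inj_rep)
  rows[, c("run_id", "sample_type", "bio_rep", "dig_rep", "inj_rep")]
}

#' @rdname defaultRunDesign
#' @details \code{mrmRunDesign} mirrors the targeted branch: duplicate
#'   injections, no digestion-replicate level (a single digestion per sample).
#' @export
mrmRunDesign <- function(sampleTypes = c("protonema", "protoplast"),
                         nBio = 3, nInj = 2) {
  defaultRunDesign(sampleTypes, nBio = nBio, digReps = 1, nInj = nInj)
}

.AA_BODY <- c("A","C","D","E","F","G","H","I","L","M","N","Q","S","T","V",
              "W","Y")

.random_peptides <- function(n, minLen = 7, maxLen = 15) {
  lens <- sample(seq(minLen, maxLen), n, replace = TRUE)
  vapply(lens, function(L) {
    paste0(paste(sample(.AA_BODY, L - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate the ground truth of a synthetic study
#'
#' Exactly \code{round(nProteins * fracDa)} proteins are differentially
#' abundant, with true log2 fold change \code{sign * abs(log2(fc))} for
#' \code{fc} sampled from \code{fcSet} and a random sign.
#'
#' @param nProteins number of proteins (default 300).
#' @param fracDa fraction of differentially abundant proteins (default 0.1).
#' @param fcSet positive linear fold changes to sample from
#'   (default \code{c(0.25, 0.5, 2, 4)}).
#' @param peptidesPerProtein,fragmentsPerPeptide integer ranges
#'   (defaults 4--8 peptides, 5--8 fragments).
#' @param fracInterference fraction of fragments carrying an additive
#'   interference transition (default 0.3).
#' @param interferenceStrength range of interference magnitude as a multiple
#'   of the fragment's clean reference-condition signal (default 2--4).
#' @param sampleTypes condition labels; first is the reference.
#' @param seed integer RNG seed (reproducible truth).
#' @return A \linkS4class{GroundTruth}.
#' @export
generateTruth <- function(nProteins = 300, fracDa = 0.1,
                          fcSet = c(0.25, 0.5, 2, 4),
                          peptidesPerProtein = c(4, 8),
                          fragmentsPerPeptide = c(5, 8),
                          fracInterference = 0.3,
                          interferenceStrength = c(2, 4),
                          sampleTypes = c("protonema", "protoplast"),
                          seed = 1) {
  if (any(fcSet <= 0)) stop("fcSet values must be positive")
  stopifnot(fracDa >= 0, fracDa <= 1, fracInterference >= 0,
            fracInterference <= 1, length(sampleTypes) >= 2)
  .with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(nProteins))
    lfc <- numeric(nProteins)
    nDa <- round(nProteins * fracDa)
    if (nDa > 0) {
      da <- sample(nProteins, nDa)
      fcs <- fcSet[sample.int(length(fcSet), nDa, replace = TRUE)]
      lfc[da] <- sample(c(-1, 1), nDa, replace = TRUE) * abs(log2(fcs))
    }
    proteins <- DataFrame(
      protein_id = ids,
      base_abundance = stats::rlnorm(nProteins, log(5e4), 1),
      true_log2_fc = lfc)

    nPep <- sample(seq(peptidesPerProtein[1], peptidesPerProtein[2]),
                   nProteins, replace = TRUE)
    pepProt <- rep(ids, nPep)
    seqs <- .random_peptides(sum(nPep))
    while (anyDuplicated(seqs))
      seqs[duplicated(seqs)] <- .random_peptides(sum(duplicated(seqs)))
    peptides <- DataFrame(
      protein_id = pepProt, peptide = seqs,
      charge = sample(2:3, sum(nPep), replace = TRUE),
      ionization_factor = stats::rlnorm(sum(nPep), 0, 0.5))

    nFrag <- sample(seq(fragmentsPerPeptide[1], fragmentsPerPeptide[2]),
                    nrow(peptides), replace = TRUE)
    fi <- rep(seq_len(nrow(peptides)), nFrag)
    raw <- stats::rgamma(sum(nFrag), shape = 2, rate = 1)
    share <- raw / stats::ave(raw, fi, FUN = sum)
    fragments <- DataFrame(
      protein_id = peptides$protein_id[fi],
      peptide = peptides$peptide[fi],
      charge = peptides$charge[fi],
      fragment_id = paste0("y", unlist(lapply(nFrag, function(k) 2 + seq_len(k)))),
      share = share,
      interference = stats::runif(sum(nFrag)) < fracInterference)
    base_sig <- proteins$base_abundance[match(fragments$protein_id, ids)] *
      peptides$ionization_factor[fi] * fragments$share
    strength <- stats::runif(sum(nFrag), interferenceStrength[1],
                             interferenceStrength[2])
    for (s in sampleTypes) {
      trend <- ifelse(fragments$interference,
                      strength * base_sig * stats::rlnorm(sum(nFrag), 0, 1.5),
                      0)
      fragments[[paste0("intf_", s)]] <- trend
    }
    new("GroundTruth", proteins = proteins, peptides = peptides,
        fragments = fragments, sampleTypes = sampleTypes)
  })
}

.sigma_ln <- function(cv) sqrt(log(1 + cv^2))

# Core intensity simulator shared by the SWATH and MRM flavors.
.simulate_intensities <- function(truth, design, noise, seed) {
  if (length(unique(design$sample_type)) < 2)
    stop("design error: need >= 2 sample types")
  if (!all(design$sample_type %in% truth@sampleTypes))
    stop("design sample types not covered by the ground truth")
  .with_seed(seed, {
    frag <- truth@fragments
    pep <- truth@peptides
    prot <- truth@proteins
    nF <- nrow(frag); nR <- nrow(design)
    pi_f <- match(frag$peptide, pep$peptide)
    base <- prot$base_abundance[match(frag$protein_id, prot$protein_id)]
    lfc <- prot$true_log2_fc[match(frag$protein_id, prot$protein_id)]
    clean <- base * pep$ionization_factor[pi_f] * frag$share

    ref <- truth@sampleTypes[1]
    isAlt <- design$sample_type != ref
    bioG <- paste(design$sample_type, design$bio_rep)
    digG <- paste(bioG, design$dig_rep)
    uBio <- unique(bioG); uDig <- unique(digG)
    eBio <- matrix(stats::rnorm(nrow(pep) * length(uBio), 0,
                                .sigma_ln(noise$cvBiological)),
                   nrow(pep), length(uBio))
    eDig <- matrix(stats::rnorm(nrow(pep) * length(uDig), 0,
                                .sigma_ln(noise$cvDigestion)),
                   nrow(pep), length(uDig))
    eInj <- matrix(stats::rnorm(nF * nR, 0, .sigma_ln(noise$cvInjection)),
                   nF, nR)
    runScale <- exp(stats::runif(nR, log(noise$runScaleRange[1]),
                                 log(noise$runScaleRange[2])))

    logx <- matrix(log(clean), nF, nR) +
      outer(log(2) * lfc, as.numeric(isAlt)) +
      eBio[pi_f, match(bioG, uBio), drop = FALSE] +
      eDig[pi_f, match(digG, uDig), drop = FALSE] +
      eInj
    x <- exp(logx)
    intf <- as.matrix(as.data.frame(
      frag[paste0("intf_", design$sample_type)]))
    ii <- which(frag$interference)
    if (length(ii) > 0) {
      # interference stems from co-eluting contaminant peptides, which carry
      # replicate noise of their own at the same hierarchy levels
      cb <- matrix(stats::rnorm(length(ii) * length(uBio), 0,
                                .sigma_ln(noise$cvBiological)),
                   length(ii), length(uBio))
      cd <- matrix(stats::rnorm(length(ii) * length(uDig), 0,
                                .sigma_ln(noise$cvDigestion)),
                   length(ii), length(uDig))
      ci <- matrix(stats::rnorm(length(ii) * nR, 0,
                                .sigma_ln(noise$cvInjection)),
                   length(ii), nR)
      intf[ii, ] <- intf[ii, , drop = FALSE] *
        exp(cb[, match(bioG, uBio), drop = FALSE] +
              cd[, match(digG, uDig), drop = FALSE] + ci)
    }
    x <- sweep(x + intf, 2, runScale, `*`)
    x[x < noise$lod] <- NA
    colnames(x) <- design$run_id
    FragmentExperiment(x, as.data.frame(frag[, .KEY_COLS]), design)
  })
}

#' Simulate a SWATH fragment x run intensity table
#'
#' Intensity of fragment f in run r:
#' \deqn{I_{fr} = s_r \cdot A_p \cdot 2^{L_p [c(r) \ne ref]} \cdot q \cdot w_f
#'   \cdot e^{\epsilon_{bio}} e^{\epsilon_{dig}} e^{\epsilon_{inj}}
#'   \; (+\; s_r t_{f,c(r)})}
#' with per-run scale s, protein base abundance A, true log2 fold change L,
#' peptide ionization factor q, fragment share w, centered normal noise
#' scaled to the configured CVs, and additive interference trend t for
#' flagged fragments. Values below the LOD are censored to NA.
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param design run design data.frame (see \code{\link{defaultRunDesign}});
#'   must contain at least two sample types.
#' @param noise A \code{\link{noiseModel}}.
#' @param seed RNG seed for the noise draws.
#' @return A \linkS4class{FragmentExperiment}.
#' @export
simulateFragmentTable <- function(truth, design = defaultRunDesign(),
                                  noise = noiseModel(), seed = 1) {
  .simulate_intensities(truth, design, noise, seed)
}

#' Simulate an MRM peak-area table
#'
#' The targeted branch measures at most 3 best-flyer peptides per protein
#' (those with the highest ionization factors) and the 3--4 most intense
#' transitions per peptide, with duplicate injections and no digestion
#' replicate level. Transition lists for targeted assays are manually
#' reviewed for interference before export, so the simulated MRM areas carry
#' no interference component.
#'
#' @inheritParams simulateFragmentTable
#' @param design run design; defaults to \code{\link{mrmRunDesign}} on the
#'   truth's sample types.
#' @param peptidesPerProtein requested peptides per protein; capped at 3 with
#'   a warning.
#' @param fragmentsPerPeptide transitions retained per peptide (top shares),
#'   default 4.
#' @param proteins optional character vector restricting the target panel.
#' @export
simulateMrmTable <- function(truth, design = NULL, noise = noiseModel(),
                             peptidesPerProtein = 3, fragmentsPerPeptide = 4,
                             proteins = NULL, seed = 1) {
  if (peptidesPerProtein > 3) {
    warning("no more than 3 best-flyer peptides per protein are retained; ",
            "capping at 3")
    peptidesPerProtein <- 3
  }
  if (is.null(design)) design <- mrmRunDesign(truth@sampleTypes)
  pep <- as.data.frame(truth@peptides)
  if (!is.null(proteins)) pep <- pep[pep$protein_id %in% proteins, ]
  keep <- unlist(lapply(split(seq_len(nrow(pep)), pep$protein_id),
                        function(i) {
    i[order(-pep$ionization_factor[i])][seq_len(min(peptidesPerProtein,
                                                    length(i)))]
  }), use.names = FALSE)
  pep <- pep[sort(keep), ]
  frag <- as.data.frame(truth@fragments)
  frag <- frag[frag$peptide %in% pep$peptide, ]
  fkeep <- unlist(lapply(split(seq_len(nrow(frag)), frag$peptide),
                         function(i) {
    i[order(-frag$share[i])][seq_len(min(fragmentsPerPeptide, length(i)))]
  }), use.names = FALSE)
  frag <- frag[sort(fkeep), ]
  # targeted transition lists are manually reviewed for interference before
  # export, so the MRM table carries none
  frag$interference <- FALSE
  for (cn in grep("^intf_", colnames(frag), value = TRUE)) frag[[cn]] <- 0
  sub <- new("GroundTruth",
             proteins = truth@proteins[
               truth@proteins$protein_id %in% pep$protein_id, ],
             peptides = DataFrame(pep), fragments = DataFrame(frag),
             sampleTypes = truth@sampleTypes)
  .simulate_intensities(sub, design, noise, seed)
}

#' Simulate a transcript expression table coupled to the protein truth
#'
#' Gene log2 fold changes are generated with a target correlation \code{rho}
#' to the standardized protein truth and rescaled to the truth's spread;
#' genes exceeding the stringent |log2 FC| > 2 rule receive a small FDR
#' (< 0.05), all others FDR ~ Uniform(0.05, 1).
#'
#' @param truth A \linkS4class{GroundTruth}; gene ids equal protein ids.
#' @param rho target protein--transcript fold-change correlation in [-1, 1].
#' @param nExtraGenes genes without a protein partner to append.
#' @param nullSd log2 FC spread used when the truth is all-null (and for the
#'   extra genes); default 0.3.
#' @param seed RNG seed.
#' @return data.frame with \code{gene_id}, per-sample \code{fpkm_*} columns,
#'   \code{log2_fc}, \code{fdr}.
#' @export
simulateTranscripts <- function(truth, rho = 0, nExtraGenes = 0,
                                nullSd = 0.3, seed = 1) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  .with_seed(seed, {
    lt <- truth@proteins$true_log2_fc
    n <- length(lt)
    sdT <- stats::sd(lt)
    z <- if (isTRUE(sdT > 0)) (lt - mean(lt)) / sdT else numeric(n)
    g <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    lfc <- g * if (isTRUE(sdT > 0)) sdT else nullSd
    gene_id <- truth@proteins$protein_id
    if (nExtraGenes > 0) {
      gene_id <- c(gene_id, sprintf("GX%04d", seq_len(nExtraGenes)))
      lfc <- c(lfc, stats::rnorm(nExtraGenes, 0, nullSd))
    }
    m <- length(gene_id)
    fdr <- ifelse(abs(lfc) > 2, stats::runif(m, 1e-4, 0.049),
                  stats::runif(m, 0.05, 1))
    fpkm1 <- stats::rlnorm(m, log(20), 1.5)
    out <- data.frame(gene_id = gene_id, fpkm1 = fpkm1,
                      fpkm2 = fpkm1 * 2^lfc, log2_fc = lfc, fdr = fdr)
    names(out)[2:3] <- paste0("fpkm_", truth@sampleTypes[1:2])
    out
  })
}

#' Generate random protein sequences for the ground-truth proteins
#'
#' Sequences are drawn with lysine/arginine frequencies typical of plant
#' proteomes so in-silico tryptic digestion yields realistic peptide counts.
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param lengthRange protein length range in residues (default 200--600).
#' @param seed RNG seed.
#' @return A \link[Biostrings]{AAStringSet} named by protein id.
#' @export
generateProteinSequences <- function(truth, lengthRange = c(200, 600),
                                     seed = 1) {
  .with_seed(seed, {
    aa <- c(.AA_BODY, "K", "R", "P")
    w <- c(rep(1, length(.AA_BODY)), 1.2, 1.1, 0.9)
    lens <- sample(seq(lengthRange[1], lengthRange[2]),
                   nrow(truth@proteins), replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(aa, L, replace = TRUE, prob = w), collapse = ""),
      character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- truth@proteins$protein_id
    out
  })
}

#' Simulate per-sample observed peptide identifications for emPAI
#'
#' Each observable in-silico peptide of a protein is detected in a sample
#' with probability \code{1 - exp(-fly * abundance / detectScale)}, where
#' \code{fly} is a per-peptide log-normal flyability factor -- detection
#' counts therefore grow with true abundance, which is what the emPAI index
#' inverts.
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param sequences \link[Biostrings]{AAStringSet} of protein sequences.
#' @param mzRange,charges,lengthRange observable-peptide window passed to
#'   \code{\link{observablePeptides}}.
#' @param detectScale abundance giving ~63\% detection at flyability 1
#'   (default 5e4, the median base abundance).
#' @param flySd log-sd of the per-peptide flyability factor (default 0.7).
#' @param seed RNG seed.
#' @return named list (one element per sample type) of data.frames with
#'   columns \code{protein_id}, \code{peptide}.
#' @export
simulatePeptideObservations <- function(truth, sequences,
                                        mzRange = c(300, 1250),
                                        charges = c(2, 3),
                                        lengthRange = c(5, 30),
                                        detectScale = 5e4, flySd = 0.7,
                                        seed = 1) {
  .with_seed(seed, {
    prot <- as.data.frame(truth@proteins)
    obs <- lapply(seq_len(nrow(prot)), function(i) {
      peps <- observablePeptides(as.character(sequences[[prot$protein_id[i]]]),
                                 mzLo = mzRange[1], mzHi = mzRange[2],
                                 charges = charges,
                                 lengthRange = lengthRange)
      if (length(peps) == 0) return(NULL)
      fly <- stats::rlnorm(length(peps), 0, flySd)
      ab <- prot$base_abundance[i] *
        c(1, 2^prot$true_log2_fc[i])
      hit <- lapply(ab, function(a)
        peps[stats::runif(length(peps)) < 1 - exp(-fly * a / detectScale)])
      hit
    })
    out <- lapply(1:2, function(s) {
      rows <- lapply(seq_along(obs), function(i) {
        if (is.null(obs[[i]]) || length(obs[[i]][[s]]) == 0) return(NULL)
        data.frame(protein_id = prot$protein_id[i], peptide = obs[[i]][[s]])
      })
      do.call(rbind, rows)
    })
    names(out) <- truth@sampleTypes[1:2]
    out
  })
}
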