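# Exponentially Modified Protein Abundance Index: emPAI = 10^(N_observed /
# N_observable) - 1, with N_observable counted from an in-silico tryptic
# digest restricted to the precursor m/z window of the acquisition.

# Monoisotopic residue masses (Da); fixed carbamidomethylation on Cys.
.AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919 + 57.02146,
              L = 113.08406, I = 113.08406, N = 114.04293, D = 115.02694,
              Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
              H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333,
              W = 186.07931)
.WATER <- 18.0105646863
.PROTON <- 1.007276466

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P (classic
#' trypsin rule). With \code{missedCleavages > 0} all peptides spanning up to
#' that many internal cleavage sites are also returned. The result is
#' ordered (by position, then span) and duplicate-free; with zero missed
#' cleavages the peptides concatenate back to the input sequence.
#'
#' @param sequence amino-acid string (the 20-letter alphabet; X tolerated,
#'   never treated as a cleavage site).
#' @param missedCleavages maximum internal missed cleavage sites (default 0).
#' @return character vector of peptides.
#' @examples
#' trypticDigest("AAAKBBBRCCC")        # AAAK BBBR CCC
#' trypticDigest("AAKPGG")             # no cleavage before proline
#' trypticDigest("AKRC", missedCleavages = 1)
#' @export
trypticDigest <- function(sequence, missedCleavages = 0) {
  stopifnot(nchar(sequence) > 0, missedCleavages >= 0)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n & aa[pmin(cut + 1, n)] != "P"]
  bounds <- c(0, cut, n)
  starts <- bounds[-length(bounds)] + 1
  ends <- bounds[-1]
  nseg <- length(starts)
  peps <- character(0)
  for (mc in 0:missedCleavages) {
    if (mc + 1 > nseg) break
    for (i in seq_len(nseg - mc)) {
      peps <- c(peps, substr(sequence, starts[i], ends[i + mc]))
    }
  }
  unique(peps)
}

#' Monoisotopic peptide mass
#'
#' @param peptide amino-acid string; unknown residues (e.g. X) give NA.
#' @return neutral monoisotopic mass in Da (fixed carbamidomethyl-Cys).
#' @export
peptideMass <- function(peptide) {
  vapply(strsplit(peptide, ""), function(aa) {
    m <- .AA_MONO[aa]
    if (anyNA(m)) NA_real_ else sum(m) + .WATER
  }, numeric(1))
}

#' Peptide m/z at a given charge
#' @param peptide amino-acid string.
#' @param charge positive integer charge state.
#' @export
peptideMz <- function(peptide, charge) {
  (peptideMass(peptide) + charge * .PROTON) / charge
}

#' Observable in-silico peptides
#'
#' Peptides whose m/z falls inside \code{[mzLo, mzHi]} for at least one
#' allowed charge state and whose length is inside \code{lengthRange}.
#'
#' @param sequence protein sequence (digested internally with
#'   \code{\link{trypticDigest}}) or a character vector of peptides when
#'   \code{digest = FALSE}.
#' @param mzLo,mzHi precursor selection window in Th (defaults 300--1250).
#' @param charges charge states considered observable (default 2 and 3).
#' @param lengthRange peptide length window (default 5--30 residues).
#' @param missedCleavages passed to the digestion (default 0).
#' @param digest set FALSE when \code{sequence} already is a peptide vector.
#' @return character vector of observable peptides.
#' @export
observablePeptides <- function(sequence, mzLo = 300, mzHi = 1250,
                               charges = c(2, 3), lengthRange = c(5, 30),
                               missedCleavages = 0, digest = TRUE) {
  stopifnot(mzLo < mzHi)
  peps <- if (digest) trypticDigest(sequence, missedCleavages) else
    unique(sequence)
  len <- nchar(peps)
  peps <- peps[len >= lengthRange[1] & len <= lengthRange[2]]
  if (length(peps) == 0) return(character(0))
  ok <- Reduce(`|`, lapply(charges, function(z) {
    mz <- peptideMz(peps, z)
    !is.na(mz) & mz >= mzLo & mz <= mzHi
  }))
  peps[ok]
}

#' @rdname observablePeptides
#' @return \code{observableCount}: the number of observable peptides.
#' @export
observableCount <- function(sequence, mzLo = 300, mzHi = 1250,
                            charges = c(2, 3), lengthRange = c(5, 30),
                            missedCleavages = 0, digest = TRUE) {
  length(observablePeptides(sequence, mzLo, mzHi, charges, lengthRange,
                            missedCleavages, digest))
}

#' emPAI from observed/observable counts
#'
#' \code{empai = 10^(nObserved/nObservable) - 1}; zero iff no peptide was
#' observed, strictly increasing in the observed count and strictly
#' decreasing in the observable count (for nObserved > 0).
#'
#' @param nObserved count of distinct identified peptides.
#' @param nObservable count of observable in-silico peptides (>= 1).
#' @export
empaiValue <- function(nObserved, nObservable) {
  stopifnot(all(nObserved >= 0), all(nObservable >= 1))
  10^(nObserved / nObservable) - 1
}

#' emPAI records for a set of proteins in one sample
#'
#' @param sequences \link[Biostrings]{AAStringSet} of protein sequences
#'   (names = protein ids).
#' @param observed data.frame with columns \code{protein_id}, \code{peptide}:
#'   the identified peptides of the sample.
#' @param ... observable-window settings passed to
#'   \code{\link{observablePeptides}}.
#' @return data.frame: \code{protein_id}, \code{n_observed},
#'   \code{n_observable}, \code{pai}, \code{empai}. Proteins with no
#'   observable peptide are dropped (emPAI undefined).
#' @export
empaiTable <- function(sequences, observed, ...) {
  ids <- names(sequences)
  obsable <- lapply(seq_along(sequences), function(i)
    observablePeptides(as.character(sequences[[i]]), ...))
  nObsable <- lengths(obsable)
  obsSplit <- split(observed$peptide, observed$protein_id)
  nObs <- vapply(seq_along(ids), function(i) {
    got <- unique(obsSplit[[ids[i]]])
    sum(got %in% obsable[[i]])
  }, integer(1))
  keep <- nObsable >= 1
  data.frame(protein_id = ids[keep], n_observed = nObs[keep],
             n_observable = nObsable[keep],
             pai = nObs[keep] / nObsable[keep],
             empai = empaiValue(nObs[keep], nObsable[keep]))
}

#' emPAI fold change between two samples
#'
#' log2 ratio of the emPAI values of each protein present in both samples;
#' proteins with emPAI = 0 in either sample are flagged undefined.
#'
#' @param recA,recB \code{\link{empaiTable}} outputs for the two samples
#'   (A relative to B).
#' @return data.frame: \code{protein_id}, \code{empai_a}, \code{empai_b},
#'   \code{log2_fc} (NA when undefined), \code{defined}.
#' @export
empaiFoldChange <- function(recA, recB) {
  shared <- intersect(recA$protein_id, recB$protein_id)
  a <- recA$empai[match(shared, recA$protein_id)]
  b <- recB$empai[match(shared, recB$protein_id)]
  defined <- a > 0 & b > 0
  data.frame(protein_id = shared, empai_a = a, empai_b = b,
             log2_fc = ifelse(defined, log2(a / b), NA_real_),
             defined = defined)
}
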