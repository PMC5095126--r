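#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
NULL

#' IonLibrary: a protein -> peptide -> fragment transition hierarchy
#'
#' Holds one row per transition (fragment ion of one peptide charge state)
#' together with precursor/fragment coordinates and the identification-level
#' annotations (shared/modified flags, peptide confidence) used for library
#' filtering.
#'
#' @slot entries A \link[S4Vectors]{DataFrame} with columns \code{protein_id},
#'   \code{peptide}, \code{charge}, \code{fragment_id}, \code{precursor_mz},
#'   \code{fragment_mz}, \code{shared}, \code{modified}, \code{confidence}.
#'
#' @details Invariants enforced by the validity method: every
#'   (peptide, charge, fragment_id) triple is unique, all m/z values are
#'   strictly positive, and each peptide sequence maps to exactly one protein
#'   (shared peptides must have been excluded or are an error).
#'
#' @export
setClass("IonLibrary", slots = c(entries = "DataFrame"))

.IONLIB_COLS <- c("protein_id", "peptide", "charge", "fragment_id",
                  "precursor_mz", "fragment_mz", "shared", "modified",
                  "confidence")

setValidity("IonLibrary", function(object) {
  e <- object@entries
  missing <- setdiff(.IONLIB_COLS, colnames(e))
  if (length(missing) > 0)
    return(sprintf("missing ion library column(s): %s",
                   paste(missing, collapse = ", ")))
  if (nrow(e) == 0)
    return(TRUE)
  key <- paste(e$peptide, e$charge, e$fragment_id, sep = "\r")
  if (anyDuplicated(key))
    return("duplicated (peptide, charge, fragment_id) triple")
  if (any(e$precursor_mz <= 0) || any(e$fragment_mz <= 0))
    return("precursor_mz and fragment_mz must be strictly positive")
  if (!all(e$charge %in% 2:5))
    return("precursor charge must be in 2..5")
  nprot <- vapply(split(e$protein_id, e$peptide),
                  function(p) length(unique(p)), integer(1))
  if (any(nprot > 1))
    return(sprintf("peptide(s) assigned to more than one protein: %s",
                   paste(head(names(nprot)[nprot > 1], 3), collapse = ", ")))
  TRUE
})

#' Construct an IonLibrary
#'
#' @param entries data.frame or DataFrame with the ion library columns
#'   (see \linkS4class{IonLibrary}).
#' @return An \linkS4class{IonLibrary}.
#' @examples
#' lib <- IonLibrary(data.frame(
#'   protein_id = "P1", peptide = "ELVISK", charge = 2,
#'   fragment_id = c("y3", "y4", "y5"),
#'   precursor_mz = 350.7, fragment_mz = c(347.2, 448.3, 561.4),
#'   shared = FALSE, modified = FALSE, confidence = 99))
#' lib
#' @export
IonLibrary <- function(entries) {
  new("IonLibrary", entries = DataFrame(entries))
}

#' @describeIn IonLibrary-class Accessor for the transition table.
#' @param x An IonLibrary.
#' @export
ionEntries <- function(x) x@entries

#' @describeIn IonLibrary-class Number of transitions in the library.
#' @aliases length,IonLibrary-method
#' @export
setMethod("length", "IonLibrary", function(x) nrow(x@entries))

setMethod("show", "IonLibrary", function(object) {
  e <- object@entries
  cat(sprintf("IonLibrary: %d transitions, %d peptides, %d proteins\n",
              nrow(e), length(unique(e$peptide)),
              length(unique(e$protein_id))))
})

#' FragmentExperiment: fragment x run intensities with a replicate design
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose single assay
#' \code{"intensity"} holds non-negative fragment-level extracted-ion
#' chromatogram intensities (NA = missing/censored). \code{rowData} carries
#' the fragment key columns \code{protein_id}, \code{peptide}, \code{charge},
#' \code{fragment_id}; \code{colData} carries the run design:
#' \code{sample_type} plus whichever of \code{bio_rep}, \code{dig_rep},
#' \code{inj_rep} have not yet been collapsed by averaging.
#'
#' @export
setClass("FragmentExperiment", contains = "SummarizedExperiment")

.KEY_COLS <- c("protein_id", "peptide", "charge", "fragment_id")

setValidity("FragmentExperiment", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  missing <- setdiff(.KEY_COLS, colnames(rowData(object)))
  if (length(missing) > 0)
    return(sprintf("missing rowData column(s): %s",
                   paste(missing, collapse = ", ")))
  if (!"sample_type" %in% colnames(colData(object)))
    return("colData must contain 'sample_type'")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("run ids (colnames) must be present and unique")
  x <- assay(object, "intensity")
  if (any(x < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  TRUE
})

#' Construct a FragmentExperiment
#'
#' @param intensity numeric matrix, fragments x runs; NA marks missing values.
#' @param fragments data.frame/DataFrame with one row per fragment and columns
#'   \code{protein_id}, \code{peptide}, \code{charge}, \code{fragment_id}.
#' @param design data.frame/DataFrame with one row per run: \code{run_id},
#'   \code{sample_type} and optionally \code{bio_rep}, \code{dig_rep},
#'   \code{inj_rep}.
#' @return A \linkS4class{FragmentExperiment}.
#' @export
FragmentExperiment <- function(intensity, fragments, design) {
  fragments <- DataFrame(fragments)
  design <- DataFrame(design)
  if (!"run_id" %in% colnames(design))
    stop("design must contain a 'run_id' column")
  if (anyDuplicated(design$run_id))
    stop("design run_ids must be unique")
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity)))
    colnames(intensity) <- design$run_id
  if (!setequal(colnames(intensity), design$run_id))
    stop("design mismatch: intensity columns do not equal design run_ids")
  design <- design[match(colnames(intensity), design$run_id), , drop = FALSE]
  rownames(design) <- design$run_id
  rownames(intensity) <- fragmentKeyString(fragments)
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = fragments, colData = design)
  new("FragmentExperiment", se)
}

#' Canonical string form of fragment keys
#'
#' @param fragments DataFrame/data.frame with the four fragment key columns.
#' @return character vector \code{protein|peptide|charge|fragment}.
#' @export
fragmentKeyString <- function(fragments) {
  paste(fragments$protein_id, fragments$peptide, fragments$charge,
        fragments$fragment_id, sep = "|")
}

#' @describeIn FragmentExperiment-class Run design (colData) as a data.frame.
#' @param x A FragmentExperiment.
#' @export
runDesign <- function(x) as.data.frame(colData(x))

#' @describeIn FragmentExperiment-class Fragment keys (rowData) as a
#'   data.frame.
#' @export
fragmentKeys <- function(x) as.data.frame(rowData(x))

#' @describeIn FragmentExperiment-class Intensity assay matrix.
#' @export
intensities <- function(x) assay(x, "intensity")

setMethod("show", "FragmentExperiment", function(object) {
  fk <- rowData(object)
  cat(sprintf(
    "FragmentExperiment: %d fragments (%d peptides, %d proteins) x %d runs\n",
    nrow(object), length(unique(fk$peptide)),
    length(unique(fk$protein_id)), ncol(object)))
  cat("sample types:",
      paste(unique(colData(object)$sample_type), collapse = ", "), "\n")
  lv <- intersect(c("bio_rep", "dig_rep", "inj_rep"),
                  colnames(colData(object)))
  cat("replicate levels present:",
      if (length(lv)) paste(lv, collapse = ", ") else "(collapsed)", "\n")
})

# Levels of the replicate hierarchy, outermost first.
.LEVELS <- c(biological = "bio_rep", digestion = "dig_rep",
             injection = "inj_rep")
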