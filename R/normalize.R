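# Hierarchical scaling-normalization/averaging cascade: injection ->
# digestion -> within sample type, followed by cross-sample scale
# normalization between sample types. "Scaling normalization" equalizes each
# run's median (or mean) log intensity over the rows shared by the group;
# averaging collapses a replicate level by the mean of log intensities.

.log_center <- function(v, center) {
  if (center == "median") stats::median(v) else mean(v)
}

#' Scale-normalize a group of runs
#'
#' Each run in the group is multiplied by a positive factor equalizing its
#' median (default) log intensity over the rows complete in all group runs to
#' the group mean of those centers; the factors' geometric mean is 1 by
#' construction.
#'
#' @param fe A \linkS4class{FragmentExperiment}.
#' @param runs run ids forming the group (default: all runs).
#' @param center \code{"median"} (default) or \code{"mean"}.
#' @param minSharedRows refuse to normalize on fewer shared rows (default 10).
#' @return list with \code{fe} (normalized) and \code{factors} (named).
#' @export
scaleNormalize <- function(fe, runs = colnames(fe), center = "median",
                           minSharedRows = 10) {
  center <- match.arg(center, c("median", "mean"))
  if (length(runs) < 2) {
    warning("scale normalization needs >= 2 runs; returning input unchanged")
    f <- rep(1, length(runs)); names(f) <- runs
    return(list(fe = fe, factors = f))
  }
  x <- intensities(fe)[, runs, drop = FALSE]
  shared <- rowSums(is.na(x)) == 0
  if (sum(shared) == 0)
    stop("normalization error: no rows shared by all runs in the group")
  if (sum(shared) < minSharedRows)
    stop(sprintf("normalization error: only %d shared rows (< %d required)",
                 sum(shared), minSharedRows))
  centers <- apply(log(x[shared, , drop = FALSE]), 2, .log_center,
                   center = center)
  f <- exp(mean(centers) - centers)
  y <- intensities(fe)
  y[, runs] <- sweep(x, 2, f, `*`)
  assay(fe, "intensity") <- y
  list(fe = fe, factors = f)
}

#' Collapse one replicate level by log-mean averaging
#'
#' Runs identical in every design column except the named level are averaged
#' (mean of log intensities; missing values ignored; the averaged cell is
#' missing only when all replicates are missing). The level column is removed
#' from the design.
#'
#' @param fe A \linkS4class{FragmentExperiment}.
#' @param level one of \code{"injection"}, \code{"digestion"},
#'   \code{"biological"}.
#' @return A \linkS4class{FragmentExperiment} with one run per replicate
#'   group.
#' @export
averageLevel <- function(fe, level = c("injection", "digestion",
                                       "biological")) {
  if (!level[1] %in% names(.LEVELS))
    stop(sprintf("unknown level '%s'", level[1]))
  level <- match.arg(level)
  col <- .LEVELS[[level]]
  cd <- runDesign(fe)
  if (!col %in% colnames(cd))
    stop(sprintf("level '%s' (%s) absent from the design", level, col))
  groupCols <- setdiff(colnames(cd), c("run_id", col))
  g <- do.call(paste, c(cd[groupCols], sep = "\r"))
  ug <- unique(g)
  lx <- log(intensities(fe))
  m <- vapply(ug, function(gr)
    rowMeans(lx[, g == gr, drop = FALSE], na.rm = TRUE),
    numeric(nrow(fe)))
  m <- matrix(m, nrow = nrow(fe))
  m[is.nan(m)] <- NA
  newcd <- cd[match(ug, g), groupCols, drop = FALSE]
  idcols <- intersect(c("sample_type", "bio_rep", "dig_rep"),
                      colnames(newcd))
  newcd$run_id <- apply(newcd[idcols], 1, paste, collapse = "_")
  colnames(m) <- newcd$run_id
  FragmentExperiment(exp(m), fragmentKeys(fe), newcd)
}

#' Cross-sample scale normalization between sample types
#'
#' Under the assumption that most proteins do not change between any pair of
#' samples, the scale shift between two samples is the median of the
#' per-row log differences (the robust L1 minimizer of the average absolute
#' between-sample difference). With more than two samples the shifts are
#' solved against the first sample as reference and re-centered so the
#' factors' geometric mean is 1.
#'
#' @param x numeric matrix of linear-scale abundances (rows = proteins or
#'   fragments, columns = samples), or a \linkS4class{FragmentExperiment}.
#' @param minShared minimum rows shared by a sample pair (default 10).
#' @return list with \code{x} (normalized, same class as input) and
#'   \code{factors}.
#' @export
crossSampleNormalize <- function(x, minShared = 10) {
  fe <- NULL
  if (is(x, "FragmentExperiment")) { fe <- x; x <- intensities(fe) }
  n <- ncol(x)
  if (n == 1) {
    f <- c(1); names(f) <- colnames(x)
    out <- if (is.null(fe)) x else fe
    return(list(x = out, factors = f))
  }
  lx <- log(x)
  shifts <- c(0, vapply(2:n, function(j) {
    d <- lx[, 1] - lx[, j]
    d <- d[!is.na(d)]
    if (length(d) < minShared)
      stop(sprintf(
        "insufficient overlap: %d shared rows between samples 1 and %d",
        length(d), j))
    stats::median(d)
  }, numeric(1)))
  shifts <- shifts - mean(shifts)
  f <- exp(shifts)
  names(f) <- colnames(x)
  y <- sweep(x, 2, f, `*`)
  if (is.null(fe)) return(list(x = y, factors = f))
  assay(fe, "intensity") <- y
  list(x = fe, factors = f)
}

#' Run the full normalization/averaging cascade
#'
#' Executes scale-normalization + averaging over whichever replicate levels
#' the design still contains, innermost first: injections within each
#' digestion sample, digestion repeats within each biological sample, then
#' biological replicates within sample type. The biological-replicate-
#' resolved table is preserved (after within-type normalization) so
#' downstream statistics keep their n; the sample-type average is computed
#' alongside. Finally the sample types are cross scale-normalized and the
#' same per-type factors are applied to the replicate-resolved table.
#'
#' @param fe A \linkS4class{FragmentExperiment} (normally reliable-filtered).
#' @param center,minSharedRows passed to \code{\link{scaleNormalize}}.
#' @param minSharedCross passed to \code{\link{crossSampleNormalize}}.
#' @param levels replicate levels the cascade should process; a requested
#'   level absent from the design is skipped with a warning.
#' @return list with \code{bioRep} (per biological replicate),
#'   \code{sampleType} (per sample type), and \code{report} (data.frame of
#'   per-run scale factors per stage).
#' @export
runCascade <- function(fe, center = "median", minSharedRows = 10,
                       minSharedCross = 10,
                       levels = c("injection", "digestion", "biological")) {
  report <- list()
  log_factors <- function(stage, f) {
    report[[length(report) + 1]] <<- data.frame(
      stage = stage, run_id = names(f), factor = unname(f))
  }
  normalize_level <- function(fe, levelName) {
    cd <- runDesign(fe)
    col <- .LEVELS[[levelName]]
    groupCols <- setdiff(intersect(colnames(cd),
                                   c("sample_type", .LEVELS)),
                         col)
    g <- do.call(paste, c(cd[groupCols], sep = "\r"))
    for (gr in unique(g)) {
      runs <- cd$run_id[g == gr]
      if (length(runs) < 2) next
      res <- scaleNormalize(fe, runs, center = center,
                            minSharedRows = minSharedRows)
      fe <- res$fe
      log_factors(switch(levelName, injection = "injection",
                         digestion = "digestion",
                         biological = "within_sample_type"),
                  res$factors)
    }
    averageLevel(fe, levelName)
  }

  for (lv in levels) {
    if (!.LEVELS[[lv]] %in% colnames(colData(fe))) {
      warning(sprintf("design lacks the %s level; stage skipped", lv))
      next
    }
    if (lv == "biological") {
      # normalize across bio reps within each sample type, keep bio
      # resolution, then average separately
      cd <- runDesign(fe)
      for (s in unique(cd$sample_type)) {
        runs <- cd$run_id[cd$sample_type == s]
        if (length(runs) < 2) next
        res <- scaleNormalize(fe, runs, center = center,
                              minSharedRows = minSharedRows)
        fe <- res$fe
        log_factors("within_sample_type", res$factors)
      }
      bioRep <- fe
      fe <- averageLevel(fe, "biological")
    } else {
      fe <- normalize_level(fe, lv)
    }
  }
  if (!exists("bioRep", inherits = FALSE)) bioRep <- fe

  cs <- crossSampleNormalize(fe, minShared = minSharedCross)
  fe <- cs$x
  log_factors("cross_sample", cs$factors)
  # propagate the per-type factors to the replicate-resolved table
  cdB <- runDesign(bioRep)
  fB <- cs$factors[cdB$sample_type]
  yB <- sweep(intensities(bioRep), 2, fB, `*`)
  assay(bioRep, "intensity") <- yB

  list(bioRep = bioRep, sampleType = fe,
       report = do.call(rbind, report))
}
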