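# Selection of quantifiable ("reliable") fragments. A fragment is a valid
# quantification channel when its intensity stays proportional to the peptide
# precursor across samples; fragments carrying interference break that
# proportionality. Trend consistency is measured with the normalized spectral
# contrast angle and fragments are grouped by a greedy agglomerative cluster
# search; only the dominant consistent cluster of >= minTrend fragments is
# retained per peptide.

#' Normalized spectral contrast angle similarity
#'
#' \code{SA(a, b) = 1 - 2*theta/pi} with \code{theta = arccos(a.b/(|a||b|))}.
#' Equals 1 iff the vectors are positive scalar multiples of each other
#' (perfectly proportional trends) and 0 when they are orthogonal; invariant
#' to positive rescaling of either argument.
#'
#' @param a,b non-negative numeric vectors of equal length >= 2.
#' @return similarity in [0, 1].
#' @examples
#' spectralAngle(c(1, 2, 3), c(2, 4, 6))  # 1
#' spectralAngle(c(1, 0), c(0, 1))        # 0
#' spectralAngle(c(1, 1), c(1, 0))        # 0.5
#' @export
spectralAngle <- function(a, b) {
  if (length(a) != length(b))
    stop("spectral angle: vectors differ in length")
  if (length(a) < 2)
    stop("spectral angle: vectors must have length >= 2")
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("spectral angle: vectors must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("spectral angle undefined for an all-zero vector")
  cosv <- min(1, max(-1, sum(a * b) / (na * nb)))
  1 - 2 * acos(cosv) / pi
}

# Pairwise SA matrix of the columns of a non-negative matrix.
.sa_matrix <- function(m) {
  cn <- sqrt(colSums(m^2))
  cosm <- crossprod(m) / outer(cn, cn)
  cosm[cosm > 1] <- 1; cosm[cosm < -1] <- -1
  1 - 2 * acos(cosm) / pi
}

#' Condition-level trend vectors of fragments
#'
#' For each fragment, the vector of linear-scale mean intensities per sample
#' type (averaging over all replicate runs of the type, missing values
#' ignored), in the order of \code{unique(sample_type)} of the design. A
#' fragment whose mean is missing in any sample type is flagged incomplete
#' and excluded from clustering.
#'
#' @param fe A \linkS4class{FragmentExperiment}.
#' @return list with \code{trends} (fragments x sample types matrix) and
#'   \code{incomplete} (logical per fragment).
#' @export
fragmentTrends <- function(fe) {
  types <- unique(colData(fe)$sample_type)
  x <- intensities(fe)
  tr <- vapply(types, function(s)
    rowMeans(x[, colData(fe)$sample_type == s, drop = FALSE], na.rm = TRUE),
    numeric(nrow(x)))
  tr <- matrix(tr, nrow = nrow(x),
               dimnames = list(rownames(x), types))
  tr[is.nan(tr)] <- NA
  list(trends = tr, incomplete = apply(tr, 1, anyNA))
}

#' Greedy iterative search of trend-consistent fragment clusters
#'
#' Clusters are grown greedily: seed with the most similar remaining pair if
#' its SA >= \code{tau}; repeatedly add the fragment whose minimum SA to all
#' current members is largest, while that minimum stays >= \code{tau}; close
#' the cluster, remove its members, and repeat. Every cluster is therefore
#' pairwise tau-consistent. Clusters with >= \code{minTrend} members are
#' "reliable"; the reliable fragment set is the largest reliable cluster
#' (ties broken by higher total intensity, then by fragment order).
#'
#' @param trends matrix of non-negative trend vectors, one row per fragment
#'   (rownames = fragment keys), or a named list of vectors.
#' @param tau similarity threshold in (0, 1); default 0.95.
#' @param minTrend minimum cluster size to count as reliable; default 3.
#' @param totalIntensity optional named numeric used for tie-breaking.
#' @return list with \code{clusters} (list of character vectors),
#'   \code{similarity} (SA matrix) and \code{reliable} (character vector).
#' @export
findClusters <- function(trends, tau = 0.95, minTrend = 3,
                         totalIntensity = NULL) {
  if (is.list(trends)) trends <- do.call(rbind, trends)
  stopifnot(tau > 0, tau < 1, minTrend >= 2)
  ids <- rownames(trends)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(trends)))
  n <- nrow(trends)
  if (n == 0)
    return(list(clusters = list(), similarity = matrix(0, 0, 0),
                reliable = character(0)))
  sa <- .sa_matrix(t(trends))
  dimnames(sa) <- list(ids, ids)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) >= 2) {
    sub <- sa[remaining, remaining, drop = FALSE]
    diag(sub) <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    if (sub[best[1], best[2]] < tau) break
    members <- remaining[c(best[1], best[2])]
    cand <- setdiff(remaining, members)
    while (length(cand) > 0) {
      minsim <- vapply(cand, function(c)
        min(sa[c, members]), numeric(1))
      top <- which.max(minsim)
      if (minsim[top] < tau) break
      members <- c(members, cand[top])
      cand <- cand[-top]
    }
    clusters[[length(clusters) + 1]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  clusters <- c(clusters, as.list(remaining))
  reliable_cl <- clusters[lengths(clusters) >= minTrend]
  reliable <- integer(0)
  if (length(reliable_cl) > 0) {
    sz <- lengths(reliable_cl)
    top <- which(sz == max(sz))
    if (length(top) > 1 && !is.null(totalIntensity)) {
      tot <- vapply(reliable_cl[top], function(m)
        sum(totalIntensity[ids[m]], na.rm = TRUE), numeric(1))
      top <- top[which.max(tot)]
    }
    reliable <- reliable_cl[[top[1]]]
  }
  list(clusters = lapply(clusters, function(m) ids[m]),
       similarity = sa, reliable = ids[reliable])
}

#' Filter a fragment table down to reliable fragments
#'
#' Applies, in order: (i) pre-exclusion of peptides with fewer than
#' \code{minFragments} quantified fragments and proteins with fewer than
#' \code{minPeptides} quantified peptides (a fragment counts as quantified
#' when present in at least half of the runs); (ii) per-peptide spectral
#' contrast angle clustering, keeping only the dominant reliable cluster;
#' (iii) exclusion of peptides left with fewer than \code{minFragments}
#' reliable fragments; (iv) exclusion of proteins left with fewer than
#' \code{minPeptides} peptides. The input is expected to be injection
#' normalized/averaged (stage 1 of the cascade).
#'
#' @param fe A \linkS4class{FragmentExperiment}.
#' @param library optional \linkS4class{IonLibrary}; if given, every fragment
#'   key must resolve in it.
#' @param tau spectral contrast angle threshold (default 0.95).
#' @param minTrend minimum fragments following a common trend (default 3).
#' @param minFragments minimum quantified/reliable fragments per peptide
#'   (default 3).
#' @param minPeptides minimum peptides per protein (default 3).
#' @return The filtered \linkS4class{FragmentExperiment}; the per-entity
#'   rejection log is stored in \code{metadata(fe)$rejections} (data.frame
#'   with columns entity, level, stage, reason).
#' @export
filterReliable <- function(fe, library = NULL, tau = 0.95, minTrend = 3,
                           minFragments = 3, minPeptides = 3) {
  fk <- fragmentKeys(fe)
  if (!is.null(library)) {
    libkey <- fragmentKeyString(as.data.frame(ionEntries(library)))
    bad <- !(fragmentKeyString(fk) %in% libkey)
    if (any(bad))
      stop(sprintf("key error: %d fragment(s) not present in the ion library",
                   sum(bad)))
  }
  x <- intensities(fe)
  rej <- list()
  note <- function(entity, level, stage, reason) {
    rej[[length(rej) + 1]] <<- data.frame(entity = entity, level = level,
                                          stage = stage, reason = reason)
  }

  # (i) pre-exclusion on quantified counts
  quantified <- rowMeans(!is.na(x)) >= 0.5
  pepOf <- fk$peptide
  qfrag <- tapply(quantified, pepOf, sum)
  badPep <- names(qfrag)[qfrag < minFragments]
  if (length(badPep))
    note(badPep, "peptide", "pre-exclusion",
         sprintf("<%d quantified fragments", minFragments))
  keep <- !(pepOf %in% badPep)
  qpep <- tapply(fk$peptide[keep], fk$protein_id[keep],
                 function(p) length(unique(p)))
  allProt <- unique(fk$protein_id)
  badProt <- union(setdiff(allProt, names(qpep)),
                   names(qpep)[qpep < minPeptides])
  if (length(badProt))
    note(badProt, "protein", "pre-exclusion",
         sprintf("<%d quantified peptides", minPeptides))
  keep <- keep & !(fk$protein_id %in% badProt)
  if (!any(keep)) {
    out <- fe[keep, ]
    metadata(out)$rejections <- do.call(rbind, rej)
    return(out)
  }

  # (ii) per-peptide clustering on condition-level trends
  tr <- fragmentTrends(fe)
  total <- rowSums(x, na.rm = TRUE)
  names(total) <- rownames(x)
  keyAll <- rownames(x)
  reliableKeys <- character(0)
  for (p in unique(pepOf[keep])) {
    idx <- which(keep & pepOf == p)
    complete <- idx[!tr$incomplete[idx]]
    if (length(complete) < length(idx)) {
      inc <- keyAll[setdiff(idx, complete)]
      note(inc, "fragment", "clustering", "incomplete condition-level trend")
    }
    if (length(complete) < minTrend) {
      note(p, "peptide", "clustering",
           sprintf("<%d complete fragments for clustering", minTrend))
      next
    }
    cl <- findClusters(tr$trends[complete, , drop = FALSE], tau = tau,
                       minTrend = minTrend,
                       totalIntensity = total[keyAll[complete]])
    rel <- cl$reliable
    if (length(rel) > 0) {
      reliableKeys <- c(reliableKeys, rel)
      drop <- setdiff(keyAll[complete], rel)
      if (length(drop))
        note(drop, "fragment", "clustering", "outside the reliable cluster")
    } else {
      note(p, "peptide", "clustering", "no reliable cluster")
    }
  }
  keep2 <- keyAll %in% reliableKeys

  # (iii)/(iv) post-clustering minimum counts
  nrel <- tapply(keep2, pepOf, sum)
  badPep2 <- names(nrel)[nrel > 0 & nrel < minFragments]
  if (length(badPep2))
    note(badPep2, "peptide", "post-filter",
         sprintf("<%d reliable fragments", minFragments))
  keep2 <- keep2 & !(pepOf %in% badPep2)
  npep <- tapply(pepOf[keep2], fk$protein_id[keep2],
                 function(p) length(unique(p)))
  badProt2 <- names(npep)[npep < minPeptides]
  if (length(badProt2))
    note(badProt2, "protein", "post-filter",
         sprintf("fewer than %d peptides", minPeptides))
  keep2 <- keep2 & !(fk$protein_id %in% badProt2)

  out <- fe[keep2, ]
  metadata(out)$rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(entity = character(0), level = character(0),
               stage = character(0), reason = character(0))
  out
}

#' Exhaustive maximum tau-consistent subset (reference oracle)
#'
#' Finds a maximum-size subset of fragments whose pairwise spectral contrast
#' angles are all >= tau, by exhaustive enumeration. Exponential in the
#' number of fragments; intended for validating the greedy search on small
#' instances.
#'
#' @inheritParams findClusters
#' @return character vector of fragment keys (one maximum subset).
#' @export
maxConsistentSubset <- function(trends, tau = 0.95) {
  if (is.list(trends)) trends <- do.call(rbind, trends)
  n <- nrow(trends)
  stopifnot(n <= 16)
  ids <- rownames(trends)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sa <- .sa_matrix(t(trends))
  best <- integer(0)
  for (code in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (length(members) <= length(best)) next
    sub <- sa[members, members, drop = FALSE]
    if (all(sub[upper.tri(sub)] >= tau)) best <- members
  }
  ids[best]
}
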