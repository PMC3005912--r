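#' Binary functional-signature vectors for a group's isoforms
#'
#' The signature universe is the sorted union of all signature accessions
#' matched by any isoform of the group; each isoform gets a 0/1 vector over
#' that universe (1 = the signature matched it).  Isoforms with no
#' assignments get all-zero vectors.
#'
#' @param group an [OrthologueGroup-class] (or a character vector of isoform
#'   ids).
#' @param assignments a data.frame with columns `isoform_id` and
#'   `signature_accession` (as returned by [readInterproscanTsv()]).
#' @return a binary integer matrix; rows are isoforms, columns the sorted
#'   signature universe.  Zero columns when no group isoform has any
#'   assignment.
#' @examples
#' sv <- buildSignatureVectors(c("p1", "p2"),
#'   data.frame(isoform_id = c("p1", "p1", "p2"),
#'              signature_accession = c("S1", "S2", "S1")))
#' diffFunc(sv["p1", ], sv["p2", ])
#' @export
buildSignatureVectors <- function(group, assignments) {
  ids <- if (is(group, "OrthologueGroup")) isoformIds(group)
         else as.character(group)
  hits <- assignments[assignments$isoform_id %in% ids, , drop = FALSE]
  universe <- sort(unique(hits$signature_accession))
  m <- matrix(0L, nrow = length(ids), ncol = length(universe),
              dimnames = list(ids, universe))
  if (nrow(hits) > 0L)
    m[cbind(match(hits$isoform_id, ids),
            match(hits$signature_accession, universe))] <- 1L
  m
}

#' Functional difference: Hamming distance of two signature vectors
#'
#' The count of signatures at which the two isoforms differ.  Both vectors
#' must be defined over the same signature universe (same names in the same
#' order).
#'
#' @param v1,v2 binary vectors named by signature accession (rows of a
#'   [buildSignatureVectors()] matrix).
#' @return a non-negative integer.
#' @export
diffFunc <- function(v1, v2) {
  if (length(v1) != length(v2) || !identical(names(v1), names(v2)))
    stop("signature vectors are defined over different universes")
  sum(v1 != v2)
}

#' Intra- and inter-sub-cluster averages of a pairwise difference measure
#'
#' For every unordered isoform pair of the group the difference is computed;
#' pairs sharing a sub-cluster contribute to the intra mean, pairs in
#' different sub-clusters to the inter mean.  Intra pairs include
#' cross-species pairs within a cluster.  A mean is `NA` exactly when its
#' pair count is zero (e.g. the intra mean of an all-singleton clustering).
#'
#' @param clustering a [GroupClustering-class].
#' @param pairDiff a function `(id1, id2) -> numeric` giving the pairwise
#'   difference (e.g. a closure over [diffFunc()] vectors or
#'   [diffDis()] profiles).
#' @param measure `"func"` or `"dis"`, recorded in the summary.
#' @param skipIfAllEqual when TRUE and every pairwise difference in the
#'   group is zero, the summary is flagged `excluded` — the "no differences
#'   found" filter applied before distribution comparisons.
#' @return a [GroupDiffSummary-class].
#' @export
groupDiffSummary <- function(clustering, pairDiff, measure = "func",
                             skipIfAllEqual = FALSE) {
  ids <- clustering@isoformIds
  assign <- clusterAssignments(clustering)
  intra <- numeric()
  inter <- numeric()
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- pairDiff(ids[i], ids[j])
        if (assign[[ids[i]]] == assign[[ids[j]]]) intra <- c(intra, d)
        else inter <- c(inter, d)
      }
    }
  }
  excluded <- skipIfAllEqual && all(c(intra, inter) == 0)
  new("GroupDiffSummary", groupId = clustering@groupId,
      measure = measure,
      intraMean = if (length(intra)) mean(intra) else NA_real_,
      interMean = if (length(inter)) mean(inter) else NA_real_,
      nIntraPairs = length(intra), nInterPairs = length(inter),
      excluded = excluded)
}
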