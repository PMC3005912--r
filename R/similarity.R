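#' Project a multiple alignment onto one isoform pair
#'
#' Restricts the group alignment to two rows and removes every column in
#' which both rows carry a gap.  Columns gapped in both rows belong to exons
#' present in neither isoform and carry no information about the pair; if
#' kept they would make two identical isoforms score below 1.
#'
#' @param msa an [IsoformAlignment-class].
#' @param id1,id2 isoform ids present in the alignment.
#' @return a [PairwiseProjection-class].
#' @export
projectPair <- function(msa, id1, id2) {
  rows <- alignedRows(msa)
  unknown <- setdiff(c(id1, id2), names(rows))
  if (length(unknown))
    stop("id(s) not in alignment: ", paste(unknown, collapse = ", "))
  c1 <- strsplit(rows[[id1]], "", fixed = TRUE)[[1]]
  c2 <- strsplit(rows[[id2]], "", fixed = TRUE)[[1]]
  keep <- !(c1 == .GAP & c2 == .GAP)
  new("PairwiseProjection", id1 = id1, id2 = id2,
      row1 = paste(c1[keep], collapse = ""),
      row2 = paste(c2[keep], collapse = ""))
}

#' Common regions of a pairwise projection
#'
#' Maximal runs of projection columns in which both rows carry a residue
#' (no gap in either row), in left-to-right order.
#'
#' @param proj a [PairwiseProjection-class].
#' @return an [IRanges::IRanges] of 1-based inclusive column intervals.
#' @export
commonRegions <- function(proj) {
  c1 <- strsplit(proj@row1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(proj@row2, "", fixed = TRUE)[[1]]
  both <- c1 != .GAP & c2 != .GAP
  if (!any(both)) return(IRanges::IRanges())
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

#' Alignment-projected similarity of two isoforms
#'
#' The score is (number of identity or substitution columns) / (total
#' aligned length including gaps), computed on the pairwise projection of
#' the group alignment.  Identities and substitutions are deliberately not
#' distinguished, so no substitution matrix enters the score: every column
#' in which both rows carry a residue counts, provided it lies in a common
#' region of length at least `minRegionLen` — short common regions are
#' removed to guard against spuriously aligned fragments.
#'
#' @param proj a [PairwiseProjection-class].
#' @param minRegionLen the filter length d; common regions shorter than this
#'   are removed (default 2).
#' @param dFilterMode `"numerator"` (default) removes short-region columns
#'   from the numerator only; `"both"` also removes them from the
#'   denominator.
#' @return a score in \[0, 1\].
#' @export
isoformSimilarity <- function(proj, minRegionLen = 2,
                              dFilterMode = c("numerator", "both")) {
  dFilterMode <- match.arg(dFilterMode)
  len <- projectionLength(proj)
  if (len == 0L) stop("zero-length projection")
  regions <- commonRegions(proj)
  keep <- width(regions) >= minRegionLen
  num <- sum(width(regions)[keep])
  den <- if (dFilterMode == "both") len - sum(width(regions)[!keep]) else len
  if (den == 0L) return(0)
  num / den
}

#' All pairwise similarity scores of a group alignment
#'
#' @param msa an [IsoformAlignment-class] with at least two rows.
#' @param minRegionLen,dFilterMode passed to [isoformSimilarity()].
#' @return a [SimilarityMatrix-class] (symmetric, unit diagonal).
#' @examples
#' aln <- IsoformAlignment(c(p1 = "MKVL--", p2 = "MKVLAE"))
#' simMatrix(similarityMatrix(aln))
#' @export
similarityMatrix <- function(msa, minRegionLen = 2,
                             dFilterMode = c("numerator", "both")) {
  dFilterMode <- match.arg(dFilterMode)
  ids <- names(alignedRows(msa))
  if (length(ids) < 2L) stop("similarityMatrix needs at least two rows")
  m <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      s <- isoformSimilarity(projectPair(msa, ids[i], ids[j]),
                             minRegionLen, dFilterMode)
      m[i, j] <- m[j, i] <- s
    }
  }
  new("SimilarityMatrix", mat = m)
}

#' Write a similarity matrix as a long-format TSV
#'
#' One row per unordered pair: group_id, id1, id2, sim (6 decimal places).
#'
#' @param sim a [SimilarityMatrix-class].
#' @param groupId group identifier written in the first column.
#' @param path output file; append when `con` already has a header.
#' @param append logical; append without header.
#' @export
writeSimilarityTsv <- function(sim, groupId, path, append = FALSE) {
  ids <- rownames(simMatrix(sim))
  rows <- data.frame()
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      rows <- rbind(rows, data.frame(
        group_id = groupId, id1 = ids[i], id2 = ids[j],
        sim = sprintf("%.6f", simMatrix(sim)[i, j])))
    }
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append, append = append)
  invisible(path)
}
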