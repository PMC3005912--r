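#' Convert a per-residue disorder score track to raw regions
#'
#' Maximal runs of positions whose score meets the threshold become 1-based
#' inclusive intervals.  The threshold default 0.5 follows the usual
#' disorder-predictor convention (a residue is called disordered when its
#' score is at least 0.5).
#'
#' @param scores numeric vector of per-residue scores in \[0, 1\], position
#'   1..L.
#' @param threshold minimum score for a disordered call (default 0.5).
#' @return an [IRanges::IRanges] of raw (unfiltered) intervals.
#' @export
scoresToRegions <- function(scores, threshold = 0.5) {
  if (any(is.na(scores)))
    stop("score track contains missing values")
  hit <- scores >= threshold
  if (!any(hit)) return(IRanges::IRanges())
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

#' Merge and length-filter raw disorder regions
#'
#' First, consecutive regions separated by fewer than `mergeGap` residues
#' (i.e. 0, 1 or 2 residues between them at the default of 3) are combined;
#' then merged regions shorter than `minLen` residues (default 10) are
#' dropped.  Merging before filtering means two nearby sub-threshold
#' fragments can survive as one region; the opposite order is available via
#' `mergeFirst = FALSE`.
#'
#' @param raw an [IRanges::IRanges] of sorted, non-overlapping intervals.
#' @param minLen minimum region length kept (default 10).
#' @param mergeGap regions separated by fewer than this many residues are
#'   combined (default 3).
#' @param mergeFirst merge before length-filtering (default TRUE).
#' @return a filtered `IRanges`.
#' @export
filterRegions <- function(raw, minLen = 10, mergeGap = 3, mergeFirst = TRUE) {
  if (length(raw) > 1L) {
    if (is.unsorted(start(raw)))
      stop("regions must be sorted by start")
    if (any(start(raw)[-1] <= end(raw)[-length(raw)]))
      stop("regions must be non-overlapping")
  }
  if (mergeFirst) {
    out <- IRanges::reduce(raw, min.gapwidth = mergeGap)
    out[width(out) >= minLen]
  } else {
    out <- raw[width(raw) >= minLen]
    IRanges::reduce(out, min.gapwidth = mergeGap)
  }
}

#' Build a filtered disorder profile for one isoform
#'
#' Applies [filterRegions()] (or [scoresToRegions()] then [filterRegions()]
#' when given a score track) and wraps the result with the protein length.
#'
#' @param isoformId the isoform.
#' @param regions raw intervals (`IRanges` or a data.frame with
#'   `start`/`end`), mutually exclusive with `scores`.
#' @param scores per-residue score track, alternative to `regions`.
#' @param proteinLen protein length; defaults to `length(scores)` when a
#'   track is given.
#' @param threshold score threshold for [scoresToRegions()].
#' @param minLen,mergeGap,mergeFirst passed to [filterRegions()].
#' @return a [DisorderProfile-class].
#' @export
disorderProfile <- function(isoformId, regions = NULL, scores = NULL,
                            proteinLen = NULL, threshold = 0.5,
                            minLen = 10, mergeGap = 3, mergeFirst = TRUE) {
  if (is.null(regions) == is.null(scores))
    stop("supply exactly one of 'regions' or 'scores'")
  if (!is.null(scores)) {
    if (is.null(proteinLen)) proteinLen <- length(scores)
    regions <- scoresToRegions(scores, threshold)
  } else {
    if (is.data.frame(regions))
      regions <- IRanges::IRanges(start = regions$start, end = regions$end)
    if (is.null(proteinLen))
      stop("proteinLen is required when intervals are supplied")
  }
  if (length(regions) && max(end(regions)) > proteinLen)
    stop("region extends beyond the protein length for ", isoformId)
  new("DisorderProfile", isoformId = as.character(isoformId),
      regions = filterRegions(regions, minLen, mergeGap, mergeFirst),
      proteinLen = as.integer(proteinLen))
}

#' Disorder difference between two isoforms
#'
#' The absolute difference in the number of (filtered) disordered regions.
#'
#' @param p1,p2 [DisorderProfile-class] objects.
#' @return a non-negative integer.
#' @examples
#' p1 <- disorderProfile("a", regions = IRanges::IRanges(1, 20),
#'                       proteinLen = 100)
#' p2 <- disorderProfile("b", regions = IRanges::IRanges(), proteinLen = 80)
#' diffDis(p1, p2)
#' @export
diffDis <- function(p1, p2) {
  abs(nRegions(p1) - nRegions(p2))
}

#' Fraction of a protein predicted disordered
#'
#' Summed region length over protein length.
#'
#' @param p a [DisorderProfile-class].
#' @return a value in \[0, 1\].
#' @export
disorderFraction <- function(p) {
  totalDisorderLength(p) / p@proteinLen
}
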