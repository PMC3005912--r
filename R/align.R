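#' @useDynLib orthoSplice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Alignment parameters
#'
#' Affine gap penalties and the substitution matrix used by the built-in
#' aligner.  A gap run of length k costs `gapOpen + (k - 1) * gapExtend`;
#' terminal gaps are penalised (global alignment).
#'
#' @slot matrixName name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @slot gapOpen penalty for opening a gap (default -10).
#' @slot gapExtend penalty per additional gap position (default -1).
#' @exportClass AlignParams
setClass("AlignParams",
  representation(matrixName = "character", gapOpen = "numeric",
                 gapExtend = "numeric"))

setValidity("AlignParams", function(object) {
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
    "gapOpen <= gapExtend <= 0 is required"
  else TRUE
})

#' @rdname AlignParams-class
#' @param matrixName,gapOpen,gapExtend see slots.
#' @export
alignParams <- function(matrixName = "BLOSUM62", gapOpen = -10,
                        gapExtend = -1) {
  new("AlignParams", matrixName = matrixName, gapOpen = gapOpen,
      gapExtend = gapExtend)
}

# substitution scores extended to the full accepted alphabet plus the gap
# symbol: residues absent from the named matrix (U under BLOSUM62) score 0
# against everything; gap-vs-residue scores gapExtend inside profile columns
# and gap-vs-gap scores 0.
.scoreMatrix <- function(params) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = params@matrixName, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(err) FALSE)
  if (!ok || !is.matrix(e[[params@matrixName]]))
    stop("unknown substitution matrix: ", params@matrixName)
  base <- e[[params@matrixName]]
  sym <- c(.AA_LETTERS, .GAP)
  E <- matrix(0, length(sym), length(sym), dimnames = list(sym, sym))
  common <- intersect(.AA_LETTERS, rownames(base))
  E[common, common] <- base[common, common]
  E[.GAP, .AA_LETTERS] <- params@gapExtend
  E[.AA_LETTERS, .GAP] <- params@gapExtend
  E[.GAP, .GAP] <- 0
  E
}

# per-column symbol counts of a profile (character matrix rows x cols),
# over the alphabet of .scoreMatrix
.profileCounts <- function(prof, sym) {
  t(apply(prof, 2, function(col) tabulate(match(col, sym), length(sym))))
}

# align two profiles (character matrices); returns list(moves, score).
# Column-pair score is the mean over all residue pairs drawn one from each
# column, with gaps scored as gap penalties.
.alignProfiles <- function(profA, profB, params, E) {
  sym <- rownames(E)
  cA <- .profileCounts(profA, sym)
  cB <- .profileCounts(profB, sym)
  S <- (cA %*% E %*% t(cB)) / (nrow(profA) * nrow(profB))
  .nwAffineCpp(S, params@gapOpen, params@gapExtend)
}

# insert gap columns into both profiles according to a move vector
# (1 = both advance, 2 = profile A advances, 3 = profile B advances)
.applyMoves <- function(profA, profB, moves) {
  L <- length(moves)
  outA <- matrix(.GAP, nrow(profA), L)
  outB <- matrix(.GAP, nrow(profB), L)
  outA[, moves != 3L] <- profA
  outB[, moves != 2L] <- profB
  rbind(outA, outB)
}

.seqToProfile <- function(seq) {
  matrix(strsplit(seq, "", fixed = TRUE)[[1]], nrow = 1)
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gap penalties and deterministic traceback
#' (ties resolved diagonal > up > left).  Terminal gaps are penalised.
#'
#' @param seq1,seq2 protein strings (uppercase; the 20 amino acids plus
#'   X/B/Z/U).
#' @param params an [alignParams()] object.
#' @return a list with elements `aligned1`, `aligned2` (gapped strings) and
#'   `score` (the optimal global score).
#' @examples
#' alignPair("MKV", "MV")$score
#' @export
alignPair <- function(seq1, seq2, params = alignParams()) {
  if (!nzchar(seq1) || !nzchar(seq2))
    stop("both sequences must be non-empty")
  bad <- .checkResidues(c(seq1, seq2))
  if (!is.null(bad)) stop(bad)
  E <- .scoreMatrix(params)
  pA <- .seqToProfile(seq1)
  pB <- .seqToProfile(seq2)
  res <- .alignProfiles(pA, pB, params, E)
  merged <- .applyMoves(pA, pB, res$moves)
  list(aligned1 = paste(merged[1, ], collapse = ""),
       aligned2 = paste(merged[2, ], collapse = ""),
       score = res$score)
}

# fraction of alignment columns in which the two rows carry the identical
# residue; distance for the guide tree is 1 minus this
.fractionIdentity <- function(a1, a2) {
  c1 <- strsplit(a1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(a2, "", fixed = TRUE)[[1]]
  sum(c1 == c2 & c1 != .GAP) / length(c1)
}

#' Progressive multiple alignment of a group's isoforms
#'
#' Builds a guide tree by UPGMA (average-linkage `hclust`) on pairwise
#' Needleman-Wunsch distances (1 - fraction identity), then merges profiles
#' leaf-to-root with profile-profile Needleman-Wunsch in which a column-pair
#' score is the mean of its residue-pair scores and gaps are scored as gap
#' penalties.  Row order follows the input group; a single-isoform group
#' yields the trivial one-row alignment.
#'
#' @param group an [OrthologueGroup-class] (or any named `AAStringSet` /
#'   named character vector of sequences).
#' @param params an [alignParams()] object.
#' @return an [IsoformAlignment-class].
#' @export
alignGroup <- function(group, params = alignParams()) {
  seqs <- if (is(group, "OrthologueGroup"))
    stats::setNames(as.character(isoformSequences(group)), isoformIds(group))
  else
    stats::setNames(as.character(group), names(group))
  n <- length(seqs)
  if (n == 0L) stop("cannot align an empty group")
  if (n == 1L) return(IsoformAlignment(seqs))
  E <- .scoreMatrix(params)

  profiles <- lapply(seqs, .seqToProfile)
  rowIds <- lapply(names(seqs), identity)

  if (n == 2L) {
    res <- .alignProfiles(profiles[[1]], profiles[[2]], params, E)
    merged <- .applyMoves(profiles[[1]], profiles[[2]], res$moves)
    rownames(merged) <- names(seqs)
    return(.profileToAlignment(merged, names(seqs)))
  }

  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- alignPair(seqs[[i]], seqs[[j]], params)
      D[i, j] <- D[j, i] <- 1 - .fractionIdentity(pa$aligned1, pa$aligned2)
    }
  }
  tree <- stats::hclust(stats::as.dist(D), method = "average")

  nodeProf <- vector("list", n - 1)
  nodeIds <- vector("list", n - 1)
  getNode <- function(k) {
    if (k < 0) list(prof = profiles[[-k]], ids = names(seqs)[-k])
    else list(prof = nodeProf[[k]], ids = nodeIds[[k]])
  }
  for (step in seq_len(n - 1)) {
    a <- getNode(tree$merge[step, 1])
    b <- getNode(tree$merge[step, 2])
    res <- .alignProfiles(a$prof, b$prof, params, E)
    nodeProf[[step]] <- .applyMoves(a$prof, b$prof, res$moves)
    nodeIds[[step]] <- c(a$ids, b$ids)
  }
  prof <- nodeProf[[n - 1]]
  rownames(prof) <- nodeIds[[n - 1]]
  .profileToAlignment(prof[names(seqs), , drop = FALSE], names(seqs))
}

# character matrix -> IsoformAlignment, dropping all-gap columns
.profileToAlignment <- function(prof, ids) {
  keep <- colSums(prof != .GAP) > 0L
  prof <- prof[, keep, drop = FALSE]
  rows <- apply(prof, 1, paste, collapse = "")
  IsoformAlignment(stats::setNames(rows, ids))
}

#' Ingest a precomputed multiple alignment (aligned FASTA)
#'
#' Lets users supply a genuine external alignment (e.g. MUSCLE output) in
#' place of the built-in progressive aligner.  The file must contain exactly
#' the group's isoforms; each gap-stripped row must reproduce the stored
#' sequence.  All-gap columns are removed with a message.
#'
#' @param path aligned FASTA file.
#' @param group the [OrthologueGroup-class] the alignment belongs to.
#' @return an [IsoformAlignment-class] with rows in group order.
#' @export
ingestAlignment <- function(path, group) {
  rows <- readFasta(path)
  ids <- isoformIds(group)
  if (!setequal(names(rows), ids) || length(rows) != length(ids)) {
    missing <- setdiff(ids, names(rows))
    extra <- setdiff(names(rows), ids)
    stop("alignment rows do not match group isoforms",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")) else "",
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")) else "")
  }
  rows <- rows[ids]
  chr <- as.character(rows)
  if (length(unique(nchar(chr))) != 1L)
    stop("aligned rows must have equal length")
  stripped <- gsub("-", "", chr, fixed = TRUE)
  orig <- as.character(isoformSequences(group))
  bad <- ids[stripped != orig]
  if (length(bad))
    stop("gap-stripped row differs from the stored sequence for: ",
         paste(bad, collapse = ", "))
  m <- .alnCharMatrix(Biostrings::AAStringSet(chr))
  allGap <- colSums(m != .GAP) == 0L
  if (any(allGap)) {
    message(sum(allGap), " all-gap column(s) removed from ", path)
    m <- m[, !allGap, drop = FALSE]
  }
  rows <- apply(m, 1, paste, collapse = "")
  IsoformAlignment(stats::setNames(rows, ids))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an [IsoformAlignment-class].
#' @param path output file.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln@aln, path)
  invisible(path)
}
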