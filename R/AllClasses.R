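#' @importFrom methods new validObject setClass setGeneric setMethod is slot
#' @importFrom methods setValidity show
#' @importFrom S4Vectors isSorted
#' @importFrom IRanges IRanges start end width reduce
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings AAStringSet
#' @import Biostrings
NULL

# residue alphabet accepted in isoform sequences: the 20 amino acids plus
# the ambiguity/rare codes X, B, Z, U.  Stop characters and whitespace are
# rejected at construction.
.AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                 "X", "B", "Z", "U")
.GAP <- "-"

.checkResidues <- function(seqs) {
  chars <- unique(unlist(strsplit(as.character(seqs), "", fixed = TRUE)))
  bad <- setdiff(chars, .AA_LETTERS)
  if (length(bad) > 0L)
    sprintf("invalid residue symbol(s): %s", paste(sQuote(bad), collapse = ", "))
  else
    NULL
}

#' OrthologueGroup: a one-to-one two-species orthologous gene pair
#'
#' Holds the protein isoform sequences of a single orthologue group: exactly
#' one gene per species, at least one isoform per species.  Sequences are
#' stored as an [Biostrings::AAStringSet] named by isoform id.
#'
#' @slot groupId single group identifier.
#' @slot sequences `AAStringSet`, names are isoform ids.
#' @slot geneId character vector parallel to `sequences`, gene per isoform.
#' @slot species character vector parallel to `sequences`, species label per
#'   isoform.
#' @exportClass OrthologueGroup
setClass("OrthologueGroup",
  representation(groupId = "character",
                 sequences = "AAStringSet",
                 geneId = "character",
                 species = "character"))

setValidity("OrthologueGroup", function(object) {
  ids <- names(object@sequences)
  msgs <- character()
  if (length(object@groupId) != 1L || is.na(object@groupId) ||
      !nzchar(object@groupId))
    msgs <- c(msgs, "groupId must be a single non-empty string")
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "isoform ids must be present and unique")
  if (length(object@geneId) != length(object@sequences) ||
      length(object@species) != length(object@sequences))
    msgs <- c(msgs, "geneId and species must parallel the sequences")
  if (any(Biostrings::width(object@sequences) == 0L))
    msgs <- c(msgs, "all sequences must be non-empty")
  res <- .checkResidues(object@sequences)
  if (!is.null(res)) msgs <- c(msgs, res)
  sp <- unique(object@species)
  if (length(sp) != 2L)
    msgs <- c(msgs, "group must contain isoforms from exactly two species")
  else {
    for (s in sp) {
      if (length(unique(object@geneId[object@species == s])) != 1L)
        msgs <- c(msgs, sprintf(
          "species %s must contribute exactly one gene (one-to-one orthology)", s))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OrthologueGroup
#'
#' @param groupId group identifier.
#' @param sequences an `AAStringSet` or named character vector of protein
#'   sequences; names are isoform ids.
#' @param geneId gene identifier per isoform (recycled if length 1 per
#'   species is not possible — must match `sequences` in length).
#' @param species species label per isoform.
#' @return an [OrthologueGroup-class] object.
#' @examples
#' g <- OrthologueGroup("G1",
#'   c(h1 = "MKVL", h2 = "MKV", m1 = "MKVL", m2 = "MKV"),
#'   geneId  = c("HG", "HG", "MG", "MG"),
#'   species = c("human", "human", "mouse", "mouse"))
#' nIsoforms(g)
#' @export
OrthologueGroup <- function(groupId, sequences, geneId, species) {
  if (!is(sequences, "AAStringSet")) {
    seqs <- toupper(as.character(sequences))
    nm <- names(sequences)
    sequences <- Biostrings::AAStringSet(seqs)
    names(sequences) <- nm
  }
  new("OrthologueGroup", groupId = as.character(groupId),
      sequences = sequences,
      geneId = as.character(geneId), species = as.character(species))
}

#' @describeIn OrthologueGroup number of isoforms in the group
#' @param x,object an `OrthologueGroup`.
#' @export
nIsoforms <- function(x) length(x@sequences)

#' @describeIn OrthologueGroup isoform identifiers
#' @export
isoformIds <- function(x) names(x@sequences)

#' @describeIn OrthologueGroup isoform sequences as an `AAStringSet`
#' @export
isoformSequences <- function(x) x@sequences

#' @describeIn OrthologueGroup species label per isoform, named by isoform id
#' @export
speciesLabels <- function(x) stats::setNames(x@species, names(x@sequences))

#' @describeIn OrthologueGroup the two species labels, in order of appearance
#' @export
speciesPair <- function(x) unique(x@species)

#' @describeIn OrthologueGroup gene id per isoform, named by isoform id
#' @export
geneIds <- function(x) stats::setNames(x@geneId, names(x@sequences))

#' @describeIn OrthologueGroup group identifier
#' @export
groupId <- function(x) x@groupId

setMethod("show", "OrthologueGroup", function(object) {
  sp <- speciesPair(object)
  cat(sprintf("OrthologueGroup %s: %d isoforms (%s: %d, %s: %d)\n",
              object@groupId, nIsoforms(object),
              sp[1], sum(object@species == sp[1]),
              sp[2], sum(object@species == sp[2])))
})

#' IsoformAlignment: a gapped multiple alignment of a group's isoforms
#'
#' Aligned rows are stored as an `AAStringSet` over residues plus the gap
#' character `-`.  All rows have equal width, stripping gaps from a row
#' reproduces the isoform sequence, and no column is all-gap.
#'
#' @slot aln `AAStringSet` of aligned rows, names are isoform ids.
#' @exportClass IsoformAlignment
setClass("IsoformAlignment", representation(aln = "AAStringSet"))

setValidity("IsoformAlignment", function(object) {
  msgs <- character()
  w <- Biostrings::width(object@aln)
  if (length(w) == 0L)
    msgs <- c(msgs, "alignment must contain at least one row")
  else if (length(unique(w)) != 1L)
    msgs <- c(msgs, "all aligned rows must have equal length")
  if (is.null(names(object@aln)) || anyDuplicated(names(object@aln)))
    msgs <- c(msgs, "rows must be uniquely named by isoform id")
  if (length(msgs) == 0L && w[1] > 0L) {
    m <- .alnCharMatrix(object@aln)
    if (any(colSums(m != .GAP) == 0L))
      msgs <- c(msgs, "alignment contains an all-gap column")
  }
  if (length(msgs)) msgs else TRUE
})

# rows x columns character matrix of an aligned AAStringSet
.alnCharMatrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
}

#' Construct an IsoformAlignment from aligned rows
#'
#' @param rows named character vector (or `AAStringSet`) of equal-length
#'   aligned strings over residues and `-`.
#' @return an [IsoformAlignment-class].
#' @export
IsoformAlignment <- function(rows) {
  if (!is(rows, "AAStringSet")) {
    nm <- names(rows)
    rows <- Biostrings::AAStringSet(toupper(as.character(rows)))
    names(rows) <- nm
  }
  new("IsoformAlignment", aln = rows)
}

#' @describeIn IsoformAlignment aligned rows as a named character vector
#' @param x an `IsoformAlignment`.
#' @export
alignedRows <- function(x) stats::setNames(as.character(x@aln), names(x@aln))

#' @describeIn IsoformAlignment number of alignment columns
#' @export
alignmentWidth <- function(x) {
  if (length(x@aln) == 0L) 0L else Biostrings::width(x@aln)[1]
}

setMethod("show", "IsoformAlignment", function(object) {
  cat(sprintf("IsoformAlignment: %d rows x %d columns\n",
              length(object@aln), alignmentWidth(object)))
})

#' PairwiseProjection: two MSA rows with double-gap columns removed
#'
#' The projection of a multiple alignment onto one pair of isoforms: the two
#' aligned rows restricted to columns where at least one of them carries a
#' residue.  The similarity score's denominator is the projection length.
#'
#' @slot id1,id2 isoform ids.
#' @slot row1,row2 projected aligned strings (equal length, no column is a
#'   gap in both).
#' @exportClass PairwiseProjection
setClass("PairwiseProjection",
  representation(id1 = "character", id2 = "character",
                 row1 = "character", row2 = "character"))

setValidity("PairwiseProjection", function(object) {
  msgs <- character()
  if (nchar(object@row1) != nchar(object@row2))
    msgs <- c(msgs, "projected rows must have equal length")
  else if (nchar(object@row1) > 0L) {
    c1 <- strsplit(object@row1, "", fixed = TRUE)[[1]]
    c2 <- strsplit(object@row2, "", fixed = TRUE)[[1]]
    if (any(c1 == .GAP & c2 == .GAP))
      msgs <- c(msgs, "projection contains a double-gap column")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PairwiseProjection number of projection columns
#' @param x a `PairwiseProjection`.
#' @export
projectionLength <- function(x) nchar(x@row1)

setMethod("show", "PairwiseProjection", function(object) {
  cat(sprintf("PairwiseProjection %s / %s: %d columns\n",
              object@id1, object@id2, projectionLength(object)))
})

#' SimilarityMatrix: symmetric isoform-pair similarity scores in \[0, 1\]
#'
#' @slot mat symmetric numeric matrix with unit diagonal; dimnames are
#'   isoform ids.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(mat = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  m <- object@mat
  msgs <- character()
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "matrix must be square with matching id dimnames")
  else {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
      msgs <- c(msgs, "matrix must be symmetric")
    if (any(m < -1e-12 | m > 1 + 1e-12))
      msgs <- c(msgs, "similarities must lie in [0, 1]")
    if (any(abs(diag(m) - 1) > 1e-12))
      msgs <- c(msgs, "diagonal must be 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SimilarityMatrix extract the similarity of a pair
#' @param x a `SimilarityMatrix`.
#' @param id1,id2 isoform ids.
#' @export
simBetween <- function(x, id1, id2) {
  if (!all(c(id1, id2) %in% rownames(x@mat)))
    stop("unknown isoform id(s): ",
         paste(setdiff(c(id1, id2), rownames(x@mat)), collapse = ", "))
  unname(x@mat[id1, id2])
}

#' @describeIn SimilarityMatrix the underlying symmetric matrix
#' @export
simMatrix <- function(x) x@mat

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d isoforms\n", nrow(object@mat)))
  print(round(object@mat, 3))
})

#' SubCluster: one transcript-level sub-cluster of an orthologue group
#'
#' A non-singleton sub-cluster is seeded by an anchor pair — the best-scoring
#' cross-species isoform pair among those not yet assigned — and contains, per
#' species, every isoform whose similarity to that species' anchor strictly
#' exceeds the anchor-pair score.  A singleton has one member and no anchors.
#'
#' @slot clusterIndex 1-based index within the group clustering.
#' @slot anchorA,anchorB anchor isoform ids (length 0 for singletons).
#' @slot anchorScore similarity of the anchor pair (length 0 for singletons).
#' @slot members isoform ids.
#' @slot memberSpecies species label per member.
#' @exportClass SubCluster
setClass("SubCluster",
  representation(clusterIndex = "integer",
                 anchorA = "character", anchorB = "character",
                 anchorScore = "numeric",
                 members = "character", memberSpecies = "character"))

setValidity("SubCluster", function(object) {
  msgs <- character()
  if (length(object@members) == 0L)
    msgs <- c(msgs, "cluster must have at least one member")
  if (length(object@members) != length(object@memberSpecies))
    msgs <- c(msgs, "memberSpecies must parallel members")
  single <- length(object@anchorA) == 0L
  if (single) {
    if (length(object@members) != 1L)
      msgs <- c(msgs, "a cluster without anchors must be a singleton")
    if (length(object@anchorScore) != 0L || length(object@anchorB) != 0L)
      msgs <- c(msgs, "singletons carry no anchor score")
  } else {
    if (!all(c(object@anchorA, object@anchorB) %in% object@members))
      msgs <- c(msgs, "anchors must be members")
    if (length(object@anchorScore) != 1L ||
        object@anchorScore < 0 || object@anchorScore > 1)
      msgs <- c(msgs, "anchorScore must be a single value in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SubCluster TRUE for a singleton (anchorless) cluster
#' @param x a `SubCluster`.
#' @export
isSingleton <- function(x) length(x@anchorA) == 0L

#' @describeIn SubCluster member isoform ids
#' @export
clusterMembers <- function(x) x@members

#' @describeIn SubCluster the anchor pair as c(a, b), or NULL for singletons
#' @export
anchorPair <- function(x) if (isSingleton(x)) NULL else c(x@anchorA, x@anchorB)

#' @describeIn SubCluster the anchor-pair similarity, or NA for singletons
#' @export
anchorScore <- function(x) if (isSingleton(x)) NA_real_ else x@anchorScore

setMethod("show", "SubCluster", function(object) {
  if (isSingleton(object))
    cat(sprintf("SubCluster %d (singleton): %s\n", object@clusterIndex,
                object@members))
  else
    cat(sprintf("SubCluster %d: anchors %s-%s (sim %.3f), %d members\n",
                object@clusterIndex, object@anchorA, object@anchorB,
                object@anchorScore, length(object@members)))
})

#' GroupClustering: the sub-cluster partition of one orthologue group
#'
#' @slot groupId the group identifier.
#' @slot isoformIds all isoform ids of the group (the partitioned universe).
#' @slot clusters list of [SubCluster-class], anchored clusters first in
#'   order of creation (non-increasing anchor score), then singletons.
#' @exportClass GroupClustering
setClass("GroupClustering",
  representation(groupId = "character", isoformIds = "character",
                 clusters = "list"))

setValidity("GroupClustering", function(object) {
  msgs <- character()
  all_members <- unlist(lapply(object@clusters, clusterMembers))
  if (anyDuplicated(all_members))
    msgs <- c(msgs, "clusters must be disjoint")
  if (!setequal(all_members, object@isoformIds))
    msgs <- c(msgs, "clusters must partition the group's isoforms")
  sc <- vapply(object@clusters, anchorScore, numeric(1))
  sc <- sc[!is.na(sc)]
  if (length(sc) > 1L && any(diff(sc) > 1e-12))
    msgs <- c(msgs, "anchor scores must be non-increasing over clusters")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GroupClustering list of SubCluster objects
#' @param x a `GroupClustering`.
#' @export
subClusters <- function(x) x@clusters

#' Number of sub-clusters in a clustering, singletons included
#'
#' @param clustering a [GroupClustering-class].
#' @return integer count of sub-clusters.
#' @export
countSubclusters <- function(clustering) length(clustering@clusters)

#' @describeIn GroupClustering cluster index per isoform, named by isoform id
#' @export
clusterAssignments <- function(x) {
  idx <- unlist(lapply(x@clusters, function(cl)
    stats::setNames(rep(cl@clusterIndex, length(cl@members)), cl@members)))
  idx[x@isoformIds]
}

setMethod("show", "GroupClustering", function(object) {
  cat(sprintf("GroupClustering %s: %d isoforms in %d sub-cluster(s)\n",
              object@groupId, length(object@isoformIds),
              countSubclusters(object)))
  for (cl in object@clusters) show(cl)
})

#' DisorderProfile: filtered intrinsically disordered regions of one isoform
#'
#' Regions are 1-based inclusive residue intervals that have already passed
#' the merge/length filter: nearby regions combined, short regions dropped.
#'
#' @slot isoformId the isoform.
#' @slot regions an [IRanges::IRanges] of disordered intervals, sorted,
#'   non-overlapping.
#' @slot proteinLen protein length in residues.
#' @exportClass DisorderProfile
setClass("DisorderProfile",
  representation(isoformId = "character", regions = "IRanges",
                 proteinLen = "integer"))

setValidity("DisorderProfile", function(object) {
  msgs <- character()
  r <- object@regions
  if (length(object@proteinLen) != 1L || object@proteinLen < 1L)
    msgs <- c(msgs, "proteinLen must be a single positive integer")
  if (length(r) > 0L) {
    if (any(start(r) < 1L) || any(end(r) > object@proteinLen))
      msgs <- c(msgs, "regions must lie within [1, proteinLen]")
    if (is.unsorted(start(r)))
      msgs <- c(msgs, "regions must be sorted by start")
    if (length(r) > 1L && any(start(r)[-1] <= end(r)[-length(r)]))
      msgs <- c(msgs, "regions must be non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DisorderProfile number of disordered regions
#' @param x a `DisorderProfile`.
#' @export
nRegions <- function(x) length(x@regions)

#' @describeIn DisorderProfile summed length of disordered regions
#' @export
totalDisorderLength <- function(x) sum(width(x@regions))

#' @describeIn DisorderProfile the region intervals as an `IRanges`
#' @export
disorderRegions <- function(x) x@regions

setMethod("show", "DisorderProfile", function(object) {
  cat(sprintf(
    "DisorderProfile %s: %d region(s), %d/%d residues disordered (%.1f%%)\n",
    object@isoformId, nRegions(object), totalDisorderLength(object),
    object@proteinLen, 100 * totalDisorderLength(object) / object@proteinLen))
})

#' GroupDiffSummary: intra/inter sub-cluster averages of a difference measure
#'
#' @slot groupId the orthologue group.
#' @slot measure `"func"` or `"dis"`.
#' @slot intraMean mean pairwise difference within sub-clusters (NA when the
#'   group has no intra pair).
#' @slot interMean mean pairwise difference between sub-clusters (NA when
#'   none).
#' @slot nIntraPairs,nInterPairs pair counts.
#' @slot excluded TRUE when the group was excluded because every pairwise
#'   difference is zero (the "no differences found" filter).
#' @exportClass GroupDiffSummary
setClass("GroupDiffSummary",
  representation(groupId = "character", measure = "character",
                 intraMean = "numeric", interMean = "numeric",
                 nIntraPairs = "integer", nInterPairs = "integer",
                 excluded = "logical"))

setValidity("GroupDiffSummary", function(object) {
  msgs <- character()
  if (!object@measure %in% c("func", "dis"))
    msgs <- c(msgs, "measure must be 'func' or 'dis'")
  if (is.na(object@intraMean) != (object@nIntraPairs == 0L))
    msgs <- c(msgs, "intraMean must be NA exactly when nIntraPairs is 0")
  if (is.na(object@interMean) != (object@nInterPairs == 0L))
    msgs <- c(msgs, "interMean must be NA exactly when nInterPairs is 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroupDiffSummary", function(object) {
  cat(sprintf(
    "GroupDiffSummary %s [%s]: intra %s (n=%d), inter %s (n=%d)%s\n",
    object@groupId, object@measure,
    ifelse(is.na(object@intraMean), "NA", sprintf("%.3f", object@intraMean)),
    object@nIntraPairs,
    ifelse(is.na(object@interMean), "NA", sprintf("%.3f", object@interMean)),
    object@nInterPairs,
    if (object@excluded) " [excluded: no differences]" else ""))
})

#' RankSumResult: a Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' @slot n1,n2 sample sizes.
#' @slot U the Mann-Whitney U statistic of the first sample.
#' @slot z normal deviate (NA in exact mode).
#' @slot p two-sided (or requested-side) p-value.
#' @slot method `"exact"` or `"normal_approx"`.
#' @exportClass RankSumResult
setClass("RankSumResult",
  representation(n1 = "integer", n2 = "integer", U = "numeric",
                 z = "numeric", p = "numeric", method = "character"))

setValidity("RankSumResult", function(object) {
  msgs <- character()
  if (object@U < 0 || object@U > object@n1 * object@n2)
    msgs <- c(msgs, "U must lie in [0, n1*n2]")
  if (object@p <= 0 || object@p > 1)
    msgs <- c(msgs, "p must lie in (0, 1]")
  if (!object@method %in% c("exact", "normal_approx"))
    msgs <- c(msgs, "method must be 'exact' or 'normal_approx'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RankSumResult", function(object) {
  cat(sprintf("RankSumResult (%s): n1=%d n2=%d U=%.1f%s p=%.4g\n",
              object@method, object@n1, object@n2, object@U,
              if (is.na(object@z)) "" else sprintf(" z=%.3f", object@z),
              object@p))
})
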