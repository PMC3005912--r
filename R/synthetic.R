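#' Specification of a synthetic two-species orthologue group
#'
#' Describes an exon-skipping construction: a gene of `nExons` exons, a set
#' of isoform exon-inclusion patterns mirrored across two species, optional
#' per-residue substitution noise in the second species' copy, per-exon
#' functional signatures, and per-exon disorder intervals.  All randomness is
#' seeded, so a spec generates the same group every time.
#'
#' @slot nExons number of exons.
#' @slot exonLengths exon lengths in residues (length `nExons`).
#' @slot patterns list of logical inclusion vectors (one per isoform,
#'   mirrored across the two species), each including at least one exon.
#' @slot substitutionRate per-residue substitution probability applied to
#'   the second species' exon copies, in \[0, 1).
#' @slot signaturePerExon when TRUE, signature k is assigned to an isoform
#'   iff exon k is in its pattern.
#' @slot disorderExons indices of exons emitted as disorder intervals.
#' @slot seed RNG seed.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(nExons = "integer", exonLengths = "integer",
                 patterns = "list", substitutionRate = "numeric",
                 signaturePerExon = "logical", disorderExons = "integer",
                 seed = "integer"))

setValidity("SynthSpec", function(object) {
  msgs <- character()
  if (length(object@exonLengths) != object@nExons)
    msgs <- c(msgs, "exonLengths must have one entry per exon")
  if (any(object@exonLengths < 1L))
    msgs <- c(msgs, "exon lengths must be >= 1")
  if (length(object@patterns) == 0L)
    msgs <- c(msgs, "at least one isoform pattern is required")
  for (p in object@patterns) {
    if (length(p) != object@nExons || !any(p))
      msgs <- c(msgs, "every pattern must cover nExons and include >= 1 exon")
  }
  if (object@substitutionRate < 0 || object@substitutionRate >= 1)
    msgs <- c(msgs, "substitutionRate must lie in [0, 1)")
  if (length(object@disorderExons) &&
      (any(object@disorderExons < 1L) ||
       any(object@disorderExons > object@nExons)))
    msgs <- c(msgs, "disorderExons must index existing exons")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SynthSpec-class
#' @param nExons,exonLengths,patterns,substitutionRate,signaturePerExon,disorderExons,seed
#'   see slots; `patterns` entries may be logical vectors or bitmask strings
#'   such as `"110"`.
#' @export
synthSpec <- function(nExons, exonLengths, patterns, substitutionRate = 0,
                      signaturePerExon = TRUE, disorderExons = integer(),
                      seed = 1L) {
  patterns <- lapply(patterns, function(p) {
    if (is.character(p))
      as.logical(as.integer(strsplit(p, "", fixed = TRUE)[[1]]))
    else as.logical(p)
  })
  new("SynthSpec", nExons = as.integer(nExons),
      exonLengths = as.integer(exonLengths), patterns = patterns,
      substitutionRate = as.numeric(substitutionRate),
      signaturePerExon = as.logical(signaturePerExon),
      disorderExons = as.integer(disorderExons), seed = as.integer(seed))
}

#' The three-exon worked-example spec
#'
#' Two isoforms per species: one carrying exons 1-2, the other exons 1-2-3,
#' with three distinct equal-length exon strings identical across species —
#' the textbook exon-skipping configuration in which same-structure
#' cross-species pairs score 1 and mixed pairs score 2/3.
#'
#' @param exonLength common exon length (default 20).
#' @param seed RNG seed.
#' @return a [SynthSpec-class].
#' @export
threeExonSpec <- function(exonLength = 20, seed = 1L) {
  synthSpec(nExons = 3, exonLengths = rep(exonLength, 3),
            patterns = list("110", "111"), substitutionRate = 0,
            signaturePerExon = TRUE, disorderExons = integer(), seed = seed)
}

.STD_AA <- setdiff(.AA_LETTERS, c("X", "B", "Z", "U"))

.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic orthologue group with known structure
#'
#' Species A exons are random amino-acid strings (pairwise distinct,
#' regenerated on collision); species B exons are per-residue substituted
#' copies.  Isoform sequences concatenate the exons of their pattern.  The
#' per-residue substitution decisions are drawn as uniforms compared against
#' the rate (with substitution targets drawn unconditionally), so for a
#' fixed seed the substituted positions at a lower rate are a subset of
#' those at a higher rate — noise levels are coupled, which stabilises
#' comparisons across rates.
#'
#' @param spec a [SynthSpec-class].
#' @return a list with elements `group` (an [OrthologueGroup-class]),
#'   `truth` (pattern class per isoform, named by isoform id),
#'   `signatures` (data.frame `isoform_id`, `signature_accession`) and
#'   `disorder` (data.frame `isoform_id`, `start`, `end`).
#' @examples
#' g <- generateGroup(threeExonSpec(seed = 7))
#' isoformIds(g$group)
#' @export
generateGroup <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, {
    lens <- spec@exonLengths
    k <- spec@nExons
    exonsA <- character(k)
    seen <- character()
    for (i in seq_len(k)) {
      repeat {
        s <- paste(sample(.STD_AA, lens[i], replace = TRUE), collapse = "")
        if (!s %in% seen) break
      }
      exonsA[i] <- s
      seen <- c(seen, s)
    }
    exonsB <- vapply(seq_len(k), function(i) {
      ch <- strsplit(exonsA[i], "", fixed = TRUE)[[1]]
      u <- stats::runif(lens[i])
      tgt <- sample(.STD_AA, lens[i], replace = TRUE)
      sub <- u < spec@substitutionRate
      if (any(sub)) {
        same <- sub & tgt == ch
        # force a real substitution when the drawn target equals the original
        tgt[same] <- .STD_AA[(match(ch[same], .STD_AA) %% length(.STD_AA)) + 1L]
        ch[sub] <- tgt[sub]
      }
      paste(ch, collapse = "")
    }, character(1))

    patStr <- vapply(spec@patterns, function(p)
      paste(as.integer(p), collapse = ""), character(1))
    mkIso <- function(exons, prefix) {
      stats::setNames(
        vapply(spec@patterns, function(p)
          paste(exons[p], collapse = ""), character(1)),
        paste0(prefix, seq_along(spec@patterns)))
    }
    seqsA <- mkIso(exonsA, "A.iso")
    seqsB <- mkIso(exonsB, "B.iso")
    seqs <- c(seqsA, seqsB)
    group <- OrthologueGroup(
      groupId = sprintf("synth%d", spec@seed),
      sequences = seqs,
      geneId = rep(c("A.gene", "B.gene"), each = length(spec@patterns)),
      species = rep(c("A", "B"), each = length(spec@patterns)))
    truth <- stats::setNames(rep(patStr, 2), names(seqs))

    sigs <- data.frame(isoform_id = character(),
                       signature_accession = character())
    if (spec@signaturePerExon) {
      rows <- lapply(names(seqs), function(id) {
        p <- spec@patterns[[match(truth[[id]], patStr)]]
        data.frame(isoform_id = id,
                   signature_accession = sprintf("SIG%02d", which(p)))
      })
      sigs <- do.call(rbind, rows)
    }

    dis <- data.frame(isoform_id = character(), start = integer(),
                      end = integer())
    if (length(spec@disorderExons)) {
      rows <- lapply(names(seqs), function(id) {
        p <- spec@patterns[[match(truth[[id]], patStr)]]
        offs <- cumsum(c(0L, lens[p]))
        present <- which(p)
        hit <- intersect(spec@disorderExons, present)
        if (length(hit) == 0L) return(NULL)
        pos <- match(hit, present)
        data.frame(isoform_id = id, start = offs[pos] + 1L,
                   end = offs[pos] + lens[hit])
      })
      rows <- Filter(Negate(is.null), rows)
      if (length(rows)) dis <- do.call(rbind, rows)
    }

    list(group = group, truth = truth, signatures = sigs, disorder = dis)
  })
}

#' Agreement between a clustering and the true pattern classes
#'
#' 1 exactly when the sub-clusters equal the truth classes as partitions;
#' otherwise the adjusted Rand index of the two partitions, clamped to
#' \[0, 1\].
#'
#' @param clustering a [GroupClustering-class].
#' @param truth class label per isoform, named by isoform id, covering all
#'   isoforms of the clustering.
#' @return a value in \[0, 1\].
#' @export
recoveryScore <- function(clustering, truth) {
  ids <- clustering@isoformIds
  if (!all(ids %in% names(truth)))
    stop("truth labels must cover all isoforms")
  pred <- clusterAssignments(clustering)[ids]
  tr <- truth[ids]
  key <- function(part) sort(vapply(split(ids, part), function(s)
    paste(sort(s), collapse = "\r"), character(1)))
  if (identical(unname(key(pred)), unname(key(tr))))
    return(1)
  max(0, mclust::adjustedRandIndex(pred, tr))
}
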