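#' Read a protein FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; sequences
#' are uppercased; record order is preserved.  Duplicate ids and sequence
#' lines appearing before any header are errors.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::AAStringSet] (possibly gapped, for aligned
#'   FASTA); empty set for an empty file.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (length(nonEmpty) == 0L) {
    out <- Biostrings::AAStringSet()
    return(out)
  }
  first <- nonEmpty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA %s: sequence before header at line %d",
                 path, first))
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  out <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs a named `AAStringSet` or named character vector.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "AAStringSet")) {
    nm <- names(seqs)
    seqs <- Biostrings::AAStringSet(as.character(seqs))
    names(seqs) <- nm
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a group manifest and assemble orthologue groups
#'
#' The manifest is a TSV with header columns `group_id`, `isoform_id`,
#' `gene_id`, `species` mapping each isoform to its gene, species and
#' orthologue group.  Rows are grouped by `group_id` and validated: a group
#' must contain exactly two species, exactly one gene per species and unique
#' isoform ids.  Invalid groups are skipped with a warning (or fatal under
#' `strict = TRUE`) so large manifests degrade gracefully.
#'
#' @param path manifest TSV.
#' @param sequences a named `AAStringSet` (from [readFasta()]) supplying the
#'   isoform sequences; every manifest isoform must be present.
#' @param strict make invalid groups fatal instead of skipped.
#' @return a named list of [OrthologueGroup-class] objects, in manifest
#'   order.
#' @export
readManifest <- function(path, sequences, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("group_id", "isoform_id", "gene_id", "species")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  absent <- setdiff(df$isoform_id, names(sequences))
  if (length(absent))
    stop("manifest isoform(s) absent from FASTA: ",
         paste(absent, collapse = ", "))
  groups <- list()
  for (gid in unique(df$group_id)) {
    rows <- df[df$group_id == gid, , drop = FALSE]
    g <- tryCatch(
      OrthologueGroup(groupId = gid,
                      sequences = stats::setNames(
                        as.character(sequences[rows$isoform_id]),
                        rows$isoform_id),
                      geneId = rows$gene_id, species = rows$species),
      error = function(e) e)
    if (is(g, "error")) {
      msg <- sprintf("skipping group %s: %s", gid, conditionMessage(g))
      if (strict) stop(msg)
      warning(msg, call. = FALSE)
    } else {
      groups[[gid]] <- g
    }
  }
  groups
}

#' Write a group manifest TSV
#'
#' @param groups list of [OrthologueGroup-class].
#' @param path output file.
#' @export
writeManifest <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g)
    data.frame(group_id = groupId(g), isoform_id = isoformIds(g),
               gene_id = unname(geneIds(g)),
               species = unname(speciesLabels(g)))))
  if (is.null(rows))
    rows <- data.frame(group_id = character(), isoform_id = character(),
                       gene_id = character(), species = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read InterProScan-style signature assignments
#'
#' Tab-separated, protein accession in column 1 and the member-database
#' signature accession in `signatureColumn` (default 5, the standard
#' InterProScan TSV layout; configurable because the dialect has varied
#' across versions).  Comment lines (`#`) are ignored; rows too short to
#' carry both columns are skipped with a warning.  Assignments are
#' de-duplicated.
#'
#' @param path InterProScan TSV.
#' @param signatureColumn 1-based column of the signature accession.
#' @return a data.frame with columns `isoform_id`, `signature_accession`,
#'   one row per distinct pair.
#' @export
readInterproscanTsv <- function(path, signatureColumn = 5) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(isoform_id = character(),
                      signature_accession = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= signatureColumn
  if (any(!ok))
    warning(sum(!ok), " unreadable row(s) skipped in ", path, call. = FALSE)
  fields <- fields[ok]
  df <- data.frame(
    isoform_id = vapply(fields, `[`, character(1), 1L),
    signature_accession = vapply(fields, `[`, character(1), signatureColumn))
  unique(df)
}

#' Read disorder annotations (intervals or per-residue scores)
#'
#' Two dialects.  `"intervals"`: columns `isoform_id`, `start`, `end`
#' (1-based inclusive residue intervals); intervals are sorted by start per
#' isoform, and `start > end` is an error.  `"scores"`: columns
#' `isoform_id`, `position`, `score`; each isoform's positions must be
#' contiguous 1..L, and the dense track is returned.
#'
#' @param path disorder TSV.
#' @param kind `"intervals"` or `"scores"`.
#' @return a named list, per isoform: an [IRanges::IRanges] of raw
#'   intervals, or a numeric score track.
#' @export
readDisorderTsv <- function(path, kind = c("intervals", "scores")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (kind == "intervals") {
    needed <- c("isoform_id", "start", "end")
    if (length(setdiff(needed, colnames(df))))
      stop("intervals dialect needs columns: ", paste(needed, collapse = ", "))
    if (nrow(df) == 0L) return(stats::setNames(list(), character()))
    bad <- df$start > df$end
    if (any(bad))
      stop("interval with start > end for isoform(s): ",
           paste(unique(df$isoform_id[bad]), collapse = ", "))
    lapply(split(df, df$isoform_id), function(d) {
      d <- d[order(d$start), , drop = FALSE]
      IRanges::IRanges(start = d$start, end = d$end)
    })
  } else {
    needed <- c("isoform_id", "position", "score")
    if (length(setdiff(needed, colnames(df))))
      stop("scores dialect needs columns: ", paste(needed, collapse = ", "))
    if (nrow(df) == 0L) return(stats::setNames(list(), character()))
    lapply(split(df, df$isoform_id), function(d) {
      d <- d[order(d$position), , drop = FALSE]
      if (!identical(as.integer(d$position), seq_len(nrow(d))))
        stop("score track for ", d$isoform_id[1],
             " is not contiguous from position 1")
      as.numeric(d$score)
    })
  }
}

#' Write sub-clusterings as a TSV
#'
#' Columns: `group_id`, `cluster_index`, `isoform_id`, `species`,
#' `is_anchor`, `anchor_score` (6 decimal places, empty for singletons).
#' Rows are ordered by group, cluster, species, then id, so identical inputs
#' produce byte-identical files.
#'
#' @param clusterings list of [GroupClustering-class].
#' @param path output file.
#' @export
writeClustersTsv <- function(clusterings, path) {
  rows <- list()
  for (gc in clusterings) {
    for (cl in subClusters(gc)) {
      anch <- anchorPair(cl)
      d <- data.frame(group_id = gc@groupId,
                      cluster_index = cl@clusterIndex,
                      isoform_id = cl@members,
                      species = cl@memberSpecies,
                      is_anchor = cl@members %in% anch,
                      anchor_score = if (isSingleton(cl)) ""
                                     else sprintf("%.6f", anchorScore(cl)))
      rows[[length(rows) + 1L]] <- d[order(d$species, d$isoform_id), ,
                                     drop = FALSE]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(group_id = character(), cluster_index = integer(),
                    isoform_id = character(), species = character(),
                    is_anchor = logical(), anchor_score = character())
  out <- out[order(out$group_id, out$cluster_index), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clusters TSV back into GroupClustering objects
#'
#' Inverse of [writeClustersTsv()], used by the verification commands so
#' they can run from a clusters file alone.
#'
#' @param path clusters TSV.
#' @return named list of [GroupClustering-class].
#' @export
readClustersTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(anchor_score = "character"))
  needed <- c("group_id", "cluster_index", "isoform_id", "species",
              "is_anchor", "anchor_score")
  if (length(setdiff(needed, colnames(df))))
    stop("clusters TSV lacks column(s): ",
         paste(setdiff(needed, colnames(df)), collapse = ", "))
  out <- list()
  for (gid in unique(df$group_id)) {
    rows <- df[df$group_id == gid, , drop = FALSE]
    clusters <- lapply(sort(unique(rows$cluster_index)), function(ci) {
      cr <- rows[rows$cluster_index == ci, , drop = FALSE]
      anchors <- cr[cr$is_anchor, , drop = FALSE]
      if (nrow(anchors) == 2L) {
        new("SubCluster", clusterIndex = as.integer(ci),
            anchorA = anchors$isoform_id[1], anchorB = anchors$isoform_id[2],
            anchorScore = as.numeric(anchors$anchor_score[1]),
            members = cr$isoform_id, memberSpecies = cr$species)
      } else {
        new("SubCluster", clusterIndex = as.integer(ci),
            anchorA = character(), anchorB = character(),
            anchorScore = numeric(),
            members = cr$isoform_id, memberSpecies = cr$species)
      }
    })
    out[[gid]] <- new("GroupClustering", groupId = gid,
                      isoformIds = rows$isoform_id, clusters = clusters)
  }
  out
}
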