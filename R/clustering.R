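#' Anchor-pair sub-clustering of an orthologue group
#'
#' Partitions the group's isoforms into transcript-level sub-clusters,
#' InParanoid-style.  Repeatedly: (1) among unassigned isoforms, the
#' cross-species pair with the highest similarity becomes the anchor pair of
#' a new sub-cluster (ties broken on the lexicographically smallest sorted id
#' pair); (2) every unassigned isoform whose similarity to its own species'
#' anchor strictly exceeds the anchor-pair similarity joins the cluster;
#' (3) the members are marked assigned.  The loop runs while both species
#' still have unassigned isoforms; leftovers become singleton sub-clusters,
#' numbered last in id order.  Membership depends only on similarity to the
#' anchor, so expansion is a single pass and insertion order is irrelevant.
#'
#' @param group an [OrthologueGroup-class].
#' @param sim a [SimilarityMatrix-class] covering all the group's isoforms.
#' @param expandOnTie if TRUE, isoforms whose similarity to the anchor
#'   equals the anchor-pair score are also added (default FALSE: strictly
#'   greater, so tied isoforms stay out).
#' @return a [GroupClustering-class].
#' @export
subclusterGroup <- function(group, sim, expandOnTie = FALSE) {
  ids <- isoformIds(group)
  missing <- setdiff(ids, rownames(simMatrix(sim)))
  if (length(missing))
    stop("similarity matrix lacks isoform(s): ",
         paste(missing, collapse = ", "))
  m <- simMatrix(sim)
  sp <- speciesLabels(group)
  spp <- speciesPair(group)
  unassigned <- ids
  clusters <- list()
  idx <- 0L

  repeat {
    ua <- unassigned[sp[unassigned] == spp[1]]
    ub <- unassigned[sp[unassigned] == spp[2]]
    if (length(ua) == 0L || length(ub) == 0L) break
    # best cross-species pair; tie-break lexicographic on the sorted id pair
    best <- -Inf
    bestPair <- NULL
    for (a in ua) {
      for (b in ub) {
        s <- m[a, b]
        key <- sort(c(a, b))
        if (s > best ||
            (s == best && (key[1] < bestPair$key[1] ||
                           (key[1] == bestPair$key[1] &&
                            key[2] < bestPair$key[2])))) {
          best <- s
          bestPair <- list(a = a, b = b, key = key)
        }
      }
    }
    cmp <- if (expandOnTie) `>=` else `>`
    extraA <- setdiff(ua, bestPair$a)
    extraA <- extraA[cmp(m[extraA, bestPair$a], best)]
    extraB <- setdiff(ub, bestPair$b)
    extraB <- extraB[cmp(m[extraB, bestPair$b], best)]
    members <- c(bestPair$a, bestPair$b, extraA, extraB)
    idx <- idx + 1L
    clusters[[idx]] <- new("SubCluster", clusterIndex = idx,
                           anchorA = bestPair$a, anchorB = bestPair$b,
                           anchorScore = best,
                           members = members,
                           memberSpecies = unname(sp[members]))
    unassigned <- setdiff(unassigned, members)
  }

  for (id in sort(unassigned)) {
    idx <- idx + 1L
    clusters[[idx]] <- new("SubCluster", clusterIndex = idx,
                           anchorA = character(), anchorB = character(),
                           anchorScore = numeric(),
                           members = id, memberSpecies = unname(sp[id]))
  }

  new("GroupClustering", groupId = groupId(group), isoformIds = ids,
      clusters = clusters)
}
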