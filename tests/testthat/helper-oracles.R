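# Independent oracles and fixture builders used across the suite.
# Each oracle is a deliberately naive re-implementation, kept structurally
# different from the package code it checks.

# score an explicit pairwise alignment: substitution scores over
# residue-residue columns plus per-run affine gap costs in each row
scoreAlignmentOracle <- function(a1, a2, subMat, gapOpen = -10,
                                 gapExtend = -1) {
  c1 <- strsplit(a1, "")[[1]]
  c2 <- strsplit(a2, "")[[1]]
  both <- c1 != "-" & c2 != "-"
  res <- if (any(both)) sum(subMat[cbind(c1[both], c2[both])]) else 0
  gapCost <- function(ch) {
    r <- rle(ch == "-")
    sum(ifelse(r$values, gapOpen + (r$lengths - 1) * gapExtend, 0))
  }
  res + gapCost(c1) + gapCost(c2)
}

# exhaustive global alignment: enumerate every alignment of two short
# strings and return the best score under the same cost model
exhaustiveAlignOracle <- function(s1, s2, subMat, gapOpen = -10,
                                  gapExtend = -1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  best <- -Inf
  rec <- function(i, j, r1, r2) {
    if (i > length(a) && j > length(b)) {
      s <- scoreAlignmentOracle(paste(r1, collapse = ""),
                                paste(r2, collapse = ""),
                                subMat, gapOpen, gapExtend)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, c(r1, a[i]), c(r2, b[j]))
    if (i <= length(a)) rec(i + 1, j, c(r1, a[i]), c(r2, "-"))
    if (j <= length(b)) rec(i, j + 1, c(r1, "-"), c(r2, b[j]))
  }
  rec(1L, 1L, character(), character())
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# brute-force anchor-pair clustering: enumerate cross pairs as a data frame,
# order by similarity then sorted-pair lexicographic key, take the head,
# expand strictly, repeat.  Returns the partition as a list of sorted member
# vectors in creation order (singletons last, by id).
bruteForceSubcluster <- function(ids, species, m, expandOnTie = FALSE) {
  left <- ids
  spp <- unique(species[ids])
  parts <- list()
  repeat {
    la <- left[species[left] == spp[1]]
    lb <- left[species[left] == spp[2]]
    if (!length(la) || !length(lb)) break
    pairs <- expand.grid(a = la, b = lb, stringsAsFactors = FALSE)
    pairs$sim <- m[cbind(pairs$a, pairs$b)]
    pairs$k1 <- pmin(pairs$a, pairs$b)
    pairs$k2 <- pmax(pairs$a, pairs$b)
    pairs <- pairs[order(-pairs$sim, pairs$k1, pairs$k2), ]
    top <- pairs[1, ]
    cmp <- if (expandOnTie) `>=` else `>`
    inA <- la[la != top$a & cmp(m[la, top$a], top$sim)]
    inB <- lb[lb != top$b & cmp(m[lb, top$b], top$sim)]
    members <- c(top$a, top$b, inA, inB)
    parts[[length(parts) + 1L]] <- sort(members)
    left <- setdiff(left, members)
  }
  for (id in sort(left)) parts[[length(parts) + 1L]] <- id
  parts
}

# exact two-sided rank-sum p by full enumeration of label assignments
enumerateRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, uOf)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# a random orthologue-group stand-in for clustering tests: ids, species and
# a symmetric similarity matrix (values rounded to induce ties)
randomSimGroup <- function(n, roundTo = 1) {
  nA <- sample(1:(n - 1), 1)
  ids <- c(sprintf("a%d", seq_len(nA)), sprintf("b%d", seq_len(n - nA)))
  species <- stats::setNames(rep(c("A", "B"), c(nA, n - nA)), ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- round(stats::runif(n * (n - 1) / 2), roundTo)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 1
  list(ids = ids, species = species, m = m)
}

# wrap a similarity matrix + memberships into package objects
groupFromSim <- function(ids, species) {
  OrthologueGroup("G", stats::setNames(strrep("M", 3 + seq_along(ids)), ids),
                  geneId = paste0("gene", species[ids]),
                  species = unname(species[ids]))
}

tableFixture <- function(name) {
  system.file("extdata", "tables", name, package = "orthoSplice")
}

loadTable3 <- function() {
  utils::read.delim(tableFixture("table3_bits.tsv"), colClasses = "character")
}

loadTable4 <- function() {
  utils::read.delim(tableFixture("table4_disorder.tsv"))
}

# signature assignments data frame from a printed bit-pattern table
bitsToAssignments <- function(bits) {
  rows <- lapply(seq_len(nrow(bits)), function(i) {
    b <- as.integer(strsplit(bits$bits[i], "")[[1]])
    if (!any(b == 1L)) return(NULL)
    data.frame(isoform_id = bits$isoform_id[i],
               signature_accession = sprintf("%s_S%02d", bits$gene[i],
                                             which(b == 1L)))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

# synthetic disorder profile reproducing printed (n regions, summed length,
# protein length): regions of near-equal length spaced 3 residues apart
profileFromCounts <- function(id, n, total, plen) {
  if (n == 0)
    return(disorderProfile(id, regions = IRanges::IRanges(),
                           proteinLen = plen))
  base <- total %/% n
  lens <- rep(base, n)
  extra <- total - base * n
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  starts <- cumsum(c(1L, head(lens, -1) + 3L))
  disorderProfile(id, regions = IRanges::IRanges(start = starts,
                                                 width = lens),
                  proteinLen = plen)
}

# clustering object straight from a (gene, cluster, isoform_id) table
clusteringFromTable <- function(tab, gene) {
  tb <- tab[tab$gene == gene, , drop = FALSE]
  readClustersTsv(tableFixture("clusters.tsv"))[[gene]]
}

# random exon-skipping spec: 3-5 exons of 10-30 residues, 2-4 distinct
# inclusion patterns mirrored across species
randomSynthSpec <- function(seed, rate = 0) {
  set.seed(seed)
  nE <- sample(3:5, 1)
  lens <- sample(10:30, nE, replace = TRUE)
  nPat <- sample(2:4, 1)
  pats <- list()
  keys <- character()
  while (length(pats) < nPat) {
    p <- as.logical(stats::rbinom(nE, 1, 0.6))
    if (!any(p)) next
    key <- paste(as.integer(p), collapse = "")
    if (key %in% keys) next
    pats[[length(pats) + 1L]] <- p
    keys <- c(keys, key)
  }
  synthSpec(nE, lens, pats, substitutionRate = rate,
            seed = (seed * 37L) %% 100000L + 1L)
}

# full pipeline on one synthetic spec -> recovery of the true classes
pipelineRecovery <- function(spec) {
  dat <- generateGroup(spec)
  sim <- similarityMatrix(alignGroup(dat$group))
  recoveryScore(subclusterGroup(dat$group, sim), dat$truth)
}
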