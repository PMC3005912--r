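test_that("signature vectors span the sorted group universe", {
  a <- data.frame(isoform_id = c("p1", "p1", "p2"),
                  signature_accession = c("S2", "S1", "S1"))
  sv <- buildSignatureVectors(c("p1", "p2", "p3"), a)
  expect_equal(colnames(sv), c("S1", "S2"))
  expect_equal(unname(sv["p1", ]), c(1L, 1L))
  expect_equal(unname(sv["p2", ]), c(1L, 0L))
  expect_equal(unname(sv["p3", ]), c(0L, 0L))   # no assignments -> all zero

  empty <- buildSignatureVectors(c("p1", "p2"),
                                 data.frame(isoform_id = character(),
                                            signature_accession = character()))
  expect_equal(ncol(empty), 0)
})

test_that("the printed bit-pattern fixture reproduces its Hamming distances", {
  bits <- loadTable3()
  sv <- buildSignatureVectors(bits$isoform_id[bits$gene == "SYNE1"],
                              bitsToAssignments(bits[bits$gene == "SYNE1", ]))
  expect_equal(ncol(sv), 17)
  # reconstructed vectors equal the printed patterns
  printed <- function(id) as.integer(strsplit(
    bits$bits[bits$isoform_id == id], "")[[1]])
  for (id in rownames(sv))
    expect_equal(unname(sv[id, order(as.integer(sub(".*_S", "",
                                                    colnames(sv))))]),
                 printed(id), info = id)
  # cluster-1 (all ones) vs cluster-2 pattern: eight zero positions
  expect_equal(diffFunc(sv["ENSP00000265368", ], sv["ENSMUSP00000093587", ]),
               8)
  # within printed clusters the distance is 0, and clusters 2 and 3 agree
  expect_equal(diffFunc(sv["ENSMUSP00000093587", ], sv["ENSP00000318783", ]),
               0)
  expect_equal(diffFunc(sv["ENSP00000318783", ], sv["ENSP00000356225", ]), 0)
})

test_that("the functional difference is a metric on binary vectors", {
  expect_equal(diffFunc(c(S1 = 1, S2 = 0, S3 = 1), c(S1 = 0, S2 = 1, S3 = 1)),
               2)
  expect_error(diffFunc(c(S1 = 1), c(S2 = 1)), "universes")
  set.seed(5)
  for (rep in 1:30) {
    u <- paste0("S", 1:6)
    v1 <- stats::setNames(rbinom(6, 1, 0.5), u)
    v2 <- stats::setNames(rbinom(6, 1, 0.5), u)
    v3 <- stats::setNames(rbinom(6, 1, 0.5), u)
    expect_gte(diffFunc(v1, v2), 0)
    expect_equal(diffFunc(v1, v2) == 0, identical(unname(v1), unname(v2)))
    expect_equal(diffFunc(v1, v2), diffFunc(v2, v1))
    expect_lte(diffFunc(v1, v3), diffFunc(v1, v2) + diffFunc(v2, v3))
  }
})

makeClustering <- function(parts, species) {
  clusters <- list()
  for (i in seq_along(parts)) {
    mem <- parts[[i]]
    if (length(mem) == 1L)
      clusters[[i]] <- new("SubCluster", clusterIndex = as.integer(i),
                           anchorA = character(), anchorB = character(),
                           anchorScore = numeric(), members = mem,
                           memberSpecies = unname(species[mem]))
    else
      clusters[[i]] <- new("SubCluster", clusterIndex = as.integer(i),
                           anchorA = mem[1], anchorB = mem[2],
                           anchorScore = 1, members = mem,
                           memberSpecies = unname(species[mem]))
  }
  new("GroupClustering", groupId = "G", isoformIds = unlist(parts),
      clusters = clusters)
}

test_that("intra/inter averages split the pairs of the group", {
  species <- stats::setNames(c("A", "B", "A"), c("a1", "a2", "b1"))
  gc <- makeClustering(list(c("a1", "a2"), "b1"), species)
  vecs <- rbind(a1 = c(1, 1, 0), a2 = c(1, 1, 0), b1 = c(0, 0, 1))
  colnames(vecs) <- paste0("S", 1:3)
  pd <- function(x, y) diffFunc(vecs[x, ], vecs[y, ])
  s <- groupDiffSummary(gc, pd, measure = "func")
  expect_equal(s@intraMean, 0)
  expect_equal(s@nIntraPairs, 1)
  expect_equal(s@interMean, 3)
  expect_equal(s@nInterPairs, 2)
  # totals: all C(3,2) pairs accounted for
  expect_equal(s@nIntraPairs + s@nInterPairs, choose(3, 2))
})

test_that("all-singleton clusterings have an undefined intra mean", {
  species <- stats::setNames(c("A", "B"), c("a1", "b1"))
  gc <- makeClustering(list("a1", "b1"), species)
  s <- groupDiffSummary(gc, function(x, y) 2, measure = "func")
  expect_true(is.na(s@intraMean))
  expect_equal(s@interMean, 2)
})

test_that("groups with no differences anywhere are flagged excluded", {
  species <- stats::setNames(c("A", "B", "A"), c("a1", "a2", "b1"))
  gc <- makeClustering(list(c("a1", "a2"), "b1"), species)
  s <- groupDiffSummary(gc, function(x, y) 0, measure = "func",
                        skipIfAllEqual = TRUE)
  expect_true(s@excluded)
  s2 <- groupDiffSummary(gc, function(x, y) 0, measure = "func",
                         skipIfAllEqual = FALSE)
  expect_false(s2@excluded)
})

test_that("exon-determined signatures separate cleanly across true clusters", {
  spec <- synthSpec(nExons = 4, exonLengths = rep(12, 4),
                    patterns = list("1100", "1111", "1010"),
                    substitutionRate = 0, seed = 21)
  dat <- generateGroup(spec)
  gc <- subclusterGroup(dat$group, similarityMatrix(alignGroup(dat$group)))
  sv <- buildSignatureVectors(dat$group, dat$signatures)
  s <- groupDiffSummary(gc, function(x, y) diffFunc(sv[x, ], sv[y, ]),
                        measure = "func")
  expect_equal(s@intraMean, 0)
  expect_gt(s@interMean, 0)
})
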