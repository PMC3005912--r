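test_that("pairwise alignment of identical and trivial inputs", {
  pa <- alignPair("MKV", "MKV")
  expect_equal(pa$aligned1, "MKV")
  expect_equal(pa$aligned2, "MKV")

  pa2 <- alignPair("A", "W")
  expect_equal(nchar(pa2$aligned1), 1)
  expect_equal(pa2$score, blosum62["A", "W"])

  pa3 <- alignPair("MKV", "MV")
  expect_equal(sum(strsplit(pa3$aligned2, "")[[1]] == "-"), 1)
  expect_equal(pa3$score,
               exhaustiveAlignOracle("MKV", "MV", blosum62))

  expect_error(alignPair("MKV", "M#V"), "invalid residue")
  expect_error(alignPair("", "MV"), "non-empty")
})

test_that("pairwise score equals exhaustive enumeration on short sequences", {
  set.seed(42)
  alpha <- c("A", "C", "D")
  for (rep in 1:40) {
    s1 <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    pa <- alignPair(s1, s2)
    expect_equal(pa$score, exhaustiveAlignOracle(s1, s2, blosum62),
                 info = paste(s1, s2))
    # reported alignment scores what it claims
    expect_equal(scoreAlignmentOracle(pa$aligned1, pa$aligned2, blosum62),
                 pa$score, info = paste(s1, s2))
    # stripping gaps recovers the inputs
    expect_equal(gsub("-", "", pa$aligned1), s1)
    expect_equal(gsub("-", "", pa$aligned2), s2)
  }
})

test_that("pairwise score agrees with an independent aligner", {
  # Biostrings charges open + k*extend per k-long gap; with open 9 extend 1
  # that equals this package's open 10 + (k-1)*1 model
  set.seed(7)
  for (rep in 1:10) {
    s1 <- paste(sample(c("M", "K", "V", "L", "A", "E"),
                       sample(4:12, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(c("M", "K", "V", "L", "A", "E"),
                       sample(4:12, 1), replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      s1, s2, substitutionMatrix = blosum62,
      gapOpening = 9, gapExtension = 1, type = "global",
      scoreOnly = TRUE)
    expect_equal(alignPair(s1, s2)$score, ref, info = paste(s1, s2))
  }
})

test_that("progressive alignment of identical sequences is gap-free", {
  for (n in 2:5) {
    seqs <- stats::setNames(rep("MKVLAEWYHH", n), paste0("p", seq_len(n)))
    aln <- alignGroup(seqs)
    expect_equal(alignmentWidth(aln), 10)
    expect_false(any(grepl("-", alignedRows(aln), fixed = TRUE)))
  }
})

test_that("exon-skipping isoforms align with the extra exon gapped", {
  dat <- generateGroup(threeExonSpec(exonLength = 20, seed = 5))
  aln <- alignGroup(dat$group)
  rows <- alignedRows(aln)
  # stripping gaps reproduces every sequence
  expect_equal(unname(gsub("-", "", rows)),
               unname(as.character(isoformSequences(dat$group)))[
                 match(names(rows), isoformIds(dat$group))])
  # the two-exon isoforms carry a 20-column gap block for exon 3
  expect_equal(alignmentWidth(aln), 60)
  expect_equal(sum(strsplit(rows[["A.iso1"]], "")[[1]] == "-"), 20)
  expect_equal(sum(strsplit(rows[["A.iso2"]], "")[[1]] == "-"), 0)
  # projecting the two 2-exon isoforms drops the shared gap block
  proj <- projectPair(aln, "A.iso1", "B.iso1")
  expect_equal(projectionLength(proj), 40)
})

test_that("a two-isoform group reduces to the pairwise alignment", {
  g <- OrthologueGroup("G", c(a = "MKVLAE", b = "MKAE"),
                       geneId = c("ga", "gb"), species = c("A", "B"))
  aln <- alignGroup(g)
  pa <- alignPair("MKVLAE", "MKAE")
  expect_equal(unname(alignedRows(aln)), c(pa$aligned1, pa$aligned2))
})

test_that("ingesting an external alignment validates and round-trips", {
  dat <- generateGroup(threeExonSpec(seed = 9))
  aln <- alignGroup(dat$group)
  f <- tempfile(fileext = ".fasta")
  writeAlignment(aln, f)
  back <- ingestAlignment(f, dat$group)
  expect_equal(alignedRows(back), alignedRows(aln))

  # a row that does not gap-strip to the stored sequence is fatal
  rows <- alignedRows(aln)
  rows[1] <- sub("^.", "W", rows[1])
  bad <- tempfile(fileext = ".fasta")
  writeFasta(rows, bad)
  expect_error(ingestAlignment(bad, dat$group), names(rows)[1])

  # missing isoform is fatal
  miss <- tempfile(fileext = ".fasta")
  writeFasta(rows[-1], miss)
  expect_error(ingestAlignment(miss, dat$group), "missing")
})

test_that("all-gap columns in external alignments are removed", {
  g <- OrthologueGroup("G", c(a = "MK", b = "MK"),
                       geneId = c("ga", "gb"), species = c("A", "B"))
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "M-K", ">b", "M-K"), f)
  expect_message(aln <- ingestAlignment(f, g), "all-gap")
  expect_equal(alignmentWidth(aln), 2)
})
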