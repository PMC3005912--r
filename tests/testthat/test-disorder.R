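test_that("score tracks threshold into maximal disorder runs", {
  r <- scoresToRegions(c(0.9, 0.9, 0.1, 0.9))
  expect_equal(IRanges::start(r), c(1, 4))
  expect_equal(IRanges::end(r), c(2, 4))
  expect_length(scoresToRegions(rep(0.1, 5)), 0)
  r2 <- scoresToRegions(rep(0.8, 7))
  expect_equal(c(IRanges::start(r2), IRanges::end(r2)), c(1, 7))
  # threshold is inclusive (a 0.5 residue is called disordered)
  expect_length(scoresToRegions(c(0.5, 0.5)), 1)
})

test_that("regions merge across short separations before length filtering", {
  ir <- function(s, e) IRanges::IRanges(start = s, end = e)
  # a lone short region is dropped
  expect_length(filterRegions(ir(1, 5)), 0)
  # separation 1 (< 3) merges; the merged region survives the length filter
  m <- filterRegions(ir(c(1, 14), c(12, 25)))
  expect_equal(IRanges::start(m), 1)
  expect_equal(IRanges::end(m), 25)
  # separation 3 does not merge
  k <- filterRegions(ir(c(1, 20), c(12, 35)))
  expect_length(k, 2)
  # merge-first rescues two sub-threshold fragments ...
  resc <- filterRegions(ir(c(1, 8), c(6, 14)))
  expect_length(resc, 1)
  # ... which filter-first would discard
  expect_length(filterRegions(ir(c(1, 8), c(6, 14)), mergeFirst = FALSE), 0)
  # malformed input is fatal
  expect_error(filterRegions(ir(c(10, 1), c(20, 5))), "sorted")
  expect_error(filterRegions(ir(c(1, 5), c(10, 20))), "overlap")
})

test_that("region filtering is idempotent and monotone in its parameters", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    starts <- sort(sample(1:300, n))
    ends <- starts + sample(0:40, n, replace = TRUE)
    # make non-overlapping
    keep <- c(TRUE, starts[-1] > cummax(ends)[-n])
    ir <- IRanges::IRanges(start = starts[keep], end = ends[keep])
    out <- filterRegions(ir)
    expect_equal(filterRegions(out), out)
    expect_lte(length(out), length(ir))
    # monotone non-increasing region count in minLen and mergeGap
    nAt <- function(ml, mg) length(filterRegions(ir, minLen = ml,
                                                 mergeGap = mg))
    expect_true(all(diff(sapply(c(1, 5, 10, 20), function(ml)
      nAt(ml, 3))) <= 0))
    # merging alone is monotone in the gap (the length filter can interact
    # with merging, so it is held at 1 here)
    expect_true(all(diff(sapply(c(1, 3, 8, 15), function(mg)
      nAt(1, mg))) <= 0))
  }
})

test_that("disorder difference and fraction recompute the printed table", {
  t4 <- loadTable4()
  profiles <- lapply(seq_len(nrow(t4)), function(i)
    profileFromCounts(t4$isoform_id[i], t4$n_regions[i], t4$total_len[i],
                      t4$protein_len[i]))
  names(profiles) <- t4$isoform_id
  # reconstructed profiles carry the printed counts and lengths
  expect_equal(vapply(profiles, nRegions, integer(1), USE.NAMES = FALSE),
               t4$n_regions)
  expect_equal(vapply(profiles, totalDisorderLength, integer(1),
                      USE.NAMES = FALSE), t4$total_len)
  # disorder fractions match the printed percentages at printed precision
  frac <- vapply(profiles, disorderFraction, numeric(1), USE.NAMES = FALSE)
  expect_equal(round(100 * frac, 1), t4$printed_pct)
  # region-count differences are plain absolute differences
  expect_equal(diffDis(profiles[["ENSMUSP00000093587"]],
                       profiles[["ENSMUSP00000039440"]]), 7)
  expect_equal(diffDis(profiles[["ENSP00000318783"]],
                       profiles[["ENSP00000318783"]]), 0)
})

test_that("the disorder difference is a pseudometric", {
  p <- lapply(c(0, 3, 5), function(n)
    profileFromCounts("x", n, n * 15, 200))
  expect_equal(diffDis(p[[1]], p[[3]]), 5)
  expect_equal(diffDis(p[[2]], p[[3]]), diffDis(p[[3]], p[[2]]))
  expect_lte(diffDis(p[[1]], p[[3]]),
             diffDis(p[[1]], p[[2]]) + diffDis(p[[2]], p[[3]]))
})

test_that("profiles can be built from scores or intervals with the filters", {
  sc <- c(rep(0.9, 12), 0.1, 0.2, rep(0.95, 11), rep(0.05, 20), rep(0.8, 4))
  p <- disorderProfile("p1", scores = sc)
  # two 0.9-runs separated by 2 residues merge into one region; the
  # trailing 4-residue run is dropped
  expect_equal(nRegions(p), 1)
  expect_equal(totalDisorderLength(p), 25)
  expect_equal(p@proteinLen, length(sc))

  expect_error(disorderProfile("p1"), "exactly one")
  expect_error(disorderProfile("p1", regions = IRanges::IRanges(1, 30),
                               proteinLen = 20), "beyond")
})
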