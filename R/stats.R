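#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample location comparison used to contrast intra- versus
#' inter-sub-cluster difference distributions.  Ties are handled with
#' midranks.  The null distribution is exact (full permutation) when
#' `n1 + n2 <= exactLimit` and the data are tie-free, otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.  P-values come from [stats::wilcox.test()]; the U statistic and the
#' tie-corrected z deviate are computed alongside for reporting.
#'
#' @param x,y numeric samples (both non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   referring to the location of `x` relative to `y`.
#' @param exactLimit largest `n1 + n2` for which the exact null is used
#'   (default 12).
#' @return a [RankSumResult-class].
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))
#' @export
rankSumTest <- function(x, y, alternative = c("two.sided", "greater", "less"),
                        exactLimit = 12) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  exact <- (n1 + n2 <= exactLimit) && !ties

  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  z <- NA_real_
  if (!exact) {
    mu <- n1 * n2 / 2
    tieTab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      (n1 + n2 + 1 - sum(tieTab^3 - tieTab) / ((n1 + n2) * (n1 + n2 - 1)))
    cc <- switch(alternative,
                 two.sided = sign(U - mu) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- if (sigma2 == 0) 0 else (U - mu - cc) / sqrt(sigma2)
    if (sigma2 == 0 || (alternative == "two.sided" && U == mu)) z <- 0
  }

  p <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact,
    correct = TRUE)$p.value)
  p <- min(1, max(p, .Machine$double.xmin))

  new("RankSumResult", n1 = as.integer(n1), n2 = as.integer(n2),
      U = U, z = z, p = p,
      method = if (exact) "exact" else "normal_approx")
}

#' Compare intra vs inter difference distributions across groups
#'
#' Gathers the per-group intra and inter means of one measure from a list of
#' [GroupDiffSummary-class] objects, drops excluded groups and undefined
#' sides, and runs [rankSumTest()] on the two distributions.
#'
#' @param summaries list of `GroupDiffSummary` (one measure).
#' @param alternative passed to [rankSumTest()].
#' @return a list (JSON-serialisable) with elements `measure`, `n_groups`,
#'   `n_excluded`, `intra` (values, n, mean), `inter` (values, n, mean) and
#'   `test` (U, z, p, method).
#' @export
compareMeasures <- function(summaries, alternative = "two.sided") {
  if (length(summaries) == 0L) stop("no summaries supplied")
  measure <- unique(vapply(summaries, function(s) s@measure, character(1)))
  if (length(measure) != 1L)
    stop("summaries mix measures: ", paste(measure, collapse = ", "))
  excluded <- vapply(summaries, function(s) s@excluded, logical(1))
  kept <- summaries[!excluded]
  intra <- vapply(kept, function(s) s@intraMean, numeric(1))
  inter <- vapply(kept, function(s) s@interMean, numeric(1))
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (length(intra) == 0L)
    stop("no group has a defined intra mean")
  if (length(inter) == 0L)
    stop("no group has a defined inter mean")
  test <- rankSumTest(intra, inter, alternative = alternative)
  list(measure = measure,
       n_groups = length(summaries),
       n_excluded = sum(excluded),
       intra = list(values = unname(intra), n = length(intra),
                    mean = mean(intra)),
       inter = list(values = unname(inter), n = length(inter),
                    mean = mean(inter)),
       test = list(U = test@U, z = test@z, p = test@p,
                   method = test@method))
}
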