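test_that("substitutions classify into match, transition, transversion", {
  expect_equal(classifyPair("A", "G"), "transition")
  expect_equal(classifyPair("G", "A"), "transition")
  expect_equal(classifyPair("C", "T"), "transition")
  expect_equal(classifyPair("A", "A"), "match")
  expect_equal(classifyPair("A", "C"), "transversion")
  expect_equal(classifyPair("g", "a"), "transition")  # case-folded
  expect_equal(classifyPair(c("A", "T", "C"), c("G", "T", "A")),
               c("transition", "match", "transversion"))
  expect_equal(classifyPair("N", "A"), "transversion")
  expect_error(classifyPair("-", "A"), "gap")
})

test_that("fragment constructor checks row/coordinate consistency", {
  expect_s3_class(genomeFragment("a", 1, 4, "+", "AC-GT",
                                 "b", 1, 5, "+", "ACTGT"),
                  "genomeFragment")
  expect_error(genomeFragment("a", 1, 5, "+", "AC-GT",
                              "b", 1, 5, "+", "ACTGT"), "A coordinates")
  expect_error(genomeFragment("a", 1, 4, "+", "AC-GT",
                              "b", 1, 5, "+", "ACT"), "lengths")
})

identityFragment <- function(seq, chromA = "gA", chromB = "gB") {
  genomeFragment(chromA, 1, nchar(seq), "+", seq,
                 chromB, 1, nchar(seq), "+", seq)
}

test_that("identical hits through a gapless identical fragment give 4 equal rows", {
  f <- identityFragment("ACGTACGT")
  p <- buildPileup(list(start = 1, end = 8), list(start = 1, end = 8), f)
  expect_equal(length(p$elementA), 8)
  expect_identical(p$elementA, p$elementB)
  expect_identical(p$elementA, p$genomeA)
  ta <- transitiveAlign(p)
  expect_equal(unname(ta$tallies["matches"]), 8)
  expect_equal(ta$score, 8)
  expect_equal(unname(ta$tallies["transversions"] + ta$tallies["gaps"]), 0)
})

test_that("toy element pairs tally as hand-classified", {
  # elements ACGT vs ACGA through a gapless fragment: 3 matches + 1 A-T...
  # final column T vs A is a transversion; score 3
  f <- genomeFragment("gA", 1, 4, "+", "ACGT", "gB", 1, 4, "+", "ACGA")
  ta <- transitiveAlign(buildPileup(list(start = 1, end = 4),
                                    list(start = 1, end = 4), f))
  expect_equal(unname(ta$tallies[c("matches", "transitions", "transversions")]),
               c(3, 0, 1))
  expect_equal(ta$score, 3)

  f2 <- genomeFragment("gA", 1, 2, "+", "AG", "gB", 1, 2, "+", "GG")
  ta2 <- transitiveAlign(buildPileup(list(start = 1, end = 2),
                                     list(start = 1, end = 2), f2))
  expect_equal(unname(ta2$tallies[c("matches", "transitions")]), c(1, 1))
  expect_equal(ta2$score, 2)
})

test_that("genome-gap columns become dot-gaps and are excluded from tallies", {
  # column 3 is gapped in genome B: element A shows lowercase, element B a dot
  f <- genomeFragment("gA", 1, 5, "+", "ACGTA", "gB", 1, 4, "+", "AC-TA")
  ta <- transitiveAlign(buildPileup(list(start = 1, end = 5),
                                    list(start = 1, end = 4), f))
  expect_equal(unname(ta$tallies["dotgaps"]), 1)
  expect_equal(ta$elementA[3], "g")
  expect_equal(ta$elementB[3], ".")
  expect_equal(sum(ta$tallies[c("matches", "transitions", "transversions",
                                "gaps")]), 4)
})

test_that("hit extensions beyond the covered region count as plain gaps", {
  f <- identityFragment("ACGTACGT")
  ta <- transitiveAlign(buildPileup(list(start = 1, end = 8),
                                    list(start = 3, end = 6), f))
  expect_equal(unname(ta$tallies["matches"]), 4)
  expect_equal(unname(ta$tallies["gaps"]), 4)       # flanking columns
  expect_equal(length(ta$classes), 8)
})

test_that("non-overlapping hits give an empty pileup and empty alignment", {
  f <- identityFragment("ACGT")
  p <- buildPileup(list(start = 100, end = 120), list(start = 1, end = 4), f)
  expect_equal(length(p$elementA), 0)
  ta <- transitiveAlign(p)
  expect_equal(ta$score, 0)
  expect_equal(length(ta$classes), 0)
})

test_that("tally conservation holds on fuzzed pileups", {
  set.seed(1234)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    w <- sample(4:20, 1)
    rowA <- sample(c(alphabet, "-"), w, replace = TRUE, prob = c(rep(.22, 4), .12))
    rowB <- sample(c(alphabet, "-"), w, replace = TRUE, prob = c(rep(.22, 4), .12))
    both <- rowA == "-" & rowB == "-"
    rowA[both] <- "A"                       # all-gap columns are meaningless
    nA <- sum(rowA != "-"); nB <- sum(rowB != "-")
    if (nA == 0 || nB == 0) next
    f <- genomeFragment("gA", 1, nA, "+", paste0(rowA, collapse = ""),
                        "gB", 1, nB, "+", paste0(rowB, collapse = ""))
    hitA <- sort(sample.int(nA, 2, replace = TRUE))
    hitB <- sort(sample.int(nB, 2, replace = TRUE))
    ta <- transitiveAlign(buildPileup(list(start = hitA[1], end = hitA[2]),
                                      list(start = hitB[1], end = hitB[2]), f))
    expect_equal(sum(ta$tallies[c("matches", "transitions", "transversions",
                                  "gaps")]),
                 sum(ta$classes != "dotgap"))
    expect_equal(ta$score,
                 unname(ta$tallies["matches"] + ta$tallies["transitions"]))
  }
})

test_that("hit-set evaluation totals alignments fragment-wise and dedupes", {
  f1 <- identityFragment("ACGTACGT")
  f2 <- genomeFragment("gA", 21, 24, "+", "GGCC", "gB", 51, 54, "+", "GACC")
  hitsA <- data.frame(target = "gA", start = c(1, 21), end = c(8, 24))
  hitsB <- data.frame(target = "gB", start = c(1, 51), end = c(8, 54))
  ev <- evaluateHitsets(hitsA, hitsB, list(f1, f2))
  expect_equal(ev$summary$nTransitive, 2)
  expect_equal(ev$summary$matches, 8 + 3)
  expect_equal(ev$summary$transitions, 0 + 1)
  expect_equal(ev$summary$score, 12)
  # duplicated fragments collapse
  ev2 <- evaluateHitsets(hitsA, hitsB, list(f1, f2, f1, f2))
  expect_equal(ev2$summary, ev$summary)
  # disjoint hit sets produce nothing
  ev0 <- evaluateHitsets(hitsA[0, ], hitsB, list(f1, f2))
  expect_equal(ev0$summary$nTransitive, 0)
  expect_equal(ev0$summary$score, 0)
})

test_that("evaluation is symmetric in the two genomes", {
  f1 <- genomeFragment("gA", 1, 5, "+", "ACG-TT", "gB", 11, 16, "+", "ACGATT")
  hitsA <- data.frame(target = "gA", start = 1, end = 6)
  hitsB <- data.frame(target = "gB", start = 12, end = 16)
  ev <- evaluateHitsets(hitsA, hitsB, list(f1))
  evSwap <- evaluateHitsets(hitsB, hitsA, list(swapFragment(f1)))
  expect_equal(evSwap$summary, ev$summary)
})

test_that("rendering shows the annotation alphabet and the footer statistics", {
  f <- genomeFragment("gA", 1, 5, "+", "ACGTA", "gB", 1, 4, "+", "AC-TT")
  ta <- transitiveAlign(buildPileup(list(start = 1, end = 5),
                                    list(start = 1, end = 4), f))
  txt <- renderTransitiveAlignment(ta)
  expect_true(any(grepl("^elementA", txt)))
  expect_true(any(grepl("matches: ", txt)))
  expect_true(any(grepl("\\.", txt)))   # the dot-gap column is rendered
})
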