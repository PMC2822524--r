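test_that("single-path deterministic models give the hand-computed likelihood", {
  m1 <- onePositionModel(pA = 1)
  expect_equal(forwardValues(m1, "A")$loglik, 0, tolerance = 1e-6)
  mHalf <- onePositionModel(pA = .5)
  expect_equal(exp(forwardValues(mHalf, "A")$loglik), .5, tolerance = 1e-6)
})

test_that("forward, backward, posteriors and counts match exhaustive path enumeration", {
  cases <- expand.grid(local = c(FALSE, TRUE), n = 1:3, K = 1:4)
  for (i in seq_len(nrow(cases))) {
    local <- cases$local[i]; n <- cases$n[i]; K <- cases$K[i]
    m <- randomModel(n, local, seed = 1000 + i)
    s <- randomDnaString(K, seed = i)
    o <- oracleEnumerate(m, s)
    f <- forwardValues(m, s)
    b <- backwardValues(m, s, f)
    post <- posteriorStates(m, s, f, b)
    expect_equal(f$loglik, o$loglik, tolerance = 1e-10)
    expect_equal(b$Lhat, f$Lhat, tolerance = 1e-10)
    expect_equal(post$M, o$postM, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(post$I, o$postI, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(post$D, o$postD, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("forward-backward identity holds at every time point", {
  for (r in 1:10) {
    m <- randomModel(4, r %% 2 == 0, seed = r)
    s <- randomDnaString(6, seed = r + 30)
    f <- forwardValues(m, s)
    b <- backwardValues(m, s, f)
    for (tau in 1:6) {
      cut <- sum(f$M[tau + 1, ] * b$M[tau + 1, ] +
                 f$I[tau + 1, ] * b$I[tau + 1, ])
      expect_equal(cut, f$Lhat, tolerance = 1e-10)
    }
  }
})

test_that("posteriors over emitting states sum to one at each emitted residue", {
  m <- randomModel(5, FALSE, seed = 7)
  s <- randomDnaString(8, seed = 7)
  post <- posteriorStates(m, s)
  sums <- rowSums(post$M[-1, ]) + rowSums(post$I[-1, ])
  expect_equal(sums, rep(1, 8), tolerance = 1e-10)
})

test_that("posterior weights competing alignments by their path probabilities", {
  # 2-position model emitting one residue: M1 (with D2) or M2 (via D1)
  ME <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0), 2, 4, byrow = TRUE)
  TR <- matrix(c(.5, .25, .25, 0, .5, .5, .5, .5), 2, 8, byrow = TRUE)
  m <- newProfileHMM(ME, rep(.25, 4), TR, c(.5, .5, 0), numeric(4),
                     validate = FALSE)
  post <- posteriorStates(m, "A")
  # hand enumeration: B->M1->D2->E weighs .5*1*.25*.5 = .0625;
  # B->D1->M2->E weighs .5*.5*1*(.5+.25) = .1875; posterior ratio 1:3
  expect_equal(post$M[2, 1] / post$M[2, 2], 1 / 3, tolerance = 1e-10)
  expect_equal(sum(post$M[2, ]), 1, tolerance = 1e-10)
})

test_that("residues outside the alphabet raise an error naming the position", {
  m <- buildPlan7(3)
  expect_error(forwardValues(m, "ACXG"), "position 3")
})

test_that("the ambiguity code N emits neutrally", {
  m <- randomModel(3, FALSE, seed = 11)
  expect_silent(f <- forwardValues(m, "ANG"))
  expect_true(is.finite(f$loglik))
})

test_that("row-wise forward recomputation matches a from-scratch pass", {
  set.seed(42)
  for (r in 1:20) {
    n <- sample(3:8, 1)
    m <- randomModel(n, FALSE, seed = 500 + r)
    s <- randomDnaString(sample(4:10, 1), seed = 600 + r)
    f <- forwardValues(m, s)
    # perturb parameters at one position, renormalizing the groups
    p <- sample(seq_len(n), 1)
    m2 <- m
    em <- m2@matchEmissions[p, ] + runif(4, 0, .5)
    m2@matchEmissions[p, ] <- em / sum(em)
    upd <- forwardRows(m2, s, f, fromPosition = p)
    scratch <- forwardValues(m2, s)
    expect_equal(upd$loglik, scratch$loglik, tolerance = 1e-12)
  }
})

test_that("row-wise recomputation without a parameter change is stable", {
  # the column-wise kernel orders the deletion-chain arithmetic differently
  # from the time-major pass, so agreement is to rounding, not bitwise
  m <- randomModel(5, TRUE, seed = 77)
  s <- randomDnaString(7, seed = 77)
  f <- forwardValues(m, s)
  again <- forwardRows(m, s, f, fromPosition = 3)
  expect_equal(again$M, f$M, tolerance = 1e-13)
  expect_equal(again$I, f$I, tolerance = 1e-13)
  expect_equal(again$D, f$D, tolerance = 1e-13)
  expect_equal(again$loglik, f$loglik, tolerance = 1e-13)
})

test_that("row-wise restart from the first position equals the full pass", {
  m <- randomModel(4, FALSE, seed = 13)
  s <- randomDnaString(6, seed = 13)
  f <- forwardValues(m, s)
  blank <- f
  blank$M[] <- 0; blank$I[] <- 0; blank$D[] <- 0
  redone <- forwardRows(m, s, blank, fromPosition = 1)
  expect_equal(redone$M, f$M, tolerance = 1e-12)
  expect_equal(redone$loglik, f$loglik, tolerance = 1e-12)
})

test_that("forwardRows rejects positions outside the model", {
  m <- randomModel(3, FALSE, seed = 1)
  s <- "ACG"
  f <- forwardValues(m, s)
  expect_error(forwardRows(m, s, f, fromPosition = 0), "position")
  expect_error(forwardRows(m, s, f, fromPosition = 4), "position")
})

test_that("local Viterbi recovers a planted consensus copy", {
  set.seed(5)
  truth <- sampleTrueProfile(30, .95, seed = 5)
  m <- localScanModel(matchEmissions(truth$model))
  flank <- function(k, seed) randomDnaString(k, seed)
  target <- paste0(flank(40, 1), truth$consensus, flank(40, 2))
  hit <- viterbiLocal(m, target)
  expect_lte(abs(hit$start - 41), 2)
  expect_lte(abs(hit$end - 70), 2)
  expect_gt(hit$score, 0)
})

test_that("local Viterbi is deterministic and handles empty input", {
  m <- buildPlan7(4, localMode = TRUE)
  h1 <- viterbiLocal(m, "ACGTACGT")
  h2 <- viterbiLocal(m, "ACGTACGT")
  expect_identical(h1, h2)
  h0 <- viterbiLocal(m, "")
  expect_identical(h0$score, -Inf)
  expect_equal(nrow(h0$path), 0)
  expect_error(viterbiLocal(buildPlan7(4), "ACGT"), "local")
})
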