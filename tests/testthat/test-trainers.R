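test_that("expected counts on a deterministic single-path model count emissions once", {
  m <- railModel("AC", eps = 1e-12)
  ec <- expectedCounts(m, "AC")
  expect_equal(unname(ec$ME[1, "A"]), 1, tolerance = 1e-9)
  expect_equal(unname(ec$ME[2, "C"]), 1, tolerance = 1e-9)
  expect_equal(sum(ec$ME), 2, tolerance = 1e-9)
  expect_equal(unname(ec$TR[1, "MM"]), 1, tolerance = 1e-9)
})

test_that("aggregate counts are the sum of per-sequence counts", {
  m <- randomModel(3, FALSE, seed = 2)
  seqs <- c(s1 = "ACGT", s2 = "GGA")
  both <- expectedCounts(m, seqs)
  one <- expectedCounts(m, seqs[1])
  two <- expectedCounts(m, seqs[2])
  expect_equal(both$ME, one$ME + two$ME, tolerance = 1e-10)
  expect_equal(both$TR, one$TR + two$TR, tolerance = 1e-10)
  expect_equal(both$IE, one$IE + two$IE, tolerance = 1e-10)
  expect_equal(both$perSeqIns[1, ], one$perSeqIns[1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("expected counts match path-enumeration expected usages", {
  for (i in 1:8) {
    m <- randomModel(3, i %% 2 == 0, seed = 40 + i)
    s <- randomDnaString(4, seed = 50 + i)
    o <- oracleEnumerate(m, s)
    ec <- expectedCounts(m, s)
    expect_equal(unname(ec$ME), o$counts$ME, tolerance = 1e-10)
    expect_equal(unname(ec$TR), o$counts$TR, tolerance = 1e-10)
    expect_equal(unname(ec$BG), o$counts$BG, tolerance = 1e-10)
    expect_equal(unname(ec$DIO), o$counts$DIO, tolerance = 1e-10)
    expect_equal(as.numeric(ec$perSeqIns), o$counts$ins, tolerance = 1e-10)
    expect_equal(as.numeric(ec$perSeqDel), o$counts$del, tolerance = 1e-10)
  }
})

test_that("the M-step normalizes counts with pseudocounts and enforces the floor", {
  m <- buildPlan7(1)
  ec <- expectedCounts(m, "A")
  ec$ME[1, ] <- c(3, 1, 0, 0)
  pr <- makePriors(m, "simulation")
  new <- maximizeStep(ec, m, pr, floor = 1e-5)
  expect_equal(unname(matchEmissions(new)[1, ]), c(4, 2, 1, 1) / 8,
               tolerance = 1e-9)

  # all-zero counts with uniform pseudocounts give the uniform distribution
  ec$ME[1, ] <- 0
  new0 <- maximizeStep(ec, m, pr, floor = 1e-5)
  expect_equal(unname(matchEmissions(new0)[1, ]), rep(.25, 4))

  # an extreme count is floored and the group still sums to one
  ec$ME[1, ] <- c(1e9, 0, 0, 0)
  pr0 <- pr; pr0$ME[] <- 1e-12
  newf <- maximizeStep(ec, m, pr0, floor = 1e-5)
  expect_true(all(matchEmissions(newf) >= 1e-5 - 1e-15))
  expect_equal(sum(matchEmissions(newf)), 1, tolerance = 1e-12)

  # zero counts with zero pseudocounts cannot be normalized
  prz <- pr; prz$ME[] <- 0
  ecz <- ec; ecz$ME[1, ] <- 0
  expect_error(maximizeStep(ecz, m, prz, floor = 1e-5), "degenerate")
})

test_that("convergence distance averages one euclidean norm per group", {
  m <- buildPlan7(3)
  expect_equal(convergenceDistance(m, m), 0)
  m2 <- m
  m2@matchEmissions[2, ] <- c(0, 1, 0, 0)  # from uniform: norm sqrt(4*.25^2+...)
  # groups: 3 emission + 9 transition + insert + begin = 14
  delta <- sqrt(sum((c(.25, .25, .25, .25) - c(0, 1, 0, 0))^2))
  expect_equal(convergenceDistance(m, m2), delta / 14, tolerance = 1e-12)
  expect_error(convergenceDistance(m, buildPlan7(4)), "shapes")
})

test_that("Baum-Welch increases the penalized objective every iteration", {
  for (r in 1:4) {
    truth <- sampleTrueProfile(8, .7, seed = r)
    seqs <- sampleSequences(truth$model, 8, seed = r + 10)
    start <- randomStartProfile(8, "simulation", seed = r + 20)
    fit <- bwTrain(start, seqs, maxIterations = 60)
    expect_gte(min(diff(fit$trace$logPosterior)), -1e-8)
  }
})

test_that("a fixed point of the update map is left unchanged", {
  truth <- sampleTrueProfile(6, .8, seed = 33)
  seqs <- sampleSequences(truth$model, 12, seed = 34)
  # converge fully, then verify one more iteration barely moves
  fit <- bwTrain(truth$model, seqs, maxIterations = 400,
                 convergenceTol = 1e-8)
  expect_true(fit$converged)
  ec <- expectedCounts(fit$model, seqs)
  pr <- makePriors(fit$model, "simulation")
  again <- maximizeStep(ec, fit$model, pr, 1e-5)
  expect_lt(convergenceDistance(fit$model, again), 1e-6)
})

test_that("training concentrates emissions on repeated consensus data", {
  seqs <- rep("ACGTACGTAT", 40)
  fit <- bwTrain(randomStartProfile(10, "simulation", seed = 3), seqs,
                 maxIterations = 200)
  ME <- matchEmissions(fit$model)
  cons <- strsplit("ACGTACGTAT", "")[[1]]
  hit <- ME[cbind(1:10, match(cons, dnaAlphabet()))]
  expect_true(all(hit > .9))
})

test_that("training is deterministic: identical inputs give identical traces", {
  truth <- sampleTrueProfile(10, .6, seed = 5)
  seqs <- sampleSequences(truth$model, 10, seed = 6)
  start <- randomStartProfile(10, "simulation", seed = 7)
  for (alg in c("BW", "CBW")) {
    f1 <- trainProfile(start, seqs, trainingConfig(alg, maxIterations = 25))
    f2 <- trainProfile(start, seqs, trainingConfig(alg, maxIterations = 25))
    expect_identical(f1$trace, f2$trace)
    expect_identical(matchEmissions(f1$model), matchEmissions(f2$model))
  }
})

test_that("a conditional sweep on a single-position model equals one BW iteration", {
  truth <- sampleTrueProfile(1, .8, seed = 9)
  seqs <- sampleSequences(truth$model, 6, seed = 10)
  start <- randomStartProfile(1, "simulation", seed = 11)
  b <- bwTrain(start, seqs, maxIterations = 1)
  c <- cbwTrain(start, seqs, maxIterations = 1)
  expect_equal(matchEmissions(c$model), matchEmissions(b$model),
               tolerance = 1e-9)
  expect_equal(transitions(c$model), transitions(b$model), tolerance = 1e-9)
})

test_that("every conditional update is monotone in the penalized objective", {
  for (r in 1:5) {
    truth <- sampleTrueProfile(6, .7, seed = 60 + r)
    seqs <- sampleSequences(truth$model, 6, seed = 70 + r)
    m <- randomStartProfile(6, "simulation", seed = 80 + r)
    pr <- makePriors(m, "simulation")
    before <- sum(cpp_loglik_for_tests(m, seqs)) + .dirichletPenaltyTest(m, pr)
    sw <- cbwSweepTracked(m, seqs, pr)
    expect_gte(min(diff(c(before, sw$objective))), -1e-8)
  }
})

test_that("the sweep trainer matches full-likelihood recomputation mid-sweep", {
  # the final tracked objective equals an independently recomputed one
  truth <- sampleTrueProfile(5, .7, seed = 91)
  seqs <- sampleSequences(truth$model, 5, seed = 92)
  m <- randomStartProfile(5, "simulation", seed = 93)
  pr <- makePriors(m, "simulation")
  sw <- cbwSweepTracked(m, seqs, pr)
  recomputed <- sum(cpp_loglik_for_tests(sw$model, seqs)) +
    .dirichletPenaltyTest(sw$model, pr)
  expect_equal(tail(sw$objective, 1), recomputed, tolerance = 1e-8)
})

test_that("surgery-assisted training recovers the consensus of a known profile", {
  # 100 sequences from a 20-position truth at conservation .8: the argmax
  # of the trained match emissions should match the consensus nearly
  # everywhere, averaged over seeds
  rates <- vapply(1:4, function(sd) {
    truth <- sampleTrueProfile(20, .8, seed = 400 + sd)
    seqs <- sampleSequences(truth$model, 100, seed = 500 + sd)
    start <- randomStartProfile(20, "simulation", seed = 600 + sd)
    fit <- trainProfile(start, seqs,
                        trainingConfig("CBW", useDMS = TRUE,
                                       maxIterations = 400))
    got <- strsplit(consensusSequence(fit$model), "")[[1]]
    want <- strsplit(truth$consensus, "")[[1]]
    if (length(got) != length(want)) return(0)
    mean(got == want)
  }, numeric(1))
  expect_gte(mean(rates), .9)
})
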