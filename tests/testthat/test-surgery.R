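usageFrom <- function(ins, del) {
  # build a counts-like object from per-sequence usage matrices
  list(perSeqIns = ins, perSeqDel = del)
}

test_that("usage fractions are exact exceedance counts", {
  ins <- matrix(c(.2, .2, .05, 0), 4, 1)
  del <- matrix(0, 4, 1)
  u <- positionUsage(usageFrom(ins, del), xi = .1)
  expect_equal(u$fIns, .5)
  expect_equal(u$fDel, 0)
  expect_error(positionUsage(list(perSeqIns = ins), .1), "missing")
})

test_that("randomized usage fractions match a direct per-sequence loop", {
  set.seed(8)
  ins <- matrix(runif(60, 0, .3), 10, 6)
  del <- matrix(runif(60, 0, .3), 10, 6)
  xi <- .12
  u <- positionUsage(usageFrom(ins, del), xi)
  for (j in 1:6) {
    expect_equal(u$fIns[j], sum(ins[, j] > xi) / 10)
    expect_equal(u$fDel[j], sum(del[, j] > xi) / 10)
  }
})

test_that("actions trigger at the configured sequence fractions", {
  cfg <- list(nuInsert = .5, nuDelete = .9)
  u <- data.frame(position = 1:4, fIns = c(.6, .2, 0, 0),
                  fDel = c(0, .95, .5, 0))
  acts <- decideActions(u, cfg)
  expect_equal(acts$kind, c("delete", "insert"))   # descending position
  expect_equal(acts$position, c(2, 1))

  none <- decideActions(data.frame(position = 1:3, fIns = c(.1, 0, .4),
                                   fDel = c(.2, 0, .8)), cfg)
  expect_equal(nrow(none), 0)
})

test_that("a deletion suppresses an insertion at the same position", {
  cfg <- list(nuInsert = .5, nuDelete = .5)
  u <- data.frame(position = 1:2, fIns = c(.9, 0), fDel = c(.9, 0))
  acts <- decideActions(u, cfg)
  expect_equal(nrow(acts), 1)
  expect_equal(acts$kind, "delete")
})

test_that("surgery adjusts length and leaves untouched positions bitwise intact", {
  m <- randomModel(4, FALSE, seed = 6)
  ins <- applySurgery(m, data.frame(kind = "insert", position = 2))
  expect_equal(modelLength(ins), 5)
  expect_identical(matchEmissions(ins)[c(1, 2), ], matchEmissions(m)[c(1, 2), ])
  expect_identical(matchEmissions(ins)[4:5, ], matchEmissions(m)[3:4, ])
  expect_identical(transitions(ins)[3, ], transitions(m)[2, ])  # copied group
  expect_equal(unname(matchEmissions(ins)[3, ]), rep(.25, 4))
  expect_equal(attr(ins, "earliestAffected"), 3L)

  del <- applySurgery(m, data.frame(kind = "delete", position = 2))
  expect_equal(modelLength(del), 3)
  expect_identical(matchEmissions(del)[1, ], matchEmissions(m)[1, ])
  expect_identical(matchEmissions(del)[2:3, ], matchEmissions(m)[3:4, ])

  # delete then re-insert restores the length
  back <- applySurgery(del, data.frame(kind = "insert", position = 1))
  expect_equal(modelLength(back), 4)
  expect_error(applySurgery(buildPlan7(1),
                            data.frame(kind = "delete", position = 1)),
               "length-1")
})

test_that("incremental DP repair after surgery equals a from-scratch pass", {
  m <- randomModel(6, FALSE, seed = 16)
  s <- randomDnaString(9, seed = 17)
  f <- forwardValues(m, s)
  for (kind in c("insert", "delete")) {
    m2 <- applySurgery(m, data.frame(kind = kind, position = 4))
    from <- attr(m2, "earliestAffected")
    # pad/truncate the stored columns to the new width, then repair rows
    K <- length(f$scales) - 1
    f2 <- f
    if (kind == "insert") {
      grow <- function(x) cbind(x[, 1:4], 0, x[, 5:6])
      f2$M <- grow(f$M); f2$I <- grow(f$I); f2$D <- grow(f$D)
    } else {
      f2$M <- f$M[, -4]; f2$I <- f$I[, -4]; f2$D <- f$D[, -4]
    }
    repaired <- forwardRows(m2, s, f2, fromPosition = from)
    scratch <- forwardValues(m2, s)
    expect_equal(repaired$loglik, scratch$loglik, tolerance = 1e-10)
    # stored values sit on different scale factors; compare unscaled
    unscale <- function(x) x$M * cumprod(x$scales)
    expect_equal(unscale(repaired), unscale(scratch), tolerance = 1e-10)
  }
})

test_that("cycles escalate the threshold; monotone histories do not", {
  cfg <- list(epsilon = .005, escalation = "fixed", cycleMemory = 20L)
  # period-2 length oscillation with actions
  sig <- c("100*", "101*", "100*", "101*")
  esc <- detectCycleAndEscalate(sig, cfg, xi = .01)
  expect_true(esc$escalated)
  expect_equal(esc$xi, .015)
  # strictly monotone growth never escalates
  expect_false(detectCycleAndEscalate(c("40*", "41*", "42*", "43*"), cfg,
                                      .01)$escalated)
  # quiet convergence (no actions) never escalates
  expect_false(detectCycleAndEscalate(c("50*", "50", "50"), cfg,
                                      .01)$escalated)
  # signatures before sinceIndex are forgotten
  expect_false(detectCycleAndEscalate(sig, cfg, .01, sinceIndex = 4L)$escalated)
})

test_that("adaptive escalation moves xi by the minimal fraction-changing amount", {
  cfg <- list(epsilon = .005, escalation = "adaptive", cycleMemory = 20L)
  counts <- matrix(c(.10, .12, .2), 1)
  esc <- detectCycleAndEscalate(c("5*", "6*", "5*"), cfg, xi = .11,
                                counts = counts)
  expect_true(esc$escalated)
  expect_equal(esc$xi, (.12 + .2) / 2)     # midpoint of the two smallest above
  one <- detectCycleAndEscalate(c("5*", "6*", "5*"), cfg, xi = .15,
                                counts = counts)
  expect_equal(one$xi, .2)                 # single count above: land on it
  none <- detectCycleAndEscalate(c("5*", "6*", "5*"), cfg, xi = .5,
                                 counts = counts)
  expect_false(none$escalated)
})

test_that("with usage below threshold, DMS training equals plain training", {
  seqs <- rep("ACGTACGT", 10)             # no indels anywhere
  start <- railModel("ACGTACGT", eps = 1e-4)
  plain <- cbwTrain(start, seqs, maxIterations = 10)
  dms <- trainProfile(start, seqs, trainingConfig("CBW", useDMS = TRUE,
                                                  maxIterations = 10))
  expect_identical(matchEmissions(plain$model), matchEmissions(dms$model))
  expect_identical(transitions(plain$model), transitions(dms$model))
  expect_equal(modelLength(dms$model), 8)
})

test_that("surgery never produces an invalid model", {
  set.seed(23)
  m <- randomModel(6, TRUE, seed = 23)
  for (i in 1:25) {
    kind <- sample(c("insert", "delete"), 1,
                   prob = c(.5 + .2 * (modelLength(m) < 4), .5))
    if (modelLength(m) == 1) kind <- "insert"
    j <- sample.int(modelLength(m), 1)
    m <- applySurgery(m, data.frame(kind = kind, position = j))
    expect_equal(nrow(validateProfile(m)), 0)
  }
})
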