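#' Dirichlet pseudocount priors for training
#'
#' In the simulation regime all free parameters get uninformative add-one
#' (Laplace) pseudocounts.  In the transposon regime the match emissions
#' keep add-one pseudocounts but the transition priors are the local-mode
#' starting values scaled by the initial profile length, reflecting their
#' repeated use across positions; the begin group keeps the unscaled
#' starting values and the insertion emission prior is the even
#' distribution.
#'
#' @param model a [ProfileHMM-class] (supplies length and mode).
#' @param regime \code{"simulation"} or \code{"transposon"}.
#' @param initialLength profile length used for transposon-regime scaling;
#'   defaults to the model's length.
#' @return list of pseudocount arrays (\code{ME}, \code{IE}, \code{TR},
#'   \code{BG}, \code{DIO}) with zeros at structurally disallowed cells.
#' @export
makePriors <- function(model, regime = c("simulation", "transposon"),
                       initialLength = modelLength(model)) {
  regime <- match.arg(regime)
  n <- modelLength(model)
  local <- isLocal(model)
  trMask <- c(1, 1, 1, as.numeric(local), 1, 1, 1, 1)
  bgMask <- c(1, 1, as.numeric(local))
  dioMask <- rep(as.numeric(local), 4)
  if (regime == "simulation") {
    list(ME = matrix(1, n, 4),
         IE = rep(1, 4),
         TR = matrix(trMask, n, 8, byrow = TRUE),
         BG = bgMask,
         DIO = dioMask)
  } else {
    start <- c(MM = .095, MI = .0025, MD = .0025, MDO = .9,
               IM = .5, II = .5, DM = .5, DD = .5)
    if (!local) {
      start[c("MM", "MI", "MD", "MDO")] <- c(.95, .025, .025, 0)
    }
    list(ME = matrix(1, n, 4),
         IE = rep(.25, 4),
         TR = matrix(start * trMask, n, 8, byrow = TRUE) * initialLength,
         BG = (if (local) c(.09, .01, .9) else c(.95, .05, 0)) * bgMask,
         DIO = c(.9999, .0001, .9999, .0001) * dioMask * initialLength)
  }
}

#' Training configuration
#'
#' Bundles the algorithm choice, priors, parameter floor, convergence
#' tolerance and the Dynamic Model Surgery settings.  The two regimes
#' mirror the package's two intended uses: \code{"simulation"} (convergence
#' tolerance 1e-5; surgery threshold starts at .01 and escalates by a fixed
#' .005; both surgery fractions .5) and \code{"transposon"} (tolerance
#' 1e-7; threshold starts at .1 with adaptive escalation; insertion
#' fraction .1, deletion fraction .9).
#'
#' @param algorithm \code{"BW"} (Baum-Welch) or \code{"CBW"} (Conditional
#'   Baum-Welch).
#' @param useDMS apply Dynamic Model Surgery during training?
#' @param regime prior/threshold preset, \code{"simulation"} or
#'   \code{"transposon"}.
#' @param parameterFloor minimum value enforced for every trained
#'   parameter (keeps EM away from absorbing zeros).
#' @param convergenceTol stop when the average per-group euclidean
#'   parameter distance falls below this.
#' @param maxIterations iteration cap.
#' @param priors optional pseudocount list as from [makePriors()]; built
#'   from the regime at training time when \code{NULL}.
#' @param dms optional overrides for the surgery settings, a list with any
#'   of \code{xi0}, \code{epsilon}, \code{nuInsert}, \code{nuDelete},
#'   \code{escalation} ("fixed" or "adaptive"), \code{cycleMemory},
#'   \code{maxActionsPerIteration} (structural changes applied per
#'   iteration) and \code{delay} (iterations before surgery engages,
#'   letting the expected counts sharpen away from the starting point).
#' @return list of class \code{plan7TrainingConfig}.
#' @export
trainingConfig <- function(algorithm = c("BW", "CBW"), useDMS = FALSE,
                           regime = c("simulation", "transposon"),
                           parameterFloor = 1e-5, convergenceTol = NULL,
                           maxIterations = 500L, priors = NULL, dms = list()) {
  algorithm <- match.arg(algorithm)
  regime <- match.arg(regime)
  if (is.null(convergenceTol))
    convergenceTol <- if (regime == "simulation") 1e-5 else 1e-7
  dmsDefault <- if (regime == "simulation")
    list(xi0 = .01, epsilon = .005, nuInsert = .5, nuDelete = .5,
         escalation = "fixed", cycleMemory = 20L,
         maxActionsPerIteration = 1L, delay = 2L)
  else
    list(xi0 = .1, epsilon = .005, nuInsert = .1, nuDelete = .9,
         escalation = "adaptive", cycleMemory = 20L,
         maxActionsPerIteration = 1L, delay = 2L)
  dmsDefault[names(dms)] <- dms
  stopifnot(parameterFloor > 0, parameterFloor < .25,
            dmsDefault$xi0 > 0,
            dmsDefault$nuInsert > 0, dmsDefault$nuInsert < 1,
            dmsDefault$nuDelete > 0, dmsDefault$nuDelete < 1)
  structure(list(algorithm = algorithm, useDMS = useDMS, regime = regime,
                 parameterFloor = parameterFloor,
                 convergenceTol = convergenceTol,
                 maxIterations = as.integer(maxIterations),
                 priors = priors, dms = dmsDefault),
            class = "plan7TrainingConfig")
}

#' Expected emission and transition counts (E-step)
#'
#' One full forward-backward pass over all sequences, accumulating for each
#' parameter the expected number of uses of the corresponding emission or
#' transition, given the current model.  Per-sequence expected insertion
#' and deletion usage per position is retained for Dynamic Model Surgery.
#'
#' @param model a [ProfileHMM-class].
#' @param seqs sequences (character vector or \code{DNAStringSet}).
#' @return list of class \code{plan7Counts}: aggregate arrays \code{ME},
#'   \code{IE}, \code{TR}, \code{BG}, \code{DIO}; matrices
#'   \code{perSeqIns}, \code{perSeqDel} (sequences x positions); and the
#'   per-sequence \code{loglik}.
#' @export
expectedCounts <- function(model, seqs) {
  codes <- .encodeSeqs(seqs)
  if (length(codes) == 0) stop("no sequences supplied")
  if (any(lengths(codes) == 0)) stop("empty sequences are not supported")
  res <- cpp_counts(.asCList(model), codes)
  dimnames(res$ME) <- list(NULL, model@alphabet)
  dimnames(res$TR) <- list(NULL, .TRANS_COLS)
  names(res$IE) <- model@alphabet
  names(res$BG) <- .BEGIN_NAMES
  names(res$DIO) <- .DIO_NAMES
  rownames(res$perSeqIns) <- rownames(res$perSeqDel) <- names(codes)
  class(res) <- "plan7Counts"
  res
}

# normalize counts + pseudocounts over the active cells, then floor and
# renormalize (twice, so the floor holds exactly)
.normGroup <- function(counts, pseudo, floor, active = rep(TRUE, length(counts))) {
  v <- numeric(length(counts))
  w <- counts[active] + pseudo[active]
  s <- sum(w)
  if (!(s > 0)) stop("degenerate update: zero counts and zero pseudocounts")
  w <- w / s
  # floored entries are pinned and the remaining mass is shared among the
  # rest, repeated until no entry sits below the floor
  repeat {
    low <- w <= floor
    if (all(low)) { w[] <- 1 / length(w); break }
    w[low] <- floor
    w[!low] <- w[!low] / sum(w[!low]) * (1 - sum(w[low]))
    if (all(w >= floor)) break
  }
  v[active] <- w
  v
}

#' Maximization step
#'
#' Turns expected counts into new parameter values: each multinomial group
#' becomes (counts + pseudocounts) normalized, then floored at
#' \code{floor} and renormalized so every group still sums to one.
#'
#' @param counts a \code{plan7Counts} object from [expectedCounts()].
#' @param model the model the counts were computed under (supplies shape,
#'   mode and alphabet).
#' @param priors pseudocount list as from [makePriors()].
#' @param floor parameter floor (default 1e-5).
#' @return A new [ProfileHMM-class].
#' @export
maximizeStep <- function(counts, model, priors, floor = 1e-5) {
  n <- modelLength(model)
  local <- isLocal(model)
  ME <- t(vapply(seq_len(n), function(p)
    .normGroup(counts$ME[p, ], priors$ME[p, ], floor), numeric(4)))
  IE <- .normGroup(counts$IE, priors$IE, floor)
  mGroup <- c(1:3, if (local) 4L)
  TR <- t(vapply(seq_len(n), function(p) {
    v <- numeric(8)
    v[mGroup] <- .normGroup(counts$TR[p, mGroup], priors$TR[p, mGroup], floor)
    v[5:6] <- .normGroup(counts$TR[p, 5:6], priors$TR[p, 5:6], floor)
    v[7:8] <- .normGroup(counts$TR[p, 7:8], priors$TR[p, 7:8], floor)
    v
  }, numeric(8)))
  bGroup <- c(1:2, if (local) 3L)
  BG <- numeric(3)
  BG[bGroup] <- .normGroup(counts$BG[bGroup], priors$BG[bGroup], floor)
  DIO <- numeric(4)
  if (local) {
    DIO[1:2] <- .normGroup(counts$DIO[1:2], priors$DIO[1:2], floor)
    DIO[3:4] <- .normGroup(counts$DIO[3:4], priors$DIO[3:4], floor)
  }
  newProfileHMM(ME, IE, TR, BG, DIO, localMode = local,
                alphabet = model@alphabet)
}

# EM/ECM objective: log-likelihood plus the Dirichlet pseudocount penalty
# sum(pc * log(theta)); this is the quantity the updates provably never
# decrease.
.dirichletPenalty <- function(model, priors) {
  pen <- 0
  add <- function(pc, th) {
    k <- pc > 0
    sum(pc[k] * log(th[k]))
  }
  pen <- pen + add(priors$ME, model@matchEmissions)
  pen <- pen + add(priors$IE, model@insertEmissions)
  pen <- pen + add(priors$TR, model@transitions)
  pen <- pen + add(priors$BG, model@begin)
  pen + add(priors$DIO, model@deletionInOut)
}

#' Average euclidean parameter distance between two models
#'
#' The convergence statistic: one euclidean norm per multinomial group
#' (each match emission row, each of the three per-position transition
#' groups, the insert emissions, the begin group and -- in local mode --
#' the two DeletionIn/Out pairs), averaged arithmetically over groups.
#' This per-group averaging keeps the statistic on a stable scale when
#' surgery changes the model length.
#'
#' @param old,new two [ProfileHMM-class] objects of identical shape.
#' @return nonnegative scalar.
#' @export
convergenceDistance <- function(old, new) {
  if (modelLength(old) != modelLength(new) ||
      isLocal(old) != isLocal(new))
    stop("models have different shapes")
  n <- modelLength(old)
  local <- isLocal(old)
  nrm <- function(a, b) sqrt(sum((a - b)^2))
  d <- numeric(0)
  for (p in seq_len(n)) {
    d <- c(d, nrm(old@matchEmissions[p, ], new@matchEmissions[p, ]))
    mGroup <- c(1:3, if (local) 4L)
    d <- c(d, nrm(old@transitions[p, mGroup], new@transitions[p, mGroup]),
           nrm(old@transitions[p, 5:6], new@transitions[p, 5:6]),
           nrm(old@transitions[p, 7:8], new@transitions[p, 7:8]))
  }
  d <- c(d, nrm(old@insertEmissions, new@insertEmissions),
         nrm(old@begin, new@begin))
  if (local)
    d <- c(d, nrm(old@deletionInOut[1:2], new@deletionInOut[1:2]),
           nrm(old@deletionInOut[3:4], new@deletionInOut[3:4]))
  mean(d)
}

#' Train a profile HMM
#'
#' Iterates Baum-Welch (full E-step then M-step) or Conditional Baum-Welch
#' (one position group at a time, then the state-independent group, each
#' conditional update using the current values of all other parameters via
#' the state-major forward recursion) until the average per-group parameter
#' distance falls below the tolerance or the iteration cap is reached.
#' With \code{useDMS}, Dynamic Model Surgery runs once per sweep: per
#' position, the fraction of sequences whose expected insertion (deletion)
#' usage exceeds the threshold xi is compared to the configured fractions
#' and the strongest-margin correction is applied immediately; the
#' threshold xi escalates whenever the structural history cycles, so the
#' search silences itself once the data stop supporting changes.  Surgery
#' engages after a short warm-up (\code{dms$delay} iterations) so its
#' decisions reflect the data rather than the diffuse starting point.
#'
#' @param model starting [ProfileHMM-class].
#' @param seqs training sequences.
#' @param config a [trainingConfig()].
#' @return list of class \code{plan7Fit}: \code{model} (trained),
#'   \code{trace} (data.frame with one row per iteration: iteration,
#'   log-likelihood, penalized log-posterior, parameter distance, model
#'   length, surgery actions, xi), \code{converged}, \code{iterations}.
#' @export
trainProfile <- function(model, seqs, config = trainingConfig()) {
  codes <- .encodeSeqs(seqs)
  if (length(codes) == 0) stop("no sequences supplied")
  if (any(lengths(codes) == 0)) stop("empty sequences are not supported")
  initialLength <- modelLength(model)
  maxLen <- max(3L * max(lengths(codes)), 2L * initialLength) + 10L
  priorsFor <- function(m) {
    if (!is.null(config$priors) && modelLength(m) == nrow(config$priors$ME))
      config$priors
    else makePriors(m, config$regime, initialLength)
  }
  # the sweep engine takes one pseudocount row per parameter family
  rowPriors <- function(pr) {
    if (nrow(pr$ME) > 1 &&
        (any(abs(sweep(pr$ME, 2, pr$ME[1, ])) > 0) ||
         any(abs(sweep(pr$TR, 2, pr$TR[1, ])) > 0)))
      stop("position-varying priors are not supported by the sweep trainer")
    list(ME = pr$ME[1, ], TR = pr$TR[1, ], IE = pr$IE, BG = pr$BG,
         DIO = pr$DIO)
  }
  xi <- config$dms$xi0
  sigs <- character(0)
  sinceEsc <- 1L
  trace <- list()
  converged <- FALSE
  iter <- 0L
  while (iter < config$maxIterations) {
    iter <- iter + 1L
    priors <- priorsFor(model)
    pen <- .dirichletPenalty(model, priors)
    actions <- data.frame(kind = character(), position = integer())
    if (config$algorithm == "BW") {
      ec <- cpp_counts(.asCList(model), codes)
      newModel <- maximizeStep(
        structure(ec, class = "plan7Counts"), model, priors,
        config$parameterFloor)
    } else {
      ec <- cpp_cbw_sweep(.asCList(model), codes, rowPriors(priors),
                          config$parameterFloor, FALSE)
      newModel <- .fromCList(ec, model)
    }
    ll <- sum(ec$loglik)   # log-likelihood under the pre-update model
    dist <- convergenceDistance(model, newModel)
    model <- newModel
    if (config$useDMS && iter > config$dms$delay) {
      usage <- positionUsage(ec, xi)
      acts <- decideActions(usage, config$dms)
      if (modelLength(model) >= maxLen)
        acts <- acts[acts$kind != "insert", , drop = FALSE]
      cap <- config$dms$maxActionsPerIteration
      if (nrow(acts) > cap) {
        # bounded appetite: correct the strongest-margin misalignment
        # first so the usage counts can react before the next decision
        marg <- ifelse(acts$kind == "delete",
                       usage$fDel[acts$position] - config$dms$nuDelete,
                       usage$fIns[acts$position] - config$dms$nuInsert)
        acts <- acts[order(-marg)[seq_len(cap)], , drop = FALSE]
        acts <- acts[order(-acts$position), , drop = FALSE]
      }
      actions <- acts
      if (nrow(actions) > 0) model <- applySurgery(model, actions)
      sigs <- c(sigs, paste0(modelLength(model),
                             if (nrow(actions) > 0) "*" else ""))
      esc <- detectCycleAndEscalate(sigs, config$dms, xi,
                                    counts = cbind(ec$perSeqIns, ec$perSeqDel),
                                    sinceIndex = sinceEsc)
      if (esc$escalated) {
        xi <- esc$xi
        sinceEsc <- length(sigs) + 1L
      }
    }
    trace[[iter]] <- data.frame(
      iteration = iter, loglik = ll, logPosterior = ll + pen,
      distance = dist, length = modelLength(model),
      actions = if (nrow(actions) == 0) "" else
        paste(actions$kind, actions$position, sep = "@", collapse = ";"),
      xi = if (config$useDMS) xi else NA_real_,
      stringsAsFactors = FALSE)
    if (nrow(actions) == 0 && !is.na(dist) && dist < config$convergenceTol) {
      converged <- TRUE
      break
    }
  }
  structure(list(model = model, trace = do.call(rbind, trace),
                 converged = converged, iterations = iter),
            class = "plan7Fit")
}

#' @rdname trainProfile
#' @param ... passed to [trainingConfig()].
#' @export
bwTrain <- function(model, seqs, ...)
  trainProfile(model, seqs, trainingConfig(algorithm = "BW", ...))

#' @rdname trainProfile
#' @export
cbwTrain <- function(model, seqs, ...)
  trainProfile(model, seqs, trainingConfig(algorithm = "CBW", ...))

#' One Conditional Baum-Welch sweep with objective tracking
#'
#' Runs a single CBW sweep and records the penalized log-posterior after
#' every conditional update (each position group in order, then the
#' state-independent group).  Used to verify the ECM monotonicity property;
#' the tracking recomputes the full likelihood after each update and is
#' quadratic in model length, so it is meant for small instances.
#'
#' @inheritParams trainProfile
#' @param priors pseudocount list; defaults to simulation-regime priors.
#' @param floor parameter floor.
#' @return list: \code{model} (after the sweep), \code{objective} (vector
#'   of penalized log-posteriors, one per conditional update).
#' @export
cbwSweepTracked <- function(model, seqs, priors = NULL, floor = 1e-5) {
  codes <- .encodeSeqs(seqs)
  if (is.null(priors)) priors <- makePriors(model, "simulation")
  rp <- list(ME = priors$ME[1, ], TR = priors$TR[1, ], IE = priors$IE,
             BG = priors$BG, DIO = priors$DIO)
  res <- cpp_cbw_sweep(.asCList(model), codes, rp, floor, TRUE)
  list(model = .fromCList(res, model), objective = res$objective)
}
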