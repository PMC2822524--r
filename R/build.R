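#' Build a Plan 7 profile HMM with default starting parameters
#'
#' In local mode the starting transition probabilities are the standard
#' repeat-search values: each Match state carries probability .9 of entering
#' DeletionOut, .095 of continuing to the next Match, and .0025 each for the
#' Insertion and Deletion branches; Begin enters DeletionIn with .9, the
#' first Match with .09 and the first Deletion with .01; DeletionIn and
#' DeletionOut continue with .9999 and exit with .0001; insertion and
#' deletion gaps extend and end with probability .5 each; flanking
#' insertions are disallowed.  In global mode a neutral default is used
#' (Match to Match .95, to Insertion and Deletion .025 each; Begin to first
#' Match .95, to first Deletion .05) -- any proper distribution serves as a
#' starting point since training moves the transitions.
#'
#' Match and insertion emissions start uniform (.25 per nucleotide).
#'
#' @param nPositions model length (number of match positions), at least 1.
#' @param alphabet residue alphabet; only DNA is supported.
#' @param localMode build the local-mode (DeletionIn/DeletionOut) topology?
#' @return A [ProfileHMM-class].
#' @examples
#' m <- buildPlan7(5, localMode = TRUE)
#' transitions(m)[1, "MDO"]  # .9
#' @export
buildPlan7 <- function(nPositions, alphabet = dnaAlphabet(),
                       localMode = FALSE) {
  if (!is.numeric(nPositions) || length(nPositions) != 1 ||
      is.na(nPositions) || nPositions < 1)
    stop("invalid model: nPositions must be a positive integer")
  n <- as.integer(nPositions)
  ME <- matrix(1 / length(alphabet), n, length(alphabet))
  IE <- rep(1 / length(alphabet), length(alphabet))
  if (localMode) {
    tr <- c(MM = .095, MI = .0025, MD = .0025, MDO = .9,
            IM = .5, II = .5, DM = .5, DD = .5)
    bg <- c(BM = .09, BD = .01, BDI = .9)
    dio <- c(.9999, .0001, .9999, .0001)
  } else {
    tr <- c(MM = .95, MI = .025, MD = .025, MDO = 0,
            IM = .5, II = .5, DM = .5, DD = .5)
    bg <- c(BM = .95, BD = .05, BDI = 0)
    dio <- c(0, 0, 0, 0)
  }
  TR <- matrix(tr, n, 8, byrow = TRUE)
  newProfileHMM(ME, IE, TR, bg, dio, localMode = localMode,
                alphabet = alphabet)
}

#' Validate a profile HMM
#'
#' Reports every violated model invariant rather than raising: emission and
#' transition distributions must each sum to one (tolerance 1e-12), all
#' probabilities must lie in \code{[0, 1]}, and mode-dependent structural
#' zeros (\code{MDO}, \code{BDI}, DeletionIn/Out parameters in global mode)
#' must hold.  Insertion-Deletion transitions cannot be expressed in this
#' representation at all, so Plan 7 topology holds by construction.
#'
#' @param model a [ProfileHMM-class] (validity is *not* assumed).
#' @param floor optional probability floor; when given, free parameters
#'   below it are reported as floor violations.
#' @return data.frame with columns \code{kind}, \code{position},
#'   \code{message}; zero rows iff the model is valid.
#' @export
validateProfile <- function(model, floor = NULL) {
  out <- list()
  bad <- function(kind, position, message)
    out[[length(out) + 1]] <<- data.frame(kind = kind, position = position,
                                          message = message,
                                          stringsAsFactors = FALSE)
  ME <- model@matchEmissions; TR <- model@transitions
  n <- nrow(ME)
  if (length(model@alphabet) != 4 || anyDuplicated(model@alphabet))
    bad("alphabet", NA, "DNA alphabet must have 4 unique symbols")
  if (ncol(ME) != 4 || ncol(TR) != 8 || nrow(TR) != n)
    bad("shape", NA, "parameter array shapes disagree")
  chk01 <- function(v, kind, position, what) {
    if (any(!is.finite(v)) || any(v < -.PROB_TOL) || any(v > 1 + .PROB_TOL))
      bad(kind, position, sprintf("%s outside [0,1]", what))
  }
  chksum <- function(v, kind, position, what) {
    chk01(v, kind, position, what)
    if (abs(sum(v) - 1) > .PROB_TOL)
      bad(kind, position, sprintf("%s sums to %.2f, not 1", what, sum(v)))
  }
  for (p in seq_len(n))
    chksum(ME[p, ], "normalization", p, sprintf("match emission %d", p))
  chksum(model@insertEmissions, "normalization", NA, "insert emissions")
  mGroup <- if (model@localMode) c("MM", "MI", "MD", "MDO")
            else c("MM", "MI", "MD")
  for (p in seq_len(n)) {
    chksum(TR[p, mGroup], "normalization", p, sprintf("M-group %d", p))
    chksum(TR[p, c("IM", "II")], "normalization", p, sprintf("I-group %d", p))
    chksum(TR[p, c("DM", "DD")], "normalization", p, sprintf("D-group %d", p))
  }
  bGroup <- if (model@localMode) c("BM", "BD", "BDI") else c("BM", "BD")
  chksum(model@begin[bGroup], "normalization", NA, "begin group")
  if (model@localMode) {
    chksum(model@deletionInOut[1:2], "normalization", NA, "DeletionIn group")
    chksum(model@deletionInOut[3:4], "normalization", NA, "DeletionOut group")
  } else {
    if (any(TR[, "MDO"] != 0))
      bad("topology", NA, "MDO transitions must be zero in global mode")
    if (model@begin["BDI"] != 0)
      bad("topology", NA, "Begin->DeletionIn must be zero in global mode")
  }
  if (!is.null(floor)) {
    below <- function(v) any(v < floor - .PROB_TOL)
    for (p in seq_len(n)) {
      if (below(ME[p, ]))
        bad("floor", p, sprintf("match emission %d below floor", p))
      grp <- c(TR[p, mGroup], TR[p, c("IM", "II")], TR[p, c("DM", "DD")])
      if (below(grp))
        bad("floor", p, sprintf("transition group %d below floor", p))
    }
    if (below(model@insertEmissions)) bad("floor", NA, "insert emissions below floor")
  }
  if (length(out) == 0)
    data.frame(kind = character(), position = integer(),
               message = character(), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Canonical state ordering of a Plan 7 model
#'
#' Orders the states Begin, DeletionIn, then Match/Insertion/Deletion for
#' each position in turn, then DeletionOut, End -- the state-major ordering
#' under which every strictly advancing transition moves at most five index
#' steps forward (the longest hop being Match at one position to Deletion at
#' the next), which is what permits the state-by-state (row-wise) dynamic
#' programming recursion used by Conditional Baum-Welch.
#'
#' @param model a [ProfileHMM-class].
#' @return data.frame with columns \code{index}, \code{role},
#'   \code{position} (NA for non-positional states).
#' @export
canonicalOrdering <- function(model) {
  n <- modelLength(model)
  roles <- c("Begin", "DeletionIn",
             as.vector(rbind(rep("Match", n), rep("Insertion", n),
                             rep("Deletion", n))),
             "DeletionOut", "End")
  pos <- c(NA, NA, as.vector(rbind(seq_len(n), seq_len(n), seq_len(n))),
           NA, NA)
  data.frame(index = seq_along(roles), role = roles, position = pos,
             stringsAsFactors = FALSE)
}

#' Enumerate the nonzero transitions of a profile HMM
#'
#' Lists every transition with nonzero probability as a pair of canonical
#' state indices.  Self-loops (Insertion, DeletionIn, DeletionOut) are
#' flagged; so are the local-mode shortcut edges mediated by the
#' DeletionIn/DeletionOut chains (Begin to a later Match, Match to End via
#' DeletionOut), whose underlying chain steps each advance a single model
#' position and which therefore do not enter the band computation.
#'
#' @param model a [ProfileHMM-class].
#' @return data.frame with columns \code{from}, \code{to} (canonical
#'   indices), \code{fromRole}, \code{toRole}, \code{prob}, \code{self},
#'   \code{banded}.
#' @export
transitionTable <- function(model) {
  n <- modelLength(model)
  TR <- model@transitions; BG <- model@begin; DIO <- model@deletionInOut
  iB <- 1L; iDI <- 2L
  iM <- function(p) 2L + 3L * (p - 1L) + 1L
  iI <- function(p) iM(p) + 1L
  iD <- function(p) iM(p) + 2L
  iDO <- 3L * n + 3L; iE <- 3L * n + 4L
  rows <- list()
  add <- function(from, to, fr, tr, prob, self = FALSE, banded = TRUE) {
    if (prob > 0)
      rows[[length(rows) + 1]] <<- data.frame(
        from = from, to = to, fromRole = fr, toRole = tr, prob = prob,
        self = self, banded = banded, stringsAsFactors = FALSE)
  }
  add(iB, iM(1), "Begin", "Match", BG["BM"])
  add(iB, iD(1), "Begin", "Deletion", BG["BD"])
  add(iB, iDI, "Begin", "DeletionIn", BG["BDI"])
  if (model@localMode && BG["BDI"] > 0) {
    add(iDI, iDI, "DeletionIn", "DeletionIn", DIO["dinContinue"], self = TRUE)
    if (n >= 2)
      add(iDI, iM(2), "DeletionIn", "Match", DIO["dinExit"], banded = FALSE)
    add(iDO, iDO, "DeletionOut", "DeletionOut", DIO["doutContinue"],
        self = TRUE)
    add(iDO, iE, "DeletionOut", "End", DIO["doutExit"])
  }
  for (p in seq_len(n)) {
    if (p < n) {
      add(iM(p), iM(p + 1), "Match", "Match", TR[p, "MM"])
      add(iM(p), iD(p + 1), "Match", "Deletion", TR[p, "MD"])
      add(iI(p), iM(p + 1), "Insertion", "Match", TR[p, "IM"])
      add(iD(p), iM(p + 1), "Deletion", "Match", TR[p, "DM"])
      add(iD(p), iD(p + 1), "Deletion", "Deletion", TR[p, "DD"])
    } else {
      add(iM(n), iE, "Match", "End", TR[n, "MM"] + TR[n, "MD"])
      add(iI(n), iE, "Insertion", "End", TR[n, "IM"])
      add(iD(n), iE, "Deletion", "End", TR[n, "DM"])
    }
    add(iM(p), iI(p), "Match", "Insertion", TR[p, "MI"])
    add(iI(p), iI(p), "Insertion", "Insertion", TR[p, "II"], self = TRUE)
    add(iM(p), iDO, "Match", "DeletionOut", TR[p, "MDO"], banded = FALSE)
  }
  do.call(rbind, rows)
}

#' Maximum strictly-advancing transition offset
#'
#' The largest index advance \code{j - i} over all nonzero, non-self,
#' banded transitions of the model under [canonicalOrdering()].  For any
#' Plan 7 model this is 5 (Match at position p to Deletion at p+1).
#'
#' @param model a [ProfileHMM-class].
#' @return integer scalar.
#' @export
maxAdvanceOffset <- function(model) {
  tt <- transitionTable(model)
  tt <- tt[!tt$self & tt$banded, ]
  max(tt$to - tt$from)
}
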