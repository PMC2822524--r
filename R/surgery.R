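#' Per-position insertion/deletion usage fractions
#'
#' For each model position j, the fraction of sequences whose expected
#' insertion usage at j exceeds the threshold xi, and likewise for
#' deletion usage.  These are the quantities Dynamic Model Surgery compares
#' to its trigger fractions.
#'
#' @param counts an [expectedCounts()] result (the per-sequence matrices
#'   must be present).
#' @param xi usage threshold.
#' @return data.frame with columns \code{position}, \code{fIns},
#'   \code{fDel}.
#' @export
positionUsage <- function(counts, xi) {
  if (is.null(counts$perSeqIns) || is.null(counts$perSeqDel))
    stop("per-sequence counts are missing")
  data.frame(position = seq_len(ncol(counts$perSeqIns)),
             fIns = colMeans(counts$perSeqIns > xi),
             fDel = colMeans(counts$perSeqDel > xi))
}

#' Decide surgery actions from usage fractions
#'
#' A position gains a neighbour (insert-after) when at least
#' \code{nuInsert} of the sequences have expected insertion usage above the
#' threshold there; a position is removed when at least \code{nuDelete}
#' of the sequences have expected deletion usage above the threshold (the
#' comparison is inclusive: a fraction exactly at the trigger acts, which
#' is what lets two positions sharing one ancestral column -- each deleted
#' by exactly half the sequences -- be cleaned up at the .5 default).  When
#' both trigger at one position the deletion wins (removing a misused
#' position changes its neighbours' usage, so the insertion is suppressed
#' for that sweep).  Actions are returned in descending position order so
#' that indices stay valid as they are applied.
#'
#' @param usage a [positionUsage()] data.frame.
#' @param config list with \code{nuInsert} and \code{nuDelete} (e.g. the
#'   \code{dms} component of a [trainingConfig()]).
#' @return data.frame with columns \code{kind} ("insert" or "delete") and
#'   \code{position}.
#' @export
decideActions <- function(usage, config) {
  del <- usage$position[usage$fDel >= config$nuDelete]
  ins <- usage$position[usage$fIns >= config$nuInsert]
  ins <- setdiff(ins, del)
  n <- nrow(usage)
  if (length(del) >= n) del <- del[-length(del)]  # never delete every position
  acts <- rbind(
    if (length(ins)) data.frame(kind = "insert", position = ins),
    if (length(del)) data.frame(kind = "delete", position = del))
  if (is.null(acts))
    return(data.frame(kind = character(), position = integer()))
  acts[order(-acts$position, acts$kind), , drop = FALSE]
}

#' Apply surgery actions to a model
#'
#' Inserting after position j adds a new position whose transition group
#' copies j's and whose match emission is neutral (the prior mean: uniform
#' under add-one pseudocounts), so the data decide what the correction
#' should hold; deleting removes the position's rows.  Parameters at
#' untouched positions are bitwise unchanged, so dynamic programming rows
#' strictly before the earliest affected position remain valid and can be
#' reused via [forwardRows()] (the earliest affected position is attached
#' as attribute \code{earliestAffected}).
#'
#' @param model a [ProfileHMM-class].
#' @param actions data.frame from [decideActions()] (applied in the order
#'   given; descending position keeps indices valid).
#' @param newEmission emission distribution for inserted positions.
#' @return the restructured [ProfileHMM-class].
#' @export
applySurgery <- function(model, actions,
                         newEmission = rep(1 / length(model@alphabet),
                                           length(model@alphabet))) {
  ME <- model@matchEmissions
  TR <- model@transitions
  earliest <- Inf
  for (i in seq_len(nrow(actions))) {
    j <- actions$position[i]
    if (actions$kind[i] == "insert") {
      if (j < 1 || j > nrow(ME)) stop("insert position out of range")
      ME <- rbind(ME[seq_len(j), , drop = FALSE], newEmission,
                  if (j < nrow(ME)) ME[(j + 1):nrow(ME), , drop = FALSE])
      TR <- rbind(TR[seq_len(j), , drop = FALSE], TR[j, ],
                  if (j < nrow(TR)) TR[(j + 1):nrow(TR), , drop = FALSE])
      earliest <- min(earliest, j + 1)
    } else {
      if (nrow(ME) <= 1) stop("cannot delete a position from a length-1 model")
      if (j < 1 || j > nrow(ME)) stop("delete position out of range")
      ME <- ME[-j, , drop = FALSE]
      TR <- TR[-j, , drop = FALSE]
      earliest <- min(earliest, j)
    }
  }
  rownames(ME) <- rownames(TR) <- NULL
  out <- newProfileHMM(ME, model@insertEmissions, TR, model@begin,
                       model@deletionInOut, localMode = model@localMode,
                       alphabet = model@alphabet)
  attr(out, "earliestAffected") <- if (is.finite(earliest))
    as.integer(min(earliest, modelLength(out))) else NA_integer_
  out
}

#' Detect a structural cycle and escalate the surgery threshold
#'
#' The structural signature of an iteration is the model length, suffixed
#' with \code{"*"} when surgery actions were taken.  A cycle is declared
#' when the current iteration took actions yet its length matches a length
#' already seen (since the last escalation, within the history window):
#' the structure is oscillating rather than progressing.  A strictly
#' monotone length history never escalates.  On a cycle the threshold xi
#' escalates: in \code{"fixed"} mode by the configured epsilon; in
#' \code{"adaptive"} mode to the midpoint of the two smallest per-sequence
#' usage counts above the current xi (or onto the single such count), the
#' minimal move that changes at least one exceedance fraction.
#'
#' @param signatures character vector of per-iteration structural
#'   signatures, most recent last (model length, with a \code{"*"} suffix
#'   when that iteration performed surgery).
#' @param config surgery settings (\code{epsilon}, \code{escalation},
#'   \code{cycleMemory}).
#' @param xi current threshold.
#' @param counts matrix of per-sequence usage counts (insertion and
#'   deletion), used in adaptive mode.
#' @param sinceIndex first signature index eligible for cycle matching
#'   (signatures before the last escalation are ignored).
#' @return list with \code{xi} (possibly increased) and \code{escalated}.
#' @export
detectCycleAndEscalate <- function(signatures, config, xi, counts = NULL,
                                   sinceIndex = 1L) {
  k <- length(signatures)
  if (k < 2) return(list(xi = xi, escalated = FALSE))
  lo <- max(sinceIndex, k - config$cycleMemory)
  if (lo > k - 1) return(list(xi = xi, escalated = FALSE))
  cur <- signatures[k]
  if (!grepl("\\*$", cur))  # no structural change: nothing to escalate
    return(list(xi = xi, escalated = FALSE))
  lens <- sub("\\*$", "", signatures)
  if (!lens[k] %in% lens[lo:(k - 1)])
    return(list(xi = xi, escalated = FALSE))
  if (config$escalation == "fixed")
    return(list(xi = xi + config$epsilon, escalated = TRUE))
  above <- sort(unique(as.numeric(counts)[as.numeric(counts) > xi]))
  newXi <- if (length(above) == 0) xi
           else if (length(above) == 1) above[1]
           else (above[1] + above[2]) / 2
  list(xi = newXi, escalated = newXi > xi)
}
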