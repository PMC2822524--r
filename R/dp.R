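#' Forward dynamic programming values
#'
#' Computes the scaled forward values \eqn{\alpha_\tau(h) = P(d^\tau, h_\tau
#' | \Theta)} for every state and time, using per-time multiplicative
#' scaling, together with the sequence log-likelihood (natural log).  Time
#' index 0 holds the pre-emission silent states (Begin and the leading
#' deletion chain).
#'
#' @param model a [ProfileHMM-class].
#' @param seq a single sequence (character string, \code{DNAString}, or a
#'   length-one \code{DNAStringSet}).
#' @return An object of class \code{plan7DP}: list with matrices \code{M},
#'   \code{I}, \code{D} (rows: time 0..K; columns: model positions), the
#'   per-time \code{scales}, the scaled terminal value \code{Lhat}, and
#'   \code{loglik}.  Unscaled values are recovered as
#'   \code{M[tau, p] * prod(scales[1..tau])}.
#' @export
forwardValues <- function(model, seq) {
  code <- .encodeSeqs(seq)[[1]]
  res <- cpp_forward(.asCList(model), code)
  res$direction <- "forward"
  res$code <- code
  class(res) <- "plan7DP"
  res
}

#' Backward dynamic programming values
#'
#' Computes the scaled backward values \eqn{\beta_\tau(h) = P(d^{-\tau} |
#' h_\tau, \Theta)}, scaled by the forward pass's scale factors so that
#' \code{sum(alpha[tau, ] * beta[tau, ])} over the emitting states equals
#' the scaled sequence likelihood at every time.
#'
#' @inheritParams forwardValues
#' @param forward the matching [forwardValues()] result; computed if absent.
#' @return An object of class \code{plan7DP} (direction \code{"backward"}).
#' @export
backwardValues <- function(model, seq, forward = NULL) {
  code <- .encodeSeqs(seq)[[1]]
  if (is.null(forward)) forward <- forwardValues(model, seq)
  if (length(forward$code) != length(code) || any(forward$code != code))
    stop("forward values were computed for a different sequence")
  res <- cpp_backward(.asCList(model), code, forward$scales)
  res$direction <- "backward"
  res$scales <- forward$scales
  res$code <- code
  res$loglik <- log(res$Lhat) + sum(log(forward$scales[-1]))
  class(res) <- "plan7DP"
  res
}

#' Recompute forward values state-row by state-row
#'
#' Under the canonical state ordering the forward recursion can proceed
#' state-by-state: the values for a model position depend only on the
#' previous position's rows.  When parameters at positions
#' \code{>= fromPosition} change, only those rows need recomputation; the
#' earlier rows (and the stored scale factors) are reused untouched.  This
#' is the primitive that makes Conditional Baum-Welch as cheap as a plain
#' Baum-Welch iteration.
#'
#' @inheritParams forwardValues
#' @param forward a prior [forwardValues()] result whose rows strictly
#'   before \code{fromPosition} are still valid for \code{model}.
#' @param fromPosition first model position to recompute (1-based).
#' @return An updated \code{plan7DP} forward object.
#' @export
forwardRows <- function(model, seq, forward, fromPosition) {
  code <- .encodeSeqs(seq)[[1]]
  if (fromPosition < 1 || fromPosition > modelLength(model))
    stop("fromPosition is not a model position")
  res <- cpp_forward_rows(.asCList(model), code, forward, as.integer(fromPosition))
  res$direction <- "forward"
  res$code <- code
  class(res) <- "plan7DP"
  res
}

#' Posterior state probabilities
#'
#' The conditional distribution of the hidden state given the observed
#' sequence, per (state, time) cell.  At every time with an emitted residue
#' the posteriors over the emitting states (Match and Insertion) sum to one.
#'
#' @inheritParams forwardValues
#' @param forward,backward matching [forwardValues()] / [backwardValues()]
#'   results for the same model and sequence.
#' @return list with matrices \code{M}, \code{I}, \code{D} of posterior
#'   probabilities (rows: time 0..K).
#' @export
posteriorStates <- function(model, seq, forward = NULL, backward = NULL) {
  code <- .encodeSeqs(seq)[[1]]
  if (is.null(forward)) forward <- forwardValues(model, seq)
  if (is.null(backward)) backward <- backwardValues(model, seq, forward)
  if (!identical(dim(forward$M), dim(backward$M)) ||
      length(forward$code) != length(backward$code) ||
      any(forward$code != backward$code))
    stop("forward and backward values do not match")
  Lhat <- forward$Lhat
  list(M = forward$M * backward$M / Lhat,
       I = forward$I * backward$I / Lhat,
       D = forward$D * backward$D / Lhat)
}

#' Best local alignment of a profile to a sequence
#'
#' Viterbi decoding with the model in local mode: the alignment may start
#' and end anywhere on the sequence, and may cover only part of the model
#' via the DeletionIn/DeletionOut states.  Scores are log-odds (natural
#' log) against a background model equal to the profile's insertion
#' emission distribution.  Ties are broken preferring Match over Deletion
#' over Insertion predecessors, then the lower position index.
#'
#' @inheritParams forwardValues
#' @return list of class \code{plan7Hit}: \code{score}, \code{start},
#'   \code{end} (1-based inclusive on the sequence; both 0 with score
#'   \code{-Inf} for an empty hit), and \code{path}, a data.frame with
#'   columns \code{position}, \code{role} (M/I/D) and \code{tau}.
#' @export
viterbiLocal <- function(model, seq) {
  if (!isLocal(model)) stop("viterbiLocal requires a local-mode model")
  code <- if (is.integer(seq)) seq else .encodeSeqs(seq)[[1]]
  res <- cpp_viterbi_local(.asCList(model), code)
  path <- res$path
  out <- list(score = res$score, start = res$start, end = res$end,
              path = data.frame(position = path[, 1],
                                role = c("M", "I", "D")[path[, 2] + 1],
                                tau = path[, 3]))
  class(out) <- "plan7Hit"
  out
}
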