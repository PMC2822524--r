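#' DNA alphabet
#'
#' The ordered nucleotide alphabet used throughout the package.  Residues are
#' case-folded on input; the ambiguity code \code{N} is accepted in sequences
#' and emits with probability one from every emitting state.
#'
#' @return Character vector \code{c("A","C","G","T")}.
#' @export
dnaAlphabet <- function() c("A", "C", "G", "T")

.TRANS_COLS <- c("MM", "MI", "MD", "MDO", "IM", "II", "DM", "DD")
.BEGIN_NAMES <- c("BM", "BD", "BDI")
.DIO_NAMES <- c("dinContinue", "dinExit", "doutContinue", "doutExit")
.PROB_TOL <- 1e-12

#' Plan 7 profile hidden Markov model
#'
#' An S4 container for the full parameter set of a Plan 7 profile HMM over
#' the DNA alphabet: per-position match emission distributions, a single
#' shared insertion emission distribution, per-position transition groups
#' (no Insertion-Deletion transitions exist, by construction), begin-state
#' transitions, and -- in local mode -- the DeletionIn/DeletionOut
#' continue/exit probabilities that let a hit cover only part of the model.
#' Flanking insertions are disallowed in local mode.
#'
#' @slot alphabet ordered residue characters (A, C, G, T).
#' @slot matchEmissions numeric matrix, one row per model position, columns
#'   named by residue; each row sums to one.
#' @slot insertEmissions named numeric vector over the alphabet, shared by
#'   all insertion states.
#' @slot transitions numeric matrix, one row per position, columns
#'   \code{MM, MI, MD, MDO, IM, II, DM, DD}.  \code{MDO} (Match to
#'   DeletionOut) is zero unless the model is in local mode.  At the last
#'   position, \code{MM} and \code{MD} both route to End.
#' @slot begin named numeric vector \code{BM, BD, BDI} (Begin to first
#'   Match, first Deletion, DeletionIn); \code{BDI} is zero unless local.
#' @slot deletionInOut named numeric vector
#'   \code{dinContinue, dinExit, doutContinue, doutExit}; ignored (all zero)
#'   in global mode.
#' @slot localMode logical flag.
#' @export
setClass("ProfileHMM",
  representation(
    alphabet = "character",
    matchEmissions = "matrix",
    insertEmissions = "numeric",
    transitions = "matrix",
    begin = "numeric",
    deletionInOut = "numeric",
    localMode = "logical"
  )
)

# S4 validity guards the representation (shapes and finiteness); the
# probabilistic invariants -- normalization, floors, structural zeros --
# are checked by validateProfile(), which the constructors apply.  This
# split lets decoded-but-unnormalized parameter sets (e.g. from a printed
# export) exist as objects while construction stays safe by default.
setValidity("ProfileHMM", function(object) {
  n <- nrow(object@matchEmissions)
  msgs <- character(0)
  if (length(object@alphabet) != 4 || anyDuplicated(object@alphabet))
    msgs <- c(msgs, "alphabet must hold 4 unique symbols")
  if (ncol(object@matchEmissions) != 4)
    msgs <- c(msgs, "matchEmissions must have 4 columns")
  if (!identical(dim(object@transitions), c(n, 8L)) &&
      !identical(dim(object@transitions), as.integer(c(n, 8))))
    msgs <- c(msgs, "transitions must be n x 8")
  if (length(object@insertEmissions) != 4)
    msgs <- c(msgs, "insertEmissions must have length 4")
  if (length(object@begin) != 3)
    msgs <- c(msgs, "begin must have length 3")
  if (length(object@deletionInOut) != 4)
    msgs <- c(msgs, "deletionInOut must have length 4")
  if (length(object@localMode) != 1 || is.na(object@localMode))
    msgs <- c(msgs, "localMode must be TRUE or FALSE")
  if (anyNA(object@matchEmissions) || anyNA(object@transitions) ||
      anyNA(object@insertEmissions))
    msgs <- c(msgs, "parameters must not contain NA")
  if (length(msgs) == 0) TRUE else paste(msgs, collapse = "; ")
})

#' @describeIn ProfileHMM number of model positions
#' @param x,object a \code{ProfileHMM}
#' @export
setGeneric("modelLength", function(x) standardGeneric("modelLength"))

#' @rdname ProfileHMM
#' @export
setMethod("modelLength", "ProfileHMM", function(x) nrow(x@matchEmissions))

#' @describeIn ProfileHMM per-position match emission matrix
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))

#' @rdname ProfileHMM
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmissions)

#' @describeIn ProfileHMM shared insertion emission distribution
#' @export
setGeneric("insertEmissions", function(x) standardGeneric("insertEmissions"))

#' @rdname ProfileHMM
#' @export
setMethod("insertEmissions", "ProfileHMM", function(x) x@insertEmissions)

#' @describeIn ProfileHMM per-position transition matrix
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @rdname ProfileHMM
#' @export
setMethod("transitions", "ProfileHMM", function(x) x@transitions)

#' @describeIn ProfileHMM is the model in local mode?
#' @export
setGeneric("isLocal", function(x) standardGeneric("isLocal"))

#' @rdname ProfileHMM
#' @export
setMethod("isLocal", "ProfileHMM", function(x) x@localMode)

#' @describeIn ProfileHMM consensus sequence (argmax of each match emission
#'   distribution; ties broken by alphabet order)
#' @export
setGeneric("consensusSequence",
           function(x) standardGeneric("consensusSequence"))

#' @rdname ProfileHMM
#' @export
setMethod("consensusSequence", "ProfileHMM", function(x) {
  paste0(x@alphabet[apply(x@matchEmissions, 1, which.max)], collapse = "")
})

setMethod("show", "ProfileHMM", function(object) {
  n <- modelLength(object)
  cat(sprintf("Plan 7 profile HMM (%s mode), %d position%s, alphabet %s\n",
              if (object@localMode) "local" else "global", n,
              if (n == 1) "" else "s",
              paste(object@alphabet, collapse = "")))
  cons <- consensusSequence(object)
  if (nchar(cons) > 60) cons <- paste0(substr(cons, 1, 57), "...")
  cat("  consensus: ", cons, "\n", sep = "")
  cat(sprintf("  mean match conservation: %.3f\n",
              mean(apply(object@matchEmissions, 1, max))))
  invisible(object)
})

# internal: slot bundle in the layout the C++ engine expects
.asCList <- function(model) {
  list(n = modelLength(model),
       ME = unname(model@matchEmissions),
       IE = unname(model@insertEmissions),
       TR = unname(model@transitions),
       BG = unname(model@begin),
       DIO = unname(model@deletionInOut),
       local = model@localMode)
}

# internal: rebuild a ProfileHMM from engine output, reusing mode/alphabet
.fromCList <- function(parts, template) {
  newProfileHMM(matchEmissions = parts$ME,
                insertEmissions = as.numeric(parts$IE),
                transitions = parts$TR,
                begin = as.numeric(parts$BG),
                deletionInOut = as.numeric(parts$DIO),
                localMode = template@localMode,
                alphabet = template@alphabet)
}

#' Construct a ProfileHMM from explicit parameter arrays
#'
#' Low-level constructor; most users should call [buildPlan7()],
#' [sampleTrueProfile()] or [randomStartProfile()].
#'
#' @param matchEmissions n x 4 matrix of match emission probabilities.
#' @param insertEmissions length-4 insertion emission probabilities.
#' @param transitions n x 8 matrix with columns
#'   \code{MM, MI, MD, MDO, IM, II, DM, DD}.
#' @param begin length-3 begin transitions \code{BM, BD, BDI}.
#' @param deletionInOut length-4 DeletionIn/DeletionOut continue/exit
#'   probabilities.
#' @param localMode logical.
#' @param alphabet residue alphabet (default DNA).
#' @param validate check validity (default TRUE).
#' @return A [ProfileHMM-class] object.
#' @export
newProfileHMM <- function(matchEmissions, insertEmissions, transitions,
                          begin, deletionInOut = numeric(4),
                          localMode = FALSE, alphabet = dnaAlphabet(),
                          validate = TRUE) {
  matchEmissions <- as.matrix(matchEmissions)
  transitions <- as.matrix(transitions)
  dimnames(matchEmissions) <- list(NULL, alphabet)
  dimnames(transitions) <- list(NULL, .TRANS_COLS)
  obj <- new("ProfileHMM",
             alphabet = alphabet,
             matchEmissions = matchEmissions,
             insertEmissions = setNames(as.numeric(insertEmissions), alphabet),
             transitions = transitions,
             begin = setNames(as.numeric(begin), .BEGIN_NAMES),
             deletionInOut = setNames(as.numeric(deletionInOut), .DIO_NAMES),
             localMode = localMode)
  if (validate) {
    rep <- validateProfile(obj)
    if (nrow(rep) > 0)
      stop("invalid profile HMM: ", paste(rep$message, collapse = "; "))
  }
  obj
}
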