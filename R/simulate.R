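#' Generate a "true" profile at a stated conservation level
#'
#' Draws a random consensus sequence of the given length, then builds a
#' profile whose match emission at each position places the conservation
#' probability on the consensus residue and divides the remainder evenly
#' among the other three nucleotides.  Transitions use high-fidelity
#' defaults (Match continues with .97, branches to Insertion and Deletion
#' with .015 each; gaps extend with .3) so that sampled sequences stay near
#' the consensus length.
#'
#' @param consensusLength number of model positions (default 100).
#' @param conservation probability mass on the consensus residue; must
#'   exceed 1/4 so the consensus is the modal residue.
#' @param seed RNG seed (integer).
#' @param alphabet residue alphabet.
#' @return list with \code{model} (a global-mode [ProfileHMM-class]),
#'   \code{consensus} (character string) and \code{spec} (the arguments).
#' @export
sampleTrueProfile <- function(consensusLength = 100, conservation,
                              seed = 1L, alphabet = dnaAlphabet()) {
  a <- length(alphabet)
  if (!is.numeric(conservation) || conservation <= 1 / a || conservation > 1)
    stop(sprintf("conservation must lie in (1/%d, 1]", a))
  n <- as.integer(consensusLength)
  set.seed(seed)
  consensus <- sample.int(a, n, replace = TRUE)
  ME <- matrix((1 - conservation) / (a - 1), n, a)
  ME[cbind(seq_len(n), consensus)] <- conservation
  TR <- matrix(c(MM = .97, MI = .015, MD = .015, MDO = 0,
                 IM = .7, II = .3, DM = .7, DD = .3), n, 8, byrow = TRUE)
  model <- newProfileHMM(ME, rep(1 / a, a), TR, c(.97, .03, 0),
                         localMode = FALSE, alphabet = alphabet)
  list(model = model,
       consensus = paste0(alphabet[consensus], collapse = ""),
       spec = list(consensusLength = n, conservation = conservation,
                   seed = seed))
}

# simulate one path through the hidden chain, returning the emitted
# residues and the (role, position) alignment of every emission
.simulateOne <- function(model, maxLen) {
  n <- modelLength(model)
  TR <- model@transitions; BG <- model@begin; DIO <- model@deletionInOut
  ME <- model@matchEmissions; IE <- model@insertEmissions
  a <- length(model@alphabet)
  res <- integer(0); role <- character(0); pos <- integer(0)
  pick <- function(p) sample.int(length(p), 1, prob = p)
  emit <- function(probs) sample.int(a, 1, prob = probs)
  # begin
  state <- switch(pick(c(BG["BM"], BG["BD"], max(BG["BDI"], 0))),
                  "M", "D", "DIn")
  p <- 1L
  if (state == "DIn") {  # skip leading positions, then enter a Match
    p <- 2L
    while (p <= n && runif(1) < DIO["dinContinue"]) p <- p + 1L
    if (p > n) return(list(res = res, role = role, pos = pos))  # all skipped
    state <- "M"
  }
  while (p <= n && length(res) < maxLen) {
    if (state == "M") {
      r <- emit(ME[p, ])
      res <- c(res, r); role <- c(role, "M"); pos <- c(pos, p)
      ch <- pick(TR[p, c("MM", "MI", "MD", "MDO")])
      if (ch == 4) break                        # DeletionOut: skip the rest
      if (ch == 2) { state <- "I" } else { state <- if (ch == 1) "M" else "D"
                                           p <- p + 1L }
    } else if (state == "I") {
      r <- emit(IE)
      res <- c(res, r); role <- c(role, "I"); pos <- c(pos, p)
      if (pick(TR[p, c("IM", "II")]) == 1) { state <- "M"; p <- p + 1L }
    } else {  # D
      role <- c(role, "D"); pos <- c(pos, p)
      state <- if (pick(TR[p, c("DM", "DD")]) == 1) "M" else "D"
      p <- p + 1L
    }
    if (p > n) break
  }
  list(res = res, role = role, pos = pos)
}

#' Sample sequences from a profile HMM
#'
#' Simulates the hidden Markov chain and its emissions.  With
#' \code{withAlignment = TRUE} the true state path of every sequence is
#' returned as well, giving the simulation-time alignment of each emitted
#' residue to its model position (used, e.g., to measure identity to the
#' consensus at match states).
#'
#' @param model a [ProfileHMM-class].
#' @param n number of sequences.
#' @param seed RNG seed.
#' @param withAlignment also return the true state paths?
#' @return A \code{DNAStringSet}; or, with alignments, a list with
#'   \code{sequences} (\code{DNAStringSet}) and \code{alignments} (one
#'   data.frame per sequence with columns \code{role}, \code{position},
#'   \code{residue}).
#' @export
sampleSequences <- function(model, n, seed = 1L, withAlignment = FALSE) {
  set.seed(seed)
  maxLen <- 50L * modelLength(model) + 1000L
  sims <- vector("list", n)
  i <- 1L
  guard <- 0L
  while (i <= n) {
    sim <- .simulateOne(model, maxLen)
    guard <- guard + 1L
    if (length(sim$res) == 0 && guard < 100L * max(n, 1L)) next  # resample empties
    sims[[i]] <- sim
    i <- i + 1L
  }
  chars <- vapply(sims, function(s)
    paste0(model@alphabet[s$res], collapse = ""), character(1))
  names(chars) <- sprintf("seq%d", seq_len(max(n, 0)))
  dss <- Biostrings::DNAStringSet(chars)
  if (!withAlignment) return(dss)
  alns <- lapply(sims, function(s) {
    emitting <- s$role != "D"
    resid <- rep(NA_character_, length(s$role))
    resid[emitting] <- model@alphabet[s$res]
    data.frame(role = s$role, position = s$pos, residue = resid,
               stringsAsFactors = FALSE)
  })
  list(sequences = dss, alignments = alns)
}

#' Mean identity of sampled sequences to the consensus at match states
#'
#' For samples drawn with \code{withAlignment = TRUE}, the fraction of
#' match-state emissions that agree with the consensus residue at their
#' position, pooled over all sequences.
#'
#' @param samples result of \code{sampleSequences(..., withAlignment=TRUE)}.
#' @param consensus consensus sequence (character string).
#' @return scalar in \code{[0, 1]}.
#' @export
matchIdentity <- function(samples, consensus) {
  cons <- strsplit(consensus, "")[[1]]
  agree <- unlist(lapply(samples$alignments, function(a) {
    m <- a$role == "M"
    a$residue[m] == cons[a$position[m]]
  }))
  mean(agree)
}

#' Random starting profile
#'
#' Match emission distributions are drawn from the uniform (flat Dirichlet)
#' distribution on the simplex; insertion emissions are even (.25 each).
#' In the simulation regime the transitions are the global-mode defaults;
#' in the transposon regime they are the local-mode starting table (Match
#' enters DeletionOut with .9, continues with .095; gaps extend and end
#' with .5 each; Begin enters DeletionIn with .9).
#'
#' @param length model length.
#' @param regime \code{"simulation"} or \code{"transposon"}.
#' @param seed RNG seed.
#' @return A [ProfileHMM-class].
#' @export
randomStartProfile <- function(length, regime = c("simulation", "transposon"),
                               seed = 1L) {
  regime <- match.arg(regime)
  set.seed(seed)
  base <- buildPlan7(length, localMode = regime == "transposon")
  g <- matrix(stats::rgamma(4 * length, 1), length, 4)
  ME <- g / rowSums(g)
  newProfileHMM(ME, base@insertEmissions, base@transitions, base@begin,
                base@deletionInOut, localMode = isLocal(base),
                alphabet = base@alphabet)
}

#' Shuffle a sequence
#'
#' Uniform random permutation of the residues; the residue composition is
#' preserved exactly.  Used to build null targets for score calibration.
#'
#' @param seq a single sequence (string, \code{DNAString}, or length-one
#'   \code{DNAStringSet}).
#' @param seed RNG seed.
#' @return character string.
#' @export
shuffleSequence <- function(seq, seed = 1L) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  set.seed(seed)
  paste0(sample(ch), collapse = "")
}
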