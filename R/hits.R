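#' Shuffle-calibrated score threshold
#'
#' Scans a shuffled copy of the target with the profile, orders the hit
#' scores, and returns the smallest score such that strictly greater
#' scores make up at most \code{topFraction} of the shuffled hits -- the
#' minimum-score rule under which only the stated fraction of null hits
#' would pass.  Hits on the shuffled target are collected down to log-odds
#' zero (no better than background).
#'
#' @param model a local-mode [ProfileHMM-class].
#' @param shuffledTarget a shuffled target sequence (see
#'   [shuffleSequence()]).
#' @param topFraction fraction of null hits allowed above the threshold
#'   (default .05).
#' @return numeric threshold; \code{-Inf} (accept-all, with a warning)
#'   when the shuffled target yields no hits at all.
#' @export
empiricalThreshold <- function(model, shuffledTarget, topFraction = .05) {
  hits <- scanProfile(model, shuffledTarget, threshold = 0,
                      bothStrands = FALSE)
  scores <- hits$score
  if (length(scores) == 0) {
    warning("no hits on the shuffled target; returning an accept-all threshold")
    return(-Inf)
  }
  thresholdFromScores(scores, topFraction)
}

#' @rdname empiricalThreshold
#' @param scores numeric vector of null hit scores.
#' @export
thresholdFromScores <- function(scores, topFraction = .05) {
  for (x in sort(unique(scores))) {
    if (mean(scores > x) <= topFraction) return(x)
  }
  max(scores)
}

#' Scan a target sequence for profile hits
#'
#' Greedy best-hit-and-mask search: the best local Viterbi alignment is
#' extracted, recorded if its score reaches the threshold, its span masked,
#' and the search repeated until no remaining hit reaches the threshold.
#' Hits are therefore non-overlapping per strand.  The reverse strand is
#' scanned on the reverse complement with coordinates mapped back to the
#' forward strand (1-based inclusive throughout).
#'
#' @param model a local-mode [ProfileHMM-class].
#' @param target a single target sequence.
#' @param threshold minimum log-odds score (e.g. from
#'   [empiricalThreshold()]).
#' @param bothStrands also scan the reverse complement?
#' @param targetId identifier recorded for the hits.
#' @param maxHits safety cap on the number of hits per strand.
#' @return data.frame of class \code{plan7Hits} with columns \code{target},
#'   \code{start}, \code{end}, \code{strand}, \code{score}, ordered by
#'   score; the Viterbi paths are attached as attribute \code{paths}.
#' @export
scanProfile <- function(model, target, threshold, bothStrands = TRUE,
                        targetId = "target", maxHits = 10000L) {
  if (!isLocal(model)) stop("scanProfile requires a local-mode model")
  code <- .encodeSeqs(target)[[1]]
  K <- length(code)
  scanStrand <- function(codes, strand) {
    rows <- list(); paths <- list()
    while (length(rows) < maxHits) {
      vit <- cpp_viterbi_local(.asCList(model), codes)
      if (!is.finite(vit$score) || vit$score < threshold) break
      s <- vit$start; e <- vit$end
      if (strand == "-") { s <- K - vit$end + 1L; e <- K - vit$start + 1L }
      rows[[length(rows) + 1]] <-
        data.frame(target = targetId, start = s, end = e, strand = strand,
                   score = vit$score, stringsAsFactors = FALSE)
      paths[[length(paths) + 1]] <- vit$path
      codes[vit$start:vit$end] <- -2L
    }
    list(rows = rows, paths = paths)
  }
  fwd <- scanStrand(code, "+")
  rev <- if (bothStrands) scanStrand(.revcompCodes(code), "-")
         else list(rows = list(), paths = list())
  rows <- c(fwd$rows, rev$rows)
  if (length(rows) == 0) {
    out <- data.frame(target = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    ord <- order(-out$score, out$start)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "paths") <- c(fwd$paths, rev$paths)[ord]
  }
  class(out) <- c("plan7Hits", class(out))
  out
}

#' Render a hit as a pairwise alignment text block
#'
#' Crossmatch-style rendering: target row on top, model consensus row on
#' the bottom, and a middle annotation row with spaces for exact matches,
#' \code{"i"} for transitions, \code{"v"} for transversions and \code{"-"}
#' for gaps.
#'
#' @param path a Viterbi path (integer matrix as stored in the
#'   \code{paths} attribute of [scanProfile()], or the \code{path}
#'   data.frame of [viterbiLocal()]).
#' @param model the profile scanned with.
#' @param target the target sequence the path refers to.
#' @param width characters per block.
#' @return character vector of text lines.
#' @export
renderHitAlignment <- function(path, model, target, width = 60L) {
  if (is.data.frame(path))
    path <- cbind(path$position,
                  match(path$role, c("M", "I", "D")) - 1L, path$tau)
  cons <- strsplit(consensusSequence(model), "")[[1]]
  tgt <- strsplit(toupper(as.character(target)), "")[[1]]
  top <- mid <- bot <- character(nrow(path))
  for (i in seq_len(nrow(path))) {
    p <- path[i, 1]; role <- path[i, 2]; tau <- path[i, 3]
    if (role == 0L) {         # Match
      top[i] <- tgt[tau]; bot[i] <- cons[p]
      mid[i] <- if (top[i] == bot[i]) " "
                else unname(c(match = " ", transition = "i",
                              transversion = "v")[classifyPair(top[i], bot[i])])
    } else if (role == 1L) {  # Insertion
      top[i] <- tgt[tau]; bot[i] <- "-"; mid[i] <- "-"
    } else {                  # Deletion
      top[i] <- "-"; bot[i] <- cons[p]; mid[i] <- "-"
    }
  }
  lines <- character(0)
  for (off in seq(1, length(top), by = width)) {
    idx <- off:min(off + width - 1, length(top))
    lines <- c(lines,
               paste0("target    ", paste0(top[idx], collapse = "")),
               paste0("          ", paste0(mid[idx], collapse = "")),
               paste0("consensus ", paste0(bot[idx], collapse = "")),
               "")
  }
  lines
}
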