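#' Classify a nucleotide substitution
#'
#' Equal residues (case-folded) are matches; substitutions within the
#' purine set (A, G) or within the pyrimidine set (C, T) are transitions,
#' the chemically favoured mutations; all other substitutions are
#' transversions.  Vectorized.  Gap characters are an error here -- gaps
#' are classified at the column level.  The ambiguity code N is placed in
#' the transversion class (the conservative choice for the score);
#' downstream tallies count such columns separately as ambiguous.
#'
#' @param a,b residue characters.
#' @return character vector over \code{match}, \code{transition},
#'   \code{transversion}.
#' @examples
#' classifyPair("A", "G")  # transition
#' @export
classifyPair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(a %in% c("-", ".")) || any(b %in% c("-", ".")))
    stop("gap characters cannot be classified as substitutions")
  out <- rep("transversion", length(a))
  sameClass <- (a %in% c("A", "G") & b %in% c("A", "G")) |
               (a %in% c("C", "T") & b %in% c("C", "T"))
  out[sameClass] <- "transition"
  out[a == b & a %in% c("A", "C", "G", "T")] <- "match"
  out
}

#' Construct a genome-genome fragment alignment
#'
#' A fragment pairs an interval on genome A with an interval on genome B
#' via a gapped alignment (two equal-length rows, \code{"-"} for gaps);
#' removing the gaps from each row recovers the genomic substring.
#' Coordinates are 1-based inclusive.  Fragments emulate the fragment
#' semantics of chain/net genome-genome alignments.
#'
#' @param chromA,startA,endA,strandA A-side location.
#' @param alnA,alnB gapped alignment rows.
#' @param chromB,startB,endB,strandB B-side location.
#' @return list of class \code{genomeFragment}.
#' @export
genomeFragment <- function(chromA, startA, endA, strandA, alnA,
                           chromB, startB, endB, strandB, alnB) {
  alnA <- toupper(alnA); alnB <- toupper(alnB)
  if (nchar(alnA) != nchar(alnB))
    stop("alignment rows have different lengths")
  lenA <- nchar(gsub("-", "", alnA)); lenB <- nchar(gsub("-", "", alnB))
  if (lenA != endA - startA + 1)
    stop("ungapped A row length disagrees with the A coordinates")
  if (lenB != endB - startB + 1)
    stop("ungapped B row length disagrees with the B coordinates")
  structure(list(chromA = chromA, startA = startA, endA = endA,
                 strandA = strandA, alnA = alnA, chromB = chromB,
                 startB = startB, endB = endB, strandB = strandB,
                 alnB = alnB),
            class = "genomeFragment")
}

#' Swap the two genomes of a fragment
#' @param fragment a [genomeFragment()].
#' @return the fragment with the A and B roles exchanged.
#' @export
swapFragment <- function(fragment) {
  genomeFragment(fragment$chromB, fragment$startB, fragment$endB,
                 fragment$strandB, fragment$alnB,
                 fragment$chromA, fragment$startA, fragment$endA,
                 fragment$strandA, fragment$alnA)
}

# per-column genomic coordinate of a gapped row ('+' ascending,
# '-' descending); NA at gap columns
.columnCoords <- function(aln, start, end, strand) {
  ch <- strsplit(aln, "")[[1]]
  nonGap <- ch != "-"
  coord <- rep(NA_integer_, length(ch))
  coord[nonGap] <- if (strand == "-") end + 1L - cumsum(nonGap)[nonGap]
                   else start - 1L + cumsum(nonGap)[nonGap]
  list(chars = ch, coord = coord)
}

#' Build a transitive pileup of two hits through a genome-genome fragment
#'
#' Projects a hit on genome A and a hit on genome B into the fragment's
#' alignment columns, yielding four column-aligned rows: element A, genome
#' A, genome B, element B.  An element row carries its genomic residue at
#' columns its hit covers and \code{"-"} elsewhere; residues are set to
#' lowercase at columns where the *other* genome's row is gapped, marking
#' stretches that cannot possibly align transitively.
#'
#' @param hitA,hitB one-row data.frames (or lists) with \code{start} and
#'   \code{end} coordinates on genome A and B respectively.
#' @param fragment a [genomeFragment()].
#' @return list of class \code{transitivePileup} with character-vector
#'   rows \code{elementA}, \code{genomeA}, \code{genomeB}, \code{elementB};
#'   zero columns when a hit does not overlap the fragment.
#' @export
buildPileup <- function(hitA, hitB, fragment) {
  A <- .columnCoords(fragment$alnA, fragment$startA, fragment$endA,
                     fragment$strandA)
  B <- .columnCoords(fragment$alnB, fragment$startB, fragment$endB,
                     fragment$strandB)
  covA <- !is.na(A$coord) & A$coord >= hitA$start & A$coord <= hitA$end
  covB <- !is.na(B$coord) & B$coord >= hitB$start & B$coord <= hitB$end
  empty <- structure(list(elementA = character(0), genomeA = character(0),
                          genomeB = character(0), elementB = character(0)),
                     class = "transitivePileup")
  if (!any(covA) || !any(covB)) return(empty)
  eA <- ifelse(covA, A$chars, "-")
  eB <- ifelse(covB, B$chars, "-")
  gapB <- B$chars == "-"; gapA <- A$chars == "-"
  eA[covA & gapB] <- tolower(eA[covA & gapB])
  eB[covB & gapA] <- tolower(eB[covB & gapA])
  structure(list(elementA = eA, genomeA = A$chars, genomeB = B$chars,
                 elementB = eB),
            class = "transitivePileup")
}

#' Transitive alignment between two elements
#'
#' Drops the genome rows from a pileup, leaving the implied pairwise
#' alignment between the two elements.  Columns at which the
#' genome-genome alignment itself is gapped become dot-gap columns
#' (rendered \code{"."}) and are excluded from all statistics; remaining
#' columns are classified as match, transition, transversion or gap.  The
#' alignment is trimmed to the span covered by at least one element.
#'
#' @param pileup a [buildPileup()] result.
#' @return list of class \code{transitiveAlignment}: \code{elementA},
#'   \code{elementB} (character vectors), \code{classes} (per column:
#'   match/transition/transversion/gap/dotgap), \code{tallies} (named
#'   counts, dot-gap columns excluded from the first four),
#'   \code{ambiguous} (count of N-containing classified columns) and
#'   \code{score} (matches + transitions).
#' @export
transitiveAlign <- function(pileup) {
  present <- function(x) x != "-" & x != "."
  keep <- which(present(pileup$elementA) | present(pileup$elementB))
  out <- structure(list(elementA = character(0), elementB = character(0),
                        classes = character(0),
                        tallies = c(matches = 0L, transitions = 0L,
                                    transversions = 0L, gaps = 0L,
                                    dotgaps = 0L),
                        ambiguous = 0L, score = 0L),
                   class = "transitiveAlignment")
  if (length(keep) == 0) return(out)
  idx <- min(keep):max(keep)
  eA <- pileup$elementA[idx]; eB <- pileup$elementB[idx]
  gA <- pileup$genomeA[idx]; gB <- pileup$genomeB[idx]
  classes <- character(length(idx))
  ambiguous <- 0L
  for (i in seq_along(idx)) {
    if (gA[i] == "-" || gB[i] == "-") {
      classes[i] <- "dotgap"
      if (gA[i] == "-" && !present(eA[i])) eA[i] <- "."
      if (gB[i] == "-" && !present(eB[i])) eB[i] <- "."
    } else if (present(eA[i]) && present(eB[i])) {
      classes[i] <- classifyPair(eA[i], eB[i])
      if (toupper(eA[i]) == "N" || toupper(eB[i]) == "N")
        ambiguous <- ambiguous + 1L
    } else {
      classes[i] <- "gap"
    }
  }
  tallies <- c(matches = sum(classes == "match"),
               transitions = sum(classes == "transition"),
               transversions = sum(classes == "transversion"),
               gaps = sum(classes == "gap"),
               dotgaps = sum(classes == "dotgap"))
  structure(list(elementA = eA, elementB = eB, classes = classes,
                 tallies = tallies, ambiguous = ambiguous,
                 score = unname(tallies["matches"] + tallies["transitions"])),
            class = "transitiveAlignment")
}

#' Render a transitive alignment
#'
#' Element rows with a middle annotation line: space for matches,
#' \code{"i"} for transitions, \code{"v"} for transversions, \code{"-"}
#' for gaps and \code{"."} for dot-gap columns; a footer reports the
#' statistics (computed after removing the dot-gap columns).
#'
#' @param ta a [transitiveAlign()] result.
#' @param width characters per block.
#' @return character vector of text lines.
#' @export
renderTransitiveAlignment <- function(ta, width = 60L) {
  sym <- c(match = " ", transition = "i", transversion = "v", gap = "-",
           dotgap = ".")
  mid <- unname(sym[ta$classes])
  lines <- character(0)
  n <- length(ta$classes)
  for (off in seq(1, max(n, 1), by = width)) {
    if (n == 0) break
    idx <- off:min(off + width - 1, n)
    lines <- c(lines,
               paste0("elementA ", paste0(ta$elementA[idx], collapse = "")),
               paste0("         ", paste0(mid[idx], collapse = "")),
               paste0("elementB ", paste0(ta$elementB[idx], collapse = "")),
               "")
  }
  t <- ta$tallies
  c(lines, sprintf(
    "matches: %d  transitions: %d  transversions: %d  gaps: %d  (score %d; %d dot-gap columns excluded)",
    t["matches"], t["transitions"], t["transversions"], t["gaps"],
    ta$score, t["dotgaps"]))
}

#' Evaluate two hit sets through a fragment map
#'
#' Every (hit on A, hit on B, fragment) triple whose coordinates mutually
#' overlap yields one transitive alignment; a hit pair aligning through
#' several fragments yields one alignment per fragment.  Duplicate triples
#' (by coordinates) are removed before totalling.  Hits are matched to
#' fragments by sequence name (\code{target} column against the fragment's
#' chromosome).
#'
#' @param hitsA,hitsB hit data.frames with columns \code{target},
#'   \code{start}, \code{end} (e.g. from [scanProfile()]).
#' @param fragments list of [genomeFragment()] objects.
#' @param dedupe drop duplicate triples?
#' @return list: \code{summary} (data.frame with \code{nTransitive},
#'   \code{matches}, \code{transitions}, \code{transversions},
#'   \code{gaps}, \code{score}) and \code{alignments} (list of
#'   \code{transitiveAlignment} objects).
#' @export
evaluateHitsets <- function(hitsA, hitsB, fragments, dedupe = TRUE) {
  alns <- list()
  seen <- character(0)
  for (f in fragments) {
    ia <- which(hitsA$target == f$chromA &
                hitsA$start <= f$endA & hitsA$end >= f$startA)
    ib <- which(hitsB$target == f$chromB &
                hitsB$start <= f$endB & hitsB$end >= f$startB)
    for (a in ia) for (b in ib) {
      key <- paste(f$chromA, f$startA, f$endA, f$chromB, f$startB, f$endB,
                   hitsA$start[a], hitsA$end[a], hitsB$start[b],
                   hitsB$end[b], sep = "|")
      if (dedupe && key %in% seen) next
      seen <- c(seen, key)
      ta <- transitiveAlign(buildPileup(hitsA[a, ], hitsB[b, ], f))
      if (length(ta$classes) > 0) alns[[length(alns) + 1]] <- ta
    }
  }
  tot <- function(k) sum(vapply(alns, function(x) as.numeric(x$tallies[k]),
                                numeric(1)))
  list(summary = data.frame(
         nTransitive = length(alns),
         matches = tot("matches"), transitions = tot("transitions"),
         transversions = tot("transversions"), gaps = tot("gaps"),
         score = tot("matches") + tot("transitions")),
       alignments = alns)
}
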