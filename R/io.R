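#' Read sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that keeps record
#' order and identifiers (first whitespace-delimited token), case-folds
#' residues and supports wrapped records.
#'
#' @param path FASTA file.
#' @return \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  first <- readLines(path, n = 1)
  if (!startsWith(first, ">"))
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  x
}

#' Write sequences to a FASTA file
#' @param seqs \code{DNAStringSet} or named character vector.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (!inherits(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Keep sequences at least a given length
#' @param seqs \code{DNAStringSet} or character vector.
#' @param minLength minimum length, inclusive.
#' @return the qualifying sequences, order preserved.
#' @export
filterByLength <- function(seqs, minLength) {
  w <- if (inherits(seqs, "XStringSet")) Biostrings::width(seqs)
       else nchar(seqs)
  seqs[w >= minLength]
}

.fmt <- function(x) sprintf("%.17g", x)

#' Serialize a profile HMM to a flat key-value text file
#'
#' A versioned, line-oriented format storing the alphabet, length, mode
#' and every probability vector at full precision; [readProfile()] is the
#' inverse and the round trip reproduces the parameters to within 1e-12.
#'
#' @param model a [ProfileHMM-class].
#' @param path output file.
#' @export
writeProfile <- function(model, path) {
  n <- modelLength(model)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  w("plan7-profile", "1")
  w("alphabet", paste(model@alphabet, collapse = ""))
  w("length", n)
  w("local", as.integer(model@localMode))
  w("insert", paste(.fmt(model@insertEmissions), collapse = "\t"))
  w("begin", paste(.fmt(model@begin), collapse = "\t"))
  w("deletionInOut", paste(.fmt(model@deletionInOut), collapse = "\t"))
  for (p in seq_len(n))
    w("match", p, paste(.fmt(model@matchEmissions[p, ]), collapse = "\t"))
  for (p in seq_len(n))
    w("trans", p, paste(.fmt(model@transitions[p, ]), collapse = "\t"))
  invisible(path)
}

#' @rdname writeProfile
#' @return \code{readProfile} returns the deserialized
#'   [ProfileHMM-class].
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t")
  if (length(fields) == 0 || fields[[1]][1] != "plan7-profile")
    stop("not a plan7 profile file: ", path)
  key <- vapply(fields, `[`, character(1), 1)
  get1 <- function(k) fields[[match(k, key)]][-1]
  alphabet <- strsplit(get1("alphabet"), "")[[1]]
  n <- as.integer(get1("length"))
  local <- as.integer(get1("local")) == 1
  IE <- as.numeric(get1("insert"))
  BG <- as.numeric(get1("begin"))
  DIO <- as.numeric(get1("deletionInOut"))
  ME <- matrix(0, n, 4); TR <- matrix(0, n, 8)
  for (f in fields[key == "match"])
    ME[as.integer(f[2]), ] <- as.numeric(f[-(1:2)])
  for (f in fields[key == "trans"])
    TR[as.integer(f[2]), ] <- as.numeric(f[-(1:2)])
  newProfileHMM(ME, IE, TR, BG, DIO, localMode = local, alphabet = alphabet)
}

#' Read and write training traces
#'
#' One record per training iteration (iteration, log-likelihood, penalized
#' log-posterior, parameter distance, model length, surgery actions, xi),
#' as tab-separated text.
#'
#' @param trace the \code{trace} data.frame of a [trainProfile()] fit.
#' @param path file path.
#' @export
writeTrace <- function(trace, path) {
  write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(actions = "character"))

#' Read and write hit tables
#' @param hits a hits data.frame from [scanProfile()].
#' @param path file path.
#' @export
writeHits <- function(hits, path) {
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' Read and write fragment maps
#'
#' A fragment map is a TSV with one genome-genome fragment per line:
#' columns \code{chromA, startA, endA, strandA, alnA, chromB, startB,
#' endB, strandB, alnB} (see [genomeFragment()]).
#'
#' @param fragments list of [genomeFragment()] objects.
#' @param path file path.
#' @export
writeFragmentMap <- function(fragments, path) {
  df <- do.call(rbind, lapply(fragments, function(f)
    as.data.frame(unclass(f), stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentMap
#' @export
readFragmentMap <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    genomeFragment(df$chromA[i], df$startA[i], df$endA[i], df$strandA[i],
                   df$alnA[i], df$chromB[i], df$startB[i], df$endB[i],
                   df$strandB[i], df$alnB[i]))
}

# HMMer-2-style integer score encoding: s = round(1000 * log2(p / null))
.toScore <- function(p, null = 1) {
  ifelse(p > 0, as.character(round(1000 * log2(p / null))), "*")
}
.fromScore <- function(s, null = 1) {
  ifelse(s == "*", 0, null * 2^(as.numeric(ifelse(s == "*", "0", s)) / 1000))
}

#' Export a local-mode profile in an HMMer-2-style text format
#'
#' Prepares the profile for FS-style search conventions: the null model
#' emission distribution equals the profile's insertion distribution, the
#' null termination probability and the loop-state (inter-hit insertion)
#' termination probability are .25, and all other probabilities transfer
#' unchanged.  Probabilities are printed as integer scores
#' \code{round(1000 * log2(p / null))} (match emissions against the null,
#' transitions against 1), with \code{"*"} for structural zeros, so
#' re-parsing recovers every probability to the printed precision.  The
#' target is semantic fidelity, not byte compatibility with any historical
#' hmmbuild output.
#'
#' @param model a local-mode [ProfileHMM-class].
#' @param name model name recorded in the header.
#' @return character vector of text lines.
#' @export
exportHmmer2 <- function(model, name = "plan7") {
  if (!isLocal(model)) stop("HMMer-2 export supports local-mode models only")
  n <- modelLength(model)
  null <- model@insertEmissions
  lines <- c("HMMER2.0  [plan7-export 1]",
             paste0("NAME  ", name),
             paste0("LENG  ", n),
             "ALPH  Nucleic",
             paste0("NULP  ", paste(.fmt(null), collapse = " ")),
             "NULT  0.25",
             "LOOPT 0.25",
             paste0("BEGIN ",
                    paste(.toScore(model@begin), collapse = " ")),
             paste0("DIO   ",
                    paste(.toScore(model@deletionInOut), collapse = " ")),
             "HMM   A C G T / MM MI MD MDO IM II DM DD")
  for (p in seq_len(n)) {
    lines <- c(lines,
      sprintf("%5d %s", p,
              paste(.toScore(model@matchEmissions[p, ], null), collapse = " ")),
      sprintf("    - %s",
              paste(.toScore(model@insertEmissions, null), collapse = " ")),
      sprintf("    - %s",
              paste(.toScore(model@transitions[p, ]), collapse = " ")))
  }
  c(lines, "//")
}

#' @rdname exportHmmer2
#' @param lines character vector as produced by \code{exportHmmer2}, or a
#'   file path.
#' @param renormalize renormalize each probability group to absorb the
#'   score rounding (yields a valid model); with \code{FALSE} the decoded
#'   probabilities are kept verbatim, so export-parse-export is
#'   byte-identical.
#' @return \code{parseHmmer2} returns the decoded [ProfileHMM-class].
#' @export
parseHmmer2 <- function(lines, renormalize = TRUE) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  if (!startsWith(lines[1], "HMMER2.0")) stop("not an HMMer-2-style file")
  val <- function(tag) {
    ln <- lines[startsWith(lines, tag)][1]
    strsplit(trimws(sub(tag, "", ln)), "\\s+")[[1]]
  }
  n <- as.integer(val("LENG"))
  null <- as.numeric(val("NULP"))
  BG <- .fromScore(val("BEGIN"))
  DIO <- .fromScore(val("DIO"))
  hmmAt <- which(startsWith(lines, "HMM "))[1]
  ME <- matrix(0, n, 4); TR <- matrix(0, n, 8)
  for (p in seq_len(n)) {
    base <- hmmAt + 3 * (p - 1)
    mrow <- strsplit(trimws(lines[base + 1]), "\\s+")[[1]]
    ME[p, ] <- .fromScore(mrow[-1], null)
    trow <- strsplit(trimws(lines[base + 3]), "\\s+")[[1]]
    TR[p, ] <- .fromScore(trow[-1])
  }
  IE <- null
  if (renormalize) {
    renorm <- function(v) if (sum(v) > 0) v / sum(v) else v
    for (p in seq_len(n)) {
      ME[p, ] <- renorm(ME[p, ])
      TR[p, 1:4] <- renorm(TR[p, 1:4])
      TR[p, 5:6] <- renorm(TR[p, 5:6])
      TR[p, 7:8] <- renorm(TR[p, 7:8])
    }
    BG <- renorm(BG)
    DIO[1:2] <- renorm(DIO[1:2]); DIO[3:4] <- renorm(DIO[3:4])
    IE <- renorm(null)
  }
  newProfileHMM(ME, IE, TR, BG, DIO, localMode = TRUE,
                validate = renormalize)
}

#' @rdname exportHmmer2
#' @param path output file.
#' @export
writeHmmer2 <- function(model, path, name = "plan7") {
  writeLines(exportHmmer2(model, name), path)
  invisible(path)
}
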