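# Sequence coercion: the package accepts Biostrings XStringSet objects,
# character vectors, or a single string wherever sequences are expected.
# Internally residues are integer codes 0..3 (A,C,G,T), -1 for the ambiguity
# code N (emits with probability one), -2 for masked positions (hit search).

.encodeOne <- function(x, id = "sequence", alphabet = dnaAlphabet()) {
  ch <- strsplit(toupper(as.character(x)), "")[[1]]
  code <- match(ch, alphabet) - 1L
  code[ch == "N"] <- -1L
  badAt <- which(is.na(code))
  if (length(badAt) > 0)
    stop(sprintf("residue '%s' at position %d of %s is not in the alphabet",
                 ch[badAt[1]], badAt[1], id))
  code
}

.encodeSeqs <- function(x, alphabet = dnaAlphabet()) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (inherits(x, "XString")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be character or Biostrings objects")
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  out <- lapply(seq_along(x), function(i) .encodeOne(x[[i]], ids[i], alphabet))
  names(out) <- ids
  out
}

.decodeSeq <- function(code, alphabet = dnaAlphabet()) {
  ch <- character(length(code))
  ch[code >= 0] <- alphabet[code[code >= 0] + 1L]
  ch[code == -1L] <- "N"
  ch[code == -2L] <- "n"
  paste0(ch, collapse = "")
}

.revcompCodes <- function(code) {
  out <- rev(code)
  pos <- out >= 0
  out[pos] <- 3L - out[pos]
  out
}
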