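# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Random nucleotide sequence
#'
#' Uniform i.i.d. bases over A/C/G/T, drawn from the current RNG stream.
#' Used by the simulator for genomic background and constructs.
#'
#' @param n sequence length in bp.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# vectorized reverse complement, character in / character out
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substitute a base by one of the three others, vectorized
other_base <- function(b) {
  bases <- c("A", "C", "G", "T")
  i <- match(b, bases)
  bases[(i - 1L + sample.int(3L, length(b), replace = TRUE)) %% 4L + 1L]
}

phred_to_string <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(as.integer(v) + 33L)), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(v) as.integer(charToRaw(v)) - 33L)
}

#' Coerce to a validated sequence set
#'
#' A sequence set is a named [Biostrings::DNAStringSet] with unique names,
#' non-empty sequences and alphabet restricted to A/C/G/T/N. It is the
#' coordinate frame for all downstream coordinates (1-based inclusive).
#'
#' @param x a named character vector or a `DNAStringSet`.
#' @return A `DNAStringSet`.
#' @export
as_seqset <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!methods::is(x, "DNAStringSet")) stop("expected a DNAStringSet or named character vector")
  nm <- names(x)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("duplicate sequence names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0)) stop("empty sequences not allowed")
  freq <- Biostrings::alphabetFrequency(x)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, !(colnames(freq) %in% allowed), drop = FALSE])
  if (any(bad > 0)) stop("alphabet restricted to A/C/G/T/N; offending record: ",
                         nm[which(bad > 0)[1]])
  x
}

#' Write a sequence set to FASTA
#'
#' @param x sequence set (see [as_seqset()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(as_seqset(x), path)
  invisible(path)
}

#' Read a FASTA file as a sequence set
#'
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  as_seqset(x)
}
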