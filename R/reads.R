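# read_set: a lightweight container for sequencing reads.
# bases: named character vector; quals: list of integer Phred vectors (or
# NULL for FASTA-style input); origin: simulator-only provenance table.

#' Construct a read set
#'
#' @param bases named character vector of read sequences.
#' @param quals optional list of per-base Phred scores (integer vectors, one
#'   per read, each the same length as its read; values in 0--60).
#' @param origin optional data.frame of simulator provenance with columns
#'   `id`, `chrom`, `start`, `end`, `strand`; consumed only by tests.
#' @return An object of class `read_set`.
#' @export
read_set <- function(bases, quals = NULL, origin = NULL) {
  if (is.null(names(bases)) || anyDuplicated(names(bases)))
    stop("reads must carry unique ids")
  if (!is.null(quals)) {
    if (length(quals) != length(bases)) stop("quals must match bases in length")
    ok <- vapply(seq_along(bases), function(i) {
      length(quals[[i]]) == nchar(bases[[i]]) &&
        all(quals[[i]] >= 0L & quals[[i]] <= 60L)
    }, logical(1))
    if (!all(ok)) stop("quality vector mismatch for read: ",
                       names(bases)[which(!ok)[1]])
    names(quals) <- names(bases)
  }
  structure(list(bases = bases, quals = quals, origin = origin),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$bases)

#' @export
`[.read_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, names(x$bases))
  org <- x$origin
  if (!is.null(org)) org <- org[match(names(x$bases)[i], org$id), , drop = FALSE]
  read_set(x$bases[i], if (is.null(x$quals)) NULL else x$quals[i], org)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, %s bases, %s\n",
              length(x), format(sum(nchar(x$bases)), big.mark = ","),
              if (is.null(x$quals)) "no qualities" else "with qualities"))
  invisible(x)
}

# mean per-read Phred (arithmetic mean of scores, not error-probability mean)
read_mean_q <- function(reads) {
  if (is.null(reads$quals)) stop("reads carry no quality strings")
  vapply(reads$quals, function(q) mean(as.numeric(q)), numeric(1))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads a [read_set()] with qualities.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(reads$quals)) stop("reads carry no quality strings")
  x <- Biostrings::DNAStringSet(reads$bases)
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(phred_to_string(reads$quals)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file.
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  bases <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  quals <- string_to_phred(as.character(S4Vectors::mcols(x)$qualities))
  read_set(bases, quals)
}

#' Summary statistics for a read set
#'
#' N50 is the largest read length L such that reads of length >= L together
#' contain at least half of all sequenced bases.
#'
#' @param reads a [read_set()].
#' @return A list with `n_reads`, `total_bases`, `mean_length`,
#'   `median_length`, `n50` and `mean_quality` (NA without qualities).
#' @export
read_stats <- function(reads) {
  if (length(reads) == 0) stop("empty read set")
  len <- unname(nchar(reads$bases))
  dec <- sort(len, decreasing = TRUE)
  n50 <- dec[which(cumsum(as.numeric(dec)) >= sum(as.numeric(dec)) / 2)[1]]
  list(n_reads = length(len),
       total_bases = sum(as.numeric(len)),
       mean_length = mean(len),
       median_length = median(len),
       n50 = n50,
       mean_quality = if (is.null(reads$quals)) NA_real_
                      else mean(unlist(lapply(reads$quals, as.numeric))))
}
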