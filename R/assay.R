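# Junction sequence assembly and in-silico PCR for event-specific
# detection assays.

#' Assemble a border junction sequence
#'
#' Concatenates the host flank and the vector border fragment in
#' genomic left-to-right order: host then vector at the LB junction,
#' vector then host at the RB junction. Lengths are recorded so the
#' arithmetic (e.g. 400 bp host + 50 bp vector = 450 bp) is explicit.
#'
#' @param host_flank host-derived part (non-empty).
#' @param vector_border vector-derived part (non-empty).
#' @param side `"LB"` or `"RB"`.
#' @return Object of class `junction_sequence`: `side`, `host_part_len`,
#'   `vector_part_len`, `total_len`, `sequence`.
#' @export
assemble_junction <- function(host_flank, vector_border, side = c("LB", "RB")) {
  side <- match.arg(side)
  host_flank <- as.character(host_flank); vector_border <- as.character(vector_border)
  if (!nchar(host_flank) || !nchar(vector_border))
    stop("both junction parts must be non-empty")
  seq <- if (side == "LB") paste0(host_flank, vector_border)
         else paste0(vector_border, host_flank)
  structure(list(side = side,
                 host_part_len = nchar(host_flank),
                 vector_part_len = nchar(vector_border),
                 total_len = nchar(seq), sequence = seq),
            class = "junction_sequence")
}

#' @export
print.junction_sequence <- function(x, ...) {
  cat(sprintf("%s junction: %d bp (%d bp host + %d bp vector)\n",
              x$side, x$total_len, x$host_part_len, x$vector_part_len))
  invisible(x)
}

# IUPAC-aware primer site matching on the plus strand of a template.
# Degenerate codes in the primer are honored; the 3'-terminal bases
# (3 nt at `exact_from`) must match with zero mismatches.
match_primer_sites <- function(primer, template, max_mismatch, three_prime,
                               end = c("last", "first")) {
  end <- match.arg(end)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(primer), template,
                                   max.mismatch = max_mismatch, fixed = FALSE)
  if (length(hits) == 0 || three_prime == 0) return(hits)
  plen <- nchar(primer)
  idx <- if (end == "last") (plen - three_prime + 1L):plen else 1:three_prime
  tail_pat <- Biostrings::DNAString(substr(primer, min(idx), max(idx)))
  keep <- vapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    seg <- Biostrings::subseq(h, min(idx), max(idx))
    Biostrings::neditStartingAt(tail_pat, seg, starting.at = 1,
                                fixed = FALSE) == 0
  }, logical(1))
  hits[keep]
}

#' In-silico PCR
#'
#' Finds forward-primer sites on the plus strand and reverse-primer sites
#' as reverse-complement matches, allowing up to `max_mismatch` mismatches
#' per primer but requiring the 3'-terminal `three_prime_exact` bases to
#' match exactly (polymerase extension realism). IUPAC degenerate bases in
#' the primers match their expansion. All non-overlapping primer-site
#' pairs producing an amplicon of at most `max_product` bp are reported.
#'
#' @param template template sequence (character or `DNAString`).
#' @param forward,reverse primer sequences, 5' to 3' (15--35 nt).
#' @param max_mismatch mismatch budget per primer outside the 3' end.
#' @param three_prime_exact number of 3'-terminal bases requiring an exact
#'   match (default 3).
#' @param max_product maximum product length in bp (default 3000).
#' @return data.frame of products: `start`, `end`, `length`
#'   (`length = end - start + 1`); zero rows when nothing amplifies.
#' @export
in_silico_pcr <- function(template, forward, reverse, max_mismatch = 2,
                          three_prime_exact = 3, max_product = 3000) {
  forward <- toupper(as.character(forward)); reverse <- toupper(as.character(reverse))
  for (p in c(forward, reverse))
    if (nchar(p) < 15 || nchar(p) > 35) stop("primer length must be 15-35 nt")
  template <- Biostrings::DNAString(as.character(template))
  if (length(template) < nchar(forward) + nchar(reverse))
    stop("template shorter than the combined primer length")
  fhits <- match_primer_sites(forward, template, max_mismatch,
                              three_prime_exact, end = "last")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(reverse)))
  # on the plus strand the reverse primer's 3' end is the FIRST base of
  # its reverse-complement site
  rhits <- match_primer_sites(rc, template, max_mismatch,
                              three_prime_exact, end = "first")
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  if (length(fhits) == 0 || length(rhits) == 0) return(out)
  fs <- Biostrings::start(fhits); fe <- Biostrings::end(fhits)
  rs <- Biostrings::start(rhits); re_ <- Biostrings::end(rhits)
  for (i in seq_along(fs)) for (j in seq_along(rs)) {
    if (fe[i] >= rs[j]) next                      # primers must not overlap
    len <- re_[j] - fs[i] + 1L
    if (len > max_product) next
    out <- rbind(out, data.frame(start = fs[i], end = re_[j], length = len))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Validate nested (TAIL-style) PCR product sizes
#'
#' Successive nested reactions with primers positioned progressively
#' inward must shorten the product; the series is valid iff the lengths
#' strictly decrease.
#'
#' @param nested_products numeric vector of product lengths from the
#'   secondary reaction onward (>= 2 values).
#' @return `TRUE` iff strictly decreasing.
#' @export
tail_pcr_product_lengths <- function(nested_products) {
  if (length(nested_products) < 2) stop("need at least two nested products")
  all(diff(nested_products) < 0)
}
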