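# Flank specificity: find all high-similarity genomic copies of a
# junction flank, then profile how their mutual similarity collapses as
# the flank is extended outward in fixed steps.

#' Find high-similarity genomic matches of a flank
#'
#' Seed-and-extend search of the flank against both strands of the genome.
#' Each candidate locus is re-aligned (banded global over the projected
#' region) and kept when its identity exceeds `min_identity` and its
#' alignment contains no single indel run longer than `max_gap`. Identity
#' is matches over alignment columns of the full flank, so partial copies
#' score low. Hits are deduplicated by locus.
#'
#' @param flank flank sequence (>= 50 bp).
#' @param genome `DNAStringSet` to search.
#' @param min_identity identity floor (exclusive), default 0.90.
#' @param max_gap longest tolerated single indel run (bp), default 100.
#' @param k seed size.
#' @return data.frame of matches: `chrom`, `start`, `end`, `strand`,
#'   `identity`, `max_internal_gap`.
#' @export
find_flank_matches <- function(flank, genome, min_identity = 0.90,
                               max_gap = 100, k = 13) {
  flank <- as.character(flank)
  if (nchar(flank) < 50) stop("flank must be at least 50 bp")
  genome <- as_seqset(genome)
  seqs <- setNames(as.character(genome), names(genome))
  diag_tol <- as.integer(1.5 * max_gap + 20)
  fl <- nchar(flank)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") flank else revcomp(flank)
    for (ch in names(seqs)) {
      rseq <- seqs[[ch]]; rlen <- nchar(rseq)
      chains <- chain_hits(cpp_seed_hits(q, rseq, k), k, diag_tol,
                           max_seed_gap = 200L)
      for (chn in chains) {
        # project the whole flank onto the reference around the chain
        rs <- max(1L, chn$rs - (chn$qs - 1L))
        re_ <- min(rlen, chn$re + (fl - chn$qe))
        band <- max(50L, chn$spread + 50L)
        al <- cpp_banded_align(q, substr(rseq, rs, re_), band)
        idy <- al$n_match / al$n_cols
        if (idy <= min_identity || al$max_gap_run > max_gap) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = rs, end = re_, strand = strand,
          identity = idy, max_internal_gap = al$max_gap_run)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), max_internal_gap = numeric(0)))
  out <- do.call(rbind, rows)
  # dedupe overlapping hits at the same locus, keep the best identity
  out <- out[order(-out$identity), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    j <- which(keep[seq_len(i - 1L)])
    same <- out$chrom[j] == out$chrom[i] & out$strand[j] == out$strand[i]
    j <- j[same]
    if (!length(j)) next
    ov <- pmin(out$end[j], out$end[i]) - pmax(out$start[j], out$start[i]) + 1L
    if (any(ov > 0.5 * (out$end[i] - out$start[i] + 1L))) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# extract the extended sequence of one match; returns list(seq, truncated).
# LB flanks extend leftward of the locus in flank orientation, RB
# rightward; minus-strand matches flip the genomic direction accordingly.
extended_sequence <- function(match, seqs, side, L) {
  s <- seqs[[match$chrom]]; n <- nchar(s)
  outward_left <- (side == "LB") == (match$strand == "+")
  if (outward_left) { a <- match$start - L; b <- match$end }
  else { a <- match$start; b <- match$end + L }
  trunc <- a < 1 || b > n
  a <- max(1L, a); b <- min(n, b)
  x <- substr(s, a, b)
  if (match$strand == "-") x <- revcomp(x)
  list(seq = x, truncated = trunc)
}

#' Profile flank ambiguity over stepped extension lengths
#'
#' For each extension length L, every match is extended by L bp in the
#' flank's outward direction (truncated at chromosome ends) and all
#' extended sequences are compared pairwise. Two sequences are similar
#' when their banded global alignment identity, with matches counted over
#' the shorter sequence, reaches `similarity_threshold`. `n_similar`
#' counts sequences having at least one similar partner; `max_hits` is the
#' largest number of partners any one sequence has.
#'
#' @param matches match table from [find_flank_matches()] (>= 1 row; with a
#'   single match the profile is trivially unique everywhere).
#' @param genome `DNAStringSet`.
#' @param side `"LB"` or `"RB"` (sets the outward direction).
#' @param lengths extension lengths in bp (default 500--7,500 by 500).
#' @param similarity_threshold identity threshold, default 0.90.
#' @param focal optional row index of the true locus among `matches`; adds
#'   a `focal_similar` column (that locus's partner count).
#' @return An object of class `flank_profile`: data.frame with
#'   `extension_len`, `n_similar`, `max_hits` (and `focal_similar`),
#'   plus attributes `side` and `similarity_threshold`.
#' @export
extend_and_profile <- function(matches, genome, side = c("LB", "RB"),
                               lengths = seq(500, 7500, by = 500),
                               similarity_threshold = 0.90, focal = NULL) {
  side <- match.arg(side)
  genome <- as_seqset(genome)
  seqs <- setNames(as.character(genome), names(genome))
  stopifnot(nrow(matches) >= 1, !is.unsorted(lengths, strictly = TRUE))
  n <- nrow(matches)
  rows <- lapply(lengths, function(L) {
    ext <- lapply(seq_len(n), function(i)
      extended_sequence(matches[i, ], seqs, side, L))
    sim <- integer(n)
    if (n >= 2) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        a <- ext[[i]]$seq; b <- ext[[j]]$seq
        band <- max(30L, abs(nchar(a) - nchar(b)) %/% 10L + 30L)
        al <- cpp_banded_align(a, b, band)
        if (al$n_match / min(nchar(a), nchar(b)) >= similarity_threshold) {
          sim[i] <- sim[i] + 1L; sim[j] <- sim[j] + 1L
        }
      }
    }
    r <- data.frame(extension_len = L, n_similar = sum(sim > 0L),
                    max_hits = max(0L, sim))
    if (!is.null(focal)) r$focal_similar <- sim[focal]
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "side") <- side
  attr(out, "similarity_threshold") <- similarity_threshold
  class(out) <- c("flank_profile", class(out))
  out
}

#' Smallest extension that makes the flank unique
#'
#' Returns the smallest profiled extension length at which no sequence has
#' more than one similar partner (`max_hits <= 1`) and, when the profile
#' tracks a focal locus, that locus has no similar partner at all; `NA`
#' when no profiled length achieves this.
#'
#' @param profile a `flank_profile` from [extend_and_profile()].
#' @return Integer extension length, or `NA_integer_` if not achieved.
#' @export
minimal_unique_extension <- function(profile) {
  stopifnot(nrow(profile) >= 1)
  ok <- profile$max_hits <= 1
  if (!is.null(profile$focal_similar)) ok <- ok & profile$focal_similar == 0
  i <- which(ok)
  if (!length(i)) NA_integer_ else as.integer(profile$extension_len[i[1]])
}
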