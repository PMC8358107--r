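# Combined host+vector reference and the in-package seed-and-extend
# aligner: exact k-mer seeds, diagonal clustering, greedy end extension
# and a banded global alignment over each chained region for identity.

#' Build a combined host + vector reference
#'
#' Concatenates the host and vector records (host first) and tags each
#' record's provenance, which read classification relies on.
#'
#' @param host,vector sequence sets (see [as_seqset()]).
#' @return A `DNAStringSet` whose `mcols()$source` is `"host"`/`"vector"`.
#' @export
build_combined_reference <- function(host, vector) {
  host <- as_seqset(host); vector <- as_seqset(vector)
  clash <- intersect(names(host), names(vector))
  if (length(clash)) stop("record name present in both host and vector: ",
                          paste(clash, collapse = ", "))
  ref <- c(host, vector)
  S4Vectors::mcols(ref) <- S4Vectors::DataFrame(
    source = rep(c("host", "vector"), c(length(host), length(vector))))
  ref
}

#' Provenance tags of a combined reference
#'
#' @param ref a reference built by [build_combined_reference()].
#' @return Named character vector of `"host"`/`"vector"` tags.
#' @export
ref_source <- function(ref) {
  src <- S4Vectors::mcols(ref)$source
  if (is.null(src)) stop("reference carries no provenance tags; ",
                         "build it with build_combined_reference()")
  setNames(as.character(src), names(ref))
}

#' Write / read a combined reference (FASTA + provenance sidecar TSV)
#'
#' @param ref combined reference.
#' @param fasta_path,tsv_path file paths.
#' @return The paths, invisibly.
#' @export
write_combined_reference <- function(ref, fasta_path, tsv_path) {
  write_fasta(ref, fasta_path)
  write.table(data.frame(name = names(ref), source = ref_source(ref)),
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, tsv_path))
}

#' @rdname write_combined_reference
#' @export
read_combined_reference <- function(fasta_path, tsv_path) {
  ref <- read_fasta(fasta_path)
  tags <- read.delim(tsv_path, stringsAsFactors = FALSE)
  S4Vectors::mcols(ref) <- S4Vectors::DataFrame(
    source = tags$source[match(names(ref), tags$name)])
  ref
}

# mode-dependent aligner defaults
align_defaults <- function(mode) {
  if (mode == "short")
    list(k = 15L, min_segment_len = 30L, min_identity = 0.90,
         diag_tol = 20L, max_seed_gap = 100L)
  else
    list(k = 13L, min_segment_len = 200L, min_identity = 0.70,
         diag_tol = 150L, max_seed_gap = 500L)
}

# grow the exact match outward from (qpos, rpos) in direction dir (+/-1)
greedy_extend <- function(q, r, qpos, rpos, dir) {
  n <- 0L
  nq <- nchar(q); nr <- nchar(r)
  repeat {
    qq <- qpos + dir * (n + 1L); rr <- rpos + dir * (n + 1L)
    if (qq < 1L || rr < 1L || qq > nq || rr > nr) break
    if (substr(q, qq, qq) != substr(r, rr, rr)) break
    n <- n + 1L
  }
  n
}

# chain seed hits for one (query, reference record) pair into segments
chain_hits <- function(hits, k, diag_tol, max_seed_gap) {
  if (nrow(hits) == 0) return(list())
  diag <- hits[, "rpos"] - hits[, "qpos"]
  o <- order(diag, hits[, "qpos"])
  hits <- hits[o, , drop = FALSE]; diag <- diag[o]
  grp <- cumsum(c(1L, diff(diag) > diag_tol))
  out <- list()
  for (g in split(seq_along(grp), grp)) {
    h <- hits[g, , drop = FALSE]
    h <- h[order(h[, "qpos"]), , drop = FALSE]
    sub <- cumsum(c(1L, diff(h[, "qpos"]) > max_seed_gap))
    for (s in split(seq_len(nrow(h)), sub)) {
      hh <- h[s, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        qs = min(hh[, "qpos"]), qe = max(hh[, "qpos"]) + k - 1L,
        rs = min(hh[, "rpos"]), re = max(hh[, "rpos"]) + k - 1L,
        spread = diff(range(hh[, "rpos"] - hh[, "qpos"])))
    }
  }
  out
}

#' Align one read to a combined reference
#'
#' Seed-and-extend local alignment: exact k-mer seeds on both strands are
#' clustered by diagonal, chains are extended outward by exact matching,
#' and each chained region is re-aligned with a banded global alignment to
#' obtain its identity. All chains passing the length and identity floors
#' are reported, so a read lying in a dispersed repeat yields one segment
#' per similar copy.
#'
#' @param read read sequence (single character string) or a 1-read
#'   [read_set()].
#' @param ref combined reference from [build_combined_reference()].
#' @param mode `"short"` or `"long"`; sets the defaults below.
#' @param k seed k-mer size (short 15, long 13).
#' @param min_segment_len minimum aligned length (short 30, long 200).
#' @param min_identity minimum identity, matches over alignment columns
#'   (short 0.90, long 0.70).
#' @param diag_tol diagonal clustering tolerance in bp (short 20, long 150).
#' @param max_seed_gap maximum read-coordinate gap between chained seeds.
#' @param read_id id used in the output (default `"read"`).
#' @return data.frame of alignment segments: `read_id`, `read_start`,
#'   `read_end` (1-based on the original read), `ref_name`, `ref_start`,
#'   `ref_end`, `strand`, `identity`, `aligned_len`, `source`.
#' @export
align_read <- function(read, ref, mode = c("long", "short"),
                       k = NULL, min_segment_len = NULL, min_identity = NULL,
                       diag_tol = NULL, max_seed_gap = NULL,
                       read_id = NULL) {
  mode <- match.arg(mode)
  if (inherits(read, "read_set")) {
    stopifnot(length(read) == 1L)
    read_id <- read_id %||% names(read$bases)
    read <- read$bases[[1L]]
  }
  read_id <- read_id %||% "read"
  d <- align_defaults(mode)
  k <- k %||% d$k
  min_segment_len <- min_segment_len %||% d$min_segment_len
  min_identity <- min_identity %||% d$min_identity
  diag_tol <- diag_tol %||% d$diag_tol
  max_seed_gap <- max_seed_gap %||% d$max_seed_gap
  if (length(ref) == 0) stop("empty reference")
  if (nchar(read) < k) stop("read shorter than the seed size")
  src <- ref_source(ref)
  refseqs <- setNames(as.character(ref), names(ref))
  L <- nchar(read)
  queries <- c(`+` = read, `-` = revcomp(read))
  rows <- list()
  for (strand in c("+", "-")) {
    q <- queries[[strand]]
    for (rn in names(refseqs)) {
      rseq <- refseqs[[rn]]
      chains <- chain_hits(cpp_seed_hits(q, rseq, k), k, diag_tol, max_seed_gap)
      for (chn in chains) {
        ls <- greedy_extend(q, rseq, chn$qs, chn$rs, -1L)
        re_ <- greedy_extend(q, rseq, chn$qe, chn$re, +1L)
        qs <- chn$qs - ls; qe <- chn$qe + re_
        rs <- chn$rs - ls; rend <- chn$re + re_
        band <- max(20L, chn$spread + 20L)
        al <- cpp_banded_align(substr(q, qs, qe), substr(rseq, rs, rend), band)
        idy <- if (al$n_cols > 0) al$n_match / al$n_cols else 0
        alen <- qe - qs + 1L
        if (alen < min_segment_len || idy < min_identity) next
        if (strand == "+") { ors <- qs; ore <- qe }
        else { ors <- L - qe + 1L; ore <- L - qs + 1L }
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read_id, read_start = ors, read_end = ore,
          ref_name = rn, ref_start = rs, ref_end = rend,
          strand = strand, identity = idy, aligned_len = alen,
          source = src[[rn]])
      }
    }
  }
  if (!length(rows)) return(empty_segments())
  out <- do.call(rbind, rows)
  out <- dedupe_segments(out)
  out[order(out$read_start, out$ref_name, out$ref_start), , drop = FALSE]
}

empty_segments <- function() {
  data.frame(read_id = character(0), read_start = integer(0),
             read_end = integer(0), ref_name = character(0),
             ref_start = integer(0), ref_end = integer(0),
             strand = character(0), identity = numeric(0),
             aligned_len = integer(0), source = character(0))
}

# drop near-duplicate segments covering the same reference region on the
# same strand (fragmented chains can rediscover one locus)
dedupe_segments <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  seg <- seg[order(-seg$aligned_len * seg$identity), , drop = FALSE]
  keep <- rep(TRUE, nrow(seg))
  for (i in seq_len(nrow(seg))[-1]) {
    j <- which(keep[seq_len(i - 1L)])
    same <- seg$ref_name[j] == seg$ref_name[i] & seg$strand[j] == seg$strand[i]
    if (!any(same)) next
    j <- j[same]
    ov <- pmin(seg$ref_end[j], seg$ref_end[i]) -
          pmax(seg$ref_start[j], seg$ref_start[i]) + 1L
    span <- seg$ref_end[i] - seg$ref_start[i] + 1L
    if (any(ov > 0.8 * span)) keep[i] <- FALSE
  }
  seg[keep, , drop = FALSE]
}

#' Align every read in a set
#'
#' @inheritParams align_read
#' @param reads a [read_set()].
#' @param ... passed on to [align_read()].
#' @return Named list of segment data.frames, one per read.
#' @export
align_reads <- function(reads, ref, mode = c("long", "short"), ...) {
  mode <- match.arg(mode)
  ids <- names(reads$bases)
  out <- lapply(ids, function(id)
    align_read(reads$bases[[id]], ref, mode = mode, read_id = id, ...))
  setNames(out, ids)
}
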