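# Long-read quality filtering, read classification against the combined
# reference, junction extraction from mixed reads, breakpoint clustering
# and the spanned-interval call.

#' Filter long reads on mean base quality
#'
#' A read is retained iff the arithmetic mean of its per-base Phred scores
#' is at least `min_mean_q` (default Q7, the customary long-read floor).
#'
#' @param reads a [read_set()] with qualities.
#' @param min_mean_q minimum mean Phred score.
#' @return List with `reads` (retained [read_set()]) and `dropped`
#'   (data.frame `read_id`, `mean_q` of removed reads).
#' @export
filter_long_reads <- function(reads, min_mean_q = 7) {
  mq <- read_mean_q(reads)
  keep <- mq >= min_mean_q
  dropped <- data.frame(read_id = names(reads$bases)[!keep],
                        mean_q = unname(mq[!keep]))
  list(reads = reads[which(keep)], dropped = dropped)
}

#' Classify a read from its alignment segments
#'
#' A read is `mixed` iff it has a host segment of at least
#' `min_anchor_host` aligned bp and a vector segment of at least
#' `min_anchor_vector` aligned bp whose read intervals overlap by at most
#' `slack` bp; `host_only`/`vector_only` if exactly one provenance passes
#' its anchor floor; `unmapped` otherwise. The four classes partition any
#' input.
#'
#' @param segments segment data.frame from [align_read()] (one read).
#' @param min_anchor_host,min_anchor_vector minimum anchor lengths (bp).
#'   Short-read work typically uses 30/30, long-read 200/200.
#' @param slack maximum tolerated read-interval overlap between the host
#'   and vector anchors (bp).
#' @return One of `"host_only"`, `"vector_only"`, `"mixed"`, `"unmapped"`.
#' @export
classify_read <- function(segments, min_anchor_host = 200,
                          min_anchor_vector = 200, slack = 20) {
  h <- segments[segments$source == "host" &
                segments$aligned_len >= min_anchor_host, , drop = FALSE]
  v <- segments[segments$source == "vector" &
                segments$aligned_len >= min_anchor_vector, , drop = FALSE]
  if (nrow(h) && nrow(v)) {
    for (i in seq_len(nrow(h))) {
      ov <- pmin(h$read_end[i], v$read_end) - pmax(h$read_start[i], v$read_start) + 1L
      if (any(ov <= slack)) return("mixed")
    }
    return("unmapped")
  }
  if (nrow(h)) return("host_only")
  if (nrow(v)) return("vector_only")
  "unmapped"
}

#' Classify every read in an aligned set
#'
#' @param segment_list named list of segment data.frames ([align_reads()]).
#' @param mode `"short"` or `"long"`; sets anchor defaults (30/30 short,
#'   200/200 long).
#' @param ... passed to [classify_read()].
#' @return Named character vector of classes.
#' @export
classify_reads <- function(segment_list, mode = c("long", "short"), ...) {
  mode <- match.arg(mode)
  anchor <- if (mode == "short") 30L else 200L
  args <- list(...)
  args$min_anchor_host <- args$min_anchor_host %||% anchor
  args$min_anchor_vector <- args$min_anchor_vector %||% anchor
  vapply(segment_list, function(s) do.call(classify_read, c(list(s), args)),
         character(1))
}

#' Extract junction evidence from a mixed read
#'
#' Takes the read's main vector anchor and looks for an adjacent host
#' anchor on each side of it along the read: host segments whose
#' read-coordinate gap to the vector anchor is within `adjacency_tol`
#' (and whose overlap does not exceed `slack`) are candidates, and the
#' longest candidate wins -- in a repeat-rich genome the host flank
#' reaching furthest into unique sequence is the informative one. A read
#' spanning the whole insert therefore yields both an LB and an RB row.
#' The breakpoint is the host anchor's reference coordinate at the read
#' boundary facing the vector; the junction side is `LB` when the
#' abutting vector coordinate lies in the left half of the vector record,
#' `RB` otherwise. If no host anchor is adjacent on either side, the
#' nearest one is used and the row is flagged low-confidence, as is any
#' pairing whose anchors overlap by more than `slack`.
#'
#' @param segments one mixed read's segments.
#' @param ref combined reference (supplies vector lengths).
#' @param min_anchor_host,min_anchor_vector anchor floors, as in
#'   [classify_read()].
#' @param slack maximum clean anchor overlap (bp).
#' @param adjacency_tol maximum read-coordinate gap between the vector
#'   anchor and an adjacent host anchor (bp).
#' @return data.frame with one row per junction side found: `read_id`,
#'   `side`, `host_chrom`, `host_breakpoint`, `vector_breakpoint`,
#'   `host_anchor_start`, `host_anchor_end`, `anchor_len_host`,
#'   `anchor_len_vector`, `low_confidence`; NULL when no host/vector
#'   anchor pair exists.
#' @export
extract_junction <- function(segments, ref, min_anchor_host = 200,
                             min_anchor_vector = 200, slack = 20,
                             adjacency_tol = 500) {
  h <- segments[segments$source == "host" &
                segments$aligned_len >= min_anchor_host, , drop = FALSE]
  v <- segments[segments$source == "vector" &
                segments$aligned_len >= min_anchor_vector, , drop = FALSE]
  if (!nrow(h) || !nrow(v)) return(NULL)
  vs <- v[which.max(v$aligned_len), ]
  vlen <- Biostrings::width(ref)[match(vs$ref_name, names(ref))]

  one_row <- function(hs, host_left, overlap) {
    if (host_left) {
      host_bp <- if (hs$strand == "+") hs$ref_end else hs$ref_start
      vec_bp  <- if (vs$strand == "+") vs$ref_start else vs$ref_end
    } else {
      host_bp <- if (hs$strand == "+") hs$ref_start else hs$ref_end
      vec_bp  <- if (vs$strand == "+") vs$ref_end else vs$ref_start
    }
    data.frame(read_id = hs$read_id,
               side = if (vec_bp <= vlen / 2) "LB" else "RB",
               host_chrom = hs$ref_name,
               host_breakpoint = host_bp, vector_breakpoint = vec_bp,
               host_anchor_start = hs$ref_start, host_anchor_end = hs$ref_end,
               anchor_len_host = hs$aligned_len,
               anchor_len_vector = vs$aligned_len,
               low_confidence = overlap > slack)
  }

  rows <- list()
  for (host_left in c(TRUE, FALSE)) {
    gap <- if (host_left) vs$read_start - h$read_end - 1L
           else h$read_start - vs$read_end - 1L
    cand <- which(gap >= -slack & gap <= adjacency_tol)
    if (length(cand)) {
      i <- cand[which.max(h$aligned_len[cand])]
      rows[[length(rows) + 1L]] <- one_row(h[i, ], host_left, -gap[i])
    }
  }
  if (!length(rows)) {
    # nothing cleanly adjacent: fall back to the nearest host anchor
    gl <- vs$read_start - h$read_end - 1L
    gr <- h$read_start - vs$read_end - 1L
    gap <- pmin(abs(gl), abs(gr))
    i <- which.min(gap)
    host_left <- abs(gl[i]) <= abs(gr[i])
    ov <- if (host_left) -gl[i] else -gr[i]
    r <- one_row(h[i, ], host_left, max(ov, slack + 1L))
    rows[[1L]] <- r
  }
  do.call(rbind, rows)
}

#' Extract junction evidence for all mixed reads
#'
#' @param segment_list named list of per-read segments.
#' @param classes classes from [classify_reads()].
#' @param ref combined reference.
#' @param ... passed to [extract_junction()].
#' @return data.frame of junction evidence (0 rows when nothing is mixed).
#' @export
extract_junctions <- function(segment_list, classes, ref, ...) {
  mixed <- names(classes)[classes == "mixed"]
  rows <- lapply(mixed, function(id) extract_junction(segment_list[[id]], ref, ...))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(read_id = character(0), side = character(0),
                      host_chrom = character(0), host_breakpoint = integer(0),
                      vector_breakpoint = integer(0),
                      host_anchor_start = integer(0), host_anchor_end = integer(0),
                      anchor_len_host = integer(0), anchor_len_vector = integer(0),
                      low_confidence = logical(0)))
  do.call(rbind, rows)
}

#' Cluster junction breakpoints
#'
#' Single-linkage clustering of host breakpoints per chromosome with link
#' distance `max_gap`; the representative is the median breakpoint.
#' Clusters are sorted by support (distinct reads) descending, ties broken
#' by chromosome name then coordinate.
#'
#' @param evidence junction evidence data.frame ([extract_junctions()]).
#' @param max_gap link distance in bp.
#' @return data.frame with `cluster`, `host_chrom`, `representative`,
#'   `support`, `sides_present`, plus a list-column `members` of the
#'   supporting evidence rows.
#' @export
cluster_junctions <- function(evidence, max_gap = 100) {
  if (nrow(evidence) == 0) stop("no junction evidence to cluster")
  out <- list()
  for (ch in sort(unique(evidence$host_chrom))) {
    e <- evidence[evidence$host_chrom == ch, , drop = FALSE]
    e <- e[order(e$host_breakpoint), , drop = FALSE]
    grp <- cumsum(c(1L, diff(e$host_breakpoint) > max_gap))
    for (g in split(seq_len(nrow(e)), grp)) {
      m <- e[g, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        host_chrom = ch,
        representative = as.integer(round(median(m$host_breakpoint))),
        support = length(unique(m$read_id)),
        sides_present = paste(sort(unique(m$side)), collapse = ","),
        members = m)
    }
  }
  df <- data.frame(
    host_chrom = vapply(out, `[[`, character(1), "host_chrom"),
    representative = vapply(out, `[[`, integer(1), "representative"),
    support = vapply(out, `[[`, integer(1), "support"),
    sides_present = vapply(out, `[[`, character(1), "sides_present"))
  df$members <- lapply(out, `[[`, "members")
  df <- df[order(-df$support, df$host_chrom, df$representative), , drop = FALSE]
  df$cluster <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("cluster", "host_chrom", "representative", "support",
         "sides_present", "members")]
}

#' Interval spanned by a cluster's host anchors
#'
#' The envelope of the supporting reads' host anchors:
#' `[min(anchor starts), max(anchor ends)]`. It contains every member's
#' breakpoint by construction.
#'
#' @param members junction evidence rows of one cluster.
#' @return A [genomic_interval()].
#' @export
span_interval <- function(members) {
  if (nrow(members) == 0) stop("need at least one supporting read")
  if (length(unique(members$host_chrom)) != 1)
    stop("members must share one chromosome")
  genomic_interval(members$host_chrom[1],
                   min(members$host_anchor_start),
                   max(members$host_anchor_end))
}
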