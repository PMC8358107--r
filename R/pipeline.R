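# Evidence integration: filter junction clusters by the genetic-mapping
# interval, call the insertion, and the end-to-end orchestration.

#' Filter junction clusters by a mapping interval
#'
#' When a bulked-segregant interval is supplied, clusters whose
#' representative breakpoint lies outside it (or on another chromosome)
#' are rejected with reason `"outside mapped interval"`; without an
#' interval the clusters pass through unchanged. This is the step that
#' lets the genetic map veto repeat-induced spurious junction clusters.
#'
#' @param clusters cluster table from [cluster_junctions()].
#' @param bsa_interval a [genomic_interval()] or `NULL`.
#' @return List with `clusters` (surviving rows) and `rejected`
#'   (data.frame `cluster`, `host_chrom`, `representative`, `reason`).
#' @export
intersect_evidence <- function(clusters, bsa_interval = NULL) {
  if (nrow(clusters) == 0) stop("no clusters supplied")
  if (is.null(bsa_interval))
    return(list(clusters = clusters,
                rejected = data.frame(cluster = integer(0),
                                      host_chrom = character(0),
                                      representative = integer(0),
                                      reason = character(0))))
  keep <- in_interval(bsa_interval, clusters$host_chrom, clusters$representative)
  list(clusters = clusters[keep, , drop = FALSE],
       rejected = data.frame(
         cluster = clusters$cluster[!keep],
         host_chrom = clusters$host_chrom[!keep],
         representative = clusters$representative[!keep],
         reason = rep("outside mapped interval", sum(!keep))))
}

#' Call the insertion site from surviving clusters
#'
#' Selects the cluster with the highest read support (ties broken by most
#' junction sides present, then by chromosome and leftmost coordinate)
#' and reports the interval spanned by its members' host anchors. With
#' zero surviving clusters an explicit no-call carrying the diagnostics is
#' returned instead of an error.
#'
#' @param filtered output of [intersect_evidence()] (or a cluster table).
#' @param bsa_interval the interval used for filtering, if any (recorded
#'   on the call).
#' @param counts optional named list of per-stage counts for the report.
#' @return Object of class `insertion_call`: `called`, `chrom`,
#'   `interval`, `n_supporting_reads`, `sides_present`,
#'   `within_bsa_interval`, `rejected`, `counts`.
#' @export
call_insertion <- function(filtered, bsa_interval = NULL, counts = list()) {
  if (is.data.frame(filtered))
    filtered <- list(clusters = filtered,
                     rejected = data.frame(cluster = integer(0),
                                           host_chrom = character(0),
                                           representative = integer(0),
                                           reason = character(0)))
  cl <- filtered$clusters
  if (nrow(cl) == 0) {
    return(structure(list(called = FALSE, chrom = NA_character_,
                          interval = NULL, n_supporting_reads = 0L,
                          sides_present = "", within_bsa_interval = NA,
                          rejected = filtered$rejected, counts = counts),
                     class = "insertion_call"))
  }
  nsides <- lengths(strsplit(cl$sides_present, ","))
  o <- order(-cl$support, -nsides, cl$host_chrom, cl$representative)
  top <- cl[o[1], ]
  interval <- span_interval(top$members[[1]])
  structure(list(called = TRUE, chrom = top$host_chrom,
                 interval = interval,
                 representative = top$representative,
                 n_supporting_reads = top$support,
                 sides_present = top$sides_present,
                 within_bsa_interval =
                   if (is.null(bsa_interval)) NA
                   else in_interval(bsa_interval, top$host_chrom,
                                    top$representative),
                 rejected = filtered$rejected, counts = counts),
            class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  if (!x$called) {
    cat("insertion call: NO CALL (no surviving junction cluster)\n")
  } else {
    cat(sprintf("insertion call: %s reads (%s side%s) support\n",
                x$n_supporting_reads, x$sides_present,
                if (grepl(",", x$sides_present)) "s" else ""))
    print(x$interval)
  }
  if (length(x$counts)) {
    cat("  stages:", paste(names(x$counts), unlist(x$counts),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Locate a transgene insertion from reads
#'
#' End-to-end orchestration of the sequencing arm: mean-quality filter
#' (long mode, when qualities are present), alignment to the combined
#' host+vector reference, read classification, junction extraction from
#' mixed reads, breakpoint clustering, optional interval veto by a
#' genetic-mapping interval, and the final call. Per-stage counts satisfy
#' `reads_in = q7_dropped + host_only + vector_only + mixed + unmapped`.
#'
#' @param reads a [read_set()].
#' @param host,vector host genome and vector sequence sets.
#' @param mode `"long"` or `"short"` (sets aligner/anchor defaults).
#' @param min_mean_q mean-quality floor applied in long mode when the
#'   reads carry qualities (`NULL` skips filtering).
#' @param bsa_interval optional [genomic_interval()] from the
#'   segregation-mapping arm.
#' @param max_gap junction clustering link distance (bp).
#' @param ... aligner overrides passed to [align_reads()].
#' @return An `insertion_call`; its `counts` hold the per-stage report and
#'   its `evidence`/`clusters` attributes the intermediate tables.
#' @export
locate_insertion <- function(reads, host, vector, mode = c("long", "short"),
                             min_mean_q = 7, bsa_interval = NULL,
                             max_gap = 100, ...) {
  mode <- match.arg(mode)
  ref <- build_combined_reference(host, vector)
  n_in <- length(reads)
  dropped <- data.frame(read_id = character(0), mean_q = numeric(0))
  if (mode == "long" && !is.null(min_mean_q) && !is.null(reads$quals)) {
    flt <- filter_long_reads(reads, min_mean_q)
    reads <- flt$reads; dropped <- flt$dropped
  }
  segs <- align_reads(reads, ref, mode = mode, ...)
  classes <- classify_reads(segs, mode = mode)
  anchor <- if (mode == "short") 30L else 200L
  evidence <- extract_junctions(segs, classes, ref,
                                min_anchor_host = anchor,
                                min_anchor_vector = anchor)
  counts <- list(reads_in = n_in, q7_dropped = nrow(dropped),
                 host_only = sum(classes == "host_only"),
                 vector_only = sum(classes == "vector_only"),
                 mixed = sum(classes == "mixed"),
                 unmapped = sum(classes == "unmapped"))
  if (nrow(evidence) == 0) {
    call <- structure(list(called = FALSE, chrom = NA_character_,
                           interval = NULL, n_supporting_reads = 0L,
                           sides_present = "", within_bsa_interval = NA,
                           rejected = data.frame(), counts = counts),
                      class = "insertion_call")
    attr(call, "evidence") <- evidence
    return(call)
  }
  clusters <- cluster_junctions(evidence, max_gap = max_gap)
  filtered <- intersect_evidence(clusters, bsa_interval)
  counts$clusters <- nrow(clusters)
  counts$rejected <- nrow(filtered$rejected)
  call <- call_insertion(filtered, bsa_interval, counts)
  attr(call, "evidence") <- evidence
  attr(call, "clusters") <- clusters
  call
}
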