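# Tabular and BED/JSON writers. All in-memory coordinates are 1-based
# inclusive; conversion to BED's 0-based half-open convention happens
# here, at the writer boundary only, and is stated in each file header.

#' Write read classifications as TSV
#'
#' @param classes named class vector from [classify_reads()].
#' @param segment_list matching per-read segment list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classes, segment_list, path) {
  df <- data.frame(read_id = names(classes), class = unname(classes),
                   n_segments = vapply(segment_list[names(classes)], nrow,
                                       integer(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write junction clusters as TSV
#'
#' @param clusters cluster table from [cluster_junctions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- clusters[, c("cluster", "host_chrom", "representative", "support",
                     "sides_present")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals or junction evidence as BED
#'
#' @param x a [genomic_interval()], an `insertion_call`, or a junction
#'   evidence data.frame.
#' @param path output path.
#' @param name feature name for interval records.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name = "feature") {
  hdr <- "# BED: 0-based half-open; converted from 1-based inclusive at this writer"
  if (inherits(x, "insertion_call")) {
    if (!x$called) stop("cannot write a no-call as BED")
    x <- x$interval
  }
  if (inherits(x, "genomic_interval")) {
    df <- data.frame(chrom = x$chrom, start = format(x$start - 1, scientific = FALSE, trim = TRUE),
                     end = format(x$end, scientific = FALSE, trim = TRUE), name = name)
  } else {
    df <- data.frame(chrom = x$host_chrom, start = x$host_breakpoint - 1L,
                     end = x$host_breakpoint, name = x$read_id)
  }
  writeLines(hdr, path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE,
                               append = TRUE))
  invisible(path)
}

#' Write a run summary as JSON
#'
#' @param call an `insertion_call`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(call, path) {
  x <- list(called = call$called, chrom = call$chrom,
            interval = if (is.null(call$interval)) NULL
                       else list(chrom = call$interval$chrom,
                                 start = call$interval$start,
                                 end = call$interval$end,
                                 size = call$interval$size),
            n_supporting_reads = call$n_supporting_reads,
            sides_present = call$sides_present,
            within_bsa_interval = call$within_bsa_interval,
            counts = call$counts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a flank profile as TSV
#'
#' @param profile a `flank_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  df <- cbind(side = attr(profile, "side"), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
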