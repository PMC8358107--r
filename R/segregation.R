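# Bulked-segregant arm: chi-square segregation test, locus-count
# inference, polymorphic-marker screen, the strict all-non-transgenic
# cosegregation rule, and recombinant-bounded interval delineation.

#' 1-based genomic interval
#'
#' Coordinates are 1-based inclusive. Following the convention of SSR
#' interval reports, `size` is `end - start` (not `end - start + 1`); the
#' off-by-one with respect to base counts is deliberate and documented.
#'
#' @param chrom chromosome name.
#' @param start,end interval bounds, `start <= end`.
#' @param bounding optional character vector naming the bounding markers.
#' @param open_ended optional flag for intervals truncated at a
#'   chromosome end.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, bounding = NULL,
                             open_ended = FALSE) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("start must be <= end")
  structure(list(chrom = chrom, start = start, end = end,
                 size = end - start, bounding = bounding,
                 open_ended = open_ended),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (size %s bp%s)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              format(x$size, big.mark = ",", scientific = FALSE),
              if (isTRUE(x$open_ended)) ", open-ended" else ""))
  if (!is.null(x$bounding))
    cat("  bounded by:", paste(x$bounding, collapse = " / "), "\n")
  invisible(x)
}

in_interval <- function(interval, chrom, pos) {
  chrom == interval$chrom & pos >= interval$start & pos <= interval$end
}

#' Chi-square test of a segregation ratio
#'
#' Tests observed positive/negative counts against an expected ratio
#' (default 3:1 for a single dominant-scored locus in an F2), with the
#' Yates continuity correction on by default:
#' statistic = sum((|O - E| - c)^2 / E), c = 0.5 (0 when correction off),
#' df = 1. The critical value is the chi-square quantile at `alpha`.
#'
#' @param n_pos,n_neg observed counts (total >= 1).
#' @param ratio expected ratio as a length-2 vector, default `c(3, 1)`.
#' @param correction apply the continuity correction (default TRUE).
#' @param alpha significance level, default 0.05.
#' @return Object of class `segregation_test`: observed/expected counts,
#'   `statistic`, `df`, `critical_value`, and `conclusion`
#'   (`"consistent"` iff statistic < critical value).
#' @export
chi_square_segregation <- function(n_pos, n_neg, ratio = c(3, 1),
                                   correction = TRUE, alpha = 0.05) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be non-negative")
  total <- n_pos + n_neg
  if (total < 1) stop("at least one observation required")
  expected <- total * ratio / sum(ratio)
  cc <- if (correction) 0.5 else 0
  dev <- pmax(0, abs(c(n_pos, n_neg) - expected) - cc)
  statistic <- sum(dev^2 / expected)
  critical <- qchisq(1 - alpha, df = 1)
  structure(list(n_pos = n_pos, n_neg = n_neg, ratio = ratio,
                 expected = expected, correction = correction,
                 statistic = statistic, df = 1L, alpha = alpha,
                 critical_value = critical,
                 conclusion = if (statistic < critical) "consistent"
                              else "inconsistent"),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("chi-square vs %d:%d | observed %d:%d, expected %.2f:%.2f\n",
              x$ratio[1], x$ratio[2], x$n_pos, x$n_neg,
              x$expected[1], x$expected[2]))
  cat(sprintf("  statistic = %.3f (df 1%s), critical = %.2f at alpha %.2f -> %s\n",
              x$statistic,
              if (x$correction) ", continuity-corrected" else "",
              x$critical_value, x$alpha, x$conclusion))
  invisible(x)
}

#' Infer the number of independent insertion loci from segregation
#'
#' Tests the observed counts against 3:1 (one locus) and 15:1 (two
#' independent loci). Returns the unique consistent model, or
#' `"indeterminate"` when both or neither fit.
#'
#' @inheritParams chi_square_segregation
#' @return `"one_locus"`, `"two_loci"` or `"indeterminate"`.
#' @export
infer_locus_count <- function(n_pos, n_neg, alpha = 0.05, correction = TRUE) {
  one <- chi_square_segregation(n_pos, n_neg, c(3, 1), correction, alpha)
  two <- chi_square_segregation(n_pos, n_neg, c(15, 1), correction, alpha)
  fits <- c(one$conclusion == "consistent", two$conclusion == "consistent")
  if (sum(fits) != 1) "indeterminate"
  else if (fits[1]) "one_locus" else "two_loci"
}

#' Screen markers for parental polymorphism
#'
#' A marker is informative for mapping only when the two parents carry
#' different, non-missing alleles.
#'
#' @param parent1,parent2 named character vectors of parental alleles over
#'   the same marker panel (`"missing"` or `NA` for failed assays).
#' @return data.frame `marker`, `polymorphic`, `reason`.
#' @export
screen_polymorphic_markers <- function(parent1, parent2) {
  if (!setequal(names(parent1), names(parent2)))
    stop("parents genotyped on different marker panels")
  parent2 <- parent2[names(parent1)]
  miss <- is.na(parent1) | is.na(parent2) |
    parent1 == "missing" | parent2 == "missing"
  poly <- !miss & parent1 != parent2
  data.frame(marker = names(parent1), polymorphic = unname(poly),
             reason = ifelse(poly, "",
                             ifelse(miss, "missing parental genotype",
                                    "monomorphic")))
}

#' Strict cosegregation linkage test for one marker
#'
#' Among verified non-transgenic F2 plants, a recombinant is a plant
#' carrying at least one transgenic-parent (P1) allele at the marker.
#' Under the strict criterion the marker is linked iff no recombinant is
#' observed; a relaxed threshold is available but off by default. Plants
#' with missing genotypes are excluded from the count.
#'
#' @param f2 an `f2_genotypes` object.
#' @param marker marker name.
#' @param max_recombinants linked iff `n_recombinants <= max_recombinants`
#'   (default 0, the strict rule).
#' @return One-row data.frame: `marker`, `chrom`, `position`, `linked`,
#'   `n_recombinants`, `n_informative`, `n_missing`.
#' @export
linkage_test <- function(f2, marker, max_recombinants = 0) {
  mi <- match(marker, f2$markers$name)
  if (is.na(mi)) stop("unknown marker: ", marker)
  g <- f2$geno[!f2$transgene, marker]
  miss <- g == "missing"
  rec <- g %in% c("P1P1", "P1P2")
  n_rec <- sum(rec & !miss)
  data.frame(marker = marker, chrom = f2$markers$chrom[mi],
             position = f2$markers$position[mi],
             linked = n_rec <= max_recombinants,
             n_recombinants = n_rec,
             n_informative = sum(!miss), n_missing = sum(miss))
}

#' Linkage scan over all markers
#'
#' @inheritParams linkage_test
#' @return data.frame with one [linkage_test()] row per marker, ordered by
#'   chromosome and position.
#' @export
linkage_scan <- function(f2, max_recombinants = 0) {
  out <- do.call(rbind, lapply(f2$markers$name, function(m)
    linkage_test(f2, m, max_recombinants)))
  out[order(out$chrom, out$position), , drop = FALSE]
}

#' Delineate the insertion interval from marker linkage
#'
#' On the chromosome carrying linked markers, the interval is bounded by
#' the nearest markers flanking the linked block that each show at least
#' one recombinant; the bounds are those markers' positions and
#' `size = end - start`. A linked block touching the end of the marker map
#' is reported open-ended on that side, bounded by the chromosome end when
#' `chrom_lengths` is given (else by the outermost linked marker).
#'
#' @param linkage linkage table from [linkage_scan()].
#' @param chrom_lengths optional named chromosome lengths.
#' @return A [genomic_interval()] with `bounding` marker names.
#' @export
delineate_interval <- function(linkage, chrom_lengths = NULL) {
  if (!any(linkage$linked)) stop("no linked marker; cannot delineate")
  ch <- unique(linkage$chrom[linkage$linked])
  if (length(ch) > 1) {
    warning("linked markers on several chromosomes; using the best-supported")
    ch <- names(which.max(tapply(linkage$linked, linkage$chrom, sum)))
  }
  lk <- linkage[linkage$chrom == ch, , drop = FALSE]
  lk <- lk[order(lk$position), , drop = FALSE]
  li <- which(lk$linked)
  left <- rev(which(!lk$linked & lk$n_recombinants >= 1 &
                    seq_len(nrow(lk)) < min(li)))[1]
  right <- which(!lk$linked & lk$n_recombinants >= 1 &
                 seq_len(nrow(lk)) > max(li))[1]
  open <- is.na(left) || is.na(right)
  start <- if (!is.na(left)) lk$position[left]
           else if (!is.null(chrom_lengths)) 1 else lk$position[min(li)]
  end <- if (!is.na(right)) lk$position[right]
         else if (!is.null(chrom_lengths)) chrom_lengths[[ch]]
         else lk$position[max(li)]
  bounding <- c(if (!is.na(left)) lk$marker[left] else "<chromosome start>",
                if (!is.na(right)) lk$marker[right] else "<chromosome end>")
  genomic_interval(ch, start, end, bounding = bounding, open_ended = open)
}
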