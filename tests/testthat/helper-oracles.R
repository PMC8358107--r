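# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

oracle_revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# N50 by brute force over sorted cumulative sums
oracle_n50 <- function(lengths) {
  dec <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(lengths)) / 2
  for (i in seq_along(dec)) if (sum(as.numeric(dec[1:i])) >= half) return(dec[i])
}

# full-DP global alignment identity, matches over alignment columns,
# scored like the package aligner (match 2 / mismatch -3 / linear gap -3)
oracle_global_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, baseOnly = TRUE,
                                                  mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 3)
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# identity with matches counted over the shorter sequence (the flank
# similarity convention)
oracle_shorter_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, baseOnly = TRUE,
                                                  mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 3)
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

# textbook chi-square with optional Yates correction, written out directly
oracle_chisq <- function(o1, o2, ratio = c(3, 1), correct = TRUE) {
  e <- (o1 + o2) * ratio / sum(ratio)
  cc <- if (correct) 0.5 else 0
  d1 <- max(0, abs(o1 - e[1]) - cc); d2 <- max(0, abs(o2 - e[2]) - cc)
  d1^2 / e[1] + d2^2 / e[2]
}

# default marker panel for BSA fixtures on the toy genome: a 10-kb grid
# plus one marker cosegregating with the locus (offset 100 bp)
bsa_markers <- function(chrom = "chr1", chrom_len = 50000, locus = 25000) {
  grid <- seq(5000, chrom_len - 5000, by = 10000)
  data.frame(name = c(sprintf("m%02d", seq_along(grid)), "mloc"),
             chrom = chrom, position = c(grid, locus + 100))
}

# run the full sequencing + mapping pipeline for one seeded case and
# report whether the called interval contains the truth position
run_end_to_end <- function(seed, coverage = 10, error_rate = 0.10,
                           with_bsa = TRUE) {
  s <- simulate_insertion_case(seed)
  lr <- simulate_long_reads(s$genome, length_mean = 15000, length_sd = 5000,
                            min_len = 1000, coverage = coverage,
                            error_rate = error_rate, seed = seed + 1000)
  bsa <- NULL
  if (with_bsa) {
    clen <- setNames(Biostrings::width(s$host), names(s$host))
    mk <- bsa_markers("chr1", clen[["chr1"]], s$truth$insert_pos)
    f2 <- simulate_f2_population(300, mk, list("chr1", s$truth$insert_pos),
                                 recomb_rate_per_bp = 2e-6, seed = seed + 2000)
    bsa <- delineate_interval(linkage_scan(f2), chrom_lengths = clen)
  }
  call <- locate_insertion(lr, s$host, s$vector, mode = "long",
                           bsa_interval = bsa)
  hit <- call$called && call$chrom == s$truth$chrom &&
    call$interval$start <= s$truth$insert_pos &&
    call$interval$end >= s$truth$insert_pos
  list(case = s, call = call, bsa = bsa, hit = hit)
}
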