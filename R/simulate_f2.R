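# F2 mapping population simulator. P1 is the transgenic parent (carries
# the insertion), P2 the non-transgenic parent; both are inbred, so each
# F2 plant is the fusion of two independently recombined F1 gametes.

haldane_r <- function(morgans) 0.5 * (1 - exp(-2 * morgans))

# one chromosome's worth of gametes: n x m allele matrix (1 = P1 allele),
# loci ordered by position, Haldane recombination between adjacent loci
sim_gametes <- function(n, positions, rate) {
  m <- length(positions)
  allele <- matrix(0L, n, m)
  allele[, 1L] <- rbinom(n, 1L, 0.5)
  if (m > 1L) {
    for (j in 2:m) {
      r <- haldane_r(rate * (positions[j] - positions[j - 1L]))
      sw <- rbinom(n, 1L, r)
      allele[, j] <- ifelse(sw == 1L, 1L - allele[, j - 1L], allele[, j - 1L])
    }
  }
  allele
}

#' Simulate an F2 population segregating for a transgene
#'
#' Each plant receives two independently recombined gametes per
#' chromosome; crossover probability between adjacent loci follows the
#' Haldane map function at `recomb_rate_per_bp` Morgans per bp. The plant
#' is transgene-positive unless both gametes carry the non-transgenic (P2)
#' allele at the insertion locus, so segregation converges to 3:1. Marker
#' genotypes derive from the same gametes, so marker-transgene linkage
#' decays with distance.
#'
#' @param n_plants number of F2 plants (>= 20).
#' @param markers data.frame with columns `name`, `chrom`, `position` (bp).
#' @param insertion_locus list or vector `(chrom, position)` of the
#'   transgene; its chromosome must carry at least two markers.
#' @param recomb_rate_per_bp Morgans per bp (maize-like genomes are around
#'   5e-9--1e-8; default 1e-8, i.e. 1 cM per Mb).
#' @param seed integer seed.
#' @param missing_rate per-genotype missing-data probability (default 0).
#' @param chrom_lengths optional named lengths used to validate marker
#'   positions.
#' @return An object of class `f2_genotypes`: list with `markers`,
#'   `plant_id`, `transgene` (logical) and `geno` (plants x markers
#'   character matrix over P1P1/P1P2/P2P2/missing).
#' @export
simulate_f2_population <- function(n_plants, markers, insertion_locus,
                                   recomb_rate_per_bp = 1e-8, seed = 1,
                                   missing_rate = 0, chrom_lengths = NULL) {
  if (n_plants < 20) stop("n_plants must be >= 20")
  if (!all(c("name", "chrom", "position") %in% names(markers)))
    stop("markers needs columns name, chrom, position")
  loc_chrom <- as.character(insertion_locus[[1]])
  loc_pos <- as.numeric(insertion_locus[[2]])
  if (sum(markers$chrom == loc_chrom) < 2)
    stop("the insertion chromosome must carry at least two markers")
  if (!is.null(chrom_lengths)) {
    bad <- markers$chrom[!(markers$chrom %in% names(chrom_lengths))]
    if (length(bad)) stop("marker off-chromosome for stated genome: ",
                          markers$name[match(bad[1], markers$chrom)])
    over <- markers$position > chrom_lengths[markers$chrom]
    if (any(over)) stop("marker beyond chromosome end: ",
                        markers$name[which(over)[1]])
  }
  with_seed(seed, {
    m <- nrow(markers)
    g1 <- matrix(0L, n_plants, m); g2 <- matrix(0L, n_plants, m)
    tg1 <- tg2 <- integer(n_plants)
    for (ch in unique(c(markers$chrom, loc_chrom))) {
      idx <- which(markers$chrom == ch)
      pos <- markers$position[idx]
      has_locus <- ch == loc_chrom
      allpos <- if (has_locus) c(pos, loc_pos) else pos
      ord <- order(allpos)
      a1 <- sim_gametes(n_plants, allpos[ord], recomb_rate_per_bp)
      a2 <- sim_gametes(n_plants, allpos[ord], recomb_rate_per_bp)
      back <- order(ord)          # map sorted columns back to input order
      a1 <- a1[, back, drop = FALSE]; a2 <- a2[, back, drop = FALSE]
      if (has_locus) {
        li <- length(allpos)      # locus was appended last
        tg1 <- a1[, li]; tg2 <- a2[, li]
        a1 <- a1[, -li, drop = FALSE]; a2 <- a2[, -li, drop = FALSE]
      }
      g1[, idx] <- a1; g2[, idx] <- a2
    }
    code <- c("P2P2", "P1P2", "P1P1")
    geno <- matrix(code[g1 + g2 + 1L], n_plants, m,
                   dimnames = list(NULL, markers$name))
    if (missing_rate > 0) {
      drop <- matrix(runif(n_plants * m) < missing_rate, n_plants, m)
      geno[drop] <- "missing"
    }
    structure(list(markers = markers,
                   plant_id = sprintf("plant%05d", seq_len(n_plants)),
                   transgene = (tg1 + tg2) > 0L,
                   geno = geno),
              class = "f2_genotypes")
  })
}

#' @export
print.f2_genotypes <- function(x, ...) {
  cat(sprintf("f2_genotypes: %d plants x %d markers; %d transgenic (%.1f%%)\n",
              length(x$plant_id), nrow(x$markers), sum(x$transgene),
              100 * mean(x$transgene)))
  invisible(x)
}

#' Write / read marker and genotype tables
#'
#' Plain TSV interchange: the marker table has columns
#' `name`/`chrom`/`position`; the genotype table one row per plant with
#' `plant_id`, `transgene` (0/1) and one column per marker.
#'
#' @param f2 an `f2_genotypes` object.
#' @param markers_path,genotypes_path output file paths.
#' @return The paths, invisibly.
#' @export
write_f2_tsv <- function(f2, markers_path, genotypes_path) {
  write.table(f2$markers, markers_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- data.frame(plant_id = f2$plant_id,
                  transgene = as.integer(f2$transgene),
                  f2$geno, check.names = FALSE)
  write.table(g, genotypes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(markers_path, genotypes_path))
}

#' @rdname write_f2_tsv
#' @export
read_f2_tsv <- function(markers_path, genotypes_path) {
  mk <- read.delim(markers_path, stringsAsFactors = FALSE)
  g <- read.delim(genotypes_path, check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(g[, mk$name, drop = FALSE])
  rownames(geno) <- NULL
  structure(list(markers = mk, plant_id = g$plant_id,
                 transgene = g$transgene == 1, geno = geno),
            class = "f2_genotypes")
}
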