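# Synthetic host genomes with dispersed near-identical repeats, plus a
# clean single-copy construct insertion with a known truth record.

#' Specify a dispersed repeat family
#'
#' Describes one family of near-identical repeat copies to embed in a
#' simulated host genome: all copies derive from a single master unit, and
#' each copy independently receives random substitutions at the stated
#' fraction, mimicking a diverged LTR-like family.
#'
#' @param unit_length length of the master repeat unit in bp (>= 100).
#' @param n_copies number of copies to place (>= 1).
#' @param per_copy_divergence substitution fraction per copy, in \[0, 0.1\].
#' @param placement `"random"` for non-overlapping random placement, or a
#'   data.frame with columns `chrom` and `start` (1-based) fixing each copy.
#' @return A list of class `repeat_spec`.
#' @export
repeat_spec <- function(unit_length, n_copies, per_copy_divergence = 0,
                        placement = "random") {
  if (n_copies < 1) stop("n_copies must be >= 1")
  if (unit_length < 100) stop("unit_length must be >= 100")
  if (per_copy_divergence < 0 || per_copy_divergence > 0.1)
    stop("per_copy_divergence must be in [0, 0.1]")
  if (is.data.frame(placement)) {
    if (!all(c("chrom", "start") %in% names(placement)))
      stop("placement data.frame needs columns chrom, start")
    if (nrow(placement) != n_copies)
      stop("placement must list one position per copy")
  } else if (!identical(placement, "random")) {
    stop("placement must be \"random\" or a data.frame")
  }
  structure(list(unit_length = as.integer(unit_length),
                 n_copies = as.integer(n_copies),
                 per_copy_divergence = per_copy_divergence,
                 placement = placement),
            class = "repeat_spec")
}

# apply per-copy divergence to the master unit (substitutions only)
diverge_unit <- function(unit, divergence) {
  if (divergence <= 0) return(unit)
  L <- nchar(unit)
  n_mut <- rbinom(1L, L, divergence)
  if (n_mut == 0L) return(unit)
  pos <- sample.int(L, n_mut)
  ch <- strsplit(unit, "", fixed = TRUE)[[1]]
  ch[pos] <- other_base(ch[pos])
  paste(ch, collapse = "")
}

#' Simulate a host genome with dispersed repeats
#'
#' Generates i.i.d. random background chromosomes, then overwrites
#' `n_copies` windows with independently diverged copies of one master
#' repeat unit. Identical arguments and seed give byte-identical output.
#'
#' @param chrom_lengths integer vector of chromosome lengths (bp); each must
#'   be at least twice the repeat unit length.
#' @param repeats a [repeat_spec()].
#' @param seed integer seed; all randomness in this call derives from it.
#' @return A `DNAStringSet` with chromosomes `chr1..chrN`. The placed repeat
#'   coordinates are recorded in `S4Vectors::metadata(x)$repeats`.
#' @export
make_host_genome <- function(chrom_lengths, repeats, seed) {
  stopifnot(inherits(repeats, "repeat_spec"))
  if (any(chrom_lengths < 2 * repeats$unit_length))
    stop("every chromosome must be at least twice the repeat unit length")
  with_seed(seed, {
    nm <- paste0("chr", seq_along(chrom_lengths))
    seqs <- vapply(chrom_lengths, random_dna, character(1))
    names(seqs) <- nm
    unit <- random_dna(repeats$unit_length)
    uL <- repeats$unit_length

    if (is.data.frame(repeats$placement)) {
      plc <- repeats$placement
      plc$chrom <- as.character(plc$chrom)
    } else {
      # rejection-sample non-overlapping placements, chromosome drawn
      # proportional to length
      plc <- data.frame(chrom = character(0), start = integer(0))
      for (i in seq_len(repeats$n_copies)) {
        ok <- FALSE
        for (try in 1:1000) {
          ci <- sample.int(length(nm), 1L, prob = chrom_lengths)
          st <- sample.int(chrom_lengths[ci] - uL + 1L, 1L)
          clash <- plc$chrom == nm[ci] & abs(plc$start - st) < uL
          if (!any(clash)) {
            plc <- rbind(plc, data.frame(chrom = nm[ci], start = st))
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place repeat copy ", i, " without overlap")
      }
    }

    for (i in seq_len(nrow(plc))) {
      ch <- plc$chrom[i]; st <- plc$start[i]
      if (!ch %in% nm) stop("repeat copy ", i, " placed on unknown chromosome ", ch)
      if (st < 1 || st + uL - 1L > nchar(seqs[[ch]]))
        stop("repeat copy ", i, " out of range on ", ch)
      prev <- plc[seq_len(i - 1L), , drop = FALSE]
      if (any(prev$chrom == ch & abs(prev$start - st) < uL))
        stop("repeat copy ", i, " overlaps an earlier copy on ", ch)
      copy <- diverge_unit(unit, repeats$per_copy_divergence)
      substr(seqs[[ch]], st, st + uL - 1L) <- copy
    }

    g <- as_seqset(seqs)
    S4Vectors::metadata(g)$repeats <-
      data.frame(copy = seq_len(nrow(plc)), chrom = plc$chrom,
                 start = plc$start, end = plc$start + uL - 1L)
    S4Vectors::metadata(g)$repeat_unit <- unit
    g
  })
}

#' Insert a construct into a host genome
#'
#' Clean insertion model: the construct is spliced between host positions
#' `insert_pos` and `insert_pos + 1`; no host bases are deleted and the
#' construct is not truncated. `insert_pos` is the 1-based host base
#' immediately left of the insert.
#'
#' @param genome host `DNAStringSet`.
#' @param chrom chromosome name.
#' @param insert_pos 1-based insertion position (1 <= pos < chrom length).
#' @param construct construct sequence (character or `DNAString`).
#' @param orientation `"forward"` or `"reverse"` (reverse complement).
#' @return A list with `genome` (modified `DNAStringSet`) and `truth`
#'   (a `truth_record`: chrom, insert_pos, construct_len, orientation).
#' @export
insert_construct <- function(genome, chrom, insert_pos, construct,
                             orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  genome <- as_seqset(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  construct <- as.character(construct)
  clen <- nchar(construct)
  if (clen == 0) stop("construct must be non-empty")
  hlen <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (insert_pos < 1 || insert_pos >= hlen)
    stop("insert_pos must satisfy 1 <= pos < chromosome length")
  oriented <- if (orientation == "reverse") revcomp(construct) else construct
  seqs <- setNames(as.character(genome), names(genome))
  s <- seqs[[chrom]]
  seqs[[chrom]] <- paste0(substr(s, 1L, insert_pos), oriented,
                          substr(s, insert_pos + 1L, hlen))
  truth <- structure(list(chrom = chrom, insert_pos = as.integer(insert_pos),
                          construct_len = as.integer(clen),
                          orientation = orientation),
                     class = "truth_record")
  out <- as_seqset(seqs)
  S4Vectors::metadata(out) <- S4Vectors::metadata(genome)
  list(genome = out, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth: %s bp construct (%s) inserted after %s:%s\n",
              format(x$construct_len, big.mark = ","), x$orientation,
              x$chrom, format(x$insert_pos, big.mark = ",")))
  invisible(x)
}

#' Extract a junction flanking sequence from the host genome
#'
#' Returns the host sequence adjacent to the insertion point: the LB flank
#' is the `flank_len` bases ending at `insert_pos`, the RB flank the
#' `flank_len` bases starting at `insert_pos + 1` (coordinates on the
#' unmodified host).
#'
#' @param host unmodified host `DNAStringSet`.
#' @param truth a `truth_record` (or list with `chrom`, `insert_pos`).
#' @param side `"LB"` or `"RB"`.
#' @param flank_len flank length in bp.
#' @return A character string.
#' @export
extract_flank <- function(host, truth, side = c("LB", "RB"), flank_len = 320) {
  side <- match.arg(side)
  host <- as_seqset(host)
  s <- as.character(host[[truth$chrom]])
  p <- truth$insert_pos
  if (side == "LB") substr(s, max(1L, p - flank_len + 1L), p)
  else substr(s, p + 1L, min(nchar(s), p + flank_len))
}

#' Simulate a complete insertion case
#'
#' Convenience wrapper used throughout tests and examples: builds a
#' repeat-bearing host genome, a random construct, and a clean insertion at
#' a stated (or random) position. The default geometry is a 50-kb single
#' chromosome carrying ten 2-kb repeat copies and an 8-kb construct.
#'
#' @param seed integer seed.
#' @param chrom_lengths host chromosome lengths.
#' @param repeats a [repeat_spec()].
#' @param construct_len construct length in bp.
#' @param insert_chrom,insert_pos insertion site; `insert_pos = NULL` draws
#'   a uniform position (excluding the outermost 10% of the chromosome).
#' @param orientation construct orientation.
#' @return List with `host`, `genome` (modified), `vector` (the construct as
#'   a one-record `DNAStringSet` named `"vector"`) and `truth`.
#' @export
simulate_insertion_case <- function(seed,
                                    chrom_lengths = 50000,
                                    repeats = repeat_spec(2000, 10, 0.01),
                                    construct_len = 8000,
                                    insert_chrom = "chr1",
                                    insert_pos = NULL,
                                    orientation = "forward") {
  host <- make_host_genome(chrom_lengths, repeats, seed)
  with_seed(seed + 1L, {
    construct <- random_dna(construct_len)
    if (is.null(insert_pos)) {
      L <- Biostrings::width(host)[match(insert_chrom, names(host))]
      insert_pos <- sample(seq.int(ceiling(L * 0.1), floor(L * 0.9)), 1L)
    }
    ins <- insert_construct(host, insert_chrom, insert_pos, construct, orientation)
    list(host = host, genome = ins$genome,
         vector = as_seqset(setNames(construct, "vector")),
         truth = ins$truth)
  })
}
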