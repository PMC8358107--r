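# Read simulators: 150-bp paired-end short reads (substitution-only
# errors) and long reads with mixed substitution/indel errors and a
# mean-quality model supporting the Q7 filter.

# vectorized substitution injection over a character vector of sequences;
# the per-base Bernoulli(rate) process is realised as a Binomial draw of
# error positions over the concatenated bases
inject_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  big <- paste(seqs, collapse = "")
  raw <- charToRaw(big)
  n <- length(raw)
  n_err <- rbinom(1L, n, rate)
  if (n_err > 0L) {
    pos <- sample.int(n, n_err)
    cur <- rawToChar(raw[pos], multiple = TRUE)
    raw[pos] <- charToRaw(paste(other_base(cur), collapse = ""))
  }
  big <- rawToChar(raw)
  ends <- cumsum(nchar(seqs))
  out <- substring(big, ends - nchar(seqs) + 1L, ends)
  names(out) <- names(seqs)
  out
}

#' Simulate paired-end short reads
#'
#' Uniform fragment sampling over all chromosomes (weighted by length),
#' fragment lengths normal(`fragment_mean`, `fragment_sd`) floored at
#' `read_len`, substitution-only sequencing errors, and mates in
#' forward/reverse-complement orientation. Fragments are emitted until the
#' first fragment that carries total emitted bases past
#' `coverage * genome length`. Per-base qualities are a constant Q37.
#'
#' @param genome `DNAStringSet` to sequence.
#' @param read_len read length (bp), default 150.
#' @param fragment_mean,fragment_sd fragment length distribution (bp);
#'   `fragment_mean` must be at least `read_len` (overlapping mates are
#'   allowed).
#' @param coverage target fold coverage (> 0).
#' @param error_rate per-base substitution rate in \[0, 0.2\].
#' @param seed integer seed.
#' @return List with `r1` and `r2`, each a [read_set()] whose `origin`
#'   records the fragment coordinates (`strand` is the strand of mate 1).
#' @export
simulate_short_reads <- function(genome, read_len = 150, fragment_mean = 450,
                                 fragment_sd = 50, coverage = 30,
                                 error_rate = 0.001, seed = 1) {
  genome <- as_seqset(genome)
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 0.2) stop("error_rate must be in [0, 0.2]")
  if (fragment_mean < read_len) stop("fragment_mean must be >= read_len")
  lens <- Biostrings::width(genome)
  gsize <- sum(as.numeric(lens))
  seqs <- setNames(as.character(genome), names(genome))
  with_seed(seed, {
    budget <- coverage * gsize
    n_frag <- ceiling(budget / (2 * read_len)) + 64L
    ci <- sample.int(length(lens), n_frag, replace = TRUE, prob = lens)
    fl <- pmax(read_len, round(rnorm(n_frag, fragment_mean, fragment_sd)))
    fl <- pmin(fl, lens[ci])
    st <- floor(runif(n_frag) * (lens[ci] - fl + 1)) + 1L
    minus <- runif(n_frag) < 0.5
    # keep fragments up to and including the first that crosses the budget
    keep <- which(cumsum(rep(2 * read_len, n_frag)) - 2 * read_len < budget)
    ci <- ci[keep]; fl <- fl[keep]; st <- st[keep]; minus <- minus[keep]
    n <- length(keep)

    frags <- character(n)
    for (ch in unique(ci)) {
      sel <- ci == ch
      frags[sel] <- substring(seqs[[ch]], st[sel], st[sel] + fl[sel] - 1L)
    }
    frags[minus] <- revcomp(frags[minus])
    r1 <- substring(frags, 1L, read_len)
    r2 <- revcomp(substring(frags, fl - read_len + 1L, fl))
    ids <- sprintf("sr%06d", seq_len(n))
    names(r1) <- names(r2) <- ids
    r1 <- inject_substitutions(r1, error_rate)
    r2 <- inject_substitutions(r2, error_rate)
    origin <- data.frame(id = ids, chrom = names(genome)[ci],
                         start = st, end = st + fl - 1L,
                         strand = ifelse(minus, "-", "+"))
    q <- lapply(seq_len(n), function(i) rep(37L, read_len))
    list(r1 = read_set(r1, q, origin), r2 = read_set(r2, q, origin))
  })
}

# apply mixed substitution/insertion/deletion errors to one sequence
mutate_read <- function(s, error_rate, mix) {
  L <- nchar(s)
  n_err <- rbinom(1L, L, error_rate)
  if (n_err == 0L) return(s)
  pos <- sort(sample.int(L, n_err))
  type <- sample(c("s", "i", "d"), n_err, replace = TRUE, prob = mix)
  pieces <- character(2L * n_err + 1L)
  prev <- 1L
  for (t in seq_len(n_err)) {
    p <- pos[t]
    pieces[2L * t - 1L] <- if (p > prev) substr(s, prev, p - 1L) else ""
    b <- substr(s, p, p)
    pieces[2L * t] <- switch(type[t],
                             s = other_base(b),
                             i = paste0(sample(c("A", "C", "G", "T"), 1L), b),
                             d = "")
    prev <- p + 1L
  }
  pieces[2L * n_err + 1L] <- if (prev <= L) substr(s, prev, L) else ""
  paste(pieces, collapse = "")
}

#' Simulate long reads with an error and quality model
#'
#' Read lengths follow a normal(`length_mean`, `length_sd`) floored at
#' `min_len` (and truncated at chromosome ends). Errors mix substitutions,
#' insertions and deletions in the proportions of `error_mix` (default
#' 50/25/25 of `error_rate`). Each read draws one mean-quality level --
#' with probability `low_q_frac` uniform in \[3, 7) (destined to fail a
#' mean-Q7 filter), otherwise uniform in \[9, 25\] -- and per-base scores
#' are that level plus integer jitter in \[-2, 2\].
#'
#' @param genome `DNAStringSet` to sequence.
#' @param length_mean,length_sd read length distribution (bp).
#' @param min_len minimum read length (>= 500).
#' @param coverage target fold coverage.
#' @param error_rate total per-base error rate in \[0, 0.2\] (the realistic
#'   long-read regime is 0.05--0.15).
#' @param seed integer seed.
#' @param error_mix length-3 proportions (substitution, insertion, deletion).
#' @param low_q_frac fraction of reads given a sub-Q7 mean quality.
#' @return A [read_set()] with `origin` (reference coordinates and strand).
#' @export
simulate_long_reads <- function(genome, length_mean = 20000, length_sd = 5000,
                                min_len = 1000, coverage = 10,
                                error_rate = 0.10, seed = 1,
                                error_mix = c(0.5, 0.25, 0.25),
                                low_q_frac = 0.10) {
  genome <- as_seqset(genome)
  if (error_rate < 0 || error_rate > 0.2) stop("error_rate must be in [0, 0.2]")
  if (min_len < 500) stop("min_len must be >= 500")
  if (coverage <= 0) stop("coverage must be positive")
  lens <- Biostrings::width(genome)
  gsize <- sum(as.numeric(lens))
  seqs <- setNames(as.character(genome), names(genome))
  with_seed(seed, {
    budget <- coverage * gsize
    bases <- 0; k <- 0L
    ids <- character(0); out <- character(0)
    org <- list()
    while (bases < budget) {
      k <- k + 1L
      ci <- sample.int(length(lens), 1L, prob = lens)
      L <- max(min_len, round(rnorm(1L, length_mean, length_sd)))
      L <- min(L, lens[ci])
      st <- sample.int(lens[ci] - L + 1L, 1L)
      minus <- runif(1L) < 0.5
      s <- substring(seqs[[ci]], st, st + L - 1L)
      if (minus) s <- revcomp(s)
      s <- mutate_read(s, error_rate, error_mix)
      id <- sprintf("lr%05d", k)
      ids <- c(ids, id); out <- c(out, s)
      org[[k]] <- data.frame(id = id, chrom = names(genome)[ci],
                             start = st, end = st + L - 1L,
                             strand = if (minus) "-" else "+")
      bases <- bases + L
    }
    names(out) <- ids
    quals <- lapply(out, function(s) {
      n <- nchar(s)
      level <- if (runif(1L) < low_q_frac) floor(runif(1L, 3, 7))
               else floor(runif(1L, 9, 25))
      pmin(60L, pmax(0L, as.integer(level) + sample(-2:2, n, replace = TRUE)))
    })
    read_set(out, quals, do.call(rbind, org))
  })
}
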