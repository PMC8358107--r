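test_that("verbatim planted flank copies are all found at identity 1", {
  set.seed(41)
  flank <- random_dna(320)
  chr <- random_dna(30000)
  starts <- c(2000, 7000, 12000, 17000, 22000)
  for (s in starts) substr(chr, s, s + 319) <- flank
  g <- as_seqset(setNames(chr, "chr1"))
  m <- find_flank_matches(flank, g)
  expect_identical(nrow(m), 5L)
  expect_setequal(m$start, starts)
  expect_true(all(m$identity == 1))
  expect_error(find_flank_matches(substr(flank, 1, 40), g), "50 bp")
})

test_that("a copy carrying a long internal deletion is excluded by the gap rule", {
  set.seed(42)
  flank <- random_dna(320)
  chr <- random_dna(20000)
  substr(chr, 3000, 3319) <- flank
  # plant a copy missing an internal 150-bp block at position 9000
  broken <- paste0(substr(flank, 1, 100), substr(flank, 251, 320))
  substr(chr, 9000, 9000 + nchar(broken) - 1) <- broken
  g <- as_seqset(setNames(chr, "chr1"))
  m <- find_flank_matches(flank, g, min_identity = 0.90, max_gap = 100)
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 3000L)
})

test_that("diverged-copy match counts agree with the per-copy DP oracle", {
  g <- make_host_genome(40000, repeat_spec(320, 10, 0.08), seed = 43)
  unit <- S4Vectors::metadata(g)$repeat_unit
  reps <- S4Vectors::metadata(g)$repeats
  chr <- as.character(g[["chr1"]])
  oracle_n <- sum(vapply(seq_len(nrow(reps)), function(i)
    oracle_global_identity(unit, substring(chr, reps$start[i], reps$end[i])) > 0.90,
    logical(1)))
  m <- find_flank_matches(unit, g, min_identity = 0.90)
  expect_identical(nrow(m), oracle_n)
})

exact_repeat_fixture <- function(seed = 44, n_copies = 10, unit = 2000,
                                 chrom_len = 120000) {
  g <- make_host_genome(chrom_len, repeat_spec(unit, n_copies, 0), seed = seed)
  reps <- S4Vectors::metadata(g)$repeats
  # flank = the last 320 bp of the repeat unit; LB extension walks leftward
  # through the rest of the unit and then out into unique background
  flank <- substring(as.character(g[["chr1"]]),
                     reps$end[1] - 319, reps$end[1])
  list(genome = g, flank = flank)
}

test_that("extension profile collapses from all-similar to unique outside the repeat", {
  fx <- exact_repeat_fixture()
  m <- find_flank_matches(fx$flank, fx$genome)
  expect_identical(nrow(m), 10L)
  p <- extend_and_profile(m, fx$genome, side = "LB",
                          lengths = c(500, 1000, 1500, 4000, 7500))
  expect_identical(p$n_similar[1], 10L)   # extension still inside the repeat
  expect_identical(p$max_hits[1], 9L)
  expect_identical(p$n_similar[nrow(p)], 0L)  # far beyond the repeat
  expect_identical(p$max_hits[nrow(p)], 0L)
})

test_that("ambiguity counts are non-increasing in extension length", {
  fx <- exact_repeat_fixture(seed = 45)
  m <- find_flank_matches(fx$flank, fx$genome)
  p <- extend_and_profile(m, fx$genome, side = "LB",
                          lengths = seq(500, 5000, by = 500))
  expect_true(all(diff(p$n_similar) <= 0))
  expect_true(all(diff(p$max_hits) <= 0))
})

test_that("pairwise similarity agrees with the all-pairs DP oracle", {
  g <- make_host_genome(60000, repeat_spec(1000, 6, 0.03), seed = 46)
  reps <- S4Vectors::metadata(g)$repeats
  chr <- as.character(g[["chr1"]])
  flank <- substring(chr, reps$end[1] - 319, reps$end[1])
  m <- find_flank_matches(flank, g, min_identity = 0.85)
  p <- extend_and_profile(m, g, side = "LB", lengths = c(500, 1500, 3000))
  for (row in seq_len(nrow(p))) {
    L <- p$extension_len[row]
    ext <- vapply(seq_len(nrow(m)), function(i) {
      mm <- m[i, ]
      left <- (mm$strand == "+")
      a <- if (left) max(1, mm$start - L) else mm$start
      b <- if (left) mm$end else min(nchar(chr), mm$end + L)
      s <- substring(chr, a, b)
      if (mm$strand == "-") oracle_revcomp(s) else s
    }, character(1))
    n <- length(ext)
    sim <- integer(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (oracle_shorter_identity(ext[i], ext[j]) >= 0.90) {
        sim[i] <- sim[i] + 1L; sim[j] <- sim[j] + 1L
      }
    }
    expect_identical(p$n_similar[row], sum(sim > 0L))
    expect_identical(p$max_hits[row], max(0L, sim))
  }
})

test_that("a single match is trivially unique at every extension", {
  set.seed(47)
  chr <- random_dna(30000)
  flank <- substr(chr, 10000, 10319)
  g <- as_seqset(setNames(chr, "chr1"))
  m <- find_flank_matches(flank, g)
  expect_identical(nrow(m), 1L)
  p <- extend_and_profile(m, g, side = "RB", lengths = c(500, 1000))
  expect_true(all(p$n_similar == 0L))
  expect_identical(minimal_unique_extension(p), 500L)
})

test_that("minimal unique extension applies its definition to a stated profile", {
  p <- data.frame(extension_len = seq(500, 2500, by = 500),
                  n_similar = c(10L, 10L, 4L, 2L, 0L),
                  max_hits = c(9L, 9L, 3L, 1L, 0L))
  class(p) <- c("flank_profile", class(p))
  expect_identical(minimal_unique_extension(p), 2000L)
  p0 <- data.frame(extension_len = c(500L, 1000L), n_similar = c(0L, 0L),
                   max_hits = c(0L, 0L))
  class(p0) <- c("flank_profile", class(p0))
  expect_identical(minimal_unique_extension(p0), 500L)
  p1 <- data.frame(extension_len = c(500L, 1000L), n_similar = c(5L, 5L),
                   max_hits = c(4L, 4L))
  class(p1) <- c("flank_profile", class(p1))
  expect_identical(minimal_unique_extension(p1), NA_integer_)
})

test_that("uniqueness emerges within a step or two of the repeat length", {
  fx <- exact_repeat_fixture(seed = 48, n_copies = 8, unit = 3000,
                             chrom_len = 150000)
  m <- find_flank_matches(fx$flank, fx$genome)
  p <- extend_and_profile(m, fx$genome, side = "LB",
                          lengths = seq(2000, 5000, by = 500))
  L <- minimal_unique_extension(p)
  expect_false(is.na(L))
  expect_lte(abs(L - 3000), 1000)
})
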