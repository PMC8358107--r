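mk_reads <- function(bases, quals) read_set(bases, quals)

test_that("mean-quality filter keeps Q>=7 reads and logs the dropped ones", {
  rs <- read_set(setNames(c(random_dna(100), random_dna(100)), c("hi", "lo")),
                 list(rep(10L, 100), rep(6L, 100)))
  out <- filter_long_reads(rs, min_mean_q = 7)
  expect_identical(names(out$reads$bases), "hi")
  expect_identical(out$dropped$read_id, "lo")
  expect_equal(out$dropped$mean_q, 6)
  no_q <- read_set(setNames(random_dna(100), "x"))
  expect_error(filter_long_reads(no_q), "no quality")
})

test_that("the Q7 filter retains the simulator's designed high-quality fraction", {
  g <- make_host_genome(50000, repeat_spec(1000, 2, 0), seed = 2)
  rd <- simulate_long_reads(g, length_mean = 2000, length_sd = 300,
                            min_len = 1000, coverage = 41, error_rate = 0.05,
                            seed = 14)
  expect_gte(length(rd), 900)
  out <- filter_long_reads(rd, 7)
  frac <- length(out$reads) / length(rd)
  expect_lt(abs(frac - 0.90), 0.03)
})

test_that("raising the quality floor never increases the retained count", {
  g <- make_host_genome(30000, repeat_spec(1000, 2, 0), seed = 2)
  rd <- simulate_long_reads(g, length_mean = 2000, length_sd = 300,
                            min_len = 1000, coverage = 10, error_rate = 0.05,
                            seed = 15)
  kept <- vapply(c(0, 3, 5, 7, 9, 12, 30), function(q)
    length(filter_long_reads(rd, q)$reads), integer(1))
  expect_true(all(diff(kept) <= 0))
})

seg_row <- function(read_id = "r", rs, re, ref, s, e, strand = "+",
                    src, idy = 0.95) {
  data.frame(read_id = read_id, read_start = rs, read_end = re,
             ref_name = ref, ref_start = s, ref_end = e, strand = strand,
             identity = idy, aligned_len = re - rs + 1L, source = src)
}

test_that("read classification is the stated partition", {
  empty <- insertlocus:::empty_segments()
  expect_identical(classify_read(empty), "unmapped")
  h <- seg_row("r", 1L, 150L, "chr1", 500L, 649L, "+", "host")
  expect_identical(classify_read(h, min_anchor_host = 30,
                                 min_anchor_vector = 30), "host_only")
  v <- seg_row("r", 1L, 150L, "vector", 10L, 159L, "+", "vector")
  expect_identical(classify_read(v, min_anchor_host = 30,
                                 min_anchor_vector = 30), "vector_only")
  hv <- rbind(seg_row("r", 1L, 3000L, "chr1", 1000L, 3999L, "+", "host"),
              seg_row("r", 3010L, 23000L, "vector", 1L, 19991L, "+", "vector"))
  expect_identical(classify_read(hv), "mixed")
  # both anchors present but fully co-located on the read -> unmapped
  hv2 <- rbind(seg_row("r", 1L, 3000L, "chr1", 1000L, 3999L, "+", "host"),
               seg_row("r", 1L, 3000L, "vector", 1L, 3000L, "+", "vector"))
  expect_identical(classify_read(hv2), "unmapped")
})

test_that("classification of simulated reads matches their true origin", {
  case <- simulate_insertion_case(17)
  lr <- simulate_long_reads(case$genome, length_mean = 10000, length_sd = 3000,
                            min_len = 1000, coverage = 6, error_rate = 0.08,
                            seed = 18)
  ref <- build_combined_reference(case$host, case$vector)
  segs <- align_reads(lr, ref, mode = "long")
  classes <- classify_reads(segs, mode = "long")
  # partition property
  expect_identical(length(classes), length(lr))
  expect_true(all(classes %in% c("host_only", "vector_only", "mixed", "unmapped")))
  # reads straddling the truth junction by >= 1 kb on both sides must be mixed
  tp <- case$truth$insert_pos; cl <- case$truth$construct_len
  org <- lr$origin
  straddle <- org$start <= tp - 1000 & org$end >= tp + 1000
  inside <- org$start >= tp + 500 & org$end <= tp + cl - 500
  expect_true(all(classes[org$id[straddle]] == "mixed"))
  expect_true(all(classes[org$id[inside]] == "vector_only"))
})

test_that("junction extraction recovers the breakpoint and side on clean reads", {
  plc <- data.frame(chrom = "chr1", start = c(2000, 8000, 40000, 46000))
  case <- simulate_insertion_case(19, repeats = repeat_spec(1000, 4, 0, plc),
                                  insert_pos = 25000)
  ref <- build_combined_reference(case$host, case$vector)
  mod <- as.character(case$genome[["chr1"]])
  # error-free read covering the LB junction only
  lb_read <- substr(mod, 22001, 27000)  # 3 kb host + 2 kb vector
  seg <- align_read(lb_read, ref, mode = "long", read_id = "lbr")
  ev <- extract_junction(seg, ref)
  expect_identical(ev$side, "LB")
  expect_lte(abs(ev$host_breakpoint - 25000), 10)
  expect_false(ev$low_confidence)
  # read covering the RB junction only (construct is 8 kb)
  rb_read <- substr(mod, 31001, 36000)  # 2 kb vector tail + 3 kb host
  seg2 <- align_read(rb_read, ref, mode = "long", read_id = "rbr")
  ev2 <- extract_junction(seg2, ref)
  expect_identical(ev2$side, "RB")
  expect_lte(abs(ev2$host_breakpoint - 25001), 10)
  # a read spanning the whole insert yields both sides
  span_read <- substr(mod, 23001, 35000)
  seg3 <- align_read(span_read, ref, mode = "long", read_id = "spn")
  ev3 <- extract_junction(seg3, ref)
  expect_setequal(ev3$side, c("LB", "RB"))
})

test_that("reverse-orientation inserts swap the reported junction side", {
  plc <- data.frame(chrom = "chr1", start = c(2000, 8000, 40000, 46000))
  case <- simulate_insertion_case(19, repeats = repeat_spec(1000, 4, 0, plc),
                                  insert_pos = 25000, orientation = "reverse")
  ref <- build_combined_reference(case$host, case$vector)
  mod <- as.character(case$genome[["chr1"]])
  lb_read <- substr(mod, 22001, 27000)  # genomic-left junction
  seg <- align_read(lb_read, ref, mode = "long", read_id = "lbr")
  ev <- extract_junction(seg, ref)
  # reverse-oriented construct presents its right border at the genomic left
  expect_identical(ev$side, "RB")
  expect_lte(abs(ev$host_breakpoint - 25000), 10)
})

test_that("anchor overlap beyond the slack is flagged low-confidence", {
  segs <- rbind(seg_row("r", 1L, 1030L, "chr1", 24000L, 25029L, "+", "host",
                        idy = 0.9),
                seg_row("r", 1001L, 3000L, "vector", 1L, 2000L, "+", "vector",
                        idy = 0.9))
  ev <- extract_junction(segs, build_combined_reference(
    as_seqset(setNames(random_dna(30000), "chr1")),
    as_seqset(setNames(random_dna(8000), "vector"))), slack = 20)
  expect_true(ev$low_confidence)
})

ev_row <- function(id, bp, side = "LB", chrom = "chr1") {
  data.frame(read_id = id, side = side, host_chrom = chrom,
             host_breakpoint = bp, vector_breakpoint = 1L,
             host_anchor_start = bp - 1000L, host_anchor_end = bp + 1000L,
             anchor_len_host = 2000L, anchor_len_vector = 2000L,
             low_confidence = FALSE)
}

test_that("junction clustering groups breakpoints by gap and ranks by support", {
  ev <- do.call(rbind, lapply(1:6, function(i) ev_row(paste0("r", i), 25000L)))
  cl <- cluster_junctions(ev, max_gap = 100)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$support, 6L)
  expect_identical(cl$representative, 25000L)
  ev2 <- rbind(ev, ev_row("s1", 25250L), ev_row("s2", 25250L))
  cl2 <- cluster_junctions(ev2, max_gap = 100)
  expect_identical(nrow(cl2), 2L)
  expect_identical(cl2$support, c(6L, 2L))  # sorted by support
  set.seed(20)
  noisy <- do.call(rbind, lapply(1:10, function(i)
    ev_row(paste0("n", i), 25000L + sample(-10:10, 1))))
  cl3 <- cluster_junctions(noisy, max_gap = 100)
  expect_identical(nrow(cl3), 1L)
  expect_lte(abs(cl3$representative - 25000L), 10L)
})

test_that("the spanned interval is the anchor envelope and contains breakpoints", {
  m1 <- ev_row("a", 25000L); m1$host_anchor_start <- 24000L; m1$host_anchor_end <- 25000L
  iv <- span_interval(m1)
  expect_identical(c(iv$start, iv$end), c(24000, 25000))
  m2 <- ev_row("b", 25000L); m2$host_anchor_start <- 25000L; m2$host_anchor_end <- 32000L
  m3 <- rbind(m1, m2)
  iv2 <- span_interval(m3)
  expect_identical(c(iv2$start, iv2$end), c(24000, 32000))
  expect_true(all(m3$host_breakpoint >= iv2$start & m3$host_breakpoint <= iv2$end))
})
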