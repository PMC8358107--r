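test_that("the 266:87 F2 gives a corrected chi-square of 0.008, consistent with 3:1", {
  res <- chi_square_segregation(266, 87)
  expect_equal(round(res$statistic, 3), 0.008)
  expect_identical(res$conclusion, "consistent")
  expect_equal(round(res$critical_value, 2), 3.84)
  # hand arithmetic: E = 264.75 / 88.25, |O-E| = 1.25, Yates c = 0.5
  expect_equal(res$statistic, 0.75^2 / 264.75 + 0.75^2 / 88.25)
  # without the continuity correction the statistic is noticeably larger
  expect_equal(round(chi_square_segregation(266, 87, correction = FALSE)$statistic, 3),
               0.024)
})

test_that("chi-square handles exact-fit and strongly deviating counts", {
  expect_identical(chi_square_segregation(75, 25, correction = FALSE)$statistic, 0)
  r <- chi_square_segregation(60, 40, correction = FALSE)
  expect_equal(r$statistic, 12)  # 225/75 + 225/25
  expect_identical(r$conclusion, "inconsistent")
  expect_error(chi_square_segregation(0, 0), "at least one")
  expect_error(chi_square_segregation(-1, 5), "non-negative")
})

test_that("chi-square equals the textbook closed form for arbitrary counts", {
  set.seed(50)
  for (i in 1:25) {
    o1 <- sample(0:500, 1); o2 <- sample(1:200, 1)
    corr <- i %% 2 == 0
    expect_equal(chi_square_segregation(o1, o2, correction = corr)$statistic,
                 oracle_chisq(o1, o2, correct = corr), tolerance = 1e-12)
  }
})

test_that("locus count inference separates 3:1 from 15:1 segregation", {
  expect_identical(infer_locus_count(266, 87), "one_locus")
  expect_identical(infer_locus_count(600, 40), "two_loci")
  expect_identical(infer_locus_count(0, 100), "indeterminate")
})

test_that("the polymorphic-marker screen keeps only informative markers", {
  p1 <- c(m1 = "A", m2 = "A", m3 = "missing", m4 = "B")
  p2 <- c(m1 = "B", m2 = "A", m3 = "A", m4 = NA)
  sc <- screen_polymorphic_markers(p1, p2)
  expect_identical(sc$polymorphic, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(sc$reason[2], "monomorphic")
  expect_match(sc$reason[3], "missing")
  expect_error(screen_polymorphic_markers(p1, p2[1:3]), "panels")
})

mk6 <- data.frame(name = paste0("m", 1:6), chrom = "chr1",
                  position = c(5000, 15000, 25000, 35000, 45000, 55000))

test_that("the strict cosegregation rule links only recombinant-free markers", {
  f2 <- simulate_f2_population(300, mk6, list("chr1", 25100),
                               recomb_rate_per_bp = 0, seed = 51)
  lt <- linkage_test(f2, "m3")
  expect_true(lt$linked)
  expect_identical(lt$n_recombinants, 0L)
  # flip one non-transgenic plant to heterozygous: strict linkage breaks
  f2b <- f2
  i <- which(!f2b$transgene)[1]
  f2b$geno[i, "m3"] <- "P1P2"
  ltb <- linkage_test(f2b, "m3")
  expect_false(ltb$linked)
  expect_identical(ltb$n_recombinants, 1L)
  expect_true(linkage_test(f2b, "m3", max_recombinants = 1)$linked)
  # missing genotypes are excluded from the count, not scored
  f2c <- f2
  f2c$geno[which(!f2c$transgene), "m3"] <- "missing"
  ltc <- linkage_test(f2c, "m3")
  expect_identical(ltc$n_informative, 0L)
  expect_identical(ltc$n_recombinants, 0L)
})

test_that("adding a recombinant individual never converts not-linked to linked", {
  f2 <- simulate_f2_population(300, mk6, list("chr1", 25100),
                               recomb_rate_per_bp = 2e-6, seed = 52)
  base <- linkage_scan(f2)
  f2b <- f2
  neg <- which(!f2b$transgene)
  f2b$geno[neg[1], ] <- "P1P2"  # one more recombinant everywhere
  after <- linkage_scan(f2b)
  expect_true(all(after$n_recombinants >= base$n_recombinants))
  expect_true(all(!(after$linked & !base$linked)))
})

test_that("an unlinked chromosome shows independent-assortment recombinant rates", {
  mk <- rbind(mk6, data.frame(name = "off", chrom = "chr2", position = 25000))
  f2 <- simulate_f2_population(10000, mk, list("chr1", 25100),
                               recomb_rate_per_bp = 2e-6, seed = 53)
  lt <- linkage_test(f2, "off")
  # unlinked marker in non-transgenic plants: P(>=1 P1 allele) = 3/4
  p_obs <- lt$n_recombinants / lt$n_informative
  expect_lt(abs(p_obs - 0.75), 3 * sqrt(0.75 * 0.25 / lt$n_informative))
})

test_that("interval delineation is bounded by the nearest recombinant markers", {
  lk <- data.frame(marker = c("a", "b", "c", "d"), chrom = "chr1",
                   position = c(5000, 10000, 15000, 20000),
                   linked = c(FALSE, FALSE, TRUE, FALSE),
                   n_recombinants = c(5L, 2L, 0L, 1L),
                   n_informative = 80L, n_missing = 0L)
  iv <- delineate_interval(lk)
  expect_identical(c(iv$start, iv$end), c(10000, 20000))
  expect_identical(iv$size, 10000)
  expect_identical(iv$bounding, c("b", "d"))
})

test_that("the delineated interval contains the locus in >=95% of replicates", {
  hits <- 0L
  for (r in 1:100) {
    f2 <- simulate_f2_population(300, mk6, list("chr1", 25100),
                                 recomb_rate_per_bp = 2e-6, seed = 600 + r)
    iv <- try(delineate_interval(linkage_scan(f2),
                                 chrom_lengths = c(chr1 = 60000)),
              silent = TRUE)
    if (!inherits(iv, "try-error") &&
        iv$chrom == "chr1" && iv$start <= 25100 && iv$end >= 25100)
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("interval size follows the end-minus-start convention exactly", {
  iv <- genomic_interval("chr9", 26822048, 100724531)
  expect_identical(iv$size, 100724531 - 26822048)
  expect_error(genomic_interval("chr1", 10, 5), "start")
})
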