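make_planted <- function(seed, n_copies = 4, ages = 1e6, genome_length = 60000,
                         ltr_length = 500, internal_length = 1500) {
  cfg <- sim_config(seed = seed, genome_length = genome_length)
  ref <- simulate_reference_element(ltr_length = ltr_length,
                                    internal_length = internal_length,
                                    seed = seed + 1)
  sim <- simulate_genome(cfg, ref, n_copies = n_copies, ages = ages)
  list(cfg = cfg, ref = ref, sim = sim)
}

test_that("an exact planted copy is found with identity and coverage 1", {
  px <- make_planted(seed = 61, n_copies = 1, ages = 0)
  copies <- find_copies(px$sim$genome, px$ref)
  expect_equal(nrow(copies), 1L)
  expect_equal(copies$identity, 1)
  expect_equal(copies$coverage, 1)
  expect_equal(copies$status, "full_length")
  expect_equal(copies$start, px$sim$truth$start)
  expect_equal(copies$end, px$sim$truth$end)
  expect_identical(copies$tsd, px$sim$truth$tsd)

  expect_error(find_copies("", px$ref), "empty genome")
  ltr <- paste0("TG", strrep("ACGT", 6), "CA")       # 28 bp
  short <- reference_element("tiny", "Copia", "x",
                             paste0(ltr, strrep("GATC", 5), ltr),
                             ltr5 = c(1L, 28L), ltr3 = c(49L, 76L))
  expect_error(find_copies(px$sim$genome, short), "reference shorter")
})

test_that("mined identity tracks the simulator's realized identity", {
  px <- make_planted(seed = 62, n_copies = 3, ages = c(2e6, 4e6, 6e6))
  copies <- find_copies(px$sim$genome, px$ref)
  expect_equal(nrow(copies), 3L)
  m <- merge(copies, px$sim$truth, by = "start")
  expect_true(all(abs(m$identity - m$realized_identity) <= 0.03))
})

test_that("a 70%-length fragment is reported but rejected on coverage", {
  ref <- simulate_reference_element(ltr_length = 500, internal_length = 1500,
                                    seed = 63)
  g <- generate_background_genome(30000, seed = 64)
  frag <- substr(ref$sequence, 1, floor(0.7 * nchar(ref$sequence)))
  g2 <- paste0(substr(g, 1, 10000), frag, substr(g, 10001, 30000))
  copies <- find_copies(g2, ref)
  expect_equal(nrow(copies), 1L)
  expect_equal(copies$status, "rejected_coverage")
  expect_lt(copies$coverage, 0.80)
  expect_equal(sum(copies$status == "full_length"), 0L)
})

test_that("mining the reverse complement flips strands and mirrors coordinates", {
  px <- make_planted(seed = 65, n_copies = 3, ages = 1e6)
  g <- px$sim$genome
  fwd <- find_copies(g, px$ref)
  rev <- find_copies(revcomp(g), px$ref)
  expect_equal(nrow(rev), nrow(fwd))
  L <- nchar(g)
  expect_equal(sort(L - rev$end + 1), sort(fwd$start))
  expect_equal(sort(L - rev$start + 1), sort(fwd$end))
  expect_true(all(rev$strand == "-"), info = "planted copies are all forward")
  # match rows through the coordinate mirror
  m <- match(L - rev$end + 1, fwd$start)
  expect_false(anyNA(m))
  expect_equal(rev$identity, fwd$identity[m])
  expect_equal(rev$status, fwd$status[m])
  # structural annotation carries over: TSDs mirror as reverse complements
  expect_equal(is.na(rev$tsd), is.na(fwd$tsd[m]))
  ok <- !is.na(rev$tsd)
  expect_identical(revcomp(rev$tsd[ok]), fwd$tsd[m][ok])
})

test_that("full-length status implies every structural filter", {
  px <- make_planted(seed = 66, n_copies = 5, ages = c(0.5e6, 1e6, 3e6))
  copies <- find_copies(px$sim$genome, px$ref)
  fl <- copies[copies$status == "full_length", ]
  expect_gt(nrow(fl), 0)
  expect_true(all(fl$identity >= 0.80))
  expect_true(all(fl$coverage >= 0.80))
  expect_true(all(fl$termini_ok))
  for (i in seq_len(nrow(fl)))
    expect_true(check_termini(fl[i, ], px$sim$genome))
})

test_that("LTR delimitation projects reference boundaries and refines termini", {
  px <- make_planted(seed = 67, n_copies = 1, ages = 2e6)
  copies <- find_copies(px$sim$genome, px$ref)
  tr <- px$sim$truth
  expect_equal(copies$ltr5_start, tr$ltr5_start)
  expect_equal(copies$ltr5_end, tr$ltr5_end)
  expect_equal(copies$ltr3_start, tr$ltr3_start)
  expect_equal(copies$ltr3_end, tr$ltr3_end)

  # standalone delimitation agrees
  ltrs <- delimit_ltrs(copies[1, ], px$ref, px$sim$genome)
  expect_equal(ltrs$ltr5, c(tr$ltr5_start, tr$ltr5_end))
  expect_equal(ltrs$ltr3, c(tr$ltr3_start, tr$ltr3_end))

  # 2-bp boundary slippage: a reference padded with 2 extra 5' bases
  # projects the LTR start 2 bp into the flank; refinement recovers truth
  pad_ref <- reference_element(
    px$ref$family_name, px$ref$superfamily, px$ref$lineage,
    paste0("GT", px$ref$sequence),
    ltr5 = c(1L, px$ref$ltr5[2] + 2L),
    ltr3 = px$ref$ltr3 + 2L)
  ltrs2 <- delimit_ltrs(copies[1, ], pad_ref, px$sim$genome)
  expect_equal(ltrs2$ltr5[1], tr$ltr5_start)

  # copy missing its 3' LTR cannot be delimited
  cut <- copies[1, ]
  cut$end <- tr$ltr3_start - 10L
  expect_error(delimit_ltrs(cut, px$ref, px$sim$genome),
               "projection outside copy")
})

test_that("termini check reads TG..CA in element orientation", {
  g <- paste0(rand_dna(50), "TG", rand_dna(30), "CA", rand_dna(50))
  copy <- list(start = 51L, end = 84L, strand = "+",
               ltr5_start = 51L, ltr5_end = 60L,
               ltr3_start = 75L, ltr3_end = 84L)
  expect_true(check_termini(copy, g))
  g_bad <- g
  substr(g_bad, 51, 52) <- "TA"
  expect_false(check_termini(copy, g_bad))
  # minus strand: genome holds the reverse complement
  grc <- revcomp(g)
  L <- nchar(g)
  copy_rc <- list(start = L - 84L + 1L, end = L - 51L + 1L, strand = "-",
                  ltr5_start = L - 60L + 1L, ltr5_end = L - 51L + 1L,
                  ltr3_start = L - 84L + 1L, ltr3_end = L - 75L + 1L)
  expect_true(check_termini(copy_rc, grc))
})

test_that("TSD detection equals the brute-force all-k flank comparison", {
  # planted example
  g <- paste0(rand_dna(40), "GACCT", "TG", rand_dna(26), "CA", "GACCT",
              rand_dna(40))
  copy <- list(start = 46L, end = 75L)
  expect_identical(detect_tsd(g, copy), "GACCT")

  # longest match wins: flanks share a 6-mer (and so also its 4/5-mers)
  g2 <- paste0(rand_dna(40), "ATCGGA", rand_dna(30), "ATCGGA", rand_dna(40))
  copy2 <- list(start = 47L, end = 76L)
  expect_identical(detect_tsd(g2, copy2), "ATCGGA")

  # contig edge: absent with a warning
  expect_warning(res <- detect_tsd("ACGTACGTACGT", list(start = 3L, end = 8L)),
                 "contig edge")
  expect_true(is.na(res))

  # property: agreement with brute force on random fixtures
  set.seed(401)
  for (i in 1:300) {
    g3 <- rand_dna(60)
    tsd_len <- sample(0:6, 1)   # 0: unrelated flanks
    if (tsd_len >= 4) {
      tsd <- rand_dna(tsd_len)
      g3 <- paste0(substr(g3, 1, 20), tsd, rand_dna(10), tsd,
                   substr(g3, 21, 60))
      copy3 <- list(start = 21L + tsd_len, end = 20L + tsd_len + 10L)
    } else {
      copy3 <- list(start = 21L, end = 40L)
    }
    expect_identical(detect_tsd(g3, copy3),
                     brute_tsd(g3, copy3$start, copy3$end))
  }
})

test_that("polypurine tracts are found upstream of the 3' LTR", {
  ppt <- "AGGAGAGGAGAG"                  # 12 purines
  g <- paste0(strrep("CT", 15), ppt, "CATTC", "TG", strrep("CT", 10))
  copy <- list(strand = "+", ltr3_start = 48L, ltr3_end = 60L)
  iv <- detect_ppt(copy, g, window = 30, min_len = 10)
  expect_equal(iv, c(31L, 42L))

  # no qualifying run
  g2 <- paste0(strrep("CT", 40))
  copy2 <- list(strand = "+", ltr3_start = 60L, ltr3_end = 70L)
  expect_null(detect_ppt(copy2, g2, window = 40, min_len = 10))

  # two runs: the longer wins
  g3 <- paste0("CC", strrep("A", 10), "CC", strrep("G", 14), "CC",
               rand_dna(20))
  copy3 <- list(strand = "+", ltr3_start = 31L, ltr3_end = 40L)
  iv3 <- detect_ppt(copy3, g3, window = 30, min_len = 10)
  expect_equal(iv3[2] - iv3[1] + 1L, 14L)
})

test_that("copy density tables conserve the full-length count", {
  empty <- copy_density(data.frame(genome_id = character(0),
                                   start = integer(0), end = integer(0),
                                   status = character(0)),
                        c(chr1 = 1000L), 100)
  expect_true(all(empty$n_copies == 0))
  expect_equal(nrow(empty), 10L)

  copies <- data.frame(genome_id = "chr1",
                       start = c(10L, 20L, 30L, 550L),
                       end = c(15L, 25L, 35L, 600L),
                       status = c(rep("full_length", 3), "rejected_identity"))
  dens <- copy_density(copies, c(chr1 = 1000L), 100)
  expect_equal(dens$n_copies[1], 3L)
  expect_equal(sum(dens$n_copies), 3L)

  set.seed(402)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    starts <- sample(1:9990, n)
    copies <- data.frame(genome_id = "g", start = starts, end = starts + 5L,
                         status = sample(c("full_length", "rejected_termini"),
                                         n, TRUE))
    dens <- copy_density(copies, c(g = 10000L), sample(c(37, 100, 512), 1))
    expect_equal(sum(dens$n_copies), sum(copies$status == "full_length"))
  }
})
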