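toy_reads <- function() {
  # reference: positions 0..19; four plus-strand reads starting with C
  ref <- "CCGGATTACCGGATTACCGG"
  reads <- data.frame(
    read_id = paste0("r", 1:4),
    start = c(0L, 0L, 8L, 8L),
    strand = "+",
    sequence = c("TCGGATTA",   # C->T at position 1
                 "CCGGATTA",   # intact
                 "TCGGATTAC",  # C->T at position 1
                 "CCGGATTAC"), # intact
    stringsAsFactors = FALSE)
  read_set(reads, ref)
}

test_that("fragment length statistics follow their definitions", {
  rs <- read_set(data.frame(read_id = c("a", "b", "c"),
                            start = c(0L, 5L, 10L), strand = "+",
                            sequence = c(strrep("A", 50), strrep("A", 60),
                                         strrep("A", 64))),
                 strrep("A", 100))
  st <- fragment_length_stats(rs)
  expect_equal(st$mean, 58)
  expect_equal(st$median, 60)
  one <- read_set(data.frame(read_id = "x", start = 0L, strand = "+",
                             sequence = strrep("A", 41)), strrep("A", 50))
  st1 <- fragment_length_stats(one)
  expect_equal(st1$mean, 41)
  expect_equal(st1$median, 41)
  expect_true(is.na(st1$sd))   # documented convention for a single read
})

test_that("a hand-built toy read set gives a terminal C->T rate of one half", {
  pr <- damage_profile(toy_reads(), K = 5)
  expect_equal(pr$ct5_rate[1], 0.5)
  expect_equal(pr$ct5_n[1], 4)
})

test_that("damage counting is strand-aware", {
  ref <- "ACGTACGTACGTACGTACGT"
  # minus-strand read over ref[1..8] "ACGTACGT": read-oriented reference
  # is its reverse complement "ACGTACGT"; give the read a C->T at its 5'
  # position 2 (reference C) and check it lands in the 5' C->T profile
  rs <- read_set(data.frame(read_id = "m", start = 0L, strand = "-",
                            sequence = "ATGTACGT"), ref)
  pr <- damage_profile(rs, K = 3)
  expect_equal(pr$ct5_rate[2], 1)
  expect_equal(pr$ct5_n[2], 1)
})

test_that("simulated damage rates and lengths are recovered by the estimators", {
  cfg <- read_sim_config(n_reads = 10000, ref_length = 12000,
                         mean_len = 57.6, seed = 31)
  rs <- gen_ancient_reads(cfg)
  st <- fragment_length_stats(rs)
  expect_lt(abs(st$mean - 57.6), 0.5)
  pr <- damage_profile(rs)
  expect_lt(abs(pr$ct5_rate[1] - 0.38), 0.02)
  expect_lt(abs(pr$ga3_rate[1] - 0.48), 0.02)
})

test_that("the position-1 estimator is unbiased across replicate simulations", {
  est <- vapply(1:20, function(s) {
    rs <- gen_ancient_reads(read_sim_config(n_reads = 2000,
                                            ref_length = 6000, seed = s))
    damage_profile(rs, K = 2)$ct5_rate[1]
  }, numeric(1))
  mc_err <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.38), 3 * mc_err + 1e-3)
})

test_that("estimated deamination decays monotonically from the terminus", {
  rs <- gen_ancient_reads(read_sim_config(n_reads = 20000,
                                          ref_length = 12000, seed = 7))
  pr <- damage_profile(rs, K = 20)
  kt <- suppressWarnings(cor.test(pr$position, pr$ct5_rate,
                                  method = "kendall"))
  expect_lt(kt$estimate, 0)
  expect_lt(kt$p.value, 0.01)
})

test_that("coverage summaries match their definitions and the stabbing oracle", {
  expect_equal(coverage_summary(c(0, 1, 2, 3)),
               list(fraction_covered = 0.75, mean_depth = 1.5, length = 4L))
  expect_equal(coverage_summary(rep(0, 10))$fraction_covered, 0)
  expect_equal(coverage_summary(rep(0, 10))$mean_depth, 0)
  expect_error(coverage_summary(numeric(0)), "empty")

  rs <- gen_ancient_reads(read_sim_config(n_reads = 300, ref_length = 2000,
                                          seed = 12))
  depth <- read_depth(rs)
  # brute-force interval stabbing oracle
  oracle <- integer(2000)
  for (i in seq_len(nrow(rs$reads))) {
    s <- rs$reads$start[i]
    e <- s + nchar(rs$reads$sequence[i])
    oracle[(s + 1):e] <- oracle[(s + 1):e] + 1L
  }
  expect_equal(depth, oracle)
})

test_that("read sets survive TSV, SAM and FASTA round trips", {
  rs <- gen_ancient_reads(read_sim_config(n_reads = 150, ref_length = 2500,
                                          seed = 9))
  fa <- tempfile(fileext = ".fa")
  write_fasta(rs$reference, fa)
  expect_identical(read_fasta(fa), rs$reference)

  tsv <- tempfile(fileext = ".tsv")
  write_reads_tsv(rs, tsv)
  back <- read_reads_tsv(tsv, fa)
  expect_equal(back$reads$sequence, rs$reads$sequence)
  expect_equal(back$reads$start, rs$reads$start)

  sam <- tempfile(fileext = ".sam")
  write_sam(rs, sam)
  b2 <- read_reads_sam(sam, fa)
  o <- match(rs$reads$read_id, b2$reads$read_id)
  expect_equal(b2$reads$sequence[o], rs$reads$sequence)
  expect_equal(b2$reads$start[o], rs$reads$start)
  expect_equal(b2$reads$strand[o], rs$reads$strand)
  # damage profiles agree whichever container carried the reads
  expect_equal(damage_profile(b2)$ct5_rate, damage_profile(rs)$ct5_rate)
})

test_that("reads outside the reference bounds are rejected", {
  expect_error(read_set(data.frame(read_id = "x", start = 95L,
                                   strand = "+", sequence = strrep("A", 10)),
                        strrep("A", 100)), "bounds")
})
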