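test_that("reference generation is seeded and honors GC content", {
  r1 <- generate_reference(100000, gc = 0.5, seed = 7)
  r2 <- generate_reference(100000, gc = 0.5, seed = 7)
  expect_equal(as.character(r1), as.character(r2))
  gc <- sum(Biostrings::letterFrequency(r1, c("G", "C"))) / 100000
  expect_lt(abs(gc - 0.5), 0.02)
  r3 <- generate_reference(50000, gc = 0.7, seed = 7)
  gc3 <- sum(Biostrings::letterFrequency(r3, c("G", "C"))) / 50000
  expect_lt(abs(gc3 - 0.7), 0.02)
  expect_error(generate_reference(0), "positive")
})

test_that("simulated read counts and depth match the target coverage", {
  ref <- generate_reference(50000, seed = 1)
  rs <- simulate_reads(ref, coverage = 30, read_len = 100,
                       fragment_mean = 500, fragment_sd = 50, seed = 2)
  expect_equal(nrow(rs$pairs), 7500)  # C * G / (2 * rl)
  d <- read_depth(rs, "chr1", 1, 50000)
  expect_lt(abs(d - 30) / 30, 0.05)
  expect_error(simulate_reads(ref, coverage = 0), "positive")
  # zero fragment-sd gives constant fragments
  rs0 <- simulate_reads(ref, coverage = 2, fragment_sd = 0, seed = 3)
  expect_equal(unique(rs0$pairs$frag), 500)
})

test_that("SAM output is byte-identical across reruns of one seed", {
  ref <- generate_reference(20000, seed = 4)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(simulate_reads(ref, 5, seed = 9), ref, f1)
  write_sam(simulate_reads(ref, 5, seed = 9), ref, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SAM round-trips through Rsamtools with aligned spans intact", {
  ref <- generate_reference(20000, seed = 4)
  rs <- simulate_reads(ref, 3, seed = 5)
  sam <- tempfile(fileext = ".sam")
  write_sam(rs, ref, sam)
  back <- read_sam(sam)
  expect_equal(nrow(back), 2 * nrow(rs$pairs))
  expect_setequal(unique(back$chrom), "chr1")
  expect_equal(sort(back$pos[back$strand == "+"]), sort(rs$pairs$pos1))
})

test_that("contig rearrangement follows each SV type's geometry", {
  contig <- "AAAACCCCGGGGTTTT"
  del <- rearrange_contig(contig, "DEL", 5, 12)
  expect_equal(del$seq, "AAAATTTT")
  expect_equal(del$junctions, 4)
  dup <- rearrange_contig(contig, "DUP", 5, 12, param = 1)
  expect_equal(nchar(dup$seq), 24)
  expect_equal(dup$seq, "AAAACCCCGGGGCCCCGGGGTTTT")
  inv <- rearrange_contig(contig, "INV", 5, 12)
  inv2 <- rearrange_contig(inv$seq, "INV", 5, 12)
  expect_equal(inv2$seq, contig)  # involution
  ins <- rearrange_contig(contig, "INS", 8, 8, param = "TTAA")
  expect_equal(ins$seq, "AAAACCCCTTAAGGGGTTTT")
  expect_error(rearrange_contig(contig, "DEL", 1, 16), "entire contig")
  expect_error(rearrange_contig(contig, "DEL", 5, 20), "outside")
})

test_that("final coverage follows C_f = VAF * C_o * (L_f / L_o)", {
  # INV keeps L_f = L_o, so C_f = VAF * C_o directly
  ref <- generate_reference(30000, seed = 11)
  rs <- simulate_reads(ref, coverage = 60, seed = 12)
  plan <- spike_plan("chr1", 14000, 16000, "INV", vaf = 0.2)
  res <- spike_sv(rs, ref, plan, seed = 13)
  L_f <- 2000 + 2 * 500 + 1  # span + both pads (fragment_mean = 500)
  expected_pairs <- round(0.2 * 60 * L_f / (2 * 100))
  expect_equal(unname(res$ledger["simulated"]), expected_pairs)
})

test_that("deletion spikes deplete the deleted interval as VAF dictates", {
  ref <- generate_reference(60000, seed = 21)
  rs <- simulate_reads(ref, coverage = 30, seed = 22)
  plan1 <- spike_plan("chr1", 20000, 28000, "DEL", vaf = 1.0)
  res1 <- spike_sv(rs, ref, plan1, seed = 23)
  d1 <- read_depth(res1$tumor, "chr1", 20000, 28000)
  expect_lte(d1, 1)
  plan5 <- spike_plan("chr1", 20000, 28000, "DEL", vaf = 0.5)
  res5 <- spike_sv(rs, ref, plan5, seed = 24)
  d5 <- read_depth(res5$tumor, "chr1", 20000, 28000)
  expect_lt(abs(d5 - 15) / 15, 0.2)
})

test_that("truth breakpoints equal the plan coordinates exactly", {
  ref <- generate_reference(80000, seed = 31)
  rs <- simulate_reads(ref, coverage = 10, seed = 32)
  plan <- spike_plan(chrom = "chr1",
                     start = c(10000, 30000, 50000),
                     end = c(13000, 32000, 52000),
                     svtype = c("DEL", "DUP", "INV"),
                     vaf = c(0.5, 0.33, 0.2))
  res <- spike_all(rs, ref, plan, seed = 33)
  expect_equal(res$truth$pos, plan$start)
  expect_equal(res$truth$end, plan$end)
  expect_equal(res$truth$svtype, plan$svtype)
  expect_equal(res$truth$vaf, plan$vaf)
})

test_that("the read-count ledger balances for every SV type", {
  ref <- generate_reference(80000, seed = 41)
  rs <- simulate_reads(ref, coverage = 10, seed = 42)
  for (row in list(
    spike_plan("chr1", 20000, 23000, "DEL", 0.5),
    spike_plan("chr1", 40000, 42000, "DUP", 0.5, param = 1),
    spike_plan("chr1", 60000, 62000, "INV", 0.33),
    spike_plan("chr1", 70000, 70000, "INS", 0.5,
               param = strrep("ACGT", 100)))) {
    res <- spike_sv(rs, ref, row, seed = 43)
    lg <- res$ledger
    expect_equal(unname(lg["input"] - lg["removed"] + lg["simulated"]),
                 unname(lg["output"]), info = row$svtype)
    if (row$svtype %in% c("DUP", "INS"))
      expect_equal(unname(lg["removed"]), 0)
  }
})

test_that("pileup outside the affected interval is untouched", {
  ref <- generate_reference(60000, seed = 51)
  rs <- simulate_reads(ref, coverage = 10, seed = 52)
  plan <- spike_plan("chr1", 25000, 27000, "DEL", vaf = 1)
  res <- spike_sv(rs, ref, plan, seed = 53)
  before <- read_depth(rs, "chr1", 40000, 55000)
  after <- read_depth(res$tumor, "chr1", 40000, 55000)
  expect_equal(after, before)
  before_l <- read_depth(rs, "chr1", 1, 15000)
  after_l <- read_depth(res$tumor, "chr1", 1, 15000)
  expect_equal(after_l, before_l)
})

test_that("junction-spanning reads appear soft-clipped near breakpoints", {
  ref <- generate_reference(60000, seed = 61)
  rs <- simulate_reads(ref, coverage = 20, seed = 62)
  plan <- spike_plan("chr1", 25000, 28000, "DEL", vaf = 0.5)
  res <- spike_sv(rs, ref, plan, seed = 63)
  aln <- svbench:::alignment_table(res$tumor)
  clipped <- aln[grepl("S", aln$cigar), ]
  expect_gt(nrow(clipped), 0)
  # clipped reads cluster at the two junctions
  expect_true(any(abs(clipped$pos - 25000) < 200 |
                    abs(clipped$end - 25000) < 200 |
                    abs(clipped$pos - 28000) < 200 |
                    abs(clipped$end - 28000) < 200))
})

test_that("VAF outside (0, 1] and overlapping plan intervals are errors", {
  expect_error(spike_plan("chr1", 100, 200, "DEL", vaf = 0), "VAF")
  expect_error(spike_plan("chr1", 100, 200, "DEL", vaf = 1.2), "VAF")
  expect_error(spike_plan("chr1", c(100, 150), c(200, 250), "DEL", 0.5),
               "non-overlapping")
})

test_that("a plan file round-trips through the plain-text format", {
  plan <- spike_plan("chr1", c(1000, 5000), c(2000, 6000),
                     c("DEL", "DUP"), vaf = c(0.5, 0.2), param = c(NA, 2))
  path <- tempfile()
  writeLines(with(plan, paste(chrom, start, end, svtype, vaf,
                              ifelse(is.na(param), "NA", param))), path)
  back <- read_spike_plan(path)
  expect_equal(back$start, plan$start)
  expect_equal(back$svtype, plan$svtype)
  expect_equal(back$vaf, plan$vaf)
})

test_that("perturbed call sets recover the planted error rates", {
  ref <- generate_reference(3e6, seed = 71)
  truth <- toy_truth(500, spacing = 5000, len = 500)
  sub <- perturb_callset(truth, ref, jitter_sd = 10, fn_rate = 0.2,
                         fp_count = 50, seed = 72)
  rep <- score(match_calls(sub, truth, scheme = "closeness", f = 100))
  expect_lt(abs(rep$recall - 0.8), 0.04)
  expect_lt(abs(rep$precision - 400 / 450), 0.02)
  # the degenerate corners
  clean <- perturb_callset(truth, ref, jitter_sd = 0, fn_rate = 0,
                           fp_count = 0, seed = 73)
  expect_equal(score(match_calls(clean, truth))$f_score, 1)
  gone <- perturb_callset(truth, ref, jitter_sd = 0, fn_rate = 1,
                          fp_count = 0, seed = 74)
  rep0 <- score(match_calls(gone, truth))
  expect_equal(c(rep0$precision, rep0$recall, rep0$f_score), c(0, 0, 0))
})
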