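test_that("breakpoint label resolution follows TP > FN > FP", {
  ann <- data.frame(chrom = "chr1", pos = c(100, 100, 200, 200, 300),
                    label = c("TP", "FN", "FN", "FP", "FP"))
  out <- resolve_breakpoint_labels(ann)
  expect_equal(out$label, c("TP", "FN", "FP"))
  # idempotent and order-independent
  expect_equal(resolve_breakpoint_labels(out), out)
  shuf <- ann[c(5, 2, 4, 1, 3), ]
  expect_equal(resolve_breakpoint_labels(shuf), out)
  expect_error(resolve_breakpoint_labels(
    data.frame(chrom = "1", pos = 1, label = "TN")), "TP, FN or FP")
})

test_that("sampled true negatives satisfy all four criteria", {
  ref <- generate_reference(200000, seed = 81)
  truth <- toy_truth(20, spacing = 8000, len = 300)
  calls <- toy_truth(10, spacing = 9000, len = 250)
  calls$pos <- calls$pos + 411; calls$end <- calls$end + 411
  gaps <- mask_set("chr1", c(100000, 150000), c(105000, 152000))
  tn <- sample_true_negatives(truth, calls, ref, excluded = gaps,
                              n_min = 50, seed = 82)
  expect_gte(nrow(tn), 50)
  overlaps <- function(df, st, en)
    any(df[[2]] <= en & df[[3]] >= st)
  for (i in seq_len(nrow(tn))) {
    expect_false(overlaps(
      data.frame(x = truth$chrom, s = truth$pos, e = truth$end),
      tn$start[i], tn$end[i]))
    expect_false(overlaps(
      data.frame(x = calls$chrom, s = calls$pos, e = calls$end),
      tn$start[i], tn$end[i]))
    expect_false(overlaps(gaps, tn$start[i], tn$start[i]))
  }
  # lengths come from the log-normal fit of truth lengths: constant
  # truth lengths (log-sd 0) give constant TN lengths
  same <- sample_true_negatives(truth, calls, ref, n_min = 10, seed = 83)
  expect_true(all(same$end - same$start + 1 == 300))
})

test_that("unsatisfiable TN constraints raise an informative error", {
  ref <- generate_reference(5000, seed = 84)
  truth <- sv_records("t", "chr1", 1, 5000, "DEL")
  expect_error(
    sample_true_negatives(truth, truth[0, ], ref, n_min = 5, seed = 85,
                          max_attempts = 200),
    "constraints too dense")
})

test_that("nucleotide entropy matches its closed forms", {
  # 100-bp contigs with the breakpoint at 50: the +/- 50 window is the
  # whole contig (truncated at its ends), with exact base composition
  bp <- data.frame(chrom = "chrW", pos = 50)
  empty_aln <- data.frame(chrom = character(), pos = numeric(),
                          end = numeric(), strand = character())
  uniform <- Biostrings::DNAStringSet(c(chrW = strrep("ACGT", 25)))
  expect_equal(compute_features(bp, empty_aln, uniform)$nucleotide_entropy, 2)
  mono <- Biostrings::DNAStringSet(c(chrW = strrep("A", 100)))
  expect_equal(compute_features(bp, empty_aln, mono)$nucleotide_entropy, 0)
  # p = (0.5, 0.5, 0, 0) -> 1 bit
  half <- Biostrings::DNAStringSet(c(chrW = strrep("AC", 50)))
  expect_equal(compute_features(bp, empty_aln, half)$nucleotide_entropy, 1)
  # entropy is invariant under reverse complement of the window
  fwd_seq <- strrep("AACG", 25)
  rc_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd_seq)))
  fwd <- Biostrings::DNAStringSet(c(chrW = fwd_seq))
  rc <- Biostrings::DNAStringSet(c(chrW = rc_seq))
  expect_equal(compute_features(bp, empty_aln, rc)$nucleotide_entropy,
               compute_features(bp, empty_aln, fwd)$nucleotide_entropy)
  expect_error(compute_features(data.frame(chrom = "chrW", pos = 9999),
                                empty_aln, mono), "off-contig")
})

test_that("bridging reads and strand bias count the right reads", {
  aln <- data.frame(
    chrom = "chr1",
    pos = c(951, 960, 970, 980, 990, 1000, 1001, 902, 905, 910),
    strand = c("+", "+", "+", "+", "+", "+", "-", "-", "-", "-"))
  aln$end <- aln$pos + 99
  ref <- generate_reference(2000, seed = 86)
  names(ref) <- "chr1"
  f <- compute_features(data.frame(chrom = "chr1", pos = 1000), aln, ref)
  # reads starting at 1001 and at 902..910 (end < 1001) do not bridge
  # the +/- 1 window [999, 1001]
  expect_equal(f$bridging_reads, 8)
  # strand bias counts reads overlapping the breakpoint itself
  over <- aln$pos <= 1000 & aln$end >= 1000
  expect_equal(f$strand_bias, mean(aln$strand[over] == "+"))
  # flipping every strand mirrors the bias
  flip <- aln; flip$strand <- ifelse(aln$strand == "+", "-", "+")
  f2 <- compute_features(data.frame(chrom = "chr1", pos = 1000), flip, ref)
  expect_equal(f2$strand_bias, 1 - f$strand_bias)
})

test_that("germline INDELs are parsed from VCF and distances computed", {
  path <- write_tmp_vcf(c(
    vcf_header,
    "chr1\t500\ti1\tAT\tA\t.\tPASS\t.",
    "chr1\t5000\ts1\tA\tG\t.\tPASS\t.",     # SNV: ignored
    "chr1\t9000\ti2\tG\tGTTC\t.\tPASS\t."))
  ref <- generate_reference(10000, seed = 87)
  names(ref) <- "chr1"
  empty_aln <- data.frame(chrom = character(), pos = numeric(),
                          end = numeric(), strand = character())
  f <- compute_features(data.frame(chrom = "chr1", pos = 1200), empty_aln,
                        ref, germline_indels = path)
  expect_equal(f$germline_indel_distance, 700)
})

test_that("univariate association applies the log10 zero rule", {
  n <- 60
  set.seed(88)
  feats <- data.frame(
    chrom = "chr1", pos = seq_len(n),
    bridging_reads = c(0, 10, 100, rep(1, n - 3)),
    nucleotide_entropy = runif(n, 1.5, 2))
  err <- runif(n)
  out <- univariate_association(feats, err)
  expect_setequal(out$variable, c("bridging_reads", "nucleotide_entropy"))
  # a variable equal to the error proportion correlates perfectly
  feats$nucleotide_entropy <- err
  out <- univariate_association(feats, err)
  expect_equal(out$statistic[out$variable == "nucleotide_entropy"], 1)
  # Pearson r is invariant under positive affine transforms
  feats2 <- feats
  feats2$nucleotide_entropy <- 3 * err + 7
  out2 <- univariate_association(feats2, err)
  expect_equal(out$statistic[out$variable == "nucleotide_entropy"],
               out2$statistic[out2$variable == "nucleotide_entropy"])
  # the transform itself: 0 -> -1, 100 -> 2
  x <- c(0, 100, 10)
  tx <- ifelse(x == 0, -1, log10(x))
  expect_equal(tx, c(-1, 2, 1))
})

test_that("categorical variables get a binomial-model P value", {
  set.seed(89)
  n <- 80
  cat_var <- sample(c("genic", "intergenic"), n, replace = TRUE)
  err <- ifelse(cat_var == "genic", 0.8, 0.2) + rnorm(n, 0, 0.05)
  err <- pmin(pmax(err, 0), 1)
  feats <- data.frame(chrom = "1", pos = seq_len(n), location = cat_var,
                      stringsAsFactors = FALSE)
  out <- univariate_association(feats, err)
  expect_equal(out$test, "binomial_glm")
  expect_lt(out$p_value, 0.01)
  expect_true(is.na(out$statistic))
})

test_that("zero-variance variables are reported as missing", {
  feats <- data.frame(chrom = "1", pos = 1:10, flat = rep(5, 10))
  out <- univariate_association(feats, runif(10))
  expect_true(is.na(out$statistic))
  expect_true(is.na(out$p_value))
})

test_that("a label-determining variable tops forest importance", {
  set.seed(90)
  n <- 150
  labels <- rep(c("FN", "TP"), each = n)
  feats <- data.frame(
    chrom = "1", pos = seq_len(2 * n), label = labels,
    bridging_reads = ifelse(labels == "FN", rnorm(2 * n, 60, 5),
                            rnorm(2 * n, 20, 5)),
    noise1 = rnorm(2 * n), noise2 = rnorm(2 * n),
    noise3 = runif(2 * n))
  fit <- fit_error_forests(feats, target = "FN_vs_TP", seed = 91)
  top <- fit$importance$variable[which.max(fit$importance$importance)]
  expect_equal(top, "bridging_reads")
  expect_gt(fit$accuracy, 0.95)
  expect_equal(fit$importance$direction[
    fit$importance$variable == "bridging_reads"], 1)
})

test_that("labels independent of all features give chance accuracy", {
  set.seed(92)
  n <- 200
  feats <- data.frame(
    chrom = "1", pos = seq_len(n),
    label = sample(c("FP", "TN"), n, replace = TRUE),
    a = rnorm(n), b = rnorm(n))
  fit <- fit_error_forests(feats, target = "FP_vs_TN", seed = 93)
  expect_lt(abs(fit$accuracy - 0.5), 0.1)
  expect_true(all(is.na(fit$importance$direction)))
})

test_that("degenerate class sizes are refused", {
  feats <- data.frame(chrom = "1", pos = 1:20,
                      label = c("FP", rep("TN", 19)), x = rnorm(20))
  expect_error(fit_error_forests(feats, "FP_vs_TN"), "insufficient data")
  big <- data.frame(chrom = "1", pos = 1:30,
                    label = rep(c("FP", "TN"), 15), x = rnorm(30))
  expect_error(fit_error_forests(big, "FP_vs_TN", max_class_size = 10),
               "convergence guard")
})
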