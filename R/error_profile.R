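## Characterizing FN and FP breakpoints: true-negative sampling,
## per-breakpoint genomic variables, univariate association with team
## error rates, and random-forest variable importance.

#' Resolve multiple annotations per breakpoint to a single label
#'
#' A breakpoint may inherit several annotations from the SVs it belongs
#' to; ambiguity is removed with the priority `TP > FN > FP` (favoring
#' good performance first, then recall). The operation is idempotent and
#' independent of input order.
#'
#' @param annotations `data.frame` with `chrom`, `pos` and `label`
#'   (values among TP/FN/FP) columns; repeated breakpoints allowed.
#' @return a `data.frame` with one row per distinct breakpoint and its
#'   resolved `label`.
#' @export
resolve_breakpoint_labels <- function(annotations) {
  pri <- c(TP = 3, FN = 2, FP = 1)
  if (!all(annotations$label %in% names(pri)))
    stop("labels must be TP, FN or FP")
  o <- order(annotations$chrom, annotations$pos, -pri[annotations$label])
  a <- annotations[o, c("chrom", "pos", "label"), drop = FALSE]
  key <- paste(a$chrom, a$pos)
  a <- a[!duplicated(key), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Sample true-negative regions from the genome
#'
#' Draws control regions for FP modeling by rejection sampling. Each
#' accepted region satisfies all four criteria: its length is drawn from
#' a log-normal distribution whose log-mean and log-sd equal those of
#' the known SV lengths; its start does not fall in a known gap/repeat
#' region; it overlaps no known SV; and it overlaps no called SV. At
#' least `m` TNs should be sampled, where `m` is the maximum FP count of
#' any submission under study.
#'
#' @param truth known SV records (lengths drive the length
#'   distribution).
#' @param calls called SV records of the submission.
#' @param reference `DNAStringSet` (contig bounds).
#' @param excluded optional `data.frame` of gap/repeat regions with
#'   `chrom`, `start`, `end` (start positions inside them are
#'   rejected).
#' @param n_min number of TN regions to sample.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap (default `1000 * n_min`);
#'   exceeding it raises an error reporting the acceptance rate.
#' @return a `data.frame` of TN regions (`chrom`, `start`, `end`).
#' @export
sample_true_negatives <- function(truth, calls, reference, excluded = NULL,
                                  n_min, seed = 1,
                                  max_attempts = 1000 * n_min) {
  set.seed(seed)
  fit <- lnorm_fit(truth$end - truth$pos + 1)
  lens <- Biostrings::width(reference)
  blocked <- function(regions, chr, st, en) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    nrow(r) && any(r[[2]] <= en & r[[3]] >= st)
  }
  tr <- data.frame(chrom = truth$chrom, start = truth$pos, end = truth$end)
  cr <- data.frame(chrom = calls$chrom, start = calls$pos, end = calls$end)
  out <- vector("list", n_min)
  n_ok <- 0L; attempts <- 0L
  while (n_ok < n_min) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("true-negative sampling failed: accepted ", n_ok, " of ",
           n_min, " after ", attempts - 1L,
           " attempts; exclusion constraints too dense")
    L <- max(1, round(rlnorm(1, fit$meanlog, fit$sdlog)))
    ci <- sample.int(length(reference), 1, prob = lens)
    if (L >= lens[ci]) next
    st <- floor(runif(1, 1, lens[ci] - L + 1))
    en <- st + L - 1
    chr <- names(reference)[ci]
    if (!is.null(excluded) && blocked(excluded, chr, st, st)) next
    if (blocked(tr, chr, st, en)) next
    if (blocked(cr, chr, st, en)) next
    n_ok <- n_ok + 1L
    out[[n_ok]] <- data.frame(chrom = chr, start = st, end = en,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compute per-breakpoint genomic variables
#'
#' For each breakpoint position, computes the four sequence/alignment
#' variables used to profile SV calling errors:
#' * `bridging_reads`: number of reads whose aligned span contains the
#'   3-bp window at the breakpoint (position +/- 1 bp); no
#'   split-alignment requirement, and per-mate alignments are counted
#'   once;
#' * `germline_indel_distance`: distance (bp) to the nearest germline
#'   INDEL (`NA` when none is supplied);
#' * `nucleotide_entropy`: Shannon entropy (bits) of the reference
#'   window at position +/- 50 bp, `-sum(p_x log2 p_x)` over
#'   `x in {A, C, G, T}` case-insensitively, with `0 log 0 = 0`;
#'   windows are truncated at contig ends;
#' * `strand_bias`: proportion of breakpoint-overlapping reads aligned
#'   to the forward strand.
#'
#' @param breakpoints `data.frame` with `chrom` and `pos`.
#' @param alignments a `read_set`, an alignment `data.frame` (from
#'   [read_sam()]), or a SAM/BAM path.
#' @param reference `DNAStringSet`.
#' @param germline_indels optional `data.frame` with `chrom`, `pos` of
#'   germline INDELs, or a VCF path (INDELs are parsed out as rows
#'   whose REF and ALT lengths differ).
#' @param entropy_flank half-width of the entropy window (default 50).
#' @return `breakpoints` with the four variable columns appended.
#' @export
compute_features <- function(breakpoints, alignments, reference,
                             germline_indels = NULL, entropy_flank = 50) {
  aln <- if (inherits(alignments, "read_set")) alignment_table(alignments)
  else if (is.character(alignments)) read_sam(alignments)
  else alignments
  if (is.character(germline_indels))
    germline_indels <- parse_germline_indels(germline_indels)

  n <- nrow(breakpoints)
  bridging <- integer(n); sbias <- rep(NA_real_, n)
  entropy <- numeric(n); idist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    chr <- breakpoints$chrom[i]; bp <- breakpoints$pos[i]
    ci <- match(chr, names(reference))
    if (is.na(ci) || bp < 1 || bp > Biostrings::width(reference)[ci])
      stop("breakpoint ", chr, ":", bp, " is off-contig")
    a <- aln[aln$chrom == chr, , drop = FALSE]
    bridging[i] <- sum(a$pos <= bp - 1 & a$end >= bp + 1)
    over <- a$pos <= bp & a$end >= bp
    if (any(over)) sbias[i] <- mean(a$strand[over] == "+")
    win <- Biostrings::subseq(
      reference[[ci]], max(1, bp - entropy_flank),
      min(Biostrings::width(reference)[ci], bp + entropy_flank))
    p <- Biostrings::letterFrequency(win, c("A", "C", "G", "T"))
    p <- p / sum(p)
    entropy[i] <- -sum(ifelse(p > 0, p * log2(p), 0))
    if (!is.null(germline_indels)) {
      gp <- germline_indels$pos[germline_indels$chrom == chr]
      if (length(gp)) idist[i] <- min(abs(gp - bp))
    }
  }
  cbind(breakpoints,
        data.frame(bridging_reads = bridging,
                   germline_indel_distance = idist,
                   nucleotide_entropy = entropy,
                   strand_bias = sbias))
}

## germline INDELs = VCF rows where REF and ALT lengths differ
parse_germline_indels <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  is_indel <- nchar(fix[, "REF"]) != nchar(fix[, "ALT"])
  data.frame(chrom = fix[is_indel, "CHROM"],
             pos = as.numeric(fix[is_indel, "POS"]),
             stringsAsFactors = FALSE)
}

#' Univariate association of genomic variables with error rates
#'
#' For each continuous variable, the Pearson correlation between the
#' variable and the per-breakpoint proportion of teams with an FN/FP is
#' computed. Variables named in `log10_vars` (counts and distances) are
#' log10-transformed first, with zeros replaced by -1 instead of
#' logged. Categorical (factor/character) variables are tested in a
#' binomial generalized linear model of the error proportion on the
#' category (likelihood-ratio P), optionally weighted by the number of
#' teams behind each proportion.
#'
#' @param features `data.frame` of per-breakpoint variables.
#' @param error_rate numeric vector in `[0, 1]`, one value per row of
#'   `features`.
#' @param log10_vars variable names to log10-transform (default: the
#'   bridging-read count and germline INDEL distance).
#' @param weights optional binomial weights (teams per breakpoint).
#' @return a `data.frame` with `variable`, `statistic` (Pearson r, `NA`
#'   for categorical or zero-variance variables), `p_value` and `test`.
#' @export
univariate_association <- function(features, error_rate,
                                   log10_vars = c("bridging_reads",
                                                  "germline_indel_distance"),
                                   weights = NULL) {
  if (nrow(features) < 3) stop("need at least 3 breakpoints")
  vars <- setdiff(names(features), c("chrom", "pos", "label"))
  rows <- lapply(vars, function(v) {
    x <- features[[v]]
    if (is.numeric(x)) {
      if (v %in% log10_vars) x <- ifelse(x == 0, -1, log10(x))
      ok <- complete.cases(x, error_rate)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 ||
          stats::sd(error_rate[ok]) == 0)
        return(data.frame(variable = v, statistic = NA_real_,
                          p_value = NA_real_, test = "pearson"))
      ct <- cor.test(x[ok], error_rate[ok], method = "pearson")
      data.frame(variable = v, statistic = unname(ct$estimate),
                 p_value = ct$p.value, test = "pearson")
    } else {
      xf <- factor(x)
      if (nlevels(xf) < 2)
        return(data.frame(variable = v, statistic = NA_real_,
                          p_value = NA_real_, test = "binomial_glm"))
      fit <- suppressWarnings(glm(error_rate ~ xf, family = binomial(),
                                  weights = weights))
      null <- suppressWarnings(glm(error_rate ~ 1, family = binomial(),
                                   weights = weights))
      p <- anova(null, fit, test = "Chisq")[2, "Pr(>Chi)"]
      data.frame(variable = v, statistic = NA_real_, p_value = p,
                 test = "binomial_glm")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random-forest importance of genomic variables for calling errors
#'
#' Fits a random forest separating erroneous from correct breakpoints:
#' FN vs TP (recall errors) or FP vs TN (precision errors). Variable
#' importance is the permutation importance (mean decrease in accuracy
#' when the variable is perturbed). Each numeric variable also gets a
#' directional effect: the sign of the median shift in the erroneous
#' class, set to `NA` (no direction) when a two-sided Mann-Whitney test
#' gives P > 0.01 or the variable is categorical.
#'
#' @param features `data.frame` of per-breakpoint variables plus a
#'   `label` column (TP/FN/FP/TN).
#' @param target `"FN_vs_TP"` or `"FP_vs_TN"`.
#' @param seed integer seed.
#' @param ntree trees in the forest (default 500).
#' @param max_class_size guard against degenerate fits on extremely
#'   unbalanced inputs: a class larger than this raises an error.
#' @return a list with `importance` (`data.frame`: `variable`,
#'   `importance`, `direction`), `accuracy` (out-of-bag), and the
#'   fitted `forest`.
#' @export
fit_error_forests <- function(features, target = c("FN_vs_TP", "FP_vs_TN"),
                              seed = 1, ntree = 500,
                              max_class_size = 15000) {
  target <- match.arg(target)
  cls <- strsplit(target, "_vs_")[[1]]
  err_class <- cls[1]; ok_class <- cls[2]
  df <- features[features$label %in% cls, , drop = FALSE]
  counts <- table(factor(df$label, levels = cls))
  if (any(counts < 2))
    stop("insufficient data to fit an error model: class ",
         names(counts)[which.min(counts)], " has ", min(counts),
         " breakpoint(s)")
  if (any(counts > max_class_size))
    stop("class ", names(counts)[which.max(counts)], " has ",
         max(counts), " breakpoints, above the convergence guard of ",
         max_class_size)
  x <- df[, setdiff(names(df), c("chrom", "pos", "label")), drop = FALSE]
  for (v in names(x)) if (is.character(x[[v]])) x[[v]] <- factor(x[[v]])
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- factor(df$label[keep], levels = cls)
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = ntree,
    mtry = max(1, floor(sqrt(ncol(x)))), importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)
  direction <- vapply(names(x), function(v) {
    if (!is.numeric(x[[v]])) return(NA_real_)
    a <- x[[v]][y == err_class]; b <- x[[v]][y == ok_class]
    wt <- suppressWarnings(wilcox.test(a, b))
    if (is.na(wt$p.value) || wt$p.value > 0.01) return(NA_real_)
    sign(median(a) - median(b))
  }, numeric(1))
  acc <- 1 - unname(rf$err.rate[ntree, "OOB"])
  list(importance = data.frame(variable = names(x),
                               importance = unname(imp[, 1]),
                               direction = direction,
                               row.names = NULL),
       accuracy = acc, forest = rf)
}
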