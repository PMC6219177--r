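## Read-level SV spike-in simulation.
##
## The simulator emulates the tumor spike-in workflow at the read level:
## a "contig" is obtained by slicing the reference around the planned SV
## (simulated reads are error-free, so the slice is an exact surrogate
## for local assembly), the contig is rearranged according to the SV
## type, and variant-supporting read pairs are simulated over the
## rearranged contig at depth C_f = VAF * C_o * (L_f / L_o), where C_o
## is the original coverage and L_o, L_f the original and rearranged
## contig lengths. Deletions and inversions additionally remove a
## VAF-scaled fraction of the original pairs covering the affected span;
## duplications and insertions only add reads. Reads simulated from the
## rearranged contig are placed back onto the reference at their
## contig-implied positions, with soft clips at junctions, so that
## breakpoint-spanning (clipped/discordant) reads exist in the output.

#' Generate a random reference sequence
#'
#' @param length contig length(s) in bp; may be a named vector for a
#'   multi-contig reference.
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed; a fixed seed yields an identical sequence.
#' @return a [Biostrings::DNAStringSet].
#' @export
generate_reference <- function(length, gc = 0.5, seed = 1) {
  if (any(length <= 0)) stop("contig length must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  if (is.null(names(length)))
    names(length) <- paste0("chr", seq_along(length))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(length, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
    character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(length)))
}

#' Write a reference to a FASTA file
#' @param reference a `DNAStringSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

## simulate n error-free read pairs over one sequence (character).
## Mate 1 is the leftmost, forward read; mate 2 the reverse read at the
## fragment's right end. Sequences are stored reference-forward.
simulate_pairs_on_seq <- function(seqchar, chrom, n_pairs, read_len,
                                  fragment_mean, fragment_sd, prefix) {
  L <- nchar(seqchar)
  frag <- round(rnorm(n_pairs, fragment_mean, fragment_sd))
  frag <- pmin(pmax(frag, 2 * read_len), L)
  start <- floor(runif(n_pairs, 1, L - frag + 1 + 1))
  p2 <- start + frag - read_len
  data.frame(
    name = sprintf("%s_%d", prefix, seq_len(n_pairs)),
    chrom = chrom, frag = frag,
    pos1 = start, strand1 = "+", cigar1 = paste0(read_len, "M"),
    seq1 = substring(seqchar, start, start + read_len - 1),
    mapped1 = TRUE,
    pos2 = p2, strand2 = "-", cigar2 = paste0(read_len, "M"),
    seq2 = substring(seqchar, p2, p2 + read_len - 1),
    mapped2 = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Simulate uniform-coverage error-free paired reads
#'
#' Places `round(coverage * L / (2 * read_len))` read pairs uniformly on
#' each contig. Fragment lengths are Gaussian (clamped to
#' `[2 * read_len, L]`); reads carry no sequencing errors, so their true
#' placements double as alignments.
#'
#' @param reference a `DNAStringSet`.
#' @param coverage target mean depth `C_o` (> 0).
#' @param read_len read length in bp.
#' @param fragment_mean,fragment_sd fragment (insert) size distribution;
#'   `fragment_sd = 0` gives constant fragments.
#' @param seed integer seed.
#' @return an object of class `read_set`: a list with `pairs` (one row
#'   per pair; reference-forward sequences, per-mate position, strand
#'   and CIGAR) and the simulation parameters.
#' @export
simulate_reads <- function(reference, coverage, read_len = 100,
                           fragment_mean = 500, fragment_sd = 50,
                           seed = 1) {
  if (coverage <= 0) stop("coverage must be positive")
  set.seed(seed)
  pairs <- do.call(rbind, lapply(seq_along(reference), function(i) {
    L <- Biostrings::width(reference)[i]
    n <- round(coverage * L / (2 * read_len))
    simulate_pairs_on_seq(as.character(reference[[i]]),
                          names(reference)[i], n, read_len,
                          fragment_mean, fragment_sd,
                          prefix = paste0("r", i))
  }))
  structure(list(pairs = pairs, read_len = read_len, coverage = coverage,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x$pairs), "pairs, read length", x$read_len,
      "bp, fragment", x$fragment_mean, "+/-", x$fragment_sd, "bp\n")
  invisible(x)
}

## reference-space width consumed by a CIGAR (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("[0-9]+[MDN=X]", cigar)),
         function(ops) sum(as.numeric(sub("[MDN=X]", "", ops))),
         numeric(1))
}

## long-format table of mapped mates: one row per aligned read
alignment_table <- function(rs) {
  p <- rs$pairs
  one <- function(k) {
    m <- p[[paste0("mapped", k)]]
    data.frame(qname = p$name[m], mate = k, chrom = p$chrom[m],
               pos = p[[paste0("pos", k)]][m],
               strand = p[[paste0("strand", k)]][m],
               cigar = p[[paste0("cigar", k)]][m],
               seq = p[[paste0("seq", k)]][m],
               stringsAsFactors = FALSE)
  }
  a <- rbind(one(1), one(2))
  a$end <- a$pos + cigar_ref_width(a$cigar) - 1
  a
}

#' Mean aligned read depth over an interval
#'
#' @param reads a `read_set` (or an alignment `data.frame` with `chrom`,
#'   `pos`, `end` columns).
#' @param chrom,from,to the 1-based inclusive interval.
#' @return mean per-base depth of aligned (non-clipped) read bases.
#' @export
read_depth <- function(reads, chrom, from, to) {
  a <- if (inherits(reads, "read_set")) alignment_table(reads) else reads
  a <- a[a$chrom == chrom & a$end >= from & a$pos <= to, , drop = FALSE]
  if (!nrow(a)) return(0)
  cov <- IRanges::coverage(IRanges::IRanges(start = pmax(a$pos, from),
                                            end = pmin(a$end, to)))
  sum(as.numeric(S4Vectors::runValue(cov) * S4Vectors::runLength(cov))) /
    (to - from + 1)
}

#' Write a read set to a SAM file
#'
#' Emits the true placements as alignments: proper pairs with MAPQ 60,
#' soft-clipped CIGARs at SV junctions, and unmapped records (placed at
#' the mate) for reads falling entirely inside novel insertions.
#'
#' @param rs a `read_set`.
#' @param reference the `DNAStringSet` the reads were simulated from
#'   (for `@SQ` header lines).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(rs, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(reference), "\tLN:",
                  Biostrings::width(reference)))
  p <- rs$pairs
  flag <- function(k) {
    other <- if (k == 1) 2 else 1
    1 + 2 +
      4 * (!p[[paste0("mapped", k)]]) +
      8 * (!p[[paste0("mapped", other)]]) +
      16 * (p[[paste0("strand", k)]] == "-") +
      32 * (p[[paste0("strand", other)]] == "-") +
      (if (k == 1) 64 else 128)
  }
  row <- function(k) {
    mapped <- p[[paste0("mapped", k)]]
    other <- if (k == 1) 2 else 1
    seqs <- p[[paste0("seq", k)]]
    paste(p$name, flag(k), p$chrom,
          ifelse(mapped, p[[paste0("pos", k)]], p[[paste0("pos", other)]]),
          ifelse(mapped, 60, 0),
          ifelse(mapped, p[[paste0("cigar", k)]], "*"),
          "=", p[[paste0("pos", other)]], 0,
          seqs, strrep("I", nchar(seqs)), sep = "\t")
  }
  out <- character(2 * nrow(p))
  if (nrow(p)) {
    out[seq(1, 2 * nrow(p), by = 2)] <- row(1)
    out[seq(2, 2 * nrow(p), by = 2)] <- row(2)
  }
  writeLines(c(hdr, out), path)
  invisible(path)
}

#' Read alignments from a SAM/BAM file
#'
#' Thin wrapper over Rsamtools: SAM input is converted with `asBam` and
#' scanned into a flat table of mapped reads.
#'
#' @param path SAM or BAM file.
#' @return a `data.frame` with `qname`, `chrom`, `pos`, `end`, `strand`,
#'   `cigar`.
#' @export
read_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path)) path
  else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                        indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar")))[[1]]
  keep <- !bitwAnd(res$flag, 4)
  df <- data.frame(qname = res$qname[keep],
                   chrom = as.character(res$rname)[keep],
                   pos = res$pos[keep],
                   strand = as.character(res$strand)[keep],
                   cigar = res$cigar[keep], stringsAsFactors = FALSE)
  df$end <- df$pos + cigar_ref_width(df$cigar) - 1
  df
}

#' Rearrange a contig according to an SV specification
#'
#' Applies the SV to a contig sequence and reports the coordinate map
#' between the rearranged contig and the original:
#' * `DEL` removes `[span_start, span_end]` (deleting the entire contig
#'   is an error);
#' * `DUP` appends `param` extra tandem copies of the span after it;
#' * `INV` reverse-complements the span in place;
#' * `INS` inserts the sequence `param` immediately after `span_start`
#'   (a single-breakpoint event; `span_end` is ignored).
#'
#' @param contig character or `DNAString` contig sequence.
#' @param svtype one of `DEL, DUP, INV, INS`.
#' @param span_start,span_end 1-based inclusive span of the event in
#'   contig coordinates.
#' @param param `DUP`: extra copy count (default 1); `INS`: the inserted
#'   sequence; unused otherwise.
#' @return a list with `seq` (rearranged sequence), `blocks` (a
#'   `data.frame` mapping rearranged-contig intervals `cstart:cend` to
#'   original-contig intervals `rstart:rend` with a `strand`), and
#'   `junctions` (rearranged-contig offsets of every junction).
#' @examples
#' rearrange_contig("AAAACCCCGGGGTTTT", "DEL", 5, 12)$seq  # "AAAATTTT"
#' @export
rearrange_contig <- function(contig, svtype, span_start, span_end,
                             param = NULL) {
  s <- as.character(contig)
  L <- nchar(s)
  if (span_start < 1 || span_end > L || span_start > span_end)
    stop("SV span outside contig")
  left <- substring(s, 1, span_start - 1)
  mid <- substring(s, span_start, span_end)
  right <- substring(s, span_end + 1, L)
  block <- function(cstart, cend, rstart, rend, strand = "+")
    data.frame(cstart = cstart, cend = cend, rstart = rstart, rend = rend,
               strand = strand, stringsAsFactors = FALSE)
  switch(svtype,
    DEL = {
      if (span_end - span_start + 1 >= L)
        stop("deletion would remove the entire contig")
      blocks <- rbind(
        if (nchar(left)) block(1, nchar(left), 1, span_start - 1),
        block(nchar(left) + 1, L - nchar(mid), span_end + 1, L))
      list(seq = paste0(left, right), blocks = blocks,
           junctions = nchar(left))
    },
    DUP = {
      copies <- if (is.null(param) || is.na(param)) 1 else as.integer(param)
      if (copies < 1) stop("DUP needs at least one extra copy")
      w <- nchar(mid)
      extra <- do.call(rbind, lapply(seq_len(copies), function(i)
        block(span_end + (i - 1) * w + 1, span_end + i * w,
              span_start, span_end)))
      blocks <- rbind(
        block(1, span_end, 1, span_end), extra,
        if (nchar(right)) block(span_end + copies * w + 1, L + copies * w,
                                span_end + 1, L))
      list(seq = paste0(left, strrep(mid, copies + 1), right),
           blocks = blocks,
           junctions = span_end + w * seq_len(copies) - w)
    },
    INV = {
      inv <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mid)))
      blocks <- rbind(
        if (nchar(left)) block(1, span_start - 1, 1, span_start - 1),
        block(span_start, span_end, span_start, span_end, "-"),
        if (nchar(right)) block(span_end + 1, L, span_end + 1, L))
      list(seq = paste0(left, inv, right), blocks = blocks,
           junctions = c(span_start - 1, span_end))
    },
    INS = {
      ins <- toupper(as.character(param))
      if (!nchar(ins)) stop("INS requires an inserted sequence")
      li <- nchar(ins)
      blocks <- rbind(
        block(1, span_start, 1, span_start),
        if (span_start < L) block(span_start + li + 1, L + li,
                                  span_start + 1, L))
      list(seq = paste0(substring(s, 1, span_start), ins,
                        substring(s, span_start + 1, L)),
           blocks = blocks, junctions = span_start)
    },
    stop("unsupported SV type for rearrangement: ", svtype)
  )
}

## place one simulated mate (contig coords [s, s+rl-1]) back on the
## reference through the block map; returns pos/cigar/strand/seq/mapped
map_mate <- function(s, rl, seq, strand, blocks, offset) {
  e <- s + rl - 1
  ovs <- pmax(s, blocks$cstart); ove <- pmin(e, blocks$cend)
  len <- ove - ovs + 1
  if (all(len <= 0))
    return(list(pos = NA_real_, cigar = "*", strand = strand, seq = seq,
                mapped = FALSE))
  b <- which.max(len)
  m <- len[b]
  lc <- ovs[b] - s           # clipped bases left of the aligned block
  rc <- e - ove[b]
  if (blocks$strand[b] == "+") {
    pos <- blocks$rstart[b] + (ovs[b] - blocks$cstart[b]) + offset
    cig <- paste0(if (lc) paste0(lc, "S"), m, "M", if (rc) paste0(rc, "S"))
  } else {
    ## inverted block: the read lands reverse-complemented, clips swap
    pos <- blocks$rstart[b] + (blocks$cend[b] - ove[b]) + offset
    cig <- paste0(if (rc) paste0(rc, "S"), m, "M", if (lc) paste0(lc, "S"))
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    strand <- if (strand == "+") "-" else "+"
  }
  list(pos = pos, cigar = cig, strand = strand, seq = seq, mapped = TRUE)
}

#' Spike one structural variant into a read set
#'
#' Plants the SV described by one spike-plan row into `reads`: a contig
#' is sliced from the reference around the SV span (padded by one
#' fragment length on each side; the slice must reach twice the mean
#' fragment length), rearranged with [rearrange_contig()], and
#' variant-supporting pairs are simulated over it at final coverage
#' `C_f = VAF * C_o * (L_f / L_o)`. For deletions and inversions a
#' VAF-scaled fraction of the original pairs with a read covering the
#' affected span is removed (duplications and insertions only add
#' reads; inversions end up with depth approximately unchanged). The
#' truth record's breakpoints equal the plan's reference coordinates
#' exactly (for `INS`, the single breakpoint is the span start).
#'
#' @param reads a `read_set` of the original (normal) reads.
#' @param reference the `DNAStringSet` reference.
#' @param plan a one-row spike plan (see [spike_plan()]).
#' @param coverage original mean coverage `C_o`; defaults to the value
#'   recorded in `reads`.
#' @param seed integer seed.
#' @return a list with `tumor` (the spiked `read_set`), `truth` (a
#'   one-row SV record with the planned `vaf`), `ledger` (pair counts:
#'   input, removed, simulated, output), and `affected` (the reference
#'   interval touched by the spike).
#' @export
spike_sv <- function(reads, reference, plan, coverage = reads$coverage,
                     seed = 1) {
  stopifnot(inherits(reads, "read_set"), nrow(plan) == 1)
  vaf <- plan$vaf
  if (is.na(vaf) || vaf <= 0 || vaf > 1)
    stop("VAF must lie in (0, 1]")
  set.seed(seed)
  rl <- reads$read_len
  ci <- match(plan$chrom, names(reference))
  if (is.na(ci)) stop("plan chromosome not in reference")
  clen <- Biostrings::width(reference)[ci]
  pad <- reads$fragment_mean
  a <- max(1, plan$start - pad)
  b <- min(clen, plan$end + pad)
  if (b - a + 1 < 2 * reads$fragment_mean)
    stop("SV interval too narrow: the local contig must span at least ",
         "twice the mean fragment length")
  contig <- as.character(Biostrings::subseq(reference[[ci]], a, b))
  L_o <- nchar(contig)

  rr <- rearrange_contig(contig, plan$svtype,
                         span_start = plan$start - a + 1,
                         span_end = plan$end - a + 1,
                         param = plan$param)
  L_f <- nchar(rr$seq)
  C_f <- vaf * coverage * L_f / L_o
  n_new <- round(C_f * L_f / (2 * rl))

  newp <- simulate_pairs_on_seq(rr$seq, plan$chrom, n_new, rl,
                                reads$fragment_mean, reads$fragment_sd,
                                prefix = paste0("sv", plan$chrom, "_",
                                                plan$start))
  if (nrow(newp)) {
    for (k in 1:2) {
      mm <- lapply(seq_len(nrow(newp)), function(i)
        map_mate(newp[[paste0("pos", k)]][i], rl,
                 newp[[paste0("seq", k)]][i],
                 newp[[paste0("strand", k)]][i], rr$blocks, offset = a - 1))
      newp[[paste0("pos", k)]] <- vapply(mm, `[[`, numeric(1), "pos")
      newp[[paste0("cigar", k)]] <- vapply(mm, `[[`, character(1), "cigar")
      newp[[paste0("strand", k)]] <- vapply(mm, `[[`, character(1), "strand")
      newp[[paste0("seq", k)]] <- vapply(mm, `[[`, character(1), "seq")
      newp[[paste0("mapped", k)]] <- vapply(mm, `[[`, logical(1), "mapped")
    }
  }

  p <- reads$pairs
  removed <- 0L
  if (plan$svtype %in% c("DEL", "INV")) {
    e1 <- p$pos1 + rl - 1; e2 <- p$pos2 + rl - 1
    hit <- p$chrom == plan$chrom &
      ((e1 >= plan$start & p$pos1 <= plan$end) |
       (e2 >= plan$start & p$pos2 <= plan$end))
    cand <- which(hit)
    n_rm <- round(vaf * length(cand))
    if (n_rm > 0) {
      drop <- sample(cand, n_rm)
      p <- p[-drop, , drop = FALSE]
      removed <- n_rm
    }
  }
  tumor <- reads
  tumor$pairs <- rbind(p, newp)
  rownames(tumor$pairs) <- NULL

  truth_pos <- if (plan$svtype == "INS") plan$start else plan$start
  truth_end <- if (plan$svtype == "INS") plan$start else plan$end
  truth <- sv_records(
    id = paste0("truth_", plan$chrom, "_", plan$start),
    chrom = plan$chrom, pos = truth_pos, end = truth_end,
    svtype = plan$svtype, vaf = vaf)
  list(tumor = tumor, truth = truth,
       ledger = c(input = nrow(reads$pairs), removed = removed,
                  simulated = nrow(newp), output = nrow(tumor$pairs)),
       affected = data.frame(chrom = plan$chrom, start = a, end = b))
}

#' Build a spike plan
#'
#' One row per SV to plant: the interval `[start, end]` is the exact SV
#' span in reference coordinates (the deleted, duplicated or inverted
#' region; for insertions, `start` is the insertion breakpoint).
#' Intervals must be pairwise non-overlapping.
#'
#' @param chrom,start,end SV spans (1-based inclusive).
#' @param svtype one of `DEL, DUP, INV, INS`.
#' @param vaf variant allele fraction in (0, 1] (e.g. 0.5, 0.33, 0.2 for
#'   a clonal event and two subclones in a diploid genome).
#' @param param per-type parameter: `DUP` extra copy count, `INS`
#'   inserted sequence; `NA` otherwise.
#' @return a spike-plan `data.frame`.
#' @export
spike_plan <- function(chrom, start, end, svtype, vaf = 0.5, param = NA) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), svtype = as.character(svtype),
                   vaf = as.numeric(vaf), param = param,
                   stringsAsFactors = FALSE)
  if (!all(df$svtype %in% c("DEL", "DUP", "INV", "INS")))
    stop("spike plan supports DEL, DUP, INV, INS")
  if (any(df$vaf <= 0 | df$vaf > 1)) stop("VAF must lie in (0, 1]")
  if (any(df$start > df$end)) stop("plan interval with start > end")
  for (chr in unique(df$chrom)) {
    x <- df[df$chrom == chr, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1 && any(x$start[-1] <= x$end[-nrow(x)]))
      stop("spike plan intervals must be pairwise non-overlapping")
  }
  df
}

#' Read a spike plan from a plain-text file
#'
#' One SV per line, whitespace-separated:
#' `chrom start end svtype vaf [param]`.
#'
#' @param path plan file.
#' @return a spike-plan `data.frame` (see [spike_plan()]).
#' @export
read_spike_plan <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           fill = TRUE)
  spike_plan(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
             svtype = tab[[4]], vaf = tab[[5]],
             param = if (ncol(tab) >= 6) tab[[6]] else NA)
}

#' Spike a whole plan of SVs and emit the truth set
#'
#' Applies [spike_sv()] row by row (the plan's non-overlap invariant
#' keeps the spikes independent) and collects the truth records and the
#' pair-count ledger.
#'
#' @inheritParams spike_sv
#' @param plan a multi-row spike plan.
#' @return a list with `tumor` (`read_set`), `truth` (SV records),
#'   `ledger` (per-SV pair accounting) and `affected` intervals.
#' @export
spike_all <- function(reads, reference, plan, coverage = reads$coverage,
                      seed = 1) {
  truth <- list(); ledgers <- list(); affected <- list()
  tumor <- reads
  for (i in seq_len(nrow(plan))) {
    res <- spike_sv(tumor, reference, plan[i, , drop = FALSE],
                    coverage = coverage, seed = seed + i)
    tumor <- res$tumor
    truth[[i]] <- res$truth
    ledgers[[i]] <- res$ledger
    affected[[i]] <- res$affected
  }
  list(tumor = tumor, truth = do.call(rbind, truth),
       ledger = do.call(rbind, ledgers),
       affected = do.call(rbind, affected))
}

## log-normal fit of SV lengths (natural-log parameterization)
lnorm_fit <- function(lengths) {
  lx <- log(lengths)
  sdl <- stats::sd(lx)
  list(meanlog = mean(lx), sdlog = if (is.na(sdl)) 0 else sdl)
}

#' Derive a synthetic submission from a truth set
#'
#' Emulates an imperfect caller: each truth SV is retained with
#' probability `1 - fn_rate`, retained breakpoints are shifted by
#' rounded Gaussian jitter, and `fp_count` spurious calls with
#' truth-like (log-normal) lengths are placed uniformly outside the
#' truth regions.
#'
#' @param truth SV record `data.frame` of known SVs.
#' @param reference `DNAStringSet` (for contig bounds of spurious
#'   calls).
#' @param jitter_sd standard deviation (bp) of the breakpoint jitter.
#' @param fn_rate per-SV dropout probability in `[0, 1]`.
#' @param fp_count number of spurious calls to add.
#' @param seed integer seed.
#' @return an SV record `data.frame` of the synthetic submission.
#' @export
perturb_callset <- function(truth, reference, jitter_sd = 10,
                            fn_rate = 0, fp_count = 0, seed = 1) {
  if (fn_rate < 0 || fn_rate > 1) stop("fn_rate must lie in [0, 1]")
  set.seed(seed)
  keep <- truth[runif(nrow(truth)) >= fn_rate, , drop = FALSE]
  if (nrow(keep)) {
    single <- keep$pos == keep$end
    js <- round(rnorm(nrow(keep), 0, jitter_sd))
    je <- round(rnorm(nrow(keep), 0, jitter_sd))
    je[single] <- js[single]
    pos <- pmax(keep$pos + js, 1)
    end <- pmax(keep$end + je, 1)
    keep$pos <- pmin(pos, end)
    keep$end <- pmax(pos, end)
    keep$id <- sprintf("call_%d", seq_len(nrow(keep)))
    keep$mate_id <- NA_character_
    keep$subset <- "unassigned"
  }
  fps <- list()
  if (fp_count > 0) {
    fit <- lnorm_fit(truth$end - truth$pos + 1)
    lens <- Biostrings::width(reference)
    attempts <- 0
    while (length(fps) < fp_count) {
      attempts <- attempts + 1
      if (attempts > 1000 * fp_count)
        stop("could not place spurious calls outside truth regions")
      L <- max(1, round(rlnorm(1, fit$meanlog, fit$sdlog)))
      ci <- sample.int(length(reference), 1, prob = lens)
      if (L >= lens[ci]) next
      st <- floor(runif(1, 1, lens[ci] - L + 1))
      chr <- names(reference)[ci]
      tt <- truth[truth$chrom == chr, , drop = FALSE]
      if (nrow(tt) && any(tt$pos <= st + L - 1 & tt$end >= st)) next
      fps[[length(fps) + 1]] <- data.frame(chrom = chr, pos = st,
                                           end = st + L - 1)
    }
    fps <- do.call(rbind, fps)
    fps <- sv_records(id = sprintf("fp_%d", seq_len(nrow(fps))),
                      chrom = fps$chrom, pos = fps$pos, end = fps$end,
                      svtype = sample(c("DEL", "DUP", "INV"),
                                      nrow(fps), replace = TRUE))
  }
  out <- if (length(fps)) {
    common <- intersect(names(keep), names(fps))
    rbind(keep[, common, drop = FALSE], fps[, common, drop = FALSE])
  } else keep
  rownames(out) <- NULL
  out
}
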