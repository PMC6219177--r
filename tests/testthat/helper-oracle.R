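# Independent oracles and fixture builders shared across tests.

# Closeness similarity recomputed from first principles (kept separate
# from the package code on purpose).
oracle_closeness <- function(a, b, f) {
  if (a$chrom != b$chrom) return(0)
  ds <- abs(a$pos - b$pos); de <- abs(a$end - b$end)
  if (a$pos == a$end && b$pos == b$end)
    return(if (ds <= f) 1 - ds / f else 0)
  if (ds <= f && de <= f) sqrt((1 - ds / f) * (1 - de / f)) else 0
}

# All qualifying (positive-similarity) edges of a called x known
# instance under the closeness scheme.
oracle_edges <- function(called, known, f) {
  out <- NULL
  for (i in seq_len(nrow(called))) for (j in seq_len(nrow(known))) {
    s <- oracle_closeness(called[i, ], known[j, ], f)
    if (s > 0) out <- rbind(out, data.frame(ci = i, ki = j, sim = s))
  }
  if (is.null(out)) data.frame(ci = integer(), ki = integer(),
                               sim = numeric()) else out
}

# Brute-force maximum total similarity over all injective assignments
# restricted to the qualifying edges.
oracle_best_total <- function(edges) {
  best <- 0
  search <- function(edges, used_c, used_k, total) {
    best <<- max(best, total)
    if (!nrow(edges)) return()
    e <- edges[1, ]
    rest <- edges[-1, , drop = FALSE]
    search(rest, used_c, used_k, total)              # skip this edge
    if (!(e$ci %in% used_c) && !(e$ki %in% used_k))  # or take it
      search(rest, c(used_c, e$ci), c(used_k, e$ki), total + e$sim)
  }
  search(edges, integer(), integer(), 0)
  best
}

# Random small matching instance on one chromosome.
random_instance <- function(seed, max_n = 6, span = 3000, f = 100) {
  set.seed(seed)
  nc <- sample.int(max_n, 1); nk <- sample.int(max_n, 1)
  mk <- function(n, prefix) {
    pos <- sort(sample.int(span, n))
    len <- sample(50:400, n, replace = TRUE)
    sv_records(id = paste0(prefix, seq_len(n)), chrom = "chr1",
               pos = pos, end = pos + len,
               svtype = sample(c("DEL", "DUP", "INV"), n, replace = TRUE))
  }
  list(called = mk(nc, "c"), known = mk(nk, "k"), f = f)
}

# Tiny deterministic truth set spread over one contig.
toy_truth <- function(n = 20, chrom = "chr1", spacing = 2000, len = 400) {
  pos <- spacing * seq_len(n)
  sv_records(id = paste0("t", seq_len(n)), chrom = chrom, pos = pos,
             end = pos + len - 1,
             svtype = rep(c("DEL", "DUP", "INV"), length.out = n))
}

write_tmp_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.1",
  "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
  "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
  "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"t\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
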