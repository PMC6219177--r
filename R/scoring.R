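## Scoring a called SV set against a known (truth) SV set.
##
## Two similarity schemes are supported. Region overlap: the Jaccard
## coefficient j of the two inclusive intervals. Breakpoint closeness:
## per breakpoint, if the distance D between called and known breakpoint
## satisfies D <= f (flank parameter, default 100 bp), a relative
## closeness c' = 1 - D/f is computed; the overall closeness c is the
## geometric mean of the start and end c' values. A pair where exactly
## one breakpoint is within f is a "partial" candidate: never matched,
## never counted.
##
## When similarity edges are ambiguous, an optimal one-to-one matching
## maximizing total similarity is found with the Hungarian algorithm
## (clue::solve_LSAP). Ties between equally similar candidates are
## broken in favor of pairs sharing SVTYPE, then train/test subset, via
## perturbations far below any real similarity difference.

#' Jaccard similarity of two genomic regions
#'
#' `j = |intersection| / |union|` in bases, on 1-based inclusive
#' intervals. Regions on different chromosomes have similarity 0.
#'
#' @param chrom_a,pos_a,end_a,chrom_b,pos_b,end_b the two regions
#'   (vectorized).
#' @return numeric in `[0, 1]`.
#' @examples
#' jaccard_similarity("1", 100, 200, "1", 150, 250)  # 51/151
#' @export
jaccard_similarity <- function(chrom_a, pos_a, end_a, chrom_b, pos_b, end_b) {
  inter <- pmin(end_a, end_b) - pmax(pos_a, pos_b) + 1
  inter <- pmax(inter, 0)
  uni <- (end_a - pos_a + 1) + (end_b - pos_b + 1) - inter
  ifelse(chrom_a == chrom_b, inter / uni, 0)
}

#' Breakpoint closeness of a called and a known SV
#'
#' Computes the closeness similarity `c` for one called/known pair. Both
#' breakpoints within the flank `f` gives
#' `c = sqrt(c'_start * c'_end)` with `c' = 1 - D/f`; exactly one
#' breakpoint within `f` marks the pair as partially matching (`c = 0`,
#' `partial = TRUE`). Single-breakpoint records (`pos == end` on both
#' sides, e.g. insertions) are compared on the start breakpoint only,
#' with `c = c'_start`.
#'
#' @param called,known single-row SV record `data.frame`s (or lists with
#'   `chrom`, `pos`, `end`).
#' @param f flank parameter in bp (> 0); default 100.
#' @return list with elements `c` (numeric in `[0, 1]`) and `partial`
#'   (logical).
#' @examples
#' a <- sv_records("a", "1", 1000, 2000, "DEL")
#' b <- sv_records("b", "1", 1020, 2080, "DEL")
#' breakpoint_closeness(a, b, f = 100)  # c = sqrt(0.8 * 0.2) = 0.4
#' @export
breakpoint_closeness <- function(called, known, f = 100) {
  if (f <= 0) stop("flank parameter f must be positive")
  if (called$chrom != known$chrom) return(list(c = 0, partial = FALSE))
  ds <- abs(called$pos - known$pos)
  de <- abs(called$end - known$end)
  if (called$pos == called$end && known$pos == known$end) {
    cs <- if (ds <= f) 1 - ds / f else 0
    return(list(c = cs, partial = FALSE))
  }
  s_in <- ds <= f
  e_in <- de <= f
  if (s_in && e_in)
    list(c = sqrt((1 - ds / f) * (1 - de / f)), partial = FALSE)
  else if (s_in || e_in)
    list(c = 0, partial = TRUE)
  else
    list(c = 0, partial = FALSE)
}

## all qualifying called x known similarity edges for one scheme.
## Returns data.frame(ci, ki, similarity, partial_only).
similarity_edges <- function(called, known, scheme, f, j_min) {
  out <- list()
  for (chr in intersect(unique(called$chrom), unique(known$chrom))) {
    ci <- which(called$chrom == chr)
    ki <- which(known$chrom == chr)
    cs <- matrix(rep(called$pos[ci], length(ki)), nrow = length(ci))
    ks <- matrix(rep(known$pos[ki], each = length(ci)), nrow = length(ci))
    ce <- matrix(rep(called$end[ci], length(ki)), nrow = length(ci))
    ke <- matrix(rep(known$end[ki], each = length(ci)), nrow = length(ci))
    if (scheme == "closeness") {
      ds <- abs(cs - ks); de <- abs(ce - ke)
      single <- (cs == ce) & (ks == ke)
      sim <- sqrt(pmax(1 - ds / f, 0) * pmax(1 - de / f, 0))
      sim[single] <- pmax(1 - ds / f, 0)[single]
      partial <- !single & ((ds <= f) != (de <= f))
      keep <- sim > 0 | partial
    } else {
      inter <- pmax(pmin(ce, ke) - pmax(cs, ks) + 1, 0)
      sim <- inter / ((ce - cs + 1) + (ke - ks + 1) - inter)
      partial <- matrix(FALSE, nrow = length(ci), ncol = length(ki))
      keep <- sim > j_min
    }
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[chr]] <- data.frame(
        ci = ci[idx[, 1]], ki = ki[idx[, 2]],
        similarity = sim[idx], partial_only = partial[idx])
    }
  }
  if (!length(out))
    return(data.frame(ci = integer(), ki = integer(),
                      similarity = numeric(), partial_only = logical()))
  do.call(rbind, out)
}

#' Match called SVs to known SVs one-to-one
#'
#' Builds all qualifying similarity edges between a called and a known
#' SV set under the chosen scheme, then finds the one-to-one matching
#' that maximizes total similarity (Hungarian algorithm). Matching is
#' type-blind: SVTYPE enters only as a tie-break between equally similar
#' candidates (same SVTYPE preferred, then same train/test subset, then
#' genomic order).
#'
#' Matched records are annotated TP on both sides. Unmatched records
#' with at least one qualifying (or breakpoint-partial) edge are
#' annotated `partial`; the rest are FP (called side) or FN (known
#' side). Break-end mate pairs are annotated separately, then an FP mate
#' whose partner is TP or partial is downgraded to partial, and each
#' mate pair is counted as a single SV.
#'
#' @param called,known SV record `data.frame`s; IDs must be unique
#'   within each set.
#' @param scheme `"closeness"` (default) or `"overlap"`.
#' @param f flank parameter in bp for the closeness scheme (default 100).
#' @param j_min minimum Jaccard coefficient for the overlap scheme; the
#'   default 0 requires any positive overlap (`j > 0`).
#' @return an object of class `sv_match`: a list with per-record
#'   annotation tables `calls` and `knowns` (columns `id`, `status`,
#'   `matched_id`, `similarity`, `unit`), the qualifying `edges`, and
#'   `total_similarity` of the matching.
#' @seealso [score()]
#' @export
match_calls <- function(called, known, scheme = c("closeness", "overlap"),
                        f = 100, j_min = 0) {
  scheme <- match.arg(scheme)
  if (f <= 0) stop("flank parameter f must be positive")
  if (anyDuplicated(called$id)) stop("duplicate IDs in called set")
  if (anyDuplicated(known$id)) stop("duplicate IDs in known set")
  ## deterministic genomic order
  called <- called[order(called$chrom, called$pos, called$end, called$id), ,
                   drop = FALSE]
  known <- known[order(known$chrom, known$pos, known$end, known$id), ,
                 drop = FALSE]
  rownames(called) <- rownames(known) <- NULL

  edges <- similarity_edges(called, known, scheme, f, j_min)
  m_edges <- edges[!edges$partial_only, , drop = FALSE]

  match_ci <- integer(0); match_ki <- integer(0)
  if (nrow(m_edges)) {
    nc <- nrow(called); nk <- nrow(known)
    ## similarity perturbed by tie-break preferences; the perturbation is
    ## orders of magnitude below any real similarity difference so the
    ## matching stays similarity-optimal
    bonus <- 2e-12 * (called$svtype[m_edges$ci] == known$svtype[m_edges$ki]) +
      1e-12 * (called$subset[m_edges$ci] == known$subset[m_edges$ki])
    w <- matrix(0, nrow = nc, ncol = nk)
    w[cbind(m_edges$ci, m_edges$ki)] <- m_edges$similarity + bonus
    if (nc <= nk) {
      sol <- clue::solve_LSAP(w, maximum = TRUE)
      pairs <- cbind(seq_len(nc), as.integer(sol))
    } else {
      sol <- clue::solve_LSAP(t(w), maximum = TRUE)
      pairs <- cbind(as.integer(sol), seq_len(nk))
    }
    real <- w[pairs] > 0
    match_ci <- pairs[real, 1]
    match_ki <- pairs[real, 2]
  }

  ann <- function(records, idx_matched, other, other_idx, sims, has_edge,
                  miss_status) {
    status <- rep(miss_status, nrow(records))
    status[has_edge] <- "partial"
    status[idx_matched] <- "TP"
    matched_id <- rep(NA_character_, nrow(records))
    matched_id[idx_matched] <- other$id[other_idx]
    similarity <- rep(NA_real_, nrow(records))
    similarity[idx_matched] <- sims
    data.frame(id = records$id, chrom = records$chrom, pos = records$pos,
               end = records$end, svtype = records$svtype,
               subset = records$subset, status = status,
               matched_id = matched_id, similarity = similarity,
               stringsAsFactors = FALSE)
  }
  sims <- if (length(match_ci)) {
    m <- matrix(0, nrow = nrow(called), ncol = nrow(known))
    m[cbind(m_edges$ci, m_edges$ki)] <- m_edges$similarity
    m[cbind(match_ci, match_ki)]
  } else numeric(0)
  calls <- ann(called, match_ci, known, match_ki, sims,
               seq_len(nrow(called)) %in% edges$ci, "FP")
  knowns <- ann(known, match_ki, called, match_ci, sims,
                seq_len(nrow(known)) %in% edges$ki, "FN")

  calls$unit <- mate_unit(called)
  knowns$unit <- mate_unit(known)
  calls <- resolve_mate_units(calls, fail_status = "FP")
  knowns <- resolve_mate_units(knowns, fail_status = "FN")

  structure(list(calls = calls, knowns = knowns, edges = edges,
                 total_similarity = sum(sims), scheme = scheme,
                 f = f, j_min = j_min),
            class = "sv_match")
}

## one unit per mate pair (shared key), one per unmated record
mate_unit <- function(records) {
  ifelse(is.na(records$mate_id), records$id,
         paste(pmin(records$id, records$mate_id),
               pmax(records$id, records$mate_id), sep = "|"))
}

## mated breakpoints: an FP whose mate is TP or partial becomes partial;
## the pair then counts once, with the best annotation
resolve_mate_units <- function(ann, fail_status) {
  for (u in unique(ann$unit[duplicated(ann$unit)])) {
    i <- which(ann$unit == u)
    st <- ann$status[i]
    if (any(st %in% c("TP", "partial")) && any(st == "FP"))
      ann$status[i][st == "FP"] <- "partial"
  }
  ann
}

#' @export
print.sv_match <- function(x, ...) {
  cat("sv_match (", x$scheme, " scheme",
      if (x$scheme == "closeness") paste0(", f = ", x$f) else
        paste0(", j > ", x$j_min),
      ")\n", sep = "")
  cat("  called units:", length(unique(x$calls$unit)),
      " known units:", length(unique(x$knowns$unit)), "\n")
  cat("  total matched similarity:", format(x$total_similarity), "\n")
  print(score(x))
  invisible(x)
}

#' Precision, recall and F-score of a matching
#'
#' Counts TP/FP/FN over a matching produced by [match_calls()] and
#' reports `precision = nTP/(nTP + nFP)`,
#' `recall = nTP/(nTP + nFN)` and the F-score (harmonic mean); each
#' ratio is defined as 0 when its denominator is 0. Partial matches are
#' counted in none of the three. Mate pairs count as single SVs.
#'
#' With `scope = "train"` or `"test"`, known-side SVs are restricted to
#' that subset label. False-positive calls carry no truth subset; when
#' `masks` are supplied an FP is attributed to the test scope iff at
#' least 50% of its region overlaps the mask set (the same rule that
#' allocates truth SVs), otherwise to train. Without masks, all FPs
#' count in either scope.
#'
#' @param match an `sv_match` object.
#' @param scope `"all"` (default), `"train"` or `"test"`.
#' @param masks optional mask `data.frame` used to attribute FP calls to
#'   a scope.
#' @return a one-row `data.frame` of class `score_report` with columns
#'   `scope`, `n_tp`, `n_fp`, `n_fn`, `n_partial`, `precision`,
#'   `recall`, `f_score`.
#' @examples
#' truth <- sv_records(c("a", "b"), "1", c(100, 5000), c(900, 5600), "DEL")
#' m <- match_calls(truth, truth)
#' score(m)  # precision = recall = F = 1
#' @export
score <- function(match, scope = c("all", "train", "test"), masks = NULL) {
  scope <- match.arg(scope)
  ku <- unit_status(match$knowns)
  cu <- unit_status(match$calls)
  if (scope != "all") {
    ku <- ku[ku$subset == scope, , drop = FALSE]
    if (!is.null(masks)) {
      fp <- cu$status == "FP"
      fp_scope <- fp_mask_scope(cu, masks)
      cu <- cu[!fp | fp_scope == scope, , drop = FALSE]
    }
    ## TPs are counted on the known side, so call-side TPs need no
    ## scope restriction
  }
  n_tp <- sum(ku$status == "TP")
  n_fp <- sum(cu$status == "FP")
  n_fn <- sum(ku$status == "FN")
  n_partial <- sum(cu$status == "partial") + sum(ku$status == "partial")
  precision <- if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else 0
  recall <- if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else 0
  f_score <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(data.frame(scope = scope, n_tp = n_tp, n_fp = n_fp,
                       n_fn = n_fn, n_partial = n_partial,
                       precision = precision, recall = recall,
                       f_score = f_score, stringsAsFactors = FALSE),
            class = c("score_report", "data.frame"))
}

## collapse per-record annotations to one row per mate unit
unit_status <- function(ann) {
  pri <- c(TP = 3, partial = 2, FP = 1, FN = 1)
  o <- order(ann$unit, -pri[ann$status])
  a <- ann[o, , drop = FALSE]
  a[!duplicated(a$unit), , drop = FALSE]
}

fp_mask_scope <- function(ann, masks) {
  out <- rep("train", nrow(ann))
  for (chr in unique(ann$chrom)) {
    mr <- mask_ranges(masks, chr)
    sel <- which(ann$chrom == chr)
    if (!length(mr)) next
    covered <- vapply(sel, function(k) {
      sum(IRanges::width(IRanges::restrict(mr, start = ann$pos[k],
                                           end = ann$end[k])))
    }, numeric(1))
    out[sel][covered / (ann$end[sel] - ann$pos[sel] + 1) >= 0.5] <- "test"
  }
  out
}

#' Write per-SV annotations and the score summary to TSV files
#'
#' @param match an `sv_match` object.
#' @param report_path summary TSV (one row per scope).
#' @param annotation_path optional per-SV annotation TSV (side, id,
#'   status, matched_id, similarity).
#' @param masks optional masks for FP scope attribution.
#' @return `report_path`, invisibly.
#' @export
write_score_report <- function(match, report_path, annotation_path = NULL,
                               masks = NULL) {
  rep <- do.call(rbind, lapply(c("all", "train", "test"), score,
                               match = match, masks = masks))
  utils::write.table(rep, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- rbind(cbind(side = "called", match$calls),
                 cbind(side = "known", match$knowns))
    utils::write.table(
      ann[, c("side", "id", "status", "matched_id", "similarity")],
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report_path)
}
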