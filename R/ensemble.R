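## "Wisdom of the crowds" aggregation of SV calls from k submissions.
##
## Both aggregators start the same way: break-end (BND) calls are
## excluded, pairwise breakpoint-length distances are computed between
## calls from *different* submissions, and pairs closer than the flank
## threshold f are deemed sufficiently similar. The baseline algorithm
## takes connected components of the similarity graph and prunes
## outliers until each set's median intra-set distance is at most f. The
## conservative algorithm additionally requires >= 1 bp region overlap
## and grows sets greedily from the closest pairs, admitting a candidate
## only if its submission is not yet covered by the set
## (guilt-by-association). Sets covering <= k/2 distinct submissions are
## removed; the survivors are collapsed to consensus calls at the median
## start and end.

#' Breakpoint-length distance between two SV calls
#'
#' A single distance that incorporates both breakpoint distances and the
#' difference in predicted SV length:
#' `d = max(|pos_a - pos_b|, |end_a - end_b|, |L_a - L_b|)` with
#' `L = end - pos + 1`. Calls on different chromosomes are infinitely
#' distant. `d < f` implies both breakpoints agree to within the flank
#' `f`, keeping the threshold semantics aligned with the closeness
#' scoring scheme.
#'
#' @param a,b single-row SV records (or lists with `chrom`, `pos`,
#'   `end`).
#' @return non-negative distance in bp (`Inf` across chromosomes).
#' @export
breakpoint_length_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  max(abs(a$pos - b$pos), abs(a$end - b$end),
      abs((a$end - a$pos) - (b$end - b$pos)))
}

## all pairwise distances among rows of a call table (matrix form)
pair_dist_matrix <- function(calls) {
  n <- nrow(calls)
  ds <- abs(outer(calls$pos, calls$pos, "-"))
  de <- abs(outer(calls$end, calls$end, "-"))
  dl <- abs(outer(calls$end - calls$pos, calls$end - calls$pos, "-"))
  d <- pmax(ds, de, dl)
  d[outer(calls$chrom, calls$chrom, "!=")] <- Inf
  d
}

#' Aggregate top-k submissions into consensus ensemble calls
#'
#' @param submissions list of SV record `data.frame`s, ordered best
#'   first (by overall F-score computed after BND exclusion; see
#'   [ensemble_sweep()] which performs the ordering). For the baseline
#'   mode this should hold one (best) submission per team; the
#'   conservative mode may include several submissions per team.
#' @param k number of top submissions to aggregate (`>= 2`).
#' @param mode `"baseline"` (connected components + median refinement)
#'   or `"conservative"` (overlap-constrained guilt-by-association).
#' @param f distance threshold in bp (default 100, consistent with the
#'   closeness scoring flank).
#' @return a list of class `ensemble_set` with `calls` (consensus SV
#'   records carrying a `supp` column, the number of distinct
#'   submissions covered, sorted by chromosome and start) and `sets`
#'   (one member table per surviving set).
#' @export
build_ensemble <- function(submissions, k,
                           mode = c("baseline", "conservative"), f = 100) {
  mode <- match.arg(mode)
  if (k < 2) stop("ensembles need k >= 2 submissions")
  if (k > length(submissions)) stop("k exceeds the number of submissions")
  if (is.null(names(submissions)))
    names(submissions) <- sprintf("S%02d", seq_along(submissions))
  top <- submissions[seq_len(k)]
  calls <- do.call(rbind, lapply(seq_along(top), function(i) {
    s <- top[[i]]
    s <- s[s$svtype != "BND", , drop = FALSE]
    if (!nrow(s)) return(NULL)
    data.frame(sub = names(top)[i], rank = i, id = s$id, chrom = s$chrom,
               pos = s$pos, end = s$end, svtype = s$svtype,
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls) || !nrow(calls))
    return(structure(list(calls = empty_sv_records(), sets = list()),
                     class = "ensemble_set"))
  calls <- calls[order(calls$chrom, calls$pos, calls$end, calls$rank,
                       calls$id), , drop = FALSE]
  rownames(calls) <- NULL

  ## sufficiently similar pairs (different submissions, d < f)
  d <- pair_dist_matrix(calls)
  d[outer(calls$sub, calls$sub, "==")] <- Inf
  if (mode == "conservative") {
    no_ov <- outer(calls$pos, calls$end, ">") |
      outer(calls$end, calls$pos, "<")
    d[no_ov] <- Inf
  }
  pr <- which(upper.tri(d) & d < f, arr.ind = TRUE)

  sets <- if (mode == "baseline") {
    comps <- igraph::components(igraph::graph_from_edgelist(
      rbind(pr, cbind(seq_len(nrow(calls)), seq_len(nrow(calls)))),
      directed = FALSE))$membership
    lapply(split(seq_len(nrow(calls)), comps), refine_set, calls = calls,
           f = f)
  } else {
    conservative_sets(calls, pr, d, f)
  }
  sets <- Filter(function(s) length(unique(calls$sub[s])) > k / 2, sets)

  cons <- lapply(sets, function(s) {
    svt <- sort(table(calls$svtype[s]), decreasing = TRUE)
    data.frame(chrom = calls$chrom[s][1],
               pos = lower_median(calls$pos[s]),
               end = lower_median(calls$end[s]),
               svtype = names(svt)[1],
               supp = length(unique(calls$sub[s])),
               stringsAsFactors = FALSE)
  })
  if (length(cons)) {
    cons <- do.call(rbind, cons)
    o <- order(cons$chrom, cons$pos, cons$end)
    cons <- cons[o, , drop = FALSE]
    sets <- sets[o]
    out <- sv_records(id = sprintf("ens_%d", seq_len(nrow(cons))),
                      chrom = cons$chrom, pos = cons$pos, end = cons$end,
                      svtype = cons$svtype, supp = cons$supp)
  } else {
    out <- empty_sv_records()
    out$supp <- integer(0)
  }
  member_tabs <- lapply(sets, function(s)
    calls[s, c("sub", "id", "chrom", "pos", "end", "svtype")])
  structure(list(calls = out, sets = member_tabs), class = "ensemble_set")
}

## lower median: even-sized sets keep an observed integer coordinate
lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

## baseline refinement: drop the member with the greatest median
## distance to the others until the median intra-set distance is <= f
refine_set <- function(members, calls, f) {
  while (length(members) > 1) {
    d <- pair_dist_matrix(calls[members, , drop = FALSE])
    if (median(d[upper.tri(d)]) <= f) break
    med <- vapply(seq_along(members),
                  function(i) median(d[i, -i]), numeric(1))
    ## ties: members are in genomic order, remove the later one
    members <- members[-max(which(med == max(med)))]
  }
  members
}

## conservative construction: iterate similar pairs from least to most
## distant; a pair with no member in any set seeds a new set, a pair
## with exactly one member in a set nominates the other for addition
conservative_sets <- function(calls, pr, d, f) {
  if (!nrow(pr)) return(list())
  o <- order(d[pr], calls$chrom[pr[, 1]], calls$pos[pr[, 1]],
             calls$rank[pr[, 1]], calls$rank[pr[, 2]])
  pr <- pr[o, , drop = FALSE]
  set_of <- rep(NA_integer_, nrow(calls))
  sets <- list()
  for (e in seq_len(nrow(pr))) {
    i <- pr[e, 1]; j <- pr[e, 2]
    si <- set_of[i]; sj <- set_of[j]
    if (is.na(si) && is.na(sj)) {
      sets[[length(sets) + 1]] <- c(i, j)
      set_of[c(i, j)] <- length(sets)
    } else if (xor(is.na(si), is.na(sj))) {
      s <- if (is.na(si)) sj else si
      cand <- if (is.na(si)) i else j
      members <- sets[[s]]
      if (!calls$sub[cand] %in% calls$sub[members]) {
        md <- median(vapply(members, function(m)
          pair_dist_matrix(calls[c(cand, m), , drop = FALSE])[1, 2],
          numeric(1)))
        if (md <= f) {
          sets[[s]] <- c(members, cand)
          set_of[cand] <- s
        }
      }
    }
    ## both already assigned: the pair is left unprocessed
  }
  sets
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat("ensemble_set:", nrow(x$calls), "consensus call(s)\n")
  if (nrow(x$calls)) print(utils::head(x$calls, 10))
  invisible(x)
}

#' Score ensembles of the top k submissions for a range of k
#'
#' Orders submissions by F-score against the truth (after excluding BND
#' calls), then for each `k` builds the ensemble of the top `k` and
#' scores it, alongside the k-th ranked individual submission. This is
#' the ensemble-versus-individual comparison used to ask whether
#' majority voting beats the best single caller.
#'
#' @param submissions named list of SV record `data.frame`s.
#' @param truth known SV record `data.frame`.
#' @param ks values of k to sweep (default `2:length(submissions)`).
#' @param mode ensemble mode, see [build_ensemble()].
#' @param f flank/distance threshold in bp.
#' @return a `data.frame` with one row per k: ensemble precision /
#'   recall / F and the k-th individual submission's scores.
#' @export
ensemble_sweep <- function(submissions, truth,
                           ks = 2:length(submissions),
                           mode = c("baseline", "conservative"), f = 100) {
  mode <- match.arg(mode)
  if (is.null(names(submissions)))
    names(submissions) <- sprintf("S%02d", seq_along(submissions))
  no_bnd <- lapply(submissions, function(s)
    s[s$svtype != "BND", , drop = FALSE])
  ind <- lapply(no_bnd, function(s)
    score(match_calls(s, truth, scheme = "closeness", f = f)))
  o <- order(-vapply(ind, function(r) r$f_score, numeric(1)))
  submissions <- submissions[o]
  ind <- ind[o]
  rows <- lapply(ks, function(k) {
    ens <- build_ensemble(submissions, k = k, mode = mode, f = f)
    es <- score(match_calls(ens$calls, truth, scheme = "closeness", f = f))
    data.frame(k = k, mode = mode,
               ens_precision = es$precision, ens_recall = es$recall,
               ens_f = es$f_score,
               ind_submission = names(submissions)[k],
               ind_precision = ind[[k]]$precision,
               ind_recall = ind[[k]]$recall, ind_f = ind[[k]]$f_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
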