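## Leaderboard-style analyses over many scored submissions.

#' Rank submissions by F-score
#'
#' @param scores `data.frame` with at least `team_id`, `f_all` and
#'   optionally `precision` columns (one row per submission).
#' @return the same table sorted descending by `f_all` (ties broken by
#'   precision, then `team_id`) with a `rank` column prepended.
#' @export
rank_submissions <- function(scores) {
  if (!nrow(scores)) stop("no submissions to rank")
  prec <- if (!is.null(scores$precision)) scores$precision else 0
  o <- order(-scores$f_all, -prec, scores$team_id)
  out <- scores[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Within-team variance of submission F-scores
#'
#' Quantifies how much of the spread in F-scores across all submissions
#' is attributable to repeated (re-parameterized) submissions by the
#' same team: the within-team sum of squares as a percentage of the
#' total sum of squares.
#'
#' @param scores `data.frame` with `team_id` and `f_all` columns.
#' @return percentage in `[0, 100]`; `NA` when the total sum of squares
#'   is zero.
#' @export
within_team_variance <- function(scores) {
  if (nrow(scores) < 2) stop("need at least 2 submissions")
  f <- scores$f_all
  tot <- sum((f - mean(f))^2)
  if (tot == 0) return(NA_real_)
  within <- sum(unlist(lapply(split(f, scores$team_id),
                              function(x) (x - mean(x))^2)))
  100 * within / tot
}

#' Overfitting-artifact resampling over train/test splits
#'
#' Even with no model fitting anywhere, the difference
#' `F_train - F_test` of a fixed call set is biased upward when the
#' testing set is small. This experiment quantifies that artifact:
#' for each combination of a mutation total and a training-set
#' fraction, truth subsets of the given total are sampled, a
#' fraction-sized part is labeled train and the rest test, each
#' submission is scored on both, and `F_train - F_test` recorded. The
#' summary per cell is the median over replicates per submission, then
#' the median across submissions.
#'
#' Each submission is matched once against the full truth set; a call
#' is a false positive only if it matches no known SV at all. Within a
#' sampled split, TPs and FNs are read off the sampled knowns' matching
#' status, while the (global) FP count cannot be attributed to either
#' side and counts against both scopes -- which is precisely what makes
#' the small-test-set artifact visible: the same FP burden weighs much
#' more heavily on the few test-set TPs than on the many training-set
#' ones.
#'
#' @param truth known SV records (at least `max(totals)` rows).
#' @param submissions list of called SV record `data.frame`s.
#' @param totals mutation totals to assess (e.g. `seq(100, 1000, 100)`).
#' @param fracs training-set fractions (e.g. `seq(0.80, 0.95, 0.01)`).
#' @param reps samples per combination.
#' @param seed integer seed.
#' @param f closeness flank used for scoring (default 100 bp).
#' @return a `data.frame` with one row per `{total, frac}`:
#'   `median_delta_f` (the double median) plus per-cell medians by
#'   submission in the `per_submission` attribute.
#' @export
overfitting_resample <- function(truth, submissions, totals, fracs,
                                 reps = 100, seed = 1, f = 100) {
  if (max(totals) > nrow(truth))
    stop("mutation total exceeds the truth-set size")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  ## one matching per submission against the full truth: per-known
  ## matched status and the global FP count fully determine every
  ## subset's scores
  matched <- lapply(submissions, function(s) {
    m <- match_calls(s, truth, scheme = "closeness", f = f)
    ko <- m$knowns[match(truth$id, m$knowns$id), ]
    list(known_tp = ko$status == "TP",
         n_fp = sum(unit_status(m$calls)$status == "FP"))
  })
  f_of <- function(tp, fn, fp) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  cells <- expand.grid(total = totals, frac = fracs)
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    total <- cells$total[ci]; frac <- cells$frac[ci]
    delta <- matrix(NA_real_, nrow = reps, ncol = length(submissions))
    for (r in seq_len(reps)) {
      idx <- sample.int(nrow(truth), total)
      n_train <- round(frac * total)
      itr <- idx[seq_len(n_train)]
      ite <- idx[-seq_len(n_train)]
      for (s in seq_along(submissions)) {
        ms <- matched[[s]]
        tp_tr <- sum(ms$known_tp[itr]); tp_te <- sum(ms$known_tp[ite])
        delta[r, s] <-
          f_of(tp_tr, n_train - tp_tr, ms$n_fp) -
          f_of(tp_te, total - n_train - tp_te, ms$n_fp)
      }
    }
    apply(delta, 2, median)
  })
  per_sub <- do.call(rbind, res)
  out <- cbind(cells, median_delta_f = apply(per_sub, 1, median))
  attr(out, "per_submission") <- per_sub
  out
}
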