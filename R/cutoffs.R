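# Empirical ROC/PR machinery over labeled per-read scores, and the four
# cutoff-derivation strategies: Youden (max TPR - FPR), ROC corner
# (min FPR^2 + (1 - TPR)^2), the equal-error central discard band, and the
# rate-bound (FPR = FNR = alpha) double cutoff.
#
# Convention throughout: "score >= t => positive". Candidate thresholds are
# the distinct observed scores plus -Inf/+Inf sentinels; rates are exact
# empirical proportions, with no interpolation except the equal-error
# midpoint.

.check_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & labels %in% c(0, 1)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  if (!any(labels == 1)) stop("no positive (methylated) examples in input")
  if (!any(labels == 0)) stop("no negative (unmethylated) examples in input")
  list(scores = scores, labels = labels)
}

#' Empirical TPR/FPR path over all candidate thresholds
#'
#' Computes, at every distinct observed score plus `-Inf`/`+Inf` sentinels,
#' the exact empirical true- and false-positive rates under the rule
#' "score >= t is called methylated". Both rates are non-increasing in `t`,
#' equal 1 at `-Inf` and 0 at `+Inf`.
#'
#' @param scores Standardized per-read scores.
#' @param labels 0/1 truth labels (1 = methylated).
#' @return A `rate_path` list with `thresholds`, `tpr`, `fpr`, `n_pos`,
#'   `n_neg`.
#' @export
rate_path <- function(scores, labels) {
  d <- .check_labels(scores, labels)
  pos <- d$scores[d$labels == 1]
  neg <- d$scores[d$labels == 0]
  thr <- c(-Inf, sort(unique(d$scores)), Inf)
  # vapply is fine at the sizes used here (candidates are distinct scores)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "rate_path")
}

#' Area under the ROC curve (trapezoidal)
#'
#' Equals the tie-corrected pairwise ordering probability
#' `P(score_pos > score_neg) + P(score_pos == score_neg) / 2`.
#'
#' @param path A [rate_path()].
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(path) {
  stopifnot(inherits(path, "rate_path"))
  # thresholds ascending => fpr descending from 1 to 0
  fpr <- path$fpr; tpr <- path$tpr
  sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

#' Precision-recall curve and its area
#'
#' Precision and recall at every candidate threshold; the area integrates the
#' precision envelope (the best precision attainable at recall at or above r)
#' over recall in `[0, 1]`, the usual interpolated PR convention, so a
#' perfectly separating score reaches area 1.
#'
#' @param scores,labels As in [rate_path()].
#' @return `pr_curve()`: a `data.table` with `threshold`, `recall`,
#'   `precision`; `auc_pr()`: the area.
#' @export
pr_curve <- function(scores, labels) {
  d <- .check_labels(scores, labels)
  pos <- d$scores[d$labels == 1]
  neg <- d$scores[d$labels == 0]
  thr <- sort(unique(d$scores))
  tp <- vapply(thr, function(t) sum(pos >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(neg >= t), numeric(1))
  data.table(threshold = thr,
             recall = tp / length(pos),
             precision = tp / pmax(tp + fp, 1))
}

#' @rdname pr_curve
#' @export
auc_pr <- function(scores, labels) {
  pc <- pr_curve(scores, labels)
  r <- sort(unique(pc$recall))
  env <- vapply(r, function(g) max(pc$precision[pc$recall >= g]), numeric(1))
  r <- c(0, r)
  env <- c(env[1], env)   # envelope is flat from recall 0 to the first point
  sum(diff(r) * (env[-length(env)] + env[-1]) / 2)
}

.finite_path <- function(path) {
  keep <- is.finite(path$thresholds)
  list(thr = path$thresholds[keep], tpr = path$tpr[keep], fpr = path$fpr[keep])
}

.break_ties <- function(idx, tpr, thr) {
  # prefer higher TPR (sensitivity), then the lower threshold
  idx <- idx[tpr[idx] == max(tpr[idx])]
  idx[which.min(thr[idx])]
}

#' Youden cutoff: threshold maximizing TPR - FPR
#'
#' Ties are broken toward higher TPR, then toward the lower threshold.
#'
#' @param path A [rate_path()].
#' @return The selected threshold.
#' @export
youden_cutoff <- function(path) {
  p <- .finite_path(path)
  j <- p$tpr - p$fpr
  best <- which(j == max(j))
  p$thr[.break_ties(best, p$tpr, p$thr)]
}

#' ROC-corner cutoff: threshold minimizing FPR^2 + (1 - TPR)^2
#'
#' The candidate closest to the perfect-classification corner (FPR 0, TPR 1);
#' ties broken toward higher TPR, then the lower threshold.
#'
#' @param path A [rate_path()].
#' @return The selected threshold.
#' @export
corner_cutoff <- function(path) {
  p <- .finite_path(path)
  obj <- p$fpr^2 + (1 - p$tpr)^2
  best <- which(obj == min(obj))
  p$thr[.break_ties(best, p$tpr, p$thr)]
}

#' Equal-error crossing of the FPR and 1 - TPR curves
#'
#' The empirical FPR (non-increasing in t) and FNR = 1 - TPR (non-decreasing)
#' step functions are generally equal over an interval between observed
#' scores; the returned crossing is the midpoint between the last candidate
#' where FPR > FNR and the first where FPR <= FNR.
#'
#' @param scores,labels As in [rate_path()].
#' @return The crossing score.
#' @export
crossing_score <- function(scores, labels) {
  p <- .finite_path(rate_path(scores, labels))
  d <- p$fpr - (1 - p$tpr)   # non-increasing in t
  above <- which(d > 0)
  at_or_below <- which(d <= 0)
  if (length(above) == 0) return(p$thr[1])
  if (length(at_or_below) == 0) return(p$thr[length(p$thr)])
  (p$thr[max(above)] + p$thr[min(at_or_below)]) / 2
}

#' Central discard band around the equal-error crossing
#'
#' Removes the given fraction of calls (both classes together) closest in
#' score to the equal-error crossing: `k = ceiling(fraction * N)` calls are
#' selected by `|score - crossing|` (ties broken by score, then input order),
#' and the band spans the extreme selected scores, inclusive, so that exactly
#' those calls are discarded.
#'
#' @param scores,labels As in [rate_path()].
#' @param fraction Fraction of all calls to discard (default 0.10).
#' @return A double `cutoff_rule` with `boundary = "discard"`; `fraction = 0`
#'   yields a degenerate band that discards nothing.
#' @export
central_band_cutoffs <- function(scores, labels, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction <= 1)
  d <- .check_labels(scores, labels)
  cx <- crossing_score(d$scores, d$labels)
  k <- ceiling(fraction * length(d$scores))
  if (k == 0) {
    rule <- double_cutoff(cx, cx, boundary = "discard")
    attr(rule, "crossing") <- cx
    return(rule)
  }
  ord <- order(abs(d$scores - cx), d$scores)
  band <- d$scores[ord[seq_len(k)]]
  rule <- double_cutoff(min(band), max(band), boundary = "discard")
  attr(rule, "crossing") <- cx
  attr(rule, "n_selected") <- k
  rule
}

#' Rate-bound double cutoff: FPR <= alpha above, FNR <= alpha below
#'
#' `t_high` is the smallest candidate threshold with empirical
#' FPR(t) <= alpha; `t_low` is the largest candidate with
#' FNR(t) = P(pos < t) <= alpha. If the band inverts (`t_low >= t_high`,
#' e.g. on well-separated scores) a single cutoff at the equal-error crossing
#' is returned with a warning.
#'
#' @param scores,labels As in [rate_path()].
#' @param alpha Bound on both error rates (default 0.05).
#' @return A double `cutoff_rule`, or a single rule on fallback.
#' @export
rate_bound_cutoffs <- function(scores, labels, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  d <- .check_labels(scores, labels)
  p <- .finite_path(rate_path(d$scores, d$labels))
  fnr <- 1 - p$tpr
  hi_ok <- which(p$fpr <= alpha)
  lo_ok <- which(fnr <= alpha)
  # fpr is non-increasing but can stay above alpha at every finite candidate
  # (e.g. heavy ties at the top score); an unattainable bound maps to +Inf
  t_high <- if (length(hi_ok)) p$thr[min(hi_ok)] else Inf
  t_low <- p$thr[max(lo_ok)]   # fnr = 0 at the minimum candidate: never empty
  if (t_low >= t_high) {
    warning("rate-bound band is empty (classes well separated); ",
            "falling back to a single cutoff at the equal-error crossing")
    return(single_cutoff(crossing_score(d$scores, d$labels)))
  }
  double_cutoff(t_low, t_high)
}
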