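# ROC/PR machinery and the four cutoff-derivation strategies, checked
# against hand enumeration and exhaustive-scan oracles.

test_that("rate path gives exact empirical rates at each candidate", {
  scores <- c(0.35, 0.8, 0.1, 0.4)
  labels <- c(1, 1, 0, 0)
  p <- rate_path(scores, labels)
  i <- which(p$thresholds == 0.4)
  expect_equal(p$tpr[i], 0.5)
  expect_equal(p$fpr[i], 0.5)
  expect_equal(p$tpr[1], 1); expect_equal(p$fpr[1], 1)                  # -Inf
  expect_equal(tail(p$tpr, 1), 0); expect_equal(tail(p$fpr, 1), 0)     # +Inf
  expect_true(all(diff(p$tpr) <= 0))
  expect_true(all(diff(p$fpr) <= 0))
})

test_that("flipping the labels swaps the roles of TPR and FPR", {
  lab <- make_labeled_scores(15, 25, seed = 4)
  p1 <- rate_path(lab$scores, lab$labels)
  p2 <- rate_path(lab$scores, 1 - lab$labels)
  expect_equal(p2$tpr, p1$fpr)
  expect_equal(p2$fpr, p1$tpr)
})

test_that("single-class input is a hard error naming the missing class", {
  expect_error(rate_path(1:5, rep(1, 5)), "negative")
  expect_error(rate_path(1:5, rep(0, 5)), "positive")
})

test_that("AUC matches hand-enumerated and degenerate cases", {
  # 3 of 4 pairs correctly ordered
  expect_equal(auc_roc(rate_path(c(0.35, 0.8, 0.1, 0.4), c(1, 1, 0, 0))), 0.75)
  # all ties
  expect_equal(auc_roc(rate_path(rep(1, 10), rep(c(0, 1), 5))), 0.5)
  # separable
  expect_equal(auc_roc(rate_path(c(1, 2, 3, 4), c(0, 0, 1, 1))), 1.0)
})

test_that("AUC equals the pairwise-comparison oracle exactly", {
  for (seed in 1:100) {
    n_pos <- withr::with_seed(seed, sample(2:25, 1))
    n_neg <- withr::with_seed(seed + 1000, sample(2:25, 1))
    lab <- make_labeled_scores(n_pos, n_neg, mu1 = 1, mu0 = 0, seed = seed)
    # inject ties to exercise the tie-correction
    lab$scores <- round(lab$scores, 1)
    expect_equal(auc_roc(rate_path(lab$scores, lab$labels)),
                 auc_pairwise_oracle(lab$scores, lab$labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  lab <- make_labeled_scores(60, 80, mu1 = 1, mu0 = 0, seed = 11)
  ours <- auc_roc(rate_path(lab$scores, lab$labels))
  theirs <- as.numeric(pROC::auc(pROC::roc(lab$labels, lab$scores,
                                           quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("PR curve endpoints and area behave on hand cases", {
  pc <- pr_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(pc[threshold == 3]$precision, 1)
  expect_equal(pc[threshold == 1]$recall, 1)
  expect_equal(pc[threshold == 1]$precision, 0.5)
  expect_equal(auc_pr(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  # all ties: precision = prevalence everywhere
  expect_equal(auc_pr(rep(1, 10), rep(c(0, 1), 5)), 0.5)
})

test_that("Youden and corner cutoffs match exhaustive scans", {
  # spec'd hand cases
  p1 <- rate_path(c(0.7, 0.8, 0.9, 0.1, 0.2, 0.6), c(1, 1, 1, 0, 0, 0))
  expect_equal(youden_cutoff(p1), 0.7)
  expect_equal(corner_cutoff(p1), 0.7)
  # tie at J = 0.5: higher-TPR rule picks 0.35 over 0.8
  p2 <- rate_path(c(0.35, 0.8, 0.1, 0.4), c(1, 1, 0, 0))
  expect_equal(youden_cutoff(p2), 0.35)
  # separable data: the lowest positive score
  p3 <- rate_path(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(youden_cutoff(p3), 5)

  for (seed in 1:100) {
    n_pos <- withr::with_seed(seed, sample(2:25, 1))
    n_neg <- withr::with_seed(seed + 2000, sample(2:25, 1))
    lab <- make_labeled_scores(n_pos, n_neg, mu1 = 1.5, mu0 = 0, seed = seed)
    lab$scores <- round(lab$scores, 1)
    p <- rate_path(lab$scores, lab$labels)
    expect_equal(youden_cutoff(p), youden_oracle(lab$scores, lab$labels))
    expect_equal(corner_cutoff(p), corner_oracle(lab$scores, lab$labels))
  }
})

test_that("the Youden cutoff dominates every other candidate threshold", {
  lab <- make_labeled_scores(100, 100, mu1 = 1, mu0 = 0, seed = 9)
  p <- rate_path(lab$scores, lab$labels)
  t <- youden_cutoff(p)
  j_at <- function(t) mean(lab$scores[lab$labels == 1] >= t) -
    mean(lab$scores[lab$labels == 0] >= t)
  for (cand in unique(lab$scores))
    expect_gte(j_at(t), j_at(cand))
})

test_that("the equal-error crossing follows the midpoint convention", {
  # FPR = FNR = 1/3 over the interval (2, 3]; midpoint of the bracket
  expect_equal(crossing_score(c(2, 3, 4, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 2.5)
  # separable: midpoint of the gap
  expect_equal(crossing_score(c(5, 6, 1, 2), c(1, 1, 0, 0)), 3.5)
  # mirror-symmetric scores cross at zero
  expect_equal(crossing_score(c(1, 3, -1, -3), c(1, 1, 0, 0)), 0)
})

test_that("the central band discards exactly the k closest calls", {
  # 20 equally spaced scores, fraction 0.10 -> the 2 closest to the crossing
  scores <- seq(-4.75, 4.75, by = 0.5)
  labels <- rep(c(0, 1), each = 10)
  rule <- central_band_cutoffs(scores, labels, fraction = 0.10)
  expect_equal(rule$kind, "double")
  expect_equal(rule$boundary, "discard")
  st <- call_read_states(make_calls(scores = scores), rule)$state
  expect_equal(sum(st == "discard"), 2)
  expect_equal(which(st == "discard"), c(10, 11))  # the two nearest 0

  # fraction 0 discards nothing
  st0 <- call_read_states(make_calls(scores = scores),
                          central_band_cutoffs(scores, labels, 0))$state
  expect_equal(sum(st0 == "discard"), 0)

  # fraction 1 discards everything; aggregation then drops the site
  rule1 <- central_band_cutoffs(scores, labels, 1)
  st1 <- call_read_states(make_calls(scores = scores), rule1)
  expect_equal(sum(st1$state == "discard"), 20)
  expect_message(agg <- aggregate_per_site(st1), "dropped")
  expect_equal(nrow(agg), 0)
})

test_that("rate-bound cutoffs bound both error rates or fall back", {
  # well-separated classes invert the band -> single-cutoff fallback
  neg <- seq(-4, -1, length.out = 100)
  pos <- seq(1, 4, length.out = 100)
  expect_warning(
    rule <- rate_bound_cutoffs(c(pos, neg), rep(c(1, 0), each = 100)),
    "empty")
  expect_equal(rule$kind, "single")
  st <- call_read_states(make_calls(scores = c(pos, neg)), rule)$state
  expect_equal(sum(st == "discard"), 0)

  # heavily overlapping classes: a real band with both rates bounded
  lab <- make_labeled_scores(500, 500, mu1 = 1, mu0 = -1, seed = 21)
  rule2 <- rate_bound_cutoffs(lab$scores, lab$labels, alpha = 0.05)
  expect_equal(rule2$kind, "double")
  pos_s <- lab$scores[lab$labels == 1]; neg_s <- lab$scores[lab$labels == 0]
  expect_lte(mean(neg_s >= rule2$t_high), 0.05)      # training FPR
  expect_lte(mean(pos_s < rule2$t_low), 0.05)        # training FNR
  cx <- crossing_score(lab$scores, lab$labels)
  expect_lt(rule2$t_low, cx); expect_gt(rule2$t_high, cx)

  # alpha = 0.5 collapses the band near the crossing (possibly to nothing)
  rule3 <- suppressWarnings(rate_bound_cutoffs(lab$scores, lab$labels,
                                               alpha = 0.5))
  if (rule3$kind == "double") {
    expect_lt(rule3$t_high - rule3$t_low, rule2$t_high - rule2$t_low)
  }
})

test_that("rate-bound band controls held-out FPR within sampling error", {
  n <- 2000
  train <- make_labeled_scores(n, n, mu1 = 1, mu0 = -1, seed = 31)
  test <- make_labeled_scores(n, n, mu1 = 1, mu0 = -1, seed = 32)
  rule <- rate_bound_cutoffs(train$scores, train$labels, alpha = 0.05)
  neg_t <- test$scores[test$labels == 0]
  fpr_held <- mean(neg_t >= rule$t_high)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(fpr_held, 0.05 + 3 * se)
})
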