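# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; nothing is read from disk except
# files the tests themselves write to tempdir().

library(data.table)

# labeled Gaussian scores: n_pos methylated ~ N(mu1, sd), n_neg ~ N(mu0, sd)
make_labeled_scores <- function(n_pos, n_neg, mu1 = 2, mu0 = -2, sd = 1,
                                seed = 1) {
  withr::with_seed(seed, {
    list(scores = c(rnorm(n_pos, mu1, sd), rnorm(n_neg, mu0, sd)),
         labels = rep(c(1L, 0L), c(n_pos, n_neg)))
  })
}

# pairwise-comparison AUC oracle: P(pos > neg) + P(pos == neg)/2
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive threshold-scan oracles under "score >= t => positive",
# ties toward higher TPR then lower threshold
scan_cutoff_oracle <- function(scores, labels, objective) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cand <- sort(unique(scores))
  tpr <- sapply(cand, function(t) mean(pos >= t))
  fpr <- sapply(cand, function(t) mean(neg >= t))
  obj <- objective(tpr, fpr)
  best <- which(obj == max(obj))
  best <- best[tpr[best] == max(tpr[best])]
  cand[best[which.min(cand[best])]]
}
youden_oracle <- function(scores, labels)
  scan_cutoff_oracle(scores, labels, function(tpr, fpr) tpr - fpr)
corner_oracle <- function(scores, labels)
  scan_cutoff_oracle(scores, labels, function(tpr, fpr) -(fpr^2 + (1 - tpr)^2))

# a standardized per-read table with known per-read states
make_calls <- function(n = 20, chrom = "chr1", pos = 100L, strand = "+",
                       scores = NULL, tool = "toolA", seed = 1) {
  if (is.null(scores))
    scores <- withr::with_seed(seed, rnorm(n))
  data.table(read_id = sprintf("r%04d", seq_along(scores)), chrom = chrom,
             pos = pos, strand = strand, score = scores, tool = tool)
}

# encode a standardized table into a caller's native file; returns the path.
# std must have read_id, chrom, pos (0-based forward anchor), strand, score.
write_native_fixture <- function(std, tool, path = tempfile(fileext = ".tsv")) {
  std <- as.data.table(std)
  native_pos <- std$pos +
    (tool == "tombo") +                         # tombo input is 1-based
    (tool != "nanopolish") * (std$strand == "-") # reverse-strand C reported
  native <- switch(tool,
    nanopolish = data.table(
      chromosome = std$chrom, strand = std$strand, start = native_pos,
      end = native_pos + 1L, read_name = std$read_id,
      log_lik_ratio = std$score, num_motifs = 1L,
      sequence = "AATACGTCTTA"),   # exactly one CG
    guppy = data.table(read_id = std$read_id, chrom = std$chrom,
                       pos = native_pos, strand = std$strand,
                       log_lik_ratio = std$score),
    tombo = data.table(read_id = std$read_id, chrom = std$chrom,
                       pos = native_pos, strand = std$strand,
                       score = -std$score),
    deepsignal = {
      pm <- 2^std$score / (1 + 2^std$score)
      data.table(chrom = std$chrom, pos = native_pos, strand = std$strand,
                 read_id = std$read_id, prob_meth = pm, prob_unmeth = 1 - pm)
    },
    megalodon = {
      pm <- exp(std$score) / (1 + exp(std$score))
      data.table(read_id = std$read_id, chrom = std$chrom,
                 strand = std$strand, pos = native_pos,
                 mod_log_prob = log(pm), can_log_prob = log(1 - pm))
    },
    stop("no fixture encoder for ", tool))
  fwrite(native, path, sep = "\t", quote = FALSE)
  path
}

# two-tool synthetic benchmark at per-tool AUC ~ 0.85:
# Phi(delta / (sd * sqrt(2))) = 0.85  =>  delta = qnorm(0.85) * sqrt(2)
delta_for_auc <- function(auc, sd = 1) qnorm(auc) * sqrt(2) * sd

two_tool_profiles <- function(auc = 0.85, missingness = 0, w = 0) {
  d <- delta_for_auc(auc)
  list(tool_profile("toolA", mu_meth = d, sd_meth = 1, mu_unmeth = 0,
                    sd_unmeth = 1, missingness = missingness, w = w),
       tool_profile("toolB", mu_meth = d, sd_meth = 1, mu_unmeth = 0,
                    sd_unmeth = 1, missingness = missingness, w = w))
}
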