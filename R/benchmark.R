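# End-to-end benchmark experiments on synthetic data, mirroring the study
# design used for real callers: controlled mixtures over singleton sites
# with exact methylated/unmethylated composition, cutoffs learned from the
# fully methylated / fully unmethylated pools, and consensus-vs-single-tool
# comparisons.

#' Gaussian tool profiles calibrated to a target per-read AUC
#'
#' Unit-variance two-component profiles whose theoretical per-read AUC is
#' `pnorm(delta / sqrt(2))`; the mean separation delta is solved from the
#' requested AUC.
#'
#' @param tools Tool names (one profile each).
#' @param auc Target per-read AUC of each tool.
#' @param missingness,w Passed to [tool_profile()].
#' @return List of [tool_profile()]s.
#' @export
profiles_for_auc <- function(tools = c("toolA", "toolB"), auc = 0.85,
                             missingness = 0, w = 0) {
  stopifnot(auc > 0.5, auc < 1)
  delta <- stats::qnorm(auc) * sqrt(2)
  lapply(tools, function(tl)
    tool_profile(tl, mu_meth = delta, sd_meth = 1, mu_unmeth = 0,
                 sd_unmeth = 1, missingness = missingness, w = w))
}

# simulate fully methylated and fully unmethylated read pools over `sites`,
# with pool-prefixed read ids so the two pools never collide
.simulate_pools <- function(sites, pool_coverage, profiles, seed) {
  pool_m <- simulate_read_scores(sites, pool_coverage, m = 1,
                                 profiles = profiles, seed = seed)
  pool_u <- simulate_read_scores(sites, pool_coverage, m = 0,
                                 profiles = profiles, seed = seed + 1L)
  for (tl in names(pool_m$calls)) {
    pool_m$calls[[tl]][, read_id := paste0("M", read_id)]
    pool_u$calls[[tl]][, read_id := paste0("U", read_id)]
  }
  list(meth = pool_m$calls, unmeth = pool_u$calls)
}

# per-level site frequencies for mixture reads scored by one calls table
.mixture_frequencies <- function(mix, calls, rule) {
  scored <- merge(mix, calls[, .(read_id, chrom, pos, strand, score)],
                  by = c("read_id", "chrom", "pos"))
  data.table::rbindlist(lapply(split(scored, by = "level"), function(sub) {
    agg <- aggregate_per_site(call_read_states(sub, rule))
    agg[, level := sub$level[1]]
    agg
  }))
}

#' End-to-end mixture recovery with a learned Youden cutoff
#'
#' The full benchmarking pipeline on one synthetic tool: a genome with
#' singleton CpG sites is simulated; fully methylated and fully unmethylated
#' read pools are drawn per site; the Youden cutoff is learned from the
#' labeled pool reads; controlled mixtures with exact methylated counts are
#' built at the given levels; per-site frequencies are computed under the
#' learned cutoff and evaluated against the designed levels.
#'
#' Defaults mirror the controlled-mixture study design at desk scale:
#' 100 singleton sites, 24 reads per site and level, 11 levels from 0 to 1.
#'
#' @param n_sites Number of singleton CpG sites.
#' @param reads_per_site Reads drawn per site and level.
#' @param levels Designed methylation levels.
#' @param profile A [tool_profile()]; default is a high-separability tool
#'   (means -4/+4, sd 1).
#' @param pool_coverage Pool reads per site and label.
#' @param seed Seed for every stochastic step.
#' @return List: `evaluation` (from [evaluate_frequencies()]), `youden`
#'   (learned cutoff), `predictions` (per site and level), `sites`.
#' @export
mixture_recovery_experiment <- function(n_sites = 100, reads_per_site = 24,
                                        levels = seq(0, 1, by = 0.1),
                                        profile = tool_profile("sim",
                                                               mu_meth = 4,
                                                               mu_unmeth = -4),
                                        pool_coverage = 40, seed = 1) {
  g <- simulate_genome(n_contigs = 1, length = 30 * n_sites + 100,
                       cpg_spacing = 30, seed = seed)
  sites <- g$sites[seq_len(min(n_sites, nrow(g$sites)))]
  pools <- .simulate_pools(sites, pool_coverage, list(profile), seed + 10L)
  calls_m <- pools$meth[[1]]; calls_u <- pools$unmeth[[1]]
  t_youden <- youden_cutoff(rate_path(
    c(calls_m$score, calls_u$score),
    rep(c(1L, 0L), c(nrow(calls_m), nrow(calls_u)))))
  mix <- build_mixture(calls_m[, .(chrom, pos, read_id)],
                       calls_u[, .(chrom, pos, read_id)],
                       sites, levels = levels,
                       reads_per_site = reads_per_site, seed = seed + 20L)
  preds <- .mixture_frequencies(mix, rbind(calls_m, calls_u),
                                single_cutoff(t_youden))
  list(evaluation = evaluate_frequencies(preds), youden = t_youden,
       predictions = preds, sites = sites)
}

#' Consensus vs single tools: cross-validated per-read AUC
#'
#' Simulates two tools with independent noise at the given per-read AUC on a
#' balanced read set, then compares each tool's AUC with the cross-validated
#' AUC of the random-forest and ridge consensus.
#'
#' @param seed Seed.
#' @param auc Target per-tool AUC (default 0.85).
#' @param n_reads Total reads (default 2000).
#' @param k Cross-validation folds (default 10).
#' @return List: `auc_single` (named per tool), `auc_rf`, `auc_reg`,
#'   `retention` from the intersection join.
#' @export
consensus_cv_benchmark <- function(seed = 1, auc = 0.85, n_reads = 2000,
                                   k = 10) {
  n_sites <- 20
  sites <- data.table(chrom = "chr1",
                      pos = seq(0L, by = 50L, length.out = n_sites))
  sim <- simulate_read_scores(sites, coverage = ceiling(n_reads / n_sites),
                              m = 0.5, profiles = profiles_for_auc(auc = auc),
                              seed = seed)
  m <- join_reads_across_tools(sim$calls)
  tools <- attr(m, "tools")
  auc_single <- vapply(tools, function(tl)
    auc_roc(rate_path(m[[tl]], m$label)), numeric(1))
  cv_rf <- cross_validated_curves(m, k = k, seed = seed, kind = "rf")
  cv_reg <- cross_validated_curves(m, k = k, seed = seed, kind = "reg")
  list(auc_single = auc_single, auc_rf = cv_rf$mean_auc_roc,
       auc_reg = cv_reg$mean_auc_roc, retention = attr(m, "retention"))
}

#' Consensus vs single tools: per-site mixture RMSE
#'
#' Two synthetic tools at the given per-read AUC are benchmarked on
#' controlled mixtures: consensus models (RF and ridge) and per-tool Youden
#' cutoffs are learned on a training mixture set, then applied to an
#' independent test mixture set over different sites and reads; pooled
#' per-site RMSE against the designed levels is reported for each tool and
#' both consensus models.
#'
#' @param seed Seed.
#' @param auc Target per-tool AUC.
#' @param n_sites Sites per mixture set (default 50).
#' @param reads_per_site Reads per site and level (default 20).
#' @param levels Designed methylation levels.
#' @param pool_coverage Pool reads per site and label.
#' @return List: `rmse_single` (named), `rmse_rf`, `rmse_reg`,
#'   `r_single`, `r_rf`, `r_reg` (pooled Pearson r).
#' @export
consensus_mixture_benchmark <- function(seed = 1, auc = 0.85, n_sites = 50,
                                        reads_per_site = 20,
                                        levels = seq(0, 1, by = 0.1),
                                        pool_coverage = 60) {
  profiles <- profiles_for_auc(auc = auc)
  tools <- vapply(profiles, `[[`, character(1), "tool")
  make_set <- function(set_seed) {
    g <- simulate_genome(n_contigs = 1, length = 30 * n_sites + 100,
                         cpg_spacing = 30, seed = set_seed)
    sites <- g$sites[seq_len(min(n_sites, nrow(g$sites)))]
    pools <- .simulate_pools(sites, pool_coverage, profiles, set_seed + 10L)
    mix <- build_mixture(pools$meth[[1]][, .(chrom, pos, read_id)],
                         pools$unmeth[[1]][, .(chrom, pos, read_id)],
                         sites, levels = levels,
                         reads_per_site = reads_per_site,
                         seed = set_seed + 20L)
    calls <- lapply(tools, function(tl)
      rbind(pools$meth[[tl]], pools$unmeth[[tl]]))
    names(calls) <- tools
    list(sites = sites, mix = mix, calls = calls)
  }
  train <- make_set(seed)
  test <- make_set(seed + 1000L)

  # restrict per-tool tables to the distinct mixture reads (a read drawn
  # into several levels enters the model matrix once), keeping the label
  mixture_calls <- function(set) {
    reads <- unique(set$mix[, .(read_id, chrom, pos, label)])
    lapply(set$calls, function(cl)
      merge(reads, cl[, .(read_id, chrom, pos, strand, score, tool)],
            by = c("read_id", "chrom", "pos")))
  }
  train_m <- join_reads_across_tools(mixture_calls(train))
  test_mix_calls <- mixture_calls(test)

  # per-tool Youden cutoffs from the distinct training mixture reads
  train_reads <- unique(train$mix[, .(read_id, chrom, pos, label)])
  cuts <- lapply(train$calls, function(cl) {
    tr <- merge(train_reads, cl[, .(read_id, chrom, pos, score)],
                by = c("read_id", "chrom", "pos"))
    youden_cutoff(rate_path(tr$score, tr$label))
  })

  rmse_of <- function(preds) evaluate_frequencies(preds)$pooled
  single_stats <- lapply(tools, function(tl)
    rmse_of(.mixture_frequencies(test$mix, test$calls[[tl]],
                                 single_cutoff(cuts[[tl]]))))
  names(single_stats) <- tools

  test_m <- join_reads_across_tools(test_mix_calls)
  consensus_stats <- lapply(c(rf = "rf", reg = "reg"), function(kind) {
    model <- train_consensus(train_m, kind = kind, seed = seed)
    # predict each distinct read once, then expand into its mixture levels
    pred <- predict_consensus(model, test_m)
    labeled <- merge(test$mix[, .(read_id, chrom, pos, level)],
                     pred[, .(read_id, chrom, pos, strand,
                              state = consensus_state)],
                     by = c("read_id", "chrom", "pos"))
    data.table::rbindlist(lapply(split(labeled, by = "level"), function(sub) {
      agg <- aggregate_per_site(sub)
      agg[, level := sub$level[1]]
      agg
    }))
  })
  cons <- lapply(consensus_stats, rmse_of)

  list(rmse_single = vapply(single_stats, `[[`, numeric(1), "rmse"),
       rmse_rf = cons$rf$rmse, rmse_reg = cons$reg$rmse,
       r_single = vapply(single_stats, `[[`, numeric(1), "pearson_r"),
       r_rf = cons$rf$pearson_r, r_reg = cons$reg$pearson_r,
       cutoffs = unlist(cuts))
}
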