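# WGBS replicate ingestion and concordance with nanopore per-site calls:
# replicate-difference quantile filtering, Table-style statistics, binned
# dispersion, coverage-stratified correlation, and read subsampling.

#' Combine two WGBS replicates into one site table
#'
#' Full outer join on (chrom, pos, strand); a replicate absent at a site
#' contributes coverage 0 and an undefined frequency.
#'
#' @param rep1,rep2 Per-site tables with `chrom`, `pos`, `strand`,
#'   `coverage` (or `n_used`) and `frequency` (e.g. from [read_bedmethyl()]).
#' @return `data.table` with per-replicate `coverage1/2`, `frequency1/2`.
#' @export
combine_wgbs_replicates <- function(rep1, rep2) {
  norm <- function(x, i) {
    x <- as.data.table(x)
    if (!"coverage" %in% names(x) && "n_used" %in% names(x))
      data.table::setnames(x, "n_used", "coverage")
    x <- x[, .(chrom, pos, strand, coverage, frequency)]
    data.table::setnames(x, c("coverage", "frequency"),
                         paste0(c("coverage", "frequency"), i))
    x
  }
  out <- merge(norm(rep1, 1), norm(rep2, 2),
               by = c("chrom", "pos", "strand"), all = TRUE)
  out[is.na(coverage1), `:=`(coverage1 = 0L)]
  out[is.na(coverage2), `:=`(coverage2 = 0L)]
  out[coverage1 == 0, frequency1 := NA_real_]
  out[coverage2 == 0, frequency2 := NA_real_]
  out[]
}

#' Filter WGBS sites by replicate concordance
#'
#' Sites with zero coverage in both replicates are discarded. Over the
#' remaining sites with both replicates covered, the replicate frequency
#' difference d = frequency1 - frequency2 is computed and only sites with
#' q0.1 <= d <= q0.9 (linear-interpolation quantiles, inclusive) are kept;
#' sites covered by a single replicate have no difference and are retained.
#' The combined frequency is the unweighted mean of the available replicate
#' frequencies.
#'
#' @param sites Output of [combine_wgbs_replicates()].
#' @param probs Lower/upper quantiles of the difference distribution.
#' @return Filtered `data.table` with a `frequency` column (combined) and a
#'   `coverage` column (summed); attributes `quantile_bounds`, `n_zero_cov`,
#'   `n_outside_quantiles`.
#' @export
filter_replicates <- function(sites, probs = c(0.1, 0.9)) {
  sites <- as.data.table(sites)
  need <- c("coverage1", "coverage2", "frequency1", "frequency2")
  if (!all(need %in% names(sites)))
    stop("need exactly 2 replicates (columns ", paste(need, collapse = ", "), ")")
  n0 <- sites[coverage1 == 0 & coverage2 == 0, .N]
  out <- sites[coverage1 > 0 | coverage2 > 0]
  d <- out$frequency1 - out$frequency2
  qb <- quantile(d, probs = probs, na.rm = TRUE, type = 7, names = FALSE)
  keep <- is.na(d) | (d >= qb[1] & d <= qb[2])
  n_out <- sum(!keep)
  out <- out[keep]
  out[, frequency := rowMeans(cbind(frequency1, frequency2), na.rm = TRUE)]
  out[, coverage := coverage1 + coverage2]
  data.table::setattr(out, "quantile_bounds", qb)
  data.table::setattr(out, "n_zero_cov", n0)
  data.table::setattr(out, "n_outside_quantiles", n_out)
  out[]
}

#' Join nanopore and WGBS per-site frequencies
#'
#' Inner join on (chrom, pos) — or (chrom, pos, strand) when
#' `by_strand = TRUE` — keeping both frequency columns and any nanopore
#' coverage columns.
#'
#' @param nanopore Per-site nanopore table (`frequency`, optionally `n_used`).
#' @param wgbs Filtered WGBS table (`frequency`).
#' @param by_strand Preserve strand in the join (default FALSE: both inputs
#'   already merged to forward anchors).
#' @return Joined `data.table` with `nanopore_frequency`, `wgbs_frequency`.
#' @export
join_nanopore_wgbs <- function(nanopore, wgbs, by_strand = FALSE) {
  nano <- as.data.table(nanopore)
  wg <- as.data.table(wgbs)
  keys <- if (by_strand) c("chrom", "pos", "strand") else c("chrom", "pos")
  keep_n <- c(keys, intersect(c("n_used", "n_total"), names(nano)), "frequency")
  nano <- nano[, ..keep_n]
  data.table::setnames(nano, "frequency", "nanopore_frequency")
  wg <- wg[, c(keys, "frequency"), with = FALSE]
  data.table::setnames(wg, "frequency", "wgbs_frequency")
  merge(nano, wg, by = keys, all = FALSE)
}

#' Concordance statistics between nanopore and WGBS frequencies
#'
#' Over the joined sites: N, Pearson r, r^2, Spearman rho, RMSE.
#'
#' @param joined Output of [join_nanopore_wgbs()], or `nanopore` and `wgbs`
#'   tables to be joined first.
#' @param wgbs,by_strand See [join_nanopore_wgbs()]; ignored when `joined`
#'   is already a joined table.
#' @return One-row `data.table`: `n`, `pearson_r`, `r_squared`,
#'   `spearman_rho`, `rmse`.
#' @export
compare_to_wgbs <- function(joined, wgbs = NULL, by_strand = FALSE) {
  if (!is.null(wgbs)) joined <- join_nanopore_wgbs(joined, wgbs, by_strand)
  joined <- as.data.table(joined)
  if (nrow(joined) < 2) stop("need >= 2 joined sites for correlations")
  x <- joined$nanopore_frequency; y <- joined$wgbs_frequency
  r <- cor(x, y)
  data.table(n = nrow(joined), pearson_r = r, r_squared = r^2,
             spearman_rho = cor(x, y, method = "spearman"),
             rmse = sqrt(mean((x - y)^2)))
}

#' Bin joined sites by WGBS methylation level
#'
#' Three bins of WGBS frequency: low `[0, 0.3)`, intermediate `[0.3, 0.7)`,
#' high `[0.7, 1]` (half-open below, top bin closed at 1). Returns the
#' per-site bin assignment plus boxplot-style summaries of the nanopore
#' frequency per bin (quartiles, 1.5 IQR whiskers, outlier count).
#'
#' @param joined Output of [join_nanopore_wgbs()].
#' @return List with `sites` (input plus `wgbs_bin` factor) and `summary`.
#' @export
bin_by_wgbs <- function(joined) {
  joined <- copy(as.data.table(joined))
  joined[, wgbs_bin := cut(wgbs_frequency, breaks = c(0, 0.3, 0.7, 1),
                           labels = c("low", "intermediate", "high"),
                           right = FALSE, include.lowest = FALSE)]
  joined[wgbs_frequency == 1, wgbs_bin := "high"]
  summary <- joined[, {
    q <- quantile(nanopore_frequency, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_w <- min(nanopore_frequency[nanopore_frequency >= q[1] - 1.5 * iqr])
    hi_w <- max(nanopore_frequency[nanopore_frequency <= q[3] + 1.5 * iqr])
    .(n = .N, q1 = q[1], median = q[2], q3 = q[3],
      whisker_low = lo_w, whisker_high = hi_w,
      n_outliers = sum(nanopore_frequency < lo_w | nanopore_frequency > hi_w))
  }, by = wgbs_bin][order(wgbs_bin)]
  list(sites = joined[], summary = summary)
}

#' Correlation with WGBS stratified by minimum nanopore coverage
#'
#' Restricts the joined sites to those with nanopore input coverage at or
#' above each threshold and recomputes the Pearson correlation.
#'
#' @param joined Joined table carrying an input-coverage column.
#' @param thresholds Minimum-coverage grid (default 1, 5, 10, 15, 20).
#' @param coverage_col Name of the input-coverage column (default `n_used`).
#' @return `data.table` with `min_cov`, `n`, `pearson_r` (NaN when a stratum
#'   has fewer than 2 sites).
#' @export
correlation_by_min_coverage <- function(joined, thresholds = c(1, 5, 10, 15, 20),
                                        coverage_col = "n_used") {
  joined <- as.data.table(joined)
  stopifnot(coverage_col %in% names(joined))
  cov <- joined[[coverage_col]]
  data.table::rbindlist(lapply(thresholds, function(th) {
    sub <- joined[cov >= th]
    r <- if (nrow(sub) >= 2) cor(sub$nanopore_frequency, sub$wgbs_frequency)
         else NaN
    data.table(min_cov = th, n = nrow(sub), pearson_r = r)
  }))
}

#' Mean reported coverage per minimum input coverage
#'
#' Companion to [correlation_by_min_coverage()]: the mean of the reported
#' coverage column over sites at or above each input-coverage threshold.
#'
#' @param joined Joined table.
#' @param thresholds Minimum-coverage grid.
#' @param input_col,reported_col Input- and reported-coverage column names.
#' @return `data.table` with `min_cov`, `n`, `mean_reported_coverage`.
#' @export
mean_reported_coverage <- function(joined, thresholds = c(1, 5, 10, 15, 20),
                                   input_col = "n_total",
                                   reported_col = "n_used") {
  joined <- as.data.table(joined)
  stopifnot(input_col %in% names(joined), reported_col %in% names(joined))
  cov_in <- joined[[input_col]]; cov_rep <- joined[[reported_col]]
  data.table::rbindlist(lapply(thresholds, function(th) {
    idx <- cov_in >= th
    data.table(min_cov = th, n = sum(idx),
               mean_reported_coverage = if (any(idx)) mean(cov_rep[idx]) else NaN)
  }))
}

#' Subsample per-read calls to fixed coverage levels
#'
#' Only sites with at least `max(levels)` reads participate, so the same
#' sites are present at every level. Per site and level, exactly `level`
#' reads are drawn without replacement (reads sorted by identifier before
#' the seeded shuffle), classified under `rule`, and aggregated.
#'
#' @param calls Standardized per-read call table.
#' @param rule A `cutoff_rule` applied after subsampling.
#' @param levels Coverage levels (default 5, 10, 20, 50).
#' @param seed Seed for the subsampling.
#' @return Named list of per-site tables, one per level.
#' @export
subsample_coverage <- function(calls, rule, levels = c(5, 10, 20, 50), seed = 1) {
  calls <- as.data.table(calls)
  lmax <- max(levels)
  site_n <- calls[, .N, by = .(chrom, pos, strand)]
  ok_sites <- site_n[N >= lmax, .(chrom, pos, strand)]
  if (nrow(ok_sites) == 0)
    stop("no sites with >= ", lmax, " reads; cannot subsample a fixed site set")
  calls <- merge(calls, ok_sites, by = c("chrom", "pos", "strand"))
  data.table::setorder(calls, chrom, pos, strand, read_id)
  out <- withr::with_seed(seed, {
    lapply(levels, function(lv) {
      sub <- calls[, .SD[sample(.N, lv)], by = .(chrom, pos, strand)]
      aggregate_per_site(call_read_states(sub, rule))
    })
  })
  names(out) <- paste0("cov", levels)
  out
}
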