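# Controlled methylation mixtures over singleton-CpG sites and the per-site
# evaluation statistics (correlation, RMSE, outside-window proportions,
# TN/TP ECDF tables).

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (length(genome) > 0 && is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  genome
}

#' Count CG dinucleotides on the forward strand
#'
#' Total number of CG occurrences across all contigs of a genome, the
#' denominator for CpG-site selection.
#'
#' @param genome A FASTA path, character vector, or `DNAStringSet`.
#' @return Integer count.
#' @export
count_forward_cg <- function(genome) {
  genome <- .as_genome(genome)
  sum(Biostrings::vcountPattern("CG", genome))
}

#' Find singleton CpG sites
#'
#' CpG anchors (0-based forward-strand C) whose flanking window contains no
#' other CG: a site is kept iff no other CG starts within `flank` bases on
#' either side, and the anchor lies at least `flank` bases from both contig
#' edges. Optionally filters by minimum read coverage.
#'
#' @param genome A FASTA path, character vector, or `DNAStringSet`.
#' @param flank Window half-width in nt (default 10).
#' @param min_coverage,coverage Optional coverage filter: `coverage` is a
#'   table with `chrom`, `pos`, `coverage`; sites below `min_coverage` are
#'   dropped.
#' @return `data.table` with `chrom`, `pos`, and the `context` sequence
#'   (`flank` nt either side of the CG).
#' @export
find_singleton_cpg_sites <- function(genome, flank = 10, min_coverage = NULL,
                                     coverage = NULL) {
  stopifnot(flank >= 1)
  genome <- .as_genome(genome)
  out <- lapply(seq_along(genome), function(i) {
    seq_i <- genome[[i]]
    len <- length(seq_i)
    starts <- Biostrings::start(Biostrings::matchPattern("CG", seq_i)) - 1L  # 0-based
    if (length(starts) == 0) return(NULL)
    gap_prev <- c(Inf, diff(starts))
    gap_next <- c(diff(starts), Inf)
    keep <- gap_prev > flank & gap_next > flank &
      starts >= flank & (starts + 2L + flank) <= len
    anchors <- starts[keep]
    if (length(anchors) == 0) return(NULL)
    data.table(chrom = names(genome)[i], pos = anchors,
               context = as.character(Biostrings::subseq(
                 rep(Biostrings::DNAStringSet(seq_i), length(anchors)),
                 start = anchors - flank + 1L, end = anchors + flank + 2L)))
  })
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0)
    return(data.table(chrom = character(), pos = integer(), context = character()))
  if (!is.null(min_coverage) && !is.null(coverage)) {
    cov <- as.data.table(coverage)
    out <- merge(out, cov[, .(chrom, pos, coverage)], by = c("chrom", "pos"),
                 all.x = TRUE)
    out <- out[!is.na(coverage) & coverage >= min_coverage]
    out[, coverage := NULL]
  }
  data.table::setkey(out, chrom, pos)
  out[]
}

.round_half_up <- function(x) floor(x + 0.5)

#' Build controlled methylation mixtures
#'
#' For each site and mixture level m, draws `round_half_up(m * n)` reads from
#' the site's methylated pool and the remainder from its unmethylated pool,
#' without replacement, deterministically under `seed` (pools are sorted by
#' read identifier before the seeded shuffle).
#'
#' @param pos_reads,neg_reads Pools of labeled reads: tables with `chrom`,
#'   `pos`, `read_id` (methylated and unmethylated respectively).
#' @param sites Site table with `chrom`, `pos` (e.g. from
#'   [find_singleton_cpg_sites()]).
#' @param levels Mixture levels (default 0, 0.1, ..., 1).
#' @param reads_per_site Reads drawn per site and level (default 24).
#' @param seed Seed for the shuffles.
#' @return A `mixture_dataset`: `data.table` with `level`, `chrom`, `pos`,
#'   `read_id`, `label` (1 = drawn from the methylated pool).
#' @export
build_mixture <- function(pos_reads, neg_reads, sites,
                          levels = seq(0, 1, by = 0.1),
                          reads_per_site = 24, seed = 1) {
  pos_reads <- as.data.table(pos_reads); neg_reads <- as.data.table(neg_reads)
  sites <- as.data.table(sites)
  stopifnot(all(levels >= 0 & levels <= 1), reads_per_site >= 1)
  pos_pools <- split(pos_reads$read_id, paste(pos_reads$chrom, pos_reads$pos))
  neg_pools <- split(neg_reads$read_id, paste(neg_reads$chrom, neg_reads$pos))
  keys <- paste(sites$chrom, sites$pos)

  need_pos <- max(.round_half_up(levels * reads_per_site))
  need_neg <- reads_per_site - min(.round_half_up(levels * reads_per_site))
  short <- vapply(keys, function(k) {
    length(pos_pools[[k]]) < need_pos || length(neg_pools[[k]]) < need_neg
  }, logical(1))
  if (any(short)) {
    stop("insufficient read pools for site(s): ",
         paste(keys[short], collapse = "; "),
         " (need >= ", need_pos, " methylated and >= ", need_neg,
         " unmethylated reads per site)")
  }

  out <- withr::with_seed(seed, {
    data.table::rbindlist(lapply(seq_along(levels), function(li) {
      m <- levels[li]
      n_meth <- .round_half_up(m * reads_per_site)
      n_unmeth <- reads_per_site - n_meth
      data.table::rbindlist(lapply(seq_len(nrow(sites)), function(si) {
        k <- keys[si]
        pp <- sort(pos_pools[[k]]); np <- sort(neg_pools[[k]])
        picked_p <- if (n_meth > 0) sample(pp, n_meth) else character()
        picked_n <- if (n_unmeth > 0) sample(np, n_unmeth) else character()
        data.table(level = m, chrom = sites$chrom[si], pos = sites$pos[si],
                   read_id = c(picked_p, picked_n),
                   label = rep(c(1L, 0L), c(n_meth, n_unmeth)))
      }))
    }))
  })
  data.table::setattr(out, "levels", levels)
  data.table::setattr(out, "reads_per_site", reads_per_site)
  out[]
}

#' Evaluate predicted per-site frequencies against designed mixture levels
#'
#' Pooled over all (site, level) pairs: Pearson r, r^2, Spearman rho, and
#' RMSE between the predicted frequency and the designed level; per level:
#' site count, mean prediction, RMSE, and the outside-window proportion.
#'
#' @param predicted Table with `level` (designed m) and `frequency`
#'   (predicted) columns, one row per site and level.
#' @param half_width Half-width of the per-level agreement window (default
#'   0.05, i.e. the 10% window).
#' @return List with `pooled` (one-row `data.table`: n, pearson_r, r_squared,
#'   spearman_rho, rmse) and `per_level`.
#' @export
evaluate_frequencies <- function(predicted, half_width = 0.05) {
  predicted <- as.data.table(predicted)
  stopifnot(all(c("level", "frequency") %in% names(predicted)))
  predicted <- predicted[!is.na(frequency)]
  if (nrow(predicted) == 0) stop("no predicted sites to evaluate")
  if (length(unique(predicted$level)) < 2)
    stop("need >= 2 distinct mixture levels for correlations")
  f <- predicted$frequency; m <- predicted$level
  r <- if (stats::sd(f) == 0) {
    warning("constant predictions: Pearson correlation undefined (NaN)")
    NaN
  } else cor(f, m)
  rho <- if (is.nan(r)) NaN else cor(f, m, method = "spearman")
  pooled <- data.table(n = length(f), pearson_r = r, r_squared = r^2,
                       spearman_rho = rho, rmse = sqrt(mean((f - m)^2)))
  per_level <- predicted[, .(
    n = .N,
    mean_frequency = mean(frequency),
    rmse = sqrt(mean((frequency - level)^2)),
    outside_proportion = outside_window_proportion(frequency, level[1],
                                                   half_width = half_width)
  ), by = level][order(level)]
  list(pooled = pooled, per_level = per_level)
}

#' Proportion of sites predicted outside the agreement window
#'
#' The window around a designed level m is `[max(0, m - h), min(1, m + h)]`,
#' boundaries inclusive; for the fully unmethylated and fully methylated sets
#' this clips to `[0, h]` and `[1 - h, 1]`.
#'
#' @param frequencies Predicted per-site frequencies at one level.
#' @param m Designed methylation level in `[0, 1]`.
#' @param half_width Window half-width (default 0.05).
#' @return Proportion outside the window.
#' @export
outside_window_proportion <- function(frequencies, m, half_width = 0.05) {
  stopifnot(m >= 0, m <= 1)
  lo <- max(0, m - half_width); hi <- min(1, m + half_width)
  mean(frequencies < lo | frequencies > hi)
}

#' True-negative / true-positive counts across frequency thresholds
#'
#' From a fully unmethylated (`direction = "tn"`) or fully methylated
#' (`direction = "tp"`) site set: the number of sites called correctly at
#' each threshold f on a grid of the observed frequencies plus 0 to 1 in
#' steps of 0.05. TN counts sites with frequency < f (non-decreasing in f);
#' TP counts sites with frequency > f (non-increasing).
#'
#' @param frequencies Predicted per-site frequencies.
#' @param direction `"tn"` or `"tp"`.
#' @return `data.table` with `threshold` and `count`.
#' @export
tn_tp_ecdf <- function(frequencies, direction = c("tn", "tp")) {
  direction <- match.arg(direction)
  grid <- sort(unique(c(frequencies, seq(0, 1, by = 0.05))))
  count <- if (direction == "tn") {
    vapply(grid, function(f) sum(frequencies < f), numeric(1))
  } else {
    vapply(grid, function(f) sum(frequencies > f), numeric(1))
  }
  data.table(threshold = grid, count = as.integer(count))
}
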