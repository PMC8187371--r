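# 8-mer sequence-context bias: per-site nanopore-vs-WGBS discrepancy in an
# NNNCGNNN context, GC-content grouping, and residue enrichment between
# low- and high-discrepancy k-mer sets.

.VAR_POSITIONS <- c(1L, 2L, 3L, 6L, 7L, 8L)  # positions 4-5 are the fixed CG

#' Extract the 8-mer context around CpG anchors
#'
#' 3 nt upstream + CG + 3 nt downstream on the forward strand. Anchors too
#' close to a contig edge yield `NA` and are counted in the `n_skipped`
#' attribute; contexts whose positions 4-5 are not CG (reference mismatch)
#' are also set to `NA` and counted.
#'
#' @param genome A FASTA path, character vector, or `DNAStringSet`.
#' @param chrom,pos Site anchors (0-based forward-strand C).
#' @return Character vector of 8-mers (with `NA` for skipped sites).
#' @export
extract_kmer_context <- function(genome, chrom, pos) {
  genome <- .as_genome(genome)
  stopifnot(length(chrom) == length(pos))
  lens <- setNames(Biostrings::width(genome), names(genome))
  out <- rep(NA_character_, length(pos))
  n_skipped <- 0L
  for (cm in unique(chrom)) {
    idx <- which(chrom == cm)
    p <- pos[idx]
    ok <- p >= 3 & (p + 5) <= (lens[[cm]] - 1)
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok)) {
      seq_cm <- genome[[cm]]
      km <- as.character(Biostrings::subseq(
        rep(Biostrings::DNAStringSet(seq_cm), sum(ok)),
        start = p[ok] - 3 + 1, width = 8))
      bad <- substr(km, 4, 5) != "CG"
      if (any(bad)) {
        warning(sum(bad), " anchors without CG at positions 4-5 skipped")
        n_skipped <- n_skipped + sum(bad)
        km[bad] <- NA_character_
      }
      out[idx[ok]] <- km
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Absolute nanopore-vs-WGBS discrepancy per site
#'
#' @param nanopore_frequency,wgbs_frequency Frequencies in `[0, 1]`.
#' @return `|nanopore - wgbs|`, in `[0, 1]`.
#' @export
site_discrepancy <- function(nanopore_frequency, wgbs_frequency) {
  abs(nanopore_frequency - wgbs_frequency)
}

#' Per-site and per-k-mer discrepancy records
#'
#' Extracts the 8-mer of every joined site, computes the per-site absolute
#' discrepancy, and aggregates to distinct k-mers by the mean discrepancy
#' across sites; both levels are returned. GC fraction is computed over the
#' 6 variable positions (the invariant CG is excluded).
#'
#' @param joined Output of [join_nanopore_wgbs()].
#' @param genome Genome for context extraction.
#' @return List with `sites` (per-site kmer + discrepancy) and `kmers`
#'   (distinct 8-mers: `kmer`, `mean_discrepancy`, `n_sites`, `gc_fraction`).
#' @export
kmer_discrepancy <- function(joined, genome) {
  joined <- copy(as.data.table(joined))
  joined[, kmer := extract_kmer_context(genome, chrom, pos)]
  joined[, discrepancy := site_discrepancy(nanopore_frequency, wgbs_frequency)]
  sites <- joined[!is.na(kmer)]
  kmers <- sites[, .(mean_discrepancy = mean(discrepancy), n_sites = .N),
                 by = kmer]
  kmers[, gc_fraction := kmer_gc_fraction(kmer)]
  list(sites = sites[], kmers = kmers[])
}

#' GC fraction of an 8-mer over its variable positions
#'
#' The invariant CG at positions 4-5 is excluded; the fraction is over the
#' 6 flanking residues, so it takes values 0, 1/6, ..., 1.
#'
#' @param kmer Character vector of 8-mers.
#' @return Numeric GC fractions.
#' @export
kmer_gc_fraction <- function(kmer) {
  vapply(kmer, function(k) {
    res <- strsplit(k, "")[[1]][.VAR_POSITIONS]
    mean(res %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Label k-mers by discrepancy
#'
#' `low` iff the (mean) discrepancy is exactly 0, `high` iff it exceeds 0.5,
#' otherwise `unlabeled` — a partition of the records.
#'
#' @param records Table with a `mean_discrepancy` (or `discrepancy`) column.
#' @return The table with a `label` column appended.
#' @export
label_kmers <- function(records) {
  records <- copy(as.data.table(records))
  col <- if ("mean_discrepancy" %in% names(records)) "mean_discrepancy"
         else "discrepancy"
  d <- records[[col]]
  records[, label := fifelse(d == 0, "low", fifelse(d > 0.5, "high", "unlabeled"))]
  records[]
}

#' Discrepancy summaries grouped by GC content
#'
#' Bins k-mer records by the GC fraction of the 6 variable positions
#' (levels 0, 1/6, ..., 1) and summarises the discrepancy per bin.
#'
#' @param records Output `kmers` table of [kmer_discrepancy()].
#' @return `data.table` with per-bin `n`, mean and quartiles of the
#'   discrepancy.
#' @export
gc_content_groups <- function(records) {
  records <- copy(as.data.table(records))
  if (!"gc_fraction" %in% names(records))
    records[, gc_fraction := kmer_gc_fraction(kmer)]
  col <- if ("mean_discrepancy" %in% names(records)) "mean_discrepancy"
         else "discrepancy"
  records[, gc_bin := factor(round(gc_fraction * 6) / 6,
                             levels = (0:6) / 6)]
  records[, .(
    n = .N,
    mean = mean(get(col)),
    q1 = quantile(get(col), 0.25, names = FALSE),
    median = quantile(get(col), 0.5, names = FALSE),
    q3 = quantile(get(col), 0.75, names = FALSE)
  ), by = gc_bin][order(gc_bin)]
}

#' Residue enrichment between foreground and background k-mer sets
#'
#' For each of the 6 variable positions and each residue A/C/G/T: the
#' foreground count, the expected count under the background residue
#' frequency at that position, a Haldane-corrected log-odds ratio, and a
#' two-sided binomial p-value, Bonferroni-adjusted across the 24 tests.
#' This is a transparent substitute statistic for external motif-logo
#' significance tools.
#'
#' @param foreground,background Non-empty character vectors of 8-mers.
#' @return `data.table` with `position`, `residue`, `fg_count`, `expected`,
#'   `log_odds`, `p_value`, `p_adjusted`.
#' @export
position_residue_enrichment <- function(foreground, background) {
  if (length(foreground) == 0 || length(background) == 0)
    stop("foreground and background k-mer sets must both be non-empty")
  residues <- c("A", "C", "G", "T")
  n_fg <- length(foreground); n_bg <- length(background)
  out <- data.table::rbindlist(lapply(.VAR_POSITIONS, function(p) {
    fg_res <- substr(foreground, p, p)
    bg_res <- substr(background, p, p)
    data.table::rbindlist(lapply(residues, function(r) {
      k_fg <- sum(fg_res == r)
      k_bg <- sum(bg_res == r)
      p_bg <- k_bg / n_bg
      pv <- if (p_bg <= 0) {
        if (k_fg == 0) 1 else 0
      } else if (p_bg >= 1) {
        if (k_fg == n_fg) 1 else 0
      } else binom.test(k_fg, n_fg, p = p_bg,
                        alternative = "two.sided")$p.value
      lo <- log(((k_fg + 0.5) / (n_fg - k_fg + 0.5)) /
                  ((k_bg + 0.5) / (n_bg - k_bg + 0.5)))
      data.table(position = p, residue = r, fg_count = k_fg,
                 expected = n_fg * p_bg, log_odds = lo, p_value = pv)
    }))
  }))
  out[, p_adjusted := pmin(p_value * .N, 1)]
  out[]
}
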