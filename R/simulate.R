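# Synthetic-data generator: genomes with regularly spaced singleton CpGs,
# per-tool per-read score tables with controlled separability, cross-tool
# correlation and missingness, and binomially sampled WGBS replicates.
# The test bed for every other module.

#' Score-distribution profile of a synthetic caller
#'
#' Two Gaussian score components, one per true read state, the minimal model
#' for the unimodal per-class score distributions of real callers.
#' `mu_meth`/`mu_unmeth` set the separability; `w` weights a latent noise
#' factor shared across tools (w = 0: independent tools, w = 1: perfectly
#' correlated noise); `missingness` is the probability that the tool fails
#' to score a read at a site.
#'
#' @param tool Tool name used in the emitted tables.
#' @param mu_meth,sd_meth Methylated-component mean and sd.
#' @param mu_unmeth,sd_unmeth Unmethylated-component mean and sd.
#' @param missingness Per-read drop probability in `[0, 1)`.
#' @param w Shared-noise weight in `[0, 1]`.
#' @return A `tool_profile` list.
#' @export
tool_profile <- function(tool, mu_meth = 2, sd_meth = 1,
                         mu_unmeth = -2, sd_unmeth = 1,
                         missingness = 0, w = 0) {
  stopifnot(sd_meth >= 0, sd_unmeth >= 0,
            missingness >= 0, missingness < 1, w >= 0, w <= 1)
  structure(list(tool = tool, mu_meth = mu_meth, sd_meth = sd_meth,
                 mu_unmeth = mu_unmeth, sd_unmeth = sd_unmeth,
                 missingness = missingness, w = w),
            class = "tool_profile")
}

#' Simulate a genome with regularly spaced singleton CpGs
#'
#' Background sequence is sampled with accidental CG dinucleotides
#' suppressed, then CG anchors are planted every `cpg_spacing` bases, so the
#' emitted site list coincides with [find_singleton_cpg_sites()] run on the
#' emitted genome (at flank < spacing). Deterministic under `seed`.
#'
#' @param n_contigs Number of contigs.
#' @param length Contig length in bases.
#' @param cpg_spacing Distance between planted CG anchors; must be at least
#'   `2 * flank + 2`.
#' @param seed Seed.
#' @param flank Flank used for the edge rule (default 10).
#' @return List with `genome` (`DNAStringSet`) and `sites` (`chrom`, `pos`).
#' @export
simulate_genome <- function(n_contigs = 1, length = 3000, cpg_spacing = 30,
                            seed = 1, flank = 10) {
  if (cpg_spacing < 2 * flank + 2)
    stop("cpg_spacing must be >= 2 * flank + 2 = ", 2 * flank + 2)
  letters4 <- c("A", "C", "G", "T")
  sim <- withr::with_seed(seed, {
    lapply(seq_len(n_contigs), function(ci) {
      s <- sample(letters4, length, replace = TRUE)
      # suppress accidental CG: resample any G following a C
      for (pass in 1:5) {
        bad <- which(s[-length] == "C" & s[-1] == "G") + 1L
        if (!length(bad)) break
        s[bad] <- sample(c("A", "C", "T"), length(bad), replace = TRUE)
      }
      anchors <- seq(flank, length - flank - 2L, by = cpg_spacing)
      s[anchors + 1L] <- "C"   # anchors are 0-based
      s[anchors + 2L] <- "G"
      list(seq = paste(s, collapse = ""), anchors = as.integer(anchors))
    })
  })
  genome <- Biostrings::DNAStringSet(vapply(sim, `[[`, character(1), "seq"))
  names(genome) <- paste0("contig", seq_len(n_contigs))
  sites <- data.table::rbindlist(lapply(seq_len(n_contigs), function(ci)
    data.table(chrom = names(genome)[ci], pos = sim[[ci]]$anchors)))
  list(genome = genome, sites = sites)
}

#' Simulate per-tool per-read scores with known truth
#'
#' Per read: true label ~ Bernoulli(m of its site); a shared latent noise
#' z ~ N(0, 1); each tool's score is
#' `mu_label + sd_label * (w * z + sqrt(1 - w^2) * eps_tool)` with
#' independent `eps_tool ~ N(0, 1)`, then the tool's rows are dropped
#' independently with its missingness probability. Deterministic under
#' `seed`.
#'
#' @param sites Table with `chrom`, `pos`.
#' @param coverage Reads per site (>= 1).
#' @param m Per-site true methylation level, scalar or vector along `sites`.
#' @param profiles List of [tool_profile()]s.
#' @param seed Seed.
#' @return List with `calls` (named list of standardized per-read tables,
#'   each carrying the true `label`) and `truth` (per-read labels).
#' @export
simulate_read_scores <- function(sites, coverage, m, profiles, seed = 1) {
  sites <- as.data.table(sites)
  stopifnot(coverage >= 1, length(profiles) >= 1)
  if (!all(vapply(profiles, inherits, logical(1), "tool_profile")))
    stop("profiles must be a list of tool_profile objects")
  m <- rep_len(m, nrow(sites))
  stopifnot(all(m >= 0 & m <= 1))
  n_sites <- nrow(sites)
  n_reads <- n_sites * coverage
  site_idx <- rep(seq_len(n_sites), each = coverage)
  withr::with_seed(seed, {
    labels <- rbinom(n_reads, 1L, m[site_idx])
    z <- rnorm(n_reads)
    truth <- data.table(
      read_id = sprintf("%s_%d_r%05d", sites$chrom[site_idx],
                        sites$pos[site_idx], rep(seq_len(coverage), n_sites)),
      chrom = sites$chrom[site_idx],
      pos = sites$pos[site_idx],
      strand = "+",
      label = labels,
      m = m[site_idx]
    )
    calls <- lapply(profiles, function(pf) {
      eps <- rnorm(n_reads)
      mu <- ifelse(labels == 1, pf$mu_meth, pf$mu_unmeth)
      sdv <- ifelse(labels == 1, pf$sd_meth, pf$sd_unmeth)
      score <- mu + sdv * (pf$w * z + sqrt(1 - pf$w^2) * eps)
      keep <- runif(n_reads) >= pf$missingness
      data.table(read_id = truth$read_id[keep], chrom = truth$chrom[keep],
                 pos = truth$pos[keep], strand = "+",
                 score = score[keep], tool = pf$tool,
                 label = labels[keep])
    })
    names(calls) <- vapply(profiles, `[[`, character(1), "tool")
    list(calls = calls, truth = truth)
  })
}

#' Simulate WGBS replicates at known methylation levels
#'
#' Per replicate and site: methylated counts ~ Binomial(coverage, m);
#' frequency = counts / coverage. Deterministic under `seed`.
#'
#' @param sites Table with `chrom`, `pos`.
#' @param m Per-site methylation, scalar or vector along `sites`.
#' @param coverage Reads per site per replicate.
#' @param n_replicates Number of replicates (default 2).
#' @param seed Seed.
#' @return Named list of per-site tables (`chrom`, `pos`, `strand`,
#'   `coverage`, `frequency`).
#' @export
simulate_wgbs <- function(sites, m, coverage, n_replicates = 2, seed = 1) {
  sites <- as.data.table(sites)
  m <- rep_len(m, nrow(sites))
  stopifnot(all(m >= 0 & m <= 1), coverage >= 1, n_replicates >= 1)
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(r) {
      k <- rbinom(nrow(sites), coverage, m)
      data.table(chrom = sites$chrom, pos = sites$pos, strand = "+",
                 coverage = as.integer(coverage), frequency = k / coverage)
    })
    names(out) <- paste0("rep", seq_len(n_replicates))
    out
  })
}
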