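# Cutoff rules on standardized per-read scores, per-site aggregation into
# methylation frequencies, and strand merging onto the forward CpG anchor.

#' Cutoff rules for classifying per-read scores
#'
#' Three kinds of rule over standardized scores (higher = more likely
#' methylated):
#' * `single_cutoff(t)`: methylated iff `score >= t`, otherwise unmethylated;
#'   no reads are discarded.
#' * `double_cutoff(t_low, t_high, boundary)`: methylated iff
#'   `score >= t_high`, unmethylated iff `score <= t_low`, reads in between
#'   are discarded. With `boundary = "discard"` the band is closed
#'   (`t_low <= score <= t_high` is discarded), used by
#'   [central_band_cutoffs()] so that exactly the selected reads are removed.
#' * `prob_pair_cutoff(p)`: the Megalodon default; methylated iff
#'   `P(mod) >= p`, unmethylated iff `P(can) >= p`, otherwise discarded
#'   (requires `p_mod`/`p_can` columns).
#'
#' @param t,t_low,t_high Thresholds on the standardized score scale
#'   (`t_low <= t_high`).
#' @param boundary `"decide"` (default: boundary scores are classified) or
#'   `"discard"` (boundary scores fall in the discard band).
#' @param p Minimum probability for either the modified or canonical call.
#' @return A `cutoff_rule` object.
#' @export
single_cutoff <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1, is.finite(t))
  structure(list(kind = "single", t = t), class = "cutoff_rule")
}

#' @rdname single_cutoff
#' @export
double_cutoff <- function(t_low, t_high, boundary = c("decide", "discard")) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(t_low), is.numeric(t_high), t_low <= t_high)
  structure(list(kind = "double", t_low = t_low, t_high = t_high,
                 boundary = boundary), class = "cutoff_rule")
}

#' @rdname single_cutoff
#' @export
prob_pair_cutoff <- function(p = 0.75) {
  stopifnot(p > 0.5, p <= 1)
  structure(list(kind = "prob_pair", p = p), class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  msg <- switch(x$kind,
    single = sprintf("single cutoff: meth iff score >= %g", x$t),
    double = sprintf("double cutoff: meth iff score >= %g, unmeth iff score <= %g (%s boundaries)",
                     x$t_high, x$t_low, x$boundary),
    prob_pair = sprintf("probability pair: meth iff P(mod) >= %g, unmeth iff P(can) >= %g",
                        x$p, x$p))
  cat(msg, "\n")
  invisible(x)
}

#' Default cutoff rule of a caller, on the standardized score scale
#'
#' Nanopolish: decide at |LLR| >= 2.5, discard in between. Tombo (native:
#' below -1.5 methylated, above 2.5 unmethylated) becomes, after the
#' orientation flip, the double rule (-2.5, +1.5). DeepSignal: methylated iff
#' P(m) >= P(u), i.e. a single cutoff at 0 on the log2 ratio. Guppy: single
#' cutoff at 0 on the log-likelihood ratio. Megalodon: the 0.75 minimum
#' probability for both the modified and canonical call.
#'
#' @param tool Dialect name.
#' @return A `cutoff_rule`.
#' @export
default_cutoff_rule <- function(tool) {
  tool <- match.arg(tool, list_dialects())
  switch(tool,
    nanopolish = double_cutoff(-2.5, 2.5),
    tombo = double_cutoff(-2.5, 1.5),
    deepsignal = single_cutoff(0),
    guppy = single_cutoff(0),
    megalodon = prob_pair_cutoff(0.75))
}

#' Classify per-read calls under a cutoff rule
#'
#' Adds a `state` column in `{meth, unmeth, discard}`. `NA`/`NaN` scores are
#' discarded with a warning giving the count.
#'
#' @param calls Standardized per-read call table.
#' @param rule A `cutoff_rule`.
#' @return The table with a `state` column appended.
#' @export
call_read_states <- function(calls, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  calls <- copy(as.data.table(calls))
  s <- calls$score
  state <- rep("discard", length(s))
  valid <- !is.na(s) & is.finite(s)
  if (rule$kind == "single") {
    state[valid] <- ifelse(s[valid] >= rule$t, "meth", "unmeth")
  } else if (rule$kind == "double") {
    if (identical(rule$boundary, "discard")) {
      state[valid & s > rule$t_high] <- "meth"
      state[valid & s < rule$t_low] <- "unmeth"
    } else {
      state[valid & s >= rule$t_high] <- "meth"
      state[valid & s <= rule$t_low] <- "unmeth"
    }
  } else if (rule$kind == "prob_pair") {
    if (!all(c("p_mod", "p_can") %in% names(calls)))
      stop("probability-pair rule needs p_mod/p_can columns (megalodon dialect)")
    pm <- calls$p_mod; pc <- calls$p_can
    valid <- valid & !is.na(pm) & !is.na(pc)
    state <- rep("discard", length(s))
    state[valid & pm >= rule$p] <- "meth"
    state[valid & pc >= rule$p] <- "unmeth"
  }
  n_bad <- sum(is.na(s) | !is.finite(s))
  if (n_bad > 0) warning(n_bad, " calls with missing scores discarded")
  calls[, state := state]
  calls[]
}

#' Aggregate labeled per-read calls into per-site methylation
#'
#' Per (chrom, pos, strand): `n_total` = all covering reads, `n_used` =
#' decided (meth + unmeth) reads, `n_meth` = methylated reads, `frequency` =
#' `n_meth / n_used`. Sites where every read was discarded are omitted and
#' counted in the `n_sites_dropped` attribute.
#'
#' @param labeled Output of [call_read_states()].
#' @return Per-site `data.table` with columns `chrom`, `pos`, `strand`,
#'   `n_total`, `n_used`, `n_meth`, `frequency`.
#' @export
aggregate_per_site <- function(labeled) {
  labeled <- as.data.table(labeled)
  if (nrow(labeled) == 0) {
    out <- data.table(chrom = character(), pos = integer(), strand = character(),
                      n_total = integer(), n_used = integer(), n_meth = integer(),
                      frequency = numeric())
    data.table::setattr(out, "n_sites_dropped", 0L)
    return(out)
  }
  stopifnot("state" %in% names(labeled))
  out <- labeled[, .(
    n_total = .N,
    n_used = sum(state != "discard"),
    n_meth = sum(state == "meth")
  ), by = .(chrom, pos, strand)]
  dropped <- out$n_used == 0L
  n_dropped <- sum(dropped)
  if (n_dropped > 0)
    message(n_dropped, " sites dropped (all reads discarded)")
  out <- out[!dropped]
  out[, frequency := n_meth / n_used]
  data.table::setkey(out, chrom, pos, strand)
  data.table::setattr(out, "n_sites_dropped", n_dropped)
  out[]
}

#' Merge per-site methylation from both strands onto the forward anchor
#'
#' Positions must already be lifted to forward-strand C anchors. Sites with
#' predictions on both strands get the unweighted mean of the two frequencies
#' and summed read counts; single-strand sites keep their frequency
#' unchanged. Output strand is `"both"`.
#'
#' @param sites Per-site table from [aggregate_per_site()].
#' @return Merged per-site `data.table` (strand = `"both"`).
#' @export
merge_strands <- function(sites) {
  sites <- as.data.table(sites)
  if (anyDuplicated(sites, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) rows; merge input must be unique per strand")
  out <- sites[, .(
    n_total = sum(n_total),
    n_used = sum(n_used),
    n_meth = sum(n_meth),
    frequency = mean(frequency),
    n_strands = .N
  ), by = .(chrom, pos)]
  out[, strand := "both"]
  data.table::setcolorder(out, c("chrom", "pos", "strand"))
  data.table::setkey(out, chrom, pos)
  out[]
}
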