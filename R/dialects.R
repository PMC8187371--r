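# Per-read call ingestion: one reader per caller dialect, all converging on a
# standardized table with a uniform score orientation (higher = more likely
# methylated) and 0-based forward-strand C anchors.

#' @import data.table
#' @importFrom stats quantile cor binom.test p.adjust rbinom rnorm runif median sd setNames predict
#' @importFrom utils head tail
#' @importFrom methods is
NULL

utils::globalVariables(c(
  ".", "..keep", "..keep_n", "..tools", "chrom", "pos", "strand", "score",
  "state", "n_total", "n_used", "n_meth", "frequency", "n_strands", "label",
  "consensus_score", "consensus_state", "level", "read_id", "coverage",
  "coverage1", "coverage2", "frequency1", "frequency2", "wgbs_frequency",
  "nanopore_frequency", "wgbs_bin", "kmer", "discrepancy", "mean_discrepancy",
  "gc_fraction", "gc_bin", "p_value", "p_adjusted", "N", "tool"
))

# clamp applied to probabilities before log ratios
.PROB_EPS <- 1e-12

.DIALECTS <- list(
  nanopolish = list(
    tool = "nanopolish",
    columns = c(chrom = "chromosome", strand = "strand", pos = "start",
                read_id = "read_name", score = "log_lik_ratio",
                n_cpgs = "num_motifs", sequence = "sequence"),
    orientation = +1L, one_based = FALSE, lift_minus = FALSE, grouped = TRUE,
    # native log-likelihood ratio; |LLR| > 2.5 decides, in between is discarded
    default_rule_native = c(t_low = -2.5, t_high = 2.5)
  ),
  guppy = list(
    tool = "guppy",
    # reference-anchored text converted upstream from the modified basecalls
    columns = c(read_id = "read_id", chrom = "chrom", pos = "pos",
                strand = "strand", score = "log_lik_ratio"),
    orientation = +1L, one_based = FALSE, lift_minus = TRUE, grouped = FALSE,
    default_rule_native = c(t = 0)
  ),
  tombo = list(
    tool = "tombo",
    # wiggle-derived TSV; native statistic is positive for canonical bases,
    # negative for modified ones, and wiggle coordinates are 1-based
    columns = c(read_id = "read_id", chrom = "chrom", pos = "pos",
                strand = "strand", score = "score"),
    orientation = -1L, one_based = TRUE, lift_minus = TRUE, grouped = FALSE,
    # native: below -1.5 methylated, above 2.5 unmethylated
    default_rule_native = c(meth_below = -1.5, unmeth_above = 2.5)
  ),
  deepsignal = list(
    tool = "deepsignal",
    columns = c(chrom = "chrom", pos = "pos", strand = "strand",
                read_id = "read_id", p_meth = "prob_meth",
                p_unmeth = "prob_unmeth"),
    orientation = +1L, one_based = FALSE, lift_minus = TRUE, grouped = FALSE,
    default_rule_native = c(t = 0)       # P(m) > P(u) <=> log2 ratio >= 0
  ),
  megalodon = list(
    tool = "megalodon",
    columns = c(read_id = "read_id", chrom = "chrom", strand = "strand",
                pos = "pos", mod_log_prob = "mod_log_prob",
                can_log_prob = "can_log_prob"),
    orientation = +1L, one_based = FALSE, lift_minus = TRUE, grouped = FALSE,
    default_rule_native = c(p = 0.75)    # minimum probability for either call
  )
)

#' Dialect specification for a methylation caller
#'
#' Returns the column mapping, score definition, coordinate convention and
#' default cutoff of one supported per-read dialect. Column names can be
#' overridden to absorb layout drift across tool versions.
#'
#' @param tool One of `"nanopolish"`, `"guppy"`, `"tombo"`, `"deepsignal"`,
#'   `"megalodon"`.
#' @param columns Optional named character vector overriding entries of the
#'   default column mapping (names are standardized fields, values are the
#'   column names found in the file).
#' @return A `dialect_spec` list.
#' @export
dialect_spec <- function(tool, columns = NULL) {
  tool <- match.arg(tool, names(.DIALECTS))
  spec <- .DIALECTS[[tool]]
  if (!is.null(columns)) {
    stopifnot(is.character(columns), !is.null(names(columns)))
    bad <- setdiff(names(columns), names(spec$columns))
    if (length(bad)) stop("unknown dialect fields: ", paste(bad, collapse = ", "))
    spec$columns[names(columns)] <- columns
  }
  structure(spec, class = "dialect_spec")
}

#' List supported per-read dialects
#' @return Character vector of dialect names.
#' @export
list_dialects <- function() names(.DIALECTS)

.clamp_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

.empty_calls <- function() {
  data.table(read_id = character(), chrom = character(), pos = integer(),
             strand = character(), score = numeric(), tool = character())
}

#' Read per-read CpG calls in a caller's native dialect
#'
#' Parses a tab-separated per-read call file and standardizes it: scores are
#' re-oriented so that higher means more likely methylated (Tombo statistics
#' are negated, DeepSignal probabilities become `log2(P(m)/P(u))`, Megalodon
#' log probabilities become `log(M) - log(C)`, Nanopolish/Guppy log-likelihood
#' ratios are kept), coordinates become 0-based forward-strand C anchors
#' (minus-strand coordinates are lifted by subtracting 1 where the dialect
#' reports the reverse-strand C), and Nanopolish CpG groups are split into
#' their constituent sites.
#'
#' Rows with non-numeric scores or invalid coordinates are rejected and
#' counted in the `n_rejected` attribute; DeepSignal probabilities are clamped
#' to `[1e-12, 1 - 1e-12]` before the log ratio, with the number of clamped
#' rows in the `n_clamped` attribute.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param dialect A dialect name or a [dialect_spec()].
#' @return A `data.table` with columns `read_id`, `chrom`, `pos`, `strand`,
#'   `score`, `tool` (Megalodon rows additionally carry `p_mod` and `p_can`).
#' @export
read_calls <- function(path, dialect) {
  if (is.character(dialect)) dialect <- dialect_spec(dialect)
  stopifnot(inherits(dialect, "dialect_spec"))
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = unname(dialect$columns[
                             intersect(c("read_id", "chrom", "strand", "sequence"),
                                       names(dialect$columns))])))
  missing_cols <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_cols))
    stop("file does not match the '", dialect$tool, "' dialect; missing columns: ",
         paste(missing_cols, collapse = ", "))
  standardize_calls(raw, dialect)
}

#' Standardize an already-loaded native table
#'
#' Same contract as [read_calls()] but starting from an in-memory data frame.
#' @param raw A data.frame/data.table in the dialect's native layout.
#' @param dialect A dialect name or a [dialect_spec()].
#' @return Standardized `data.table` of per-read calls.
#' @export
standardize_calls <- function(raw, dialect) {
  if (is.character(dialect)) dialect <- dialect_spec(dialect)
  raw <- as.data.table(raw)
  cmap <- dialect$columns
  get <- function(field) raw[[cmap[[field]]]]
  n_in <- nrow(raw)
  n_clamped <- 0L

  if (isTRUE(dialect$grouped)) {
    out <- split_cpg_groups(raw, dialect)
    n_rejected <- attr(out, "n_rejected")
  } else {
    pos <- suppressWarnings(as.integer(get("pos")))
    strand <- as.character(get("strand"))
    if (dialect$tool == "deepsignal") {
      pm <- suppressWarnings(as.numeric(get("p_meth")))
      pu <- suppressWarnings(as.numeric(get("p_unmeth")))
      n_clamped <- sum((pm < .PROB_EPS | pm > 1 - .PROB_EPS |
                          pu < .PROB_EPS | pu > 1 - .PROB_EPS) &
                         !is.na(pm) & !is.na(pu))
      score <- log2(.clamp_prob(pm) / .clamp_prob(pu))
    } else if (dialect$tool == "megalodon") {
      lm_ <- suppressWarnings(as.numeric(get("mod_log_prob")))
      lc_ <- suppressWarnings(as.numeric(get("can_log_prob")))
      score <- lm_ - lc_
    } else {
      score <- dialect$orientation * suppressWarnings(as.numeric(get("score")))
    }
    ok <- is.finite(score) & !is.na(pos) & pos >= 0 & strand %in% c("+", "-")
    n_rejected <- sum(!ok)
    out <- data.table(read_id = as.character(get("read_id"))[ok],
                      chrom = as.character(get("chrom"))[ok],
                      pos = pos[ok], strand = strand[ok], score = score[ok],
                      tool = dialect$tool)
    if (dialect$tool == "megalodon") {
      out[, `:=`(p_mod = exp(lm_[ok]), p_can = exp(lc_[ok]))]
    }
    if (isTRUE(dialect$one_based)) out[, pos := pos - 1L]
    if (isTRUE(dialect$lift_minus)) out[strand == "-", pos := pos - 1L]
    bad_pos <- out$pos < 0
    if (any(bad_pos)) {
      n_rejected <- n_rejected + sum(bad_pos)
      out <- out[!bad_pos]
    }
  }
  if (n_rejected > 0)
    message(dialect$tool, ": rejected ", n_rejected, " of ", n_in, " rows")
  if (n_clamped > 0)
    message(dialect$tool, ": clamped probabilities on ", n_clamped, " rows")
  if (anyDuplicated(out, by = c("read_id", "chrom", "pos", "strand", "tool")))
    stop("duplicate (read_id, chrom, pos, strand, tool) rows after standardization")
  data.table::setattr(out, "n_rejected", n_rejected)
  data.table::setattr(out, "n_clamped", n_clamped)
  out[]
}

#' Split Nanopolish CpG groups into constituent sites
#'
#' Nanopolish reports nearby CpG sites as one group sharing a log-likelihood
#' ratio. Each group is split into one row per constituent CpG, located by
#' scanning the group's sequence context for CG occurrences; every constituent
#' inherits the group's score. Rows whose declared CpG count disagrees with
#' the number of CG occurrences found in the context are rejected and counted.
#'
#' @param raw Native Nanopolish rows (data.frame/data.table).
#' @param dialect A `dialect_spec` with `grouped = TRUE` (default: nanopolish).
#' @return Standardized `data.table` of per-read calls with attribute
#'   `n_rejected`.
#' @export
split_cpg_groups <- function(raw, dialect = dialect_spec("nanopolish")) {
  if (is.character(dialect)) dialect <- dialect_spec(dialect)
  raw <- as.data.table(raw)
  cmap <- dialect$columns
  chrom <- as.character(raw[[cmap[["chrom"]]]])
  strand <- as.character(raw[[cmap[["strand"]]]])
  start <- suppressWarnings(as.integer(raw[[cmap[["pos"]]]]))
  read_id <- as.character(raw[[cmap[["read_id"]]]])
  score <- suppressWarnings(as.numeric(raw[[cmap[["score"]]]]))
  n_cpgs <- suppressWarnings(as.integer(raw[[cmap[["n_cpgs"]]]]))
  seqs <- as.character(raw[[cmap[["sequence"]]]])

  offs <- lapply(seqs, function(s) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m) - 1L
  })
  found <- lengths(offs)
  ok <- is.finite(score) & !is.na(start) & start >= 0 &
    strand %in% c("+", "-") & !is.na(n_cpgs) & found == n_cpgs & found > 0L
  n_rejected <- sum(!ok)

  idx <- which(ok)
  rep_idx <- rep(idx, found[idx])
  rel <- unlist(lapply(idx, function(i) offs[[i]] - offs[[i]][1]), use.names = FALSE)
  out <- data.table(read_id = read_id[rep_idx], chrom = chrom[rep_idx],
                    pos = start[rep_idx] + rel, strand = strand[rep_idx],
                    score = score[rep_idx], tool = dialect$tool)
  if (isTRUE(dialect$one_based)) out[, pos := pos - 1L]
  if (isTRUE(dialect$lift_minus)) out[strand == "-", pos := pos - 1L]
  data.table::setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Write and read the standardized per-read table
#'
#' Plain tab-separated text; `read_standard_tsv(write_standard_tsv(x))` is the
#' identity on all fields.
#'
#' @param calls Standardized per-read call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standard_tsv <- function(calls, path) {
  data.table::fwrite(as.data.table(calls), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_standard_tsv
#' @export
read_standard_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("read_id", "chrom",
                                                           "strand", "tool")))
  if (nrow(out) == 0 && ncol(out) == 0) out <- .empty_calls()
  out[]
}

#' Write and read per-site methylation in bedMethyl (BED9+2)
#'
#' Columns: chrom, start (0-based), end = start + 1, name, score =
#' min(coverage, 1000), strand, thickStart, thickEnd, color, coverage,
#' methylation percentage (integer 0-100). The `both`-strand label maps to
#' `"."` on write and back on read.
#'
#' @param sites Per-site methylation table (see [aggregate_per_site()]).
#' @param path File path.
#' @return `path` invisibly (write); a per-site `data.table` (read).
#' @export
write_bedmethyl <- function(sites, path) {
  sites <- as.data.table(sites)
  bed <- data.table(
    chrom = sites$chrom,
    start = sites$pos,
    end = sites$pos + 1L,
    name = ".",
    score = pmin(sites$n_used, 1000L),
    strand = ifelse(sites$strand == "both", ".", sites$strand),
    thickStart = sites$pos,
    thickEnd = sites$pos + 1L,
    color = "0,0,0",
    coverage = sites$n_used,
    pct = as.integer(round(sites$frequency * 100))
  )
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedmethyl
#' @export
read_bedmethyl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "thickStart", "thickEnd", "color", "coverage", "pct")
  bed <- if (file.size(path) == 0) data.table()
         else data.table::fread(path, sep = "\t", header = FALSE)
  if (nrow(bed) == 0) {
    return(data.table(chrom = character(), pos = integer(), strand = character(),
                      n_used = integer(), n_meth = integer(), frequency = numeric()))
  }
  if (ncol(bed) < 11) stop("not a bedMethyl (BED9+2) file: ", path)
  data.table::setnames(bed, seq_along(cols), cols)
  out <- data.table(
    chrom = as.character(bed$chrom),
    pos = as.integer(bed$start),
    strand = ifelse(bed$strand == ".", "both", as.character(bed$strand)),
    n_used = as.integer(bed$coverage),
    n_meth = as.integer(round(bed$coverage * bed$pct / 100)),
    frequency = bed$pct / 100
  )
  out[]
}
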