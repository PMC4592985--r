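#' Observed (usage-weighted) GC_syn of amino acids in a bin
#'
#' The average GC-content of the synonymous codons of an amino acid as they
#' actually appear in a bin: each codon's GC fraction weighted by its
#' within-amino-acid usage share.  Equals the unweighted code-table GC_syn
#' when all synonymous codons are used equally.
#'
#' @param usage A `usage_table`.
#' @param bin Bin index.
#' @param aa Optional subset of amino acids (default: all 20).
#' @param code A `genetic_code` table.
#' @return Named numeric vector; `NA` for amino acids absent from the bin.
#' @export
observed_gc_syn <- function(usage, bin, aa = NULL, code = genetic_code()) {
  counts <- usage$codon_count[bin, ]
  aa_of <- code$aa[match(usage$codons, code$codon)]
  if (is.null(aa)) aa <- usage$aa
  vapply(aa, function(a) {
    sel <- aa_of == a
    tot <- sum(counts[sel])
    if (tot == 0) NA_real_
    else sum(counts[sel] * .CODON_GC[.CODON_INDEX[usage$codons[sel]]] / 3) / tot
  }, numeric(1))
}

#' Exact decomposition of a GC-content change into usage and codon-choice
#' components
#'
#' Splits each amino acid's contribution to a regional GC-content change,
#' `dGC = A_high x GCsyn_high - A_low x GCsyn_low`, exactly into an
#' amino-acid-usage component `dA x GCsyn_high` and a synonymous-codon-
#' choice component `dGCsyn x A_low`.  The identity
#' `effect_aa + effect_syn = dGC` holds algebraically, with no residual.
#'
#' @param a_low,a_high Amino-acid usage fractions in the low- and high-GC
#'   bins.
#' @param gcsyn_low,gcsyn_high Observed GC_syn in the two bins.
#' @param aa Optional amino-acid labels for the rows.
#' @param total_delta_gc Optional total GC-content change (over all 20
#'   amino acids) against which the summed effects are expressed as
#'   percentages.
#' @return Data frame of class `gc_decomposition` with per-row columns
#'   `gc_low`, `gc_high`, `d_gc`, `a_low`, `a_high`, `d_a`, `gcsyn_low`,
#'   `gcsyn_high`, `d_gcsyn`, `effect_aa`, `effect_syn`, plus a `"totals"`
#'   attribute (sums and, when `total_delta_gc` is given, `pct_aa` /
#'   `pct_syn`).
#' @examples
#' gc_decomposition(0.042, 0.204, 0.727, 0.973, aa = "Ala")
#' @export
gc_decomposition <- function(a_low, a_high, gcsyn_low, gcsyn_high,
                             aa = NULL, total_delta_gc = NULL) {
  n <- length(a_low)
  stopifnot(length(a_high) == n, length(gcsyn_low) == n,
            length(gcsyn_high) == n)
  if (is.null(aa)) aa <- names(a_low)
  if (is.null(aa)) aa <- as.character(seq_len(n))
  out <- data.frame(aa = aa,
                    gc_low = a_low * gcsyn_low,
                    gc_high = a_high * gcsyn_high,
                    d_gc = a_high * gcsyn_high - a_low * gcsyn_low,
                    a_low = a_low, a_high = a_high, d_a = a_high - a_low,
                    gcsyn_low = gcsyn_low, gcsyn_high = gcsyn_high,
                    d_gcsyn = gcsyn_high - gcsyn_low,
                    effect_aa = (a_high - a_low) * gcsyn_high,
                    effect_syn = (gcsyn_high - gcsyn_low) * a_low,
                    row.names = NULL, stringsAsFactors = FALSE)
  totals <- list(d_gc = sum(out$d_gc), effect_aa = sum(out$effect_aa),
                 effect_syn = sum(out$effect_syn),
                 total_delta_gc = total_delta_gc)
  if (!is.null(total_delta_gc)) {
    if (total_delta_gc == 0) {
      totals$pct_aa <- NA_real_; totals$pct_syn <- NA_real_
    } else {
      totals$pct_aa <- 100 * totals$effect_aa / total_delta_gc
      totals$pct_syn <- 100 * totals$effect_syn / total_delta_gc
    }
  }
  attr(out, "totals") <- totals
  class(out) <- c("gc_decomposition", "data.frame")
  out
}

#' @export
print.gc_decomposition <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  t <- attr(x, "totals")
  cat(sprintf("totals: d_gc = %.*f, effect_aa = %.*f, effect_syn = %.*f\n",
              digits, t$d_gc, digits, t$effect_aa, digits, t$effect_syn))
  if (!is.null(t$total_delta_gc) && !is.null(t$pct_aa))
    cat(sprintf("relative to total dGC = %.3f: amino-acid usage %.1f%%, synonymous-codon choice %.1f%%\n",
                t$total_delta_gc, t$pct_aa, t$pct_syn))
  invisible(x)
}

.decomp_inputs <- function(usage, low_bin, high_bin, code) {
  nb <- .nonempty_bins(usage)
  if (is.null(low_bin)) low_bin <- nb[1L]
  if (is.null(high_bin)) high_bin <- nb[length(nb)]
  if (!(usage$bins$n_codons[low_bin] > 0) || !(usage$bins$n_codons[high_bin] > 0))
    stop("both bins must be nonempty")
  list(low = low_bin, high = high_bin,
       a_low = usage$aa_freq[low_bin, ], a_high = usage$aa_freq[high_bin, ],
       g_low = observed_gc_syn(usage, low_bin, code = code),
       g_high = observed_gc_syn(usage, high_bin, code = code))
}

#' GC-direction decomposition between two bins of a usage table
#'
#' Computes the usage/codon-choice decomposition from a usage table for a
#' chosen amino-acid subset (by default the four high-GC_syn amino acids
#' Ala, Gly, Pro, Arg, which carry most of the GC gain from low- to high-GC
#' regions).  When `total_delta_gc` is not supplied, it is computed
#' internally as the summed `d_gc` over all 20 amino acids — which equals
#' the difference of codon-weighted bin GC-contents exactly.
#'
#' @param usage A `usage_table`.
#' @param low_bin,high_bin Bin indices (defaults: first/last nonempty bin).
#' @param aa_subset Amino acids to report (default: high-GC_syn group).
#' @param total_delta_gc Total GC change used for the percentages; default
#'   computed over all 20 amino acids.
#' @param profile A `gcsyn_profile` for the default subset.
#' @param code A `genetic_code` table.
#' @return A `gc_decomposition` data frame (see [gc_decomposition()]).
#' @export
decompose_delta_gc <- function(usage, low_bin = NULL, high_bin = NULL,
                               aa_subset = NULL, total_delta_gc = NULL,
                               profile = gc_syn_profile(),
                               code = genetic_code()) {
  inp <- .decomp_inputs(usage, low_bin, high_bin, code)
  if (is.null(aa_subset)) aa_subset <- profile$aa[profile$group == "high"]
  if (is.null(total_delta_gc))
    total_delta_gc <- sum(inp$a_high * inp$g_high - inp$a_low * inp$g_low,
                          na.rm = TRUE)
  sel <- match(aa_subset, usage$aa)
  gc_decomposition(inp$a_low[sel], inp$a_high[sel], inp$g_low[sel],
                   inp$g_high[sel], aa = aa_subset,
                   total_delta_gc = total_delta_gc)
}

#' AT-direction decomposition (high-GC to low-GC regions)
#'
#' The mirror analysis: the increase of AT-content going from the high-GC
#' to the low-GC bin, decomposed per amino acid into usage and
#' synonymous-codon-choice components.  Algebraically this is the GC
#' decomposition with every GC fraction replaced by its complement and the
#' roles of the two bins swapped; the default subset is the five low-GC_syn
#' amino acids.
#'
#' @inheritParams decompose_delta_gc
#' @param total_delta_at Total AT change used for percentages; default
#'   computed over all 20 amino acids.
#' @return A `gc_decomposition` data frame in AT units: `gc_low`/`gc_high`
#'   etc. then refer to AT fractions, with "low" = the high-GC bin.
#' @export
at_decomposition <- function(usage, low_bin = NULL, high_bin = NULL,
                             aa_subset = NULL, total_delta_at = NULL,
                             profile = gc_syn_profile(),
                             code = genetic_code()) {
  inp <- .decomp_inputs(usage, low_bin, high_bin, code)
  if (is.null(aa_subset)) aa_subset <- profile$aa[profile$group == "low"]
  # AT rises from the high-GC bin ("low-AT") to the low-GC bin ("high-AT")
  at_low <- 1 - inp$g_high   # ATsyn in the high-GC bin
  at_high <- 1 - inp$g_low   # ATsyn in the low-GC bin
  if (is.null(total_delta_at))
    total_delta_at <- sum(inp$a_low * at_high - inp$a_high * at_low,
                          na.rm = TRUE)
  sel <- match(aa_subset, usage$aa)
  gc_decomposition(inp$a_high[sel], inp$a_low[sel], at_low[sel],
                   at_high[sel], aa = aa_subset,
                   total_delta_gc = total_delta_at)
}
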