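#' GC bin boundaries
#'
#' @param start,end,step Bin range and width.  The number of bins
#'   `(end - start) / step` must be a whole number.
#' @return Data frame with columns `index`, `lo`, `hi`.
#' @export
gc_bins <- function(start = 0.30, end = 0.80, step = 0.01) {
  if (step <= 0) stop("'step' must be > 0")
  if (end <= start) stop("'end' must be greater than 'start'")
  nb <- (end - start) / step
  if (abs(nb - round(nb)) > 1e-8) stop("(end - start) must be a multiple of 'step'")
  nb <- as.integer(round(nb))
  data.frame(index = seq_len(nb), lo = start + (seq_len(nb) - 1L) * step,
             hi = start + seq_len(nb) * step)
}

#' Assign GC fractions to bins
#'
#' Bins are half-open `[lo, hi)` except the top bin, which is closed at
#' `end`.  Values outside `[start, end]` are excluded (`NA`).  A small
#' tolerance guards against floating-point representation of the bin edges.
#'
#' @param gc Numeric vector of GC fractions in \[0, 1\].
#' @inheritParams gc_bins
#' @return Integer bin indices (1-based), `NA` for excluded values.
#' @examples
#' assign_gc_bin(c(0.305, 0.295, 0.80))   # 1, NA, 50
#' @export
assign_gc_bin <- function(gc, start = 0.30, end = 0.80, step = 0.01) {
  bins <- gc_bins(start, end, step)
  nb <- nrow(bins)
  eps <- step * 1e-6
  idx <- as.integer(floor((gc - start) / step + eps)) + 1L
  idx[idx > nb] <- nb
  idx[gc < start - eps | gc > end + eps] <- NA_integer_
  idx
}

.sense_aa_matrix <- function(code) {
  sense <- !is.na(code$aa)
  aa <- sort(unique(code$aa[sense]))
  M <- matrix(0, sum(sense), length(aa),
              dimnames = list(code$codon[sense], aa))
  M[cbind(seq_len(sum(sense)), match(code$aa[sense], aa))] <- 1
  M
}

.usage_table_from_counts <- function(counts64, gc_sum, n_units, params, code) {
  bins <- gc_bins(params$start, params$end, params$step)
  nb <- nrow(bins)
  sense <- !is.na(code$aa)
  cc <- counts64[, sense, drop = FALSE]
  colnames(cc) <- code$codon[sense]
  tot <- rowSums(cc)
  freq <- cc / ifelse(tot > 0, tot, NA_real_)
  M <- .sense_aa_matrix(code)
  aa_freq <- freq %*% M
  bins$mean_gc <- ifelse(n_units > 0, gc_sum / n_units, NA_real_)
  bins$n_units <- as.integer(n_units)
  bins$n_codons <- tot
  bins$low_confidence <- tot > 0 & tot < params$min_codons
  structure(list(bins = bins,
                 codon_count = cc,
                 codon_freq = freq,
                 aa_freq = aa_freq,
                 codons = code$codon[sense],
                 aa = colnames(M),
                 params = params),
            class = "usage_table")
}

#' Per-GC-bin codon and amino-acid usage table
#'
#' Assigns every unit to a GC bin (by its all-position GC or its GC3,
#' depending on `gc_mode`), pools the codons of all units per bin, and
#' computes codon and amino-acid usage frequencies.  Frequencies are
#' normalised over the sense codons actually counted in the bin, so any
#' stop codons present in a raw codon stream (e.g. random sequences read in
#' frame) are excluded and the remaining frequencies renormalised.  Bins
#' whose pooled codon count falls below `min_codons` are flagged
#' low-confidence; empty bins carry `NA` frequencies.
#'
#' @param units A `codon_units` object.
#' @param gc_mode `"all_positions"` (bin on unit GC) or `"third_position"`
#'   (bin on unit GC3).
#' @param min_codons Minimum pooled codons per bin before the bin's usage
#'   row is considered well supported.
#' @inheritParams gc_bins
#' @param code A `genetic_code` table.
#' @return A `usage_table`: list with `bins` (per-bin metadata incl.
#'   `mean_gc`, the unweighted mean GC of member units), `codon_count`,
#'   `codon_freq` (bins x 61), `aa_freq` (bins x 20) and `params`.
#' @export
usage_table <- function(units, start = 0.30, end = 0.80, step = 0.01,
                        gc_mode = c("all_positions", "third_position"),
                        min_codons = 1000, code = genetic_code()) {
  gc_mode <- match.arg(gc_mode)
  params <- list(start = start, end = end, step = step, gc_mode = gc_mode,
                 min_codons = min_codons)
  stat <- if (gc_mode == "all_positions") units$info$gc else units$info$gc3
  bin <- assign_gc_bin(stat, start, end, step)
  nb <- nrow(gc_bins(start, end, step))
  codonvec <- unlist(units$codons, use.names = FALSE)
  binrep <- rep.int(bin, units$info$n_codons)
  keep <- !is.na(binrep)
  counts64 <- matrix(tabulate((binrep[keep] - 1L) * 64L + codonvec[keep],
                              nbins = nb * 64L),
                     nrow = nb, ncol = 64L, byrow = TRUE)
  ok <- !is.na(bin)
  n_units <- tabulate(bin[ok], nb)
  gc_sum <- vapply(seq_len(nb), function(b) sum(stat[ok][bin[ok] == b]),
                   numeric(1))
  .usage_table_from_counts(counts64, gc_sum, n_units, params, code)
}

#' @export
print.usage_table <- function(x, ...) {
  nonempty <- sum(x$bins$n_codons > 0)
  cat("usage_table:", nrow(x$bins), "GC bins (",
      sprintf("%.2f-%.2f by %.2f", x$params$start, x$params$end,
              x$params$step),
      ", mode", x$params$gc_mode, ")\n")
  cat("  nonempty bins:", nonempty, "; total codons:",
      sum(x$bins$n_codons), "\n")
  if (any(x$bins$low_confidence))
    cat("  low-confidence bins (<", x$params$min_codons, "codons):",
        sum(x$bins$low_confidence), "\n")
  invisible(x)
}

.usage_bin_meta <- function(usage) {
  data.frame(index = usage$bins$index,
             gc_range = sprintf("%.2f-%.2f", usage$bins$lo, usage$bins$hi),
             mean_gc = usage$bins$mean_gc,
             n_units = usage$bins$n_units,
             n_codons = usage$bins$n_codons,
             stringsAsFactors = FALSE)
}

#' Write per-bin usage tables as TSV
#'
#' Writes the codon table (one row per bin: index, GC range, mean GC, unit
#' and codon counts, then the 61 sense-codon frequencies) and optionally the
#' companion 20-column amino-acid table.
#'
#' @param usage A `usage_table`.
#' @param codon_file,aa_file Output paths (`NULL` to skip one of them).
#' @return Invisibly, the codon-level data frame.
#' @export
write_usage_table <- function(usage, codon_file, aa_file = NULL) {
  meta <- .usage_bin_meta(usage)
  ctab <- cbind(meta, as.data.frame(usage$codon_freq))
  if (!is.null(codon_file))
    utils::write.table(ctab, codon_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  if (!is.null(aa_file)) {
    atab <- cbind(meta, as.data.frame(usage$aa_freq))
    utils::write.table(atab, aa_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(ctab)
}
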