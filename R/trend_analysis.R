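.nonempty_bins <- function(usage) which(usage$bins$n_codons > 0)

#' Per-amino-acid usage trends against bin GC
#'
#' Ordinary least-squares regression (with intercept) of each amino acid's
#' usage frequency against the bins' mean GC-content.  Only nonempty bins
#' enter the fit, and by default low-confidence bins are excluded too:
#' sparse tail bins are populated by the selection tails of the GC
#' distribution, whose usage reflects the neighbouring dense regions and
#' systematically steepens the fitted trends.  At least three usable bins
#' are required.
#'
#' @param usage A `usage_table`.
#' @param profile A `gcsyn_profile` (used to annotate each amino acid's
#'   GC_syn group).
#' @param include_low_confidence Also fit over bins flagged low-confidence.
#' @return Data frame with one row per amino acid: `aa`, `group`, `slope`
#'   (usage change per unit GC), `se` (standard error of the slope), `r2`,
#'   `p` (two-sided p-value of the slope).
#' @export
usage_slopes <- function(usage, profile = gc_syn_profile(),
                         include_low_confidence = FALSE) {
  nb <- .nonempty_bins(usage)
  if (!include_low_confidence) nb <- setdiff(nb, which(usage$bins$low_confidence))
  if (length(nb) < 3L) stop("need at least 3 nonempty bins for trend fits")
  x <- usage$bins$mean_gc[nb]
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  res <- lapply(usage$aa, function(a) {
    y <- usage$aa_freq[nb, a]
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(resid^2) / (n - 2L) / sxx)
    # numerically flat usage: no trend by convention (the tolerance absorbs
    # ulp-level noise from the frequency normalisation)
    flat <- diff(range(y)) <= 1e-12 * max(abs(y), .Machine$double.xmin)
    if (flat) { slope <- 0; se <- 0 }
    r2 <- if (flat) 0 else stats::cor(x, y)^2
    p <- if (se == 0) NA_real_ else 2 * stats::pt(-abs(slope / se), n - 2L)
    data.frame(aa = a, slope = slope, se = se, r2 = r2, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$group <- profile$group[match(out$aa, profile$aa)]
  out[, c("aa", "group", "slope", "se", "r2", "p")]
}

#' Per-bin usage totals of the three GC_syn groups
#'
#' Sums amino-acid usage within the high-, intermediate- and low-GC_syn
#' groups for every bin and forms the high/low usage ratio.
#'
#' @inheritParams usage_slopes
#' @return Data frame: `index`, `mean_gc`, `high`, `intermediate`, `low`,
#'   `high_low_ratio` (`NA` when the low-group total is 0 or the bin is
#'   empty).
#' @export
group_usage_series <- function(usage, profile = gc_syn_profile()) {
  grp <- profile$group[match(usage$aa, profile$aa)]
  tot <- function(g) {
    cols <- usage$aa[grp == g]
    rowSums(usage$aa_freq[, cols, drop = FALSE])
  }
  out <- data.frame(index = usage$bins$index, mean_gc = usage$bins$mean_gc,
                    high = tot("high"), intermediate = tot("intermediate"),
                    low = tot("low"))
  out$high_low_ratio <- ifelse(!is.na(out$low) & out$low > 0,
                               out$high / out$low, NA_real_)
  out
}

#' Correlation between amino-acid usage and synonymous-codon number
#'
#' Pearson correlation, per GC bin, between amino-acid usage frequencies and
#' the number of synonymous codons, either over the eleven
#' intermediate-GC_syn amino acids or over all twenty.
#'
#' @inheritParams usage_slopes
#' @param bins Bin indices to evaluate (default: all nonempty bins).
#' @param subset `"intermediate11"` or `"all20"`.
#' @return Data frame: `index`, `mean_gc`, `r`, `p`, `n_aa`.  `r` is `NA`
#'   (flagged by `p = NA`) when either vector has zero variance.
#' @export
codon_number_correlation <- function(usage, profile = gc_syn_profile(),
                                     bins = NULL,
                                     subset = c("intermediate11", "all20")) {
  subset <- match.arg(subset)
  if (is.null(bins)) bins <- .nonempty_bins(usage)
  sel <- if (subset == "intermediate11") {
    profile$aa[profile$group == "intermediate"]
  } else profile$aa
  ncod <- profile$n_codons[match(sel, profile$aa)]
  res <- lapply(bins, function(b) {
    y <- usage$aa_freq[b, sel]
    if (anyNA(y) || stats::sd(y) == 0 || stats::sd(ncod) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(y, ncod, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(index = b, mean_gc = usage$bins$mean_gc[b], r = r, p = p,
               n_aa = length(sel))
  })
  do.call(rbind, res)
}

#' Per-amino-acid GC-content change between two bins
#'
#' For each amino acid, the change in its contribution to regional
#' GC-content between a low-GC and a high-GC bin:
#' `A_high x GCsyn_high - A_low x GCsyn_low`, where `A` is the amino acid's
#' usage and `GCsyn` its observed (usage-weighted) synonymous-codon
#' GC-content in that bin.
#'
#' @inheritParams usage_slopes
#' @param low_bin,high_bin Bin indices (defaults: first and last nonempty
#'   bin).
#' @param code A `genetic_code` table.
#' @return Data frame: `aa`, `a_low`, `a_high`, `gcsyn_low`, `gcsyn_high`,
#'   `delta_gc`; rows are `NA`-flagged where the amino acid is absent from a
#'   bin.
#' @export
per_aa_delta_gc <- function(usage, low_bin = NULL, high_bin = NULL,
                            code = genetic_code()) {
  nb <- .nonempty_bins(usage)
  if (is.null(low_bin)) low_bin <- nb[1L]
  if (is.null(high_bin)) high_bin <- nb[length(nb)]
  gl <- observed_gc_syn(usage, low_bin, code = code)
  gh <- observed_gc_syn(usage, high_bin, code = code)
  data.frame(aa = usage$aa,
             a_low = usage$aa_freq[low_bin, ],
             a_high = usage$aa_freq[high_bin, ],
             gcsyn_low = gl, gcsyn_high = gh,
             delta_gc = usage$aa_freq[high_bin, ] * gh -
                        usage$aa_freq[low_bin, ] * gl,
             row.names = NULL, stringsAsFactors = FALSE)
}
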