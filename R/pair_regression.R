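#' Enumerate GC-N bin pairs
#'
#' A GC-N pair is a pair of bins whose indices differ by `N` (GC-nearest =
#' GC-1).  By default pairs slide: `(1, 1+N), (2, 2+N), ..., (B-N, B)`,
#' giving `B - N` pairs.  With `disjoint = TRUE` the pairs are
#' non-overlapping (`(1,2), (3,4), ...` for N = 1), the enumeration
#' illustrated by some presentations of the GC-nearest comparison.
#'
#' @param n_bins Number of bins B.
#' @param N Index gap, `1 <= N <= B - 1`.
#' @param disjoint Use the non-overlapping variant.
#' @return Two-column integer matrix of pairs `(i, j)`.
#' @examples
#' nrow(enumerate_gc_pairs(50, 1))   # 49
#' nrow(enumerate_gc_pairs(50, 2))   # 48
#' @export
enumerate_gc_pairs <- function(n_bins, N, disjoint = FALSE) {
  n_bins <- as.integer(n_bins); N <- as.integer(N)
  if (N < 1L || N > n_bins - 1L) stop("'N' must be in 1..(n_bins - 1)")
  i <- if (disjoint) seq.int(1L, n_bins - N, by = N + 1L)
       else seq_len(n_bins - N)
  cbind(i = as.integer(i), j = as.integer(i + N))
}

#' Regress one usage vector on another
#'
#' Ordinary least squares of `y` on `x` over paired usage frequencies (the
#' 20 amino-acid or 61 codon frequencies of two GC bins; the lower-GC bin
#' belongs on x).  R-squared is the squared Pearson correlation.  Slope and
#' intercept are computed in closed form, so regressing a vector on itself
#' returns slope 1 and R-squared 1 exactly.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `slope`, `intercept`, `r2`, `n`.  Zero variance on `x`
#'   yields `NA` slope with a warning.
#' @export
regress_usage_pair <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  vx <- stats::var(x)
  if (is.na(vx) || vx == 0) {
    warning("zero variance on x; slope undefined")
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                n = length(x)))
  }
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r2 = r2, n = length(x))
}

#' All pairwise usage regressions up to GC-N_max
#'
#' Runs [regress_usage_pair()] for every GC-N pair, N = 1..`n_max`, over
#' either the 61 codon or the 20 amino-acid frequency vectors.  The
#' lower-GC (lower-index) bin is always placed on x.  Pairs with an empty
#' member bin are skipped.
#'
#' @param usage A `usage_table`.
#' @param vector_kind `"codon61"` or `"aa20"`.
#' @param n_max Largest index gap (default: all, B - 1).
#' @param disjoint Passed to [enumerate_gc_pairs()].
#' @return Data frame of class `pair_stats`: `vector_kind`, `n_gap`, `i`,
#'   `j`, `delta_gc` (difference of bin mean GC), `slope`, `intercept`,
#'   `r2`.
#' @export
pair_stats <- function(usage, vector_kind = c("codon61", "aa20"),
                       n_max = NULL, disjoint = FALSE) {
  vector_kind <- match.arg(vector_kind)
  mat <- if (vector_kind == "codon61") usage$codon_freq else usage$aa_freq
  nb <- nrow(usage$bins)
  if (is.null(n_max)) n_max <- nb - 1L
  nonempty <- usage$bins$n_codons > 0
  rows <- list()
  for (N in seq_len(n_max)) {
    pr <- enumerate_gc_pairs(nb, N, disjoint = disjoint)
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1L]; j <- pr[k, 2L]
      if (!nonempty[i] || !nonempty[j]) next
      fit <- regress_usage_pair(mat[i, ], mat[j, ])
      rows[[length(rows) + 1L]] <-
        data.frame(vector_kind = vector_kind, n_gap = N, i = i, j = j,
                   delta_gc = usage$bins$mean_gc[j] - usage$bins$mean_gc[i],
                   slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pair_stats", "data.frame")
  out
}

#' Decay of pairwise slope and R-squared with GC divergence
#'
#' Averages pairwise regression slope and R-squared per index gap N and
#' reports them against the mean GC-content difference of the pairs, the
#' summary used to show that usage profiles diverge smoothly as bins grow
#' apart in GC.
#'
#' @param ps A `pair_stats` data frame.
#' @return Data frame with one row per N: `n_gap`, `mean_delta_gc`,
#'   `mean_slope`, `mean_r2`, `n_pairs`; attribute
#'   `"r2_monotone_decreasing"` records whether mean R-squared decreases
#'   with every step of N.
#' @export
delta_gc_curve <- function(ps) {
  sp <- split(ps, ps$n_gap)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(n_gap = d$n_gap[1L],
               mean_delta_gc = mean(d$delta_gc, na.rm = TRUE),
               mean_slope = mean(d$slope, na.rm = TRUE),
               mean_r2 = mean(d$r2, na.rm = TRUE),
               n_pairs = nrow(d))
  }))
  out <- out[order(out$n_gap), ]
  rownames(out) <- NULL
  attr(out, "r2_monotone_decreasing") <- all(diff(out$mean_r2) < 0)
  out
}

#' One-sample and paired t tests for pairwise R-squared sets
#'
#' One-sample t test of a set of values against a null mean (default 1.0,
#' the no-divergence limit for pairwise usage regressions), or a paired t
#' test between two equally sized sets (e.g. real vs simulated adjacent-bin
#' R-squared values).  Zero-variance inputs are flagged: the statistic is 0
#' when the mean equals the null and the p-value is undefined (`NA`).
#'
#' @param a Numeric vector (>= 2 values).
#' @param b Optional second vector for a paired test (same length as `a`).
#' @param mu Null mean for the one-sample test.
#' @return List: `method`, `estimate` (mean or mean difference), `t`, `df`,
#'   `p`, `zero_variance`.
#' @export
mean_tests <- function(a, b = NULL, mu = 1) {
  stopifnot(length(a) >= 2L)
  d <- if (is.null(b)) a - mu else { stopifnot(length(b) == length(a)); a - b }
  method <- if (is.null(b)) "one-sample t" else "paired t"
  est <- mean(d)
  if (stats::sd(d) == 0) {
    return(list(method = method, estimate = est + if (is.null(b)) mu else 0,
                t = if (est == 0) 0 else sign(est) * Inf,
                df = length(d) - 1L, p = NA_real_, zero_variance = TRUE))
  }
  tt <- stats::t.test(d, mu = 0)
  list(method = method,
       estimate = est + if (is.null(b)) mu else 0,
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       zero_variance = FALSE)
}
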