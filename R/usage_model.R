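# Parametric codon-usage models: a `usage_model` maps a target GC value to a
# 61-codon frequency vector.  They stand in for real multi-genome corpora in
# parameter-recovery experiments: the model prescribes how amino-acid usage
# moves with GC, the generator samples CDS from it, and the pipeline's
# fitted trends can be compared against the model's own.

new_usage_model <- function(freq_fun, aa_usage_fun, slopes, name,
                            support) {
  structure(list(freq = freq_fun, aa_usage = aa_usage_fun, slopes = slopes,
                 name = name, support = support),
            class = "usage_model")
}

#' @export
print.usage_model <- function(x, ...) {
  cat("usage_model:", x$name, " support:",
      sprintf("[%.2f, %.2f]", x$support[1], x$support[2]), "\n")
  invisible(x)
}

#' The i.i.d. random-DNA usage model
#'
#' Codon frequencies follow [expected_codon_usage_random()]; amino-acid
#' usage trends are whatever the genetic code imposes on i.i.d. sequence
#' (high-GC_syn amino acids rise with GC, low-GC_syn ones fall).
#'
#' @param code A `genetic_code` table.
#' @return A `usage_model`.
#' @export
usage_model_random <- function(code = genetic_code()) {
  new_usage_model(
    freq_fun = function(g) expected_codon_usage_random(g, code = code),
    aa_usage_fun = function(g) expected_aa_usage_random(g, code = code),
    slopes = NULL, name = "iid_random", support = c(0, 1))
}

.cond_gcsyn <- function(u, code) {
  # per-aa observed GC_syn when synonymous codons are used with i.i.d.
  # weights at GC fraction u
  p <- expected_codon_usage_random(u, sense_only = TRUE, code = code)
  aa <- code$aa[match(names(p), code$codon)]
  k <- .CODON_GC[.CODON_INDEX[names(p)]] / 3
  num <- tapply(p * k, aa, sum)
  den <- tapply(p, aa, sum)
  (num / den)[sort(unique(aa))]
}

#' A usage model with prescribed linear amino-acid trends
#'
#' Amino-acid usage is linear in the target GC value t:
#' `A_aa(t) = base_aa + slope_aa (t - t0)`, with slopes summing to 0 and
#' base usage summing to 1.  Within each amino acid, synonymous codons are
#' weighted as in i.i.d. DNA at an auxiliary GC value u(t), solved (by
#' [stats::uniroot()]) so that the implied overall GC-content of the codon
#' vector equals t.  The model's slopes are therefore slopes of amino-acid
#' usage against the GC-content of the generated sequence itself, directly
#' comparable to the pipeline's fitted trends.
#'
#' @param slopes Named per-amino-acid slopes summing to ~0.  The default
#'   rises for the four high-GC_syn amino acids (+0.54 total), falls for the
#'   five low-GC_syn ones (-0.40 total) and drifts slightly down for the
#'   intermediate eleven, resembling the trends seen in real coding
#'   sequence.
#' @param base Named base usage at `t0` (default: the i.i.d. model's
#'   amino-acid usage at `t0`).
#' @param t0 Reference GC value.
#' @param support GC interval on which the model must stay a valid
#'   composition (checked on construction).
#' @param code A `genetic_code` table.
#' @return A `usage_model` with element `slopes` (the prescription).
#' @export
usage_model_linear <- function(slopes = NULL, base = NULL, t0 = 0.55,
                               support = c(0.35, 0.75),
                               code = genetic_code()) {
  prof <- gc_syn_profile(code)
  if (is.null(slopes)) {
    slopes <- stats::setNames(numeric(nrow(prof)), prof$aa)
    slopes[prof$aa[prof$group == "high"]] <- c(0.18, 0.12, 0.12, 0.12)
    slopes[prof$aa[prof$group == "low"]] <- -0.08
    slopes[prof$aa[prof$group == "intermediate"]] <- -(sum(slopes)) / 11
  }
  if (is.null(base)) base <- expected_aa_usage_random(t0, code = code)
  base <- base[sort(names(base))]
  slopes <- slopes[names(base)]
  stopifnot(abs(sum(slopes)) < 1e-8, abs(sum(base) - 1) < 1e-8)
  aa_usage <- function(t) {
    a <- base + slopes * (t - t0)
    if (any(a < 0)) stop("model leaves the simplex at t = ", t)
    a
  }
  # validate across the support
  for (t in seq(support[1], support[2], length.out = 9)) aa_usage(t)
  sense <- attr(code, "sense_codons")
  aa_of <- code$aa[match(sense, code$codon)]
  kfrac <- .CODON_GC[.CODON_INDEX[sense]] / 3
  freq <- function(t) {
    a <- aa_usage(t)
    h <- function(u) sum(a * .cond_gcsyn(u, code)) - t
    u <- stats::uniroot(h, c(1e-4, 1 - 1e-4), tol = 1e-10)$root
    p <- expected_codon_usage_random(u, sense_only = TRUE, code = code)
    q <- p / stats::ave(p, aa_of, FUN = sum)        # within-aa shares
    out <- q * a[aa_of]
    stats::setNames(as.numeric(out), sense)
  }
  new_usage_model(freq, aa_usage, slopes, "linear_aa_trends", support)
}

#' Sample synthetic CDS from a usage model
#'
#' For each target GC value, draws `n_per_target` CDS whose internal codons
#' are i.i.d. from the model's 61-codon frequency vector at that target;
#' each CDS gets a leading ATG and a trailing stop codon (uniform over the
#' three stops), so the sequences flow through [prepare_codons()] like real
#' CDS.  Codon counts are multinomial around the model.
#'
#' @param model A `usage_model`.
#' @param gc_targets Target GC values (within the model's support).
#' @param n_per_target CDS per target.
#' @param length_range_codons Range of internal codon counts per CDS.
#' @param seed RNG seed.
#' @param code A `genetic_code` table.
#' @return Named character vector of CDS strings; names encode the target.
#' @export
cds_from_usage_model <- function(model, gc_targets, n_per_target,
                                 length_range_codons = c(300L, 500L),
                                 seed = 1L, code = genetic_code()) {
  stopifnot(inherits(model, "usage_model"))
  set.seed(seed)
  stops <- attr(code, "stop_codons")
  sense <- attr(code, "sense_codons")
  out <- character(0)
  for (t in gc_targets) {
    p <- model$freq(t)
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("model frequency vector is not a probability vector at t = ", t)
    nc <- length_range_codons[1] +
      sample.int(length_range_codons[2] - length_range_codons[1] + 1L,
                 n_per_target, replace = TRUE) - 1L
    draws <- sample.int(length(p), sum(nc), replace = TRUE, prob = p)
    codstr <- sense[draws]
    uid <- rep.int(seq_len(n_per_target), nc)
    body <- vapply(split(codstr, uid), paste, character(1), collapse = "")
    stopc <- stops[sample.int(length(stops), n_per_target, replace = TRUE)]
    seqs <- paste0("ATG", body, stopc)
    names(seqs) <- sprintf("t%.3f_%04d", t, seq_len(n_per_target))
    out <- c(out, seqs)
  }
  out
}
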