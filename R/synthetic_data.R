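# Random-sequence control and synthetic CDS generators.  All generators are
# seeded through their spec/argument so a fixed seed gives byte-identical
# output; the heavy control path never materialises sequence strings.

#' Specification for the random-sequence control
#'
#' The control emulates pools of i.i.d. random DNA: for each target GC value
#' g, bases are drawn independently with P(G) = P(C) = g/2 and
#' P(A) = P(T) = (1 - g)/2, sequence lengths uniform over `length_range`
#' (truncated to a whole number of codons).  Defaults follow the study
#' conditions: 51 targets 0.30--0.80 in 0.01 steps, 10,000 sequences per
#' target, lengths 1200--1500 bp.
#'
#' @param gc_targets Target GC fractions.
#' @param n_per_bin Sequences per target.
#' @param length_range Length range in bp (min, max).
#' @param seed RNG seed recorded in the spec and used by the generators.
#' @return A list of class `random_seq_spec`.
#' @export
random_seq_spec <- function(gc_targets = seq(0.30, 0.80, by = 0.01),
                            n_per_bin = 10000L,
                            length_range = c(1200L, 1500L),
                            seed = 20150806L) {
  stopifnot(all(gc_targets >= 0 & gc_targets <= 1),
            n_per_bin >= 1, length(length_range) == 2L,
            length_range[1] >= 3, length_range[2] >= length_range[1])
  structure(list(gc_targets = gc_targets, n_per_bin = as.integer(n_per_bin),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "random_seq_spec")
}

# one target's worth of i.i.d. codon draws; consumes RNG deterministically
.r_iid_target <- function(g, n, length_range) {
  # sample.int keeps a degenerate range honest (sample() would expand it)
  lens <- length_range[1] +
    sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE) - 1L
  nc <- lens %/% 3L
  M <- sum(nc)
  pr <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
  b1 <- sample.int(4L, M, replace = TRUE, prob = pr)
  b2 <- sample.int(4L, M, replace = TRUE, prob = pr)
  b3 <- sample.int(4L, M, replace = TRUE, prob = pr)
  ci <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
  uid <- rep.int(seq_len(n), nc)
  gc <- rowsum(.CODON_GC[ci], uid)[, 1] / (3 * nc)
  gc3 <- rowsum(.CODON_GC3[ci], uid)[, 1] / nc
  list(ci = ci, nc = nc, gc = unname(gc), gc3 = unname(gc3), uid = uid)
}

#' Generate random i.i.d. DNA sequences as analysis units
#'
#' Materialises the control sequences of a [random_seq_spec()] as a
#' `codon_units` object (kind `"random"`).  Realised stop codons stay in the
#' codon stream; [usage_table()] excludes them from usage counts and
#' renormalises over sense codons.  Units carry their realised GC, which is
#' what the pipeline bins on.  Intended for moderate sizes; the full-scale
#' control should use [random_usage_table()], which draws the identical
#' sequences but streams them directly into per-bin counts.
#'
#' @param spec A `random_seq_spec`.
#' @return A `codon_units` object; `info` carries `target_gc`.
#' @export
random_sequences <- function(spec) {
  stopifnot(inherits(spec, "random_seq_spec"))
  set.seed(spec$seed)
  all_codons <- list()
  ids <- character(); targets <- numeric()
  for (g in spec$gc_targets) {
    d <- .r_iid_target(g, spec$n_per_bin, spec$length_range)
    all_codons <- c(all_codons, unname(split(d$ci, d$uid)))
    ids <- c(ids, sprintf("g%.2f_%05d", g, seq_len(spec$n_per_bin)))
    targets <- c(targets, rep(g, spec$n_per_bin))
  }
  new_codon_units(all_codons, ids, "random",
                  extra = data.frame(target_gc = targets))
}

#' Usage table of the random-sequence control, computed by streaming
#'
#' Runs the random-sequence control end to end without materialising
#' sequences: for each target GC it draws exactly the same sequences as
#' [random_sequences()] (same seed, same RNG stream), bins each sequence by
#' its realised GC (or GC3) and accumulates per-bin codon counts.  The
#' result is identical to `usage_table(random_sequences(spec), ...)`.
#'
#' @param spec A `random_seq_spec`.
#' @inheritParams usage_table
#' @return A `usage_table`.
#' @export
random_usage_table <- function(spec, start = 0.30, end = 0.80, step = 0.01,
                               gc_mode = c("all_positions", "third_position"),
                               min_codons = 1000, code = genetic_code()) {
  stopifnot(inherits(spec, "random_seq_spec"))
  gc_mode <- match.arg(gc_mode)
  params <- list(start = start, end = end, step = step, gc_mode = gc_mode,
                 min_codons = min_codons)
  nb <- nrow(gc_bins(start, end, step))
  counts64 <- matrix(0, nb, 64L)
  gc_sum <- numeric(nb)
  n_units <- integer(nb)
  set.seed(spec$seed)
  for (g in spec$gc_targets) {
    d <- .r_iid_target(g, spec$n_per_bin, spec$length_range)
    stat <- if (gc_mode == "all_positions") d$gc else d$gc3
    bin <- assign_gc_bin(stat, start, end, step)
    cb <- bin[d$uid]
    keep <- !is.na(cb)
    counts64 <- counts64 +
      matrix(tabulate((cb[keep] - 1L) * 64L + d$ci[keep], nbins = nb * 64L),
             nrow = nb, ncol = 64L, byrow = TRUE)
    ok <- !is.na(bin)
    n_units <- n_units + tabulate(bin[ok], nb)
    gc_sum <- gc_sum + vapply(seq_len(nb),
                              function(b) sum(stat[ok][bin[ok] == b]),
                              numeric(1))
  }
  .usage_table_from_counts(counts64, gc_sum, n_units, params, code)
}

#' Expected codon usage of i.i.d. random DNA
#'
#' Closed-form oracle for the random-sequence control: under i.i.d. bases
#' with GC fraction `g`, a codon with k G/C bases has probability
#' `(g/2)^k ((1-g)/2)^(3-k)`.
#'
#' @param g GC fraction in \[0, 1\].
#' @param sense_only Renormalise over the 61 sense codons (default);
#'   otherwise return all 64 codon probabilities.
#' @param code A `genetic_code` table.
#' @return Named probability vector over codons.
#' @examples
#' p <- expected_codon_usage_random(0.5)
#' all.equal(unname(p), rep(1/61, 61))
#' @export
expected_codon_usage_random <- function(g, sense_only = TRUE,
                                        code = genetic_code()) {
  stopifnot(g >= 0, g <= 1)
  p <- (g / 2)^.CODON_GC * ((1 - g) / 2)^(3 - .CODON_GC)
  names(p) <- .CODONS
  if (!sense_only) return(p)
  sense <- attr(code, "sense_codons")
  p <- p[sense]
  p / sum(p)
}

#' Expected amino-acid usage of i.i.d. random DNA
#'
#' Aggregates [expected_codon_usage_random()] over synonymous codons.
#'
#' @inheritParams expected_codon_usage_random
#' @return Named probability vector over the 20 amino acids.
#' @export
expected_aa_usage_random <- function(g, code = genetic_code()) {
  p <- expected_codon_usage_random(g, sense_only = TRUE, code = code)
  aa <- code$aa[match(names(p), code$codon)]
  tapply(p, aa, sum)[sort(unique(aa))]
}

#' Write sequences to FASTA
#'
#' Deterministic single-purpose writer (fixed line wrapping, no metadata),
#' so a fixed-seed generator yields byte-identical files.
#'
#' @param x A `codon_units` object or a named character vector of sequences.
#' @param path Output path.
#' @param width Line width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "codon_units")) {
    seqs <- vapply(x$codons, function(i) paste(.CODONS[i], collapse = ""),
                   character(1))
    names(seqs) <- x$info$source_id
  } else seqs <- x
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}
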