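# shared fixtures, all built in code

write_temp_fasta <- function(seqs, width = 60L) {
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path, width = width)
  path
}

# usage table whose per-bin codon frequencies follow the analytic i.i.d.
# model evaluated at the bin midpoints (a smooth, noise-free table)
analytic_usage <- function(start = 0.30, end = 0.80, step = 0.01,
                           scale = 1e6) {
  bins <- gc_bins(start, end, step)
  mids <- (bins$lo + bins$hi) / 2
  counts64 <- t(vapply(mids, function(g) {
    scale * expected_codon_usage_random(g, sense_only = FALSE)
  }, numeric(64)))
  params <- list(start = start, end = end, step = step,
                 gc_mode = "all_positions", min_codons = 0)
  gcsyn:::.usage_table_from_counts(counts64, gc_sum = mids,
                                   n_units = rep(1L, nrow(bins)),
                                   params = params, code = genetic_code())
}

# usage table with one identical composition replicated across bins but
# distinct bin GC coordinates (GC-independent usage)
flat_usage <- function(n_bins = 20, start = 0.30, step = 0.01) {
  end <- start + n_bins * step
  bins <- gc_bins(start, end, step)
  p <- expected_codon_usage_random(0.5, sense_only = FALSE)
  counts64 <- matrix(rep(1e6 * p, n_bins), nrow = n_bins, byrow = TRUE)
  params <- list(start = start, end = end, step = step,
                 gc_mode = "all_positions", min_codons = 0)
  gcsyn:::.usage_table_from_counts(counts64, gc_sum = (bins$lo + bins$hi) / 2,
                                   n_units = rep(1L, n_bins),
                                   params = params, code = genetic_code())
}

# Table 1 printed values (inputs and derived cells) for the worked example
table1_printed <- function() {
  data.frame(
    aa = c("Ala", "Gly", "Pro", "Arg"),
    a_low = c(0.042, 0.042, 0.027, 0.033),
    a_high = c(0.204, 0.119, 0.102, 0.109),
    gcsyn_low = c(0.727, 0.735, 0.727, 0.510),
    gcsyn_high = c(0.973, 0.954, 0.963, 0.943),
    gc_low = c(0.030, 0.031, 0.020, 0.017),
    gc_high = c(0.199, 0.114, 0.098, 0.103),
    d_gc = c(0.169, 0.083, 0.078, 0.086),
    d_a = c(0.162, 0.077, 0.075, 0.076),
    d_gcsyn = c(0.246, 0.220, 0.236, 0.433),
    effect_aa = c(0.158, 0.074, 0.073, 0.072),
    effect_syn = c(0.010, 0.009, 0.006, 0.014))
}
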