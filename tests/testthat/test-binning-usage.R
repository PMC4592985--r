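test_that("bin assignment uses half-open bins with a closed top edge", {
  expect_equal(assign_gc_bin(0.305), 1L)
  expect_true(is.na(assign_gc_bin(0.295)))
  expect_equal(assign_gc_bin(0.80), 50L)
  expect_true(is.na(assign_gc_bin(0.801)))
  # boundary values land in the upper bin despite floating-point edges
  expect_equal(assign_gc_bin(0.31), 2L)
  expect_equal(assign_gc_bin(0.79), 50L)
  expect_equal(assign_gc_bin(seq(0.30, 0.79, 0.01)), 1:50)
  expect_error(assign_gc_bin(0.5, step = 0), "> 0")
  expect_error(assign_gc_bin(0.5, start = 0.8, end = 0.3), "greater")
})

test_that("a GC3 range of 0.06-0.32 yields 26 bins", {
  expect_equal(nrow(gc_bins(0.06, 0.32, 0.01)), 26)
})

test_that("usage frequencies normalise per bin and aggregate to amino acids", {
  u <- codon_units(list(c("GCT", "GCT", "AAA", "AAA")))
  # unit GC = 4/12; bin on the full [0,1] range
  ut <- usage_table(u, start = 0, end = 1, step = 0.01, min_codons = 0)
  b <- which(ut$bins$n_codons > 0)
  expect_length(b, 1)
  expect_equal(ut$bins$lo[b], 0.33)
  expect_equal(unname(ut$codon_freq[b, "GCT"]), 0.5)
  expect_equal(unname(ut$codon_freq[b, "AAA"]), 0.5)
  expect_equal(unname(ut$aa_freq[b, "Ala"]), 0.5)
  expect_equal(unname(ut$aa_freq[b, "Lys"]), 0.5)
})

test_that("usage rows sum to one and obey the Leu aggregation identity", {
  set.seed(3)
  sense <- setdiff(gcsyn:::.CODONS, c("TAA", "TAG", "TGA"))
  cods <- replicate(120, sample(sense, 50, replace = TRUE), simplify = FALSE)
  u <- codon_units(cods)
  ut <- usage_table(u, start = 0, end = 1, step = 0.02, min_codons = 0)
  nz <- ut$bins$n_codons > 0
  expect_true(all(abs(rowSums(ut$codon_freq[nz, , drop = FALSE]) - 1) < 1e-12))
  expect_true(all(abs(rowSums(ut$aa_freq[nz, , drop = FALSE]) - 1) < 1e-12))
  leu_codons <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  expect_equal(unname(ut$aa_freq[nz, "Leu"]),
               unname(rowSums(ut$codon_freq[nz, leu_codons, drop = FALSE])))
  # every non-excluded unit is counted exactly once
  expect_equal(sum(ut$bins$n_units),
               sum(!is.na(assign_gc_bin(u$info$gc, 0, 1, 0.02))))
})

test_that("codon-weighted bin GC stays inside the bin bounds", {
  set.seed(9)
  sense <- setdiff(gcsyn:::.CODONS, c("TAA", "TAG", "TGA"))
  cods <- replicate(200, sample(sense, 50, replace = TRUE), simplify = FALSE)
  ut <- usage_table(codon_units(cods), start = 0, end = 1, step = 0.01,
                    min_codons = 0)
  gc_of_codon <- gcsyn:::.CODON_GC[match(ut$codons, gcsyn:::.CODONS)] / 3
  for (b in which(ut$bins$n_codons > 0)) {
    wgc <- sum(ut$codon_freq[b, ] * gc_of_codon)
    expect_gte(wgc, ut$bins$lo[b] - 1e-9)
    expect_lte(wgc, ut$bins$hi[b] + 1e-9)
  }
})

test_that("stop codons in raw streams are excluded and renormalised", {
  # a raw (unprepared) stream containing a stop codon
  u <- codon_units(list(c("GCT", "TAA", "AAA", "GCT")), unit_kind = "cds")
  ut <- usage_table(u, start = 0, end = 1, step = 0.05, min_codons = 0)
  b <- which(ut$bins$n_codons > 0)
  expect_equal(ut$bins$n_codons[b], 3)  # sense codons only
  expect_equal(unname(ut$codon_freq[b, "GCT"]), 2 / 3)
  expect_false("TAA" %in% colnames(ut$codon_freq))
})

test_that("low-confidence flag marks sparse bins", {
  u <- codon_units(list(c("GCT", "GCT", "AAA", "AAA")))
  ut <- usage_table(u, start = 0, end = 1, step = 0.01, min_codons = 1000)
  b <- which(ut$bins$n_codons > 0)
  expect_true(ut$bins$low_confidence[b])
})
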