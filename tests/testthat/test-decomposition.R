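test_that("observed GC_syn weights codons by within-amino-acid usage", {
  # Ala encoded only by GCG in the pooled bin -> observed GC_syn 1
  u <- codon_units(list(c("GCG", "GCG", "AAA")))
  ut <- usage_table(u, start = 0, end = 1, step = 0.5, min_codons = 0)
  b <- which(ut$bins$n_codons > 0)
  expect_equal(unname(observed_gc_syn(ut, b, aa = "Ala")), 1)
  # equal use of all four Ala codons -> the unweighted code-table value
  u2 <- codon_units(list(c("GCT", "GCC", "GCA", "GCG")))
  ut2 <- usage_table(u2, start = 0, end = 1, step = 0.5, min_codons = 0)
  b2 <- which(ut2$bins$n_codons > 0)
  expect_equal(unname(observed_gc_syn(ut2, b2, aa = "Ala")), 10 / 12)
  # absent amino acid is flagged NA
  expect_true(is.na(observed_gc_syn(ut2, b2, aa = "Lys")))
})

test_that("the worked decomposition reproduces the published example", {
  t1 <- table1_printed()
  dec <- gc_decomposition(t1$a_low, t1$a_high, t1$gcsyn_low, t1$gcsyn_high,
                          aa = t1$aa, total_delta_gc = 0.490)
  tol <- 0.001 + 1e-9
  for (col in c("gc_low", "gc_high", "d_gc", "d_a", "d_gcsyn",
                "effect_aa", "effect_syn")) {
    expect_true(all(abs(round(dec[[col]], 3) - t1[[col]]) <= tol),
                info = col)
  }
  tot <- attr(dec, "totals")
  expect_equal(tot$pct_aa, 76.7, tolerance = 0.3 / 76.7)
  expect_equal(tot$pct_syn, 8.2, tolerance = 0.3 / 8.2)
  # identical bins give an all-zero decomposition
  z <- gc_decomposition(t1$a_low, t1$a_low, t1$gcsyn_low, t1$gcsyn_low)
  expect_true(all(z$d_gc == 0 & z$effect_aa == 0 & z$effect_syn == 0))
})

test_that("the decomposition is exact for arbitrary inputs", {
  set.seed(13)
  n <- 1000
  al <- runif(n); ah <- runif(n); gl <- runif(n); gh <- runif(n)
  dec <- gc_decomposition(al, ah, gl, gh)
  resid <- dec$effect_aa + dec$effect_syn - (ah * gh - al * gl)
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("summed per-amino-acid dGC equals the bins' codon-weighted GC change", {
  set.seed(17)
  sense <- setdiff(gcsyn:::.CODONS, c("TAA", "TAG", "TGA"))
  cods <- replicate(300, sample(sense, 50, replace = TRUE), simplify = FALSE)
  ut <- usage_table(codon_units(cods), start = 0, end = 1, step = 0.02,
                    min_codons = 0)
  nb <- which(ut$bins$n_codons >= 2000)  # all 20 amino acids present
  lo <- nb[1]; hi <- nb[length(nb)]
  dec <- decompose_delta_gc(ut, lo, hi, aa_subset = ut$aa)
  gc_of_codon <- gcsyn:::.CODON_GC[match(ut$codons, gcsyn:::.CODONS)] / 3
  wgc <- function(b) sum(ut$codon_freq[b, ] * gc_of_codon)
  expect_equal(sum(dec$d_gc), wgc(hi) - wgc(lo), tolerance = 1e-12)
  # and the totals attribute used for percentages is that same number
  expect_equal(attr(dec, "totals")$total_delta_gc, wgc(hi) - wgc(lo),
               tolerance = 1e-12)
})

test_that("the AT-direction decomposition is the algebraic mirror", {
  set.seed(19)
  sense <- setdiff(gcsyn:::.CODONS, c("TAA", "TAG", "TGA"))
  cods <- replicate(300, sample(sense, 50, replace = TRUE), simplify = FALSE)
  ut <- usage_table(codon_units(cods), start = 0, end = 1, step = 0.02,
                    min_codons = 0)
  nb <- which(ut$bins$n_codons >= 2000)
  lo <- nb[1]; hi <- nb[length(nb)]
  at <- at_decomposition(ut, lo, hi, aa_subset = ut$aa)
  # identity: effects sum to the per-amino-acid AT change
  a_lo <- ut$aa_freq[lo, ]; a_hi <- ut$aa_freq[hi, ]
  g_lo <- observed_gc_syn(ut, lo); g_hi <- observed_gc_syn(ut, hi)
  d_at <- a_lo * (1 - g_lo) - a_hi * (1 - g_hi)
  ok <- !is.na(d_at)
  expect_equal(at$effect_aa[ok] + at$effect_syn[ok], unname(d_at[ok]),
               tolerance = 1e-12)
  # mirror: same as a GC decomposition on complemented fractions with the
  # bin roles swapped
  mirror <- gc_decomposition(a_hi, a_lo, 1 - g_hi, 1 - g_lo, aa = ut$aa)
  expect_equal(at$effect_aa, mirror$effect_aa)
  expect_equal(at$effect_syn, mirror$effect_syn)
})

test_that("an all-AT amino acid contributes no synonymous effect", {
  # Lys (AAA/AAG) used as AAA only in both bins: gcsyn 0 both sides
  dec <- gc_decomposition(a_low = 0.1, a_high = 0.05, gcsyn_low = 0,
                          gcsyn_high = 0, aa = "Lys")
  expect_equal(dec$effect_syn, 0)
})
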