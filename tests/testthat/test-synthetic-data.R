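test_that("a fixed seed gives byte-identical generated FASTA", {
  spec <- random_seq_spec(gc_targets = c(0.4, 0.6), n_per_bin = 20,
                          length_range = c(120, 150), seed = 99)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(random_sequences(spec), f1)
  write_fasta(random_sequences(spec), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and the streamed usage table sees the very same sequences
  ut1 <- usage_table(random_sequences(spec), start = 0, end = 1, step = 0.01,
                     min_codons = 0)
  ut2 <- random_usage_table(spec, start = 0, end = 1, step = 0.01,
                            min_codons = 0)
  expect_equal(ut1$codon_count, ut2$codon_count)
  expect_equal(ut1$bins, ut2$bins)
})

test_that("extreme GC targets produce pure-composition sequences", {
  spec <- random_seq_spec(gc_targets = 0, n_per_bin = 5,
                          length_range = c(90, 120), seed = 3)
  u <- random_sequences(spec)
  expect_true(all(u$info$gc == 0))
  expect_true(all(grepl("^[AT]+$",
                        vapply(u$codons,
                               function(i) paste(gcsyn:::.CODONS[i],
                                                 collapse = ""),
                               character(1)))))
})

test_that("realised GC concentrates around the target", {
  spec <- random_seq_spec(gc_targets = 0.5, n_per_bin = 200,
                          length_range = c(1350, 1350), seed = 21)
  u <- random_sequences(spec)
  # pooled estimate: 200 x 450 codons = 270,000 bases
  n_bases <- 3 * sum(u$info$n_codons)
  se <- sqrt(0.25 / n_bases)
  expect_lt(abs(mean(u$info$gc) - 0.5), 4 * se)
  # each single 1350-base sequence stays within a generous binomial bound
  expect_true(all(abs(u$info$gc - 0.5) < 4.5 * sqrt(0.25 / 1350)))
})

test_that("the analytic usage oracle behaves as a probability model", {
  for (g in c(0, 0.25, 0.5, 0.8, 1)) {
    p64 <- expected_codon_usage_random(g, sense_only = FALSE)
    expect_equal(sum(p64), 1)
    expect_true(all(p64 >= 0))
  }
  expect_equal(unname(expected_codon_usage_random(0.8,
                                                  sense_only = FALSE)["GGG"]),
               0.4^3)
  p <- expected_codon_usage_random(0.5)
  expect_equal(unname(p), rep(1 / 61, 61))
  paa <- expected_aa_usage_random(0.5)
  expect_equal(unname(paa["Leu"]), 6 / 61)
})

test_that("empirical usage converges to the analytic oracle", {
  spec_small <- random_seq_spec(gc_targets = 0.5, n_per_bin = 30,
                                length_range = c(300, 300), seed = 11)
  spec_big <- random_seq_spec(gc_targets = 0.5, n_per_bin = 600,
                              length_range = c(300, 300), seed = 11)
  dev <- function(spec) {
    ut <- random_usage_table(spec, start = 0, end = 1, step = 1 - 1e-9,
                             min_codons = 0)
    b <- which(ut$bins$n_codons > 0)
    max(abs(ut$codon_freq[b, ] - expected_codon_usage_random(0.5)))
  }
  expect_lt(dev(spec_big), dev(spec_small))
})

test_that("model-generated CDS follow the prescribed codon vector", {
  code <- genetic_code()
  sense <- attr(code, "sense_codons")
  # degenerate model: all mass on GCT
  p <- setNames(numeric(61), sense); p["GCT"] <- 1
  m <- gcsyn:::new_usage_model(function(t) p, NULL, NULL, "point", c(0, 1))
  cds <- cds_from_usage_model(m, gc_targets = 0.5, n_per_target = 5,
                              length_range_codons = c(10, 12), seed = 2)
  u <- prepare_codons(cds)
  expect_true(all(unlist(u$codons) == gcsyn:::.CODON_INDEX[["GCT"]]))
  # multinomial recovery from a fixed nondegenerate vector
  m2 <- usage_model_random()
  cds2 <- cds_from_usage_model(m2, gc_targets = 0.55, n_per_target = 400,
                               length_range_codons = c(200, 220), seed = 4)
  u2 <- prepare_codons(cds2)
  ut <- usage_table(u2, start = 0, end = 1, step = 1 - 1e-9, min_codons = 0)
  b <- which(ut$bins$n_codons > 0)
  p_exp <- m2$freq(0.55)
  n <- ut$bins$n_codons[b]
  z <- abs(ut$codon_freq[b, ] - p_exp) / sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(max(z), 4)
})

test_that("the linear usage model keeps its contract", {
  m <- usage_model_linear()
  for (t in c(0.4, 0.55, 0.7)) {
    p <- m$freq(t)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    # implied GC-content of the vector equals the target
    gc_of <- gcsyn:::.CODON_GC[match(names(p), gcsyn:::.CODONS)] / 3
    expect_equal(sum(p * gc_of), t, tolerance = 1e-6)
    # amino-acid marginals match the linear prescription
    aa <- genetic_code()$aa[match(names(p), genetic_code()$codon)]
    expect_equal(unname(tapply(p, aa, sum)[names(m$aa_usage(t))]),
                 unname(m$aa_usage(t)), tolerance = 1e-9)
  }
  expect_equal(sum(m$slopes), 0)
})
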