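test_that("read_cds drops ambiguous records and keeps longest isoforms", {
  seqs <- c(t1 = paste(rep("ATGGCTGCT", 10), collapse = ""),   # 90 nt
            t2 = paste(rep("ATGGCTGCT", 15), collapse = ""),   # 135 nt
            t3 = "ATGGNTTAA",
            t4 = "ATGAAATAA")
  fa <- write_temp_fasta(seqs, width = 50L)
  map <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g1"))
  got <- read_cds(fa, gene_map = map)
  expect_setequal(names(got), c("t2", "t4"))
  expect_equal(unname(got["t2"]), unname(seqs["t2"]))
  rep <- attr(got, "filter_report")
  expect_equal(rep$reason[rep$id == "t3"], "ambiguous_base")
  expect_equal(rep$reason[rep$id == "t1"], "shorter_isoform")
})

test_that("read_cds warns on empty input", {
  fa <- tempfile(fileext = ".fa")
  file.create(fa)
  expect_warning(got <- read_cds(fa), "no records")
  expect_length(got, 0)
})

test_that("prepare_codons applies the start/stop exclusions", {
  u <- prepare_codons(c(a = "ATGGCTTAA"))
  expect_equal(gcsyn:::.CODONS[u$codons[[1]]], "GCT")
  # internal Met is retained
  u <- prepare_codons(c(b = "ATGATGTGA"))
  expect_equal(gcsyn:::.CODONS[u$codons[[1]]], "ATG")
})

test_that("prepare_codons drops invalid records with reasons", {
  seqs <- c(stopin = "ATGTAAGCTTGA",    # internal stop
            notrip = "ATGGCTTA",        # length not multiple of 3
            nostart = "GCTGCTTAA",      # no leading ATG
            bare = "ATGTAA",            # nothing left after trimming
            ok = "ATGGCTAAATAA")
  expect_warning(u <- prepare_codons(seqs), "dropped")
  expect_equal(u$info$source_id, "ok")
  rep <- attr(u, "filter_report")
  expect_equal(setNames(rep$reason, rep$id),
               c(stopin = "internal_stop",
                 notrip = "length_not_multiple_of_3",
                 nostart = "no_start_codon",
                 bare = "empty_after_trimming"))
})

test_that("windows are exact, ordered, and the remainder is discarded", {
  set.seed(42)
  sense <- setdiff(gcsyn:::.CODONS, c("TAA", "TAG", "TGA"))
  cod <- sample(sense, 173, replace = TRUE)
  u <- codon_units(list(x = cod))
  w <- segment_windows(u, 50)
  expect_equal(nrow(w$info), 3)
  expect_true(all(w$info$n_codons == 50))
  # concatenating windows reconstitutes the head of the codon stream
  expect_equal(unlist(w$codons, use.names = FALSE), u$codons[[1]][1:150])
  expect_equal(nrow(segment_windows(codon_units(list(sense[1:50])), 50)$info), 1)
  expect_equal(nrow(segment_windows(codon_units(list(sense[1:49])), 50)$info), 0)
  expect_error(segment_windows(u, 0), "positive integer")
})

test_that("gc_content matches direct base counting in both modes", {
  expect_equal(gc_content(c("GCG", "GCC")), 1)
  expect_equal(gc_content(c("ATT", "AAA")), 0)
  expect_equal(gc_content(c("ATG", "GCC"), "third_position"), 1)
  expect_error(gc_content(character(0)), "empty")
  # consistency oracle against string-level counting, plus bounds
  set.seed(7)
  sense <- setdiff(gcsyn:::.CODONS, c("TAA", "TAG", "TGA"))
  for (i in 1:25) {
    cod <- sample(sense, sample(5:80, 1), replace = TRUE)
    s <- paste(cod, collapse = "")
    chars <- strsplit(s, "")[[1]]
    expect_equal(gc_content(cod), mean(chars %in% c("G", "C")))
    gc3_direct <- mean(chars[seq(3, length(chars), 3)] %in% c("G", "C"))
    expect_equal(gc_content(cod, "third_position"), gc3_direct)
    expect_lte(abs(gc_content(cod) - gc_content(cod, "third_position")), 2 / 3)
  }
})

test_that("unit GC stored in codon_units equals gc_content of its codons", {
  set.seed(11)
  sense <- setdiff(gcsyn:::.CODONS, c("TAA", "TAG", "TGA"))
  cods <- replicate(10, sample(sense, sample(10:60, 1), replace = TRUE),
                    simplify = FALSE)
  u <- codon_units(cods)
  expect_equal(u$info$gc, vapply(cods, gc_content, numeric(1)))
  expect_equal(u$info$gc3,
               vapply(cods, gc_content, numeric(1), mode = "third_position"))
})
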