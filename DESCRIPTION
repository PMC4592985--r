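Package: gcsyn
Title: GC-Content of Synonymous Codons and Amino Acid Usage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how the GC-content of synonymous codons
    (GC_syn) structures amino-acid and codon usage along coding sequences.
    Coding sequences are segmented into fixed-width codon windows (or kept
    whole, or pooled per genome), sorted into narrow GC-content bins, and
    per-bin codon and amino-acid usage tables are built.  Usage trends are
    quantified by per-amino-acid regressions against bin GC, pairwise
    usage-profile regressions between GC bins, and an exact decomposition of
    regional GC-content change into an amino-acid-usage component and a
    synonymous-codon-choice component.  A random-sequence simulator with an
    analytic i.i.d. usage oracle is included as a built-in control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
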