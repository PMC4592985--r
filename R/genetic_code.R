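# Codon index convention used throughout: bases ordered A,C,G,T and codon
# index = 16*(b1-1) + 4*(b2-1) + b3, i.e. 1..64 with the third base varying
# fastest.  All counting code works on these integer indices.

.BASES <- c("A", "C", "G", "T")
.BASE_GC <- c(A = 0L, C = 1L, G = 1L, T = 0L)

.codon_grid <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
.CODONS <- paste0(.BASES[.codon_grid$b1], .BASES[.codon_grid$b2],
                  .BASES[.codon_grid$b3])
.CODON_GC <- unname(.BASE_GC[.codon_grid$b1] + .BASE_GC[.codon_grid$b2] +
                    .BASE_GC[.codon_grid$b3])
.CODON_GC3 <- unname(.BASE_GC[.codon_grid$b3])
.CODON_INDEX <- stats::setNames(seq_len(64L), .CODONS)

.code_cache <- new.env(parent = emptyenv())

#' The genetic code as a codon table
#'
#' Returns the standard nuclear genetic code (by default, taken from
#' [Biostrings::GENETIC_CODE]) as a 64-row data frame, one row per codon,
#' with the encoded amino acid in IUPAC three-letter code (`NA` for stop
#' codons) and the number of G/C bases of each codon.
#'
#' @param file Optional path to a tab-separated override table with columns
#'   `codon` and `aa` (three-letter amino-acid code, or `*` for a stop), one
#'   row per codon, covering all 64 triplets.  Used for robustness testing
#'   with non-standard codes.
#' @return A data frame of class `genetic_code` with columns `codon`, `aa`,
#'   `gc_bases` (0--3) and `gc3` (0/1), plus attributes `stop_codons` and
#'   `sense_codons`.
#' @examples
#' code <- genetic_code()
#' attr(code, "stop_codons")
#' @export
genetic_code <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.code_cache$standard)) return(.code_cache$standard)
    one <- Biostrings::GENETIC_CODE[.CODONS]
    aa3 <- ifelse(one == "*", NA_character_,
                  unname(Biostrings::AMINO_ACID_CODE[one]))
  } else {
    tab <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("codon", "aa") %in% names(tab)))
      stop("genetic code file needs 'codon' and 'aa' columns")
    m <- match(.CODONS, toupper(tab$codon))
    if (anyNA(m)) stop("genetic code file must cover all 64 codons")
    aa3 <- tab$aa[m]
    aa3[aa3 %in% c("*", "Stop", "STOP", "Ter")] <- NA_character_
  }
  code <- data.frame(codon = .CODONS, aa = aa3, gc_bases = .CODON_GC,
                     gc3 = .CODON_GC3, stringsAsFactors = FALSE)
  class(code) <- c("genetic_code", "data.frame")
  attr(code, "stop_codons") <- code$codon[is.na(code$aa)]
  attr(code, "sense_codons") <- code$codon[!is.na(code$aa)]
  validate_genetic_code(code)
  if (is.null(file)) .code_cache$standard <- code
  code
}

validate_genetic_code <- function(code) {
  stopifnot(nrow(code) == 64L, !anyDuplicated(code$codon),
            setequal(code$codon, .CODONS))
  n_stop <- sum(is.na(code$aa))
  if (n_stop == 0L) stop("genetic code has no stop codons")
  if (all(c("TAA", "TAG", "TGA") %in% .CODONS) && n_stop != length(attr(code, "stop_codons")))
    stop("inconsistent stop codon attribute")
  if (any(table(code$aa) < 1L)) stop("every amino acid needs >= 1 codon")
  invisible(code)
}

#' Per-amino-acid GC-content of synonymous codons (GC_syn)
#'
#' For each amino acid, GC_syn is the G+C base fraction pooled over all of
#' its synonymous codons: (total G/C bases among the codons) / (3 x number
#' of codons).  Amino acids are then classified into three groups by fixed
#' cut-points: `low` (GC_syn below `low_cut`), `high` (above `high_cut`) and
#' `intermediate` otherwise.  With the standard nuclear code and the default
#' cut-points this yields four high- (Ala, Gly, Pro, Arg), eleven
#' intermediate- (including Trp and Met) and five low-GC_syn amino acids
#' (Tyr, Phe, Asn, Ile, Lys).
#'
#' @param code A `genetic_code` table.
#' @param low_cut,high_cut Group cut-points on GC_syn.  An amino acid whose
#'   GC_syn falls exactly on a cut-point cannot be assigned and raises an
#'   error (can happen with non-standard codes).
#' @return A data frame of class `gcsyn_profile` with one row per amino
#'   acid: `aa`, `gc_syn`, `n_codons`, `group` (factor high/intermediate/low).
#' @examples
#' prof <- gc_syn_profile()
#' range(prof$gc_syn)          # 1/9 (Ile) .. 10/12 (Ala, Gly, Pro)
#' table(prof$group)
#' @export
gc_syn_profile <- function(code = genetic_code(), low_cut = 0.25,
                           high_cut = 0.70) {
  sense <- code[!is.na(code$aa), ]
  gc_tot <- tapply(sense$gc_bases, sense$aa, sum)
  n_cod <- tapply(sense$aa, sense$aa, length)
  aa <- sort(names(gc_tot))
  gc_syn <- as.numeric(gc_tot[aa]) / (3 * as.numeric(n_cod[aa]))
  if (any(abs(gc_syn - low_cut) < 1e-12) || any(abs(gc_syn - high_cut) < 1e-12))
    stop("ambiguous grouping: a GC_syn value falls exactly on a cut-point")
  group <- ifelse(gc_syn < low_cut, "low",
                  ifelse(gc_syn > high_cut, "high", "intermediate"))
  out <- data.frame(aa = aa, gc_syn = gc_syn,
                    n_codons = as.integer(n_cod[aa]),
                    group = factor(group, levels = c("high", "intermediate", "low")),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gcsyn_profile", "data.frame")
  out
}
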