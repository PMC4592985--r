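# Analysis units are held as a `codon_units` object: a list of integer codon
# index vectors plus an `info` data frame with one row per unit carrying the
# unit's GC and GC3 fractions.  GC here is always computed over the unit's
# retained codons (post start/stop exclusion), so usage-weighted
# reconstruction identities hold exactly.

new_codon_units <- function(codons, ids, unit_kind, extra = NULL) {
  n <- lengths(codons)
  gc_sum <- vapply(codons, function(i) sum(.CODON_GC[i]), numeric(1))
  gc3_sum <- vapply(codons, function(i) sum(.CODON_GC3[i]), numeric(1))
  info <- data.frame(source_id = as.character(ids),
                     unit_kind = rep_len(unit_kind, length(n)),
                     n_codons = as.integer(n),
                     gc = ifelse(n > 0, gc_sum / (3 * n), NA_real_),
                     gc3 = ifelse(n > 0, gc3_sum / n, NA_real_),
                     stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(extra)) info <- cbind(info, extra)
  structure(list(codons = codons, info = info), class = "codon_units")
}

#' Build analysis units from codon vectors
#'
#' Low-level constructor turning a list of codon character vectors (or
#' uninterrupted DNA strings with length a multiple of 3) into a
#' `codon_units` object with per-unit GC and GC3 fractions.  No start/stop
#' trimming is applied; see [prepare_codons()] for the CDS preparation rules.
#'
#' @param x A list of character vectors of codons, or a character vector of
#'   in-frame DNA strings.
#' @param ids Unit identifiers; defaults to `names(x)` or an index.
#' @param unit_kind Label stored per unit (`"cds"`, `"window"`, ...).
#' @return A `codon_units` object.
#' @examples
#' u <- codon_units(list(c("GCT", "AAA"), "GCGGCC"))
#' u$info$gc
#' @export
codon_units <- function(x, ids = NULL, unit_kind = "cds") {
  if (is.character(x)) x <- as.list(x)
  codons <- lapply(x, function(s) {
    if (length(s) == 1L && nchar(s) > 3L) {
      if (nchar(s) %% 3L != 0L) stop("sequence length not a multiple of 3")
      s <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    }
    idx <- unname(.CODON_INDEX[toupper(s)])
    if (anyNA(idx)) stop("invalid codon: ", paste(s[is.na(idx)], collapse = ","))
    idx
  })
  if (is.null(ids)) ids <- if (!is.null(names(x))) names(x) else seq_along(x)
  new_codon_units(codons, ids, unit_kind)
}

#' Read coding sequences from FASTA with basic filtering
#'
#' Reads a (possibly line-wrapped) multi-record FASTA of CDS, drops records
#' containing ambiguous bases (anything outside A/C/G/T), and, when a
#' transcript-to-gene map is supplied, keeps only the longest CDS per gene.
#' Dropped records are collected in a filter report attached as the
#' `"filter_report"` attribute (columns `id`, `reason`).
#'
#' @param file Path to a FASTA file.
#' @param gene_map Optional transcript-to-gene map: a two-column data frame
#'   (`transcript_id`, `gene_id`) or the path of a headerless TSV with those
#'   two columns.  Transcripts absent from the map are treated as their own
#'   gene.
#' @return A named character vector of uppercase sequences (names are the
#'   first whitespace-delimited token of each FASTA header), with attribute
#'   `filter_report`.
#' @export
read_cds <- function(file, gene_map = NULL) {
  x <- Biostrings::readDNAStringSet(file)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- stats::setNames(toupper(as.character(x)), ids)
  report <- data.frame(id = character(), reason = character(),
                       stringsAsFactors = FALSE)
  if (length(seqs) == 0L) {
    warning("FASTA file contains no records: ", file)
  } else {
    amb <- grepl("[^ACGT]", seqs)
    if (any(amb))
      report <- rbind(report, data.frame(id = ids[amb],
                                         reason = "ambiguous_base"))
    seqs <- seqs[!amb]
  }
  if (!is.null(gene_map) && length(seqs)) {
    if (is.character(gene_map)) {
      gene_map <- utils::read.delim(gene_map, header = FALSE,
                                    stringsAsFactors = FALSE)[, 1:2]
    }
    names(gene_map)[1:2] <- c("transcript_id", "gene_id")
    gene <- gene_map$gene_id[match(names(seqs), gene_map$transcript_id)]
    gene[is.na(gene)] <- names(seqs)[is.na(gene)]
    keep <- unlist(lapply(split(seq_along(seqs), gene), function(i) {
      i[which.max(nchar(seqs)[i])]
    }), use.names = FALSE)
    dropped <- setdiff(seq_along(seqs), keep)
    if (length(dropped))
      report <- rbind(report, data.frame(id = names(seqs)[dropped],
                                         reason = "shorter_isoform"))
    seqs <- seqs[sort(keep)]
  }
  attr(seqs, "filter_report") <- report
  seqs
}

#' Prepare CDS codon streams for usage analysis
#'
#' Validates each CDS and converts it to its analysed codon list: the
#' leading start codon (the first Met, encoded by ATG) and the trailing stop
#' codon are excluded, internal Met codons are retained.  Records are
#' dropped (with a reason in the filter report) when their length is not a
#' multiple of 3, they do not begin with ATG, they contain an in-frame
#' internal stop codon, or nothing remains after trimming.  A missing
#' trailing stop is tolerated (the record is kept in full after removing the
#' start codon).
#'
#' @param seqs Named character vector of CDS (e.g. from [read_cds()]).
#' @param code A `genetic_code` table.
#' @return A `codon_units` object of kind `"cds"` with attribute
#'   `filter_report`.
#' @examples
#' u <- prepare_codons(c(a = "ATGGCTTAA"))
#' # the single retained codon is GCT
#' @export
prepare_codons <- function(seqs, code = genetic_code()) {
  stop_idx <- unname(.CODON_INDEX[attr(code, "stop_codons")])
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  keep <- logical(length(seqs))
  codons <- vector("list", length(seqs))
  reasons <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n %% 3L != 0L) { reasons[i] <- "length_not_multiple_of_3"; next }
    idx <- unname(.CODON_INDEX[substring(s, seq(1L, n, 3L), seq(3L, n, 3L))])
    if (anyNA(idx)) { reasons[i] <- "ambiguous_base"; next }
    if (.CODONS[idx[1L]] != "ATG") { reasons[i] <- "no_start_codon"; next }
    if (idx[length(idx)] %in% stop_idx) idx <- idx[-length(idx)]
    idx <- idx[-1L]
    if (any(idx %in% stop_idx)) { reasons[i] <- "internal_stop"; next }
    if (length(idx) == 0L) { reasons[i] <- "empty_after_trimming"; next }
    keep[i] <- TRUE
    codons[[i]] <- idx
  }
  if (any(!keep))
    warning(sum(!keep), " CDS dropped during preparation")
  units <- new_codon_units(codons[keep], ids[keep], "cds")
  attr(units, "filter_report") <-
    data.frame(id = ids[!keep], reason = reasons[!keep],
               stringsAsFactors = FALSE)
  units
}

#' Dissect units into fixed-width codon windows
#'
#' Each unit's codon stream is cut sequentially into non-overlapping windows
#' of exactly `width` consecutive codons; the trailing remainder shorter
#' than `width` is discarded.  Units shorter than `width` contribute no
#' window.
#'
#' @param units A `codon_units` object (typically prepared CDS).
#' @param width Window width in codons (default 50; 30 and 100 are common
#'   alternatives).
#' @return A `codon_units` object of kind `"window"`; `info` carries the
#'   originating `source_id` and a `window` index.
#' @export
segment_windows <- function(units, width = 50L) {
  if (length(width) != 1L || !is.finite(width) || width <= 0 ||
      width != as.integer(width))
    stop("'width' must be a positive integer")
  width <- as.integer(width)
  out_codons <- list()
  out_ids <- character()
  out_win <- integer()
  for (i in seq_along(units$codons)) {
    v <- units$codons[[i]]
    k <- length(v) %/% width
    if (k == 0L) next
    w <- split(v[seq_len(k * width)], rep(seq_len(k), each = width))
    out_codons <- c(out_codons, unname(w))
    out_ids <- c(out_ids, rep(units$info$source_id[i], k))
    out_win <- c(out_win, seq_len(k))
  }
  new_codon_units(out_codons, out_ids, "window",
                  extra = data.frame(window = out_win))
}

#' Pool units into per-group aggregate units
#'
#' Concatenates the codon streams of all units sharing a group label into a
#' single pooled unit (e.g. one codon pool per genome).
#'
#' @param units A `codon_units` object.
#' @param groups Character vector of group labels, one per unit.
#' @return A `codon_units` object of kind `"genome"`, one unit per label.
#' @export
pool_units <- function(units, groups) {
  stopifnot(length(groups) == nrow(units$info))
  sp <- split(units$codons, as.character(groups))
  pooled <- lapply(sp, function(l) unlist(l, use.names = FALSE))
  new_codon_units(pooled, names(pooled), "genome")
}

#' GC-content of a codon vector or sequence string
#'
#' @param x Character vector of codons, or a single in-frame DNA string.
#' @param mode `"all_positions"` counts G/C over all three bases of every
#'   codon; `"third_position"` counts only the third base (GC3).
#' @return A fraction in \[0, 1\].
#' @examples
#' gc_content(c("GCG", "GCC"))                      # 1
#' gc_content(c("ATG", "GCC"), "third_position")    # 1
#' @export
gc_content <- function(x, mode = c("all_positions", "third_position")) {
  mode <- match.arg(mode)
  if (length(x) == 1L && nchar(x) > 3L)
    x <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  if (length(x) == 0L) stop("empty unit")
  idx <- unname(.CODON_INDEX[toupper(x)])
  if (anyNA(idx)) stop("invalid codon in input")
  if (mode == "all_positions") sum(.CODON_GC[idx]) / (3 * length(idx))
  else sum(.CODON_GC3[idx]) / length(idx)
}

#' @export
print.codon_units <- function(x, ...) {
  cat("codon_units:", nrow(x$info), "units (",
      paste(unique(x$info$unit_kind), collapse = ","), "), ",
      sum(x$info$n_codons), "codons\n")
  if (nrow(x$info)) {
    cat("  GC range:", sprintf("%.3f-%.3f", min(x$info$gc), max(x$info$gc)),
        "\n")
  }
  invisible(x)
}
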