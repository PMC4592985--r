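#' Pipeline configuration
#'
#' Collects and validates every knob of a full analysis run.  Exactly one
#' input source must be given: a CDS FASTA (`input_fasta`) or a
#' random-sequence control spec (`simulate`).
#'
#' @param input_fasta Path to a CDS FASTA, or `NULL`.
#' @param simulate A [random_seq_spec()], or `NULL`.
#' @param gene_map Optional transcript-to-gene map (path or data frame),
#'   see [read_cds()].
#' @param group_labels Optional per-record group labels: path of a
#'   headerless two-column TSV (`id`, `group`) or a data frame.  Used to
#'   restrict the run (`group`) or to define genome pools
#'   (`unit_kind = "genome"`).
#' @param group Optional single label: only records with this label are
#'   analysed.
#' @param unit_kind `"window"`, `"cds"` or `"genome"`.
#' @param window_size Window width in codons (window unit only).
#' @param gc_mode `"all_positions"` or `"third_position"`.
#' @param bin_start,bin_end,bin_step GC bin range and width.
#' @param n_max Largest GC-N gap for pairwise regressions (default: all).
#' @param decomp_bins Length-2 vector of (low, high) bin indices for the
#'   decomposition; `NULL` picks the first and last nonempty bin.
#' @param min_codons Low-confidence threshold per bin.
#' @param seed Seed applied at the start of the run.
#' @param out_dir Output directory for the report bundle.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_fasta = NULL, simulate = NULL, gene_map = NULL,
                       group_labels = NULL, group = NULL,
                       unit_kind = c("window", "cds", "genome"),
                       window_size = 50L,
                       gc_mode = c("all_positions", "third_position"),
                       bin_start = 0.30, bin_end = 0.80, bin_step = 0.01,
                       n_max = NULL, decomp_bins = NULL, min_codons = 1000,
                       seed = 1L, out_dir = tempfile("gcsyn_run_")) {
  unit_kind <- match.arg(unit_kind)
  gc_mode <- match.arg(gc_mode)
  if (is.null(input_fasta) == is.null(simulate))
    stop("give exactly one of 'input_fasta' or 'simulate'")
  if (!is.null(input_fasta) && !file.exists(input_fasta))
    stop("input FASTA not found: ", input_fasta)
  if (!is.null(simulate)) stopifnot(inherits(simulate, "random_seq_spec"))
  if (!is.null(gene_map) && is.character(gene_map) && !file.exists(gene_map))
    stop("gene map not found: ", gene_map)
  if (!is.null(group_labels) && is.character(group_labels) &&
      !file.exists(group_labels))
    stop("group label file not found: ", group_labels)
  gc_bins(bin_start, bin_end, bin_step)  # validates the range
  if (!is.null(decomp_bins)) stopifnot(length(decomp_bins) == 2L)
  structure(list(input_fasta = input_fasta, simulate = simulate,
                 gene_map = gene_map, group_labels = group_labels,
                 group = group, unit_kind = unit_kind,
                 window_size = as.integer(window_size), gc_mode = gc_mode,
                 bin_start = bin_start, bin_end = bin_end,
                 bin_step = bin_step, n_max = n_max,
                 decomp_bins = decomp_bins, min_codons = min_codons,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.write_tsv <- function(df, path, md5) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# config_md5: ", md5), con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: input loading (or control simulation), CDS
#' preparation, unit construction (windows / whole CDS / per-genome pools),
#' GC binning and usage tables, per-amino-acid trends, group series,
#' usage-vs-codon-number correlations, pairwise GC-N regressions with their
#' decay curve, and the GC- and AT-direction decompositions.  All tables
#' are written as TSV into `config$out_dir`, each stamped with the MD5 of
#' the serialised configuration; a deterministic run log records counts at
#' every filtering step.  Given the same configuration (including seed) the
#' bundle is byte-identical across runs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all computed tables (`usage`, `trends`,
#'   `groups`, `correlations`, `pairs_codon`, `pairs_aa`, `curve_codon`,
#'   `curve_aa`, `decomposition_gc`, `decomposition_at`, `filter_report`,
#'   `config`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  code <- genetic_code()
  profile <- gc_syn_profile(code)
  filter_report <- data.frame(id = character(), reason = character(),
                              stringsAsFactors = FALSE)

  labels <- NULL
  if (!is.null(config$group_labels)) {
    labels <- config$group_labels
    if (is.character(labels))
      labels <- utils::read.delim(labels, header = FALSE,
                                  stringsAsFactors = FALSE)[, 1:2]
    names(labels)[1:2] <- c("id", "group")
  }

  if (!is.null(config$simulate)) {
    say("INFO simulating random sequences: ",
        length(config$simulate$gc_targets), " targets x ",
        config$simulate$n_per_bin, " sequences")
    units <- random_sequences(config$simulate)
  } else {
    seqs <- read_cds(config$input_fasta, gene_map = config$gene_map)
    filter_report <- rbind(filter_report, attr(seqs, "filter_report"))
    say("INFO loaded ", length(seqs), " CDS from ", config$input_fasta,
        " (", nrow(filter_report), " dropped at load)")
    if (!is.null(config$group) && !is.null(labels)) {
      sel <- names(seqs) %in% labels$id[labels$group == config$group]
      say("INFO group filter '", config$group, "': ", sum(sel), " of ",
          length(seqs), " records kept")
      seqs <- seqs[sel]
    }
    units <- suppressWarnings(prepare_codons(seqs, code))
    filter_report <- rbind(filter_report, attr(units, "filter_report"))
    say("INFO prepared ", nrow(units$info), " CDS (",
        nrow(attr(units, "filter_report")), " dropped in preparation)")
  }

  if (config$unit_kind == "window") {
    units <- segment_windows(units, config$window_size)
    say("INFO segmented into ", nrow(units$info), " windows of ",
        config$window_size, " codons")
  } else if (config$unit_kind == "genome") {
    grp <- if (!is.null(labels))
      labels$group[match(units$info$source_id, labels$id)]
    else rep("all", nrow(units$info))
    grp[is.na(grp)] <- "unlabelled"
    units <- pool_units(units, grp)
    say("INFO pooled into ", nrow(units$info), " genome units")
  }
  if (nrow(units$info) == 0L) {
    .write_tsv(filter_report, file.path(config$out_dir, "filter_report.tsv"),
               "NA")
    stop("no units survive filtering; see filter_report.tsv")
  }

  usage <- usage_table(units, start = config$bin_start, end = config$bin_end,
                       step = config$bin_step, gc_mode = config$gc_mode,
                       min_codons = config$min_codons, code = code)
  n_binned <- sum(usage$bins$n_units)
  say("INFO binned ", n_binned, " of ", nrow(units$info), " units (",
      nrow(units$info) - n_binned, " outside the GC range); ",
      sum(usage$bins$n_codons > 0), " nonempty bins")
  if (any(usage$bins$low_confidence))
    say("WARN ", sum(usage$bins$low_confidence),
        " bins below the ", config$min_codons, "-codon threshold")

  trends <- tryCatch(usage_slopes(usage, profile), error = function(e) {
    say("WARN trend fits skipped: ", conditionMessage(e)); NULL
  })
  groups <- group_usage_series(usage, profile)
  correlations <- codon_number_correlation(usage, profile)
  nbins <- nrow(usage$bins)
  n_max <- if (is.null(config$n_max)) nbins - 1L else config$n_max
  pairs_codon <- pair_stats(usage, "codon61", n_max = n_max)
  pairs_aa <- pair_stats(usage, "aa20", n_max = n_max)
  curve_codon <- delta_gc_curve(pairs_codon)
  curve_aa <- delta_gc_curve(pairs_aa)
  lowhi <- config$decomp_bins
  decomposition_gc <- tryCatch(
    decompose_delta_gc(usage, lowhi[1], lowhi[2], profile = profile,
                       code = code),
    error = function(e) { say("WARN decomposition skipped: ",
                              conditionMessage(e)); NULL })
  decomposition_at <- tryCatch(
    at_decomposition(usage, lowhi[1], lowhi[2], profile = profile,
                     code = code),
    error = function(e) NULL)

  cfg_json <- file.path(config$out_dir, "run_config.json")
  cfg_out <- unclass(config)
  cfg_out$simulate <- if (is.null(config$simulate)) NULL
                      else unclass(config$simulate)
  jsonlite::write_json(cfg_out, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  md5 <- unname(tools::md5sum(cfg_json))

  out <- c(
    usage_codon = "usage_codon.tsv", usage_aa = "usage_aa.tsv",
    trends = "trends_aa.tsv", groups = "group_series.tsv",
    correlations = "codon_number_correlation.tsv",
    pairs = "pair_stats.tsv", curve = "pair_curve.tsv",
    dgc = "decomposition_gc.tsv", dat = "decomposition_at.tsv",
    filt = "filter_report.tsv")
  out <- stats::setNames(file.path(config$out_dir, out), names(out))
  meta <- .usage_bin_meta(usage)
  .write_tsv(cbind(meta, as.data.frame(usage$codon_freq)), out["usage_codon"], md5)
  .write_tsv(cbind(meta, as.data.frame(usage$aa_freq)), out["usage_aa"], md5)
  if (!is.null(trends)) .write_tsv(trends, out["trends"], md5)
  .write_tsv(groups, out["groups"], md5)
  .write_tsv(correlations, out["correlations"], md5)
  .write_tsv(rbind(pairs_codon, pairs_aa), out["pairs"], md5)
  curve <- rbind(cbind(vector_kind = "codon61", curve_codon),
                 cbind(vector_kind = "aa20", curve_aa))
  .write_tsv(curve, out["curve"], md5)
  if (!is.null(decomposition_gc))
    .write_tsv(as.data.frame(decomposition_gc), out["dgc"], md5)
  if (!is.null(decomposition_at))
    .write_tsv(as.data.frame(decomposition_at), out["dat"], md5)
  .write_tsv(filter_report, out["filt"], md5)
  logcon <- file(file.path(config$out_dir, "run_log.txt"), open = "wb")
  writeLines(c(paste0("# config_md5: ", md5), log), logcon, sep = "\n")
  close(logcon)

  invisible(list(usage = usage, trends = trends, groups = groups,
                 correlations = correlations, pairs_codon = pairs_codon,
                 pairs_aa = pairs_aa, curve_codon = curve_codon,
                 curve_aa = curve_aa, decomposition_gc = decomposition_gc,
                 decomposition_at = decomposition_at,
                 filter_report = filter_report, config = config,
                 config_md5 = md5))
}
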