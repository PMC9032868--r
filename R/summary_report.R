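#' Length summary of a sequence collection
#'
#' Count, total bp, mean length (half-up, one decimal), min/max, and a
#' fixed-width histogram (right-open bins `[k*w, (k+1)*w)`) covering 0 to
#' the maximum length.
#'
#' @param records [Biostrings::DNAStringSet] or character vector.
#' @param bin_width histogram bin width in bp (default 1000).
#' @return list `n, total_bp, mean_len, min_len, max_len, histogram`
#'   (data.frame `bin_start, bin_end, count`). Empty input gives a zero
#'   summary with an empty histogram.
#' @export
summarize_lengths <- function(records, bin_width = 1000) {
  if (bin_width <= 0) stop("bin_width must be positive")
  len <- if (is.character(records)) nchar(records) else
    Biostrings::width(records)
  if (!length(len)) {
    return(list(n = 0L, total_bp = 0, mean_len = NA_real_,
                min_len = NA_integer_, max_len = NA_integer_,
                histogram = data.frame(bin_start = integer(0),
                                       bin_end = integer(0),
                                       count = integer(0))))
  }
  bins <- seq(0, max(len), by = bin_width)
  idx <- findInterval(len, bins)   # right-open bins
  counts <- tabulate(idx, nbins = length(bins))
  list(
    n = length(len), total_bp = sum(len),
    mean_len = round_half_up(mean(len), 1),
    min_len = min(len), max_len = max(len),
    histogram = data.frame(bin_start = as.integer(bins),
                           bin_end = as.integer(bins + bin_width),
                           count = counts)
  )
}

#' Percentages of labelled counts over a common denominator
#'
#' BUSCO-style arithmetic: each count is expressed as a percentage of one
#' denominator, rounded half-up to the requested number of decimals.
#' Categories need not be exhaustive (their sum may fall short of the
#' denominator).
#'
#' @param counts named non-negative integer vector.
#' @param denominator positive total.
#' @param digits decimal places (default 1).
#' @return named numeric vector of percentages.
#' @export
category_percentages <- function(counts, denominator, digits = 1) {
  if (denominator <= 0) stop("denominator must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  percent_of(counts, denominator, digits)
}

#' Run the full synthetic-to-report pipeline
#'
#' Convenience wrapper used for end-to-end determinism checks and the
#' command-line `report` subcommand: simulates a read set, classifies it,
#' clusters the FLNC inserts, collapses to representatives, and runs the
#' SSR, ORF, built-in lncRNA and AS stages, writing every report as TSV or
#' JSON under `out_dir`. All randomness derives from `seed`, so two runs
#' with the same seed produce byte-identical files.
#'
#' @param config a [fixture_config()].
#' @param out_dir output directory (created).
#' @param seed integer seed for the run.
#' @param identity_threshold clustering threshold (default 0.99).
#' @return named list of the in-memory results, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = 1,
                         identity_threshold = 0.99) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_reads(config)
  write_sequences(sim$reads, file.path(out_dir, "reads.fasta"))
  write_truth_table(sim$truth, out_dir)

  cls <- classify_reads(sim$reads,
                        primers = c(primer_5 = config$primer_5,
                                    primer_3 = config$primer_3))
  utils::write.table(cls[setdiff(names(cls), "insert")],
                     file.path(out_dir, "flnc_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inserts <- flnc_inserts(cls)
  write_sequences(inserts, file.path(out_dir, "flnc.fasta"))

  clusters <- cluster_sequences(inserts, identity_threshold = identity_threshold)
  utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reps <- collapse_representatives(clusters, inserts)
  write_sequences(reps, file.path(out_dir, "transcripts.fasta"))

  hits <- find_ssrs(reps)
  utils::write.table(hits, file.path(out_dir, "ssr_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ssr_gff3(hits, file.path(out_dir, "ssr.gff3"))
  ssr_rep <- ssr_report(hits, reps)
  utils::write.table(ssr_rep$summary, file.path(out_dir, "ssr_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ssr_rep$unit_counts,
                     file.path(out_dir, "ssr_unit_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  orfs <- find_best_orfs(reps, min_aa = 100)
  utils::write.table(orfs, file.path(out_dir, "orfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bins <- orf_length_bins(orfs)
  utils::write.table(bins, file.path(out_dir, "orf_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nc_ids <- builtin_noncoding_calls(reps)
  lnc <- consensus_lncrna(reps, list(BUILTIN = nc_ids), min_len = 200)
  utils::write.table(lnc$calls, file.path(out_dir, "lncrna_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lensum <- summarize_lengths(sim$reads)
  summary <- list(
    n_reads = lensum$n, total_bp = lensum$total_bp,
    mean_read_len = lensum$mean_len,
    n_flnc = sum(cls$label == "FLNC"),
    n_chimeric = sum(cls$label == "CHIMERIC"),
    flnc_rate_pct = flnc_rate(sum(cls$label == "FLNC"), nrow(cls)),
    n_clusters = max(clusters$cluster, 0),
    n_transcripts = length(reps),
    n_ssrs = nrow(hits),
    n_orfs = nrow(orfs),
    n_complete_orfs = sum(orfs$completeness == "complete"),
    n_lncrna = sum(lnc$calls$consensus)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, classification = cls, clusters = clusters,
                 transcripts = reps, ssr = ssr_rep, orfs = orfs,
                 bins = bins, lncrna = lnc, summary = summary))
}
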