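#' Default cDNA primer pair for read simulation and classification
#'
#' The common template-switching adapter pair used in full-length cDNA
#' library preparation. `primer_5` ends in the G-rich template-switch tail;
#' `primer_3` is the oligo-dT anchor sequence. A full-length read is laid out
#' as `primer_5 + insert + poly(A) + reverseComplement(primer_3)`.
#'
#' @return named character vector with elements `primer_5` and `primer_3`.
#' @export
default_primers <- function() {
  c(primer_5 = "AAGCAGTGGTATCAACGCAGAGTACATGGGG",
    primer_3 = "AAGCAGTGGTATCAACGCAGAGTAC")
}

#' Configuration for the synthetic read generator
#'
#' Defines the simulated library: a log-normal read-length model centred
#' near 2 kb (the scale typical of full-length cDNA consensus reads), the
#' primer pair flanking each insert, a geometric poly(A)-length model, the
#' class mixture (full-length non-chimeric, non-full-length, chimeric), and
#' optional planted features (SSR motifs and complete ORFs inside inserts).
#'
#' @param n_reads number of reads to simulate.
#' @param length_mean,length_sd mean and standard deviation (bp) of the
#'   log-normal insert length distribution.
#' @param primer_5,primer_3 cDNA primer sequences (see [default_primers()]).
#' @param polya_len_mean mean poly(A) tail length (bp); lengths are drawn
#'   geometrically above a floor of 20 bp and may carry up to 2 non-A
#'   interruptions, to exercise tolerant poly(A) detection.
#' @param fraction_flnc,fraction_missing_primer,fraction_chimeric class
#'   probabilities; the remainder (if any) becomes non-full-length reads
#'   missing the poly(A) tail instead of a primer.
#' @param ssr_spec `NULL` or a data.frame with columns `motif`, `repeats`,
#'   `count`: plant `count` inserts containing `motif` repeated `repeats`
#'   times.
#' @param orf_spec `NULL` or a data.frame with columns `aa_len`, `count`:
#'   plant `count` inserts containing a complete ORF (`ATG`, `aa_len - 1`
#'   random non-stop codons, stop codon).
#' @return a `fixture_config` list, validated.
#' @export
fixture_config <- function(n_reads = 1000,
                           length_mean = 2000, length_sd = 800,
                           primer_5 = default_primers()[["primer_5"]],
                           primer_3 = default_primers()[["primer_3"]],
                           polya_len_mean = 30,
                           fraction_flnc = 0.8,
                           fraction_missing_primer = 0.12,
                           fraction_chimeric = 0.05,
                           ssr_spec = NULL,
                           orf_spec = NULL) {
  fr <- c(fraction_flnc, fraction_missing_primer, fraction_chimeric)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12) {
    stop("class fractions must lie in [0,1] and sum to at most 1")
  }
  if (n_reads < 1 || length_mean <= 0 || length_sd <= 0 || polya_len_mean <= 0) {
    stop("n_reads and all length parameters must be positive")
  }
  if (grepl("[^ACGT]", primer_5) || grepl("[^ACGT]", primer_3)) {
    stop("primers must be plain ACGT strings")
  }
  structure(list(
    n_reads = as.integer(n_reads), length_mean = length_mean,
    length_sd = length_sd, primer_5 = primer_5, primer_3 = primer_3,
    polya_len_mean = polya_len_mean, fraction_flnc = fraction_flnc,
    fraction_missing_primer = fraction_missing_primer,
    fraction_chimeric = fraction_chimeric,
    ssr_spec = ssr_spec, orf_spec = orf_spec
  ), class = "fixture_config")
}

draw_insert_lengths <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(200L, pmin(12000L, as.integer(round(stats::rlnorm(n, meanlog, sdlog)))))
}

draw_polya <- function(len_mean, min_len = 20L) {
  extra <- stats::rgeom(1, 1 / max(1, len_mean - min_len + 1))
  len <- min_len + extra
  tail <- rep("A", len)
  # up to 2 interior non-A interruptions, kept under a 10% non-A fraction
  n_int <- min(sample(0:2, 1), floor(0.08 * len))
  if (n_int > 0 && len > 6) {
    pos <- sample(3:(len - 3), n_int)
    tail[pos] <- sample(c("C", "G", "T"), n_int, replace = TRUE)
  }
  paste(tail, collapse = "")
}

# random codons avoiding in-frame stops
random_codons <- function(n_aa) {
  codons <- character(n_aa)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(n_aa)) {
    repeat {
      cd <- random_dna(3)
      if (!(cd %in% stops)) break
    }
    codons[i] <- cd
  }
  codons[1] <- "ATG"
  paste(codons, collapse = "")
}

#' Simulate a read set with a truth table
#'
#' Generates `config$n_reads` reads. FLNC reads have the full layout
#' `primer_5 + insert + poly(A) + revcomp(primer_3)`; non-full-length reads
#' lack either the 5' primer or the poly(A) tail; chimeric reads carry an
#' interior copy of the 5' primer (two fused inserts), the signature of a
#' cDNA fusion artifact. Planted SSRs and ORFs are embedded in FLNC inserts
#' and recorded with exact coordinates. All randomness flows from the
#' session RNG: call `set.seed()` beforehand for reproducibility; the same
#' seed gives byte-identical output.
#'
#' @param config a [fixture_config()].
#' @return list with `reads` (a [Biostrings::DNAStringSet]) and `truth`, a
#'   list of data.frames: `reads` (id, label, insert coordinates and
#'   sequence), `ssrs` and `orfs` (planted features, coordinates both within
#'   the read and within the insert).
#' @export
make_reads <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_reads
  labels <- sample(
    c("FLNC", "NON_FL_PRIMER", "NON_FL_POLYA", "CHIMERIC"), n, replace = TRUE,
    prob = c(config$fraction_flnc, config$fraction_missing_primer,
             1 - config$fraction_flnc - config$fraction_missing_primer -
               config$fraction_chimeric,
             config$fraction_chimeric)
  )
  ins_len <- draw_insert_lengths(n, config$length_mean, config$length_sd)
  p5 <- config$primer_5
  p3rc <- revcomp_chr(config$primer_3)

  # assign planted features to distinct FLNC reads
  flnc_idx <- which(labels == "FLNC")
  plant <- data.frame(read = integer(0), kind = character(0), key = integer(0))
  n_ssr <- if (is.null(config$ssr_spec)) 0 else sum(config$ssr_spec$count)
  n_orf <- if (is.null(config$orf_spec)) 0 else sum(config$orf_spec$count)
  if (n_ssr + n_orf > length(flnc_idx)) {
    stop("more planted features than FLNC reads available")
  }
  carriers <- if (n_ssr + n_orf > 0) sample(flnc_idx, n_ssr + n_orf) else integer(0)

  seqs <- character(n)
  truth_reads <- data.frame(
    id = sprintf("read%05d", seq_len(n)), label = character(n),
    insert_start = NA_integer_, insert_end = NA_integer_,
    insert = NA_character_, stringsAsFactors = FALSE
  )
  ssr_rows <- list(); orf_rows <- list()

  carrier_feats <- character(0)
  carrier_keys <- integer(0)
  if (n_ssr > 0) {
    carrier_feats <- c(carrier_feats, rep("ssr", n_ssr))
    carrier_keys <- c(carrier_keys, rep(seq_len(nrow(config$ssr_spec)),
                                        config$ssr_spec$count))
  }
  if (n_orf > 0) {
    carrier_feats <- c(carrier_feats, rep("orf", n_orf))
    carrier_keys <- c(carrier_keys, rep(seq_len(nrow(config$orf_spec)),
                                        config$orf_spec$count))
  }

  for (i in seq_len(n)) {
    L <- ins_len[i]
    insert <- random_dna(L)
    feat <- which(carriers == i)
    feat_kind <- if (length(feat)) carrier_feats[feat[1]] else ""
    feat_rec <- NULL
    if (feat_kind == "ssr") {
      spec <- config$ssr_spec[carrier_keys[feat[1]], ]
      block <- strrep(spec$motif, spec$repeats)
      if (nchar(block) + 2 > L) stop("planted SSR longer than insert")
      at <- sample(2:(L - nchar(block)), 1)
      insert <- paste0(substr(insert, 1, at - 1), block,
                       substr(insert, at + nchar(block), L))
      insert <- substr(insert, 1, L)
      feat_rec <- data.frame(read_id = truth_reads$id[i], motif = spec$motif,
                             repeats = spec$repeats, insert_start = at,
                             insert_end = at + nchar(block) - 1L)
    } else if (feat_kind == "orf") {
      spec <- config$orf_spec[carrier_keys[feat[1]], ]
      cds <- paste0(random_codons(spec$aa_len), "TAA")
      if (nchar(cds) + 2 > L) stop("planted ORF longer than insert")
      at <- sample(2:(L - nchar(cds)), 1)
      insert <- paste0(substr(insert, 1, at - 1), cds,
                       substr(insert, at + nchar(cds), L))
      insert <- substr(insert, 1, L)
      feat_rec <- data.frame(read_id = truth_reads$id[i], aa_len = spec$aa_len,
                             insert_start = at,
                             insert_end = at + nchar(cds) - 1L)
    }

    lab <- labels[i]
    if (lab == "FLNC") {
      tail <- draw_polya(config$polya_len_mean)
      seqs[i] <- paste0(p5, insert, tail, p3rc)
      truth_reads$label[i] <- "FLNC"
      truth_reads$insert_start[i] <- nchar(p5) + 1L
      truth_reads$insert_end[i] <- nchar(p5) + L
      truth_reads$insert[i] <- insert
    } else if (lab == "NON_FL_PRIMER") {
      tail <- draw_polya(config$polya_len_mean)
      seqs[i] <- paste0(insert, tail, p3rc)   # 5' primer lost
      truth_reads$label[i] <- "NON_FL"
    } else if (lab == "NON_FL_POLYA") {
      seqs[i] <- paste0(p5, insert, p3rc)     # tail lost
      truth_reads$label[i] <- "NON_FL"
    } else {
      half <- random_dna(max(200L, L %/% 2))
      tail <- draw_polya(config$polya_len_mean)
      seqs[i] <- paste0(p5, insert, p5, half, tail, p3rc)
      truth_reads$label[i] <- "CHIMERIC"
    }
    if (!is.null(feat_rec)) {
      off <- if (lab %in% c("FLNC", "NON_FL_POLYA", "CHIMERIC")) nchar(p5) else 0L
      feat_rec$read_start <- feat_rec$insert_start + off
      feat_rec$read_end <- feat_rec$insert_end + off
      if (feat_kind == "ssr") ssr_rows[[length(ssr_rows) + 1L]] <- feat_rec
      else orf_rows[[length(orf_rows) + 1L]] <- feat_rec
    }
  }

  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- truth_reads$id
  list(
    reads = reads,
    truth = list(
      reads = truth_reads,
      ssrs = if (length(ssr_rows)) do.call(rbind, ssr_rows) else NULL,
      orfs = if (length(orf_rows)) do.call(rbind, orf_rows) else NULL
    )
  )
}

#' Construct one alternative-splicing test pair
#'
#' Sequence A is random of length `total_len`; sequence B is A with the
#' block `gap_start..gap_start + gap_len - 1` (1-based) deleted. Aligning A
#' against B yields two HSPs that are contiguous on B and separated by the
#' deleted block on A, the geometry of a candidate splicing event. The
#' returned `expected` record states whether the pair satisfies the calling
#' rules (gap strictly longer than `min_gap`, both gap boundaries at least
#' `min_end_distance` from the ends of A).
#'
#' @param total_len length of the gapped sequence A (bp).
#' @param gap_start 1-based first deleted position.
#' @param gap_len number of deleted bases.
#' @param min_gap,min_end_distance calling thresholds used to fill
#'   `expected$callable`.
#' @param ids names for the two records.
#' @return list with `seqs` (DNAStringSet of A and B) and `expected`
#'   (one-row data.frame: gapped id, gap span, gap length, end distances,
#'   callable flag).
#' @export
make_as_pair <- function(total_len, gap_start, gap_len,
                         min_gap = 100, min_end_distance = 100,
                         ids = c("gapped", "contig")) {
  gap_end <- gap_start + gap_len - 1
  if (gap_start < 2 || gap_end > total_len - 1) {
    stop("gap must lie strictly inside the sequence with >= 1 bp flanks")
  }
  a <- random_dna(total_len)
  b <- paste0(substr(a, 1, gap_start - 1), substr(a, gap_end + 1, total_len))
  d5 <- gap_start - 1
  d3 <- total_len - gap_end
  expected <- data.frame(
    gapped_id = ids[1], contig_id = ids[2],
    gap_start = gap_start, gap_end = gap_end, gap_len = gap_len,
    dist5 = d5, dist3 = d3,
    callable = gap_len > min_gap && d5 >= min_end_distance && d3 >= min_end_distance,
    stringsAsFactors = FALSE
  )
  seqs <- Biostrings::DNAStringSet(c(a, b))
  names(seqs) <- ids
  list(seqs = seqs, expected = expected)
}

#' Simulate isoform families for clustering tests
#'
#' Each family descends from an independent random ancestor; members carry
#' independent point substitutions at rate `1 - within_identity`. Unrelated
#' random sequences share about 25% identity under a global alignment, so
#' any `between_identity` well above that is a statement of the planted
#' structure rather than a constructed similarity.
#'
#' @param n_families,members_per_family family structure.
#' @param seq_len ancestor length (bp).
#' @param within_identity expected per-base identity of a member to its
#'   ancestor; must exceed `between_identity`.
#' @param between_identity upper bound claimed for cross-family identity.
#' @return list with `seqs` (DNAStringSet, ids `famF_mM`) and `truth`
#'   (data.frame id, family).
#' @export
make_cluster_families <- function(n_families = 5, members_per_family = 4,
                                  seq_len = 1000, within_identity = 0.995,
                                  between_identity = 0.85) {
  if (within_identity <= between_identity) {
    stop("within_identity must exceed between_identity")
  }
  if (n_families < 1 || members_per_family < 1 || seq_len < 50) {
    stop("degenerate family specification")
  }
  mut_rate <- 1 - within_identity
  ids <- character(0); seqs <- character(0); fam <- integer(0)
  for (f in seq_len(n_families)) {
    anc <- strsplit(random_dna(seq_len), "")[[1]]
    for (m in seq_len(members_per_family)) {
      s <- anc
      nmut <- stats::rbinom(1, seq_len, mut_rate)
      if (m == 1) nmut <- 0   # founder is the ancestor itself
      if (nmut > 0) {
        pos <- sample(seq_len, nmut)
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      }
      ids <- c(ids, sprintf("fam%d_m%d", f, m))
      seqs <- c(seqs, paste(s, collapse = ""))
      fam <- c(fam, f)
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  list(seqs = out, truth = data.frame(id = ids, family = fam,
                                      stringsAsFactors = FALSE))
}

#' Write a truth table to TSV files
#'
#' @param truth the `truth` element of [make_reads()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_table <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth)) {
    if (!is.null(truth[[nm]])) {
      utils::write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
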