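#' Microsatellite search thresholds
#'
#' Minimum repeat counts per motif unit size 1..6. Defaults are the MISA
#' defaults (`1-10 2-6 3-5 4-5 5-5 6-5`): a mononucleotide run must repeat
#' at least 10 times, a dinucleotide at least 6, tri- to hexanucleotides at
#' least 5. Two microsatellites separated by at most
#' `max_compound_interruption` bp form a compound SSR.
#'
#' @param min_repeats integer vector of length 6.
#' @param max_compound_interruption maximum gap (bp) inside a compound
#'   group (default 100).
#' @return validated `ssr_thresholds` list.
#' @export
ssr_thresholds <- function(min_repeats = c(10, 6, 5, 5, 5, 5),
                           max_compound_interruption = 100) {
  if (length(min_repeats) != 6 || any(min_repeats < 1)) {
    stop("min_repeats must be six counts >= 1")
  }
  if (max_compound_interruption < 0) stop("interruption must be >= 0")
  structure(list(min_repeats = as.integer(min_repeats),
                 max_compound_interruption = as.integer(max_compound_interruption)),
            class = "ssr_thresholds")
}

# TRUE if the motif is not itself a repetition of a shorter unit
motif_is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1) return(TRUE)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 && strrep(substr(motif, 1, d), u / d) == motif) return(FALSE)
  }
  TRUE
}

#' Canonical form of an SSR motif
#'
#' The lexicographically smallest string over all rotations of the motif
#' and all rotations of its reverse complement, so that e.g. `AG`, `GA`,
#' `CT` and `TC` all report as `AG`. Used for density reporting by motif
#' class.
#'
#' @param motif character vector of motifs.
#' @return character vector of canonical motifs.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    rots <- function(s) vapply(seq_len(u), function(i) {
      paste0(substr(s, i, u), substr(s, 1, i - 1))
    }, character(1))
    min(c(rots(m), rots(revcomp_chr(m))))
  }, character(1), USE.NAMES = FALSE)
}

scan_one_sequence <- function(seq, id, thresholds) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  valid <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in 1:6) {
    thr <- thresholds$min_repeats[u]
    if (n < u * thr) next
    eq <- ch[seq_len(n - u)] == ch[(u + 1):n] &
      valid[seq_len(n - u)] & valid[(u + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      reps <- (j - i + 1 + u) %/% u
      if (reps < thr) next
      motif <- substr(seq, i, i + u - 1)
      if (!motif_is_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, motif = motif, unit_size = u, repeats = reps,
        start = i, end = i + u * reps - 1L, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), motif = character(0),
                      unit_size = integer(0), repeats = integer(0),
                      start = integer(0), end = integer(0),
                      compound_id = character(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$start, hits$unit_size), , drop = FALSE]
  # compound grouping: a hit within max_compound_interruption bp of the
  # running end of the previous group joins that group (MISA convention)
  gid <- integer(nrow(hits))
  cur <- 1L
  running_end <- hits$end[1]
  gid[1] <- cur
  if (nrow(hits) > 1) {
    for (i in 2:nrow(hits)) {
      gap <- hits$start[i] - running_end - 1L
      if (gap > thresholds$max_compound_interruption) cur <- cur + 1L
      gid[i] <- cur
      running_end <- max(running_end, hits$end[i])
    }
  }
  sizes <- table(gid)
  hits$compound_id <- ifelse(sizes[as.character(gid)] > 1,
                             paste0(id, "_c", gid), NA_character_)
  rownames(hits) <- NULL
  hits
}

#' Find microsatellites (SSRs) in sequences
#'
#' Reports every maximal perfect tandem repeat of a 1-6 bp unit meeting the
#' per-unit-size repeat thresholds. Motifs are primitive (a run of `AAAA...`
#' is reported once as motif `A`, never as `AA`), so a run qualifying at
#' several unit sizes appears once at its smallest primitive unit. Spans
#' cover whole repeat units only and are 1-based inclusive. Any base outside
#' `{A,C,G,T}` terminates a run. Hits on the same sequence whose gap to the
#' previous hit is at most `max_compound_interruption` bp share a
#' `compound_id`; isolated hits have `NA`.
#'
#' @param records [Biostrings::DNAStringSet] or named character vector.
#' @param thresholds an [ssr_thresholds()].
#' @return data.frame: `seq_id, motif, unit_size, repeats, start, end,
#'   compound_id`.
#' @export
find_ssrs <- function(records, thresholds = ssr_thresholds()) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  ids <- names(records) %||% sprintf("seq%d", seq_along(records))
  seqs <- as.character(records)
  out <- lapply(seq_along(seqs), function(i) {
    scan_one_sequence(seqs[i], ids[i], thresholds)
  })
  do.call(rbind, out)
}

#' Summarize SSR search results
#'
#' Produces the standard search-summary table (sequences examined, total bp
#' examined, SSR totals, SSR-containing sequences, sequences with more than
#' one SSR, SSRs in compound formation), per-unit-size counts with their
#' percentage of all SSRs (half-up, 2 decimals), and a density table per
#' canonical motif (hits per Mbp of examined sequence).
#'
#' @param hits data.frame from [find_ssrs()].
#' @param records the sequence collection that was scanned.
#' @return list with data.frames `summary`, `unit_counts`, `density`.
#' @export
ssr_report <- function(hits, records) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  total_bp <- sum(Biostrings::width(records))
  per_seq <- table(hits$seq_id)
  unit_names <- c("Mononucleotide", "Dinucleotide", "Trinucleotide",
                  "Tetranucleotide", "Pentanucleotide", "Hexanucleotide")
  counts <- vapply(1:6, function(u) sum(hits$unit_size == u), integer(1))
  total <- nrow(hits)
  summary <- data.frame(
    item = c("Total number of sequences examined",
             "Total size of examined sequences (bp)",
             "Total number of identified SSRs",
             "Number of SSR-containing sequences",
             "Number of sequences containing more than 1 SSR",
             "Number of SSRs present in compound formation"),
    value = c(length(records), total_bp, total, length(per_seq),
              sum(per_seq > 1), sum(!is.na(hits$compound_id))),
    stringsAsFactors = FALSE
  )
  unit_counts <- data.frame(
    unit_size = 1:6, class = unit_names, count = counts,
    pct = if (total > 0) percent_of(counts, total, 2) else rep(NA_real_, 6),
    stringsAsFactors = FALSE
  )
  if (total > 0) {
    canon <- canonical_motif(hits$motif)
    dens <- sort(table(canon), decreasing = TRUE)
    density <- data.frame(
      motif = names(dens), count = as.integer(dens),
      per_mbp = round_half_up(as.integer(dens) / (total_bp / 1e6), 2),
      stringsAsFactors = FALSE
    )
  } else {
    density <- data.frame(motif = character(0), count = integer(0),
                          per_mbp = numeric(0))
  }
  list(summary = summary, unit_counts = unit_counts, density = density)
}

#' Write SSR hits as GFF3 features
#'
#' @param hits data.frame from [find_ssrs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ssr_gff3 <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    attrs <- sprintf("ID=ssr%d;motif=%s;repeats=%d%s", seq_len(nrow(hits)),
                     hits$motif, hits$repeats,
                     ifelse(is.na(hits$compound_id), "",
                            paste0(";compound=", hits$compound_id)))
    writeLines(sprintf("%s\tisoscan\tmicrosatellite\t%d\t%d\t.\t+\t.\t%s",
                       hits$seq_id, hits$start, hits$end, attrs), con)
  }
  invisible(path)
}
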