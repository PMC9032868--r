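.stop_codons <- c("TAA", "TAG", "TGA")

# translate a concatenated codon string with the standard code; codons
# containing N become X
translate_codons <- function(cds) {
  if (!nchar(cds)) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X", no.init.codon = TRUE
  )))
}

# enumerate ORF candidates in one frame of one strand-oriented sequence.
# Within a frame the codon stream is split at stop codons; each region
# yields at most one candidate:
#   - first ATG .. stop           -> complete
#   - first ATG .. sequence end   -> 3prime_partial (no stop downstream)
#   - frame start .. stop         -> 5prime_partial (leading region, no ATG)
#   - frame start .. sequence end -> internal (no ATG, no stop anywhere)
# Coordinates returned are on the oriented sequence, 1-based, stop included.
frame_orfs <- function(codons, frame) {
  nc <- length(codons)
  if (nc == 0) return(NULL)
  is_stop <- codons %in% .stop_codons
  is_atg <- codons == "ATG"
  stops <- which(is_stop)
  region_starts <- c(1L, stops + 1L)
  region_stops <- c(stops, NA_integer_)   # NA = runs to sequence end
  n_reg <- length(region_starts)
  start <- end <- aa_len <- integer(n_reg)
  comp <- character(n_reg)
  keep <- 0L
  for (k in seq_len(n_reg)) {
    rs <- region_starts[k]
    rstop <- region_stops[k]
    re <- if (is.na(rstop)) nc else rstop - 1L   # last coding codon index
    if (rs > nc || re < rs) next
    atg <- which(is_atg[rs:re])
    has_start <- length(atg) > 0
    if (has_start) {
      cstart <- rs + atg[1] - 1L
    } else if (k == 1L) {
      cstart <- rs
    } else {
      next
    }
    has_stop <- !is.na(rstop)
    al <- re - cstart + 1L
    if (al < 1L) next
    keep <- keep + 1L
    start[keep] <- frame + (cstart - 1L) * 3L + 1L
    end[keep] <- frame + (if (has_stop) rstop else re) * 3L
    aa_len[keep] <- al
    comp[keep] <- if (has_start && has_stop) "complete"
      else if (has_start) "3prime_partial"
      else if (has_stop) "5prime_partial"
      else "internal"
  }
  if (keep == 0L) return(NULL)
  idx <- seq_len(keep)
  list(frame = rep.int(frame, keep), start = start[idx], end = end[idx],
       aa_length = aa_len[idx], completeness = comp[idx])
}

orfs_one_strand <- function(seq, strand) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 1) next
    starts <- frame + 3 * (seq_len(ncod) - 1) + 1
    codons <- substring(seq, starts, starts + 2)
    fr <- frame_orfs(codons, frame)
    if (!is.null(fr)) out[[length(out) + 1L]] <- fr
  }
  if (!length(out)) return(NULL)
  df <- data.frame(
    frame = unlist(lapply(out, `[[`, "frame")),
    start = unlist(lapply(out, `[[`, "start")),
    end = unlist(lapply(out, `[[`, "end")),
    aa_length = unlist(lapply(out, `[[`, "aa_length")),
    completeness = unlist(lapply(out, `[[`, "completeness")),
    stringsAsFactors = FALSE
  )
  df$strand <- strand
  df
}

#' Find the best open reading frame of a transcript
#'
#' Enumerates all ORFs (start codon `ATG`, stops `TAA`/`TAG`/`TGA`,
#' standard code) in three frames of one or both strands. Transcript ends
#' open the partial completeness classes: a frame region with no start
#' codon but a downstream stop is `5prime_partial`, one with a start but no
#' stop before the end is `3prime_partial`, a frame with neither is
#' `internal`; `complete` ORFs have both. Only ORFs of at least `min_aa`
#' amino acids qualify; the longest wins, measured by nucleotide span with
#' the stop codon included (so a complete ORF outranks a partial one of
#' equal coding length), with remaining ties preferring complete over
#' partial classes, the forward strand, then the smaller start coordinate.
#'
#' @param record one-element [Biostrings::DNAStringSet] or single string.
#' @param min_aa minimum peptide length in amino acids (default 100, the
#'   usual long-ORF convention; the stop codon does not count).
#' @param strands `"both"` or `"forward"`.
#' @return one-row data.frame (`transcript_id, strand, frame, start, end,
#'   completeness, peptide, aa_length`; coordinates are 1-based on the
#'   input transcript, stop codon included when present) or `NULL` when no
#'   ORF reaches `min_aa`.
#' @export
find_best_orf <- function(record, min_aa = 100, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (min_aa < 1) stop("min_aa must be >= 1")
  id <- names(record) %||% "seq1"
  seq <- toupper(as.character(record)[1])
  n <- nchar(seq)
  rc <- if (strands == "both") revcomp_chr(seq) else NULL
  cands <- orfs_one_strand(seq, "+")
  if (strands == "both") {
    cands <- rbind(cands, orfs_one_strand(rc, "-"))
  }
  if (is.null(cands)) return(NULL)
  cands <- cands[cands$aa_length >= min_aa, , drop = FALSE]
  if (!nrow(cands)) return(NULL)

  # map minus-strand spans back onto forward transcript coordinates
  minus <- cands$strand == "-"
  fwd_start <- ifelse(minus, n - cands$end + 1L, cands$start)
  fwd_end <- ifelse(minus, n - cands$start + 1L, cands$end)
  cands$report_start <- fwd_start
  cands$report_end <- fwd_end

  # primary key is the nucleotide span (stop codon included), so that a
  # complete ORF outranks a partial one of the same coding length; then
  # completeness class, forward strand, smaller start
  comp_rank <- match(cands$completeness,
                     c("complete", "5prime_partial", "3prime_partial", "internal"))
  span_len <- cands$end - cands$start + 1L
  ord <- order(-span_len, comp_rank, cands$strand != "+",
               cands$report_start, method = "radix")
  best <- cands[ord[1], ]
  oriented <- if (best$strand == "+") seq else rc
  cds <- substr(oriented, best$start, best$start + 3 * best$aa_length - 1)
  data.frame(
    transcript_id = id[1], strand = best$strand, frame = best$frame,
    start = best$report_start, end = best$report_end,
    completeness = best$completeness,
    peptide = translate_codons(cds), aa_length = best$aa_length,
    stringsAsFactors = FALSE
  )
}

#' Best ORF for each transcript in a collection
#'
#' @param records [Biostrings::DNAStringSet] or named character vector.
#' @inheritParams find_best_orf
#' @return data.frame with one row per transcript that has an ORF of at
#'   least `min_aa` amino acids (see [find_best_orf()]).
#' @export
find_best_orfs <- function(records, min_aa = 100, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  ids <- names(records) %||% sprintf("seq%d", seq_along(records))
  rows <- lapply(seq_along(records), function(i) {
    x <- records[i]
    names(x) <- ids[i]
    find_best_orf(x, min_aa = min_aa, strands = strands)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(transcript_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      completeness = character(0), peptide = character(0),
                      aa_length = integer(0)))
  }
  do.call(rbind, rows)
}

#' Bin complete-ORF peptide lengths
#'
#' Counts complete ORFs in the bins `<= 1000` aa, `1000 < aa <= 2000`, and
#' `> 2000` aa, with percentages of the complete-ORF total (half-up, two
#' decimals). Only complete ORFs enter the denominator.
#'
#' @param orfs data.frame from [find_best_orfs()] (rows with
#'   `completeness != "complete"` are dropped), or an integer vector of
#'   complete-ORF amino-acid lengths.
#' @return data.frame `bin, count, pct`.
#' @export
orf_length_bins <- function(orfs) {
  lens <- if (is.data.frame(orfs)) {
    orfs$aa_length[orfs$completeness == "complete"]
  } else {
    as.integer(orfs)
  }
  counts <- c(sum(lens <= 1000), sum(lens > 1000 & lens <= 2000),
              sum(lens > 2000))
  total <- sum(counts)
  data.frame(
    bin = c("<=1000aa", "1000-2000aa", ">2000aa"),
    count = counts,
    pct = if (total > 0) percent_of(counts, total, 2) else rep(NA_real_, 3),
    stringsAsFactors = FALSE
  )
}
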