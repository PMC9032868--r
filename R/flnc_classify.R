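#' Parameters for FLNC classification
#'
#' @param max_primer_mismatch maximum edit distance (substitutions + indels)
#'   allowed when locating a primer (default 3).
#' @param search_window distance from each read end (bp) within which a
#'   terminal primer must begin/end (default 100).
#' @param min_polya_len minimum poly(A) tail length (default 20 bp).
#' @param max_polya_nonA_frac maximum tolerated fraction of non-A bases
#'   inside the poly(A) window (default 0.1).
#' @param min_insert_len minimum trimmed insert length (default 50 bp,
#'   mirroring the usual short-read floor of long-read preprocessing).
#' @return a validated `flnc_params` list.
#' @export
flnc_params <- function(max_primer_mismatch = 3, search_window = 100,
                        min_polya_len = 20, max_polya_nonA_frac = 0.1,
                        min_insert_len = 50) {
  if (max_primer_mismatch < 0 || search_window < 0 || min_polya_len < 0 ||
      min_insert_len < 0) {
    stop("all lengths and distances must be non-negative")
  }
  if (max_polya_nonA_frac < 0 || max_polya_nonA_frac > 1) {
    stop("max_polya_nonA_frac must lie in [0, 1]")
  }
  structure(list(max_primer_mismatch = as.integer(max_primer_mismatch),
                 search_window = as.integer(search_window),
                 min_polya_len = as.integer(min_polya_len),
                 max_polya_nonA_frac = max_polya_nonA_frac,
                 min_insert_len = as.integer(min_insert_len)),
            class = "flnc_params")
}

# best occurrence of `pattern` inside `subject` (character) at <= max_mm
# edits; among hits at the smallest distance, `pick` chooses the position
# closest to the relevant read end. Returns NULL or list(start, end, dist).
best_primer_hit <- function(pattern, subject, max_mm,
                            pick = c("leftmost", "rightmost")) {
  pick <- match.arg(pick)
  subj <- Biostrings::DNAString(subject)
  for (d in 0:max_mm) {
    m <- Biostrings::matchPattern(pattern, subj, max.mismatch = d,
                                  with.indels = TRUE)
    if (length(m) > 0) {
      i <- if (pick == "leftmost") which.min(IRanges::start(m)) else
        which.max(IRanges::end(m))
      return(list(start = IRanges::start(m)[i], end = IRanges::end(m)[i],
                  dist = d))
    }
  }
  NULL
}

# longest suffix of `region` whose non-A fraction stays within `frac` and
# whose 5'-most base is an A (the tail may contain interruptions but cannot
# begin with one, or it would swallow insert bases); returns its length
polya_suffix_len <- function(region, frac) {
  if (!nchar(region)) return(0L)
  ch <- rev(strsplit(region, "")[[1]])
  nonA <- cumsum(ch != "A")
  k <- seq_along(ch)
  ok <- nonA <= frac * k & ch == "A"
  if (!any(ok)) 0L else max(k[ok])
}

classify_one <- function(seq, id, primer_5, primer_3, params) {
  p5 <- primer_5
  p3rc <- revcomp_chr(primer_3)
  w <- params$search_window
  mm <- params$max_primer_mismatch

  attempt <- function(s) {
    n <- nchar(s)
    head_win <- substr(s, 1, min(n, w + nchar(p5) + mm))
    tail_from <- max(1, n - (w + nchar(p3rc) + mm) + 1)
    tail_win <- substr(s, tail_from, n)
    h5 <- best_primer_hit(p5, head_win, mm, pick = "leftmost")
    h3 <- best_primer_hit(p3rc, tail_win, mm, pick = "rightmost")
    if (!is.null(h5) && h5$start - 1 > w) h5 <- NULL
    if (!is.null(h3)) {
      h3$start <- h3$start + tail_from - 1
      h3$end <- h3$end + tail_from - 1
      if (n - h3$end > w) h3 <- NULL
    }
    list(h5 = h5, h3 = h3,
         score = (!is.null(h5)) + (!is.null(h3)),
         dist = (if (is.null(h5)) mm + 1 else h5$dist) +
                (if (is.null(h3)) mm + 1 else h3$dist))
  }

  fwd <- attempt(seq)
  revseq <- revcomp_chr(seq)
  rev <- attempt(revseq)
  flipped <- (rev$score > fwd$score) ||
    (rev$score == fwd$score && rev$dist < fwd$dist)
  s <- if (flipped) revseq else seq
  hit <- if (flipped) rev else fwd
  n <- nchar(s)

  res <- data.frame(
    id = id, label = "NON_FL", strand = if (flipped) "-" else "+",
    primer5_start = NA_integer_, primer5_end = NA_integer_,
    polya_start = NA_integer_, polya_end = NA_integer_,
    primer3_start = NA_integer_, primer3_end = NA_integer_,
    insert = NA_character_, stringsAsFactors = FALSE
  )
  if (is.null(hit$h5) || is.null(hit$h3) || hit$h5$end >= hit$h3$start) {
    return(res)
  }
  res$primer5_start <- hit$h5$start; res$primer5_end <- hit$h5$end
  res$primer3_start <- hit$h3$start; res$primer3_end <- hit$h3$end

  region <- substr(s, hit$h5$end + 1, hit$h3$start - 1)
  pa_len <- polya_suffix_len(region, params$max_polya_nonA_frac)
  if (pa_len < params$min_polya_len) return(res)
  res$polya_end <- hit$h3$start - 1L
  res$polya_start <- res$polya_end - pa_len + 1L

  insert <- substr(region, 1, nchar(region) - pa_len)
  if (nchar(insert) < params$min_insert_len) return(res)

  # interior primer occurrence (either primer, either orientation) => chimera;
  # only existence matters, so a single maximum-tolerance search per pattern
  ins_subj <- Biostrings::DNAString(insert)
  interior <- vapply(
    unique(c(p5, primer_3, revcomp_chr(p5), p3rc)),
    function(p) length(Biostrings::matchPattern(
      p, ins_subj, max.mismatch = params$max_primer_mismatch,
      with.indels = TRUE)) > 0,
    logical(1)
  )
  res$insert <- insert
  res$label <- if (any(interior)) "CHIMERIC" else "FLNC"
  if (res$label == "CHIMERIC") res$insert <- NA_character_
  res
}

#' Classify one read as FLNC, non-full-length, or chimeric
#'
#' A read is FLNC when (a) the 5' primer is found within `search_window` of
#' the 5' end at no more than `max_primer_mismatch` edits, (b) the reverse
#' complement of the 3' primer is found within `search_window` of the 3'
#' end, (c) a poly(A) run of at least `min_polya_len` bp with a non-A
#' fraction within `max_polya_nonA_frac` lies immediately 5' of the 3'
#' primer, (d) no additional primer occurrence exists in the trimmed insert
#' (otherwise the read is a chimera), and (e) the trimmed insert is at least
#' `min_insert_len` bp. Reads whose primers are found in the flipped
#' arrangement are reverse-complemented before reporting (`strand = "-"`).
#' Everything else is non-full-length. Classification is total: no input
#' raises an error.
#'
#' @param read a single-element [Biostrings::DNAStringSet] (or 1-element
#'   named character vector).
#' @param primers character vector with elements `primer_5` and `primer_3`
#'   (see [default_primers()]).
#' @param params a [flnc_params()].
#' @return one-row data.frame: id, label (`FLNC`/`NON_FL`/`CHIMERIC`),
#'   strand, primer and poly(A) spans (coordinates on the reported
#'   orientation), and the trimmed insert sequence (FLNC only).
#' @export
classify_read <- function(read, primers = default_primers(),
                          params = flnc_params()) {
  id <- names(read) %||% "read1"
  classify_one(as.character(read)[1], id[1],
               primers[["primer_5"]], primers[["primer_3"]], params)
}

#' Classify a collection of reads
#'
#' @param reads a [Biostrings::DNAStringSet], e.g. from [read_sequences()]
#'   or [make_reads()].
#' @inheritParams classify_read
#' @return data.frame with one row per read (see [classify_read()]).
#' @export
classify_reads <- function(reads, primers = default_primers(),
                           params = flnc_params()) {
  ids <- names(reads) %||% sprintf("read%d", seq_along(reads))
  seqs <- as.character(reads)
  rows <- lapply(seq_along(seqs), function(i) {
    classify_one(seqs[i], ids[i], primers[["primer_5"]],
                 primers[["primer_3"]], params)
  })
  do.call(rbind, rows)
}

#' Extract the trimmed FLNC inserts as a sequence set
#'
#' @param classified output of [classify_reads()].
#' @return [Biostrings::DNAStringSet] of inserts, named by read id.
#' @export
flnc_inserts <- function(classified) {
  keep <- classified$label == "FLNC"
  out <- Biostrings::DNAStringSet(classified$insert[keep])
  names(out) <- classified$id[keep]
  out
}

#' Full-length non-chimeric rate
#'
#' The share of reads classified FLNC, as a percentage rounded half-up to
#' two decimals (e.g. 195027 FLNC out of 234508 consensus reads is 83.16).
#'
#' @param n_flnc FLNC read count.
#' @param n_total total read count; must be positive and at least `n_flnc`.
#' @return percentage with two decimals.
#' @export
flnc_rate <- function(n_flnc, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_flnc < 0 || n_flnc > n_total) stop("need 0 <= n_flnc <= n_total")
  percent_of(n_flnc, n_total, 2)
}
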