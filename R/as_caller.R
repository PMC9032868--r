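#' Criteria for calling candidate alternative-splicing events
#'
#' Two same-orientation HSPs between a transcript pair support a candidate
#' event when, on one sequence (the contiguous one), the two aligned spans
#' are contiguous or separated/overlapping by strictly less than
#' `max_contiguous_overlap` bp, while on the other (the gapped one) they
#' flank an unaligned gap strictly longer than `min_gap` bp whose
#' boundaries lie at least `min_end_distance` bp from both sequence ends.
#' Optionally the two HSPs must jointly cover at least `min_joint_coverage`
#' of the contiguous sequence ("almost completely aligned").
#'
#' @param max_contiguous_overlap bp; overlap (and, symmetrically,
#'   separation) on the contiguous side must be strictly below this
#'   (default 5).
#' @param min_gap bp; the gap must be strictly greater (default 100).
#' @param min_end_distance bp; inclusive distance of both gap boundaries
#'   from the sequence ends (default 100).
#' @param require_same_orientation only pair HSPs on the same strand
#'   (default TRUE).
#' @param min_joint_coverage fraction of the contiguous sequence the two
#'   HSPs must jointly cover; set `NA` to disable (default 0.8).
#' @return validated `as_criteria` list.
#' @export
as_criteria <- function(max_contiguous_overlap = 5, min_gap = 100,
                        min_end_distance = 100,
                        require_same_orientation = TRUE,
                        min_joint_coverage = 0.8) {
  if (max_contiguous_overlap < 0 || min_gap < 0 || min_end_distance < 0) {
    stop("criteria distances must be non-negative")
  }
  structure(list(max_contiguous_overlap = max_contiguous_overlap,
                 min_gap = min_gap, min_end_distance = min_end_distance,
                 require_same_orientation = require_same_orientation,
                 min_joint_coverage = min_joint_coverage),
            class = "as_criteria")
}

empty_events <- function() {
  data.frame(gapped_id = character(0), contig_id = character(0),
             gap_start = integer(0), gap_end = integer(0),
             gap_len = integer(0), dist5 = integer(0), dist3 = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

# an empty, correctly-typed HSP table
empty_hsps <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             identity_pct = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bit_score = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

# split one local alignment into HSP segments at indel runs of at least
# `split_gap` columns; a dynamic-programming local aligner with affine gaps
# happily bridges a multi-hundred-bp deletion when the flanks are long,
# whereas BLAST reports two separate HSPs — cutting the alignment at long
# gap runs restores that HSP geometry. Returns per-segment coordinate rows
# in alignment-column space plus match statistics.
split_alignment <- function(aln, split_gap) {
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gapcol <- pa == "-" | su == "-"
  r <- rle(gapcol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cut <- r$values & r$lengths >= split_gap
  seg_bounds <- c(0, ends[cut], length(pa))
  q_off <- cumsum(pa != "-")
  s_off <- cumsum(su != "-")
  segs <- list()
  for (k in seq_len(length(seg_bounds) - 1)) {
    c1 <- seg_bounds[k] + 1
    c2 <- seg_bounds[k + 1]
    if (k < length(seg_bounds) - 1) c2 <- c2 - r$lengths[cut][k] + 0
    # trim any gap columns at the segment edges
    while (c1 <= c2 && gapcol[c1]) c1 <- c1 + 1
    while (c2 >= c1 && gapcol[c2]) c2 <- c2 - 1
    if (c1 > c2) next
    cols <- c1:c2
    nmatch <- sum(pa[cols] == su[cols] & !gapcol[cols])
    nmm <- sum(pa[cols] != su[cols] & !gapcol[cols])
    g <- rle(gapcol[cols])
    gap_runs <- g$lengths[g$values]
    score <- 2 * nmatch - 3 * nmm - sum(5 + 2 * gap_runs)
    segs[[length(segs) + 1L]] <- data.frame(
      q1 = q_off[c1] - (pa[c1] == "-"), q2 = q_off[c2],
      s1 = s_off[c1] - (su[c1] == "-"), s2 = s_off[c2],
      aln_len = length(cols), nmatch = nmatch, nmismatch = nmm,
      gap_opens = length(gap_runs), score = score
    )
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

#' Find high-scoring segment pairs between two sequences
#'
#' Greedy iterated local alignment: the best local alignment (match 2 /
#' mismatch -3 / gap open 5 / extend 2) across both orientations is taken,
#' split into segments at internal indel runs of `split_gap` bp or more
#' (restoring the separate-HSP geometry a database search tool would
#' report around a large unaligned block), its footprint is masked with
#' `N` on both sequences (`N` scores -6 against everything, so masked
#' regions cannot re-align), and the search repeats until no alignment
#' reaches `min_score`. Segments below `min_score` or `min_identity` are
#' dropped. Coordinates are 1-based on the original sequences;
#' minus-orientation hits carry `strand = "-"` with `s_start < s_end`.
#'
#' @param a,b sequences (one-element [Biostrings::DNAStringSet] or
#'   strings); names become query/subject ids.
#' @param min_score minimum segment score (default 100, i.e. 50 matched
#'   bases net).
#' @param min_identity minimum percent identity of an HSP (default 85).
#' @param split_gap indel runs at least this long (bp) split an alignment
#'   into separate HSPs (default 10).
#' @param max_rounds stop after this many align-and-mask rounds
#'   (default 10).
#' @return HSP table in the layout of [read_tabular_alignments()].
#' @export
find_hsps <- function(a, b, min_score = 100, min_identity = 85,
                      split_gap = 10, max_rounds = 10) {
  qid <- names(a) %||% "query"
  sid <- names(b) %||% "subject"
  qa <- as.character(a)[1]
  sb <- as.character(b)[1]
  len_b <- nchar(sb)
  submat <- .aln_submat()
  work_q <- qa
  work_s <- sb
  work_s_rc <- revcomp_chr(sb)
  rows <- list()
  for (round in seq_len(max_rounds)) {
    alns <- list(
      `+` = Biostrings::pairwiseAlignment(
        Biostrings::DNAString(work_q), Biostrings::DNAString(work_s),
        type = "local", substitutionMatrix = submat,
        gapOpening = 5, gapExtension = 2),
      `-` = Biostrings::pairwiseAlignment(
        Biostrings::DNAString(work_q), Biostrings::DNAString(work_s_rc),
        type = "local", substitutionMatrix = submat,
        gapOpening = 5, gapExtension = 2)
    )
    scores <- vapply(alns, Biostrings::score, numeric(1))
    st <- names(which.max(scores))
    aln <- alns[[st]]
    if (Biostrings::score(aln) < min_score) break
    q0 <- IRanges::start(Biostrings::pattern(aln)) - 1L
    s0 <- IRanges::start(Biostrings::subject(aln)) - 1L
    segs <- split_alignment(aln, split_gap)
    if (!is.null(segs)) for (k in seq_len(nrow(segs))) {
      sg <- segs[k, ]
      qs <- q0 + sg$q1; qe <- q0 + sg$q2
      ss <- s0 + sg$s1; se <- s0 + sg$s2
      if (st == "-") {        # map back from the reverse-complemented copy
        tmp <- ss
        ss <- len_b - se + 1
        se <- len_b - tmp + 1
      }
      pid <- 100 * sg$nmatch / sg$aln_len
      if (sg$score >= min_score && pid >= min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, subject_id = sid, identity_pct = pid,
          aln_len = sg$aln_len, mismatches = sg$nmismatch,
          gap_opens = sg$gap_opens, q_start = qs, q_end = qe,
          s_start = ss, s_end = se, evalue = 0,
          bit_score = sg$score, strand = st, stringsAsFactors = FALSE
        )
      }
    }
    # mask the whole footprint on all working copies, then continue
    qs <- IRanges::start(Biostrings::pattern(aln))
    qe <- IRanges::end(Biostrings::pattern(aln))
    ss <- IRanges::start(Biostrings::subject(aln))
    se <- IRanges::end(Biostrings::subject(aln))
    if (st == "-") {
      tmp <- ss
      ss <- len_b - se + 1
      se <- len_b - tmp + 1
    }
    substr(work_q, qs, qe) <- strrep("N", qe - qs + 1)
    substr(work_s, ss, se) <- strrep("N", se - ss + 1)
    substr(work_s_rc, len_b - se + 1, len_b - ss + 1) <- strrep("N", se - ss + 1)
  }
  if (!length(rows)) return(empty_hsps())
  out <- do.call(rbind, rows)
  out[order(out$q_start, out$s_start), , drop = FALSE]
}

#' Call candidate AS events from the HSPs of one transcript pair
#'
#' Applies the gap rules of [as_criteria()] to every pair of
#' same-orientation HSPs between one query/subject pair. For a pair of
#' HSPs, if the two aligned spans on one sequence are contiguous (within
#' the overlap tolerance) while on the other they flank a gap longer than
#' `min_gap` with both boundaries at least `min_end_distance` from the
#' sequence ends, one event is emitted naming the gapped sequence and the
#' gap span. Events are deduplicated on (gapped id, gap span).
#'
#' @param hsps HSP table (internal aligner or ingested 12-column file);
#'   all rows must share one query_id/subject_id pair.
#' @param query_len,subject_len sequence lengths (bp).
#' @param criteria an [as_criteria()].
#' @return data.frame of events: `gapped_id, contig_id, gap_start, gap_end,
#'   gap_len, dist5, dist3, strand`.
#' @export
call_as_events <- function(hsps, query_len, subject_len,
                           criteria = as_criteria()) {
  if (!nrow(hsps)) return(empty_events())
  if (length(unique(hsps$query_id)) > 1 || length(unique(hsps$subject_id)) > 1) {
    stop("call_as_events expects HSPs from a single transcript pair")
  }
  qid <- hsps$query_id[1]; sid <- hsps$subject_id[1]
  ov <- criteria$max_contiguous_overlap
  events <- list()
  n <- nrow(hsps)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h1 <- hsps[i, ]; h2 <- hsps[j, ]
    if (criteria$require_same_orientation && h1$strand != h2$strand) next
    # separation (negative = overlap) between the two spans on each side
    sep <- function(a1, a2, b1, b2) {
      if (a1 <= b1) b1 - a2 - 1 else a1 - b2 - 1
    }
    dq <- sep(h1$q_start, h1$q_end, h2$q_start, h2$q_end)
    ds <- sep(h1$s_start, h1$s_end, h2$s_start, h2$s_end)
    contiguous <- function(d) d > -ov && d < ov
    check <- function(gap_d, side_len, s1, e1, s2, e2, gid, cid, cov_len) {
      if (gap_d <= criteria$min_gap) return(NULL)
      gs <- min(e1, e2) + 1; ge <- max(s1, s2) - 1
      d5 <- gs - 1; d3 <- side_len - ge
      if (d5 < criteria$min_end_distance || d3 < criteria$min_end_distance) {
        return(NULL)
      }
      if (!is.na(criteria$min_joint_coverage) &&
          cov_len < criteria$min_joint_coverage) {
        return(NULL)
      }
      data.frame(gapped_id = gid, contig_id = cid, gap_start = gs,
                 gap_end = ge, gap_len = ge - gs + 1, dist5 = d5, dist3 = d3,
                 strand = h1$strand, stringsAsFactors = FALSE)
    }
    q_span <- (h1$q_end - h1$q_start + 1) + (h2$q_end - h2$q_start + 1)
    s_span <- (h1$s_end - h1$s_start + 1) + (h2$s_end - h2$s_start + 1)
    ev <- NULL
    if (contiguous(dq)) {
      ev <- check(ds, subject_len, h1$s_start, h1$s_end, h2$s_start, h2$s_end,
                  sid, qid, q_span / query_len)
    } else if (contiguous(ds)) {
      ev <- check(dq, query_len, h1$q_start, h1$q_end, h2$q_start, h2$q_end,
                  qid, sid, s_span / subject_len)
    }
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  if (!length(events)) return(empty_events())
  out <- do.call(rbind, events)
  out[!duplicated(out[c("gapped_id", "gap_start", "gap_end")]), , drop = FALSE]
}

# distinct-kmer prescreen used by scan_all_pairs: transcript pairs sharing
# fewer than `min_shared` 11-mers cannot produce two long high-identity
# HSPs, so the expensive alignment is skipped
pair_has_homology <- function(km_a, km_b, min_shared = 5) {
  sum(km_a %in% km_b) >= min_shared
}

#' Scan all transcript pairs for candidate AS events
#'
#' Aligns every unordered pair once (ids in canonical sort order decide the
#' query/subject roles, making the scan symmetric) and applies
#' [call_as_events()]. A shared-11-mer prescreen skips pairs with no
#' detectable homology.
#'
#' @param records [Biostrings::DNAStringSet] of two or more transcripts.
#' @param criteria an [as_criteria()].
#' @param min_score,min_identity HSP thresholds, see [find_hsps()].
#' @param prescreen_min_shared minimum number of shared 11-mers for a pair
#'   to be aligned (default 5); set 0 to align every pair.
#' @return data.frame of events over all pairs, in canonical pair order.
#' @export
scan_all_pairs <- function(records, criteria = as_criteria(),
                           min_score = 100, min_identity = 85,
                           prescreen_min_shared = 5) {
  if (length(records) < 2) return(empty_events())
  ids <- names(records) %||% sprintf("seq%d", seq_along(records))
  ord <- order(ids, method = "radix")
  records <- records[ord]
  ids <- ids[ord]
  seqs <- as.character(records)
  lens <- nchar(seqs)
  kms <- if (prescreen_min_shared > 0) lapply(seqs, kmer_set, k = 11) else NULL
  out <- list()
  for (i in 1:(length(seqs) - 1)) for (j in (i + 1):length(seqs)) {
    if (!is.null(kms) &&
        !pair_has_homology(kms[[i]], kms[[j]], prescreen_min_shared)) next
    a <- Biostrings::DNAStringSet(seqs[i]); names(a) <- ids[i]
    b <- Biostrings::DNAStringSet(seqs[j]); names(b) <- ids[j]
    hsps <- find_hsps(a, b, min_score = min_score, min_identity = min_identity)
    ev <- call_as_events(hsps, lens[i], lens[j], criteria)
    if (nrow(ev)) out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(empty_events())
  do.call(rbind, out)
}
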