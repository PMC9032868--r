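#' Built-in coding-potential call for one transcript
#'
#' A deliberately simple ORF-based surrogate for dedicated coding-potential
#' tools: a transcript is called non-coding when it has no start-codon
#' anchored ORF (classes `complete` or `3prime_partial`; a frame without an
#' `ATG` is no coding evidence), or when its best ORF is both short (below
#' `max_orf_aa` amino acids) and covers only a minor fraction of the
#' transcript (nucleotide span below `max_orf_coverage` of the transcript
#' length).
#'
#' @param record one-element [Biostrings::DNAStringSet] or string.
#' @param orf the transcript's best ORF (one-row data.frame from
#'   [find_best_orf()]) or `NULL` when absent.
#' @param max_orf_aa coding-length threshold (default 100 aa).
#' @param max_orf_coverage coding-coverage threshold (default 0.5).
#' @return `TRUE` when the transcript looks non-coding.
#' @export
builtin_noncoding_call <- function(record, orf, max_orf_aa = 100,
                                   max_orf_coverage = 0.5) {
  if (is.null(orf) || nrow(orf) == 0) return(TRUE)
  if (!orf$completeness %in% c("complete", "3prime_partial")) return(TRUE)
  len <- nchar(as.character(record)[1])
  span <- orf$end - orf$start + 1
  orf$aa_length < max_orf_aa && span / len < max_orf_coverage
}

#' Built-in non-coding calls over a collection
#'
#' Runs [find_best_orf()] with a permissive `min_aa` so that short ORFs are
#' visible to the coverage test, then applies [builtin_noncoding_call()].
#'
#' @param records [Biostrings::DNAStringSet] or named character vector.
#' @param max_orf_aa,max_orf_coverage see [builtin_noncoding_call()].
#' @param min_aa ORF enumeration floor (default 30 aa).
#' @return character vector of ids called non-coding.
#' @export
builtin_noncoding_calls <- function(records, max_orf_aa = 100,
                                    max_orf_coverage = 0.5, min_aa = 30) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  ids <- names(records) %||% sprintf("seq%d", seq_along(records))
  nc <- vapply(seq_along(records), function(i) {
    x <- records[i]
    names(x) <- ids[i]
    orf <- find_best_orf(x, min_aa = min_aa)
    builtin_noncoding_call(x, orf, max_orf_aa, max_orf_coverage)
  }, logical(1))
  ids[nc]
}

#' Read one external predictor's calls
#'
#' Two-column TSV: transcript id, then `coding` or `noncoding`.
#'
#' @param path file path.
#' @return character vector of ids called non-coding.
#' @export
read_method_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "call"))
  bad <- !df$call %in% c("coding", "noncoding")
  if (any(bad)) stop("unrecognized call '", df$call[bad][1], "' in ", path)
  df$id[df$call == "noncoding"]
}

#' Consensus lncRNA screen across coding-potential methods
#'
#' A transcript enters the consensus lncRNA set when its length passes the
#' length filter (strictly greater than `min_len` by default) and every
#' supplied method voted it non-coding — the intersection logic of the
#' usual multi-tool Venn diagram. Method calls may come from external
#' predictor tables ([read_method_calls()]) and/or the built-in classifier
#' ([builtin_noncoding_calls()]).
#'
#' @param records [Biostrings::DNAStringSet] of candidate transcripts.
#' @param method_calls named list; each element is the character vector of
#'   ids one method called non-coding. At least one method is required.
#' @param min_len length threshold in nt (default 200).
#' @param strict if `TRUE` (default) the filter is `length > min_len`,
#'   otherwise `length >= min_len`.
#' @return list with `calls` (data.frame: id, length, one logical column
#'   per method, `consensus`) and `venn` (data.frame: one row per
#'   non-empty method combination over the union of method sets, with the
#'   count of ids falling in exactly that combination, plus per-method
#'   totals as attribute `totals`).
#' @export
consensus_lncrna <- function(records, method_calls, min_len = 200,
                             strict = TRUE) {
  if (!length(method_calls)) stop("at least one method is required")
  if (is.null(names(method_calls)) || any(names(method_calls) == "")) {
    stop("method_calls must be a named list")
  }
  ids <- names(records) %||% sprintf("seq%d", seq_along(records))
  for (m in names(method_calls)) {
    unknown <- setdiff(method_calls[[m]], ids)
    if (length(unknown)) {
      stop("method ", m, " refers to unknown transcript id: ", unknown[1])
    }
  }
  len <- nchar(as.character(records))
  pass_len <- if (strict) len > min_len else len >= min_len
  votes <- vapply(method_calls, function(s) ids %in% s,
                  logical(length(ids)))
  votes <- matrix(votes, nrow = length(ids),
                  dimnames = list(NULL, names(method_calls)))
  consensus <- pass_len & apply(votes, 1, all)
  calls <- data.frame(id = ids, length = len, votes, consensus = consensus,
                      stringsAsFactors = FALSE)

  in_union <- apply(votes, 1, any)
  key <- apply(votes[in_union, , drop = FALSE], 1, function(v) {
    paste(names(method_calls)[v], collapse = "&")
  })
  venn <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(venn) <- c("region", "count")
  venn <- venn[order(venn$region), , drop = FALSE]
  rownames(venn) <- NULL
  attr(venn, "totals") <- colSums(votes)
  list(calls = calls, venn = venn)
}
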