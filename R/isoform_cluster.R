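# shared substitution scheme for all pairwise alignment in the package:
# match 2, mismatch -3, gap open 5, gap extend 2 (BLAST-like megablast-ish
# weights); N is scored -6 against everything including N so that masked
# regions can never re-align
.aln_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 2
  m["N", ] <- -6
  m[, "N"] <- -6
  m
}

# global alignment identity: matches / alignment columns (gaps included)
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .aln_submat(), gapOpening = 5, gapExtension = 2
  )
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# distinct k-mer sets for the prefilter
kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' Greedy identity clustering of transcript sequences
#'
#' An incremental clustering in the style of CD-HIT-EST: sequences are
#' sorted by decreasing length (ties broken by id, C-locale), and each
#' sequence joins the first existing cluster whose representative it matches
#' at global-alignment identity of at least `identity_threshold` with length
#' coverage of the shorter sequence of at least `min_coverage`; otherwise it
#' founds a new cluster. Identity is matches divided by alignment columns of
#' a global alignment (match 2 / mismatch -3 / gap open 5 / extend 2).
#' Because the alignment is end-to-end, coverage of the shorter sequence
#' reduces to the length ratio `shorter/longer`, which is what the
#' `min_coverage` test uses. The sort rule makes the output independent of
#' input order.
#'
#' An optional k-mer prefilter skips the alignment for representative
#' candidates that share no 11-mer with the query; a pair with no shared
#' 11-mer cannot reach any high identity threshold, so results are identical
#' with the filter on or off.
#'
#' @param records [Biostrings::DNAStringSet] (or named character vector).
#' @param identity_threshold minimum identity to join a cluster, in (0, 1].
#' @param min_coverage minimum length coverage of the shorter sequence,
#'   in (0, 1].
#' @param use_prefilter enable the shared-k-mer prescreen (default TRUE).
#' @param prefilter_k k-mer size for the prescreen (default 11).
#' @return data.frame with one row per input sequence: `id`, `cluster`
#'   (integer, in founding order), `representative` (founder id), `identity`
#'   to the representative (1 for the representative itself).
#' @export
cluster_sequences <- function(records, identity_threshold = 0.99,
                              min_coverage = 0.9, use_prefilter = TRUE,
                              prefilter_k = 11) {
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      min_coverage <= 0 || min_coverage > 1) {
    stop("identity_threshold and min_coverage must lie in (0, 1]")
  }
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  if (length(records) == 0) {
    return(data.frame(id = character(0), cluster = integer(0),
                      representative = character(0), identity = numeric(0)))
  }
  ids <- names(records) %||% sprintf("seq%d", seq_along(records))
  seqs <- as.character(records)
  w <- nchar(seqs)
  ord <- order(-w, ids, method = "radix")
  ids <- ids[ord]; seqs <- seqs[ord]; w <- w[ord]

  rep_idx <- integer(0)
  rep_kmers <- list()
  cluster <- integer(length(seqs))
  identity <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    km <- if (use_prefilter) kmer_set(seqs[i], prefilter_k) else NULL
    assigned <- 0L
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      if (w[i] / w[r] < min_coverage) next    # w[r] >= w[i] by sort order
      if (use_prefilter && !any(km %in% rep_kmers[[ci]])) next
      pid <- global_identity(seqs[i], seqs[r])
      if (pid >= identity_threshold) {
        assigned <- ci
        identity[i] <- pid
        break
      }
    }
    if (assigned == 0L) {
      rep_idx <- c(rep_idx, i)
      if (use_prefilter) rep_kmers[[length(rep_idx)]] <- km
      cluster[i] <- length(rep_idx)
      identity[i] <- 1
    } else {
      cluster[i] <- assigned
    }
  }
  data.frame(id = ids, cluster = cluster,
             representative = ids[rep_idx[cluster]],
             identity = identity, stringsAsFactors = FALSE)
}

#' Collapse clusters to a non-redundant representative set
#'
#' One sequence per cluster: the longest member, ties broken by id
#' (C-locale). Under the length-descending clustering order this is the
#' cluster founder.
#'
#' @param clusters data.frame from [cluster_sequences()].
#' @param records the sequence collection that was clustered.
#' @return [Biostrings::DNAStringSet] of representatives, one per cluster,
#'   in cluster order.
#' @export
collapse_representatives <- function(clusters, records) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  ids <- names(records)
  out_ids <- character(max(clusters$cluster, 0))
  for (ci in seq_len(max(clusters$cluster, 0))) {
    members <- clusters$id[clusters$cluster == ci]
    len <- nchar(as.character(records[match(members, ids)]))
    ord <- order(-len, members, method = "radix")
    out_ids[ci] <- members[ord[1]]
  }
  records[match(out_ids, ids)]
}
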