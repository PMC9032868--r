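#' Read sequences from FASTA or FASTQ
#'
#' Single entry point for sequence input. Sequences are uppercased; any
#' character outside `{A,C,G,T,N}` (lowercase input is uppercased first) is
#' replaced by `N` with a warning, so downstream scanners only ever see the
#' five-letter alphabet. Record ids are the first whitespace-delimited token
#' of the header; the remainder is kept as the description.
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (by file extension;
#'   `.fq`/`.fastq` mean FASTQ, anything else FASTA).
#' @return a [Biostrings::DNAStringSet] named by record id, with metadata
#'   columns `description` and (for FASTQ) `quality` (Phred+33 strings).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x some desc", "ACGT", "ACGT"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fastq") {
    # Biostrings emits a spurious dropped-mcols warning while assembling
    # the quality-scaled set; silence that one message only
    qs <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    x <- stats::setNames(as.character(qs), names(qs))
    qual <- unname(as.character(methods::slot(qs, "quality")))
  } else {
    x <- Biostrings::readBStringSet(path)
    qual <- NULL
  }
  headers <- names(x) %||% character(length(x))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) == 0)) {
    stop("zero-length sequence for id: ", ids[which(nchar(seqs) == 0)[1]])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " record(s) contained non-ACGTN characters; mapped to N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  if (!is.null(qual)) {
    if (any(nchar(qual) != nchar(seqs))) stop("quality length differs from sequence length")
    S4Vectors::mcols(out)$quality <- qual
  }
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a [Biostrings::DNAStringSet] as returned by [read_sequences()],
#'   or a named character vector.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires a `quality` metadata
#'   column (Phred+33 strings).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  headers <- names(x)
  mc <- S4Vectors::mcols(x)
  if (!is.null(mc) && !is.null(mc$description)) {
    has_desc <- !is.na(mc$description) & mc$description != ""
    headers[has_desc] <- paste(headers[has_desc], mc$description[has_desc])
  }
  if (format == "fastq") {
    qual <- if (!is.null(mc)) mc$quality else NULL
    if (is.null(qual)) stop("FASTQ output needs a 'quality' metadata column")
    lines <- as.vector(rbind(paste0("@", headers), as.character(x), "+", qual))
    writeLines(lines, path)
  } else {
    y <- x
    names(y) <- headers
    S4Vectors::mcols(y) <- NULL   # already folded into the headers
    Biostrings::writeXStringSet(y, path, width = 70L)
  }
  invisible(path)
}

hsp_columns <- c(
  "query_id", "subject_id", "identity_pct", "aln_len", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue",
  "bit_score", "strand"
)

# validate and normalize an HSP table: minus-strand rows arrive with
# s_start > s_end and are flipped to s_start < s_end plus strand = "-"
as_hsp_table <- function(df) {
  flip_q <- df$q_start > df$q_end
  if (any(flip_q)) stop("q_start > q_end is not a valid alignment row")
  minus <- df$s_start > df$s_end
  tmp <- df$s_start[minus]
  df$s_start[minus] <- df$s_end[minus]
  df$s_end[minus] <- tmp
  df$strand <- ifelse(minus, "-", "+")
  if (any(df$identity_pct < 0 | df$identity_pct > 100)) {
    stop("identity_pct outside [0, 100]")
  }
  if (any(df$aln_len <= 0)) stop("aln_len must be positive")
  df[hsp_columns]
}

#' Read 12-column tabular alignments (BLAST outfmt-6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Minus-strand hits (sstart > send on disk) are
#' normalized so that `s_start < s_end` with an explicit `strand = "-"` flag;
#' all coordinates are 1-based inclusive.
#'
#' @param path tab- or whitespace-separated file.
#' @return a data.frame with columns `query_id, subject_id, identity_pct,
#'   aln_len, mismatches, gap_opens, q_start, q_end, s_start, s_end, evalue,
#'   bit_score, strand`.
#' @export
read_tabular_alignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    df <- as.data.frame(matrix(nrow = 0, ncol = 12))
  } else {
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 12)) {
      stop("line ", which(nf != 12)[1], ": expected 12 columns, found ", nf[nf != 12][1])
    }
    df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  }
  names(df) <- c("query_id", "subject_id", "identity_pct", "aln_len",
                 "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                 "s_end", "evalue", "bit_score")
  num_cols <- setdiff(names(df), c("query_id", "subject_id"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && nrow(df)) {
      stop("line ", which(is.na(v))[1], ": non-numeric value in column ", cc)
    }
    df[[cc]] <- v
  }
  int_cols <- c("aln_len", "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  if (!nrow(df)) {
    df$strand <- character(0)
    return(df[hsp_columns])
  }
  as_hsp_table(df)
}

#' Write an HSP table as 12-column tabular alignments
#'
#' Inverse of [read_tabular_alignments()]: minus-strand rows are written with
#' subject coordinates swapped back (`sstart > send`), the on-disk encoding
#' of orientation in the 12-column dialect.
#'
#' @param hsps normalized HSP table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tabular_alignments <- function(hsps, path) {
  s1 <- ifelse(hsps$strand == "-", hsps$s_end, hsps$s_start)
  s2 <- ifelse(hsps$strand == "-", hsps$s_start, hsps$s_end)
  out <- data.frame(
    hsps$query_id, hsps$subject_id, hsps$identity_pct, hsps$aln_len,
    hsps$mismatches, hsps$gap_opens, hsps$q_start, hsps$q_end, s1, s2,
    format(hsps$evalue), hsps$bit_score
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
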