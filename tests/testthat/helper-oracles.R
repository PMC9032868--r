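# Independent brute-force oracles used to cross-check the scanners.

# SSR oracle: PCRE backreference search per unit size. For unit size u and
# minimum repeat count k the pattern ([ACGT]{u})\1{k-1,} finds, leftmost and
# greedy, every maximal perfect tandem repeat of complete units; matches
# with a non-primitive motif are discarded (those repeats are found again at
# their smallest unit).
ssr_oracle <- function(seq, thresholds = ssr_thresholds()) {
  rows <- list()
  for (u in 1:6) {
    thr <- thresholds$min_repeats[u]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thr - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      motif <- substr(seq, m[i], m[i] + u - 1)
      primitive <- TRUE
      if (u > 1) {
        for (d in seq_len(u - 1)) {
          if (u %% d == 0 && strrep(substr(motif, 1, d), u / d) == motif) {
            primitive <- FALSE
            break
          }
        }
      }
      if (!primitive) next
      reps <- len[i] %/% u
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, unit_size = u, repeats = reps,
        start = as.integer(m[i]), end = as.integer(m[i]) + u * reps - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(0), unit_size = integer(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ORF oracle: exhaustive six-frame enumeration at the peptide level. Each
# frame is translated in full; the peptide is split at stop codons and each
# region yields at most one candidate (first M .. stop; leading region
# without M opens the 5'-partial / internal classes). Ranking follows the
# declared rule: longest nucleotide span (stop included), then completeness
# class, then forward strand, then smaller start.
orf_oracle <- function(seq, min_aa = 100, strands = "both") {
  n <- nchar(seq)
  cands <- list()
  strand_set <- if (strands == "both") c("+", "-") else "+"
  for (st in strand_set) {
    s <- if (st == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (frame in 0:2) {
      ncod <- (nchar(s) - frame) %/% 3
      if (ncod < 1) next
      sub <- substr(s, frame + 1, frame + 3 * ncod)
      pep <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X",
        no.init.codon = TRUE)))
      aa <- strsplit(pep, "")[[1]]
      stars <- which(aa == "*")
      bounds <- c(0, stars, length(aa) + 1)
      for (k in seq_len(length(bounds) - 1)) {
        rs <- bounds[k] + 1
        next_star <- if (k < length(bounds) - 1) stars[k] else NA
        re <- if (is.na(next_star)) length(aa) else next_star - 1
        if (rs > re && is.na(next_star)) next
        ms <- which(aa[rs:re] == "M")
        if (length(ms)) {
          cstart <- rs + ms[1] - 1
        } else if (k == 1) {
          cstart <- rs
        } else next
        aa_len <- re - cstart + 1
        if (aa_len < 1 || aa_len < min_aa) next
        has_stop <- !is.na(next_star)
        has_start <- length(ms) > 0
        comp <- if (has_start && has_stop) "complete"
          else if (has_start) "3prime_partial"
          else if (has_stop) "5prime_partial"
          else "internal"
        o_start <- frame + (cstart - 1) * 3 + 1
        o_end <- frame + (if (has_stop) next_star else re) * 3
        r_start <- if (st == "+") o_start else n - o_end + 1
        r_end <- if (st == "+") o_end else n - o_start + 1
        cands[[length(cands) + 1L]] <- data.frame(
          strand = st, start = r_start, end = r_end, completeness = comp,
          aa_length = aa_len,
          peptide = paste(aa[cstart:re], collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(cands)) return(NULL)
  df <- do.call(rbind, cands)
  comp_rank <- match(df$completeness,
                     c("complete", "5prime_partial", "3prime_partial", "internal"))
  span <- df$end - df$start + 1
  ord <- order(-span, comp_rank, df$strand != "+", df$start, method = "radix")
  df[ord[1], ]
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
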