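test_that("identical sequences yield a single full-span HSP", {
  set.seed(61)
  s <- random_dna_str(500)
  h <- find_hsps(c(a = s), c(b = s))
  expect_equal(nrow(h), 1)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1, 500, 1, 500))
  expect_equal(h$identity_pct, 100)
})

test_that("unrelated random sequences yield no HSPs", {
  set.seed(62)
  h <- find_hsps(c(a = random_dna_str(400)), c(b = random_dna_str(400)))
  expect_equal(nrow(h), 0)
})

test_that("a constructed deletion pair yields the two-HSP geometry", {
  set.seed(63)
  pr <- make_as_pair(1000, 401, 200)
  h <- find_hsps(pr$seqs[1], pr$seqs[2])
  expect_equal(nrow(h), 2)
  h <- h[order(h$q_start), ]
  wobble <- 2
  expect_lte(abs(h$q_start[1] - 1), wobble)
  expect_lte(abs(h$q_end[1] - 400), wobble)
  expect_lte(abs(h$q_start[2] - 601), wobble)
  expect_lte(abs(h$q_end[2] - 1000), wobble)
  expect_lte(abs(h$s_start[2] - 401), wobble)
  expect_lte(abs(h$s_end[2] - 800), wobble)
  expect_true(all(h$strand == "+"))
})

test_that("reverse-complemented partners produce minus-strand HSPs", {
  set.seed(64)
  s <- random_dna_str(500)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h <- find_hsps(c(a = s), c(b = rc))
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(c(h$s_start, h$s_end), c(1, 500))
})

test_that("event calling applies the gap rules to constructed coordinates", {
  mk_hsps <- function(q2_start, q2_end, s2_start, s2_end) {
    data.frame(query_id = "A", subject_id = "B",
               identity_pct = 100, aln_len = 400, mismatches = 0,
               gap_opens = 0,
               q_start = c(1, q2_start), q_end = c(400, q2_end),
               s_start = c(1, s2_start), s_end = c(400, s2_end),
               evalue = NA, bit_score = 800,
               strand = "+", stringsAsFactors = FALSE)
  }
  # contiguous on A (401 follows 400), 200-bp gap on B: one event on B
  ev <- call_as_events(mk_hsps(401, 800, 601, 1000), 800, 1000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gapped_id, "B")
  expect_equal(c(ev$gap_start, ev$gap_end, ev$gap_len), c(401, 600, 200))

  # gap of exactly 100 bp is not strictly greater than min_gap: no event
  ev <- call_as_events(mk_hsps(401, 800, 501, 900), 800, 900)
  expect_equal(nrow(ev), 0)
  # 101 bp qualifies
  ev <- call_as_events(mk_hsps(401, 800, 502, 901), 800, 901)
  expect_equal(ev$gap_len, 101)

  # 5-bp overlap on the contiguous side is not < 5: no event
  h <- mk_hsps(396, 800, 601, 1000)
  expect_equal(nrow(call_as_events(h, 800, 1000)), 0)
  # 4-bp overlap passes
  h <- mk_hsps(397, 800, 601, 1000)
  expect_equal(nrow(call_as_events(h, 800, 1000)), 1)

  # gap boundary 50 bp from the subject 3' end: no event
  ev <- call_as_events(mk_hsps(401, 800, 601, 1000), 800, 1050)
  expect_equal(nrow(ev), 1)   # 1050 - 1000 = 50 from end is the HSP, gap ok
  ev <- call_as_events(mk_hsps(401, 450, 601, 650), 450, 650)
  expect_equal(nrow(ev), 0)   # gap end 600, dist3 = 50 < 100
})

test_that("mixed transcript pairs are rejected", {
  h <- data.frame(query_id = c("A", "C"), subject_id = "B",
                  identity_pct = 100, aln_len = 10, mismatches = 0,
                  gap_opens = 0, q_start = 1, q_end = 10, s_start = 1,
                  s_end = 10, evalue = NA, bit_score = 20, strand = "+")
  expect_error(call_as_events(h, 100, 100), "single transcript pair")
})

test_that("event calling is exact at every rule boundary", {
  # sweep gap length and end distance over the +/-1 neighbourhoods of the
  # thresholds on constructed coordinate sets
  flank <- 400
  for (gap_len in c(99, 100, 101)) for (d3 in c(99, 100, 101)) {
    len_a <- 2 * flank
    len_b <- flank + gap_len + flank + (d3 - flank)  # gap end = len_b - d3
    len_b <- flank + gap_len + d3
    hsps <- data.frame(
      query_id = "A", subject_id = "B", identity_pct = 100,
      aln_len = flank, mismatches = 0, gap_opens = 0,
      q_start = c(1, flank + 1), q_end = c(flank, 2 * flank),
      s_start = c(1, flank + gap_len + 1),
      s_end = c(flank, flank + gap_len + d3),
      evalue = NA, bit_score = 2 * flank, strand = "+",
      stringsAsFactors = FALSE
    )
    ev <- call_as_events(hsps, len_a, len_b)
    should <- gap_len > 100 && d3 >= 100
    expect_equal(nrow(ev) == 1, should,
                 info = sprintf("gap_len=%d d3=%d", gap_len, d3))
  }

  # overlap boundary on the contiguous side
  for (overlap in c(4, 5, 6)) {
    hsps <- data.frame(
      query_id = "A", subject_id = "B", identity_pct = 100,
      aln_len = 400, mismatches = 0, gap_opens = 0,
      q_start = c(1, 401 - overlap), q_end = c(400, 800 - overlap),
      s_start = c(1, 601), s_end = c(400, 1000),
      evalue = NA, bit_score = 800, strand = "+", stringsAsFactors = FALSE
    )
    ev <- call_as_events(hsps, 800 - overlap, 1000)
    expect_equal(nrow(ev) == 1, overlap < 5,
                 info = sprintf("overlap=%d", overlap))
  }
})

test_that("scanning is symmetric and handles singletons", {
  set.seed(65)
  pr <- make_as_pair(900, 301, 150, ids = c("x", "y"))
  ev1 <- scan_all_pairs(pr$seqs)
  ev2 <- scan_all_pairs(rev(pr$seqs))
  expect_equal(ev1, ev2)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$gapped_id, "x")
  expect_equal(nrow(scan_all_pairs(pr$seqs[1])), 0)
})

test_that("ingested tabular alignments give the same events as the aligner", {
  set.seed(66)
  pr <- make_as_pair(1000, 401, 200, ids = c("a", "b"))
  h <- find_hsps(pr$seqs[1], pr$seqs[2])
  f <- tempfile()
  write_tabular_alignments(h, f)
  h2 <- read_tabular_alignments(f)
  ev1 <- call_as_events(h, 1000, 800)
  ev2 <- call_as_events(h2, 1000, 800)
  expect_equal(ev1[order(ev1$gap_start), c("gapped_id", "gap_start", "gap_end")],
               ev2[order(ev2$gap_start), c("gapped_id", "gap_start", "gap_end")],
               ignore_attr = TRUE)
})

test_that("planted AS events are recovered among decoys", {
  set.seed(67)
  seqs <- character(0)
  truth <- list()
  for (k in 1:4) {
    pr <- make_as_pair(1000, sample(300:500, 1), 200,
                       ids = sprintf(c("as%02d_gapped", "as%02d_contig"), k))
    seqs <- c(seqs, stats::setNames(as.character(pr$seqs), names(pr$seqs)))
    truth[[k]] <- pr$expected
  }
  for (k in 1:10) seqs <- c(seqs, stats::setNames(random_dna_str(1000),
                                                  sprintf("decoy%02d", k)))
  ev <- scan_all_pairs(Biostrings::DNAStringSet(seqs))
  truth <- do.call(rbind, truth)
  expect_equal(nrow(ev), 4)
  m <- match(ev$gapped_id, truth$gapped_id)
  expect_false(anyNA(m))
  expect_true(all(abs(ev$gap_start - truth$gap_start[m]) <= 5))
  expect_true(all(abs(ev$gap_end - truth$gap_end[m]) <= 5))
})
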