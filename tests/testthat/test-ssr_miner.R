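test_that("unit-size thresholds behave exactly at the MISA boundaries", {
  # mononucleotide boundary at 10 repeats
  h <- find_ssrs(c(x = strrep("A", 10)))
  expect_equal(nrow(h), 1)
  expect_equal(h$motif, "A")
  expect_equal(h$repeats, 10)
  expect_equal(c(h$start, h$end), c(1, 10))
  expect_equal(nrow(find_ssrs(c(x = strrep("A", 9)))), 0)

  # dinucleotide boundary at 6 repeats
  h <- find_ssrs(c(x = strrep("AT", 6)))
  expect_equal(h$motif, "AT")
  expect_equal(h$repeats, 6)
  expect_equal(nrow(find_ssrs(c(x = strrep("AT", 5)))), 0)
})

test_that("motifs are primitive and runs are counted once at the smallest unit", {
  # an A-run is never reported as AA/AAA...
  h <- find_ssrs(c(x = paste0("GC", strrep("A", 14), "GC")))
  expect_equal(nrow(h), 1)
  expect_equal(h$unit_size, 1)
  # (ACG)x6 is reported as the trinucleotide, not as (ACGACG)x3
  h <- find_ssrs(c(x = strrep("ACG", 6)))
  expect_equal(h$motif, "ACG")
  expect_equal(h$repeats, 6)
})

test_that("N bases terminate runs", {
  h <- find_ssrs(c(x = paste0(strrep("A", 8), "N", strrep("A", 8))))
  expect_equal(nrow(h), 0)
  h <- find_ssrs(c(x = paste0(strrep("A", 11), "N", strrep("A", 4))))
  expect_equal(h$repeats, 11)
})

test_that("nearby hits share a compound id, distant hits do not", {
  set.seed(40)
  thr <- ssr_thresholds()
  mk <- function(gap) paste0(strrep("AT", 7), random_dna_str(gap),
                             strrep("AG", 7))
  h <- find_ssrs(c(x = mk(50)), thr)
  expect_equal(nrow(h), 2)
  expect_equal(length(unique(h$compound_id)), 1)
  expect_false(any(is.na(h$compound_id)))

  h <- find_ssrs(c(x = mk(150)), thr)
  expect_true(all(is.na(h$compound_id)))
})

test_that("the scanner matches the brute-force oracle on random sequences", {
  set.seed(41)
  thr <- ssr_thresholds()
  for (i in 1:20) {
    s <- random_dna_str(2000)
    got <- find_ssrs(c(x = s), thr)
    want <- ssr_oracle(s, thr)
    expect_equal(got[c("motif", "unit_size", "repeats", "start", "end")],
                 want, ignore_attr = TRUE)
  }
})

test_that("reverse-complementing mirrors spans and motifs", {
  set.seed(42)
  # embed assorted repeats in a random background
  s <- paste0(random_dna_str(100), strrep("AT", 8), random_dna_str(50),
              strrep("CTG", 6), random_dna_str(100), strrep("T", 12),
              random_dna_str(60))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- find_ssrs(c(x = s))
  h2 <- find_ssrs(c(x = rc))
  expect_equal(nrow(h1), nrow(h2))
  n <- nchar(s)
  # spans mirror up to a phase shift below one unit: both orientations trim
  # a periodic run to complete units from its own leftmost position, so a
  # run whose length is not an exact multiple of the unit shifts by the
  # remainder when viewed from the other strand
  ord <- order(n - h1$end + 1)
  mirrored <- data.frame(start = (n - h1$end + 1)[ord],
                         end = (n - h1$start + 1)[ord],
                         unit = h1$unit_size[ord])
  expect_true(all(abs(h2$start - mirrored$start) < mirrored$unit))
  expect_true(all(abs(h2$end - mirrored$end) < mirrored$unit))
  expect_equal(h2$repeats[order(h2$start)], h1$repeats[ord])
  expect_setequal(canonical_motif(h1$motif), canonical_motif(h2$motif))
})

test_that("same-unit-size hits never overlap and are maximal", {
  set.seed(43)
  for (i in 1:5) {
    s <- paste0(random_dna_str(500), strrep("AG", 10), random_dna_str(500))
    h <- find_ssrs(c(x = s))
    for (u in unique(h$unit_size)) {
      hu <- h[h$unit_size == u, ]
      if (nrow(hu) > 1) {
        hu <- hu[order(hu$start), ]
        expect_true(all(hu$start[-1] > hu$end[-nrow(hu)]))
      }
    }
    # extending any hit by one unit breaks the repeat
    for (k in seq_len(nrow(h))) {
      unit <- h$motif[k]
      u <- h$unit_size[k]
      after <- substr(s, h$end[k] + 1, h$end[k] + u)
      if (nchar(after) == u) expect_false(after == unit)
    }
  }
})

test_that("the report reproduces the reference table arithmetic", {
  counts <- c(21885, 9024, 5553, 466, 124, 209)
  total <- 37261
  expect_equal(sum(counts), total)
  pct <- percent_of(counts, total, 2)
  expect_equal(pct, c(58.73, 24.22, 14.90, 1.25, 0.33, 0.56))
  expect_lte(abs(sum(pct) - 100), 0.03)
})

test_that("report shape covers totals, multi-SSR sequences and compounds", {
  set.seed(44)
  seqs <- c(
    s1 = paste0(random_dna_str(200), strrep("AT", 7), random_dna_str(30),
                strrep("AAG", 6), random_dna_str(200)),
    s2 = paste0(random_dna_str(100), strrep("C", 12), random_dna_str(400),
                strrep("GT", 8), random_dna_str(100)),
    s3 = random_dna_str(300)
  )
  hits <- find_ssrs(seqs)
  rep <- ssr_report(hits, seqs)
  val <- stats::setNames(rep$summary$value, rep$summary$item)
  expect_equal(val[["Total number of sequences examined"]], 3)
  expect_equal(val[["Total size of examined sequences (bp)"]],
               sum(nchar(seqs)))
  expect_equal(val[["Total number of identified SSRs"]], nrow(hits))
  expect_equal(val[["Number of SSR-containing sequences"]],
               length(unique(hits$seq_id)))
  expect_equal(sum(rep$unit_counts$count), nrow(hits))
  expect_equal(sum(rep$density$count), nrow(hits))

  empty <- ssr_report(find_ssrs(c(x = "ACGTACGTAA")), c(x = "ACGTACGTAA"))
  expect_equal(empty$summary$value[3], 0)
  expect_true(all(is.na(empty$unit_counts$pct)))
})
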