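test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- fixture_config(n_reads = 50)
  set.seed(42); a <- make_reads(cfg)
  set.seed(42); b <- make_reads(cfg)
  expect_identical(as.character(a$reads), as.character(b$reads))
  expect_identical(a$truth, b$truth)
})

test_that("class fractions shape the truth table", {
  cfg <- fixture_config(n_reads = 200, fraction_chimeric = 0)
  set.seed(1)
  sim <- make_reads(cfg)
  expect_false(any(sim$truth$reads$label == "CHIMERIC"))

  # FLNC count within the binomial 99% interval around n * p
  cfg <- fixture_config(n_reads = 1000, fraction_flnc = 0.8)
  set.seed(2)
  sim <- make_reads(cfg)
  n_flnc <- sum(sim$truth$reads$label == "FLNC")
  lo <- stats::qbinom(0.005, 1000, 0.8)
  hi <- stats::qbinom(0.995, 1000, 0.8)
  expect_gte(n_flnc, lo)
  expect_lte(n_flnc, hi)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(fixture_config(fraction_flnc = 0.9, fraction_missing_primer = 0.2),
               "sum")
  expect_error(fixture_config(n_reads = 0), "positive")
  expect_error(fixture_config(primer_5 = "ACGU"), "ACGT")
})

test_that("planted FLNC reads carry the documented layout", {
  cfg <- fixture_config(n_reads = 40)
  set.seed(5)
  sim <- make_reads(cfg)
  tr <- sim$truth$reads
  seqs <- as.character(sim$reads)
  flnc <- tr[tr$label == "FLNC", ]
  p5 <- cfg$primer_5
  for (i in seq_len(nrow(flnc))) {
    s <- seqs[[flnc$id[i]]]
    expect_identical(substr(s, 1, nchar(p5)), p5)
    expect_identical(substr(s, flnc$insert_start[i], flnc$insert_end[i]),
                     flnc$insert[i])
  }
})

test_that("planted truth features are re-locatable by exact string match", {
  cfg <- fixture_config(
    n_reads = 30,
    ssr_spec = data.frame(motif = "AT", repeats = 8, count = 3),
    orf_spec = data.frame(aa_len = 60, count = 3)
  )
  set.seed(9)
  sim <- make_reads(cfg)
  seqs <- as.character(sim$reads)
  for (i in seq_len(nrow(sim$truth$ssrs))) {
    r <- sim$truth$ssrs[i, ]
    expect_identical(substr(seqs[[r$read_id]], r$read_start, r$read_end),
                     strrep(r$motif, r$repeats))
  }
  for (i in seq_len(nrow(sim$truth$orfs))) {
    r <- sim$truth$orfs[i, ]
    cds <- substr(seqs[[r$read_id]], r$read_start, r$read_end)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_identical(substr(cds, nchar(cds) - 2, nchar(cds)), "TAA")
    expect_equal(nchar(cds), 3 * (r$aa_len + 1))
  }
})

test_that("make_as_pair deletes the stated block and grades callability", {
  set.seed(7)
  pr <- make_as_pair(1000, 401, 200)
  a <- as.character(pr$seqs)[[1]]
  b <- as.character(pr$seqs)[[2]]
  expect_equal(nchar(b), 800)
  expect_identical(b, paste0(substr(a, 1, 400), substr(a, 601, 1000)))
  expect_true(pr$expected$callable)

  expect_false(make_as_pair(1000, 401, 100)$expected$callable)  # gap not > 100
  # gap ending 50 bp from the 3' end fails the end-distance rule
  expect_false(make_as_pair(1000, 801, 150)$expected$callable)
  expect_error(make_as_pair(1000, 950, 60), "inside")
})

test_that("cluster families match their specification", {
  set.seed(13)
  fam <- make_cluster_families(5, 4, seq_len = 600,
                               within_identity = 0.995,
                               between_identity = 0.85)
  expect_length(fam$seqs, 20)
  expect_equal(length(unique(fam$truth$family)), 5)

  # realized identity, verified by alignment: every member stays >= 0.99 to
  # its family founder (the ancestor); member-member pairs accumulate the
  # mutations of both sides, so they are only bounded near 1 - 2*(1 - w)
  for (f in unique(fam$truth$family)) {
    ids <- fam$truth$id[fam$truth$family == f]
    seqs <- as.character(fam$seqs[ids])
    for (j in 2:length(seqs)) {
      expect_gte(isoscan:::global_identity(seqs[1], seqs[j]), 0.99)
    }
    for (i in 1:(length(seqs) - 1)) for (j in (i + 1):length(seqs)) {
      expect_gte(isoscan:::global_identity(seqs[i], seqs[j]), 0.98)
    }
  }

  single <- make_cluster_families(3, 1, seq_len = 300)
  expect_length(single$seqs, 3)
  expect_error(make_cluster_families(2, 2, within_identity = 0.8,
                                     between_identity = 0.9),
               "exceed")
})
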