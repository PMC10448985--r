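test_that("scan_motifs finds all four families", {
  mo <- scan_motifs("ATGTAA")
  expect_equal(mo$start, 1L)
  expect_equal(mo$stop, 4L)            # TAA
  expect_equal(mo$donor, 3L)           # GT inside ATGT
  expect_length(mo$acceptor, 0L)
  mo <- scan_motifs("CAGGT")
  expect_equal(mo$acceptor, 1L)
  expect_equal(mo$donor, 4L)
  mo <- scan_motifs("NNNN")
  expect_true(all(lengths(mo) == 0L))
  expect_length(scan_motifs("ANTGNT")$start, 0L)   # N breaks motifs
})

test_that("enumerate_potential_cds applies boundary conventions and strict bounds", {
  f <- fig1_fixture()
  cands <- enumerate_potential_cds(f$seq, consensus_config(lmin = 5, lmax = 60))
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$cds_type, "internal")
  expect_equal(cands$start, f$start)
  expect_equal(cands$end, f$end)
  expect_equal(cands$length, 10L)
  # strict exclusion at L == lmin and L == lmax
  expect_equal(nrow(enumerate_potential_cds(
    f$seq, consensus_config(lmin = 10, lmax = 60))), 0L)
  expect_equal(nrow(enumerate_potential_cds(
    f$seq, consensus_config(lmin = 5, lmax = 10))), 0L)
})

test_that("single-type candidates span ATG through the stop codon", {
  # lone ATG ... TAA in a motif-free background
  seq <- paste0(strrep("C", 20), "ATG", "ACCACCACC", "TAA", strrep("C", 20))
  cands <- enumerate_potential_cds(seq, consensus_config(lmin = 5, lmax = 60))
  single <- cands[cands$cds_type == "single", ]
  expect_equal(nrow(single), 1L)
  expect_equal(single$start, 21L)
  expect_equal(single$end, 21L + 15L - 1L)      # ATG + 9 + TAA = 15 nt
  expect_equal(substr(seq, single$start, single$start + 2L), "ATG")
  expect_equal(substr(seq, single$end - 2L, single$end), "TAA")
})

test_that("score_region counts N1/N0 with Inf and zero edge cases", {
  f <- fig1_fixture()
  labels <- integer(nchar(f$seq))
  labels[f$start:(f$start + 5L)] <- 1L          # six 1s in the 10-nt interior
  init <- prediction_track("s", labels, window = 9L)
  cfg <- consensus_config(lmin = 5, lmax = 60)
  sc <- score_regions(enumerate_potential_cds(f$seq, cfg), init)
  expect_equal(sc$n1, 6L)
  expect_equal(sc$n0, 4L)
  expect_equal(sc$ratio, 1.5)
  all1 <- prediction_track("s", rep(1L, nchar(f$seq)), window = 9L)
  expect_equal(score_regions(enumerate_potential_cds(f$seq, cfg), all1)$ratio, Inf)
  all0 <- prediction_track("s", integer(nchar(f$seq)), window = 9L)
  expect_equal(score_regions(enumerate_potential_cds(f$seq, cfg), all0)$ratio, 0)
})

test_that("adjust_predictions flips whole regions by threshold", {
  f <- fig1_fixture()
  labels <- integer(nchar(f$seq))
  labels[f$start:(f$start + 5L)] <- 1L
  labels[3L] <- 1L                               # a stray 1 outside candidates
  init <- prediction_track("s", labels, window = 9L)
  cfg <- consensus_config(lmin = 5, lmax = 60)
  up <- adjust_predictions(f$seq, init, cfg, threshold = 1)
  expect_equal(which(up$adjusted$labels == 1L), f$start:f$end)  # flip up, stray zeroed
  down <- adjust_predictions(f$seq, init, cfg, threshold = 2)
  expect_equal(sum(down$adjusted$labels), 0L)                   # flip down
  expect_equal(nrow(down$accepted), 0L)
})

test_that("containment precedence: nested candidates yield only the largest", {
  # ATG ... [ATG ... TAA] ... TAA: inner single nested in outer single
  seq <- paste0(strrep("C", 20), "ATGAAC", "ATGACCACCTAA", "AACTAA",
                strrep("C", 20))
  cfg <- consensus_config(lmin = 5, lmax = 100)
  cands <- enumerate_potential_cds(seq, cfg)
  expect_gte(nrow(cands), 2L)
  init <- prediction_track("s", rep(1L, nchar(seq)), window = 9L)
  res <- adjust_predictions(seq, init, cfg, threshold = 1)
  outer_len <- max(cands$length)
  expect_equal(res$accepted$length[1], outer_len)
  inner <- cands[cands$length < outer_len, ]
  contained <- inner$start >= res$accepted$start[1] &
    inner$end <= res$accepted$end[1]
  expect_false(any(paste(res$accepted$start, res$accepted$end) %in%
                   paste(inner$start[contained], inner$end[contained])))
})

test_that("adjustment matches the brute-force oracle on random inputs", {
  set.seed(31)
  cfg <- consensus_config(lmin = 5, lmax = 60)
  for (i in 1:40) {
    n <- sample(80:300, 1)
    seq <- random_seq(n, p_n = 0.03)
    init <- prediction_track("s", stats::rbinom(n, 1, runif(1, 0.2, 0.8)),
                             window = 9L)
    th <- sample(c(0.4, 1, 2), 1)
    fast <- adjust_predictions(seq, init, cfg, threshold = th)
    slow <- oracle_adjust(seq, init, cfg, th)
    expect_identical(fast$adjusted$labels, slow$labels)
  }
})

test_that("re-adjustment preserves accepted regions (monotone growth)", {
  # exact idempotence does not hold for the published procedure: flipping a
  # region to all-coding can lift a longer, partially overlapping candidate
  # above threshold on the second pass. What does hold: every accepted
  # interior stays coding, so the adjusted label set can only grow.
  set.seed(32)
  for (i in 1:10) {
    seq <- random_seq(400)
    init <- prediction_track("s", stats::rbinom(400, 1, 0.5), window = 9L)
    cfg <- consensus_config(lmin = 5, lmax = 80)
    a1 <- adjust_predictions(seq, init, cfg, threshold = 1)
    a2 <- adjust_predictions(seq, a1$adjusted, cfg, threshold = 1)
    expect_true(all(a2$adjusted$labels >= a1$adjusted$labels))
  }
  # on an isolated single-candidate fixture idempotence is exact
  f <- fig1_fixture()
  labels <- integer(nchar(f$seq)); labels[f$start:(f$start + 5L)] <- 1L
  init <- prediction_track("s", labels, window = 9L)
  cfg <- consensus_config(lmin = 5, lmax = 60)
  b1 <- adjust_predictions(f$seq, init, cfg, threshold = 1)
  b2 <- adjust_predictions(f$seq, b1$adjusted, cfg, threshold = 1)
  expect_identical(b2$adjusted$labels, b1$adjusted$labels)
  expect_equal(b2$accepted[, c("start", "end")],
               b1$accepted[, c("start", "end")])
})

test_that("coding_fraction counts valid positions only", {
  labels <- integer(100); labels[41:65] <- 1L
  tr <- prediction_track("s", labels, window = 69L)   # valid 35..66
  expect_equal(coding_fraction(tr), 25 / 32)
  expect_equal(coding_fraction(prediction_track("s", integer(100), 69L)), 0)
  expect_equal(coding_fraction(prediction_track("s", rep(1L, 100), 69L)), 1)
})

test_that("fraction_targeted_sweep stops at the first qualifying threshold", {
  set.seed(33)
  seq <- random_seq(2000)
  init <- prediction_track("s", stats::rbinom(2000, 1, 0.7), window = 9L)
  cfg <- consensus_config(lmin = 5, lmax = 120,
                          threshold_grid = c(0.5, 1, 2, 4, 8, 16),
                          target_coding_fraction = 0.1,
                          fraction_margin = 0.1)
  sw <- fraction_targeted_sweep(seq, init, cfg)
  # reference walk of the stated stopping rule
  fr <- vapply(cfg$threshold_grid, function(th)
    coding_fraction(adjust_predictions(seq, init, cfg, th)$adjusted),
    numeric(1))
  qualifying <- which(fr <= 0.2)
  expect_equal(sw$threshold, cfg$threshold_grid[qualifying[1]])
  expect_equal(sw$trajectory$fraction, fr[seq_len(qualifying[1])])
  expect_false(sw$exhausted)
  # immediate stop when already below target + margin
  quiet <- prediction_track("s", integer(2000), window = 9L)
  sw0 <- fraction_targeted_sweep(seq, quiet, cfg)
  expect_equal(sw0$threshold, 0.5)
  # exhaustion: all-1 predictions, dense candidates, unreachable target
  dense <- prediction_track("s", rep(1L, 2000), window = 9L)
  cfg2 <- consensus_config(lmin = 5, lmax = 120, threshold_grid = c(0.5, 1),
                           target_coding_fraction = 0.01,
                           fraction_margin = 0.01)
  expect_warning(sw1 <- fraction_targeted_sweep(seq, dense, cfg2), "exhausted")
  expect_true(sw1$exhausted)
  expect_equal(sw1$threshold, 1)
})

test_that("threshold monotonicity of adjusted coding fraction", {
  set.seed(34)
  seq <- random_seq(3000)
  init <- prediction_track("s", stats::rbinom(3000, 1, 0.6), window = 9L)
  cfg <- consensus_config(lmin = 5, lmax = 120)
  fr <- vapply(cfg$threshold_grid, function(th)
    coding_fraction(adjust_predictions(seq, init, cfg, th)$adjusted),
    numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("BED output is 0-based half-open with type names", {
  f <- fig1_fixture()
  labels <- integer(nchar(f$seq)); labels[f$start:f$end] <- 1L
  init <- prediction_track("s", labels, window = 9L)
  res <- adjust_predictions(f$seq, init, consensus_config(lmin = 5, lmax = 60),
                            threshold = 1)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_cds_bed(res$accepted, "s", bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields[1:4], c("s", as.character(f$start - 1L),
                              as.character(f$end), "internal"))
  expect_equal(fields[5], "1000")      # ratio Inf caps at 1000
})
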