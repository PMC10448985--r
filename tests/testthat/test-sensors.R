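test_that("voss_encode maps bases to the published indicator vectors", {
  m <- voss_encode("AT")
  expect_equal(unname(m[, 1]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(m[, 2]), c(0L, 1L, 0L, 0L))
  expect_equal(unname(voss_encode("N")[, 1]), c(0L, 0L, 0L, 0L))
  set.seed(2)
  cs <- colSums(voss_encode(random_seq(100, p_n = 0.2)))
  expect_true(all(cs <= 1L))
})

test_that("sensor_dft reproduces analytic anchors", {
  expect_equal(sensor_dft(strrep("ACG", 23)), 69)
  expect_equal(sensor_dft(strrep("A", 69)), 0, tolerance = 1e-12)
  expect_equal(sensor_dft(strrep("N", 69)), 0)
  expect_error(sensor_dft(strrep("A", 70)), "divisible by 3")
})

test_that("sensor_dft matches the brute-force oracle on random windows", {
  set.seed(11)
  for (i in 1:200) {
    w <- random_seq(69, p_n = 0.05)
    expect_equal(sensor_dft(w), oracle_dft(w), tolerance = 1e-9)
  }
})

test_that("sensor_kmer equals per-position oracle recomputation exactly", {
  set.seed(12)
  tab <- toy_kmer_table(3, list(AAA = exp(1), CGT = exp(-2), TTT = 5))
  for (i in 1:50) {
    w <- random_seq(69, p_n = 0.05)
    expect_identical(sensor_kmer(w, tab), oracle_kmer(w, tab))
    expect_identical(sensor_kmer(w, tab, "as_printed"),
                     oracle_kmer(w, tab, full = FALSE))
  }
})

test_that("sensor_kmer analytic cases", {
  tab <- toy_kmer_table(3, list(AAA = exp(1)))
  expect_equal(sensor_kmer(strrep("A", 69), tab), -67)       # W-k+1 positions
  expect_equal(sensor_kmer(strrep("A", 69), tab, "as_printed"), -65)
  expect_equal(sensor_kmer(strrep("N", 69), tab), 0)
  unit <- toy_kmer_table(3)
  expect_equal(sensor_kmer(random_seq(69), unit), 0)         # p1 == p0
})

test_that("sensor_gc handles composition and degenerate windows", {
  expect_equal(sensor_gc(strrep("GC", 30)), 1)
  expect_equal(sensor_gc("ATGCATGCATGC"), 0.5)
  expect_equal(sensor_gc(strrep("N", 69)), 0)
  expect_equal(sensor_gc("GGNN"), 1)                         # N excluded
})

test_that("motif-distance sensor implements max(W/2 - D, 0)", {
  base <- strrep("C", 69)
  w <- base; substr(w, 45, 47) <- "ATG"                      # D = 10 right
  expect_equal(sensor_motif_distance(w, "start", "right"), 24.5)
  expect_equal(sensor_motif_distance(w, "start", "left"), 0)
  w <- base; substr(w, 1, 3) <- "ATG"                        # left edge, D = 34
  expect_equal(sensor_motif_distance(w, "start", "left"), 0.5)
  w <- base; substr(w, 35, 37) <- "ATG"                      # at center: right, D = 0
  expect_equal(sensor_motif_distance(w, "start", "right"), 34.5)
  expect_equal(sensor_motif_distance(w, "start", "left"), 0)
  expect_equal(sensor_motif_distance(base, "stop", "right"), 0)
  w <- base; substr(w, 40, 42) <- "TGA"
  expect_equal(sensor_motif_distance(w, "stop", "right"), 34.5 - 5)
  w <- base; substr(w, 30, 31) <- "GT"
  expect_equal(sensor_motif_distance(w, "donor", "left"), 34.5 - 5)
  w <- base; substr(w, 20, 22) <- "TAG"                      # acceptor & stop
  expect_equal(sensor_motif_distance(w, "acceptor", "left"), 34.5 - 15)
  w <- strrep("N", 69)
  for (f in c("start", "stop", "acceptor", "donor"))
    expect_equal(sensor_motif_distance(w, f, "right"), 0)
})

test_that("sensor_entropy anchors for both variants", {
  expect_equal(sensor_entropy(strrep("A", 69), "as_printed"), 0)
  expect_equal(sensor_entropy(strrep("A", 69), "standard"), 0)
  u <- strrep("ACGT", 16)                                    # n_b = W/4 each
  expect_equal(sensor_entropy(u, "as_printed"), 0.25 * log(4))
  expect_equal(sensor_entropy(u, "standard"), log(4))
  expect_equal(sensor_entropy(strrep("N", 69), "as_printed"), 0)
})

test_that("entropy (standard) is maximal for uniform and 0 for homopolymers", {
  set.seed(3)
  u_val <- sensor_entropy(strrep("ACGT", 17), "standard")
  for (i in 1:50) {
    w <- random_seq(68)
    expect_lte(sensor_entropy(w, "standard"), u_val + 1e-12)
  }
})

test_that("featurize_track agrees with the scalar sensors window by window", {
  set.seed(21)
  seq <- random_seq(400, p_n = 0.02)
  rec <- sequence_record("s", seq)
  tabs <- lapply(2:6, function(k)
    toy_kmer_table(k, stats::setNames(list(exp(1)), strrep("A", k))))
  fm <- featurize_track(rec, sensor_config(), tabs)
  expect_equal(nrow(fm$values), 400 - 68)
  for (i in sample(nrow(fm$values), 15)) {
    p <- fm$positions[i]
    w <- substr(seq, p - 34L, p + 34L)
    expected <- c(sensor_dft(w),
                  vapply(tabs, function(t) sensor_kmer(w, t), numeric(1)),
                  sensor_gc(w),
                  sensor_motif_distance(w, "start", "right"),
                  sensor_motif_distance(w, "start", "left"),
                  sensor_motif_distance(w, "stop", "right"),
                  sensor_motif_distance(w, "stop", "left"),
                  sensor_motif_distance(w, "acceptor", "right"),
                  sensor_motif_distance(w, "acceptor", "left"),
                  sensor_motif_distance(w, "donor", "right"),
                  sensor_motif_distance(w, "donor", "left"),
                  sensor_entropy(w, "as_printed"))
    expect_equal(unname(fm$values[i, ]), expected, tolerance = 1e-10)
  }
})

test_that("featurize_track row count, degenerate all-N input, determinism", {
  tabs <- lapply(2:6, function(k) toy_kmer_table(k))
  rec100 <- sequence_record("s", random_seq(100))
  expect_equal(nrow(featurize_track(rec100, sensor_config(), tabs)$values), 32L)
  recN <- suppressWarnings(sequence_record("n", strrep("N", 80)))
  fmN <- featurize_track(recN, sensor_config(), tabs)
  expect_true(all(fmN$values == 0))
  seq <- random_seq(150)
  f1 <- featurize_track(sequence_record("a", seq), sensor_config(), tabs)
  f2 <- featurize_track(sequence_record("b", seq), sensor_config(), tabs)
  expect_equal(unname(f1$values), unname(f2$values))
  expect_error(featurize_track(sequence_record("x", "ACGT"),
                               sensor_config(), tabs), "shorter")
})

test_that("distance sensors stay in [0, W/2] and all outputs are finite", {
  set.seed(4)
  tabs <- lapply(2:6, function(k) toy_kmer_table(k))
  fm <- featurize_track(sequence_record("s", random_seq(500, p_n = 0.1)),
                        sensor_config(), tabs)
  dist_cols <- grep("_(left|right)$", colnames(fm$values))
  expect_true(all(fm$values[, dist_cols] >= 0))
  expect_true(all(fm$values[, dist_cols] <= 34.5))
  expect_true(all(is.finite(fm$values)))
})

test_that("feature TSV round-trips", {
  tabs <- lapply(2:6, function(k) toy_kmer_table(k))
  fm <- featurize_track(sequence_record("s", random_seq(120)),
                        sensor_config(), tabs)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(fm, tsv)
  back <- read_features_tsv(tsv, "s", 120L)
  expect_equal(back$positions, fm$positions)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-8)
})
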