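# Independent oracles, deliberately naive: these re-derive expected values by
# brute force and must never share code with the implementation paths they
# check.

# DFT oracle: literal complex-exponential double sum over the four binary
# indicator tracks at frequency W/3
oracle_dft <- function(window_seq) {
  ch <- strsplit(window_seq, "", fixed = TRUE)[[1]]
  W <- length(ch)
  total <- 0
  for (b in c("A", "T", "G", "C")) {
    acc <- 0 + 0i
    for (n in seq_len(W)) {
      if (ch[n] == b) acc <- acc + exp(-1i * 2 * pi * (n - 1) * (W / 3) / W)
    }
    total <- total + Mod(acc)
  }
  total
}

# k-mer oracle: per-position lookup and literal summation
oracle_kmer <- function(window_seq, table, full = TRUE) {
  W <- nchar(window_seq)
  k <- table$k
  last <- if (full) W - k + 1L else W - k - 1L
  if (last < 1L) return(0)
  lr <- -log(table$p1 / table$p0)
  vals <- numeric(0)
  for (i in seq_len(last)) {
    word <- substr(window_seq, i, i + k - 1L)
    if (!grepl("N", word, fixed = TRUE)) vals <- c(vals, lr[[word]])
  }
  sum(vals)
}

# consensus oracle: the literal published procedure — candidates tested in
# length-descending order, accepted iff ratio strictly above threshold and
# not contained in an already-accepted region
oracle_adjust <- function(seq, initial, config, threshold) {
  regs <- score_regions(enumerate_potential_cds(seq, config), initial)
  acc <- regs[0, ]
  if (nrow(regs) > 0) {
    for (i in seq_len(nrow(regs))) {
      r <- regs[i, ]
      if (nrow(acc) > 0 &&
          any(acc$start <= r$start & acc$end >= r$end)) next
      if (r$ratio > threshold) acc <- rbind(acc, r)
    }
  }
  labels <- integer(length(initial$labels))
  if (nrow(acc) > 0)
    for (i in seq_len(nrow(acc))) labels[acc$start[i]:acc$end[i]] <- 1L
  list(labels = labels, accepted = acc)
}

# checks that every maximal run of 1s in an adjusted track is the interior of
# a motif-bounded region: left edge an ATG or preceded by YAG, right edge a
# stop codon end or followed by GT
runs_motif_bounded <- function(seq, labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- TRUE
  for (i in which(r$values == 1L)) {
    s <- starts[i]; e <- ends[i]
    left_ok <- substr(seq, s, s + 2L) == "ATG" ||
      (s >= 4L && substr(seq, s - 3L, s - 1L) %in% c("CAG", "TAG"))
    right_ok <- substr(seq, e - 2L, e) %in% c("TAG", "TAA", "TGA") ||
      substr(seq, e + 1L, e + 2L) == "GT"
    if (!left_ok || !right_ok) ok <- FALSE
  }
  ok
}

# random test sequence over ACGTN
random_seq <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# uniform-ratio k-mer table with selected overrides of p1/p0
toy_kmer_table <- function(k, ratio_overrides = list()) {
  km <- all_kmers(k)
  p1 <- stats::setNames(rep(0.25, 4^k), km)
  p0 <- p1
  for (w in names(ratio_overrides))
    p1[w] <- p0[w] * ratio_overrides[[w]]
  kmer_frequency_table(k, p1, p0)
}

# the Fig-1-style fixture: lone YAG ... 10 nt interior ... GT inside a
# motif-free C background; exactly one (internal) candidate of L = 10
fig1_fixture <- function(flank = 30L) {
  interior <- "ACCACCACCA"                     # 10 nt, no motifs
  seq <- paste0(strrep("C", flank), "CAG", interior, "GT", strrep("C", flank))
  int_start <- flank + 4L
  list(seq = seq, start = int_start, end = int_start + 9L)
}
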