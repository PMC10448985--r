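# The 16 per-nucleotide sensors, each computed over a window of W nt centered
# on the query base:
#   1     period-3 DFT magnitude (Voss binary encoding)
#   2-6   k-mer coding-potential sums, k = 2..6, score -ln(p1/p0)
#   7     GC content
#   8-15  distance to the nearest start / stop / YAG-acceptor / GT-donor motif
#         on each side of the center, scored max(W/2 - D, 0)
#   16    Shannon entropy of base composition
# Scalar single-window functions are the reference implementation; featurize
# computes all positions at once with cumulative-sum sliding windows.

FEATURE_NAMES <- c("dft", "kmer2", "kmer3", "kmer4", "kmer5", "kmer6", "gc",
                   "start_right", "start_left", "stop_right", "stop_left",
                   "acc_right", "acc_left", "don_right", "don_left", "entropy")

MOTIF_STRINGS <- list(start    = "ATG",
                      stop     = c("TAG", "TAA", "TGA"),
                      acceptor = c("CAG", "TAG"),    # YAG, Y in {C,T}
                      donor    = "GT")

#' Sensor configuration
#'
#' @param window Odd window width W (default 69; the DFT sensor additionally
#'   requires W divisible by 3). Accuracy is reported to degrade for W > 99.
#' @param kmer_ks k-mer sensor lengths (default `2:6`).
#' @param entropy_variant `"as_printed"` keeps the extra `P(b)` factor of the
#'   published entropy formula; `"standard"` is Shannon entropy
#'   `-sum P(b) ln P(b)`.
#' @param kmer_sum `"full"` sums all `W-k+1` k-mer start positions in the
#'   window; `"as_printed"` reproduces the published summation limit of
#'   `W-k-1` terms.
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(window = 69L, kmer_ks = 2:6,
                          entropy_variant = c("as_printed", "standard"),
                          kmer_sum = c("full", "as_printed")) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3, got ", window)
  kmer_ks <- sort(as.integer(kmer_ks))
  if (!all(kmer_ks %in% 2:6)) stop("kmer_ks must be a subset of {2,...,6}")
  structure(list(window = window, kmer_ks = kmer_ks,
                 entropy_variant = match.arg(entropy_variant),
                 kmer_sum = match.arg(kmer_sum)),
            class = "sensor_config")
}

#' Voss binary encoding of a window
#'
#' Maps A to `[1,0,0,0]`, T to `[0,1,0,0]`, G to `[0,0,1,0]`, C to
#' `[0,0,0,1]` (one column per position, rows in A,T,G,C order); N gives a
#' null all-zero column.
#'
#' @param window_seq DNA string.
#' @return A 4 x `nchar(window_seq)` 0/1 matrix with rownames `A,T,G,C`.
#' @export
voss_encode <- function(window_seq) {
  ch <- strsplit(window_seq, "", fixed = TRUE)[[1]]
  m <- rbind(A = as.integer(ch == "A"), T = as.integer(ch == "T"),
             G = as.integer(ch == "G"), C = as.integer(ch == "C"))
  m
}

#' Period-3 DFT sensor
#'
#' Magnitude of the DFT of each Voss indicator track at frequency `W/3`
#' (phase `e^{-i 2 pi n / 3}`), summed over the four tracks. Coding DNA shows
#' an enhanced period-3 signal from codon structure.
#'
#' @param window_seq DNA string of length divisible by 3.
#' @return Non-negative real.
#' @export
sensor_dft <- function(window_seq) {
  W <- nchar(window_seq)
  if (W %% 3L != 0L)
    stop("DFT sensor requires a window length divisible by 3, got ", W)
  x <- voss_encode(window_seq)
  w <- exp(-2i * pi * (0:(W - 1L)) / 3)
  sum(Mod(x %*% w))
}

#' k-mer coding-potential sensor
#'
#' Slides one base at a time over the window and sums the per-k-mer score
#' `-ln(p1/p0)`; k-mers containing N contribute 0. Negative sums indicate
#' coding-like composition.
#'
#' @param window_seq DNA string, at least `k` long.
#' @param table A [kmer_frequency_table()].
#' @param sum_mode `"full"` (all `W-k+1` start positions) or `"as_printed"`
#'   (`W-k-1` terms, the published summation limit).
#' @return Real.
#' @export
sensor_kmer <- function(window_seq, table, sum_mode = c("full", "as_printed")) {
  sum_mode <- match.arg(sum_mode)
  W <- nchar(window_seq); k <- table$k
  if (W < k) stop("window shorter than k")
  last <- if (sum_mode == "full") W - k + 1L else W - k - 1L
  if (last < 1L) return(0)
  words <- substring(window_seq, 1:last, k:(last + k - 1L))
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0L) return(0)
  sum(kmer_log_ratio(table)[words])
}

#' GC-content sensor
#'
#' `(nG+nC)/(nA+nT+nG+nC)` over the window; N is excluded from numerator and
#' denominator, and an all-N window returns 0.
#'
#' @param window_seq DNA string.
#' @return Real in `[0,1]`.
#' @export
sensor_gc <- function(window_seq) {
  ch <- strsplit(window_seq, "", fixed = TRUE)[[1]]
  den <- sum(ch != "N")
  if (den == 0L) return(0)
  sum(ch == "G" | ch == "C") / den
}

#' Motif-distance sensor
#'
#' Distance from the window center to the nearest motif of the requested
#' family on the requested side, scored `max(W/2 - D, 0)` where `D` is the
#' number of nt from the center to the motif's first base. A motif whose first
#' base sits exactly on the center counts to the right side with `D = 0`;
#' left-side scans use `D >= 1`. Motifs must lie entirely inside the window
#' and may not contain N. Returns 0 when no motif is found on that side.
#'
#' @param window_seq DNA string of odd length W.
#' @param motif_family One of `"start"` (ATG), `"stop"` (TAG/TAA/TGA),
#'   `"acceptor"` (YAG), `"donor"` (GT).
#' @param side `"left"` or `"right"` of the center.
#' @return Real in `[0, W/2]`.
#' @export
sensor_motif_distance <- function(window_seq,
                                  motif_family = c("start", "stop",
                                                   "acceptor", "donor"),
                                  side = c("left", "right")) {
  motif_family <- match.arg(motif_family); side <- match.arg(side)
  W <- nchar(window_seq)
  if (W %% 2L == 0L) stop("window length must be odd")
  h <- W %/% 2L; center <- h + 1L
  occ <- motif_positions(window_seq, motif_family)
  if (side == "right") {
    D <- occ[occ >= center] - center
  } else {
    D <- center - occ[occ <= center - 1L]
  }
  D <- D[D <= h]
  if (length(D) == 0L) return(0)
  max(W / 2 - min(D), 0)
}

# 1-based first-base positions of all (fully contained) motif matches
motif_positions <- function(seq, motif_family) {
  motifs <- MOTIF_STRINGS[[motif_family]]
  n <- nchar(seq)
  m <- nchar(motifs[1])
  if (n < m) return(integer(0))
  words <- substring(seq, 1:(n - m + 1L), m:n)
  which(words %in% motifs)
}

#' Shannon-entropy sensor
#'
#' Base-composition entropy of the window with `P(b) = n_b / W` (N counts in
#' the denominator W but has no term of its own). The `"as_printed"` variant
#' follows the published formula `-(1/W) sum_b n_b P(b) ln P(b)`, which
#' carries an extra `P(b)` factor relative to Shannon entropy; `"standard"`
#' is `-sum_b P(b) ln P(b)`. Natural log.
#'
#' @param window_seq DNA string.
#' @param variant `"as_printed"` or `"standard"`.
#' @return Non-negative real.
#' @export
sensor_entropy <- function(window_seq, variant = c("as_printed", "standard")) {
  variant <- match.arg(variant)
  ch <- strsplit(window_seq, "", fixed = TRUE)[[1]]
  W <- length(ch)
  nb <- c(sum(ch == "A"), sum(ch == "T"), sum(ch == "G"), sum(ch == "C"))
  nb <- nb[nb > 0L]
  if (length(nb) == 0L) return(0)
  P <- nb / W
  if (variant == "as_printed") -(1 / W) * sum(nb * P * log(P))
  else -sum(P * log(P))
}

# ---- vectorized featurization ------------------------------------------------

# windowed sums of v (length n) for windows [p-h, p+h] at positions p
window_sums <- function(v, p, h) {
  cs <- c(0, cumsum(v))
  cs[p + h + 1L] - cs[p - h]
}

#' Per-position 16-component sensor feature matrix
#'
#' Computes every sensor at every valid position (those with a full centered
#' window) of a sequence, using cumulative-sum sliding windows; results are
#' identical to calling the scalar sensor functions window by window.
#'
#' @param record A [sequence_record()].
#' @param config A [sensor_config()].
#' @param tables Named list of [kmer_frequency_table()], one per configured k
#'   (names ignored; matched by their `k` field).
#' @return An object of class `feature_matrix`: fields `seq_id`, `seq_len`,
#'   `window`, `positions` (1-based), and `values` (one row per position,
#'   columns named as in `FEATURE_NAMES`).
#' @export
featurize_track <- function(record, config = sensor_config(), tables) {
  stopifnot(inherits(record, "sequence_record"),
            inherits(config, "sensor_config"))
  seq <- record$seq
  n <- nchar(seq); W <- config$window; h <- W %/% 2L
  if (n < W) stop("sequence '", record$id, "' (", n,
                  " nt) is shorter than the window (", W, " nt)")
  ks <- config$kmer_ks
  tk <- vapply(tables, function(t) t$k, integer(1))
  if (!all(ks %in% tk))
    stop("missing k-mer table(s) for k = ",
         paste(setdiff(ks, tk), collapse = ", "))
  p <- (h + 1L):(n - h)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]

  cols <- list()

  # (1) period-3 DFT: per-base complex carrier, windowed complex sums
  if (W %% 3L == 0L) {
    wt <- exp(-2i * pi * ((0:(n - 1L)) %% 3L) / 3)
    dft <- numeric(length(p))
    for (b in c("A", "T", "G", "C")) {
      cs <- c(0 + 0i, cumsum((ch == b) * wt))
      dft <- dft + Mod(cs[p + h + 1L] - cs[p - h])
    }
    cols$dft <- dft
  } else {
    stop("DFT sensor requires window divisible by 3, got ", W)
  }

  # (2-6) k-mer coding potential
  d <- match(ch, c("A", "C", "G", "T")) - 1L        # N -> NA
  for (k in ks) {
    tab <- tables[[which(tk == k)[1]]]
    lr <- kmer_log_ratio(tab)
    nk <- n - k + 1L
    idx <- d[1:nk]
    for (i in 1:(k - 1L)) idx <- idx * 4L + d[(1L + i):(nk + i)]
    sc <- lr[idx + 1L]
    sc[is.na(sc)] <- 0                               # N-containing k-mers
    # window [p-h, p+h] holds k-mer starts p-h .. p+h-k+1 ("full" mode)
    last_off <- if (config$kmer_sum == "full") h - k + 1L else h - k - 1L
    cs <- c(0, cumsum(sc))
    cols[[paste0("kmer", k)]] <- cs[p + last_off + 1L] - cs[p - h]
  }

  # (7) GC content, N excluded from both counts
  ngc <- window_sums(ch == "G" | ch == "C", p, h)
  nacgt <- window_sums(ch != "N", p, h)
  cols$gc <- ifelse(nacgt > 0, ngc / nacgt, 0)

  # (8-15) motif distances
  fam_prefix <- c(start = "start", stop = "stop", acceptor = "acc",
                  donor = "don")
  for (fam in c("start", "stop", "acceptor", "donor")) {
    m <- nchar(MOTIF_STRINGS[[fam]][1])
    occ <- logical(n)
    occ[motif_positions(seq, fam)] <- TRUE
    idx <- seq_len(n)
    nxt <- rev(cummin(rev(ifelse(occ, idx, Inf))))   # nearest match at/after
    prv <- cummax(ifelse(occ, idx, -Inf))            # nearest match at/before
    Dr <- nxt[p] - p
    right <- ifelse(Dr <= h - m + 1L, W / 2 - Dr, 0) # containment in window
    Dl <- p - prv[p - 1L]
    left <- ifelse(Dl <= h, W / 2 - Dl, 0)
    cols[[paste0(fam_prefix[[fam]], "_right")]] <- right
    cols[[paste0(fam_prefix[[fam]], "_left")]] <- left
  }

  # (16) entropy
  ent <- numeric(length(p))
  if (config$entropy_variant == "as_printed") {
    for (b in c("A", "T", "G", "C")) {
      nb <- window_sums(ch == b, p, h)
      P <- nb / W
      term <- ifelse(nb > 0, nb * P * log(P), 0)
      ent <- ent - term / W
    }
  } else {
    for (b in c("A", "T", "G", "C")) {
      P <- window_sums(ch == b, p, h) / W
      ent <- ent - ifelse(P > 0, P * log(P), 0)
    }
  }
  cols$entropy <- ent

  wanted <- FEATURE_NAMES[FEATURE_NAMES %in% names(cols)]
  values <- do.call(cbind, cols[wanted])
  colnames(values) <- wanted
  if (any(!is.finite(values))) stop("non-finite sensor value produced")
  structure(list(seq_id = record$id, seq_len = n, window = W,
                 positions = p, values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d positions x %d sensors (W=%d)\n",
              x$seq_id, nrow(x$values), ncol(x$values), x$window))
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' Columns: `position` plus the named sensor columns.
#'
#' @param fm A [feature_matrix()] from [featurize_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(fm, path) {
  df <- data.frame(position = fm$positions, fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_tsv()]
#'
#' @param path TSV path.
#' @param seq_id,seq_len,window Metadata to restore (not stored in the TSV).
#' @return A `feature_matrix`.
#' @export
read_features_tsv <- function(path, seq_id, seq_len, window = 69L) {
  df <- utils::read.delim(path, check.names = FALSE)
  structure(list(seq_id = seq_id, seq_len = as.integer(seq_len),
                 window = as.integer(window),
                 positions = as.integer(df$position),
                 values = as.matrix(df[, setdiff(names(df), "position"),
                                       drop = FALSE])),
            class = "feature_matrix")
}
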