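# Coding/noncoding k-mer frequency weights p1(j|k), p0(j|k) backing the k-mer
# sensors. Weights are counts divided by the number of bases in the extracted
# corpus (not the number of k-mer windows), so they need not sum to 1.

#' All k-mers of a given length
#'
#' @param k k-mer length.
#' @return Character vector of the `4^k` k-mers over `{A,C,G,T}` in
#'   lexicographic order.
#' @export
all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- b
  if (k > 1L)
    for (i in 2:k) out <- as.vector(outer(out, b, paste0))
  sort(out)
}

#' Coding/noncoding k-mer frequency weight table
#'
#' @param k k-mer length in `{2,...,6}`.
#' @param p1,p0 Named numeric vectors over all `4^k` k-mers: frequency weights
#'   in coding (`p1`) and noncoding (`p0`) sequence. Must be strictly positive
#'   (apply a pseudocount before construction).
#' @param pseudocount The pseudocount that was applied (metadata).
#' @return An object of class `kmer_frequency_table`.
#' @export
kmer_frequency_table <- function(k, p1, p0, pseudocount = 1) {
  k <- as.integer(k)
  if (!(k %in% 2:6)) stop("k must be in {2,...,6}, got ", k)
  km <- all_kmers(k)
  if (!setequal(names(p1), km) || !setequal(names(p0), km))
    stop("p1/p0 must be named over all ", 4^k, " k-mers of length ", k)
  p1 <- p1[km]; p0 <- p0[km]
  if (any(p1 <= 0) || any(p0 <= 0) || any(!is.finite(p1)) || any(!is.finite(p0)))
    stop("all frequency weights must be strictly positive and finite")
  structure(list(k = k, p1 = p1, p0 = p0, pseudocount = pseudocount),
            class = "kmer_frequency_table")
}

#' @export
print.kmer_frequency_table <- function(x, ...) {
  lr <- kmer_log_ratio(x)
  cat(sprintf("<kmer_frequency_table> k=%d (%d k-mers), score range [%.3f, %.3f]\n",
              x$k, 4^x$k, min(lr), max(lr)))
  invisible(x)
}

#' Per-k-mer sensor score -ln(p1/p0)
#'
#' Negative for k-mers enriched in coding sequence.
#'
#' @param table A [kmer_frequency_table()].
#' @return Named numeric vector over all k-mers.
#' @export
kmer_log_ratio <- function(table) {
  -log(table$p1 / table$p0)
}

# count k-mers (stride 1) within each segment separately, never across
# boundaries; k-mers containing N are skipped. Returns named integer vector.
count_kmers <- function(segments, k) {
  km <- all_kmers(k)
  counts <- stats::setNames(integer(4^k), km)
  for (s in segments) {
    n <- nchar(s)
    if (n < k) next
    words <- substring(s, 1:(n - k + 1L), k:n)
    words <- words[!grepl("N", words, fixed = TRUE)]
    if (length(words) == 0L) next
    t <- table(words)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  counts
}

# pull contiguous coding / noncoding segments from records+annotations
class_segments <- function(records, annotations) {
  if (inherits(records, "sequence_record")) records <- list(records)
  if (inherits(annotations, "cds_annotation")) annotations <- list(annotations)
  stopifnot(length(records) == length(annotations))
  coding <- character(0); noncoding <- character(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]; ann <- annotations[[i]]
    if (rec$id != ann$seq_id)
      stop("record/annotation mismatch: '", rec$id, "' vs '", ann$seq_id, "'")
    iv <- ann$intervals
    n <- nchar(rec$seq)
    if (nrow(iv) > 0L) {
      coding <- c(coding, substring(rec$seq, iv$start, iv$end))
      gaps_s <- c(1L, iv$end + 1L)
      gaps_e <- c(iv$start - 1L, n)
      keep <- gaps_e >= gaps_s
      if (any(keep))
        noncoding <- c(noncoding,
                       substring(rec$seq, gaps_s[keep], gaps_e[keep]))
    } else {
      noncoding <- c(noncoding, rec$seq)
    }
  }
  list(coding = coding, noncoding = noncoding)
}

# take segments (in order, or shuffled under seed) until >= budget bases,
# truncating the last one
take_budget <- function(segments, budget, shuffle = FALSE, seed = 1L) {
  if (shuffle)
    segments <- withr::with_seed(seed, sample(segments))
  lens <- nchar(segments)
  tot <- cumsum(lens)
  last <- which(tot >= budget)[1]
  if (is.na(last)) return(segments)              # shortfall: take everything
  segments <- segments[1:last]
  excess <- tot[last] - budget
  if (excess > 0L)
    segments[last] <- substr(segments[last], 1L, lens[last] - excess)
  segments
}

#' Estimate k-mer frequency weight tables from labeled sequence
#'
#' Extracts up to `4^k * k * 1000` bases from the coding class (concatenated
#' CDS intervals) and the same from the noncoding complement, counts k-mers
#' with a stride-1 sliding window within each contiguous segment (never across
#' segment boundaries; k-mers containing N are skipped), and sets
#' `p(j|k) = (count(j) + pseudocount) / bases_extracted`. When a class holds
#' fewer bases than the target, all available bases are used and the shortfall
#' is reported via `message()`.
#'
#' @param records A [sequence_record()] or list thereof.
#' @param annotations Matching [cds_annotation()] (or list).
#' @param k k-mer length in `{2,...,6}`.
#' @param seed Seed used only when `sample_segments = TRUE`.
#' @param pseudocount Added to every k-mer count (default 1) so the sensor
#'   log-ratio stays finite for unobserved k-mers.
#' @param sample_segments If `TRUE`, segments are consumed in random order
#'   under `seed` instead of genomic order.
#' @return A [kmer_frequency_table()].
#' @export
estimate_kmer_tables <- function(records, annotations, k, seed = 1L,
                                 pseudocount = 1, sample_segments = FALSE) {
  k <- as.integer(k)
  if (!(k %in% 2:6)) stop("k must be in {2,...,6}, got ", k)
  segs <- class_segments(records, annotations)
  if (sum(nchar(segs$coding)) == 0L) stop("coding class is empty")
  if (sum(nchar(segs$noncoding)) == 0L) stop("noncoding class is empty")
  budget <- 4^k * k * 1000
  tabs <- lapply(c(coding = "coding", noncoding = "noncoding"), function(cl) {
    taken <- take_budget(segs[[cl]], budget, sample_segments, seed)
    nb <- sum(nchar(taken))
    if (nb < budget)
      message(sprintf("k=%d %s corpus shortfall: %d of %d target bases",
                      k, cl, nb, budget))
    (count_kmers(taken, k) + pseudocount) / nb
  })
  kmer_frequency_table(k, tabs$coding, tabs$noncoding, pseudocount)
}

#' Load a k-mer frequency table from CSV
#'
#' Expects one row per k-mer. Column names are configurable via `columns`
#' (defaults `kmer`, `coding_freq`, `noncoding_freq`). Missing k-mers are
#' filled with a pseudocount-only weight `pseudocount / (4^k * k * 1000)` and
#' reported with a warning.
#'
#' @param path CSV path.
#' @param k Expected k-mer length.
#' @param pseudocount Fill pseudocount for absent k-mers.
#' @param columns Named character vector mapping roles `kmer`, `coding`,
#'   `noncoding` to header names in the file.
#' @return A [kmer_frequency_table()].
#' @export
load_kmer_table_csv <- function(path, k,
                                pseudocount = 1,
                                columns = c(kmer = "kmer",
                                            coding = "coding_freq",
                                            noncoding = "noncoding_freq")) {
  k <- as.integer(k)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), names(df))
  if (length(miss) > 0L)
    stop("CSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  kmers <- toupper(df[[columns[["kmer"]]]])
  if (any(nchar(kmers) != k))
    stop("CSV contains k-mer(s) of length != ", k)
  if (any(grepl("[^ACGT]", kmers)))
    stop("CSV contains k-mer(s) with characters outside {A,C,G,T}")
  if (anyDuplicated(kmers)) stop("CSV contains duplicated k-mers")
  p1 <- df[[columns[["coding"]]]]; p0 <- df[[columns[["noncoding"]]]]
  if (!is.numeric(p1) || !is.numeric(p0) || anyNA(p1) || anyNA(p0))
    stop("non-numeric frequency value(s) in ", path)
  names(p1) <- kmers; names(p0) <- kmers
  km <- all_kmers(k)
  absent <- setdiff(km, kmers)
  if (length(absent) > 0L) {
    warning(length(absent), " of ", 4^k,
            " k-mers absent from ", path, "; filled with pseudocount weight")
    fill <- pseudocount / (4^k * k * 1000)
    p1[absent] <- fill; p0[absent] <- fill
  }
  kmer_frequency_table(k, p1[km], p0[km], pseudocount)
}

#' Write a k-mer frequency table as CSV
#'
#' @param table A [kmer_frequency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table_csv <- function(table, path) {
  utils::write.csv(data.frame(kmer = names(table$p1),
                              coding_freq = unname(table$p1),
                              noncoding_freq = unname(table$p0)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
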