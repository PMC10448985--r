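#' @keywords internal
"_PACKAGE"

# Internal coordinates are 1-based inclusive throughout (IRanges convention).
# GFF3 is 1-based inclusive, so the reader/writer converts nothing; the BED
# writer is the single point where 0-based half-open coordinates are produced.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' A named DNA sequence
#'
#' Container for one DNA sequence over the alphabet `{A,C,G,T,N}`. Sequences
#' are uppercased on construction and any character outside the alphabet is
#' replaced by `N`.
#'
#' @param id Sequence identifier (single non-empty string).
#' @param seq DNA string.
#' @return An object of class `sequence_record` with fields `id` and `seq`.
#' @export
sequence_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("sequence '", id, "' is empty")
  bad <- nchar(gsub("[ACGTN]", "", seq))
  if (bad > 0L) {
    seq <- gsub("[^ACGTN]", "N", seq)
    warning(sprintf("sequence '%s': %d non-ACGTN character(s) replaced by N",
                    id, bad))
  }
  structure(list(id = id, seq = seq), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d nt)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Reads a (multi-record) FASTA file via [Biostrings::readBStringSet()] and
#' normalizes each record: sequences are uppercased and characters outside
#' `{A,C,G,T,N}` are mapped to `N` with a warning giving the replacement count.
#'
#' @param path Path to a FASTA file.
#' @return A list of [sequence_record()] objects, one per FASTA entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  recs <- lapply(seq_along(set), function(i)
    sequence_record(ids[i], as.character(set[[i]])))
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records A list of [sequence_record()] objects.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "sequence_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    n <- nchar(r$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# merge sorted-or-not intervals (matrix/data.frame with start,end; 1-based
# inclusive) into a sorted, non-overlapping, non-adjacent union
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me + 1L) {            # overlapping or adjacent: fuse
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' CDS annotation for one sequence
#'
#' Holds the union of all CDS intervals on a sequence (merged across
#' transcripts, so alternatively spliced bases count as coding).
#'
#' @param seq_id Sequence identifier.
#' @param start,end Integer vectors of 1-based inclusive interval bounds.
#' @param seq_len Length of the sequence the intervals live on.
#' @return An object of class `cds_annotation` with a merged `intervals`
#'   data.frame (`start`, `end`).
#' @export
cds_annotation <- function(seq_id, start, end, seq_len) {
  stopifnot(length(start) == length(end))
  if (length(start) > 0L) {
    if (any(start < 1L) || any(end > seq_len) || any(end < start))
      stop("CDS interval outside [1, ", seq_len, "] on '", seq_id, "'")
  }
  structure(list(seq_id = seq_id,
                 intervals = merge_intervals(start, end),
                 seq_len = as.integer(seq_len)),
            class = "cds_annotation")
}

#' @export
print.cds_annotation <- function(x, ...) {
  cat(sprintf("<cds_annotation> %s: %d merged CDS interval(s), %d coding nt\n",
              x$seq_id, nrow(x$intervals),
              sum(x$intervals$end - x$intervals$start + 1L)))
  invisible(x)
}

#' Read CDS features from a GFF3 file
#'
#' Collects all features of type `CDS` on `seq_id` and unions them across
#' transcripts. GFF3 coordinates are 1-based inclusive, matching the internal
#' convention, so no conversion is applied.
#'
#' @param path Path to a GFF3 file.
#' @param seq_id Sequence identifier (column 1) to collect features for.
#' @param seq_len Length of that sequence, for bounds checking.
#' @return A [cds_annotation()].
#' @export
read_gff_cds <- function(path, seq_id, seq_len) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  starts <- integer(0); ends <- integer(0)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed GFF line ", i, " in ", path,
           " (", length(f), " field(s), expected >= 8)")
    if (f[1] != seq_id || f[3] != "CDS") next
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("malformed GFF line ", i, " in ", path, " (non-integer coordinates)")
    if (s < 1L || e > seq_len || e < s)
      stop("CDS interval [", s, ",", e, "] on line ", i,
           " exceeds sequence length ", seq_len)
    starts <- c(starts, s); ends <- c(ends, e)
  }
  cds_annotation(seq_id, starts, ends, seq_len)
}

#' Write a CDS annotation as GFF3
#'
#' @param annotation A [cds_annotation()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff_cds <- function(annotation, path, source = "genesensor") {
  iv <- annotation$intervals
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", annotation$seq_id,
                     annotation$seq_len))
  if (nrow(iv) > 0L)
    lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t+\t.\tID=cds%d",
                              annotation$seq_id, source, iv$start, iv$end,
                              seq_len(nrow(iv))))
  writeLines(lines, path)
  invisible(path)
}

#' Per-nucleotide 0/1 label track
#'
#' A label (truth, initial, or adjusted prediction) per nucleotide plus the
#' valid coordinate range: `floor(window/2)` nucleotides at each sequence end
#' are sequestered because a full centered sensor window does not fit there,
#' and all metrics ignore them.
#'
#' @param seq_id Sequence identifier.
#' @param labels Integer vector of 0/1, one per nucleotide.
#' @param window Odd sensor window width W (default 69, sequestering 34 nt).
#' @return An object of class `prediction_track` with fields `seq_id`,
#'   `labels`, `valid_start`, `valid_end` (both 1-based inclusive).
#' @export
prediction_track <- function(seq_id, labels, window = 69L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3, got ", window)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  h <- window %/% 2L
  n <- length(labels)
  vs <- h + 1L; ve <- n - h
  if (ve < vs)
    stop("sequence of length ", n, " has no valid positions for window ", window)
  structure(list(seq_id = seq_id, labels = labels,
                 valid_start = vs, valid_end = ve, window = window),
            class = "prediction_track")
}

#' @export
print.prediction_track <- function(x, ...) {
  v <- x$labels[x$valid_start:x$valid_end]
  cat(sprintf("<prediction_track> %s: %d nt, valid [%d,%d], coding fraction %.4f\n",
              x$seq_id, length(x$labels), x$valid_start, x$valid_end, mean(v)))
  invisible(x)
}

#' Build the per-nucleotide truth track from an annotation
#'
#' `labels[i]` is 1 iff position `i` lies inside a CDS interval. The valid
#' range excludes `floor(window/2)` nucleotides at each end.
#'
#' @param record A [sequence_record()].
#' @param annotation A [cds_annotation()] for the same sequence.
#' @param window Sensor window width (odd).
#' @return A [prediction_track()].
#' @export
label_nucleotides <- function(record, annotation, window = 69L) {
  stopifnot(inherits(record, "sequence_record"),
            inherits(annotation, "cds_annotation"))
  if (record$id != annotation$seq_id)
    stop("annotation seq_id '", annotation$seq_id,
         "' does not match record id '", record$id, "'")
  n <- nchar(record$seq)
  labels <- integer(n)
  iv <- annotation$intervals
  if (nrow(iv) > 0L)
    for (i in seq_len(nrow(iv))) labels[iv$start[i]:iv$end[i]] <- 1L
  prediction_track(record$id, labels, window)
}

#' Write a label track as two-column TSV
#'
#' Columns `position` (1-based) and `label`, valid range only.
#'
#' @param track A [prediction_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  pos <- track$valid_start:track$valid_end
  utils::write.table(data.frame(position = pos, label = track$labels[pos]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}
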