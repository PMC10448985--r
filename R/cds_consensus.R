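# Motif-bounded CDS consensus post-processing. A potential CDS is any region
# bounded on the left by an ATG start codon or a YAG acceptor splice site and
# on the right by a GT donor site or a stop codon (TAG/TAA/TGA), with interior
# length strictly between Lmin and Lmax. Each candidate is scored by the ratio
# N1/N0 of initial coding to noncoding calls inside it; candidates above a
# threshold are accepted in length-descending order, candidates contained in
# an accepted region are dropped, and the adjusted track is 1 exactly on the
# union of accepted interiors.
#
# Interior conventions (1-based inclusive):
#   left  ATG  -> interior starts at the A of ATG (start codon inside the CDS)
#   left  YAG  -> interior starts just after the G (splice site outside)
#   right GT   -> interior ends just before the G (splice site outside)
#   right stop -> interior ends at the last base of the stop codon

CDS_TYPES <- c("single", "start", "internal", "end")

#' Consensus post-processing configuration
#'
#' @param lmin,lmax Interior length bounds; only candidates with
#'   `lmin < L < lmax` are considered (defaults 40 and 400, excluding very
#'   few real exons).
#' @param threshold N1/N0 acceptance threshold (strictly above passes).
#' @param threshold_grid Increasing grid for sweeps; the default covers the
#'   published working range 0.5-30.
#' @param target_coding_fraction Expected genomic coding fraction used by the
#'   fraction-targeted sweep.
#' @param fraction_margin Sweep tolerance: stop at the first threshold whose
#'   predicted coding fraction is at most `target + margin` (rule of thumb:
#'   predicted fraction about 0.1 above the empirical coding content).
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(lmin = 40L, lmax = 400L, threshold = 1,
                             threshold_grid = c(seq(0.5, 1, by = 0.1),
                                                1.5, 2:30),
                             target_coding_fraction = 0.1,
                             fraction_margin = 0.1) {
  lmin <- as.integer(lmin); lmax <- as.integer(lmax)
  if (lmin >= lmax) stop("lmin must be < lmax")
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.unsorted(threshold_grid, strictly = TRUE))
    stop("threshold_grid must be strictly increasing")
  if (target_coding_fraction <= 0 || target_coding_fraction >= 1)
    stop("target_coding_fraction must be in (0,1)")
  structure(list(lmin = lmin, lmax = lmax, threshold = threshold,
                 threshold_grid = threshold_grid,
                 target_coding_fraction = target_coding_fraction,
                 fraction_margin = fraction_margin),
            class = "consensus_config")
}

#' Positions of CDS boundary motifs
#'
#' First-base positions (1-based) of every ATG, stop codon (TAG/TAA/TGA),
#' YAG acceptor (Y in `{C,T}`) and GT donor occurrence; motifs containing N
#' never match.
#'
#' @param seq DNA string.
#' @return List with sorted integer vectors `start`, `stop`, `acceptor`,
#'   `donor`.
#' @export
scan_motifs <- function(seq) {
  lapply(stats::setNames(nm = names(MOTIF_STRINGS)),
         function(f) motif_positions(seq, f))
}

#' Enumerate potential CDS regions
#'
#' Builds every candidate from the four boundary-type combinations
#' (single = ATG..stop, start = ATG..GT, internal = YAG..GT, end = YAG..stop)
#' whose interior length satisfies `lmin < L < lmax`, sorted by length
#' descending with ties by start ascending.
#'
#' @param seq DNA string.
#' @param config A [consensus_config()].
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   interior), `length`, `cds_type`, `left_motif`, `right_motif` (first-base
#'   positions of the bounding motifs).
#' @export
enumerate_potential_cds <- function(seq, config = consensus_config()) {
  mo <- scan_motifs(seq)
  # interior start / end coordinate per boundary motif occurrence
  lefts <- list(start = list(pos = mo$start, interior = mo$start),
                acceptor = list(pos = mo$acceptor, interior = mo$acceptor + 3L))
  rights <- list(donor = list(pos = mo$donor, interior = mo$donor - 1L),
                 stop = list(pos = mo$stop, interior = mo$stop + 2L))
  type_of <- function(lf, rf)
    switch(paste(lf, rf), "start donor" = "start", "start stop" = "single",
           "acceptor donor" = "internal", "acceptor stop" = "end")
  out <- list()
  for (lf in names(lefts)) for (rf in names(rights)) {
    ls <- lefts[[lf]]; rs <- rights[[rf]]
    if (length(ls$pos) == 0L || length(rs$pos) == 0L) next
    re <- rs$interior; o <- order(re); re <- re[o]; rpos <- rs$pos[o]
    # interior [s, e], L = e - s + 1 in (lmin, lmax) strictly:
    # s + lmin <= e <= s + lmax - 2
    lo <- findInterval(ls$interior + config$lmin - 1L, re) + 1L
    hi <- findInterval(ls$interior + config$lmax - 2L, re)
    keep <- hi >= lo
    if (!any(keep)) next
    li <- which(keep)
    counts <- hi[li] - lo[li] + 1L
    i_left <- rep(li, counts)
    i_right <- unlist(lapply(li, function(i) lo[i]:hi[i]), use.names = FALSE)
    out[[paste(lf, rf)]] <- data.frame(
      start = ls$interior[i_left], end = re[i_right],
      cds_type = type_of(lf, rf),
      left_motif = ls$pos[i_left], right_motif = rpos[i_right])
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), cds_type = character(0),
                      left_motif = integer(0), right_motif = integer(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df$length <- df$end - df$start + 1L
  # degenerate interiors (end < start) cannot arise because lmin >= 1
  df <- df[order(-df$length, df$start,
                 match(df$cds_type, CDS_TYPES)), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("start", "end", "length", "cds_type", "left_motif", "right_motif")]
}

#' Score candidates by initial predictions
#'
#' Adds `n1` (initial coding calls inside the interior), `n0` (noncoding
#' calls) and `ratio = n1/n0` (`Inf` when `n0 = 0`, 0 when `n1 = 0`).
#' Interiors are scored on their overlap with the track's valid range.
#'
#' @param regions data.frame from [enumerate_potential_cds()].
#' @param initial A [prediction_track()] of initial predictions.
#' @return `regions` with `n1`, `n0`, `ratio` columns.
#' @export
score_regions <- function(regions, initial) {
  if (nrow(regions) == 0L) {
    regions$n1 <- integer(0); regions$n0 <- integer(0)
    regions$ratio <- numeric(0)
    return(regions)
  }
  cs <- c(0L, cumsum(initial$labels))
  s <- pmax(regions$start, initial$valid_start)
  e <- pmin(regions$end, initial$valid_end)
  len <- pmax(e - s + 1L, 0L)
  n1 <- ifelse(len > 0L, cs[pmax(e, 1L) + 1L] - cs[pmax(s, 1L)], 0L)
  regions$n1 <- as.integer(n1)
  regions$n0 <- as.integer(len - n1)
  regions$ratio <- ifelse(regions$n0 == 0L,
                          ifelse(regions$n1 > 0L, Inf, 0),
                          regions$n1 / regions$n0)
  regions
}

# accepted set = candidates above threshold that are maximal under interval
# containment (equivalent to the literal length-descending test with
# containment precedence; containment is transitive, so a candidate inside a
# rejected region is also inside the accepting region that rejected it)
accept_regions <- function(scored, threshold) {
  pass <- scored[scored$ratio > threshold, , drop = FALSE]
  if (nrow(pass) == 0L) return(pass)
  # order by start asc, end desc, original (length-desc) rank; an entry is
  # contained in an earlier one iff the running max of `end` reaches its end
  o <- order(pass$start, -pass$end, seq_len(nrow(pass)))
  pass <- pass[o, , drop = FALSE]
  prior_max_end <- c(-Inf, cummax(pass$end)[-nrow(pass)])
  kept <- pass[prior_max_end < pass$end, , drop = FALSE]
  kept <- kept[order(-kept$length, kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Adjust initial predictions into motif-consistent CDS calls
#'
#' Candidates are tested in length-descending order; a candidate is accepted
#' iff its N1/N0 ratio is strictly above the threshold and it is not contained
#' in an already-accepted region (contained candidates are skipped outright).
#' The adjusted labels are 1 exactly on the union of accepted interiors;
#' initial coding calls outside every accepted region become noncoding.
#'
#' @param seq DNA string (used to enumerate candidates; pass `regions` to
#'   reuse a previous enumeration).
#' @param initial A [prediction_track()] of initial predictions.
#' @param config A [consensus_config()].
#' @param threshold Override of `config$threshold`.
#' @param regions Optional precomputed (unscored) candidate data.frame.
#' @return List with `adjusted` (a [prediction_track()]) and `accepted`
#'   (scored data.frame of accepted regions, length-descending).
#' @export
adjust_predictions <- function(seq, initial, config = consensus_config(),
                               threshold = config$threshold, regions = NULL) {
  if (is.null(regions)) regions <- enumerate_potential_cds(seq, config)
  scored <- score_regions(regions, initial)
  accepted <- accept_regions(scored, threshold)
  labels <- integer(length(initial$labels))
  if (nrow(accepted) > 0L)
    for (i in seq_len(nrow(accepted)))
      labels[accepted$start[i]:accepted$end[i]] <- 1L
  adjusted <- prediction_track(initial$seq_id, labels, initial$window)
  list(adjusted = adjusted, accepted = accepted)
}

#' Coding fraction of a track
#'
#' Fraction of valid positions labeled 1.
#'
#' @param track A [prediction_track()].
#' @return Real in `[0,1]`.
#' @export
coding_fraction <- function(track) {
  v <- track$valid_start:track$valid_end
  if (length(v) == 0L) stop("track has an empty valid range")
  mean(track$labels[v])
}

#' Fraction-targeted threshold sweep
#'
#' Walks the threshold grid from low to high, re-adjusting predictions at
#' each step, and stops at the first threshold whose adjusted coding fraction
#' is at most `target + margin` (predicted coding content should sit slightly
#' above the empirical value). If no threshold qualifies the grid maximum is
#' returned with a warning.
#'
#' @param seq DNA string.
#' @param initial A [prediction_track()] of initial predictions.
#' @param config A [consensus_config()] (grid, target, margin).
#' @return List with `threshold` (chosen), `adjusted` (track at that
#'   threshold), `accepted`, `trajectory` (data.frame threshold/fraction for
#'   every evaluated grid point up to the stop), and `exhausted` flag.
#' @export
fraction_targeted_sweep <- function(seq, initial, config = consensus_config()) {
  grid <- config$threshold_grid
  if (length(grid) == 0L) stop("threshold_grid is empty")
  limit <- config$target_coding_fraction + config$fraction_margin
  regions <- enumerate_potential_cds(seq, config)
  thresholds <- numeric(0); fractions <- numeric(0)
  chosen <- NULL
  for (th in grid) {
    res <- adjust_predictions(seq, initial, config, threshold = th,
                              regions = regions)
    f <- coding_fraction(res$adjusted)
    thresholds <- c(thresholds, th); fractions <- c(fractions, f)
    if (f <= limit) { chosen <- list(th = th, res = res); break }
  }
  exhausted <- is.null(chosen)
  if (exhausted) {
    warning(sprintf(
      "sweep exhausted: no threshold reached fraction <= %.3f; using grid max %g",
      limit, grid[length(grid)]))
    chosen <- list(th = grid[length(grid)], res = res)
  }
  list(threshold = chosen$th, adjusted = chosen$res$adjusted,
       accepted = chosen$res$accepted,
       trajectory = data.frame(threshold = thresholds, fraction = fractions),
       exhausted = exhausted)
}

#' Write accepted CDS regions as BED6
#'
#' BED is 0-based half-open: `start - 1` / `end`. Name is the CDS type,
#' score is `min(1000, round(100 * ratio))`.
#'
#' @param accepted Scored accepted data.frame from [adjust_predictions()].
#' @param seq_id Chromosome/sequence name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_bed <- function(accepted, seq_id, path) {
  if (nrow(accepted) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(1000, round(100 * ifelse(is.finite(accepted$ratio),
                                         accepted$ratio, 1e9)))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t+", seq_id,
                     accepted$start - 1L, accepted$end,
                     accepted$cds_type, as.integer(score)),
             path)
  invisible(path)
}
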