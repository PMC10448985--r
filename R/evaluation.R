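# Nucleotide-level accuracy measures: Sn = TP/(TP+FN), Sp = TN/(TN+FP),
# BA = (Sn+Sp)/2, PPV = TP/(TP+FP), MSP = (Sn+PPV)/2, F1 = 2TP/(2TP+FP+FN).
# Positions outside the valid (non-sequestered) range are never counted.

#' Confusion counts between two label tracks
#'
#' Counted over the intersection of the two valid ranges only.
#'
#' @param pred,truth [prediction_track()]s for the same sequence.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred$labels) != length(truth$labels))
    stop("tracks have different lengths (", length(pred$labels), " vs ",
         length(truth$labels), ")")
  vs <- max(pred$valid_start, truth$valid_start)
  ve <- min(pred$valid_end, truth$valid_end)
  if (ve < vs) stop("valid ranges do not intersect")
  p <- pred$labels[vs:ve]; t <- truth$labels[vs:ve]
  structure(list(tp = sum(p == 1L & t == 1L), fp = sum(p == 1L & t == 0L),
                 tn = sum(p == 0L & t == 0L), fn = sum(p == 0L & t == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, degenerate = TRUE)
  else list(value = num / den, degenerate = FALSE)
}

#' Accuracy measures from confusion counts
#'
#' Ratios with a zero denominator are reported as 0 and flagged in
#' `degenerate` (so batch summaries never propagate NaN).
#'
#' @param counts A [confusion()] result.
#' @return An object of class `metrics_report`: `sn`, `sp`, `ba`, `ppv`,
#'   `msp`, `f1`, the `counts`, and a named logical `degenerate` vector.
#' @export
cds_metrics <- function(counts) {
  sn <- safe_ratio(counts$tp, counts$tp + counts$fn)
  sp <- safe_ratio(counts$tn, counts$tn + counts$fp)
  ppv <- safe_ratio(counts$tp, counts$tp + counts$fp)
  f1 <- safe_ratio(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  structure(list(sn = sn$value, sp = sp$value,
                 ba = (sn$value + sp$value) / 2,
                 ppv = ppv$value, msp = (sn$value + ppv$value) / 2,
                 f1 = f1$value, counts = counts,
                 degenerate = c(sn = sn$degenerate, sp = sp$degenerate,
                                ppv = ppv$degenerate, f1 = f1$degenerate)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> Sn=%.4f Sp=%.4f BA=%.4f PPV=%.4f MSP=%.4f F1=%.4f%s\n",
    x$sn, x$sp, x$ba, x$ppv, x$msp, x$f1,
    if (any(x$degenerate)) paste0("  [degenerate: ",
      paste(names(x$degenerate)[x$degenerate], collapse = ","), "]") else ""))
  invisible(x)
}

#' Per-sequence threshold optimization
#'
#' Evaluates the consensus adjustment at every grid threshold against the
#' truth track and returns the threshold maximizing MSP or F1, or minimizing
#' `|Sn - Sp|` (`"sn_eq_sp"`). Ties go to the smallest threshold.
#'
#' @param seq DNA string.
#' @param initial Initial [prediction_track()].
#' @param truth Truth [prediction_track()].
#' @param grid Numeric threshold grid.
#' @param objective `"msp"`, `"f1"`, or `"sn_eq_sp"`.
#' @param config A [consensus_config()] supplying `lmin`/`lmax`.
#' @return List with `threshold`, `metrics` (a `metrics_report` at that
#'   threshold) and `trajectory` (data.frame of threshold and objective).
#' @export
best_threshold <- function(seq, initial, truth,
                           grid = consensus_config()$threshold_grid,
                           objective = c("msp", "f1", "sn_eq_sp"),
                           config = consensus_config()) {
  objective <- match.arg(objective)
  if (length(grid) == 0L) stop("threshold grid is empty")
  regions <- enumerate_potential_cds(seq, config)
  reports <- lapply(grid, function(th) {
    adj <- adjust_predictions(seq, initial, config, threshold = th,
                              regions = regions)$adjusted
    cds_metrics(confusion(adj, truth))
  })
  score <- vapply(reports, function(r)
    switch(objective, msp = r$msp, f1 = r$f1, sn_eq_sp = -abs(r$sn - r$sp)),
    numeric(1))
  best <- which.max(score)          # which.max takes the first (smallest) tie
  list(threshold = grid[best], metrics = reports[[best]],
       trajectory = data.frame(threshold = grid, objective = score))
}

#' Write an evaluation report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(counts = report$counts[c("tp", "fp", "tn", "fn")],
         sn = report$sn, sp = report$sp, ba = report$ba, ppv = report$ppv,
         msp = report$msp, f1 = report$f1,
         degenerate = as.list(report$degenerate)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
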