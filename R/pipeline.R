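# One entry point wiring the stages: simulate -> estimate-tables -> featurize
# -> train -> predict -> sweep -> evaluate. A run is reproducible from its
# config; every artifact name is stamped with the config hash and the log
# records seeds, corpus shortfalls and warnings.

#' Assemble a pipeline run configuration
#'
#' @param stages Character vector of stages to execute, in order, from
#'   `simulate`, `estimate_tables`, `featurize`, `train`, `predict`, `sweep`,
#'   `evaluate`.
#' @param out_dir Output directory (created if needed).
#' @param fasta,gff Input paths (ignored when `simulate` is among the
#'   stages, which generates them).
#' @param seed Global seed.
#' @param n_samples Balanced training-set size Ns (split evenly between the
#'   classes).
#' @param sim Optional [genome_sim_config()].
#' @param sensors Optional [sensor_config()].
#' @param model Optional [model_spec()].
#' @param consensus Optional [consensus_config()].
#' @param threshold Fixed consensus threshold for `predict` (defaults to the
#'   consensus config's); the `sweep` stage tunes it instead.
#' @param scan_reverse Also scan the reverse complement and union the
#'   predicted regions (off by default; the forward strand alone matches the
#'   published procedure).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "estimate_tables", "featurize",
                                  "train", "predict", "evaluate"),
                       out_dir = tempfile("genesensor_run_"),
                       fasta = NULL, gff = NULL, seed = 1L,
                       n_samples = 20000L,
                       sim = NULL, sensors = NULL, model = NULL,
                       consensus = NULL, threshold = NULL,
                       scan_reverse = FALSE) {
  known <- c("simulate", "estimate_tables", "featurize", "train", "predict",
             "sweep", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, out_dir = out_dir, fasta = fasta, gff = gff,
                 seed = as.integer(seed), n_samples = as.integer(n_samples),
                 sim = if (is.null(sim)) genome_sim_config(seed = seed) else sim,
                 sensors = if (is.null(sensors)) sensor_config() else sensors,
                 model = if (is.null(model)) model_spec() else model,
                 consensus = if (is.null(consensus)) consensus_config()
                             else consensus,
                 threshold = threshold, scan_reverse = isTRUE(scan_reverse)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 8L)
}

#' Run the prediction pipeline
#'
#' Executes the configured stages in order, writing artifacts (FASTA/GFF3,
#' k-mer CSVs, feature TSV, model archive, BED/track, sweep CSV, report JSON)
#' into `config$out_dir`. A stage failure aborts with an error naming the
#' stage.
#'
#' @param config A [run_config()].
#' @return Invisible list of produced artifact paths plus in-memory results
#'   (`tables`, `ensemble`, `initial`, `adjusted`, `metrics` as applicable).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  art <- function(name) file.path(config$out_dir, paste0(hash, ".", name))
  logf <- art("log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  log_line("run %s  seed=%d  stages=%s", hash, config$seed,
           paste(config$stages, collapse = ","))
  state <- list(paths = list(log = logf))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  for (stage in config$stages) {
    state <- switch(stage,
      simulate = run_stage("simulate", {
        sim <- simulate_genome(config$sim)
        paths <- write_genome(sim, art("genome"))
        log_line("simulate: %d nt, %d exon(s), coding fraction %.4f",
                 nchar(sim$record$seq), nrow(sim$genes),
                 sum(sim$genes$end - sim$genes$start + 1) /
                   nchar(sim$record$seq))
        state$record <- sim$record; state$annotation <- sim$annotation
        state$paths <- c(state$paths, as.list(paths))
        state
      }),
      estimate_tables = run_stage("estimate_tables", {
        st <- load_inputs(state, config)
        st$tables <- lapply(st$config_ks(), function(k) {
          tab <- estimate_kmer_tables(st$record, st$annotation, k,
                                      seed = config$seed)
          p <- art(sprintf("kmer%d.csv", k))
          write_kmer_table_csv(tab, p)
          tab
        })
        log_line("estimate_tables: k = %s",
                 paste(st$config_ks(), collapse = ","))
        st
      }),
      featurize = run_stage("featurize", {
        st <- load_inputs(state, config)
        if (is.null(st$tables)) stop("no k-mer tables (run estimate_tables)")
        st$features <- featurize_track(st$record, config$sensors, st$tables)
        p <- art("features.tsv")
        write_features_tsv(st$features, p)
        st$paths$features <- p
        log_line("featurize: %d positions x %d sensors",
                 nrow(st$features$values), ncol(st$features$values))
        st
      }),
      train = run_stage("train", {
        st <- state
        if (is.null(st$features)) stop("no features (run featurize)")
        truth <- label_nucleotides(st$record, st$annotation,
                                   config$sensors$window)
        ns <- config$n_samples
        pos <- sample_balanced(truth, ns %/% 2L, ns - ns %/% 2L,
                               seed = config$seed)
        ri <- match(pos, st$features$positions)
        st$ensemble <- train_ensemble(st$features$values[ri, , drop = FALSE],
                                      truth$labels[pos], config$model,
                                      seed = config$seed)
        p <- art("model.rds")
        save_ensemble(st$ensemble, p)
        st$paths$model <- p
        va <- vapply(st$ensemble$models, `[[`, numeric(1), "val_accuracy")
        log_line("train: Ns=%d, fold val acc %.4f +/- %.4f", ns, mean(va),
                 stats::sd(va))
        st
      }),
      predict = run_stage("predict", {
        st <- state
        if (is.null(st$ensemble)) stop("no model (run train or load one)")
        if (is.null(st$features)) stop("no features (run featurize)")
        st$initial <- predict_initial(st$ensemble, st$features, "majority")
        th <- if (is.null(config$threshold)) config$consensus$threshold
              else config$threshold
        res <- adjust_predictions(st$record$seq, st$initial, config$consensus,
                                  threshold = th)
        st$adjusted <- res$adjusted; st$accepted <- res$accepted
        st$paths$bed <- art("predicted.bed")
        write_cds_bed(res$accepted, st$record$id, st$paths$bed)
        st$paths$track <- art("adjusted.tsv")
        write_track_tsv(res$adjusted, st$paths$track)
        log_line("predict: threshold %g, %d region(s), coding fraction %.4f",
                 th, nrow(res$accepted), coding_fraction(res$adjusted))
        st
      }),
      sweep = run_stage("sweep", {
        st <- state
        if (is.null(st$initial)) stop("no initial predictions (run predict)")
        sw <- fraction_targeted_sweep(st$record$seq, st$initial,
                                      config$consensus)
        st$adjusted <- sw$adjusted; st$accepted <- sw$accepted
        st$paths$sweep <- art("sweep.csv")
        utils::write.csv(sw$trajectory, st$paths$sweep, row.names = FALSE)
        st$paths$bed <- art("predicted.bed")
        write_cds_bed(sw$accepted, st$record$id, st$paths$bed)
        log_line("sweep: chose threshold %g%s", sw$threshold,
                 if (sw$exhausted) " (grid exhausted)" else "")
        st
      }),
      evaluate = run_stage("evaluate", {
        st <- state
        if (is.null(st$adjusted)) stop("nothing to evaluate (run predict)")
        truth <- label_nucleotides(st$record, st$annotation,
                                   config$sensors$window)
        st$metrics <- cds_metrics(confusion(st$adjusted, truth))
        st$paths$report <- art("report.json")
        write_metrics_json(st$metrics, st$paths$report)
        log_line("evaluate: Sn=%.4f Sp=%.4f BA=%.4f", st$metrics$sn,
                 st$metrics$sp, st$metrics$ba)
        st
      }),
      stop("unknown stage: ", stage))
  }
  invisible(state)
}

# resolve record/annotation either from a previous simulate stage or from the
# configured FASTA/GFF3 paths; attaches a config_ks() accessor
load_inputs <- function(state, config) {
  if (is.null(state$record)) {
    if (is.null(config$fasta)) stop("no input: set fasta= or run simulate")
    recs <- read_fasta(config$fasta)
    state$record <- recs[[1]]
    state$annotation <- if (!is.null(config$gff))
      read_gff_cds(config$gff, state$record$id, nchar(state$record$seq))
    else cds_annotation(state$record$id, integer(0), integer(0),
                        nchar(state$record$seq))
  }
  state$config_ks <- function() config$sensors$kmer_ks
  state
}
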