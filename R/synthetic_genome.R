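# Synthetic genome simulator: plants non-overlapping multi-exon genes whose
# exon interiors obey the boundary-motif grammar used by the consensus module
# (first exon starts with ATG, last ends with a stop codon, introns run
# GT ... YAG), over an order-0 noncoding background. Coding sequence is drawn
# codon-by-codon from a multinomial over the 61 sense codons interpolated
# between uniform and a skewed usage table, so one knob (codon_bias_strength)
# controls the compositional contrast the sensors can detect.

SENSE_CODONS <- setdiff(all_kmers(3), c("TAA", "TAG", "TGA"))

# fixed skewed codon usage: product of positional base preferences
# (G/A-rich first position, A/T-rich second, C/G-rich wobble), renormalized
# over sense codons. Sharpness is set so the full-bias model has an effective
# number of codons (inverse Simpson) of ~30, typical of strongly
# codon-biased, highly expressed genes; bias interpolates toward uniform.
skewed_codon_probs <- function() {
  p1 <- c(A = 0.30, C = 0.15, G = 0.45, T = 0.10)
  p2 <- c(A = 0.40, C = 0.20, G = 0.10, T = 0.30)
  p3 <- c(A = 0.10, C = 0.40, G = 0.35, T = 0.15)
  w <- vapply(SENSE_CODONS, function(cdn) {
    b <- strsplit(cdn, "")[[1]]
    p1[b[1]] * p2[b[2]] * p3[b[3]]
  }, numeric(1))
  w / sum(w)
}

codon_probs <- function(bias) {
  u <- rep(1 / length(SENSE_CODONS), length(SENSE_CODONS))
  p <- (1 - bias) * u + bias * skewed_codon_probs()
  stats::setNames(p, SENSE_CODONS)
}

codon_gc <- function(probs) {
  gc <- vapply(names(probs), function(cdn)
    sum(strsplit(cdn, "")[[1]] %in% c("G", "C")), numeric(1))
  sum(probs * gc) / 3
}

#' Genome simulation configuration
#'
#' Defaults state a realistic eukaryotic test world: exon interiors mostly
#' 40-400 nt, 1-6 exons per gene, short introns, a 20% coding target, and a
#' noncoding GC matched to the coding model (so composition bias is the only
#' knob separating the classes).
#'
#' @param length Genome length in nt.
#' @param target_coding_fraction Desired fraction of coding nt; the realized
#'   fraction must land within 0.05 of it or generation errors out.
#' @param exon_len_range Interior length range of planted exons.
#' @param exons_per_gene Range for the uniform exon-count draw.
#' @param intron_len_range Intron length range (must be >= 7 to host
#'   `GT ... YAG`).
#' @param codon_bias_strength In `[0,1]`: 0 makes coding composition
#'   (uniform sense codons) essentially indistinguishable from noncoding;
#'   1 applies the full skewed codon-usage table.
#' @param gc_coding Optional target GC of coding sequence, achieved by
#'   exponential tilting of the codon distribution; `NULL` leaves the codon
#'   model's natural GC.
#' @param gc_noncoding GC of the noncoding background. The default 0.45
#'   leaves noncoding DNA modestly AT-richer than the coding model
#'   (~0.55 under the skewed codon table), the usual exon/intergenic
#'   contrast; `NULL` matches the coding model's GC exactly, removing GC as
#'   a discriminating signal.
#' @param min_intergenic Minimum gap between genes.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `genome_sim_config`.
#' @export
genome_sim_config <- function(length = 100000L,
                              target_coding_fraction = 0.2,
                              exon_len_range = c(40L, 400L),
                              exons_per_gene = c(1L, 6L),
                              intron_len_range = c(60L, 200L),
                              codon_bias_strength = 0.8,
                              gc_coding = NULL, gc_noncoding = 0.45,
                              min_intergenic = 200L,
                              seed = 1L) {
  stopifnot(length >= 1000L,
            target_coding_fraction > 0, target_coding_fraction < 1,
            exon_len_range[1] >= 9L, exon_len_range[1] < exon_len_range[2],
            exons_per_gene[1] >= 1L, exons_per_gene[1] <= exons_per_gene[2],
            intron_len_range[1] >= 7L,
            intron_len_range[1] <= intron_len_range[2],
            codon_bias_strength >= 0, codon_bias_strength <= 1,
            min_intergenic >= 1L)
  probs <- codon_probs(codon_bias_strength)
  if (!is.null(gc_coding)) {
    gcn <- vapply(names(probs), function(cdn)
      sum(strsplit(cdn, "")[[1]] %in% c("G", "C")), numeric(1))
    f <- function(lw) codon_gc(local({p <- probs * exp(lw * gcn); p / sum(p)})) -
      gc_coding
    lw <- stats::uniroot(f, c(-5, 5))$root
    probs <- probs * exp(lw * gcn); probs <- probs / sum(probs)
  }
  gc_cod <- codon_gc(probs)
  if (is.null(gc_noncoding)) gc_noncoding <- gc_cod
  structure(list(length = as.integer(length),
                 target_coding_fraction = target_coding_fraction,
                 exon_len_range = as.integer(exon_len_range),
                 exons_per_gene = as.integer(exons_per_gene),
                 intron_len_range = as.integer(intron_len_range),
                 codon_bias_strength = codon_bias_strength,
                 codon_probs = probs, gc_coding = gc_cod,
                 gc_noncoding = gc_noncoding,
                 min_intergenic = as.integer(min_intergenic),
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

# iid background at the configured GC
rand_noncoding <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_codons <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# draw one gene: exon interior lengths, intron lengths, and its sequence.
# The spliced CDS is ATG + sense codons + stop (no premature in-frame stop by
# construction), cut into exons at arbitrary phases.
draw_gene <- function(cfg) {
  n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
  lens <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], n_ex,
                 replace = TRUE)
  total <- sum(lens)
  # total CDS length must be a codon multiple >= ATG + 1 codon + stop
  adj <- total %% 3L
  lens[n_ex] <- lens[n_ex] - adj
  if (lens[n_ex] < cfg$exon_len_range[1]) lens[n_ex] <- lens[n_ex] + 3L
  total <- sum(lens)
  stopifnot(total %% 3L == 0L, total >= 9L)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  cds <- paste0("ATG", rand_codons(total / 3L - 2L, cfg$codon_probs),
                stop_codon)
  # cut into exon interiors
  ends <- cumsum(lens)
  starts <- c(1L, ends[-n_ex] + 1L)
  exon_seqs <- substring(cds, starts, ends)
  introns <- if (n_ex > 1L) {
    vapply(seq_len(n_ex - 1L), function(i) {
      len <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2], 1L)
      y <- sample(c("C", "T"), 1L)
      paste0("GT", rand_noncoding(len - 5L, cfg$gc_noncoding), y, "AG")
    }, character(1))
  } else character(0)
  pieces <- character(2L * n_ex - 1L)
  pieces[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
  if (n_ex > 1L) pieces[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
  list(seq = paste(pieces, collapse = ""), exon_lens = lens,
       intron_lens = nchar(introns), n_ex = n_ex,
       coding = total, span = total + sum(nchar(introns)))
}

#' Generate a synthetic genome with planted genes
#'
#' Walks along the genome placing adaptively sized intergenic gaps and genes
#' drawn by [genome_sim_config()]'s model, steering the running coding
#' fraction toward the target. Fully reproducible under the config seed.
#'
#' @param config A [genome_sim_config()].
#' @return List with `record` (a [sequence_record()]), `annotation`
#'   (a [cds_annotation()] of the planted exons) and `genes` (data.frame:
#'   `gene`, `exon`, `start`, `end`, `cds_type` per planted exon).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  n <- cfg$length
  chunks <- character(0)
  pos <- 1L                       # next unwritten position
  coding_total <- 0
  exon_rows <- list()
  gene_id <- 0L
  max_span <- cfg$exons_per_gene[2] * cfg$exon_len_range[2] +
    (cfg$exons_per_gene[2] - 1L) * cfg$intron_len_range[2]
  repeat {
    g <- draw_gene(cfg)
    # choose the preceding gap so the running fraction tracks the target
    want_len <- (coding_total + g$coding) / cfg$target_coding_fraction
    gap <- max(cfg$min_intergenic, round(want_len - (pos - 1L) - g$span))
    if (pos - 1L + gap + g$span > n - cfg$min_intergenic) break
    chunks <- c(chunks, rand_noncoding(gap, cfg$gc_noncoding), g$seq)
    gstart <- pos + gap
    gene_id <- gene_id + 1L
    at <- gstart
    for (i in seq_len(g$n_ex)) {
      ex_s <- at; ex_e <- at + g$exon_lens[i] - 1L
      cds_type <- if (g$n_ex == 1L) "single"
        else if (i == 1L) "start"
        else if (i == g$n_ex) "end" else "internal"
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(gene = paste0("gene", gene_id), exon = i,
                   start = ex_s, end = ex_e, cds_type = cds_type)
      at <- ex_e + 1L
      if (i < g$n_ex) at <- at + g$intron_lens[i]
    }
    coding_total <- coding_total + g$coding
    pos <- pos + gap + g$span
  }
  if (gene_id == 0L)
    stop("genome length ", n, " too short to place a gene (max span ",
         max_span, ")")
  chunks <- c(chunks, rand_noncoding(n - (pos - 1L), cfg$gc_noncoding))
  seq <- paste(chunks, collapse = "")
  stopifnot(nchar(seq) == n)
  genes <- do.call(rbind, exon_rows)
  realized <- coding_total / n
  if (abs(realized - cfg$target_coding_fraction) > 0.05)
    stop(sprintf(
      "infeasible config: realized coding fraction %.3f vs target %.3f",
      realized, cfg$target_coding_fraction))
  record <- sequence_record(sprintf("synth_L%d_seed%d", n, cfg$seed), seq)
  annotation <- cds_annotation(record$id, genes$start, genes$end, n)
  list(record = record, annotation = annotation, genes = genes)
}

#' Write a simulated genome to disk
#'
#' Writes `<prefix>.fasta`, `<prefix>.gff3` (one CDS feature per planted
#' exon, grouped by gene via `Parent`), and `<prefix>.genes.tsv`.
#'
#' @param sim Result of [simulate_genome()].
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_genome <- function(sim, prefix) {
  fa <- paste0(prefix, ".fasta")
  gff <- paste0(prefix, ".gff3")
  tsv <- paste0(prefix, ".genes.tsv")
  write_fasta(sim$record, fa)
  g <- sim$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", sim$record$id,
                     nchar(sim$record$seq)),
             sprintf("%s\tgenesensor_sim\tCDS\t%d\t%d\t.\t+\t.\tID=%s.cds%d;Parent=%s",
                     sim$record$id, g$start, g$end, g$gene, g$exon, g$gene))
  writeLines(lines, gff)
  utils::write.table(g, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, genes = tsv))
}
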