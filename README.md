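# genesensor

Ab initio prediction of protein-coding nucleotides in genomic DNA, for
annotating assemblies of nonmodel organisms where no phylogenetically close
training material exists. The method deliberately avoids learning
species-specific gene structure: it classifies each nucleotide from generic
compositional signals and then forces the classification to be biologically
consistent.

## Method

Three stages, each exposed as plain R functions:

1. **Sensors.** Every nucleotide is described by a 16-component feature
   vector computed over a centered window of W = 69 nt:
   - the period-3 DFT magnitude of the four Voss indicator tracks,
     `S_DFT = Σ_j |Σ_n x_n(j) e^{-i2πn/3}|` (codon structure produces excess
     power at frequency 1/3 in coding DNA);
   - five k-mer coding-potential sums (k = 2..6),
     `Σ_n -ln(p1(j_n|k) / p0(j_n|k))`, where `p1`/`p0` are k-mer frequency
     weights estimated from labeled coding/noncoding sequence;
   - GC content `(n_G + n_C) / (n_A + n_T + n_G + n_C)`;
   - eight motif-distance sensors `max(W/2 - D, 0)` to the nearest start
     codon (ATG), stop codon (TAG/TAA/TGA), acceptor (YAG) and donor (GT)
     on each side of the window center;
   - Shannon entropy of the window's base composition.
2. **Classifier.** A 16→10→2 feed-forward network with SELU activations and
   unnormalized output scores, trained with softmax cross-entropy from
   logits on a balanced sample (N1 = N0) of labeled positions, 80/20
   train/validation split realized as 5-fold cross-validation (five models).
   Argmax over the two scores gives the *initial* per-nucleotide call.
3. **CDS consensus.** Every *potential CDS* — a region bounded by a legal
   left motif (ATG or YAG) and right motif (GT or stop), with interior
   length strictly between Lmin = 40 and Lmax = 400 — is scored by the ratio
   N1/N0 of initial calls inside it. Regions above a threshold are flipped
   entirely to coding (largest-region precedence for nested candidates),
   everything else to noncoding, so every predicted CDS is motif-bounded.
   The threshold is either fixed or swept upward until the predicted coding
   fraction falls to the expected genomic coding content plus a 0.1 margin.

A synthetic-genome simulator (`simulate_genome()`) plants multi-exon genes
obeying exactly this motif grammar over an AT-richer noncoding background,
with one knob (`codon_bias_strength`) controlling the codon-usage contrast,
so the whole pipeline is testable without external downloads.

## Worked example

```r
library(genesensor)

sim <- simulate_genome(genome_sim_config(length = 100000,
                                         target_coding_fraction = 0.2,
                                         seed = 7))
tables <- lapply(2:6, function(k)
  estimate_kmer_tables(sim$record, sim$annotation, k))
fm    <- featurize_track(sim$record, sensor_config(), tables)
truth <- label_nucleotides(sim$record, sim$annotation)

pos <- sample_balanced(truth, 10000, 10000, seed = 7)
ens <- train_ensemble(fm$values[match(pos, fm$positions), ],
                      truth$labels[pos], model_spec(), seed = 7)
ens
#> <model_ensemble> 5 models (16->10->2 SELU); val loss 0.0932 +/- 0.0062,
#>   val acc 0.9661 +/- 0.0041

initial <- predict_initial(ens, fm, "majority")
sw <- fraction_targeted_sweep(sim$record$seq, initial,
                              consensus_config(target_coding_fraction = 0.2))
sw$threshold
#> [1] 3
cds_metrics(confusion(sw$adjusted, truth))
#> <metrics_report> Sn=0.9945 Sp=0.8941 BA=0.9443 PPV=0.6874 MSP=0.8410 F1=0.8130
```

The fold validation accuracy (0.966) is balanced accuracy on held-out
*positions* of the same genome (in-sample for the k-mer tables, hence
optimistic); after the consensus sweep settles on threshold 3 the
predictions are motif-consistent with nucleotide-level Sn 0.99 / Sp 0.89 on
this genome. On genomes the tables and network never saw, initial balanced
accuracy lands near 0.87 and post-consensus near 0.92 — see the acceptance
tests. `sw$adjusted` is the final 0/1 track; `write_cds_bed()` exports the
accepted regions as BED6.

A command-line front end with `simulate`, `estimate-tables`, `train`,
`predict` and `evaluate` subcommands is installed at
`system.file("cli", "genesensor.R", package = "genesensor")`.

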