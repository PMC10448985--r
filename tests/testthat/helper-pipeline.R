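# Shared end-to-end runner for the signal-recovery and no-signal acceptance
# criteria: simulate a training genome, estimate tables, train the ensemble
# on a balanced sample, and score a held-out genome from the same generator.
e2e_heldout <- function(seed, bias, gc_noncoding, train_len = 500000L,
                        test_len = 100000L, n_samples = 100000L,
                        coding_fraction = 0.2) {
  sim_tr <- simulate_genome(genome_sim_config(
    length = train_len, target_coding_fraction = coding_fraction,
    codon_bias_strength = bias, gc_noncoding = gc_noncoding, seed = seed))
  tabs <- lapply(2:6, function(k) suppressMessages(
    estimate_kmer_tables(sim_tr$record, sim_tr$annotation, k)))
  fm_tr <- featurize_track(sim_tr$record, sensor_config(), tabs)
  truth_tr <- label_nucleotides(sim_tr$record, sim_tr$annotation)
  n1 <- n_samples %/% 2L
  pos <- sample_balanced(truth_tr, n1, n_samples - n1, seed = seed)
  ens <- train_ensemble(fm_tr$values[match(pos, fm_tr$positions), ],
                        truth_tr$labels[pos], model_spec(), seed = seed)
  sim_te <- simulate_genome(genome_sim_config(
    length = test_len, target_coding_fraction = coding_fraction,
    codon_bias_strength = bias, gc_noncoding = gc_noncoding,
    seed = seed + 500L))
  fm_te <- featurize_track(sim_te$record, sensor_config(), tabs)
  truth_te <- label_nucleotides(sim_te$record, sim_te$annotation)
  per_model <- predict_initial(ens, fm_te, "per_model")
  init_ba <- mean(vapply(per_model, function(tr)
    cds_metrics(confusion(tr, truth_te))$ba, numeric(1)))
  majority <- predict_initial(ens, fm_te, "majority")
  list(init_ba = init_ba, majority = majority, truth = truth_te,
       seq = sim_te$record$seq, ensemble = ens)
}
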