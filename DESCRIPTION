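Package: genesensor
Title: Sensor-Based Neural Network Prediction of Protein-Coding Regions
Version: 0.1.0
Authors@R:
    person("BioMolecular", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ab initio prediction of protein-coding nucleotides in genomic DNA.
    Sixteen window-based sensor features (period-3 discrete Fourier transform
    signal, k-mer log-likelihood coding potential for k = 2..6, GC content,
    distances to start/stop codon and splice-site motifs, Shannon entropy) are
    computed per nucleotide and classified by a small SELU feed-forward neural
    network trained on balanced samples with 5-fold cross-validation. Initial
    per-nucleotide calls are post-processed into biologically consistent CDS
    predictions by enumerating motif-bounded potential coding regions (ATG,
    stop codons, YAG acceptor, GT donor) and applying an N1/N0 consensus
    threshold, optionally auto-tuned against a target genomic coding fraction.
    Includes a synthetic genome simulator with planted multi-exon genes,
    nucleotide-level accuracy measures, and a scriptable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
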