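---
title: "Sensor-based neural-network gene prediction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-based neural-network gene prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`genesensor` predicts, for every nucleotide of a DNA sequence, whether it
lies inside a protein-coding sequence (CDS). It makes no attempt to assemble
gene models or respect reading frames during classification; instead it
combines three ideas:

1. **Window sensors.** Coding DNA differs from noncoding DNA in several
   generic, largely species-independent ways: triplet periodicity (excess
   spectral power at frequency 1/3), k-mer composition, GC content, entropy,
   and proximity to the motifs that bound real CDS regions. Each of the 16
   sensors reduces a 69-nt window centered on the query base to one number.
   No reading frame is referenced anywhere.
2. **A deliberately small classifier.** A single hidden layer of 10 SELU
   neurons maps the 16 features to two unnormalized class scores. Larger
   networks do not help: the sensors already are the representation, and the
   network only has to carve a 16-dimensional decision boundary.
3. **Consensus post-processing.** Raw per-nucleotide calls are noisy and not
   biologically possible (runs of coding labels start and end anywhere). The
   consensus step enumerates every *potential CDS* — an interval bounded by
   ATG or a YAG acceptor on the left and by a GT donor or a stop codon on
   the right, with interior length strictly between `lmin` and `lmax` — and
   assigns each the ratio N1/N0 of coding to noncoding initial calls inside
   it. Regions above a threshold become all-coding, everything else
   all-noncoding. Cooperativity is the point: one strong region absorbs
   scattered errors, and every maximal run of predicted coding bases is
   bounded by legitimate motifs afterwards.

## Sensor definitions and numerical conventions

All sensors use natural logarithms and a window of odd width `W` (default
69, so 34 nt at each sequence end are sequestered and carry no prediction).

* **Period-3 DFT.** The window is Voss-encoded (A→[1,0,0,0], T→[0,1,0,0],
  G→[0,0,1,0], C→[0,0,0,1]; N→null). The sensor is
  `Σ_{j=1..4} |Σ_{n=0..W-1} x_n(j) e^{-i 2π n/3}|`, the DFT magnitude at
  frequency W/3 summed over the four indicator tracks. Requires `3 | W`.
* **k-mer coding potential (k = 2..6).** Per k-mer score
  `-ln(p1(j|k)/p0(j|k))`; the sensor sums the score of every k-mer start
  position in the window. The published summation limit reads `W-k-1`,
  which misses the last two windowed k-mers; we treat that as a typo and sum
  all `W-k+1` positions (`sensor_config(kmer_sum = "as_printed")` restores
  the literal count). Negative sums mean coding-like composition.
* **Frequency weights.** `p(j|k) = (count(j) + 1) / bases_extracted`, with
  up to `4^k · k · 1000` bases extracted per class, counted stride-1 within
  contiguous segments and never across segment boundaries. The pseudocount
  (1) keeps the log-ratio finite for unobserved k-mers — at k = 6 there are
  4096 k-mers and small corpora routinely miss some. The denominator is the
  number of *bases*, following the published normalization, not the number
  of k-mer windows; only the ratio matters downstream, and both classes are
  normalized the same way. When a class holds fewer bases than the target
  the whole class is used and the shortfall logged.
* **GC content.** N is excluded from numerator and denominator; an all-N
  window scores 0.
* **Motif distances.** `max(W/2 - D, 0)` where `D` is the distance from the
  center to the first base of the nearest motif on the requested side
  (start = ATG, stop = TAG/TAA/TGA, acceptor = YAG with Y∈{C,T},
  donor = GT). A motif whose first base sits on the center counts to the
  right with `D = 0`; left-side scans use `D ≥ 1`. Motifs must lie entirely
  inside the window (the sensor sees nothing else), may straddle the center
  (assigned to the side holding their first base), and never contain N.
  With `W = 69`, `W/2 = 34.5`, so any motif found scores at least 0.5 and
  absence scores exactly 0.
* **Entropy.** The published formula carries an extra `P(b)` factor
  relative to Shannon entropy: `-(1/W) Σ_b n_b P(b) ln P(b)` with
  `P(b) = n_b/W`. The default (`"as_printed"`) implements it verbatim for
  fidelity; `"standard"` gives `-Σ_b P(b) ln P(b)`. N counts toward `W` in
  the denominator but contributes no term, so an all-N window scores 0.
  Since the classifier standardizes features, the choice mostly rescales
  one input.

`featurize_track()` computes all sensors at all positions with
cumulative-sum sliding windows; unit tests pin it window-by-window to the
scalar sensor functions.

## Classifier

The published architecture (16→10→2, SELU, two unnormalized outputs,
sparse categorical cross-entropy from logits, balanced sample with
N1 = N0, 80/20 split under 5-fold cross-validation) fixes everything except
the optimizer. We use Adam (lr 1e-3, batch 256, ≤100 epochs, early stopping
with patience 5 on validation loss, LeCun-normal initialization) — standard
choices for a network this size, all exposed in `model_spec()`. The 80/20 ×
5-fold combination is realized as five disjoint 20% validation folds, each
model training on the complementary 80%. Features are standardized (mean/sd
fitted once on the full balanced sample and stored with the ensemble) since
SELU assumes roughly normalized input; the per-fold training sets are 80%
subsamples of the set the statistics were fitted on, so the leakage through
two moments is negligible. Exact score ties classify as noncoding, making
predictions deterministic.

## Consensus and thresholds

Candidate interiors follow standard CDS conventions: start and stop codons
are inside the CDS, splice dinucleotides outside. So a `single` region runs
from the A of ATG to the last base of the stop codon; `start` from the A of
ATG to just before the G of GT; `internal` from just after YAG to just
before GT; `end` from just after YAG to the last stop base. Length bounds
are strict (`lmin < L < lmax`, defaults 40/400). The acceptance rule is
literal: ratio strictly above the threshold passes; candidates contained in
an accepted region are skipped. The shipped implementation uses an
equivalent vectorized formulation — accepted regions are exactly the
passing candidates that are maximal under interval containment — proved
equivalent to the sequential procedure and pinned against a brute-force
oracle in the tests. `n0 = 0` yields ratio `+Inf` (always accepted),
`n1 = 0` ratio 0. Candidates extending beyond the valid range are scored on
the overlap.

Two threshold heuristics are provided. For assembled genomes,
`fraction_targeted_sweep()` walks an increasing grid (default 0.5–30,
covering the published working range) and stops at the first threshold
whose predicted coding fraction is at most the expected coding content plus
a margin of 0.1 — the predicted fraction should sit slightly *above* the
empirical content. For isolated sequences, `best_threshold()` optimizes
MSP, F1, or `|Sn - Sp|` per sequence against truth labels. The adjusted
coding fraction is provably non-increasing in the threshold (the union of
accepted interiors equals the union of all passing interiors, and the
passing set shrinks), which the sweep relies on.

One stated invariant did **not** survive implementation: re-running the
adjustment on its own output is *not* exactly idempotent. Once a region is
flipped all-coding, a longer candidate that partially overlaps it (and is
therefore not subject to containment precedence) can rise above the
threshold on a second pass. What does hold, and is tested, is monotone
growth: re-adjustment never removes an accepted interior.

## The synthetic genome: what it emulates and what it does not

`simulate_genome()` plants non-overlapping genes of 1–6 exons with interior
lengths uniform on [40, 400] and introns on [60, 200], each spliced CDS
reading ATG + sense codons + stop in frame, with GT/YAG planted on intron
flanks so every exon is recoverable as a motif-bounded candidate. Coding
sequence is drawn codon-by-codon from a 61-sense-codon multinomial
interpolated by `codon_bias_strength` between uniform and a fixed skewed
table (product of positional base preferences; at full bias its effective
number of codons is ≈30, matching strongly codon-biased, highly expressed
genes). Noncoding DNA is an order-0 background, by default at GC 0.45
against ≈0.55 for the coding model — the usual exon/intergenic contrast;
passing `gc_noncoding = NULL` matches the GC exactly, which the no-signal
null test uses together with bias 0. Intergenic gap sizes are steered
adaptively so the realized coding fraction lands within 0.05 of the target,
else generation errors out as infeasible.

What the simulator does *not* emulate: isochore structure, repeats,
alternative splicing, pseudogenes, non-canonical splice sites, sequencing
error, or any higher-order dependence in noncoding DNA. A green end-to-end
test therefore establishes that the pipeline recovers a planted
compositional contrast through the full sensor → network → consensus path
(and, via the bias-0 null, that nothing else leaks labels) — not that the
same accuracy will be reached on real chromosomes, where the contrast is
weaker and the noncoding model is wrong.

## Degenerate inputs and edge policies

Characters outside {A,C,G,T,N} become N with a warning. N breaks motif
matches, contributes null DFT columns, skips k-mers, is excluded from GC,
and counts only in the entropy denominator. Sequences shorter than the
window cannot be featurized. Zero-denominator accuracy measures are
reported as 0 with a `degenerate` flag rather than NaN. Strand handling is
forward-only; `reverse_complement()` is provided for callers who wish to
scan both strands and union the BED output.

## Known limitations

* k-mer weights estimated from sub-megabase corpora are noisy at k = 5, 6;
  the network then partially fits table noise that does not transfer across
  genomes. The published corpus target (`4^k·k·1000` bases) avoids this but
  requires chromosome-scale training data.
* The consensus step's accuracy gain depends on a sensible target coding
  fraction; a badly wrong target pushes the sweep to a threshold that over-
  or under-predicts globally.
* Training is single-threaded base R; an ensemble on 10^5 samples takes
  about a minute. This is deliberate — no deep-learning runtime dependency —
  but means 10^7-sample training, while supported, is slow.
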