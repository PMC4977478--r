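---
title: "Methods: enhancer prediction, importance analysis, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer prediction, importance analysis, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Enhancers are distal cis-regulatory elements that upregulate transcription
independent of orientation and distance. They cannot be recognized from
sequence alone, but active enhancers carry a characteristic combination of
histone modifications (H3K4me1, H3K27ac, and others) measurable genome-wide
by ChIP-seq. `enhancerDNN` predicts enhancer locations from such
histone-modification enrichment with a small fully connected feedforward
network, makes the trained network interpretable by propagating connection
weights backward into per-feature and per-mark importance scores, and uses
those scores to retrain reduced models on only the top-k features.

No single mark separates enhancers from everything else: enhancer-like
enrichment of any one mark also occurs at promoters and at unrelated
domains, so the class-conditional signal distributions overlap heavily.
The premise of the method is that the *combination* of marks — and the
spatial profile of each mark across a ±1 kb window — carries the
discriminating information, which is why an expressive classifier over the
full windowed feature set is used rather than per-mark rules.

# Feature construction

Aligned reads for each histone-modification replicate (BED intervals) are
binned into 100 bp bins by their 5'-most coordinate, converted to RPKM
(`count / (bin_width/1000) / (total_mapped/1e6)`), and replicate tracks are
averaged. At a candidate bin, the feature vector concatenates, for each of
the M marks, the 20 bin values spanning −1 kb to +1 kb. A 2 kb window of
100 bp bins cannot center symmetrically on one bin; the window covers
offsets −10..+9 relative to the center bin, and every column's (mark,
offset) pair is recorded in the feature matrix's `column_map`. The feature
count is M × 20: 480 features for 24 marks, 220 for 11, 180 for 9.

Optional input-control normalization is per-bin subtraction of the control
RPKM floored at zero (`subtract_control()`), off by default: the
appropriate treatment of input libraries is assay-dependent, and the
pipeline's defaults assume none. Replicates are averaged after
normalization.

# Training and test sets

Positives are p300 co-activator peaks that overlap a DNase-I
hypersensitive site and lie more than 1 kb (summit-to-summit) from every
TSS: distal, open-chromatin p300 binding marks active enhancers while
excluding promoter-proximal binding. Negatives are TSS that overlap a DHS
(promoters in open chromatin — the hard negatives) plus random 100 bp bins
whose centers are >1 kb from every DHS and TSS summit. Training uses a
1:10 positive:negative ratio; the negative subsample is stratified so the
TSS:background proportion of the input pools is preserved. All distance
rules are summit-to-summit, because peak calls localize the underlying
event at a single position; cross-chromosome distances are infinite by
convention so no rule fires across chromosomes.

# The network

A fully connected feedforward network (default hidden layers 600-500-400,
one output neuron) with softplus activations `log(1 + exp(x))` on every
unit, trained by mini-batch SGD (batches of 100) on the mean squared error
between the raw output and the 0/1 label, with dropout rate 0.5 on the
hidden layers (inverted scaling, fresh Bernoulli masks per batch). The
output unit's activation is configurable (`softplus` default, `linear`
available); under softplus the raw score is non-negative and unbounded
above, and a location is called an enhancer when its score strictly
exceeds a chosen threshold.

Choices the published operating point leaves open, fixed here as the
package's initialization and optimization policy:

* **Learning rate 0.01, no momentum**, both configurable. Mini-batch
  gradients of the MSE are averaged within the batch.
* **Hidden layers** are initialized uniformly on
  `[-1/sqrt(fan_in), +1/sqrt(fan_in)]`.
* **The input layer is initialized at 1/100 of that range**
  (`input_init_scale = 0.01`). The importance analysis below reads
  absolute input-weight magnitudes; starting them near zero means the
  magnitude a feature accumulates is built by gradient signal rather than
  inherited from the random draw. With full-scale input initialization the
  random |w| mass dominates and the importance ranking of a trained
  network is statistically indistinguishable from that of an untrained
  one. Hidden layers keep full-scale initialization to preserve gradient
  flow and symmetry breaking.
* **The output bias starts at the inverse softplus of the label mean.**
  With a 1:10 class imbalance, a zero-started softplus output unit is
  pushed hard toward zero by the negative majority early in training and
  can land in the activation's dead zone (all gradients vanish; training
  collapses to a constant). Starting the output at the base rate removes
  the initial imbalance shock. The training loop also aborts with a
  diagnostic if the loss becomes non-finite.
* **Epochs**: `train_config()` defaults to the published 5 epochs. The
  desk-scale synthetic runs in this package use 30 epochs
  (`default_run_config()`): with a ~2–3k-sample training set, 30 epochs is
  roughly the same number of SGD updates as 5 epochs at the ~47k-sample
  scale the 5-epoch figure comes from.
* **Ties at the threshold** are excluded (strict `>`), fixed for
  reproducibility.
* **Determinism**: initialization, shuffling, and dropout masks all derive
  from `train_config(seed = )`; identical data, configuration and seed
  reproduce identical parameters bit-for-bit.

# Importance scores and top-k reduction

The output neuron receives importance 1. Importance then propagates
backward: the score of neuron i is `S_i = sum_j |w_ij| S_j` over the
neurons j of the next layer it feeds into; biases play no part. The
input-layer scores are the per-feature importances — equivalently, each
input's score is the sum over all directed paths to the output of the
product of absolute weights along the path, which is how the independent
test oracle (`path_product_oracle()`) computes it by brute-force
enumeration on small networks. A mark's importance is the sum of its 20
feature scores, so the per-mark total conserves the per-feature total.

Features are ranked by importance (descending, ties broken by ascending
index); reduced models keep the top-k columns and retrain with the same
hidden architecture. Importance is computed from a single trained model by
default — rankings are seed-sensitive, and averaging over restarts is left
to the caller (train with several seeds and average the per-feature
vectors) rather than hidden inside the function.

# Evaluation: validation rate

Precision/recall are not meaningful here: the universe of true enhancers
is mostly unannotated, so a "false positive" may simply be an unannotated
enhancer. Instead a prediction is *validated* if it lies within 2.5 kb
(inclusive, summit-to-summit) of a true-positive marker (TPM): a distal
DHS, p300, CBP or TFBS peak more than 1 kb from every TSS. Predictions
near nothing known are counted as errors. The validation rate is the
validated fraction of predictions at a given threshold; sweeping the
threshold trades prediction count against validation rate. With zero
predictions the rate is reported as missing, never as 0 or 1.

Raw score scales differ across feature sets and architectures, so reduced
and full models are compared **at matched prediction counts**: each
model's threshold is taken from its own score-quantile grid at the point
whose prediction count is closest to a common target
(`operating_point()`). The desk-scale benchmark uses ~3,000 genome-wide
predictions on a 50,000-bin genome — roughly ten predicted bins per
planted enhancer, the middle of the useful range between confident-only
and saturated calling.

The class-distribution overlap statistic is histogram intersection:
both samples are binned on a shared 100-bin grid over the pooled range and
the overlap is `sum_b min(p_a(b), p_b(b))`. The bin count is exposed
because the statistic's value depends on it; it is reported alongside
results.

# The synthetic epigenome

The generator plants P300/CBP/TFBS (enhancer-class) and TSS sites uniformly
at random with a minimum 5 kb spacing on a small genome (default two 2.5 Mb
chromosomes, 300 enhancer-class sites, 150 TSS), co-places a DHS at every
enhancer site and (by default) every TSS — open chromatin accompanies both
active enhancers and active promoters — and draws per-mark reads per 100 bp
bin from a Poisson whose mean is a background rate (default 1 read/bin)
plus Gaussian enrichment bumps around sites. Reads are materialized as
100 bp intervals, and RPKM normalization uses a declared library size
(default 1e7): the synthetic chromosomes stand in for a window of a
genome-scale experiment, which keeps RPKM values on the realistic O(1–20)
scale rather than inflating them by the small window's read count.

Three features of real enhancer chromatin are modeled deliberately,
because each is what makes some part of the method non-trivial:

* **Per-site, per-mark strength dispersion.** Each site expresses each
  mark at a Gamma-distributed multiple of the class amplitude (shape 2,
  mean 1). Real class-conditional signal distributions overlap heavily;
  deterministic amplitudes would separate cleanly and make the problem
  artificially easy.
* **Decoy enrichment domains.** Every mark, including the informative
  ones, has enrichment domains at per-mark random positions unrelated to
  any planted site (default 200 per mark, at ~60% of the enhancer
  amplitude for informative marks). Enhancer-associated signal at
  non-enhancer loci is what makes any single mark ambiguous; a decoy
  lights one mark where a true enhancer lights all four, so only the
  combination resolves them. Decoys are also what the no-signal control
  retains: with class amplitudes zeroed, structured signal remains but
  none of it is label-correlated.
* **Bimodal enhancer profiles.** Enhancer-class bumps are two
  half-amplitude Gaussians at ±300 bp around the summit (decoys and TSS
  are unimodal): enhancer marks flank the nucleosome-free region where the
  co-activator binds. The enhancer signature therefore lives in the
  spatial profile across the window, not in the central bin alone — which
  is also why very small top-k feature sets lose accuracy.

Four of the twelve default marks (H3K4me1, H3K27ac, H3K4me2, H3K9ac) are
informative — enhancer amplitude ~14–20 expected reads at the peak versus
2 at TSS; the other eight are class-independent: flat at planted sites,
with decoy domains of amplitude 5. Default widths follow the familiar
shapes (wider H3K4me1-like flanks, narrower acetylation peaks). All of
this is config-exposed and none of it is asserted as measured biology.

**What the generator does not emulate:** mappability and GC structure,
fragment-length effects, copy-number variation, replicate batch effects
beyond independent Poisson draws, chromatin-state autocorrelation along
the genome, and the sheer scale and annotation incompleteness of real
genomes. Passing the synthetic benchmark shows the pipeline's machinery is
correct and its operating behavior matches the intended regime; it does
not certify genome-scale accuracy figures on real Roadmap/ENCODE data.

# Problem sizes used in the checks

The test suite and the acceptance script run: a 5 Mb / 300-enhancer
benchmark (training ~200 positives + 2,000 negatives after the 1:10
subsample; prediction over all 50,000 bins) for the end-to-end, top-k and
control checks; ten 1 Mb / 60-enhancer replicates for planted-mark
recovery; and small analytic fixtures for the importance oracle (≥50
random networks up to 4 hidden/total layers), the gradient check
(5-4-3-1), and the overlap statistic. These sizes were chosen so the full
distribution of checks completes comfortably on a single CPU while keeping
every rate estimate's sampling error a few points at most.

# Degenerate inputs and numerical choices

* `softplus` is evaluated as `max(x, 0) + log1p(exp(-|x|))`, exact and
  overflow-safe at |x| in the thousands.
* Windows at chromosome ends are zero-padded (rows flagged
  `edge_padded`), keeping location sets rectangular.
* Empty reference sets: `is_distal()` is vacuously true (with a warning);
  `overlaps_any()` is false; an empty TPM set validates nothing.
* An empty prediction set yields an undefined (NA) validation rate.
* The background-bin sampler rejection-samples with an attempt cap and
  reports the achieved count on failure.
* Reads outside declared chromosomes are dropped with a warning count.
* `distribution_overlap` of two identical constants is 1 (zero pooled
  range is treated as identical distributions).

# Known limitations

Connection-weight importance is a global, model-level attribution; it does
not attribute individual predictions, and single-run rankings vary with
the training seed. The |w|-propagation ignores activation saturation and
input scale, so scores are comparable within a model, not across models.
The validation-rate protocol inherits the TPM set's incompleteness on real
data: rates are upper-bounded by annotation coverage near predictions.
Training is plain SGD on MSE by design fidelity; no early stopping,
weight decay, or adaptive optimizers are used.
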