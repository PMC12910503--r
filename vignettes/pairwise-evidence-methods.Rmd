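---
title: "Learning evidence of pairwise association between genomic windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning evidence of pairwise association between genomic windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epair)
```

## The problem and the model

Many biologically meaningful relationships between two genomic loci — shared
gene bodies, co-regulated enhancer–promoter pairs, joint membership in a
topologically associating domain (TAD) — leave coordinated footprints in
epigenomic and transcription-factor (TF) binding data, yet are invisible to
any single assay and only partially captured by chromatin-contact
experiments. `epair` scores *evidence of association* for every pair of
fixed-size genomic windows within a maximum distance, using nothing but
binary functional-genomics features and the genomic distance itself.

The genome is tiled with non-overlapping windows of `r` bases. Each window
gets a binary feature vector: one bit per peak-call assay (1 iff the window
overlaps a peak by at least one base) and one bit per (epigenome, chromatin
state) combination under one-hot encoding, so a window may carry several
states of one epigenome when the segmentation changes inside it. For every
pairwise distance `d` on the grid `r, 2r, ..., D` a classifier is trained to
separate *positive* pairs — windows whose first bases are exactly `d` apart —
from *negative* pairs obtained by randomly re-pairing the same windows
within each chromosome. Because positives and negatives are built from
exactly the same windows (per chromosome and per role), nothing marginal
about an individual window can separate the classes: the classifier is
forced to learn joint structure. The core assumption is that windows a fixed
short distance apart are more likely to be genuinely associated than random
same-chromosome re-pairings; the method does not require every positive to
be a true association, only the two distributions to differ.

The classifier is a Siamese neural network: a twin sub-network with a single
hidden layer maps each window's feature vector to a hidden representation —
the two twins *share their weights*, implemented here as a single parameter
store whose gradient accumulates both twins' contributions — and a combining
sub-network with one hidden layer maps the ordered concatenation of the two
twin outputs to a probability. During training every pair is presented in
both orders (flip augmentation), doubling the training stream. A raw
forward pass is still order-sensitive, because the combiner sees an ordered
concatenation; exact symmetry of the final score comes from averaging over
flips at prediction time.

The final score for a pair at an interior distance `d` averages 30
predictions: 5 ensemble members for each of the distances `d - r`, `d`,
`d + r`, each applied to both input orders. At the ends of the distance
range the missing neighbour leaves 20 predictions. Classifiers at adjacent
distances learn similar structure, so this cross-distance averaging reduces
variance and smooths the score across the distance grid; the 30-value
multiset is invariant under swapping the windows, so the score is exactly
symmetric.

## Training protocol

Chromosome splits follow a parity scheme: to score pairs on odd autosomes
(and chrX, which is scored but never trained on), classifiers are trained
on even autosomes, with a few even autosomes (three at genome scale) held
out for validation, and evaluation pairs drawn from the odd autosomes —
symmetrically for even targets. Per distance, hyperparameters are selected
by random search: 10 combinations (3 at the package's synthetic test scale)
drawn without replacement from fixed grids — batch size {16, 32, 64},
learning rate {1e-8, 1e-6, 1e-4}, dropout {0, 0.25, 0.5}, twin and combiner
hidden widths {32, 64, 128}; 243 combinations in all. Every trial trains on
the same pair sample and the combination with the best validation AUROC
(ties: first trial) seeds the final ensemble: 5 classifiers (2 at test
scale), each trained on an independent sample of up to 50,000 pairs.

Several training details are deliberate package choices, since only the
grids and the protocol shape are fixed by the design: ReLU activations,
binary cross-entropy loss, and the Adam optimiser. Adam bounds each
parameter's per-step displacement by the learning rate, and the grid's top
rate is 1e-4, so useful training runs need many small steps; the schedule
therefore allows up to 120 epochs but watches the validation AUROC each
epoch and stops once it has failed to improve by at least 0.001 for 5 consecutive
epochs, restoring the best-epoch parameters. Trials drawn with learning
rates too small to move the loss abandon within a handful of epochs, while
learning trials run to their plateau. Class balance is exact (1:1) by
construction, so the loss is unweighted. The combiner input is the
concatenation of the twin outputs; the combination operator is otherwise
unconstrained by the design, and we rely solely on flip averaging — not a
symmetric combiner — for order invariance.

All randomness flows from one master seed through named substreams (one per
distance, role and ensemble member), so every artifact — worlds, shuffles,
weight initialisations, minibatch orders — regenerates exactly.

## Evaluation and baselines

Predictive power is summarised as AUROC (Mann–Whitney formulation, ties
counted one half) of held-out positives versus held-out shuffled negatives,
per distance, averaged over the two parity replicates trained on
non-overlapping chromosome sets. Two baselines receive identical inputs and
identical evaluation: the Jaccard index of the two windows' binary feature
vectors (pure similarity; no training), and a per-distance decision tree on
the concatenated pair vector with flip augmentation, its depth tuned on
validation AUROC over {4, 8, 16, 30} — 30 is the tree implementation's
ceiling and serves as the unlimited arm. Test pairs are deliberately *not*
filtered against assembly gaps; gap filtering (drop any pair whose either
window touches a gap by one base or more) applies to all biological
analyses, where unmappable windows would distort enrichments, but not to
reporting predictive performance.

Distance confounding is handled by empirical percentile transforms with
mean ranks for ties: within each distance stratum (the default for all
enrichment analyses, making them invariant to any strictly monotone
per-distance rescoring) or globally (for score-distribution summaries).
Whether percentiles should be pooled or distance-stratified is genuinely
ambiguous for some analyses, so both modes are implemented; the
distance-stratified default removes the residual negative correlation of
score with distance before any biological contrast.

## Biological validation statistics

All validation analyses consume the same score-table schema
(`chrom, start1, start2, distance, score`), so learned, Jaccard and contact
scorings are compared by running identical code.

* **Gene-body quartile contrast.** For a gene of length `l` (quartile
  `q = l/4`) the pair of bases at the first and third quartile points (2`q`
  apart, both inside the gene) is compared to the distance-matched pair
  sharing the third-quartile base but ending `q` beyond the transcription
  end site. Both bases snap to their window starts; genes shorter than
  `4r`, no longer distance-matched after snapping, or with an unscored pair
  are dropped and counted. A one-sided Wilcoxon signed-rank test asks
  whether within-gene percentiles exceed boundary-crossing ones. Minus-strand
  genes mirror the geometry.
* **Chromatin-state pair matrices.** At one distance, each window pair
  contributes to the cell (upstream state, downstream state) with weight
  equal to the product of the two states' base counts inside the respective
  windows; cells holding less than 0.0005% (fraction `5e-6`) of the total
  weight are masked. Cells fall into three disjoint categories — same
  state, same group but different state, and cross-group pairs of "active"
  groups (promoter, transcription, enhancer) — compared across score kinds
  with two-sided Mann–Whitney tests.
* **TAD contrast.** Per distance, pairs with both windows fully inside the
  same TAD are tested (one-sided Mann–Whitney) against pairs with exactly
  one window inside a TAD and the other outside any TAD; pairs spanning two
  different TADs belong to neither group. Reported: the number of distances
  significant at `p < 1e-4`.
* **Contact-frequency correlation.** Pearson correlation with a normalized
  contact table per distance (inner join on pairs), averaged over distances
  with defined variance.
* **Fine-mapped variant contrast.** Per trait, original pairs are all
  same-chromosome window pairs containing fine-mapped variants within `D`;
  each original pair (a, b) at distance d yields mirrored controls
  (a−d, a) and (b, b+d), each sharing one window and preserving the
  distance, with controls dropped when the free window carries a trait
  variant, leaves the scored territory, or overlaps an assembly gap. A
  trait is "higher" when its original pairs' mean score beats its retained
  controls' mean — means rather than a rank test, and ties count as not
  higher; these details are unstated in the design and fixed here as
  package policy. The count of higher traits is tested against the
  binomial null (half the traits).

## The synthetic worlds: what they emulate and what they do not

Real inputs at the scale this method targets (thousands of ENCODE and
Roadmap assays, hundreds of millions of pairs) are not reproducible at desk
scale, so the package ships a generator that plants the one statistical
property the method exploits, at a scale where the full pipeline runs in
minutes on one CPU. Chromosomes are tiled by latent domains with
geometric lengths (mean `decay_scale`, default `10r`), so the probability
that two windows share a domain — and with it the planted association —
decays approximately as `exp(-d / decay_scale)`: the mechanism behind the
distance-decaying AUROC curve. A domain is *active* with probability 0.9;
active domains activate one planted block of 6 peak features in their
windows at rate `0.05 + 0.9 * strength` against a background firing rate of
0.05. Those defaults were chosen once so that, at strength 0.8, the
planted signal is strong at `d = r` and clearly separable by both the
learned score and similarity, while block collisions between unrelated
domains (1 in 10 blocks) stay rare; chromatin states are uniform per-window
noise so that similarity in state space carries no hidden signal.

Three modes differ in *where* the signal lives. `shared` plants the same
block on both windows (association visible to similarity). `complementary`
alternates two disjoint block pools by window parity inside a domain, so at
`d = r` every true pair has disjoint planted supports: similarity is blind
(Jaccard AUROC ~0.5) while block-identity correspondence remains learnable —
the miniature of the claim that the learned score captures association
beyond similarity. Window-parity alternation, rather than domain halves, is
used so that the similarity-blindness holds exactly at the evaluated
distance instead of only for boundary-spanning pairs. `none` plants
nothing, and every distance's AUROC must stay near chance.

Genes and TADs coincide with (active) domains, fine-mapped variants cluster
inside active domains, and assembly gaps sit at a fraction of domain
boundaries — so each validation statistic has a planted expected outcome.
The worlds default to 6 chromosomes of 500 windows: enough for the parity
split to keep two training chromosomes after holding one out for validation
(the genome-scale protocol holds out three of eleven); a 4-chromosome world
would leave a single training chromosome and an unstably small training
pool. What the fixtures do **not** emulate: realistic chromatin biology,
correlated assays, state-activity coupling, signal-level (non-binary)
features, inter-chromosomal structure, or genome-scale class imbalance —
passing on fixtures shows the machinery is correct and the learning
behaviour qualitatively right, not that genome-scale performance numbers
transfer.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) throughout; windows
  are grid-aligned, so interval-to-window overlap is exact integer
  arithmetic, cross-checked in the tests against an independent
  interval-tree implementation.
* Trailing partial windows are dropped: feature density on a short window
  is not comparable. A chromosome shorter than `r` yields zero windows with
  a warning.
* Overlap threshold is one base, for peaks, states and gaps alike.
* Shuffled negatives may coincide with a true-distance pair (a permutation
  fixed point); a derangement is *not* enforced, and the coincidence count
  is recorded. A chromosome contributing a single pair keeps it verbatim.
* AUROC with an empty class is an error; correlations over degenerate
  (zero-variance) strata are reported as missing and excluded from means.
* Percentile ties take mean ranks; an all-tied table maps to 0.5
  everywhere.
* Ensemble scoring refuses to run when the ensemble for a required distance
  (including an interior neighbour) is missing, and refuses to score
  chromosomes that any member saw in training.
* Zero-variance feature columns are retained: dropping them would change
  feature indices between worlds and they are harmless to the classifier.

## Known limitations

The score is defined only within chromosomes and up to `D`; negatives are
same-chromosome by construction, so nothing is learned about
inter-chromosomal association. Scores are probabilities of a synthetic
discrimination task, not calibrated association probabilities. The training
cost of the grid's small learning rates makes the neural step the slowest
part of the pipeline; at genome scale the protocol is embarrassingly
parallel across distances, but this package runs it serially. Decision-tree
baseline details beyond the protocol mirror (depth grid, concatenated
input, flip augmentation) are package choices. The problem sizes used
throughout the documentation and checks — 6 x 500 windows, 10 distances,
3-trial searches, 2-member ensembles — are the package's reference
synthetic scale, chosen so a full three-mode evaluation completes in
minutes on a single CPU.
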