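# epair

Learned evidence of pairwise association between genomic windows, from
binary epigenomic and transcription-factor (TF) binding features.

## What problem this solves, and for whom

Chromatin-contact assays see only part of the pairwise structure of a
genome: two loci can be functionally associated — transcribed as one gene
body, co-active across the same tissues, jointly regulated — without a
measurable physical contact. For computational biologists with access to
large collections of peak calls and chromatin-state segmentations, `epair`
turns those binary annotations into a per-pair **evidence-of-association
score** on a fixed window grid, plus the full evaluation and biological
validation stack around it.

## The method

The genome is binned into non-overlapping windows of `r` bases; each window
gets a binary feature vector (one bit per peak assay, one bit per
epigenome × chromatin state under one-hot encoding). For every pairwise
distance `d ∈ {r, 2r, …, D}` a **Siamese neural network** — twin
weight-sharing sub-networks, one hidden layer each, feeding a combining
sub-network — is trained to discriminate

* positive pairs: windows whose first bases are exactly `d` apart, from
* negative pairs: the same windows re-paired at random within each
  chromosome,

so the two classes have identical marginal window content and the
classifier must learn *joint* structure. Hyperparameters are picked by
random search over fixed grids (batch size, learning rate, dropout, two
hidden widths; 3⁵ = 243 combinations), maximising validation AUROC, and
5 final classifiers per distance are trained on independent samples of up
to 50,000 pairs. The score of a pair at distance `d` averages the
predictions of the ensembles at `d − r`, `d`, `d + r`, each member applied
to both input orders — 30 values at interior distances, 20 at the range
edges — and is exactly symmetric in the two windows. Chromosome splits are
by parity (train on even autosomes to score odd ones and chrX, and vice
versa), so scored chromosomes are never seen in training.

Around the score, the package implements AUROC-by-distance evaluation
against Jaccard-index and decision-tree baselines, distance and similarity
correlations, per-distance percentile transforms, and the validation
statistics: gene-body quartile contrasts, chromatin-state pair matrices
with coverage masking, TAD within-versus-cross tests, contact-frequency
correlation, and matched-control fine-mapped-variant tests. A synthetic
genome generator plants distance-decaying pairwise association in three
modes (`shared`, `complementary`, `none`) together with toy genes, TADs,
gaps and variant sets, so the whole pipeline is testable offline.

## A worked example

Simulate a small genome with planted shared-feature association, train the
per-distance ensembles, and evaluate held-out AUROC by distance:

```r
library(epair)

world <- simulate_world(fixture_params(seed = 7, association_mode = "shared",
                                       association_strength = 0.8))
pl <- run_fixture_pipeline(world, distances = c(1000, 2000, 3000))

dplyr::distinct(tidy(pl$curve)[c("distance", "mean_auroc")])
#> # A tibble: 3 x 2
#>   distance mean_auroc
#>      <dbl>      <dbl>
#> 1     1000      0.881
#> 2     2000      0.846
#> 3     3000      0.796
```

Windows 1 kb apart are separated from shuffled pairs with AUROC ≈ 0.88 by
classifiers that never saw the evaluated chromosomes; the signal decays
with distance because planted domains (mean 10 kb) end. Scoring a held-out
chromosome and testing the planted TADs:

```r
tab <- score_genome(pl$ensembles$odd, pl$windows, pl$features,
                    target_chroms = pl$splits$odd$test_chroms,
                    distances = c(1000, 2000, 3000))
tad_within_vs_cross(filter_gap_pairs(tab, world$gaps), world$tads)
#> TAD within vs cross: 3 of 3 distance(s) significant at p < 0.0001
```

Pairs inside the same planted domain score higher than distance-matched
pairs crossing a domain boundary at every distance — the contrast the
statistic is designed to detect against real TAD calls.

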