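---
title: "Evaluating short-read 16S rRNA study designs with ampligauge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating short-read 16S rRNA study designs with ampligauge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampligauge)
```

## The problem

High-throughput sequencing of the bacterial 16S rRNA gene interrogates
microbial communities at great depth, but short-read platforms cover
only part of the gene. A study design therefore has to choose a
hypervariable region (via a primer pair), a read length, and a
single-end or paired-end strategy — and then a taxonomic classifier and
a confidence threshold for accepting its predictions. The same
bootstrap confidence value carries very different error rates at
different taxonomic ranks and gene regions, so a single universal
threshold (the 50 or 80 used by convention) yields uneven, unknown
precision. `ampligauge` implements a framework that makes those error
rates explicit: it simulates the reads a design would produce from
reference alignments, measures the precision of a naive Bayesian
classifier on them by a species-exclusion cross-validation, calibrates
rank- and region-specific confidence thresholds that guarantee a chosen
false-prediction rate, and reports the coverage the design then
achieves on query sequences. Designs can be compared on the resulting
FPR-versus-coverage curves rather than on a fixed, arbitrary
confidence cutoff.

## From alignment to reads

Amplicons are excised from a multiple sequence alignment by alignment
coordinates (`extract_amplicons()`): the primer pair is located once on
a named reference row, and the window `[first_col, last_col]` is
applied to every row. One flanking column is included on each side
while deciding which rows truly span the window — this is what catches
insertion states sitting immediately next to a primer — and sequences
must begin at or before the widened start and end at or after the
widened end to be kept. The flanking columns are then stripped and the
window degapped. In-silico primer matching with mismatches is
deliberately out of scope: an ideal, bias-free amplification is
assumed, so results are best-case. If the widened window would leave
the alignment it is clamped to the boundary with a warning; without
clamping, windows touching the alignment edge could never yield
amplicons. Amplicons are then length-filtered; with no external
criterion to inherit we default to rejecting lengths outside 50–150%
of the median, a configurable choice that the extraction report makes
visible.

Reads follow the platform geometry exactly (`make_single_read()`,
`make_paired_read()`): a forward read is the first *X* bases of the
amplicon, a reverse read the last *X* (not reverse-complemented, since
training sequences are trimmed by the same rule — a `revcomp` option
exists); a paired read fuses the first and last *X* bases around a run
of ten `N`s, unless the amplicon is no longer than *2X*, in which case
the amplicon itself is used. Reads with more than ten ambiguous
characters — not counting the constructed spacer — are removed.
Sequencing error is intentionally not modelled; all results are
best-case for the design under study.

## The classifier

The classifier (`train_classifier()`, `classify_read()`) is the
word-based naive Bayesian classifier standard in this field. With
*N* training sequences and `n(w)` of them containing the 8-mer *w*,
the word prior is

$$P(w) = \frac{n(w) + 0.5}{N + 1},$$

and for a genus *G* with *M* sequences of which `m(w)` contain *w*,

$$p(w \mid G) = \frac{m(w) + P(w)}{M + 1}.$$

A query is assigned to the genus maximizing
$\sum_{w} \log p(w \mid G)$ over its distinct valid words (words
containing non-ACGT characters, including the paired-read spacer, are
skipped; U is read as T). Each of the bootstrap trials redraws
$\max(1, \lfloor W/8 \rfloor)$ of the *W* words with replacement and
recomputes the winner; the confidence reported for every taxon on the
assigned lineage is the percentage of trials whose winning genus lies
under that taxon. Consequently a parent's confidence is always at
least each child's, and the per-genus trial shares sum to one before
rounding.

Numerical choices worth knowing: ties between equal-scoring genera are
broken uniformly at random within the seeded stream (both for the
point assignment and inside each trial); confidences are rounded half
up to integers, because thresholds are integer percentages; per-read
seeds are derived from the batch seed and the read ID, so batches are
reproducible and permutation-stable. Internally the genus word counts
are stored sparsely — where `m(w) = 0` the log numerator is just
`log P(w)` — which keeps models cheap to rebuild many times during
cross-validation.

## Leave-k-out precision testing

Leave-one-out is too lenient for taxonomic benchmarks: the training
set usually contains further sequences of the same species. The
framework instead removes, for each test sequence, *all* training
sequences annotated with its species (`run_lko()`). Test sequences
whose species is absent from the training set need no modification and
are classified as one batch.

Reference collections are highly redundant, so training sets are first
reduced at 100% identity: identity counts every mismatch and gap, so
clusters are exact string-equality classes (`cluster_identical()`),
and within each cluster one representative is kept per genus
(`build_nonredundant_set()`) — identical sequences survive only when
they belong to different genera, preserving taxonomic information
while removing redundancy. The result is the original non-redundant
training set. Crucially, the non-redundant set is rebuilt *after* each
species exclusion from the precomputed clusters, so that when an
excluded sequence was a cluster's representative, another sequence of
the same genus (different species) takes its slot — without this the
test would be stricter than intended. Representatives are chosen by
input order, a deterministic stand-in for an unspecified upstream
convention. Because the exclusion set is a property of the species,
the package groups test sequences by species and retrains once per
species; repeats of the whole experiment differ only in bootstrap
seeds, which is the only stochastic component.

## Threshold calibration

A prediction at rank *R* is **true** when predicted and reference
names match (or are synonymous under a user-supplied map), **false**
when both carry the rank but the names differ *or* when the rank
appears only in the prediction (the sequence belongs to no currently
defined taxon there), and **neither** when the prediction lacks the
rank. The false prediction rate is

$$\mathrm{FPR} = \frac{FP}{TP + FP}.$$

TP/FP counts are accumulated in confidence intervals of size 5 —
[0–4], …, [95–99] — with confidence 100 forming its own interval
(`bin_confidences()`). For a desired FPR *e*, each non-empty interval
is tested: the binomial probability of observing at most the
interval's TP count under success probability $1 - e$ is computed, and
scanning intervals downward from 100, the first interval with
probability ≤ 0.05 fails; the interval above it becomes the threshold
(`pick_threshold()`). The choice is conservative: it holds even if
every confidence score fell into the threshold bin. If no interval
fails the threshold is 0; if the 100 interval itself fails, the
desired FPR is unattainable for that rank and region (represented as
`Inf`, printed `unattainable`, and contributing zero coverage).
Empty intervals are skipped — a bin with no predictions is no evidence
of failure, and the binomial test is undefined at *n* = 0. The
experiment is repeated (100 times at full scale) and the final
threshold is the median over repeats, taking the *larger* middle value
for even counts so the combined threshold never understates the
per-repeat ones; thresholds whose bin holds a median of fewer than 10
predictions are flagged as low-count. The default grid of desired
FPRs spans 0.001–0.95 in twelve steps; only the range is prescribed by
the framework, the intermediate values are a package choice and
configurable.

## Coverage and taxonomy gaps

Coverage at rank *R* and threshold *c* is

$$\mathrm{coverage}(R, c) = \frac{n}{S},$$

where *n* counts query sequences predicted at *R* with confidence ≥
*c* and *S* is the number of sequences with any prediction.
Taxonomic hierarchies contain gaps — phyla with no child taxa, or
lineages where only classes and genera are defined — and sequences
classified into such lineages can never receive a prediction at the
omitted ranks. The denominator is therefore corrected post hoc by
subtracting the sequences whose predicted lineage omits *R*
(`coverage()`; `ranks_omitted_below()` exposes the gap structure of a
hierarchy). Since the point assignment is always a genus lineage, the
omission can be read directly off the prediction. Additionally,
because thresholds are calibrated per rank, a sequence can pass a
fine-rank threshold while failing a coarser one; such rank-inconsistent
predictions carry a high error rate and are excluded from the
numerator. `coverage_table()` applies both rules across a calibrated
threshold table, and `fpr_coverage_curve()` pairs each desired FPR
with the coverage at its threshold, ending each curve where threshold
0 is reached.

## Combining two regions

When two regions of the same molecule are sequenced separately,
`combine_predictions()` merges the two classifications per query: the
comparison rank is the deepest rank predicted by both; the full path of
the higher-confidence prediction at that rank is copied; equal
confidence with different taxa is discarded; queries covering only one
region are skipped. An equal-confidence tie on the *same* taxon keeps
region A's path — the outcome at the comparison rank is identical
either way, and the rule is order-stable given fixed region labels.

## The synthetic benchmark generator

`fixture_spec()` describes a balanced taxonomy (fan-outs per rank) and
a sequence model: a random root sequence accumulates substitutions at
rate 0.04 per rank above genus, each genus diverges from its family
ancestor at `between_genus_divergence` (default 0.10), species at
0.03, and individual sequences at 0.005 — values chosen once to mimic
the separation scales of 16S hypervariable regions: genera clearly
separated at the word level, species close enough that same-genus
assignment is still easy, individuals nearly identical. Defaults are
250 nt sequences and a 2×2×1×2×3 hierarchy of 24 genera with 2 species
× 2 sequences each. Two stress features exercise the framework's
distinctive rules: `confusable_pairs` generates a genus directly from
its partner's sequence at a small divergence `q`, manufacturing the
genus-level ambiguity that drives thresholds up (as `q` shrinks, the
calibrated genus threshold rises — at divergence 0.04/0.01/0.002 we
observe thresholds 0/95/100 at a 5% desired FPR); and
`gap_lineage_fraction` (default 0.1) attaches genera directly under
their class, omitting order and family, exercising the coverage
correction. Insertion events (`indel_rate`, default 0.01 per root
position) add alignment columns carried by one genus clade, so
extraction must handle gapped alignments. The substitution process is
uniform per site with no rate heterogeneity, no secondary-structure
constraint and no chimeras: passing tests demonstrates the machinery's
correctness and the calibration's guarantee under its assumptions, not
classifier performance on real communities — absolute thresholds and
coverages from real reference databases will differ.

## Problem sizes and determinism

The shipped tests and the acceptance script run the framework at desk
scale, a deliberate package choice: the standard conditions are the
default fixture (96 sequences, 24 genera) with three confusable pairs
at `q = 0.01`, 20 leave-k-out repeats of 100 bootstrap iterations, and
144 query reads; the exclusion audit runs at 200 species × 2
sequences with 5 repeats. Full-scale studies would use 100 repeats
and 1000 bootstrap iterations — both are plain configuration values.
Every stage derives its seed from a single master seed
(`pipeline_config(seed = )`), and identically configured runs produce
byte-identical tables; the run manifest records the configuration and
output checksums.

## A worked run

```{r pipeline}
cfg <- pipeline_config(
  fixture = list(confusable_pairs = data.frame(g1 = c(1, 7, 13),
                                               g2 = c(2, 8, 14),
                                               q = 0.01)),
  lko = list(repeats = 10, bootstrap = 100),
  seed = 42
)
res <- run_pipeline(cfg)
subset(res$thresholds, rank == "genus" & e %in% c(0.01, 0.05, 0.5))
subset(res$curve, rank == "genus")
```

## Known limitations

Primer universality, amplification bias, sequencing error and chimeras
are outside the model, so all results are upper bounds on real-world
performance. The classifier reproduces the standard word-based
algorithm but not any specific implementation's undocumented
tie-breaking or rounding; where those were unspecified, this package's
choices are documented above and fixed. Database-specific taxonomy
reconciliation (merging hierarchies from different providers) is out
of scope — the taxonomy reader accepts any already-parsed table.
Synonym handling is an optional user-supplied map; no synonym list is
bundled.
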