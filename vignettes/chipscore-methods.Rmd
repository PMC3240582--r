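---
title: "Methods: probabilistic bin scoring, noise normalization, and promoter chromatin analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic bin scoring, noise normalization, and promoter chromatin analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

chipscore implements a complete analytic chain for short-read ChIP-seq in a
repeat-rich genome: multi-mapping-aware probabilistic scoring of the genome
in 50-bp bins, a three-step normalization ending in an empirical-FDR
reporting threshold, and the downstream promoter-chromatin analyses that
such tracks feed — feature and transposon-class score distributions,
expression-stratified metagene profiles, RNA polymerase II stalling
classification and 5-bp positioning, splice-junction occupancy profiles,
and TSS chromatin-signature clustering with a small feed-forward network
predicting expression. A synthetic-data generator with planted truth makes
every stage testable without external downloads. This vignette records the
models, the tunable parameters, and the design decisions taken where the
design was genuinely open.

## Tag scoring model

Sequencing reads only the first 35 nt from the 5' end of each precipitated
fragment, so a tag is evidence for occupancy over an *unknown* downstream
extent. Scoring uses the survival function of the fragment-length
distribution at bin resolution: with bin width $b = 50$ bp and
$w_i = \Pr(L > i\,b)$ for $i = 0..9$, a plus-strand tag whose 5' base falls
in bin $j$ adds $w_0..w_9$ to bins $j..j{+}9$; a minus-strand tag extends
toward decreasing coordinates. The bin holding the 5' base receives $w_0$
even when the tag starts mid-bin: the scheme is deliberately
bin-resolution, with no sub-bin proration. $w$ is a survival function, not
normalized to sum to one, so the total raw score of a track equals
$\left(\sum_i w_i\right) \times$ (number of contributing tag-equivalents),
up to truncation at chromosome ends — a conservation law the tests check
exactly.

The default fragment-length distribution is triangular on 100–500 bp with
mode 200 bp, a stylized mono/di/poly-nucleosome smear; any discrete
distribution can be supplied, and mass beyond the last bin is truncated
into it.

Two scoring modes handle mapping multiplicity:

* **U** — unique-mapping tags only, weight 1. Used for gene-centric
  analyses (metagene profiles, stalling), where signal bleeding between
  near-identical repeats would contaminate averages.
* **U+M** — every best-tier site of a multi-mapping tag contributes with
  weight $1/k$, $k$ the number of sites, so each tag distributes exactly
  one tag-equivalent. Used for transposon and repeat analyses, which
  unique-only scoring systematically erases.

## Read mapping

`map_tags()` performs exact best-tier Hamming search with an iteratively
relaxed allowance: round $m$ admits reads whose best hit has exactly $m$
mismatches, and iteration stops once more than 60% of input reads are
mapped (or at the 5-mismatch cap). All sites at the minimal tier are
retained — no random site selection — and $k$ is recorded. Candidate
generation uses pigeonhole trusted bands on Biostrings `matchPDict`: at
tier $m$ the read is split into $m+1$ segments, each anchored exactly with
$m$ mismatches allowed outside it, which provably sees every site with at
most $m$ mismatches; candidates are then verified by exact counting. Reads
with five or more ambiguous bases are dropped; remaining ambiguous bases
count as mismatches everywhere. Indels are not modelled: the downstream
scoring is indifferent to how sites were found, and the desk-scale
synthetic data contains no indels.

## Normalization chain

1. **Depth scaling** — every bin is multiplied by $10^7/\text{tags}$, so
   tracks read as "score per 10 million tags". Idempotent by flag.
2. **Noise normalization** — the score histograms of an experimental and a
   control track share a noise regime at low scores. The *critical value*
   is the right-most histogram crossing: the largest score cell at which
   the control count still reaches the experimental count while every
   occupied cell above is experiment-dominant. A normalizer $c$ is then
   fitted by grid search maximizing the Pearson correlation between the
   histogram of $c \cdot \text{exp}$ and the control histogram over cells
   below the critical value; the ratio $X/Y$ of the two histogram modes
   (control over experimental) centers the grid and is reported alongside.
   If the sub-critical histograms are degenerate (fewer than three occupied
   cells) the ratio estimate is used, with a warning. Histogram cell width
   defaults to Freedman–Diaconis on the control scores.
3. **Background subtraction** — adjusted score
   $\max(0,\; c\,e(b) - c_0(b))$ per bin.

Two degenerate regimes deserve mention. Identical histograms have no
crossing and are rejected as incomparable. And a library with essentially
no nonspecific background (the synthetic polII libraries are nearly pure
signal) has no shared noise floor to fit; for such pairs
`normalize_pair(c_override = 1)` skips the histogram fit, which is the
configuration the stalling analyses use.

### Empirical FDR threshold

For the reporting threshold a *null* adjusted track is built by the
role-swapped subtraction $\max(0,\; c_0(b) - c\,e(b))$ — an empirical
exchange null describing what the control says should occur by chance. For
a candidate score $s$,
$\mathrm{FDR}(s) = \#\{\text{null bins} \ge s\} / \#\{\text{exp bins} \ge s\}$.
Raw count ratios need not be monotone, so the curve is monotonized to be
non-increasing in $s$ by assigning each score the worst raw ratio at or
beyond it (a suffix running maximum); the reporting threshold is the
smallest $s$ whose monotonized FDR is below $\alpha = 0.001$ — i.e. the
smallest adjusted score beyond which the estimated FDR always stays under
the level. The suffix *maximum* is the only direction compatible with a
non-increasing curve; a suffix minimum would let a single empty null tail
cell drag the whole curve under $\alpha$ and collapse the threshold to the
smallest positive score, destroying null calibration. Bins below the
threshold are zeroed in reported output; when no score reaches the level
the threshold is undefined and nothing is reported, which is the correct
behavior on signal-free data.

The calibration guarantee is tested end to end: with control,
experimental, and held-out null tag sets all drawn from the same uniform
background over a 10 Mb genome ($5\times10^5$ tags each, ten seed
triplets), the realized fraction of held-out bins above the selected
threshold stays at or below $\alpha$ within binomial slack.

## Feature and transposon analyses

Bins are labelled exclusively under the precedence transposon/repeat >
CDS > 5'UTR > 3'UTR > intron > intergenic; a bin takes the
highest-precedence category it overlaps at all, so per-percentile
compositions sum to 100%. (A non-exclusive "windows overlapping feature"
count is a different convention; the exclusive one was chosen so
compositions form a partition.) Percentile composition sorts bins
ascending by score with ties broken by genomic order — deterministic and
invariant to positive rescaling. Transposon-class tables report both total
score and per-bp density per family; pairwise mark correlations over class
densities use Pearson's r with the t-transform p-value on $n-2$ degrees of
freedom. External windowed tracks (e.g. tiling-array scores in 1-kb
windows) are compared by ranking windows into 100 percentiles on the
external score and correlating per-percentile means; windows spanning
several 50-bp bins take the mean bin score.

## Metagene profiles

Profiles align genes at the TSS, gene-body midpoint, or TxEnd, oriented so
positive offsets are downstream on the gene strand, over ±2 kb in 10-bp
steps, stratified by rank-based expression groups (10 groups or 100
percentiles; ties broken by stable gene-id order). Per offset the mean is
trimmed: the stated trimming of 10% of genes is read as 5% per end
(configurable); a group too small to trim at least one gene per side is an
error rather than a silent no-op. Genes with multiple annotated TSSs or
TxEnds contribute the average over their anchors once. Windows truncated
by a chromosome end contribute the positions they cover. U-mode tracks are
the intended input.

## PolII stalling and positioning

Promoter score = mean adjusted polII over TSS −500 to +500 bp; body
score = mean over +750 to +2500 bp; bins claimed by more than one gene's
promoter-or-body window are excluded from every window they touch.
Stalling index SI = promoter/body, with SI = +∞ when the body is zero but
the promoter is not (such genes classify as stalled). Classes: elongating
(promoter ≥ 5, SI < 3), stalled (promoter ≥ 5, SI > 10), no polII (both
< 1), otherwise unclassified.

Read-level positioning counts tag 5' ends in 5-bp windows around anchors,
separated by tag orientation relative to the gene, each library scaled to
$10^7$ tags, reporting ChIP minus mock (positive = enrichment, negative =
depletion). **Window labelling convention:** windows are labelled by their
right edge — the "+35" window covers +30..+34 — and the modal window
breaks ties toward the anchor, an exact-distance tie taking the smaller
offset. The synthetic generator plants a footprint quoted as "+35" with
its continuous center at offset −2.5 from the label (i.e. 32.5) so the
labelled window is the modal one.

Junction profiles apply the same machinery at donor (exon→intron) and
acceptor (intron→exon) junctions, anchored at the first base after the
boundary in transcription direction; junctions within 500 bp of a TSS are
excluded so the TSS footprint cannot masquerade as junction signal.

The slowing-gene detector is explicitly an operationalization: a gene is
flagged when its ChIP/mock occupancy *ratio* in the exon-side window
[−120, −60] of its donor junctions is at least $\tau = 2$ times the same
ratio over its gene body. Ratios rather than mock-subtracted differences
anchor the criterion: for a uniformly transcribed body the subtracted
level is near zero by construction and cannot serve as a ratio
denominator. Flagged and remaining genes are compared on splice-variant
(or exon) counts by a two-sided Mann–Whitney rank-sum test with box-plot
descriptives.

## Signature clustering and the network

The signature matrix is either ten named TSS windows (per mark, mean score
over fixed strand-oriented windows such as H3K4me3 upstream −500→0) or
6 marks × 19 positions (−450→+450 bp in 50-bp steps; 114 inputs), each
feature z-standardized, zero-variance features dropped with a warning.
Clustering is plain agglomerative (correlation distance, average linkage)
cut at $k = 6$ by default; expression is displayed per cluster but never
enters the metric — the "supervised" look of ordered heatmaps is display
only.

The network is a four-layer perceptron — inputs, hidden layers of 2 then 3
logistic-sigmoid neurons, one linear output estimating expression on a
0–10 scale — trained on a seeded random half of the genes by BFGS
(`stats::optim`) on mean squared error with analytic backprop gradients,
evaluated on the held-out half, for ten independent runs. The published
analysis this mirrors does not state its accuracy metric or activations;
accuracy here is defined as $1 - \operatorname{mean}|{\hat y} - y|/10$ and
reported alongside the Pearson r, and absolute published accuracy figures
are treated as context, not targets. Input importance is Garson-style: per
input, the sum over all input→output paths of products of absolute
weights, normalized to sum to one, averaged over runs with a standard
deviation (the error bars of the importance plot). Non-finite training
losses trigger a fresh initialization, at most three times.

## The synthetic generator

`build_world()` makes a small multi-chromosome genome with:

* transposon families as mutated copies of a per-family consensus
  (per-base substitution rate $1-$identity; minus-strand copies
  reverse-complemented) — at 100% identity copies are exact duplicates,
  which is what makes multi-mapping reads a *planted*, verifiable
  phenomenon;
* genes with exon/UTR structure, splice-variant counts, and planted polII
  classes; expression drawn per class (silent genes at zero, elongating
  genes log-normally high), echoing the observation that promoter-proximal
  elongating polII marks highly expressed genes;
* a planted junction-slowing gene set carrying extra splice variants.

`simulate_mark_tags()` samples fragment 5' positions from an additive rate
landscape — background, TSS footprints, expression-scaled gene bodies,
per-family transposon affinities, and multiplicative junction bumps or
depletions — by exact inverse-CDF categorical sampling, picks strands
uniformly, draws fragment lengths, and emits 35-nt reads (constant 'I'
qualities; substitution errors only). Reads overhanging a chromosome end
are resampled. The true-origin table doubles as a tag table so score-level
analyses can bypass mapping. The elongating-class polII footprint
amplitude is derived per gene from a target raw stalling index (1.6)
against the gene's own expression-scaled body rate, keeping planted
elongation strong across the expression range; a fixed amplitude would let
low-expression elongating genes drift into the unclassifiable SI band
after background subtraction.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: realistic sequence composition and
mappability structure, PCR duplicates, paired ends, chromatin-accessibility
bias beyond an optional smooth term, antibody efficiency differences, and
indel divergence between repeat copies.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale conditions
chosen to make each recovery statistically comfortable: 10 Mb genomes with
$5\times10^5$-tag libraries for null calibration; 0.5 Mb worlds with 30
genes and $2\times10^5$ tags for footprint positioning (ten seeds); 2 Mb
worlds with 60 multi-exon genes and $10^6$-tag libraries for junction
profiles, whose signal is spread across ~170 junctions and therefore needs
a deeper library than single-window positioning; 1 Mb worlds with 60 genes
and $2\times10^5$ tags for class recovery. Categorical sampling is exact
multinomial; fixed seeds make every simulation bit-reproducible (`withr`
scoping keeps the caller's RNG state untouched). Ties are broken
deterministically throughout: genomic order in percentile ranking, stable
gene-id order in expression ranking, anchor-proximal-then-smaller in modal
windows.

## Known limitations

* Hamming-only mapping: repeat copies diverged by indels will not produce
  the multi-mapping structure they would with a gapped aligner.
* The exchange null for the FDR assumes experimental and control noise are
  exchangeable after the normalizer; strongly structured nonspecific
  backgrounds (accessibility, copy number) would need a split-control
  null, which the interface accepts as a drop-in replacement for the null
  score vector.
* The critical-value construction requires the two histograms to actually
  cross; libraries without a shared noise floor must use a fixed
  normalizer.
* WIG output emits every bin at full span, so the final bin of a
  chromosome may overhang its end by up to 49 bp.
* The network is intentionally tiny; it demonstrates signal recovery and
  importance attribution, not a competitive expression predictor.
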