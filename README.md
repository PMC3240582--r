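# chipscore

Multi-mapping-aware ChIP-seq bin scoring, noise normalization with
empirical FDR thresholding, and promoter chromatin analytics — with a
synthetic-data generator that plants recoverable truth, so the whole chain
is testable on a laptop with no downloads.

## Who this is for

Genomicists analysing ChIP-seq of histone marks, HP1a-like chromatin
proteins, or RNA polymerase II in repeat-rich genomes, where the standard
unique-reads-only treatment silently erases the transposon and repeat
compartments; and methodologists who want a fully simulated, seed-exact
test bed for tag-extension scoring, background subtraction and
promoter-state analyses.

## The model in brief

Each sequenced 35-nt tag marks the 5' end of a precipitated fragment of
unknown length. With `w[i] = Pr(fragment length > i * 50 bp)` the tag adds
`w[0..9]` to the 50-bp bin holding its 5' base and the nine bins downstream
along the read strand (toward lower coordinates for minus-strand tags).
Mapping multiplicity is handled in two modes:

* **U** — unique-mapping tags only (weight 1); used for gene-centric
  analyses,
* **U+M** — every best-tier site of a multi-mapping tag weighted `1/k`,
  so each tag spends exactly one tag-equivalent; used for
  transposon/repeat analyses.

Tracks are depth-scaled to 10 million tags, a noise normalizer `c` is
fitted from the sub-critical score histograms of an experimental/control
pair, the adjusted score is `max(0, c*exp - ctrl)` per bin, and a
reporting threshold is selected as the smallest adjusted score whose
empirical FDR — null bins over experimental bins at or above the score,
with the null built by role-swapped subtraction — stays below 0.001.

Downstream analytics: genomic-feature and transposon-class score
distributions; expression-stratified metagene profiles around TSS /
midpoint / TxEnd; polII stalling index `SI = promoter / body` with the
classes elongating (promoter >= 5, SI < 3), stalled (promoter >= 5,
SI > 10) and no-polII (both < 1); strand-resolved 5-bp positioning
histograms and splice-junction occupancy profiles; TSS chromatin-signature
clustering; and a 2-by-3-neuron feed-forward network predicting expression
with Garson weight-path importance.

## Worked example

Simulate a 1-Mb world with planted polII classes, score the libraries,
subtract the mock, and recover the classes and the stalled footprint:

```r
library(chipscore)
library(tibble)

cfg <- world_config(
  chrom_lengths = c(chr1 = 1e6), n_genes = 60, gene_length = c(4000, 8000),
  families = tibble(family = character(), n_copies = integer(),
                    length = integer(), identity = numeric()),
  class_fractions = c(stalled = 1/3, elongating = 1/3, none = 1/3))
world <- build_world(cfg, seed = 1)
world
#> <synthetic_world>
#>   chromosomes: 1 totalling 1e+06 bp
#>   genes: 60  transposon copies: 0
#>   planted polII classes: elongating 14, none 26, stalled 20

chip <- simulate_mark_tags(world, polii_model(world), n_tags = 2e5,
                           seed = 2, emit_reads = FALSE)$origins
mock <- simulate_control_tags(world$layout, n_tags = 2e5, seed = 3,
                              emit_reads = FALSE)$origins

sm <- score_matrix(frag_triangular())
sm
#> <score_matrix> bin 50 bp, w = 1 1 1 0.936 0.748 0.519 0.332 0.186 0.083 0.02

exp_track  <- depth_normalize(score_tags(chip, sm, "U", world, mark = "polII"))
ctrl_track <- depth_normalize(score_tags(mock, sm, "U", world, mark = "mock"))
adjusted   <- subtract_background(exp_track, ctrl_track, 1)

records <- classify_polii(promoter_body_scores(adjusted, world))
dplyr::count(records, class)
#> # A tibble: 3 × 2
#>   class          n
#>   <chr>      <int>
#> 1 elongating    14
#> 2 none          26
#> 3 stalled       20
```

Each count matches its planted class exactly (a gene-by-gene cross-check
gives a diagonal confusion table). The stalled footprint position is
recovered at read level:

```r
tss <- dplyr::inner_join(anchor_positions(world, "tss"),
                         world$truth$classes, by = "gene_id")
ph <- position_histogram(chip, mock, dplyr::filter(tss, class == "stalled"))
mode_offset(ph, window = c(0, 200))
#> [1] 35
```

meaning the modal 5-bp window of the ChIP-minus-mock read histogram sits
at the "+35" window downstream of the TSS — the planted stalling position.
`w` above is the survival function of the triangular 100–500 bp fragment
model: a tag always covers its own bin and the next two (fragments are at
least 100 bp), then coverage probability decays to 2% nine bins out.

For a genuinely noisy mark the full normalization chain, including the
critical value, fitted normalizer and FDR threshold, runs as
`normalize_pair(exp_track, ctrl_track)` or end-to-end from reads via
`run_mark_pipeline(world, model, n_tags, map = TRUE)`.

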