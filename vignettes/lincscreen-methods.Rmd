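---
title: "lincscreen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincscreen: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
package, the meaning and rationale of every default parameter, what the
synthetic generators emulate (and deliberately do not), and the design
decisions a reader should know before trusting or extending the code.

# Coordinates and file formats

All intervals inside the package are `GenomicRanges::GRanges`, i.e.
**1-based, closed** coordinates — the universal Bioconductor convention.
Conversion to and from external conventions happens exclusively at the I/O
boundary, in `R/io.R`, delegated to `rtracklayer`:

* GTF is 1-based closed on disk, so `read_gtf()`/`write_gtf()` pass
  coordinates through unchanged; only `exon` features are kept and each
  transcript is validated to live on one chromosome and one strand.
* BED and bedGraph are 0-based half-open on disk; `rtracklayer` shifts them
  at import/export. A BED line `chrI 0 100` becomes `chrI:1-100`.
* Wiggle `fixedStep`/`variableStep` and bedGraph dialects are sniffed from
  the first data line by `read_scores_wig()`.

Choosing the native convention of the substrate (rather than carrying a
0-based convention through an ecosystem built on 1-based ranges) eliminates
the largest class of off-by-one bugs; the invariant that matters —
*conversion only at the boundary* — is preserved.

# Annotation arm

## Locus assembly

`merge_across_libraries()` concatenates per-library transcript calls and
groups transcripts whose exons overlap by ≥ 1 bp on the same strand
(unstranded calls match either strand), taking the transitive closure via
graph components. Each locus's exon model is the union (`reduce`) of member
exons; a locus is *multi-exonic* when the union has more than one block.
Library support is the number of distinct source libraries among members.
The locus strand is the unique stranded value among members, else `*`.

## Filters

A locus survives only if (defaults in parentheses):

1. **Coding potential** — *every* member transcript has CPC score strictly
   below 0 and CPAT score strictly below 0.403. Both cutoffs are exclusive:
   a CPAT score of exactly 0.403 is coding. The 0.403 value is the
   published CPAT operating point for a genome of this size; strictness at
   the boundary is part of the contract and is pinned by tests.
2. **Size** (`min_len = 200` nt) — summed exonic length strictly greater
   than 200 nt ("long" in lncRNA). `length_mode = "span"` switches to
   genomic extent for sensitivity analyses.
3. **Intergenicity** — no overlap with any annotated gene on either strand,
   and ≥ 50 nt (`min_same_strand_dist`) of clear sequence to the nearest
   same-strand gene. Distance counts bases strictly between the features.
   Unstranded loci cannot be tested against "same-strand" neighbours and
   face only the overlap rule.

## CAGE orientation

`cluster_cage()` chains same-strand tag positions with gaps ≤ 25 nt
(`merge_dist`), discards clusters with fewer than 2 reads (`min_reads`),
and records each cluster's summit — the deepest tag position, ties broken
to the 5′-most position on the cluster strand. `orient_monoexonic()` then
assigns a strand to unstranded mono-exonic loci from the nearest summit
within 100 nt (`max_summit_dist`; distance 0 if the summit falls inside the
locus). When the two nearest summits are equidistant but on opposite
strands the locus is left `"ambiguous"` rather than guessed.

## Sequence features

GC content is `(G+C)/(A+C+G+T)` over the reduced interval set, so
ambiguous bases drop out of the denominator. The metagene profile splits
each spliced locus sequence 5′→3′ into 10 equal windows (remainder bases go
to the last window so the windows exactly partition the sequence) and
summarises per-window GC across loci by the 5th/50th/95th percentiles; the
baseline is GC over 500-bp flanks. Conservation summaries are
width-weighted means of a per-base score track over exonic bases, `NA`
where nothing is covered. Group comparisons use `stats::kruskal.test`
(with an optional label-permutation p-value) plus a Bonferroni multiplier.

# Permutation enrichment

`test_enrichment()` asks whether query intervals overlap an annotation more
(or less) than expected when each query interval is placed uniformly at
random inside the workspace, *preserving its length* and staying inside a
single workspace segment (segments chosen with probability proportional to
their number of valid start positions). The statistic is total base-pair
overlap (`"bp"`, default) or the number of overlapping query intervals
(`"count"`). The workspace is flattened to one axis and the annotation
indicator cumulative-summed once, so each permuted interval's overlap is
two array lookups; 10⁴ permutations on a megabase workspace are cheap.

Empirical p-values use the add-one estimator
`(1 + #{permutation ≥ observed}) / (1 + n_perm)` — never exactly zero — and
both tails are computed; the reported `p` is the smaller tail with its
direction. Note that the *minimum* of two dependent tails is not a
calibrated quantity (its null distribution is not uniform); calibration
statements should be made on a single tail (`p_enriched`/`p_depleted`), and
that is what the package's own calibration test asserts. When both observed
and expected are zero the result is `fold = 1, p = 1`: nothing can be
concluded from an empty comparison.

# Imaging arm

The counting procedure models a backlit plate: dark animals on a bright
field, filmed at 1 Hz after agitating the plate so everything moves.

1. **Background**: pixelwise *maximum* projection of the first 15 frames.
   Any pixel an animal vacates at least once shows pure background in the
   projection, so moving animals are erased.
2. **Difference images**: `background − frame`, clipped at zero (animals
   are darker than the field).
3. **Threshold**: Otsu's method on the pooled difference images of the 10
   counting frames (one shared threshold, not one per frame, so frame
   counts are comparable).
4. **Components**: 8-connected labeling. `EBImage::bwlabel` is 4-connected,
   so the package merges 4-connected labels that touch diagonally (a
   vectorized label-pair union) to get exact 8-connectivity.
5. **Count**: components of ≥ 10 px (`min_area`) per frame; the plate count
   is the statistical mode of the 10 per-frame counts, ties broken to the
   larger count (touching animals merge components, so undercounting is the
   common error mode).

`detect_all()` runs the same pipeline per frame and emits centroid, area
and length per detection. Length is the extent of the component along its
principal axis (first eigenvector of the pixel covariance). A true
centerline length would require skeletonization, which no installed package
provides; for near-straight worm shapes the principal-axis extent equals
the centerline length, and this choice is documented rather than hidden.

## Tracking

`link_tracks()` associates detections frame-to-frame by minimum-cost
assignment on centroid distances. The assignment itself, `lap_solve()`, is
an exact O(n³) Hungarian solver in shortest-augmenting-path form, written
in the package because no linear-assignment solver is installed — and
verified in tests against exhaustive permutation matching. Pairings
farther than `max_link_dist` (20 px) are refused by padding the cost matrix
with dummy nodes at that cost: a refused detection starts a new trajectory.
A trajectory undetected for more than `max_gap_frames` (0) consecutive
frames is closed, so brief occlusions can be bridged by raising the gap.

# Growth and phenotype statistics

`growth_curve()` implements the windowed estimator for long recordings:
each animal's attribute is averaged within consecutive 20-min windows
(`w = 1200` s), and the population curve is the *unweighted ensemble mean
across animals* with its SEM — so an animal sampled 1000 times counts the
same as one sampled 10 times, which is the correct weighting when sampling
density varies per animal.

`combine_curves()` pools strains that match a designated standard: with the
default `"pointwise"` criterion a strain combines when its curve lies
within the standard's `mean ± z(1 − α/2)·SEM` band at *every* shared window
(α = 0.01). This is deliberately strict — the band shrinks as the standard
cohort grows, so with many animals even biologically identical strains may
fail occasionally; it guarantees that anything pooled is indistinguishable
from the standard at the resolution the data support. The alternative
`"ztest"` criterion (per-window two-sample z-tests, Bonferroni-corrected
across windows) is the forgiving version. `length_ratio_at()` reports the
windowed attribute ratio to a control at a chosen time (default 50 h) with
a t-interval over per-animal ratios.

Brood statistics: totals are the sum of three daily counts, censored
animals (crawled off) are dropped; each strain is compared to the control
by a two-sample Student t test (`var_equal = TRUE`; Welch via flag),
Bonferroni-corrected over the strains tested, significant at corrected
p ≤ 0.05. Effects are reported as mean ratios to the control mean with
t-intervals, and `effect_comparison()` classifies knockout vs RNAi arms by
whether each CI excludes 1 and whether the CIs overlap. The classification
is symmetric under swapping the arms. `delta_ct()` implements ΔΔCt qPCR
quantification with replicates paired by index and fold change `2^−ΔΔCt`.
Wherever replicate spread is exactly zero (possible in noiseless synthetic
fixtures) confidence intervals degenerate to `[mean, mean]` instead of
erroring.

# Synthetic data: what is and is not emulated

All generators derive their randomness from a root seed through
`child_seed(seed, tag)` — a fixed affine hash — so adding or reordering
generator calls never shifts another generator's stream, and every output
is reproducible from one integer.

**Toy genome** (`gen_genome`): 2 × 100-kb chromosomes with 30 coding genes
and 20 true intergenic lncRNA loci (8 multi-, 12 mono-exonic), placed
without overlap and with ≥ 100-bp gaps (comfortably above the 50-nt
distance filter, so planted loci survive it by construction). Sequence GC
follows region class (exon 0.42 > lncRNA exon 0.38 > intron 0.33 >
intergenic 0.30) and per-base conservation is Normal with mean 2 in coding
and multi-exonic-lncRNA exons and 0 elsewhere (SD 0.5) — a caricature of
the empirical gradients, sufficient to exercise the feature code, not a
model of any real genome.

**Library calls** (`gen_library_calls`): each locus has a log-normal latent
FPKM; each of 20 libraries detects it with probability
`expr/(expr + 0.5)`, reports the exact exon model when detected, and draws
an observed FPKM around the latent value. Mono-exonic calls carry no
splice junction and are therefore emitted unstranded — recovering their
strand is exactly the CAGE step's job. False-positive mono-exonic
fragments are injected over coding genes at `fp_rate = 0.2` per gene per
library *with non-coding scores*, so only the intergenic filter can remove
them; they stay within 80 bp of their gene so that a spurious call hugs the
gene that spawned it rather than bridging between neighbours. Not
emulated: assembly fragmentation of true loci, chimeric models, expression-
dependent boundary noise.

**CAGE** (`gen_cage`): 5 tags per true TSS with 3-bp Gaussian jitter on the
locus strand, plus 200 uniform single-read noise tags. Noise tags can, by
chance, form ≥ 2-read clusters — mis-orientation by a noise cluster is a
real failure mode of the method and is left in.

**Plate videos** (`gen_video`): worms are dark capsules (12 × 3 px) on a
bright field (levels 60 vs 200, Gaussian pixel noise SD 4), doing a
persistent random walk (3 px/frame step, heading SD 0.25 rad/frame,
reflecting walls) in a 320 × 320 arena at 1 Hz. The geometry emulates the
brood-size counting scenario — many small L1 progeny at low magnification —
where occlusion is rare. Animals *can* still touch and merge into one
component for several frames; with large or dense animals this breaks any
connected-component counter, which is a physical limit of the method, not
of the implementation. A spec requesting > 50 % arena coverage is refused
as a capacity error rather than silently degraded. Not emulated:
self-coiling postures, egg clusters, lighting gradients, lens distortion.

**Growth cohorts** (`gen_growth_cohort`): per-animal logistic area
`K/(1 + exp(−r(t − t_mid)))` sampled every 60 s for 65 h, with 5 %
between-animal variation in asymptote and midpoint and 5 % multiplicative
observation noise; length is `3.5·√area` (constant aspect ratio). Not
emulated: molts, lethargus pauses, tracking dropouts.

**Brood tables** (`gen_brood`): daily progeny counts over three 24-h
intervals from a negative binomial (variance `μ + 0.05 μ²`; overdispersion
0 recovers Poisson), day split 45/40/15 % (early-peaked laying), 10 %
censoring.

# Numerical choices

* Empirical p-values always use the add-one estimator; permutation streams
  are seeded through `child_seed` and recorded in the result object.
* The Hungarian solver maintains dual potentials in double precision;
  `Inf` encodes forbidden pairings and infeasibility is an error, not a
  silent drop.
* Otsu thresholds are computed after min–max normalization (EBImage expects
  `[0, 1]`) and mapped back to the original scale.
* Mode-of-counts ties break upward because component merging biases counts
  downward.
* `findInterval`-based windowing puts a sample at a window boundary into
  the window it starts (left-closed windows).

# Limitations

* The annotation arm trusts its inputs' transcript models; it does not
  re-assemble or split chimeric transcripts.
* The enrichment null places intervals independently; clustered queries
  violate that independence, and p-values are then anti-conservative.
* Counting accuracy degrades with persistent animal contact (large/dense
  animals); the tracker links by centroid distance only and does not
  resolve identity through long occlusions.
* The principal-axis length underestimates the centerline length of bent
  animals.
* Synthetic generators are validation instruments: they make the planted
  truth recoverable and the failure modes visible, but none of them is a
  calibrated model of real microscopy or sequencing data.
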