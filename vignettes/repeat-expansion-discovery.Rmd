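---
title: "Catalog-free repeat-expansion discovery: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalog-free repeat-expansion discovery: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irrscan)
```

## The problem

Pathogenic short-tandem-repeat (STR) expansions are frequently longer
than a sequencing read. A read drawn entirely from inside such a repeat
carries no unique sequence, so the aligner either leaves it unplaced or
drops its mapping quality to ~0. Catalog-based genotypers recover these
reads only at loci they were told about; expansions at novel loci, or
with motifs absent from the reference genome, are invisible to them.
`irrscan` turns the alignment failure itself into signal: poorly
mapped reads are classified by their sequence content alone, and the
genomic placement comes from their confidently mapped mates.

## Single-read model

A read $r$ of length $L$ is tested for periodicity with

$$S(k) = \frac{1}{L-k}\sum_{i=0}^{L-k-1} \mathbf{1}[r_i = r_{i+k}],$$

evaluated for $k = k_{\min},\dots,k_{\max}$ in increasing order; the
first $k$ with $S(k) \ge t$ is taken as the period. Base comparison is
case-insensitive and `N` matches nothing, including another `N` — an
uncalled base can only lower the score. The repeat unit is the
consensus base at each offset modulo $k$ (`N` excluded from the counts;
ties broken $A<C<G<T$), reduced to its canonical form: the
lexicographic minimum over all rotations of the unit and of its
reverse complement, which removes the strand and phase ambiguity of a
unit read out of an arbitrary position on an arbitrary strand.

The unit is then validated by a weighted purity (WP) score comparing
the read against the tandem concatenation of the unit: a high-quality
match scores $+1$, a high-quality mismatch $-1$, and any low-quality
base $+0.5$; the sum is clamped below at $0$, divided by $L$, and
maximized over the $k$ possible phases. Low-quality mismatches are
deliberately cheap because base-calling error rates rise inside long
low-complexity tracts; a read should not be rejected for errors the
sequencer itself flagged. The exact per-base weighting is a design
choice of this package (the quality-weighted match/mismatch scheme
above); it is isolated in `weighted_purity()` and configurable through
`detection_params()`.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `k_min`, `k_max` | 2, 20 | repeat-unit lengths searched (bp). Unit length 1 is excluded: homopolymer tracts are vastly abundant and would swamp the profiles. A homopolymer read is attributed to the 2-bp unit. |
| `t` | 0.8 | periodicity threshold; tolerates interruptions and sequencing errors in the tract |
| `wp_threshold` | 0.9 | minimum weighted purity for an IRR call |
| `low_quality_cutoff` | Phred 20 | below this a base is "low quality" in WP |
| `irr_mapq_max` | 40 | only unaligned reads or reads with MAPQ strictly below this are IRR-eligible |
| `anchor_mapq_min` | 50 | a mate must map at or above this to anchor an IRR |

Raising `irr_mapq_max` to above the aligner's maximum and lowering
`anchor_mapq_min` to 0 makes every pair eligible, at a proportional
runtime cost.

### A known blind spot: internally periodic long motifs

Because the *smallest* qualifying $k$ wins, a long unit whose tandem
repeat has a strong sub-periodicity is attributed to the shorter
period. The dodecamer `CCCCGCCCCGCG`, for example, satisfies
$S(5) = 0.834 \ge t$ on a pure tract, so its reads are assigned period
5; the 5-mer consensus then matches only ~83% of bases and the read
fails the 0.9 purity gate entirely. Long motifs are therefore
detectable only when no $k$ below the unit length reaches $t$. The
package's tests exercise 12- and 20-bp motifs without such internal
structure.

## From reads to profiles

Only read pairs in which at least one mate is unmapped or has
MAPQ < 40 are examined (`stream_candidate_pairs()`); confidently
mapped pairs cannot contain an IRR and are discarded at streaming
time, which is what makes a genome-wide scan cheap. Each candidate
pair is classified (`classify_pair()`):

* **paired IRR** — both mates are IRRs with the same canonical motif:
  evidence for a repeat longer than the fragment length, counted per
  motif only, because a genome with several long repeats of the same
  motif makes the pair's origin ambiguous;
* **anchored IRR** — exactly one mate is an IRR and the other maps
  with MAPQ ≥ 50: recorded at the *anchor's* position (the IRR's own
  coordinates are ignored as unreliable);
* anything else — including two IRRs with *different* motifs, on which
  the method is deliberately conservative — is dropped.

Anchors of one motif within 500 bp of one another (single linkage on
anchor start positions) merge into a region; a single repeat scatters
its anchors over roughly a fragment length, so 500 bp comfortably
groups them without bridging distinct loci. Profiles store raw integer
counts plus the sample's mean depth; normalization to a nominal 40×
($\mathrm{count} \times 40/\mathrm{depth}$) is deferred to the cohort
merge so a profile remains reusable if the depth estimate is revised.

At the cohort merge the per-sample regions are pooled per motif and
re-merged with the same gap rule (here the gap is measured between
region envelopes), and every sample receives a count in every merged
region — zero when absent, which is the informative case for controls.
Profiles built with different detection parameters refuse to merge;
for the same reason, all samples of a comparison should come from the
same aligner and comparable library preparation.

## Prioritization

**Case-control** (`case_control_analysis()`): a one-sided Wilcoxon
rank-sum test per region (locus method) or per motif's paired counts
(motif method), alternative "cases stochastically greater". The exact
null distribution is used for tie-free samples with $n+m \le 12$,
otherwise the normal approximation with tie and continuity correction.
Raw p-values are reported first-class, with Bonferroni adjustment over
the tested targets alongside; rank order is the primary output, as the
target use case is candidate generation for targeted follow-up, not
genome-wide significance claims.

**Outlier** (`outlier_analysis()`): for heterogeneous cohorts where no
single locus is expected to recur. The sampling distribution of the
cohort's 95% quantile is bootstrapped ($B = 1000$ resamples with
replacement, linear-interpolation quantile, mandatory seed); a case
whose count exceeds the bootstrap mean $\mu_q$ scores
$z = (\mathrm{count}-\mu_q)/\sigma_q$, with $\sigma_q$ the bootstrap
standard deviation — a pragmatic spread estimate that is exactly as
resolvable as the bootstrap itself. Cases at or below $\mu_q$ are
omitted; a degenerate bootstrap ($\sigma_q < 10^{-9}$) with a count
above $\mu_q$ yields $+\infty$, which sorts first. A region's
statistic is the **maximum** case $z$ — the method hunts single
extreme samples, and a max is the matching summary (a mean-z variant
would dilute one true outlier among unaffected cases).

Ranking ties break deterministically: larger total case count first,
then lexicographic target id.

### Small-cohort behavior of the quantile bootstrap

By default the bootstrap resamples the full cohort, matching the view
of the cohort as "the dataset". This is sound when cases are a small
fraction of it: at 1 case in 21 samples the case can barely influence
the 95% quantile. But when cases exceed the quantile's tail mass —
e.g. 5 shared-expansion cases in 25 samples, 20% of the cohort — the
quantile lands *inside* the case counts, $\mu_q$ rises to meet them,
and the shared signal masks itself. For such designs
`outlier_params(controls_only = TRUE)` resamples only the controls,
restoring the intended "case versus background" comparison; the
package's multi-case tests use it, and it is the recommended setting
whenever shared expansions among several cases are plausible in a
small cohort.

### Filters

`filter_cohort()` composes the standard restrictions: motif length
range (e.g. 2–6 bp, where most known pathogenic motifs live), overlap
with user-supplied BED intervals extended by a flank (e.g. ±5 kb
around exons of genes of interest; boundary contact of half-open
intervals counts as overlap), and raw-count minima per target in at
least one sample (≥5 anchored / ≥5 paired is a sensible
high-confidence cut, corresponding to repeats of roughly 150–200 bp
and beyond).

## The simulator

`build_haplotype()` assembles left flank + repeat tract + right flank;
tracts are ordered motif segments, so complex non-reference
compositions (an `AAGGG` tract replacing a reference `AAAAG` repeat,
say) are one segment list. Flanks are drawn from a uniform base model
and rejection-checked so no 150-bp window is itself periodic — the
flank cannot generate IRRs.

`simulate_read_pairs()` draws fragment starts uniformly, fragment
lengths from Normal(450, 50) truncated below at the read length (the
sd is a library-prep-typical choice), and extracts 2×150 bp mates at
20× coverage with a 0.1% uniform substitution error rate; error bases
get Phred 10, everything else Phred 30, so the purity score sees
realistic quality structure. Everything is deterministic given the
seed.

`emulate_alignment()` replaces a real aligner with a deterministic
rule: ≥ 30 bases outside the tract → mapped at the true position with
MAPQ 60; otherwise MAPQ 0 at the repeat start (or unmapped on
request). Positions are projected onto coordinates in which the tract
has its *reference* length, so samples with different expansion sizes
share a coordinate frame, as they would after alignment to a common
reference. The downstream stages consume only MAPQ, flags and
positions, so this emulation exercises the full pipeline;
`write_fastq()` is the escape hatch for users who want a real aligner.
What the emulation does **not** model: mapping ambiguity from genomic
repeat families, reference STRs partially absorbing reads at the
boundary, GC/PCR coverage bias, and indel errors. Passing tests
demonstrate the statistical machinery on clean signal; real data adds
aligner- and library-specific noise on top.

## Problem sizes used in the test suite

The suite runs entirely on simulated loci of 1-kb flanks around
0–1020 bp tracts at 20× (the package's baseline design): a
case-control analog with 14 cases sharing a 900-bp expansion versus 30
controls over 5 loci; outlier analogs with 1 case (and a 5-case
variant) versus 20 controls over 13 polymorphic loci across 10 seeds;
null calibration of the Wilcoxon stage over 1000 i.i.d. regions at 20
cases / 20 controls; and a 10,000-motif canonicalization sweep. These
sizes keep every property measurable with comfortable statistical
margins while the whole suite completes in a couple of minutes.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally and in JSON/TSV
  outputs; region strings render as `contig:start-end`.
* MAPQ 255 ("unavailable") is treated as anchor-eligible; duplicate
  and secondary/supplementary records are excluded (duplicates can be
  kept with a flag).
* Quantiles use linear interpolation (R type 7).
* Short reads ($L \le k_{\min}$) and empty inputs yield "no call" /
  empty profiles rather than errors; `S(k)` with $k \ge L$ is an
  error because its denominator vanishes.
* The Wilcoxon stage switches from the exact distribution to the
  corrected normal approximation at $n + m > 12$ or on ties.

## Limitations

* Repeats shorter than the read length are out of reach by
  construction; the 120-bp pathogenic cutoff of the Huntington repeat
  sits below a 150-bp read, and such loci are better served by
  catalog-based genotypers.
* Internally periodic long motifs can be invisible (see above).
* Motif-method hits are not localizable; the origin of paired IRRs is
  inherently ambiguous.
* No repeat-length genotyping: counts correlate with length but the
  intended workflow is discovery here, sizing with a targeted caller
  afterwards.
* The outlier z is a ranking score, not a calibrated tail
  probability.
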