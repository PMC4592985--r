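---
title: "Methods: GC_syn, GC binning, and the decomposition of regional GC-content change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC_syn, GC binning, and the decomposition of regional GC-content change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsyn)
```

## The statistic and the model

Every amino acid is encoded by one to six synonymous codons, and those
codons differ in how many of their three bases are G or C.  The package is
built around a single per-amino-acid parameter,

$$\mathrm{GC}_{syn}(aa) \;=\; \frac{\#\{\text{G/C bases over all synonymous
codons of } aa\}}{3 \times \#\{\text{codons of } aa\}},$$

the unweighted G+C fraction of an amino acid's codon repertoire.  Under the
standard nuclear code it ranges from $1/9$ (Ile) to $10/12$ (Ala, Gly,
Pro), and the twenty amino acids separate into three clusters: four
high-GC$_{syn}$ (Ala, Gly, Pro, Arg), five low (Tyr, Phe, Asn, Ile, Lys),
and eleven intermediate.  Trp ($2/3$) and Met ($1/3$) sit midway between
clusters; because each has a single codon and behaves like the
less-variable amino acids in usage, they are assigned to the intermediate
group.

```{r}
prof <- gc_syn_profile()
table(prof$group)
range(prof$gc_syn)
```

The scientific question the rest of the machinery addresses is how regional
GC-content structures codon and amino-acid usage: coding sequence is cut
into analysis units (50-codon windows by default, whole CDS, or per-genome
codon pools), units are sorted into 0.01-wide GC bins spanning 0.30–0.80,
and per-bin usage frequencies over the 61 sense codons (and the 20 amino
acids) are compared across bins.

## Group cut-points

No numeric thresholds separate the three GC$_{syn}$ clusters in the
underlying analysis tradition; the clusters are read off the sorted values.
The package fixes cut-points at $0.25$ and $0.70$ (`low` $< 0.25 \le$
`intermediate` $\le 0.70 <$ `high`), which reproduces the 4/11/5 partition
with Trp and Met intermediate and leaves a wide margin on both sides of
every observed value (nearest values: 1/6 and 1/3 around the low cut, 2/3
and 13/18 around the high cut).  A non-standard code whose GC$_{syn}$
lands exactly on a cut-point raises an error rather than guessing.

## Preparing coding sequence

`read_cds()` drops records with ambiguous bases and, given a
transcript-to-gene map, keeps the longest CDS per gene.  `prepare_codons()`
then excludes the leading start codon (the first Met) and the trailing stop
from every CDS — start and stop codons are constrained by translation, not
by composition — while internal ATG codons are retained as Met.  Records
whose length is not a multiple of 3, that lack a leading ATG, or that
contain an internal in-frame stop are dropped, not truncated, and counted
in a filter report; silently repairing a broken reading frame would
contaminate the codon stream with out-of-frame triplets.  A missing
trailing stop is tolerated (truncated annotations are common) and the
record is kept.

These exclusions are applied *before* windowing, so windows, whole CDS and
genome pools all share one codon stream, and every unit's GC-content is
computed over exactly the codons that are counted.  This makes the
usage-weighted reconstruction identities exact: the codon-frequency-weighted
GC of a bin always lies inside the bin's bounds, and the decomposition
below conserves totals to machine precision.

## Binning

Bins are half-open $[lo, hi)$ with the top bin closed at the range end, so
the full range partitions cleanly; a relative tolerance absorbs the
floating-point representation of edges (0.31 lands in the 0.31–0.32 bin,
never below).  Units outside $[0.30, 0.80]$ are excluded, following the
observation that almost no real coding windows fall outside that range.
Binning on third-position GC (GC3) instead of all positions is a
configuration switch (`gc_mode = "third_position"`); the GC3 range is
configurable because reasonable presets differ (the 0.06–0.32/26-bin preset
is supported without asserting its generality).

Bins with fewer than `min_codons` pooled codons (default 1000) are flagged
*low-confidence*.  Trend fits exclude flagged bins by default, and not only
because their frequencies are noisy: tail bins are populated by the
selection tails of the unit-GC distribution, so their usage reflects the
adjacent dense region while their x-coordinate is extreme.  During
development this one-sided truncation measurably steepened fitted trends
(about 2–3% slope inflation in recovery experiments); excluding flagged
bins removes most of it.  For the same reason the parameter-recovery test
generates its GC grid one step beyond the fitted bin range, so boundary
bins are fed symmetrically from both sides.

## Trends, pairwise regressions, and tests

Per-amino-acid trends are ordinary least squares of usage frequency on the
bin's **mean** GC (the average GC of member units, not the bin midpoint —
the bin's empirical x-coordinate), with intercept.  Usage is compositional,
so the twenty slopes sum to zero up to fit error; a numerically flat usage
series is reported as slope 0, $R^2$ 0 by convention.

The pairwise engine regresses the usage vector of one bin on another
(lower-GC bin on x), for every GC-N pair — bins whose indices differ by
$N$, enumerated as sliding pairs $(1, 1+N), \dots, (B-N, B)$.  GC-nearest
means $N = 1$: 49 pairs for 50 bins.  A non-overlapping variant
($(1,2), (3,4), \dots$) is available behind a switch for comparison with
presentations that enumerate disjoint pairs.  Slope and intercept are
computed in closed form and $R^2$ is the squared Pearson correlation, so
the identical-bin limit is exact: slope 1, intercept 0, $R^2$ 1.  Means of
slope and $R^2$ per $N$, plotted against the mean GC difference, summarise
how usage profiles diverge as bins grow apart; one-sample (against the
no-divergence null of 1) and paired t tests are provided for comparing
$R^2$ sets, with zero-variance inputs flagged rather than erroring.

## The decomposition

For one amino acid between a low-GC and a high-GC bin, write $A$ for its
usage and $\overline{\mathrm{GC}}_{syn}$ for its *observed* (usage-weighted)
synonymous-codon GC in each bin.  Its contribution to the regional
GC-content change splits exactly:

$$\Delta \mathrm{GC} \;=\; A_h\overline{\mathrm{GC}}_{syn,h} -
A_l\overline{\mathrm{GC}}_{syn,l} \;=\;
\underbrace{\Delta A \times \overline{\mathrm{GC}}_{syn,h}}_{\text{amino-acid
usage}} \;+\;
\underbrace{\Delta \overline{\mathrm{GC}}_{syn} \times A_l}_{\text{synonymous
codon choice}}.$$

The identity is algebraic — there is no residual term for any input, which
the tests verify on $10^4$ random quadruples at $10^{-12}$.  Summed over
all twenty amino acids, $\sum \Delta \mathrm{GC}$ equals the difference of
the bins' codon-weighted GC-contents exactly, and that sum is the default
denominator for the percentage contributions.  The default reported subset
is the four high-GC$_{syn}$ amino acids (a conservative accounting of the
GC gain); the AT-direction mirror (complement every GC fraction, swap the
bins, default subset the five low-GC$_{syn}$ amino acids) is
`at_decomposition()`.  Report output rounds to 3 decimals; internal
arithmetic is unrounded.

```{r}
dec <- gc_decomposition(a_low = 0.042, a_high = 0.204,
                        gcsyn_low = 0.727, gcsyn_high = 0.973, aa = "Ala")
round(dec$effect_aa + dec$effect_syn - dec$d_gc, 15)
```

## The random-sequence control

`random_seq_spec()` describes the built-in null model: i.i.d. DNA with
$P(G) = P(C) = g/2$, $P(A) = P(T) = (1-g)/2$ for targets $g = 0.30, 0.31,
\dots, 0.80$, 10,000 sequences per target with lengths uniform on
1200–1500 bp — the study conditions for the control.  Sequences are read
in frame 0 and treated whole (not windowed); realised stop codons stay in
the codon stream but are excluded from usage counts, with frequencies
renormalised over the 61 sense codons.  Units are binned by **realised**
GC, exactly as real data would be, not by their target.

The closed-form oracle for this model is
`expected_codon_usage_random()`: a codon with $k$ G/C bases has probability
$(g/2)^k((1-g)/2)^{3-k}$, renormalised over sense codons.  At $g = 0.5$
every sense codon has frequency $1/61$, so high-group usage is $18/61$,
low-group $11/61$.  `random_usage_table()` streams the control straight
into per-bin counts without materialising strings; it consumes the RNG
identically to `random_sequences()`, so the two agree sequence-for-sequence
under a fixed seed.

Run at full scale, the adjacent-bin 61-codon regressions of this control
give a mean $R^2$ measurably below 1 — multinomial sampling noise plus
genuine within-bin GC heterogeneity — where real coding sequence sits much
closer to 1.  The control demonstrates what "no biology, composition only"
looks like in this pipeline.

## What the synthetic CDS generator does and does not emulate

`usage_model_linear()` prescribes amino-acid usage linear in the target GC
$t$ with slopes summing to zero (defaults: the four high-GC$_{syn}$ amino
acids rise by $+0.54$ in total per unit GC, the five low ones fall by
$-0.40$, the intermediate eleven drift slightly — magnitudes resembling
real coding sequence).  Within each amino acid, synonymous codons are
weighted as i.i.d. DNA at an auxiliary GC value solved by `uniroot()` (to
$10^{-10}$) so the codon vector's implied GC equals $t$; the prescribed
slopes are therefore slopes against the sequence's own GC-content and are
directly comparable to the pipeline's fits.  `cds_from_usage_model()`
samples multinomial CDS from the model, wrapped in ATG ... stop.

What passing recovery tests shows: the segmentation, binning, usage
counting and regression stages jointly estimate a known usage-vs-GC law
without material bias at realistic effect sizes.  What it does not show:
real CDS are not i.i.d. codon strings — no codon autocorrelation, no gene-
or lineage-specific bias, no expression-linked selection, no isochore
structure.  Conclusions about real genomes require real genomes.

## Numerical choices and problem sizes

* Bin edges: half-open, top bin closed; edge tolerance `step * 1e-6`.
* Flat-usage convention in trend fits: a usage series whose range is below
  $10^{-12}$ of its magnitude is slope 0, $R^2$ 0, p `NA` (absorbs
  ulp-level noise from frequency normalisation).
* Degenerate pair regressions: zero variance on x yields a flagged `NA`
  slope; zero-variance t tests report $t = 0$ (mean at null) with p `NA`.
* Statistical checks against the analytic oracle compare ensembles of
  standardised deviations (mean and spread) across bins, and apply hard
  per-codon 3-SE bounds only within a single best-supported bin: the
  maximum of hundreds of independent z-scores exceeds 3 routinely by pure
  order statistics, so a max-bound across all cells would reject a correct
  implementation.
* Test problem sizes are scaled to what the checks need: the full-scale
  control (51 × 10,000 sequences) runs once for the adjacent-bin $R^2$
  summary; recovery experiments use 45 targets × 70 CDS of 1500–2100
  codons; oracle-agreement checks use 9 targets × 3000 sequences.

## Known limitations

* The genome analysis unit pools *prepared CDS codons* per genome label;
  genomic GC including non-coding sequence is not computed from annotation
  (a separately computed genome GC can be supplied through the group
  labels workflow by binning on externally chosen labels).
* The three-group assignment is by fixed cut-points; exotic genetic codes
  may produce partitions in which the high/intermediate/low vocabulary is
  strained, and single-codon amino acids are always border cases.
* Usage tables require enough codons per bin to be meaningful; the
  low-confidence machinery flags but does not repair sparse bins.
* p-values from per-amino-acid trend fits are conditional on the binning
  and are not adjusted for the twenty parallel fits.
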