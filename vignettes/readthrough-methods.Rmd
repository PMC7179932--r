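---
title: "Detecting 3'UTR extensions and transcription read-through with utrx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 3'UTR extensions and transcription read-through with utrx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrx)
```

## The problem

Transcription termination deposits the 3' end of an mRNA at a defined
cleavage/polyadenylation site. When termination is impaired — as in plant
mutants of THO/TREX-complex components — polymerase continues past the site
and polyA+ RNA-seq coverage extends into the normally untranscribed
intergenic region. `utrx` quantifies this read-through genome-wide from
strand-specific coverage, decides which genes gain a 3'UTR extension in
which genotype, asks whether affected genes have unusual polyadenylation
signals, and evaluates the locus-level qPCR assay used for validation.

## Coordinate model

Internally every feature is 0-based, half-open; GFF3 (1-based inclusive)
and bedGraph (0-based half-open) are converted at the I/O boundary only.
Each gene's termination site (TTS) is its annotated 3' end. The search
space for an extension is the intergenic interval anchored at the TTS,
oriented along transcription, and truncated at the nearest annotated gene
boundary **on either strand** or the chromosome end: a called extension
must never enter an annotated gene body, and convergent gene pairs each
get their own oriented copy of the shared gap, with calls made
independently per gene. Intervals of length zero are kept, so every gene
has a defined (possibly empty) search space. Where an intergenic gap is
flanked by two same-strand genes, it is attributed to the upstream (5')
gene only; coverage from the downstream gene's promoter region would need
orthogonal data to disentangle, which we do not attempt.

Intervals are tiled from the TTS outward into `bin_width = 10` nt bins
(bin 0 adjacent to the TTS; the last bin may be short). Ten nucleotides is
the resolution at which extension boundaries are reported; all call
lengths are multiples of it except truncated calls ending on a short final
bin.

## Normalization and assembly

Size factors are the classic median-of-ratios: for sample *j*,
`s_j = median_g(K_gj / geomean(K_g.))` over genes with nonzero counts in
every sample, rescaled so the factors have geometric mean 1. Factors are
estimated from **gene-body** counts, not bins: intergenic bins are mostly
near zero and the median over sparse rows degenerates. When no gene is
nonzero in all samples the function stops rather than silently falling
back; such a matrix indicates a data problem a user must see.

Assembly walks each interval's bins from the TTS and keeps the maximal
*contiguous* prefix whose per-bin statistic is at or above
`stop_threshold = 1` normalized readcount. The first failing bin ends the
call and is excluded (the rule reads "until a bin falls below", so the
failing bin is not part of the extension), even if coverage resurges
later — a deliberate conservatism that prevents chaining a genuine
extension to a downstream independent transcription unit through a single
noisy bin. If no bin fails before the interval ends, the call is kept and
flagged `truncated`. Calls of length ≤ `min_length = 200` nt are then
discarded (strictly greater-than: a 200-nt call is removed); 200 nt at
10-nt bins means at least 21 consecutive covered bins, which background
noise essentially never produces at the default rates.

Two choices here were genuinely open:

* **Replicate summary.** The per-bin statistic is the **mean** of
  normalized counts across the replicates of one genotype (configurable to
  `median` or `intersection` = per-sample minimum). The mean is the least
  surprising summary and, unlike the intersection, does not make call
  length collapse to the weakest replicate.
* **Per-genotype assembly.** Assembly runs separately per genotype, which
  is what makes genotype-specific extension sets (and their overlaps)
  well-defined. For differential testing, each gene's quantification
  region is the union of its per-genotype calls — since all calls share
  the TTS anchor, the union is simply the longest called prefix — so both
  genotypes are counted over the same region.

A short final bin participates in assembly with its normalized count
un-rescaled for width; rescaling a 3-nt bin's count by 10/3 would
triple its noise, and the bin can at most add one bin-width to a call.

## Differential read-through

For each extended gene, the extension/gene-body ratio is computed per
sample, `r = (ext/s_j + pc) / (body/s_j + pc)`, and per genotype on the
means of normalized counts, with pseudocount `pc = 0.5` so zero counts
never divide by zero. Ratios make the test independent of gene-body
expression differences between genotypes. Per-sample log2 ratios are
compared between the two genotypes with a Welch t-test (group variances
floored at `1e-8`; identical groups give p = 1), p-values are
Benjamini–Hochberg adjusted, and an extension is significant when
`padj < 0.1` **and** the ratio fold change exceeds 2 in either direction.
The two thresholds are the published decision rule and are deliberately
kept; the test behind them is our own transparent construction — a count
GLM with dispersion shrinkage would be a natural extension point, but a
Welch test on stabilized log ratios is fully specifiable, has no hidden
estimator, and its null calibration is verified in the test suite (type-I
error within (0.03, 0.07) at nominal 0.05, 500 null extensions, 10 seeds;
sensitivity ≥ 90% at ratio fold change 8 with 3 replicates).

## Cleavage-site sequence analysis

Composition profiles cover positions −200..−1 and +1..+200 around the
cleavage site; −1 is the last transcribed base and **there is no position
0**. Minus-strand sites are reverse-complemented before profiling and DNA
is reported in the RNA alphabet. Sites closer than 200 nt to a sequence
end contribute only their existing positions (per-position `n` is
reported).

The near-upstream element (NUE) is located per gene as the hexamer with
minimal Hamming distance to AAUAAA among all hexamers lying fully inside
the window −35..−10; ties go to the most 3' occurrence. The window
brackets the canonical "approximately −20" NUE location while excluding
the atypically distal signals (−50, −135) known from the bacterial-origin
NOS terminator; it is configurable.

To compare polyadenylation signals between two gene sets, base counts over
the six NUE positions are pooled into a 4 × 2 base-by-set table and tested
with a Pearson chi-square (df = 3 when all bases occur; rows that are empty
in both sets are dropped). When any expected cell is below 1 the function
warns that an exact test is advisable. One caveat this package makes
explicit: the pooled table treats the 6 × n bases as independent draws,
but they arrive in highly structured per-gene clusters (most best-match
hexamers are AAUAAA-like), so under gene resampling the test is
*conservative* — its p-values pile up near 1 rather than being uniform.
The test suite therefore checks exact null calibration on independent
multinomial tables and non-anti-conservativeness on gene subsets; a
significant result from this test is trustworthy, a non-significant one is
weak evidence of similarity.

## The qPCR long/short ratio

The assay normalizes both the long (read-through) and short (correctly
terminated) amplicon to a co-transfected reference transcript:
`dCT(x) = CT(x) − CT(ref)`, then `ddCT = dCT(long) / dCT(short)` and
`ratio = 2^ddCT`. The division in `ddCT` is implemented exactly as
published; it differs from the standard Livak combination
`2^(dCT(long) − dCT(short))`, which is provided as `method = "livak"` and
clearly labelled as the non-default alternative. Whether the division is
intentional cannot be decided from the published text, so fidelity wins
and both behaviours are exposed. Note the division form is invariant to
adding a constant to all three CTs (both ΔCTs are differences), but not to
rescaling; it requires `CT(short) ≠ CT(ref)` and raises an explicit error
otherwise. Per-genotype means are reported ± sd and relative to a control
genotype (control = 1).

## What the simulator does and does not emulate

`simulation_config()` defines a two-genotype (control/mutant) study with 3
replicates per genotype, mirroring a typical termination-mutant RNA-seq
design. Genes (default 50, 600–2000 nt) alternate strands along a toy
chromosome with 2–4 kb intergenic gaps — long enough that default-length
read-through never reaches a neighbouring gene. Counts are negative
binomial with one shared dispersion `phi = 0.05` (a typical RNA-seq value
for replicate variability); per-gene expression is log-uniform over 5–50
expected reads per 10-nt gene-body bin, spanning weakly to strongly
expressed genes. Read-through at an affected gene contributes
`e_g * f * S(d)` expected reads to the bin at distance *d*, where *f* is
the genotype's read-through fraction and `S(d)` either decays
geometrically (`(1 − q)^d`, default `q = 0.05`, a ~140-nt half-life chosen
as a plausible decay scale; the real decay shape is unknown) or is a step
of fixed length `L_true` (used whenever a test needs a known true
boundary). Background intergenic noise is 0.1 expected reads per bin.
Everything is seeded and byte-reproducible, and a truth table records
`e_g`, `f` and `L_true` per gene and genotype so callers are scored
against the generator, never against hard-coded effect sizes.

Not emulated: read-level artefacts (mapping ambiguity, fragment-end
effects — counts are drawn directly at bin resolution), splicing,
polyA-site microheterogeneity, and antisense contamination beyond an
optional leakage term from convergent neighbours (off by default, as in
strand-specific libraries). Passing tests on this generator therefore
demonstrates the *procedure* is implemented correctly and is calibrated
under its own model; they do not certify performance on real libraries
with positional biases or annotation errors.

## Numerical and degenerate-input choices

* Assembly, filtering and classification are deterministic; the only
  randomness anywhere is the seeded generator.
* `stop_threshold` is applied as ≥ (a bin exactly at 1 passes), the length
  filter as > (a call exactly at 200 nt is removed) — both follow the
  strict/non-strict reading of the published wording.
* Zero-length intervals yield zero bins and no call; a gene whose bin 0
  fails yields no call (not a zero-length call).
* Genes with all-zero body counts are excluded from ratio testing with a
  logged reason rather than producing pseudocount-only ratios.
* Welch p-values use floored variances, so two identical groups give
  t = 0, p = 1 instead of 0/0.
* BED output uses the interval's genomic span; minus-strand calls have
  `start`/`end` swapped relative to transcription order, as BED requires.

## Problem sizes used in the checks

The shipped tests run on 8–200 simulated genes with 3 replicates per
genotype, 10–20 seeds for properties stated in expectation, 200 randomized
coverage vectors for the bin-granularity check, and 200 resamples for test
calibration; the full suite and the acceptance script each complete in
well under a minute of CPU. These sizes give stable pass/fail behaviour at
the asserted tolerances while staying desk-scale.

## Limitations

* The caller inherits the annotation's TTS positions; systematically
  mis-annotated 3' ends shift all extensions accordingly.
* The prefix rule cannot represent extensions with internal coverage gaps
  larger than one bin, by design.
* The Welch-on-ratios test does not share dispersion information across
  genes; at 2 replicates per genotype it is valid but underpowered.
* The chi-square NUE comparison is conservative under gene resampling (see
  above).
* Attribution of shared intergenic coverage between convergent genes is
  per-gene and independent; a single shared read-through signal can in
  principle be credited to both neighbours.
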