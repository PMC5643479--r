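---
title: "Methods: DNA-SIP gradient analysis and taxon activity inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-SIP gradient analysis and taxon activity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipact)
library(dplyr)
```

## The problem

DNA stable isotope probing (DNA-SIP) identifies which members of a
microbial community assimilate a particular substrate. Organisms fed an
isotopically heavy substrate (here ^13^C cellulose or ^15^N urea)
synthesize denser DNA; isopycnic CsCl centrifugation then separates
labeled from unlabeled DNA by buoyant density. The gradient is collected
drop-wise from the bottom of the tube into fractions (fraction 1 =
densest), fractions are grouped into named *pooled fractions* by density
window, and the pooled fractions are sequenced by 16S amplicon
sequencing. An organism that incorporated the heavy isotope is revealed
by its *enrichment* in the dense pooled fractions of the labeled gradient
relative to the same pooled fractions of an unlabeled control gradient.

`sipact` implements the full post-sequencing inference chain —
percent-of-gradient normalization, density-window pooling, the per-taxon
activity statistic with Fisher-exact/FDR significance, copy-number
normalized KO-profile prediction and enrichment, and IRMS δ^15^N
calibration and comparison — plus a synthetic-data generator with known
ground truth that the whole chain is validated against.

## The activity statistic

For a taxon *t* and a dense pooled fraction, with `tNS` the taxon's
sequence count and `NS` the library total,

$$A_t = 100\,\frac{tNS_{\text{labeled}}}{NS_{\text{labeled}}}
      - 100\,\frac{tNS_{\text{control}}}{NS_{\text{control}}}$$

in percentage points. Because both percentage columns sum to 100, the
activities in any dense pool sum to zero: one taxon's enrichment is
necessarily another's underrepresentation. Negative values are reported
as underrepresentation, not clipped.

Significance of each (taxon, pool) contrast is assessed with a two-sided
Fisher exact test on the 2×2 table `[[tNS_lab, NS_lab − tNS_lab],
[tNS_ctl, NS_ctl − tNS_ctl]]`, summing hypergeometric probabilities not
exceeding the observed table's (relative tie tolerance 1e−7, the common
convention for ranking floating-point table probabilities). P-values are
adjusted with the Benjamini–Hochberg step-up procedure across taxa
*within each dense pool* (a `fdr_scope = "global"` option pools all
records instead; which scope original SIP studies used is typically
unstated, and within-pool is the more conservative default for
per-fraction interpretation). Tiers follow the heatmap legend convention
`**` (< 0.01), `*` (< 0.05), `+` (< 0.1), applied to adjusted values by
default; `tier_on = "p"` switches to raw p-values since published
heatmap annotations are often ambiguous about adjustment.

Activity is computed at one taxonomic rank per run (typically family or
genus) on the collapsed table. Collapsing groups taxa unresolved at the
target rank as "unclassified *parent*" using the nearest resolved higher
rank, preserving column totals and idempotence. Taxa present in only one
table are zero-filled; taxa absent from both are dropped.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not raw reads (no FASTQ, chimeras, sequencing error, or rotor physics).

**Buoyant density.** Unlabeled DNA bands at `BD0 = 1.660 + 0.098·GC`
g/ml, the classic linear CsCl relationship; full labeling adds 0.036 g/ml
(^13^C) or 0.016 g/ml (^15^N), scaled by the atom fraction excess. These
constants are standard SIP-methodology values and are overridable via
`bd_constants()`. The smaller ^15^N shift is why ^15^N gradients need
longer centrifugation and finer fractionation in practice, and why the
default gradient geometry is 12 fractions for cellulose but 24 for urea
(a 4.8 ml gradient collected as 400 µL or 200 µL fractions;
`n_collected_fractions()`).

**Bands and fractions.** Each taxon's band is a single Gaussian in
density with spread `band_sigma` (default 0.006 g/ml) — the simplest
model that produces overlapping light/heavy bands, the regime the
statistic must resolve. Partial labeling shifts the whole band; an
optional per-taxon `label_fraction` < 1 produces a two-component band
instead. Per-fraction DNA mass is the deterministic Gaussian integral
over the fraction's density window, renormalized over collected windows,
times `total_dna_ng` (default 750 ng, inside the typical 500–1,000 ng
recovery range) and the taxon's relative abundance.

**Noise.** qPCR 16S copy numbers are the copy-number-weighted DNA masses
scaled to copies (assuming ~5 Mb genomes; only the scale depends on
this) with multiplicative lognormal noise of CV `qpcr_cv` (default 0.1).
Amplicon counts are multinomial draws of `reads_per_pool` reads (default
50,000) from each pool's 16S-copy-weighted DNA shares — multinomial only,
with no PCR bias term, which is sufficient for power analysis and makes
the all-unlabeled null exactly multinomial (so Fisher/BH error control
can be verified against it).

**Seeding.** One root seed; each stochastic stage (qPCR noise and counts,
per treatment) derives its own stream via a single multiplicative
congruential step (MINSTD multiplier, modulus 2^31 − 1) plus a stage
offset, so datasets are bit-reproducible and stages never share a
stream.

**Default community.** 30 taxa with lognormal rank-abundances
(`sdlog = 1`), GC uniform on (0.35, 0.65), 16S copy numbers uniform on
1–7, gut-associated family names cycled over taxa with one genus per
taxon. The benchmark scenario labels 3 taxa at atom excess 0.5.

## Choosing pooled-fraction windows

The default pooling schemes place the dense windows *above* the buoyant
density range of unlabeled bands (GC 0.35–0.65 maps to ≤ ~1.724 g/ml):
cellulose uses upper/medium/lower with medium + lower dense (two activity
values per taxon), urea uses upper/upper-medium/lower-medium/lower with
the three densest windows dense (three activity values). This mirrors the
experimental practice of selecting density ranges where the labeled
gradient shows visibly more DNA than the control, and it matters
statistically: a dense window that overlaps the unlabeled community band
loses mass when a labeled band shifts out of it, which inflates every
other taxon's relative share there and produces spurious "enrichment" of
unlabeled taxa — a compositional artifact, not labeling. With the default
geometry the dense pools only ever *gain* mass in the labeled gradient,
so unlabeled taxa can only appear depleted there, and the benchmark
below controls its false discovery proportion. Window bounds are
configuration values (real experiments set them per gradient from the
DNA-density profile); windows are half-open `[low, high)` with ties at a
shared boundary assigned to the denser window, making assignment
deterministic.

Percent-of-gradient normalization always uses *all* recovered fractions
as the denominator, including any left unpooled; unpooled fractions are
reported, never silently dropped.

## Benchmark properties

These are computed by the test suite, at these problem sizes (chosen to
give stable Monte-Carlo estimates at interactive runtimes):

- **Parameter recovery**: 30 taxa, 3 labeled at atom excess 0.5, 50,000
  reads per pool, 50 seeds; a taxon is flagged when some dense pool has
  `A > 0` and `q < 0.05`. Mean sensitivity and false discovery
  proportion are required to be ≥ 0.9 and ≤ 0.1; the run reported by the
  suite achieves sensitivity 1.0 and FDP ≈ 0.01.
- **Null calibration**: 200 all-unlabeled replicates of the same
  scenario; the per-replicate fraction of taxa reaching `q < 0.05` must
  stay ≤ 5% (observed ≈ 0.1%, since the exact test is conservative at
  multinomial counts).
- **Oracle equivalence**: Fisher p-values match exhaustive
  hypergeometric enumeration on every 2×2 table with margins ≤ 30 to
  1e−12; BH matches a naive step-up; exact Mann–Whitney matches full
  assignment enumeration for group sizes ≤ 6.

Passing these shows the chain is correct and well-calibrated *under the
generator's assumptions*. Real data add effects the generator omits —
PCR and primer bias, overdispersion between gradient replicates,
chimeras, density smile/compression across tubes — so real-data error
rates can exceed the nominal FDR even though the arithmetic is exact.

## Metagenome-profile arithmetic

KO (KEGG Ortholog) profiles are predicted PICRUSt-style on user-supplied
reference tables: counts are divided by 16S copy number
(`copy_number_normalize()`), optionally restricted to the labeled
families (`filter_to_labeled_taxa()`), and multiplied against a
taxon × KO gene-count reference
(`predict_ko_profile()`; missing taxon/KO cells count as zero gene
copies). Reference databases and the NSTI uncertainty measure are out of
scope — the tables are inputs. KO enrichment applies the activity formula
to each KO's percent share of the column total, by default over a
curated KO subset (so the denominator is the subset; a flag uses all
KOs). Shares are scale-free: doubling all copy numbers or scaling one
sample's abundances leaves enrichment unchanged, which the tests verify.

## IRMS calibration and comparison

Isotope ratios are expressed in δ notation,
δ = (R~sample~/R~standard~ − 1)·10³ ‰. (The form sometimes printed with
an extra "− 1" after the ratio quotient is dimensionally inconsistent —
it would assign δ = −1000 ‰ to a sample identical to the standard — so
the standard form above is implemented.) Measured values are calibrated
by two-point normalization: the affine map sending the measured readings
of IAEA-N1 (+0.43 ‰) and IAEA-N2 (+20.40 ‰) exactly to their certified
values, applied to sample readings. A working-standard chain (sample vs
lab standard vs certified anchors) is the composition of two such maps.
No m/z = 30 (^15^N₂) trace correction is applied.

Technical replicates are averaged per biological replicate before any
testing. Group comparisons report mean ± SEM (sample sd/√n) and the
Mann–Whitney U test with exact p-values by full enumeration of rank
assignments for group sizes ≤ 8 (midranks for ties) and a tie- and
continuity-corrected normal approximation above. With n = 3 biological
replicates per treatment, the smallest achievable exact two-sided p is
2/C(6,3) = 0.10, so a two-sided test can never reach a 0.05 threshold;
the significance call therefore defaults to the one-sided alternative
(^15^N group greater), with full separation giving exactly p = 0.05,
counted as significant at the threshold. Both sidedness values are
always reported.

## Numerical choices and degenerate inputs

- Bands falling entirely outside the collected range at double precision
  are assigned to the nearest window (mass must be conserved).
- Pools whose DNA weight underflows to zero yield zero counts; activity
  computation refuses zero-total libraries explicitly.
- Gradient profiles must be bottom-first (density non-increasing with
  index); top-first files are detected and re-indexed with a warning,
  anything else is an error. Densities outside 1.60–1.80 g/ml are
  rejected as physically implausible for CsCl gradients of DNA.
- "Highest activity" rankings sort by max A over dense pools, ties
  broken lexicographically by taxon name, making reports deterministic.
- All percentages are written to TSV with six decimal places; counts as
  integers; every report carries the configuration hash and seed.

## Known limitations

- The Gaussian single-band model ignores diffusion, rotor geometry and
  gradient relaxation; `band_sigma` absorbs them phenomenologically.
- The activity statistic is compositional; enrichment magnitudes are not
  comparable across pools with very different library compositions, and
  dense windows must be chosen above the control band (see above).
- KO prediction inherits all limitations of reference-based inference;
  with synthetic references it demonstrates arithmetic, not biology.
  Curated KO lists ship as placeholders to be replaced by the user's
  own selections.
- The Mann–Whitney normal approximation is only used above n = 8 per
  group; at n = 8 it agrees with the exact enumeration within 0.02.
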