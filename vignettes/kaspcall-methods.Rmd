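---
title: "Control-anchored KASP genotype calling and allele-specific occupancy quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-anchored KASP genotype calling and allele-specific occupancy quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspcall)
```

## The measurement and its geometry

KASP (Kompetitive Allele-Specific PCR) genotyping reads each well of a
384-well plate on two endpoint fluorescence channels: FAM reports the
mutant/variant allele-specific primer, HEX the wildtype one. In a CRISPR
clone screen the wells carry genomic DNA of clonal colonies; the assay
targets the engineered variant, and the allele-specific primers fail to
bind alleles carrying NHEJ indels near that site. Three physical facts
drive everything downstream:

* the *direction* of a well in the (HEX, FAM) plane encodes allelic
  composition — pure wildtype along the HEX axis, homozygous edited along
  FAM, heterozygous in between;
* the *total* signal encodes how much amplifiable template was present —
  a clone with one edited and one NHEJ allele amplifies at roughly half
  strength, and a clone with NHEJ on both alleles does not amplify at all,
  landing with the no-template controls (NTCs);
* wells seeded with several cells pool their alleles, so a low mutant
  fraction (one heterozygous cell among ten) displaces the well slightly
  but systematically off the wildtype direction.

`kaspcall` formalizes the visual cluster-plot reading of such plates as
polar geometry. After subtracting the per-channel NTC mean (clamped at
zero), each well becomes `x` (wildtype channel), `y` (mutant channel),
`magnitude = x + y`, `angle = atan2(y, x)` in degrees. Genotype-control
wells anchor one angular centroid per class; unknown wells are assigned by
standardized angular distance `angle_z = |angle - centroid| / angle_sd`.

## The caller's tunable parameters

`caller_params()` holds the few knobs, all dimensionally interpretable:

* `ntc_sd_multiplier` (default 5): the amplification threshold is the mean
  raw NTC magnitude plus this many NTC standard deviations. Wells at or
  below it are `NO_AMP`. Five sds makes a spurious amplification call from
  NTC-level noise vanishingly rare while half-signal clones (about 50% of
  full magnitude, i.e. roughly a thousand units against a threshold of a
  couple of hundred) are never lost.
* `max_angle_z` (default 3): the classing window per centroid.
* `half_signal_ratio` (default 0.6): a classed well whose magnitude is
  below 0.6 of its class median magnitude is flagged half-signal. Compound
  edited/NHEJ clones sit near 0.5 of the class magnitude, fully
  amplifiable clones near 1.0; 0.6 separates the two with margin for
  multiplicative noise.
* `angle_sd_floor` (default 0.75 degrees): control wells can be nearly
  noise-free (and exactly noise-free in simulation), and a zero angular sd
  would turn every unknown well into `AMBIGUOUS`. The floor keeps a
  usable window. Its value matters at the wildtype end: a well with a 5%
  mutant-allele fraction sits at `atan2(0.05, 0.95)` = 3.0 degrees, and
  with a 0.75-degree floor that is `angle_z` = 4 — outside the class
  window, hence visible as `INTERMEDIATE`. A floor of 1.5 degrees would
  swallow such wells into the wildtype cluster and make the multi-cell
  screening design blind at exactly the fraction it is built to detect
  (one heterozygous cell in ten), which is why we chose the smaller
  floor.

Calls that amplify but fit no class window are `INTERMEDIATE` when the
angle lies strictly between two adjacent centroids (the mixed-population
signature; `detect_intermediate_wells()` ranks them by closeness to the
heterozygous centroid) and `AMBIGUOUS` otherwise. Nearest-centroid ties
break toward the lower-mutant class: in a screen, a false HDR positive
costs more than a false negative. Classification is invariant to scaling
both channels of every well by a common constant, because angles, NTC
statistics and magnitude ratios all scale together.

## ChIPnQASO quantitation

For allele-specific occupancy, chromatin from a heterozygous line is
immunoprecipitated and the pulled-down DNA is KASP-genotyped alongside
input DNA. Input carries both alleles at exactly 50/50, so the mean input
signal per channel is a conversion factor for that channel; an IP well's
allelic fraction is

`frac_mut = (y / factor_mut) / (y / factor_mut + x / factor_wt)`.

This ratio-of-ratios is the unique linear correction that maps input to
exactly 50/50, and any channel-gain asymmetry shared by input and IP wells
cancels identically — a property tested across gain factors from 0.25 to 4.
Multiple input wells are pooled by per-channel means before the factors
are formed (input clusters as one group on the plate), IgG wells are never
used for normalization and are carried through flagged `low_signal`, and
no significance test is attached to the preference ratio
`mean_frac_mut / (1 - mean_frac_mut)`: replicate means and standard
deviations are reported and hypothesis testing is left to the caller.

## Titration and the limit of detection

`lod_analysis()` takes replicate fraction measurements at known
mutant-allele percentages (0, 1, 2.5, 5, 10, 15, 20, 25, 50 in the
standard design, four replicates each) and runs a two-sided
pooled-variance Student's t-test of every nonzero level against the 0%
replicates. The limit of detection is the smallest level with p below a
single stringent alpha of 0.001; no multiplicity correction is applied
across levels, the stringent threshold playing that role. Choices worth
stating:

* the test statistic is the derived allelic *fraction*, not raw
  mutant-channel fluorescence — scale-free and comparable across plates
  (rerunning on raw signal is a caller-side substitution of the input
  column);
* a pooled-variance floor of 1e-12 keeps noise-free fixtures defined:
  identical groups give t = 0 and p = 1, separated ones a p-value of
  essentially zero (note that with two replicates per group the t
  distribution has df = 2, so "essentially zero" is around 1e-8, not
  arbitrarily small);
* a Welch test is deliberately not the default; the classic equal-variance
  Student form matches how such titrations are conventionally analyzed.

## What the simulator emulates, and what it does not

`sim_params()` encodes the instrument model used everywhere: measured
mutant fraction = true fraction + background `b (1 - f)` + Gaussian noise
(sd `fraction_noise_sd`), clipped to [0, 1]; magnitude = `gain` times the
amplifiable-allele fraction with multiplicative noise (`magnitude_cv`);
each channel adds an independent no-template draw (`ntc_mean`, `ntc_sd`);
the mutant channel may carry a gain multiplier. NHEJ alleles contribute
nothing to amplification. Defaults — gain 2000, fraction noise sd 0.008,
background 0.005, magnitude CV 0.08, NTC 60 ± 12 — are calibration
choices, not measured instrument values: they are fixed so that the
standard 9-level, 4-replicate titration detects 5% but not 2.5% mutant
allele at alpha 0.001, which is the sensitivity boundary the screening
design assumes (10-cell wells put one heterozygous HDR cell at exactly
5% of alleles).

One honest caveat on that calibration: the detect-5%-miss-2.5% boundary
holds at the level of means, but with four replicates the t statistic has
substantial sampling variation. Under the defaults the 2.5% level reaches
significance in roughly a quarter of runs and the 5% level misses in a few
percent, so a fixed-design run (the packaged seed) yields a 5% LOD while
across random seeds about seven in ten do; this is a property of the
assay design (n = 4, alpha 0.001, noise ~0.008–0.01), not of the
implementation, and tightening it would require more replicates or a
different alpha. Per-well NTC draws also leak roughly 0.006 of additional
fraction noise at gain 2000, slightly widening the same spread.

The simulator does not model competitive-PCR nonlinearity (real KASP
chemistry exaggerates small allele fractions, which can only help
detection), PCR bias, pipetting structure, plate-position effects, or
partial primer tolerance of NHEJ alleles. Passing tests therefore show
that the *analysis* is correct under a linear two-channel noise model, not
that any particular instrument achieves these numbers.

Multi-cell wells may optionally be thinned for viability in user code
(seeded wells often grow from fewer cells than plated); the generator
itself keeps the plated composition for clarity.

## Amplicon read classification

`classify_reads()` re-implements a deliberately minimal editing-outcome
classifier rather than wrapping an external tool:

1. **HDR**: the read, trimmed 20 bp at each end, matches the expected
   HDR amplicon exactly as a substring (either orientation). Exact
   matching after trimming is the stringent published convention for
   merged amplicon reads with unreliable ends; HDR is checked first, so a
   read can never be both HDR and NHEJ.
2. otherwise the read is globally aligned to the reference
   (match +1, mismatch −1, gap open −2, gap extend −0.5 via
   `Biostrings::pairwiseAlignment`; these scores are conventional, not
   derived, and are configurable): **NHEJ** if an indel overlaps the
   ±10 bp window around the blunt cut; **WT** with no indel in the window
   and ≥ 98% identity; **UNCLASSIFIED** otherwise (including reads
   shorter than 2·trim + 1, flagged `short`).

The cut-site offset is part of the assay description, not inferred from a
PAM; indel placement by the aligner can shift within repeats, so windows
much smaller than the default ±10 are not recommended.

## Bookkeeping conventions

Genotype frequency tables round half-up to one decimal for display
(2.45 → 2.5), keeping unrounded values alongside; allelic efficiency
counts edited alleles over all screened alleles,
`(het + ploidy · hom) / (ploidy · total)`. The plate CSV dialect writes
RFUs at nine significant digits so write→read→write is a byte-level fixed
point. Simulated runs larger than one 384-well plate continue onto
numbered plates within the same panel; well identifiers always respect
the A–P × 1–24 grammar (96-well layouts are the A–H × 1–12 subset).

## Problem sizes used in the test suite

The packaged checks run at sizes chosen to give tight binomial/normal
margins while staying quick: 400–500-well noise-free concordance screens,
5000-clone truth calibration, 200 seeded ChIP recovery runs, 600 null
titration series for type-I control, and 10,000-read classification runs
(three-binomial-sd agreement). All fixtures are generated in code with
fixed seeds; identical seeds reproduce panels and read sets byte for
byte.
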