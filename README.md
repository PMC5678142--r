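# kaspcall

Analysis toolkit for **scarless CRISPR clone screening with KASP
genotyping** and for **allele-specific occupancy quantitation
(ChIPnQASO)**.

Creating isogenic cell models of a disease-associated SNP or variant of
uncertain significance means screening dozens of clones for a precise
HDR edit while most wells carry wildtype or NHEJ-disrupted alleles. KASP
(Kompetitive Allele-Specific PCR) genotyping reads each well on two
endpoint fluorescence channels — FAM for the mutant allele-specific
primer, HEX for the wildtype one — and genotypes appear as clusters in
the two-channel plane. `kaspcall` turns that visual readout into a tested
pipeline for:

* **plate I/O and validation** — a canonical CSV dialect for two-channel
  endpoint plates (`read_plate_csv()`, `write_plate_csv()`,
  `validate_layout()`);
* **control-anchored genotype calling** — NTC-subtracted polar geometry
  (angle = allelic composition, magnitude = amplification), centroids
  fitted on genotype controls, and per-well calls in
  {WT_WT, WT_MUT, MUT_MUT, NO_AMP, INTERMEDIATE, AMBIGUOUS} with a
  half-signal flag for compound edited/NHEJ clones
  (`normalize_readings()`, `fit_control_clusters()`, `call_genotypes()`,
  `detect_intermediate_wells()`);
* **ChIPnQASO quantitation** — input DNA of a heterozygous line defines
  per-channel conversion factors (input ≡ 50/50); IP wells become allelic
  fractions and preference ratios with replicate spread
  (`compute_conversion_factors()`, `allelic_fraction()`,
  `quantify_chip()`);
* **titration limit of detection** — pooled-variance Student's t-tests of
  each mixture level against the 0% control at a stringent alpha
  (`lod_analysis()`, `mixture_series_design()`);
* **editing metrics** — T7 endonuclease indel percentages, genotype
  frequency tables with allelic efficiency, multi-cell allele math, and a
  minimal amplicon-read HDR/NHEJ classifier (`t7_indel_percent()`,
  `frequency_table()`, `multiwell_mut_fraction()`, `classify_reads()`);
* **a synthetic instrument** — seeded generators for genotyping plates,
  clone screens with per-allele HDR/NHEJ truth, ChIP panels with a known
  allelic preference, titration series and amplicon reads
  (`simulate_*()`), used to calibrate and test every stage.

The central statistic of ChIPnQASO: with input-anchored conversion
factors `F_mut`, `F_wt` (mean input signal per channel), an IP well with
NTC-subtracted channels `(x, y)` has mutant-allele fraction

    frac_mut = (y / F_mut) / (y / F_mut + x / F_wt)

and allelic preference ratio `frac_mut / (1 − frac_mut)`. Input maps to
exactly 0.5 by construction and any shared channel-gain asymmetry
cancels.

## Worked example

```r
library(kaspcall)

# genotype frequencies of a 48-clone single-cell screen
frequency_table(42, 4, 2)
#> <genotype_frequency> 48 clones (ploidy 2)
#>   WT/WT 42 (87.5%), WT/Mut 4 (8.3%), Mut/Mut 2 (4.2%)
#>   allelic efficiency 8.3%

# one heterozygous cell among ten diploid cells
multiwell_mut_fraction(10, 1, 0)
#> [1] 5

# allele-specific occupancy: input (wt 800, mut 1000), IP (wt 640, mut 1600)
factors <- compute_conversion_factors(tibble::tibble(x = 800, y = 1000))
frac <- allelic_fraction(list(x = 640, y = 1600), factors)
c(frac_mut = frac, preference = frac / (1 - frac))
#>  frac_mut preference
#> 0.6666667  2.0000000

# limit of detection of a simulated 9-level x 4-replicate titration
lod_analysis(simulate_titration(seed = 1234)$measurements)
#> <titration_result> alpha = 0.001 ; LOD = 5% mutant allele
```

The frequency table says 8.3% of the 96 screened alleles carry the
precise edit; the occupancy example quantifies a 2:1 binding preference
for the mutant allele; the titration finds 5% mutant allele as the
smallest mixture distinguishable from pure wildtype at p < 0.001.

A thin command-line front end ships in `exec/`:

```sh
kaspcall validate plate.csv
kaspcall call plate.csv --out calls.csv
kaspcall chip plate.csv --out quant.csv
kaspcall t7 --bands 25 25 50
kaspcall table --counts 50 3 4
```

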