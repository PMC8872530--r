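# sparsekin

Kinship, biological sex and mitochondrial genome inference from sparse,
degraded-DNA shotgun sequencing.

## The problem

DNA recovered from highly degraded specimens — aged rootless hair shafts,
old skeletal material, keepsake relics — yields ultrashort fragments
(~30–90 bp) at well under 1× nuclear coverage. Standard genotype-based
kinship tools and amplicon-based mitochondrial typing both fail in this
regime. What *is* recoverable, and what this package implements, is:

1. **Forced pseudo-haploid relatedness.** Each sample is reduced to a large
   biallelic SNP panel (the ~1.3 M sites typed by genealogy arrays), every
   covered site is represented by a single randomly sampled allele, and the
   two samples are compared by their **allele mismatch proportion** over the
   sites covered in both. For a site with population alternate-allele
   frequency *p*, the expected per-site mismatch under Hardy–Weinberg is

   *m = (1 − 2φ) · 2p(1−p)*,

   where φ is the kinship coefficient (½ same individual, ¼ parent–child
   and full siblings, 0 unrelated), giving panel-average expectations of
   *p(1−p)*, 1.5 *p(1−p)* and 2 *p(1−p)* respectively. A symmetric
   per-observation genotyping error *e* (deamination, PCR, sequencing,
   mapping) transforms this to *m((1−e)² + e²) + (1−m)·2e(1−e)*. The
   observed proportion is judged against Monte Carlo null distributions
   simulated per relationship class and error rate, conditioned on exactly
   the overlap-site set of the comparison.

2. **Rx sexing.** For each autosome *i*, the length-normalised ratio
   *r_i = (N_X/L_X)/(N_i/L_i)*; Rx is the mean of the 22 ratios with a 95%
   CI of ±1.96·SD/√22. Male if the CI upper bound < 0.60, female if the
   lower bound > 0.80, otherwise inconclusive.

3. **Circular mitogenome calling.** A chimeric doubled reference (genome +
   14 N spacer + a second copy rotated to start at position 8284; 33,152 bp
   for the 16,569 bp human mitogenome) lets linear aligners place reads
   spanning the circular origin. Placements are lifted back to circle
   coordinates, filtered (MQ ≥ 30), deduplicated on fragment endpoints, and
   piled up into consensus calls with point-heteroplasmy handling: a minor
   allele joins the call as an IUPAC code when it reaches ≥ 10% of depth
   with ≥ 2 reads (so 57 T / 18 C → `Y` at 76% major fraction, while
   53 C / 1 T stays homoplasmic `C`). Haplotypes are reported as
   differences from the reference (`263G`, `315.1C`, …).

A synthetic-data layer generates every input the pipeline consumes — SNP
panels, related genotype pairs, correlated sparse coverage, error-prone
observations, sexed chromosome counts, and degraded circular reads with
terminal C→T deamination, low-MQ fractions and PCR duplicates — so the
whole method is testable without restricted samples.

## Worked example

```r
library(sparsekin)
report <- run_pipeline(default_run_config(seed = 1))
report
#> <run_report> 647408304e98
#>   kinship: 487 overlap sites, mismatch 0.1869 -> same_individual
#>   sexing:  Rx 0.987 (CI 0.979-0.996) -> female
#>   mito:    15601/17365 placements retained, depth 56.6x, profile recovered exactly (14 diffs)
```

Reading the three lines:

* **kinship** — two simulated libraries of a same-individual pair (1,500
  and 3,000 covered panel sites with correlated coverage, 1% genotyping
  error) shared 487 sites; their pseudo-haploid mismatch proportion, 0.187,
  falls inside the same-individual null interval at the plausible error
  rates and outside every other class, so the verdict is
  `same_individual`. (At zero relatedness the same panel would give ≈ 0.37.)
* **sexing** — a simulated female count table at 10⁵ reads gives Rx 0.987
  with CI lower bound 0.979 > 0.80 → `female`.
* **mito** — 17,365 simulated degraded reads (terminal deamination, 5%
  low-MQ, 5% duplicates) are placed on the chimeric reference, lifted,
  filtered and deduplicated to 15,601 placements (56.6× depth), and the
  14-difference haplotype they were simulated from — including
  origin-spanning fragments and the `315.1C` / `524.1A` / `524.2C`
  insertions — is called back exactly.

Individual stages are ordinary data-frame functions and chain with the
pipe; every result object has `tidy()`, `glance()` and `autoplot()`
methods:

```r
counts <- simulate_chromosome_counts("male", 1e5, seed = 2)
glance(compute_rx(counts))
#> # A tibble: 1 × 6
#>      rx     sd      ci ci_low ci_high assignment
#>   <dbl>  <dbl>   <dbl>  <dbl>   <dbl> <chr>
#> 1 0.503 0.0101 0.00423  0.499   0.508 male
```

## Acceptance script

`scripts/acceptance.R` re-runs the complete synthetic pipeline from scratch
against the installed package — panel and coverage simulation through
relatedness classification, Rx sexing, and the chimeric-reference
mitochondrial branch — and writes its JSON outputs:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the headline numbers land in
`results/run_report.json` next to the requested output file.
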