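---
title: "Methods: kinship, sexing and mitogenome calling for sparse degraded DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship, sexing and mitogenome calling for sparse degraded DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsekin)
```

This vignette is the package's account of its models, its tunable
parameters, the synthetic world it validates itself on, and the numerical
and design choices that were genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Forced pseudo-haploid relatedness

### Model

At shotgun coverages of 0.01–0.6×, diploid genotype calling is impossible:
most SNP sites are covered by zero or one read. The forced-haploid
representation accepts this and keeps a **single randomly sampled allele**
per covered site (`pseudo_haploidize()`). Two samples are compared by the
**mismatch proportion** over the sites called in both
(`mismatch_proportion()`).

The statistic's expectation follows from the kinship coefficient
$\varphi$ — the probability that one allele sampled from each individual is
identical by descent ($\varphi = \tfrac12$ same individual, $\tfrac14$
parent–child and full siblings, $0$ unrelated). Sampled alleles that are
IBD never mismatch; non-IBD alleles are independent population draws and
mismatch with probability $2p(1-p)$ at alternate-allele frequency $p$.
Hence, per site,

$$ m(p) \;=\; (1 - 2\varphi)\, \cdot 2p(1-p), $$

i.e. $p(1-p)$, $1.5\,p(1-p)$ and $2p(1-p)$ for same-individual,
first-degree and unrelated pairs. A symmetric observation error $e$
(each sampled allele flipped to the site's other allele independently)
gives the observable

$$ m_{\mathrm{obs}} = m\left((1-e)^2 + e^2\right) + (1-m)\,2e(1-e), $$

which is what `expected_mismatch_closed_form()` averages over the panel.
Note two structural facts that shape interpretation:

* **parent–child and full siblings are indistinguishable in expectation**
  under single-allele sampling (both $\varphi = \tfrac14$); separating
  them needs genotype-level statistics that this data regime does not
  support. The replicate distributions coincide too: since per-site
  mismatch indicators are independent Bernoulli draws with equal means,
  the classes match in all moments, not just the mean.
* the statistic only orders classes when the panel has nonzero mean
  heterozygosity, which is why monomorphic sites contribute nothing.

### The simulated null and the classification rule

The null (`simulate_mismatch_null()`) is Monte Carlo, **conditioned on
exactly the overlap-site set** of the observed comparison: each replicate
draws a fresh genotype pair under Hardy–Weinberg at those sites'
frequencies, pseudo-haploidises both members, applies the error, and
records the mismatch proportion. Summaries keep the mean, SD and the
central 95% replicate interval per (class, error) cell.

`classify_relationship()` calls a class *compatible* at error rate $e$
when the observation lies inside that cell's 95% interval, and issues a
verdict only when exactly one class is compatible anywhere on the error
grid; otherwise the result is explicitly inconclusive (outside all
classes, or ambiguous between several). Interval membership was chosen
over a likelihood ratio because the null is empirical and the published
practice this mirrors reads compatibility off simulated distributions; it
is reproducible and makes no distributional assumption on the replicate
spread.

Parameters that matter:

| parameter | default | why |
|---|---|---|
| `error_grid` | 0, 0.005, 0.01, 0.02 | spans the 0–2% error range plausible for degraded libraries; the grid is the discretisation of an unknown nuisance parameter, not an estimate |
| `n_replicates` | 10,000 | interval endpoints stable to ~1 SE of the 2.5% quantile at 1,000+ sites; recorded in the output |
| het. of the panel | from frequencies | everything scales with mean $p(1-p)$ |

The replicate engine is vectorised at allele-dosage level (matrix
Bernoulli sampling) rather than looping the public per-pair simulator;
the tests assert its means against both the closed form and an
independent enumeration oracle over the joint genotype distribution.

### What a green test establishes — and what it does not

The synthetic world draws panel frequencies uniform on (0.05, 0.95) — a
stand-in for genotyping-array spectra that keeps per-site informativeness
realistic without external frequency downloads; the law is pluggable
(`freq_beta()` for rare-allele-skewed spectra). Coverage for two samples
is correlated through a shared log-normal per-site mappability weight
(`simulate_coverage_mask()`, sd $2\rho$ on the log scale), because real
degraded libraries share severalfold more sites than independent sampling
predicts; at $\rho \approx 0.55$ the enrichment is about 3×. The error
model is a single symmetric flip on sampled alleles.

Real data differ in ways the generator does not emulate: frequencies are
mis-specified for any particular ancestry, error is asymmetric
(deamination is C→T biased) and site-dependent, and coverage correlation
has structure beyond a scalar weight. A green parameter-recovery test
therefore establishes that the *statistic and decision rule* work in a
world obeying their assumptions at the stated sparsity (≈1,200 overlap
sites) — not that any particular real comparison is correctly called.
With ~1,200 overlap sites the same-vs-unrelated gap is ~14 SD, so
discrimination is driven by model validity, not sampling noise.

## 2. Rx sexing

For autosome $i$, $r_i = (N_X/L_X)/(N_i/L_i)$; $R_x = \bar r$, with the
normal 95% CI $\bar r \pm 1.96\,s/\sqrt{22}$ using the sample SD over the
22 ratios. Assignment is male when the CI upper bound is **below 0.60**,
female when the lower bound is **above 0.80**, both strict, else
inconclusive. The orientation (X in the numerator) and the
$1.96/\sqrt{22}$ half-width were fixed by verifying that they reproduce
published table arithmetic to 3 decimals from printed (Rx, SD) pairs; one
published row rounds to 0.096 where 0.097 is printed, so the audit
targets the rows whose arithmetic reproduces exactly. `rx_table()` exists
precisely for such audits. Y-chromosome reads are ignored: the statistic
uses only X and the autosomes, and no shrinkage or Bayesian variant is
attempted. Counts scale out of every ratio, so library size affects only
the CI width through the multinomial noise in the counts.

The generator (`simulate_chromosome_counts()`) is a multinomial over
chr1–22 + X with weights length × dosage (X dosage ½ for males), GRCh37
lengths by default. It ignores mappability variation and GC bias; at the
$10^5$ reads of the recovery tests the dosage signal is ~40 CI
half-widths from either threshold, so those tests certify the decision
rule and its arithmetic, not robustness to alignment artefacts.

## 3. Circular mitogenome pipeline

### Chimeric reference and liftover

`build_chimeric_reference()` concatenates the full circle (length $L$), a
14 N spacer, and a second copy rotated to start at position 8284 —
33,152 bp for $L = 16{,}569$. The spacer stops reads from bridging the
junction; the rotated copy gives origin-spanning fragments a contiguous
linear home. `liftover_to_rcrs()` is the deterministic inverse: copy-1
positions map identically; copy-2 position $q$ maps to
$((q - (L + 14) + 8284 - 2) \bmod L) + 1$; footprints running past $L$
split into two circular intervals. A placement overlapping the spacer is
rejected with a reason — it cannot arise from a genuine circular
fragment. The package does not re-align reads (no aligner is
re-implemented): placements on the chimeric reference fully determine
circle footprints, so a second mapping pass would be redundant at desk
scale. The round-trip invariant — every non-spacer chimeric position maps
to exactly one circle position and every circle position has exactly two
preimages — is asserted in the tests.

### Filtering, deduplication, calling

Placements are filtered at MQ ≥ 30 (boundary kept), then collapsed on
identical circular fragment endpoints (start, end, strand), keeping the
highest-MQ copy with read-id tie-break — the duplicate criterion
appropriate to merged single-end fragments, where identical endpoints
mark PCR copies. The stage accounting is conserved:
input = spacer-rejected + MQ-filtered + duplicates-removed + retained.

`pileup_and_call()` counts bases per circle position from
reference-aligned sequences and applies the heteroplasmy rule of
`call_position()`: consensus is the major base; a minor base with
**fraction ≥ 10% and ≥ 2 reads** joins it as an IUPAC code, with the
major fraction recorded. The thresholds are this package's choice — set
once so that the two published decision patterns both reproduce (a 24%
minor allele is called mixed; a 1.9% minor allele, consistent with a
single deaminated molecule, is not) — and they sit far above the
per-position damage rate that end-concentrated deamination induces
(≈ rate × 2/length ≈ 0.2% at 5% terminal damage and 50 bp reads), which
is why damage does not produce false mixed calls at ≥ 60× depth in the
tests. Zero-depth positions are no-calls, never silent reference matches.

Insertions travel as per-read annotations (anchor, rank, base) — what a
CIGAR conveys after alignment — are counted like bases, join the
consensus at > 50% of anchor depth, and are reported in `anchor.rank`
notation (`315.1C`). No realignment of the dinucleotide-repeat region is
attempted: notation is emitted as the pileup presents it, and complex
rearrangements are out of scope. Haplotypes are difference lists vs the
reference; `compare_haplotypes()` restricts to positions called in both
samples before taking the symmetric difference.

### Synthetic reads and the synthetic reference

`simulate_mt_reads()` draws starts uniform on the circle (origin-spanning
fragments arise naturally), lengths from a log-normal floored at 18 bp
(mean 38–93 bp covers the observed range for century-old hair; default
60), applies terminal-base C→T damage at `deamination_rate`, and
optionally injects low-MQ reads and exact PCR duplicates so the filters
have work to do. Damage is applied to terminal bases only — degraded-DNA
damage concentrates at fragment ends — and on one notional strand;
strandedness and within-read damage gradients are not modelled.

The reference itself is **synthetic** (`synthetic_rcrs()`): a random
16,569 bp circle. Nothing in the coordinate arithmetic, the caller or the
notation depends on the true human mitochondrial bases, and shipping a
synthetic sequence avoids misrepresenting a canonical reference that
cannot be bundled. `locket_like_haplotype()` builds a 14-difference
haplotype with the structure of a real full-mitogenome forensic profile
(11 substitutions, one single-base and one dinucleotide insertion at the
classic control-region anchors); substituted bases follow the canonical
profile unless the random reference already carries them.

## 4. Orchestration and reproducibility

`run_pipeline()` drives all stages from one validated JSON config
(`default_run_config()`, `read_run_config()`); unknown keys are rejected,
a master seed is mandatory, and every stage seed is derived
deterministically from it, so identical configs give byte-identical
headline JSON (`write_run_report()`), which embeds the config hash. The
config format is JSON rather than YAML because the package's dependency
set includes a JSON parser only. There is no shell entry point: this is
an analysis package, and one orchestration function plus the stage
functions is its interface; `scripts/acceptance.R` is a thin wrapper over
`run_pipeline()`.

```{r demo, eval = FALSE}
report <- run_pipeline(default_run_config(seed = 1))
report$kinship$verdict
report$sexing$assignment
report$mito$profile
```

## 5. Numerical choices and degenerate inputs

* Seeds are 32-bit; user-facing functions accept `seed = NULL` (use the
  current RNG stream) or an integer, applied via a scoped RNG so library
  code never clobbers the caller's stream.
* `mismatch_proportion()` errors on zero overlap rather than returning
  NaN; `compute_rx()` errors on any zero-count autosome (a ratio would be
  undefined) and on a missing X.
* Consensus ties at 50/50 base counts resolve to the alphabetically first
  base — deterministic, and at any realistic depth the position is also
  flagged heteroplasmic, which is the scientifically relevant output.
* Null intervals are empirical type-7 quantiles; no smoothing.
* Pseudo-haploidisation at multi-read sites samples one *read*
  uniformly; whether published practice sampled reads or called alleles
  first is unknowable from the description, and read-level sampling is
  the assumption-free choice.
* Error rates are restricted to $[0, 0.5)$; at 0.5 the flip model carries
  no information and the closed form degenerates.

## 6. Known limitations

* First-degree classes (parent–child vs full siblings) are inherently
  unresolvable by this statistic; the classifier reports ambiguity rather
  than guessing.
* The null conditions on the overlap-site set but not on per-site read
  depths; with depth > 1 at some sites the pseudo-haploid draw is still
  one read, so this matches the statistic, but depth-aware nulls could
  tighten intervals slightly.
* Frequency mis-specification (wrong ancestry panel) biases the expected
  mismatch of *all* classes; the error grid absorbs some but not all of
  this.
* The mitochondrial caller handles substitutions and simple insertions
  only; deletions appear as coverage gaps, not calls.
* Rx assumes autosomal coverage is unbiased relative to X beyond the
  dosage factor; strong capture or mappability bias would shift Rx
  without widening its CI.
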