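---
title: "Whole-genome variant association for breed-defining recessive traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome variant association for breed-defining recessive traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgva)
```

## The problem this package addresses

Some traits define entire dog breeds: every member of a handful of closely
related breeds carries them, and almost no dog outside those breeds does. A
truncated, kinked tail built from malformed and fused caudal vertebrae
("screw tail") is one such trait. For a recessive, breed-fixed variant the
classical array-GWAS-then-fine-map strategy is unnecessary: with
whole-genome sequence for on the order of a hundred dogs, one can test
*every* bi-allelic variant directly and expect the causative site to be the
single most differentiated, most associated variant in the genome.

The statistical obstacle is stratification. Cases and controls are entire
breeds, so every variant that drifted apart between breeds is associated
with the phenotype; genomic inflation factors above 3 are expected rather
than pathological. `wgva` implements the complete screen for this setting:

1. **Site-level hard filtering** of GATK-style annotations, restriction to
   bi-allelic variants on characterized chromosomes, and recoding of indel
   alleles to single characters so association treats all variants
   uniformly.
2. **Cohort QC**: missingness and minor-allele-frequency filters,
   identity-by-state (IBS) distances with a UPGMA dendrogram, LD pruning by
   variance inflation factor (VIF), and a trio Mendelian-error audit as a
   genotyping-accuracy index.
3. **Allelic association** (1-df Pearson chi-square on allele counts) with
   **genomic control** and **Bonferroni correction over the pruned
   haplotype count**.
4. A **fixation scan** selecting variants with case/control allelic
   difference above 90% and assembling them into candidate regions ranked
   by span, mirroring the prioritisation of long runs of fixed variants as
   evidence of identity-by-descent.
5. **Segregation and penetrance tables** with exact tests.
6. A **frameshift consequence caller** that translates a coding indel
   through the 3'UTR and reports the first affected residue, the novel
   residue run, and the truncation or extension of the protein.

A synthetic cohort generator stands in for real genomes, so every stage is
exercised by tests with known ground truth.

## The models and statistics

### Balding–Nichols breed structure

Breed `b`'s alternate-allele frequency at a variant with ancestral
frequency `p` is drawn from

$$q_b \sim \mathrm{Beta}\!\left(\frac{p(1-F)}{F},\ \frac{(1-p)(1-F)}{F}\right),$$

which has mean `p` and variance `F·p(1−p)`. `F` is the divergence (FST)
parameter; `F = 0` returns `p` exactly, and the degenerate frequencies 0
and 1 stay fixed. Genotypes are Hardy–Weinberg within breed. The default
`F = 0.25` is on the scale observed between closed dog breeds and puts the
cohort in the strong-inflation regime (`λ ≈ 2.5–3.5` with the default
design) that motivates genomic control.

### Linkage disequilibrium

Real dog genomes carry megabase-scale LD. The generator emulates it
cheaply: variants are tiled into blocks of `ld_block_size` (default 10)
that share breed frequencies, and each genotype cell copies a latent
per-sample block genotype with probability `ld_rho` (default 0.9, giving
pairwise within-block genotype correlation around `ld_rho²`). This is
sufficient to give VIF pruning real work to do; it makes no attempt at
coalescent realism, recombination maps, or decay of LD with distance.

### The allelic test and genomic control

For allele counts `a, b` (case alt/ref) and `c, d` (control alt/ref),

$$\chi^2 = \frac{N(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)}, \qquad N = a+b+c+d,$$

with 1 df. A perfectly separated table (`b = c = 0`) attains `χ² = N`
exactly, which is why a fully genotyped causal variant is the top hit by
construction. Genomic control estimates the inflation factor λ as the
*mean* of the statistics (default, following the rationale that most
variants are null so the mean should be 1) or as `median/0.4549364`; the
statistics are divided by λ (floored at 1 so deflated cohorts are not
inflated) and p-values recomputed from the χ²₁ upper tail. Bonferroni
correction divides α by the number of *independent* tests, taken as the
size of the VIF-pruned set because variants on one haplotype share their
association signal; the full tested count can be substituted via
`n_tests`.

### VIF pruning

Within a sliding window (defaults 50 variants, step 5, threshold 2) the
variance inflation factor of variant `j` is `1/(1−R²_j)`, with `R²_j` the
squared multiple correlation of `j`'s mean-imputed dosage on the other
currently kept window variants. While any VIF exceeds the threshold the
worst variant is removed (ties: larger index). Two implementation choices
are deliberate:

* VIFs are computed as the diagonal of the inverse correlation matrix,
  with a QR least-squares fallback when that matrix is singular; perfect
  collinearity (`R² ≥ 1 − 10⁻¹²`) maps to infinite VIF, so exact
  duplicates always lose exactly one copy.
* Whole passes over each chromosome repeat until no variant is removed.
  A single sliding pass is not idempotent (windows shift when variants
  vanish); iterating to a fixed point makes pruning the kept set a no-op,
  which is the behaviour a pruned list should have.

### Mendelian-error audit

A trio-site is an error when the offspring dosage cannot be assembled from
one allele per parent. The per-meiosis rate divides errors by two meioses
per evaluated trio-site. Only about a third of uniform dosage
substitutions are detectable this way per meiosis, which is why the
generator's `genotype_error_rate` default (0.115) is deliberately larger
than the ~4% detected rate it is calibrated to produce.

### Exact tests

`fisher_exact()` uses the hypergeometric distribution over tables with
fixed margins; the two-sided p-value sums all tables whose point
probability is at most the observed one, with a relative comparison
tolerance of 10⁻¹² to make the inclusion boundary deterministic under
floating-point evaluation. The genotypic segregation test enumerates the
full r×2 table space, which is exact and fast at pedigree-scale counts.

### Frameshift consequence calls

The caller translates the wild-type CDS and the mutant sequence from the
CDS start *through the 3'UTR*, because a frameshifted stop routinely lies
beyond the wild-type stop. It reports the first divergent residue, the
count of novel residues before the new stop (`n_altered`), and
`truncation = wt_length − mutant_length` (negative for extensions), with
the invariant `mutant_length = fs_position − 1 + n_altered` whenever a
stop is found. Two notations are rendered because two counting
conventions coexist for frameshifts: strict HGVS counts the stop itself
(`fsTer{n_altered+1}`), while the `fsX{n_altered}` form counts only novel
residues. The structured fields are the source of truth; transcripts whose
shifted frame never reaches a stop return a flagged, non-failing call.

## The synthetic cohort as study conditions

The generator's defaults describe the mapping design the pipeline is meant
for, and are not intended to be tuned per run:

| parameter | default | rationale |
|---|---|---|
| breeds / sizes | 21 breeds; 5+3+2 case dogs, 18×5 controls | ~100-dog cohort, 10 cases from 3 related breeds |
| `breed_fst` | 0.25 | closed-breed divergence; strong-inflation regime |
| `missing_rate` | 0.064 | ~93.6% total genotyping rate |
| `n_trios` | 6 | trio audit of genotyping accuracy |
| `genotype_error_rate` | 0.115 | detected per-meiosis Mendel rate ≈ 4% |
| `annotation_fail_rate` | 0.02/field | ~13% of SNPs fail ≥1 hard filter |
| causal spec | case freq 1, control freq 0 | breed-fixed recessive variant, fully separated |
| causal flank | 10 variants/side at 0.95/0.02 | the long fixed haplotype around the causal site |

The causal site itself is written as a 1-bp deletion with pass-region
annotations and full genotyping: it models the genuine, well-supported
variant the screen exists to find, while background sites carry the
cohort's missingness and annotation contamination. The flanking sweep is
deliberately weaker than the causal site so the causal variant is the
unique maximum of the association statistic while still giving the
fixation scan a multi-variant region to assemble.

What the generator does **not** emulate: read-level evidence, alignment
artefacts, coalescent LD structure, recombination, related individuals
beyond the explicit trios, and realistic allele-frequency spectra (ancestral
frequencies are uniform on [0.05, 0.95]). Passing tests therefore
demonstrate that the statistical machinery is correct under its stated
model, not that the pipeline is robust to every artefact of real
sequencing data.

## Numerical and degenerate-input choices

* Hard-filter inequalities are strict, so a site exactly at a threshold
  passes; a missing annotation skips that criterion (with a message)
  rather than failing the site.
* Zero-marginal allele tables give `χ² = 0, p = 1` instead of `NaN`,
  keeping result tables rectangular.
* Missingness strictly above `max_missing` removes a variant; MAF exactly
  at `min_maf` keeps it; allelic difference exactly at `min_diff` fails
  the fixation filter (all matching the quoted inequality directions).
* IBS distance requires at least one overlapping non-missing site per
  pair and reports offending pairs by id.
* Indel recoding always maps ref→A, alt→T; any fixed injective assignment
  preserves the allelic contrast, and a deterministic one keeps output
  byte-reproducible.
* Penetrance keeps the full-precision fraction alongside a one-decimal
  round-half-up display value (published tables sometimes truncate
  instead; 47/51 is 92.16%, displayed there as 92.1, here as 92.2).

## Scale of the shipped checks

The test-suite and acceptance-script problem sizes are chosen as the
package's own verification scale: cohorts of 20,000 variants × 106 samples
for the 20-seed end-to-end recovery runs, 100,000 draws for
genomic-control calibration, every 2×2 table with total ≤ 40 for the
exact-test oracle, 50 random 8-variant windows for the pruning oracle, and
1,000 random transcript/deletion pairs for the consequence caller. The
heavy pieces (IBS at full variant count, VIF pruning of millions of sites)
scale linearly in variants and are exercised at representative sizes.

## Known limitations

* The association model is the plain allelic test plus genomic control —
  no mixed models, covariates, or permutation; this is a deliberate match
  to the breed-fixed recessive design, where relatedness *is* the signal
  and mixed models would absorb it.
* Candidate regions are chains of individually fixed variants, not formal
  runs-of-homozygosity or haplotype-based segments.
* The consequence caller handles single-transcript, CDS-internal
  variants; splice sites, UTR variants and multi-transcript annotation are
  out of scope.
* `fisher_exact()` and the r×2 enumeration are exact but combinatorial;
  they are meant for pedigree-scale counts, not genome-wide use.
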