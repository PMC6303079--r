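# wgva — whole-genome variant association for breed-defining recessive traits

`wgva` is an R package for mapping recessive, breed-defining traits by
case/control association over *all* bi-allelic variants called from
whole-genome sequence, in cohorts where cases and controls are entire
breeds and population stratification is therefore extreme. It was built
around the canine screw-tail mapping design — on the order of 100 dogs
from ~20 breeds, ~10 cases, a causal variant fixed in the case breeds and
essentially absent elsewhere — and ships a synthetic breed-structured
cohort generator so the whole pipeline is testable without real genomes.

## What it computes

For allele counts `a, b` (case alt/ref) and `c, d` (control alt/ref) at
each variant, the 1-df allelic chi-square

```
chi2 = N (ad − bc)² / [(a+b)(c+d)(a+c)(b+d)],   N = a+b+c+d
```

is corrected for genomic inflation by dividing all statistics by
`λ = mean(chi2)` (genomic control; `median/0.4549` also available) and for
multiple testing by Bonferroni over the number of LD-independent
haplotypes, estimated as the variant count surviving variance-inflation-
factor pruning (`VIF_j = 1/(1−R²_j) ≤ 2` in 50-variant windows stepping
by 5). Around the association sit the standard stages of the screen:
GATK-style hard filters (`QD < 2`, `FS > 60`, `SOR > 4`,
`ReadPosRankSum < −8`, `DP > 3105`; `MQ < 40`, `MQRankSum < −12.5` for
SNPs; `InbreedingCoeff < −0.8` for indels), indel-to-SNP allele recoding,
missingness/MAF filters, identity-by-state dendrograms, trio
Mendelian-error audits, a >90% allelic-difference fixation scan that
assembles candidate regions, exact segregation/penetrance tables, and a
frameshift consequence caller (`p.Pro684LeufsX26`-style calls from a
transcript sequence and a coding indel).

## A worked example

```r
library(wgva)
cfg <- run_config(n_variants = 4000, seed = 11,
                  out_prefix = file.path(tempdir(), "demo", "run"))
res <- run_all(cfg)
#> simulate: 4000 variants x 106 samples
#> filter: 532 sites failed hard filters; 3468 retained
#> prune: 384 of 812 QC-subset variants kept at VIF 2.0
#> mendel: 4.782% errors per meiosis over 6 trios
#> assoc filters: 519 removed by missingness, 1 by MAF, 2948 tested
#> assoc: lambda = 3.3769; raw-p threshold at alpha 0.05 = 2.05e-12
#> scan: 13 passing variants in 1 candidate regions
#> segregate: top variant chr5:265000, recessive exact p = 3.14e-14

print(res$assoc)
#> wgva_assoc: 2948 variants, lambda = 3.3769 (mean), n_tests = 384
#> top hit: chr5:265000  chi2 = 200.00  p_gc = 1.41e-14  p_bonf = 5.4e-12
```

Reading the output: the simulated breed structure inflates the null
statistics more than three-fold (`lambda = 3.3769`), exactly the regime
genomic control is for. The implanted causal deletion at `chr5:265000` is
fully separated — homozygous alternate in all 10 cases, absent from
controls — so its chi-square equals the total allele count (200 for 100
genotyped founders), the genome-wide maximum by construction. It survives
Bonferroni correction over the 384 pruned haplotypes (`p_bonf = 5.4e-12`)
and sits inside the single candidate region the fixation scan assembles
(chr5:220000–315000, 13 member variants). The per-meiosis trio error rate
(~4.8% here) audits genotyping accuracy. Segregation of the top variant
with phenotype gives an exact recessive-model p of 3.1e-14.

Individual stages are plain functions (`apply_hard_filters()`,
`vif_prune()`, `run_association()`, `fixation_filter()` +
`build_regions()`, `fisher_exact()`, `call_consequence()`, …) usable on
any dosage matrix / variant table, e.g. one read from a VCF with
`read_vcf()`. A thin command-line wrapper (`exec/wgva`) exposes
`run`, `simulate`, `filter`, `assoc`, `scan` and `csq` subcommands.

```r
penetrance(20, 24)
#> penetrance: 20/44 = 45.5%
```

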