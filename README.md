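# regulomine

Mining GATA1-driven regulatory sites in blood-group genes, and the cohort
genetics to validate them.

## What problem this solves, and for whom

Expression levels of many blood-group antigens are controlled by the
erythroid transcription factor GATA1 through WGATAR-motif binding sites, and
single-nucleotide variants (SNVs) that disrupt such a site can produce
weak or near-null phenotypes — clinically relevant in transfusion medicine,
where a weakly expressed antigen can be mistyped as absent. `regulomine` is
for researchers who have ChIP-seq **peak calls** for an erythroid
transcription factor and want to go from there to *ranked, variant-annotated
candidate regulatory sites in blood-group genes*, and then to test a
candidate variant in genotyped human cohorts.

The package implements two connected toolkits, all tibble-in / tibble-out:

**Regulome mining** (`mine_candidates()` and its parts)

- replicate peak merging per dataset (coalesce intervals sharing ≥ 1 bp,
  max score), reference selection (most peaks), and per-reference-peak
  overlap counting `k` across datasets;
- PWM motif scanning from a JASPAR-format count matrix with log₂-odds
  scores `w = log2((n + c·b) / ((N + c)·b))`, JASPAR-style relative scores
  `(s − s_min)/(s_max − s_min)`, and FIMO-style exact p-values by
  dynamic-programming convolution of the column score distributions;
- gene annotation (body / promoter window / nearest TSS), blood-group
  filtering with excluded-TF removal, and ranking by `(k, peak score,
  motif score)`;
- variant impact: strand-aware REF→ALT substitution inside motif windows,
  Δ relative score, core-column flags, and Hardy–Weinberg AF² triage
  against a phenotype prevalence.

**Cohort genetics** (`run_ld()`, `run_assoc()` and their parts)

- two-locus haplotype frequencies from unphased 0/1/2 dose genotypes, by
  the double-heterozygote counting rule (double heterozygotes assumed to
  carry the common haplotypes) or by EM;
- linkage disequilibrium `D`, `D′ = |D|/D_max`, `r² = D²/(p_A p_a p_B p_b)`,
  with the exact convention that an absent haplotype gives `D′ = 1`;
- genotype-dose association: geometric MFI, one-way ANOVA with Bonferroni
  post-hoc pairwise t tests, OLS dose regression with 95% CIs (and a
  deliberate rank-deficiency error when the two loci are in complete LD),
  ΔΔCt with calibrator normalization, and paired-t luciferase ratio
  analysis.

A first-class synthetic-data module (`simulation_manifest()`,
`simulate_bundle()`) emits complete ground-truth input bundles — FASTA
genome with planted motifs, four narrowPeak datasets, gene BED, VCF with a
motif-disrupting SNV at minor allele frequency 0.157, and an n = 396 cohort
with a dose-dependent expression effect — so the whole pipeline is testable
offline. Fitted objects have `tidy()` / `glance()` methods and `autoplot()`
ggplot views.

## Worked example

```r
library(regulomine)
library(dplyr)

manifest <- simulation_manifest(seed = 7)
paths <- simulate_bundle(manifest, "bundle")

peaks <- bind_rows(lapply(names(paths$peaks), function(id) {
  read_narrowpeak(paths$peaks[[id]], dataset_id = id)
}))
res <- mine_candidates(
  peaks,
  genome   = read_fasta(paths$genome),
  genes    = read_gene_bed(paths$genes),
  pfm      = read_jaspar_pfm(paths$pwm),
  variants = read_vcf_lite(paths$vcf)
)
res$candidates[, c("rank", "start", "end", "k", "assigned_gene", "best_relative_score")]
#>    rank start   end     k assigned_gene best_relative_score
#> 1     1  3869  4191     4 BG1                             1
#> 2     2 13364 13656     4 BG2                             1
#> 3     3  4602  4849     4 BG1                             1
```

All three true planted sites are recovered with overlaps in all four
datasets (`k = 4`); the decoys planted in an excluded-TF gene and a
non-blood-group gene were filtered out with logged reasons. The two `BG1`
sites are the planted motif pair 710 bp apart. The impact table ranks the
planted causal SNV first:

```r
res$impacts[, c("id", "rel_wt", "rel_mut", "delta", "hom_freq", "fit")]
#> 1 snv_motif2      1   0.827 0.173  2.46e- 2 candidate_fit
#> 2 snv_motif1      1   0.867 0.133  1.72e-10 too_rare
```

`snv_motif2` (MAF 0.157) drops the motif's relative score by 0.173 and its
expected homozygote frequency AF² ≈ 0.025 is compatible with a ~1%
phenotype prevalence, while `snv_motif1` is three orders of magnitude too
rare to explain it. The cohort side recovers the planted genetics:

```r
cohort <- readr::read_tsv(paths$cohort)
glance(run_ld(cohort))
#>    p_AB   p_Ab   p_aB  p_ab     D D_prime r_squared   mode n_separable
#> 1 0.816 0.0139 0.0101 0.160 0.131   0.928     0.839 paper-rule       19

tidy(run_assoc(cohort, calibrator = manifest$calibrator_dct)) |>
  filter(term != "(Intercept)")
#>   outcome term        estimate  p_value
#> 1 log_mfi dose_locus1  -0.546  6.9e-12   # planted effect -0.5: recovered
#> 2 log_mfi dose_locus2  -0.0000055  1.0   # no direct effect: null
#> 3 ddct    dose_locus1   0.662  1.6e-15   # planted +0.8 cycles per dose
#> 4 ddct    dose_locus2   0.083  0.31
```

Expression falls dose-dependently with the locus-1 minor allele at both the
protein (MFI) and transcript (ΔΔCt) level, while locus 2 — associated only
through linkage — is correctly null once locus 1 is in the model.

## Command line

A thin wrapper (`inst/cli/regulomine`) exposes the same pipeline as
subcommands:

```sh
regulomine simulate --seed 7 --out bundle/
regulomine mine --peaks d1=bundle/peaks_d1.narrowPeak ... \
    --genome bundle/genome.fa --genes bundle/genes.bed \
    --pwm bundle/pwm.jaspar --vcf bundle/variants.vcf --out candidates.tsv
regulomine ld --genotypes bundle/cohort.tsv --out ld.tsv
regulomine assoc --cohort bundle/cohort.tsv --calibrator 4 --out assoc.tsv
```

Every report carries a commented `# key=value` header with the package
version, seed and configuration hash; identical seeds give byte-identical
simulation bundles.

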