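---
title: "Methods: mining a GATA1-driven blood-group regulome and testing its cohort genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining a GATA1-driven blood-group regulome and testing its cohort genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulomine)
library(dplyr)
```

## The scientific problem

Erythroid expression of many blood-group genes is driven by the
transcription factor GATA1, which binds a degenerate WGATAR DNA motif.
Single-nucleotide variants (SNVs) that disrupt a GATA1-binding site can
silence or attenuate a blood-group gene without touching its coding
sequence — the mechanism behind the Duffy-negative phenotype and, in the
use case this package is modelled on, the very-low-CR1 "Helgeson"
phenotype of the Knops blood-group system. Finding such regulatory sites
means combining three kinds of evidence:

1. **ChIP-seq consensus.** A genomic interval repeatedly bound by GATA1
   across independent ChIP-seq experiments is more credible than a
   single-dataset peak. `regulomine` consumes called peak files (narrowPeak
   or BED6), merges replicates per dataset, takes the dataset with the most
   peaks as the reference, and counts for each reference peak how many
   datasets overlap it by at least one base (`k`).
2. **Motif evidence.** Within candidate intervals, a position weight matrix
   (PWM) built from a count matrix localizes and scores GATA-type motifs,
   with JASPAR-style relative scores and FIMO-style exact p-values.
3. **Variant impact.** SNVs intersected with motif occurrences are scored
   by the change in relative score between the reference and alternate
   allele, and triaged by whether their Hardy–Weinberg homozygote frequency
   (AF²) could plausibly account for a phenotype prevalence.

A companion cohort-genetics toolkit covers the statistical analyses used to
validate such a candidate in human cohorts: two-locus haplotype frequency
estimation, linkage disequilibrium (D′, r²), and genotype-dose association
with expression readouts (geometric mean fluorescence intensity from flow
cytometry, ΔΔCt from qPCR, firefly/Renilla luciferase ratios).

## Models and conventions

### Coordinates

All internal coordinates are 0-based half-open, the BED/BEDtools
convention. Conversion happens only at I/O boundaries: VCF positions are
decremented on read, FASTA substrings are extracted with 1-based helpers
internally. Overlap everywhere means "at least one shared base", matching
`bedtools intersect` defaults.

### The PWM scoring model

From a count matrix with column totals $N_j$, background base
probabilities $b$ and pseudocount $c$ the log-odds weight of base $\beta$
at position $j$ is

$$w_{j\beta} = \log_2 \frac{(n_{j\beta} + c\, b_\beta)}
                           {(N_j + c)\, b_\beta}.$$

A window scores $s = \sum_j w_{j,\text{window}_j}$ and its **relative
score** is $(s - s_{\min}) / (s_{\max} - s_{\min})$, where $s_{\min}$ and
$s_{\max}$ are the column-wise minimal/maximal totals; the consensus window
scores exactly 1 and the anti-consensus exactly 0. Relative scores are
invariant to the log base, so the choice of bits is cosmetic.

Defaults: pseudocount 0.8 distributed proportionally to the background, and
a uniform background — the common JASPAR/TFBS-tools convention — with a
scan threshold of relative score ≥ 0.8, the JASPAR web default. All three
are arguments, because published relative scores depend on the server-side
pseudocount and flank handling, which public interfaces do not always
document; reproducing a specific published value may require matching those
settings.

Exact p-values $P(S \ge s)$ under the background model are computed the way
FIMO does: each column's score distribution is discretized (default
granularity: $10^{-3}$ of the score range) and convolved column by column,
giving the full null distribution in $O(L \cdot \text{support})$. Just
above $s_{\max}$ the p-value is the probability mass of the top-scoring
window(s), never 0; at or below $s_{\min}$ it is 1. The suite verifies the
DP against exhaustive enumeration of all $4^L$ windows for matrices with
$L \le 6$.

Windows containing `N` are unscorable; scans skip and count them. Reverse
strand hits are found by scanning the reverse-complemented matrix and are
reported at their forward-strand interval with strand `-`; the stored
window is always in motif orientation, which makes the strand-aware variant
substitution unambiguous.

### Consensus peaks and gene assignment

Replicates are merged at peak level (coalescing intervals that share ≥ 1 bp,
keeping the maximum member score). Merging upstream BAM files and re-calling
peaks would require the raw reads; peak-level union is the deterministic
analogue and is recorded in the run configuration. The reference dataset is
the one with the most peaks (ties: lexicographically smallest id), and each
consensus site keeps the *reference peak's* interval — the overlap count is
a property of the reference peak, not of a cross-dataset union.

Gene assignment is deliberately simpler than annotation tools with
tool-internal priority schemes: gene body overlap first, then a
configurable strand-aware promoter window upstream of the TSS (default
2000 bp), then nearest TSS, with coordinate-order tie-breaks. Every rule is
stated, so every assignment is testable. Candidate filtering keeps sites in
blood-group genes and drops sites in excluded transcription-factor genes
(the KLF1/GATA1 class), logging each removal with its reason. Ranking is a
total order: overlap count `k` desc, reference peak score desc, best motif
relative score desc, then coordinates.

### Haplotypes and linkage disequilibrium

Genotypes are coded as minor-allele doses 0/1/2 per locus. Every two-locus
genotype except the double heterozygote (1,1) resolves into two haplotypes
uniquely; the default `"paper-rule"` estimator assigns all double
heterozygotes to the configuration (cis AB/ab vs trans Ab/aB) that is more
likely under the unambiguous-sample frequencies — i.e. it assumes double
heterozygotes carry the common haplotypes — with ties going to cis and
logged. An EM estimator (`mode = "em"`) iterates the standard two-locus
update to the maximum-likelihood frequencies; it is initialized at the
counting-rule estimate, so EM's monotone ascent guarantees it never ends
below the rule's likelihood. With no double heterozygotes both reduce to
direct gamete counting and the mode is reported as `"direct"`.

From haplotype frequencies, $D = p_{AB} - p_A p_B$,
$D_{\max} = \min(p_A p_b,\, p_a p_B)$ for $D > 0$ (else
$\min(p_A p_B,\, p_a p_b)$), $D' = |D| / D_{\max}$ reported non-negative,
and $r^2 = D^2 / (p_A p_a p_B p_b)$. When any haplotype frequency is zero,
$|D|$ attains $D_{\max}$, so `compute_ld()` returns $D' = 1$ exactly rather
than as a floating-point ratio; when $D = 0$ without an absent haplotype,
$D' = 0$. A monomorphic locus leaves $r^2$ undefined (`NA` with a warning)
rather than silently dividing by zero. $r^2 \le D'^2$ holds for every valid
frequency vector since $\min(x, y)^2 \le xy$; the suite asserts it over
10⁴ random simplex draws.

### Association statistics

- **Geometric MFI** is `exp(mean(log(x)))` over strictly positive values;
  filtering non-positive events is the caller's explicit decision.
- **ANOVA** across genotype groups is the classic equal-variance one-way
  analysis, followed by all pairwise two-sided pooled-variance t tests with
  Bonferroni adjustment (m = number of pairs, capped at 1). All-constant
  input degenerates to F = 0, p = 1 instead of erroring.
- **Dose regression** fits `y ~ dose1 + dose2` by OLS with t-based 95% CIs
  and no multiplicity adjustment. Identical dose columns (loci in complete
  LD, the situation in a cohort where the two markers never separate) make
  the design rank-deficient; the error says so and points to a single-locus
  analysis, which the `run_assoc()` driver then performs automatically.
  Because the simulated MFI effect is multiplicative, the driver regresses
  log geometric MFI; ΔΔCt is already on an additive (cycles) scale.
- **ΔΔCt** is `mean(target Ct) − mean(reference Ct) − calibrator ΔCt`. The
  sign convention is fixed: lower ΔΔCt means higher target expression. No
  claim is made about the axis orientation of any particular published
  figure.
- **Luciferase ratios** are firefly/Renilla per well, averaged per
  independent experiment, scaled to the baseline construct, and compared by
  a two-sided paired t test on experiment means. All-zero paired
  differences are reported as p = 1 with a degenerate flag rather than an
  error, so edge-case constructs cannot crash a pipeline. Ratios are not
  scale-invariant in Renilla — doubling all Renilla values halves ratios —
  which is documented rather than "fixed".

## The synthetic study design

`simulation_manifest()` pins the default conditions to the shape of the
study the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| datasets K | 4 | ChIP-seq experiments, reference = most peaks |
| planted sites | 5 | two motifs 710 bp apart in a CR1-like gene (one on the minus strand), one site in a second blood-group gene, one decoy in an excluded-TF gene, one decoy in a non-blood-group gene |
| genome | 30 kb, GC 0.41 | i.i.d. background at genome-like GC |
| peak width / jitter | 300 bp / σ = 25 bp | Normal end jitter, kept valid |
| miss rate / false peaks | 0 / 6 per dataset | false peaks constructively avoid motifs |
| causal SNV | T>C, MAF 0.157 | second core position of the minus-strand motif (GATA→GGTA in motif space) |
| rare SNV | G>A, MAF 1.31×10⁻⁵ | first core position of motif 1 (GATA→AATA) |
| cohort | n = 396 | haplotype frequencies (0.828, 0.015, 0.010, 0.147) so the locus-1 MAF is 0.157 |
| expression | β₁ = −0.5 per dose (log MFI), β_ct = +0.8 cycles | locus 2 has no direct effect; any signal it shows arises through LD |

Motif instances are planted as the consensus window (relative score 1).
After planting, the background is re-randomized wherever a chance window
scores ≥ 0.9 relative, so "scan at 0.95 finds exactly the planted sites" is
a constructive guarantee and the ground truth is unambiguous; overlapping
planted motifs are an error for the same reason. MFI noise is lognormal
(flow-cytometry-like); Ct triplicates carry Normal replicate noise scaled
so the realized ΔΔCt noise SD equals the stated σ_ct. Haplotypes are drawn
under Hardy–Weinberg random mating.

The shipped count matrix (`gata1_synthetic_pfm()`) is an 11-column
GATA-type matrix whose four highest-information columns spell GATA with W/R
flanks. It is a synthetic construction for simulation and testing — not a
database matrix — and any JASPAR-format matrix can be supplied instead.

What the simulation does **not** emulate: read-level ChIP-seq artefacts,
LD decay along real chromosomes, population structure or genotyping error.
Passing the recovery tests therefore demonstrates the correctness of the
algorithms under the stated generative model, not performance on real
peak-caller output.

### Determinism

Every simulation call sets the RNG kind explicitly
(Mersenne-Twister/Inversion/Rejection), so identical manifests give
byte-identical bundles across platforms; the seed and the hash of the
resolved configuration are embedded in every report header.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data at desk scale: oracle
equivalences use 100–200 random instances of up to 10³ intervals,
exhaustive PWM enumeration uses matrices of length ≤ 6 (≤ 4096 windows),
LD identities use 10⁴ simplex draws, and parameter-recovery uses 500
cohort replicates of n = 396 plus ~100-replicate Monte-Carlo checks of the
allele-frequency and separability expectations. These sizes were chosen so
the binomial/Monte-Carlo error bounds in the assertions are meaningful
while the whole suite stays fast.

## Known limitations

- Gene assignment is a stated approximation, not a re-implementation of any
  specific annotation tool's priority scheme.
- Published relative scores from motif servers depend on server-side
  settings (pseudocount, flanks); reproducing a specific printed value
  requires matching them, which is why both are exposed.
- The double-heterozygote counting rule is biased toward the cis
  configuration when LD is weak; the EM mode exists precisely as the
  sensitivity check, and the likelihood comparison between the two is part
  of the result object.
- Only SNVs are impact-scored; indels overlapping motifs are reported but
  not scored.
- Reproducing external-data results (database matrices on a real genome
  build, phased reference-panel LD, full ChIP-seq reruns from public
  accessions) requires those external inputs and pinned tool versions;
  they are documented reproduction goals, not part of the offline suite.

## A worked example

```{r example, message = FALSE, warning = FALSE}
manifest <- simulation_manifest(seed = 7)
dir <- file.path(tempdir(), "bundle")
paths <- simulate_bundle(manifest, dir)

peaks <- bind_rows(lapply(names(paths$peaks), function(id) {
  read_narrowpeak(paths$peaks[[id]], dataset_id = id)
}))
res <- mine_candidates(
  peaks,
  genome = read_fasta(paths$genome),
  genes = read_gene_bed(paths$genes),
  pfm = read_jaspar_pfm(paths$pwm),
  variants = read_vcf_lite(paths$vcf)
)
res$candidates
res$impacts[, c("id", "rel_wt", "rel_mut", "delta", "fit")]

cohort <- readr::read_tsv(paths$cohort, show_col_types = FALSE)
glance(run_ld(cohort))
tidy(run_assoc(cohort, calibrator = manifest$calibrator_dct))
```
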