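---
title: "Methods: SV genotype concordance and cis-eQTL mapping in inbred cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV genotype concordance and cis-eQTL mapping in inbred cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sveqtl)
```

## Setting

`sveqtl` targets a study design that is becoming standard in crop
genomics: a panel of highly inbred lines, all with short-read whole-genome
and RNA-seq data, of which a subset also has long-read data. Long reads
yield reliable per-sample structural-variant (SV) genotypes; these serve
as a *truth set* against which graph-based short-read genotyping of the
same samples can be scored variant by variant. The SVs that survive this
screen, together with SNPs, then enter a joint cis-eQTL scan against leaf
expression.

Because the lines are inbred, genotypes are modelled as a two-state system
(homozygous reference / homozygous alternative). Heterozygous calls do
occur in real data but are overwhelmingly genotyping artefacts in this
material, and the package treats them as missing throughout the
concordance machinery.

## Dual-perspective F1 concordance

For one variant and one allele perspective, each sample that is
non-missing in both the truth and the test vector contributes to a
confusion matrix; for the ALT perspective a positive call is
`ALT_HOM`, for the REF perspective `REF_HOM`. The score is

$$F1 = \frac{2\,TP}{2\,TP + FP + FN},$$

the harmonic mean of precision and recall. Scoring both perspectives
matters because they respond differently to allele frequency: a variant
whose two ALT carriers are both recovered, plus one spurious ALT call,
scores 0.8 from the ALT side but 108/109 ≈ 0.99 from the REF side
(`worked_example_genotypes()` reproduces this case over 57 lines).

Conventions, chosen where the definition alone does not decide:

* **Vacuous case.** If TP = FP = FN = 0 (no positive call anywhere, e.g. a
  variant monomorphic for the other allele), F1 is defined as 1.
  Agreement is perfect; returning 0 would misclassify monomorphic
  variants as genotyping failures.
* **Missing rate.** The denominator is all samples; the numerator counts
  samples missing — after mapping heterozygous calls to missing — in
  *either* vector, since a sample informs the comparison only when both
  calls exist. A joint-missing rate above 20% sets both F1 values to 0
  regardless of the agreement among the remaining samples: variants that
  largely fail to genotype are failures even if the residue agrees.
* **Quality bands.** HIGH (correctly genotyped) requires F1 ≥ 0.8 on
  *both* perspectives; LOW (poorly genotyped) is triggered by F1 ≤ 0.2 on
  *either*; everything else is INTERMEDIATE. With these bands the two
  conditions cannot overlap.

`compare_groups()` contrasts HIGH vs LOW variants on length, genome copy
number, breakpoint/length confidence-interval widths and gene proximity.
Copy number is the count of merged local-alignment hits of the SV sequence
against a genome (blastn, E ≤ 1e-5; hits overlapping by more than half of
the shorter hit are merged). Rank-sum (Mann–Whitney) tests are used for
the continuous features — the distributions are strongly skewed, so a
non-parametric comparison is the safe default; the gene-proximal fraction
uses a chi-square test.

## Variant QC

The post-calling filters use strict inequalities exactly as conventionally
stated: missing rate < 5%, heterozygous rate < 5%, SNP MAF > 5%; SVs
longer than 20 kb are removed (a 20,000 bp variant is retained). The
association-stage MAF filter is inclusive (MAF ≥ threshold) and also
requires the minor allele in at least five samples; whether the SNP-stage
5% was meant strictly or inclusively is genuinely ambiguous at n = 100,
so the comparison mode is a configuration switch (`maf_strict`). MAF is
computed over non-missing calls with additive dosage; HET calls count one
ALT allele and count toward the het-rate numerator.

## Quantification concordance and permutation enrichment

Two quantifications of the same RNA-seq samples (e.g. a linear-reference
and a pangenome-graph quantifier) are compared per transcript by Pearson
and Spearman correlation over shared samples; transcripts constant in
either matrix have no defined correlation and are excluded. Transcripts
with Pearson r below 0.75 form the discordant set; an equal number of
top-correlated transcripts forms the matched concordant set.

The enrichment statistic is the total count of variants overlapping the
transcript set, with transcript intervals taken as gene body ± 1 kb. Each
permutation draws an equally sized transcript set from the universe
without replacement. Whether such a test should count overlapping
variants or overlapping transcripts is not decided by the method itself;
counting variants is the package default because it is strictly more
informative (a transcript hit 12 times counts 12), and the per-transcript
counts are exposed so either statistic can be formed. The p-value uses the
small-sample correction $p = (1 + \#\{perm \ge obs\})/(n_{perm}+1)$, so
100 iterations can never report p = 0; the floor is 1/101. Depletion uses
the mirrored tail.

## cis-eQTL scan

* **Expression filter**: mean TPM ≥ 0.1 and ≥ 1 TPM in at least two
  samples.
* **Inverse normal transformation (INT)**: per transcript, values are
  ranked (ties averaged) and mapped through
  $\Phi^{-1}((r - 3/8)/(n + 1/4))$ — the Blom offset, the common choice
  for expression data. The output is monotone in the input and has mean
  ≈ 0 per transcript.
* **Covariates**: the top five principal components of the centred SNP
  dosage matrix absorb population structure; expression PCs absorb hidden
  technical and biological factors. The number of expression PCs is
  chosen by a scree elbow rule made fully deterministic: the elbow is the
  scree point with maximum perpendicular distance to the chord joining
  the first and last scree points (computed on axes normalised to the
  unit square). When that farthest point lies *below* the chord it is the
  first component of the noise floor, so the retained count stops one
  short of it — with k strong planted factors this returns exactly k,
  whereas the raw arg-max would systematically return k + 1. A scree with
  no elbow (collinear points) yields the minimal model of one component.
* **Model**: for each candidate transcript–variant pair, ordinary least
  squares of INT expression on additive dosage (0/1/2; missing dosages
  mean-imputed per variant, the standard matrix-scan behaviour) plus
  covariates and intercept. The implementation projects the covariates
  out of both sides once per scan (Frisch–Waugh), which is algebraically
  identical to the full per-pair regression; tests verify equality with
  a per-pair `lm()` oracle to 1e-8. The t statistic has `n − k − 2`
  degrees of freedom; p-values are two-sided; FDR is Benjamini–Hochberg
  across all tested pairs. Variants with zero dosage variance after
  imputation are skipped and logged.
* **Windows**: candidate pairs are restricted to variants within the gene
  body ± 100 kb (the testing window also used to compare scans between
  cohorts); final cis labels use the ± 3 kb definition. Declaring an eQTL
  requires FDR < 0.05 — a field default, exposed as an argument, since no
  single threshold is canonical.
* **cis classification** is strand-aware: promoter = 3 kb upstream of the
  TSS in transcription direction, downstream = 3 kb past the TTS; within
  the gene body, exon vs intron by interval membership. A variant
  spanning several features takes the label by precedence
  exon > intron > promoter > downstream, ranking coding impact above
  regulatory context; with this rule every position of the ± 3 kb
  neighbourhood maps to exactly one category (property-tested
  exhaustively on both strands, including the 3,000/3,001 bp boundary).
* **Lead variants** per transcript are the minimum-p associations; exact
  ties (a SNP and an SV with bitwise-equal p) are all retained.

## TE annotation

SV sequences are compared against a TE library by local alignment (NCBI
blastn, E-value cutoff 1e-5, dust masking disabled because synthetic and
repeat-derived sequences must not be filtered). The top-scoring hit
assigns the family; ties break by higher bitscore, then lower E-value,
then library order — the last step makes assignment deterministic, which
matters for reproducibility and is otherwise arbitrary. Families map to
Class I (retro: LTR, LINE, SINE, Copia, Gypsy) or Class II (DNA: TIR,
CACTA, Mutator, PIF-Harbinger, hAT, Tc1-Mariner, Helitron). Positional
confirmation between two annotation sets counts an interval as confirmed
when at least half its length (configurable) is covered by the other set,
the `-f 0.5` convention of interval tools; a threshold of 0 degenerates
to "any overlap".

## Effect summaries

Effect sizes (beta) are per ALT-dosage unit on the INT scale; for a
deletion the ALT allele is the deleted state, so a negative beta on an
insertion and a negative beta on a deletion mean opposite things for the
inserted sequence — this sign convention is what makes the
insertion-vs-deletion comparison interpretable. For the effect–frequency
trend, allele frequency is folded to minor allele frequency, and the
trend is the Spearman correlation of MAF with |beta| plus equal-width bin
means. Partial variance explained by a lead variant is
$(RSS_{reduced} - RSS_{full})/RSS_{reduced}$, which equals
$t^2/(t^2 + df)$ and is computed from the two model fits rather than the
identity so the identity can serve as an independent check.

## The synthetic cohort generator

`simulate_cohort()` generates the full input bundle under one seed:
truth and observed SV genotypes, a SNP panel, SV sequences, a TE library,
gene models, two expression matrices and ground-truth tables.

What it emulates, and the defaults' provenance:

* **Inbred genotypes**: two-state calls with residual heterozygosity
  (0.5%) and baseline missingness (1%); allele frequencies from a
  low-frequency-skewed Beta(0.6, 2) spectrum clipped to [0.02, 0.98];
  population structure as three subpopulations with Balding–Nichols
  divergence (Fst 0.1) so that genotype PCs are meaningful covariates.
* **The genotyping-error process**: a fraction of variants (default 36%,
  matching the reported share of poorly genotyped SVs for the better
  genotyper) is "poorly genotypable". Observed genotypes of that class
  receive symmetric REF/ALT flips (default rate 0.5) and elevated
  missingness (default 0.30). The elevated missingness is deliberate:
  failure to genotype — not merely wrong calls — is the dominant error
  mode for repeat-rich SVs, and it is exactly what the > 20% missing-rate
  rule encodes, so the resulting per-variant F1 distribution is bimodal
  (near 1 for the good class, 0 or near 0 for the poor class).
* **Class-linked features**: poor-class variants draw shorter lengths
  (log-normal medians 432 vs 776 bp), higher copy numbers (medians 5 vs
  4) and wider confidence intervals than good-class variants, matching
  the direction and, where reported, the magnitude of the real contrasts.
* **TE provenance**: 70% of SV sequences are fragments of TE-library
  entries (half of them Helitron, reflecting Helitron abundance in
  Brassica genomes) with 1% substitution divergence; fragments rather
  than full elements, since that is what SV breakpoints usually capture.
* **Expression**: latent log expression is hidden factors (3 factors,
  loading sd 0.55) plus Gaussian noise (sd 1) plus, for a causal subset
  of transcripts (15%), `beta_raw × centred dosage` of an SV placed in
  the transcript's cis window. `|beta_raw|` scales as
  `(maf/0.5)^(−0.5)` — rarer alleles get larger effects — and causal TE
  insertions are shifted by −0.5, implanting the expected
  insertion-repression signal. TPM values are a log-normal baseline times
  the exponentiated latent scale, so the rank-based INT recovers the
  latent structure exactly.
* **Two truth scales for beta.** The INT rescales every transcript to
  unit variance, so the estimable effect is
  `beta_int = beta_raw / sd(y)`, with `sd(y)` computed analytically per
  transcript from the implanted effect, factor loadings and noise.
  `SimTruth` records both; recovery tests compare estimates to
  `beta_int`, the scale on which unbiasedness is well defined.
* **LD structure**: real LD between SVs and SNPs is not reported for this
  kind of panel, so the generator exposes it as a knob instead of
  asserting a value: a configurable fraction of causal SVs (default 0.5)
  gets a nearby tag SNP copying its genotypes with a 5% mismatch rate;
  the rest are LD-free from all SNPs.
* **Quantification bias**: the second expression matrix equals the first
  except that transcripts overlapping SVs receive per-cell multiplicative
  log-normal noise (sd 1.0) — the simplest mechanism that makes
  variant-overlapping transcripts discordant between quantifiers and
  hence drives the permutation-enrichment signal.

What it does **not** emulate: read-level errors (no FASTQ), haplotype
blocks beyond the tag-SNP device, polyploid subgenome mapping ambiguity,
and any dependence of genotyping failure on sequence content (the poor
class is drawn independently of the TE status). Passing recovery tests on
these cohorts therefore demonstrates correctness of the statistical
machinery under the stated generative model, not performance on real
short-read data.

## Problem sizes and numerical choices in the test suite

The package's own validation uses desk-scale cohorts chosen to keep the
full suite fast while leaving every stage non-trivial: concordance and QC
properties on 60–150-sample, 150–1,500-variant cohorts; the
classification-band check on 500 SVs at the planted poor fraction 0.4;
the association-scan oracle on 200 random pairs (tolerance 1e-8) with a
1,000-pair permutation null (Kolmogorov–Smirnov calibration); parameter
recovery on the generator's default scale (100 samples, 2,000 SVs, 20,000
SNPs, 2,000 transcripts), requiring ≥ 80% of strong implanted effects
(|beta_raw| ≥ 1, MAF ≥ 0.1) recovered as leads at FDR 0.05 with mean
signed bias below 0.1. Permutation p-values are floor-bounded at
1/(n_perm + 1) by construction and all resampling is seeded.

## Known limitations

* The concordance score treats the long-read genotypes as error-free;
  truth-set errors deflate F1 symmetrically and are not modelled.
* Only biallelic insertions and deletions are supported; inversions,
  duplications, breakends and multi-allelic records are out of scope.
* The scan fits one variant at a time; conditional/secondary signals and
  trans effects are not searched.
* blastn is invoked as an external binary; E-values depend on its
  Karlin–Altschul parametrisation and the subject set supplied, so copy
  numbers are comparable within a run, not across databases.
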