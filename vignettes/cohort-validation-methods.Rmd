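---
title: "Methods: technical validation of cohort genotyping archives"
author: "cohortval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: technical validation of cohort genotyping archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortval)
```

# The problem

Cohort-scale genotyping archives — an array callset, imputed dosages,
HLA imputations, exome variant tables — are released to a community that
will not re-derive them from raw intensities or reads.  Before release,
a battery of technical validations establishes that the data behave as
genetics says they must: technical replicates reproduce each other,
nominally unrelated donors are in fact unrelated, inferred ancestry is
coherent with an external reference, imputed HLA agrees with sequenced
truth, risk scores behave additively, two genotyping platforms agree at
shared sites, and rare-variant prioritization recovers known findings.
`cohortval` packages this battery as reusable, seeded, testable code,
paired with a synthetic cohort generator so every check can be exercised
end-to-end with known ground truth and no controlled-access data.

# Data model

Hard calls live in a `GenotypeMatrix` (a `SummarizedExperiment`:
variants x samples, values 0/1/2 counting a recorded per-variant
*counted allele*, `NA` for missing — missingness is never conflated with
zero copies).  Imputed dosages live in a `DosageMatrix` (values in
[0, 2] plus per-variant imputation R^2^).  PLINK text and binary
filesets and VCF 4.2 (GT, DS, R2) are read and written; variant identity
for cross-platform merging is (chromosome, position, unordered allele
pair), because variant names differ across platforms.  At merge,
counted alleles are aligned by flipping calls (2 - g) where platforms
count opposite alleles; strand-complement ambiguous SNPs (A/T, C/G) are
dropped deterministically rather than rescued by frequency, and
irreconcilable allele pairs are dropped and counted, never fatal.

One subtlety of the text PLINK dialect: `.ped` stores unordered allele
pairs with no orientation metadata.  The writer places the counted
allele first in heterozygous calls, and the reader recovers the counted
allele from the first heterozygous sample (falling back to first-seen);
round trips are exact whenever a variant has at least one heterozygote.

# Quality control

Call rate is the non-missing fraction per sample, per variant and per
plate.  Defaults: sample >= 0.97, variant >= 0.95, plate mean >= 0.985,
with the plate mean computed over samples passing the sample threshold
(plate acceptance is judged on passing samples).  A vendor dish-QC
column is thresholded at 0.82 when supplied, never computed — it is
defined on raw intensities this package does not touch.

Sex is inferred directly from X-chromosome heterozygosity: the fraction
of non-missing X calls that are heterozygous, with defaults male below
0.05 and female above 0.20, ambiguous between.  A het-rate reading is
the most direct statistic for the screen and keeps both thresholds
user-visible; no population-frequency-dependent F statistic is fitted.
Ambiguous calls are never counted concordant.

Replicate agreement uses Bland–Altman: bias `mean(a - b)` and 95%
limits of agreement `bias ± 1.96 sd(a - b)`.  The standard deviation is
the sample (n − 1) form — the replicate sets this is used on are small,
and the choice is documented because the two conventions differ
noticeably at n = 24.

Cross-platform per-SNP concordance filters to autosomal, biallelic
variants with minor-allele count >= 1 in a designated callset, then
scores each variant as the fraction of samples non-missing in *both*
platforms whose calls agree (pairwise-complete denominator).  Variants
with no comparable calls are flagged rather than divided by zero.

# Relatedness

Pairwise kinship uses the robust heterozygote-concordance estimator:
over shared non-missing autosomal SNPs, with $N_{Aa,Aa}$ the count of
SNPs where both samples are heterozygous, $N_{AA,aa}$ the count of
opposite homozygotes and $N_{Aa}(s)$ each sample's heterozygote count,

$$\phi = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{2\min(N_{Aa}(a), N_{Aa}(b))}
  + \frac{1}{2} - \frac{N_{Aa}(a)+N_{Aa}(b)}{4\min(N_{Aa}(a), N_{Aa}(b))}.$$

Identical samples give exactly 1/2 (an identity asserted in the tests);
the estimator is symmetric because of the min.  Pairs where either
sample has no heterozygous call are undefined and excluded from
classification.  X variants are excluded (the estimator assumes
autosomal diploidy) and missing calls are skipped pairwise.  Only the
between-family robust form is implemented: the intended use is cohorts
of nominally unrelated donors.

Degrees are assigned on the lower-cutoff ladder $2^{-(2d+3)/2}$ for
$d = 0..3$: duplicate/MZ 0.354, first 0.177, second 0.0884, third
0.0442 — the geometric midpoints between expected kinship coefficients
of adjacent degrees.  A value exactly at a cutoff takes the
closer-related class, reading the cutoffs as lower bounds.

# Ancestry

LD pruning is greedy left-to-right within a sliding window (defaults:
50 SNPs, step 10, r^2^ > 0.1 removes the later variant, ties by lower
MAF).  Monomorphic variants have undefined correlation and are
retained without entering the computation.  The exact pruning order of
the classical tools is tool-internal behavior; this package documents
its own deterministic rule rather than replicating any tool bit for
bit.

The ancestry model is a K x M matrix F of per-population counted-allele
frequencies.  Because the reference panel is labeled, F is fitted
*supervised*: pseudocount-smoothed per-population sample frequencies
(pseudocount 0.5), clamped to [1e-4, 1 − 1e-4] to keep the projection
likelihood finite.  The classical workflow instead fits an unsupervised
K-cluster model and names clusters afterwards by their continental
majority; with labels available the supervised fit has the identical
downstream contract (an F matrix plus projection), is deterministic,
and removes label switching.  Cluster-to-continent assignment therefore
becomes an explicit labeled step rather than a post hoc one.

Projection maximizes, per sample, the binomial admixture log-likelihood
$\ell(q) = \sum_m g_m \log p_m + (2-g_m)\log(1-p_m)$ with
$p_m = \sum_k q_k f_{km}$, by EM on the simplex from a uniform start
(tolerance 1e-6 on max |Δq|, cap 1000 iterations, missing genotypes
skipped).  EM guarantees a non-decreasing likelihood and simplex-valid
iterates — both asserted in the tests, along with agreement within
1e-3 against a 1-D grid-search oracle at K = 2.  Samples with no
usable genotypes are flagged undefined; samples whose likelihood is
flat (identical rows of F) keep the uniform start and are flagged
non-identifiable.  Pure-population samples converge toward a simplex
corner, where EM slows; the iteration cap with the convergence flag
reported is the accepted trade-off.

PCA of the Q vectors is centered, with a deterministic sign convention
(largest-magnitude loading positive); the simplex constraint caps the
rank at K − 1.  Majority-ancestry assignment is argmax with first-index
tie-breaking and an explicit tie flag.

# HLA imputation scoring

Three scores compare imputed HLA calls (with per-allele probabilities)
against sequencing-derived typed truth, at 2-digit (allele group) or
4-digit (protein) resolution:

- locus accuracy $Acc(L) = \sum_i [P_i(A1) + P_i(A2)] / 2n$, with the
  probability of each discordant allele set to 0;
- genotype-of-interest concordance: imputed alleles matching a pattern
  (e.g. DRB1\*03:01, or DRB1\*04:xx where xx is any sub-allele),
  divided by typed alleles matching it, summed over donors;
- donor accuracy $Acc(S)$: the same probability average taken across
  the donor's typed loci (four by default), discordant probabilities
  zeroed, with the per-donor locus count reported when fewer loci are
  typed.

Concordance of a pair against a pair uses *multiset* matching: each
typed allele can absorb at most one imputed allele, and of the two
possible pairings the one maximizing concordant alleles is used.  Read
literally, set-membership scoring would let a homozygous imputed pair
double-claim a single typed allele, and would let the concordance
numerator exceed its denominator; the pairing cap keeps every score in
[0, 1].  For the same reason the genotype-of-interest numerator counts
an imputed matching allele only where a typed matching allele can
absorb it.  Homozygous typed genotypes contribute two alleles to the
denominators (alleles are counted, not donors).  Allele strings are
normalized (case, zero padding) and fields beyond the protein level are
truncated before comparison.  Missing imputed probabilities are scored
0 with a warning.

# Risk scores

The GRS engine is weight-table-agnostic: a model is a config file (YAML
or JSON) of per-SNP effect-allele weights, optional HLA diplotype
interaction weights (plus per-haplotype additive weights), an ordered
proxy map, an imputation-R^2^ floor (variants kept when strictly
greater, default 0.97) and an optional affine normalization applied
last.  Resolution prefers the direct variant, falls back to its proxy
under the same quality rule, and otherwise records the term missing;
missing terms contribute 0 and a per-sample completeness fraction is
reported rather than any imputation of the term.  Effect alleles are
aligned by flipping dosage to 2 − d when the counted allele is the
non-effect allele.  The published T1D score families (GRS1, GRS2,
AA-GRS) are defined by weight tables in their original publications,
which this package does not reproduce; the shipped
`grs_model_example.yaml` demonstrates the schema with example weights
and is documented as such.

# Rare-variant prioritization

Annotated coding variants (gene, HGVS change, zygosity, population
frequency in percent, scaled deleteriousness score) are filtered within
configured gene panels to candidates that are rare (frequency strictly
below 0.01 percent) and deleterious (score at least 20).  The strict
`<` on frequency and inclusive `>=` on score read the thresholds
literally; the score comparator is configurable because report captions
sometimes state it both ways.  Frequencies recorded as 0 are numeric
zero and pass; missing frequencies are treated as absence from the
population database (0) with a provenance note.  Decisions are
per-row, so table order can never change results — asserted as a
property test.  Two small published variant tables ship with the
package as worked examples: six previously published monogenic
diabetes gene variants (five of which pass; one fails on frequency)
and two candidates (both pass).

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions of the test-suite.

- **Population divergence** follows the Balding–Nichols model:
  ancestral frequency p ~ U(0.05, 0.95), population frequency ~
  Beta(p(1−F)/F, (1−p)(1−F)/F) with per-population divergence F.  Any
  divergence model with a tunable F suffices for parameter-recovery
  testing; this one is the standard two-parameter choice.
- **Admixture**: per-sample q ~ Dirichlet(alpha), genotypes
  Binomial(2, Σ q_k f_km); the drawn Q is the recorded truth.
- **Pedigrees** are gene-dropped allele by allele: duplicates are
  copies with independent per-genotype corruption; parent-offspring
  and full siblings share a nuclear family; second degree is realized
  as half siblings, third degree as first cousins.  Offspring can
  never carry an allele absent from both parents, by construction and
  by test.
- **Sex-linked X**: males are hemizygous, coded 0/2 on the diploid
  scale as array exports commonly do.
- **HLA**: imputed alleles equal truth with probability 1 − e, else a
  decoy drawn from a fixed per-locus allele dictionary shipped with
  the package, avoiding the donor's typed set so that a miscall is
  always discordant.  Concordance arithmetic needs right-versus-wrong,
  not realistic allele frequencies, so the dictionary is a flat pool.
  Reported probabilities of correct calls are Beta-distributed with
  mean equal to the calibration parameter, giving the closed-form
  expectation E[Acc(L)] = (1 − e)·c used as a recovery check.
- **Second platform**: per-call corruption at a discordance rate plus
  independent missingness.
- **Annotated variants**: rarity and deleteriousness drawn
  independently at configured fractions, so the combined filter's
  expected pass count is their product; the truth subset is recorded.

Everything is seeded: identical spec + seed reproduces byte-identical
outputs, for every generator and for the whole pipeline (the report
timestamp is the one excluded field).

What the generator does *not* emulate: realistic LD block structure
(variants are exchangeable given ancestry; pooled-panel correlation
comes from population structure only), realistic HLA haplotype
frequencies or linkage between HLA loci, genotyping-intensity error
modes, and sequence-level reads.  Passing recovery tests therefore
demonstrates correctness of the estimators and plumbing under the
stated models, not robustness to array artifacts or fine-scale LD.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU while leaving comfortable
statistical margins: pedigree recovery at 20,000 SNPs and 30 pairs per
relationship class; ancestry recovery at a 5-population reference
(divergence 0.2) of 7,000 variants pruned to roughly 5,000, with 200
admixed samples (RMSE tolerance 0.05); HLA calibration at 500 donors
(tolerance 0.03 around (1 − e)·c); the end-to-end pipeline at 300
samples and 2,000 variants.  A real archive is larger in every
dimension; all estimators here scale linearly in variants and samples
except all-pairs kinship, which is quadratic in samples and implemented
with dense cross-products.

Numerical choices collected in one place: frequency clamp 1e-4;
pseudocount 0.5; EM tolerance 1e-6, cap 1000; kinship undefined without
heterozygotes in both samples; cutoff boundaries take the
closer-related class; Bland–Altman uses the n − 1 standard deviation;
plate means are over passing samples; missing calls are a sentinel
(`NA`), never 0; concordance denominators are pairwise-complete;
pruning ties drop the lower-MAF variant; PCA signs fixed by
largest-magnitude loading; strict `<` for rarity, `>=` for
deleteriousness, strict `>` for imputation-R^2^ floors.

# Known limitations

- Kinship is not ancestry-adjusted; in strongly structured cohorts the
  robust estimator is conservative for between-population pairs.
- The supervised ancestry fit requires a labeled reference; an
  unsupervised fit is out of scope, and subcontinental resolution is
  not attempted.
- HLA scoring evaluates loci independently; haplotype phasing across
  loci (e.g. DQA1–DQB1 haplotypes) is evaluated per locus.
- The GRS engine ships no published weight tables.
- Dish QC, intensity-level QC, imputation itself (HLA or genome-wide),
  read alignment, and variant calling are all upstream of this
  package and are consumed, not produced.
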