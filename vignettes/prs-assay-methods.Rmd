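---
title: "Methods: population-structure-adjusted polygenic risk scoring for individual samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-structure-adjusted polygenic risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsassay)
```

## The problem

A polygenic risk score (PRS) is a weighted sum of risk-allele dosages,
$\mathrm{PRS}_{raw} = \sum_j w_j d_j$, with weights $w_j$ taken from a
published genome-wide association study and dosages $d_j \in [0,2]$ from a
genotyping array (hard calls or imputed dosages). Two things make a raw PRS
unusable as a clinical result for an individual patient:

1. **Population structure.** Allele frequencies differ systematically
   between ancestral groups, so raw PRS distributions shift by ancestry
   even when the per-allele effects do not. A threshold calibrated on one
   group misclassifies members of another wholesale.
2. **Single-sample batches.** Cohort-level corrections (e.g. including
   principal components as covariates in the association model) need a
   cohort. A prospective clinical sample arrives alone.

`prsassay` implements the laboratory answer to both: build a reference
panel once (PCA over variance-standardized dosages, per-disease linear
models fitted in controls), then place each new sample into that fixed
reference frame by projection and residualize its score against the
prediction.

## The adjustment model

For the reference cohort with dosage matrix $G$ ($n$ samples $\times$ $m$
variants) and panel allele frequencies $p_j$, dosages are
variance-standardized, $z_{ij} = (g_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$, and
decomposed, $Z = UDV^\top$. For each disease, ordinary least squares in
*controls only* fits

$$\mathrm{PRS}_{raw} \sim PC_1 + PC_2 + PC_3 + PC_4,$$

and for every sample

$$\mathrm{PRS}_{adj} = \mathrm{PRS}_{raw} - \mathrm{PRS}_{pred}, \qquad
  \mathrm{PRS}_{std\text{-}adj} = \frac{\mathrm{PRS}_{adj} - \mu_{ref}}{\sigma_{ref}},$$

where $\mu_{ref}, \sigma_{ref}$ are the mean and SD of
$\mathrm{PRS}_{adj}$ over the full reference cohort (a controls-only
option exists, but the all-samples convention is the default). Cases are
excluded from the model fit so that a real score--disease association is
not absorbed into the structure correction; they are included in the
standardization so that the reported scale describes the population the
thresholds were published for.

Two OLS identities double as machine-checkable invariants: control
residuals are exactly orthogonal to each fitted PC and have exactly zero
mean, and the standardized score has reference mean 0 and SD 1 by
construction. The test suite asserts both at $10^{-10}$ and $10^{-12}$.

## Projecting a prospective sample

A new sample's dosages are standardized with the *reference* frequencies
(never its own), and its coordinate on PC $k$ is the sum of standardized
dosage times stored per-allele loading, scaled by
$2\sqrt{\lambda_k}$ — the square root of the eigenvalue times two. The
bundle stores loadings pre-divided by $2\sqrt{\lambda_k}$, so this recipe
reproduces held-in reference coordinates exactly; the composition is
recorded in the bundle manifest (`scaling_mode`) because the relationship
between a score-averaging projection and the eigenvalue rescaling is a
tool convention, not something derivable from the recipe alone. The
leave-one-out property test pins it empirically: a sample excluded from
the PCA and then projected lands within $0.1\sqrt{\lambda_k}$ of its
held-in coordinate on every PC (simulated panel, $n = 1200$, five
subpopulations of unequal size so that all four axes carry well-separated
structure).

Missing variants are skipped, never mean-imputed — a single-sample batch
has no cohort mean to borrow, and silent imputation would make the score
depend on who else was in the batch. Coverage of the reference variant set
is reported; below 90% the projection warns (it is attenuated toward the
origin), and below a 50% floor it errors.

## Harmonization and QC

Weight-table alleles are matched to VCF REF/ALT directly and, for
non-palindromic SNVs, by reverse complement. The effect dosage is the ALT
dosage (identity) or $2 - d$ (complement). A/T and C/G pairs cannot be
strand-verified from alleles alone and are dropped by default (a `keep`
policy exists for data known to be strand-aligned, e.g. simulations).
Every unused locus is logged with a reason; nothing is silently skipped,
and the drop log is part of the assay output. Missing genotype calls
contribute nothing to the sum — scoring runs over *available* loci.

Sample QC is a single call-rate gate: the fraction of non-missing
genotypes must be *strictly greater than* 0.985 (the published wording is
"greater than", so a rate of exactly 0.985 fails).

## From odds ratio to threshold

Published per-SD odds ratios $OR_{sd}$ are converted into a
standardized-score threshold

$$\tau = \frac{\ln(\text{target OR})}{\ln(OR_{sd})},$$

with target OR 2 by default (configurable per disease). A sample is called
**high risk** only when $\mathrm{PRS}_{std\text{-}adj} > \tau$, strictly;
everything else is **average risk**. $\tau$ is strictly decreasing in
$OR_{sd}$, and the published $OR_{sd}$ values are deliberately *required
configuration*, never defaulted — they live in per-study supplementary
data and must be supplied by the laboratory.

```{r tau}
tau_threshold(1.6, target_or = 2)$tau
```

## Validation statistics

* `odds_ratio_ci()`: $OR = ad/bc$ with the Woolf interval
  $\exp(\ln OR \pm z\sqrt{1/a+1/b+1/c+1/d})$. Woolf was adopted because
  recomputing the published replication tables (shipped as
  `replication_tables()`) from their printed counts reproduces every
  printed interval at printed precision — the adoption *is* the
  verification, and it is automated in the test suite. Zero cells yield
  the degenerate display (OR 0 or $\infty$, undefined interval) rather
  than an error.
* `quantile_log_odds()`: rank-based near-equal bins (sizes differ by at
  most one, ties broken by stable input order for determinism), per-bin
  $\log(n_{cases}/n_{controls})$ against mean score, Pearson $r$ over
  bins. Bins with zero cases or controls are flagged and excluded with a
  warning, mirroring how such strata are handled in practice.
* `concordance()`: agreement fraction and Matthews correlation
  coefficient for paired dichotomous calls; an undefined MCC (zero
  marginal) is flagged, not coerced.
* `site_concordance()`: set arithmetic over normalized
  `chrom:pos:ref:alt` keys, optionally restricted to BED regions (0-based
  half-open, so a 1-based position is inside when
  $start < pos \le end$).

## The synthetic cohort generator

Real reference cohorts are access-restricted, so the package ships a
generator whose structure is known by construction. Ancestral ALT
frequencies are Uniform(0.1, 0.9); subpopulation frequencies follow the
Balding--Nichols model
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$;
genotypes are Binomial(2, $p_{sub}$). Disease status is logistic in the
standardized true score, $P(\text{case}) =
\mathrm{logit}^{-1}(\beta_0 + \ln(OR_{sd})\,z)$, with $\beta_0$ solved
numerically for the target prevalence. All randomness flows from one seed
through fixed named substreams (alleles, weights, frequencies, genotypes,
disease), so the generator is reproducible byte-for-byte and stages do
not perturb each other's draws.

**Default conditions** (chosen once, as a realistic desk-scale analogue
of a biobank replication): two subpopulations of 10,000 samples,
$F_{ST} = 0.1$ (continental-scale divergence), 300 markers that serve as
both ancestry-informative markers and score loci, weights
$N(0, 0.05^2)$ with effect alleles assigned at random to REF/ALT, one
disease with true $OR_{sd} = 1.3$ at 10% prevalence — values typical of
externally validated type-2-diabetes- and colorectal-cancer-class scores
and of biobank disease prevalence. The panel is ~50-fold smaller than a
production ancestry-marker panel (which has tens of thousands of SNPs);
this scaling keeps the whole replicate pipeline at about a second without
changing any of the properties being tested, and the vignette-stated
sizes are the ones the test suite runs.

The per-SD odds ratio deserves a note. Dichotomizing a continuous
logistic risk factor at $\tau$ produces a *group-level* OR that exceeds
the target: the high group's mean score sits well above $\tau$, and
$\exp(\cdot)$ is convex. The inflation grows with $\ln(OR_{sd})$ —
deterministic evaluation gives an expected dichotomized OR of ~2.12 at
$OR_{sd} = 1.3$ but ~2.34 at $OR_{sd} = 1.5$. At the default conditions
the Woolf CI of the empirical OR covers the target 2 in ≳94% of
replicates; at much larger $OR_{sd}$ the high-risk tail is so small and
the inflation so large that coverage collapses. This is a property of
threshold dichotomization itself, and it is one reason observed
replication ORs cluster near — rather than exactly at — the target.

**What the generator does not emulate:** linkage disequilibrium,
admixture gradients, imputation error, genotyping batch effects, and
ancestry-dependent effect-size attenuation. Passing tests therefore
demonstrate the *mathematics* of the pipeline (scoring, projection,
residualization, thresholds, statistics) on structured data — they do not
certify performance on any real cohort, which is exactly why the
published replication tables are carried as a separate, fixed
verification input.

## Secondary findings

The screen is a pure pre-filter over externally annotated variants in the
59-gene secondary-findings panel (shipped as an editable TSV with a
per-gene loss-of-function-mechanism flag): laboratory-known P/LP
variants; ClinVar P/LP with MAF < 0.1%; HGMD disease-causing with
MAF < 0.03%; and loss-of-function consequences (nonsense, frameshift,
canonical splice, start-lost) with MAF < 0.1% in LoF-mechanism genes. All
MAF comparisons are strict; an unknown MAF passes by default (absence
from frequency databases is evidence of rarity in a screening context;
configurable). Output is explicitly a candidate list — classification and
orthogonal confirmation are human steps. Findings and PRS results are
reported in separate blocks and no interaction between them is computed.

## Numerical choices and degenerate inputs

* PC sign convention: the largest-magnitude loading on each axis is made
  positive, so refitting the same panel reproduces the same bundle.
* Eigenvalues use the variance convention $d_k^2/(n-1)$; zero-variance
  variants are excluded before decomposition, and identical-sample panels
  error rather than emitting a rank-deficient bundle.
* Constant PC columns in the adjustment fit receive a zero coefficient
  (the intercept then equals the control mean) instead of poisoning the
  design matrix; a genuinely rank-deficient varying design errors.
* Reference bundles are plain tab-separated files, one concern per file,
  with values written at full double precision (`%.17g`) so a write/read
  round trip is bit-identical; a manifest of counts makes cross-file
  consistency checkable before parsing.
* The 95% normal quantile is taken from `qnorm(0.975)` (1.959964...),
  with the confidence level configurable.
* Multi-allelic VCF records are rejected: the contract is biallelic,
  upstream-normalized input, because the handling of unnormalized records
  is not specifiable without a reference genome in hand.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile(); dir.create(dir)
spec <- cohort_spec(n_samples = c(500, 500), n_variants = 150,
                    or_sd_true = c(afib = 1.3), seed = 1)
sim <- simulate_cohort(spec, dir = dir)          # VCF + weights + bundle

write_vcf(sim$cohort$dosages[1, , drop = FALSE],
          sim$cohort$variants, file.path(dir, "patient.vcf"))
writeLines(c("diseases:",
             "  - disease: afib",
             "    or_sd: 1.3",
             "    weights: weights_afib.tsv"), file.path(dir, "config.yaml"))

res <- run_assay(file.path(dir, "patient.vcf"), weights = dir,
                 bundle = file.path(dir, "bundle"),
                 config = file.path(dir, "config.yaml"),
                 sex = "unspecified", ambiguous_policy = "keep",
                 out = file.path(dir, "report.json"))
res$results[, c("disease", "prs_std_adj", "tau", "category")]
```

## Known limitations

* Adjustment removes *mean* structure along four PCs; it does not model
  ancestry-specific effect-size attenuation, local ancestry, or
  score-variance differences between groups. The report's limitations
  block says so.
* The threshold logic inherits the dichotomization inflation described
  above: an empirical above-vs-below-$\tau$ OR is expected to sit
  somewhat above the target even when the per-SD model is exactly right.
* Strand-ambiguous loci are dropped without frequency-based rescue; for
  scores dense in palindromic SNVs this costs loci (the drop log
  quantifies it).
* No liftover: weights and genotypes must share a genome build, and the
  package only sanity-checks chromosome naming style.
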