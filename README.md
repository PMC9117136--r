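# prsassay

Population-structure-adjusted polygenic risk score (PRS) assays for
individual samples, in R.

Clinical laboratories that want to report a PRS for a single prospective
patient face two problems that cohort research does not. First, raw PRS
distributions shift wholesale with genetic ancestry — systematic allele
frequency differences move the whole score distribution even when
per-allele effects are identical — so a fixed high-risk cutoff
misclassifies by ancestry unless the score is adjusted. Second, a clinical
sample arrives alone or in a tiny batch, so cohort-style corrections
cannot be fitted on the fly. `prsassay` implements the laboratory
solution: build a reference panel once (PCA over variance-standardized
genotypes, plus per-disease linear models fitted in reference controls),
then place each new sample into that fixed frame.

For each sample and disease the pipeline computes

```
PRS_raw     = sum_j  w_j * dosage_j                  (published weights)
PRS_pred    = b0 + b1*PC1 + b2*PC2 + b3*PC3 + b4*PC4 (control-fitted model,
                                                      PCs by projection)
PRS_adj     = PRS_raw - PRS_pred
PRS_std_adj = (PRS_adj - mean_ref) / sd_ref
```

and calls **high risk** when `PRS_std_adj` is strictly above

```
tau = ln(target OR) / ln(OR_sd)        # target OR = 2 by default
```

where `OR_sd` is the published odds ratio per SD of the score. A separate
rule-based screen flags candidate actionable secondary findings (59-gene
panel; laboratory-known P/LP, ClinVar P/LP with MAF < 0.1%, HGMD DM with
MAF < 0.03%, loss-of-function with MAF < 0.1% in LoF-mechanism genes), and
a validation-statistics module provides Woolf odds-ratio intervals,
quantile log-odds curves, agreement/Matthews correlation, and
variant-site sensitivity/PPV. A seedable Balding–Nichols cohort simulator
makes the whole pipeline testable without restricted biobank data.

## Worked example

Simulate a two-subpopulation reference cohort, build its reference bundle,
then run one of its members through the prospective single-sample assay:

```r
library(prsassay)
dir <- tempfile(); dir.create(dir)
spec <- cohort_spec(n_samples = c(500, 500), n_variants = 150,
                    or_sd_true = c(afib = 1.3), seed = 1)
sim <- simulate_cohort(spec, dir = dir)      # writes VCF, weights, bundle/

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
res$results[, c("disease", "prs_raw", "prs_std_adj", "tau", "category")]
#>   disease   prs_raw prs_std_adj      tau category
#> 1    afib 0.4546948   0.1560933 2.641927  average
```

The patient's adjusted standardized score is 0.16 SD above the reference
mean; the high-risk threshold for a disease with `OR_sd = 1.3` is
`tau = ln(2)/ln(1.3) = 2.64` SD, so the report (written to `report.json`)
calls average risk. Validation statistics work directly on printed
contingency tables:

```r
odds_ratio_ci(286, 1400, 1427, 16606)
#> OR 2.38 (95% CI 2.07-2.73)
```

The same assay is available from a shell via the thin CLI wrapper
(`system.file("cli", "prs-score.R", package = "prsassay")`), with exit
code 2 for call-rate QC failure and 1 for I/O errors:

```sh
Rscript prs-score.R --vcf patient.vcf --bundle bundle/ --weights weights/ \
    --config config.yaml --sex female --out report.json --drop-log drops.tsv
```

See `vignettes/prs-assay-methods.Rmd` for the model, its assumptions,
default parameters, and known limitations.

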