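# Deterministic, seedable generator of multi-subpopulation genotype panels,
# weight tables and disease labels with known structure. Genotypes follow
# the Balding-Nichols model: an ancestral allele frequency p drawn uniform,
# subpopulation frequencies Beta(p(1-F)/F, (1-p)(1-F)/F) around it, and
# genotypes Binomial(2, p_sub). Disease status is logistic in the
# standardized true score with a chosen per-SD odds ratio.

#' Specify a synthetic cohort
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: two subpopulations of 10,000 samples each, 300 ancestry-informative
#' markers that double as score loci, continental-scale divergence F = 0.1,
#' weights drawn N(0, 0.05^2) with effect alleles assigned at random to
#' REF/ALT, one disease with a true per-SD odds ratio of 1.3 at 10\%
#' prevalence.
#'
#' @param n_samples integer vector: samples per subpopulation.
#' @param n_variants number of variants.
#' @param fst Balding-Nichols divergence parameter in [0, 1).
#' @param ancestral_freq_range range of the uniform ancestral ALT frequency.
#' @param weights_scale SD of the simulated per-allele weights.
#' @param or_sd_true named numeric: true per-SD odds ratio per disease.
#' @param prevalence_target target disease prevalence in (0, 1).
#' @param confounding_shift logit-scale shift of the last subpopulation's
#'   allele frequencies toward the effect allele (0 = none). Nonzero values
#'   create a cohort whose subpopulations differ systematically in
#'   risk-allele frequency while the true per-SD effect is identical --
#'   the confounded scenario population-structure adjustment must fix.
#' @param seed integer seed; all randomness is derived from it through
#'   fixed named substreams, so e.g. adding variants does not perturb
#'   disease labels.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_samples = c(10000, 10000), n_variants = 300,
                        fst = 0.1, ancestral_freq_range = c(0.1, 0.9),
                        weights_scale = 0.05,
                        or_sd_true = c(disease_a = 1.3),
                        prevalence_target = 0.1,
                        confounding_shift = 0, seed = 1) {
  stopifnot(fst >= 0, fst < 1, prevalence_target > 0, prevalence_target < 1,
            all(n_samples >= 1), n_variants >= 1, weights_scale > 0,
            all(or_sd_true > 0))
  structure(list(n_samples = n_samples, n_variants = n_variants, fst = fst,
                 ancestral_freq_range = ancestral_freq_range,
                 weights_scale = weights_scale, or_sd_true = or_sd_true,
                 prevalence_target = prevalence_target,
                 confounding_shift = confounding_shift,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Variant table: one chromosome, evenly spaced positions, random non-equal
# REF/ALT drawn from ACGT (palindromic pairs arise naturally, exercising
# the harmonization policy).
.simulate_variant_table <- function(spec) {
  set.seed(.substream(spec$seed, "alleles"))
  m <- spec$n_variants
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(chrom = "1", pos = seq_len(m) * 1000L, ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

#' Simulate a weight table for a cohort
#'
#' Weights are N(0, weights_scale^2); each locus's effect allele is
#' assigned at random to REF or ALT so that downstream harmonization has
#' real work to do.
#'
#' @param spec a \code{cohort_spec}.
#' @param variants variant table (defaults to the spec's own).
#' @param prs_id score identifier.
#' @return a \code{prs_weight_table}.
#' @export
simulate_weights <- function(spec, variants = NULL, prs_id = "SIM_PRS") {
  variants <- variants %||% .simulate_variant_table(spec)
  set.seed(.substream(spec$seed, "weights"))
  m <- nrow(variants)
  w <- stats::rnorm(m, 0, spec$weights_scale)
  effect_is_alt <- sample(c(TRUE, FALSE), m, replace = TRUE)
  weight_table(data.frame(
    chrom = variants$chrom, pos = variants$pos,
    effect_allele = ifelse(effect_is_alt, variants$alt, variants$ref),
    other_allele = ifelse(effect_is_alt, variants$ref, variants$alt),
    weight = w, stringsAsFactors = FALSE
  ), prs_id = prs_id)
}

#' Simulate Balding-Nichols genotypes
#'
#' @param spec a \code{cohort_spec}.
#' @param weights optional \code{prs_weight_table}; required when
#'   \code{confounding_shift} is nonzero (the shift is applied toward each
#'   locus's effect allele in proportion to the sign of its weight).
#' @param vcf_path optional path: also write the cohort as a VCF with GT
#'   and DS fields (byte-identical across runs for a fixed seed).
#' @return list of class \code{sim_cohort}: \code{dosages} (samples x
#'   variants ALT-dosage matrix), \code{variants}, \code{subpop} (factor),
#'   \code{subpop_freqs} (variants x pops ALT frequencies), \code{spec}.
#' @export
simulate_genotypes <- function(spec, weights = NULL, vcf_path = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  variants <- .simulate_variant_table(spec)
  m <- spec$n_variants
  n_pop <- length(spec$n_samples)

  set.seed(.substream(spec$seed, "frequencies"))
  p_anc <- stats::runif(m, spec$ancestral_freq_range[1],
                        spec$ancestral_freq_range[2])
  f <- spec$fst
  freqs <- matrix(NA_real_, m, n_pop)
  for (k in seq_len(n_pop)) {
    freqs[, k] <- if (f == 0) p_anc else
      stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }
  if (spec$confounding_shift != 0) {
    if (is.null(weights))
      .stopf("confounding_shift != 0 requires the weight table (the shift is toward effect alleles)")
    rec <- weights$records
    idx <- match(paste(variants$chrom, variants$pos), paste(rec$chrom, rec$pos))
    # weight signed toward the ALT allele at each locus
    w_alt <- ifelse(rec$effect_allele[idx] == variants$alt,
                    rec$weight[idx], -rec$weight[idx])
    shift <- spec$confounding_shift * sign(w_alt)
    shift[is.na(shift)] <- 0
    freqs[, n_pop] <- stats::plogis(stats::qlogis(freqs[, n_pop]) + shift)
  }
  # keep frequencies away from fixation so every variant stays informative
  freqs <- pmin(pmax(freqs, 1e-4), 1 - 1e-4)

  set.seed(.substream(spec$seed, "genotypes"))
  n_total <- sum(spec$n_samples)
  dosages <- matrix(NA_real_, n_total, m)
  subpop <- factor(rep(paste0("pop", seq_len(n_pop)), times = spec$n_samples))
  row0 <- 0
  for (k in seq_len(n_pop)) {
    nk <- spec$n_samples[k]
    dosages[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * m, 2, rep(freqs[, k], each = nk)), nk, m)
    row0 <- row0 + nk
  }
  rownames(dosages) <- sprintf("S%05d", seq_len(n_total))
  out <- structure(list(dosages = dosages, variants = variants,
                        subpop = subpop, subpop_freqs = freqs,
                        ancestral_freqs = p_anc, spec = spec),
                   class = "sim_cohort")
  if (!is.null(vcf_path)) write_vcf(dosages, variants, vcf_path)
  out
}

#' Simulate disease labels from standardized scores
#'
#' P(case) = logistic(b0 + ln(or_sd_true) * prs_std); the intercept b0 is
#' solved numerically so that the mean case probability equals the target
#' prevalence.
#'
#' @param prs_std numeric vector of standardized scores.
#' @param or_sd_true true odds ratio per SD (> 0; 1 = no association).
#' @param prevalence_target target mean prevalence in (0, 1).
#' @param seed integer seed for the Bernoulli draws.
#' @return integer vector of 0/1 labels with attribute \code{b0}.
#' @export
simulate_disease <- function(prs_std, or_sd_true, prevalence_target, seed = 1) {
  stopifnot(or_sd_true > 0, prevalence_target > 0, prevalence_target < 1)
  beta <- log(or_sd_true)
  target <- function(b0) mean(stats::plogis(b0 + beta * prs_std)) - prevalence_target
  sol <- tryCatch(stats::uniroot(target, c(-50, 50), tol = 1e-10),
                  error = function(e) .stopf(
                    "prevalence target %.3f unattainable for this score distribution",
                    prevalence_target))
  p <- stats::plogis(sol$root + beta * prs_std)
  set.seed(.substream(seed, "disease"))
  labels <- stats::rbinom(length(p), 1, p)
  attr(labels, "b0") <- sol$root
  labels
}

#' Simulate a complete cohort with reference artifacts
#'
#' Orchestrates the generator end to end: variant table, weight table,
#' Balding-Nichols genotypes, true raw scores (via the same cohort scoring
#' path the assay uses), disease labels logistic in the standardized raw
#' score, the reference PCA, and control-fitted adjustment models -- i.e.
#' everything a prospective assay needs, built from the simulated panel.
#'
#' @param spec a \code{cohort_spec}.
#' @param dir optional directory: write cohort.vcf, weights_<disease>.tsv,
#'   truth.tsv and the reference bundle (subdirectory \code{bundle/}).
#' @return list: \code{cohort} (\code{sim_cohort}), \code{weights},
#'   \code{prs_raw}, \code{prs_std_true}, \code{labels} (named list per
#'   disease), \code{pca}, \code{models}, \code{scores} (per-disease
#'   cohort-mode \code{score_result}).
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  weights <- simulate_weights(spec)
  cohort <- simulate_genotypes(spec, weights = weights,
                               vcf_path = if (!is.null(dir)) {
                                 if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
                                 file.path(dir, "cohort.vcf")
                               })
  scored <- cohort_raw_prs(cohort$dosages, cohort$variants, weights,
                           ambiguous_policy = "keep")
  prs_raw <- scored$prs_raw
  prs_std_true <- (prs_raw - mean(prs_raw)) / stats::sd(prs_raw)

  labels <- list()
  for (dz in names(spec$or_sd_true)) {
    labels[[dz]] <- simulate_disease(prs_std_true, spec$or_sd_true[[dz]],
                                     spec$prevalence_target,
                                     seed = spec$seed + match(dz, names(spec$or_sd_true)))
  }

  pca <- fit_reference_pca(cohort$dosages, cohort$variants, k = 4)
  models <- list(); scores <- list()
  for (dz in names(labels)) {
    models[[dz]] <- fit_adjustment_model(prs_raw, pca$ref_coordinates,
                                         controls = labels[[dz]] == 0,
                                         disease = dz)
    scores[[dz]] <- adjust_cohort(prs_raw, pca$ref_coordinates, models[[dz]])
  }

  if (!is.null(dir)) {
    for (dz in names(labels)) {
      wt <- weights$records
      names(wt)[names(wt) == "weight"] <- "weight"
      .write_tsv(wt, file.path(dir, paste0("weights_", dz, ".tsv")))
    }
    truth <- data.frame(sample_id = rownames(cohort$dosages),
                        subpop = as.character(cohort$subpop),
                        prs_raw = unname(prs_raw),
                        prs_std_true = unname(prs_std_true))
    for (dz in names(labels)) truth[[paste0("label_", dz)]] <- as.integer(labels[[dz]])
    .write_tsv(truth, file.path(dir, "truth.tsv"))
    write_reference_bundle(pca, models, file.path(dir, "bundle"))
  }

  list(cohort = cohort, weights = weights, prs_raw = prs_raw,
       prs_std_true = prs_std_true, labels = labels, pca = pca,
       models = models, scores = scores)
}
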