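# Conversion of published per-SD odds ratios into standardized-score
# thresholds, dichotomous risk classification, and the end-to-end
# single-sample assay.

#' Threshold for high polygenic risk
#'
#' For a target odds ratio T (default 2) and a published per-SD odds ratio
#' OR_sd, the standardized-score threshold is tau = ln(T) / ln(OR_sd):
#' assuming the published OR_sd captures the score-disease relationship, a
#' sample at standardized score tau has T-fold the odds of a sample at the
#' median.
#'
#' @param or_sd published odds ratio per SD of the standardized adjusted
#'   score; must be > 1 or the threshold is undefined.
#' @param target_or target odds ratio defining high risk (> 1, default 2).
#' @param disease disease label carried along.
#' @return list of class \code{risk_threshold}: \code{disease},
#'   \code{or_sd}, \code{target_or}, \code{tau}.
#' @export
tau_threshold <- function(or_sd, target_or = 2, disease = NA_character_) {
  if (!is.finite(or_sd) || or_sd <= 1)
    .stopf("or_sd must be > 1 (got %s): tau = ln(target)/ln(or_sd) is undefined or non-positive",
           format(or_sd))
  if (!is.finite(target_or) || target_or <= 1)
    .stopf("target_or must be > 1 (got %s)", format(target_or))
  structure(list(disease = disease, or_sd = or_sd, target_or = target_or,
                 tau = log(target_or) / log(or_sd)),
            class = "risk_threshold")
}

#' Classify a score result against a threshold
#'
#' A result is high risk only when the standardized adjusted score is
#' strictly above tau; a score exactly at tau, or anywhere below, confers
#' average risk.
#'
#' @param result a \code{score_result} (any number of rows).
#' @param threshold a \code{risk_threshold}; its disease must match the
#'   result's disease when both are labelled.
#' @return the \code{score_result} with \code{category} filled in
#'   (\code{"high"}/\code{"average"}) and columns \code{tau}, \code{or_sd},
#'   \code{target_or} attached.
#' @export
classify <- function(result, threshold) {
  stopifnot(inherits(threshold, "risk_threshold"))
  mismatch <- !is.na(threshold$disease) & !is.na(result$disease) &
    result$disease != threshold$disease
  if (any(mismatch))
    .stopf("threshold is for disease '%s' but result rows are for '%s'",
           threshold$disease, paste(unique(result$disease[mismatch]), collapse = ", "))
  result$category <- ifelse(result$prs_std_adj > threshold$tau, "high", "average")
  result$tau <- threshold$tau
  result$or_sd <- threshold$or_sd
  result$target_or <- threshold$target_or
  result
}

# Condition object for QC failures so callers (and the CLI) can
# distinguish them from I/O errors.
.qc_error <- function(sample_id, rate, threshold) {
  structure(class = c("prsassay_qc_error", "error", "condition"),
            list(message = sprintf(
              "sample %s failed call-rate QC: %.4f is not greater than %.4f",
              sample_id, rate, threshold),
              call = NULL, sample_id = sample_id, call_rate = rate))
}

#' Run the full single-sample PRS assay
#'
#' For each sample in the VCF: call-rate QC (strictly greater than the
#' threshold, or the assay aborts), then per configured disease --
#' harmonize the weight table, compute the raw score, project the sample
#' onto the reference PCs, residualize against the disease's control-fitted
#' model, standardize with the reference statistics, and classify at
#' tau = ln(target OR)/ln(OR_sd). Sex-specific diseases are only scored
#' when the sample's reported sex matches the configuration; an unspecified
#' sex scores every disease.
#'
#' @param vcf path to the sample VCF.
#' @param weights named list of \code{prs_weight_table}s (names = disease),
#'   or a directory containing the per-disease scoring files named in the
#'   config.
#' @param bundle a reference bundle directory or the list returned by
#'   \code{\link{read_reference_bundle}}.
#' @param config a disease-config data.frame (see
#'   \code{\link{read_disease_config}}) or a YAML path.
#' @param sex \code{"male"}, \code{"female"} or \code{"unspecified"}.
#' @param call_rate_threshold QC threshold, default 0.985.
#' @param ambiguous_policy palindromic-SNV policy for harmonization.
#' @param out optional path: write the JSON report there.
#' @param drop_log_path optional path: write the combined drop log there.
#' @return list: \code{results} (score_result data.frame over all samples
#'   and diseases), \code{qc} (per-sample call rates), \code{drop_logs},
#'   \code{report} (the report list when \code{out} is given).
#' @export
run_assay <- function(vcf, weights, bundle, config,
                      sex = c("unspecified", "male", "female"),
                      call_rate_threshold = 0.985,
                      ambiguous_policy = "drop",
                      out = NULL, drop_log_path = NULL) {
  sex <- match.arg(sex)
  if (is.character(config)) config <- read_disease_config(config)
  if (is.character(bundle)) bundle <- read_reference_bundle(bundle)
  if (is.character(weights)) {
    wdir <- weights
    weights <- lapply(seq_len(nrow(config)), function(i) {
      read_weight_table(file.path(wdir, config$weights[i]),
                        prs_id = config$disease[i])
    })
    names(weights) <- config$disease
  }
  cfg <- config[sex == "unspecified" | config$sex == "any" | config$sex == sex, ,
                drop = FALSE]
  if (nrow(cfg) == 0) .stopf("no diseases configured for sex '%s'", sex)
  missing_w <- setdiff(cfg$disease, names(weights))
  if (length(missing_w) > 0)
    .stopf("no weight table provided for disease(s): %s",
           paste(missing_w, collapse = ", "))
  missing_m <- setdiff(cfg$disease, names(bundle$models))
  if (length(missing_m) > 0)
    .stopf("reference bundle has no adjustment model for disease(s): %s",
           paste(missing_m, collapse = ", "))

  genos <- read_genotypes(vcf)
  all_results <- list(); qc <- list(); dlogs <- list()
  for (s in names(genos)) {
    g <- genos[[s]]
    cr <- check_call_rate(g, call_rate_threshold)
    qc[[s]] <- cr
    if (!cr$pass) stop(.qc_error(s, cr$call_rate, call_rate_threshold))
    pcs <- project_sample(g, bundle$pca)
    for (i in seq_len(nrow(cfg))) {
      dz <- cfg$disease[i]
      h <- harmonize(weights[[dz]], g, ambiguous_policy = ambiguous_policy)
      dl <- drop_log(h)
      if (nrow(dl) > 0) {
        dlogs[[paste(s, dz, sep = "/")]] <-
          cbind(sample_id = s, disease = dz, dl)
      }
      raw <- compute_raw_prs(h, sample_id = s, disease = dz)
      res <- adjust_and_standardize(raw, pcs, bundle$models[[dz]])
      res <- classify(res, tau_threshold(cfg$or_sd[i], cfg$target_or[i], dz))
      res$n_loci_used <- raw$n_loci_used
      res$n_loci_total <- raw$n_loci_total
      res$pc_coverage <- pcs$coverage
      all_results[[paste(s, dz, sep = "/")]] <- res
    }
  }
  results <- do.call(rbind, all_results)
  rownames(results) <- NULL
  dlog <- do.call(rbind, dlogs)
  rownames(dlog) <- NULL
  if (!is.null(drop_log_path))
    utils::write.table(dlog, drop_log_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  report <- NULL
  if (!is.null(out)) {
    qc_json <- lapply(qc, function(x) list(call_rate = x$call_rate,
                                           pass = x$pass))
    report <- write_report(results,
                           findings = data.frame(),
                           path = out, qc = qc_json)
  }
  list(results = results, qc = qc, drop_logs = dlog, report = report)
}
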