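# Population-structure adjustment: reference PCA, projection of new samples
# into the reference PC space, control-fitted per-disease linear models, and
# residualization/standardization of raw scores.

#' Fit the reference-panel PCA
#'
#' Dosages are variance-standardized per variant, z = (g - 2p) /
#' sqrt(2p(1-p)) with p the panel ALT frequency, and decomposed. Loadings
#' are stored pre-divided by 2*sqrt(eigenvalue), so that projecting a new
#' sample (sum of standardized dosage times loading) and then applying the
#' published scaling recipe -- multiply by the square root of the eigenvalue
#' and then by 2 -- reproduces the held-in reference coordinates exactly.
#' This composition is recorded in the bundle as the scaling mode.
#'
#' Eigenvalues follow the variance convention (singular value squared over
#' n - 1). The sign of each PC is fixed deterministically: the
#' largest-magnitude raw loading is made positive, so refitting the same
#' panel reproduces the same bundle.
#'
#' @param dosages numeric matrix, samples x variants, ALT dosage in [0, 2],
#'   no missing values (the reference panel is assumed complete).
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} for the columns of \code{dosages}.
#' @param k number of PCs to retain (>= 4 for downstream models).
#' @return object of class \code{pca_reference}: \code{variants} (the
#'   retained, non-monomorphic variants), \code{allele_frequencies},
#'   \code{loadings} (variants x k), \code{eigenvalues},
#'   \code{ref_coordinates} (samples x k), \code{scaling_mode}.
#' @export
fit_reference_pca <- function(dosages, variants, k = 4) {
  stopifnot(is.matrix(dosages), ncol(dosages) == nrow(variants), k >= 1)
  n <- nrow(dosages)
  if (n < k + 1) .stopf("PCA needs at least k + 1 = %d samples, got %d", k + 1, n)
  if (anyNA(dosages))
    .stopf("reference panel dosages contain missing values; the panel must be complete")
  p <- colMeans(dosages) / 2
  keep <- which(p > 0 & p < 1 & apply(dosages, 2, stats::var) > 0)
  if (length(keep) == 0)
    .stopf("no polymorphic variants in the reference panel (zero variance everywhere)")
  p <- p[keep]
  z <- sweep(dosages[, keep, drop = FALSE], 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  m <- ncol(z)
  if (k > min(n - 1, m))
    .stopf("k = %d exceeds the rank bound min(n - 1, m) = %d", k, min(n - 1, m))

  if (m <= n) {
    ed <- eigen(crossprod(z) / (n - 1), symmetric = TRUE)
    lambda <- ed$values[seq_len(k)]
    v <- ed$vectors[, seq_len(k), drop = FALSE]
  } else {
    sv <- svd(z, nu = 0, nv = k)
    lambda <- (sv$d[seq_len(k)]^2) / (n - 1)
    v <- sv$v
  }
  if (any(lambda <= .Machine$double.eps * max(lambda)))
    .stopf("k = %d exceeds the effective rank of the panel", k)
  # deterministic sign: largest-|loading| entry positive per PC
  for (j in seq_len(k)) {
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) v[, j] <- -v[, j]
  }
  coords <- z %*% v
  rownames(coords) <- rownames(dosages)
  colnames(coords) <- paste0("PC", seq_len(k))
  loadings <- sweep(v, 2, 2 * sqrt(lambda), "/")
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(
    variants = variants[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE],
    allele_frequencies = unname(p),
    loadings = loadings,
    eigenvalues = lambda,
    ref_coordinates = coords,
    scaling_mode = "times_2_sqrt_eigenvalue"
  ), class = "pca_reference")
}

#' @export
print.pca_reference <- function(x, ...) {
  cat(sprintf("<pca_reference> %d variants, %d PCs, %d reference samples\n",
              nrow(x$variants), length(x$eigenvalues), nrow(x$ref_coordinates)))
  invisible(x)
}

#' Project a sample onto the reference principal components
#'
#' Standardizes the sample's dosages with the reference allele frequencies
#' (never its own), sums standardized dosage times stored loading per PC,
#' and scales the result by the square root of the eigenvalue times 2 to
#' place it on the reference coordinate scale. Variants missing from the
#' sample are skipped -- no mean imputation -- and the fraction of reference
#' variants actually used is reported as coverage.
#'
#' @param genotypes a \code{sample_genotypes}.
#' @param ref a \code{pca_reference}.
#' @param min_coverage error below this fraction of reference variants
#'   (default 0.5); a warning is raised below \code{warn_coverage}
#'   (default 0.9).
#' @param warn_coverage see above.
#' @return list of class \code{pc_coordinates}: \code{sample_id}, \code{pc}
#'   (named numeric of length k), \code{coverage}.
#' @export
project_sample <- function(genotypes, ref, min_coverage = 0.5,
                           warn_coverage = 0.9) {
  stopifnot(inherits(genotypes, "sample_genotypes"),
            inherits(ref, "pca_reference"))
  gv <- genotypes$variants
  idx <- match(paste(ref$variants$chrom, ref$variants$pos),
               paste(gv$chrom, gv$pos))
  found <- !is.na(idx)
  dos <- rep(NA_real_, nrow(ref$variants))
  same <- found & gv$ref[idx] == ref$variants$ref & gv$alt[idx] == ref$variants$alt
  swap <- found & gv$ref[idx] == ref$variants$alt & gv$alt[idx] == ref$variants$ref
  dos[same] <- gv$dosage[idx[same]]
  dos[swap] <- 2 - gv$dosage[idx[swap]]
  use <- !is.na(dos)
  coverage <- mean(use)
  if (coverage < min_coverage)
    .stopf("sample %s covers only %.1f%% of reference variants (floor %.1f%%)",
           genotypes$sample_id, 100 * coverage, 100 * min_coverage)
  if (coverage < warn_coverage)
    .warnf("sample %s covers %.1f%% of reference variants; projection may be attenuated",
           genotypes$sample_id, 100 * coverage)
  p <- ref$allele_frequencies[use]
  z <- (dos[use] - 2 * p) / sqrt(2 * p * (1 - p))
  raw <- drop(crossprod(ref$loadings[use, , drop = FALSE], z))
  pc <- raw * 2 * sqrt(ref$eigenvalues)
  names(pc) <- colnames(ref$loadings)
  structure(list(sample_id = genotypes$sample_id, pc = pc,
                 coverage = coverage), class = "pc_coordinates")
}

#' Construct a per-disease adjustment model
#'
#' @param disease disease label.
#' @param intercept,beta OLS intercept and the four PC coefficients.
#' @param ref_mean_adj,ref_sd_adj mean and SD of the adjusted score in the
#'   reference cohort, used downstream for standardization.
#' @return object of class \code{adjustment_model}.
#' @export
adjustment_model <- function(disease, intercept, beta, ref_mean_adj, ref_sd_adj) {
  if (length(beta) != 4)
    .stopf("adjustment model for '%s' must have exactly 4 PC coefficients, got %d",
           disease, length(beta))
  if (!is.finite(ref_sd_adj) || ref_sd_adj <= 0)
    .stopf("adjustment model for '%s': reference SD must be > 0", disease)
  structure(list(disease = disease, intercept = unname(intercept),
                 beta = unname(beta), ref_mean_adj = unname(ref_mean_adj),
                 ref_sd_adj = unname(ref_sd_adj)),
            class = "adjustment_model")
}

#' Fit the control-based adjustment model for one disease
#'
#' Ordinary least squares of the raw score on the first four PCs, fitted in
#' controls only (cases are excluded so disease-associated score shifts do
#' not leak into the structure model). The model is then applied to every
#' reference sample to form adjusted scores (raw minus predicted), whose
#' mean and SD over the chosen standardization population become the
#' reference statistics.
#'
#' @param prs_raw numeric vector of raw scores, one per reference sample.
#' @param pcs matrix (samples x >= 4) of reference PC coordinates; the first
#'   four columns are used.
#' @param controls logical vector, TRUE for controls.
#' @param disease disease label.
#' @param standardize_population \code{"all"} (default) computes the
#'   reference mean/SD of the adjusted score over all reference samples;
#'   \code{"controls"} restricts to controls.
#' @return an \code{adjustment_model}.
#' @export
fit_adjustment_model <- function(prs_raw, pcs, controls, disease = "disease",
                                 standardize_population = c("all", "controls")) {
  standardize_population <- match.arg(standardize_population)
  pcs <- as.matrix(pcs)[, 1:4, drop = FALSE]
  stopifnot(length(prs_raw) == nrow(pcs), length(controls) == length(prs_raw))
  n_controls <- sum(controls)
  if (n_controls < 6)
    .stopf("adjustment model for '%s' needs >= 6 controls, got %d",
           disease, n_controls)
  # constant PCs (e.g. a degenerate axis) carry no structure information:
  # they get a zero coefficient rather than poisoning the design matrix
  varying <- apply(pcs[controls, , drop = FALSE], 2, stats::sd) > 0
  x <- cbind(1, pcs[controls, varying, drop = FALSE])
  if (qr(x)$rank < ncol(x))
    .stopf("adjustment model for '%s': PC design matrix is rank deficient", disease)
  fit <- stats::lm.fit(x, prs_raw[controls])
  coefs <- numeric(5)
  coefs[c(TRUE, varying)] <- fit$coefficients
  pred_all <- drop(cbind(1, pcs) %*% coefs)
  adj_all <- prs_raw - pred_all
  pop <- if (standardize_population == "all") rep(TRUE, length(adj_all)) else controls
  adjustment_model(disease = disease, intercept = coefs[1], beta = coefs[-1],
                   ref_mean_adj = mean(adj_all[pop]),
                   ref_sd_adj = stats::sd(adj_all[pop]))
}

#' Adjust and standardize a raw score
#'
#' Computes the predicted score from the four PC coordinates, the adjusted
#' score as raw minus predicted, and the standardized adjusted score using
#' the reference mean/SD stored in the model. The risk category is left
#' unset; see \code{\link{classify}}.
#'
#' @param raw a \code{raw_score} (or a bare numeric raw score).
#' @param pcs a \code{pc_coordinates} (or numeric vector of length >= 4).
#' @param model an \code{adjustment_model}; its disease must match the raw
#'   score's disease when both are labelled.
#' @return one-row data.frame (class \code{score_result}) with columns
#'   \code{sample_id}, \code{disease}, \code{prs_raw}, \code{prs_pred},
#'   \code{prs_adj}, \code{prs_std_adj}, \code{category} (NA).
#' @export
adjust_and_standardize <- function(raw, pcs, model) {
  stopifnot(inherits(model, "adjustment_model"))
  if (inherits(raw, "raw_score")) {
    if (!is.na(raw$disease) && raw$disease != model$disease)
      .stopf("raw score is for disease '%s' but model is for '%s'",
             raw$disease, model$disease)
    sample_id <- raw$sample_id; prs_raw <- raw$prs_raw
  } else {
    sample_id <- NA_character_; prs_raw <- as.numeric(raw)
  }
  pc <- if (inherits(pcs, "pc_coordinates")) pcs$pc else as.numeric(pcs)
  pc <- pc[1:4]
  prs_pred <- model$intercept + sum(model$beta * pc)
  prs_adj <- prs_raw - prs_pred
  out <- data.frame(
    sample_id = sample_id, disease = model$disease,
    prs_raw = prs_raw, prs_pred = prs_pred, prs_adj = prs_adj,
    prs_std_adj = (prs_adj - model$ref_mean_adj) / model$ref_sd_adj,
    category = NA_character_, stringsAsFactors = FALSE
  )
  class(out) <- c("score_result", "data.frame")
  out
}

#' Cohort-mode adjustment
#'
#' Applies an adjustment model to a whole reference cohort at once:
#' predicted, adjusted and standardized adjusted scores for every sample.
#'
#' @param prs_raw numeric vector of raw scores.
#' @param pcs matrix of PC coordinates (samples x >= 4).
#' @param model an \code{adjustment_model}.
#' @return data.frame with one row per sample (class \code{score_result}).
#' @export
adjust_cohort <- function(prs_raw, pcs, model) {
  stopifnot(inherits(model, "adjustment_model"))
  pcs <- as.matrix(pcs)[, 1:4, drop = FALSE]
  prs_pred <- drop(cbind(1, pcs) %*% c(model$intercept, model$beta))
  prs_adj <- prs_raw - prs_pred
  out <- data.frame(
    sample_id = rownames(pcs) %||% names(prs_raw) %||% as.character(seq_along(prs_raw)),
    disease = model$disease,
    prs_raw = unname(prs_raw), prs_pred = prs_pred, prs_adj = prs_adj,
    prs_std_adj = (prs_adj - model$ref_mean_adj) / model$ref_sd_adj,
    category = NA_character_, stringsAsFactors = FALSE
  )
  class(out) <- c("score_result", "data.frame")
  out
}
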