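# Validation mathematics for the assay: 2x2 odds ratios with Woolf
# confidence intervals, quantile log-odds dose-response curves, paired
# dichotomous concordance (agreement + Matthews correlation), and
# variant-site sensitivity/PPV against a truth set.

#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table (a = high-risk cases, b = high-risk controls, c = other
#' cases, d = other controls): OR = (a d)/(b c) and the Woolf interval is
#' exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell makes the
#' interval undefined; the point estimate is still evaluated (0 when a or d
#' is zero, infinite when b or c is zero, NaN when both).
#'
#' @param a,b,c,d non-negative integer cell counts; \code{a} may also be a
#'   length-4 vector \code{c(a, b, c, d)}.
#' @param conf_level confidence level, default 0.95.
#' @return list of class \code{or_ci}: \code{or}, \code{ci_lo}, \code{ci_hi},
#'   \code{log_or}, \code{se}, \code{conf_level}, \code{degenerate}.
#' @export
odds_ratio_ci <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (length(a) == 4 && is.null(b)) { b <- a[2]; c <- a[3]; d <- a[4]; a <- a[1] }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    .stopf("cell counts must be non-negative integers")
  if (sum(cells) == 0) .stopf("empty contingency table")
  or <- (a * d) / (b * c)
  degenerate <- any(cells == 0)
  if (degenerate) {
    ci_lo <- ci_hi <- se <- NA_real_
    log_or <- suppressWarnings(log(or))
  } else {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    log_or <- log(or)
    ci_lo <- exp(log_or - z * se)
    ci_hi <- exp(log_or + z * se)
  }
  structure(list(or = or, ci_lo = ci_lo, ci_hi = ci_hi, log_or = log_or,
                 se = se, conf_level = conf_level, degenerate = degenerate),
            class = "or_ci")
}

#' @export
print.or_ci <- function(x, ...) {
  cat(sprintf("OR %.2f (%.0f%% CI %.2f-%.2f)%s\n", x$or, 100 * x$conf_level,
              x$ci_lo, x$ci_hi, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Deterministic near-equal bin assignment: samples sorted by score (ties in
# stable input order), sizes differing by at most one, larger bins first.
.quantile_bins <- function(scores, n_quantiles) {
  n <- length(scores)
  sizes <- rep(n %/% n_quantiles, n_quantiles)
  extra <- n %% n_quantiles
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin <- integer(n)
  bin[order(scores)] <- rep(seq_len(n_quantiles), times = sizes)
  bin
}

#' Quantile log-odds dose-response curve
#'
#' Samples are split into near-equal rank-based score quantiles; for each
#' bin the log odds of disease, log(n_cases / n_controls), is paired with
#' the bin's mean score, and the linearity of the dose-response is
#' summarized by the Pearson correlation over bins. Bins with zero cases or
#' zero controls have no finite log odds; they are flagged and excluded
#' with a warning.
#'
#' @param scores numeric vector of standardized adjusted scores.
#' @param labels case status (logical or 0/1).
#' @param n_quantiles number of bins (>= 2), default 50.
#' @return list of class \code{quantile_curve}: \code{bins} (data.frame
#'   with \code{quantile}, \code{n}, \code{n_cases}, \code{n_controls},
#'   \code{mean_score}, \code{log_odds}, \code{degenerate}),
#'   \code{pearson_r}, \code{n_quantiles}, \code{n_degenerate}.
#' @export
quantile_log_odds <- function(scores, labels, n_quantiles = 50) {
  stopifnot(length(scores) == length(labels), n_quantiles >= 2)
  labels <- as.logical(labels)
  if (length(scores) < n_quantiles)
    .stopf("fewer samples (%d) than quantiles (%d)", length(scores), n_quantiles)
  bin <- .quantile_bins(scores, n_quantiles)
  n_cases <- tapply(labels, bin, sum)
  n_tot <- tabulate(bin, n_quantiles)
  n_controls <- n_tot - n_cases
  mean_score <- tapply(scores, bin, mean)
  degenerate <- n_cases == 0 | n_controls == 0
  bins <- data.frame(
    quantile = seq_len(n_quantiles), n = n_tot,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    mean_score = as.numeric(mean_score),
    log_odds = ifelse(degenerate, NA_real_, log(n_cases / n_controls)),
    degenerate = as.logical(degenerate)
  )
  if (all(degenerate))
    .stopf("every quantile has zero cases or zero controls; no curve can be formed")
  if (any(degenerate))
    .warnf("%d of %d quantiles have zero cases or zero controls and were excluded",
           sum(degenerate), n_quantiles)
  ok <- !degenerate
  r <- if (sum(ok) >= 2) stats::cor(bins$mean_score[ok], bins$log_odds[ok])
  else NA_real_
  structure(list(bins = bins, pearson_r = r, n_quantiles = n_quantiles,
                 n_degenerate = sum(degenerate)),
            class = "quantile_curve")
}

#' Concordance of paired dichotomous classifications
#'
#' Compares two raters' high/average calls over the same samples:
#' agreement fraction and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A zero
#' factor in the denominator leaves the MCC undefined (flagged, not
#' silently zeroed).
#'
#' @param x,y logical vectors (or anything coercible): TRUE = high risk,
#'   per rater.
#' @return list of class \code{concordance_result}: \code{n_pairs},
#'   \code{n_concordant}, \code{agreement}, \code{mcc},
#'   \code{mcc_defined}.
#' @export
concordance <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  stopifnot(length(x) == length(y), length(x) >= 1, !anyNA(x), !anyNA(y))
  tp <- sum(x & y); tn <- sum(!x & !y); fp <- sum(!x & y); fn <- sum(x & !y)
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else NA_real_
  structure(list(n_pairs = length(x), n_concordant = tp + tn,
                 agreement = (tp + tn) / length(x),
                 mcc = mcc, mcc_defined = denom2 > 0,
                 confusion = c(tp = tp, tn = tn, fp = fp, fn = fn)),
            class = "concordance_result")
}

#' Read a BED file of benchmarking regions
#'
#' Standard BED semantics: 0-based half-open intervals, so a 1-based
#' variant position lies in a region when start < pos <= end.
#'
#' @param path BED path (first three columns used).
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(bed[, 1:3], c("chrom", "start", "end"))
}

.keys_in_regions <- function(keys, regions) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, character(1), 1)
  pos <- as.integer(vapply(parts, `[[`, character(1), 2))
  keep <- logical(length(keys))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (chrom == regions$chrom[i] &
                      pos > regions$start[i] & pos <= regions$end[i])
  }
  keys[keep]
}

.as_variant_keys <- function(x) {
  if (is.character(x)) return(unique(x))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
  unique(variant_key(x$chrom, x$pos, x$ref, x$alt))
}

#' Variant-site concordance against a truth set
#'
#' Sites are matched by normalized (chrom, pos, ref, alt) key, optionally
#' restricted to benchmarking regions. Sensitivity = TP/(TP+FN) over truth
#' sites; PPV = TP/(TP+FP) over called sites (undefined when no calls
#' remain).
#'
#' @param calls,truth character vectors of variant keys
#'   (\code{chrom:pos:ref:alt}) or data.frames with those columns.
#' @param regions optional region data.frame from \code{\link{read_bed}}.
#' @return list of class \code{site_concordance}: \code{tp}, \code{fp},
#'   \code{fn}, \code{sensitivity}, \code{ppv}.
#' @export
site_concordance <- function(calls, truth, regions = NULL) {
  calls <- .as_variant_keys(calls)
  truth <- .as_variant_keys(truth)
  if (!is.null(regions)) {
    calls <- .keys_in_regions(calls, regions)
    truth <- .keys_in_regions(truth, regions)
  }
  tp <- length(intersect(calls, truth))
  fp <- length(setdiff(calls, truth))
  fn <- length(setdiff(truth, calls))
  structure(list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  ), class = "site_concordance")
}
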