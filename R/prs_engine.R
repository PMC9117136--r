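# Allele harmonization between weight tables and genotypes, sample QC, and
# raw PRS computation.

#' Harmonize a weight table against a sample's genotypes
#'
#' Each weight-table locus is matched to the sample's VCF record at the same
#' (chrom, pos). The effect allele is matched to ALT (identity transform:
#' effect dosage = ALT dosage) or to REF (complement transform: effect
#' dosage = 2 - ALT dosage), trying the reported alleles first and their
#' reverse complements second for non-palindromic SNVs. Strand-ambiguous
#' palindromic pairs (A/T, C/G) cannot be oriented from alleles alone and
#' are handled per \code{ambiguous_policy}. Everything that cannot be used
#' is dropped with a reason, never silently: absent loci, allele mismatches,
#' palindromic drops, and loci whose genotype call is missing.
#'
#' @param weights a \code{prs_weight_table}.
#' @param genotypes a \code{sample_genotypes}.
#' @param ambiguous_policy \code{"drop"} (default) or \code{"keep"} for
#'   palindromic SNVs. When kept, the reported alleles are taken at face
#'   value.
#' @return data.frame of class \code{harmonized_loci}, one row per weight
#'   record, with columns \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{weight}, \code{status} (\code{matched},
#'   \code{flipped}, \code{dropped_ambiguous}, \code{dropped_missing}),
#'   \code{transform} (\code{identity}/\code{complement}/\code{NA}),
#'   \code{effect_dosage}, \code{reason}.
#' @export
harmonize <- function(weights, genotypes, ambiguous_policy = c("drop", "keep")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(inherits(weights, "prs_weight_table"),
            inherits(genotypes, "sample_genotypes"))
  rec <- weights$records
  gv <- genotypes$variants
  n <- nrow(rec)
  out <- data.frame(
    chrom = rec$chrom, pos = rec$pos,
    effect_allele = rec$effect_allele, other_allele = rec$other_allele,
    weight = rec$weight,
    status = rep(NA_character_, n), transform = rep(NA_character_, n),
    effect_dosage = rep(NA_real_, n), reason = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_loci", "data.frame")
  if (n == 0) return(out)

  # light build-compatibility guard: mismatched chromosome naming styles
  # ("chr1" vs "1") mean nothing would match and usually signal a build or
  # export mismatch
  if (nrow(gv) > 0) {
    w_chr <- any(startsWith(rec$chrom, "chr"))
    g_chr <- any(startsWith(gv$chrom, "chr"))
    if (w_chr != g_chr)
      .warnf("weight table and genotypes use different chromosome naming styles ('chr' prefix vs bare); check that both are on the same genome build")
  }

  idx <- match(paste(rec$chrom, rec$pos), paste(gv$chrom, gv$pos))
  palindromic <- .is_palindromic(rec$effect_allele, rec$other_allele)
  eff_rc <- .complement_allele(rec$effect_allele)
  oth_rc <- .complement_allele(rec$other_allele)

  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) {
      out$status[i] <- "dropped_missing"; out$reason[i] <- "absent_from_genotypes"
      next
    }
    if (palindromic[i] && ambiguous_policy == "drop") {
      out$status[i] <- "dropped_ambiguous"; out$reason[i] <- "palindromic_snv"
      next
    }
    ref <- gv$ref[j]; alt <- gv$alt[j]
    ea <- rec$effect_allele[i]; oa <- rec$other_allele[i]
    transform <- if (ea == alt && oa == ref) "identity"
    else if (ea == ref && oa == alt) "complement"
    else if (!palindromic[i] && !is.na(eff_rc[i]) &&
             eff_rc[i] == alt && oth_rc[i] == ref) "identity"
    else if (!palindromic[i] && !is.na(eff_rc[i]) &&
             eff_rc[i] == ref && oth_rc[i] == alt) "complement"
    else NA_character_
    if (is.na(transform)) {
      out$status[i] <- "dropped_missing"; out$reason[i] <- "allele_mismatch"
      next
    }
    dos <- gv$dosage[j]
    if (is.na(dos)) {
      out$status[i] <- "dropped_missing"; out$reason[i] <- "missing_genotype"
      out$transform[i] <- transform
      next
    }
    out$transform[i] <- transform
    out$effect_dosage[i] <- if (transform == "identity") dos else 2 - dos
    out$status[i] <- if (transform == "identity") "matched" else "flipped"
  }
  out
}

#' Extract the drop log from harmonized loci
#'
#' @param harmonized output of \code{\link{harmonize}}.
#' @return data.frame with one row per dropped locus: variant key and reason.
#' @export
drop_log <- function(harmonized) {
  d <- harmonized[startsWith(harmonized$status, "dropped"), , drop = FALSE]
  data.frame(
    variant = paste(d$chrom, d$pos, d$effect_allele, d$other_allele, sep = ":"),
    status = d$status, reason = d$reason,
    stringsAsFactors = FALSE
  )
}

#' Write the drop log as TSV
#'
#' @param harmonized output of \code{\link{harmonize}}.
#' @param path output path.
#' @export
write_drop_log <- function(harmonized, path) {
  utils::write.table(drop_log(harmonized), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compute the raw PRS from harmonized loci
#'
#' The raw score is the sum over usable loci of weight times effect-allele
#' dosage. Dropped loci contribute nothing; missing genotypes are never
#' mean-imputed, so the sum runs over available loci only.
#'
#' @param harmonized output of \code{\link{harmonize}}.
#' @param sample_id,disease labels carried into the result.
#' @return list of class \code{raw_score}: \code{sample_id}, \code{disease},
#'   \code{prs_raw}, \code{n_loci_used}, \code{n_loci_total}.
#' @export
compute_raw_prs <- function(harmonized, sample_id = NA_character_,
                            disease = NA_character_) {
  usable <- harmonized$status %in% c("matched", "flipped")
  if (!any(usable))
    .stopf("no usable loci when scoring disease '%s' for sample '%s'",
           disease, sample_id)
  structure(list(
    sample_id = sample_id,
    disease = disease,
    prs_raw = sum(harmonized$weight[usable] * harmonized$effect_dosage[usable]),
    n_loci_used = sum(usable),
    n_loci_total = nrow(harmonized)
  ), class = "raw_score")
}

#' Cohort-level raw PRS
#'
#' Vectorized scoring of a full dosage matrix against one weight table,
#' used for reference-cohort work and simulations. Harmonization follows
#' the same rules as \code{\link{harmonize}}, applied once to the shared
#' variant table. Missing dosages contribute nothing to the affected
#' sample's score.
#'
#' @param dosages numeric matrix (samples x variants) of ALT dosages.
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} describing the columns of \code{dosages}.
#' @param weights a \code{prs_weight_table}.
#' @param ambiguous_policy see \code{\link{harmonize}}.
#' @return list: \code{prs_raw} (named vector, one per sample),
#'   \code{harmonized} (per-locus table), \code{n_loci_used}.
#' @export
cohort_raw_prs <- function(dosages, variants, weights,
                           ambiguous_policy = c("drop", "keep")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  proto <- sample_genotypes("cohort", data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    dosage = 1, stringsAsFactors = FALSE))
  h <- harmonize(weights, proto, ambiguous_policy = ambiguous_policy)
  usable <- which(h$status %in% c("matched", "flipped"))
  if (length(usable) == 0) .stopf("no usable loci for cohort scoring")
  col <- match(paste(h$chrom[usable], h$pos[usable]),
               paste(variants$chrom, variants$pos))
  w <- h$weight[usable]
  complement <- h$transform[usable] == "complement"
  d <- dosages[, col, drop = FALSE]
  d[, complement] <- 2 - d[, complement]
  d[is.na(d)] <- 0  # missing contributes nothing to the sum
  scores <- drop(d %*% w)
  names(scores) <- rownames(dosages)
  list(prs_raw = scores, harmonized = h, n_loci_used = length(usable))
}

#' Sample call-rate QC
#'
#' A sample passes only when its overall call rate is strictly greater than
#' the threshold.
#'
#' @param genotypes a \code{sample_genotypes}.
#' @param threshold call-rate threshold in (0, 1]; default 0.985.
#' @return list: \code{pass}, \code{call_rate}, \code{threshold}.
#' @export
check_call_rate <- function(genotypes, threshold = 0.985) {
  stopifnot(inherits(genotypes, "sample_genotypes"),
            threshold > 0, threshold <= 1)
  rate <- genotypes$call_rate
  list(pass = isTRUE(rate > threshold), call_rate = rate, threshold = threshold)
}
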