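# Rule-based screening of annotated variants for candidate actionable
# monogenic (secondary) findings. Output is a candidate list for manual
# classification and confirmation -- the rules only pre-filter.

.lof_consequences <- c("nonsense", "frameshift", "canonical_splice", "start_lost")

#' The default secondary-findings gene panel
#'
#' The 59-gene ACMG SF v2.0 panel with a per-gene flag marking genes for
#' which loss of function is an established disease mechanism. Shipped as
#' an editable tab-separated file so the panel can be extended as updated
#' recommendations accrue.
#'
#' @param path optional path to an alternative panel TSV with columns
#'   \code{gene} and \code{lof_mechanism}.
#' @return data.frame with columns \code{gene}, \code{lof_mechanism}.
#' @export
acmg_sf_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "acmg_sf_v2_panel.tsv",
                                package = "prsassay", mustWork = TRUE)
  panel <- .read_tsv(path)
  stopifnot(all(c("gene", "lof_mechanism") %in% names(panel)))
  panel$lof_mechanism <- as.logical(panel$lof_mechanism)
  panel
}

#' Construct secondary-findings filter rules
#'
#' @param gene_panel data.frame with \code{gene} and \code{lof_mechanism}
#'   columns; default \code{\link{acmg_sf_panel}()}.
#' @param maf_clinvar MAF cutoff (strict \code{<}) for ClinVar P/LP
#'   variants; default 0.001 (0.1\%).
#' @param maf_hgmd MAF cutoff for HGMD disease-causing (DM) variants;
#'   default 0.0003 (0.03\%).
#' @param maf_lof MAF cutoff for loss-of-function variants in
#'   LoF-mechanism genes; default 0.001 (0.1\%).
#' @param unknown_maf_passes treat an unknown MAF as passing the MAF
#'   condition (default TRUE: absence from frequency databases is evidence
#'   of rarity in a screening context).
#' @return list of class \code{filter_rules}.
#' @export
filter_rules <- function(gene_panel = acmg_sf_panel(),
                         maf_clinvar = 0.001, maf_hgmd = 0.0003,
                         maf_lof = 0.001, unknown_maf_passes = TRUE) {
  if (nrow(gene_panel) == 0) .stopf("gene panel is empty")
  for (th in c(maf_clinvar, maf_hgmd, maf_lof))
    if (!is.finite(th) || th <= 0 || th >= 1)
      .stopf("MAF thresholds must lie in (0, 1)")
  structure(list(gene_panel = gene_panel, maf_clinvar = maf_clinvar,
                 maf_hgmd = maf_hgmd, maf_lof = maf_lof,
                 unknown_maf_passes = unknown_maf_passes),
            class = "filter_rules")
}

#' Filter annotated variants to secondary-findings candidates
#'
#' A variant in a panel gene is flagged when it satisfies at least one of
#' four criteria: (1) previously identified as disease causing by the
#' laboratory (\code{lab_known_plp}); (2) ClinVar pathogenic/likely
#' pathogenic with MAF < 0.1\%; (3) an HGMD disease-causing (DM) variant
#' with MAF < 0.03\%; (4) a loss-of-function variant (nonsense, frameshift,
#' canonical splice-site, start-lost) with MAF < 0.1\% in a gene where loss
#' of function is a disease mechanism. All MAF comparisons are strict;
#' an unknown MAF passes by default. Every triggered rule is recorded.
#'
#' @param variants data.frame with columns \code{variant} (key), \code{gene},
#'   \code{consequence} (\code{nonsense}, \code{frameshift},
#'   \code{canonical_splice}, \code{start_lost}, \code{missense},
#'   \code{synonymous}, \code{other}), \code{maf} (fraction or NA),
#'   \code{clinvar} (\code{P}, \code{LP}, \code{VUS}, \code{LB}, \code{B},
#'   \code{none}), \code{hgmd_dm} (logical), \code{lab_known_plp} (logical).
#' @param rules a \code{\link{filter_rules}} object.
#' @return data.frame of flagged variants with a \code{rules_triggered}
#'   column (comma-separated subset of \code{lab_known}, \code{clinvar_plp},
#'   \code{hgmd_dm}, \code{lof}).
#' @export
filter_variants <- function(variants, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  required <- c("variant", "gene", "consequence", "maf", "clinvar",
                "hgmd_dm", "lab_known_plp")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0)
    .stopf("annotated variant table is missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  if (any(!is.na(variants$maf) & (variants$maf < 0 | variants$maf > 1)))
    .stopf("MAF values must lie in [0, 1] when known")

  in_panel <- variants$gene %in% rules$gene_panel$gene
  lof_genes <- rules$gene_panel$gene[rules$gene_panel$lof_mechanism]
  maf_lt <- function(threshold) {
    ifelse(is.na(variants$maf), rules$unknown_maf_passes,
           variants$maf < threshold)
  }
  hit <- cbind(
    lab_known = in_panel & variants$lab_known_plp %in% TRUE,
    clinvar_plp = in_panel & variants$clinvar %in% c("P", "LP") &
      maf_lt(rules$maf_clinvar),
    hgmd_dm = in_panel & variants$hgmd_dm %in% TRUE & maf_lt(rules$maf_hgmd),
    lof = in_panel & variants$consequence %in% .lof_consequences &
      variants$gene %in% lof_genes & maf_lt(rules$maf_lof)
  )
  flagged <- rowSums(hit) > 0
  out <- variants[flagged, , drop = FALSE]
  out$rules_triggered <- apply(hit[flagged, , drop = FALSE], 1, function(r) {
    paste(colnames(hit)[r], collapse = ",")
  })
  rownames(out) <- NULL
  out
}
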