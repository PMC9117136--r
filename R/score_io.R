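# Readers and writers for on-disk assay artifacts: scoring (weight) files,
# VCF genotypes, the reference-panel bundle, disease configuration, and the
# JSON report.

#' Construct a PRS weight table
#'
#' A weight table holds the loci of one published polygenic score: one row
#' per variant with its effect allele, other allele and per-allele weight on
#' the scale published by the score author (typically log-odds).
#'
#' @param records data.frame with columns \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{weight}.
#' @param prs_id identifier for the score (e.g. a PGS Catalog accession).
#' @return object of class \code{prs_weight_table}.
#' @export
weight_table <- function(records, prs_id = "PRS") {
  required <- c("chrom", "pos", "effect_allele", "other_allele", "weight")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    .stopf("weight table is missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  records <- records[required]
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  if (nrow(records) > 0) {
    if (anyNA(records$pos) || any(records$pos < 1))
      .stopf("weight table: positions must be 1-based and >= 1")
    if (any(!is.finite(records$weight)))
      .stopf("weight table: non-finite weight at row(s) %s",
             paste(which(!is.finite(records$weight)), collapse = ", "))
    same <- records$effect_allele == records$other_allele
    if (any(same))
      .stopf("weight table: effect allele equals other allele at row(s) %s",
             paste(which(same), collapse = ", "))
    key <- paste(records$chrom, records$pos, records$effect_allele, sep = ":")
    if (anyDuplicated(key))
      .stopf("weight table: duplicate variant key at row(s) %s",
             paste(which(duplicated(key)), collapse = ", "))
  }
  structure(list(prs_id = prs_id, records = records),
            class = "prs_weight_table")
}

#' @export
print.prs_weight_table <- function(x, ...) {
  cat(sprintf("<prs_weight_table> %s: %d loci\n", x$prs_id, nrow(x$records)))
  invisible(x)
}

# Column-name dialects for scoring files. PGS Catalog files use
# chr_name/chr_position/effect_allele/other_allele/effect_weight and may
# carry '#' metadata lines; generic files use chrom/pos/... directly.
.weight_dialects <- list(
  pgs_catalog = c(chrom = "chr_name", pos = "chr_position",
                  effect_allele = "effect_allele",
                  other_allele = "other_allele", weight = "effect_weight"),
  generic_tsv = c(chrom = "chrom", pos = "pos",
                  effect_allele = "effect_allele",
                  other_allele = "other_allele", weight = "weight")
)

#' Read a tab-separated PRS scoring file
#'
#' Accepts PGS-Catalog-style headers (\code{chr_name}, \code{chr_position},
#' \code{effect_allele}, \code{other_allele}, \code{effect_weight}; leading
#' \code{#} metadata lines are skipped) and generic headers (\code{chrom},
#' \code{pos}, \code{effect_allele}, \code{other_allele}, \code{weight}).
#'
#' @param path path to the scoring file.
#' @param dialect one of \code{"auto"}, \code{"pgs_catalog"},
#'   \code{"generic_tsv"}.
#' @param prs_id score identifier; defaults to the file name without
#'   extension.
#' @return a \code{prs_weight_table}.
#' @export
read_weight_table <- function(path, dialect = c("auto", "pgs_catalog", "generic_tsv"),
                              prs_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("scoring file not found: %s", path)
  prs_id <- prs_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- .read_tsv(path, comment.char = "#")
  if (dialect == "auto") {
    dialect <- if (all(.weight_dialects$pgs_catalog %in% names(raw)))
      "pgs_catalog"
    else if (all(.weight_dialects$generic_tsv %in% names(raw)))
      "generic_tsv"
    else .stopf(
      "scoring file %s: header matches neither the PGS Catalog nor the generic dialect (columns: %s)",
      path, paste(names(raw), collapse = ", "))
  }
  map <- .weight_dialects[[dialect]]
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0)
    .stopf("scoring file %s: missing required column(s): %s",
           path, paste(missing_cols, collapse = ", "))
  records <- data.frame(
    chrom = as.character(raw[[map[["chrom"]]]]),
    pos = raw[[map[["pos"]]]],
    effect_allele = raw[[map[["effect_allele"]]]],
    other_allele = raw[[map[["other_allele"]]]],
    weight = raw[[map[["weight"]]]],
    stringsAsFactors = FALSE
  )
  if (nrow(records) == 0) {
    .warnf("scoring file %s contains a header but no records", path)
  } else {
    w <- suppressWarnings(as.numeric(records$weight))
    bad <- which(is.na(w) & !is.na(records$weight))
    if (length(bad) > 0)
      .stopf("scoring file %s: non-numeric weight at row(s) %s",
             path, paste(bad, collapse = ", "))
    records$weight <- w
    records$pos <- as.integer(records$pos)
  }
  weight_table(records, prs_id = prs_id)
}

#' Construct per-sample genotypes
#'
#' @param sample_id sample identifier.
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{dosage} (ALT-allele dosage in [0, 2];
#'   \code{NA} marks a missing call).
#' @return object of class \code{sample_genotypes} with a \code{call_rate}
#'   field equal to the non-missing fraction.
#' @export
sample_genotypes <- function(sample_id, variants) {
  required <- c("chrom", "pos", "ref", "alt", "dosage")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0)
    .stopf("sample_genotypes: missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  variants <- variants[required]
  variants$chrom <- as.character(variants$chrom)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  d <- variants$dosage
  if (any(!is.na(d) & (d < 0 | d > 2)))
    .stopf("sample_genotypes: dosage outside [0, 2] for sample %s", sample_id)
  structure(list(
    sample_id = sample_id,
    variants = variants,
    call_rate = if (nrow(variants) == 0) NA_real_ else mean(!is.na(d))
  ), class = "sample_genotypes")
}

#' @export
print.sample_genotypes <- function(x, ...) {
  cat(sprintf("<sample_genotypes> %s: %d variants, call rate %.4f\n",
              x$sample_id, nrow(x$variants), x$call_rate))
  invisible(x)
}

# ALT-allele count from a GT string; NA when any allele is missing.
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_real_, length(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  if (any(ok)) {
    alleles <- strsplit(gt[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), numeric(1))
  }
  out
}

#' Read genotypes or imputed dosages from a VCF
#'
#' Records must be biallelic (normalized upstream); multi-allelic records are
#' rejected. The per-variant dosage is the imputed dosage (\code{DS} FORMAT
#' field) when present and \code{prefer_dosage} is set, otherwise the
#' ALT-allele count derived from \code{GT}. Missing genotypes stay missing:
#' they are masked, never imputed, and drive the call rate down.
#'
#' @param path VCF path (plain or gzip/bgzip).
#' @param samples optional character vector restricting to these sample ids;
#'   requesting an absent sample is an error.
#' @param prefer_dosage use the \code{DS} field over \code{GT} when both are
#'   present.
#' @return named list of \code{\link{sample_genotypes}}, one per sample.
#' @export
read_genotypes <- function(path, samples = NULL, prefer_dosage = TRUE) {
  if (!file.exists(path)) .stopf("VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    .stopf("VCF %s contains multi-allelic records; normalize to biallelic records upstream",
           path)
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_mat)) .stopf("VCF %s has no GT field", path)
  all_samples <- colnames(gt_mat)
  if (!is.null(samples)) {
    absent <- setdiff(samples, all_samples)
    if (length(absent) > 0)
      .stopf("sample(s) not present in VCF %s: %s", path,
             paste(absent, collapse = ", "))
    keep <- samples
  } else keep <- all_samples
  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  ds_mat <- if (has_ds && prefer_dosage)
    suppressWarnings(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
  else NULL
  out <- lapply(keep, function(s) {
    dos <- .gt_to_dosage(gt_mat[, s])
    if (!is.null(ds_mat)) {
      ds <- ds_mat[, s]
      dos <- ifelse(!is.na(ds), ds, dos)
    }
    sample_genotypes(s, data.frame(
      chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]),
      ref = fix[, "REF"],
      alt = alt,
      dosage = dos,
      stringsAsFactors = FALSE
    ))
  })
  names(out) <- keep
  out
}

#' Write a biallelic VCF with GT and DS fields
#'
#' Minimal VCF 4.2 writer used to materialize simulated cohorts. Hard-call
#' genotypes are derived by rounding the dosage; the dosage itself is carried
#' in \code{DS}. \code{NA} dosages become \code{./.} with no DS.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns,
#'   values in [0, 2] or NA.
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (one row per column of \code{dosages}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(dosages, variants, path) {
  stopifnot(ncol(dosages) == nrow(variants))
  ids <- rownames(dosages) %||% sprintf("S%05d", seq_len(nrow(dosages)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(variants)), function(j) {
    d <- dosages[, j]
    cell <- ifelse(is.na(d), "./.",
                   paste0(gt_codes[pmin(pmax(round(d), 0), 2) + 1], ":",
                          formatC(d, format = "g", digits = 6)))
    paste(c(variants$chrom[j], variants$pos[j], ".", variants$ref[j],
            variants$alt[j], ".", "PASS", ".", "GT:DS", cell), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reference bundle: one concern per plain tab-separated file, plus a
# manifest of counts so cross-file consistency is checkable before parsing.

.bundle_files <- c("manifest.tsv", "loadings.tsv", "eigenvalues.tsv",
                   "afreq.tsv", "coords.tsv", "models.tsv")

#' Write a reference bundle to a directory
#'
#' The bundle carries everything needed to adjust a prospective sample:
#' per-allele PC loadings, eigenvalues, reference allele frequencies,
#' reference-sample PC coordinates, and the per-disease adjustment models
#' with the reference mean/SD of the adjusted score. All values are written
#' in full double precision so a write/read round trip is exact.
#'
#' @param ref a \code{pca_reference} (see \code{\link{fit_reference_pca}}).
#' @param models list of \code{adjustment_model} objects.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_reference_bundle <- function(ref, models, dir) {
  stopifnot(inherits(ref, "pca_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- length(ref$eigenvalues)
  pc_names <- paste0("PC", seq_len(k))
  loadings <- cbind(ref$variants,
                    as.data.frame(ref$loadings, optional = TRUE))
  names(loadings) <- c(names(ref$variants), pc_names)
  .write_tsv(loadings, file.path(dir, "loadings.tsv"))
  .write_tsv(data.frame(pc = pc_names, eigenvalue = ref$eigenvalues),
             file.path(dir, "eigenvalues.tsv"))
  .write_tsv(cbind(ref$variants, data.frame(alt_freq = ref$allele_frequencies)),
             file.path(dir, "afreq.tsv"))
  coords <- data.frame(sample_id = rownames(ref$ref_coordinates),
                       as.data.frame(ref$ref_coordinates, optional = TRUE))
  names(coords) <- c("sample_id", pc_names)
  .write_tsv(coords, file.path(dir, "coords.tsv"))
  mdf <- do.call(rbind, lapply(models, function(m) {
    stopifnot(inherits(m, "adjustment_model"))
    data.frame(disease = m$disease, intercept = m$intercept,
               b1 = m$beta[1], b2 = m$beta[2], b3 = m$beta[3], b4 = m$beta[4],
               ref_mean = m$ref_mean_adj, ref_sd = m$ref_sd_adj,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(mdf, file.path(dir, "models.tsv"))
  manifest <- data.frame(
    key = c("n_variants", "n_pcs", "n_ref_samples", "n_models", "scaling_mode"),
    value = c(nrow(ref$variants), k, nrow(ref$ref_coordinates),
              length(models), ref$scaling_mode)
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a reference bundle
#'
#' Validates cross-file consistency: loadings and allele frequencies must
#' cover the identical variant set, coordinate/eigenvalue PC counts must
#' agree, and every adjustment model must carry exactly four PC
#' coefficients.
#'
#' @param dir bundle directory written by \code{\link{write_reference_bundle}}.
#' @return list with elements \code{pca} (a \code{pca_reference}) and
#'   \code{models} (named list of \code{adjustment_model}).
#' @export
read_reference_bundle <- function(dir) {
  missing_files <- .bundle_files[!file.exists(file.path(dir, .bundle_files))]
  if (length(missing_files) > 0)
    .stopf("reference bundle %s is missing file(s): %s", dir,
           paste(missing_files, collapse = ", "))
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  man <- stats::setNames(manifest$value, manifest$key)
  loadings <- .read_tsv(file.path(dir, "loadings.tsv"))
  eig <- .read_tsv(file.path(dir, "eigenvalues.tsv"))
  afreq <- .read_tsv(file.path(dir, "afreq.tsv"))
  coords <- .read_tsv(file.path(dir, "coords.tsv"))
  mdf <- .read_tsv(file.path(dir, "models.tsv"))

  pc_names <- grep("^PC[0-9]+$", names(loadings), value = TRUE)
  k <- length(pc_names)
  if (k != nrow(eig))
    .stopf("reference bundle %s: %d PC columns in loadings but %d eigenvalues",
           dir, k, nrow(eig))
  vcols <- c("chrom", "pos", "ref", "alt")
  key_l <- do.call(variant_key, loadings[vcols])
  key_f <- do.call(variant_key, afreq[vcols])
  if (!identical(key_l, key_f))
    .stopf("reference bundle %s: loadings and allele frequencies cover different variant sets",
           dir)
  beta_cols <- grep("^b[0-9]+$", names(mdf), value = TRUE)
  if (!identical(sort(beta_cols), c("b1", "b2", "b3", "b4")))
    .stopf("reference bundle %s: adjustment models must have exactly 4 PC coefficients (b1..b4); found: %s",
           dir, paste(beta_cols, collapse = ", "))
  ev <- eig$eigenvalue
  if (is.unsorted(rev(ev))) .stopf("reference bundle %s: eigenvalues not sorted descending", dir)
  coord_mat <- as.matrix(coords[pc_names])
  rownames(coord_mat) <- coords$sample_id
  variants <- loadings[vcols]
  variants$chrom <- as.character(variants$chrom)
  ref <- structure(list(
    variants = variants,
    allele_frequencies = afreq$alt_freq,
    loadings = as.matrix(loadings[pc_names]),
    eigenvalues = ev,
    ref_coordinates = coord_mat,
    scaling_mode = unname(man["scaling_mode"])
  ), class = "pca_reference")
  models <- lapply(seq_len(nrow(mdf)), function(i) {
    adjustment_model(disease = mdf$disease[i], intercept = mdf$intercept[i],
                     beta = as.numeric(mdf[i, c("b1", "b2", "b3", "b4")]),
                     ref_mean_adj = mdf$ref_mean[i], ref_sd_adj = mdf$ref_sd[i])
  })
  names(models) <- mdf$disease
  list(pca = ref, models = models)
}

#' Read the per-disease assay configuration (YAML)
#'
#' The file lists one entry per disease with the published per-SD odds ratio
#' (\code{or_sd}), the target odds ratio defining high risk (default 2), the
#' sex the disease applies to (\code{male}, \code{female} or \code{any}),
#' and the scoring-file name under the weights directory.
#'
#' @param path YAML file.
#' @return data.frame with columns \code{disease}, \code{or_sd},
#'   \code{target_or}, \code{sex}, \code{weights}.
#' @export
read_disease_config <- function(path) {
  if (!file.exists(path)) .stopf("disease config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  entries <- cfg$diseases %||% .stopf("disease config %s: no 'diseases' key", path)
  out <- do.call(rbind, lapply(entries, function(e) {
    if (is.null(e$disease) || is.null(e$or_sd))
      .stopf("disease config %s: every entry needs 'disease' and 'or_sd'", path)
    data.frame(disease = e$disease,
               or_sd = as.numeric(e$or_sd),
               target_or = as.numeric(e$target_or %||% 2),
               sex = as.character(e$sex %||% "any"),
               weights = as.character(e$weights %||% NA_character_),
               stringsAsFactors = FALSE)
  }))
  if (any(out$or_sd <= 1))
    .stopf("disease config %s: or_sd must be > 1 (threshold undefined otherwise)", path)
  if (any(out$target_or <= 1))
    .stopf("disease config %s: target_or must be > 1", path)
  bad_sex <- setdiff(out$sex, c("male", "female", "any"))
  if (length(bad_sex) > 0)
    .stopf("disease config %s: sex must be male/female/any", path)
  out
}

# Fixed limitations text included verbatim in every report.
.report_limitations <- paste(
  "Polygenic risk scores summarize common-variant risk only and do not",
  "account for monogenic variants, family history, or non-genetic risk",
  "factors. Score transferability is reduced in individuals whose genetic",
  "ancestry is under-represented in the discovery studies, even after",
  "population-structure adjustment. Secondary-findings candidates require",
  "manual classification and orthogonal confirmation before clinical",
  "reporting. This report does not estimate absolute disease risk and is",
  "not a clinical recommendation.")

#' Write the assay report as JSON
#'
#' One entry per configured disease per sample with the raw, predicted,
#' adjusted and standardized adjusted scores, the threshold used, and the
#' dichotomous category (\code{"high"} or \code{"average"}). Secondary
#' findings are listed in a separate block, never merged with the PRS
#' results, and no interaction between the two is computed or commented on.
#'
#' @param results data.frame of score results (one row per sample/disease)
#'   as produced by \code{\link{classify}}; must contain columns
#'   \code{sample_id}, \code{disease}, \code{prs_raw}, \code{prs_pred},
#'   \code{prs_adj}, \code{prs_std_adj}, \code{tau}, \code{category}.
#' @param findings data.frame of secondary findings (possibly 0-row), as
#'   produced by \code{\link{filter_variants}}.
#' @param path output JSON path.
#' @param qc optional named list with per-sample call rates.
#' @return the report list, invisibly.
#' @export
write_report <- function(results, findings, path, qc = NULL) {
  stopifnot(is.data.frame(results))
  samples <- unique(results$sample_id)
  sample_blocks <- lapply(samples, function(s) {
    rows <- results[results$sample_id == s, , drop = FALSE]
    prs <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      list(disease = r$disease,
           prs_raw = r$prs_raw, prs_pred = r$prs_pred, prs_adj = r$prs_adj,
           prs_std_adj = r$prs_std_adj, tau = r$tau,
           category = r$category)
    })
    block <- list(sample_id = s, prs = prs)
    if (!is.null(qc) && !is.null(qc[[s]])) block$qc <- qc[[s]]
    block
  })
  fnd <- if (is.null(findings) || nrow(findings) == 0) list()
  else lapply(seq_len(nrow(findings)), function(i) {
    f <- findings[i, ]
    list(variant = f$variant, gene = f$gene,
         rules_triggered = strsplit(f$rules_triggered, ",")[[1]],
         status = "candidate for review")
  })
  report <- list(samples = sample_blocks,
                 secondary_findings = fnd,
                 limitations = .report_limitations)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}
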