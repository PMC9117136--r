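# Shared fixtures, all generated in code at test time.

write_generic_weights <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal hand-written VCF with optional DS values (NA = GT only).
write_toy_vcf <- function(path, chrom, pos, ref, alt, gt, ds = NULL,
                          sample_ids = "SAMPLE1") {
  n_s <- length(sample_ids)
  gt <- matrix(gt, ncol = n_s)
  fmt <- if (is.null(ds)) "GT" else "GT:DS"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(ds)) "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  for (i in seq_along(pos)) {
    cells <- vapply(seq_len(n_s), function(j) {
      if (is.null(ds) || is.na(ds[i])) {
        if (is.null(ds)) gt[i, j] else paste0(gt[i, j], ":.")
      } else paste0(gt[i, j], ":", ds[i])
    }, character(1))
    lines <- c(lines, paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".",
                              "PASS", ".", fmt, cells), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# sample_genotypes built directly from vectors
toy_genotypes <- function(dosage, ref = "A", alt = "G", chrom = "1",
                          pos = seq_along(dosage) * 100L, id = "T1") {
  sample_genotypes(id, data.frame(
    chrom = chrom, pos = pos,
    ref = rep_len(ref, length(dosage)), alt = rep_len(alt, length(dosage)),
    dosage = dosage, stringsAsFactors = FALSE))
}

# One moderate structured cohort reused by several adjustment tests.
.shared <- new.env()
shared_cohort <- function() {
  if (is.null(.shared$sim)) {
    spec <- cohort_spec(n_samples = c(700, 700), n_variants = 200,
                        or_sd_true = c(disease_a = 1.3), seed = 42)
    .shared$sim <- simulate_cohort(spec)
  }
  .shared$sim
}

# Rebuild a reference cohort member as a prospective sample_genotypes
cohort_member <- function(sim, i) {
  v <- sim$cohort$variants
  sample_genotypes(rownames(sim$cohort$dosages)[i], data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    dosage = sim$cohort$dosages[i, ], stringsAsFactors = FALSE))
}

# independent palindromic-pair check for oracle computations
.is_pal <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  nchar(a) == 1 & nchar(b) == 1 & unname(comp[a]) == b
}

# 2x2 cells from classified categories and true labels
cells_from_calls <- function(category, labels) {
  c(a = sum(category == "high" & labels == 1),
    b = sum(category == "high" & labels == 0),
    c = sum(category == "average" & labels == 1),
    d = sum(category == "average" & labels == 0))
}
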