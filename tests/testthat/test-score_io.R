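test_that("generic scoring files parse into weight tables", {
  path <- write_generic_weights(data.frame(
    chrom = "1", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    weight = c(0.2, -0.3, 0.1)))
  wt <- read_weight_table(path)
  expect_s3_class(wt, "prs_weight_table")
  expect_equal(nrow(wt$records), 3)
  expect_equal(wt$records$weight, c(0.2, -0.3, 0.1))
})

test_that("PGS-Catalog headers and comment lines are accepted", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("#pgs_id=PGS000999", "#genome_build=GRCh37",
               paste("chr_name", "chr_position", "effect_allele",
                     "other_allele", "effect_weight", sep = "\t"),
               paste("2", "5000", "T", "C", "0.05", sep = "\t")), path)
  wt <- read_weight_table(path, prs_id = "PGS000999")
  expect_equal(wt$prs_id, "PGS000999")
  expect_equal(wt$records$pos, 5000L)
  expect_equal(wt$records$weight, 0.05)
})

test_that("malformed scoring files are rejected with row-level errors", {
  dup <- write_generic_weights(data.frame(
    chrom = "1", pos = c(100L, 100L), effect_allele = c("A", "A"),
    other_allele = c("G", "G"), weight = c(0.1, 0.2)))
  expect_error(read_weight_table(dup), "duplicate variant key at row\\(s\\) 2")

  nonnum <- tempfile()
  writeLines(c("chrom\tpos\teffect_allele\tother_allele\tweight",
               "1\t100\tA\tG\tnot_a_number"), nonnum)
  expect_error(read_weight_table(nonnum), "non-numeric weight at row\\(s\\) 1")

  nocol <- write_generic_weights(data.frame(
    chrom = "1", pos = 100L, effect_allele = "A", weight = 0.1))
  expect_error(read_weight_table(nocol), "neither the PGS Catalog nor the generic")

  same_alleles <- write_generic_weights(data.frame(
    chrom = "1", pos = 100L, effect_allele = "A", other_allele = "A",
    weight = 0.1))
  expect_error(read_weight_table(same_alleles), "effect allele equals other allele")
})

test_that("a header-only scoring file yields an empty table with a warning", {
  path <- tempfile()
  writeLines("chrom\tpos\teffect_allele\tother_allele\tweight", path)
  expect_warning(wt <- read_weight_table(path), "no records")
  expect_equal(nrow(wt$records), 0)
})

test_that("VCF genotypes load with GT-derived dosages and masked missingness", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"),
                        chrom = c("1", "1", "1", "1"),
                        pos = c(100, 200, 300, 400),
                        ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
                        gt = c("0/1", "1/1", "./.", "0/0"))
  g <- read_genotypes(path)[["SAMPLE1"]]
  expect_equal(g$variants$dosage, c(1, 2, NA, 0))
  expect_equal(g$call_rate, 3 / 4)
})

test_that("imputed dosage takes precedence over GT only when preferred", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"),
                        chrom = "1", pos = 100, ref = "A", alt = "G",
                        gt = "1/1", ds = 1.73)
  expect_equal(read_genotypes(path, prefer_dosage = TRUE)[["SAMPLE1"]]$variants$dosage, 1.73)
  expect_equal(read_genotypes(path, prefer_dosage = FALSE)[["SAMPLE1"]]$variants$dosage, 2)
})

test_that("multi-allelic records and absent samples are rejected", {
  bad <- write_toy_vcf(tempfile(fileext = ".vcf"), chrom = "1", pos = 100,
                       ref = "A", alt = "G,T", gt = "1/2")
  expect_error(read_genotypes(bad), "multi-allelic")
  ok <- write_toy_vcf(tempfile(fileext = ".vcf"), chrom = "1", pos = 100,
                      ref = "A", alt = "G", gt = "0/1")
  expect_error(read_genotypes(ok, samples = "NOPE"), "not present")
})

test_that("reference bundles round-trip bit-identically", {
  sim <- shared_cohort()
  dir <- tempfile("bundle")
  write_reference_bundle(sim$pca, sim$models, dir)
  back <- read_reference_bundle(dir)
  expect_identical(unname(back$pca$loadings), unname(sim$pca$loadings))
  expect_identical(back$pca$eigenvalues, sim$pca$eigenvalues)
  expect_identical(back$pca$allele_frequencies, sim$pca$allele_frequencies)
  expect_identical(unname(back$pca$ref_coordinates),
                   unname(sim$pca$ref_coordinates))
  m1 <- back$models$disease_a; m2 <- sim$models$disease_a
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$ref_mean_adj, m2$ref_mean_adj)
  expect_identical(m1$ref_sd_adj, m2$ref_sd_adj)
})

test_that("incomplete or non-conforming bundles are rejected", {
  sim <- shared_cohort()
  dir <- tempfile("bundle")
  write_reference_bundle(sim$pca, sim$models, dir)
  file.remove(file.path(dir, "eigenvalues.tsv"))
  expect_error(read_reference_bundle(dir), "missing file.*eigenvalues")

  dir2 <- tempfile("bundle")
  write_reference_bundle(sim$pca, sim$models, dir2)
  mdf <- read.table(file.path(dir2, "models.tsv"), header = TRUE, sep = "\t")
  mdf$b4 <- NULL
  write.table(mdf, file.path(dir2, "models.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_reference_bundle(dir2), "exactly 4 PC coefficients")
})

test_that("disease config YAML parses and validates", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("diseases:",
               "  - disease: afib", "    or_sd: 1.45", "    weights: w.tsv",
               "  - disease: brca", "    or_sd: 1.6", "    target_or: 3",
               "    sex: female", "    weights: w2.tsv"), path)
  cfg <- read_disease_config(path)
  expect_equal(cfg$disease, c("afib", "brca"))
  expect_equal(cfg$target_or, c(2, 3))
  expect_equal(cfg$sex, c("any", "female"))

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("diseases:", "  - disease: x", "    or_sd: 0.9"), bad)
  expect_error(read_disease_config(bad), "or_sd must be > 1")
})

test_that("the JSON report separates PRS results from secondary findings", {
  results <- data.frame(
    sample_id = "S1", disease = c("a", "b", "c", "d", "e", "f"),
    prs_raw = 0, prs_pred = 0, prs_adj = 0,
    prs_std_adj = c(0.5, -1, 0, 1, 0.2, 3.5), tau = 3,
    category = c(rep("average", 5), "high"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".json")
  write_report(results, findings = data.frame(), path = path)
  rep <- jsonlite::read_json(path)
  cats <- vapply(rep$samples[[1]]$prs, `[[`, character(1), "category")
  expect_equal(sum(cats == "average"), 5)
  expect_equal(sum(cats == "high"), 1)
  expect_equal(rep$secondary_findings, list())
  expect_match(rep$limitations, "not a clinical recommendation")

  results$category <- "average"
  write_report(results, findings = NULL, path = path)
  rep2 <- jsonlite::read_json(path)
  expect_equal(vapply(rep2$samples[[1]]$prs, `[[`, character(1), "category"),
               rep("average", 6))
})
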