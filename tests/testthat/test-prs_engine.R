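toy_weights <- function(df) weight_table(df, prs_id = "TOY")

test_that("effect alleles are matched to ALT (identity) or REF (complement)", {
  g <- toy_genotypes(c(1, 0.5), ref = c("A", "A"), alt = c("G", "G"))
  wt <- toy_weights(data.frame(
    chrom = "1", pos = c(100L, 200L),
    effect_allele = c("G", "A"), other_allele = c("A", "G"),
    weight = c(0.2, 0.2)))
  h <- harmonize(wt, g)
  expect_equal(h$status, c("matched", "flipped"))
  expect_equal(h$transform, c("identity", "complement"))
  expect_equal(h$effect_dosage, c(1, 1.5))
})

test_that("strand-complemented non-palindromic alleles are rescued", {
  # weights report G/A; VCF carries the other strand C/T
  g <- toy_genotypes(0.5, ref = "T", alt = "C")
  wt <- toy_weights(data.frame(chrom = "1", pos = 100L,
                               effect_allele = "G", other_allele = "A",
                               weight = 1))
  h <- harmonize(wt, g)
  expect_equal(h$status, "matched")
  expect_equal(h$effect_dosage, 0.5)
})

test_that("a five-variant table with one palindromic site drops it under policy drop", {
  g <- sample_genotypes("T1", data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("A", "C", "G", "T", "A"), alt = c("G", "T", "A", "C", "T"),
    dosage = c(2, 1, 0, 1, 2), stringsAsFactors = FALSE))
  wt <- toy_weights(data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
    effect_allele = c("G", "T", "G", "C", "A"),
    other_allele = c("A", "C", "A", "T", "T"),
    weight = c(0.1, 0.2, -0.1, 0.3, 0.5)))
  h_drop <- harmonize(wt, g, ambiguous_policy = "drop")
  expect_equal(sum(h_drop$status %in% c("matched", "flipped")), 4)
  expect_equal(sum(h_drop$status == "dropped_ambiguous"), 1)
  expect_equal(h_drop$reason[5], "palindromic_snv")
  h_keep <- harmonize(wt, g, ambiguous_policy = "keep")
  expect_equal(sum(h_keep$status %in% c("matched", "flipped")), 5)
  # locus 5: effect A vs VCF A/T -> complement transform, dosage 2 - 2 = 0
  expect_equal(h_keep$effect_dosage[5], 0)
})

test_that("unmatchable loci are dropped with reasons, never fatal", {
  g <- toy_genotypes(c(1, NA), ref = c("A", "A"), alt = c("G", "G"),
                     pos = c(100L, 200L))
  wt <- toy_weights(data.frame(
    chrom = "1", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "G", "G"), other_allele = c("C", "A", "A"),
    weight = c(0.1, 0.1, 0.1)))
  h <- harmonize(wt, g)
  expect_equal(h$status, c("dropped_missing", "dropped_missing", "dropped_missing"))
  expect_equal(h$reason, c("allele_mismatch", "missing_genotype",
                           "absent_from_genotypes"))
  expect_equal(nrow(drop_log(h)), 3)
})

test_that("the raw score is the dosage-weighted sum over available loci", {
  g <- toy_genotypes(c(0, 1, 2), alt = "G", ref = "A")
  wt <- toy_weights(data.frame(
    chrom = "1", pos = c(100L, 200L, 300L),
    effect_allele = "G", other_allele = "A", weight = c(0.2, -0.3, 0.1)))
  rs <- compute_raw_prs(harmonize(wt, g), "T1", "toy")
  expect_equal(rs$prs_raw, -0.1)
  expect_equal(rs$n_loci_used, 3)

  # one missing call of three: sum over the remaining two only
  g2 <- toy_genotypes(c(0, NA, 2), alt = "G", ref = "A")
  rs2 <- compute_raw_prs(harmonize(wt, g2), "T1", "toy")
  expect_equal(rs2$prs_raw, 0.2)
  expect_equal(rs2$n_loci_used, 2)
  expect_equal(rs2$n_loci_total, 3)

  wt0 <- toy_weights(data.frame(chrom = "1", pos = c(100L, 200L),
                                effect_allele = "G", other_allele = "A",
                                weight = c(0, 0)))
  expect_equal(compute_raw_prs(harmonize(wt0, g), "T1", "toy")$prs_raw, 0)

  g3 <- toy_genotypes(NA_real_, alt = "G", ref = "A")
  wt3 <- toy_weights(data.frame(chrom = "1", pos = 100L,
                                effect_allele = "G", other_allele = "A",
                                weight = 0.5))
  expect_error(compute_raw_prs(harmonize(wt3, g3), "T1", "afib"),
               "no usable loci.*afib")
})

test_that("scoring is invariant to locus order and accounts for every drop", {
  set.seed(5)
  for (rep in 1:10) {
    m <- 30
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    dos <- sample(c(0, 1, 2, NA), m, TRUE, prob = c(.3, .3, .3, .1))
    g <- sample_genotypes("P", data.frame(chrom = "1", pos = seq_len(m) * 10L,
                                          ref = ref, alt = alt, dosage = dos,
                                          stringsAsFactors = FALSE))
    eff_is_alt <- sample(c(TRUE, FALSE), m, TRUE)
    wt_df <- data.frame(chrom = "1", pos = seq_len(m) * 10L,
                        effect_allele = ifelse(eff_is_alt, alt, ref),
                        other_allele = ifelse(eff_is_alt, ref, alt),
                        weight = rnorm(m), stringsAsFactors = FALSE)
    h <- harmonize(toy_weights(wt_df), g)
    rs <- compute_raw_prs(h, "P", "toy")
    # permutation invariance
    perm <- sample(m)
    rs_p <- compute_raw_prs(harmonize(toy_weights(wt_df[perm, ]), g), "P", "toy")
    expect_equal(rs_p$prs_raw, rs$prs_raw)
    # drop accounting
    expect_equal(rs$n_loci_total - rs$n_loci_used, nrow(drop_log(h)))
    # brute-force oracle: effect dosage rebuilt from scratch per locus
    oracle <- 0
    for (i in seq_len(m)) {
      if (is.na(dos[i])) next
      if (.is_pal(wt_df$effect_allele[i], wt_df$other_allele[i])) next
      d_eff <- if (eff_is_alt[i]) dos[i] else 2 - dos[i]
      oracle <- oracle + wt_df$weight[i] * d_eff
    }
    expect_equal(rs$prs_raw, oracle)
  }
})

test_that("relabelling REF/ALT at every locus leaves the score unchanged", {
  # complement correctness: swapping the VCF's REF/ALT (dosage -> 2 - d)
  # must not move the harmonized score
  set.seed(6)
  m <- 25
  dos <- sample(0:2, m, TRUE)
  wt_df <- data.frame(chrom = "1", pos = seq_len(m) * 10L,
                      effect_allele = "G", other_allele = "A",
                      weight = rnorm(m), stringsAsFactors = FALSE)
  g1 <- toy_genotypes(dos, ref = "A", alt = "G")
  g2 <- toy_genotypes(2 - dos, ref = "G", alt = "A")
  s1 <- compute_raw_prs(harmonize(toy_weights(wt_df), g1), "P", "t")$prs_raw
  s2 <- compute_raw_prs(harmonize(toy_weights(wt_df), g2), "P", "t")$prs_raw
  expect_equal(s1, s2)
})

test_that("call-rate QC uses a strict greater-than boundary", {
  g_full <- toy_genotypes(rep(1, 200))
  expect_true(check_call_rate(g_full, 0.985)$pass)

  d <- rep(1, 1000); d[1:15] <- NA  # call rate exactly 0.985
  g_edge <- toy_genotypes(d)
  cr <- check_call_rate(g_edge, 0.985)
  expect_equal(cr$call_rate, 0.985)
  expect_false(cr$pass)

  d2 <- rep(1, 100); d2[1:3] <- NA  # 0.97
  expect_false(check_call_rate(toy_genotypes(d2), 0.985)$pass)
})

test_that("cohort scoring agrees with per-sample scoring", {
  sim <- shared_cohort()
  idx <- c(1, 500, 1400)
  for (i in idx) {
    g <- cohort_member(sim, i)
    rs <- compute_raw_prs(harmonize(sim$weights, g, ambiguous_policy = "keep"),
                          g$sample_id, "disease_a")
    expect_equal(rs$prs_raw, unname(sim$prs_raw[i]), tolerance = 1e-12)
  }
})

test_that("mismatched chromosome naming styles raise a warning", {
  g <- toy_genotypes(1, ref = "A", alt = "G")
  wt <- weight_table(data.frame(chrom = "chr1", pos = 100L,
                                effect_allele = "G", other_allele = "A",
                                weight = 0.1), "TOY")
  expect_warning(harmonize(wt, g), "naming styles")
})
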