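review_cand <- function(...) {
  row <- list(variant_key = "chr1:100:A:T", chrom = "chr1", pos = 100,
              proband = "P", pattern = "de_novo", impact_tier = "HIGH",
              clinvar = "absent", gnomad_af = 0, gnomad_ac = 0,
              gnomad_hom = 0, gnomad_hemi = 0, controls_ac = 0,
              non_neuro_ac = 0, cadd_phred = 32, revel = 0.9,
              alphamissense = 0.8, spliceai = 0.2, gene = "G1", moi = "AD",
              ndd = FALSE, susceptibility_only = FALSE,
              incomplete_penetrance = FALSE, pli = 0.99, dosage = 1,
              hemizygous = FALSE, depth = 40, alt_fraction = 0.5,
              partner_key = NA_character_)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

test_that("locus evidence sums same-impact alleles at the coordinate", {
  pop <- data.frame(chrom = "chr1", pos = c(100, 100, 100),
                    ref = "A", alt = c("T", "G", "C"),
                    impact_tier = c("MODERATE", "MODERATE", "LOW"),
                    ac = c(1, 2, 50), an = 1e5, af = c(1e-5, 2e-5, 5e-4),
                    hom = c(0, 1, 3), hemi = 0, controls_ac = c(0, 1, 9),
                    non_neuro_ac = 0)
  pop$variant_key <- variant_key(pop$chrom, pop$pos, pop$ref, pop$alt)
  cand <- review_cand(impact_tier = "MODERATE", gnomad_ac = 1,
                      gnomad_af = 1e-5)
  ev <- aggregate_locus_evidence(cand, pop)
  # two missense alleles summed, the co-located synonymous row excluded
  expect_equal(ev$summed_ac, 3)
  expect_equal(ev$summed_af, 3e-5)
  expect_equal(ev$hom_count, 1)
  expect_equal(ev$controls_ac, 1)
  # sole variant at a site: aggregates equal its own counts
  lone <- review_cand(pos = 999, gnomad_ac = 4, gnomad_af = 4e-5)
  ev2 <- aggregate_locus_evidence(lone, pop)
  expect_equal(ev2$summed_ac, 4)
  expect_equal(ev2$summed_af, 4e-5)
  ev3 <- aggregate_locus_evidence(lone, NULL)
  expect_equal(ev3$summed_ac, 4)
})

ev0 <- function(...) {
  ev <- list(summed_ac = 0, summed_af = 0, hom_count = 0, hemi_count = 0,
             controls_ac = 0, non_neuro_ac = 0)
  over <- list(...)
  ev[names(over)] <- over
  ev
}

test_that("first-pass screen applies the ordered rejection clauses", {
  cfg <- review_config(strong_similarity = 3)
  # a clean de novo with a good match is retained
  expect_identical(first_pass_screen(review_cand(), ev0(), 2, cfg)$status,
                   "retain")
  # recessive summed AF above 0.001
  d <- first_pass_screen(review_cand(pattern = "homozygous", moi = "AR"),
                         ev0(summed_af = 0.005), 2, cfg)
  expect_identical(d$reason, "frequency_fail")
  # recessive hom/hemi above 2
  d <- first_pass_screen(review_cand(pattern = "homozygous", moi = "AR"),
                         ev0(hom_count = 3), 4, cfg)
  expect_identical(d$reason, "frequency_fail")
  # hom presence tolerated only under a strong phenotype match
  d <- first_pass_screen(review_cand(pattern = "homozygous", moi = "AR"),
                         ev0(hom_count = 1), 1, cfg)
  expect_identical(d$reason, "frequency_fail")
  d <- first_pass_screen(review_cand(pattern = "homozygous", moi = "AR"),
                         ev0(hom_count = 1), 4, cfg)
  expect_identical(d$status, "retain")
  # dominant non-NDD with summed AC 3 and no penetrance escape
  d <- first_pass_screen(review_cand(), ev0(summed_ac = 3), 2, cfg)
  expect_identical(d$reason, "frequency_fail")
  expect_identical(first_pass_screen(
    review_cand(incomplete_penetrance = TRUE),
    ev0(summed_ac = 3), 2, cfg)$status, "retain")
  # dominant NDD: controls AC > 2 rejects, non-neuro up to 1 is retained
  d <- first_pass_screen(review_cand(ndd = TRUE), ev0(controls_ac = 3), 2, cfg)
  expect_identical(d$reason, "frequency_fail")
  expect_identical(first_pass_screen(review_cand(ndd = TRUE),
                                     ev0(non_neuro_ac = 1), 2, cfg)$status,
                   "retain")
  d <- first_pass_screen(review_cand(ndd = TRUE), ev0(non_neuro_ac = 2), 2,
                         cfg)
  expect_identical(d$reason, "frequency_fail")
  # any hom/hemi presence is disallowed for dominant variants
  d <- first_pass_screen(review_cand(), ev0(hemi_count = 1), 4, cfg)
  expect_identical(d$reason, "frequency_fail")
  # de novo het in an AR-only gene without a partner
  d <- first_pass_screen(review_cand(moi = "AR"), ev0(), 2, cfg)
  expect_identical(d$reason, "moi_inconsistent")
  # missing gene record
  d <- first_pass_screen(review_cand(gene = NA, moi = NA), ev0(), 2, cfg)
  expect_identical(d$reason, "moi_inconsistent")
  # susceptibility-only association
  d <- first_pass_screen(review_cand(susceptibility_only = TRUE), ev0(), 2,
                         cfg)
  expect_identical(d$reason, "susceptibility_only")
  # phenotype floor
  d <- first_pass_screen(review_cand(), ev0(), 0.1, cfg)
  expect_identical(d$reason, "phenotype_mismatch")
  # in-silico benign consensus fires first
  d <- first_pass_screen(review_cand(cadd_phred = 3, revel = 0.05,
                                     alphamissense = 0.1, spliceai = 0.01),
                         ev0(summed_ac = 10), 2, cfg)
  expect_identical(d$reason, "insilico_benign")
  # read-support quality proxy
  d <- first_pass_screen(review_cand(alt_fraction = 0.1), ev0(), 2, cfg)
  expect_identical(d$reason, "quality_fail")
  d <- first_pass_screen(review_cand(pattern = "homozygous", moi = "AR",
                                     dosage = 2, alt_fraction = 0.6),
                         ev0(), 2, cfg)
  expect_identical(d$reason, "quality_fail")
})

test_that("screening decisions do not depend on candidate order", {
  cfg <- review_config(strong_similarity = 3)
  cands <- list(review_cand(), review_cand(moi = "AR"),
                review_cand(susceptibility_only = TRUE),
                review_cand(alt_fraction = 0.1))
  sims <- c(2, 2, 2, 2)
  ref <- lapply(seq_along(cands), function(i)
    first_pass_screen(cands[[i]], ev0(), sims[i], cfg)$reason)
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    got <- lapply(perm, function(i)
      first_pass_screen(cands[[i]], ev0(), sims[i], cfg)$reason)
    expect_identical(got, ref[perm])
  }
})

test_that("ACMG criteria follow their codified clauses", {
  crit <- assign_acmg_criteria(review_cand(), ev0())
  expect_setequal(crit$criterion, c("PVS1", "PS2", "PM2", "PP3"))
  # stand-alone frequency
  crit2 <- assign_acmg_criteria(review_cand(gnomad_af = 0.06, cadd_phred = 15,
                                            revel = 0.5, pattern = "unknown",
                                            impact_tier = "MODERATE"),
                                ev0(summed_af = 0.06))
  expect_true("BA1" %in% crit2$criterion)
  # benign in-silico consensus
  crit3 <- assign_acmg_criteria(review_cand(impact_tier = "MODERATE",
                                            pattern = "unknown",
                                            cadd_phred = 3, revel = 0.05,
                                            alphamissense = 0.1,
                                            spliceai = 0.01),
                                ev0())
  expect_true("BP4" %in% crit3$criterion)
  # in-trans partner with P/LP annotation in a recessive gene
  crit4 <- assign_acmg_criteria(review_cand(pattern = "compound_het",
                                            moi = "AR"), ev0(),
                                partner_clinvar = "likely_pathogenic")
  expect_true("PM3" %in% crit4$criterion)
  # BS1/BS2 on elevated frequency and hom counts
  crit5 <- assign_acmg_criteria(review_cand(gnomad_af = 0.02),
                                ev0(summed_af = 0.02, hom_count = 5))
  expect_true(all(c("BS1", "BS2") %in% crit5$criterion))
})

# independent closed-form evaluation of the points framework
ref_tavtigian <- function(criteria, prior = 0.10, odds = 350) {
  if (any(criteria$strength == "stand_alone" & criteria$benign)) return(0)
  pts <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8)
  total <- sum(ifelse(criteria$benign, -1, 1) * pts[criteria$strength]) / 8
  o <- odds^total
  o * prior / ((o - 1) * prior + 1)
}

test_that("the Bayesian combiner matches closed-form hand evaluations", {
  empty <- data.frame(criterion = character(), strength = character(),
                      benign = logical())
  r0 <- combine_tavtigian(empty)
  expect_equal(r0$posterior, 0.10)
  expect_identical(r0$class, "VUS")
  expect_false(r0$returnable)
  # PVS1 + PM2: odds 350^1.25
  r1 <- combine_tavtigian(data.frame(
    criterion = c("PVS1", "PM2"), strength = c("very_strong", "moderate"),
    benign = FALSE))
  expect_equal(r1$posterior, 350^1.25 * 0.1 / ((350^1.25 - 1) * 0.1 + 1))
  expect_equal(r1$posterior, 0.9941, tolerance = 1e-4)
  expect_identical(r1$class, "P")
  # PM2 alone
  r2 <- combine_tavtigian(data.frame(criterion = "PM2",
                                     strength = "moderate", benign = FALSE))
  expect_equal(r2$posterior, 0.32460, tolerance = 1e-4)
  expect_identical(r2$class, "VUS")
  # BA1 forces benign regardless of pathogenic evidence
  r3 <- combine_tavtigian(data.frame(
    criterion = c("PVS1", "BA1"), strength = c("very_strong", "stand_alone"),
    benign = c(FALSE, TRUE)))
  expect_identical(r3$class, "B")
})

test_that("the combiner agrees with an independent evaluation on random sets", {
  set.seed(99)
  pool <- data.frame(
    criterion = c("PVS1", "PS2", "PM2", "PM3", "PP3", "BP4", "BS1", "BS2"),
    strength = c("very_strong", "strong", "moderate", "moderate",
                 "supporting", "supporting", "strong", "strong"),
    benign = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  for (i in 1:200) {
    take <- pool[runif(nrow(pool)) < 0.4, , drop = FALSE]
    got <- combine_tavtigian(take)$posterior
    expect_equal(got, ref_tavtigian(take), tolerance = 1e-9)
  }
})

test_that("second pass attaches classification and rejects documented pairs", {
  cfg <- review_config()
  cand <- review_cand()
  lp <- combine_tavtigian(data.frame(
    criterion = c("PS2", "PM2", "PP3"),
    strength = c("strong", "moderate", "supporting"), benign = FALSE))
  expect_identical(lp$class, "LP")
  out <- second_pass_classify(cand, lp, 3, cfg)
  expect_identical(out$status, "retain")
  expect_true(out$returnable)
  # leaning VUS with a high match stays returnable
  vus <- combine_tavtigian(data.frame(
    criterion = c("PS2", "PM2"), strength = c("strong", "moderate"),
    benign = FALSE))
  expect_identical(vus$class, "VUS")
  expect_gt(vus$posterior, 0.5)
  expect_true(second_pass_classify(cand, vus, 3, cfg)$returnable)
  # already documented in the record
  doc <- documented_key("P", "chr1:100:A:T")
  out2 <- second_pass_classify(cand, lp, 3, cfg, documented = doc)
  expect_identical(out2$reason, "already_documented")
  # stricter second-pass phenotype floor
  out3 <- second_pass_classify(cand, lp, 0.2, cfg)
  expect_identical(out3$reason, "phenotype_mismatch")
})
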