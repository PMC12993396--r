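test_that("inheritance inference covers the trio patterns", {
  # de novo: het with both parents reference
  expect_identical(infer_inheritance(1, FALSE, 0, 0)$pattern, "de_novo")
  # homozygous regardless of parental phase detail
  expect_identical(infer_inheritance(2, FALSE, 1, 1)$pattern, "homozygous")
  # hemizygous male chrX with carrier mother
  h <- infer_inheritance(1, TRUE, 0, 1)
  expect_identical(h$pattern, "hemizygous")
  expect_identical(h$parental_origin, "maternal")
  # transmitted by an affected parent
  s <- infer_inheritance(1, FALSE, 1, 0, father_affected = TRUE)
  expect_identical(s$pattern, "segregating_dominant")
  expect_identical(s$parental_origin, "paternal")
  # transmitted by an unaffected parent
  u <- infer_inheritance(1, FALSE, 0, 1)
  expect_identical(u$pattern, "inherited_unphased")
  expect_identical(u$parental_origin, "maternal")
  # missing parental genotype
  expect_identical(infer_inheritance(1, FALSE, NA, 0)$pattern, "unknown")
  # duo/singleton: only genotype-alone calls
  expect_identical(infer_inheritance(1, FALSE, structure = "duo")$pattern,
                   "unknown")
  expect_identical(infer_inheritance(2, FALSE, structure = "singleton")$pattern,
                   "homozygous")
  expect_identical(infer_inheritance(1, TRUE, structure = "singleton")$pattern,
                   "hemizygous")
})

test_that("compound-het pairing requires opposite parental origins in trios", {
  hets <- data.frame(variant_key = c("v1", "v2"),
                     father_dosage = c(0, 1), mother_dosage = c(1, 0))
  pairs <- find_compound_hets(hets, "trio")
  expect_identical(nrow(pairs), 1L)
  expect_setequal(c(pairs$origin1, pairs$origin2), c("maternal", "paternal"))
  # in cis: both from the mother
  cis <- data.frame(variant_key = c("v1", "v2"),
                    father_dosage = c(0, 0), mother_dosage = c(1, 1))
  expect_identical(nrow(find_compound_hets(cis, "trio")), 0L)
  # a parent carrying both blocks the pair
  both <- data.frame(variant_key = c("v1", "v2"),
                     father_dosage = c(1, 1), mother_dosage = c(1, 0))
  expect_identical(nrow(find_compound_hets(both, "trio")), 0L)
  # non-trio: provisional pair with unknown origin
  single <- data.frame(variant_key = c("v1", "v2"),
                       father_dosage = NA_real_, mother_dosage = NA_real_)
  p2 <- find_compound_hets(single, "singleton")
  expect_identical(nrow(p2), 1L)
  expect_identical(p2$origin1, "unknown")
})

base_cand <- function(...) {
  row <- list(variant_key = "chr1:1:A:T", proband = "P", structure = "trio",
              pattern = "de_novo", impact_tier = "HIGH",
              distance_to_exon = 0, clinvar = "absent",
              acmg_auto = NA_character_, gnomad_af = 0, cohort_af = 0,
              het_count = 1, hom_count = 0, depth = 40, quality = 90,
              cadd_phred = 30, pli = 0.99, s_het = 0.1, spliceai = 0.1,
              phen_overlap = TRUE)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

test_that("CFA clauses fire on their thresholds", {
  th <- cfa_thresholds()
  # a clean de novo stop-gain passes every clause
  expect_true(apply_cfa_filters(base_cand(), th)$passed)
  # allele frequency above 1.5%
  d <- apply_cfa_filters(base_cand(gnomad_af = 0.02), th)
  expect_false(d$passed)
  expect_true("FREQUENCY" %in% d$reasons[[1]])
  # heterozygous carrier count above 30
  d <- apply_cfa_filters(base_cand(het_count = 31), th)
  expect_true("HET_COUNT" %in% d$reasons[[1]])
  # homozygous count above 2
  d <- apply_cfa_filters(base_cand(hom_count = 3), th)
  expect_true("HOM_COUNT" %in% d$reasons[[1]])
  # synonymous LOW impact without ClinVar rescue
  d <- apply_cfa_filters(base_cand(impact_tier = "LOW"), th)
  expect_true("IMPACT" %in% d$reasons[[1]])
  # ClinVar P/LP rescues impact and region
  d <- apply_cfa_filters(base_cand(impact_tier = "LOW", distance_to_exon = 100,
                                   clinvar = "pathogenic"), th)
  expect_true(d$passed)
  # benign annotation
  d <- apply_cfa_filters(base_cand(clinvar = "likely_benign"), th)
  expect_true("BENIGN" %in% d$reasons[[1]])
  d <- apply_cfa_filters(base_cand(acmg_auto = "LB"), th)
  expect_true("BENIGN" %in% d$reasons[[1]])
  # unknown inheritance in a trio
  d <- apply_cfa_filters(base_cand(pattern = "unknown"), th)
  expect_true("INHERITANCE" %in% d$reasons[[1]])
  # quality floors
  d <- apply_cfa_filters(base_cand(depth = 5), th)
  expect_true("QUALITY" %in% d$reasons[[1]])
  # beyond the exonic flank
  d <- apply_cfa_filters(base_cand(distance_to_exon = 21), th)
  expect_true("REGION" %in% d$reasons[[1]])
})

test_that("the non-trio branch demands rarity, evidence and overlap", {
  th <- cfa_thresholds()
  ok <- base_cand(structure = "singleton", pattern = "unknown",
                  impact_tier = "MODERATE", gnomad_af = 0.0005,
                  cadd_phred = 30, pli = 0, s_het = 0, spliceai = 0)
  expect_true(apply_cfa_filters(ok, th)$passed)
  # too common for a non-trio even though under the global cap
  d <- apply_cfa_filters(base_cand(structure = "singleton",
                                   pattern = "unknown",
                                   gnomad_af = 0.005), th)
  expect_true("NON_TRIO_EVIDENCE" %in% d$reasons[[1]])
  # no strong in-silico / constraint / splicing evidence
  weak <- base_cand(structure = "singleton", pattern = "unknown",
                    cadd_phred = 10, pli = 0, s_het = 0, spliceai = 0)
  expect_true("NON_TRIO_EVIDENCE" %in%
                apply_cfa_filters(weak, th)$reasons[[1]])
  # missing CADD never counts as passing evidence
  na_ev <- base_cand(structure = "singleton", pattern = "unknown",
                     cadd_phred = NA, pli = NA, s_het = NA, spliceai = NA)
  expect_true("NON_TRIO_EVIDENCE" %in%
                apply_cfa_filters(na_ev, th)$reasons[[1]])
  # no phenotype overlap and no pathogenic annotation
  no_ov <- base_cand(structure = "singleton", pattern = "unknown",
                     phen_overlap = FALSE)
  expect_true("NON_TRIO_EVIDENCE" %in%
                apply_cfa_filters(no_ov, th)$reasons[[1]])
  # pathogenic annotation substitutes for overlap
  cv <- base_cand(structure = "singleton", pattern = "unknown",
                  phen_overlap = FALSE, clinvar = "pathogenic")
  expect_true(apply_cfa_filters(cv, th)$passed)
})

test_that("run_cfa produces a monotone funnel, reasons for every drop, and
          recovers planted variants", {
  sim <- cached_sim()
  cfa <- run_cfa(sim$cohort, sim$ontology)
  expect_true(all(diff(cfa$funnel) <= 0))
  dec <- cfa$decisions
  expect_true(all(lengths(dec$reasons[!dec$passed]) >= 1))
  expect_true(all(lengths(dec$reasons[dec$passed]) == 0))
  # planted causal variants all pass by construction
  gt <- sim$ground_truth
  sk <- paste(cfa$candidates$proband, cfa$candidates$variant_key)
  expect_gte(mean(paste(gt$proband, gt$variant_key) %in% sk), 0.99)
})

test_that("run_cfa equals a naive clause-by-clause reference filter", {
  sim <- cached_sim()
  th <- cfa_thresholds()
  cfa <- run_cfa(sim$cohort, sim$ontology, thresholds = th)
  dec <- cfa$decisions
  expect_identical(dec$passed, naive_cfa_pass(dec))
})

test_that("an empty cohort yields an empty funnel", {
  sim <- cached_sim()
  empty <- sim$cohort
  empty$genotypes <- empty$genotypes[0, ]
  empty$annotations <- empty$annotations[0, ]
  cfa <- run_cfa(empty, sim$ontology)
  expect_identical(unname(cfa$funnel), c(0L, 0L, 0L))
})
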