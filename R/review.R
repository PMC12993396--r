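# Codified review: locus-level population-evidence aggregation, the ordered
# first-pass screening rules, ACMG criteria assignment and their Bayesian
# (points-framework) combination, and the second-pass classification.

#' Review-rule configuration
#'
#' @param recessive_max_af Maximum summed allele frequency for recessive
#'   candidates (default 0.001).
#' @param recessive_max_homhemi Maximum summed homozygote+hemizygote count
#'   for recessive candidates (default 2); any hom/hemi presence requires a
#'   strong phenotype match.
#' @param dominant_max_ac Maximum summed allele count for dominant
#'   candidates outside neurodevelopmental-disorder (NDD) genes (default 2),
#'   waived under an incomplete-penetrance flag or compelling phenotype
#'   match.
#' @param ndd_controls_max_ac Maximum allele count in the control
#'   population for dominant candidates in NDD genes (default 2).
#' @param ndd_non_neuro_max_ac Maximum allele count in non-neuro
#'   populations for dominant NDD candidates (default 1), waived under
#'   incomplete penetrance.
#' @param min_similarity First-pass phenotype-similarity floor.
#' @param second_pass_min_similarity Stricter second-pass similarity floor.
#' @param strong_similarity Similarity counting as a strong/compelling
#'   phenotype match for the override clauses; `NA` (default) means the
#'   pipeline substitutes the 90th percentile of the cohort's similarity
#'   distribution.
#' @param benign_cutoffs,deleterious_cutoffs Named per-score cutoffs for
#'   the in-silico consensus calls.
#' @return A `review_config` list.
#' @export
review_config <- function(recessive_max_af = 0.001, recessive_max_homhemi = 2,
                          dominant_max_ac = 2, ndd_controls_max_ac = 2,
                          ndd_non_neuro_max_ac = 1,
                          min_similarity = 0.5,
                          second_pass_min_similarity = 1.0,
                          strong_similarity = NA_real_,
                          benign_cutoffs = c(cadd_phred = 10, revel = 0.2,
                                             alphamissense = 0.34,
                                             spliceai = 0.1),
                          deleterious_cutoffs = c(cadd_phred = 25, revel = 0.7,
                                                  alphamissense = 0.56,
                                                  spliceai = 0.5)) {
  structure(as.list(environment()), class = "review_config")
}

#' In-silico consensus call
#'
#' A majority of the available scores below their benign cutoffs yields
#' `"benign"`; a majority at or above their deleterious cutoffs yields
#' `"deleterious"`; otherwise (or with no scores available) `"mixed"`.
#'
#' @param cand One candidate row (list or one-row data frame).
#' @param config A [review_config()].
#' @return `"benign"`, `"deleterious"` or `"mixed"`.
#' @export
insilico_consensus <- function(cand, config = review_config()) {
  scores <- vapply(names(config$benign_cutoffs), function(s) {
    v <- cand[[s]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  avail <- !is.na(scores)
  if (!any(avail)) return("mixed")
  n <- sum(avail)
  if (sum(scores[avail] < config$benign_cutoffs[avail]) > n / 2) return("benign")
  if (sum(scores[avail] >= config$deleterious_cutoffs[avail]) > n / 2) {
    return("deleterious")
  }
  "mixed"
}

#' Aggregate population evidence at a locus
#'
#' Sums allele counts, frequencies and homozygote/hemizygote counts over
#' all population-table alleles sharing the candidate's coordinate and
#' impact tier ("similar impact"), including the candidate's own counts
#' (taken from its annotation when the table has no row for it).
#'
#' @param cand One candidate row with `chrom`, `pos`, `variant_key`,
#'   `impact_tier` and its own `gnomad_*` / `controls_ac` / `non_neuro_ac`
#'   columns.
#' @param population Population table from [read_population_table()]
#'   (may be `NULL`).
#' @return List with `summed_ac`, `summed_af`, `hom_count`, `hemi_count`,
#'   `controls_ac`, `non_neuro_ac`.
#' @export
aggregate_locus_evidence <- function(cand, population = NULL) {
  own <- list(ac = or0(cand$gnomad_ac), af = or0(cand$gnomad_af),
              hom = or0(cand$gnomad_hom), hemi = or0(cand$gnomad_hemi),
              controls = or0(cand$controls_ac),
              non_neuro = or0(cand$non_neuro_ac))
  rows <- NULL
  if (!is.null(population) && nrow(population) > 0) {
    sel <- population$chrom == cand$chrom & population$pos == cand$pos &
      !is.na(population$impact_tier) &
      population$impact_tier == cand$impact_tier
    rows <- population[sel, , drop = FALSE]
  }
  if (is.null(rows) || nrow(rows) == 0) {
    return(list(summed_ac = own$ac, summed_af = own$af, hom_count = own$hom,
                hemi_count = own$hemi, controls_ac = own$controls,
                non_neuro_ac = own$non_neuro))
  }
  has_own <- cand$variant_key %in% rows$variant_key
  list(summed_ac = sum(or0(rows$ac)) + if (has_own) 0 else own$ac,
       summed_af = sum(or0(rows$af)) + if (has_own) 0 else own$af,
       hom_count = sum(or0(rows$hom)) + if (has_own) 0 else own$hom,
       hemi_count = sum(or0(rows$hemi)) + if (has_own) 0 else own$hemi,
       controls_ac = sum(or0(rows$controls_ac)) + if (has_own) 0 else own$controls,
       non_neuro_ac = sum(or0(rows$non_neuro_ac)) + if (has_own) 0 else own$non_neuro)
}

recessive_pattern <- function(pattern) {
  pattern %in% c("homozygous", "compound_het", "hemizygous")
}

moi_compatible <- function(pattern, moi) {
  if (length(moi) == 0) return(FALSE)
  switch(pattern,
         homozygous = any(moi %in% c("AR", "XLR")),
         compound_het = "AR" %in% moi,
         hemizygous = any(moi %in% c("XLR", "XLD")),
         # heterozygous patterns, including unconfirmed inheritance
         any(moi %in% c("AD", "XLD")))
}

#' First-pass bioinformatician screen
#'
#' Applies the codified screening rules in a fixed order, the first failing
#' clause deciding the rejection reason: (1) in-silico consensus benign;
#' (2) population frequency, with a recessive branch (summed AF at most
#' 0.001, hom/hemi at most 2 and any hom/hemi presence requiring a strong
#' phenotype match) and a dominant branch (summed AC at most 2 outside NDD
#' genes unless incomplete penetrance or a compelling match; control AC at
#' most 2 and non-neuro AC at most 1 for NDD genes; no hom/hemi presence
#' at all); (3) inheritance-call versus gene mode-of-inheritance
#' consistency; (4) susceptibility-only gene associations; (5) phenotype
#' similarity floor; (6) a genotype quality proxy (het allele fraction in
#' \[0.25, 0.75\], hom/hemi at least 0.85, depth at least 10).
#'
#' @param cand One candidate row.
#' @param evidence Output of [aggregate_locus_evidence()].
#' @param phen_similarity The candidate's phenotype similarity score.
#' @param config A [review_config()] (with `strong_similarity` resolved to
#'   a number).
#' @return List with `status` (`"retain"`/`"reject"`), `reason`, `notes`.
#' @export
first_pass_screen <- function(cand, evidence, phen_similarity,
                              config = review_config()) {
  reject <- function(reason, notes = "") list(status = "reject",
                                              reason = reason, notes = notes)
  strong <- config$strong_similarity
  if (is.na(strong)) strong <- Inf

  if (identical(insilico_consensus(cand, config), "benign")) {
    return(reject("insilico_benign"))
  }
  homhemi <- evidence$hom_count + evidence$hemi_count
  if (recessive_pattern(cand$pattern)) {
    if (evidence$summed_af > config$recessive_max_af) {
      return(reject("frequency_fail", "recessive summed AF"))
    }
    if (homhemi > config$recessive_max_homhemi) {
      return(reject("frequency_fail", "recessive hom/hemi count"))
    }
    if (homhemi > 0 && phen_similarity < strong) {
      return(reject("frequency_fail", "hom/hemi presence without strong match"))
    }
  } else {
    if (homhemi > 0) {
      return(reject("frequency_fail", "hom/hemi presence for dominant"))
    }
    penetrance <- isTRUE(cand$incomplete_penetrance)
    if (isTRUE(cand$ndd)) {
      if (evidence$controls_ac > config$ndd_controls_max_ac) {
        return(reject("frequency_fail", "NDD controls AC"))
      }
      if (evidence$non_neuro_ac > config$ndd_non_neuro_max_ac && !penetrance) {
        return(reject("frequency_fail", "NDD non-neuro AC"))
      }
    } else {
      if (evidence$summed_ac > config$dominant_max_ac && !penetrance &&
          phen_similarity < strong) {
        return(reject("frequency_fail", "dominant summed AC"))
      }
    }
  }
  moi <- moi_set(cand$moi)[[1]]
  if (is.na(cand$gene) || length(moi) == 0) {
    return(reject("moi_inconsistent", "no gene record"))
  }
  if (!moi_compatible(cand$pattern, moi)) {
    return(reject("moi_inconsistent"))
  }
  if (isTRUE(cand$susceptibility_only)) {
    return(reject("susceptibility_only"))
  }
  if (phen_similarity < config$min_similarity) {
    return(reject("phenotype_mismatch"))
  }
  af <- cand$alt_fraction
  hom_like <- or0(cand$dosage) >= 2 | isTRUE(cand$hemizygous)
  qual_ok <- orF(cand$depth >= 10) &&
    ((hom_like && orF(af >= 0.85)) ||
     (!hom_like && orF(af >= 0.25) && orF(af <= 0.75)))
  if (!qual_ok) return(reject("quality_fail"))
  list(status = "retain", reason = "none", notes = "")
}

acmg_strengths <- c(PVS1 = "very_strong", PS2 = "strong", PM2 = "moderate",
                    PM3 = "moderate", PP3 = "supporting",
                    BP4 = "supporting", BA1 = "stand_alone",
                    BS1 = "strong", BS2 = "strong")
acmg_benign <- c(PVS1 = FALSE, PS2 = FALSE, PM2 = FALSE, PM3 = FALSE,
                 PP3 = FALSE, BP4 = TRUE, BA1 = TRUE, BS1 = TRUE, BS2 = TRUE)

#' Assign the codified subset of ACMG criteria
#'
#' PVS1: HIGH-impact variant in a loss-of-function-intolerant gene
#' (pLI at least 0.9). PS2: confirmed de novo. PM2: absent or ultra-rare
#' (summed AF at most 1e-5). PM3: compound het in trans with a ClinVar
#' P/LP partner in a recessive gene. PP3/BP4: in-silico consensus
#' deleterious/benign. BA1: AF at least 5% (stand-alone benign). BS1: AF
#' above a disease-plausible ceiling (default 1%). BS2: hom/hemi
#' observations exceeding disease expectation.
#'
#' @param cand One candidate row.
#' @param evidence Output of [aggregate_locus_evidence()].
#' @param partner_clinvar ClinVar class of the compound-het partner, if any.
#' @param config A [review_config()].
#' @param bs1_max_af Disease-plausible frequency ceiling for BS1.
#' @return Data frame with `criterion`, `strength`, `benign`.
#' @export
assign_acmg_criteria <- function(cand, evidence, partner_clinvar = NA,
                                 config = review_config(), bs1_max_af = 0.01) {
  crit <- character(0)
  if (orF(cand$impact_tier == "HIGH") && orF(cand$pli >= 0.9)) {
    crit <- c(crit, "PVS1")
  }
  if (identical(cand$pattern, "de_novo")) crit <- c(crit, "PS2")
  if (evidence$summed_af <= 1e-5) crit <- c(crit, "PM2")
  moi <- moi_set(cand$moi)[[1]]
  if (identical(cand$pattern, "compound_het") && "AR" %in% moi &&
      !is.na(partner_clinvar) &&
      partner_clinvar %in% c("pathogenic", "likely_pathogenic")) {
    crit <- c(crit, "PM3")
  }
  consensus <- insilico_consensus(cand, config)
  if (consensus == "deleterious") crit <- c(crit, "PP3")
  if (consensus == "benign") crit <- c(crit, "BP4")
  af <- or0(cand$gnomad_af)
  if (af >= 0.05) crit <- c(crit, "BA1")
  else if (af >= bs1_max_af) crit <- c(crit, "BS1")
  if (evidence$hom_count + evidence$hemi_count > config$recessive_max_homhemi) {
    crit <- c(crit, "BS2")
  }
  data.frame(criterion = crit, strength = unname(acmg_strengths[crit]),
             benign = unname(acmg_benign[crit]), stringsAsFactors = FALSE)
}

#' Combine ACMG criteria under the Bayesian points framework
#'
#' Pathogenic evidence strengths are exponents of the base odds of
#' pathogenicity (supporting 1/8, moderate 1/4, strong 1/2, very strong 1);
#' benign supporting/strong evidence subtracts 1/8 and 1/2. The combined
#' odds update the prior into a posterior probability of pathogenicity,
#' binned into P (> 0.99), LP (0.90, 0.99], VUS \[0.10, 0.90), LB
#' \[0.001, 0.10) and B (< 0.001). A stand-alone benign criterion (BA1)
#' forces class B. Returnable means P/LP, or a VUS leaning P/LP
#' (posterior above 0.5).
#'
#' @param criteria Data frame from [assign_acmg_criteria()] (columns
#'   `criterion`, `strength`, `benign`).
#' @param prior Prior probability of pathogenicity (default 0.10).
#' @param odds_vst Odds of pathogenicity of very strong evidence
#'   (default 350).
#' @return List with `criteria`, `posterior`, `class`, `returnable`.
#' @export
combine_tavtigian <- function(criteria, prior = 0.10, odds_vst = 350) {
  valid <- c("supporting", "moderate", "strong", "very_strong", "stand_alone")
  stopifnot(all(criteria$strength %in% valid))
  if (any(criteria$strength == "stand_alone" & criteria$benign)) {
    return(list(criteria = criteria, posterior = 0, class = "B",
                returnable = FALSE))
  }
  w <- c(supporting = 1 / 8, moderate = 1 / 4, strong = 1 / 2,
         very_strong = 1)
  sgn <- ifelse(criteria$benign, -1, 1)
  expo <- sum(sgn * w[criteria$strength])
  odds <- odds_vst^expo
  posterior <- odds * prior / ((odds - 1) * prior + 1)
  class <- if (posterior > 0.99) "P"
  else if (posterior > 0.90) "LP"
  else if (posterior >= 0.10) "VUS"
  else if (posterior >= 0.001) "LB"
  else "B"
  list(criteria = criteria, posterior = posterior, class = class,
       returnable = class %in% c("P", "LP") ||
         (class == "VUS" && posterior > 0.50))
}

#' Second-pass classification
#'
#' Attaches the combined ACMG result and returnability, rejects candidates
#' already documented for the proband, and applies the stricter
#' second-pass phenotype floor.
#'
#' @param cand One candidate row.
#' @param acmg Result of [combine_tavtigian()].
#' @param phen_similarity The candidate's similarity score.
#' @param config A [review_config()].
#' @param documented Character vector of already-documented
#'   `proband:variant_key` pairs (see [documented_key()]).
#' @return List with `status`, `reason`, `acmg_class`, `posterior`,
#'   `returnable`.
#' @export
second_pass_classify <- function(cand, acmg, phen_similarity,
                                 config = review_config(),
                                 documented = character(0)) {
  out <- list(status = "retain", reason = "none",
              acmg_class = acmg$class, posterior = acmg$posterior,
              returnable = acmg$returnable)
  if (documented_key(cand$proband, cand$variant_key) %in% documented) {
    out$status <- "reject"; out$reason <- "already_documented"
    return(out)
  }
  if (phen_similarity < config$second_pass_min_similarity) {
    out$status <- "reject"; out$reason <- "phenotype_mismatch"
    return(out)
  }
  out
}

#' Key identifying a documented proband-variant pair
#'
#' @param proband,variant_key Vectors.
#' @return `proband|variant_key` strings.
#' @export
documented_key <- function(proband, variant_key) {
  paste(proband, variant_key, sep = "|")
}
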