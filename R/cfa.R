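# Cohort Family Analysis: inheritance-mode inference, compound-het pairing
# and the impact / frequency / carrier-count / benign / inheritance filter
# cascade, with the stricter evidence branch for non-trio families.

#' CFA filter thresholds
#'
#' Defaults follow the standard cascade: HIGH/MODERATE impact (or ClinVar
#' P/LP) within 20 bp of an exon, allele frequency at most 1.5%,
#' heterozygous carrier count at most 30, homozygous count at most 2, and
#' for non-trio families a stronger frequency bound (0.1%) plus an
#' in-silico / constraint evidence requirement.
#'
#' @param max_af Maximum allele frequency (gnomAD or internal cohort).
#' @param max_het_count Maximum heterozygous carrier count.
#' @param max_hom_count Maximum homozygous carrier count.
#' @param exon_flank_bp Exonic flank in base pairs.
#' @param non_trio_max_af Frequency ceiling in the non-trio branch.
#' @param non_trio_min_cadd CADD PHRED floor counting as strong in-silico
#'   evidence in the non-trio branch.
#' @param non_trio_min_pli,non_trio_min_s_het,non_trio_min_spliceai
#'   Alternative constraint / splicing evidence floors for non-trios.
#' @param min_depth,min_gq Genotype quality floors.
#' @return A `cfa_thresholds` list.
#' @export
cfa_thresholds <- function(max_af = 0.015, max_het_count = 30,
                           max_hom_count = 2, exon_flank_bp = 20,
                           non_trio_max_af = 0.001, non_trio_min_cadd = 25,
                           non_trio_min_pli = 0.9, non_trio_min_s_het = 0.05,
                           non_trio_min_spliceai = 0.5,
                           min_depth = 10, min_gq = 20) {
  stopifnot(non_trio_max_af <= max_af)
  structure(as.list(environment()), class = "cfa_thresholds")
}

or0 <- function(x) ifelse(is.na(x), 0, x)
orF <- function(x) !is.na(x) & x

#' Infer the inheritance pattern of a proband variant
#'
#' In trios: heterozygous with both parents reference is de novo; dosage 2
#' is homozygous; a hemizygous call (male non-PAR chrX) is hemizygous with
#' maternal origin when the mother carries the allele; a single carrier
#' parent who is affected gives a segregating dominant call; an unaffected
#' carrier parent (or two carrier parents) gives an inherited, unphased
#' call; missing parental genotypes give unknown. In duos and singletons
#' only homozygous and hemizygous calls can be made from genotype alone.
#'
#' @param dosage Proband alt-allele dosage (0/1/2).
#' @param hemizygous Logical, proband call is hemizygous.
#' @param father_dosage,mother_dosage Parental dosages (`NA` if ungenotyped
#'   or parent absent).
#' @param father_affected,mother_affected Parental affection status.
#' @param structure Family structure (`"trio"`, `"duo"`, `"singleton"`).
#' @return List with `pattern` and `parental_origin`.
#' @export
infer_inheritance <- function(dosage, hemizygous = FALSE,
                              father_dosage = NA, mother_dosage = NA,
                              father_affected = FALSE, mother_affected = FALSE,
                              structure = "trio") {
  res <- function(pattern, origin = "unknown") {
    list(pattern = pattern, parental_origin = origin)
  }
  if (is.na(dosage) || (dosage < 1 && !isTRUE(hemizygous))) {
    return(res("unknown"))
  }
  if (isTRUE(hemizygous)) {
    origin <- if (or0(mother_dosage) >= 1) "maternal" else "unknown"
    return(res("hemizygous", origin))
  }
  if (dosage >= 2) return(res("homozygous"))
  if (!identical(structure, "trio") ||
      is.na(father_dosage) || is.na(mother_dosage)) {
    return(res("unknown"))
  }
  fc <- father_dosage >= 1; mc <- mother_dosage >= 1
  if (!fc && !mc) return(res("de_novo"))
  origin <- if (fc && mc) "unknown" else if (fc) "paternal" else "maternal"
  carrier_affected <- (fc && father_affected) || (mc && mother_affected)
  if (xor(fc, mc) && carrier_affected) return(res("segregating_dominant", origin))
  res("inherited_unphased", origin)
}

#' Pair candidate compound-heterozygous variants in a gene
#'
#' In trios, two heterozygous candidates form a compound-het pair when their
#' parental origins differ (one allele transmitted by each parent and
#' neither parent carrying both). In non-trio families any pair of rare
#' heterozygous candidates is flagged as a provisional pair with unknown
#' origin.
#'
#' @param hets Data frame of heterozygous candidates in one gene for one
#'   proband, with columns `variant_key`, `father_dosage`, `mother_dosage`.
#' @param structure Family structure.
#' @return Data frame of pairs (`key1`, `key2`, `origin1`, `origin2`),
#'   zero rows if none.
#' @export
find_compound_hets <- function(hets, structure = "trio") {
  empty <- data.frame(key1 = character(), key2 = character(),
                      origin1 = character(), origin2 = character(),
                      stringsAsFactors = FALSE)
  if (is.null(hets) || nrow(hets) < 2) return(empty)
  if (identical(structure, "trio")) {
    origin <- ifelse(or0(hets$father_dosage) >= 1 & or0(hets$mother_dosage) == 0,
                     "paternal",
              ifelse(or0(hets$mother_dosage) >= 1 & or0(hets$father_dosage) == 0,
                     "maternal", "ambiguous"))
  } else {
    origin <- rep("unknown", nrow(hets))
  }
  pairs <- list()
  for (i in seq_len(nrow(hets) - 1)) {
    for (j in seq(i + 1, nrow(hets))) {
      ok <- if (identical(structure, "trio")) {
        origin[i] != origin[j] && all(c(origin[i], origin[j]) != "ambiguous")
      } else TRUE
      if (ok) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          key1 = hets$variant_key[i], key2 = hets$variant_key[j],
          origin1 = origin[i], origin2 = origin[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs) == 0) empty else do.call(rbind, pairs)
}

cfa_reason_codes <- c("IMPACT", "FREQUENCY", "HET_COUNT", "HOM_COUNT",
                      "BENIGN", "INHERITANCE", "QUALITY", "REGION",
                      "NON_TRIO_EVIDENCE")

#' Apply the CFA filter cascade to candidate rows
#'
#' Evaluates every clause and returns all failing reason codes per
#' candidate, so no variant is dropped silently. Missing allele frequencies
#' count as 0 (absence from the reference database); missing in-silico
#' evidence never satisfies the non-trio evidence requirement.
#'
#' @param cand Data frame of candidates (see [run_cfa()] for the columns).
#' @param thresholds A [cfa_thresholds()] list.
#' @return Data frame with `variant_key`, `proband`, `passed` and a
#'   `reasons` list-column of failing codes.
#' @export
apply_cfa_filters <- function(cand, thresholds = cfa_thresholds()) {
  th <- thresholds
  clinvar_plp <- cand$clinvar %in% c("pathogenic", "likely_pathogenic")
  region_fail <- orF(cand$distance_to_exon > th$exon_flank_bp) & !clinvar_plp
  impact_fail <- !(cand$impact_tier %in% c("HIGH", "MODERATE")) & !clinvar_plp
  freq_fail <- pmax(or0(cand$gnomad_af), or0(cand$cohort_af)) > th$max_af
  het_fail <- or0(cand$het_count) > th$max_het_count
  hom_fail <- or0(cand$hom_count) > th$max_hom_count
  benign_fail <- cand$clinvar %in% c("benign", "likely_benign") |
    cand$acmg_auto %in% c("B", "LB")
  inh_fail <- cand$structure == "trio" & cand$pattern == "unknown"
  qual_fail <- !orF(cand$depth >= th$min_depth) | !orF(cand$quality >= th$min_gq)
  non_trio <- cand$structure != "trio"
  strong_insilico <- orF(cand$cadd_phred >= th$non_trio_min_cadd) |
    orF(cand$pli >= th$non_trio_min_pli) |
    orF(cand$s_het >= th$non_trio_min_s_het) |
    orF(cand$spliceai >= th$non_trio_min_spliceai)
  nt_ok <- pmax(or0(cand$gnomad_af), or0(cand$cohort_af)) <= th$non_trio_max_af &
    strong_insilico & (orF(cand$phen_overlap) | clinvar_plp)
  nt_fail <- non_trio & !nt_ok

  reasons <- lapply(seq_len(nrow(cand)), function(i) {
    cfa_reason_codes[c(impact_fail[i], freq_fail[i], het_fail[i], hom_fail[i],
                       benign_fail[i], inh_fail[i], qual_fail[i],
                       region_fail[i], nt_fail[i])]
  })
  out <- data.frame(variant_key = cand$variant_key, proband = cand$proband,
                    stringsAsFactors = FALSE)
  out$passed <- lengths(reasons) == 0L
  out$reasons <- reasons
  out$screen_passed <- !(region_fail | qual_fail)
  out
}

assemble_candidates <- function(cohort) {
  fams <- cohort$pedigree$families
  members <- cohort$pedigree$members
  gt <- cohort$genotypes
  carrier <- gt[!is.na(gt$dosage) & (gt$dosage >= 1 | gt$hemizygous), ]
  cand <- carrier[carrier$sample %in% fams$proband, ]
  names(cand)[names(cand) == "sample"] <- "proband"
  fam_of <- stats::setNames(members$family_id, members$sample_id)
  cand$family_id <- fam_of[cand$proband]
  fam_idx <- match(cand$family_id, fams$family_id)
  cand$structure <- fams$structure[fam_idx]
  father <- fams$father_id[fam_idx]
  mother <- fams$mother_id[fam_idx]
  gt_key <- paste(gt$variant_key, gt$sample, sep = "@")
  # genotype table is carrier-sparse: a genotyped parent without a row is
  # homozygous reference (dosage 0); an explicit ./. row stays NA
  lookup_dosage <- function(parent) {
    idx <- match(paste(cand$variant_key, parent, sep = "@"), gt_key)
    d <- gt$dosage[idx]
    d[is.na(idx) & !is.na(parent)] <- 0L
    d
  }
  cand$father_dosage <- lookup_dosage(father)
  cand$mother_dosage <- lookup_dosage(mother)
  aff <- stats::setNames(members$affected, members$sample_id)
  cand$father_affected <- ifelse(is.na(father), FALSE, or0(aff[father]) > 0)
  cand$mother_affected <- ifelse(is.na(mother), FALSE, or0(aff[mother]) > 0)
  cand <- merge(cand, cohort$annotations[, setdiff(names(cohort$annotations),
                                                   c("chrom", "pos", "ref", "alt"))],
                by = "variant_key", all.x = TRUE, sort = FALSE)
  vi <- match(cand$variant_key, cohort$variants$variant_key)
  cand$chrom <- cohort$variants$chrom[vi]
  cand$pos <- cohort$variants$pos[vi]
  cand$ref <- cohort$variants$ref[vi]
  cand$alt <- cohort$variants$alt[vi]
  gi <- match(cand$gene, cohort$genes$gene)
  for (col in c("moi", "susceptibility_only", "ndd", "disease_terms", "pli",
                "s_het", "s_coef", "misfit_s", "incomplete_penetrance")) {
    cand[[col]] <- cohort$genes[[col]][gi]
  }
  cand[order(cand$proband, cand$variant_key), , drop = FALSE]
}

cohort_carrier_counts <- function(cohort) {
  fams <- cohort$pedigree$families
  gt <- cohort$genotypes[cohort$genotypes$sample %in% fams$proband, ]
  het <- tapply(or0(gt$dosage) == 1 & !gt$hemizygous, gt$variant_key, sum)
  hom <- tapply(or0(gt$dosage) >= 2 | (gt$hemizygous & or0(gt$dosage) >= 1),
                gt$variant_key, sum)
  list(het = het, hom = hom)
}

#' Run the Cohort Family Analysis cascade over a cohort
#'
#' Assembles candidate variants (proband carries at least one alt allele),
#' infers inheritance, pairs compound hets, evaluates phenotype overlap for
#' the non-trio branch and applies the full filter cascade, returning the
#' survivors together with a funnel of per-stage counts (input, post
#' screen, post filter). Heterozygous/homozygous carrier counts are the sum
#' of counts observed across the cohort's probands and the optional
#' `ref_het_count` / `ref_hom_count` annotation columns.
#'
#' @param cohort A `pgr_cohort`.
#' @param ontology A `pgr_ontology` (for phenotype overlap in non-trios).
#' @param ic Optional information-content vector; computed from the
#'   cohort's gene-phenotype annotations when `NULL`.
#' @param thresholds A [cfa_thresholds()] list.
#' @return List with `candidates` (survivor rows), `decisions` (all
#'   candidate rows with `passed`/`reasons`), and `funnel`.
#' @export
run_cfa <- function(cohort, ontology, ic = NULL,
                    thresholds = cfa_thresholds()) {
  if (is.null(ic)) {
    corpus <- gene_corpus(cohort)
    ic <- information_content(ontology, corpus)
  }
  cand <- assemble_candidates(cohort)
  funnel <- c(input_variants = nrow(cand))
  if (nrow(cand) == 0) {
    return(list(candidates = cand, decisions = cand,
                funnel = c(funnel, post_screen = 0L, post_cfa = 0L)))
  }
  counts <- cohort_carrier_counts(cohort)
  cand$het_count <- or0(as.numeric(counts$het[cand$variant_key])) +
    or0(cand$ref_het_count)
  cand$hom_count <- or0(as.numeric(counts$hom[cand$variant_key])) +
    or0(cand$ref_hom_count)

  # inheritance per candidate
  inh <- lapply(seq_len(nrow(cand)), function(i) {
    infer_inheritance(cand$dosage[i], cand$hemizygous[i],
                      cand$father_dosage[i], cand$mother_dosage[i],
                      cand$father_affected[i], cand$mother_affected[i],
                      cand$structure[i])
  })
  cand$pattern <- vapply(inh, `[[`, character(1), "pattern")
  cand$parental_origin <- vapply(inh, `[[`, character(1), "parental_origin")
  cand$partner_key <- NA_character_

  # compound-het pass: upgrade paired hets within one gene; in non-trio
  # families only rare hets in recessive-capable genes are provisionally
  # paired (origin cannot be established)
  het_idx <- which(or0(cand$dosage) == 1 & !cand$hemizygous & !is.na(cand$gene))
  if (length(het_idx) > 0) {
    non_trio_ok <- vapply(moi_set(cand$moi[het_idx]),
                          function(m) "AR" %in% m, logical(1)) &
      or0(cand$gnomad_af[het_idx]) <= thresholds$max_af
    keep_het <- cand$structure[het_idx] == "trio" | non_trio_ok
    het_idx <- het_idx[keep_het]
  }
  if (length(het_idx) > 0) {
    groups <- split(het_idx, paste(cand$proband[het_idx], cand$gene[het_idx]))
    for (g in groups) {
      if (length(g) < 2) next
      pairs <- find_compound_hets(cand[g, , drop = FALSE], cand$structure[g[1]])
      if (nrow(pairs) == 0) next
      for (r in seq_len(nrow(pairs))) {
        for (side in c("key1", "key2")) {
          idx <- g[cand$variant_key[g] == pairs[[side]][r]]
          partner <- pairs[[if (side == "key1") "key2" else "key1"]][r]
          if (cand$pattern[idx] %in% c("inherited_unphased", "unknown")) {
            cand$pattern[idx] <- "compound_het"
          }
          if (is.na(cand$partner_key[idx])) cand$partner_key[idx] <- partner
        }
      }
    }
  }

  # phenotype overlap (exact + one-level match >= 1) per proband x gene
  cand$phen_overlap <- FALSE
  need <- which(cand$structure != "trio" & !is.na(cand$gene))
  if (length(need) > 0) {
    keys <- unique(data.frame(proband = cand$proband[need],
                              gene = cand$gene[need]))
    ov <- logical(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      prof <- cohort$profiles[[keys$proband[i]]]
      gterms <- gene_terms_of(cohort, keys$gene[i])
      if (is.null(prof) || length(gterms) == 0 ||
          length(prof$combined) == 0) next
      mf <- match_features(prof$combined, gterms, ontology, ic)
      ov[i] <- (mf$exact_count + mf$one_level_count) >= 1
    }
    lk <- stats::setNames(ov, paste(keys$proband, keys$gene))
    cand$phen_overlap[need] <- lk[paste(cand$proband[need], cand$gene[need])]
  }

  dec <- apply_cfa_filters(cand, thresholds)
  cand$passed <- dec$passed
  cand$reasons <- dec$reasons
  funnel <- c(funnel, post_screen = sum(dec$screen_passed),
              post_cfa = sum(dec$passed))
  list(candidates = cand[cand$passed, , drop = FALSE],
       decisions = cand, funnel = funnel)
}

#' Gene-phenotype annotation corpus of a cohort
#'
#' @param cohort A `pgr_cohort`.
#' @return Named list mapping gene symbols to disease term ids.
#' @export
gene_corpus <- function(cohort) {
  terms <- split_field(cohort$genes$disease_terms)
  stats::setNames(terms, cohort$genes$gene)
}

gene_terms_of <- function(cohort, gene) {
  i <- match(gene, cohort$genes$gene)
  if (is.na(i)) return(character(0))
  split_field(cohort$genes$disease_terms[i])[[1]]
}
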