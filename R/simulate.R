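# Seeded synthetic-cohort generator: ontology, gene panel, pedigrees,
# genotypes, annotations, population table and phenotype profiles with
# planted causal variants, emitted in exactly the formats the readers
# consume. Every stage of the pipeline has ground truth here.

#' Simulation configuration
#'
#' The defaults emulate a desk-scale reanalysis cohort: 300 families with a
#' half/quarter/quarter trio/duo/singleton mix, a 60-gene disease panel
#' with an AD-heavy mode-of-inheritance mix, roughly 36 background variants
#' per proband spanning every filter threshold, planted causal variants in
#' 60% of probands (half of them with deliberately weaker, VUS-like
#' in-silico support), 20% NLP term dropout with two spurious terms, and a
#' small fraction of causal findings pre-documented in the record.
#'
#' @param n_families Number of families.
#' @param structure_mix Named proportions for trio/duo/singleton.
#' @param n_genes Number of panel genes.
#' @param moi_mix Named proportions for AD/AR/XLR causal inheritance.
#' @param background_variants_per_proband Background variants per proband.
#' @param causal_fraction Probability a proband has a planted causal
#'   variant.
#' @param vus_fraction Fraction of causal variants with VUS-like (weaker)
#'   in-silico support.
#' @param comphet_fraction Fraction of AR-trio causal events planted as
#'   true compound hets rather than homozygotes.
#' @param documented_fraction Fraction of causal findings already
#'   documented in the record (rejected at second pass).
#' @param phenotype_noise List with `dropout` (per-term NLP dropout
#'   probability) and `spurious` (spurious NLP terms added).
#' @param ontology_depth,ontology_branching Shape of the simulated
#'   ontology (see [simulate_ontology()]).
#' @param seed Integer seed; all outputs are byte-identical per seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 300,
                       structure_mix = c(trio = 0.5, duo = 0.25,
                                         singleton = 0.25),
                       n_genes = 60,
                       moi_mix = c(AD = 0.5, AR = 0.35, XLR = 0.15),
                       background_variants_per_proband = 52,
                       causal_fraction = 0.6,
                       vus_fraction = 0.5,
                       comphet_fraction = 0.3,
                       documented_fraction = 0.05,
                       phenotype_noise = list(dropout = 0.2, spurious = 2),
                       ontology_depth = 6, ontology_branching = 3,
                       seed = 1L) {
  stopifnot(abs(sum(structure_mix) - 1) < 1e-9, abs(sum(moi_mix) - 1) < 1e-9,
            causal_fraction >= 0, causal_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a phenotype ontology and write it as OBO
#'
#' Builds a rooted DAG with `branching` level-2 systems, `branching`
#' level-3 anchors under each, and 2-3 children per node down to `depth`
#' levels. A small fraction of deeper nodes receive a second parent from a
#' different level-3 branch (diamonds), and two obsolete terms are
#' included. Deterministic per seed.
#'
#' @param depth Number of levels (root = level 1); at least 4 so level-3
#'   branches exist.
#' @param branching Fan-out of the top two levels.
#' @param seed Integer seed.
#' @param path Output OBO path.
#' @return The path, invisibly.
#' @export
simulate_ontology <- function(depth = 6, branching = 3, seed = 1L, path) {
  if (depth < 4) stop("depth must be at least 4 so level-3 branches exist")
  set.seed(seed)
  ids <- character(); name <- character(); parents <- list()
  level <- integer(); anchor3 <- character()
  counter <- 0L
  new_term <- function(nm, ps, lvl, anc) {
    counter <<- counter + 1L
    id <- sprintf("HP:%07d", counter)
    ids <<- c(ids, id); name[[id]] <<- nm; parents[[id]] <<- ps
    level <<- c(level, lvl); anchor3 <<- c(anchor3, anc)
    id
  }
  root <- new_term("Phenotypic abnormality", character(0), 1L, NA_character_)
  l2 <- vapply(seq_len(branching), function(i)
    new_term(sprintf("System %d abnormality", i), root, 2L, NA_character_),
    character(1))
  anchors <- character(0)
  for (p2 in l2) {
    for (j in seq_len(branching)) {
      a <- new_term(sprintf("%s cluster %d", name[[p2]], j), p2, 3L, NA)
      anchor3[ids == a] <- a
      anchors <- c(anchors, a)
    }
  }
  frontier <- anchors
  lvl <- 3L
  while (lvl < depth) {
    nxt <- character(0)
    for (p in frontier) {
      p_anchor <- anchor3[ids == p]
      for (k in seq_len(sample(2:3, 1))) {
        t <- new_term(sprintf("Finding %d under %s", k, p), p, lvl + 1L,
                      p_anchor)
        nxt <- c(nxt, t)
      }
    }
    frontier <- nxt
    lvl <- lvl + 1L
  }
  # diamonds: ~5% of nodes at level >= 4 gain a second parent in a
  # different level-3 branch at the same parent level
  deep <- ids[level >= 4L]
  n_diamond <- max(1L, round(0.05 * length(deep)))
  for (t in sample(deep, n_diamond)) {
    t_lvl <- level[ids == t]
    cand_parents <- ids[level == t_lvl - 1L &
                          (is.na(anchor3) | anchor3 != anchor3[ids == t])]
    cand_parents <- setdiff(cand_parents, parents[[t]])
    if (length(cand_parents) > 0) {
      parents[[t]] <- c(parents[[t]], sample(cand_parents, 1))
    }
  }
  obsolete <- stats::setNames(rep(FALSE, length(ids)), ids)
  for (k in 1:2) {
    o <- new_term(sprintf("Obsolete finding %d", k), sample(l2, 1), 3L, NA)
    obsolete[[o]] <- TRUE
  }

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in ids) {
    stanza <- c("[Term]", paste0("id: ", id), paste0("name: ", name[[id]]),
                if (length(parents[[id]]) > 0) paste0("is_a: ", parents[[id]]))
    if (isTRUE(obsolete[[id]])) stanza <- c(stanza, "is_obsolete: true")
    writeLines(c(stanza, ""), con)
  }
  invisible(path)
}

descendants_of <- function(ontology, term) {
  out <- term
  frontier <- term
  while (length(frontier) > 0) {
    kids <- unique(unlist(ontology$children[frontier], use.names = FALSE))
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Simulate a disease gene panel
#'
#' Each gene receives a mode of inheritance from the configured mix (XLR
#' genes are placed on chrX), 3-8 disease terms drawn within a single
#' level-3 ontology branch (so pruning that branch removes the gene's
#' entire phenotype signal), constraint scores correlated with dominance,
#' about 10% susceptibility-only and 30% (of dominant genes)
#' neurodevelopmental flags, and about 10% incomplete-penetrance flags.
#'
#' @param ontology A `pgr_ontology`.
#' @param config A [sim_config()] (uses `n_genes`, `moi_mix`; does not
#'   reseed, callers control the RNG state).
#' @return Gene table data frame (with `chrom`, `start`, `end` coordinate
#'   columns used by the cohort generator).
#' @export
simulate_gene_panel <- function(ontology, config) {
  n <- config$n_genes
  anchors <- ontology$ids[!is.na(ontology$depth) & ontology$depth == 3L &
                            !ontology$obsolete]
  moi <- sample(names(config$moi_mix), n, replace = TRUE,
                prob = config$moi_mix)
  rows <- lapply(seq_len(n), function(i) {
    anchor <- sample(anchors, 1)
    pool <- descendants_of(ontology, anchor)
    pool <- pool[!ontology$obsolete[pool]]
    terms <- sample(pool, min(length(pool), sample(3:8, 1)))
    dominant <- moi[i] %in% c("AD", "XLR")
    chrom <- if (moi[i] == "XLR") "chrX" else sample(c("chr1", "chr2"), 1)
    data.frame(
      gene = sprintf("GENE%03d", i), chrom = chrom,
      start = 1e5 + i * 2e5, end = 1e5 + i * 2e5 + 5e3,
      moi = moi[i],
      susceptibility_only = stats::runif(1) < 0.10,
      ndd = moi[i] == "AD" && stats::runif(1) < 0.30,
      disease_terms = paste(terms, collapse = ";"),
      pli = if (dominant) stats::runif(1, 0.85, 1) else stats::runif(1, 0, 0.5),
      s_het = if (dominant) stats::runif(1, 0.06, 0.3)
              else stats::runif(1, 0.001, 0.04),
      s_coef = stats::runif(1, 0, 0.5),
      misfit_s = stats::runif(1, 0, 1),
      incomplete_penetrance = stats::runif(1) < 0.10,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

rand_alleles <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  c(ref, alt)
}

#' Simulate a complete cohort with planted causal variants
#'
#' Generates families per the structure mix; plants causal variants
#' (AD: de novo in trios, rare damaging hets elsewhere; AR: homozygous or
#' phased compound het; XLR: maternally inherited hemizygous in males,
#' resampled when the family has no male proband) whose annotations
#' satisfy every filter and review clause; plants review-rule "decoys"
#' that match the patient phenotype but each violate exactly one screening
#' rule; and draws background variants across a frequency/impact/quality
#' spectrum spanning every filter threshold. Writes VCF, PED, annotation,
#' gene, population, phenotype-profile, documented-variant and
#' ground-truth files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths`, `ground_truth` (data frame: `proband`,
#'   `family_id`, `variant_key`, `partner_key`, `gene`, `pattern`,
#'   `label`, `documented`), the loaded `cohort` and `ontology`.
#' @export
simulate_cohort <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obo_path <- file.path(dir, "ontology.obo")
  simulate_ontology(config$ontology_depth, config$ontology_branching,
                    seed = config$seed, path = obo_path)
  ontology <- load_obo(obo_path)
  set.seed(config$seed + 1L)
  genes <- simulate_gene_panel(ontology, config)
  gene_terms <- stats::setNames(split_field(genes$disease_terms), genes$gene)
  usable_terms <- ontology$ids[!ontology$obsolete &
                                 !is.na(ontology$depth) &
                                 ontology$depth >= 3L]

  n <- config$n_families
  n_trio <- round(config$structure_mix[["trio"]] * n)
  n_duo <- round(config$structure_mix[["duo"]] * n)
  structures <- sample(c(rep("trio", n_trio), rep("duo", n_duo),
                         rep("singleton", n - n_trio - n_duo)))

  ped_rows <- list(); gt_cells <- list(); variants <- list()
  annotations <- list(); pop_rows <- list(); truth <- list()
  profiles <- list(); samples <- character(0)
  gene_pos_counter <- stats::setNames(rep(0L, nrow(genes)), genes$gene)

  next_pos <- function(gene) {
    gene_pos_counter[[gene]] <<- gene_pos_counter[[gene]] + sample(3:9, 1)
    gi <- match(gene, genes$gene)
    list(chrom = genes$chrom[gi], pos = genes$start[gi] + gene_pos_counter[[gene]])
  }
  add_gt <- function(key, sample, cell) {
    gt_cells[[length(gt_cells) + 1L]] <<-
      list(key = key, sample = sample, cell = cell)
  }
  gt_string <- function(dosage, depth, af, gq, haploid = FALSE) {
    alt_reads <- round(depth * af)
    sprintf("%s:%d,%d:%d:%d",
            if (haploid) as.character(dosage)
            else c("0/0", "0/1", "1/1")[dosage + 1L],
            depth - alt_reads, alt_reads, depth, gq)
  }
  het_cell <- function(gq = sample(55:99, 1), depth = 15L + stats::rpois(1, 25),
                       af = stats::runif(1, 0.34, 0.66)) {
    gt_string(1L, depth, af, gq)
  }
  hom_cell <- function(gq = sample(55:99, 1), depth = 15L + stats::rpois(1, 25)) {
    gt_string(2L, depth, stats::runif(1, 0.92, 1), gq)
  }
  hemi_cell <- function(gq = sample(55:99, 1), depth = 15L + stats::rpois(1, 25)) {
    gt_string(1L, depth, stats::runif(1, 0.92, 1), gq, haploid = TRUE)
  }
  add_variant <- function(gene, ann_overrides = list()) {
    loc <- next_pos(gene)
    al <- rand_alleles()
    key <- variant_key(loc$chrom, loc$pos, al[1], al[2])
    variants[[length(variants) + 1L]] <<- data.frame(
      variant_key = key, chrom = loc$chrom, pos = loc$pos,
      ref = al[1], alt = al[2], stringsAsFactors = FALSE)
    ann <- list(chrom = loc$chrom, pos = loc$pos, ref = al[1], alt = al[2],
                gene = gene, consequence = "missense_variant",
                impact_tier = "MODERATE", distance_to_exon = 0L,
                clinvar = "absent", acmg_auto = NA_character_,
                cadd_phred = NA_real_, revel = NA_real_,
                alphamissense = NA_real_, spliceai = NA_real_,
                misfit_d = NA_real_, gnomad_af = 0, cohort_af = 0,
                gnomad_ac = 0L, gnomad_hom = 0L, gnomad_hemi = 0L,
                controls_ac = 0L, non_neuro_ac = 0L,
                ref_het_count = 0L, ref_hom_count = 0L)
    ann[names(ann_overrides)] <- ann_overrides
    ann$variant_key <- key
    annotations[[length(annotations) + 1L]] <<- as.data.frame(
      ann, stringsAsFactors = FALSE)
    key
  }
  strong_scores <- function() list(cadd_phred = stats::runif(1, 26, 45),
                                   revel = stats::runif(1, 0.72, 0.99),
                                   alphamissense = stats::runif(1, 0.6, 0.98),
                                   spliceai = stats::runif(1, 0, 0.3),
                                   misfit_d = stats::runif(1, 0.6, 0.98))
  vus_scores <- function() list(cadd_phred = stats::runif(1, 25, 33),
                                revel = stats::runif(1, 0.4, 0.72),
                                alphamissense = stats::runif(1, 0.35, 0.65),
                                spliceai = stats::runif(1, 0, 0.25),
                                misfit_d = stats::runif(1, 0.3, 0.7))

  decoy_types <- c("dominant_ac", "ndd_controls", "dominant_homhemi",
                   "recessive_freq", "susceptibility", "moi_mismatch",
                   "insilico_benign", "quality")
  n_decoy_sets <- max(1L, round(n / 60))
  decoy_queue <- rep(decoy_types, n_decoy_sets)

  for (f in seq_len(n)) {
    fam <- sprintf("FAM%03d", f)
    proband <- paste0(fam, "_p")
    father <- paste0(fam, "_f"); mother <- paste0(fam, "_m")
    struct <- structures[f]
    sex <- sample(c("male", "female"), 1)
    duo_parent <- if (struct == "duo") sample(c("father", "mother"), 1) else NA

    members <- data.frame(sample_id = proband,
                          father_id = if (struct == "trio" ||
                                          identical(duo_parent, "father"))
                            father else "0",
                          mother_id = if (struct == "trio" ||
                                          identical(duo_parent, "mother"))
                            mother else "0",
                          sex = if (sex == "male") "1" else "2",
                          phe = "2", stringsAsFactors = FALSE)
    if (members$father_id != "0") {
      members <- rbind(members, data.frame(sample_id = father, father_id = "0",
                                           mother_id = "0", sex = "1",
                                           phe = "1"))
    }
    if (members$mother_id[1] != "0") {
      members <- rbind(members, data.frame(sample_id = mother, father_id = "0",
                                           mother_id = "0", sex = "2",
                                           phe = "1"))
    }
    for (r in seq_len(nrow(members))) {
      ped_rows[[length(ped_rows) + 1L]] <- paste(
        fam, members$sample_id[r], members$father_id[r], members$mother_id[r],
        members$sex[r], members$phe[r])
    }
    samples <- c(samples, members$sample_id)
    has_father <- father %in% members$sample_id
    has_mother <- mother %in% members$sample_id

    # ---- causal planting --------------------------------------------------
    causal_gene <- NA_character_
    manual_terms <- character(0)
    if (stats::runif(1) < config$causal_fraction) {
      mode <- sample(names(config$moi_mix), 1, prob = config$moi_mix)
      if (mode == "XLR" && sex != "male") {
        mode <- sample(c("AD", "AR"), 1)  # resample: XLR needs a male proband
      }
      pool <- genes$gene[genes$moi == mode & !genes$susceptibility_only]
      causal_gene <- sample(pool, 1)
      vus_like <- stats::runif(1) < config$vus_fraction
      label <- if (vus_like) "VUS" else
        sample(c("pathogenic", "likely_pathogenic"), 1, prob = c(0.35, 0.65))
      scores <- if (vus_like) vus_scores() else strong_scores()
      gi <- match(causal_gene, genes$gene)
      high_impact <- !vus_like && genes$pli[gi] >= 0.9 && stats::runif(1) < 0.6
      base_ann <- c(scores, list(
        impact_tier = if (high_impact) "HIGH" else "MODERATE",
        consequence = if (high_impact) "stop_gained" else "missense_variant",
        acmg_auto = if (vus_like) "VUS" else sample(c("LP", "P"), 1,
                                                    prob = c(0.7, 0.3)),
        cohort_af = 0))  # novel finding: absent from prior internal cohorts

      pattern <- NA_character_; partner <- NA_character_
      if (mode == "AD") {
        key <- add_variant(causal_gene, base_ann)
        add_gt(key, proband, het_cell())
        pattern <- if (struct == "trio") "de_novo" else "unknown"
      } else if (mode == "XLR") {
        key <- add_variant(causal_gene, base_ann)
        add_gt(key, proband, hemi_cell())
        if (has_mother) add_gt(key, mother, het_cell())
        pattern <- "hemizygous"
      } else { # AR
        comphet <- struct == "trio" && stats::runif(1) < config$comphet_fraction
        if (comphet) {
          key <- add_variant(causal_gene, base_ann)
          scores2 <- if (vus_like) vus_scores() else strong_scores()
          partner <- add_variant(causal_gene, c(scores2, list(
            acmg_auto = base_ann$acmg_auto, cohort_af = base_ann$cohort_af,
            clinvar = sample(c("likely_pathogenic", "absent"), 1))))
          add_gt(key, proband, het_cell()); add_gt(partner, proband, het_cell())
          add_gt(key, mother, het_cell()); add_gt(partner, father, het_cell())
          pattern <- "compound_het"
        } else {
          key <- add_variant(causal_gene, base_ann)
          add_gt(key, proband, hom_cell())
          if (has_father) add_gt(key, father, het_cell())
          if (has_mother) add_gt(key, mother, het_cell())
          pattern <- "homozygous"
        }
      }
      documented <- stats::runif(1) < config$documented_fraction
      truth[[length(truth) + 1L]] <- data.frame(
        proband = proband, family_id = fam, variant_key = key,
        partner_key = partner, gene = causal_gene, pattern = pattern,
        label = label, documented = documented, stringsAsFactors = FALSE)
      if (!is.na(partner)) {
        truth[[length(truth) + 1L]] <- data.frame(
          proband = proband, family_id = fam, variant_key = partner,
          partner_key = key, gene = causal_gene, pattern = pattern,
          label = label, documented = documented, stringsAsFactors = FALSE)
      }
      manual_terms <- sample(gene_terms[[causal_gene]],
                             min(length(gene_terms[[causal_gene]]),
                                 sample(3:6, 1)))
    }

    # ---- phenotype profile ------------------------------------------------
    n_noise <- if (is.na(causal_gene)) sample(4:8, 1) else sample(1:3, 1)
    noise_pool <- setdiff(usable_terms,
                          if (is.na(causal_gene)) character(0)
                          else descendants_of(
                            ontology,
                            third_level_partition(
                              gene_terms[[causal_gene]], ontology)[[1]]$anchor))
    manual_terms <- unique(c(manual_terms, sample(noise_pool, n_noise)))

    # ---- review-rule decoys (trios only, phenotype-matched) ---------------
    if (struct == "trio" && length(decoy_queue) > 0) {
      dtype <- decoy_queue[1]; decoy_queue <- decoy_queue[-1]
      dg <- switch(dtype,
        ndd_controls = genes$gene[genes$moi == "AD" & genes$ndd &
                                    !genes$incomplete_penetrance],
        susceptibility = genes$gene[genes$susceptibility_only],
        moi_mismatch = genes$gene[genes$moi == "AR" &
                                    !genes$susceptibility_only],
        recessive_freq = genes$gene[genes$moi == "AR" &
                                      !genes$susceptibility_only],
        genes$gene[genes$moi == "AD" & !genes$ndd &
                     !genes$incomplete_penetrance &
                     !genes$susceptibility_only])
      dg <- setdiff(dg, causal_gene)
      if (length(dg) > 0) {
        dg <- sample(dg, 1)
        ann <- c(strong_scores(), list(acmg_auto = "VUS"))
        if (dtype == "dominant_ac") {
          ann$gnomad_ac <- 5L; ann$gnomad_af <- 2.5e-5
        } else if (dtype == "ndd_controls") {
          ann$gnomad_ac <- 2L; ann$gnomad_af <- 1e-5; ann$controls_ac <- 4L
        } else if (dtype == "dominant_homhemi") {
          ann$gnomad_ac <- 2L; ann$gnomad_af <- 1e-5; ann$gnomad_hom <- 1L
        } else if (dtype == "recessive_freq") {
          ann$gnomad_af <- 0.005; ann$gnomad_ac <- 1000L
        } else if (dtype == "insilico_benign") {
          ann[c("cadd_phred", "revel", "alphamissense", "spliceai")] <-
            list(5, 0.08, 0.15, 0.02)
        }
        dkey <- add_variant(dg, ann)
        if (dtype == "recessive_freq") {
          add_gt(dkey, proband, hom_cell())
          add_gt(dkey, father, het_cell()); add_gt(dkey, mother, het_cell())
        } else if (dtype == "quality") {
          add_gt(dkey, proband, gt_string(1L, 40L, 0.15, 80L))
        } else {
          add_gt(dkey, proband, het_cell())
        }
        manual_terms <- unique(c(manual_terms,
                                 sample(gene_terms[[dg]],
                                        min(2, length(gene_terms[[dg]])))))
      }
    }

    # ---- background variants ---------------------------------------------
    n_bg <- config$background_variants_per_proband
    bg_cat <- sample(c("common", "het_count", "hom_count", "benign_cv",
                       "low_impact", "off_region", "low_qual",
                       "missing_parent", "clinvar_plp", "rare"),
                     n_bg, replace = TRUE,
                     prob = c(0.15, 0.05, 0.04, 0.07, 0.09, 0.04, 0.04,
                              0.03, 0.03, 0.46))
    for (cat in bg_cat) {
      bgene <- sample(genes$gene, 1)
      on_x <- genes$chrom[match(bgene, genes$gene)] == "chrX"
      ann <- list(cadd_phred = stats::runif(1, 2, 28),
                  revel = stats::runif(1, 0.05, 0.6),
                  alphamissense = stats::runif(1, 0.1, 0.6),
                  spliceai = stats::runif(1, 0, 0.4),
                  misfit_d = stats::runif(1, 0, 0.6),
                  acmg_auto = sample(c(NA, "VUS", "LB"), 1,
                                     prob = c(0.5, 0.35, 0.15)),
                  clinvar = sample(c("absent", "VUS", "conflicting"), 1,
                                   prob = c(0.8, 0.15, 0.05)))
      af <- if (stats::runif(1) < 0.5) 0 else 10^stats::runif(1, -6, -2.4)
      cell <- het_cell()
      if (cat == "common") {
        af <- stats::runif(1, 0.02, 0.2)
      } else if (cat == "het_count") {
        af <- 10^stats::runif(1, -4, -2.5)
        ann$ref_het_count <- sample(31:200, 1)
      } else if (cat == "hom_count") {
        af <- 10^stats::runif(1, -4, -2.5)
        ann$ref_hom_count <- sample(3:10, 1)
      } else if (cat == "benign_cv") {
        ann$clinvar <- sample(c("benign", "likely_benign"), 1)
        af <- 10^stats::runif(1, -4, -2)
      } else if (cat == "low_impact") {
        ann$impact_tier <- sample(c("LOW", "MODIFIER"), 1)
        ann$consequence <- "synonymous_variant"
      } else if (cat == "off_region") {
        ann$distance_to_exon <- sample(21:500, 1)
      } else if (cat == "low_qual") {
        cell <- het_cell(gq = sample(4:15, 1), depth = sample(3:8, 1))
      } else if (cat == "clinvar_plp") {
        # previously reported alleles: pass the non-trio evidence clause too
        ann$clinvar <- sample(c("pathogenic", "likely_pathogenic"), 1)
        ann$cadd_phred <- stats::runif(1, 25, 35)
        af <- 10^stats::runif(1, -6, -3.5)
      }
      ann$gnomad_af <- af
      ann$gnomad_ac <- as.integer(round(af * 2e5))
      ann$gnomad_hom <- if (af > 0.01) as.integer(round(af^2 * 1e5)) else 0L
      ann$cohort_af <- round(af * stats::runif(1, 0.5, 1.5), 6)
      key <- add_variant(bgene, ann)
      male_x <- on_x && sex == "male"
      if (male_x) cell <- hemi_cell()
      if (cat == "low_qual") {
        # keep the low-quality genotype generated above
      }
      add_gt(key, proband, cell)
      if (cat == "missing_parent" && struct == "trio") {
        add_gt(key, sample(c(father, mother), 1), "./.")
      } else if (struct == "trio" && !male_x && stats::runif(1) < 0.85) {
        add_gt(key, sample(c(father, mother), 1), het_cell())
      } else if (struct == "duo" && stats::runif(1) < 0.6) {
        pp <- if (identical(duo_parent, "father")) father else mother
        if (!(on_x && identical(duo_parent, "father"))) add_gt(key, pp, het_cell())
      }
    }

    nlp <- manual_terms[stats::runif(length(manual_terms)) >=
                          config$phenotype_noise$dropout]
    nlp <- unique(c(nlp, sample(usable_terms,
                                config$phenotype_noise$spurious)))
    profiles[[proband]] <- list(manual = as.list(manual_terms),
                                nlp = as.list(nlp))
  }

  variants <- do.call(rbind, variants)
  annotations <- do.call(rbind, annotations)
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(proband = character(), family_id = character(),
               variant_key = character(), partner_key = character(),
               gene = character(), pattern = character(),
               label = character(), documented = logical())

  # co-located same-impact alleles so locus aggregation has work to do
  extra_pop <- list()
  bg_idx <- which(!(annotations$variant_key %in%
                      c(truth$variant_key, truth$partner_key)))
  for (i in sample(bg_idx, max(1L, round(0.08 * length(bg_idx))))) {
    row <- annotations[i, ]
    alt2 <- setdiff(c("A", "C", "G", "T"), c(row$ref, row$alt))[1]
    extra_pop[[length(extra_pop) + 1L]] <- data.frame(
      chrom = row$chrom, pos = row$pos, ref = row$ref, alt = alt2,
      impact_tier = row$impact_tier, ac = sample(1:3, 1), an = 2e5,
      af = 0, hom = 0L, hemi = 0L, controls_ac = 0L, non_neuro_ac = 0L,
      stringsAsFactors = FALSE)
  }
  own_pop <- data.frame(
    chrom = annotations$chrom, pos = annotations$pos,
    ref = annotations$ref, alt = annotations$alt,
    impact_tier = annotations$impact_tier, ac = annotations$gnomad_ac,
    an = 2e5, af = annotations$gnomad_af, hom = annotations$gnomad_hom,
    hemi = annotations$gnomad_hemi, controls_ac = annotations$controls_ac,
    non_neuro_ac = annotations$non_neuro_ac, stringsAsFactors = FALSE)
  population <- rbind(own_pop, do.call(rbind, extra_pop))
  population$af <- round(population$af, 8)

  # ---- write files --------------------------------------------------------
  paths <- list(
    obo = obo_path,
    ped = file.path(dir, "cohort.ped"),
    vcf = file.path(dir, "cohort.vcf"),
    variants = file.path(dir, "variants.tsv"),
    genes = file.path(dir, "genes.tsv"),
    population = file.path(dir, "population.tsv"),
    phenotypes = file.path(dir, "phenotypes.json"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    documented = file.path(dir, "documented.tsv"))
  writeLines(unlist(ped_rows), paths$ped)

  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, ]
  cell_df <- data.frame(key = vapply(gt_cells, `[[`, character(1), "key"),
                        sample = vapply(gt_cells, `[[`, character(1), "sample"),
                        cell = vapply(gt_cells, `[[`, character(1), "cell"),
                        stringsAsFactors = FALSE)
  cells_by_var <- split(cell_df[, c("sample", "cell")], cell_df$key)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  sample_index <- stats::setNames(seq_along(samples), samples)
  body <- vapply(seq_len(nrow(variants)), function(i) {
    cells <- rep("0/0", length(samples))
    vc <- cells_by_var[[variants$variant_key[i]]]
    if (!is.null(vc)) cells[sample_index[vc$sample]] <- vc$cell
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], "100", "PASS", ".", "GT:AD:DP:GQ", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), paths$vcf)

  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
  }
  write_tsv(annotations[order(annotations$chrom, annotations$pos,
                              annotations$alt),
                        setdiff(names(annotations), "variant_key")],
            paths$variants)
  write_tsv(genes[, setdiff(names(genes), c("start", "end"))], paths$genes)
  write_tsv(population, paths$population)
  jsonlite::write_json(profiles, paths$phenotypes, auto_unbox = FALSE)
  write_tsv(truth, paths$ground_truth)
  doc <- truth[truth$documented, c("proband", "variant_key"), drop = FALSE]
  write_tsv(doc, paths$documented)

  loaded <- read_cohort_dir(dir)
  list(paths = paths, ground_truth = truth, cohort = loaded$cohort,
       ontology = loaded$ontology)
}
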