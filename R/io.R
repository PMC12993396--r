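# Readers and writers for the standard formats the pipeline touches:
# 6-column PED, multi-sample VCF (via vcfR), tab-delimited annotation /
# gene / population tables, JSON phenotype profiles and JSON/TSV reports.

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Vectors of coordinates and alleles.
#' @return `chrom:pos:ref:alt` character keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

split_field <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";", fixed = TRUE),
         function(v) if (length(v) == 1 && is.na(v)) character(0) else v)
}

#' Read a 6-column pedigree file
#'
#' Reads a whitespace-delimited PED file (family, individual, father, mother,
#' sex 1/2/0, phenotype 2/1/0), assembles families, classifies the family
#' structure (trio if both of the proband's parents are present, duo if
#' exactly one, singleton otherwise) and selects the proband as the first
#' affected non-founder (first affected member if no affected non-founder
#' exists).
#'
#' @param path Path to a PED file.
#' @param proband_override Optional named character vector
#'   `c(family_id = sample_id)` overriding proband selection.
#' @return A `pgr_pedigree` list with data frames `members` (`family_id`,
#'   `sample_id`, `father_id`, `mother_id`, `sex`, `affected`) and `families`
#'   (`family_id`, `proband`, `father_id`, `mother_id`, `structure`).
#' @export
read_pedigree <- function(path, proband_override = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(rows, length, integer(1)) != 6L)
  if (length(bad) > 0) {
    stop("malformed PED line ", bad[1], ": expected 6 columns, got ",
         length(rows[[bad[1]]]))
  }
  m <- do.call(rbind, rows)
  sex_code <- m[, 5]
  if (!all(sex_code %in% c("0", "1", "2"))) {
    stop("malformed PED sex code on line ",
         which(!sex_code %in% c("0", "1", "2"))[1])
  }
  phe_code <- m[, 6]
  if (!all(phe_code %in% c("0", "1", "2"))) {
    stop("malformed PED phenotype code on line ",
         which(!phe_code %in% c("0", "1", "2"))[1])
  }
  members <- data.frame(
    family_id = m[, 1], sample_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[sex_code],
    affected = phe_code == "2",
    stringsAsFactors = FALSE
  )
  rownames(members) <- NULL
  if (anyDuplicated(members$sample_id)) {
    stop("duplicate sample ids in pedigree: ",
         paste(unique(members$sample_id[duplicated(members$sample_id)]),
               collapse = ", "))
  }
  fams <- lapply(split(members, members$family_id), function(fm) {
    present <- fm$sample_id
    # parents referenced but absent from the file are treated as unavailable
    for (col in c("father_id", "mother_id")) {
      missing_ref <- !is.na(fm[[col]]) & !(fm[[col]] %in% present)
      if (any(missing_ref)) {
        warning("family ", fm$family_id[1], ": parent id(s) ",
                paste(unique(fm[[col]][missing_ref]), collapse = ", "),
                " referenced but absent; treated as unavailable", call. = FALSE)
        fm[[col]][missing_ref] <- NA_character_
      }
    }
    proband <- proband_override[[fm$family_id[1]]]
    if (is.null(proband)) {
      aff <- fm[fm$affected, , drop = FALSE]
      if (nrow(aff) == 0) stop("family ", fm$family_id[1], " has no affected member")
      nonfounder <- aff[!is.na(aff$father_id) | !is.na(aff$mother_id), , drop = FALSE]
      proband <- if (nrow(nonfounder) > 0) nonfounder$sample_id[1] else aff$sample_id[1]
    } else if (!proband %in% present) {
      stop("proband override ", proband, " is not a member of family ",
           fm$family_id[1])
    }
    pr <- fm[fm$sample_id == proband, ]
    n_par <- sum(!is.na(c(pr$father_id, pr$mother_id)))
    data.frame(family_id = fm$family_id[1], proband = proband,
               father_id = pr$father_id, mother_id = pr$mother_id,
               structure = c("singleton", "duo", "trio")[n_par + 1L],
               stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, fams)
  rownames(families) <- NULL
  structure(list(members = members, families = families),
            class = "pgr_pedigree")
}

parse_gt_dosage <- function(gt) {
  # returns list(dosage, ploidy); gt like "0/1", "1|0", "1", "./."
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
    return(list(dosage = NA_integer_, ploidy = NA_integer_))
  }
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(list(dosage = NA_integer_, ploidy = length(alleles)))
  list(dosage = sum(alleles != "0"), ploidy = length(alleles))
}

#' Read a multi-sample cohort VCF
#'
#' Parses a VCFv4.2 file with vcfR, splits multi-allelic sites into biallelic
#' records, extracts dosage (from GT), depth (DP), alt fraction (from AD) and
#' genotype quality (GQ), and flags hemizygous calls for male samples on
#' non-pseudoautosomal chrX (and on chrY/chrM). The genotype table is
#' carrier-sparse: only genotypes with at least one alt allele or an
#' explicitly missing GT (`./.`) are stored; a sample without a row at a
#' site is homozygous reference there.
#'
#' @param path Path to a VCF file.
#' @param pedigree A `pgr_pedigree` from [read_pedigree()]; all pedigree
#'   samples must be present in the VCF header.
#' @param par_intervals Optional data frame (`chrom`, `start`, `end`) of
#'   pseudoautosomal intervals exempt from hemizygosity; default none.
#' @return List with data frames `variants` (`variant_key`, `chrom`, `pos`,
#'   `ref`, `alt`) and `genotypes` (`variant_key`, `sample`, `dosage`,
#'   `hemizygous`, `depth`, `alt_fraction`, `quality`).
#' @export
read_cohort_vcf <- function(path, pedigree, par_intervals = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(pedigree$members$sample_id, vcf_samples)
  if (length(missing) > 0) {
    stop("pedigree sample(s) absent from VCF: ", paste(missing, collapse = ", "))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  sex <- stats::setNames(pedigree$members$sex, pedigree$members$sample_id)
  use_samples <- intersect(vcf_samples, pedigree$members$sample_id)
  sample_sex <- sex[use_samples]

  is_par <- function(chrom, pos) {
    if (is.null(par_intervals) || nrow(par_intervals) == 0) return(FALSE)
    any(par_intervals$chrom == chrom & par_intervals$start <= pos &
          par_intervals$end >= pos)
  }
  dosage_map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
                  "1|0" = 1, "1/1" = 2, "1|1" = 2, "0" = 0, "1" = 1,
                  "./." = NA, ".|." = NA, "." = NA)
  ploidy_map <- c("0/0" = 2, "0|0" = 2, "0/1" = 2, "1/0" = 2, "0|1" = 2,
                  "1|0" = 2, "1/1" = 2, "1|1" = 2, "0" = 1, "1" = 1,
                  "./." = 2, ".|." = 2, "." = 1)

  var_rows <- list(); gt_rows <- list()
  for (i in seq_len(nrow(fix))) {
    chrom <- fix$CHROM[i]; pos <- as.integer(fix$POS[i])
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    keys <- strsplit(gt_raw[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    cells <- gt_raw[i, use_samples]
    cells[is.na(cells)] <- "./."  # vcfR reads fully missing calls as NA
    gt_field <- sub(":.*$", "", cells)
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
        warning("skipping non-ACGT allele at ", chrom, ":", pos, " (",
                ref, ">", alt, ")", call. = FALSE)
        next
      }
      if (ref == alt) next
      key <- variant_key(chrom, pos, ref, alt)
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        variant_key = key, chrom = chrom, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
      hemi_chrom <- chrom %in% c("chrY", "Y", "chrM", "MT") ||
        (chrom %in% c("chrX", "X") && !is_par(chrom, pos))
      known <- gt_field %in% names(dosage_map)
      dosage <- rep(NA_integer_, length(gt_field))
      ploidy <- rep(NA_integer_, length(gt_field))
      explicit_missing <- logical(length(gt_field))
      dosage[known] <- if (length(alts) == 1) {
        unname(dosage_map[gt_field[known]])
      } else {
        # multi-allelic: count only this alt's allele index
        vapply(gt_field[known], function(g) {
          al <- strsplit(g, "[/|]")[[1]]
          if (any(al == ".")) NA_integer_ else sum(al == as.character(ai))
        }, integer(1), USE.NAMES = FALSE)
      }
      if (length(alts) == 1) {
        ploidy[known] <- unname(ploidy_map[gt_field[known]])
        explicit_missing[known] <- is.na(dosage_map[gt_field[known]])
      }
      odd <- which(!known)
      for (j in odd) {
        al <- strsplit(gt_field[j], "[/|]")[[1]]
        ploidy[j] <- length(al)
        if (any(al == ".")) {
          explicit_missing[j] <- TRUE
        } else {
          dosage[j] <- sum(al == as.character(ai))
        }
      }
      if (length(alts) > 1) {
        explicit_missing <- is.na(dosage) &
          vapply(strsplit(gt_field, "[/|]"), function(a) any(a == "."),
                 logical(1))
      }
      keep <- which((!is.na(dosage) & dosage > 0) | explicit_missing)
      if (length(keep) == 0) next
      parsed <- strsplit(cells[keep], ":", fixed = TRUE)
      get <- function(f, k) {
        j <- match(k, keys)
        if (is.na(j) || j > length(f)) NA_character_ else f[[j]]
      }
      dp <- af <- gq <- rep(NA_real_, length(keep))
      for (k in seq_along(keep)) {
        f <- parsed[[k]]
        ad <- get(f, "AD")
        if (!is.na(ad)) {
          counts <- suppressWarnings(as.numeric(strsplit(ad, ",")[[1]]))
          if (length(counts) >= ai + 1 && sum(counts, na.rm = TRUE) > 0) {
            af[k] <- counts[ai + 1] / sum(counts, na.rm = TRUE)
          }
          dp[k] <- sum(counts, na.rm = TRUE)
        }
        dpf <- get(f, "DP")
        if (!is.na(dpf)) dp[k] <- suppressWarnings(as.numeric(dpf))
        gq[k] <- suppressWarnings(as.numeric(get(f, "GQ")))
      }
      kd <- dosage[keep]; kp <- ploidy[keep]
      hemi <- !is.na(kd) & kd > 0 & hemi_chrom &
        (unname(sample_sex[keep]) == "male" | chrom %in% c("chrM", "MT")) &
        (is.na(kp) | kp == 1 | kd == kp)
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        variant_key = key, sample = use_samples[keep],
        dosage = as.integer(kd),
        hemizygous = hemi, depth = dp,
        alt_fraction = ifelse(is.na(kd), NA_real_, af),
        quality = gq, stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, var_rows)
  genotypes <- do.call(rbind, gt_rows)
  rownames(variants) <- rownames(genotypes) <- NULL
  list(variants = variants, genotypes = genotypes)
}

read_tsv_na <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", "", "NA"))
}

IMPACT_TIERS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
CLINVAR_LEVELS <- c("pathogenic", "likely_pathogenic", "VUS", "conflicting",
                    "likely_benign", "benign", "absent")
ACMG_CLASSES <- c("P", "LP", "VUS", "LB", "B")

#' Read variant-annotation and gene tables
#'
#' Both tables are tab-delimited with a header row; `.` or empty cells are
#' missing and stay missing (they are imputed only at feature-encoding time).
#' The variant table is keyed by `chrom:pos:ref:alt`, the gene table by
#' symbol; duplicate keys are an error, as is an impact tier outside
#' HIGH/MODERATE/LOW/MODIFIER.
#'
#' @param variant_tsv,gene_tsv Paths to the two tables.
#' @return List with data frames `annotations` and `genes` (the latter keeps
#'   `moi` and `disease_terms` as `;`-separated strings; see [moi_set()]).
#' @export
read_annotation_tables <- function(variant_tsv, gene_tsv) {
  ann <- read_tsv_na(variant_tsv)
  ann$variant_key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$variant_key)) {
    stop("duplicate variant key(s) in annotation table: ",
         paste(unique(ann$variant_key[duplicated(ann$variant_key)]),
               collapse = ", "))
  }
  bad_tier <- setdiff(stats::na.omit(unique(ann$impact_tier)), IMPACT_TIERS)
  if (length(bad_tier) > 0) stop("unknown impact tier: ",
                                 paste(bad_tier, collapse = ", "))
  bad_cv <- setdiff(stats::na.omit(unique(ann$clinvar)), CLINVAR_LEVELS)
  if (length(bad_cv) > 0) stop("unknown ClinVar status: ",
                               paste(bad_cv, collapse = ", "))
  genes <- read_tsv_na(gene_tsv)
  if (anyDuplicated(genes$gene)) {
    stop("duplicate gene symbol(s): ",
         paste(unique(genes$gene[duplicated(genes$gene)]), collapse = ", "))
  }
  for (col in c("susceptibility_only", "ndd", "incomplete_penetrance")) {
    if (col %in% names(genes)) genes[[col]] <- as.logical(genes[[col]])
  }
  list(annotations = ann, genes = genes)
}

#' Split a `;`-separated mode-of-inheritance cell
#'
#' @param x Character vector of cells such as `"AD;AR"`.
#' @return List of character vectors of modes.
#' @export
moi_set <- function(x) split_field(x)

#' Read the locus population table
#'
#' Columns: chrom, pos, ref, alt, impact_tier, ac, an, af, hom, hemi,
#' controls_ac, non_neuro_ac.
#'
#' @param path Path to the TSV.
#' @return Data frame with a `variant_key` column added.
#' @export
read_population_table <- function(path) {
  pop <- read_tsv_na(path)
  pop$variant_key <- variant_key(pop$chrom, pop$pos, pop$ref, pop$alt)
  pop
}

#' Read per-proband phenotype profiles from JSON
#'
#' Expects `{sample: {manual: [...], nlp: [...]}}`. When an ontology is
#' given, profiles are combined with [combine_profiles()] (obsolete terms
#' dropped from the combined set); otherwise `combined` is the plain union.
#'
#' @param path Path to the JSON file.
#' @param ontology Optional `pgr_ontology`.
#' @return Named list of `pgr_profile` objects.
#' @export
read_phenotype_profiles <- function(path, ontology = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) {
    manual <- as.character(unlist(p$manual))
    nlp <- as.character(unlist(p$nlp))
    if (is.null(ontology)) {
      structure(list(manual = unique(manual), nlp = unique(nlp),
                     combined = unique(union(manual, nlp))),
                class = "pgr_profile")
    } else {
      combine_profiles(manual, nlp, ontology)
    }
  })
}

#' Assemble a cohort object
#'
#' Bundles pedigree, genotype, annotation, gene, population and phenotype
#' data and validates the cross-references: every genotype sample must
#' belong to a family and every annotated variant must carry at least one
#' genotype.
#'
#' @param pedigree A `pgr_pedigree`.
#' @param variants,genotypes Data frames from [read_cohort_vcf()].
#' @param annotations,genes Data frames from [read_annotation_tables()].
#' @param population Optional population table ([read_population_table()]).
#' @param profiles Named list of `pgr_profile` objects.
#' @return A `pgr_cohort` list.
#' @export
as_cohort <- function(pedigree, variants, genotypes, annotations, genes,
                      population = NULL, profiles = list()) {
  stray <- setdiff(unique(genotypes$sample), pedigree$members$sample_id)
  if (length(stray) > 0) {
    stop("genotype sample(s) not in pedigree: ", paste(stray, collapse = ", "))
  }
  orphan <- setdiff(annotations$variant_key, genotypes$variant_key)
  if (length(orphan) > 0) {
    stop("annotated variant(s) with no genotype: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  structure(list(pedigree = pedigree, variants = variants,
                 genotypes = genotypes, annotations = annotations,
                 genes = genes, population = population, profiles = profiles),
            class = "pgr_cohort")
}

#' @export
print.pgr_cohort <- function(x, ...) {
  cat(sprintf(paste0("<pgr_cohort> %d families (%s), %d variants, ",
                     "%d genotypes, %d genes, %d profiles\n"),
              nrow(x$pedigree$families),
              paste(names(table(x$pedigree$families$structure)),
                    table(x$pedigree$families$structure),
                    sep = ":", collapse = " "),
              nrow(x$variants), nrow(x$genotypes), nrow(x$genes),
              length(x$profiles)))
  invisible(x)
}

#' Read a cohort directory
#'
#' Convenience loader for the file layout written by [simulate_cohort()]:
#' `cohort.ped`, `cohort.vcf`, `variants.tsv`, `genes.tsv`, `population.tsv`,
#' `phenotypes.json`, `ontology.obo`.
#'
#' @param dir Directory containing the files.
#' @return List with elements `cohort` (a `pgr_cohort`) and `ontology`.
#' @export
read_cohort_dir <- function(dir) {
  ontology <- load_obo(file.path(dir, "ontology.obo"))
  ped <- read_pedigree(file.path(dir, "cohort.ped"))
  vg <- read_cohort_vcf(file.path(dir, "cohort.vcf"), ped)
  tabs <- read_annotation_tables(file.path(dir, "variants.tsv"),
                                 file.path(dir, "genes.tsv"))
  pop <- read_population_table(file.path(dir, "population.tsv"))
  profiles <- read_phenotype_profiles(file.path(dir, "phenotypes.json"), ontology)
  list(cohort = as_cohort(ped, vg$variants, vg$genotypes, tabs$annotations,
                          tabs$genes, pop, profiles),
       ontology = ontology)
}

#' Write the internal report
#'
#' Emits one machine-readable JSON record per proband (at most the top two
#' retained variants by score, mirroring a one-to-two-variant internal
#' report) plus a TSV summary of all retained candidates and the funnel of
#' per-stage variant counts. An empty candidate set yields valid files.
#'
#' @param candidates Data frame of scored, reviewed candidates (must carry
#'   `proband`, `family_id`, `variant_key`, `score`, `acmg_class`,
#'   `posterior`, `returnable`).
#' @param stage_counts Named list or data frame of funnel counts.
#' @param dir Output directory (created if needed).
#' @param run_info Optional named list recorded in the report header.
#' @return Invisibly, the paths written.
#' @export
write_internal_report <- function(candidates, stage_counts, dir,
                                  run_info = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  tsv_path <- file.path(dir, "report_summary.tsv")
  probands <- list()
  if (!is.null(candidates) && nrow(candidates) > 0) {
    ord <- order(candidates$proband, -candidates$score)
    candidates <- candidates[ord, , drop = FALSE]
    for (p in unique(candidates$proband)) {
      rows <- candidates[candidates$proband == p, , drop = FALSE]
      rows <- utils::head(rows, 2L)
      probands[[p]] <- list(
        proband = p, family = rows$family_id[1],
        variants = lapply(seq_len(nrow(rows)), function(i) list(
          variant = rows$variant_key[i], gene = rows$gene[i],
          score = rows$score[i], inheritance = rows$pattern[i],
          acmg_class = rows$acmg_class[i], posterior = rows$posterior[i],
          returnable = rows$returnable[i], gnomad_af = rows$gnomad_af[i]))
      )
    }
  }
  payload <- list(run = run_info, funnel = as.list(stage_counts),
                  probands = unname(probands))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  keep <- intersect(c("proband", "family_id", "variant_key", "gene", "pattern",
                      "score", "acmg_class", "posterior", "returnable"),
                    names(candidates))
  tab <- if (!is.null(candidates) && nrow(candidates) > 0) {
    candidates[, keep, drop = FALSE]
  } else {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(keep))), keep)
  }
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}
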