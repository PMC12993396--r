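# Deterministic encoding of candidate variants into the ordered 43-value
# feature vector, median imputation, z-standardization and training-set
# assembly.

#' Default 43-slot feature schema
#'
#' Seventeen numeric slots (allele fraction, depth, population and cohort
#' frequency, three phenotype-scorer slots that fall back to the built-in
#' similarity, HPO match counts at no cutoff and at information-content
#' cutoffs 2 and 4, five in-silico scores and two constraint scores) plus
#' one-hot expansions of the inheritance call (6), gene mode of inheritance
#' (4, multi-hot), impact tier (4), ClinVar class (7) and automated ACMG
#' class (5). The `unknown` inheritance pattern and an absent ACMG class
#' are the all-zero reference levels.
#'
#' @return Data frame with columns `name`, `source`, `kind`, `level`.
#' @export
default_feature_schema <- function() {
  numeric_slots <- c("alt_fraction", "depth", "gnomad_af", "cohort_af",
                     "hpo3", "amelie", "shepherd",
                     "hpo_match", "hpo_ic2", "hpo_ic4",
                     "cadd_phred", "revel", "alphamissense", "spliceai",
                     "misfit_d", "s_het", "pli")
  one_hot <- rbind(
    data.frame(source = "pattern",
               level = c("de_novo", "homozygous", "hemizygous", "compound_het",
                         "segregating_dominant", "inherited_unphased")),
    data.frame(source = "moi", level = c("AD", "AR", "XLD", "XLR")),
    data.frame(source = "impact_tier", level = IMPACT_TIERS),
    data.frame(source = "clinvar", level = CLINVAR_LEVELS),
    data.frame(source = "acmg_auto", level = ACMG_CLASSES)
  )
  schema <- rbind(
    data.frame(name = numeric_slots, source = numeric_slots,
               kind = "numeric", level = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = paste(one_hot$source, one_hot$level, sep = "."),
               source = one_hot$source, kind = "one_hot",
               level = one_hot$level, stringsAsFactors = FALSE)
  )
  stopifnot(nrow(schema) == 43L, !anyDuplicated(schema$name))
  schema
}

#' Phenotype scores between a patient profile and a gene
#'
#' Computes the built-in best-match-average Resnik similarity and the HPO
#' match-count features for one patient term set against one gene's disease
#' terms.
#'
#' @param patient_terms,gene_terms Character vectors of term ids.
#' @param ontology A `pgr_ontology`.
#' @param ic Information-content vector.
#' @return List with `similarity` and `match` (a [match_features()] list).
#' @export
phenotype_scores <- function(patient_terms, gene_terms, ontology, ic) {
  if (length(patient_terms) == 0 || length(gene_terms) == 0) {
    return(list(similarity = 0,
                match = list(exact_count = 0L, one_level_count = 0L,
                             ic2_count = 0L, ic4_count = 0L)))
  }
  list(similarity = similarity(patient_terms, gene_terms, ontology, ic),
       match = match_features(patient_terms, gene_terms, ontology, ic))
}

#' Encode candidate rows into the 43-column feature matrix
#'
#' Categorical fields are one-hot expanded per the schema; numeric fields
#' are copied; phenotype slots are computed from the supplied term sets
#' (defaulting to each proband's combined profile), with externally
#' supplied `hpo3` / `amelie` / `shepherd` columns passed through when
#' present in the candidate rows and the built-in similarity filling those
#' slots otherwise. Missing values stay `NA` here and are median-imputed at
#' model time; the mask records which slots were missing.
#'
#' @param cand Candidate data frame (output rows of [run_cfa()]).
#' @param cohort The `pgr_cohort` (for profiles and gene terms).
#' @param ontology A `pgr_ontology`.
#' @param ic Information-content vector.
#' @param schema Feature schema, default [default_feature_schema()].
#' @param term_set Which profile term set feeds the phenotype features:
#'   `"combined"` (default), `"manual"` or `"nlp"`.
#' @param term_override Optional named list (proband -> term vector)
#'   overriding profile terms, used by the pruning experiment.
#' @return List with matrix `X` (rows x 43), logical `mask` of originally
#'   missing cells, the per-row built-in `similarity`, and the `schema`.
#' @export
encode_features <- function(cand, cohort, ontology, ic,
                            schema = default_feature_schema(),
                            term_set = "combined", term_override = NULL) {
  n <- nrow(cand)
  X <- matrix(NA_real_, nrow = n, ncol = nrow(schema),
              dimnames = list(NULL, schema$name))
  if (n == 0) return(list(X = X, mask = X > 0, similarity = numeric(0),
                          schema = schema))

  terms_for <- function(proband) {
    if (!is.null(term_override) && proband %in% names(term_override)) {
      return(term_override[[proband]])
    }
    prof <- cohort$profiles[[proband]]
    if (is.null(prof)) character(0) else prof[[term_set]]
  }
  cache <- new.env(parent = emptyenv())
  phen_for <- function(proband, gene) {
    key <- paste(proband, gene, sep = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ps <- phenotype_scores(terms_for(proband), gene_terms_of(cohort, gene),
                           ontology, ic)
    cache[[key]] <- ps
    ps
  }
  phen <- lapply(seq_len(n), function(i) phen_for(cand$proband[i],
                                                  cand$gene[i]))
  sim <- vapply(phen, `[[`, numeric(1), "similarity")
  getm <- function(f) vapply(phen, function(p) as.numeric(p$match[[f]]),
                             numeric(1))
  phen_cols <- list(
    hpo3 = sim, amelie = sim, shepherd = sim,
    hpo_match = getm("exact_count") + getm("one_level_count"),
    hpo_ic2 = getm("ic2_count"), hpo_ic4 = getm("ic4_count"))
  for (ext in c("hpo3", "amelie", "shepherd")) {
    if (ext %in% names(cand) && any(!is.na(cand[[ext]]))) {
      phen_cols[[ext]] <- ifelse(is.na(cand[[ext]]), sim, cand[[ext]])
    }
  }

  moi_list <- moi_set(cand$moi)
  for (j in seq_len(nrow(schema))) {
    src <- schema$source[j]
    if (schema$kind[j] == "numeric") {
      X[, j] <- if (src %in% names(phen_cols)) {
        phen_cols[[src]]
      } else if (src %in% names(cand)) {
        as.numeric(cand[[src]])
      } else {
        NA_real_
      }
    } else if (src == "moi") {
      X[, j] <- vapply(moi_list, function(m) as.numeric(schema$level[j] %in% m),
                       numeric(1))
    } else {
      X[, j] <- as.numeric(!is.na(cand[[src]]) & cand[[src]] == schema$level[j])
    }
  }
  mask <- is.na(X)
  list(X = X, mask = mask, similarity = sim, schema = schema)
}

#' Fit per-column median imputation values
#'
#' @param X Feature matrix with `NA`s.
#' @return Numeric vector of column medians (0 for all-missing columns).
#' @export
fit_imputer <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  ifelse(is.na(med), 0, med)
}

#' Apply median imputation
#'
#' @param X Feature matrix.
#' @param medians Vector from [fit_imputer()].
#' @return Matrix without `NA`s.
#' @export
apply_imputer <- function(X, medians) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- medians[j]
  X
}

#' Fit a column z-standardizer
#'
#' Means and population standard deviations are fit on the supplied rows;
#' constant columns record a standard deviation of 1 so they standardize to
#' zero.
#'
#' @param X Complete (imputed) feature matrix with at least two rows.
#' @return List with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(X) {
  if (nrow(X) < 2) stop("need at least 2 rows to fit a standardizer")
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sd[sd < .Machine$double.eps^0.5] <- 1
  list(mean = mu, sd = sd)
}

#' Apply (or invert) a standardizer
#'
#' @param params List from [fit_standardizer()].
#' @param X Feature matrix.
#' @param invert If `TRUE`, undo the transformation.
#' @return Transformed matrix.
#' @export
apply_standardizer <- function(params, X, invert = FALSE) {
  if (invert) {
    sweep(sweep(X, 2, params$sd, `*`), 2, params$mean, `+`)
  } else {
    sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
  }
}

#' Assemble the labeled training set
#'
#' Positive instances are the reported pathogenic / likely pathogenic / VUS
#' variants; negative instances are CFA survivors of the same probands that
#' were absent from reports. Reported variants that failed CFA are kept as
#' positives (their candidate rows are recovered from the decision table);
#' reported variants absent from the cohort are dropped with a warning.
#' Rows are grouped by proband for leakage-safe splitting.
#'
#' @param cfa Result of [run_cfa()].
#' @param reported Data frame with `proband`, `variant_key`, `label`
#'   (one of `pathogenic`, `likely_pathogenic`, `VUS`).
#' @return List with `rows` (candidate data frame), `labels` (character,
#'   the reported class or `"negative"`), and `groups` (proband ids).
#' @export
assemble_training_set <- function(cfa, reported) {
  stopifnot(all(reported$label %in% c("pathogenic", "likely_pathogenic", "VUS")))
  all_rows <- cfa$decisions
  rk <- paste(reported$proband, reported$variant_key)
  ak <- paste(all_rows$proband, all_rows$variant_key)
  missing <- !(rk %in% ak)
  if (any(missing)) {
    warning(sum(missing), " reported variant(s) absent from the cohort; excluded: ",
            paste(utils::head(rk[missing], 3), collapse = ", "), call. = FALSE)
    reported <- reported[!missing, , drop = FALSE]
    rk <- rk[!missing]
  }
  pos_rows <- all_rows[match(rk, ak), , drop = FALSE]
  surv <- cfa$candidates
  sk <- paste(surv$proband, surv$variant_key)
  neg_rows <- surv[surv$proband %in% reported$proband & !(sk %in% rk), ,
                   drop = FALSE]
  rows <- rbind(pos_rows, neg_rows)
  labels <- c(reported$label, rep("negative", nrow(neg_rows)))
  list(rows = rows, labels = labels, groups = rows$proband)
}
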