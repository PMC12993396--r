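# End-to-end orchestration: the full reanalysis funnel, the HPO
# branch-pruning experiment, and the small statistical utilities the
# experiment relies on (exact/approximate Wilcoxon rank-sum,
# Benjamini-Hochberg, accounting fractions).

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses exact enumeration of the null distribution of the Mann-Whitney U
#' statistic (midranks, so ties are handled exactly) when the pooled sample
#' size is at most `exact_max`, and the normal approximation with tie
#' correction and continuity correction otherwise. The two-sided p-value of
#' the exact branch is the null probability of a U at least as far from its
#' mean as observed.
#'
#' @param a,b Nonempty numeric samples.
#' @param exact_max Pooled-size cutoff for exact enumeration (default 12).
#' @return List with `statistic` (Mann-Whitney U of `a`) and `p`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, na)
    us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u_obs, p = 1))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u_obs, p = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper over
#' the standard adjustment.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted q-values, order-preserving, capped at 1.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Accounting fraction with display rounding
#'
#' @param numerator,denominator Nonnegative counts, denominator positive.
#' @param digits Decimal places of the percentage display (default 0).
#' @return List with `numerator`, `denominator`, `fraction`, `percent`
#'   (rounded) and a formatted `label` such as `"2% (42/2,144)"`.
#' @export
accounting_fraction <- function(numerator, denominator, digits = 0) {
  if (denominator <= 0) stop("denominator must be positive")
  stopifnot(numerator >= 0, numerator <= denominator)
  fraction <- numerator / denominator
  percent <- round(100 * fraction, digits)
  list(numerator = numerator, denominator = denominator, fraction = fraction,
       percent = percent,
       label = sprintf("%s%% (%s/%s)", format(percent),
                       format(numerator, big.mark = ","),
                       format(denominator, big.mark = ",")))
}

#' Accounting summary over named count pairs
#'
#' @param pairs Named list of `c(numerator, denominator)` pairs.
#' @param digits Display precision of each percentage.
#' @return Data frame with one row per pair.
#' @export
accounting_summary <- function(pairs, digits = 0) {
  rows <- lapply(names(pairs), function(nm) {
    f <- accounting_fraction(pairs[[nm]][1], pairs[[nm]][2], digits)
    data.frame(name = nm, numerator = f$numerator,
               denominator = f$denominator, fraction = f$fraction,
               percent = f$percent, label = f$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

resolve_strong_similarity <- function(config, similarities) {
  if (!is.na(config$strong_similarity)) return(config)
  config$strong_similarity <-
    if (length(similarities) == 0) Inf
    else as.numeric(stats::quantile(similarities, 0.9, names = FALSE))
  config
}

#' Run the full proactive-reanalysis pipeline over a cohort
#'
#' Load, CFA, phenotype scoring, feature encoding, neural-network scoring
#' with the 0.5 decision threshold, first-pass screening, second-pass ACMG
#' classification and internal-report generation, with a funnel of variant
#' and proband counts per stage.
#'
#' @param cohort A `pgr_cohort`.
#' @param ontology A `pgr_ontology`.
#' @param model A trained `pgr_vsnn`.
#' @param cfa_config A [cfa_thresholds()] list.
#' @param review_cfg A [review_config()]; an `NA` `strong_similarity` is
#'   resolved to the 90th percentile of the scored candidates' similarity
#'   distribution.
#' @param term_set Profile term set feeding the phenotype features.
#' @param documented Character vector of already-documented
#'   `proband|variant_key` pairs ([documented_key()]).
#' @param out_dir If non-`NULL`, the internal report is written there.
#' @param seed Seed recorded in the run metadata (the pipeline itself is
#'   deterministic given a trained model).
#' @return List with `funnel` (data frame of per-stage variant and proband
#'   counts), `report` (final retained candidates), `scored` (all CFA
#'   survivors with scores), `first_pass` and `cfa` intermediates.
#' @export
run_pgr <- function(cohort, ontology, model,
                    cfa_config = cfa_thresholds(),
                    review_cfg = review_config(),
                    term_set = "combined", documented = character(0),
                    out_dir = NULL, seed = 1L) {
  ic <- information_content(ontology, gene_corpus(cohort))
  cfa <- run_cfa(cohort, ontology, ic, cfa_config)
  surv <- cfa$candidates
  stage <- function(name, rows) data.frame(
    stage = name, variants = nrow(rows),
    probands = length(unique(rows$proband)), stringsAsFactors = FALSE)
  funnel <- rbind(stage("input_variants", cfa$decisions),
                  stage("post_cfa", surv))

  if (nrow(surv) > 0) {
    enc <- encode_features(surv, cohort, ontology, ic,
                           term_set = term_set)
    pred <- predict_scores(model, enc$X)
    surv$score <- pred$score
    surv$similarity <- enc$similarity
    flagged <- surv[pred$flagged, , drop = FALSE]
  } else {
    surv$score <- numeric(0)
    surv$similarity <- numeric(0)
    flagged <- surv
  }
  funnel <- rbind(funnel, stage("post_score_threshold", flagged))

  review_cfg <- resolve_strong_similarity(review_cfg, surv$similarity)
  ann_clinvar <- stats::setNames(cohort$annotations$clinvar,
                                 cohort$annotations$variant_key)
  first <- lapply(seq_len(nrow(flagged)), function(i) {
    cand <- flagged[i, ]
    ev <- aggregate_locus_evidence(cand, cohort$population)
    dec <- first_pass_screen(cand, ev, cand$similarity, review_cfg)
    c(dec, list(evidence = ev))
  })
  flagged$first_pass <- vapply(first, `[[`, character(1), "status")
  flagged$first_pass_reason <- vapply(first, `[[`, character(1), "reason")
  retained <- flagged[flagged$first_pass == "retain", , drop = FALSE]
  retained_ev <- first[flagged$first_pass == "retain"]
  funnel <- rbind(funnel, stage("post_first_pass", retained))

  second <- lapply(seq_len(nrow(retained)), function(i) {
    cand <- retained[i, ]
    partner_cv <- if (is.na(cand$partner_key)) NA_character_
                  else unname(ann_clinvar[cand$partner_key])
    crit <- assign_acmg_criteria(cand, retained_ev[[i]]$evidence,
                                 partner_clinvar = partner_cv,
                                 config = review_cfg)
    acmg <- combine_tavtigian(crit)
    second_pass_classify(cand, acmg, cand$similarity, review_cfg, documented)
  })
  if (nrow(retained) > 0) {
    retained$acmg_class <- vapply(second, `[[`, character(1), "acmg_class")
    retained$posterior <- vapply(second, `[[`, numeric(1), "posterior")
    retained$returnable <- vapply(second, `[[`, logical(1), "returnable")
    retained$second_pass <- vapply(second, `[[`, character(1), "status")
    retained$second_pass_reason <- vapply(second, `[[`, character(1), "reason")
  } else {
    retained$acmg_class <- character(0)
    retained$posterior <- numeric(0)
    retained$returnable <- logical(0)
    retained$second_pass <- character(0)
    retained$second_pass_reason <- character(0)
  }
  final <- retained[retained$second_pass == "retain", , drop = FALSE]
  funnel <- rbind(funnel, stage("post_second_pass", final))
  stopifnot(all(diff(funnel$variants) <= 0))

  paths <- NULL
  if (!is.null(out_dir)) {
    counts <- stats::setNames(as.list(funnel$variants), funnel$stage)
    paths <- write_internal_report(
      final, counts, out_dir,
      run_info = list(seed = seed, package = "pgrpipe",
                      version = as.character(utils::packageVersion("pgrpipe"))))
  }
  list(funnel = funnel, report = final, first_pass = flagged,
       scored = surv, cfa = cfa, report_paths = paths,
       review_cfg = review_cfg)
}

#' HPO branch-pruning experiment
#'
#' For each proband in the evaluation set, partitions the manually curated
#' terms into third-level branches and, removing one branch at a time,
#' rebuilds the phenotype features, re-encodes the proband's variants and
#' re-scores them. Deltas (pruned minus original manual-profile score) are
#' collected per variant and branch; TP and FN delta distributions are
#' compared with two-sided Wilcoxon rank-sum tests and adjusted with
#' Benjamini-Hochberg. Probands with fewer than two branches are skipped.
#'
#' @param cohort A `pgr_cohort`.
#' @param ontology A `pgr_ontology`.
#' @param model A trained `pgr_vsnn`.
#' @param eval_rows Candidate rows to re-score (typically the reported
#'   variants of the validation probands).
#' @param eval_labels Character labels aligned with `eval_rows`.
#' @param ic Optional information-content vector.
#' @return List with `deltas` (per proband x branch x variant:
#'   `branch_anchor`, `branch_size`, `n_branches`, `group` (TP/FN by the
#'   0.5 threshold on the manual-profile score), `original`, `pruned`,
#'   `delta`, `branch_overlaps_gene`), `scores` (per-variant combined /
#'   manual scores and group), and `tests` (rank-sum comparisons with BH
#'   q-values).
#' @export
pruning_experiment <- function(cohort, ontology, model, eval_rows,
                               eval_labels, ic = NULL) {
  if (is.null(ic)) ic <- information_content(ontology, gene_corpus(cohort))
  keep <- eval_labels != "negative"
  rows <- eval_rows[keep, , drop = FALSE]
  if (nrow(rows) == 0) stop("no positive rows to prune")

  score_with <- function(term_set, term_override = NULL) {
    enc <- encode_features(rows, cohort, ontology, ic,
                           term_set = term_set, term_override = term_override)
    predict_scores(model, enc$X)$score
  }
  combined <- score_with("combined")
  manual <- score_with("manual")
  group <- ifelse(manual >= model$config$threshold, "TP", "FN")
  scores <- data.frame(proband = rows$proband, variant_key = rows$variant_key,
                       gene = rows$gene, combined = combined, manual = manual,
                       group = group, stringsAsFactors = FALSE)

  deltas <- list()
  for (p in unique(rows$proband)) {
    prof <- cohort$profiles[[p]]
    if (is.null(prof) || length(prof$manual) == 0) next
    branches <- third_level_partition(prof$manual, ontology)
    if (length(branches) < 2) {
      message("proband ", p, ": fewer than 2 branches, skipped")
      next
    }
    ridx <- which(rows$proband == p)
    for (br in branches) {
      pruned_terms <- setdiff(prof$manual, br$members)
      override <- stats::setNames(list(pruned_terms), p)
      pr_scores <- {
        enc <- encode_features(rows[ridx, , drop = FALSE], cohort, ontology,
                               ic, term_set = "manual",
                               term_override = override)
        predict_scores(model, enc$X)$score
      }
      for (k in seq_along(ridx)) {
        i <- ridx[k]
        gene_anchors <- vapply(
          third_level_partition(gene_terms_of(cohort, rows$gene[i]), ontology),
          `[[`, character(1), "anchor")
        deltas[[length(deltas) + 1L]] <- data.frame(
          proband = p, variant_key = rows$variant_key[i],
          gene = rows$gene[i], group = group[i],
          branch_anchor = br$anchor, branch_size = length(br$members),
          n_branches = length(branches),
          original = manual[i], pruned = pr_scores[k],
          delta = pr_scores[k] - manual[i],
          branch_overlaps_gene = !is.na(br$anchor) &&
            br$anchor %in% gene_anchors,
          stringsAsFactors = FALSE)
      }
    }
  }
  deltas <- if (length(deltas) > 0) do.call(rbind, deltas) else
    data.frame()

  tests <- list()
  add_test <- function(name, a, b) {
    if (length(a) >= 3 && length(b) >= 3) {
      w <- wilcoxon_rank_sum(a, b)
      tests[[length(tests) + 1L]] <<- data.frame(
        comparison = name, n_a = length(a), n_b = length(b),
        statistic = w$statistic, p = w$p, stringsAsFactors = FALSE)
    }
  }
  add_test("combined_vs_manual_diff_TP_vs_FN",
           scores$combined[scores$group == "TP"] -
             scores$manual[scores$group == "TP"],
           scores$combined[scores$group == "FN"] -
             scores$manual[scores$group == "FN"])
  if (nrow(deltas) > 0) {
    add_test("pruned_delta_TP_vs_FN",
             deltas$delta[deltas$group == "TP"],
             deltas$delta[deltas$group == "FN"])
    add_test("pruned_delta_TP_causal_vs_disjoint",
             deltas$delta[deltas$group == "TP" & deltas$branch_overlaps_gene],
             deltas$delta[deltas$group == "TP" & !deltas$branch_overlaps_gene])
  }
  tests <- if (length(tests) > 0) do.call(rbind, tests) else data.frame()
  if (nrow(tests) > 0) tests$q <- benjamini_hochberg(tests$p)
  list(deltas = deltas, scores = scores, tests = tests)
}
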