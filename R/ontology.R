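# Ontology handling: OBO parsing, information content, term matching,
# semantic similarity, profile combination and third-level branch partition.

#' Load an OBO-format phenotype ontology
#'
#' Parses an OBO 1.2 flat file containing `[Term]` stanzas with `id`, `name`,
#' `is_a` and optional `is_obsolete` fields into a validated directed acyclic
#' graph. Obsolete terms are retained but flagged; they never participate in
#' matching or similarity.
#'
#' @param path Path to an OBO file.
#' @return An object of class `pgr_ontology`: a list with elements `ids`,
#'   `name`, `parents`, `children`, `obsolete`, `root`, `depth` (minimum
#'   number of nodes on a path from the root, root = 1) and `ancestors`
#'   (proper ancestors, excluding the term itself).
#' @export
load_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  nm <- character()
  parents <- list()
  obsolete <- logical()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nzchar(cur$id)) {
      ids[[length(ids) + 1L]] <<- cur$id
      nm[[cur$id]] <<- cur$name
      parents[[cur$id]] <<- cur$parents
      obsolete[[cur$id]] <<- cur$obsolete
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      if (in_term) flush()
      in_term <- TRUE
      cur <- list(id = "", name = "", parents = character(), obsolete = FALSE)
    } else if (grepl("^\\[", ln)) {
      if (in_term) flush()
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3) {
        key <- kv[2]; val <- trimws(kv[3])
        if (key == "id") cur$id <- val
        else if (key == "name") cur$name <- val
        else if (key == "is_a") cur$parents <- c(cur$parents, val)
        else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
      }
    }
  }
  if (in_term) flush()
  if (length(ids) == 0) stop("no [Term] stanzas found in ", path)
  build_ontology(ids, nm, parents, obsolete)
}

#' Construct an ontology from term tables
#'
#' Validates the parent graph (acyclicity, a single root among non-obsolete
#' terms, reachability of the root) and precomputes depths and ancestor sets.
#'
#' @param ids Character vector of term identifiers.
#' @param name Named character vector of term names.
#' @param parents Named list mapping each term to its parent term ids.
#' @param obsolete Named logical vector of obsolete flags.
#' @return A `pgr_ontology` object; see [load_obo()].
#' @export
build_ontology <- function(ids, name, parents, obsolete = NULL) {
  if (anyDuplicated(ids)) stop("duplicate term ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(obsolete)) obsolete <- stats::setNames(rep(FALSE, length(ids)), ids)
  obsolete <- obsolete[ids]
  parents <- parents[ids]
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown) > 0) stop("is_a references unknown terms: ",
                                paste(unknown, collapse = ", "))

  # Kahn topological sort over the parent->child direction; leftover nodes
  # with unresolved parents indicate a cycle.
  indeg <- vapply(parents, length, integer(1))
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  order <- character(0)
  queue <- ids[indeg == 0L]
  indeg_work <- indeg
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    bad <- setdiff(ids, order)
    edge <- sprintf("%s -> %s", bad[1], intersect(parents[[bad[1]]], bad)[1])
    stop("cycle detected in ontology (edge ", edge, ")")
  }
  roots <- ids[indeg == 0L & !obsolete]
  if (length(roots) != 1) stop("ontology must have exactly one root, found: ",
                               paste(roots, collapse = ", "))
  root <- roots

  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ancestors <- stats::setNames(vector("list", length(ids)), ids)
  depth[[root]] <- 1L
  ancestors[[root]] <- character(0)
  for (t in order) {
    if (t == root) next
    ps <- parents[[t]]
    if (length(ps) == 0) { # obsolete orphan or secondary root (obsolete only)
      depth[[t]] <- NA_integer_
      ancestors[[t]] <- character(0)
      next
    }
    pdepth <- depth[ps]
    depth[[t]] <- if (all(is.na(pdepth))) NA_integer_ else min(pdepth, na.rm = TRUE) + 1L
    ancestors[[t]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
  }
  if (any(is.na(depth[!obsolete]))) {
    stop("non-obsolete terms cannot reach the root: ",
         paste(ids[!obsolete & is.na(depth)], collapse = ", "))
  }
  structure(list(ids = ids, name = name[ids], parents = parents,
                 children = children, obsolete = obsolete, root = root,
                 depth = depth, ancestors = ancestors),
            class = "pgr_ontology")
}

#' @export
print.pgr_ontology <- function(x, ...) {
  cat(sprintf("<pgr_ontology> %d terms (%d obsolete), root %s, max depth %d\n",
              length(x$ids), sum(x$obsolete), x$root,
              max(x$depth, na.rm = TRUE)))
  invisible(x)
}

check_terms <- function(terms, ontology) {
  bad <- setdiff(terms, ontology$ids)
  if (length(bad) > 0) stop("unknown ontology term id(s): ",
                            paste(bad, collapse = ", "))
  invisible(terms)
}

#' Propagate gene-phenotype annotations to ancestors
#'
#' Closes each gene's annotated term set under the ancestor relation, the
#' standard preliminary to corpus information-content estimation.
#'
#' @param gene_terms Named list mapping gene symbols to term-id vectors.
#' @param ontology A `pgr_ontology`.
#' @return Named list with each gene's set closed under ancestors.
#' @export
propagate_annotations <- function(gene_terms, ontology) {
  lapply(gene_terms, function(ts) {
    check_terms(ts, ontology)
    unique(c(ts, unlist(ontology$ancestors[ts], use.names = FALSE)))
  })
}

#' Corpus information content of ontology terms
#'
#' For every term, computes the Resnik-style information content
#' \eqn{IC(t) = -\ln(n_t / N)} where \eqn{n_t} is the number of genes
#' annotated (after ancestor propagation) with the term and \eqn{N} the total
#' number of genes in the corpus. Terms annotated to no gene receive `Inf`
#' (maximally specific with respect to the corpus).
#'
#' @param ontology A `pgr_ontology`.
#' @param gene_terms Named list mapping genes to term ids (the annotation
#'   corpus).
#' @param propagate If `TRUE` (default) the corpus is closed under ancestors
#'   first; pass `FALSE` only if it is already propagated.
#' @return Named numeric vector of information contents over all terms.
#' @export
information_content <- function(ontology, gene_terms, propagate = TRUE) {
  if (length(gene_terms) == 0) stop("empty annotation corpus")
  if (propagate) gene_terms <- propagate_annotations(gene_terms, ontology)
  n_total <- length(gene_terms)
  counts <- table(factor(unlist(lapply(gene_terms, unique), use.names = FALSE),
                         levels = ontology$ids))
  ic <- ifelse(counts == 0, Inf, -log(as.numeric(counts) / n_total))
  stats::setNames(as.numeric(ic), ontology$ids)
}

#' HPO term match features between a patient and a gene
#'
#' Counts exact term matches, matches one ontology level apart (a gene term
#' that is a direct parent or child of a patient term; each patient term
#' contributes at most one such match and exact matches are not re-counted),
#' and exact matches whose information content passes the specificity cutoffs
#' (defaults 2 and 4 on a natural-log scale).
#'
#' @param patient_terms,gene_terms Character vectors of term ids.
#' @param ontology A `pgr_ontology`.
#' @param ic Named information-content vector from [information_content()].
#' @param ic_cutoffs Two increasing cutoffs applied to exact matches.
#' @param include_siblings If `TRUE`, terms sharing a parent also count as
#'   one-level matches (off by default).
#' @return List with `exact_count`, `one_level_count`, `ic2_count`,
#'   `ic4_count`.
#' @export
match_features <- function(patient_terms, gene_terms, ontology, ic,
                           ic_cutoffs = c(2, 4), include_siblings = FALSE) {
  check_terms(patient_terms, ontology)
  check_terms(gene_terms, ontology)
  patient_terms <- unique(patient_terms[!ontology$obsolete[patient_terms]])
  gene_terms <- unique(gene_terms[!ontology$obsolete[gene_terms]])
  exact <- intersect(patient_terms, gene_terms)
  one_level <- 0L
  for (p in setdiff(patient_terms, exact)) {
    near <- c(ontology$parents[[p]], ontology$children[[p]])
    if (include_siblings) {
      near <- c(near, unlist(ontology$children[ontology$parents[[p]]],
                             use.names = FALSE))
    }
    if (length(intersect(near, gene_terms)) > 0) one_level <- one_level + 1L
  }
  list(exact_count = length(exact),
       one_level_count = one_level,
       ic2_count = sum(ic[exact] >= ic_cutoffs[1]),
       ic4_count = sum(ic[exact] >= ic_cutoffs[2]))
}

mica_ic <- function(a, b, ontology, ic) {
  common <- intersect(c(a, ontology$ancestors[[a]]),
                      c(b, ontology$ancestors[[b]]))
  if (length(common) == 0) return(0)
  vals <- ic[common]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) 0 else max(vals)
}

#' Symmetric best-match-average Resnik similarity
#'
#' For each term on one side, takes the maximum over the other side of the
#' information content of the most informative common ancestor, averages
#' within each direction, then averages the two directions. An empty gene
#' set yields 0.
#'
#' @inheritParams match_features
#' @return A nonnegative similarity score.
#' @export
similarity <- function(patient_terms, gene_terms, ontology, ic) {
  check_terms(patient_terms, ontology)
  check_terms(gene_terms, ontology)
  patient_terms <- unique(patient_terms[!ontology$obsolete[patient_terms]])
  gene_terms <- unique(gene_terms[!ontology$obsolete[gene_terms]])
  if (length(patient_terms) == 0 || length(gene_terms) == 0) return(0)
  m <- outer(patient_terms, gene_terms,
             Vectorize(function(p, g) mica_ic(p, g, ontology, ic)))
  dim(m) <- c(length(patient_terms), length(gene_terms))
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

#' Combine manual and NLP phenotype profiles
#'
#' The combined set is the union of the manually curated and NLP-extracted
#' term sets with obsolete terms removed. No ancestor-redundancy collapsing
#' is applied: downstream features consume counts and redundant ancestors are
#' informative about annotation granularity.
#'
#' @param manual,nlp Character vectors of term ids.
#' @param ontology A `pgr_ontology`.
#' @return A `pgr_profile` list with `manual`, `nlp`, `combined`.
#' @export
combine_profiles <- function(manual, nlp, ontology) {
  check_terms(c(manual, nlp), ontology)
  drop_obs <- function(ts) unique(ts[!ontology$obsolete[ts]])
  structure(list(manual = drop_obs(manual), nlp = drop_obs(nlp),
                 combined = drop_obs(union(manual, nlp))),
            class = "pgr_profile")
}

#' Partition patient terms into third-level phenotype branches
#'
#' Each term is assigned to every level-3 ancestor it reaches (the root is
#' level 1; level is minimum depth). Terms above level 3 fall into a residual
#' branch with anchor `NA`. Multi-parent terms can appear in several
#' branches, so removing a branch is guaranteed to remove the whole
#' phenotype cluster under its anchor.
#'
#' @param patient_terms Character vector of term ids.
#' @param ontology A `pgr_ontology`.
#' @return List of branches, each a list with `anchor` and `members`.
#' @export
third_level_partition <- function(patient_terms, ontology) {
  check_terms(patient_terms, ontology)
  patient_terms <- unique(patient_terms)
  if (length(patient_terms) == 0) return(list())
  branches <- list()
  residual <- character(0)
  for (t in patient_terms) {
    anc <- c(t, ontology$ancestors[[t]])
    anchors <- anc[!is.na(ontology$depth[anc]) & ontology$depth[anc] == 3L]
    if (length(anchors) == 0) {
      residual <- c(residual, t)
    } else {
      for (a in anchors) branches[[a]] <- c(branches[[a]], t)
    }
  }
  out <- lapply(names(branches), function(a)
    list(anchor = a, members = unique(branches[[a]])))
  if (length(residual) > 0) {
    out <- c(out, list(list(anchor = NA_character_, members = residual)))
  }
  out
}

#' Remove one phenotype branch from a profile
#'
#' Returns a profile whose manual term set excludes the branch members,
#' simulating a phenotype cluster not yet recorded in the patient's history.
#'
#' @param profile A `pgr_profile`.
#' @param branch One element of [third_level_partition()] output computed
#'   from this profile's manual terms.
#' @return A `pgr_profile` with the branch removed from `manual` (and from
#'   `combined`, which is recomputed from the pruned manual set and the
#'   untouched NLP set).
#' @export
prune_branch <- function(profile, branch) {
  stopifnot(inherits(profile, "pgr_profile"))
  if (!all(branch$members %in% profile$manual)) {
    stop("branch was not derived from this profile's manual terms")
  }
  manual <- setdiff(profile$manual, branch$members)
  structure(list(manual = manual, nlp = profile$nlp,
                 combined = unique(union(manual, profile$nlp))),
            class = "pgr_profile")
}
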