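test_that("load_obo parses chains, preserves diamonds and rejects cycles", {
  chain <- write_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: T1", "name: one", "",
    "[Term]", "id: T2", "name: two", "is_a: T1", "",
    "[Term]", "id: T3", "name: three", "is_a: T2", "",
    "[Term]", "id: T4", "name: four", "is_a: T3", "",
    "[Term]", "id: T5", "name: five", "is_a: T4", ""))
  ont <- load_obo(chain)
  expect_identical(ont$root, "T1")
  expect_identical(unname(ont$depth[c("T1", "T5")]), c(1L, 5L))

  diamond <- write_obo(c(
    "[Term]", "id: R", "name: r", "",
    "[Term]", "id: P1", "name: p1", "is_a: R", "",
    "[Term]", "id: P2", "name: p2", "is_a: R", "",
    "[Term]", "id: C", "name: c", "is_a: P1", "is_a: P2", ""))
  ont2 <- load_obo(diamond)
  expect_setequal(ont2$parents[["C"]], c("P1", "P2"))
  expect_setequal(ont2$ancestors[["C"]], c("P1", "P2", "R"))

  cyc <- write_obo(c(
    "[Term]", "id: X", "name: x", "is_a: Y", "",
    "[Term]", "id: Y", "name: y", "is_a: X", ""))
  expect_error(load_obo(cyc), "cycle")

  two_roots <- write_obo(c(
    "[Term]", "id: R1", "name: r1", "",
    "[Term]", "id: R2", "name: r2", ""))
  expect_error(load_obo(two_roots), "exactly one root")
})

test_that("information content matches hand computation and brute force", {
  ont <- tiny_ontology()
  ic <- information_content(ont, tiny_corpus())
  expect_equal(unname(ic[["R"]]), 0)          # all 8 genes reach the root
  expect_equal(unname(ic[["A1"]]), log(4))    # 2 of 8 genes
  expect_equal(unname(ic[["G"]]), log(8))     # 1 of 8 genes
  expect_gt(ic[["G"]], 2)                     # passes the cutoff-2 screen
  expect_true(is.infinite(ic[["A2a"]]) == FALSE)  # annotated directly
  expect_true(is.infinite(ic[["OBS"]]))       # never annotated

  # independent oracle: count genes by brute-force ancestor closure
  corpus <- tiny_corpus()
  closed <- lapply(corpus, function(ts)
    unique(c(ts, unlist(lapply(ts, brute_ancestors, ontology = ont)))))
  for (t in ont$ids) {
    n_t <- sum(vapply(closed, function(s) t %in% s, logical(1)))
    expected <- if (n_t == 0) Inf else -log(n_t / length(corpus))
    expect_equal(unname(ic[[t]]), expected, info = t)
  }
  expect_error(information_content(ont, list()), "empty")
})

test_that("child IC dominates parent IC under propagated counts", {
  ont <- tiny_ontology()
  ic <- information_content(ont, tiny_corpus())
  for (t in setdiff(ont$ids, ont$root)) {
    for (p in ont$parents[[t]]) {
      expect_gte(ic[[t]], ic[[p]])
    }
  }
})

test_that("match features count exact, one-level and IC-cutoff matches", {
  ont <- tiny_ontology()
  ic <- information_content(ont, tiny_corpus())
  # identity
  m <- match_features("A1", "A1", ont, ic)
  expect_identical(m$exact_count, 1L)
  expect_identical(m$one_level_count, 0L)
  # child of a gene term -> one level
  m2 <- match_features("A1a", "A1", ont, ic)
  expect_identical(m2$exact_count, 0L)
  expect_identical(m2$one_level_count, 1L)
  # grandchild -> nothing
  m3 <- match_features("G", "A1", ont, ic)
  expect_identical(m3$exact_count, 0L)
  expect_identical(m3$one_level_count, 0L)
  # ic cutoffs apply to exact matches only
  m4 <- match_features(c("A1", "G"), c("A1", "G"), ont, ic)
  expect_identical(m4$exact_count, 2L)
  expect_identical(m4$ic2_count, 1L)   # only G has ic >= 2 (ln 8)
  expect_identical(m4$ic4_count, 0L)
  expect_error(match_features("NOPE", "A1", ont, ic), "NOPE")
})

test_that("similarity is a symmetric best-match average with MICA oracle", {
  ont <- tiny_ontology()
  ic <- information_content(ont, tiny_corpus())
  # self-similarity of a singleton is its own IC
  expect_equal(similarity("A1", "A1", ont, ic), unname(ic[["A1"]]))
  # sets sharing only the root score 0
  expect_equal(similarity("A1a", "B1a", ont, ic), 0)
  expect_equal(similarity(c("A1", "G"), "B1a", ont, ic), 0)
  # brute-force MICA over all ancestor pairs
  brute_sim <- function(p_terms, g_terms) {
    mica <- function(a, b) {
      common <- intersect(c(a, brute_ancestors(ont, a)),
                          c(b, brute_ancestors(ont, b)))
      vals <- ic[common][is.finite(ic[common])]
      if (length(vals) == 0) 0 else max(vals)
    }
    m <- outer(p_terms, g_terms, Vectorize(mica))
    dim(m) <- c(length(p_terms), length(g_terms))
    (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
  }
  sets <- list(c("A1", "G"), "A1a", c("A2a", "B1a"), c("D", "G"), "B1")
  for (p in sets) for (g in sets) {
    expect_equal(similarity(p, g, ont, ic), brute_sim(p, g))
    expect_equal(similarity(p, g, ont, ic), similarity(g, p, ont, ic))
  }
  # self-dominance holds for singleton sets (the MICA of a term with any
  # other term is bounded by its own information content); multi-term
  # best-match averages do not carry this guarantee
  singletons <- c("A1", "A1a", "A2a", "B1a", "B1", "G")
  for (s in singletons) for (t in singletons) {
    expect_gte(similarity(s, s, ont, ic) + 1e-12, similarity(s, t, ont, ic))
  }
  # empty gene set scores 0
  expect_equal(similarity("A1", character(0), ont, ic), 0)
})

test_that("profiles combine as a union with obsolete terms dropped", {
  ont <- tiny_ontology()
  p <- combine_profiles(c("A1"), c("A1", "B1"), ont)
  expect_setequal(p$combined, c("A1", "B1"))
  p2 <- combine_profiles(character(0), c("B1", "OBS"), ont)
  expect_setequal(p2$combined, "B1")
  p3 <- combine_profiles(character(0), "B1", ont)
  expect_setequal(p3$combined, "B1")
})

test_that("third-level partition groups terms by anchor with residuals", {
  ont <- tiny_ontology()
  # A1a, G under anchor A1; A2a under A2
  br <- third_level_partition(c("A1a", "G", "A2a"), ont)
  anchors <- vapply(br, `[[`, character(1), "anchor")
  expect_setequal(anchors, c("A1", "A2"))
  expect_setequal(br[[which(anchors == "A1")]]$members, c("A1a", "G"))
  expect_setequal(br[[which(anchors == "A2")]]$members, "A2a")
  # empty set -> no branches
  expect_length(third_level_partition(character(0), ont), 0)
  # diamond term D reaches both A1 and B1 anchors
  br2 <- third_level_partition("D", ont)
  expect_setequal(vapply(br2, `[[`, character(1), "anchor"), c("A1", "B1"))
  # terms above level 3 fall into the residual branch
  br3 <- third_level_partition(c("A", "A1a"), ont)
  anchors3 <- vapply(br3, `[[`, character(1), "anchor")
  expect_true(any(is.na(anchors3)))
  expect_identical(br3[[which(is.na(anchors3))]]$members, "A")
  # coverage: union of branch members equals the input set
  terms <- c("A1a", "G", "A2a", "D", "A")
  all_members <- unique(unlist(lapply(third_level_partition(terms, ont),
                                      `[[`, "members")))
  expect_setequal(all_members, terms)
})

test_that("branch pruning removes exactly the branch and validates input", {
  ont <- tiny_ontology()
  prof <- combine_profiles(c("A1a", "G", "A2a"), character(0), ont)
  br <- third_level_partition(prof$manual, ont)
  anchors <- vapply(br, `[[`, character(1), "anchor")
  pruned <- prune_branch(prof, br[[which(anchors == "A1")]])
  expect_setequal(pruned$manual, "A2a")
  # pruning everything is allowed
  prof2 <- combine_profiles("A2a", character(0), ont)
  br2 <- third_level_partition(prof2$manual, ont)
  expect_length(prune_branch(prof2, br2[[1]])$manual, 0)
  # a branch not derived from the profile errors
  expect_error(prune_branch(prof2, list(anchor = "A1", members = "A1a")),
               "not derived")
  # re-partitioning never recreates the pruned anchor
  for (seed in 1:20) {
    set.seed(seed)
    terms <- sample(setdiff(ont$ids, c("R", "A", "B", "OBS")), 4)
    p <- combine_profiles(terms, character(0), ont)
    brs <- third_level_partition(p$manual, ont)
    brs <- brs[!is.na(vapply(brs, `[[`, character(1), "anchor"))]
    for (b in brs) {
      re <- third_level_partition(prune_branch(p, b)$manual, ont)
      expect_false(b$anchor %in% vapply(re, `[[`, character(1), "anchor"))
    }
  }
})
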