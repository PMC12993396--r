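# Shared fixtures: a small hand-built ontology whose structure is easy to
# reason about, an annotation corpus with round information contents, and a
# cached small simulated cohort for the heavier integration tests.

# Levels:  R (1) -> A, B (2) -> A1, A2, B1 (3) -> A1a, A1b, A2a, B1a (4)
#          -> G (5, child of A1a); D (4) is a diamond child of both A1 and B1.
tiny_ontology <- function() {
  ids <- c("R", "A", "B", "A1", "A2", "B1", "A1a", "A1b", "A2a", "B1a",
           "G", "D", "OBS")
  parents <- list(R = character(0), A = "R", B = "R",
                  A1 = "A", A2 = "A", B1 = "B",
                  A1a = "A1", A1b = "A1", A2a = "A2", B1a = "B1",
                  G = "A1a", D = c("A1", "B1"), OBS = "B")
  obsolete <- stats::setNames(rep(FALSE, length(ids)), ids)
  obsolete[["OBS"]] <- TRUE
  build_ontology(ids, stats::setNames(paste("term", ids), ids), parents,
                 obsolete)
}

# 8-gene corpus: g1..g8. After propagation "A1" sits on 2 genes (ic = ln 4)
# and "G" on 1 (ic = ln 8).
tiny_corpus <- function() {
  list(g1 = c("A1", "G"), g2 = c("A1"), g3 = c("A2a"), g4 = c("B1a"),
       g5 = c("B1"), g6 = c("B1a"), g7 = c("A2"), g8 = c("B"))
}

write_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# cached simulated cohorts so several test files can share one build
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(n_families = 40, seed = 7, ...) {
  key <- paste(n_families, seed, ...)
  if (is.null(sim_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("pgr_sim_", gsub("[^0-9]", "_", key)))
    sim_cache[[key]] <- simulate_cohort(
      sim_config(n_families = n_families, seed = seed, ...), dir)
  }
  sim_cache[[key]]
}

# brute-force ancestor walk used as the independent oracle for information
# content and branch partitions
brute_ancestors <- function(ontology, term) {
  out <- character(0)
  frontier <- ontology$parents[[term]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
  }
  out
}
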