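# Independent clause-by-clause reference implementation of the CFA filter,
# written as explicit per-row if-chains (the production path is vectorized).
# Used as the survivor-set oracle.
naive_cfa_pass <- function(dec) {
  vapply(seq_len(nrow(dec)), function(i) {
    r <- dec[i, ]
    plp <- !is.na(r$clinvar) && r$clinvar %in% c("pathogenic",
                                                 "likely_pathogenic")
    af <- max(ifelse(is.na(r$gnomad_af), 0, r$gnomad_af),
              ifelse(is.na(r$cohort_af), 0, r$cohort_af))
    if (!plp && !is.na(r$distance_to_exon) && r$distance_to_exon > 20)
      return(FALSE)
    if (!plp && !(r$impact_tier %in% c("HIGH", "MODERATE"))) return(FALSE)
    if (af > 0.015) return(FALSE)
    if (!is.na(r$het_count) && r$het_count > 30) return(FALSE)
    if (!is.na(r$hom_count) && r$hom_count > 2) return(FALSE)
    if (!is.na(r$clinvar) && r$clinvar %in% c("benign", "likely_benign"))
      return(FALSE)
    if (!is.na(r$acmg_auto) && r$acmg_auto %in% c("B", "LB")) return(FALSE)
    if (r$structure == "trio" && r$pattern == "unknown") return(FALSE)
    if (is.na(r$depth) || r$depth < 10) return(FALSE)
    if (is.na(r$quality) || r$quality < 20) return(FALSE)
    if (r$structure != "trio") {
      strong <- (!is.na(r$cadd_phred) && r$cadd_phred >= 25) ||
        (!is.na(r$pli) && r$pli >= 0.9) ||
        (!is.na(r$s_het) && r$s_het >= 0.05) ||
        (!is.na(r$spliceai) && r$spliceai >= 0.5)
      if (af > 0.001 || !strong || !(isTRUE(r$phen_overlap) || plp))
        return(FALSE)
    }
    TRUE
  }, logical(1))
}
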