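# Brute-force oracles, kept independent of the package implementations.

GT3 <- c("AA", "AB", "BB")

gt_alleles <- function(gt) strsplit(gt, "")[[1]]

# enumerate-all-models reference for per-SNP disomy evidence
oracle_snp_state <- function(focus, mother, father) {
  if (anyNA(c(focus, mother, father))) return("uninformative")
  fa <- gt_alleles(focus)
  bip <- FALSE
  for (x in gt_alleles(mother)) for (y in gt_alleles(father))
    if (identical(sort(c(x, y)), sort(fa))) bip <- TRUE
  uni <- FALSE
  for (par in c(mother, father)) {
    pa <- gt_alleles(par)
    # isodisomy: two copies of one parental homologue
    for (x in pa) if (identical(sort(c(x, x)), sort(fa))) uni <- TRUE
    # heterodisomy: both parental homologues
    if (identical(sort(pa), sort(fa))) uni <- TRUE
  }
  if (!bip && !uni) return("mendelian_error")
  if (!bip && uni) return(if (focus %in% c("AA", "BB")) "iso_evidence" else "hetero_evidence")
  if (bip && !uni) return("biparental_evidence")
  "uninformative"
}

# enumerate-all-phase-assignments reference for two-variant phasing.
# counts: named integer allele counts (0/1/2, NA = untyped) per member for
# each variant; children of the carrier listed with their other parent.
oracle_phase <- function(child_counts1, child_counts2,
                         other_counts1, other_counts2) {
  trans_of <- function(cnt) if (is.na(cnt)) 0:1 else switch(cnt + 1L, 0L, 0:1, 1L)
  consistent <- function(haps) {
    for (i in seq_along(child_counts1)) {
      ok_child <- FALSE
      for (h in 1:2) {
        t1 <- haps[[h]][1]; t2 <- haps[[h]][2]
        s1_ok <- (child_counts1[i] - t1) %in% trans_of(other_counts1[i])
        s2_ok <- (child_counts2[i] - t2) %in% trans_of(other_counts2[i])
        if (s1_ok && s2_ok) ok_child <- TRUE
      }
      if (!ok_child) return(FALSE)
    }
    TRUE
  }
  fits <- c(
    cis = consistent(list(c(1L, 1L), c(0L, 0L))),
    trans = consistent(list(c(1L, 0L), c(0L, 1L)))
  )
  if (sum(fits) == 1) names(fits)[fits] else "unknown"
}

# one-row genotype table for classifier unit cases
trio_row <- function(focus, gm, gf, pos = 100L) {
  df <- data.frame(snp_id = "s1", chrom = "chr6", pos = pos,
                   mother = focus, grandmother = gm, grandfather = gf,
                   stringsAsFactors = FALSE)
  class(df) <- c("genotype_table", "data.frame")
  df
}
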