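#!/usr/bin/env Rscript
# Interpret the 13 maternal SCMC variants of the fixture: population
# frequency tiers, the frequency-only ACMG tier, the in-silico harmfulness
# consensus, Mendelian segregation (the family-1 anomaly) and two-variant
# phasing (families 3 and 5).
suppressPackageStartupMessages(library(mlidscan))

dir.create("results", showWarnings = FALSE)
fx <- load_table1_fixture()
dv <- fixture_distinct_variants(fx)

tab <- do.call(rbind, lapply(dv, function(v) data.frame(
  gene = v$gene, hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p, rsid = v$rsid,
  af = v$af, tier = classify_af_tier(v), acmg = acmg_frequency_tier(v),
  harmful = harmfulness_consensus(v), stringsAsFactors = FALSE)))
write.table(tab, "results/variant_tiers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "-")
print(tab, row.names = FALSE)
cat(sprintf("\nTiers: %d novel, %d rare, %d common; ACMG: %d VUS, %d benign; harmful: %d/13\n",
            sum(tab$tier == "novel"), sum(tab$tier == "rare"),
            sum(tab$tier == "common"), sum(tab$acmg == "VUS"),
            sum(tab$acmg == "benign"), sum(tab$harmful)))

# family 1: the mother's homozygosity is Mendelian-inconsistent with her
# het/wt parents, the anomaly that prompted SNP-array UPD testing
ped1 <- pedigree_model(data.frame(
  id = c("grandmother", "grandfather", "mother", "father", "proband"),
  mother = c(NA, NA, "grandmother", NA, "mother"),
  father = c(NA, NA, "grandfather", NA, "father"),
  stringsAsFactors = FALSE))
khdc3l <- Filter(function(v) v$gene == "KHDC3L", fx$variants)[[1]]
seg1 <- check_mendelian_segregation(khdc3l, ped1)
cat("\nFamily 1 KHDC3L segregation consistent:", seg1$consistent, "\n")
if (!seg1$consistent) print(seg1$violations, row.names = FALSE)

# families 5 and 3: phase of the rare and common variants in the mother
trio <- pedigree_model(data.frame(
  id = c("mother", "father", "proband"),
  mother = c(NA, NA, "mother"), father = c(NA, NA, "father"),
  stringsAsFactors = FALSE))
fam_variants <- function(fam)
  Filter(function(v) attr(v, "family") == fam, fx$variants)
f5 <- fam_variants(5)
cat("Family 5 rare/common phase:",
    phase_two_variants(f5[[1]], f5[[2]], trio, "mother"), "\n")
f3 <- fam_variants(3)[1:2]   # the two NLRP5 variants; father untyped
cat("Family 3 rare/common phase:",
    phase_two_variants(f3[[1]], f3[[2]], trio, "mother"),
    "(father untyped: paternal transmission of the common variant cannot be excluded)\n")
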