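vrec <- function(af = NA_real_, rsid = if (is.na(af)) "novel" else "rs1",
                 polyphen = "benign", sift = "tolerated", sdm = "destabilizing",
                 genotypes = character()) {
  variant_record(gene = "NLRP5", hgvs_c = "c.1A>G", rsid = rsid, af = af,
                 polyphen = polyphen, sift = sift, sdm = sdm,
                 genotypes = genotypes)
}

test_that("allele-frequency tiers partition novel/rare/common", {
  expect_equal(classify_af_tier(vrec(af = 0.145)), "common")
  expect_equal(classify_af_tier(vrec(af = 8.95e-06)), "rare")
  expect_equal(classify_af_tier(vrec(af = NA_real_)), "novel")
  expect_equal(classify_af_tier(vrec(af = 0)), "rare")     # AF printed as 0 with an rsid
  expect_equal(classify_af_tier(vrec(af = 0.01)), "rare")  # boundary to the reported side
  expect_error(vrec(af = 1.5), "af outside")
  expect_error(variant_record("G", "c.1A>G", rsid = "novel", af = 0.2,
                              polyphen = "benign", sift = "tolerated",
                              sdm = "destabilizing"), "novel")
})

test_that("the frequency-only ACMG tier is benign strictly above 5%", {
  expect_equal(acmg_frequency_tier(vrec(af = 0.145)), "benign")
  expect_equal(acmg_frequency_tier(vrec(af = 0.041)), "VUS")
  expect_equal(acmg_frequency_tier(vrec(af = 0.05)), "VUS")
  expect_equal(acmg_frequency_tier(vrec(af = NA_real_)), "VUS")
})

test_that("harmfulness consensus is a disjunction over the three tools", {
  expect_true(harmfulness_consensus(vrec(polyphen = "benign", sift = "tolerated",
                                         sdm = "destabilizing")))
  expect_true(harmfulness_consensus(vrec(polyphen = "probably_damaging",
                                         sift = "deleterious", sdm = "stabilizing")))
  expect_false(harmfulness_consensus(vrec(polyphen = "benign", sift = "tolerated",
                                          sdm = "stabilizing")))
  expect_error(vrec(polyphen = "awful"), "polyphen")
  v <- vrec()
  v$predictions$sift <- NA
  expect_true(is.na(harmfulness_consensus(v)))
})

test_that("Mendelian segregation flags the homozygote-without-carrier-parents anomaly", {
  trio <- pedigree_model(data.frame(
    id = c("mother", "father", "proband"),
    mother = c(NA, NA, "mother"), father = c(NA, NA, "father"),
    stringsAsFactors = FALSE))
  v <- vrec(genotypes = c(mother = "hom", proband = "het", father = "wt"))
  expect_true(check_mendelian_segregation(v, trio)$consistent)

  ext <- pedigree_model(data.frame(
    id = c("grandmother", "grandfather", "mother"),
    mother = c(NA, NA, "grandmother"), father = c(NA, NA, "grandfather"),
    stringsAsFactors = FALSE))
  v2 <- vrec(genotypes = c(mother = "hom", grandmother = "het", grandfather = "wt"))
  res <- check_mendelian_segregation(v2, ext)
  expect_false(res$consistent)
  expect_equal(res$violations$child, "mother")

  v3 <- vrec(genotypes = c(mother = "wt", father = "wt", proband = "wt"))
  expect_true(check_mendelian_segregation(v3, trio)$consistent)

  # an untyped parent may transmit either allele, so het child stays consistent
  v4 <- vrec(genotypes = c(mother = "wt", proband = "het", father = "missing"))
  expect_true(check_mendelian_segregation(v4, trio)$consistent)
})

test_that("pedigree validation rejects cycles and unknown parents", {
  expect_error(pedigree_model(data.frame(
    id = c("a", "b"), mother = c("b", "a"), father = c(NA, NA),
    stringsAsFactors = FALSE)), "cycle")
  expect_error(pedigree_model(data.frame(
    id = "a", mother = "ghost", father = NA, stringsAsFactors = FALSE)),
    "not in pedigree")
})

trio_ped <- pedigree_model(data.frame(
  id = c("mother", "father", "proband"),
  mother = c(NA, NA, "mother"), father = c(NA, NA, "father"),
  stringsAsFactors = FALSE))

phase_pair <- function(gt1, gt2) {
  v1 <- vrec(af = 0.001, genotypes = gt1)
  v2 <- vrec(af = 0.11, genotypes = gt2)
  phase_two_variants(v1, v2, trio_ped, "mother")
}

test_that("two-variant phasing resolves cis, trans and unknown", {
  # child received only the common variant, father carries neither: trans
  expect_equal(phase_pair(c(mother = "het", proband = "wt", father = "wt"),
                          c(mother = "het", proband = "het", father = "wt")),
               "trans")
  # child received both from the mother: cis
  expect_equal(phase_pair(c(mother = "het", proband = "het", father = "wt"),
                          c(mother = "het", proband = "het", father = "wt")),
               "cis")
  # untyped father could himself have transmitted the variant: unknown
  expect_equal(phase_pair(c(mother = "het", proband = "wt", father = "missing"),
                          c(mother = "het", proband = "het", father = "missing")),
               "unknown")
  expect_error(phase_pair(c(mother = "hom", proband = "wt", father = "wt"),
                          c(mother = "het", proband = "het", father = "wt")),
               "heterozygous")
})

test_that("phasing agrees with brute-force phase enumeration", {
  gts <- c("wt", "het", "hom")
  oth <- c("wt", "het", "hom", "missing")
  cnt <- c(wt = 0L, het = 1L, hom = 2L, missing = NA_integer_)
  combos <- expand.grid(c1 = gts, c2 = gts, f1 = oth, f2 = oth,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    with_combo <- combos[i, ]
    got <- suppressWarnings(phase_pair(
      c(mother = "het", proband = with_combo$c1, father = with_combo$f1),
      c(mother = "het", proband = with_combo$c2, father = with_combo$f2)))
    want <- oracle_phase(cnt[[with_combo$c1]], cnt[[with_combo$c2]],
                         cnt[[with_combo$f1]], cnt[[with_combo$f2]])
    expect_equal(got, want,
                 info = paste(unlist(with_combo), collapse = "/"))
  }
})
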