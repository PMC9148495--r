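test_that("SNP-state classifier matches the exhaustive enumeration oracle", {
  combos <- expand.grid(focus = GT3, gm = GT3, gf = GT3,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    got <- classify_snp_states(
      trio_row(combos$focus[i], combos$gm[i], combos$gf[i]),
      "mother", c("grandmother", "grandfather"))$state
    want <- oracle_snp_state(combos$focus[i], combos$gm[i], combos$gf[i])
    expect_equal(got, want,
                 info = sprintf("focus=%s gm=%s gf=%s", combos$focus[i],
                                combos$gm[i], combos$gf[i]))
  }
  # missing genotypes are uninformative
  expect_equal(classify_snp_states(trio_row(NA, "AA", "AB"), "mother",
                                   c("grandmother", "grandfather"))$state,
               "uninformative")
  expect_equal(classify_snp_states(trio_row("AA", NA, "AB"), "mother",
                                   c("grandmother", "grandfather"))$state,
               "uninformative")
  expect_error(classify_snp_states(trio_row("AA", "AA", "AA"), "mother",
                                   c("granny", "grandfather")),
               "absent")
})

test_that("landmark trio configurations classify as expected", {
  st <- function(f, gm, gf)
    classify_snp_states(trio_row(f, gm, gf), "mother",
                        c("grandmother", "grandfather"))$state
  # both parents could have contributed: uninformative
  expect_equal(st("AB", "AB", "AA"), "uninformative")
  # focus hom for an allele the grandfather lacks: uniparental, homozygous
  expect_equal(st("BB", "AB", "AA"), "iso_evidence")
  # focus carries an allele neither parent has under any disomy model
  expect_equal(st("AA", "BB", "BB"), "mendelian_error")
  # heterozygote that must have one allele from each parent
  expect_equal(st("AB", "AA", "BB"), "biparental_evidence")
})

test_that("segmentation recovers planted iso/hetero/iso structure", {
  plan <- upd_plan("chr6",
                   data.frame(start = c(0, 10e6, 25e6),
                              end = c(10e6, 25e6, 40e6),
                              state = c("isodisomy", "heterodisomy", "isodisomy")))
  gt <- gen_upd_trio_genotypes(plan, 5000, 0.3, seed = 11)
  st <- classify_snp_states(gt, "mother", c("grandmother", "grandfather"))
  seg <- segment_disomy(st)
  truth <- plan$segments$state[findInterval(gt$pos - 1, plan$segments$start)]
  called <- vapply(gt$pos, function(p) {
    h <- which(seg$start_pos <= p & p <= seg$end_pos)
    if (length(h)) seg$state[h[1]] else "uncovered"
  }, "")
  expect_gte(mean(called == truth), 0.95)
  expect_equal(rle(seg$state)$values, c("isodisomy", "heterodisomy", "isodisomy"))
  # segments ordered and non-overlapping
  expect_true(all(seg$start_pos[-1] > seg$end_pos[-nrow(seg)]))
})

test_that("segmentation degenerate inputs behave", {
  plan <- upd_plan("chr2", data.frame(start = 0, end = 1e7, state = "biparental"))
  gt <- gen_upd_trio_genotypes(plan, 1000, 0.3, seed = 5)
  st <- classify_snp_states(gt, "mother", c("grandmother", "grandfather"))
  seg <- segment_disomy(st)
  expect_equal(seg$state, "biparental")
  expect_equal(nrow(seg), 1)

  # a handful of scattered uniparental states below min_support emit no UPD
  st2 <- st
  set.seed(7)
  iso_idx <- sample(which(st2$state == "biparental_evidence"), 5)
  st2$state[iso_idx] <- "iso_evidence"
  st2$focus_het[iso_idx] <- FALSE
  seg2 <- segment_disomy(st2, window = 5, min_fraction = 0.8, min_support = 10)
  expect_false(any(seg2$state %in% c("isodisomy", "heterodisomy")))

  expect_error(segment_disomy(st, window = 0), "window")

  noisy <- st
  noisy$state[seq_len(200)] <- "mendelian_error"
  expect_error(segment_disomy(noisy), "Mendelian-error rate")
})

test_that("parental origin follows the methylated-allele logic", {
  ctl <- gen_dmr_catalog(6, 0, 4, seed = 2)
  # GL01 maternal germline; put it on chr6 for the test
  ctl$chrom[1] <- "chr6"
  ctl$chrom[2:6] <- "chr11"
  calls <- data.frame(
    sample_id = "mo", dmr_name = ctl$name,
    mean = c(1.0, rep(0.5, 5)), z = c(16, rep(0, 5)),
    status = c("hypermethylated", rep("normal", 5)),
    mosaic_fraction = c(1, rep(NA, 5)), stringsAsFactors = FALSE)
  expect_equal(infer_parental_origin_from_methylation(calls, ctl, "chr6"),
               "maternal")

  lost <- calls
  lost$mean[1] <- 0; lost$z[1] <- -16; lost$status[1] <- "hypomethylated"
  expect_equal(infer_parental_origin_from_methylation(lost, ctl, "chr6"),
               "paternal")

  quiet <- calls
  quiet$status[1] <- "normal"
  expect_equal(infer_parental_origin_from_methylation(quiet, ctl, "chr6"),
               "inconclusive")

  # antisymmetry: relabeling the methylated parental allele flips the call
  flipped <- ctl
  flipped$methylated_allele[1] <- "paternal"
  expect_equal(infer_parental_origin_from_methylation(calls, flipped, "chr6"),
               "paternal")

  # a disturbed off-chromosome background withdraws the conclusion
  messy <- calls
  messy$status[2:6] <- "hypomethylated"
  expect_equal(infer_parental_origin_from_methylation(messy, ctl, "chr6"),
               "inconclusive")
})

test_that("variant position lookup reports the overlapping disomy state", {
  seg <- data.frame(chrom = "chr6",
                    start_pos = c(1, 1e6 + 1, 2e6 + 1),
                    end_pos = c(1e6, 2e6, 3e6),
                    state = c("isodisomy", "biparental", "heterodisomy"),
                    n_support = c(50, 60, 70), stringsAsFactors = FALSE)
  hit <- locate_variant_in_segments(5e5, seg)
  expect_equal(hit$state, "isodisomy")
  expect_true(hit$homozygosity_explained)

  bip <- locate_variant_in_segments(1.5e6, seg)
  expect_equal(bip$state, "biparental")
  expect_false(bip$homozygosity_explained)

  gap <- locate_variant_in_segments(9e6, seg)
  expect_equal(gap$state, "uncovered")
})

test_that("BED export converts to 0-based half-open coordinates", {
  seg <- data.frame(chrom = "chr6", start_pos = 101, end_pos = 200,
                    state = "isodisomy", n_support = 10, stringsAsFactors = FALSE)
  bed <- segments_to_bed(seg)
  expect_equal(bed$start, 100)
  expect_equal(bed$end, 200)
})
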