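make_means <- function(...) {
  # dmr -> named vector of sample means
  vals <- list(...)
  do.call(rbind, lapply(names(vals), function(d) {
    data.frame(sample_id = names(vals[[d]]), dmr_name = d,
               mean = unname(vals[[d]]), n_probes = 4L,
               stringsAsFactors = FALSE)
  }))
}

make_ref <- function(dmr, mu, sigma, n = 12L) {
  out <- data.frame(dmr_name = dmr, mu = mu, sigma = sigma, n_controls = n,
                    degenerate = sigma < 1e-6, stringsAsFactors = FALSE)
  class(out) <- c("control_reference", "data.frame")
  out
}

test_that("region means are unweighted means over non-missing probes", {
  ctl <- gen_dmr_catalog(1, 0, 4, seed = 1)
  B <- matrix(c(0.4, 0.5, 0.6, 0.5), ncol = 1,
              dimnames = list(ctl$probe_ids[[1]], "s1"))
  expect_equal(summarize_dmr(B, ctl)$mean, 0.5)

  B[2, 1] <- NA
  out <- summarize_dmr(B, ctl)
  expect_equal(out$mean, 0.5)
  expect_equal(out$n_probes, 3L)

  B[, 1] <- NA
  out <- summarize_dmr(B, ctl)
  expect_true(is.na(out$mean))
  expect_equal(out$n_probes, 0L)
})

test_that("region means equal a brute-force loop on a random matrix", {
  ctl <- gen_dmr_catalog(5, 0, 6, seed = 13)
  cfg <- sim_config(seed = 14, n_controls = 7)
  B <- gen_control_betas(ctl, cfg)
  B[sample(length(B), 20)] <- NA  # seeded upstream by the generator call
  got <- summarize_dmr(B, ctl)
  for (i in seq_len(nrow(got))) {
    probes <- ctl$probe_ids[[which(ctl$name == got$dmr_name[i])]]
    acc <- c()
    for (p in probes) {
      v <- B[p, got$sample_id[i]]
      if (!is.na(v)) acc <- c(acc, v)
    }
    expect_equal(got$mean[i], mean(acc))
  }
})

test_that("control reference uses the n-1 SD and flags degeneracy", {
  means <- make_means(D1 = c(c1 = 0.48, c2 = 0.52))
  man <- sample_manifest(c("c1", "c2"), c("control", "control"))
  ref <- fit_control_reference(means, man)
  expect_equal(ref$mu, 0.50)
  expect_equal(ref$sigma, sd(c(0.48, 0.52)))  # 0.02828..., n-1 denominator
  expect_equal(ref$n_controls, 2L)
  expect_false(ref$degenerate)

  flat <- make_means(D1 = c(c1 = 0.5, c2 = 0.5, c3 = 0.5))
  manf <- sample_manifest(c("c1", "c2", "c3"), rep("control", 3))
  expect_warning(reff <- fit_control_reference(flat, manf), "degenerate")
  expect_true(reff$degenerate)

  expect_error(fit_control_reference(means, sample_manifest("c1", "control")),
               "2 control")
})

test_that("simulated control cohorts recover the baseline", {
  ctl <- gen_dmr_catalog(3, 0, 8, seed = 21)
  cfg <- sim_config(seed = 22, n_controls = 100, probe_noise_sd = 0.03)
  B <- gen_control_betas(ctl, cfg)
  man <- sample_manifest(colnames(B), rep("control", ncol(B)))
  ref <- fit_control_reference(summarize_dmr(B, ctl), man)
  expect_true(all(abs(ref$mu - 0.5) < 0.01))
})

test_that("the 3-SD rule calls direction from the signed z", {
  ref <- make_ref("D1", 0.50, 0.03)
  hi <- call_dmr_status(make_means(D1 = c(p = 1.00)), ref)
  expect_equal(hi$z, (1 - 0.5) / 0.03)             # ~16.7
  expect_equal(hi$status, "hypermethylated")

  mid <- call_dmr_status(make_means(D1 = c(p = 0.50)), ref)
  expect_equal(mid$z, 0)
  expect_equal(mid$status, "normal")

  lo <- call_dmr_status(make_means(D1 = c(p = 0.35)), make_ref("D1", 0.50, 0.04))
  expect_equal(lo$z, -3.75)
  expect_equal(lo$status, "hypomethylated")

  expect_error(call_dmr_status(make_means(D1 = c(p = 0.5)), ref, k = 0), "k must")
  expect_warning(call_dmr_status(make_means(D1 = c(p = 0.5)),
                                 make_ref("D1", 0.5, 0)), "degenerate")
})

test_that("negating the deviation flips hypo/hyper with |z| preserved", {
  ref <- make_ref("D1", 0.45, 0.025)
  for (delta in c(0.08, 0.12, 0.2, 0.3)) {
    up <- call_dmr_status(make_means(D1 = c(p = 0.45 + delta)), ref)
    dn <- call_dmr_status(make_means(D1 = c(p = 0.45 - delta)), ref)
    expect_equal(up$z, -dn$z)
    expect_equal(up$status, "hypermethylated")
    expect_equal(dn$status, "hypomethylated")
  }
})

test_that("raising k never converts a normal call to altered", {
  ref <- make_ref("D1", 0.5, 0.03)
  means <- make_means(D1 = c(a = 0.4, b = 0.45, c = 0.48, d = 0.5, e = 0.62))
  ks <- c(1, 2, 3, 4, 6)
  prev_altered <- NULL
  for (k in ks) {
    st <- call_dmr_status(means, ref, k = k)
    altered <- st$sample_id[st$status != "normal"]
    if (!is.null(prev_altered)) expect_true(all(altered %in% prev_altered))
    prev_altered <- altered
  }
})

test_that("mosaic fraction inverts the generator's shift formulas", {
  ref <- make_ref("D1", 0.5, 0.02)
  gone <- call_dmr_status(make_means(D1 = c(p = 0.0)), ref)
  expect_equal(gone$mosaic_fraction, 1.0)
  expect_equal(estimate_mosaic_fraction(gone, ref), 1.0)

  part <- call_dmr_status(make_means(D1 = c(p = 0.30)), ref)
  expect_equal(estimate_mosaic_fraction(part, ref), 0.40)

  gain <- call_dmr_status(make_means(D1 = c(p = 0.80)), ref)
  expect_equal(estimate_mosaic_fraction(gain, ref), 0.60)

  normal <- call_dmr_status(make_means(D1 = c(p = 0.50)), ref)
  expect_error(estimate_mosaic_fraction(normal, ref), "undefined")
})

test_that("direction and mosaic fraction round-trip through simulation", {
  ctl <- gen_dmr_catalog(2, 0, 8, seed = 31)
  for (dir in c("hypo", "hyper")) {
    m_hat <- vapply(1:5, function(r) {
      cfg <- sim_config(seed = 100 + r, n_controls = 12, probe_noise_sd = 0.03)
      B <- gen_control_betas(ctl, cfg)
      C <- gen_case_betas(ctl, cfg, list(case = list(epimutation("GL01", dir, 0.6))))
      means <- summarize_dmr(cbind(B, C), ctl)
      man <- sample_manifest(c(colnames(B), "case"),
                             c(rep("control", 12), "case"),
                             c(rep(NA, 12), "BWS"))
      ref <- fit_control_reference(means, man)
      st <- call_dmr_status(means[means$sample_id == "case", ], ref)
      row <- st[st$dmr_name == "GL01", ]
      expect_equal(row$status,
                   if (dir == "hypo") "hypomethylated" else "hypermethylated")
      row$mosaic_fraction
    }, 0)
    expect_lt(abs(mean(m_hat) - 0.6), 0.05)
  }
})

test_that("the MLID rule needs the diagnostic DMR plus one more germline DMR", {
  ctl <- gen_dmr_catalog(3, 1, 4, seed = 1)  # GL01 = BWS diagnostic
  calls <- data.frame(
    sample_id = "p", dmr_name = c("GL01", "GL02", "GL03", "SC01"),
    mean = c(0.1, 0.1, 0.5, 0.9), z = c(-9, -9, 0, 9),
    status = c("hypomethylated", "hypomethylated", "normal", "hypermethylated"),
    mosaic_fraction = c(0.8, 0.8, NA, 0.8), stringsAsFactors = FALSE)
  res <- call_mlid(calls, ctl, "BWS")
  expect_true(res$is_mlid)
  expect_setequal(res$altered_germline_dmrs, c("GL01", "GL02"))
  expect_equal(res$altered_secondary_dmrs, "SC01")

  only_diag <- calls
  only_diag$status[2] <- "normal"
  expect_false(call_mlid(only_diag, ctl, "BWS")$is_mlid)

  # secondary alterations never count toward the rule
  sec_only <- calls
  sec_only$status[2] <- "normal"
  expect_false(call_mlid(sec_only, ctl, "BWS")$is_mlid)

  # altered elsewhere but normal diagnostic DMR is not MLID
  no_diag <- calls
  no_diag$status[1] <- "normal"
  expect_false(call_mlid(no_diag, ctl, "BWS")$is_mlid)

  no_cat <- ctl[ctl$diagnostic_for != "PHP1B", ]
  expect_error(call_mlid(calls, no_cat, "PHP1B"), "diagnostic")
})

test_that("the MLID rule applies to reported locus status lists", {
  pos <- list(hypo = c("KCNQ1OT1", "PLAGL1"), hyper = character())
  expect_true(call_mlid_from_status_lists(pos, "BWS")$is_mlid)

  diag_only <- list(hypo = "KCNQ1OT1", hyper = character())
  expect_false(call_mlid_from_status_lists(diag_only, "BWS")$is_mlid)

  # a secondary DMR as the only companion does not qualify
  with_sec <- list(hypo = "KCNQ1OT1", hyper = "GNAS-NESP")
  expect_false(call_mlid_from_status_lists(with_sec, "BWS")$is_mlid)

  php <- list(hypo = c("GNAS A/B", "PEG13"), hyper = character())
  expect_true(call_mlid_from_status_lists(php, "PHP1B")$is_mlid)
})
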