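#' Region-average methylation
#'
#' The unweighted mean of the non-missing probe betas of each DMR, per
#' sample. A sample whose probes are all missing for a DMR gets an NA mean
#' with `n_probes = 0` (flagged, not an error).
#'
#' @param betas probes x samples beta matrix.
#' @param catalog a `dmr_catalog`, already coverage-filtered
#'   (see [filter_low_coverage_dmrs()]).
#' @return long data.frame: sample_id, dmr_name, mean, n_probes.
#' @export
summarize_dmr <- function(betas, catalog) {
  samples <- colnames(betas)
  out <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    p <- intersect(catalog$probe_ids[[i]], rownames(betas))
    sub <- betas[p, , drop = FALSE]
    data.frame(
      sample_id = samples,
      dmr_name = catalog$name[i],
      mean = colMeans(sub, na.rm = TRUE),
      n_probes = colSums(!is.na(sub)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  out$mean[out$n_probes == 0L] <- NA_real_
  out
}

#' Control reference statistics
#'
#' Per-DMR sample mean and sample SD (n - 1 denominator, appropriate for the
#' small control cohorts typical of this assay) of the region means over the
#' control samples. A zero SD is flagged as degenerate rather than dropped.
#'
#' @param region_means output of [summarize_dmr()].
#' @param manifest a [sample_manifest()]; at least 2 controls required.
#' @return `control_reference` data.frame: dmr_name, mu, sigma, n_controls,
#'   degenerate.
#' @export
fit_control_reference <- function(region_means, manifest) {
  ctrl <- manifest$sample_id[manifest$role == "control"]
  if (length(ctrl) < 2) stop("at least 2 control samples are required")
  rm_c <- region_means[region_means$sample_id %in% ctrl, ]
  sp <- split(rm_c$mean, rm_c$dmr_name)
  out <- data.frame(
    dmr_name = names(sp),
    mu = vapply(sp, function(x) mean(x, na.rm = TRUE), 0),
    sigma = vapply(sp, function(x) stats::sd(x, na.rm = TRUE), 0),
    n_controls = vapply(sp, function(x) sum(!is.na(x)), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$degenerate <- out$sigma < 1e-6
  if (any(out$degenerate))
    warning("degenerate control SD (< 1e-6) at: ",
            paste(out$dmr_name[out$degenerate], collapse = ", "))
  class(out) <- c("control_reference", "data.frame")
  out
}

#' Call hypo/hypermethylation against the control reference
#'
#' Computes z = (region mean - mu_c) / sigma_c per sample and DMR and calls a
#' DMR altered when |z| meets the threshold k (default 3, the
#' three-standard-deviations rule), two-sided: z <= -k is hypomethylated,
#' z >= k hypermethylated, otherwise normal. Degenerate-reference DMRs emit
#' no call (warned). For altered calls the mosaic fraction is estimated (see
#' [estimate_mosaic_fraction()]).
#'
#' @param region_means output of [summarize_dmr()] (any subset of samples).
#' @param ref a `control_reference`.
#' @param k positive z threshold (default 3).
#' @return data.frame: sample_id, dmr_name, mean, z, status,
#'   mosaic_fraction (NA for normal calls).
#' @export
call_dmr_status <- function(region_means, ref, k = 3) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be a positive number")
  usable <- ref[!ref$degenerate, ]
  if (nrow(usable) < nrow(ref))
    warning("no calls for degenerate-reference DMRs: ",
            paste(setdiff(ref$dmr_name, usable$dmr_name), collapse = ", "))
  df <- merge(region_means, usable[, c("dmr_name", "mu", "sigma")],
              by = "dmr_name", sort = FALSE)
  df$z <- (df$mean - df$mu) / df$sigma
  df$status <- rep("normal", nrow(df))
  df$status[df$z <= -k] <- "hypomethylated"
  df$status[df$z >= k] <- "hypermethylated"
  df$status[is.na(df$z)] <- NA_character_
  df$mosaic_fraction <- rep(NA_real_, nrow(df))
  hypo <- which(df$status == "hypomethylated")
  hyper <- which(df$status == "hypermethylated")
  df$mosaic_fraction[hypo] <- pmin(1, pmax(0, (df$mu[hypo] - df$mean[hypo]) / df$mu[hypo]))
  df$mosaic_fraction[hyper] <- pmin(1, pmax(0, (df$mean[hyper] - df$mu[hyper]) / (1 - df$mu[hyper])))
  out <- df[, c("sample_id", "dmr_name", "mean", "z", "status", "mosaic_fraction")]
  rownames(out) <- NULL
  out
}

#' Mosaic-fraction estimate for an altered DMR
#'
#' Model-based estimator under a two-allele 0/0.5/1 methylation model: a
#' fraction m of cells carrying the epimutation shifts the expected beta
#' from mu to mu(1 - m) (loss) or mu + (1 - mu)m (gain), so
#' m-hat = (mu - beta) / mu for hypomethylation and
#' (beta - mu) / (1 - mu) for hypermethylation, clamped to \[0, 1\].
#' Undefined (error) for a normal-status call.
#'
#' @param call one row of [call_dmr_status()] output (or any list with
#'   `mean`, `dmr_name`, `status`).
#' @param ref a `control_reference`.
#' @return mosaic fraction in \[0, 1\].
#' @export
estimate_mosaic_fraction <- function(call, ref) {
  status <- call$status
  if (is.na(status) || status == "normal")
    stop("mosaic fraction is undefined for a normal call")
  i <- match(call$dmr_name, ref$dmr_name)
  mu <- ref$mu[i]
  m <- if (status == "hypomethylated") (mu - call$mean) / mu
       else (call$mean - mu) / (1 - mu)
  min(1, max(0, m))
}

#' The MLID decision rule
#'
#' A proband has multi-locus imprinting disturbance when the DMR diagnostic
#' for their disorder (KCNQ1OT1:TSS-DMR for BWS, GNAS A/B:TSS-DMR for PHP1B)
#' is altered and at least one additional germline DMR is altered.
#' Secondary-DMR alterations are reported but never count toward the rule.
#'
#' @param calls [call_dmr_status()] rows for one proband.
#' @param catalog a `dmr_catalog` carrying `class` and `diagnostic_for`; must
#'   contain the disorder's diagnostic DMR.
#' @param disorder "BWS" or "PHP1B".
#' @return list of class `mlid_result`: proband_id, disorder,
#'   diagnostic_dmr, diagnostic_status, altered_germline_dmrs,
#'   altered_secondary_dmrs, is_mlid.
#' @export
call_mlid <- function(calls, catalog, disorder = c("BWS", "PHP1B")) {
  disorder <- match.arg(disorder)
  proband <- unique(calls$sample_id)
  if (length(proband) != 1)
    stop("call_mlid expects the calls of exactly one proband")
  diag_dmr <- catalog$name[catalog$diagnostic_for == disorder]
  if (length(diag_dmr) != 1)
    stop("catalog must contain exactly one ", disorder, "-diagnostic DMR")
  altered <- calls[!is.na(calls$status) & calls$status != "normal", ]
  cls <- catalog$class[match(altered$dmr_name, catalog$name)]
  germ <- altered$dmr_name[cls == "germline"]
  sec <- altered$dmr_name[cls == "secondary"]
  diag_status <- calls$status[calls$dmr_name == diag_dmr]
  diag_status <- if (length(diag_status)) diag_status[1] else NA_character_
  structure(list(
    proband_id = proband, disorder = disorder,
    diagnostic_dmr = diag_dmr, diagnostic_status = diag_status,
    altered_germline_dmrs = germ, altered_secondary_dmrs = sec,
    is_mlid = (diag_dmr %in% germ) && length(setdiff(germ, diag_dmr)) >= 1
  ), class = "mlid_result")
}

#' MLID rule on reported locus status lists
#'
#' Applies the diagnostic-plus-one rule directly to hypo/hypermethylated
#' locus-token lists (as reported in clinical summary tables), classifying
#' tokens with the imprinted-locus vocabulary instead of a simulated
#' catalog.
#'
#' @param status a `list(hypo = ..., hyper = ...)` of locus tokens.
#' @param disorder "BWS" or "PHP1B".
#' @param proband_id label for the result.
#' @param vocab locus vocabulary, default [imprinted_locus_table()].
#' @return `mlid_result` (see [call_mlid()]).
#' @export
call_mlid_from_status_lists <- function(status, disorder = c("BWS", "PHP1B"),
                                        proband_id = "proband",
                                        vocab = imprinted_locus_table()) {
  disorder <- match.arg(disorder)
  diag_dmr <- vocab$locus[vocab$diagnostic_for == disorder]
  altered <- normalize_locus(c(status$hypo, status$hyper))
  cls <- vocab$class[match(altered, vocab$locus)]
  if (anyNA(cls))
    warning("locus tokens missing from vocabulary: ",
            paste(altered[is.na(cls)], collapse = ", "))
  germ <- altered[!is.na(cls) & cls == "germline"]
  sec <- altered[!is.na(cls) & cls == "secondary"]
  diag_status <- if (diag_dmr %in% normalize_locus(status$hypo)) "hypomethylated"
                 else if (diag_dmr %in% normalize_locus(status$hyper)) "hypermethylated"
                 else "normal"
  structure(list(
    proband_id = proband_id, disorder = disorder,
    diagnostic_dmr = diag_dmr, diagnostic_status = diag_status,
    altered_germline_dmrs = germ, altered_secondary_dmrs = sec,
    is_mlid = (diag_dmr %in% germ) && length(setdiff(germ, diag_dmr)) >= 1
  ), class = "mlid_result")
}

#' @export
print.mlid_result <- function(x, ...) {
  cat(sprintf("MLID result for %s (%s)\n", x$proband_id, x$disorder))
  cat(sprintf("  diagnostic DMR %s: %s\n", x$diagnostic_dmr, x$diagnostic_status))
  cat("  altered germline DMRs:",
      if (length(x$altered_germline_dmrs)) paste(x$altered_germline_dmrs, collapse = ", ") else "none", "\n")
  cat("  altered secondary DMRs:",
      if (length(x$altered_secondary_dmrs)) paste(x$altered_secondary_dmrs, collapse = ", ") else "none", "\n")
  cat("  MLID:", if (x$is_mlid) "yes" else "no", "\n")
  invisible(x)
}
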