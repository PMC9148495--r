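#' Run configuration for the end-to-end pipeline
#'
#' @param betas path to a beta-matrix TSV, or a probes x samples matrix.
#' @param catalog path to a DMR-catalog TSV, or a `dmr_catalog`.
#' @param manifest path to a manifest TSV (sample_id, role, disorder), or a
#'   [sample_manifest()].
#' @param k z threshold for the methylation caller (default 3).
#' @param min_probes DMR coverage filter threshold (default 4).
#' @param seed integer seed recorded in the report.
#' @param out_dir output directory for the report bundle, or NULL to skip
#'   writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(betas, catalog, manifest, k = 3, min_probes = 4L,
                       seed = 1L, out_dir = NULL) {
  stopifnot(k > 0, min_probes >= 1)
  structure(list(betas = betas, catalog = catalog, manifest = manifest,
                 k = k, min_probes = min_probes, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

resolve_input <- function(x, reader, what) {
  if (is.character(x)) {
    if (!file.exists(x)) stop(what, " file not found: ", x)
    reader(x)
  } else x
}

#' Run the MLID-calling pipeline end to end
#'
#' Coverage filter, region means, control reference, 3-SD calls and the MLID
#' verdict per case sample, in order; writes a deterministic JSON report and
#' a calls TSV when the config names an output directory.
#'
#' @param cfg a [run_config()].
#' @return list: config echo, reference, calls (data.frame), mlid (list of
#'   `mlid_result`), report_path (NULL unless written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  betas <- resolve_input(cfg$betas, read_beta_matrix, "beta matrix")
  catalog <- resolve_input(cfg$catalog, read_dmr_catalog, "DMR catalog")
  manifest <- cfg$manifest
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest file not found: ", manifest)
    df <- utils::read.delim(manifest, stringsAsFactors = FALSE, na.strings = ".")
    manifest <- sample_manifest(df$sample_id, df$role, df$disorder)
  }
  missing_samples <- setdiff(manifest$sample_id, colnames(betas))
  if (length(missing_samples))
    stop("manifest samples absent from beta matrix: ",
         paste(missing_samples, collapse = ", "))

  catalog <- filter_low_coverage_dmrs(catalog, betas, cfg$min_probes)
  means <- summarize_dmr(betas, catalog)
  ref <- fit_control_reference(means, manifest)
  cases <- manifest[manifest$role == "case", ]
  case_means <- means[means$sample_id %in% cases$sample_id, ]
  calls <- call_dmr_status(case_means, ref, k = cfg$k)
  mlid <- lapply(seq_len(nrow(cases)), function(i) {
    call_mlid(calls[calls$sample_id == cases$sample_id[i], ], catalog,
              cases$disorder[i])
  })
  names(mlid) <- cases$sample_id

  results <- list(
    parameters = list(k = cfg$k, min_probes = cfg$min_probes, seed = cfg$seed),
    n_dmrs = nrow(catalog), n_controls = sum(manifest$role == "control"),
    reference = ref, calls = calls,
    mlid = lapply(mlid, unclass)
  )
  report_path <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(calls, file.path(cfg$out_dir, "dmr_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    report_path <- write_report(results, file.path(cfg$out_dir, "mlid_report.json"))
  }
  list(config = cfg, reference = ref, calls = calls, mlid = mlid,
       report_path = report_path)
}

canonicalize <- function(x) {
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    return(lapply(x, canonicalize))
  }
  if (is.double(x)) return(round(x, 4))
  x
}

#' Write a deterministic JSON report
#'
#' Serialization is canonical - keys sorted, doubles rounded to 4 decimals -
#' so identical results give byte-identical files, which keeps reports
#' diff-able.
#'
#' @param results named list (data.frames allowed).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(results, path) {
  json <- jsonlite::toJSON(canonicalize(results), auto_unbox = TRUE,
                           pretty = TRUE, null = "null", na = "null",
                           digits = NA)
  writeLines(json, path)
  invisible(path)
}
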