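#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids, a `probe_id` first column, and numeric
#' beta values in \[0, 1\]. Blank cells or "." are missing values; anything
#' else non-numeric, any value outside \[0, 1\], and duplicate probe or
#' sample ids are errors naming the offending probe/sample.
#'
#' @param path TSV file path.
#' @return numeric matrix, probes in rows, samples in columns.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = c("", "."))
  if (names(df)[1] != "probe_id") stop("first column must be 'probe_id'")
  probes <- df[[1]]
  samples <- names(df)[-1]
  if (anyDuplicated(probes)) stop("duplicate probe ids: ",
                                  paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(samples)) stop("duplicate sample ids: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad))
      stop("non-numeric beta value '", raw[bad[1]], "' at probe ",
           probes[bad[1]], ", sample ", samples[j])
    out_of_range <- which(!is.na(val) & (val < 0 | val > 1))
    if (length(out_of_range))
      stop("beta value ", val[out_of_range[1]], " outside [0,1] at probe ",
           probes[out_of_range[1]], ", sample ", samples[j])
    m[, j] <- val
  }
  m
}

#' Write a beta-value matrix to TSV
#' @param betas probes x samples numeric matrix.
#' @param path output path. Missing values are written as ".".
#' @export
write_beta_matrix <- function(betas, path) {
  df <- data.frame(probe_id = rownames(betas), betas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Write / read a DMR catalog as TSV
#'
#' Columns: chrom, start, end (0-based half-open), name, class,
#' methylated_allele, diagnostic_for, coupled_germline, probe_ids
#' (comma-joined).
#'
#' @param catalog a `dmr_catalog` data.frame.
#' @param path file path.
#' @export
write_dmr_catalog <- function(catalog, path) {
  df <- catalog
  df$probe_ids <- vapply(catalog$probe_ids, paste, "", collapse = ",")
  class(df) <- "data.frame"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_dmr_catalog
#' @export
read_dmr_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  df$probe_ids <- strsplit(df$probe_ids, ",", fixed = TRUE)
  if (anyDuplicated(df$name)) stop("duplicate DMR names in catalog")
  class(df) <- c("dmr_catalog", "data.frame")
  df
}

#' Write / read a genotype table as TSV
#' @param genotypes a `genotype_table` data.frame (snp_id, chrom, pos, one
#'   column per pedigree member).
#' @param path file path.
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on ", ch)
  }
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Sample manifest
#'
#' Assigns every sample a role: "control", or "case" with a disorder.
#'
#' @param sample_id character vector.
#' @param role "control" or "case" per sample.
#' @param disorder "BWS"/"PHP1B" for cases, NA for controls.
#' @return `sample_manifest` data.frame.
#' @export
sample_manifest <- function(sample_id, role, disorder = NA_character_) {
  stopifnot(length(role) == length(sample_id),
            all(role %in% c("control", "case")))
  disorder <- rep_len(disorder, length(sample_id))
  if (any(role == "case" & !disorder %in% c("BWS", "PHP1B")))
    stop("every case sample needs a disorder (BWS or PHP1B)")
  out <- data.frame(sample_id = sample_id, role = role, disorder = disorder,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_manifest", "data.frame")
  out
}

#' Drop DMRs with low probe coverage
#'
#' Retains exactly the catalog entries whose probes present in the beta
#' matrix (with at least one non-missing value) number at least
#' `min_probes`; the published analysis removed imprinted DMRs covered by
#' fewer than 4 probes. Removals are reported via message; an empty result
#' is legal but warned.
#'
#' @param catalog a `dmr_catalog`.
#' @param betas probes x samples beta matrix.
#' @param min_probes minimum probe count to keep a DMR (>= 1; default 4).
#' @return the filtered catalog.
#' @export
filter_low_coverage_dmrs <- function(catalog, betas, min_probes = 4L) {
  stopifnot(min_probes >= 1)
  counts <- vapply(catalog$probe_ids, function(p) {
    p <- intersect(p, rownames(betas))
    if (!length(p)) return(0L)
    sum(rowSums(!is.na(betas[p, , drop = FALSE])) > 0L)
  }, integer(1))
  keep <- counts >= min_probes
  for (i in which(!keep))
    message("dropping DMR ", catalog$name[i], ": ", counts[i],
            " probe(s) < ", min_probes)
  out <- catalog[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no DMR passes the coverage filter")
  out
}
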