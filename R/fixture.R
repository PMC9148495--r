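#' Load the packaged cohort fixture
#'
#' The fixture transcribes the published summary table of the ten-family
#' MLID cohort: per-proband hypo/hypermethylated locus lists, clinical
#' feature lists with the printed BWS scores where given, and the 13 distinct
#' maternal SCMC variants (15 family-occurrences; two common variants recur
#' in two families each) with population allele frequency, in-silico
#' prediction labels and per-member genotypes. Family 1 additionally carries
#' the maternal-grandparental genotypes established by the segregation
#' analysis. Locus tokens are normalized via [normalize_locus()] on load.
#'
#' @param path fixture JSON path; defaults to the packaged fixture. A
#'   sidecar `<path>.md5` file must hold the file's checksum; a mismatch
#'   (corrupted or hand-edited fixture) is fatal.
#' @return list with components:
#'   \describe{
#'     \item{probands}{data.frame: family, proband_id, sex, age, disorder,
#'       bws_score (NA where not printed).}
#'     \item{variants}{list of [variant_record()] objects, one per
#'       family-occurrence (15), each with a `family` attribute.}
#'     \item{status_lists}{named list (by proband_id) of
#'       `list(hypo = ..., hyper = ...)` locus-token vectors.}
#'     \item{clinical}{named list (by proband_id) of
#'       `list(features = ..., bws_score = ...)`.}
#'   }
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_fixture.json", package = "mlidscan",
                        mustWork = TRUE)
  md5_path <- paste0(path, ".md5")
  expected <- readLines(md5_path, warn = FALSE)[1]
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, expected))
    stop("cohort fixture failed its integrity check (md5 ", actual,
         ", expected ", expected, ")")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  probands <- do.call(rbind, lapply(raw$probands, function(p) {
    data.frame(family = p$family, proband_id = p$proband_id, sex = p$sex,
               age = p$age, disorder = p$disorder,
               bws_score = if (is.null(p$bws_score)) NA_integer_ else p$bws_score,
               stringsAsFactors = FALSE)
  }))

  status_lists <- lapply(raw$probands, function(p) {
    list(hypo = normalize_locus(unlist(p$hypomethylated, use.names = FALSE)),
         hyper = normalize_locus(as.character(unlist(p$hypermethylated, use.names = FALSE))))
  })
  names(status_lists) <- probands$proband_id

  clinical <- lapply(raw$probands, function(p) {
    list(features = unlist(p$clinical_features, use.names = FALSE),
         bws_score = if (is.null(p$bws_score)) NA_integer_ else p$bws_score)
  })
  names(clinical) <- probands$proband_id

  variants <- lapply(raw$variants, function(v) {
    rec <- variant_record(
      gene = v$gene, hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p, rsid = v$rsid,
      af = if (is.null(v$af)) NA_real_ else v$af,
      gf = if (is.null(v$gf)) NA_real_ else v$gf,
      polyphen = v$predictions$polyphen, sift = v$predictions$sift,
      sdm = v$predictions$sdm,
      genotypes = unlist(v$genotypes)
    )
    attr(rec, "family") <- v$family
    rec
  })

  list(probands = probands, variants = variants,
       status_lists = status_lists, clinical = clinical)
}

#' Distinct variants of the fixture
#'
#' Collapses the per-family variant occurrences to distinct variants, keyed
#' by gene + cDNA change (the two recurrent common variants are counted
#' once).
#'
#' @param fixture output of [load_table1_fixture()].
#' @return list of [variant_record()] objects (13 on the packaged fixture).
#' @export
fixture_distinct_variants <- function(fixture) {
  key <- vapply(fixture$variants, function(v) paste(v$gene, v$hgvs_c), "")
  fixture$variants[!duplicated(key)]
}
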