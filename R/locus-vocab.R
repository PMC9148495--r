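#' Normalize imprinted-locus tokens
#'
#' Locus names in clinical reports are free text and the same DMR is often
#' spelled in more than one way (notably "GNAS-AS" vs "GNAS-AS1", which name
#' the same antisense DMR). Tokens are trimmed, internal whitespace collapsed,
#' and known spelling variants mapped to a single canonical token so that
#' cohort counts aggregate correctly.
#'
#' @param tokens character vector of locus names.
#' @return character vector of canonical tokens, same length.
#' @examples
#' normalize_locus(c("GNAS-AS", " GNAS A/B ", "PLAGL1"))
#' @export
normalize_locus <- function(tokens) {
  stopifnot(is.character(tokens))
  x <- gsub("\\s+", " ", trimws(tokens))
  synonyms <- c(
    "GNAS-AS"   = "GNAS-AS1",
    "GNAS-XLAS" = "GNAS-XLas",
    "NHP2L1"    = "SNU13"
  )
  hit <- match(toupper(x), toupper(names(synonyms)))
  x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  x
}

#' Imprinted-locus vocabulary
#'
#' Classification of the locus tokens used in the cohort analyses: whether a
#' DMR acquires methylation in the germline or post-zygotically (secondary),
#' and which parental allele is methylated. Secondary paternally methylated
#' DMRs (GNAS-NESP, ZNF597, ZDBF2/GPR1) sit under the control of a maternally
#' methylated germline DMR and are the ones expected to gain methylation when
#' their controller loses it.
#'
#' @return data.frame with columns `locus`, `class` ("germline"/"secondary"),
#'   `methylated_allele` ("maternal"/"paternal"), `diagnostic_for`
#'   ("BWS"/"PHP1B"/"none") and `chrom`.
#' @export
imprinted_locus_table <- function() {
  tab <- rbind(
    c("KCNQ1OT1",    "germline",  "maternal", "BWS",   "chr11"),
    c("H19/IGF2",    "germline",  "paternal", "none",  "chr11"),
    c("GNAS A/B",    "germline",  "maternal", "PHP1B", "chr20"),
    c("GNAS-XLas",   "germline",  "maternal", "none",  "chr20"),
    c("GNAS-AS1",    "germline",  "maternal", "none",  "chr20"),
    c("GNAS-NESP",   "secondary", "paternal", "none",  "chr20"),
    c("PLAGL1",      "germline",  "maternal", "none",  "chr6"),
    c("FAM50B",      "germline",  "maternal", "none",  "chr6"),
    c("NAP1L5",      "germline",  "maternal", "none",  "chr4"),
    c("PPIEL",       "germline",  "maternal", "none",  "chr1"),
    c("DIRAS3:TSS",  "germline",  "maternal", "none",  "chr1"),
    c("DIRAS3:Ex2",  "germline",  "maternal", "none",  "chr1"),
    c("DIRAS3",      "germline",  "maternal", "none",  "chr1"),
    c("GRB10",       "germline",  "maternal", "none",  "chr7"),
    c("PEG10",       "germline",  "maternal", "none",  "chr7"),
    c("MEST",        "germline",  "maternal", "none",  "chr7"),
    c("PEG13",       "germline",  "maternal", "none",  "chr8"),
    c("ERLIN2",      "germline",  "maternal", "none",  "chr8"),
    c("IGF1R",       "germline",  "maternal", "none",  "chr15"),
    c("SNU13",       "germline",  "maternal", "none",  "chr22"),
    c("NNAT",        "germline",  "maternal", "none",  "chr20"),
    c("MCTS2P",      "germline",  "maternal", "none",  "chr20"),
    c("NDN",         "secondary", "maternal", "none",  "chr15"),
    c("ZNF331-DMR1", "germline",  "maternal", "none",  "chr19"),
    c("ZNF331-DMR2", "germline",  "maternal", "none",  "chr19"),
    c("ZNF331",      "germline",  "maternal", "none",  "chr19"),
    c("ZNF597",      "secondary", "paternal", "none",  "chr16"),
    c("ZDBF2/GPR1",  "secondary", "paternal", "none",  "chr2")
  )
  data.frame(
    locus = tab[, 1], class = tab[, 2], methylated_allele = tab[, 3],
    diagnostic_for = tab[, 4], chrom = tab[, 5],
    stringsAsFactors = FALSE
  )
}

#' Coupled germline/secondary DMR pairs
#'
#' Maternally methylated germline DMRs paired with the paternally methylated
#' secondary DMR under their control. Hypomethylation of the controller is
#' expected to release methylation gain at the dependent DMR. Only the GNAS
#' pair can be expressed with the cohort's locus tokens: ZNF597 and
#' ZDBF2/GPR1 are each reported under a single token covering both the
#' germline and the secondary DMR of their locus.
#'
#' @return data.frame with columns `germline` and `secondary`.
#' @export
coupled_dmr_pairs <- function() {
  data.frame(
    germline  = "GNAS A/B",
    secondary = "GNAS-NESP",
    stringsAsFactors = FALSE
  )
}
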