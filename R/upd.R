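#' Per-SNP disomy evidence in a parent-offspring trio
#'
#' Classifies each biallelic SNP of the focus individual against their two
#' parents under the possible transmission models: biparental (one allele
#' from each parent), isodisomy (two copies of one parental homologue) and
#' heterodisomy (both homologues of one parent). A SNP is evidence for a
#' model class only when the competing class is impossible:
#' \itemize{
#'   \item `iso_evidence` / `hetero_evidence`: biparental transmission is
#'     impossible but uniparental transmission fits (the focus is
#'     homozygous / heterozygous, respectively);
#'   \item `biparental_evidence`: uniparental transmission from either
#'     single parent is impossible but biparental fits;
#'   \item `mendelian_error`: no disomy model fits;
#'   \item `uninformative`: several models fit, or a genotype is missing.
#' }
#' At fully typed biallelic SNPs `hetero_evidence` cannot arise (a
#' heterozygous parent shares an allele with any biallelic other parent), so
#' heterodisomy is recognised at the segmentation stage from focus
#' heterozygosity inside uniparental runs.
#'
#' @param genotypes a `genotype_table`.
#' @param focus column name of the focus individual (e.g. "mother").
#' @param parents character(2): column names of the focus's mother and
#'   father (e.g. the proband's maternal grandparents).
#' @param spouse optional column name of the focus's spouse; accepted for
#'   pedigree completeness but never used, since a spouse's genotype does
#'   not constrain which parent the focus's own alleles came from.
#' @return data.frame: snp_id, chrom, pos, state, focus_het (NA when the
#'   focus genotype is missing).
#' @export
classify_snp_states <- function(genotypes, focus, parents, spouse = NULL) {
  missing_members <- setdiff(c(focus, parents), names(genotypes))
  if (length(missing_members))
    stop("members absent from genotype table: ",
         paste(missing_members, collapse = ", "))
  gt_f <- genotypes[[focus]]
  gt_m <- genotypes[[parents[1]]]
  gt_p <- genotypes[[parents[2]]]

  carries <- function(gt, a)
    !is.na(gt) & (substr(gt, 1, 1) == a | substr(gt, 2, 2) == a)
  hom_allele <- function(gt) ifelse(gt == "AA", "A", ifelse(gt == "BB", "B", NA))

  f_hom <- !is.na(gt_f) & gt_f %in% c("AA", "BB")
  f_het <- !is.na(gt_f) & gt_f == "AB"
  a1 <- substr(gt_f, 1, 1); a2 <- substr(gt_f, 2, 2)

  bip <- (carries(gt_m, a1) & carries(gt_p, a2)) |
         (carries(gt_m, a2) & carries(gt_p, a1))
  uni_from <- function(gt_par) {
    iso <- f_hom & carries(gt_par, hom_allele(gt_f))
    het <- !is.na(gt_par) & gt_f == gt_par
    iso | het
  }
  uni <- uni_from(gt_m) | uni_from(gt_p)

  complete <- !is.na(gt_f) & !is.na(gt_m) & !is.na(gt_p)
  state <- rep("uninformative", nrow(genotypes))
  state[complete & !bip & !uni] <- "mendelian_error"
  state[complete & !bip & uni & f_hom] <- "iso_evidence"
  state[complete & !bip & uni & f_het] <- "hetero_evidence"
  state[complete & bip & !uni] <- "biparental_evidence"

  data.frame(snp_id = genotypes$snp_id, chrom = genotypes$chrom,
             pos = genotypes$pos, state = state,
             focus_het = ifelse(is.na(gt_f), NA, gt_f == "AB"),
             stringsAsFactors = FALSE)
}

# centered rolling fraction with edge shrinkage
roll_frac <- function(x, window) {
  n <- length(x)
  half <- max(0L, floor(window / 2))
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half); hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

runs_of <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, from = ends - r$lengths + 1L, to = ends,
             stringsAsFactors = FALSE)
}

#' Segment a chromosome into biparental / isodisomic / heterodisomic runs
#'
#' Windowed majority vote over the informative per-SNP states from
#' [classify_snp_states()]: positions where at least `min_fraction` of the
#' surrounding `window` informative SNPs carry uniparental evidence form
#' uniparental runs, the rest biparental. Inside uniparental runs, stretches
#' where the focus is predominantly homozygous (fraction >= `min_fraction`
#' over the same window) are isodisomy, the rest heterodisomy. Uniparental
#' runs supported by fewer than `min_support` informative SNPs are not
#' emitted (folded into biparental). A chromosome with > 5% Mendelian
#' errors among classified SNPs aborts (genotyping-quality guard).
#'
#' @param states output of [classify_snp_states()], position-ordered.
#' @param window SNP count of the majority-vote window (>= 1).
#' @param min_fraction vote fraction required to call a window (default 0.8).
#' @param min_support minimum informative SNPs per UPD segment (default 10).
#' @return data.frame: chrom, start_pos, end_pos (1-based inclusive), state,
#'   n_support; ordered and non-overlapping. See [segments_to_bed()] for the
#'   0-based half-open export.
#' @export
segment_disomy <- function(states, window = 50L, min_fraction = 0.8,
                           min_support = 10L) {
  if (window < 1) stop("window must be >= 1")
  if (is.unsorted(states$pos)) stop("states must be position-ordered")
  classified <- states$state != "uninformative"
  if (any(classified)) {
    err_rate <- mean(states$state[classified] == "mendelian_error")
    if (err_rate > 0.05)
      stop(sprintf("Mendelian-error rate %.1f%% exceeds 5%%: aborting UPD calling",
                   100 * err_rate))
  }
  empty <- data.frame(chrom = character(), start_pos = numeric(),
                      end_pos = numeric(), state = character(),
                      n_support = integer(), stringsAsFactors = FALSE)
  info <- states[states$state %in%
                   c("iso_evidence", "hetero_evidence", "biparental_evidence"), ]
  if (nrow(info) == 0) return(empty)
  chrom <- states$chrom[1]

  uni_vote <- info$state %in% c("iso_evidence", "hetero_evidence")
  frac <- roll_frac(uni_vote, window)
  lab <- ifelse(frac >= min_fraction, "uniparental",
                ifelse(frac <= 1 - min_fraction, "biparental", NA))
  # ambiguous windows inherit the nearest preceding label (then following)
  lab <- fill_nearest(lab)
  runs <- runs_of(lab)
  # fold under-supported uniparental runs into biparental, then re-merge
  runs$label[runs$label == "uniparental" &
               (runs$to - runs$from + 1L) < min_support] <- "biparental"
  lab2 <- rep(runs$label, runs$to - runs$from + 1L)
  runs <- runs_of(lab2)

  out <- list()
  span_lo <- min(states$pos); span_hi <- max(states$pos)
  for (i in seq_len(nrow(runs))) {
    lo <- if (i == 1) span_lo else
      floor((info$pos[runs$to[i - 1]] + info$pos[runs$from[i]]) / 2) + 1
    hi <- if (i == nrow(runs)) span_hi else
      floor((info$pos[runs$to[i]] + info$pos[runs$from[i + 1]]) / 2)
    n_sup <- runs$to[i] - runs$from[i] + 1L
    if (runs$label[i] == "biparental") {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start_pos = lo, end_pos = hi, state = "biparental",
        n_support = n_sup, stringsAsFactors = FALSE)
    } else {
      sub <- states[states$pos >= lo & states$pos <= hi & !is.na(states$focus_het), ]
      if (nrow(sub) == 0) next
      hom_frac <- roll_frac(!sub$focus_het, window)
      sub_lab <- ifelse(hom_frac >= min_fraction, "isodisomy", "heterodisomy")
      sruns <- runs_of(sub_lab)
      for (j in seq_len(nrow(sruns))) {
        slo <- if (j == 1) lo else
          floor((sub$pos[sruns$to[j - 1]] + sub$pos[sruns$from[j]]) / 2) + 1
        shi <- if (j == nrow(sruns)) hi else
          floor((sub$pos[sruns$to[j]] + sub$pos[sruns$from[j + 1]]) / 2)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start_pos = slo, end_pos = shi,
          state = sruns$label[j],
          n_support = sruns$to[j] - sruns$from[j] + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

fill_nearest <- function(x) {
  n <- length(x)
  obs <- !is.na(x)
  if (all(obs)) return(x)
  if (!any(obs)) return(rep("biparental", n))
  # carry last observation forward; a leading gap takes the first observation
  last <- cummax(ifelse(obs, seq_len(n), 0L))
  last[last == 0L] <- which(obs)[1]
  x[last]
}

#' Export disomy segments as BED
#'
#' Converts the 1-based inclusive segment coordinates to 0-based half-open
#' BED intervals (chrom, start, end, state).
#'
#' @param segments output of [segment_disomy()].
#' @param path optional file path; when given, a headerless BED file is
#'   written there.
#' @return data.frame with BED columns (invisibly when written to file).
#' @export
segments_to_bed <- function(segments, path = NULL) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_pos - 1L,
                    end = segments$end_pos,
                    name = segments$state, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Parental origin of a UPD from imprinted methylation
#'
#' On the UPD chromosome, a maternally methylated germline DMR driven to
#' full methylation implies two maternal copies (maternal origin), and to
#' zero implies paternal origin; paternally methylated DMRs read the other
#' way. DMRs on other chromosomes serve as a sanity check and must be
#' predominantly normal. Conflicting votes, no informative call, or a
#' disturbed off-chromosome background give "inconclusive".
#'
#' @param calls [call_dmr_status()] rows for the individual under test.
#' @param catalog a `dmr_catalog` (needs `chrom`, `class`,
#'   `methylated_allele`).
#' @param chrom the UPD chromosome label.
#' @param off_chrom_normal_min minimum fraction of off-chromosome calls that
#'   must be normal (default 0.8).
#' @return "maternal", "paternal" or "inconclusive".
#' @export
infer_parental_origin_from_methylation <- function(calls, catalog, chrom,
                                                   off_chrom_normal_min = 0.8) {
  cat_idx <- match(calls$dmr_name, catalog$name)
  on_chrom <- !is.na(cat_idx) & catalog$chrom[cat_idx] == chrom &
    catalog$class[cat_idx] == "germline"
  votes <- character(0)
  for (i in which(on_chrom)) {
    st <- calls$status[i]
    if (is.na(st) || st == "normal") next
    maternal_methylated <- catalog$methylated_allele[cat_idx[i]] == "maternal"
    gain <- st == "hypermethylated"
    votes <- c(votes, if (gain == maternal_methylated) "maternal" else "paternal")
  }
  if (length(votes) == 0 || length(unique(votes)) > 1) return("inconclusive")
  off <- calls[!is.na(cat_idx) & catalog$chrom[cat_idx] != chrom, ]
  if (nrow(off) > 0) {
    frac_normal <- mean(off$status == "normal", na.rm = TRUE)
    if (!is.nan(frac_normal) && frac_normal < off_chrom_normal_min)
      return("inconclusive")
  }
  unique(votes)
}

#' Disomy state at a variant position
#'
#' Looks up the segment overlapping a position; overlap with an isodisomy
#' segment is flagged as explaining a homozygous genotype (two copies of one
#' parental homologue).
#'
#' @param pos 1-based position of the variant.
#' @param segments output of [segment_disomy()].
#' @return list: state ("isodisomy", "heterodisomy", "biparental" or
#'   "uncovered") and homozygosity_explained (TRUE only for isodisomy).
#' @export
locate_variant_in_segments <- function(pos, segments) {
  hit <- which(segments$start_pos <= pos & pos <= segments$end_pos)
  state <- if (length(hit)) segments$state[hit[1]] else "uncovered"
  list(state = state, homozygosity_explained = identical(state, "isodisomy"))
}
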