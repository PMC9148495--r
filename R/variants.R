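#' Maternal-effect variant record
#'
#' One SCMC gene variant with its population allele frequency (AF), the
#' frequency of its homozygous genotype (GF), in-silico prediction labels
#' and locus-level genotypes of the pedigree members. A variant is "novel"
#' exactly when it has no population AF.
#'
#' @param gene gene symbol.
#' @param hgvs_c,hgvs_p coding / protein change labels.
#' @param rsid dbSNP id, or "novel".
#' @param af allele frequency in \[0, 1\], NA when unknown (novel).
#' @param gf homozygous-genotype frequency, NA allowed.
#' @param polyphen "benign", "possibly_damaging" or "probably_damaging".
#' @param sift "tolerated" or "deleterious".
#' @param sdm "stabilizing" or "destabilizing".
#' @param genotypes named character vector, member -> one of
#'   "wt", "het", "hom", "missing".
#' @return list of class `variant_record`.
#' @export
variant_record <- function(gene, hgvs_c, hgvs_p = NA_character_, rsid = "novel",
                           af = NA_real_, gf = NA_real_,
                           polyphen, sift, sdm, genotypes = character()) {
  if (!is.na(af) && (af < 0 || af > 1)) stop("af outside [0, 1]")
  if (rsid == "novel" && !is.na(af))
    stop("a novel variant cannot carry a population allele frequency")
  ok <- list(polyphen = c("benign", "possibly_damaging", "probably_damaging"),
             sift = c("tolerated", "deleterious"),
             sdm = c("stabilizing", "destabilizing"))
  for (tool in names(ok)) {
    lab <- get(tool)
    if (!is.na(lab) && !lab %in% ok[[tool]])
      stop("unknown ", tool, " label: ", lab)
  }
  bad_gt <- setdiff(genotypes, c("wt", "het", "hom", "missing"))
  if (length(bad_gt)) stop("unknown genotype label(s): ", paste(bad_gt, collapse = ", "))
  structure(list(gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p, rsid = rsid,
                 af = af, gf = gf,
                 predictions = list(polyphen = polyphen, sift = sift, sdm = sdm),
                 genotypes = genotypes),
            class = "variant_record")
}

#' Population-frequency tier
#'
#' "novel" when the variant has no population allele frequency, "rare" when
#' AF <= 1%, "common" when AF > 1% (the boundary itself is assigned to the
#' reported, conservative side).
#'
#' @param v a [variant_record()].
#' @return "novel", "rare" or "common".
#' @export
classify_af_tier <- function(v) {
  if (is.na(v$af)) return("novel")
  if (v$af < 0 || v$af > 1) stop("af outside [0, 1]")
  if (v$af > 0.01) "common" else "rare"
}

#' Frequency-based ACMG tier
#'
#' Within this cohort's scope (missense variants with in-silico-only
#' evidence) the only ACMG criterion applied is frequency: benign iff
#' AF > 5% in the general population, otherwise a variant of uncertain
#' significance.
#'
#' @param v a [variant_record()].
#' @return "benign" or "VUS".
#' @export
acmg_frequency_tier <- function(v) {
  if (!is.na(v$af) && v$af > 0.05) "benign" else "VUS"
}

#' In-silico harmfulness consensus
#'
#' TRUE iff at least one tool flags the variant: PolyPhen-2 possibly or
#' probably damaging, OR SIFT deleterious, OR SDM destabilizing. The
#' disjunctive reading is used because it is the only one under which every
#' variant of the cohort is predicted harmful. Missing labels give NA
#' (inconclusive), never TRUE.
#'
#' @param v a [variant_record()].
#' @return TRUE, FALSE, or NA when a label is missing.
#' @export
harmfulness_consensus <- function(v) {
  p <- v$predictions
  if (any(vapply(p, function(x) is.null(x) || is.na(x), TRUE))) return(NA)
  ok <- list(polyphen = c("benign", "possibly_damaging", "probably_damaging"),
             sift = c("tolerated", "deleterious"),
             sdm = c("stabilizing", "destabilizing"))
  for (tool in names(ok))
    if (!p[[tool]] %in% ok[[tool]]) stop("unknown ", tool, " label: ", p[[tool]])
  p$polyphen %in% c("possibly_damaging", "probably_damaging") ||
    p$sift == "deleterious" || p$sdm == "destabilizing"
}

#' Pedigree model
#'
#' Members with optional parent links and roles. Parent links must be
#' acyclic and reference known members.
#'
#' @param members data.frame with columns `id`, `mother`, `father` (NA when
#'   unknown) and optionally `sex`, `role`.
#' @return `pedigree_model` data.frame.
#' @export
pedigree_model <- function(members) {
  stopifnot(all(c("id", "mother", "father") %in% names(members)))
  if (anyDuplicated(members$id)) stop("duplicate member ids")
  links <- c(members$mother, members$father)
  unknown <- setdiff(links[!is.na(links)], members$id)
  if (length(unknown)) stop("parent(s) not in pedigree: ", paste(unknown, collapse = ", "))
  # cycle check: repeatedly peel founders
  remaining <- members$id
  repeat {
    founders <- remaining[
      (!members$mother[match(remaining, members$id)] %in% remaining |
         is.na(members$mother[match(remaining, members$id)])) &
      (!members$father[match(remaining, members$id)] %in% remaining |
         is.na(members$father[match(remaining, members$id)]))]
    if (!length(founders)) break
    remaining <- setdiff(remaining, founders)
  }
  if (length(remaining)) stop("pedigree contains a cycle: ",
                              paste(remaining, collapse = ", "))
  class(members) <- c("pedigree_model", "data.frame")
  members
}

gt_count <- function(gt) {
  unname(c(wt = 0L, het = 1L, hom = 2L, missing = NA_integer_)[gt])
}

transmissible <- function(count) {
  if (is.na(count)) return(0:1)        # unknown parent may or may not carry
  switch(count + 1L, 0L, 0:1, 1L)      # wt -> 0; het -> 0 or 1; hom -> 1
}

#' Check biallelic Mendelian segregation in a pedigree
#'
#' For every member with at least one known parent, verifies that the
#' member's allele count can be written as the sum of one transmissible
#' count per parent (wt transmits 0, het 0 or 1, hom 1; an absent or
#' untyped parent may transmit 0 or 1). A homozygote whose parents cannot
#' both have transmitted the allele is the classic anomaly that points to
#' uniparental disomy.
#'
#' @param v a [variant_record()] carrying member genotypes.
#' @param ped a [pedigree_model()].
#' @return list: `consistent` (logical) and `violations` (data.frame child,
#'   mother, father, child_genotype).
#' @export
check_mendelian_segregation <- function(v, ped) {
  viol <- list()
  for (i in seq_len(nrow(ped))) {
    child <- ped$id[i]
    if (!child %in% names(v$genotypes)) next
    c_cnt <- gt_count(v$genotypes[[child]])
    if (is.na(c_cnt)) next
    mo <- ped$mother[i]; fa <- ped$father[i]
    if (is.na(mo) && is.na(fa)) next
    cnt_of <- function(id) {
      if (is.na(id) || !id %in% names(v$genotypes)) NA_integer_
      else gt_count(v$genotypes[[id]])
    }
    sums <- outer(transmissible(cnt_of(mo)), transmissible(cnt_of(fa)), `+`)
    if (!c_cnt %in% sums)
      viol[[length(viol) + 1L]] <- data.frame(
        child = child, mother = mo, father = fa,
        child_genotype = v$genotypes[[child]], stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(child = character(), mother = character(), father = character(),
               child_genotype = character(), stringsAsFactors = FALSE)
  list(consistent = nrow(violations) == 0L, violations = violations)
}

# per-variant set of transmitted-allele counts (0/1) from a het carrier to a
# child, given the child's count and the other parent's genotype count
carrier_transmitted <- function(child_count, other_count) {
  s <- transmissible(other_count)
  intersect(child_count - s, 0:1)
}

#' Phase two heterozygous variants of one carrier
#'
#' Determines whether two linked variants carried in heterozygosity by one
#' parent lie on the same haplotype (cis) or opposite haplotypes (trans,
#' i.e. compound heterozygosity), from their transmission to the carrier's
#' children. A child who demonstrably received exactly one of the two
#' variants from the carrier proves trans; a child who received both (or
#' neither) proves cis. When the other parent's genotype leaves the
#' transmission ambiguous - e.g. an untyped father who could himself have
#' contributed the common variant - the result is "unknown".
#'
#' @param v1,v2 [variant_record()]s at linked sites (no recombination
#'   assumed between them).
#' @param ped a [pedigree_model()].
#' @param carrier member id; must be het for both variants.
#' @return "cis", "trans" or "unknown".
#' @export
phase_two_variants <- function(v1, v2, ped, carrier) {
  for (v in list(v1, v2))
    if (!identical(unname(v$genotypes[carrier]), "het"))
      stop("carrier must be heterozygous for both variants")
  children <- ped$id[!is.na(ped$mother) & ped$mother == carrier |
                     !is.na(ped$father) & ped$father == carrier]
  votes <- character(0)
  for (child in children) {
    i <- match(child, ped$id)
    other <- setdiff(c(ped$mother[i], ped$father[i]), carrier)
    other <- if (length(other)) other[1] else NA_character_
    resolve <- function(v) {
      if (!child %in% names(v$genotypes)) return(NULL)      # untyped child
      cc <- gt_count(v$genotypes[[child]])
      if (is.na(cc)) return(NULL)
      oc <- if (!is.na(other) && other %in% names(v$genotypes))
        gt_count(v$genotypes[[other]]) else NA_integer_
      carrier_transmitted(cc, oc)
    }
    t1 <- resolve(v1); t2 <- resolve(v2)
    if (is.null(t1) || is.null(t2)) next                    # untyped child
    if (length(t1) == 0 || length(t2) == 0) {
      # typed child incompatible with any transmission: contradicts both phases
      warning("child ", child, " is Mendelian-inconsistent with the carrier")
      return("unknown")
    }
    if (length(t1) != 1 || length(t2) != 1) next            # ambiguous child
    votes <- c(votes, if (t1 == t2) "cis" else "trans")
  }
  if (!length(votes)) return("unknown")
  if (length(unique(votes)) > 1) {
    warning("children give conflicting phase evidence (recombination or genotype error?)")
    return("unknown")
  }
  unique(votes)
}
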