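#' Per-locus alteration frequencies across a cohort
#'
#' For each locus token, direction and disorder group, counts the probands
#' whose status list contains it; denominators are group sizes. Tokens are
#' normalized before counting; tokens absent from the imprinted-locus
#' vocabulary are counted verbatim with a warning.
#'
#' @param status_lists named list (proband -> `list(hypo=, hyper=)`).
#' @param groups named character vector (proband -> disorder).
#' @return data.frame: locus, group, direction, numerator, denominator.
#' @export
cohort_locus_frequencies <- function(status_lists, groups) {
  if (!all(names(status_lists) %in% names(groups)))
    stop("every proband needs a disorder group")
  if (length(status_lists) == 0)
    return(data.frame(locus = character(), group = character(),
                      direction = character(), numerator = integer(),
                      denominator = integer(), stringsAsFactors = FALSE))
  vocab <- imprinted_locus_table()$locus
  rows <- list()
  for (pid in names(status_lists)) {
    g <- groups[[pid]]
    for (dir in c("hypo", "hyper")) {
      loci <- unique(normalize_locus(status_lists[[pid]][[dir]]))
      unknown <- setdiff(loci, vocab)
      if (length(unknown))
        warning("unknown locus token(s) from ", pid, ": ",
                paste(unknown, collapse = ", "))
      if (length(loci))
        rows[[length(rows) + 1L]] <- data.frame(
          locus = loci, group = g, direction = dir, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  denom <- table(groups[names(status_lists)])
  agg <- stats::aggregate(numerator ~ locus + group + direction,
                          data = transform(long, numerator = 1L), FUN = sum)
  agg$denominator <- as.integer(denom[agg$group])
  agg[order(agg$group, agg$direction, -agg$numerator, agg$locus), ]
}

#' Cohort hypo/hyper balance
#'
#' Total hypomethylated and hypermethylated DMR reports across the cohort
#' (list lengths summed over probands) and their ratio. In the published
#' cohort hypomethylation predominates.
#'
#' @param status_lists named list (proband -> `list(hypo=, hyper=)`).
#' @return list: hypo, hyper, ratio (hypo/hyper; Inf when hyper = 0).
#' @export
hypo_hyper_balance <- function(status_lists) {
  hypo <- sum(vapply(status_lists, function(s) length(s$hypo), 0L))
  hyper <- sum(vapply(status_lists, function(s) length(s$hyper), 0L))
  list(hypo = hypo, hyper = hyper, ratio = hypo / hyper)
}

#' Germline-to-secondary coupling check
#'
#' For each proband and each (germline, secondary) DMR couple, reports
#' whether hypomethylation of the maternally methylated germline DMR
#' co-occurs with hypermethylation of its dependent paternally methylated
#' secondary DMR ("satisfied"), occurs without it ("violated"), or whether
#' the couple is not applicable (germline member not hypomethylated).
#'
#' @param status_lists named list (proband -> `list(hypo=, hyper=)`).
#' @param couples data.frame with columns `germline`, `secondary`
#'   (default [coupled_dmr_pairs()]).
#' @return data.frame: proband, germline, secondary, result in
#'   {"satisfied", "violated", "not_applicable"}.
#' @export
coupled_dmr_check <- function(status_lists, couples = coupled_dmr_pairs()) {
  out <- expand.grid(proband = names(status_lists),
                     pair = seq_len(nrow(couples)),
                     stringsAsFactors = FALSE)
  out$germline <- couples$germline[out$pair]
  out$secondary <- couples$secondary[out$pair]
  out$result <- vapply(seq_len(nrow(out)), function(i) {
    s <- status_lists[[out$proband[i]]]
    hypo <- normalize_locus(s$hypo); hyper <- normalize_locus(s$hyper)
    if (!out$germline[i] %in% hypo) "not_applicable"
    else if (out$secondary[i] %in% hyper) "satisfied"
    else "violated"
  }, "")
  out$pair <- NULL
  out
}
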