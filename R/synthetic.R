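#' Simulation configuration
#'
#' Bundles the knobs of the beta-value generators. Defaults emulate the study
#' conditions: a reference cohort of 12 unaffected controls typed on a
#' methylation array, imprinted DMRs centred at 50% methylation, and modest
#' per-probe technical noise.
#'
#' @param seed integer seed; identical seed + config reproduce the output
#'   bit-for-bit.
#' @param n_controls number of control samples (>= 2; the reference SD is
#'   undefined below that).
#' @param probe_noise_sd per-probe Gaussian noise SD on the beta scale, in
#'   (0, 0.2].
#' @param probes_per_dmr probes simulated per DMR (>= 1).
#' @param baseline_mean_germline expected control beta at an imprinted DMR.
#' @param coupling_enabled if TRUE, `gen_case_betas()` propagates germline
#'   hypomethylation to the coupled secondary DMR as hypermethylation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_controls = 12L, probe_noise_sd = 0.03,
                       probes_per_dmr = 8L, baseline_mean_germline = 0.5,
                       coupling_enabled = FALSE) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_controls == as.integer(n_controls),
    probe_noise_sd > 0, probe_noise_sd <= 0.2,
    probes_per_dmr >= 1,
    baseline_mean_germline > 0, baseline_mean_germline < 1,
    is.logical(coupling_enabled)
  )
  structure(
    list(
      seed = as.integer(seed), n_controls = as.integer(n_controls),
      probe_noise_sd = probe_noise_sd,
      probes_per_dmr = as.integer(probes_per_dmr),
      baseline_mean_germline = baseline_mean_germline,
      coupling_enabled = coupling_enabled
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic imprinted-DMR catalog
#'
#' Lays out disjoint germline and secondary DMRs across autosomes with
#' synthetic probe ids. The first germline DMR is tagged as the BWS
#' diagnostic locus and the second (when present) as the PHP1B diagnostic
#' locus, mirroring KCNQ1OT1:TSS-DMR and GNAS A/B:TSS-DMR. Secondary DMR i
#' is coupled to germline DMR i where both exist (paternally methylated
#' secondary under a maternally methylated germline controller).
#'
#' @param n_germline,n_secondary DMR counts (germline >= 1, secondary >= 0).
#' @param probes_per_dmr probes per DMR (>= 1).
#' @param seed integer seed (DMR widths are drawn from it).
#' @return `dmr_catalog` data.frame with columns chrom, start, end (0-based
#'   half-open), name, class, methylated_allele, diagnostic_for,
#'   coupled_germline and a `probe_ids` list-column.
#' @export
gen_dmr_catalog <- function(n_germline, n_secondary, probes_per_dmr, seed = 1L) {
  stopifnot(n_germline >= 1, n_secondary >= 0)
  if (probes_per_dmr < 1) stop("probes_per_dmr must be >= 1")
  set.seed(as.integer(seed))
  n <- n_germline + n_secondary
  name <- c(sprintf("GL%02d", seq_len(n_germline)),
            if (n_secondary > 0) sprintf("SC%02d", seq_len(n_secondary)))
  class <- rep(c("germline", "secondary"), c(n_germline, n_secondary))
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% 22L) + 1L)
  start <- 2e6 * seq_len(n)
  width <- sample(2000:10000, n, replace = TRUE)
  # maternal except every 4th germline DMR; diagnostics forced maternal
  allele <- ifelse(class == "germline",
                   ifelse(seq_len(n) %% 4L == 0L, "paternal", "maternal"),
                   "paternal")
  diagnostic <- rep("none", n)
  diagnostic[1L] <- "BWS"
  if (n_germline >= 2) diagnostic[2L] <- "PHP1B"
  allele[diagnostic != "none"] <- "maternal"
  coupled <- rep(NA_character_, n)
  if (n_secondary > 0) {
    k <- seq_len(min(n_secondary, n_germline))
    coupled[n_germline + k] <- name[k]
  }
  probes <- lapply(name, function(nm) sprintf("cg_%s_%02d", nm, seq_len(probes_per_dmr)))
  out <- data.frame(
    chrom = chrom, start = start, end = start + width, name = name,
    class = class, methylated_allele = allele, diagnostic_for = diagnostic,
    coupled_germline = coupled, stringsAsFactors = FALSE
  )
  out$probe_ids <- probes
  class(out) <- c("dmr_catalog", "data.frame")
  out
}

catalog_baselines <- function(catalog, cfg) {
  # all imprinted DMRs are hemimethylated in normal tissue
  stats::setNames(rep(cfg$baseline_mean_germline, nrow(catalog)), catalog$name)
}

probe_matrix <- function(catalog, means_by_dmr, sample_ids, noise_sd) {
  probes <- unlist(catalog$probe_ids, use.names = FALSE)
  dmr_of_probe <- rep(catalog$name, lengths(catalog$probe_ids))
  mu <- means_by_dmr[dmr_of_probe, , drop = FALSE]
  m <- mu + stats::rnorm(length(mu), 0, noise_sd)
  m[m < 0] <- 0
  m[m > 1] <- 1
  dimnames(m) <- list(probes, sample_ids)
  m
}

#' Generate control beta values
#'
#' Each probe's control beta is its DMR baseline plus zero-mean truncated
#' Gaussian noise, one column per control sample.
#'
#' @param catalog a `dmr_catalog`.
#' @param cfg a [sim_config()].
#' @return beta matrix (probes x samples), values in \[0, 1\].
#' @export
gen_control_betas <- function(catalog, cfg) {
  stopifnot(inherits(catalog, "dmr_catalog"), inherits(cfg, "sim_config"))
  if (cfg$n_controls < 2) stop("n_controls must be >= 2: the control reference SD is undefined")
  set.seed(cfg$seed)
  base <- catalog_baselines(catalog, cfg)
  means <- matrix(base, nrow = nrow(catalog), ncol = cfg$n_controls,
                  dimnames = list(catalog$name, NULL))
  probe_matrix(catalog, means, sprintf("ctrl%03d", seq_len(cfg$n_controls)),
               cfg$probe_noise_sd)
}

#' Epimutation specification
#'
#' One planted methylation defect: the DMR, its direction, and the mosaic
#' fraction m, the proportion of cells carrying the epimutation. Under the
#' two-allele model, a defect with fraction m shifts the expected beta from
#' the baseline mu to mu(1-m) (hypomethylation) or mu + (1-mu)m
#' (hypermethylation); m = 0 is indistinguishable from a control in
#' expectation.
#'
#' @param dmr_name catalog DMR name.
#' @param direction "hypo" or "hyper".
#' @param mosaic_fraction m in \[0, 1\].
#' @return list of class `epimutation_spec`.
#' @export
epimutation <- function(dmr_name, direction = c("hypo", "hyper"), mosaic_fraction) {
  direction <- match.arg(direction)
  if (!is.numeric(mosaic_fraction) || mosaic_fraction < 0 || mosaic_fraction > 1)
    stop("mosaic_fraction must lie in [0, 1]")
  structure(list(dmr_name = dmr_name, direction = direction,
                 mosaic_fraction = mosaic_fraction),
            class = "epimutation_spec")
}

#' Generate case beta values with planted epimutations
#'
#' Each case sample carries the epimutations listed for it; unaffected DMRs
#' follow the control model. With coupling, hypomethylation at a germline DMR
#' induces hypermethylation with the same mosaic fraction at its coupled
#' secondary DMR (the epimutated cell lineage carries both defects).
#'
#' @param catalog a `dmr_catalog`.
#' @param cfg a [sim_config()].
#' @param epimutations either a list of [epimutation()] specs (one case
#'   sample) or a list of such lists (one sample per element; names become
#'   sample ids).
#' @param coupling named character vector mapping germline DMR name to
#'   coupled secondary DMR name, or NULL. Defaults to the catalog pairing
#'   when `cfg$coupling_enabled` is TRUE.
#' @return beta matrix (probes x case samples).
#' @export
gen_case_betas <- function(catalog, cfg, epimutations, coupling = NULL) {
  stopifnot(inherits(catalog, "dmr_catalog"), inherits(cfg, "sim_config"))
  if (inherits(epimutations, "epimutation_spec")) epimutations <- list(epimutations)
  if (length(epimutations) > 0 && all(vapply(epimutations, inherits, TRUE, "epimutation_spec")))
    epimutations <- list(epimutations)
  if (is.null(coupling) && cfg$coupling_enabled) coupling <- default_coupling(catalog)

  base <- catalog_baselines(catalog, cfg)
  n_case <- length(epimutations)
  ids <- names(epimutations)
  if (is.null(ids) || any(!nzchar(ids))) ids <- sprintf("case%03d", seq_len(n_case))
  means <- matrix(base, nrow = nrow(catalog), ncol = n_case,
                  dimnames = list(catalog$name, ids))
  for (j in seq_len(n_case)) {
    specs <- epimutations[[j]]
    listed <- vapply(specs, `[[`, "", "dmr_name")
    for (sp in specs) {
      if (!sp$dmr_name %in% catalog$name)
        stop("unknown DMR name: ", sp$dmr_name)
      mu <- base[[sp$dmr_name]]
      m <- sp$mosaic_fraction
      means[sp$dmr_name, j] <- if (sp$direction == "hypo") mu * (1 - m) else mu + (1 - mu) * m
      if (sp$direction == "hypo" && !is.null(coupling) && sp$dmr_name %in% names(coupling)) {
        sec <- coupling[[sp$dmr_name]]
        if (!sec %in% catalog$name) stop("coupled secondary DMR not in catalog: ", sec)
        if (!sec %in% listed) {
          mu2 <- base[[sec]]
          means[sec, j] <- mu2 + (1 - mu2) * m
        }
      }
    }
  }
  set.seed(cfg$seed + 1L)  # offset so cases and controls are independent draws
  probe_matrix(catalog, means, ids, cfg$probe_noise_sd)
}

#' Default germline-to-secondary coupling map of a catalog
#' @param catalog a `dmr_catalog`.
#' @return named character vector (names = germline DMRs, values = coupled
#'   secondary DMRs); empty when the catalog has no coupled pairs.
#' @export
default_coupling <- function(catalog) {
  sec <- catalog[catalog$class == "secondary" & !is.na(catalog$coupled_germline), ]
  stats::setNames(sec$name, sec$coupled_germline)
}

#' Uniparental-disomy plan
#'
#' Ordered, non-overlapping segments tiling one chromosome, each biparental,
#' isodisomic or heterodisomic, plus the grandparental origin of the disomy
#' ("maternal" = the focus individual's mother, i.e. the proband's maternal
#' grandmother).
#'
#' @param chromosome chromosome label.
#' @param segments data.frame with columns start, end (0-based half-open) and
#'   state in {"biparental", "isodisomy", "heterodisomy"}.
#' @param origin "maternal" or "paternal" grandparent.
#' @return list of class `upd_plan`.
#' @export
upd_plan <- function(chromosome, segments, origin = c("maternal", "paternal")) {
  origin <- match.arg(origin)
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "state") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$end <= segments$start)) stop("empty or inverted segment")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)]))
    stop("overlapping segments")
  bad <- setdiff(segments$state, c("biparental", "isodisomy", "heterodisomy"))
  if (length(bad)) stop("unknown segment state: ", paste(bad, collapse = ", "))
  structure(list(chromosome = chromosome, segments = segments, origin = origin),
            class = "upd_plan")
}

#' Simulate trio genotypes under a UPD plan
#'
#' Emits unphased biallelic genotypes for the focus individual (here the
#' proband's mother) and her two parents (the maternal grandparents).
#' Grandparental haplotypes are drawn at the given minor-allele frequency;
#' within isodisomy segments the focus carries two copies of one haplotype of
#' the origin grandparent, within heterodisomy segments both haplotypes of
#' the origin grandparent, and within biparental segments one allele from
#' each grandparent.
#'
#' @param plan an [upd_plan()].
#' @param n_snps number of SNPs (>= 1), placed uniformly over the plan's span.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param seed integer seed.
#' @return `genotype_table` data.frame: snp_id, chrom, pos (1-based,
#'   strictly increasing), mother, grandmother, grandfather with genotypes
#'   in {"AA", "AB", "BB"}.
#' @export
gen_upd_trio_genotypes <- function(plan, n_snps, maf, seed = 1L) {
  stopifnot(inherits(plan, "upd_plan"))
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  set.seed(as.integer(seed))
  L <- max(plan$segments$end)
  pos <- sort(sample.int(L, min(n_snps, L)))
  n <- length(pos)

  draw_hap <- function() stats::rbinom(n, 1L, maf)  # 1 = allele B
  g1 <- draw_hap(); g2 <- draw_hap()                # grandmother
  f1 <- draw_hap(); f2 <- draw_hap()                # grandfather
  if (plan$origin == "maternal") { o1 <- g1; o2 <- g2 } else { o1 <- f1; o2 <- f2 }

  seg_idx <- findInterval(pos - 1L, plan$segments$start)
  if (any(seg_idx < 1 | (pos - 1L) >= plan$segments$end[seg_idx]))
    stop("plan segments do not cover all SNP positions")
  state <- plan$segments$state[seg_idx]

  pick <- function(h1, h2) ifelse(stats::rbinom(n, 1L, 0.5) == 1L, h1, h2)
  iso_hap_choice <- stats::rbinom(nrow(plan$segments), 1L, 0.5)  # per-segment haplotype
  m1 <- integer(n); m2 <- integer(n)
  bip <- state == "biparental"
  gm_allele <- pick(g1, g2); gf_allele <- pick(f1, f2)
  m1[bip] <- gm_allele[bip]; m2[bip] <- gf_allele[bip]
  iso <- state == "isodisomy"
  iso_hap <- ifelse(iso_hap_choice[seg_idx] == 1L, o1, o2)
  m1[iso] <- iso_hap[iso]; m2[iso] <- iso_hap[iso]
  het <- state == "heterodisomy"
  m1[het] <- o1[het]; m2[het] <- o2[het]

  code <- function(a, b) c("AA", "AB", "BB")[a + b + 1L]
  out <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n)),
    chrom = plan$chromosome, pos = pos,
    mother = code(m1, m2),
    grandmother = code(g1, g2),
    grandfather = code(f1, f2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("genotype_table", "data.frame")
  out
}
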