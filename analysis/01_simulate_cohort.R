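#!/usr/bin/env Rscript
# Simulate a control cohort plus MLID cases with planted mosaic epimutations
# (germline hypomethylation coupled to secondary hypermethylation), and write
# the pipeline inputs under results/simulated/.
suppressPackageStartupMessages(library(mlidscan))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

catalog <- gen_dmr_catalog(n_germline = 12, n_secondary = 4,
                           probes_per_dmr = 8, seed = 20)
cfg <- sim_config(seed = 21, n_controls = 12, probe_noise_sd = 0.03,
                  coupling_enabled = TRUE)

# three BWS-like cases: MLID with partial (mosaic) defects, an MLID case
# with full loss at the diagnostic DMR, and an isolated-epimutation case
cases <- list(
  mlid_partial = list(epimutation("GL01", "hypo", 0.5),
                      epimutation("GL03", "hypo", 0.4),
                      epimutation("GL05", "hypo", 0.7)),
  mlid_full    = list(epimutation("GL01", "hypo", 1.0),
                      epimutation("GL04", "hypo", 0.6)),
  isolated     = list(epimutation("GL01", "hypo", 0.6))
)

betas <- cbind(gen_control_betas(catalog, cfg),
               gen_case_betas(catalog, cfg, cases))
write_beta_matrix(betas, file.path(out, "betas.tsv"))
write_dmr_catalog(catalog, file.path(out, "dmr_catalog.tsv"))
manifest <- sample_manifest(
  colnames(betas),
  c(rep("control", cfg$n_controls), rep("case", length(cases))),
  c(rep(NA, cfg$n_controls), rep("BWS", length(cases))))
write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = ".")

cat("Simulated", nrow(catalog), "DMRs x", ncol(betas), "samples ->", out, "\n")
cat("Planted cases:", paste(names(cases), collapse = ", "), "\n")
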