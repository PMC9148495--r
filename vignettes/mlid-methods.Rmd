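---
title: "Calling multi-locus imprinting disturbances: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling multi-locus imprinting disturbances: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlidscan)
```

## The problem

Imprinted genes are expressed from one parental allele under the control of
differentially methylated regions (DMRs). In normal tissue an imprinted DMR
is methylated on exactly one of the two alleles, so its methylation fraction
(beta value) sits near 0.5. Beckwith–Wiedemann syndrome (BWS) and
pseudohypoparathyroidism 1B (PHP1B) are each diagnosed by an epimutation at
one specific DMR (KCNQ1OT1:TSS-DMR and GNAS A/B:TSS-DMR respectively); in a
subset of patients additional imprinted DMRs are disturbed — multi-locus
imprinting disturbance (MLID). MLID in these disorders is associated with
maternal-effect variants in genes of the subcortical maternal complex
(SCMC), variants carried by the healthy mother that perturb imprint
establishment or maintenance in her offspring.

`mlidscan` implements the full desk-scale analysis: MLID calling from
region-average methylation, cohort episignature summaries, uniparental
disomy (UPD) detection from pedigree SNP genotypes, SCMC variant
interpretation, and the two-tier BWS clinical score, together with a
synthetic-data generator so every stage runs self-contained.

## The methylation model

For each catalogued DMR and sample we take the unweighted mean
$\bar\beta$ of the non-missing probe betas (DMRs covered by fewer than
`min_probes = 4` probes are removed first). Controls define a per-DMR
reference $(\mu_c, \sigma_c)$ — sample mean and sample SD with the $n-1$
denominator, deliberate because reference cohorts in this setting are small
(a dozen to a few dozen samples). A case DMR is called through

$$z = \frac{\bar\beta - \mu_c}{\sigma_c},$$

hypomethylated when $z \le -k$, hypermethylated when $z \ge k$, with $k = 3$
by default (the three-standard-deviations rule). The rule is applied
**two-sided**: losses and gains are both reported, under one threshold, and
the sign of $z$ gives the direction. A proband has MLID when the DMR
diagnostic for their disorder is altered *and* at least one additional
**germline** DMR is altered; secondary (post-zygotically methylated) DMRs
are reported but never count toward the rule.

Assumptions worth stating: region means of controls are approximately
Gaussian (means over several probes with modest, roughly symmetric probe
noise); the control cohort is representative of the case platform and
tissue; and probes within a DMR are exchangeable (the mean is unweighted).

### Mosaic fraction

Methylation defects in MLID are usually partial: only a fraction $m$ of
cells carries the epimutation. Under a two-allele 0/0.5/1 model the expected
beta at an affected DMR is

$$\mathbb{E}[\beta] = \mu(1-m) \ \text{(loss)}, \qquad
  \mathbb{E}[\beta] = \mu + (1-\mu)\,m \ \text{(gain)},$$

and the estimator simply inverts these, clamped to $[0,1]$:
$\hat m = (\mu_c-\bar\beta)/\mu_c$ for losses,
$(\bar\beta-\mu_c)/(1-\mu_c)$ for gains. It is explicitly model-based: it
reads the beta shift as cell-fraction mosaicism and is undefined for
normal-status calls.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `k` | 3 | control SDs | the field's outlier convention for iDMR screens |
| `min_probes` | 4 | probes/DMR | regions with fewer probes give unstable means |
| `probe_noise_sd` | 0.03 | beta | typical array-scale dispersion at a well-behaved probe |
| `n_controls` | 12 | samples | a realistic reference cohort for this assay |
| `window` | 50 | informative SNPs | UPD vote window; smaller finds shorter segments, noisier |
| `min_fraction` | 0.8 | — | vote agreement to call a window |
| `min_support` | 10 | informative SNPs | minimum evidence for a UPD segment |
| AF thresholds | 0.01 / 0.05 | allele freq. | rare/common split and the frequency-only benign rule |

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, not tuning knobs. It emulates:

* **controls** — per-probe betas = DMR baseline (0.5 at imprinted DMRs) plus
  zero-mean truncated-Gaussian noise. A truncated Gaussian was chosen over a
  beta distribution as the simplest model with the right support and
  dispersion; at baseline 0.5 and noise SD 0.03 truncation essentially never
  binds, so Gaussian theory applies to the caller's null.
* **cases** — planted epimutations with the mosaic shift formulas above.
  With coupling enabled, hypomethylation of a maternally methylated germline
  DMR induces hypermethylation with the *same* $m$ at its dependent
  paternally methylated secondary DMR — the single-cell-lineage reading of
  the germline-to-secondary coupling observed in MLID cohorts (e.g. GNAS A/B
  loss with GNAS-NESP gain).
* **UPD trios** — grandparental haplotypes drawn at a given minor-allele
  frequency; the focus individual (the proband's mother) receives, per
  segment, two copies of one origin-grandparental haplotype (isodisomy),
  both origin-grandparental haplotypes (heterodisomy), or one allele from
  each grandparent (biparental). Genotypes are emitted unphased as
  {AA, AB, BB}, the granularity of SNP-array output.

What it does **not** emulate: probe-specific biases, cross-reactive probes,
batch effects, cell-composition differences, genotyping error in the SNP
tables, or linkage disequilibrium between SNPs. Passing tests therefore
demonstrate correctness of the statistics under the stated model, not
robustness to every artefact of real arrays; on real data the upstream
normalization pipeline is assumed to have dealt with those.

Because no per-DMR control means/SDs are published at desk scale, the
baselines are conventional (0.5 everywhere) rather than calibrated to a
specific platform.

## UPD segmentation

Per SNP, the classifier asks which transmission models are possible for the
focus individual given her parents' genotypes, and emits evidence only when
the competing model class is excluded: `iso_evidence` (homozygous focus,
biparental impossible), `biparental_evidence` (uniparental impossible), and
`mendelian_error` (nothing fits). A point worth documenting: at fully typed
biallelic SNPs `hetero_evidence` can never fire, because a parent who is
heterozygous necessarily shares an allele with any biallelic other parent.
Heterodisomy is therefore recovered at the *segment* level: within
uniparental runs (windowed majority vote, window 50 informative SNPs,
agreement 0.8), stretches where the focus is predominantly homozygous are
isodisomy and the rest heterodisomy. Windowed majority voting was chosen
over an HMM deliberately: it matches how these profiles are read visually,
has three auditable parameters, and recovers planted segment structure at
99%+ base-level accuracy at realistic SNP densities; boundary placement is
accurate to about one window.

Safeguards: a chromosome with more than 5% Mendelian errors among
classified SNPs aborts UPD calling (quality guard); uniparental runs with
fewer than `min_support` informative SNPs are not emitted. Parental origin
is then read from imprinted methylation — a maternally methylated germline
DMR at full methylation on the UPD chromosome means two maternal copies —
and is withdrawn (`"inconclusive"`) when on-chromosome votes conflict or
when fewer than 80% of off-chromosome DMR calls are normal.

## Variant interpretation

Variants partition into **novel** (no population allele frequency),
**rare** (AF ≤ 1%) and **common** (AF > 1%); AF exactly 1% is assigned to
the rare side, the conservative choice for a boundary the thresholds leave
open. A variant with an rsid and a printed AF of 0 is a known rare variant,
not novel — novelty is keyed on the *absence* of a population record. The
frequency-only ACMG tier is benign strictly above 5%, otherwise VUS. The
harmfulness consensus is a **disjunction** — PolyPhen-2 damaging OR SIFT
deleterious OR SDM destabilizing — because a conjunctive reading would
contradict the cohort-level observation that every one of the thirteen
variants is predicted harmful (several are flagged by SDM alone).

Segregation checking uses locus-level allele counts (wt/het/hom): a child's
count must decompose into one transmissible count per parent, an untyped
parent being allowed either 0 or 1. Two-variant phasing from a het/het
carrier's children is decided per child by resolving how many copies of
each variant the carrier transmitted; exactly one variant means trans
(compound heterozygosity), both-or-neither means cis, and anything the
other parent's genotype leaves ambiguous — notably an untyped father who
could have transmitted the common variant himself — is `"unknown"`. Both
the phasing and the SNP-state classifier are verified against brute-force
enumeration oracles in the test suite.

## Clinical scoring

The BWS score is $2\times$(distinct cardinal categories) $+\ 1\times$
(distinct suggestive categories), with the category vocabulary shipped as
an editable YAML resource of case-insensitive regex synonyms. Two free-text
rules were needed to reproduce the printed cohort scores and are worth
knowing about: *asymmetry/dysmetria* counts as lateralized overgrowth
unless facial, and *hypoglycaemia* scores only with a
neonatal/perinatal/transient qualifier. Under this mapping six of the seven
printed BWS-proband scores reproduce exactly; proband 6's printed score is
one point below any consistent sum of its printed features, so that row is
carried verbatim but excluded from score assertions rather than forcing a
bespoke mapping.

## Numerical choices and degenerate inputs

* Control SDs below $10^{-6}$ are flagged degenerate and excluded from
  calling (avoids infinite $z$), with a warning.
* Missing betas are excluded from region means; a DMR's probe count for the
  coverage filter is the number of probes with at least one non-missing
  value; an all-missing sample×DMR mean is NA-flagged, never silently 0.
* $\hat m$ is clamped to $[0,1]$; noise can push the raw inverse slightly
  outside.
* Report serialization is canonical (sorted keys, doubles at 4 decimals) so
  identical results are byte-identical.
* The null-rate check of the caller uses 500 simulated controls: with small
  reference cohorts the empirical rate exceeds the Gaussian
  $2\Phi(-3)\approx 0.0027$ purely through $t$-tail heaviness of the
  estimated reference, a property of small cohorts rather than of the
  implementation, so the nominal-rate property is asserted where the
  Gaussian limit applies. Statistical checks run at deliberately modest
  problem sizes — 10,000 null DMR draws, 20 replicates per mosaic fraction,
  5,000-SNP UPD round trips — chosen as the smallest sizes at which the
  binomial/SE bounds being asserted are meaningful.

## Known limitations

* The 3-SD rule's sidedness and SD denominator are conventions of this
  implementation; the defaults (two-sided, $n-1$) are decisions, not
  published facts.
* The cohort's "GNAS (5/7)" hypomethylation frequency is reproduced by
  counting the GNAS A/B token only; counting any GNAS DMR gives 6/7. The
  A/B-only reading is an inference and is flagged in the episignature
  output.
* UPD calling is genotype-only (no B-allele-frequency/log-R intensity
  evidence) and the segmentation parameters have not been validated against
  a real SNP-array profile.
* MS-MLPA data enter as one pseudo-probe per MLPA probe through the same
  region-mean interface; no MLPA-specific error model is applied.
* No genome-wide differential methylation, no epi-signature classifier (the
  cohort shows none), and no ACMG criteria beyond the frequency tier.
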