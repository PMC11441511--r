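---
title: "Methods: clonal selection inference, barcode lineage tracing, and methylation regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal selection inference, barcode lineage tracing, and methylation regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonevo)
```

clonevo quantifies clonal evolution of cultured cancer-cell populations
under serial passage on engineered extracellular matrices (ECMs) of defined
stiffness. This vignette explains the models and procedures, the choices
behind their defaults, and what the synthetic-data generators do and do not
emulate.

## The deterministic selection model

A focal clone competes against the rest of the population. With initial
frequency $p_0$, competing frequency $q = 1 - p$, and per-generation
relative fitness $w^*$ (the ratio of the multiplication factors of the two
classes), the focal-clone frequency after $t$ generations satisfies

$$\frac{p_t}{q_t} = \frac{p_0}{q_0}\, (w^*)^t ,$$

so $p_t = p_0 (w^*)^t / (p_0 (w^*)^t + 1 - p_0)$. `clone_frequency()`
evaluates this on the log-odds scale, so very large $(w^*)^t$ cannot
overflow; a property test confirms agreement with the literal
per-generation update to $10^{-12}$ relative error up to $t = 100$.

The observable is the population growth rate $\eta$ (doublings/day, from
$N_f = N_0 2^{\eta t}$, `growth_rate_from_counts()`). The model never
prescribes how clone frequency maps onto the measured population growth
rate, so the package adopts the simplest link consistent with the
endpoints: the frequency-weighted arithmetic mean of the two clonal rates,

$$\mathrm{GR}(t) = \eta_{\mathrm{anc}} +
  (\eta_{\mathrm{sel}} - \eta_{\mathrm{anc}})\, p_t .$$

At $t = 0$ with $p_0 \ll 1$ this reduces to the background rate; as the
sweep completes it plateaus at the focal clone's rate — matching the
observed pattern of an initially halved growth rate on soft ECM that
converges to the stiff-ECM rate.

### Fitting

`fit_selection_model()` minimizes the residual sum of squares of
$\mathrm{GR}(t)$ against the replicate-mean growth rates by bounded
Levenberg–Marquardt least squares ($p_0 \in (10^{-6}, 1-10^{-6})$,
$w^* \in (10^{-3}, 10^3)$; cost tolerance $10^{-10}$). Because $p_0$ and
$w^*$ trade off along a ridge when the trajectory covers only part of the
sweep, the optimizer is multi-started (default 10 jittered restarts from a
caller-supplied seed) and the lowest-cost solution kept. All four
parameters are free by default; `fix_eta` pins the endpoint rates (for
example to the day-0 mean and the stiff-ECM mean), reproducing a
two-parameter $(p_0, w^*)$ fit. Both routes recover the generating
parameters of noiseless curves to better than $10^{-3}$ relative error
across a grid $p_0 \in \{0.001, 0.01, 0.1\}$, $w^* \in \{1.2, 2, 5\}$.

A trajectory with no selection signal (flat growth rate) leaves $p_0$ and
$w^*$ unconstrained; the fit returns with `unidentifiable = TRUE` rather
than failing. Optional residual-bootstrap intervals are available via
`bootstrap =`.

"Sweep time" is operationalized by `time_to_frequency()` as the smallest
integer generation at which $p_t$ reaches a threshold, solved in closed
form; 0.9 (near-dominance) is the conventional threshold here and is an
explicit argument. The generation axis is converted from days by
`days_to_generations()` with a default doubling time of 1.875 days (75 days
≈ 40 generations); whether "generation" means background or focal-clone
doublings is genuinely ambiguous in chronic-culture data, so the conversion
factor is exposed rather than hidden.

```{r fit-example}
truth <- selection_params(p0 = 0.0103, w_star = 2.23,
                          eta_anc = 0.25, eta_sel = 0.5)
traj <- growth_trajectory(0:40, predicted_growth_rate(truth, 0:40))
fit_selection_model(traj)
time_to_frequency(truth, 0.9)
```

## Barcode lineage tracing

The pipeline goes from paired-end amplicon FASTQ to clustered 20-bp
lineage counts and clone-dynamics summaries.

* **Merging** (`merge_read_pair()`): mate 2 is reverse-complemented and the
  longest 3′ overlap of at least 10 bases with mismatch fraction ≤ 0.1 is
  accepted; disagreements resolve to the higher-Phred base.
* **Quality** (`quality_filter()`): "Phred 30" is interpreted as a
  *mean* read quality threshold, the common amplicon practice; a per-base
  floor is available as an option.
* **Extraction** (`extract_barcode()`): the barcode is anchored between
  the vector flanks `GAGCCTCGTCTCCCACCG` and `GTTTTGAGACGCATGCTGCA`,
  allowing $\lfloor 0.1 \cdot \mathrm{len} \rfloor$ substitutions per
  flank. Matching is substitution-only: amplicon indels are rare, and a
  fixed-offset layout keeps extraction deterministic and fast. Barcodes
  containing N are rejected; the leftmost fully qualifying layout wins.
* **Clustering** (`cluster_barcodes()`): abundance-ordered greedy
  clustering at Levenshtein distance ≤ 1 with a parent/child count ratio
  ≥ 3, emulating starcode's message passing. Attachment is transitive —
  a two-error read one edit from a one-error variant collapses through it
  onto the true barcode — which is what makes ≥ 99% recovery of erroneous
  reads achievable at a 0.5% per-base substitution rate. The ratio
  interpretation of the ambiguous "minimum radius size of 3" setting is a
  deliberate reading; distance and ratio are both arguments. Ties in
  processing order break lexicographically for reproducibility. Clustering
  conserves total reads exactly.
* **Retention filters** (`apply_lineage_filters()`): a lineage is kept if
  it (1) exceeds 0.1% in some sample *and* is detected in the ancestral
  population, or (2) appears in both soft- and stiff-selected samples or
  in more than two samples of one selected group, or (3) exceeds 0.5% in
  some gel-selected sample. The 0.1% rule's frequency scope ("in any
  sample") and the log₂ fold-change pseudocount (default: reciprocal of
  the smallest library) are configuration, since either convention is
  defensible.

Downstream metrics are per-sample percent abundances, selected-sample
membership, group-mean log₂ fold change vs the ancestral frequency, the
soft-vs-stiff preference score (`preference_score()`), and the
unique-lineage diversity summary (`diversity_summary()`), whose percent
decrease is computed from the union of detected lineages across a group's
replicates relative to the ancestral count.

## Methylation regions

Region-level differential methylation from Bismark-style coverage files:

1. **Coverage filter** — a CpG locus is kept only with ≥ 25 reads in
   *every* sample. The per-sample scope is the strictest reading of the
   coverage rule and avoids condition imbalance; a pooled mode exists.
2. **Chaining** — consecutive loci within 200 bp (gap measured between
   member positions, not region span) chain into a region; counts are
   summed per sample over members.
3. **Methylation filter** — a region is kept if, in some condition, more
   than 75% of replicates show region methylation ≥ 50%.
4. **Test** — per region, a binomial-logistic GLM
   $\mathrm{logit}(\pi_j) = \beta_0 + \beta_1\,\mathrm{cond}_j$ is fitted
   by IRLS (deviance tolerance $10^{-8}$, ≤ 50 iterations); the
   likelihood-ratio statistic against the intercept-only null is referred
   to $\chi^2_1$. The binomial proportion model is implemented natively
   because the LRT against "no condition effect" is the inferential step
   itself; with one pooled replicate per condition it reduces exactly to
   the 2×2 G-test, which the tests use as an independent oracle (alongside
   `stats::glm`). Null simulations at 1000 regions match $\chi^2_1$
   (Kolmogorov–Smirnov) and hold the raw-p type-I error near 5%.
5. **Calling** — BH adjustment, then `is_dmr` iff
   $P_{\mathrm{adjust}} \le 0.01$ *and* $P \le 0.05$. Under BH the raw-p
   condition is implied by the adjusted one; the dual rule is kept
   literal.

Separated regions (all-0 or all-1 proportions in a group) are handled by
clamping proportions to $[0.5/T,\, 1 - 0.5/T]$ before IRLS, which keeps
estimates finite without penalized likelihood. Binomial proportions are
scale-free, so library-size normalization reduces to using each sample's
own total $T$; a TMM-style normalization factor is intentionally not
applied. Dispersion (beta-binomial) modelling is out of scope, so p-values
on overdispersed real data will be anti-conservative — a stated
limitation, not a bug.

## Phenotype quantification

`spreading_area()` is the shoelace area of a traced outline scaled by the
pixel size squared. `nc_ratio()` implements
$[(\mathrm{nuc}) - (\mathrm{bg})] / [(\mathrm{cyto}) - (\mathrm{bg})]$;
when only a cell and a nuclear mask are given, cytoplasm is cell minus
nucleus and background defaults to the mean outside the cell mask (how
background regions were drawn is unspecified in imaging protocols of this
kind, so it is configuration). `normalize_rho()` divides lysate
luminescence by the positive-control signal. `compare_groups()` offers the
two-sided Mann–Whitney U (exact null for small groups without ties,
tie-corrected normal approximation otherwise; verified against full
enumeration for $n \le 6$) and Welch's ANOVA; the significance convention
throughout is two-sided $\alpha = 0.05$.

## The synthetic-data generators

`simulate_experiment()` embodies the serial-passage design: clones grow
deterministically within a passage ($N_i \to N_i 2^{\eta_i d}$ over $d$
days) and genetic drift enters only at the bottleneck, where exactly
$2 \times 10^4$ cells (default) are re-seeded — multinomially in
stochastic mode, by largest-remainder rounding in deterministic mode. The
within-passage determinism is justified because a $2 \times 10^4$-cell
bottleneck dominates the stochasticity of a growing population by orders
of magnitude, the standard assumption in serial-dilution models.
Generations per passage are `eta_ref * passage_days` with the reference
clone configurable (default: the fastest clone), consistent with equating
a 75-day selection with ~40 generations. `eta_from_fitness()` converts a
per-generation relative fitness $w$ into a growth rate over a doubling
background: $\eta = \eta_{\mathrm{bg}} (1 + \log_2 w)$.

The default roster (`default_experiment_config()`) mirrors the study
conditions: 220 barcoded lineages in a $2 \times 10^4$-cell founder, a
focal clone at 1% with per-generation fitness 2.23 on soft ECM over a
0.25 doublings/day background, neutral growth at 0.5 doublings/day on
stiff ECM, five replicates per condition, 7-day passages, 10 passages.

`generate_reads()` writes paired FASTQ with the true amplicon layout
(pads, flanks, barcode), per-base substitution error, and a high/low
Phred mixture; a truth table accompanies every dataset.
`generate_methylation_dataset()` draws per-region methylation levels in
(0.55, 0.95) — inside the region-methylation filter — and shifts a random
subset of regions by a configured log-odds effect in condition B.
`generate_cell_image()` renders disk nucleus/cell geometry at configured
intensities with optional Gaussian noise, so the analytic N/C ratio and
area are known exactly.

What the generators deliberately do **not** emulate: PCR amplification
bias and chimeras, indel sequencing errors, position-dependent quality
profiles, biological overdispersion of methylation counts, mutation during
the experiment (adaptation is assumed to act on pre-existing variants),
spatial structure, and realistic cell morphology. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
assumptions, not robustness to every artefact of real libraries. The
harvest population size before re-seeding is unspecified in serial-passage
protocols of this kind; growth runs uncapped for `passage_days`, and a
carrying-capacity cap is left to the caller by shortening passages.

## Problem sizes and numerical conventions

Simulation-backed tests use sizes chosen to give stable statistics while
staying desk-scale: $10^5$ reads for clustering recovery, 1000 regions for
null calibration of the DMR test, 1000 bottleneck draws for multinomial
moment checks, and 100 noisy trajectories (noise sd 0.02 doublings/day,
20 optimizer restarts each) for the parameter-recovery study, whose
acceptance bands are a median $p_0$ within ±50% and $w^*$ within ±15% of
truth. Seeds are fixed in every stochastic test. Degenerate inputs follow
one rule: impossible values error early (negative counts, empty groups,
malformed files report the offending line); legitimately uninformative
data return flagged results (unidentifiable fits, `NA` barcode
extractions, "never reached" sweep times) rather than errors.
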