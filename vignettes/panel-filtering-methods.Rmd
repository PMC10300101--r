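---
title: "Methods: tumor-only variant filtering for large cfDNA panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-only variant filtering for large cfDNA panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsift)
```

# The filtering problem

A large targeted cfDNA amplicon panel produces, per plasma sample,
hundreds to thousands of single-nucleotide variant calls, of which only
a handful are tumor-derived. Without matched normal DNA, three
confusable populations must be separated from true somatic variants:
sequencing/PCR artifacts (typically very low VAF, biased strand and
position profiles, lower call quality), germline heterozygous variants
(VAF near 50%) and germline homozygous variants (VAF near 100%).
panelsift addresses them in three stages: a supervised false-positive
filter (errors vs real variants), a VAF mixture model plus dbSNP lookup
(germline vs somatic), and consequence/cohort annotation filters
(enrichment for driver-like events).

# The classifier

## Task and ground truth

The supervised signal comes from profiling the same patients with a
small, well-validated hotspot assay: in the genomic regions covered by
both panels, a large-panel call is labeled positive when the hotspot
assay also calls it. Filtering then becomes binary classification.
Ground-truth variants the large panel never called cannot be recovered
by any filter; they are carried as label-only rows and counted as false
negatives of every strategy (the `missed` argument of
`lopo_evaluate()`).

Hotspot-panel calls are themselves filtered first
(`hotspot_panel_filter()`): allele call neither "absent" nor "no call",
PHRED quality ≥ 20, at least 4 unique molecules supporting the variant,
and no blacklisted (homopolymer) sites.

## Features

Each call is represented by 22 features in a fixed order
(`feature_names()`): 16 from the caller output — quality, a
segregation-based metric, four bias p-values (read position, mapping
quality, mapping quality vs strand, base quality), allele count, the
four strand-specific high-quality support counts, mapping quality, the
number of reference alleles in the genotype (2 for `0/0`, 1 for `0/1`),
coverage, VAF, unique molecules supporting the variant — and 6 from the
sequence context in a 60 bp window, 30 bases upstream plus 30 bases
downstream with the variant base itself excluded (the stated window
arithmetic, 30 + 30 = 60, only holds when the center base is not
counted): A, C, G, T counts, GC fraction, repeat fraction. Repeat
content is consumed as lowercase soft-masking in the reference sequence;
this reproduces the repeat fraction without invoking a repeat annotator
at run time. `N` bases count toward no nucleotide bin but remain in the
fraction denominators, keeping the window length fixed; windows truncate
at chromosome ends and fractions then use the truncated length.

Callers omit some annotations for some records. Missing values are
imputed with the neutral value of each feature and flagged in a
missing-value mask: bias p-values to 1 (no evidence of bias), the
segregation metric to 0, mapping quality to the median of the
non-missing mapping qualities in the batch being featurized (60 when all
are missing), coverage to the unique-molecule total, allele count to 1,
and absent strand splits to an even split of the allelic depths. Calls
are never dropped for missing annotations.

Features are standardized to zero mean and unit variance. The
standardizer is fitted on training rows only — re-fitted inside every
cross-validation fold and every leave-one-patient-out iteration — so
held-out data never influence the scaling. A zero-variance feature gets
divisor 1 and is flagged; it carries no information and standardizes to
0.

## Model selection and evaluation

The SVM grid (`svm_config_grid()`) crosses a linear kernel with 11
values of C (1e−4, 1e−3, 1e−2, 0.1, 0.5, 1, 2, 5, 10, 20, 50) and an
RBF kernel with the same 11 values for both C and γ — 132
configurations. γ applies only to the RBF kernel. No class weighting is
applied. The winner maximizes the mean F1 across stratified fourfold
cross-validation on the pooled training variants; ties break by grid
order, making selection deterministic given the fold seed. If a fold
draw leaves a single-class fold, the assignment is re-drawn with the
next seed and the event logged.

Generalization is estimated leave-one-patient-out: each patient's calls
are held out in turn, hyperparameters are tuned on the remaining
patients by the inner fourfold loop (inner seed = base seed + outer
iteration, recorded in the result), the model is re-trained on all
remaining patients' calls, and applied to the held-out patient at
decision threshold 0. Per-patient confusion counts are summed into the
pooled counts (patients with no labeled calls contribute zeros and are
excluded from the per-patient metric list). The rule-based baseline —
inclusive minima on unique-molecule coverage, VAF and quality over the
990-point grid (9 coverage × 11 VAF × 10 quality values) — and the
no-filtering reference run through the same harness. The production
model (`train_final()`) repeats the fourfold tuning on all patients and
re-trains on everything.

Metrics are precision, recall, F1, MCC and Youden's J with explicit
zero-denominator conventions (all 0/0 ratios and MCC with a zero factor
under the root evaluate to 0). Under these conventions the accept-all
strategy on any cohort with both classes has recall 1 and MCC = J = 0 —
random-guessing performance — which anchors the no-filtering row of any
comparison.

# Germline genotyping by VAF

VAFs of calls surviving the classifier are modeled as a mixture of four
beta distributions for sequencing errors, somatic variants, germline
heterozygous and germline homozygous variants. EM details:

* **Initialization.** Component means 0.005, 0.10, 0.50, 0.95 with
  concentration (α+β) 20 and equal weights — each component biased
  toward one category. The fit is deterministic given the data (no
  random restarts), so no seed is needed.
* **M-step.** Weights in closed form; each component's (α, β) by
  Nelder-Mead on the log scale starting from the current values, which
  cannot decrease the objective, so the observed-data log-likelihood
  trace is non-decreasing (asserted in tests to 1e−6).
* **Convergence.** Relative log-likelihood change < 1e−6 or 500
  iterations.
* **Degenerate inputs.** VAFs are clamped to [1e−4, 1−1e−4] (open beta
  support); fewer than 40 observations or an all-identical sample is an
  error.
* **Roles.** Assigned by sorted component means after fitting.

The germline VAF intervals are the ranges where the germline-het
(respectively -hom) component has the highest posterior: found by a
dense scan over (0, 1) at step 1e−3 and refined at the boundaries by
root-finding on the posterior log-ratio of the two adjacent components.
The het interval is half-open at the top where it abuts the hom
interval, so the two germline ranges partition their union. When no fit
is feasible (few variants), the published defaults het [0.36, 0.67),
hom [0.67, 1.0] are available via `default_germline_intervals()`. A call
is flagged germline only when its VAF is in a germline interval **and**
its key is in dbSNP.

# Post-processing cascade

Three pure key-based selections applied sequentially with per-step
counts: consequence (keep the seven protein-impacting terms; "most
severe" is resolved against the standard Ensembl severity ranking
embedded in `consequence_severity_order()`; unannotated calls are
removed and logged; unknown terms are an error), cohort presence (key in
at least one supplied cancer-cohort variant set) and the dbSNP/VAF
germline filter. Because each step is a set selection, the final kept
set is order-invariant and each step idempotent (both asserted in
tests); the order only affects the step-count log. The cascade is
configurable (`cascade_config()`): steps can be re-ordered, the allowed
consequences changed and other variant databases substituted.
Matched-germline subtraction (`germline_subtraction()`) is the
comparator when germline DNA exists: cfDNA calls are kept unless their
full key (not just the position) appears in the matched germline call
set.

# Cross-panel VAF concordance

Whether variants found only in panel-specific regions have plausible
VAFs is tested by a Bayesian no-intercept regression of the test-assay
logit-VAF on the reference-assay logit-VAF. Priors: slope
β ~ Normal(1, 0.5) — the two assays are expected to be nearly equal —
and error variance ~ Exponential(mean 1). Whether 0.5 is a standard
deviation or a variance is ambiguous in this notation; the package reads
it as a standard deviation by default and offers `slope_prior = "var"`.
The exponential prior is placed on the variance exactly as stated.
Sampling uses JAGS with 4 chains × 2000 post-warmup draws, seeded per
chain; the Gelman-Rubin statistic is reported and results are flagged
(with a warning) above 1.01. With zero pairs the posterior equals the
prior and is sampled directly. VAFs are clamped at 1e−4 before the
logit. Posterior-predictive intervals are computed on the logit scale —
per posterior draw, β·logit(v) plus one seeded noise draw — and
back-transformed, so they always lie in (0, 1); a measured VAF is
"within the expected range" when inside the interval.

# The synthetic cohort generator

`make_cohort()` emulates the cohort structure the pipeline assumes.
Defaults are chosen to mirror the study conditions the pipeline was
built for: 70 patients; per patient 2 somatic, 2 germline-het, 1
germline-hom and 4 error calls (about 9 COSMIC calls per patient, the
reported per-patient average in the shared regions), plus 1 non-COSMIC
control and 1 multi-allelic record to exercise the basic filters;
unique-molecule coverage negative-binomial with mean 800 (the reported
median depth is 783×). Class-conditional VAF laws: errors Beta(1, 200),
somatic Beta(2, 8), germline-het Beta(45, 45), germline-hom Beta(90, 2).
The `separation` knob (default 2) scales how far real-variant call
quality (Normal(20 + 10·separation, 8) vs Normal(20, 8) for errors),
bias p-values (Beta(5, 1) vs Beta(1, 1 + separation)), mapping quality
and strand balance separate real variants from artifacts. Membership
tables are consistent with the truth by construction: every non-control
call in COSMIC, germline calls in dbSNP, somatic calls in at least one
cohort set, plus decoy keys that are never called. The truth label is
"real variant" (somatic or germline) versus artifact — in the shared
hotspot regions of the motivating design there are essentially no
common germline variants, so this coincides with "called by the hotspot
assay" there; separating somatic from germline is deliberately left to
the post-processing stage, as in the real pipeline. All output is
byte-identical under a fixed seed.

What the generator does **not** emulate: mappability and amplicon-edge
artifacts, position-correlated error processes (each call is
independent), realistic linkage between bias annotations, indels and
multi-nucleotide variants, batch effects between samples, and
contamination. Passing tests on synthetic cohorts therefore demonstrate
the correctness and internal consistency of the machinery — not the
real-data operating point, which depends on cohort-specific error
processes and must be established per assay.

# Problem sizes and runtime choices

Tests and the acceptance script run reduced cohorts so the full nested
evaluation stays interactive: typically 6–8 patients (about 50–80
labeled calls) for leave-one-patient-out runs with the full 132-point
grid, the reduced grid (C ∈ {0.1, 1, 10}) where tuning breadth is not
the property under test, mixture recovery at n = 10,000 draws, and the
interval fit at n = 16,717 (the production fit size). These sizes are
stated here as the package's own test design.

# Known limitations

* The classifier inherits the biases of its hotspot-panel ground truth:
  variant types the small panel cannot call are unlabeled.
* A germline variant whose VAF drifts outside the germline intervals
  (copy-number change, low tumor fraction) or that is absent from dbSNP
  escapes the germline filter; conversely a somatic variant at VAF
  ≈ 50% present in dbSNP is wrongly removed.
* The cohort-presence filter removes genuinely novel somatic variants
  by design; substitute broader variant sets when novelty matters.
* Multi-allelic sites and indels are parsed but excluded from analysis.
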