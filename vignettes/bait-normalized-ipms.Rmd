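---
title: "Bait-normalized differential IP-MS: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bait-normalized differential IP-MS: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmsdiff)
library(dplyr)
```

## The quantification model

`ipmsdiff` analyses label-free AP-MS experiments in which a bait protein is
immunoprecipitated in replicate from two conditions and peptide-ion
intensities are extracted per run. The atomic observation is one peptide
ion (sequence × charge) in one run, with an intensity in arbitrary units.

Protein abundance in a run is the sum of that protein's **unique** peptide
ion intensities after restricting to multicharged ions (2+, 3+, 4+). A
peptide sequence attributed to more than one accession anywhere in the
input is excluded from every protein's sum — no razor-peptide assignment
is attempted, because any such assignment injects an inference model the
downstream statistics do not account for. Both counts are reported:
`total_peptides` (distinct sequences observed for the protein) and
`quantified_peptides` (distinct unique sequences actually summed), and the
hit rule conditions on the latter.

Bait normalization divides each protein's summed intensity by the bait's
summed intensity **in the same run**:

$$N(p, r) = \frac{S(p, r)}{S(\mathrm{bait}, r)}.$$

Per-run division (rather than dividing by a per-group bait mean) is the
choice that makes the statistic invariant to arbitrary positive per-run
scale factors — differences in IP efficiency, elution recovery, or
injection amount cancel exactly. This invariance is verified as a property
test: multiplying every intensity in a run by any positive constant leaves
every normalized value in that run unchanged, and the bait is identically
1. The cost is that the bait itself carries no differential information
and per-run bait measurement error propagates into every prey; with a
high-abundance bait (the usual AP-MS situation) the latter is small
relative to prey-level variation.

A protein enters the differential comparison only if it is *recovered* —
positive summed intensity from at least one unique peptide — in every run
the presence scope demands. The default scope `all_runs` requires recovery
in all runs of both groups, the strictest reading of "recovered in all
experiments"; since the published protocol could also be read as requiring
recovery only within the reference IPs or within each genotype's three
IPs, `all_reference_runs` and `per_group` (recovered in every run of at
least one group) are exposed as alternatives. Absence of a (protein, run)
record and an observed zero are treated alike: not recovered.

## Differential testing and the hit rule

Group means are arithmetic means of the normalized intensities across each
group's runs, and the fold change is their ratio, test over reference. The
per-protein test is a two-sided unpaired t-test on the per-run normalized
values; the Student (pooled-variance) variant is the default for protein
comparisons, Welch is available and is the default for the Q-FISH helper,
where unequal variances between genotypes are the rule. Tests run on the
linear normalized scale by default because the upstream workflow this
package models applies none; `log_scale = TRUE` is exposed since
multiplicative error is better behaved in logs, but it is off by default
so that default output matches the reference workflow.

A protein is a **hit** iff all three conditions hold:

* `quantified_peptides` ≥ 2 — single-peptide quantifications are too
  fragile to call;
* fold change ≥ 1.5 or ≤ 0.667 — a symmetric 1.5-fold bound on either
  side;
* raw p < 0.05.

No multiple-testing correction enters the hit call; the conjunction with
the fold-change and peptide-count filters is itself the false-positive
control in this workflow. A Benjamini–Hochberg column (`p_adjusted`) is
emitted for information only.

Degenerate cases are handled explicitly rather than left to the t
machinery: two constant equal samples give t = 0, p = 1 (no evidence of a
difference); zero variance with unequal means is undefined and raises a
typed error, which the pipeline converts to an `NA` p-value — and `NA`
ratios or p-values are never hits. A zero reference mean makes the ratio
undefined (`NA` with a warning), never silently infinite. Result tables
are ordered by p ascending with lexicographic accession tie-break, and
`write_result_table()` prints the summary numerics with fixed 5-decimal
formatting so repeated writes are byte-identical.

## The packaged worked example

`ipms_table1()` returns the nine-protein result table of a β-catenin IP-MS
comparison between wild-type and telomerase-null mouse embryonic stem
cells (three contemporaneous IPs per genotype; WT is the reference group,
KO/WT the reported ratio). The replicate-level intensities behind it were
never deposited, so group means, p-values and peptide counts are inputs
here, not outputs: what *is* recomputable — and what the tests and the
acceptance script recompute — is every ratio from the printed means
(agreement within ±0.01, the printed means being rounded to 5 decimals),
the row ordering, and the hit calls. Note that under the strict
conjunction the armadillo-repeat row (ratio 0.81088) is **not** a hit even
though it appears in the published table; the package applies the rule as
stated and documents the discrepancy rather than reproducing the
inclusion. Similarly, the published "152 proteins recovered in all three
experiments" cannot be reproduced without the raw data; the presence
filter is instead validated against a closed-form binomial oracle on
synthetic data (below).

## What the synthetic generator emulates

`simulate_ipms()` draws a replicate IP-MS experiment under a fully known
model so every pipeline stage has a ground truth:

* **Design** — `replicates_per_group = 3` by default, mirroring the
  three-contemporaneous-IPs-per-genotype design; two group labels with a
  designated reference.
* **Intensities** — log-normal, composed multiplicatively on the natural
  log scale: `log I = base_log_mean + protein deviation (sd
  protein_log_sd, default 1.0) + peptide deviation (sd peptide_log_sd,
  default 0.5, constant across runs: ionization efficiency is a property
  of the peptide) + run noise (sd base_log_sd, default 0.25) + log run
  scale`. All deviations have mean zero, so the expected log intensity of
  a prey peptide ion is `base_log_mean` (default `log(1e6)`, a typical
  arbitrary-unit magnitude). The defaults are chosen as realistic
  label-free values: ~2.7-fold protein-to-protein spread, ~1.6-fold
  peptide-to-peptide spread, ~28% replicate CV.
* **Bait** — one extra protein at `bait_abundance_multiplier` (default
  50×) above the median prey, present in every run and never subject to
  missingness: a bait that fails to IP has no analysable experiment.
* **Spikes** — `spiked_proteins` maps accessions to true fold changes;
  test-group intensities are multiplied by the fold, so the true ratio of
  expected normalized means is exactly the configured fold (the log-normal
  noise mean cancels between groups).
* **Missingness** — independent per peptide ion per run (MCAR), because
  no intensity-dependent mechanism is specified for the workflow being
  modelled; MCAR is the simplest model that still exercises the presence
  filter, and it admits a closed-form retention probability
  `(1 − m^k)^{2n}` for a protein with `k` peptides under dropout `m`,
  which the tests check empirically to within three binomial standard
  errors.
* **Shared peptides** — optionally, a fraction of prey peptides is
  duplicated under a second accession to exercise the unique-peptide
  exclusion rule; by default every peptide maps to exactly one protein.
* **Determinism** — the seed is an explicit argument, randomness is local
  to the call (the global RNG state is saved and restored), and identical
  `(config, seed)` pairs give identical tables.

What it does **not** emulate: intensity-dependent (censoring-type)
missingness, retention-time or m/z structure, identification error and
FDR, interference between co-eluting peptides, and protein inference
beyond the shared-peptide rule. Passing the simulation-based tests
therefore shows the pipeline's statistics are correct under a clean
multiplicative log-normal model — not that real, censored, search-engine
output will behave as cleanly.

## Calibration and recovery checks

Three simulation-based properties back the pipeline (problem sizes chosen
to give stable empirical rates at desk scale):

* **Null calibration** — 200 null experiments (30 prey proteins, 2–6
  peptides each, 3 vs 3): the per-protein hit rate must not exceed the
  nominal 0.05. The conjunction with the fold-change bound makes the
  realised rate far lower (under 1% in practice).
* **Fold recovery** — 50 experiments with 120 prey proteins, four spiked
  2-fold up and four 2-fold down: the median recovered ratio must land
  within ±10% of 2.0 and 0.5. The estimator is the ratio of arithmetic
  group means of normalized intensities, which is consistent for the true
  fold under the generator's model.
* **t-test oracle** — at 3 + 3 the Student p-value is compared against the
  exhaustive 20-relabeling permutation distribution (rank agreement and
  bounded deviation; the permutation p is discrete in steps of 0.05), and
  against an independent closed form (pooled-variance statistic plus
  regularized incomplete beta tail).

## Assay statistics

The three small helpers share the same normalization-then-test logic as
the main pipeline:

* `densitometry_compare()` — per-lane band/loading-control ratios,
  compared between two conditions by Student's t-test; a warning is
  issued below three lanes per condition, and a zero loading control is an
  error naming the lane. Invariant to rescaling any single lane's
  (signal, control) pair.
* `qfish_compare()` — Welch's unpaired t-test on per-spot telomere
  fluorescence intensities; exactly `unpaired_t_test(variant = "welch")`.
* `luciferase_normalize()` — `(Top firefly / Top Renilla) / (Fop firefly /
  Fop Renilla)`: Renilla normalization removes transfection-efficiency
  differences, Fop normalization removes TCF-independent promoter
  activity. Replicate experiments are aggregated by arithmetic mean of
  per-experiment normalized activities.

## Known limitations

* No imputation and no empirical-Bayes variance moderation: with three
  replicates per group the per-protein variance estimate is noisy, and the
  fold-change bound is what keeps the false-positive rate down.
* The linear-scale default t-test is faithful to the modelled workflow but
  is not the statistically optimal choice under multiplicative error;
  `log_scale = TRUE` is usually preferable for new analyses.
* The presence filter's `all_runs` default is strict; proteins genuinely
  absent in one condition (the most interesting kind of differential
  interactor) are excluded by construction, as they are in the workflow
  this package models.
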