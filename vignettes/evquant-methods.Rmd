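---
title: "evquant: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{evquant: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evquant)
```

## The assay in one paragraph

Small extracellular vesicles are below the scatter detection limit of an
entry-level flow cytometer, so they are identified by chemistry instead of
size: an esterase-activated dye (CFDA-SE) fluoresces only after hydrolysis
inside a membrane-bound, esterase-containing particle. An event is called
an EV when its FL1 (dye) intensity exceeds a threshold set from a dye-only
negative control; an FL4 threshold set from a no-antibody control then
splits EVs into biomarker-positive and -negative. The assay statistic is
the *display percentage* — the fraction of FL1-positive events that are
also FL4-positive — and the diagnostic question is whether that statistic
separates two biological groups.

## Gating model

**Threshold rule.** The default is *max-of-control*: the threshold equals
the maximum control intensity, and classification is strictly greater-than,
so every control event (including the maximum itself) is negative. This
matches the assay's definition of the threshold as "the largest signal seen
without the analyte", but it is an extreme order statistic: it grows with
control sample size and is fragile to a single outlier. A percentile rule
(`rule = "percentile"`, default 99.9th) is provided as a clearly non-default
alternative for users who prefer robustness over fidelity.

**FL4 reference.** Both a no-antibody control and an isotype control can
serve as the FL4 reference; the package defaults to the no-antibody control
(the pipeline uses its single negative control table for both channels) and
lets the user supply an explicit isotype-derived `threshold_spec` instead.

**Undefined display.** When a replicate has no FL1-positive events its
display percentage is *missing*, never zero: zero would drag group means
toward "no display" on what is actually a failed measurement. The pipeline
aborts if more than half the samples end up undefined.

**Trigger contract.** Event tables honour the acquisition trigger
(FSC-H ≥ 500 **or** SSC-H ≥ 1000 by default). The OR combination is an
assumption — instrument documentation rarely states the logic — and is
recorded here rather than silently guessed as exclusive; rows violating it
are dropped with a count, mirroring what the instrument would never have
recorded.

## Synthetic data: the stated world

The generator exists so that every analysis stage has a testable input with
known truth. Its distributional choices are cytometry conventions, not fits
to data (no event-level instrument data is available to fit):

* **Intensities are log10-normal.** Noise floor: mean 1.0, SD 0.25 (≈10
  a.u.); EV and protein-particle FL1: mean 2.5, SD 0.35 — about 1.5 decades
  above the floor, so a max-of-control threshold on a few thousand control
  events separates the populations the way the published scatter plots do.
  Protein (albumin-activated) particles are deliberately
  FL1-indistinguishable from EVs: only detergent response tells them apart.
* **Antibody dose–response.** Labelled-EV FL4 is log-normal with median
  proportional to antibody amount (each EV has many binding sites; more
  antibody per EV at higher amounts means a brighter particle). The
  fraction above a fixed threshold is then Φ((log₁₀ median − log₁₀ thr)/σ),
  a probit in log amount — approximately linear mid-range, which reproduces
  the observed log-linear dose curve without inventing binding constants.
* **Perturbation flags.** `detergent` collapses EV FL1 to the noise
  distribution and leaves protein particles untouched; `trypan_blue`
  quenches all FL1 to the floor and adds an FL4-bright component to
  protein-bearing events (the dye's red-shifted emission); `bsa_present`
  adds a protein-particle population.
* **Coincidence (swarm) loss.** Detected counts follow
  `E[detected] = true · exp(−true/saturation)` — a single-parameter,
  monotone model that undercounts only at high concentration. The default
  saturation equals the undiluted expected count, placing ~39% loss at the
  1:2 point and ≤18% within the 1:5–1:80 fit range, so exactly one point
  of the default ladder is flagged.
* **Cohorts.** Group display percentages are normal with the printed
  summaries as defaults (pregnant 21.5 ± 3.0, control 33.0 ± 5.9, isotype
  12.6 ± 3.4, n = 6, three technical replicates); replicate noise SD is
  1.5 display points — not a published figure, chosen once as small
  relative to the group SDs. Values are truncated to [0, 100], a
  negligible distortion at these parameters.

What the generator does **not** emulate: fluorophore spillover and
compensation, Mie-theory scatter physics, event-rate/time structure,
doublet morphology, or instrument-specific noise spectra. A green test
therefore establishes that the *analytics* are correct on data with the
assumed statistical shape — not that the assay itself performs as modelled
on a real instrument.

## Calibration and quantification choices

* **Size calibration** is ordinary least squares in
  (log₁₀ size, log₁₀ FSC-H). The source protocol states that FSC-H was
  log-transformed but is silent on the size axis; log–log is the default
  because scatter intensity scales as a power of diameter, and the semilog
  variant is available (`size_scale = "linear"`). Neither can be validated
  against the published flow-size estimates, whose raw event data is not
  deposited.
* **D-values** use the order-statistic convention: D_p is the
  `ceiling(p·n/100)`-th order statistic, no interpolation — the smallest
  observed size that includes p% of particles.
* **Linearity fitting** is zero-intercept least squares of count versus
  dilution factor (a blank has zero particles). `r_squared` is the squared
  Pearson correlation within the fit range, which degrades to 0 for a
  pathological constant series. Out-of-range points are flagged as swarm
  when observed/predicted < 0.8 (tolerance configurable).
* **Peak-bead validation** clusters log-intensities by k-means with
  deterministic quantile initialisation — reproducible without a seed —
  and computes CVs on the linear scale.
* **Concentration back-calculation** is
  `(count/volume_µL) · 1000 / ∏(aliquot/final)`. The published
  per-mL-plasma figures do not state their dilution chain, so the chain is
  a required user input here.

## Statistical choices

* **Test selection** follows the assay's reporting rule: Shapiro–Wilk per
  group and median-centred Levene (Brown–Forsythe, implemented as a
  one-way ANOVA on absolute deviations) gate at α = 0.05; all pass → a
  *pooled-variance* t test (pooled, not Welch, because equality of
  variance has just been asserted; Welch is available); any fail →
  Mann–Whitney U. Constant groups are treated as passing normality: they
  carry no evidence against it and would otherwise crash the test.
* **ROC construction** sweeps all unique pooled values plus ±∞ sentinels
  with strict inequality on the chosen side. Whether published
  "above/below" thresholds included the sample values themselves is
  unstated; strict inequality is chosen and documented. The trapezoid AUC
  over this sweep equals the tie-adjusted rank statistic divided by
  n₁n₂ — a property the test suite checks exhaustively.
* **Operating point.** The published optimal-threshold criterion is
  unstated (and its sensitivity/specificity pair is reported inconsistently
  — 0.83/1 in one place, 1/0.83 in another, both a 5/6-vs-6/6 split).
  The package maximises Youden's J, breaks ties toward higher specificity,
  and always reports *both* coordinates of the chosen point rather than
  resolving the ambiguity.
* **Power** uses the exact noncentral-t formulation: effect size
  d = 1/(SD/Δ), df = 2n−2, noncentrality d·√(n/2), two-sided α = 0.05 (the
  design statement is silent on sidedness; two-sided is assumed and
  stated). For n = 6 and SD = 55% of the difference this gives
  `r round(ttest_power(6, 0.55), 4)`, consistent with the ≥ 0.80 design
  claim.
* **Replicates** are always averaged per biological sample before group
  statistics; technical replicates are never treated as independent
  samples.

## Numerical and degenerate-input conventions

* Percent-positive complements exactly: %above (strict) + %at-or-below
  = 100.
* Profile peak ties break toward the earlier fraction; elution windows are
  the maximal contiguous run around the peak at ≥ 10% of max (threshold
  configurable and echoed in the result) — reported ranges in the
  literature are set by inspection, so this rule is an artifact definition.
* Profile overlap normalises by the smaller total mass, so a narrow peak
  fully nested in a broad one scores 1: the statistic measures co-elution
  risk, not distributional equality.
* Generators save and restore the caller's RNG state; fixed seed ⇒
  bit-identical output; child seeds in the pipeline are derived from the
  run seed and stay below 2³¹.
* Event I/O writes doubles at 17 significant digits, so
  `read(write(x)) == x` bitwise.

## Known limitations

* The FCS adapter reads list-mode float/integer FCS 3.0/3.1 only — no log
  amplification (`$PnE`), no compensation, no FCS writing.
* Max-of-control thresholds are order statistics; comparisons between
  samples gated with controls of very different sizes inherit that bias.
* The published headline numbers (AUC 0.99, the 63.5 nm flow size, the
  printed group means) derive from undeposited event data; they appear
  here only as generator defaults and qualitative patterns, and the test
  suite claims consistency with them, not reproduction of them.
* The coincidence-loss and dose–response models are single-parameter
  stand-ins chosen for monotonicity and testability, not fitted physical
  models.
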