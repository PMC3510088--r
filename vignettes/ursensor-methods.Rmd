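---
title: "Unique-reporter sensors: design rules, quantification and Bayesian inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unique-reporter sensors: design rules, quantification and Bayesian inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A unique-reporter (UR) sensor library measures transcription-factor (TF)
activity directly. Each reporter plasmid places one TF binding site (TFBS)
upstream of a minimal thymidine-kinase promoter driving a short artificial
transcript: a 23-nt variable UR tag, one per TFBS, fused to a 58-nt
constant region shared by the whole library. When a treatment activates a
TF, transcription of its tagged reporter rises; the tag identifies the TF
on two detection platforms. On microarrays, a capture oligo complementary
to the variable region hybridizes a universally amplified, fluorescently
labelled 120-bp amplicon. On qPCR, a tag-specific forward primer, with a
hydrolysis probe and reverse primer in the constant region, quantifies
each transcript absolutely against a standard curve. A co-transfected
Renilla luciferase (Rluc) plasmid provides the normalization denominator
that absorbs transfection efficiency and global expression differences.

`ursensor` implements the computational side of this platform: tag design,
both quantification paths, and the Bayesian inference of log2 fold
induction (FI) per reporter, together with a ground-truth simulator that
makes the whole chain testable without wet-lab data.

## Tag design

Candidate tags are drawn uniformly over A/C/G/T at fixed length 23 and
screened by a cascade of exact, reproducible filters:

* **Composition.** GC fraction within [0.40, 0.60] and nearest-neighbor
  melting temperature within [50, 64] degrees. Tags should be
  physicochemically interchangeable so the entire library runs under one
  cycling program; a second pass therefore also restricts accepted tags to
  plus or minus 3 degrees around the accepted pool's median Tm. Runs of
  four or more identical nucleotides are rejected (slippage and synthesis
  artefacts).
* **Melting temperature model.** Unified nearest-neighbor
  enthalpy/entropy parameters with terminal initiation terms, 25 nM per
  strand, 50 mM monovalent salt and the entropy correction
  0.368 (N-1) ln[Na+]. This model is the de facto standard for
  primer-length oligos and, unlike folding-based scores, is exactly
  reproducible; the implementation agrees with an independent
  implementation of the same tables to below 1e-5 degrees.
* **Secondary structure.** String-matching screens rather than
  thermodynamic folding: a tag (fused to its downstream constant region)
  is rejected if it contains an intramolecular inverted repeat with stem
  longer than 6 bp separated by at least a 3-nt loop, or any
  self-complementary window longer than 8 bp (the intermolecular
  self-dimer case). Both bounds are strict: a stem of exactly the bound
  passes. Window screens are decidable and testable against exhaustive
  search, which thermodynamic folding is not.
* **Background uniqueness.** Exact k-mer exclusion (k = 12, both strands,
  canonical form) against a user-supplied background collection. A tag is
  unique when none of its twelve 12-mers occurs in the background. Exact
  matching is conservative (no alignment heuristics) and verifiable by a
  naive substring scan.
* **Cross-specificity.** Ungapped identity with every previously accepted
  tag, and with its reverse complement, must stay at or below 0.75. Assay
  oligos have been shown to discriminate tags at 74% identity, so 0.75 is
  a demonstrated-safe ceiling, not a guarantee of failure above it.

Assignment of accepted tags to catalogue entries is deterministic: tags
are taken in generation order from the seeded stream, so the same
catalogue, constraints, background and seed always give byte-identical
libraries. One extra tag is reserved as the Rluc-analogue control.

The packaged constant-region and universal-primer sequences are synthetic
stand-ins with the published lengths and roles (the original sequences are
not redistributed); they were themselves selected to pass the package's
composition and structure screens so that fused candidates are judged on
their own merits.

## qPCR quantification

Standard curves are least-squares fits of Ct on log10(copies) over a
10-fold dilution series (at least 3 points spanning 2 decades).
Amplification efficiency is E = 10^(-1/slope); curves outside the
inclusive gate E in [1.6, 2.4] are flagged with a warning but not
silently dropped, since the gate describes typical practice rather than a
hard validity bound. Unknowns convert as copies = 10^((Ct - b)/m), with
extrapolation beyond the fitted Ct range flagged. Not-detected wells
propagate as missing values, never as zero or an imputed maximal Ct.

Each UR measurement is divided by the Rluc measurement of the same sample
and replicate. Because the transfection scale multiplies the UR and Rluc
transcripts jointly, the ratio cancels it exactly; this invariance is a
tested property. Point estimates of fold induction are
log2(mean treated ratio / mean control ratio) with a standard error
combining the per-condition SEMs of replicate-level log2 values; the
replicate-level log2 normalized values themselves (not the ratios) feed
the Bayesian model.

## Microarray quantification

Spot-level input is already image-quantified (segmentation is out of
scope). Per hybridization unit (a slide/subarray incubated with one
labelled sample; each sample covers two successive subarrays, treated as
technical replicates) the package takes the mean of signal minus
background over the 5 replicate spots of each capture, floors
non-positive corrected values at 1.0 fluorescence unit with a
`below_floor` flag (log2 must be defined; no rule for negative spots is
established, so the floor is explicit and visible), divides by the unit's
Rluc value, and proceeds exactly as for qPCR. Cy3 and Cy5 are treated as
technical replicates of the same sample by default.

## The Bayesian ANOVA

All modelling happens on log2 normalized values. For qPCR, the three-way
model is

y = mu + a_target + d_target x 1[treated] + e_experiment + residual

with the repeated experiment as a random intercept; for microarrays the
experiment factor is replaced by a random intercept per hybridization
unit (the repeated measure). The per-target treatment contrast d_target
**is** the mean log2 fold induction; modelling it directly as
condition-plus-interaction in one parameter is an exact reparameterization
under the flat-ish priors used and keeps every reported quantity a single
monitored node. Priors are weakly informative: normal(0, 10^2) on fixed
effects, half-Cauchy(0, 2.5) on standard deviations. Scale parameters are
truncated below at 1e-3 log2 units — a numerical guard that keeps the
posterior proper on degenerate (for example noise-free synthetic) inputs;
at any realistic assay noise the truncation is never active.

Sampling uses JAGS (Gibbs) via `rjags` with per-chain seeded RNGs, so
fits are bit-reproducible. Defaults are 4 chains of 5000 iterations after
1000 burn-in; the pipeline wrapper uses 2 chains of 1500 after 500, which
for this conjugate-like model yields effective sample sizes in the
hundreds per contrast and split-chain scale reduction below 1.02 — the
model is low-dimensional and nearly Gaussian, so long chains buy nothing.
Convergence is monitored with the Gelman-Rubin potential scale reduction
factor (implemented in-package, including the degrees-of-freedom
correction, and cross-checked against `coda::gelman.diag` to 1e-6) and
`coda` effective sample sizes; parameters above 1.1 are flagged.

Posterior summaries per reporter: mean, central 95% credible interval,
and the two-sided tail p-value 2 min(P(d <= 0), P(d >= 0)) — the
posterior probability of no induction — floored at 1e-9, the smallest
resolution at which such tail probabilities are conventionally reported
from finite chains.

**Significance** is the conjunction of three rules, the conservative
reading of how basal variation and credible intervals are used together:
(i) the posterior mean lies outside the basal-variation band of plus or
minus 1 log2 unit (two-fold changes occur without treatment); (ii) the
95% CrI excludes zero **and** its bound nearer zero also clears the basal
band (error bars re-entering the band disqualify); (iii) the tail
p-value is at most alpha = 0.05. Failed rules are reported as reasons, so
a call is auditable.

## The synthetic generator

The generator encodes the study conditions rather than convenient ones:

* 4 biological replicates per condition per experiment, 3 experiment
  repeats (experiments were repeated at least three times);
* replicate-level noise as unit-mean lognormal multipliers on copy
  numbers with coefficient of variation 0.30 — the reported ceiling of
  intra-experimental replicate variation, taken as the default;
* a per-(experiment, target) Normal jitter of the realized log2 fold
  change on treated samples. The reported inter-experimental fold-change
  variation of *up to* 60% is a ceiling, so the jitter standard deviation
  is set to log2(1 + 0.6)/2 (about 0.34 log2 units), making a ~2 sd
  excursion multiply the fold change by 1.6; parameterizing the ceiling
  directly as a coefficient of variation instead would put roughly 40% of
  experiments beyond the stated bound and occasionally realize genuinely
  induced effects in near-null cells, contradicting the conditions being
  emulated;
* a per-sample lognormal transfection scale (sdlog 0.3) multiplying
  every target including Rluc — exactly the nuisance Rluc normalization
  exists to cancel;
* basal copy numbers (10^4 per UR, 10^5 for Rluc) and standard-curve
  parameters (slope -1/log10(2), i.e. E = 2; intercept 37) are
  arbitrary-but-documented defaults: the per-target basal expression
  levels of the real library are unpublished, and normalization makes the
  results insensitive to them;
* arrays: 8 subarrays per slide, 5 replicate spots per capture per
  subarray, two subarrays per sample, signal = background + gain x
  copies x noise in both channels.

Scenario builders inject the published per-treatment effect sizes as
ground truth for the full 60-reporter library (all unlisted reporters at
0). Two deliberate stand-ins are documented as such: the cadmium scenario
uses MRE = 4.5 and ARE = 3.0 log2 (the per-reporter supplementary
magnitudes are not redistributable; the values encode the reported
pattern of strong MRE and clear ARE induction with no other responders),
and the 60-name target list pads the named reporters with representative
TFBS names.

What the generator does **not** emulate: PCR saturation at high cycle
number (the documented array limitation), dose-response and toxicity
profiles (the up-to-300% replicate variation seen at toxic doses),
spatial artefacts on slides, and probe-specific hybridization biases.
Passing recovery tests therefore demonstrates correctness of the
computational chain under the stated noise model, not robustness to every
failure mode of the wet assay.

## Numerical choices and degenerate inputs

* Efficiency gate bounds inclusive; structure-screen bounds strict; both
  boundary conventions are tested.
* Ties in tag assignment resolved by generation order (determinism).
* Zero-variance dilution series, missing Rluc, empty design cells,
  non-finite observations and ambiguity codes in sequences all raise
  immediate, named errors rather than propagating silently.
* Problem sizes used by the packaged checks — 20 seeds per treatment
  scenario for recovery averages in the test suite (30 in the
  reproduction script), 20 simulations per effect size on the
  {0, 1, 2, 4} log2 grid for calibration, 3 seeds for the cadmium
  significance count — were chosen so Monte-Carlo error is small relative
  to the tolerances tested (recovery tolerance is two posterior SDs;
  calibration uses a binomial band around nominal 95% coverage).

## Known limitations

* Uniqueness is exact-match k-mer exclusion, not a hybridization
  thermodynamics model; near-matches below k survive by design, bounded
  by the cross-specificity ceiling.
* The identity of the third qPCR ANOVA factor is taken to be the repeated
  experiment; a per-plate factor is the plausible alternative and would
  drop in as the same random intercept.
* No multiple-testing correction across reporters is applied, matching
  the original analysis; with 60 reporters the basal-band rule, not the
  p-value, is the operative guard against false calls.
* The ± values attached to published effect sizes are read as 1 SEM each
  way (the figure-legend convention), not posterior SDs.
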