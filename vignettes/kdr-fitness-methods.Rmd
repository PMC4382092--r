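---
title: "Methods: selection and dominance of the Kdr allele from hole-penetration assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection and dominance of the Kdr allele from hole-penetration assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrfitness)
```

## The assay and its outcomes

A female *Anopheles gambiae* mosquito is released into a wind tunnel whose
far end holds a host bait behind a piece of netting with a single 1 cm hole.
The net is untreated (`UTN`) or insecticide-treated (`OLYSET`,
permethrin-incorporated; `PERMANET`, deltamethrin-coated). Within the 60-min
assay each trial ends in one of three outcomes: the mosquito passes through
the hole (`SUCCESS`), stays in the release chamber alive (`FAIL_ALIVE`), or
is knocked down by the insecticide — on its side or back with no tarsal
contact (`FAIL_KD`). Knock-down never occurs on the untreated net, and the
package enforces that invariant at ingestion.

The scientific question is how the *Kdr* (L1014F) genotype — `SS`
(susceptible homozygote), `RS` (heterozygote), `RR` (resistant homozygote) —
shifts these outcomes: physiological resistance should protect `RS`/`RR`
from knock-down on treated nets, while any behavioral side-effect of the
mutation would depress `RR` success even without insecticide.

## Outcome models

Success (vs pooled failure) is modeled with the saturated binomial logistic
model

$$\operatorname{logit} P(\text{success}) = \beta_0 + \beta_{\text{genotype}}
  + \beta_{\text{treatment}} + \beta_{\text{genotype} \times
  \text{treatment}},$$

and every pairwise contrast (genotype pairs within a treatment, treatment
pairs within a genotype) is reported as a Wald odds ratio, reproducing the
successive re-leveling of the reference class. Because the model is
saturated, each contrast equals the 2x2 cross-product ratio with standard
error $\sqrt{1/a + 1/b + 1/c + 1/d}$; the tests assert both routes agree to
1e-6. Contrasts touching a zero margin receive the Haldane–Anscombe +0.5
correction on all four cells and are flagged — the correction keeps the
estimate finite at the cost of a small bias, and the flag lets a user drop
those rows.

The three-outcome comparison uses a multinomial logistic model with baseline
`SUCCESS`, fit by exact Newton iteration on the multinomial log-likelihood
(convergence: maximum absolute coefficient change below 1e-10, at most 100
iterations, with a small ridge on the information matrix only when boundary
cells flatten it). Keeping `SUCCESS` as the baseline carries the success
proportions along, so the knock-down vs alive odds ratio between two nets is
the difference of two coefficient differences; for the saturated fit it
equals the conditional cross-product ratio of the four failure counts.

Proportions are reported with Wilson score intervals. Both the plain and
continuity-corrected forms are available (`continuity = TRUE` is the
default); the two disagree in the third decimal for the sample sizes here,
and the overall success interval printed by the original analysis is
reproduced by the plain form. Simultaneous intervals for the three outcome
proportions of one cell use the Sison–Glaz construction (truncated-Poisson
representation with an Edgeworth-corrected coverage calibration),
implemented in-package and validated by simulated coverage.

## Fitness decomposition and the Monte-Carlo profile likelihood

The success proportion $p_i$ of genotype $i$ serves as a proxy of relative
fitness: $w_i = p_i / p_{SS}$, and the single-locus decomposition

$$w_{SS} = 1, \qquad w_{RS} = 1 + hs, \qquad w_{RR} = 1 + s$$

defines the selection coefficient $s$ (negative = cost of `RR`, positive =
advantage) and dominance $h$ ($h = 0$ recessive, $h = 1$ dominant, $h > 1$
overdominant). Point estimates are the plug-in values; $h$ is undefined and
flagged when $s = 0$.

For interval estimation the three genotype success probabilities under one
treatment are treated as independent binomials with logits $a_{SS}, a_{RS},
a_{RR}$. Since $(s, h)$ are functions of the three logits, their profile
likelihoods are estimated by the cloud construction: sample $(a_{RS},
a_{RR})$ pairs uniformly, profile out $a_{SS}$, and take the upper envelope
of attained log-likelihood against the implied $s$ or $h$. The likelihood
factorizes over genotypes, so the conditional maximizer of $a_{SS}$ is the
same for every draw, $\operatorname{logit}(k_{SS}/n_{SS})$; the closed form
is used by default and a numerical 1-D maximization is retained behind
`profile_a_ss = "numeric"` as a fidelity check. Likelihood-ratio confidence
intervals collect the parameter values whose envelope stays within
$\chi^2_1(0.95)/2 = 1.9207$ log-units of the maximum; no small-sample
correction is applied.

Numerical choices that required a decision:

* **Sampling box.** By default each coefficient is drawn uniformly from a
  box centered on its maximum-likelihood value with half-width
  $\max(6\,\mathrm{SE}, 1.5)$ logit units, clipped to $[-12, 12]$. A fixed
  global box (e.g. `box = c(-8, 8)`) is supported, but at 100,000 draws it
  leaves the envelope sparse near the confidence-interval crossings: the
  envelope is a lower bound of the profile, and under-sampling biases the
  intervals inward — with the fixed box the endpoints sat several bin widths
  inside the grid-search profile and coverage fell below nominal, while the
  adaptive box restores agreement to within one bin width. Six standard
  errors cover the region within ~18 log-units of the maximum, far beyond
  the 1.92 threshold that matters.
* **Envelope binning.** 512 equal-width bins for $s$ over $[-1, 1]$ and
  1,024 bins for $h$ over $[-5, 105]$. Values beyond the $h$ range are
  tracked as overflow and reported in the ">100" style.
* **Endpoints.** Crossings are interpolated linearly between bin midpoints.
  The scan runs from the outside in: because Monte-Carlo noise can only
  carve false gaps into the envelope, interior dips below the threshold are
  not treated as crossings.
* **Unbounded sides.** Whether the interval extends beyond the binned range
  is decided deterministically, not by sampling luck: the exact profile is
  probed at the range edges (closed form for fixed $s$ by separability; a
  fine-grid 1-D maximization over $a_{RR}$ for fixed $h$). If the profile at
  the edge still exceeds the threshold, the side is flagged unbounded. The
  overdominant treated-net fits always flag the upper $h$ bound this way —
  with $\hat s$ near zero the data cannot distinguish $h = 10$ from
  $h = 1000$.
* **Degenerate cells.** A success count of 0 or $n$ makes the logit
  infinite; it is clamped to ±12 and the estimate flagged
  (`ss_clamped`). Relative fitness is undefined when $p_{SS} = 0$.
* **MLE augmentation.** The analytic maximum-likelihood point is appended to
  the cloud so the envelope attains the global maximum exactly in the MLE's
  bin regardless of the draw count.

## The bundled count table

`kdr_assay_counts()` ships a reconstruction of the published 601-trial count
table. The failure splits on treated nets (43/44, 6/13, 2/39, 37/38, 11/12,
2/27) are reported counts; treated-net success counts follow from the
printed odds ratios and success-rate reductions, and reproduce the printed
selection/dominance estimates at printed precision, which pins them down
uniquely. The untreated-net cells are a constrained integer reconstruction
(matching the printed odds ratios, the 376/601 totals, and the printed
$s = -0.35$, $h = 0.09$); they carry `provenance = "reconstructed"` and are
treated as approximate in every check. One printed contrast
(`OR_RS-SS` = 1.16 on the untreated net) is inconsistent in direction with
$p_{RS} < p_{SS}$ and is matched by its reciprocal; we read it as a
reference-labeling slip in the source.

## Behavioral traits

Net-contact counts are compared with a Poisson log-linear model with a
log-duration offset — the duration is the time to pass for successful trials
and the full 3600 s otherwise, so the genotype coefficients are contact-rate
ratios per unit time. The remaining video-derived variables (fraction of
time in flight, mean flight speed, fractions of time on net and walls, time
to pass among successes) are compared with tie-corrected Kruskal–Wallis
tests followed by Dunn's post-hoc z tests. The post-hoc correction defaults
to Bonferroni over the three pairwise comparisons (the source names the
procedure but not the correction); `holm` and `none` are available.

## The synthetic generator

`simulate_trials()` draws full trial-level datasets under the generative
model the analysis assumes: per cell, success is binomial with
$p_i = p_{SS} w_i$; failures split into knocked-down vs alive with a
conditional probability `q_kd` (zero on the untreated net); successful
trials get a gamma time-to-pass (shape 2, mean 666 s, truncated at the
assay length); contacts are Poisson in time; flight-time fraction is beta;
speed is log-normal. Defaults are calibrated to the published summaries:
baseline success 0.80/0.50/0.58 (UTN/Olyset/PermaNet), $(s, h)$ =
$(-0.35, 0.09)$ untreated and $(0.1, 2.5)$ treated, `q_kd` from the printed
failure splits, cell sizes from the reconstructed table, and contact rates
whose ratios match the printed values (0.261 for RR vs SS, 0.187 for RR vs
RS).

The generator emulates the statistical structure the estimators rely on —
independent per-trial outcomes, binomial cells, conditional knock-down,
genotype-specific trait distributions. It does not emulate real-data
features such as day/batch effects, over-dispersion from shared rearing,
censoring quirks of video tracking, or correlation between traits and
outcome within a trial. Passing recovery tests on synthetic data therefore
demonstrates the estimators are correct under the stated model, not that
the model captures every feature of wind-tunnel data.

Distributional shapes for the traits (gamma, beta, log-normal) are our
calibration choices — the source publishes only summaries — and are labeled
as such, not as ground truth.

## Problem sizes used in the checks

The test suite runs the Monte-Carlo profile at 100,000 draws on the bundled
table (single-treatment fits take about a second); oracle-equivalence
properties use 1,000 random tables; profile fidelity is checked against a
2001 x 2001 grid search on three fixtures; parameter recovery uses 200
simulations at 2,000 trials per cell; and type-I control uses 100 null
simulations of the same size. These sizes were chosen to keep each property
estimable with comfortable margins while the whole suite runs in a few
minutes.

## Known limitations

* The Wald odds-ratio machinery assumes non-degenerate cells; the +0.5
  corrections are flagged but still only first-order fixes.
* The likelihood-ratio intervals rely on the $\chi^2_1$ calibration, which
  is approximate at these sample sizes (60–90 trials per cell) and near the
  $s = -1$ boundary.
* $h$ is weakly identified whenever $|s|$ is small; expect unbounded upper
  limits on treated nets and wide intervals elsewhere. This mirrors the
  original report.
* Printed multinomial odds ratios from the original analysis differ from
  the saturated cross-ratios in the second decimal for one contrast; we
  treat that as optimizer noise in the original fit and report the exact
  maximum-likelihood value.
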