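---
title: "uvphos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{uvphos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvphos)
```

## The biological setting

UV irradiation of human cells activates the stress kinase p38, which in turn
activates the MAPKAP kinases MK2/3/5. The downstream program can be read out
at three levels, and `uvphos` implements the computational analysis for each:

1. **SILAC phosphoproteomics.** Light/medium/heavy labeling lets one MS run
   quantify, per phosphosite, the UV response (UV/mock ratio) and its
   sensitivity to kinase inhibition (inhibitor+UV/mock ratio). The analysis
   asks which sites are UV-induced, which of those depend on p38, and which
   of the p38-dependent ones depend on MK2/3/5.
2. **14-3-3 interactome.** MK2 substrates often become 14-3-3 docking sites;
   pulldown SILAC ratios identify UV-induced 14-3-3 interactors and the
   subset whose binding is p38-dependent.
3. **RNA pol II chromatin binding.** One consequence of this signaling is
   release of promoter-proximally paused polymerase (NELF-mediated pausing)
   into gene bodies, quantified from coverage tracks by the polymerase
   release ratio (PRR).

A synthetic-data generator plants known effects in all four data types, so
the entire pipeline is testable without the deposited raw data.

## The moderated one-sample t-test

SILAC experiments have very few replicates (here two), so per-site variance
estimates are unstable. `fit_ebayes()` implements the standard
empirical-Bayes remedy: per-feature sample variances $s_g^2$ on $d_g$
degrees of freedom are assumed scaled-$\chi^2$ around a latent $\sigma_g^2$,
with an inverse-$\chi^2$ prior $\sigma_g^2 \sim s_0^2\, d_0 / \chi^2_{d_0}$
shared across features. Hyperparameters are estimated by moment matching on
$\log s_g^2$:

$$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2), \qquad
  \operatorname{trigamma}(d_0/2) = \widehat{\operatorname{Var}}(e) -
  \overline{\psi'(d_g/2)},$$

with the trigamma inversion done by Newton iteration (`trigamma_inverse()`);
$s_0^2$ follows from the matched mean. The posterior variance is the
df-weighted blend $\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and
the moderated statistic $\tilde{t}_g = \bar{x}_g / \sqrt{\tilde{s}_g^2/n_g}$
is referred to a Student distribution on $d_g + d_0$ degrees of freedom.
When the observed variances show no excess dispersion beyond sampling, the
solution degenerates to $d_0 = \infty$ and the statistic becomes z-like with
the pooled variance; a `d0_override = 0` switch recovers the ordinary t.
Tests verify both limits, agreement to at least six decimals with an
independent bisection solver of the same moment equations, and agreement
with `limma::squeezeVar` as an external cross-check (limma is never used in
the computation itself).

Numerical choices: a variance floor of `1e-8` is applied before taking logs,
which also makes degenerate all-zero inputs well-posed (they yield $t = 0$,
hence "not significant" — the error about an ill-posed prior is reserved for
a zero floor); features observed in a single replicate have no sample
variance and are flagged and excluded from both hyperparameter estimation
and testing, unless `posterior_only = TRUE` deliberately assigns them the
prior variance.

## Regulation and dependency calling

`call_uv_regulation()` tests the UV/mock contrast two-sided and labels sites
`up`/`down`/`ns` at raw $p < 0.01$ (the study's printed threshold; q-values
are reported alongside but do not gate the calls). Sites below a
localization-probability cutoff (default 0.75) are excluded: the original
peptide-level score filters are not reproducible from site tables, and the
localization probability is the standard site-level surrogate.

Dependency is hierarchical and within-experiment: among `up` sites,
`call_dependency()` forms per-replicate differences of log2 ratios
(inhibitor+UV/mock minus UV/mock, i.e. log2 of inhibitor+UV over UV, which
cancels the common mock reference) and tests them one-sided for a decrease
with the same moderated machinery, at $p < 0.01$. MK dependency applies the
identical operation within the p38-dependent stratum. An optional
fold-change cutoff exists but defaults to off (p-only), matching the printed
counts' description.

A known property worth stating: sites that reach the `up` stratum as false
positives do so because their UV ratio is extreme, while their inhibitor
ratio regresses to the mean; the difference is therefore biased negative and
such sites are preferentially called "dependent". On synthetic data this
inflates the dependent fraction among calls by a few points above the
planted fraction. This selection effect is intrinsic to any hierarchical
scheme of this shape, not an implementation artifact; the recovery tests
bound it.

**Percentage display.** The published summary labels round inconsistently:
25.65% is printed as 25.6 (truncation) while 1.17% is printed as 1.2
(rounding). No single convention reproduces all labels, so
`percent_forms()` reports truncated-1dp, rounded-1dp and rounded-integer
forms side by side and `summarize_fractions()` carries all three.

## Sequence-motif analysis

`count_position_frequencies()` builds position-specific residue counts over
a 13-position frame (±6 around the phosphoacceptor), tallying terminal `_`
padding separately. `icelogo_enrichment()` compares foreground and
background frequencies per cell with the binomial z-score of the reference
set, $z = (f_{fg} - f_{bg}) / \sqrt{f_{bg}(1-f_{bg})/n_{fg}}$, two-sided
normal p, and — following the iceLogo default — no multiple-testing
correction unless requested (`adjust = "BH"`). The background is the set of
all quantified sites' windows, not a proteome model, matching the study's
stated reference.

Fixed consensus matchers cover S/TQ (the ATM/ATR/DNA-PKcs motif), LXRQXS/T
(the MK2/3/5 substrate consensus: Leu −5, Arg −3, Gln −2) and RXXS/TXDXDI
(Arg −3, Asp +2/+4, Ile +5; the MK-independent p38-downstream motif).
`predict_14_3_3()` is a deliberately transparent rule-based surrogate for
consensus-based 14-3-3 predictors, scoring mode I (R−3, S/T/aromatic at −2,
P+2), mode II (R−4 or R−3 with P+2) and a relaxed arginine-anchor rule
(R−3 with S−2). The relaxed rule is what recognizes the NELFE S115 context
(`...QRSI-pS-ADDDL...`), which carries the anchor but no +2 proline; the
scorer is documented as a surrogate, not a reimplementation of any
published predictor. Note the S115 peptide appears in two spellings in the
source material (one aspartate apart); the structure-section spelling
(`SISADDDLQE`), which matches the MS peptide, is used in tests.

## Phosphosite occupancy

In the phosphatase-reference design, dephosphorylating one SILAC channel
returns the phosphorylated pool to the unmodified peptide, so the
unmodified-peptide ratio $r$ (treated/untreated) satisfies $r = 1/(1-o)$
for occupancy $o$, inverted as $o = (1 - 1/r) \times 100\%$. Ratios below 1
imply negative occupancy and are flagged invalid rather than clamped to
zero, so the flag count doubles as a noise QC. The Monte-Carlo recovery test
checks the *bias* of the estimator (about −0.1 points under 5% CV noise);
the mean absolute error at 5% CV is analytically
$\approx 100\,\mathbb{E}(1-o)\,\sqrt{2/\pi}\,\mathrm{CV} \approx 2$ points
and is reported, not thresholded, since it sits exactly at that value.

## Interactome and gene-set enrichment

`call_interactors()` applies the moderated test at $p < 0.05$ to
bait-vs-control ratios (positive mean required) and, for dependency, the
one-sided decrease test to the inhibitor-vs-UV contrast.
`gene_set_enrichment()` computes the one-sided hypergeometric tail
$P(X \ge k)$ — identical to one-sided Fisher, both exposed and tested for
equality — with set-size filters (defaults 3–1000) and BH correction across
retained sets. Universes are explicit arguments: all-quantified proteins
for the proteomic enrichments, all pol-II-bound genes for the PRR
enrichment. Identifiers are uppercased and deduplicated.

## Polymerase release ratio

Per gene, two windows are laid out in transcription direction from the TSS:
a TSS window (−300, +1000) and a downstream window (+1000, +3000). Window
signals are mean per-base coverage converted to RPKM-scale units
(`sum * 1e9 / (width * library_size)`), which makes the PRR invariant to
sequencing depth. The PRR is
$\log_2\!\big((e_{down} + \varepsilon)/(e_{tss} + \varepsilon)\big)$ with a
pseudocount $\varepsilon$ = 0.1 RPKM (the source states none; the value
keeps silent windows finite and is reported in the output). Eligibility
requires gene length > 3 kb — the downstream window must lie inside the
gene — and untreated TSS signal ≥ 1 RPKM (the study's own GRO-seq rule,
adopted because its TSS filter is otherwise described only qualitatively).

Replicates are handled by computing a PRR per replicate and averaging
within condition, which preserves replicate variance for testing.
Differential release is the replicate-paired delta (UV − mock per
replicate), tested over genes with the moderated t and BH-corrected — the
original region-level differential-binding step is not reproducible at gene
level, so this defined, testable substitute stands in and is documented as
such. The global mock-vs-UV comparison uses the Wilcoxon rank-sum test with
continuity correction on per-gene mean PRRs. `metagene_profile()` gives the
strand-oriented average coverage around TSSs for visual QC.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 13,091 sites, 4% planted
UV-induced, 26% of those p38-dependent, 60% of those MK-dependent, 17% of
UV-induced sites in a disjoint S/TQ ("ATR-type") stratum, effect size 1.5
log2 units, replicate noise SD 0.35 in log2 space (Normal — the standard
SILAC error model), two replicates. Pulldowns plant 28% dependent
interactors. Coverage tracks are Poisson draws around a per-base rate built
from a Gaussian TSS bump plus a uniform gene-body rate; planted release
multiplies the body beyond +1000 bp by $2^{\Delta PRR}$ (default +1 on 30%
of genes), so the planted shift is exact up to the pseudocount. Gene
lengths are uniform on 1–30 kb so the ≤3 kb filter is exercised;
NELF-target labels cover 70% of released genes. Where the source states no
value (noise SDs, bump geometry, interactor fraction), values were chosen
once at what a practitioner would call realistic magnitudes and are not
revisited.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: inter-replicate correlation (replicate noise is
independent; real replicates share biology), missing-value structure
(real SILAC missingness is intensity-dependent), peptide-level evidence,
read-level artifacts (mappability, GC), and planted downregulation (the
config plants only upregulated sites; observed down-calls on synthetic data
are false positives by construction).

Determinism: every simulator runs under a locally seeded Mersenne-Twister
stream derived from `sim_config(seed=)` and restores the caller's RNG
state, so a fixed seed gives byte-identical output across platforms.

## Problem sizes and runtime choices

Unit tests use reduced sizes (hundreds to a few thousand sites, 30–80
genes); the planted-recovery and calibration checks run at study scale —
13,091 sites, 10^4-feature null matrices, 300–500 genes — once each in the
acceptance-style tests and in `scripts/acceptance.R`. These sizes keep the
whole suite under a minute while leaving the stochastic checks' standard
errors well inside their 3-SE bands.

## Known limitations

* The dependency selection effect described above inflates dependent
  fractions among borderline calls; interpret dependent-fraction summaries
  on real data accordingly.
* The Wilcoxon normal approximation deviates from the exact distribution by
  up to ~0.016 mid-distribution at $n = 12$; exact enumeration is used
  automatically for small tie-free samples.
* The 14-3-3 scorer trades sensitivity/specificity transparency for
  fidelity to any particular published predictor; it is a labeled surrogate.
* PRR epsilon and the TSS-signal threshold are conventions, not estimates;
  both are configurable and recorded in outputs.
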