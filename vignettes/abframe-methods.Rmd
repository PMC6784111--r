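---
title: "Methods: germline-guided VL framework optimization and its downstream analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline-guided VL framework optimization and its downstream analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abframe)
```

`abframe` implements the analysis workflow behind a germline-guided
optimization of an antibody light-chain framework, from sequence design
through biophysical characterization to pharmacokinetics. This vignette is the
package's account of the underlying models, the defaults we chose where the
method left room, and what the bundled synthetic data do and do not emulate.

## Kabat numbering and region delineation

V-domain residues are addressed by Kabat position. The light (kappa) chain
runs 1–107 with frameworks FR1 1–23, FR2 35–49, FR3 57–88, FR4 98–107 and
CDRs L1 24–34, L2 50–56, L3 89–97; the heavy chain runs 1–113 with FR1 1–30,
FR2 36–49, FR3 66–94, FR4 103–113 and CDRs H1 31–35, H2 50–65, H3 95–102.
Length variation is absorbed by letter-coded insertions at canonical sites
(L: 27a–f, 95a–f, 106a; H: 35a–b, 52a–c, 82a–c, 100a–k) and by omitted
numbers for deletions.

`assign_kabat_numbering()` aligns the query globally against a bundled
per-chain consensus template whose positions are exactly the plain numbers
(107 residues for kappa, 113 for heavy), using BLOSUM62 with affine gap costs
(opening 10, extension 0.5). The alignment serves only to apportion query
residues to regions; within each region the residues are then renumbered by
rule:

* a region at its canonical length takes the canonical numbers;
* surplus residues become insertion codes at the region's canonical site
  (24–27, 27a, 27b, …, 28–34 for a long CDR-L1), failing with a clear error
  if the site's letter capacity is exceeded or the region has no canonical
  site;
* deficits omit numbers in a fixed order around the site (first the numbers
  after the site, then the site itself, then backwards), so a given length
  always yields the same numbering.

Because the within-region gap placement chosen by the aligner is discarded by
this renumbering, alignment ties cannot influence the result; that is why the
implementation does not need position-specific gap penalties to steer gaps.
Queries whose identity to the chain consensus falls below 40% are refused
with an error naming the chain, as are sequences outside 80–140 residues.
`X` is accepted as a residue but never counts as a match in any identity
computation. The deletion omission order is our convention; real antibodies
with unusual short CDRs may be numbered differently by other tools, which
matters only if numberings are mixed across tools.

## Germline scan, mismatch regions and the variant panel

`percent_identity()` counts matches over Kabat positions present in both
sequences; the framework denominator is FR1–FR3 (70 positions for an
insertion-free kappa VL) because germline V genes do not encode FR4. Total
V-region identity uses every position the germline covers — V genes end
within CDR3, so the bundled kappa germlines stop at Kabat 95. A parental
framework differing from its closest germline at Kabat 1, 3, 4, 66 and 79
therefore scores 65/70 = 92.86%.

`find_closest_germline()` maximizes framework identity, breaking ties by
total V-region identity, then by reference order. `group_mismatches()` merges
neighbouring mismatches into one mutation region when at most one matching
position lies between them — this is what turns the mismatch set
{1, 3, 4, 66, 79} into the three regions 1–4, 66 and 79 (position 2 matches
and is bridged).

`enumerate_variants()` builds all 2^k parental/germline combinations over k
mutation regions (capped at 12) and names each variant by concatenating the
residues at the signature positions — the full residue span of each region,
so a 1–4 region contributes four letters and single positions one each. The
panel is ordered by the number of germlined regions and then
lexicographically by region combination; a duplicate of the parental carrying
the heavy-chain C-terminal lysine can be inserted as the second entry with a
`-K` suffix, reproducing the nine-entry panel layout used for BaxM159
(1-DIQMAQ … 9-EIVLGE). The lysine is a panel-level flag only; no
constant-domain sequence is modelled.

The bundled germline reference (`inst/extdata/germline_v_synthetic.fasta`) is
a synthetic stand-in for a public germline database: six kappa V genes built
around the consensus template — one IGKV3-20-like entry that is the planted
closest gene — plus one VH3-23-like heavy gene. Positional residue
frequencies (`frequency_profile()`, `positional_frequency()`) are computed
from whatever reference set the user supplies; the published database
frequencies (e.g. 0.5% alanine vs 61% glycine at L66) come from an external
curated resource and are emulated, not reproduced, by fixtures.

## SPR kinetics: 1:1 Langmuir

For analyte concentration $C$, association follows
$R(t) = R_\mathrm{max}\,\frac{C k_a}{C k_a + k_d}\left(1 - e^{-(C k_a + k_d)t}\right)$
and dissociation decays from the injection-stop response as $e^{-k_d (t - t_\mathrm{stop})}$.
`fit_langmuir_1to1()` fits shared $k_a$, $k_d$, $R_\mathrm{max}$ globally
across all concentrations by least squares on log-parameterized (hence
positive) parameters, reporting $K_D = k_d/k_a$. Initial values are
deterministic: $k_d$ from a log-linear regression of the highest
concentration's dissociation tail, then $R_\mathrm{max}$ and $K_D$ from a
double-reciprocal regression of the near-plateau responses. Mass-transport
and drift terms are deliberately absent, matching a plain 1:1 analysis;
reference-channel subtraction is out of scope. The choice of a global fit
(rather than per-concentration averaging) follows standard practice; the
instrument software's exact mode is not public.

## DSF melting points

A two-state melt is simulated as
$F(T) = (a_0 + a_1 T) + \frac{(b_0 + b_1 T) - (a_0 + a_1 T)}{1 + e^{(T_m - T)/s}}$,
optionally extended to several transitions as a sum of logistic steps over a
common pre-baseline.

The vendor's proprietary midpoint algorithm is not public, so `extract_tm()`
offers two standard estimators. The default `derivative` method smooths the
curve with a Savitzky–Golay filter (cubic, 15-point window on the default
0.5 °C grid), takes central-difference derivatives, and reports the first
(lowest-temperature) local maximum that qualifies as a transition, refined by
three-point parabolic interpolation. A peak qualifies when it reaches 10% of
the global derivative maximum and five times the derivative noise floor
(median absolute derivative); flat or amplitude-zero curves therefore fail
with a no-transition error rather than returning a number. The `sigmoid-fit`
method refits the two-state model inside a window around that first peak and
is roughly five-fold more precise at realistic noise, which is why the
variant-panel ΔTm comparisons use it. "First transition" means the
lowest-temperature qualifying peak, so a two-domain melt reports the less
stable domain. `delta_tm()` is a plain difference and insists both estimates
came from the same method; it is invariant to any shared affine rescaling of
the fluorescence axis.

## SEC species quantification

Chromatograms are modelled as Gaussian peaks over a linear baseline in the
elution order aggregate < dimer < monomer < fragment. `quantify_species()`
follows routine SE-HPLC practice: a linear baseline is fitted to configured
blank regions (by default the leading and trailing 5% of the trace),
the baseline-subtracted signal is integrated by the trapezoidal rule inside
fixed retention-time windows, and the areas are normalized to fractions.
Fixed windows, not peak deconvolution, are used deliberately — reported
stability data are area classes, and windows are what routine batch analyses
apply. Strongly overlapping species therefore exchange tail area
symmetrically; the tests quantify this against the analytic Gaussian overlap.
`summarize_timecourse()` reduces a storage series to per-week monomer
percentages, the minimum over the course and the total change.

## Pharmacokinetics

Plasma decays are fitted on the linear concentration scale (unweighted — the
source analysis does not state a weighting; log-scale weighting would be a
user-side transformation) as either
$C(t) = C_0 e^{-kt}$ or
$C(t) = C_{0\alpha} e^{-\alpha t} + C_{0\beta} e^{-\beta t}$ with
$\alpha > \beta > 0$.

The bi-exponential optimum is found by an exhaustive search over a
log-spaced rate grid with the two amplitudes profiled out exactly by linear
least squares for every rate pair, followed by a Levenberg–Marquardt polish
(also started from classic curve peeling: terminal log-linear regression,
then a log-linear fit of the positive early-phase residuals). This costs a
few hundred 2-parameter linear solves per fit and removes the local-minimum
fragility that plain descent shows when the second phase is weak or absent.

Model selection uses the extra-sum-of-squares F-test:
$F = \frac{(SS_\mathrm{mono} - SS_\mathrm{bi})/2}{SS_\mathrm{bi}/(n-4)}$
against $F(2, n-4)$, choosing the two-compartment model iff $p < 0.05$. One
calibration subtlety is documented rather than hidden: with amplitudes
constrained non-negative (the physically meaningful bolus solution, and the
default of `fit_biexponential()`), the null hypothesis sits on the boundary
of the parameter space and the test is conservative — simulations under a
mono-exponential truth select the richer model in well under 5% of datasets.
With `constrain_positive = FALSE` the unconstrained nested family is fitted,
the setting under which the F-test attains (approximately) its nominal size
and the default behaviour of common PK software. The package's calibration
checks run 1000 simulated null datasets of 10 time points with additive
Gaussian noise — the assumption set under which the F-distribution reference
is exact in the linear limit.

`nca()` computes the non-compartmental parameters exactly as defined:
AUC(0–t_end) by the trapezoidal rule over the observed (group-mean,
uncensored) points with the fitted model value anchoring C(0) — no sample
exists at t = 0, and an integral "from 0" needs one; AUMC likewise on
$t \cdot C$; CL = dose/AUC scaled to mL/h/kg; $t_{1/2,\beta} = \ln 2/\beta$;
MRT by the model moments
$(C_{0\alpha}/\alpha^2 + C_{0\beta}/\beta^2)/(C_{0\alpha}/\alpha + C_{0\beta}/\beta)$
by default (1/k for a mono fit), with a trapezoid AUMC/AUC alternative;
$V_{D,ss} = CL \times MRT$. Model-based MRT was chosen because the published
CL and $V_{D,ss}$ are presented as fit-derived; note that some printed CL
values are not exactly dose/AUC(0–144) of the printed AUC, presumably
reflecting extrapolation or per-animal fitting in the original analysis — we
flag rather than guess, and the acceptance checks use the printed numbers'
own internal arithmetic where exactness is claimed.

`censor_loq()` flags concentrations below the limit of quantification;
censored points are excluded from fitting and the AUC is truncated (with a
warning) at the last uncensored time. If fewer than five uncensored points
remain, only the mono-exponential model is fitted.

## Cross-variant statistics

Titer replicates are screened for normality (Kolmogorov–Smirnov on
standardized residuals), compared by one-way ANOVA with Tukey's HSD
(`anova_tukey()`), and the stability–expression association is tested by
Spearman rank correlation (`spearman_tm_titer()`). For n ≤ 10 the p-value is
an exact permutation probability — every arrangement of one rank vector is
enumerated in compiled code, which also handles ties correctly because tied
average ranks make all distinct arrangements equally likely. Beyond n = 10
the usual t-approximation applies. The default alternative is one-sided
positive: the working hypothesis is directional (stability helps
expression); the original report gives only a p-value without stating
sidedness, so this is our choice and a `two.sided` flag is provided.
`fold_check()` screens a value set against a reference with an inclusive
bound, used for the claim that no variant's $K_D$ moved by more than
two-fold.

## The synthetic study and what it does (not) show

Every generator draws from one seed (`generator_config()`), emits its truth
table alongside the data, and reproduces byte-identically under the same
seed. Defaults are the study's conditions:

* **Panel** — five planted framework mismatches (1, 3, 4, 66, 79) on an
  IGKV3-20-like backbone, three mutation regions, 2^3 combinations plus the
  lysine parental: nine entries.
* **SPR** — five analyte concentrations 3.125–25 nM, association 0–300 s,
  dissociation to 600 s, 0.5 RU noise; per-variant truths drawn inside the
  published envelopes ($k_a$ 1.3–3.1 × 10⁵, $k_d$ 2.9–6.4 × 10⁻⁴) with every
  $K_D$ constrained within two-fold of the parental truth (1.1 × 10⁵ /
  2.9 × 10⁻⁴).
* **DSF** — Tm offsets keyed to region content: ~+0.5 °C for the 1–4 or 66
  single regions, ~+2 °C for anything carrying 79, ~+4 °C for the synergistic
  1–4 + 66 combinations; noise 1% of the 5000-unit amplitude on a 0.5 °C
  grid from 25–95 °C.
* **Titer** — lognormal replicates (titers are positive and right-skewed),
  CV 20%, five replicates per variant, matching the visible spread of the
  reported expression experiments; fold effects of 3–5× for the lone
  position-66 glycine reversion and 4–10× for its combinations, neutral
  otherwise.
* **SEC** — starting monomer fractions 0.89 (parental) to 0.975 (fully
  germlined), declining by 4 vs 2 percentage points over 12 weeks; fixed
  retention times 6.0/7.2/8.6/11.0 min, σ = 0.12 min.
* **PK** — doses 5/15/30 mg/kg, sampling at {1, 2, 4, 8, 24, 48, 72, 96,
  120, 144} h (a conventional IgG schedule; the study does not list its
  draw times), n = 4 animals, 3% multiplicative lognormal noise, LOQ
  0.15 mg/L, distribution half-life 5 h (never printed; configurable),
  truths taken from the published two-compartment parameters. The parental
  5 mg/kg arm's parameters were not determinable in the study (the tail fell
  below the LOQ after 48 h), so its generating curve is imputed: a
  mono-exponential with dose-scaled C(0) ≈ 3.2 mg/L and a 12 h half-life.
  The faster-than-dose-proportional decay is forced by arithmetic — under
  dose-proportional decay the 15 mg/kg arm at 144 h would sit below the
  5 mg/kg arm at 72 h, making the reported censoring pattern impossible
  under one assay LOQ — and is consistent with the parental clearance rising
  with dose. The imputed row is flagged `imputed` in the truth table.

What passing tests show: the estimators recover planted truths at the
study's noise levels, the identities the parameters must satisfy hold
exactly, and the printed summary quantities are internally consistent. What
they do not show: behaviour on real instrument data — real sensorgrams carry
drift, bulk shifts and mass-transport limitation; real melt curves have
sloped, non-linear baselines and aggregation exotherms; real chromatograms
have asymmetric peaks; real PK has inter-animal variability far above 3% and
possible target-mediated disposition. Figure-only quantities of the original
study (absolute Tm values, titer bar heights, weekly monomer percentages,
database residue frequencies, the exact correlation p-value) are emulated by
effect-size-faithful generators, not reproduced.

## Problem sizes and numerical choices

The shipped tests run the full suite in about a minute: 20-seed recovery
loops for SPR rates and the PK terminal half-life, 50 seeds for Tm recovery,
40 seeds for ANOVA and F-test power, and 1000 simulated datasets for the
F-test size check. Tolerances follow the quantity's own precision: exact
identities to 1e-9 or tighter, estimator recovery at the level the noise
model implies (5% for rate constants, 0.2 °C for Tm differences, half a
percentage point for SEC fractions). Fits use log-parameterization for
positivity, deterministic initialization everywhere, and fail loudly (with
the last estimates in the message) rather than returning silent defaults.

## Limitations

Chothia/IMGT numbering, nucleotide input, CDR grafting and humanness scoring
are out of scope. The germline reference is a synthetic toy set; real
assignments need the public databases. Subcutaneous absorption and
mixed-effects (per-animal) PK modelling are not implemented — fitting uses
group means, matching how the source data are presented.
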