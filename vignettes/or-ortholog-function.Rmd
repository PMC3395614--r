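---
title: "Comparing sequence and functional evolution of odorant receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sequence and functional evolution of odorant receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orevo)
library(dplyr)
```

Odorant receptors (ORs) are the largest mammalian GPCR family and evolve
rapidly. A recurring question is how well sequence divergence between
orthologous receptors predicts divergence of their *in vitro* function —
which odorants they respond to (selectivity), at what concentration
(potency, EC50), and how strongly (efficacy, the dynamic range of the
response). `orevo` implements the full analysis chain for that question:
pairwise sequence-evolution metrics, luciferase-screen processing,
dose-response fitting and comparison, sequence-versus-function statistics,
an odor-panel selector, and seeded simulators so that every stage can be
exercised against known ground truth.

## Sequence metrics

All sequence operations work on a `coding_pair`: two codon-aligned
nucleotide sequences plus their translations. The package does not align;
orthologous OR ORFs are near-equal length and codon-aware alignment is a
standard external step. Gaps must cover whole codons, and every metric
drops codons gapped in either member (pairwise deletion).

**Jukes-Cantor distance.** The observed mismatch proportion $p$ over
compared sites is corrected as $d = -\tfrac34 \log(1 - \tfrac43 p)$,
substitutions per site. $p \ge 3/4$ is outside the model domain and raises
a typed saturation error rather than returning infinity, so downstream
statistics stay well defined.

**Grantham distance.** The residue-pair matrix is rebuilt from the
underlying physicochemical properties (composition, polarity, molecular
volume) with the classical weights, and rescaled so the mean over the 190
heterotypic pairs is exactly 100; entries then agree with the published
integer matrix to rounding (Ser-Leu 145, Leu-Ile 5). The sequence-level
distance is the *mean* per-site matrix entry over compared positions, not
the sum — this keeps values comparable between the full ORF and a
binding-site subset of positions. The 22 putative ligand-binding residues
used in the field are cited as residues, not alignment coordinates, so the
position set is a configuration input; `binding_positions_22aa()` ships a
provisional synthetic stand-in (22 evenly spaced positions) for simulated
data.

**Nei-Gojobori dN/dS.** Sites: each codon position contributes the
fraction of its three possible changes that are synonymous; changes
creating stop codons count as nonsynonymous, so $S + N = 3$ per codon
exactly. Differences: codons differing at $k$ sites are resolved by
averaging over all $k!$ single-step pathways that avoid stop codons; if
every pathway crosses a stop, the unrestricted average is used. The
proportions $p_S = S_d/S$ and $p_N = N_d/N$ receive the same Jukes-Cantor
correction, and $\omega = d_N/d_S$ carries an explicit undefined flag when
$d_S = 0$ (identical or synonymously-identical pairs), rather than an
infinity or NaN that would poison rank statistics. Only the plain 1986
counting method is implemented; the modified variant and likelihood-based
branch tests are out of scope.

**Trees.** Distance matrices (e.g. mean Grantham distance between all
receptor pairs) go to Neighbor-Joining via `ape`; the two-taxon edge case
is handled explicitly. Newick export is provided for interoperability.

## Luciferase screen

Raw wells carry firefly and Renilla luminescence. Each well is first
normalized to its Renilla reading (transfection-efficiency control), then
min-max scaled by the extremes of a declared scope — the whole plate set
(default) or each plate separately. The scope and anchors are recorded in
the result because the choice is auditable, not innocuous. Responses are
reported relative to the receptor's no-odor control mean, so inhibitory
odors are negative and stay negative.

Agonist calls use a two-sample t test per receptor × odor cell against the
no-odor wells at the Bonferroni level $\alpha/42$ (two-sided). The test is
pooled-variance by default — with triplicates there is little information
to estimate separate variances — and Welch is available via
`var_equal = FALSE`. Non-significant cells are zeroed only in the display
copy (`tuning_responses()`); the underlying means are never modified.

Tuning curves order the panel center-out by the reference receptor's
response: rank 1 at the center, then alternating right, left, right.
The rightward start is arbitrary but deterministic; ties break
lexicographically by odor label. Variants within an ortholog set reuse the
reference ordering, which is what makes the curves visually comparable.

## Dose-response analysis

The model is the three-parameter logistic with Hill slope 1:
$y = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) / (1 +
10^{\log EC_{50} - x})$, $x$ in log10 molar. The default design mirrors
the screening practice: seven decades from 10 nM to 10 mM, triplicates.
Fitting is Levenberg-Marquardt least squares, multi-started from a grid of
logEC50 values spanning the tested range with bottom/top initialized at
the data extremes; the best converged start by residual sum of squares
wins. Multi-start matters for flat or noisy curves, where a single start
can stall in a local minimum. A flat dataset yields a *flagged* degenerate
fit (top ≈ bottom), never an exception, because screens legitimately
contain non-responders. Standard errors come from the curvature at the
optimum, and 95% confidence intervals use $t_{n-3}$.

An odorant is accepted as an agonist only if three criteria hold: the 95%
CIs of top and bottom do not overlap; the standard deviation of the fitted
logEC50 — read as its asymptotic standard error, the quantity a standard
curve fitter reports — is below one log unit; and the
extra-sum-of-squares test finds the receptor's curve significantly
different from the vector-only control. Failed criteria are reported by
name.

Pairs of receptors are compared by the extra-sum-of-squares F test: one
shared curve (3 parameters) versus two separate curves (6), so
$F = ((SS_{pool} - SS_{sep})/3)/(SS_{sep}/(n-6))$ with $F(3, n-6)$. With
the standard design ($2 \times 7 \times 3$ observations) the denominator
df is 36. When the test rejects, the pair is classified on the concordance
of potency and efficacy: `a_hyperfunctional` when A has both the lower
EC50 and the larger span, `a_hypofunctional` in the mirror case,
`undefined` when the two move discordantly, and `not_comparable` when
either member fails the agonist gate. The classifier is deliberately
defined only on the (EC50 direction, span direction) pair; prose
descriptions of hyper/hypofunction elsewhere swap the words potency and
efficacy, and pinning the rule to the parameters removes the ambiguity.
$\alpha = 0.05$ throughout; fits and tests always run on the
Renilla-normalized responses, while `normalize_curve_set()` (max-of-set or
reference scaling) is display-only and never feeds the F test.

## Sequence versus function

Functional distance between two receptors is $1 - R$, the Pearson
correlation of their 42-odor response profiles, computed on the
significance-zeroed display copies over the full panel (zeros included) —
correlating only responsive odors would discard exactly the information
that distinguishes selectivity change from magnitude change. A pair
enters the analysis only if both members respond to at least
`min_responsive` odors (default 3; the threshold is exposed because the
inclusive and exclusive readings of "more than three" both appear in
practice and the choice is reported with the output).

Rank correlations are Spearman with mid-rank ties and two-sided t
approximation p values. Common-ligand rates report exact counts alongside
display-rounded percentages. Group comparisons (e.g. ortholog versus
paralog Grantham distributions) use the Wilcoxon rank-sum z with
tie-corrected normal approximation, signed so that $z < 0$ means the first
group is stochastically smaller. Distribution summaries expose the
box-plot order statistics (min, 10/25/50/75/90% quantiles with linear
interpolation, max).

## Odor-panel selection

A chemically diverse panel is chosen from a descriptor matrix (odorants ×
physicochemical descriptors; the descriptors themselves are an input, not
re-derived). Columns are z-scored before clustering because descriptor
scales are wildly heterogeneous. Partitioning is k-means with seeded
greedy k-means++ initialization (candidates drawn proportional to squared
distance, keeping the one that most reduces the potential) and ten
restarts keeping the lowest within-cluster sum of squares; everything is
deterministic given the seed. Per cluster, the known-active odorant
nearest the centroid is selected, else the nearest odorant outright —
diversity with a bias toward ligands that have a chance of producing a
response.

## What the simulators emulate — and what they do not

`simulate_ortholog_pair()` evolves two descendants of a random stop-free
ORF by proposing point mutations uniformly over sites (optionally
transition/transversion weighted) and accepting synonymous proposals
always, nonsynonymous ones with probability $\omega$, stops never. For a
target $\omega > 1$ the scheme inverts (synonymous acceptance $1/\omega$).
This acceptance scheme was chosen over full codon-model matrix
exponentiation because it is simple, auditable, and — since the proposal
process is exactly the uniform-mutation model underlying the NG86 site
counting — the realized dN/dS tracks the target: at 300 codons and target
0.3 the mean NG86 estimate over a thousand replicates is within ±0.05.
What it does not model: codon-usage bias, indels, CpG hypermutability,
rate variation across sites.

`simulate_screen()` and `simulate_dose_response()` generate well-level
plates at the study conditions: 42 odors in triplicate, a handful of
agonists per receptor with geometrically decaying effects, a small
fraction of inhibitory odors, Gaussian homoscedastic noise (default 2% of
the ratio scale for screens, 5% of the set span for dose-response;
log-normal noise is available since luciferase errors are roughly
scale-proportional). They do not model plate-position effects, reader
drift, or transfection-batch structure — which is precisely why the
normalization scope is recorded rather than assumed away.

`simulate_study()` composes these into 12 ortholog trios (reference plus
two variants at 1× and 3× branch length, emulating a human/chimp/macaque
design) plus one longer-branch paralog per set. The coupling between
levels is explicit: each variant's tuning profile is the reference
profile attenuated plus a perturbation whose standard deviation grows
with the realized nonsynonymous divergence of the pair, so
sequence-function correlation is genuinely present; responder status for
the common ligand is Bernoulli at 82% for orthologs and 33% for paralogs,
the rates observed in comparable experimental work; responders draw
logEC50 shifts (SD 0.7 log units) and span scalings (log-normal, SD 0.5)
large enough that most comparable pairs differ detectably. Passing tests
on this material demonstrates that the estimators recover what the
generator put in — not that real plates are this clean.

## Numerical choices and degenerate inputs

* Saturated distances (JC or NG86 rate components) are typed errors or
  per-component flags, never infinities.
* Undefined $\omega$ (dS = 0) is `NA` plus a flag; tables propagate it.
* Flat dose-response data: flagged degenerate fit; zero-span normalizing
  members are errors in display scaling.
* Exact-fit extra-SS comparisons (separate SS = 0, pooled > 0) report
  p = 0 with an `exact_fit` flag.
* Ties: tuning order breaks by odor label; k-means selection breaks by
  odorant id; rank statistics use mid-ranks with tie-corrected variance.
* Empty k-means clusters are handled by re-seeding that restart.

## Problem sizes

The test-suite simulations use the sizes the methods were designed for:
500 replicates for 3PL bias/coverage and extra-SS type-I error, 2000 null
screens for family-wise error, 1000 replicates of 300-codon pairs for
simulator calibration, and 12-set studies for end-to-end recovery. The
acceptance script (`scripts/acceptance.R`) re-runs a 12-set study plus
scaled calibrations (300/200/1000 replicates) from a single `--seed`.

## A worked example

```{r example, eval = FALSE}
res <- run_study("study-out", seed = 1, n_sets = 12)
res$compare$correlations   # Spearman rho of each metric vs 1 - R
res$compare$rates          # common-ligand response rates by stratum
res$dr$summary             # classification label fractions
```

## Known limitations

* Only the 3-parameter logistic (Hill slope 1) is fitted; variable-slope
  and biphasic curves are out of scope.
* NG86 is the only dN/dS estimator; no ML codon models or branch tests.
* The default 22-residue binding-site set is a synthetic placeholder;
  supply experimentally motivated coordinates for real analyses.
* The normal-approximation rank-sum z is inaccurate for very small groups
  (< ~8 total observations) where an exact test would be preferable.
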