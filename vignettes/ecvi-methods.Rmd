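---
title: "Methods: extreme-climate indices, homoclimatic zoning and the Alkire-Foster vulnerability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extreme-climate indices, homoclimatic zoning and the Alkire-Foster vulnerability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvi)
```

This package implements a three-stage analysis of health-related
vulnerability to climate extremes: (1) reduce daily weather series to seven
extreme-climate indices per region; (2) cluster regions into two
homoclimatic zones with a Bayesian Grade of Membership (GoM) model on the
quintile-coded indices; (3) estimate a weighted, population-weighted
Alkire-Foster vulnerability index (ECVI) over 18 indicators in three
dimensions, with exact decompositions, cutoff diagnostics and
disease-incidence stratification. A seeded synthetic-study generator with
known ground truth stands in for the restricted census, hospitalization and
gridded-meteorology inputs of the original study, so every stage is
testable end to end.

## Extreme climate indices

From daily `tmax`, `tmin` and `precip` per region we compute TXx, TNx
(block maxima of daily maximum/minimum temperature), TX90p, TN90p (share of
days above calendar-day 90th percentiles), DTR (mean diurnal range), CDD
(longest dry spell below 1 mm) and R99p (precipitation total above the
wet-day 99th percentile). The multi-year reductions — one scalar per region
per index — are: mean of annual maxima for TXx/TNx, mean of annual values
for CDD and R99p, a single percentage over all days for TX90p/TN90p, and
the mean of monthly means for DTR. These follow common multi-year ETCCDI
summaries; the block choice is exposed (`block` argument) because the index
definitions themselves do not fix the multi-year aggregation.

Numerical conventions, each a single configurable constant:

* Percentile thresholds use calendar-day values pooled over all years of
  the base period in a centered 5-day window (leap days keep their own
  calendar slot; windows wrap circularly at year boundaries). No bootstrap
  correction is applied: the base period and the analysis period coincide
  here, so the out-of-base bias that motivates the correction does not
  arise.
* All empirical quantiles use linear interpolation (type 7).
* Exceedance is strict (`>`), so a constant series has TX90p = 0.
* Wet days are days with at least 1 mm, the Climdex convention.
* A month or year with more than 20% missing days for the relevant
  variable is excluded from aggregation with a warning
  (`missing_tolerance`); missing days interrupt a dry run rather than
  extending it, the conservative reading for CDD.

Quintile coding of the cross-region index distribution is rank-based with a
stable tie-break on region id, which makes it deterministic and invariant
under strictly monotone transforms of an index. An all-constant index is
degenerate — every region goes to category 1 with a warning — and is
rejected outright by the GoM stage, which requires at least two observed
categories per item. Five categories are used throughout; the coding is the
`L = 5` categorical input of the membership model.

## Grade of Membership model

Each region i holds a membership vector $g_i$ on the K-simplex and each
extreme profile k has a response distribution $\lambda_{kj\cdot}$ on the
L-simplex per item j, with cell probability
$P(Y_{ijl}=1) = \sum_k g_{ik}\lambda_{kjl}$, $\sum_k g_{ik}=1$ and
$\sum_l \lambda_{kjl}=1$. Memberships are i.i.d.
$\mathrm{Dirichlet}(\alpha_0\xi)$: $\xi$ gives expected profile
proportions and $\alpha_0$ the spread — lower $\alpha_0$ means memberships
nearer the simplex vertices, i.e. cleaner extreme profiles.

Estimation is the standard conjugate Gibbs scheme with per-(region, item)
latent profile indicators: the indicator from its full conditional, $g_i$
and $\lambda$ from conjugate Dirichlet updates, and a Metropolis step for
$(\alpha_0,\xi)$ given the memberships (log-normal random walk on
$\alpha_0$, Dirichlet proposal for $\xi$ with the exact Hastings ratio).
Priors are weakly informative and exposed in `gom_config()`:
$\mathrm{Dirichlet}(1)$ on each $\lambda_{kj\cdot}$ and on $\xi$, and a
diffuse $\mathrm{Gamma}(1, 0.5)$ on $\alpha_0$. The default chain keeps
5,000 draws after a 2,500-draw burn-in. One master seed makes draws
bit-identical across runs.

Label switching — inherent to any mixture MCMC — is undone after sampling:
each draw's profile labels are permuted to minimize the squared distance of
its $\lambda$ array to the highest-likelihood draw. With K = 2 this is a
single swap test per draw and is deterministic given the draws.
Convergence is summarized by a split-chain potential-scale-reduction factor
on the log-likelihood trace, warning above 1.1; the package never re-runs a
chain silently.

Classification uses posterior mean memberships: the dominant profile is the
argmax, the tier comes from the cutoffs 0.90 (extreme), 0.75 (high-mixed)
and 0.50 (medium-mixed), and the binary zoning reclassifies mixed tiers to
their dominant extreme profile. Exact ties go to the lower profile index
with a warning. Profiles are named by their climate signature: the profile
with the higher expected R99p category is the extreme-rain zone (ER), the
other the extreme-drought/high-temperature zone (ED-HT). A profile
characteristic is *salient* when its posterior response probability is at
least 1.2 times the category's marginal frequency in the study area.

No automated choice of K is attempted: the two-profile solution is a
modeling input here, and the package only reports fit summaries for the K
the user requests.

## The Alkire-Foster index

Eighteen indicators in three equally weighted dimensions: 7 exposure
indicators (the climate indices; deprived at or above the lower bound of
the fourth quartile), 5 susceptibility indicators (elderly, children and
poverty shares in the fourth quartile; per capita income strictly below an
absolute threshold; literacy at or below the first quartile) and 6
adaptive-capacity indicators (at or below the first quartile). Weights are
equal within dimension — 1/21, 1/15, 1/18 — and sum to one.

Two conventions deserve note. First, quartile bounds are inclusive
(`value >= Q3` / `value <= Q1`): boundary regions are deprived
deterministically rather than by floating-point accident, and the
convention is a config constant. The absolute income rule is strict
(`<`), so a region exactly at the threshold is not deprived. Second, the
published text and its cutoff table disagree on the income threshold
(R$255.00 vs R$296.8); both are retained as presets with 296.8 the
default, and no adjudication is attempted. Cutoffs are always computed on
the pooled study area and reused within subgroups — required for the
subgroup decomposition identity to hold exactly.

The index uses the weighted dual-cutoff formulation: region score
$c_i = \sum_j w_j\,\mathrm{flag}_{ij}$, vulnerable iff $c_i \ge k_p$, and,
population-weighted,

$$\mathrm{CH} = \frac{\sum_i n_i\,\mathbb{1}(c_i \ge k_p)}{\sum_i n_i},
\qquad
\mathrm{DI} = \frac{\sum_i n_i\,c_i\,\mathbb{1}(c_i \ge k_p)}
                    {\sum_i n_i\,\mathbb{1}(c_i \ge k_p)},
\qquad
\mathrm{ECVI} = \mathrm{CH}\times\mathrm{DI}.$$

At equal weights this reduces to the counting ("deprived in at least k of
I indicators") definitions; an unweighted region-counting mode
(`weighted = FALSE`) is provided for those verbal definitions. Both
decompositions are exact identities, tested to 1e-12: subgroup
($\mathrm{ECVI} = \sum_g (n_g/n)\,\mathrm{ECVI}_g$) and indicator
($\mathrm{ECVI} = \sum_j w_j\,\mathrm{CH}_j$ with $\mathrm{CH}_j$ the
population-weighted share vulnerable *and* deprived in j), with dimension
contributions as sums over member indicators.

Standard errors: the published tables report SEs without formulas, so the
package offers a nonparametric bootstrap over regions (default, B = 1000,
seeded) and a ratio-estimator linearization (CH and ECVI as
population-weighted means of censored quantities, DI by the delta method).
Bootstrapping regions treats the region panel as the sample — the natural
resampling unit for a regional index.

## Choosing the cutoff k_p

The forward-local-variance criterion computes, at each grid point p, the
population variance (divide by t) of the t curve values starting at p, and
proposes the k_p with the smallest window variance — the start of the
flattest forward stretch; ties resolve to the smallest k_p. Population
rather than sample variance keeps window scores comparable across t. The
default grid is 0.05–1.00 in steps of 0.05 with t = 3; neither is fixed by
the method, so both are config-exposed and reported in output, and the
stage-4 analysis script reports t = 4 side by side. Across groups the
criterion averages window variances over the group curves. The criterion
is advisory: it can propose a cutoff so high that almost no region remains
vulnerable (exactly the over-censoring the original analysis overrode when
its criterion suggested 45% but 25% was chosen), so every report carries
the vulnerable share at each candidate plus the CH/DI-intersection
advisory (the grid point minimizing |CH − DI|). Dominance between zone
curves is checked weakly — curve A dominates B when A ≥ B at every grid
point where either is positive — and violations are listed pointwise; no
formal dominance test is attempted.

## Synthetic studies

The generator emulates the real inputs' structure, not their physics. Two
latent regimes differ in the directions that matter downstream: the
ER-like regime has frequent wet days (dry-to-wet 0.50, wet-to-wet 0.75),
gamma wet-day amounts (shape 1.2, scale 9 mm) with rare heavy events (2%
of wet days gain an exponential excess, mean 60 mm) and cooler maxima
(30°C, diurnal range 7°C); the ED-HT-like regime has long dry runs
(dry-to-wet 0.06), hotter maxima (35°C) and a wider diurnal range (11°C).
Memberships are $\mathrm{Dirichlet}(\alpha_0\xi)$ with $\alpha_0 = 0.5$,
$\xi = (0.5, 0.5)$ — clear-cut profiles at balanced proportions — and each
region's weather mixes the regime parameters by membership.
Socioeconomic indicators are a baseline plus a dominant-zone effect plus
Gaussian noise, with default effect signs making the ED-HT zone worse off;
populations are log-normal; disease counts are
$\mathrm{Poisson}(n_i \cdot \mathrm{rate}_i/10^5)$ with
$\log(\mathrm{rate}_i)$ linear in the region's weighted deprivation score
(baseline 400 per 100,000, slope 2.5), giving rates spanning roughly the
few-hundred-to-two-thousand range plausible for climate-sensitive
infectious-disease hospitalizations. All values were fixed once as part of
the study design; the default `"study"` profile is 62 regions and 34 years
of daily data, and a `"fast"` profile (30 regions, 3 years) keeps test
runs small.

What the generator does *not* emulate: spatial autocorrelation, realistic
weather physics, seasonality of disease counts, or measurement error in
the indicator panel. Passing tests therefore demonstrate that the
*methods* are implemented correctly and recover known structure under the
stated design — not that the substantive regional estimates of any real
study are reproduced. The deliberately strong indicator effects make the
synthetic ED-HT zone's vulnerability dominate more sharply than a real
panel would; the end-to-end tests assert only the qualitative orderings
(ED-HT above ER, high-incidence above low-incidence) that the design
guarantees.

## Test design and problem sizes

Unit tests pin each index to hand-computable examples and to independent
brute-force oracles (explicit per-calendar-day sorting, explicit run-length
scans) on series up to 3 years, exactly. The AF implementation is checked
against a first-principles enumeration oracle over exhaustive micro-panels
(every flag combination on 2x5, 3x4 and 4x3 region-by-indicator designs)
and against 200 random panels for the decomposition identities at 1e-12.
GoM correctness uses the closed-form conjugate reduction at K = 1 (the
posterior mean of $\lambda$ has an exact Dirichlet-multinomial form,
checked within Monte-Carlo error), a constructed label-swapped chain that
alignment must undo, and recovery runs on the well-separated two-profile
design: 60 regions, 5 seeds at the full 5,000/2,500 chain length, with at
least 90% of clearly-assigned regions (true dominant membership at or
above 0.75) classified into their true zone. Shorter chains (a few hundred
draws) are used in the unit suite where only invariants, not posterior
accuracy, are at stake.
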