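---
title: "Multi-group grooming network analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-group grooming network analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groomnet)
```

## The problem

Zoo-housed bonobos live in many small groups of differing size and
composition. Per-individual grooming behaviour is shaped both by who the
animal is (sex, age, rearing history) and by the group it lives in (size, sex
ratio). `groomnet` implements the full analysis chain for such multi-group
studies: scan-sampling records are turned into one directed, weighted
grooming network per group; five node-level measures are computed and
standardized for group size; dominance hierarchies are estimated from
ad libitum agonistic data with randomization tests; and linear mixed models
relate the measures to individual and group traits.

## From scans to edge weights

A scan records the instantaneous behaviour of every group member every 10-15
minutes. The edge weight from A to B is the *index of interactions*:

$$ w_{AB} = \frac{\#\{\text{scans where A groomed B}\}}
                 {\#\{\text{scans}\} - \#\{\text{scans where A and B were both out of sight}\}} $$

Only *simultaneous* invisibility removes a scan from a dyad's denominator: if
one animal is visible and not grooming the other, that is informative. The
denominator is therefore per-dyad; a single shared denominator (total scans)
is available behind `shared_denominator = TRUE` since observation protocols
differ in whether visibility was dyad-resolved. Mutual grooming is two
directed events. A scan in which an actor grooms at most one receiver is the
expected case; multiple receivers per scan are counted but flagged with a
validation warning.

## The five node measures

With $s^{out}_i = \sum_j w_{ij}$, $s^{in}_i = \sum_j w_{ji}$ and
$M = W + W^\top$, $s_i = \sum_j m_{ij}$:

* **out-/in-strength** - total grooming given / received;
* **disparity** $Y_i = \sum_j (w_{ij}/s^{out}_i)^2$ - concentration of
  grooming given: $1/k$ for an even split over $k$ partners, 1 for a single
  partner; undefined (missing, never zero) when no grooming was given;
* **affinity** $a_i = \sum_j m_{ij} s_j / s_i$ - the edge-weighted mean
  strength of one's partners (an unweighted variant sits behind
  `weighted = FALSE`);
* **eigenvector centrality** - leading eigenvector of $M$, max-scaled to 1
  per group.

Two measures use the symmetrized matrix because they describe total dyadic
grooming involvement rather than its direction; disparity uses out-going
edges (grooming *given*; a `total` switch exists). Affinity and eigenvector
centrality are withheld from groups with fewer than 5 members, where indirect
connectedness is not biologically meaningful.

Eigenvector centrality is computed by shifted power iteration
($M + cI$, $c$ the largest row sum) with tolerance $10^{-10}$: the shift makes
the dominant eigenvalue strictly largest in magnitude, so the iteration also
converges on bipartite-like weight patterns where the raw iteration would
oscillate. The tests verify agreement with a dense eigendecomposition to
$10^{-8}$ on random networks. Disconnected networks are handled per connected
component (each max-scaled to 1) and flagged; isolated nodes get missing
values. A network with no edges at all is an error, not a zero vector.

### Group-size standardization

Strengths are divided by the number of available partners ($N-1$). For
disparity we use the *deviation from edge-weight disparity*
$\Delta Y_i = Y_i - 1/k_i$, the excess concentration over the even-split
baseline with the same number of partners; this is the unique parameter-free
deviation against the uniform expectation, and it is non-negative by the
Cauchy-Schwarz inequality. Affinity and centrality are scaled to the maximum
value within the individual's own network. When the standardized battery is
modelled, group size is dropped as a predictor.

### Correlation screen

All five measures are computed from the same matrix, so they are screened
pairwise (Pearson) before modelling; any pair with $|r| > 0.70$ is flagged.
Measures enter separate models in any case.

## Dominance

Wins are flee-upon-aggression events. The chance-corrected dyadic index
$D_{ij} = P_{ij} - (P_{ij} - 0.5)/(n_{ij} + 1)$ (raw proportions behind
`method = "Pij"`) feeds normalized David's scores
$\mathrm{normDS} = (DS + N(N-1)/2)/N$, which sum to $N(N-1)/2$ by
construction and are mean-centered within groups before cross-group use.
Steepness is the absolute slope of the scores on descending rank; its null
distribution keeps every dyad's interaction count and redraws wins as fair
coins. Landau's $h$ is computed from dominance counts $V_i$ (ties and unknown
dyads contribute 0.5), and $h' = h + 6u/(N^3 - N)$ corrects for the $u$
unknown dyads; significance compares $h'$ against random complete dominance
orders. The exact randomization scheme used by legacy tools for $h'$ is not
fully documented, so a two-step variant that randomly fills unknown dyads is
provided behind `fill_unknowns = TRUE`; the single-step null is the default.
All p-values carry the $+1$ small-sample correction, so they live in
$[1/(n_{rand}+1), 1]$ and cannot be zero. Randomization counts default to
10,000 and are always seedable. Groups pass the hierarchy screen when both
steepness and linearity are significant at $\alpha = 0.10$ - a deliberately
relaxed level, because decided agonistic interactions are rare in this
species and a stricter level would leave almost no groups; rank results are
descriptive (rank-age plots) and never enter the grooming models.

## Mixed models

Each measure is modelled separately with fixed effects sex, mean-centered age
and its square (centering removes the age/age² collinearity; the VIF check
with threshold 5 guards the rest), rearing history, group size and sex ratio,
plus two-way interactions of sex with each other predictor, and random
intercepts for individual identity (repeated observations across group
compositions) and group identity. Reference levels are female and
mother-reared. Rosner's generalized-ESD test (up to 3 outliers, $\alpha =
0.05$) screens each response before fitting. Backward elimination removes one
term at a time under ML, respecting marginality (interactions before their
main effects, age² before age), until no removal lowers the AIC; ties go to
the larger drop, then alphabetical order. The final model is refit with REML
and reported with Satterthwaite degrees of freedom - these df (and hence
exact t and p values) are solver-dependent and are not treated as exact
reproduction targets. Singular fits (a variance component estimated at zero,
common when most animals are observed once) are recorded, not hidden.
Tukey-adjusted contrasts on estimated marginal means unpack factor
interactions such as sex-by-rearing. Shapiro-Wilk statistics and residual
plots are reported without automatic action.

One property of this selection procedure deserves emphasis: backward AIC
retains a truly-null term whenever removing it would raise the AIC, which
happens with asymptotic probability $P(\chi^2_1 > 2) \approx 0.16$ per
decision; with a sex interaction above a null main effect and the marginality
rule, a null group-level predictor survives in roughly a quarter to a third
of runs. Simulation checks of "null terms get eliminated" must therefore
expect elimination rates around 65-85%, not near 100% - this is a property
of AIC selection itself, not of the implementation.

## The synthetic generator

The generator emulates the study conditions: 22 groups of 3-15 adults
(median 6 in the fixed-composition archive), sex ratios within 0.20-2.00,
ages 7-71, about a quarter of animals atypically reared, 274-1103 scans per
group, and animals re-observed across group compositions (probability 0.35
per slot) so the individual random intercept is estimable. Grooming is
generated per scan and ordered dyad with probability
$\mathrm{logit}^{-1}(g_i + r_j + d_{ij})$, where the giver propensity $g_i$
carries the plantable effects (sex, rearing deficit, quadratic age peaking at
25 years), $r_j$ is a receiver effect (female bonus 0.25 - females are
preferred grooming targets), and $d_{ij}$ adds female-female assortment (0.30)
plus dyadic noise; each animal is out of sight with probability 0.05 per scan
and grooms at most one receiver per scan (instantaneous sampling semantics).
The intercept (-4.0 on the logit scale) is calibrated once so that average
out-strength is about 0.08, the observed scale of male grooming effort.
Agonistic events are Poisson per dyad (rate 1.5) with win probabilities
$\mathrm{logit}^{-1}(dom_i - dom_j)$ from latent dominance values that follow
a quadratic age trend per sex (female peak near 35, male minimum near 25,
females above males on average).

`synthetic_bonobo_study()` freezes a specific composition - 22 groups, 136
individual-in-group records from 84 unique animals, the published
sex-by-rearing sample sizes, 14 female-biased groups, and three fully
peripheral animals in large groups so that the indirect-measure analysis set
is 126 records from 20 groups. The composition is reconstructed from the
published summary tables; every grooming and agonistic *value* in it is
synthetic, generated under the defaults above. Tests that pass on this
archive therefore validate the machinery and the compositional bookkeeping,
not the field data: emergent quantities that depend on real behaviour (e.g.
the sign of the out-strength/affinity correlation, outlier counts, exact
means) should not be read off the synthetic archive as empirical findings.

## Problem sizes used in the checks

Property checks use 200 random networks (sizes 3-15) and 200 random win
matrices; the steepness null calibration uses 500 replicate matrices with 199
randomizations each; parameter recovery runs 100 seeded end-to-end studies of
about 33 groups (~300 records) each; null-term elimination runs 100 seeded
backward reductions on the 136-record design. These sizes keep every rate's
simulation standard error small relative to its acceptance band.

## Known limitations

* The scan generator draws dyads independently within a scan (apart from the
  one-receiver rule); real grooming bouts persist across consecutive scans,
  so synthetic edge-count variances are mildly optimistic.
* Ages are fixed per animal across group compositions, although real repeated
  observations span years.
* Kinship (mother-son bonds), female transfer dynamics and bout durations are
  not modelled; effects that hinge on them cannot be planted.
* Eigenvector centrality on disconnected networks is a per-component
  convention (each component max-scaled); other software may zero-fill minor
  components instead.
* Satterthwaite df, and therefore exact t/p values, vary across mixed-model
  solvers; signs and magnitudes of coefficients are the stable quantities.
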