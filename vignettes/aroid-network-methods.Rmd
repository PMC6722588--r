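---
title: "Methods: quantitative analysis of aroid-insect interaction webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of aroid-insect interaction webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aroidnet)
```

## The data and its published form

The package is organized around a survey of endophagous insects reared
from the infructescences of eight aroid species at three elevation strata
(250 infructescences, 34 insect species, 16,120 individuals). The raw
per-infructescence records were never deposited; what is printed are
three tables — the sampling design (units per host and stratum), the
insects-by-hosts abundance table expressed as *column percentages* with
exact per-species totals, and a per-host table of relative frequency,
relative abundance and the IFA index. The fixtures ship these verbatim,
including their mutual inconsistencies: the design table counts 77
infructescences for *D. oerstedii* where the IFA table uses 73, and so on
for four further hosts. We deliberately do not reconcile them; each
analysis uses the denominators of the table it reproduces.

## Reconstructing the count web

All network metrics need the integer web, so the column-percentage
presentation has to be inverted. Only the row (species) totals are exact
integers; the host totals are unknown. We solve for non-negative column
totals $c_j$ minimizing $\sum_i (\sum_j p_{ij} c_j / 100 - T_i)^2$ subject
to $\sum_j c_j = m$, via non-negative least squares with the equality
constraint as a heavily weighted penalty row (weight $10^4$, large against
the unit-scale percentage coefficients) followed by an exact rescaling of
the solution onto the constraint. The system is strongly overdetermined
(34 equations, 8 unknowns) and well conditioned; the worst per-species
residual on the survey table is 0.76 individuals, and `reconstruct_counts`
aborts with a residual report beyond 2 individuals. Real values
$p_{ij} c_j / 100$ are then rounded *within each row* by largest-remainder
apportionment so every species total matches its printed integer exactly
(ties broken by column position). Percentages computed at full precision
from any integer web invert exactly, which the suite checks on random
webs.

## Specialization: H2' and d'

$H_2 = -\sum_{ij} p_{ij} \ln p_{ij}$ (nats throughout, matching the
Shannon/Kullback-Leibler conventions of the underlying indices) is
standardized between marginal-preserving extremes:
$H_2' = (H_{2max} - H_2)/(H_{2max} - H_{2min})$, so 1 means maximal
concentration given the species totals and 0 means marginal-product
(opportunistic) use. Both bounds are integer tables, found heuristically:

* $H_{2max}$: floor of the proportional expectation $k_i d_j / m$ with
  remainders handed to the feasible cells with the largest fractional
  parts;
* $H_{2min}$: greedy concentration (repeatedly pair the largest remaining
  row with the largest remaining column). The first pairing matters — a
  largest-largest start can be a local optimum that no
  marginal-preserving move escapes — so every (row, column) first
  pairing is tried and the most concentrated result kept;
* both are then refined by a deterministic first-improvement hill climb
  over the $2 \times 2$ unit moves that preserve both marginals
  (increasing entropy for the upper bound, decreasing for the lower).

On all small margins we enumerate (tables of up to ~12 individuals), the
refined bounds coincide with exhaustive enumeration; on larger webs they
remain heuristic bounds, which is the standard trade-off for this index
family. On the reconstructed survey web $H_2' = 0.780$.

Species-level selectivity uses
$d_i = \sum_j p'_{ij} \ln (p'_{ij}/q_j)$ with $p'_{ij} = a_{ij}/A_i$ and
availability $q_j = A_j/m$, standardized by integer marginal-feasible
fillings of $A_i$: $d_{max}$ packs individuals into the scarcest hosts
first (capped by column marginals), $d_{min}$ is the
closest-to-proportional apportionment; both refined by single-unit shift
moves, and $d' = 0$ when the bounds coincide. The d' threshold for
calling a species "highly specialized" is not part of any estimator here;
the summary reports the count of species with $d' \ge 0.3$ as exploratory
output only.

## Niche overlap

The survey reports a single "niche overlap" number without naming the
index. We fix it to the Morisita-Horn similarity — the default abundance
overlap of the software ecosystem this analysis style comes from —
averaged over all unordered pairs of insect rows, unweighted. Pairs are
never excluded: every retained species has a positive total after
trimming, so the index is always defined. This choice reproduces the
printed full-network value (0.21).

## Modularity

Barber's bipartite modularity is maximized by label propagation: rows
start with unique labels, columns adopt the row label with the largest
modularity gain, rows answer likewise, and sweeps repeat while Q grows;
when propagation stalls, the module merge with the best positive gain is
applied and propagation resumes. Ties in label adoption go to the lowest
module id and sweeps run in ascending index order, so a single run is
fully deterministic. The repeated-restart driver adds aggregated starts
with $c = 2 \ldots \min(\text{dims})$ modules and seeded uniform-random
labelings, returning the best partition; 20 restarts is the default. On
every toy instance we can search exhaustively (all row set-partitions of
webs up to 4+5 nodes, with the provably optimal per-column assignment),
the driver attains the global maximum; on the survey web it finds
$Q = 0.535$ with 6 modules. Module membership is exploratory output — the
survey printed no partition to compare against.

## Null models

Significance uses the Patefield fixed-marginal null: tables drawn from
the multivariate hypergeometric law (sequential conditioned cells), i.e.
`stats::r2dtable`, which implements exactly that algorithm. We fix the
law deliberately — "Patefield" is sometimes read loosely as
uniform-over-tables, which is a different distribution. Ensembles default
to $n = 100$ draws; the Z-score is $(obs - \bar{x}_{null})/s_{null}$ with
the $|Z| \ge 2$ significance convention, and the empirical tail
probability uses the $(1+b)/(1+n)$ estimator so $p$ can never be 0 at
$n = 100$. Both are reported since the survey's asterisks could have come
from either rule. A statistic conserved by the marginals (the grand
total, say) yields a degenerate ensemble; this is flagged, not an error.
Because Patefield draws share the observed marginals, the H2' ensemble
computes the entropy bounds once — an exact shortcut, not an
approximation.

## Diversity and beta-diversity

Richness uses the first-order jackknife over sampling units
(infructescences), $S_{jack1} = S_{obs} + Q_1 (m-1)/m$. The survey's
phrase "jackknife based on abundance" is ambiguous: the classical
estimator is incidence-based ($Q_1$ = species in exactly one unit), so
that is the default, with the singleton-abundance variant ($f_1$ =
species with one individual) available as an option; neither is asserted
to be the one behind the printed 43.3 expected species, but the printed
completeness arithmetic (34/43.3 = 78.5%) is reproduced exactly.
Accumulation curves are sample-based random-ordering curves
(`vegan::specaccum`). Bray-Curtis dissimilarity is partitioned after
Baselga into balanced variation, $\min(B,C)/(A+\min(B,C))$, and the
abundance-gradient remainder, pairwise and multi-site (pair-sum form);
additivity is exact to $10^{-12}$ and a community whose sites differ only
by a common scale factor has balanced component exactly 0. The survey's
per-elevation beta values are *not* reproduction targets: the underlying
stratified matrices were never published, so these routines are validated
on synthetic data instead.

## IFA and the guild G-test

$IFA = rf \times ra \times 100$ combines occupancy (share of a host's
units occupied) with dominance (share of the host's individuals).
Reproducing printed values uses the IFA table's own unit denominators and
the percentage table's abundances; from raw records both quantities are
exact counts. The guild-by-host table aggregates web rows by trophic
guild (four guilds: P, S, M, P-S as labelled in the abundance table,
which we follow where the narrative text disagrees with it); the G-test
is $G = 2\sum O \ln(O/E)$ with the Williams factor
$q = 1 + (N\sum 1/R_i - 1)(N \sum 1/C_j - 1) / (6N(r-1)(c-1))$ and
$G_{adj} = G/q$ tested against $\chi^2_{(r-1)(c-1)}$. Both statistics are
returned: at $N = 16{,}120$ the correction is 2%, and the survey's
printed value matches the uncorrected $G$ (6652.4 recomputed vs 6651.66
printed) rather than $G_{adj}$ (6512).

## The synthetic generator

`generate_community()` produces per-infructescence records with the
features the analyses assume, so every stage can be tested against
planted ground truth: lognormal species-abundance dominance, host use
concentrated in planted blocks (an individual lands inside its species'
block with probability $\kappa$, uniformly outside otherwise), species
turnover along the elevation gradient via a sliding rank window over a
shuffled species order (fraction $\tau$ of the pool replaced per stratum
step, so $\tau = 0$ gives identical pools and $\tau = 1$ disjoint ones),
allocation across strata proportional to sampling effort, and a
symmetric multinomial spread over units. `survey_config()` mirrors the
survey design: 8 hosts, 34 species, the actual 123/94/33 unit layout, and
dominance (`meanlog = 3.5`, `sdlog = 3`) set so the four most abundant
species hold roughly three quarters of all individuals, the regime the
survey observed. The generator does *not* emulate phenology, tissue-level
niches within an infructescence, spatial autocorrelation among units, or
overdispersed within-unit aggregation; tests passing on synthetic data
therefore validate the estimators' algebra and recovery behavior, not any
claim about those unmodelled features of real rearing data.

Two planted-structure facts anchor the tests: with $\kappa = 1$ and equal
block weights the aggregated web is block-diagonal and the optimizer must
recover $Q = 1 - 1/k$ exactly, and mean recovered $Q$ and $H_2'$ must
increase monotonically with $\kappa$ (checked over 20 seeds).

## Numerical choices and problem sizes

Natural logarithms everywhere; HITS runs on the rectangular matrix with
`log10(x)+1` weights, tolerance $10^{-12}$, cap $10^4$ iterations, scores
scaled to max 1 per side; modularity tie-breaks and sweep order are fixed
as above; label-propagation convergence uses a $10^{-12}$ slack on Q; the
reconstruction residual gate is 2 individuals. Every stochastic stage
takes an explicit seed, restores the caller's RNG state, and the pipeline
expands one global seed into fixed per-stage seeds so adding a stage
never shifts earlier draws. The test suite works at deliberately small
problem sizes — enumeration oracles up to ~12 individuals and 4+5 nodes,
synthetic communities of 8-34 species, null ensembles of 50-100 draws —
which keeps the full suite under half a minute while still covering
every code path; the survey web itself (34 x 8, 16,120 individuals)
runs the complete pipeline in a few seconds.

## Known limitations

The entropy bounds (hence H2' and d') are heuristic beyond enumerable
sizes; label propagation is a local optimizer and, despite restarts,
carries no global guarantee on large webs; the reconstruction inherits
the two-decimal rounding of the printed percentages (its effect on the
survey metrics is within ±0.001 on H2' and overlap); and the per-elevation
analyses of the original survey cannot be reproduced numerically because
their input matrices were never published.
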