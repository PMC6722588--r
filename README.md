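# aroidnet

Quantitative analysis of bipartite insect–host trophic networks built from
per-infructescence rearing records, developed around a survey of the
endophagous insect community of eight aroid (Araceae) species sampled at
three elevations in the Los Tuxtlas Biosphere Reserve, Mexico. It is aimed
at community ecologists who rear insects from discrete plant structures
(infructescences, fruits, galls) and want the full standard analysis of the
resulting quantitative interaction web from a single package.

## What it computes

Given an integer count web `A` (insects × hosts, cell `a_ij` = individuals
of insect *i* reared from host *j*, grand total `m`):

* **Network-level specialization** `H2' = (H2max − H2) / (H2max − H2min)`,
  where `H2 = −Σ p_ij ln p_ij` is the two-dimensional Shannon entropy of
  the interaction distribution and the bounds come from marginal-preserving
  integer fillings (most even / most concentrated), refined by a
  deterministic hill climb so they agree with exhaustive enumeration on
  small tables.
* **Species-level selectivity** `d'_i`, the standardized Kullback–Leibler
  divergence of species *i*'s host use `p'_ij = a_ij / A_i` from host
  availability `q_j = A_j / m`.
* **Niche overlap**: mean pairwise Morisita–Horn similarity among insect
  rows (or host columns).
* **Modularity**: Barber's weighted bipartite
  `Q = (1/m) Σ_ij (a_ij − k_i d_j / m) δ(g_i, h_j)`, maximized by
  label propagation with module merging and repeated seeded restarts
  (DIRTLPAwb+-style).
* **Null models**: Patefield fixed-marginal randomizations with Z-scores
  and empirical p-values (`|Z| ≥ 2` significance rule).
* **Centrality**: Kleinberg HITS hub (insect) and authority (host) scores
  on `log10(x) + 1` transformed weights.
* **Diversity**: sample-based accumulation curves, first-order jackknife
  richness and sampling completeness, and Baselga's partition of
  Bray–Curtis dissimilarity into balanced-variation and abundance-gradient
  components (pairwise and multi-site).
* **Community structure**: the frequency/abundance index
  `IFA = rf × ra × 100` per host, and the Williams-corrected G-test of
  guild × host independence.

The survey's printed tables ship as plain-CSV fixtures
(`load_fixture("table1" | "table2" | "table5")`), and
`reconstruct_counts()` inverts the published column-percentage presentation
back to the integer count web (`aroid_web()`), solving host totals by
constrained non-negative least squares and restoring the exact printed
per-species totals by largest-remainder rounding. A synthetic community
generator (`generate_community()`) with planted module structure, lognormal
dominance and elevational turnover supports validation of every stage
against known ground truth.

## Worked example

```r
library(aroidnet)
fit <- analyze_community(aroid_web(), guilds = aroid_guilds(),
                         n_null = 100, n_restarts = 20, seed = 1)
summary(fit)
```

```
Community network analysis: 34 insect species x 8 hosts, 16120 individuals
  H2' = 0.780   niche overlap = 0.210   Q = 0.535 (6 modules)
  null H2prime  Z = 1735.75  (|Z| >= 2)
  null Q        Z =  265.41  (|Z| >= 2)
  null NO       Z =  -15.91  (|Z| >= 2)
  guild x host G = 6652.41 (df = 21, p = 0)
  insect d': median 0.52, 27/34 species with d' >= 0.3
  top hubs: Sym, Nit1, Mer1
```

Reading this: the web is highly specialized (`H2'` near 1 means
interactions are far more concentrated than the species totals require),
insect species barely share hosts (mean Morisita–Horn overlap 0.21), and
the network splits into 6 modules with strong modularity (`Q = 0.535`).
All three statistics sit far outside their Patefield null distributions
(`|Z| ≥ 2`), and guild composition differs strongly among hosts
(`G = 6652.4` on 21 df). The tipulid *Symplecta* and the nitidulid beetle
are the best-connected insects (hubs), and *P. tripartitum* is the most
central host (authority 1.0).

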