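---
title: "Methods: land use, water chemistry and lake microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land use, water chemistry and lake microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakemicro)
```

`lakemicro` implements an analysis chain for landscape-scale lake
microbiome surveys: a set of lakes, each with a 16S OTU count profile,
water-chemistry measurements, coordinates, a drainage-basin label, and the
fractional land-use composition of its surroundings at two scales. The
chain asks three nested questions: does land use predict water chemistry;
does chemistry predict community structure; and do taxonomic clades
respond to chemistry coherently, as groups. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
built-in synthetic generator does and does not emulate.

## Preprocessing

OTU tables enter in the QIIME-classic TSV dialect (OTUs in rows, samples
in columns, optional trailing semicolon-delimited lineage with
Greengenes-style rank prefixes, which are stripped). Three steps precede
every analysis:

* **Low-count filter** (`filter_low_abundance`, default `min_total = 5`
  reads summed over all samples): removes OTUs so scarce that they are
  indistinguishable from sequencing artifacts.
* **Rarefaction** (`rarefy`, default `depth = 25000` reads): classic
  subsampling without replacement (multivariate hypergeometric per
  sample), so all samples carry equal weight in count-based analyses.
  Samples shallower than the depth are dropped with a warning. The seed
  is a mandatory argument and is recorded in output provenance headers:
  rarefaction is the one irreducibly stochastic preprocessing step.
* **Log transform** (`log_transform`): `log10(pseudocount + x)` with
  pseudocount 1, so zeros map to zero and sparse tables stay finite. The
  pseudocount is exposed because the choice is a convention, not a fact
  about the data.

Gamma-diversity (occupancy) categories are computed on the rarefied table
by default (`prevalence_on` in `pipeline_config`), since occupancy
comparisons across samples are only fair at equal depth; the filtered
table is available as an alternative. The printed occupancy bins overlap
if read literally (an OTU in >90 % of sites is also in >50 %), so the
categories are made mutually exclusive with precedence core >
cosmopolitan > common > intermediate > rare > unique; the never-named
10–50 % band is labelled *intermediate*.

## Distance decay

Community dissimilarity (Bray–Curtis on rarefied counts; Jaccard on
presence/absence as a robustness check) is related to geographic distance
(haversine, Earth radius 6371 km) over site pairs, optionally restricted
to within- or between-basin pairs. Because the `n(n-1)/2` pairs share `n`
sites, the naive pairwise Spearman p-value is anticonservative; the
default inference is therefore a Mantel-style permutation (site labels of
the community matrix permuted jointly, default 9999 permutations,
`p = (#{|rho_perm| >= |rho_obs|} + 1)/(n_perm + 1)`). The plain Spearman
test p is reported alongside, since the point estimate `rho` is identical
either way.

## Land use → chemistry: AIC multimodel inference

For one chemistry response and the six land-use fractions, all `2^6 = 64`
first-order OLS models are fitted (Gaussian errors, identity link —
responses are continuous concentrations; a `log10` response flag exists
for right-skewed variables). Each model's AIC yields an Akaike weight
`w_i = exp(-Delta_i/2)/sum_j exp(-Delta_j/2)`; a predictor's *importance*
is the summed weight of the models containing it, and model-averaged
coefficients use shrinkage (zero-substitution) averaging, with
conditional averaging behind a flag. AIC is the default criterion; AICc
is available and advisable at n near 46. Hierarchical partitioning
(`independent_contribution`) splits the full-model R² into per-predictor
independent contributions by averaging R² gains over all entry orders.

Two numerical notes. First, land-use fractions sum to 1, so the largest
subsets are rank-deficient against the intercept; the ensemble fits
proceed with aliased coefficients dropped (`allow_aliased = TRUE`),
exactly as `lm()` behaves, while the single-fit contract
(`fit_gaussian_glm`) errors on collinearity by default. Second, the same
compositional constraint means hierarchical partitioning spreads shared
variance across correlated fractions; importance rankings are the more
stable summary on compositional predictors.

## Chemistry → community: CCA and variation partitioning

`cca()` follows the classic algorithm: with `P = Y/grand total`, row and
column masses `r, c`, the chi-square-standardized matrix is
`Q = D_r^{-1/2}(P - r c') D_c^{-1/2}` (its squared Frobenius norm — the
total inertia — equals Pearson's chi-square over the grand total; this
identity is tested). Constraints are standardized to zero weighted mean
and unit weighted variance under the site masses, `Q` is projected onto
their weighted span, and the SVD of the fitted matrix gives the canonical
axes (eigenvalue = squared singular value). Scores use scaling 2 (OTU
scores multiplied by the axis singular value; site scores are
linear-combination scores), and the constraint "eigenvectors" reported
are weighted correlations of each constraint with the LC site scores —
the conventions of the ordination software family this package follows,
against which its output is tested to machine precision. Singular values
below `1e-10` of the largest are treated as zero; collinear constraint
columns raise an error that names them.

The CCA runs on rarefied counts (correspondence analysis is built for
count-like data); whether to ordinate counts or the log-transformed table
is configurable, since conventions differ. The whole-model permutation
test uses pseudo-F `= (constrained/q)/(residual/(n-1-q))` with
unrestricted permutation of constraint rows (default 999); per-constraint
(margin) tests permute the tested column only, with the remaining columns
partialled out of both `Q` and the tested constraint (partial CCA).

Variation partitioning uses RDA on the `log10(1+x)` table — not partial
CCA — matching the variance-partitioning convention for transformed
abundances: adjusted R² (Ezekiel) for the seven subset models of
{basin land use, local land use, chemistry}, decomposed by
inclusion–exclusion into three unique, three pairwise-shared, one
three-way-shared fraction and a residual. The eight fractions sum to 1 by
construction; shared fractions may be negative because they are
differences of adjusted R² values.

## Clade coherence: the permutation tests

The ordination answers whether single OTUs track the constraints. The
clade tests ask whether a lineage behaves coherently *as a group* in the
plane of the first two canonical axes (the plane in which ordinations are
read; higher axes are deliberately ignored).

For a clade `p` with `s_p` member OTUs:

* **Clustering**: `d_p` = sum of Euclidean distances over all member
  pairs. The null draws `s_p` OTUs without replacement from the pool and
  recomputes the score `n` times (default 1000);
  `p = #{d_p >= d_random}/n`, so small p means tighter-than-random
  clustering. Ties count toward the upper tail (with a `1e-9` relative
  guard so summation order cannot break exact ties). The pool is the
  union of members over the clades of the tested rank — the question is
  "is this clade tighter than a random set of *classified* OTUs" — with
  the full ordinated OTU set available as an override.
* **Association**: `d_{p,v}` = sum of scalar projections of member
  coordinates on the unit-normalized eigenvector `v`. The null replaces
  the clade by `s_p` points from a bivariate normal with independent axes
  and the clade's own per-axis variances. The null's mean is the
  ordination origin — the anchor of the eigenvector arrows, so the score
  measures displacement *from the center of the ordination* along `v`; a
  clade-centroid-mean variant is provided (`null_mean = "centroid"`) for
  sensitivity analysis, under which the test degenerates to asking
  whether the clade's shape, not position, projects extremely. From the
  upper-tail proportion `u = #{d_{p,v} >= d_random,v}/n`, the two-sided
  `p = 2 min(u, 1-u)` is computed; direction is positive when the upper
  tail is extreme (the `> 0.975` tail at the 0.05 family level), negative
  for the lower tail.

Benjamini–Hochberg correction is applied per rank: across clades for
clustering, across the clade × eigenvector family for association. The
family is a genuine design choice (no convention fixes it); per-rank
families keep the four phylogenetic resolutions — phylum, class, order,
family — independently interpretable. The default permutation count is
1000 for both tests; 100 association draws remain available
(`n_association = 100`) but resolve the 0.025 tail only marginally, which
is why 1000 is the default. Clades below `min_clade_size` (default 5
OTUs) are skipped but still feed the clustering pool; singleton clades
have no defined `d_p`.

One consequence of running the association test on compositional data
deserves note: when one clade expands strongly along a gradient, all
other clades' relative abundances are compressed there, so apparently
"negative" associations of unrelated clades are expected — they are real
features of relative-abundance geometry, not artifacts.

## The synthetic landscape

`simulate_lake_dataset()` generates the study conditions the package is
tested under: 46 lakes in 5 basins on a Brandenburg-sized lat/lon box,
basin-specific Dirichlet land-use compositions (concentrations drawn from
Gamma(2, 0.5) + 0.3, giving realistic within-basin coherence) at two
scales, chemistry `= landuse %*% B + noise` with per-variable baselines
folded into `B` (fractions sum to 1, so constant column offsets act as
intercepts) and a dominant urban → NO₂+NO₃ coefficient (+3 mg/L per unit
fraction against 0.15 mg/L noise, chosen to put the full-model R² in the
0.7–0.9 range typical of strong land-use signals), plus smaller
arable → TP, pasture → turbidity and forest → chlorophyll effects.

Communities follow a log-linear niche model: OTU `i` in clade `p` has log
relative abundance `baseline_i + sum_k (gamma_pk + eta_ik) z_k(chem)`
with chemistry standardized (so `gamma` is in SD units), within-clade
coefficient scatter `eta ~ N(0, dispersion_p^2)`, a softmax across OTUs,
and multinomial sampling at depth 40 000 (rarefied to 25 000 downstream;
Dirichlet-multinomial overdispersion optional, default off). Per-OTU
baselines are N(0, 1.5), giving a right-skewed abundance distribution.
Three clades are planted: a *clustered* phylum (dispersion 0.05 — its
OTUs share a niche response, so they co-locate in the ordination), a
*TP-associated* phylum (`gamma_tp = +2`), and a *neutral* phylum (all
`gamma = 0`). Taxonomies are fabricated with nested classes, orders and
families so the clade tests run unchanged at every rank.

What the generator does **not** emulate: spatial autocorrelation and
mass-effect dispersal between connected lakes (an optional distance-decay
term exists solely to give the decay test something to detect), seasonal
dynamics, OTU-level phylogenetic signal beyond the clade hierarchy, and
compositional biases of amplicon sequencing. Passing recovery tests
therefore demonstrates that the statistics detect the planted structure
through multinomial sampling noise — not that real lake data satisfy the
generative model.

## Test design and problem sizes

The test suite checks each statistic against an independent oracle
(closed forms, brute-force enumeration, a generalized-eigenproblem
construction for the CCA, exhaustive-orderings Shapley values for
hierarchical partitioning, and an established ordination package for
cross-validation), calibrates every permutation test under its null
(300 replicates each, Kolmogorov–Smirnov at 0.01), and verifies parameter
recovery on 50 replicates of the default landscape (urban ranked first
for NO₂+NO₃, both planted clades detected with correct sign, chemistry
awarded the largest unique variation fraction, each in at least 90 % of
replicates). Calibration replicates use small problems (10–15 sites,
99–199 permutations) — the calibration property is size-free, and these
sizes keep the full suite in the minutes range on one CPU.

## Limitations

Adjusted-R² differences make shared variation fractions noisy and
possibly negative at n = 46; the clade tests inherit the sign ambiguity
and 2-D truncation of the ordination plane; hierarchical partitioning on
exactly compositional predictors divides shared variance by convention;
and permutation p-values have granularity `1/n_perm` — at the default
counts the smallest achievable two-sided association p is 0.002 before
correction.
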