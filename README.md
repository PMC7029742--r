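# lakemicro

Tools for asking how the landscape around a network of lakes shapes the
water they hold and the microbes that live in it. Given a 16S OTU count
table and per-lake metadata (water chemistry, coordinates, drainage-basin
membership, and fractional land-use composition at basin and local scale),
the package runs a complete, reproducible analysis chain:

1. **Preprocessing** — QIIME-classic TSV ingestion, removal of OTUs with
   fewer than 5 reads overall, rarefaction to a common depth (default
   25 000 reads, multivariate hypergeometric), `log10(1 + x)` transform.
2. **Community description** — Shannon alpha diversity, Bray–Curtis and
   Jaccard dissimilarities, and an occupancy classification of the pooled
   OTU inventory into *core* (all sites), *cosmopolitan* (>90 %), *common*
   (>50 %), *intermediate*, *rare* (<10 %) and *unique* (one site) OTUs.
3. **Distance decay** — Spearman correlation between geographic
   (haversine) and community distance over site pairs, within or between
   basins, with Mantel-style permutation inference.
4. **Land use → chemistry** — for each chemistry response, all 2^6
   first-order OLS models over the six land-use fractions; Akaike weights,
   per-predictor importance (sum of weights of the models containing it),
   shrinkage model-averaged coefficients, and hierarchical-partitioning
   independent contributions.
5. **Chemistry → community** — canonical correspondence analysis (CCA)
   with permutation tests (whole model and per constraint), and three-way
   variation partitioning (basin land use / local land use / chemistry)
   via RDA adjusted R².
6. **Clade coherence** — a permutation test asking whether a taxonomic
   clade *as a group* behaves coherently in the ordination plane: the
   clustering score `d_p` (sum of pairwise Euclidean distances between a
   clade's OTUs) is compared against random OTU sets of the same size, and
   the association score `d_{p,v}` (sum of scalar projections on an
   environmental eigenvector `v`) against a bivariate Gaussian null with
   the clade's own spread; both are Benjamini–Hochberg corrected, the
   association two-tailed at 0.025/0.975.

A synthetic lake-landscape generator (`simulate_lake_dataset()`) produces
datasets with known ground truth — Dirichlet land-use compositions per
basin, chemistry linear in land use, OTU counts from a log-linear niche
response sampled multinomially, and planted clustered/associated/neutral
clades — so every stage has a parameter-recovery test without any
download.

## Worked example

```r
library(lakemicro)

ds  <- simulate_lake_dataset(seed = 1)          # 46 lakes, 5 basins, 2000 OTUs
cfg <- pipeline_config()                        # filter 5, depth 25000, ...
res <- run_pipeline(cfg, seed = 11, table = ds$table, metadata = ds$metadata)

res$ordination
#> CCA: 46 sites x 1976 OTUs, 7 constraints
#>   total inertia 8.5193, constrained 3.0084 (35.3%)
#>   eigenvalues: 0.6301 0.5181 0.4491 0.4382 0.3726 0.3198

round(res$glm[["basin.no23"]]$importance, 2)
#> agri_hetero      arable      forest     pasture       urban       water
#>        0.48        0.36        0.85        0.39        0.98        0.37

res$decay$all
#> Distance decay (all pairs, n=1035): Spearman rho = 0.091, Mantel p = 0.1344
```

The urban land-use fraction is the top-ranked predictor of NO₂+NO₃
(importance 0.98 — it appears in essentially every well-supported model),
chemistry constraints absorb ~35 % of the community inertia, and there is
no distance decay — exactly the structure the generator plants. The clade
table `res$clades` flags the planted tightly-clustered phylum
(`q_clust = 0`) and the planted TP-associated phylum (`direction =
"positive"` on the `tp` eigenvector).

The same analysis as a narrated workflow lives in `analysis/01_simulate.R`
… `analysis/06_clade_tests.R`; each script reads the previous stage's
files and writes its tables under `results/analysis/`. Set
`LAKEMICRO_SEED` to change the seed. Real data go through the same door:
point `pipeline_config(otu_path=, metadata_path=)` at a QIIME-classic OTU
TSV and a metadata TSV.

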