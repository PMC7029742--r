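#!/usr/bin/env Rscript
# Stage 4 — does land use predict water chemistry? For every chemistry
# response and each land-use scale (whole drainage basin vs local
# surroundings), fit all 2^6 first-order models over the six land-use
# fractions, convert AICs to Akaike weights, and summarize per-predictor
# importance, model-averaged coefficients and hierarchical-partitioning
# independent contributions.

suppressPackageStartupMessages(library(lakemicro))
datadir <- "results/analysis/data"
outdir <- "results/analysis"

meta <- read_site_metadata(file.path(datadir, "metadata.tsv"))
rows <- list()
for (scale in c("basin", "local")) {
  lu <- as.data.frame(landuse_matrix(meta, scale))
  for (resp in chemistry_vars()) {
    ens <- aic_ensemble(meta[[resp]], lu)
    rows[[paste(scale, resp)]] <- data.frame(
      scale = scale, response = resp,
      predictor = names(ens$importance),
      importance = unname(ens$importance),
      avg_coefficient = unname(ens$averaged_coefficients),
      independent_r2 = unname(ens$independent),
      full_r2 = ens$full_r2, best_r2 = ens$best_r2)
  }
}
imp <- do.call(rbind, rows); rownames(imp) <- NULL
write_tsv_provenance(imp, file.path(outdir, "landuse_glm.tsv"),
                     "04 land-use model ensembles")

top <- imp[imp$scale == "basin" & imp$response == "no23", ]
top <- top[order(-top$importance), ]
message("basin-scale predictors of NO2+NO3, by importance:")
print(top[, c("predictor", "importance", "avg_coefficient", "independent_r2")],
      row.names = FALSE, digits = 3)
message(sprintf("full-model R2 for NO2+NO3 = %.2f; top predictor explains %.0f%% of it independently",
                top$full_r2[1], 100 * top$independent_r2[1] / top$full_r2[1]))
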