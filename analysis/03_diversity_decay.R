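#!/usr/bin/env Rscript
# Stage 3 — community overview: Shannon alpha diversity per lake,
# occupancy-based gamma-diversity categories (core ... unique), and the
# distance-decay question: does community dissimilarity grow with
# geographic distance, within or between basins?

suppressPackageStartupMessages(library(lakemicro))
seed <- as.integer(Sys.getenv("LAKEMICRO_SEED", "1"))
datadir <- "results/analysis/data"
outdir <- "results/analysis"

rare <- read_otu_table(file.path(datadir, "otu_table_rarefied.tsv"))
meta <- read_site_metadata(file.path(datadir, "metadata.tsv"))

alpha <- data.frame(sample_id = sample_ids(rare),
                    shannon = apply(rare$counts, 1, shannon))
write_tsv_provenance(alpha, file.path(outdir, "alpha_diversity.tsv"),
                     "03 alpha diversity")
message(sprintf("Shannon index: %.2f - %.2f across %d lakes",
                min(alpha$shannon), max(alpha$shannon), nrow(alpha)))

prev <- prevalence_categories(rare)
write_tsv_provenance(prev$otus, file.path(outdir, "prevalence.tsv"),
                     "03 prevalence categories")
message("gamma-diversity categories (% of OTUs):")
print(round(100 * prev$category_otu_fraction, 2))
message(sprintf("rare+unique OTUs carry %.2f%% of all reads",
                100 * prev$rare_unique_read_fraction))

geo <- geographic_distances(meta)
bc <- dissimilarity(rare, "bray_curtis")
basins <- setNames(meta$basin, meta$sample_id)
for (scope in c("all", "within_basin", "between_basin")) {
  dec <- distance_decay(geo, bc, scope, basins, n_perm = 1999,
                        seed = seed + 200)
  message(sprintf("distance decay [%s]: rho = %.3f, Mantel p = %.3f (%d pairs)",
                  scope, dec$rho, dec$p_mantel, nrow(dec$pairs)))
  if (scope == "all") {
    write_tsv_provenance(dec$pairs, file.path(outdir, "decay_pairs.tsv"),
                         "03 distance decay", seed = seed + 200)
  }
}
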