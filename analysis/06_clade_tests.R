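#!/usr/bin/env Rscript
# Stage 6 — do taxonomic clades behave coherently in the ordination plane?
# For each clade (phylum through family): the clustering permutation test
# (sum of pairwise distances vs random OTU sets of the same size) and the
# signed association test (sum of projections on each environmental
# eigenvector vs a Gaussian null with the clade's own spread).

suppressPackageStartupMessages(library(lakemicro))
seed <- as.integer(Sys.getenv("LAKEMICRO_SEED", "1"))
datadir <- "results/analysis/data"
outdir <- "results/analysis"

rare <- read_otu_table(file.path(datadir, "otu_table_rarefied.tsv"))
meta <- read_site_metadata(file.path(datadir, "metadata.tsv"))
ord <- cca(rare, chemistry_matrix(meta))

res <- run_clade_tests(ord, rare, ranks = c("phylum", "class", "order", "family"),
                       n_clustering = 1000, n_association = 1000,
                       seed = seed + 400)
write_tsv_provenance(res, file.path(outdir, "clade_tests.tsv"),
                     "06 clade permutation tests", seed = seed + 400)

clust <- unique(res[res$q_clust <= 0.05, c("rank", "clade", "s_p", "q_clust")])
message(sprintf("%d clade(s) significantly clustered (BH <= 0.05):", nrow(clust)))
print(clust, row.names = FALSE, digits = 3)
assoc <- res[res$direction != "none", c("rank", "clade", "vector", "u",
                                        "q_assoc", "direction")]
message(sprintf("%d clade x eigenvector association(s) called:", nrow(assoc)))
print(utils::head(assoc[order(assoc$q_assoc), ], 15), row.names = FALSE,
      digits = 3)
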