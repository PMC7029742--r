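#!/usr/bin/env Rscript
# Stage 2 — preprocessing: drop OTUs with fewer than 5 reads overall,
# rarefy every lake to 25000 reads (classic subsampling without
# replacement), and keep the rarefied table for all downstream community
# analyses.

suppressPackageStartupMessages(library(lakemicro))
seed <- as.integer(Sys.getenv("LAKEMICRO_SEED", "1"))
datadir <- "results/analysis/data"

tab <- read_otu_table(file.path(datadir, "otu_table.tsv"))
filtered <- filter_low_abundance(tab, min_total = 5)
rarefied <- filter_low_abundance(rarefy(filtered, depth = 25000,
                                        seed = seed + 100), 1)
write_otu_table(rarefied, file.path(datadir, "otu_table_rarefied.tsv"),
                seed = seed + 100)

message(sprintf("raw: %d OTUs; after <5-read filter: %d; after rarefaction: %d",
                ncol(tab$counts), ncol(filtered$counts), ncol(rarefied$counts)))
message(sprintf("all %d samples now at %d reads", nrow(rarefied$counts),
                unique(rowSums(rarefied$counts))))
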