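test_that("Shannon index matches its closed forms and bounds", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(25000, 0, 0)), 0)
  expect_equal(shannon(c(30, 10)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon(c(8, 8), base = "2"), 1)
  expect_error(shannon(c(0, 0)), "all-zero")
  # 0 <= H <= log(S), with the uniform case attaining the bound
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(12, 5) + ifelse(seq_len(12) == 1, 1, 0)
    h <- shannon(x)
    expect_gte(h, 0)
    expect_lte(h, log(sum(x > 0)) + 1e-12)
  }
})

test_that("dissimilarities match hand-evaluated formulas and metric properties", {
  x <- make_counts(c(2, 2, 2, 0), 2, 2)
  d <- dissimilarity(x, "bray_curtis")
  expect_equal(d$values["S1", "S2"], 1 / 3, tolerance = 1e-12)
  same <- make_counts(rep(c(3, 1, 4), each = 2), 2, 3)
  expect_equal(max(dissimilarity(same, "bray_curtis")$values), 0)
  expect_equal(max(dissimilarity(same, "jaccard")$values), 0)
  disjoint <- make_counts(c(5, 0, 3, 0, 0, 2, 0, 9), 2, 4)
  expect_equal(dissimilarity(disjoint, "bray_curtis")$values["S1", "S2"], 1)
  expect_equal(dissimilarity(disjoint, "jaccard")$values["S1", "S2"], 1)
  # hand-rolled Bray-Curtis oracle on a random matrix
  set.seed(9)
  m <- make_counts(rpois(5 * 8, 6), 5, 8)
  m[m == 0] <- 1
  d <- dissimilarity(m, "bray_curtis")$values
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]),
                 tolerance = 1e-12)
  }
  # Jaccard is invariant to positive rescaling of any sample
  m2 <- m; m2[2, ] <- m2[2, ] * 17
  expect_equal(dissimilarity(m2, "jaccard")$values,
               dissimilarity(m, "jaccard")$values)
  expect_true(all(d >= 0 & d <= 1))
  zero <- make_counts(c(1, 0, 2, 0), 2, 2)
  expect_error(dissimilarity(zero, "bray_curtis"), "S2")
})

test_that("prevalence categories honour their occupancy bins and precedence", {
  n <- 46
  # occupancies chosen to hit every bin and its boundaries
  occ <- c(46, 42, 30, 23, 10, 4, 2, 1)
  counts <- sapply(occ, function(k) c(rep(1, k), rep(0, n - k)))
  dimnames(counts) <- list(sprintf("S%02d", 1:n), sprintf("OTU%d", seq_along(occ)))
  ps <- prevalence_categories(OtuTable(counts))
  expect_equal(as.character(ps$otus$category),
               c("core",          # 46/46
                 "cosmopolitan",  # 42/46 = 91.3% > 90%
                 "common",        # 30/46 = 65%
                 "intermediate",  # 23/46 = 50% (inclusive upper edge)
                 "intermediate",  # 10/46 = 21.7%
                 "rare",          # 4/46 = 8.7% < 10%
                 "rare",          # 2/46
                 "unique"))       # 1 site only, not rare
  expect_equal(sum(ps$category_otu_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(ps$category_read_fraction), 1, tolerance = 1e-9)
  expect_equal(ps$rare_unique_otu_fraction, 3 / 8)
  expect_error(prevalence_categories(OtuTable(counts), rare_frac = 0.6),
               "thresholds")
})

test_that("prevalence category counts are exhaustive on synthetic data", {
  ds <- simulate_lake_dataset(small_sim_config(), seed = 5)
  ps <- prevalence_categories(ds$table)
  # every observed OTU lands in exactly one category
  expect_equal(sum(table(ps$otus$category)), sum(colSums(ds$table$counts) > 0))
  # rare+unique OTUs are below-average abundance by construction
  expect_lte(ps$rare_unique_read_fraction, ps$rare_unique_otu_fraction)
})

test_that("taxon relative abundances sum to one and pool unassigned OTUs", {
  tab <- read_otu_table(qiime_fixture_path())
  ra <- phylum_relative_abundance(tab)
  expect_equal(unname(rowSums(ra)), rep(1, 3), tolerance = 1e-12)
  expect_true("Unassigned" %in% colnames(ra))
  # symmetry: equal reads from two phyla -> 0.5 each
  counts <- make_counts(c(5, 5), 1, 2)
  lin <- cbind(kingdom = "Bacteria", phylum = c("A", "B"), class = "",
               order = "", family = "", genus = "", species = "")
  ra2 <- phylum_relative_abundance(OtuTable(counts, lin))
  expect_equal(unname(ra2[1, c("A", "B")]), c(0.5, 0.5))
  # single phylum -> 1 everywhere
  lin[, "phylum"] <- "A"
  expect_true(all(phylum_relative_abundance(OtuTable(counts, lin)) == 1))
  expect_error(phylum_relative_abundance(tab, "subspecies"), "rank")
})

test_that("environmental correlations match the closed-form oracle", {
  x <- c(1.2, 2.1, 2.9, 4.5, 5.1, 6.3, 7.7, 8.2, 9.9, 11.0)
  y <- c(2.0, 4.4, 5.8, 9.3, 9.9, 13.1, 15.0, 16.9, 19.6, 22.5)
  res <- env_correlation(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$r2, r_oracle^2, tolerance = 1e-12)
  # perfect linear and monotone-nonlinear cases
  expect_equal(env_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(env_correlation(x, exp(x), method = "spearman")$r, 1)
  expect_lt(env_correlation(x, exp(x))$r, 1)
  expect_error(env_correlation(x, rep(1, 10)), "zero variance")
  expect_error(env_correlation(1:2, 2:3), "at least 3")
})

test_that("geographic distances use the haversine form on a 6371 km sphere", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     lat = c(52, 53, 52), lon = c(13, 13, 13))
  g <- geographic_distances(meta)
  expect_equal(g$values["a", "c"], 0)
  expect_equal(g$values["a", "b"], pi * 6371 / 180, tolerance = 1e-6)
  set.seed(2)
  meta2 <- data.frame(sample_id = letters[1:6], lat = runif(6, -60, 60),
                      lon = runif(6, -170, 170))
  g2 <- geographic_distances(meta2)$values
  expect_equal(g2, t(g2))
  meta2$lat[3] <- NA
  expect_error(geographic_distances(meta2), "c")
})

test_that("distance decay recovers a planted monotone signal", {
  n <- 10
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     lat = 52 + (1:n) * 0.1, lon = 13)
  geo <- geographic_distances(meta)
  community <- distance_matrix(0.9 * geo$values / max(geo$values), "bray_curtis")
  res <- distance_decay(geo, community, "all", n_perm = 99, seed = 4)
  expect_equal(res$rho, 1, tolerance = 1e-12)
  expect_equal(res$p_mantel, 1 / 100)
  expect_equal(nrow(res$pairs), n * (n - 1) / 2)
})

test_that("basin scoping selects the right pairs", {
  n <- 10
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     lat = 52 + (1:n) * 0.05, lon = 13 + (1:n) %% 2)
  basins <- setNames(rep(c("b1", "b2"), each = 5), meta$sample_id)
  geo <- geographic_distances(meta)
  set.seed(8)
  cm <- matrix(runif(n * n), n, n); cm <- (cm + t(cm)) / 2; diag(cm) <- 0
  dimnames(cm) <- list(meta$sample_id, meta$sample_id)
  community <- distance_matrix(cm, "bray_curtis")
  within <- distance_decay(geo, community, "within_basin", basins,
                           n_perm = 99, seed = 1)
  between <- distance_decay(geo, community, "between_basin", basins,
                            n_perm = 99, seed = 1)
  expect_equal(nrow(within$pairs), 2 * choose(5, 2))   # 20
  expect_equal(nrow(between$pairs), 25)
  expect_true(all(within$pairs$same_basin))
  expect_true(!any(between$pairs$same_basin))
  expect_error(distance_decay(geo, community, "within_basin",
                              setNames(as.character(1:n), meta$sample_id),
                              n_perm = 99, seed = 1),
               "fewer than 3")
})
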