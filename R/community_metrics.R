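#' Shannon alpha diversity of one sample
#'
#' Entropy of the relative abundances, `H = -sum p_i log p_i` over OTUs with
#' positive counts. Natural log by default (the convention of the community
#' ecology software this pipeline follows); base 2 available.
#'
#' @param counts non-negative count (or abundance) vector for one sample.
#' @param base log base: `"e"` (nats, default) or `"2"` (bits).
#' @return Shannon index, a single number in `[0, log S]`.
#' @export
shannon <- function(counts, base = c("e", "2")) {
  base <- match.arg(base)
  if (any(counts < 0)) stop("validation error: negative counts", call. = FALSE)
  if (sum(counts) <= 0) stop("validation error: all-zero sample", call. = FALSE)
  vegan::diversity(counts, index = "shannon",
                   base = if (base == "e") exp(1) else 2)
}

#' Pairwise community dissimilarities
#'
#' Bray-Curtis on abundances, `sum|x-y| / sum(x+y)`, or Jaccard on
#' presence/absence, `1 - |intersection| / |union|`. Both lie in `[0,1]`.
#'
#' @param x abundance matrix, samples in rows (an [OtuTable] is accepted).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return A [distance_matrix()].
#' @export
dissimilarity <- function(x, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "OtuTable")) x$counts else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(m < 0)) stop("validation error: negative abundances", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop(sprintf("validation error: sample(s) with zero total: %s",
                 paste(rownames(m)[zero], collapse = ", ")), call. = FALSE)
  }
  d <- switch(metric,
    bray_curtis = vegan::vegdist(m, method = "bray"),
    jaccard = vegan::vegdist(m, method = "jaccard", binary = TRUE))
  distance_matrix(as.matrix(d), metric)
}

#' Occupancy-based gamma-diversity classification of OTUs
#'
#' Classifies every OTU by the fraction of sites where it occurs (count >
#' 0) into mutually exclusive categories, resolved in the precedence order
#' core > cosmopolitan > common > intermediate > rare > unique:
#' \describe{
#'   \item{core}{present at all sites}
#'   \item{cosmopolitan}{more than 90\% of sites (but not all)}
#'   \item{common}{more than 50\%, up to 90\%}
#'   \item{intermediate}{10\% up to 50\%}
#'   \item{rare}{below 10\% of sites, at 2 or more sites}
#'   \item{unique}{exactly one site}
#' }
#'
#' @param table an [OtuTable].
#' @param rare_frac upper occupancy fraction of the rare bin (default 0.10).
#' @param common_frac lower occupancy fraction of the common bin (default 0.50).
#' @param cosmo_frac lower occupancy fraction of the cosmopolitan bin
#'   (default 0.90).
#' @return A list of class `PrevalenceSummary` with: `otus` (per-OTU data
#'   frame: id, occupancy, category), `category_otu_fraction` and
#'   `category_read_fraction` (named vectors over the six categories),
#'   `rare_unique_otu_fraction`, `rare_unique_read_fraction`, and
#'   `phylum_by_category` (per-category phylum composition of OTUs).
#' @export
prevalence_categories <- function(table, rare_frac = 0.10, common_frac = 0.50,
                                  cosmo_frac = 0.90) {
  stopifnot(inherits(table, "OtuTable"))
  if (!(0 < rare_frac && rare_frac < common_frac && common_frac < cosmo_frac &&
        cosmo_frac < 1)) {
    stop("validation error: thresholds must satisfy 0 < rare < common < cosmo < 1",
         call. = FALSE)
  }
  n <- nrow(table$counts)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  occ <- colSums(table$counts > 0)
  frac <- occ / n
  category <- ifelse(occ == n, "core",
              ifelse(frac > cosmo_frac, "cosmopolitan",
              ifelse(frac > common_frac, "common",
              ifelse(frac >= rare_frac, "intermediate",
              ifelse(occ > 1, "rare", "unique")))))
  category[occ == 0] <- NA  # absent OTUs are unclassifiable
  levels <- c("core", "cosmopolitan", "common", "intermediate", "rare", "unique")
  category <- factor(category, levels = levels)
  reads <- colSums(table$counts)
  otu_frac <- as.vector(table(category)) / sum(!is.na(category))
  read_frac <- vapply(levels, function(l) {
    sum(reads[which(category == l)])
  }, numeric(1)) / sum(reads[!is.na(category)])
  names(otu_frac) <- levels
  phy <- table$lineages[, "phylum"]
  phy[phy == ""] <- "Unassigned"
  phylum_by_category <- lapply(setNames(levels, levels), function(l) {
    idx <- which(category == l)
    if (length(idx) == 0) return(numeric(0))
    sort(table(phy[idx]) / length(idx), decreasing = TRUE)
  })
  structure(list(
    otus = data.frame(otu_id = otu_ids(table), occupancy = occ,
                      category = category, row.names = NULL),
    category_otu_fraction = otu_frac,
    category_read_fraction = read_frac,
    rare_unique_otu_fraction = sum(otu_frac[c("rare", "unique")]),
    rare_unique_read_fraction = sum(read_frac[c("rare", "unique")]),
    phylum_by_category = phylum_by_category,
    n_sites = n
  ), class = "PrevalenceSummary")
}

#' @export
print.PrevalenceSummary <- function(x, ...) {
  cat("Gamma-diversity occupancy categories over", x$n_sites, "sites\n")
  print(round(100 * x$category_otu_fraction, 1))
  invisible(x)
}

#' Per-sample taxon composition at a taxonomic rank
#'
#' Pools reads per taxon at the requested rank (default phylum) within each
#' sample and returns relative abundances; OTUs unassigned at that rank are
#' pooled into `"Unassigned"`.
#'
#' @param table an [OtuTable].
#' @param rank one of [taxonomy_ranks()].
#' @return Matrix (samples x taxa) of fractions summing to 1 per sample.
#' @export
phylum_relative_abundance <- function(table, rank = "phylum") {
  stopifnot(inherits(table, "OtuTable"))
  if (!rank %in% taxonomy_ranks()) {
    stop(sprintf("validation error: unknown rank '%s'", rank), call. = FALSE)
  }
  taxon <- table$lineages[, rank]
  taxon[taxon == ""] <- "Unassigned"
  groups <- unique(taxon)
  pooled <- vapply(groups, function(g) {
    rowSums(table$counts[, taxon == g, drop = FALSE])
  }, numeric(nrow(table$counts)))
  pooled <- matrix(pooled, nrow = nrow(table$counts),
                   dimnames = list(sample_ids(table), groups))
  sweep(pooled, 1L, rowSums(pooled), "/")
}

#' Correlation between two per-sample variables
#'
#' Standard product-moment (Pearson) or rank (Spearman, average ranks for
#' ties) correlation with its squared value and two-sided p-value.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values are
#'   dropped.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `r2`, `p`, `n`.
#' @export
env_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  list(r = r, r2 = r * r, p = ct$p.value, n = length(x))
}

# Upper-triangle pair table of a DistanceMatrix pair selection.
pair_indices <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Distance-decay analysis of community dissimilarity
#'
#' Tests whether communities become more dissimilar with geographic
#' distance: Spearman correlation between geographic and community
#' distances over site pairs, with significance from a Mantel-style
#' permutation (site labels of the community matrix are permuted jointly,
#' so the site-level dependence among pairs is respected;
#' `p = (#{|rho_perm| >= |rho_obs|} + 1) / (n_perm + 1)`). The plain
#' pairwise Spearman test p-value is also reported for reference.
#'
#' @param geo geographic [distance_matrix()].
#' @param community community [distance_matrix()] over the same ids.
#' @param scope `"all"` pairs, `"within_basin"`, or `"between_basin"`.
#' @param basins named basin labels (required unless `scope = "all"`).
#' @param n_perm number of permutations (>= 99; default 9999).
#' @param seed RNG seed.
#' @return A list of class `DecayResult`: `pairs` (pair table with
#'   distances and `same_basin`), `rho`, `p_mantel`, `p_spearman`,
#'   `n_perm`, `scope`, `seed`.
#' @export
distance_decay <- function(geo, community, scope = c("all", "within_basin", "between_basin"),
                           basins = NULL, n_perm = 9999, seed) {
  scope <- match.arg(scope)
  stopifnot(inherits(geo, "DistanceMatrix"), inherits(community, "DistanceMatrix"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  assert_scalar_count(n_perm, "n_perm", min = 99)
  if (!identical(sort(geo$ids), sort(community$ids))) {
    stop("geo and community matrices cover different ids", call. = FALSE)
  }
  ids <- geo$ids
  cm <- community$values[ids, ids]
  gm <- geo$values
  n <- length(ids)
  pairs <- pair_indices(n)
  if (is.null(basins)) {
    if (scope != "all") stop("`basins` required for basin-scoped analysis", call. = FALSE)
    same <- rep(NA, nrow(pairs))
  } else {
    b <- basins[ids]
    same <- b[pairs[, 1]] == b[pairs[, 2]]
  }
  keep <- switch(scope, all = rep(TRUE, nrow(pairs)),
                 within_basin = same, between_basin = !same)
  if (sum(keep) < 3) stop("validation error: scope leaves fewer than 3 pairs", call. = FALSE)
  gv <- gm[pairs[keep, , drop = FALSE]]
  cv <- cm[pairs[keep, , drop = FALSE]]
  rho_obs <- cor(gv, cv, method = "spearman")
  p_spear <- suppressWarnings(
    cor.test(gv, cv, method = "spearman", exact = FALSE)$p.value)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(n)
      cp <- cm[perm, perm][pairs[keep, , drop = FALSE]]
      abs(cor(gv, cp, method = "spearman")) >= abs(rho_obs)
    }, logical(1)))
  })
  structure(list(
    pairs = data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                       geographic_km = gm[pairs], dissimilarity = cm[pairs],
                       same_basin = same)[keep, , drop = FALSE],
    rho = rho_obs,
    p_mantel = (exceed + 1) / (n_perm + 1),
    p_spearman = p_spear,
    n_perm = n_perm, scope = scope, seed = seed
  ), class = "DecayResult")
}

#' @export
print.DecayResult <- function(x, ...) {
  cat(sprintf("Distance decay (%s pairs, n=%d): Spearman rho = %.3f, Mantel p = %.4g\n",
              x$scope, nrow(x$pairs), x$rho, x$p_mantel))
  invisible(x)
}
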