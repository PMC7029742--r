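#' Default configuration for the synthetic lake landscape
#'
#' The generator emulates the structure of a connected-lake survey: lakes
#' grouped in drainage basins, per-basin Dirichlet land-use compositions at
#' two scales, water chemistry responding linearly to basin-scale land use
#' plus noise, and OTU counts from a log-linear niche response to
#' (standardized) chemistry sampled multinomially at fixed depth. Three
#' clades are planted as ground truth: a *clustered* clade (near-zero
#' within-clade coefficient dispersion, so its OTUs respond coherently), an
#' *associated* clade (strong positive niche coefficient on total
#' phosphorus), and a *neutral* clade (no chemistry response).
#'
#' Defaults are the study conditions the pipeline is tested under: 46
#' lakes in 5 basins, 2000 OTUs, 40000 reads per lake (rarefied to 25000
#' downstream), six land-use categories, and an urban-to-NO2+NO3
#' coefficient that dominates all other land-use effects.
#'
#' @param n_lakes,n_basins,n_otus,depth landscape dimensions.
#' @param lat_range,lon_range bounding box (WGS84 decimal degrees).
#' @param basin_jitter_sd spread (degrees) of lakes around basin centers.
#' @param landuse_alpha optional `n_basins x 6` Dirichlet concentration
#'   matrix; by default drawn (per landscape) from Gamma(2, 0.5) + 0.3.
#' @param B 6 x 7 land-use-to-chemistry coefficient matrix (categories x
#'   [chemistry_vars()]); because land-use fractions sum to 1, per-variable
#'   baselines are folded into `B` as constant column offsets.
#' @param noise_sd named per-variable chemistry noise standard deviations.
#' @param clades data frame of clade specs: `name`, `prop` (OTU share),
#'   `dispersion` (within-clade coefficient SD), one `gamma_<var>` column
#'   per chemistry variable (niche coefficients, in SD units of chemistry).
#' @param baseline_sd SD of per-OTU log-abundance baselines.
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives plain multinomial sampling.
#' @param decay_strength optional distance-decay term (0 disables): each
#'   OTU gets a preferred location and its log abundance falls off with
#'   distance at this rate (per degree).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_lakes = 46, n_basins = 5, n_otus = 2000,
                              depth = 40000,
                              lat_range = c(52.7, 53.6),
                              lon_range = c(12.4, 13.9),
                              basin_jitter_sd = 0.07,
                              landuse_alpha = NULL,
                              B = default_landuse_chemistry_B(),
                              noise_sd = c(temperature = 1.2, ph = 0.3, do = 1.0,
                                           turbidity = 1.2, chl_a = 0.03,
                                           tp = 0.06, no23 = 0.15),
                              clades = default_clade_specs(),
                              baseline_sd = 1.5,
                              overdispersion = 0,
                              decay_strength = 0) {
  stopifnot(n_lakes >= n_basins, n_basins >= 1, n_otus >= 10, depth >= 1,
            all(noise_sd >= 0), overdispersion >= 0,
            diff(lat_range) > 0, diff(lon_range) > 0)
  structure(list(n_lakes = n_lakes, n_basins = n_basins, n_otus = n_otus,
                 depth = depth, lat_range = lat_range, lon_range = lon_range,
                 basin_jitter_sd = basin_jitter_sd, landuse_alpha = landuse_alpha,
                 B = B, noise_sd = noise_sd, clades = clades,
                 baseline_sd = baseline_sd, overdispersion = overdispersion,
                 decay_strength = decay_strength),
            class = "SimulationConfig")
}

#' @rdname simulation_config
#' @export
default_landuse_chemistry_B <- function() {
  base <- c(temperature = 20, ph = 8, do = 9, turbidity = 5,
            chl_a = 0.08, tp = 0.15, no23 = 0.4)
  B <- matrix(rep(base, each = 6), nrow = 6,
              dimnames = list(landuse_categories(), chemistry_vars()))
  B["urban", "no23"] <- B["urban", "no23"] + 3.0    # dominant planted effect
  B["arable", "tp"] <- B["arable", "tp"] + 0.4
  B["pasture", "turbidity"] <- B["pasture", "turbidity"] + 2.0
  B["forest", "chl_a"] <- B["forest", "chl_a"] - 0.05
  B
}

#' @rdname simulation_config
#' @export
default_clade_specs <- function() {
  g <- function(...) {
    v <- setNames(numeric(length(chemistry_vars())), chemistry_vars())
    upd <- c(...)
    v[names(upd)] <- upd
    v
  }
  specs <- rbind(
    Actinobacteria  = g(chl_a = -1.2, tp = -0.8, temperature = -0.5),
    Proteobacteria  = g(temperature = 0.3),
    Cyanobacteria   = g(tp = 2.0),
    Bacteroidetes   = g(chl_a = 0.5),
    Verrucomicrobia = g(no23 = 0.8),
    Planctomycetes  = g(),
    Chloroflexi     = g(do = -0.4),
    Firmicutes      = g(turbidity = 0.4))
  colnames(specs) <- paste0("gamma_", chemistry_vars())
  out <- data.frame(
    name = rownames(specs),
    prop = c(0.20, 0.22, 0.15, 0.12, 0.10, 0.08, 0.07, 0.06),
    dispersion = c(0.05, 0.9, 0.4, 0.9, 0.9, 0.9, 0.9, 0.9),
    specs, row.names = NULL, check.names = FALSE)
  attr(out, "planted") <- list(clustered = "Actinobacteria",
                               associated = list(clade = "Cyanobacteria",
                                                 var = "tp", sign = 1),
                               neutral = "Planctomycetes")
  out
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Generate lake coordinates, basins and land-use compositions
#'
#' Basin centers are placed uniformly in the bounding box; lakes are
#' jittered normally around their basin center; each lake's land-use
#' fraction vectors (basin and local scale) are independent draws from its
#' basin's Dirichlet distribution, so lakes within a basin share a land-use
#' regime.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return List: `sites` (data frame `sample_id`, `lat`, `lon`, `basin`),
#'   `landuse_basin`, `landuse_local` (matrices, lakes x 6).
#' @export
generate_landscape <- function(config, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  with_seed(seed, {
    nb <- config$n_basins; nl <- config$n_lakes
    centers <- cbind(lat = runif(nb, config$lat_range[1], config$lat_range[2]),
                     lon = runif(nb, config$lon_range[1], config$lon_range[2]))
    basin <- sort(rep_len(seq_len(nb), nl))
    lat <- pmin(pmax(centers[basin, "lat"] + rnorm(nl, 0, config$basin_jitter_sd),
                     config$lat_range[1]), config$lat_range[2])
    lon <- pmin(pmax(centers[basin, "lon"] + rnorm(nl, 0, config$basin_jitter_sd),
                     config$lon_range[1]), config$lon_range[2])
    alpha <- config$landuse_alpha
    if (is.null(alpha)) {
      alpha <- matrix(rgamma(nb * 6, shape = 2, rate = 0.5) + 0.3, nrow = nb)
    }
    lu_b <- matrix(NA_real_, nl, 6)
    lu_l <- matrix(NA_real_, nl, 6)
    for (b in seq_len(nb)) {
      idx <- which(basin == b)
      lu_b[idx, ] <- rdirichlet(length(idx), alpha[b, ])
      lu_l[idx, ] <- rdirichlet(length(idx), alpha[b, ])
    }
    ids <- sprintf("L%02d", seq_len(nl))
    dimnames(lu_b) <- dimnames(lu_l) <- list(ids, landuse_categories())
    list(sites = data.frame(sample_id = ids, lat = lat, lon = lon,
                            basin = paste0("basin_", basin)),
         landuse_basin = lu_b, landuse_local = lu_l)
  })
}

#' Generate water chemistry from land use
#'
#' `chem = landuse %*% B + noise`, with independent Gaussian noise per
#' variable; with `noise_sd = 0` the relation is exact.
#'
#' @param landuse lakes x 6 land-use fraction matrix.
#' @param B 6 x 7 coefficient matrix (see [simulation_config()]).
#' @param noise_sd per-variable noise SDs (recycled if scalar).
#' @param seed RNG seed.
#' @return Lakes x 7 chemistry matrix with [chemistry_vars()] columns.
#' @export
generate_chemistry <- function(landuse, B, noise_sd, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(ncol(landuse) == nrow(B))
  chem <- landuse %*% B
  noise_sd <- rep_len(noise_sd, ncol(B))
  with_seed(seed, {
    chem <- chem + sapply(seq_len(ncol(B)), function(j) {
      rnorm(nrow(landuse), 0, noise_sd[j])
    })
  })
  colnames(chem) <- colnames(B)
  rownames(chem) <- rownames(landuse)
  chem
}

# Build a 7-rank lineage matrix in which clade = phylum, with two nested
# classes per phylum, two orders per class, two families per order.
fabricate_taxonomy <- function(phylum, otu_id) {
  n <- length(phylum)
  cls <- paste0(phylum, "_c", sample.int(2, n, replace = TRUE))
  ord <- paste0(cls, "_o", sample.int(2, n, replace = TRUE))
  fam <- paste0(ord, "_f", sample.int(2, n, replace = TRUE))
  lin <- cbind(kingdom = rep("Bacteria", n), phylum = phylum, class = cls,
               order = ord, family = fam, genus = "", species = "")
  rownames(lin) <- otu_id
  lin
}

#' Generate an OTU table from chemistry via a log-linear niche model
#'
#' Per OTU `i` in clade `p`, the log expected relative abundance at a site
#' is `baseline_i + sum_k (gamma_pk + eta_ik) z_k`, where `z` is the
#' site-standardized chemistry and `eta_ik ~ N(0, dispersion_p^2)` is the
#' within-clade coefficient scatter; a softmax across OTUs gives site
#' relative abundances and counts are multinomial at fixed depth
#' (Dirichlet-multinomial when `overdispersion > 0`). Taxonomy strings are
#' fabricated so that each clade is a phylum with nested classes, orders
#' and families.
#'
#' @param chemistry lakes x 7 chemistry matrix.
#' @param config a [simulation_config()] (supplies clade specs, depth,
#'   baseline SD, overdispersion, decay term).
#' @param seed RNG seed.
#' @param sites optional site data frame (needed only when
#'   `decay_strength > 0`).
#' @return List: `table` (an [OtuTable]) and `truth` (clade memberships,
#'   true gamma matrix, per-OTU coefficients, planted clade labels).
#' @export
generate_community <- function(chemistry, config, seed, sites = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  clades <- config$clades
  gamma_cols <- paste0("gamma_", chemistry_vars())
  gam <- as.matrix(clades[, gamma_cols])
  rownames(gam) <- clades$name
  z <- scale(chemistry)
  z[, attr(z, "scale") == 0] <- 0   # constant chemistry column: no gradient
  n <- nrow(chemistry)
  m <- config$n_otus
  with_seed(seed, {
    phylum <- sample(clades$name, m, replace = TRUE, prob = clades$prop)
    otu_id <- sprintf("OTU%05d", seq_len(m))
    baseline <- rnorm(m, 0, config$baseline_sd)
    disp <- clades$dispersion[match(phylum, clades$name)]
    coefs <- gam[phylum, , drop = FALSE] +
      matrix(rnorm(m * ncol(gam), 0, disp), nrow = m)
    loglam <- matrix(baseline, n, m, byrow = TRUE) + z %*% t(coefs)
    if (config$decay_strength > 0) {
      if (is.null(sites)) stop("`sites` needed when decay_strength > 0", call. = FALSE)
      pref_lat <- runif(m, config$lat_range[1], config$lat_range[2])
      pref_lon <- runif(m, config$lon_range[1], config$lon_range[2])
      dd <- sqrt(outer(sites$lat, pref_lat, "-")^2 +
                 outer(sites$lon, pref_lon, "-")^2)
      loglam <- loglam - config$decay_strength * dd
    }
    loglam <- loglam - apply(loglam, 1L, max)   # softmax underflow guard
    prob <- exp(loglam)
    prob <- prob / rowSums(prob)
    counts <- t(vapply(seq_len(n), function(i) {
      p <- prob[i, ]
      if (config$overdispersion > 0) {
        p <- rgamma(m, shape = p / config$overdispersion)
        p <- p / sum(p)
      }
      drop(rmultinom(1, config$depth, p))
    }, numeric(m)))
    dimnames(counts) <- list(rownames(chemistry), otu_id)
    lineages <- fabricate_taxonomy(phylum, otu_id)
    table <- OtuTable(counts, lineages)
    truth <- list(gamma = gam, membership = setNames(phylum, otu_id),
                  coefs = coefs, baseline = baseline,
                  planted = attr(config$clades, "planted"))
    list(table = table, truth = truth)
  })
}

#' Simulate a complete synthetic lake dataset
#'
#' Chains [generate_landscape()], [generate_chemistry()] (driven by the
#' basin-scale land use) and [generate_community()] into one dataset with a
#' ground-truth record, ready for the full pipeline.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (sub-stage seeds are derived from it).
#' @return A `SyntheticDataset` list: `table` (an [OtuTable]), `metadata`
#'   (a validated site-metadata data frame), `truth`.
#' @export
simulate_lake_dataset <- function(config = simulation_config(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  land <- generate_landscape(config, seed = seed)
  chem <- generate_chemistry(land$landuse_basin, config$B, config$noise_sd,
                             seed = seed + 1)
  comm <- generate_community(chem, config, seed = seed + 2, sites = land$sites)
  meta <- data.frame(land$sites, as.data.frame(chem),
                     as.data.frame(land$landuse_basin) |>
                       stats::setNames(landuse_cols("basin")),
                     as.data.frame(land$landuse_local) |>
                       stats::setNames(landuse_cols("local")),
                     row.names = NULL)
  validate_site_metadata(meta)
  structure(list(table = comm$table, metadata = meta, truth = comm$truth,
                 config = config, seed = seed),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d lakes, %d basins, %d OTUs, depth %d (seed %d)\n",
              nrow(x$metadata), length(unique(x$metadata$basin)),
              ncol(x$table$counts), x$config$depth, x$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the OTU table (QIIME-classic TSV), the metadata TSV, and a
#' ground-truth JSON side by side.
#'
#' @param dataset a [simulate_lake_dataset()] result.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$table, file.path(dir, "otu_table.tsv"),
                  seed = dataset$seed)
  write_site_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  truth <- dataset$truth
  truth$membership <- as.list(truth$membership)
  truth$coefs <- NULL   # bulky per-OTU matrix; gamma + membership suffice
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
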