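#' Water-chemistry variable names
#'
#' The seven per-site aquatic environmental measurements carried in site
#' metadata: temperature (deg C), pH, dissolved oxygen (mg/L), turbidity
#' (NTU), chlorophyll a (mg/L), total phosphorus (mg/L), and nitrite +
#' nitrate (mg/L).
#' @return Character vector of column names.
#' @export
chemistry_vars <- function() {
  c("temperature", "ph", "do", "turbidity", "chl_a", "tp", "no23")
}

#' Land-use category names
#'
#' The six land-use classes whose fractional cover is recorded per site, at
#' both the drainage-basin scale and the local (shoreline-adjacent) scale:
#' urban, heterogeneous agriculture, pasture, arable land, forest, and
#' water/wetland.
#' @return Character vector of category names.
#' @export
landuse_categories <- function() {
  c("urban", "agri_hetero", "pasture", "arable", "forest", "water")
}

landuse_cols <- function(scale = c("basin", "local")) {
  scale <- match.arg(scale)
  paste0("lu_", scale, "_", landuse_categories())
}

#' Validate a site-metadata data frame
#'
#' Site metadata has one row per sample with columns: `sample_id`, the seven
#' [chemistry_vars()], WGS84 `lat`/`lon`, a categorical `basin` label, and
#' two land-use composition vectors (columns `lu_basin_*` and `lu_local_*`
#' over the six [landuse_categories()]). Each land-use vector must lie on
#' the unit simplex (entries in \[0,1\] summing to 1 within 1e-6),
#' coordinates must be in range, and chemistry values finite or `NA`.
#'
#' @param meta data frame of site metadata.
#' @return `meta`, invisibly, or an error describing the violation.
#' @export
validate_site_metadata <- function(meta) {
  need <- c("sample_id", chemistry_vars(), "lat", "lon", "basin",
            landuse_cols("basin"), landuse_cols("local"))
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    stop(sprintf("metadata is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  for (scale in c("basin", "local")) {
    lu <- as.matrix(meta[, landuse_cols(scale)])
    if (any(lu < -1e-9 | lu > 1 + 1e-9)) {
      stop(sprintf("%s-scale land-use fractions outside [0,1]", scale), call. = FALSE)
    }
    s <- rowSums(lu)
    if (any(abs(s - 1) > 1e-6)) {
      stop(sprintf("%s-scale land-use fractions do not sum to 1 (sample %s)",
                   scale, meta$sample_id[which(abs(s - 1) > 1e-6)[1]]), call. = FALSE)
    }
  }
  if (any(!is.na(meta$lat) & abs(meta$lat) > 90) ||
      any(!is.na(meta$lon) & abs(meta$lon) > 180)) {
    stop("coordinates outside valid WGS84 ranges", call. = FALSE)
  }
  chem <- as.matrix(meta[, chemistry_vars()])
  if (any(is.infinite(chem))) stop("non-finite chemistry value", call. = FALSE)
  invisible(meta)
}

#' Read and write site metadata TSV
#'
#' One row per sample; `#`-prefixed comment lines are ignored on read and a
#' provenance comment is written first. See [validate_site_metadata()] for
#' the column contract.
#'
#' @param path file path.
#' @return For the reader, a validated metadata data frame.
#' @export
read_site_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  meta <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                     check.names = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta$basin <- as.character(meta$basin)
  validate_site_metadata(meta)
  meta
}

#' @rdname read_site_metadata
#' @param meta validated metadata data frame.
#' @export
write_site_metadata <- function(meta, path) {
  validate_site_metadata(meta)
  write_tsv_provenance(meta, path, what = "write_site_metadata")
}

#' Extract the land-use or chemistry block as a numeric matrix
#'
#' @param meta site metadata (see [validate_site_metadata()]).
#' @param scale `"basin"` or `"local"` land use.
#' @return Numeric matrix with sample ids as row names; land-use columns are
#'   named by category (the `lu_<scale>_` prefix is stripped).
#' @export
landuse_matrix <- function(meta, scale = c("basin", "local")) {
  scale <- match.arg(scale)
  m <- as.matrix(meta[, landuse_cols(scale)])
  dimnames(m) <- list(meta$sample_id, landuse_categories())
  m
}

#' @rdname landuse_matrix
#' @export
chemistry_matrix <- function(meta) {
  m <- as.matrix(meta[, chemistry_vars()])
  rownames(m) <- meta$sample_id
  m
}

#' Distance matrices
#'
#' A `DistanceMatrix` bundles a symmetric zero-diagonal matrix with the
#' identifier ordering and a metric label (`bray_curtis`, `jaccard`, or
#' `geographic_km`).
#'
#' @param values symmetric numeric matrix with identical row/column names.
#' @param metric metric label.
#' @return An object of class `DistanceMatrix`.
#' @export
distance_matrix <- function(values, metric) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("distance matrix needs ids", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) stop("matrix not symmetric", call. = FALSE)
  diag(values) <- 0
  structure(list(ids = rownames(values), values = values, metric = metric),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("DistanceMatrix (%s): %d ids, range [%.4g, %.4g]\n",
              x$metric, length(x$ids), min(x$values), max(x$values)))
  invisible(x)
}

#' Great-circle distances between sampling sites
#'
#' Haversine distances (Earth radius 6371.0 km) between all pairs of sites,
#' from their WGS84 decimal-degree coordinates.
#'
#' @param meta site metadata with `sample_id`, `lat`, `lon` columns.
#' @return A [distance_matrix()] with metric `"geographic_km"`.
#' @export
geographic_distances <- function(meta) {
  bad <- is.na(meta$lat) | is.na(meta$lon)
  if (any(bad)) {
    stop(sprintf("missing coordinates for sample(s): %s",
                 paste(meta$sample_id[bad], collapse = ", ")), call. = FALSE)
  }
  pts <- cbind(meta$lon, meta$lat)
  km <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371.0)
  })
  dimnames(km) <- list(meta$sample_id, meta$sample_id)
  distance_matrix(km, "geographic_km")
}
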