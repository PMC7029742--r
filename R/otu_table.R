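#' OTU count tables
#'
#' An `OtuTable` is the pipeline's central object: a samples x OTUs matrix of
#' non-negative integer read counts together with a per-OTU ranked taxonomy
#' (kingdom through species; ranks may be empty strings where unassigned).
#'
#' @param counts integer matrix, samples in rows, OTUs in columns, with
#'   dimnames giving sample and OTU identifiers.
#' @param lineages character matrix (OTUs x 7) of taxon names at the ranks
#'   kingdom, phylum, class, order, family, genus, species; or `NULL` for a
#'   table without taxonomy (all ranks empty).
#' @return An object of class `OtuTable` with elements `counts` and
#'   `lineages`.
#' @export
OtuTable <- function(counts, lineages = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("`counts` must carry sample (row) and OTU (column) names", call. = FALSE)
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids", call. = FALSE)
  if (any(!is.finite(counts))) stop("counts must be finite", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integral", call. = FALSE)
  storage.mode(counts) <- "double"   # holds integers; double avoids overflow on sums
  if (is.null(lineages)) {
    lineages <- matrix("", nrow = ncol(counts), ncol = length(taxonomy_ranks()),
                       dimnames = list(colnames(counts), taxonomy_ranks()))
  } else {
    lineages <- as.matrix(lineages)
    if (nrow(lineages) != ncol(counts)) {
      stop("`lineages` must have one row per OTU", call. = FALSE)
    }
    rownames(lineages) <- colnames(counts)
    colnames(lineages) <- taxonomy_ranks()
  }
  structure(list(counts = counts, lineages = lineages), class = "OtuTable")
}

#' @export
print.OtuTable <- function(x, ...) {
  cat(sprintf("OtuTable: %d samples x %d OTUs, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  with_tax <- sum(x$lineages[, "phylum"] != "")
  cat(sprintf("  %d OTUs with phylum-level taxonomy\n", with_tax))
  invisible(x)
}

#' @export
dim.OtuTable <- function(x) dim(x$counts)

#' Taxonomic rank names used throughout the package
#' @return Character vector of the seven ranks, kingdom through species.
#' @export
taxonomy_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Sample and OTU identifiers of a table
#' @param table an [OtuTable].
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(table) colnames(table$counts)

# Split "k__Bacteria; p__Cyanobacteria; ..." into a 7-slot rank vector,
# stripping Greengenes-style prefixes and whitespace. Empty ranks stay "".
parse_lineage <- function(strings) {
  ranks <- taxonomy_ranks()
  out <- matrix("", nrow = length(strings), ncol = length(ranks))
  pieces <- strsplit(strings, ";", fixed = TRUE)
  for (i in seq_along(pieces)) {
    p <- trimws(pieces[[i]])
    p <- sub("^[kpcofgs]__", "", p)
    n <- min(length(p), length(ranks))
    if (n > 0) out[i, seq_len(n)] <- p[seq_len(n)]
  }
  colnames(out) <- ranks
  out
}

format_lineage <- function(lineages) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(lineages, 1L, function(r) {
    paste0(prefixes, r, collapse = "; ")
  })
}

#' Read an OTU table in QIIME-classic TSV format
#'
#' The on-disk layout is OTUs in rows and samples in columns, a header line
#' starting with `#OTU ID`, and an optional trailing `taxonomy` column with
#' a semicolon-delimited lineage. Leading `#` comment lines (other than the
#' header) are skipped. The returned table is re-oriented to samples x OTUs.
#'
#' @param path path to the TSV file.
#' @param dialect input dialect; only `"qiime_classic_tsv"` is supported.
#' @return An [OtuTable].
#' @export
read_otu_table <- function(path, dialect = "qiime_classic_tsv") {
  dialect <- match.arg(dialect, "qiime_classic_tsv")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_header <- grepl("^#?OTU[ _]?ID\t", lines, ignore.case = TRUE)
  hdr_idx <- which(is_header)[1]
  if (is.na(hdr_idx)) {
    stop(sprintf("malformed header: no '#OTU ID' line found in %s (first line: %s)",
                 path, lines[1]), call. = FALSE)
  }
  header <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_idx)]
  body <- body[!grepl("^#", body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad) > 0) {
    stop(sprintf("parse error at line %d of %s: %d fields, header has %d",
                 hdr_idx + bad[1], path, lengths(cells)[bad[1]], length(header)),
         call. = FALSE)
  }
  tab <- do.call(rbind, cells)
  colnames(tab) <- header
  has_tax <- tolower(header[length(header)]) %in% c("taxonomy", "consensus lineage", "consensuslineage")
  otu_id <- tab[, 1]
  count_cols <- seq(2L, length(header) - if (has_tax) 1L else 0L)
  counts_chr <- tab[, count_cols, drop = FALSE]
  counts <- suppressWarnings(matrix(as.numeric(counts_chr), nrow = nrow(tab)))
  if (any(is.na(counts))) {
    stop("validation error: non-numeric count value in OTU table", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("validation error: negative count value in OTU table", call. = FALSE)
  }
  dimnames(counts) <- list(otu_id, header[count_cols])
  lineages <- if (has_tax) parse_lineage(tab[, length(header)]) else NULL
  OtuTable(t(counts), lineages)
}

#' Write an OTU table in QIIME-classic TSV format
#'
#' Inverse of [read_otu_table()]: OTUs in rows, samples in columns, a
#' trailing taxonomy column with Greengenes-style rank prefixes, and a
#' provenance comment line first.
#'
#' @param table an [OtuTable].
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, seed = NULL) {
  stopifnot(inherits(table, "OtuTable"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# write_otu_table | lakemicro %s%s",
                     as.character(utils::packageVersion("lakemicro")),
                     if (is.null(seed)) "" else sprintf(" | seed=%d", as.integer(seed))),
             con)
  writeLines(paste(c("#OTU ID", sample_ids(table), "taxonomy"), collapse = "\t"), con)
  body <- cbind(otu_ids(table),
                format(t(table$counts), scientific = FALSE, trim = TRUE),
                format_lineage(table$lineages))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Remove OTUs with few reads across all samples
#'
#' Drops every OTU whose total read count over all samples is below
#' `min_total`; retained counts are unmodified and the sample set is
#' unchanged. The default threshold of 5 reads removes singleton-like OTUs
#' that are likely sequencing artifacts.
#'
#' @param table an [OtuTable].
#' @param min_total minimum total reads an OTU needs to be kept (>= 1).
#' @return A filtered [OtuTable].
#' @export
filter_low_abundance <- function(table, min_total = 5) {
  stopifnot(inherits(table, "OtuTable"))
  assert_scalar_count(min_total, "min_total", min = 1)
  keep <- colSums(table$counts) >= min_total
  if (!any(keep)) {
    warning("all OTUs fall below `min_total`; returning an empty table", call. = FALSE)
  }
  OtuTable(table$counts[, keep, drop = FALSE],
           table$lineages[keep, , drop = FALSE])
}

#' Rarefy samples to a common sequencing depth
#'
#' Classic rarefaction: each sample's reads are subsampled without
#' replacement (multivariate hypergeometric) to exactly `depth` reads.
#' Samples with fewer than `depth` reads are dropped with a warning.
#'
#' @param table an [OtuTable].
#' @param depth target reads per sample (default 25000).
#' @param seed mandatory RNG seed; rarefaction is random and the seed is the
#'   only way to reproduce a run.
#' @return A rarefied [OtuTable] whose per-sample totals all equal `depth`.
#' @export
rarefy <- function(table, depth = 25000, seed) {
  stopifnot(inherits(table, "OtuTable"))
  assert_scalar_count(depth, "depth", min = 1)
  if (missing(seed)) stop("`seed` is required for rarefaction", call. = FALSE)
  totals <- rowSums(table$counts)
  shallow <- totals < depth
  if (any(shallow)) {
    warning(sprintf("dropping %d sample(s) with fewer than %d reads: %s",
                    sum(shallow), depth,
                    paste(sample_ids(table)[shallow], collapse = ", ")),
            call. = FALSE)
  }
  counts <- table$counts[!shallow, , drop = FALSE]
  m <- ncol(counts)
  out <- with_seed(seed, {
    t(apply(counts, 1L, function(x) {
      if (sum(x) == depth) return(x)
      pool <- rep.int(seq_len(m), x)       # one entry per read, labelled by OTU
      tabulate(pool[sample.int(length(pool), depth)], nbins = m)
    }))
  })
  dimnames(out) <- dimnames(counts)
  OtuTable(out, table$lineages)
}

#' Log-transform an abundance matrix
#'
#' Elementwise `log10(pseudocount + x)`. With the default pseudocount of 1,
#' zeros map to zero and the transform is finite on sparse tables.
#'
#' @param table an [OtuTable] or a non-negative numeric matrix.
#' @param pseudocount value added before taking log10 (default 1).
#' @return A real matrix of the same shape as the counts.
#' @export
log_transform <- function(table, pseudocount = 1) {
  x <- if (inherits(table, "OtuTable")) table$counts else as.matrix(table)
  if (any(x < 0)) stop("validation error: negative abundances", call. = FALSE)
  if (pseudocount <= 0) stop("`pseudocount` must be positive", call. = FALSE)
  log10(pseudocount + x)
}
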