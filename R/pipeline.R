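#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one list. Defaults
#' mirror the standard protocol: low-count filter at 5 reads, rarefaction
#' to 25000 reads, all seven chemistry variables as CCA constraints, the
#' six land-use fractions (basin and local scale) as GLM predictors for
#' each chemistry response, 1000 clustering and 1000 association
#' permutations, 999 for the CCA permutation test, 9999 Mantel
#' permutations, and phylum through family clade tests with a minimum
#' clade size of 5 OTUs.
#'
#' @param otu_path,metadata_path input file paths (`NULL` when the data are
#'   passed to [run_pipeline()] directly as objects).
#' @param min_count low-abundance OTU filter threshold.
#' @param depth rarefaction depth.
#' @param constraints chemistry columns used as CCA constraints.
#' @param glm_responses chemistry columns modelled from land use.
#' @param glm_scales land-use scales fitted per response.
#' @param criterion information criterion for the model ensemble.
#' @param ranks taxonomy ranks for the clade tests.
#' @param n_clustering,n_association,n_perm_anova,n_perm_mantel permutation
#'   counts for the respective tests.
#' @param min_clade_size smallest clade tested.
#' @param prevalence_on `"rarefied"` (default) or `"filtered"`: which table
#'   the gamma-diversity categories are computed on.
#' @param alpha significance level used when summarizing results.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(otu_path = NULL, metadata_path = NULL,
                            min_count = 5, depth = 25000,
                            constraints = chemistry_vars(),
                            glm_responses = chemistry_vars(),
                            glm_scales = c("basin", "local"),
                            criterion = "AIC",
                            ranks = c("phylum", "class", "order", "family"),
                            n_clustering = 1000, n_association = 1000,
                            n_perm_anova = 999, n_perm_mantel = 9999,
                            min_clade_size = 5,
                            prevalence_on = c("rarefied", "filtered"),
                            alpha = 0.05) {
  structure(list(otu_path = otu_path, metadata_path = metadata_path,
                 min_count = min_count, depth = depth,
                 constraints = constraints, glm_responses = glm_responses,
                 glm_scales = glm_scales, criterion = criterion,
                 ranks = ranks, n_clustering = n_clustering,
                 n_association = n_association, n_perm_anova = n_perm_anova,
                 n_perm_mantel = n_perm_mantel,
                 min_clade_size = min_clade_size,
                 prevalence_on = match.arg(prevalence_on), alpha = alpha),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys are the arguments of [pipeline_config()]; unknown keys are
#' rejected. Keys not present keep their defaults.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (low-count filter, rarefaction, log
#' transform), alpha diversity and gamma-diversity prevalence categories,
#' distance decay, per-response land-use model ensembles, CCA with
#' whole-model and per-constraint permutation tests, three-way variation
#' partitioning (basin land use / local land use / chemistry), and the
#' clade clustering/association tests. Writes per-stage TSV/JSON outputs
#' under `outdir` (if given) plus a single machine-readable `report.json`,
#' and returns the full result bundle invisibly.
#'
#' Input columns named in the config are checked up front; a failure in any
#' stage aborts with the stage name while earlier outputs remain on disk.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed; stage seeds are derived from it and recorded.
#' @param table,metadata optional in-memory inputs (an [OtuTable] and a
#'   metadata data frame), used instead of the config paths.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return (Invisibly) a list with elements `prep`, `diversity`,
#'   `prevalence`, `decay`, `glm`, `ordination`, `anova`, `varpart`,
#'   `clades`, and `report` (the summary written to `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), seed, table = NULL,
                         metadata = NULL, outdir = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  seed <- as.integer(seed)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # ---- load & fail-fast validation -------------------------------------
  loaded <- stage("load", {
    if (is.null(table)) {
      if (is.null(config$otu_path)) stop("no OTU table given", call. = FALSE)
      table <- read_otu_table(config$otu_path)
    }
    if (is.null(metadata)) {
      if (is.null(config$metadata_path)) stop("no metadata given", call. = FALSE)
      metadata <- read_site_metadata(config$metadata_path)
    }
    validate_site_metadata(metadata)
    missing_cols <- setdiff(unique(c(config$constraints, config$glm_responses)),
                            names(metadata))
    if (length(missing_cols) > 0) {
      stop(sprintf("metadata lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    shared <- intersect(sample_ids(table), metadata$sample_id)
    if (length(shared) < 3) stop("fewer than 3 shared samples", call. = FALSE)
    list(table = OtuTable(table$counts[shared, , drop = FALSE], table$lineages),
         metadata = metadata[match(shared, metadata$sample_id), , drop = FALSE])
  })
  table <- loaded$table
  metadata <- loaded$metadata

  # ---- prep ------------------------------------------------------------
  prep <- stage("prep", {
    filtered <- filter_low_abundance(table, config$min_count)
    rarefied <- rarefy(filtered, depth = config$depth, seed = seed + 1)
    rarefied <- filter_low_abundance(rarefied, 1)  # drop OTUs emptied by rarefaction
    list(filtered = filtered, rarefied = rarefied,
         logged = log_transform(rarefied), seed = seed + 1)
  })
  rare <- prep$rarefied

  # ---- diversity, prevalence, decay ------------------------------------
  diversity <- stage("diversity", {
    data.frame(sample_id = sample_ids(rare),
               shannon = apply(rare$counts, 1L, shannon),
               row.names = NULL)
  })
  prevalence <- stage("prevalence", {
    prevalence_categories(if (config$prevalence_on == "rarefied") rare
                          else prep$filtered)
  })
  decay <- stage("decay", {
    geo <- geographic_distances(metadata)
    bc <- dissimilarity(rare, "bray_curtis")
    basins <- setNames(metadata$basin, metadata$sample_id)
    list(all = distance_decay(geo, bc, "all", basins, config$n_perm_mantel,
                              seed = seed + 2),
         within_basin = tryCatch(
           distance_decay(geo, bc, "within_basin", basins,
                          config$n_perm_mantel, seed = seed + 3),
           error = function(e) NULL),
         between_basin = tryCatch(
           distance_decay(geo, bc, "between_basin", basins,
                          config$n_perm_mantel, seed = seed + 4),
           error = function(e) NULL))
  })

  # ---- land-use GLM ensembles ------------------------------------------
  glm_res <- stage("glm", {
    out <- list()
    for (scale in config$glm_scales) {
      lu <- as.data.frame(landuse_matrix(metadata, scale))
      for (resp in config$glm_responses) {
        out[[paste(scale, resp, sep = ".")]] <-
          aic_ensemble(metadata[[resp]], lu, criterion = config$criterion)
      }
    }
    out
  })

  # ---- ordination + permutation anova ----------------------------------
  chem <- chemistry_matrix(metadata)[, config$constraints, drop = FALSE]
  ordination <- stage("ordination", cca(rare, chem))
  anova_res <- stage("anova", {
    whole <- permutation_anova(rare, chem, "model", config$n_perm_anova,
                               seed = seed + 5)
    margins <- lapply(setNames(nm = colnames(chem)), function(v) {
      permutation_anova(rare, chem, paste0("margin:", v), config$n_perm_anova,
                        seed = seed + 5)
    })
    list(model = whole, margins = margins)
  })

  # ---- variation partitioning ------------------------------------------
  varpart <- stage("varpart", {
    varpart3(prep$logged,
             landuse_matrix(metadata, "basin"),
             landuse_matrix(metadata, "local"),
             chemistry_matrix(metadata),
             names = c("landuse_basin", "landuse_local", "chemistry"))
  })

  # ---- clade tests ------------------------------------------------------
  clades <- stage("clades", {
    run_clade_tests(ordination, rare, ranks = config$ranks,
                    n_clustering = config$n_clustering,
                    n_association = config$n_association,
                    min_size = config$min_clade_size, seed = seed + 6)
  })

  # ---- report -----------------------------------------------------------
  sig_clades <- if (nrow(clades) > 0) {
    unique(clades[clades$q_clust <= config$alpha, c("rank", "clade")])
  } else {
    data.frame(rank = character(0), clade = character(0))
  }
  report <- list(
    seed = seed,
    stage_seeds = list(rarefy = seed + 1, decay = seed + 2:4,
                       anova = seed + 5, clades = seed + 6),
    n_samples = nrow(rare$counts),
    n_otus_filtered = ncol(prep$filtered$counts),
    n_otus_rarefied = ncol(rare$counts),
    shannon_range = range(diversity$shannon),
    prevalence_pct = as.list(round(100 * prevalence$category_otu_fraction, 2)),
    rare_unique_read_pct = 100 * prevalence$rare_unique_read_fraction,
    decay = list(rho = decay$all$rho, p_mantel = decay$all$p_mantel,
                 p_spearman = decay$all$p_spearman),
    glm_importance = lapply(glm_res, function(e) as.list(round(e$importance, 4))),
    cca = list(total_inertia = ordination$total_inertia,
               constrained_inertia = ordination$constrained_inertia,
               explained_pct = 100 * ordination$constrained_inertia /
                 ordination$total_inertia,
               eigenvalues = unname(ordination$eigenvalues[1:min(4, length(ordination$eigenvalues))]),
               model_p = anova_res$model$p,
               margin_p = lapply(anova_res$margins, `[[`, "p")),
    varpart = as.list(round(varpart$fractions, 4)),
    significant_clades = sig_clades
  )

  if (!is.null(outdir)) {
    write_tsv_provenance(diversity, file.path(outdir, "alpha_diversity.tsv"),
                         "diversity")
    write_tsv_provenance(prevalence$otus, file.path(outdir, "prevalence.tsv"),
                         "prevalence")
    write_tsv_provenance(decay$all$pairs, file.path(outdir, "decay_pairs.tsv"),
                         "decay", seed = seed + 2)
    write_tsv_provenance(as.data.frame(ordination$site_scores) |>
                           (\(d) cbind(sample_id = rownames(d), d))(),
                         file.path(outdir, "cca_site_scores.tsv"), "ordination")
    write_tsv_provenance(as.data.frame(ordination$otu_scores) |>
                           (\(d) cbind(otu_id = rownames(d), d))(),
                         file.path(outdir, "cca_otu_scores.tsv"), "ordination")
    write_tsv_provenance(as.data.frame(ordination$biplot) |>
                           (\(d) cbind(constraint = rownames(d), d))(),
                         file.path(outdir, "cca_biplot.tsv"), "ordination")
    if (nrow(clades) > 0) {
      write_tsv_provenance(clades, file.path(outdir, "clade_tests.tsv"),
                           "clades", seed = seed + 6)
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  invisible(list(prep = prep, diversity = diversity, prevalence = prevalence,
                 decay = decay, glm = glm_res, ordination = ordination,
                 anova = anova_res, varpart = varpart, clades = clades,
                 report = report))
}
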