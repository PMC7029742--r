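# Shared fixtures, built in code.

# A 4-OTU x 3-sample QIIME-classic TSV, with taxonomy.
qiime_fixture_path <- function(taxonomy = TRUE) {
  path <- tempfile(fileext = ".tsv")
  if (taxonomy) {
    lines <- c(
      "# Constructed from biom file",
      "#OTU ID\tS1\tS2\tS3\ttaxonomy",
      "OTU1\t10\t0\t3\tk__Bacteria; p__Cyanobacteria; c__Synechococcales; o__; f__; g__; s__",
      "OTU2\t1\t2\t0\tk__Bacteria; p__Actinobacteria; c__Acidimicrobiia; o__; f__; g__; s__",
      "OTU3\t0\t5\t5\tk__Bacteria; p__Proteobacteria",
      "OTU4\t2\t2\t2\tUnassigned")
  } else {
    lines <- c(
      "#OTU ID\tS1\tS2\tS3",
      "OTU1\t10\t0\t3", "OTU2\t1\t2\t0", "OTU3\t0\t5\t5", "OTU4\t2\t2\t2")
  }
  writeLines(lines, path)
  path
}

# Minimal count table with named dims.
make_counts <- function(x, nsamp, notu) {
  matrix(x, nsamp, notu,
         dimnames = list(sprintf("S%d", seq_len(nsamp)),
                         sprintf("OTU%d", seq_len(notu))))
}

# A small, fast landscape for end-to-end tests: 3 clades, one planted
# tightly clustered (A), one strongly TP-associated (B), one neutral (C).
small_clade_specs <- function() {
  g <- function(...) {
    v <- setNames(numeric(length(chemistry_vars())), chemistry_vars())
    upd <- c(...); v[names(upd)] <- upd
    v
  }
  specs <- rbind(CladeA = g(chl_a = -1.2, temperature = -0.6),
                 CladeB = g(tp = 2.0),
                 CladeC = g())
  colnames(specs) <- paste0("gamma_", chemistry_vars())
  out <- data.frame(name = rownames(specs), prop = c(0.3, 0.35, 0.35),
                    dispersion = c(0.03, 0.4, 0.8), specs,
                    row.names = NULL, check.names = FALSE)
  attr(out, "planted") <- list(clustered = "CladeA",
                               associated = list(clade = "CladeB", var = "tp",
                                                 sign = 1),
                               neutral = "CladeC")
  out
}

small_sim_config <- function(...) {
  simulation_config(n_lakes = 20, n_basins = 3, n_otus = 300, depth = 5000,
                    clades = small_clade_specs(), ...)
}

# Independent generalized-eigenproblem oracle for CCA: eigenvalues of
# Q' Xw (Xw' Xw)^-1 Xw' Q built directly from the weighted cross-products.
oracle_cca_eigen <- function(Y, X, k = NULL) {
  tot <- sum(Y); P <- Y / tot
  r <- rowSums(P); cc <- colSums(P)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  Xc <- sweep(as.matrix(X), 2, colSums(r * as.matrix(X)))
  Xw <- Xc * sqrt(r)
  M <- t(Q) %*% Xw %*% solve(crossprod(Xw)) %*% t(Xw) %*% Q
  ev <- sort(eigen(M, symmetric = TRUE)$values, decreasing = TRUE)
  if (is.null(k)) k <- qr(Xw)$rank
  ev[seq_len(k)]
}

# Random strictly positive contingency-like table.
random_table <- function(n, m, seed, lambda = 10) {
  set.seed(seed)
  matrix(rpois(n * m, lambda) + 1, n, m,
         dimnames = list(sprintf("s%d", seq_len(n)), sprintf("o%d", seq_len(m))))
}
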