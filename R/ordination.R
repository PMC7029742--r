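# Chi-square-standardized community matrix used by correspondence analysis:
# Q = D_r^{-1/2} (P - r c^T) D_c^{-1/2} with P = Y / grand total.
# Total inertia is ||Q||_F^2 = Pearson chi-square / grand total.
chi_square_matrix <- function(Y) {
  if (any(Y < 0)) stop("validation error: negative abundances", call. = FALSE)
  tot <- sum(Y)
  if (tot <= 0) stop("validation error: empty table", call. = FALSE)
  P <- Y / tot
  r <- rowSums(P)
  cc <- colSums(P)
  if (any(r == 0)) stop("validation error: zero-sum row(s)", call. = FALSE)
  if (any(cc == 0)) stop("validation error: zero-sum column(s)", call. = FALSE)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  list(Q = Q, r = r, c = cc)
}

# Weighted standardization of constraints: zero weighted mean, unit weighted
# variance under site weights r. Errors on collinear columns, naming them.
standardize_constraints <- function(X, r, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mu <- colSums(r * X)
  Xc <- sweep(X, 2L, mu)
  wsd <- sqrt(colSums(r * Xc^2))
  if (any(wsd == 0)) {
    stop(sprintf("rank-deficiency: constant constraint column(s): %s",
                 paste(colnames(X)[wsd == 0], collapse = ", ")), call. = FALSE)
  }
  Xs <- sweep(Xc, 2L, wsd, "/")
  Xw <- Xs * sqrt(r)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(Xw)]]
    stop(sprintf("rank-deficiency: collinear constraint column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  list(Xs = Xs, Xw = Xw, qr = qrX)
}

#' Canonical correspondence analysis
#'
#' Correspondence analysis of a community table constrained to the span of
#' environmental predictors. The chi-square-standardized matrix `Q` is
#' projected, under site weights `r` (row masses), onto the column space of
#' the weighted, standardized constraints; the SVD of the fitted matrix
#' yields the canonical axes (eigenvalue = squared singular value). With
#' `X = NULL` an unconstrained correspondence analysis is returned.
#'
#' Scores use scaling 2: OTU scores are scaled by the axis singular value
#' (sqrt of eigenvalue); site scores are the linear-combination (LC)
#' scores, with unit weighted variance per axis. Constraint "eigenvectors"
#' (biplot arrows) are the weighted correlations of each constraint with
#' the LC site scores.
#'
#' @param Y community matrix (n sites x m OTUs), non-negative with positive
#'   row and column sums; an [OtuTable] is accepted.
#' @param X constraint matrix (n x q), or `NULL` for plain CA.
#' @return An object of class `OrdinationResult`: `eigenvalues`,
#'   `total_inertia`, `constrained_inertia`, `residual_inertia`,
#'   `site_scores`, `otu_scores`, `biplot` (q x axes, `NULL` for CA),
#'   `axis_labels`, `scaling = 2`.
#' @export
cca <- function(Y, X = NULL) {
  if (inherits(Y, "OtuTable")) Y <- Y$counts
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  cs <- chi_square_matrix(Y)
  Q <- cs$Q; r <- cs$r; cc <- cs$c
  total <- sum(Q^2)
  constrained_fit <- !is.null(X) && ncol(as.matrix(X)) > 0
  if (constrained_fit) {
    X <- as.matrix(X)
    if (n <= ncol(X) + 1) stop("need n > q + 1 sites", call. = FALSE)
    st <- standardize_constraints(X, r)
    Yfit <- qr.fitted(st$qr, Q)
    max_axes <- min(ncol(X), m - 1L, n - 1L)
  } else {
    Yfit <- Q
    max_axes <- min(m - 1L, n - 1L)
  }
  sv <- svd(Yfit)
  keep <- which(sv$d > 1e-10 * max(sv$d, 0))
  keep <- keep[keep <= max_axes]
  d <- sv$d[keep]
  labels <- paste0(if (constrained_fit) "CCA" else "CA", seq_along(keep))
  otu_raw <- sv$v[, keep, drop = FALSE] / sqrt(cc)       # m x k
  site_raw <- sv$u[, keep, drop = FALSE] / sqrt(r)       # n x k, LC scores
  otu_scores <- sweep(otu_raw, 2L, d, "*")               # scaling 2
  dimnames(otu_scores) <- list(colnames(Y), labels)
  dimnames(site_raw) <- list(rownames(Y), labels)
  biplot <- NULL
  constrained <- if (constrained_fit) sum(Yfit^2) else 0
  if (constrained_fit) {
    # weighted correlation of each (unit weighted variance) constraint with
    # the LC scores, which also have unit weighted variance
    biplot <- t(st$Xs * r) %*% site_raw
    dimnames(biplot) <- list(colnames(X), labels)
  }
  structure(list(
    eigenvalues = setNames(d^2, labels),
    singular_values = setNames(d, labels),
    total_inertia = total,
    constrained_inertia = constrained,
    residual_inertia = total - constrained,
    site_scores = site_raw,
    otu_scores = otu_scores,
    biplot = biplot,
    axis_labels = labels,
    scaling = 2,
    n_sites = n, n_otus = m,
    n_constraints = if (constrained_fit) ncol(X) else 0L
  ), class = "OrdinationResult")
}

#' @export
print.OrdinationResult <- function(x, ...) {
  kind <- if (x$n_constraints > 0) "CCA" else "CA"
  cat(sprintf("%s: %d sites x %d OTUs", kind, x$n_sites, x$n_otus))
  if (x$n_constraints > 0) {
    cat(sprintf(", %d constraints\n", x$n_constraints))
    cat(sprintf("  total inertia %.4f, constrained %.4f (%.1f%%)\n",
                x$total_inertia, x$constrained_inertia,
                100 * x$constrained_inertia / x$total_inertia))
  } else {
    cat(sprintf("\n  total inertia %.4f\n", x$total_inertia))
  }
  cat("  eigenvalues:", paste(sprintf("%.4f", utils::head(x$eigenvalues, 6)),
                              collapse = " "), "\n")
  invisible(x)
}

# Constrained inertia of Q projected on weighted standardized X (helper for
# permutation tests; returns sum of squares of the fitted matrix).
constrained_inertia_of <- function(Q, X, r) {
  st <- standardize_constraints(X, r)
  sum(qr.fitted(st$qr, Q)^2)
}

#' Permutation test for a CCA model or a single constraint
#'
#' Pseudo-F for the whole model is
#' `(constrained inertia / q) / (residual inertia / (n - 1 - q))`; for a
#' margin term, the tested constraint is partialled against the remaining
#' columns (partial CCA) and its single-axis inertia forms the numerator.
#' Significance is by unrestricted permutation of constraint rows: whole
#' rows of `X` for the model test, the tested column alone (covariates
#' fixed) for a margin test; `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`.
#'
#' @inheritParams cca
#' @param term `"model"` for the omnibus test, or `margin:<column name>`
#'   (alternatively just the column name) for one constraint.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return A list of class `PermutationAnovaResult`: `pseudo_F`, `p`,
#'   `n_perm`, `term`, `seed`.
#' @export
permutation_anova <- function(Y, X, term = "model", n_perm = 999, seed) {
  if (inherits(Y, "OtuTable")) Y <- Y$counts
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  assert_scalar_count(n_perm, "n_perm", min = 99)
  cs <- chi_square_matrix(Y)
  Q <- cs$Q; r <- cs$r
  n <- nrow(Y); q <- ncol(X)
  if (n <= q + 1) stop("need n > q + 1 sites", call. = FALSE)
  total <- sum(Q^2)
  constrained_full <- constrained_inertia_of(Q, X, r)
  resid_ms <- (total - constrained_full) / (n - 1 - q)
  margin <- sub("^margin:", "", term)
  if (term == "model") {
    f_of <- function(Xp) (constrained_inertia_of(Q, Xp, r) / q) / resid_ms
    F_obs <- f_of(X)
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        f_of(X[sample.int(n), , drop = FALSE]) >= F_obs
      }, logical(1)))
    })
  } else {
    if (!margin %in% colnames(X)) {
      stop(sprintf("validation error: no constraint column '%s'", margin), call. = FALSE)
    }
    j <- match(margin, colnames(X))
    f_margin <- function(xj) {
      Xp <- X; Xp[, j] <- xj
      st <- standardize_constraints(Xp, r)
      Zw <- st$Xw[, -j, drop = FALSE]
      if (ncol(Zw) > 0) {
        qz <- qr(Zw)
        Qres <- Q - qr.fitted(qz, Q)
        xres <- st$Xw[, j] - qr.fitted(qz, st$Xw[, j])
      } else {
        Qres <- Q
        xres <- st$Xw[, j]
      }
      lam <- sum(drop(crossprod(xres, Qres))^2) / sum(xres^2)
      lam / resid_ms
    }
    F_obs <- f_margin(X[, j])
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        f_margin(X[sample.int(n), j]) >= F_obs
      }, logical(1)))
    })
  }
  structure(list(pseudo_F = F_obs, p = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, term = term, seed = seed),
            class = "PermutationAnovaResult")
}

#' @export
print.PermutationAnovaResult <- function(x, ...) {
  cat(sprintf("CCA permutation test (%s): pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$term, x$pseudo_F, x$p, x$n_perm))
  invisible(x)
}

#' Adjusted R-squared of a redundancy analysis
#'
#' RDA explained variance: `R2` is the sum of squares of the fitted,
#' column-centered response matrix over its total sum of squares (ordinary
#' least squares on the constraints), with the Ezekiel adjustment
#' `R2adj = 1 - (1 - R2) (n - 1) / (n - q - 1)`; may be negative.
#'
#' @param Y response matrix (n x m), e.g. log-transformed abundances.
#' @param X predictor matrix (n x q), or `NULL` for the intercept-only
#'   model (adjusted R2 = 0).
#' @return List with `r2`, `adj_r2`, `q` (predictor rank), `n`.
#' @export
rda_adjusted_r2 <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  if (is.null(X) || ncol(as.matrix(X)) == 0) {
    return(list(r2 = 0, adj_r2 = 0, q = 0L, n = n))
  }
  X <- as.matrix(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  q <- qrX$rank
  if (q >= n - 1) stop("validation error: q >= n - 1", call. = FALSE)
  r2 <- sum(qr.fitted(qrX, Yc)^2) / ss_tot
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - q - 1), q = q, n = n)
}

#' Three-way variation partitioning
#'
#' Partitions the adjusted explained variance of a (transformed) community
#' matrix among three predictor sets by inclusion-exclusion over the seven
#' RDA subset models: three unique fractions, three pairwise-shared, one
#' three-way-shared, and the residual; the eight fractions sum to 1 by
#' construction. Shared fractions can be negative (they are differences of
#' adjusted R-squared values, not variances).
#'
#' @param Y response matrix (typically `log10(1 + x)` abundances).
#' @param X1,X2,X3 predictor matrices over the same samples.
#' @param names labels for the three sets.
#' @return A list of class `VarpartResult`: `adj_r2` (the 7 subset models),
#'   `fractions` (named: `unique_<i>`, `shared_<i>_<j>`, `shared_all`,
#'   `residual`).
#' @export
varpart3 <- function(Y, X1, X2, X3, names = c("X1", "X2", "X3")) {
  Y <- as.matrix(Y)
  sets <- list(as.matrix(X1), as.matrix(X2), as.matrix(X3))
  adj <- function(parts) rda_adjusted_r2(Y, do.call(cbind, sets[parts]))$adj_r2
  A1 <- adj(1); A2 <- adj(2); A3 <- adj(3)
  A12 <- adj(c(1, 2)); A13 <- adj(c(1, 3)); A23 <- adj(c(2, 3))
  A123 <- adj(c(1, 2, 3))
  u1 <- A123 - A23; u2 <- A123 - A13; u3 <- A123 - A12
  g <- A1 + A2 + A3 - A12 - A13 - A23 + A123
  s12 <- A1 + A2 - A12 - g
  s13 <- A1 + A3 - A13 - g
  s23 <- A2 + A3 - A23 - g
  fr <- c(u1, u2, u3, s12, s13, s23, g, 1 - A123)
  names(fr) <- c(paste0("unique_", names),
                 paste0("shared_", c(paste(names[1], names[2], sep = "_"),
                                     paste(names[1], names[3], sep = "_"),
                                     paste(names[2], names[3], sep = "_"))),
                 "shared_all", "residual")
  adj_r2 <- c(A1, A2, A3, A12, A13, A23, A123)
  names(adj_r2) <- c(names, paste(names[1], names[2], sep = "+"),
                     paste(names[1], names[3], sep = "+"),
                     paste(names[2], names[3], sep = "+"),
                     paste(names, collapse = "+"))
  structure(list(adj_r2 = adj_r2, fractions = fr, set_names = names),
            class = "VarpartResult")
}

#' @export
print.VarpartResult <- function(x, ...) {
  cat("Variation partitioning (adjusted R2 fractions):\n")
  print(round(x$fractions, 4))
  invisible(x)
}
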