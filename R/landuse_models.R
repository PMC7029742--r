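#' Enumerate all first-order predictor subsets
#'
#' All `2^k` subsets of the predictor names, including the intercept-only
#' (empty) model, ordered by subset size and then lexicographically within
#' a size. This is the model set over which Akaike weights are computed.
#'
#' @param predictors character vector of predictor names (1 to 20, unique).
#' @return List of character vectors (the empty model is `character(0)`).
#' @export
enumerate_models <- function(predictors) {
  if (length(predictors) < 1 || length(predictors) > 20) {
    stop("validation error: need between 1 and 20 predictors", call. = FALSE)
  }
  if (anyDuplicated(predictors)) {
    stop("validation error: duplicate predictor names", call. = FALSE)
  }
  out <- list(character(0))
  for (size in seq_along(predictors)) {
    subs <- combn(sort(predictors), size, simplify = FALSE)
    ord <- order(vapply(subs, paste, character(1), collapse = "\r"))
    out <- c(out, subs[ord])
  }
  out
}

#' Fit one Gaussian linear model
#'
#' Ordinary least squares with a Gaussian likelihood via [stats::lm()].
#' Reports the standard information-criterion quantities with
#' `k = #coefficients + 1` (the residual variance counts as a parameter):
#' `AIC = -2 logLik + 2k` and the small-sample
#' `AICc = AIC + 2k(k+1)/(n-k-1)`.
#'
#' @param y numeric response vector.
#' @param X data frame or matrix of predictor columns (may have zero
#'   columns for the intercept-only model).
#' @param allow_aliased collinear predictors are an error by default; with
#'   `TRUE` the fit proceeds with aliased coefficients dropped (treated as
#'   0), which is needed when compositional predictors that sum to 1 make
#'   the largest subsets rank-deficient against the intercept.
#' @return A list of class `ModelFit`: `predictors`, `coefficients`, `se`,
#'   `sigma2`, `logLik`, `AIC`, `AICc`, `r2`, `n`, `fit` (the `lm` object).
#' @export
fit_gaussian_glm <- function(y, X = NULL, allow_aliased = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- data.frame(row.names = seq_len(n))
  X <- as.data.frame(X)
  k_pred <- ncol(X)
  if (n <= k_pred + 2) stop("validation error: too few observations", call. = FALSE)
  if (any(!is.finite(y)) || (k_pred > 0 && any(!is.finite(as.matrix(X))))) {
    stop("validation error: non-finite values", call. = FALSE)
  }
  dat <- cbind(data.frame(.y = y), X)
  fml <- if (k_pred == 0) .y ~ 1 else
    stats::reformulate(sprintf("`%s`", names(X)), response = ".y")
  fit <- lm(fml, data = dat)
  if (fit$rank < k_pred + 1 && !allow_aliased) {
    stop("rank error: collinear predictors", call. = FALSE)
  }
  ll <- as.numeric(logLik(fit))
  k <- fit$rank + 1
  aic <- -2 * ll + 2 * k
  sm <- suppressWarnings(summary(fit))   # noise-free fits trip a benign warning
  cf <- coef(fit)
  cf[is.na(cf)] <- 0   # aliased terms contribute nothing
  structure(list(
    predictors = names(X),
    coefficients = cf,
    se = sm$coefficients[, "Std. Error"],
    sigma2 = sum(fit$residuals^2) / n,
    logLik = ll,
    AIC = aic,
    AICc = aic + 2 * k * (k + 1) / (n - k - 1),
    r2 = sm$r.squared,
    n = n,
    fit = fit
  ), class = "ModelFit")
}

#' Akaike weights of a model set
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`; computed after subtracting the minimum so
#' large AICs cannot underflow the normalization. Each weight is the
#' probability that model i is the best (by expected information loss) in
#' the set.
#'
#' @param aics numeric vector of AIC (or AICc) values, length >= 2.
#' @return Numeric weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 2) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(aics))) stop("validation error: non-finite AIC", call. = FALSE)
  rel <- exp(-(aics - min(aics)) / 2)
  rel / sum(rel)
}

#' Variable importance and model-averaged coefficients
#'
#' The importance of a predictor is the sum of the Akaike weights of the
#' models that contain it; a variable appearing in many well-supported
#' models scores near 1. Model-averaged coefficients use shrinkage
#' (zero-substitution) averaging by default: a model not containing the
#' predictor contributes a coefficient of 0; conditional averaging
#' (averaging only over the containing models) is available.
#'
#' @param fits list of [fit_gaussian_glm()] results covering a model set.
#' @param weights Akaike weights of the same length.
#' @param conditional if `TRUE`, average coefficients only across models
#'   containing the term.
#' @return A list of class `EnsembleResult`: `importance` (named, in
#'   `[0,1]`), `averaged_coefficients`, `weights`, `best_index`,
#'   `best_predictors`, `best_r2`, `full_r2`.
#' @export
importance_and_average <- function(fits, weights, conditional = FALSE) {
  if (length(fits) != length(weights)) {
    stop("validation error: weights/fits length mismatch", call. = FALSE)
  }
  predictors <- sort(unique(unlist(lapply(fits, `[[`, "predictors"))))
  has <- vapply(fits, function(f) predictors %in% f$predictors,
                logical(length(predictors)))
  has <- matrix(has, nrow = length(predictors),
                dimnames = list(predictors, NULL))
  importance <- drop(has %*% weights)
  avg <- vapply(predictors, function(p) {
    b <- vapply(fits, function(f) {
      if (p %in% f$predictors) unname(f$coefficients[p]) else 0
    }, numeric(1))
    if (conditional) {
      sum(weights[has[p, ]] * b[has[p, ]]) / sum(weights[has[p, ]])
    } else {
      sum(weights * b)
    }
  }, numeric(1))
  best <- which.max(weights)
  full <- which(vapply(fits, function(f) length(f$predictors), integer(1)) ==
                  length(predictors))[1]
  structure(list(
    importance = importance,
    averaged_coefficients = avg,
    weights = weights,
    best_index = best,
    best_predictors = fits[[best]]$predictors,
    best_r2 = fits[[best]]$r2,
    full_r2 = if (is.na(full)) NA_real_ else fits[[full]]$r2
  ), class = "EnsembleResult")
}

# R2 of y on the named predictor subset (helper for hierarchical
# partitioning); empty subset gives 0.
subset_r2 <- function(y, X, subset) {
  if (length(subset) == 0) return(0)
  Xs <- as.matrix(X[, subset, drop = FALSE])
  qrX <- qr(scale(Xs, center = TRUE, scale = FALSE))
  yc <- y - mean(y)
  sum(qr.fitted(qrX, yc)^2) / sum(yc^2)
}

#' Hierarchical partitioning of explained variance
#'
#' Splits the full-model R2 into one independent contribution per
#' predictor: for predictor j, the increase in R2 from adding j is averaged
#' over all subsets not containing j within each hierarchy level (subset
#' size), and then averaged over levels. Independent contributions sum to
#' the full-model R2. The joint contribution of j is its marginal
#' (single-predictor) R2 minus its independent contribution — the part of
#' its explanatory power it shares with the other predictors.
#'
#' @param y response vector.
#' @param X predictor matrix or data frame (k <= 12; the method enumerates
#'   all `2^k` subsets).
#' @return List with `independent` and `joint` (named vectors) and
#'   `full_r2`.
#' @export
independent_contribution <- function(y, X) {
  X <- as.data.frame(X)
  k <- ncol(X)
  if (k > 12) {
    stop("validation error: more than 12 predictors; reduce the set", call. = FALSE)
  }
  preds <- names(X)
  subsets <- enumerate_models(preds)
  skey <- function(s) if (length(s) == 0) "(none)" else paste(sort(s), collapse = "|")
  r2 <- vapply(subsets, function(s) subset_r2(y, X, s), numeric(1))
  r2_of <- setNames(r2, vapply(subsets, skey, character(1)))
  indep <- vapply(preds, function(p) {
    others <- setdiff(preds, p)
    # level h = number of other predictors already in the model (0..k-1)
    level_means <- vapply(0:(k - 1), function(h) {
      subs <- if (h == 0) list(character(0)) else
        combn(others, h, simplify = FALSE)
      gains <- vapply(subs, function(s) {
        r2_of[[skey(c(s, p))]] - r2_of[[skey(s)]]
      }, numeric(1))
      mean(gains)
    }, numeric(1))
    mean(level_means)
  }, numeric(1))
  marginal <- vapply(preds, function(p) r2_of[[p]], numeric(1))
  list(independent = indep, joint = marginal - indep,
       full_r2 = r2_of[[skey(preds)]])
}

#' All-subsets AIC multimodel inference for one response
#'
#' Convenience wrapper running the whole chain: enumerate all first-order
#' predictor subsets, fit each by OLS, convert AIC (or AICc) to Akaike
#' weights, compute per-predictor importance and model-averaged
#' coefficients, and add hierarchical-partitioning independent
#' contributions. Rows with a missing response or predictor are dropped
#' (listwise deletion) with a message.
#'
#' @param y response vector.
#' @param X predictor data frame or matrix.
#' @param criterion `"AIC"` (default) or the small-sample `"AICc"`.
#' @param log10_response if `TRUE`, model `log10(y)` (right-skewed
#'   concentrations); requires positive `y`.
#' @return An `EnsembleResult` (see [importance_and_average()]) with the
#'   extra elements `independent`, `joint`, `full_r2`, `criterion`,
#'   `n_models`, `n_obs`.
#' @export
aic_ensemble <- function(y, X, criterion = c("AIC", "AICc"), log10_response = FALSE) {
  criterion <- match.arg(criterion)
  X <- as.data.frame(X)
  ok <- is.finite(y) & stats::complete.cases(X)
  if (any(!ok)) {
    message(sprintf("dropping %d observation(s) with missing values", sum(!ok)))
  }
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (log10_response) {
    if (any(y <= 0)) stop("log10 response requires positive values", call. = FALSE)
    y <- log10(y)
  }
  subsets <- enumerate_models(names(X))
  fits <- lapply(subsets, function(s) {
    fit_gaussian_glm(y, X[, s, drop = FALSE], allow_aliased = TRUE)
  })
  aics <- vapply(fits, `[[`, numeric(1), criterion)
  w <- akaike_weights(aics)
  ens <- importance_and_average(fits, w)
  hp <- independent_contribution(y, X)
  ens$independent <- hp$independent
  ens$joint <- hp$joint
  ens$full_r2 <- hp$full_r2
  ens$criterion <- criterion
  ens$n_models <- length(fits)
  ens$n_obs <- length(y)
  ens
}

#' @export
print.EnsembleResult <- function(x, ...) {
  cat("AIC multimodel inference\n")
  cat("  importance:\n")
  print(round(sort(x$importance, decreasing = TRUE), 3))
  cat(sprintf("  best model: {%s}, R2 = %.3f\n",
              paste(x$best_predictors, collapse = ", "), x$best_r2))
  if (!is.null(x$full_r2)) cat(sprintf("  full-model R2 = %.3f\n", x$full_r2))
  invisible(x)
}
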