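test_that("model enumeration covers every first-order subset in stable order", {
  ms <- enumerate_models(c("b", "a"))
  expect_equal(ms, list(character(0), "a", "b", c("a", "b")))
  expect_length(enumerate_models(letters[1:6]), 64)
  expect_length(enumerate_models("x"), 2)
  expect_error(enumerate_models(character(0)), "between 1 and 20")
  expect_error(enumerate_models(c("a", "a")), "duplicate")
  sizes <- lengths(enumerate_models(letters[1:4]))
  expect_true(all(diff(sizes) >= 0))   # ordered by subset size
})

test_that("Gaussian fits match the normal-equations oracle and AIC identities", {
  x <- seq(0, 5, length.out = 20)
  exact <- fit_gaussian_glm(3 + 2 * x, data.frame(x = x))
  expect_equal(unname(exact$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(exact$r2, 1, tolerance = 1e-10)
  null <- fit_gaussian_glm(rnorm(20))
  expect_equal(null$r2, 0)
  set.seed(13)
  n <- 30
  X <- as.data.frame(matrix(rnorm(n * 3), n, 3,
                            dimnames = list(NULL, c("p1", "p2", "p3"))))
  y <- 1 + X$p1 - 2 * X$p2 + rnorm(n)
  fit <- fit_gaussian_glm(y, X)
  beta_oracle <- solve(crossprod(cbind(1, as.matrix(X))),
                       crossprod(cbind(1, as.matrix(X)), y))
  expect_equal(unname(fit$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-10)
  expect_equal(fit$AIC, stats::AIC(fit$fit), tolerance = 1e-10)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * (3 + 1 + 1), tolerance = 1e-12)
  expect_equal(fit$AICc, fit$AIC + 2 * 5 * 6 / (n - 5 - 1), tolerance = 1e-12)
  expect_error(fit_gaussian_glm(y, cbind(X, p4 = X$p1 + X$p2)), "rank")
  expect_error(fit_gaussian_glm(1:3, X[1:3, ]), "too few")
})

test_that("Akaike weights have their closed forms and invariances", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w[1] / w[2], exp(1), tolerance = 1e-12)
  set.seed(19)
  for (i in 1:10) {
    a <- runif(8, 0, 500)
    w <- akaike_weights(a)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(akaike_weights(a + 123.4), w, tolerance = 1e-12)
  }
  expect_error(akaike_weights(c(1, NA)), "non-finite")
  expect_error(akaike_weights(5), "at least 2")
})

test_that("a dominant predictor earns importance near 1 and a recovered coefficient", {
  hits <- 0; coefs <- numeric(0)
  for (seed in 1:12) {
    set.seed(seed)
    n <- 46
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                              dimnames = list(NULL, paste0("v", 1:4))))
    y <- 5 * X$v1 + rnorm(n)   # effect 5 SD of noise
    ens <- aic_ensemble(y, X)
    if (ens$importance["v1"] > 0.95) hits <- hits + 1
    coefs <- c(coefs, ens$averaged_coefficients["v1"])
    expect_equal(names(which.max(ens$importance)), "v1")
  }
  expect_gte(hits, 11)
  expect_lt(abs(mean(coefs) - 5) / 5, 0.1)
})

test_that("pure-noise predictors never reach full importance", {
  set.seed(77)
  imp <- replicate(20, {
    n <- 46
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                              dimnames = list(NULL, paste0("v", 1:4))))
    max(aic_ensemble(rnorm(n), X)$importance)
  })
  expect_lt(mean(imp), 0.9)
})

test_that("hierarchical partitioning matches the exhaustive-orderings oracle", {
  set.seed(29)
  n <- 25
  X <- as.data.frame(matrix(rnorm(n * 3), n, 3,
                            dimnames = list(NULL, c("a", "b", "c"))))
  y <- X$a + 0.5 * X$b + rnorm(n, 0, 0.7)
  hp <- independent_contribution(y, X)
  # Shapley oracle: average marginal R2 gain over all 3! orderings
  r2 <- function(s) {
    if (length(s) == 0) return(0)
    summary(lm(y ~ ., data = X[, s, drop = FALSE]))$r.squared
  }
  orderings <- list(c("a","b","c"), c("a","c","b"), c("b","a","c"),
                    c("b","c","a"), c("c","a","b"), c("c","b","a"))
  shapley <- sapply(c("a", "b", "c"), function(p) {
    mean(sapply(orderings, function(o) {
      pos <- match(p, o)
      before <- o[seq_len(pos - 1)]
      r2(c(before, p)) - r2(before)
    }))
  })
  expect_equal(hp$independent, shapley, tolerance = 1e-10)
  expect_equal(sum(hp$independent), hp$full_r2, tolerance = 1e-10)
})

test_that("hierarchical partitioning resolves orthogonal and duplicated designs", {
  n <- 30
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 2), n), scale = FALSE)))
  X <- as.data.frame(Q); names(X) <- c("a", "b")
  y <- drop(2 * Q[, 1] + Q[, 2])
  hp <- independent_contribution(y, X)
  marg_a <- summary(lm(y ~ a, data = X))$r.squared
  marg_b <- summary(lm(y ~ b, data = X))$r.squared
  expect_equal(unname(hp$independent["a"]), marg_a, tolerance = 1e-10)
  expect_equal(unname(hp$independent["b"]), marg_b, tolerance = 1e-10)
  expect_equal(unname(hp$joint), c(0, 0), tolerance = 1e-10)
  # duplicated predictors split their shared variance equally
  Xd <- data.frame(a = Q[, 1], b = Q[, 1])
  yd <- drop(Q[, 1]) + rnorm(n, 0, 0.3)
  hpd <- independent_contribution(yd, Xd)
  expect_equal(unname(hpd$independent["a"]), unname(hpd$independent["b"]),
               tolerance = 1e-10)
  expect_equal(unname(hpd$independent["a"]),
               summary(lm(yd ~ a, data = Xd))$r.squared / 2, tolerance = 1e-10)
  expect_error(independent_contribution(yd, as.data.frame(matrix(rnorm(n * 13), n))),
               "12")
})

test_that("the ensemble handles compositional predictors and missing data", {
  ds <- simulate_lake_dataset(small_sim_config(), seed = 15)
  lu <- as.data.frame(landuse_matrix(ds$metadata, "basin"))
  y <- ds$metadata$no23
  y[3] <- NA
  expect_message(ens <- aic_ensemble(y, lu), "dropping 1")
  expect_equal(ens$n_obs, nrow(lu) - 1)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-9)
  expect_true(all(ens$importance >= 0 & ens$importance <= 1))
  expect_equal(sum(ens$independent), ens$full_r2, tolerance = 1e-8)
})
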