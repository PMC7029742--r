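test_that("unconstrained CA inertia equals chi-square over grand total", {
  Y <- matrix(c(10, 0, 0, 10), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(cca(Y)$total_inertia, 1.0, tolerance = 1e-12)
  Y2 <- random_table(7, 11, seed = 21)
  chisq <- suppressWarnings(stats::chisq.test(Y2, correct = FALSE)$statistic)
  expect_equal(cca(Y2)$total_inertia, unname(chisq) / sum(Y2), tolerance = 1e-10)
})

test_that("CCA matches the generalized-eigenproblem oracle and vegan", {
  for (seed in c(11, 12, 13)) {
    Y <- random_table(8, 12, seed = seed)
    set.seed(seed + 100)
    X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
    fit <- cca(Y, X)
    expect_equal(unname(fit$eigenvalues), oracle_cca_eigen(Y, X, k = 2),
                 tolerance = 1e-8)
    vfit <- vegan::cca(Y ~ a + b, data = as.data.frame(X))
    expect_equal(unname(fit$eigenvalues), unname(vfit$CCA$eig), tolerance = 1e-10)
    expect_equal(fit$total_inertia, vfit$tot.chi, tolerance = 1e-10)
    # scores agree with the reference implementation up to axis sign
    vsc <- vegan::scores(vfit, display = c("sp", "lc", "bp"), scaling = 2)
    for (k in 1:2) {
      sgn <- sign(sum(fit$otu_scores[, k] * vsc$species[, k]))
      expect_equal(unname(fit$otu_scores[, k]), sgn * unname(vsc$species[, k]),
                   tolerance = 1e-8)
      expect_equal(unname(fit$site_scores[, k]),
                   sgn * unname(vsc$constraints[, k]), tolerance = 1e-8)
      expect_equal(unname(fit$biplot[, k]), sgn * unname(vsc$biplot[, k]),
                   tolerance = 1e-8)
    }
  }
})

test_that("CCA inertia decomposition, bounds and nesting hold", {
  Y <- random_table(10, 15, seed = 31)
  set.seed(32)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- cca(Y, X)
  expect_equal(fit$constrained_inertia + fit$residual_inertia,
               fit$total_inertia, tolerance = 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-10))
  expect_true(all(fit$eigenvalues <= 1 + 1e-10))   # CA eigenvalue bound
  # nesting: adding a constraint never decreases constrained inertia
  fit2 <- cca(Y, X[, 1:2])
  expect_gte(fit$constrained_inertia, fit2$constrained_inertia - 1e-12)
  # effectively saturated constraints recover the full inertia: sites 9 and
  # 10 share a group and identical profiles, so 8 indicators fit Q exactly
  Ysat <- Y; Ysat[10, ] <- Ysat[9, ]
  G <- stats::model.matrix(~ 0 + factor(c(1:8, 9, 9)))[, -1]
  colnames(G) <- paste0("g", seq_len(ncol(G)))
  sat <- cca(Ysat, G)
  expect_equal(sat$constrained_inertia, sat$total_inertia, tolerance = 1e-10)
  # collinear constraints are refused with the offending column named
  Xbad <- cbind(X, d = X[, 1] + X[, 2])
  expect_error(cca(Y, Xbad), "collinear.*d")
  expect_error(cca(cbind(Y, o99 = 0)), "zero-sum")
})

test_that("whole-model permutation test recovers a planted gradient", {
  cfg <- small_sim_config()
  ds <- simulate_lake_dataset(cfg, seed = 301)
  chem <- chemistry_matrix(ds$metadata)
  res <- permutation_anova(ds$table, chem, "model", n_perm = 99, seed = 5)
  expect_equal(res$p, 1 / 100)
  expect_gt(res$pseudo_F, 1)
  # a margin test on the strongest niche variable is also significant
  mar <- permutation_anova(ds$table, chem, "margin:tp", n_perm = 99, seed = 6)
  expect_equal(mar$p, 1 / 100)
  expect_error(permutation_anova(ds$table, chem, "margin:nope", n_perm = 99,
                                 seed = 1), "nope")
})

test_that("RDA adjusted R2 matches the least-squares trace oracle", {
  expect_equal(rda_adjusted_r2(random_table(8, 5, 1))$adj_r2, 0)
  set.seed(41)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  B <- matrix(rnorm(3 * 6), 3, 6)
  Yexact <- X %*% B
  exact <- rda_adjusted_r2(Yexact, X)
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_equal(exact$adj_r2, 1, tolerance = 1e-12)
  Y <- Yexact + matrix(rnorm(n * 6), n, 6)
  got <- rda_adjusted_r2(Y, X)
  # normal-equations oracle
  X1 <- cbind(1, X)
  H <- X1 %*% solve(crossprod(X1)) %*% t(X1)
  Yc <- scale(Y, scale = FALSE)
  r2_oracle <- sum((H %*% Yc)^2) / sum(Yc^2)
  expect_equal(got$r2, r2_oracle, tolerance = 1e-10)
  expect_equal(got$adj_r2, 1 - (1 - r2_oracle) * (n - 1) / (n - 3 - 1),
               tolerance = 1e-10)
  vr <- vegan::RsquareAdj(vegan::rda(Y ~ X))
  expect_equal(got$adj_r2, vr$adj.r.squared, tolerance = 1e-10)
  expect_error(rda_adjusted_r2(Y[1:4, ], X[1:4, ]), "q >= n - 1")
})

test_that("three-way variation partitioning decomposes correctly", {
  set.seed(51)
  n <- 40
  X1 <- matrix(rnorm(n * 2), n); X2 <- matrix(rnorm(n * 2), n)
  X3 <- matrix(rnorm(n * 2), n)
  Y <- X1 %*% matrix(rnorm(8), 2) + matrix(rnorm(n * 4), n)
  vp <- varpart3(Y, X1, X2, X3)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-8)
  # agrees with the reference implementation
  vvp <- vegan::varpart(Y, X1, X2, X3)$part$indfract$Adj.R.square
  expect_equal(sort(unname(vp$fractions)), sort(vvp), tolerance = 1e-8)
  # duplicated set has no unique fraction
  vp_dup <- varpart3(Y, X1, X1, X3)
  expect_equal(unname(vp_dup$fractions["unique_X2"]), 0, tolerance = 1e-10)
  # orthogonal additive construction recovers the variance shares; shared
  # fractions vanish only up to the O(q/n) Ezekiel-adjustment mismatch
  # between subset sizes, so use a larger n here
  n <- 100
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 6), n), scale = FALSE)))
  O1 <- Q[, 1:2]; O2 <- Q[, 3:4]; O3 <- Q[, 5:6]
  Yadd <- O1 %*% matrix(2, 2, 3) + O2 %*% matrix(1, 2, 3)
  vpo <- varpart3(Yadd, O1, O2, O3)
  expect_lt(max(abs(vpo$fractions[c("shared_X1_X2", "shared_X1_X3",
                                    "shared_X2_X3", "shared_all")])), 0.06)
  expect_gt(vpo$fractions["unique_X1"], vpo$fractions["unique_X2"])
  expect_equal(unname(vpo$fractions["unique_X1"] / vpo$fractions["unique_X2"]),
               4, tolerance = 1e-6)   # effect 2 vs 1 => variance ratio 4
})
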