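coords_fixture <- function(n = 60, seed = 17, sd = 1) {
  set.seed(seed)
  matrix(rnorm(2 * n, 0, sd), n, 2,
         dimnames = list(sprintf("OTU%03d", seq_len(n)), c("CCA1", "CCA2")))
}

test_that("clustering score is the sum of pairwise Euclidean distances", {
  xy <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(clustering_score(xy, c("a", "b")), 5)
  xy3 <- rbind(a = c(0, 0), b = c(1, 0), c = c(2, 0))
  expect_equal(clustering_score(xy3, rownames(xy3)), 4)   # 1 + 2 + 1
  pts <- coords_fixture(6)
  brute <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    brute <- brute + sqrt(sum((pts[i, ] - pts[j, ])^2))
  }
  expect_equal(clustering_score(pts, rownames(pts)), brute, tolerance = 1e-12)
  expect_error(clustering_score(pts, "OTU001"), "singleton")
})

test_that("clustering score is invariant under rotation and translation", {
  pts <- coords_fixture(12)
  d0 <- clustering_score(pts, rownames(pts))
  theta <- 0.73
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- pts %*% R + matrix(c(5, -2), 12, 2, byrow = TRUE)
  rownames(moved) <- rownames(pts)
  expect_equal(clustering_score(moved, rownames(pts)), d0, tolerance = 1e-9)
})

test_that("projection score normalizes v, carries sign, and is antisymmetric", {
  xy <- rbind(a = c(3, 4), b = c(1, 0))
  expect_equal(projection_score(xy, c("a", "b"), c(1, 0)), 4)
  expect_equal(projection_score(xy, "a", c(0, 2)), 4)  # magnitude irrelevant
  pts <- coords_fixture(15)
  expect_equal(projection_score(pts, rownames(pts), c(1, 0)),
               -projection_score(pts, rownames(pts), c(-1, 0)))
  # translation orthogonal to v leaves the score unchanged
  shifted <- pts; shifted[, 2] <- shifted[, 2] + 100
  expect_equal(projection_score(shifted, rownames(pts), c(1, 0)),
               projection_score(pts, rownames(pts), c(1, 0)))
  expect_error(projection_score(pts, rownames(pts), c(0, 0)), "zero")
})

test_that("clustering test flags a planted coincident clade and saturates correctly", {
  pool <- coords_fixture(500, sd = 3)
  pool[1:10, 1] <- 0.001 * (1:10); pool[1:10, 2] <- 0   # coincident clade
  map <- list(planted = rownames(pool)[1:10],
              background = rownames(pool)[11:500])
  res <- clustering_test(pool, map, n = 1000, seed = 99)
  expect_equal(res$p_clust[res$clade == "planted"], 0)
  expect_lte(res$q_clust[res$clade == "planted"], 0.05)
  expect_gt(res$p_clust[res$clade == "background"], 0.05)
  # clade == entire pool: every draw reproduces d_p, ties count upward
  whole <- list(all = rownames(pool))
  res_sat <- clustering_test(pool, whole, n = 100, seed = 1,
                             pool = rownames(pool))
  expect_equal(res_sat$p_clust, 1)
  expect_error(clustering_test(pool, list(big = rownames(pool)), n = 100,
                               seed = 1, pool = rownames(pool)[1:5]),
               "larger than the null pool")
})

test_that("association test detects planted displacement with the right sign", {
  set.seed(23)
  pool <- coords_fixture(300, sd = 1.5)
  pool[1:20, 1] <- pool[1:20, 1] + 5    # clade shifted along +x
  map <- list(shifted = rownames(pool)[1:20])
  ev <- rbind(CCA1 = c(1, 0), CCA1neg = c(-1, 0), CCA2 = c(0, 1))
  res <- association_test(pool, map, ev, n = 1000, seed = 7)
  r1 <- res[res$vector == "CCA1", ]
  expect_equal(r1$direction, "positive")
  expect_lte(r1$q_assoc, 0.05)
  # v and -v: u flips, two-sided p unchanged, direction swaps
  r1n <- res[res$vector == "CCA1neg", ]
  expect_equal(r1n$u, 1 - r1$u)
  expect_equal(r1n$p_assoc, r1$p_assoc)
  expect_equal(r1n$direction, "negative")
})

test_that("a clade symmetric about the origin along v is unassociated", {
  base <- matrix(rnorm(40, 0, 2), 20, 2)
  pts <- rbind(base, -base)   # exactly symmetric
  rownames(pts) <- sprintf("OTU%03d", 1:40)
  map <- list(sym = rownames(pts))
  res <- association_test(pts, map, rbind(CCA1 = c(1, 0)), n = 1000, seed = 3)
  expect_lt(abs(res$u - 0.5), 0.07)
  expect_equal(res$direction, "none")
})

test_that("end-to-end clade tests recover the planted phylum structure", {
  cfg <- small_sim_config()
  ds <- simulate_lake_dataset(cfg, seed = 71)
  rare <- rarefy(ds$table, 4000, seed = 72)
  rare <- filter_low_abundance(rare, 1)
  ord <- cca(rare, chemistry_matrix(ds$metadata))
  res <- run_clade_tests(ord, rare, ranks = "phylum", seed = 73,
                         n_clustering = 1000, n_association = 1000)
  planted <- attr(cfg$clades, "planted")
  clust_p <- res$q_clust[match(unique(res$clade), res$clade)]
  names(clust_p) <- unique(res$clade)
  expect_lte(clust_p[[planted$clustered]], 0.05)
  expect_gt(clust_p[[planted$neutral]], 0.05)
  assoc <- res[res$clade == planted$associated$clade &
                 res$vector == planted$associated$var, ]
  expect_equal(assoc$direction, "positive")
  # determinism: the same seed reproduces the table exactly
  res2 <- run_clade_tests(ord, rare, ranks = "phylum", seed = 73,
                          n_clustering = 1000, n_association = 1000)
  expect_identical(res, res2)
})

test_that("clade tests degrade gracefully without taxonomy", {
  tab <- OtuTable(make_counts(rpois(40, 20) + 1, 4, 10))
  ord <- cca(tab, matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b"))))
  expect_warning(
    expect_warning(res <- run_clade_tests(ord, tab, ranks = "phylum", seed = 1),
                   "no clade meets"),
    "no clade tested")
  expect_equal(nrow(res), 0)
})
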