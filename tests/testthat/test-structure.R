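test_that("genotype PCA separates two clusters of clones on PC1 with all
          the variance", {
  d <- rbind(matrix(0L, 5, 20), matrix(2L, 5, 20))
  pan <- make_panel(d)
  pc <- geno_pca(pan)
  expect_equal(pc$explained[1], 100)
  expect_true(all(pc$scores$PC1[1:5] * pc$scores$PC1[6:10] < 0))
})

test_that("duplicated locus columns carry identical loadings and the sign
          convention is deterministic", {
  set.seed(4)
  d <- matrix(sample(0:2, 120, replace = TRUE), 12, 10)
  pan <- make_panel(cbind(d, d))
  pc <- geno_pca(pan)
  expect_equal(unname(pc$loadings[1:10, 1]), unname(pc$loadings[11:20, 1]),
               tolerance = 1e-10)
  pc2 <- geno_pca(pan)
  expect_identical(pc$scores, pc2$scores)
  expect_error(geno_pca(make_panel(matrix(1L, 5, 3))), "polymorphic")
})

test_that("UPGMA: two samples halve their distance at the root, forced
          merge order holds, and cophenetic distances are ultrametric", {
  pan <- make_panel(rbind(c(0L, 0L), c(2L, 2L)))
  tr <- distance_upgma(pan)
  d12 <- sqrt(sum((c(0, 0) - c(2, 2))^2))
  expect_equal(max(tr$hclust$height) / 2, d12 / 2)
  expect_equal(unname(tr$phylo$edge.length), rep(d12 / 2, 2))

  # closest pair (distance 2 vs 3.46 and 4) must merge first
  pan3 <- make_panel(rbind(c(0L, 0L, 0L, 0L), c(2L, 0L, 0L, 0L),
                           c(0L, 2L, 2L, 2L)))
  hc <- distance_upgma(pan3)$hclust
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  set.seed(6)
  d <- matrix(sample(0:2, 25 * 30, replace = TRUE), 25, 30)
  tru <- distance_upgma(make_panel(d))
  coph <- as.matrix(stats::cophenetic(tru$hclust))
  n <- nrow(coph)
  for (rep in 1:200) {
    ijk <- sample(n, 3)
    trio <- c(coph[ijk[1], ijk[2]], coph[ijk[1], ijk[3]],
              coph[ijk[2], ijk[3]])
    expect_lte(max(trio), sort(trio, decreasing = TRUE)[2] + 1e-9)
  }
  expect_true(grepl("^\\(", tru$newick))
})

test_that("LD r-squared: duplicates give 1, complements give 1, and the
          null expectation is approximately 1/n", {
  set.seed(8)
  x <- rbinom(40, 2, 0.4)
  pan <- make_panel(cbind(x, x, 2L - x), pos = c(10L, 20L, 30L))
  storage.mode(pan$dosage) <- "integer"
  ld <- ld_scan(pan)
  expect_equal(ld$r2[ld$locus_a == "1_10" & ld$locus_b == "1_20"], 1)
  expect_equal(ld$r2[ld$locus_a == "1_10" & ld$locus_b == "1_30"], 1)
  expect_equal(ld$distance, c(10, 20, 10))

  n <- 200
  set.seed(12)
  r2 <- replicate(500, {
    a <- rbinom(n, 2, 0.3)
    b <- rbinom(n, 2, 0.3)
    cor(a, b)^2
  })
  mc_se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 1 / n), 3 * mc_se)
})

test_that("LD decay binning aggregates correctly and ranks constructed
          block structure", {
  pairs <- tibble::tibble(locus_a = "a", locus_b = "b",
                          distance = c(100, 300, 900), r2 = c(1, 0.5, 0.1))
  one <- ld_decay(pairs, bin_width = 1000)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_r2, mean(pairs$r2))
  expect_equal(one$n_pairs, 3)
  expect_error(ld_decay(pairs, bin_width = 0), "positive")

  # two tight blocks of duplicated loci far apart: within-block bins beat
  # cross-block bins
  set.seed(10)
  a <- rbinom(60, 2, 0.5)
  b <- rbinom(60, 2, 0.5)
  d <- cbind(a, a, a, b, b, b)
  pan <- make_panel(d, pos = c(100L, 200L, 300L, 50100L, 50200L, 50300L))
  storage.mode(pan$dosage) <- "integer"
  curve <- ld_decay(ld_scan(pan), bin_width = 1000)
  within <- curve$mean_r2[curve$midpoint < 1000]
  across <- curve$mean_r2[curve$midpoint > 40000]
  expect_equal(within, 1)
  expect_lt(max(across), min(within))
})

test_that("Evanno delta-K reproduces hand arithmetic and its edge cases", {
  mk <- function(means, sds, reps = 4) {
    do.call(rbind, lapply(seq_along(means), function(i) {
      data.frame(K = i, rep = seq_len(reps),
                 loglik = means[i] + sds[i] * scale(seq_len(reps))[, 1])
    }))
  }
  ev <- evanno_delta_k(mk(c(-100, -50, -45, -44), rep(1, 4)))
  expect_equal(ev$delta_K[ev$K == 2], 45, tolerance = 1e-9)
  expect_equal(best_k(ev), 2)

  # linear mean with zero replicate spread: no curvature, no peak
  lin <- mk(c(-90, -60, -30, 0), rep(0, 4))
  ev2 <- evanno_delta_k(lin)
  expect_equal(ev2$L_doubleprime_abs[2:3], c(0, 0))
  expect_true(is.na(best_k(ev2)))

  # permuting replicates within a K changes nothing
  tab <- mk(c(-100, -50, -45, -44), c(1, 2, 1, 3))
  ev3 <- evanno_delta_k(tab)
  tab_p <- tab[order(tab$K, -tab$rep), ]
  tab_p$rep <- ave(tab_p$rep, tab_p$K, FUN = seq_along)
  ev4 <- evanno_delta_k(tab_p)
  expect_equal(ev3$delta_K, ev4$delta_K)

  expect_error(evanno_delta_k(mk(c(-1, -2), c(1, 1))), ">= 3 K")
  bad <- mk(c(-1, -2, -3), c(1, 1, 1))
  bad$K[bad$K == 3] <- 5
  expect_error(evanno_delta_k(bad), "consecutive")
})

test_that("three-population panels are recovered by PCA clustering and
          UPGMA clades for nearly all unadmixed samples", {
  sim <- simulate_panel(sim_config(n_samples = 150, n_loci = 300,
                                   divergence = 0.1, seed = 42))
  pan <- sim$panel
  unadm <- pan$samples$group != "admixed"
  truth <- pan$samples$group[unadm]

  pc <- geno_pca(pan)
  set.seed(1)
  km <- kmeans(as.matrix(pc$scores[unadm, c("PC1", "PC2")]), centers = 3,
               nstart = 25)
  expect_gte(best_label_accuracy(km$cluster, truth), 0.95)

  cl <- cutree(distance_upgma(pan[which(unadm), ])$hclust, k = 3)
  expect_gte(best_label_accuracy(cl, truth), 0.95)
})
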