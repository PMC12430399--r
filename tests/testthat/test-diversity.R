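test_that("allele frequencies come from non-missing genotypes", {
  pan <- make_panel(cbind(c(0L, 1L, 2L), c(0L, 0L, 0L), c(NA, 1L, 1L)))
  expect_equal(allele_freqs(pan, 1), c(ref = 0.5, alt = 0.5))
  expect_equal(allele_freqs(pan, 2)[["alt"]], 0)
  expect_equal(allele_freqs(pan, 3)[["alt"]], 0.5)
  pan_na <- make_panel(matrix(NA_integer_, 3, 1))
  expect_error(allele_freqs(pan_na, 1), "non-missing")

  # counting oracle on a random fixture
  set.seed(7)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 10, 6)
  d[1, 1] <- 1L # guard against an all-missing column
  pan2 <- make_panel(d)
  for (j in 1:6) {
    x <- d[, j]
    x <- x[!is.na(x)]
    tally <- (sum(x == 1) + 2 * sum(x == 2)) / (2 * length(x))
    expect_equal(unname(allele_freqs(pan2, j)["alt"]), tally)
  }
})

test_that("locus indices hit their closed forms at p = 0.5 and collapse for
          monomorphic loci", {
  pan <- make_panel(cbind(c(0L, 1L, 2L, 1L), c(0L, 0L, 0L, 0L)))
  ls <- locus_stats(pan)
  i <- 1 # p = 0.5 with Ho = 0.5
  expect_equal(ls$He[i], 0.5)
  expect_equal(ls$Ne[i], 2)
  expect_equal(ls$H_prime[i], log(2))
  expect_equal(ls$PIC[i], 0.375)
  expect_equal(ls$Nei[i], ls$He[i])
  expect_equal(ls$Na[2], 1L)
  expect_equal(ls$Ne[2], 1)
  expect_equal(ls$He[2], 0)
  expect_equal(ls$Ho[2], 0)
  expect_equal(ls$PIC[2], 0)
  expect_equal(ls$H_prime[2], 0)
})

test_that("PIC is maximized at 0.375 for p = 0.5 and never exceeds He;
          indices are invariant to allele-label swap", {
  p_grid <- seq(0.01, 0.5, by = 0.01)
  pic <- 1 - (p_grid^2 + (1 - p_grid)^2) - 2 * p_grid^2 * (1 - p_grid)^2
  expect_equal(max(pic), 0.375)
  expect_equal(p_grid[which.max(pic)], 0.5)

  set.seed(3)
  d <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  pan <- make_panel(d)
  ls <- locus_stats(pan)
  expect_true(all(ls$PIC <= ls$He + 1e-12))
  expect_true(all(ls$Ne <= ls$Na + 1e-12))
  expect_true(all(ls$Ho >= 0 & ls$Ho <= 1))
  swapped <- make_panel(2L - d)
  ls2 <- locus_stats(swapped)
  for (col in c("Na", "Ne", "Ho", "He", "PIC", "H_prime", "Nei")) {
    expect_equal(ls2[[col]], ls[[col]], info = col)
  }
})

test_that("group diversity equals whole-panel means for a single group and
          ranks diverged groups correctly", {
  sim <- simulate_panel(sim_config(n_samples = 30, n_loci = 40,
                                   missing_rate = 0, seed = 16))
  pan <- sim$panel
  pan$samples$group <- "all"
  gd <- group_diversity(pan)
  ls <- locus_stats(pan)
  expect_equal(gd$He, mean(ls$He))
  expect_equal(gd$PIC, mean(ls$PIC))

  # high- vs low-diversity groups with known frequency spread
  set.seed(5)
  d_hi <- matrix(rbinom(20 * 50, 2, 0.5), 20, 50)
  d_lo <- matrix(rbinom(20 * 50, 2, 0.03), 20, 50)
  pan2 <- make_panel(rbind(d_hi, d_lo),
                     groups = rep(c("hi", "lo"), each = 20))
  gd2 <- group_diversity(pan2)
  gd2 <- gd2[match(c("hi", "lo"), gd2$group), ]
  expect_gt(gd2$He[1], gd2$He[2])
  expect_gt(gd2$PIC[1], gd2$PIC[2])
  expect_gt(gd2$H_prime[1], gd2$H_prime[2])

  pan3 <- pan2
  pan3$samples$group <- c("solo", rep("rest", 39))
  expect_warning(group_diversity(pan3), "fewer than 2")
})

test_that("observed-vs-expected heterozygosity deficit recovers a planted
          inbreeding coefficient", {
  F_true <- 0.2
  set.seed(11)
  f_hat <- replicate(20, {
    p <- runif(150, 0.2, 0.5)
    pan <- make_panel(sim_inbred_dosage(120, p, F_true))
    ls <- locus_stats(pan)
    1 - mean(ls$Ho) / mean(ls$He)
  })
  se <- sd(f_hat) / sqrt(length(f_hat))
  expect_lt(abs(mean(f_hat) - F_true), 2 * se + 0.02)
})

test_that("trait summaries: zero-variance, two-point and equal-class cases", {
  tr <- data.frame(accession_id = sprintf("S%03d", 1:297),
                   leaf = rep(3, 297))
  out <- trait_summary(tr)
  expect_equal(out$sd, 0)
  expect_equal(out$cv, 0)
  expect_equal(out$H_prime, 0)
  expect_equal(out$maximum, 3)
  expect_equal(out$minimum, 3)

  tr2 <- data.frame(accession_id = paste0("S", 1:10),
                    x = rep(c(1, 3), 5))
  out2 <- trait_summary(tr2)
  expect_equal(out2$mean, 2)
  expect_equal(out2$sd, 1) # population SD
  expect_equal(out2$cv, 50)

  for (k in 2:6) {
    trk <- data.frame(accession_id = paste0("S", 1:(k * 6)),
                      x = rep(seq_len(k), 6))
    expect_equal(trait_summary(trk)$H_prime, log(k))
  }
})

test_that("trait correlations match the textbook formula and flag constant
          traits", {
  set.seed(9)
  tr <- data.frame(accession_id = paste0("S", 1:15),
                   a = rnorm(15), b = rnorm(15))
  tr$c <- -tr$a
  r <- trait_correlations(tr)
  expect_equal(diag(r), setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(r["a", "c"], -1)
  long_hand <- sum((tr$a - mean(tr$a)) * (tr$b - mean(tr$b))) /
    sqrt(sum((tr$a - mean(tr$a))^2) * sum((tr$b - mean(tr$b))^2))
  expect_equal(r["a", "b"], long_hand, tolerance = 1e-12)

  tr$d <- 5
  expect_warning(r2 <- trait_correlations(tr), "constant")
  expect_true(is.na(r2["a", "d"]))
})

test_that("trait PCA handles rank-1, symmetric and reconstruction cases", {
  tr <- data.frame(accession_id = paste0("S", 1:20),
                   a = 1:20, b = 2 * (1:20) + 5)
  pc <- pheno_pca(tr)
  expect_equal(pc$explained[1], 100)

  set.seed(2)
  tr2 <- data.frame(accession_id = paste0("S", 1:50),
                    a = rnorm(50), b = rnorm(50), c = rnorm(50))
  pc2 <- pheno_pca(tr2)
  z <- scale(as.matrix(tr2[, -1]))
  recon <- as.matrix(pc2$scores[, -1]) %*% t(pc2$loadings)
  expect_equal(unname(recon), unname(z[, rownames(pc2$loadings)]),
               tolerance = 1e-8)
  expect_true(all(diff(pc2$explained) <= 1e-8))
  expect_lte(sum(pc2$explained), 100 + 1e-8)

  tr3 <- data.frame(accession_id = paste0("S", 1:5), a = 1, b = 2)
  expect_error(suppressMessages(pheno_pca(tr3)), "non-constant")
})

test_that("membership-function D-values hit their boundary and midpoint
          values", {
  tr <- data.frame(accession_id = c("best", "worst", "mid"),
                   a = c(10, 0, 5), b = c(4, 2, 3))
  d <- membership_D(tr)
  expect_equal(d$D, c(1, 0, 0.5))
  d2 <- membership_D(tr, direction = c(a = "smaller", b = "smaller"))
  expect_equal(d2$D, c(0, 1, 0.5))
  tr$c <- 7
  expect_error(membership_D(tr), "constant")
})
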