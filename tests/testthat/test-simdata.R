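test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(divergence = 1), "divergence")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("missing_rate zero gives a complete matrix and a fixed seed is
          bit-reproducible", {
  cfg <- sim_config(n_samples = 30, n_loci = 50, missing_rate = 0, seed = 11)
  a <- simulate_panel(cfg)
  expect_false(anyNA(a$panel$dosage))
  b <- simulate_panel(cfg)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_panel(sim_config(n_samples = 30, n_loci = 50,
                                  missing_rate = 0, seed = 12))
  expect_false(identical(a$panel$dosage, c2$panel$dosage))
})

test_that("with no drift and one population, realized frequencies track the
          ancestral frequencies at binomial precision", {
  cfg <- sim_config(n_samples = 500, n_loci = 200, n_pops = 1,
                    divergence = 0, admixed_fraction = 0, missing_rate = 0,
                    seed = 3)
  sim <- simulate_panel(cfg)
  p_hat <- colMeans(sim$panel$dosage) / 2
  p0 <- sim$truth$ancestral_freqs
  se <- sqrt(p0 * (1 - p0) / (2 * cfg$n_samples))
  expect_true(mean(abs(p_hat - p0) <= 3 * se) > 0.95)
})

test_that("allele-frequency recovery error shrinks with sample size", {
  err <- vapply(c(50, 5000), function(n) {
    sim <- simulate_panel(sim_config(n_samples = n, n_loci = 100, n_pops = 1,
                                     divergence = 0, admixed_fraction = 0,
                                     missing_rate = 0, seed = 5))
    mean(abs(colMeans(sim$panel$dosage) / 2 - sim$truth$ancestral_freqs))
  }, numeric(1))
  expect_lt(err[2], err[1] / 3)
})

test_that("ancestry proportions are simplex vectors and admixture raises
          mean heterozygosity", {
  sim <- simulate_panel(sim_config(n_samples = 40, n_loci = 40, seed = 8))
  expect_equal(rowSums(sim$truth$ancestry), rep(1, 40))
  expect_true(all(sim$truth$ancestry >= 0))

  het_at <- function(adm, seed) {
    sim <- simulate_panel(sim_config(n_samples = 60, n_loci = 80,
                                     divergence = 0.25,
                                     admixed_fraction = adm,
                                     missing_rate = 0, seed = seed))
    mean(sim$panel$dosage == 1L)
  }
  reps <- 1:20
  h0 <- vapply(reps, function(s) het_at(0, s), numeric(1))
  h1 <- vapply(reps, function(s) het_at(0.5, s), numeric(1))
  h2 <- vapply(reps, function(s) het_at(1, s), numeric(1))
  expect_lt(mean(h0), mean(h1))
  expect_lt(mean(h1), mean(h2))
})

test_that("planted annotation failures are exactly the hard-filter rejects", {
  sim <- simulate_panel(sim_config(n_samples = 20, n_loci = 100, seed = 2))
  ann0 <- simulate_annotations(sim$panel, fail_fraction = 0, seed = 1)
  expect_true(all(hard_filter_sites(ann0)$pass))

  ann <- simulate_annotations(sim$panel, fail_fraction = 0.1, seed = 1)
  expect_length(ann$planted_fail, 10)
  hf <- hard_filter_sites(ann)
  expect_identical(which(!hf$pass), ann$planted_fail)
  expect_error(simulate_annotations(sim$panel, fail_fraction = 1), "fail_")
})

test_that("phenotype heritability limits behave as specified", {
  sim <- simulate_panel(sim_config(n_samples = 80, n_loci = 60,
                                   missing_rate = 0, seed = 13))
  ph1 <- simulate_phenotypes(sim$panel, sim$truth, heritability = 1,
                             n_categorical = 0, seed = 1)
  g <- as.numeric(sim$panel$dosage[, sim$truth$causal_loci] %*%
                    sim$truth$causal_effects)
  expect_equal(ph1$growth, g)

  # heritability 0: association scan is null-calibrated
  sim0 <- simulate_panel(sim_config(n_samples = 120, n_loci = 1000,
                                    missing_rate = 0, seed = 21))
  ph0 <- simulate_phenotypes(sim0$panel, sim0$truth, heritability = 0,
                             n_categorical = 0, seed = 2)
  res <- glm_scan(sim0$panel, ph0, trait_name = "growth")
  ks <- suppressWarnings(stats::ks.test(res$p[!is.na(res$p)], "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(simulate_phenotypes(sim$panel, sim$truth, heritability = 1.2),
               "heritability")
})

test_that("a single-class categorical trait has zero Shannon diversity", {
  sim <- simulate_panel(sim_config(n_samples = 30, n_loci = 10, seed = 4))
  ph <- simulate_phenotypes(sim$panel, sim$truth, n_categorical = 2,
                            class_freqs = 1, seed = 3)
  out <- trait_summary(ph, trait = "cat01")
  expect_equal(out$H_prime, 0)
  expect_equal(out$sd, 0)
})
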