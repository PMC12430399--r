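test_that("hard filter uses strict printed inequalities and lists reasons", {
  site <- tibble::tibble(
    id = c("s1", "s2", "s3", "s4"),
    QD = c(2.0, 1.9, 25, 25),
    MQ = c(55, 55, 55, 55),
    FS = c(10, 10, 61, 10),
    SOR = c(1, 1, 1, 1),
    MQRankSum = c(0, 0, 0, NA),
    ReadPosRankSum = c(0, 0, -8.5, 0)
  )
  hf <- hard_filter_sites(site)
  expect_identical(hf$pass, c(TRUE, FALSE, FALSE, TRUE)) # QD=2.0 passes
  expect_identical(hf$reasons[2], "QD")
  expect_identical(hf$reasons[3], "FS,ReadPosRankSum")
})

test_that("HWE exact test matches enumeration: spot cases and the full
          sweep of configurations up to n = 30", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 10, 0), hwe_oracle(0, 10, 0))
  expect_error(hwe_exact_test(0, 0, 0), "genotype")

  for (n in c(5, 12, 19, 25, 30)) {
    cfg <- expand.grid(a = 0:n, b = 0:n)
    cfg <- cfg[cfg$a + cfg$b <= n, ]
    cfg$c <- n - cfg$a - cfg$b
    got <- hwe_exact_test(cfg$a, cfg$b, cfg$c)
    want <- mapply(hwe_oracle, cfg$a, cfg$b, cfg$c)
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
})

test_that("clean balanced panels pass the cascade untouched and the MAF
          boundary is strict", {
  d <- rbind(matrix(0L, 5, 4), matrix(1L, 10, 4), matrix(2L, 5, 4))
  pan <- make_panel(d)
  out <- site_filters(pan)
  expect_equal(out$report$n_output, 4)
  expect_equal(out$report$n_input, 4)
  expect_identical(out$panel$dosage, pan$dosage)

  # one column with MAF exactly 0.05: 2 alt alleles among 20 (10 samples)
  d2 <- cbind(c(rep(1L, 2), rep(0L, 18)), c(rep(1L, 10), rep(0L, 10)))
  pan2 <- make_panel(d2)
  out2 <- site_filters(pan2)
  expect_equal(out2$report$n_output, 1)
  expect_identical(out2$report$fail_reasons$reasons, "maf")
})

test_that("the cascade removes planted violations at the right stages and
          reports consistent bookkeeping", {
  sim <- simulate_panel(sim_config(n_samples = 50, n_loci = 120,
                                   maf_range = c(0.2, 0.5),
                                   missing_rate = 0, seed = 9))
  ann <- simulate_annotations(sim$panel, fail_fraction = 0.1, seed = 4)
  out <- site_filters(sim$panel, ann)
  st <- out$report$stages
  expect_equal(st$n_removed[st$stage == "hard_filter"], 12)
  expect_equal(out$report$n_input - nrow(out$report$fail_reasons),
               out$report$n_output)

  # every retained site re-audits clean against every criterion
  keep_ids <- out$panel$loci$id
  ann_kept <- ann
  kept_idx <- match(keep_ids, sim$panel$loci$id)
  ann_kept$site <- ann$site[kept_idx, ]
  ann_kept$gq <- ann$gq[, kept_idx, drop = FALSE]
  ann_kept$dp <- ann$dp[, kept_idx, drop = FALSE]
  expect_true(all(hard_filter_sites(ann_kept)$pass))
  d <- out$panel$dosage
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  expect_true(all(pmin(p, 1 - p) > 0.05))
  expect_true(all(colMeans(is.na(d)) <= 0.01))
  nh <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  expect_true(all(hwe_exact_test(n_called - nh - n2, nh, n2) >= 1e-4))
})

test_that("retained set is invariant to sample and locus order, and
          relaxing a threshold never shrinks it", {
  sim <- simulate_panel(sim_config(n_samples = 40, n_loci = 80, seed = 14))
  ann <- simulate_annotations(sim$panel, fail_fraction = 0.05, seed = 5)
  base <- site_filters(sim$panel, ann)

  set.seed(1)
  perm_s <- sample(seq_len(40))
  perm_l <- sample(seq_len(80))
  pan_p <- sim$panel[perm_s, perm_l]
  ann_p <- ann
  ann_p$site <- ann$site[perm_l, ]
  ann_p$gq <- ann$gq[perm_s, perm_l]
  ann_p$dp <- ann$dp[perm_s, perm_l]
  perm <- site_filters(pan_p, ann_p)
  expect_setequal(perm$panel$loci$id, base$panel$loci$id)

  relaxed <- site_filters(sim$panel, ann,
                          filter_thresholds(min_maf = 0.01,
                                            max_missing_post = 0.10))
  expect_true(all(base$panel$loci$id %in% relaxed$panel$loci$id))
})

test_that("threshold validation rejects nonsense configurations", {
  expect_error(filter_thresholds(min_maf = 0.6), "min_maf")
  expect_error(filter_thresholds(max_missing = 1.5), "missing")
  expect_error(filter_thresholds(depth_range = c(10, 3)), "depth_range")
  expect_error(site_filters(make_panel(matrix(0L, 2, 1)), NULL,
                            thresholds = list()), "filter_thresholds")
})
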