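test_that("fingerprint codes use genotype tokens in genomic order", {
  pan <- make_panel(matrix(1L, 1, 1))
  expect_equal(fingerprint_codes(pan, 1)$code, "0/1")

  # selected out of order across chromosomes: emitted chr1 first
  d <- matrix(c(0L, 2L), 1, 2)
  loci <- data.frame(chrom = c("chr2", "chr1"), pos = c(10L, 5L),
                     ref = "A", alt = "G")
  pan2 <- geno_panel(d, loci)
  expect_equal(fingerprint_codes(pan2, c("2_10", "1_5"))$code, "1/1|0/0")
})

test_that("identical samples share codes and missing calls render ./.", {
  d <- rbind(c(0L, 1L), c(0L, 1L), c(NA, 2L))
  pan <- make_panel(d)
  fc <- fingerprint_codes(pan, 1:2)
  expect_equal(fc$code[1], fc$code[2])
  expect_equal(fc$code[3], "./.|1/1")
  expect_error(fingerprint_codes(pan, "nope"), "unknown locus")
})

test_that("greedy selection needs a second locus when one leaves a pair
          confounded, as brute force confirms", {
  # locus A: (0,1,2,0) leaves pair (1,4) confounded; locus B is constant;
  # locus C splits samples 1 and 4
  d <- cbind(A = c(0L, 1L, 2L, 0L),
             B = c(1L, 1L, 1L, 1L),
             C = c(0L, 0L, 0L, 2L))
  pan <- make_panel(d)
  sel <- greedy_core_select(pan)
  expect_equal(sel$size, 2)
  expect_setequal(sel$markers$id, c("1_100", "1_300"))
  expect_equal(sel$resolution_rate, 1)
  expect_length(sel$unresolved_groups, 0)
  oracle <- brute_force_min_set(pan)
  expect_equal(oracle$size, 2)

  # one locus with all-distinct genotypes resolves three samples alone
  pan1 <- make_panel(cbind(c(0L, 1L, 2L), c(0L, 0L, 2L)))
  expect_equal(greedy_core_select(pan1)$size, 1)
})

test_that("byte-identical duplicate samples end in an explicit unresolved
          group", {
  d <- rbind(c(0L, 1L), c(0L, 1L), c(2L, 0L))
  pan <- make_panel(d)
  sel <- greedy_core_select(pan)
  expect_equal(length(sel$unresolved_groups), 1)
  expect_setequal(sel$unresolved_groups[[1]], c("S01", "S02"))
  expect_equal(sel$resolution_rate, 2 / 3)
})

test_that("selection is deterministic and immune to monomorphic padding", {
  sim <- simulate_panel(sim_config(n_samples = 25, n_loci = 40,
                                   missing_rate = 0, seed = 19))
  s1 <- greedy_core_select(sim$panel)
  s2 <- greedy_core_select(sim$panel)
  expect_identical(s1$markers, s2$markers)

  mono <- matrix(0L, 25, 5)
  pan_pad <- geno_panel(
    cbind(sim$panel$dosage, mono),
    rbind(sim$panel$loci,
          tibble::tibble(chrom = "chr9", pos = seq_len(5) * 10L,
                         ref = "A", alt = "G",
                         id = paste0("9_", seq_len(5) * 10L))),
    sim$panel$samples)
  s3 <- greedy_core_select(pan_pad)
  expect_identical(s3$markers$id, s1$markers$id)
})

test_that("greedy matches the exhaustive oracle across random small
          instances and is irredundant", {
  set.seed(77)
  n_inst <- 100
  for (i in seq_len(n_inst)) {
    n <- sample(4:10, 1)
    m <- sample(4:12, 1)
    d <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                       prob = c(0.35, 0.3, 0.3, 0.05)), n, m)
    pan <- make_panel(d)
    sel <- greedy_core_select(pan)
    oracle <- brute_force_min_set(pan)
    if (!is.na(oracle$size)) {
      # oracle found a fully-resolving subset: greedy must too, and never
      # with fewer loci than the optimum
      expect_length(sel$unresolved_groups, 0)
      expect_gte(sel$size, oracle$size)
    } else {
      expect_gt(length(sel$unresolved_groups), 0)
    }
    # irredundancy: removing any selected locus strictly loses pairs
    if (sel$size > 1) {
      full_idx <- match(sel$markers$id, pan$loci$id)
      n_full <- count_resolved_pairs_loop(pan$dosage, full_idx)
      for (k in seq_len(sel$size)) {
        n_red <- count_resolved_pairs_loop(pan$dosage, full_idx[-k])
        expect_lt(n_red, n_full)
      }
    }
  }
})

test_that("the exhaustive oracle enforces its feasibility guard", {
  pan <- make_panel(matrix(0L, 13, 2))
  expect_error(brute_force_min_set(pan), "guard")
})

test_that("discrimination report counts pairs like a double loop", {
  codes <- tibble::tibble(accession_id = paste0("S", 1:5),
                          code = c("a", "a", "b", "c", "a"))
  rep_ <- discrimination_report(codes)
  n <- 5
  resolved <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    resolved <- resolved + (codes$code[i] != codes$code[j])
  }
  expect_equal(rep_$resolution_rate, resolved / choose(n, 2))
  expect_length(rep_$duplicate_groups, 1)
  expect_setequal(rep_$duplicate_groups[[1]], c("S1", "S2", "S5"))

  all_same <- tibble::tibble(accession_id = paste0("S", 1:3), code = "x")
  expect_equal(discrimination_report(all_same)$resolution_rate, 0)
  all_diff <- tibble::tibble(accession_id = paste0("S", 1:3),
                             code = c("x", "y", "z"))
  expect_equal(discrimination_report(all_diff)$resolution_rate, 1)
})
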