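test_that("reads-per-million normalization scales each sample to 1e6", {
  m <- matrix(c(10L, 90L), 2, 3)
  cnt <- make_counts(m, 1)
  norm <- normalize_total(cnt)
  expect_equal(unname(norm$rpm[, 1]), c(1e5, 9e5))

  single <- make_counts(matrix(7L, 1, 3), 1)
  expect_equal(unname(normalize_total(single)$rpm[1, 1]), 1e6)

  set.seed(42)
  big <- make_counts(matrix(rpois(100 * 12, 50), 100, 12), 4)
  expect_equal(unname(colSums(normalize_total(big)$rpm)), rep(1e6, 12))

  zero <- make_counts(matrix(c(0L, 5L, 5L), 1, 3), 1)
  expect_error(normalize_total(zero), "input_r1")
})

test_that("low-count exclusion is strict at the threshold", {
  m <- matrix(c(19L, 20L, 21L, 100L, 100L, 100L), nrow = 2, byrow = TRUE)
  cnt <- make_counts(m, 1)
  mask <- low_count_mask(cnt, analysis_config())
  expect_equal(unname(mask[1, ]), c(FALSE, TRUE, TRUE))  # 19 out, 20 in
  expect_true(all(mask[2, ]))

  any_cfg <- analysis_config(filter_scope = "any_sample")
  mask2 <- low_count_mask(cnt, any_cfg)
  expect_false(any(mask2[1, ]))  # one low sample invalidates everywhere
  expect_true(all(mask2[2, ]))
})

test_that("replicate ratios follow normalized abundance within replicate", {
  # two sgRNAs; second acts as ballast so totals differ between samples
  m <- matrix(c(100L, 100L, 200L,
                900L, 900L, 800L), nrow = 2, byrow = TRUE)
  cnt <- make_counts(m, 1)
  cfg <- analysis_config()
  norm <- normalize_total(cnt)
  rr <- replicate_ratios(norm, low_count_mask(cnt, cfg), "yap_vs_empty", cfg)
  expect_equal(unname(rr$ratios[1, 1]), (200 / 1000) / (100 / 1000))
  expect_equal(unname(rr$ratios[2, 1]), (800 / 1000) / (900 / 1000))

  # YAP == Empty gives exactly 1
  m2 <- matrix(c(100L, 300L, 300L, 900L, 700L, 700L), nrow = 2, byrow = TRUE)
  cnt2 <- make_counts(m2, 1)
  rr2 <- replicate_ratios(normalize_total(cnt2),
                          low_count_mask(cnt2, cfg), "yap_vs_empty", cfg)
  expect_equal(unname(rr2$ratios[, 1]), c(1, 1))

  # low count in the reference invalidates only that replicate's ratio
  m3 <- matrix(c(100L, 5L, 100L, 100L, 100L, 100L,
                 900L, 995L, 900L, 900L, 900L, 900L),
               nrow = 2, byrow = TRUE)
  cnt3 <- make_counts(m3, 2)
  rr3 <- replicate_ratios(normalize_total(cnt3),
                          low_count_mask(cnt3, cfg), "yap_vs_empty", cfg)
  expect_false(rr3$valid[1, 1])
  expect_true(rr3$valid[1, 2])
  expect_true(is.na(rr3$ratios[1, 1]))
})

test_that("median over valid replicates uses midpoint and min-replicate rule", {
  rr <- list(ratios = matrix(c(2, 1, 4, 3), 1), valid = matrix(TRUE, 1, 4))
  expect_equal(median_ratio(rr, analysis_config())$median, 2.5,
               ignore_attr = TRUE)

  rr2 <- list(ratios = matrix(c(2, NA, 4, 3), 1),
              valid = matrix(c(TRUE, FALSE, TRUE, TRUE), 1))
  expect_equal(median_ratio(rr2, analysis_config())$median, 3,
               ignore_attr = TRUE)

  rr3 <- list(ratios = matrix(c(NA, NA, NA, 2), 1),
              valid = matrix(c(FALSE, FALSE, FALSE, TRUE), 1))
  res <- median_ratio(rr3, analysis_config(min_valid_replicates = 2))
  expect_true(is.na(res$median))
  expect_equal(res$n_valid, 1, ignore_attr = TRUE)
})

test_that("z-scores standardize log2 medians against the reference set", {
  lib <- toy_library(4, n_ntc = 2)
  med <- c(1, 1, 0.5, 2)  # NTC log2: -1, +1 -> mean 0, sd sqrt(2)
  names(med) <- lib$sgrna_id
  z <- zscores(med, lib, analysis_config())
  expect_equal(unname(z[4]), 1 / stats::sd(c(-1, 1)))
  expect_equal(unname(z[1]), 0)  # log2(1) equals the reference mean

  med_flat <- c(1, 2, 1, 1)
  names(med_flat) <- lib$sgrna_id
  expect_error(zscores(med_flat, lib, analysis_config()), "zero variance")

  # fallback reference over all sgRNAs
  z_all <- zscores(med, lib, analysis_config(zscore_reference = "all"))
  lg <- log2(med)
  expect_equal(unname(z_all), unname((lg - mean(lg)) / stats::sd(lg)))
})

test_that("ratios are invariant to per-sample scaling of raw counts", {
  set.seed(7)
  m <- matrix(rpois(40 * 12, 80) + 20L, 40, 12)
  cnt <- make_counts(m, 4)
  m2 <- m
  m2[, 3] <- m2[, 3] * 5L  # scale one yap sample
  cnt2 <- make_counts(m2, 4)
  cfg <- analysis_config()
  rr1 <- replicate_ratios(normalize_total(cnt), low_count_mask(cnt, cfg),
                          "yap_vs_empty", cfg)
  rr2 <- replicate_ratios(normalize_total(cnt2), low_count_mask(cnt2, cfg),
                          "yap_vs_empty", cfg)
  expect_equal(rr1$ratios, rr2$ratios, tolerance = 1e-12)
})

test_that("raising the count threshold never adds valid ratios", {
  set.seed(8)
  m <- matrix(rpois(30 * 12, 25), 30, 12)
  cnt <- make_counts(m, 4)
  n_valid <- vapply(c(5, 20, 40, 80), function(th) {
    cfg <- analysis_config(low_count_threshold = th)
    rr <- replicate_ratios(normalize_total(cnt), low_count_mask(cnt, cfg),
                           "yap_vs_empty", cfg)
    sum(rr$valid)
  }, numeric(1))
  expect_true(all(diff(n_valid) <= 0))
})

test_that("vectorized scoring equals loop-based brute force on random data", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 50
    lib <- toy_library(n, n_ntc = 10)
    m <- matrix(rpois(n * 12, 60), n, 12)
    m[sample(length(m), 40)] <- rpois(40, 10)  # force low-count exclusions
    cnt <- make_counts(m, 4, sgrna_ids = lib$sgrna_id)
    cfg <- analysis_config()
    got <- screen_ratios(cnt, lib, cfg)
    want <- oracle_scores(cnt, lib, cfg)
    expect_equal(got$median_yap_vs_empty, want$median_empty,
                 tolerance = 1e-12)
    expect_equal(got$median_yap_vs_input, want$median_input,
                 tolerance = 1e-12)
    expect_equal(got$zscore, want$z, tolerance = 1e-12)
  }
})

test_that("per-sgRNA results table round-trips through disk", {
  cfg <- tiny_sim(seed = 41, n_genes = 8, n_ntc = 4, mean_depth = 60)
  sim <- simulate_library(cfg)
  cnt <- simulate_counts(sim$library, sim$truth, cfg)
  rt <- screen_ratios(cnt, sim$library)
  d <- tmpdir(); on.exit(unlink(d, recursive = TRUE))
  p <- file.path(d, "rt.tsv")
  write_ratio_table(rt, p)
  back <- read_ratio_table(p)
  expect_equal(back$median_yap_vs_empty, rt$median_yap_vs_empty,
               tolerance = 1e-10)
  expect_equal(back$zscore, rt$zscore, tolerance = 1e-10)
})
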