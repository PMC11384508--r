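test_that("simulated library has the configured composition", {
  cfg <- sim_config(n_genes = 950, sgrnas_per_gene = 4, n_ntc = 50, seed = 3)
  sim <- simulate_library(cfg)
  expect_equal(nrow(sim$library), 3850)
  expect_equal(sum(sim$library$gene == "NTC"), 50)
  expect_equal(length(unique(sim$library$gene[sim$library$gene != "NTC"])),
               950)
  # ground truth covers every sgRNA exactly once; NTCs are null and inactive
  expect_identical(sim$truth$sgrnas$sgrna_id, sim$library$sgrna_id)
  expect_false(any(sim$truth$sgrnas$active[sim$library$gene == "NTC"]))
  expect_false("NTC" %in% sim$truth$genes$gene)
})

test_that("degenerate one-sgRNA library is a null gene", {
  cfg <- sim_config(n_genes = 1, sgrnas_per_gene = 1, n_ntc = 0,
                    effector_fraction = 0, inhibitor_fraction = 0, seed = 5)
  sim <- simulate_library(cfg)
  expect_equal(nrow(sim$library), 1)
  expect_equal(sim$truth$genes$class, "null")
  expect_equal(sim$truth$genes$effect_fold, 1)
})

test_that("same config and seed give byte-identical library and counts", {
  cfg <- tiny_sim(seed = 11)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a, b)
  ca <- simulate_counts(a$library, a$truth, cfg)
  cb <- simulate_counts(b$library, b$truth, cfg)
  expect_identical(ca$counts, cb$counts)
  expect_true(all(ca$counts >= 0))
  expect_true(is.integer(ca$counts))
})

test_that("spacers are unique and no two are 1-mismatch neighbors", {
  cfg <- tiny_sim(seed = 2)
  sp <- simulate_library(cfg)$library$spacer
  expect_false(anyDuplicated(sp) > 0)
  expect_true(all(nchar(sp) == 20))
  pairs <- utils::combn(seq_len(min(40, length(sp))), 2)
  dmin <- min(apply(pairs, 2, function(ij) hamming(sp[ij[1]], sp[ij[2]])))
  expect_gte(dmin, 2)
})

test_that("gene classes are drawn binomially at the configured fraction", {
  # 1 sgRNA/gene keeps spacer generation cheap; class draws are per gene
  n_seeds <- 150
  n_genes <- 400
  frac <- 0.02
  counts <- vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(n_genes = n_genes, sgrnas_per_gene = 1, n_ntc = 0,
                      effector_fraction = frac, inhibitor_fraction = 0,
                      seed = 1000 + s)
    sum(simulate_library(cfg)$truth$genes$class == "effector")
  }, numeric(1))
  # binomial oracle: total effectors ~ Binomial(n_seeds * n_genes, frac)
  n_tot <- n_seeds * n_genes
  expect_lt(abs(sum(counts) - n_tot * frac),
            5 * sqrt(n_tot * frac * (1 - frac)))
  expect_gt(stats::var(counts), 0)
})

test_that("null screen is symmetric and depth scales counts linearly", {
  cfg0 <- tiny_sim(seed = 21, effector_fraction = 0, inhibitor_fraction = 0)
  sim <- simulate_library(cfg0)
  cnt <- simulate_counts(sim$library, sim$truth, cfg0)
  norm <- normalize_total(cnt)
  rr <- replicate_ratios(norm, low_count_mask(cnt, analysis_config(
    low_count_threshold = 1)), "yap_vs_empty", analysis_config())
  # enrichment and depletion are symmetric under no effect: the median ratio
  # sits at 1 (the arithmetic mean of noisy ratios is Jensen-biased upward)
  expect_lt(abs(stats::median(rr$ratios, na.rm = TRUE) - 1), 0.05)
  expect_lt(abs(mean(log(rr$ratios), na.rm = TRUE)), 0.05)

  cfg2 <- tiny_sim(seed = 21, effector_fraction = 0, inhibitor_fraction = 0,
                   mean_depth = 200)
  cnt2 <- simulate_counts(sim$library, sim$truth, cfg2)
  ratio <- sum(cnt2$counts) / sum(cnt$counts)
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("an active effector sgRNA enriches by effect_fold on average", {
  # Monte-Carlo comparison against an independent draw from the same
  # generative law, coded directly here.
  n_seeds <- 300
  cfg <- sim_config(n_genes = 100, sgrnas_per_gene = 4, n_ntc = 0,
                    n_replicates = 1, effector_fraction = 0,
                    inhibitor_fraction = 0, effect_fold = 3,
                    drift_sd = 0.05, mean_depth = 200, seed = 1)
  base <- simulate_library(cfg)
  base <- spike_gene(base, "gene0002", "EFF", "effector", effect_fold = 3,
                     active = TRUE)
  eff_idx <- which(base$library$gene == "EFF")

  sim_ratios <- vapply(seq_len(n_seeds), function(s) {
    cfg_s <- sim_config(n_genes = 100, sgrnas_per_gene = 4, n_ntc = 0,
                        n_replicates = 1, effector_fraction = 0,
                        inhibitor_fraction = 0, effect_fold = 3,
                        drift_sd = 0.05, mean_depth = 200, seed = 5000 + s)
    cnt <- simulate_counts(base$library, base$truth, cfg_s)
    rpm <- sweep(cnt$counts, 2, colSums(cnt$counts), "/")
    stats::median(rpm[eff_idx, "yap_r1"] / rpm[eff_idx, "empty_r1"])
  }, numeric(1))

  # independent oracle: same law, plain rlnorm/rpois draws
  set.seed(99)
  n_sg <- 400
  oracle <- replicate(n_seeds, {
    baseline <- rlnorm(n_sg, 0, cfg$abundance_sdlog)
    fold <- c(rep(1, 4), rep(3, 4), rep(1, n_sg - 8))
    a_e <- baseline * exp(rnorm(n_sg, 0, 0.05))
    a_y <- baseline * exp(rnorm(n_sg, 0, 0.05)) * fold
    draw <- function(a) {
      mu <- 200 * n_sg * a / sum(a)
      rpois(n_sg, mu * exp(rnorm(n_sg, 0, cfg$baseline_dispersion) -
                             cfg$baseline_dispersion^2 / 2))
    }
    ce <- draw(a_e); cy <- draw(a_y)
    stats::median((cy[5:8] / sum(cy)) / (ce[5:8] / sum(ce)))
  })
  expect_lt(abs(mean(sim_ratios) - mean(oracle)), 0.15)
  expect_lt(abs(mean(sim_ratios) - 3), 0.3)
})

test_that("fixture round-trips and FASTQ read counts equal matrix entries", {
  lib <- toy_library(3)
  m <- matrix(c(5L, 0L, 2L), nrow = 3, ncol = 3)
  cnt <- make_counts(m, 1, sgrna_ids = lib$sgrna_id)
  out <- tmpdir()
  on.exit(unlink(out, recursive = TRUE))
  paths <- write_fixture(lib, cnt, truth = NULL, out, emit_fastq = TRUE)
  fq <- readLines(paths[["fastq_yap_r1"]])
  expect_equal(length(fq), 4 * 7)  # counts 5 + 0 + 2
  expect_true(all(startsWith(fq[seq(2, length(fq), by = 4)], lib$spacer[1]) |
                    startsWith(fq[seq(2, length(fq), by = 4)], lib$spacer[3])))

  back <- read_counts(paths[["counts"]], paths[["samples"]],
                      library = read_library(paths[["library"]]))
  expect_identical(back$counts, cnt$counts)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(effector_fraction = 0.6, inhibitor_fraction = 0.5),
               "<= 1")
  expect_error(sim_config(effect_fold = 1))
  expect_error(sim_config(n_genes = 0))
})
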