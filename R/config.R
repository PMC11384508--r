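#' Simulation configuration for a synthetic rescue screen
#'
#' Bundles and validates every parameter of the synthetic-screen generator.
#' Defaults reproduce the design of a targeted knockout screen read out in
#' biological quadruplicate: ~950 targeted genes with 4 sgRNAs each plus 50
#' nontargeting controls, sequenced in three conditions (input at day 10,
#' empty vector at day 25, YAP-expressing at day 25).
#'
#' @param n_genes Number of targeted genes.
#' @param sgrnas_per_gene Number of sgRNAs per targeted gene.
#' @param n_ntc Number of nontargeting control sgRNAs.
#' @param n_replicates Number of biological replicates; each replicate has one
#'   sample per condition.
#' @param effector_fraction,inhibitor_fraction Probability that a targeted
#'   gene is, respectively, an effector (knockout rescues growth under the
#'   selective pressure, so its sgRNAs enrich) or an inhibitor (knockout
#'   worsens growth, so its sgRNAs deplete). Must sum to at most 1; remaining
#'   genes are nulls.
#' @param effect_fold Multiplicative fitness effect (> 1) of an effective
#'   knockout in the YAP arm: effector sgRNAs enrich by `effect_fold`,
#'   inhibitor sgRNAs deplete by `1/effect_fold`.
#' @param sgrna_active_prob Probability that a given sgRNA produces a
#'   functional knockout; inactive sgRNAs behave like nontargeting controls.
#' @param baseline_dispersion Standard deviation, on the natural-log scale, of
#'   the multiplicative noise applied to each sgRNA's expected count when
#'   sequencing a sample (Poisson-lognormal overdispersion).
#' @param mean_depth Expected reads per sgRNA per sample.
#' @param drift_sd Standard deviation (natural-log scale) of multiplicative
#'   passage drift per sgRNA between the day-10 input and a day-25 sample.
#' @param abundance_sdlog Lognormal spread of the library representation:
#'   the per-replicate baseline abundance of each sgRNA is
#'   `rlnorm(meanlog = 0, sdlog = abundance_sdlog)`.
#' @param seed Master RNG seed; all randomness in the simulator derives from
#'   it through named substreams, so identical configurations give
#'   byte-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_library()], [simulate_counts()]
#' @export
sim_config <- function(n_genes = 950,
                       sgrnas_per_gene = 4,
                       n_ntc = 50,
                       n_replicates = 4,
                       effector_fraction = 0.02,
                       inhibitor_fraction = 0.02,
                       effect_fold = 3,
                       sgrna_active_prob = 0.75,
                       baseline_dispersion = 0.15,
                       mean_depth = 500,
                       drift_sd = 0.10,
                       abundance_sdlog = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    sgrnas_per_gene = as.integer(sgrnas_per_gene),
    n_ntc = as.integer(n_ntc),
    n_replicates = as.integer(n_replicates),
    effector_fraction = as.numeric(effector_fraction),
    inhibitor_fraction = as.numeric(inhibitor_fraction),
    effect_fold = as.numeric(effect_fold),
    sgrna_active_prob = as.numeric(sgrna_active_prob),
    baseline_dispersion = as.numeric(baseline_dispersion),
    mean_depth = as.numeric(mean_depth),
    drift_sd = as.numeric(drift_sd),
    abundance_sdlog = as.numeric(abundance_sdlog),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 1, cfg$sgrnas_per_gene >= 1, cfg$n_ntc >= 0,
    cfg$n_replicates >= 1,
    cfg$effector_fraction >= 0, cfg$effector_fraction <= 1,
    cfg$inhibitor_fraction >= 0, cfg$inhibitor_fraction <= 1,
    cfg$effect_fold > 1,
    cfg$sgrna_active_prob >= 0, cfg$sgrna_active_prob <= 1,
    cfg$baseline_dispersion >= 0, cfg$mean_depth > 0,
    cfg$drift_sd >= 0, cfg$abundance_sdlog >= 0,
    !is.na(cfg$seed)
  )
  if (cfg$effector_fraction + cfg$inhibitor_fraction > 1) {
    stop("effector_fraction + inhibitor_fraction must be <= 1")
  }
  structure(cfg, class = "sim_config")
}

#' Analysis configuration for screen scoring
#'
#' Holds the scoring constants: the raw-count exclusion cutoff, the
#' fold-change threshold for calling an sgRNA enriched or depleted, and the
#' gene-level classification rules. Defaults implement strict exclusion of
#' raw counts below 20 and an inclusive 1.5-fold threshold on the median
#' ratio, with depletion judged at the reciprocal (<= 1/1.5).
#'
#' @param low_count_threshold Raw counts strictly below this value are
#'   excluded (count 19 is excluded, count 20 retained).
#' @param fold_threshold Median-ratio cutoff for enrichment (`>=`) and, via
#'   its reciprocal, depletion (`<=`) in the YAP/Empty contrast.
#' @param filter_scope `"pairwise"` drops a replicate ratio only when one of
#'   its two samples is below the count threshold; `"any_sample"` invalidates
#'   an sgRNA everywhere once it is low in any sample.
#' @param min_valid_replicates Minimum number of valid replicate ratios for a
#'   median to be reported; below it the median is `NA`.
#' @param pseudocount Nonnegative value added to both normalized abundances
#'   before taking their ratio (default 0, i.e. plain ratios).
#' @param zscore_reference Reference set for z-scores of log2 median ratios:
#'   `"ntc"` (nontargeting controls, the default) or `"all"` sgRNAs.
#' @param input_rule_min_sgrnas How many of a gene's qualifying sgRNAs must
#'   also pass the Input-contrast rule for an effector to be prioritized (and
#'   for an inhibitor call). Default 1.
#' @param input_rule_fold Fold threshold for the Input contrast (enrichment
#'   `>=` this value; depletion `<=` its reciprocal). Default 1.0, i.e. any
#'   enrichment/depletion; set to `fold_threshold` for the stricter reading.
#' @param min_hit_sgrnas Number of sgRNAs that must pass the YAP/Empty rule
#'   for a gene-level call (default 2).
#'
#' @return An object of class `analysis_config`.
#' @seealso [screen_ratios()], [call_hits()]
#' @export
analysis_config <- function(low_count_threshold = 20,
                            fold_threshold = 1.5,
                            filter_scope = c("pairwise", "any_sample"),
                            min_valid_replicates = 2,
                            pseudocount = 0,
                            zscore_reference = c("ntc", "all"),
                            input_rule_min_sgrnas = 1,
                            input_rule_fold = 1.0,
                            min_hit_sgrnas = 2) {
  cfg <- list(
    low_count_threshold = as.numeric(low_count_threshold),
    fold_threshold = as.numeric(fold_threshold),
    filter_scope = match.arg(filter_scope),
    min_valid_replicates = as.integer(min_valid_replicates),
    pseudocount = as.numeric(pseudocount),
    zscore_reference = match.arg(zscore_reference),
    input_rule_min_sgrnas = as.integer(input_rule_min_sgrnas),
    input_rule_fold = as.numeric(input_rule_fold),
    min_hit_sgrnas = as.integer(min_hit_sgrnas)
  )
  stopifnot(
    cfg$low_count_threshold > 0,
    cfg$fold_threshold > 0,
    cfg$min_valid_replicates >= 1,
    cfg$pseudocount >= 0,
    cfg$input_rule_min_sgrnas >= 0,
    cfg$input_rule_fold > 0,
    cfg$min_hit_sgrnas >= 1
  )
  structure(cfg, class = "analysis_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Rescue-screen simulation config\n")
  cat(sprintf("  library : %d genes x %d sgRNAs + %d NTCs\n",
              x$n_genes, x$sgrnas_per_gene, x$n_ntc))
  cat(sprintf("  design  : %d replicates x {input, empty, yap}, depth %g reads/sgRNA\n",
              x$n_replicates, x$mean_depth))
  cat(sprintf("  effects : %g%% effectors, %g%% inhibitors, fold %g, P(active sgRNA) %g\n",
              100 * x$effector_fraction, 100 * x$inhibitor_fraction,
              x$effect_fold, x$sgrna_active_prob))
  cat(sprintf("  noise   : abundance sdlog %g, drift sd %g, dispersion %g, seed %d\n",
              x$abundance_sdlog, x$drift_sd, x$baseline_dispersion, x$seed))
  invisible(x)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Rescue-screen analysis config\n")
  cat(sprintf("  exclude raw counts < %g (%s scope)\n",
              x$low_count_threshold, x$filter_scope))
  cat(sprintf("  hit rule: >= %d sgRNAs with median ratio >= %g (or <= %.4g)\n",
              x$min_hit_sgrnas, x$fold_threshold, 1 / x$fold_threshold))
  cat(sprintf("  input rule: >= %d sgRNA(s) at fold %g; z reference: %s\n",
              x$input_rule_min_sgrnas, x$input_rule_fold, x$zscore_reference))
  invisible(x)
}

# Reserved gene token for nontargeting controls in library tables.
NTC_TOKEN <- "NTC"
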