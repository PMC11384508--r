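#' Classify one gene from its sgRNA median ratios
#'
#' Applies the screen's decision rules to a gene's sgRNAs:
#'
#' * **effector** — at least `min_hit_sgrnas` (default 2) sgRNAs with
#'   YAP/Empty median ratio `>= fold_threshold` (inclusive, default 1.5);
#' * **effector_prioritized** — an effector for which at least
#'   `input_rule_min_sgrnas` of those enriched sgRNAs also have a YAP/Input
#'   median `>= input_rule_fold`;
#' * **inhibitor** — at least `min_hit_sgrnas` sgRNAs with YAP/Empty median
#'   `<= 1/fold_threshold`, of which at least `input_rule_min_sgrnas` also
#'   have YAP/Input median `<= 1/input_rule_fold`;
#' * **insufficient_data** — fewer than `min_hit_sgrnas` sgRNAs with a valid
#'   YAP/Empty median;
#' * **none** — otherwise.
#'
#' Missing medians never qualify. If a gene meets both the effector and
#' inhibitor rules (possible only for extreme configurations), the class
#' with more qualifying sgRNAs wins; a tie yields `none`.
#'
#' @param median_empty,median_input Numeric vectors of per-sgRNA median
#'   ratios for the YAP/Empty and YAP/Input contrasts (`NA` = invalid).
#' @param config An [analysis_config()].
#' @return List: `class`, `n_sgrnas_total`, `n_valid`, `n_enriched_empty`,
#'   `n_depleted_empty`, `n_enriched_input`, `n_depleted_input`.
#' @export
classify_gene <- function(median_empty, median_input,
                          config = analysis_config()) {
  stopifnot(length(median_empty) == length(median_input))
  enr_e <- !is.na(median_empty) & median_empty >= config$fold_threshold
  dep_e <- !is.na(median_empty) & median_empty <= 1 / config$fold_threshold
  enr_i <- !is.na(median_input) & median_input >= config$input_rule_fold
  dep_i <- !is.na(median_input) & median_input <= 1 / config$input_rule_fold

  n_valid <- sum(!is.na(median_empty))
  counts <- list(
    n_sgrnas_total = length(median_empty),
    n_valid = n_valid,
    n_enriched_empty = sum(enr_e),
    n_depleted_empty = sum(dep_e),
    n_enriched_input = sum(enr_i),
    n_depleted_input = sum(dep_i)
  )

  is_eff <- counts$n_enriched_empty >= config$min_hit_sgrnas
  eff_prior <- is_eff &&
    sum(enr_e & enr_i) >= config$input_rule_min_sgrnas
  is_inh <- counts$n_depleted_empty >= config$min_hit_sgrnas &&
    sum(dep_e & dep_i) >= config$input_rule_min_sgrnas

  cls <- if (n_valid < config$min_hit_sgrnas) {
    "insufficient_data"
  } else if (is_eff && is_inh) {
    if (counts$n_enriched_empty > counts$n_depleted_empty) {
      if (eff_prior) "effector_prioritized" else "effector"
    } else if (counts$n_depleted_empty > counts$n_enriched_empty) {
      "inhibitor"
    } else "none"
  } else if (is_eff) {
    if (eff_prior) "effector_prioritized" else "effector"
  } else if (is_inh) {
    "inhibitor"
  } else "none"

  c(list(class = cls), counts)
}

#' Gene-level hit calling for a whole screen
#'
#' Applies [classify_gene()] to every targeted gene and, as an empirical
#' negative-control readout, to pseudo-genes formed by a seeded random
#' partition of the nontargeting controls into groups the size of a typical
#' gene's sgRNA set.
#'
#' @param ratio_table A `ratio_table` from [screen_ratios()].
#' @param library A `screen_library` matching the table.
#' @param config An [analysis_config()].
#' @param ntc_seed Seed for the nontargeting pseudo-gene partition.
#' @return A `gene_hits` data frame: `gene`, `class`, `is_ntc`, the
#'   qualifying-sgRNA counts, and `best_z` (the most extreme z-score among
#'   the gene's sgRNAs).
#' @export
call_hits <- function(ratio_table, library, config = analysis_config(),
                      ntc_seed = 1L) {
  if (nrow(ratio_table) == 0) stop("empty ratio table")
  need <- c("median_yap_vs_empty", "median_yap_vs_input")
  if (!all(need %in% names(ratio_table))) {
    stop("ratio table must cover both contrasts (columns ",
         paste(need, collapse = ", "), ")")
  }
  validate_library(library)
  tab <- ratio_table[match(library$sgrna_id, ratio_table$sgrna_id), ]
  if (any(is.na(tab$sgrna_id))) stop("ratio table is missing library sgRNAs")

  group <- library$gene
  is_ntc_sg <- group == NTC_TOKEN
  if (any(is_ntc_sg)) {
    sizes <- table(group[!is_ntc_sg])
    g_size <- if (length(sizes)) {
      as.integer(names(sort(table(as.integer(sizes)),
                            decreasing = TRUE))[1])  # modal sgRNAs/gene
    } else 4L
    idx <- which(is_ntc_sg)
    perm <- with_seed(ntc_seed, sample(idx))
    group[perm] <- sprintf("NTC_pseudo%02d",
                           ceiling(seq_along(perm) / g_size))
  }

  genes <- unique(group)
  rows <- lapply(genes, function(g) {
    sel <- group == g
    cl <- classify_gene(tab$median_yap_vs_empty[sel],
                        tab$median_yap_vs_input[sel], config)
    z <- tab$zscore[sel]
    cl$best_z <- if (all(is.na(z))) NA_real_ else z[which.max(abs(z))]
    as.data.frame(cl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(gene = genes,
                          is_ntc = startsWith(genes, "NTC_pseudo"),
                          stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  class(out) <- c("gene_hits", "data.frame")
  out
}

# Evaluate expr under a temporary seed, restoring RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Compare hit calls with simulation ground truth
#'
#' Scores recovery of the simulated effector and inhibitor genes. A call is
#' an effector call if its class is `effector` or `effector_prioritized`.
#' Nontargeting pseudo-genes are excluded from scoring.
#'
#' @param hits A `gene_hits` from [call_hits()].
#' @param truth A `sim_truth` over the same targeted genes.
#' @return A `recovery_report` data frame with one row per class
#'   (`effector`, `inhibitor`): true/false positives, false negatives,
#'   precision, recall, F1 (`NA` where undefined, e.g. precision with no
#'   calls).
#' @export
evaluate_recovery <- function(hits, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  h <- hits[!hits$is_ntc, ]
  if (!setequal(h$gene, truth$genes$gene)) {
    stop("hit table and truth cover different gene sets")
  }
  tr <- truth$genes$class[match(h$gene, truth$genes$gene)]
  called <- list(
    effector = h$class %in% c("effector", "effector_prioritized"),
    inhibitor = h$class == "inhibitor"
  )
  rows <- lapply(names(called), function(cl) {
    pos <- called[[cl]]
    true_pos <- tr == cl
    tp <- sum(pos & true_pos)
    fp <- sum(pos & !true_pos)
    fn <- sum(!pos & true_pos)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    data.frame(class = cl, n_truth = sum(true_pos), n_called = sum(pos),
               tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' Write a gene-level hit table
#' @param hits A `gene_hits`.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  write_tsv(as.data.frame(hits), path,
            provenance = "rescuescreen gene-level hit calls")
  invisible(path)
}
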