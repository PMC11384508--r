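#' Run the full screen pipeline on simulated data
#'
#' Orchestrates simulate -> (optionally write FASTQ and re-quantify) ->
#' score -> call hits -> evaluate, writing every stage output plus a run
#' manifest to `out_dir`. Identical configuration and seed give
#' byte-identical output files.
#'
#' @param sim A [sim_config()] (its `seed` is the master seed).
#' @param analysis An [analysis_config()].
#' @param out_dir Output directory.
#' @param emit_fastq Also write per-sample FASTQ fixtures.
#' @param quantify_from_fastq When `TRUE` (implies `emit_fastq`), the scored
#'   count matrix is re-derived from the FASTQ files with exact spacer
#'   matching instead of being taken directly from the simulator — an
#'   end-to-end exercise of the read counter.
#' @param spikes Optional list of spike definitions passed to [spike_gene()]
#'   (each a list with `gene`, `class`, optional `active`, `effect_fold`);
#'   spiked genes replace `gene0001`, `gene0002`, ... in order.
#' @return Invisibly, the manifest list (also written as `manifest.json`):
#'   config echo, seed, file inventory, and stage row counts.
#' @export
run_pipeline <- function(sim = sim_config(), analysis = analysis_config(),
                         out_dir, emit_fastq = FALSE,
                         quantify_from_fastq = FALSE, spikes = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(analysis, "analysis_config"))
  if (quantify_from_fastq) emit_fastq <- TRUE
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  simulated <- simulate_library(sim)
  if (!is.null(spikes)) {
    for (i in seq_along(spikes)) {
      s <- spikes[[i]]
      simulated <- spike_gene(simulated, sprintf("gene%04d", i), s$gene,
                              s$class,
                              effect_fold = s$effect_fold %||% sim$effect_fold,
                              active = s$active %||% TRUE)
    }
  }
  counts <- simulate_counts(simulated$library, simulated$truth, sim)
  paths <- write_fixture(simulated$library, counts, simulated$truth, out_dir,
                         emit_fastq = emit_fastq)

  scored_counts <- counts
  if (quantify_from_fastq) {
    fq <- paths[startsWith(names(paths), "fastq_")]
    names(fq) <- sub("^fastq_", "", names(fq))
    scored_counts <- quantify_samples(simulated$library, fq, counts$samples,
                                      mismatch_mode = "exact")
  }

  ratio_table <- screen_ratios(scored_counts, simulated$library, analysis)
  hits <- call_hits(ratio_table, simulated$library, analysis,
                    ntc_seed = sim$seed)
  recovery <- evaluate_recovery(hits, simulated$truth)

  paths <- c(paths,
             ratios = file.path(out_dir, "sgrna_results.tsv"),
             hits = file.path(out_dir, "gene_hits.tsv"),
             recovery = file.path(out_dir, "recovery.tsv"))
  write_ratio_table(ratio_table, paths[["ratios"]])
  write_hits(hits, paths[["hits"]])
  write_tsv(as.data.frame(recovery), paths[["recovery"]],
            provenance = "rescuescreen recovery vs simulation truth")

  manifest <- list(
    package = "rescuescreen",
    version = as.character(utils::packageVersion("rescuescreen")),
    seed = sim$seed,
    sim_config = unclass(sim),
    analysis_config = unclass(analysis),
    files = as.list(paths),
    n_sgrnas = nrow(simulated$library),
    n_genes = length(unique(simulated$library$gene[
      simulated$library$gene != NTC_TOKEN])),
    n_ntc = sum(simulated$library$gene == NTC_TOKEN),
    hit_counts = as.list(table(hits$class[!hits$is_ntc])),
    ntc_pseudo_hits = sum(hits$is_ntc &
                            hits$class %in% c("effector",
                                              "effector_prioritized",
                                              "inhibitor"))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest$files$manifest <- manifest_path
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize pipeline outputs as a plain-text report
#'
#' Reads the tables written by [run_pipeline()] from `results_dir` and
#' renders a short markdown report: hit counts per class (fixed order),
#' nontargeting pseudo-gene calls, recovery metrics when a truth table is
#' present, and the top sgRNAs by absolute z-score.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param n_top Number of top-|z| sgRNAs to list.
#' @return Character vector of report lines (also usable with
#'   `writeLines()`).
#' @export
summarize_run <- function(results_dir, n_top = 10) {
  hits_path <- file.path(results_dir, "gene_hits.tsv")
  ratios_path <- file.path(results_dir, "sgrna_results.tsv")
  if (!file.exists(hits_path) || !file.exists(ratios_path)) {
    stop("missing pipeline outputs in ", results_dir)
  }
  hits <- read_tsv_strict(hits_path)
  ratios <- read_tsv_strict(ratios_path)

  class_order <- c("effector_prioritized", "effector", "inhibitor", "none",
                   "insufficient_data")
  targeted <- hits[!hits$is_ntc, ]
  lines <- c("# Rescue-screen summary", "",
             sprintf("Genes: %d targeted, %d nontargeting pseudo-genes",
                     nrow(targeted), sum(hits$is_ntc)),
             "", "## Gene classes")
  for (cl in class_order) {
    lines <- c(lines, sprintf("- %s: %d", cl, sum(targeted$class == cl)))
  }
  lines <- c(lines, "",
             sprintf("Nontargeting pseudo-genes called as hits: %d",
                     sum(hits$is_ntc & hits$class %in%
                           c("effector", "effector_prioritized",
                             "inhibitor"))))

  rec_path <- file.path(results_dir, "recovery.tsv")
  if (file.exists(rec_path)) {
    rec <- read_tsv_strict(rec_path)
    lines <- c(lines, "", "## Recovery vs simulation truth")
    for (i in seq_len(nrow(rec))) {
      lines <- c(lines, sprintf(
        "- %s: precision %.3f, recall %.3f (tp %d, fp %d, fn %d)",
        rec$class[i], rec$precision[i], rec$recall[i],
        rec$tp[i], rec$fp[i], rec$fn[i]))
    }
  }

  ok <- !is.na(ratios$zscore)
  top <- ratios[ok, ][order(-abs(ratios$zscore[ok])), ][seq_len(
    min(n_top, sum(ok))), ]
  lines <- c(lines, "", sprintf("## Top %d sgRNAs by |z|", nrow(top)))
  for (i in seq_len(nrow(top))) {
    lines <- c(lines, sprintf("- %s (%s): median YAP/Empty %.2f, z %.2f",
                              top$sgrna_id[i], top$gene[i],
                              top$median_yap_vs_empty[i], top$zscore[i]))
  }
  lines
}
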