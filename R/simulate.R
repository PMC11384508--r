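#' Simulate an sgRNA library with ground truth
#'
#' Generates a knockout library of `n_genes * sgrnas_per_gene` targeted
#' sgRNAs plus `n_ntc` nontargeting controls, each with a unique synthetic
#' 20-nt spacer, together with the ground truth used by
#' [simulate_counts()]: a class per gene (effector / inhibitor / null,
#' drawn independently with the configured fractions) and an active flag per
#' sgRNA (drawn with probability `sgrna_active_prob`; nontargeting controls
#' are always null and inactive).
#'
#' Spacers are random 20-mers screened so that no two are within Hamming
#' distance 1 of each other, which makes exact-match read counting
#' unambiguous even in mismatch-tolerant mode.
#'
#' @param config A [sim_config()].
#' @return A list with components `library` (a `screen_library` data frame
#'   with columns `sgrna_id`, `gene`, `spacer`) and `truth` (a `sim_truth`
#'   list with data frames `genes` (`gene`, `class`, `effect_fold`) and
#'   `sgrnas` (`sgrna_id`, `gene`, `active`)).
#' @export
simulate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  streams <- rng_streams(config$seed, c("library", "truth"))

  n_targeted <- config$n_genes * config$sgrnas_per_gene
  n_total <- n_targeted + config$n_ntc
  genes <- sprintf("gene%04d", seq_len(config$n_genes))

  lib <- data.frame(
    sgrna_id = c(
      sprintf("%s_sg%d", rep(genes, each = config$sgrnas_per_gene),
              rep(seq_len(config$sgrnas_per_gene), config$n_genes)),
      if (config$n_ntc > 0) sprintf("NTC_sg%02d", seq_len(config$n_ntc))
    ),
    gene = c(rep(genes, each = config$sgrnas_per_gene),
             rep(NTC_TOKEN, config$n_ntc)),
    spacer = with_stream(streams, "library", random_spacers(n_total)),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("screen_library", "data.frame")
  validate_library(lib)

  truth <- with_stream(streams, "truth", {
    cls <- sample(
      c("effector", "inhibitor", "null"), config$n_genes, replace = TRUE,
      prob = c(config$effector_fraction, config$inhibitor_fraction,
               1 - config$effector_fraction - config$inhibitor_fraction)
    )
    targeted <- lib$gene != NTC_TOKEN
    active <- logical(nrow(lib))
    active[targeted] <- stats::runif(sum(targeted)) < config$sgrna_active_prob
    list(
      genes = data.frame(
        gene = genes, class = cls,
        effect_fold = ifelse(cls == "null", 1, config$effect_fold),
        stringsAsFactors = FALSE
      ),
      sgrnas = data.frame(
        sgrna_id = lib$sgrna_id, gene = lib$gene, active = active,
        stringsAsFactors = FALSE
      )
    )
  })
  class(truth) <- "sim_truth"
  list(library = lib, truth = truth)
}

# Random unique 20-mers with pairwise Hamming distance >= 2, via mask
# hashing: two spacers are within distance 1 iff they collide on one of the
# 20 single-position-wildcard masks. Bounded retries guard against (very
# unlikely) exhaustion at these sizes.
random_spacers <- function(n, width = 20L, max_rounds = 25L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  mask_keys <- function(sp) {
    # width keys per spacer, each with one position replaced by '.'
    keys <- vapply(seq_len(width), function(i) {
      paste0(i, "_", substr(sp, 1, i - 1), ".",
             substr(sp, i + 1, width))
    }, character(length(sp)))
    t(matrix(keys, nrow = length(sp)))  # width x n
  }
  accepted <- character(0)
  seen <- character(0)
  need <- n
  for (round in seq_len(max_rounds)) {
    cand <- unique(draw(need))
    keys <- mask_keys(cand)  # width x n_cand
    # a candidate is rejected if any of its masked keys repeats an earlier
    # candidate's key (within-batch duplicate) or one already accepted
    bad_key <- duplicated(as.vector(keys)) | (as.vector(keys) %in% seen)
    cand_bad <- colSums(matrix(bad_key, nrow = width)) > 0
    ok <- cand[!cand_bad]
    if (length(ok) > need) ok <- ok[seq_len(need)]
    if (length(ok)) {
      accepted <- c(accepted, ok)
      seen <- c(seen, as.vector(mask_keys(ok)))
    }
    if (length(accepted) == n) return(accepted)
    need <- n - length(accepted)
  }
  stop("spacer-space exhaustion: could not generate ", n,
       " spacers with pairwise Hamming distance >= 2")
}

#' Override the simulated ground truth for a named gene
#'
#' Renames one simulated gene and pins its class, effect size, and per-sgRNA
#' active flags. Used to spike genes with known, fixed behavior (e.g. an
#' effector with exactly 3 of 4 functional sgRNAs) into an otherwise random
#' simulated screen.
#'
#' @param sim A `list(library, truth)` as returned by [simulate_library()].
#' @param old_gene Placeholder gene name to replace.
#' @param new_gene Replacement gene name.
#' @param class One of `"effector"`, `"inhibitor"`, `"null"`.
#' @param effect_fold Fitness fold for the gene (ignored for class
#'   `"null"`, where it is 1).
#' @param active Logical vector of per-sgRNA active flags, recycled to the
#'   gene's sgRNA count.
#' @return The modified `list(library, truth)`.
#' @export
spike_gene <- function(sim, old_gene, new_gene, class,
                       effect_fold = 3, active = TRUE) {
  stopifnot(class %in% c("effector", "inhibitor", "null"))
  lib <- sim$library
  truth <- sim$truth
  idx <- which(lib$gene == old_gene)
  if (length(idx) == 0) stop("gene not in library: ", old_gene)
  if (new_gene != old_gene && new_gene %in% lib$gene) {
    stop("gene already in library: ", new_gene)
  }
  active <- rep_len(as.logical(active), length(idx))
  lib$gene[idx] <- new_gene
  lib$sgrna_id[idx] <- sprintf("%s_sg%d", new_gene, seq_along(idx))
  gi <- truth$genes$gene == old_gene
  truth$genes$gene[gi] <- new_gene
  truth$genes$class[gi] <- class
  truth$genes$effect_fold[gi] <- if (class == "null") 1 else effect_fold
  truth$sgrnas$gene[idx] <- new_gene
  truth$sgrnas$sgrna_id[idx] <- lib$sgrna_id[idx]
  truth$sgrnas$active[idx] <- active
  sim$library <- lib
  sim$truth <- truth
  sim
}

#' Simulate sgRNA sequencing counts for a rescue screen
#'
#' Generative model, per biological replicate: each sgRNA receives a
#' lognormal baseline abundance (library representation). The input (day-10)
#' sample measures that baseline. Each day-25 arm drifts the baseline by an
#' independent lognormal passage factor (`drift_sd`); in the YAP arm the
#' abundance of each *active* sgRNA is additionally multiplied by
#' `effect_fold` (effector genes) or `1/effect_fold` (inhibitor genes).
#' Abundances are renormalized within each sample — sequencing measures
#' composition, not absolute cell number, so the global cytostasis of the
#' selected arm enters only through relative abundance — and counts are drawn
#' Poisson-lognormally with expected depth `mean_depth` reads per sgRNA and
#' log-scale overdispersion `baseline_dispersion`.
#'
#' @param library,truth As returned by [simulate_library()].
#' @param config The same [sim_config()] used to build the library.
#' @return A `screen_counts` object: list with `counts` (integer matrix,
#'   sgRNAs x samples), `samples` (data frame `sample_id`, `condition`,
#'   `replicate`) and `unassigned` (per-sample unassigned-read counts, all 0
#'   for simulated data).
#' @export
simulate_counts <- function(library, truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_library(library)
  if (!identical(library$sgrna_id, truth$sgrnas$sgrna_id)) {
    stop("library and truth disagree on sgRNA identities")
  }
  n_sg <- nrow(library)

  cls <- truth$genes$class[match(library$gene, truth$genes$gene)]
  fold_gene <- truth$genes$effect_fold[match(library$gene, truth$genes$gene)]
  sgn <- ifelse(is.na(cls), 0, ifelse(cls == "effector", 1,
                                      ifelse(cls == "inhibitor", -1, 0)))
  fold_gene[is.na(fold_gene)] <- 1
  yap_factor <- ifelse(truth$sgrnas$active,
                       fold_gene^sgn, 1)  # NTCs: active FALSE -> 1

  reps <- seq_len(config$n_replicates)
  stream_names <- as.vector(t(outer(
    reps, c("baseline", "input", "empty", "yap"),
    function(r, s) sprintf("rep%d_%s", r, s)
  )))
  streams <- rng_streams(config$seed, c("spare", stream_names))

  sample_one <- function(abund, stream) {
    tot <- sum(abund)
    if (tot <= 0) stop("degenerate configuration: zero total abundance")
    rel <- abund / tot
    mu <- config$mean_depth * n_sg * rel
    with_stream(streams, stream, {
      eps <- stats::rnorm(n_sg, 0, config$baseline_dispersion)
      stats::rpois(n_sg, mu * exp(eps - config$baseline_dispersion^2 / 2))
    })
  }

  counts <- matrix(0L, n_sg, 3 * config$n_replicates)
  samples <- data.frame(
    sample_id = character(3 * config$n_replicates),
    condition = character(3 * config$n_replicates),
    replicate = integer(3 * config$n_replicates),
    stringsAsFactors = FALSE
  )
  j <- 0
  for (r in reps) {
    baseline <- with_stream(streams, sprintf("rep%d_baseline", r),
                            stats::rlnorm(n_sg, 0, config$abundance_sdlog))
    drift_empty <- with_stream(streams, sprintf("rep%d_empty", r),
                               exp(stats::rnorm(n_sg, 0, config$drift_sd)))
    drift_yap <- with_stream(streams, sprintf("rep%d_yap", r),
                             exp(stats::rnorm(n_sg, 0, config$drift_sd)))
    abund <- list(
      input = baseline,
      empty = baseline * drift_empty,
      yap = baseline * drift_yap * yap_factor
    )
    for (cond in c("input", "empty", "yap")) {
      j <- j + 1
      counts[, j] <- sample_one(abund[[cond]], sprintf("rep%d_%s", r, cond))
      samples$sample_id[j] <- sprintf("%s_r%d", cond, r)
      samples$condition[j] <- cond
      samples$replicate[j] <- r
    }
  }
  dimnames(counts) <- list(library$sgrna_id, samples$sample_id)
  new_screen_counts(counts, samples)
}

#' Write a simulated screen to disk as plain-text fixtures
#'
#' Writes the library table, count matrix, sample sheet, and ground-truth
#' tables as tab-delimited text, and optionally one FASTQ file per sample
#' whose reads start with the sgRNA spacer and whose per-sgRNA read
#' multiplicities equal the count-matrix entries exactly.
#'
#' @param library,counts,truth Simulated screen components
#'   ([simulate_library()], [simulate_counts()]); `truth` may be `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param emit_fastq If `TRUE`, write `<sample_id>.fastq` per sample.
#' @param read_length Read length for FASTQ output (>= 20; the bases after
#'   the 20-nt spacer are filled with a constant scaffold sequence).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(library, counts, truth = NULL, out_dir,
                          emit_fastq = FALSE, read_length = 26L) {
  validate_library(library)
  stopifnot(inherits(counts, "screen_counts"), read_length >= 20)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    library = file.path(out_dir, "library.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    samples = file.path(out_dir, "samples.tsv")
  )
  write_library(library, paths[["library"]])
  write_counts(counts, paths[["counts"]], paths[["samples"]])
  if (!is.null(truth)) {
    paths <- c(paths,
               truth_genes = file.path(out_dir, "truth_genes.tsv"),
               truth_sgrnas = file.path(out_dir, "truth_sgrnas.tsv"))
    write_truth(truth, paths[["truth_genes"]], paths[["truth_sgrnas"]])
  }
  if (emit_fastq) {
    scaffold <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGG"  # tracrRNA scaffold start
    tail_seq <- substr(scaffold, 1, read_length - 20L)
    for (j in seq_len(ncol(counts$counts))) {
      sid <- counts$samples$sample_id[j]
      fq <- file.path(out_dir, paste0(sid, ".fastq"))
      paths <- c(paths, stats::setNames(fq, paste0("fastq_", sid)))
      n <- counts$counts[, j]
      reads <- rep(paste0(library$spacer, tail_seq), n)
      ids <- sprintf("%s_read%07d", sid, seq_along(reads))
      if (length(reads) == 0) {
        writeLines(character(0), fq)
      } else {
        x <- Biostrings::DNAStringSet(reads)
        names(x) <- ids
        qual <- Biostrings::BStringSet(rep(strrep("I", read_length),
                                           length(reads)))
        Biostrings::writeXStringSet(x, fq, format = "fastq", qualities = qual)
      }
    }
  }
  invisible(paths)
}

#' Simulate the reference screen used for validation
#'
#' Builds a synthetic stand-in for the published screen-results table, which
#' is not machine-readable from the article text. The stand-in uses the
#' documented screen design (950 genes x 4 sgRNAs + 50 nontargeting
#' controls, biological quadruplicate) and spikes in genes whose per-sgRNA
#' outcomes the article reports: SAP30 as an effector with exactly 3 of 4
#' functional sgRNAs, MORC2 as an inhibitor with all 4 sgRNAs functional,
#' plus the positive-control effectors (YAP1, TEAD1, TEAD4, ITGB5, UNC5B,
#' TGIF2) and inhibitors (AMOTL2, KIRREL, NF2). Everything downstream of the
#' ground truth — counts, ratios, hit calls — is recomputed by the pipeline,
#' so the stand-in is synthetic data with known truth, not published data.
#'
#' @param seed Master seed for the simulation.
#' @param config Optional [sim_config()] override; the library dimensions
#'   must remain 950 x 4 + 50.
#' @return A list with `library`, `truth`, and `counts`.
#' @export
simulate_reference_screen <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  sim <- simulate_library(config)
  spikes <- list(
    list(gene = "SAP30", class = "effector",
         active = c(TRUE, TRUE, TRUE, FALSE)),
    list(gene = "MORC2", class = "inhibitor", active = TRUE),
    list(gene = "YAP1", class = "effector", active = TRUE),
    list(gene = "TEAD1", class = "effector", active = TRUE),
    list(gene = "TEAD4", class = "effector", active = TRUE),
    list(gene = "ITGB5", class = "effector", active = TRUE),
    list(gene = "UNC5B", class = "effector", active = TRUE),
    list(gene = "TGIF2", class = "effector", active = TRUE),
    list(gene = "AMOTL2", class = "inhibitor", active = TRUE),
    list(gene = "KIRREL", class = "inhibitor", active = TRUE),
    list(gene = "NF2", class = "inhibitor", active = TRUE)
  )
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    sim <- spike_gene(sim, sprintf("gene%04d", i), s$gene, s$class,
                      effect_fold = config$effect_fold, active = s$active)
  }
  counts <- simulate_counts(sim$library, sim$truth, config)
  list(library = sim$library, truth = sim$truth, counts = counts)
}
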