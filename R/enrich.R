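#' Total-read (reads-per-million) normalization
#'
#' Scales each sample so the counts of all library sgRNAs sum to one
#' million: `rpm = count / sample_total * 1e6`. Totals are computed over the
#' full library before any exclusion, so later low-count filtering does not
#' change the normalization.
#'
#' @param counts A `screen_counts`.
#' @return A `screen_rpm` object: list with `rpm` (numeric matrix), `totals`
#'   (per-sample totals), `samples`, and the raw `counts` matrix.
#' @export
normalize_total <- function(counts) {
  stopifnot(inherits(counts, "screen_counts"))
  totals <- colSums(counts$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with zero total reads: ", paste(zero, collapse = ", "))
  }
  rpm <- sweep(counts$counts, 2, totals, "/") * 1e6
  structure(list(rpm = rpm, totals = totals, samples = counts$samples,
                 raw = counts$counts),
            class = "screen_rpm")
}

#' Low-count validity mask
#'
#' Marks a (sgRNA, sample) entry invalid when its *raw* count is strictly
#' below `low_count_threshold` (default 20: a count of 19 is excluded, 20 is
#' retained). With `filter_scope = "any_sample"`, an sgRNA below threshold in
#' any sample is invalidated in every sample.
#'
#' @param counts A `screen_counts`.
#' @param config An [analysis_config()].
#' @return Logical matrix, `TRUE` = valid, same dimensions as the counts.
#' @export
low_count_mask <- function(counts, config = analysis_config()) {
  stopifnot(inherits(counts, "screen_counts"),
            inherits(config, "analysis_config"))
  mask <- counts$counts >= config$low_count_threshold
  if (config$filter_scope == "any_sample") {
    keep <- rowSums(!mask) == 0
    mask[] <- mask & keep
  }
  mask
}

contrast_conditions <- function(contrast) {
  switch(contrast,
         yap_vs_empty = c("yap", "empty"),
         yap_vs_input = c("yap", "input"),
         stop("unknown contrast: ", contrast))
}

#' Per-replicate enrichment/depletion ratios
#'
#' For every replicate, divides the normalized abundance of the
#' YAP-expressing day-25 sample by that of the reference sample of the same
#' replicate (empty-vector day 25, or input day 10). A replicate ratio is
#' valid only when both members pass the low-count mask; a zero denominator
#' with zero pseudocount makes the ratio invalid rather than infinite.
#'
#' @param norm A `screen_rpm` from [normalize_total()].
#' @param mask Validity mask from [low_count_mask()].
#' @param contrast `"yap_vs_empty"` or `"yap_vs_input"`.
#' @param config An [analysis_config()].
#' @return List with matrices `ratios` and `valid` (sgRNAs x replicates;
#'   invalid ratios are `NA`) and the `replicates` vector.
#' @export
replicate_ratios <- function(norm, mask,
                             contrast = c("yap_vs_empty", "yap_vs_input"),
                             config = analysis_config()) {
  stopifnot(inherits(norm, "screen_rpm"))
  contrast <- match.arg(contrast)
  cond <- contrast_conditions(contrast)
  smp <- norm$samples
  reps <- sort(unique(smp$replicate))
  ratios <- matrix(NA_real_, nrow(norm$rpm), length(reps),
                   dimnames = list(rownames(norm$rpm),
                                   sprintf("rep%d", reps)))
  valid <- matrix(FALSE, nrow(norm$rpm), length(reps),
                  dimnames = dimnames(ratios))
  pc <- config$pseudocount
  for (k in seq_along(reps)) {
    r <- reps[k]
    num_id <- smp$sample_id[smp$condition == cond[1] & smp$replicate == r]
    den_id <- smp$sample_id[smp$condition == cond[2] & smp$replicate == r]
    if (length(num_id) != 1 || length(den_id) != 1) {
      stop("replicate ", r, " lacks a unique ", cond[1], "/", cond[2],
           " sample pair")
    }
    num <- norm$rpm[, num_id] + pc
    den <- norm$rpm[, den_id] + pc
    ok <- mask[, num_id] & mask[, den_id] & den > 0
    ratios[ok, k] <- num[ok] / den[ok]
    valid[, k] <- ok
  }
  list(ratios = ratios, valid = valid, replicates = reps)
}

#' Median ratio across valid replicates
#'
#' Takes, per sgRNA, the median of the valid replicate ratios (even counts
#' use the midpoint mean). The median is reported only when at least
#' `min_valid_replicates` replicates are valid; otherwise it is `NA`.
#'
#' @param rr Result of [replicate_ratios()].
#' @param config An [analysis_config()].
#' @return Data frame with `median` and `n_valid` per sgRNA.
#' @export
median_ratio <- function(rr, config = analysis_config()) {
  n_valid <- rowSums(rr$valid)
  med <- apply(rr$ratios, 1, stats::median, na.rm = TRUE)
  med[n_valid < config$min_valid_replicates] <- NA_real_
  med[is.nan(med)] <- NA_real_
  data.frame(median = med, n_valid = n_valid,
             row.names = rownames(rr$ratios))
}

#' Z-scores of log2 median ratios against a reference set
#'
#' Standardizes `log2(median ratio)` using the mean and standard deviation
#' of the reference set: nontargeting controls by default, or all sgRNAs
#' with a valid median (`zscore_reference = "all"`).
#'
#' @param medians Named numeric vector (or `median_ratio()` data frame
#'   column) of median ratios; `NA` where invalid.
#' @param library A `screen_library` identifying the nontargeting subset.
#' @param config An [analysis_config()].
#' @return Named numeric vector of z-scores (`NA` where the median is `NA`).
#' @export
zscores <- function(medians, library, config = analysis_config()) {
  if (is.data.frame(medians)) {
    medians <- stats::setNames(medians$median, rownames(medians))
  }
  validate_library(library)
  stopifnot(identical(names(medians), library$sgrna_id))
  lg <- log2(medians)
  ref <- if (config$zscore_reference == "ntc") {
    lg[library$gene == NTC_TOKEN]
  } else {
    lg
  }
  ref <- ref[is.finite(ref)]
  if (length(ref) < 2) {
    stop("z-score reference set has fewer than 2 valid members; ",
         "use zscore_reference = \"all\"")
  }
  s <- stats::sd(ref)
  if (s == 0) {
    stop("z-score reference set has zero variance; ",
         "use zscore_reference = \"all\"")
  }
  (lg - mean(ref)) / s
}

#' Full per-sgRNA scoring of a screen
#'
#' Runs the scoring chain — reads-per-million normalization, strict
#' low-count exclusion, per-replicate YAP/Empty and YAP/Input ratios, median
#' over replicates, and z-scores of the YAP/Empty log2 median ratios — and
#' returns one row per sgRNA.
#'
#' @param counts A `screen_counts` containing, per replicate, the three
#'   conditions `input`, `empty`, `yap`.
#' @param library A `screen_library` covering the count matrix.
#' @param config An [analysis_config()].
#' @return A `ratio_table` data frame: `sgrna_id`, `gene`, per-replicate
#'   ratios per contrast (`empty_rep*`, `input_rep*`), per-contrast valid
#'   replicate counts and medians, and `zscore`. The config is attached as
#'   attribute `"config"`.
#' @export
screen_ratios <- function(counts, library, config = analysis_config()) {
  validate_library(library)
  if (!identical(rownames(counts$counts), library$sgrna_id)) {
    stop("count matrix rows and library disagree")
  }
  norm <- normalize_total(counts)
  mask <- low_count_mask(counts, config)
  rr_e <- replicate_ratios(norm, mask, "yap_vs_empty", config)
  rr_i <- replicate_ratios(norm, mask, "yap_vs_input", config)
  med_e <- median_ratio(rr_e, config)
  med_i <- median_ratio(rr_i, config)
  z <- tryCatch(
    zscores(stats::setNames(med_e$median, library$sgrna_id), library, config),
    error = function(e) rep(NA_real_, nrow(library))
  )
  out <- data.frame(sgrna_id = library$sgrna_id, gene = library$gene,
                    stringsAsFactors = FALSE)
  colnames(rr_e$ratios) <- paste0("empty_", colnames(rr_e$ratios))
  colnames(rr_i$ratios) <- paste0("input_", colnames(rr_i$ratios))
  out <- cbind(out, as.data.frame(rr_e$ratios), as.data.frame(rr_i$ratios))
  out$median_yap_vs_empty <- med_e$median
  out$n_valid_yap_vs_empty <- med_e$n_valid
  out$median_yap_vs_input <- med_i$median
  out$n_valid_yap_vs_input <- med_i$n_valid
  out$zscore <- as.numeric(z)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Write / read a per-sgRNA results table
#' @param ratio_table A `ratio_table` from [screen_ratios()].
#' @param path Output path (tab-delimited text).
#' @export
write_ratio_table <- function(ratio_table, path) {
  write_tsv(as.data.frame(ratio_table), path,
            provenance = "rescuescreen per-sgRNA screen results")
  invisible(path)
}

#' @rdname write_ratio_table
#' @export
read_ratio_table <- function(path) {
  out <- read_tsv_strict(path)
  class(out) <- c("ratio_table", "data.frame")
  out
}
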