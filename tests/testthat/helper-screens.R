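# Shared fixtures: small simulated screens and a loop-based brute-force
# oracle for the scoring chain, kept deliberately independent of the
# vectorized implementation in the package.

tiny_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 30, sgrnas_per_gene = 4, n_ntc = 10,
               n_replicates = 4, mean_depth = 100, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Build a screen_counts from an sgRNA x sample matrix laid out as
# (input, empty, yap) x replicates.
make_counts <- function(m, n_reps, sgrna_ids = NULL) {
  conds <- rep(c("input", "empty", "yap"), n_reps)
  reps <- rep(seq_len(n_reps), each = 3)
  ids <- sprintf("%s_r%d", conds, reps)
  stopifnot(ncol(m) == 3 * n_reps)
  colnames(m) <- ids
  if (is.null(sgrna_ids)) sgrna_ids <- sprintf("sg%03d", seq_len(nrow(m)))
  rownames(m) <- sgrna_ids
  screen_counts(m, data.frame(sample_id = ids, condition = conds,
                              replicate = reps, stringsAsFactors = FALSE))
}

# A toy library for hand-built count matrices: n sgRNAs, last n_ntc are
# nontargeting, the rest grouped in fours.
toy_library <- function(n, n_ntc = 0) {
  gene <- c(sprintf("g%02d", ceiling(seq_len(n - n_ntc) / 4)),
            rep("NTC", n_ntc))
  bases <- c("A", "C", "G", "T")
  # deterministic unique spacers: base-4 encoding of the row index
  spacer <- vapply(seq_len(n), function(i) {
    digits <- integer(20)
    x <- i
    for (p in 1:20) { digits[p] <- x %% 4; x <- x %/% 4 }
    paste(bases[digits + 1], collapse = "")
  }, character(1))
  lib <- data.frame(sgrna_id = sprintf("sg%03d", seq_len(n)),
                    gene = gene, spacer = spacer, stringsAsFactors = FALSE)
  class(lib) <- c("screen_library", "data.frame")
  lib
}

# Brute-force recomputation of medians and z-scores from raw counts,
# written with explicit loops and stats::median/sd only.
oracle_scores <- function(counts, library, cfg) {
  raw <- counts$counts
  smp <- counts$samples
  totals <- sapply(seq_len(ncol(raw)), function(j) sum(raw[, j]))
  rpm <- raw
  for (j in seq_len(ncol(raw))) rpm[, j] <- raw[, j] / totals[j] * 1e6
  reps <- sort(unique(smp$replicate))
  med <- function(num_cond, den_cond) {
    out <- rep(NA_real_, nrow(raw))
    for (i in seq_len(nrow(raw))) {
      vals <- c()
      for (r in reps) {
        jn <- which(smp$condition == num_cond & smp$replicate == r)
        jd <- which(smp$condition == den_cond & smp$replicate == r)
        ok <- raw[i, jn] >= cfg$low_count_threshold &&
          raw[i, jd] >= cfg$low_count_threshold
        if (cfg$filter_scope == "any_sample") {
          ok <- all(raw[i, ] >= cfg$low_count_threshold)
        }
        if (ok && rpm[i, jd] > 0) vals <- c(vals, rpm[i, jn] / rpm[i, jd])
      }
      if (length(vals) >= cfg$min_valid_replicates) {
        out[i] <- stats::median(vals)
      }
    }
    out
  }
  med_e <- med("yap", "empty")
  med_i <- med("yap", "input")
  lg <- log2(med_e)
  ref <- if (cfg$zscore_reference == "ntc") {
    lg[library$gene == "NTC"]
  } else lg
  ref <- ref[is.finite(ref)]
  z <- if (length(ref) >= 2 && stats::sd(ref) > 0) {
    (lg - mean(ref)) / stats::sd(ref)
  } else rep(NA_real_, length(lg))
  list(median_empty = med_e, median_input = med_i, z = z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tmpdir <- function() {
  d <- tempfile("rescuescreen_test_")
  dir.create(d)
  d
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
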