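#' Count sgRNA spacers in a FASTQ file
#'
#' Assigns each read to an sgRNA by comparing the 20-mer at a fixed offset
#' (default 0: the spacer is the first 20 bases, as when sequencing skips
#' the vector anchor with dark cycles) against the library spacers.
#'
#' In `exact` mode a read is assigned to the sgRNA whose spacer it matches
#' exactly, otherwise it is unassigned. In `one_mismatch` mode a read is
#' assigned to the unique sgRNA whose spacer is within Hamming distance 1;
#' reads equidistant from several spacers are discarded to unassigned.
#' Reads shorter than `offset + 20` are unassigned. In every mode,
#' `sum(counts) + unassigned` equals the number of reads.
#'
#' @param library A `screen_library`.
#' @param fastq_path FASTQ file (optionally gzip-compressed).
#' @param mismatch_mode `"exact"` (default) or `"one_mismatch"`.
#' @param offset 0-based position of the spacer within the read.
#' @return A list with `counts` (named integer vector over all library
#'   sgRNAs), `unassigned`, and `n_reads`.
#' @export
count_reads <- function(library, fastq_path,
                        mismatch_mode = c("exact", "one_mismatch"),
                        offset = 0L) {
  validate_library(library)
  mismatch_mode <- match.arg(mismatch_mode)
  if (!file.exists(fastq_path)) stop("FASTQ not found: ", fastq_path)

  counts <- stats::setNames(integer(nrow(library)), library$sgrna_id)
  reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  n_reads <- length(reads)
  if (n_reads == 0) {
    warning("empty FASTQ: ", fastq_path)
    return(list(counts = counts, unassigned = 0L, n_reads = 0L))
  }

  long_enough <- Biostrings::width(reads) >= offset + 20L
  kmers <- rep(NA_character_, n_reads)
  kmers[long_enough] <- as.character(
    Biostrings::subseq(reads[long_enough], start = offset + 1L, width = 20L)
  )

  if (mismatch_mode == "exact") {
    hit <- match(kmers, library$spacer)
  } else {
    lut <- mismatch_lookup(library)
    idx <- match(kmers, lut$key)
    hit <- lut$sgrna_index[idx]          # NA for ambiguous keys
  }
  assigned <- hit[!is.na(hit)]
  if (length(assigned)) {
    tab <- tabulate(assigned, nbins = nrow(library))
    counts[] <- as.integer(tab)
  }
  list(counts = counts,
       unassigned = n_reads - length(assigned),
       n_reads = n_reads)
}

# Lookup table mapping every spacer and every 1-mismatch variant to its
# sgRNA row index, with keys reachable from more than one sgRNA mapped to
# NA (ambiguous -> discard).
mismatch_lookup <- function(library) {
  sp <- library$spacer
  n <- length(sp)
  bases <- c("A", "C", "G", "T")
  chars <- matrix(unlist(strsplit(sp, "", fixed = TRUE)), nrow = 20L)
  keys <- vector("list", 20L * 3L + 1L)
  owners <- vector("list", 20L * 3L + 1L)
  keys[[1]] <- sp
  owners[[1]] <- seq_len(n)
  k <- 1L
  for (pos in 1:20) {
    for (b in bases) {
      alt <- chars
      changed <- alt[pos, ] != b
      if (!any(changed)) next
      alt[pos, ] <- b
      k <- k + 1L
      keys[[k]] <- apply(alt[, changed, drop = FALSE], 2, paste0,
                         collapse = "")
      owners[[k]] <- which(changed)
    }
  }
  key <- unlist(keys[seq_len(k)], use.names = FALSE)
  owner <- unlist(owners[seq_len(k)], use.names = FALSE)
  # a key seen for >1 distinct sgRNA is ambiguous
  first <- !duplicated(key)
  idx_first <- match(key, key[first])
  ambiguous <- rep(FALSE, sum(first))
  ref_owner <- owner[first]
  clash <- owner != ref_owner[idx_first]
  if (any(clash)) ambiguous[unique(idx_first[clash])] <- TRUE
  sgrna_index <- ifelse(ambiguous, NA_integer_, ref_owner)
  list(key = key[first], sgrna_index = sgrna_index)
}

#' Quantify several FASTQ samples into a count matrix
#'
#' Runs [count_reads()] per sample and assembles a validated
#' `screen_counts`, attaching conditions and replicates from the sample
#' sheet.
#'
#' @param library A `screen_library`.
#' @param fastq_paths Named character vector `sample_id = path`.
#' @param samples Sample sheet data frame (`sample_id`, `condition`,
#'   `replicate`) covering every quantified sample.
#' @inheritParams count_reads
#' @return A `screen_counts` with per-sample unassigned totals.
#' @export
quantify_samples <- function(library, fastq_paths, samples,
                             mismatch_mode = c("exact", "one_mismatch"),
                             offset = 0L) {
  mismatch_mode <- match.arg(mismatch_mode)
  stopifnot(!is.null(names(fastq_paths)), all(nzchar(names(fastq_paths))))
  missing_meta <- setdiff(names(fastq_paths), samples$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) missing from sample sheet: ",
         paste(missing_meta, collapse = ", "))
  }
  m <- matrix(0L, nrow(library), length(fastq_paths),
              dimnames = list(library$sgrna_id, names(fastq_paths)))
  unassigned <- stats::setNames(integer(length(fastq_paths)),
                                names(fastq_paths))
  for (sid in names(fastq_paths)) {
    res <- count_reads(library, fastq_paths[[sid]],
                       mismatch_mode = mismatch_mode, offset = offset)
    m[, sid] <- res$counts
    unassigned[[sid]] <- res$unassigned
  }
  sheet <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  new_screen_counts(m, sheet, unassigned = unassigned)
}
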