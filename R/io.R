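# Plain-text interchange formats.
#
# Library table:  sgrna_id, gene, spacer     (gene == "NTC" marks controls)
# Count matrix :  sgrna_id + one column per sample_id (integer counts)
# Sample sheet :  sample_id, condition in {input, empty, yap}, replicate
# Truth tables :  genes  (gene, class, effect_fold)
#                 sgrnas (sgrna_id, gene, active)
# All tab-delimited with a header row; '#' lines are comments.

CONDITIONS <- c("input", "empty", "yap")

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

validate_library <- function(lib) {
  if (!is.data.frame(lib)) stop("library must be a data frame")
  need <- c("sgrna_id", "gene", "spacer")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stop("library table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(lib$sgrna_id)) {
    stop("duplicate sgrna_id: ",
         lib$sgrna_id[duplicated(lib$sgrna_id)][1])
  }
  if (anyDuplicated(lib$spacer)) {
    bad <- which(duplicated(lib$spacer))[1]
    stop("duplicate spacer at row ", bad, ": ", lib$spacer[bad])
  }
  bad_len <- which(nchar(lib$spacer) != 20L)
  if (length(bad_len)) {
    stop("spacer at row ", bad_len[1], " (", lib$sgrna_id[bad_len[1]],
         ") is not 20 nt: ", lib$spacer[bad_len[1]])
  }
  bad_chr <- grep("[^ACGT]", lib$spacer)
  if (length(bad_chr)) {
    stop("spacer at row ", bad_chr[1], " (", lib$sgrna_id[bad_chr[1]],
         ") contains non-ACGT characters")
  }
  invisible(lib)
}

#' Read and validate an sgRNA library table
#'
#' @param path Tab-delimited file with header columns `sgrna_id`, `gene`,
#'   `spacer`; `gene == "NTC"` marks nontargeting controls. Rows with
#'   duplicate ids/spacers, non-ACGT spacers, or spacers not exactly 20 nt
#'   are rejected with an error naming the offending row.
#' @return A `screen_library` data frame.
#' @export
read_library <- function(path) {
  lib <- read_tsv_strict(path)
  validate_library(lib)
  lib$sgrna_id <- as.character(lib$sgrna_id)
  lib$gene <- as.character(lib$gene)
  lib$spacer <- as.character(lib$spacer)
  class(lib) <- c("screen_library", "data.frame")
  lib
}

#' Write an sgRNA library table
#' @param library A `screen_library`.
#' @param path Output path.
#' @export
write_library <- function(library, path) {
  validate_library(library)
  write_tsv(library[c("sgrna_id", "gene", "spacer")], path,
            provenance = "rescuescreen library table")
  invisible(path)
}

#' Construct a raw count container from a matrix and sample sheet
#'
#' @param counts Nonnegative integer matrix, sgRNAs x samples, with row and
#'   column names.
#' @param samples Data frame with `sample_id` (matching the matrix columns,
#'   in order), `condition` (`input`, `empty` or `yap`) and `replicate`.
#' @param unassigned Optional named per-sample unassigned-read counts.
#' @return A `screen_counts` object.
#' @export
screen_counts <- function(counts, samples, unassigned = NULL) {
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  samples$replicate <- as.integer(samples$replicate)
  new_screen_counts(as.matrix(counts), samples, unassigned)
}

new_screen_counts <- function(counts, samples, unassigned = NULL) {
  storage.mode(counts) <- "integer"
  if (is.null(unassigned)) {
    unassigned <- stats::setNames(rep(0L, ncol(counts)), samples$sample_id)
  }
  validate_counts(counts, samples)
  structure(list(counts = counts, samples = samples, unassigned = unassigned),
            class = "screen_counts")
}

validate_counts <- function(counts, samples) {
  if (any(is.na(counts))) stop("count matrix contains missing values")
  if (any(counts < 0)) stop("count matrix contains negative counts")
  if (!identical(colnames(counts), samples$sample_id)) {
    stop("count-matrix columns and sample sheet disagree")
  }
  bad <- setdiff(unique(samples$condition), CONDITIONS)
  if (length(bad)) {
    stop("unknown condition token(s) in sample sheet: ",
         paste(bad, collapse = ", "),
         " (expected ", paste(CONDITIONS, collapse = ", "), ")")
  }
  key <- paste(samples$condition, samples$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, replicate) pair in sample sheet: ",
         key[duplicated(key)][1])
  }
  invisible(NULL)
}

#' Read a raw count matrix with its sample sheet
#'
#' @param path Tab-delimited count matrix: first column `sgrna_id`, one
#'   integer column per sample.
#' @param sample_sheet_path Tab-delimited sheet with columns `sample_id`,
#'   `condition` (one of `input`, `empty`, `yap`) and integer `replicate`.
#' @param library Optional `screen_library`; when given, every matrix
#'   sgRNA must be present in the library and rows are reordered to match it.
#' @return A `screen_counts` object.
#' @export
read_counts <- function(path, sample_sheet_path, library = NULL) {
  tab <- read_tsv_strict(path)
  if (names(tab)[1] != "sgrna_id") {
    stop("count matrix must have 'sgrna_id' as its first column")
  }
  sheet <- read_tsv_strict(sample_sheet_path)
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$condition <- as.character(sheet$condition)
  sheet$replicate <- as.integer(sheet$replicate)

  m <- as.matrix(tab[-1])
  if (!is.numeric(m)) stop("count matrix contains non-numeric entries")
  if (any(m != floor(m))) stop("count matrix contains non-integer counts")
  rownames(m) <- as.character(tab$sgrna_id)

  missing_samples <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing_samples)) {
    stop("sample(s) in matrix missing from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  }
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL

  if (!is.null(library)) {
    validate_library(library)
    unknown <- setdiff(rownames(m), library$sgrna_id)
    if (length(unknown)) {
      stop("sgRNA(s) in count matrix absent from library: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    full <- matrix(0L, nrow(library), ncol(m),
                   dimnames = list(library$sgrna_id, colnames(m)))
    full[rownames(m), ] <- m
    m <- full
  }
  new_screen_counts(m, sheet)
}

#' Write a count matrix and its sample sheet
#' @param counts A `screen_counts`.
#' @param path Count-matrix output path.
#' @param sample_sheet_path Sample-sheet output path (skipped if `NULL`).
#' @export
write_counts <- function(counts, path, sample_sheet_path = NULL) {
  stopifnot(inherits(counts, "screen_counts"))
  df <- data.frame(sgrna_id = rownames(counts$counts),
                   counts$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, provenance = "rescuescreen raw count matrix")
  if (!is.null(sample_sheet_path)) {
    write_tsv(counts$samples, sample_sheet_path,
              provenance = "rescuescreen sample sheet")
  }
  invisible(path)
}

#' Read / write simulation ground truth
#' @param genes_path,sgrnas_path Paths of the gene-level and sgRNA-level
#'   truth tables.
#' @return `read_truth()`: a `sim_truth` list with `genes` and `sgrnas`.
#' @export
read_truth <- function(genes_path, sgrnas_path) {
  genes <- read_tsv_strict(genes_path)
  sgrnas <- read_tsv_strict(sgrnas_path)
  stopifnot(all(c("gene", "class", "effect_fold") %in% names(genes)),
            all(c("sgrna_id", "gene", "active") %in% names(sgrnas)))
  sgrnas$active <- as.logical(sgrnas$active)
  structure(list(genes = genes, sgrnas = sgrnas), class = "sim_truth")
}

#' @rdname read_truth
#' @param truth A `sim_truth`.
#' @export
write_truth <- function(truth, genes_path, sgrnas_path) {
  stopifnot(inherits(truth, "sim_truth"))
  write_tsv(truth$genes, genes_path, provenance = "rescuescreen truth (genes)")
  write_tsv(truth$sgrnas, sgrnas_path,
            provenance = "rescuescreen truth (sgRNAs)")
  invisible(genes_path)
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d sgRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$condition)
  cat("  samples:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  total reads: %s (plus %s unassigned)\n",
              format(sum(x$counts), big.mark = ","),
              format(sum(x$unassigned), big.mark = ",")))
  invisible(x)
}

#' @export
print.screen_library <- function(x, ...) {
  n_ntc <- sum(x$gene == NTC_TOKEN)
  cat(sprintf("screen_library: %d sgRNAs, %d targeted genes, %d nontargeting\n",
              nrow(x), length(unique(x$gene[x$gene != NTC_TOKEN])), n_ntc))
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}
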