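## Core containers and tabular I/O shared by every stage of the pipeline.

#' Construct a count matrix container
#'
#' A `count_matrix` is an integer genes-by-samples matrix with unique row
#' (gene) and column (sample) ids.  All downstream contrasts operate on this
#' container; joins across assays are by gene id.
#'
#' @param counts numeric matrix of non-negative integers (genes x samples).
#' @param gene_ids character vector of unique gene ids (defaults to rownames).
#' @param sample_ids character vector of unique sample ids (defaults to
#'   colnames).
#' @return an object of class `count_matrix`: the integer matrix with
#'   dimnames set.
#' @examples
#' cm <- count_matrix(matrix(0:5, nrow = 2,
#'                           dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids must be supplied or present as dimnames")
  if (length(gene_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("id lengths do not match matrix dimensions")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id: ", dup[1L])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id: ", dup[1L])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at row '%s', column '%s': must be a non-negative integer",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  storage.mode(counts) <- "double"   # doubles avoid integer overflow on sums
  dimnames(counts) <- list(gene_ids, sample_ids)
  class(counts) <- c("count_matrix", "matrix", "array")
  counts
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... (%d more genes)\n", nrow(x) - 5L))
  invisible(x)
}

#' Read a count table from a tab-separated file
#'
#' Expects a header row of sample ids whose first token is `gene_id`, one row
#' per gene, tab-separated, no quoting.  Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("count table needs a gene_id column and >= 1 sample")
  gene_ids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(gene_ids, colnames(m))))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 gene_ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  count_matrix(num, gene_ids, colnames(m))
}

#' Write a count table as TSV
#'
#' Inverse of [read_counts()]; `read_counts(write_counts(cm, f))` reproduces
#' `cm` exactly.
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm), unclass(cm), check.names = FALSE)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `condition` (control/treated), `assay`
#' (rna/pro/intron/ribo) and `replicate`.
#'
#' @param path path to the design TSV.
#' @return a `data.frame` with validated factor levels.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                         stringsAsFactors = FALSE)
  sample_design(d)
}

#' Validate a sample design
#'
#' @param df data.frame with columns `sample_id`, `condition`, `assay`,
#'   `replicate`.
#' @return the validated data.frame (class `sample_design`).
#' @export
sample_design <- function(df) {
  need <- c("sample_id", "condition", "assay", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in design: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  if (!all(df$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  if (!all(df$assay %in% c("rna", "pro", "intron", "ribo")))
    stop("assay must be one of rna, pro, intron, ribo")
  df$replicate <- as.integer(df$replicate)
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Analysis configuration
#'
#' Bundles the significance and filtering thresholds used throughout:
#' `q_threshold` and `lfc_threshold` (log2) define significance calls,
#' `cpm_floor` the expression filter (counts per million must exceed it in
#' every sample), `strong_score_threshold` the external efficacy score below
#' which a predicted target counts as strong, and `au_window` the total
#' flanking window (nt) for local AU content.
#'
#' @param q_threshold q-value cutoff (default 0.05).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 0.2).
#' @param cpm_floor CPM floor for expression filtering (default 1).
#' @param strong_score_threshold efficacy score cutoff, must be <= 0
#'   (default -0.2).
#' @param au_window even total window size in nt for local AU content
#'   (default 30).
#' @param rng_seed optional integer seed recorded with results.
#' @return a list of class `carp_config`.
#' @export
carp_config <- function(q_threshold = 0.05, lfc_threshold = 0.2,
                        cpm_floor = 1, strong_score_threshold = -0.2,
                        au_window = 30L, rng_seed = NULL) {
  stopifnot(q_threshold > 0, lfc_threshold > 0, cpm_floor >= 0,
            strong_score_threshold <= 0, au_window > 0,
            au_window %% 2 == 0)
  structure(list(q_threshold = q_threshold, lfc_threshold = lfc_threshold,
                 cpm_floor = cpm_floor,
                 strong_score_threshold = strong_score_threshold,
                 au_window = as.integer(au_window), rng_seed = rng_seed),
            class = "carp_config")
}

#' Read a YAML analysis configuration
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#'
#' @param path YAML file whose keys mirror [carp_config()] arguments.
#' @return a `carp_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(carp_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(carp_config, vals)
}

#' Counts per million
#'
#' @param cm a [count_matrix()] (or plain matrix of counts).
#' @return real matrix of the same shape; each column sums to 1e6.
#' @export
cpm <- function(cm) {
  libs <- colSums(cm)
  zero <- which(libs == 0)
  if (length(zero))
    stop("zero library size for sample: ", colnames(cm)[zero[1L]])
  sweep(unclass(cm), 2L, libs, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Retains genes whose CPM exceeds `floor` in every sample.  Library sizes
#' are the raw column sums of the unfiltered matrix, so the operation is
#' idempotent only when the caller recomputes CPM on the same library sizes;
#' applied to its own output with recomputed libraries it may drop further
#' genes (CPMs grow, so in practice it is idempotent -- see tests).
#'
#' @param cm a [count_matrix()].
#' @param floor CPM floor (default 1, the conventional cutoff).
#' @return the filtered [count_matrix()] (possibly zero rows).
#' @export
filter_low_expression <- function(cm, floor = 1) {
  stopifnot(floor >= 0)
  keep <- rowSums(cpm(cm) > floor) == ncol(cm)
  count_matrix(unclass(cm)[keep, , drop = FALSE])
}

## Commented provenance header written atop every output TSV.
output_header <- function(cfg = NULL) {
  h <- sprintf("# carp %s", as.character(utils::packageVersion("carp")))
  if (!is.null(cfg)) {
    dump <- paste(vapply(names(unclass(cfg)), function(k)
      paste0(k, "=", paste(format(cfg[[k]]), collapse = ",")), character(1)),
      collapse = " ")
    h <- c(h, paste0("# config: ", dump))
  }
  h
}

#' Write a result table as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param cfg optional [carp_config()] recorded in the commented header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
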