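## Contrast assembly: one-factor differential tests per assay and the
## two-factor interaction test that reads out post-transcriptional change.
##
## Factor coding is treatment coding with 'control' and the transcription
## proxy assay as references, so the interaction coefficient is directly
## delta(target assay) - delta(proxy assay): for RNA-seq vs PRO-seq this is
## the post-transcriptional log fold-change, for ribosome profiling vs
## RNA-seq it is the change in translational efficiency.

LN2 <- log(2)

subset_design <- function(design, assays) {
  d <- design[design$assay %in% assays, , drop = FALSE]
  for (a in assays) {
    da <- d[d$assay == a, , drop = FALSE]
    if (!nrow(da)) stop("design lacks assay '", a, "'")
    tab <- table(da$condition)
    if (!all(c("control", "treated") %in% names(tab)))
      stop("assay '", a, "' is missing a condition")
    if (any(tab < 2L))
      stop("no replication: assay '", a,
           "' needs >= 2 replicates per condition")
  }
  d
}

assay_columns <- function(cm, design, assay) {
  ids <- design$sample_id[design$assay == assay]
  missing <- setdiff(ids, colnames(cm))
  if (length(missing))
    stop("sample id(s) absent from ", assay, " counts: ",
         paste(missing, collapse = ", "))
  count_matrix(unclass(cm)[, ids, drop = FALSE])
}

## One-factor NB GLM LRT on an aligned (already filtered) matrix.
one_factor_test <- function(y, treated, contrast) {
  nf <- compute_norm_factors(y)
  off <- log(colSums(y) * nf)
  X_full <- cbind(intercept = 1, condition = as.numeric(treated))
  X_red <- X_full[, 1L, drop = FALSE]
  disp <- estimate_dispersions(y, design_matrix(X_full, off))
  full <- nb_glm_fit(unclass(y), design_matrix(X_full, off), disp$tagwise)
  red <- nb_glm_fit(unclass(y), design_matrix(X_red, off), disp$tagwise)
  tst <- lrt(full, red, df = 1L)
  p <- pmax(tst$p, 1e-300)
  q <- storey_qvalue(p)$q
  data.frame(gene_id = rownames(y),
             log2fc = full$beta[, "condition"] / LN2,
             lrt_stat = tst$statistic, pvalue = p, qvalue = q,
             contrast = contrast, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' One-factor differential test for a single assay
#'
#' Filters lowly expressed genes, computes TMM offsets, estimates tagwise
#' dispersions and tests the condition coefficient of a per-gene NB GLM with
#' a likelihood-ratio test; q-values are Storey q-values.
#'
#' @param cm a [count_matrix()] holding the assay's samples (may contain
#'   extra columns; the design selects them).
#' @param design a [sample_design()].
#' @param assay which assay to test (`"rna"`, `"pro"`, `"intron"`, `"ribo"`).
#' @param cfg a [carp_config()]; `cpm_floor` controls filtering.
#' @return data.frame: `gene_id`, `log2fc`, `lrt_stat`, `pvalue`, `qvalue`,
#'   `contrast`.
#' @export
de_test <- function(cm, design, assay, cfg = carp_config()) {
  d <- subset_design(design, assay)
  y <- assay_columns(cm, d, assay)
  y <- filter_low_expression(y, cfg$cpm_floor)
  if (!nrow(y)) stop("no genes pass the expression filter")
  treated <- d$condition[match(colnames(y), d$sample_id)] == "treated"
  one_factor_test(y, treated, paste0(assay, ":treated_vs_control"))
}

interaction_test <- function(cm_target, cm_proxy, design, target_assay,
                             proxy_assay, contrast, cfg) {
  d <- subset_design(design, c(target_assay, proxy_assay))
  yt <- assay_columns(cm_target, d, target_assay)
  yp <- assay_columns(cm_proxy, d, proxy_assay)
  yt <- filter_low_expression(yt, cfg$cpm_floor)
  yp <- filter_low_expression(yp, cfg$cpm_floor)
  shared <- intersect(rownames(yt), rownames(yp))
  dropped <- (nrow(yt) - length(shared)) + (nrow(yp) - length(shared))
  if (length(shared) < 20L)
    stop("fewer than 20 genes shared between assays after filtering")
  message(sprintf("interaction test: %d shared genes (%d unmatched filtered ids dropped)",
                  length(shared), dropped))
  yt <- count_matrix(unclass(yt)[shared, , drop = FALSE])
  yp <- count_matrix(unclass(yp)[shared, , drop = FALSE])

  y <- cbind(unclass(yt), unclass(yp))
  treated <- d$condition[match(colnames(y), d$sample_id)] == "treated"
  is_target <- colnames(y) %in% colnames(yt)
  off <- c(log(colSums(yt) * compute_norm_factors(yt)),
           log(colSums(yp) * compute_norm_factors(yp)))
  X_full <- cbind(intercept = 1, condition = as.numeric(treated),
                  assay = as.numeric(is_target),
                  interaction = as.numeric(treated & is_target))
  X_red <- X_full[, 1:3, drop = FALSE]
  disp <- estimate_dispersions(y, design_matrix(X_full, off))
  full <- nb_glm_fit(y, design_matrix(X_full, off), disp$tagwise)
  red <- nb_glm_fit(y, design_matrix(X_red, off), disp$tagwise)
  tst <- lrt(full, red, df = 1L)
  p_post <- pmax(tst$p, 1e-300)
  q_post <- storey_qvalue(p_post)$q

  tt <- one_factor_test(yt, treated[is_target],
                        paste0(target_assay, ":treated_vs_control"))
  tp <- one_factor_test(yp, treated[!is_target],
                        paste0(proxy_assay, ":treated_vs_control"))

  res <- data.frame(gene_id = shared,
                    lfc_rna = tt$log2fc, lfc_pro = tp$log2fc,
                    lfc_post = full$beta[, "interaction"] / LN2,
                    lrt_post = tst$statistic,
                    p_post = p_post, q_post = q_post,
                    p_rna = tt$pvalue, q_rna = tt$qvalue,
                    p_pro = tp$pvalue, q_pro = tp$qvalue,
                    contrast = contrast, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("carp_result", "data.frame")
  res
}

#' CARP interaction test: post-transcriptional regulation
#'
#' Builds the joint RNA-seq/PRO-seq matrix on genes passing the expression
#' filter in both assays and compares the full NB GLM
#' `~ condition + assay + condition:assay` against the reduced model without
#' the interaction by likelihood-ratio test.  The interaction coefficient
#' (log2) is the post-transcriptional fold-change: change in steady-state
#' RNA not explained by the change in transcription.  Negative values mean
#' post-transcriptional repression.
#'
#' @param cm_rna,cm_pro [count_matrix()] objects for RNA-seq and PRO-seq.
#' @param design a [sample_design()] covering both assays.
#' @param cfg a [carp_config()].
#' @return a `carp_result` data.frame with columns `gene_id`, `lfc_rna`,
#'   `lfc_pro`, `lfc_post`, `lrt_post`, `p_post`, `q_post`, `p_rna`,
#'   `q_rna`, `p_pro`, `q_pro`, `contrast`.  `lfc_rna`/`lfc_pro` come from
#'   the per-assay one-factor tests on the same genes.
#' @export
carp_test <- function(cm_rna, cm_pro, design, cfg = carp_config()) {
  interaction_test(cm_rna, cm_pro, design, "rna", "pro", "carp", cfg)
}

#' Exon-intron split analysis (EISA) interaction test
#'
#' Identical contract to [carp_test()] with intronic read counts (a
#' pre-mRNA proxy for transcription) in place of PRO-seq.
#'
#' @inheritParams carp_test
#' @param cm_exon exonic (steady-state) counts.
#' @param cm_intron intronic counts.
#' @return a `carp_result` data.frame; `lfc_pro` holds the intron proxy
#'   fold-change.
#' @export
eisa_test <- function(cm_exon, cm_intron, design, cfg = carp_config()) {
  interaction_test(cm_exon, cm_intron, design, "rna", "intron", "eisa", cfg)
}

#' Translational-efficiency interaction test
#'
#' Ribosome-profiling counts against RNA-seq counts; the interaction
#' coefficient is the change in translational efficiency (log2).
#'
#' @inheritParams carp_test
#' @param cm_ribo ribosome-footprint counts.
#' @param cm_rna RNA-seq counts.
#' @return a `carp_result` data.frame; `lfc_post` is the delta-TE (log2).
#' @export
te_test <- function(cm_ribo, cm_rna, design, cfg = carp_config()) {
  interaction_test(cm_ribo, cm_rna, design, "ribo", "rna", "te", cfg)
}

#' Classify each gene's regulatory mode
#'
#' A gene is called transcriptionally regulated when the transcription-proxy
#' test is significant (`q_pro < q_threshold` and `|lfc_pro| >
#' lfc_threshold`), post-transcriptionally regulated when the interaction
#' test is (`q_post`/`lfc_post` likewise); genes meeting both are `both`,
#' neither are `neither`.
#'
#' @param res a `carp_result` from [carp_test()] and friends.
#' @param cfg a [carp_config()].
#' @return factor with levels `transcriptional`, `post_transcriptional`,
#'   `both`, `neither`, named by gene id.
#' @export
classify_mode <- function(res, cfg = carp_config()) {
  tx <- res$q_pro < cfg$q_threshold & abs(res$lfc_pro) > cfg$lfc_threshold
  pt <- res$q_post < cfg$q_threshold & abs(res$lfc_post) > cfg$lfc_threshold
  out <- ifelse(tx & pt, "both",
         ifelse(tx, "transcriptional",
         ifelse(pt, "post_transcriptional", "neither")))
  factor(stats::setNames(out, res$gene_id),
         levels = c("transcriptional", "post_transcriptional", "both", "neither"))
}

#' Relative read density (log2 ratio of normalized counts)
#'
#' Per-feature `log2((cpm_treated + pseudo) / (cpm_control + pseudo))`, the
#' readout used e.g. for relative AGO occupancy at crosslinking peaks.
#'
#' @param counts_treated,counts_control per-feature counts.
#' @param libsizes length-2 vector of library sizes (treated, control).
#' @param pseudo pseudo-count added to both CPMs (default 0.5).
#' @return numeric vector of log2 ratios.
#' @export
relative_read_density <- function(counts_treated, counts_control, libsizes,
                                  pseudo = 0.5) {
  if (any(libsizes <= 0)) stop("library sizes must be positive")
  cpm_t <- counts_treated / libsizes[1L] * 1e6
  cpm_c <- counts_control / libsizes[2L] * 1e6
  log2((cpm_t + pseudo) / (cpm_c + pseudo))
}
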