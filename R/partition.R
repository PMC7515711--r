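## Gene-set partitioning: three binary labels (predicted strong target,
## reduced mRNA, post-transcriptionally repressed) define a seven-set Venn
## partition a-g plus 'none'.

SET_TABLE <- within(expand.grid(predicted_strong = c(FALSE, TRUE),
                                rna_down = c(FALSE, TRUE),
                                carp_down = c(FALSE, TRUE)), {
  set_label <- rep(NA_character_, 8L)
})
## truth table: (strong, rna_down, carp_down) -> label
SET_TABLE$set_label <- apply(SET_TABLE[, c("predicted_strong", "rna_down",
                                           "carp_down")], 1L, function(z) {
  key <- paste(as.integer(z), collapse = "")
  switch(key,
         "100" = "a", "111" = "b", "110" = "c", "010" = "d",
         "011" = "e", "101" = "f", "001" = "g", "000" = "none")
})

#' Derive the three partition labels for one gene
#'
#' `rna_down` requires a significant decrease in mRNA abundance
#' (`q_rna < q_threshold` and `lfc_rna < -lfc_threshold`); `carp_down`
#' requires significant post-transcriptional repression (`q_post`,
#' `lfc_post` likewise); `predicted_strong` requires an external efficacy
#' score below `strong_score_threshold`.  Direction matters: upregulation
#' never sets a label.  A missing score yields `predicted_strong = FALSE`.
#'
#' @param res one row of a `carp_result`.
#' @param score external efficacy score (more negative = stronger), or `NA`.
#' @param cfg a [carp_config()].
#' @return named logical vector `(predicted_strong, rna_down, carp_down)`.
#' @export
label_gene <- function(res, score, cfg = carp_config()) {
  c(predicted_strong = isTRUE(!is.na(score) && score < cfg$strong_score_threshold),
    rna_down = isTRUE(res$q_rna < cfg$q_threshold &&
                        res$lfc_rna < -cfg$lfc_threshold),
    carp_down = isTRUE(res$q_post < cfg$q_threshold &&
                         res$lfc_post < -cfg$lfc_threshold))
}

#' Assign the Venn set label from three booleans
#'
#' Truth table (predicted_strong, rna_down, carp_down): (1,0,0) a,
#' (1,1,1) b, (1,1,0) c, (0,1,0) d, (0,1,1) e, (1,0,1) f, (0,0,1) g,
#' (0,0,0) none.  Set b is the direct-target class: predicted strong
#' targets with reduced mRNA explained by post-transcriptional repression.
#'
#' @param predicted_strong,rna_down,carp_down logicals (vectorized).
#' @return character vector of labels.
#' @export
assign_set <- function(predicted_strong, rna_down, carp_down) {
  key <- paste0(as.integer(predicted_strong), as.integer(rna_down),
                as.integer(carp_down))
  lab <- c(`100` = "a", `111` = "b", `110` = "c", `010` = "d",
           `011` = "e", `101` = "f", `001` = "g", `000` = "none")
  unname(lab[key])
}

#' Build the full gene-class table for a contrast
#'
#' @param res a `carp_result`.
#' @param scores named numeric vector of external efficacy scores (NA or
#'   absent = no prediction).
#' @param cfg a [carp_config()].
#' @param exclude_weak drop genes whose score lies in
#'   `(strong_score_threshold, 0]`-ish weak range, i.e. predicted weak
#'   targets (score present but above the strong threshold), mirroring the
#'   partition's upstream exclusion (default TRUE).
#' @return data.frame: `gene_id`, `predicted_strong`, `rna_down`,
#'   `carp_down`, `set_label`.
#' @export
gene_classes <- function(res, scores, cfg = carp_config(),
                         exclude_weak = TRUE) {
  sc <- scores[match(res$gene_id, names(scores))]
  if (exclude_weak) {
    weak <- !is.na(sc) & sc >= cfg$strong_score_threshold
    res <- res[!weak, , drop = FALSE]
    sc <- sc[!weak]
  }
  strong <- !is.na(sc) & sc < cfg$strong_score_threshold
  rna_down <- res$q_rna < cfg$q_threshold & res$lfc_rna < -cfg$lfc_threshold
  carp_down <- res$q_post < cfg$q_threshold & res$lfc_post < -cfg$lfc_threshold
  data.frame(gene_id = res$gene_id, predicted_strong = strong,
             rna_down = rna_down, carp_down = carp_down,
             set_label = assign_set(strong, rna_down, carp_down),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count genes per Venn set
#'
#' @param classes data.frame from [gene_classes()] (needs `set_label`).
#' @return named integer vector over `a`-`g` and `none`; sums to the number
#'   of genes.
#' @export
venn_counts <- function(classes) {
  levels <- c(letters[1:7], "none")
  tab <- table(factor(classes$set_label, levels = levels))
  stats::setNames(as.integer(tab), levels)
}

#' Score-matched subsampling of one gene set against another
#'
#' Bins the target set's scores into `n_bins` equal-width bins over the
#' pooled score range and samples candidates from the other set so the
#' subsample reproduces the target's bin histogram exactly.  Sampling is
#' without replacement; a bin whose candidates are exhausted is topped up
#' with replacement (reported via the `with_replacement` attribute), and a
#' target bin with zero candidates is dropped with a warning (reported via
#' `dropped_bins`).
#'
#' @param scores_b scores of the target set (the histogram to match).
#' @param scores_c scores of the candidate set to subsample.
#' @param n_bins number of equal-width bins (default 10).
#' @param seed integer seed for reproducibility.
#' @return integer indices into `scores_c`.
#' @export
matched_subsample <- function(scores_b, scores_c, n_bins = 10L, seed = 1L) {
  if (!length(scores_b) || !length(scores_c))
    stop("both score vectors must be nonempty")
  set.seed(seed)
  rng <- range(c(scores_b, scores_c))
  brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin_b <- findInterval(scores_b, brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
  bin_c <- findInterval(scores_c, brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
  idx <- integer(0); replaced <- 0L; dropped <- integer(0)
  for (b in sort(unique(bin_b))) {
    need <- sum(bin_b == b)
    cand <- which(bin_c == b)
    if (!length(cand)) {
      warning(sprintf("bin %d has no candidates; dropped (%d genes)", b, need))
      dropped <- c(dropped, b)
      next
    }
    take <- cand[sample.int(length(cand), min(need, length(cand)))]
    if (need > length(cand)) {
      extra <- cand[sample.int(length(cand), need - length(cand),
                               replace = TRUE)]
      replaced <- replaced + (need - length(cand))
      take <- c(take, extra)
    }
    idx <- c(idx, take)
  }
  attr(idx, "with_replacement") <- replaced
  attr(idx, "dropped_bins") <- dropped
  idx
}
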