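## Decay vs translational repression: set-level medians of
## background-normalized log2 fold-changes.

#' Normalize fold-changes to a background set
#'
#' Subtracts the median background fold-change, centering the target set's
#' changes on the behavior of unregulated genes (genes lacking predicted
#' sites for the cognate miRNA with no significant change in the same
#' measurement).
#'
#' @param lfcs log2 fold-changes of the target set.
#' @param background_lfcs log2 fold-changes of the background set
#'   (nonempty).
#' @return `lfcs - median(background_lfcs)`.
#' @export
normalize_to_background <- function(lfcs, background_lfcs) {
  if (!length(background_lfcs)) stop("background set is empty")
  lfcs - stats::median(background_lfcs)
}

#' Relative contributions of mRNA decay and translational repression
#'
#' With background-normalized per-gene log2 fold-changes of mRNA abundance
#' and translational efficiency for a target set, the decay fraction is
#' `med(-mrna) / (med(-mrna) + med(-te))`, clamping positive (activated)
#' medians to zero before taking the ratio.  Defined only when at least one
#' clamped median is positive.
#'
#' @param mrna_lfcs background-normalized mRNA log2 fold-changes.
#' @param te_lfcs background-normalized translational-efficiency log2
#'   fold-changes.
#' @return list of class `contribution_result`: `median_mrna_lfc`,
#'   `median_te_lfc`, `frac_decay`, `frac_translation`
#'   (`frac_decay + frac_translation == 1`).
#' @examples
#' contribution_fractions(rep(-0.6, 9), rep(-0.2, 9))$frac_decay  # 0.75
#' @export
contribution_fractions <- function(mrna_lfcs, te_lfcs) {
  med_m <- stats::median(mrna_lfcs)
  med_t <- stats::median(te_lfcs)
  dec <- max(-med_m, 0)
  tra <- max(-med_t, 0)
  if (dec + tra == 0) stop("no net repression: both medians are >= 0")
  if (-med_m < 0 || -med_t < 0)
    message("positive (activated) median clamped to 0 before the ratio")
  structure(list(median_mrna_lfc = med_m, median_te_lfc = med_t,
                 frac_decay = dec / (dec + tra),
                 frac_translation = tra / (dec + tra)),
            class = "contribution_result")
}
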