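## Synthetic data generators.
##
## Counts follow the generative structure the interaction model assumes:
## a shared per-gene expression propensity, per-sample depth factors, and
## planted log2 effects entering assays as
##   RNA    ~ 2^(tx + pt)
##   PRO    ~ 2^(tx)
##   ribo   ~ 2^(tx + pt + te)
##   intron ~ 2^(tx)   (depth-scaled, optionally noisier)
## so tx is transcriptional, pt post-transcriptional and te translational
## regulation.  Counts are NB2 (Var = mu + phi mu^2), drawn as a
## gamma-Poisson mixture which stays exact as phi -> 0.

#' Specification for a count simulation
#'
#' Defaults encode the simulation conditions used throughout the test
#' suite: 3 replicates per (condition, assay) cell, NB dispersion 0.05, a
#' log-normal baseline around 150 counts, and mild library-size variation.
#'
#' @param n_genes number of genes.
#' @param replicates replicates per (condition, assay) cell (default 3).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean (defaults `log(150)`, 1.3).
#' @param dispersion NB dispersion phi, scalar or per-gene (default 0.05).
#' @param libsize_sdlog log-normal sd of per-sample depth factors
#'   (default 0.15).
#' @param tx_lfc,pt_lfc,te_lfc planted log2 effects (length `n_genes` or
#'   scalar 0): transcriptional, post-transcriptional, translational.
#' @param intron_depth depth of the intron matrix relative to PRO-seq
#'   (default 1; e.g. 0.1 = 10x shallower).
#' @param intron_extra_sdlog extra per-observation log-normal noise on the
#'   intron proxy (default 0).
#' @param seed integer RNG seed recorded in the output.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000L, replicates = 3L,
                            baseline_meanlog = log(150),
                            baseline_sdlog = 1.3, dispersion = 0.05,
                            libsize_sdlog = 0.15,
                            tx_lfc = 0, pt_lfc = 0, te_lfc = 0,
                            intron_depth = 1, intron_extra_sdlog = 0,
                            seed = 1L) {
  expand <- function(v) if (length(v) == 1L) rep(v, n_genes) else v
  tx_lfc <- expand(tx_lfc); pt_lfc <- expand(pt_lfc); te_lfc <- expand(te_lfc)
  stopifnot(length(tx_lfc) == n_genes, length(pt_lfc) == n_genes,
            length(te_lfc) == n_genes, all(dispersion >= 0),
            replicates >= 1, intron_depth > 0)
  structure(list(n_genes = as.integer(n_genes),
                 replicates = as.integer(replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, libsize_sdlog = libsize_sdlog,
                 tx_lfc = tx_lfc, pt_lfc = pt_lfc, te_lfc = te_lfc,
                 intron_depth = intron_depth,
                 intron_extra_sdlog = intron_extra_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

rnb <- function(mu, phi) {
  n <- length(mu)
  if (length(phi) == 1L) phi <- rep(phi, n)
  y <- numeric(n)
  pos <- phi > 0
  if (any(pos))
    y[pos] <- stats::rpois(sum(pos),
                           stats::rgamma(sum(pos), shape = 1 / phi[pos],
                                         scale = mu[pos] * phi[pos]))
  if (any(!pos)) y[!pos] <- stats::rpois(sum(!pos), mu[!pos])
  y
}

#' Simulate paired count matrices with planted effects
#'
#' @param spec a [simulation_spec()].
#' @return list: `rna`, `pro`, `ribo`, `intron` ([count_matrix()] each),
#'   `design` (a [sample_design()] covering all assays), and `truth`
#'   (data.frame of planted per-gene effects).  Deterministic in
#'   `spec$seed`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  G <- spec$n_genes; n <- spec$replicates
  genes <- sprintf("gene%04d", seq_len(G))
  set.seed(spec$seed)
  base <- stats::rlnorm(G, spec$baseline_meanlog, spec$baseline_sdlog)
  phi <- spec$dispersion
  effects <- list(rna = spec$tx_lfc + spec$pt_lfc,
                  pro = spec$tx_lfc,
                  ribo = spec$tx_lfc + spec$pt_lfc + spec$te_lfc,
                  intron = spec$tx_lfc)
  out <- list()
  for (k in seq_along(effects)) {
    assay <- names(effects)[k]
    set.seed(spec$seed + 1000L * k)       # fixed per-assay sub-seed
    depth <- stats::rlnorm(2L * n, 0, spec$libsize_sdlog)
    if (assay == "intron") depth <- depth * spec$intron_depth
    treated <- rep(c(FALSE, TRUE), each = n)
    mu <- outer(base, depth) *
      2^(effects[[assay]] %o% as.numeric(treated))
    if (assay == "intron" && spec$intron_extra_sdlog > 0)
      mu <- mu * matrix(stats::rlnorm(length(mu), 0, spec$intron_extra_sdlog),
                        nrow(mu))
    y <- matrix(rnb(mu, rep(phi, length.out = G)[row(mu)]), G)
    colnames(y) <- sprintf("%s_%s_%d", assay,
                           ifelse(treated, "treated", "control"),
                           rep(seq_len(n), 2L))
    rownames(y) <- genes
    out[[assay]] <- count_matrix(y)
  }
  design <- sample_design(data.frame(
    sample_id = unlist(lapply(out, colnames), use.names = FALSE),
    condition = rep(rep(c("control", "treated"), each = n), length(out)),
    assay = rep(names(out), each = 2L * n),
    replicate = rep(seq_len(n), 2L * length(out)),
    stringsAsFactors = FALSE))
  truth <- data.frame(gene_id = genes, baseline = base,
                      tx_lfc = spec$tx_lfc, pt_lfc = spec$pt_lfc,
                      te_lfc = spec$te_lfc, stringsAsFactors = FALSE)
  c(out, list(design = design, truth = truth, spec = spec))
}

#' Simulate transcripts with planted miRNA target sites
#'
#' Builds uniform-random transcripts with region boundaries and plants the
#' requested sites at random positions fully inside their regions.  A
#' transcript is resampled until scanning it recovers exactly the planted
#' truth, so backgrounds are guaranteed free of spurious matches of the
#' planted miRNA's site types.
#'
#' @param n number of transcripts.
#' @param length transcript length in nt (default 500).
#' @param plan data.frame with columns `transcript` (1..n), `site_type`
#'   (one of `8mer`, `7mer-m8`, `7mer-A1`, `g-bulge`) and `region`
#'   (`utr5`/`orf`/`utr3`); empty plan plants nothing.
#' @param motifs motif map from [site_motifs()].
#' @param utr5_frac,orf_frac fractions of the transcript assigned to the
#'   5'UTR and ORF (defaults 0.1 and 0.6; the remainder is 3'UTR).
#' @param seed integer seed.
#' @param max_tries resampling attempts per transcript before erroring
#'   (default 500).
#' @return list: `transcripts` (named list of [transcript_record()]),
#'   `truth` (hit data.frame as from [scan_transcript()], without AU).
#' @export
simulate_transcripts <- function(n, length = 500L,
                                 plan = data.frame(), motifs,
                                 utr5_frac = 0.1, orf_frac = 0.6,
                                 seed = 1L, max_tries = 500L) {
  set.seed(seed)
  utr5_end <- round(utr5_frac * length)
  orf_end <- round((utr5_frac + orf_frac) * length)
  bounds <- list(utr5 = c(0L, utr5_end), orf = c(utr5_end, orf_end),
                 utr3 = c(orf_end, length))
  transcripts <- vector("list", n)
  truth <- list()
  for (i in seq_len(n)) {
    pl <- if (nrow(plan)) plan[plan$transcript == i, , drop = FALSE] else plan
    id <- sprintf("tx%04d", i)
    for (try in seq_len(max_tries)) {
      chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      placed <- data.frame()
      ok <- TRUE
      if (nrow(pl)) {
        occupied <- integer(0)
        for (r in seq_len(nrow(pl))) {
          w <- nchar(motifs[[pl$site_type[r]]])
          b <- bounds[[pl$region[r]]]
          lo <- b[1L]; hi <- b[2L] - w
          if (hi < lo) stop("region too small for site in transcript ", i)
          pos <- NA
          for (t2 in seq_len(50L)) {
            cand <- sample(lo:hi, 1L)
            if (!any((cand:(cand + w - 1L)) %in% occupied)) { pos <- cand; break }
          }
          if (is.na(pos)) { ok <- FALSE; break }
          chars[(pos + 1L):(pos + w)] <- strsplit(motifs[[pl$site_type[r]]],
                                                  "")[[1L]]
          occupied <- c(occupied, pos:(pos + w - 1L))
          placed <- rbind(placed, data.frame(
            gene_id = id, site_type = pl$site_type[r],
            region = pl$region[r], start = pos, end = pos + w,
            stringsAsFactors = FALSE))
        }
      }
      if (!ok) next
      tr <- transcript_record(id, paste(chars, collapse = ""),
                              utr5_end, orf_end)
      hits <- scan_transcript(tr, motifs, au_window = NULL)
      want <- if (nrow(placed))
        placed[order(placed$start), c("site_type", "start", "end")]
      else placed
      got <- hits[, c("site_type", "start", "end"), drop = FALSE]
      rownames(want) <- rownames(got) <- NULL
      if (nrow(got) == nrow(want) &&
          (nrow(got) == 0L || isTRUE(all.equal(want, got)))) {
        transcripts[[i]] <- tr
        if (nrow(placed)) truth[[length(truth) + 1L]] <- placed
        break
      }
    }
    if (is.null(transcripts[[i]]))
      stop("could not pack planted sites into transcript ", i)
  }
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "gene_id")
  truth <- if (length(truth)) do.call(rbind, truth)
  else data.frame(gene_id = character(0), site_type = character(0),
                  region = character(0), start = integer(0),
                  end = integer(0))
  list(transcripts = transcripts, truth = truth)
}

#' Write simulated transcripts as FASTA plus region TSV
#'
#' @param transcripts named list of [transcript_record()].
#' @param fasta_path,regions_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, regions_path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- names(transcripts)
  Biostrings::writeXStringSet(seqs, fasta_path)
  reg <- data.frame(gene_id = names(transcripts),
                    utr5_end = vapply(transcripts, `[[`, integer(1), "utr5_end"),
                    orf_end = vapply(transcripts, `[[`, integer(1), "orf_end"))
  utils::write.table(reg, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, regions = regions_path))
}

#' Simulate peak windows with a planted consensus motif
#'
#' @param n_peaks named integer vector of subset sizes, names from
#'   `up`/`down`/`unchanged`.
#' @param consensus consensus word (DNA) planted at a random position and
#'   strand.
#' @param planted_fraction named fractions in `[0, 1]` per subset.
#' @param width window width (default 150).
#' @param seed integer seed.
#' @return list: `peaks` (a [peak_set()]) and `truth` (logical: planted).
#'   Unplanted windows are resampled until free of the consensus on either
#'   strand.
#' @export
simulate_peaks <- function(n_peaks, consensus, planted_fraction,
                           width = 150L, seed = 1L) {
  stopifnot(all(names(n_peaks) %in% c("up", "down", "unchanged")),
            all(planted_fraction[names(n_peaks)] >= 0),
            all(planted_fraction[names(n_peaks)] <= 1))
  set.seed(seed)
  consensus <- normalize_na(consensus)
  rc <- dna_revcomp(consensus)
  w <- nchar(consensus)
  ids <- character(0); seqs <- character(0); labels <- character(0)
  planted <- logical(0)
  for (s in names(n_peaks)) {
    n <- n_peaks[[s]]
    plant <- seq_len(n) <= round(planted_fraction[[s]] * n)
    plant <- sample(plant)
    for (i in seq_len(n)) {
      repeat {
        chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
        sq <- paste(chars, collapse = "")
        clean <- !grepl(consensus, sq, fixed = TRUE) &&
          !grepl(rc, sq, fixed = TRUE)
        if (clean) break
      }
      if (plant[i]) {
        pos <- sample.int(width - w + 1L, 1L)
        word <- if (stats::runif(1) < 0.5) consensus else rc
        substr(sq, pos, pos + w - 1L) <- word
      }
      ids <- c(ids, sprintf("%s_peak%05d", s, i))
      seqs <- c(seqs, sq); labels <- c(labels, s)
    }
    planted <- c(planted, plant)
  }
  list(peaks = peak_set(ids, seqs, labels, width = width), truth = planted)
}

#' Simulate a genes-by-tissues expression table
#'
#' Log-normal expression with a designated target set reduced by `effect`
#' log2 units in one tissue, emulating depletion of miRNA targets in the
#' tissue where the miRNA is highly expressed.
#'
#' @param n_genes,n_tissues table dimensions (defaults 3000 and 53).
#' @param n_targets number of target genes (default 100).
#' @param specific_tissue column index of the miRNA's home tissue
#'   (default 1).
#' @param effect log2 reduction of targets in that tissue (default 1; 0
#'   gives a null table).
#' @param seed integer seed.
#' @return list: `expr` (matrix with dimnames), `targets` (gene ids),
#'   `tissue` (the specific tissue's column name).
#' @export
simulate_tissue_expression <- function(n_genes = 3000L, n_tissues = 53L,
                                       n_targets = 100L,
                                       specific_tissue = 1L, effect = 1,
                                       seed = 1L) {
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  expr <- matrix(stats::rlnorm(n_genes * n_tissues, log(50), 1),
                 n_genes, n_tissues, dimnames = list(genes, tissues))
  targets <- sample(genes, n_targets)
  expr[targets, specific_tissue] <- expr[targets, specific_tissue] * 2^(-effect)
  list(expr = expr, targets = targets, tissue = tissues[specific_tissue])
}
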