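## Motif and target-site enrichment.
##
## PWM hits are defined by an exact score threshold: log-odds scores are
## integerized (1/1000 granularity by default) and the full null
## distribution of the window score under a 0th-order background is
## computed by dynamic programming over motif positions, so the threshold
## corresponds to an exact tail probability rather than an approximation.

DNA_LETTERS <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param mat w-by-4 matrix of letter probabilities (columns A, C, G, T).
#' @param pseudocount added to every entry before renormalizing rows
#'   (default 0.01), guaranteeing strictly positive probabilities.
#' @param name optional motif name.
#' @return object of class `pwm`.
#' @export
pwm <- function(mat, pseudocount = 0.01, name = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  colnames(mat) <- DNA_LETTERS
  structure(list(mat = mat, width = nrow(mat), pseudocount = pseudocount,
                 name = name %||% "motif"), class = "pwm")
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' other lines are ignored.
#'
#' @param path MEME minimal format file.
#' @param pseudocount passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1L]][1L]
    hdr <- s + grep("letter-probability matrix",
                    lines[(s + 1L):min(s + 10L, length(lines))])[1L]
    if (is.na(hdr)) stop("motif ", name, " lacks a letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    out[[name]] <- pwm(mat, pseudocount = pseudocount, name = name)
  }
  out
}

## Integerized log2-odds score matrix (w x 4) at the given granularity.
pwm_int_scores <- function(p, background, granularity = 1000L) {
  round(log2(sweep(p$mat, 2L, background, "/")) * granularity)
}

#' Exact PWM score threshold for a target p-value
#'
#' Computes, by dynamic programming over motif positions, the exact null
#' distribution of the integerized log2-odds score of a random window drawn
#' from the 0th-order `background`, and returns the smallest integer score
#' whose upper-tail probability is at most `alpha`.  When `alpha` is below
#' the smallest attainable atom the threshold exceeds the maximal score (no
#' window can ever match) and a warning is issued.
#'
#' @param p a [pwm()].
#' @param background length-4 probability vector (A, C, G, T), strictly
#'   positive; default uniform.
#' @param alpha target p-value cutoff in (0, 1), e.g. `1e-5`.
#' @param granularity integer score granularity (default 1000, i.e. scores
#'   rounded to 1/1000 bit).
#' @return list of class `pwm_threshold`: `threshold` (integer score),
#'   `scores` (w x 4 integer matrix), `alpha`, `background`, `granularity`,
#'   `tail_prob` (exact tail probability at the threshold).
#' @export
pwm_score_threshold <- function(p, background = rep(0.25, 4), alpha = 1e-5,
                                granularity = 1000L) {
  stopifnot(alpha > 0, alpha < 1, length(background) == 4L,
            all(background > 0))
  background <- background / sum(background)
  sc <- pwm_int_scores(p, background, granularity)
  dist <- 1
  base <- 0L
  for (i in seq_len(p$width)) {
    row <- sc[i, ]
    lo <- min(row)
    nd <- numeric(length(dist) + max(row) - lo)
    for (l in 1:4) {
      off <- row[l] - lo
      idx <- seq_along(dist) + off
      nd[idx] <- nd[idx] + dist * background[l]
    }
    dist <- nd
    base <- base + lo
  }
  tail <- rev(cumsum(rev(dist)))
  ok <- which(tail <= alpha)
  if (!length(ok)) {
    warning("alpha below the minimal score atom: no hit is possible")
    thr <- base + length(dist)        # max score + 1
    tp <- 0
  } else {
    thr <- base + ok[1L] - 1L
    tp <- tail[ok[1L]]
  }
  structure(list(threshold = thr, scores = sc, alpha = alpha,
                 background = background, granularity = granularity,
                 tail_prob = tp, dist = dist, min_score = base),
            class = "pwm_threshold")
}

## Integer codes 1..4 for ACGT, 5 for anything else (N): scores -> -Inf.
encode_dna <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1L]], DNA_LETTERS)
  x[is.na(x)] <- 5L
  x
}

## Best window score of one strand of one sequence under integer scores.
best_window_score <- function(code, sc) {
  w <- nrow(sc)
  L <- length(code)
  if (L < w) return(-Inf)
  total <- numeric(L - w + 1L)
  for (i in seq_len(w)) {
    v <- c(sc[i, ], -1e9)
    total <- total + v[code[i:(L - w + i)]]
  }
  max(total)
}

#' Flag peaks containing a PWM hit on either strand
#'
#' A peak is flagged when any window position on either strand scores at or
#' above the exact threshold.  `N` bases never contribute to a hit.
#'
#' @param peaks a `peak_set` (see [peak_set()]) or character vector of
#'   window sequences.
#' @param thr a [pwm_score_threshold()].
#' @return logical vector, one per peak.
#' @export
scan_peaks <- function(peaks, thr) {
  seqs <- if (is.data.frame(peaks)) peaks$sequence else peaks
  vapply(seqs, function(s) {
    code <- encode_dna(s)
    if (best_window_score(code, thr$scores) >= thr$threshold) return(TRUE)
    rc <- rev(c(4L, 3L, 2L, 1L, 5L)[code])
    best_window_score(rc, thr$scores) >= thr$threshold
  }, logical(1), USE.NAMES = FALSE)
}

#' Construct a peak set
#'
#' @param peak_id character ids.
#' @param sequence window sequences (nominally 150 nt; shorter windows are
#'   kept but flagged in the `truncated` column).
#' @param label activity-change label per peak: `up`, `down` or
#'   `unchanged`.
#' @param width nominal window width (default 150).
#' @return data.frame of class `peak_set`.
#' @export
peak_set <- function(peak_id, sequence, label, width = 150L) {
  stopifnot(length(peak_id) == length(sequence),
            length(label) == length(sequence))
  if (!all(label %in% c("up", "down", "unchanged")))
    stop("labels must be up/down/unchanged")
  df <- data.frame(peak_id = peak_id, sequence = toupper(sequence),
                   label = label, truncated = nchar(sequence) != width,
                   stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' One-sided binomial enrichment p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)` - the probability of seeing at
#' least `k` flagged peaks in a subset of `n` when the null fraction is
#' `p0`.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n subset size.
#' @param p0 null fraction in (0, 1).
#' @return upper-tail p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly between 0 and 1")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Motif enrichment across peak subsets with a random-peak null
#'
#' For every motif, the null fraction `p0` is the proportion of `n_null`
#' randomly selected peaks (without replacement) containing at least one
#' hit at the exact score threshold; each labeled subset (`up`, `down`) is
#' then tested against it with a one-sided binomial test, and p-values are
#' FDR-adjusted across motifs within each subset.
#'
#' @param peaks a [peak_set()].
#' @param pwms named list of [pwm()] objects.
#' @param n_null size of the random null set (default 10000, capped at the
#'   number of peaks).
#' @param alpha PWM hit p-value cutoff (default 1e-5).
#' @param background length-4 background; default is the 0th-order base
#'   composition of the scanned windows.
#' @param subsets labels to test (default `c("down", "up")`).
#' @param seed integer seed for the null draw.
#' @return data.frame: `motif`, `subset`, `k`, `n`, `p0`, `pvalue`, `fdr`.
#' @export
motif_enrichment_suite <- function(peaks, pwms, n_null = 10000L,
                                   alpha = 1e-5, background = NULL,
                                   subsets = c("down", "up"), seed = 1L) {
  set.seed(seed)
  n_null <- min(n_null, nrow(peaks))
  null_idx <- sample.int(nrow(peaks), n_null)
  if (is.null(background)) {
    comp <- table(factor(unlist(strsplit(peaks$sequence, "")), DNA_LETTERS))
    background <- (as.numeric(comp) + 1) / sum(comp + 1)
  }
  rows <- list()
  for (m in names(pwms)) {
    thr <- pwm_score_threshold(pwms[[m]], background, alpha)
    flag <- scan_peaks(peaks, thr)
    p0 <- mean(flag[null_idx])
    for (s in subsets) {
      in_s <- peaks$label == s
      n <- sum(in_s)
      if (!n) { warning("empty subset '", s, "' skipped"); next }
      k <- sum(flag & in_s)
      pv <- if (p0 <= 0 || p0 >= 1) NA_real_ else binomial_enrichment(k, n, p0)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = m, subset = s, k = k, n = n, p0 = p0, pvalue = pv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (s in unique(out$subset)) {
    i <- out$subset == s
    out$fdr[i] <- bh_adjust(out$pvalue[i])
  }
  out
}

#' Seed-site enrichment in promoter sequences
#'
#' Per promoter, an indicator of at least one canonical seed match (8mer,
#' 7mer-m8 or 7mer-A1 combined) on the given strand; each tested gene set
#' is compared against the fraction among `n_null` randomly selected null
#' promoters with a one-sided binomial test, FDR-adjusted across sets.
#'
#' @param promoters_subset named list of character vectors (one vector of
#'   promoter sequences per tested gene set), or a single character vector.
#' @param promoters_null character vector of null promoter sequences
#'   (nonempty).
#' @param motifs motif map from [site_motifs()].
#' @param n_null null sample size (default 5000, capped at availability).
#' @param seed integer seed.
#' @return data.frame: `set`, `k`, `n`, `p0`, `pvalue`, `fdr`.
#' @export
promoter_site_enrichment <- function(promoters_subset, promoters_null,
                                     motifs, n_null = 5000L, seed = 1L) {
  if (!length(promoters_null)) stop("null promoter set is empty")
  if (!is.list(promoters_subset))
    promoters_subset <- list(subset = promoters_subset)
  set.seed(seed)
  canon <- motifs[intersect(c("8mer", "7mer-m8", "7mer-A1"), names(motifs))]
  has_site <- function(seqs) vapply(seqs, function(s) {
    chars <- strsplit(normalize_na(s), "")[[1L]]
    any(vapply(canon, function(m) length(match_positions(chars, m)) > 0,
               logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  null_idx <- sample.int(length(promoters_null),
                         min(n_null, length(promoters_null)))
  p0 <- mean(has_site(promoters_null[null_idx]))
  rows <- lapply(names(promoters_subset), function(nm) {
    seqs <- promoters_subset[[nm]]
    k <- sum(has_site(seqs))
    pv <- if (p0 <= 0 || p0 >= 1) {
      if (k == 0) 1 else NA_real_
    } else binomial_enrichment(k, length(seqs), p0)
    data.frame(set = nm, k = k, n = length(seqs), p0 = p0, pvalue = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out
}

#' Tissue-specificity rank test for a target gene set
#'
#' For each gene, tissues are ranked by expression (ascending, average
#' ranks for ties); for each tissue, the ranks of the target genes are
#' compared with those of `n_random` randomly sampled eligible genes by a
#' one-sided Wilcoxon rank-sum test (alternative: targets lower), with
#' exact enumeration for small untied groups and the normal approximation
#' with tie and continuity correction otherwise; p-values are BH-adjusted
#' across tissues.  Genes with zero expression in more than half the
#' tissues are excluded first.
#'
#' @param expr genes-by-tissues expression matrix with dimnames.
#' @param targets character vector of target gene ids (nonempty, subset of
#'   the eligible genes).
#' @param n_random number of random comparison genes (default 5000; capped
#'   with a warning).
#' @param seed integer seed.
#' @return data.frame: `tissue`, `pvalue`, `fdr`.
#' @export
tissue_specificity <- function(expr, targets, n_random = 5000L, seed = 1L) {
  if (!length(targets)) stop("target set is empty")
  expr <- as.matrix(expr)
  eligible <- rowSums(expr == 0) <= ncol(expr) / 2
  expr <- expr[eligible, , drop = FALSE]
  missing <- setdiff(targets, rownames(expr))
  if (length(missing))
    stop("target gene(s) not among eligible genes: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  set.seed(seed)
  pool <- setdiff(rownames(expr), targets)
  if (length(pool) < n_random) {
    warning("fewer eligible genes than n_random; using all ", length(pool))
    n_random <- length(pool)
  }
  rand <- sample(pool, n_random)
  ranks <- t(apply(expr, 1L, rank))   # ascending with expression
  pv <- vapply(seq_len(ncol(expr)), function(j) {
    stats::wilcox.test(ranks[targets, j], ranks[rand, j],
                       alternative = "less")$p.value
  }, numeric(1))
  data.frame(tissue = colnames(expr), pvalue = pv, fdr = bh_adjust(pv),
             row.names = NULL, stringsAsFactors = FALSE)
}
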