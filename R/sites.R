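## miRNA seed-match site construction and transcript scanning.
##
## The seed is miRNA positions 2-8 (5'->3').  Target motifs are written
## 5'->3' on the mRNA in DNA alphabet:
##   7mer-m8 : reverse complement of positions 2-8
##   8mer    : 7mer-m8 followed by an A (opposite miRNA position 1)
##   7mer-A1 : reverse complement of positions 2-7 followed by an A
##   g-bulge : 7mer-m8 with a G inserted in the target between the
##             nucleotides pairing miRNA positions 6 and 5 (a bulged
##             target G within the seed duplex; convention documented in
##             the methods vignette)

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "g-bulge")

dna_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

normalize_na <- function(seq) {
  s <- toupper(gsub("U", "T", toupper(seq)))
  if (!grepl("^[ACGTN]*$", s))
    stop("sequence contains characters outside {A,C,G,T,U,N}")
  s
}

#' Build target-site motifs for a mature miRNA
#'
#' @param mirna mature miRNA sequence, 5'->3', RNA or DNA alphabet,
#'   length >= 8.
#' @return named character vector of DNA motifs (5'->3' on the target):
#'   `8mer`, `7mer-m8`, `7mer-A1`, `g-bulge`.
#' @examples
#' site_motifs("UGGAAUGUAAAGAAGUAUGUAU")[["8mer"]]  # miR-1 -> "ACATTCCA"
#' @export
site_motifs <- function(mirna) {
  s <- normalize_na(mirna)
  if (nchar(s) < 8L) stop("miRNA must be at least 8 nt")
  if (grepl("N", s)) stop("miRNA sequence may not contain N")
  seed28 <- substr(s, 2L, 8L)
  seed27 <- substr(s, 2L, 7L)
  m7m8 <- dna_revcomp(seed28)
  c(`8mer` = paste0(m7m8, "A"),
    `7mer-m8` = m7m8,
    `7mer-A1` = paste0(dna_revcomp(seed27), "A"),
    `g-bulge` = paste0(substr(m7m8, 1L, 3L), "G", substr(m7m8, 4L, 7L)))
}

#' Construct a transcript record with region boundaries
#'
#' Coordinates are 0-based half-open: 5'UTR = `[0, utr5_end)`,
#' ORF = `[utr5_end, orf_end)`, 3'UTR = `[orf_end, length)`.
#'
#' @param gene_id gene identifier.
#' @param sequence transcript sequence (RNA or DNA; stored as DNA,
#'   uppercase).
#' @param utr5_end,orf_end region boundaries, `0 <= utr5_end <= orf_end <=
#'   nchar(sequence)`.
#' @return list of class `transcript_record`.
#' @export
transcript_record <- function(gene_id, sequence, utr5_end, orf_end) {
  s <- normalize_na(sequence)
  utr5_end <- as.integer(utr5_end); orf_end <- as.integer(orf_end)
  if (!(0 <= utr5_end && utr5_end <= orf_end && orf_end <= nchar(s)))
    stop("require 0 <= utr5_end <= orf_end <= sequence length")
  structure(list(gene_id = gene_id, sequence = s,
                 utr5_end = utr5_end, orf_end = orf_end),
            class = "transcript_record")
}

#' Read transcripts from FASTA plus a region table
#'
#' @param fasta_path FASTA of transcript sequences (names = gene ids).
#' @param regions_path TSV with columns `gene_id`, `utr5_end`, `orf_end`.
#' @return named list of [transcript_record()]s (FASTA order).
#' @export
read_transcripts <- function(fasta_path, regions_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  reg <- utils::read.delim(regions_path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  m <- match(ids, reg$gene_id)
  if (anyNA(m)) stop("no region annotation for: ", ids[is.na(m)][1L])
  out <- lapply(seq_along(seqs), function(i)
    transcript_record(ids[i], as.character(seqs[[i]]),
                      reg$utr5_end[m[i]], reg$orf_end[m[i]]))
  stats::setNames(out, ids)
}

## All match start positions (0-based) of a fixed motif, overlapping allowed.
## N in the subject never matches because motifs are pure ACGT.
match_positions <- function(seq_chars, motif) {
  L <- length(seq_chars)
  w <- nchar(motif)
  if (L < w) return(integer(0))
  mc <- strsplit(motif, "")[[1L]]
  ok <- rep(TRUE, L - w + 1L)
  for (k in seq_len(w)) ok <- ok & seq_chars[k:(L - w + k)] == mc[k]
  which(ok) - 1L
}

#' Scan a transcript for miRNA target sites
#'
#' Exact matches on the given strand only, with overlap precedence
#' 8mer > 7mer-m8 > 7mer-A1 > g-bulge: a lower-priority hit wholly contained
#' in an already reported higher-priority hit is suppressed.  Each retained
#' hit is assigned the region that fully contains it; hits spanning a region
#' boundary are dropped (their number is recorded in the
#' `n_boundary_dropped` attribute).
#'
#' @param tr a [transcript_record()].
#' @param motifs motif map from [site_motifs()].
#' @param au_window total local-AU window (nt) passed to [local_au()];
#'   `NULL` skips AU scoring.
#' @return data.frame of hits: `gene_id`, `site_type`, `region`, `start`,
#'   `end` (0-based half-open), `local_au`.
#' @export
scan_transcript <- function(tr, motifs, au_window = 30L) {
  stopifnot(inherits(tr, "transcript_record"))
  chars <- strsplit(tr$sequence, "")[[1L]]
  types <- intersect(SITE_TYPES, names(motifs))
  starts <- integer(0); ends <- integer(0); type <- character(0)
  for (tp in types) {
    w <- nchar(motifs[[tp]])
    pos <- match_positions(chars, motifs[[tp]])
    if (!length(pos)) next
    keep <- rep(TRUE, length(pos))
    if (length(starts)) {
      for (i in seq_along(pos))
        keep[i] <- !any(pos[i] >= starts & pos[i] + w <= ends)
    }
    starts <- c(starts, pos[keep]); ends <- c(ends, pos[keep] + w)
    type <- c(type, rep(tp, sum(keep)))
  }
  if (!length(starts)) {
    out <- data.frame(gene_id = character(0), site_type = character(0),
                      region = character(0), start = integer(0),
                      end = integer(0), local_au = numeric(0))
    attr(out, "n_boundary_dropped") <- 0L
    return(out)
  }
  region <- ifelse(ends <= tr$utr5_end, "utr5",
            ifelse(starts >= tr$utr5_end & ends <= tr$orf_end, "orf",
            ifelse(starts >= tr$orf_end, "utr3", NA_character_)))
  dropped <- sum(is.na(region))
  keep <- !is.na(region)
  out <- data.frame(gene_id = rep(tr$gene_id, sum(keep)),
                    site_type = type[keep],
                    region = region[keep], start = starts[keep],
                    end = ends[keep], local_au = rep(NA_real_, sum(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(au_window) && nrow(out))
    out$local_au <- vapply(seq_len(nrow(out)), function(i)
      local_au(tr, out[i, ], window = au_window), numeric(1))
  attr(out, "n_boundary_dropped") <- dropped
  out
}

#' Local AU content around a site
#'
#' Fraction of A/T among the `window/2` nucleotides flanking each side of
#' the hit (the site itself excluded).  Flanks are truncated at the
#' transcript ends and the denominator is the number of bases actually
#' available; with no flanking bases at all the value is `NaN` (flagged by
#' a warning).
#'
#' @param tr a [transcript_record()].
#' @param hit one row of a hit data.frame (needs `start`, `end`).
#' @param window even total window size (default 30).
#' @return fraction in `[0, 1]`, or `NaN` when undefined.
#' @export
local_au <- function(tr, hit, window = 30L) {
  stopifnot(window %% 2 == 0, window > 0)
  half <- window %/% 2L
  L <- nchar(tr$sequence)
  up <- seq.int(max(1L, hit$start - half + 1L), hit$start)      # 1-based
  up <- up[up >= 1L & up <= hit$start]
  dn <- seq.int(hit$end + 1L, min(L, hit$end + half))
  dn <- dn[dn > hit$end & dn <= L]
  idx <- c(if (hit$start > 0L) up, if (hit$end < L) dn)
  if (!length(idx)) {
    warning("site has no flanking bases; local AU undefined")
    return(NaN)
  }
  chars <- strsplit(tr$sequence, "")[[1L]][idx]
  mean(chars %in% c("A", "T"))
}

#' Per-gene site counts in a region
#'
#' @param hits hit data.frame from [scan_transcript()] (possibly several
#'   transcripts row-bound).
#' @param region one of `"utr5"`, `"orf"`, `"utr3"`.
#' @return named integer vector of per-gene counts (genes with >= 1 hit in
#'   the region).
#' @export
count_sites <- function(hits, region) {
  stopifnot(region %in% c("utr5", "orf", "utr3"))
  h <- hits[hits$region == region, , drop = FALSE]
  tab <- table(h$gene_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Partition hits into quartiles of local AU content
#'
#' Boundaries are the empirical 25/50/75 percentiles (linear interpolation);
#' a hit whose AU value equals a boundary goes to the lower quartile, so
#' fully tied inputs all land in quartile 1.
#'
#' @param hits hit data.frame with a defined `local_au` column (>= 4 rows).
#' @return list with `groups` (list of four data.frames) and `boundaries`
#'   (the three percentiles).
#' @export
au_quartile_partition <- function(hits) {
  au <- hits$local_au
  ok <- is.finite(au)
  if (sum(ok) < 4L) stop("need at least 4 hits with defined local AU")
  hits <- hits[ok, , drop = FALSE]; au <- au[ok]
  b <- stats::quantile(au, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  qi <- 1L + (au > b[1L]) + (au > b[2L]) + (au > b[3L])
  list(groups = lapply(1:4, function(k) hits[qi == k, , drop = FALSE]),
       boundaries = b)
}

#' Write a site-hit table as TSV
#'
#' Adds 1-based inclusive coordinate columns (`start1`, `end1`) alongside
#' the 0-based half-open `start`/`end`.
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @param cfg optional [carp_config()] for the provenance header.
#' @return `path`, invisibly.
#' @export
write_sites <- function(hits, path, cfg = NULL) {
  hits$start1 <- hits$start + 1L
  hits$end1 <- hits$end
  write_result_table(hits, path, cfg)
}
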