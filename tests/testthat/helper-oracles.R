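# Independent oracles used across test files.  These deliberately avoid the
# package's internal scanning/statistics code paths.

# Overlap-aware site scan via perl lookahead regexes, with the same
# precedence contract (8mer > 7mer-m8 > 7mer-A1 > g-bulge, containment
# suppression, full-containment region assignment).
oracle_scan <- function(seqstr, motifs, utr5_end, orf_end) {
  prio <- c("8mer", "7mer-m8", "7mer-A1", "g-bulge")
  hits <- data.frame()
  for (tp in intersect(prio, names(motifs))) {
    m <- gregexpr(paste0("(?=", motifs[[tp]], ")"), seqstr, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    st <- as.integer(m) - 1L
    hits <- rbind(hits, data.frame(site_type = tp, start = st,
                                   end = st + nchar(motifs[[tp]]),
                                   prio = match(tp, prio)))
  }
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$prio, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    higher <- which(keep & hits$prio < hits$prio[i])
    if (length(higher) &&
        any(hits$start[i] >= hits$start[higher] &
            hits$end[i] <= hits$end[higher]))
      keep[i] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  L <- nchar(seqstr)
  region <- ifelse(hits$end <= utr5_end, "utr5",
            ifelse(hits$start >= utr5_end & hits$end <= orf_end, "orf",
            ifelse(hits$start >= orf_end, "utr3", NA)))
  hits$region <- region
  hits <- hits[!is.na(region), c("site_type", "region", "start", "end")]
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Random DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Random probability PWM of a given width.
random_pwm <- function(w) {
  m <- matrix(stats::rgamma(4 * w, 1), w, 4)
  carp::pwm(m / rowSums(m))
}

# A tiny simulation wrapper shared by pipeline tests.
quick_sim <- function(..., seed = 1L) {
  simulate_counts(simulation_spec(..., seed = seed))
}
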