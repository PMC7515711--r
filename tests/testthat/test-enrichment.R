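test_that("PWM construction validates and normalizes probability rows", {
  m <- matrix(c(0.97, 0.01, 0.01, 0.01), 1)
  p <- pwm(m)
  expect_equal(sum(p$mat), 1, tolerance = 1e-9)
  expect_true(all(p$mat > 0))
  expect_error(pwm(matrix(1, 2, 3)), "4 columns")
  expect_error(pwm(matrix(-1, 1, 4)), "non-negative")
})

test_that("MEME minimal files parse into PWMs", {
  f <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF motifA", "letter-probability matrix: alength= 4 w= 3 nsites= 20",
               " 0.97 0.01 0.01 0.01", " 0.01 0.97 0.01 0.01",
               " 0.25 0.25 0.25 0.25", "",
               "MOTIF motifB", "letter-probability matrix: alength= 4 w= 2",
               " 0.01 0.01 0.01 0.97", " 0.01 0.01 0.97 0.01"), f)
  ms <- read_meme(f)
  expect_named(ms, c("motifA", "motifB"))
  expect_equal(ms$motifA$width, 3L)
  expect_equal(ms$motifB$width, 2L)
  expect_equal(unname(which.max(ms$motifB$mat[1, ])), 4L)  # T
})

test_that("exact DP threshold matches exhaustive enumeration", {
  # width-1 motif identical to the background: all scores 0, tail prob 1
  flat <- pwm(matrix(0.25, 1, 4), pseudocount = 0)
  # the whole mass sits on score 0, so no tail is <= 0.5: flagged
  expect_warning(thr <- pwm_score_threshold(flat, alpha = 0.5),
                 "no hit is possible")
  expect_equal(unique(as.vector(thr$scores)), 0)
  expect_equal(sum(thr$dist), 1, tolerance = 1e-12)
  # width-4 random motif, uniform background: enumerate all 256 words
  set.seed(61)
  p4 <- random_pwm(4)
  thr4 <- pwm_score_threshold(p4, alpha = 0.01)
  words <- expand.grid(1:4, 1:4, 1:4, 1:4)
  scores <- apply(words, 1, function(w)
    sum(thr4$scores[cbind(1:4, as.integer(w))]))
  for (s in unique(scores)) {
    dp_tail <- sum(thr4$dist[seq_along(thr4$dist) + thr4$min_score - 1 >= s])
    expect_equal(dp_tail, mean(scores >= s), tolerance = 1e-9)
  }
  expect_equal(mean(scores >= thr4$threshold), thr4$tail_prob,
               tolerance = 1e-12)
  expect_lte(thr4$tail_prob, 0.01)
  # near-deterministic width-4 motif at alpha 1e-5: consensus atom is
  # 1/256 > 1e-5, so no admissible hit exists
  det <- pwm(diag(4), pseudocount = 1e-4)
  expect_warning(thr_det <- pwm_score_threshold(det, alpha = 1e-5),
                 "no hit is possible")
  expect_gt(thr_det$threshold, sum(apply(thr_det$scores, 1, max)))
})

test_that("peak scanning matches a naive rescoring oracle and strand symmetry", {
  set.seed(62)
  p <- random_pwm(6)
  thr <- pwm_score_threshold(p, alpha = 0.005)
  seqs <- vapply(1:500, function(i) random_dna(60), character(1))
  flags <- scan_peaks(seqs, thr)
  # naive oracle: rescore every offset of both strands directly
  naive_flag <- function(s) {
    code <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
    rc <- rev(5 - code)
    hit <- function(cd) {
      if (anyNA(cd)) return(FALSE)
      any(vapply(seq_len(length(cd) - 5L), function(o)
        sum(thr$scores[cbind(1:6, cd[o:(o + 5L)])]) >= thr$threshold,
        logical(1)))
    }
    hit(code) || hit(rc)
  }
  expect_equal(flags, vapply(seqs, naive_flag, logical(1), USE.NAMES = FALSE))
  expect_gt(mean(flags), 0)        # threshold chosen so some windows hit
  # reverse-complementing every window leaves the flags unchanged
  rcseqs <- vapply(seqs, function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
  expect_equal(scan_peaks(rcseqs, thr), flags)
  # planted consensus is found; all-N windows never hit
  cons <- paste(c("A", "C", "G", "T")[apply(p$mat, 1, which.max)],
                collapse = "")
  planted <- paste0(random_dna(20), cons, random_dna(20))
  expect_true(any(scan_peaks(planted, thr)))
  expect_false(scan_peaks(strrep("N", 60), thr))
})

test_that("binomial tail equals pmf summation", {
  expect_equal(binomial_enrichment(0, 10, 0.3), 1)
  expect_equal(binomial_enrichment(10, 10, 0.5), 0.0009765625)
  expect_equal(binomial_enrichment(2, 5, 0.2),
               1 - 0.8^5 - 5 * 0.2 * 0.8^4, tolerance = 1e-12)
  set.seed(63)
  for (i in 1:20) {
    n <- sample(1:20, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    oracle <- sum(exp(lchoose(n, k:n) + (k:n) * log(p0) +
                        (n - (k:n)) * log(1 - p0)))
    expect_equal(binomial_enrichment(k, n, p0), oracle, tolerance = 1e-10)
  }
  expect_error(binomial_enrichment(1, 2, 0), "strictly between")
  expect_error(binomial_enrichment(1, 2, 1), "strictly between")
})

test_that("motif enrichment flags planted subsets and is deterministic", {
  set.seed(64)
  cons <- "TTACGTCAGC"
  sim <- simulate_peaks(c(down = 200, unchanged = 2000), cons,
                        c(down = 0.5, unchanged = 0.01), seed = 65)
  pm <- pwm(diag(4)[match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")), ],
            pseudocount = 0.001)
  tab <- motif_enrichment_suite(sim$peaks, list(planted = pm),
                                n_null = 2000, alpha = 1e-5,
                                background = rep(0.25, 4),
                                subsets = "down", seed = 66)
  expect_lt(tab$pvalue[tab$motif == "planted"], 1e-10)
  expect_gte(tab$k[1], 80)
  tab2 <- motif_enrichment_suite(sim$peaks, list(planted = pm),
                                 n_null = 2000, alpha = 1e-5,
                                 background = rep(0.25, 4),
                                 subsets = "down", seed = 66)
  expect_identical(tab, tab2)
})

test_that("null-drawn subsets give roughly uniform enrichment p-values", {
  set.seed(67)
  seqs <- vapply(1:600, function(i) random_dna(150), character(1))
  labels <- rep("unchanged", 600)
  labels[sample.int(600, 120)] <- "down"   # subset drawn from the same null
  peaks <- peak_set(sprintf("p%03d", 1:600), seqs, labels)
  pwms <- lapply(1:120, function(i) random_pwm(7))
  names(pwms) <- sprintf("m%03d", 1:120)
  tab <- motif_enrichment_suite(peaks, pwms, n_null = 600, alpha = 1e-3,
                                subsets = "down", seed = 68)
  pv <- tab$pvalue[!is.na(tab$pvalue)]
  expect_gt(length(pv), 100)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
  expect_lt(mean(pv < 0.05), 0.12)
})

test_that("promoter seed-site enrichment matches the closed form", {
  motifs <- site_motifs("UGGAAUGUAAAGAAGUAUGUAU")
  # no promoter contains any site
  clean <- rep(strrep("C", 100), 10)
  r0 <- promoter_site_enrichment(clean, clean, motifs, seed = 69)
  expect_equal(r0$k, 0)
  expect_equal(r0$pvalue, 1)
  # all 20 subset promoters planted, null fraction exactly 0.1
  set.seed(70)
  base <- vapply(1:500, function(i) paste0(strrep("C", 40), strrep("G", 60)),
                 character(1))
  planted <- paste0(strrep("C", 40), "ACATTCCA", strrep("G", 52))
  null_pool <- base
  null_pool[1:50] <- planted
  subset <- rep(planted, 20)
  r <- promoter_site_enrichment(subset, null_pool, motifs, n_null = 500,
                                seed = 71)
  expect_equal(r$p0, 0.1)
  expect_equal(r$pvalue, 0.1^20)
  expect_error(promoter_site_enrichment(subset, character(0), motifs),
               "empty")
})

test_that("tissue specificity detects target depletion in the home tissue", {
  sim <- simulate_tissue_expression(n_genes = 1200, n_tissues = 20,
                                    n_targets = 60, specific_tissue = 3,
                                    effect = 1.5, seed = 72)
  expect_warning(
    res <- tissue_specificity(sim$expr, sim$targets, n_random = 5000,
                              seed = 73),
    "fewer eligible")
  expect_equal(res$tissue[which.min(res$fdr)], sim$tissue)
  expect_lt(res$fdr[res$tissue == sim$tissue], 0.05)
  # null table: most tissues non-significant
  sim0 <- simulate_tissue_expression(n_genes = 1200, n_tissues = 20,
                                     n_targets = 60, effect = 0, seed = 74)
  res0 <- suppressWarnings(tissue_specificity(sim0$expr, sim0$targets,
                                              n_random = 1000, seed = 75))
  expect_gte(mean(res0$pvalue >= 0.05), 0.9)
  expect_error(tissue_specificity(sim$expr, character(0)), "empty")
})

test_that("small-group rank test takes the exact enumeration path", {
  # 6 genes over 10 tissues, constructed so that in tissue 1 the targets
  # hold per-gene ranks 1, 2, 3 and the comparison genes ranks 8, 9, 10:
  # one-sided exact p = 1 / choose(6, 3) = 0.05
  t1_rank <- c(1, 2, 3, 8, 9, 10)
  expr <- t(vapply(t1_rank, function(r) {
    others <- setdiff(1:10, r)
    c(r, others)                      # tissue 1 value has rank r
  }, numeric(10)))
  dimnames(expr) <- list(paste0("g", 1:6), paste0("t", 1:10))
  # ties in the other tissues route those to the approximation with a
  # warning; tissue 1 itself is untied and exact
  res <- suppressWarnings(
    tissue_specificity(expr, paste0("g", 1:3), n_random = 3, seed = 77))
  expect_equal(res$pvalue[res$tissue == "t1"], 0.05)
})

test_that("normal-approximation rank test stays near exact enumeration", {
  set.seed(78)
  for (sizes in list(c(8, 8), c(8, 12), c(10, 10), c(12, 12))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2])
    approx_p <- wilcox.test(x, y, alternative = "less", exact = FALSE,
                            correct = TRUE)$p.value
    # exact tail via the Mann-Whitney U distribution
    U <- sum(outer(x, y, ">"))
    exact_p <- pwilcox(U, sizes[1], sizes[2])
    expect_lte(abs(approx_p - exact_p), 0.01)
  }
})
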