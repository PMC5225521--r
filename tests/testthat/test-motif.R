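test_that("WPCM parsing validates structure and round-trips", {
  f <- tempfile(fileext = ".wpcm")
  writeLines(c(">ONECOL 1", "4 0 0 0"), f)
  wp <- read_wpcm(f)
  expect_equal(wp$w, 1L)
  expect_equal(wp$W, 4)
  expect_equal(unname(wp$counts[, 1]), c(4, 0, 0, 0))

  writeLines(c(">BAD 3", "4 0 0 0", "0 4 0 0"), f)
  expect_error(read_wpcm(f), "3 positions but 2 rows")
  writeLines(c(">BAD 1", "4 0 0"), f)
  expect_error(read_wpcm(f), "malformed")
  writeLines(c(">BAD 2", "4 0 0 0", "1 1 1 2"), f)
  expect_error(read_wpcm(f), "column sums")
  writeLines(c(">BAD 1", "-1 5 0 0"), f)
  expect_error(read_wpcm(f), "negative")

  for (name in c("SYN_GTCT.wpcm", "SYN_RAND10.wpcm")) {
    wp <- read_wpcm(motif_file(name))
    f2 <- tempfile(fileext = ".wpcm")
    write_wpcm(wp, f2)
    back <- read_wpcm(f2)
    expect_equal(back$counts, wp$counts, tolerance = 1e-9)
    expect_equal(back$motif_id, wp$motif_id)
  }
})

test_that("PWM cells follow the log-odds formula with pseudocount ln(W)", {
  wp <- dhsreg:::new_wpcm("m", matrix(c(4, 0, 0, 0), 4, 1,
                          dimnames = list(c("A", "C", "G", "T"), NULL)))
  pw <- build_pwm(wp, uniform_q)
  a <- log(4)
  expect_equal(pw$a, a)
  expect_equal(unname(pw$S["A", 1]), log((4 + a * 0.25) / ((4 + a) * 0.25)),
               tolerance = 1e-12)
  expect_equal(unname(pw$S["A", 1]), 1.1718, tolerance = 1e-4)
  expect_equal(unname(pw$S["C", 1]), -1.3573, tolerance = 1e-4)

  # counts proportional to background give zero scores
  wp2 <- dhsreg:::new_wpcm("flat", matrix(rep(c(2, 2, 2, 2), 3), 4, 3,
                           dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(max(abs(build_pwm(wp2, uniform_q)$S)), 0)

  wp3 <- dhsreg:::new_wpcm("tiny", matrix(c(0.25, 0.25, 0.25, 0.25), 4, 1,
                           dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_error(build_pwm(wp3, uniform_q), "exceed 1")
})

test_that("threshold calibration matches enumeration and edge rules", {
  pw <- build_pwm(consensus_wpcm("CA", W = 8), uniform_q)
  # p = 1: minimal achievable score (up to the discretization band)
  expect_equal(score_threshold(pw, p = 1), sum(apply(pw$S, 2, min)),
               tolerance = 2e-4)
  # p = 1/16 with uniform background on a 2-mer: only the best word
  expect_equal(score_threshold(pw, p = 0.0625),
               max(outer(pw$S[, 1], pw$S[, 2], "+")), tolerance = 2e-4)
  expect_warning(t_inf <- score_threshold(pw, p = 1e-9), "\\+Inf")
  expect_equal(t_inf, Inf)
})

test_that("threshold is monotone non-increasing in p", {
  pw <- build_pwm(read_wpcm(motif_file("SYN_RAND5.wpcm")), uniform_q)
  ps <- c(0.001, 0.01, 0.05, 0.2, 0.5, 1)
  ts <- vapply(ps, function(p) score_threshold(pw, p = p), numeric(1))
  expect_true(all(diff(ts) <= 1e-12))
})

test_that("DP score distribution equals brute-force enumeration (w <= 6)", {
  q <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (name in c("SYN_GTCT.wpcm", "SYN_RAND5.wpcm", "SYN_CAGACA.wpcm",
                 "SYN_GGCGCC.wpcm")) {
    pw <- build_pwm(read_wpcm(motif_file(name)), q)
    dp <- pwm_score_distribution(pw, q)
    en <- enum_score_distribution(pw, q)
    expect_equal(dp$score, en$score, tolerance = 1e-9)
    dp_tail <- enum_tail(dp); en_tail <- enum_tail(en)
    expect_lt(max(abs(dp_tail$tail - en_tail$tail)), 1e-8)
  }
})

test_that("scanning reports both strands in forward coordinates", {
  zero <- dhsreg:::new_wpcm("z", matrix(2, 4, 2,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  pz <- build_pwm(zero, uniform_q)       # all-zero score matrix
  hits <- scan_pwm(c(s = "ACGTA"), pz, threshold = 0)
  expect_equal(sort(unique(hits$start)), 0:3)
  expect_equal(nrow(hits), 8L)           # every offset on both strands

  # ambiguous base suppresses windows containing it
  hits_n <- scan_pwm(c(s = "ACNTA"), pz, threshold = 0)
  expect_false(any(hits_n$start %in% 1:2))

  # shorter than the motif: zero hits, no error
  expect_equal(nrow(scan_pwm(c(s = "A"), pz, 0)), 0L)

  pw <- build_pwm(consensus_wpcm("GTCT", W = 12), uniform_q)
  thr <- score_threshold(pw, p = 0.01)
  hits <- scan_pwm(c(s = "AAGTCTAGACA"), pw, thr)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 2L)            # GTCT at 0-based offset 2
  # AGAC at forward offset 6 is a reverse-strand GTCT match
  rev <- hits[hits$strand == "-", ]
  expect_equal(rev$start, 6L)
})

test_that("planted consensus occurrences are recovered by scanning", {
  a <- generate_annotation(20, 1, 1e6, seed = 21)
  p <- generate_promoters(a, "CAGACA", 2, 0, gc = 0.41, seed = 22,
                          fg_genes = a$genes$gene_id)
  pw <- build_pwm(consensus_wpcm("CAGACA", W = 18),
                  background_frequencies(p$sequences))
  thr <- score_threshold(pw, p = 0.001)
  hits <- scan_pwm(p$sequences, pw, thr)
  pos <- p$truth$motif_positions
  found <- merge(pos, hits, by.x = c("sequence_id", "offset"),
                 by.y = c("sequence_id", "start"))
  expect_equal(nrow(found), nrow(pos))
})

test_that("scan of the reverse complement mirrors the hit set", {
  pw <- build_pwm(read_wpcm(motif_file("SYN_RAND5.wpcm")), uniform_q)
  thr <- score_threshold(pw, p = 0.05)
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_pwm(c(x = s), pw, thr)
  h2 <- scan_pwm(c(x = rc), pw, thr)
  L <- nchar(s)
  mirrored <- data.frame(start = L - h1$end,
                         strand = ifelse(h1$strand == "+", "-", "+"),
                         score = h1$score)
  o1 <- order(mirrored$start, mirrored$strand)
  o2 <- order(h2$start, h2$strand)
  expect_equal(mirrored$start[o1], h2$start[o2])
  expect_equal(mirrored$strand[o1], h2$strand[o2])
  expect_equal(mirrored$score[o1], h2$score[o2])
})

test_that("adding a constant to one column shifts scores, not hit sets", {
  pw <- build_pwm(read_wpcm(motif_file("SYN_RAND5.wpcm")), uniform_q)
  thr <- score_threshold(pw, p = 0.02)
  set.seed(24)
  s <- c(x = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = ""))
  h1 <- scan_pwm(s, pw, thr)
  pw2 <- pw
  cshift <- 0.8
  pw2$S[, 3] <- pw2$S[, 3] + cshift
  thr2 <- score_threshold(pw2, p = 0.02)
  expect_equal(thr2, thr + cshift, tolerance = 2e-4)
  h2 <- scan_pwm(s, pw2, thr + cshift)
  expect_equal(h2$start, h1$start)
  expect_equal(h2$strand, h1$strand)
  expect_equal(h2$score, h1$score + cshift, tolerance = 1e-10)
})

test_that("IUPAC consensus search covers wildcards and reverse strand", {
  occ <- find_consensus(c(s1 = "AGTCTA"), "GTCT")
  expect_equal(occ$start, 1L)
  occ2 <- find_consensus(c(s1 = "TTGCCGACGCTT"), "GCCGNCGC")
  expect_equal(nrow(occ2), 1L)
  expect_equal(occ2$start, 2L)
  # CGCC found as reverse complement of GGCG
  occ3 <- find_consensus(c(s1 = "AAGGCGAA"), "CGCC")
  expect_equal(occ3$strand, "-")
  expect_equal(occ3$start, 2L)
  expect_equal(occ3$end, 6L)
})
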