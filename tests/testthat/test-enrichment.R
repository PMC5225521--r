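test_that("foreground/background split keeps shared-promoter DHSs foreground", {
  assign <- data.frame(
    peak_id = c("p1", "p2", "p3", "p3", "p4", "p5"),
    gene_id = c("g1", "g2", "g2", "g3", "g4", "g5"),
    stringsAsFactors = FALSE)
  sp <- build_background(assign, upregulated = c("g2"))
  expect_setequal(sp$foreground$peak_id, c("p2", "p3"))  # p3 shared -> fg
  expect_setequal(sp$background$peak_id, c("p1", "p4", "p5"))

  # empty upregulated set: everything is background
  sp0 <- build_background(assign, upregulated = character(0))
  expect_equal(nrow(sp0$foreground), 0L)
  expect_setequal(sp0$background$peak_id, c("p1", "p2", "p3", "p4", "p5"))

  expect_error(build_background(assign, unique(assign$gene_id)),
               "empty background")
})

test_that("expected sites and enrichment ratio follow the length scaling", {
  expect_equal(expected_sites(10, 1000, 500), 5.0)
  expect_equal(expected_sites(7, 800, 800), 7)
  expect_equal(expected_sites(0, 1000, 500), 0)
  expect_error(expected_sites(5, 0, 100), "> 0")

  expect_equal(enrichment_ratio(8, 8), 1.0)
  expect_error(enrichment_ratio(3, 0), "undefined")
  # scale invariance in the lengths
  expect_equal(enrichment_ratio(12, expected_sites(30, 3000, 1200)),
               enrichment_ratio(12, expected_sites(30, 30000, 12000)))
})

test_that("printed enrichment-table arithmetic is internally consistent", {
  tab <- read.delim(system.file("extdata", "tfbs_enrichment_reported.tsv",
                                package = "dhsreg"))
  expect_equal(nrow(tab), 30L)
  direct <- round_half_up(
    enrichment_ratio(tab$observed_sites, tab$expected_sites), 2)
  exact <- direct == tab$ratio
  # most rows reproduce at printed precision from the printed pair
  expect_gte(sum(exact), 17)
  expect_true(all(exact[tab$tf_name %in%
                        c("MBD2", "HIF1A", "CBFB", "TFAP2A")]))
  # the rest are consistent with an expected value that was rounded to one
  # decimal after the printed ratio was formed: the ratio interval implied
  # by expected +/- 0.05 must meet the printed ratio +/- half a ratio ulp
  for (i in which(!exact)) {
    r_hi <- tab$observed_sites[i] / (tab$expected_sites[i] - 0.05)
    r_lo <- tab$observed_sites[i] / (tab$expected_sites[i] + 0.05)
    expect_lt(tab$ratio[i] - 0.005, r_hi + 1e-12)
    expect_gt(tab$ratio[i] + 0.005, r_lo - 1e-12)
  }
})

test_that("full enrichment recovers a planted foreground motif", {
  a <- generate_annotation(60, 1, 3e6, seed = 31)
  fg <- a$genes$gene_id[1:12]
  p <- generate_promoters(a, "CAGACA", planted_rate_fg = 4,
                          planted_rate_bg = 0.4, gc = 0.41, seed = 32,
                          fg_genes = fg)
  seqs <- as.character(p$sequences)
  enr <- tfbs_enrichment(seqs[fg], seqs[setdiff(names(seqs), fg)],
                         build_pwm(consensus_wpcm("CAGACA", W = 18),
                                   background_frequencies(seqs)))
  expect_gt(enr$ratio, 2)
  expect_equal(enr$foreground_length, 12 * 2000)
})

test_that("candidate selection demands opposite enrichment plus expression", {
  ea <- data.frame(motif_id = c("m1", "m2", "m3", "m4"),
                   ratio = c(1.5, 1.5, 0.7, 2.0))
  eb <- data.frame(motif_id = c("m1", "m2", "m3", "m4"),
                   ratio = c(0.8, 1.2, 1.4, 0.9))
  expr <- data.frame(motif_id = c("m1", "m2", "m3", "m4"),
                     reads_a = c(500, 500, 500, 0),
                     reads_b = c(10, 10, 500, 10))
  sel <- select_candidates(ea, eb, expr, min_reads = 50)
  # m2 not depleted in B; m4 unexpressed in A; m1 qualifies for A, m3 for B
  expect_equal(sel$a$motif_id, "m1")
  expect_equal(sel$b$motif_id, "m3")
  expect_equal(sel$b$ratio, 1.4)
})

test_that("planted asymmetric enrichment ranks first among candidates", {
  a <- generate_annotation(40, 1, 3e6, seed = 33)
  fg <- a$genes$gene_id[1:10]
  bg <- setdiff(a$genes$gene_id, fg)
  # line A promoters carry CAGACA in the foreground, line B does not
  pA <- generate_promoters(a, "CAGACA", 4, 0.3, gc = 0.41, seed = 34,
                           fg_genes = fg)
  pB <- generate_promoters(a, "CAGACA", 0.1, 0.6, gc = 0.41, seed = 35,
                           fg_genes = fg)
  q <- background_frequencies(pA$sequences)
  pwms <- list(build_pwm(consensus_wpcm("CAGACA", W = 18), q),
               build_pwm(consensus_wpcm("GGCGCC", W = 20), q))
  sa <- as.character(pA$sequences); sb <- as.character(pB$sequences)
  ea <- tfbs_enrichment(sa[fg], sa[bg], pwms, q = q)
  eb <- tfbs_enrichment(sb[fg], sb[bg], pwms, q = q)
  expr <- data.frame(motif_id = c("CAGACA", "GGCGCC"),
                     reads_a = c(1000, 1000), reads_b = c(1000, 1000))
  sel <- select_candidates(ea, eb, expr, min_reads = 1)
  expect_equal(sel$a$motif_id[1], "CAGACA")
})

test_that("resampled foregrounds from the background give mean ratio 1", {
  a <- generate_annotation(60, 1, 3e6, seed = 36)
  p <- generate_promoters(a, "CAGACA", 1, 1, gc = 0.41, seed = 37,
                          fg_genes = character(0))
  seqs <- as.character(p$sequences)
  pw <- build_pwm(consensus_wpcm("CAGACA", W = 18),
                  background_frequencies(seqs))
  thr <- score_threshold(pw, p = 0.001)
  hits_per <- table(factor(scan_pwm(seqs, pw, thr)$sequence_id,
                           levels = names(seqs)))
  lens <- nchar(seqs)
  set.seed(38)
  ratios <- replicate(200, {
    fg <- sample(names(seqs), 15)
    bg <- setdiff(names(seqs), fg)
    enrichment_ratio(sum(hits_per[fg]),
                     expected_sites(sum(hits_per[bg]), sum(lens[bg]),
                                    sum(lens[fg])))
  })
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)
})

test_that("co-localization uses inclusive distance and binomial tail", {
  lens <- c(r1 = 1000)
  hits <- data.frame(sequence_id = "r1", start = 100, end = 110)
  sbe_near <- data.frame(sequence_id = "r1", start = 250, end = 254)
  res <- colocalization_test(hits, sbe_near, lens, window = 200)
  expect_equal(res$colocalized, 1L)          # gap 140

  sbe_far <- data.frame(sequence_id = "r1", start = 311, end = 315)
  res2 <- colocalization_test(hits, sbe_far, lens, window = 200)
  expect_equal(res2$colocalized, 0L)         # gap 201: out

  sbe_edge <- data.frame(sequence_id = "r1", start = 310, end = 314)
  expect_equal(colocalization_test(hits, sbe_edge, lens, 200)$colocalized,
               1L)                           # gap exactly 200: in

  # binomial arithmetic: engineer null probability 0.5 with 5/5 successes
  w <- 10
  L <- 2 * (200 + w) + 4 + (w - 1)   # valid offsets: twice the coloc width
  lens2 <- c(r1 = 2 * L)
  sbe <- data.frame(sequence_id = "r1", start = L, end = L + 4)
  hits5 <- data.frame(sequence_id = "r1",
                      start = c(L - 50, L - 20, L, L + 30, L + 100))
  hits5$end <- hits5$start + w
  res5 <- colocalization_test(hits5, sbe, lens2, window = 200)
  expect_equal(res5$total_hits, 5L)
  expect_equal(res5$colocalized, 5L)
  expect_equal(res5$null_probability, 0.5, tolerance = 0.05)
  # all 5 of 5 hits co-localized: upper binomial tail is exactly p0^5
  expect_equal(res5$p_value, res5$null_probability^5)

  # no hits: NA result, not an error
  none <- colocalization_test(hits[0, ], sbe_near, lens, 200)
  expect_true(is.na(none$p_value))
  expect_equal(none$total_hits, 0L)
})
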