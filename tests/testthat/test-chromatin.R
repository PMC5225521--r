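test_that("DHS filtering is boundary-inclusive on reads and blacklist-aware", {
  pk <- peak_df(c(100, 300, 500), c(200, 400, 600),
                reads_sample = c(20, 19, 100),
                reads_input = c(20, 100, 100))
  kept <- filter_dhs(pk, min_reads = 20)
  expect_equal(kept$start, c(100, 500))      # 19 sample reads removed

  bl <- data.frame(chrom = "chr1", start = 199, end = 300)
  kept_bl <- filter_dhs(pk, min_reads = 20, blacklist = bl)
  expect_equal(kept_bl$start, 500)           # 1-bp overlap [100,200) removed

  unsorted <- pk[c(3, 1, 2), ]
  expect_message(filter_dhs(unsorted, 20), "unsorted")
})

test_that("filtering is monotone in the read threshold", {
  set.seed(1)
  pk <- peak_df(seq(0, 990, 10) * 100, seq(0, 990, 10) * 100 + 500,
                reads_sample = rpois(100, 30), reads_input = rpois(100, 30))
  strict <- filter_dhs(pk, min_reads = 25)$peak_id
  loose <- filter_dhs(pk, min_reads = 20)$peak_id
  expect_true(all(strict %in% loose))
})

test_that("merging closes gaps up to 100 bp transitively and sums counts", {
  pk <- peak_df(c(100, 300), c(200, 400), n = c(1L, 1L))
  m <- merge_adjacent(pk, 100, count_cols = "n")   # gap exactly 100
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100, 400))

  pk2 <- peak_df(c(100, 301), c(200, 400), n = c(1L, 1L))
  expect_equal(nrow(merge_adjacent(pk2, 100, count_cols = "n")), 2L)  # gap 101

  pk3 <- peak_df(c(0, 150, 310), c(100, 230, 400), n = c(2L, 3L, 4L))
  m3 <- merge_adjacent(pk3, 100, count_cols = "n") # gaps 50 and 80: one chain
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$n, 9)
  expect_equal(m3$n_merged, 3L)

  # idempotence
  m3$reads <- m3$n
  again <- merge_adjacent(m3[, c("chrom", "start", "end", "n")], 100,
                          count_cols = "n")
  expect_equal(again$start, m3$start)
  expect_equal(again$end, m3$end)
  expect_equal(again$n, m3$n)
})

test_that("feature annotation follows the fixed priority order", {
  # gene gA: body [10000,16000), promoter [8000,10000), exon1 [10000,11000),
  # intron [11000,12000), exon2 [12000,16000)
  ann <- two_tx_annotation()
  pk <- peak_df(start = c(9500, 500, 10900, 11100, 9900),
                end = c(9700, 600, 11200, 11500, 10100))
  lab <- annotate_dhs(pk, ann)
  expect_equal(lab[1], "promoter")
  expect_equal(lab[2], "intergenic")
  expect_equal(lab[3], "exon")        # spans exon-intron boundary -> exon
  expect_equal(lab[4], "intron")
  expect_equal(lab[5], "promoter")    # promoter wins over exon

  pk_off <- peak_df(1000, 1100, chrom = "chrX")
  expect_warning(lab_off <- annotate_dhs(pk_off, ann), "absent")
  expect_equal(lab_off, "intergenic")
})

test_that("deltaDHS matches the worked example and is antisymmetric", {
  expect_equal(delta_dhs(c(400, 0, 0, 0), c(100, 100, 100, 100)),
               c(1, -1, -1, -1))
  expect_equal(delta_dhs(c(7, 3, 9), c(7, 3, 9)), c(0, 0, 0))

  set.seed(4)
  for (i in 1:25) {
    nt <- rpois(50, 80); nv <- rpois(50, 80)
    expect_equal(delta_dhs(nt, nv), -delta_dhs(nv, nt))
  }
  expect_warning(d0 <- delta_dhs(c(0, 0), c(1, 3)), "zero total")
  expect_equal(d0, -sqrt(c(1, 3) / 2))
})

test_that("scaled counts have mean squared condition term equal to 1", {
  set.seed(5)
  n <- rpois(200, 60)
  m <- length(n)
  term_sq <- n / (sum(n) / m)
  expect_equal(mean(term_sq), 1, tolerance = 1e-12)
})

test_that("differential selection is boundary-inclusive in both directions", {
  sc <- c(0.20, 0.19, -0.25, 0.5)
  expect_equal(select_differential(sc), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(select_differential(sc, direction = "closing"),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(select_differential(sc, direction = "both"),
               c(TRUE, FALSE, TRUE, TRUE))
})

test_that("planted open peaks dominate the selected differential set", {
  a <- generate_annotation(30, 1, 2e6, seed = 6)
  d <- generate_dhs(a, 200, 20, openness_fold = 4, seed = 7)
  delta <- delta_dhs(d$peaks$reads_treated, d$peaks$reads_vehicle)
  sel <- d$peaks$peak_id[select_differential(delta, 0.20)]
  truth <- d$truth$diff_dhs$peak_id
  expect_gte(sum(truth %in% sel), 18)            # recovers nearly all planted
  expect_gte(mean(sel %in% truth), 0.8)          # and few spurious calls
})

test_that("peak overlap fraction counts query peaks with any overlap", {
  A <- peak_df(c(0, 200), c(100, 300))
  expect_equal(peak_overlap_fraction(A, A), 1.0)
  B <- peak_df(c(250), c(260))
  expect_equal(peak_overlap_fraction(A, B), 0.5)
  expect_equal(peak_overlap_fraction(A, peak_df(1000, 1100)), 0.0)
  expect_error(peak_overlap_fraction(A[0, ], B), "empty")
})
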