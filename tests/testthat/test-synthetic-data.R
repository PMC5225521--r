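test_that("annotation generation is seeded, disjoint, and promoter-complete", {
  a1 <- generate_annotation(1, 1, 10000, seed = 7)
  a2 <- generate_annotation(1, 1, 10000, seed = 7)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$genes), 1L)

  empty <- generate_annotation(0, 1, 10000, seed = 7)
  expect_equal(nrow(empty$genes), 0L)
  expect_s3_class(empty, "gene_annotation")

  a <- generate_annotation(50, 2, 1e6, seed = 1)
  expect_equal(nrow(a$genes), 50L)
  expect_equal(nrow(a$transcripts), 100L)
  expect_true(intervals_disjoint(a$genes$start, a$genes$end))
  # promoters: 2000 bp, strand-aware, inside the chromosome
  expect_true(all(a$genes$promoter_end - a$genes$promoter_start == 2000))
  expect_true(all(a$genes$promoter_start >= 0 &
                  a$genes$promoter_end <= a$chrom_length))
  plus <- a$genes$strand == "+"
  expect_true(all(a$genes$promoter_end[plus] == a$genes$start[plus]))
  expect_true(all(a$genes$promoter_start[!plus] == a$genes$end[!plus]))
  # gene tss is the 5'-most transcript coordinate respecting strand
  for (g in a$genes$gene_id[1:5]) {
    tx <- a$transcripts[a$transcripts$gene_id == g, ]
    gi <- a$genes[a$genes$gene_id == g, ]
    expect_equal(gi$tss,
                 if (gi$strand == "+") min(tx$tss) else max(tx$tss))
  }
  # exons sorted and non-overlapping within each transcript
  for (t in unique(a$exons$transcript_id[1:20])) {
    ex <- a$exons[a$exons$transcript_id == t, ]
    expect_true(intervals_disjoint(ex$start, ex$end))
  }
  expect_error(generate_annotation(50, 1, 5000, seed = 1),
               "chrom_length too small")
})

test_that("count simulation plants exact mean folds and rejects bad input", {
  a <- generate_annotation(20, 1, 1e6, seed = 2)
  cnt <- generate_counts(a, n_de = 5, log2_fold = 1, dispersion = 0,
                         depth = 1e5, seed = 3)
  tr <- cnt$truth
  expect_equal(nrow(tr$de_genes), 5L)
  for (g in tr$de_genes$gene_id)
    expect_equal(tr$mu_treated[[g]], 2 * tr$mu_vehicle[[g]])
  others <- setdiff(names(tr$mu_vehicle), tr$de_genes$gene_id)
  expect_equal(tr$mu_treated[others], tr$mu_vehicle[others])

  null_run <- generate_counts(a, n_de = 0, log2_fold = 1, dispersion = 0.1,
                              depth = 1e5, seed = 3)
  expect_equal(nrow(null_run$truth$de_genes), 0L)

  expect_error(generate_counts(a, 1, 0, 0.1, 1e5, seed = 1), "magnitude 0")
  expect_error(generate_counts(a, 1, 1, -0.1, 1e5, seed = 1), "dispersion")
  expect_error(generate_counts(a, 1, 1, 0.1, -5, seed = 1), "depth")
})

test_that("simulated counts match negative-binomial moments at 1e4 draws", {
  a <- generate_annotation(1, 1, 50000, seed = 4)
  disp <- 0.1
  cnt <- generate_counts(a, 0, 1, dispersion = disp, depth = 500,
                         seed = 5, n_reps = 10000, libsize_jitter = 0)
  x <- as.numeric(cnt$vehicle)
  mu <- cnt$truth$mu_vehicle[[1]]
  expect_equal(mean(x), mu, tolerance = 4 * sqrt((mu + disp * mu^2) / 1e4) / mu)
  expect_equal(var(x), mu + disp * mu^2, tolerance = 0.1)
})

test_that("DHS simulation plants recoverable differential openness", {
  a <- generate_annotation(30, 1, 2e6, seed = 5)
  d1 <- generate_dhs(a, 100, 0, openness_fold = 1, seed = 6)
  d2 <- generate_dhs(a, 100, 0, openness_fold = 1, seed = 6)
  expect_identical(d1, d2)
  delta <- delta_dhs(d1$peaks$reads_treated, d1$peaks$reads_vehicle)
  expect_lt(abs(mean(delta)), 0.05)

  d <- generate_dhs(a, 100, 1, openness_fold = 4, seed = 7)
  delta <- delta_dhs(d$peaks$reads_treated, d$peaks$reads_vehicle)
  expect_equal(d$peaks$peak_id[which.max(delta)],
               d$truth$diff_dhs$peak_id)
  expect_true(all(d$truth$diff_dhs$peak_id %in% d$peaks$peak_id))
  expect_error(generate_dhs(a, 10, 1, openness_fold = 0, seed = 1), "> 0")
})

test_that("promoter simulation controls GC and records every insertion", {
  a <- generate_annotation(50, 1, 2e6, seed = 8)
  none <- generate_promoters(a, "GGCGCC", 0, 0, gc = 0.5, seed = 9)
  expect_equal(nrow(none$truth$motif_positions), 0L)
  # 50 promoters x 2000 bp = 100 kb of sequence
  freq <- Biostrings::alphabetFrequency(none$sequences, collapse = TRUE)
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)

  p <- generate_promoters(a, "GGCGCC", 2, 0.5, gc = 0.41, seed = 10,
                          fg_genes = a$genes$gene_id[1:10])
  pos <- p$truth$motif_positions
  expect_gt(nrow(pos), 0)
  seqs <- as.character(p$sequences)
  for (i in seq_len(nrow(pos)))
    expect_equal(substring(seqs[[pos$sequence_id[i]]],
                           pos$offset[i] + 1, pos$offset[i] + 6), "GGCGCC")
  expect_true(all(pos$sequence_id %in% a$genes$gene_id))
  expect_error(generate_promoters(a, strrep("A", 3000), 1, 1, gc = 0.4,
                                  seed = 1), "longer than promoter")
})

test_that("survival simulation honors censoring and planted hazards", {
  s0 <- generate_survival(100, 1, censor_rate = 0, seed = 11)
  expect_true(all(s0$event == 1))
  expect_error(generate_survival(100, 1, censor_rate = 1, seed = 1),
               "censor_rate")
  expect_error(generate_survival(100, 0, 0, seed = 1), "hazard_ratio")

  # strong effect: median log-rank p over 20 seeds is small
  ps <- vapply(1:20, function(s) {
    d <- generate_survival(200, 3, censor_rate = 0.1, seed = s)
    logrank_test(d$time, d$event, median_split(d$expression))$p
  }, numeric(1))
  expect_lt(median(ps), 0.01)
})

test_that("null survival p-values are uniform across seeds", {
  ps <- vapply(1:200, function(s) {
    d <- generate_survival(60, 1, censor_rate = 0.2, seed = s)
    logrank_test(d$time, d$event, median_split(d$expression))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("generator substreams are independent of one another", {
  a <- generate_annotation(10, 1, 1e6, seed = 42)
  c1 <- generate_counts(a, 2, 1, 0.05, 1e4, seed = 42)
  # drawing from another generator in between must not perturb the stream
  invisible(generate_dhs(a, 20, 2, 2, seed = 42))
  c2 <- generate_counts(a, 2, 1, 0.05, 1e4, seed = 42)
  expect_identical(c1, c2)
})
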