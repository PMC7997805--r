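test_that("normalization puts a diploid locus at 2.0", {
  # region depth equal to the baseline depth
  expect_equal(normalize_depth(read_count = 2000, unit_length = 10000,
                               baseline_depth = 30, read_length = 150), 2.0)
  expect_error(normalize_depth(100, 1000, 0), "positive")
})

test_that("GC correction is the identity without bias and clamps extremes", {
  baseline <- data.frame(depth = rep(30, 100),
                         gc = rep(seq(0.3, 0.7, by = 0.05),
                                  length.out = 100))
  same <- gc_correct(depth = c(30, 45), gc = c(0.45, 0.45), baseline)
  expect_equal(same$factor, c(1, 1))
  expect_equal(same$depth, c(30, 45))

  # a bin with depth scaled by 0.8 is restored
  biased <- baseline
  bin <- biased$gc >= 0.40 & biased$gc < 0.45
  biased$depth[bin] <- biased$depth[bin] * 0.8
  fixed <- gc_correct(depth = 24, gc = 0.42, biased)
  expect_lt(abs(fixed$depth - 30) / 30, 0.05)

  # factor that would be 3 is clamped to 2 with a QC flag
  extreme <- baseline
  bin <- extreme$gc >= 0.60 & extreme$gc < 0.65
  extreme$depth[bin] <- 10
  out <- gc_correct(depth = 10, gc = 0.62, extreme)
  expect_equal(max(out$factor), 2)
  expect_true("gc_factor_clamped" %in% out$qc_flags)

  # empty GC bin falls back to the global median and flags
  sparse <- data.frame(depth = rep(30, 10), gc = rep(0.3, 10))
  out <- gc_correct(depth = 30, gc = 0.7, sparse)
  expect_true("gc_bin_empty" %in% out$qc_flags)
  expect_equal(out$depth, 30)
})

test_that("integer CN calls follow the mixture posterior", {
  expect_equal(call_integer_cn(5.02)$cn, 5L)
  expect_equal(call_integer_cn(0)$cn, 0L)
  # exact midpoint splits the posterior ~50/50 and no-calls
  mid <- call_integer_cn(4.5)
  expect_true(is.na(mid$cn))
  expect_lt(mid$posterior, 0.95)
})

test_that("mixture posteriors are normalized and the call is monotone", {
  vals <- runif(200, 0, 9)
  prev <- -1L
  for (v in sort(vals)) {
    out <- call_integer_cn(v, sigma = 0.25)
    expect_equal(sum(out$posteriors), 1, tolerance = 1e-9)
    if (!is.na(out$cn)) {
      expect_gte(out$cn, prev)
      prev <- out$cn
    }
  }
})

test_that("mixture calls match a brute-force posterior oracle", {
  set.seed(11)
  vals <- runif(1000, 0, 10.5)
  for (sigma in c(0.25, 0.18, 0.13)) {
    got <- lapply(vals, call_integer_cn, sigma = sigma)
    want <- lapply(vals, oracle_gmm_cn, sigma = sigma)
    expect_identical(vapply(got, `[[`, 1L, "cn"),
                     vapply(want, function(w) as.integer(w$cn), 1L))
  }
})

test_that("simulated depth recovers the constructed copy numbers", {
  # no-SV sample: CN(CYP2D6+CYP2D7) 4, CN(spacer) 2
  ev <- simulate_counts("*1/*1", res38, seed = 101)
  tc <- call_total_and_spacer(ev)
  expect_equal(tc$cn_total, 4L)
  expect_equal(tc$cn_spacer, 2L)
  expect_gt(tc$depth_total, 3.7); expect_lt(tc$depth_total, 4.3)

  # homozygous deletion: two CYP2D7 only
  ev <- simulate_counts("*5/*5", res38, seed = 102)
  tc <- call_total_and_spacer(ev)
  expect_equal(tc$cn_total, 2L)
  expect_gt(tc$depth_total, 1.7); expect_lt(tc$depth_total, 2.3)

  # hemizygous deletion concentrates near 3
  ev <- simulate_counts("*1/*5", res38, seed = 103)
  tc <- call_total_and_spacer(ev)
  expect_equal(tc$cn_total, 3L)

  # NA12878-like: 2 CYP2D6 + exon-1 hybrid + 2 CYP2D7 -> CN5, spacer 3
  ev <- simulate_counts("*3/*68+*4", res38, seed = 104)
  tc <- call_total_and_spacer(ev)
  expect_equal(tc$cn_total, 5L)
  expect_equal(tc$cn_spacer, 3L)
})

test_that("a cohort across CN 2..7 reproduces every depth mode", {
  cohort <- c("*5/*5", "*1/*5", "*1/*1", "*1x2/*1", "*1x2/*1x2",
              "*1x3/*1x2")
  depths <- unlist(lapply(seq_along(cohort), function(i)
    vapply(1:50, function(r) {
      ev <- simulate_counts(cohort[i], res38, seed = 5000 + 100 * i + r)
      row <- ev$regions[ev$regions$region == "total", ]
      normalize_depth(row$read_count, row$unit_length,
                      median(ev$baseline$depth))
    }, numeric(1))))
  # bins centred on the integers so each CN mode falls in one bin
  h <- hist(depths, breaks = seq(1.75, 7.75, by = 0.5), plot = FALSE)
  modes <- h$mids[h$counts >= 25]
  expect_true(all(c(2, 3, 4, 5, 6, 7) %in% modes))
})
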