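test_that("per-site CN calls match the spec worked examples", {
  # cn_total 5, 20 vs 30 reads: p = 0.4 maximizes the likelihood
  out <- call_site_cn(20, 30, 5)
  expect_equal(out$called_cn, 2L)
  expect_equal(out$raw_cn, 5 * 20 / 50)

  # symmetric split
  expect_equal(call_site_cn(50, 50, 4)$called_cn, 2L)

  # all-CYP2D6 boundary survives the error clamp
  expect_equal(call_site_cn(150, 0, 3)$called_cn, 3L)

  # zero total copies is a trivial zero
  expect_equal(call_site_cn(0, 0, 0)$called_cn, 0L)
})

test_that("per-site calls equal exhaustive likelihood enumeration", {
  set.seed(42)
  grid <- expand.grid(n6 = seq(0, 200, by = 7), n7 = seq(0, 200, by = 9),
                      N = 1:8)
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      if (n6 + n7 == 0) return(invisible())
      got <- call_site_cn(n6, n7, N)
      want <- oracle_binom_cn(n6, n6 + n7, N)
      expect_identical(got$called_cn, as.integer(want$cn))
      expect_equal(got$posterior, unname(want$posterior),
                   tolerance = 1e-9)
    })
  }
})

test_that("relabelling the paralogs mirrors the called CN", {
  set.seed(7)
  for (r in 1:200) {
    N <- sample(1:8, 1)
    n6 <- rpois(1, 40)
    n7 <- rpois(1, 40)
    if (n6 + n7 == 0) next
    a <- call_site_cn(n6, n7, N)$called_cn
    b <- call_site_cn(n7, n6, N)$called_cn
    if (!is.na(a) && !is.na(b)) expect_equal(a + b, N)
    else expect_true(is.na(a) && is.na(b))
  }
})

test_that("segment consensus requires agreement and enough sites", {
  # counts at cn_total 4: 50/50 calls CN2, 75/25 calls CN3, 4/4 is below
  # the informative depth
  support_for <- function(per_segment) {
    rows <- lapply(names(per_segment), function(s) {
      counts <- per_segment[[s]]
      data.frame(site_id = seq_len(nrow(counts)), segment = s,
                 n_d6 = counts[, 1], n_d7 = counts[, 2], n_other = 0L,
                 informative = counts[, 1] + counts[, 2] >= 10)
    })
    do.call(rbind, rows)
  }
  balanced <- matrix(rep(c(50L, 50L), 5), ncol = 2, byrow = TRUE)
  spec <- setNames(rep(list(balanced), 11), cypstar:::SEGMENTS_5TO3)

  site_cns <- call_site_cn_all(support_for(spec), cn_total = 4)
  prof <- consensus_segments(site_cns, cn_total = 4)
  expect_equal(prof$segment, rev(cypstar:::SEGMENTS_5TO3))
  expect_true(all(prof$cn == 2L))
  expect_true(all(prof$agreement == 1))

  # one outlier site is tolerated by the mode rule
  spec$exon5 <- rbind(balanced[1:4, ], c(75L, 25L))
  # an even CN2/CN3 split pools to a between-states fraction: no-call
  spec$exon4 <- rbind(balanced[1:2, ], c(75L, 25L), c(75L, 25L))
  # fewer than three informative sites: no-call regardless of counts
  spec$exon3 <- rbind(c(50L, 50L), c(50L, 50L), c(4L, 4L), c(4L, 4L))
  site_cns <- call_site_cn_all(support_for(spec), cn_total = 4)
  prof <- consensus_segments(site_cns, cn_total = 4)
  expect_equal(prof$cn[prof$segment == "exon5"], 2L)
  expect_true(is.na(prof$cn[prof$segment == "exon4"]))
  expect_true(is.na(prof$cn[prof$segment == "exon3"]))

  # an uncalled total leaves every segment uncalled
  prof <- consensus_segments(site_cns, cn_total = NA)
  expect_true(all(is.na(prof$cn)))
})

test_that("pooled counts rescue underpowered sites but not mixed segments", {
  support <- do.call(rbind, lapply(cypstar:::SEGMENTS_5TO3, function(s)
    data.frame(site_id = 1:6, segment = s,
               # at cn_total 7 a 4-of-7 fraction rarely reaches the
               # per-site posterior threshold at 60 reads
               n_d6 = c(33L, 35L, 34L, 36L, 33L, 35L),
               n_d7 = c(27L, 25L, 26L, 24L, 27L, 25L),
               n_other = 0L, informative = TRUE)))
  site_cns <- call_site_cn_all(support, cn_total = 7)
  expect_true(sum(!is.na(site_cns$called_cn[
    site_cns$segment == "exon5"])) < 3)
  prof <- consensus_segments(site_cns, cn_total = 7)
  expect_true(all(prof$cn == 4L))  # pooled 206/360 is decisively 4/7
})

test_that("structural variants are typed from profile steps and spacer arithmetic", {
  prof <- function(cn) data.frame(segment = rev(cypstar:::SEGMENTS_5TO3),
                                  cn = cn, n_sites = 10, n_called = 10,
                                  agreement = 1)

  # reference configuration: 2 + 2, no hybrid
  sv <- detect_sv(prof(rep(2L, 11)), cn_total = 4, cn_spacer = 2)
  expect_equal(sv$cn_full_d6, 2L)
  expect_equal(sv$cn_full_d7, 2L)
  expect_length(sv$d6_d7_hybrids, 0)
  expect_equal(sv$cn_d7_d6_hybrid, 0L)

  # deletion carrier
  sv <- detect_sv(prof(rep(1L, 11)), cn_total = 3, cn_spacer = 2)
  expect_equal(sv$cn_full_d6, 1L)
  expect_equal(sv$cn_full_d7, 2L)

  # exon-1 step up: one D6-D7 hybrid switching after exon 1
  cn <- rep(2L, 11); cn[10:11] <- 3L  # exon1, flank5 (3' -> 5' order)
  sv <- detect_sv(prof(cn), cn_total = 5, cn_spacer = 3)
  expect_equal(sv$cn_full_d6, 2L)
  expect_equal(sv$d6_d7_hybrids, "exon1")
  expect_equal(sv$cn_full_d7, 2L)

  # conflicting spacer arithmetic is a no-call, not a guess
  sv <- detect_sv(prof(rep(2L, 11)), cn_total = 5, cn_spacer = 2)
  expect_equal(sv$status, "no_call")
  expect_match(sv$diagnostics, "disagrees|conflict")
})

test_that("partition conservation holds for every simulated archetype", {
  for (g in sv_archetypes) {
    truth <- expand_genotype(g, res38$defs)
    ev <- simulate_counts(g, res38, seed = 321)
    call <- genotype_sample(ev, res38)
    sv <- call$sv
    expect_equal(sv$status, "ok", info = g)
    expect_equal(sv$cn_full_d6 + sv$cn_full_d7 +
                   length(sv$d6_d7_hybrids) + length(sv$d7_d6_hybrids),
                 truth$cn_total, info = g)
    expect_equal(sv$cn_d6_3prime, sv$cn_full_d6 + sv$cn_d7_d6_hybrid,
                 info = g)
  }
})

test_that("pooled site support is informative and balanced without SV", {
  ev <- simulate_counts("*1/*1", res38, seed = 55)
  sup <- gather_site_support(ev, res38$panel)
  expect_equal(nrow(sup), 117)
  expect_true(all(sup$informative))
  frac <- sup$n_d6 / (sup$n_d6 + sup$n_d7)
  expect_gte(mean(frac >= 0.35 & frac <= 0.65), 0.9)
})

test_that("a deleted CYP2D6 leaves no CYP2D6-supporting reads", {
  ev <- simulate_counts("*5/*5", res38, seed = 56, exact = TRUE)
  sup <- gather_site_support(ev, res38$panel)
  expect_true(all(sup$n_d6 == 0))
  expect_true(all(sup$n_d7 > 0))
})
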