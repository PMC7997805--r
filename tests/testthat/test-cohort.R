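test_that("trio transmission is recognized as consistent", {
  defs <- res38$defs
  expect_equal(check_trio("*1/*2", "*1/*1", "*2/*2", defs)$status,
               "consistent")
  expect_equal(check_trio("*3/*68+*4", "*3/*1", "*68+*4/*5", defs)$status,
               "consistent")
  # tandems are atomic under the stated phasing: a *68+*4 chromosome does
  # not donate a lone *4 unless the trio is re-phased
  expect_equal(check_trio("*1/*4", "*1/*1", "*68+*4/*1", defs)$status,
               "resolvable_by_rephasing")
})

test_that("phase moves rescue apparent inconsistencies", {
  defs <- res38$defs
  # child called *1/*1; deletion parent implies child is *5/*1x2
  tr <- check_trio("*1/*1", "*5/*5", "*1x2/*1", defs)
  expect_equal(tr$status, "resolvable_by_rephasing")
  expect_equal(unname(tr$proposed_rephasing["child"]), "*1x2/*5")

  # allele absent from both parents can never be rescued
  expect_equal(check_trio("*4/*4", "*1/*1", "*1/*1", defs)$status,
               "inconsistent")
})

test_that("no-call members leave the trio unevaluated", {
  tr <- check_trio(NA_character_, "*1/*1", "*1/*1", res38$defs)
  expect_equal(tr$status, "not_evaluated")
})

test_that("simulated transmission is always Mendelian consistent", {
  defs <- res38$defs
  pool <- list("*1", "*2", "*4", c("*68", "*4"), c("*36", "*10"),
               character(0), c("*2", "*2"))
  set.seed(17)
  for (r in 1:100) {
    m <- sample(pool, 2, replace = TRUE)
    f <- sample(pool, 2, replace = TRUE)
    child <- list(m[[sample(2, 1)]], f[[sample(2, 1)]])
    tr <- check_trio(format_genotype(child[[1]], child[[2]], defs),
                     format_genotype(m[[1]], m[[2]], defs),
                     format_genotype(f[[1]], f[[2]], defs), defs)
    expect_equal(tr$status, "consistent")
  }
})

test_that("frequency tables conserve 100% per population", {
  defs <- res38$defs
  calls <- data.frame(
    sample = paste0("s", 1:6),
    population = c("A", "A", "A", "B", "B", "B"),
    genotype = c("*1/*1", "*1/*2", NA, "*36+*10/*1", "*36+*10/*36+*10",
                 "*1/*5"),
    stringsAsFactors = FALSE)
  freq <- aggregate_frequencies(calls, defs)
  sums <- tapply(freq$percent, freq$population, sum)
  expect_true(all(abs(sums - 100) < 0.01))
  a1 <- freq$percent[freq$population == "A" & freq$haplotype == "*1"]
  expect_equal(a1, 100 * 3 / 6)
  unk <- freq$percent[freq$population == "A" & freq$haplotype == "Unknown"]
  expect_equal(unk, 100 * 2 / 6)
  # tandems counted as single haplotypes
  t36 <- freq$percent[freq$population == "B" & freq$haplotype == "*36+*10"]
  expect_equal(t36, 100 * 3 / 6)
})

test_that("two identical samples give a 100% haplotype", {
  calls <- data.frame(sample = c("a", "b"), population = "X",
                      genotype = "*1/*1", stringsAsFactors = FALSE)
  freq <- aggregate_frequencies(calls, res38$defs)
  expect_equal(freq$percent[freq$haplotype == "*1"], 100)
})

test_that("a seeded cohort recovers its sampling haplotype frequency", {
  defs <- res38$defs
  # East-Asian-style pool dominated by *1/*10/*36+*10
  haps <- list("*1", "*10", "*2", c("*36", "*10"), "*41", "*5")
  probs <- c(0.30, 0.17, 0.08, 0.34, 0.04, 0.07)
  set.seed(504)
  n <- 504
  gts <- vapply(seq_len(n), function(i) {
    pick <- sample(seq_along(haps), 2, replace = TRUE, prob = probs)
    format_genotype(haps[[pick[1]]], haps[[pick[2]]], defs)
  }, character(1))
  calls <- data.frame(sample = paste0("s", 1:n), population = "EAS",
                      genotype = gts, stringsAsFactors = FALSE)
  freq <- aggregate_frequencies(calls, defs)
  got <- freq$percent[freq$haplotype == "*36+*10"] / 100
  p <- probs[4]
  sd3 <- 3 * sqrt(p * (1 - p) / (2 * n))
  expect_lt(abs(got - p), sd3)
})

test_that("concordance applies the multiset match rule with strata", {
  defs <- res38$defs
  truth <- data.frame(
    sample = paste0("s", 1:6),
    genotype = c("*1/*1", "*1/*5", "*2x2/*1", "*3/*68+*4",
                 "*1/*36+*36+*10", "*2/*17"),
    stringsAsFactors = FALSE)
  calls <- truth
  calls$genotype[5] <- "*1+*36/*36+*10"   # different phasing, same alleles
  calls$genotype[6] <- "*2/*2"            # genuine miscall
  conc <- concordance(calls, truth, defs)
  expect_equal(conc$n_compared, 6)
  expect_equal(conc$n_concordant, 5)
  expect_equal(conc$overall_percent, 100 * 5 / 6, tolerance = 1e-9)
  bs <- conc$by_stratum
  expect_equal(bs$n[bs$stratum == "deletion"], 1)
  expect_equal(bs$n[bs$stratum == "duplication"], 1)
  expect_equal(bs$n[bs$stratum == "hybrid"], 2)
  expect_equal(bs$n[bs$stratum == "no_sv"], 2)
  expect_equal(sum(bs$n), conc$n_compared)

  # self-comparison is 100%
  self <- concordance(truth, truth, defs)
  expect_equal(self$overall_percent, 100)

  # samples missing from the truth table are excluded, not failed
  extra <- rbind(calls, data.frame(sample = "s7", genotype = "*1/*1"))
  expect_message(conc2 <- concordance(extra, truth, defs), "excluded")
  expect_equal(conc2$n_compared, 6)
  expect_equal(conc2$excluded, "s7")
})
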