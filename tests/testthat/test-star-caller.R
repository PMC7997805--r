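test_that("genotype strings parse and format round-trip", {
  expect_equal(parse_genotype("*3/*68+*4"),
               list("*3", c("*68", "*4")))
  expect_equal(parse_genotype("*1x2/*5"),
               list(c("*1", "*1"), character(0)))
  expect_error(parse_genotype("*5+*2/*1"), "combined")
  expect_error(parse_genotype("bogus"), "parse")

  defs <- res38$defs
  expect_equal(format_haplotype(c("*1", "*1"), defs), "*1x2")
  expect_equal(format_haplotype(c("*4", "*68"), defs), "*68+*4")
  expect_equal(format_haplotype(character(0), defs), "*5")
  expect_equal(format_genotype(c("*68", "*4"), "*3", defs), "*3/*68+*4")
})

test_that("genotype matching compares star-allele multisets only", {
  expect_true(genotype_match("*1+*36/*36+*10", "*1/*36+*36+*10"))
  expect_false(genotype_match("*1/*2", "*1/*4"))
  expect_true(genotype_match("*2x2/*1", "*2/*2+*1"))
  expect_false(genotype_match("*1/*1", "*5/*1x2"))
})

test_that("evidence-free sample resolves to *1/*1 and candidates include *1 only", {
  ev <- simulate_counts("*1/*1", res38, seed = 1, exact = TRUE)
  call <- genotype_sample(ev, res38)
  expect_equal(call$diplotype$genotype, "*1/*1")
  expect_equal(call$diplotype$filter, "PASS")
  cands <- enumerate_haplotypes(call$sv, call$variant_calls, res38$defs)
  expect_equal(vapply(cands, `[[`, "", "label"), "*1")
})

test_that("NA12878-like evidence resolves to *3/*68+*4", {
  ev <- simulate_counts("*3/*68+*4", res38, seed = 2)
  call <- genotype_sample(ev, res38)
  expect_equal(call$diplotype$genotype, "*3/*68+*4")
  expect_equal(call$diplotype$filter, "PASS")
  cands <- enumerate_haplotypes(call$sv, call$variant_calls, res38$defs)
  expect_true("*68+*4" %in% vapply(cands, `[[`, "", "label"))
})

test_that("a deletion pairs the remaining haplotype with *5", {
  ev <- simulate_counts("*1/*5", res38, seed = 3, exact = TRUE)
  call <- genotype_sample(ev, res38)
  expect_equal(call$diplotype$genotype, "*1/*5")
  cands <- enumerate_haplotypes(call$sv, call$variant_calls, res38$defs)
  expect_true("*5" %in% vapply(cands, `[[`, "", "label"))
})

test_that("tandem conventions rank above alternative phasings", {
  ev <- simulate_counts("*1/*36+*36+*10", res38, seed = 4, exact = TRUE)
  call <- genotype_sample(ev, res38)
  expect_equal(call$diplotype$genotype, "*1/*36+*36+*10")
  # the alternative grouping is still an exact cover, recorded not chosen
  expect_true(any(grepl("\\*36\\+\\*10", call$diplotype$alternatives)))
  expect_true(genotype_match("*1+*36/*36+*10", call$diplotype$genotype))
})

test_that("the hybrid class distinguishes *68+*4 from *4.013+*4", {
  ev <- simulate_counts("*4.013+*4/*1", res38, seed = 5, exact = TRUE)
  call <- genotype_sample(ev, res38)
  expect_equal(allele_multiset(call$diplotype$genotype),
               allele_multiset("*4.013+*4/*1"))
  ev <- simulate_counts("*68+*4/*1", res38, seed = 6, exact = TRUE)
  call <- genotype_sample(ev, res38)
  expect_equal(allele_multiset(call$diplotype$genotype),
               allele_multiset("*68+*4/*1"))
})

test_that("exact-cover soundness: chosen genotypes re-imply the evidence", {
  for (g in c("*2/*17", "*3/*68+*4", "*10/*10", "*13+*2/*1")) {
    ev <- simulate_counts(g, res38, seed = 7, exact = TRUE)
    call <- genotype_sample(ev, res38)
    expect_equal(call$diplotype$filter, "PASS", info = g)
    re <- expand_genotype(call$diplotype$genotype, res38$defs)
    vc <- call$variant_calls
    called <- setNames(vc$cn_alt, vc$g_label)
    called <- called[!is.na(called)]
    expect_equal(unname(re$variant_cn[names(called)]), unname(called),
                 info = g)
    expect_equal(re$cn_full_d6, call$sv$cn_full_d6, info = g)
    expect_equal(sort(re$d6_d7_hybrids), sort(call$sv$d6_d7_hybrids),
                 info = g)
  }
})

test_that("ranked output is deterministic for identical evidence", {
  ev <- simulate_counts("*2x2/*1", res38, seed = 8, exact = TRUE)
  a <- genotype_sample(ev, res38)$diplotype
  b <- genotype_sample(ev, res38)$diplotype
  expect_identical(a$genotype, b$genotype)
  expect_identical(a$alternatives, b$alternatives)
  # duplication grouped as x2, mixed tandem listed as alternative
  expect_equal(a$genotype, "*1/*2x2")
})

test_that("unexplainable evidence yields a diagnostic no-call", {
  ev <- simulate_counts("*1/*1", res38, seed = 9, exact = TRUE)
  # fabricate an impossible variant pattern: lone g.100C>T at one copy
  ev$variant_support$n_alt[ev$variant_support$g_label == "g.100C>T"] <- 15
  ev$variant_support$n_ref[ev$variant_support$g_label == "g.100C>T"] <- 15
  call <- genotype_sample(ev, res38)
  expect_equal(call$diplotype$filter, "no_call")
  expect_match(call$diplotype$diagnostics, "g.100C>T")
})

test_that("activity scores translate to CPIC metabolizer categories", {
  defs <- res38$defs
  p <- translate_phenotype("*1/*1", defs)
  expect_equal(p$activity_score, 2)
  expect_equal(p$category, "normal")

  expect_equal(translate_phenotype("*5/*5", defs)$category, "poor")
  expect_equal(translate_phenotype("*1/*1x2", defs)$activity_score, 3)
  expect_equal(translate_phenotype("*1/*1x2", defs)$category, "ultrarapid")
  expect_equal(translate_phenotype("*4/*10", defs)$category,
               "intermediate")
  expect_equal(translate_phenotype("*1/*22", defs)$category,
               "indeterminate")

  nc <- structure(list(filter = "no_call", genotype = NA),
                  class = "cyp_diplotype")
  expect_equal(translate_phenotype(nc, defs)$category, "indeterminate")
})
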