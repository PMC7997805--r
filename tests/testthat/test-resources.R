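test_that("GRCh38 region model matches the published locus coordinates", {
  sp <- res38$model$spans
  expect_equal(GenomicRanges::start(sp["rep6"]), 42123192)
  expect_equal(GenomicRanges::end(sp["rep6"]), 42125972)
  expect_equal(GenomicRanges::start(sp["rep7"]), 42135344)
  expect_equal(GenomicRanges::end(sp["rep7"]), 42138124)
  expect_equal(GenomicRanges::start(sp["spacer"]), 42138124)
  expect_equal(GenomicRanges::end(sp["spacer"]), 42139676)
  expect_length(res38$model$d6_exons, 9)
  expect_length(res38$model$d7_exons, 9)
})

test_that("GRCh37 and GRCh38 models have identical interval structure", {
  for (nm in c("d6", "d7", "rep6", "rep7", "spacer"))
    expect_equal(GenomicRanges::width(res37$model$spans[nm]),
                 GenomicRanges::width(res38$model$spans[nm]), info = nm)
  expect_equal(GenomicRanges::width(res37$model$d6_exons),
               GenomicRanges::width(res38$model$d6_exons))
})

test_that("unknown build is a fatal configuration error", {
  expect_error(load_region_model("GRCh99"), "unsupported genome build")
})

test_that("site panel has 117 valid, segment-assigned sites", {
  panel <- res38$panel
  expect_equal(nrow(panel), 117)
  expect_true(all(panel$d6_base != panel$d7_base))
  expect_true(all(diff(panel$d6_pos) > 0))
  n_per <- table(panel$segment)
  expect_setequal(names(n_per), cypstar:::SEGMENTS_5TO3)
  expect_true(all(n_per >= 3))
})

test_that("site panel integrity violations are rejected", {
  panel_path <- system.file("extdata", "site_panel.tsv",
                            package = "cypstar")
  raw <- read.delim(panel_path)
  tmp <- tempfile(fileext = ".tsv")

  write.table(raw[-1, ], tmp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_site_panel("GRCh38", path = tmp), "117")

  bad <- raw
  bad$d7_base[5] <- bad$d6_base[5]
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_site_panel("GRCh38", path = tmp),
               "identical paralog bases")

  bad <- raw
  bad$d6_pos_grch38[2] <- bad$d6_pos_grch38[1]
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_site_panel("GRCh38", path = tmp), "duplicate")
})

test_that("panel round-trips through serialization unchanged", {
  tmp <- tempfile(fileext = ".tsv")
  raw <- read.delim(system.file("extdata", "site_panel.tsv",
                                package = "cypstar"))
  write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  reloaded <- load_site_panel("GRCh38", model = res38$model, path = tmp)
  expect_equal(as.data.frame(reloaded), as.data.frame(res38$panel))
})

test_that("both builds carry the same base pair at every site", {
  p37 <- res37$panel[order(res37$panel$site_id), ]
  p38 <- res38$panel[order(res38$panel$site_id), ]
  expect_equal(p37$d6_base, p38$d6_base)
  expect_equal(p37$d7_base, p38$d7_base)
  expect_equal(p37$segment, p38$segment)
})

test_that("allele definitions cover the validated set with referential integrity", {
  defs <- res38$defs
  validated <- Filter(function(a) a$validated, defs$alleles)
  expect_gte(length(validated), 40)
  expect_true("*1" %in% names(defs$alleles))
  expect_length(defs$alleles[["*1"]]$variants, 0)
  expect_equal(defs$alleles[["*5"]]$sv$class, "deletion")
  expect_equal(defs$alleles[["*68"]]$sv$class, "d6d7")
  expect_equal(defs$alleles[["*68"]]$sv$switch, "exon1")
  expect_equal(defs$alleles[["*36"]]$sv$class, "d6d7")
  expect_true(all(unlist(lapply(defs$alleles, `[[`, "variants")) %in%
                    defs$catalogue$g_label))
})

test_that("dangling variant keys are a resource integrity error", {
  defs_path <- system.file("extdata", "allele_definitions.json",
                           package = "cypstar")
  js <- jsonlite::read_json(defs_path)
  js$alleles[[2]]$variants <- list("g.9999X>Y")
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(js, tmp, auto_unbox = TRUE)
  expect_error(load_allele_definitions("GRCh38", defs_path = tmp),
               "dangling")
})

test_that("homology flags in the catalogue agree with the region model", {
  cat_tab <- res38$defs$catalogue
  hom <- res38$model$homology
  in_hom <- vapply(cat_tab$pos, function(p)
    any(p >= GenomicRanges::start(hom) & p <= GenomicRanges::end(hom)),
    logical(1))
  # indels never pool across paralogs, SNVs follow the regions
  expect_true(all(cat_tab$in_homology ==
                    (in_hom & cat_tab$type == "snv")))
  expect_true(all(!is.na(cat_tab$mirror_pos[cat_tab$in_homology])))
})
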