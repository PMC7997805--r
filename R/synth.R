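#' Expand a diplotype into its ground-truth copy structure
#'
#' Deterministically expands a genotype string against the allele
#' definitions into the physical copy structure it implies.  Every
#' chromosome carries one complete CYP2D7; star-allele units add complete
#' CYP2D6 genes, CYP2D6-CYP2D7 hybrids (CYP2D7-derived at the 3' end, so
#' they carry a spacer) or CYP2D7-CYP2D6 hybrids (CYP2D6-derived at the 3'
#' end); `*5` deletes the chromosome's CYP2D6.
#'
#' @param genotype Diplotype string, e.g. `"*3/*68+*4"`.
#' @param defs Allele definitions from [load_allele_definitions()].
#' @return An object of class `cyp_truth`: list with `genotype`,
#'   `haplotypes`, `units` (data frame: haplotype, allele, class, switch),
#'   `cn_total`, `cn_spacer`, `cn_full_d6`, `d6_d7_hybrids`,
#'   `d7_d6_hybrids`, `segment_cn` (named, 5' to 3'), `variant_cn` (named
#'   over the full catalogue).
#' @export
expand_genotype <- function(genotype, defs) {
  haps <- parse_genotype(genotype, defs)
  units <- do.call(rbind, lapply(seq_along(haps), function(i) {
    if (length(haps[[i]]) == 0L) return(NULL)
    data.frame(haplotype = i, allele = haps[[i]], stringsAsFactors = FALSE)
  }))
  if (is.null(units))
    units <- data.frame(haplotype = integer(0), allele = character(0))
  units$class <- vapply(units$allele, function(a)
    defs$alleles[[a]]$sv$class, character(1))
  units$switch <- vapply(units$allele, function(a)
    as.character(defs$alleles[[a]]$sv$switch), character(1))
  if (any(units$class == "deletion"))
    stop("*5 cannot appear as a tandem unit")

  segment_cn <- setNames(integer(length(SEGMENTS_5TO3)), SEGMENTS_5TO3)
  variant_cn <- setNames(integer(nrow(defs$catalogue)),
                         defs$catalogue$g_label)
  for (i in seq_len(nrow(units))) {
    a <- defs$alleles[[units$allele[i]]]
    d6_side <- .segments_d6_side(a$sv)
    segment_cn[d6_side] <- segment_cn[d6_side] + 1L
    for (v in a$variants) variant_cn[v] <- variant_cn[v] + 1L
  }
  n67 <- sum(units$class == "d6d7")
  n76 <- sum(units$class == "d7d6")
  cn_full_d6 <- sum(units$class == "none")
  cn_total <- cn_full_d6 + 2L + n67 + n76  # one complete CYP2D7 per chromosome
  cn_spacer <- 2L + n67
  structure(list(
    genotype = genotype, haplotypes = haps, units = units,
    cn_total = cn_total, cn_spacer = cn_spacer, cn_full_d6 = cn_full_d6,
    d6_d7_hybrids = units$switch[units$class == "d6d7"],
    d7_d6_hybrids = units$switch[units$class == "d7d6"],
    segment_cn = segment_cn, variant_cn = variant_cn),
    class = "cyp_truth")
}

#' Simulate a counts-level evidence bundle for a diplotype
#'
#' Generates the full evidence a WGS alignment would yield for a sample of
#' the given diplotype, at the counts level: region read counts for the
#' combined CYP2D6+CYP2D7 gene region and the spacer (Poisson per-copy
#' depth, optional GC bias), a baseline panel of diploid windows spanning
#' the GC range, per-differentiating-site paralog support and per-variant
#' support (binomial/multinomial read splits with per-base error
#' contamination).  Fully reproducible from `seed`; with `exact = TRUE` the
#' noise-free expected values are emitted instead (rounded), emulating the
#' infinite-depth limit.
#'
#' @param genotype Diplotype string.
#' @param resources Resource bundle from [load_resources()].
#' @param seed Integer seed controlling all randomness.
#' @param params Parameter list from [cyp_params()]; `per_copy_depth = 15`
#'   corresponds to a 30x diploid genome.
#' @param gc_bias Optional function mapping a GC fraction to a depth
#'   multiplier, used to inject GC bias into region and baseline counts.
#' @param exact Emit deterministic expected counts instead of sampling.
#' @return An object of class `cyp_evidence`: list with `regions`,
#'   `baseline`, `site_support`, `variant_support`, `truth`, `meta`.
#' @export
simulate_counts <- function(genotype, resources, seed = NULL,
                            params = cyp_params(), gc_bias = NULL,
                            exact = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  truth <- expand_genotype(genotype, resources$defs)
  lambda <- params$per_copy_depth          # depth per copy (x units)
  rl <- params$read_length
  e <- if (exact) 0 else params$error_rate
  bias <- if (is.null(gc_bias)) function(gc) 1 else gc_bias
  draw <- function(mu) if (exact) round(mu) else rpois(length(mu), mu)

  gene_len <- GenomicRanges::width(resources$model$spans["d6"])
  spacer_len <- GenomicRanges::width(resources$model$spans["spacer"])
  gc_regions <- c(total = 0.45, spacer = 0.55)
  regions <- data.frame(
    region = c("total", "spacer"),
    read_count = c(
      draw(truth$cn_total * lambda * gene_len / rl *
             bias(gc_regions["total"])),
      draw(truth$cn_spacer * lambda * spacer_len / rl *
             bias(gc_regions["spacer"]))),
    unit_length = c(gene_len, spacer_len),
    gc = unname(gc_regions), stringsAsFactors = FALSE)

  # baseline panel: diploid windows spread across the GC working range
  n_win <- 500L
  win_len <- 2000L
  gc_win <- rep(seq(0.275, 0.725, by = 0.05), length.out = n_win)
  base_reads <- draw(2 * lambda * win_len / rl * vapply(gc_win, bias, 1))
  baseline <- data.frame(window = seq_len(n_win),
                         depth = base_reads * rl / win_len, gc = gc_win)

  # per-site paralog support: pooled pileup over both loci of each site
  panel <- resources$panel
  seg_cn <- truth$segment_cn[panel$segment]
  site_support <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    c6 <- seg_cn[[i]]
    c7 <- truth$cn_total - c6
    .split_reads(src = c(draw(c6 * lambda), draw(c7 * lambda)),
                 probs = rbind(c(1 - e, e / 3, 2 * e / 3),
                               c(e / 3, 1 - e, 2 * e / 3)),
                 exact = exact,
                 names = c("n_d6", "n_d7", "n_other"))
  }))
  site_support <- cbind(site_id = panel$site_id, site_support)

  # per-variant support: CYP2D6-derived copies split into alt and ref
  # carriers; homology SNVs additionally see the CYP2D7 copies, whose
  # paralog base lands in n_other
  cat_tab <- resources$defs$catalogue
  variant_support <- do.call(rbind, lapply(seq_len(nrow(cat_tab)),
                                           function(i) {
    n_copies <- truth$segment_cn[[cat_tab$segment[i]]]
    a <- truth$variant_cn[[cat_tab$g_label[i]]]
    stopifnot(a <= n_copies)
    src <- c(draw(a * lambda), draw((n_copies - a) * lambda))
    probs <- rbind(c(1 - e, e / 3, 2 * e / 3),
                   c(e / 3, 1 - e, 2 * e / 3))
    if (cat_tab$in_homology[i]) {
      m <- truth$cn_total - n_copies
      src <- c(src, draw(m * lambda))
      probs <- rbind(probs, c(e / 3, e / 3, 1 - 2 * e / 3))
    }
    .split_reads(src, probs, exact, c("n_alt", "n_ref", "n_other"))
  }))
  variant_support <- cbind(g_label = cat_tab$g_label, variant_support)

  structure(list(regions = regions, baseline = baseline,
                 site_support = site_support,
                 variant_support = variant_support, truth = truth,
                 meta = list(genotype = genotype, seed = seed,
                             per_copy_depth = lambda, exact = exact,
                             build = resources$defs$build)),
            class = "cyp_evidence")
}

# Distribute reads from each source class over outcome categories.
.split_reads <- function(src, probs, exact, names) {
  out <- numeric(ncol(probs))
  for (j in seq_along(src)) {
    if (src[j] == 0) next
    out <- out + if (exact) src[j] * probs[j, ]
                 else as.numeric(rmultinom(1, src[j], probs[j, ]))
  }
  res <- as.data.frame(as.list(round(out)))
  names(res) <- names
  res
}

#' Simulate a cohort of counts bundles
#'
#' @param genotypes Character vector of diplotype strings (one per sample).
#' @param resources Resource bundle.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param ... Passed to [simulate_counts()].
#' @return List of `cyp_evidence` bundles named `sample_1..n`.
#' @export
simulate_cohort <- function(genotypes, resources, seed = 1L, ...) {
  seeds <- seed + seq_along(genotypes) * 1013L
  out <- lapply(seq_along(genotypes), function(i)
    simulate_counts(genotypes[i], resources, seed = seeds[i] %% .Machine$integer.max, ...))
  names(out) <- paste0("sample_", seq_along(genotypes))
  out
}
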