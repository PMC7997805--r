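#' Collect read support for the catalogued small variants
#'
#' Builds the per-variant support table from a counts evidence bundle and
#' attaches each variant's CYP2D6-derived copy number at its position
#' (`site_total_cn`), taken from the segment consensus profile so that
#' hybrid copies containing the position are counted.  For variants inside
#' the CYP2D6/CYP2D7 homology regions the read counts are pooled across the
#' CYP2D6 position and its CYP2D7 mirror, so alternate reads misaligned to
#' the paralog are recovered; reads carrying the paralog base are excluded
#' from the denominator.  Variants in unique sequence use CYP2D6-aligned
#' reads only.
#'
#' @param evidence A `cyp_evidence` bundle.
#' @param defs Allele definitions from [load_allele_definitions()].
#' @param segments Segment profile from [consensus_segments()].
#' @param params Parameter list.
#' @return Data frame with columns `g_label`, `n_alt`, `n_ref`, `n_other`,
#'   `site_total_cn`, `informative`.
#' @export
collect_variant_support <- function(evidence, defs, segments,
                                    params = cyp_params()) {
  sup <- evidence$variant_support
  cat_tab <- defs$catalogue
  stopifnot(!is.null(sup), all(cat_tab$g_label %in% sup$g_label))
  sup <- sup[match(cat_tab$g_label, sup$g_label), ]
  seg_cn <- segments$cn[match(cat_tab$segment, segments$segment)]
  data.frame(g_label = cat_tab$g_label, n_alt = sup$n_alt,
             n_ref = sup$n_ref,
             n_other = if (!is.null(sup$n_other)) sup$n_other else 0L,
             site_total_cn = seg_cn,
             informative = (sup$n_alt + sup$n_ref) >= params$min_depth,
             stringsAsFactors = FALSE)
}

#' Call the copy number of a small variant
#'
#' Uses the same binomial-argmax machinery as [call_site_cn()], with the
#' variant's CYP2D6-derived copy number as the number of copies: a variant
#' can be called at any copy number between zero and the CYP2D6 CN at its
#' site.  A winning posterior below `min_posterior` yields a no-call.
#'
#' @param n_alt,n_ref Reads supporting the alternate and reference allele.
#' @param site_total_cn CYP2D6-derived copy number at the variant position.
#' @param eps Error floor.
#' @param min_posterior No-call threshold.
#' @return List with `cn_alt` (integer or `NA`) and `posterior`.
#' @export
call_variant_cn <- function(n_alt, n_ref, site_total_cn, eps = 0.01,
                            min_posterior = 0.95) {
  stopifnot(n_alt >= 0, n_ref >= 0, site_total_cn >= 0)
  res <- .binom_cn(n_alt, n_alt + n_ref, site_total_cn, eps = eps,
                   min_posterior = min_posterior)
  list(cn_alt = res$cn, posterior = res$posterior,
       posteriors = res$posteriors)
}

#' Call copy numbers for every catalogued variant
#'
#' @param support Variant support table from [collect_variant_support()].
#' @param params Parameter list.
#' @return `support` with added columns `cn_alt` and `posterior`.  Variants
#'   at uninformative depth, or whose segment has no consensus, are no-calls
#'   (`NA`) unless they have zero alternate reads, which call 0 copies.
#' @export
call_variant_cn_all <- function(support, params = cyp_params()) {
  res <- lapply(seq_len(nrow(support)), function(i) {
    if (support$n_alt[i] == 0L)
      return(list(cn_alt = 0L, posterior = 1))
    if (!support$informative[i] || is.na(support$site_total_cn[i]))
      return(list(cn_alt = NA_integer_, posterior = NA_real_))
    call_variant_cn(support$n_alt[i], support$n_ref[i],
                    support$site_total_cn[i], eps = params$eps,
                    min_posterior = params$min_posterior)
  })
  support$cn_alt <- vapply(res, function(r) as.integer(r$cn_alt),
                           integer(1))
  support$posterior <- vapply(res, `[[`, numeric(1), "posterior")
  support
}
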