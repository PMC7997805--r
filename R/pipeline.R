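#' Genotype one sample from a counts-level evidence bundle
#'
#' Runs the full calling chain: total and spacer copy number from
#' GC-corrected normalized depth, per-site paralog apportioning and segment
#' consensus, structural-variant typing, small-variant copy numbers, and
#' exact-cover diplotype resolution with CPIC phenotype translation.
#' A no-call at any required stage yields a no-call diplotype with the
#' stage's diagnostic; no-calls are data, not errors.
#'
#' @param evidence A `cyp_evidence` bundle (from [simulate_counts()] or
#'   [extract_evidence_bam()]).
#' @param resources Resource bundle from [load_resources()].
#' @param params Parameter list from [cyp_params()].
#' @return An object of class `cyp_call`: list with `diplotype`
#'   (`cyp_diplotype`), `phenotype`, `total_cn`, `segments`, `sv`,
#'   `site_cns`, `variant_calls`.
#' @export
genotype_sample <- function(evidence, resources,
                            params = cyp_params()) {
  total <- call_total_and_spacer(evidence, params)
  support <- gather_site_support(evidence, resources$panel, params)
  site_cns <- if (!is.na(total$cn_total))
    call_site_cn_all(support, total$cn_total, params)
  else cbind(support, raw_cn = NA_real_, called_cn = NA_integer_,
             posterior = NA_real_)
  segments <- consensus_segments(site_cns, total$cn_total, params)
  sv <- detect_sv(segments, total$cn_total, total$cn_spacer)
  var_support <- collect_variant_support(evidence, resources$defs,
                                         segments, params)
  variant_calls <- call_variant_cn_all(var_support, params)
  diplotype <- resolve_diplotype(sv, variant_calls, resources$defs)
  phenotype <- translate_phenotype(diplotype, resources$defs)
  structure(list(diplotype = diplotype, phenotype = phenotype,
                 total_cn = total, segments = segments, sv = sv,
                 site_cns = site_cns, variant_calls = variant_calls),
            class = "cyp_call")
}

#' @export
print.cyp_call <- function(x, ...) {
  print(x$diplotype)
  print(x$total_cn)
  print(x$sv)
  cat(sprintf("Phenotype: %s (activity score %s)\n", x$phenotype$category,
              ifelse(is.na(x$phenotype$activity_score), "unknown",
                     x$phenotype$activity_score)))
  invisible(x)
}

#' Summarize a call as a one-row data frame
#'
#' @param call A `cyp_call`.
#' @param sample Sample name.
#' @return Data frame with columns `sample`, `genotype`, `filter`,
#'   `cn_total`, `cn_spacer`, `phenotype`, `activity_score`.
#' @export
call_summary <- function(call, sample = NA_character_) {
  data.frame(sample = sample,
             genotype = call$diplotype$genotype,
             filter = call$diplotype$filter,
             cn_total = call$total_cn$cn_total,
             cn_spacer = call$total_cn$cn_spacer,
             phenotype = call$phenotype$category,
             activity_score = call$phenotype$activity_score,
             stringsAsFactors = FALSE)
}

#' Serialize a call (evidence and decisions) to JSON
#'
#' @param call A `cyp_call`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @param sample Sample name recorded in the document.
#' @return The JSON string, invisibly when written to `path`.
#' @export
call_to_json <- function(call, path = NULL, sample = NA_character_) {
  doc <- list(
    schema_version = "1.0",
    sample = sample,
    genotype = call$diplotype$genotype,
    filter = call$diplotype$filter,
    alternatives = call$diplotype$alternatives,
    phenotype = unclass(call$phenotype),
    cn_total = call$total_cn$cn_total,
    cn_spacer = call$total_cn$cn_spacer,
    depth_total = call$total_cn$depth_total,
    depth_spacer = call$total_cn$depth_spacer,
    qc_flags = call$total_cn$qc_flags,
    sv = unclass(call$sv),
    segments = as.data.frame(call$segments),
    variants = as.data.frame(call$variant_calls[
      !is.na(call$variant_calls$cn_alt) & call$variant_calls$cn_alt > 0 |
        is.na(call$variant_calls$cn_alt), ]))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
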