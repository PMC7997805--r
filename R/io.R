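#' Write a counts-level evidence bundle to a directory
#'
#' Serializes the bundle as four TSV files (`regions.tsv`, `baseline.tsv`,
#' `site_support.tsv`, `variant_support.tsv`) plus a small `meta.json`.
#'
#' @param evidence A `cyp_evidence` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evidence <- function(evidence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) write.table(
    df, file.path(dir, paste0(name, ".tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wr(evidence$regions, "regions")
  wr(evidence$baseline, "baseline")
  wr(evidence$site_support, "site_support")
  wr(evidence$variant_support, "variant_support")
  meta <- evidence$meta
  meta$truth_genotype <- if (!is.null(evidence$truth))
    evidence$truth$genotype
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a counts-level evidence bundle from a directory
#'
#' @param dir Directory written by [write_evidence()].
#' @return A `cyp_evidence` bundle (without the simulation truth).
#' @export
read_evidence <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) stop("missing evidence file: ", path)
    read.delim(path, stringsAsFactors = FALSE)
  }
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list()
  structure(list(regions = rd("regions"), baseline = rd("baseline"),
                 site_support = rd("site_support"),
                 variant_support = rd("variant_support"),
                 truth = NULL, meta = meta),
            class = "cyp_evidence")
}
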