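#' Load the build-specific CYP2D6/CYP2D7 region model
#'
#' Reads the packaged region table and returns a validated model of the
#' CYP2D6 locus on chromosome 22: the two gene spans, the near-identical
#' REP6/REP7 repeats, the unique 1.6 kb spacer between CYP2D7 and REP7, the
#' nine exons of each gene, and the intragenic homology regions where
#' cross-paralog misalignment is expected.  All coordinates are 1-based
#' inclusive (VCF/samtools convention).
#'
#' The model also carries the exon-anchored segmentation used for paralog
#' copy-number consensus: nine exon segments whose boundaries are the
#' midpoints of the introns, plus a 5' and a 3' flank segment.  Because
#' CYP2D6 is transcribed on the minus strand, the 5' flank has the highest
#' genomic coordinates.
#'
#' @param build Genome build, `"GRCh38"` or `"GRCh37"`.
#' @param path Optional override of the packaged region table (TSV).
#' @return An object of class `cyp_region_model`: a list with elements
#'   `build`, `chrom`, `spans` (named [GenomicRanges::GRanges] for
#'   `d6`, `d7`, `rep6`, `rep7`, `spacer`), `d6_exons`, `d7_exons`,
#'   `homology`, `segments` (data frame, 5' to 3'), and `d7_offset`.
#' @export
load_region_model <- function(build = c("GRCh38", "GRCh37"), path = NULL) {
  build <- tryCatch(match.arg(build),
                    error = function(e) stop("unsupported genome build: ",
                                             paste(build, collapse = ","),
                                             call. = FALSE))
  if (is.null(path))
    path <- system.file("extdata", "region_model.tsv", package = "cypstar",
                        mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$build == build, ]
  if (nrow(tab) == 0L) stop("no region records for build ", build)
  gr1 <- function(nm) {
    row <- tab[tab$name == nm, ]
    if (nrow(row) != 1L) stop("region model integrity: missing region ", nm)
    GenomicRanges::GRanges(row$chrom, IRanges(row$start, row$end))
  }
  spans <- do.call(c, lapply(c("d6", "d7", "rep6", "rep7", "spacer"), gr1))
  names(spans) <- c("d6", "d7", "rep6", "rep7", "spacer")
  exon_gr <- function(prefix) {
    rows <- tab[grepl(paste0("^", prefix, "_exon"), tab$name), ]
    rows <- rows[order(-rows$start), ]  # exon 1 first (minus strand)
    if (nrow(rows) != 9L)
      stop("region model integrity: expected 9 exons for ", prefix)
    gr <- GenomicRanges::GRanges(rows$chrom, IRanges(rows$start, rows$end))
    names(gr) <- paste0("exon", 1:9)
    gr
  }
  d6_exons <- exon_gr("d6")
  d7_exons <- exon_gr("d7")
  hom_rows <- tab[grepl("^homology", tab$name), ]
  homology <- GenomicRanges::GRanges(hom_rows$chrom,
                                     IRanges(hom_rows$start, hom_rows$end))

  model <- structure(list(
    build = build, chrom = tab$chrom[1], spans = spans,
    d6_exons = d6_exons, d7_exons = d7_exons, homology = homology,
    segments = .make_segments(spans["d6"], d6_exons),
    d7_offset = GenomicRanges::start(spans["d7"]) -
      GenomicRanges::start(spans["d6"])
  ), class = "cyp_region_model")
  .validate_region_model(model)
  model
}

# Exon-anchored segment intervals in D6 coordinates, ordered 5' -> 3'.
.make_segments <- function(d6_span, exons) {
  st <- GenomicRanges::start(exons)
  en <- GenomicRanges::end(exons)
  lo <- GenomicRanges::start(d6_span)
  hi <- GenomicRanges::end(d6_span)
  mids <- as.integer(floor((en[-1] + st[-9]) / 2))  # intron midpoints 1..8
  seg_start <- c(hi + 1L, mids + 1L, lo, lo - 400L)
  seg_end <- c(hi + 400L, hi, mids, lo - 1L)
  data.frame(segment = SEGMENTS_5TO3, start = seg_start, end = seg_end,
             stringsAsFactors = FALSE)
}

.validate_region_model <- function(m) {
  s <- m$spans
  # pairwise span overlap; the printed spacer/REP7 coordinates share one
  # boundary base, so a 1 bp touch is tolerated
  ov <- GenomicRanges::findOverlaps(s, s, minoverlap = 2L)
  ov <- ov[S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)]
  if (length(ov) > 0L) stop("region model integrity: overlapping spans")
  for (g in c("d6", "d7")) {
    exons <- if (g == "d6") m$d6_exons else m$d7_exons
    if (length(exons) != 9L) stop("expected 9 exons for ", g)
    if (!all(GenomicRanges::start(exons) >= GenomicRanges::start(s[g]) &
             GenomicRanges::end(exons) <= GenomicRanges::end(s[g])))
      stop("region model integrity: exons outside gene span for ", g)
  }
  if (!all(GenomicRanges::start(m$homology) >=
           GenomicRanges::start(s["d6"]) &
           GenomicRanges::end(m$homology) <= GenomicRanges::end(s["d6"])))
    stop("region model integrity: homology regions must lie within CYP2D6")
  invisible(m)
}

#' Locate the segment containing a CYP2D6 position
#'
#' @param model A `cyp_region_model`.
#' @param pos Genomic positions on the CYP2D6 (D6) side.
#' @return Character vector of segment names (`NA` outside all segments).
#' @export
segment_of <- function(model, pos) {
  segs <- model$segments
  vapply(pos, function(p) {
    hit <- which(p >= segs$start & p <= segs$end)
    if (length(hit) == 1L) segs$segment[hit] else NA_character_
  }, character(1))
}

#' Load the panel of CYP2D6/CYP2D7 differentiating sites
#'
#' The packaged panel contains exactly 117 reliable base positions at which
#' CYP2D6 and CYP2D7 differ.  Each site records its position in both
#' paralogs (for both genome builds), the gene-specific bases, and the
#' exon-anchored segment it belongs to.
#'
#' @inheritParams load_region_model
#' @param model Optional pre-loaded region model used to cross-check segment
#'   assignments.
#' @return A data frame of class `cyp_site_panel` with columns `site_id`,
#'   `d6_pos`, `d7_pos`, `d6_base`, `d7_base`, `segment`, sorted by
#'   increasing `d6_pos`.
#' @export
load_site_panel <- function(build = c("GRCh38", "GRCh37"), model = NULL,
                            path = NULL) {
  build <- match.arg(build)
  if (is.null(path))
    path <- system.file("extdata", "site_panel.tsv", package = "cypstar",
                        mustWork = TRUE)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  sel <- if (build == "GRCh38") c("d6_pos_grch38", "d7_pos_grch38")
         else c("d6_pos_grch37", "d7_pos_grch37")
  panel <- data.frame(site_id = raw$site_id, d6_pos = raw[[sel[1]]],
                      d7_pos = raw[[sel[2]]], d6_base = raw$d6_base,
                      d7_base = raw$d7_base, segment = raw$segment,
                      stringsAsFactors = FALSE)
  panel <- panel[order(panel$d6_pos), ]
  rownames(panel) <- NULL
  if (nrow(panel) != 117L)
    stop("site panel integrity: expected 117 sites, found ", nrow(panel))
  if (any(panel$d6_base == panel$d7_base))
    stop("site panel integrity: site with identical paralog bases")
  if (anyDuplicated(panel$d6_pos) || anyDuplicated(panel$d7_pos))
    stop("site panel integrity: duplicate positions")
  if (!all(panel$segment %in% SEGMENTS_5TO3))
    stop("site panel integrity: unknown segment label")
  n_per <- table(factor(panel$segment, levels = SEGMENTS_5TO3))
  if (any(n_per < 3L))
    stop("site panel integrity: every segment needs >= 3 sites")
  if (!is.null(model)) {
    want <- segment_of(model, panel$d6_pos)
    if (!identical(want, panel$segment))
      stop("site panel integrity: segment assignment disagrees with model")
  }
  class(panel) <- c("cyp_site_panel", "data.frame")
  attr(panel, "build") <- build
  panel
}

#' Load star-allele definitions and the variant catalogue
#'
#' Loads the packaged star-allele definition table (PharmVar-style, JSON)
#' together with the catalogue of star-allele-defining protein-changing small
#' variants.  Variants are keyed by their gene-relative `g.` label (e.g.
#' `g.100C>T`); per-build genomic positions and, for variants inside the
#' CYP2D6/CYP2D7 homology regions, the mirrored CYP2D7 position are attached
#' from the catalogue.  Structural requirements are encoded per allele as
#' `none`, `deletion`, `d6d7:<segment>` (CYP2D6-CYP2D7 hybrid whose last
#' CYP2D6-derived segment is `<segment>`), or `d7d6:<segment>`
#' (CYP2D7-CYP2D6 hybrid whose last CYP2D7-derived segment is `<segment>`).
#'
#' @inheritParams load_site_panel
#' @param defs_path,catalogue_path Optional file overrides.
#' @return A list of class `cyp_allele_defs` with elements `alleles` (named
#'   list), `catalogue` (data frame), `tandem_conventions`, and `build`.
#' @export
load_allele_definitions <- function(build = c("GRCh38", "GRCh37"),
                                    model = NULL, defs_path = NULL,
                                    catalogue_path = NULL) {
  build <- match.arg(build)
  if (is.null(defs_path))
    defs_path <- system.file("extdata", "allele_definitions.json",
                             package = "cypstar", mustWork = TRUE)
  if (is.null(catalogue_path))
    catalogue_path <- system.file("extdata", "variant_catalogue.tsv",
                                  package = "cypstar", mustWork = TRUE)
  cat_raw <- read.delim(catalogue_path, stringsAsFactors = FALSE)
  sel <- if (build == "GRCh38") c("d6_pos_grch38", "d7_mirror_grch38")
         else c("d6_pos_grch37", "d7_mirror_grch37")
  catalogue <- data.frame(
    g_label = cat_raw$g_label, ref = cat_raw$ref, alt = cat_raw$alt,
    type = cat_raw$type, segment = cat_raw$segment,
    in_homology = cat_raw$in_homology, pos = cat_raw[[sel[1]]],
    mirror_pos = cat_raw[[sel[2]]], stringsAsFactors = FALSE)
  if (anyDuplicated(catalogue$g_label))
    stop("variant catalogue integrity: duplicate g. labels")
  if (any(catalogue$in_homology & is.na(catalogue$mirror_pos)))
    stop("variant catalogue integrity: homology variant without mirror")
  if (!is.null(model)) {
    hom <- model$homology
    in_hom <- vapply(catalogue$pos, function(p)
      any(p >= GenomicRanges::start(hom) & p <= GenomicRanges::end(hom)),
      logical(1))
    bad <- catalogue$in_homology & !in_hom
    if (any(bad))
      stop("variant catalogue integrity: homology flag outside regions: ",
           paste(catalogue$g_label[bad], collapse = ","))
    seg <- segment_of(model, catalogue$pos)
    if (!identical(seg, catalogue$segment))
      stop("variant catalogue integrity: segment assignment mismatch")
  }

  js <- jsonlite::read_json(defs_path)
  alleles <- lapply(js$alleles, function(a) {
    sv <- .parse_sv(a$sv)
    score <- a$activity_score
    known <- !identical(score, "unknown")
    list(name = a$name,
         variants = as.character(unlist(a$variants)),
         sv = sv,
         activity = if (known) as.numeric(score) else NA_real_,
         activity_known = known,
         fun = a$fun,
         validated = isTRUE(a$validated))
  })
  names(alleles) <- vapply(alleles, `[[`, "", "name")
  if (anyDuplicated(names(alleles)))
    stop("allele definition integrity: duplicate allele names")
  if (length(alleles[["*1"]]$variants) != 0L)
    stop("allele definition integrity: *1 must have no defining variants")
  dangling <- setdiff(unlist(lapply(alleles, `[[`, "variants")),
                      catalogue$g_label)
  if (length(dangling) > 0L)
    stop("allele definition integrity: dangling variant keys: ",
         paste(dangling, collapse = ","))
  # defining variants of a hybrid allele must sit on its CYP2D6-derived part
  for (a in alleles) {
    if (a$sv$class %in% c("d6d7", "d7d6") && length(a$variants) > 0L) {
      segs <- catalogue$segment[match(a$variants, catalogue$g_label)]
      on_d6 <- .segments_d6_side(a$sv)
      if (!all(segs %in% on_d6))
        stop("allele definition integrity: ", a$name,
             " has defining variants outside its CYP2D6-derived part")
    }
  }
  structure(list(
    alleles = alleles, catalogue = catalogue,
    tandem_conventions = lapply(js$tandem_conventions, as.character),
    build = build), class = "cyp_allele_defs")
}

.parse_sv <- function(sv) {
  if (identical(sv, "none")) return(list(class = "none", switch = NA))
  if (identical(sv, "deletion")) return(list(class = "deletion", switch = NA))
  parts <- strsplit(sv, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("d6d7", "d7d6") ||
      !parts[2] %in% SEGMENTS_5TO3)
    stop("allele definition integrity: malformed sv requirement '", sv, "'")
  list(class = parts[1], switch = parts[2])
}

# Segments on the CYP2D6-derived side of a unit.
.segments_d6_side <- function(sv) {
  k <- match(sv$switch, SEGMENTS_5TO3)
  switch(sv$class,
         none = SEGMENTS_5TO3,
         deletion = character(0),
         d6d7 = SEGMENTS_5TO3[seq_len(k)],
         d7d6 = SEGMENTS_5TO3[-seq_len(k)])
}

#' Load all resources for a genome build
#'
#' @inheritParams load_region_model
#' @return A list of class `cyp_resources` with `model`, `panel`, `defs`.
#' @export
load_resources <- function(build = c("GRCh38", "GRCh37")) {
  build <- match.arg(build)
  model <- load_region_model(build)
  structure(list(model = model,
                 panel = load_site_panel(build, model = model),
                 defs = load_allele_definitions(build, model = model)),
            class = "cyp_resources")
}
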