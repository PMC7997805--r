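# Alignment-level evidence extraction.  All functions work on a
# coordinate-sorted, indexed BAM and a resource bundle whose coordinates
# match the BAM's contigs -- either genuine GRCh37/GRCh38 chromosome 22, or
# the miniature synthetic contig pair produced by simulate_bam() together
# with contig_resources().

.bam_flags <- function() Rsamtools::scanBamFlag(
  isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
  isDuplicate = FALSE, isSupplementaryAlignment = FALSE)

#' Count qualifying reads starting in a region
#'
#' Counts primary, non-duplicate, non-secondary/supplementary reads whose
#' alignment start lies inside the region(s).  Mapping quality is not
#' filtered: MAPQ 0 reads are included, because reads in the
#' CYP2D6/CYP2D7 homology cannot be placed uniquely and would otherwise be
#' lost.  Counting by alignment start avoids double counting at region
#' boundaries.
#'
#' @param bam Path to an indexed BAM file.
#' @param regions A [GenomicRanges::GRanges] of regions (may span several
#'   contigs); zero-width input returns 0.
#' @return Integer read count.
#' @export
count_region_reads <- function(bam, regions) {
  if (length(regions) == 0L) return(0L)
  bf <- Rsamtools::BamFile(bam)
  param <- Rsamtools::ScanBamParam(flag = .bam_flags(), what = "pos",
                                   which = regions)
  res <- Rsamtools::scanBam(bf, param = param)
  total <- 0L
  for (i in seq_along(res)) {
    pos <- res[[i]]$pos
    lo <- GenomicRanges::start(regions)[i]
    hi <- GenomicRanges::end(regions)[i]
    total <- total + sum(!is.na(pos) & pos >= lo & pos <= hi)
  }
  total
}

# Pileup base counts at a set of single-base positions.
# Returns data frame keyed by (chrom, pos, nucleotide).
.pileup_bases <- function(bam, chroms, positions, min_bq = 13L,
                          max_depth = 10000L) {
  gr <- GenomicRanges::GRanges(chroms, IRanges(positions, positions))
  pp <- Rsamtools::PileupParam(max_depth = max_depth, min_mapq = 0L,
                               min_base_quality = min_bq,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  sp <- Rsamtools::ScanBamParam(flag = .bam_flags(), which = gr)
  p <- Rsamtools::pileup(Rsamtools::BamFile(bam), scanBamParam = sp,
                         pileupParam = pp)
  data.frame(chrom = as.character(p$seqnames), pos = p$pos,
             nucleotide = as.character(p$nucleotide), count = p$count,
             stringsAsFactors = FALSE)
}

.pileup_count <- function(piles, chrom, pos, base) {
  hit <- piles$chrom == chrom & piles$pos == pos &
    piles$nucleotide == base
  if (any(hit)) sum(piles$count[hit]) else 0L
}

.pileup_depth <- function(piles, chrom, pos) {
  hit <- piles$chrom == chrom & piles$pos == pos
  if (any(hit)) sum(piles$count[hit]) else 0L
}

# Count CIGAR-declared indel events at a position.  `type` is "del" or
# "ins"; the declared event must match the expected length and start
# within `tol` bases of the expected start (left-alignment tolerance).
# Returns c(n_alt, n_ref) where n_ref counts reads spanning the locus
# without the event.
.count_indel_reads <- function(bam, chrom, pos, ref, alt, type, tol = 5L) {
  ev_len <- abs(nchar(ref) - nchar(alt))
  ev_start <- pos + 1L  # event begins after the anchor base
  gr <- GenomicRanges::GRanges(chrom, IRanges(pos - tol, pos + ev_len + tol))
  param <- Rsamtools::ScanBamParam(flag = .bam_flags(),
                                   what = c("pos", "cigar"), which = gr)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_alt <- 0L
  n_ref <- 0L
  op_letter <- if (type == "del") "D" else "I"
  for (i in seq_along(res$pos)) {
    cig <- res$cigar[i]
    if (is.na(cig)) next
    ops <- .parse_cigar(cig)
    refpos <- res$pos[i]
    found <- FALSE
    spans <- FALSE
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]
      len <- ops$len[j]
      if (op %in% c("M", "=", "X", "D", "N")) {
        if (op %in% c("M", "=", "X") && refpos <= pos &&
            refpos + len - 1L >= pos + ev_len)
          spans <- TRUE
        if (op == op_letter && op == "D" && len == ev_len &&
            abs(refpos - ev_start) <= tol)
          found <- TRUE
        refpos <- refpos + len
      } else if (op == "I") {
        if (type == "ins" && len == ev_len && abs(refpos - ev_start) <= tol)
          found <- TRUE
      }
    }
    if (found) n_alt <- n_alt + 1L
    else if (spans) n_ref <- n_ref + 1L
  }
  c(n_alt = n_alt, n_ref = n_ref)
}

.parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

#' Estimate the diploid baseline depth from a BAM
#'
#' Median per-base depth over a panel of presumed-diploid windows.
#'
#' @param bam Indexed BAM path.
#' @param windows [GenomicRanges::GRanges] of baseline windows.
#' @param read_length Read length in bases.
#' @return Data frame with columns `window`, `depth` (and `gc` if windows
#'   carry a `gc` metadata column).
#' @export
baseline_from_bam <- function(bam, windows, read_length = 150) {
  counts <- vapply(seq_along(windows), function(i)
    count_region_reads(bam, windows[i]), integer(1))
  out <- data.frame(window = seq_along(windows),
                    depth = counts * read_length /
                      GenomicRanges::width(windows))
  gc <- S4Vectors::mcols(windows)$gc
  if (!is.null(gc)) out$gc <- gc
  out
}

#' Extract a counts-level evidence bundle from a BAM
#'
#' Runs the full alignment-level extraction: MAPQ0-inclusive region read
#' counts for the combined gene region and the spacer, baseline depth from
#' the supplied windows, pooled pileup support at the 117 differentiating
#' sites (bases from both the CYP2D6 and the CYP2D7 locus of each site
#' pair), and per-variant support with homology-aware pooling (SNVs by
#' pileup base match at base quality >= `params$min_bq`; indels by
#' CIGAR-declared events with a 5 bp left-alignment tolerance, CYP2D6 locus
#' only).
#'
#' @param bam Indexed BAM path.
#' @param resources Resource bundle whose coordinates match the BAM
#'   contigs (see [contig_resources()] for simulated BAMs).
#' @param baseline_windows [GenomicRanges::GRanges] of diploid baseline
#'   windows.
#' @param params Parameter list.
#' @return A `cyp_evidence` bundle, directly usable by
#'   [genotype_sample()].
#' @export
extract_evidence_bam <- function(bam, resources, baseline_windows,
                                 params = cyp_params()) {
  model <- resources$model
  panel <- resources$panel
  cat_tab <- resources$defs$catalogue
  gene_regions <- c(model$spans["d6"], model$spans["d7"])
  n_total <- count_region_reads(bam, gene_regions)
  n_spacer <- count_region_reads(bam, model$spans["spacer"])
  regions <- data.frame(
    region = c("total", "spacer"),
    read_count = c(n_total, n_spacer),
    unit_length = c(GenomicRanges::width(model$spans["d6"]),
                    GenomicRanges::width(model$spans["spacer"])),
    gc = NA_real_, stringsAsFactors = FALSE)
  baseline <- baseline_from_bam(bam, baseline_windows, params$read_length)

  d6_chrom <- .side_chrom(panel, "d6", model)
  d7_chrom <- .side_chrom(panel, "d7", model)
  piles <- .pileup_bases(bam,
                         c(d6_chrom, d7_chrom),
                         c(panel$d6_pos, panel$d7_pos),
                         min_bq = params$min_bq)
  site_support <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    n6 <- .pileup_count(piles, d6_chrom[i], panel$d6_pos[i],
                        panel$d6_base[i]) +
      .pileup_count(piles, d7_chrom[i], panel$d7_pos[i], panel$d6_base[i])
    n7 <- .pileup_count(piles, d6_chrom[i], panel$d6_pos[i],
                        panel$d7_base[i]) +
      .pileup_count(piles, d7_chrom[i], panel$d7_pos[i], panel$d7_base[i])
    tot <- .pileup_depth(piles, d6_chrom[i], panel$d6_pos[i]) +
      .pileup_depth(piles, d7_chrom[i], panel$d7_pos[i])
    data.frame(site_id = panel$site_id[i], n_d6 = n6, n_d7 = n7,
               n_other = tot - n6 - n7)
  }))

  v6_chrom <- .side_chrom(cat_tab, "d6", model)
  v7_chrom <- .side_chrom(cat_tab, "d7", model)
  snv <- cat_tab$type == "snv"
  vpos <- c(cat_tab$pos[snv],
            cat_tab$mirror_pos[snv & cat_tab$in_homology])
  vchrom <- c(v6_chrom[snv], v7_chrom[snv & cat_tab$in_homology])
  vpiles <- .pileup_bases(bam, vchrom, vpos, min_bq = params$min_bq)
  variant_support <- do.call(rbind, lapply(seq_len(nrow(cat_tab)),
                                           function(i) {
    if (cat_tab$type[i] == "snv") {
      ref1 <- substr(cat_tab$ref[i], 1, 1)
      alt1 <- substr(cat_tab$alt[i], 1, 1)
      n_alt <- .pileup_count(vpiles, v6_chrom[i], cat_tab$pos[i], alt1)
      n_ref <- .pileup_count(vpiles, v6_chrom[i], cat_tab$pos[i], ref1)
      n_oth <- .pileup_depth(vpiles, v6_chrom[i], cat_tab$pos[i]) -
        n_alt - n_ref
      if (cat_tab$in_homology[i]) {
        n_alt <- n_alt + .pileup_count(vpiles, v7_chrom[i],
                                       cat_tab$mirror_pos[i], alt1)
        n_ref <- n_ref + .pileup_count(vpiles, v7_chrom[i],
                                       cat_tab$mirror_pos[i], ref1)
        n_oth <- n_oth + .pileup_depth(vpiles, v7_chrom[i],
                                       cat_tab$mirror_pos[i]) -
          .pileup_count(vpiles, v7_chrom[i], cat_tab$mirror_pos[i], alt1) -
          .pileup_count(vpiles, v7_chrom[i], cat_tab$mirror_pos[i], ref1)
      }
    } else {
      counts <- .count_indel_reads(bam, v6_chrom[i], cat_tab$pos[i],
                                   cat_tab$ref[i], cat_tab$alt[i],
                                   cat_tab$type[i])
      n_alt <- counts[["n_alt"]]
      n_ref <- counts[["n_ref"]]
      n_oth <- 0L
    }
    data.frame(g_label = cat_tab$g_label[i], n_alt = n_alt, n_ref = n_ref,
               n_other = n_oth)
  }))

  structure(list(regions = regions, baseline = baseline,
                 site_support = site_support,
                 variant_support = variant_support, truth = NULL,
                 meta = list(bam = bam, build = resources$defs$build)),
            class = "cyp_evidence")
}

# Chromosome carrying the d6/d7-side positions of a panel or catalogue
# table; plain chromosome-22 resources fall back to the model chromosome.
.side_chrom <- function(tab, side, model) {
  col <- paste0(side, "_chrom")
  if (col %in% names(tab)) return(tab[[col]])
  rep(model$chrom, nrow(tab))
}

#' Genotype one sample directly from a BAM
#'
#' Convenience wrapper: [extract_evidence_bam()] then [genotype_sample()].
#'
#' @inheritParams extract_evidence_bam
#' @return A `cyp_call`.
#' @export
genotype_bam <- function(bam, resources, baseline_windows,
                         params = cyp_params()) {
  ev <- extract_evidence_bam(bam, resources, baseline_windows, params)
  genotype_sample(ev, resources, params)
}
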