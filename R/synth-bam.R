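# Miniature BAM simulation.  Reads are placed on a synthetic two-contig
# reference (a CYP2D6-like and a CYP2D7-like contig embedding the
# differentiating-site panel and the variant catalogue) plus a diploid
# baseline contig, so the alignment-level extraction path can be exercised
# without any genome download.  A coordinate shim (contig_resources())
# maps the chromosome-22 resource coordinates onto the contigs.

.C6_ORIGIN <- 42125899L  # D6ctg coordinate = GRCh38 pos - origin
.C7_ORIGIN <- 42137899L  # D7ctg likewise
.C6_LEN <- 5501L
.C7_LEN <- 6801L
.BASE_LEN <- 40000L

.map6 <- function(p) as.integer(p - .C6_ORIGIN)
.map7 <- function(p) as.integer(p - .C7_ORIGIN)

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Map chromosome-22 resources onto the synthetic contig pair
#'
#' Returns a resource bundle whose region model, site panel and variant
#' catalogue carry coordinates on the miniature contigs (`D6ctg`,
#' `D7ctg`) written by [simulate_bam()], so the standard extraction path
#' ([extract_evidence_bam()]) runs unchanged against simulated BAMs.
#'
#' @param resources GRCh38 resource bundle from [load_resources()].
#' @return A shimmed `cyp_resources` bundle.
#' @export
contig_resources <- function(resources) {
  stopifnot(resources$defs$build == "GRCh38")
  model <- resources$model
  sp <- model$spans
  spans <- GenomicRanges::GRanges(
    c("D6ctg", "D7ctg", "D6ctg", "D7ctg", "D7ctg"),
    IRanges(c(.map6(GenomicRanges::start(sp["d6"])),
              .map7(GenomicRanges::start(sp["d7"])), 1L, 1L,
              .map7(GenomicRanges::start(sp["spacer"]))),
            c(.map6(GenomicRanges::end(sp["d6"])),
              .map7(GenomicRanges::end(sp["d7"])), 1L, 1L,
              .map7(GenomicRanges::end(sp["spacer"])))))
  names(spans) <- c("d6", "d7", "rep6", "rep7", "spacer")
  segments <- model$segments
  segments$start <- .map6(segments$start)
  segments$end <- .map6(segments$end)
  homology <- GenomicRanges::GRanges(
    "D6ctg", IRanges(.map6(GenomicRanges::start(model$homology)),
                     .map6(GenomicRanges::end(model$homology))))
  model2 <- structure(list(
    build = model$build, chrom = "D6ctg", spans = spans,
    d6_exons = NULL, d7_exons = NULL, homology = homology,
    segments = segments, d7_offset = NA_integer_),
    class = "cyp_region_model")

  panel <- resources$panel
  panel$d6_pos <- .map6(panel$d6_pos)
  panel$d7_pos <- .map7(panel$d7_pos)
  panel$d6_chrom <- "D6ctg"
  panel$d7_chrom <- "D7ctg"

  defs <- resources$defs
  defs$catalogue$pos <- .map6(defs$catalogue$pos)
  defs$catalogue$mirror_pos <- .map7(defs$catalogue$mirror_pos)
  defs$catalogue$d6_chrom <- "D6ctg"
  defs$catalogue$d7_chrom <- "D7ctg"

  structure(list(model = model2, panel = panel, defs = defs),
            class = "cyp_resources")
}

# Deterministic synthetic reference: random sequence with the
# differentiating bases, variant reference context and (for homology SNVs)
# a mirror base distinct from both ref and alt planted at the mapped
# positions.
.build_reference <- function(resources) {
  .with_seed(20260924, {
    bases <- c("A", "C", "G", "T")
    d6 <- sample(bases, .C6_LEN, replace = TRUE)
    d7 <- sample(bases, .C7_LEN, replace = TRUE)
    bg <- sample(bases, .BASE_LEN, replace = TRUE)
    panel <- resources$panel
    d6[.map6(panel$d6_pos)] <- panel$d6_base
    d7[.map7(panel$d7_pos)] <- panel$d7_base
    cat_tab <- resources$defs$catalogue
    for (i in seq_len(nrow(cat_tab))) {
      ref <- strsplit(cat_tab$ref[i], "")[[1]]
      p6 <- .map6(cat_tab$pos[i])
      d6[p6:(p6 + length(ref) - 1L)] <- ref
      if (cat_tab$in_homology[i]) {
        p7 <- .map7(cat_tab$mirror_pos[i])
        d7[p7] <- setdiff(bases, c(ref[1],
                                   substr(cat_tab$alt[i], 1, 1)))[1]
      }
    }
    list(D6ctg = paste(d6, collapse = ""),
         D7ctg = paste(d7, collapse = ""),
         BASE = paste(bg, collapse = ""))
  })
}

#' Baseline windows on the synthetic diploid contig
#'
#' @param n Number of windows.
#' @param width Window width in bases.
#' @return [GenomicRanges::GRanges] on the `BASE` contig.
#' @export
contig_baseline_windows <- function(n = 16L, width = 2500L) {
  stopifnot(n * width <= .BASE_LEN)
  GenomicRanges::GRanges("BASE",
                         IRanges(seq(1L, by = width, length.out = n),
                                 width = width))
}

#' Simulate a miniature BAM for a diplotype
#'
#' Generates single-end 150 bp reads for every gene copy implied by the
#' diplotype, placed on the synthetic contig pair: each copy's reads
#' follow its per-segment paralog origin (a CYP2D6-CYP2D7 hybrid switches
#' contig at its breakpoint, and CYP2D7-3' copies cover the spacer), reads
#' within the homology regions get MAPQ 0, star-allele-defining variants
#' are spelled into the reads of the copies that carry them (SNVs as base
#' substitutions, indels via their CIGAR), and sequencing errors are added
#' at `params$error_rate`.  A diploid background contig provides the depth
#' baseline.  The result is a coordinate-sorted, indexed BAM plus the
#' reference FASTA, ready for [extract_evidence_bam()] with
#' [contig_resources()].
#'
#' @param genotype Diplotype string.
#' @param resources GRCh38 resource bundle.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param params Parameter list; `per_copy_depth = 15` emulates a 30x
#'   diploid genome.
#' @return List with `bam`, `fasta`, `baseline_windows`, and `resources`
#'   (the contig-space shim).
#' @export
simulate_bam <- function(genotype, resources, dir = tempfile("cypbam"),
                         seed = NULL, params = cyp_params()) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shim <- contig_resources(resources)
  refs <- .build_reference(resources)
  truth <- expand_genotype(genotype, resources$defs)

  fasta <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(refs)), fasta)
  Rsamtools::indexFa(fasta)

  segs <- shim$model$segments            # D6ctg coordinates, 5'->3'
  spacer <- shim$model$spans["spacer"]   # D7ctg
  cat_tab <- shim$defs$catalogue
  rl <- params$read_length
  lam <- params$per_copy_depth

  # physical copies: star-allele units plus one complete CYP2D7 per
  # chromosome
  units <- truth$units
  copies <- lapply(seq_len(nrow(units)), function(i) list(
    d6_side = .segments_d6_side(resources$defs$alleles[[
      units$allele[i]]]$sv),
    variants = resources$defs$alleles[[units$allele[i]]]$variants))
  copies <- c(copies, rep(list(list(d6_side = character(0),
                                    variants = character(0))), 2L))

  reads <- list()
  emit <- function(chrom, pos, seq, cigar, mapq) {
    reads[[length(reads) + 1L]] <<- list(chrom = chrom, pos = pos,
                                         seq = seq, cigar = cigar,
                                         mapq = mapq)
  }
  hom <- shim$model$homology
  mapq_for <- function(chrom, start, end) {
    if (chrom != "D6ctg" && chrom != "D7ctg") return(60L)
    sh <- if (chrom == "D6ctg") 0L else 1200L  # mirrored homology on D7ctg
    lo <- GenomicRanges::start(hom) + sh
    hi <- GenomicRanges::end(hom) + sh
    if (any(start <= hi & end >= lo)) 0L else 60L
  }

  for (cp in copies) {
    cp_vars <- cat_tab[cat_tab$g_label %in% cp$variants, , drop = FALSE]
    # per-segment origin, 5'->3', then merged into maximal same-contig
    # runs (a physical copy is contiguous on its backbone)
    seg_loc <- lapply(seq_len(nrow(segs)), function(si) {
      seg <- segs$segment[si]
      if (seg %in% cp$d6_side)
        list(chrom = "D6ctg", lo = segs$start[si], hi = segs$end[si])
      else if (seg == "flank3")
        list(chrom = "D7ctg", lo = GenomicRanges::start(spacer),
             hi = GenomicRanges::end(spacer))
      else
        list(chrom = "D7ctg", lo = segs$start[si] + 1200L,
             hi = segs$end[si] + 1200L)
    })
    runs <- list()
    for (loc in seg_loc) {
      k <- length(runs)
      if (k > 0L && runs[[k]]$chrom == loc$chrom) {
        runs[[k]]$lo <- min(runs[[k]]$lo, loc$lo)
        runs[[k]]$hi <- max(runs[[k]]$hi, loc$hi)
      } else runs[[k + 1L]] <- loc
    }
    for (run in runs) {
      # starts may precede the run so every position keeps full coverage;
      # start counts inside the modelled regions stay Poisson(len * depth)
      ctg_max <- nchar(refs[[run$chrom]]) - rl + 1L
      lo_s <- max(1L, run$lo - rl + 1L)
      hi_s <- min(run$hi, ctg_max)
      n <- rpois(1, (hi_s - lo_s + 1L) * lam / rl)
      if (n == 0L) next
      starts <- sample(lo_s:hi_s, n, replace = TRUE)
      run_vars <- if (run$chrom == "D6ctg") cp_vars
                  else cp_vars[0, , drop = FALSE]
      for (s in starts) {
        rd <- .make_read(refs[[run$chrom]], s, rl, run_vars,
                         params$error_rate)
        emit(run$chrom, s, rd$seq, rd$cigar,
             mapq_for(run$chrom, s, s + rl - 1L))
      }
    }
  }
  # diploid baseline contig
  nb <- rpois(1, .BASE_LEN * 2 * lam / rl)
  for (s in sample(1:(.BASE_LEN - rl + 1L), nb, replace = TRUE)) {
    rd <- .make_read(refs$BASE, s, rl, NULL, params$error_rate)
    emit("BASE", s, rd$seq, rd$cigar, 60L)
  }

  bam <- .write_bam(reads, refs, dir)
  list(bam = bam, fasta = fasta,
       baseline_windows = contig_baseline_windows(), resources = shim)
}

# One read: reference substring with the copy's variants applied (SNV
# substitution, deletion/insertion with matching CIGAR) and uniform
# sequencing errors.
.make_read <- function(ref, start, rl, vars, error_rate) {
  seq <- substr(ref, start, start + rl - 1L)
  cigar <- paste0(rl, "M")
  if (!is.null(vars) && nrow(vars) > 0L) {
    for (i in seq_len(nrow(vars))) {
      pos <- vars$pos[i]
      type <- vars$type[i]
      off <- pos - start + 1L  # 1-based offset of the anchor base
      if (type == "snv") {
        if (off >= 1L && off <= rl)
          substr(seq, off, off) <- vars$alt[i]
      } else if (type == "del") {
        dlen <- nchar(vars$ref[i]) - nchar(vars$alt[i])
        if (off >= 1L && off <= rl - 1L) {
          m1 <- off
          m2 <- rl - m1
          seq <- paste0(substr(ref, start, pos),
                        substr(ref, pos + dlen + 1L,
                               pos + dlen + m2))
          cigar <- paste0(m1, "M", dlen, "D", m2, "M")
        }
      } else if (type == "ins") {
        ins <- substr(vars$alt[i], 2L, nchar(vars$alt[i]))
        ilen <- nchar(ins)
        if (off >= 1L && off <= rl - ilen - 1L) {
          m1 <- off
          m2 <- rl - m1 - ilen
          seq <- paste0(substr(ref, start, pos), ins,
                        substr(ref, pos + 1L, pos + m2))
          cigar <- paste0(m1, "M", ilen, "I", m2, "M")
        }
      }
    }
  }
  if (error_rate > 0) {
    n_err <- rbinom(1, nchar(seq), error_rate)
    if (n_err > 0L) {
      at <- sample(nchar(seq), n_err)
      for (p in at)
        substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(seq, p, p)), 1)
    }
  }
  list(seq = seq, cigar = cigar)
}

.write_bam <- function(reads, refs, dir) {
  sam <- file.path(dir, "sample.sam")
  con <- file(sam, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(refs),
                       vapply(refs, nchar, 1L))), con)
  ord <- order(match(vapply(reads, `[[`, "", "chrom"), names(refs)),
               vapply(reads, `[[`, 1L, "pos"))
  lines <- vapply(seq_along(ord), function(k) {
    r <- reads[[ord[k]]]
    sprintf("r%06d\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s", k, r$chrom,
            r$pos, r$mapq, r$cigar, r$seq,
            strrep("I", nchar(r$seq)))
  }, character(1))
  writeLines(lines, con)
  close(con)
  on.exit(NULL)
  bam <- Rsamtools::asBam(sam, file.path(dir, "sample"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}
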