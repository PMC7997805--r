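# Genotype-string grammar: "/" separates the two chromosomes, "+" joins the
# gene units of a tandem arrangement, "xN" marks N identical copies on one
# chromosome, ";" separates alternative genotypes.  "*5" denotes the
# CYP2D6-deleted chromosome (zero gene units).

#' Parse a diplotype string into per-chromosome gene units
#'
#' @param genotype Genotype string, e.g. `"*3/*68+*4"` or `"*1x2/*5"`.
#' @param defs Optional allele definitions; when given, unit names are
#'   validated against the definition table.
#' @return List of two character vectors of star-allele unit names (a
#'   deleted chromosome gives `character(0)`).
#' @export
parse_genotype <- function(genotype, defs = NULL) {
  genotype <- gsub("[[:space:]]", "", genotype)
  if (genotype == "" || is.na(genotype)) stop("empty genotype string")
  haps <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  if (length(haps) < 1L || length(haps) > 2L || any(haps == ""))
    stop("cannot parse genotype string '", genotype, "'")
  if (length(haps) == 1L) haps <- c(haps, "*5")  # hemizygous shorthand
  out <- lapply(haps, .parse_haplotype)
  if (!is.null(defs)) {
    unknown <- setdiff(unlist(out), names(defs$alleles))
    if (length(unknown) > 0L)
      stop("unknown star allele(s): ", paste(unknown, collapse = ","))
  }
  out
}

.parse_haplotype <- function(hap) {
  units <- strsplit(hap, "+", fixed = TRUE)[[1]]
  out <- character(0)
  for (u in units) {
    m <- regmatches(u, regexec("^(\\*[0-9]+(?:\\.[0-9]+)?)(?:x([0-9]+))?$", u))[[1]]
    if (length(m) == 0L) stop("cannot parse star-allele unit '", u, "'")
    n <- if (m[3] == "") 1L else as.integer(m[3])
    out <- c(out, rep(m[2], n))
  }
  if (identical(out, "*5")) return(character(0))
  if ("*5" %in% out) stop("*5 cannot be combined with other units")
  out
}

# Numeric-aware allele ordering: *4 < *10 < *68, sub-alleles after parents.
.allele_key <- function(allele) {
  m <- regmatches(allele, regexec("^\\*([0-9]+)(?:\\.([0-9]+))?$", allele))[[1]]
  as.numeric(m[2]) + if (m[3] == "") 0 else as.numeric(m[3]) / 1000
}

#' Format one chromosome's units as a haplotype string
#'
#' Pure duplications collapse to `xN`; mixed tandems list hybrid units
#' first, then full genes, each in numeric allele order.
#' @param units Character vector of unit allele names (empty = `"*5"`).
#' @param defs Allele definitions (used to order hybrids first).
#' @return Haplotype string.
#' @export
format_haplotype <- function(units, defs) {
  if (length(units) == 0L) return("*5")
  if (length(unique(units)) == 1L) {
    if (length(units) == 1L) return(units)
    return(paste0(units[1], "x", length(units)))
  }
  is_hybrid <- vapply(units, function(u)
    defs$alleles[[u]]$sv$class %in% c("d6d7", "d7d6"), logical(1))
  key <- vapply(units, .allele_key, numeric(1))
  units <- units[order(!is_hybrid, key)]
  paste(units, collapse = "+")
}

#' Format a diplotype from two unit vectors
#' @param hap1,hap2 Unit vectors as returned by [parse_genotype()].
#' @param defs Allele definitions.
#' @return Genotype string with chromosomes in canonical order.
#' @export
format_genotype <- function(hap1, hap2, defs) {
  s <- c(format_haplotype(hap1, defs), format_haplotype(hap2, defs))
  k <- vapply(s, function(x) .allele_key(strsplit(x, "[+x]")[[1]][1]),
              numeric(1))
  s <- s[order(k, s)]
  paste(s, collapse = "/")
}

#' Star-allele multiset of a genotype
#'
#' Expands a genotype string (or parsed haplotypes) into the sorted
#' multiset of star alleles, ignoring phasing and tandem grouping.  A
#' deleted chromosome contributes the allele `*5`.
#' @param genotype Genotype string or list of unit vectors.
#' @return Sorted character vector (with repeats).
#' @export
allele_multiset <- function(genotype) {
  haps <- if (is.character(genotype)) parse_genotype(genotype) else genotype
  units <- unlist(lapply(haps, function(h) if (length(h) == 0L) "*5" else h))
  units[order(vapply(units, .allele_key, numeric(1)), units)]
}

#' Compare two genotypes as star-allele multisets
#'
#' Two genotypes match when they carry the same multiset of star alleles,
#' even if the haplotype assignment (phasing or tandem grouping) differs.
#'
#' @param call Genotype string or `cyp_diplotype` object.
#' @param truth Genotype string.
#' @return `TRUE` or `FALSE`.
#' @export
genotype_match <- function(call, truth) {
  if (inherits(call, "cyp_diplotype")) {
    if (identical(call$filter, "no_call")) return(FALSE)
    call <- call$genotype
  }
  identical(allele_multiset(call), allele_multiset(truth))
}
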