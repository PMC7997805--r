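#' Check Mendelian consistency of a genotyped trio
#'
#' A trio is consistent when the child's two haplotypes can be assigned one
#' to each parent, with tandem arrangements inherited as atomic units.  When
#' the stated phasings are inconsistent, the check searches alternative
#' phasings of all three samples that preserve each sample's gene-unit
#' multiset (and therefore its copy-number evidence) — for example
#' `*1/*1` rephased as `*5/*1x2` when a parent carries a deletion.  A trio
#' is `inconsistent` only when no rephasing works, which requires a child
#' allele absent from both parents.
#'
#' @param child,mother,father Genotype strings or `cyp_diplotype` objects.
#' @param defs Allele definitions.
#' @return An object of class `cyp_trio`: list with `status`
#'   (`consistent`, `resolvable_by_rephasing`, `inconsistent`, or
#'   `not_evaluated` when any member is a no-call) and
#'   `proposed_rephasing` (named genotype strings, only for rephasing).
#' @export
check_trio <- function(child, mother, father, defs) {
  gt <- lapply(list(child = child, mother = mother, father = father),
               function(x) {
                 if (inherits(x, "cyp_diplotype")) {
                   if (identical(x$filter, "no_call")) return(NULL)
                   x <- x$genotype
                 }
                 if (is.na(x)) return(NULL)
                 parse_genotype(x, defs)
               })
  if (any(vapply(gt, is.null, logical(1))))
    return(structure(list(status = "not_evaluated",
                          proposed_rephasing = NULL), class = "cyp_trio"))

  hap_eq <- function(a, b) identical(sort(a), sort(b))
  transmits <- function(parent_haps, hap)
    hap_eq(parent_haps[[1]], hap) || hap_eq(parent_haps[[2]], hap)
  consistent_with <- function(ch, mo, fa)
    (transmits(mo, ch[[1]]) && transmits(fa, ch[[2]])) ||
    (transmits(mo, ch[[2]]) && transmits(fa, ch[[1]]))

  if (consistent_with(gt$child, gt$mother, gt$father))
    return(structure(list(status = "consistent",
                          proposed_rephasing = NULL), class = "cyp_trio"))

  rephasings <- function(haps) {
    units <- c(haps[[1]], haps[[2]])
    .partitions_all(units)
  }
  for (ch in rephasings(gt$child))
    for (mo in rephasings(gt$mother))
      for (fa in rephasings(gt$father))
        if (consistent_with(ch, mo, fa)) {
          prop <- c(child = format_genotype(ch[[1]], ch[[2]], defs),
                    mother = format_genotype(mo[[1]], mo[[2]], defs),
                    father = format_genotype(fa[[1]], fa[[2]], defs))
          return(structure(list(status = "resolvable_by_rephasing",
                                proposed_rephasing = prop),
                          class = "cyp_trio"))
        }
  structure(list(status = "inconsistent", proposed_rephasing = NULL),
            class = "cyp_trio")
}

# All unordered partitions of a unit multiset into two (possibly empty)
# chromosomes; empty side = deleted chromosome (*5).
.partitions_all <- function(units) {
  n <- length(units)
  if (n == 0L) return(list(list(character(0), character(0))))
  seen <- character(0)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    a <- sort(units[sel])
    b <- sort(units[!sel])
    key <- paste(paste(a, collapse = ","), paste(b, collapse = ","),
                 sep = "|")
    key2 <- paste(paste(b, collapse = ","), paste(a, collapse = ","),
                  sep = "|")
    if (key %in% seen || key2 %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(a, b)
  }
  out
}

#' Aggregate haplotype frequencies by population
#'
#' Counts each called sample's two haplotypes (tandem arrangements counted
#' as single haplotypes) and reports percent frequencies per population.
#' No-call samples contribute their two chromosomes to the `Unknown`
#' fraction, so each population column sums to 100.
#'
#' @param calls Data frame with columns `sample`, `population`, `genotype`
#'   (string, `NA` for no-call); an optional `filter` column marks no-calls
#'   (`"no_call"`).
#' @param defs Allele definitions (for haplotype normalization).
#' @return Data frame of class `cyp_freq_table` with columns `population`,
#'   `haplotype`, `count`, `percent`.
#' @export
aggregate_frequencies <- function(calls, defs) {
  stopifnot(all(c("sample", "population", "genotype") %in% names(calls)))
  if (nrow(calls) == 0L) stop("no calls to aggregate")
  no_call <- is.na(calls$genotype)
  if ("filter" %in% names(calls))
    no_call <- no_call | calls$filter == "no_call"
  out <- list()
  for (pop in unique(calls$population)) {
    sub <- calls[calls$population == pop, ]
    if (nrow(sub) == 0L) { warning("empty population ", pop); next }
    haps <- character(0)
    n_unknown <- 0L
    for (i in seq_len(nrow(sub))) {
      if (no_call[calls$population == pop][i]) {
        n_unknown <- n_unknown + 2L
        next
      }
      parsed <- parse_genotype(sub$genotype[i], defs)
      haps <- c(haps, vapply(parsed, format_haplotype, "", defs = defs))
    }
    tab <- table(haps)
    denom <- 2L * nrow(sub)
    rows <- data.frame(population = pop,
                       haplotype = c(names(tab), "Unknown"),
                       count = c(as.integer(tab), n_unknown),
                       stringsAsFactors = FALSE)
    rows$percent <- 100 * rows$count / denom
    out[[pop]] <- rows[rows$count > 0L | rows$haplotype == "Unknown", ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cyp_freq_table", "data.frame")
  res
}

#' Concordance of calls against a truth table
#'
#' Applies the star-allele multiset match rule per sample and summarizes
#' overall and per structural-variant stratum.  Strata are derived from the
#' truth genotype: `hybrid` when any allele requires a hybrid gene,
#' otherwise `deletion` when a chromosome is deleted, `duplication` when
#' one chromosome carries more than one complete gene, else `no_sv`.
#'
#' @param calls Data frame with columns `sample`, `genotype` (`NA` or a
#'   no-call marker counts as discordant).
#' @param truth Data frame with columns `sample`, `genotype`.
#' @param defs Allele definitions.
#' @return List of class `cyp_concordance`: `overall_percent`,
#'   `n_compared`, `n_concordant`, `by_stratum` (data frame), `excluded`
#'   (samples absent from the truth table).
#' @export
concordance <- function(calls, truth, defs) {
  stopifnot(all(c("sample", "genotype") %in% names(calls)),
            all(c("sample", "genotype") %in% names(truth)))
  excluded <- setdiff(calls$sample, truth$sample)
  if (length(excluded) > 0L)
    message("excluded (not in truth table): ",
            paste(excluded, collapse = ","))
  common <- intersect(calls$sample, truth$sample)
  res <- lapply(common, function(s) {
    called <- calls$genotype[calls$sample == s][1]
    tru <- truth$genotype[truth$sample == s][1]
    match <- !is.na(called) && genotype_match(called, tru)
    data.frame(sample = s, stratum = .sv_stratum(tru, defs),
               concordant = match, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  by_stratum <- do.call(rbind, lapply(
    c("deletion", "duplication", "hybrid", "no_sv"), function(st) {
      sub <- res[res$stratum == st, ]
      data.frame(stratum = st, n = nrow(sub),
                 concordant = sum(sub$concordant),
                 percent = if (nrow(sub)) 100 * mean(sub$concordant)
                           else NA_real_)
    }))
  structure(list(overall_percent = 100 * mean(res$concordant),
                 n_compared = nrow(res), n_concordant = sum(res$concordant),
                 by_stratum = by_stratum, per_sample = res,
                 excluded = excluded), class = "cyp_concordance")
}

.sv_stratum <- function(genotype, defs) {
  haps <- parse_genotype(genotype, defs)
  units <- unlist(haps)
  hyb <- any(vapply(units, function(u)
    defs$alleles[[u]]$sv$class %in% c("d6d7", "d7d6"), logical(1)))
  if (isTRUE(hyb)) return("hybrid")
  if (any(lengths(haps) == 0L)) return("deletion")
  full_per_hap <- vapply(haps, function(h)
    sum(vapply(h, function(u) defs$alleles[[u]]$sv$class == "none",
               logical(1))), integer(1))
  if (any(full_per_hap > 1L)) return("duplication")
  "no_sv"
}

#' @export
print.cyp_concordance <- function(x, ...) {
  cat(sprintf("Concordance: %d/%d (%.1f%%)\n", x$n_concordant,
              x$n_compared, x$overall_percent))
  print(x$by_stratum, row.names = FALSE)
  invisible(x)
}
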