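# Exact-cover diplotype resolution.
#
# A genotype explains the evidence when (a) its hybrid units match the
# structural-variant call's hybrid multiset, (b) it uses exactly the called
# number of complete CYP2D6 genes, and (c) summing the defining variants of
# all its units reproduces every called variant copy number exactly.
# Variants whose copy number is a no-call (posterior below threshold) do not
# constrain the search.  A chromosome with no CYP2D6-bearing unit is the
# deletion allele *5; *5 is introduced only when fewer than two gene-bearing
# units exist, so a plain two-copy sample resolves to *1/*1 rather than the
# depth-indistinguishable *5/*1x2 (trio data can revise such phasings, see
# check_trio()).

# All exact covers: each cover is a character vector of unit allele names
# (hybrids assigned to concrete hybrid alleles, full genes to full alleles).
.exact_covers <- function(sv, variants, defs) {
  called <- variants$cn_alt
  names(called) <- variants$g_label
  wildcard <- names(called)[is.na(called)]
  called <- called[!is.na(called)]

  hybrid_units <- c(if (length(sv$d6_d7_hybrids))
                      paste0("d6d7:", sv$d6_d7_hybrids),
                    if (length(sv$d7_d6_hybrids))
                      paste0("d7d6:", sv$d7_d6_hybrids))
  cand_for_unit <- lapply(hybrid_units, function(u) {
    names(Filter(function(a)
      paste0(a$sv$class, ":", a$sv$switch) == u, defs$alleles))
  })
  if (any(lengths(cand_for_unit) == 0L)) return(list())
  hyb_assigns <- if (length(hybrid_units) == 0L) list(character(0)) else {
    grid <- do.call(expand.grid,
                    c(cand_for_unit, stringsAsFactors = FALSE))
    assigns <- lapply(seq_len(nrow(grid)), function(i)
      sort(as.character(unlist(grid[i, ]))))
    unique(assigns)
  }

  full_alleles <- names(Filter(function(a) a$sv$class == "none",
                               defs$alleles))
  full_alleles <- full_alleles[order(vapply(full_alleles, .allele_key, 1))]

  covers <- list()
  for (hybs in hyb_assigns) {
    budget <- called
    ok <- TRUE
    for (h in hybs) for (v in defs$alleles[[h]]$variants) {
      if (v %in% wildcard) next
      if (is.na(budget[v]) || budget[v] < 1L) { ok <- FALSE } else
        budget[v] <- budget[v] - 1L
    }
    if (!ok) next
    fulls <- .full_covers(sv$cn_full_d6, budget, wildcard, full_alleles,
                          defs)
    for (f in fulls) covers[[length(covers) + 1L]] <- c(hybs, f)
  }
  unique(covers)
}

# Multisets of `slots` full alleles whose combined defining variants equal
# the remaining called budget exactly (wildcard variants unconstrained).
.full_covers <- function(slots, budget, wildcard, full_alleles, defs) {
  results <- list()
  recurse <- function(slots_left, budget, start, acc) {
    if (slots_left == 0L) {
      if (all(budget == 0L)) results[[length(results) + 1L]] <<- acc
      return(invisible())
    }
    for (idx in start:length(full_alleles)) {
      a <- full_alleles[idx]
      vars <- setdiff(defs$alleles[[a]]$variants, wildcard)
      if (length(vars) > 0L && any(budget[vars] < 1L)) next
      b2 <- budget
      if (length(vars) > 0L) b2[vars] <- b2[vars] - 1L
      recurse(slots_left - 1L, b2, idx, c(acc, a))
    }
  }
  if (slots == 0L) {
    if (all(budget == 0L)) return(list(character(0)))
    return(list())
  }
  recurse(slots, budget, 1L, character(0))
  results
}

# Unordered partitions of a unit multiset into two chromosomes.  With two
# or more units both chromosomes must carry at least one; with one unit the
# partner chromosome is *5; with none the genotype is *5/*5.
.partitions <- function(units) {
  n <- length(units)
  if (n == 0L) return(list(list(character(0), character(0))))
  if (n == 1L) return(list(list(units, character(0))))
  seen <- character(0)
  out <- list()
  for (mask in 1:(2^n - 2)) {
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

.partner_of <- function(allele, defs) {
  for (conv in defs$tandem_conventions)
    if (conv[1] == allele) return(conv[2])
  NA_character_
}

# Ranking keys for one phased genotype.  Lower is better.
.rank_keys <- function(hap1, hap2, defs) {
  all_units <- c(hap1, hap2)
  violations <- 0L
  for (chrom in list(hap1, hap2)) {
    for (h in chrom) {
      if (!defs$alleles[[h]]$sv$class %in% c("d6d7", "d7d6")) next
      p <- .partner_of(h, defs)
      if (!is.na(p) && p %in% all_units && !p %in% chrom)
        violations <- violations + 1L
    }
  }
  unconventional <- 0L
  for (chrom in list(hap1, hap2)) {
    if (length(chrom) <= 1L) next
    if (length(unique(chrom)) == 1L) next
    hybs <- chrom[vapply(chrom, function(u)
      defs$alleles[[u]]$sv$class %in% c("d6d7", "d7d6"), logical(1))]
    fulls <- setdiff(chrom, hybs)
    conventional <- length(unique(fulls)) == 1L && length(hybs) >= 1L &&
      sum(chrom %in% fulls[1]) == 1L &&
      all(vapply(hybs, function(h) {
        p <- .partner_of(h, defs)
        is.na(p) || p == fulls[1]
      }, logical(1)))
    if (!conventional) unconventional <- unconventional + 1L
  }
  c(violations, unconventional,
    length(unique(c(all_units, if (length(hap1) == 0L ||
                                   length(hap2) == 0L) "*5"))))
}

# Full search: every exact cover, every phasing, ranked.
.search_genotypes <- function(sv, variants, defs) {
  covers <- .exact_covers(sv, variants, defs)
  seen <- character(0)
  rows <- list()
  for (cov in covers) {
    for (part in .partitions(cov)) {
      g <- format_genotype(part[[1]], part[[2]], defs)
      if (g %in% seen) next
      seen <- c(seen, g)
      keys <- .rank_keys(part[[1]], part[[2]], defs)
      rows[[length(rows) + 1L]] <-
        list(genotype = g, hap1 = part[[1]], hap2 = part[[2]], keys = keys)
    }
  }
  if (length(rows) == 0L) return(rows)
  ord <- order(vapply(rows, function(r) r$keys[1], 1),
               vapply(rows, function(r) r$keys[2], 1),
               vapply(rows, function(r) r$keys[3], 1),
               vapply(rows, function(r) r$genotype, ""))
  rows[ord]
}

#' Enumerate candidate haplotypes consistent with the evidence
#'
#' Generates every haplotype (including tandem arrangements) that appears
#' in at least one genotype whose implied variants and structural-variant
#' units exactly reproduce the calls.  `*1` is generated for variant-free
#' complete CYP2D6 copies and `*5` for a chromosome left without CYP2D6.
#'
#' @param sv A `cyp_sv_call`.
#' @param variants Variant call table from [call_variant_cn_all()].
#' @param defs Allele definitions.
#' @return List of candidate haplotypes, each a list with `units`
#'   (character vector) and `label`.
#' @export
enumerate_haplotypes <- function(sv, variants, defs) {
  rows <- .search_genotypes(sv, variants, defs)
  out <- list()
  seen <- character(0)
  for (r in rows) for (h in list(r$hap1, r$hap2)) {
    lab <- format_haplotype(h, defs)
    if (lab %in% seen) next
    seen <- c(seen, lab)
    out[[length(out) + 1L]] <- list(units = h, label = lab)
  }
  out
}

#' Resolve the star-allele diplotype from structural and small-variant calls
#'
#' Performs an exact-cover search over unordered haplotype pairs: a pair is
#' kept only when its combined implied variant copy numbers and structural
#' units equal the calls exactly.  Consistent genotypes are ranked by (1)
#' use of known tandem conventions (a hybrid phased with its conventional
#' partner, duplications grouped as `xN`), (2) fewest distinct alleles, (3)
#' lexicographic order.  A unique top genotype passes; rank ties keep the
#' first genotype with filter `more_than_one_possible_genotype` and the
#' rest as alternatives; no consistent pair is a no-call carrying the
#' unexplained residue as a diagnostic.
#'
#' @inheritParams enumerate_haplotypes
#' @return An object of class `cyp_diplotype`: list with `genotype`,
#'   `hap1`, `hap2`, `filter`, `alternatives`, `diagnostics`.
#' @export
resolve_diplotype <- function(sv, variants, defs) {
  if (!identical(sv$status, "ok"))
    return(structure(list(genotype = NA_character_, hap1 = NULL,
                          hap2 = NULL, filter = "no_call",
                          alternatives = character(0),
                          diagnostics = paste("structural variant no-call:",
                                              sv$diagnostics)),
                     class = "cyp_diplotype"))
  rows <- .search_genotypes(sv, variants, defs)
  if (length(rows) == 0L) {
    resid <- variants$g_label[!is.na(variants$cn_alt) & variants$cn_alt > 0]
    return(structure(list(genotype = NA_character_, hap1 = NULL,
                          hap2 = NULL, filter = "no_call",
                          alternatives = character(0),
                          diagnostics = paste0(
                            "no genotype explains the evidence; called ",
                            "variants: ",
                            if (length(resid)) paste(resid, collapse = ",")
                            else "none")),
                     class = "cyp_diplotype"))
  }
  top <- rows[[1]]
  tie <- length(rows) > 1L &&
    identical(rows[[2]]$keys, top$keys)
  structure(list(
    genotype = top$genotype, hap1 = top$hap1, hap2 = top$hap2,
    filter = if (tie) "more_than_one_possible_genotype" else "PASS",
    alternatives = vapply(rows[-1], `[[`, "", "genotype"),
    diagnostics = NULL), class = "cyp_diplotype")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.cyp_diplotype <- function(x, ...) {
  cat(sprintf("CYP2D6 diplotype: %s [%s]\n",
              ifelse(is.na(x$genotype), "none", x$genotype), x$filter))
  if (length(x$alternatives) > 0L)
    cat("  alternatives:", paste(x$alternatives, collapse = "; "), "\n")
  if (!is.null(x$diagnostics)) cat("  ", x$diagnostics, "\n", sep = "")
  invisible(x)
}

#' Translate a diplotype into a CPIC metabolizer phenotype
#'
#' Sums the activity score of every star allele in the genotype multiset
#' (duplicated alleles counted per copy) and maps the sum to a metabolizer
#' category: 0 poor; (0, 1.25) intermediate; [1.25, 2.25] normal; above
#' 2.25 ultrarapid.  A genotype containing an allele with unknown activity,
#' or a no-call, is indeterminate.
#'
#' @param call A `cyp_diplotype` or genotype string.
#' @param defs Allele definitions (carrying the activity table).
#' @return An object of class `cyp_phenotype`: list with
#'   `activity_score` and `category`.
#' @export
translate_phenotype <- function(call, defs) {
  if (inherits(call, "cyp_diplotype")) {
    if (identical(call$filter, "no_call"))
      return(structure(list(activity_score = NA_real_,
                            category = "indeterminate"),
                       class = "cyp_phenotype"))
    call <- call$genotype
  }
  alleles <- allele_multiset(call)
  defs_hit <- defs$alleles[alleles]
  if (any(vapply(defs_hit, is.null, logical(1))))
    stop("unknown star allele in genotype '", call, "'")
  known <- vapply(defs_hit, `[[`, logical(1), "activity_known")
  if (!all(known))
    return(structure(list(activity_score = NA_real_,
                          category = "indeterminate"),
                     class = "cyp_phenotype"))
  s <- sum(vapply(defs_hit, `[[`, numeric(1), "activity"))
  category <- if (s == 0) "poor" else if (s < 1.25) "intermediate"
    else if (s <= 2.25) "normal" else "ultrarapid"
  structure(list(activity_score = s, category = category),
            class = "cyp_phenotype")
}
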