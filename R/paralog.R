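# Shared binomial-argmax machinery for integer CN apportioning.  Given k
# successes out of n informative reads and a total of N copies, evaluates
# L(i) = Binom(k | n, clamp(i/N, eps, 1-eps)) for i in 0..N and returns the
# maximum-posterior i under a uniform prior.
.binom_cn <- function(k, n, N, eps = 0.01, min_posterior = 0.95) {
  if (N == 0L)
    return(list(cn = 0L, posterior = 1, posteriors = c(`0` = 1)))
  if (n == 0L)
    return(list(cn = NA_integer_, posterior = NA_real_, posteriors = NULL))
  i <- 0:N
  p <- pmin(pmax(i / N, eps), 1 - eps)
  loglik <- dbinom(k, n, p, log = TRUE)
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  names(post) <- i
  best <- which.max(post)
  cn <- if (post[best] >= min_posterior) i[best] else NA_integer_
  list(cn = cn, posterior = unname(post[best]), posteriors = post)
}

#' Gather per-site paralog support from a counts evidence bundle
#'
#' Returns the per-differentiating-site read support table: reads matching
#' the CYP2D6-specific base (`n_d6`), the CYP2D7-specific base (`n_d7`), and
#' mismatching reads (`n_other`), pooled across both alignment loci of each
#' site pair.  Sites whose pooled informative depth (`n_d6 + n_d7`) is below
#' `params$min_depth` are flagged uninformative and excluded from segment
#' consensus.
#'
#' @param evidence A `cyp_evidence` bundle.
#' @param panel Site panel from [load_site_panel()].
#' @param params Parameter list from [cyp_params()].
#' @return Data frame with columns `site_id`, `segment`, `n_d6`, `n_d7`,
#'   `n_other`, `informative`.
#' @export
gather_site_support <- function(evidence, panel, params = cyp_params()) {
  sup <- evidence$site_support
  stopifnot(!is.null(sup), all(panel$site_id %in% sup$site_id))
  sup <- sup[match(panel$site_id, sup$site_id), ]
  data.frame(site_id = panel$site_id, segment = panel$segment,
             n_d6 = sup$n_d6, n_d7 = sup$n_d7, n_other = sup$n_other,
             informative = (sup$n_d6 + sup$n_d7) >= params$min_depth,
             stringsAsFactors = FALSE)
}

#' Call the CYP2D6 copy number at one differentiating site
#'
#' Apportions the called total copy number between the paralogs at a single
#' differentiating site by binomial likelihood: `L(i) = Binom(n_d6 |
#' n_d6 + n_d7, p_i)` with `p_i = clamp(i / cn_total, eps, 1 - eps)` for
#' `i = 0..cn_total`.  The maximum-posterior `i` under a uniform prior is
#' returned, or a no-call when the winning posterior is below
#' `min_posterior`.
#'
#' @param n_d6,n_d7 Reads supporting the CYP2D6 and CYP2D7 base.
#' @param cn_total Called combined CYP2D6+CYP2D7 copy number.
#' @param eps Error floor for the success probability.
#' @param min_posterior No-call threshold.
#' @return List with `raw_cn` (`cn_total * n_d6 / (n_d6 + n_d7)`),
#'   `called_cn` (integer or `NA`) and `posterior`.
#' @export
call_site_cn <- function(n_d6, n_d7, cn_total, eps = 0.01,
                         min_posterior = 0.95) {
  stopifnot(n_d6 >= 0, n_d7 >= 0, cn_total >= 0)
  n <- n_d6 + n_d7
  res <- .binom_cn(n_d6, n, cn_total, eps = eps,
                   min_posterior = min_posterior)
  raw <- if (n > 0) cn_total * n_d6 / n else NA_real_
  list(raw_cn = raw, called_cn = res$cn, posterior = res$posterior)
}

#' Call the CYP2D6 copy number at every panel site
#'
#' @param support Site support table from [gather_site_support()].
#' @param cn_total Called combined copy number.
#' @param params Parameter list.
#' @return `support` with added columns `raw_cn`, `called_cn`, `posterior`.
#' @export
call_site_cn_all <- function(support, cn_total, params = cyp_params()) {
  res <- lapply(seq_len(nrow(support)), function(i) {
    if (!support$informative[i])
      return(list(raw_cn = NA_real_, called_cn = NA_integer_,
                  posterior = NA_real_))
    call_site_cn(support$n_d6[i], support$n_d7[i], cn_total,
                 eps = params$eps, min_posterior = params$min_posterior)
  })
  support$raw_cn <- vapply(res, `[[`, numeric(1), "raw_cn")
  support$called_cn <- vapply(res, function(r)
    as.integer(r$called_cn), integer(1))
  support$posterior <- vapply(res, `[[`, numeric(1), "posterior")
  support
}

#' Form the per-segment CYP2D6 copy-number consensus
#'
#' Aggregates per-site calls into the exon-anchored segments (ordered 3' to
#' 5', i.e. flank3, exon9 .. exon1, flank5).  A segment needs at least
#' `params$min_sites` informative sites.  The primary consensus is the mode
#' of the called site copy numbers, accepted when it is supported by at
#' least `params$mode_frac` of the called sites (robust to single-site
#' misalignment artifacts).  When the site-level calls are inconclusive --
#' too few sites reach the posterior threshold individually, which is
#' common at high total copy number, or no value reaches the agreement
#' fraction -- the counts of all informative sites in the segment are
#' pooled and the same binomial machinery is applied to the pooled counts;
#' a genuinely mixed segment pools to a fraction between two copy states
#' and still ends as a no-call.
#'
#' @param site_cns Output of [call_site_cn_all()].
#' @param cn_total Called combined CYP2D6+CYP2D7 copy number (`NA` leaves
#'   every segment uncalled).
#' @param params Parameter list.
#' @return Data frame of class `cyp_segment_profile` with columns `segment`,
#'   `cn` (integer or `NA`), `n_sites` (informative sites), `n_called`,
#'   `agreement`, ordered 3' to 5'.
#' @export
consensus_segments <- function(site_cns, cn_total, params = cyp_params()) {
  seg_order <- rev(SEGMENTS_5TO3)  # 3' -> 5'
  rows <- lapply(seg_order, function(s) {
    sub <- site_cns[site_cns$segment == s, ]
    inf <- sub[sub$informative, , drop = FALSE]
    called <- sub$called_cn[!is.na(sub$called_cn)]
    n_called <- length(called)
    agreement <- NA_real_
    cn <- NA_integer_
    if (nrow(inf) >= params$min_sites && !is.na(cn_total)) {
      mode_cn <- NA_integer_
      if (n_called >= params$min_sites) {
        tab <- table(called)
        agreement <- max(tab) / n_called
        if (agreement >= params$mode_frac)
          mode_cn <- as.integer(names(tab)[which.max(tab)])
      }
      if (!is.na(mode_cn)) {
        cn <- mode_cn
      } else {
        pooled <- .binom_cn(sum(inf$n_d6), sum(inf$n_d6) + sum(inf$n_d7),
                            cn_total, eps = params$eps,
                            min_posterior = params$min_posterior)
        cn <- pooled$cn
      }
    }
    data.frame(segment = s, cn = cn, n_sites = nrow(inf),
               n_called = n_called, agreement = agreement)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cyp_segment_profile", "data.frame")
  out
}

#' Type structural variants from the segment profile and spacer arithmetic
#'
#' Reconciles three lines of evidence into a structural-variant call: (a)
#' `cn_total - cn_spacer` gives the number of genes that are CYP2D6-derived
#' at the 3' end (complete CYP2D6 plus CYP2D7-CYP2D6 hybrids) and must match
#' the 3'-most segment copy number; (b) each step up in CYP2D6 copy number
#' going 3' to 5' contributes a CYP2D6-CYP2D7 hybrid whose last
#' CYP2D6-derived segment is the 5' side of the step; (c) each step down
#' contributes a CYP2D7-CYP2D6 hybrid whose last CYP2D7-derived segment is
#' the 5' side of the step.  Uniform profiles classify as no-SV, deletion or
#' duplication of complete CYP2D6.  The minimal hybrid set consistent with
#' the profile is reported.
#'
#' Segments without consensus are imputed only when both called neighbours
#' agree (no step can hide there under the minimal-hybrid reading); an
#' uncalled 5'-flank copies its nearest called neighbour.  Any remaining
#' gap, or an arithmetic conflict, yields a structural-variant no-call with
#' a diagnostic instead of a guess.
#'
#' @param segments Segment profile from [consensus_segments()].
#' @param cn_total,cn_spacer Called total and spacer copy numbers.
#' @return An object of class `cyp_sv_call`: list with `cn_full_d6`,
#'   `cn_full_d7`, `d6_d7_hybrids` (character vector of switch segments),
#'   `d7_d6_hybrids` (likewise), `cn_d7_d6_hybrid`, `cn_d6_3prime`,
#'   `status` (`"ok"` or `"no_call"`), `diagnostics`.
#' @export
detect_sv <- function(segments, cn_total, cn_spacer) {
  fail <- function(msg) structure(list(
    cn_full_d6 = NA_integer_, cn_full_d7 = NA_integer_,
    d6_d7_hybrids = character(0), d7_d6_hybrids = character(0),
    cn_d7_d6_hybrid = NA_integer_, cn_d6_3prime = NA_integer_,
    status = "no_call", diagnostics = msg), class = "cyp_sv_call")

  if (is.na(cn_total) || is.na(cn_spacer))
    return(fail("total or spacer copy number is a no-call"))
  cn_d6_3prime <- cn_total - cn_spacer
  if (cn_d6_3prime < 0)
    return(fail("CN(spacer) exceeds CN(CYP2D6+CYP2D7)"))

  stopifnot(identical(segments$segment, rev(SEGMENTS_5TO3)))
  prof <- segments$cn  # 3' -> 5'
  prof <- .impute_profile(prof, cn_d6_3prime)
  if (anyNA(prof))
    return(fail(paste0("uncallable segment(s): ",
                       paste(segments$segment[is.na(prof)], collapse = ","))))
  if (prof[1] != cn_d6_3prime)
    return(fail(sprintf(
      "3'-most segment CN (%d) disagrees with CN(total)-CN(spacer) (%d)",
      prof[1], cn_d6_3prime)))

  seg_names <- segments$segment
  d6d7 <- character(0)
  d7d6 <- character(0)
  for (i in seq_len(length(prof) - 1L)) {
    step <- prof[i + 1L] - prof[i]
    if (step > 0) d6d7 <- c(d6d7, rep(seg_names[i + 1L], step))
    if (step < 0) d7d6 <- c(d7d6, rep(seg_names[i + 1L], -step))
  }
  full_d6 <- prof[1] - length(d7d6)
  full_d7 <- cn_total - full_d6 - length(d6d7) - length(d7d6)
  if (full_d6 < 0 || full_d7 < 0)
    return(fail("segment profile implies negative gene counts"))
  if (full_d7 + length(d6d7) != cn_spacer)
    return(fail(sprintf(
      "spacer arithmetic conflict: CN(spacer)=%d but profile implies %d",
      cn_spacer, full_d7 + length(d6d7))))
  structure(list(
    cn_full_d6 = as.integer(full_d6), cn_full_d7 = as.integer(full_d7),
    d6_d7_hybrids = d6d7, d7_d6_hybrids = d7d6,
    cn_d7_d6_hybrid = length(d7d6), cn_d6_3prime = as.integer(cn_d6_3prime),
    status = "ok", diagnostics = NULL), class = "cyp_sv_call")
}

# Fill uncalled segments only where no hybrid switch can hide in the gap:
# the 3'-most segment is anchored by the spacer arithmetic; an uncalled 5'
# flank copies exon 1 (no modelled switch lies in the 5' flank); interior
# gaps take the shared value of their flanking called segments.  Anything
# else stays NA and becomes a structural-variant no-call.
.impute_profile <- function(prof, cn_d6_3prime) {
  n <- length(prof)
  if (is.na(prof[1])) prof[1] <- cn_d6_3prime
  if (is.na(prof[n]) && !is.na(prof[n - 1L])) prof[n] <- prof[n - 1L]
  called <- which(!is.na(prof))
  for (g in which(is.na(prof))) {
    lo <- max(called[called < g], -Inf)
    hi <- min(called[called > g], Inf)
    if (is.finite(lo) && is.finite(hi) && prof[lo] == prof[hi])
      prof[g] <- prof[lo]
  }
  prof
}

#' @export
print.cyp_sv_call <- function(x, ...) {
  if (x$status != "ok") {
    cat("SV call: no-call (", x$diagnostics, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "SV call: %d full CYP2D6, %d full CYP2D7, %d D6-D7 hybrid(s)%s, %d D7-D6 hybrid(s)%s\n",
    x$cn_full_d6, x$cn_full_d7, length(x$d6_d7_hybrids),
    if (length(x$d6_d7_hybrids)) paste0(" [switch after ",
      paste(x$d6_d7_hybrids, collapse = ","), "]") else "",
    length(x$d7_d6_hybrids),
    if (length(x$d7_d6_hybrids)) paste0(" [switch after ",
      paste(x$d7_d6_hybrids, collapse = ","), "]") else ""))
  invisible(x)
}
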