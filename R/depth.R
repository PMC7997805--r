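#' GC-correct a depth observation against a baseline panel
#'
#' Scales per-window (or per-region) depth by the ratio of the overall
#' baseline median depth to the median depth of baseline windows falling in
#' the same GC bin.  GC bins are 0.05 wide between 0.25 and 0.75; fractions
#' outside that range are clamped into the nearest bin.  Correction factors
#' are clamped to `[0.5, 2]`; a clamped factor or an empty GC bin (which
#' falls back to the global median) raises a QC flag.
#'
#' @param depth Numeric vector of raw depths.
#' @param gc GC fraction of each window, same length as `depth`.
#' @param baseline Data frame with columns `depth` and `gc` describing the
#'   baseline panel of presumed-diploid regions.
#' @return List with `depth` (corrected), `factor`, and `qc_flags`.
#' @export
gc_correct <- function(depth, gc, baseline) {
  stopifnot(length(depth) == length(gc), nrow(baseline) > 0)
  global_med <- median(baseline$depth)
  if (!is.finite(global_med) || global_med <= 0)
    stop("baseline median depth must be positive")
  bin <- .gc_bin(gc)
  base_bin <- .gc_bin(baseline$gc)
  qc <- character(0)
  factor <- vapply(bin, function(b) {
    in_bin <- baseline$depth[base_bin == b]
    if (length(in_bin) == 0L) return(NA_real_)
    global_med / median(in_bin)
  }, numeric(1))
  if (anyNA(factor)) {
    qc <- c(qc, "gc_bin_empty")
    factor[is.na(factor)] <- 1
  }
  clamped <- factor < 0.5 | factor > 2
  if (any(clamped)) qc <- c(qc, "gc_factor_clamped")
  factor <- pmin(pmax(factor, 0.5), 2)
  list(depth = depth * factor, factor = factor, qc_flags = qc)
}

.gc_bin <- function(gc) {
  gc <- pmin(pmax(gc, 0.25), 0.7499)
  floor(gc / 0.05)
}

#' Normalize region depth to copy-number units
#'
#' Converts a region read count into normalized depth on the copy-number
#' scale: an unduplicated diploid locus scores 2.0, so the CYP2D6+CYP2D7
#' region of a sample without structural variant scores about 4.0.  The
#' combined gene region is normalized against the length of a single gene
#' unit so that each gene copy contributes one copy-number unit pair.
#'
#' @param read_count Number of qualifying reads whose alignment start falls
#'   in the region.
#' @param unit_length Length in bases of one copy of the counted unit.
#' @param baseline_depth Median per-base depth of the diploid baseline panel.
#' @param read_length Read length in bases.
#' @return Normalized depth (numeric scalar), `>= 0`.
#' @export
normalize_depth <- function(read_count, unit_length, baseline_depth,
                            read_length = 150) {
  if (!is.finite(baseline_depth) || baseline_depth <= 0)
    stop("baseline depth must be positive for normalization")
  stopifnot(read_count >= 0, unit_length > 0)
  2 * (read_count * read_length / unit_length) / baseline_depth
}

#' Call an integer copy number from normalized depth
#'
#' Gaussian mixture with components centred at the integers `0..max_cn`,
#' shared standard deviation and uniform prior.  The maximum-posterior
#' component is returned; when the maximum posterior falls below
#' `min_posterior` the call is `NA` (a no-call, not an error).
#'
#' @param value Normalized depth in copy-number units.
#' @param sigma Component standard deviation in copy-number units.
#' @param max_cn Largest modelled copy number.
#' @param min_posterior No-call threshold on the winning posterior.
#' @return List with `cn` (integer or `NA`), `posterior`, and the full
#'   `posteriors` vector (named `0..max_cn`, summing to 1).
#' @export
call_integer_cn <- function(value, sigma = 0.25, max_cn = 10L,
                            min_posterior = 0.95) {
  stopifnot(length(value) == 1L, value >= 0)
  k <- 0:max_cn
  loglik <- dnorm(value, mean = k, sd = sigma, log = TRUE)
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  names(post) <- k
  best <- which.max(post)
  cn <- if (post[best] >= min_posterior) k[best] else NA_integer_
  list(cn = cn, posterior = unname(post[best]), posteriors = post)
}

#' Call total CYP2D6+CYP2D7 and spacer copy number from counts evidence
#'
#' Runs the count -> GC-correct -> normalize -> mixture-call chain on the
#' combined CYP2D6+CYP2D7 gene region and on the unique spacer region of a
#' counts-level evidence bundle (see [simulate_counts()] or
#' [extract_evidence_bam()]).  GC correction is applied when the bundle
#' carries GC annotation for its regions and baseline windows; otherwise the
#' depths are used as-is and a `gc_uncorrected` QC flag is recorded.
#'
#' @param evidence A `cyp_evidence` bundle.
#' @param params Parameter list from [cyp_params()].
#' @return An object of class `cyp_total_cn`: list with `cn_total`,
#'   `cn_spacer`, `posterior_total`, `posterior_spacer`, `depth_total`,
#'   `depth_spacer`, `baseline_depth`, `qc_flags`.
#' @export
call_total_and_spacer <- function(evidence, params = cyp_params()) {
  regions <- evidence$regions
  stopifnot(all(c("total", "spacer") %in% regions$region))
  baseline <- evidence$baseline
  if (is.null(baseline) || nrow(baseline) == 0L)
    stop("evidence bundle has no baseline panel")
  if (sum(regions$read_count) == 0L)
    stop("no reads observed in the CYP2D6/CYP2D7 regions")
  base_depth <- median(baseline$depth)
  qc <- character(0)

  one <- function(name, sigma) {
    row <- regions[regions$region == name, , drop = FALSE]
    depth <- row$read_count * params$read_length / row$unit_length
    if (!is.null(row$gc) && !is.na(row$gc) && !is.null(baseline$gc)) {
      corr <- gc_correct(depth, row$gc, baseline)
      depth <- corr$depth
      qc <<- union(qc, corr$qc_flags)
    } else {
      qc <<- union(qc, "gc_uncorrected")
    }
    value <- 2 * depth / base_depth
    call_integer_cn(value, sigma = sigma, max_cn = params$max_cn,
                    min_posterior = params$min_posterior)
  }
  tot <- one("total", params$sigma_total)
  spc <- one("spacer", params$sigma_spacer)
  dt <- function(x) 2 * x / base_depth
  row_depth <- function(name) {
    row <- regions[regions$region == name, ]
    row$read_count * params$read_length / row$unit_length
  }
  structure(list(
    cn_total = tot$cn, cn_spacer = spc$cn,
    posterior_total = tot$posterior, posterior_spacer = spc$posterior,
    depth_total = dt(row_depth("total")),
    depth_spacer = dt(row_depth("spacer")),
    baseline_depth = base_depth, qc_flags = qc), class = "cyp_total_cn")
}

#' @export
print.cyp_total_cn <- function(x, ...) {
  cat(sprintf("CN(CYP2D6+CYP2D7) = %s (depth %.2f, posterior %.3f)\n",
              ifelse(is.na(x$cn_total), "no-call", x$cn_total),
              x$depth_total, x$posterior_total))
  cat(sprintf("CN(spacer)        = %s (depth %.2f, posterior %.3f)\n",
              ifelse(is.na(x$cn_spacer), "no-call", x$cn_spacer),
              x$depth_spacer, x$posterior_spacer))
  invisible(x)
}
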