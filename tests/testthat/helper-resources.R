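# Shared fixtures: resources are loaded once per run; all simulated
# evidence is generated in code under fixed seeds.

res38 <- load_resources("GRCh38")
res37 <- load_resources("GRCh37")

# The eight structural archetypes with distinct depth signatures:
# no SV, deletion, duplication, D7-D6 hybrid, D6-D7 hybrids (exon-8 and
# exon-1 switch), hybrid tandem, and two different hybrids in one sample.
sv_archetypes <- c("*1/*1", "*1/*5", "*1x2/*1", "*13/*1", "*36/*1",
                   "*3/*68+*4", "*13+*2/*1", "*13/*68")

# Round-trip panel: every validated star allele paired with *1, plus the
# tandem arrangements and duplications the definitions model.  (*4x2/*5 is
# depth-indistinguishable from *4/*4 and is deliberately absent.)
roundtrip_panel <- function(defs) {
  validated <- names(Filter(function(a) a$validated, defs$alleles))
  c(paste0(setdiff(validated, "*5"), "/*1"), "*5/*1",
    "*36+*10/*1", "*36+*36+*10/*1", "*36+*36+*36+*10/*2",
    "*68+*4/*1", "*68+*68+*4/*1", "*13+*2/*1", "*4.013+*4/*1",
    "*1x2/*1", "*2x2/*2", "*13/*68", "*36+*36/*1",
    "*36+*36+*83+*10/*1")
}

# Independent brute-force oracle for binomial integer-CN apportioning:
# likelihoods written out directly from the binomial mass formula.
oracle_binom_cn <- function(k, n, N, eps = 0.01, cutoff = 0.95) {
  i <- 0:N
  p <- pmin(pmax(i / N, eps), 1 - eps)
  loglik <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  best <- which.max(post)
  list(cn = if (post[best] >= cutoff) i[best] else NA_integer_,
       posterior = post[best])
}

# Independent oracle for the depth mixture: densities written out from the
# Gaussian formula on the integer grid.
oracle_gmm_cn <- function(v, sigma, max_cn = 10L, cutoff = 0.95) {
  k <- 0:max_cn
  dens <- exp(-(v - k)^2 / (2 * sigma^2))
  post <- dens / sum(dens)
  best <- which.max(post)
  list(cn = if (post[best] >= cutoff) k[best] else NA_integer_,
       posterior = post[best])
}

sv_matches_truth <- function(sv, truth) {
  identical(sv$status, "ok") &&
    sv$cn_full_d6 == truth$cn_full_d6 &&
    identical(sort(sv$d6_d7_hybrids), sort(truth$d6_d7_hybrids)) &&
    identical(sort(sv$d7_d6_hybrids), sort(truth$d7_d6_hybrids))
}
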