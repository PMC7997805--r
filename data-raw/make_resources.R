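# Generates the curated resource tables under inst/extdata.
# Run once from the repo root: Rscript data-raw/make_resources.R

set.seed(220622)

D7_OFFSET   <- 13200L   # constant CYP2D6 -> CYP2D7 position shift (GRCh38)
B37_OFFSET  <- 396002L  # GRCh38 -> GRCh37 chr22 shift in this region

## ---- region model (GRCh38) --------------------------------------------
d6 <- c(42126499L, 42130810L)
exons <- list(
  exon1 = c(42130612L, 42130810L),
  exon2 = c(42129738L, 42129909L),
  exon3 = c(42129033L, 42129185L),
  exon4 = c(42128784L, 42128944L),
  exon5 = c(42128174L, 42128350L),
  exon6 = c(42127842L, 42127983L),
  exon7 = c(42127447L, 42127634L),
  exon8 = c(42127008L, 42127171L),
  exon9 = c(42126499L, 42126752L)
)
regions <- rbind(
  data.frame(name = "d6",     start = d6[1],      end = d6[2]),
  data.frame(name = "d7",     start = d6[1] + D7_OFFSET, end = d6[2] + D7_OFFSET),
  data.frame(name = "rep6",   start = 42123192L,  end = 42125972L),
  data.frame(name = "rep7",   start = 42135344L,  end = 42138124L),
  data.frame(name = "spacer", start = 42138124L,  end = 42139676L),
  data.frame(name = paste0("d6_", names(exons)),
             start = vapply(exons, `[`, 0L, 1), end = vapply(exons, `[`, 0L, 2)),
  data.frame(name = paste0("d7_", names(exons)),
             start = vapply(exons, `[`, 0L, 1) + D7_OFFSET,
             end   = vapply(exons, `[`, 0L, 2) + D7_OFFSET),
  data.frame(name = c("homology1", "homology2"),
             start = c(42127800L, 42129650L), end = c(42128300L, 42130050L))
)
rm38 <- cbind(build = "GRCh38", chrom = "chr22", regions)
rm37 <- cbind(build = "GRCh37", chrom = "chr22", regions)
rm37$start <- rm37$start + B37_OFFSET
rm37$end   <- rm37$end + B37_OFFSET
write.table(rbind(rm38, rm37), "inst/extdata/region_model.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- segment intervals (derived the same way the package does) ---------
mid <- function(a, b) as.integer(floor((a + b) / 2))
segs <- data.frame(
  segment = c("flank5", names(exons), "flank3"),
  start = c(d6[2] + 1L,
            mid(exons$exon2[2], exons$exon1[1]) + 1L,
            mid(exons$exon3[2], exons$exon2[1]) + 1L,
            mid(exons$exon4[2], exons$exon3[1]) + 1L,
            mid(exons$exon5[2], exons$exon4[1]) + 1L,
            mid(exons$exon6[2], exons$exon5[1]) + 1L,
            mid(exons$exon7[2], exons$exon6[1]) + 1L,
            mid(exons$exon8[2], exons$exon7[1]) + 1L,
            mid(exons$exon9[2], exons$exon8[1]) + 1L,
            d6[1],
            d6[1] - 400L),
  end = c(d6[2] + 400L,
          d6[2],
          mid(exons$exon2[2], exons$exon1[1]),
          mid(exons$exon3[2], exons$exon2[1]),
          mid(exons$exon4[2], exons$exon3[1]),
          mid(exons$exon5[2], exons$exon4[1]),
          mid(exons$exon6[2], exons$exon5[1]),
          mid(exons$exon7[2], exons$exon6[1]),
          mid(exons$exon8[2], exons$exon7[1]),
          mid(exons$exon9[2], exons$exon8[1]),
          d6[1] - 1L)
)
print(segs)

## ---- variant catalogue --------------------------------------------------
# g. numbering: g.1 at the 5' end of CYP2D6 (position 42130810, minus strand),
# genomic = 42130810 - (g - 1).
gpos <- function(g) 42130810L - (g - 1L)
vc <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
g_label      g     ref  alt   type
g.5C>G       5     C    G     snv
g.19G>A      19    G    A     snv
g.31G>A      31    G    A     snv
g.77G>A      77    G    A     snv
g.82C>T      82    C    T     snv
g.100C>T     100   C    T     snv
g.125G>A     125   G    A     snv
g.137insT    137   A    AT    ins
g.237A>C     237   A    C     snv
g.883G>C     883   G    C     snv
g.939C>T     939   C    T     snv
g.1012G>A    1012  G    A     snv
g.1022C>T    1022  C    T     snv
g.1513C>T    1513  C    T     snv
g.1598A>G    1598  A    G     snv
g.1611T>A    1611  T    A     snv
g.1660G>A    1660  G    A     snv
g.1704C>G    1704  C    G     snv
g.1708delT   1708  AT   A     del
g.1716G>A    1716  G    A     snv
g.1759G>A    1759  G    A     snv
g.1847G>A    1847  G    A     snv
g.1863insTTT 1863  A    ATTT  ins
g.2225C>T    2225  C    T     snv
g.2549delA   2549  CA   C     del
g.2573insC   2573  G    GC    ins
g.2616delAAG 2616  TAAG T     del
g.2851C>T    2851  C    T     snv
g.2936A>C    2936  A    C     snv
g.2939G>A    2939  G    A     snv
g.2989G>A    2989  G    A     snv
g.3184G>A    3184  G    A     snv
g.3201C>T    3201  C    T     snv
g.3254T>C    3254  T    C     snv
g.3877G>C    3877  G    C     snv
g.4042G>A    4042  G    A     snv
g.4181G>C    4181  G    C     snv
g.4222G>C    4222  G    C     snv
")
vc$d6_pos_grch38 <- gpos(vc$g)
stopifnot(!anyDuplicated(vc$d6_pos_grch38),
          all(vc$d6_pos_grch38 >= d6[1] & vc$d6_pos_grch38 <= d6[2]))
hom <- regions[regions$name %in% c("homology1", "homology2"), ]
# only SNVs take part in cross-paralog read pooling; indel events are counted
# at the CYP2D6 locus alone
vc$in_homology <- vapply(vc$d6_pos_grch38, function(p)
  any(p >= hom$start & p <= hom$end), TRUE) & vc$type == "snv"
vc$d7_mirror_grch38 <- ifelse(vc$in_homology, vc$d6_pos_grch38 + D7_OFFSET, NA)
vc$segment <- vapply(vc$d6_pos_grch38, function(p)
  segs$segment[p >= segs$start & p <= segs$end][1], "")
vc$d6_pos_grch37 <- vc$d6_pos_grch38 + B37_OFFSET
vc$d7_mirror_grch37 <- vc$d7_mirror_grch38 + B37_OFFSET
out <- vc[, c("g_label", "ref", "alt", "type", "segment", "in_homology",
              "d6_pos_grch37", "d6_pos_grch38",
              "d7_mirror_grch37", "d7_mirror_grch38")]
write.table(out, "inst/extdata/variant_catalogue.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE, na = "")
cat("variants in homology:", sum(vc$in_homology), "\n")
print(table(vc$segment))

## ---- 117-site differentiating panel ------------------------------------
n_per <- c(flank5 = 6, exon1 = 12, exon2 = 12, exon3 = 11, exon4 = 11,
           exon5 = 11, exon6 = 11, exon7 = 11, exon8 = 11, exon9 = 12,
           flank3 = 9)
stopifnot(sum(n_per) == 117)
bases <- c("A", "C", "G", "T")
taken <- vc$d6_pos_grch38
rows <- list()
for (s in segs$segment) {
  k <- n_per[[s]]
  iv <- segs[segs$segment == s, ]
  pos <- as.integer(round(seq(iv$start + 60, iv$end - 60, length.out = k)))
  while (any(pos %in% taken) || anyDuplicated(pos))
    pos[pos %in% taken | duplicated(pos)] <- pos[pos %in% taken | duplicated(pos)] + 1L
  taken <- c(taken, pos)
  rows[[s]] <- data.frame(d6_pos_grch38 = pos, segment = s)
}
panel <- do.call(rbind, rows)
panel <- panel[order(panel$d6_pos_grch38), ]
panel$site_id <- seq_len(nrow(panel))
i <- seq_len(nrow(panel))
panel$d6_base <- bases[(i %% 4) + 1]
panel$d7_base <- bases[((i + 1) %% 4) + 1]
panel$d7_pos_grch38 <- panel$d6_pos_grch38 + D7_OFFSET
panel$d6_pos_grch37 <- panel$d6_pos_grch38 + B37_OFFSET
panel$d7_pos_grch37 <- panel$d7_pos_grch38 + B37_OFFSET
panel <- panel[, c("site_id", "d6_pos_grch37", "d6_pos_grch38",
                   "d7_pos_grch37", "d7_pos_grch38",
                   "d6_base", "d7_base", "segment")]
stopifnot(nrow(panel) == 117, all(panel$d6_base != panel$d7_base))
write.table(panel, "inst/extdata/site_panel.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- star-allele definitions -------------------------------------------
al <- function(name, variants, sv = "none", score, fn, validated = TRUE)
  list(name = name, variants = as.list(variants), sv = sv,
       activity_score = score, fun = fn, validated = validated)
defs <- list(
  al("*1",  character(0), "none", 1,   "normal"),
  al("*2",  c("g.2851C>T", "g.4181G>C"), "none", 1, "normal"),
  al("*3",  "g.2549delA", "none", 0, "no"),
  al("*4",  c("g.100C>T", "g.1847G>A"), "none", 0, "no"),
  al("*4.013", "g.1847G>A", "d7d6:exon1", 0, "no", validated = FALSE),
  al("*5",  character(0), "deletion", 0, "no"),
  al("*6",  "g.1708delT", "none", 0, "no"),
  al("*7",  "g.2936A>C", "none", 0, "no"),
  al("*9",  "g.2616delAAG", "none", 0.5, "decreased"),
  al("*10", c("g.100C>T", "g.4181G>C"), "none", 0.25, "decreased"),
  al("*11", "g.883G>C", "none", 0, "no"),
  al("*13", character(0), "d7d6:exon2", 0, "no"),
  al("*14", "g.1759G>A", "none", 0.5, "decreased"),
  al("*15", "g.137insT", "none", 0, "no"),
  al("*17", c("g.1022C>T", "g.2851C>T"), "none", 0.5, "decreased"),
  al("*21", "g.2573insC", "none", 0, "no"),
  al("*22", "g.82C>T", "none", "unknown", "uncertain"),
  al("*28", "g.19G>A", "none", "unknown", "uncertain"),
  al("*29", c("g.1660G>A", "g.3184G>A"), "none", 0.5, "decreased"),
  al("*31", "g.4042G>A", "none", 0, "no"),
  al("*33", "g.237A>C", "none", 1, "normal"),
  al("*35", "g.31G>A", "none", 1, "normal"),
  al("*36", "g.100C>T", "d6d7:exon8", 0, "no"),
  al("*39", "g.4222G>C", "none", 1, "normal"),
  al("*40", "g.1863insTTT", "none", 0, "no"),
  al("*41", "g.2989G>A", "none", 0.25, "decreased"),
  al("*43", "g.77G>A", "none", "unknown", "uncertain"),
  al("*45", "g.1716G>A", "none", 1, "normal"),
  al("*46", "g.1704C>G", "none", 1, "normal"),
  al("*49", "g.1611T>A", "none", 0.5, "decreased"),
  al("*52", "g.3877G>C", "none", "unknown", "uncertain"),
  al("*56", "g.3201C>T", "none", 0, "no"),
  al("*59", "g.2939G>A", "none", 0.5, "decreased"),
  al("*68", "g.100C>T", "d6d7:exon1", 0, "no"),
  al("*71", "g.125G>A", "none", "unknown", "uncertain"),
  al("*82", "g.2225C>T", "none", "unknown", "unknown"),
  al("*83", "g.100C>T", "d6d7:exon2", "unknown", "uncertain"),
  al("*99", "g.3254T>C", "none", 0, "no"),
  al("*106", "g.939C>T", "none", "unknown", "uncertain"),
  al("*108", "g.1012G>A", "none", "unknown", "unknown"),
  al("*111", "g.1513C>T", "none", "unknown", "unknown"),
  al("*112", "g.1598A>G", "none", "unknown", "unknown"),
  al("*113", "g.5C>G", "none", "unknown", "unknown")
)
names(defs) <- vapply(defs, `[[`, "", "name")
stopifnot(all(unlist(lapply(defs, `[[`, "variants")) %in% vc$g_label))
cat("alleles:", length(defs), " validated:",
    sum(vapply(defs, `[[`, TRUE, "validated")), "\n")
json <- list(
  schema_version = "1.0",
  source_note = paste("Synthetic curated star-allele definition table in the",
                      "PharmVar style; g. labels for classic alleles follow",
                      "conventional usage, rare-allele variants are synthetic",
                      "placeholders with catalogue-consistent positions."),
  tandem_conventions = list(c("*68", "*4"), c("*36", "*10"),
                            c("*13", "*2"), c("*4.013", "*4")),
  alleles = unname(defs)
)
jsonlite::write_json(json, "inst/extdata/allele_definitions.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("done\n")
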