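# Shared fixtures and independent brute-force oracles.
# The oracles deliberately avoid GRanges interval machinery: plain loops and
# integer comparisons only, so they are an independent route to the same
# answers.

# Two-gene-plus-overlap toy annotation (1-based closed coordinates):
#   A chr1 [1001, 2000]  exons [1001,1200] [1801,2000]  intron [1201,1800]
#   B chr1 [3000, 4000]  exons [3000,3400] [3601,4000]
#   C chr1 [5001, 6000]  exons [5001,5200] [5801,6000]  (overlaps D)
#   D chr1 [5100, 5400]  exon  [5100,5400]              (inside C's territory)
#   E chr2 [ 501, 1500]  exons [501,700] [1301,1500]
toyAnnotation <- function() {
  g <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1001, 3000, 5001, 5100, 501),
                     c(2000, 4000, 6000, 5400, 1500)))
  S4Vectors::mcols(g)$gene_id <- c("A", "B", "C", "D", "E")
  ex <- GenomicRanges::GRanges(
    c(rep("chr1", 7), "chr2", "chr2"),
    IRanges::IRanges(c(1001, 1801, 3000, 3601, 5001, 5801, 5100, 501, 1301),
                     c(1200, 2000, 3400, 4000, 5200, 6000, 5400, 700, 1500)))
  S4Vectors::mcols(ex)$gene_id <- c("A", "A", "B", "B", "C", "C", "D",
                                    "E", "E")
  GenomeAnnotation(g, ex)
}

# build a calls GRanges from a data.frame with columns
# chrom, start, end, sv_type, svlen, sample_id (+ optional filter etc.)
makeCalls <- function(df) {
  defaults <- list(filter = "PASS", mate_chrom = NA_character_,
                   mate_pos = NA_integer_, unpaired = FALSE)
  for (k in names(defaults))
    if (is.null(df[[k]])) df[[k]] <- defaults[[k]]
  if (is.null(df$sv_id)) df$sv_id <- sprintf("sv%03d", seq_len(nrow(df)))
  if (is.null(df$event_id)) df$event_id <- df$sv_id
  if (is.null(df$svlen))
    df$svlen <- ifelse(df$sv_type == "BND", NA_integer_,
                       df$end - df$start + 1L)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sv_id = df$sv_id, sv_type = df$sv_type,
    svlen = as.integer(df$svlen), filter = df$filter,
    event_id = df$event_id, mate_chrom = df$mate_chrom,
    mate_pos = as.integer(df$mate_pos), unpaired = df$unpaired,
    sample_id = df$sample_id)
  gr
}

# plain-loop extraction of the annotation geometry for the oracles
annTables <- function(ann) {
  g <- geneRanges(ann); e <- exonRanges(ann)
  list(
    genes = data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g), end = GenomicRanges::end(g),
      gene_id = S4Vectors::mcols(g)$gene_id),
    exons = data.frame(chrom = as.character(GenomicRanges::seqnames(e)),
      start = GenomicRanges::start(e), end = GenomicRanges::end(e),
      gene_id = S4Vectors::mcols(e)$gene_id))
}

# brute-force nearest gene: linear scan, tie by span start then gene_id
bruteNearest <- function(ann, chrom, pos) {
  t <- annTables(ann)$genes
  t <- t[t$chrom == chrom, ]
  d <- integer(nrow(t))
  for (i in seq_len(nrow(t))) {
    d[i] <- if (pos < t$start[i]) t$start[i] - pos
            else if (pos > t$end[i]) pos - t$end[i] else 0L
  }
  o <- order(d, t$start, t$gene_id)[1L]
  list(gene_id = t$gene_id[o], distance = d[o])
}

# brute-force point location
bruteLocate <- function(ann, chrom, pos) {
  t <- annTables(ann)
  exg <- character(0); spg <- character(0)
  for (i in seq_len(nrow(t$exons)))
    if (t$exons$chrom[i] == chrom && pos >= t$exons$start[i] &&
        pos <= t$exons$end[i])
      exg <- c(exg, t$exons$gene_id[i])
  for (i in seq_len(nrow(t$genes)))
    if (t$genes$chrom[i] == chrom && pos >= t$genes$start[i] &&
        pos <= t$genes$end[i])
      spg <- c(spg, t$genes$gene_id[i])
  exg <- unique(exg)
  if (length(exg)) list(class = "exon", genes = exg)
  else if (length(spg)) list(class = "intron", genes = unique(spg))
  else list(class = "intergenic", genes = character(0))
}

# brute-force region classifier: enumerates every exon/gene interval
# relation for one SV, returning sorted "gene:class" strings
bruteClassifyOne <- function(ann, chrom, s, e, sv_type) {
  t <- annTables(ann)
  if (sv_type == "BND") e <- s
  inExon <- function(p, gid) {
    any(t$exons$gene_id == gid & t$exons$chrom == chrom &
        p >= t$exons$start & p <= t$exons$end)
  }
  out <- character(0)
  genes <- t$genes[t$genes$chrom == chrom, ]
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    if (e < genes$start[i] || s > genes$end[i]) next   # no span overlap
    ex <- t$exons[t$exons$gene_id == gid, ]
    cls <- character(0)
    if (inExon(s, gid) && inExon(e, gid)) cls <- c(cls, "exonic")
    crosses <- FALSE
    for (j in seq_len(nrow(ex))) {
      overlaps <- !(e < ex$start[j] || s > ex$end[j])
      within <- s >= ex$start[j] && e <= ex$end[j]
      if (overlaps && !within) crosses <- TRUE
    }
    if (crosses) cls <- c(cls, "splicing")
    if (length(cls) == 0L) cls <- "intronic"
    out <- c(out, paste(gid, cls, sep = ":"))
  }
  if (length(out) == 0L) {
    mid <- (s + e) %/% 2L
    ng <- bruteNearest(ann, chrom, mid)
    out <- paste(ng$gene_id, "intergenic", sep = ":")
  }
  sort(out)
}

# exhaustive two-sided Fisher p via log-binomial enumeration (lchoose route,
# independent of dhyper)
bruteFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# minimal VCF writer for hand-built fixture records (independent of
# writeSVVcf); rows: list of character vectors c(chrom,pos,id,ref,alt,info)
writeFixtureVcf <- function(path, rows, contigs, filter = "PASS") {
  hdr <- c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contigs, ">"),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INS,Description="Insertion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=INV,Description="Inversion">',
    '##FILTER=<ID=MinQUAL,Description="Low quality">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(rows, function(r)
    paste(r[1], r[2], r[3], r[4], r[5], ".",
          if (length(r) >= 7) r[7] else filter, r[6], sep = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  path
}

smallManifest <- function() {
  data.frame(
    sample_id = c("aa_ca1", "aa_co1", "ea_ca1", "ea_co1"),
    phenotype = c("case", "control", "case", "control"),
    stratum = c("AA", "AA", "EA", "EA"))
}
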