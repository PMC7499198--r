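# gene A: span [1001,2000], exons [1001,1200] [1801,2000], intron [1201,1800]

test_that("breakpoint geometry drives the four-way classification", {
  ann <- toyAnnotation()
  calls <- makeCalls(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1251, 1101, 1100, 2001),
    end = c(1700, 1500, 1100, 2100),
    sv_type = c("DEL", "DEL", "INS", "DEL"),
    svlen = c(450, 400, 120, 100),
    sample_id = "s1"))
  asn <- as.data.frame(classifySV(calls, ann))
  # fully inside the intron
  expect_equal(asn$gene_id[asn$sv_id == "sv001"], "A")
  expect_equal(asn$region_class[asn$sv_id == "sv001"], "intronic")
  # start in exon, end in intron: crosses the boundary
  expect_equal(asn$region_class[asn$sv_id == "sv002"], "splicing")
  # point insertion inside an exon
  expect_equal(asn$region_class[asn$sv_id == "sv003"], "exonic")
  # no overlapped gene: intergenic to the nearest gene, gap distance
  # (E ends at 1500, the deletion starts at 2001: 500 bp between them)
  row <- asn[asn$sv_id == "sv004", ]
  expect_equal(row$region_class, "intergenic")
  expect_equal(row$gene_id, "E")
  expect_equal(row$distance, 500L)
  # non-intergenic assignments have distance 0
  expect_true(all(asn$distance[asn$region_class != "intergenic"] == 0L))
})

test_that("an SV running exon-to-exon earns both exonic and splicing for the gene", {
  ann <- toyAnnotation()
  calls <- makeCalls(data.frame(chrom = "chr1", start = 1100, end = 1900,
    sv_type = "DEL", svlen = 801, sample_id = "s1"))
  cls <- sort(as.data.frame(classifySV(calls, ann))$region_class)
  expect_equal(cls, c("exonic", "splicing"))
})

test_that("a gene entirely contained in an SV is classified splicing", {
  ann <- toyAnnotation()
  # D [5100,5400] sits inside this deletion; breakpoints in C's intron/exon
  calls <- makeCalls(data.frame(chrom = "chr1", start = 5050, end = 5500,
    sv_type = "DEL", svlen = 451, sample_id = "s1"))
  asn <- as.data.frame(classifySV(calls, ann))
  expect_equal(asn$region_class[asn$gene_id == "D"], "splicing")
})

test_that("breakends classify independently as points", {
  ann <- toyAnnotation()
  calls <- makeCalls(data.frame(
    chrom = c("chr1", "chr2"), start = c(1100, 1400), end = c(1100, 1400),
    sv_type = "BND", svlen = NA,
    sample_id = "s1", sv_id = c("b1", "b2"), event_id = "ev1",
    mate_chrom = c("chr2", "chr1"), mate_pos = c(1400, 1100)))
  asn <- as.data.frame(classifySV(calls, ann))
  expect_equal(asn$region_class[asn$sv_id == "b1"], "exonic")
  expect_equal(asn$gene_id[asn$sv_id == "b2"], "E")
  expect_equal(asn$region_class[asn$sv_id == "b2"], "exonic")
})

test_that("classification matches the brute-force interval oracle on fuzzed SVs", {
  ann <- simulateAnnotation(simulationConfig(seed = 9, n_genes = 20))
  set.seed(77)
  n <- 500
  maxpos <- max(GenomicRanges::end(geneRanges(ann))) + 3000L
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  s <- sample.int(maxpos, n, replace = TRUE)
  len <- sample(50:3000, n, replace = TRUE)
  ty <- sample(c("DEL", "DUP", "INV", "INS", "BND"), n, replace = TRUE)
  e <- ifelse(ty %in% c("INS", "BND"), s, s + len - 1L)
  calls <- makeCalls(data.frame(chrom = chrom, start = s, end = e,
    sv_type = ty, svlen = ifelse(ty == "BND", NA, len), sample_id = "s1"))
  asn <- as.data.frame(classifySV(calls, ann))
  got <- split(paste(asn$gene_id, asn$region_class, sep = ":"), asn$sv_id)
  ids <- S4Vectors::mcols(calls)$sv_id
  mismatches <- 0L
  for (i in seq_len(n)) {
    want <- bruteClassifyOne(ann, chrom[i], s[i], e[i], ty[i])
    if (!identical(sort(unname(got[[ids[i]]])), want))
      mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("every filtered SV yields at least one assignment with a legal class set", {
  ann <- simulateAnnotation(simulationConfig(seed = 13, n_genes = 10))
  cfg <- simulationConfig(seed = 13, n_genes = 10,
    strata = data.frame(label = "AA", n_cases = 6, n_controls = 6))
  sim <- simulateCohort(cfg, ann)
  flt <- filterCalls(sim$calls)
  asn <- as.data.frame(classifySV(flt, ann))
  expect_true(all(S4Vectors::mcols(flt)$sv_id %in% asn$sv_id))
  legal <- c("exonic", "splicing", "intronic", "intergenic")
  for (grp in split(asn, paste(asn$sample_id, asn$sv_id, asn$gene_id))) {
    cls <- sort(grp$region_class)
    expect_true(identical(cls, "exonic") || identical(cls, "splicing") ||
                identical(cls, "intronic") || identical(cls, "intergenic") ||
                identical(cls, c("exonic", "splicing")))
    if ("intergenic" %in% cls) expect_equal(nrow(grp), 1L)
  }
})

test_that("intronic and intergenic assignments dominate on a realistic gene density", {
  cfg <- simulationConfig(seed = 21, n_genes = 40,
    strata = data.frame(label = "AA", n_cases = 15, n_controls = 15))
  ann <- simulateAnnotation(cfg)
  sim <- simulateCohort(cfg, ann)
  asn <- as.data.frame(classifySV(filterCalls(sim$calls), ann))
  frac <- mean(asn$region_class %in% c("intronic", "intergenic"))
  expect_gt(frac, 0.9)
})

test_that("recurrent loci merge on breakpoint windows and reciprocal overlap", {
  base <- data.frame(chrom = "chr5", start = 171723713, end = 171724032,
    sv_type = "DEL", svlen = 320, sample_id = NA)
  three <- do.call(rbind, lapply(c("p1", "p2", "p3"), function(s)
    transform(base, sample_id = s)))
  cl <- mergeLoci(makeCalls(three))
  expect_length(cl, 1L)
  expect_equal(S4Vectors::mcols(cl)$occurrence, 3L)
  expect_equal(GenomicRanges::width(cl), 320L)
  # offset beyond the window splits
  two <- makeCalls(data.frame(chrom = "chr1",
    start = c(1000, 1200), end = c(1319, 1519), sv_type = "DEL",
    svlen = 320, sample_id = c("p1", "p2")))
  expect_length(mergeLoci(two), 2L)
  # breakpoints within the window but reciprocal overlap below threshold
  ro <- makeCalls(data.frame(chrom = "chr1",
    start = c(1000, 1000), end = c(1049, 1089), sv_type = "DEL",
    svlen = c(50, 90), sample_id = c("p1", "p2")))
  expect_length(mergeLoci(ro), 2L)
  expect_length(mergeLoci(ro, reciprocal_overlap = 0.5), 1L)
})

test_that("locus merging is input-order invariant and conserves carriers", {
  cfg <- simulationConfig(seed = 31, n_genes = 12,
    strata = data.frame(label = "AA", n_cases = 8, n_controls = 8))
  ann <- simulateAnnotation(cfg)
  sim <- simulateCohort(cfg, ann)
  flt <- filterCalls(sim$calls)
  cl1 <- mergeLoci(flt)
  set.seed(1)
  cl2 <- mergeLoci(flt[sample(length(flt))])
  expect_identical(as.data.frame(cl1), as.data.frame(cl2))
  expect_equal(sum(S4Vectors::mcols(cl1)$n_calls), length(flt))
})

test_that("carrier matrix collapses events per person and respects the manifest", {
  man <- smallManifest()
  asn <- S4Vectors::DataFrame(
    sample_id = c("aa_ca1", "aa_ca1", "aa_ca1", "aa_co1"),
    sv_id = c("v1", "v2", "v3", "v4"), event_id = c("v1", "v2", "v3", "v4"),
    sv_type = "DEL", chrom = "chr1",
    start = c(100, 300, 500, 100), end = c(200, 400, 600, 200),
    svlen = 100L, gene_id = "X", region_class = "intronic",
    distance = 0L)
  cm <- buildCarrierMatrix(asn, man)
  expect_equal(dim(cm), c(1L, 4L))
  expect_equal(sum(SummarizedExperiment::assay(cm)), 2L)  # one per person
  # unknown sample errors in strict mode, drops otherwise
  asn2 <- rbind(asn, S4Vectors::DataFrame(sample_id = "ghost", sv_id = "v9",
    event_id = "v9", sv_type = "DEL", chrom = "chr1", start = 1, end = 2,
    svlen = 2L, gene_id = "X", region_class = "intronic", distance = 0L))
  expect_error(buildCarrierMatrix(asn2, man), "ghost")
  expect_warning(cm2 <- buildCarrierMatrix(asn2, man, strict = FALSE),
                 "dropping")
  expect_equal(dim(cm2), c(1L, 4L))
})

test_that("locus-mode carrier matrix row sums equal cluster carrier counts", {
  cfg <- simulationConfig(seed = 41, n_genes = 10,
    strata = data.frame(label = "AA", n_cases = 10, n_controls = 10))
  ann <- simulateAnnotation(cfg)
  sim <- simulateCohort(cfg, ann)
  flt <- filterCalls(sim$calls)
  cl <- mergeLoci(flt)
  asn <- classifySV(flt, ann)
  cm <- buildCarrierMatrix(asn, sim$manifest, unit = "locus", clusters = cl)
  expect_equal(unname(rowSums(SummarizedExperiment::assay(cm))),
               S4Vectors::mcols(cl)$occurrence)
})
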