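test_that("odds ratios reproduce published carrier tables and obey inversion", {
  # counts with AA stratum 116/408, EA 89/262
  expect_equal(round(oddsRatio(contingencyTable(9, 107, 7, 401)), 1), 4.8)
  expect_equal(round(oddsRatio(contingencyTable(29, 60, 44, 218)), 2), 2.39)
  expect_equal(round(oddsRatio(contingencyTable(70, 46, 183, 225)), 2), 1.87)
  expect_equal(oddsRatio(contingencyTable(5, 5, 5, 5)), 1)
  # swapping carrier and non-carrier columns inverts the OR
  set.seed(3)
  for (i in 1:20) {
    t <- contingencyTable(sample(1:50, 1), sample(1:50, 1),
                          sample(1:50, 1), sample(1:50, 1))
    expect_equal(oddsRatio(t[, c(2, 1)]), 1 / oddsRatio(t))
  }
  # Haldane correction only engages on zero cells
  expect_equal(oddsRatio(contingencyTable(2, 8, 0, 10)),
               (2.5 * 10.5) / (8.5 * 0.5))
  expect_error(oddsRatio(contingencyTable(0, 0, 5, 5), "none"), "margin")
})

test_that("chi-square test matches the closed-form statistic and handles degeneracy", {
  expect_equal(chiSquareTest(contingencyTable(5, 5, 5, 5))$statistic, 0)
  expect_equal(chiSquareTest(contingencyTable(5, 5, 5, 5))$p, 1)
  # n(ad-bc)^2 / (r1 r2 c1 c2) computed by hand: 15.1319
  ct <- chiSquareTest(contingencyTable(18, 98, 20, 388))
  expect_equal(ct$statistic, 15.1319, tolerance = 1e-4)
  expect_false(ct$degenerate)
  # Yates correction shrinks the statistic
  expect_lt(chiSquareTest(contingencyTable(18, 98, 20, 388),
                          yates = TRUE)$statistic, ct$statistic)
  dg <- chiSquareTest(contingencyTable(0, 10, 0, 20))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
  # invariant under simultaneous row and column swaps
  t <- contingencyTable(12, 30, 7, 44)
  expect_equal(chiSquareTest(t[2:1, 2:1])$statistic,
               chiSquareTest(t)$statistic)
  # statistic 0 exactly when OR is 1
  expect_equal(chiSquareTest(contingencyTable(10, 20, 30, 60))$statistic, 0)
})

test_that("chi-square p agrees with a hypergeometric permutation null on well-filled tables", {
  set.seed(19)
  for (i in 1:20) {
    a <- sample(200:800, 1); b <- sample(600:1600, 1)
    c_ <- sample(200:800, 1); d <- sample(600:1600, 1)
    t <- contingencyTable(a, b, c_, d)
    obs <- chiSquareTest(t)
    # permutation under fixed margins: redraw the case-carrier cell
    m <- a + b; n <- c_ + d; k <- a + c_
    astar <- rhyper(100000, k, (m + n) - k, m)
    stat <- function(aa) {
      bb <- m - aa; cc <- k - aa; dd <- n - cc
      (m + n) * (aa * dd - bb * cc)^2 /
        (as.numeric(m) * n * k * (m + n - k))
    }
    pperm <- mean(stat(astar) >= obs$statistic - 1e-9)
    se <- sqrt(pperm * (1 - pperm) / 100000)
    # 0.005 covers the systematic conditional-vs-asymptotic gap at this n,
    # which Monte Carlo precision at 1e5 draws otherwise resolves
    expect_lt(abs(obs$p - pperm), 3 * se + 5e-3)
  }
})

test_that("Fisher's exact test equals exhaustive enumeration and the stats oracle", {
  expect_equal(fisherExactTest(contingencyTable(0, 5, 0, 5)), 1)
  # every table with total up to 16 against the lchoose enumeration
  for (tot in 2:16) {
    for (a in 0:tot) for (b in 0:(tot - a)) for (c_ in 0:(tot - a - b)) {
      d <- tot - a - b - c_
      p <- fisherExactTest(contingencyTable(a, b, c_, d))
      expect_equal(p, bruteFisherP(a, b, c_, d), tolerance = 1e-12)
    }
  }
  # dual route: stats::fisher.test on random larger tables
  set.seed(8)
  for (i in 1:25) {
    t <- contingencyTable(sample(0:30, 1), sample(0:60, 1),
                          sample(0:30, 1), sample(0:60, 1))
    if (sum(t) == 0) next
    expect_equal(fisherExactTest(t), fisher.test(t)$p.value,
                 tolerance = 1e-9)
  }
  # asymptotic agreement with chi-square for balanced large counts
  t <- contingencyTable(300, 700, 280, 720)
  expect_lt(abs(fisherExactTest(t) - chiSquareTest(t)$p) /
              chiSquareTest(t)$p, 0.2)
})

test_that("Bonferroni adjustment caps at one, preserves order and honours overrides", {
  expect_equal(bonferroniAdjust(0.01, m = 10), 0.1)
  expect_equal(bonferroniAdjust(0.5, m = 10), 1)
  expect_equal(bonferroniAdjust(2.57e-4, m = 1e5), 1)
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- bonferroniAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj) >= 0))
  expect_equal(adj, p.adjust(p, "bonferroni"))
  expect_error(bonferroniAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher's combined probability test reproduces the two-stratum example", {
  mc <- metaCombine(c(0.79, 0.0032))
  expect_equal(mc$p, 0.0176463, tolerance = 1e-5)
  expect_equal(mc$df, 4L)
  # printed as 0.017: within 5% relative of the combined value
  expect_lt(abs(mc$p - 0.017) / 0.017, 0.05)
  # single stratum is the identity, to machine precision
  for (p in c(1e-8, 0.0032, 0.5, 1))
    expect_equal(metaCombine(p)$p, p, tolerance = 1e-12)
  expect_equal(metaCombine(c(1, 1))$p, 1)
  expect_error(metaCombine(c(0, 0.5)), "0")
})

test_that("combined p is monotone in each input and decreasing in replicates below 1/e", {
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(2:4, 1))
    j <- sample(length(p), 1)
    q <- p; q[j] <- q[j] * runif(1)
    expect_lte(metaCombine(q)$p, metaCombine(p)$p + 1e-12)
  }
  alpha <- 0.05  # < exp(-1)
  ps <- vapply(1:5, function(k) metaCombine(rep(alpha, k))$p, numeric(1))
  expect_lte(ps[1], alpha + 1e-12)
  expect_true(all(diff(ps) < 0))
})

test_that("carrier tables preserve stratum margins for every key", {
  man <- data.frame(
    sample_id = sprintf("s%03d", 1:30),
    phenotype = rep(c("case", "control"), c(10, 20)),
    stratum = "AA")
  set.seed(6)
  mat <- matrix(rbinom(5 * 30, 1, 0.3), nrow = 5,
                dimnames = list(paste0("G", 1:5, "|intronic|DEL"),
                                man$sample_id))
  cm <- CarrierMatrix(SummarizedExperiment::SummarizedExperiment(
    assays = list(carrier = mat),
    rowData = S4Vectors::DataFrame(gene_id = paste0("G", 1:5),
      region_class = "intronic", sv_type = "DEL"),
    colData = S4Vectors::DataFrame(phenotype = man$phenotype,
      stratum = man$stratum, row.names = man$sample_id)))
  for (k in rownames(cm)) {
    t <- carrierTable(cm, k, "AA")
    expect_equal(sum(t["case", ]), 10)
    expect_equal(sum(t["control", ]), 20)
  }
  expect_error(carrierTable(cm, rownames(cm)[1], "EA"), "empty stratum")
  expect_error(carrierTable(cm, "nope", "AA"), "unknown key")
  # explicit toy: 2 of 3 cases, 0 of 3 controls
  t <- contingencyTable(2, 1, 0, 3)
  expect_equal(as.vector(t), c(2L, 0L, 1L, 3L))
})

test_that("per-stratum association ranks by chi-square p and flags risk", {
  man <- data.frame(sample_id = sprintf("s%03d", 1:60),
    phenotype = rep(c("case", "control"), each = 30), stratum = "AA")
  mat <- matrix(0L, nrow = 3, ncol = 60,
                dimnames = list(c("G1|intronic|DEL", "G2|intronic|DEL",
                                  "G3|exonic|INS"), man$sample_id))
  mat[1, 1:12] <- 1L                      # 12 cases, 0 controls: risk
  mat[2, c(1:3, 31:45)] <- 1L             # 3 cases, 15 controls: protective
  mat[3, c(1:6, 31:36)] <- 1L             # balanced
  cm <- CarrierMatrix(SummarizedExperiment::SummarizedExperiment(
    assays = list(carrier = mat),
    rowData = S4Vectors::DataFrame(gene_id = c("G1", "G2", "G3"),
      region_class = c("intronic", "intronic", "exonic"),
      sv_type = c("DEL", "DEL", "INS")),
    colData = S4Vectors::DataFrame(phenotype = man$phenotype,
      stratum = man$stratum, row.names = man$sample_id)))
  res <- associateStratum(cm, "AA")
  expect_equal(res$key[1], "G1|intronic|DEL")
  expect_true(all(diff(res$chi2_p) >= 0))
  expect_equal(res$a + res$b, rep(30L, 3))
  expect_equal(res$c + res$d, rep(30L, 3))
  # protective key is significant by p but excluded from the risk set
  g2 <- res[res$key == "G2|intronic|DEL", ]
  expect_lt(g2$chi2_p, 0.05)
  expect_false(g2$is_risk)
  expect_false(g2$significant)
  full <- associateStratum(cm, "AA", risk_only = FALSE)
  expect_true(full[full$key == "G2|intronic|DEL", "significant"])
  expect_error(associateStratum(cm, "ZZ"), "ZZ")
})

test_that("rare recurrent filtering enforces occurrence and control-frequency rules", {
  mk <- function(carriers) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 419))
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(sv_type = "DEL",
      carriers = IRanges::CharacterList(list(carriers)),
      occurrence = length(carriers), n_calls = length(carriers),
      cluster_id = "chr1:100-419:DEL")
    g
  }
  man <- data.frame(
    sample_id = c(sprintf("ca%02d", 1:10), sprintf("co%03d", 1:500)),
    phenotype = rep(c("case", "control"), c(10, 500)), stratum = "AA")
  # 3 cases, no controls: kept under case_only
  kept <- rareRecurrentFilter(mk(c("ca01", "ca02", "ca03")), man,
                              case_only = TRUE)
  expect_length(kept, 1L)
  expect_equal(S4Vectors::mcols(kept)$case_carriers, 3L)
  # 2 cases but control frequency 3/500 = 0.6%: dropped at the 0.5% bound
  expect_length(rareRecurrentFilter(
    mk(c("ca01", "ca02", "co001", "co002", "co003")), man), 0L)
  # control frequency 2/500 = 0.4%: kept when not case-only
  expect_length(rareRecurrentFilter(
    mk(c("ca01", "ca02", "co001", "co002")), man), 1L)
  expect_length(rareRecurrentFilter(
    mk(c("ca01", "ca02", "co001", "co002")), man, case_only = TRUE), 0L)
  # a single case carrier is not recurrent
  expect_length(rareRecurrentFilter(mk("ca01"), man, case_only = TRUE), 0L)
})

test_that("cross-stratum overlap summaries follow direct set algebra", {
  mkres <- function(genes, classes, ps) S4Vectors::DataFrame(
    key = paste0(genes, "|", classes, "|DEL"), gene_id = genes,
    region_class = classes, sv_type = "DEL", stratum = "x",
    a = 1L, b = 1L, c = 1L, d = 1L, odds_ratio = 2,
    chi2_stat = 1, chi2_p = ps, chi2_p_adj = 1,
    fisher_p = ps, fisher_p_adj = 1, is_risk = TRUE,
    significant = ps <= 0.05)
  ten <- sprintf("g%02d", 1:10)
  same <- mkres(ten, "intronic", 0.01)
  ov <- ethnicityOverlap(list(AA = same, EA = same))
  expect_equal(length(ov$all$intersection), 10L)
  expect_equal(unname(ov$all$fraction), c(1, 1))
  dis <- ethnicityOverlap(list(
    AA = mkres(c("a1", "a2", "a3"), "exonic", 0.01),
    EA = mkres(c("e1", "e2", "e3", "e4"), "exonic", 0.01)))
  expect_length(dis$exonic$intersection, 0L)
  expect_equal(unname(dis$exonic$fraction), c(0, 0))
  # fuzzed lists against direct set computation
  set.seed(12)
  for (i in 1:10) {
    gA <- sample(sprintf("g%02d", 1:20), 8)
    gE <- sample(sprintf("g%02d", 1:20), 8)
    pA <- sample(c(0.01, 0.5), 8, replace = TRUE)
    pE <- sample(c(0.01, 0.5), 8, replace = TRUE)
    ov <- ethnicityOverlap(list(AA = mkres(gA, "intronic", pA),
                                EA = mkres(gE, "intronic", pE)))
    expect_setequal(ov$all$intersection,
                    intersect(gA[pA <= 0.05], gE[pE <= 0.05]))
  }
  expect_error(ethnicityOverlap(list(AA = same)), "two strata")
})

test_that("gene-set tallies report significant and trend members per set", {
  res <- S4Vectors::DataFrame(
    key = paste0(c("X", "Y", "Z", "X"), "|intronic|DEL"),
    gene_id = c("X", "Y", "Z", "X"), region_class = "intronic",
    sv_type = "DEL", stratum = c("AA", "AA", "AA", "EA"),
    a = 1L, b = 1L, c = 1L, d = 1L, odds_ratio = 2, chi2_stat = 1,
    chi2_p = c(0.02, 0.08, 0.5, 0.6), chi2_p_adj = 1,
    fisher_p = 0.5, fisher_p_adj = 1, is_risk = TRUE,
    significant = c(TRUE, FALSE, FALSE, FALSE))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tX\tY\tZ", "setB\tdesc\tX\tQ", "empty\tdesc"),
             gmt)
  sets <- readGmt(gmt)
  expect_warning(tal <- genesetTally(res, sets), "empty")
  a <- tal[tal$set == "setA", ]
  expect_setequal(a$gene_id, c("X", "Y"))
  expect_equal(a$level[a$gene_id == "X"], "significant")
  expect_equal(a$level[a$gene_id == "Y"], "trend")
  # a gene in two sets appears in both
  expect_true("X" %in% tal$gene_id[tal$set == "setB"])
  expect_false("Z" %in% tal$gene_id)
})
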