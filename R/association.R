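#' Carrier odds ratio of a 2x2 table
#'
#' The cross-product ratio `(a*d)/(b*c)` on the carrier layout.  With the
#' (default) Haldane policy, 0.5 is added to every cell when any cell is
#' zero; with `"none"` a zero denominator yields `Inf` and an all-zero
#' margin is an error.
#'
#' @param t 2x2 matrix from [contingencyTable()] / [carrierTable()].
#' @param zero_correction `"haldane"` or `"none"`.
#' @return The odds ratio (positive double, possibly `Inf`).
#' @examples
#' oddsRatio(contingencyTable(9, 107, 7, 401))   # 4.82
#' @export
oddsRatio <- function(t, zero_correction = c("haldane", "none")) {
  zero_correction <- match.arg(zero_correction)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
    if (zero_correction == "none") stop("undefined odds ratio: zero margin")
  if (zero_correction == "haldane" && any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square with 1 df (continuity correction off by default; the
#' `yates` flag enables it).  A table with a zero row or column margin is
#' degenerate: the statistic is 0 and p is 1.
#'
#' @inheritParams oddsRatio
#' @param yates Apply the Yates continuity correction.
#' @return List with `statistic`, `p` and `degenerate`.
#' @export
chiSquareTest <- function(t, yates = FALSE) {
  if (sum(t) == 0 || any(rowSums(t) == 0) || any(colSums(t) == 0))
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  ht <- suppressWarnings(chisq.test(t, correct = yates))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       degenerate = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums, over the hypergeometric support with the observed margins fixed,
#' the probabilities of all tables no more probable than the observed one.
#' A relative tie tolerance of 1e-7 guards against floating-point
#' misclassification of exact ties (the same guard `stats::fisher.test`
#' uses).
#'
#' @inheritParams oddsRatio
#' @return The two-sided p-value.
#' @export
fisherExactTest <- function(t) {
  a <- t[1, 1]; m <- sum(t[1, ]); n <- sum(t[2, ]); k <- sum(t[, 1])
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size `m` and caps at 1.  `m`
#' defaults to the number of p-values; the override supports families
#' defined at a different granularity (for example genes rather than keys).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size override.
#' @return Adjusted p-values (never smaller than the input, order
#'   preserving, capped at 1).
#' @export
bonferroniAdjust <- function(p, m = NULL) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(m)) m <- length(p)
  pmin(1, p * m)
}

#' Fisher's combined probability test across strata
#'
#' Combines k independent per-stratum p-values through
#' `X = -2 * sum(log(p))`, referred to the chi-square distribution with
#' `2k` degrees of freedom.  A single input is returned unchanged
#' (`exp(-X/2) = p` at 2 df).
#'
#' @param p Numeric vector of per-stratum p-values, each in `(0, 1]`.
#' @return List with `statistic`, `df` and `p`.
#' @examples
#' metaCombine(c(0.79, 0.0032))$p   # ~0.0176
#' @export
metaCombine <- function(p) {
  if (length(p) < 1L) stop("need at least one p-value")
  if (any(p <= 0))
    stop("p-value of 0 cannot be combined; substitute the smallest ",
         "representable value (.Machine$double.xmin) explicitly if intended")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  x <- -2 * sum(log(p))
  list(statistic = x, df = 2L * length(p),
       p = pchisq(x, df = 2L * length(p), lower.tail = FALSE))
}

#' Per-stratum case-control association over all keys
#'
#' For every key of the carrier matrix, forms the stratum 2x2 carrier table
#' and computes the odds ratio, chi-square and (optionally) Fisher's exact
#' p-values, with Bonferroni adjustment within the chosen family.  Results
#' are sorted by chi-square p (ties by key).  All keys are returned;
#' `significant` flags the rows driving downstream analyses: raw chi-square
#' p below `alpha` and, when `risk_only`, odds ratio above 1.
#'
#' @param cm A [CarrierMatrix-class].
#' @param stratum Stratum label to analyse.
#' @param alpha Raw-p significance threshold.
#' @param risk_only Restrict the significant set to risk keys (OR > 1);
#'   protective keys remain in the output, flagged `is_risk = FALSE`.
#' @param yates Continuity correction for the chi-square test.
#' @param adjust_by Bonferroni family: `"class"` adjusts within each
#'   region class (the default), `"all"` across every key in the stratum.
#' @param m Family-size override passed to [bonferroniAdjust()].
#' @param tests `"both"` or `"chi2"` (skips Fisher's exact test, useful in
#'   large calibration simulations).
#' @return DataFrame with key fields, cells `a`..`d`, `odds_ratio`,
#'   `chi2_stat`, `chi2_p`, `chi2_p_adj`, `fisher_p`, `fisher_p_adj`,
#'   `is_risk`, `significant`.
#' @export
associateStratum <- function(cm, stratum, alpha = 0.05, risk_only = TRUE,
                             yates = FALSE, adjust_by = c("class", "all"),
                             m = NULL, tests = c("both", "chi2")) {
  adjust_by <- match.arg(adjust_by)
  tests <- match.arg(tests)
  cd <- colData(cm)
  sel <- cd$stratum == stratum
  pheno <- cd$phenotype[sel]
  if (!any(pheno == "case") || !any(pheno == "control"))
    stop("stratum ", stratum, " needs both cases and controls")
  x <- assay(cm, "carrier")[, sel, drop = FALSE]
  ncase <- sum(pheno == "case"); nctrl <- sum(pheno == "control")
  a <- as.integer(x[, pheno == "case", drop = FALSE] %*%
                    rep(1L, ncase))
  c_ <- as.integer(x[, pheno == "control", drop = FALSE] %*%
                     rep(1L, nctrl))
  b <- ncase - a; d <- nctrl - c_
  n <- nrow(x)
  or <- chi2s <- chi2p <- fishp <- numeric(n)
  for (i in seq_len(n)) {
    t <- contingencyTable(a[i], b[i], c_[i], d[i])
    or[i] <- oddsRatio(t)
    ct <- chiSquareTest(t, yates = yates)
    chi2s[i] <- ct$statistic; chi2p[i] <- ct$p
    fishp[i] <- if (tests == "both") fisherExactTest(t) else NA_real_
  }
  rd <- rowData(cm)
  fam <- if (adjust_by == "class" && "region_class" %in% colnames(rd))
    rd$region_class else rep("all", n)
  chi2adj <- fishadj <- numeric(n)
  for (f in unique(fam)) {
    idx <- fam == f
    mm <- if (is.null(m)) sum(idx) else m
    chi2adj[idx] <- bonferroniAdjust(chi2p[idx], mm)
    fishadj[idx] <- if (tests == "both")
      bonferroniAdjust(fishp[idx], mm) else NA_real_
  }
  out <- cbind(DataFrame(key = rownames(cm)), rd,
    DataFrame(stratum = stratum, a = a, b = b, c = c_, d = d,
      odds_ratio = or, chi2_stat = chi2s, chi2_p = chi2p,
      chi2_p_adj = chi2adj, fisher_p = fishp, fisher_p_adj = fishadj,
      is_risk = or > 1,
      significant = chi2p < alpha & (or > 1 | !risk_only)))
  out[order(out$chi2_p, out$key), ]
}

#' Meta-analysis across strata
#'
#' Runs [associateStratum()] in every stratum and combines the per-stratum
#' chi-square p-values per key with [metaCombine()].  Keys untested in a
#' stratum (the carrier matrix spans all samples, so every key has a table
#' in every stratum) contribute their degenerate p of 1.
#'
#' @inheritParams associateStratum
#' @param strata Stratum labels; default all strata in the matrix.
#' @param ... Passed to [associateStratum()].
#' @return DataFrame with key fields, one `p_<stratum>` column per stratum,
#'   `meta_stat`, `meta_df`, `meta_p`, sorted by `meta_p`.
#' @export
metaAnalyze <- function(cm, strata = NULL, ...) {
  if (is.null(strata)) strata <- unique(colData(cm)$stratum)
  res <- lapply(strata, function(s) associateStratum(cm, s, ...))
  names(res) <- strata
  keys <- rownames(cm)
  pmat <- sapply(res, function(r) r$chi2_p[match(keys, r$key)])
  pmat <- matrix(pmat, nrow = length(keys),
                 dimnames = list(keys, strata))
  pmat[pmat <= 0] <- .Machine$double.xmin
  comb <- t(apply(pmat, 1L, function(p) {
    mc <- metaCombine(p)
    c(mc$statistic, mc$df, mc$p)
  }))
  out <- cbind(DataFrame(key = keys), rowData(cm),
               DataFrame(setNames(as.data.frame(pmat),
                                  paste0("p_", strata)),
                         meta_stat = comb[, 1L], meta_df = comb[, 2L],
                         meta_p = comb[, 3L]))
  out[order(out$meta_p, out$key), ]
}

#' Rare recurrent (optionally case-only) locus filter
#'
#' Keeps clusters carried by at least `min_case_occurrence` cases and either
#' absent from controls (`case_only`) or with control carrier frequency
#' strictly below `max_control_freq`.
#'
#' @param clusters GRanges from [mergeLoci()].
#' @param manifest Data.frame from [readManifest()].
#' @param min_case_occurrence Minimum number of distinct case carriers.
#' @param max_control_freq Control carrier frequency bound (fraction).
#' @param case_only Require zero control carriers.
#' @return The filtered clusters, with added metadata columns
#'   `case_carriers`, `control_carriers`, `control_freq`.
#' @export
rareRecurrentFilter <- function(clusters, manifest, min_case_occurrence = 2,
                                max_control_freq = 0.005, case_only = FALSE) {
  cases <- manifest$sample_id[manifest$phenotype == "case"]
  ctrls <- manifest$sample_id[manifest$phenotype == "control"]
  carr <- mcols(clusters)$carriers
  ncl <- length(clusters)
  ncase <- vapply(seq_len(ncl), function(i)
    sum(unlist(carr[[i]]) %in% cases), integer(1))
  nctrl <- vapply(seq_len(ncl), function(i)
    sum(unlist(carr[[i]]) %in% ctrls), integer(1))
  freq <- nctrl / length(ctrls)
  mcols(clusters)$case_carriers <- ncase
  mcols(clusters)$control_carriers <- nctrl
  mcols(clusters)$control_freq <- freq
  keep <- ncase >= min_case_occurrence &
    (if (case_only) nctrl == 0L else freq < max_control_freq)
  clusters[keep]
}

#' Cross-stratum overlap of significant SV-genes
#'
#' For each region class (and overall) collects the significant gene set of
#' every stratum and reports intersections, per-stratum exclusives and
#' overlap fractions, optionally restricted to a supplied set of known
#' genes.
#'
#' @param results_by_stratum Named list of [associateStratum()] outputs
#'   (two or more strata).
#' @param alpha Significance threshold on the raw chi-square p.
#' @param known_genes Optional character vector restricting the universe.
#' @return A list, one element per class (`all`, `exonic`, `splicing`,
#'   `intronic`, `intergenic`), each containing `sets` (per-stratum gene
#'   sets), `intersection`, `only` (per-stratum exclusives), and
#'   `fraction` (intersection size over each stratum's set size).
#' @export
ethnicityOverlap <- function(results_by_stratum, alpha = 0.05,
                             known_genes = NULL) {
  if (length(results_by_stratum) < 2L) stop("need at least two strata")
  classes <- c("all", "exonic", "splicing", "intronic", "intergenic")
  sigGenes <- function(r, cls) {
    keep <- r$chi2_p <= alpha & r$is_risk
    if (cls != "all") keep <- keep & r$region_class == cls
    g <- unique(r$gene_id[keep])
    if (!is.null(known_genes)) g <- intersect(g, known_genes)
    sort(g)
  }
  out <- lapply(classes, function(cls) {
    sets <- lapply(results_by_stratum, sigGenes, cls = cls)
    inter <- Reduce(intersect, sets)
    list(sets = sets, intersection = inter,
         only = lapply(seq_along(sets), function(i)
           setdiff(sets[[i]], unlist(sets[-i]))),
         fraction = vapply(sets, function(s)
           if (length(s)) length(inter) / length(s) else NA_real_,
           numeric(1)))
  })
  names(out) <- classes
  out
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (set name, description, member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Gene-set membership tally of association hits
#'
#' For each gene set, lists member genes whose best association result is
#' significant (p at or below `alpha`) or trending (p at or below
#' `trend_alpha`), annotated with stratum, region class, SV type and the
#' p-value.  A gene belonging to several sets appears once per set; empty
#' sets are skipped with a warning.
#'
#' @param results DataFrame of association rows, e.g. the concatenation of
#'   [associateStratum()] outputs across strata.
#' @param gene_sets Named list from [readGmt()].
#' @param alpha Significance threshold.
#' @param trend_alpha Trend threshold.
#' @return A data.frame with columns `set`, `gene_id`, `stratum`,
#'   `region_class`, `sv_type`, `p`, `level` (significant/trend).
#' @export
genesetTally <- function(results, gene_sets, alpha = 0.05,
                         trend_alpha = 0.1) {
  res <- as.data.frame(results)
  res <- res[res$is_risk & res$chi2_p <= trend_alpha, , drop = FALSE]
  res <- res[order(res$chi2_p), , drop = FALSE]
  best <- res[!duplicated(paste(res$gene_id, res$stratum)), , drop = FALSE]
  rows <- list()
  for (set in names(gene_sets)) {
    members <- gene_sets[[set]]
    if (length(members) == 0L) {
      warning("empty gene set skipped: ", set)
      next
    }
    hit <- best[best$gene_id %in% members, , drop = FALSE]
    if (nrow(hit) == 0L) next
    rows[[set]] <- data.frame(set = set, gene_id = hit$gene_id,
      stratum = hit$stratum, region_class = hit$region_class,
      sv_type = hit$sv_type, p = hit$chi2_p,
      level = ifelse(hit$chi2_p <= alpha, "significant", "trend"))
  }
  if (length(rows) == 0L)
    return(data.frame(set = character(), gene_id = character(),
      stratum = character(), region_class = character(),
      sv_type = character(), p = numeric(), level = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
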