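#' Simulation configuration for synthetic SV cohorts
#'
#' Bundles and validates every knob of the generator: the toy genome layout,
#' the cohort strata, the planted per-gene carrier effects and the background
#' SV process.  Fixing `seed` makes every downstream artifact (GTF, VCFs,
#' manifest, truth table) byte-identical between runs.
#'
#' Planted effects are parameterised by the carrier odds ratio directly:
#' controls carry with probability `carrier_freq_controls = f`, cases with
#' probability `OR*f / (1 - f + OR*f)` (see [carrierCaseProb()]), so the
#' analysis estimand is exactly the planted quantity.
#'
#' @param seed Integer RNG seed.
#' @param n_chroms Number of toy chromosomes.
#' @param n_genes Number of genes (spread across chromosomes).
#' @param exons_per_gene Integer range `c(min, max)`.
#' @param exon_len,intron_len,intergenic_len Length ranges in bp.
#' @param strata Data.frame with columns `label`, `n_cases`, `n_controls`.
#' @param effects Data.frame with columns `gene_id`, `region_class`
#'   (exonic/splicing/intronic/intergenic), `sv_type`, `stratum`,
#'   `carrier_freq_controls`, `odds_ratio`; may be empty.
#' @param background_rate Mean background SVs per sample (Poisson).
#' @param class_props Named background class proportions; the default is the
#'   genome-wide SV class mix reported for deep WGS callsets (exonic 0.96%,
#'   splicing 0.59%, intronic 42.3%, intergenic 56.13%).
#' @param type_props Named SV-type proportions for background calls.
#' @param sv_len Background SV length range (min must be >= 50 so background
#'   calls survive the default length filter).
#' @param fail_rate Fraction of background records labelled `MinQUAL`
#'   instead of `PASS`, exercising the quality filter.
#' @param avoid_effect_genes Keep background SVs off the planted-effect
#'   genes so the truth table stays clean.
#' @param vcf_mode `"per_sample"` or `"multi"` (one multi-sample VCF).
#' @return A validated list of class `sv_sim_config`.
#' @export
simulationConfig <- function(seed = 1L, n_chroms = 2L, n_genes = 20L,
    exons_per_gene = c(2L, 8L), exon_len = c(100L, 400L),
    intron_len = c(200L, 2000L), intergenic_len = c(1000L, 5000L),
    strata = data.frame(label = "AA", n_cases = 10L, n_controls = 10L),
    effects = NULL,
    background_rate = 8,
    class_props = c(exonic = 0.0096, splicing = 0.0059,
                    intronic = 0.423, intergenic = 0.5613),
    type_props = c(DEL = 0.45, INS = 0.30, DUP = 0.10, INV = 0.10,
                   BND = 0.05),
    sv_len = c(50L, 1000L), fail_rate = 0.05,
    avoid_effect_genes = TRUE,
    vcf_mode = c("per_sample", "multi")) {
  vcf_mode <- match.arg(vcf_mode)
  if (is.null(effects))
    effects <- data.frame(gene_id = character(), region_class = character(),
      sv_type = character(), stratum = character(),
      carrier_freq_controls = numeric(), odds_ratio = numeric())
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_genes >= 1L, n_chroms >= 1L,
            all(c("label", "n_cases", "n_controls") %in% names(strata)),
            all(strata$n_cases >= 1L), all(strata$n_controls >= 1L))
  if (sv_len[1L] < 50L) stop("background sv_len minimum must be >= 50 bp")
  if (exon_len[1L] < 10L) stop("exon lengths too short")
  if (nrow(effects)) {
    if (any(effects$carrier_freq_controls <= 0 |
            effects$carrier_freq_controls >= 1))
      stop("effect carrier frequencies must lie in (0, 1)")
    if (any(effects$odds_ratio <= 0)) stop("odds ratios must be positive")
    if (any(!effects$stratum %in% strata$label))
      stop("effect stratum not present in the strata table")
  }
  if (abs(sum(class_props) - 1) > 0.01 || abs(sum(type_props) - 1) > 0.01)
    stop("class_props and type_props must each sum to 1")
  class_props <- class_props / sum(class_props)
  type_props <- type_props / sum(type_props)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    n_genes = as.integer(n_genes), exons_per_gene = exons_per_gene,
    exon_len = exon_len, intron_len = intron_len,
    intergenic_len = intergenic_len, strata = strata, effects = effects,
    background_rate = background_rate, class_props = class_props,
    type_props = type_props, sv_len = sv_len, fail_rate = fail_rate,
    avoid_effect_genes = avoid_effect_genes, vcf_mode = vcf_mode),
    class = "sv_sim_config")
}

#' Case carrier probability implied by a carrier odds ratio
#'
#' Solves `odds(case) = OR * odds(control)` for the case carrier
#' probability: `OR*f / (1 - f + OR*f)`.
#'
#' @param f Control carrier frequency in `(0, 1)`.
#' @param or Carrier odds ratio.
#' @return Case carrier probability.
#' @examples
#' carrierCaseProb(0.05, 3)   # 0.13636...
#' @export
carrierCaseProb <- function(f, or) or * f / (1 - f + or * f)

#' Simulate a toy gene annotation
#'
#' Places non-overlapping multi-exon genes sequentially along
#' `n_chroms` chromosomes, alternating exons and introns with lengths drawn
#' from the configured ranges.  Deterministic under the config seed.
#'
#' @param config A [simulationConfig()].
#' @return A [GenomeAnnotation-class]; write it with [writeGtf()] or
#'   [writeGff3()].
#' @export
simulateAnnotation <- function(config) {
  set.seed(config$seed)
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  rint <- function(rng) if (rng[1L] >= rng[2L]) rng[1L] else
    as.integer(floor(runif(1L, rng[1L], rng[2L] + 1)))
  genes <- list(); exons <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    pos <- 1L
    for (k in seq_len(per_chrom)) {
      gi <- gi + 1L
      if (gi > config$n_genes) break
      gid <- sprintf("G%04d", gi)
      pos <- pos + rint(config$intergenic_len)
      nex <- rint(config$exons_per_gene)
      exw <- vapply(seq_len(nex), function(i) rint(config$exon_len),
                    integer(1))
      inw <- if (nex > 1L)
        vapply(seq_len(nex - 1L), function(i) rint(config$intron_len),
               integer(1)) else integer(0)
      s <- pos
      p <- pos
      for (i in seq_len(nex)) {
        exons[[length(exons) + 1L]] <-
          data.frame(chrom = chrom, start = p, end = p + exw[i] - 1L,
                     gene_id = gid)
        p <- p + exw[i]
        if (i < nex) p <- p + inw[i]
      }
      genes[[length(genes) + 1L]] <-
        data.frame(chrom = chrom, start = s, end = p - 1L, gene_id = gid)
      pos <- p
    }
  }
  gdf <- do.call(rbind, genes)
  edf <- do.call(rbind, exons)
  g <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end), strand = "+")
  mcols(g)$gene_id <- gdf$gene_id
  mcols(g)$gene_name <- gdf$gene_id
  e <- GRanges(edf$chrom, IRanges(edf$start, edf$end), strand = "+")
  mcols(e)$gene_id <- edf$gene_id
  GenomeAnnotation(g, e)
}

#' Write a GenomeAnnotation as GTF
#'
#' One gene row, one transcript row and the merged exon rows per gene,
#' GENCODE-attribute style (`gene_id`, `transcript_id`, `gene_name`).
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGtf <- function(annotation, path) {
  g <- annotation@genes
  lines <- character(0)
  for (i in seq_along(g)) {
    gid <- mcols(g)$gene_id[i]
    nm <- mcols(g)$gene_name[i]
    chrom <- as.character(seqnames(g))[i]
    att <- sprintf('gene_id "%s"; gene_name "%s";', gid, nm)
    txa <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                   gid, gid, nm)
    ex <- annotation@exons[mcols(annotation@exons)$gene_id == gid]
    lines <- c(lines,
      paste(chrom, "sim", "gene", start(g)[i], end(g)[i], ".", "+", ".",
            att, sep = "\t"),
      paste(chrom, "sim", "transcript", start(g)[i], end(g)[i], ".", "+",
            ".", txa, sep = "\t"),
      vapply(seq_along(ex), function(j)
        paste(chrom, "sim", "exon", start(ex)[j], end(ex)[j], ".", "+", ".",
              txa, sep = "\t"), character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a GenomeAnnotation as GFF3
#'
#' @inheritParams writeGtf
#' @return Invisibly, `path`.
#' @export
writeGff3 <- function(annotation, path) {
  g <- annotation@genes
  lines <- "##gff-version 3"
  for (i in seq_along(g)) {
    gid <- mcols(g)$gene_id[i]
    chrom <- as.character(seqnames(g))[i]
    ex <- annotation@exons[mcols(annotation@exons)$gene_id == gid]
    lines <- c(lines,
      paste(chrom, "sim", "gene", start(g)[i], end(g)[i], ".", "+", ".",
            sprintf("ID=gene:%s;gene_id=%s;Name=%s", gid, gid,
                    mcols(g)$gene_name[i]), sep = "\t"),
      paste(chrom, "sim", "mRNA", start(g)[i], end(g)[i], ".", "+", ".",
            sprintf("ID=tx:%s.t1;Parent=gene:%s;gene_id=%s", gid, gid, gid),
            sep = "\t"),
      vapply(seq_along(ex), function(j)
        paste(chrom, "sim", "exon", start(ex)[j], end(ex)[j], ".", "+", ".",
              sprintf("ID=exon:%s.%d;Parent=tx:%s.t1;gene_id=%s",
                      gid, j, gid, gid), sep = "\t"), character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

# --- SV placement --------------------------------------------------------

# deterministically place one SV of the requested (class, type) for a gene;
# returns a one-row data.frame (chrom, start, end, svlen, mate_chrom,
# mate_pos) or errors when the gene cannot host the class
.placeSV <- function(annotation, gene_id, region_class, sv_type, len) {
  g <- annotation@genes[mcols(annotation@genes)$gene_id == gene_id]
  if (length(g) == 0L) stop("effect gene absent from annotation: ", gene_id)
  chrom <- as.character(seqnames(g))
  ex <- annotation@exons[mcols(annotation@exons)$gene_id == gene_id]
  intr <- annotation@introns[mcols(annotation@introns)$gene_id == gene_id]
  point <- sv_type %in% c("INS", "BND")
  pick <- function(rng) rng[which.max(width(rng))]
  if (region_class == "exonic") {
    host <- pick(ex)
    if (point) { s <- start(host) + width(host) %/% 2L; e <- s }
    else { l <- min(len, width(host) - 2L)
           s <- start(host) + 1L; e <- s + l - 1L }
  } else if (region_class == "intronic") {
    if (length(intr) == 0L)
      stop("gene ", gene_id, " has no intron for an intronic effect")
    host <- pick(intr)
    if (point) { s <- start(host) + width(host) %/% 2L; e <- s }
    else {
      if (width(host) < len + 2L && width(host) < 52L)
        stop("intron of ", gene_id, " too short for an intronic SV")
      l <- min(len, width(host) - 2L)
      s <- start(host) + 1L; e <- s + l - 1L }
  } else if (region_class == "splicing") {
    if (point) stop("a point-like ", sv_type,
                    " cannot produce a splicing assignment")
    if (length(intr) == 0L)
      stop("gene ", gene_id, " has no exon/intron boundary")
    # first exon with an intron immediately to its right
    idx <- which((end(ex) + 1L) %in% start(intr))
    if (length(idx) == 0L) idx <- 1L
    host <- ex[idx[1L]]
    nxt <- intr[start(intr) == end(host) + 1L][1L]
    half <- max(1L, len %/% 2L)
    s <- max(start(host), end(host) - half + 1L)
    e <- min(end(nxt), s + len - 1L)
    if (e <= end(host)) e <- end(host) + 1L
  } else if (region_class == "intergenic") {
    all_g <- annotation@genes
    same <- all_g[as.character(seqnames(all_g)) == chrom]
    nxt <- same[start(same) > end(g)]
    gap_end <- if (length(nxt)) min(start(nxt)) - 1L else end(g) + 100000L
    gap <- gap_end - end(g)
    off <- max(2L, gap %/% 10L)
    s <- end(g) + off
    if (point) e <- s
    else e <- min(s + len - 1L, end(g) + gap %/% 3L)
    if (e < s) e <- s
  } else stop("unknown region class: ", region_class)
  data.frame(chrom = chrom, start = s, end = e,
             svlen = if (sv_type == "INS") len else e - s + 1L,
             mate_chrom = if (sv_type == "BND") "chrM" else NA_character_,
             mate_pos = if (sv_type == "BND") 1000L else NA_integer_)
}

#' Simulate a case-control SV cohort with planted effects
#'
#' Draws per-sample carrier status for every configured effect (controls at
#' `carrier_freq_controls`, cases at the odds-transformed probability),
#' places the effect SV so that [classifySV()] assigns the intended
#' (gene, class) - the placement is validated by running the classifier -
#' and adds background SVs of the configured class/type mix placed uniformly
#' off the effect genes.  Each effect locus is a single recurrent template
#' shared by its carriers, so it merges into one cluster.
#'
#' @param config A [simulationConfig()].
#' @param annotation A [GenomeAnnotation-class], normally from
#'   [simulateAnnotation()] with the same config.
#' @param dir Optional directory; when given, VCFs (per sample or one
#'   multi-sample file, per `config$vcf_mode`), `manifest.tsv` and
#'   `truth.tsv` are written there.
#' @return List with `calls` (GRanges across all samples), `manifest`
#'   (data.frame), `truth` (data.frame of planted effects with realized
#'   per-stratum carrier counts) and, when `dir` is given, `vcf_paths`.
#' @export
simulateCohort <- function(config, annotation, dir = NULL) {
  set.seed(config$seed + 1L)
  man <- do.call(rbind, lapply(seq_len(nrow(config$strata)), function(i) {
    s <- config$strata[i, ]
    data.frame(
      sample_id = c(sprintf("%s_case_%04d", s$label, seq_len(s$n_cases)),
                    sprintf("%s_ctrl_%04d", s$label, seq_len(s$n_controls))),
      phenotype = rep(c("case", "control"), c(s$n_cases, s$n_controls)),
      stratum = s$label)
  }))
  rownames(man) <- NULL

  calls <- list()
  truth <- list()
  eff <- config$effects
  for (i in seq_len(nrow(eff))) {
    e <- eff[i, ]
    len <- max(52L, min(320L, config$sv_len[2L]))
    tmpl <- .placeSV(annotation, e$gene_id, e$region_class, e$sv_type, len)
    tg <- GRanges(tmpl$chrom, IRanges(tmpl$start, tmpl$end))
    mcols(tg) <- DataFrame(sv_id = "tmpl", sv_type = e$sv_type,
      svlen = tmpl$svlen, filter = "PASS", event_id = "tmpl",
      mate_chrom = tmpl$mate_chrom, mate_pos = tmpl$mate_pos,
      unpaired = FALSE, sample_id = "tmpl")
    asn <- classifySV(tg, annotation)
    ok <- any(asn$gene_id == e$gene_id & asn$region_class == e$region_class)
    if (!ok)
      stop("placed SV for ", e$gene_id, " failed to classify as ",
           e$region_class)
    idx <- man$stratum == e$stratum
    pcar <- ifelse(man$phenotype[idx] == "case",
                   carrierCaseProb(e$carrier_freq_controls, e$odds_ratio),
                   e$carrier_freq_controls)
    carries <- rbinom(sum(idx), 1L, pcar) == 1L
    carr_samples <- man$sample_id[idx][carries]
    if (length(carr_samples)) {
      rep_gr <- rep(granges(tg), length(carr_samples))
      mcols(rep_gr) <- DataFrame(
        sv_id = sprintf("eff%03d", i), sv_type = e$sv_type,
        svlen = tmpl$svlen, filter = "PASS",
        event_id = sprintf("eff%03d", i),
        mate_chrom = tmpl$mate_chrom, mate_pos = tmpl$mate_pos,
        unpaired = FALSE, sample_id = carr_samples)
      calls[[length(calls) + 1L]] <- rep_gr
    }
    ph <- man$phenotype[idx]
    truth[[i]] <- data.frame(e,
      case_carriers = sum(carries & ph == "case"),
      control_carriers = sum(carries & ph == "control"),
      case_prob = carrierCaseProb(e$carrier_freq_controls, e$odds_ratio))
  }

  bg <- .simulateBackground(config, annotation, man)
  if (length(bg)) calls[[length(calls) + 1L]] <- bg
  allcalls <- if (length(calls))
    unlist(GenomicRanges::GRangesList(calls), use.names = FALSE)
  else .emptyCalls()

  out <- list(calls = allcalls, manifest = man,
              truth = if (length(truth)) do.call(rbind, truth) else
                data.frame())
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (config$vcf_mode == "multi") {
      p <- file.path(dir, "cohort.vcf")
      writeSVVcf(allcalls, p, samples = man$sample_id)
      out$vcf_paths <- p
    } else {
      out$vcf_paths <- vapply(man$sample_id, function(sm) {
        p <- file.path(dir, paste0(sm, ".vcf"))
        sub <- allcalls[mcols(allcalls)$sample_id == sm]
        writeSVVcf(sub, p, samples = sm)
        p
      }, character(1))
    }
  }
  out
}

.simulateBackground <- function(config, annotation, man) {
  if (config$background_rate <= 0) return(GRanges())
  g <- annotation@genes
  avoid <- if (config$avoid_effect_genes) unique(config$effects$gene_id)
           else character(0)
  keep <- !mcols(g)$gene_id %in% avoid
  ex <- annotation@exons[!mcols(annotation@exons)$gene_id %in% avoid]
  intr <- annotation@introns[!mcols(annotation@introns)$gene_id %in% avoid]
  intr <- intr[width(intr) >= 54L]
  gaps <- unlist(GenomicRanges::GRangesList(lapply(
    split(g, as.character(seqnames(g))), function(gg) {
      gg <- gg[order(start(gg))]
      if (length(gg) < 2L) return(GRanges())
      GRanges(seqnames(gg)[1L],
              IRanges(utils::head(end(gg), -1L) + 1L,
                      utils::tail(start(gg), -1L) - 1L))
    })), use.names = FALSE)
  gaps <- gaps[width(gaps) >= 200L]

  # plain lookup tables; element-wise GRanges access is too slow here
  tab <- function(gr) data.frame(chrom = as.character(seqnames(gr)),
    start = start(gr), end = end(gr), width = width(gr))
  host <- list(exonic = tab(ex), intronic = tab(intr),
               intergenic = tab(gaps))
  spl <- tab(ex[(end(ex) + 1L) %in% start(intr)])
  intr_start <- setNames(seq_len(length(intr)), start(intr))

  classes <- names(config$class_props)
  types <- names(config$type_props)
  res <- list()
  for (sm in man$sample_id) {
    nsv <- rpois(1L, config$background_rate)
    if (nsv == 0L) next
    cls <- sample(classes, nsv, replace = TRUE, prob = config$class_props)
    ty <- sample(types, nsv, replace = TRUE, prob = config$type_props)
    # point-like types cannot realise a splicing assignment
    pointlike <- ty %in% c("INS", "BND")
    cls[pointlike & cls == "splicing"] <- "intronic"
    lens <- as.integer(floor(runif(nsv, config$sv_len[1L],
                                   config$sv_len[2L] + 1)))
    fails <- runif(nsv) < config$fail_rate
    chrom <- character(nsv); s <- integer(nsv); e <- integer(nsv)
    ok <- logical(nsv)
    for (j in seq_len(nsv)) {
      if (cls[j] != "splicing") {
        h <- host[[cls[j]]]
        if (nrow(h) == 0L) next
        i <- sample.int(nrow(h), 1L)
        if (pointlike[j]) {
          s[j] <- h$start[i] + sample.int(max(1L, h$width[i] - 2L), 1L)
          e[j] <- s[j]
        } else {
          l <- min(lens[j], h$width[i] - 2L)
          if (l < 1L) next
          s[j] <- h$start[i] + sample.int(h$width[i] - l - 1L, 1L)
          e[j] <- s[j] + l - 1L
        }
        chrom[j] <- h$chrom[i]
      } else {
        if (nrow(spl) == 0L) next
        i <- sample.int(nrow(spl), 1L)
        nxt <- intr[intr_start[[as.character(spl$end[i] + 1L)]]]
        s[j] <- max(spl$start[i], spl$end[i] - lens[j] %/% 2L)
        e[j] <- min(end(nxt), s[j] + lens[j] - 1L)
        if (e[j] <= spl$end[i]) e[j] <- spl$end[i] + 1L
        chrom[j] <- spl$chrom[i]
      }
      ok[j] <- TRUE
    }
    if (!any(ok)) next
    nk <- sum(ok)
    gr <- GRanges(chrom[ok], IRanges(s[ok], e[ok]))
    tyk <- ty[ok]
    mcols(gr) <- DataFrame(
      sv_id = sprintf("bg_%s_%03d", sm, seq_len(nk)),
      sv_type = tyk,
      svlen = ifelse(tyk == "INS", lens[ok],
                     ifelse(tyk == "BND", NA_integer_,
                            e[ok] - s[ok] + 1L)),
      filter = ifelse(fails[ok], "MinQUAL", "PASS"),
      event_id = sprintf("bg_%s_%03d", sm, seq_len(nk)),
      mate_chrom = ifelse(tyk == "BND", "chrM", NA_character_),
      mate_pos = ifelse(tyk == "BND", 1000L, NA_integer_),
      unpaired = FALSE, sample_id = sm)
    res[[sm]] <- gr
  }
  if (length(res) == 0L) return(GRanges())
  unlist(GenomicRanges::GRangesList(res), use.names = FALSE)
}

#' Directly simulate a carrier matrix (the generator's statistical core)
#'
#' Skips genome placement and VCF round-tripping: carrier indicators per
#' (gene, class, type) key are drawn straight from the configured control
#' frequencies and carrier odds ratios.  This is the tool for calibration
#' and power studies that need hundreds of replicate cohorts.
#'
#' @param strata Data.frame with `label`, `n_cases`, `n_controls`.
#' @param n_genes Number of gene keys.
#' @param carrier_freq Control carrier frequency shared by all null genes.
#' @param effects Optional data.frame with `gene_id`, `stratum`,
#'   `carrier_freq_controls`, `odds_ratio` overriding individual genes.
#' @param region_class,sv_type Key annotation applied to all genes.
#' @param seed RNG seed.
#' @return A [CarrierMatrix-class].
#' @export
simulateCarrierMatrix <- function(strata, n_genes = 200,
    carrier_freq = 0.05, effects = NULL,
    region_class = "intronic", sv_type = "DEL", seed = 1L) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  man <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    data.frame(
      sample_id = c(sprintf("%s_case_%04d", s$label, seq_len(s$n_cases)),
                    sprintf("%s_ctrl_%04d", s$label, seq_len(s$n_controls))),
      phenotype = rep(c("case", "control"), c(s$n_cases, s$n_controls)),
      stratum = s$label)
  }))
  nsamp <- nrow(man)
  pm <- matrix(carrier_freq, nrow = n_genes, ncol = nsamp)
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      r <- match(e$gene_id, genes)
      if (is.na(r)) stop("effect gene not among keys: ", e$gene_id)
      idx <- man$stratum == e$stratum
      pm[r, idx] <- ifelse(man$phenotype[idx] == "case",
                           carrierCaseProb(e$carrier_freq_controls,
                                           e$odds_ratio),
                           e$carrier_freq_controls)
    }
  }
  mat <- matrix(rbinom(length(pm), 1L, pm), nrow = n_genes,
                dimnames = list(paste(genes, region_class, sv_type,
                                      sep = "|"),
                                man$sample_id))
  rd <- DataFrame(gene_id = genes, region_class = region_class,
                  sv_type = sv_type, row.names = rownames(mat))
  cd <- DataFrame(phenotype = man$phenotype, stratum = man$stratum,
                  row.names = man$sample_id)
  CarrierMatrix(SummarizedExperiment(assays = list(carrier = mat),
                                     rowData = rd, colData = cd))
}

#' Preset: two-ancestry ADHD-style cohort scenario
#'
#' Configuration mirroring the design of a two-ancestry ADHD WGS study:
#' strata AA with 116 cases / 408 controls and EA with 89 cases / 262
#' controls (205 cases, 670 controls in total), 200 genes on 4 chromosomes,
#' and largely disjoint planted effect gene sets per stratum (2 of 31
#' affected genes shared, ~6% overlap).  Output is a single multi-sample
#' VCF.
#'
#' @param seed RNG seed for the whole scenario.
#' @return A [simulationConfig()].
#' @export
adhdCohortScenario <- function(seed = 1L) {
  aa_genes <- sprintf("G%04d", 1:16)
  ea_genes <- sprintf("G%04d", 15:31)
  mkeff <- function(genes, stratum) {
    n <- length(genes)
    data.frame(gene_id = genes,
      region_class = rep(c("intronic", "intergenic", "exonic", "splicing"),
                         length.out = n),
      sv_type = rep(c("DEL", "INS", "DUP", "INV"), length.out = n),
      stratum = stratum,
      carrier_freq_controls = rep(c(0.03, 0.05, 0.08), length.out = n),
      odds_ratio = rep(c(2.5, 3, 4, 6), length.out = n))
  }
  eff <- rbind(mkeff(aa_genes, "AA"), mkeff(ea_genes, "EA"))
  # point-like types cannot realise splicing; swap those onto DEL
  bad <- eff$region_class == "splicing" & eff$sv_type %in% c("INS", "BND")
  eff$sv_type[bad] <- "DEL"
  simulationConfig(seed = seed, n_chroms = 4L, n_genes = 200L,
    strata = data.frame(label = c("AA", "EA"),
                        n_cases = c(116L, 89L),
                        n_controls = c(408L, 262L)),
    effects = eff, background_rate = 8, vcf_mode = "multi")
}
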