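#' Run the end-to-end SV association pipeline
#'
#' Sequences the whole analysis: read annotation and calls, apply quality
#' filters, classify, merge recurrent loci, build the carrier matrix,
#' associate per stratum, meta-combine, apply the rare/recurrent case-only
#' filter, summarise cross-stratum overlap and tally gene sets.  All
#' intermediate artifacts are plain TSV/BED/JSON with a provenance header
#' (producing step, config hash, package version, seed), so any stage can be
#' inspected or re-entered from the shell.
#'
#' @param config Named list (or YAML-loaded equivalent) with elements:
#'   `annotation` (GTF/GFF3 path), `vcfs` (character vector of VCF paths, or
#'   a directory), `manifest` (TSV path), optional `gene_sets` (GMT path),
#'   `out_dir`, and optional parameters `min_len` (50), `require_pass`
#'   (TRUE), `window` (50), `reciprocal_overlap` (0.8), `alpha` (0.05),
#'   `risk_only` (TRUE), `yates` (FALSE), `min_case_occurrence` (2),
#'   `max_control_freq` (0.005), `case_only` (TRUE), `seed` (1).
#' @return Invisibly, a list with every stage result (`annotation`, `calls`,
#'   `filtered`, `assignments`, `clusters`, `carrier_matrix`, `results`
#'   per stratum, `meta`, `recurrent`, `overlap`, `geneset`, `summary`)
#'   plus the paths written.
#' @export
runPipeline <- function(config) {
  cfg <- .fillConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  prov <- sprintf("# svgenes %s | config %s | seed %d",
                  as.character(packageVersion("svgenes")), hash, cfg$seed)
  log <- function(...) message("[svgenes] ", ...)

  stage <- "annotate"
  res <- tryCatch({
    annotation <- loadAnnotation(cfg$annotation)
    log("annotation: ", length(geneRanges(annotation)), " genes")

    stage <- "read"
    vcfs <- cfg$vcfs
    if (length(vcfs) == 1L && dir.exists(vcfs))
      vcfs <- list.files(vcfs, pattern = "\\.vcf$", full.names = TRUE)
    calls <- unlist(GenomicRanges::GRangesList(lapply(vcfs, function(p)
      readSVVcf(p, sample_id = sub("\\.vcf$", "", basename(p))))),
      use.names = FALSE)
    manifest <- readManifest(cfg$manifest)
    log("calls in: ", length(calls), " from ", length(vcfs), " VCF(s)")

    stage <- "filter"
    filtered <- filterCalls(calls, min_len = cfg$min_len,
                            require_pass = cfg$require_pass)
    log("calls after filters: ", length(filtered), " (removed ",
        length(calls) - length(filtered), ")")

    stage <- "classify"
    assignments <- classifySV(filtered, annotation)
    cls <- table(assignments$region_class)
    log("assignments: ", nrow(assignments), " (",
        paste(names(cls), as.integer(cls), sep = "=", collapse = ", "), ")")

    stage <- "merge"
    clusters <- mergeLoci(filtered, window = cfg$window,
                          reciprocal_overlap = cfg$reciprocal_overlap)
    log("clusters: ", length(clusters))

    stage <- "matrix"
    cm <- buildCarrierMatrix(assignments, manifest, unit = "sv_gene",
                             strict = FALSE)

    stage <- "associate"
    strata <- unique(manifest$stratum)
    results <- lapply(strata, function(s)
      associateStratum(cm, s, alpha = cfg$alpha, risk_only = cfg$risk_only,
                       yates = cfg$yates))
    names(results) <- strata

    stage <- "meta"
    meta <- if (length(strata) > 1L)
      metaAnalyze(cm, strata, alpha = cfg$alpha,
                  risk_only = cfg$risk_only, yates = cfg$yates) else NULL

    stage <- "recur"
    recurrent <- rareRecurrentFilter(clusters, manifest,
      min_case_occurrence = cfg$min_case_occurrence,
      max_control_freq = cfg$max_control_freq, case_only = cfg$case_only)
    log("rare recurrent clusters kept: ", length(recurrent))

    stage <- "overlap"
    overlap <- if (length(strata) > 1L)
      ethnicityOverlap(results, alpha = cfg$alpha) else NULL

    stage <- "geneset"
    geneset <- if (!is.null(cfg$gene_sets)) {
      allres <- do.call(rbind, lapply(results, as.data.frame))
      genesetTally(allres, readGmt(cfg$gene_sets), alpha = cfg$alpha)
    } else NULL

    summary <- list(
      n_calls = length(calls), n_filtered = length(filtered),
      n_assignments = nrow(assignments),
      class_proportions = as.list(
        round(prop.table(table(assignments$region_class)), 4)),
      n_clusters = length(clusters), n_recurrent = length(recurrent),
      strata = as.list(table(manifest$stratum)),
      config_hash = hash, seed = cfg$seed,
      version = as.character(packageVersion("svgenes")))

    list(annotation = annotation, calls = calls, filtered = filtered,
         assignments = assignments, clusters = clusters,
         carrier_matrix = cm, results = results, meta = meta,
         recurrent = recurrent, overlap = overlap, geneset = geneset,
         summary = summary)
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))

  paths <- .writePipelineOutputs(res, cfg, prov)
  res$paths <- paths
  invisible(res)
}

.fillConfig <- function(config) {
  defaults <- list(min_len = 50, require_pass = TRUE, window = 50,
    reciprocal_overlap = 0.8, alpha = 0.05, risk_only = TRUE,
    yates = FALSE, min_case_occurrence = 2, max_control_freq = 0.005,
    case_only = TRUE, seed = 1L, gene_sets = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  need <- c("annotation", "vcfs", "manifest", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing: ", paste(miss, collapse = ", "))
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  for (p in c(config$annotation, config$manifest))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  config
}

# small polynomial rolling hash so output provenance lines are reproducible
# without a digest dependency
.configHash <- function(cfg) {
  # fingerprint the analytical parameters, not file locations
  cfg[c("annotation", "vcfs", "manifest", "gene_sets", "out_dir")] <- NULL
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.writePipelineOutputs <- function(res, cfg, prov) {
  out <- cfg$out_dir
  wtsv <- function(df, name) {
    p <- file.path(out, name)
    con <- file(p, "w")
    writeLines(paste(prov, "|", name), con)
    write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    p
  }
  paths <- list()
  paths$assignments <- wtsv(res$assignments, "assignments.tsv")
  cl <- res$clusters
  if (length(cl)) {
    bed <- data.frame(chrom = as.character(seqnames(cl)),
      start = start(cl) - 1L, end = end(cl),
      name = mcols(cl)$cluster_id, score = mcols(cl)$occurrence,
      strand = ".", sv_type = mcols(cl)$sv_type)
    p <- file.path(out, "clusters.bed")
    writeLines(c(paste(prov, "| clusters.bed"),
                 do.call(paste, c(bed, sep = "\t"))), p)
    paths$clusters <- p
  }
  for (s in names(res$results))
    paths[[paste0("association_", s)]] <-
      wtsv(res$results[[s]], paste0("association_", s, ".tsv"))
  if (!is.null(res$meta)) paths$meta <- wtsv(res$meta, "meta.tsv")
  if (length(res$recurrent)) {
    rec <- res$recurrent
    paths$recurrent <- wtsv(data.frame(
      cluster_id = mcols(rec)$cluster_id, sv_type = mcols(rec)$sv_type,
      chrom = as.character(seqnames(rec)), start = start(rec),
      end = end(rec), occurrence = mcols(rec)$occurrence,
      case_carriers = mcols(rec)$case_carriers,
      control_carriers = mcols(rec)$control_carriers,
      control_freq = mcols(rec)$control_freq), "recurrent.tsv")
  }
  if (!is.null(res$overlap)) {
    p <- file.path(out, "overlap.json")
    write_json(res$overlap, p, auto_unbox = TRUE, pretty = TRUE,
               digits = NA)
    paths$overlap <- p
  }
  if (!is.null(res$geneset))
    paths$geneset <- wtsv(res$geneset, "geneset.tsv")
  p <- file.path(out, "summary.json")
  write_json(res$summary, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$summary <- p
  paths
}
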