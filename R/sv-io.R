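#' Read a MANTA-style structural variant VCF
#'
#' Parses VCF 4.x SV records (INFO `SVTYPE`, `END`, `SVLEN`, `MATEID`;
#' symbolic ALTs `<DEL>`, `<INS>`, `<DUP>`, `<DUP:TANDEM>`, `<INV>`; breakend
#' bracket ALTs) into a GRanges of per-sample calls.  `POS` is taken as the
#' first affected base, so a deletion with `POS = p` and `END = e` occupies
#' the closed interval `[p, e]` of length `e - p + 1`.  Insertions occupy the
#' single anchor base `[POS, POS]` and take their length from `|SVLEN|`.
#' Breakends occupy `[POS, POS]`; mates are paired through `MATEID`, or
#' through the ALT coordinates when `MATEID` is absent, into two records
#' sharing an `event_id`.  Records with neither `SVTYPE` nor a symbolic ALT
#' are skipped with a warning; breakends without a resolvable mate are kept
#' and flagged `unpaired`.
#'
#' For a multi-sample VCF every sample whose genotype contains a non-reference
#' allele receives the record; for a VCF without genotype columns all records
#' are assigned to `sample_id`.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample to assign records to when the file has no
#'   genotype columns (single-sample MANTA output).  Ignored when genotype
#'   columns are present.
#' @return GRanges with metadata columns `sample_id`, `sv_id`, `sv_type`
#'   (DEL/INS/DUP/INV/BND), `svlen` (bp, `NA` when undefined), `filter`,
#'   `event_id`, `mate_chrom`, `mate_pos`, `unpaired`.
#' @seealso [filterCalls()], [writeSVVcf()]
#' @export
readSVVcf <- function(path, sample_id = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) return(.emptyCalls())
  info <- VariantAnnotation::info(vcf)
  alt <- .firstElement(VariantAnnotation::alt(vcf), n)
  svtype <- if ("SVTYPE" %in% colnames(info))
    as.character(info$SVTYPE) else rep(NA_character_, n)
  svtype[is.na(svtype)] <- .typeFromAlt(alt[is.na(svtype)])
  drop <- is.na(svtype)
  if (any(drop))
    warning(sum(drop), " record(s) without SVTYPE or symbolic ALT skipped")
  svtype[svtype == "DUP:TANDEM"] <- "DUP"
  endv <- if ("END" %in% colnames(info)) .firstElement(info$END, n)
          else rep(NA_integer_, n)
  svlen <- if ("SVLEN" %in% colnames(info)) abs(.firstElement(info$SVLEN, n))
           else rep(NA_integer_, n)
  mateid <- if ("MATEID" %in% colnames(info)) .firstElement(info$MATEID, n)
            else rep(NA_character_, n)
  pos <- start(rr)
  chrom <- as.character(seqnames(rr))
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0("sv", seq_len(n))
  filt <- as.character(VariantAnnotation::filt(vcf))

  isbnd <- !is.na(svtype) & svtype == "BND"
  s <- pos
  e <- ifelse(isbnd | svtype == "INS", pos,
              ifelse(!is.na(endv), endv,
                     ifelse(!is.na(svlen), pos + svlen - 1L, pos)))
  len <- ifelse(isbnd, NA_integer_,
                ifelse(!is.na(svlen), svlen, e - s + 1L))
  mate <- .parseBndAlt(alt)
  mate$chrom[!isbnd] <- NA_character_
  mate$pos[!isbnd] <- NA_integer_
  event <- ids
  # pair breakends through MATEID (preferred) or mate coordinates
  if (any(isbnd)) {
    key <- ifelse(!is.na(mateid),
                  .pairKey(ids, mateid),
                  ifelse(!is.na(mate$chrom),
                         .pairKey(paste0(chrom, ":", pos),
                                  paste0(mate$chrom, ":", mate$pos)),
                         NA_character_))
    event[isbnd] <- ifelse(is.na(key[isbnd]), ids[isbnd],
                           paste0("bnd_", key[isbnd]))
    # resolve mate position from the MATEID partner when ALT lacked it
    m <- match(mateid, ids)
    fix <- isbnd & is.na(mate$chrom) & !is.na(m)
    mate$chrom[fix] <- chrom[m[fix]]
    mate$pos[fix] <- pos[m[fix]]
  }
  unpaired <- isbnd & is.na(mate$chrom)

  keep <- !drop
  gr <- GRanges(chrom[keep], IRanges(s[keep], pmax(s, e)[keep]))
  mcols(gr) <- DataFrame(
    sv_id = ids[keep], sv_type = svtype[keep],
    svlen = as.integer(len[keep]), filter = filt[keep],
    event_id = event[keep], mate_chrom = mate$chrom[keep],
    mate_pos = as.integer(mate$pos[keep]), unpaired = unpaired[keep])

  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  if (!is.null(gt) && ncol(gt) > 0L) {
    gt <- gt[keep, , drop = FALSE]
    carrier <- apply(gt, 2L, function(g) grepl("1", g))
    if (nrow(gt) == 1L) carrier <- matrix(carrier, nrow = 1L)
    out <- lapply(colnames(gt), function(sm) {
      sub <- gr[carrier[, sm]]
      if (length(sub)) mcols(sub)$sample_id <- sm
      sub
    })
    gr <- unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
  } else {
    if (is.null(sample_id))
      stop("VCF has no genotype columns; supply sample_id")
    mcols(gr)$sample_id <- sample_id
  }
  gr
}

.emptyCalls <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(sv_id = character(), sv_type = character(),
    svlen = integer(), filter = character(), event_id = character(),
    mate_chrom = character(), mate_pos = integer(), unpaired = logical(),
    sample_id = character())
  gr
}

.firstElement <- function(x, n) {
  if (is(x, "List") || is.list(x)) {
    out <- sapply(x, function(v) if (length(v)) v[[1L]] else NA)
    if (length(out) == 0L) out <- rep(NA, n)
    out
  } else x
}

.typeFromAlt <- function(alt) {
  out <- rep(NA_character_, length(alt))
  sym <- grepl("^<.+>$", alt)
  out[sym] <- sub("^<([A-Z]+)(:[A-Z]+)?>$", "\\1", alt[sym])
  out[grepl("[][]", alt)] <- "BND"
  out[!out %in% c("DEL", "INS", "DUP", "INV", "BND")] <- NA_character_
  out
}

.parseBndAlt <- function(alt) {
  m <- regmatches(alt, regexpr("[][][^][]+:[0-9]+[][]", alt))
  chrom <- rep(NA_character_, length(alt))
  pos <- rep(NA_integer_, length(alt))
  hit <- grepl("[][][^][]+:[0-9]+[][]", alt)
  inner <- sub("^[][]", "", sub("[][]$", "", m))
  chrom[hit] <- sub(":.*$", "", inner)
  pos[hit] <- as.integer(sub("^.*:", "", inner))
  list(chrom = chrom, pos = pos)
}

.pairKey <- function(a, b) {
  mapply(function(x, y) paste(sort(c(x, y)), collapse = "__"), a, b,
         USE.NAMES = FALSE)
}

#' Apply SV quality filters
#'
#' Keeps calls rated `PASS` (when `require_pass`) with length at least
#' `min_len` bp.  Breakends have no meaningful length and are exempt from the
#' length rule; they are kept on the filter status alone.
#'
#' @param calls GRanges from [readSVVcf()].
#' @param min_len Minimum SV length in bp (default 50).
#' @param require_pass Drop records whose FILTER is not `PASS`.
#' @return The filtered GRanges (a subset of the input; idempotent).
#' @export
filterCalls <- function(calls, min_len = 50, require_pass = TRUE) {
  ok <- rep(TRUE, length(calls))
  if (require_pass) ok <- ok & mcols(calls)$filter == "PASS"
  len <- mcols(calls)$svlen
  ok <- ok & (mcols(calls)$sv_type == "BND" | (!is.na(len) & len >= min_len))
  calls[ok]
}

#' Read a cohort manifest
#'
#' Tab-separated file with header columns `sample_id`, `phenotype`
#' (`case`/`control`) and `stratum` (an ancestry label such as `AA` or `EA`).
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with the three validated columns; per-stratum
#'   case/control counts are reported with `message()`.
#' @export
readManifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype", "stratum")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in manifest: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  bad <- !df$phenotype %in% c("case", "control")
  if (any(bad))
    stop("unknown phenotype value: ", df$phenotype[bad][1L])
  tab <- table(df$stratum, df$phenotype)
  for (s in rownames(tab))
    message("stratum ", s, ": ", tab[s, "case"], " cases, ",
            tab[s, "control"], " controls")
  df
}

#' Write SV calls as a MANTA-dialect VCF
#'
#' Emits VCF 4.2 with symbolic ALTs, INFO `SVTYPE`/`END`/`SVLEN`
#' (`MATEID` and bracket ALTs for breakends) and one `GT` genotype column per
#' sample.  Calls identical across samples (same type, coordinates and
#' length) are written as one record with carrier genotypes.
#'
#' @param calls GRanges in the layout produced by [readSVVcf()].
#' @param path Output path.
#' @param samples Sample column order; defaults to the samples present.
#' @return Invisibly, `path`.
#' @export
writeSVVcf <- function(calls, path, samples = NULL) {
  mc <- mcols(calls)
  if (is.null(samples)) samples <- unique(mc$sample_id)
  key <- paste(seqnames(calls), start(calls), mc$sv_type, end(calls),
               mc$svlen, mc$mate_chrom, mc$mate_pos, mc$event_id)
  first <- !duplicated(key)
  uk <- key[first]
  u <- calls[first]
  um <- mcols(u)
  ids <- um$sv_id
  ids[duplicated(ids)] <- paste0(ids[duplicated(ids)], "_",
                                 seq_len(sum(duplicated(ids))))
  # breakend mates: point members of the same event at each other
  mate_of <- rep(NA_character_, length(u))
  for (ev in unique(um$event_id[um$sv_type == "BND"])) {
    i <- which(um$event_id == ev)
    if (length(i) == 2L) mate_of[i] <- ids[rev(i)]
  }
  alt <- character(length(u))
  infof <- character(length(u))
  for (i in seq_along(u)) {
    ty <- um$sv_type[i]
    if (ty == "BND") {
      alt[i] <- if (!is.na(um$mate_chrom[i]))
        paste0("N[", um$mate_chrom[i], ":", um$mate_pos[i], "[") else "N."
      infof[i] <- paste0("SVTYPE=BND",
        if (!is.na(mate_of[i])) paste0(";MATEID=", mate_of[i]) else "")
    } else {
      sl <- um$svlen[i]
      sgn <- if (ty == "DEL") -1L else 1L
      infof[i] <- paste0("SVTYPE=", ty, ";END=", end(u)[i],
        if (!is.na(sl)) paste0(";SVLEN=", sgn * sl) else "")
      alt[i] <- paste0("<", ty, ">")
    }
  }
  gt <- matrix("0/0", nrow = length(u), ncol = length(samples),
               dimnames = list(NULL, samples))
  ridx <- match(key, uk)
  cidx <- match(mc$sample_id, samples)
  keep <- !is.na(cidx)
  gt[cbind(ridx[keep], cidx[keep])] <- "0/1"
  hdr <- c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(as.character(seqnames(calls))), ">"),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend id">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INS,Description="Insertion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=INV,Description="Inversion">',
    '##FILTER=<ID=MinQUAL,Description="Low quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  o <- order(as.character(seqnames(u)), start(u), ids)
  gtstr <- do.call(paste,
                   c(lapply(seq_len(ncol(gt)), function(j) gt[, j]),
                     sep = "\t"))
  rows <- paste(as.character(seqnames(u)), start(u), ids, "N", alt, ".",
                um$filter, infof, "GT", gtstr, sep = "\t")[o]
  writeLines(c(hdr, rows), path)
  invisible(path)
}
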