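#' Classify SVs against the gene model
#'
#' Implements the four-way region classification.  For each deletion,
#' duplication, inversion or insertion, every gene whose span overlaps the SV
#' is evaluated independently:
#'
#' * **exonic** - both breakpoints fall in exons of the gene;
#' * **splicing** - the SV crosses at least one boundary of the gene's merged
#'   exon union (it overlaps an exon without being contained in it).  A gene
#'   may receive both `exonic` and `splicing` when the SV runs from exon to
#'   exon across an intron;
#' * **intronic** - the SV lies inside the gene but touches no exon (both
#'   breakpoints in one intron, no exon spanned).
#'
#' Breakends are classified per breakend as single points (a point in an exon
#' is exonic, in a gene span but not an exon intronic, otherwise intergenic).
#' An SV overlapping no gene span is **intergenic** and is assigned to its
#' nearest gene: the gene is chosen by the SV midpoint, the reported distance
#' is the gap between the SV interval and the gene span.  SVs overlapping
#' several genes contribute one assignment per gene, with no severity
#' pruning.
#'
#' @param calls GRanges of filtered calls from [filterCalls()].
#' @param annotation A [GenomeAnnotation-class].
#' @param strict Error on chromosomes absent from the annotation instead of
#'   assigning an intergenic record with `NA` gene.
#' @return A [S4Vectors::DataFrame] with one row per (SV, gene, class):
#'   columns `sample_id`, `sv_id`, `event_id`, `sv_type`, `chrom`, `start`,
#'   `end`, `svlen`, `gene_id`, `region_class`
#'   (exonic/splicing/intronic/intergenic) and `distance` (0 unless
#'   intergenic).
#' @export
classifySV <- function(calls, annotation, strict = FALSE) {
  if (length(calls) == 0L) return(.emptyAssignments())
  mc <- mcols(calls)
  genes <- annotation@genes
  exons <- annotation@exons
  gid <- mcols(genes)$gene_id
  eid <- mcols(exons)$gene_id

  known <- as.character(seqnames(calls)) %in%
    unique(as.character(seqnames(genes)))
  if (any(!known)) {
    msg <- paste0(sum(!known), " call(s) on chromosomes absent from the ",
                  "annotation")
    if (strict) stop(msg) else warning(msg)
  }

  # breakends reduce to their breakend point
  iv <- granges(calls)
  isbnd <- mc$sv_type == "BND"
  iv[isbnd] <- resize(iv[isbnd], 1L, fix = "start")
  startp <- resize(iv, 1L, fix = "start")
  endp <- resize(iv, 1L, fix = "end")

  pairkey <- function(q, s_gene) paste(q, s_gene)
  ov <- findOverlaps(iv, genes)
  qi <- queryHits(ov); gj <- gid[subjectHits(ov)]

  sHit <- findOverlaps(startp, exons)
  eHit <- findOverlaps(endp, exons)
  sSet <- unique(pairkey(queryHits(sHit), eid[subjectHits(sHit)]))
  eSet <- unique(pairkey(queryHits(eHit), eid[subjectHits(eHit)]))
  # exon-boundary crossing: SV overlaps an exon it does not lie within
  xo <- findOverlaps(iv, exons)
  xw <- findOverlaps(iv, exons, type = "within")
  crossKeys <- setdiff(pairkey(queryHits(xo), eid[subjectHits(xo)]),
                       pairkey(queryHits(xw), eid[subjectHits(xw)]))

  keys <- pairkey(qi, gj)
  exonic <- keys %in% sSet & keys %in% eSet
  splicing <- keys %in% crossKeys
  intronic <- !exonic & !splicing

  take <- function(flag, cls)
    if (any(flag)) data.frame(q = qi[flag], gene_id = gj[flag],
                              region_class = cls, distance = 0L)
  rows <- rbind(take(exonic, "exonic"), take(splicing, "splicing"),
                take(intronic, "intronic"))

  # intergenic: no gene-span overlap at all (including unknown chromosomes)
  hasgene <- seq_along(calls) %in% qi
  inter <- which(!hasgene & known)
  if (length(inter)) {
    mids <- GRanges(seqnames(iv)[inter],
                    IRanges((start(iv)[inter] + end(iv)[inter]) %/% 2L,
                            width = 1L))
    # the midpoint picks the gene; ties by lower span start then gene_id
    hits <- GenomicRanges::distanceToNearest(mids, genes, select = "all",
                                             ignore.strand = TRUE)
    hdf <- data.frame(q = queryHits(hits), g = subjectHits(hits))
    hdf <- hdf[order(hdf$q, start(genes)[hdf$g], gid[hdf$g]), ]
    hdf <- hdf[!duplicated(hdf$q), ]
    d <- GenomicRanges::distance(iv[inter][hdf$q], genes[hdf$g],
                                 ignore.strand = TRUE)
    rows <- rbind(rows, data.frame(q = inter[hdf$q],
      gene_id = gid[hdf$g], region_class = "intergenic",
      distance = as.integer(d)))
  }
  if (any(!known)) {
    rows <- rbind(rows, data.frame(q = which(!known),
      gene_id = NA_character_, region_class = "intergenic",
      distance = NA_integer_))
  }
  rows <- rows[order(rows$q, rows$gene_id, rows$region_class), ]
  DataFrame(
    sample_id = mc$sample_id[rows$q],
    sv_id = mc$sv_id[rows$q],
    event_id = mc$event_id[rows$q],
    sv_type = mc$sv_type[rows$q],
    chrom = as.character(seqnames(calls))[rows$q],
    start = start(iv)[rows$q],
    end = end(iv)[rows$q],
    svlen = mc$svlen[rows$q],
    gene_id = rows$gene_id,
    region_class = rows$region_class,
    distance = rows$distance)
}

.emptyAssignments <- function() {
  DataFrame(sample_id = character(), sv_id = character(),
    event_id = character(), sv_type = character(), chrom = character(),
    start = integer(), end = integer(), svlen = integer(),
    gene_id = character(), region_class = character(), distance = integer())
}

#' Merge equivalent SVs across samples into recurrent loci
#'
#' Single-linkage clustering of same-type, same-chromosome calls.  Two calls
#' are linked when both breakpoints agree within `window` bp and, for
#' interval types (DEL/DUP/INV), their reciprocal overlap is at least
#' `reciprocal_overlap`.  Breakends additionally require matching mate
#' chromosome and a mate position within `window` when both mates are known.
#' The result is order-invariant and idempotent.
#'
#' @param calls GRanges of filtered calls (across samples).
#' @param window Breakpoint match window in bp.
#' @param reciprocal_overlap Minimum reciprocal overlap fraction for
#'   interval types.
#' @return GRanges of clusters ordered by (chrom, start), each spanning its
#'   members, with metadata columns `cluster_id`, `sv_type`, `carriers`
#'   (CharacterList of sample ids), `occurrence` (number of distinct
#'   carriers) and `n_calls`.
#' @export
mergeLoci <- function(calls, window = 50, reciprocal_overlap = 0.8) {
  n <- length(calls)
  if (n == 0L)
    return(GRanges())
  mc <- mcols(calls)
  comp <- seq_len(n)            # union-find parent vector
  findp <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  unite <- function(i, j) {
    ri <- findp(i); rj <- findp(j)
    if (ri != rj) comp[min(ri, rj)] <<- comp[max(ri, rj)] <<- min(ri, rj)
  }
  grp <- paste(mc$sv_type, as.character(seqnames(calls)))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- calls[idx]
    o <- idx[order(start(sub), end(sub))]
    ss <- start(calls)[o]; ee <- end(calls)[o]; ww <- width(calls)[o]
    ty <- mc$sv_type[o][1L]
    for (a in seq_along(o)) {
      b <- a + 1L
      while (b <= length(o) && ss[b] - ss[a] <= window) {
        okend <- abs(ee[b] - ee[a]) <= window
        ok <- okend
        if (ok && ty %in% c("DEL", "DUP", "INV")) {
          ovl <- min(ee[a], ee[b]) - max(ss[a], ss[b]) + 1L
          ok <- ovl / ww[a] >= reciprocal_overlap &&
                ovl / ww[b] >= reciprocal_overlap
        }
        if (ok && ty == "BND") {
          ma <- mc$mate_chrom[o[a]]; mb <- mc$mate_chrom[o[b]]
          if (!is.na(ma) && !is.na(mb))
            ok <- ma == mb &&
              abs(mc$mate_pos[o[a]] - mc$mate_pos[o[b]]) <= window
        }
        if (ok) unite(o[a], o[b])
        b <- b + 1L
      }
    }
  }
  root <- vapply(seq_len(n), findp, integer(1))
  members <- unname(split(seq_len(n), root))
  chrom <- as.character(seqnames(calls))
  first <- vapply(members, `[`, integer(1), 1L)
  smin <- vapply(members, function(i) min(start(calls)[i]), integer(1))
  emax <- vapply(members, function(i) max(end(calls)[i]), integer(1))
  carr <- unname(lapply(members, function(i) sort(unique(mc$sample_id[i]))))
  out <- GRanges(chrom[first], IRanges(smin, emax))
  mcols(out) <- DataFrame(sv_type = mc$sv_type[first],
    carriers = CharacterList(carr),
    occurrence = lengths(carr), n_calls = lengths(members))
  out <- out[order(chrom[first], smin, emax, mc$sv_type[first])]
  mcols(out)$cluster_id <- paste0(seqnames(out), ":", start(out), "-",
                                  end(out), ":", mcols(out)$sv_type)
  out
}

#' Build the carrier matrix
#'
#' Collapses assignments to binary person-level carrier indicators: a sample
#' either carries at least one qualifying SV for a key or it does not.
#' In `sv_gene` mode the key is (gene_id, region_class, sv_type); in `locus`
#' mode the key is a cluster from [mergeLoci()].  All manifest samples appear
#' as columns, carriers or not, so contingency tables can be formed against
#' the full stratum denominators.
#'
#' @param assignments DataFrame from [classifySV()] (`sv_gene` mode).
#' @param manifest Data.frame from [readManifest()].
#' @param unit `"sv_gene"` or `"locus"`.
#' @param clusters GRanges from [mergeLoci()], required in `locus` mode.
#' @param strict Error when an assignment sample is absent from the manifest
#'   (otherwise such samples are dropped with a warning).
#' @return A [CarrierMatrix-class]; rows are keys, columns samples, assay
#'   `carrier` is 0/1.
#' @export
buildCarrierMatrix <- function(assignments, manifest,
                               unit = c("sv_gene", "locus"),
                               clusters = NULL, strict = TRUE) {
  unit <- match.arg(unit)
  samples <- manifest$sample_id
  if (unit == "sv_gene") {
    a <- as.data.frame(assignments)
    a <- a[!is.na(a$gene_id), , drop = FALSE]
    extra <- setdiff(unique(a$sample_id), samples)
    if (length(extra)) {
      if (strict)
        stop("sample(s) in assignments but not manifest: ",
             paste(extra, collapse = ", "))
      warning("dropping ", length(extra), " sample(s) absent from manifest")
      a <- a[a$sample_id %in% samples, , drop = FALSE]
    }
    key <- paste(a$gene_id, a$region_class, a$sv_type, sep = "|")
    keys <- sort(unique(key))
    mat <- matrix(0L, nrow = length(keys), ncol = length(samples),
                  dimnames = list(keys, samples))
    mat[cbind(match(key, keys), match(a$sample_id, samples))] <- 1L
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    rd <- DataFrame(gene_id = parts[, 1L], region_class = parts[, 2L],
                    sv_type = parts[, 3L], row.names = keys)
  } else {
    if (is.null(clusters)) stop("locus mode requires clusters")
    keys <- mcols(clusters)$cluster_id
    mat <- matrix(0L, nrow = length(keys), ncol = length(samples),
                  dimnames = list(keys, samples))
    for (i in seq_along(clusters)) {
      carr <- unlist(mcols(clusters)$carriers[[i]])
      extra <- setdiff(carr, samples)
      if (length(extra) && strict)
        stop("cluster carrier absent from manifest: ", extra[1L])
      mat[i, intersect(carr, samples)] <- 1L
    }
    rd <- DataFrame(cluster_id = keys, sv_type = mcols(clusters)$sv_type,
                    chrom = as.character(seqnames(clusters)),
                    start = start(clusters), end = end(clusters),
                    row.names = keys)
  }
  cd <- DataFrame(phenotype = manifest$phenotype, stratum = manifest$stratum,
                  row.names = samples)
  CarrierMatrix(
    SummarizedExperiment(assays = list(carrier = mat),
                         rowData = rd, colData = cd))
}
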