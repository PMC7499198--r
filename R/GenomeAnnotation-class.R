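#' GenomeAnnotation: gene, exon and intron geometry for SV classification
#'
#' Holds one gene model per `gene_id`: the gene span, the exon union merged
#' across all transcripts, and the derived introns (the complement of the
#' exon union within the span).  All coordinates are 1-based closed intervals
#' on the GRanges convention; GTF/GFF3 input (also 1-based closed) is taken
#' as-is.
#'
#' Invariants enforced by the validity method:
#' * every exon lies within its gene span;
#' * per gene, exon and intron widths sum exactly to the span width
#'   (the exon union and intron set tile the span with no gaps or overlaps).
#'
#' @slot genes GRanges of gene spans with metadata columns `gene_id`,
#'   `gene_name` and (carried, unused by classification) `strand`.
#' @slot exons GRanges of the merged exon union, metadata column `gene_id`.
#' @slot introns GRanges of derived introns, metadata column `gene_id`.
#'
#' @seealso [loadAnnotation()], [locatePosition()], [nearestGene()]
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  slots = c(genes = "GRanges", exons = "GRanges", introns = "GRanges")
)

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  if (is.null(mcols(g)$gene_id)) return("genes must carry a gene_id column")
  if (anyDuplicated(mcols(g)$gene_id)) return("duplicated gene_id in genes")
  if (length(object@exons) == 0L && length(g) > 0L)
    return("no exons for a non-empty gene set")
  span <- setNames(g, mcols(g)$gene_id)
  ex <- object@exons
  idx <- match(mcols(ex)$gene_id, mcols(g)$gene_id)
  if (anyNA(idx)) return("exon with gene_id absent from genes")
  bad <- start(ex) < start(g)[idx] | end(ex) > end(g)[idx] |
    as.character(seqnames(ex)) != as.character(seqnames(g))[idx]
  if (any(bad))
    return(paste0("exon outside gene span for gene_id ",
                  mcols(ex)$gene_id[which(bad)[1L]]))
  exw <- tapply(width(ex), mcols(ex)$gene_id, sum)
  inw <- tapply(width(object@introns), mcols(object@introns)$gene_id, sum)
  tot <- exw
  tot[names(inw)] <- tot[names(inw)] + inw
  spw <- setNames(width(g), mcols(g)$gene_id)
  if (!all(tot == spw[names(tot)]))
    return("exon union and introns do not tile the gene span")
  TRUE
})

#' Construct a GenomeAnnotation from gene spans and exons
#'
#' Exons are merged (reduced) per gene across transcripts before storage;
#' introns are derived as the within-span complement of the merged exons.
#'
#' @param genes GRanges with metadata columns `gene_id` and optionally
#'   `gene_name` (defaults to `gene_id`).
#' @param exons GRanges with a metadata column `gene_id`; may contain
#'   overlapping exons from multiple transcripts.
#' @return A [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(genes, exons) {
  if (is.null(mcols(genes)$gene_name))
    mcols(genes)$gene_name <- mcols(genes)$gene_id
  o <- order(as.character(seqnames(genes)), start(genes),
             mcols(genes)$gene_id)
  genes <- genes[o]
  merged <- lapply(split(exons, mcols(exons)$gene_id), function(e) {
    r <- GenomicRanges::reduce(granges(e))
    mcols(r)$gene_id <- mcols(e)$gene_id[1L]
    r
  })
  exons <- unlist(GenomicRanges::GRangesList(merged), use.names = FALSE)
  introns <- .deriveIntrons(genes, exons)
  new("GenomeAnnotation", genes = genes, exons = exons, introns = introns)
}

.deriveIntrons <- function(genes, exons) {
  per <- lapply(seq_along(genes), function(i) {
    gid <- mcols(genes)$gene_id[i]
    ex <- exons[mcols(exons)$gene_id == gid]
    intr <- GenomicRanges::setdiff(granges(genes[i]), granges(ex))
    if (length(intr)) mcols(intr)$gene_id <- gid
    intr
  })
  unlist(GenomicRanges::GRangesList(per), use.names = FALSE)
}

#' @describeIn GenomeAnnotation gene spans as GRanges
#' @param x,object A `GenomeAnnotation`.
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GenomeAnnotation merged exon union as GRanges
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GenomeAnnotation derived introns as GRanges
#' @export
intronRanges <- function(x) x@introns

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@genes), "genes on",
      length(seqlevelsInUse(object@genes)), "sequences;",
      length(object@exons), "merged exons,",
      length(object@introns), "introns\n")
})

#' Load a GTF or GFF3 gene annotation
#'
#' Reads GENCODE/Ensembl-style annotation and builds one gene model per
#' `gene_id` with the exon union merged across all transcripts.  Both
#' dialects must provide `gene` and `exon` feature rows; exons are attached
#' to genes through the `gene_id` attribute when present, or through
#' `Parent` -> transcript -> gene resolution for GFF3.  When no `gene` rows
#' exist the span defaults to the exon hull per gene.
#'
#' @param path Path to a GTF or GFF3 file (uncompressed text).
#' @param dialect `"auto"` (from the file extension), `"gtf"` or `"gff3"`.
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "A"; gene_name "A";',
#'   'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "A"; transcript_id "A.1";',
#'   'chr1\tsrc\texon\t1801\t2000\t.\t+\t.\tgene_id "A"; transcript_id "A.1";'
#' ), gtf)
#' ann <- loadAnnotation(gtf)
#' intronRanges(ann)   # one intron, chr1:1201-1800
#' @export
loadAnnotation <- function(path, dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
               else "gtf"
  }
  .checkNineColumns(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  type <- as.character(gr$type)
  if (dialect == "gff3")
    gr <- .resolveGff3GeneIds(gr, type)
  if (is.null(mcols(gr)$gene_id))
    stop("annotation carries no gene_id attribute")
  exons <- gr[type == "exon"]
  if (length(exons) == 0L) stop("annotation contains no exon rows")
  if (anyNA(mcols(exons)$gene_id))
    stop("exon rows without resolvable gene_id")
  generows <- gr[type == "gene"]
  if (length(generows)) {
    genes <- granges(generows)
    mcols(genes)$gene_id <- mcols(generows)$gene_id
    nm <- mcols(generows)$gene_name
    if (is.null(nm)) nm <- mcols(generows)$Name
    mcols(genes)$gene_name <- if (is.null(nm)) mcols(generows)$gene_id else
      ifelse(is.na(nm), mcols(generows)$gene_id, nm)
  } else {
    # span = exon hull per gene
    hull <- lapply(split(exons, mcols(exons)$gene_id), function(e)
      range(granges(e)))
    genes <- unlist(GenomicRanges::GRangesList(hull), use.names = TRUE)
    mcols(genes)$gene_id <- names(genes)
    mcols(genes)$gene_name <- names(genes)
    names(genes) <- NULL
  }
  idx <- match(mcols(exons)$gene_id, mcols(genes)$gene_id)
  if (anyNA(idx))
    stop("exon gene_id absent from gene rows: ",
         mcols(exons)$gene_id[which(is.na(idx))[1L]])
  out <- granges(exons)
  mcols(out)$gene_id <- mcols(exons)$gene_id
  bad <- start(out) < start(genes)[idx] | end(out) > end(genes)[idx]
  if (any(bad))
    stop("exon outside gene span for gene_id ",
         mcols(out)$gene_id[which(bad)[1L]])
  GenomeAnnotation(genes, out)
}

# reject rows that do not have the 9 tab-separated GTF/GFF columns,
# reporting the first offending line number
.checkNineColumns <- function(path) {
  ln <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", ln) & nzchar(ln)
  nf <- lengths(strsplit(ln[keep], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(keep)[which(nf != 9L)[1L]]
    stop("malformed annotation row at line ", bad, " of ", path)
  }
  invisible(TRUE)
}

.resolveGff3GeneIds <- function(gr, type) {
  has <- !is.null(mcols(gr)$gene_id) && !all(is.na(mcols(gr)$gene_id))
  if (has) return(gr)
  id <- as.character(mcols(gr)$ID)
  parent <- as.character(S4Vectors::unstrsplit(mcols(gr)$Parent, ","))
  parent[parent == ""] <- NA_character_
  gene_of <- setNames(rep(NA_character_, length(gr)), id)
  gene_of[type == "gene"] <- id[type == "gene"]
  istx <- !type %in% c("gene", "exon")
  gene_of[id[istx]] <- parent[istx]            # transcript -> gene
  gid <- ifelse(type == "gene", id,
                ifelse(type == "exon", unname(gene_of[parent]), NA))
  mcols(gr)$gene_id <- gid
  gr
}

#' Classify a genomic point against the annotation
#'
#' A point is `exon` if it falls in the exon union of any gene (all such
#' genes are reported), `intron` if it falls inside at least one gene span
#' but in no exon, and `intergenic` otherwise.  When the point is exonic for
#' one gene and intronic for an overlapping second gene, the second gene is
#' reported in `intron_genes`.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param strict Error (rather than warn) on a chromosome absent from the
#'   annotation.
#' @return A list with elements `class` (`"exon"`, `"intron"` or
#'   `"intergenic"`), `genes` (character vector) and `intron_genes`.
#' @export
locatePosition <- function(annotation, chrom, pos, strict = FALSE) {
  if (!chrom %in% as.character(seqnames(annotation@genes))) {
    msg <- paste0("chromosome ", chrom, " absent from annotation")
    if (strict) stop(msg)
    warning(msg)
    return(list(class = "intergenic", genes = character(),
                intron_genes = character()))
  }
  pt <- GRanges(chrom, IRanges(pos, pos))
  exhit <- subjectHits(findOverlaps(pt, annotation@exons))
  spanhit <- subjectHits(findOverlaps(pt, annotation@genes))
  span_genes <- mcols(annotation@genes)$gene_id[spanhit]
  exon_genes <- unique(mcols(annotation@exons)$gene_id[exhit])
  if (length(exon_genes))
    return(list(class = "exon", genes = exon_genes,
                intron_genes = setdiff(span_genes, exon_genes)))
  if (length(span_genes))
    return(list(class = "intron", genes = unique(span_genes),
                intron_genes = character()))
  list(class = "intergenic", genes = character(),
       intron_genes = character())
}

#' Nearest gene to a genomic point
#'
#' Distance is 0 when the point lies inside a gene span, otherwise the number
#' of bases between the point and the closer span edge.  Ties are broken by
#' lower span start, then lexicographic `gene_id`.
#'
#' @inheritParams locatePosition
#' @return A list with `gene_id`, `gene_name` and `distance` (bp).
#' @export
nearestGene <- function(annotation, chrom, pos) {
  g <- annotation@genes
  g <- g[as.character(seqnames(g)) == chrom]
  if (length(g) == 0L)
    stop("no genes on chromosome ", chrom)
  d <- ifelse(pos < start(g), start(g) - pos,
       ifelse(pos > end(g), pos - end(g), 0L))
  o <- order(d, start(g), mcols(g)$gene_id)[1L]
  list(gene_id = mcols(g)$gene_id[o],
       gene_name = mcols(g)$gene_name[o],
       distance = as.integer(d[o]))
}
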