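#' CarrierMatrix: person-level carrier indicators for association testing
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper holding one
#' binary assay `carrier` with keys as rows (either SV-gene keys
#' `gene_id | region_class | sv_type` or recurrent-locus cluster ids) and
#' cohort samples as columns.  `colData` carries `phenotype`
#' (case/control) and `stratum`.  The validity method enforces a 0/1 assay
#' and the presence of those two columns.
#'
#' @seealso [buildCarrierMatrix()], [carrierTable()], [associateStratum()]
#' @exportClass CarrierMatrix
setClass("CarrierMatrix", contains = "SummarizedExperiment")

setValidity("CarrierMatrix", function(object) {
  if (!"carrier" %in% SummarizedExperiment::assayNames(object))
    return("assay 'carrier' missing")
  a <- assay(object, "carrier")
  if (!all(a %in% c(0L, 1L))) return("carrier assay must be binary 0/1")
  if (!all(c("phenotype", "stratum") %in% colnames(colData(object))))
    return("colData must have phenotype and stratum")
  if (!all(colData(object)$phenotype %in% c("case", "control")))
    return("phenotype must be case/control")
  TRUE
})

#' @describeIn CarrierMatrix wrap a SummarizedExperiment as a CarrierMatrix
#' @param se A SummarizedExperiment with a binary `carrier` assay and
#'   `phenotype`/`stratum` columns in its colData.
#' @export
CarrierMatrix <- function(se) new("CarrierMatrix", se)

setMethod("show", "CarrierMatrix", function(object) {
  cd <- colData(object)
  cat("CarrierMatrix:", nrow(object), "keys x", ncol(object), "samples\n")
  for (s in unique(cd$stratum))
    cat("  stratum ", s, ": ",
        sum(cd$stratum == s & cd$phenotype == "case"), " cases / ",
        sum(cd$stratum == s & cd$phenotype == "control"), " controls\n",
        sep = "")
})

#' 2x2 carrier contingency table for one key in one stratum
#'
#' Cells follow the carrier layout: `a` case carriers, `b` case
#' non-carriers, `c` control carriers, `d` control non-carriers, so that
#' `a + b` and `c + d` equal the stratum case and control totals.
#'
#' @param cm A [CarrierMatrix-class].
#' @param key Row name (or index) of the key.
#' @param stratum Stratum label present in `colData(cm)$stratum`.
#' @return The 2x2 integer matrix from [contingencyTable()].
#' @export
carrierTable <- function(cm, key, stratum) {
  cd <- colData(cm)
  sel <- cd$stratum == stratum
  if (!any(sel)) stop("empty stratum: ", stratum)
  if (is.character(key) && !key %in% rownames(cm))
    stop("unknown key: ", key)
  x <- assay(cm, "carrier")[key, sel]
  pheno <- cd$phenotype[sel]
  contingencyTable(
    a = sum(x == 1L & pheno == "case"),
    b = sum(x == 0L & pheno == "case"),
    c = sum(x == 1L & pheno == "control"),
    d = sum(x == 0L & pheno == "control"))
}

#' Build a 2x2 carrier table from the four cell counts
#'
#' @param a,b,c,d Case carriers, case non-carriers, control carriers,
#'   control non-carriers.
#' @return A 2x2 integer matrix with dimnames
#'   `(case, control) x (carrier, noncarrier)`.
#' @export
contingencyTable <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  matrix(as.integer(cells), nrow = 2L, byrow = TRUE,
         dimnames = list(c("case", "control"), c("carrier", "noncarrier")))
}
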