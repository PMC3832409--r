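#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

# Calls accepted in a genotype panel.  Diploid loci use two-letter calls;
# haploid / hemizygous loci (mtDNA, Y, male X) use single-letter calls.
.DIPLOID_CALLS <- c("AA", "AB", "BB")
.HAPLOID_CALLS <- c("A", "B")
.MISSING_CALL  <- "--"
.ALL_CALLS     <- c(.DIPLOID_CALLS, .HAPLOID_CALLS, .MISSING_CALL)
.LOCUS_CLASSES <- c("autosomal", "X", "mtDNA", "Y")

#' Restriction-enzyme recognition site
#'
#' A recognition pattern together with the cut position within it.  The
#' enzyme cuts between \code{cutOffset} and \code{cutOffset + 1} bases into
#' the pattern (5' to 3'), so \code{cutOffset = 1} for BglII (A^GATCT).
#'
#' @slot pattern Recognition sequence, A/C/G/T only.
#' @slot cutOffset Integer in \code{0..nchar(pattern)}: number of pattern
#'   bases 5' of the cut.
#'
#' @examples
#' recognitionSite("AGATCT", 1L)
#' @export
setClass("RecognitionSite",
  representation(pattern = "character", cutOffset = "integer"))

setValidity("RecognitionSite", function(object) {
  msg <- character()
  if (length(object@pattern) != 1L || is.na(object@pattern) ||
      nchar(object@pattern) == 0L)
    msg <- c(msg, "'pattern' must be a single non-empty string")
  else if (grepl("[^ACGT]", object@pattern))
    msg <- c(msg, "'pattern' may contain only A, C, G, T")
  if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
      object@cutOffset < 0L ||
      (length(object@pattern) == 1L && !is.na(object@pattern) &&
       object@cutOffset > nchar(object@pattern)))
    msg <- c(msg, "'cutOffset' must lie in 0..nchar(pattern)")
  if (length(msg)) msg else TRUE
})

#' @param pattern Recognition sequence (case-insensitive; stored uppercase).
#' @param cutOffset Cut position within the pattern (bases 5' of the cut).
#' @rdname RecognitionSite-class
#' @export
recognitionSite <- function(pattern, cutOffset) {
  new("RecognitionSite", pattern = toupper(as.character(pattern)),
      cutOffset = as.integer(cutOffset))
}

#' @describeIn RecognitionSite-class The BglII site, A^GATCT.
#' @export
bglII <- function() recognitionSite("AGATCT", 1L)

setMethod("show", "RecognitionSite", function(object) {
  p <- object@pattern
  k <- object@cutOffset
  cat("RecognitionSite: ", substr(p, 1, k), "^", substr(p, k + 1, nchar(p)),
      "\n", sep = "")
})

#' Genotype panel: individuals x loci with marker-class metadata
#'
#' A \linkS4class{SummarizedExperiment} with loci as rows and individuals as
#' columns.  The single \code{"calls"} assay holds character genotype calls:
#' \code{AA}/\code{AB}/\code{BB} for diploid loci, \code{A}/\code{B} for
#' haploid or hemizygous calls (mtDNA, Y, male X), and \code{--} for
#' missing.  \code{rowData} carries the locus \code{class} (one of
#' \code{autosomal}, \code{X}, \code{mtDNA}, \code{Y}); \code{colData}
#' carries individual \code{sex} (\code{M}, \code{F} or \code{unknown}) and
#' optional \code{group}.
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  calls <- assay(object, "calls")
  if (!is.character(calls))
    return("assay 'calls' must be a character matrix")
  bad <- !(calls %in% .ALL_CALLS)
  if (any(bad))
    msg <- c(msg, sprintf("invalid call(s): %s",
                          paste(unique(calls[bad]), collapse = ", ")))
  rd <- rowData(object)
  if (!"class" %in% colnames(rd))
    msg <- c(msg, "rowData must have a 'class' column")
  else {
    if (!all(rd$class %in% .LOCUS_CLASSES))
      msg <- c(msg, "locus class must be autosomal, X, mtDNA or Y")
    hap <- rd$class %in% c("mtDNA", "Y")
    if (any(hap) && any(calls[hap, , drop = FALSE] == "AB"))
      msg <- c(msg, "haploid loci (mtDNA, Y) cannot carry AB calls")
  }
  cd <- colData(object)
  if (!"sex" %in% colnames(cd))
    msg <- c(msg, "colData must have a 'sex' column")
  else if (!all(cd$sex %in% c("M", "F", "unknown")))
    msg <- c(msg, "sex must be M, F or unknown")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param calls Character matrix of genotype calls, loci in rows and
#'   individuals in columns (dimnames required).
#' @param locusClass Character vector of locus classes, one per row of
#'   \code{calls}: \code{autosomal}, \code{X}, \code{mtDNA} or \code{Y}.
#' @param sex Character vector of individual sexes (\code{M}, \code{F},
#'   \code{unknown}), one per column.
#' @param group Optional grouping label per individual (e.g. subpopulation).
#'
#' @return A \linkS4class{GenotypePanel}.
#' @examples
#' calls <- matrix(c("AA", "AB", "BB", "AB"), nrow = 2,
#'                 dimnames = list(c("L1", "L2"), c("i1", "i2")))
#' genotypePanel(calls, locusClass = c("autosomal", "autosomal"),
#'               sex = c("M", "F"))
#' @export
genotypePanel <- function(calls, locusClass, sex,
                          group = rep(NA_character_, ncol(calls))) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            !is.null(colnames(calls)))
  se <- SummarizedExperiment(
    assays = list(calls = calls),
    rowData = DataFrame(class = as.character(locusClass),
                        row.names = rownames(calls)),
    colData = DataFrame(sex = as.character(sex),
                        group = as.character(group),
                        row.names = colnames(calls)))
  new("GenotypePanel", se)
}

#' @describeIn GenotypePanel-class Locus ids.
#' @param x,object A \code{GenotypePanel}.
#' @export
lociIds <- function(x) rownames(x)

#' @describeIn GenotypePanel-class Individual ids.
#' @export
individualIds <- function(x) colnames(x)

#' @describeIn GenotypePanel-class Locus classes (named character vector).
#' @export
locusClass <- function(x) stats::setNames(rowData(x)$class, rownames(x))

#' @describeIn GenotypePanel-class Individual sexes (named character vector).
#' @export
individualSex <- function(x) stats::setNames(colData(x)$sex, colnames(x))

#' @describeIn GenotypePanel-class The genotype call matrix (loci x
#'   individuals).
#' @export
genotypeCalls <- function(x) assay(x, "calls")

setMethod("show", "GenotypePanel", function(object) {
  cls <- table(factor(rowData(object)$class, levels = .LOCUS_CLASSES))
  cat("GenotypePanel: ", nrow(object), " loci x ", ncol(object),
      " individuals\n", sep = "")
  cat("  loci: ", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n", sep = "")
  sx <- table(factor(colData(object)$sex, levels = c("M", "F", "unknown")))
  cat("  individuals: ", paste(sprintf("%s=%d", names(sx), sx),
      collapse = ", "), "\n", sep = "")
  miss <- mean(assay(object, "calls") == .MISSING_CALL)
  cat("  missing calls: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
})
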