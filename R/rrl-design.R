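#' @importFrom Biostrings DNAString DNAStringSet matchPattern readDNAStringSet
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
NULL

.cutPositions <- function(seq, site) {
  # 0-based positions immediately after which the enzyme cuts.
  # fixed = TRUE: ambiguity codes (incl. N) in the subject never match,
  # which is the conservative behaviour for draft assemblies.
  m <- matchPattern(site@pattern, seq, fixed = TRUE)
  IRanges::start(m) - 1L + site@cutOffset
}

#' In-silico digestion of a single sequence
#'
#' Cuts \code{seq} at every exact occurrence of the recognition pattern, at
#' \code{occurrence_start + cutOffset}.  Matching is exact and
#' case-insensitive; windows containing non-ACGT characters (e.g. N) are
#' never cut sites.  Terminal fragments are included, so fragment lengths
#' always sum to the sequence length.
#'
#' @param seq A single sequence: character string or
#'   \link[Biostrings]{DNAString}.
#' @param site A \linkS4class{RecognitionSite}.
#' @param scaffoldId Sequence name used in the returned ranges.
#'
#' @return A \link[GenomicRanges]{GRanges} of fragments tiling the sequence
#'   (1-based, inclusive ends, the Bioconductor convention).
#' @examples
#' digestSequence("GGGAGATCTGGG", bglII())
#' @export
digestSequence <- function(seq, site, scaffoldId = "seq1") {
  stopifnot(is(site, "RecognitionSite"))
  validObject(site)
  if (is.character(seq)) seq <- DNAString(toupper(seq))
  n <- length(seq)
  if (n == 0L)
    return(GRanges())
  cuts <- .cutPositions(seq, site)
  cuts <- cuts[cuts > 0L & cuts < n]     # cuts at the ends make no fragment
  bounds <- c(0L, sort(unique(cuts)), n) # 0-based half-open boundaries
  GRanges(scaffoldId,
          IRanges(start = bounds[-length(bounds)] + 1L, end = bounds[-1L]))
}

#' In-silico digestion of a multi-sequence genome
#'
#' Digests every scaffold of a genome and summarizes the digest: total
#' genome size G (bases), fragment count and mean fragment length G / count.
#'
#' @param x A \link[Biostrings]{DNAStringSet}, or the path to a FASTA file
#'   (gzip transparent).
#' @param site A \linkS4class{RecognitionSite}.
#'
#' @return A list with elements \code{fragments} (GRanges over all
#'   scaffolds), \code{G}, \code{count} and \code{meanLength}.
#' @export
digestGenome <- function(x, site) {
  if (is.character(x)) x <- readFasta(x)
  stopifnot(is(x, "DNAStringSet"))
  if (length(x) == 0L)
    stop("genome contains no sequences")
  if (is.null(names(x)))
    names(x) <- paste0("scaffold", seq_along(x))
  perScaf <- lapply(seq_along(x), function(i)
    digestSequence(x[[i]], site, scaffoldId = names(x)[i]))
  frags <- GRanges(
    seqnames = rep(names(x), lengths(perScaf)),
    ranges = do.call(c, lapply(perScaf, GenomicRanges::ranges)))
  G <- sum(as.numeric(Biostrings::width(x)))
  list(fragments = frags, G = G, count = length(frags),
       meanLength = G / length(frags))
}

#' Size-select fragments
#'
#' Keeps fragments with length in \code{[minLen, maxLen]} (inclusive bounds;
#' order preserved).
#'
#' @param fragments GRanges of fragments (from \code{\link{digestSequence}}
#'   or \code{\link{digestGenome}}).
#' @param minLen,maxLen Window bounds in bp, \code{minLen < maxLen}.
#' @return The selected GRanges subset.
#' @export
sizeSelect <- function(fragments, minLen = 100, maxLen = 700) {
  stopifnot(minLen < maxLen)
  w <- GenomicRanges::width(fragments)
  fragments[w >= minLen & w <= maxLen]
}

#' Expected size-selected fragment count under an exponential model
#'
#' For a genome of size \code{G} digested into fragments whose lengths
#' follow an exponential distribution with mean \code{d}, the expected
#' number of fragments with length in \code{[a, b]} is
#' \deqn{(G/d)\,(e^{-a/d} - e^{-b/d}).}
#' At d = 3100, G = 2.4e9, a = 100, b = 700 this gives 131,910 fragments.
#'
#' @param d Mean fragment length (bp).
#' @param G Genome size (bp).
#' @param a,b Size-selection window bounds (bp), \code{a <= b}.
#' @return Expected fragment count (not rounded).
#' @examples
#' expectedFragmentCount(3100, 2.4e9, 100, 700)
#' @export
expectedFragmentCount <- function(d, G, a, b) {
  stopifnot(d > 0, G > 0, a <= b, a >= 0)
  (G / d) * (exp(-a / d) - exp(-b / d))
}

#' RRL design summary: coverage and per-individual read depth
#'
#' Given \code{D} size-selected fragments sequenced as paired-end reads of
#' \code{readLen} bases from each end, the maximum genomic coverage is
#' \code{D * 2 * readLen / G * 100} percent (reported to 2 decimals) and
#' the expected read depth per individual is
#' \code{yieldPerIndividual / (D * 2 * readLen)} (reported to the nearest
#' integer).  The default yield of 1 Gbp per individual corresponds to one
#' 2x100 bp HiSeq lane split across ten samples.
#'
#' @param D Count of size-selected fragments.
#' @param G Genome size (bp).
#' @param readLen Read length (bp).
#' @param yieldPerIndividual Sequenced bases per individual (bp).
#' @return A list with \code{D}, \code{depth} and \code{coveragePct}.
#' @examples
#' designSummary(131910, 2.4e9)            # coverage 1.10%, depth 38
#' designSummary(93678, 2277069268)        # coverage 0.82%, depth 53
#' @export
designSummary <- function(D, G, readLen = 100, yieldPerIndividual = 1e9) {
  stopifnot(G > 0, readLen > 0, yieldPerIndividual > 0)
  if (D <= 0)
    stop("degenerate design: no size-selected fragments (D = 0)")
  basesTargeted <- D * 2 * readLen
  list(D = D,
       depth = round(yieldPerIndividual / basesTargeted),
       coveragePct = round(basesTargeted / G * 100, 2))
}

#' Percent difference between an estimate and the realized value
#'
#' \code{(estimated - actual) / estimated * 100}, one decimal.  Negative
#' values indicate underestimates.
#'
#' @param estimated,actual Numeric values; \code{estimated} must be nonzero.
#' @return Signed percent difference, rounded to 1 decimal.
#' @examples
#' percentDiff(2.4e9, 2277069268)  # 5.1
#' @export
percentDiff <- function(estimated, actual) {
  if (any(estimated == 0))
    stop("'estimated' must be nonzero")
  round((estimated - actual) / estimated * 100, 1)
}
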