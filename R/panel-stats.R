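#' @importFrom stats setNames
NULL

.alleleCounts <- function(calls) {
  # pooled A/B allele counts: diploid calls contribute 2, haploid 1
  nA <- sum(calls == "AA") * 2 + sum(calls == "AB") + sum(calls == "A")
  nB <- sum(calls == "BB") * 2 + sum(calls == "AB") + sum(calls == "B")
  c(A = nA, B = nB)
}

#' Per-locus descriptive statistics
#'
#' Allele frequencies pool diploid (2 alleles per call) and haploid
#' (1 allele per call) contributions; observed heterozygosity is computed
#' over diploid calls only; expected heterozygosity is 2p(1-p); the exact
#' Hardy-Weinberg p-value uses the diploid genotype counts.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param locus A locus id (rowname of \code{panel}).
#' @return A one-row data.frame: \code{locus}, \code{class}, \code{p}
#'   (frequency of A), \code{maf}, \code{Ho}, \code{He}, \code{hweP},
#'   \code{nCalled}.
#' @examples
#' pnl <- genotypePanel(
#'   matrix(c("AA", "AB", "BB"), 1, 3,
#'          dimnames = list("L1", c("i1", "i2", "i3"))),
#'   locusClass = "autosomal", sex = c("M", "F", "F"))
#' locusStats(pnl, "L1")   # p = 0.5, Ho = 1/3, He = 0.5
#' @export
locusStats <- function(panel, locus) {
  calls <- genotypeCalls(panel)[locus, ]
  calls <- calls[calls != .MISSING_CALL]
  if (length(calls) == 0L)
    stop("locus ", locus, " has no non-missing calls")
  ac <- .alleleCounts(calls)
  p <- ac["A"] / sum(ac)
  dip <- calls[calls %in% .DIPLOID_CALLS]
  Ho <- if (length(dip)) mean(dip == "AB") else NA_real_
  He <- 2 * p * (1 - p)
  hweP <- if (length(dip))
    hweExact(sum(dip == "AA"), sum(dip == "AB"), sum(dip == "BB"))
  else NA_real_
  data.frame(locus = locus,
             class = unname(locusClass(panel)[locus]),
             p = unname(p), maf = unname(min(p, 1 - p)),
             Ho = Ho, He = unname(He), hweP = hweP,
             nCalled = length(calls), row.names = NULL)
}

#' Descriptive statistics for every locus of a panel
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param group Optional: restrict to individuals whose \code{group}
#'   equals this value (e.g. one subpopulation for stratified HWE).
#' @return data.frame, one row per locus, as \code{\link{locusStats}}.
#' @export
panelStats <- function(panel, group = NULL) {
  if (!is.null(group))
    panel <- panel[, colData(panel)$group %in% group]
  do.call(rbind, lapply(lociIds(panel), function(l) locusStats(panel, l)))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional-on-allele-counts exact test for a biallelic locus: the
#' p-value is the summed probability of all heterozygote counts (with the
#' observed allele counts) whose conditional probability does not exceed
#' that of the observed configuration.  Probabilities follow the standard
#' recurrence over heterozygote counts of matching parity.
#'
#' @param nAA,nAB,nBB Genotype counts.
#' @return Exact p-value in (0, 1].
#' @examples
#' hweExact(5, 1, 5)     # heterozygote deficit
#' hweExact(10, 0, 0)    # monomorphic: p = 1
#' @export
hweExact <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("genotype counts must be >= 0")
  n <- nAA + nAB + nBB
  if (n == 0L) stop("need at least one genotype")
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  nMin <- min(nA, nB)
  if (nMin == 0) return(1)      # monomorphic: single configuration
  hetVals <- seq(nMin %% 2, nMin, by = 2)
  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = 4 * nAA(h) * nBB(h) / ((h+2)(h+1))
  lp <- numeric(length(hetVals))
  for (i in seq_along(hetVals)[-1]) {
    h <- hetVals[i - 1]
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lp[i] <- lp[i - 1] + log(4 * aa * bb) - log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAB, hetVals)]
  if (is.na(obs)) stop("nAB inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Pairwise D' by EM haplotype-frequency estimation
#'
#' Estimates two-locus haplotype frequencies from unphased diploid calls by
#' EM (double heterozygotes are the only ambiguous class), starting from
#' linkage-equilibrium frequencies, then normalizes the disequilibrium
#' coefficient: D = p_AB - p_A p_B and D' = |D| / Dmax, where Dmax is
#' min(p_A(1-p_B), (1-p_A)p_B) for D > 0 and min(p_A p_B, (1-p_A)(1-p_B))
#' for D < 0.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param locusA,locusB Locus ids (diploid loci).
#' @param tol,maxIter EM convergence controls: stop when the largest
#'   absolute haplotype-frequency change is below \code{tol} or after
#'   \code{maxIter} iterations.
#' @return A list with \code{dPrime}, \code{D}, \code{pA}, \code{pB},
#'   \code{hapFreqs} (AB, Ab, aB, ab) and \code{nUsed}.
#' @export
ldDprime <- function(panel, locusA, locusB, tol = 1e-9, maxIter = 1000L) {
  calls <- genotypeCalls(panel)
  gA <- calls[locusA, ]
  gB <- calls[locusB, ]
  use <- gA %in% .DIPLOID_CALLS & gB %in% .DIPLOID_CALLS
  if (sum(use) < 2L)
    stop("need >= 2 individuals with diploid calls at both loci")
  dose <- c(AA = 2L, AB = 1L, BB = 0L)        # copies of allele A
  xa <- dose[gA[use]]
  xb <- dose[gB[use]]
  n <- length(xa)
  pA <- mean(xa) / 2
  pB <- mean(xb) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("D' undefined: monomorphic locus")
  # haplotype freqs h = (AB, Ab, aB, ab); EM over double heterozygotes
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  nDH <- sum(xa == 1L & xb == 1L)
  # haplotype counts resolvable without phase information; double
  # heterozygotes (nDH of them) contribute via the E step only
  tabs <- table(factor(xa, levels = 0:2), factor(xb, levels = 0:2))
  f <- function(i, j) tabs[as.character(i), as.character(j)]
  baseAB <- 2 * f(2, 2) + f(2, 1) + f(1, 2)
  baseAb <- 2 * f(2, 0) + f(2, 1) + f(1, 0)
  baseaB <- 2 * f(0, 2) + f(0, 1) + f(1, 2)
  baseab <- 2 * f(0, 0) + f(0, 1) + f(1, 0)
  for (it in seq_len(maxIter)) {
    # E step: split double heterozygotes between AB/ab and Ab/aB phases
    wCis <- h[1] * h[4]
    wTrans <- h[2] * h[3]
    pCis <- if (wCis + wTrans > 0) wCis / (wCis + wTrans) else 0.5
    cAB <- baseAB + nDH * pCis
    cab <- baseab + nDH * pCis
    cAb <- baseAb + nDH * (1 - pCis)
    caB <- baseaB + nDH * (1 - pCis)
    hNew <- c(cAB, cAb, caB, cab) / (2 * n)
    delta <- max(abs(hNew - h))
    h <- hNew
    if (delta < tol) break
  }
  D <- h[1] - pA * pB
  dMax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dPrime <- if (dMax == 0) 0 else abs(D) / dMax
  list(dPrime = unname(dPrime), D = unname(D), pA = unname(pA),
       pB = unname(pB),
       hapFreqs = setNames(h, c("AB", "Ab", "aB", "ab")), nUsed = n)
}

#' Flag locus pairs in strong linkage disequilibrium
#'
#' Evaluates D' for every unordered pair of polymorphic diploid loci and
#' returns the pairs at or above the threshold, sorted by D' descending.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param loci Locus ids to consider (default: all autosomal).
#' @param threshold D' threshold (default 0.9).
#' @return data.frame with \code{locusA}, \code{locusB}, \code{dPrime}.
#' @export
flagLinkedPairs <- function(panel, loci = NULL, threshold = 0.9) {
  if (is.null(loci))
    loci <- lociIds(panel)[locusClass(panel) == "autosomal"]
  # drop monomorphic / unusable loci up front
  ok <- vapply(loci, function(l) {
    s <- try(locusStats(panel, l), silent = TRUE)
    !inherits(s, "try-error") && s$maf > 0
  }, logical(1))
  loci <- loci[ok]
  if (length(loci) < 2L)
    return(data.frame(locusA = character(), locusB = character(),
                      dPrime = numeric()))
  pairs <- utils::combn(loci, 2)
  dp <- apply(pairs, 2, function(pr)
    ldDprime(panel, pr[1], pr[2])$dPrime)
  out <- data.frame(locusA = pairs[1, ], locusB = pairs[2, ], dPrime = dp)
  out <- out[out$dPrime >= threshold, , drop = FALSE]
  out[order(-out$dPrime), , drop = FALSE]
}

#' Probability that all males are homozygous at an autosomal locus
#'
#' The Type-I-error probability attached to an X-linkage call: under
#' Hardy-Weinberg proportions at an autosomal locus with minor allele
#' frequency \code{maf}, each male is homozygous with probability
#' maf^2 + (1-maf)^2, so all \code{nMales} males are homozygous by chance
#' with probability (maf^2 + (1-maf)^2)^nMales.  With 36 males and
#' maf = 0.31 this is 1.87e-9, i.e. one in 535 million.
#'
#' @param nMales Number of called males.
#' @param maf Minor allele frequency in [0, 0.5].
#' @return The probability.
#' @examples
#' xTypeIError(36, 0.31)
#' @export
xTypeIError <- function(nMales, maf) {
  stopifnot(nMales >= 0, maf >= 0, maf <= 0.5)
  (maf^2 + (1 - maf)^2)^nMales
}

#' Detect X-linked loci from sexed genotypes
#'
#' Flags polymorphic loci at which every called male is homozygous (or
#' hemizygous) for one and the same allele while at least one female is
#' heterozygous — the genotype signature of an X locus scored on a diploid
#' chip.  Each flagged locus carries the probability of that signature
#' arising at an autosomal locus by chance
#' (\code{\link{xTypeIError}}(number of called males, locus MAF)).
#'
#' @param panel A \linkS4class{GenotypePanel} with sexes annotated.
#' @param loci Locus ids to scan (default: all autosomal + X rows).
#' @return data.frame with \code{locus}, \code{nMales}, \code{maf},
#'   \code{typeIError} for each flagged locus.
#' @export
detectXLinked <- function(panel, loci = NULL) {
  sex <- individualSex(panel)
  if (!any(sex == "M") || !any(sex == "F"))
    stop("need at least one male and one female with annotated sex")
  if (is.null(loci))
    loci <- lociIds(panel)[locusClass(panel) %in% c("autosomal", "X")]
  calls <- genotypeCalls(panel)
  res <- lapply(loci, function(l) {
    m <- calls[l, sex == "M"]
    f <- calls[l, sex == "F"]
    m <- m[m != .MISSING_CALL]
    f <- f[f != .MISSING_CALL]
    if (length(m) == 0L || length(f) == 0L) return(NULL)
    homA <- all(m %in% c("AA", "A"))
    homB <- all(m %in% c("BB", "B"))
    if (!(homA || homB)) return(NULL)
    if (!any(f == "AB")) return(NULL)
    st <- locusStats(panel, l)
    if (st$maf == 0) return(NULL)
    data.frame(locus = l, nMales = length(m), maf = st$maf,
               typeIError = xTypeIError(length(m), st$maf))
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    data.frame(locus = character(), nMales = integer(), maf = numeric(),
               typeIError = numeric())
  else res
}

#' Assign a mitochondrial haplotype from four marker calls
#'
#' The four mtDNA markers (Ua03mt, Ua04mt, Ua05mt, Ua07mt) jointly code
#' three haplotypes: ABAA = NorthA, AAAA = NorthB, BBBB = South; any other
#' combination (including missing calls) is \code{unknown}.
#'
#' @param calls Character vector of 4 haploid calls (\code{A}, \code{B} or
#'   \code{--}), in marker order Ua03mt, Ua04mt, Ua05mt, Ua07mt.
#' @return One of \code{"NorthA"}, \code{"NorthB"}, \code{"South"},
#'   \code{"unknown"}.
#' @examples
#' assignMtHaplotype(c("A", "B", "A", "A"))  # NorthA
#' @export
assignMtHaplotype <- function(calls) {
  if (length(calls) != 4L)
    stop("expected 4 mtDNA marker calls")
  if (any(calls %in% .DIPLOID_CALLS))
    stop("diploid call at an mtDNA marker")
  key <- paste(calls, collapse = "")
  switch(key, ABAA = "NorthA", AAAA = "NorthB", BBBB = "South", "unknown")
}

#' Determine sex from two monomorphic Y-chromosome markers
#'
#' Y markers are presence/absence assays: both present is male, both
#' absent female, a discordant pair inconclusive.
#'
#' @param yCalls Character vector of 2 Y-marker calls; any non-missing
#'   call counts as presence, \code{--} as absence.
#' @return \code{"M"}, \code{"F"} or \code{"inconclusive"}.
#' @export
determineSex <- function(yCalls) {
  if (length(yCalls) != 2L)
    stop("expected 2 Y-marker calls")
  present <- yCalls != .MISSING_CALL
  if (all(present)) "M" else if (!any(present)) "F" else "inconclusive"
}

#' Select a marker panel by minor allele frequency
#'
#' Reserved markers (e.g. the mtDNA and Y markers) are included
#' unconditionally; the remaining slots are filled with the candidates of
#' highest MAF, ties broken by expected heterozygosity descending, then
#' locus id ascending, so the selection is deterministic and invariant to
#' input order.
#'
#' @param stats data.frame of candidate locus statistics (from
#'   \code{\link{panelStats}}): needs \code{locus}, \code{maf}, \code{He}.
#' @param targetSize Panel size (default 96).
#' @param reserved Locus ids included unconditionally.
#' @return Character vector of selected locus ids, reserved first.
#' @export
selectPanel <- function(stats, targetSize = 96L, reserved = character()) {
  if (!all(reserved %in% stats$locus))
    stop("reserved markers absent from candidates: ",
         paste(setdiff(reserved, stats$locus), collapse = ", "))
  if (targetSize < length(reserved))
    stop("target size smaller than the reserved set")
  pool <- stats[!(stats$locus %in% reserved), , drop = FALSE]
  nFill <- targetSize - length(reserved)
  if (nrow(pool) < nFill)
    stop("insufficient candidates: need ", nFill, " more, have ",
         nrow(pool))
  pool <- pool[order(-pool$maf, -pool$He, pool$locus), , drop = FALSE]
  c(reserved, pool$locus[seq_len(nFill)])
}
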