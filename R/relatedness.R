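#' Population allele frequencies from a genotype panel
#'
#' Frequency of allele A per locus, pooling diploid and haploid calls.
#' By default computed over the full sample (including any dyad later
#' evaluated with them); pass \code{exclude} for leave-out frequencies.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param loci Locus ids (default: all autosomal).
#' @param exclude Individual ids to leave out.
#' @return Named numeric vector: frequency of allele A per locus.
#' @export
alleleFreqs <- function(panel, loci = NULL, exclude = character()) {
  if (is.null(loci))
    loci <- lociIds(panel)[locusClass(panel) == "autosomal"]
  calls <- genotypeCalls(panel)[loci, !(colnames(panel) %in% exclude),
                                drop = FALSE]
  vapply(loci, function(l) {
    cl <- calls[l, ]
    cl <- cl[cl != .MISSING_CALL]
    ac <- .alleleCounts(cl)
    if (sum(ac) == 0) NA_real_ else unname(ac["A"] / sum(ac))
  }, numeric(1))
}

# genotype string -> two allele indicators (1 = allele A)
.gtAlleles <- function(g) {
  switch(g,
         AA = c(1L, 1L), AB = c(1L, 0L), BB = c(0L, 0L),
         stop("not a diploid call: ", g))
}

#' Lynch-Ritland locus components
#'
#' For reference individual x carrying alleles (a, b) and proband y
#' carrying (c, d), with population frequencies p of each allele, the
#' locus contributes
#' \deqn{N_l = p_a (S_{bc} + S_{bd}) + p_b (S_{ac} + S_{ad}) - 4 p_a p_b}
#' \deqn{D_l = (1 + S_{ab}) (p_a + p_b) - 4 p_a p_b}
#' where the S indicators are 1 when the subscripted alleles are identical
#' in state.  Components are combined across loci as a ratio of sums,
#' which also removes the p = 0.5 heterozygous-reference singularity.
#'
#' @param xCall,yCall Diploid calls (\code{AA}, \code{AB}, \code{BB});
#'   x is the reference individual.
#' @param pA Population frequency of allele A at the locus, in (0, 1).
#' @return c(N = numerator, D = denominator).
#' @examples
#' lrLocusComponents("AB", "AA", 0.6)  # N = -0.16, D = 0.04
#' @export
lrLocusComponents <- function(xCall, yCall, pA) {
  stopifnot(pA > 0, pA < 1)
  x <- .gtAlleles(xCall)
  y <- .gtAlleles(yCall)
  pa <- if (x[1] == 1L) pA else 1 - pA
  pb <- if (x[2] == 1L) pA else 1 - pA
  Sab <- as.integer(x[1] == x[2])
  Sac <- as.integer(x[1] == y[1]); Sad <- as.integer(x[1] == y[2])
  Sbc <- as.integer(x[2] == y[1]); Sbd <- as.integer(x[2] == y[2])
  c(N = pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb,
    D = (1 + Sab) * (pa + pb) - 4 * pa * pb)
}

# vectorized over loci: returns list(N=..., D=...) for x as reference
.lrComponentsVec <- function(xCalls, yCalls, pA) {
  doseX <- c(AA = 2L, AB = 1L, BB = 0L)[xCalls]
  doseY <- c(AA = 2L, AB = 1L, BB = 0L)[yCalls]
  # reference alleles a, b as A-indicators
  a1 <- as.integer(doseX >= 1L)       # first allele: A if any A copy
  a2 <- as.integer(doseX == 2L)       # second allele: A only if AA
  c1 <- as.integer(doseY >= 1L)
  c2 <- as.integer(doseY == 2L)
  pa <- ifelse(a1 == 1L, pA, 1 - pA)
  pb <- ifelse(a2 == 1L, pA, 1 - pA)
  Sab <- as.integer(a1 == a2)
  Sac <- as.integer(a1 == c1); Sad <- as.integer(a1 == c2)
  Sbc <- as.integer(a2 == c1); Sbd <- as.integer(a2 == c2)
  list(N = pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb,
       D = (1 + Sab) * (pa + pb) - 4 * pa * pb)
}

.usableLoci <- function(xCalls, yCalls, freqs) {
  ok <- xCalls %in% .DIPLOID_CALLS & yCalls %in% .DIPLOID_CALLS &
    !is.na(freqs) & freqs > 0 & freqs < 1
  which(ok)
}

#' Lynch-Ritland pairwise relatedness
#'
#' Method-of-moments estimator combining allele-sharing indicators with
#' population allele frequencies (see \code{\link{lrLocusComponents}}).
#' The multilocus estimate in each direction is the ratio of summed
#' numerators to summed denominators over usable loci (both calls present,
#' locus polymorphic); the reported r is the average of the two directions,
#' so r(x, y) = r(y, x) exactly.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param ind1,ind2 Individual ids.
#' @param freqs Named vector of allele-A frequencies (from
#'   \code{\link{alleleFreqs}}); its names define the candidate loci.
#' @return The symmetrized relatedness estimate.
#' @export
lynchRitlandR <- function(panel, ind1, ind2, freqs) {
  calls <- genotypeCalls(panel)
  loci <- names(freqs)
  x <- calls[loci, ind1]
  y <- calls[loci, ind2]
  use <- .usableLoci(x, y, freqs)
  if (length(use) == 0L)
    stop("no usable loci for dyad ", ind1, " - ", ind2)
  fw <- .lrComponentsVec(x[use], y[use], freqs[use])
  bw <- .lrComponentsVec(y[use], x[use], freqs[use])
  sumDf <- sum(fw$D)
  sumDb <- sum(bw$D)
  if (sumDf == 0 && sumDb == 0)
    stop("relatedness undefined: zero denominator in both directions")
  (sum(fw$N) / sumDf + sum(bw$N) / sumDb) / 2
}

#' Percentile bootstrap confidence interval for relatedness
#'
#' Resamples loci with replacement, recomputes the symmetrized
#' Lynch-Ritland estimate per replicate and returns the 2.5 and 97.5
#' percentiles.  Deterministic under a fixed seed.
#'
#' @inheritParams lynchRitlandR
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @return c(ciLow, ciHigh).
#' @export
bootstrapCI <- function(panel, ind1, ind2, freqs, reps = 1000L,
                        seed = 1L) {
  calls <- genotypeCalls(panel)
  loci <- names(freqs)
  x <- calls[loci, ind1]
  y <- calls[loci, ind2]
  use <- .usableLoci(x, y, freqs)
  if (length(use) < 2L)
    stop("need >= 2 usable loci for a bootstrap interval")
  fw <- .lrComponentsVec(x[use], y[use], freqs[use])
  bw <- .lrComponentsVec(y[use], x[use], freqs[use])
  L <- length(use)
  idx <- .withSeed(seed,
    matrix(sample.int(L, reps * L, replace = TRUE), nrow = reps))
  rStar <- vapply(seq_len(reps), function(i) {
    j <- idx[i, ]
    (sum(fw$N[j]) / sum(fw$D[j]) + sum(bw$N[j]) / sum(bw$D[j])) / 2
  }, numeric(1))
  rStar <- rStar[is.finite(rStar)]
  q <- stats::quantile(rStar, c(0.025, 0.975), names = FALSE, type = 7)
  c(ciLow = q[1], ciHigh = q[2])
}

#' Screen for candidate first-order dyads
#'
#' Computes the symmetrized Lynch-Ritland r for every unordered pair of
#' individuals and returns the dyads with r above the threshold, annotated
#' with sexes and mitochondrial haplotypes.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param freqs Allele frequencies (see \code{\link{alleleFreqs}}).
#' @param threshold Screening threshold on r (default 0.40).
#' @param mtMarkers Locus ids of the four mtDNA haplotype markers, in
#'   marker order; \code{NULL} skips haplotype annotation.
#' @return data.frame with \code{ind1}, \code{ind2}, \code{sex1},
#'   \code{sex2}, \code{hap}, \code{r}.
#' @export
candidateFirstOrder <- function(panel, freqs, threshold = 0.40,
                                mtMarkers = NULL) {
  inds <- individualIds(panel)
  if (length(inds) < 2L)
    stop("need at least two individuals")
  sex <- individualSex(panel)
  calls <- genotypeCalls(panel)
  hapOf <- function(ind) {
    if (is.null(mtMarkers)) return(NA_character_)
    assignMtHaplotype(calls[mtMarkers, ind])
  }
  pairs <- utils::combn(inds, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    r <- lynchRitlandR(panel, i, j, freqs)
    if (r <= threshold) return(NULL)
    h1 <- hapOf(i); h2 <- hapOf(j)
    hap <- if (is.na(h1) || is.na(h2)) NA_character_
           else if (h1 == h2) h1 else paste0(h1, "/", h2)
    data.frame(ind1 = i, ind2 = j, sex1 = unname(sex[i]),
               sex2 = unname(sex[j]), hap = hap, r = r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ind1 = character(), ind2 = character(),
                      sex1 = character(), sex2 = character(),
                      hap = character(), r = numeric())
  out
}

#' Parent-offspring exclusion by autosomal allele sharing
#'
#' A true parent-offspring dyad shares at least one allele identical by
#' descent at every autosomal locus, so a dyad is excluded as
#' parent-offspring as soon as one locus shows opposite homozygotes
#' (AA vs BB).  Missing calls never exclude.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param ind1,ind2 Individual ids.
#' @param loci Locus ids to evaluate (default: all autosomal).
#' @return list(status = "Possible"|"Excluded", excludingLoci).
#' @export
poExclusionAutosomal <- function(panel, ind1, ind2, loci = NULL) {
  if (is.null(loci))
    loci <- lociIds(panel)[locusClass(panel) == "autosomal"]
  calls <- genotypeCalls(panel)
  x <- calls[loci, ind1]
  y <- calls[loci, ind2]
  opp <- (x == "AA" & y == "BB") | (x == "BB" & y == "AA")
  excl <- loci[opp]
  list(status = if (length(excl)) "Excluded" else "Possible",
       excludingLoci = excl)
}

# X-inheritance violation for one parent->offspring orientation at one
# locus; calls already non-missing. Mother passes one of her X alleles to
# every child; a father passes his single X to daughters only.
.xViolates <- function(parentSex, childSex, pCall, cCall) {
  alleles <- function(g) {
    if (g %in% .HAPLOID_CALLS) g
    else if (g %in% .DIPLOID_CALLS) strsplit(g, "", fixed = TRUE)[[1]]
    else character()
  }
  pa <- unique(alleles(pCall))
  ca <- unique(alleles(cCall))
  if (!length(pa) || !length(ca)) return(FALSE)
  if (parentSex == "M" && childSex == "M") return(FALSE)  # no paternal X
  if (parentSex == "F" && childSex == "M")
    return(!any(ca %in% pa))                  # son's X must be maternal
  if (parentSex == "M" && childSex == "F")
    return(!any(pa %in% ca))                  # daughter carries father's X
  # mother-daughter: must share at least one allele
  !any(ca %in% pa)
}

#' Parent-offspring exclusion by X-chromosome inheritance
#'
#' Checks the X-linked loci of a dyad against X inheritance: a son's X
#' allele must occur in his mother, a daughter must carry her father's X
#' allele, mother and daughter must share an allele, and father-son pairs
#' are unconstrained.  Since which member would be the parent is unknown,
#' both orientations compatible with the sexes are evaluated and the dyad
#' is excluded only when every orientation is violated at some locus.
#' Males must be hemizygous (single-letter or homozygous calls) at X loci.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param ind1,ind2 Individual ids (sexes must be M or F).
#' @param xLoci X-linked locus ids (default: rows of class \code{X}).
#' @return list(status = "Possible"|"Excluded", violations per
#'   orientation).
#' @export
poExclusionX <- function(panel, ind1, ind2, xLoci = NULL) {
  if (is.null(xLoci))
    xLoci <- lociIds(panel)[locusClass(panel) == "X"]
  sex <- individualSex(panel)
  s1 <- sex[ind1]; s2 <- sex[ind2]
  if (!all(c(s1, s2) %in% c("M", "F")))
    stop("both sexes must be annotated M or F for X-based exclusion")
  calls <- genotypeCalls(panel)
  if (length(xLoci) == 0L)
    return(list(status = "Possible", violations = list()))
  g1 <- calls[xLoci, ind1, drop = TRUE]
  g2 <- calls[xLoci, ind2, drop = TRUE]
  for (ind in c(ind1, ind2)) {
    if (sex[ind] == "M" && any(calls[xLoci, ind] == "AB"))
      stop("male ", ind, " has a heterozygous X call")
  }
  orientViol <- function(parent, child) {
    pc <- if (parent == ind1) g1 else g2
    cc <- if (parent == ind1) g2 else g1
    ok <- pc != .MISSING_CALL & cc != .MISSING_CALL
    v <- vapply(which(ok), function(k)
      .xViolates(unname(sex[parent]), unname(sex[child]), pc[k], cc[k]),
      logical(1))
    xLoci[which(ok)[v]]
  }
  v12 <- orientViol(ind1, ind2)   # ind1 as parent
  v21 <- orientViol(ind2, ind1)   # ind2 as parent
  excluded <- length(v12) > 0L && length(v21) > 0L
  list(status = if (excluded) "Excluded" else "Possible",
       violations = list(parent1 = v12, parent2 = v21))
}

#' Classify candidate dyads for parent-offspring status
#'
#' Runs the full relatedness workflow: screen all pairs at
#' \code{r > threshold}, attach bootstrap confidence limits, apply
#' autosomal allele-sharing exclusion and (when X loci are present and
#' both sexes known) X-inheritance exclusion, then label each dyad
#' \code{Known} (listed in \code{knownPO} and not excluded),
#' \code{Possible} or \code{Excluded}.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param freqs Allele frequencies for the estimator.
#' @param threshold Screening threshold (default 0.40).
#' @param knownPO Optional list/data.frame of known parent-offspring
#'   pairs (columns/elements ind1, ind2; unordered).
#' @param mtMarkers Optional mtDNA marker ids for haplotype annotation.
#' @param reps,seed Bootstrap controls (see \code{\link{bootstrapCI}}).
#' @return data.frame sorted by ids: \code{ind1}, \code{ind2},
#'   \code{sex1}, \code{sex2}, \code{hap}, \code{r}, \code{ciLow},
#'   \code{ciHigh}, \code{poStatus}, \code{nExcludingLoci},
#'   \code{xExcluded}.
#' @export
classifyDyads <- function(panel, freqs, threshold = 0.40,
                          knownPO = NULL, mtMarkers = NULL,
                          reps = 1000L, seed = 1L) {
  cand <- candidateFirstOrder(panel, freqs, threshold = threshold,
                              mtMarkers = mtMarkers)
  if (nrow(cand) == 0L)
    return(cbind(cand, data.frame(ciLow = numeric(), ciHigh = numeric(),
                                  poStatus = character(),
                                  nExcludingLoci = integer(),
                                  xExcluded = logical())))
  isKnown <- function(i, j) {
    if (is.null(knownPO)) return(FALSE)
    kp <- as.data.frame(knownPO)
    any((kp[[1]] == i & kp[[2]] == j) | (kp[[1]] == j & kp[[2]] == i))
  }
  sex <- individualSex(panel)
  haveX <- any(locusClass(panel) == "X")
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    i <- cand$ind1[k]; j <- cand$ind2[k]
    ci <- bootstrapCI(panel, i, j, freqs, reps = reps,
                      seed = seed + k)
    auto <- poExclusionAutosomal(panel, i, j)
    xex <- FALSE
    if (auto$status == "Possible" && haveX &&
        all(sex[c(i, j)] %in% c("M", "F"))) {
      xres <- poExclusionX(panel, i, j)
      xex <- xres$status == "Excluded"
    }
    status <- if (auto$status == "Excluded" || xex) "Excluded"
              else if (isKnown(i, j)) "Known" else "Possible"
    data.frame(cand[k, ], ciLow = unname(ci[1]), ciHigh = unname(ci[2]),
               poStatus = status,
               nExcludingLoci = length(auto$excludingLoci),
               xExcluded = xex, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(out$ind1, out$ind2), , drop = FALSE]
}
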