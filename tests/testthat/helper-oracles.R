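# Independent brute-force oracles the implementation is checked against.

# character-scan digest: cut after occurrence_start + cutOffset (0-based),
# windows containing non-ACGT never cut
naiveDigestLengths <- function(seq, pattern = "AGATCT", cutOffset = 1L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  plen <- nchar(pattern)
  cuts <- integer()
  for (s in seq_len(max(0L, n - plen + 1L))) {
    if (substr(seq, s, s + plen - 1L) == pattern)
      cuts <- c(cuts, s - 1L + cutOffset)   # 0-based cut position
  }
  cuts <- cuts[cuts > 0L & cuts < n]
  diff(c(0L, sort(unique(cuts)), n))
}

# exact HWE p-value by direct closed-form enumeration over heterozygote
# counts (log-factorial route, independent of the package's recurrence)
enumHweP <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  if (min(nA, nB) == 0) return(1)
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  logP <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logP)
  obs <- pr[hs == nAB]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# random sequence of given length
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# tiny genotype panel from a character matrix of calls
tinyPanel <- function(calls, locusClass = rep("autosomal", nrow(calls)),
                      sex = rep(c("M", "F"), length.out = ncol(calls))) {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("i%d", seq_len(ncol(calls)))
  genotypePanel(calls, locusClass = locusClass, sex = sex)
}

# unphased two-locus panel simulated from known phased haplotype
# frequencies; planted D' is exact in the generating distribution
simPhasedPair <- function(n, pA, pB, dPrime, seed) {
  dMax <- if (dPrime >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  D <- dPrime * dMax
  h <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
         (1 - pA) * (1 - pB) + D)
  stopifnot(all(h >= 0))
  set.seed(seed)
  h1 <- sample(1:4, n, TRUE, prob = h)
  h2 <- sample(1:4, n, TRUE, prob = h)
  dosA <- (h1 <= 2) + (h2 <= 2)
  dosB <- (h1 %% 2 == 1) + (h2 %% 2 == 1)
  code <- c("BB", "AB", "AA")
  calls <- rbind(L1 = code[dosA + 1], L2 = code[dosB + 1])
  colnames(calls) <- sprintf("i%d", seq_len(n))
  tinyPanel(calls)
}
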