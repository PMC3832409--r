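#' @importFrom stats rexp rbinom runif
NULL

.BASES <- c("A", "C", "G", "T")

# random sequence with no single-nucleotide run longer than maxRun
.randSeqNoRun <- function(n, maxRun = 5L) {
  s <- sample(.BASES, n, replace = TRUE)
  r <- rle(s)
  while (any(r$lengths > maxRun)) {
    ends <- cumsum(r$lengths)
    for (k in which(r$lengths > maxRun)) {
      i <- ends[k]                     # break the run at its last base
      s[i] <- sample(setdiff(.BASES, s[i]), 1)
    }
    r <- rle(s)
  }
  paste(s, collapse = "")
}

#' Simulate a genome with Poisson-spaced restriction sites
#'
#' Generates scaffolds of i.i.d. uniform A/C/G/T background and plants the
#' recognition pattern at positions whose spacings are exponential with
#' mean \code{meanSpacing}, so that digest fragment lengths are exactly
#' exponential and the design model's predictions are sharp.  Accidental
#' background occurrences of the pattern are removed by regenerating a
#' base inside each one, so a scan finds exactly the planted sites.
#'
#' @param genomeLength Total genome length (bp), split evenly across
#'   scaffolds.
#' @param meanSpacing Mean distance between planted sites (bp); use
#'   \code{Inf} (or \code{siteDensity = 0}) for a site-free genome.
#' @param site A \linkS4class{RecognitionSite}.
#' @param nScaffolds Number of scaffolds.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return list(genome = DNAStringSet, truth = data.frame(scaffold, pos)
#'   of planted 0-based site starts).
#' @export
simGenome <- function(genomeLength, meanSpacing, site = bglII(),
                      nScaffolds = 1L, seed = 1L) {
  stopifnot(genomeLength >= 1, nScaffolds >= 1, meanSpacing > 0)
  pat <- strsplit(site@pattern, "", fixed = TRUE)[[1]]
  plen <- length(pat)
  .withSeed(seed, {
    lens <- rep(genomeLength %/% nScaffolds, nScaffolds)
    lens[1] <- lens[1] + genomeLength %% nScaffolds
    seqs <- character(nScaffolds)
    truth <- vector("list", nScaffolds)
    for (sc in seq_len(nScaffolds)) {
      n <- lens[sc]
      s <- sample(.BASES, n, replace = TRUE)
      # planted site starts: exponential spacings; regeneration resolves
      # collisions (spacings shorter than the pattern)
      pos <- integer()
      if (is.finite(meanSpacing)) {
        cur <- 0
        repeat {
          gap <- rexp(1, rate = 1 / meanSpacing)
          if (gap < plen) next
          cur <- cur + gap
          if (cur + plen > n) break
          pos <- c(pos, as.integer(floor(cur)))
        }
        for (p in pos) s[(p + 1):(p + plen)] <- pat
      }
      planted <- IRanges(pos + 1L, width = plen)
      # scrub accidental occurrences, re-scanning until clean
      repeat {
        hits <- matchPattern(site@pattern, DNAString(paste(s, collapse = "")),
                             fixed = TRUE)
        occ <- as(hits, "IRanges")
        accidental <- occ[!(IRanges::start(occ) %in% IRanges::start(planted))]
        if (length(accidental) == 0L) break
        for (k in seq_along(accidental)) {
          cand <- IRanges::start(accidental)[k]:IRanges::end(accidental)[k]
          inPlanted <- IRanges::overlapsAny(IRanges(cand, cand), planted)
          cand <- cand[!inPlanted]
          if (!length(cand)) next
          i <- cand[sample.int(length(cand), 1)]
          s[i] <- sample(setdiff(.BASES, s[i]), 1)
        }
      }
      seqs[sc] <- paste(s, collapse = "")
      truth[[sc]] <- if (length(pos))
        data.frame(scaffold = sprintf("scaffold%d", sc), pos = sort(pos))
      else data.frame(scaffold = character(), pos = integer())
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("scaffold%d", seq_len(nScaffolds))
    list(genome = genome, truth = do.call(rbind, truth))
  })
}

# ---- pedigree panel --------------------------------------------------------

#' A simple two-generation pedigree specification
#'
#' Builds a pedigree data.frame with \code{nFamilies} father-mother-child
#' trios plus \code{nUnrelated} extra founders.  Offspring sex alternates.
#'
#' @param nFamilies Number of trios.
#' @param nUnrelated Additional unrelated founders.
#' @return data.frame with \code{id}, \code{sex}, \code{mother},
#'   \code{father} (NA for founders).
#' @export
basicPedigree <- function(nFamilies = 2L, nUnrelated = 8L) {
  rows <- list()
  for (f in seq_len(nFamilies)) {
    fa <- sprintf("fam%d_father", f)
    mo <- sprintf("fam%d_mother", f)
    ch <- sprintf("fam%d_child", f)
    rows[[length(rows) + 1]] <- data.frame(
      id = c(fa, mo, ch),
      sex = c("M", "F", if (f %% 2) "M" else "F"),
      mother = c(NA, NA, mo), father = c(NA, NA, fa))
  }
  if (nUnrelated > 0)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("unrel%d", seq_len(nUnrelated)),
      sex = rep(c("M", "F"), length.out = nUnrelated),
      mother = NA_character_, father = NA_character_)
  do.call(rbind, rows)
}

# dyad relationship classes implied by a two-generation pedigree
.dyadClasses <- function(ped) {
  ids <- ped$id
  mo <- stats::setNames(ped$mother, ids)
  fa <- stats::setNames(ped$father, ids)
  pairs <- utils::combn(ids, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  po <- (!is.na(mo[i]) & mo[i] == j) | (!is.na(fa[i]) & fa[i] == j) |
        (!is.na(mo[j]) & mo[j] == i) | (!is.na(fa[j]) & fa[j] == i)
  sharedM <- !is.na(mo[i]) & !is.na(mo[j]) & mo[i] == mo[j]
  sharedF <- !is.na(fa[i]) & !is.na(fa[j]) & fa[i] == fa[j]
  shared <- sharedM + sharedF
  cls <- ifelse(po, "P-O",
         ifelse(shared == 2, "full-sib",
         ifelse(shared == 1, "half-sib", "unrelated")))
  data.frame(ind1 = i, ind2 = j, class = unname(cls), row.names = NULL)
}

#' Simulate a pedigree genotype panel with ground truth
#'
#' Founder alleles are drawn per locus under Hardy-Weinberg proportions
#' from minor allele frequencies sampled uniformly in \code{mafRange}
#' (default 0.28-0.50, giving the mean MAF of about 0.39 typical of a
#' MAF-ranked SNP panel); offspring genotypes follow Mendelian
#' transmission.  X-linked loci: sons receive the maternal X only and are
#' hemizygous (single-letter calls), daughters one X from each parent.
#' mtDNA haplotypes (ABAA / AAAA / BBBB over four markers) are maternally
#' inherited; Y markers are present in males only.
#'
#' @param pedigree data.frame with \code{id}, \code{sex}, \code{mother},
#'   \code{father} (NA for founders), parents listed before offspring.
#' @param nAutosomal,nX Number of autosomal and X-linked SNP loci.
#' @param mafRange Range the founder MAFs are drawn from.
#' @param missingRate Per-call probability of a missing autosomal call.
#' @param dyadTruth Whether to tabulate the relationship class of every
#'   dyad in the truth set; defaults to off for pedigrees above 1000
#'   individuals, where the all-pairs table gets unwieldy.
#' @param seed Integer seed.
#' @return list(panel = GenotypePanel, freqs = true allele-A frequencies
#'   of the autosomal loci, truth = list(pedigree, dyads, mafA, mafX,
#'   mtHaplotype)).
#' @export
simPedigreePanel <- function(pedigree = basicPedigree(),
                             nAutosomal = 87L, nX = 3L,
                             mafRange = c(0.28, 0.5),
                             missingRate = 0,
                             dyadTruth = nrow(pedigree) <= 1000L,
                             seed = 1L) {
  ped <- pedigree
  stopifnot(all(c("id", "sex", "mother", "father") %in% colnames(ped)),
            all(ped$sex %in% c("M", "F")))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  for (k in seq_len(nrow(ped))) {
    pp <- c(ped$mother[k], ped$father[k])
    pp <- pp[!is.na(pp)]
    if (!all(pp %in% ped$id[seq_len(k - 1)]))
      stop("parents must be listed before offspring (row ", k, ")")
  }
  nInd <- nrow(ped)
  .withSeed(seed, {
    mafA <- runif(nAutosomal, mafRange[1], mafRange[2])
    pA <- 1 - mafA                       # A is the major allele
    mafX <- if (nX > 0) runif(nX, mafRange[1], mafRange[2]) else numeric()
    pX <- 1 - mafX
    autoIds <- sprintf("auto%03d", seq_len(nAutosomal))
    xIds <- if (nX > 0) sprintf("x%02d", seq_len(nX)) else character()
    mtIds <- sprintf("Ua%02dmt", c(3, 4, 5, 7))
    yIds <- c("y1", "y2")

    # allele matrices: 1 = allele A; columns follow ped order
    a1 <- matrix(NA_integer_, nAutosomal, nInd)
    a2 <- matrix(NA_integer_, nAutosomal, nInd)
    xm <- matrix(NA_integer_, max(nX, 1), nInd)  # maternal X
    xp <- matrix(NA_integer_, max(nX, 1), nInd)  # paternal X (females)
    mtHap <- character(nInd)
    haps <- c(NorthA = "ABAA", NorthB = "AAAA", South = "BBBB")
    idx <- stats::setNames(seq_len(nInd), ped$id)
    for (k in seq_len(nInd)) {
      mo <- ped$mother[k]; fa <- ped$father[k]
      if (is.na(mo)) {                   # founder
        a1[, k] <- rbinom(nAutosomal, 1, pA)
        a2[, k] <- rbinom(nAutosomal, 1, pA)
        if (nX > 0) {
          xm[seq_len(nX), k] <- rbinom(nX, 1, pX)
          if (ped$sex[k] == "F") xp[seq_len(nX), k] <- rbinom(nX, 1, pX)
        }
        mtHap[k] <- sample(names(haps), 1, prob = c(0.4, 0.3, 0.3))
      } else {
        m <- idx[[mo]]; f <- idx[[fa]]
        pickM <- rbinom(nAutosomal, 1, 0.5) == 1
        pickF <- rbinom(nAutosomal, 1, 0.5) == 1
        a1[, k] <- ifelse(pickM, a1[, m], a2[, m])
        a2[, k] <- ifelse(pickF, a1[, f], a2[, f])
        if (nX > 0) {
          pickX <- rbinom(nX, 1, 0.5) == 1
          motherX2 <- if (ped$sex[m] == "F") xp[seq_len(nX), m]
                      else stop("mother ", mo, " is not female")
          xm[seq_len(nX), k] <- ifelse(pickX, xm[seq_len(nX), m], motherX2)
          if (ped$sex[k] == "F") xp[seq_len(nX), k] <- xm[seq_len(nX), f]
        }
        mtHap[k] <- mtHap[m]
      }
    }

    code <- function(d) c("BB", "AB", "AA")[d + 1L]   # d = A dose 0..2
    calls <- matrix("--", nAutosomal + nX + 4L + 2L, nInd,
                    dimnames = list(c(autoIds, xIds, mtIds, yIds), ped$id))
    calls[autoIds, ] <- code(a1 + a2)
    if (missingRate > 0) {
      drop <- matrix(runif(nAutosomal * nInd) < missingRate,
                     nAutosomal, nInd)
      calls[autoIds, ][drop] <- "--"
    }
    if (nX > 0) {
      for (k in seq_len(nInd)) {
        if (ped$sex[k] == "M")
          calls[xIds, k] <- c("B", "A")[xm[seq_len(nX), k] + 1L]
        else
          calls[xIds, k] <- code(xm[seq_len(nX), k] + xp[seq_len(nX), k])
      }
    }
    for (k in seq_len(nInd))
      calls[mtIds, k] <- strsplit(haps[[mtHap[k]]], "", fixed = TRUE)[[1]]
    calls[yIds, ] <- ifelse(rep(ped$sex == "M", each = 2), "A", "--")

    panel <- genotypePanel(
      calls,
      locusClass = c(rep("autosomal", nAutosomal), rep("X", nX),
                     rep("mtDNA", 4), rep("Y", 2)),
      sex = ped$sex)
    list(panel = panel,
         freqs = stats::setNames(pA, autoIds),
         truth = list(pedigree = ped,
                      dyads = if (dyadTruth) .dyadClasses(ped) else NULL,
                      mafA = stats::setNames(mafA, autoIds),
                      mafX = stats::setNames(mafX, xIds),
                      mtHaplotype = stats::setNames(mtHap, ped$id)))
  })
}

# ---- stack fixtures --------------------------------------------------------

.STRATA <- c("pass", "single_snp", "position", "individuals_classes",
             "low_identity", "gapped_alignment", "multiple_alignments",
             "unaligned", "shared_scaffold", "homopolymer")

#' Simulate a stack catalog and alignment hits with planted filter outcomes
#'
#' Generates consensus-stack records in labeled strata, each failing
#' exactly one criterion of the filter cascade (or none, for the
#' \code{pass} stratum): multi-SNP reads, off-window SNP positions, too
#' few called individuals or a missing genotype class, low-identity or
#' gapped or multi-mapping alignments, unaligned stacks, pairs sharing a
#' scaffold, and homopolymer flanks.  The truth table records each
#' stack's stratum and expected rejection reason, so
#' \code{\link{runFilterPipeline}} can be checked exactly.
#'
#' @param nPerStratum Records per stratum (the shared-scaffold stratum is
#'   rounded up to an even count).
#' @param nIndividuals Individuals carrying genotype calls.
#' @param readLen Consensus length (nt).
#' @param seed Integer seed.
#' @param cfg A \code{\link{filterConfig}} the strata are built against.
#' @return list(records, hits, truth = data.frame(stack_id, stratum,
#'   reason)).
#' @export
simStackFixtures <- function(nPerStratum = 20L, nIndividuals = 9L,
                             readLen = 100L, seed = 1L,
                             cfg = filterConfig()) {
  stopifnot(nPerStratum >= 1, nIndividuals >= cfg$minIndividuals)
  .withSeed(seed, {
    inds <- sprintf("ind%d", seq_len(nIndividuals))
    lo <- cfg$minFlank5                       # admissible 0-based window
    hi <- readLen - 1L - cfg$minFlank3
    records <- list(); hitRows <- list(); truthRows <- list()
    scafN <- 0L
    nextScaf <- function() {
      scafN <<- scafN + 1L
      sprintf("scaf%04d", scafN)
    }
    goodCalls <- function() {
      calls <- matrix(sample(c("aa", "ab", "bb"), nIndividuals,
                             replace = TRUE), ncol = 1,
                      dimnames = list(inds, NULL))
      calls[1:3, 1] <- c("aa", "ab", "bb")    # guarantee all classes
      calls
    }
    hit <- function(id, scaf, pident = 100, gapopen = 0L)
      data.frame(qseqid = id, sseqid = scaf, pident = pident,
                 length = readLen, mismatch = ifelse(pident < 100, 2L, 0L),
                 gapopen = gapopen)
    snpAlleles <- function(seq, pos) {
      ref <- substr(seq, pos + 1, pos + 1)
      alt <- sample(setdiff(.BASES, ref), 1)
      c(ref, alt)
    }
    addRecord <- function(stratum, reason, build) {
      id <- sprintf("stk_%s_%03d", stratum, sum(vapply(truthRows,
              function(t) t$stratum == stratum, logical(1))) + 1L)
      out <- build(id)
      records[[id]] <<- out$record
      if (!is.null(out$hits)) hitRows[[length(hitRows) + 1L]] <<- out$hits
      truthRows[[length(truthRows) + 1L]] <<- data.frame(
        stack_id = id, stratum = stratum,
        reason = if (is.na(reason)) NA_character_ else reason)
    }
    cleanRecord <- function(id, scaf = nextScaf()) {
      seq <- .randSeqNoRun(readLen, cfg$maxHomopolymerRun)
      pos <- sample(lo:hi, 1)
      ra <- snpAlleles(seq, pos)
      list(record = stackRecord(id, seq, pos, ra[1], ra[2], goodCalls()),
           hits = hit(id, scaf))
    }

    for (i in seq_len(nPerStratum)) {
      addRecord("pass", NA_character_, cleanRecord)
      addRecord("single_snp", "single_snp", function(id) {
        seq <- .randSeqNoRun(readLen, cfg$maxHomopolymerRun)
        pos <- sort(sample(lo:hi, 2))
        ra1 <- snpAlleles(seq, pos[1]); ra2 <- snpAlleles(seq, pos[2])
        gt <- cbind(goodCalls(), goodCalls())
        list(record = stackRecord(id, seq, pos, c(ra1[1], ra2[1]),
                                  c(ra1[2], ra2[2]), gt),
             hits = hit(id, nextScaf()))
      })
      addRecord("position", "position", function(id) {
        seq <- .randSeqNoRun(readLen, cfg$maxHomopolymerRun)
        offWindow <- c(0:(lo - 1L), (hi + 1L):(readLen - 1L))
        pos <- sample(offWindow, 1)
        ra <- snpAlleles(seq, pos)
        list(record = stackRecord(id, seq, pos, ra[1], ra[2], goodCalls()),
             hits = hit(id, nextScaf()))
      })
      addRecord("individuals_classes", "individuals_classes", function(id) {
        out <- cleanRecord(id)
        calls <- out$record$genotypes
        if (i %% 2 == 0) {               # too few called individuals
          calls[, 1] <- "--"
          calls[1:(cfg$minIndividuals - 1L), 1] <-
            sample(c("aa", "ab", "bb"), cfg$minIndividuals - 1L,
                   replace = TRUE)
        } else {                         # bb class never observed
          calls[, 1] <- sample(c("aa", "ab"), nIndividuals, replace = TRUE)
          calls[1:2, 1] <- c("aa", "ab")
        }
        out$record$genotypes <- calls
        out
      })
      addRecord("low_identity", "low_identity", function(id) {
        out <- cleanRecord(id)
        out$hits <- hit(id, out$hits$sseqid, pident = 97)
        out
      })
      addRecord("gapped_alignment", "gapped_alignment", function(id) {
        out <- cleanRecord(id)
        out$hits <- hit(id, out$hits$sseqid, gapopen = 1L)
        out
      })
      addRecord("multiple_alignments", "multiple_alignments", function(id) {
        out <- cleanRecord(id)
        out$hits <- rbind(out$hits, hit(id, nextScaf()))
        out
      })
      addRecord("unaligned", "unaligned", function(id) {
        out <- cleanRecord(id)
        out$hits <- NULL
        out
      })
      if (i %% 2 == 1) {                 # shared-scaffold records in pairs
        shared <- nextScaf()
        addRecord("shared_scaffold", "shared_scaffold",
                  function(id) cleanRecord(id, scaf = shared))
        addRecord("shared_scaffold", "shared_scaffold",
                  function(id) cleanRecord(id, scaf = shared))
      }
      addRecord("homopolymer", "homopolymer", function(id) {
        seq <- .randSeqNoRun(readLen, cfg$maxHomopolymerRun)
        pos <- sample((lo + 8L):(hi - 8L), 1)  # room for the run nearby
        run <- strrep(sample(.BASES, 1), cfg$maxHomopolymerRun + 1L)
        offset <- sample(2:(cfg$flankScanLen - cfg$maxHomopolymerRun), 1)
        side <- sample(c(-1L, 1L), 1)
        at <- if (side < 0) pos - offset - cfg$maxHomopolymerRun else
          pos + offset
        substr(seq, at + 1L, at + nchar(run)) <- run
        # the planted run must not create a new cut-site-free SNP issue;
        # re-read alleles from the final sequence
        ra <- snpAlleles(seq, pos)
        list(record = stackRecord(id, seq, pos, ra[1], ra[2], goodCalls()),
             hits = hit(id, nextScaf()))
      })
    }
    hits <- do.call(rbind, hitRows)
    truth <- do.call(rbind, truthRows)
    rownames(truth) <- NULL
    list(records = records, hits = hits, truth = truth)
  })
}
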