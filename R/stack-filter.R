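#' Filter-cascade configuration
#'
#' Defaults encode the cascade applied to putative SNPs on 100-nt consensus
#' stacks: one SNP per read located at least 20 nt from the 5' end and 35 nt
#' from the 3' end, called in at least three individuals with all three
#' genotype classes observed, a unique gap-free genome alignment at >= 99\%
#' identity, no second SNP on the same scaffold, and no long homopolymer in
#' the flanking sequence.
#'
#' @param minFlank5 Minimum bases strictly 5' of the SNP.
#' @param minFlank3 Minimum bases strictly 3' of the SNP.
#' @param minIndividuals Minimum individuals with a non-missing call.
#' @param minIdentityPct Minimum alignment identity (percent).
#' @param allowGaps Accept alignments with gap opens.
#' @param requireUniqueHit Reject stacks with more than one qualifying hit.
#' @param maxHomopolymerRun Longest tolerated single-nucleotide run in the
#'   scanned flank; runs strictly longer fail.
#' @param flankScanLen Bases scanned outward from the SNP on each side.
#' @return A list of class \code{filterConfig}.
#' @export
filterConfig <- function(minFlank5 = 20L, minFlank3 = 35L,
                         minIndividuals = 3L, minIdentityPct = 99,
                         allowGaps = FALSE, requireUniqueHit = TRUE,
                         maxHomopolymerRun = 5L, flankScanLen = 20L) {
  cfg <- list(minFlank5 = as.integer(minFlank5),
              minFlank3 = as.integer(minFlank3),
              minIndividuals = as.integer(minIndividuals),
              minIdentityPct = as.numeric(minIdentityPct),
              allowGaps = isTRUE(allowGaps),
              requireUniqueHit = isTRUE(requireUniqueHit),
              maxHomopolymerRun = as.integer(maxHomopolymerRun),
              flankScanLen = as.integer(flankScanLen))
  stopifnot(all(vapply(cfg[c(1:3, 7, 8)], function(v) v >= 0L, logical(1))))
  class(cfg) <- "filterConfig"
  cfg
}

.oneSnp <- function(record) {
  if (nrow(record$snps) != 1L)
    stop("expected exactly one SNP in stack ", record$stack_id)
  invisible(record)
}

#' Single-SNP criterion
#'
#' A stack passes only if it carries exactly one SNP; multi-SNP reads are
#' dropped as candidate hypervariable or error-prone sequence, zero-SNP
#' reads carry nothing forward.
#'
#' @param record A stack record (see \code{\link{stackRecord}}).
#' @return TRUE/FALSE.
#' @export
fcSingleSnp <- function(record) {
  nrow(record$snps) == 1L
}

#' Read-position criterion
#'
#' The single SNP must sit at least \code{minFlank5} bases from the 5' end
#' and \code{minFlank3} bases from the 3' end of the consensus, so that
#' assay-design flanks remain on both sides.  On 100-nt reads with the
#' defaults this admits 0-based positions 20..64.
#'
#' @param record A stack record with exactly one SNP.
#' @param cfg A \code{\link{filterConfig}}.
#' @return TRUE/FALSE.
#' @export
fcPosition <- function(record, cfg = filterConfig()) {
  .oneSnp(record)
  pos <- record$snps$pos[1]
  n <- nchar(record$consensus)
  pos >= cfg$minFlank5 && (n - 1L - pos) >= cfg$minFlank3
}

#' Individual-count and genotype-class criterion
#'
#' Requires at least \code{minIndividuals} non-missing calls and all three
#' genotype classes (aa, ab, bb) observed at least once.
#'
#' @inheritParams fcPosition
#' @return TRUE/FALSE.
#' @export
fcIndividualsAndClasses <- function(record, cfg = filterConfig()) {
  calls <- record$genotypes[, 1]
  calls <- calls[calls != "--"]
  length(calls) >= cfg$minIndividuals &&
    all(c("aa", "ab", "bb") %in% calls)
}

#' Alignment criterion
#'
#' A qualifying hit aligns with at least \code{minIdentityPct} identity and
#' (unless \code{allowGaps}) zero gap opens.  The stack passes iff it has
#' exactly one qualifying hit (multi-mapping stacks are candidate
#' paralogs); the scaffold of that hit is returned for the
#' scaffold-uniqueness step.
#'
#' @param hits data.frame of alignment hits for one stack (possibly empty).
#' @param cfg A \code{\link{filterConfig}}.
#' @return A list with \code{pass}, \code{scaffold} (NA unless pass) and
#'   \code{reason}.
#' @export
fcAlignment <- function(hits, cfg = filterConfig()) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(pass = FALSE, scaffold = NA_character_,
                reason = "unaligned"))
  ok <- hits$pident >= cfg$minIdentityPct &
    (cfg$allowGaps | hits$gapopen == 0L)
  nq <- sum(ok)
  if (nq == 0L)
    return(list(pass = FALSE, scaffold = NA_character_,
                reason = if (all(hits$gapopen > 0L)) "gapped_alignment"
                         else "low_identity"))
  if (cfg$requireUniqueHit && nq > 1L)
    return(list(pass = FALSE, scaffold = NA_character_,
                reason = "multiple_alignments"))
  list(pass = TRUE, scaffold = hits$sseqid[which(ok)[1]], reason = NA_character_)
}

#' Scaffold-uniqueness criterion
#'
#' Drops every SNP on any scaffold carrying two or more surviving SNPs, to
#' minimize linkage through close physical vicinity.
#'
#' @param snpToScaffold Named character vector: stack id -> scaffold id.
#' @return Character vector of surviving stack ids.
#' @export
fcScaffoldUnique <- function(snpToScaffold) {
  if (length(snpToScaffold) == 0L) return(character())
  tab <- table(snpToScaffold)
  keep <- names(snpToScaffold)[snpToScaffold %in% names(tab)[tab == 1L]]
  keep
}

.maxRun <- function(s) {
  if (nchar(s) == 0L) return(0L)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' Homopolymer-flank criterion
#'
#' Scans \code{flankScanLen} bases outward from the SNP on each side; the
#' stack fails if either scanned flank contains a single-nucleotide run
#' longer than \code{maxHomopolymerRun}.
#'
#' @inheritParams fcPosition
#' @return TRUE/FALSE.
#' @export
fcHomopolymer <- function(record, cfg = filterConfig()) {
  .oneSnp(record)
  pos <- record$snps$pos[1]          # 0-based
  n <- nchar(record$consensus)
  left <- substr(record$consensus, max(1L, pos + 1L - cfg$flankScanLen), pos)
  right <- substr(record$consensus, pos + 2L,
                  min(n, pos + 1L + cfg$flankScanLen))
  .maxRun(left) <= cfg$maxHomopolymerRun &&
    .maxRun(right) <= cfg$maxHomopolymerRun
}

#' Run the full SNP filter cascade
#'
#' Applies, in order: single-SNP, read-position, individuals+classes,
#' unique gap-free alignment, scaffold uniqueness, homopolymer flank.  The
#' first three criteria are order-independent (each looks at a different
#' facet of the record); they are applied sequentially and yield the same
#' surviving set in any order.
#'
#' @param records List of stack records (named by stack id or not).
#' @param hits data.frame of alignment hits for all stacks
#'   (\code{qseqid} keys them to records).
#' @param cfg A \code{\link{filterConfig}}.
#' @return A list of class \code{filterReport}: \code{counts} (named
#'   integer vector of survivors after each step, starting at
#'   \code{input}), \code{survivors} (stack ids), \code{reasons} (named
#'   character: first failure reason per rejected stack), and
#'   \code{scaffold} (named map for stacks reaching the alignment step).
#' @export
runFilterPipeline <- function(records, hits, cfg = filterConfig()) {
  ids <- vapply(records, function(r) r$stack_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate stack ids in catalog")
  names(records) <- ids
  orphan <- setdiff(unique(hits$qseqid), ids)
  if (length(orphan))
    stop("alignment hits reference unknown stacks: ",
         paste(utils::head(orphan, 5), collapse = ", "))

  reasons <- stats::setNames(rep(NA_character_, length(ids)), ids)
  counts <- c(input = length(ids))
  alive <- ids

  stepFilter <- function(alive, name, predicate) {
    pass <- vapply(alive, function(id) predicate(records[[id]]), logical(1))
    reasons[alive[!pass]] <<- name
    counts[name] <<- sum(pass)
    alive[pass]
  }
  alive <- stepFilter(alive, "single_snp", fcSingleSnp)
  alive <- stepFilter(alive, "position", function(r) fcPosition(r, cfg))
  alive <- stepFilter(alive, "individuals_classes",
                      function(r) fcIndividualsAndClasses(r, cfg))

  scaffold <- stats::setNames(rep(NA_character_, length(alive)), alive)
  alnPass <- logical(length(alive))
  names(alnPass) <- alive
  for (id in alive) {
    res <- fcAlignment(hits[hits$qseqid == id, , drop = FALSE], cfg)
    alnPass[id] <- res$pass
    scaffold[id] <- res$scaffold
    if (!res$pass) reasons[id] <- res$reason
  }
  alive <- alive[alnPass[alive]]
  counts["alignment"] <- length(alive)

  keep <- fcScaffoldUnique(scaffold[alive])
  reasons[setdiff(alive, keep)] <- "shared_scaffold"
  alive <- keep
  counts["scaffold_unique"] <- length(alive)

  alive <- stepFilter(alive, "homopolymer", function(r) fcHomopolymer(r, cfg))

  out <- list(counts = counts, survivors = unname(alive),
              reasons = reasons[!is.na(reasons)],
              scaffold = scaffold[alive])
  class(out) <- "filterReport"
  out
}

#' @export
print.filterReport <- function(x, ...) {
  cat("SNP filter cascade:\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  %-20s %d\n", names(x$counts)[i], x$counts[i]))
  invisible(x)
}

#' Find variable columns in pre-aligned sequences
#'
#' Returns the columns (0-based) at which at least two distinct non-gap,
#' non-N characters occur, with the alleles observed there — the screen
#' used to pull SNPs out of aligned Sanger amplicon sequences.
#'
#' @param seqs Character vector (or DNAStringSet) of >= 2 equal-length
#'   aligned sequences.
#' @return data.frame with \code{pos} (0-based column) and \code{alleles}
#'   (comma-joined, alphabetical).
#' @export
findVariableSites <- function(seqs) {
  if (!is.character(seqs)) seqs <- as.character(seqs)
  if (length(seqs) < 2L)
    stop("need at least two sequences")
  seqs <- toupper(seqs)
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("sequences must be pre-aligned to equal length")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  keep <- c("A", "C", "G", "T")
  res <- lapply(seq_len(n), function(j) {
    al <- sort(unique(mat[, j][mat[, j] %in% keep]))
    if (length(al) >= 2L)
      data.frame(pos = j - 1L, alleles = paste(al, collapse = ","))
    else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) data.frame(pos = integer(), alleles = character())
  else res
}
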