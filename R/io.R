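#' @importFrom utils read.table write.table
NULL

#' Read a FASTA file
#'
#' Thin wrapper over \link[Biostrings]{readDNAStringSet}: gzip transparent,
#' sequences case-folded to upper, names truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A \link[Biostrings]{DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path)
  x <- readDNAStringSet(path)
  if (length(x) == 0L)
    stop("no FASTA records in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Write sequences as FASTA
#'
#' @param x A named \link[Biostrings]{DNAStringSet} or named character
#'   vector of sequences.
#' @param path Output path.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write digest fragments as BED3 + length
#'
#' Coordinates are serialized 0-based half-open (BED convention); a header
#' comment states this.
#'
#' @param fragments GRanges of fragments.
#' @param path Output path.
#' @export
writeFragmentsBed <- function(fragments, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(fragments)),
    start = GenomicRanges::start(fragments) - 1L,
    end = GenomicRanges::end(fragments),
    length = GenomicRanges::width(fragments))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED3+length; coordinates 0-based half-open", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- stack catalog ---------------------------------------------------------

#' Read a consensus-stack catalog (TSV)
#'
#' Dialect: columns \code{stack_id}, \code{consensus}, \code{snp_pos}
#' (comma list of 0-based positions), \code{alleles} (comma list of
#' \code{ref/alt}), then one column per individual holding per-SNP calls
#' (\code{aa|ab|bb|--}, comma separated across SNPs).
#'
#' @param path Path to the catalog TSV.
#' @return A list of stack records, each a list with \code{stack_id},
#'   \code{consensus}, \code{snps} (data.frame \code{pos}, \code{ref},
#'   \code{alt}) and \code{genotypes} (individuals x SNPs character
#'   matrix).
#' @export
readStackCatalog <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "#",
                   check.names = FALSE)
  fixed <- c("stack_id", "consensus", "snp_pos", "alleles")
  if (!all(fixed %in% colnames(df)))
    stop("catalog must have columns: ", paste(fixed, collapse = ", "))
  inds <- setdiff(colnames(df), fixed)
  records <- lapply(seq_len(nrow(df)), function(i) {
    pos <- if (nzchar(df$snp_pos[i]))
      as.integer(strsplit(df$snp_pos[i], ",", fixed = TRUE)[[1]])
    else integer()
    al <- if (nzchar(df$alleles[i]))
      strsplit(df$alleles[i], ",", fixed = TRUE)[[1]]
    else character()
    if (length(al) != length(pos))
      stop("stack ", df$stack_id[i], ": snp_pos/alleles length mismatch")
    refalt <- if (length(al)) do.call(rbind, strsplit(al, "/", fixed = TRUE))
              else matrix(character(), 0, 2)
    gt <- matrix("--", nrow = length(inds), ncol = length(pos),
                 dimnames = list(inds, NULL))
    for (ind in inds) {
      calls <- strsplit(df[[ind]][i], ",", fixed = TRUE)[[1]]
      if (length(pos) && length(calls) != length(pos))
        stop("stack ", df$stack_id[i], ", individual ", ind,
             ": expected ", length(pos), " calls")
      if (length(pos)) gt[ind, ] <- calls
    }
    stackRecord(df$stack_id[i], toupper(df$consensus[i]),
                pos = pos, ref = refalt[, 1], alt = refalt[, 2],
                genotypes = gt)
  })
  names(records) <- df$stack_id
  records
}

#' Write a consensus-stack catalog (TSV)
#'
#' Inverse of \code{\link{readStackCatalog}}.
#'
#' @param records List of stack records.
#' @param path Output path.
#' @export
writeStackCatalog <- function(records, path) {
  inds <- if (length(records)) rownames(records[[1]]$genotypes)
          else character()
  rows <- lapply(records, function(r) {
    base <- c(stack_id = r$stack_id, consensus = r$consensus,
              snp_pos = paste(r$snps$pos, collapse = ","),
              alleles = paste(paste(r$snps$ref, r$snps$alt, sep = "/"),
                              collapse = ","))
    calls <- vapply(inds, function(ind)
      paste(r$genotypes[ind, ], collapse = ","), character(1))
    c(base, calls)
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a stack record
#'
#' @param stack_id Stack identifier.
#' @param consensus Consensus sequence (nominally 100 nt).
#' @param pos Integer vector of 0-based SNP positions within the consensus.
#' @param ref,alt Single-nucleotide alleles per SNP.
#' @param genotypes Character matrix (individuals x SNPs) of calls in
#'   \code{aa}, \code{ab}, \code{bb}, \code{--}.
#' @return A stack-record list.
#' @export
stackRecord <- function(stack_id, consensus, pos, ref, alt, genotypes) {
  if (any(pos < 0L | pos >= nchar(consensus)))
    stop("SNP position outside consensus for stack ", stack_id)
  if (length(pos) && any(ref == alt))
    stop("ref and alt alleles must differ for stack ", stack_id)
  bad <- !(genotypes %in% c("aa", "ab", "bb", "--"))
  if (any(bad))
    stop("invalid genotype call(s) in stack ", stack_id, ": ",
         paste(unique(genotypes[bad]), collapse = ", "))
  list(stack_id = as.character(stack_id), consensus = consensus,
       snps = data.frame(pos = as.integer(pos), ref = as.character(ref),
                         alt = as.character(alt)),
       genotypes = genotypes)
}

# ---- alignment hits --------------------------------------------------------

#' Read blast-tabular-like alignment hits (TSV)
#'
#' Expects at least the columns \code{qseqid}, \code{sseqid},
#' \code{pident}, \code{length}, \code{mismatch}, \code{gapopen} (blast
#' outfmt-6 subset); extra columns are ignored, \code{#} comment lines are
#' skipped.
#'
#' @param path Path to the hits TSV.
#' @return data.frame of typed hits.
#' @export
readAlignmentHits <- function(path) {
  need <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen")
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^#", first) & nzchar(first)]
  if (length(first) == 0L)
    return(stats::setNames(
      data.frame(character(), character(), numeric(), integer(), integer(),
                 integer()), need))
  hasHeader <- grepl("qseqid", first[1], fixed = TRUE)
  df <- read.table(path, header = hasHeader, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE)
  if (!hasHeader) {
    if (ncol(df) < length(need))
      stop("expected at least ", length(need), " columns in ", path)
    colnames(df)[seq_along(need)] <- need
  }
  if (!all(need %in% colnames(df)))
    stop("hits file must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (!is.numeric(df$pident))
    stop("non-numeric pident in ", path)
  df$pident <- as.numeric(df$pident)
  for (k in c("length", "mismatch", "gapopen"))
    df[[k]] <- as.integer(df[[k]])
  df
}

#' Write alignment hits (TSV, blast outfmt-6 subset with header)
#'
#' @param hits data.frame as returned by \code{\link{readAlignmentHits}}.
#' @param path Output path.
#' @export
writeAlignmentHits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- genotype matrices -----------------------------------------------------

#' Read a genotype panel from TSV
#'
#' Genotype TSV: one row per individual with columns \code{id}, \code{sex},
#' \code{group} followed by one column per locus with calls
#' \code{AA|AB|BB|A|B|--}.  Locus-metadata TSV: columns \code{id},
#' \code{class}.
#'
#' @param genotypesPath Path to the genotype TSV.
#' @param lociPath Path to the locus-metadata TSV.
#' @return A \linkS4class{GenotypePanel}.
#' @export
readGenotypes <- function(genotypesPath, lociPath) {
  g <- read.table(genotypesPath, header = TRUE, sep = "\t",
                  colClasses = "character", comment.char = "#",
                  check.names = FALSE)
  meta <- read.table(lociPath, header = TRUE, sep = "\t",
                     colClasses = "character", comment.char = "#")
  if (!all(c("id", "sex", "group") %in% colnames(g)))
    stop("genotype TSV must start with columns id, sex, group")
  if (!all(c("id", "class") %in% colnames(meta)))
    stop("locus TSV must have columns id, class")
  loci <- setdiff(colnames(g), c("id", "sex", "group"))
  missingMeta <- setdiff(loci, meta$id)
  if (length(missingMeta))
    stop("loci missing from metadata: ", paste(missingMeta, collapse = ", "))
  calls <- t(as.matrix(g[loci]))
  colnames(calls) <- g$id
  badMat <- matrix(!(calls %in% .ALL_CALLS), nrow = nrow(calls))
  bad <- which(badMat, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid call '%s' at locus %s, individual %s",
                 calls[bad[1, 1], bad[1, 2]], rownames(calls)[bad[1, 1]],
                 colnames(calls)[bad[1, 2]]))
  sex <- g$sex
  unknown <- !(sex %in% c("M", "F"))
  if (any(unknown & sex != "unknown"))
    warning("unrecognized sex token(s) parsed as 'unknown': ",
            paste(unique(sex[unknown & sex != "unknown"]), collapse = ", "))
  sex[unknown] <- "unknown"
  cls <- stats::setNames(meta$class, meta$id)[rownames(calls)]
  genotypePanel(calls, locusClass = cls, sex = sex, group = g$group)
}

#' Write a genotype panel to TSV
#'
#' Writes the genotype TSV and the locus-metadata TSV read back by
#' \code{\link{readGenotypes}}.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param genotypesPath,lociPath Output paths.
#' @export
writeGenotypes <- function(panel, genotypesPath, lociPath) {
  calls <- genotypeCalls(panel)
  g <- data.frame(id = colnames(calls),
                  sex = individualSex(panel),
                  group = colData(panel)$group,
                  t(calls), check.names = FALSE)
  g$group[is.na(g$group)] <- "NA"
  write.table(g, genotypesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = rownames(calls), class = locusClass(panel)),
              lociPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(genotypesPath)
}

# ---- reports ---------------------------------------------------------------

#' Write an analysis report to JSON or TSV
#'
#' JSON output has stable key order and full numeric precision; TSV output
#' expects a data.frame and fixes float formatting so reruns diff clean.
#'
#' @param report A list (JSON) or data.frame (TSV).
#' @param path Output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @param digits Decimal places for TSV floats.
#' @export
writeReport <- function(report, path, format = c("json", "tsv"),
                        digits = 4) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stopifnot(is.data.frame(report))
    num <- vapply(report, is.double, logical(1))
    report[num] <- lapply(report[num], function(v)
      formatC(v, format = "f", digits = digits))
    write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a dyad report as a Table-3-shaped TSV
#'
#' Columns: \code{Ind_1}, \code{Ind_2}, \code{Sex}, \code{Hap},
#' \code{r_xy}, \code{2.5}, \code{97.5}, \code{P-O}.
#'
#' @param dyads data.frame from \code{\link{classifyDyads}}.
#' @param path Output path.
#' @export
writeDyadReport <- function(dyads, path) {
  out <- data.frame(
    Ind_1 = dyads$ind1, Ind_2 = dyads$ind2,
    Sex = paste(dyads$sex1, dyads$sex2, sep = "-"),
    Hap = dyads$hap,
    r_xy = formatC(dyads$r, format = "f", digits = 4),
    `2.5` = formatC(dyads$ciLow, format = "f", digits = 4),
    `97.5` = formatC(dyads$ciHigh, format = "f", digits = 4),
    `P-O` = dyads$poStatus, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
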