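test_that("simGenome plants exactly the recorded sites, deterministically", {
  g <- simGenome(1e5, 2500, seed = 5)
  hits <- Biostrings::matchPattern("AGATCT", g$genome[[1]])
  expect_equal(IRanges::start(hits) - 1L, g$truth$pos)
  # site-free genome: a scan finds nothing
  g0 <- simGenome(5e4, Inf, seed = 5)
  expect_equal(
    length(Biostrings::matchPattern("AGATCT", g0$genome[[1]])), 0)
  expect_equal(nrow(g0$truth), 0)
  # same seed, identical bytes; different seed differs
  g2 <- simGenome(1e5, 2500, seed = 5)
  expect_identical(as.character(g$genome), as.character(g2$genome))
  g3 <- simGenome(1e5, 2500, seed = 6)
  expect_false(identical(as.character(g$genome), as.character(g3$genome)))
})

test_that("pedigree panel obeys Mendelian, X, mtDNA and Y transmission", {
  ped <- basicPedigree(nFamilies = 30, nUnrelated = 4)
  pp <- simPedigreePanel(ped, seed = 77)
  calls <- genotypeCalls(pp$panel)
  autoIds <- lociIds(pp$panel)[locusClass(pp$panel) == "autosomal"]
  xIds <- lociIds(pp$panel)[locusClass(pp$panel) == "X"]
  alleles <- function(g) if (g == "--") character()
                         else unique(strsplit(g, "")[[1]])
  for (f in 1:30) {
    ch <- sprintf("fam%d_child", f)
    mo <- sprintf("fam%d_mother", f)
    fa <- sprintf("fam%d_father", f)
    # P-O dyads share an allele at every autosomal locus, by construction
    for (par in c(mo, fa)) {
      share <- vapply(autoIds, function(l)
        length(intersect(alleles(calls[l, ch]),
                         alleles(calls[l, par]))) > 0, logical(1))
      expect_true(all(share))
    }
    # sons are hemizygous with a maternal X allele; daughters carry the
    # paternal X allele
    sexCh <- individualSex(pp$panel)[ch]
    for (l in xIds) {
      if (sexCh == "M") {
        expect_true(calls[l, ch] %in% c("A", "B"))
        expect_true(calls[l, ch] %in% alleles(calls[l, mo]))
      } else {
        expect_true(calls[l, fa] %in% alleles(calls[l, ch]))
      }
    }
    # mtDNA maternal
    mt <- sprintf("Ua%02dmt", c(3, 4, 5, 7))
    expect_equal(calls[mt, ch], calls[mt, mo])
  }
  # Y presence tracks sex
  sex <- individualSex(pp$panel)
  expect_true(all(calls["y1", sex == "M"] == "A"))
  expect_true(all(calls["y1", sex == "F"] == "--"))
})

test_that("realized founder MAFs match their targets within 3 SE", {
  ped <- basicPedigree(nFamilies = 0, nUnrelated = 200)
  pp <- simPedigreePanel(ped, seed = 101)
  st <- panelStats(pp$panel)
  st <- st[st$class == "autosomal", ]
  target <- pp$truth$mafA[st$locus]
  se <- sqrt(target * (1 - target) / (2 * 200))
  expect_true(all(abs(st$maf - target) <= 3 * se |
                  abs((1 - st$maf) - target) <= 3 * se))
  # founders drawn under HWE: exact-test p-values not systematically small
  expect_gt(mean(st$hweP > 0.05), 0.9)
})

test_that("stack fixtures are seed-deterministic and label every record", {
  a <- simStackFixtures(nPerStratum = 4, seed = 3)
  b <- simStackFixtures(nPerStratum = 4, seed = 3)
  t1 <- tempfile(); t2 <- tempfile()
  writeStackCatalog(a$records, t1)
  writeStackCatalog(b$records, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_setequal(a$truth$stack_id,
                  vapply(a$records, `[[`, character(1), "stack_id"))
  expect_false(anyDuplicated(a$truth$stack_id) > 0)
})

test_that("FASTA round trip preserves ids and sequences", {
  g <- simGenome(2e4, 3000, nScaffolds = 3, seed = 12)
  fp <- tempfile(fileext = ".fa")
  writeFasta(g$genome, fp)
  back <- readFasta(fp)
  expect_equal(names(back), names(g$genome))
  expect_equal(as.character(back), as.character(g$genome))
  # gzip transparency
  gz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(fp), con)
  close(con)
  expect_equal(as.character(readFasta(gz)), as.character(g$genome))
  # empty file errors
  ef <- tempfile()
  writeLines(character(), ef)
  expect_error(readFasta(ef))
})

test_that("stack catalog and alignment hits round-trip losslessly", {
  sf <- simStackFixtures(nPerStratum = 3, seed = 8)
  cp <- tempfile(fileext = ".tsv")
  writeStackCatalog(sf$records, cp)
  back <- readStackCatalog(cp)
  expect_equal(names(back), names(sf$records))
  for (id in names(back)) {
    expect_equal(back[[id]]$consensus, sf$records[[id]]$consensus)
    expect_equal(back[[id]]$snps, sf$records[[id]]$snps)
    expect_equal(back[[id]]$genotypes, sf$records[[id]]$genotypes)
  }
  hp <- tempfile(fileext = ".tsv")
  writeAlignmentHits(sf$hits, hp)
  hback <- readAlignmentHits(hp)
  expect_equal(hback, sf$hits, ignore_attr = TRUE)
  # the filter pipeline gives identical results on the round-tripped data
  expect_identical(runFilterPipeline(back, hback)$survivors,
                   runFilterPipeline(sf$records, sf$hits)$survivors)
})

test_that("alignment-hit reader skips comments and validates pident", {
  hp <- tempfile()
  writeLines(c("# comment line",
               "stk1\tscafA\t100.000\t100\t0\t0",
               "stk2\tscafB\t98.000\t100\t2\t1"), hp)
  hits <- readAlignmentHits(hp)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$pident, c(100, 98))
  empty <- tempfile()
  writeLines("# only comments", empty)
  expect_equal(nrow(readAlignmentHits(empty)), 0)
})

test_that("genotype TSV round trip preserves the panel", {
  pp <- simPedigreePanel(basicPedigree(2, 4), seed = 15,
                         missingRate = 0.05)
  gp <- tempfile(); lp <- tempfile()
  writeGenotypes(pp$panel, gp, lp)
  back <- readGenotypes(gp, lp)
  expect_equal(genotypeCalls(back), genotypeCalls(pp$panel))
  expect_equal(unname(locusClass(back)), unname(locusClass(pp$panel)))
  expect_equal(unname(individualSex(back)), unname(individualSex(pp$panel)))
})

test_that("genotype reader rejects bad calls and odd sex tokens warn", {
  gp <- tempfile(); lp <- tempfile()
  writeLines(c("id\tsex\tgroup\tL1\tL2",
               "i1\tM\tg1\tAA\tA",
               "i2\tX?\tg1\tAB\tB"), gp)
  writeLines(c("id\tclass", "L1\tautosomal", "L2\tmtDNA"), lp)
  expect_warning(panel <- readGenotypes(gp, lp), "unknown|unrecognized")
  expect_equal(unname(individualSex(panel)["i2"]), "unknown")
  # AB at an mtDNA locus is structurally invalid
  writeLines(c("id\tsex\tgroup\tL1\tL2",
               "i1\tM\tg1\tAA\tAB"), gp)
  expect_error(readGenotypes(gp, lp))
  # unknown call token names the cell
  writeLines(c("id\tsex\tgroup\tL1\tL2",
               "i1\tM\tg1\tAC\tA"), gp)
  expect_error(readGenotypes(gp, lp), "L1")
})

test_that("reports serialize deterministically and dyad TSV has 8 columns", {
  sf <- simStackFixtures(nPerStratum = 2, seed = 2)
  repx <- runFilterPipeline(sf$records, sf$hits)
  j1 <- tempfile(); j2 <- tempfile()
  writeReport(unclass(repx), j1)
  writeReport(unclass(repx), j2)
  expect_identical(readLines(j1), readLines(j2))
  parsed <- jsonlite::read_json(j1, simplifyVector = TRUE)
  expect_equal(parsed$survivors, repx$survivors)

  dy <- data.frame(ind1 = "Ua98", ind2 = "Ua99", sex1 = "F", sex2 = "F",
                   hap = "NorthB", r = 0.62, ciLow = 0.51, ciHigh = 0.75,
                   poStatus = "Known", nExcludingLoci = 0L,
                   xExcluded = FALSE)
  dp <- tempfile()
  writeDyadReport(dy, dp)
  tab <- read.delim(dp, check.names = FALSE)
  expect_equal(colnames(tab),
               c("Ind_1", "Ind_2", "Sex", "Hap", "r_xy", "2.5", "97.5",
                 "P-O"))
  expect_equal(tab$Sex, "F-F")
})

test_that("genotype panel class enforces its call vocabulary", {
  calls <- matrix("AB", 1, 1, dimnames = list("m1", "i1"))
  expect_error(genotypePanel(calls, "mtDNA", "F"), "haploid")
  calls2 <- matrix("ZZ", 1, 1, dimnames = list("L1", "i1"))
  expect_error(genotypePanel(calls2, "autosomal", "F"), "invalid call")
  expect_error(genotypePanel(matrix("AA", 1, 1,
                                    dimnames = list("L1", "i1")),
                             "autosomal", "girl"), "sex")
})
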