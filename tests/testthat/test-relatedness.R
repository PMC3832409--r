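test_that("lrLocusComponents reproduces hand-evaluated cases", {
  got <- lrLocusComponents("AB", "AA", 0.6)
  expect_equal(unname(got["N"]), -0.16)
  expect_equal(unname(got["D"]), 0.04)
  # heterozygous reference at p = 0.5: singular locus (D = 0)
  het <- lrLocusComponents("AB", "AB", 0.5)
  expect_equal(unname(het["D"]), 0)
  # E[N] = 0 for unrelated pairs under HWE
  set.seed(53)
  pA <- 0.6
  n <- 1e5
  code <- c("BB", "AB", "AA")
  x <- code[rbinom(n, 2, pA) + 1]
  y <- code[rbinom(n, 2, pA) + 1]
  comp <- RRLpanel:::.lrComponentsVec(x, y, rep(pA, n))
  expect_lt(abs(mean(comp$N)), 3 * sd(comp$N) / sqrt(n))
})

test_that("lynchRitlandR is symmetric and near 1 for self-comparison", {
  pp <- simPedigreePanel(basicPedigree(nFamilies = 4, nUnrelated = 10),
                         seed = 31)
  ids <- individualIds(pp$panel)
  for (k in 1:5) {
    i <- ids[k]; j <- ids[k + 5]
    expect_identical(lynchRitlandR(pp$panel, i, j, pp$freqs),
                     lynchRitlandR(pp$panel, j, i, pp$freqs))
  }
  expect_lt(abs(lynchRitlandR(pp$panel, ids[1], ids[1], pp$freqs) - 1),
            0.1)
})

test_that("mean r recovers 0.5 / 0.25 / 0 across relationship classes", {
  ped <- basicPedigree(nFamilies = 120, nUnrelated = 0)
  # extend: half-sib = two children sharing only the father
  hs <- do.call(rbind, lapply(1:60, function(f) data.frame(
    id = sprintf("hs%d_c%d", f, 1:2),
    sex = c("M", "F"),
    mother = sprintf("fam%d_mother", c(2 * f - 1, 2 * f)),
    father = sprintf("fam%d_father", 2 * f - 1))))
  pp <- simPedigreePanel(rbind(ped, hs), seed = 61)
  rOf <- function(i, j) lynchRitlandR(pp$panel, i, j, pp$freqs)
  rPO <- vapply(1:120, function(f)
    rOf(sprintf("fam%d_mother", f), sprintf("fam%d_child", f)), numeric(1))
  rFS <- vapply(1:60, function(f)
    rOf(sprintf("fam%d_child", 2 * f - 1), sprintf("hs%d_c1", f)),
    numeric(1))  # share both parents: full sibs
  rHS <- vapply(1:60, function(f)
    rOf(sprintf("hs%d_c1", f), sprintf("hs%d_c2", f)), numeric(1))
  rUN <- vapply(1:119, function(f)
    rOf(sprintf("fam%d_child", f), sprintf("fam%d_mother", f + 1)),
    numeric(1))
  expect_lt(abs(mean(rPO) - 0.5), 0.05)
  expect_lt(abs(mean(rFS) - 0.5), 0.07)
  expect_lt(abs(mean(rHS) - 0.25), 0.07)   # share the father only
  expect_lt(abs(mean(rUN) - 0), 0.05)
})

test_that("bootstrapCI is seeded, degenerate on one locus, and ordered", {
  pp <- simPedigreePanel(basicPedigree(nFamilies = 2, nUnrelated = 4),
                         seed = 3)
  a <- bootstrapCI(pp$panel, "fam1_father", "fam1_child", pp$freqs,
                   reps = 300, seed = 7)
  b <- bootstrapCI(pp$panel, "fam1_father", "fam1_child", pp$freqs,
                   reps = 300, seed = 7)
  expect_identical(a, b)
  expect_lte(a["ciLow"], a["ciHigh"])
  r <- lynchRitlandR(pp$panel, "fam1_father", "fam1_child", pp$freqs)
  expect_lte(a[["ciLow"]], r)
  expect_gte(a[["ciHigh"]], r)
  # duplicated single locus: zero-width interval
  calls <- genotypeCalls(pp$panel)
  one <- calls[rep("auto001", 87), , drop = FALSE]
  rownames(one) <- sprintf("d%02d", 1:87)
  dup <- genotypePanel(one, rep("autosomal", 87),
                       sex = individualSex(pp$panel))
  fr <- stats::setNames(rep(pp$freqs[["auto001"]], 87), rownames(one))
  ci <- bootstrapCI(dup, "fam1_father", "fam1_child", fr, reps = 100,
                    seed = 1)
  expect_equal(ci[["ciLow"]], ci[["ciHigh"]])
})

test_that("candidateFirstOrder screens on the r threshold", {
  pp <- simPedigreePanel(basicPedigree(nFamilies = 2, nUnrelated = 10),
                         seed = 13)
  cand <- candidateFirstOrder(pp$panel, pp$freqs, threshold = 0.40,
                              mtMarkers = sprintf("Ua%02dmt", c(3, 4, 5, 7)))
  # duplicate-genotype "twins": r near 1, always included
  calls <- genotypeCalls(pp$panel)
  calls <- cbind(calls, twin = calls[, "unrel1"])
  twin <- genotypePanel(calls, locusClass(pp$panel),
                        sex = c(individualSex(pp$panel), "M"))
  cand2 <- candidateFirstOrder(twin, pp$freqs, threshold = 0.40)
  expect_true(any((cand2$ind1 == "unrel1" & cand2$ind2 == "twin") |
                  (cand2$ind1 == "twin" & cand2$ind2 == "unrel1")))
  expect_equal(nrow(candidateFirstOrder(pp$panel, pp$freqs,
                                        threshold = 1.1)), 0)
  # annotations: dyads carry sexes and shared mt haplotype labels
  if (nrow(cand) > 0)
    expect_true(all(cand$sex1 %in% c("M", "F")))
})

test_that("autosomal exclusion triggers only on opposite homozygotes", {
  calls <- rbind(L1 = c("AA", "BB"), L2 = c("AA", "AB"),
                 L3 = c("--", "BB"))
  colnames(calls) <- c("x", "y")
  pnl <- tinyPanel(calls)
  ex <- poExclusionAutosomal(pnl, "x", "y")
  expect_equal(ex$status, "Excluded")
  expect_equal(ex$excludingLoci, "L1")   # missing never excludes (L3)
  calls2 <- rbind(L1 = c("AA", "AB"), L2 = c("AA", "AB"))
  colnames(calls2) <- c("x", "y")
  expect_equal(poExclusionAutosomal(tinyPanel(calls2), "x", "y")$status,
               "Possible")
})

test_that("X-inheritance exclusion follows transmission rules", {
  mkx <- function(g1, g2, s1, s2) {
    calls <- matrix(c(g1, g2), 1, 2,
                    dimnames = list("x1", c("p", "c")))
    genotypePanel(calls, "X", sex = c(s1, s2))
  }
  # putative mother AA, son B: both orientations violated
  expect_equal(poExclusionX(mkx("AA", "B", "F", "M"), "p", "c")$status,
               "Excluded")
  # father A, daughter BB: both orientations violated
  expect_equal(poExclusionX(mkx("A", "BB", "M", "F"), "p", "c")$status,
               "Excluded")
  # father-son: never excluded through X
  expect_equal(poExclusionX(mkx("A", "B", "M", "M"), "p", "c")$status,
               "Possible")
  # mother AB can mother any child
  expect_equal(poExclusionX(mkx("AB", "B", "F", "M"), "p", "c")$status,
               "Possible")
  # mother-daughter sharing no allele: excluded
  expect_equal(poExclusionX(mkx("AA", "BB", "F", "F"), "p", "c")$status,
               "Excluded")
  # missing calls never exclude
  expect_equal(poExclusionX(mkx("--", "B", "F", "M"), "p", "c")$status,
               "Possible")
  expect_error(poExclusionX(mkx("AB", "B", "M", "M"), "p", "c"),
               "heterozygous X")
})

test_that("classifyDyads labels known dyads and never excludes true P-O", {
  pp <- simPedigreePanel(basicPedigree(nFamilies = 2, nUnrelated = 8),
                         seed = 47)
  known <- data.frame(ind1 = c("fam1_father", "fam2_father"),
                      ind2 = c("fam1_child", "fam2_child"))
  rep <- classifyDyads(pp$panel, pp$freqs, knownPO = known,
                       mtMarkers = sprintf("Ua%02dmt", c(3, 4, 5, 7)),
                       reps = 200, seed = 5)
  truePo <- pp$truth$dyads[pp$truth$dyads$class == "P-O", ]
  for (k in seq_len(nrow(rep))) {
    isPo <- any((truePo$ind1 == rep$ind1[k] & truePo$ind2 == rep$ind2[k]) |
                (truePo$ind1 == rep$ind2[k] & truePo$ind2 == rep$ind1[k]))
    if (isPo) expect_true(rep$poStatus[k] %in% c("Known", "Possible"))
  }
  # empty knownPO: no Known labels
  rep2 <- classifyDyads(pp$panel, pp$freqs, reps = 100, seed = 5)
  expect_false(any(rep2$poStatus == "Known"))
})

test_that("exclusion power grows with the number of loci", {
  ped <- basicPedigree(nFamilies = 0, nUnrelated = 80)
  pp <- simPedigreePanel(ped, seed = 71)
  excl <- function(nLoci) {
    loci <- lociIds(pp$panel)[locusClass(pp$panel) == "autosomal"][1:nLoci]
    mean(vapply(1:40, function(k)
      poExclusionAutosomal(pp$panel, sprintf("unrel%d", 2 * k - 1),
                           sprintf("unrel%d", 2 * k),
                           loci = loci)$status == "Excluded", logical(1)))
  }
  p10 <- excl(10); p40 <- excl(40); p87 <- excl(87)
  expect_lte(p10, p40)
  expect_lte(p40, p87)
})
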