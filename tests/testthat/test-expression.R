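flat22 <- matrix(22, 2, 3)   # equal FPKM in every genotype x time cell

test_that("expression tables round-trip through TSV and are validated", {
  tmp <- tempfile("expr")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  x <- makeTinyExpression(list(
    g1 = rbind(c(10, 12, 14), c(25, 12, 14)),
    g2 = flat22))
  p1 <- writeExpression(x, file.path(tmp, "a.tsv"))
  y <- loadExpression(p1)
  expect_equal(assay(y, "fpkm"), assay(x, "fpkm"))
  p2 <- writeExpression(y, file.path(tmp, "b.tsv"))
  expect_identical(readLines(p1), readLines(p2))

  # malformed header
  writeLines(c("locus_id\tancestor_18h_r1\tweird", "g1\t1\t2"),
             file.path(tmp, "bad.tsv"))
  expect_error(loadExpression(file.path(tmp, "bad.tsv")), "weird")
  # negative value names the locus and row
  d <- utils::read.delim(p1, check.names = FALSE)
  d[2, 3] <- -1
  utils::write.table(d, file.path(tmp, "neg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(loadExpression(file.path(tmp, "neg.tsv")), "g2.*row 2")
  # duplicate loci
  d <- utils::read.delim(p1, check.names = FALSE)
  d$locus_id <- c("g1", "g1")
  utils::write.table(d, file.path(tmp, "dup.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(loadExpression(file.path(tmp, "dup.tsv")), "duplicate")
})

test_that("GO maps round-trip and synthetic matrices reload intact", {
  tmp <- tempfile("gomap")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  gm <- makeGOUniverse(5, 4, multiMembershipProb = 0.3, seed = 2)
  path <- writeGOMap(gm, file.path(tmp, "map.tsv"))
  gm2 <- loadGOMap(path)
  expect_equal(goMemberships(gm2), goMemberships(gm))

  sim <- simulateExpression(gm, nBackgroundLoci = 30, seed = 4)
  ep <- writeExpression(sim$expression, file.path(tmp, "expr.tsv"))
  back <- loadExpression(ep)
  expect_equal(nrow(back), nrow(sim$expression))
  expect_equal(sort(rownames(back)), sort(rownames(sim$expression)))
})

test_that("fold-change filter flags loci past two-fold at any timepoint", {
  # identical genotypes: nothing passes
  x <- makeTinyExpression(list(g1 = flat22, g2 = rbind(c(1, 2, 3), c(1, 2, 3))))
  expect_length(foldChangeLoci(x), 0)
  # 10 vs 25 at one timepoint only: |log2(25.1/10.1)| ~ 1.31 > 1
  x <- makeTinyExpression(list(
    up = rbind(c(10, 12, 14), c(25, 12, 14)),
    same = flat22))
  expect_equal(foldChangeLoci(x), "up")
  expect_equal(abs(log2((25 + 0.1) / (10 + 0.1))) > 1, TRUE)
  # a stricter threshold excludes it again
  expect_length(foldChangeLoci(x, thresholdLog2 = 2), 0)
  # planted four-fold loci are always recovered at zero noise
  gm <- makeGOUniverse(3, 5, seed = 6)
  truth <- plantedTruth(
    foldChangeMultipliers = stats::setNames(rep(4, 10), sprintf("B%05d", 1:10)),
    noiseSd = 0)
  sim <- simulateExpression(gm, truth, nBackgroundLoci = 40, seed = 6)
  hits <- foldChangeLoci(sim$expression)
  expect_true(all(sprintf("B%05d", 1:10) %in% hits))
  expect_length(setdiff(hits, sprintf("B%05d", 1:10)), 0)
})

test_that("normalization produces per-locus shares that sum to one", {
  x <- makeTinyExpression(list(
    flat = flat22,
    zero = matrix(0, 2, 3),
    mixed = rbind(c(5, 50, 500), c(1, 10, 100))))
  norm <- normalizeExpression(x)
  s <- assay(norm, "share")
  expect_equal(unname(s["flat", ]), rep(1 / 6, 6))
  expect_equal(unname(s["zero", ]), rep(0, 6))
  expect_true(rowData(norm)$all_zero[rownames(norm) == "zero"])
  expect_lt(abs(sum(s["mixed", ]) - 1), 1e-12)
  # the exact transform order: log(x + 1) then the per-locus share
  v <- log(c(5, 50, 500, 1, 10, 100) + 1)
  expect_equal(sort(unname(s["mixed", ])), sort(v / sum(v)))
  # share sums hold over random matrices
  set.seed(31)
  gm <- makeGOUniverse(4, 10, seed = 31)
  sim <- simulateExpression(gm, nBackgroundLoci = 50, seed = 32)
  sAll <- assay(normalizeExpression(sim$expression), "share")
  expect_true(all(abs(rowSums(sAll) - 1) < 1e-12))
})

test_that("the global cell-mean ANOVA has the 4G-1 / 2G df structure", {
  for (G in c(2, 5, 28)) {
    gm <- makeGOUniverse(G, 6, seed = 40 + G)
    sim <- simulateExpression(gm, plantedTruth(noiseSd = 0.01),
                              nBackgroundLoci = 0, seed = 50 + G)
    fit <- globalFit(normalizeExpression(sim$expression), gm)
    expect_equal(modelDf(fit), 4L * G - 1L)
    expect_equal(residualDf(fit), 2L * G)
    expect_lte(adjRsquared(fit), 1)
  }
})

test_that("a flat cell-mean table yields F = 0 and no spurious fit", {
  x <- makeTinyExpression(list(a = flat22, b = flat22, c = flat22,
                               d = flat22))
  gm <- goMap(data.frame(locus_id = c("a", "b", "c", "d"),
                         go_term = c("T1", "T1", "T2", "T2")))
  fit <- globalFit(normalizeExpression(x), gm)
  expect_equal(fStatistic(fit), 0)
  expect_lte(adjRsquared(fit), 0)
})

test_that("terms without loci are dropped with a warning, tiny terms untested", {
  x <- makeTinyExpression(list(a = flat22, b = flat22, c = flat22))
  gm <- goMap(data.frame(locus_id = c("a", "b", "c"),
                         go_term = c("T1", "T1", "T2")),
              terms = c("T1", "T2", "T3"))
  expect_warning(globalFit(normalizeExpression(x), gm), "T3")
  st <- goGroupTests(normalizeExpression(x), gm)
  expect_true(is.na(st$p[st$term == "T2"]))   # single locus: untested
  expect_true(is.na(st$p[st$term == "T3"]))
})

test_that("planted directional effects are recovered with the right sign", {
  gm <- makeGOUniverse(6, 20, seed = 60)
  truth <- plantedTruth(
    directionalEffects = c(GO01 = 0.02, GO02 = 0.02, GO03 = -0.02),
    noiseSd = 0.005)
  sim <- simulateExpression(gm, truth, nBackgroundLoci = 0, seed = 61)
  st <- goGroupTests(normalizeExpression(sim$expression), gm)
  expect_true(all(st$directional[st$term %in% c("GO01", "GO02", "GO03")]))
  expect_equal(st$direction[st$term == "GO01"], 1)
  expect_equal(st$direction[st$term == "GO03"], -1)
  # loci with identical shares across genotypes are never flagged
  x <- makeTinyExpression(list(a = rbind(c(1, 5, 9), c(1, 5, 9)),
                               b = rbind(c(2, 4, 8), c(2, 4, 8)),
                               c2 = flat22, d = flat22))
  gmFlat <- goMap(data.frame(locus_id = c("a", "b", "c2", "d"),
                             go_term = c("T1", "T1", "T2", "T2")))
  stFlat <- goGroupTests(normalizeExpression(x), gmFlat)
  expect_true(all(!stFlat$directional, na.rm = TRUE))
})

test_that("temporal tests flag divergence and sign its slope", {
  gm <- makeGOUniverse(6, 20, seed = 70)
  truth <- plantedTruth(
    temporalSlopes = c(GO01 = 0.006, GO02 = -0.006),
    noiseSd = 0.003)
  sim <- simulateExpression(gm, truth, nBackgroundLoci = 0, seed = 71)
  st <- temporalTests(normalizeExpression(sim$expression), gm)
  expect_true(st$temporal[st$term == "GO01"])
  expect_true(st$temporal[st$term == "GO02"])
  expect_equal(st$slope_sign[st$term == "GO01"], 1)
  expect_equal(st$slope_sign[st$term == "GO02"], -1)
  # a genotype effect constant in time is directional, not temporal
  truth2 <- plantedTruth(directionalEffects = c(GO03 = 0.02),
                         noiseSd = 0.003)
  sim2 <- simulateExpression(gm, truth2, nBackgroundLoci = 0, seed = 72)
  st2 <- temporalTests(normalizeExpression(sim2$expression), gm)
  expect_false(st2$temporal[st2$term == "GO03"])
  expect_true(st2$directional[st2$term == "GO03"])
})

test_that("deviation profiles center to zero and track planted shapes", {
  x <- makeTinyExpression(list(a = flat22, b = flat22))
  gm0 <- goMap(data.frame(locus_id = c("a", "b"), go_term = c("T1", "T1")))
  prof0 <- deviationProfile(normalizeExpression(x), gm0)
  expect_true(all(prof0$deviation == 0))

  gm <- makeGOUniverse(4, 15, seed = 80)
  truth <- plantedTruth(temporalSlopes = c(GO01 = 0.008), noiseSd = 0.002)
  sim <- simulateExpression(gm, truth, nBackgroundLoci = 0, seed = 81)
  prof <- deviationProfile(normalizeExpression(sim$expression), gm)
  sums <- tapply(prof$deviation, prof$term, sum)
  expect_true(all(abs(sums) < 1e-12))
  # late-up planted term: derived deviations increase from 18 to 24 h
  d <- prof[prof$term == "GO01" & prof$genotype == "derived", ]
  d <- d[order(d$time), ]
  expect_true(all(diff(d$deviation) > 0))
})

test_that("pipeline outputs are byte-identical across repeated runs", {
  tmp <- tempfile("determinism")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  run <- function(dir) {
    gm <- makeGOUniverse(4, 6, seed = 90)
    sim <- simulateExpression(gm, nBackgroundLoci = 10, seed = 91)
    st <- goGroupTests(normalizeExpression(sim$expression), gm)
    writeGroupStats(st, file.path(dir, "stats.csv"))
    readLines(file.path(dir, "stats.csv"))
  }
  a <- run(tmp)
  b <- run(tmp)
  expect_identical(a, b)
})
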