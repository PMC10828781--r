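test_that("trivial crosses segregate as Punnett dictates", {
  set.seed(1)
  pop <- simulateCross(list(m = c("0", "0")), list(m = c("0", "0")),
                       n = 20)
  expect_true(all(genotypeStrings(pop, "m") == "0/0"))
  expect_equal(length(pop), 20L)
  # dominant-presence model: R1R2 x R2R2 -> half carriers
  pop2 <- simulateCross(list(te = c("R1", "R2")),
                        list(te = c("R2", "R2")), n = 4000)
  d <- alleleDosage(pop2, setNames("R1", "te"))[, "te"]
  expect_true(all(d %in% 0:1))
  expect_lt(abs(mean(d) - 0.5), 0.05)
})

test_that("unknown or malformed parental markers are rejected by name", {
  expect_error(simulateCross(list(a = c("1", "2"), b = c("1", "2")),
                             list(a = c("1", "2")), n = 5), "b")
  expect_error(simulateCross(list(a = c("1", "2")),
                             list(a = c("1", "2"), zz = c("1", "2")),
                             n = 5), "zz")
  expect_error(simulateCross(list(a = "1"), list(a = c("1", "2")),
                             n = 5), "two alleles")
})

test_that("recombinant fraction matches the Haldane closed form", {
  expect_equal(haldane(0.1), (1 - exp(-0.2)) / 2)
  mk <- data.frame(name = c("L1", "L2"), chrom = "chr1",
                   pos = c(1, 1e7))                 # 10 cM at 1 cM/Mb
  set.seed(99)
  pop <- simulateCross(list(L1 = c("A", "a"), L2 = c("B", "b")),
                       list(L1 = c("a", "a"), L2 = c("b", "b")),
                       n = 10000, markers = mk, recombRate = 1)
  g <- pop@gamete1
  recomb <- mean((g[, "L1"] == "A") != (g[, "L2"] == "B"))
  expect_lt(abs(recomb - 0.0906), 0.01)
})

test_that("single-locus genotype frequencies converge to 1:2:1", {
  set.seed(12)
  ok <- 0L
  for (i in 1:100) {
    pop <- simulateCross(list(m = c("0", "9")), list(m = c("0", "9")),
                         n = 200)
    counts <- table(factor(genotypeStrings(pop, "m"),
                           c("0/0", "0/9", "9/9")))
    r <- chiSquareGof(as.numeric(counts), "1:2:1")
    if (!r@reject) ok <- ok + 1L
  }
  expect_gte(ok, 90L)
})

test_that("phenotype assignment follows the dominant TE / FDP-shift model", {
  set.seed(13)
  pop <- simulateCross(
    list(bloodTE = c("R1", "R2"), ins9 = c("0", "9")),
    list(bloodTE = c("R2", "R2"), ins9 = c("0", "9")), n = 400)
  pop <- assignPhenotypes(pop, ins9Marker = "ins9", teEffect = 1L)
  ph <- phenotypes(pop)
  carrier <- alleleDosage(pop, setNames("R1", "bloodTE"))[, 1] >= 1
  expect_equal(ph$flesh, ifelse(carrier, "blood", "none"))
  gt <- genotypeStrings(pop, "ins9")
  # non-carriers follow the genotype map exactly
  expect_equal(ph$fdp_class[!carrier], genotypeExpectedFdp(gt[!carrier]))
  # carriers are advanced one class, floored at the earliest
  base <- match(genotypeExpectedFdp(gt[carrier]), fdpClassLevels())
  expect_equal(ph$fdp_class[carrier],
               fdpClassLevels()[pmax(base - 1L, 1L)])
  # spot values from the model definition
  i <- which(carrier & gt == "0/9")[1]
  expect_equal(ph$fdp_class[i], "60-90")
  j <- which(!carrier & gt == "0/0")[1]
  expect_equal(ph$fdp_class[j], "120-150")
  expect_error(assignPhenotypes(pop, teMarker = "nope"), "nope")
})

test_that("bulk construction samples within phenotype classes", {
  set.seed(14)
  pop <- simulateCross(list(bloodTE = c("R1", "R2")),
                       list(bloodTE = c("R2", "R2")), n = 60)
  pop <- assignPhenotypes(pop)
  b <- buildBulks(pop, bulkSize = 15)
  expect_equal(length(b$mut), 15L)
  expect_equal(length(b$wt), 15L)
  ph <- phenotypes(pop)$flesh
  expect_true(all(ph[b$mut] == "blood"))
  expect_true(all(ph[b$wt] == "none"))
  # expected carrier-allele frequency: 0.5 in mut bulk, 0 in wt bulk
  expect_equal(unname(bulkAlleleFrequencies(pop, b$mut, "R1")), 0.5)
  expect_equal(unname(bulkAlleleFrequencies(pop, b$wt, "R1")), 0)
  expect_error(buildBulks(pop, bulkSize = 50), "not enough")
})

test_that("allele-depth sampling is unbiased and guards its inputs", {
  mk <- data.frame(chrom = "chr1", pos = c(1e3, 2e3, 3e3))
  expect_error(sampleAlleleDepths(c(0.5, 0.2, 0), c(0, 0, 0), mk,
                                  depth = 0), "depth")
  set.seed(15)
  p <- c(0.5, 0.2, 0)
  reps <- replicate(300, {
    s <- sampleAlleleDepths(p, rep(0, 3), mk, depth = 30)
    alt <- as.matrix(s[, c("A_mut", "C_mut", "G_mut", "T_mut")])
    rowSums(alt * (col(alt) == match(s$alt, c("A", "C", "G", "T")))) /
      pmax(rowSums(alt), 1)
  })
  m <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(m - p) <= pmax(3 * se, 1e-12)))
  # configurable fraction of sites fails each clause
  set.seed(16)
  mk2 <- data.frame(chrom = "chr1", pos = seq_len(2000))
  s <- sampleAlleleDepths(runif(2000, 0, 0.5), rep(0, 2000), mk2,
                          depth = 30,
                          qualityFailRates = list(qd = 0.2))
  frac <- mean(filterSnps(s)$rejected$reason == "QD") *
    nrow(filterSnps(s)$rejected) / 2000
  expect_lt(abs(frac - 0.2), 0.05)
})

test_that("the full experiment is byte-identical under a fixed seed", {
  cfg <- simConfig(seed = 123, nChrom = 1L, chromLen = 5e5,
                   causalChrom = "chr1", causalPos = 2.5e5,
                   snpSpacing = 1e4)
  a <- simulateBsaExperiment(cfg)
  b <- simulateBsaExperiment(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$bulks, b$bulks)
  expect_identical(a$population@gamete1, b$population@gamete1)
  c <- simulateBsaExperiment(simConfig(seed = 124, nChrom = 1L,
                                       chromLen = 5e5,
                                       causalChrom = "chr1",
                                       causalPos = 2.5e5,
                                       snpSpacing = 1e4))
  expect_false(identical(a$sites, c$sites))
})

test_that("expected ED at the causal SNP matches the design value", {
  # R1R2 x R2R2 design: mut-pool alt frequency 0.5, wt-pool 0,
  # so E[ED] ~ sqrt(0.5^2 + 0.5^2) at the causal site
  eds <- vapply(1:200, function(seed) {
    set.seed(seed)
    pop <- simulateCross(list(te = c("1", "2")),
                         list(te = c("2", "2")), n = 60)
    pop <- assignPhenotypes(pop, teMarker = "te", teAllele = "1")
    b <- buildBulks(pop, 15)
    fm <- bulkAlleleFrequencies(pop, b$mut, "1")
    fw <- bulkAlleleFrequencies(pop, b$wt, "1")
    s <- sampleAlleleDepths(fm, fw,
                            data.frame(chrom = "chr1", pos = 1),
                            depth = 30)
    edStatistic(s)$ed
  }, 0)
  expect_lt(abs(mean(eds) - sqrt(0.5)), 0.05)
})

test_that("simConfig validity catches inconsistent parameters", {
  expect_error(simConfig(depth = 0), "depth")
  expect_error(simConfig(causalPos = 4e7), "causalPos")
  expect_error(simConfig(nOffspring = 20, bulkSize = 15),
               "nOffspring")
})
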