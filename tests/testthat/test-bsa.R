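test_that("quality filter is a pure keep/reject partition with reasons", {
  s <- makeSites("chr1", 1:7,
                 matrix(10, 7, 4), matrix(10, 7, 4))
  s$qd <- c(1.5, 10, 30, 30, 30, 30, 30)
  s$fs <- c(5, 5, 70, 5, 5, 5, 5)
  s$mq <- c(50, 50, 50, 30, 50, 50, 50)
  s$mq_rank_sum <- c(0, 0, 0, 0, -13, 0, 0)
  s$read_pos_rank_sum <- c(0, 0, 0, 0, 0, -9, 0)
  s$dp <- c(30, 30, 30, 30, 30, 30, 3)
  fl <- filterSnps(s)
  expect_equal(nrow(fl$kept) + nrow(fl$rejected), nrow(s))
  expect_equal(intersect(fl$kept$pos, fl$rejected$pos), integer(0))
  expect_equal(fl$kept$pos, 2L)
  expect_equal(fl$rejected$reason[fl$rejected$pos == 1], "QD")
  expect_equal(fl$rejected$reason[fl$rejected$pos == 3], "FS")
  expect_equal(fl$rejected$reason[fl$rejected$pos == 4], "MQ")
  expect_equal(fl$rejected$reason[fl$rejected$pos == 5], "MQRankSum")
  expect_equal(fl$rejected$reason[fl$rejected$pos == 6],
               "ReadPosRankSum")
  expect_equal(fl$rejected$reason[fl$rejected$pos == 7], "DP")
  # missing annotations pass unless strict
  s2 <- s[2, ]; s2$qd <- NA
  expect_equal(nrow(filterSnps(s2)$kept), 1L)
  expect_equal(nrow(filterSnps(s2, strict = TRUE)$kept), 0L)
})

test_that("pool frequencies normalise counts and flag empty pools", {
  s <- makeSites("chr1", 1, matrix(c(30, 0, 0, 0), 1),
                 matrix(c(15, 0, 15, 0), 1))
  f <- poolFrequencies(s)
  expect_equal(unname(f$mut), c(1, 0, 0, 0))
  expect_equal(unname(f$wt), c(0.5, 0, 0.5, 0))
  expect_true(f$usable)
  s2 <- makeSites("chr1", 1, matrix(c(20, 5, 5, 0), 1),
                  matrix(0, 1, 4))
  f2 <- poolFrequencies(s2)
  expect_equal(round(unname(f2$mut), 4), c(0.6667, 0.1667, 0.1667, 0))
  expect_false(f2$usable)
  expect_true(all(is.na(f2$wt)))
})

test_that("ED has its closed-form values, bounds and symmetry", {
  expect_equal(euclideanDistance(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(euclideanDistance(c(1, 0, 0, 0), c(0, 0, 1, 0)),
               sqrt(2))
  expect_equal(euclideanDistance(c(0.75, 0, 0.25, 0),
                                 c(0.25, 0, 0.75, 0)),
               sqrt(0.5))
  set.seed(2)
  for (i in 1:50) {
    a <- rmultinom(1, 60, runif(4))[, 1] / 60
    b <- rmultinom(1, 60, runif(4))[, 1] / 60
    ed <- euclideanDistance(a, b)
    expect_gte(ed, 0); expect_lte(ed, sqrt(2))
    expect_equal(ed, euclideanDistance(b, a))
    expect_equal(ed == 0, all(a == b))
  }
  expect_error(euclideanDistance(c(0.5, 0.5, 0.5, 0.5),
                                 c(1, 0, 0, 0)), "sum to 1")
  expect_error(euclideanDistance(c(1, 0), c(1, 0)), "length 4")
})

test_that("vectorised ED matches the scalar definition and drops empty pools", {
  set.seed(3)
  s <- randomSites(40, 1e5)
  s[3, c("A_wt", "C_wt", "G_wt", "T_wt")] <- 0
  e <- edStatistic(s)
  expect_true(is.na(e$ed[3]))
  for (i in c(1, 2, 10, 40)) {
    f <- poolFrequencies(s[i, ])
    expect_equal(e$ed[i], euclideanDistance(f$mut, f$wt))
  }
})

test_that("power transform is monotone and preserves the argmax", {
  expect_equal(transformEd(1, 5), 1)
  expect_equal(transformEd(0, 5), 0)
  expect_equal(transformEd(sqrt(2), 5), 2^2.5)
  set.seed(4)
  ed <- runif(100, 0, sqrt(2))
  expect_equal(order(ed), order(transformEd(ed, 5)))
  expect_equal(which.max(ed), which.max(transformEd(ed, 5)))
  expect_error(transformEd(ed, 0.5))
})

test_that("window enumeration follows the start-anchored truncated scheme", {
  s <- makeSites("chr1", 50000, matrix(c(30, 0, 0, 0), 1),
                 matrix(c(0, 0, 30, 0), 1))
  s$stat <- 1.7
  w <- windowScan(s, c(chr1 = 250000), window = 1e5, step = 1e4,
                  statCol = "stat")
  expect_equal(length(w), 25L)
  expect_equal(GenomicRanges::start(w),
               as.integer(seq(1, 240001, by = 1e4)))
  expect_equal(max(GenomicRanges::end(w)), 250000L)
  w2 <- windowScan(s, c(chr1 = 1e5), window = 1e5, step = 1e4,
                   statCol = "stat")
  expect_equal(length(w2), 10L)
  expect_equal(GenomicRanges::width(w2)[1], 1e5)
  expect_true(all(GenomicRanges::end(w2) == 1e5))
  # every window covering the single site carries its stat (mean agg)
  covering <- GenomicRanges::start(w) <= 50000 &
    GenomicRanges::end(w) >= 50000
  expect_true(all(w$stat[covering] == 1.7))
  expect_true(all(is.na(w$stat[!covering])))
  expect_equal(w$n_snps[covering], rep(1L, sum(covering)))
})

test_that("window statistics equal a brute-force oracle", {
  set.seed(6)
  s <- randomSites(1000, 2e6)
  s <- edStatistic(s)
  s$stat <- transformEd(s$ed, 5)
  for (agg in c("mean", "sum")) {
    w <- windowScan(s, c(chr1 = 2e6), window = 1e5, step = 1e4,
                    statCol = "stat", aggregate = agg)
    starts <- seq(1, 2e6, by = 1e4)
    expected <- vapply(starts, function(st) {
      en <- min(st + 1e5 - 1, 2e6)
      v <- s$stat[s$pos >= st & s$pos <= en]
      if (!length(v)) return(NA_real_)
      if (agg == "mean") mean(v) else sum(v)
    }, 0)
    expect_equal(w$stat, expected)
  }
  expect_error(windowScan(s[c(2, 1), ], c(chr1 = 2e6)), "sorted")
})

test_that("empirical threshold uses the linear-interpolation quantile", {
  mkw <- function(stats) GRanges("chr1",
                                 IRanges(seq_along(stats), width = 10),
                                 n_snps = 1L, stat = stats)
  expect_equal(as.numeric(computeThreshold(mkw(1:100), 0.95)), 95.05)
  thr <- computeThreshold(mkw(rep(3, 10)), 0.95)
  expect_equal(as.numeric(thr), 3)
  expect_equal(attr(thr, "nWindows"), 10L)
  spiked <- c(rep(1, 99), 50)
  expect_gt(50, as.numeric(computeThreshold(mkw(spiked), 0.95)))
  expect_error(computeThreshold(mkw(NA_real_)), "no defined")
})

test_that("supra-threshold runs merge into candidate intervals", {
  w <- GRanges("chr1", IRanges(seq(1, 90001, by = 1e4), width = 1e5),
               n_snps = 1L,
               stat = c(5, 6, 1, 1, 7, 8, 9, 1, 1, 4))
  metadata(w) <- list(step = 1e4)
  iv <- callCandidateIntervals(w, threshold = 3)
  expect_equal(length(iv), 3L)
  expect_equal(iv$max_stat[1], 9)            # sorted by peak stat
  expect_equal(GenomicRanges::start(iv[1]), 40001L)
  expect_equal(GenomicRanges::end(iv[1]), 160000L)
  expect_equal(iv$peak_start[1], 60001L)
  # union semantics for two adjacent windows
  w2 <- GRanges("chr1", IRanges(c(1, 10001), width = 1e5),
                n_snps = 1L, stat = c(5, 5))
  iv2 <- callCandidateIntervals(w2, threshold = 1, step = 1e4)
  expect_equal(length(iv2), 1L)
  expect_equal(GenomicRanges::start(iv2), 1L)
  expect_equal(GenomicRanges::end(iv2), 110000L)
  expect_equal(iv2$peak_start, 1L)           # tie -> smaller start
  # nothing above threshold -> empty
  expect_equal(length(callCandidateIntervals(w, threshold = 100)), 0L)
})

test_that("bsaScan composes the stages and records provenance", {
  sim <- simulateBsaExperiment(simConfig(seed = 8, nChrom = 4L,
                                         chromLen = 2.5e6,
                                         causalChrom = "chr2",
                                         causalPos = 1.25e6,
                                         snpSpacing = 5e3))
  scan <- bsaScan(sim$sites, sim$chromLengths)
  expect_s4_class(scan, "BsaScan")
  expect_equal(length(windowStats(scan)), 4L * 250L)
  expect_gt(scanThreshold(scan), 0)
  p <- scanParams(scan)
  expect_equal(p$window, 1e5)
  expect_equal(p$power, 5)
  expect_equal(p$nInput, nrow(sim$sites))
  iv <- candidateIntervals(scan)
  expect_true(length(iv) >= 1)
  # the causal chromosome dominates the scan: its windows carry far
  # more signal than the three unlinked chromosomes
  expect_equal(as.character(GenomicRanges::seqnames(iv[1])), "chr2")
  w <- windowStats(scan)
  byChrom <- tapply(w$stat, as.character(GenomicRanges::seqnames(w)),
                    mean, na.rm = TRUE)
  expect_equal(names(which.max(byChrom)), "chr2")
  expect_gt(byChrom["chr2"], 5 * max(byChrom[c("chr1", "chr3",
                                               "chr4")]))
})
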