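test_that("intact filtering applies the inclusive 2000-7000 bp bounds", {
  el <- data.frame(id = c("a", "b", "c", "d", "e"),
                   start = 1000,
                   end = c(7687, 2999, 7999, 8000, 2998))
  len <- el$end - el$start + 1        # 6688 2000 7000 7001 1999
  expect_equal(len, c(6688, 2000, 7000, 7001, 1999))
  kept <- filterIntact(el)
  expect_equal(kept$id, c("a", "b", "c"))  # inclusive bounds
  expect_equal(kept$id, el$id[len >= 2000 & len <= 7000])
})

test_that("flank extraction does 500 bp coordinate arithmetic and round-trips", {
  fx <- plantedFixture(seed = 30, n = 2)
  e <- fx$elements[1, ]
  fl <- extractFlanks(e, fx$genome)
  expect_equal(nchar(fl$up), 500L)
  expect_equal(nchar(fl$down), 500L)
  g <- fx$genome[[e$contig]]
  expect_equal(fl$up, as.character(subseq(g, e$start - 500,
                                          e$start - 1)))
  expect_equal(fl$down, as.character(subseq(g, e$end + 1,
                                            e$end + 500)))
  # explicit coordinates: element at [10001, 16688]
  host <- randomGenome(c(c1 = 20000))
  e2 <- data.frame(contig = "c1", start = 10001, end = 16688)
  fl2 <- extractFlanks(e2, host)
  expect_equal(fl2$up, as.character(subseq(host[[1]], 9501, 10000)))
  expect_equal(fl2$down, as.character(subseq(host[[1]], 16689, 17188)))
  # element at the contig start has no usable up flank
  e3 <- data.frame(contig = "c1", start = 1, end = 3000)
  fl3 <- extractFlanks(e3, host)
  expect_true(is.na(fl3$up))
  expect_false(is.na(fl3$down))
  expect_error(extractFlanks(data.frame(contig = "c1", start = 100,
                                        end = 30000), host),
               "outside")
})

test_that("flank anchoring scores, uniqueness and orientation behave", {
  set.seed(31)
  target <- randomGenome(c(t1 = 40000))
  flank <- as.character(subseq(target[[1]], 20001, 20500))
  hit <- anchorFlank(flank, target)
  expect_true(hit$unique)
  expect_equal(hit$start, 20001L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$score, 500)
  # two mismatches cost 4 under +1/-1
  fl2 <- flank
  substr(fl2, 100, 100) <- if (substr(fl2, 100, 100) == "A") "C" else "A"
  substr(fl2, 300, 300) <- if (substr(fl2, 300, 300) == "G") "T" else "G"
  hit2 <- anchorFlank(fl2, target)
  expect_equal(hit2$score, 500 - 4)
  expect_true(hit2$unique)
  # duplicated placement is not unique
  dup <- DNAStringSet(c(t1 = paste0(as.character(target[[1]]),
                                    flank)))
  hit3 <- anchorFlank(flank, dup)
  expect_false(hit3$unique)
  expect_equal(hit3$score, hit3$secondBest)
  # reverse-complement placement is found on the minus strand
  rcTarget <- DNAStringSet(c(t1 = as.character(
    reverseComplement(target[[1]]))))
  hit4 <- anchorFlank(flank, rcTarget)
  expect_true(hit4$unique)
  expect_equal(hit4$strand, "-")
  expect_equal(hit4$score, 500)
  # absent flank finds nothing
  none <- anchorFlank(strrep("ACGT", 125), target)
  expect_false(none$found && none$unique)
  expect_error(anchorFlank(NA_character_, target), "empty")
})

test_that("anchor pairing enforces contig, orientation and the 20 kb span", {
  up <- list(found = TRUE, contig = "t1", start = 1000L, strand = "+",
             score = 500, secondBest = -500, unique = TRUE,
             flankLen = 500L)
  dn <- up; dn$start <- 4000L
  g <- pairAnchors(up, dn)
  expect_equal(g$status, "paired")
  expect_equal(g$gap, 4000 - 1499 - 1)
  other <- dn; other$contig <- "t2"
  expect_equal(pairAnchors(up, other)$status, "unpaired")
  flipped <- dn; flipped$strand <- "-"
  expect_equal(pairAnchors(up, flipped)$status, "unpaired")
  far <- dn; far$start <- 30000L
  expect_equal(pairAnchors(up, far)$status, "unpaired")
  nonUnique <- dn; nonUnique$unique <- FALSE
  expect_equal(pairAnchors(up, nonUnique)$status, "unpaired")
})

test_that("classifier recovers the simulator truth table per action", {
  fx <- plantedFixture(seed = 32, n = 8,
                       contigLens = c(ctg1 = 60000, ctg2 = 40000))
  acts <- setNames(rep(c("keep", "delete_element", "delete_flank",
                         "degrade_element"), 2), fx$elements$id)
  tg <- deriveTargetGenome(fx$genome, fx$elements, acts,
                           degradeIdentity = 0.85)
  cls <- classifyElements(fx$genome, tg$genome, fx$elements)
  m <- merge(as.data.frame(cls), tg$expected, by = "id")
  expect_equal(m$label, m$expected)
  degraded <- m[m$action == "degrade_element", ]
  expect_true(all(degraded$identity > 0.80 & degraded$identity < 0.95))
  expect_true(all(degraded$coverage > 0.95))
  # severe degradation falls through to ELIMINATION
  tgBad <- deriveTargetGenome(fx$genome, fx$elements,
                              acts[names(acts)[4]],
                              degradeIdentity = 0.5)
  clsBad <- classifyElement(fx$elements[4, ], fx$genome, tgBad$genome)
  expect_equal(clsBad$label, "ELIMINATION")
})

test_that("self-comparison yields HIGH_SHARED for every retained element", {
  fx <- plantedFixture(seed = 33, n = 5, perLtrDivergence = 0.01)
  cls <- classifyElements(fx$genome, fx$genome, fx$elements)
  expect_equal(nrow(cls), 5L)
  expect_true(all(cls$label == "HIGH_SHARED"))
  expect_true(all(cls$identity == 1))
  expect_true(all(abs(cls$gap - fx$elements$length) <= 0))
  # classification is total: exactly one label per element
  expect_true(all(cls$label %in% c("HIGH_SHARED", "LOW_SHARED",
                                   "INSERTION", "ELIMINATION",
                                   "UNKNOWN")))
  counts <- metadata(cls)$classCounts
  expect_equal(sum(counts), 5)
})

test_that("twin-LTR dating follows the Jukes-Cantor closed form", {
  ltr <- strrep("ACGT", 125)                     # 500 bp
  a0 <- estimateAge(ltr, ltr)
  expect_equal(a0$d, 0)
  expect_equal(a0$years, 0)
  # exactly 10 substitutions in 500 bp -> d = 0.02
  mut <- ltr
  for (i in seq(5, 50, by = 5))
    substr(mut, i, i) <- if (substr(mut, i, i) == "A") "G" else "A"
  a <- estimateAge(ltr, mut, mu = 1e-8)
  expect_equal(a$d, 0.02)
  expect_equal(a$K, -0.75 * log(1 - 4 * 0.02 / 3), tolerance = 1e-12)
  expect_equal(a$mya, 1.0136, tolerance = 1e-4)
  # monotone in d, zero at zero
  ds <- c(0.005, 0.02, 0.05, 0.2, 0.5)
  Ks <- -0.75 * log(1 - 4 * ds / 3)
  expect_true(all(diff(Ks) > 0))
  expect_true(all(Ks >= ds))
  # saturation guard: fully diverged copies (d = 1 >= 0.75)
  expect_error(estimateAge(strrep("A", 300), strrep("C", 300)),
               "saturation")
  expect_error(estimateAge(ltr, ltr, mu = 0), "mu")
})
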