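suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Minimal all-passing site table with given per-pool counts.
makeSites <- function(chrom, pos, mutCounts, wtCounts) {
  n <- length(pos)
  stopifnot(nrow(mutCounts) == n, nrow(wtCounts) == n)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = "A", alt = "G",
             A_mut = mutCounts[, 1], C_mut = mutCounts[, 2],
             G_mut = mutCounts[, 3], T_mut = mutCounts[, 4],
             A_wt = wtCounts[, 1], C_wt = wtCounts[, 2],
             G_wt = wtCounts[, 3], T_wt = wtCounts[, 4],
             qd = 30, fs = 1, mq = 60, mq_rank_sum = 0,
             read_pos_rank_sum = 0,
             dp = rowSums(mutCounts) + rowSums(wtCounts),
             stringsAsFactors = FALSE)
}

# Random usable site table on one chromosome.
randomSites <- function(n, chromLen, depth = 30) {
  pos <- sort(sample.int(chromLen, n))
  counts <- function() {
    dp <- rpois(n, depth) + 1L
    alt <- rbinom(n, dp, runif(n))
    cbind(dp - alt, 0L, alt, 0L)
  }
  makeSites("chr1", pos, counts(), counts())
}

# Small planted-element fixture shared by ltr tests.
plantedFixture <- function(seed = 11, n = 6, contigLens = c(ctg1 = 60000),
                           perLtrDivergence = 0) {
  set.seed(seed)
  host <- randomGenome(contigLens)
  specs <- sampleElementSpecs(host, n,
                              perLtrDivergence = perLtrDivergence)
  c(plantElements(host, specs), list(host = host, specs = specs))
}

writeTinyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "chi1", "chi2", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT:AD",
          "0/1:12,18", "0/0:25,0", sep = "\t"),
    paste("chr1", "200", ".", "C", "T", ".", "PASS", ".", "GT:AD",
          "0/1:10,10", "0/1:9,11", sep = "\t"),
    paste("chr1", "300", ".", "G", "GTT", ".", "PASS", ".", "GT:AD",
          "0/1:5,5", "0/1:5,5", sep = "\t")), path)
  path
}
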