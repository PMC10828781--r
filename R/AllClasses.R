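#' Simulation configuration
#'
#' Parameters of the default in silico experiment: an F1 cross with a
#' single dominant causal locus, two phenotypic bulks, and pooled
#' short-read allele depths at evenly spaced SNPs.  Defaults reproduce
#' the study conditions the package validates against: a peach-scale
#' genome (8 chromosomes x 30 Mb) with the causal insertion near the
#' top of chromosome 5, an F1 population of 120, bulks of 15
#' individuals sequenced at 30x mean depth per pool, a uniform genetic
#' map of 1 cM/Mb, and a one-class advancement of the fruit
#' development period (FDP) for carriers of the element.  The
#' genome-wide scan geometry matters: the empirical 95% threshold is
#' only meaningful when the region linked to the causal locus is a
#' small fraction of the scanned windows, as it is in a real
#' multi-chromosome genome.
#'
#' @slot seed integer seed; every downstream draw is deterministic
#'   given it.
#' @slot nChrom number of chromosomes.
#' @slot chromLen chromosome length in bp (all chromosomes equal).
#' @slot snpSpacing distance between simulated SNPs in bp.
#' @slot causalChrom,causalPos location of the causal insertion.
#' @slot nOffspring F1 population size.
#' @slot bulkSize individuals per phenotypic pool.
#' @slot depth mean reads per site per pool (Poisson).
#' @slot recombRate uniform recombination rate in cM/Mb.
#' @slot teEffectOnFdp ordinal FDP-class advancement for carriers.
#' @slot errorRate per-read uniform base-miscall probability.
#'
#' @seealso [simConfig()], [simulateBsaExperiment()]
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nChrom = "integer",
    chromLen = "numeric",
    snpSpacing = "numeric",
    causalChrom = "character",
    causalPos = "numeric",
    nOffspring = "integer",
    bulkSize = "integer",
    depth = "numeric",
    recombRate = "numeric",
    teEffectOnFdp = "integer",
    errorRate = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@causalPos < 1 || object@causalPos > object@chromLen)
    msg <- c(msg, "causalPos must lie in [1, chromLen]")
  if (object@snpSpacing <= 0 || object@snpSpacing > object@chromLen)
    msg <- c(msg, "snpSpacing must lie in (0, chromLen]")
  if (object@bulkSize < 1) msg <- c(msg, "bulkSize must be >= 1")
  if (object@nOffspring < 2 * object@bulkSize)
    msg <- c(msg, "nOffspring must be at least 2 * bulkSize")
  if (object@recombRate < 0) msg <- c(msg, "recombRate must be >= 0")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param seed integer random seed.
#' @param nChrom,chromLen,snpSpacing genome layout (bp).
#' @param causalChrom,causalPos causal locus location.
#' @param nOffspring,bulkSize F1 population and pool sizes.
#' @param depth mean reads per site per pool.
#' @param recombRate cM/Mb.
#' @param teEffectOnFdp ordinal FDP-class shift for carriers.
#' @param errorRate per-read base-miscall probability.
#' @return a validated `SimConfig`.
#' @examples
#' simConfig(seed = 1)
#' @export
simConfig <- function(seed = 1L, nChrom = 8L, chromLen = 3e7,
                      snpSpacing = 2e3, causalChrom = "chr5",
                      causalPos = 3e6, nOffspring = 120L,
                      bulkSize = 15L, depth = 30, recombRate = 1.0,
                      teEffectOnFdp = 1L, errorRate = 0) {
  new("SimConfig",
    seed = as.integer(seed), nChrom = as.integer(nChrom),
    chromLen = as.numeric(chromLen), snpSpacing = as.numeric(snpSpacing),
    causalChrom = as.character(causalChrom), causalPos = as.numeric(causalPos),
    nOffspring = as.integer(nOffspring), bulkSize = as.integer(bulkSize),
    depth = as.numeric(depth), recombRate = as.numeric(recombRate),
    teEffectOnFdp = as.integer(teEffectOnFdp),
    errorRate = as.numeric(errorRate))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  genome   :", object@nChrom, "x", object@chromLen, "bp, SNP every",
      object@snpSpacing, "bp\n")
  cat("  causal   :", object@causalChrom, "@", object@causalPos, "\n")
  cat("  cross    :", object@nOffspring, "offspring, bulks of",
      object@bulkSize, ",", object@depth, "x per pool\n")
  cat("  map      :", object@recombRate, "cM/Mb; FDP shift",
      object@teEffectOnFdp, "; error rate", object@errorRate, "\n")
  cat("  seed     :", object@seed, "\n")
})

#' Simulated F1 population
#'
#' One diploid offspring population from a two-parent cross.  Each
#' offspring holds one gamete per parent; gamete haplotypes are formed
#' by Mendelian sampling with Haldane crossover probabilities between
#' adjacent loci.  Gametes are stored as allele matrices
#' (offspring x marker), which keeps dosage computations vectorised.
#'
#' @slot markers data.frame with columns `name`, `chrom`, `pos`
#'   (1-based bp; `NA` position means unlinked).
#' @slot gamete1,gamete2 character matrices of transmitted alleles,
#'   offspring in rows, markers in columns (`gamete1` from parent 1).
#' @slot pheno data.frame of per-offspring phenotype assignments,
#'   always containing column `id`.
#'
#' @seealso [simulateCross()], [assignPhenotypes()]
#' @export
setClass("CrossPopulation",
  representation(
    markers = "data.frame",
    gamete1 = "matrix",
    gamete2 = "matrix",
    pheno = "data.frame"
  )
)

setValidity("CrossPopulation", function(object) {
  msg <- character()
  L <- nrow(object@markers)
  if (ncol(object@gamete1) != L || ncol(object@gamete2) != L)
    msg <- c(msg, "gamete matrices must have one column per marker")
  if (nrow(object@gamete1) != nrow(object@gamete2))
    msg <- c(msg, "gamete matrices must have equal row counts")
  if (nrow(object@pheno) != nrow(object@gamete1))
    msg <- c(msg, "pheno must have one row per offspring")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CrossPopulation", function(object) {
  cat("CrossPopulation:", nrow(object@gamete1), "offspring x",
      nrow(object@markers), "markers\n")
  extra <- setdiff(colnames(object@pheno), "id")
  if (length(extra)) cat("  phenotypes:", paste(extra, collapse = ", "), "\n")
})

#' @describeIn CrossPopulation number of offspring.
#' @param x,object a `CrossPopulation`.
#' @export
setMethod("length", "CrossPopulation", function(x) nrow(x@gamete1))

#' Marker table of a cross
#' @param x a [CrossPopulation-class].
#' @return data.frame of marker name, chrom, pos.
#' @export
crossMarkers <- function(x) {
  stopifnot(is(x, "CrossPopulation"))
  x@markers
}

#' Phenotype table of a cross
#' @param x a [CrossPopulation-class].
#' @return data.frame with one row per offspring.
#' @export
phenotypes <- function(x) {
  stopifnot(is(x, "CrossPopulation"))
  x@pheno
}

#' Result of a windowed ED genome scan
#'
#' Container for the output of [bsaScan()]: per-window aggregated
#' ED^k statistics, the genome-wide empirical threshold, and the
#' merged supra-threshold candidate intervals.
#'
#' @slot windows `GRanges` of scan windows with metadata columns
#'   `n_snps` and `stat` (`NA` where fewer than the minimum SNPs).
#' @slot threshold empirical quantile of the defined window stats.
#' @slot level quantile level used (default 0.95).
#' @slot intervals `GRanges` of candidate intervals with `max_stat`,
#'   `n_windows`, `peak_start`, `peak_end`.
#' @slot nSites number of sites contributing to the scan.
#' @slot params list echoing all resolved scan parameters.
#'
#' @seealso [bsaScan()], [windowStats()], [candidateIntervals()]
#' @export
setClass("BsaScan",
  representation(
    windows = "GRanges",
    threshold = "numeric",
    level = "numeric",
    intervals = "GRanges",
    nSites = "integer",
    params = "list"
  )
)

setMethod("show", "BsaScan", function(object) {
  cat("BsaScan:", length(object@windows), "windows over", object@nSites,
      "sites\n")
  cat("  threshold:", format(object@threshold, digits = 6),
      sprintf("(empirical %g quantile)\n", object@level))
  cat("  candidate intervals:", length(object@intervals), "\n")
  if (length(object@intervals)) {
    top <- object@intervals[which.max(object@intervals$max_stat)]
    cat(sprintf("  top: %s:%d-%d (max stat %.4g)\n",
                as.character(seqnames(top)), start(top),
                end(top), top$max_stat))
  }
})

#' Window statistics of a scan
#' @param x a [BsaScan-class].
#' @return `GRanges` of windows with `n_snps` and `stat`.
#' @export
windowStats <- function(x) {
  stopifnot(is(x, "BsaScan"))
  x@windows
}

#' Threshold of a scan
#' @param x a [BsaScan-class].
#' @return the empirical quantile threshold (numeric scalar).
#' @export
scanThreshold <- function(x) {
  stopifnot(is(x, "BsaScan"))
  x@threshold
}

#' Candidate intervals of a scan
#' @param x a [BsaScan-class].
#' @return `GRanges` of merged supra-threshold intervals.
#' @export
candidateIntervals <- function(x) {
  stopifnot(is(x, "BsaScan"))
  x@intervals
}

#' Scan parameters
#' @param x a [BsaScan-class].
#' @return list of resolved parameters.
#' @export
scanParams <- function(x) {
  stopifnot(is(x, "BsaScan"))
  x@params
}

#' Chi-square goodness-of-fit result
#'
#' Pearson goodness-of-fit against an expected Mendelian ratio, with
#' the upper-tail critical value at `alpha` and the resulting
#' accept/reject decision.
#'
#' @slot statistic Pearson statistic, `sum((O - E)^2 / E)`.
#' @slot df degrees of freedom (classes - 1).
#' @slot alpha significance level.
#' @slot criticalValue upper-tail chi-square quantile at `alpha`.
#' @slot pValue upper-tail probability of the statistic.
#' @slot reject `TRUE` iff `statistic > criticalValue`.
#' @slot observed,expected counts per class.
#'
#' @seealso [chiSquareGof()]
#' @export
setClass("ChiSquareResult",
  representation(
    statistic = "numeric",
    df = "numeric",
    alpha = "numeric",
    criticalValue = "numeric",
    pValue = "numeric",
    reject = "logical",
    observed = "numeric",
    expected = "numeric"
  )
)

setValidity("ChiSquareResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "statistic must be >= 0")
  if (object@reject != (object@statistic > object@criticalValue))
    msg <- c(msg, "reject must equal statistic > criticalValue")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChiSquareResult", function(object) {
  cat(sprintf("Chi-square goodness of fit: X2 = %.4g on %d df\n",
              object@statistic, object@df))
  cat(sprintf("  critical value (alpha = %g): %.4g -> %s (p = %.3g)\n",
              object@alpha, object@criticalValue,
              if (object@reject) "reject" else "accept", object@pValue))
})
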