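# F1 cross and pooled-sequencing simulator.  All randomness flows
# through R's RNG, so a single set.seed() upstream makes every output
# byte-identical.

#' Haldane mapping function
#'
#' Recombination fraction between two loci separated by `d` Morgans,
#' assuming no crossover interference: `r = (1 - exp(-2 d)) / 2`.
#'
#' @param d map distance in Morgans (>= 0).
#' @return recombination fraction in \[0, 0.5).
#' @examples
#' haldane(0.1) # 10 cM -> ~0.0906
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d)) / 2
}

# Recombination fraction between each pair of adjacent markers.
# Markers on different chromosomes (or with NA position) segregate
# independently (r = 0.5).
.adjacentRecomb <- function(markers, recombRate) {
  L <- nrow(markers)
  if (L <= 1) return(numeric(0))
  same <- markers$chrom[-L] == markers$chrom[-1] &
    !is.na(markers$pos[-L]) & !is.na(markers$pos[-1])
  d <- abs(markers$pos[-1] - markers$pos[-L]) / 1e6 * recombRate / 100
  ifelse(same, haldane(d), 0.5)
}

# n gamete haplotype indicators (0 = chromatid 1, 1 = chromatid 2)
# along L ordered loci, switching between adjacent loci with the
# given recombination fractions.
.gameteHaplotypes <- function(n, rfrac) {
  L <- length(rfrac) + 1L
  h0 <- matrix(0L, n, L)
  h0[, 1L] <- rbinom(n, 1L, 0.5)
  if (L > 1L) {
    sw <- matrix(rbinom(n * (L - 1L), 1L,
                        rep(rfrac, each = n)), n, L - 1L)
    h0[, -1L] <- sw
    h0 <- t(apply(h0, 1L, cumsum)) %% 2L
  }
  h0
}

# Pick transmitted alleles given haplotype indicators and the
# parent's two allele vectors (length L each).
.pickAlleles <- function(hap, a1, a2) {
  n <- nrow(hap); L <- ncol(hap)
  sel <- hap == 1L
  if (length(unique(a1)) == 1L && length(unique(a2)) == 1L) {
    # common case (e.g. every SNP shares the same allele coding)
    g <- matrix(a1[1L], n, L)
    g[sel] <- a2[1L]
    return(g)
  }
  idx <- rep(seq_len(L), each = n)
  g <- matrix(a1[idx], n, L)
  g[sel] <- a2[idx][sel]
  g
}

.checkParentMarkers <- function(parent1, parent2) {
  if (is.null(names(parent1)) || is.null(names(parent2)))
    stop("parent genotype lists must be named by marker")
  only1 <- setdiff(names(parent1), names(parent2))
  only2 <- setdiff(names(parent2), names(parent1))
  if (length(only1) || length(only2))
    stop("markers present in one parent only: ",
         paste(c(only1, only2), collapse = ", "))
  bad <- names(parent1)[vapply(parent1, length, 1L) != 2L |
                          vapply(parent2, length, 1L) != 2L]
  if (length(bad))
    stop("parent genotypes must hold exactly two alleles: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Simulate an F1 cross
#'
#' Each offspring receives one gamete from each parent.  Gametes are
#' formed by Mendelian sampling: the transmitted chromatid switches
#' between adjacent loci with the Haldane recombination fraction
#' implied by their map distance (`recombRate` cM/Mb, uniform map);
#' loci on different chromosomes, or without a map position,
#' segregate independently.
#'
#' @param parent1,parent2 named lists; each element is a length-2
#'   character vector of the parent's alleles at that marker.  Both
#'   parents must name the same markers.
#' @param n number of offspring.
#' @param markers optional data.frame with columns `name`, `chrom`,
#'   `pos` giving marker locations; omitted markers (or `markers =
#'   NULL`) are treated as unlinked.
#' @param recombRate recombination rate in cM/Mb.
#' @return a [CrossPopulation-class].
#' @examples
#' set.seed(1)
#' pop <- simulateCross(list(ins9 = c("0", "9")),
#'                      list(ins9 = c("0", "9")), n = 40)
#' table(genotypeStrings(pop, "ins9"))
#' @export
simulateCross <- function(parent1, parent2, n, markers = NULL,
                          recombRate = 1.0) {
  .checkParentMarkers(parent1, parent2)
  nm <- names(parent1)
  if (is.null(markers)) {
    markers <- data.frame(name = nm, chrom = "un", pos = NA_real_,
                          stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("name", "chrom", "pos") %in% colnames(markers)))
    markers <- markers[markers$name %in% nm,
                       c("name", "chrom", "pos"), drop = FALSE]
    miss <- setdiff(nm, markers$name)
    if (length(miss))
      markers <- rbind(markers,
                       data.frame(name = miss, chrom = "un",
                                  pos = NA_real_))
    markers <- markers[order(markers$chrom, markers$pos,
                             na.last = TRUE), , drop = FALSE]
    rownames(markers) <- NULL
  }
  nm <- markers$name
  rfrac <- .adjacentRecomb(markers, recombRate)
  g1 <- .pickAlleles(.gameteHaplotypes(n, rfrac),
                     vapply(parent1[nm], `[`, "", 1L),
                     vapply(parent1[nm], `[`, "", 2L))
  g2 <- .pickAlleles(.gameteHaplotypes(n, rfrac),
                     vapply(parent2[nm], `[`, "", 1L),
                     vapply(parent2[nm], `[`, "", 2L))
  colnames(g1) <- colnames(g2) <- nm
  new("CrossPopulation", markers = markers, gamete1 = g1, gamete2 = g2,
      pheno = data.frame(id = sprintf("F1_%04d", seq_len(n)),
                         stringsAsFactors = FALSE))
}

#' Genotype strings of a cross
#'
#' @param pop a [CrossPopulation-class].
#' @param marker marker name(s); default all.
#' @return character matrix (offspring x markers) of sorted `"a/b"`
#'   genotype strings, dropped to a vector for a single marker.
#' @export
genotypeStrings <- function(pop, marker = NULL) {
  stopifnot(is(pop, "CrossPopulation"))
  if (is.null(marker)) marker <- pop@markers$name
  g1 <- pop@gamete1[, marker, drop = FALSE]
  g2 <- pop@gamete2[, marker, drop = FALSE]
  out <- matrix(paste(pmin(g1, g2), pmax(g1, g2), sep = "/"),
                nrow(g1), ncol(g1), dimnames = dimnames(g1))
  if (length(marker) == 1L) out[, 1L] else out
}

#' Allele dosage in a cross
#'
#' Counts how many of an offspring's two alleles match a focal allele
#' at each marker.
#'
#' @param pop a [CrossPopulation-class].
#' @param alleles a single allele applied to every marker, or a named
#'   character vector (marker -> focal allele).
#' @return integer matrix (offspring x markers) of dosages in 0..2.
#' @export
alleleDosage <- function(pop, alleles) {
  stopifnot(is(pop, "CrossPopulation"))
  nm <- pop@markers$name
  if (length(alleles) == 1L && is.null(names(alleles)))
    alleles <- setNames(rep(alleles, length(nm)), nm)
  miss <- setdiff(names(alleles), nm)
  if (length(miss))
    stop("unknown marker(s): ", paste(miss, collapse = ", "))
  nm <- nm[nm %in% names(alleles)]       # restrict to named markers
  g1 <- pop@gamete1[, nm, drop = FALSE]
  g2 <- pop@gamete2[, nm, drop = FALSE]
  a <- alleles[nm]
  if (length(unique(a)) == 1L) {
    d <- (g1 == a[1L]) + (g2 == a[1L])
  } else {
    amat <- matrix(a[rep(seq_along(nm), each = nrow(g1))],
                   nrow(g1), length(nm))
    d <- (g1 == amat) + (g2 == amat)
  }
  dimnames(d) <- dimnames(g1)
  d
}

#' Assign flesh-colour and FDP phenotypes
#'
#' Phenotype model: blood flesh is dominant for presence of the
#' element -- any offspring carrying at least one copy of `teAllele`
#' at `teMarker` is scored `"blood"`, all others `"none"`.  The fruit
#' development period (FDP) class follows the 9 bp insertion genotype
#' (9/9 -> 60-90, 0/9 -> 90-120, 0/0 -> 120-150 days) and is then
#' advanced by `teEffect` classes for element carriers, floored at
#' the earliest class.
#'
#' @param pop a [CrossPopulation-class].
#' @param teMarker,teAllele marker and allele defining carriers.
#' @param ins9Marker optional marker holding the 9 bp-insertion
#'   genotype (alleles `"9"`/`"0"`); when `NULL` no FDP class is set.
#' @param teEffect ordinal FDP advancement for carriers.
#' @return `pop` with `flesh` (and possibly `fdp_class`) phenotype
#'   columns filled in.
#' @export
assignPhenotypes <- function(pop, teMarker = "bloodTE", teAllele = "R1",
                             ins9Marker = NULL, teEffect = 1L) {
  stopifnot(is(pop, "CrossPopulation"))
  if (!teMarker %in% pop@markers$name)
    stop("unknown marker: ", teMarker)
  carrier <- alleleDosage(pop, setNames(teAllele, teMarker))[, teMarker] >= 1L
  pop@pheno$flesh <- ifelse(carrier, "blood", "none")
  if (!is.null(ins9Marker)) {
    if (!ins9Marker %in% pop@markers$name)
      stop("unknown marker: ", ins9Marker)
    gt <- genotypeStrings(pop, ins9Marker)
    cls <- match(gt, c("9/9", "0/9", "0/0"))
    if (anyNA(cls))
      stop("ins9 marker genotypes must use alleles '0' and '9'")
    cls <- ifelse(carrier, pmax(cls - as.integer(teEffect), 1L), cls)
    pop@pheno$fdp_class <- fdpClassLevels()[cls]
  }
  pop
}

#' FDP class labels
#' @return the ordered FDP class labels (days).
#' @export
fdpClassLevels <- function() c("60-90", "90-120", "120-150")

#' Select the two phenotypic bulks
#'
#' Random sample without replacement of `bulkSize` offspring from
#' each phenotype class (`mut` = case phenotype, `wt` = the rest),
#' mirroring the construction of the two 15-individual pools.
#'
#' @param pop a [CrossPopulation-class] with phenotypes assigned.
#' @param bulkSize individuals per pool.
#' @param phenotype phenotype column to split on.
#' @param case value of `phenotype` defining the mutant pool.
#' @return list with integer index vectors `mut` and `wt`.
#' @export
buildBulks <- function(pop, bulkSize = 15L, phenotype = "flesh",
                       case = "blood") {
  stopifnot(is(pop, "CrossPopulation"))
  if (!phenotype %in% colnames(pop@pheno))
    stop("phenotype column not assigned: ", phenotype)
  ph <- pop@pheno[[phenotype]]
  mutIdx <- which(ph == case)
  wtIdx <- which(ph != case)
  if (length(mutIdx) < bulkSize || length(wtIdx) < bulkSize)
    stop(sprintf(paste0("not enough individuals for bulks of %d ",
                        "(%s: %d, other: %d)"),
                 bulkSize, case, length(mutIdx), length(wtIdx)))
  list(mut = sort(sample(mutIdx, bulkSize)),
       wt = sort(sample(wtIdx, bulkSize)),
       bulkSize = as.integer(bulkSize))
}

#' Pooled allele frequencies of a bulk
#'
#' @param pop a [CrossPopulation-class].
#' @param idx offspring indices forming the bulk.
#' @param alleles focal allele(s), as in [alleleDosage()].
#' @return numeric vector of focal-allele frequencies per marker
#'   (mean dosage / 2).
#' @export
bulkAlleleFrequencies <- function(pop, idx, alleles) {
  d <- alleleDosage(pop, alleles)[idx, , drop = FALSE]
  colMeans(d) / 2
}

.passQuality <- list(qd = 25, fs = 1, mq = 60, mq_rank_sum = 0,
                     read_pos_rank_sum = 0)
.failQuality <- list(qd = 1, fs = 100, mq = 20, mq_rank_sum = -20,
                     read_pos_rank_sum = -10)

#' Sample pooled read depths at simulated SNPs
#'
#' Per pool and site, total depth is Poisson(`depth`) and base counts
#' are multinomial over A/C/G/T with the pool's expected base
#' frequencies (ref gets `1 - p`, alt gets `p`, optionally perturbed
#' by a uniform miscall rate).  GATK-style quality annotations are
#' filled with passing values; `qualityFailRates` makes a chosen
#' fraction of sites fail each filter clause.  Ground-truth pool
#' frequencies are retained in columns `p_mut` / `p_wt`.
#'
#' @param freqMut,freqWt expected alt-allele frequency per site in
#'   the mutant and wild-type pool.
#' @param markers data.frame with `chrom` and `pos` per site.
#' @param depth mean reads per site per pool (> 0).
#' @param errorRate per-read uniform base-miscall probability.
#' @param qualityFailRates optional named list (names among `qd`,
#'   `fs`, `mq`, `mq_rank_sum`, `read_pos_rank_sum`, `dp`) of
#'   per-site probabilities of drawing a failing annotation.
#' @param refBases,altBases optional per-site bases; random distinct
#'   bases by default.
#' @return a site table (data.frame) in the package's TSV dialect:
#'   `chrom`, `pos`, `ref`, `alt`, per-pool A/C/G/T counts
#'   (`A_mut`..`T_wt`), quality annotations, `dp`, and truth columns.
#' @export
sampleAlleleDepths <- function(freqMut, freqWt, markers, depth = 30,
                               errorRate = 0, qualityFailRates = NULL,
                               refBases = NULL, altBases = NULL) {
  if (depth <= 0) stop("depth must be > 0")
  L <- length(freqMut)
  stopifnot(length(freqWt) == L, nrow(markers) == L)
  bases <- c("A", "C", "G", "T")
  if (is.null(refBases)) refBases <- sample(bases, L, replace = TRUE)
  if (is.null(altBases))
    altBases <- vapply(refBases,
                       function(b) sample(setdiff(bases, b), 1L), "")
  poolCounts <- function(p) {
    dp <- rpois(L, depth)
    q <- matrix(0, L, 4, dimnames = list(NULL, bases))
    q[cbind(seq_len(L), match(refBases, bases))] <- 1 - p
    q[cbind(seq_len(L), match(altBases, bases))] <-
      q[cbind(seq_len(L), match(altBases, bases))] + p
    if (errorRate > 0)
      q <- q * (1 - errorRate) + errorRate * (1 - q) / 3
    # multinomial as a chain of conditional binomials, vectorised
    # over sites
    counts <- matrix(0L, L, 4, dimnames = list(NULL, bases))
    rem <- dp
    ptot <- rep(1, L)
    for (b in 1:3) {
      pb <- ifelse(ptot > 0, q[, b] / ptot, 0)
      counts[, b] <- rbinom(L, rem, pmin(pmax(pb, 0), 1))
      rem <- rem - counts[, b]
      ptot <- ptot - q[, b]
    }
    counts[, 4] <- rem
    counts
  }
  mutC <- poolCounts(freqMut)
  wtC <- poolCounts(freqWt)
  ann <- lapply(names(.passQuality), function(a) {
    v <- rep(.passQuality[[a]], L)
    fr <- qualityFailRates[[a]]
    if (!is.null(fr) && fr > 0) {
      hit <- runif(L) < fr
      v[hit] <- .failQuality[[a]]
    }
    v
  })
  names(ann) <- names(.passQuality)
  dp <- as.integer(rowSums(mutC) + rowSums(wtC))
  frDp <- qualityFailRates[["dp"]]
  if (!is.null(frDp) && frDp > 0) {
    hit <- runif(L) < frDp
    dp[hit] <- sample(0:3, sum(hit), replace = TRUE)
  }
  data.frame(chrom = markers$chrom, pos = markers$pos,
             ref = refBases, alt = altBases,
             A_mut = mutC[, "A"], C_mut = mutC[, "C"],
             G_mut = mutC[, "G"], T_mut = mutC[, "T"],
             A_wt = wtC[, "A"], C_wt = wtC[, "C"],
             G_wt = wtC[, "G"], T_wt = wtC[, "T"],
             qd = ann$qd, fs = ann$fs, mq = ann$mq,
             mq_rank_sum = ann$mq_rank_sum,
             read_pos_rank_sum = ann$read_pos_rank_sum,
             dp = dp, p_mut = freqMut, p_wt = freqWt,
             stringsAsFactors = FALSE)
}

#' Simulate a complete bulked-segregant experiment
#'
#' End-to-end generator with known ground truth: an F1 cross between
#' a heterozygous carrier of the causal insertion (informative,
#' phase-known alleles at every SNP) and a homozygous non-carrier;
#' dominant phenotype assignment; two bulks of `bulkSize`; and pooled
#' allele depths at evenly spaced SNPs.  At the causal SNP the
#' expected pool frequencies are 0.5 (mutant) and 0 (wild type), so
#' the expected per-site ED is `sqrt(0.5)` ~ 0.707.
#'
#' @param cfg a [SimConfig-class]; `cfg@seed` seeds all draws.
#' @return list with elements `sites` (site table, see
#'   [sampleAlleleDepths()]), `population`, `bulks`, `causal`
#'   (list of `chrom`, `pos`, `marker`), `chromLengths` (named
#'   vector), and `config`.
#' @examples
#' sim <- simulateBsaExperiment(simConfig(seed = 1, nChrom = 1L,
#'                                        chromLen = 1e6,
#'                                        causalChrom = "chr1",
#'                                        causalPos = 5e5))
#' head(sim$sites)
#' @export
simulateBsaExperiment <- function(cfg = simConfig()) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  chroms <- paste0("chr", seq_len(cfg@nChrom))
  stopifnot(cfg@causalChrom %in% chroms)
  mk <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- seq(cfg@snpSpacing, cfg@chromLen, by = cfg@snpSpacing)
    if (ch == cfg@causalChrom)
      pos <- sort(unique(c(pos, cfg@causalPos)))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  mk$name <- sprintf("%s_%09d", mk$chrom, mk$pos)
  mk <- mk[, c("name", "chrom", "pos")]
  causalMarker <- sprintf("%s_%09d", cfg@causalChrom, cfg@causalPos)
  # parent 1 heterozygous carrier: allele "1" marks the causal
  # haplotype at every SNP; parent 2 homozygous non-carrier
  p1 <- setNames(rep(list(c("1", "2")), nrow(mk)), mk$name)
  p2 <- setNames(rep(list(c("2", "2")), nrow(mk)), mk$name)
  pop <- simulateCross(p1, p2, cfg@nOffspring, markers = mk,
                       recombRate = cfg@recombRate)
  pop <- assignPhenotypes(pop, teMarker = causalMarker, teAllele = "1")
  bulks <- buildBulks(pop, cfg@bulkSize)
  fm <- bulkAlleleFrequencies(pop, bulks$mut, "1")
  fw <- bulkAlleleFrequencies(pop, bulks$wt, "1")
  sites <- sampleAlleleDepths(fm, fw, pop@markers, depth = cfg@depth,
                              errorRate = cfg@errorRate)
  list(sites = sites, population = pop, bulks = bulks,
       causal = list(chrom = cfg@causalChrom, pos = cfg@causalPos,
                     marker = causalMarker),
       chromLengths = setNames(rep(cfg@chromLen, cfg@nChrom), chroms),
       config = cfg)
}
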