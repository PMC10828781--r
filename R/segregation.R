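# Mendelian expectations, chi-square goodness of fit,
# marker-phenotype co-segregation, haplotype-combination colour
# rules, FDP classes and carrier-ratio summaries.

.parseGenotype <- function(g) {
  a <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(a) != 2L) stop("genotype must be 'a/b': ", g)
  a
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Punnett expectation for a single-locus cross
#'
#' Distribution of offspring genotypes implied by the parents'
#' diploid genotypes, reduced to the lowest integer ratio.
#'
#' @param parent1,parent2 genotype strings `"a/b"`.
#' @return named integer vector of genotype : ratio, genotypes as
#'   sorted `"a/b"` strings.
#' @examples
#' expectedOffspringRatio("0/9", "0/9") # 1 (0/0) : 2 (0/9) : 1 (9/9)
#' expectedOffspringRatio("0/0", "0/9") # 1 : 1
#' @export
expectedOffspringRatio <- function(parent1, parent2) {
  a <- .parseGenotype(parent1)
  b <- .parseGenotype(parent2)
  combos <- as.vector(outer(a, b, function(x, y)
    paste(pmin(x, y), pmax(x, y), sep = "/")))
  tab <- table(combos)
  counts <- as.integer(tab)
  g <- Reduce(.gcd, counts)
  setNames(counts %/% g, names(tab))
}

#' Upper-tail chi-square critical value
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1).
#' @return the value exceeded with probability `alpha`.
#' @examples
#' chiSquareCritical(2)        # 5.99
#' chiSquareCritical(1)        # 3.84
#' @export
chiSquareCritical <- function(df, alpha = 0.05) {
  if (any(df < 1)) stop("df must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  qchisq(alpha, df, lower.tail = FALSE)
}

.parseRatio <- function(ratio) {
  if (is.character(ratio) && length(ratio) == 1L)
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  as.numeric(ratio)
}

#' Pearson chi-square goodness of fit against a Mendelian ratio
#'
#' `X2 = sum((O - E)^2 / E)` with `E = total * ratio / sum(ratio)`,
#' no continuity correction; `df = classes - 1`.  The statistic is
#' invariant under scaling of the ratio.
#'
#' @param observed counts per class (>= 2 classes, positive total).
#' @param ratio expected ratio: numeric vector or a string like
#'   `"1:2:1"`.
#' @param alpha significance level for the decision.
#' @return a [ChiSquareResult-class].
#' @examples
#' chiSquareGof(c(9, 31, 19), "1:2:1")   # 3.54, accept at 5.99
#' chiSquareGof(c(36, 20, 0), "1:2:1")   # 50.86, reject
#' @export
chiSquareGof <- function(observed, ratio, alpha = 0.05) {
  observed <- as.numeric(observed)
  ratio <- .parseRatio(ratio)
  if (length(observed) < 2L) stop("need at least 2 classes")
  if (length(ratio) != length(observed))
    stop("ratio and observed must have the same length")
  if (any(ratio < 0) || sum(ratio) <= 0)
    stop("expected ratio must be positive")
  total <- sum(observed)
  if (total <= 0) stop("total observed count must be > 0")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0 & observed > 0))
    stop("zero expected count with nonzero observed; ",
         "collapse classes explicitly")
  keep <- expected > 0
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- length(observed) - 1L
  crit <- chiSquareCritical(df, alpha)
  new("ChiSquareResult", statistic = stat, df = as.numeric(df),
      alpha = alpha, criticalValue = crit,
      pValue = pchisq(stat, df, lower.tail = FALSE),
      reject = stat > crit, observed = observed, expected = expected)
}

#' Marker-phenotype co-segregation concordance
#'
#' Fraction of individuals whose binary phenotype matches their
#' marker carrier status: `(carriers with the phenotype +
#' non-carriers without it) / n`.  Pairs with a missing value are
#' dropped and counted.
#'
#' @param carrier logical marker-presence vector.
#' @param phenotype logical phenotype vector of the same length.
#' @return list with `concordance`, `n`, `nDropped` and the 2x2
#'   contingency `table` (carrier x phenotype).
#' @examples
#' cosegregationConcordance(rep(c(TRUE, FALSE), c(143, 190)),
#'                          rep(c(TRUE, FALSE), c(143, 190)))
#' @export
cosegregationConcordance <- function(carrier, phenotype) {
  if (length(carrier) != length(phenotype))
    stop("carrier and phenotype must have the same length")
  ok <- !is.na(carrier) & !is.na(phenotype)
  nDropped <- sum(!ok)
  carrier <- as.logical(carrier[ok])
  phenotype <- as.logical(phenotype[ok])
  n <- length(carrier)
  if (n == 0) stop("no complete pairs")
  tab <- table(factor(carrier, c(TRUE, FALSE)),
               factor(phenotype, c(TRUE, FALSE)),
               dnn = c("carrier", "phenotype"))
  conc <- (sum(carrier & phenotype) + sum(!carrier & !phenotype)) / n
  list(concordance = conc, n = n, nDropped = nDropped, table = tab)
}

.COLOR_RULES <- data.frame(
  d_hap = c("D1D1", "D1D2", "D2D2", "D2D2"),
  t_hap = c("T1T1", "T1T1", "T1T1", "T1T2"),
  flesh = c("dark", "blood", "light", "none"),
  stringsAsFactors = FALSE)

#' Blood-flesh colour intensity from the three-locus genotype
#'
#' Rule observed in carriers of the promoter element (blood TE,
#' haplotype R1): with the modifier genotypes at the two
#' anthocyanin-regulator promoter loci, (D1D1, T1T1) gives dark
#' blood flesh, (D1D2, T1T1) blood, (D2D2, T1T1) light, and
#' (D2D2, T1T2) none.  Non-carriers (R2R2) are `"none"` for every
#' modifier combination.  Carrier combinations outside the observed
#' table return the `"unclassified"` sentinel, never a guessed
#' class.
#'
#' @param bloodTe `"R1R2"` (carrier) or `"R2R2"` (non-carrier).
#' @param dHap one of `"D1D1"`, `"D1D2"`, `"D2D2"`.
#' @param tHap one of `"T1T1"`, `"T1T2"`, `"T2T2"`.
#' @return flesh class: `"dark"`, `"blood"`, `"light"`, `"none"` or
#'   `"unclassified"`.  Vectorised over its arguments.
#' @examples
#' colorIntensityRule("R1R2", "D1D1", "T1T1")  # dark
#' colorIntensityRule("R2R2", "D1D1", "T1T1")  # none
#' @export
colorIntensityRule <- function(bloodTe, dHap, tHap) {
  n <- max(length(bloodTe), length(dHap), length(tHap))
  bloodTe <- rep_len(bloodTe, n)
  dHap <- rep_len(dHap, n)
  tHap <- rep_len(tHap, n)
  if (anyNA(bloodTe) || anyNA(dHap) || anyNA(tHap))
    stop("missing genotype field")
  stopifnot(all(bloodTe %in% c("R1R1", "R1R2", "R2R2")),
            all(dHap %in% c("D1D1", "D1D2", "D2D2")),
            all(tHap %in% c("T1T1", "T1T2", "T2T2")))
  hit <- match(paste(dHap, tHap),
               paste(.COLOR_RULES$d_hap, .COLOR_RULES$t_hap))
  out <- ifelse(is.na(hit), "unclassified", .COLOR_RULES$flesh[hit])
  out[bloodTe == "R2R2"] <- "none"
  out
}

#' Classify fruit development period (days) into classes
#'
#' Bins: `[60, 90]`, `(90, 120]`, `(120, 150]` days -- boundary
#' values go to the lower class.  Values outside `[60, 150]` return
#' the `"out-of-range"` sentinel.
#'
#' @param fdpDays positive number of days from early full bloom to
#'   harvest maturity.
#' @return FDP class label; vectorised.
#' @export
fdpClassify <- function(fdpDays) {
  stopifnot(all(fdpDays > 0, na.rm = TRUE))
  out <- rep("out-of-range", length(fdpDays))
  out[fdpDays >= 60 & fdpDays <= 90] <- "60-90"
  out[fdpDays > 90 & fdpDays <= 120] <- "90-120"
  out[fdpDays > 120 & fdpDays <= 150] <- "120-150"
  out[is.na(fdpDays)] <- NA_character_
  out
}

#' Expected FDP class of a 9 bp-insertion genotype
#'
#' The maturity-date locus genotype maps 9/9 -> 60-90 days,
#' 0/9 -> 90-120, 0/0 -> 120-150.
#'
#' @param ins9 genotype string(s): `"9/9"`, `"0/9"` or `"0/0"`.
#' @return FDP class label; vectorised.
#' @export
genotypeExpectedFdp <- function(ins9) {
  out <- c("9/9" = "60-90", "0/9" = "90-120",
           "0/0" = "120-150")[ins9]
  if (anyNA(out)) stop("unknown ins9 genotype: ",
                       paste(ins9[is.na(out)], collapse = ", "))
  unname(out)
}

#' Per-group carrier ratios
#'
#' For each group of accessions, the number screened, the number
#' carrying the marker, and the carrier percentage rounded to the
#' integer (the precision such tables print).
#'
#' @param group group label per accession.
#' @param carrier logical carrier flag per accession.
#' @return data.frame with `group`, `n`, `carriers`, `percent`
#'   (integer-rounded) and `percent_raw`.
#' @examples
#' carrierRatio(rep(c("A", "B"), c(20, 22)),
#'              rep(c(TRUE, FALSE, TRUE, FALSE), c(7, 13, 10, 12)))
#' @export
carrierRatio <- function(group, carrier) {
  if (length(group) != length(carrier))
    stop("group and carrier must have the same length")
  if (!length(group)) stop("empty input")
  carrier <- as.logical(carrier)
  sp <- split(carrier, group)
  if (any(vapply(sp, length, 1L) == 0)) stop("empty group")
  data.frame(
    group = names(sp),
    n = vapply(sp, length, 1L),
    carriers = vapply(sp, sum, 1L),
    percent = vapply(sp, function(z) round(100 * mean(z)), 0),
    percent_raw = vapply(sp, function(z) 100 * mean(z), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}
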