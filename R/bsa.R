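# Euclidean-distance bulked-segregant scan: site filtering, pool
# frequencies, ED and ED^k, sliding windows, empirical threshold,
# candidate-interval calling.

.qualityClauses <- list(
  DP = function(s) !is.na(s$dp) & s$dp < 4,
  QD = function(s) !is.na(s$qd) & s$qd < 2.0,
  FS = function(s) !is.na(s$fs) & s$fs > 60.0,
  MQ = function(s) !is.na(s$mq) & s$mq < 40.0,
  MQRankSum = function(s) !is.na(s$mq_rank_sum) & s$mq_rank_sum < -12.5,
  ReadPosRankSum = function(s) !is.na(s$read_pos_rank_sum) &
    s$read_pos_rank_sum < -8.0
)

#' Filter SNP sites on GATK-style quality annotations
#'
#' A site is kept iff `dp >= 4` and no quality clause fails:
#' `qd >= 2.0`, `fs <= 60.0`, `mq >= 40.0`, `mq_rank_sum >= -12.5`,
#' `read_pos_rank_sum >= -8.0`.  The depth clause is applied as a
#' keep rule (low-depth sites are removed); missing annotations pass
#' unless `strict = TRUE`, in which case a missing annotation fails
#' its clause.
#'
#' @param sites site table (see [sampleAlleleDepths()] /
#'   [readSnpSites()]); missing annotation columns are treated as
#'   all-`NA`.
#' @param strict treat missing annotations as failing.
#' @return list with `kept` (passing rows) and `rejected` (dropped
#'   rows plus a `reason` column listing every failing clause,
#'   comma-separated).
#' @examples
#' s <- data.frame(chrom = "chr1", pos = 1:2, qd = c(1.5, 30),
#'                 fs = 0, mq = 60, mq_rank_sum = 0,
#'                 read_pos_rank_sum = 0, dp = 40)
#' filterSnps(s)$rejected$reason
#' @export
filterSnps <- function(sites, strict = FALSE) {
  need <- c("qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum", "dp")
  for (cn in need) if (!cn %in% colnames(sites)) sites[[cn]] <- NA_real_
  fails <- sapply(.qualityClauses, function(f) f(sites))
  if (nrow(sites) == 1L)
    fails <- matrix(fails, nrow = 1L,
                    dimnames = list(NULL, names(.qualityClauses)))
  if (strict) {
    na <- cbind(DP = is.na(sites$dp), QD = is.na(sites$qd),
                FS = is.na(sites$fs), MQ = is.na(sites$mq),
                MQRankSum = is.na(sites$mq_rank_sum),
                ReadPosRankSum = is.na(sites$read_pos_rank_sum))
    fails <- fails | na[, colnames(fails), drop = FALSE]
  }
  bad <- rowSums(fails) > 0
  reason <- apply(fails, 1L, function(z)
    paste(colnames(fails)[z], collapse = ","))
  rejected <- sites[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  list(kept = sites[!bad, , drop = FALSE], rejected = rejected)
}

#' Pool base-frequency vectors of one site
#'
#' @param site one-row site table with per-pool A/C/G/T counts.
#' @return list with numeric `mut` and `wt` vectors over (A, C, G, T)
#'   summing to 1, or `NA` vectors (and `usable = FALSE`) when a pool
#'   has zero depth.
#' @export
poolFrequencies <- function(site) {
  m <- as.numeric(site[1, c("A_mut", "C_mut", "G_mut", "T_mut")])
  w <- as.numeric(site[1, c("A_wt", "C_wt", "G_wt", "T_wt")])
  if (any(m < 0) || any(w < 0)) stop("negative allele depths")
  sm <- sum(m); sw <- sum(w)
  usable <- sm > 0 && sw > 0
  list(mut = if (sm > 0) setNames(m / sm, c("A", "C", "G", "T"))
             else setNames(rep(NA_real_, 4), c("A", "C", "G", "T")),
       wt = if (sw > 0) setNames(w / sw, c("A", "C", "G", "T"))
            else setNames(rep(NA_real_, 4), c("A", "C", "G", "T")),
       usable = usable)
}

#' Euclidean distance between two pool frequency vectors
#'
#' `ED = sqrt(sum_b (f_mut,b - f_wt,b)^2)` over the four bases.
#' Bounded by `sqrt(2)` (pools fixed for different bases) and
#' symmetric in its arguments.
#'
#' @param freqMut,freqWt numeric length-4 frequency vectors, each
#'   summing to 1 within 1e-9.
#' @return the ED value.
#' @examples
#' euclideanDistance(c(0.75, 0, 0.25, 0), c(0.25, 0, 0.75, 0))
#' @export
euclideanDistance <- function(freqMut, freqWt) {
  if (length(freqMut) != 4L || length(freqWt) != 4L)
    stop("frequency vectors must have length 4")
  if (any(freqMut < 0) || any(freqWt < 0) ||
      abs(sum(freqMut) - 1) > 1e-9 || abs(sum(freqWt) - 1) > 1e-9)
    stop("frequency vectors must be non-negative and sum to 1")
  sqrt(sum((freqMut - freqWt)^2))
}

#' Per-site ED for a whole site table
#'
#' Vectorised [euclideanDistance()] over a site table.  Sites where
#' either pool has zero total depth get `NA` (excluded from the
#' scan).
#'
#' @param sites site table with per-pool A/C/G/T counts.
#' @return `sites` with columns `ed` and `usable` appended.
#' @export
edStatistic <- function(sites) {
  m <- as.matrix(sites[, c("A_mut", "C_mut", "G_mut", "T_mut")])
  w <- as.matrix(sites[, c("A_wt", "C_wt", "G_wt", "T_wt")])
  if (any(m < 0) || any(w < 0)) stop("negative allele depths")
  sm <- rowSums(m); sw <- rowSums(w)
  usable <- sm > 0 & sw > 0
  fm <- m / ifelse(sm > 0, sm, NA_real_)
  fw <- w / ifelse(sw > 0, sw, NA_real_)
  sites$ed <- sqrt(rowSums((fm - fw)^2))
  sites$ed[!usable] <- NA_real_
  sites$usable <- usable
  sites
}

#' Power transform of ED values
#'
#' Raising ED to a power `k > 1` (5 in the default scan) sharpens
#' peaks relative to background before window smoothing; the
#' transform is strictly monotone on non-negative values, so window
#' rankings by a fixed site set are preserved.
#'
#' @param ed non-negative ED values.
#' @param power exponent `k >= 1`.
#' @return `ed ^ power`.
#' @export
transformEd <- function(ed, power = 5) {
  stopifnot(power >= 1)
  ed^power
}

.windowStarts <- function(chromLen, step) seq(1, chromLen, by = step)

#' Sliding-window aggregation of a per-site statistic
#'
#' Windows start at 1, 1 + step, 1 + 2 step, ... while the start does
#' not exceed the chromosome length; the final windows are truncated
#' at the chromosome end.  Each window aggregates (mean by default)
#' the statistic over sites with `start <= pos <= end`; windows with
#' fewer than `minSnps` sites carry `NA` and are excluded from
#' threshold estimation.
#'
#' @param sites site table with `chrom`, `pos` and the statistic
#'   column, sorted by (chrom, pos); rows with `NA` statistic are
#'   ignored.
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param window,step window and step size in bp (`0 < step <=
#'   window`).
#' @param statCol name of the statistic column.
#' @param aggregate `"mean"` or `"sum"`.
#' @param minSnps minimum sites for a defined window statistic.
#' @return `GRanges` of windows with metadata columns `n_snps` and
#'   `stat`.
#' @export
windowScan <- function(sites, chromLengths, window = 1e5, step = 1e4,
                       statCol = "stat", aggregate = c("mean", "sum"),
                       minSnps = 1L) {
  aggregate <- match.arg(aggregate)
  stopifnot(step > 0, step <= window, !is.null(names(chromLengths)))
  if (!statCol %in% colnames(sites)) stop("missing column: ", statCol)
  ord <- order(match(sites$chrom, names(chromLengths)), sites$pos)
  if (is.unsorted(ord)) stop("sites must be sorted by (chrom, pos)")
  if (!all(sites$chrom %in% names(chromLengths)))
    stop("sites on chromosomes without a known length")
  perChrom <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- .windowStarts(len, step)
    ends <- pmin(starts + window - 1, len)
    ss <- sites[sites$chrom == ch & !is.na(sites[[statCol]]), ,
                drop = FALSE]
    hits <- findOverlaps(IRanges(ss$pos, ss$pos),
                         IRanges(starts, ends))
    n <- tabulate(subjectHits(hits), nbins = length(starts))
    tot <- rep(0, length(starts))
    if (length(hits)) {
      agg <- rowsum(ss[[statCol]][queryHits(hits)], subjectHits(hits))
      tot[as.integer(rownames(agg))] <- agg[, 1L]
    }
    stat <- if (aggregate == "mean") ifelse(n > 0, tot / n, NA_real_)
            else ifelse(n > 0, tot, NA_real_)
    stat[n < minSnps] <- NA_real_
    data.frame(chrom = ch, start = starts, end = ends, n_snps = n,
               stat = stat, stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, perChrom)
  out <- GRanges(factor(win$chrom, levels = names(chromLengths)),
                 IRanges(win$start, win$end), n_snps = win$n_snps,
                 stat = win$stat)
  metadata(out) <- list(window = window, step = step,
                        aggregate = aggregate, minSnps = minSnps)
  out
}

#' Empirical scan threshold
#'
#' The screening threshold is the genome-wide empirical quantile (at
#' `level`, default the 95% level) of all defined window statistics,
#' computed with the linear-interpolation quantile (R type 7) so the
#' value is reproducible bit-for-bit.  A per-chromosome variant is
#' available via `perChrom = TRUE` (returns one threshold per
#' chromosome).
#'
#' @param windows `GRanges` from [windowScan()].
#' @param level quantile level in (0, 1).
#' @param perChrom compute thresholds per chromosome instead.
#' @return numeric threshold (named vector when `perChrom`), with
#'   attribute `nWindows` giving the number of contributing windows.
#' @export
computeThreshold <- function(windows, level = 0.95, perChrom = FALSE) {
  stopifnot(level > 0, level < 1)
  st <- windows$stat
  if (all(is.na(st))) stop("no defined window statistics")
  if (perChrom) {
    ch <- as.character(seqnames(windows))
    out <- vapply(split(st, ch), function(z)
      quantile(z, level, na.rm = TRUE, names = FALSE, type = 7), 0)
    attr(out, "nWindows") <- vapply(split(st, ch),
                                    function(z) sum(!is.na(z)), 0L)
    return(out)
  }
  out <- quantile(st, level, na.rm = TRUE, names = FALSE, type = 7)
  attr(out, "nWindows") <- sum(!is.na(st))
  out
}

#' Merge supra-threshold windows into candidate intervals
#'
#' Maximal runs of consecutive (start difference equal to the step)
#' same-chromosome windows with statistic strictly above the
#' threshold are merged; the interval spans the union of its member
#' windows.  The peak window is the member with the largest
#' statistic, ties broken towards the smaller start.
#'
#' @param windows `GRanges` from [windowScan()].
#' @param threshold scalar threshold (see [computeThreshold()]).
#' @param step window step in bp; taken from
#'   `metadata(windows)$step` when missing.
#' @return `GRanges` of candidate intervals with metadata columns
#'   `n_windows`, `max_stat`, `peak_start`, `peak_end`, sorted by
#'   decreasing `max_stat`.
#' @export
callCandidateIntervals <- function(windows, threshold, step = NULL) {
  if (is.null(step)) step <- metadata(windows)$step
  stopifnot(is.numeric(step), length(threshold) == 1L)
  sel <- !is.na(windows$stat) & windows$stat > threshold
  if (!any(sel)) {
    empty <- GRanges()
    mcols(empty) <- DataFrame(n_windows = integer(0),
                              max_stat = numeric(0),
                              peak_start = integer(0),
                              peak_end = integer(0))
    return(empty)
  }
  w <- windows[sel]
  w <- w[order(as.character(seqnames(w)), start(w))]
  ch <- as.character(seqnames(w))
  newRun <- c(TRUE, ch[-1] != ch[-length(w)] |
                diff(start(w)) != step)
  run <- cumsum(newRun)
  perRun <- lapply(split(seq_along(w), run), function(i) {
    ww <- w[i]
    pk <- which.max(ww$stat)
    GRanges(seqnames(ww)[1],
            IRanges(min(start(ww)), max(end(ww))),
            n_windows = length(ww), max_stat = max(ww$stat),
            peak_start = start(ww)[pk], peak_end = end(ww)[pk])
  })
  out <- do.call(c, unname(perRun))
  out[order(-out$max_stat, start(out))]
}

#' Run the full ED genome scan
#'
#' Pipeline: quality filtering ([filterSnps()]), per-site ED
#' ([edStatistic()]), power transform ([transformEd()]), sliding
#' windows ([windowScan()]), empirical threshold
#' ([computeThreshold()]) and candidate intervals
#' ([callCandidateIntervals()]).
#'
#' @param sites site table (see [readSnpSites()]).
#' @param chromLengths named chromosome lengths in bp.
#' @param window,step window and step size in bp.
#' @param power ED exponent.
#' @param level threshold quantile level.
#' @param aggregate window aggregation, `"mean"` or `"sum"`.
#' @param minSnps minimum SNPs per defined window.
#' @param filter apply the quality filter first.
#' @param strict strict missing-annotation handling (see
#'   [filterSnps()]).
#' @return a [BsaScan-class].
#' @examples
#' sim <- simulateBsaExperiment(simConfig(seed = 1, nChrom = 4L,
#'                                        chromLen = 1e6,
#'                                        causalChrom = "chr2",
#'                                        causalPos = 5e5))
#' scan <- bsaScan(sim$sites, sim$chromLengths)
#' candidateIntervals(scan)
#' @export
bsaScan <- function(sites, chromLengths, window = 1e5, step = 1e4,
                    power = 5, level = 0.95,
                    aggregate = c("mean", "sum"), minSnps = 1L,
                    filter = TRUE, strict = FALSE) {
  aggregate <- match.arg(aggregate)
  nIn <- nrow(sites)
  rejected <- sites[0, , drop = FALSE]
  if (filter) {
    fl <- filterSnps(sites, strict = strict)
    sites <- fl$kept
    rejected <- fl$rejected
  }
  sites <- edStatistic(sites)
  sites$stat <- transformEd(sites$ed, power)
  sites <- sites[order(match(sites$chrom, names(chromLengths)),
                       sites$pos), , drop = FALSE]
  windows <- windowScan(sites, chromLengths, window = window,
                        step = step, statCol = "stat",
                        aggregate = aggregate, minSnps = minSnps)
  threshold <- computeThreshold(windows, level)
  intervals <- callCandidateIntervals(windows, threshold, step = step)
  new("BsaScan", windows = windows,
      threshold = as.numeric(threshold), level = level,
      intervals = intervals,
      nSites = as.integer(sum(!is.na(sites$stat))),
      params = list(window = window, step = step, power = power,
                    level = level, aggregate = aggregate,
                    minSnps = minSnps, filter = filter,
                    strict = strict, nInput = nIn,
                    nRejected = nrow(rejected),
                    nWindows = attr(threshold, "nWindows")))
}

#' Plot a scan
#'
#' Simple per-chromosome base-graphics view of the window statistics
#' with the threshold line and candidate intervals.
#'
#' @param x a [BsaScan-class].
#' @param chrom chromosome to plot (default: first).
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plotScan <- function(x, chrom = NULL, ...) {
  stopifnot(is(x, "BsaScan"))
  w <- windowStats(x)
  if (is.null(chrom)) chrom <- as.character(seqnames(w))[1]
  w <- w[as.character(seqnames(w)) == chrom]
  mid <- (start(w) + end(w)) / 2
  plot(mid / 1e6, w$stat, type = "l", xlab = paste(chrom, "(Mb)"),
       ylab = "window ED^k", ...)
  abline(h = scanThreshold(x), lty = 2)
  iv <- candidateIntervals(x)
  iv <- iv[as.character(seqnames(iv)) == chrom]
  if (length(iv))
    points((start(iv) + end(iv)) / 2e6,
           rep(max(w$stat, na.rm = TRUE), length(iv)), pch = 25)
  invisible(x)
}
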