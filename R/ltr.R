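# Flank-anchored cross-assembly classification of intact LTR-RTs and
# twin-LTR insertion-age dating.
#
# The anchoring aligner is deliberately simple and deterministic:
# exact k-mer seeding (k = 31) followed by ungapped rescoring of the
# whole flank at each candidate offset, match +1 / mismatch -1.  Its
# output contract (best hit, second-best score, uniqueness flag) is
# the same shape an external mapper's hit table would provide.

.LTR_LABELS <- c("HIGH_SHARED", "LOW_SHARED", "INSERTION",
                 "ELIMINATION", "UNKNOWN")

#' Default classifier thresholds
#'
#' Identity/coverage bounds separating the five classes, the paired
#' anchor span limit, and the adjacency tolerance under which the two
#' anchors are considered to abut (element absent).
#'
#' @param hiId,hiCov high-shared identity and coverage bounds.
#' @param loId,loCov low-shared bounds.
#' @param gapTol anchors closer than this (bp) mean "absent".
#' @param maxSpan maximum anchor span on the target (bp).
#' @param lengthTol relative tolerance of the anchor gap around the
#'   element length for "present" geometry.
#' @return named list of thresholds.
#' @export
ltrThresholds <- function(hiId = 0.95, hiCov = 0.95, loId = 0.80,
                          loCov = 0.50, gapTol = 1000,
                          maxSpan = 20000, lengthTol = 0.20) {
  list(hiId = hiId, hiCov = hiCov, loId = loId, loCov = loCov,
       gapTol = gapTol, maxSpan = maxSpan, lengthTol = lengthTol)
}

#' Keep intact elements by length
#'
#' Intact LTR-RTs are restricted to total lengths between 2000 and
#' 7000 bp (inclusive).
#'
#' @param elements element table with `start`, `end` (1-based
#'   inclusive).
#' @param range inclusive length bounds.
#' @return the rows whose `end - start + 1` lies within `range`.
#' @export
filterIntact <- function(elements, range = c(2000, 7000)) {
  len <- elements$end - elements$start + 1
  elements[len >= range[1] & len <= range[2], , drop = FALSE]
}

#' Extract the 500 bp flanks of an element
#'
#' Up flank is `[start - flankLen, start - 1]`, down flank
#' `[end + 1, end + flankLen]`, both clipped at the contig ends.  A
#' flank shorter than `minFlank` after clipping is returned as `NA`
#' (the element cannot be anchored on that side).
#'
#' @param element one element-table row (`contig`, `start`, `end`).
#' @param genome `DNAStringSet` holding the contig.
#' @param flankLen flank length in bp.
#' @param minFlank minimum usable flank length after clipping.
#' @return list with character scalars `up` and `down` (`NA` when
#'   too short).
#' @export
extractFlanks <- function(element, genome, flankLen = 500,
                          minFlank = 100) {
  ct <- element$contig[1]
  if (!ct %in% names(genome)) stop("unknown contig: ", ct)
  len <- width(genome)[match(ct, names(genome))]
  if (element$start[1] < 1 || element$end[1] > len)
    stop("element outside contig bounds")
  upFrom <- max(1, element$start[1] - flankLen)
  upTo <- element$start[1] - 1
  dnFrom <- element$end[1] + 1
  dnTo <- min(len, element$end[1] + flankLen)
  up <- if (upTo - upFrom + 1 >= minFlank)
    as.character(subseq(genome[[ct]], upFrom, upTo)) else NA_character_
  dn <- if (dnTo - dnFrom + 1 >= minFlank)
    as.character(subseq(genome[[ct]], dnFrom, dnTo)) else NA_character_
  list(up = up, down = dn)
}

# Ungapped +1/-1 score of `flank` laid on `contigSeq` starting at
# `at`; candidates extending past the contig are rejected (-Inf).
.ungappedScore <- function(flankChars, contigSeq, at) {
  L <- length(flankChars)
  if (at < 1 || at + L - 1 > nchar(contigSeq)) return(-Inf)
  tgt <- strsplit(substr(contigSeq, at, at + L - 1), "",
                  fixed = TRUE)[[1]]
  m <- sum(flankChars == tgt)
  2 * m - L
}

#' Anchor one flank on a target genome
#'
#' Exact `k`-mer seeds taken along the flank (every `seedStep` bp
#' plus the final position) are located in the target with
#' [Biostrings::matchPattern()]; each seed match implies a candidate
#' placement of the whole flank, which is rescored ungapped at
#' +1/-1.  Both orientations are searched.  The hit is `unique` iff
#' the best score reaches `minScore` and exceeds the second-best
#' candidate by at least `margin`.
#'
#' @param flank flank sequence (character scalar).
#' @param target `DNAStringSet`.
#' @param k seed length.
#' @param seedStep spacing of seed start positions along the flank.
#' @param margin uniqueness margin; default `0.1 * nchar(flank)`.
#' @param minScore minimum best score; default `0.5 * nchar(flank)`.
#' @return list: `found`, `contig`, `start`, `strand`, `score`,
#'   `secondBest`, `unique`, `flankLen`.
#' @export
anchorFlank <- function(flank, target, k = 31L, seedStep = 97L,
                        margin = NULL, minScore = NULL) {
  if (is.na(flank) || nchar(flank) == 0) stop("empty flank")
  L <- nchar(flank)
  if (is.null(margin)) margin <- 0.1 * L
  if (is.null(minScore)) minScore <- 0.5 * L
  if (L < k) stop("flank shorter than seed length")
  tgtChar <- as.character(target)
  orientations <- list(`+` = flank,
                       `-` = as.character(
                         reverseComplement(DNAString(flank))))
  cand <- NULL
  for (strand in names(orientations)) {
    fl <- orientations[[strand]]
    flChars <- strsplit(fl, "", fixed = TRUE)[[1]]
    offs <- unique(c(seq(1L, L - k + 1L, by = seedStep), L - k + 1L))
    for (ct in names(target)) {
      starts <- integer(0)
      for (o in offs) {
        seed <- substr(fl, o, o + k - 1L)
        hits <- matchPattern(seed, target[[ct]])
        if (length(hits))
          starts <- c(starts, start(hits) - o + 1L)
      }
      starts <- unique(starts)
      for (at in starts) {
        sc <- .ungappedScore(flChars, tgtChar[[ct]], at)
        if (is.finite(sc))
          cand <- rbind(cand, data.frame(
            contig = ct, start = at, strand = strand, score = sc,
            stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(cand) || nrow(cand) == 0)
    return(list(found = FALSE, contig = NA_character_,
                start = NA_integer_, strand = NA_character_,
                score = -Inf, secondBest = -Inf, unique = FALSE,
                flankLen = L))
  cand <- cand[order(-cand$score, cand$contig, cand$start), ,
               drop = FALSE]
  best <- cand[1L, ]
  second <- if (nrow(cand) > 1L) cand$score[2L] else -L
  list(found = TRUE, contig = best$contig, start = best$start,
       strand = best$strand, score = best$score, secondBest = second,
       unique = best$score >= minScore &&
         (best$score - second) >= margin,
       flankLen = L)
}

#' Pair the two flank anchors of an element
#'
#' Anchors are retained when both are unique, on the same target
#' contig, in the same orientation, and the distance between their
#' inner ends does not exceed `maxSpan` (20 kb).  The inner gap `g`
#' (bp of target between the two anchored flanks) is approximately
#' the element length when a copy is present and about zero (one TSD
#' copy) when it is absent.
#'
#' @param upHit,downHit [anchorFlank()] results for the up and down
#'   flank.
#' @param thresholds see [ltrThresholds()].
#' @return list: `status` (`"paired"` or `"unpaired"`), `gap`,
#'   `contig`, `strand`.
#' @export
pairAnchors <- function(upHit, downHit, thresholds = ltrThresholds()) {
  unpaired <- list(status = "unpaired", gap = NA_real_,
                   contig = NA_character_, strand = NA_character_)
  if (!isTRUE(upHit$unique) || !isTRUE(downHit$unique))
    return(unpaired)
  if (upHit$contig != downHit$contig ||
      upHit$strand != downHit$strand)
    return(unpaired)
  if (upHit$strand == "+") {
    g <- downHit$start - (upHit$start + upHit$flankLen - 1L) - 1L
    innerFrom <- upHit$start + upHit$flankLen
    innerTo <- downHit$start - 1L
  } else {
    g <- upHit$start - (downHit$start + downHit$flankLen - 1L) - 1L
    innerFrom <- downHit$start + downHit$flankLen
    innerTo <- upHit$start - 1L
  }
  if (abs(g) > thresholds$maxSpan) return(unpaired)
  list(status = "paired", gap = as.numeric(g), contig = upHit$contig,
       strand = upHit$strand, innerFrom = innerFrom, innerTo = innerTo)
}

# Global alignment identity/coverage of the query middle against the
# target span between the anchors.
.middleAlignment <- function(queryMid, targetSpan) {
  aln <- pairwiseAlignment(DNAString(queryMid), DNAString(targetSpan),
                           type = "global")
  alnLen <- nchar(as.character(alignedPattern(aln)))
  pairs <- nmatch(aln) + nmismatch(aln)
  list(identity = if (alnLen > 0) nmatch(aln) / alnLen else 0,
       coverage = pairs / nchar(queryMid))
}

#' Classify one element against a target genome
#'
#' Decision rule, given the paired-anchor geometry:
#' * anchors abut (`gap <= gapTol`) -> `INSERTION` (present in the
#'   query, absent from the target);
#' * gap within the element length +/- `lengthTol` -> the query
#'   middle is aligned to the target span between the anchors:
#'   identity >= `hiId` and coverage >= `hiCov` -> `HIGH_SHARED`;
#'   identity >= `loId` and coverage >= `loCov` -> `LOW_SHARED`;
#'   otherwise `ELIMINATION` (a decayed target copy);
#' * any other geometry (unpaired anchors, missing flank,
#'   out-of-range gap) -> `UNKNOWN`.
#'
#' @param element element-table row.
#' @param queryGenome,targetGenome `DNAStringSet`s.
#' @param thresholds see [ltrThresholds()].
#' @param flankLen,minFlank see [extractFlanks()].
#' @param ... passed to [anchorFlank()].
#' @return one-row data.frame: `id`, `label`, `identity`, `coverage`,
#'   `gap`, `target_contig`, `strand`, `reason`.
#' @export
classifyElement <- function(element, queryGenome, targetGenome,
                            thresholds = ltrThresholds(),
                            flankLen = 500, minFlank = 100, ...) {
  res <- data.frame(id = element$id[1], label = "UNKNOWN",
                    identity = NA_real_, coverage = NA_real_,
                    gap = NA_real_, target_contig = NA_character_,
                    strand = NA_character_, reason = "",
                    stringsAsFactors = FALSE)
  fl <- extractFlanks(element, queryGenome, flankLen, minFlank)
  if (is.na(fl$up) || is.na(fl$down)) {
    res$reason <- "flank_too_short"
    return(res)
  }
  up <- anchorFlank(fl$up, targetGenome, ...)
  dn <- anchorFlank(fl$down, targetGenome, ...)
  geom <- pairAnchors(up, dn, thresholds)
  if (geom$status != "paired") {
    res$reason <- "anchors_unpaired"
    return(res)
  }
  res$gap <- geom$gap
  res$target_contig <- geom$contig
  res$strand <- geom$strand
  elen <- element$end[1] - element$start[1] + 1
  if (geom$gap <= thresholds$gapTol) {
    res$label <- "INSERTION"
    res$reason <- "anchors_adjacent"
    return(res)
  }
  if (geom$gap < (1 - thresholds$lengthTol) * elen ||
      geom$gap > (1 + thresholds$lengthTol) * elen) {
    res$reason <- "gap_out_of_range"
    return(res)
  }
  queryMid <- elementSequence(queryGenome, element)
  span <- as.character(subseq(targetGenome[[geom$contig]],
                              geom$innerFrom, geom$innerTo))
  if (geom$strand == "-")
    span <- as.character(reverseComplement(DNAString(span)))
  st <- .middleAlignment(queryMid, span)
  res$identity <- st$identity
  res$coverage <- st$coverage
  res$label <- if (st$identity >= thresholds$hiId &&
                   st$coverage >= thresholds$hiCov) "HIGH_SHARED"
    else if (st$identity >= thresholds$loId &&
             st$coverage >= thresholds$loCov) "LOW_SHARED"
    else "ELIMINATION"
  res$reason <- "middle_compared"
  res
}

#' Classify all intact elements of a query genome
#'
#' Applies [filterIntact()] then [classifyElement()] to every
#' element.  Classification is total: every retained element gets
#' exactly one of the five labels.
#'
#' @param queryGenome,targetGenome `DNAStringSet`s.
#' @param elements element table (see [plantElements()] or
#'   [readElementsGff3()]).
#' @param thresholds see [ltrThresholds()].
#' @param intactRange length bounds for [filterIntact()]; `NULL`
#'   keeps all.
#' @param ... passed to [classifyElement()].
#' @return `DataFrame` with one row per retained element and a
#'   per-class count summary in its metadata.
#' @examples
#' set.seed(7)
#' host <- randomGenome(c(ctg1 = 60000))
#' pl <- plantElements(host, sampleElementSpecs(host, 4))
#' cls <- classifyElements(pl$genome, pl$genome, pl$elements)
#' table(cls$label)  # self-comparison: all HIGH_SHARED
#' @export
classifyElements <- function(queryGenome, targetGenome, elements,
                             thresholds = ltrThresholds(),
                             intactRange = c(2000, 7000), ...) {
  if (!is.null(intactRange))
    elements <- filterIntact(elements, intactRange)
  rows <- lapply(seq_len(nrow(elements)), function(i)
    classifyElement(elements[i, , drop = FALSE], queryGenome,
                    targetGenome, thresholds, ...))
  out <- DataFrame(do.call(rbind, rows))
  metadata(out) <- list(
    classCounts = table(factor(out$label, levels = .LTR_LABELS)),
    thresholds = thresholds)
  out
}

#' Twin-LTR insertion age under a Jukes-Cantor clock
#'
#' The two LTRs of an element are identical at insertion and diverge
#' neutrally afterwards, so the insertion age is `T = K / (2 mu)`
#' where `K` is the Jukes-Cantor-corrected divergence between the
#' 5' and 3' LTR copies and `mu` the substitution rate per site per
#' year.  The raw mismatch proportion `d` is computed over gap-free
#' columns of a global alignment of the two copies;
#' `K = -(3/4) log(1 - (4/3) d)`.
#'
#' @param ltr5,ltr3 the two LTR sequences (character or
#'   `DNAString`).
#' @param mu substitution rate per site per year (default 1.5e-8).
#' @return data.frame with `d`, `K`, `mu`, `years`, `mya`.
#' @examples
#' estimateAge("ACGTACGT", "ACGTACGT")$years  # 0
#' @export
estimateAge <- function(ltr5, ltr3, mu = 1.5e-8) {
  stopifnot(mu > 0)
  aln <- pairwiseAlignment(DNAString(as.character(ltr5)),
                           DNAString(as.character(ltr3)),
                           type = "global")
  cols <- nmatch(aln) + nmismatch(aln)   # gap-free columns only
  if (cols == 0) stop("no alignable gap-free columns")
  d <- nmismatch(aln) / cols
  if (d >= 0.75)
    stop("JC saturation: d = ", signif(d, 4), " >= 0.75")
  K <- -0.75 * log(1 - 4 * d / 3)
  T <- K / (2 * mu)
  data.frame(d = d, K = K, mu = mu, years = T, mya = T / 1e6)
}

#' Insertion ages of a set of planted/annotated elements
#'
#' @param elements element table with LTR spans (`ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end`).
#' @param genome `DNAStringSet` the coordinates refer to.
#' @param mu substitution rate per site per year.
#' @return data.frame with one row per element (`id`, `d`, `K`,
#'   `mu`, `years`, `mya`).
#' @export
ltrAges <- function(elements, genome, mu = 1.5e-8) {
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    a <- estimateAge(
      subseq(genome[[e$contig]], e$ltr5_start, e$ltr5_end),
      subseq(genome[[e$contig]], e$ltr3_start, e$ltr3_end), mu)
    cbind(data.frame(id = e$id, stringsAsFactors = FALSE), a)
  })
  do.call(rbind, rows)
}
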