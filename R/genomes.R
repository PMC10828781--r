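# Genome fixtures: random host sequences, planted intact LTR-RT
# elements with target-site duplications, and derived target genomes
# with per-element presence/absence edits.  Genomes at this scale
# (a few hundred kb to a few Mb) are manipulated as character
# strings and wrapped as DNAStringSet at the boundary.

.BASES <- c("A", "C", "G", "T")

.randomBases <- function(n, gc = 0.38) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Random host genome
#'
#' I.i.d. nucleotide sequences at a given GC content (default 38%,
#' typical of a peach assembly).
#'
#' @param lengths named numeric vector of contig lengths (bp).
#' @param gc GC content in (0, 1).
#' @return a `DNAStringSet`.
#' @export
randomGenome <- function(lengths, gc = 0.38) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1))
  DNAStringSet(setNames(vapply(lengths, function(n)
    .randomBases(n, gc), ""), names(lengths)))
}

.mutateSequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit))
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(.BASES, b), 1L), "")
  paste(ch, collapse = "")
}

#' Random specifications of intact LTR-RT elements to plant
#'
#' Draws non-conflicting insertion points along the contigs of a
#' host genome, leaving `minGap` bp between consecutive insertion
#' points (room for flank extraction and flank-deletion edits), and
#' random LTR / internal sequences whose total length falls in
#' `lengthRange`.
#'
#' @param genome host `DNAStringSet`.
#' @param n number of elements.
#' @param ltrLenRange,lengthRange LTR length and total element
#'   length bounds (bp).
#' @param tsdLen target-site duplication length (bp).
#' @param perLtrDivergence per-LTR-copy point-mutation proportion
#'   applied at planting.
#' @param minGap minimum spacing between insertion points (bp).
#' @return data.frame of [plantElements()] specs.
#' @export
sampleElementSpecs <- function(genome, n, ltrLenRange = c(300, 500),
                               lengthRange = c(2000, 3000),
                               tsdLen = 5L, perLtrDivergence = 0,
                               minGap = 4000) {
  lens <- setNames(width(genome), names(genome))
  margin <- 2000
  slots <- do.call(rbind, lapply(names(lens), function(ct) {
    pos <- seq(margin, lens[[ct]] - margin, by = minGap)
    if (!length(pos)) return(NULL)
    data.frame(contig = ct, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(slots) || nrow(slots) < n)
    stop("genome too small for ", n, " elements at minGap ", minGap)
  slots <- slots[sort(sample(nrow(slots), n)), , drop = FALSE]
  ltrLen <- sample(seq(ltrLenRange[1], ltrLenRange[2]), n,
                   replace = TRUE)
  totLen <- sample(seq(lengthRange[1], lengthRange[2]), n,
                   replace = TRUE)
  totLen <- pmax(totLen, 2 * ltrLen + 100)
  data.frame(id = sprintf("ltr_%03d", seq_len(n)),
             contig = slots$contig, pos = slots$pos,
             ltr_seq = vapply(ltrLen, .randomBases, ""),
             internal_seq = vapply(totLen - 2 * ltrLen,
                                   .randomBases, ""),
             tsd_len = as.integer(tsdLen),
             per_ltr_divergence = perLtrDivergence,
             stringsAsFactors = FALSE)
}

#' Plant intact LTR-RT elements into a genome
#'
#' Each element (5' LTR + internal region + 3' LTR) is inserted
#' immediately after its insertion point; the `tsd_len` host bases
#' ending at the insertion point are duplicated after the element,
#' emulating the target-site duplication of a retrotransposition
#' event.  The two LTR copies receive independent point mutations at
#' `per_ltr_divergence` before insertion.  The returned truth table
#' records final 1-based inclusive element and LTR coordinates in
#' the output genome.
#'
#' @param genome host `DNAStringSet`.
#' @param specs data.frame with columns `id`, `contig`, `pos`
#'   (1-based insertion point), `ltr_seq`, `internal_seq`, and
#'   optionally `tsd_len` (default 5) and `per_ltr_divergence`
#'   (default 0).
#' @param lengthRange permissible total element length; `NULL`
#'   disables the check.
#' @return list with `genome` (the query `DNAStringSet`) and
#'   `elements`, a truth data.frame with columns `id`, `contig`,
#'   `start`, `end`, `length`, `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end`, `tsd_len`.
#' @export
plantElements <- function(genome, specs, lengthRange = c(2000, 7000)) {
  stopifnot(is(genome, "DNAStringSet"),
            all(c("id", "contig", "pos", "ltr_seq", "internal_seq")
                %in% colnames(specs)))
  if (anyDuplicated(specs$id)) stop("duplicate element ids")
  if (!"tsd_len" %in% colnames(specs)) specs$tsd_len <- 5L
  if (!"per_ltr_divergence" %in% colnames(specs))
    specs$per_ltr_divergence <- 0
  if (!all(specs$contig %in% names(genome)))
    stop("unknown contig(s): ",
         paste(setdiff(specs$contig, names(genome)), collapse = ", "))
  lens <- setNames(width(genome), names(genome))
  if (any(specs$pos < specs$tsd_len) ||
      any(specs$pos > lens[specs$contig]))
    stop("insertion points must lie in [tsd_len, contig length]")
  elen <- 2L * nchar(specs$ltr_seq) + nchar(specs$internal_seq)
  if (!is.null(lengthRange) &&
      (any(elen < lengthRange[1]) || any(elen > lengthRange[2])))
    stop("element length outside [", lengthRange[1], ", ",
         lengthRange[2], "]: ",
         paste(specs$id[elen < lengthRange[1] | elen > lengthRange[2]],
               collapse = ", "))
  # conflicting insertions: TSD source regions may not overlap
  conflict <- unlist(lapply(split(specs, specs$contig), function(s) {
    s <- s[order(s$pos), ]
    if (nrow(s) < 2) return(character(0))
    close <- which(diff(s$pos) < pmax(s$tsd_len[-nrow(s)],
                                      s$tsd_len[-1]))
    unique(c(s$id[close], s$id[close + 1L]))
  }))
  if (length(conflict))
    stop("overlapping insertions: ", paste(conflict, collapse = ", "))
  truth <- NULL
  out <- as.character(genome)
  for (ct in unique(specs$contig)) {
    s <- specs[specs$contig == ct, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    host <- out[[ct]]
    pieces <- character(0)
    prev <- 0L
    offset <- 0L
    for (i in seq_len(nrow(s))) {
      p <- s$pos[i]
      tsd <- substr(host, p - s$tsd_len[i] + 1L, p)
      ltr5 <- .mutateSequence(s$ltr_seq[i], s$per_ltr_divergence[i])
      ltr3 <- .mutateSequence(s$ltr_seq[i], s$per_ltr_divergence[i])
      element <- paste0(ltr5, s$internal_seq[i], ltr3)
      pieces <- c(pieces, substr(host, prev + 1L, p), element, tsd)
      eStart <- p + offset + 1L
      eLen <- nchar(element)
      lL <- nchar(ltr5)
      truth <- rbind(truth, data.frame(
        id = s$id[i], contig = ct, start = eStart,
        end = eStart + eLen - 1L, length = eLen,
        ltr5_start = eStart, ltr5_end = eStart + lL - 1L,
        ltr3_start = eStart + eLen - lL, ltr3_end = eStart + eLen - 1L,
        tsd_len = s$tsd_len[i], stringsAsFactors = FALSE))
      offset <- offset + eLen + s$tsd_len[i]
      prev <- p
    }
    pieces <- c(pieces, substr(host, prev + 1L, nchar(host)))
    out[[ct]] <- paste(pieces, collapse = "")
  }
  truth <- truth[match(specs$id, truth$id), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = DNAStringSet(out), elements = truth)
}

#' Extract an element's sequence from its genome
#'
#' @param genome `DNAStringSet`.
#' @param element one row of a [plantElements()] truth table (or any
#'   data.frame row with `contig`, `start`, `end`).
#' @return the element sequence as a character scalar.
#' @export
elementSequence <- function(genome, element) {
  as.character(subseq(genome[[element$contig[1]]],
                      element$start[1], element$end[1]))
}

#' Derive a target genome by editing planted elements
#'
#' Applies one action per element to produce a second ("target")
#' assembly together with the classification label the flank-anchored
#' classifier is expected to assign:
#'
#' * `keep` -- untouched; expected `HIGH_SHARED`.
#' * `degrade_element` -- the element span is point-mutated down to
#'   `degradeIdentity`; expected `LOW_SHARED` when the identity is at
#'   least `loId`, `ELIMINATION` below it.
#' * `delete_element` -- element plus one TSD copy removed, restoring
#'   the pre-insertion haplotype; expected `INSERTION` (present in
#'   the query only).
#' * `delete_flank` -- `flankDeletion` bp immediately upstream of the
#'   element removed, destroying the up-flank anchor; expected
#'   `UNKNOWN`.
#'
#' @param genome query `DNAStringSet` from [plantElements()].
#' @param elements its truth table.
#' @param actions named character vector (element id -> action).
#' @param degradeIdentity target identity of degraded elements.
#' @param flankDeletion bp removed by `delete_flank`.
#' @param loId classifier low-shared identity bound used to derive
#'   the expected label of degraded elements.
#' @return list with `genome` (target `DNAStringSet`) and `expected`,
#'   a data.frame of `id`, `action`, `expected`.
#' @export
deriveTargetGenome <- function(genome, elements, actions,
                               degradeIdentity = 0.85,
                               flankDeletion = 600, loId = 0.80) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(actions)))
  unknown <- setdiff(names(actions), elements$id)
  if (length(unknown))
    stop("unknown element id(s): ", paste(unknown, collapse = ", "))
  ok <- c("keep", "delete_element", "degrade_element", "delete_flank")
  if (!all(actions %in% ok))
    stop("unknown action(s): ",
         paste(setdiff(actions, ok), collapse = ", "))
  out <- as.character(genome)
  el <- elements[match(names(actions), elements$id), , drop = FALSE]
  el$action <- unname(actions)
  for (ct in unique(el$contig)) {
    s <- el[el$contig == ct, , drop = FALSE]
    s <- s[order(-s$start), , drop = FALSE]        # right to left
    g <- out[[ct]]
    for (i in seq_len(nrow(s))) {
      a <- s$action[i]
      if (a == "keep") next
      if (a == "delete_element") {
        g <- paste0(substr(g, 1L, s$start[i] - 1L),
                    substr(g, s$end[i] + s$tsd_len[i] + 1L, nchar(g)))
      } else if (a == "degrade_element") {
        mid <- .mutateSequence(substr(g, s$start[i], s$end[i]),
                               1 - degradeIdentity)
        g <- paste0(substr(g, 1L, s$start[i] - 1L), mid,
                    substr(g, s$end[i] + 1L, nchar(g)))
      } else if (a == "delete_flank") {
        from <- max(1L, s$start[i] - flankDeletion)
        g <- paste0(substr(g, 1L, from - 1L),
                    substr(g, s$start[i], nchar(g)))
      }
    }
    out[[ct]] <- g
  }
  expected <- vapply(unname(actions), function(a) switch(a,
    keep = "HIGH_SHARED",
    delete_element = "INSERTION",
    degrade_element = if (degradeIdentity >= loId) "LOW_SHARED"
                      else "ELIMINATION",
    delete_flank = "UNKNOWN"), "")
  list(genome = DNAStringSet(out),
       expected = data.frame(id = names(actions),
                             action = unname(actions),
                             expected = expected,
                             stringsAsFactors = FALSE))
}
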