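# Readers and writers for the formats the pipeline touches, and the
# 1-based-inclusive <-> BED coordinate conversion done only at the
# boundary.

.SITE_NUMERIC <- c("pos", "A_mut", "C_mut", "G_mut", "T_mut",
                   "A_wt", "C_wt", "G_wt", "T_wt", "qd", "fs", "mq",
                   "mq_rank_sum", "read_pos_rank_sum", "dp")

#' Write a site table as TSV
#'
#' @param sites site table (see [sampleAlleleDepths()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeSnpSites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a site table
#'
#' Reads the package's TSV dialect (one row per SNP, per-pool
#' A/C/G/T depths, GATK-style annotations) or a two-sample VCF whose
#' `AD` FORMAT field carries the pooled allele depths.  Malformed
#' TSV rows (negative depths, missing position) are dropped and
#' reported with their line numbers.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param mutSample,wtSample for VCF input, sample names mapped to
#'   the mutant and wild-type pool.
#' @return site table data.frame; dropped TSV rows are reported in
#'   attribute `rejectedLines`.
#' @export
readSnpSites <- function(path, dialect = c("tsv", "vcf"),
                         mutSample = NULL, wtSample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "vcf")
    return(.readSitesVcf(path, mutSample, wtSample))
  sites <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "A_mut", "C_mut", "G_mut", "T_mut",
            "A_wt", "C_wt", "G_wt", "T_wt")
  miss <- setdiff(need, colnames(sites))
  if (length(miss))
    stop("site table lacks column(s): ", paste(miss, collapse = ", "))
  depthCols <- grep("_(mut|wt)$", need, value = TRUE)
  bad <- is.na(sites$pos) |
    rowSums(is.na(sites[depthCols]) | sites[depthCols] < 0) > 0
  if (any(bad))
    warning(sum(bad), " malformed row(s) dropped (lines ",
            paste(which(bad) + 1L, collapse = ", "), ")")
  out <- sites[!bad, , drop = FALSE]
  attr(out, "rejectedLines") <- which(bad) + 1L
  out
}

.readSitesVcf <- function(path, mutSample, wtSample) {
  if (is.null(mutSample) || is.null(wtSample))
    stop("VCF input needs mutSample and wtSample names")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  samples <- colnames(vcf)
  miss <- setdiff(c(mutSample, wtSample), samples)
  if (length(miss))
    stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD FORMAT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altL <- lapply(rr$ALT, as.character)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_along(rr), function(i) {
    alleles <- c(ref[i], altL[[i]])
    if (any(nchar(alleles) != 1) || !all(alleles %in% bases))
      return(NULL)                     # biallelic/multiallelic SNVs only
    fill <- function(sample) {
      depths <- setNames(rep(0, 4), bases)
      adi <- ad[i, sample][[1]]
      k <- min(length(adi), length(alleles))
      for (j in seq_len(k))
        if (!is.na(adi[j]))
          depths[alleles[j]] <- depths[alleles[j]] + adi[j]
      depths
    }
    m <- fill(mutSample); w <- fill(wtSample)
    data.frame(chrom = as.character(seqnames(rr)[i]),
               pos = start(rr)[i], ref = ref[i],
               alt = altL[[i]][1],
               A_mut = m["A"], C_mut = m["C"], G_mut = m["G"],
               T_mut = m["T"],
               A_wt = w["A"], C_wt = w["C"], G_wt = w["G"],
               T_wt = w["T"],
               qd = NA_real_, fs = NA_real_, mq = NA_real_,
               mq_rank_sum = NA_real_, read_pos_rank_sum = NA_real_,
               dp = sum(m) + sum(w),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable SNV records in ", path)
  rownames(out) <- NULL
  out
}

#' Read chromosome lengths
#'
#' Accepts a samtools `.fai` index or any headerless tab-separated
#' file whose first two columns are contig name and length.
#'
#' @param path input file.
#' @return named numeric vector of lengths.
#' @export
readChromLengths <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected at least two columns")
  setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Convert 1-based inclusive intervals to BED records
#'
#' @param intervals `GRanges` or data.frame with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return data.frame with BED columns `chrom`, `start` (0-based),
#'   `end` (half-open).
#' @examples
#' intervalsToBed(data.frame(chrom = "chr1", start = 1, end = 100))
#' @export
intervalsToBed <- function(intervals) {
  if (is(intervals, "GRanges")) {
    df <- data.frame(chrom = as.character(seqnames(intervals)),
                     start = start(intervals), end = end(intervals),
                     stringsAsFactors = FALSE)
  } else df <- intervals
  if (any(df$start < 1)) stop("1-based starts must be >= 1")
  data.frame(chrom = df$chrom, start = df$start - 1, end = df$end,
             stringsAsFactors = FALSE)
}

#' Convert BED records to 1-based inclusive intervals
#'
#' @param bed data.frame with BED `chrom`, `start`, `end`.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
bedToIntervals <- function(bed) {
  if (any(bed$start < 0)) stop("BED starts must be >= 0")
  data.frame(chrom = bed$chrom, start = bed$start + 1, end = bed$end,
             stringsAsFactors = FALSE)
}

#' Write candidate intervals as BED
#'
#' @param intervals `GRanges` (e.g. [candidateIntervals()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeBed <- function(intervals, path) {
  bed <- intervalsToBed(intervals)
  if (is(intervals, "GRanges") && !is.null(intervals$max_stat)) {
    bed$name <- sprintf("interval_%d", seq_len(nrow(bed)))
    bed$score <- intervals$max_stat
  }
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an element truth/annotation table as GFF3
#'
#' One `LTR_retrotransposon` feature per element with two
#' `long_terminal_repeat` children, 1-based inclusive.
#'
#' @param elements element table (see [plantElements()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeElementsGff3 <- function(elements, path) {
  parent <- GRanges(elements$contig,
                    IRanges(elements$start, elements$end),
                    type = "LTR_retrotransposon", ID = elements$id)
  kids <- rbind(
    data.frame(contig = elements$contig, start = elements$ltr5_start,
               end = elements$ltr5_end, Parent = elements$id,
               ID = paste0(elements$id, "_ltr5")),
    data.frame(contig = elements$contig, start = elements$ltr3_start,
               end = elements$ltr3_end, Parent = elements$id,
               ID = paste0(elements$id, "_ltr3")))
  child <- GRanges(kids$contig, IRanges(kids$start, kids$end),
                   type = "long_terminal_repeat", ID = kids$ID,
                   Parent = kids$Parent)
  rtracklayer::export(c(parent, child), path, format = "gff3")
  invisible(path)
}

#' Read an element annotation from GFF3
#'
#' Inverse of [writeElementsGff3()]: reassembles the element table
#' from `LTR_retrotransposon` features and their
#' `long_terminal_repeat` children.
#'
#' @param path GFF3 file.
#' @return element table data.frame.
#' @export
readElementsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parents <- gr[gr$type == "LTR_retrotransposon"]
  kids <- gr[gr$type == "long_terminal_repeat"]
  kidParent <- vapply(kids$Parent, function(p) as.character(p)[1], "")
  rows <- lapply(seq_along(parents), function(i) {
    id <- parents$ID[i]
    k <- kids[kidParent == id]
    k <- k[order(start(k))]
    if (length(k) != 2)
      stop("element ", id, " must have exactly two LTR children")
    data.frame(id = id,
               contig = as.character(seqnames(parents)[i]),
               start = start(parents)[i], end = end(parents)[i],
               length = width(parents)[i],
               ltr5_start = start(k)[1], ltr5_end = end(k)[1],
               ltr3_start = start(k)[2], ltr3_end = end(k)[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a JSON run summary
#'
#' Full-provenance record of a scan: resolved parameters, threshold,
#' window and interval counts, and the package version.
#'
#' @param scan a [BsaScan-class].
#' @param path output JSON file.
#' @param extra optional named list merged into the summary.
#' @return invisibly, `path`.
#' @export
writeScanSummary <- function(scan, path, extra = list()) {
  stopifnot(is(scan, "BsaScan"))
  summary <- c(list(
    package = "bsaTE",
    version = as.character(utils::packageVersion("bsaTE")),
    params = scanParams(scan),
    threshold = scanThreshold(scan),
    level = scan@level,
    nWindows = length(windowStats(scan)),
    nIntervals = length(candidateIntervals(scan))), extra)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
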