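#' Load one sequencing lane from SAM or BED
#'
#' Reads single-end alignments for one lane, drops unmapped, secondary and
#' supplementary records, removes duplicate alignments (reads sharing
#' chromosome, leftmost position and strand — a PCR-artefact correction; the
#' first occurrence is kept) and returns a `methcap_lane` ready for binning.
#'
#' For SAM input, `total_raw_reads` defaults to the number of primary records
#' in the file (mapped or not). BED carries no unmapped reads, so
#' `total_raw_reads` must come from the manifest; it defaults to the number
#' of BED records.
#'
#' @param path SAM (minimal dialect: header optional; FLAG, RNAME, POS and
#'   SEQ or CIGAR required) or BED6 file. Format is taken from the file
#'   extension unless `format` is given.
#' @param index A `methcap_index`; every mapped contig must be present unless
#'   listed in `exclude_contigs`.
#' @param sample_id,lane_id,library_id Identifiers for the lane.
#' @param fragment_length Sonication fragment length in bp used for read
#'   extension (default 150).
#' @param total_raw_reads Pre-alignment read total; see Details.
#' @param format `"sam"`, `"bed"`, or `NULL` to infer from the extension.
#' @param exclude_contigs Contigs to drop from the lane (still counted in
#'   `total_raw_reads`), e.g. a spike-in construct.
#' @return A `methcap_lane`: deduplicated reads plus read totals.
#' @export
load_alignments <- function(path, index, sample_id = NA_character_,
                            lane_id = basename(path),
                            library_id = NA_character_,
                            fragment_length = 150L,
                            total_raw_reads = NULL, format = NULL,
                            exclude_contigs = character()) {
  stopifnot(inherits(index, "methcap_index"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bed", "bedgraph")) "bed" else "sam"
  }
  if (format == "sam") {
    rec <- read_sam(path)
    primary <- !bitwAnd(rec$flag, 0x100L) & !bitwAnd(rec$flag, 0x800L)
    if (is.null(total_raw_reads)) total_raw_reads <- sum(primary)
    keep <- primary & !bitwAnd(rec$flag, 0x4L)
    reads <- data.frame(
      chrom = rec$rname[keep],
      start = rec$pos[keep] - 1L,
      strand = ifelse(bitwAnd(rec$flag[keep], 0x10L) > 0L, "-", "+"),
      read_length = rec$read_length[keep],
      stringsAsFactors = FALSE)
  } else {
    bed <- rtracklayer::import(path, format = "BED")
    reads <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(bed)),
      start = GenomicRanges::start(bed) - 1L,
      strand = as.character(GenomicRanges::strand(bed)),
      read_length = GenomicRanges::width(bed),
      stringsAsFactors = FALSE)
    reads$strand[!reads$strand %in% c("+", "-")] <- "+"
    if (is.null(total_raw_reads)) total_raw_reads <- nrow(reads)
  }
  if (length(exclude_contigs))
    reads <- reads[!reads$chrom %in% exclude_contigs, , drop = FALSE]
  if (nrow(reads) == 0L)
    stop("no usable (mapped, primary) reads in ", path)
  unknown <- setdiff(unique(reads$chrom), index$chrom_names)
  if (length(unknown))
    stop("contig not in genome index: ", paste(unknown, collapse = ", "))
  lane_from_reads(reads, sample_id = sample_id, lane_id = lane_id,
                  library_id = library_id,
                  fragment_length = fragment_length,
                  total_raw_reads = total_raw_reads)
}

# Minimal SAM text reader: FLAG, RNAME, POS plus read length from SEQ (or
# CIGAR query length when SEQ is "*"). Header lines optional. Rsamtools is
# BAM-only, and the assay's single-end SAM dialect needs just these fields.
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L) stop("no alignment records in ", path)
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 10L))
    stop("malformed SAM record (fewer than 10 fields) in ", path)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  seq <- vapply(f, `[[`, "", 10L)
  read_length <- nchar(seq)
  star <- seq == "*"
  if (any(star)) {
    cig <- vapply(f, `[[`, "", 6L)[star]
    read_length[star] <- cigar_query_length(cig)
  }
  list(flag = flag, rname = rname, pos = pos, read_length = read_length)
}

cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    num <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[MIS=X]|[DNHP]", cg))[[1L]]
    sum(num[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Shared lane constructor: dedup on (chrom, start, strand), keep first.
lane_from_reads <- function(reads, sample_id, lane_id, library_id,
                            fragment_length, total_raw_reads) {
  key <- paste(reads$chrom, reads$start, reads$strand)
  reads <- reads[!duplicated(key), , drop = FALSE]
  rownames(reads) <- NULL
  structure(list(
    sample_id = sample_id,
    lane_id = lane_id,
    library_id = library_id,
    reads = reads,
    total_raw_reads = as.integer(total_raw_reads),
    total_unique_aligned = nrow(reads),
    fragment_length = as.integer(fragment_length)
  ), class = "methcap_lane")
}

#' @export
print.methcap_lane <- function(x, ...) {
  cat(sprintf("MethylCap-seq lane %s (sample %s, library %s)\n",
              x$lane_id, x$sample_id, x$library_id))
  cat(sprintf("  %d unique aligned / %d raw reads; fragment length %d bp\n",
              x$total_unique_aligned, x$total_raw_reads, x$fragment_length))
  invisible(x)
}

#' Extend reads to fragment length
#'
#' Each aligned read is extended in its strand direction to the average
#' sonication fragment length: a plus-strand read at `start` becomes
#' `[start, start + L)`; a minus-strand read becomes
#' `[start + read_length - L, start + read_length)`. Intervals are clipped
#' to the contig.
#'
#' @param lane A `methcap_lane` (or a data frame with columns chrom, start,
#'   strand, read_length).
#' @param index A `methcap_index`.
#' @param fragment_length Fragment length override; defaults to the lane's.
#' @return Data frame of 0-based half-open fragment intervals (chrom, start,
#'   end).
#' @export
extend_reads <- function(lane, index, fragment_length = NULL) {
  reads <- if (inherits(lane, "methcap_lane")) lane$reads else lane
  L <- if (!is.null(fragment_length)) fragment_length
       else if (inherits(lane, "methcap_lane")) lane$fragment_length
       else 150L
  if (any(L < reads$read_length))
    stop("fragment_length shorter than read length")
  plus <- reads$strand == "+"
  s <- ifelse(plus, reads$start, reads$start + reads$read_length - L)
  e <- s + L
  lens <- index$chrom_lengths[reads$chrom]
  data.frame(chrom = reads$chrom,
             start = pmax(s, 0L),
             end = pmin(e, lens),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count a lane's extended fragments into the bin grid
#'
#' Every deduplicated read is extended to fragment length and assigned to
#' exactly one bin — the bin containing the fragment midpoint
#' (`floor((start + end - 1) / 2)` of the half-open interval). Single
#' assignment keeps bin counts true fractions of reads: the counts sum to
#' the number of reads, and RPM later sums to one million.
#'
#' @param lane A `methcap_lane`.
#' @param index A `methcap_index`.
#' @return A `methcap_bins` object: integer `counts` over the flattened
#'   grid, `total_assigned`, and the grid signature.
#' @export
bin_counts <- function(lane, index) {
  stopifnot(inherits(lane, "methcap_lane"))
  frags <- extend_reads(lane, index)
  bins_from_fragments(frags, index)
}

bins_from_fragments <- function(frags, index) {
  mid <- (frags$start + frags$end - 1L) %/% 2L
  gbin <- index$bin_offset[frags$chrom] + mid %/% index$bin_size
  counts <- tabulate(gbin + 1L, nbins = index$total_bins)
  new_bins(counts, index)
}

new_bins <- function(counts, index, rpm = NULL) {
  structure(list(
    counts = as.integer(counts),
    rpm = rpm,
    total_assigned = sum(counts),
    bin_size = index$bin_size,
    n_bins = index$n_bins,
    chrom_names = index$chrom_names
  ), class = "methcap_bins")
}

same_grid <- function(a, b) {
  a$bin_size == b$bin_size && identical(a$n_bins, b$n_bins)
}

#' Normalize bin counts to reads per million
#'
#' `rpm[i] = counts[i] * 1e6 / total_assigned`, so the RPM vector always
#' sums to one million.
#'
#' @param bins A `methcap_bins` from [bin_counts()].
#' @return The same object with the `rpm` field filled.
#' @export
rpm_normalize <- function(bins) {
  stopifnot(inherits(bins, "methcap_bins"))
  if (bins$total_assigned == 0L)
    stop("cannot normalize a lane with zero assigned reads")
  bins$rpm <- bins$counts * 1e6 / bins$total_assigned
  bins
}

#' Average replicate lanes of one sample
#'
#' Methylation signal is normalized per lane and then averaged among
#' replicate lanes: the merged profile is the per-bin arithmetic mean of the
#' lanes' RPM vectors, and itself sums to one million.
#'
#' @param lanes List of RPM-normalized `methcap_bins` on one grid.
#' @return A `methcap_bins` with `rpm` set (counts are the summed raw
#'   counts, kept for reference; `total_assigned` is their sum).
#' @export
merge_replicate_lanes <- function(lanes) {
  stopifnot(length(lanes) >= 1L)
  if (!all(vapply(lanes, inherits, TRUE, "methcap_bins")))
    stop("all elements must be methcap_bins")
  if (any(vapply(lanes, function(b) is.null(b$rpm), TRUE)))
    stop("normalize lanes with rpm_normalize() before merging")
  g <- lanes[[1L]]
  if (!all(vapply(lanes, same_grid, TRUE, g)))
    stop("lanes are on different bin grids")
  out <- g
  out$counts <- Reduce(`+`, lapply(lanes, `[[`, "counts"))
  out$total_assigned <- sum(out$counts)
  out$rpm <- Reduce(`+`, lapply(lanes, `[[`, "rpm")) / length(lanes)
  out
}

#' @export
print.methcap_bins <- function(x, ...) {
  cat(sprintf("Binned lane: %d reads in %d bins of %d bp%s\n",
              x$total_assigned, length(x$counts), x$bin_size,
              if (is.null(x$rpm)) " (raw counts)" else " (RPM-normalized)"))
  invisible(x)
}

#' Read a lane manifest
#'
#' Tab-delimited, one row per lane, with columns `sample_id`, `lane_id`,
#' `library_id`, `path`, `fragment_length`, `total_raw_reads`, `group`.
#' Empty `total_raw_reads` entries are taken from the alignment file.
#'
#' @param path Manifest TSV.
#' @return Data frame of lane descriptions.
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("sample_id", "lane_id", "library_id", "path",
            "fragment_length", "total_raw_reads", "group")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$lane_id))
    stop("duplicate lane_id in manifest")
  m
}

#' Write a bin vector as bedGraph
#'
#' @param bins A `methcap_bins`.
#' @param index The matching `methcap_index`.
#' @param path Output bedGraph path.
#' @param what `"rpm"` (default) or `"counts"`.
#' @param keep_zero Write zero bins too (default FALSE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, index, path, what = c("rpm", "counts"),
                           keep_zero = FALSE) {
  what <- match.arg(what)
  v <- bins[[what]]
  if (is.null(v)) stop("bins carry no '", what, "' values")
  gr <- bin_granges(index)
  keep <- if (keep_zero) rep(TRUE, length(v)) else v != 0
  bed <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    value = v[keep])
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
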