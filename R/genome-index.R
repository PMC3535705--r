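#' Build a CpG genome index
#'
#' Scans a reference genome for CpG dinucleotides and lays a fixed-width bin
#' grid over every contig. The resulting index holds, per contig, the sorted
#' 0-based positions of the C of every CG dinucleotide on the forward strand
#' and the number of CpGs falling in each bin. All downstream computations
#' (bin counting, QC metrics, the CpG-density methylation distribution) are
#' defined against this index.
#'
#' Coordinates are 0-based, half-open throughout; bin `i` of a contig covers
#' `[i * bin_size, (i + 1) * bin_size)` and a CpG belongs to the bin
#' containing its C. Soft-masked (lowercase) bases are treated as ordinary
#' bases; ambiguous bases (N) never form a CpG.
#'
#' @param fasta Path to a (multi-contig) FASTA file.
#' @param bin_size Bin width in bp (default 500).
#' @return An object of class `methcap_index` with fields `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `cpg_sites` (list of 0-based integer
#'   vectors), `bin_cpg_counts` (list of integer vectors), `n_bins`,
#'   `total_cpg`, `total_length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' idx <- build_genome_index(fa, bin_size = 4)
#' idx$cpg_sites$chr1       # 1, 5
#' idx$bin_cpg_counts$chr1  # 1, 1
#' @export
build_genome_index <- function(fasta, bin_size = 500L) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L)
    stop("bin_size must be a positive integer")
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L)
    stop("empty FASTA: ", fasta)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms))
    stop("duplicate contig names in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(seqs) <- nms
  lens <- Biostrings::width(seqs)
  hits <- Biostrings::vmatchPattern("CG", seqs, fixed = TRUE)
  cpg_sites <- lapply(seq_along(seqs), function(i) {
    as.integer(IRanges::start(hits[[i]])) - 1L   # 0-based C position
  })
  names(cpg_sites) <- nms
  new_genome_index(nms, lens, bin_size, cpg_sites)
}

# Assemble the index object from its primary fields; recomputes the derived
# per-bin CpG counts and layout so every constructor shares one code path.
new_genome_index <- function(chrom_names, chrom_lengths, bin_size, cpg_sites) {
  chrom_lengths <- as.integer(chrom_lengths)
  names(chrom_lengths) <- chrom_names
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  names(n_bins) <- chrom_names
  bin_cpg_counts <- lapply(chrom_names, function(cn) {
    tabulate(cpg_sites[[cn]] %/% bin_size + 1L, nbins = n_bins[[cn]])
  })
  names(bin_cpg_counts) <- chrom_names
  bin_offset <- c(0L, cumsum(n_bins))[seq_along(chrom_names)]
  names(bin_offset) <- chrom_names
  structure(list(
    chrom_names = chrom_names,
    chrom_lengths = chrom_lengths,
    bin_size = as.integer(bin_size),
    cpg_sites = cpg_sites[chrom_names],
    bin_cpg_counts = bin_cpg_counts,
    n_bins = n_bins,
    bin_offset = bin_offset,
    total_bins = sum(n_bins),
    total_cpg = sum(lengths(cpg_sites)),
    total_length = sum(as.numeric(chrom_lengths))
  ), class = "methcap_index")
}

#' Fraction of bins containing no CpG
#'
#' Zero-CpG ("CpG barren") bins define the noise domain of a MethylCap-seq
#' lane: reads landing there cannot reflect methylation.
#'
#' @param index A `methcap_index`.
#' @return Proportion of grid bins whose CpG count is zero, in \[0, 1\].
#' @export
zero_cpg_bin_fraction <- function(index) {
  stopifnot(inherits(index, "methcap_index"))
  counts <- unlist(index$bin_cpg_counts, use.names = FALSE)
  mean(counts == 0L)
}

#' Persist a genome index to a directory
#'
#' Writes two tab-delimited sidecar files, `contigs.tsv` (contig, length,
#' bin_size) and `cpg_sites.tsv` (contig, 0-based position), from which the
#' full index including per-bin CpG counts is reconstructed on load, so FASTA
#' scanning is a one-time cost.
#'
#' @param index A `methcap_index`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_genome_index <- function(index, dir) {
  stopifnot(inherits(index, "methcap_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(
    data.table::data.table(contig = index$chrom_names,
                           length = index$chrom_lengths,
                           bin_size = index$bin_size),
    file.path(dir, "contigs.tsv"), sep = "\t")
  sites <- data.table::data.table(
    contig = rep(index$chrom_names, lengths(index$cpg_sites)),
    pos = unlist(index$cpg_sites, use.names = FALSE))
  data.table::fwrite(sites, file.path(dir, "cpg_sites.tsv"), sep = "\t")
  invisible(dir)
}

#' Load a genome index written by [write_genome_index()]
#'
#' @param dir Directory holding `contigs.tsv` and `cpg_sites.tsv`.
#' @return A `methcap_index`.
#' @export
read_genome_index <- function(dir) {
  contigs <- data.table::fread(file.path(dir, "contigs.tsv"), sep = "\t")
  sites <- data.table::fread(file.path(dir, "cpg_sites.tsv"), sep = "\t")
  cpg_sites <- lapply(contigs$contig, function(cn)
    sort(sites$pos[sites$contig == cn]))
  names(cpg_sites) <- contigs$contig
  new_genome_index(contigs$contig, contigs$length, contigs$bin_size[1L],
                   cpg_sites)
}

#' Export per-bin CpG counts as BED4
#'
#' @param index A `methcap_index`.
#' @param path Output BED file (chrom, start, end, cpg_count).
#' @return `path`, invisibly.
#' @export
export_bin_cpg_bed <- function(index, path) {
  stopifnot(inherits(index, "methcap_index"))
  bed <- data.table::data.table(
    chrom = rep(index$chrom_names, index$n_bins),
    start = unlist(lapply(index$chrom_names, function(cn)
      (seq_len(index$n_bins[[cn]]) - 1L) * index$bin_size),
      use.names = FALSE))
  bed$end <- pmin(bed$start + index$bin_size,
                  index$chrom_lengths[bed$chrom])
  bed$count <- unlist(index$bin_cpg_counts, use.names = FALSE)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# Number of CpG C positions in [start, end) per interval (0-based, half-open),
# all on one contig. findInterval against the sorted site vector gives the
# count of sites <= x.
cpg_count_in_intervals <- function(index, chrom, start, end) {
  sites <- index$cpg_sites[[chrom]]
  if (is.null(sites)) stop("contig not in index: ", chrom)
  if (length(sites) == 0L) return(integer(length(start)))
  findInterval(end - 1L, sites) - findInterval(start - 1L, sites)
}

# Flattened per-bin CpG counts across contigs (grid order).
bin_cpg_flat <- function(index) {
  unlist(index$bin_cpg_counts, use.names = FALSE)
}

# GRanges of the full bin grid (1-based for IRanges machinery).
bin_granges <- function(index) {
  starts <- unlist(lapply(index$chrom_names, function(cn)
    (seq_len(index$n_bins[[cn]]) - 1L) * index$bin_size), use.names = FALSE)
  chroms <- rep(index$chrom_names, index$n_bins)
  ends <- pmin(starts + index$bin_size, index$chrom_lengths[chroms])
  GenomicRanges::GRanges(chroms, IRanges::IRanges(starts + 1L, ends))
}

#' @export
print.methcap_index <- function(x, ...) {
  cat("MethylCap-seq genome index\n")
  cat(sprintf("  contigs: %d (%s bp total)\n", length(x$chrom_names),
              format(x$total_length, big.mark = ",")))
  cat(sprintf("  bin size: %d bp (%d bins)\n", x$bin_size, x$total_bins))
  cat(sprintf("  CpG sites: %s (%.1f%% of bins CpG-free)\n",
              format(x$total_cpg, big.mark = ","),
              100 * zero_cpg_bin_fraction(x)))
  invisible(x)
}
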