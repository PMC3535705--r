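# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from stored data files.

write_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

make_index <- function(seqs, bin_size = 500L) {
  build_genome_index(write_test_fasta(seqs), bin_size = bin_size)
}

# Direct lane construction for arithmetic-focused tests (the loading path has
# its own tests against SAM/BED files).
make_lane <- function(chrom, start, strand = "+", read_length = 36L,
                      fragment_length = 150L, raw = NULL) {
  reads <- data.frame(chrom = chrom, start = as.integer(start),
                      strand = strand, read_length = as.integer(read_length),
                      stringsAsFactors = FALSE)
  methcapr:::lane_from_reads(reads, sample_id = "S1", lane_id = "L1",
                             library_id = "S1",
                             fragment_length = fragment_length,
                             total_raw_reads = if (is.null(raw)) nrow(reads)
                                               else raw)
}

# Minimal SAM writer: records are lists/data frames with flag, rname, pos
# (1-based), seq.
write_test_sam <- function(records, sq = list(chr1 = 1000L),
                           path = tempfile(fileext = ".sam"),
                           header = TRUE) {
  lines <- character(0)
  if (header)
    lines <- c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unlist(sq)))
  rec <- vapply(seq_len(nrow(records)), function(i)
    sprintf("r%03d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
            i, records$flag[i], records$rname[i], records$pos[i],
            if (is.null(records$cigar)) paste0(nchar(records$seq[i]), "M")
            else records$cigar[i],
            records$seq[i]), "")
  writeLines(c(lines, rec), path)
  path
}

# Small simulation config for unit tests (the acceptance tests run the
# full-size default).
tiny_config <- function(reads_per_lane = 2e4, ...) {
  sim_config(genome_length = 2e5, n_islands = 20L,
             reads_per_lane = reads_per_lane, ...)
}

# Brute-force CpG scan: every position whose 2-mer is exactly "CG"
# (case-insensitive), as an independent oracle for the index builder.
brute_cpg_sites <- function(s) {
  x <- gregexpr("CG", toupper(s), fixed = TRUE)[[1L]]
  if (x[1L] == -1L) integer(0) else as.integer(x) - 1L
}
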