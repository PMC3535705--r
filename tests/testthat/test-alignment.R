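make_ref <- function(len = 2000L, bin_size = 500L) {
  make_index(c(chr1 = paste(rep("ACGT", len / 4), collapse = "")),
             bin_size = bin_size)
}

test_that("SAM loading drops unmapped and secondary records and dedups", {
  idx <- make_ref()
  seq36 <- strrep("A", 36)
  rec <- data.frame(
    flag = c(0L, 0L, 16L, 4L, 256L, 0L),
    rname = c("chr1", "chr1", "chr1", "*", "chr1", "chr1"),
    pos = c(101L, 101L, 101L, 0L, 201L, 301L),
    seq = seq36, stringsAsFactors = FALSE)
  sam <- write_test_sam(rec, sq = list(chr1 = 2000L))
  lane <- load_alignments(sam, idx, sample_id = "S1")
  # r1/r2 duplicate pair collapses; r3 same pos other strand stays;
  # unmapped r4 counts toward raw only; secondary r5 is ignored entirely
  expect_identical(lane$total_raw_reads, 5L)
  expect_identical(lane$total_unique_aligned, 3L)
  expect_identical(sort(lane$reads$start), c(100L, 100L, 300L))
  expect_setequal(lane$reads$strand[lane$reads$start == 100L], c("+", "-"))

  # read length from CIGAR when SEQ is "*"
  rec2 <- data.frame(flag = 0L, rname = "chr1", pos = 1L, seq = "*",
                     cigar = "20M5S", stringsAsFactors = FALSE)
  lane2 <- load_alignments(write_test_sam(rec2, sq = list(chr1 = 2000L)),
                           idx, fragment_length = 150L)
  expect_identical(lane2$reads$read_length, 25L)

  # headerless SAM is accepted
  hl <- write_test_sam(data.frame(flag = 0L, rname = "chr1", pos = 11L,
                                  seq = seq36), header = FALSE)
  expect_identical(load_alignments(hl, idx)$reads$start, 10L)
})

test_that("unknown contigs and empty lanes are errors", {
  idx <- make_ref()
  sam <- write_test_sam(data.frame(flag = 0L, rname = "chrX", pos = 1L,
                                   seq = strrep("A", 36)))
  expect_error(load_alignments(sam, idx), "chrX")
  only_unmapped <- write_test_sam(data.frame(flag = 4L, rname = "*",
                                             pos = 0L, seq = strrep("A", 36)))
  expect_error(load_alignments(only_unmapped, idx), "no usable")
  # spike-in contig can be excluded instead of erroring
  mix <- write_test_sam(data.frame(flag = 0L, rname = c("chr1", "plasmid"),
                                   pos = c(1L, 1L), seq = strrep("A", 36)))
  lane <- load_alignments(mix, idx, exclude_contigs = "plasmid")
  expect_identical(lane$total_unique_aligned, 1L)
  expect_identical(lane$total_raw_reads, 2L)
})

test_that("BED loading dedups on (chrom, start, strand)", {
  idx <- make_ref()
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t136\tr1\t0\t+",
               "chr1\t100\t136\tr2\t0\t+",
               "chr1\t300\t336\tr3\t0\t-"), bed)
  lane <- load_alignments(bed, idx, total_raw_reads = 10L)
  expect_identical(lane$total_unique_aligned, 2L)
  expect_identical(lane$total_raw_reads, 10L)
  expect_identical(lane$reads$read_length, c(36L, 36L))
})

test_that("read extension follows strand and clips at contig ends", {
  idx <- make_ref()
  lane <- make_lane("chr1", c(1000L, 1000L, 1990L, 100L),
                    strand = c("+", "-", "+", "-"))
  fr <- extend_reads(lane, idx)
  expect_equal(fr$start, c(1000L, 886L, 1990L, 0L))
  expect_equal(fr$end, c(1150L, 1036L, 2000L, 136L))
  expect_error(extend_reads(make_lane("chr1", 1L, read_length = 200L), idx),
               "fragment_length")
})

test_that("fragments are assigned to the bin holding their midpoint", {
  idx <- make_ref()
  b1 <- bin_counts(make_lane("chr1", 0L), idx)       # fragment [0,150)
  expect_identical(which(b1$counts != 0L), 1L)
  # fragment [400,550): midpoint 474 stays in bin 0
  b2 <- bin_counts(make_lane("chr1", 400L), idx)
  expect_identical(which(b2$counts != 0L), 1L)
  # fragment [450,600): midpoint 524 moves to bin 1
  b3 <- bin_counts(make_lane("chr1", 450L), idx)
  expect_identical(which(b3$counts != 0L), 2L)
})

test_that("uniform fragments distribute over bins as the placement law says", {
  n <- 100000L
  G <- 100000L
  L <- 150L
  idx <- make_index(c(chr1 = paste(rep("ACGT", G / 4), collapse = "")), 500L)
  set.seed(99)
  starts <- sample.int(G - L + 1L, n, replace = TRUE) - 1L
  b <- bin_counts(make_lane("chr1", starts,
                            strand = sample(c("+", "-"), n, TRUE)), idx)
  # oracle: the exact bin law of a uniform fragment start (midpoint s + 74)
  p <- tabulate((0:(G - L) + 74L) %/% 500L + 1L, idx$total_bins)
  expect_gt(stats::chisq.test(b$counts, p = p / sum(p))$p.value, 0.01)
})

test_that("RPM normalization and lane merging keep their identities", {
  idx <- make_ref(2000L)
  set.seed(3)
  lane <- make_lane("chr1", sample(0:1800, 500, TRUE),
                    strand = sample(c("+", "-"), 500, TRUE))
  b <- bin_counts(lane, idx)
  expect_identical(b$total_assigned, lane$total_unique_aligned)
  expect_identical(sum(b$counts), b$total_assigned)
  b <- rpm_normalize(b)
  expect_equal(sum(b$rpm), 1e6, tolerance = 1e-6)

  one_bin <- rpm_normalize(bin_counts(make_lane("chr1", c(10L, 20L)), idx))
  expect_equal(max(one_bin$rpm), 1e6)

  # merging: mean of RPM vectors; idempotent on copies; sums preserved
  two <- make_index(c(chr1 = strrep("ACGT", 250)), 500L)  # 2-bin grid
  l1 <- rpm_normalize(bin_counts(make_lane("chr1", c(10L, 20L)), two))
  l2 <- rpm_normalize(bin_counts(make_lane("chr1", c(600L, 610L)), two))
  m <- merge_replicate_lanes(list(l1, l2))
  expect_equal(m$rpm, c(5e5, 5e5))
  expect_equal(merge_replicate_lanes(list(l1, l1, l1))$rpm, l1$rpm)
  expect_equal(sum(m$rpm), 1e6)

  expect_error(merge_replicate_lanes(list(l1, rpm_normalize(b))),
               "different bin grids")
  expect_error(merge_replicate_lanes(list(bin_counts(lane, idx))),
               "normalize")
  empty <- lane
  empty$reads <- empty$reads[0, ]
  expect_error(rpm_normalize(bin_counts(empty, idx)), "zero assigned")
})

test_that("deduplication is idempotent", {
  set.seed(11)
  lane <- make_lane("chr1", sample(0:500, 300, TRUE),
                    strand = sample(c("+", "-"), 300, TRUE))
  again <- methcapr:::lane_from_reads(lane$reads, "S1", "L1", "S1", 150L,
                                      lane$total_raw_reads)
  expect_identical(again$reads, lane$reads)
})

test_that("simulator SAM round-trips through the loader with exact truth", {
  cfg <- tiny_config(seed = 21, duplicate_rate = 0.05)
  g <- simulate_genome(cfg)
  idx <- sim_index(g)
  sam <- tempfile(fileext = ".sam")
  sl <- simulate_lane(g, "captured", seed = 9, sam = sam)
  lane <- load_alignments(sam, idx, sample_id = "S1",
                          exclude_contigs = cfg$construct_name)
  expect_identical(lane$total_raw_reads, sl$truth$n_emitted)
  expect_identical(lane$total_unique_aligned, sl$truth$n_unique_genome)
  mem <- as_lane(sl)
  expect_identical(lane$total_unique_aligned, mem$total_unique_aligned)
  expect_equal(sort(lane$reads$start), sort(mem$reads$start))
})

test_that("replicate lanes of one library correlate highly at depth", {
  cfg <- sim_config(seed = 31, reads_per_lane = 5e6)
  g <- simulate_genome(cfg)
  idx <- sim_index(g)
  r1 <- rpm_normalize(bin_counts(as_lane(simulate_lane(g, "captured",
                                                       seed = 1)), idx))
  r2 <- rpm_normalize(bin_counts(as_lane(simulate_lane(g, "captured",
                                                       seed = 2)), idx))
  set.seed(5)
  pick <- sample(idx$total_bins, 1000L)
  expect_gt(stats::cor(r1$rpm[pick], r2$rpm[pick])^2, 0.9)
})

test_that("manifests are validated and bedGraph export is faithful", {
  m <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("sample_id", "lane_id", "library_id", "path",
                       "fragment_length", "total_raw_reads", "group"),
                     collapse = "\t"),
               "S1\tL1\tS1\tx.sam\t150\t1000\tA"), m)
  mf <- read_manifest(m)
  expect_identical(mf$lane_id, "L1")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlane_id", "S1\tL1"), bad)
  expect_error(read_manifest(bad), "missing columns")

  idx <- make_ref(2000L)
  b <- rpm_normalize(bin_counts(make_lane("chr1", c(10L, 600L)), idx))
  p <- tempfile(fileext = ".bedgraph")
  write_bedgraph(b, idx, p)
  bg <- read.table(p, sep = "\t")
  expect_identical(nrow(bg), 2L)
  expect_equal(bg$V4, c(5e5, 5e5))
  expect_equal(bg$V2, c(0L, 500L))
})
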