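test_that("CpG enrichment is 1 for a perfect tiling and 0 off-CpG", {
  # 1500 bp genome, CpGs only in the first third
  s <- paste0(strrep("ACGT", 125), strrep("AT", 500))
  idx <- make_index(c(chr1 = s), 500L)
  tiling <- make_lane("chr1", seq(0L, 1350L, by = 150L))
  expect_equal(cpg_enrichment(tiling, idx), 1.0)
  inside_desert <- make_lane("chr1", c(600L, 800L, 1000L))
  expect_equal(cpg_enrichment(inside_desert, idx), 0.0)
  no_cpg <- make_index(c(chr1 = strrep("A", 1000)), 500L)
  expect_error(cpg_enrichment(make_lane("chr1", 0L), no_cpg), "no CpGs")
})

test_that("uniformly placed fragments score enrichment near 1", {
  g <- simulate_genome(tiny_config(seed = 13))
  idx <- sim_index(g)
  lane <- as_lane(simulate_lane(g, "input", seed = 3,
                                reads_per_lane = 10000L))
  expect_lt(abs(cpg_enrichment(lane, idx) - 1), 0.05)
})

test_that("5x CpG coverage counts stacked fragments at the threshold", {
  idx <- make_index(c(chr1 = paste0("AACG", strrep("A", 496))), 500L)
  expect_identical(idx$total_cpg, 1L)
  five <- make_lane("chr1", c(0L, 1L, 2L, 50L, 60L),
                    strand = c("+", "+", "+", "-", "-"))
  expect_equal(coverage_5x(five, idx), 1.0)
  four <- make_lane("chr1", c(0L, 1L, 2L, 50L),
                    strand = c("+", "+", "+", "-"))
  expect_equal(coverage_5x(four, idx), 0.0)
})

test_that("5x CpG coverage equals a brute-force pileup", {
  g <- simulate_genome(sim_config(seed = 17, genome_length = 5e4,
                                  n_islands = 5L, reads_per_lane = 2000L))
  idx <- sim_index(g)
  lane <- as_lane(simulate_lane(g, "captured", seed = 4))
  got <- coverage_5x(lane, idx)
  fr <- extend_reads(lane, idx)
  depth <- vapply(idx$cpg_sites$chr1, function(p)
    sum(fr$start <= p & p < fr$end), 0L)
  expect_equal(got, mean(depth >= 5L))
  expect_equal(coverage_5x(lane, idx, depth_threshold = 1L),
               mean(depth >= 1L))
})

test_that("5x coverage grows monotonically with nested read subsets", {
  g <- simulate_genome(tiny_config(seed = 23))
  idx <- sim_index(g)
  lane <- as_lane(simulate_lane(g, "captured", seed = 8))
  n <- nrow(lane$reads)
  cov <- vapply(c(0.25, 0.5, 0.75, 1), function(f) {
    sub <- lane
    sub$reads <- lane$reads[seq_len(round(f * n)), ]
    coverage_5x(sub, idx)
  }, 0)
  expect_true(all(diff(cov) >= 0))
  expect_gt(cov[4], cov[1])
})

test_that("noise is the read mass in zero-CpG bins", {
  s <- paste0(strrep("ACGT", 125), strrep("AT", 250))  # bin 2 is CpG-free
  idx <- make_index(c(chr1 = s), 500L)
  all_cpg <- make_lane("chr1", c(0L, 100L, 200L))
  expect_equal(noise_pct(all_cpg, idx), 0.0)
  half <- make_lane("chr1", c(100L, 700L))
  expect_equal(noise_pct(half, idx), 50.0)
})

test_that("uniform-lane noise matches the exact placement oracle", {
  g <- simulate_genome(tiny_config(seed = 29))
  idx <- sim_index(g)
  sl <- simulate_lane(g, "input", seed = 6)
  lane <- as_lane(sl)
  # exact law: fragment starts are uniform, the midpoint is start + 74
  G <- g$config$genome_length
  L <- g$config$fragment_length
  zero <- methcapr:::bin_cpg_flat(idx) == 0L
  p_true <- mean(zero[(0:(G - L) + 74L) %/% 500L + 1L])
  n <- lane$total_unique_aligned
  band <- stats::qnorm(0.995) * sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(noise_pct(lane, idx) / 100 - p_true), band)
})

test_that("failed-enrichment lanes are noisier than captured lanes", {
  g <- simulate_genome(tiny_config(seed = 37))
  idx <- sim_index(g)
  captured <- as_lane(simulate_lane(g, "captured", seed = 2))
  failed <- as_lane(simulate_lane(g, "failed", seed = 2))
  expect_gt(noise_pct(failed, idx), noise_pct(captured, idx))
})

test_that("QC verdicts use strict thresholds and name failed criteria", {
  th <- qc_thresholds()
  pass <- qc_classify(list(cpg_enrichment = 2.33, saturation = 0.79,
                           coverage5x = 0.21), th)
  expect_true(pass$passed)
  expect_length(pass$failed_criteria, 0)
  # equality passes (strict < comparison)
  boundary <- qc_classify(list(cpg_enrichment = 1.4, saturation = 0.5,
                               coverage5x = 0.05), th)
  expect_true(boundary$passed)
  one_low <- qc_classify(list(cpg_enrichment = 1.39, saturation = 0.9,
                              coverage5x = 0.2), th)
  expect_false(one_low$passed)
  expect_identical(one_low$failed_criteria, "cpg_enrichment")
  both <- qc_classify(list(cpg_enrichment = 1.0, saturation = 0.4,
                           coverage5x = 0.2), th)
  expect_setequal(both$failed_criteria, c("cpg_enrichment", "saturation"))
  expect_error(qc_classify(list(cpg_enrichment = 2, saturation = NA,
                                coverage5x = 0.2), th), "missing QC metric")
  expect_error(qc_thresholds(min_enrichment = 0), "min_enrichment")
})

test_that("saturation is deterministic per seed and 1 for one-bin lanes", {
  g <- simulate_genome(tiny_config(seed = 43))
  idx <- sim_index(g)
  lane <- as_lane(simulate_lane(g, "captured", seed = 3,
                                reads_per_lane = 5000L))
  expect_identical(saturation(lane, idx, seed = 17),
                   saturation(lane, idx, seed = 17))
  expect_false(isTRUE(all.equal(saturation(lane, idx, seed = 17),
                                saturation(lane, idx, seed = 18))))
  one_bin <- make_lane("chr1", 0:9)
  expect_equal(saturation(one_bin, sim_index(g), seed = 1), 1.0)
  expect_error(saturation(make_lane("chr1", 0L), idx), "at least 2 reads")
})

test_that("saturation improves with sequencing depth", {
  g <- simulate_genome(tiny_config(seed = 47))
  idx <- sim_index(g)
  shallow <- deep <- numeric(3)
  for (s in 1:3) {
    lane <- as_lane(simulate_lane(g, "captured", seed = s))
    sub <- lane
    sub$reads <- lane$reads[seq_len(2000L), ]
    shallow[s] <- saturation(sub, idx, seed = s)
    deep[s] <- saturation(lane, idx, seed = s)
  }
  expect_gt(mean(deep), mean(shallow))
})

test_that("noise averaging groups lanes by sample and QC status", {
  qc <- data.frame(sample_id = c("S1", "S1", "S2", "S2"),
                   noise_pct = c(2, 4, 3, 9),
                   passed = c(TRUE, TRUE, TRUE, FALSE))
  avg <- average_noise_by_sample(qc)
  expect_equal(avg$noise_pct[avg$sample_id == "S1" & avg$passed], 3)
  # S2 split across QC groups appears in both, one lane each
  s2 <- avg[avg$sample_id == "S2", ]
  expect_identical(nrow(s2), 2L)
  expect_equal(sort(s2$noise_pct), c(3, 9))
  expect_identical(s2$n_lanes, c(1L, 1L))
})

test_that("qc_run reports every lane and honors force_include", {
  g <- simulate_genome(tiny_config(seed = 53))
  idx <- sim_index(g)
  lanes <- list(as_lane(simulate_lane(g, "captured", seed = 1,
                                      lane_id = "good")),
                as_lane(simulate_lane(g, "failed", seed = 2,
                                      lane_id = "bad")))
  tab <- qc_run(lanes, idx, seed = 5)
  expect_identical(tab$lane_id, c("good", "bad"))
  expect_identical(tab$passed, c(TRUE, FALSE))
  expect_match(tab$failed_criteria[2], "cpg_enrichment")
  forced <- qc_run(lanes, idx, seed = 5, force_include = "bad")
  expect_true(all(forced$passed))
  expect_identical(forced$forced_include, c(FALSE, TRUE))
})

test_that("replicate reproducibility is higher for captured than failed", {
  g <- simulate_genome(tiny_config(seed = 59))
  idx <- sim_index(g)
  rpm_of <- function(mode, seed)
    rpm_normalize(bin_counts(as_lane(simulate_lane(g, mode, seed = seed)),
                             idx))$rpm
  r_pass <- stats::cor(rpm_of("captured", 1), rpm_of("captured", 2))
  r_fail <- stats::cor(rpm_of("failed", 3), rpm_of("failed", 4))
  expect_gt(r_pass, r_fail)
  expect_gt(r_pass, 0.9)
})
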