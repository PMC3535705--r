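#' Lane-exclusion QC thresholds
#'
#' A lane is excluded when any metric falls strictly below its threshold:
#' CpG enrichment < 1.4, saturation < 0.5, or 5x CpG coverage < 0.05.
#' A metric exactly equal to its threshold passes.
#'
#' @param min_enrichment,min_saturation,min_coverage5x Threshold values.
#' @return A `methcap_qc_thresholds` list.
#' @export
qc_thresholds <- function(min_enrichment = 1.4, min_saturation = 0.5,
                          min_coverage5x = 0.05) {
  stopifnot(min_enrichment > 0, min_saturation > 0, min_coverage5x > 0)
  structure(list(min_enrichment = min_enrichment,
                 min_saturation = min_saturation,
                 min_coverage5x = min_coverage5x),
            class = "methcap_qc_thresholds")
}

#' CpG enrichment of a lane
#'
#' Compares the frequency of CpGs in the sequenced sample with the frequency
#' of CpGs in the reference genome: sample frequency is the total number of
#' CpG sites falling inside the extended fragments divided by the total
#' fragment length; genome frequency is total CpGs over genome length. A
#' successfully captured lane scores well above 1; a failed enrichment
#' scores near 1 because fragments then sample the genome uniformly.
#'
#' @param lane A `methcap_lane`.
#' @param index A `methcap_index`.
#' @return Enrichment ratio (>= 0).
#' @export
cpg_enrichment <- function(lane, index) {
  stopifnot(inherits(lane, "methcap_lane"), inherits(index, "methcap_index"))
  if (index$total_cpg == 0L)
    stop("reference genome contains no CpGs")
  frags <- extend_reads(lane, index)
  ncpg <- 0
  nbp <- 0
  for (cn in unique(frags$chrom)) {
    i <- frags$chrom == cn
    ncpg <- ncpg + sum(cpg_count_in_intervals(index, cn, frags$start[i],
                                              frags$end[i]))
    nbp <- nbp + sum(frags$end[i] - frags$start[i])
  }
  (ncpg / nbp) / (index$total_cpg / index$total_length)
}

#' Saturation of a lane
#'
#' The Pearson correlation of two random partitions of the lane's reads:
#' reads are split into two near-equal halves (the extra read goes to the
#' first), each half is binned, and the correlation of the two count vectors
#' over all grid bins is returned. High saturation means the binned profile
#' is reproducible at the lane's depth.
#'
#' @param lane A `methcap_lane` with at least 2 reads.
#' @param index A `methcap_index`.
#' @param seed RNG seed for the random partition (recorded in QC reports).
#' @return Pearson r in \[-1, 1\].
#' @export
saturation <- function(lane, index, seed = 1L) {
  stopifnot(inherits(lane, "methcap_lane"))
  n <- nrow(lane$reads)
  if (n < 2L) stop("saturation needs at least 2 reads")
  perm <- with_seed(seed, sample.int(n))
  h1 <- perm[seq_len(ceiling(n / 2))]
  h2 <- perm[-seq_len(ceiling(n / 2))]
  sub_bins <- function(i) {
    sub <- lane
    sub$reads <- lane$reads[i, , drop = FALSE]
    bin_counts(sub, index)$counts
  }
  c1 <- sub_bins(h1)
  c2 <- sub_bins(h2)
  if (stats::sd(c1) == 0 || stats::sd(c2) == 0) {
    # constant count vector: correlation undefined; proportional halves get
    # the limit 1, anything else is a degenerate partition
    if (isTRUE(all.equal(c1 * sum(c2), c2 * sum(c1)))) return(1.0)
    stop("degenerate partition: constant bin counts in one half")
  }
  stats::cor(c1, c2)
}

#' 5x CpG coverage of a lane
#'
#' Fraction of all genomic CpG sites overlapped by at least `depth_threshold`
#' deduplicated extended fragments (a CpG is covered by a fragment when its
#' C position lies inside the fragment interval).
#'
#' @param lane A `methcap_lane`.
#' @param index A `methcap_index`.
#' @param depth_threshold Minimum fragment depth (default 5).
#' @return Proportion in \[0, 1\].
#' @export
coverage_5x <- function(lane, index, depth_threshold = 5L) {
  stopifnot(inherits(lane, "methcap_lane"))
  if (index$total_cpg == 0L)
    stop("reference genome contains no CpGs")
  frags <- extend_reads(lane, index)
  covered <- 0L
  for (cn in index$chrom_names) {
    sites <- index$cpg_sites[[cn]]
    if (length(sites) == 0L) next
    i <- frags$chrom == cn
    if (!any(i)) next
    fr <- IRanges::IRanges(frags$start[i] + 1L, frags$end[i])
    cp <- IRanges::IRanges(sites + 1L, width = 1L)
    depth <- IRanges::countOverlaps(cp, fr)
    covered <- covered + sum(depth >= depth_threshold)
  }
  covered / index$total_cpg
}

#' Noise: percentage of reads in zero-CpG bins
#'
#' Reads whose assigned 500-bp bin contains no CpG dinucleotide cannot
#' reflect methylation; their percentage of the lane's assigned reads is a
#' direct noise readout. Failed-enrichment lanes approach the genome's
#' CpG-barren territory fraction; well-captured lanes sit far below it.
#'
#' @param lane A `methcap_lane`, or a precomputed `methcap_bins`.
#' @param index A `methcap_index`.
#' @return Percentage in \[0, 100\].
#' @export
noise_pct <- function(lane, index) {
  bins <- if (inherits(lane, "methcap_bins")) lane else bin_counts(lane, index)
  zero <- bin_cpg_flat(index) == 0L
  100 * sum(bins$counts[zero]) / bins$total_assigned
}

#' Classify a lane against the QC thresholds
#'
#' A lane fails if any metric is strictly below its threshold; values
#' exactly on a threshold pass.
#'
#' @param metrics Named list or vector with `cpg_enrichment`, `saturation`,
#'   `coverage5x`.
#' @param thresholds A `methcap_qc_thresholds`.
#' @return List with `passed` (logical) and `failed_criteria` (character).
#' @export
qc_classify <- function(metrics, thresholds = qc_thresholds()) {
  m <- as.list(metrics)
  need <- c("cpg_enrichment", "saturation", "coverage5x")
  miss <- setdiff(need, names(m))
  if (length(miss) || any(vapply(m[need], function(x)
        is.null(x) || is.na(x), TRUE)))
    stop("missing QC metric: ",
         paste(union(miss, need[vapply(m[need], function(x)
           is.null(x) || is.na(x), TRUE)]), collapse = ", "))
  failed <- c(
    if (m$cpg_enrichment < thresholds$min_enrichment) "cpg_enrichment",
    if (m$saturation < thresholds$min_saturation) "saturation",
    if (m$coverage5x < thresholds$min_coverage5x) "coverage5x")
  list(passed = length(failed) == 0L, failed_criteria = failed)
}

#' QC report for one lane
#'
#' Computes all four lane metrics (CpG enrichment, saturation, 5x CpG
#' coverage, zero-CpG-bin noise) and the pass/fail verdict.
#'
#' @param lane A `methcap_lane`.
#' @param index A `methcap_index`.
#' @param thresholds A `methcap_qc_thresholds`.
#' @param seed Seed for the saturation partition.
#' @return One-row data frame.
#' @export
qc_lane <- function(lane, index, thresholds = qc_thresholds(), seed = 1L) {
  bins <- bin_counts(lane, index)
  metrics <- list(cpg_enrichment = cpg_enrichment(lane, index),
                  saturation = saturation(lane, index, seed = seed),
                  coverage5x = coverage_5x(lane, index))
  verdict <- qc_classify(metrics, thresholds)
  data.frame(sample_id = lane$sample_id, lane_id = lane$lane_id,
             library_id = lane$library_id,
             total_raw_reads = lane$total_raw_reads,
             total_unique_aligned = lane$total_unique_aligned,
             cpg_enrichment = metrics$cpg_enrichment,
             saturation = metrics$saturation,
             coverage5x = metrics$coverage5x,
             noise_pct = noise_pct(bins, index),
             passed = verdict$passed,
             failed_criteria = paste(verdict$failed_criteria, collapse = ","),
             seed = seed,
             stringsAsFactors = FALSE)
}

#' QC summary table for a set of lanes
#'
#' One row per lane, mirroring a sequencing-core QC summary: metrics, read
#' totals, noise and verdict. Lanes listed in `force_include` keep their
#' metric values but are marked passed (the manual borderline override;
#' never applied automatically).
#'
#' @param lanes List of `methcap_lane` objects.
#' @param index A `methcap_index`.
#' @param thresholds A `methcap_qc_thresholds`.
#' @param seed Base seed; lane i uses `seed + i - 1` for its saturation
#'   partition.
#' @param force_include Character vector of lane_ids to retain despite
#'   failing.
#' @return Data frame of class `methcap_qc_table`.
#' @export
qc_run <- function(lanes, index, thresholds = qc_thresholds(), seed = 1L,
                   force_include = character()) {
  rows <- lapply(seq_along(lanes), function(i)
    qc_lane(lanes[[i]], index, thresholds, seed = seed + i - 1L))
  tab <- do.call(rbind, rows)
  forced <- tab$lane_id %in% force_include & !tab$passed
  tab$forced_include <- forced
  tab$passed[forced] <- TRUE
  class(tab) <- c("methcap_qc_table", "data.frame")
  tab
}

#' Average noise among replicate lanes, by sample and QC status
#'
#' Noise is computed per lane and averaged among a sample's replicate lanes
#' within each QC group. A sample with both a passing and a failing lane
#' appears in both groups, so group sizes need not sum to the number of
#' samples.
#'
#' @param qc_table A `methcap_qc_table` (or data frame with `sample_id`,
#'   `noise_pct`, `passed`).
#' @return Data frame (sample_id, passed, n_lanes, noise_pct).
#' @export
average_noise_by_sample <- function(qc_table) {
  stopifnot(all(c("sample_id", "noise_pct", "passed") %in% names(qc_table)))
  agg <- stats::aggregate(noise_pct ~ sample_id + passed, data = qc_table,
                          FUN = mean)
  n <- stats::aggregate(noise_pct ~ sample_id + passed, data = qc_table,
                        FUN = length)
  out <- merge(agg, n, by = c("sample_id", "passed"),
               suffixes = c("", "_n"))
  names(out)[names(out) == "noise_pct_n"] <- "n_lanes"
  out[order(out$sample_id, out$passed), c("sample_id", "passed", "n_lanes",
                                          "noise_pct")]
}

#' @export
print.methcap_qc_table <- function(x, ...) {
  cat(sprintf("MethylCap-seq QC: %d lanes, %d passed, %d failed\n",
              nrow(x), sum(x$passed), sum(!x$passed)))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
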