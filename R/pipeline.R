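#' Analyze a set of lanes end to end (in memory)
#'
#' The standard workflow on already-loaded lanes: per-lane QC, per-lane
#' binning and RPM normalization, QC exclusion (unless disabled), averaging
#' of replicate lanes per sample, per-sample GMI, and one DMR table per
#' feature set. Samples left with no usable lane after exclusion are
#' dropped; with exclusion disabled every lane contributes, reproducing the
#' "all samples" condition.
#'
#' @param lanes List of `methcap_lane` objects.
#' @param groups Named character vector mapping sample_id to group label.
#' @param index A `methcap_index`.
#' @param features Named list of `methcap_features` (may be empty).
#' @param thresholds A `methcap_qc_thresholds`.
#' @param exclude_failed Drop QC-fail lanes before merging (default TRUE).
#' @param force_include lane_ids retained despite failing QC.
#' @param fdr_cutoff FDR cutoff for DMR significance.
#' @param c_max Top CpG-density class for the GMI.
#' @param seed Base seed for the saturation partitions.
#' @return List with `qc`, `noise_by_sample`, `merged` (per-sample
#'   `methcap_bins`), `gmi` (data frame), `dmr` (list of `methcap_dmr`),
#'   and `samples_used`.
#' @export
analyze_lanes <- function(lanes, groups, index, features = list(),
                          thresholds = qc_thresholds(),
                          exclude_failed = TRUE,
                          force_include = character(),
                          fdr_cutoff = 0.05, c_max = 25L, seed = 1L) {
  stopifnot(length(lanes) >= 1L)
  qc <- qc_run(lanes, index, thresholds, seed = seed,
               force_include = force_include)
  keep <- if (exclude_failed) qc$passed else rep(TRUE, nrow(qc))
  used <- lanes[keep]
  if (length(used) == 0L) stop("no lanes left after QC exclusion")

  by_sample <- split(used, vapply(used, `[[`, "", "sample_id"))
  merged <- lapply(by_sample, function(ls)
    merge_replicate_lanes(lapply(ls, function(l)
      rpm_normalize(bin_counts(l, index)))))

  gmi_tab <- data.frame(
    sample_id = names(merged),
    gmi = vapply(merged, gmi, 0, index = index, c_max = c_max),
    stringsAsFactors = FALSE, row.names = NULL)

  dmr <- list()
  if (length(features)) {
    grp <- groups[names(merged)]
    if (anyNA(grp)) stop("samples missing from groups: ",
                         paste(names(merged)[is.na(grp)], collapse = ", "))
    enough <- length(unique(grp)) == 2L && all(table(grp) >= 2L)
    if (enough) {
      dmr <- lapply(features, function(fs) {
        mat <- vapply(merged, feature_rpm_sum, numeric(nrow(fs)),
                      features = fs, index = index)
        if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(fs),
                                             dimnames = list(fs$feature_id,
                                                             names(merged)))
        rownames(mat) <- fs$feature_id
        call_dmrs(mat, grp, features = fs, fdr_cutoff = fdr_cutoff)
      })
    }
  }
  list(qc = qc,
       noise_by_sample = average_noise_by_sample(qc),
       merged = merged,
       gmi = gmi_tab,
       dmr = dmr,
       samples_used = names(merged))
}

#' Run the full MethylCap-seq pipeline from files
#'
#' Orchestrates index loading/building, lane loading from a manifest, QC
#' with exclusion, replicate merging, DMR calling per feature BED, GMI, and
#' (optionally) spike-in counting plus the GMI regression, writing every
#' table as TSV into the run directory. Re-running with identical inputs
#' reproduces identical outputs: the only randomness is the saturation
#' partition, seeded from the config.
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   entries: `manifest` (TSV path), one of `index_dir` or `fasta`,
#'   `features` (named list of BED paths), `out_dir`, and optionally
#'   `bin_size` (default 500), `thresholds` (named list), `fdr_cutoff`
#'   (0.05), `c_max` (25), `seed` (1), `force_include` (lane ids),
#'   `skip_qc_exclusion` (FALSE), `spikein` (list with `construct_name`).
#' @return The [analyze_lanes()] result, invisibly, with `spikein` and
#'   `out_dir` attached.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("manifest", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing: ", paste(miss, collapse = ", "))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)

  index <- if (!is.null(config$index_dir)) read_genome_index(config$index_dir)
           else if (!is.null(config$fasta))
             build_genome_index(config$fasta, config$bin_size %||% 500L)
           else stop("config needs index_dir or fasta")
  logf("index: %d contigs, %d bins, %d CpGs", length(index$chrom_names),
       index$total_bins, index$total_cpg)

  manifest <- read_manifest(config$manifest)
  construct <- config$spikein$construct_name
  lanes <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    load_alignments(m$path, index, sample_id = m$sample_id,
                    lane_id = m$lane_id, library_id = m$library_id,
                    fragment_length = m$fragment_length,
                    total_raw_reads = if (is.na(m$total_raw_reads)) NULL
                                      else m$total_raw_reads,
                    exclude_contigs = construct %||% character())
  })
  names(lanes) <- manifest$lane_id
  groups <- stats::setNames(manifest$group, manifest$sample_id)
  groups <- groups[!duplicated(names(groups))]

  th <- do.call(qc_thresholds, config$thresholds %||% list())
  res <- analyze_lanes(
    lanes, groups, index,
    features = load_feature_list(config$features),
    thresholds = th,
    exclude_failed = !isTRUE(config$skip_qc_exclusion),
    force_include = config$force_include %||% character(),
    fdr_cutoff = config$fdr_cutoff %||% 0.05,
    c_max = config$c_max %||% 25L,
    seed = config$seed %||% 1L)

  for (i in seq_len(nrow(res$qc)))
    logf("lane %s: enrichment=%.3f saturation=%.3f coverage5x=%.4f noise=%.2f%% %s",
         res$qc$lane_id[i], res$qc$cpg_enrichment[i], res$qc$saturation[i],
         res$qc$coverage5x[i], res$qc$noise_pct[i],
         if (res$qc$passed[i]) "PASS" else
           paste0("FAIL[", res$qc$failed_criteria[i], "]"))

  data.table::fwrite(as.data.frame(res$qc), file.path(out_dir, "qc.tsv"),
                     sep = "\t")
  data.table::fwrite(res$noise_by_sample,
                     file.path(out_dir, "noise_by_sample.tsv"), sep = "\t")
  data.table::fwrite(res$gmi, file.path(out_dir, "gmi.tsv"), sep = "\t")
  for (nm in names(res$dmr))
    write_dmr_table(res$dmr[[nm]], file.path(out_dir,
                                             paste0("dmr_", nm, ".tsv")))
  for (nm in names(res$merged))
    write_bedgraph(res$merged[[nm]], index,
                   file.path(out_dir, paste0("merged_", nm, ".bedgraph")))

  spike <- NULL
  if (!is.null(construct)) {
    per_sample <- split(manifest, manifest$sample_id)
    spike <- do.call(rbind, lapply(per_sample, function(m) {
      recs <- lapply(seq_len(nrow(m)), function(i)
        count_spikein_reads(m$path[i], construct,
                            total_raw_reads = if (is.na(m$total_raw_reads[i]))
                              NULL else m$total_raw_reads[i],
                            sample_id = m$sample_id[i]))
      data.frame(sample_id = m$sample_id[1L],
                 construct_read_count = sum(vapply(recs, `[[`, 0L,
                                                   "construct_read_count")),
                 total_raw_reads = sum(vapply(recs, `[[`, 0L,
                                              "total_raw_reads")),
                 stringsAsFactors = FALSE)
    }))
    spike$construct_rpm <- spike$construct_read_count * 1e6 /
      spike$total_raw_reads
    spike <- merge(spike, res$gmi, by = "sample_id")
    data.table::fwrite(spike, file.path(out_dir, "spikein.tsv"), sep = "\t")
    if (nrow(spike) >= 3L && all(spike$construct_rpm > 0) &&
        stats::sd(1 / spike$construct_rpm) > 0) {
      reg <- gmi_spikein_regression(spike$gmi, spike$construct_rpm)
      data.table::fwrite(
        data.frame(slope = reg$slope, intercept = reg$intercept,
                   r_squared = reg$r_squared, p_value = reg$p_value,
                   n = reg$n),
        file.path(out_dir, "spikein_regression.tsv"), sep = "\t")
      logf("spike-in regression: n=%d R2=%.3f p=%.3g", reg$n,
           reg$r_squared, reg$p_value)
    }
  }
  res$spikein <- spike
  res$out_dir <- out_dir
  logf("done: %d lanes in, %d samples analyzed", length(lanes),
       length(res$samples_used))
  invisible(res)
}

load_feature_list <- function(features) {
  if (is.null(features)) return(list())
  out <- lapply(names(features), function(nm)
    read_features_bed(features[[nm]], name = nm))
  names(out) <- names(features)
  out
}
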