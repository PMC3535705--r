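#' Read a genomic feature set from BED4
#'
#' @param path BED file (chrom, start, end, name). Missing names get
#'   generated ids.
#' @param name Label for the feature class (CpG islands, shores,
#'   promoters, ...); defaults to the file stem.
#' @return A `methcap_features` data frame (chrom, start, end, feature_id).
#' @export
read_features_bed <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name)
         else sprintf("feature_%05d", seq_along(gr))
  feature_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    feature_id = ids,
    stringsAsFactors = FALSE),
    name = name %||% sub("\\.bed$", "", basename(path), ignore.case = TRUE))
}

#' Construct a feature set
#'
#' @param df Data frame with columns chrom, start, end (0-based half-open)
#'   and feature_id.
#' @param name Feature-class label.
#' @return A `methcap_features` data frame.
#' @export
feature_set <- function(df, name = "features") {
  stopifnot(all(c("chrom", "start", "end", "feature_id") %in% names(df)))
  if (any(df$end <= df$start)) stop("features must have end > start")
  if (anyDuplicated(df$feature_id)) stop("feature_ids must be unique")
  structure(df[, c("chrom", "start", "end", "feature_id")],
            class = c("methcap_features", "data.frame"), name = name)
}

#' Sum bin RPM over genomic features
#'
#' For each feature, sums RPM over every grid bin overlapping the feature by
#' at least 1 bp. A bin overlapping two features contributes fully to both.
#'
#' @param sample_bins RPM-normalized (merged) `methcap_bins` for one sample.
#' @param features A `methcap_features`.
#' @param index A `methcap_index`.
#' @return Named numeric vector of summed RPM, one entry per feature.
#' @export
feature_rpm_sum <- function(sample_bins, features, index) {
  stopifnot(inherits(sample_bins, "methcap_bins"),
            inherits(features, "methcap_features"))
  if (is.null(sample_bins$rpm))
    stop("normalize bins with rpm_normalize() first")
  unknown <- setdiff(unique(features$chrom), index$chrom_names)
  if (length(unknown))
    stop("feature on unknown contig: ", paste(unknown, collapse = ", "))
  fgr <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1L, features$end))
  hits <- GenomicRanges::findOverlaps(fgr, bin_granges(index))
  sums <- rep(0, nrow(features))
  contrib <- tapply(sample_bins$rpm[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
  sums[as.integer(names(contrib))] <- as.numeric(contrib)
  stats::setNames(sums, features$feature_id)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. For combined sample sizes
#' up to `exact_max` the p-value is exact, by full enumeration of all
#' `choose(m + n, m)` group assignments of the pooled values; beyond that a
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used. The reported statistic `W` is the rank sum of the first group.
#'
#' @param group_a,group_b Numeric vectors (both nonempty).
#' @param exact_max Largest combined size for exact enumeration (default 12).
#' @return List with `statistic` (W), `p_value`, and `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 (exact)
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_max = 12L) {
  m <- length(group_a); n <- length(group_b)
  if (m == 0L || n == 0L) stop("both groups must be nonempty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  N <- m + n
  if (N <= exact_max) {
    combos <- utils::combn(N, m)
    ws <- colSums(matrix(r[combos], nrow = m))
    tol <- 1e-8
    p <- min(1, 2 * min(mean(ws <= w_obs + tol), mean(ws >= w_obs - tol)))
    return(list(statistic = w_obs, p_value = p, method = "exact"))
  }
  mu <- m * (N + 1) / 2
  ties <- table(pooled)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(statistic = w_obs, p_value = 1, method = "normal"))
  d <- w_obs - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  list(statistic = w_obs,
       p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up procedure: with ordered p-values p_(1) <= ... <= p_(m),
#' `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1, returned in the input
#' order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values)))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially methylated regions
#'
#' One two-sided Wilcoxon rank-sum test per feature on the per-sample summed
#' RPM, Benjamini-Hochberg correction across all features of the set, and a
#' significance flag at the FDR cutoff. Features with zero RPM in every
#' sample are tested anyway (p = 1) so the number of tests is reproducible
#' from the feature set alone.
#'
#' @param feature_sums Numeric matrix, features x samples (rownames =
#'   feature_id), e.g. columns from [feature_rpm_sum()].
#' @param groups Factor or vector of two group labels, one per column.
#' @param features Optional `methcap_features` supplying coordinates for the
#'   output table.
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @return A `methcap_dmr` data frame: feature_id, coordinates, group mean
#'   summed RPM, W, p_value, q_value, significant.
#' @export
call_dmrs <- function(feature_sums, groups, features = NULL,
                      fdr_cutoff = 0.05) {
  feature_sums <- as.matrix(feature_sums)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups required")
  if (length(groups) != ncol(feature_sums))
    stop("one group label per sample column required")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  ga <- groups == levels(groups)[1L]
  tests <- apply(feature_sums, 1L, function(v)
    wilcoxon_rank_sum(v[ga], v[!ga]))
  p <- vapply(tests, `[[`, 0, "p_value")
  q <- bh_fdr(p)
  out <- data.frame(
    feature_id = rownames(feature_sums) %||%
      sprintf("feature_%05d", seq_len(nrow(feature_sums))),
    mean_a = rowMeans(feature_sums[, ga, drop = FALSE]),
    mean_b = rowMeans(feature_sums[, !ga, drop = FALSE]),
    W = vapply(tests, `[[`, 0, "statistic"),
    p_value = p,
    q_value = q,
    significant = q <= fdr_cutoff,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(features)) {
    ord <- match(out$feature_id, features$feature_id)
    out <- cbind(out[, "feature_id", drop = FALSE],
                 features[ord, c("chrom", "start", "end")],
                 out[, -1L])
    rownames(out) <- NULL
  }
  structure(out, class = c("methcap_dmr", "data.frame"),
            fdr_cutoff = fdr_cutoff,
            groups = levels(groups))
}

#' @export
print.methcap_dmr <- function(x, ...) {
  cat(sprintf(
    "DMR table: %d features tested (%s vs %s), %d significant at FDR %.3g\n",
    nrow(x), attr(x, "groups")[1], attr(x, "groups")[2],
    sum(x$significant), attr(x, "fdr_cutoff")))
  print.data.frame(utils::head(x[order(x$q_value), ], 10L), digits = 3,
                   row.names = FALSE)
  if (nrow(x) > 10L) cat("  ... (showing 10 smallest q-values)\n")
  invisible(x)
}

#' Write a DMR table as TSV
#'
#' @param dmr A `methcap_dmr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmr, path) {
  data.table::fwrite(as.data.frame(dmr), path, sep = "\t")
  invisible(path)
}
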