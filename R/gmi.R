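#' CpG-density methylation distribution and GMI
#'
#' Classifies every grid bin with at least one CpG by its CpG count (bins
#' with `c_max` or more CpGs pool into the top class), averages the
#' normalized signal (RPM) over all bins of each class — zero-signal bins
#' included — and sums the class means. That sum, the estimated area under
#' the methylation distribution curve (unit class width), is the global
#' methylation indicator (GMI). Because capture shifts signal from CpG-poor
#' to CpG-dense bins as global methylation rises, GMI rises with the
#' sample's overall methylation while remaining invariant to sequencing
#' depth. Zero-CpG bins are excluded: they are the noise domain, and
#' including them would let enrichment failures inflate the indicator.
#'
#' @param sample_bins RPM-normalized (merged) `methcap_bins`.
#' @param index A `methcap_index`.
#' @param c_max Top (pooled) CpG-density class (default 25).
#' @return A `methcap_gmidist`: data frame (class, n_bins, mean_rpm) plus
#'   attributes `gmi` and `c_max`.
#' @export
methylation_distribution <- function(sample_bins, index, c_max = 25L) {
  stopifnot(inherits(sample_bins, "methcap_bins"),
            inherits(index, "methcap_index"))
  if (is.null(sample_bins$rpm))
    stop("normalize bins with rpm_normalize() first")
  cls <- pmin(bin_cpg_flat(index), as.integer(c_max))
  keep <- cls >= 1L
  if (!any(keep))
    stop("no bins with at least one CpG")
  cls <- cls[keep]
  rpm <- sample_bins$rpm[keep]
  n_bins <- tabulate(cls, nbins = c_max)
  sums <- vapply(seq_len(c_max), function(k) sum(rpm[cls == k]), 0)
  present <- n_bins > 0L
  tab <- data.frame(class = seq_len(c_max)[present],
                    n_bins = n_bins[present],
                    mean_rpm = sums[present] / n_bins[present])
  structure(tab, class = c("methcap_gmidist", "data.frame"),
            gmi = sum(tab$mean_rpm), c_max = as.integer(c_max))
}

#' Global methylation indicator
#'
#' Convenience wrapper returning just the GMI scalar of
#' [methylation_distribution()].
#'
#' @inheritParams methylation_distribution
#' @return GMI (sum of class mean RPM).
#' @export
gmi <- function(sample_bins, index, c_max = 25L) {
  attr(methylation_distribution(sample_bins, index, c_max), "gmi")
}

#' @export
print.methcap_gmidist <- function(x, ...) {
  cat(sprintf("CpG-density methylation distribution (%d classes, c_max %d)\n",
              nrow(x), attr(x, "c_max")))
  cat(sprintf("  GMI (area under the distribution): %.2f RPM\n",
              attr(x, "gmi")))
  invisible(x)
}

#' @export
plot.methcap_gmidist <- function(x, ...) {
  plot(x$class, x$mean_rpm, type = "b", pch = 16,
       xlab = "CpG count per bin", ylab = "mean RPM",
       main = sprintf("Methylation distribution (GMI = %.1f)",
                      attr(x, "gmi")), ...)
  invisible(x)
}

#' Count spike-in construct reads
#'
#' Counts all primary alignments to the in vitro methylated construct
#' contig, duplicates retained (unlike the genomic workflow), and
#' normalizes against the total raw read count of the lane — not the
#' aligned count — to control for lane-yield fluctuation.
#'
#' @param alignments Path to the lane's SAM file (the construct must appear
#'   as a contig in its records or header).
#' @param construct_name Contig name of the spike-in construct.
#' @param total_raw_reads Lane raw read total; defaults to the number of
#'   primary records in the SAM.
#' @param sample_id Optional sample label.
#' @return A `methcap_spikein` list: construct_read_count, construct_rpm,
#'   total_raw_reads.
#' @export
count_spikein_reads <- function(alignments, construct_name,
                                total_raw_reads = NULL,
                                sample_id = NA_character_) {
  rec <- read_sam(alignments)
  hdr <- grep("^@SQ", readLines(alignments, n = 1000L), value = TRUE)
  sq <- sub(".*\tSN:([^\t]+).*", "\\1", hdr)
  targets <- union(sq, unique(rec$rname))
  if (!construct_name %in% targets)
    stop("construct contig not among alignment targets: ", construct_name)
  primary <- !bitwAnd(rec$flag, 0x100L) & !bitwAnd(rec$flag, 0x800L)
  if (is.null(total_raw_reads)) total_raw_reads <- sum(primary)
  k <- sum(primary & !bitwAnd(rec$flag, 0x4L) & rec$rname == construct_name)
  structure(list(sample_id = sample_id,
                 construct_name = construct_name,
                 construct_read_count = k,
                 construct_rpm = k * 1e6 / total_raw_reads,
                 total_raw_reads = as.integer(total_raw_reads)),
            class = "methcap_spikein")
}

#' @export
print.methcap_spikein <- function(x, ...) {
  cat(sprintf("Spike-in %s: %d reads (%.2f RPM of %d raw reads)\n",
              x$construct_name, x$construct_read_count, x$construct_rpm,
              x$total_raw_reads))
  invisible(x)
}

#' Regress GMI on inverse spike-in RPM
#'
#' The fully methylated construct competes with natively methylated genomic
#' fragments for MBD binding, so its post-capture read share falls as the
#' sample's global methylation rises: GMI should scale with the inverse of
#' the construct RPM. This fits ordinary least squares of GMI on
#' 1 / construct RPM and reports the slope, intercept, R-squared and the
#' two-sided t-test p-value on the slope (df = n - 2).
#'
#' @param gmi Numeric vector of per-sample GMI values (or a data frame with
#'   columns `gmi` and `construct_rpm`).
#' @param construct_rpm Per-sample spike-in RPM (all > 0).
#' @return A `methcap_spikereg` list: slope, intercept, r_squared, p_value,
#'   n, and the fitted points.
#' @export
gmi_spikein_regression <- function(gmi, construct_rpm = NULL) {
  if (is.data.frame(gmi)) {
    construct_rpm <- gmi$construct_rpm
    gmi <- gmi$gmi
  }
  n <- length(gmi)
  if (n < 3L) stop("at least 3 samples required")
  if (length(construct_rpm) != n)
    stop("gmi and construct_rpm lengths differ")
  if (any(construct_rpm <= 0))
    stop("all construct_rpm must be positive")
  x <- 1 / construct_rpm
  if (stats::sd(x) == 0) stop("zero variance in inverse construct RPM")
  fit <- stats::lm(gmi ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared,
                 p_value = s$coefficients[2L, 4L],
                 n = n,
                 data = data.frame(inv_rpm = x, gmi = gmi),
                 fit = fit),
            class = "methcap_spikereg")
}

#' @export
print.methcap_spikereg <- function(x, ...) {
  cat("GMI ~ 1 / spike-in RPM (ordinary least squares)\n")
  cat(sprintf("  n = %d, slope = %.4g, intercept = %.4g\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  R-squared = %.3f, p = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' @export
plot.methcap_spikereg <- function(x, ...) {
  plot(x$data$inv_rpm, x$data$gmi, pch = 16,
       xlab = "1 / construct RPM", ylab = "GMI",
       main = sprintf("R-squared = %.3f, p = %.3g", x$r_squared,
                      x$p_value), ...)
  graphics::abline(x$fit, lty = 2)
  invisible(x)
}
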