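#' Simulation configuration for an MBD-capture experiment
#'
#' Desk-scale defaults: a 2 Mb single-contig genome carrying CpG islands on
#' a CpG-poor background with 10% CpG-free territory, 100,000 reads per
#' lane, 36-bp single-end reads extended to 150-bp fragments, 5% injected
#' PCR duplicates, and a fully methylated CpG-dense spike-in construct
#' present at 2.5 copies per genome that competes for capture in the same
#' weighted draw as the genomic fragments. The capture model selects a
#' fragment with weight `1 + capture_strength * (methylated CpGs in the
#' fragment)`; `capture_strength = 0` reproduces a failed enrichment (or an
#' input library), where sampling is uniform.
#'
#' @param seed RNG seed; (config, seed) fully determines every output.
#' @param genome_length Genome size in bp.
#' @param n_islands Number of CpG islands.
#' @param island_length Island length in bp (placed on bin boundaries).
#' @param island_cpg_rate CpGs per bp inside islands.
#' @param background_cpg_rate CpGs per bp in background regions.
#' @param zero_cpg_fraction Fraction of bins with no CpGs at all.
#' @param methylation_level Probability that a CpG region (island or
#'   background segment) is methylated.
#' @param capture_strength Capture weight slope k (>= 0).
#' @param fragment_length,read_length Fragment and read sizes in bp.
#' @param reads_per_lane Reads emitted per lane (before duplicate injection).
#' @param duplicate_rate Expected injected PCR-duplicate fraction in \[0, 1).
#' @param failed_dispersion_library,failed_dispersion_lane Gamma shapes of
#'   the two per-bin distortion fields applied in failed-enrichment mode
#'   (squared coefficient of variation `1/shape` each). A capture failure
#'   does not yield a clean input profile: residual, uncontrolled binding
#'   distorts fragment recovery. Part of the distortion arises at library
#'   preparation and is shared by replicate lanes of the library; the rest
#'   is lane-specific, which is what makes failed libraries poorly
#'   reproducible across lanes. The combined field is re-centered within
#'   every bin CpG-density class, because a failed capture redistributes
#'   fragments without enriching CpGs. `input` mode stays undistorted
#'   uniform sampling.
#' @param spikein_copies_per_genome Construct copy number (0 disables).
#' @param construct_length,construct_name,construct_cpg_period Spike-in
#'   construct size, contig name, and CpG spacing (one CpG every
#'   `construct_cpg_period` bp; the construct is always fully methylated).
#' @param bin_size Bin grid width in bp.
#' @param background_region_bins Background segmentation unit, in bins, for
#'   region-level methylation states.
#' @return A validated `methcap_simconfig` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_islands = 100L,
                       island_length = 1000L,
                       island_cpg_rate = 0.1,
                       background_cpg_rate = 0.01,
                       zero_cpg_fraction = 0.10,
                       methylation_level = 0.5,
                       capture_strength = 2,
                       fragment_length = 150L,
                       read_length = 36L,
                       reads_per_lane = 1e5,
                       duplicate_rate = 0.05,
                       failed_dispersion_library = 1.6,
                       failed_dispersion_lane = 2.8,
                       spikein_copies_per_genome = 2.5,
                       construct_length = 5300L,
                       construct_name = "construct_mSssI",
                       construct_cpg_period = 10L,
                       bin_size = 500L,
                       background_region_bins = 4L) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_islands = as.integer(n_islands),
              island_length = as.integer(island_length),
              island_cpg_rate = island_cpg_rate,
              background_cpg_rate = background_cpg_rate,
              zero_cpg_fraction = zero_cpg_fraction,
              methylation_level = methylation_level,
              capture_strength = capture_strength,
              fragment_length = as.integer(fragment_length),
              read_length = as.integer(read_length),
              reads_per_lane = as.integer(reads_per_lane),
              duplicate_rate = duplicate_rate,
              failed_dispersion_library = failed_dispersion_library,
              failed_dispersion_lane = failed_dispersion_lane,
              spikein_copies_per_genome = spikein_copies_per_genome,
              construct_length = as.integer(construct_length),
              construct_name = construct_name,
              construct_cpg_period = as.integer(construct_cpg_period),
              bin_size = as.integer(bin_size),
              background_region_bins = as.integer(background_region_bins))
  stopifnot(cfg$genome_length >= cfg$bin_size,
            cfg$island_cpg_rate > 0, cfg$island_cpg_rate <= 0.5,
            cfg$background_cpg_rate >= 0, cfg$background_cpg_rate <= 0.5,
            cfg$zero_cpg_fraction >= 0, cfg$zero_cpg_fraction < 1,
            cfg$methylation_level >= 0, cfg$methylation_level <= 1,
            cfg$capture_strength >= 0,
            cfg$fragment_length >= cfg$read_length,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate < 1,
            cfg$failed_dispersion_library > 0,
            cfg$failed_dispersion_lane > 0,
            cfg$spikein_copies_per_genome >= 0,
            cfg$construct_length > cfg$fragment_length)
  if (cfg$n_islands * cfg$island_length >
      (1 - cfg$zero_cpg_fraction) * cfg$genome_length)
    stop("island territory exceeds available genome")
  structure(cfg, class = "methcap_simconfig")
}

#' @export
print.methcap_simconfig <- function(x, ...) {
  cat("MBD-capture simulation config\n")
  cat(sprintf("  genome %s bp, %d islands x %d bp, %.0f%% CpG-free bins\n",
              format(x$genome_length, big.mark = ","), x$n_islands,
              x$island_length, 100 * x$zero_cpg_fraction))
  cat(sprintf("  methylation level %.2f, capture strength %.2f\n",
              x$methylation_level, x$capture_strength))
  cat(sprintf("  %s reads/lane, %d bp reads -> %d bp fragments, %.0f%% dups\n",
              format(x$reads_per_lane, big.mark = ","), x$read_length,
              x$fragment_length, 100 * x$duplicate_rate))
  cat(sprintf("  spike-in: %.1f copies of %d bp construct\n",
              x$spikein_copies_per_genome, x$construct_length))
  invisible(x)
}

#' Simulate a genome with known CpG layout and methylation truth
#'
#' Builds a single-contig genome of three strata — CpG islands, CpG-poor
#' background, and CpG-free territory — plus the spike-in construct
#' sequence. CpG-free territory is assigned at bin granularity so the
#' zero-CpG-bin fraction of the built index tracks `zero_cpg_fraction`;
#' islands sit on bin boundaries inside non-desert territory; the remaining
#' territory is chopped into background segments of a few bins each. CpGs
#' are planted at even offsets within each region at the region's rate, and
#' the base sequence is scrubbed of accidental CG dinucleotides first, so
#' the CpG truth table is exact. A baseline region methylation state vector
#' is drawn at `methylation_level` (per-sample overrides are drawn in
#' [simulate_cohort()]).
#'
#' @param config A `methcap_simconfig`.
#' @param seed Seed override (defaults to `config$seed`).
#' @return A `methcap_simgenome` with fields `seq`, `construct_seq`,
#'   `regions`, `cpg`, `region_state`, `islands`, `desert_bins`.
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "methcap_simconfig"))
  with_seed(seed, {
    G <- config$genome_length
    bs <- config$bin_size
    n_full <- G %/% bs
    nbins <- as.integer(ceiling(G / bs))

    n_desert <- round(config$zero_cpg_fraction * nbins)
    desert <- sort(sample.int(n_full, n_desert))
    is_desert <- rep(FALSE, nbins)
    is_desert[desert] <- TRUE

    span <- as.integer(ceiling(config$island_length / bs))
    free <- !is_desert
    if (nbins > n_full) free[nbins] <- FALSE  # partial last bin stays empty
    island_start_bin <- integer(config$n_islands)
    for (i in seq_len(config$n_islands)) {
      ok <- which(vapply(seq_len(nbins - span + 1L), function(b)
        all(free[b:(b + span - 1L)]), TRUE))
      if (length(ok) == 0L) stop("island territory exceeds genome")
      b <- if (length(ok) == 1L) ok else sample(ok, 1L)
      island_start_bin[i] <- b
      free[b:(b + span - 1L)] <- FALSE
    }
    island_start_bin <- sort(island_start_bin)
    islands <- data.frame(
      island_id = sprintf("island_%03d", seq_len(config$n_islands)),
      start = (island_start_bin - 1L) * bs,
      end = (island_start_bin - 1L) * bs + config$island_length,
      stringsAsFactors = FALSE)

    # background: contiguous runs of remaining free bins, chopped into
    # segments of background_region_bins bins
    bg_runs <- rle_runs(free)
    bg <- do.call(rbind, lapply(seq_len(nrow(bg_runs)), function(i) {
      b0 <- bg_runs$start[i]; b1 <- bg_runs$end[i]
      cuts <- seq(b0, b1 + 1L, by = config$background_region_bins)
      if (cuts[length(cuts)] != b1 + 1L) cuts <- c(cuts, b1 + 1L)
      data.frame(start = (cuts[-length(cuts)] - 1L) * bs,
                 end = pmin((cuts[-1L] - 1L) * bs, G))
    }))
    regions <- rbind(
      data.frame(start = islands$start, end = islands$end,
                 type = "island", stringsAsFactors = FALSE),
      data.frame(start = bg$start, end = bg$end, type = "background",
                 stringsAsFactors = FALSE))
    regions <- regions[order(regions$start), ]
    regions$region_id <- seq_len(nrow(regions))
    rownames(regions) <- NULL

    cpg <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      rate <- if (r$type == "island") config$island_cpg_rate
              else config$background_cpg_rate
      cand <- seq.int(r$start, r$end - 2L, by = 2L)
      pos <- cand[stats::runif(length(cand)) < 2 * rate]
      if (length(pos) == 0L) return(NULL)
      data.frame(pos = pos, region_id = r$region_id)
    }))
    if (is.null(cpg)) cpg <- data.frame(pos = integer(), region_id = integer())

    seq_chr <- plant_cpgs(random_cg_free_sequence(G), cpg$pos)
    con_pos <- seq.int(0L, config$construct_length - 2L,
                       by = config$construct_cpg_period)
    construct_seq <- plant_cpgs(
      random_cg_free_sequence(config$construct_length), con_pos)

    region_state <- stats::rbinom(nrow(regions), 1L,
                                  config$methylation_level) == 1L

    structure(list(config = config,
                   chrom_name = "chr1",
                   seq = seq_chr,
                   construct_seq = construct_seq,
                   construct_cpg = con_pos,
                   regions = regions,
                   islands = islands,
                   cpg = cpg,
                   region_state = region_state,
                   desert_bins = desert),
              class = "methcap_simgenome")
  })
}

rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Uniform random sequence with every accidental CG dinucleotide broken
# (the G of each CG becomes A), so planted CpGs are the only CpGs.
random_cg_free_sequence <- function(n) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  cg <- which(b[-n] == "C" & b[-1L] == "G")
  if (length(cg)) b[cg + 1L] <- "A"
  b
}

# Plant CG at the given 0-based C positions (callers guarantee spacing >= 2).
plant_cpgs <- function(b, pos) {
  if (length(pos)) {
    b[pos + 1L] <- "C"
    b[pos + 2L] <- "G"
  }
  paste(b, collapse = "")
}

#' Write a simulated genome (plus spike-in construct) as FASTA
#'
#' @param genome A `methcap_simgenome`.
#' @param path Output FASTA path.
#' @param include_construct Append the construct contig (default TRUE).
#' @return `path`, invisibly.
#' @export
write_sim_fasta <- function(genome, path, include_construct = TRUE) {
  stopifnot(inherits(genome, "methcap_simgenome"))
  seqs <- c(genome$seq)
  names(seqs) <- genome$chrom_name
  if (include_construct) {
    seqs <- c(seqs, genome$construct_seq)
    names(seqs)[2L] <- genome$config$construct_name
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Genome index of a simulated genome, from truth
#'
#' Builds the `methcap_index` directly from the simulator's exact CpG truth
#' table (no FASTA scan); identical to running [build_genome_index()] on
#' the written FASTA without the construct contig.
#'
#' @param genome A `methcap_simgenome`.
#' @return A `methcap_index`.
#' @export
sim_index <- function(genome) {
  stopifnot(inherits(genome, "methcap_simgenome"))
  new_genome_index(genome$chrom_name, genome$config$genome_length,
                   genome$config$bin_size,
                   stats::setNames(list(sort(genome$cpg$pos)),
                                   genome$chrom_name))
}

#' Simulate one sequencing lane
#'
#' Fragments of `fragment_length` bp are drawn (with replacement) from all
#' genomic start positions with probability proportional to
#' `1 + k * (methylated CpGs in the fragment)` in captured mode, or
#' uniformly in failed/input mode (k forced to 0). Spike-in construct
#' fragments compete in the same draw, weighted additionally by the
#' construct copy number. Each fragment yields one read — its first (plus
#' strand) or last (minus strand) `read_length` bases — and PCR duplicates
#' are injected by resampling emitted reads at `duplicate_rate`. The truth
#' log records everything needed to verify downstream statistics.
#'
#' @param genome A `methcap_simgenome`.
#' @param mode `"captured"`, `"failed"` (enrichment failure) or `"input"`
#'   (no capture step); the latter two sample uniformly, and failed mode
#'   additionally applies a per-lane distortion field (see [sim_config()]).
#' @param seed Lane seed.
#' @param region_states Optional logical vector overriding the genome's
#'   baseline per-region methylation states (one entry per region).
#' @param cpg_states Optional logical vector of per-CpG methylation states
#'   (one entry per row of `genome$cpg`), taking precedence over
#'   `region_states`; used for fractional region methylation, where a
#'   sample's CpG states are drawn once and shared by its replicate lanes.
#' @param sample_id,lane_id,library_id Lane identifiers.
#' @param library_seed Seed of the library-preparation distortion shared by
#'   replicate lanes of one library (defaults to the lane seed); only used
#'   in failed mode.
#' @param reads_per_lane Override of `config$reads_per_lane`.
#' @param sam Optional path; when given, the lane is also written as SAM
#'   (header + one record per read, real sequences, reverse-complemented on
#'   the minus strand).
#' @return A `methcap_simlane`: `reads` data frame (chrom, start, strand,
#'   read_length, is_duplicate), `truth` list, ids, and `sam` path if
#'   written.
#' @export
simulate_lane <- function(genome, mode = c("captured", "failed", "input"),
                          seed = 1L, region_states = NULL,
                          cpg_states = NULL,
                          sample_id = "S1", lane_id = "L1",
                          library_id = sample_id,
                          library_seed = seed,
                          reads_per_lane = NULL, sam = NULL) {
  stopifnot(inherits(genome, "methcap_simgenome"))
  mode <- match.arg(mode)
  cfg <- genome$config
  n_reads <- as.integer(reads_per_lane %||% cfg$reads_per_lane)
  if (n_reads < 1L) stop("reads_per_lane must be >= 1")
  if (is.null(cpg_states)) {
    states <- region_states %||% genome$region_state
    if (length(states) != nrow(genome$regions))
      stop("region_states length must match the number of regions")
    cpg_states <- states[genome$cpg$region_id]
  }
  if (length(cpg_states) != nrow(genome$cpg))
    stop("cpg_states length must match the number of CpGs")
  k <- if (mode == "captured") cfg$capture_strength else 0
  L <- cfg$fragment_length
  rl <- cfg$read_length
  G <- cfg$genome_length

  meth_pos <- genome$cpg$pos[cpg_states]
  w_gen <- 1 + k * window_counts(meth_pos, G, L)
  n_gen <- length(w_gen)

  if (mode == "failed") {
    # residual, uncontrolled binding: per-bin distortion, partly shared by
    # all lanes of the library, partly lane-specific; constrained to be
    # CpG-neutral (re-centered within each bin CpG-density class)
    nb <- as.integer(ceiling(G / cfg$bin_size))
    g_lib <- with_seed(library_seed + 104729L,
                       stats::rgamma(nb, shape = cfg$failed_dispersion_library,
                                     rate = cfg$failed_dispersion_library))
    g_lane <- with_seed(seed + 224737L,
                        stats::rgamma(nb, shape = cfg$failed_dispersion_lane,
                                      rate = cfg$failed_dispersion_lane))
    gf <- g_lib * g_lane
    cls <- tabulate(genome$cpg$pos %/% cfg$bin_size + 1L, nb)
    for (cv in unique(cls)) {
      i <- cls == cv
      gf[i] <- gf[i] / mean(gf[i])
    }
    w_gen <- w_gen * gf[(0:(G - L)) %/% cfg$bin_size + 1L]
  }

  use_spike <- cfg$spikein_copies_per_genome > 0
  if (use_spike) {
    w_con <- cfg$spikein_copies_per_genome *
      (1 + k * window_counts(genome$construct_cpg, cfg$construct_length, L))
  } else w_con <- numeric(0)

  with_seed(seed, {
    pick <- sample.int(n_gen + length(w_con), n_reads, replace = TRUE,
                       prob = c(w_gen, w_con))
    from_construct <- pick > n_gen
    frag_start <- ifelse(from_construct, pick - n_gen - 1L, pick - 1L)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    start <- ifelse(strand == "+", frag_start, frag_start + L - rl)
    reads <- data.frame(
      chrom = ifelse(from_construct, cfg$construct_name, genome$chrom_name),
      start = as.integer(start),
      strand = strand,
      read_length = rl,
      is_duplicate = FALSE,
      stringsAsFactors = FALSE)
    n_dup <- stats::rbinom(1L, n_reads, cfg$duplicate_rate)
    if (n_dup > 0L) {
      di <- sample.int(n_reads, n_dup, replace = TRUE)
      dup <- reads[di, , drop = FALSE]
      dup$is_duplicate <- TRUE
      reads <- rbind(reads, dup)
      from_construct <- c(from_construct, from_construct[di])
      frag_start <- c(frag_start, frag_start[di])
    }
    rownames(reads) <- NULL
    key <- paste(reads$chrom, reads$start, reads$strand)
    gkey <- !reads$chrom %in% cfg$construct_name
    meth_frag <- rep(FALSE, nrow(reads))
    if (length(meth_pos) && any(!from_construct)) {
      idx <- which(!from_construct)
      meth_frag[idx] <- (findInterval(frag_start[idx] + L - 1L, meth_pos) -
                           findInterval(frag_start[idx] - 1L, meth_pos)) > 0L
    }
    truth <- list(
      mode = mode, seed = seed,
      n_emitted = nrow(reads),
      n_injected_duplicates = n_dup,
      n_construct_reads = sum(from_construct),
      n_unique_aligned = length(unique(key)),
      n_unique_genome = length(unique(key[gkey])),
      frac_reads_methylated_fragment = mean(meth_frag[!from_construct]))
    out <- structure(list(reads = reads, truth = truth,
                          sample_id = sample_id, lane_id = lane_id,
                          library_id = library_id, mode = mode,
                          chrom_name = genome$chrom_name,
                          construct_name = cfg$construct_name,
                          fragment_length = L, sam = NULL),
                     class = "methcap_simlane")
    if (!is.null(sam)) {
      write_sim_sam(out, genome, sam)
      out$sam <- sam
    }
    out
  })
}

# Number of elements of sorted 0-based positions `pos` in [s, s+L) for every
# fragment start s = 0 .. G-L.
window_counts <- function(pos, G, L) {
  st <- 0:(G - L)
  if (length(pos) == 0L) return(numeric(length(st)))
  pos <- sort(pos)
  ind <- integer(G)
  ind[pos + 1L] <- 1L
  cs <- c(0L, cumsum(ind))
  as.numeric(cs[st + L + 1L] - cs[st + 1L])
}

#' Write a simulated lane as SAM
#'
#' @param lane A `methcap_simlane`.
#' @param genome The `methcap_simgenome` it was drawn from.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(lane, genome, path) {
  cfg <- genome$config
  r <- lane$reads
  seqs <- c(stats::setNames(genome$seq, genome$chrom_name),
            stats::setNames(genome$construct_seq, cfg$construct_name))
  raw <- substring(seqs[r$chrom], r$start + 1L, r$start + r$read_length)
  minus <- r$strand == "-"
  if (any(minus))
    raw[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(raw[minus])))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom_name, cfg$genome_length),
           if (cfg$spikein_copies_per_genome > 0)
             sprintf("@SQ\tSN:%s\tLN:%d", cfg$construct_name,
                     cfg$construct_length))
  rec <- sprintf("read%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                 seq_len(nrow(r)), ifelse(minus, 16L, 0L), r$chrom,
                 r$start + 1L, r$read_length, raw)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Convert a simulated lane to an analysis lane
#'
#' Applies the standard loading rules in memory: construct reads are set
#' aside (they count toward the raw total only) and genomic reads are
#' deduplicated on (chrom, start, strand).
#'
#' @param simlane A `methcap_simlane`.
#' @return A `methcap_lane`.
#' @export
as_lane <- function(simlane) {
  stopifnot(inherits(simlane, "methcap_simlane"))
  reads <- simlane$reads[simlane$reads$chrom != simlane$construct_name,
                         c("chrom", "start", "strand", "read_length")]
  lane_from_reads(reads,
                  sample_id = simlane$sample_id,
                  lane_id = simlane$lane_id,
                  library_id = simlane$library_id,
                  fragment_length = simlane$fragment_length,
                  total_raw_reads = nrow(simlane$reads))
}

#' Simulate a two-group cohort with known differential methylation
#'
#' Simulates one genome and designates a fraction of its CpG islands —
#' together with the regions overlapping their 500-bp shores, since
#' differential methylation rarely stops at an island boundary — as truly
#' differentially methylated units. Every region is methylated
#' independently per sample (biological heterogeneity): non-DM regions at
#' `methylation_level`, DM units at `methylation_level + d` in group A and
#' `methylation_level - d` in group B, with the effect size `d` drawn once
#' per unit from `dm_effect_range`, so true effects span borderline to
#' strong. A chosen number of samples per group are sequenced in
#' failed-enrichment mode, emulating capture failures that QC should catch.
#' Feature sets (islands, shores, island promoters) and the full truth are
#' returned; with `dir` set, FASTA, per-lane SAM files, a manifest, feature
#' BEDs and a JSON truth log are written, forming a complete on-disk
#' experiment for the pipeline.
#'
#' @param config A `methcap_simconfig`.
#' @param n_per_group Samples per group, length 2.
#' @param lanes_per_sample Replicate lanes per sample.
#' @param n_failed_per_group Samples per group whose lanes are simulated in
#'   failed-enrichment mode (the last ones of each group).
#' @param dm_fraction Fraction of islands truly differentially methylated.
#' @param dm_effect_range Range of the per-unit methylation-fraction
#'   shift between groups (group A gets `+d`, group B `-d`).
#' @param methylation_concentration Beta concentration of per-sample region
#'   methylation fractions around their group mean; smaller values mean
#'   more biological heterogeneity (default 10, i.e. SD ~ 0.15 at a mean
#'   of 0.5).
#' @param methylation_levels Optional per-sample global methylation levels
#'   (overrides `config$methylation_level` for non-DM regions).
#' @param seed Cohort seed (genome and all lane seeds derive from it).
#' @param dir Optional output directory for on-disk artifacts.
#' @return A `methcap_simcohort`: `genome`, `samples` data frame, `lanes`
#'   (list of `methcap_simlane`), `features` (list of three
#'   `methcap_features`), `truth` (DM island ids, per-sample states), and
#'   file paths when written.
#' @export
simulate_cohort <- function(config, n_per_group = c(10L, 10L),
                            lanes_per_sample = 1L,
                            n_failed_per_group = c(0L, 0L),
                            dm_fraction = 0.1,
                            dm_effect_range = c(0.2, 0.5),
                            methylation_concentration = 10,
                            methylation_levels = NULL,
                            seed = config$seed, dir = NULL) {
  stopifnot(inherits(config, "methcap_simconfig"),
            length(n_per_group) == 2L, all(n_per_group >= 1L),
            all(n_failed_per_group <= n_per_group))
  genome <- simulate_genome(config, seed = seed)
  n_samples <- sum(n_per_group)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    group = rep(c("A", "B"), n_per_group),
    mode = "captured",
    methylation_level = methylation_levels %||%
      rep(config$methylation_level, n_samples),
    stringsAsFactors = FALSE)
  for (g in 1:2) {
    gi <- which(samples$group == c("A", "B")[g])
    nf <- n_failed_per_group[g]
    if (nf > 0L) samples$mode[utils::tail(gi, nf)] <- "failed"
  }

  with_seed(seed + 1L, {
    n_dm <- round(dm_fraction * config$n_islands)
    dm_islands <- sort(sample.int(config$n_islands, n_dm))
    island_region_ids <- genome$regions$region_id[
      genome$regions$type == "island"]
    # a DM unit is an island plus any region overlapping its 500-bp shores:
    # differential methylation rarely stops dead at an island boundary
    shore <- 500L
    dm_units <- lapply(dm_islands, function(i) {
      isl <- genome$islands[i, ]
      hit <- genome$regions$start < isl$end + shore &
        genome$regions$end > isl$start - shore
      genome$regions$region_id[hit]
    })
    # per-unit effect size: mean methylation fraction methylation_level +/- d
    # with d drawn once per unit, so true effects range from borderline to
    # strong
    dm_delta <- stats::runif(n_dm, dm_effect_range[1], dm_effect_range[2])
    n_regions <- nrow(genome$regions)
    shift <- numeric(n_regions)
    for (u in seq_along(dm_units)) shift[dm_units[[u]]] <- dm_delta[u]
    # fractional methylation: each region of each sample has a methylation
    # fraction drawn from a Beta around its group mean (biological
    # heterogeneity: subclones, cellularity), and each CpG of the sample is
    # methylated with that fraction. CpG states belong to the sample's DNA,
    # so replicate lanes share them.
    kappa <- methylation_concentration
    frac_mat <- matrix(0, n_regions, n_samples)
    cpg_state_mat <- matrix(FALSE, nrow(genome$cpg), n_samples)
    for (s in seq_len(n_samples)) {
      mu <- samples$methylation_level[s] +
        if (samples$group[s] == "A") shift else -shift
      mu <- pmin(pmax(mu, 0.02), 0.98)
      f <- stats::rbeta(n_regions, mu * kappa, (1 - mu) * kappa)
      frac_mat[, s] <- f
      cpg_state_mat[, s] <- stats::runif(nrow(genome$cpg)) <
        f[genome$cpg$region_id]
    }
    dm_region_ids <- sort(unique(unlist(dm_units)))
    lane_seeds <- matrix(sample.int(.Machine$integer.max %/% 2L,
                                    n_samples * lanes_per_sample),
                         n_samples, lanes_per_sample)
    library_seeds <- sample.int(.Machine$integer.max %/% 2L, n_samples)
  })

  lanes <- list()
  manifest <- NULL
  for (s in seq_len(n_samples)) {
    for (l in seq_len(lanes_per_sample)) {
      lane_id <- sprintf("%s_L%d", samples$sample_id[s], l)
      sam_path <- if (!is.null(dir))
        file.path(dir, "lanes", paste0(lane_id, ".sam"))
      if (!is.null(sam_path))
        dir.create(dirname(sam_path), showWarnings = FALSE, recursive = TRUE)
      sl <- simulate_lane(
        genome,
        mode = if (samples$mode[s] == "failed") "failed" else "captured",
        seed = lane_seeds[s, l],
        cpg_states = cpg_state_mat[, s],
        sample_id = samples$sample_id[s], lane_id = lane_id,
        library_id = samples$sample_id[s],
        library_seed = library_seeds[s], sam = sam_path)
      lanes[[lane_id]] <- sl
      manifest <- rbind(manifest, data.frame(
        sample_id = samples$sample_id[s], lane_id = lane_id,
        library_id = samples$sample_id[s],
        path = if (is.null(sam_path)) NA_character_ else sam_path,
        fragment_length = config$fragment_length,
        total_raw_reads = sl$truth$n_emitted,
        group = samples$group[s], stringsAsFactors = FALSE))
    }
  }

  features <- sim_feature_sets(genome)
  truth <- list(dm_islands = genome$islands$island_id[dm_islands],
                dm_delta = dm_delta,
                dm_region_ids = dm_region_ids,
                region_fractions = frac_mat,
                cpg_states = cpg_state_mat,
                samples = samples)
  out <- structure(list(genome = genome, samples = samples, lanes = lanes,
                        manifest = manifest, features = features,
                        truth = truth, dir = dir),
                   class = "methcap_simcohort")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    # reference for indexing excludes the construct: spike-in reads are
    # counted separately, never binned
    write_sim_fasta(genome, file.path(dir, "genome.fa"),
                    include_construct = FALSE)
    write_sim_fasta(genome, file.path(dir, "genome_plus_construct.fa"),
                    include_construct = TRUE)
    data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
    for (fs in features) {
      bed <- data.frame(fs$chrom, fs$start, fs$end, fs$feature_id)
      data.table::fwrite(bed, file.path(dir, paste0(attr(fs, "name"), ".bed")),
                         sep = "\t", col.names = FALSE)
    }
    jsonlite::write_json(
      list(dm_islands = truth$dm_islands, samples = samples),
      file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  out
}

#' Feature sets of a simulated genome
#'
#' Islands (the simulated CpG islands), shores (500-bp flanks on both sides
#' of each island) and promoters (1-kb windows centered on each island
#' start, as if the island sat at a transcription start site).
#'
#' @param genome A `methcap_simgenome`.
#' @param shore_width Shore width in bp (default 500).
#' @param promoter_halfwidth Promoter half-width in bp (default 500).
#' @return Named list of three `methcap_features`.
#' @export
sim_feature_sets <- function(genome, shore_width = 500L,
                             promoter_halfwidth = 500L) {
  isl <- genome$islands
  G <- genome$config$genome_length
  cn <- genome$chrom_name
  islands <- feature_set(data.frame(
    chrom = cn, start = isl$start, end = isl$end,
    feature_id = isl$island_id, stringsAsFactors = FALSE), "islands")
  sh <- data.frame(
    chrom = cn,
    start = pmax(c(isl$start - shore_width, isl$end), 0L),
    end = pmin(c(isl$start, isl$end + shore_width), G),
    feature_id = c(paste0(isl$island_id, "_shoreL"),
                   paste0(isl$island_id, "_shoreR")),
    stringsAsFactors = FALSE)
  shores <- feature_set(sh[sh$end > sh$start, ], "shores")
  promoters <- feature_set(data.frame(
    chrom = cn,
    start = pmax(isl$start - promoter_halfwidth, 0L),
    end = pmin(isl$start + promoter_halfwidth, G),
    feature_id = sub("island", "promoter", isl$island_id),
    stringsAsFactors = FALSE), "promoters")
  list(islands = islands, shores = shores, promoters = promoters)
}

#' Draw per-CpG methylation states for a sample at a global level
#'
#' Defines "a sample with global methylation level m": each region receives
#' a methylation fraction drawn from a Beta distribution with mean `level`
#' and the given concentration (biological heterogeneity), and each CpG of
#' the sample is methylated with its region's fraction. With
#' `concentration = Inf` every region sits exactly at `level`, the idealized
#' homogeneous condition used for parameter-recovery experiments. States
#' describe the sample's DNA, so replicate lanes should share one draw.
#'
#' @param genome A `methcap_simgenome`.
#' @param level Target global methylation level in \[0, 1\].
#' @param seed RNG seed for the draw.
#' @param concentration Beta concentration of region fractions around
#'   `level` (default 10); `Inf` for a homogeneous sample.
#' @return Logical vector, one state per row of `genome$cpg`, usable as
#'   `cpg_states` in [simulate_lane()].
#' @export
sample_cpg_states <- function(genome, level, seed, concentration = 10) {
  stopifnot(inherits(genome, "methcap_simgenome"),
            level >= 0, level <= 1, concentration > 0)
  with_seed(seed, {
    n_regions <- nrow(genome$regions)
    f <- if (is.finite(concentration)) {
      mu <- pmin(pmax(level, 0.02), 0.98)
      stats::rbeta(n_regions, mu * concentration,
                   (1 - mu) * concentration)
    } else rep(level, n_regions)
    stats::runif(nrow(genome$cpg)) < f[genome$cpg$region_id]
  })
}
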