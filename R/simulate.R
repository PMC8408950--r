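#' Specification for a synthetic snATAC-seq sample
#'
#' Describes a fully synthetic single-nucleus ATAC-seq experiment on a small
#' fictitious genome with known singlet/multiplet truth. Each singlet nucleus
#' is diploid: per accessible peak it contributes 0, 1 or 2 distinct
#' fragments (one per captured open allele), so no singlet can exceed depth 2
#' at a peak after deduplication. Cell types are defined by disjoint
#' marker-peak sets on top of a common set of shared peaks. Repeat hotspots
#' are loci where most nuclei pile up more than two fragments, giving the
#' repetitive-region inference real signal. PCR duplicates are emitted via
#' the fragments-file duplicate-count column.
#'
#' Sequencing depth is specified on the published scale (median valid read
#' pairs per nucleus, e.g. 25000) and mapped onto the toy genome with the
#' fixed `depth_scale` factor: the per-allele capture probability is
#' `1 - exp(-d * (1 - noise_rate) / (2 * n_accessible * allele_open_prob))`
#' with `d = depth_per_nucleus * depth_scale`, so the capture regime (and
#' hence the depth-recall relationship) tracks the real-data depth axis while
#' the absolute fragment counts stay small enough for fast tests.
#'
#' @param n_nuclei Number of cell-called singlet nuclei.
#' @param n_cell_types Number of cell types (equal proportions by default).
#' @param proportions Optional explicit proportions (must sum to 1).
#' @param n_peaks Total peaks on the toy genome.
#' @param markers_per_type Marker peaks private to each cell type.
#' @param peak_width Peak width in bp.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param depth_per_nucleus Nominal median valid read pairs per nucleus
#'   (published scale).
#' @param depth_scale Fixed toy-genome scale factor applied to
#'   `depth_per_nucleus` (default 1/25; 25k nominal -> ~1000 fragments).
#' @param depth_cv Log-normal spread of per-nucleus depth around the median.
#' @param allele_open_prob Probability that an allele of an accessible peak is
#'   open in a given nucleus.
#' @param noise_rate Fraction of a nucleus's fragments placed uniformly on
#'   the genome rather than in peaks.
#' @param n_repeat_hotspots Number of planted repeat hotspots.
#' @param hotspot_rate Mean fragments per nucleus per hotspot.
#' @param duplicate_rate Mean extra PCR copies per unique fragment.
#' @param frag_len_shape,frag_len_scale Gamma parameters of the fragment
#'   length distribution (mean ~250 bp by default, truncated to [50, 900]).
#' @param n_background Non-cell background barcodes written to the barcode
#'   table with a trickle of fragments.
#' @param seed Master seed; all stage streams derive from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nuclei = 1000L, n_cell_types = 4L,
                           proportions = NULL, n_peaks = 2000L,
                           markers_per_type = 100L, peak_width = 400L,
                           chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                           depth_per_nucleus = 25000, depth_scale = 1 / 25,
                           depth_cv = 0.15, allele_open_prob = 0.9,
                           noise_rate = 0.1, n_repeat_hotspots = 5L,
                           hotspot_rate = 5, duplicate_rate = 0.3,
                           frag_len_shape = 4, frag_len_scale = 62.5,
                           n_background = 50L, seed = 1L) {
  if (is.null(proportions)) proportions <- rep(1 / n_cell_types, n_cell_types)
  stop_if(abs(sum(proportions) - 1) > 1e-8, "proportions must sum to 1")
  stop_if(length(proportions) != n_cell_types,
          "need one proportion per cell type")
  stop_if(any(c(allele_open_prob, noise_rate) < 0) ||
            any(c(allele_open_prob, noise_rate) > 1) ||
            noise_rate >= 1 || duplicate_rate < 0,
          "allele_open_prob and noise_rate must be in [0, 1]")
  stop_if(n_cell_types * markers_per_type >= n_peaks,
          "marker peaks exhaust the peak set")
  structure(as.list(environment()), class = "synthetic_spec")
}

# truncated-gamma fragment lengths
rfrag_len <- function(n, spec) {
  pmin(900L, pmax(50L, as.integer(round(
    stats::rgamma(n, shape = spec$frag_len_shape, scale = spec$frag_len_scale)
  ))))
}

#' Generate a synthetic snATAC-seq sample
#'
#' Realises a [synthetic_spec()] into in-memory tables and (optionally) the
#' on-disk formats the detection CLI consumes unmodified: a position-sorted
#' fragments TSV (with duplicate-count column), a `singlecell.csv`-dialect
#' barcode table, a peak BED, a cluster-label TSV and truth tables (cell
#' types per barcode; planted hotspot regions). Identical seeds give
#' identical outputs.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; when given, files are written and
#'   their paths returned in `$paths`.
#' @return List of class `synthetic_sample`: `fragments` (chrom, start, end,
#'   barcode, dup_count), `barcodes`, `labels` (barcode, cell_type), `peaks`
#'   (with `peak_type`), `hotspots`, `spec`, and `paths` when written.
#' @export
make_synthetic_sample <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  stage_seed <- sample.int(.Machine$integer.max, 6L)

  ## genome layout: evenly spaced non-overlapping peaks, hotspots in between
  set.seed(stage_seed[1L])
  per_chrom <- ceiling(spec$n_peaks / length(spec$chrom_sizes))
  peaks <- data.table::rbindlist(lapply(names(spec$chrom_sizes), function(ch) {
    spacing <- floor((spec$chrom_sizes[[ch]] - 2e4) / per_chrom)
    stop_if(spacing < spec$peak_width + 4000,
            "too many peaks for the genome size")
    start <- 1e4 + spacing * (seq_len(per_chrom) - 1L) +
      sample.int(spacing - spec$peak_width - 2000L, per_chrom, replace = TRUE)
    data.table::data.table(chrom = ch, start = as.integer(start),
                           end = as.integer(start + spec$peak_width))
  }))[seq_len(spec$n_peaks)]
  data.table::setorder(peaks, chrom, start)
  peaks[, peak_id := .I]

  type_names <- paste0("type", LETTERS[seq_len(spec$n_cell_types)])
  marker_ids <- sample(peaks$peak_id,
                       spec$n_cell_types * spec$markers_per_type)
  peaks[, peak_type := "shared"]
  for (i in seq_len(spec$n_cell_types)) {
    ids <- marker_ids[((i - 1L) * spec$markers_per_type + 1L):
                        (i * spec$markers_per_type)]
    peaks[peak_id %in% ids, peak_type := type_names[i]]
  }
  # hotspots midway between consecutive peaks, away from any peak
  hot_after <- sample(which(diff(peaks$start) > 5000 &
                              peaks$chrom[-1] == peaks$chrom[-nrow(peaks)]),
                      spec$n_repeat_hotspots)
  hotspots <- data.table::data.table(
    chrom = peaks$chrom[hot_after],
    start = as.integer(peaks$end[hot_after] + 1500L),
    end = as.integer(peaks$end[hot_after] + 1500L + spec$peak_width))

  ## nuclei
  set.seed(stage_seed[2L])
  bcs <- sprintf("BC%05d", seq_len(spec$n_nuclei))
  labels <- sample(type_names, spec$n_nuclei, replace = TRUE,
                   prob = spec$proportions)
  d <- spec$depth_per_nucleus * spec$depth_scale *
    exp(stats::rnorm(spec$n_nuclei, 0, spec$depth_cv))

  ## diploid in-peak fragments, one per captured open allele
  set.seed(stage_seed[3L])
  frag_parts <- vector("list", spec$n_cell_types + 2L)
  for (i in seq_len(spec$n_cell_types)) {
    acc <- peaks[peak_type %in% c("shared", type_names[i])]
    n_acc <- nrow(acc)
    cells <- which(labels == type_names[i])
    if (length(cells) == 0L) next
    lam_a <- d[cells] * (1 - spec$noise_rate) /
      (2 * n_acc * spec$allele_open_prob)
    s <- spec$allele_open_prob * (1 - exp(-lam_a))  # per-allele emission prob
    cnt <- stats::rbinom(n_acc * length(cells), 2L, rep(s, each = n_acc))
    iz <- which(cnt > 0L)
    cell_idx <- cells[(iz - 1L) %/% n_acc + 1L]
    peak_idx <- (iz - 1L) %% n_acc + 1L
    reps <- cnt[iz]
    cell_idx <- rep(cell_idx, reps)
    peak_idx <- rep(peak_idx, reps)
    len <- rfrag_len(length(peak_idx), spec)
    mid <- as.integer(floor(stats::runif(length(peak_idx),
                                         acc$start[peak_idx],
                                         acc$end[peak_idx])))
    start <- pmax(0L, as.integer(mid - len %/% 2L))
    frag_parts[[i]] <- data.table::data.table(
      chrom = acc$chrom[peak_idx], start = start,
      end = start + len, barcode = bcs[cell_idx])
  }

  ## uniform background noise
  set.seed(stage_seed[4L])
  n_noise <- stats::rpois(spec$n_nuclei, d * spec$noise_rate)
  tot <- sum(n_noise)
  if (tot > 0L) {
    ch <- sample(names(spec$chrom_sizes), tot, replace = TRUE)
    len <- rfrag_len(tot, spec)
    start <- as.integer(floor(stats::runif(
      tot, 0, spec$chrom_sizes[ch] - 1000)))
    frag_parts[[spec$n_cell_types + 1L]] <- data.table::data.table(
      chrom = ch, start = start, end = start + len,
      barcode = rep(bcs, n_noise))
  }

  ## repeat hotspots: shared pile-ups in most nuclei
  set.seed(stage_seed[5L])
  if (nrow(hotspots) > 0L) {
    m <- stats::rpois(spec$n_nuclei * nrow(hotspots), spec$hotspot_rate)
    hs_idx <- rep(rep(seq_len(nrow(hotspots)), each = spec$n_nuclei), m)
    bc_idx <- rep(rep(seq_len(spec$n_nuclei), nrow(hotspots)), m)
    if (length(hs_idx) > 0L) {
      len <- rfrag_len(length(hs_idx), spec)
      mid <- as.integer(floor(stats::runif(length(hs_idx),
                                           hotspots$start[hs_idx],
                                           hotspots$end[hs_idx])))
      start <- pmax(0L, as.integer(mid - len %/% 2L))
      frag_parts[[spec$n_cell_types + 2L]] <- data.table::data.table(
        chrom = hotspots$chrom[hs_idx], start = start,
        end = start + len, barcode = bcs[bc_idx])
    }
  }

  frags <- data.table::rbindlist(frag_parts[!vapply(frag_parts, is.null,
                                                    logical(1))])
  frags <- unique(frags, by = c("chrom", "start", "end", "barcode"))

  ## background (non-cell) barcodes and PCR duplicate counts
  set.seed(stage_seed[6L])
  if (spec$n_background > 0L) {
    bg_bcs <- sprintf("BG%05d", seq_len(spec$n_background))
    n_bg <- stats::rpois(spec$n_background, 20)
    totb <- sum(n_bg)
    ch <- sample(names(spec$chrom_sizes), totb, replace = TRUE)
    len <- rfrag_len(totb, spec)
    start <- as.integer(floor(stats::runif(totb, 0,
                                           spec$chrom_sizes[ch] - 1000)))
    frags <- rbind(frags, data.table::data.table(
      chrom = ch, start = start, end = start + len,
      barcode = rep(bg_bcs, n_bg)))
  } else {
    bg_bcs <- character()
  }
  frags[, dup_count := 1L + stats::rpois(.N, spec$duplicate_rate)]
  data.table::setorder(frags, chrom, start, end, barcode)

  bc_tab <- barcode_table(c(bcs, bg_bcs),
                          is_cell = c(rep(TRUE, length(bcs)),
                                      rep(FALSE, length(bg_bcs))))
  bc_tab <- tally_valid_pairs(bc_tab, frags)
  out <- structure(list(
    fragments = frags, barcodes = bc_tab,
    labels = data.table::data.table(barcode = bcs, cell_type = labels),
    peaks = peaks, hotspots = hotspots, spec = spec
  ), class = "synthetic_sample")
  if (!is.null(dir)) out$paths <- write_synthetic_sample(out, dir)
  out
}

#' Write a synthetic sample in standard on-disk formats
#'
#' @param sim A `synthetic_sample`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_synthetic_sample <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fragments = file.path(dir, "fragments.tsv"),
    barcodes = file.path(dir, "singlecell.csv"),
    peaks = file.path(dir, "peaks.bed"),
    clusters = file.path(dir, "clusters.tsv"),
    hotspots = file.path(dir, "hotspots_truth.bed")
  )
  data.table::fwrite(sim$fragments, paths$fragments, sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(
    data.table::data.table(barcode = sim$barcodes$barcode,
                           is__cell_barcode = as.integer(sim$barcodes$is_cell),
                           passed_filters = sim$barcodes$valid_pair_count),
    paths$barcodes)
  data.table::fwrite(sim$peaks[, .(chrom, start, end, peak_type)],
                     paths$peaks, sep = "\t", col.names = FALSE)
  data.table::fwrite(sim$labels, paths$clusters, sep = "\t")
  data.table::fwrite(sim$hotspots, paths$hotspots, sep = "\t",
                     col.names = FALSE)
  paths
}

#' Count fragments in peaks
#'
#' Builds the peak-by-nucleus count matrix consumed by the annotation
#' pipeline: entry (p, b) is the number of fragments of barcode `b` sharing
#' at least one base with peak `p`.
#'
#' @param fragments Fragment data.table.
#' @param peaks data.table with chrom, start, end (0-based half-open).
#' @param barcodes Character vector of barcodes to include as columns.
#' @return Sparse `dgCMatrix`, peaks x barcodes, with dimnames.
#' @export
count_fragments_in_peaks <- function(fragments, peaks, barcodes) {
  fragments <- as_dt(fragments)[barcode %in% barcodes]
  peaks <- as_dt(peaks)
  pk_names <- peaks[, paste0(chrom, ":", start, "-", end)]
  hits <- GenomicRanges::findOverlaps(
    sites_to_granges(fragments), sites_to_granges(peaks), minoverlap = 1L)
  j <- match(fragments$barcode[S4Vectors::queryHits(hits)], barcodes)
  M <- Matrix::sparseMatrix(
    i = S4Vectors::subjectHits(hits), j = j, x = 1,
    dims = c(nrow(peaks), length(barcodes)),
    dimnames = list(pk_names, barcodes))
  M
}
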