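#' Infer residual repetitive regions from row sums
#'
#' Even after exclusion-list filtering, genuinely repetitive loci produce
#' pile-ups shared across many nuclei. For each merged region the row sum (how
#' many nuclei observe a site there) is compared against a Poisson null whose
#' expectation is the mean row sum; upper-tail p-values are Benjamini-Hochberg
#' adjusted across regions and rows with `q < fdr` are flagged and removed
#' from the matrix before the multiplet test.
#'
#' @param om An `overlap_matrix` from [build_overlap_matrix()].
#' @param fdr FDR threshold (default 0.01).
#' @return List: `calls` (data.table: region_id, chrom, start, end, n_nuclei,
#'   lambda_row, p, q, flagged) and `reduced` (the `overlap_matrix` with
#'   flagged rows removed).
#' @export
infer_repetitive <- function(om, fdr = 0.01) {
  stopifnot(inherits(om, "overlap_matrix"))
  if (nrow(om$M) == 0L) {
    calls <- data.table::data.table(
      region_id = integer(), chrom = character(), start = integer(),
      end = integer(), n_nuclei = integer(), lambda_row = numeric(),
      p = numeric(), q = numeric(), flagged = logical())
    return(list(calls = calls, reduced = om))
  }
  rs <- Matrix::rowSums(om$M)
  lambda <- mean(rs)
  p <- poisson_upper_tail(rs, lambda)
  q <- bh_adjust(p)
  flagged <- q < fdr
  calls <- data.table::data.table(
    region_id = om$regions$region_id, chrom = om$regions$chrom,
    start = om$regions$start, end = om$regions$end,
    n_nuclei = as.integer(rs), lambda_row = lambda, p = p, q = q,
    flagged = flagged)
  reduced <- om
  if (any(flagged)) {
    reduced$M <- om$M[!flagged, , drop = FALSE]
    reduced$regions <- om$regions[!flagged]
  }
  list(calls = calls, reduced = reduced)
}

#' Call multiplet nuclei from column sums
#'
#' On the repetitive-row-reduced matrix, the column sum of a nucleus counts
#' its distinct merged regions with more than the threshold number of
#' overlapping fragments. The Poisson expectation is the mean column sum,
#' recomputed on the reduced matrix so the null stays calibrated after row
#' removal. Upper-tail p-values are Benjamini-Hochberg adjusted across all
#' cell-called nuclei (nuclei with zero sites get p = 1 and stay in the
#' family) and a nucleus is a multiplet iff `q < fdr`.
#'
#' @param om Reduced `overlap_matrix` (repetitive rows already removed).
#' @param fdr FDR threshold (default 0.01).
#' @param test_zero_counts If `FALSE`, nuclei with zero sites are left out of
#'   the BH family instead of entering with p = 1.
#' @return data.table: `barcode`, `k` (site count), `lambda`, `p`, `q`,
#'   `is_multiplet`; one row per cell barcode.
#' @export
detect_multiplets <- function(om, fdr = 0.01, test_zero_counts = TRUE) {
  stopifnot(inherits(om, "overlap_matrix"))
  k <- if (nrow(om$M) == 0L) stats::setNames(rep(0, length(om$barcodes)),
                                             om$barcodes)
       else Matrix::colSums(om$M)
  out <- data.table::data.table(
    barcode = om$barcodes, k = as.integer(k),
    lambda = NA_real_, p = NA_real_, q = NA_real_, is_multiplet = FALSE)
  if (all(k == 0)) {
    warning("all column sums are zero; no multiplet calls made")
    return(out[])
  }
  lambda <- mean(k)
  out[, lambda := ..lambda]
  idx <- if (test_zero_counts) seq_len(nrow(out)) else which(out$k > 0L)
  pv <- poisson_upper_tail(out$k[idx], lambda)
  qv <- bh_adjust(pv)
  out[idx, `:=`(p = ..pv, q = ..qv, is_multiplet = ..qv < ..fdr)]
  out[]
}

#' End-to-end multiplet detection
#'
#' Orchestrates the full pipeline: read fragments (BAM or fragments file),
#' deduplicate, sweep per-nucleus overlap sites, drop sites in exclusion
#' regions, merge across nuclei, build the binary matrix, remove inferred
#' repetitive rows, and call multiplets. All thresholds default to the
#' published operating point (MAPQ > 30, insert <= 900 bp, overlap depth
#' > 2, FDR < 0.01).
#'
#' @param bam,fragments Exactly one of: path to a coordinate-sorted BAM, or
#'   path to a 10x-style fragments file.
#' @param barcodes Path to a `singlecell.csv`-dialect table, or a barcode
#'   table already read by [read_barcode_table()].
#' @param exclude Character vector of exclusion BED paths (may be empty).
#' @param cfg A [filter_config()].
#' @param threshold Overlap depth threshold (default 2).
#' @param fdr FDR threshold for both tests (default 0.01).
#' @param test_zero_counts See [detect_multiplets()].
#' @param verbose Log per-stage counts to stderr.
#' @return List of class `multiplet_result`: `calls`, `repetitive`,
#'   `merged_regions`, `sites`, `barcodes` (with valid-pair counts),
#'   `diagnostics`, `params`.
#' @export
run_multiplet_detection <- function(bam = NULL, fragments = NULL, barcodes,
                                    exclude = character(),
                                    cfg = filter_config(), threshold = 2L,
                                    fdr = 0.01, test_zero_counts = TRUE,
                                    verbose = TRUE) {
  stop_if(is.null(bam) == is.null(fragments),
          "provide exactly one of `bam` or `fragments`")
  if (is.character(barcodes)) barcodes <- read_barcode_table(barcodes)
  rd <- if (!is.null(bam)) read_bam_fragments(bam, barcodes, cfg)
        else read_fragment_file(fragments, barcodes, cfg)
  msg("fragments passing filters: %d (%d cell barcodes)",
      nrow(rd$fragments), sum(rd$barcodes$is_cell), verbose = verbose)
  frags <- if (cfg$dedupe_mode %in% c("coordinate", "both"))
    dedupe_coordinate(rd$fragments) else rd$fragments
  msg("after coordinate dedup: %d", nrow(frags), verbose = verbose)
  bc_tab <- tally_valid_pairs(rd$barcodes, frags)

  sites <- sweep_overlap_sites(frags, threshold = threshold)
  msg("overlap sites (depth > %d): %d", threshold, nrow(sites),
      verbose = verbose)
  excl <- load_region_beds(exclude)
  sites_f <- filter_sites(sites, excl)
  msg("sites after exclusion filter: %d", nrow(sites_f), verbose = verbose)
  merged <- merge_sites(sites_f)
  cell_bcs <- bc_tab$barcode[bc_tab$is_cell]
  om <- build_overlap_matrix(merged, sites_f, cell_bcs)
  rep_res <- infer_repetitive(om, fdr = fdr)
  msg("merged regions: %d; inferred repetitive: %d", nrow(merged),
      sum(rep_res$calls$flagged), verbose = verbose)
  calls <- detect_multiplets(rep_res$reduced, fdr = fdr,
                             test_zero_counts = test_zero_counts)
  calls[bc_tab, valid_pairs := i.valid_pair_count, on = "barcode"]
  data.table::setcolorder(calls, c("barcode", "valid_pairs"))
  msg("multiplets at FDR %.3g: %d / %d nuclei", fdr,
      sum(calls$is_multiplet), nrow(calls), verbose = verbose)
  structure(list(
    calls = calls, repetitive = rep_res$calls, merged_regions = merged,
    sites = sites_f, barcodes = bc_tab, diagnostics = rd$diagnostics,
    params = list(threshold = threshold, fdr = fdr, cfg = cfg,
                  test_zero_counts = test_zero_counts)
  ), class = "multiplet_result")
}

#' @export
print.multiplet_result <- function(x, ...) {
  cat(sprintf(
    "multiplet detection: %d nuclei, %d multiplets (FDR < %.3g), %d merged regions (%d repetitive)\n",
    nrow(x$calls), sum(x$calls$is_multiplet), x$params$fdr,
    nrow(x$merged_regions), sum(x$repetitive$flagged)))
  invisible(x)
}

#' Write detection outputs
#'
#' Writes `overlap_summary.tsv` (per-nucleus calls), `multiplet_barcodes.txt`,
#' `merged_regions.bed` and `repetitive_regions.bed` into `dir`.
#'
#' @param res A `multiplet_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_detection_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(res$calls, file.path(dir, "overlap_summary.tsv"),
                     sep = "\t")
  writeLines(res$calls$barcode[res$calls$is_multiplet],
             file.path(dir, "multiplet_barcodes.txt"))
  data.table::fwrite(res$merged_regions[, .(chrom, start, end)],
                     file.path(dir, "merged_regions.bed"),
                     sep = "\t", col.names = FALSE)
  rep_bed <- res$repetitive[flagged == TRUE, .(chrom, start, end)]
  data.table::fwrite(rep_bed, file.path(dir, "repetitive_regions.bed"),
                     sep = "\t", col.names = FALSE)
  invisible(dir)
}
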