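#' Per-nucleus overlap sites by breakpoint sweep
#'
#' For every (barcode, chromosome) group, finds each maximal subinterval
#' covered by more than `threshold` distinct fragments. Every fragment
#' contributes two breakpoints: +1 at its start and -1 at its (half-open)
#' end. Breakpoints are visited in position order, ends before starts at equal
#' positions so abutting fragments never count as overlapping, and the running
#' cumulative sum is the overlap depth on the interval up to the next
#' breakpoint. Maximal runs with depth above the threshold become sites.
#'
#' A diploid nucleus contributes at most two distinct fragments at any locus,
#' so with the default threshold of 2 a site is evidence of either a
#' repetitive artifact or more than one genome in the droplet. The threshold
#' is exposed so higher-ploidy samples can raise the expected copy number.
#'
#' @param fragments Deduplicated fragment data.table sorted by (chrom, start).
#' @param threshold Overlap depth that must be exceeded (default 2).
#' @return data.table of sites: `chrom`, `start`, `end` (0-based half-open,
#'   tightest subinterval at depth > threshold), `barcode`, `max_depth`.
#' @export
sweep_overlap_sites <- function(fragments, threshold = 2L) {
  check_fragment_cols(fragments)
  frags <- as_dt(fragments)
  empty_sites <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    barcode = character(), max_depth = integer())
  if (nrow(frags) == 0L) return(empty_sites)
  unsorted <- frags[, any(diff(start) < 0L), by = chrom]$V1
  stop_if(any(unsorted), "fragments must be sorted by (chrom, start)")

  bp <- data.table::data.table(
    barcode = rep(frags$barcode, 2L),
    chrom = rep(frags$chrom, 2L),
    pos = c(frags$start, frags$end),
    delta = rep(c(1L, -1L), each = nrow(frags))
  )
  # ends (-1) before starts (+1) at equal positions: half-open semantics
  data.table::setorder(bp, barcode, chrom, pos, delta)
  bp[, depth := cumsum(delta), by = .(barcode, chrom)]
  # collapse coincident breakpoints: the depth on [pos_i, pos_{i+1}) is the
  # running sum after the last breakpoint at pos_i
  agg <- bp[, .(depth = depth[.N]), by = .(barcode, chrom, pos)]
  agg[, next_pos := data.table::shift(pos, type = "lead"),
      by = .(barcode, chrom)]
  agg[, idx := .I]
  q <- agg[depth > threshold & !is.na(next_pos)]
  if (nrow(q) == 0L) return(empty_sites)
  # maximal sites = runs of consecutive qualifying inter-breakpoint
  # intervals; a skipped index means depth fell to <= threshold (or a group
  # boundary) between them, since the group's last row never qualifies
  q[, run := cumsum(c(1L, diff(idx) != 1L))]
  sites <- q[, .(chrom = chrom[1L], start = pos[1L],
                 end = next_pos[.N], barcode = barcode[1L],
                 max_depth = max(depth)), by = run][, run := NULL]
  data.table::setorder(sites, chrom, start, end, barcode)
  sites[]
}

#' Count overlap sites per nucleus
#'
#' Tallies sites per barcode; every cell-called barcode appears in the result,
#' with 0 for nuclei without any site.
#'
#' @param sites Site table from [sweep_overlap_sites()].
#' @param barcodes Character vector of cell barcodes to report (typically all
#'   cell-called barcodes).
#' @return data.table with columns `barcode`, `n_sites`.
#' @export
count_sites_per_nucleus <- function(sites, barcodes) {
  out <- data.table::data.table(barcode = as.character(barcodes),
                                n_sites = 0L)
  if (nrow(sites) > 0L) {
    cnt <- as_dt(sites)[, .N, by = barcode]
    out[cnt, n_sites := i.N, on = "barcode"]
  }
  out[]
}

#' Write overlap sites as BED
#'
#' Debug output: chrom, start, end, barcode (name), max_depth (score).
#'
#' @param sites Site table.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  data.table::fwrite(as_dt(sites)[, .(chrom, start, end, barcode, max_depth)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
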