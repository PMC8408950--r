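#' Load exclusion region BED files
#'
#' Reads one or more BED3+ files (0-based half-open) and pools their intervals
#' into a single queryable region set. Intervals are kept as given; exclusion
#' semantics are defined by overlap queries, not interval arithmetic, so
#' overlapping inputs need no pre-merging. Typical inputs are simple repeats,
#' segmental duplications, RepeatMasker annotations and blacklist regions.
#'
#' @param paths Character vector of BED paths (may be empty).
#' @return A `GRanges` region set (possibly empty).
#' @export
load_region_beds <- function(paths) {
  if (length(paths) == 0L) return(GenomicRanges::GRanges())
  parts <- lapply(paths, function(p) {
    stop_if(!file.exists(p), "BED file not found: %s", p)
    tab <- tryCatch(
      data.table::fread(p, header = FALSE, sep = "\t", fill = TRUE),
      error = function(e) stop(sprintf("cannot parse BED %s: %s",
                                       p, conditionMessage(e)), call. = FALSE)
    )
    if (nrow(tab) == 0L) return(NULL)
    stop_if(ncol(tab) < 3L, "%s: BED needs >= 3 columns", p)
    s <- suppressWarnings(as.integer(tab[[2L]]))
    e <- suppressWarnings(as.integer(tab[[3L]]))
    bad <- which(is.na(s) | is.na(e) | s < 0L | e <= s)
    stop_if(length(bad) > 0L, "%s: malformed BED record at line %d",
            p, bad[1L])
    data.table::data.table(chrom = as.character(tab[[1L]]),
                           start = s, end = e)
  })
  pooled <- data.table::rbindlist(parts[!vapply(parts, is.null, logical(1))])
  if (nrow(pooled) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(pooled$chrom,
                         IRanges::IRanges(start = pooled$start + 1L,
                                          end = pooled$end))
}

# site table (0-based half-open) -> GRanges (1-based closed)
sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(start = sites$start + 1L,
                                          end = sites$end))
}

#' Remove overlap sites hitting exclusion regions
#'
#' Drops every site sharing at least one base with any exclusion interval;
#' all other sites pass through unchanged.
#'
#' @param sites Site table from [sweep_overlap_sites()].
#' @param excl `GRanges` from [load_region_beds()].
#' @return Filtered site table.
#' @export
filter_sites <- function(sites, excl) {
  sites <- as_dt(sites)
  if (nrow(sites) == 0L || length(excl) == 0L) return(sites)
  hits <- GenomicRanges::findOverlaps(sites_to_granges(sites), excl,
                                      minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0L) sites else sites[-drop]
}

#' Merge overlap sites across nuclei into a unified region list
#'
#' Pools the per-nucleus sites from all barcodes and merges any two sites
#' sharing at least one base pair, transitively, per chromosome. Abutting
#' half-open sites (no shared base) stay separate. The merged regions are the
#' rows of the binary overlap matrix.
#'
#' @param sites Site table (all nuclei pooled).
#' @return data.table of merged regions: `chrom`, `start`, `end` (0-based
#'   half-open), sorted and pairwise non-overlapping, with a `region_id`.
#' @export
merge_sites <- function(sites) {
  sites <- as_dt(sites)
  if (nrow(sites) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), region_id = integer()))
  }
  # min.gapwidth = 0 merges only genuinely overlapping (>= 1 shared base)
  # ranges, never merely adjacent ones
  red <- GenomicRanges::reduce(sites_to_granges(sites), min.gapwidth = 0L)
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
  data.table::setorder(out, chrom, start)
  out[, region_id := .I]
  out[]
}
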