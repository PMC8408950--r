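#' Build the binary region-by-nucleus overlap matrix
#'
#' Rows are the merged regions, columns the cell-called barcodes;
#' `M[r, b] = 1` iff nucleus `b` has at least one site with more than the
#' threshold number of overlapping fragments inside region `r`. The matrix is
#' binary by construction: multiple sites of one nucleus falling in one merged
#' region still yield a single 1. Stored sparsely. Row sums feed repetitive-
#' region inference, column sums feed multiplet detection.
#'
#' @param merged Merged region table from [merge_sites()].
#' @param sites Site table (same pool that produced `merged`).
#' @param barcodes Character vector of cell barcodes (matrix columns; nuclei
#'   without sites become all-zero columns).
#' @return A list of class `overlap_matrix`: `M` (sparse binary dgCMatrix,
#'   regions x barcodes), `regions` (the merged table), `barcodes`.
#' @export
build_overlap_matrix <- function(merged, sites, barcodes) {
  barcodes <- as.character(barcodes)
  sites <- as_dt(sites)
  if (nrow(merged) == 0L || nrow(sites) == 0L) {
    M <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(merged), length(barcodes)))
  } else {
    hits <- GenomicRanges::findOverlaps(
      sites_to_granges(sites),
      sites_to_granges(merged[, .(chrom, start, end)]),
      minoverlap = 1L)
    stop_if(length(unique(S4Vectors::queryHits(hits))) != nrow(sites),
            "internal error: a site overlaps no merged region")
    j <- match(sites$barcode[S4Vectors::queryHits(hits)], barcodes)
    keep <- !is.na(j)                   # sites of non-cell barcodes, if any
    ij <- unique(cbind(S4Vectors::subjectHits(hits)[keep], j[keep]))
    M <- Matrix::sparseMatrix(i = ij[, 1L], j = ij[, 2L], x = 1,
                              dims = c(nrow(merged), length(barcodes)))
  }
  rownames(M) <- if (nrow(merged)) merged[, paste0(chrom, ":", start, "-", end)]
                 else character()
  colnames(M) <- barcodes
  structure(list(M = M, regions = as_dt(merged), barcodes = barcodes),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("overlap_matrix: %d merged regions x %d nuclei, %d entries\n",
              nrow(x$M), ncol(x$M), length(x$M@x)))
  invisible(x)
}
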