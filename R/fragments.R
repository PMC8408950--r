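#' Read valid fragments from a coordinate-sorted, barcode-tagged BAM
#'
#' Streams a position-sorted BAM of paired-end snATAC-seq alignments and emits
#' one fragment interval per retained read pair. A pair is retained iff the
#' read is paired, both mates are mapped, the record is neither secondary nor
#' supplementary, it is not duplicate-flagged (when `cfg$dedupe_mode` includes
#' the flag pass), both mates map to the same chromosome, mapping quality
#' exceeds `cfg$min_mapq_exclusive`, the template length is at most
#' `cfg$max_insert`, the chromosome is in `cfg$autosomes`, and the barcode tag
#' resolves to a cell-called barcode. Each pair contributes exactly once,
#' processed from its leftmost mate (positive template length), and the
#' fragment interval is `[leftmost 5' position, leftmost 5' position + |TLEN|)`
#' in 0-based half-open coordinates.
#'
#' @param bam_path Path to a coordinate-sorted BAM file.
#' @param barcodes Barcode table from [read_barcode_table()].
#' @param cfg A [filter_config()].
#' @param yield_size Records per streaming chunk.
#' @return A list with `fragments` (data.table: chrom, start, end, barcode,
#'   sorted by chrom/start), `barcodes` (input table with `valid_pair_count`
#'   filled from the emitted fragments) and `diagnostics` (named counts,
#'   including `missing_tag` records skipped for lack of a barcode tag).
#' @export
read_bam_fragments <- function(bam_path, barcodes, cfg = filter_config(),
                               yield_size = 2e6L) {
  stop_if(!file.exists(bam_path), "BAM not found: %s", bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]
  hd <- hdr$text[["@HD"]]
  sorted <- !is.null(hd) && any(grepl("^SO:coordinate$", hd))
  stop_if(!sorted,
          "BAM %s is not coordinate-sorted (header lacks SO:coordinate)",
          bam_path)

  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = if (cfg$dedupe_mode %in% c("flag", "both")) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("rname", "pos", "mapq", "isize", "mrnm"),
    tag = cfg$barcode_tag,
    mapqFilter = cfg$min_mapq_exclusive + 1L
  )

  bf <- Rsamtools::BamFile(bam_path, yieldSize = as.integer(yield_size))
  open(bf)
  on.exit(close(bf), add = TRUE)

  cell_set <- barcodes$barcode[barcodes$is_cell]
  chunks <- list()
  diag <- c(missing_tag = 0L, wrong_chrom_pair = 0L, too_long = 0L,
            non_autosome = 0L, not_cell_barcode = 0L)

  repeat {
    res <- Rsamtools::scanBam(bf, param = param)[[1L]]
    n <- length(res$pos)
    if (n == 0L) break
    bc <- res$tag[[cfg$barcode_tag]]
    if (is.null(bc)) bc <- rep(NA_character_, n)
    # leftmost mate only: one emission per pair
    left <- !is.na(res$isize) & res$isize > 0L
    keep <- left
    no_tag <- keep & is.na(bc)
    diag[["missing_tag"]] <- diag[["missing_tag"]] + sum(no_tag)
    keep <- keep & !is.na(bc)
    same_chrom <- as.character(res$rname) == as.character(res$mrnm)
    diag[["wrong_chrom_pair"]] <- diag[["wrong_chrom_pair"]] +
      sum(keep & !same_chrom, na.rm = TRUE)
    keep <- keep & same_chrom & !is.na(same_chrom)
    long <- res$isize > cfg$max_insert
    diag[["too_long"]] <- diag[["too_long"]] + sum(keep & long)
    keep <- keep & !long
    if (cfg$strip_suffix) bc <- sub("-[0-9]+$", "", bc)
    chrom <- as.character(res$rname)
    auto <- chrom %in% cfg$autosomes
    diag[["non_autosome"]] <- diag[["non_autosome"]] + sum(keep & !auto)
    keep <- keep & auto
    cell <- bc %in% cell_set
    diag[["not_cell_barcode"]] <- diag[["not_cell_barcode"]] +
      sum(keep & !cell)
    keep <- keep & cell
    if (any(keep)) {
      chunks[[length(chunks) + 1L]] <- data.table::data.table(
        chrom = chrom[keep],
        start = res$pos[keep] - 1L,
        end = res$pos[keep] - 1L + res$isize[keep],
        barcode = bc[keep]
      )
    }
  }

  frags <- if (length(chunks)) data.table::rbindlist(chunks) else
    empty_fragments()
  data.table::setorder(frags, chrom, start, end, barcode)
  list(
    fragments = frags,
    barcodes = tally_valid_pairs(barcodes, frags),
    diagnostics = as.list(diag)
  )
}

#' Read valid fragments from a 10x-style fragments file
#'
#' Parses the 5-column tab-separated fragments format (chrom, start, end,
#' barcode, duplicate count; 0-based half-open; position-sorted; plain or
#' gzip/bgzip) and applies the autosome, fragment-length and cell-call
#' filters. The duplicate count column is collapsed: each row yields at most
#' one fragment.
#'
#' @inheritParams read_bam_fragments
#' @param path Path to the fragments file.
#' @return As [read_bam_fragments()].
#' @export
read_fragment_file <- function(path, barcodes, cfg = filter_config()) {
  stop_if(!file.exists(path), "fragments file not found: %s", path)
  tab <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop(sprintf("cannot parse %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  # tolerate leading comment lines written by 10x
  if (ncol(tab) >= 1L && is.character(tab[[1L]])) {
    cm <- startsWith(tab[[1L]], "#")
    if (any(cm)) tab <- tab[!cm]
  }
  stop_if(ncol(tab) < 4L,
          "%s: expected >= 4 tab-separated columns, found %d", path, ncol(tab))
  frags <- data.table::data.table(
    chrom = as.character(tab[[1L]]),
    start = suppressWarnings(as.integer(tab[[2L]])),
    end = suppressWarnings(as.integer(tab[[3L]])),
    barcode = as.character(tab[[4L]])
  )
  bad <- which(is.na(frags$start) | is.na(frags$end) |
                 frags$start < 0L | frags$end <= frags$start)
  stop_if(length(bad) > 0L, "%s: malformed fragment record at line %d",
          path, bad[1L])
  un <- frags[, any(diff(start) < 0L), by = chrom]$V1
  stop_if(any(un), "%s: fragments are not position-sorted", path)

  if (cfg$strip_suffix) frags[, barcode := sub("-[0-9]+$", "", barcode)]
  diag <- c(non_autosome = 0L, too_long = 0L, not_cell_barcode = 0L)
  auto <- frags$chrom %in% cfg$autosomes
  diag[["non_autosome"]] <- sum(!auto)
  frags <- frags[auto]
  long <- (frags$end - frags$start) > cfg$max_insert
  diag[["too_long"]] <- sum(long)
  frags <- frags[!long]
  cell <- frags$barcode %in% barcodes$barcode[barcodes$is_cell]
  diag[["not_cell_barcode"]] <- sum(!cell)
  frags <- frags[cell]
  data.table::setorder(frags, chrom, start, end, barcode)
  list(
    fragments = frags,
    barcodes = tally_valid_pairs(barcodes, frags),
    diagnostics = as.list(diag)
  )
}

#' Coordinate-based duplicate removal
#'
#' Keeps at most one fragment per (chrom, start, end, barcode) key, preserving
#' input order. Backstop for inputs whose aligner did not set duplicate flags.
#'
#' @param fragments Fragment data.table.
#' @return Deduplicated fragment data.table.
#' @export
dedupe_coordinate <- function(fragments) {
  check_fragment_cols(fragments)
  unique(as_dt(fragments), by = c("chrom", "start", "end", "barcode"))
}

# recompute valid_pair_count from an emitted fragment set
tally_valid_pairs <- function(barcodes, fragments) {
  out <- data.table::copy(as_dt(barcodes))
  cnt <- as_dt(fragments)[, .N, by = barcode]
  out[, valid_pair_count := 0L]
  out[cnt, valid_pair_count := i.N, on = "barcode"]
  out[]
}
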