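#' Read a per-barcode cell-call table
#'
#' Parses the `singlecell.csv` dialect written by Cell Ranger ATAC: a header
#' row, the barcode in the first column, and a 0/1 column flagging barcodes
#' called as cells. Only barcodes flagged as cells take part in downstream
#' multiplet detection; the remaining barcodes are retained so diagnostics can
#' report how much signal was discarded.
#'
#' @param path Path to a CSV file (plain or gzip).
#' @param barcode_col Column holding the barcode; name or 1-based index.
#' @param is_cell_col Name of the 0/1 cell-call column. Cell Ranger spells it
#'   `is__cell_barcode` (double underscore); that spelling is the default.
#' @return A `data.table` with columns `barcode` (character, unique),
#'   `is_cell` (logical) and `valid_pair_count` (integer, initialised to 0 and
#'   filled in by the fragment readers).
#' @export
read_barcode_table <- function(path, barcode_col = 1L,
                               is_cell_col = "is__cell_barcode") {
  stop_if(!file.exists(path), "barcode table not found: %s", path)
  tab <- data.table::fread(path, header = TRUE)
  stop_if(nrow(tab) == 0L, "barcode table is empty: %s", path)
  bc <- if (is.numeric(barcode_col)) names(tab)[barcode_col] else barcode_col
  stop_if(is.na(bc) || !bc %in% names(tab),
          "barcode column %s not found in %s", as.character(barcode_col), path)
  stop_if(!is_cell_col %in% names(tab),
          "cell-call column '%s' not found in %s (columns: %s)",
          is_cell_col, path, paste(names(tab), collapse = ", "))
  out <- data.table::data.table(
    barcode = as.character(tab[[bc]]),
    is_cell = as.integer(tab[[is_cell_col]]) == 1L,
    valid_pair_count = 0L
  )
  stop_if(anyDuplicated(out$barcode) > 0L,
          "duplicate barcodes in %s", path)
  out[]
}

#' Construct a barcode table in memory
#'
#' Convenience constructor used by the simulator and by tests.
#'
#' @param barcodes Character vector of barcodes (unique).
#' @param is_cell Logical vector (recycled) marking cell-called barcodes.
#' @return A barcode `data.table` as in [read_barcode_table()].
#' @export
barcode_table <- function(barcodes, is_cell = TRUE) {
  stop_if(anyDuplicated(barcodes) > 0L, "barcodes must be unique")
  data.table::data.table(
    barcode = as.character(barcodes),
    is_cell = rep_len(as.logical(is_cell), length(barcodes)),
    valid_pair_count = 0L
  )
}

#' Fragment filtering configuration
#'
#' Groups the read-pair quality filters: pairs with mapping quality less than
#' or equal to `min_mapq_exclusive` are dropped, as are fragments longer than
#' `max_insert` (about six nucleosomes at the default 900 bp) and fragments on
#' anything but the configured autosomes. `dedupe_mode` chooses whether
#' duplicate removal trusts the aligner's duplicate flag, a coordinate-based
#' pass, or both (the coordinate pass is the backstop for inputs without
#' duplicate flags).
#'
#' @param min_mapq_exclusive Pairs with MAPQ `<=` this value are removed.
#' @param max_insert Maximum fragment (template) length in bp, inclusive.
#' @param autosomes Character vector of chromosome names to keep.
#' @param dedupe_mode One of `"flag"`, `"coordinate"`, `"both"`.
#' @param barcode_tag BAM tag carrying the cell barcode.
#' @param strip_suffix If `TRUE`, a trailing `-<digits>` (the 10x GEM-well
#'   suffix) is removed from barcodes before matching the barcode table.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_mapq_exclusive = 30L, max_insert = 900L,
                          autosomes = default_autosomes(),
                          dedupe_mode = c("both", "flag", "coordinate"),
                          barcode_tag = "CB", strip_suffix = FALSE) {
  dedupe_mode <- match.arg(dedupe_mode)
  stop_if(min_mapq_exclusive < 0L, "min_mapq_exclusive must be >= 0")
  stop_if(max_insert <= 0L, "max_insert must be > 0")
  structure(list(
    min_mapq_exclusive = as.integer(min_mapq_exclusive),
    max_insert = as.integer(max_insert),
    autosomes = as.character(autosomes),
    dedupe_mode = dedupe_mode,
    barcode_tag = barcode_tag,
    strip_suffix = isTRUE(strip_suffix)
  ), class = "filter_config")
}
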