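#' Inject artificial multiplets by barcode remapping
#'
#' Implements the validation protocol: nuclei equal to `select_fraction`
#' (default 5%) of the cell population are selected at random (without
#' replacement, rounded down to an even count) and additively paired, giving
#' artificial multiplets equivalent to half the selected fraction (2.5% of
#' the population at the default). In `heterotypic` or `homotypic` mode,
#' partners are randomly reselected until every pair satisfies the
#' cluster-label constraint. Both constituents' reads are assigned to the
#' first constituent's barcode and the second constituent is removed from the
#' cell list, so each artificial multiplet is a single barcode carrying two
#' nuclei's fragments.
#'
#' @param barcodes Barcode table (only `is_cell` rows are eligible) or a
#'   character vector of cell barcodes.
#' @param cluster_labels data.table (barcode, cell_type) or named character
#'   vector; required for `heterotypic`/`homotypic` modes.
#' @param select_fraction Fraction of cells selected for pairing.
#' @param mode `"any"`, `"heterotypic"` or `"homotypic"`.
#' @param seed Integer seed for the selection stream.
#' @param max_restarts Bounded reselection attempts before failing (e.g.
#'   homotypic mode over all-singleton clusters).
#' @return List of class `injection`: `truth` (data.table:
#'   `multiplet_barcode`, `constituent1`, `constituent2`, `mode`,
#'   `constituent_types`), `removed_barcodes`, `remap` (data.table: `old`,
#'   `new` for the second constituents).
#' @export
inject_artificial_multiplets <- function(barcodes, cluster_labels = NULL,
                                         select_fraction = 0.05,
                                         mode = c("any", "heterotypic",
                                                  "homotypic"),
                                         seed = 1L, max_restarts = 100L) {
  mode <- match.arg(mode)
  cells <- if (is.character(barcodes)) barcodes
           else barcodes$barcode[barcodes$is_cell]
  N <- length(cells)
  n_sel <- floor(select_fraction * N)
  if (n_sel %% 2L == 1L) n_sel <- n_sel - 1L
  stop_if(n_sel < 2L, "select_fraction * N must be >= 2")

  lab <- NULL
  if (mode != "any") {
    stop_if(is.null(cluster_labels),
            "cluster labels are required for mode '%s'", mode)
    if (is.data.frame(cluster_labels)) {
      lab <- stats::setNames(as.character(cluster_labels[[2L]]),
                             as.character(cluster_labels[[1L]]))
    } else {
      lab <- cluster_labels
    }
    stop_if(any(!cells %in% names(lab)),
            "cluster labels missing for some cell barcodes")
  }

  set.seed(seed)
  pair_ok <- function(a, b) switch(mode,
    any = TRUE,
    heterotypic = lab[[a]] != lab[[b]],
    homotypic = lab[[a]] == lab[[b]])

  for (attempt in seq_len(max_restarts)) {
    pool <- sample(cells, n_sel)
    first <- character(n_sel / 2L)
    second <- character(n_sel / 2L)
    ok <- TRUE
    for (i in seq_len(n_sel / 2L)) {
      a <- pool[1L]
      cand <- pool[-1L]
      if (mode != "any") cand <- cand[vapply(cand, pair_ok, logical(1), a = a)]
      if (length(cand) == 0L) { ok <- FALSE; break }
      b <- if (length(cand) == 1L) cand else sample(cand, 1L)
      first[i] <- a; second[i] <- b
      pool <- setdiff(pool, c(a, b))
    }
    if (ok) {
      if (is.null(lab) && !is.null(cluster_labels) &&
            is.data.frame(cluster_labels)) {
        lab <- stats::setNames(as.character(cluster_labels[[2L]]),
                               as.character(cluster_labels[[1L]]))
      }
      truth <- data.table::data.table(
        multiplet_barcode = first, constituent1 = first, constituent2 = second)
      if (!is.null(lab)) {
        truth[, constituent_types := paste(lab[constituent1],
                                           lab[constituent2], sep = "+")]
        truth[, mode := ifelse(lab[constituent1] == lab[constituent2],
                               "homotypic", "heterotypic")]
      } else {
        truth[, constituent_types := NA_character_]
        truth[, mode := "any"]
      }
      return(structure(list(
        truth = truth, removed_barcodes = second,
        remap = data.table::data.table(old = second, new = first)
      ), class = "injection"))
    }
  }
  stop(sprintf(
    "could not form %s pairs after %d reselection attempts", mode,
    max_restarts), call. = FALSE)
}

#' Apply an injection to fragments and barcode table
#'
#' Reassigns every fragment of a removed (second) constituent to its pair's
#' barcode and drops the removed barcodes from the cell list. The total
#' fragment count is conserved; coordinates are untouched so position order
#' is preserved.
#'
#' @param fragments Fragment data.table.
#' @param barcodes Barcode table.
#' @param injection An `injection` from [inject_artificial_multiplets()].
#' @return List with remapped `fragments` and reduced `barcodes`.
#' @export
apply_injection <- function(fragments, barcodes, injection) {
  stopifnot(inherits(injection, "injection"))
  frags <- data.table::copy(as_dt(fragments))
  frags[injection$remap, barcode := i.new, on = c(barcode = "old")]
  bc <- as_dt(barcodes)[!barcode %in% injection$removed_barcodes]
  bc <- tally_valid_pairs(bc, frags)
  list(fragments = frags, barcodes = bc)
}

#' Recall and worst-case precision against injected truth
#'
#' Recall is the fraction of injected artificial multiplets that were called;
#' the precision lower bound assumes every call that is not an injected
#' multiplet is a false positive (real multiplets present in the sample make
#' true precision higher).
#'
#' @param truth Truth table from [inject_artificial_multiplets()] or a
#'   character vector of true multiplet barcodes.
#' @param calls Call table from [detect_multiplets()] or a character vector
#'   of called multiplet barcodes.
#' @return List: `recall`, `precision_lower_bound` (NA when there are no
#'   calls), `n_true`, `n_called`, `n_hit`.
#' @export
evaluate_calls <- function(truth, calls) {
  true_bcs <- if (is.character(truth)) truth else truth$multiplet_barcode
  called <- if (is.character(calls)) calls
            else calls$barcode[calls$is_multiplet]
  n_hit <- length(intersect(true_bcs, called))
  list(
    recall = if (length(true_bcs)) n_hit / length(true_bcs) else NA_real_,
    precision_lower_bound = if (length(called)) n_hit / length(called)
                            else NA_real_,
    n_true = length(true_bcs), n_called = length(called), n_hit = n_hit
  )
}
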