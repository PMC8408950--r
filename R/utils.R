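# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom utils head tail
NULL

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

# human autosomes; overridable everywhere a FilterConfig is accepted
default_autosomes <- function() paste0("chr", 1:22)

as_dt <- function(x) {
  if (!data.table::is.data.table(x)) data.table::as.data.table(x) else x
}

# empty fragment table with canonical column types
empty_fragments <- function() {
  data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    barcode = character()
  )
}

check_fragment_cols <- function(frags) {
  need <- c("chrom", "start", "end", "barcode")
  stop_if(!all(need %in% names(frags)),
          "fragment table must have columns %s", paste(need, collapse = ", "))
  invisible(frags)
}
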