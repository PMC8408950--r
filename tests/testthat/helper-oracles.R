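# Independent oracles, deliberately naive: these re-derive expected results
# by brute force and must stay free of the code paths they check.

# per-base depth oracle for overlap sites: tabulates depth at every base and
# reads off maximal runs with depth > threshold, per (barcode, chrom)
oracle_depth_sites <- function(frags, threshold = 2L) {
  out <- list()
  for (key in unique(paste(frags$barcode, frags$chrom, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- frags[frags$barcode == parts[1] & frags$chrom == parts[2], ]
    hi <- max(sub$end)
    depth <- integer(hi + 1L)              # depth[i+1] = depth at base i
    for (r in seq_len(nrow(sub))) {
      span <- (sub$start[r] + 1L):(sub$end[r])   # bases start..end-1
      depth[span] <- depth[span] + 1L
    }
    above <- depth > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = parts[2], start = starts[j] - 1L, end = ends[j],
        barcode = parts[1],
        max_depth = max(depth[starts[j]:ends[j]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), barcode = character(),
                      max_depth = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$end, res$barcode), , drop = FALSE]
}

# random fuzzed fragment set for one or more barcodes
fuzz_fragments <- function(n_frags = 50L, max_pos = 500L, n_barcodes = 1L) {
  start <- sample.int(max_pos - 2L, n_frags, replace = TRUE) - 1L
  len <- sample.int(60L, n_frags, replace = TRUE)
  dt <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), n_frags, replace = TRUE),
    start = start, end = pmin(start + len, max_pos),
    barcode = sample(paste0("b", seq_len(n_barcodes)), n_frags,
                     replace = TRUE))
  dt <- unique(dt, by = c("chrom", "start", "end", "barcode"))
  data.table::setorder(dt, chrom, start, end, barcode)
  dt
}

# direct series summation of the Poisson upper tail P(X >= k)
oracle_poisson_tail <- function(k, lambda) {
  if (k == 0) return(1)
  term <- exp(-lambda)
  s <- term
  for (i in seq_len(k - 1)) {
    term <- term * lambda / i
    s <- s + term
  }
  max(0, 1 - s)
}

# literal step-up formula: q_i = min over p_(j) >= p_i of m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    js <- which(p[ord] >= p[i])
    min(1, min(m * p[ord][js] / js))
  }, numeric(1))
}

# union-find oracle for >= 1 bp overlap merging
oracle_merge <- function(sites) {
  n <- nrow(sites)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sites$chrom[i] == sites$chrom[j] &&
          sites$start[i] < sites$end[j] && sites$start[j] < sites$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    grp <- sites[roots == r, , drop = FALSE]
    data.frame(chrom = grp$chrom[1], start = min(grp$start),
               end = max(grp$end), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# shared small synthetic sample, generated once per test session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_synthetic_sample(synthetic_spec(
        n_nuclei = 200L, n_peaks = 600L, markers_per_type = 40L,
        n_background = 10L, seed = 424L))
    }
    cache
  }
})
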