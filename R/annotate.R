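#' Read a peak-by-nucleus count matrix with sidecar files
#'
#' Loads a Matrix Market triplet file plus its `peaks.bed` (rows) and
#' `barcodes.tsv` (columns) sidecars.
#'
#' @param mtx_path Matrix Market file.
#' @param peaks_path BED3+ file of peaks (row order).
#' @param barcodes_path One barcode per line (column order).
#' @return List: `counts` (sparse dgCMatrix with dimnames), `peaks`
#'   (data.table chrom/start/end), `barcodes`.
#' @export
read_peak_matrix <- function(mtx_path, peaks_path, barcodes_path) {
  M <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  pk <- data.table::fread(peaks_path, header = FALSE)
  peaks <- data.table::data.table(chrom = as.character(pk[[1L]]),
                                  start = as.integer(pk[[2L]]),
                                  end = as.integer(pk[[3L]]))
  bcs <- readLines(barcodes_path)
  stop_if(nrow(peaks) != nrow(M) || length(bcs) != ncol(M),
          "sidecar dimensions (%d peaks, %d barcodes) do not match matrix %dx%d",
          nrow(peaks), length(bcs), nrow(M), ncol(M))
  dimnames(M) <- list(peaks[, paste0(chrom, ":", start, "-", end)], bcs)
  list(counts = M, peaks = peaks, barcodes = bcs)
}

#' Write a peak-by-nucleus count matrix with sidecar files
#'
#' @param counts Sparse matrix (peaks x barcodes) with dimnames.
#' @param peaks Peak data.table (chrom, start, end) in row order.
#' @param dir Output directory.
#' @return Named list of paths.
#' @export
write_peak_matrix <- function(counts, peaks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mtx = file.path(dir, "matrix.mtx"),
                peaks = file.path(dir, "peaks.bed"),
                barcodes = file.path(dir, "barcodes.tsv"))
  Matrix::writeMM(counts, paths$mtx)
  data.table::fwrite(as_dt(peaks)[, .(chrom, start, end)], paths$peaks,
                     sep = "\t", col.names = FALSE)
  writeLines(colnames(counts), paths$barcodes)
  paths
}

# library-size normalization to 10k counts per cell (log scale optional)
normalize_counts <- function(counts, log = TRUE) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  X <- counts %*% Matrix::Diagonal(x = 1e4 / cs)
  if (log) X@x <- log1p(X@x)
  colnames(X) <- colnames(counts)
  rownames(X) <- rownames(counts)
  X
}

#' Identify marker peaks per cell type by one-vs-rest logistic regression
#'
#' For every cell type with at least `min_cells` members, each peak is tested
#' one-vs-rest: a binomial GLM of type membership on the peak's normalized
#' accessibility is compared with the intercept-only model by a likelihood
#' ratio test. P-values are Bonferroni-adjusted over peaks and the top
#' `top_n` peaks with positive average log fold change are retained, ranked
#' by adjusted p-value with |avg logFC| as tie-break.
#'
#' @param counts Peak-by-nucleus sparse count matrix with dimnames.
#' @param labels data.table (barcode, cell_type) or named character vector.
#' @param top_n Markers retained per type (default 100).
#' @param min_cells Minimum cells for a type to be eligible (default 150).
#' @return data.table: `cell_type`, `peak` (rowname), `peak_index`,
#'   `adjusted_p`, `avg_logFC`, `rank`.
#' @export
find_marker_peaks <- function(counts, labels, top_n = 100L,
                              min_cells = 150L) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  }
  cells <- intersect(colnames(counts), names(labels))
  stop_if(length(cells) == 0L, "no labelled cells found in the matrix")
  X <- counts[, cells, drop = FALSE]
  lab <- labels[cells]
  sizes <- table(lab)
  eligible <- names(sizes)[sizes >= min_cells]
  stop_if(length(eligible) < 2L,
          "need >= 2 cell types with >= %d cells (have %d)", min_cells,
          length(eligible))
  Xn <- normalize_counts(X, log = TRUE)
  n_peaks <- nrow(X)
  dense <- as.matrix(Xn)

  res <- lapply(eligible, function(tp) {
    y <- as.numeric(lab == tp)
    null_dev <- stats::glm.fit(matrix(1, length(y), 1L), y,
                               family = stats::binomial())$deviance
    pv <- numeric(n_peaks)
    lfc <- numeric(n_peaks)
    in_mean <- rowMeans(dense[, y == 1, drop = FALSE])
    out_mean <- rowMeans(dense[, y == 0, drop = FALSE])
    lfc <- log((expm1(in_mean) + 1) / (expm1(out_mean) + 1))
    for (p in seq_len(n_peaks)) {
      x <- dense[p, ]
      if (stats::sd(x) == 0) { pv[p] <- 1; next }
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
      pv[p] <- stats::pchisq(null_dev - fit$deviance, df = 1L,
                             lower.tail = FALSE)
    }
    adj <- pmin(pv * n_peaks, 1)
    data.table::data.table(cell_type = tp,
                           peak = rownames(X) %||% as.character(seq_len(n_peaks)),
                           peak_index = seq_len(n_peaks),
                           adjusted_p = adj, avg_logFC = lfc)
  })
  out <- data.table::rbindlist(res)
  out <- out[avg_logFC > 0]
  data.table::setorder(out, cell_type, adjusted_p, -avg_logFC)
  out[, rank := seq_len(.N), by = cell_type]
  out <- out[rank <= top_n]
  out[]
}

#' Embed nuclei with truncated SVD of the term-frequency matrix
#'
#' Columns (cells) are scaled to unit total (term frequency) to damp depth
#' effects, then the top singular subspace is computed from the cell-cell
#' Gram matrix; cell coordinates are the right singular vectors scaled by
#' their singular values. Component signs are fixed (largest-magnitude
#' loading positive), so the embedding is fully deterministic.
#'
#' @param counts Peak-by-nucleus sparse matrix.
#' @param n_components Components to keep (default 50; reduced with a warning
#'   when the matrix is smaller).
#' @param tf_scale Disable to embed raw counts.
#' @return Dense matrix, cells x components, rownames = barcodes.
#' @export
svd_embedding <- function(counts, n_components = 50L, tf_scale = TRUE) {
  stop_if(nrow(counts) == 0L || ncol(counts) == 0L, "counts matrix is empty")
  X <- if (tf_scale) {
    cs <- Matrix::colSums(counts)
    cs[cs == 0] <- 1
    counts %*% Matrix::Diagonal(x = 1 / cs)
  } else counts
  k_max <- min(dim(X))
  if (n_components >= k_max) {
    warning(sprintf("n_components reduced from %d to %d (matrix is %dx%d)",
                    n_components, k_max, nrow(X), ncol(X)))
    n_components <- k_max
  }
  G <- as.matrix(Matrix::crossprod(X))      # cells x cells
  eig <- eigen(G, symmetric = TRUE)
  k <- n_components
  val <- pmax(eig$values[seq_len(k)], 0)
  emb <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(emb[, j]))
    if (emb[i_max, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- colnames(counts)
  colnames(emb) <- paste0("SV", seq_len(k))
  emb
}

#' Aggregate read counts over nearest neighbors
#'
#' Smooths the sparse per-cell signal: for every cell, each marker peak's
#' aggregated value is the mean raw count over the cell's `k` nearest
#' neighbors in the embedding (Euclidean), the cell itself included by
#' default (`k = 0` with `include_self` returns the raw counts).
#'
#' @param counts Peak-by-nucleus count matrix.
#' @param embedding Cells-x-components matrix from [svd_embedding()].
#' @param k Number of neighbors (excluding self).
#' @param peak_index Optional integer rows to aggregate (e.g. marker peaks).
#' @param include_self Include the cell in its own neighborhood.
#' @param exclude_neighbors Barcodes barred from serving as neighbors of
#'   other cells (each still neighbors itself). Passing the detected
#'   multiplets here keeps one multiplet's mixed profile from bleeding into
#'   another's aggregate.
#' @return Dense matrix, selected peaks x cells.
#' @export
knn_aggregate <- function(counts, embedding, k = 15L, peak_index = NULL,
                          include_self = TRUE,
                          exclude_neighbors = character()) {
  n <- nrow(embedding)
  stop_if(k >= n, "k must be smaller than the number of cells")
  stop_if(!include_self && k < 1L, "k must be >= 1 when self is excluded")
  sq <- rowSums(embedding^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(embedding)
  if (length(exclude_neighbors)) {
    banned <- rownames(embedding) %in% exclude_neighbors
    stop_if(n - sum(banned) < k + 1L,
            "too few eligible neighbors after exclusion")
    D2[, banned] <- Inf
  }
  diag(D2) <- if (include_self) -Inf else Inf   # force self in/out
  nb <- apply(D2, 1L, function(d) order(d)[seq_len(k + include_self)])
  nb <- matrix(nb, ncol = n)                    # (k + self) x cells
  W <- Matrix::sparseMatrix(i = as.vector(nb),
                            j = rep(seq_len(n), each = nrow(nb)),
                            x = 1 / nrow(nb), dims = c(n, n))
  sel <- if (is.null(peak_index)) seq_len(nrow(counts)) else peak_index
  agg <- as.matrix(counts[sel, , drop = FALSE] %*% W)
  colnames(agg) <- rownames(embedding)
  agg
}

#' Cell type association scores from empirical CDFs
#'
#' For each marker peak, the empirical cumulative distribution of aggregated
#' counts over all cells is evaluated at each cell's value, giving a score in
#' (0, 1]: the fraction of cells with at most this much signal at the peak. A
#' peak constant across all cells scores 1 for everyone (degenerate but
#' harmless). The per-cell-type summary score is the mean over that type's
#' marker peaks.
#'
#' @param agg Aggregated matrix (marker peaks x cells) from [knn_aggregate()].
#' @param markers Marker table from [find_marker_peaks()]; `peak_index` must
#'   address rows of `agg` via `agg_index` (see [annotate_multiplets()]) or
#'   match `rownames(agg)` by `peak`.
#' @return List: `profile` (marker peaks x cells score matrix), `summary`
#'   (cell types x cells matrix of mean scores).
#' @export
association_scores <- function(agg, markers) {
  n <- ncol(agg)
  profile <- t(apply(agg, 1L, function(v)
    data.table::frank(v, ties.method = "max") / n))
  dimnames(profile) <- dimnames(agg)
  idx <- if ("agg_index" %in% names(markers)) markers$agg_index
         else match(markers$peak, rownames(agg))
  stop_if(anyNA(idx), "marker peaks not found among aggregated rows")
  types <- unique(markers$cell_type)
  summary <- do.call(rbind, lapply(types, function(tp) {
    colMeans(profile[idx[markers$cell_type == tp], , drop = FALSE])
  }))
  rownames(summary) <- types
  list(profile = profile, summary = summary)
}

#' Classify multiplets as homotypic or heterotypic and assign origins
#'
#' Each multiplet's most abundant cell type is the argmax of its per-type
#' summary score. Its full marker-peak score profile is compared (Euclidean
#' distance) with that type's singlet profile: the average score profile over
#' confidently-singlet cells of the type. A one-dimensional Gaussian mixture
#' (components chosen among 1-3 by BIC) is fitted to all multiplet distances;
#' members of the component with the largest mean are heterotypic, all
#' others homotypic. Homotypic multiplets get their top-1 type as origin,
#' heterotypic ones their top-2.
#'
#' Two degenerate cases are handled explicitly. A single multiplet skips the
#' mixture and is classified homotypic with a warning. When BIC selects a
#' single component there is no "farthest group" to separate, and labelling
#' the lone component heterotypic would make even a multiplet at distance 0
#' heterotypic; instead each multiplet is compared with the empirical null of
#' singlet distances (every singlet's distance to its own type's mean
#' profile): distances beyond the `null_quantile` cutoff of the top type's
#' singlet null are heterotypic.
#'
#' @param scores Output of [association_scores()].
#' @param labels data.table (barcode, cell_type) or named vector.
#' @param multiplet_barcodes Character vector of detected multiplets.
#' @param null_quantile Singlet-null quantile used by the one-component
#'   fallback (default 0.95).
#' @return List: `origin_calls` (data.table: barcode, type_class, origin1,
#'   origin2, distance_to_top_singlet), `singlet_profiles` (marker peaks x
#'   cell types), `gmm` (the fitted mixture, or NULL for a single multiplet).
#' @export
classify_and_annotate <- function(scores, labels, multiplet_barcodes,
                                  null_quantile = 0.95) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  }
  stop_if(length(multiplet_barcodes) < 1L, "no multiplets to annotate")
  prof <- scores$profile
  summ <- scores$summary
  mset <- intersect(multiplet_barcodes, colnames(prof))
  stop_if(length(mset) == 0L, "no multiplet barcode found in score matrix")

  types <- rownames(summ)
  singlets <- setdiff(colnames(prof), multiplet_barcodes)
  singlet_profiles <- vapply(types, function(tp) {
    cells <- singlets[labels[singlets] == tp & !is.na(labels[singlets])]
    stop_if(length(cells) == 0L, "no singlet cells for type %s", tp)
    rowMeans(prof[, cells, drop = FALSE])
  }, numeric(nrow(prof)))

  top1 <- apply(summ[, mset, drop = FALSE], 2L, function(v)
    types[order(-v)[1L]])
  top2 <- apply(summ[, mset, drop = FALSE], 2L, function(v)
    types[order(-v)[2L]])
  dist <- vapply(seq_along(mset), function(i) {
    sqrt(sum((prof[, mset[i]] - singlet_profiles[, top1[i]])^2))
  }, numeric(1))

  if (length(mset) == 1L) {
    warning("single multiplet: mixture fitting skipped, classified homotypic")
    hetero <- FALSE
    gmm <- NULL
  } else {
    gmm <- fit_gmm1d(dist, G_range = 1:3)
    if (gmm$G > 1L) {
      hetero <- gmm$classification == which.max(gmm$mean)
    } else {
      # one component: no farthest group exists; fall back to the singlet
      # distance null of each multiplet's top type
      null_cut <- vapply(types, function(tp) {
        cells <- singlets[labels[singlets] == tp & !is.na(labels[singlets])]
        dn <- sqrt(colSums((prof[, cells, drop = FALSE] -
                              singlet_profiles[, tp])^2))
        stats::quantile(dn, null_quantile, names = FALSE)
      }, numeric(1))
      hetero <- dist > null_cut[top1]
    }
  }
  calls <- data.table::data.table(
    barcode = mset,
    type_class = ifelse(hetero, "heterotypic", "homotypic"),
    origin1 = top1,
    origin2 = ifelse(hetero, top2, NA_character_),
    distance_to_top_singlet = dist)
  list(origin_calls = calls, singlet_profiles = singlet_profiles, gmm = gmm)
}

#' End-to-end multiplet origin annotation
#'
#' Runs the full annotation pipeline on a peak-by-nucleus count matrix:
#' marker-peak identification, SVD embedding, nearest-neighbor count
#' aggregation at marker peaks, ecdf association scores, and
#' homotypic/heterotypic classification with cell-type-of-origin assignment.
#'
#' @param counts Peak-by-nucleus sparse count matrix with dimnames.
#' @param labels data.table (barcode, cell_type) or named vector.
#' @param multiplet_barcodes Detected multiplet barcodes.
#' @param k Neighbors for aggregation (default 15).
#' @param n_components SVD components (default 50).
#' @param top_markers Marker peaks per type (default 100).
#' @param min_cells Minimum cells per eligible type (default 150).
#' @param include_self Include each cell in its own neighborhood.
#' @param isolate_multiplets Bar detected multiplets from serving as
#'   neighbors of other cells during aggregation (default TRUE), so one
#'   multiplet's mixed profile cannot contaminate another's association
#'   scores.
#' @return List of class `annotation_result`: `origin_calls`, `markers`,
#'   `scores`, `singlet_profiles`, `gmm`, `embedding`.
#' @export
annotate_multiplets <- function(counts, labels, multiplet_barcodes,
                                k = 15L, n_components = 50L,
                                top_markers = 100L, min_cells = 150L,
                                include_self = TRUE,
                                isolate_multiplets = TRUE) {
  markers <- find_marker_peaks(counts, labels, top_n = top_markers,
                               min_cells = min_cells)
  emb <- svd_embedding(counts, n_components = n_components)
  idx <- sort(unique(markers$peak_index))
  agg <- knn_aggregate(counts, emb, k = k, peak_index = idx,
                       include_self = include_self,
                       exclude_neighbors = if (isolate_multiplets)
                         multiplet_barcodes else character())
  markers[, agg_index := match(peak_index, idx)]
  scores <- association_scores(agg, markers)
  cls <- classify_and_annotate(scores, labels, multiplet_barcodes)
  structure(list(origin_calls = cls$origin_calls, markers = markers,
                 scores = scores, singlet_profiles = cls$singlet_profiles,
                 gmm = cls$gmm, embedding = emb),
            class = "annotation_result")
}

#' Write annotation outputs
#'
#' Writes `origin_calls.tsv`, `marker_peaks.tsv` and
#' `singlet_profiles.tsv` into `dir`.
#'
#' @param res An `annotation_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_annotation_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(res$origin_calls, file.path(dir, "origin_calls.tsv"),
                     sep = "\t")
  data.table::fwrite(res$markers, file.path(dir, "marker_peaks.tsv"),
                     sep = "\t")
  sp <- data.table::as.data.table(res$singlet_profiles, keep.rownames = "peak")
  data.table::fwrite(sp, file.path(dir, "singlet_profiles.tsv"), sep = "\t")
  invisible(dir)
}
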