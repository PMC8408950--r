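# compact labelled count matrix: 3 types, one private peak block per type
toy_counts <- function(n_per_type = 160L, n_marker = 6L, n_shared = 20L,
                       seed = 15L) {
  set.seed(seed)
  types <- c("A", "B", "C")
  n <- n_per_type * length(types)
  lab <- rep(types, each = n_per_type)
  bcs <- sprintf("c%04d", seq_len(n))
  n_peaks <- n_shared + n_marker * length(types)
  M <- matrix(0, n_peaks, n)
  M[seq_len(n_shared), ] <- stats::rpois(n_shared * n, 1.5)
  for (t in seq_along(types)) {
    rows <- n_shared + (t - 1L) * n_marker + seq_len(n_marker)
    cols <- which(lab == types[t])
    M[rows, cols] <- stats::rpois(n_marker * length(cols), 2)
  }
  M <- Matrix::Matrix(M, sparse = TRUE)
  dimnames(M) <- list(sprintf("chr1:%d-%d", seq_len(n_peaks) * 1000L,
                              seq_len(n_peaks) * 1000L + 400L), bcs)
  list(counts = M, labels = data.table::data.table(barcode = bcs,
                                                   cell_type = lab),
       marker_rows = lapply(seq_along(types), function(t)
         n_shared + (t - 1L) * n_marker + seq_len(n_marker)))
}

test_that("marker peaks recover type-private accessibility", {
  toy <- toy_counts()
  mk <- find_marker_peaks(toy$counts, toy$labels, top_n = 6L,
                          min_cells = 150L)
  for (t in seq_along(c("A", "B", "C"))) {
    got <- sort(mk$peak_index[mk$cell_type == c("A", "B", "C")[t]])
    expect_equal(got, sort(toy$marker_rows[[t]]))
  }
  # shared peaks never make the list
  expect_false(any(mk$peak_index <= 20L))
})

test_that("types below the cell floor are excluded from marker finding", {
  toy <- toy_counts()
  lab <- toy$labels
  c_cells <- lab[cell_type == "C"]$barcode
  lab2 <- lab[!barcode %in% c_cells[1:11]]   # leaves C with 149 cells
  mk <- find_marker_peaks(toy$counts, lab2, top_n = 6L, min_cells = 150L)
  expect_false("C" %in% mk$cell_type)      # 149 cells < 150
  expect_setequal(unique(mk$cell_type), c("A", "B"))
  # fewer than two eligible types is an error
  lab3 <- toy$labels[cell_type == "A"]
  expect_error(find_marker_peaks(toy$counts, lab3, min_cells = 150L),
               ">= 2 cell types")
})

test_that("SVD embedding is deterministic and respects structure", {
  toy <- toy_counts()
  emb1 <- svd_embedding(toy$counts, n_components = 10L)
  emb2 <- svd_embedding(toy$counts, n_components = 10L)
  expect_identical(emb1, emb2)
  # duplicated cells land on identical coordinates
  M2 <- cbind(toy$counts, toy$counts[, 1, drop = FALSE])
  colnames(M2) <- c(colnames(toy$counts), "dup")
  emb <- svd_embedding(M2, n_components = 5L)
  expect_equal(emb["dup", ], emb[1, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # a rank-1 matrix concentrates everything on component 1; asking for more
  # components than min(dim) reduces with a warning
  R <- Matrix::Matrix(outer(1:20, rep(1, 15)), sparse = TRUE)
  dimnames(R) <- list(NULL, sprintf("c%02d", 1:15))
  expect_warning(e1 <- svd_embedding(R, n_components = 50L,
                                     tf_scale = FALSE), "reduced")
  expect_gt(sum(e1[, 1]^2) / sum(e1^2), 0.999)
})

test_that("knn aggregation matches the quadratic oracle", {
  set.seed(44)
  n <- 200L
  emb <- matrix(stats::rnorm(n * 5L), n, 5L,
                dimnames = list(sprintf("c%03d", 1:n), NULL))
  counts <- Matrix::Matrix(matrix(stats::rpois(30L * n, 2), 30L, n,
                                  dimnames = list(NULL, rownames(emb))),
                           sparse = TRUE)
  k <- 7L
  agg <- knn_aggregate(counts, emb, k = k)
  dense <- as.matrix(counts)
  for (i in sample.int(n, 25L)) {
    d <- colSums((t(emb) - emb[i, ])^2)
    nb <- order(d)[seq_len(k + 1L)]        # self has distance 0
    expect_equal(agg[, i], rowMeans(dense[, nb, drop = FALSE]),
                 ignore_attr = TRUE)
  }
  # k = 0 with self inclusion returns the raw counts
  expect_equal(unname(knn_aggregate(counts, emb, k = 0L)), unname(dense))
  # cells identical in counts and embedding: aggregation is the identity
  same_emb <- emb; same_emb[] <- 1
  same_counts <- counts
  same_counts[] <- rep(counts[, 1], n)
  expect_equal(unname(knn_aggregate(same_counts, same_emb, k = k)),
               unname(as.matrix(same_counts)))
  expect_error(knn_aggregate(counts, emb, k = n), "smaller")
})

test_that("association scores are ecdf evaluations", {
  agg <- matrix(c(0, 1, 2, 5,
                  3, 3, 3, 3), nrow = 2, byrow = TRUE,
                dimnames = list(c("p1", "p2"), sprintf("c%d", 1:4)))
  mk <- data.table::data.table(cell_type = c("T1", "T2"),
                               peak = c("p1", "p2"),
                               peak_index = 1:2, adjusted_p = 0,
                               avg_logFC = 1, rank = 1L)
  sc <- association_scores(agg, mk)
  expect_equal(unname(sc$profile["p1", ]), c(0.25, 0.5, 0.75, 1))
  expect_equal(unname(sc$profile["p2", ]), rep(1, 4))   # constant peak
  expect_true(all(sc$profile >= 0 & sc$profile <= 1))
  expect_equal(unname(sc$summary["T1", "c4"]), 1)
})

test_that("one-dimensional EM recovers well-separated mixtures", {
  set.seed(2)
  x <- c(stats::rnorm(150, 0.5, 0.15), stats::rnorm(150, 5, 0.6))
  g <- fit_gmm1d(x)
  expect_equal(g$G, 2L)
  mu <- sort(g$mean)
  expect_lt(abs(mu[1] - 0.5) / 0.5, 0.1)
  expect_lt(abs(mu[2] - 5) / 5, 0.1)
  expect_equal(length(g$classification), length(x))
  # unimodal data prefers one component
  expect_equal(fit_gmm1d(stats::rnorm(200))$G, 1L)
})

test_that("distance-zero multiplets are homotypic", {
  toy <- toy_counts()
  mk <- find_marker_peaks(toy$counts, toy$labels, top_n = 6L,
                          min_cells = 150L)
  emb <- svd_embedding(toy$counts, n_components = 10L)
  idx <- sort(unique(mk$peak_index))
  agg <- knn_aggregate(toy$counts, emb, k = 15L, peak_index = idx)
  mk[, agg_index := match(peak_index, idx)]
  sc <- association_scores(agg, mk)
  # fabricate one multiplet whose profile equals the A singlet mean exactly
  a_cells <- toy$labels[cell_type == "A"]$barcode
  fake <- a_cells[1]
  sc$profile[, fake] <- rowMeans(sc$profile[, setdiff(a_cells, fake)])
  expect_warning(
    cls <- classify_and_annotate(sc, toy$labels, fake),
    "single multiplet")
  expect_equal(cls$origin_calls$type_class, "homotypic")
  expect_equal(cls$origin_calls$origin1, "A")
  expect_true(is.na(cls$origin_calls$origin2))
})
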