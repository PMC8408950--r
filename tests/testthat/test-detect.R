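site_dt <- function(start, end, barcode = "b1", chrom = "chr1",
                    max_depth = 3L) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), barcode = barcode,
                         max_depth = max_depth)
}

test_that("exclusion BEDs load as a pooled region set", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.bed"); f2 <- file.path(dir, "b.bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t250"), f1)
  writeLines("chr2\t0\t50", f2)
  rs <- load_region_beds(c(f1, f2))
  expect_equal(length(rs), 3L)              # overlapping inputs kept as given
  expect_equal(length(load_region_beds(character())), 0L)
  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\tx"), bad)
  expect_error(load_region_beds(bad), "line 2")
})

test_that("site exclusion follows the 1-bp half-open rule", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "excl.bed")
  writeLines(c("chr1\t105\t200", "chr1\t300\t400"), bed)
  excl <- load_region_beds(bed)
  sites <- site_dt(c(100, 100, 400), c(110, 105, 410))
  kept <- filter_sites(sites, excl)
  # [100,110) shares bases 105..109 -> removed; [100,105) abuts -> kept;
  # [400,410) starts where the exclusion ends -> kept
  expect_equal(kept$start, c(100L, 400L))
  # empty exclusion set is the identity
  expect_equal(filter_sites(sites, GenomicRanges::GRanges()), sites)
})

test_that("merging is transitive over >= 1 bp overlaps only", {
  m <- merge_sites(site_dt(c(5, 9), c(10, 20)))
  expect_equal(m[, c("start", "end")],
               data.table::data.table(start = 5L, end = 20L))
  m <- merge_sites(site_dt(c(5, 10), c(10, 20)))
  expect_equal(nrow(m), 2L)                 # abutting stays separate
  m <- merge_sites(site_dt(c(0, 4, 7), c(5, 8, 12)))
  expect_equal(m$start, 0L)
  expect_equal(m$end, 12L)
})

test_that("merging equals a union-find oracle on random site sets", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    s <- sample.int(200, n, replace = TRUE)
    sites <- site_dt(s, s + sample.int(25, n, replace = TRUE),
                     chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    got <- merge_sites(sites)
    want <- oracle_merge(sites)
    expect_equal(got$chrom, want$chrom, info = i)
    expect_equal(got$start, want$start, info = i)
    expect_equal(got$end, want$end, info = i)
  }
})

test_that("the overlap matrix is binary with all cell barcodes as columns", {
  sites <- rbind(site_dt(100, 110, "b1"), site_dt(105, 115, "b1"))
  merged <- merge_sites(sites)
  om <- build_overlap_matrix(merged, sites, c("b1", "b2"))
  expect_equal(dim(om$M), c(1L, 2L))
  # two sites of one nucleus in one region still give a single 1
  expect_equal(as.numeric(om$M[1, ]), c(1, 0))
})

test_that("poisson upper tail matches series summation and is monotone", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  # k = 5, lambda = 1: 1 - e^-1 * sum_{i<5} 1/i!
  expect_equal(poisson_upper_tail(5, 1), 1 - exp(-1) * sum(1 / factorial(0:4)),
               tolerance = 1e-12)
  ks <- 0:60
  p <- poisson_upper_tail(ks, 7)
  expect_true(all(diff(p) < 0))
  expect_error(poisson_upper_tail(3, 0), "lambda")
  expect_error(poisson_upper_tail(-1, 1), "k must")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  set.seed(5)
  for (i in 1:25) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), info = i)
  }
})

make_om <- function(M, barcodes = paste0("b", seq_len(ncol(M)))) {
  sites <- data.table::rbindlist(lapply(seq_len(ncol(M)), function(j) {
    rows <- which(M[, j] == 1)
    if (!length(rows)) return(NULL)
    data.table::data.table(chrom = "chr1", start = rows * 100L,
                           end = rows * 100L + 10L, barcode = barcodes[j],
                           max_depth = 3L)
  }))
  regions <- data.table::data.table(chrom = "chr1",
                                    start = seq_len(nrow(M)) * 100L,
                                    end = seq_len(nrow(M)) * 100L + 10L,
                                    region_id = seq_len(nrow(M)))
  build_overlap_matrix(regions, sites, barcodes)
}

test_that("repetitive rows are inferred from row sums and removed", {
  # 60 regions seen by exactly 2 of 100 nuclei, one region seen by 90
  set.seed(11)
  M <- matrix(0L, 61, 100)
  for (r in 1:60) M[r, sample(100, 2)] <- 1L
  M[61, sample(100, 90)] <- 1L
  om <- make_om(M)
  res <- infer_repetitive(om, fdr = 0.01)
  expect_true(res$calls$flagged[61])
  expect_equal(sum(res$calls$flagged), 1L)
  expect_equal(nrow(res$reduced$M), 60L)
  expect_false(61L %in% res$reduced$regions$region_id)
  # column sums can only decrease
  expect_true(all(Matrix::colSums(res$reduced$M) <= Matrix::colSums(om$M)))

  # uniform row sums: nothing flagged
  M2 <- matrix(1L, 10, 30)
  res2 <- infer_repetitive(make_om(M2), fdr = 0.01)
  expect_equal(sum(res2$calls$flagged), 0L)
})

test_that("multiplet calls flag only genuine count excess", {
  # uniform counts give no calls
  M <- matrix(0L, 50, 40)
  for (j in 1:40) M[sample(50, 5), j] <- 1L
  det <- detect_multiplets(make_om(M))
  expect_equal(sum(det$is_multiplet), 0L)

  # one nucleus far in the tail among Poisson(5) counts
  set.seed(8)
  n <- 1000L
  counts <- stats::rpois(n - 1L, 5)
  counts <- pmin(counts, 45L)
  M2 <- matrix(0L, 60, n)
  for (j in seq_len(n - 1L)) M2[sample(60, counts[j]), j] <- 1L
  M2[, n] <- 1L                                     # count 60
  det2 <- detect_multiplets(make_om(M2))
  expect_true(det2$is_multiplet[n])
  expect_equal(sum(det2$is_multiplet), 1L)
  # q is monotone in the FDR threshold: 0.01 calls form a subset of 0.05
  det5 <- detect_multiplets(make_om(M2), fdr = 0.05)
  expect_true(all(which(det2$is_multiplet) %in% which(det5$is_multiplet)))
})

test_that("degenerate matrices are handled without errors", {
  empty <- build_overlap_matrix(
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), region_id = integer()),
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), barcode = character(),
                           max_depth = integer()),
    c("b1", "b2"))
  res <- infer_repetitive(empty)
  expect_equal(nrow(res$calls), 0L)
  expect_warning(det <- detect_multiplets(empty), "zero")
  expect_equal(nrow(det), 2L)
  expect_false(any(det$is_multiplet))
})

test_that("zero-count nuclei stay in the BH family by default", {
  M <- matrix(0L, 20, 10)
  M[, 1] <- 1L
  M[1:2, 2] <- 1L
  om <- make_om(M)
  det_all <- detect_multiplets(om)
  expect_equal(nrow(det_all), 10L)
  expect_true(all(det_all$p[det_all$k == 0] == 1))
  det_nz <- detect_multiplets(om, test_zero_counts = FALSE)
  expect_true(all(is.na(det_nz$p[det_nz$k == 0])))
  expect_equal(sum(!is.na(det_nz$p)), 2L)
})

test_that("detection is deterministic end to end", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_synthetic_sample(sim, dir)
  r1 <- run_multiplet_detection(fragments = paths$fragments,
                                barcodes = paths$barcodes, verbose = FALSE)
  r2 <- run_multiplet_detection(fragments = paths$fragments,
                                barcodes = paths$barcodes, verbose = FALSE)
  expect_equal(r1$calls, r2$calls)
  expect_equal(r1$merged_regions, r2$merged_regions)
})
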