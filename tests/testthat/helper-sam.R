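# Build tiny coordinate-sorted BAMs from in-code alignment descriptions.
# Each row of `pairs` describes one read pair: chrom, start (0-based leftmost
# 5'), tlen, barcode, plus optional mapq / dup / mate_chrom / no_tag fields.

FLAG_PAIRED <- 1L; FLAG_PROPER <- 2L; FLAG_MREV <- 32L
FLAG_READ1 <- 64L; FLAG_READ2 <- 128L; FLAG_REV <- 16L; FLAG_DUP <- 1024L

write_pair_bam <- function(pairs, dir = NULL,
                           sq = c(chr1 = 100000L, chr2 = 100000L, chrX = 100000L),
                           sorted = TRUE, read_len = 50L) {
  if (is.null(dir)) {
    dir <- tempfile("bamfix")
    dir.create(dir)
  }
  pairs <- data.table::as.data.table(pairs)
  if (is.null(pairs$mapq)) pairs$mapq <- 60L
  if (is.null(pairs$dup)) pairs$dup <- FALSE
  if (is.null(pairs$mate_chrom)) pairs$mate_chrom <- pairs$chrom
  if (is.null(pairs$no_tag)) pairs$no_tag <- FALSE
  pairs[is.na(mapq), mapq := 60L]
  pairs[is.na(dup), dup := FALSE]
  pairs[is.na(mate_chrom), mate_chrom := chrom]
  pairs[is.na(no_tag), no_tag := FALSE]
  hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s",
                   if (sorted) "coordinate" else "unsorted"),
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  recs <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i]
    qn <- sprintf("q%04d", i)
    pos1 <- p$start + 1L                       # SAM is 1-based
    # place the mate so that TLEN is consistent; for cross-chrom mates the
    # mate position is arbitrary
    pos2 <- if (p$mate_chrom == p$chrom) p$start + p$tlen - read_len + 1L
            else 5000L
    cig <- sprintf("%dM", read_len)
    seqs <- strrep("A", read_len); qual <- strrep("I", read_len)
    tag <- if (p$no_tag) "" else sprintf("\tCB:Z:%s", p$barcode)
    f1 <- FLAG_PAIRED + FLAG_PROPER + FLAG_MREV + FLAG_READ1 +
      if (p$dup) FLAG_DUP else 0L
    f2 <- FLAG_PAIRED + FLAG_PROPER + FLAG_REV + FLAG_READ2 +
      if (p$dup) FLAG_DUP else 0L
    recs[[length(recs) + 1L]] <- data.table::data.table(
      chrom = c(p$chrom, p$mate_chrom), pos = c(pos1, pos2),
      line = c(
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s", qn, f1,
                p$chrom, pos1, p$mapq, cig,
                if (p$mate_chrom == p$chrom) "=" else p$mate_chrom,
                pos2, p$tlen, seqs, qual, tag),
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s", qn, f2,
                p$mate_chrom, pos2, p$mapq, cig,
                if (p$mate_chrom == p$chrom) "=" else p$chrom,
                pos1, -p$tlen, seqs, qual, tag)))
  }
  body <- data.table::rbindlist(recs)
  if (sorted) {
    body[, chrom := factor(chrom, levels = names(sq))]
    data.table::setorder(body, chrom, pos)
  }
  sam <- file.path(dir, "reads.sam")
  writeLines(c(hdr, body$line), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = FALSE)
  bam
}
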