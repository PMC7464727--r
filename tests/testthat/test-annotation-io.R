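gtf_line <- function(chrom, start, end, strand, gene, tx,
                     biotype = "protein_coding", feature = "exon") {
  sprintf(paste0('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                 'transcript_id "%s"; gene_biotype "%s";'),
          chrom, feature, start, end, strand, gene, tx, biotype)
}

test_that("GTF exons are read, typed, and deduplicated across transcripts", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("c1", 100, 200, "+", "g1", "g1.t1"),
    gtf_line("c1", 100, 200, "+", "g1", "g1.t2"),  # shared exon
    gtf_line("c1", 300, 400, "+", "g1", "g1.t1"),
    gtf_line("c1", 900, 980, "-", "g2", "g2.t1", biotype = "lncRNA"),
    gtf_line("c1", 50, 1500, "+", "g1", "g1.t1", feature = "gene")
  ), f)
  ex <- read_exons_gtf(f)
  expect_equal(nrow(ex), 3L)
  shared <- ex[ex$start == 100, ]
  expect_equal(shared$transcript_id, "g1.t1,g1.t2")
  expect_equal(sort(unique(ex$biotype)), c("coding", "lnc"))
  expect_equal(ex$list_id, rep(1L, 3))
})

test_that("empty GTF yields an empty exon set without error", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), f)
  expect_equal(nrow(read_exons_gtf(f)), 0L)
})

test_that("simulator GTF reloads with the planted exon count", {
  sim <- small_sim(noise = FALSE)
  ex <- read_exons_gtf(sim$paths$gtf)
  planted <- sim$ann$exons[sim$ann$exons$list_id == 1L, ]
  expect_equal(nrow(ex), nrow(planted))
  expect_setequal(coord_key(ex$chrom, ex$strand, ex$start, ex$end),
                  coord_key(planted$chrom, planted$strand, planted$start,
                            planted$end))
})

test_that("BED exons convert 0-based half-open to 1-based inclusive", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tx\t0\t+", f)
  ex <- read_exons_bed(f, list_id = 2L)
  expect_equal(ex$start, 1000L)
  expect_equal(ex$end, 2000L)
  expect_equal(ex$biotype, "lnc")

  f12 <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 999, 2000, "gx", 0, "+", 999, 2000, "0", 3,
                   "100,100,100", "0,400,901", sep = "\t"), f12)
  ex12 <- read_exons_bed(f12, list_id = 3L)
  expect_equal(nrow(ex12), 3L)
  expect_equal(ex12$start, c(1000L, 1400L, 1901L))
  expect_equal(ex12$end, c(1099L, 1499L, 2000L))
})

test_that("BED writer and reader round-trip exon coordinates", {
  sim <- small_sim(noise = FALSE)
  lnc <- sim$ann$exons[sim$ann$exons$list_id == 2L, ]
  ex <- read_exons_bed(sim$paths$lnc_bed, list_id = 2L)
  expect_equal(nrow(ex), nrow(lnc))
  expect_setequal(coord_key(ex$chrom, ex$strand, ex$start, ex$end),
                  coord_key(lnc$chrom, lnc$strand, lnc$start, lnc$end))
  expect_setequal(unique(ex$gene_id), unique(lnc$gene_id))
})

test_that("introns are transcript gaps, deduplicated per gene", {
  ex <- data.frame(chrom = "c1", strand = "+",
                   start = c(100L, 300L), end = c(200L, 400L),
                   gene_id = "g1", transcript_id = "t1",
                   biotype = "coding", list_id = 1L,
                   stringsAsFactors = FALSE)
  intr <- derive_introns(ex)
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$start, 201L)
  expect_equal(intr$end, 299L)
  expect_equal(intr$upstream_exon_end, 200L)
  expect_equal(intr$downstream_exon_start, 300L)
  ## single-exon transcript: no introns
  expect_equal(nrow(derive_introns(ex[1, ])), 0L)
  ## identical intron in a second transcript collapses
  ex2 <- rbind(ex, transform(ex, transcript_id = "t2"))
  expect_equal(nrow(derive_introns(ex2)), 1L)
  ## overlapping exons within a transcript are an error
  bad <- transform(ex, start = c(100L, 150L))
  expect_error(derive_introns(bad), "overlap")
})

test_that("intron derivation agrees with brute-force gap enumeration on simulated genes", {
  sim <- small_sim(noise = FALSE)
  coding <- sim$ann$exons[sim$ann$exons$biotype == "coding", ]
  intr <- derive_introns(coding)
  ## oracle: enumerate gaps row-wise per transcript
  expected <- character(0)
  for (tx in unique(coding$transcript_id)) {
    e <- coding[coding$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1)) {
      expected <- c(expected, coord_key(e$chrom[1], e$strand[1],
                                        e$end[i] + 1, e$start[i + 1] - 1))
    }
  }
  expect_setequal(coord_key(intr$chrom, intr$strand, intr$start, intr$end),
                  unique(expected))
})

test_that("annotation operations commute with a genome-wide coordinate shift", {
  sim <- small_sim(noise = FALSE)
  coding <- sim$ann$exons[sim$ann$exons$biotype == "coding", ]
  delta <- 1234L
  shifted <- transform(coding, start = start + delta, end = end + delta)
  i0 <- derive_introns(coding)
  i1 <- derive_introns(shifted)
  expect_equal(i1$start, i0$start + delta)
  expect_equal(i1$end, i0$end + delta)
})

test_that("mono-exonic genes are flagged iff every transcript has one exon", {
  ex <- data.frame(
    chrom = "c1", strand = "+",
    start = c(100L, 500L, 700L, 1200L),
    end = c(200L, 600L, 800L, 1300L),
    gene_id = c("sno1", "g2", "g2", "g3"),
    transcript_id = c("sno1.t1", "g2.t1", "g2.t1", "g3.t1"),
    biotype = c("other_nc", "coding", "coding", "other_nc"),
    list_id = 1L, stringsAsFactors = FALSE)
  genes <- find_mono_exonic(ex)
  expect_equal(genes$mono_exonic[genes$gene_id == "sno1"], TRUE)
  expect_equal(genes$mono_exonic[genes$gene_id == "g2"], FALSE)
  expect_equal(genes$mono_exonic[genes$gene_id == "g3"], TRUE)
})

test_that("all planted mono-exonic genes are recovered from the simulator annotation", {
  sim <- small_sim(noise = FALSE)
  ex <- read_exons_gtf(sim$paths$gtf)
  genes <- find_mono_exonic(ex)
  planted <- sim$ann$genes$gene_id[sim$ann$genes$gene_class == "mono"]
  expect_setequal(genes$gene_id[genes$mono_exonic], planted)
})

test_that("exon lists stay disjoint with list-priority deduplication", {
  e1 <- data.frame(chrom = "c1", strand = "+", start = 100L, end = 200L,
                   gene_id = "a", transcript_id = "a.t", biotype = "coding",
                   list_id = 1L, stringsAsFactors = FALSE)
  e2 <- transform(e1, gene_id = "b", biotype = "lnc", list_id = 2L)
  e3 <- transform(e1, start = 500L, end = 600L, list_id = 3L,
                  biotype = "novel")
  out <- dedup_exon_lists(rbind(e2, e1, e3))
  expect_equal(nrow(out), 2L)
  expect_equal(out$list_id[out$start == 100L], 1L)
})
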