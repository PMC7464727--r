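test_that("chimeric-junction parsing maps fields faithfully and skips comments", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header comment",
               chim_line(bp_d = 2001L, st_d = "+", bp_a = 1000L, st_a = "-",
                         name = "rA/2"),
               chim_line(name = "rB/1"),
               paste(chim_line(name = "rC"), "extra1", "extra2",
                     sep = "\t")), f)
  rec <- parse_chimeric_junctions(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$strand_donor[1], "+")
  expect_equal(rec$strand_acceptor[1], "-")
  expect_equal(rec$brkpt_donor[1], 2001L)
  expect_equal(rec$mate, c(2L, 1L, NA))
  expect_equal(rec$read_id, c("rA", "rB", "rC"))
})

test_that("malformed chimeric lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(chim_line(), "c1\t100\t+"), f)
  expect_error(parse_chimeric_junctions(f), "line 2")
  writeLines(c(chim_line(st_d = "?")), f)
  expect_error(parse_chimeric_junctions(f), "strand")
  writeLines(c(chim_line(), sub("2001", "abc", chim_line())), f)
  expect_error(parse_chimeric_junctions(f), "line 2")
})

test_that("simulator chimeric output round-trips field for field", {
  sim <- small_sim(noise = TRUE)
  rec <- parse_chimeric_junctions(sim$paths$chimeric)
  emitted <- utils::read.table(sim$paths$chimeric, sep = "\t",
                               stringsAsFactors = FALSE)
  expect_equal(nrow(rec), nrow(emitted))
  cols <- c("chrom_donor", "brkpt_donor", "strand_donor", "chrom_acceptor",
            "brkpt_acceptor", "strand_acceptor", "junction_code",
            "repeat_left", "repeat_right", "read_name", "seg1_start",
            "seg1_cigar", "seg2_start", "seg2_cigar")
  for (i in seq_along(cols)) {
    expect_equal(rec[[cols[i]]], emitted[[i]], info = cols[i])
  }
})

test_that("is_ccr requires same chrom/strand, inverted order, segment size, within-read code", {
  base <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    chim_line(bp_d = 5000L, bp_a = 2000L, c1 = "60M40S", c2 = "60S40M"),
    chim_line(bp_d = 5000L, bp_a = 2000L, st_a = "-"),
    chim_line(bp_d = 5000L, bp_a = 2000L, chrom_a = "c2"),
    chim_line(bp_d = 2000L, bp_a = 5000L),
    chim_line(bp_d = 5000L, bp_a = 2000L, code = -1L),
    chim_line(bp_d = 5000L, bp_a = 2000L, c1 = "14M86S", c2 = "14S86M"),
    chim_line(bp_d = 5000L, bp_a = 2000L, c1 = "15M85S", c2 = "15S85M"),
    chim_line(bp_d = 2000L, bp_a = 5000L, st_d = "-", st_a = "-")
  ), base)
  rec <- parse_chimeric_junctions(base)
  expect_equal(is_ccr(rec),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  ## minimum segment size is configurable
  expect_true(is_ccr(rec, min_segment = 14)[6])
})

test_that("breakpoints convert to closed junction intervals on both strands", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(chim_line(bp_d = 2001L, bp_a = 999L),
               chim_line(bp_d = 999L, bp_a = 2001L, st_d = "-", st_a = "-")),
             f)
  rec <- parse_chimeric_junctions(f)
  j <- ccr_to_junction(rec)
  ## same locus, both strands: identical [start, end]
  expect_equal(j$start, c(1000L, 1000L))
  expect_equal(j$end, c(2000L, 2000L))
  expect_equal(j$size, c(1001L, 1001L))
  ## wrong dialect offsets surface as an error, not silent drift
  expect_error(ccr_to_junction(rec[1, ], offsets = c(1500L, -1500L)),
               "offsets")
})

test_that("junction conversion recovers every planted circle on both strands", {
  sim <- small_sim(noise = FALSE)
  j <- select_ccrs(sim$paths$chimeric)
  jk <- unique(coord_key(j$chrom, j$strand, j$start, j$end))
  tk <- coord_key(sim$truth$chrom, sim$truth$strand, sim$truth$start,
                  sim$truth$end)
  expect_setequal(jk, tk)
  sizes <- j$size[match(tk, coord_key(j$chrom, j$strand, j$start, j$end))]
  expect_equal(sizes, sim$truth$size)
  expect_true(any(sim$truth$strand == "-"))
})

test_that("chromosome filtering keeps listed chromosomes, is idempotent, empty keeps all", {
  df <- data.frame(chrom = c("c1", "c2", "c1"), x = 1:3,
                   stringsAsFactors = FALSE)
  expect_equal(filter_chromosomes(df, "c1")$x, c(1L, 3L))
  expect_equal(filter_chromosomes(df, character()), df)
  once <- filter_chromosomes(df, "c1")
  expect_equal(filter_chromosomes(once, "c1"), once)
})

test_that("reads on multiple chimeric lines are dropped entirely", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(chim_line(name = "dup/1"), chim_line(name = "dup/1"),
               chim_line(name = "solo/1")), f)
  rec <- drop_ambiguous_reads(parse_chimeric_junctions(f))
  expect_equal(rec$read_name, "solo/1")
})

test_that("split-read counting handles SJ tables and N-gapped SAM alignments", {
  sj <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("chrA\t201\t300\t1\t0\t1\t287\t12\t30",
               "chrA\t500\t700\t2\t0\t1\t55\t0\t30"), sj)
  expect_equal(count_split_reads(sj, "chrA", 200, 301, "+"), 287)
  expect_equal(count_split_reads(sj, "chrA", 499, 701, "-"), 55)
  expect_equal(count_split_reads(sj, "chrA", 499, 701, "+"), 0L)
  expect_equal(count_split_reads(sj, "chrA", 900, 1000, "+"), 0L)

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:chrA\tLN:10000",
               sprintf("r%d\t0\tchrA\t%d\t255\t30M100N30M\t*\t0\t0\t*\t*",
                       1:12, 171),
               "lin\t0\tchrA\t150\t255\t60M\t*\t0\t0\t*\t*",
               "oth\t0\tchrA\t160\t255\t30M120N30M\t*\t0\t0\t*\t*"), sam)
  expect_equal(count_split_reads(sam, "chrA", 200, 301), 12)
  expect_error(count_split_reads("no_such_file.tab", "chrA", 1, 2))
})
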