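mk_introns <- function(start, end, chrom = "c1", strand = "+",
                       gene = "g1") {
  data.frame(chrom = rep_len(chrom, length(start)),
             strand = rep_len(strand, length(start)),
             start = as.integer(start), end = as.integer(end),
             gene_id = rep_len(gene, length(start)),
             upstream_exon_end = as.integer(start) - 1L,
             downstream_exon_start = as.integer(end) + 1L,
             stringsAsFactors = FALSE)
}

mk_mono_exons <- function(start, end, chrom = "c1", strand = "+",
                          gene = "m1") {
  data.frame(chrom = rep_len(chrom, length(start)),
             strand = rep_len(strand, length(start)),
             start = as.integer(start), end = as.integer(end),
             gene_id = rep_len(gene, length(start)),
             transcript_id = paste0(gene, ".t1"), biotype = "other_nc",
             list_id = 1L, stringsAsFactors = FALSE)
}

test_that("intron circles require exact intron coordinates", {
  intr <- mk_introns(201, 299)
  expect_true(match_intron_circle(mk_lacs(201, 299), intr))
  expect_false(match_intron_circle(mk_lacs(202, 299), intr))
  expect_false(match_intron_circle(mk_lacs(201, 299, strand = "-"), intr))
})

test_that("lariat matching anchors the intron 5' base and trims a 3' tail", {
  intr <- mk_introns(201, 500)
  hit <- match_lariat(mk_lacs(201, 470), intr)
  expect_true(hit$match)
  expect_equal(hit$tail_gap, 30L)
  ## 5' boundary mismatch
  expect_false(match_lariat(mk_lacs(202, 470), intr)$match)
  ## the full intron is not a lariat (tail gap 0 below min_tail)
  expect_false(match_lariat(mk_lacs(201, 500), intr)$match)
  ## minus strand: the 5' first intron base is the genomic end
  intr_m <- mk_introns(201, 500, strand = "-")
  hit_m <- match_lariat(mk_lacs(231, 500, strand = "-"), intr_m)
  expect_true(hit_m$match)
  expect_equal(hit_m$tail_gap, 30L)
  expect_false(match_lariat(mk_lacs(201, 470, strand = "-"), intr_m)$match)
  ## a branch-point window bounds the trimmed tail when enabled
  expect_false(match_lariat(mk_lacs(201, 470), intr,
                            branch_window = 20)$match)
  expect_true(match_lariat(mk_lacs(201, 470), intr,
                           branch_window = 30)$match)
})

test_that("a 78-nt lariat circle from a short intron is recovered (no size floor)", {
  intr <- mk_introns(201, 320)
  hit <- match_lariat(mk_lacs(201, 278), intr)
  expect_true(hit$match)
  expect_equal(278 - 201 + 1, 78)
})

test_that("sub-exonic circles sit inside a mono-exonic exon without being it", {
  ex <- mk_mono_exons(1000, 1257)  # 258 bp exon
  hit <- match_subexonic(mk_lacs(1040, 1184), ex)  # 145 nt
  expect_true(hit$match)
  expect_true(hit$confident)
  ## below the 55 nt floor
  expect_false(match_subexonic(mk_lacs(1040, 1093), ex)$match)
  ## 55-70 nt: retained but not confident
  h60 <- match_subexonic(mk_lacs(1040, 1099), ex)
  expect_true(h60$match)
  expect_false(h60$confident)
  ## the full exon is exonic, not sub-exonic
  expect_false(match_subexonic(mk_lacs(1000, 1257), ex)$match)
  ## partial overlap beyond the exon does not count
  expect_false(match_subexonic(mk_lacs(1200, 1300), ex)$match)
  expect_false(match_subexonic(mk_lacs(1040, 1184, strand = "-"), ex)$match)
})

test_that("the cascade assigns exactly one class per LAC, circles before lariats", {
  intr <- mk_introns(c(201, 601), c(500, 800))
  ex <- mk_mono_exons(2000, 2400)
  lacs <- mk_lacs(start = c(201, 201, 601, 2050, 2050, 3000),
                  end = c(500, 470, 800, 2200, 2085, 3200))
  lab <- classify_noncanonical(lacs, intr, ex)
  expect_equal(lab$klass,
               c("intron_circle", "lariat_intronic", "intron_circle",
                 "sub_exonic", "unallocated", "unallocated"))
  ## 2050-2085 is 36 nt, below the sub-exonic floor
  expect_equal(sum(table(lab$klass)), nrow(lacs))
})

test_that("noise-free synthetic circles all receive their planted class", {
  sim <- small_sim(noise = FALSE)
  res <- run_small_pipeline(noise = FALSE)
  got <- truth_classes(sim, res)
  expect_false(anyNA(got))
  expect_equal(got, sim$truth$class)
  expect_equal(sum(res$noncanonical$klass == "unallocated"), 0L)
})

test_that("per-gene set grouping is single linkage on strict overlap", {
  lacs <- mk_lacs(start = c(100, 150, 190, 400, 450),
                  end = c(200, 260, 300, 500, 520))
  sets <- group_sets(lacs, gene_ids = rep("m1", 5))
  expect_equal(length(unique(sets$sets$set_id)), 2L)
  expect_equal(sort(sets$summary$n_lacs), c(2L, 3L))
  expect_match(sets$summary$set_spec, "^\\d+ x \\d+(-\\d+)? nt$")
  ## adjacent but non-overlapping intervals stay separate
  adj <- mk_lacs(start = c(100, 201), end = c(200, 300))
  expect_equal(length(unique(group_sets(adj, rep("m1", 2))$sets$set_id)), 2L)
  ## all pairwise overlapping: one set
  one <- mk_lacs(start = c(100, 110, 120), end = c(300, 310, 320))
  expect_equal(length(unique(group_sets(one, rep("m1", 3))$sets$set_id)), 1L)
})

test_that("set partitioning equals brute-force connected components on random input", {
  set.seed(404)
  for (rep in 1:5) {
    n <- 30
    start <- sample(1:500, n, replace = TRUE)
    end <- start + sample(20:120, n, replace = TRUE)
    lacs <- mk_lacs(start, end)
    sets <- group_sets(lacs, rep("g", n))$sets
    want <- oracle_components(start, end)
    got <- match(sets$set_id, unique(sets$set_id))
    ## same partition: equal label co-membership
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("size statistics report class means and never report empty means as 0", {
  lab <- data.frame(klass = c(rep("lariat_intronic", 3), "intron_circle"),
                    size = c(100L, 200L, 300L, 700L),
                    stringsAsFactors = FALSE)
  st <- size_stats(lab)
  expect_equal(unname(st$mean_size["lariat_intronic"]), 200)
  expect_equal(unname(st$counts["lariat_intronic"]), 3L)
  expect_equal(st$frac_large, 0.25)
  empty <- size_stats(lab[0, ])
  expect_false("lariat_intronic" %in% names(empty$mean_size))
  expect_true(is.na(empty$frac_large))
})
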