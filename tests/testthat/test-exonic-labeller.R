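test_that("both-boundary matching is exact and strand-aware", {
  b <- mk_boundaries(position = c(300L, 400L),
                     side = c("acceptor_start", "donor_end"))
  expect_true(match_both(mk_lacs(300, 400), b))
  expect_false(match_both(mk_lacs(300, 401), b))
  expect_false(match_both(mk_lacs(300, 400, strand = "-"), b))
  ## sides must not swap: an exon end cannot validate a LAC start
  expect_false(match_both(mk_lacs(400, 400), b))
})

test_that("a LAC spanning distant exon boundaries of one simulated gene matches", {
  sim <- small_sim(noise = FALSE)
  ex <- sim$ann$exons
  g <- ex[ex$biotype == "coding" & ex$gene_id == ex$gene_id[1], ]
  g <- g[order(g$start), ]
  b <- build_boundaries(g)
  lac <- mk_lacs(g$start[2], g$end[4], chrom = g$chrom[1],
                 strand = g$strand[1])
  expect_true(match_both(lac, b))
})

test_that("iterative labelling follows chains of promoted novel boundaries, side-typed", {
  b <- mk_boundaries(position = c(100L, 200L),
                     side = c("acceptor_start", "donor_end"))
  lacs <- mk_lacs(start = c(100L, 340L, 340L, 900L, 500L),
                  end = c(500L, 500L, 700L, 950L, 800L))
  ## A=[100,500]: start known -> round 1, promotes novel end 500
  ## B=[340,500]: end matches novel 500 -> round 2, promotes novel start 340
  ## C=[340,700]: start matches novel 340 -> round 3
  ## D=[900,950]: never matched
  ## E=[500,800]: 500 was promoted as an *end*; as a start it must not match
  out <- iterative_label(lacs, b)
  lab <- out$labels[order(out$labels$lac_id), ]
  expect_equal(lab$lac_id, c("L001", "L002", "L003"))
  expect_equal(lab$mode, c("iterative_one_known", "iterative_novel_match",
                           "iterative_novel_match"))
  expect_equal(lab$round, c(1L, 2L, 3L))
  expect_false(any(c("L004", "L005") %in% lab$lac_id))
  ## the augmented boundary set records the promoted entries, side-typed
  nov <- out$boundaries[out$boundaries$origin == "novel", ]
  expect_setequal(paste(nov$position, nov$side),
                  c("500 donor_end", "340 acceptor_start",
                    "700 donor_end"))
})

test_that("no boundary contact yields zero labels in one round", {
  b <- mk_boundaries(position = c(100L, 200L),
                     side = c("acceptor_start", "donor_end"))
  out <- iterative_label(mk_lacs(5000, 6000), b)
  expect_equal(nrow(out$labels), 0L)
})

test_that("re-running the labeller on its own leftovers adds nothing (fixpoint)", {
  sim <- small_sim(noise = FALSE)
  res <- run_small_pipeline(noise = FALSE)
  ex1 <- sim$ann$exons[sim$ann$exons$list_id == 1L, ]
  b <- build_boundaries(ex1)
  out <- iterative_label(res$retained, b)
  leftover <- res$retained[!(res$retained$lac_id %in% out$labels$lac_id), ]
  again <- iterative_label(leftover, b)
  expect_equal(nrow(again$labels), 0L)
})

test_that("iterative labelling equals the transitive-closure oracle on random sets", {
  set.seed(202)
  for (rep in 1:5) {
    pos <- sample(1000:1100, 40)
    b <- mk_boundaries(position = pos[1:6],
                       side = rep(c("acceptor_start", "donor_end"), 3))
    lacs <- mk_lacs(start = sample(pos, 25, replace = TRUE),
                    end = sample(pos, 25, replace = TRUE) + 200L)
    out <- iterative_label(lacs, b)
    expect_setequal(out$labels$lac_id, oracle_closure(lacs, b))
  }
})

test_that("label assignment is independent of LAC input order", {
  set.seed(303)
  b <- mk_boundaries(position = c(100L, 250L, 400L),
                     side = c("acceptor_start", "donor_end",
                              "acceptor_start"))
  lacs <- mk_lacs(start = c(100L, 180L, 180L, 400L, 800L),
                  end = c(250L, 250L, 320L, 900L, 900L))
  ref <- iterative_label(lacs, b)$labels
  for (i in 1:5) {
    perm <- lacs[sample.int(nrow(lacs)), ]
    out <- iterative_label(perm, b)$labels
    expect_equal(out[order(out$lac_id), c("lac_id", "mode", "round")],
                 ref[order(ref$lac_id), c("lac_id", "mode", "round")],
                 ignore_attr = TRUE)
  }
})

test_that("the cascade prioritizes earlier exon lists and skips empty ones", {
  e1 <- data.frame(chrom = "c1", strand = "+", start = 100L, end = 200L,
                   gene_id = "a", transcript_id = "a.t", biotype = "coding",
                   list_id = 1L, stringsAsFactors = FALSE)
  e2 <- transform(e1, gene_id = "b", biotype = "lnc", list_id = 2L)
  e3 <- transform(e1, start = 700L, end = 900L, gene_id = "c",
                  biotype = "novel", list_id = 3L)
  lacs <- mk_lacs(start = c(100L, 700L), end = c(200L, 900L))
  ## LAC matching both list 1 and list 2 exons gets list 1
  lab <- cascade_label(lacs, dedup_exon_lists(rbind(e1, e2, e3)))
  expect_equal(lab$list_id[lab$lac_id == "L001"], 1L)
  expect_equal(lab$list_id[lab$lac_id == "L002"], 3L)
  ## dropping list 2 changes nothing here
  lab13 <- cascade_label(lacs, rbind(e1, e3))
  expect_equal(lab13[order(lab13$lac_id), c("lac_id", "list_id")],
               lab[order(lab$lac_id), c("lac_id", "list_id")],
               ignore_attr = TRUE)
})

test_that("per-list label counts on the simulator match the planted truth", {
  sim <- small_sim(noise = FALSE)
  res <- run_small_pipeline(noise = FALSE)
  truth_ex <- sim$truth[sim$truth$class == "exonic", ]
  expect_equal(nrow(res$exonic_labels), nrow(truth_ex))
  ## list assignment follows the gene the circle was planted on
  lab_list <- table(res$exonic_labels$list_id)
  want_list <- table(sim$ann$genes$list_id[
    match(truth_ex$gene_id, sim$ann$genes$gene_id)])
  expect_equal(as.vector(lab_list), as.vector(want_list))
  ## planted chain circles are found in successive rounds
  chain <- truth_ex[grepl("chain", truth_ex$exonic_mode), ]
  lk <- coord_key(res$retained$chrom, res$retained$strand,
                  res$retained$start, res$retained$end)
  ids <- res$retained$lac_id[match(coord_key(chain$chrom, chain$strand,
                                             chain$start, chain$end), lk)]
  rounds <- res$exonic_labels$round[match(ids, res$exonic_labels$lac_id)]
  expect_equal(sort(unique(rounds[chain$exonic_mode == "chain_a"])), 1L)
  expect_equal(sort(unique(rounds[chain$exonic_mode == "chain_b"])), 2L)
  expect_equal(sort(unique(rounds[chain$exonic_mode == "chain_c"])), 3L)
})

test_that("labelling past the round cap is an error, converged runs are not", {
  b <- mk_boundaries(position = 100L, side = "acceptor_start")
  chain <- mk_lacs(start = c(100L, 340L), end = c(500L, 500L))
  expect_silent(iterative_label(chain, b, max_rounds = 20))
  expect_error(iterative_label(chain, b, max_rounds = 1), "converge")
  ## a convergent run is fine even when its final empty round is past the cap
  single <- mk_lacs(100L, 500L)
  expect_silent(iterative_label(single, b, max_rounds = 1))
})
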