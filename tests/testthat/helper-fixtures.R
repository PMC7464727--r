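## Shared fixtures and independent oracles for the test suite.
## Oracles are deliberately naive (loops, enumeration) and never call the
## code paths they check.

.sim_cache <- new.env(parent = emptyenv())

## Reduced-size simulation shared across test files (memoised).
small_sim <- function(noise = FALSE, seed = 42) {
  key <- paste0("sim_", noise, "_", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- sim_config(
    seed = seed,
    n_coding = 10, n_lnc = 3, n_other_nc = 2, n_novel = 2, n_mono = 5,
    n_exonic = 24, n_lariat = 10, n_circle = 3, n_subexonic = 10,
    exonic_novel = 4, exonic_chains = 1,
    reads_per_circle = c(6, 15), n_decoys = 10, n_ambiguous = 2,
    duplicate_rate = if (noise) 0.3 else 0,
    microhomology_max = if (noise) 3 else 0,
    mismatch_rate = if (noise) 0.2 else 0,
    mate1_dropout = if (noise) 0.5 else 0
  )
  dir <- file.path(tempdir(), key)
  sim <- simulate_ccr_dataset(cfg, dir)
  sim$cfg <- cfg
  .sim_cache[[key]] <- sim
  sim
}

pipeline_config <- function(sim, ...) {
  c(sim$paths[c("chimeric", "gtf", "lnc_bed", "novel_bed", "genome_fa",
                "sam", "sj")], list(...))
}

run_small_pipeline <- function(noise = FALSE, seed = 42) {
  key <- paste0("res_", noise, "_", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- small_sim(noise, seed)
  res <- suppressMessages(run_pipeline(pipeline_config(sim)))
  .sim_cache[[key]] <- res
  res
}

coord_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end)
}

## map each truth circle to its retained LAC's assigned class (NA if the
## exact-coordinate LAC was not retained)
truth_classes <- function(sim, res) {
  tk <- coord_key(sim$truth$chrom, sim$truth$strand, sim$truth$start,
                  sim$truth$end)
  rk <- coord_key(res$retained$chrom, res$retained$strand,
                  res$retained$start, res$retained$end)
  cls <- setNames(res$classification$klass, res$classification$lac_id)
  unname(cls[res$retained$lac_id[match(tk, rk)]])
}

## quick builder for LAC tables
mk_lacs <- function(start, end, chrom = "c1", strand = "+",
                    ccr = 10L, distinct = ccr) {
  n <- length(start)
  data.frame(lac_id = sprintf("L%03d", seq_len(n)),
             chrom = rep_len(chrom, n), strand = rep_len(strand, n),
             start = as.integer(start), end = as.integer(end),
             size = as.integer(end - start + 1L),
             ccr_count = as.integer(rep_len(ccr, n)),
             distinct_ccr_count = as.integer(rep_len(distinct, n)),
             stringsAsFactors = FALSE)
}

mk_boundaries <- function(position, side, chrom = "c1", strand = "+",
                          list_id = 1L, gene_id = "g1") {
  data.frame(chrom = rep_len(chrom, length(position)),
             strand = rep_len(strand, length(position)),
             position = as.integer(position), side = side,
             origin = "known", list_id = list_id,
             gene_id = rep_len(gene_id, length(position)),
             stringsAsFactors = FALSE)
}

## one well-formed chimeric-junction line
chim_line <- function(chrom_d = "c1", bp_d = 2001L, st_d = "+",
                      chrom_a = "c1", bp_a = 999L, st_a = "+",
                      code = 0L, rl = 0L, rr = 0L, name = "r1/1",
                      s1 = 1941L, c1 = "60M40S", s2 = 1000L,
                      c2 = "60S40M") {
  paste(chrom_d, bp_d, st_d, chrom_a, bp_a, st_a, code, rl, rr, name,
        s1, c1, s2, c2, sep = "\t")
}

## ---- oracles --------------------------------------------------------

## brute-force transitive closure of the iterative labelling reachability:
## repeatedly scan one LAC at a time, labelling it when either boundary is
## a known boundary or a previously promoted novel boundary (side-typed),
## until nothing changes; returns the set of labelled lac_ids
oracle_closure <- function(lacs, boundaries) {
  known <- boundaries[boundaries$origin == "known", , drop = FALSE]
  starts <- paste(known$chrom, known$strand,
                  known$position)[known$side == "acceptor_start"]
  ends <- paste(known$chrom, known$strand,
                known$position)[known$side == "donor_end"]
  labelled <- rep(FALSE, nrow(lacs))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(lacs))) {
      if (labelled[i]) next
      sk <- paste(lacs$chrom[i], lacs$strand[i], lacs$start[i])
      ek <- paste(lacs$chrom[i], lacs$strand[i], lacs$end[i])
      s_hit <- sk %in% starts
      e_hit <- ek %in% ends
      if (s_hit || e_hit) {
        labelled[i] <- TRUE
        changed <- TRUE
        if (!s_hit) starts <- c(starts, sk)
        if (!e_hit) ends <- c(ends, ek)
      }
    }
    if (!changed) break
  }
  lacs$lac_id[labelled]
}

## naive single-linkage connected components over strict interval overlap
oracle_components <- function(start, end) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            start[i] <= end[j] && start[j] <= end[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

## brute-force: do two circle coordinate pairs describe the same circular
## molecule? Compares the full circle sequence of B with the rotation of
## A's circle sequence by the coordinate offset.
oracle_same_circle <- function(genome, chrom, startA, endA, startB, endB) {
  g <- as.character(genome[[chrom]])
  if (endA - startA != endB - startB) return(FALSE)
  circA <- substr(g, startA, endA)
  circB <- substr(g, startB, endB)
  s <- startB - startA
  size <- nchar(circA)
  if (abs(s) >= size) return(FALSE)
  rot <- function(x, k) {
    k <- ((k %% nchar(x)) + nchar(x)) %% nchar(x)
    if (k == 0) return(x)
    paste0(substr(x, k + 1, nchar(x)), substr(x, 1, k))
  }
  circB == rot(circA, s)
}

## small genome with a planted junction microhomology of exact length m
## around the circle [start, end]
plant_test_genome <- function(start, end, m, len = 3000, seed = 1,
                              chrom = "tg1") {
  set.seed(seed)
  g <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (i in seq_len(m)) g[end + i] <- g[start + i - 1]
  if (g[end + m + 1] == g[start + m]) {
    g[end + m + 1] <- setdiff(c("A", "C", "G", "T"), g[start + m])[1]
  }
  if (g[start - 1] == g[end]) {
    g[start - 1] <- setdiff(c("A", "C", "G", "T"), g[end])[1]
  }
  gen <- Biostrings::DNAStringSet(paste(g, collapse = ""))
  names(gen) <- chrom
  gen
}

## construct junction-table rows for reads of a circle, following the
## breakpoint and segment conventions of the chimeric dialect
mk_circle_reads <- function(genome, chrom, strand, start, end, shifts,
                            splits, L = 100L, snp_at = NA, snp_reads = c()) {
  g <- as.character(genome[[chrom]])
  size <- end - start + 1L
  rows <- list()
  for (i in seq_along(shifts)) {
    s <- shifts[i]; a <- splits[i]; b <- L - a
    if (strand == "+") {
      seq <- paste0(substr(g, end - a + 1L, end),
                    substr(g, start, start + b - 1L))
      seg1_start <- end - a + 1L
      seg1_cigar <- sprintf("%dM%dS", a + s, b - s)
    } else {
      rc <- function(x) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x)))
      seq <- paste0(rc(substr(g, start, start + a - 1L)),
                    rc(substr(g, end - b + 1L, end)))
      seg1_start <- start + s
      seg1_cigar <- sprintf("%dM%dS", a - s, b + s)
    }
    if (i %in% snp_reads && !is.na(snp_at)) {
      ## plant an internal difference at a fixed transcript offset from
      ## the junction (negative = upstream of it)
      pos <- a + snp_at
      substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(seq, pos, pos))[1]
    }
    rows[[i]] <- data.frame(
      chrom = chrom, strand = strand,
      start = start + s, end = end + s, size = size,
      read_id = sprintf("m%03d", i), read_name = sprintf("m%03d/1", i),
      mate = 1L, fingerprint = sprintf("fp%03d", i), junction_code = 0L,
      seg1_start = seg1_start, seg1_cigar = seg1_cigar,
      seg2_start = 0L, seg2_cigar = "NA", read_seq = seq,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
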