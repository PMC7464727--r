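## Synthetic-data module: a toy genome, annotation, and chimeric read-level
## evidence with a truth table, carrying the statistical structure the
## classification pipeline assumes (planted circles of all four classes,
## PCR duplicates, junction microhomology causing alignment shifts,
## reverse-transcriptase mismatches near lariat junctions, a mate-specific
## read deficit, linear split reads). Everything is generated from a seeded
## configuration so the whole pipeline is testable without downloads.

#' Simulation configuration
#'
#' Builds the configuration list that drives the generator. The defaults
#' describe the emulated dataset: a mix of 100 and 125 nt reads at 1:3,
#' a 30\% PCR duplicate rate, junction microhomologies of 0-3 nt, a 20\%
#' near-junction mismatch rate on lariat-derived reads, a 50\% dropout of
#' mate-1 reads (GC-deficit mimic), and roughly 200 planted circles of
#' mixed classes supported by 8-40 reads each.
#'
#' @param seed integer RNG seed (derived sub-seeds stay below 2^31).
#' @param chroms chromosome names.
#' @param n_coding,coding_exons coding multi-exonic genes and exons each.
#' @param n_lnc lncRNA genes (exons emitted only on exon list 2).
#' @param n_other_nc other non-coding multi-exonic genes (exon list 1).
#' @param n_novel genes whose exons appear only on the novel list (3).
#' @param n_mono mono-exonic non-coding genes.
#' @param exon_len,intron_len,mono_len,intergenic length ranges (nt).
#' @param n_exonic,n_lariat,n_circle,n_subexonic planted circles per class.
#' @param exonic_novel number of exonic circles with one undescribed
#'   boundary; \code{exonic_chains} chains of 3 circles linked through
#'   shared undescribed boundaries (both drawn from \code{n_exonic}).
#' @param reads_per_circle range of junction-spanning reads per circle.
#' @param read_len_probs named probabilities of read lengths.
#' @param duplicate_rate probability a read gets a PCR duplicate copy.
#' @param microhomology_max maximal planted junction microhomology (nt);
#'   per circle the length is drawn uniformly from 0..max.
#' @param mismatch_rate probability a lariat-derived read carries a
#'   mismatch within 5 nt of the junction.
#' @param mate1_dropout probability a mate-1 read is dropped.
#' @param linear_depth unique split-read depth per linear exon junction.
#' @param n_decoys non-circular chimeric decoy records.
#' @param n_ambiguous reads emitted twice (ambiguous chimeras, to be
#'   dropped by the selection rule).
#' @return configuration list (class \code{sim_config}).
#' @export
sim_config <- function(seed = 1,
                       chroms = c("sim1", "sim2"),
                       n_coding = 26, coding_exons = 4,
                       n_lnc = 6, n_other_nc = 4, n_novel = 4, n_mono = 8,
                       exon_len = c(120, 300), intron_len = c(250, 900),
                       mono_len = c(100, 600), intergenic = c(300, 1000),
                       n_exonic = 120, n_lariat = 40, n_circle = 8,
                       n_subexonic = 32,
                       exonic_novel = 10, exonic_chains = 2,
                       reads_per_circle = c(8, 40),
                       read_len_probs = c("100" = 0.25, "125" = 0.75),
                       duplicate_rate = 0.3,
                       microhomology_max = 3,
                       mismatch_rate = 0.2,
                       mate1_dropout = 0.5,
                       linear_depth = 30,
                       n_decoys = 50, n_ambiguous = 4) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed), cfg$seed < 2^31 - 3,
            all(c(duplicate_rate, mismatch_rate, mate1_dropout) >= 0),
            all(c(duplicate_rate, mismatch_rate, mate1_dropout) <= 1))
  class(cfg) <- c("sim_config", "list")
  cfg
}

.runif_int <- function(n, range) {
  if (range[1] >= range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Build the synthetic genome and annotation
#'
#' Lays out non-overlapping genes along the configured chromosomes with
#' random strands and intergenic spacing, then draws a random genome long
#' enough to hold them. Coding and other multi-exonic non-coding genes
#' plus mono-exonic genes form exon list 1 (the reference annotation);
#' lncRNA genes form list 2 and novel genes list 3 (emitted as BED).
#'
#' @param cfg configuration from [sim_config()].
#' @return list: \code{genome} (\code{DNAStringSet}), \code{exons}
#'   (all lists, with \code{list_id} and \code{biotype}), \code{genes}
#'   (gene table with \code{gene_class}).
#' @export
build_genome_and_annotation <- function(cfg) {
  set.seed(cfg$seed)
  specs <- list()
  add_gene <- function(class, biotype, list_id, n, n_exons) {
    for (i in seq_len(n)) {
      specs[[length(specs) + 1L]] <<- list(class = class, biotype = biotype,
                                           list_id = list_id,
                                           n_exons = n_exons)
    }
  }
  add_gene("coding", "coding", 1L, cfg$n_coding, cfg$coding_exons)
  add_gene("other_nc", "other_nc", 1L, cfg$n_other_nc, 3L)
  add_gene("mono", "other_nc", 1L, cfg$n_mono, 1L)
  add_gene("lnc", "lnc", 2L, cfg$n_lnc, 3L)
  add_gene("novel", "novel", 3L, cfg$n_novel, 3L)

  n_genes <- length(specs)
  chrom_of <- if (n_genes > 0L)
    sort(rep_len(cfg$chroms, n_genes)) else character(0)
  exon_rows <- list()
  gene_rows <- list()
  cursor <- setNames(rep(1000L, length(cfg$chroms)), cfg$chroms)
  counter <- 0L
  for (i in seq_len(n_genes)) {
    sp <- specs[[i]]
    counter <- counter + 1L
    gid <- sprintf("G%s%03d", toupper(substr(sp$class, 1, 2)), counter)
    chrom <- chrom_of[i]
    strand <- sample(c("+", "-"), 1)
    pos <- cursor[[chrom]] + .runif_int(1, cfg$intergenic)
    if (sp$n_exons == 1L) {
      lens <- .runif_int(1, cfg$mono_len)
      starts <- pos
      ends <- pos + lens - 1L
    } else {
      lens <- .runif_int(sp$n_exons, cfg$exon_len)
      gaps <- .runif_int(sp$n_exons - 1L, cfg$intron_len)
      starts <- pos + cumsum(c(0L, lens[-sp$n_exons] + gaps))
      ends <- starts + lens - 1L
    }
    cursor[[chrom]] <- ends[sp$n_exons]
    exon_rows[[i]] <- data.frame(
      chrom = chrom, strand = strand, start = starts, end = ends,
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      biotype = sp$biotype, list_id = sp$list_id, stringsAsFactors = FALSE)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, gene_class = sp$class, chrom = chrom, strand = strand,
      start = starts[1], end = ends[sp$n_exons], n_exons = sp$n_exons,
      biotype = sp$biotype, list_id = sp$list_id, stringsAsFactors = FALSE)
  }
  genome_len <- pmax(cursor + 1000L, 2000L)
  genome <- Biostrings::DNAStringSet(vapply(cfg$chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), genome_len[[ch]], replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- cfg$chroms
  exons <- if (length(exon_rows)) do.call(rbind, exon_rows) else .empty_exons()
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(), gene_class = character(),
               chrom = character(), strand = character(), start = integer(),
               end = integer(), n_exons = integer(), biotype = character(),
               list_id = integer(), stringsAsFactors = FALSE)
  rownames(exons) <- rownames(genes) <- NULL
  list(genome = genome, exons = exons, genes = genes)
}

## genome editing helpers: enforce (or forbid) junction microhomology
.set_base <- function(genome, chrom, pos, base) {
  Biostrings::subseq(genome[[chrom]], pos, pos) <- Biostrings::DNAString(base)
  genome
}
.other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

#' Plant circles of all four classes
#'
#' Draws circle coordinates compatible with each class definition:
#' exonic circles on exon boundary pairs of multi-exonic genes (a
#' configured number with one or two undescribed boundaries, forming
#' labelling chains), lariat circles from the 5' first intron base to a
#' branch-like position 15-60 nt upstream of the intron 3' end, intron
#' circles as full introns, and sub-exonic circles strictly inside
#' mono-exonic exons (>= 55 nt). The genome is edited so each circle
#' carries exactly its drawn junction microhomology (and no accidental
#' extra homology), which later causes alignment-shifted LACs.
#'
#' @param cfg configuration.
#' @param ann output of [build_genome_and_annotation()].
#' @return list: \code{truth} (one row per circle: \code{circle_id},
#'   \code{class}, coordinates, \code{gene_id}, \code{gene_class},
#'   \code{size}, \code{mh_len}, \code{exonic_mode}), \code{genome}
#'   (edited \code{DNAStringSet}).
#' @export
plant_circles <- function(cfg, ann) {
  set.seed(cfg$seed + 1L)
  genome <- ann$genome
  exons <- ann$exons
  genes <- ann$genes
  used_coord <- character(0)   # circle coordinate keys
  locked <- character(0)       # genome positions other circles rely on
  truth <- list()

  ## A circle's junction structure depends on the bases at
  ## start-1..start+m and end..end+m+1; those positions are locked so a
  ## later circle cannot edit them. Mandatory homology edits hitting a
  ## locked position abort the planting (caller resamples); optional
  ## anti-homology edits are simply skipped there.
  try_plant <- function(class, chrom, strand, start, end, gene_id,
                        gene_class, mode = NA_character_, m_force = NULL) {
    m <- if (is.null(m_force)) .runif_int(1, c(0L, cfg$microhomology_max))
    else m_force
    key <- .coord_key(chrom, strand, start, end)
    if (key %in% used_coord) return(FALSE)
    mandatory <- if (m > 0L) paste(chrom, end + seq_len(m)) else character(0)
    if (any(mandatory %in% locked)) return(FALSE)
    ## plant microhomology of exactly m: g[end+i] == g[start+i-1] for
    ## i in 1..m, then break homology just beyond and just before
    for (i in seq_len(m)) {
      b <- .genome_sub(genome, chrom, start + i - 1L, start + i - 1L)
      genome <<- .set_base(genome, chrom, end + i, b)
    }
    bs <- .genome_sub(genome, chrom, start + m, start + m)
    if (.genome_sub(genome, chrom, end + m + 1L, end + m + 1L) == bs &&
        !(paste(chrom, end + m + 1L) %in% locked)) {
      genome <<- .set_base(genome, chrom, end + m + 1L, .other_base(bs))
    }
    bl <- .genome_sub(genome, chrom, end, end)
    if (.genome_sub(genome, chrom, start - 1L, start - 1L) == bl &&
        !(paste(chrom, start - 1L) %in% locked)) {
      genome <<- .set_base(genome, chrom, start - 1L, .other_base(bl))
    }
    used_coord <<- c(used_coord, key)
    locked <<- c(locked, paste(chrom, c((start - 1L):(start + m),
                                        end:(end + m + 1L))))
    truth[[length(truth) + 1L]] <<- data.frame(
      circle_id = sprintf("circ%03d", length(truth) + 1L),
      class = class, chrom = chrom, strand = strand,
      start = start, end = end, size = end - start + 1L,
      gene_id = gene_id, gene_class = gene_class, mh_len = m,
      exonic_mode = mode, stringsAsFactors = FALSE)
    TRUE
  }

  multi <- genes[genes$n_exons > 1L, , drop = FALSE]
  coding <- multi[multi$gene_class == "coding", , drop = FALSE]
  ## partition coding genes: introns-planting genes vs exonic-planting genes
  n_intron_genes <- ceiling((cfg$n_lariat + cfg$n_circle) /
                              max(1L, cfg$coding_exons - 1L))
  n_intron_genes <- min(n_intron_genes, nrow(coding))
  intron_genes <- coding$gene_id[seq_len(n_intron_genes)]
  exonic_coding <- coding[!(coding$gene_id %in% intron_genes), ,
                          drop = FALSE]

  gene_exons <- function(gid) {
    e <- exons[exons$gene_id == gid, , drop = FALSE]
    e[order(e$start), , drop = FALSE]
  }

  ## --- exonic circles ------------------------------------------------
  exonic_pool <- rbind(exonic_coding,
                       multi[multi$gene_class %in%
                               c("other_nc", "lnc", "novel"), , drop = FALSE])
  n_plain <- cfg$n_exonic - cfg$exonic_novel - 3L * cfg$exonic_chains
  stopifnot(n_plain >= 0)
  ## known-boundary circles: cycle through genes and exon pairs
  pairs <- do.call(rbind, lapply(seq_len(nrow(exonic_pool)), function(i) {
    g <- exonic_pool[i, ]
    e <- gene_exons(g$gene_id)
    p <- expand.grid(a = seq_len(nrow(e)), b = seq_len(nrow(e)))
    p <- p[p$a <= p$b, , drop = FALSE]
    data.frame(gene = g$gene_id, gene_class = g$gene_class,
               chrom = g$chrom, strand = g$strand,
               start = e$start[p$a], end = e$end[p$b],
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  planted <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (planted >= n_plain) break
    p <- pairs[i, ]
    if (try_plant("exonic", p$chrom, p$strand, p$start, p$end, p$gene,
                  p$gene_class, mode = "known_both")) planted <- planted + 1L
  }
  if (planted < n_plain) .stopf("could not place %d exonic circles", n_plain)

  ## exonic circles with one undescribed boundary: known exon start to a
  ## random intronic position of the same gene
  free_pos <- function(g, e) {
    ## a position inside the gene body, away from annotated boundaries
    for (attempt in 1:50) {
      j <- sample(nrow(e) - 1L, 1)
      lo <- e$end[j] + 20L
      hi <- e$start[j + 1L] - 20L
      if (hi <= lo) next
      pos <- .runif_int(1, c(lo, hi))
      return(pos)
    }
    NA_integer_
  }
  planted <- 0L
  guard <- 0L
  while (planted < cfg$exonic_novel && guard < 500L) {
    guard <- guard + 1L
    g <- exonic_pool[sample.int(nrow(exonic_pool), 1), ]
    e <- gene_exons(g$gene_id)
    pos <- free_pos(g, e)
    if (is.na(pos)) next
    start <- e$start[1]
    if (pos <= start + 60L) next
    if (try_plant("exonic", g$chrom, g$strand, start, pos, g$gene_id,
                  g$gene_class, mode = "one_novel")) planted <- planted + 1L
  }
  if (planted < cfg$exonic_novel) .stopf("could not place novel-boundary circles")

  ## chains of three circles sharing undescribed boundaries:
  ## A = [e1.start, X], B = [Y, X], C = [Y, Z] with X, Y, Z undescribed
  planted <- 0L
  guard <- 0L
  while (planted < cfg$exonic_chains && guard < 500L) {
    guard <- guard + 1L
    g <- exonic_pool[sample.int(nrow(exonic_pool), 1), ]
    e <- gene_exons(g$gene_id)
    x <- free_pos(g, e); y <- free_pos(g, e); z <- free_pos(g, e)
    if (anyNA(c(x, y, z))) next
    s1 <- e$start[1]
    if (!(s1 + 60L < y && y + 60L < x && y + 60L < z)) next
    if (length(unique(c(x, y, z))) < 3L) next
    ## plant atomically: all three coordinate pairs must be free
    keys <- c(.coord_key(g$chrom, g$strand, s1, x),
              .coord_key(g$chrom, g$strand, y, x),
              .coord_key(g$chrom, g$strand, y, z))
    if (any(keys %in% used_coord) || anyDuplicated(keys)) next
    okA <- try_plant("exonic", g$chrom, g$strand, s1, x, g$gene_id,
                     g$gene_class, mode = "chain_a", m_force = 0L)
    okB <- try_plant("exonic", g$chrom, g$strand, y, x, g$gene_id,
                     g$gene_class, mode = "chain_b", m_force = 0L)
    okC <- try_plant("exonic", g$chrom, g$strand, y, z, g$gene_id,
                     g$gene_class, mode = "chain_c", m_force = 0L)
    if (!(okA && okB && okC)) .stopf("chain planting failed unexpectedly")
    planted <- planted + 1L
  }
  if (planted < cfg$exonic_chains) .stopf("could not place labelling chains")

  ## --- intron-derived circles ----------------------------------------
  introns <- derive_introns(exons[exons$gene_id %in% intron_genes, ,
                                  drop = FALSE])
  if (cfg$n_lariat + cfg$n_circle > nrow(introns)) {
    .stopf("not enough introns (%d) for %d intron-derived circles",
           nrow(introns), cfg$n_lariat + cfg$n_circle)
  }
  idx <- sample.int(nrow(introns))
  lariat_idx <- idx[seq_len(cfg$n_lariat)]
  circle_idx <- idx[cfg$n_lariat + seq_len(cfg$n_circle)]
  for (i in lariat_idx) {
    intr <- introns[i, ]
    tail <- .runif_int(1, c(15L, 60L))  # branch point 15-60 nt from 3' end
    if (intr$strand == "+") {
      start <- intr$start; end <- intr$end - tail
    } else {
      start <- intr$start + tail; end <- intr$end
    }
    if (!try_plant("lariat_intronic", intr$chrom, intr$strand, start, end,
                   intr$gene_id, "coding")) {
      .stopf("could not place lariat circle in intron %d", i)
    }
  }
  for (i in circle_idx) {
    intr <- introns[i, ]
    if (!try_plant("intron_circle", intr$chrom, intr$strand, intr$start,
                   intr$end, intr$gene_id, "coding")) {
      .stopf("could not place intron circle in intron %d", i)
    }
  }

  ## --- sub-exonic circles --------------------------------------------
  mono <- genes[genes$gene_class == "mono", , drop = FALSE]
  planted <- 0L
  guard <- 0L
  while (planted < cfg$n_subexonic && guard < 2000L) {
    guard <- guard + 1L
    g <- mono[sample.int(nrow(mono), 1), ]
    elen <- g$end - g$start + 1L
    max_size <- min(elen - 2L, 350L)
    if (max_size < 55L) next
    size <- .runif_int(1, c(55L, max_size))
    ## strictly inside the exon: neither boundary touches an annotated
    ## exon boundary (a boundary-touching locus belongs to the exonic
    ## cascade, not here)
    start <- .runif_int(1, c(g$start + 1L, g$end - size))
    end <- start + size - 1L
    if (try_plant("sub_exonic", g$chrom, g$strand, start, end, g$gene_id,
                  "mono")) planted <- planted + 1L
  }
  if (planted < cfg$n_subexonic) .stopf("could not place sub-exonic circles")

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(truth = truth, genome = genome)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Emit synthetic read-level evidence
#'
#' For each planted circle, emits junction-spanning reads as two-segment
#' chimeric-junction records obeying the breakpoint convention (each
#' breakpoint names the first excluded base beyond its segment), with PCR
#' duplicates, microhomology-induced alignment shifts of the reported
#' coordinates, near-junction mismatches on lariat-derived reads, and a
#' mate-1 read deficit. Linear split reads over the exon junctions of
#' coding genes are emitted as an SJ-style table. Decoy chimeric records
#' (non-circular geometry) and ambiguous duplicated read names exercise
#' the selection rules.
#'
#' @param truth truth table from [plant_circles()].
#' @param cfg configuration.
#' @param ann annotation list (for the SJ table and decoy placement).
#' @param genome edited genome from [plant_circles()].
#' @return list: \code{chimeric} (14-column data frame), \code{sam}
#'   (character vector of SAM lines), \code{sj} (SJ table),
#'   \code{read_truth} (per emitted read: circle, shift, mate,
#'   duplicate flag), \code{circle_stats} (per circle bookkeeping:
#'   reads emitted, duplicates, expected distinct fingerprints, expected
#'   number of LACs).
#' @export
emit_reads <- function(truth, cfg, ann, genome) {
  set.seed(cfg$seed + 2L)
  chim <- list()
  sam <- list()
  read_truth <- list()
  stats <- list()
  lens <- as.integer(names(cfg$read_len_probs))

  ctx <- 128L  # sequence context window on each side of the junction

  for (ci in seq_len(nrow(truth))) {
    tr <- truth[ci, ]
    n <- .runif_int(1, cfg$reads_per_circle)
    m <- tr$mh_len
    contiguous <- tr$class != "exonic"
    rna_cap <- if (contiguous) tr$size else Inf
    ok_lens <- lens[lens < 2L * rna_cap]
    if (length(ok_lens) == 0L) {
      .stopf("circle %s too small for any read length", tr$circle_id)
    }
    ## sequence context: part 1 of a read ends at the donor boundary,
    ## part 2 starts at the acceptor boundary; both stay within the
    ## circle because a, b <= circle size for contiguous circles
    w_end <- .genome_sub(genome, tr$chrom, tr$end - ctx + 1L, tr$end)
    w_start <- .genome_sub(genome, tr$chrom, tr$start, tr$start + ctx - 1L)

    mate <- sample(1:2, n, replace = TRUE)
    keep <- !(mate == 1L & runif(n) < cfg$mate1_dropout)
    mate <- mate[keep]
    nk <- length(mate)
    p <- cfg$read_len_probs[as.character(ok_lens)]
    L <- ok_lens[sample.int(length(ok_lens), nk, replace = TRUE, prob = p)]
    lo <- as.integer(pmax(15L + m, L - rna_cap))
    hi <- as.integer(pmin(L - 15L - m, rna_cap))
    if (any(lo > hi)) .stopf("no valid split for circle %s", tr$circle_id)
    ## distinct molecules fragment at distinct positions: draw split
    ## points without replacement per read length, so identical
    ## fingerprints arise only from PCR duplicates (or exhausted split
    ## space)
    a <- integer(nk)
    for (ul in unique(L)) {
      ii <- which(L == ul)
      rng <- seq.int(lo[ii[1]], hi[ii[1]])
      a[ii] <- rng[sample.int(length(rng), length(ii),
                              replace = length(ii) > length(rng))]
    }
    b <- L - a
    s <- if (m > 0L) as.integer(floor(runif(nk) * (m + 1L))) else
      integer(nk)
    if (tr$strand == "+") {
      seq <- paste0(substr(rep(w_end, nk), ctx - a + 1L, ctx),
                    substr(rep(w_start, nk), 1L, b))
      donor <- tr$end + s + 1L
      acceptor <- tr$start + s - 1L
      seg1_start <- tr$end - a + 1L
      seg1_cigar <- sprintf("%dM%dS", a + s, b - s)
      seg2_start <- tr$start + s
      seg2_cigar <- sprintf("%dS%dM", a + s, b - s)
    } else {
      rc_start <- .revcomp(w_start)  # revcomp of [start, start+ctx-1]
      rc_end <- .revcomp(w_end)      # revcomp of [end-ctx+1, end]
      seq <- paste0(substr(rep(rc_start, nk), ctx - a + 1L, ctx),
                    substr(rep(rc_end, nk), 1L, b))
      donor <- tr$start + s - 1L
      acceptor <- tr$end + s + 1L
      seg1_start <- tr$start + s
      seg1_cigar <- sprintf("%dM%dS", a - s, b + s)
      seg2_start <- tr$end - b + 1L
      seg2_cigar <- sprintf("%dS%dM", a - s, b + s)
    }
    if (tr$class == "lariat_intronic" && cfg$mismatch_rate > 0 && nk > 0L) {
      mut <- runif(nk) < cfg$mismatch_rate
      for (i in which(mut)) {
        pos <- .runif_int(1, c(max(1L, a[i] - 4L), min(L[i], a[i] + 5L)))
        substr(seq[i], pos, pos) <- .other_base(substr(seq[i], pos, pos))
      }
    }
    dup <- runif(nk) < cfg$duplicate_rate
    ord <- rep(seq_len(nk), 1L + dup)
    is_dup <- duplicated(ord)
    name <- sprintf("%s.r%03d%s/%d", tr$circle_id, seq_along(ord),
                    ifelse(is_dup, "d", ""), mate[ord])
    fp <- paste(seg1_start[ord], seg1_cigar[ord], seg2_start[ord],
                seg2_cigar[ord], L[ord], sep = ":")
    chim[[length(chim) + 1L]] <- data.frame(
      chrom_donor = tr$chrom, brkpt_donor = donor[ord],
      strand_donor = tr$strand, chrom_acceptor = tr$chrom,
      brkpt_acceptor = acceptor[ord], strand_acceptor = tr$strand,
      junction_code = 0L, repeat_left = m, repeat_right = m,
      read_name = name, seg1_start = seg1_start[ord],
      seg1_cigar = seg1_cigar[ord], seg2_start = seg2_start[ord],
      seg2_cigar = seg2_cigar[ord], stringsAsFactors = FALSE)
    sam[[length(sam) + 1L]] <- sprintf(
      "%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
      name, if (tr$strand == "-") 16L else 0L, tr$chrom,
      seg1_start[ord], seg1_cigar[ord], seq[ord])
    read_truth[[length(read_truth) + 1L]] <- data.frame(
      circle_id = tr$circle_id, read_name = name, mate = mate[ord],
      shift = s[ord], read_len = L[ord], split = a[ord],
      duplicate = is_dup, stringsAsFactors = FALSE)
    stats[[ci]] <- data.frame(
      circle_id = tr$circle_id, n_reads = length(ord),
      n_duplicates = sum(is_dup),
      n_distinct = length(unique(fp)),
      n_lacs = length(unique(s)), stringsAsFactors = FALSE)
  }

  ## decoys: chimeric records that are not CCRs
  genes <- ann$genes
  for (d in seq_len(cfg$n_decoys)) {
    kind <- d %% 5L
    chrom <- cfg$chroms[1]
    pos <- 1500L + 37L * d
    row <- data.frame(chrom_donor = chrom, brkpt_donor = pos + 500L,
                      strand_donor = "+", chrom_acceptor = chrom,
                      brkpt_acceptor = pos, strand_acceptor = "+",
                      junction_code = 0L, repeat_left = 0L,
                      repeat_right = 0L,
                      read_name = sprintf("decoy%03d/1", d),
                      seg1_start = pos + 440L, seg1_cigar = "60M40S",
                      seg2_start = pos + 1L, seg2_cigar = "60S40M",
                      stringsAsFactors = FALSE)
    if (kind == 0L) {                       # linear order (not inverted)
      row$brkpt_donor <- pos; row$brkpt_acceptor <- pos + 500L
    } else if (kind == 1L) {                # strand mismatch
      row$strand_acceptor <- "-"
    } else if (kind == 2L) {                # cross-chromosome
      row$chrom_acceptor <- cfg$chroms[length(cfg$chroms)]
    } else if (kind == 3L) {                # mate-encompassing junction
      row$junction_code <- -1L
    } else {                                # segment below minimum size
      row$seg1_cigar <- "14M86S"; row$seg2_cigar <- "14S86M"
    }
    chim[[length(chim) + 1L]] <- row
  }
  ## ambiguous reads: same name on two chimeric lines
  for (d in seq_len(cfg$n_ambiguous)) {
    pos <- 4000L + 53L * d
    for (rep in 1:2) {
      chim[[length(chim) + 1L]] <- data.frame(
        chrom_donor = cfg$chroms[1], brkpt_donor = pos + 300L + rep,
        strand_donor = "+", chrom_acceptor = cfg$chroms[1],
        brkpt_acceptor = pos + rep, strand_acceptor = "+",
        junction_code = 0L, repeat_left = 0L, repeat_right = 0L,
        read_name = sprintf("multi%03d/2", d),
        seg1_start = pos + 240L, seg1_cigar = "60M40S",
        seg2_start = pos + 1L, seg2_cigar = "60S40M",
        stringsAsFactors = FALSE)
    }
  }

  ## SJ-style linear split reads over coding exon-exon junctions
  coding_exons <- ann$exons[ann$exons$biotype == "coding", , drop = FALSE]
  introns <- derive_introns(coding_exons)
  sj <- if (nrow(introns) > 0L) data.frame(
    chrom = introns$chrom, start = introns$start, end = introns$end,
    strand_code = ifelse(introns$strand == "+", 1L, 2L),
    motif = 0L, annotated = 1L, unique_count = cfg$linear_depth,
    multi_count = 0L, overhang = 30L, stringsAsFactors = FALSE)
  else data.frame()

  chim <- do.call(rbind, chim)
  rownames(chim) <- NULL
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  list(chimeric = chim, sam = c(header, unlist(sam)), sj = sj,
       read_truth = do.call(rbind, read_truth),
       circle_stats = do.call(rbind, stats))
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [build_genome_and_annotation()], [plant_circles()], and
#' [emit_reads()], writing genome FASTA, annotation GTF, lncRNA and
#' novel-exon BEDs, the 14-column chimeric-junction table, a SAM with
#' read sequences, the SJ-style split-read table, and the truth table.
#' Identical configurations produce byte-identical files.
#'
#' @param cfg configuration from [sim_config()].
#' @param dir output directory (created if absent).
#' @return list: \code{paths} (named file paths), \code{truth},
#'   \code{read_truth}, \code{circle_stats}, \code{ann}, \code{genome}.
#' @export
simulate_ccr_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- build_genome_and_annotation(cfg)
  pl <- plant_circles(cfg, ann)
  ann$genome <- pl$genome
  em <- emit_reads(pl$truth, cfg, ann, pl$genome)

  paths <- list(
    genome_fa = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    lnc_bed = file.path(dir, "lnc_exons.bed"),
    novel_bed = file.path(dir, "novel_exons.bed"),
    chimeric = file.path(dir, "chimeric.junction.tsv"),
    sam = file.path(dir, "reads.sam"),
    sj = file.path(dir, "sj.tab"),
    truth = file.path(dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(pl$genome, paths$genome_fa)
  .write_gtf(ann$exons[ann$exons$list_id == 1L, , drop = FALSE], paths$gtf)
  .write_exon_bed(ann$exons[ann$exons$list_id == 2L, , drop = FALSE],
                  paths$lnc_bed)
  .write_exon_bed(ann$exons[ann$exons$list_id == 3L, , drop = FALSE],
                  paths$novel_bed)
  write.table(em$chimeric, paths$chimeric, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(em$sam, paths$sam)
  write.table(em$sj, paths$sj, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(pl$truth, paths$truth)
  list(paths = paths, truth = pl$truth, read_truth = em$read_truth,
       circle_stats = em$circle_stats, ann = ann, genome = pl$genome)
}

.biotype_to_gtf <- c(coding = "protein_coding", lnc = "lncRNA",
                     other_nc = "misc_RNA", novel = "novel")

.write_gtf <- function(exons, path) {
  if (nrow(exons) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                   exons$gene_id, exons$transcript_id,
                   .biotype_to_gtf[exons$biotype])
  lines <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, exons$start, exons$end, exons$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

.write_exon_bed <- function(exons, path) {
  bed <- data.frame(exons$chrom, exons$start - 1L, exons$end,
                    exons$gene_id, 0L, exons$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
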