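## Classification of LACs left unlabelled by the exonic cascade:
## intron circles (the full intron), lariat-derived intronic circRNAs
## (intron 5' end to near the branch point, 3' tail trimmed), and
## sub-exonic circRNAs (part of the single exon of a mono-exonic gene).
## Evaluation order is intron circle, then lariat, then sub-exonic:
## specificity decreases in that order, and a full-intron LAC must not be
## mistaken for a lariat (its tail gap of 0 is below the minimum tail).

#' Does a LAC coincide exactly with an intron?
#'
#' @param lacs LAC table.
#' @param introns intron data frame ([derive_introns()], coding genes).
#' @return logical vector along rows of \code{lacs}.
#' @export
match_intron_circle <- function(lacs, introns) {
  .coord_key(lacs$chrom, lacs$strand, lacs$start, lacs$end) %in%
    .coord_key(introns$chrom, introns$strand, introns$start, introns$end)
}

#' Match LACs to lariat-derived intronic circRNAs
#'
#' A lariat-derived circle starts at the first base of the intron (its 5'
#' end in transcript orientation: the genomic start on \code{+}, the
#' genomic end on \code{-}) and ends strictly inside the intron, the 3'
#' tail beyond the branch point having been trimmed. \code{tail_gap} is
#' the trimmed-tail length (distance from the circle's internal boundary
#' to the intron's 3' end); it must be at least \code{min_tail}, and at
#' most \code{branch_window} when a branch-point distance window is
#' enabled (\code{branch_window > 0}). No minimum circle size is applied.
#'
#' @param lacs LAC table.
#' @param introns intron data frame.
#' @param min_tail minimum trimmed tail (nt); 1 means strictly inside.
#' @param branch_window maximum trimmed tail (nt); 0 disables the bound.
#' @return data frame along rows of \code{lacs}: \code{match} (logical),
#'   \code{gene_id}, \code{intron_start}, \code{intron_end},
#'   \code{tail_gap} (NA where no match; smallest tail gap wins when a
#'   LAC anchors several transcripts' introns).
#' @export
match_lariat <- function(lacs, introns, min_tail = 1, branch_window = 0) {
  n <- nrow(lacs)
  out <- data.frame(match = logical(n),
                    gene_id = rep(NA_character_, n),
                    intron_start = rep(NA_integer_, n),
                    intron_end = rep(NA_integer_, n),
                    tail_gap = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(introns) == 0L) return(out)
  ## anchor key: the intron 5' first base
  i5 <- ifelse(introns$strand == "+", introns$start, introns$end)
  ikey <- .pos_key(introns$chrom, introns$strand, i5)
  l5 <- ifelse(lacs$strand == "+", lacs$start, lacs$end)
  lkey <- .pos_key(lacs$chrom, lacs$strand, l5)
  for (i in seq_len(n)) {
    cand <- which(ikey == lkey[i])
    if (length(cand) == 0L) next
    if (lacs$strand[i] == "+") {
      gap <- introns$end[cand] - lacs$end[i]
      inside <- lacs$end[i] >= introns$start[cand]
    } else {
      gap <- lacs$start[i] - introns$start[cand]
      inside <- lacs$start[i] <= introns$end[cand]
    }
    ok <- inside & gap >= min_tail &
      (branch_window <= 0 | gap <= branch_window)
    if (!any(ok)) next
    best <- cand[ok][which.min(gap[ok])]
    out$match[i] <- TRUE
    out$gene_id[i] <- introns$gene_id[best]
    out$intron_start[i] <- introns$start[best]
    out$intron_end[i] <- introns$end[best]
    out$tail_gap[i] <- min(gap[ok])
  }
  out
}

#' Match LACs to sub-exonic circRNAs
#'
#' A sub-exonic circRNA lies with both boundaries inside the single exon
#' of a mono-exonic gene (same strand) without being the full exon (a
#' LAC equal to the exon is a mono-exonic exonic circRNA and belongs to
#' the exonic cascade). Because the chimeric mapping of a read requires
#' two segments, very small loci are unreliable and LACs under
#' \code{min_size} are not retained; LACs above \code{confident_size} are
#' flagged as the confident subset.
#'
#' @param lacs LAC table.
#' @param mono_exons exon data frame restricted to mono-exonic genes.
#' @param min_size minimum LAC size (nt) to retain.
#' @param confident_size size (nt) strictly above which a match is
#'   flagged confident.
#' @return data frame along rows of \code{lacs}: \code{match},
#'   \code{gene_id}, \code{confident}.
#' @export
match_subexonic <- function(lacs, mono_exons, min_size = 55,
                            confident_size = 70) {
  n <- nrow(lacs)
  out <- data.frame(match = logical(n),
                    gene_id = rep(NA_character_, n),
                    confident = rep(NA, n), stringsAsFactors = FALSE)
  if (n == 0L || nrow(mono_exons) == 0L) return(out)
  lac_gr <- GenomicRanges::GRanges(lacs$chrom,
                                   IRanges::IRanges(lacs$start, lacs$end),
                                   strand = lacs$strand)
  ex_gr <- GenomicRanges::GRanges(mono_exons$chrom,
                                  IRanges::IRanges(mono_exons$start,
                                                   mono_exons$end),
                                  strand = mono_exons$strand)
  hits <- GenomicRanges::findOverlaps(lac_gr, ex_gr, type = "within")
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  full <- lacs$start[qi] == mono_exons$start[si] &
    lacs$end[qi] == mono_exons$end[si]
  big <- lacs$size[qi] >= min_size
  keep <- !full & big
  qi <- qi[keep]; si <- si[keep]
  first <- !duplicated(qi)
  out$match[qi[first]] <- TRUE
  out$gene_id[qi[first]] <- mono_exons$gene_id[si[first]]
  out$confident[qi[first]] <- lacs$size[qi[first]] > confident_size
  out
}

#' Classify non-canonical LACs
#'
#' Applies the cascade intron circle, then lariat, then sub-exonic to LACs
#' left unlabelled by the exonic stage; the rest is \code{unallocated}.
#' Each LAC receives exactly one class.
#'
#' @param lacs LAC table of unlabelled loci.
#' @param introns intron data frame (coding genes only).
#' @param mono_exons exon data frame of mono-exonic genes.
#' @param min_tail,branch_window see [match_lariat()].
#' @param min_size,confident_size see [match_subexonic()].
#' @return label data frame: \code{lac_id}, \code{klass}
#'   (\code{lariat_intronic}, \code{intron_circle}, \code{sub_exonic},
#'   \code{unallocated}), \code{gene_id}, \code{intron_start},
#'   \code{intron_end}, \code{tail_gap}, \code{confident}, \code{size}.
#' @export
classify_noncanonical <- function(lacs, introns, mono_exons,
                                  min_tail = 1, branch_window = 0,
                                  min_size = 55, confident_size = 70) {
  n <- nrow(lacs)
  klass <- rep("unallocated", n)
  gene <- rep(NA_character_, n)
  istart <- rep(NA_integer_, n); iend <- rep(NA_integer_, n)
  tailg <- rep(NA_integer_, n); conf <- rep(NA, n)

  circle <- match_intron_circle(lacs, introns)
  if (any(circle)) {
    klass[circle] <- "intron_circle"
    ckey <- .coord_key(lacs$chrom, lacs$strand, lacs$start, lacs$end)
    ikey <- .coord_key(introns$chrom, introns$strand, introns$start,
                       introns$end)
    idx <- match(ckey[circle], ikey)
    gene[circle] <- introns$gene_id[idx]
    istart[circle] <- introns$start[idx]
    iend[circle] <- introns$end[idx]
  }
  todo <- !circle
  lar <- match_lariat(lacs[todo, , drop = FALSE], introns,
                      min_tail = min_tail, branch_window = branch_window)
  li <- which(todo)[lar$match]
  klass[li] <- "lariat_intronic"
  gene[li] <- lar$gene_id[lar$match]
  istart[li] <- lar$intron_start[lar$match]
  iend[li] <- lar$intron_end[lar$match]
  tailg[li] <- lar$tail_gap[lar$match]

  todo <- klass == "unallocated"
  sub <- match_subexonic(lacs[todo, , drop = FALSE], mono_exons,
                         min_size = min_size,
                         confident_size = confident_size)
  si <- which(todo)[sub$match]
  klass[si] <- "sub_exonic"
  gene[si] <- sub$gene_id[sub$match]
  conf[si] <- sub$confident[sub$match]

  data.frame(lac_id = lacs$lac_id, klass = klass, gene_id = gene,
             intron_start = istart, intron_end = iend, tail_gap = tailg,
             confident = conf, size = lacs$size, stringsAsFactors = FALSE)
}

#' Group sub-exonic LACs of a gene into overlap sets
#'
#' Partitions the sub-exonic LACs of each gene by single linkage on
#' strictly positive interval overlap: LACs sharing at least one base,
#' directly or through intermediates, form one set. Each set is
#' summarized as "count x min-max nt".
#'
#' @param lacs LAC table rows classified sub-exonic.
#' @param gene_ids gene id per row of \code{lacs}.
#' @return list with \code{sets} (per-LAC data frame: \code{lac_id},
#'   \code{gene_id}, \code{set_id}) and \code{summary} (per-set data
#'   frame: \code{set_id}, \code{gene_id}, \code{n_lacs}, \code{min_size},
#'   \code{max_size}, \code{set_spec}).
#' @export
group_sets <- function(lacs, gene_ids) {
  if (nrow(lacs) == 0L) {
    return(list(sets = data.frame(lac_id = character(),
                                  gene_id = character(),
                                  set_id = character(),
                                  stringsAsFactors = FALSE),
                summary = data.frame(set_id = character(),
                                     gene_id = character(),
                                     n_lacs = integer(),
                                     min_size = integer(),
                                     max_size = integer(),
                                     set_spec = character(),
                                     stringsAsFactors = FALSE)))
  }
  set_id <- character(nrow(lacs))
  for (g in unique(gene_ids)) {
    idx <- which(gene_ids == g)
    ir <- IRanges::IRanges(lacs$start[idx], lacs$end[idx])
    ## reduce with min.gapwidth = 0 merges only genuinely overlapping
    ## ranges, i.e. the connected components of the overlap graph
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, merged))
    set_id[idx] <- paste0(g, ".set", comp)
  }
  sets <- data.frame(lac_id = lacs$lac_id, gene_id = gene_ids,
                     set_id = set_id, stringsAsFactors = FALSE)
  per <- lapply(split(seq_len(nrow(lacs)), set_id), function(i) {
    data.frame(set_id = set_id[i[1]], gene_id = gene_ids[i[1]],
               n_lacs = length(i),
               min_size = min(lacs$size[i]), max_size = max(lacs$size[i]),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, per)
  summary$set_spec <- ifelse(
    summary$min_size == summary$max_size,
    sprintf("%d x %d nt", summary$n_lacs, summary$min_size),
    sprintf("%d x %d-%d nt", summary$n_lacs, summary$min_size,
            summary$max_size))
  rownames(summary) <- NULL
  list(sets = sets, summary = summary)
}

#' Size statistics per class
#'
#' @param labels label data frame from [classify_noncanonical()] (or any
#'   frame with \code{klass} and \code{size}).
#' @param large_cutoff size (nt) above which a circle counts as large.
#' @return list: \code{counts} (named integer per class),
#'   \code{mean_size} (named numeric per class; absent classes are
#'   dropped, never reported as 0), \code{frac_large} (fraction of
#'   lariat-derived + intron-circle sizes above \code{large_cutoff},
#'   NA when the classes are empty).
#' @export
size_stats <- function(labels, large_cutoff = 600) {
  counts <- table(labels$klass)
  mean_size <- vapply(split(labels$size, labels$klass), mean, numeric(1))
  intronic <- labels$size[labels$klass %in% c("lariat_intronic",
                                              "intron_circle")]
  list(counts = c(counts),
       mean_size = mean_size,
       frac_large = if (length(intronic)) mean(intronic > large_cutoff)
       else NA_real_)
}
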