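## Read-sequence-level refinement: junction-sequences, merging of
## alignment-shift-equivalent LACs into circularization events, a
## consistency check for circles shorter than the read, and splice-motif
## annotation.

#' Extract the junction-spanning fragment of a read
#'
#' Concatenates the last \code{min(k, available)} read bases before the
#' circular junction and the first \code{min(k, available)} bases after
#' it, in transcript orientation. The split point is the number of read
#' bases belonging to the donor-side segment (for a chimeric record, the
#' matched bases of segment 1, see [junction_split()]).
#'
#' @param read_seq read sequence (transcript orientation).
#' @param split 1-based read position of the last base before the
#'   junction; must satisfy \code{1 <= split < nchar(read_seq)}.
#' @param k context bases on each side.
#' @return list: \code{sequence} (the fragment, length <= 2k),
#'   \code{left_len}, \code{right_len}.
#' @export
extract_junction_sequence <- function(read_seq, split, k = 15) {
  len <- nchar(read_seq)
  if (is.na(split) || split < 1L || split >= len) {
    .stopf("junction not locatable in read: split %s outside 1..%d",
           as.character(split), len - 1L)
  }
  left <- substr(read_seq, max(1L, split - k + 1L), split)
  right <- substr(read_seq, split + 1L, min(len, split + k))
  list(sequence = paste0(left, right),
       left_len = nchar(left), right_len = nchar(right))
}

#' Read split position of a chimeric record
#'
#' Number of read bases matched by the first (donor-side) segment's CIGAR;
#' the circular junction sits between this base and the next.
#'
#' @param seg1_cigar CIGAR string(s) of segment 1.
#' @return integer vector.
#' @export
junction_split <- function(seg1_cigar) {
  cigar_aligned_bases(seg1_cigar)
}

.genome_sub <- function(genome, chrom, start, end) {
  if (!(chrom %in% names(genome))) {
    .stopf("genome lacks sequence %s", chrom)
  }
  len <- Biostrings::width(genome[chrom])
  if (start < 1L || end > len) {
    .stopf("region %s:%d-%d outside genome bounds (1-%d)",
           chrom, start, end, len)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Test whether two LACs are alignment-shift equivalents
#'
#' Two LACs on the same chromosome and strand whose start and end differ
#' by the same offset \code{s} (|s| <= \code{max_shift}) describe the
#' same circular junction when the junction point can slide by \code{s}:
#' the |s| genomic bases at one border must equal the |s| bases at the
#' other (microhomology of length >= |s|). Equivalently, the circular
#' sequences of the two loci are identical up to rotation.
#'
#' @param lacA,lacB lists or single-row data frames with \code{chrom},
#'   \code{strand}, \code{start}, \code{end}.
#' @param genome named \code{DNAStringSet}.
#' @param max_shift maximum junction slide considered (nt).
#' @return the integer offset (startB - startA; 0 for identical
#'   coordinates) or \code{NA} when the LACs are not shift-equivalent.
#' @export
shift_equivalent <- function(lacA, lacB, genome, max_shift = 5) {
  if (lacA$chrom != lacB$chrom || lacA$strand != lacB$strand)
    return(NA_integer_)
  s <- lacB$start - lacA$start
  if (lacB$end - lacA$end != s) return(NA_integer_)
  if (abs(s) > max_shift) return(NA_integer_)
  if (s == 0L) return(0L)
  ## orient so that `a` is the leftmost-start member
  a <- if (s > 0L) lacA else lacB
  m <- abs(s)
  left <- .genome_sub(genome, a$chrom, a$start, a$start + m - 1L)
  right <- .genome_sub(genome, a$chrom, a$end + 1L, a$end + m)
  if (left == right) as.integer(s) else NA_integer_
}

#' Merge shift-equivalent LACs into circularization events
#'
#' Single-linkage merge of LACs that are pairwise shift-equivalent
#' ([shift_equivalent()]). Within each event, the number of distinct
#' circRNAs is the number of distinct junction-sequences among the
#' event's reads after aligning them to a common junction frame using the
#' member shifts; mismatches within \code{junction_window} nt of the
#' junction are tolerated when clustering (the reverse transcriptase has
#' limited fidelity near a 2'-5' link). Events without read sequences
#' count one circRNA.
#'
#' @param lacs LAC table (classified loci to merge).
#' @param genome named \code{DNAStringSet}.
#' @param reads optional junction table ([ccr_to_junction()]) with
#'   \code{read_seq} filled, used to build junction-sequences.
#' @param max_shift maximum junction slide (nt).
#' @param k junction-sequence context per side (nt).
#' @param junction_window half-width (nt) of the near-junction zone in
#'   which mismatches are tolerated.
#' @return list with \code{events} (data frame: \code{event_id},
#'   \code{chrom}, \code{strand}, \code{start}, \code{end} of the
#'   representative = leftmost member, \code{n_lacs}, \code{member_lacs}
#'   comma-separated, \code{ccr_count}, \code{n_distinct_circRNAs},
#'   \code{support_r1}, \code{support_r2}) and \code{membership}
#'   (\code{lac_id} -> \code{event_id}).
#' @export
merge_events <- function(lacs, genome, reads = NULL, max_shift = 5, k = 15,
                         junction_window = 5) {
  n <- nrow(lacs)
  if (n == 0L) {
    return(list(events = data.frame(event_id = character(),
                                    chrom = character(), strand = character(),
                                    start = integer(), end = integer(),
                                    n_lacs = integer(),
                                    member_lacs = character(),
                                    ccr_count = integer(),
                                    n_distinct_circRNAs = integer(),
                                    support_r1 = integer(),
                                    support_r2 = integer(),
                                    stringsAsFactors = FALSE),
                membership = data.frame(lac_id = character(),
                                        event_id = character(),
                                        stringsAsFactors = FALSE)))
  }
  parent <- .uf_new(n)
  ## candidate pairs: same chrom/strand/size, starts within max_shift
  grp <- paste(lacs$chrom, lacs$strand, lacs$size, sep = "\r")
  for (g in split(seq_len(n), grp)) {
    if (length(g) < 2L) next
    g <- g[order(lacs$start[g])]
    for (i in seq_along(g)[-1]) {
      for (j in rev(seq_len(i - 1L))) {
        if (lacs$start[g[i]] - lacs$start[g[j]] > max_shift) break
        s <- shift_equivalent(lacs[g[j], ], lacs[g[i], ], genome,
                              max_shift = max_shift)
        if (!is.na(s)) parent <- .uf_union(parent, g[j], g[i])
      }
    }
  }
  comp <- .uf_components(parent)
  events <- lapply(split(seq_len(n), comp), function(idx) {
    idx <- idx[order(lacs$start[idx])]
    rep_lac <- lacs[idx[1], ]
    ev <- data.frame(chrom = rep_lac$chrom, strand = rep_lac$strand,
                     start = rep_lac$start, end = rep_lac$end,
                     n_lacs = length(idx),
                     member_lacs = paste(lacs$lac_id[idx], collapse = ","),
                     ccr_count = sum(lacs$ccr_count[idx]),
                     stringsAsFactors = FALSE)
    js <- .event_junction_sequences(lacs[idx, , drop = FALSE], reads,
                                    k = k, junction_window = junction_window)
    ev$n_distinct_circRNAs <- js$n_distinct
    ev$support_r1 <- js$support_r1
    ev$support_r2 <- js$support_r2
    ev
  })
  events <- do.call(rbind, events)
  ord <- order(events$chrom, events$strand, events$start)
  events <- events[ord, , drop = FALSE]
  events <- cbind(event_id = sprintf("EV%05d", seq_len(nrow(events))),
                  events, stringsAsFactors = FALSE)
  rownames(events) <- NULL
  membership <- data.frame(
    lac_id = unlist(strsplit(events$member_lacs, ",", fixed = TRUE)),
    event_id = rep(events$event_id,
                   lengths(strsplit(events$member_lacs, ",", fixed = TRUE))),
    stringsAsFactors = FALSE)
  list(events = events, membership = membership)
}

## Junction-sequences of one event's reads, in the representative frame.
.event_junction_sequences <- function(members, reads, k, junction_window) {
  empty <- list(n_distinct = 1L, support_r1 = 0L, support_r2 = 0L)
  if (is.null(reads)) return(empty)
  mk <- .coord_key(members$chrom, members$strand, members$start, members$end)
  rk <- .coord_key(reads$chrom, reads$strand, reads$start, reads$end)
  rr <- reads[rk %in% mk & !is.na(reads$read_seq), , drop = FALSE]
  s1 <- sum(rr$mate == 1L, na.rm = TRUE)
  s2 <- sum(rr$mate == 2L, na.rm = TRUE)
  if (nrow(rr) == 0L) return(list(n_distinct = 1L, support_r1 = 0L,
                                  support_r2 = 0L))
  rep_start <- members$start[1]
  offset <- rr$start - rep_start
  split <- junction_split(rr$seg1_cigar)
  ## bring each read's split into the representative junction frame:
  ## a LAC shifted by +s genomically has its junction s transcript bases
  ## later on '+' (earlier on '-')
  canon <- ifelse(rr$strand == "+", split - offset, split + offset)
  frags <- vector("list", nrow(rr))
  ok <- logical(nrow(rr))
  for (i in seq_len(nrow(rr))) {
    f <- tryCatch(extract_junction_sequence(rr$read_seq[i], canon[i], k = k),
                  error = function(e) NULL)
    if (!is.null(f)) { frags[[i]] <- f; ok[i] <- TRUE }
  }
  frags <- frags[ok]
  if (length(frags) == 0L) return(list(n_distinct = 1L, support_r1 = s1,
                                       support_r2 = s2))
  nf <- length(frags)
  parent <- .uf_new(nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      if (.frags_compatible(frags[[i]], frags[[j]], junction_window)) {
        parent <- .uf_union(parent, i, j)
      }
    }
  }
  list(n_distinct = max(.uf_components(parent)),
       support_r1 = s1, support_r2 = s2)
}

## Two junction fragments are the same junction-sequence when they agree
## on the overlap of their aligned contexts, except possibly within
## `window` nt of the junction point.
.frags_compatible <- function(a, b, window) {
  l <- min(a$left_len, b$left_len)
  r <- min(a$right_len, b$right_len)
  sa <- substr(a$sequence, a$left_len - l + 1L, a$left_len + r)
  sb <- substr(b$sequence, b$left_len - l + 1L, b$left_len + r)
  if (sa == sb) return(TRUE)
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  mm <- which(ca != cb)
  ## positions 1..l are left of the junction, l+1..l+r right of it
  dist <- ifelse(mm <= l, l - mm + 1L, mm - l)
  all(dist <= window)
}

#' Multi-pass consistency of a small circle
#'
#' A read at least twice as long as the circle it derives from must cross
#' the circular junction more than once; a single junction passage in
#' such a read is inconsistent with the proposed circle size.
#'
#' @param read_length read length(s), nt.
#' @param circle_size proposed circle size(s), nt.
#' @param n_passes observed junction passages in the read (default 1, the
#'   only value a two-segment chimeric record can show).
#' @return character vector: \code{"inconsistent"} or
#'   \code{"consistent"}.
#' @export
check_multipass <- function(read_length, circle_size, n_passes = 1L) {
  ifelse(read_length >= 2L * circle_size & n_passes < 2L,
         "inconsistent", "consistent")
}

#' Splice motif flanking a circular junction
#'
#' Returns the strand-oriented donor and acceptor dinucleotides flanking
#' the junction: for a back-spliced circle \code{[start, end]} on
#' \code{+}, the donor site is the two bases after \code{end} and the
#' acceptor site the two bases before \code{start}; reverse-complemented
#' and swapped on \code{-}. Canonical means GT/AG.
#'
#' @param junction list or single-row data frame with \code{chrom},
#'   \code{strand}, \code{start}, \code{end}.
#' @param genome named \code{DNAStringSet}.
#' @return list: \code{donor}, \code{acceptor}, \code{motif}
#'   ("donor/acceptor"), \code{canonical}.
#' @export
splice_motif <- function(junction, genome) {
  after <- .genome_sub(genome, junction$chrom, junction$end + 1L,
                       junction$end + 2L)
  before <- .genome_sub(genome, junction$chrom, junction$start - 2L,
                        junction$start - 1L)
  if (junction$strand == "+") {
    donor <- after
    acceptor <- before
  } else {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    donor <- rc(before)
    acceptor <- rc(after)
  }
  list(donor = donor, acceptor = acceptor,
       motif = paste(donor, acceptor, sep = "/"),
       canonical = donor == "GT" && acceptor == "AG")
}
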