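## Parsing of aligner chimeric-junction records and selection of circular
## chimeric reads (CCRs).
##
## The input dialect is the headerless 14-column tab-separated table written
## by splice-aware aligners for chimeric alignments: donor chrom, donor
## breakpoint, donor strand, acceptor chrom, acceptor breakpoint, acceptor
## strand, junction code, left repeat, right repeat, read name, segment-1
## first base, segment-1 CIGAR, segment-2 first base, segment-2 CIGAR.
## '#'-prefixed lines and extra trailing columns are tolerated.

.chimeric_cols <- c("chrom_donor", "brkpt_donor", "strand_donor",
                    "chrom_acceptor", "brkpt_acceptor", "strand_acceptor",
                    "junction_code", "repeat_left", "repeat_right",
                    "read_name", "seg1_start", "seg1_cigar",
                    "seg2_start", "seg2_cigar")

#' Parse a chimeric-junction file
#'
#' Reads the 14-column tab-separated chimeric-junction dialect into a
#' data frame of chimeric records, one row per line. Comment lines starting
#' with \code{#} are skipped and columns beyond the 14th are ignored.
#' The mate (1/2) is recovered from a \code{/1} or \code{/2} read-name
#' suffix when present; \code{read_id} is the name with the suffix removed.
#'
#' @param path path to the chimeric-junction file.
#' @return data frame of chimeric records with columns
#'   \code{read_id}, \code{read_name}, \code{mate} (integer or NA),
#'   the 14 dialect fields, and \code{read_seq} (NA until sequences are
#'   attached from a SAM file).
#' @seealso [attach_read_sequences()], [is_ccr()], [ccr_to_junction()]
#' @export
parse_chimeric_junctions <- function(path) {
  if (!file.exists(path)) .stopf("chimeric-junction file not found: %s", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(.empty_chimeric())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 14L)) {
    .stopf("malformed chimeric-junction line %d: expected >= 14 fields, got %d",
           line_no[which(nf < 14L)[1]], nf[nf < 14L][1])
  }
  mat <- t(vapply(fields, function(f) f[1:14], character(14)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- .chimeric_cols
  for (col in c("brkpt_donor", "brkpt_acceptor", "junction_code",
                "repeat_left", "repeat_right", "seg1_start", "seg2_start")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) {
      .stopf("malformed chimeric-junction line %d: non-integer value '%s' in field %s",
             line_no[which(is.na(v))[1]], df[[col]][is.na(v)][1], col)
    }
    df[[col]] <- v
  }
  bad <- !(df$strand_donor %in% c("+", "-")) |
    !(df$strand_acceptor %in% c("+", "-"))
  if (any(bad)) {
    .stopf("unknown strand symbol on chimeric-junction line %d",
           line_no[which(bad)[1]])
  }
  mate <- rep(NA_integer_, nrow(df))
  has_suffix <- grepl("/[12]$", df$read_name)
  mate[has_suffix] <- as.integer(sub("^.*/", "", df$read_name[has_suffix]))
  df$read_id <- sub("/[12]$", "", df$read_name)
  df$mate <- mate
  df$read_seq <- NA_character_
  df[, c("read_id", "read_name", "mate", .chimeric_cols, "read_seq")]
}

.empty_chimeric <- function() {
  df <- data.frame(read_id = character(), read_name = character(),
                   mate = integer(), stringsAsFactors = FALSE)
  for (col in .chimeric_cols) {
    df[[col]] <- if (col %in% c("brkpt_donor", "brkpt_acceptor",
                                "junction_code", "repeat_left",
                                "repeat_right", "seg1_start", "seg2_start"))
      integer() else character()
  }
  df$read_seq <- character()
  df
}

#' Drop reads with ambiguous chimeric evidence
#'
#' A read name appearing in more than one chimeric line describes a read
#' with more than two segments or conflicting chimeras; such reads are
#' removed entirely, keeping only reads with exactly two segments in a
#' single chimeric record.
#'
#' @param records chimeric record data frame.
#' @return filtered data frame (order preserved).
#' @export
drop_ambiguous_reads <- function(records) {
  n <- table(records$read_name)
  records[records$read_name %in% names(n)[n == 1L], , drop = FALSE]
}

#' Identify circular chimeric reads
#'
#' A chimeric record is a circular chimeric read (CCR) when its two segments
#' map to the same chromosome and strand in inverted genomic order
#' (on \code{+}: donor breakpoint downstream of acceptor breakpoint;
#' mirrored on \code{-}), both segments align at least \code{min_segment}
#' read bases, and the junction code denotes a within-read junction
#' (code >= 0; negative codes mark junctions spanning the two mates of a
#' pair, which cannot pinpoint a circular junction).
#'
#' @param records chimeric record data frame.
#' @param min_segment minimum aligned bases of the smallest segment (nt).
#' @return logical vector along rows of \code{records}.
#' @export
is_ccr <- function(records, min_segment = 15) {
  if (nrow(records) == 0L) return(logical(0))
  same <- records$chrom_donor == records$chrom_acceptor &
    records$strand_donor == records$strand_acceptor
  inverted <- ifelse(records$strand_donor == "+",
                     records$brkpt_donor > records$brkpt_acceptor,
                     records$brkpt_donor < records$brkpt_acceptor)
  within_read <- records$junction_code >= 0L
  a1 <- cigar_aligned_bases(records$seg1_cigar)
  a2 <- cigar_aligned_bases(records$seg2_cigar)
  same & inverted & within_read & a1 >= min_segment & a2 >= min_segment
}

#' Convert CCRs to circular junction coordinates
#'
#' Translates the two breakpoints of each circular chimeric read into the
#' 1-based closed genomic interval \code{[start, end]} of the circularized
#' transcript. Under the default breakpoint convention each breakpoint
#' names the first excluded base beyond its segment, so on \code{+}
#' \code{start = brkpt_acceptor + offsets[1]} and
#' \code{end = brkpt_donor + offsets[2]} with offsets \code{c(1, -1)};
#' the convention is mirrored on \code{-}. The offsets are configurable so
#' a different aligner dialect can be accommodated explicitly; a resulting
#' \code{start > end} signals wrong offsets and is an error.
#'
#' @param records chimeric record data frame (rows must satisfy [is_ccr()]).
#' @param offsets integer pair applied to (acceptor, donor) breakpoints.
#' @return data frame of circular junctions: \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, \code{size}, \code{read_id}, \code{read_name},
#'   \code{mate}, \code{fingerprint} (distinct-read identity:
#'   segment starts, CIGARs, read length), \code{junction_code},
#'   \code{seg1_start}, \code{seg1_cigar}, \code{seg2_start},
#'   \code{seg2_cigar}, \code{read_seq}.
#' @export
ccr_to_junction <- function(records, offsets = c(1L, -1L)) {
  stopifnot(length(offsets) == 2L)
  plus <- records$strand_donor == "+"
  start <- ifelse(plus,
                  records$brkpt_acceptor + offsets[1],
                  records$brkpt_donor - offsets[2])
  end <- ifelse(plus,
                records$brkpt_donor + offsets[2],
                records$brkpt_acceptor - offsets[1])
  if (any(start > end)) {
    .stopf("junction conversion produced start > end for read %s; check breakpoint offsets",
           records$read_name[which(start > end)[1]])
  }
  read_len <- ifelse(is.na(records$read_seq),
                     cigar_read_length(records$seg1_cigar),
                     nchar(records$read_seq))
  data.frame(
    chrom = records$chrom_donor,
    strand = records$strand_donor,
    start = as.integer(start),
    end = as.integer(end),
    size = as.integer(end - start + 1L),
    read_id = records$read_id,
    read_name = records$read_name,
    mate = records$mate,
    fingerprint = paste(records$seg1_start, records$seg1_cigar,
                        records$seg2_start, records$seg2_cigar,
                        read_len, sep = ":"),
    junction_code = records$junction_code,
    seg1_start = records$seg1_start,
    seg1_cigar = records$seg1_cigar,
    seg2_start = records$seg2_start,
    seg2_cigar = records$seg2_cigar,
    read_seq = records$read_seq,
    stringsAsFactors = FALSE
  )
}

#' Keep records on a set of chromosomes
#'
#' @param records chimeric records or junction table (any data frame with a
#'   \code{chrom} column, or chimeric records with \code{chrom_donor}).
#' @param include chromosome names to keep; an empty vector keeps all.
#' @return filtered data frame (order preserved; idempotent).
#' @export
filter_chromosomes <- function(records, include = character()) {
  if (length(include) == 0L) return(records)
  chrom <- if ("chrom" %in% names(records)) records$chrom
  else records$chrom_donor
  keep <- chrom %in% include
  if ("chrom_acceptor" %in% names(records)) {
    keep <- keep & records$chrom_acceptor %in% include
  }
  records[keep, , drop = FALSE]
}

#' Select CCRs from a chimeric-junction file
#'
#' Convenience wrapper chaining [parse_chimeric_junctions()],
#' [drop_ambiguous_reads()], [is_ccr()], [filter_chromosomes()], and
#' [ccr_to_junction()].
#'
#' @inheritParams parse_chimeric_junctions
#' @inheritParams is_ccr
#' @inheritParams ccr_to_junction
#' @param include chromosomes to keep (empty = all).
#' @param sam_path optional SAM file from which read sequences are attached.
#' @return junction table as from [ccr_to_junction()].
#' @export
select_ccrs <- function(path, min_segment = 15, include = character(),
                        offsets = c(1L, -1L), sam_path = NULL) {
  rec <- parse_chimeric_junctions(path)
  rec <- drop_ambiguous_reads(rec)
  if (!is.null(sam_path)) rec <- attach_read_sequences(rec, sam_path)
  rec <- rec[is_ccr(rec, min_segment = min_segment), , drop = FALSE]
  rec <- filter_chromosomes(rec, include)
  ccr_to_junction(rec, offsets = offsets)
}

#' Attach read sequences from a SAM file
#'
#' Looks up each record's read name in a SAM file and fills
#' \code{read_seq}. Sequences are taken as stored in the SAM (the
#' simulator writes them in transcript orientation).
#'
#' @param records chimeric record data frame.
#' @param sam_path path to a SAM file whose QNAMEs match
#'   \code{records$read_name}.
#' @return \code{records} with \code{read_seq} filled where found.
#' @export
attach_read_sequences <- function(records, sam_path) {
  if (!file.exists(sam_path)) .stopf("SAM file not found: %s", sam_path)
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) return(records)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(fields, `[`, character(1), 1L)
  seq <- vapply(fields, `[`, character(1), 10L)
  idx <- match(records$read_name, qname)
  hit <- !is.na(idx) & seq[pmax(idx, 1L)] != "*"
  records$read_seq[hit] <- seq[idx[hit]]
  records
}

#' Count split reads supporting a linear junction
#'
#' Returns the number of unique reads spanning the linear exon-exon
#' junction defined by a donor exon end and an acceptor exon start, from
#' either an SJ-style 9-column tab file (chrom, intron start, intron end,
#' strand code 0/1/2, motif, annotated, unique count, multi count,
#' overhang) or a SAM file with N-gapped alignments.
#'
#' @param sj_source path to the SJ tab file or SAM file.
#' @param chrom chromosome.
#' @param donor_end 1-based last base of the upstream exon.
#' @param acceptor_start 1-based first base of the downstream exon.
#' @param strand \code{"+"} or \code{"-"}; ignored for SAM sources and for
#'   SJ lines with strand code 0.
#' @param format \code{"auto"} (by extension), \code{"sj"} or \code{"sam"}.
#' @return integer count; 0 when the junction is absent.
#' @export
count_split_reads <- function(sj_source, chrom, donor_end, acceptor_start,
                              strand = "+", format = c("auto", "sj", "sam")) {
  format <- match.arg(format)
  if (!file.exists(sj_source)) .stopf("split-read source not found: %s", sj_source)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", sj_source, ignore.case = TRUE)) "sam" else "sj"
  }
  intron_start <- donor_end + 1L
  intron_end <- acceptor_start - 1L
  if (format == "sj") {
    sj <- read.table(sj_source, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(sj) < 7L) .stopf("SJ file %s has fewer than 7 columns", sj_source)
    sj_strand <- c("0" = NA, "1" = "+", "2" = "-")[as.character(sj[[4]])]
    hit <- sj[[1]] == chrom & sj[[2]] == intron_start & sj[[3]] == intron_end &
      (is.na(sj_strand) | sj_strand == strand)
    return(if (any(hit)) sum(sj[[7]][hit]) else 0L)
  }
  ## SAM route: convert to BAM and count alignments whose N gap matches.
  bam <- Rsamtools::asBam(sj_source, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  aln <- GenomicAlignments::readGAlignments(bam)
  j <- GenomicAlignments::junctions(aln)
  target <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(intron_start, intron_end))
  hits <- vapply(seq_along(j), function(i) {
    any(IRanges::overlapsAny(j[[i]], target, type = "equal"))
  }, logical(1))
  sum(hits)
}
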