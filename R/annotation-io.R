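## Loading of exon lists (GTF / BED), intron derivation for coding genes,
## and identification of mono-exonic genes.
##
## Coordinates are 1-based inclusive everywhere inside the package; BED
## input/output converts at the boundary of the system only (rtracklayer
## performs that conversion).

.default_biotype_map <- c(protein_coding = "coding",
                          lncRNA = "lnc", lincRNA = "lnc")

#' Read exons from a GTF file
#'
#' Imports \code{exon} features, assigns a simplified biotype from the
#' gene biotype attribute, and deduplicates identical exons shared by
#' several transcripts of a gene. All transcript ids sharing an exon are
#' retained (comma-collapsed).
#'
#' @param path GTF file (Ensembl dialect).
#' @param biotype_map named character vector mapping gene biotype strings
#'   to \code{"coding"}, \code{"lnc"}, or \code{"other_nc"}; unmapped
#'   biotypes become \code{"other_nc"}.
#' @param list_id exon-list priority id recorded on each record (1-3).
#' @return exon data frame: \code{chrom}, \code{strand}, \code{start},
#'   \code{end}, \code{gene_id}, \code{transcript_id}, \code{biotype},
#'   \code{list_id}.
#' @export
read_exons_gtf <- function(path, biotype_map = .default_biotype_map,
                           list_id = 1L) {
  first <- readLines(path, n = 100L)
  if (!any(nzchar(first) & !startsWith(first, "#"))) return(.empty_exons())
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) return(.empty_exons())
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L) return(.empty_exons())
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    .stopf("GTF %s has exon features without gene_id", path)
  }
  raw_bt <- if (!is.null(gr$gene_biotype)) gr$gene_biotype
  else rep(NA_character_, length(gr))
  biotype <- unname(biotype_map[raw_bt])
  biotype[is.na(biotype)] <- "other_nc"
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_id = gr$gene_id,
    transcript_id = if (!is.null(gr$transcript_id)) gr$transcript_id
    else gr$gene_id,
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  key <- paste(df$chrom, df$strand, df$start, df$end, df$gene_id, sep = "\r")
  tx <- vapply(split(df$transcript_id, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  df <- df[!duplicated(key), , drop = FALSE]
  df$transcript_id <- unname(tx[paste(df$chrom, df$strand, df$start, df$end,
                                      df$gene_id, sep = "\r")])
  df$list_id <- as.integer(list_id)
  rownames(df) <- NULL
  df
}

.empty_exons <- function() {
  data.frame(chrom = character(), strand = character(), start = integer(),
             end = integer(), gene_id = character(),
             transcript_id = character(), biotype = character(),
             list_id = integer(), stringsAsFactors = FALSE)
}

#' Read exons from a BED file
#'
#' Accepts BED6 (one exon per line) or BED12 (blocks expanded to exons).
#' The 0-based half-open BED coordinates are converted to the package's
#' 1-based inclusive convention.
#'
#' @param path BED6/BED12 file.
#' @param list_id exon-list priority id (2 for curated lncRNA exon lists,
#'   3 for novel-exon lists).
#' @param biotype biotype recorded on each exon (default \code{"lnc"} for
#'   list 2, \code{"novel"} otherwise).
#' @return exon data frame as in [read_exons_gtf()].
#' @export
read_exons_bed <- function(path, list_id, biotype = NULL) {
  if (is.null(biotype)) biotype <- if (list_id == 2L) "lnc" else "novel"
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) .stopf("malformed BED %s: %s",
                                            path, conditionMessage(e)))
  if (length(gr) == 0L) return(.empty_exons())
  name <- if (!is.null(gr$name)) gr$name else paste0("bed_", seq_along(gr))
  if (!is.null(gr$blocks)) {
    blocks <- rtracklayer::blocks(gr)  # GRangesList in genomic coordinates
    n <- lengths(blocks)
    flat <- unlist(blocks, use.names = FALSE)
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(flat)),
      strand = as.character(GenomicRanges::strand(flat)),
      start = GenomicRanges::start(flat),
      end = GenomicRanges::end(flat),
      gene_id = rep(name, n),
      transcript_id = rep(name, n),
      stringsAsFactors = FALSE
    )
  } else {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      gene_id = name,
      transcript_id = name,
      stringsAsFactors = FALSE
    )
  }
  df$biotype <- biotype
  df$list_id <- as.integer(list_id)
  rownames(df) <- NULL
  df
}

#' Enforce disjointness of prioritized exon lists
#'
#' Exons identical in coordinates (chrom, strand, start, end) across lists
#' are kept only in the lowest \code{list_id}, matching the cascade that
#' purges circRNAs identified on an earlier list before the next list is
#' used.
#'
#' @param exons combined exon data frame (rbind of per-list frames).
#' @return exon data frame with cross-list coordinate duplicates removed.
#' @export
dedup_exon_lists <- function(exons) {
  ord <- order(exons$list_id)
  exons <- exons[ord, , drop = FALSE]
  key <- .coord_key(exons$chrom, exons$strand, exons$start, exons$end)
  first_list <- setNames(exons$list_id[!duplicated(key)], unique(key))
  keep <- exons$list_id == first_list[key]
  out <- exons[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive introns from exons of coding genes
#'
#' Per transcript, gaps between consecutive exons become introns; introns
#' identical in coordinates are deduplicated per gene across transcripts,
#' so a locus may match any transcript's intron of the gene. Overlapping
#' exons within one transcript are an annotation error.
#'
#' @param exons exon data frame (typically coding-gene exons).
#' @return intron data frame: \code{chrom}, \code{strand}, \code{start},
#'   \code{end} (first and last intronic base), \code{gene_id},
#'   \code{upstream_exon_end}, \code{downstream_exon_start}.
#' @export
derive_introns <- function(exons) {
  out <- list()
  for (tx in split(exons, exons$transcript_id)) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) < 2L) next
    if (any(tx$start[-1] <= tx$end[-nrow(tx)])) {
      .stopf("overlapping exons within transcript %s", tx$transcript_id[1])
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = tx$chrom[1],
      strand = tx$strand[1],
      start = tx$end[-nrow(tx)] + 1L,
      end = tx$start[-1] - 1L,
      gene_id = tx$gene_id[1],
      upstream_exon_end = tx$end[-nrow(tx)],
      downstream_exon_start = tx$start[-1],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), upstream_exon_end = integer(),
                      downstream_exon_start = integer(),
                      stringsAsFactors = FALSE))
  }
  introns <- do.call(rbind, out)
  key <- paste(.coord_key(introns$chrom, introns$strand, introns$start,
                          introns$end), introns$gene_id)
  introns <- introns[!duplicated(key), , drop = FALSE]
  rownames(introns) <- NULL
  introns
}

#' Identify mono-exonic genes
#'
#' A gene is mono-exonic when every one of its transcripts has exactly one
#' exon. Returns one row per gene with its span, biotype, exon count
#' (maximum over transcripts) and the flag.
#'
#' @param exons exon data frame covering all genes of interest.
#' @return gene data frame: \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, \code{biotype}, \code{exon_count},
#'   \code{mono_exonic}.
#' @export
find_mono_exonic <- function(exons) {
  if (nrow(exons) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), biotype = character(),
                      exon_count = integer(), mono_exonic = logical(),
                      stringsAsFactors = FALSE))
  }
  per_gene <- lapply(split(exons, exons$gene_id), function(g) {
    per_tx <- table(g$transcript_id)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               biotype = g$biotype[1],
               exon_count = as.integer(max(per_tx)),
               mono_exonic = all(per_tx == 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}

#' Build the boundary set of an exon list
#'
#' Collects exon starts as acceptor boundaries and exon ends as donor
#' boundaries (genomic sides; strand is carried and must match during
#' lookup). Duplicate (chrom, strand, position, side) entries are merged,
#' collapsing gene ids.
#'
#' @param exons exon data frame for one list.
#' @return boundary data frame: \code{chrom}, \code{strand},
#'   \code{position}, \code{side} (\code{"acceptor_start"} or
#'   \code{"donor_end"}), \code{origin} (\code{"known"}), \code{list_id},
#'   \code{gene_id}.
#' @export
build_boundaries <- function(exons) {
  if (nrow(exons) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      position = integer(), side = character(),
                      origin = character(), list_id = integer(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  b <- rbind(
    data.frame(chrom = exons$chrom, strand = exons$strand,
               position = exons$start, side = "acceptor_start",
               origin = "known", list_id = exons$list_id,
               gene_id = exons$gene_id, stringsAsFactors = FALSE),
    data.frame(chrom = exons$chrom, strand = exons$strand,
               position = exons$end, side = "donor_end",
               origin = "known", list_id = exons$list_id,
               gene_id = exons$gene_id, stringsAsFactors = FALSE)
  )
  key <- paste(.pos_key(b$chrom, b$strand, b$position), b$side)
  gene <- vapply(split(b$gene_id, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  b <- b[!duplicated(key), , drop = FALSE]
  b$gene_id <- unname(gene[paste(.pos_key(b$chrom, b$strand, b$position),
                                 b$side)])
  rownames(b) <- NULL
  b
}
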