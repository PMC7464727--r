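## Summary quantities and the end-to-end pipeline driver.

#' Percentage, rounded half away from zero
#'
#' @param part,whole counts; \code{whole} must be positive.
#' @param decimals decimal places.
#' @return numeric percentage.
#' @export
percent <- function(part, whole, decimals = 1) {
  if (any(whole == 0)) .stopf("percent(): whole is zero")
  round_half_away(100 * part / whole, decimals)
}

#' Mean CCRs per LAC
#'
#' @param total_ccr total CCR count.
#' @param total_lac number of LACs; must be positive.
#' @param decimals decimal places.
#' @return rounded quotient.
#' @export
mean_ccr_per_lac <- function(total_ccr, total_lac, decimals = 1) {
  if (any(total_lac == 0)) .stopf("mean_ccr_per_lac(): zero LACs")
  round_half_away(total_ccr / total_lac, decimals)
}

#' Circular-to-linear support ratio (CCR/SR)
#'
#' Ratio of circular-junction reads to linear split reads at the matching
#' exon-exon junction, rounded half away from zero to an integer. A zero
#' split-read count yields \code{Inf} (reported, not an error).
#'
#' @param ccr_count CCR count of the circular event.
#' @param sr_count split-read count of the linear junction.
#' @return numeric (integer-valued or \code{Inf}).
#' @export
ccr_sr_ratio <- function(ccr_count, sr_count) {
  ifelse(sr_count == 0, Inf, round_half_away(ccr_count / sr_count, 0))
}

#' Build the summary report
#'
#' Assembles the per-stage totals, per-class LAC and CCR counts, and
#' origin percentages from pipeline stage outputs. Percentages are always
#' computed from the stated counts (half-away-from-zero rounding), never
#' stored independently.
#'
#' @param n_records chimeric records parsed.
#' @param junctions CCR junction table (after selection).
#' @param lacs all LACs (pre-threshold).
#' @param retained retained LACs (post-threshold).
#' @param exonic_labels exonic label table ([cascade_label()]).
#' @param noncanonical label table ([classify_noncanonical()]).
#' @param exon_origin optional character vector along rows of
#'   \code{exonic_labels}: \code{"coding"}, \code{"lnc"}, or
#'   \code{"other"} origin of each exonic LAC.
#' @param decimals decimal places for percentages.
#' @return object of class \code{circlass_report} (a list).
#' @export
build_report <- function(n_records, junctions, lacs, retained,
                         exonic_labels, noncanonical, exon_origin = NULL,
                         decimals = 2) {
  ccr_by_lac <- setNames(retained$ccr_count, retained$lac_id)
  exonic_ccr <- sum(ccr_by_lac[exonic_labels$lac_id])
  class_lacs <- c(exonic = nrow(exonic_labels),
                  table(factor(noncanonical$klass,
                               levels = c("lariat_intronic", "intron_circle",
                                          "sub_exonic", "unallocated"))))
  class_ccrs <- c(exonic = exonic_ccr,
                  vapply(c("lariat_intronic", "intron_circle", "sub_exonic",
                           "unallocated"), function(k) {
                    ids <- noncanonical$lac_id[noncanonical$klass == k]
                    sum(ccr_by_lac[ids])
                  }, numeric(1)))
  total_retained_ccr <- sum(retained$ccr_count)
  origin_ccr <- NULL
  if (!is.null(exon_origin) && nrow(exonic_labels) > 0L) {
    origin_ccr <- vapply(split(ccr_by_lac[exonic_labels$lac_id],
                               exon_origin), sum, numeric(1))
  }
  mate_split <- table(factor(junctions$mate, levels = c(1L, 2L)))
  out <- list(
    totals = list(
      chimeric_records = n_records,
      ccrs = nrow(junctions),
      lacs = nrow(lacs),
      lacs_retained = nrow(retained),
      ccrs_retained = total_retained_ccr,
      mean_ccr_per_lac = if (nrow(lacs) > 0L)
        mean_ccr_per_lac(nrow(junctions), nrow(lacs)) else NA_real_
    ),
    class_lacs = class_lacs,
    class_ccrs = class_ccrs,
    class_ccr_pct = if (total_retained_ccr > 0L)
      percent(class_ccrs, total_retained_ccr, decimals) else
        setNames(rep(NA_real_, length(class_ccrs)), names(class_ccrs)),
    origin_ccr = origin_ccr,
    origin_pct = if (!is.null(origin_ccr) && total_retained_ccr > 0L)
      percent(origin_ccr, total_retained_ccr, decimals) else NULL,
    mate_split = c(mate_split),
    decimals = decimals
  )
  class(out) <- "circlass_report"
  out
}

#' @export
print.circlass_report <- function(x, ...) {
  cat("circRNA junction classification report\n")
  cat(sprintf("  chimeric records parsed : %d\n", x$totals$chimeric_records))
  cat(sprintf("  CCRs selected           : %d\n", x$totals$ccrs))
  cat(sprintf("  LACs (pre-threshold)    : %d (mean %.1f CCRs per LAC)\n",
              x$totals$lacs, x$totals$mean_ccr_per_lac))
  cat(sprintf("  LACs retained           : %d (%d CCRs)\n",
              x$totals$lacs_retained, x$totals$ccrs_retained))
  cat("  per-class LACs (CCRs, % of retained CCRs;",
      "percentages rounded half away from zero):\n")
  for (k in names(x$class_lacs)) {
    cat(sprintf("    %-15s %6d  (%d, %s%%)\n", k, x$class_lacs[[k]],
                x$class_ccrs[[k]],
                format(x$class_ccr_pct[[k]], nsmall = x$decimals)))
  }
  if (!is.null(x$origin_pct)) {
    cat("  exonic CCR origin (% of retained CCRs):\n")
    for (k in names(x$origin_pct)) {
      cat(sprintf("    %-15s %s%%\n", k,
                  format(x$origin_pct[[k]], nsmall = x$decimals)))
    }
  }
  cat(sprintf("  mate split (Reads-1 / Reads-2): %d / %d\n",
              x$mate_split[["1"]], x$mate_split[["2"]]))
  invisible(x)
}

## Origin class of each exonic label: coding wins over lnc over other.
.exonic_origin <- function(exonic_labels, exons, genes = NULL) {
  biotype_of <- setNames(exons$biotype, exons$gene_id)
  vapply(seq_len(nrow(exonic_labels)), function(i) {
    g <- exonic_labels$gene_id[i]
    if (is.na(g)) {
      ## novel-boundary matches carry no gene; fall back on the list
      return(if (!is.na(exonic_labels$list_id[i]) &&
                 exonic_labels$list_id[i] == 2L) "lnc" else "other")
    }
    ids <- unlist(strsplit(g, "[;,]"))
    bts <- unique(biotype_of[ids])
    if ("coding" %in% bts) "coding"
    else if ("lnc" %in% bts) "lnc"
    else "other"
  }, character(1))
}

#' Run the full classification pipeline
#'
#' Drives chimeric-record selection, LAC clustering and thresholding, the
#' exonic cascade, the non-canonical cascade, and (when a genome is
#' given) event merging, then builds the summary report. All input files
#' are checked before any processing; per-stage record counts are logged
#' to standard error.
#'
#' @param config named list:
#'   \describe{
#'     \item{chimeric}{chimeric-junction file (required).}
#'     \item{gtf}{exon annotation GTF, exons-list-1 (required).}
#'     \item{lnc_bed}{optional BED of lncRNA exons (exons-list-2).}
#'     \item{novel_bed}{optional BED of novel exons (exons-list-3).}
#'     \item{genome_fa}{optional genome FASTA (enables event merging and
#'       splice motifs).}
#'     \item{sam}{optional SAM with read sequences.}
#'     \item{sj}{optional SJ-style split-read file (carried for ratio
#'       queries).}
#'     \item{include_chroms}{chromosomes to keep (empty = all).}
#'     \item{min_segment, offsets, min_ccr, min_distinct, min_tail,
#'       branch_window, min_size, confident_size, max_shift, k,
#'       junction_window, max_rounds, min_support}{thresholds; defaults as
#'       in the stage functions.}
#'   }
#' @return list: \code{report}, \code{junctions}, \code{lacs},
#'   \code{retained}, \code{exonic_labels}, \code{noncanonical},
#'   \code{subexonic_sets}, \code{events} (NULL without a genome),
#'   \code{classification} (per retained LAC: \code{lac_id},
#'   \code{klass}, \code{gene_id}).
#' @export
run_pipeline <- function(config) {
  cfg <- function(name, default = NULL) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  required <- c("chimeric", "gtf")
  for (f in required) {
    if (is.null(config[[f]])) .stopf("config misses required input '%s'", f)
  }
  paths <- c(config$chimeric, config$gtf, config$lnc_bed, config$novel_bed,
             config$genome_fa, config$sam, config$sj)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) .stopf("input file not found: %s", missing[1])

  records <- parse_chimeric_junctions(config$chimeric)
  message(sprintf("[select] %d chimeric records parsed", nrow(records)))
  n_records <- nrow(records)
  records <- drop_ambiguous_reads(records)
  if (!is.null(config$sam)) {
    records <- attach_read_sequences(records, config$sam)
  }
  records <- records[is_ccr(records,
                            min_segment = cfg("min_segment", 15)), ,
                     drop = FALSE]
  records <- filter_chromosomes(records, cfg("include_chroms", character()))
  junctions <- ccr_to_junction(records, offsets = cfg("offsets", c(1L, -1L)))
  message(sprintf("[select] %d CCRs", nrow(junctions)))

  lacs <- cluster_ccrs(junctions)
  junctions <- assign_lac_ids(junctions, lacs)
  retained <- apply_threshold(lacs, min_ccr = cfg("min_ccr", 5),
                              min_distinct = cfg("min_distinct", 4))
  message(sprintf("[cluster] %d LACs, %d retained by threshold",
                  nrow(lacs), nrow(retained)))

  exons1 <- read_exons_gtf(config$gtf)
  exons <- exons1
  if (!is.null(config$lnc_bed)) {
    exons <- rbind(exons, read_exons_bed(config$lnc_bed, list_id = 2L))
  }
  if (!is.null(config$novel_bed)) {
    exons <- rbind(exons, read_exons_bed(config$novel_bed, list_id = 3L))
  }
  exons <- dedup_exon_lists(exons)

  exonic_labels <- cascade_label(retained, exons,
                                 max_rounds = cfg("max_rounds", 20),
                                 min_support = cfg("min_support", 0))
  message(sprintf("[classify] %d exonic LACs", nrow(exonic_labels)))

  coding_exons <- exons1[exons1$biotype == "coding", , drop = FALSE]
  introns <- derive_introns(coding_exons)
  genes <- find_mono_exonic(exons1)
  mono_exons <- exons1[exons1$gene_id %in%
                         genes$gene_id[genes$mono_exonic], , drop = FALSE]
  unlab <- retained[!(retained$lac_id %in% exonic_labels$lac_id), ,
                    drop = FALSE]
  noncanonical <- classify_noncanonical(
    unlab, introns, mono_exons,
    min_tail = cfg("min_tail", 1), branch_window = cfg("branch_window", 0),
    min_size = cfg("min_size", 55),
    confident_size = cfg("confident_size", 70))
  message(sprintf(
    "[classify] %d lariat, %d intron circle, %d sub-exonic, %d unallocated",
    sum(noncanonical$klass == "lariat_intronic"),
    sum(noncanonical$klass == "intron_circle"),
    sum(noncanonical$klass == "sub_exonic"),
    sum(noncanonical$klass == "unallocated")))

  sub_idx <- noncanonical$klass == "sub_exonic"
  sub_lacs <- unlab[match(noncanonical$lac_id[sub_idx], unlab$lac_id), ,
                    drop = FALSE]
  subexonic_sets <- group_sets(sub_lacs, noncanonical$gene_id[sub_idx])

  events <- NULL
  if (!is.null(config$genome_fa)) {
    genome <- Biostrings::readDNAStringSet(config$genome_fa)
    names(genome) <- sub("\\s.*$", "", names(genome))
    events <- merge_events(retained, genome, reads = junctions,
                           max_shift = cfg("max_shift", 5),
                           k = cfg("k", 15),
                           junction_window = cfg("junction_window", 5))
    message(sprintf("[refine] %d events from %d retained LACs",
                    nrow(events$events), nrow(retained)))
  }

  origin <- .exonic_origin(exonic_labels, exons)
  report <- build_report(n_records, junctions, lacs, retained,
                         exonic_labels, noncanonical, exon_origin = origin)
  classification <- rbind(
    if (nrow(exonic_labels) > 0L)
      data.frame(lac_id = exonic_labels$lac_id, klass = "exonic",
                 gene_id = exonic_labels$gene_id, stringsAsFactors = FALSE),
    noncanonical[, c("lac_id", "klass", "gene_id")]
  )
  list(report = report, junctions = junctions, lacs = lacs,
       retained = retained, exonic_labels = exonic_labels,
       noncanonical = noncanonical, subexonic_sets = subexonic_sets,
       events = events, classification = classification)
}

#' Write a table as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention at the output boundary.
#'
#' @param df data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} and optionally a \code{name} column (else
#'   \code{lac_id} or row numbers).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if (!is.null(df$name)) df$name
  else if (!is.null(df$lac_id)) df$lac_id
  else as.character(seq_len(nrow(df)))
  bed <- data.frame(df$chrom, df$start - 1L, df$end, name, 0L, df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
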