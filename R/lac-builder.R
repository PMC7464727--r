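## Clustering of circular junctions into loci associated with circRNA
## production (LACs) and the abundance threshold.

#' Cluster circular junctions into LACs
#'
#' Groups junctions by exact genomic coordinates (chrom, strand, start,
#' end). Each group is one locus associated with circRNA production (LAC)
#' with its total CCR count and distinct CCR count, where "distinct" is
#' judged by the alignment fingerprint (segment starts, segment CIGARs,
#' read length) so that PCR duplicates collapse while same-locus reads
#' from different molecules do not.
#'
#' @param junctions junction table from [ccr_to_junction()].
#' @return LAC data frame: \code{lac_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, \code{size}, \code{ccr_count},
#'   \code{distinct_ccr_count}. The sum of \code{ccr_count} equals
#'   \code{nrow(junctions)}.
#' @export
cluster_ccrs <- function(junctions) {
  if (nrow(junctions) == 0L) {
    return(data.frame(lac_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), size = integer(),
                      ccr_count = integer(), distinct_ccr_count = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- .coord_key(junctions$chrom, junctions$strand, junctions$start,
                    junctions$end)
  first <- !duplicated(key)
  lacs <- junctions[first, c("chrom", "strand", "start", "end", "size")]
  lacs_key <- key[first]
  cnt <- table(key)
  dst <- vapply(split(junctions$fingerprint, key), count_distinct, integer(1))
  lacs$ccr_count <- as.integer(cnt[lacs_key])
  lacs$distinct_ccr_count <- unname(dst[lacs_key])
  ord <- order(lacs$chrom, lacs$strand, lacs$start, lacs$end)
  lacs <- lacs[ord, , drop = FALSE]
  lacs <- cbind(lac_id = sprintf("LAC%06d", seq_len(nrow(lacs))), lacs,
                stringsAsFactors = FALSE)
  rownames(lacs) <- NULL
  lacs
}

#' Count distinct alignment fingerprints
#'
#' @param fingerprints character vector of fingerprints of the reads of
#'   one LAC.
#' @return integer number of distinct fingerprints.
#' @export
count_distinct <- function(fingerprints) {
  length(unique(fingerprints))
}

#' Attach LAC ids to a junction table
#'
#' @param junctions junction table.
#' @param lacs LAC table from [cluster_ccrs()].
#' @return \code{junctions} with a \code{lac_id} column (NA where the
#'   junction's coordinates are absent from \code{lacs}).
#' @export
assign_lac_ids <- function(junctions, lacs) {
  jk <- .coord_key(junctions$chrom, junctions$strand, junctions$start,
                   junctions$end)
  lk <- .coord_key(lacs$chrom, lacs$strand, lacs$start, lacs$end)
  junctions$lac_id <- lacs$lac_id[match(jk, lk)]
  junctions
}

#' Apply the LAC abundance threshold
#'
#' Keeps only LACs supported by at least \code{min_ccr} CCRs of which at
#' least \code{min_distinct} are distinct, discarding loci whose support
#' could come from duplicate reads alone. Defaults correspond to the
#' "5 CCRs including 4 distinct CCRs" rule.
#'
#' @param lacs LAC table.
#' @param min_ccr minimum total CCR count.
#' @param min_distinct minimum distinct CCR count.
#' @return filtered LAC table.
#' @export
apply_threshold <- function(lacs, min_ccr = 5, min_distinct = 4) {
  keep <- lacs$ccr_count >= min_ccr & lacs$distinct_ccr_count >= min_distinct
  out <- lacs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
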