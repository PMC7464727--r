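#' @importFrom stats rbinom runif setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

## CIGAR helpers built on GenomicAlignments' parser.

#' Number of read bases a CIGAR aligns to the reference
#'
#' Counts read bases consumed by M/=/X operations, i.e. bases actually
#' matched or mismatched against the reference (soft clips and insertions
#' are excluded). This is the "mapped segment size" a chimeric-segment
#' filter operates on.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of aligned read-base counts.
#' @export
cigar_aligned_bases <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  vapply(seq_along(ops), function(i) {
    sum(lens[[i]][ops[[i]] %in% c("M", "=", "X")])
  }, integer(1))
}

#' Read length implied by a CIGAR
#'
#' Total read bases consumed (M/I/S/=/X), i.e. the full length of the
#' sequenced read including soft-clipped parts.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector.
#' @export
cigar_read_length <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                               after.soft.clipping = FALSE)
}

#' Round half away from zero
#'
#' Commercial rounding: 0.5 always rounds away from zero, matching how the
#' summary percentages and ratios in the report are printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## key for exact-coordinate operations
.coord_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = "\r")
}

.pos_key <- function(chrom, strand, pos) {
  paste(chrom, strand, pos, sep = "\r")
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Minimal union-find used for single-linkage merges.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i)
  rj <- .uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}
.uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) .uf_find(parent, i),
                  integer(1))
  match(roots, unique(roots))
}
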