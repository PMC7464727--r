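## Iterative labelling of LACs produced by back splicing.
##
## Round 1 matches LAC boundaries against known exon boundaries (start
## against exon starts, end against exon ends, same chrom and strand).
## A LAC with both boundaries known is a standard annotation hit; a LAC
## with exactly one known boundary is labelled too and its unmatched
## boundary enters the boundary set as a putative novel exon boundary
## (side-typed). Later rounds label LACs whose boundary matches a novel
## entry, promoting their own unmatched boundary in turn, until a round
## adds no label (fixpoint). The cascade runs this per exon list in
## priority order, purging labelled LACs between lists; novel boundaries
## never carry across lists.

#' Do both LAC boundaries match known exon boundaries?
#'
#' @param lacs LAC table.
#' @param boundaries boundary set from [build_boundaries()].
#' @return logical vector along rows of \code{lacs}.
#' @export
match_both <- function(lacs, boundaries) {
  known <- boundaries[boundaries$origin == "known", , drop = FALSE]
  sk <- .pos_key(known$chrom, known$strand, known$position)
  start_set <- sk[known$side == "acceptor_start"]
  end_set <- sk[known$side == "donor_end"]
  .pos_key(lacs$chrom, lacs$strand, lacs$start) %in% start_set &
    .pos_key(lacs$chrom, lacs$strand, lacs$end) %in% end_set
}

.boundary_lookup <- function(boundaries, side, origin = NULL) {
  b <- boundaries[boundaries$side == side, , drop = FALSE]
  if (!is.null(origin)) b <- b[b$origin %in% origin, , drop = FALSE]
  setNames(b$gene_id, .pos_key(b$chrom, b$strand, b$position))
}

#' Iterative exonic labelling against one exon list
#'
#' @param lacs LAC table (rows still unlabelled for this list).
#' @param boundaries boundary set of the list ([build_boundaries()]).
#' @param max_rounds safety cap on rounds; exceeding it is an error
#'   (guards against a pathological boundary cycle).
#' @param min_support minimum \code{ccr_count} a labelled LAC needs before
#'   its unmatched boundary is promoted as a novel boundary (0 promotes
#'   unconditionally).
#' @return list with \code{labels} (data frame: \code{lac_id}, \code{mode}
#'   in standard_both / iterative_one_known / iterative_novel_match,
#'   \code{round}, \code{list_id}, \code{gene_id}, \code{novel_position},
#'   \code{novel_side}) and \code{boundaries} (the input set augmented
#'   with origin \code{"novel"} entries).
#' @export
iterative_label <- function(lacs, boundaries, max_rounds = 20,
                            min_support = 0) {
  list_id <- if (nrow(boundaries) > 0L) boundaries$list_id[1] else NA_integer_
  known_start <- .boundary_lookup(boundaries, "acceptor_start", "known")
  known_end <- .boundary_lookup(boundaries, "donor_end", "known")
  novel_start <- character(0)  # keys of novel acceptor_start boundaries
  novel_end <- character(0)
  labels <- list()
  unlab <- lacs
  round <- 0L
  repeat {
    round <- round + 1L
    if (nrow(unlab) == 0L) break
    skey <- .pos_key(unlab$chrom, unlab$strand, unlab$start)
    ekey <- .pos_key(unlab$chrom, unlab$strand, unlab$end)
    if (round == 1L) {
      s_hit <- skey %in% names(known_start)
      e_hit <- ekey %in% names(known_end)
      hit <- s_hit | e_hit
      mode <- ifelse(s_hit & e_hit, "standard_both", "iterative_one_known")
      gene <- ifelse(s_hit,
                     unname(known_start[skey]),
                     unname(known_end[ekey]))
      both_gene <- s_hit & e_hit
      gene[both_gene] <- paste(known_start[skey[both_gene]],
                               known_end[ekey[both_gene]], sep = ";")
    } else {
      s_hit <- skey %in% novel_start
      e_hit <- ekey %in% novel_end
      hit <- s_hit | e_hit
      mode <- rep("iterative_novel_match", length(hit))
      gene <- rep(NA_character_, length(hit))
    }
    if (!any(hit)) break
    if (round > max_rounds) {
      .stopf("iterative labelling did not converge within %d rounds",
             max_rounds)
    }
    lab <- unlab[hit, , drop = FALSE]
    lab_s_hit <- s_hit[hit]
    lab_e_hit <- e_hit[hit]
    novel_position <- ifelse(lab_s_hit & lab_e_hit, NA_integer_,
                             ifelse(lab_s_hit, lab$end, lab$start))
    novel_side <- ifelse(lab_s_hit & lab_e_hit, NA_character_,
                         ifelse(lab_s_hit, "donor_end", "acceptor_start"))
    labels[[round]] <- data.frame(
      lac_id = lab$lac_id, mode = mode[hit], round = round,
      list_id = list_id, gene_id = gene[hit],
      novel_position = as.integer(novel_position),
      novel_side = novel_side, stringsAsFactors = FALSE
    )
    ## promote unmatched boundaries (side-typed) as novel entries
    promote <- !is.na(novel_side) & lab$ccr_count >= min_support
    if (any(promote)) {
      nkey <- .pos_key(lab$chrom[promote], lab$strand[promote],
                       novel_position[promote])
      is_start <- novel_side[promote] == "acceptor_start"
      novel_start <- union(novel_start, nkey[is_start])
      novel_end <- union(novel_end, nkey[!is_start])
    }
    unlab <- unlab[!hit, , drop = FALSE]
  }
  labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(lac_id = character(), mode = character(), round = integer(),
               list_id = integer(), gene_id = character(),
               novel_position = integer(), novel_side = character(),
               stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  aug <- boundaries
  .novel_rows <- function(keys, side) {
    if (length(keys) == 0L) return(NULL)
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(chrom = parts[, 1], strand = parts[, 2],
               position = as.integer(parts[, 3]), side = side,
               origin = "novel", list_id = list_id,
               gene_id = NA_character_, stringsAsFactors = FALSE)
  }
  aug <- rbind(aug, .novel_rows(novel_start, "acceptor_start"),
               .novel_rows(novel_end, "donor_end"))
  rownames(aug) <- NULL
  list(labels = labels, boundaries = aug)
}

#' Standard (non-iterative) exonic labelling
#'
#' Labels only LACs whose both boundaries match known exon boundaries of
#' one list; the comparison baseline for the iterative strategy.
#'
#' @inheritParams iterative_label
#' @return label data frame as in [iterative_label()] (all rows
#'   \code{standard_both}, round 1).
#' @export
standard_label <- function(lacs, boundaries) {
  hit <- match_both(lacs, boundaries)
  list_id <- if (nrow(boundaries) > 0L) boundaries$list_id[1] else NA_integer_
  data.frame(lac_id = lacs$lac_id[hit], mode = "standard_both",
             round = 1L, list_id = list_id, gene_id = NA_character_,
             novel_position = NA_integer_, novel_side = NA_character_,
             stringsAsFactors = FALSE)
}

#' Cascade exonic labelling over prioritized exon lists
#'
#' Runs [iterative_label()] per exon list in increasing \code{list_id}
#' order, removing labelled LACs before the next list so that a LAC
#' matching several lists is labelled with the highest-priority one.
#' Novel boundaries discovered on one list are not reused on another.
#'
#' @param lacs LAC table (retained LACs).
#' @param exons exon data frame covering all lists (column \code{list_id});
#'   run through [dedup_exon_lists()] beforehand if the lists may share
#'   coordinates.
#' @param standard_only if TRUE, use [standard_label()] per list instead of
#'   the iterative strategy (for comparison).
#' @param ... passed to [iterative_label()].
#' @return label data frame over all lists.
#' @export
cascade_label <- function(lacs, exons, standard_only = FALSE, ...) {
  out <- list()
  remaining <- lacs
  for (lid in sort(unique(exons$list_id))) {
    if (nrow(remaining) == 0L) break
    b <- build_boundaries(exons[exons$list_id == lid, , drop = FALSE])
    labels <- if (standard_only) standard_label(remaining, b)
    else iterative_label(remaining, b, ...)$labels
    out[[length(out) + 1L]] <- labels
    remaining <- remaining[!(remaining$lac_id %in% labels$lac_id), ,
                           drop = FALSE]
  }
  labels <- if (length(out)) do.call(rbind, out) else
    iterative_label(lacs[0, , drop = FALSE], build_boundaries(exons[0, ]))$labels
  rownames(labels) <- NULL
  labels
}
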