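# Defragmentation of hit records into element copies, the >50%-of-query
# coverage filter, and full/deletion-derivative variant assignment.

#' Merge collinear hit fragments into element copies
#'
#' Annotation tools report one diverged, interrupted copy as several
#' fragments. Two fragments chain iff they share family, contig and
#' strand, their genomic gap is at most `max_gap_bp` (a small genomic
#' overlap up to `max_query_overlap_bp` is tolerated), their query
#' intervals are collinear with the strand (query order follows genomic
#' order on `+`, is reversed on `-`), and their query overlap is at most
#' `max_query_overlap_bp`. Chains are built greedily left-to-right along
#' the genome, each fragment joining the nearest admissible open chain.
#' Every hit ends up in exactly one copy; unchainable hits become
#' single-fragment copies.
#'
#' @param hits a `mite_hits` data frame.
#' @param query_lengths named integer vector: consensus length per family
#'   (`query_id`), used for query coverage.
#' @param max_gap_bp maximum genomic gap between chained fragments
#'   (default 500).
#' @param max_query_overlap_bp maximum overlap of chained query intervals
#'   (default 20).
#' @return a `data.frame` of class `element_copies`: `copy_id`, `family`,
#'   `contig`, `start`, `end` (0-based half-open, spanning all fragments),
#'   `strand`, `n_fragments`, `query_coverage`, and a list-column
#'   `fragments` holding each copy's hit rows.
#' @export
merge_fragments <- function(hits, query_lengths, max_gap_bp = 500L,
                            max_query_overlap_bp = 20L) {
  if (nrow(hits) == 0L) return(empty_copies())
  missing_q <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(missing_q)) stopf("no query length for family '%s'", missing_q[1])
  o <- order(hits$target_id, hits$strand, hits$query_id, hits$target_start,
             hits$target_end)
  h <- hits[o, , drop = FALSE]
  n <- nrow(h)
  chain_of <- integer(n)
  t_start <- h$target_start; t_end <- h$target_end
  q_start <- h$query_start; q_end <- h$query_end
  strand <- h$strand
  key <- paste(h$target_id, h$strand, h$query_id)
  # open chains: last fragment index per chain, keyed by (contig,strand,family)
  open_last <- integer(0)
  chain_key <- character(0)
  n_chain <- 0L
  for (i in seq_len(n)) {
    cand <- which(chain_key == key[i] &
                    t_end[open_last] >= t_start[i] - max_gap_bp)
    best <- 0L
    if (length(cand)) {
      last_idx <- open_last[cand]
      gap <- t_start[i] - t_end[last_idx]
      admissible <- gap <= max_gap_bp & gap >= -max_query_overlap_bp
      if (strand[i] == "+") {
        q_ok <- q_start[i] >= q_end[last_idx] - max_query_overlap_bp &
          q_start[i] >= q_start[last_idx]
      } else {
        q_ok <- q_end[i] <= q_start[last_idx] + max_query_overlap_bp &
          q_end[i] <= q_end[last_idx]
      }
      admissible <- admissible & q_ok
      if (any(admissible)) {
        # nearest admissible: the open chain ending closest to this fragment
        best <- cand[admissible][which.max(t_end[last_idx][admissible])]
      }
    }
    if (best > 0L) {
      chain_of[i] <- best
      open_last[best] <- i
    } else {
      n_chain <- n_chain + 1L
      chain_of[i] <- n_chain
      open_last[n_chain] <- i
      chain_key[n_chain] <- key[i]
    }
  }
  rows <- lapply(seq_len(n_chain), function(cid) {
    f <- h[chain_of == cid, , drop = FALSE]
    fam <- f$query_id[1]
    cov <- interval_union_length(f$query_start, f$query_end) /
      query_lengths[[fam]]
    data.frame(copy_id = NA_character_, family = fam,
               contig = f$target_id[1], start = min(f$target_start),
               end = max(f$target_end), strand = f$strand[1],
               n_fragments = nrow(f), query_coverage = cov,
               stringsAsFactors = FALSE)
  })
  copies <- do.call(rbind, rows)
  frag_list <- lapply(seq_len(n_chain), function(cid) {
    h[chain_of == cid, , drop = FALSE]
  })
  o2 <- order(copies$contig, copies$start, copies$end)
  copies <- copies[o2, , drop = FALSE]
  copies$fragments <- frag_list[o2]
  copies$copy_id <- sprintf("cp%05d", seq_len(nrow(copies)))
  rownames(copies) <- NULL
  class(copies) <- c("element_copies", "data.frame")
  copies
}

empty_copies <- function() {
  structure(data.frame(copy_id = character(0), family = character(0),
                       contig = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       n_fragments = integer(0), query_coverage = numeric(0),
                       fragments = I(list()), stringsAsFactors = FALSE),
            class = c("element_copies", "data.frame"))
}

#' Filter copies by query coverage
#'
#' Keeps copies whose union of fragment query intervals covers strictly
#' more than `min_fraction` of the consensus — the classic >50% rule that
#' prevents a full-length family and its deletion derivative from
#' cross-matching each other's copies.
#'
#' @param copies an `element_copies` data frame.
#' @param min_fraction strict lower bound on `query_coverage` (default
#'   0.5).
#' @return the surviving copies, unchanged.
#' @export
filter_by_coverage <- function(copies, min_fraction = 0.5) {
  out <- copies[copies$query_coverage > min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign full/deletion-derivative variant from deletion-window coverage
#'
#' For each copy, the fraction of the master's deletion window covered by
#' the union of the copy's fragment query intervals decides the call:
#' below `derivative_max` (default 10%) the copy is a
#' `deletion_derivative`; above `full_min` (default 50%) it is `full`;
#' anything between is `ambiguous`.
#'
#' @param copies an `element_copies` data frame.
#' @param master a `master_element` with `deletion_window` set.
#' @param derivative_max,full_min window-coverage thresholds.
#' @return `copies` with added columns `window_coverage` and `variant`.
#' @export
assign_variant <- function(copies, master, derivative_max = 0.1,
                           full_min = 0.5) {
  dw <- master$deletion_window
  if (is.null(dw)) stopf("master has no deletion_window")
  w_len <- dw[2] - dw[1]
  wc <- vapply(copies$fragments, function(f) {
    if (is.null(f) || nrow(f) == 0L) return(0)
    s <- pmax(f$query_start, dw[1])
    e <- pmin(f$query_end, dw[2])
    keep <- s < e
    interval_union_length(s[keep], e[keep]) / w_len
  }, numeric(1))
  copies$window_coverage <- wc
  copies$variant <- ifelse(wc < derivative_max, "deletion_derivative",
                           ifelse(wc > full_min, "full", "ambiguous"))
  copies
}

#' Write copies as BED6 (+ variants TSV)
#'
#' @param copies an `element_copies` data frame.
#' @param path BED output path; a TSV with coverage/variant columns goes
#'   to `<path>.tsv`.
#' @export
write_copies <- function(copies, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.3f\t%s", copies$contig, copies$start,
                     copies$end, copies$copy_id, copies$query_coverage,
                     copies$strand), path)
  cols <- intersect(c("copy_id", "family", "contig", "start", "end", "strand",
                      "n_fragments", "query_coverage", "window_coverage",
                      "variant"), names(copies))
  utils::write.table(as.data.frame(copies)[, cols], paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
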