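# Genomic context of element copies: genes +/- flanking regions,
# transcript sub-features, and species-by-context independence tests.

copies_granges <- function(copies) {
  GenomicRanges::GRanges(copies$contig,
                         IRanges::IRanges(start = copies$start + 1L,
                                          end = copies$end))
}

features_granges <- function(features) {
  GenomicRanges::GRanges(features$contig,
                         IRanges::IRanges(start = features$start + 1L,
                                          end = features$end))
}

#' Classify copies as genic / flank-only / intergenic
#'
#' A copy is *genic* iff its interval shares at least one base with any
#' gene interval extended by `flank_bp` on both sides (strand-agnostic,
#' half-open arithmetic); *flank-only* iff genic but not overlapping the
#' unextended gene. Extended intervals are clipped at contig ends when
#' `contig_lengths` is given. Copies on contigs absent from the
#' annotation are counted as non-genic with a warning.
#'
#' @param copies an `element_copies` data frame (any data frame with
#'   `contig`, `start`, `end` works).
#' @param genes a `gene_features` data frame; only `gene` rows are used.
#' @param flank_bp flanking-region width (default 5000).
#' @param contig_lengths optional named integer vector for clipping.
#' @return list of class `context_table`: `n_total`, `n_genic`,
#'   `n_gene_body`, `n_flank_only`, `percent_genic`, plus a logical
#'   per-copy data frame `per_copy`.
#' @export
genic_overlap <- function(copies, genes, flank_bp = 5000L,
                          contig_lengths = NULL) {
  g <- genes[genes$feature_kind == "gene", , drop = FALSE]
  n_total <- nrow(copies)
  if (n_total == 0L) {
    return(structure(list(n_total = 0L, n_genic = 0L, n_gene_body = 0L,
                          n_flank_only = 0L, percent_genic = NaN,
                          per_copy = data.frame()),
                     class = "context_table"))
  }
  unknown <- setdiff(unique(copies$contig), unique(g$contig))
  if (length(unknown) && nrow(g)) {
    warning(sprintf("%d copies on contigs without annotation counted as non-genic",
                    sum(copies$contig %in% unknown)))
  }
  ext_start <- pmax(g$start - flank_bp, 0L)
  ext_end <- g$end + flank_bp
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[g$contig]
    ext_end <- pmin(ext_end, ifelse(is.na(lim), ext_end, lim))
  }
  cr <- copies_granges(copies)
  # suppress GenomicRanges' own cross-seqlevel chatter: disjoint contig
  # sets are already reported above
  genic <- suppressWarnings(IRanges::overlapsAny(
    cr, GenomicRanges::GRanges(g$contig,
                               IRanges::IRanges(ext_start + 1L, ext_end))))
  body <- suppressWarnings(IRanges::overlapsAny(cr, features_granges(g)))
  per_copy <- data.frame(copy_id = copies$copy_id %||% seq_len(n_total),
                         genic = genic, gene_body = body,
                         flank_only = genic & !body,
                         stringsAsFactors = FALSE)
  structure(list(n_total = n_total, n_genic = sum(genic),
                 n_gene_body = sum(body), n_flank_only = sum(genic & !body),
                 percent_genic = 100 * sum(genic) / n_total,
                 per_copy = per_copy),
            class = "context_table")
}

#' @export
print.context_table <- function(x, ...) {
  cat(sprintf("<context_table> %d copies: %.1f%% genic (%d gene body, %d flank only)\n",
              x$n_total, x$percent_genic, x$n_gene_body, x$n_flank_only))
  invisible(x)
}

#' Chi-square test of context-by-species independence
#'
#' Pearson chi-square without continuity correction on a k x 2 table of
#' genic vs non-genic counts per species; df = k - 1.
#'
#' @param table integer matrix, one row per species, columns
#'   `c(genic, non_genic)`.
#' @return list with `chi2`, `df`, `p`.
#' @export
independence_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L) stopf("need at least 2 species")
  if (any(rowSums(table) == 0)) stopf("zero row sum in contingency table")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' All pairwise species comparisons with Bonferroni correction
#'
#' Each species pair is tested with a 2x2 chi-square (no continuity
#' correction); raw p-values are Bonferroni-corrected over all
#' `k (k - 1) / 2` comparisons.
#'
#' @param table integer matrix as in [independence_test()], with species
#'   rownames.
#' @param alpha significance level applied to corrected p-values
#'   (default 0.01).
#' @return data frame: `species_i`, `species_j`, `chi2`, `p_raw`,
#'   `p_bonferroni`, `significant`.
#' @export
posthoc_pairwise <- function(table, alpha = 0.01) {
  table <- as.matrix(table)
  k <- nrow(table)
  if (k < 3L) stopf("need at least 3 species for a meaningful correction")
  sp <- rownames(table) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    res <- independence_test(table[c(i, j), , drop = FALSE])
    data.frame(species_i = sp[i], species_j = sp[j], chi2 = res$chi2,
               p_raw = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Classify genic copies by transcript sub-feature
#'
#' Each copy overlapping an `mRNA` feature is classified by the
#' sub-feature(s) it intersects, with priority `CDS` > `five_prime_UTR` >
#' `three_prime_UTR` when it overlaps several; copies overlapping a
#' `lncRNA` are counted separately; mRNA-overlapping copies hitting no
#' annotated sub-feature fall into `other`.
#'
#' @param copies an `element_copies` data frame.
#' @param features a `gene_features` data frame containing `mRNA` rows and
#'   their `CDS`/UTR children (linked by `parent_id`).
#' @return list with `counts` (named vector over `five_prime_UTR`, `CDS`,
#'   `three_prime_UTR`, `lncRNA`, `other`) and per-copy `classification`.
#' @export
transcript_context <- function(copies, features) {
  cr <- copies_granges(copies)
  in_kind <- function(kind) {
    f <- features[features$feature_kind == kind, , drop = FALSE]
    if (nrow(f) == 0L) return(rep(FALSE, nrow(copies)))
    IRanges::overlapsAny(cr, features_granges(f))
  }
  mrna <- features[features$feature_kind == "mRNA", , drop = FALSE]
  in_mrna <- if (nrow(mrna)) IRanges::overlapsAny(cr, features_granges(mrna))
             else rep(FALSE, nrow(copies))
  hit_cds <- in_kind("CDS")
  hit_5 <- in_kind("five_prime_UTR")
  hit_3 <- in_kind("three_prime_UTR")
  hit_lnc <- in_kind("lncRNA")
  cls <- rep(NA_character_, nrow(copies))
  cls[in_mrna] <- "other"
  cls[in_mrna & hit_3] <- "three_prime_UTR"
  cls[in_mrna & hit_5] <- "five_prime_UTR"
  cls[in_mrna & hit_cds] <- "CDS"
  counts <- c(five_prime_UTR = sum(cls == "five_prime_UTR", na.rm = TRUE),
              CDS = sum(cls == "CDS", na.rm = TRUE),
              three_prime_UTR = sum(cls == "three_prime_UTR", na.rm = TRUE),
              lncRNA = sum(hit_lnc),
              other = sum(cls == "other", na.rm = TRUE))
  list(counts = counts,
       classification = data.frame(
         copy_id = copies$copy_id %||% seq_len(nrow(copies)),
         mrna_context = cls, lncRNA = hit_lnc, stringsAsFactors = FALSE))
}
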